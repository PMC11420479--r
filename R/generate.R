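#' Configuration for the synthetic case-table generator
#'
#' Defaults reproduce the shape of the femicide case table the package is
#' designed around: 491 cases of intimate partner violence abstracted
#' from penal sentences, of which 161 are femicides (IPF, the positive
#' class), stratified into a disengagement-coping cluster (G1) and an
#' engagement-coping cluster (G2), with 39 coded predictors and
#' per-variable missingness at the rates given by [default_schema()].
#' The planted generating model defaults to [reference_model()].
#'
#' @param n_cases number of rows to generate.
#' @param n_positive number of positive-class (outcome 1) rows; used by
#'   the `"rank"` outcome rule.
#' @param cluster_proportions named fractions for clusters; must sum
#'   to 1.
#' @param schema predictor schema as returned by [default_schema()];
#'   columns `name`, `coding`, `missingness` and (for binary codings)
#'   `prevalence`.
#' @param planted an [lmm_coefficients] object giving the latent
#'   generating model over the interaction-expanded feature space.
#' @param noise_sd standard deviation of the Gaussian noise added to the
#'   latent score.
#' @param outcome_rule `"rank"` labels the `n_positive` largest latent
#'   scores positive (exact class balance); `"threshold"` labels scores
#'   strictly above 0.5 positive and ignores `n_positive`.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_cases = 491,
                             n_positive = 161,
                             cluster_proportions = c(G1 = 0.5, G2 = 0.5),
                             schema = default_schema(),
                             planted = reference_model(),
                             noise_sd = 0.3,
                             outcome_rule = c("rank", "threshold"),
                             seed = NULL) {
  outcome_rule <- match.arg(outcome_rule)
  if (n_cases < 1) stop("n_cases must be positive")
  if (n_positive < 0 || n_positive > n_cases)
    stop("n_positive must lie in [0, n_cases]")
  if (is.null(names(cluster_proportions)) || length(cluster_proportions) < 1)
    stop("cluster_proportions must be a named vector")
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster proportions must sum to 1")
  req <- c("name", "coding", "missingness")
  if (!all(req %in% names(schema)))
    stop("schema must have columns: ", paste(req, collapse = ", "))
  if (any(schema$missingness < 0 | schema$missingness > 1))
    stop("missingness rates must lie in [0, 1]")
  if (anyDuplicated(schema$name)) stop("duplicate predictor names in schema")
  if (!inherits(planted, "lmm_coefficients"))
    stop("planted must be an lmm_coefficients object")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_cases = n_cases, n_positive = n_positive,
                 cluster_proportions = cluster_proportions,
                 schema = schema, planted = planted, noise_sd = noise_sd,
                 outcome_rule = outcome_rule, seed = seed),
            class = "generator_config")
}

# draw one predictor column of length n according to its schema row
draw_predictor <- function(n, coding, prevalence) {
  switch(coding,
         binary = stats::rbinom(n, 1, if (is.na(prevalence)) 0.3 else prevalence),
         ordinal3 = sample(coding_levels("ordinal3"), n, replace = TRUE),
         ordinal5 = sample(coding_levels("ordinal5"), n, replace = TRUE),
         # zero-inflated sentence duration: absent for ~60% of cases,
         # otherwise exponential with mean 12 months
         duration = ifelse(stats::runif(n) < 0.6, 0,
                           stats::rexp(n, rate = 1 / 12)),
         stop("unknown coding: ", coding))
}

#' Generate a synthetic case table from a planted mixed linear model
#'
#' Draws predictors column-by-column from the schema marginals, assigns
#' cluster labels, computes a latent continuous score `fixed part +
#' cluster random part + N(0, noise_sd^2)` on the 0-1 scaled,
#' interaction-expanded complete data, converts the score to a binary
#' outcome (rank thresholding by default, so the positive count is hit
#' exactly), and finally blanks predictor cells completely at random at
#' each column's configured missingness rate.
#'
#' The latent score of every row is retained as `attr(x, "latent")`; it
#' is the quantity parameter-recovery studies fit against.
#'
#' @param config a [generator_config()].
#' @return A `case_table`: a data frame with one column per schema
#'   predictor plus `outcome` (0/1) and `cluster`, with attributes
#'   `schema`, `latent` and `seed`.
#' @export
#' @examples
#' cfg <- generator_config(n_cases = 60, n_positive = 20, seed = 7)
#' tab <- generate_cases(cfg)
#' sum(tab$outcome)  # 20
generate_cases <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_cases
  sch <- config$schema
  K <- nrow(sch)

  X <- matrix(NA_real_, n, K, dimnames = list(NULL, sch$name))
  for (j in seq_len(K))
    X[, j] <- draw_predictor(n, sch$coding[j],
                             if ("prevalence" %in% names(sch)) sch$prevalence[j] else NA)

  cluster <- sample(names(config$cluster_proportions), n, replace = TRUE,
                    prob = config$cluster_proportions)

  # latent score is defined on the scaled, expanded complete data
  Xs <- apply(X, 2, scale_minmax)
  expanded <- expand_interactions(Xs)
  need <- setdiff(unlist(lapply(c(list(config$planted$fixed),
                                  config$planted$random), names)),
                  "(Intercept)")
  if (length(setdiff(need, colnames(expanded))))
    stop("planted model names features absent from the expanded schema: ",
         paste(setdiff(need, colnames(expanded)), collapse = ", "))
  latent <- score_linear(config$planted, expanded, cluster)
  if (config$noise_sd > 0)
    latent <- latent + stats::rnorm(n, 0, config$noise_sd)

  if (config$outcome_rule == "rank") {
    ord <- order(latent, decreasing = TRUE)
    k <- config$n_positive
    if (k > 0 && k < n && latent[ord[k]] == latent[ord[k + 1]])
      stop("cannot reach n_positive exactly: tied latent scores at the ",
           "class boundary")
    outcome <- integer(n)
    outcome[ord[seq_len(k)]] <- 1L
  } else {
    outcome <- as.integer(latent > 0.5)
  }

  # missing completely at random, per-column rate
  for (j in seq_len(K)) {
    r <- sch$missingness[j]
    if (r > 0) X[stats::runif(n) < r, j] <- NA
  }

  case_table(as.data.frame(X), outcome, cluster, schema = sch,
             latent = latent, seed = config$seed)
}

#' Construct and validate a case table
#'
#' @param predictors data frame of predictor columns (missing values
#'   allowed), one column per schema row, in schema order.
#' @param outcome integer 0/1 vector, no missing values.
#' @param cluster cluster label vector, no missing values.
#' @param schema predictor schema; defaults to [default_schema()].
#' @param latent optional latent score vector kept as an attribute.
#' @param seed optional seed recorded as an attribute.
#' @return A `case_table` data frame.
#' @export
case_table <- function(predictors, outcome, cluster,
                       schema = default_schema(), latent = NULL,
                       seed = NULL) {
  predictors <- as.data.frame(predictors)
  if (!identical(names(predictors), schema$name))
    stop("predictor columns must match the schema names in order")
  n <- nrow(predictors)
  if (length(outcome) != n || length(cluster) != n)
    stop("outcome and cluster must have one entry per row")
  if (anyNA(outcome)) stop("outcome must not contain missing values")
  if (anyNA(cluster)) stop("cluster must not contain missing values")
  if (n > 0 && !all(outcome %in% c(0, 1)))
    stop("outcome must be coded 0/1")
  for (j in seq_len(nrow(schema)))
    check_coding(predictors[[j]], schema$coding[j],
                 id = sprintf("column '%s'", schema$name[j]))
  out <- predictors
  out$outcome <- as.integer(outcome)
  out$cluster <- as.character(cluster)
  structure(out, class = c("case_table", "data.frame"),
            schema = schema, latent = latent, seed = seed)
}

#' Write / read a case table as CSV
#'
#' RFC-4180 CSV with a header row; missing cells are written as empty
#' fields.  `read_case_table()` validates every predictor column against
#' its coding and errors naming the offending row and column.
#'
#' @param table a `case_table`.
#' @param path file path.
#' @return `write_case_table()` returns `path` invisibly;
#'   `read_case_table()` returns a `case_table`.
#' @export
write_case_table <- function(table, path) {
  stopifnot(inherits(table, "case_table"))
  df <- as.data.frame(table)
  # full-precision numeric formatting so the round trip is lossless
  for (j in seq_along(df))
    if (is.double(df[[j]])) {
      v <- df[[j]]
      df[[j]] <- ifelse(is.na(v), NA, sprintf("%.17g", v))
    }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_case_table
#' @param schema schema the file is validated against.
#' @export
read_case_table <- function(path, schema = default_schema()) {
  df <- utils::read.csv(path, na.strings = "", check.names = FALSE,
                        colClasses = "character")
  need <- c(schema$name, "outcome", "cluster")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("case-table file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  pred <- df[schema$name]
  for (j in seq_along(pred)) {
    v <- suppressWarnings(as.numeric(pred[[j]]))
    bad <- which(!is.na(pred[[j]]) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   pred[[j]][bad[1]], schema$name[j], bad[1]))
    pred[[j]] <- v
  }
  outcome <- suppressWarnings(as.numeric(df$outcome))
  case_table(pred, outcome, df$cluster, schema = schema)
}

#' @export
print.case_table <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Case table: %d cases, %d positive (outcome = 1)\n",
              n, sum(x$outcome)))
  if (n) print(table(cluster = x$cluster, outcome = x$outcome))
  miss <- vapply(x[setdiff(names(x), c("outcome", "cluster"))],
                 function(col) sum(is.na(col)), integer(1))
  cat(sprintf("Missing predictor cells: %d (%.2f%% of entries)\n",
              sum(miss), if (n) 100 * sum(miss) / (n * length(miss)) else 0))
  invisible(x)
}
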