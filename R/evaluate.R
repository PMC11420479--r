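#' Threshold a continuous score into class labels
#'
#' The 0-1 regression classification rule: a case is assigned the
#' positive class when its predicted score is strictly above the
#' threshold; scores at or below the threshold (including ties) go to
#' the negative class.
#'
#' @param scores numeric vector of finite scores.
#' @param threshold decision threshold (default 0.5).
#' @return Integer 0/1 labels.
#' @export
#' @examples
#' classify(c(0.49, 0.5, 0.51))  # 0 0 1
classify <- function(scores, threshold = 0.5) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  as.integer(scores > threshold)
}

#' Confusion matrix for 0/1 labels
#'
#' Rows are actual classes (C0 = negative first, C1 = positive second),
#' columns are predicted classes in the same order.
#'
#' @param actual,predicted equal-length 0/1 vectors.
#' @return 2 x 2 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted) {
  if (length(actual) == 0) stop("empty input")
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  if (!all(actual %in% c(0, 1)) || !all(predicted %in% c(0, 1)))
    stop("labels must be coded 0/1")
  cm <- matrix(0L, 2, 2,
               dimnames = list(actual = c("C0", "C1"),
                               predicted = c("C0", "C1")))
  for (a in 0:1) for (p in 0:1)
    cm[a + 1, p + 1] <- sum(actual == a & predicted == p)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Correct classification rates from a confusion matrix
#'
#' @param cm 2 x 2 confusion matrix, rows = actual (C0 first), columns
#'   = predicted.
#' @return Named numeric: `ccr` (global), `ccr_c0` and `ccr_c1`
#'   (row-normalized diagonal; `NaN` when the class is absent).
#' @export
#' @examples
#' cm <- matrix(c(208, 27, 13, 80), 2, 2)  # rows: actual C0, C1
#' ccr_metrics(cm)["ccr"]  # 288/328
ccr_metrics <- function(cm) {
  cm <- unclass(as.matrix(cm))
  if (!all(dim(cm) == c(2, 2))) stop("cm must be 2 x 2")
  if (any(cm < 0)) stop("counts must be non-negative")
  c(ccr = (cm[1, 1] + cm[2, 2]) / sum(cm),
    ccr_c0 = cm[1, 1] / sum(cm[1, ]),
    ccr_c1 = cm[2, 2] / sum(cm[2, ]))
}

#' Regression metrics of a continuous fit
#'
#' @param actual observed values.
#' @param fitted predicted values.
#' @return Named numeric: `rmse` (root mean squared error) and `r2`
#'   (`1 - SSE/SST`, `NA` when the actual values have zero variance).
#' @export
regression_metrics <- function(actual, fitted) {
  n <- length(actual)
  if (n < 2) stop("need at least 2 cases")
  if (n != length(fitted)) stop("actual and fitted must have equal length")
  sse <- sum((actual - fitted)^2)
  sst <- sum((actual - mean(actual))^2)
  c(rmse = sqrt(sse / n),
    r2 = if (sst == 0) NA_real_ else 1 - sse / sst)
}

# metrics of one scored split
split_metrics <- function(actual, scores, threshold) {
  pred <- classify(scores, threshold)
  cm <- confusion(actual, pred)
  c(ccr_metrics(cm), regression_metrics(actual, scores))
}

#' Repeated hold-out evaluation of the full pipeline
#'
#' Repeats `n_repeats` times: randomly split the case table into a
#' training part (`floor(train_fraction * N)` cases) and a test part,
#' preprocess, select the model structure by the `m + 1` GA runs on the
#' training data, fit the mixed model, score both parts, and record
#' confusion-matrix, CCR, RMSE and R-squared metrics.  Metrics are
#' aggregated as mean and standard deviation over repeats, and the
#' best-performing repeat (highest test CCR, ties broken by test CCR of
#' the positive class) is returned in full.
#'
#' A split is redrawn (up to 100 times) if its training part lacks one
#' of the two outcome classes or one of the clusters.
#'
#' @param table a `case_table`.
#' @param config a [ga_config()]; the default uses a sparse initial
#'   gene density because the candidate pool (780 features) is wider
#'   than any realistic training sample.
#' @param n_repeats number of random splits (default 30).
#' @param train_fraction fraction of cases assigned to training
#'   (default 0.66).
#' @param window_length imputation window span.
#' @param threshold classification threshold (default 0.5).
#' @param preprocess_mode `"split"` (default) learns scaling and
#'   imputation statistics on the training part only and replays them on
#'   the test part; `"pooled"` preprocesses the full table once before
#'   splitting.
#' @param seed master seed; the whole experiment is reproducible from
#'   it.
#' @return An `eval_report`: `repeats` (per-split metric frame),
#'   `summary` (mean/sd per metric), `best` (index, fit, model spec and
#'   confusion matrices of the best repeat), and the experiment
#'   settings.
#' @export
holdout_experiment <- function(table,
                               config = ga_config(init_density = 0.02),
                               n_repeats = 30,
                               train_fraction = 0.66,
                               window_length = 100,
                               threshold = 0.5,
                               preprocess_mode = c("split", "pooled"),
                               seed = NULL) {
  stopifnot(inherits(table, "case_table"))
  preprocess_mode <- match.arg(preprocess_mode)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  N <- nrow(table)
  n_train <- floor(train_fraction * N)
  if (n_train < 2 || N - n_train < 1) stop("table too small for the split")
  cfg <- config
  cfg$seed <- NULL  # runs draw from the master RNG stream

  pooled <- if (preprocess_mode == "pooled")
    preprocess(table, window_length) else NULL

  rows <- list()
  best <- NULL
  for (r in seq_len(n_repeats)) {
    ok <- FALSE
    for (try in seq_len(100)) {
      idx_train <- sort(sample.int(N, n_train))
      tr_out <- table$outcome[idx_train]
      tr_cl <- table$cluster[idx_train]
      if (length(unique(tr_out)) == 2 &&
          setequal(unique(tr_cl), unique(table$cluster))) { ok <- TRUE; break }
    }
    if (!ok) stop("could not draw a training split containing both ",
                  "classes and every cluster")
    idx_test <- setdiff(seq_len(N), idx_train)

    if (preprocess_mode == "split") {
      ds_tr <- preprocess(reclass_case_table(table[idx_train, , drop = FALSE],
                                             table), window_length)
      ds_te <- preprocess(reclass_case_table(table[idx_test, , drop = FALSE],
                                             table), window_length,
                          state = ds_tr$state)
    } else {
      ds_tr <- design_subset(pooled, idx_train)
      ds_te <- design_subset(pooled, idx_test)
    }

    spec <- select_model(ds_tr, cfg)
    fit <- lmm_fit(ds_tr, spec)
    sc_tr <- fit$fitted
    sc_te <- predict(fit, ds_te$features, ds_te$cluster)

    m_tr <- split_metrics(ds_tr$outcome, sc_tr, threshold)
    m_te <- split_metrics(ds_te$outcome, sc_te, threshold)
    row <- c(repeat_index = r,
             stats::setNames(m_tr, paste0("train_", names(m_tr))),
             stats::setNames(m_te, paste0("test_", names(m_te))))
    rows[[r]] <- row

    better <- is.null(best) ||
      m_te[["ccr"]] > best$test_ccr ||
      (m_te[["ccr"]] == best$test_ccr && m_te[["ccr_c1"]] > best$test_ccr_c1)
    if (better) {
      best <- list(repeat_index = r, fit = fit, spec = spec,
                   test_ccr = m_te[["ccr"]], test_ccr_c1 = m_te[["ccr_c1"]],
                   cm_train = confusion(ds_tr$outcome,
                                        classify(sc_tr, threshold)),
                   cm_test = confusion(ds_te$outcome,
                                       classify(sc_te, threshold)))
    }
  }

  repeats <- as.data.frame(do.call(rbind, rows))
  metric_cols <- setdiff(names(repeats), "repeat_index")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(repeats[metric_cols], mean, numeric(1)),
    sd = vapply(repeats[metric_cols], stats::sd, numeric(1)),
    row.names = NULL)

  structure(list(repeats = repeats, summary = summary, best = best,
                 settings = list(n_repeats = n_repeats,
                                 train_fraction = train_fraction,
                                 n_train = n_train,
                                 window_length = window_length,
                                 threshold = threshold,
                                 preprocess_mode = preprocess_mode,
                                 ga = config, seed = seed)),
            class = "eval_report")
}

# subsetting a case_table with [ drops attributes; restore them
reclass_case_table <- function(df, template) {
  case_table(df[attr(template, "schema")$name], df$outcome, df$cluster,
             schema = attr(template, "schema"))
}

#' @export
print.eval_report <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Hold-out evaluation: %d repeats, %d training cases per split\n",
              s$n_repeats, s$n_train))
  main <- x$summary[x$summary$metric %in%
                      c("test_ccr", "test_ccr_c0", "test_ccr_c1",
                        "test_rmse", "test_r2"), ]
  cat("Test-set metrics (mean +/- sd over repeats):\n")
  for (i in seq_len(nrow(main)))
    cat(sprintf("  %-12s %.4f +/- %.4f\n", main$metric[i],
                main$mean[i], main$sd[i]))
  cat(sprintf("Best repeat: #%d (test CCR %.4f)\n",
              x$best$repeat_index, x$best$test_ccr))
  invisible(x)
}

#' Render an evaluation report to JSON and Markdown files
#'
#' Writes `report.json` (machine-readable: per-repeat metrics, summary,
#' best-repeat coefficient tables and confusion matrices) and
#' `report.md` (a human-readable digest with a coefficient table per
#' effects block in estimate / SE / t layout) into `dir`.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
report_render <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  md_path <- file.path(dir, "report.md")

  best <- report$best
  payload <- list(
    settings = report$settings[c("n_repeats", "train_fraction", "n_train",
                                 "window_length", "threshold",
                                 "preprocess_mode", "seed")],
    repeats = report$repeats,
    summary = report$summary,
    best = list(
      repeat_index = best$repeat_index,
      fixed = best$fit$coef_table$fixed,
      random = best$fit$coef_table$random,
      sigma2 = best$fit$sigma2,
      converged = best$fit$converged,
      cm_train = unclass(best$cm_train),
      cm_test = unclass(best$cm_test)))
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")

  fmt_tab <- function(tab) {
    if (is.null(tab) || nrow(tab) == 0)
      return("*no features selected*\n")
    paste0("| Term | Estimate | SE | t |\n|---|---|---|---|\n",
           paste(sprintf("| %s | %.3f | %.3f | %.3f |",
                         tab$term, tab$estimate, tab$se, tab$t),
                 collapse = "\n"), "\n")
  }
  fmt_cm <- function(cm)
    sprintf("|  | pred C0 | pred C1 |\n|---|---|---|\n| actual C0 | %d | %d |\n| actual C1 | %d | %d |\n",
            cm[1, 1], cm[1, 2], cm[2, 1], cm[2, 2])

  md <- c(
    "# Hold-out evaluation report", "",
    sprintf("%d repeats, train fraction %.2f, threshold %.2f, preprocessing: %s.",
            report$settings$n_repeats, report$settings$train_fraction,
            report$settings$threshold, report$settings$preprocess_mode), "",
    "## Metric summary (mean +/- sd over repeats)", "",
    "| Metric | Mean | SD |", "|---|---|---|",
    sprintf("| %s | %.4f | %.4f |", report$summary$metric,
            report$summary$mean, report$summary$sd), "",
    sprintf("## Best repeat (#%d)", best$repeat_index), "",
    "### Fixed effects", "", fmt_tab(best$fit$coef_table$fixed))
  for (g in names(best$fit$coef_table$random))
    md <- c(md, sprintf("### Random effects, cluster %s", g), "",
            fmt_tab(best$fit$coef_table$random[[g]]))
  md <- c(md, "### Confusion matrices", "", "Training:", "",
          fmt_cm(best$cm_train), "Test:", "", fmt_cm(best$cm_test))
  writeLines(md, md_path)

  invisible(c(json = json_path, md = md_path))
}

#' Reload the serialized portion of an evaluation report
#'
#' @param path a `report.json` written by [report_render()].
#' @return A list with `settings`, `repeats`, `summary` and `best`
#'   elements mirroring the serialized report.
#' @export
report_load <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
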