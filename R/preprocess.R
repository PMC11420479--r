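#' Linearly scale a column to the unit interval
#'
#' Observed entries are mapped by `(x - min) / (max - min)`; missing
#' entries are left missing.  A constant column maps to all zeros, which
#' keeps the design matrix well defined (such a column carries no
#' information and variable selection will simply never keep it).
#'
#' @param x numeric vector, possibly with `NA`s.
#' @param id column identifier used in error messages.
#' @return Scaled vector of the same length, `NA`s preserved.
#' @export
#' @examples
#' scale_minmax(c(2, 4, 6))        # 0, 0.5, 1
#' scale_minmax(c(0, NA, 10, 5))   # 0, NA, 1, 0.5
scale_minmax <- function(x, id = "column") {
  obs <- !is.na(x)
  if (!any(obs)) stop("cannot scale ", id, ": all values missing")
  r <- range(x[obs])
  if (r[1] == r[2]) {
    x[obs] <- 0
  } else {
    x[obs] <- (x[obs] - r[1]) / (r[2] - r[1])
  }
  x
}

#' Impute missing entries by a moving-window median
#'
#' Each missing entry is replaced by the median of the observed values
#' inside a window centred on it: `floor(window_length / 2)` positions to
#' each side, truncated at the ends of the vector.  Rows are taken in
#' dataset order.  If the window around a missing entry contains no
#' observed value the whole-column observed median is used instead.
#' Originally observed entries are never altered.
#'
#' @param x numeric vector in dataset row order.
#' @param window_length window span; the default of 100 gives 50
#'   neighbours on each side.
#' @param id column identifier used in error messages.
#' @return Complete numeric vector.
#' @export
#' @examples
#' impute_moving_median(c(1, NA, 3), window_length = 3)  # 1, 2, 3
impute_moving_median <- function(x, window_length = 100, id = "column") {
  if (window_length < 1) stop("window_length must be >= 1")
  obs <- !is.na(x)
  if (!any(obs)) stop("cannot impute ", id, ": all values missing")
  if (all(obs)) return(x)
  half <- floor(window_length / 2)
  global_med <- stats::median(x[obs])
  out <- x
  for (i in which(!obs)) {
    lo <- max(1L, i - half)
    hi <- min(length(x), i + half)
    w <- x[lo:hi]
    w <- w[!is.na(w)]
    out[i] <- if (length(w)) stats::median(w) else global_med
  }
  out
}

#' Expand a feature matrix with all first-order interactions
#'
#' Appends to the `K` original columns all `choose(K, 2)` unordered
#' pairwise elementwise products, in lexicographic order of the column
#' index pair `(i, j)`, `i < j`.  Interaction columns are named
#' `"a:b"` from the parent names.  With unit-interval inputs every
#' product stays in the unit interval.
#'
#' @param X complete numeric matrix (no missing values), `K >= 2`
#'   columns.
#' @return Matrix with `K + K(K-1)/2` columns (780 when `K = 39`).
#' @export
#' @examples
#' X <- matrix(c(1, 0, 0.5), 1, 3,
#'             dimnames = list(NULL, c("a", "b", "c")))
#' expand_interactions(X)  # 1 0 0.5 0 0.5 0
expand_interactions <- function(X) {
  X <- as.matrix(X)
  K <- ncol(X)
  if (K < 2) stop("interaction expansion requires at least 2 columns")
  if (anyNA(X)) stop("interaction expansion requires complete data")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(K))
  pairs <- utils::combn(K, 2)
  inter <- X[, pairs[1, ], drop = FALSE] * X[, pairs[2, ], drop = FALSE]
  colnames(inter) <- paste(colnames(X)[pairs[1, ]],
                           colnames(X)[pairs[2, ]], sep = ":")
  cbind(X, inter)
}

#' Preprocess a case table into a model-ready design set
#'
#' Runs the three preprocessing steps in order: 0-1 scaling of every
#' predictor column, moving-window median imputation of the scaled
#' columns, and first-order interaction expansion.  Scaling parameters
#' and per-column imputation counts are recorded in the result so the
#' identical transformation can be replayed on held-out data (pass the
#' returned `state`): held-out columns are scaled with the training
#' min/max (clipped to the unit interval) and their missing cells filled with the
#' training column medians.
#'
#' @param table a `case_table`.
#' @param window_length imputation window span (default 100).
#' @param state a `state` element from a previous `preprocess()` call;
#'   when supplied, scaling and imputation statistics are taken from it
#'   instead of being learned from `table`.
#' @return A `design_set`: list with `features` (N x (K + K(K-1)/2)
#'   matrix of unit-interval values), `outcome`, `cluster`, `feature_names`, `schema`,
#'   `state` (per-column min, max, median) and `imputation_log`
#'   (per-column number of imputed cells).
#' @export
preprocess <- function(table, window_length = 100, state = NULL) {
  stopifnot(inherits(table, "case_table"))
  schema <- attr(table, "schema")
  X <- as.matrix(table[schema$name])
  K <- ncol(X)
  n_imputed <- integer(K)

  if (is.null(state)) {
    mins <- meds <- maxs <- numeric(K)
    for (j in seq_len(K)) {
      obs <- !is.na(X[, j])
      if (!any(obs))
        stop("cannot preprocess: column '", schema$name[j],
             "' is entirely missing")
      mins[j] <- min(X[obs, j]); maxs[j] <- max(X[obs, j])
      X[, j] <- scale_minmax(X[, j], id = paste0("column '", schema$name[j], "'"))
      n_imputed[j] <- sum(!obs)
      X[, j] <- impute_moving_median(X[, j], window_length,
                                     id = paste0("column '", schema$name[j], "'"))
      meds[j] <- stats::median(X[obs, j])
    }
    state <- list(min = stats::setNames(mins, schema$name),
                  max = stats::setNames(maxs, schema$name),
                  median = stats::setNames(meds, schema$name),
                  window_length = window_length)
  } else {
    for (j in seq_len(K)) {
      nm <- schema$name[j]
      lo <- state$min[[nm]]; hi <- state$max[[nm]]
      v <- X[, j]
      obs <- !is.na(v)
      v[obs] <- if (hi > lo) (v[obs] - lo) / (hi - lo) else 0
      v[obs] <- pmin(1, pmax(0, v[obs]))
      n_imputed[j] <- sum(!obs)
      v[!obs] <- state$median[[nm]]
      X[, j] <- v
    }
  }

  features <- expand_interactions(X)
  structure(list(features = features,
                 feature_names = colnames(features),
                 outcome = table$outcome,
                 cluster = table$cluster,
                 schema = schema,
                 state = state,
                 imputation_log = stats::setNames(n_imputed, schema$name)),
            class = "design_set")
}

#' @export
print.design_set <- function(x, ...) {
  cat(sprintf("Design set: %d cases x %d features (%d original + %d interactions)\n",
              nrow(x$features), ncol(x$features), nrow(x$schema),
              ncol(x$features) - nrow(x$schema)))
  cat(sprintf("Imputed cells: %d; clusters: %s\n",
              sum(x$imputation_log),
              paste(names(table(x$cluster)), collapse = ", ")))
  invisible(x)
}

# subset the rows of a design set (used by the hold-out harness)
design_subset <- function(design, idx) {
  structure(list(features = design$features[idx, , drop = FALSE],
                 feature_names = design$feature_names,
                 outcome = design$outcome[idx],
                 cluster = design$cluster[idx],
                 schema = design$schema,
                 state = design$state,
                 imputation_log = design$imputation_log),
            class = "design_set")
}
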