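# --- linear-algebra helpers -------------------------------------------------

# Solve A x = b for a Gram matrix A, falling back to the Moore-Penrose
# pseudoinverse when A is singular (collinear interaction sets proposed
# during variable selection must not crash the fit).
gram_solve <- function(A, b, warn_id = NULL) {
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    if (!is.null(warn_id))
      warning("singular normal equations in ", warn_id,
              "; using pseudoinverse", call. = FALSE)
    out <- MASS::ginv(A) %*% b
  }
  out
}

# inverse of a Gram matrix with pseudoinverse fallback
gram_inv <- function(A) {
  out <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(out)) out <- MASS::ginv(A)
  out
}

# symmetrize then clip negative eigenvalues to zero
make_psd <- function(D) {
  S <- (D + t(D)) / 2
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  out <- e$vectors %*% (ev * t(e$vectors))
  (out + t(out)) / 2
}

# --- estimation building blocks --------------------------------------------

#' Ordinary least-squares fixed-effects estimate
#'
#' Computes `beta = (P'P)^{-1} P' y`, the initial fixed-effects estimate
#' of the iterative scheme.  Rank-deficient `P'P` is handled by the
#' Moore-Penrose pseudoinverse.
#'
#' @param P design matrix (N x p, p >= 1).
#' @param y response vector.
#' @return Coefficient vector of length `p` (named when `P` has column
#'   names).
#' @export
ols_fixed <- function(P, y) {
  P <- as.matrix(P)
  if (ncol(P) < 1 || nrow(P) < 1) stop("empty design matrix")
  if (nrow(P) != length(y)) stop("nrow(P) must equal length(y)")
  beta <- gram_solve(crossprod(P), crossprod(P, y))
  stats::setNames(as.vector(beta), colnames(P))
}

#' Per-cluster random-effects estimate
#'
#' Least-squares regression of a cluster's fixed-effects residual on its
#' random-effects design: `b = (Z'Z)^{-1} Z' r` with
#' `resid = y_i - P_i beta`.
#'
#' @param Z cluster random-effects design matrix (n_i x z_i, z_i >= 1).
#' @param residual the cluster's residual vector `y_i - P_i beta`.
#' @return Coefficient vector of length `z_i`.
#' @export
random_effects <- function(Z, residual) {
  Z <- as.matrix(Z)
  if (ncol(Z) < 1) stop("random-effects design must have >= 1 column")
  if (nrow(Z) != length(residual)) stop("nrow(Z) must equal length(residual)")
  b <- gram_solve(crossprod(Z), crossprod(Z, residual),
                  warn_id = "random-effects estimation")
  stats::setNames(as.vector(b), colnames(Z))
}

#' Pooled residual-variance estimate
#'
#' `sigma2 = sum_i e_i' e_i / (N - sum_i z_i)`: the residual sum of
#' squares pooled over clusters, divided by the degrees of freedom left
#' after the random-effects columns.
#'
#' @param eps_list list of per-cluster residual vectors
#'   `y_i - P_i beta - Z_i b_i`.
#' @param N total number of cases.
#' @param z_total total number of random-effects columns over clusters.
#' @return Non-negative scalar.
#' @export
variance_estimate <- function(eps_list, N, z_total) {
  if (N <= z_total)
    stop("non-positive degrees of freedom: N must exceed the total ",
         "number of random-effects columns")
  sum(vapply(eps_list, function(e) sum(e^2), numeric(1))) / (N - z_total)
}

#' Random-effects covariance-scale estimate
#'
#' Moment estimator `D = sum_i b_i b_i' / (m sigma2) -
#' sum_i (Z_i'Z_i)^{-1} / m`, symmetrized and eigenvalue-clipped at zero
#' so the result is symmetric nonnegative definite as the model requires
#' (the raw moment formula subtracts a matrix and can dip below PSD).
#' All `b_i` must share one dimension; clusters with differently sized
#' random sets are handled per cluster (`m = 1` each) by the fitting
#' routine.
#'
#' @param b_list list of per-cluster random-effects vectors, all of
#'   length `q`.
#' @param Z_list list of the matching random-effects design matrices.
#' @param sigma2 residual variance estimate (> 0).
#' @return `q x q` PSD matrix; the unprojected matrix is attached as
#'   `attr(, "raw")`.
#' @export
d_estimate <- function(b_list, Z_list, sigma2) {
  q <- unique(vapply(b_list, length, integer(1)))
  if (length(q) != 1)
    stop("all clusters must share the same random-effects dimension ",
         "for a pooled D estimate")
  if (sigma2 <= 0) stop("sigma2 must be positive for the D estimate")
  m <- length(b_list)
  bb <- Reduce(`+`, lapply(b_list, function(b) tcrossprod(as.vector(b))))
  gi <- Reduce(`+`, lapply(Z_list, function(Z) gram_inv(crossprod(as.matrix(Z)))))
  raw <- bb / (m * sigma2) - gi / m
  out <- make_psd(raw)
  attr(out, "raw") <- raw
  out
}

#' Weighted least-squares fixed-effects estimate
#'
#' Re-estimates the fixed effects as `beta = (P'WP)^{-1} P'W y` with the
#' block-diagonal weight `W = blockdiag{ (Z_i D_i Z_i' + I)^{-1} }`.
#' The blocks are formed and inverted per cluster; the full N x N weight
#' matrix is never materialized.
#'
#' @param P fixed-effects design matrix over all cases.
#' @param y response vector.
#' @param cluster cluster label per row.
#' @param Z_list named list (by cluster label) of random-effects design
#'   matrices, rows matching that cluster's rows of `P`; a cluster may
#'   be absent or `NULL` (its weight block is the identity).
#' @param D_list a single PSD matrix shared by all clusters, or a named
#'   list of per-cluster PSD matrices.
#' @return Coefficient vector of length `ncol(P)`.
#' @export
wls_fixed <- function(P, y, cluster, Z_list = list(), D_list = NULL) {
  P <- as.matrix(P)
  if (ncol(P) < 1) stop("empty design matrix")
  cluster <- as.character(cluster)
  labels <- unique(cluster)
  A <- matrix(0, ncol(P), ncol(P))
  v <- numeric(ncol(P))
  for (g in labels) {
    idx <- which(cluster == g)
    Pg <- P[idx, , drop = FALSE]
    yg <- y[idx]
    Zg <- Z_list[[g]]
    if (is.null(Zg) || ncol(as.matrix(Zg)) == 0) {
      A <- A + crossprod(Pg)
      v <- v + crossprod(Pg, yg)
    } else {
      Zg <- as.matrix(Zg)
      Dg <- if (is.list(D_list)) D_list[[g]] else D_list
      if (is.null(Dg)) stop("no D matrix supplied for cluster ", g)
      if (min(eigen((Dg + t(Dg)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values) < -1e-8)
        stop("D must be positive semidefinite (project it first)")
      M <- Zg %*% Dg %*% t(Zg) + diag(length(idx))
      Wg <- chol2inv(chol(M))
      WPg <- Wg %*% Pg
      A <- A + crossprod(Pg, WPg)
      v <- v + crossprod(WPg, yg)
    }
  }
  beta <- gram_solve(A, v, warn_id = "weighted least squares")
  stats::setNames(as.vector(beta), colnames(P))
}

# --- model specification ----------------------------------------------------

#' Specify the fixed and random structure of a mixed linear model
#'
#' A model specification names which expanded features enter the shared
#' fixed-effects part, and, per cluster, which features (plus optionally
#' a cluster-specific intercept) enter that cluster's random-effects
#' part.
#'
#' @param fixed character vector of feature names for the fixed effects.
#' @param random named list (by cluster label) of character vectors of
#'   feature names; may be empty vectors.
#' @param intercept named logical, one entry per cluster in `random`:
#'   whether the cluster has a random intercept.
#' @return A `model_spec` object.
#' @export
#' @examples
#' model_spec(fixed = "frequency_of_violence",
#'            random = list(G1 = "history_sexual_aggression",
#'                          G2 = character(0)),
#'            intercept = c(G1 = TRUE, G2 = TRUE))
model_spec <- function(fixed, random = list(),
                       intercept = stats::setNames(rep(TRUE, length(random)),
                                                   names(random))) {
  fixed <- as.character(fixed)
  if (anyDuplicated(fixed)) stop("duplicate fixed-effect feature names")
  if (length(random) && is.null(names(random)))
    stop("random must be a named list (cluster labels)")
  if (!setequal(names(intercept), names(random)))
    stop("intercept flags must match the clusters of `random`")
  structure(list(fixed = fixed,
                 random = lapply(random, as.character),
                 intercept = intercept),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model specification\n")
  cat("  fixed effects (", length(x$fixed), "): ",
      paste(x$fixed, collapse = ", "), "\n", sep = "")
  for (g in names(x$random))
    cat("  random effects ", g, " (intercept: ",
        x$intercept[[g]], "): ",
        paste(x$random[[g]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# build the Z matrix for one cluster from a spec
build_Z <- function(features, spec, g) {
  cols <- spec$random[[g]]
  Z <- features[, cols, drop = FALSE]
  if (isTRUE(spec$intercept[[g]]))
    Z <- cbind(`(Intercept)` = 1, Z)
  Z
}

# --- full iterative fit ------------------------------------------------------

#' Fit a multilevel linear mixed model by iterative (weighted) least squares
#'
#' Estimates the model `y_i = P_i beta + Z_i b_i + eps_i` for clusters
#' `G_i` under `eps_i ~ N(0, sigma2 I)`, `b_i ~ N(0, sigma2 D)`:
#' the fixed effects are initialized by ordinary least squares, each
#' cluster's random effects are estimated by least squares on the fixed
#' residual, `sigma2` and `D` follow from the moment formulas, the fixed
#' effects are then re-estimated by weighted least squares with
#' `W = blockdiag{(Z_i D Z_i' + I)^{-1}}`, and the cycle repeats until
#' the largest change in `(beta, sigma2)` relative to `max(|old|, 1)`
#' drops below `tol`.
#'
#' When the clusters' random sets have equal dimension `D` is estimated
#' jointly (pooled over clusters); with unequal dimensions a per-cluster
#' `D` is estimated (the pooled moment formula requires one shared
#' dimension).  `D` is projected to the nearest symmetric PSD matrix
#' after each update.
#'
#' @param design a `design_set` from [preprocess()], or any list with
#'   `features`, `outcome`, `cluster`.
#' @param spec a [model_spec()].
#' @param tol convergence tolerance (default `1e-6`).
#' @param max_iter iteration cap (default 100).
#' @return An `lmm_fit`: coefficients (`beta`, per-cluster `b`),
#'   `sigma2`, `D` (named list per cluster), `fitted`, `residuals`,
#'   `converged`, `n_iterations`, per-iteration `history`, and
#'   Table-style coefficient frames (`coef_table`) with standard errors
#'   and t statistics.
#' @export
lmm_fit <- function(design, spec, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(spec, "model_spec"))
  X <- design$features
  y <- design$outcome
  cluster <- as.character(design$cluster)
  N <- length(y)
  labels <- names(spec$random)
  extra <- setdiff(unique(cluster), labels)
  if (length(labels) && length(extra))
    stop("data contain cluster label(s) absent from the spec: ",
         paste(extra, collapse = ", "))

  p <- length(spec$fixed)
  P <- X[, spec$fixed, drop = FALSE]
  groups <- lapply(stats::setNames(labels, labels),
                   function(g) which(cluster == g))
  Z_list <- lapply(stats::setNames(labels, labels), function(g) {
    Z <- build_Z(X, spec, g)[groups[[g]], , drop = FALSE]
    if (ncol(Z) == 0) NULL else Z
  })
  z_sizes <- vapply(Z_list, function(Z) if (is.null(Z)) 0L else ncol(Z),
                    integer(1))
  z_total <- sum(z_sizes)
  if (N <= z_total + 0)
    stop("not enough cases for the requested random-effects structure")
  for (g in labels)
    if (!is.null(Z_list[[g]]) && length(groups[[g]]) < z_sizes[[g]])
      stop("cluster ", g, " has fewer cases than random-effects columns")

  beta <- if (p > 0) ols_fixed(P, y) else numeric(0)
  fixed_part <- if (p > 0) as.vector(P %*% beta) else rep(0, N)

  b_list <- stats::setNames(vector("list", length(labels)), labels)
  D_list <- stats::setNames(vector("list", length(labels)), labels)
  sigma2 <- NA_real_
  history <- data.frame(iteration = integer(0), delta = numeric(0),
                        sigma2 = numeric(0))
  converged <- FALSE
  iter <- 0L

  if (z_total == 0) {
    # no random structure anywhere: the model is plain OLS
    eps <- y - fixed_part
    sigma2 <- sum(eps^2) / N
    converged <- TRUE
    iter <- 1L
    history <- data.frame(iteration = 1L, delta = 0, sigma2 = sigma2)
  } else {
    repeat {
      iter <- iter + 1L
      eps_list <- list()
      for (g in labels) {
        idx <- groups[[g]]
        r <- y[idx] - fixed_part[idx]
        if (is.null(Z_list[[g]])) {
          b_list[[g]] <- numeric(0)
          eps_list[[g]] <- r
        } else {
          b_list[[g]] <- random_effects(Z_list[[g]], r)
          eps_list[[g]] <- r - as.vector(Z_list[[g]] %*% b_list[[g]])
        }
      }
      sigma2_new <- variance_estimate(eps_list, N, z_total)

      active <- labels[z_sizes > 0]
      qs <- z_sizes[active]
      if (length(active)) {
        s2 <- max(sigma2_new, 1e-12)
        if (length(unique(qs)) == 1 && length(active) > 1) {
          Dpool <- d_estimate(b_list[active], Z_list[active], s2)
          for (g in active) D_list[[g]] <- Dpool
        } else {
          for (g in active)
            D_list[[g]] <- d_estimate(b_list[g], Z_list[g], s2)
        }
      }

      beta_new <- if (p > 0)
        wls_fixed(P, y, cluster, Z_list, D_list) else numeric(0)

      if (any(!is.finite(c(beta_new, sigma2_new))))
        stop("estimation diverged (non-finite values) at iteration ", iter)

      old <- c(beta, sigma2)
      new <- c(beta_new, sigma2_new)
      delta <- if (iter == 1L) Inf else
        max(abs(new - old) / pmax(abs(old), 1))
      history <- rbind(history,
                       data.frame(iteration = iter, delta = delta,
                                  sigma2 = sigma2_new))
      beta <- stats::setNames(beta_new, names(beta_new))
      sigma2 <- sigma2_new
      fixed_part <- if (p > 0) as.vector(P %*% beta) else rep(0, N)
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
  }

  fitted <- fixed_part
  for (g in labels) {
    if (is.null(Z_list[[g]])) next
    idx <- groups[[g]]
    fitted[idx] <- fitted[idx] + as.vector(Z_list[[g]] %*% b_list[[g]])
  }

  # standard errors: WLS covariance for beta, per-cluster LS covariance
  # for b (a reporting convention; the scheme itself defines no SEs)
  se_beta <- rep(NA_real_, p)
  if (p > 0) {
    A <- matrix(0, p, p)
    for (g in if (length(labels)) labels else "all") {
      idx <- if (length(labels)) groups[[g]] else seq_len(N)
      Pg <- P[idx, , drop = FALSE]
      Zg <- if (length(labels)) Z_list[[g]] else NULL
      if (is.null(Zg)) {
        A <- A + crossprod(Pg)
      } else {
        M <- Zg %*% D_list[[g]] %*% t(Zg) + diag(length(idx))
        A <- A + crossprod(Pg, chol2inv(chol(M)) %*% Pg)
      }
    }
    se_beta <- sqrt(pmax(diag(gram_inv(A)) * sigma2, 0))
  }
  coef_fixed <- data.frame(term = names(beta),
                           estimate = as.vector(beta),
                           se = se_beta,
                           t = as.vector(beta) / se_beta,
                           row.names = NULL)
  coef_random <- list()
  for (g in labels) {
    if (is.null(Z_list[[g]])) { coef_random[[g]] <- NULL; next }
    seb <- sqrt(pmax(diag(gram_inv(crossprod(Z_list[[g]]))) * sigma2, 0))
    coef_random[[g]] <- data.frame(term = names(b_list[[g]]),
                                   estimate = as.vector(b_list[[g]]),
                                   se = seb,
                                   t = as.vector(b_list[[g]]) / seb,
                                   row.names = NULL)
  }

  structure(list(beta = beta, b = b_list, sigma2 = sigma2, D = D_list,
                 fitted = fitted, residuals = y - fitted,
                 converged = converged, n_iterations = iter,
                 history = history, spec = spec,
                 coef_table = list(fixed = coef_fixed,
                                   random = coef_random)),
            class = "lmm_fit")
}

#' Extract the coefficient set of a fitted model
#'
#' @param fit an `lmm_fit`.
#' @return An [lmm_coefficients] object usable with [score_linear()].
#' @export
coef_set <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  lmm_coefficients(fit$beta, fit$b)
}

#' Predict continuous scores from a fitted mixed model
#'
#' @param object an `lmm_fit`.
#' @param features matrix of (expanded) feature rows.
#' @param cluster cluster label per row; labels must appear in the fit.
#' @param ... unused.
#' @return Numeric score vector (fixed part + cluster random part).
#' @export
predict.lmm_fit <- function(object, features, cluster, ...) {
  score_linear(lmm_coefficients(object$beta, object$b), features, cluster)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Mixed linear model fit: %d fixed terms, %s; sigma2 = %.4g\n",
              length(x$beta),
              if (x$converged)
                sprintf("converged in %d iteration(s)", x$n_iterations)
              else sprintf("NOT converged after %d iterations",
                           x$n_iterations),
              x$sigma2))
  cat("Fixed effects:\n")
  print(x$coef_table$fixed, digits = 4)
  for (g in names(x$coef_table$random)) {
    cat("Random effects,", g, ":\n")
    print(x$coef_table$random[[g]], digits = 4)
  }
  invisible(x)
}
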