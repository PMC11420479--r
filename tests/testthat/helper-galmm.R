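# shared fixtures and independent oracles, built in code

# a small 6-predictor schema for fast end-to-end runs
small_schema <- function(missingness = 0) {
  data.frame(
    name = c("s_bin_a", "s_bin_b", "s_ord3", "s_bin_c", "s_dur", "s_ord5"),
    coding = c("binary", "binary", "ordinal3", "binary", "duration",
               "ordinal5"),
    missingness = rep(missingness, 6),
    prevalence = c(0.4, 0.5, NA, 0.3, NA, NA),
    stringsAsFactors = FALSE)
}

small_planted <- function() {
  lmm_coefficients(
    fixed = c(s_bin_a = 0.7, `s_bin_b:s_ord3` = -0.5),
    random = list(G1 = c(`(Intercept)` = 0.4),
                  G2 = c(`(Intercept)` = -0.2, s_bin_c = 0.6)))
}

small_table <- function(n = 120, n_positive = 40, seed = 1,
                        missingness = 0, noise_sd = 0.2) {
  generate_cases(generator_config(
    n_cases = n, n_positive = n_positive,
    schema = small_schema(missingness), planted = small_planted(),
    noise_sd = noise_sd, seed = seed))
}

# brute-force windowed-median imputation, written independently of the
# package implementation: collect observed neighbours in the index range
# and take their median
oracle_moving_median <- function(x, window_length) {
  half <- floor(window_length / 2)
  out <- x
  for (i in seq_along(x)) {
    if (!is.na(x[i])) next
    neigh <- x[max(1, i - half):min(length(x), i + half)]
    neigh <- neigh[!is.na(neigh)]
    out[i] <- if (length(neigh)) median(neigh) else median(x, na.rm = TRUE)
  }
  out
}

# independent fitness: ordinary lm residuals plus the closed formula
oracle_fitness <- function(genes, X, y, lambda = 4) {
  l <- length(y)
  h <- sum(genes)
  if (h >= l) return(Inf)
  if (h == 0) {
    es2 <- mean((y - mean(y))^2)
  } else {
    r <- residuals(lm.fit(X[, genes == 1, drop = FALSE], y))
    es2 <- sum(r^2) / l
  }
  l * log(max(es2, 1e-12)) + lambda * h * log(l)
}

# exhaustive minimization of the fitness over all non-empty subsets
oracle_exhaustive <- function(X, y, lambda = 4, include_empty = FALSE) {
  L <- ncol(X)
  best <- NULL
  best_f <- Inf
  from <- if (include_empty) 0 else 1
  for (code in from:(2^L - 1)) {
    genes <- as.integer(intToBits(code)[seq_len(L)])
    f <- oracle_fitness(genes, X, y, lambda)
    if (f < best_f) { best_f <- f; best <- genes }
  }
  list(genes = best, fitness = best_f)
}
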