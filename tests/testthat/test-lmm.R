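test_that("OLS initialization matches closed forms and an independent solver", {
  expect_equal(unname(ols_fixed(matrix(1, 2, 1), c(1, 3))), 2)

  # orthonormal columns: beta = P'y
  Q <- qr.Q(qr(matrix(rnorm(30), 10, 3)))
  y <- rnorm(10)
  expect_equal(unname(ols_fixed(Q, y)), as.vector(crossprod(Q, y)))

  set.seed(1)
  P <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(50)
  expect_equal(unname(ols_fixed(P, y)),
               unname(coef(lm.fit(P, y))), tolerance = 1e-10)
  expect_error(ols_fixed(matrix(numeric(0), 5, 0), y[1:5]), "empty design")
})

test_that("random effects solve least squares on the cluster residual", {
  expect_equal(unname(random_effects(matrix(1, 3, 1), c(1, 1, 1))), 1)

  # residual orthogonal to Z: coefficients vanish
  Z <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  r <- c(1, -1, 2, -2)
  expect_equal(unname(random_effects(Z, r)), c(0, 0))

  set.seed(2)
  Z <- matrix(rnorm(80), 20, 4)
  r <- rnorm(20)
  expect_equal(unname(random_effects(Z, r)),
               unname(coef(lm.fit(Z, r))), tolerance = 1e-10)
})

test_that("the pooled residual variance follows its formula", {
  expect_equal(variance_estimate(list(c(1, -1)), N = 2, z_total = 0), 1)
  expect_equal(variance_estimate(list(rep(0, 5), rep(0, 3)), 8, 2), 0)
  e1 <- c(0.5, -0.5, 1); e2 <- c(2, 0)
  expect_equal(variance_estimate(list(e1, e2), N = 5, z_total = 2),
               (sum(e1^2) + sum(e2^2)) / 3)
  expect_error(variance_estimate(list(c(1, 1)), N = 2, z_total = 2),
               "degrees of freedom")
})

test_that("the D estimate matches the moment formula and is projected to PSD", {
  # all-zero random effects: raw D is minus the mean Gram inverse
  Z1 <- diag(2); Z2 <- 2 * diag(2)
  D <- d_estimate(list(c(0, 0), c(0, 0)), list(Z1, Z2), sigma2 = 1)
  raw_expect <- -(solve(crossprod(Z1)) + solve(crossprod(Z2))) / 2
  expect_equal(attr(D, "raw"), raw_expect)
  # negative definite clips to the zero matrix
  expect_equal(matrix(as.numeric(D), 2, 2), matrix(0, 2, 2))

  # single cluster, scalar: b^2/sigma2 - 1/(z'z); 1/1 - 1/1 = 0
  D1 <- d_estimate(list(1), list(matrix(1, 1, 1)), sigma2 = 1)
  expect_equal(as.vector(D1), 0)

  # random instance: raw formula equals direct matrix arithmetic
  set.seed(3)
  Zs <- replicate(2, matrix(rnorm(40), 10, 4), simplify = FALSE)
  bs <- replicate(2, rnorm(4), simplify = FALSE)
  s2 <- 0.7
  D2 <- d_estimate(bs, Zs, s2)
  raw <- (tcrossprod(bs[[1]]) + tcrossprod(bs[[2]])) / (2 * s2) -
    (solve(crossprod(Zs[[1]])) + solve(crossprod(Zs[[2]]))) / 2
  expect_equal(attr(D2, "raw"), raw, tolerance = 1e-10)
  expect_true(min(eigen(unclass(D2), symmetric = TRUE,
                        only.values = TRUE)$values) >= -1e-12)
  expect_error(d_estimate(list(1:2, 1:3), Zs, 1), "same random-effects")
})

test_that("weighted least squares reduces to OLS when D vanishes", {
  set.seed(4)
  P <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(20)
  cl <- rep(c("G1", "G2"), each = 10)
  Z <- list(G1 = matrix(rnorm(20), 10, 2), G2 = matrix(rnorm(20), 10, 2))
  D0 <- matrix(0, 2, 2)
  expect_equal(wls_fixed(P, y, cl, Z, D0), ols_fixed(P, y),
               tolerance = 1e-10)
  # clusters with no random columns also weight as identity
  expect_equal(wls_fixed(P, y, cl, list(G1 = NULL, G2 = NULL)),
               ols_fixed(P, y), tolerance = 1e-10)
})

test_that("blocked WLS equals a dense explicitly-assembled-W solve", {
  set.seed(5)
  n1 <- 12; n2 <- 8; N <- n1 + n2
  P <- matrix(rnorm(N * 3), N, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(N)
  cl <- c(rep("G1", n1), rep("G2", n2))
  Z1 <- matrix(rnorm(n1 * 2), n1, 2)
  Z2 <- matrix(rnorm(n2 * 2), n2, 2)
  A <- matrix(rnorm(4), 2, 2)
  D <- crossprod(A)  # PSD by construction

  W <- matrix(0, N, N)
  W[1:n1, 1:n1] <- solve(Z1 %*% D %*% t(Z1) + diag(n1))
  W[(n1 + 1):N, (n1 + 1):N] <- solve(Z2 %*% D %*% t(Z2) + diag(n2))
  dense <- solve(t(P) %*% W %*% P, t(P) %*% W %*% y)

  expect_equal(unname(wls_fixed(P, y, cl, list(G1 = Z1, G2 = Z2), D)),
               as.vector(dense), tolerance = 1e-8)
  expect_error(wls_fixed(P, y, cl, list(G1 = Z1, G2 = Z2), -diag(2)),
               "positive semidefinite")
})

test_that("a spec without random effects collapses to a one-step OLS fit", {
  tab <- small_table(n = 100, n_positive = 35, seed = 6)
  ds <- preprocess(tab)
  spec <- model_spec(fixed = c("s_bin_a", "s_bin_b:s_ord3"),
                     random = list(G1 = character(0), G2 = character(0)),
                     intercept = c(G1 = FALSE, G2 = FALSE))
  fit <- lmm_fit(ds, spec)
  expect_true(fit$converged)
  expect_equal(fit$n_iterations, 1L)
  expect_equal(fit$beta,
               ols_fixed(ds$features[, spec$fixed], ds$outcome))
  expect_equal(fit$fitted,
               as.vector(ds$features[, spec$fixed] %*% fit$beta))
})

test_that("the iterative fit is deterministic and honestly flagged", {
  tab <- small_table(n = 150, n_positive = 50, seed = 7)
  ds <- preprocess(tab)
  spec <- model_spec(fixed = c("s_bin_a", "s_bin_b:s_ord3"),
                     random = list(G1 = character(0), G2 = "s_bin_c"),
                     intercept = c(G1 = TRUE, G2 = TRUE))
  f1 <- lmm_fit(ds, spec)
  f2 <- lmm_fit(ds, spec)
  expect_identical(f1, f2)
  expect_true(f1$converged)
  expect_true(f1$sigma2 >= 0)
  expect_true(all(diff(f1$history$iteration) == 1))
  # fitted values decompose as fixed part + cluster random part
  coefs <- coef_set(f1)
  expect_equal(f1$fitted,
               score_linear(coefs, ds$features, ds$cluster))
})

test_that("sigma2 is invariant to permuting cases within clusters", {
  tab <- small_table(n = 120, n_positive = 40, seed = 8)
  ds <- preprocess(tab)
  spec <- model_spec(fixed = "s_bin_a",
                     random = list(G1 = "s_bin_b", G2 = character(0)),
                     intercept = c(G1 = TRUE, G2 = TRUE))
  f1 <- lmm_fit(ds, spec)
  set.seed(9)
  perm <- unlist(lapply(split(seq_len(120), ds$cluster), sample),
                 use.names = FALSE)
  ds2 <- ds
  ds2$features <- ds$features[perm, ]
  ds2$outcome <- ds$outcome[perm]
  ds2$cluster <- ds$cluster[perm]
  f2 <- lmm_fit(ds2, spec)
  expect_equal(f1$sigma2, f2$sigma2, tolerance = 1e-8)
})

test_that("random effects never hurt the training fit", {
  tab <- small_table(n = 200, n_positive = 70, seed = 10)
  ds <- preprocess(tab)
  fixed_only <- model_spec(fixed = c("s_bin_a", "s_bin_b:s_ord3"),
                           random = list(G1 = character(0),
                                         G2 = character(0)),
                           intercept = c(G1 = FALSE, G2 = FALSE))
  augmented <- model_spec(fixed = c("s_bin_a", "s_bin_b:s_ord3"),
                          random = list(G1 = character(0), G2 = "s_bin_c"),
                          intercept = c(G1 = TRUE, G2 = TRUE))
  rmse <- function(f) sqrt(mean(f$residuals^2))
  expect_lte(rmse(lmm_fit(ds, augmented)), rmse(lmm_fit(ds, fixed_only)))
})

test_that("prediction applies the cluster-specific part and stays affine", {
  m <- reference_model()
  named <- unique(setdiff(unlist(lapply(c(list(m$fixed), m$random), names)),
                          "(Intercept)"))
  X <- matrix(0, 3, 780)
  colnames(X) <- c(named, paste0("pad", seq_len(780 - length(named))))
  # worked examples from the published coefficient table
  X1 <- X; X1[, "frequency_of_violence"] <- 1
  expect_equal(score_linear(lmm_coefficients(m$fixed), X1, rep("G1", 3))[1],
               0.852)
  expect_equal(score_linear(m, X, c("G1", "G2", "G1"))[1:2],
               c(0.568, -0.275))
  expect_error(score_linear(m, X, c("G1", "G3", "G1")), "unknown cluster")

  # affine in any single feature holding the rest fixed
  f <- function(v) {
    Xi <- X; Xi[, "frequency_of_violence"] <- v
    score_linear(m, Xi, rep("G1", 3))[1]
  }
  expect_equal(f(0.75) - f(0.25), 2 * (f(0.5) - f(0.25)))
})
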