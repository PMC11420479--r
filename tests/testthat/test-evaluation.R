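test_that("classification is strict at the threshold", {
  expect_equal(classify(c(0.49, 0.5, 0.51)), c(0L, 0L, 1L))
  expect_equal(classify(c(0.2, 0.7), threshold = 0), c(1L, 1L))
  expect_error(classify(c(0.1, NA)), "finite")
  # positives are non-increasing in the threshold
  set.seed(19)
  s <- runif(100)
  counts <- vapply(seq(0, 1, 0.1), function(t) sum(classify(s, t)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("confusion matrices and CCRs reproduce the published arithmetic", {
  # training: rows actual C0 = (208, 13), actual C1 = (27, 80)
  cm_tr <- matrix(c(208, 27, 13, 80), 2, 2,
                  dimnames = list(actual = c("C0", "C1"),
                                  predicted = c("C0", "C1")))
  m_tr <- ccr_metrics(cm_tr)
  expect_equal(unname(round(m_tr["ccr"], 3)), 0.878)
  expect_equal(unname(round(m_tr["ccr_c0"], 3)), 0.941)

  cm_te <- matrix(c(90, 12, 19, 42), 2, 2)
  m_te <- ccr_metrics(cm_te)
  expect_equal(unname(round(m_te["ccr"], 3)), 0.810)
  # the published per-class test rates are printed truncated, so compare
  # at printed precision: 90/109 = 0.8257, 42/54 = 0.7778
  expect_lt(abs(m_te["ccr_c0"] - 0.825), 1e-3)
  expect_lt(abs(m_te["ccr_c1"] - 0.777), 1e-3)
  expect_equal(unname(m_te["ccr_c1"]), 42 / 54)

  # perfect prediction
  perfect <- confusion(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(ccr_metrics(perfect)), c(1, 1, 1))
  expect_equal(unclass(perfect),
               matrix(c(2L, 0L, 0L, 2L), 2, 2,
                      dimnames = dimnames(perfect)))
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("global CCR is the class-size-weighted mean of per-class CCRs", {
  set.seed(20)
  for (i in 1:10) {
    a <- rbinom(60, 1, 0.4)
    p <- rbinom(60, 1, 0.5)
    if (length(unique(a)) < 2) next
    cm <- confusion(a, p)
    m <- ccr_metrics(cm)
    n0 <- sum(a == 0); n1 <- sum(a == 1)
    expect_equal(unname(m["ccr"]),
                 unname((m["ccr_c0"] * n0 + m["ccr_c1"] * n1) / (n0 + n1)))
    # invariant under a common permutation of case order
    perm <- sample(60)
    expect_identical(unclass(confusion(a[perm], p[perm])), unclass(cm))
  }
})

test_that("regression metrics match the textbook formulas", {
  expect_equal(unname(regression_metrics(c(1, 2, 3), c(1, 2, 3))), c(0, 1))
  y <- c(0, 1, 1, 0, 1)
  m <- regression_metrics(y, rep(mean(y), 5))
  expect_equal(unname(m["r2"]), 0)
  set.seed(21)
  a <- rnorm(40); f <- a + rnorm(40, 0, 0.3)
  m2 <- regression_metrics(a, f)
  expect_equal(unname(m2["rmse"]), sqrt(mean((a - f)^2)))
  expect_equal(unname(m2["r2"]), 1 - sum((a - f)^2) / sum((a - mean(a))^2))
  expect_true(is.na(regression_metrics(c(1, 1), c(1, 2))["r2"]))
})

test_that("the hold-out split follows the floor convention at the study size", {
  tab <- generate_cases(generator_config(seed = 23))
  rep1 <- holdout_experiment(
    tab, config = ga_config(population_size = 8, generations = 2,
                            init_density = 0.01),
    n_repeats = 1, seed = 1)
  expect_equal(rep1$settings$n_train, 324)  # floor(0.66 * 491); test = 167
})

test_that("the hold-out experiment is reproducible and sanely aggregated", {
  tab <- small_table(n = 140, n_positive = 45, seed = 24,
                     missingness = 0.05)
  cfg <- ga_config(population_size = 10, generations = 8,
                   init_density = 0.1)
  r1 <- holdout_experiment(tab, cfg, n_repeats = 3, seed = 42)
  r2 <- holdout_experiment(tab, cfg, n_repeats = 3, seed = 42)
  expect_identical(r1$repeats, r2$repeats)
  expect_identical(r1$best$repeat_index, r2$best$repeat_index)

  ccr <- r1$repeats$test_ccr
  mean_ccr <- r1$summary$mean[r1$summary$metric == "test_ccr"]
  expect_gte(mean_ccr, min(ccr))
  expect_lte(mean_ccr, max(ccr))
  expect_true(all(r1$repeats$train_ccr >= 0 & r1$repeats$train_ccr <= 1))
  # the best repeat attains the maximal test CCR
  expect_equal(r1$best$test_ccr, max(ccr))
})

test_that("reports render to JSON and Markdown and reload intact", {
  tab <- small_table(n = 120, n_positive = 40, seed = 25)
  rep1 <- holdout_experiment(
    tab, ga_config(population_size = 10, generations = 8,
                   init_density = 0.1),
    n_repeats = 2, seed = 7)
  dir <- withr::local_tempdir()
  paths <- report_render(rep1, dir)
  expect_true(file.exists(paths["json"]))
  expect_true(file.exists(paths["md"]))

  back <- report_load(paths["json"])
  expect_equal(back$summary$mean, rep1$summary$mean, tolerance = 1e-12)
  expect_equal(back$best$repeat_index, rep1$best$repeat_index)
  expect_equal(matrix(as.numeric(back$best$cm_test), 2, 2),
               matrix(as.numeric(unclass(rep1$best$cm_test)), 2, 2))

  md <- readLines(paths["md"])
  expect_true(any(grepl("Fixed effects", md)))
  # one rendered row per selected fixed-effect feature
  fixed_tab <- rep1$best$fit$coef_table$fixed
  block <- grep("^### Fixed effects", md)
  if (nrow(fixed_tab) > 0) {
    rows <- grep("^\\| (?!Term)(?!---)", md[(block + 1):length(md)],
                 perl = TRUE)
    expect_gte(length(rows), nrow(fixed_tab))
  } else {
    expect_true(any(grepl("no features selected", md)))
  }
})
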