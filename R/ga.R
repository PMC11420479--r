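#' Configuration for the genetic-algorithm variable search
#'
#' Defaults follow the study settings: population 60, 150 generations,
#' 2% per-gene mutation, complexity weight `lambda = 4` in the BIC-style
#' fitness.  Crossover probability, elitism and the initial gene density
#' are implementation choices (the search scheme leaves them open);
#' survivor selection pools parents and offspring and keeps the best
#' `population_size`, so the best-so-far fitness never worsens.
#'
#' @param population_size even number of individuals (default 60).
#' @param generations number of generations (default 150).
#' @param mutation_rate per-gene flip probability (default 0.02).
#' @param lambda_penalty complexity weight in the fitness (default 4).
#' @param crossover_rate probability a paired couple is crossed rather
#'   than copied (default 0.9).
#' @param init_density probability a gene starts switched on
#'   (default 0.5; use a sparse value such as 0.02 when the candidate
#'   pool is wider than the sample, where dense chromosomes give
#'   saturated, uninformative fits).
#' @param seed optional integer seed for a self-contained reproducible
#'   run; when `NULL` the current RNG stream is used.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 60, generations = 150,
                      mutation_rate = 0.02, lambda_penalty = 4,
                      crossover_rate = 0.9, init_density = 0.5,
                      seed = NULL) {
  if (population_size < 2 || population_size %% 2 != 0)
    stop("population_size must be an even number >= 2")
  if (generations < 1) stop("generations must be >= 1")
  for (r in c(mutation_rate, crossover_rate, init_density))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (lambda_penalty <= 0) stop("lambda_penalty must be positive")
  structure(list(population_size = population_size,
                 generations = generations,
                 mutation_rate = mutation_rate,
                 lambda_penalty = lambda_penalty,
                 crossover_rate = crossover_rate,
                 init_density = init_density,
                 seed = seed),
            class = "ga_config")
}

#' BIC-style fitness of a candidate feature subset
#'
#' `f(s) = l * ln(e_s^2) + lambda * h * ln(l)` where `l` is the sample
#' size, `h` the number of selected features, and `e_s^2` the residual
#' variance (`SSE / l`) of the least-squares fit of the target on the
#' selected columns.  An empty selection scores the variance of the
#' target.  Lower is better; the residual variance is floored at 1e-12
#' so a perfectly explained target keeps a finite fitness.  A subset
#' with at least as many columns as cases (`h >= l`) is unidentifiable
#' — its interpolating fit says nothing about the target — and scores
#' `+Inf`, which also keeps downstream mixed fits well posed.
#'
#' @param genes binary inclusion vector over the candidate columns.
#' @param X candidate feature matrix (`l` rows).
#' @param y target vector.
#' @param lambda_penalty complexity weight.
#' @return Scalar fitness (lower = better).
#' @export
#' @examples
#' # h = 2 selected columns that explain nothing, residual variance 1:
#' # fitness = 0 + 4 * 2 * log(10)
bic_fitness <- function(genes, X, y, lambda_penalty = 4) {
  l <- length(y)
  if (l < 2) stop("fitness requires at least 2 cases")
  h <- sum(genes)
  if (h >= l) return(Inf)  # unidentifiable: p >= n
  if (h == 0) {
    es2 <- mean((y - mean(y))^2)
  } else {
    r <- .lm.fit(X[, genes == 1, drop = FALSE], y)$residuals
    es2 <- sum(r^2) / l
  }
  es2 <- max(es2, 1e-12)
  l * log(es2) + lambda_penalty * h * log(l)
}

#' Single-point crossover of two chromosomes
#'
#' @param a,b binary parent vectors of equal length.
#' @param cut cut position in `1..length-1`: offspring 1 takes
#'   `a[1:cut]` then the tail of `b`, offspring 2 the converse.
#' @return List of two offspring vectors.
#' @export
crossover_single_point <- function(a, b, cut) {
  if (length(a) != length(b)) stop("parents must have equal length")
  if (cut < 1 || cut >= length(a)) stop("cut must lie in 1..length-1")
  head_idx <- seq_len(cut)
  o1 <- a; o1[-head_idx] <- b[-head_idx]
  o2 <- b; o2[-head_idx] <- a[-head_idx]
  list(o1, o2)
}

#' Bit-flip mutation
#'
#' Flips each gene independently with probability `rate`.
#'
#' @param genes binary vector.
#' @param rate per-gene flip probability.
#' @return Mutated binary vector.
#' @export
mutate_genes <- function(genes, rate = 0.02) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  flip <- stats::runif(length(genes)) < rate
  out <- genes
  out[flip] <- 1L - out[flip]
  out
}

#' Run the genetic algorithm on one selection problem
#'
#' Evolves a population of binary chromosomes over the candidate columns
#' of `X`, minimizing [bic_fitness()] against `y`.  Each generation the
#' population is randomly paired (every individual equally likely to be
#' paired with every other), pairs are crossed at a uniform random cut
#' with probability `crossover_rate` (otherwise copied), offspring are
#' bit-flip mutated, and the best `population_size` of parents plus
#' offspring survive.  Returns the best individual ever evaluated.
#'
#' @param X candidate feature matrix with column names.
#' @param y target vector.
#' @param config a [ga_config()].
#' @return A `ga_result`: `genes`, `fitness`, selected column names
#'   (`selected`), and a per-generation `trace` (best/mean fitness and
#'   best-individual size).
#' @export
run_ga <- function(X, y, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  X <- as.matrix(X)
  if (ncol(X) < 1) stop("no candidate columns")
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- ncol(X)
  np <- config$population_size

  eval_pop <- function(mat)
    vapply(seq_len(nrow(mat)),
           function(i) bic_fitness(mat[i, ], X, y, config$lambda_penalty),
           numeric(1))

  pop <- matrix(stats::rbinom(np * L, 1, config$init_density), np, L)
  fit <- eval_pop(pop)
  if (all(!is.finite(fit)))
    stop("all initial individuals have non-finite fitness; with a wide ",
         "candidate pool and few cases, lower init_density so initial ",
         "subsets are identifiable")

  best_i <- which.min(fit)
  best_genes <- pop[best_i, ]
  best_fit <- fit[best_i]
  trace <- data.frame(generation = 0L, best = best_fit,
                      mean = mean(fit), best_h = sum(best_genes))

  for (gen in seq_len(config$generations)) {
    perm <- sample(np)
    off <- matrix(0L, np, L)
    for (k in seq_len(np / 2)) {
      pa <- pop[perm[2 * k - 1], ]
      pb <- pop[perm[2 * k], ]
      if (L > 1 && stats::runif(1) < config$crossover_rate) {
        cut <- sample.int(L - 1, 1)
        ch <- crossover_single_point(pa, pb, cut)
      } else {
        ch <- list(pa, pb)
      }
      off[2 * k - 1, ] <- mutate_genes(ch[[1]], config$mutation_rate)
      off[2 * k, ]     <- mutate_genes(ch[[2]], config$mutation_rate)
    }
    off_fit <- eval_pop(off)
    pool <- rbind(pop, off)
    pool_fit <- c(fit, off_fit)
    if (all(!is.finite(pool_fit)))
      stop("all individuals have non-finite fitness at generation ", gen)
    keep <- order(pool_fit)[seq_len(np)]
    pop <- pool[keep, , drop = FALSE]
    fit <- pool_fit[keep]
    if (fit[1] < best_fit) {
      best_fit <- fit[1]
      best_genes <- pop[1, ]
    }
    trace <- rbind(trace, data.frame(generation = gen, best = best_fit,
                                     mean = mean(fit),
                                     best_h = sum(best_genes)))
  }

  selected <- colnames(X)[best_genes == 1]
  structure(list(genes = best_genes, fitness = best_fit,
                 selected = selected, trace = trace, config = config),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("GA result: fitness %.4f, %d feature(s) selected\n",
              x$fitness, sum(x$genes)))
  if (length(x$selected)) cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Select the model structure by m + 1 genetic-algorithm runs
#'
#' Runs the GA once over all cases to choose the fixed-effects feature
#' set (target: the outcome; candidates: every expanded feature), fits
#' the fixed part by ordinary least squares, and then runs the GA once
#' per cluster on that cluster's residual (`y_i - P_i beta`) with an
#' intercept column added to the candidate pool, to choose each
#' cluster's random-effects set.  With `m` clusters this is `m + 1` GA
#' runs in total.
#'
#' @param design a `design_set` from [preprocess()].
#' @param config a [ga_config()] applied to every run; when it carries a
#'   seed, run `k` uses `seed + k - 1` so the runs are independent but
#'   jointly reproducible.
#' @return A [model_spec()] with attributes `ga_runs` (the `ga_result`
#'   of each run, named) and `fixed_beta` (the interim OLS coefficients
#'   used to form the residual targets).
#' @export
select_model <- function(design, config = ga_config()) {
  stopifnot(inherits(config, "ga_config"))
  X <- design$features
  y <- design$outcome
  cluster <- as.character(design$cluster)
  labels <- sort(unique(cluster))
  for (g in labels)
    if (sum(cluster == g) < 2)
      stop("cluster ", g, " has fewer than 2 cases")

  run_cfg <- function(k) {
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + k - 1
    cfg
  }

  runs <- list()
  runs$fixed <- run_ga(X, y, run_cfg(1))
  fixed_sel <- runs$fixed$selected

  beta <- if (length(fixed_sel))
    ols_fixed(X[, fixed_sel, drop = FALSE], y) else numeric(0)
  fixed_part <- if (length(fixed_sel))
    as.vector(X[, fixed_sel, drop = FALSE] %*% beta) else rep(0, length(y))

  random <- list()
  intercept <- logical(0)
  for (k in seq_along(labels)) {
    g <- labels[k]
    idx <- which(cluster == g)
    target <- y[idx] - fixed_part[idx]
    cand <- cbind(`(Intercept)` = 1, X[idx, , drop = FALSE])
    res <- run_ga(cand, target, run_cfg(k + 1))
    runs[[g]] <- res
    random[[g]] <- setdiff(res$selected, "(Intercept)")
    intercept[g] <- "(Intercept)" %in% res$selected
  }

  spec <- model_spec(fixed = fixed_sel, random = random,
                     intercept = intercept)
  attr(spec, "ga_runs") <- runs
  attr(spec, "fixed_beta") <- beta
  spec
}
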