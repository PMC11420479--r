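#' Default case-table variable schema
#'
#' Returns the 39-predictor schema used throughout the package: criminal
#' records and sentences of intimate-partner-violence (IPV) offences,
#' sentence durations, unregistered criminal history, characteristics of
#' the violence, and environmental/situational descriptors of the crime.
#' Each predictor carries a coding, a default per-column missingness rate
#' (the rate at which entries are absent in case files abstracted from
#' penal sentences), and a default marginal prevalence used by the
#' synthetic generator.
#'
#' Codings:
#' \describe{
#'   \item{binary}{0 = absent, 1 = present}
#'   \item{ordinal3}{0 / 0.5 / 1 (e.g. low / medium / high frequency of
#'     violence)}
#'   \item{ordinal5}{0 / 0.25 / 0.5 / 0.75 / 1 (time of crime: dawn,
#'     morning, afternoon, night, various)}
#'   \item{duration}{non-negative numeric (sentence durations, months)}
#' }
#'
#' @return A data frame with columns `name`, `coding`, `missingness`,
#'   `prevalence` (prevalence is `NA` for non-binary codings).
#' @export
#' @examples
#' sch <- default_schema()
#' nrow(sch)      # 39 predictors
#' table(sch$coding)
default_schema <- function() {
  rec <- function(name, coding, missingness, prevalence = NA_real_) {
    data.frame(name = name, coding = coding, missingness = missingness,
               prevalence = prevalence, stringsAsFactors = FALSE)
  }
  sch <- rbind(
    # criminal records (convictions on record)
    rec("general_criminal_records",            "binary", 0.005, 0.3),
    rec("specific_criminal_records",           "binary", 0.005, 0.3),
    rec("records_injuries",                    "binary", 0.005, 0.3),
    rec("records_threats",                     "binary", 0.005, 0.3),
    rec("records_constraints",                 "binary", 0.005, 0.3),
    rec("records_habitual_violence",           "binary", 0.005, 0.3),
    rec("records_insults",                     "binary", 0.005, 0.3),
    # sentences attached to those records
    rec("custodial_sentence",                  "binary", 0.025, 0.3),
    rec("non_custodial_sentence",              "binary", 0.025, 0.3),
    rec("prison_sentence",                     "binary", 0.025, 0.3),
    rec("weapons_prohibition_sentence",        "binary", 0.025, 0.3),
    rec("approximation_prohibition_sentence",  "binary", 0.025, 0.3),
    rec("communication_prohibition_sentence",  "binary", 0.025, 0.3),
    rec("community_service_sentence",          "binary", 0.025, 0.3),
    rec("fine_sentence",                       "binary", 0.025, 0.3),
    # sentence durations (months)
    rec("prison_duration",                     "duration", 0.025),
    rec("weapons_prohibition_duration",        "duration", 0.025),
    rec("approximation_prohibition_duration",  "duration", 0.025),
    rec("communication_prohibition_duration",  "duration", 0.025),
    rec("community_service_duration",          "duration", 0.025),
    rec("fine_duration",                       "duration", 0.025),
    # unregistered criminal history
    rec("history_injuries",                    "binary", 0.005, 0.3),
    rec("history_illegal_detention",           "binary", 0.005, 0.3),
    rec("history_threats",                     "binary", 0.005, 0.3),
    rec("history_constraints",                 "binary", 0.005, 0.3),
    rec("history_habitual_violence",           "binary", 0.005, 0.3),
    rec("history_sexual_aggression",           "binary", 0.005, 0.3),
    rec("history_sexual_abuse",                "binary", 0.005, 0.3),
    rec("history_invasion_privacy",            "binary", 0.005, 0.3),
    rec("history_insults",                     "binary", 0.005, 0.3),
    # characteristics of the violence
    rec("frequency_of_violence",               "ordinal3", 0.05, NA),
    rec("escalation_of_violence",              "binary", 0.115, 0.3),
    rec("physical_violence",                   "binary", 0.115, 0.3),
    rec("psychological_violence",              "binary", 0.115, 0.3),
    # environment / situation of the crime
    rec("place_of_crime",                      "binary", 0.15, 0.5),
    rec("time_of_crime",                       "ordinal5", 0.10, NA),
    rec("situational_characteristic",          "binary", 0.04, 0.3),
    rec("community_presence",                  "binary", 0.15, 0.3),
    rec("discussion",                          "binary", 0.025, 0.3)
  )
  rownames(sch) <- NULL
  sch
}

#' Admissible values for a coding
#'
#' @param coding one of `"binary"`, `"ordinal3"`, `"ordinal5"`,
#'   `"duration"`.
#' @return A numeric vector of levels, or `NULL` for `duration`
#'   (any non-negative value is admissible).
#' @export
coding_levels <- function(coding) {
  switch(coding,
         binary   = c(0, 1),
         ordinal3 = c(0, 0.5, 1),
         ordinal5 = c(0, 0.25, 0.5, 0.75, 1),
         duration = NULL,
         stop("unknown coding: ", coding))
}

# validate one predictor column against its coding; id used in messages
check_coding <- function(x, coding, id = "column") {
  obs <- which(!is.na(x))
  if (coding == "duration") {
    bad <- obs[x[obs] < 0]
  } else {
    lev <- coding_levels(coding)
    bad <- obs[!x[obs] %in% lev]
  }
  if (length(bad)) {
    stop(sprintf("invalid value %s for coding '%s' in %s, row %d",
                 format(x[bad[1]]), coding, id, bad[1]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Published best-model coefficients
#'
#' The coefficient set of the best-performing fitted model reported for
#' the Spanish penal-sentence femicide study: five fixed-effect terms
#' (all on the frequency/escalation/physical-violence/situational axis),
#' a disengagement-coping (G1) random-effects model with an intercept and
#' a history-of-sexual-aggression slope, and an engagement-coping (G2)
#' random-effects model with an intercept and four interaction slopes.
#' Interaction terms are named `"a:b"` with parents in schema order, the
#' convention produced by [expand_interactions()].
#'
#' Used as the default planted model of the synthetic generator, and as a
#' worked example for [score_linear()].
#'
#' @return An object of class `lmm_coefficients`: a list with elements
#'   `fixed` (named numeric) and `random` (list of named numerics per
#'   cluster, each possibly containing an `"(Intercept)"` entry).
#' @export
#' @examples
#' m <- reference_model()
#' m$fixed["frequency_of_violence"]   # 0.852
reference_model <- function() {
  fixed <- c(
    "frequency_of_violence"                          =  0.852,
    "frequency_of_violence:escalation_of_violence"   =  0.481,
    "frequency_of_violence:community_presence"       = -0.395,
    "physical_violence:situational_characteristic"   =  0.144,
    "history_injuries:situational_characteristic"    = -0.230)
  random <- list(
    G1 = c("(Intercept)"                             =  0.568,
           "history_sexual_aggression"               = -0.858),
    G2 = c("(Intercept)"                             = -0.275,
           "frequency_of_violence:escalation_of_violence" = -0.625,
           "frequency_of_violence:physical_violence" =  0.945,
           "physical_violence:place_of_crime"        = -0.766,
           "place_of_crime:community_presence"       =  0.884))
  lmm_coefficients(fixed, random)
}

#' Construct a coefficient set for a mixed linear scorer
#'
#' @param fixed named numeric vector of fixed-effect coefficients over
#'   (expanded) feature names.
#' @param random named list, one named numeric vector per cluster label;
#'   an `"(Intercept)"` entry is the cluster-specific intercept.
#' @return An `lmm_coefficients` object.
#' @seealso [score_linear()], [reference_model()]
#' @export
lmm_coefficients <- function(fixed, random = list()) {
  stopifnot(is.numeric(fixed))
  if (length(fixed) && is.null(names(fixed)))
    stop("fixed coefficients must be named")
  if (!is.list(random)) stop("random must be a list of named vectors")
  for (g in names(random)) {
    if (length(random[[g]]) && is.null(names(random[[g]])))
      stop("random coefficients for cluster ", g, " must be named")
  }
  structure(list(fixed = fixed, random = random),
            class = "lmm_coefficients")
}

#' Evaluate a mixed linear scorer on feature rows
#'
#' Computes `score = x' beta_fixed + z' b_cluster` for each row, where the
#' cluster-specific part uses the row's cluster label.  This is the
#' noise-free mean of the mixed model, used both for prediction and to
#' plant a generating model in synthetic data.
#'
#' @param coefs an [lmm_coefficients] object.
#' @param features numeric matrix with column names covering every
#'   coefficient name (except `"(Intercept)"`).
#' @param cluster character/factor vector of cluster labels, one per row.
#'   Every label must have an entry in `coefs$random` (possibly empty) if
#'   any random coefficients are present.
#' @return Numeric vector of scores, one per row.
#' @export
#' @examples
#' m <- reference_model()
#' X <- matrix(0, 2, 780)
#' colnames(X) <- paste0("f", seq_len(780))
#' colnames(X)[1:5] <- names(m$fixed)
#' score_linear(m, X, c("G1", "G2"))  # 0.568, -0.275
score_linear <- function(coefs, features, cluster) {
  stopifnot(inherits(coefs, "lmm_coefficients"))
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(cluster) != n)
    stop("cluster must have one label per feature row")
  cluster <- as.character(cluster)

  need <- setdiff(unlist(lapply(c(list(coefs$fixed), coefs$random), names)),
                  "(Intercept)")
  missing_cols <- setdiff(need, colnames(features))
  if (length(missing_cols))
    stop("features lack columns named in the coefficients: ",
         paste(missing_cols, collapse = ", "))

  score <- rep(0, n)
  if (length(coefs$fixed))
    score <- as.vector(features[, names(coefs$fixed), drop = FALSE] %*%
                         coefs$fixed)
  if (length(coefs$random)) {
    unknown <- setdiff(unique(cluster), names(coefs$random))
    if (length(unknown))
      stop("unknown cluster label(s): ", paste(unknown, collapse = ", "))
    for (g in names(coefs$random)) {
      idx <- which(cluster == g)
      if (!length(idx)) next
      cf <- coefs$random[[g]]
      if (!length(cf)) next
      if ("(Intercept)" %in% names(cf))
        score[idx] <- score[idx] + cf[["(Intercept)"]]
      slopes <- cf[setdiff(names(cf), "(Intercept)")]
      if (length(slopes))
        score[idx] <- score[idx] +
          as.vector(features[idx, names(slopes), drop = FALSE] %*% slopes)
    }
  }
  score
}

#' @export
print.lmm_coefficients <- function(x, ...) {
  cat("Mixed linear model coefficients\n")
  cat("Fixed effects (", length(x$fixed), " terms):\n", sep = "")
  if (length(x$fixed)) print(round(x$fixed, 4))
  for (g in names(x$random)) {
    cat("Random effects, cluster ", g, " (", length(x$random[[g]]),
        " terms):\n", sep = "")
    if (length(x$random[[g]])) print(round(x$random[[g]], 4))
  }
  invisible(x)
}
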