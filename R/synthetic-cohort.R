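#' Parameters for a synthetic screening cohort
#'
#' Bundles the knobs of the cohort generator. Defaults emulate the study
#' population the analysis assumes: age groups of 240/225/215 children
#' (ages 4/5/6) with DLD prevalences 0.35/0.26/0.19, and per-question
#' marginal risk-perception rates by condition taken from the observed
#' group percentages (e.g. question 1: 75% among DLD, 37% among TLD).
#' Inter-question dependence follows a one-factor probit model: each child
#' carries a latent severity z and perceives question q as a risk when
#' `rho*z + sqrt(1-rho^2)*e_q` exceeds a threshold calibrated to the
#' marginal rate. `rho = 0` gives independent questions; the default 0.5
#' is a modelling choice (the dependence structure of real cohorts is
#' unknown), not an estimate.
#'
#' @param n_per_age Named integer vector, children per age group
#'   (names "4", "5", "6").
#' @param prevalence_per_age DLD prevalence within each age group.
#' @param p_risk_dld,p_risk_tld Length-8 marginal risk-perception
#'   probabilities per question for the DLD and TLD conditions.
#' @param rho Latent-severity loading in `[0, 1)`.
#' @param becq_params Per-condition distributions for the 11 BECQ
#'   variables; see [default_becq_params()].
#' @param p_missing Probability that any single PLCQ answer is missing
#'   (default 0; nonzero values exercise the listwise-exclusion paths).
#' @param seed Integer seed; one substream per age group is derived from
#'   it so regenerating a single age group is stable.
#' @return An object of class `cohort_params` (a validated list).
#' @export
cohort_params <- function(n_per_age = c("4" = 240, "5" = 225, "6" = 215),
                          prevalence_per_age = c("4" = 0.35, "5" = 0.26,
                                                 "6" = 0.19),
                          p_risk_dld = c(0.75, 0.65, 0.57, 0.49,
                                         0.64, 0.37, 0.41, 0.33),
                          p_risk_tld = c(0.37, 0.19, 0.36, 0.20,
                                         0.19, 0.30, 0.16, 0.09),
                          rho = 0.5,
                          becq_params = default_becq_params(),
                          p_missing = 0,
                          seed = 1L) {
  if (length(n_per_age) != 3L || any(n_per_age < 0)) {
    stop("n_per_age must give nonnegative counts for ages 4, 5, 6",
         call. = FALSE)
  }
  names(n_per_age) <- names(prevalence_per_age) <- c("4", "5", "6")
  probs <- c(prevalence_per_age, p_risk_dld, p_risk_tld, p_missing)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(p_risk_dld) != 8L || length(p_risk_tld) != 8L) {
    stop("p_risk_dld and p_risk_tld must have 8 entries", call. = FALSE)
  }
  if (!is.finite(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  out <- list(n_per_age = n_per_age,
              prevalence_per_age = prevalence_per_age,
              p_risk_dld = p_risk_dld, p_risk_tld = p_risk_tld,
              rho = rho, becq_params = becq_params,
              p_missing = p_missing, seed = as.integer(seed))
  class(out) <- "cohort_params"
  out
}

#' Default per-condition distributions for the BECQ variables
#'
#' Binary flags are Bernoulli; continuous variables are normal truncated
#' below. Preschool-attendance years (`becq17`) get age-specific means of
#' 1.5/2.5/3.5 years (so within-age medians land near the cut points used
#' for dichotomization) with the DLD mean shifted down by
#' `preschool_effect_d` pooled standard deviations (default 0.2, a
#' deliberately conservative group effect). The remaining settings are
#' plausible cohort-level values chosen once and documented in the
#' package vignette; they are generator defaults, not estimates.
#'
#' @param preschool_effect_d Standardized downward shift of the DLD
#'   preschool-years mean.
#' @return A named list of distribution specifications; each entry has a
#'   `type` ("bernoulli" or "truncnorm") and per-condition parameters
#'   (`dld`/`tld` named values).
#' @export
default_becq_params <- function(preschool_effect_d = 0.2) {
  bern <- function(p_dld, p_tld) {
    list(type = "bernoulli", p = c(dld = p_dld, tld = p_tld))
  }
  tnorm <- function(m_dld, m_tld, sd, lower = 0) {
    list(type = "truncnorm", mean = c(dld = m_dld, tld = m_tld),
         sd = sd, lower = lower)
  }
  list(
    becq9  = bern(0.37, 0.44),          # sex (1 = female)
    becq10 = bern(0.15, 0.05),          # motor problems
    becq11 = bern(0.08, 0.03),          # neurological problems
    becq12 = bern(0.12, 0.04),          # psychological problems
    becq13 = tnorm(16, 12, 5, lower = 6),   # first words (months)
    becq14 = tnorm(10.7, 11.9, 3.9),    # maternal education (years)
    becq15 = tnorm(10.9, 11.8, 4.0),    # paternal education (years)
    becq16 = bern(0.25, 0.10),          # family history of language problems
    becq17 = list(type = "preschool",   # preschool attendance (years)
                  mean_by_age = c("4" = 1.5, "5" = 2.5, "6" = 3.5),
                  sd = 1.0, effect_d = preschool_effect_d, lower = 0),
    becq18 = tnorm(1.5, 2.0, 1.0),      # social interaction (h/day)
    becq19 = tnorm(1.0, 1.5, 1.0),      # communicative interaction (h/day)
    becq20 = tnorm(3.0, 2.5, 1.5)       # screen time (h/day)
  )
}

#' Calibrate the latent-model risk threshold for a marginal rate
#'
#' In the one-factor probit model the question-level latent variable
#' `rho*Z + sqrt(1-rho^2)*E` is standard normal for any loading, so the
#' threshold giving marginal exceedance probability `target_rate` is
#' exactly `qnorm(1 - target_rate)`, independent of `rho`.
#'
#' @param target_rate Desired marginal risk probability in (0, 1).
#' @param rho Latent loading (accepted for interface symmetry; the result
#'   does not depend on it).
#' @return The threshold tau. Rates 0 and 1 return `Inf`/`-Inf` with a
#'   warning.
#' @export
calibrate_threshold <- function(target_rate, rho = 0) {
  stopifnot(is.finite(target_rate), target_rate >= 0, target_rate <= 1,
            rho >= 0, rho < 1)
  if (target_rate %in% c(0, 1)) {
    warning("degenerate target rate ", target_rate,
            "; threshold is infinite", call. = FALSE)
    return(if (target_rate == 0) Inf else -Inf)
  }
  stats::qnorm(1 - target_rate)
}

# inverse-CDF sampler for a normal truncated below at `lower`
.rtruncnorm_lower <- function(n, mean, sd, lower) {
  u <- stats::runif(n, stats::pnorm(lower, mean, sd), 1)
  stats::qnorm(u, mean, sd)
}

.sample_becq <- function(spec, n, condition, age) {
  cond <- tolower(condition)
  if (spec$type == "bernoulli") {
    return(stats::rbinom(n, 1L, unname(spec$p[cond])))
  }
  if (spec$type == "truncnorm") {
    return(round(.rtruncnorm_lower(n, unname(spec$mean[cond]), spec$sd,
                                   spec$lower), 2))
  }
  if (spec$type == "preschool") {
    mu <- unname(spec$mean_by_age[as.character(age)])
    mu <- mu - ifelse(cond == "dld", spec$effect_d * spec$sd, 0)
    return(round(.rtruncnorm_lower(n, mu, spec$sd, spec$lower), 2))
  }
  stop("unknown BECQ distribution type: ", spec$type, call. = FALSE)
}

#' Generate a synthetic screening cohort
#'
#' Draws one child-level record per row: condition by age-specific
#' prevalence, the eight PLCQ answers from the one-factor probit model
#' calibrated to the per-condition marginal risk rates, and the BECQ
#' variables from the configured per-condition distributions. Risk
#' indicators are translated back to raw yes/no answers through the
#' questionnaire schema (a "risk" on question 3 or 6 is a "no" answer).
#' The whole cohort is reproducible from `params$seed`; each age group
#' uses its own derived substream so a single age group regenerates
#' identically regardless of the others.
#'
#' @param params A [cohort_params()] object.
#' @return A cohort data.frame (one row per child) with the header
#'   contract of [read_children()].
#' @examples
#' coh <- generate_cohort(cohort_params(n_per_age = c(50, 50, 50), seed = 7))
#' table(coh$condition, coh$age_group)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params")) {
    stop("params must be created by cohort_params()", call. = FALSE)
  }
  sch <- plcq_schema()
  ages <- c(4L, 5L, 6L)
  parts <- vector("list", 3L)
  for (i in seq_along(ages)) {
    age <- ages[i]
    n <- params$n_per_age[[as.character(age)]]
    if (n == 0L) next
    # documented substream scheme: one seed per age group
    set.seed((params$seed + 104729L * i) %% .Machine$integer.max)
    cond <- ifelse(stats::rbinom(n, 1L,
                                 params$prevalence_per_age[[as.character(age)]]) == 1L,
                   "DLD", "TLD")
    z <- stats::rnorm(n)
    risk <- matrix(FALSE, n, 8L)
    answers <- matrix(NA_character_, n, 8L)
    for (q in 1:8) {
      p <- ifelse(cond == "DLD", params$p_risk_dld[q], params$p_risk_tld[q])
      tau <- stats::qnorm(1 - p)
      latent <- params$rho * z +
        sqrt(1 - params$rho^2) * stats::rnorm(n)
      risk[, q] <- latent > tau
      yes_is_risk <- sch$risk_when[q] == "yes"
      answers[, q] <- ifelse(risk[, q] == yes_is_risk, "yes", "no")
      if (params$p_missing > 0) {
        answers[stats::runif(n) < params$p_missing, q] <- NA_character_
      }
    }
    becq <- lapply(params$becq_params, .sample_becq, n = n,
                   condition = cond, age = age)
    part <- data.frame(
      child_id = sprintf("a%d_%04d", age, seq_len(n)),
      age_group = age, condition = cond,
      stringsAsFactors = FALSE
    )
    colnames(answers) <- paste0("q", 1:8)
    part <- cbind(part, as.data.frame(answers, stringsAsFactors = FALSE),
                  as.data.frame(becq))
    parts[[i]] <- part
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) {
    stop("empty cohort: all n_per_age are zero", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
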