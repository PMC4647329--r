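# Synthetic cohort generator.  Emulates the marginal statistical structure
# the analysis assumes -- demographic and history prevalences, day-1
# symptom prevalences, day-1 to day-3 transition rates, NIHSS
# distributions, and a logistic outcome model on the scale's category
# codings -- so the whole pipeline is exercisable without patient data.

#' Default synthetic-cohort parameters
#'
#' Encodes the development-cohort conditions of the published study (413
#' patients from three TCM hospitals): age normal (66.4, 10.8) truncated to
#' 25--95 years, 61.5\% male, history prevalences
#' hypertension/stroke/CHD/DM/AF = 0.608/0.327/0.245/0.199/0.058, day-1
#' symptom prevalences pooled from the published good/poor counts,
#' symptom-specific day-1-to-day-3 transition rates where the study
#' tabulated them, a rounded-lognormal day-1 NIHSS (mean 6.3, SD 4.6), a
#' discretized-normal NIHSS change (mean -0.5, SD 2.25), and a logistic
#' outcome model on the 8 scale category codes with the published
#' coefficients (1.20, 0.79, 1.15, 1.12, 1.53, 0.91, 2.05, 2.58); the
#' intercept is calibrated so the expected poor fraction is 181/413.
#'
#' @param n Cohort size.
#' @param seed Integer RNG seed used by [generate_cohort()].
#' @return Object of class `cohort_params` (a list); see the fields in the
#'   source for the full set.
#' @export
default_params <- function(n = 413, seed = 1) {
  sym_prev <- c(
    spiritlessness        = (107 + 105) / 413,
    anxiety               = (49 + 94) / 413,
    cough_drinking        = (48 + 69) / 413,
    anorexia              = (27 + 39) / 413,
    salivation            = (22 + 31) / 413,
    analeptic             = (17 + 27) / 413,
    limb_flaccid_paralysis = (11 + 28) / 413,
    thirst_hot_drink      = (25 + 9) / 413,
    circumrotating        = (25 + 8) / 413,
    emaciation            = (9 + 24) / 413,
    limb_stiffness        = (12 + 22) / 413,
    tinnitus              = (23 + 5) / 413,
    irritability          = (5 + 18) / 413,
    incontinence_urinary  = (10 + 19) / 413,
    difficult_cough_sputum = 0.10  # day-1 prevalence not tabulated; assumed
  )
  # P(resolve by day 3 | present day 1), P(appear by day 3 | absent day 1);
  # tabulated change counts where the study reports them, else defaults.
  transitions <- list(default = c(resolve = 0.30, appear = 0.02))
  transitions$irritability <- c(resolve = 14 / 23, appear = 3 / (413 - 23))
  transitions$circumrotating <- c(resolve = 15 / 33, appear = 4 / (413 - 33))
  transitions$tinnitus <- c(resolve = 12 / 28, appear = 3 / (413 - 28))
  transitions$difficult_cough_sputum <-
    c(resolve = 8 / (0.10 * 413), appear = 11 / (0.90 * 413))
  params <- list(
    n = n, seed = seed,
    age_mean = 66.4, age_sd = 10.8, age_range = c(25, 95),
    male_prop = 254 / 413,
    history_prev = c(hypertension = 251 / 413, stroke = 135 / 413,
                     chd = 101 / 413, dm = 82 / 413, af = 24 / 413),
    onset_mean = 10.0, onset_sd = 7.17,
    nihss_day1_mean = 6.3, nihss_day1_sd = 4.6,
    delta_nihss_mean = -0.5, delta_nihss_sd = 2.25,
    symptom_prev_day1 = sym_prev,
    change_transitions = transitions,
    outcome_model = list(
      intercept = NULL,  # calibrated on demand
      coefficients = c(age_degree = 1.20, history_dm = 0.79,
                       anxiety_day1 = 1.15, nihss_day1_degree = 1.12,
                       irritability_day1 = 1.53, delta_nihss_degree = 0.91,
                       circumrotating_change = 2.05,
                       tinnitus_change = 2.58)),
    target_poor_prop = 181 / 413
  )
  validate_params(params)
  structure(params, class = "cohort_params")
}

validate_params <- function(p) {
  props <- c(p$male_prop, p$history_prev, p$symptom_prev_day1,
             p$target_poor_prop,
             unlist(p$change_transitions, use.names = FALSE))
  if (any(props < 0 | props > 1)) {
    stop("all proportions/transition probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$n < 1) stop("n must be positive", call. = FALSE)
  invisible(p)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Rounded, clipped lognormal with the requested arithmetic mean/sd.
r_nihss <- function(n, mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  pmin(pmax(round(stats::rlnorm(n, meanlog, sdlog)), 0L), 42L)
}

# Integer NIHSS change from a discretized normal on -10..10.
r_delta <- function(n, mean, sd) {
  support <- -10:10
  prob <- stats::dnorm(support, mean, sd)
  sample(support, n, replace = TRUE, prob = prob / sum(prob))
}

# Draw covariates (everything except outcome/BI) for n patients; returns
# the data columns plus the linear predictor of the outcome model without
# its intercept.
draw_covariates <- function(params, n) {
  p <- params
  age <- round(rtruncnorm(n, p$age_mean, p$age_sd,
                          p$age_range[1], p$age_range[2]), 1)
  sex <- ifelse(stats::runif(n) < p$male_prop, "male", "female")
  hx <- vapply(HISTORY_FLAGS, function(h) {
    stats::rbinom(n, 1, p$history_prev[[h]])
  }, numeric(n))
  onset <- round(rtruncnorm(n, p$onset_mean, p$onset_sd, 0, 24), 1)
  nihss_d1 <- r_nihss(n, p$nihss_day1_mean, p$nihss_day1_sd)
  delta <- r_delta(n, p$delta_nihss_mean, p$delta_nihss_sd)
  nihss_d3 <- pmin(pmax(nihss_d1 + delta, 0L), 42L)

  panel <- names(p$symptom_prev_day1)
  sym <- list()
  for (s in panel) {
    d1 <- stats::rbinom(n, 1, p$symptom_prev_day1[[s]])
    tr <- p$change_transitions[[s]]
    if (is.null(tr)) tr <- p$change_transitions$default
    d3 <- integer(n)
    d3[d1 == 1] <- stats::rbinom(sum(d1 == 1), 1, 1 - tr[["resolve"]])
    d3[d1 == 0] <- stats::rbinom(sum(d1 == 0), 1, tr[["appear"]])
    sym[[paste0("sym_", s, "_d1")]] <- d1
    sym[[paste0("sym_", s, "_d3")]] <- d3
  }

  data <- data.frame(id = paste0("S", seq_len(n)), age = age, sex = sex,
                     stringsAsFactors = FALSE)
  data[paste0("hx_", HISTORY_FLAGS)] <- as.data.frame(hx)
  data$onset_hours <- onset
  data$nihss_d1 <- as.integer(nihss_d1)
  data$nihss_d3 <- as.integer(nihss_d3)
  data$bi_d90 <- 0L  # placeholder until the outcome is drawn
  data[names(sym)] <- sym

  coefs <- p$outcome_model$coefficients
  codes <- cbind(
    age_degree = as.integer(age > 56.44),
    history_dm = data$hx_dm,
    anxiety_day1 = data$sym_anxiety_d1,
    nihss_day1_degree = bin_variable(nihss_d1, c(2, 6)),
    irritability_day1 = data$sym_irritability_d1,
    delta_nihss_degree = as.integer((nihss_d3 - nihss_d1) > -1),
    circumrotating_change = change_code(derive_change_status(
      data$sym_circumrotating_d1, data$sym_circumrotating_d3)),
    tinnitus_change = change_code(derive_change_status(
      data$sym_tinnitus_d1, data$sym_tinnitus_d3)))
  lp0 <- as.vector(codes[, names(coefs), drop = FALSE] %*% coefs)
  list(data = data, lp0 = lp0, panel = panel)
}

#' Calibrate the outcome-model intercept to a target poor fraction
#'
#' Bisection on the intercept until the simulated expected poor fraction
#' (mean of the logistic probabilities over a large fixed covariate sample)
#' is within `tol` of the target.  The covariate sample uses its own fixed
#' RNG substream, so calibration does not perturb the caller's stream and
#' is reproducible.
#'
#' @param coefficients Named coefficient vector of the outcome model.
#' @param covariate_sampler Function of `n` returning the linear predictor
#'   without intercept for `n` simulated patients; if `NULL`, built from
#'   `params`.
#' @param target_poor_prop Target expected poor fraction, in (0, 1).
#' @param tol Tolerance on the achieved fraction.
#' @param n_sim Size of the calibration sample.
#' @param params A `cohort_params` used to build the default sampler.
#' @return The calibrated intercept (numeric scalar).
#' @export
calibrate_intercept <- function(coefficients = NULL, covariate_sampler = NULL,
                                target_poor_prop, tol = 1e-3,
                                n_sim = 50000, params = NULL) {
  if (target_poor_prop <= 0 || target_poor_prop >= 1) {
    stop("target_poor_prop must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(covariate_sampler)) {
    if (is.null(params)) stop("need covariate_sampler or params",
                              call. = FALSE)
    covariate_sampler <- function(n) draw_covariates(params, n)$lp0
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(987654)  # fixed calibration substream
  lp0 <- covariate_sampler(n_sim)
  f <- function(a) mean(stats::plogis(a + lp0))
  lo <- -20; hi <- 20
  expand <- 0
  while (f(lo) > target_poor_prop && expand < 10) { lo <- lo * 2; expand <- expand + 1 }
  while (f(hi) < target_poor_prop && expand < 20) { hi <- hi * 2; expand <- expand + 1 }
  if (f(lo) > target_poor_prop || f(hi) < target_poor_prop) {
    stop("could not bracket the target poor fraction", call. = FALSE)
  }
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target_poor_prop) <= tol || (hi - lo) < 1e-10) return(mid)
    if (fm < target_poor_prop) lo <- mid else hi <- mid
  }
}

#' Generate a synthetic stroke cohort
#'
#' Draws demographics, histories, day-1/day-3 NIHSS, day-1 symptom presence
#' and day-3 transitions per the parameters, computes the scale category
#' codes, draws the poor/good outcome from the logistic outcome model, and
#' back-fills a day-90 Barthel Index consistent with the drawn label
#' (poor: uniform on \{0, 5, ..., 85\}; good: uniform on \{90, 95, 100\};
#' explicitly synthetic).  Reproducible given `params$seed`.
#'
#' @param params A `cohort_params`, e.g. [default_params()].
#' @return A [cohort_table()] of `params$n` patients.
#' @examples
#' cohort <- generate_cohort(default_params(n = 100, seed = 42))
#' nrow(cohort)
#' @export
generate_cohort <- function(params) {
  validate_params(params)
  intercept <- params$outcome_model$intercept
  if (is.null(intercept)) {
    intercept <- calibrate_intercept(
      params = params, target_poor_prop = params$target_poor_prop)
  }
  set.seed(params$seed)
  cov <- draw_covariates(params, params$n)
  poor <- stats::rbinom(params$n, 1, stats::plogis(intercept + cov$lp0))
  bi <- integer(params$n)
  bi[poor == 1] <- 5L * sample(0:17, sum(poor == 1), replace = TRUE)
  bi[poor == 0] <- 5L * sample(18:20, sum(poor == 0), replace = TRUE)
  cov$data$bi_d90 <- bi
  cohort_table(cov$data, panel = cov$panel)
}
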