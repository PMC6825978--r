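# Synthetic cohort generator: a latent-frailty threshold model for the 23
# deficits, Table-2-style marginal distributions for the observable
# variables, proportional-hazards survival, administrative + uniform
# censoring, and MCAR missingness masks. The generating truth (deficit
# matrix, score, category) travels with the cohort as attr(, "truth") so
# parameter recovery can be checked against it.

#' Marginal distributions for the observable cohort variables
#'
#' One entry per variable: distribution family and parameters, plus the
#' frail direction (`-1` when low values are the adverse side). Right-skewed
#' labs are log-normal, parameterized by matching the reported median
#' (`exp(mu)`) and mean (`sigma = sqrt(2 log(mean/median))`); roughly
#' symmetric labs are normal. Defaults reflect a ~270-patient unplanned
#' oncology admission cohort.
#'
#' @return Named list of marginal specifications.
#' @export
default_marginals <- function() {
  lnorm_mm <- function(mean, median) {
    list(dist = "lnorm", meanlog = log(median),
         sdlog = sqrt(2 * log(mean / median)))
  }
  list(
    sodium            = list(dist = "norm", mean = 136, sd = 4.98, dir = -1),
    albumin           = list(dist = "norm", mean = 3.42, sd = 0.71, dir = -1),
    hemoglobin        = list(dist = "norm", mean = 10.68, sd = 2.33, dir = -1),
    corrected_calcium = list(dist = "norm", mean = 9.57, sd = 0.91, dir = +1),
    creatinine        = c(lnorm_mm(1.02, 0.80), dir = +1),
    wbc               = c(lnorm_mm(9.95, 7.92), dir = +1),
    neutrophils       = c(lnorm_mm(7.07, 5.73), dir = +1),
    platelets         = c(lnorm_mm(239, 214), dir = -1),
    lymphocytes       = c(lnorm_mm(1.59, 0.87), dir = -1),
    bmi               = list(dist = "norm", mean = 26.5, sd = 6.39, dir = -1),
    length_of_index_admission = c(lnorm_mm(4.88, 3.0), dir = +1),
    height_cm         = list(dist = "norm", mean = 169, sd = 9.87, dir = 0),
    age               = list(dist = "norm", mean = 61.63, sd = 13.05, dir = 0),
    healthcare_visits_6mo = list(dist = "pois", lambda = 0.65, dir = +1),
    n_medications     = list(dist = "nbinom", mu = 11.36, size = 10.8, dir = +1)
  )
}

# deficit regions, as [lower, upper) interval(s) on the variable scale
LAB_FACTOR_REGIONS <- list(
  corrected_calcium = list(var = "corrected_calcium", lo = 11, hi = Inf, closed_lo = TRUE),
  creatinine        = list(var = "creatinine", lo = 1.3, hi = Inf, closed_lo = FALSE),
  neutrophils       = list(var = "neutrophils", lo = -Inf, hi = 1.8),
  hemoglobin        = list(var = "hemoglobin", lo = -Inf, hi = 12),
  lymphocytes       = list(var = "lymphocytes", lo = -Inf, hi = 1.1),
  albumin           = list(var = "albumin", lo = -Inf, hi = 3.5),
  sodium            = list(var = "sodium", lo = -Inf, hi = 135),
  wbc               = list(var = "wbc", lo = 11, hi = Inf, closed_lo = FALSE),
  bmi               = list(var = "bmi", lo = -Inf, hi = 19),
  length_of_stay    = list(var = "length_of_index_admission", lo = 5, hi = Inf, closed_lo = FALSE)
)

marg_p <- function(m, q, lower = TRUE) {
  switch(m$dist,
         norm = pnorm(q, m$mean, m$sd, lower.tail = lower),
         lnorm = stats::plnorm(q, m$meanlog, m$sdlog, lower.tail = lower),
         pois = stats::ppois(q, m$lambda, lower.tail = lower),
         nbinom = stats::pnbinom(q, mu = m$mu, size = m$size, lower.tail = lower))
}
marg_q <- function(m, p) {
  switch(m$dist,
         norm = qnorm(p, m$mean, m$sd),
         lnorm = stats::qlnorm(p, m$meanlog, m$sdlog),
         pois = stats::qpois(p, m$lambda),
         nbinom = stats::qnbinom(p, mu = m$mu, size = m$size))
}

#' Default per-factor deficit probabilities
#'
#' Marginal probability that each of the 23 deficits is present. For the
#' single-variable laboratory/anthropometric factors these are computed
#' analytically as the mass of the deficit region under the corresponding
#' default marginal (so the generated variables keep their marginal
#' distributions exactly); for the categorical/count factors and the
#' ratio-index factors they are set to the prevalences typical of this
#' population.
#'
#' @param marginals Marginal list, default [default_marginals()].
#' @param p_readmit Readmission probability, default 0.5 (a ~50/50 two-arm
#'   cohort).
#' @return Named numeric vector of length 23 in registry order.
#' @export
default_deficit_probs <- function(marginals = default_marginals(),
                                  p_readmit = 0.5) {
  direct <- c(
    readmission = p_readmit,
    marital_support = 0.31, language = 0.041, fall_risk = 0.393,
    healthcare_visits = 1 - stats::ppois(2, marginals$healthcare_visits_6mo$lambda),
    ecog = 0.225,
    medications = stats::pnbinom(5, mu = marginals$n_medications$mu,
                                 size = marginals$n_medications$size,
                                 lower.tail = FALSE),
    metastasis = 0.616,
    # ratio indices: generative prevalences (the measured index is a proxy)
    nlr = 0.62, plr = 0.50, sii = 0.50, pni = 0.62
  )
  lab <- vapply(names(LAB_FACTOR_REGIONS), function(f) {
    r <- LAB_FACTOR_REGIONS[[f]]
    m <- marginals[[r$var]]
    p_lo <- if (is.finite(r$hi)) marg_p(m, r$hi) else 1
    p_be <- if (is.finite(r$lo)) marg_p(m, r$lo) else 0
    p_lo - p_be
  }, numeric(1))
  # platelets: outside 150-450 (both tails)
  mp <- marginals$platelets
  lab <- c(lab, platelets = marg_p(mp, 150) + marg_p(mp, 450, lower = FALSE))
  probs <- c(direct, lab)
  probs[default_factor_registry()$factor]
}

#' Default MCAR missingness rates
#'
#' Per-field probabilities that a value is masked missing, reflecting the
#' documentation gaps typical of retrospective inpatient chart review
#' (performance status worst, core chemistry nearly complete).
#'
#' @return Named numeric vector of rates in \[0, 1\].
#' @export
default_missingness <- function() {
  c(marital_status = 0.019, language = 0, race = 0, fall_risk = 0.015,
    ecog_ps = 0.36, karnofsky = 0.47, metastasis = 0.03,
    weight_kg = 0.13, height_cm = 0.13,
    corrected_calcium = 0.105, creatinine = 0.06, hemoglobin = 0.019,
    lymphocytes = 0.068, neutrophils = 0.165, platelets = 0.019,
    albumin = 0.09, sodium = 0.064, wbc = 0.019, n_medications = 0.015)
}

#' Build a synthetic cohort configuration
#'
#' @param n Number of patients.
#' @param p_readmit 30-day readmission probability (the two-arm split).
#'   Feeds the default `deficit_probs`; a user-supplied `deficit_probs`
#'   vector is authoritative, including its `readmission` entry.
#' @param rho Loading of the shared latent frailty factor on each deficit's
#'   latent Gaussian (0 = independent deficits); default 0.3, which makes
#'   the deficit score overdispersed relative to independence, as frailty
#'   indices are.
#' @param deficit_probs Named 23-vector of marginal deficit probabilities;
#'   default [default_deficit_probs()].
#' @param beta_readmit Log hazard ratio of 30-day readmission; default
#'   `log(2)`.
#' @param beta_dasi Log hazard ratio per unit deficit score; default 4
#'   (about a 4-fold hazard spread between score 0.15 and 0.50).
#' @param baseline Baseline hazard family, `"exponential"` or `"weibull"`.
#' @param h0 Baseline hazard scale (events/day at score 0, non-readmitted).
#' @param shape Weibull shape (ignored for exponential).
#' @param horizon Administrative censoring horizon in days.
#' @param uniform_censoring Fraction of patients additionally censored at a
#'   Uniform(0, horizon) time (loss to follow-up).
#' @param missingness Named vector of per-field MCAR rates.
#' @param marginals Observable-variable marginals, [default_marginals()].
#' @param seed Default seed used by [generate_cohort()].
#' @return A `cohort_config` object (validated list).
#' @export
cohort_config <- function(n = 270, p_readmit = 0.5, rho = 0.3,
                          deficit_probs = default_deficit_probs(marginals, p_readmit),
                          beta_readmit = log(2), beta_dasi = 4,
                          baseline = c("exponential", "weibull"),
                          h0 = 0.000167, shape = 1, horizon = 450,
                          uniform_censoring = 0.15,
                          missingness = default_missingness(),
                          marginals = default_marginals(), seed = 1L) {
  baseline <- match.arg(baseline)
  cfg <- list(n = n, p_readmit = p_readmit, rho = rho,
              deficit_probs = deficit_probs, beta_readmit = beta_readmit,
              beta_dasi = beta_dasi, baseline = baseline, h0 = h0,
              shape = shape, horizon = horizon,
              uniform_censoring = uniform_censoring,
              missingness = missingness, marginals = marginals, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$p_readmit, cfg$rho, cfg$deficit_probs,
             cfg$uniform_censoring, cfg$missingness)
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]",
          class = "dasi_validation_error")
  }
  if (cfg$n < 1) abort("n must be >= 1", class = "dasi_validation_error")
  if (cfg$h0 <= 0 || cfg$shape <= 0) {
    abort("hazard parameters must be > 0", class = "dasi_validation_error")
  }
  if (cfg$horizon <= 0) {
    abort("censoring horizon must be > 0", class = "dasi_validation_error")
  }
  reg <- default_factor_registry()$factor
  if (!setequal(names(cfg$deficit_probs), reg)) {
    abort("deficit_probs must be named by the 23 registered factors",
          class = "dasi_schema_error")
  }
  invisible(cfg)
}

#' Default mid-sized oncology study configuration
#'
#' A ~270-patient two-arm cohort: 50% 30-day readmission, laboratory
#' marginals moment-matched to the reported summaries (e.g. sodium mean 136,
#' SD 4.98; albumin mean 3.42, SD 0.71), per-variable missingness matching
#' the reported gaps, and a proportional-hazards survival structure
#' calibrated to ~41% observed deaths at the administrative horizon.
#'
#' @param n Cohort size; default 270.
#' @param seed Default generation seed.
#' @return A `cohort_config`.
#' @export
default_study_config <- function(n = 270, seed = 1L) {
  cohort_config(n = n, seed = seed)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config: n =", x$n, ", readmission p =", x$p_readmit,
      "\n  baseline", x$baseline, "h0 =", x$h0,
      ", HR(readmit) =", round(exp(x$beta_readmit), 2),
      ", HR(score +0.1) =", round(exp(0.1 * x$beta_dasi), 2), "\n")
  invisible(x)
}

# draw from a marginal truncated to [lo, hi) / the deficit or its complement
draw_region <- function(m, n, deficit, lo, hi) {
  p_lo <- if (is.finite(lo)) marg_p(m, lo) else 0
  p_hi <- if (is.finite(hi)) marg_p(m, hi) else 1
  u <- runif(n)
  inside <- p_lo + u * (p_hi - p_lo)           # within the deficit region
  outside_mass <- 1 - (p_hi - p_lo)
  # complement: stack [0, p_lo) and [p_hi, 1)
  uo <- u * outside_mass
  outside <- ifelse(uo < p_lo, uo, uo + (p_hi - p_lo))
  marg_q(m, ifelse(deficit == 1, inside, outside))
}

draw_count_region <- function(m, n, deficit, threshold) {
  # deficit when value > threshold
  p_le <- marg_p(m, threshold)
  u <- runif(n)
  q <- ifelse(deficit == 1, p_le + u * (1 - p_le), u * p_le)
  marg_q(m, pmin(q, 1 - 1e-12))
}

sample_levels <- function(n, levels, probs) {
  levels[1 + findInterval(runif(n), cumsum(probs / sum(probs)))]
}

REASON_TEXTS <- list(
  pain = c("back pain", "abdominal pain", "neoplasm-related pain"),
  neurologic = c("dizziness", "syncope", "headache"),
  dyspnea = c("shortness of breath", "hypoxia"),
  chemo_side_effect = c("nausea and vomiting after chemotherapy",
                        "diarrhea within 1 week of chemotherapy"),
  abnormal_findings = c("abnormal laboratory values",
                        "abnormal findings on imaging"),
  dehydration = c("dehydration"),
  fever = c("fever"),
  other = c("generalized weakness", "fatigue", "failure to thrive")
)
REASON_FREQS <- c(pain = 0.222, neurologic = 0.038, dyspnea = 0.150,
                  chemo_side_effect = 0.117, abnormal_findings = 0.098,
                  dehydration = 0.041, fever = 0.098, other = 0.236)
CANCER_FREQS <- c(bladder = 0.038, breast = 0.071, gi = 0.229,
                  `head and neck` = 0.049, hepatocellular = 0.026,
                  lung = 0.180, melanoma = 0.079, neuroendocrine = 0.030,
                  other = 0.244, sarcoma = 0.053)

#' Generate a synthetic cohort
#'
#' Draws, in order: the 23 correlated latent deficit indicators (one-factor
#' Gaussian threshold model), the observable variables consistent with
#' those indicators (region-truncated marginal draws for the
#' single-variable factors; conditional categorical draws for the
#' flag/count factors; ratio indices emerge from the drawn labs), survival
#' times from the proportional-hazards model
#' `h(t | x) = h0(t) exp(beta_readmit * readmit + beta_dasi * score)` with
#' the generating score = latent deficits / 23, then censoring and MCAR
#' masks. Fully deterministic given the seed; the output passes
#' [validate_cohort()] and round-trips through [write_cohort()] /
#' [read_cohort()] unchanged.
#'
#' The generating truth is attached as `attr(cohort, "truth")`: a tibble
#' with the latent deficit matrix, the true score and category, and the
#' uncensored event time.
#'
#' @param config A `cohort_config`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A validated cohort tibble of `config$n` patients.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_config(config)
  withr::with_seed(seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n
  reg <- default_factor_registry()
  probs <- cfg$deficit_probs[reg$factor]

  # latent one-factor threshold model for the 23 deficits
  z <- rnorm(n)
  eps <- matrix(rnorm(n * nrow(reg)), n, nrow(reg))
  lat <- sqrt(cfg$rho) * z + sqrt(1 - cfg$rho) * eps
  b <- sweep(lat, 2, qnorm(probs), "<") * 1L
  colnames(b) <- reg$factor
  true_score <- rowSums(b) / nrow(reg)

  mg <- cfg$marginals

  # observables realized from the latent indicators --------------------------
  readmitted <- b[, "readmission"] == 1L
  marital <- ifelse(b[, "marital_support"] == 1L,
                    sample_levels(n, c("single", "divorced", "widowed"),
                                  c(0.126, 0.103, 0.080)),
                    "married")
  language <- ifelse(b[, "language"] == 1L, "not_english", "english")
  fall <- ifelse(b[, "fall_risk"] == 1L, "high",
                 sample_levels(n, c("moderate", "low", "universal"),
                               c(0.565, 0.008, 0.034)))
  ecog <- ifelse(b[, "ecog"] == 1L,
                 sample_levels(n, c("2", "3", "4"), c(0.148, 0.077, 0.01)),
                 sample_levels(n, c("0", "1"), c(0.154, 0.621)))
  ecog <- as.integer(ecog)
  # Karnofsky drawn within the band matching ECOG (0 has no band; use 10)
  kband <- list(`0` = c(90, 100), `1` = c(70, 80), `2` = c(50, 60),
                `3` = c(30, 40), `4` = c(10, 20))
  karnofsky <- vapply(ecog, function(e) sample(kband[[as.character(e)]], 1),
                      numeric(1))
  visits <- draw_count_region(mg$healthcare_visits_6mo, n,
                              b[, "healthcare_visits"], 2)
  meds <- draw_count_region(mg$n_medications, n, b[, "medications"], 5)
  metastasis <- b[, "metastasis"] == 1L

  los_m <- mg$length_of_index_admission
  los <- round(draw_region(los_m, n, b[, "length_of_stay"],
                           lo = 5, hi = Inf), 0)
  # rounding must not move a value across the >5 boundary
  los <- ifelse(b[, "length_of_stay"] == 1L, pmax(los, 6), pmin(los, 5))
  los <- pmax(los, 0)

  labs <- list()
  for (f in names(LAB_FACTOR_REGIONS)) {
    r <- LAB_FACTOR_REGIONS[[f]]
    if (f %in% c("length_of_stay")) next
    labs[[r$var]] <- draw_region(mg[[r$var]], n, b[, f], r$lo, r$hi)
  }
  # platelets: two-sided region (outside 150-450)
  mp <- mg$platelets
  p_low_tail <- marg_p(mp, 150)
  p_high_tail <- marg_p(mp, 450, lower = FALSE)
  u <- runif(n)
  in_def <- b[, "platelets"] == 1L
  tail_split <- p_low_tail / (p_low_tail + p_high_tail)
  q_def <- ifelse(u < tail_split,
                  (u / tail_split) * p_low_tail,
                  (1 - p_high_tail) + (u - tail_split) / (1 - tail_split) * p_high_tail)
  q_non <- p_low_tail + u * (1 - p_low_tail - p_high_tail)
  labs$platelets <- marg_q(mp, ifelse(in_def, q_def, q_non))

  # labs must be strictly positive; the normal marginals have negligible
  # negative mass but the invariant is hard
  for (v in c("sodium", "albumin", "hemoglobin", "corrected_calcium"))
    labs[[v]] <- pmax(labs[[v]], 0.1)
  bmi <- pmax(labs$bmi, 12)
  labs$bmi <- NULL

  # record labs at clinical precision without letting rounding move a value
  # across its deficit boundary
  lab_digits <- c(wbc = 2, hemoglobin = 2, platelets = 1, neutrophils = 2,
                  lymphocytes = 2, sodium = 1, creatinine = 2,
                  corrected_calcium = 2, albumin = 2)
  clamp <- function(val, def, lo, hi, closed_lo, unit) {
    if (is.finite(hi)) {                      # deficit when val < hi
      val <- ifelse(def == 1L, pmin(val, hi - unit), pmax(val, hi))
    } else if (isTRUE(closed_lo)) {           # deficit when val >= lo
      val <- ifelse(def == 1L, pmax(val, lo), pmin(val, lo - unit))
    } else {                                  # deficit when val > lo
      val <- ifelse(def == 1L, pmax(val, lo + unit), pmin(val, lo))
    }
    val
  }
  for (v in names(lab_digits)) {
    labs[[v]] <- round(labs[[v]], lab_digits[[v]])
  }
  for (f in setdiff(names(LAB_FACTOR_REGIONS), c("bmi", "length_of_stay"))) {
    r <- LAB_FACTOR_REGIONS[[f]]
    unit <- 10^(-lab_digits[[r$var]])
    labs[[r$var]] <- clamp(labs[[r$var]], b[, f], r$lo, r$hi,
                           isTRUE(r$closed_lo), unit)
  }
  low_def <- b[, "platelets"] == 1L
  labs$platelets <- ifelse(low_def,
                           ifelse(labs$platelets < 300,
                                  pmin(labs$platelets, 149.9),
                                  pmax(labs$platelets, 450.1)),
                           pmin(pmax(labs$platelets, 150), 450))

  height <- rnorm(n, mg$height_cm$mean, mg$height_cm$sd)
  weight <- bmi * (height / 100)^2
  age <- pmin(pmax(rnorm(n, mg$age$mean, mg$age$sd), 19), 92)
  sex <- sample_levels(n, c("male", "female"), c(0.53, 0.47))
  race <- sample_levels(n, c("white", "not_white"), c(0.853, 0.147))
  reason_cat <- sample_levels(n, names(REASON_FREQS), REASON_FREQS)
  chief <- unname(vapply(reason_cat, function(rc) sample(REASON_TEXTS[[rc]], 1),
                         character(1)))
  cancer <- sample_levels(n, names(CANCER_FREQS), CANCER_FREQS)

  # survival -----------------------------------------------------------------
  lp <- cfg$beta_readmit * readmitted + cfg$beta_dasi * true_score
  rate <- cfg$h0 * exp(lp)
  e_std <- stats::rexp(n)
  t_event <- if (cfg$baseline == "exponential") {
    e_std / rate
  } else {
    (e_std / rate)^(1 / cfg$shape)
  }
  c_admin <- rep(cfg$horizon, n)
  lost <- runif(n) < cfg$uniform_censoring
  c_unif <- ifelse(lost, runif(n, 0, cfg$horizon), Inf)
  c_all <- pmin(c_admin, c_unif)
  time <- pmin(t_event, c_all)
  event <- t_event <= c_all
  time <- pmax(ceiling(time), 1)  # day-level resolution; ties are realistic

  cohort <- tibble::tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    readmitted_30d = readmitted,
    sex = sex, age = round(age, 1),
    marital_status = marital, language = language, race = race,
    fall_risk = fall, ecog_ps = ecog, karnofsky = karnofsky,
    healthcare_visits_6mo = visits,
    length_of_index_admission = los,
    chief_complaint = chief, cancer_type_raw = cancer,
    metastasis = metastasis,
    weight_kg = round(weight, 1), height_cm = round(height, 1),
    wbc = round(labs$wbc, 2), hemoglobin = round(labs$hemoglobin, 2),
    platelets = round(labs$platelets, 1),
    neutrophils = round(labs$neutrophils, 2),
    lymphocytes = round(labs$lymphocytes, 2),
    sodium = round(labs$sodium, 1), creatinine = round(labs$creatinine, 2),
    corrected_calcium = round(labs$corrected_calcium, 2),
    albumin = round(labs$albumin, 2),
    n_medications = meds,
    survival_time = time, event = event
  )

  # MCAR masks (outcome and readmission are never masked)
  for (v in names(cfg$missingness)) {
    r <- cfg$missingness[[v]]
    if (r > 0 && v %in% names(cohort)) {
      cohort[[v]][runif(n) < r] <- NA
    }
  }

  cohort <- validate_cohort(cohort)
  truth <- dplyr::bind_cols(
    tibble::tibble(patient_id = cohort$patient_id),
    tibble::as_tibble(b),
    tibble::tibble(true_score = true_score,
                   true_category = categorize_dasi(true_score),
                   latent_frailty = z,
                   event_time = t_event)
  )
  attr(cohort, "truth") <- truth
  attr(cohort, "provenance") <- paste0("generate_cohort(seed=", cfg$seed, ")")
  cohort
}
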