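# Independent hand-written oracles used by the acceptance tests. These
# deliberately avoid the survival package: the product-limit estimator,
# log-rank statistic, Breslow partial likelihood and Pearson chi-square are
# recomputed from their textbook definitions.

# product-limit estimate evaluated at each requested time point
oracle_km <- function(time, event, at = sort(unique(time[event == 1]))) {
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    n_risk <- sum(time >= ev_times[i])
    d <- sum(time == ev_times[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  vapply(at, function(t0) {
    before <- ev_times <= t0
    if (!any(before)) 1 else surv[max(which(before))]
  }, numeric(1))
}

# two-group log-rank statistic (hypergeometric variance, ties allowed)
oracle_logrank <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  o1 <- e1 <- v <- 0
  for (t0 in sort(unique(time[event == 1]))) {
    at_risk <- time >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & group == g[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Breslow log partial likelihood for a single covariate
oracle_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force maximizer of the partial likelihood (coarse-to-fine grid)
oracle_grid_max <- function(time, event, x, lo = -10, hi = 10) {
  b <- NA_real_
  for (step in c(0.01, 1e-4, 1e-6)) {
    bs <- seq(lo, hi, by = step)
    ll <- vapply(bs, oracle_partial_loglik, numeric(1),
                 time = time, event = event, x = x)
    b <- bs[which.max(ll)]
    lo <- b - step
    hi <- b + step
  }
  b
}

# Pearson chi-square from first principles
oracle_chisq <- function(counts) {
  counts <- as.matrix(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  sum((counts - expected)^2 / expected)
}

# one-row cohort slice holding every deficit source column at a clearly
# non-deficit value (derived indices supplied directly)
base_patient <- function() {
  tibble::tibble(
    readmitted_30d = FALSE, marital_status = "married",
    language = "english", fall_risk = "low", healthcare_visits_6mo = 0,
    bmi = 25, corrected_calcium = 9.5, creatinine = 1.0, ecog_ps = 1,
    nlr = 2, neutrophils = 4, plr = 100, platelets = 250, hemoglobin = 14,
    length_of_index_admission = 3, lymphocytes = 2, sii = 500, albumin = 4,
    sodium = 140, wbc = 7, n_medications = 2, pni = 60, metastasis = FALSE
  )
}

# the same patient with every factor in its deficit region
deficit_patient <- function() {
  tibble::tibble(
    readmitted_30d = TRUE, marital_status = "single",
    language = "not_english", fall_risk = "high", healthcare_visits_6mo = 3,
    bmi = 18, corrected_calcium = 11.5, creatinine = 1.5, ecog_ps = 3,
    nlr = 6, neutrophils = 1.0, plr = 300, platelets = 500, hemoglobin = 10,
    length_of_index_admission = 7, lymphocytes = 0.9, sii = 1700,
    albumin = 3.0, sodium = 130, wbc = 12, n_medications = 8, pni = 40,
    metastasis = TRUE
  )
}

# score one perturbed patient and return the named deficit value
deficit_of <- function(column, value, factor_name) {
  p <- base_patient()
  p[[column]] <- value
  def <- score_deficits(p)
  as.integer(def[[factor_name]])
}
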