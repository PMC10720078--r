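#' Synthetic two-group cohort configuration
#'
#' Generates patient tables with the structure of a pulmonary hypertension
#' (PH) case-control study: right-heart-catheterization pressures (mPAP,
#' SPAP, DPAP in mmHg) and nine CT measurements (diameter, cross-sectional
#' area and volume of the main/right/left pulmonary artery), with PH defined
#' by the strict rule mPAP > 20 mmHg.
#'
#' Default group sizes (18 non-PH / 41 PH), per-group pressure and
#' measurement distributions and pooled measurement-pressure correlation
#' targets follow published values for such a cohort. Quantities reported as
#' median (IQR) are converted once to a mean/SD parameterization
#' (`mean = median`, `sd = IQR width / 1.349`); non-PH mPAP is modelled as a
#' lognormal matched to its median/IQR (the non-PH pressures are reported as
#' non-normal), truncated at the 20 mmHg diagnostic boundary, while PH mPAP
#' is a normal truncated to > 20 mmHg. Every measurement is linked linearly
#' to mPAP within each group; the within-group correlation is solved
#' analytically so the pooled correlation hits the configured target while
#' per-group means/SDs match their configured values exactly in expectation.
#'
#' @param n_nonph,n_ph group sizes (each >= 2), defaults 18 and 41.
#' @param measurements data.frame with columns `name`, `nonph_mean`,
#'   `nonph_sd`, `ph_mean`, `ph_sd`, `target_r` (pooled Pearson correlation
#'   with mPAP, each in (-1, 1)); defaults built in.
#' @param link_rho within-group correlation linking SPAP and DPAP to mPAP
#'   (default 0.9).
#' @param seed default RNG seed used by [generate_cohort()].
#' @return A `cohort_config`.
#' @export
cohort_config <- function(n_nonph = 18, n_ph = 41, measurements = NULL,
                          link_rho = 0.9, seed = 20231213) {
  if (n_nonph < 2 || n_ph < 2) stop("need at least 2 patients per group")
  iqr_sd <- function(lo, hi) (hi - lo) / (qnorm(0.75) - qnorm(0.25))
  if (is.null(measurements)) {
    measurements <- data.frame(
      name = c("D_MPA", "A_MPA", "V_MPA", "D_RPA", "A_RPA", "V_RPA",
               "D_LPA", "A_LPA", "V_LPA"),
      nonph_mean = c(25.93, 601.57, 25751.64, 19.37, 348.58, 15594.91,
                     17.51, 314.36, 23118.99),
      nonph_sd = c(4.68, 184.37, 7154.24, 3.32, 114.38,
                   iqr_sd(12662.13, 29474.24), 3.47, 75.18, 13552.82),
      ph_mean = c(36.01, 1046.88, 55557.10, 24.37, 536.47, 48454.73,
                  21.68, 459.79, 37963.42),
      ph_sd = c(6.36, 278.94, 18449.48, 4.15, 176.59, 19118.22,
                4.36, 182.64, 16972.93),
      target_r = c(0.60, 0.65, 0.744, 0.527, 0.58, 0.640,
                   0.45, 0.495, 0.302),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "nonph_mean", "nonph_sd", "ph_mean", "ph_sd",
                  "target_r") %in% names(measurements)))
  if (any(measurements$nonph_sd < 0) || any(measurements$ph_sd < 0))
    stop("measurement SDs must be >= 0")
  if (any(abs(measurements$target_r) >= 1))
    stop("target correlations must lie in (-1, 1)")
  pressures <- list(
    mpap = list(
      nonph = list(dist = "lognormal", median = 18, iqr = c(16, 19), upper = 20),
      ph = list(dist = "normal", mean = 26, sd = iqr_sd(20, 35), lower = 20)),
    spap = list(nonph = list(mean = 26.00, sd = iqr_sd(24, 29)),
                ph = list(mean = 72.22, sd = 19.73)),
    dpap = list(nonph = list(mean = 10.00, sd = iqr_sd(8.5, 11)),
                ph = list(mean = 27.85, sd = 10.77)))
  structure(list(n_nonph = as.integer(n_nonph), n_ph = as.integer(n_ph),
                 measurements = measurements, pressures = pressures,
                 link_rho = link_rho, seed = seed),
            class = "cohort_config")
}

# analytic moments of the truncated group mPAP distributions
.mpap_moments <- function(config) {
  pn <- config$pressures$mpap$nonph
  sig <- log(pn$iqr[2] / pn$iqr[1]) / (qnorm(0.75) - qnorm(0.25))
  mu <- log(pn$median)
  beta <- (log(pn$upper) - mu) / sig
  E1 <- exp(mu + sig^2 / 2) * pnorm(beta - sig) / pnorm(beta)
  E2 <- exp(2 * mu + 2 * sig^2) * pnorm(beta - 2 * sig) / pnorm(beta)
  nonph <- list(mean = E1, sd = sqrt(E2 - E1^2), mu_log = mu, sd_log = sig,
                upper = pn$upper)
  pp <- config$pressures$mpap$ph
  alpha <- (pp$lower - pp$mean) / pp$sd
  lam <- dnorm(alpha) / (1 - pnorm(alpha))
  ph <- list(mean = pp$mean + pp$sd * lam,
             sd = pp$sd * sqrt(1 + alpha * lam - lam^2),
             mu = pp$mean, sigma = pp$sd, lower = pp$lower)
  list(nonph = nonph, ph = ph)
}

#' Analytic generating moments and linkage coefficients
#'
#' `cohort_moments()` returns the per-group mPAP moments implied by the
#' truncated group distributions. `cohort_linkage()` returns, per
#' measurement, the within-group correlation solved from the pooled target
#' plus the per-group intercept/slope/noise-SD of the linear link to mPAP.
#'
#' @param config a [cohort_config()].
#' @export
cohort_moments <- function(config) .mpap_moments(config)

#' @rdname cohort_moments
#' @export
cohort_linkage <- function(config) {
  mm <- .mpap_moments(config)
  w1 <- config$n_nonph / (config$n_nonph + config$n_ph)
  w2 <- 1 - w1
  mu_p <- w1 * mm$nonph$mean + w2 * mm$ph$mean
  var_p <- w1 * (mm$nonph$sd^2 + (mm$nonph$mean - mu_p)^2) +
           w2 * (mm$ph$sd^2 + (mm$ph$mean - mu_p)^2)
  out <- list()
  for (i in seq_len(nrow(config$measurements))) {
    m <- config$measurements[i, ]
    mu_m <- w1 * m$nonph_mean + w2 * m$ph_mean
    var_m <- w1 * (m$nonph_sd^2 + (m$nonph_mean - mu_m)^2) +
             w2 * (m$ph_sd^2 + (m$ph_mean - mu_m)^2)
    between <- w1 * (m$nonph_mean - mu_m) * (mm$nonph$mean - mu_p) +
               w2 * (m$ph_mean - mu_m) * (mm$ph$mean - mu_p)
    within_scale <- w1 * m$nonph_sd * mm$nonph$sd + w2 * m$ph_sd * mm$ph$sd
    r_w <- (m$target_r * sqrt(var_m * var_p) - between) / within_scale
    if (!is.finite(r_w) || abs(r_w) > 1)
      stop("target correlation ", m$target_r, " for ", m$name,
           " is infeasible given the configured group moments")
    mk <- function(ms, sds, grp) {
      beta <- r_w * sds / grp$sd
      list(alpha = ms - beta * grp$mean, beta = beta,
           eps_sd = sds * sqrt(1 - r_w^2))
    }
    out[[m$name]] <- list(r_within = r_w,
                          nonph = mk(m$nonph_mean, m$nonph_sd, mm$nonph),
                          ph = mk(m$ph_mean, m$ph_sd, mm$ph))
  }
  out
}

.r_trunc_lognormal_upper <- function(n, mu, sig, upper) {
  u <- runif(n, 0, pnorm((log(upper) - mu) / sig))
  exp(mu + sig * qnorm(u))
}

.r_trunc_normal_lower <- function(n, mu, sig, lower) {
  u <- runif(n, pnorm((lower - mu) / sig), 1)
  mu + sig * qnorm(u)
}

#' Generate a synthetic cohort table
#'
#' Pressures are drawn per group (truncated distributions either side of the
#' 20 mmHg boundary), then group labels are (re)assigned by the strict rule
#' `PH iff mPAP > 20`. SPAP and DPAP are generated jointly with mPAP through
#' a within-group linear link; draws violating `SPAP >= mPAP >= DPAP` are
#' resampled (and finally clamped if a record keeps violating). Each of the
#' nine measurements is `alpha_g + beta_g * mPAP + eps` with group-specific
#' coefficients from [cohort_linkage()].
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed; defaults to the seed stored in the config.
#' @return data.frame with columns `mPAP, SPAP, DPAP, D_MPA, A_MPA, V_MPA,
#'   D_RPA, A_RPA, V_RPA, D_LPA, A_LPA, V_LPA, group`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  restore <- .seed_guard(seed)
  on.exit(if (!is.null(restore)) restore())
  mm <- .mpap_moments(config)
  n1 <- config$n_nonph; n2 <- config$n_ph
  mpap <- c(.r_trunc_lognormal_upper(n1, mm$nonph$mu_log, mm$nonph$sd_log,
                                     mm$nonph$upper),
            .r_trunc_normal_lower(n2, mm$ph$mu, mm$ph$sigma, mm$ph$lower))
  group <- ifelse(mpap > 20, "PH", "non-PH")
  gi <- ifelse(group == "PH", "ph", "nonph")
  n <- n1 + n2

  draw_one <- function(spec_by_group, g, mp) {
    sp <- spec_by_group[[g]]; gm <- mm[[g]]
    beta <- config$link_rho * sp$sd / gm$sd
    alpha <- sp$mean - beta * gm$mean
    eps_sd <- sp$sd * sqrt(1 - config$link_rho^2)
    alpha + beta * mp + rnorm(1, 0, eps_sd)
  }
  spap <- vapply(seq_len(n), function(i)
    draw_one(config$pressures$spap, gi[i], mpap[i]), numeric(1))
  dpap <- vapply(seq_len(n), function(i)
    draw_one(config$pressures$dpap, gi[i], mpap[i]), numeric(1))
  for (i in seq_len(n)) {
    tries <- 0
    while ((spap[i] < mpap[i] || dpap[i] > mpap[i] || dpap[i] <= 0) &&
           tries < 200) {
      if (spap[i] < mpap[i])
        spap[i] <- draw_one(config$pressures$spap, gi[i], mpap[i])
      if (dpap[i] > mpap[i] || dpap[i] <= 0)
        dpap[i] <- draw_one(config$pressures$dpap, gi[i], mpap[i])
      tries <- tries + 1
    }
    if (spap[i] < mpap[i]) spap[i] <- mpap[i]
    if (dpap[i] > mpap[i]) dpap[i] <- mpap[i]
    if (dpap[i] <= 0) dpap[i] <- 0.5
  }

  link <- cohort_linkage(config)
  out <- data.frame(mPAP = mpap, SPAP = spap, DPAP = dpap)
  for (nm in config$measurements$name) {
    lk <- link[[nm]]
    vals <- vapply(seq_len(n), function(i) {
      co <- lk[[gi[i]]]
      co$alpha + co$beta * mpap[i] + rnorm(1, 0, co$eps_sd)
    }, numeric(1))
    out[[nm]] <- vals
  }
  out$group <- factor(group, levels = c("non-PH", "PH"))
  out
}

.categorical_defaults <- list(
  sex_male = c(nonph = 7 / 18, ph = 10 / 41),
  dyspnea = c(nonph = 4 / 18, ph = 36 / 41),
  fever = c(nonph = 1 / 18, ph = 0 / 41),
  dizzy = c(nonph = 8 / 18, ph = 0 / 41),
  edema_lower_limbs = c(nonph = 1 / 18, ph = 1 / 41),
  chest_pain = c(nonph = 1 / 18, ph = 1 / 41),
  palpitation = c(nonph = 0 / 18, ph = 2 / 41),
  syncope = c(nonph = 1 / 18, ph = 2 / 41),
  congenital_heart_disease = c(nonph = 12 / 18, ph = 10 / 41),
  acute_pulmonary_embolism = c(nonph = 2 / 18, ph = 20 / 41),
  copd = c(nonph = 0 / 18, ph = 3 / 41),
  coronary_heart_disease = c(nonph = 3 / 18, ph = 11 / 41),
  rheumatic_disease = c(nonph = 0 / 18, ph = 1 / 41))

#' Attach categorical variables by per-group Bernoulli draws
#'
#' Default rates are the observed per-group proportions of the reference
#' cohort (counts, not the printed percentages, which are internally
#' inconsistent in the source table). Draws are independent across patients
#' and variables.
#'
#' @param cohort a cohort data.frame with a `group` column.
#' @param rates named list; each element a length-2 vector `c(nonph=, ph=)`
#'   of probabilities in `[0, 1]`. Names must come from the supported set
#'   (see `names(pamorph:::.categorical_defaults)`). Default: sex, dyspnea
#'   and congenital heart disease.
#' @param seed optional RNG seed.
#' @export
attach_categoricals <- function(cohort,
                                rates = .categorical_defaults[
                                  c("sex_male", "dyspnea",
                                    "congenital_heart_disease")],
                                seed = NULL) {
  restore <- .seed_guard(seed)
  on.exit(if (!is.null(restore)) restore())
  unknown <- setdiff(names(rates), names(.categorical_defaults))
  if (length(unknown))
    stop("unknown categorical variable(s): ", paste(unknown, collapse = ", "))
  isph <- cohort$group == "PH"
  for (nm in names(rates)) {
    p <- rates[[nm]]
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    pr <- ifelse(isph, p[["ph"]], p[["nonph"]])
    cohort[[nm]] <- rbinom(nrow(cohort), 1, pr) == 1
  }
  cohort
}
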