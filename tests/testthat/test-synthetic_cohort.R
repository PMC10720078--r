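test_that("cohorts are deterministic and respect the diagnostic rule", {
  cfg <- cohort_config()
  c1 <- generate_cohort(cfg, seed = 123)
  c2 <- generate_cohort(cfg, seed = 123)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(cfg, seed = 124)))
  expect_named(c1, c("mPAP", "SPAP", "DPAP", "D_MPA", "A_MPA", "V_MPA",
                     "D_RPA", "A_RPA", "V_RPA", "D_LPA", "A_LPA", "V_LPA",
                     "group"))
  expect_identical(nrow(c1), 59L)
})

test_that("PH labels equal {mPAP > 20} and pressures are ordered, always", {
  cfg <- cohort_config()
  for (s in 1:20) {
    co <- generate_cohort(cfg, seed = s)
    expect_identical(co$group == "PH", co$mPAP > 20)
    expect_true(all(co$SPAP >= co$mPAP))
    expect_true(all(co$mPAP >= co$DPAP))
    expect_true(all(co$DPAP > 0))
  }
})

test_that("a near-unit correlation target produces near-deterministic linkage", {
  mk <- function(target) {
    meas <- data.frame(name = "V_MPA", nonph_mean = 25751.64,
                       nonph_sd = 7154.24, ph_mean = 55557.10,
                       ph_sd = 18449.48, target_r = target)
    cohort_config(measurements = meas)
  }
  # r_within is affine in the pooled target: extrapolate to r_within = 1
  r1 <- cohort_linkage(mk(0.5))$V_MPA$r_within
  r2 <- cohort_linkage(mk(0.7))$V_MPA$r_within
  tstar <- 0.5 + (1 - r1) * 0.2 / (r2 - r1)
  expect_lt(tstar, 1)
  lk <- cohort_linkage(mk(tstar * (1 - 1e-9)))$V_MPA
  expect_lt(abs(lk$r_within - 1), 1e-5)
  # noise SD collapses with the vanishing residual correlation
  expect_lt(lk$ph$eps_sd, 0.01 * 18449.48)
  # and a generated cohort shows an essentially exact within-group correlation
  co <- generate_cohort(mk(tstar * (1 - 1e-9)), seed = 8)
  isph <- co$group == "PH"
  expect_gt(cor(co$V_MPA[isph], co$mPAP[isph]), 1 - 1e-4)
})

test_that("infeasible correlation targets raise a config error", {
  meas <- data.frame(name = "V_LPA", nonph_mean = 23118.99, nonph_sd = 13552.82,
                     ph_mean = 37963.42, ph_sd = 16972.93, target_r = 0.99)
  cfg <- cohort_config(measurements = meas)
  expect_error(cohort_linkage(cfg), "infeasible")
})

test_that("large cohorts reproduce the configured group moments", {
  n <- 5000
  cfg <- cohort_config(n_nonph = round(n * 18 / 59), n_ph = round(n * 41 / 59))
  co <- generate_cohort(cfg, seed = 20231213)
  isph <- co$group == "PH"
  # 36 simultaneous moment checks: per-moment 3-SE bounds are Bonferroni
  # adjusted so the joint confidence matches a single 3-SE comparison
  zcrit <- qnorm(1 - pnorm(-3) / 36)
  for (i in seq_len(nrow(cfg$measurements))) {
    m <- cfg$measurements[i, ]
    for (grp in c("nonph", "ph")) {
      x <- co[[m$name]][if (grp == "ph") isph else !isph]
      mu <- m[[paste0(grp, "_mean")]]
      sg <- m[[paste0(grp, "_sd")]]
      expect_lt(abs(mean(x) - mu), zcrit * sg / sqrt(length(x)))
      expect_lt(abs(sd(x) - sg), zcrit * sg / sqrt(2 * length(x)))
    }
  }
  # mPAP matches its analytic truncated-group moments
  mm <- cohort_moments(cfg)
  expect_lt(abs(mean(co$mPAP[!isph]) - mm$nonph$mean),
            3 * mm$nonph$sd / sqrt(sum(!isph)))
  expect_lt(abs(mean(co$mPAP[isph]) - mm$ph$mean),
            3 * mm$ph$sd / sqrt(sum(isph)))
})

test_that("the configured pooled correlation is recovered at n = 2000", {
  cfg <- cohort_config(n_nonph = round(2000 * 18 / 59),
                       n_ph = round(2000 * 41 / 59))
  co <- generate_cohort(cfg, seed = 77)
  expect_lt(abs(cor(co$V_MPA, co$mPAP) - 0.744), 0.05)
})

test_that("OLS on a large cohort recovers the generating slope", {
  cfg <- cohort_config(n_nonph = 1000, n_ph = 3000)
  co <- generate_cohort(cfg, seed = 5)
  lk <- cohort_linkage(cfg)
  isph <- co$group == "PH"
  fit <- lm(V_MPA ~ mPAP, data = co[isph, ])
  se <- summary(fit)$coefficients["mPAP", "Std. Error"]
  expect_lt(abs(coef(fit)[["mPAP"]] - lk$V_MPA$ph$beta), 3 * se)
})

test_that("categorical rates are honored on average", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 9)
  rates <- list(dyspnea = c(nonph = 4 / 18, ph = 36 / 41))
  set.seed(101)
  acc <- c(nonph = 0, ph = 0)
  reps <- 5000
  for (r in seq_len(reps)) {
    cc <- attach_categoricals(co, rates)
    acc["nonph"] <- acc["nonph"] + mean(cc$dyspnea[cc$group == "non-PH"])
    acc["ph"] <- acc["ph"] + mean(cc$dyspnea[cc$group == "PH"])
  }
  expect_lt(abs(acc[["nonph"]] / reps - 4 / 18), 0.02)
  expect_lt(abs(acc[["ph"]] / reps - 36 / 41), 0.02)
})

test_that("degenerate categorical probabilities and names behave", {
  co <- generate_cohort(cohort_config(), seed = 3)
  all0 <- attach_categoricals(co, list(dyspnea = c(nonph = 0, ph = 0)))
  expect_false(any(all0$dyspnea))
  all1 <- attach_categoricals(co, list(dyspnea = c(nonph = 1, ph = 1)))
  expect_true(all(all1$dyspnea))
  expect_error(attach_categoricals(co, list(nonsense = c(nonph = 0.5, ph = 0.5))),
               "unknown")
  expect_error(attach_categoricals(co, list(dyspnea = c(nonph = -0.1, ph = 0.5))),
               "probabilities")
})
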