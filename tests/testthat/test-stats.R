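test_that("the normality gate routes to t or Wilcoxon as expected", {
  set.seed(41)
  expect_identical(normality_gate(rnorm(80), rnorm(90)), "t")
  expect_identical(normality_gate(rnorm(80), rlnorm(200, 0, 1)), "wilcoxon")
  expect_error(normality_gate(c(1, 2), rnorm(10)), "n >= 3")
  cc <- compare_continuous(rnorm(40, 1), rnorm(50, 2))
  expect_identical(cc$test, "t")
  expect_true(cc$p >= 0 && cc$p <= 1)
})

test_that("2x2 comparisons use Pearson chi-square or Fisher as appropriate", {
  dysp <- matrix(c(4, 14, 36, 5), 2, byrow = TRUE)
  expect_equal(compare_categorical(dysp)$statistic, 24.642, tolerance = 5e-4)
  chd <- matrix(c(12, 6, 10, 31), 2, byrow = TRUE)
  expect_equal(compare_categorical(chd)$statistic, 9.560, tolerance = 5e-4)
  sex <- matrix(c(7, 11, 10, 31), 2, byrow = TRUE)
  expect_equal(compare_categorical(sex)$statistic, 1.282, tolerance = 5e-4)
  # identical proportions -> chi-square 0
  expect_equal(compare_categorical(matrix(c(5, 5, 10, 10), 2, byrow = TRUE))
               $statistic, 0)
  # small expected counts -> Fisher, matching fisher.test
  small <- matrix(c(1, 9, 8, 2), 2, byrow = TRUE)
  got <- compare_categorical(small)
  expect_identical(got$test, "fisher")
  expect_equal(got$p, fisher.test(small)$p.value)
  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), 2)), "degenerate")
})

test_that("correlation is gated and Spearman matches a rank oracle", {
  set.seed(42)
  x <- rnorm(50)
  got <- correlate(x, 2 * x + 1)
  expect_identical(got$method, "pearson")
  expect_equal(got$r, 1)
  xl <- rlnorm(100, 0, 1)
  got2 <- correlate(xl, xl^3)          # strictly monotone transform
  expect_identical(got2$method, "spearman")
  expect_equal(got2$r, 1)
  # explicit rank-transform oracle on integer pairs
  xi <- c(3L, 1L, 4L, 1L, 5L, 9L, 2L, 6L, 5L, 3L)
  yi <- c(2L, 7L, 1L, 8L, 2L, 8L, 1L, 8L, 2L, 8L)
  oracle <- cor(rank(xi), rank(yi))
  got3 <- suppressWarnings(cor.test(xi, yi, method = "spearman",
                                    exact = FALSE))
  expect_equal(unname(got3$estimate), oracle)
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate(1:3, 1:3), "n >= 4")
})

test_that("ROC analysis equals brute-force pair counting and Youden rules", {
  r <- roc_analysis(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  r2 <- roc_analysis(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(r2$auc, 0.75)
  expect_equal(r2$auc, auc_bruteforce(c(1, 2, 3, 4), c(0, 1, 0, 1)))
  set.seed(43)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    scores <- sample(1:6, n, replace = TRUE)   # with ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    rr <- roc_analysis(scores, labels)
    expect_equal(rr$auc, auc_bruteforce(scores, labels))
    # cutoff is an observed value and accuracy is (TP+TN)/N
    expect_true(rr$cutoff %in% scores)
    tp <- sum(scores >= rr$cutoff & labels == 1)
    tn <- sum(scores < rr$cutoff & labels == 0)
    expect_equal(rr$accuracy, (tp + tn) / n)
    expect_true(rr$auc_ci_95[1] <= rr$auc && rr$auc <= rr$auc_ci_95[2])
  }
  expect_error(roc_analysis(1:4, c(1, 1, 1, 1)), "single class")
})

test_that("AUC is invariant to monotone transforms and flips with sign", {
  set.seed(44)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.4)
  labels[1:2] <- c(0, 1)
  a <- roc_analysis(scores, labels)$auc
  expect_equal(roc_analysis(exp(scores), labels)$auc, a)
  expect_equal(roc_analysis(-scores, labels)$auc, 1 - a)
})

test_that("the DeLong test matches pROC and its invariances", {
  set.seed(45)
  n <- 59
  labels <- c(rep(0, 18), rep(1, 41))
  s1 <- rnorm(n) + labels
  s2 <- 0.5 * s1 + rnorm(n, 0, 0.8)
  dt <- delong_test(s1, s2, labels)
  expect_equal(dt$z, -delong_test(s2, s1, labels)$z)
  # self and rank-transform comparisons are exactly null
  expect_identical(delong_test(s1, s1, labels)$z, 0)
  expect_identical(delong_test(s1, exp(s1), labels)$p, 1)
  skip_if_not_installed("pROC")
  r1 <- pROC::roc(labels, s1, quiet = TRUE, direction = "<")
  r2 <- pROC::roc(labels, s2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(r1, r2, method = "delong")
  expect_equal(dt$z, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(dt$p, ref$p.value, tolerance = 1e-9)
  expect_equal(roc_analysis(s1, labels)$auc, as.numeric(pROC::auc(r1)))
  expect_error(delong_test(s1[-1], s2, labels), "pairing|mismatch")
})

test_that("decision curves match the closed-form references and brute force", {
  set.seed(46)
  n <- 30
  labels <- c(rep(1, 12), rep(0, 18))
  scores <- rnorm(n) + labels
  d <- decision_curve(scores, labels)
  expect_true(all(d$nb_none == 0))
  prev <- mean(labels)
  expect_equal(d$nb_all, prev - (1 - prev) * d$threshold / (1 - d$threshold))
  expect_equal(d$nb_all[d$threshold == 0.25],
               prev - (1 - prev) * 0.25 / 0.75)
  expect_true(all(d$nb_model <= prev + 1e-12))
  # brute-force confusion counts at one threshold
  prob <- fitted(glm(labels ~ scores, family = binomial()))
  pt <- 0.4
  tp <- 0; fp <- 0
  for (i in seq_len(n)) {
    if (prob[i] >= pt && labels[i] == 1) tp <- tp + 1
    if (prob[i] >= pt && labels[i] == 0) fp <- fp + 1
  }
  expect_equal(d$nb_model[abs(d$threshold - pt) < 1e-9],
               tp / n - fp / n * pt / (1 - pt))
  # perfect separation falls back to min-max calibration with a warning
  sep_scores <- c(rnorm(15, -3), rnorm(15, 3))
  sep_labels <- rep(c(0, 1), each = 15)
  expect_warning(ds <- decision_curve(sep_scores, sep_labels), "separation")
  expect_true(all(is.finite(ds$nb_model)))
  expect_error(decision_curve(scores, labels, thresholds = c(0, 0.5)),
               "strictly inside")
})

test_that("forward stepwise recovers exact relations and matches the oracle", {
  set.seed(47)
  x1 <- rnorm(50)
  noise <- rnorm(50)
  fit <- forward_stepwise(data.frame(x1 = x1, noise = noise), 2 * x1)
  expect_identical(fit$predictors, "x1")
  expect_equal(unname(fit$coefficients["x1"]), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # p_enter = 0 admits nothing
  empty <- forward_stepwise(data.frame(x1 = x1), 2 * x1, p_enter = 0)
  expect_identical(length(empty$predictors), 0L)
  # exhaustive add-one oracle over seeded n = 50 problems
  for (s in 1:5) {
    set.seed(100 + s)
    X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
    y <- 1.5 * X$a + 0.8 * X$b + rnorm(50, 0, 1)
    got <- forward_stepwise(X, y)
    oracle <- character(0)
    repeat {
      rem <- setdiff(names(X), oracle)
      if (!length(rem)) break
      ps <- sapply(rem, function(v) {
        f0 <- if (length(oracle)) lm(y ~ ., data = X[oracle]) else lm(y ~ 1)
        f1 <- lm(y ~ ., data = X[c(oracle, v)])
        anova(f0, f1)[2, "Pr(>F)"]
      })
      if (min(ps) >= 0.05) break
      oracle <- c(oracle, rem[which.min(ps)])
    }
    expect_identical(got$predictors, oracle)
    # r-squared is non-decreasing along the selection path
    expect_true(all(diff(c(0, got$path)) >= -1e-12))
  }
})

test_that("published fixture models predict from measurements", {
  models <- pa_pressure_models()
  expect_equal(predict_pressure(models$mPAP, list(V_MPA = 0)), 8.178)
  expect_equal(predict_pressure(models$DPAP, list(v_mpa = 0)), 1.418)
  # linearity: the increment doubles with the predictor
  p1 <- predict_pressure(models$mPAP, list(V_MPA = 10000)) - 8.178
  p2 <- predict_pressure(models$mPAP, list(V_MPA = 20000)) - 8.178
  expect_equal(p2, 2 * p1)
  # vessel_measurements objects are accepted via case-insensitive names
  meas <- structure(list(d_mpa = 40.5, v_mpa = 70680.46, v_rpa = 44664.05),
                    class = "vessel_measurements")
  expect_equal(predict_pressure(models$mPAP, meas), 8.178 + 0.0006 * 70680.46)
  expect_equal(predict_pressure(models$SPAP, meas),
               -11.137 + 0.0006 * 44664.05 + 1.259 * 40.5)
  expect_error(predict_pressure(models$SPAP, list(V_MPA = 1)), "missing")
})

test_that("cohort-level tables carry the expected structure", {
  co <- attach_categoricals(generate_cohort(cohort_config(), seed = 55),
                            seed = 56)
  tab <- compare_cohort(co)
  expect_true(all(c("mPAP", "V_MPA", "dyspnea") %in% tab$variable))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  cm <- correlate_cohort(co)
  expect_identical(nrow(cm), 27L)
  expect_true(all(abs(cm$r) <= 1))
  rt <- roc_table(co)
  expect_identical(nrow(rt), 9L)
  expect_true(all(rt$auc >= 0 & rt$auc <= 1))
  dl <- delong_table(co)
  expect_identical(nrow(dl), 9L)
  models <- stepwise_pressures(co)
  expect_named(models, c("mPAP", "SPAP", "DPAP"))
  expect_true(all(vapply(models, function(m) m$r_squared, numeric(1)) >= 0))
})
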