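#' Normality-gated choice between Student t and Wilcoxon rank-sum
#'
#' Returns `"t"` iff both samples pass the Shapiro-Wilk test at `alpha`
#' (default 0.05, the study-wide significance level), otherwise
#' `"wilcoxon"`.
#'
#' @param sample_a,sample_b numeric vectors, each with n >= 3.
#' @param alpha Shapiro-Wilk significance level.
#' @return `"t"` or `"wilcoxon"`.
#' @export
normality_gate <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 3 || length(sample_b) < 3)
    stop("normality gate requires n >= 3 in both samples")
  pa <- shapiro.test(sample_a)$p.value
  pb <- shapiro.test(sample_b)$p.value
  if (pa > alpha && pb > alpha) "t" else "wilcoxon"
}

#' Two-group comparison of a continuous variable
#'
#' Student t-test (pooled variance) when both groups pass the normality
#' gate, Wilcoxon rank-sum (normal approximation) otherwise; per-group
#' summaries are mean (SD) under the t branch and median (IQR) under the
#' Wilcoxon branch.
#'
#' @param sample_a,sample_b numeric vectors (e.g. non-PH and PH groups).
#' @param alpha normality-gate level.
#' @return A `group_comparison`: `test`, `statistic`, `p`, `summary_a`,
#'   `summary_b`.
#' @export
compare_continuous <- function(sample_a, sample_b, alpha = 0.05) {
  test <- normality_gate(sample_a, sample_b, alpha)
  if (test == "t") {
    ht <- t.test(sample_a, sample_b, var.equal = TRUE)
    summ <- function(x) sprintf("%.2f ± %.2f", mean(x), sd(x))
  } else {
    ht <- wilcox.test(sample_a, sample_b, exact = FALSE, correct = FALSE)
    summ <- function(x) sprintf("%.2f (%.2f~%.2f)", median(x),
                                quantile(x, 0.25), quantile(x, 0.75))
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p = ht$p.value, summary_a = summ(sample_a),
                 summary_b = summ(sample_b)),
            class = "group_comparison")
}

#' Two-by-two categorical comparison
#'
#' Pearson chi-square without continuity correction when all expected counts
#' are >= 5, otherwise Fisher's exact test (two-sided, point-probability
#' rule). These conventions reproduce the statistics printed by mainstream
#' clinical statistics software.
#'
#' @param table 2x2 matrix of nonnegative integer counts (rows: groups,
#'   columns: outcome), both margins positive.
#' @param method `"auto"`, `"chisq"` or `"fisher"`.
#' @return A `group_comparison` with `test` (`"chi-square"` or `"fisher"`),
#'   `statistic` (the X^2 statistic, NA for Fisher) and `p`.
#' @export
compare_categorical <- function(table, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("expected a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: a margin is zero")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  use_chisq <- switch(method, auto = all(expected >= 5),
                      chisq = TRUE, fisher = FALSE)
  if (use_chisq) {
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    structure(list(test = "chi-square", statistic = unname(ht$statistic),
                   p = ht$p.value, table = table),
              class = "group_comparison")
  } else {
    ht <- fisher.test(table)
    structure(list(test = "fisher", statistic = NA_real_, p = ht$p.value,
                   table = table), class = "group_comparison")
  }
}

#' Distribution-gated correlation
#'
#' Pearson when both variables pass the Shapiro-Wilk normality test at
#' `alpha`, Spearman otherwise.
#'
#' @param x,y equal-length numeric vectors, n >= 4, neither constant.
#' @param alpha normality-gate level.
#' @return list with `r`, `p`, `method`.
#' @export
correlate <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("correlation requires n >= 4")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  method <- if (shapiro.test(x)$p.value > alpha &&
                shapiro.test(y)$p.value > alpha) "pearson" else "spearman"
  ht <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ht$estimate), p = ht$p.value, method = method)
}

# DeLong structural components of one marker
.delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' ROC analysis with Youden-optimal cutpoint
#'
#' AUC by the Mann-Whitney pair-counting estimator (ties count 1/2); the
#' cutoff maximizes Youden's J = sensitivity + specificity - 1 over the
#' observed score values, ties broken toward the lower cutoff (higher
#' sensitivity). Positivity rule: `score >= cutoff`. The 95% CI uses the
#' DeLong variance.
#'
#' @param scores numeric marker values (higher = more disease-like).
#' @param labels binary outcome (0/1, logical, or a 2-level factor whose
#'   second level is the positive class).
#' @return A `roc_result`: `auc`, `auc_ci_95`, `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `accuracy`, `youden`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- .as_binary(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  dc <- .delong_components(scores, labels)
  v <- function(x) if (length(x) > 1) var(x) else 0
  se <- sqrt(v(dc$v10) / dc$m + v(dc$v01) / dc$n)
  ci <- pmin(pmax(dc$auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cand <- sort(unique(scores))
  sens <- vapply(cand, function(c) mean(pos >= c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg < c), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1]          # ties -> lower cutoff
  cutoff <- cand[best]
  tp <- sum(pos >= cutoff); fn <- dc$m - tp
  fp <- sum(neg >= cutoff); tn <- dc$n - fp
  structure(list(auc = dc$auc, auc_ci_95 = ci, cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
                 accuracy = (tp + tn) / (dc$m + dc$n),
                 youden = j[best]),
            class = "roc_result")
}

.as_binary <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2])
  else if (is.logical(labels)) as.integer(labels)
  else {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1))) stop("labels must be binary")
    as.integer(labels)
  }
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using
#' DeLong's structural-components covariance; `Z = (auc_1 - auc_2) /
#' SE(diff)` with a two-sided normal p-value. When the markers are
#' rank-identical the difference variance is zero and `Z = 0, p = 1`.
#'
#' @param scores_1,scores_2 paired marker values.
#' @param labels binary outcome shared by both markers.
#' @return A `delong_result`: `z`, `p`, `auc_1`, `auc_2`.
#' @export
delong_test <- function(scores_1, scores_2, labels) {
  if (length(scores_1) != length(scores_2))
    stop("markers are not paired: length mismatch")
  labels <- .as_binary(labels)
  d1 <- .delong_components(scores_1, labels)
  d2 <- .delong_components(scores_2, labels)
  cv <- function(a, b) if (length(a) > 1) cov(cbind(a, b)) else matrix(0, 2, 2)
  s10 <- cv(d1$v10, d2$v10)
  s01 <- cv(d1$v01, d2$v01)
  vdiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / d1$m +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / d1$n
  if (!is.finite(vdiff) || vdiff <= 0 ||
      abs(d1$auc - d2$auc) < .Machine$double.eps) {
    z <- 0; p <- 1
    if (is.finite(vdiff) && vdiff > 0) {
      z <- (d1$auc - d2$auc) / sqrt(vdiff)
      p <- 2 * pnorm(-abs(z))
    }
  } else {
    z <- (d1$auc - d2$auc) / sqrt(vdiff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(z = z, p = p, auc_1 = d1$auc, auc_2 = d2$auc,
                 var_diff = vdiff),
            class = "delong_result")
}

#' Decision curve analysis (net benefit)
#'
#' Scores are calibrated to probabilities by a univariable logistic fit (on
#' perfect separation: a rank-preserving min-max rescaling with a warning);
#' net benefit at threshold probability pt is `TP/N - (FP/N) * pt/(1-pt)`
#' with positivity `probability >= pt`. Treat-all and treat-none reference
#' curves are included.
#'
#' @param scores numeric marker.
#' @param labels binary outcome.
#' @param thresholds probability grid in (0, 1); default 0.01..0.99 step
#'   0.01.
#' @return A `dca_result` data.frame: `threshold`, `nb_model`, `nb_all`,
#'   `nb_none`.
#' @export
decision_curve <- function(scores, labels, thresholds = seq(0.01, 0.99, 0.01)) {
  labels <- .as_binary(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  sep <- FALSE
  prob <- withCallingHandlers(
    fitted(glm(labels ~ scores, family = binomial())),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep && min(prob[labels == 1]) > max(prob[labels == 0])) {
    warning("perfect separation in the logistic calibration; ",
            "falling back to rank-preserving min-max calibration")
    prob <- (scores - min(scores)) / (max(scores) - min(scores))
  }
  N <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(pt) {
    pos <- prob >= pt
    sum(pos & labels == 1) / N - sum(pos & labels == 0) / N * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  structure(data.frame(threshold = thresholds, nb_model = nb,
                       nb_all = nb_all, nb_none = 0),
            class = c("dca_result", "data.frame"))
}

#' Forward stepwise linear regression (p-to-enter)
#'
#' Starts from the intercept-only model and repeatedly adds the candidate
#' with the smallest partial-F p-value while it is below `p_enter`
#' (default 0.05); there is no removal step. The selected set is refit by
#' ordinary least squares.
#'
#' @param predictors data.frame of candidate predictors (named numeric
#'   columns).
#' @param response numeric response vector.
#' @param p_enter entry threshold on the partial-F p-value.
#' @param response_name label stored in the result.
#' @return A `linear_model`: `response`, `predictors` (in selection order),
#'   `intercept`, `coefficients`, `r_squared`, `path` (per-step r-squared).
#' @export
forward_stepwise <- function(predictors, response, p_enter = 0.05,
                             response_name = "response") {
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(response)) stop("length mismatch")
  if (length(response) <= ncol(predictors) + 2)
    stop("need n > number of candidates + 2")
  selected <- character(0)
  path_r2 <- numeric(0)
  dat <- cbind(predictors, .y = response)
  repeat {
    remaining <- setdiff(names(predictors), selected)
    if (length(remaining) == 0) break
    base_f <- if (length(selected)) paste(selected, collapse = " + ") else "1"
    fit0 <- lm(stats::as.formula(paste(".y ~", base_f)), data = dat)
    pvals <- vapply(remaining, function(v) {
      fit1 <- lm(stats::as.formula(paste(".y ~", base_f, "+", v)), data = dat)
      anova(fit0, fit1)[2, "Pr(>F)"]
    }, numeric(1))
    if (all(!is.finite(pvals)) || min(pvals, na.rm = TRUE) >= p_enter) break
    best <- remaining[which.min(pvals)]
    selected <- c(selected, best)
    fit <- lm(stats::as.formula(paste(".y ~", paste(selected, collapse = " + "))),
              data = dat)
    path_r2 <- c(path_r2, suppressWarnings(summary(fit)$r.squared))
  }
  if (length(selected)) {
    fit <- lm(stats::as.formula(paste(".y ~", paste(selected, collapse = " + "))),
              data = dat)
    mm <- stats::model.matrix(fit)
    if (kappa(mm, exact = TRUE) > 1e8)
      stop("selected predictors are collinear (condition number > 1e8)")
    cf <- coef(fit)
    linear_model(intercept = unname(cf[1]),
                 coefficients = cf[-1][selected],
                 response = response_name,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 path = path_r2)
  } else {
    linear_model(intercept = mean(response), coefficients = numeric(0),
                 response = response_name, r_squared = 0, path = numeric(0))
  }
}

#' Linear pressure-prediction model
#'
#' @param intercept model intercept (mmHg).
#' @param coefficients named numeric vector of slopes.
#' @param response which pressure the model predicts.
#' @param r_squared goodness of fit (optional).
#' @param path per-step r-squared of the selection path (optional).
#' @export
linear_model <- function(intercept, coefficients, response = "mPAP",
                         r_squared = NA_real_, path = numeric(0)) {
  stopifnot(length(coefficients) == 0 || !is.null(names(coefficients)))
  structure(list(response = response,
                 predictors = names(coefficients) %||% character(0),
                 intercept = intercept, coefficients = coefficients,
                 r_squared = r_squared, path = path),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  rhs <- if (length(x$coefficients))
    paste(sprintf("%+.4g * %s", x$coefficients, names(x$coefficients)),
          collapse = " ")
  else ""
  cat(sprintf("predicted %s = %.4g %s  (R^2 = %.3f)\n", x$response,
              x$intercept, rhs, x$r_squared))
  invisible(x)
}

#' Published pressure-prediction equations
#'
#' The forward-stepwise linear models reported for this cohort type:
#' `mPAP = 8.178 + 0.0006 V_MPA` (R^2 0.574), `DPAP = 1.418 + 0.0005 V_MPA`
#' (R^2 0.590), `SPAP = -11.137 + 0.0006 V_RPA + 1.259 D_MPA` (R^2 0.583).
#' Shipped as fixture models for [predict_pressure()].
#'
#' @return named list of [linear_model()] objects.
#' @export
pa_pressure_models <- function() {
  list(
    mPAP = linear_model(8.178, c(V_MPA = 0.0006), "mPAP", r_squared = 0.574),
    DPAP = linear_model(1.418, c(V_MPA = 0.0005), "DPAP", r_squared = 0.590),
    SPAP = linear_model(-11.137, c(V_RPA = 0.0006, D_MPA = 1.259), "SPAP",
                        r_squared = 0.583))
}

#' Predict a pulmonary artery pressure from CT measurements
#'
#' @param model a [linear_model()].
#' @param measurements a `vessel_measurements`, or any named list/vector
#'   containing the model's predictors (names matched case-insensitively).
#' @return predicted pressure in mmHg.
#' @export
predict_pressure <- function(model, measurements) {
  vals <- unlist(unclass(measurements))
  names(vals) <- toupper(names(vals))
  out <- model$intercept
  for (nm in names(model$coefficients)) {
    key <- toupper(nm)
    if (!key %in% names(vals))
      stop("measurement ", nm, " required by the model is missing")
    out <- out + model$coefficients[[nm]] * vals[[key]]
  }
  unname(out)
}

# ---------------------------------------------------------------------------
# Cohort-level convenience analyses (the CSV-in, tables-out layer)
# ---------------------------------------------------------------------------

.measurement_cols <- c("D_MPA", "A_MPA", "V_MPA", "D_RPA", "A_RPA", "V_RPA",
                       "D_LPA", "A_LPA", "V_LPA")
.pressure_cols <- c("mPAP", "SPAP", "DPAP")

#' Group-comparison table for a cohort
#'
#' One row per continuous variable (pressures + measurements, gated t /
#' Wilcoxon) and per logical column (chi-square / Fisher), mirroring the
#' usual Table 1/2 layout of a case-control report.
#'
#' @param cohort a cohort data.frame with a `group` column.
#' @return data.frame with columns `variable`, `test`, `statistic`, `p`,
#'   `nonph`, `ph`.
#' @export
compare_cohort <- function(cohort) {
  isph <- cohort$group == "PH"
  rows <- list()
  for (v in intersect(c(.pressure_cols, .measurement_cols), names(cohort))) {
    cc <- compare_continuous(cohort[[v]][!isph], cohort[[v]][isph])
    rows[[v]] <- data.frame(variable = v, test = cc$test,
                            statistic = cc$statistic, p = cc$p,
                            nonph = cc$summary_a, ph = cc$summary_b,
                            stringsAsFactors = FALSE)
  }
  for (v in names(cohort)[vapply(cohort, is.logical, logical(1))]) {
    tab <- rbind(c(sum(cohort[[v]][!isph]), sum(!cohort[[v]][!isph])),
                 c(sum(cohort[[v]][isph]), sum(!cohort[[v]][isph])))
    cc <- compare_categorical(tab)
    rows[[v]] <- data.frame(variable = v, test = cc$test,
                            statistic = cc$statistic, p = cc$p,
                            nonph = sprintf("%d/%d", tab[1, 1], sum(tab[1, ])),
                            ph = sprintf("%d/%d", tab[2, 1], sum(tab[2, ])),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measurement-pressure correlation matrix
#'
#' Gated Pearson/Spearman correlation of each CT measurement against each
#' pressure (the correlation-heatmap data of such studies).
#'
#' @param cohort a cohort data.frame.
#' @return data.frame with `measurement`, `pressure`, `r`, `p`, `method`.
#' @export
correlate_cohort <- function(cohort) {
  out <- expand.grid(measurement = intersect(.measurement_cols, names(cohort)),
                     pressure = intersect(.pressure_cols, names(cohort)),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i)
    correlate(cohort[[out$measurement[i]]], cohort[[out$pressure[i]]]))
  out$r <- vapply(res, `[[`, numeric(1), "r")
  out$p <- vapply(res, `[[`, numeric(1), "p")
  out$method <- vapply(res, `[[`, character(1), "method")
  out
}

#' ROC table over all measurements
#'
#' Per-measurement ROC against the PH label, with Youden cutoff and
#' confusion metrics (the Table-3 layout).
#'
#' @param cohort a cohort data.frame.
#' @return data.frame with columns `variable`, `cutoff`, `auc`, `ci_lo`,
#'   `ci_hi`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
roc_table <- function(cohort) {
  labels <- cohort$group == "PH"
  rows <- lapply(intersect(.measurement_cols, names(cohort)), function(v) {
    r <- roc_analysis(cohort[[v]], labels)
    data.frame(variable = v, cutoff = r$cutoff, auc = r$auc,
               ci_lo = r$auc_ci_95[1], ci_hi = r$auc_ci_95[2],
               sensitivity = r$sensitivity, specificity = r$specificity,
               ppv = r$ppv, npv = r$npv, accuracy = r$accuracy,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise DeLong comparisons within each artery
#'
#' Compares D vs A, D vs V and A vs V for MPA, RPA and LPA.
#'
#' @param cohort a cohort data.frame.
#' @return data.frame with `artery`, `marker_1`, `marker_2`, `auc_1`,
#'   `auc_2`, `z`, `p`.
#' @export
delong_table <- function(cohort) {
  labels <- cohort$group == "PH"
  rows <- list()
  for (art in c("MPA", "RPA", "LPA")) {
    pairs <- utils::combn(paste0(c("D_", "A_", "V_"), art), 2)
    for (j in seq_len(ncol(pairs))) {
      dt <- delong_test(cohort[[pairs[1, j]]], cohort[[pairs[2, j]]], labels)
      rows[[length(rows) + 1]] <-
        data.frame(artery = art, marker_1 = pairs[1, j], marker_2 = pairs[2, j],
                   auc_1 = dt$auc_1, auc_2 = dt$auc_2, z = dt$z, p = dt$p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Forward-stepwise pressure models for a cohort
#'
#' For each pressure, candidates are the measurements with a significant
#' gated correlation against that pressure (p < 0.05); the model is then
#' selected by [forward_stepwise()].
#'
#' @param cohort a cohort data.frame.
#' @param p_enter entry threshold.
#' @return named list of [linear_model()] objects (one per pressure).
#' @export
stepwise_pressures <- function(cohort, p_enter = 0.05) {
  out <- list()
  meas <- intersect(.measurement_cols, names(cohort))
  for (pr in intersect(.pressure_cols, names(cohort))) {
    sig <- meas[vapply(meas, function(v)
      correlate(cohort[[v]], cohort[[pr]])$p < 0.05, logical(1))]
    out[[pr]] <- if (length(sig))
      forward_stepwise(cohort[sig], cohort[[pr]], p_enter, response_name = pr)
    else
      linear_model(mean(cohort[[pr]]), numeric(0), pr, 0)
  }
  out
}
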