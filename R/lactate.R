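#' Normalize local capillary lactate by the systemic level
#'
#' Normalized LCL is the local capillary lactate minus the subject's systemic
#' lactate; values may be negative and are preserved as-is.
#'
#' @param lcl Numeric vector of local capillary lactates (mmol/L), or a
#'   cohort data.frame with columns `lcl_mmol_l` and
#'   `systemic_lactate_mmol_l`.
#' @param systemic Numeric vector of systemic lactates (ignored when `lcl`
#'   is a data.frame).
#' @return Numeric vector, elementwise `lcl - systemic`, order preserved.
#' @export
normalize_lcl <- function(lcl, systemic = NULL) {
  if (is.data.frame(lcl)) {
    systemic <- lcl$systemic_lactate_mmol_l
    lcl <- lcl$lcl_mmol_l
  }
  if (!length(lcl))
    stop_perfmap("perfmap_parameter_error", "no records")
  lcl - systemic
}

#' Fit the exponential decay model y = exp(-a x + b)
#'
#' Nonlinear least squares on the raw scale (Levenberg-Marquardt), i.e.
#' minimizing `sum (y_i - exp(-a x_i + b))^2`, initialized from a log-linear
#' fit of `log(max(y, eps))` on `x`. With `loss = "log"` the log-linear fit
#' itself is returned (both conventions are plausible readings of a
#' published exponential calibration; raw is the default).
#'
#' @param x Predictor values (>= 3 points, not all equal).
#' @param y Response values (normalized lactate; non-positive values are
#'   kept in the raw-scale fit and floored at `eps` only for
#'   initialization).
#' @param loss `"raw"` (default) or `"log"`.
#' @param eps Floor applied to `y` for the log-scale initialization.
#' @param max_restarts Jittered re-initializations tried on non-convergence.
#' @return List with `a`, `b`, `fitted`, `loss`, `converged`.
#' @export
fit_exponential <- function(x, y, loss = c("raw", "log"), eps = 1e-3,
                            max_restarts = 5) {
  loss <- match.arg(loss)
  if (length(x) != length(y) || length(x) < 3)
    stop_perfmap("perfmap_parameter_error", "need >= 3 paired points")
  if (stats::sd(x) == 0)
    stop_perfmap("perfmap_parameter_error", "predictor values are all equal")
  ll <- stats::lm(log(pmax(y, eps)) ~ x)
  a0 <- -unname(stats::coef(ll)[2]); b0 <- unname(stats::coef(ll)[1])
  if (loss == "log") {
    return(list(a = a0, b = b0, fitted = exp(-a0 * x + b0),
                loss = "log", converged = TRUE))
  }
  # the initializer may already fit to machine precision (degenerate for the
  # optimizer's gradient check): accept it outright
  r0 <- y - exp(-a0 * x + b0)
  if (sum(r0^2) <= 1e-20 * max(1, sum(y^2)))
    return(list(a = a0, b = b0, fitted = exp(-a0 * x + b0),
                loss = "raw", converged = TRUE))
  dat <- data.frame(x = x, y = y)
  start <- c(a = a0, b = b0)
  fit <- NULL; last_err <- NULL
  for (k in 0:max_restarts) {
    st <- if (k == 0) start else
      start * stats::runif(2, 0.5, 1.5) + stats::rnorm(2, 0, c(0.01, 0.1))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ exp(-a * x + b), data = dat,
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop_perfmap("perfmap_fit_failure",
                 "exponential fit failed after %d restarts (%s)",
                 max_restarts, last_err %||% "unknown")
  cf <- stats::coef(fit)
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       fitted = exp(-cf[["a"]] * x + cf[["b"]]),
       loss = "raw", converged = TRUE)
}

#' Exponential lactate prediction model
#'
#' Fits `LCL = exp(-a * metric + b) + systemic lactate` to a cohort, where
#' the metric is either the tissue oxygen saturation (`"sto2"`) or the
#' fluorescence time-to-peak slope (`"fler_slope"`), and the exponential
#' term is fit to the systemic-normalized lactate by raw-scale least
#' squares (see [fit_exponential()]). Returns a classed model object with
#' the usual methods (`print`, `summary`, `coef`, `predict`, `residuals`,
#' `fitted`, `plot`, `simulate`).
#'
#' @param cohort Data.frame with columns `subject_id`, `roi_label`,
#'   `sto2_pct`, `fler_slope`, `lcl_mmol_l`, `systemic_lactate_mmol_l`
#'   (see [generate_cohort()]).
#' @param predictor `"sto2"` or `"fler_slope"`.
#' @param loss Passed to [fit_exponential()].
#' @return Object of class `lcl_model`.
#' @export
fit_lcl_model <- function(cohort, predictor = c("sto2", "fler_slope"),
                          loss = c("raw", "log")) {
  predictor <- match.arg(predictor)
  loss <- match.arg(loss)
  xcol <- if (predictor == "sto2") "sto2_pct" else "fler_slope"
  x <- cohort[[xcol]]
  y <- normalize_lcl(cohort)
  fit <- fit_exponential(x, y, loss = loss)
  structure(list(a = fit$a, b = fit$b, predictor = predictor, loss = loss,
                 data = data.frame(subject_id = cohort$subject_id,
                                   roi_label = cohort$roi_label,
                                   x = x, y = y,
                                   lcl = cohort$lcl_mmol_l,
                                   systemic = cohort$systemic_lactate_mmol_l),
                 call = match.call()),
            class = "lcl_model")
}

#' Predict local capillary lactate from a perfusion metric
#'
#' `predicted LCL = exp(-a x + b) + systemic`: strictly decreasing in the
#' metric, always above the systemic level, approaching it as the metric
#' grows.
#'
#' @param model An `lcl_model` or any list with elements `a` and `b`.
#' @param x Metric value(s).
#' @param systemic Systemic lactate (mmol/L), >= 0; recycled.
#' @return Predicted LCL, mmol/L.
#' @export
predict_lcl <- function(model, x, systemic = 0) {
  if (any(systemic < 0))
    stop_perfmap("perfmap_parameter_error", "systemic lactate must be >= 0")
  exp(-model$a * x + model$b) + systemic
}

#' @export
coef.lcl_model <- function(object, ...) c(a = object$a, b = object$b)

#' @export
#' @param newdata Optional data.frame with the predictor column
#'   (`sto2_pct`/`fler_slope`) and `systemic_lactate_mmol_l`; defaults to the
#'   training data.
#' @rdname fit_lcl_model
predict.lcl_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(predict_lcl(object, object$data$x, object$data$systemic))
  xcol <- if (object$predictor == "sto2") "sto2_pct" else "fler_slope"
  predict_lcl(object, newdata[[xcol]],
              newdata$systemic_lactate_mmol_l %||% 0)
}

#' @export
fitted.lcl_model <- function(object, ...) {
  predict_lcl(object, object$data$x, object$data$systemic)
}

#' @export
residuals.lcl_model <- function(object, ...) {
  object$data$lcl - fitted(object)
}

#' @export
print.lcl_model <- function(x, digits = 4, ...) {
  cat(sprintf("Exponential lactate model (%s predictor, %s-scale fit)\n",
              x$predictor, x$loss))
  cat(sprintf("  predicted LCL = exp(-%.*g * x + %.*g) + systemic lactate\n",
              digits, x$a, digits, x$b))
  cat(sprintf("  n = %d records, %d subjects\n", nrow(x$data),
              length(unique(x$data$subject_id))))
  invisible(x)
}

#' @export
summary.lcl_model <- function(object, ...) {
  err <- abs(residuals(object))
  out <- list(model = object,
              coefficients = coef(object),
              errors = error_summary(err, object$data$lcl))
  class(out) <- "summary.lcl_model"
  out
}

#' @export
print.summary.lcl_model <- function(x, ...) {
  print(x$model)
  cat("In-sample absolute prediction error:\n")
  print(x$errors)
  invisible(x)
}

#' @export
plot.lcl_model <- function(x, ...) {
  ord <- order(x$data$x)
  graphics::plot(x$data$x, x$data$y,
                 xlab = if (x$predictor == "sto2") "StO2 (%)" else
                   "time-to-peak slope (1/s)",
                 ylab = "normalized LCL (mmol/L)", pch = 19, ...)
  xx <- seq(min(x$data$x), max(x$data$x), length.out = 200)
  graphics::lines(xx, exp(-x$a * xx + x$b), col = "red3", lwd = 2)
  invisible(x)
}

#' @export
#' @param nsim,seed,object Standard [stats::simulate()] arguments.
#' @param noise_sd Log-scale SD of the multiplicative noise applied to the
#'   exponential term.
#' @rdname fit_lcl_model
simulate.lcl_model <- function(object, nsim = 1, seed = NULL,
                               noise_sd = 0.3, ...) {
  mu <- exp(-object$a * object$data$x + object$b)
  with_seed(seed, {
    out <- replicate(nsim, mu * exp(stats::rnorm(length(mu), 0, noise_sd)) +
                       object$data$systemic)
    as.data.frame(out)
  })
}

#' Leave-one-subject-out cross-validation of a lactate model
#'
#' For each subject, fits the model on all other subjects and predicts the
#' held-out subject's ROIs; all of a subject's ROIs are held out together.
#'
#' @inheritParams fit_lcl_model
#' @return Data.frame (class `lcl_cv`) with one row per record:
#'   `subject_id`, `roi_label`, `observed`, `predicted`, `abs_error`.
#' @export
loo_cv <- function(cohort, predictor = c("sto2", "fler_slope"),
                   loss = c("raw", "log")) {
  predictor <- match.arg(predictor)
  loss <- match.arg(loss)
  subjects <- unique(cohort$subject_id)
  if (length(subjects) < 3)
    stop_perfmap("perfmap_parameter_error", "need >= 3 subjects for LOO-CV")
  xcol <- if (predictor == "sto2") "sto2_pct" else "fler_slope"
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    train <- cohort[cohort$subject_id != s, ]
    test <- cohort[cohort$subject_id == s, ]
    m <- tryCatch(fit_lcl_model(train, predictor, loss),
                  error = function(e)
                    stop_perfmap("perfmap_fit_failure",
                                 "fold for subject %s failed: %s",
                                 s, conditionMessage(e)))
    pred <- predict_lcl(m, test[[xcol]], test$systemic_lactate_mmol_l)
    rows[[i]] <- data.frame(subject_id = test$subject_id,
                            roi_label = test$roi_label,
                            observed = test$lcl_mmol_l,
                            predicted = pred,
                            abs_error = abs(test$lcl_mmol_l - pred))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$subject_id, sort(subjects))), ]
  rownames(out) <- NULL
  class(out) <- c("lcl_cv", "data.frame")
  out
}

#' Summary statistics of absolute prediction errors
#'
#' Mean, SD and median of the absolute errors, plus `q95_threshold`: the
#' observed-LCL level below which 95 percent of the errors occur (the 95th
#' percentile, linear interpolation, of the observed LCL over the
#' error-bearing records).
#'
#' @param errors Absolute prediction errors, mmol/L.
#' @param lcls Observed LCLs aligned with `errors`.
#' @return Object of class `error_summary`.
#' @export
error_summary <- function(errors, lcls) {
  if (!length(errors))
    stop_perfmap("perfmap_parameter_error", "no errors supplied")
  if (length(errors) != length(lcls))
    stop_perfmap("perfmap_dimension_error", "errors and lcls lengths differ")
  structure(list(mean = mean(errors),
                 sd = if (length(errors) > 1) stats::sd(errors) else 0,
                 median = stats::median(errors),
                 q95_threshold = unname(stats::quantile(lcls, 0.95, type = 7)),
                 n = length(errors)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("  mean %.3g +/- %.3g mmol/L, median %.3g mmol/L (n = %d)\n",
              x$mean, x$sd, x$median, x$n))
  cat(sprintf("  95%% of errors occur for LCL < %.3g mmol/L\n", x$q95_threshold))
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of two error vectors
#'
#' Compares two lactate-prediction models record-wise (same subject-ROI
#' under both models). Zero differences are dropped; for up to
#' `exact_max` nonzero pairs the p-value comes from the exact tie-aware
#' null distribution of the positive-rank sum (computed by convolution over
#' the signed ranks), above that from the normal approximation with tie
#' correction and continuity correction. If all differences are zero the
#' result is degenerate with p = 1 by convention.
#'
#' @param errors_a,errors_b Paired absolute errors, equal length >= 5.
#' @param exact_max Largest number of nonzero pairs for which the exact
#'   distribution is used (default 25).
#' @return List with `statistic` (positive-rank sum V), `p.value`,
#'   `n_effective`, `method`.
#' @export
compare_models_wilcoxon <- function(errors_a, errors_b, exact_max = 25) {
  if (length(errors_a) != length(errors_b))
    stop_perfmap("perfmap_dimension_error", "error vectors must be paired")
  if (length(errors_a) < 5)
    stop_perfmap("perfmap_parameter_error", "need >= 5 pairs")
  d <- errors_a - errors_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p.value = 1, n_effective = 0,
                method = "degenerate (all differences zero)"))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact null: convolution of independent +/- contributions of 2*rank
    # (doubling makes average ranks integral)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    prob <- numeric(total + 1)          # prob[s + 1] = P(2V = s)
    prob[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), prob[seq_len(total + 1 - rr)])
      prob <- 0.5 * prob + 0.5 * shifted
    }
    v2 <- as.integer(round(2 * V))
    p_le <- sum(prob[seq_len(v2 + 1)])
    p_ge <- sum(prob[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact signed-rank (tie-aware convolution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (abs(V - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = V, p.value = p, n_effective = n, method = method)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks; the two-sided p-value uses the
#' t-distribution approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors, length >= 4, finite.
#' @return List with `rho`, `p.value`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop_perfmap("perfmap_parameter_error", "need paired vectors of length >= 4")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_perfmap("perfmap_parameter_error", "values must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop_perfmap("perfmap_undefined_correlation",
                 "zero variance in ranks; correlation undefined")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Sample size for detecting a correlation (Fisher z method)
#'
#' `n = ceil(((z_{1-alpha/2} + z_power) / C)^2 + 3)` with
#' `C = 0.5 * log((1 + r) / (1 - r))`: the standard normal-approximation
#' sample size for testing a correlation of magnitude `r` against zero.
#'
#' @param r Expected correlation magnitude, in (0, 1).
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Required number of paired values (integer).
#' @export
sample_size_correlation <- function(r, alpha = 0.05, power = 0.9) {
  if (!(r > 0 && r < 1))
    stop_perfmap("perfmap_parameter_error", "r must lie strictly in (0, 1)")
  if (!(alpha > 0 && alpha < 1 && power > 0 && power < 1))
    stop_perfmap("perfmap_parameter_error", "alpha and power must lie in (0, 1)")
  C <- 0.5 * log((1 + r) / (1 - r))
  as.integer(ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / C)^2 + 3))
}
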