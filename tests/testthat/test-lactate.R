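test_that("LCL normalization subtracts systemic lactate elementwise", {
  expect_equal(normalize_lcl(10.2, 1.87), 8.33)
  expect_equal(normalize_lcl(3.1, 3.1), 0)
  lcl <- c(5, 2, 9); sys <- c(1, 2, 3)
  expect_equal(normalize_lcl(lcl, sys), c(4, 0, 6))
  df <- data.frame(lcl_mmol_l = lcl, systemic_lactate_mmol_l = sys)
  expect_equal(normalize_lcl(df), c(4, 0, 6))
})

test_that("exponential fit recovers generating coefficients on noise-free data", {
  x <- seq(5, 90, length.out = 40)
  for (cf in list(c(a = 0.0343, b = 2.72), c(a = 0.403, b = 2.32))) {
    y <- exp(-cf["a"] * x + cf["b"])
    fit <- fit_exponential(x, y)
    expect_equal(fit$a, unname(cf["a"]), tolerance = 1e-6)
    expect_equal(fit$b, unname(cf["b"]), tolerance = 1e-6)
  }
  # constant positive response: a ~ 0, b ~ log(c)
  yc <- rep(4.2, 10)
  fitc <- fit_exponential(seq_len(10), yc)
  expect_equal(fitc$a, 0, tolerance = 1e-6)
  expect_equal(fitc$b, log(4.2), tolerance = 1e-6)

  expect_error(fit_exponential(1:2, 1:2), class = "perfmap_parameter_error")
  expect_error(fit_exponential(rep(1, 5), 1:5), class = "perfmap_parameter_error")
})

test_that("noisy parameter recovery: median relative error in a below 25%", {
  set.seed(17)
  a_true <- 0.0343
  errs <- replicate(200, {
    co <- generate_cohort(cohort_params(
      n_subjects = 60, lcl_noise_sd = 0.3,
      seed = sample.int(2^31 - 1, 1)))
    fit <- fit_exponential(co$sto2_pct, normalize_lcl(co))
    abs(fit$a - a_true) / a_true
  })
  expect_lt(stats::median(errs), 0.25)
})

test_that("prediction follows exp(-a x + b) + systemic with its limits", {
  m <- list(a = 0.0343, b = 2.72)
  expect_equal(predict_lcl(m, 0, 0), exp(2.72))
  expect_equal(predict_lcl(m, 1e6, 1.5), 1.5, tolerance = 1e-9)  # x -> Inf
  expect_gt(predict_lcl(m, 10, 1), predict_lcl(m, 20, 1))        # decreasing
  expect_error(predict_lcl(m, 5, -1), class = "perfmap_parameter_error")
})

test_that("lcl_model methods are mutually consistent", {
  co <- generate_cohort(cohort_params(n_subjects = 30, seed = 8))
  m <- fit_lcl_model(co, "sto2")
  expect_s3_class(m, "lcl_model")
  expect_named(coef(m), c("a", "b"))
  expect_equal(unname(predict(m)),
               unname(predict_lcl(m, co$sto2_pct, co$systemic_lactate_mmol_l)))
  expect_equal(residuals(m), co$lcl_mmol_l - fitted(m))
  s <- summary(m)
  expect_equal(s$errors$mean, mean(abs(residuals(m))))
  # log-linearity of the exponential term over the predictor
  xx <- c(10, 30, 50, 70)
  lp <- log(predict_lcl(m, xx, 0))
  expect_equal(diff(lp) / diff(xx), rep(-m$a, 3), tolerance = 1e-10)
  sim <- simulate(m, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(nrow(co), 2L))
  expect_true(all(sim > 0))
  expect_output(print(m), "Exponential lactate model")
})

test_that("leave-one-subject-out CV holds whole subjects out", {
  co0 <- generate_cohort(cohort_params(n_subjects = 6, lcl_noise_sd = 0, seed = 9))
  cv0 <- loo_cv(co0, "sto2")
  expect_equal(nrow(cv0), 18)                          # 6 folds x 3 ROIs
  expect_equal(length(unique(cv0$subject_id)), 6)
  expect_lt(max(cv0$abs_error), 1e-6)                  # noise-free self-consistency

  co <- generate_cohort(cohort_params(n_subjects = 8, seed = 10))
  cv <- loo_cv(co, "sto2")
  # permutation invariance: shuffling subjects leaves per-record errors intact
  perm <- co[order(rev(seq_len(nrow(co)))), ]
  cvp <- loo_cv(perm, "sto2")
  key <- function(d) d[order(d$subject_id, d$roi_label), "abs_error"]
  # summation order differs across permutations; agreement to optimizer noise
  expect_equal(key(cvp), key(cv), tolerance = 1e-6)

  expect_error(loo_cv(co[co$subject_id <= 2, ], "sto2"),
               class = "perfmap_parameter_error")
})

test_that("error summaries report mean/sd/median and the 95% LCL threshold", {
  s <- error_summary(rep(2.5, 6), rep(4, 6))
  expect_equal(s$mean, 2.5); expect_equal(s$sd, 0); expect_equal(s$median, 2.5)
  expect_equal(error_summary(c(1, 2, 3), c(1, 5, 9))$median, 2)
  expect_equal(error_summary(c(1, 2, 3), c(1, 5, 9))$q95_threshold,
               unname(stats::quantile(c(1, 5, 9), 0.95)))
  expect_error(error_summary(1:3, 1:2), class = "perfmap_dimension_error")

  # Monte-Carlo: CV mean error matches the folded log-normal expectation
  sd_eps <- 0.3
  co <- generate_cohort(cohort_params(n_subjects = 120, lcl_noise_sd = sd_eps,
                                      seed = 12))
  cv <- loo_cv(co, "sto2")
  mu <- exp(-0.0343 * co$sto2_pct + 2.72)
  efold <- stats::integrate(function(e) abs(exp(e) - 1) * stats::dnorm(e, 0, sd_eps),
                            -10 * sd_eps, 10 * sd_eps)$value  # E|e^eps - 1|
  expected <- mean(mu) * efold
  expect_lt(abs(mean(cv$abs_error) - expected) / expected, 0.10)
})

test_that("paired Wilcoxon comparison matches exhaustive enumeration", {
  e <- c(1.2, 0.4, 2.2, 0.9, 3.0, 1.1)
  expect_equal(compare_models_wilcoxon(e, e)$p.value, 1)

  # all differences shifted one way: smallest attainable p for that n
  res <- compare_models_wilcoxon(e, e + 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 2 * 0.5^6)

  # n = 10: exact p equals full 2^10 sign enumeration
  set.seed(23)
  a <- stats::rlnorm(10); b <- stats::rlnorm(10)
  res10 <- compare_models_wilcoxon(a, b)
  d <- a - b; r <- rank(abs(d)); v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 10)))
  v_all <- as.vector(signs %*% r)
  p_exact <- min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
  expect_equal(res10$p.value, p_exact, tolerance = 1e-12)
  expect_equal(res10$statistic, v_obs)

  # large n: normal approximation agrees with the reference implementation
  set.seed(31)
  a2 <- stats::rlnorm(40); b2 <- a2 * stats::rlnorm(40, 0, 0.4)
  ours <- compare_models_wilcoxon(a2, b2)
  ref <- stats::wilcox.test(a2, b2, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-6)

  expect_error(compare_models_wilcoxon(1:4, 2:5),
               class = "perfmap_parameter_error")
})

test_that("Spearman correlation uses average ranks with a t-approximation", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_correlation(x, x^3)$rho, 1)
  expect_equal(spearman_correlation(x, x^3)$p.value, 0)
  expect_equal(spearman_correlation(x, -x)$rho, -1)

  # ties: rho equals the averaged-rank formula (reference oracle)
  set.seed(2)
  xt <- c(1, 2, 2, 3, 4, 4); yt <- c(2, 1, 3, 3, 5, 4)
  expect_equal(spearman_correlation(xt, yt)$rho,
               stats::cor(xt, yt, method = "spearman"))

  expect_error(spearman_correlation(rep(1, 5), 1:5),
               class = "perfmap_undefined_correlation")
  expect_error(spearman_correlation(1:3, 1:3), class = "perfmap_parameter_error")
})

test_that("correlation sample size follows the Fisher z formula", {
  expect_identical(sample_size_correlation(0.78, 0.05, 0.9), 13L)
  expect_identical(sample_size_correlation(0.9999), 4L)   # formula floor
  expect_gte(sample_size_correlation(0.7, power = 0.9),
             sample_size_correlation(0.7, power = 0.8))
  expect_gte(sample_size_correlation(0.5), sample_size_correlation(0.7))
  expect_error(sample_size_correlation(1), class = "perfmap_parameter_error")
})
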