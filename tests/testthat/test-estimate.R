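test_that("log-likelihood matches term-by-term hand computation", {
  f1 <- llogis2(0.4, 2); f2 <- weibull2(1.2, 0.1)
  # hand formulas written out independently of the package evaluators
  hS1 <- function(t) 1 / (1 + 0.4 * t^2)
  hf1 <- function(t) 0.4 * 2 * t / (1 + 0.4 * t^2)^2
  hS2 <- function(t) exp(-(0.1 * t)^1.2)
  hf2 <- function(t) 1.2 * 0.1 * (0.1 * t)^0.2 * exp(-(0.1 * t)^1.2)
  # single censored observation: log S1 + log S2
  expect_equal(cr_loglik(f1, f2, cr_sample(3, 0)),
               log(hS1(3)) + log(hS2(3)), tolerance = 1e-12)
  # single cause-1 event: log f1 + log S2
  expect_equal(cr_loglik(f1, f2, cr_sample(3, 1)),
               log(hf1(3)) + log(hS2(3)), tolerance = 1e-12)
  # five-observation toy sample
  tt <- c(0.5, 1, 1.5, 2, 4); ev <- c(1, 2, 0, 1, 2)
  expected <- sum(ifelse(ev == 1, log(hf1(tt)), log(hS1(tt))) +
                  ifelse(ev == 2, log(hf2(tt)), log(hS2(tt))))
  expect_equal(cr_loglik(f1, f2, cr_sample(tt, ev)), expected,
               tolerance = 1e-12)
})

test_that("the two-cause likelihood factorises into independent cause blocks", {
  set.seed(41)
  s <- simulate_sample(design_loglogistic(n = 400, seed = 41))
  fit <- fit_mle(s, family = c("ll2", "weibull"), n_starts = 8)
  # block log-likelihoods reassemble the joint one at the estimates
  f1 <- llogis2(fit$psi1[["lambda"]], fit$psi1[["tau"]])
  f2 <- weibull2(fit$psi2[["shape"]], fit$psi2[["rate"]])
  expect_equal(cr_loglik(f1, f2, s), fit$loglik, tolerance = 1e-8)
  # perturbing cause 2 must not move the cause-1 block's optimum
  fit_b <- fit_mle(s, family = c("ll2", "gompertz"), n_starts = 8)
  expect_equal(fit$psi1, fit_b$psi1, tolerance = 1e-6)
  # information criteria identities
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$npar)
  expect_equal(fit$bic, -2 * fit$loglik + log(nrow(s)) * fit$npar)
})

test_that("maximum likelihood recovers known two-parameter log-logistic parameters", {
  set.seed(42)
  tt <- r_ll2(5000, 0.3, 2.97)
  s <- cr_sample(tt, rep(1L, 5000))
  fit <- fit_mle(s, family = "ll2")
  expect_true(fit$converged)
  expect_true(fit$skipped[["cause2"]])
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$psi1[["lambda"]] - 0.3), 3 * se[["cause1.lambda"]])
  expect_lt(abs(fit$psi1[["tau"]] - 2.97), 3 * se[["cause1.tau"]])
})

test_that("the optimum beats a brute-force grid search", {
  set.seed(43)
  tt <- r_ll4(200, 0.4, 2, 0.8, 1.5)
  s <- cr_sample(tt, rep(1L, 200))
  fit <- fit_mle(s, family = "ll4", n_starts = 12)
  negll <- llogis4:::make_cause_negll("ll4", s$time, s$event == 1L)
  grid <- llogis4:::family_start_grid("ll4")
  grid_best <- min(apply(grid, 1, function(p)
    negll(llogis4:::to_transformed("ll4", p))))
  block1 <- fit$loglik   # single-cause sample: the whole loglik is block 1
  expect_gte(block1, -grid_best)
})

test_that("refitting from the returned optimum is a fixed point", {
  set.seed(44)
  s <- simulate_sample(design_loglogistic(n = 300, seed = 44))
  fit <- fit_mle(s, family = "ll2", n_starts = 6)
  refit <- fit_mle(s, family = "ll2", n_starts = 0,
                   extra_starts = list(cause1 = fit$psi1, cause2 = fit$psi2))
  expect_equal(refit$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(refit$psi1, fit$psi1, tolerance = 1e-4)
})

test_that("covariance is symmetric PSD and consistent with the score outer product", {
  set.seed(45)
  tt <- r_ll2(3000, 0.5, 1.8)
  s <- cr_sample(tt, rep(1L, 3000))
  fit <- fit_mle(s, family = "ll2")
  v <- fit$vcov[1:2, 1:2]
  expect_equal(v, t(v), tolerance = 1e-8)
  expect_true(all(eigen(v, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # outer product of per-observation scores at the MLE (natural scale)
  opg <- matrix(0, 2, 2)
  for (i in seq_len(nrow(s))) {
    g <- llogis4:::cause_score("ll2", fit$psi1, s$time[i], s$time[i])
    opg <- opg + tcrossprod(g)
  }
  v_opg <- solve(opg)
  ratio <- diag(v) / diag(v_opg)
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("CIF from a fit equals the parametric integral at the estimates", {
  set.seed(46)
  s <- simulate_sample(design_loglogistic(n = 300, seed = 46))
  fit <- fit_mle(s, family = "ll2", n_starts = 6)
  cv <- cif_from_fit(fit, 1)
  direct <- parametric_cif(llogis2(fit$psi1[["lambda"]], fit$psi1[["tau"]]),
                           llogis2(fit$psi2[["lambda"]], fit$psi2[["tau"]]), 1)
  expect_identical(cv$values, direct$values)
  expect_true(all(diff(cv$values) >= 0) && all(cv$values <= 1))
})

test_that("a cause with no events is skipped and yields a zero incidence curve", {
  s <- cr_sample(c(0.5, 1, 2, 3, 4.5), c(1, 1, 0, 1, 1))
  fit <- fit_mle(s, family = "ll2")
  expect_true(fit$skipped[["cause2"]])
  expect_warning(cv <- cif_from_fit(fit, 2), "no events")
  expect_true(all(cv$values == 0))
  # cause 1 is unaffected: overall survival reduces to S1
  cv1 <- cif_from_fit(fit, 1, times = c(1, 5, 50))
  expect_gt(max(cv1$values), 0.5)
})

test_that("model comparison reports information criteria and LR tests", {
  set.seed(47)
  # pronounced departure from the two-parameter special case
  tt <- r_ll4(1500, 0.4, 0.9, 0.35, 2.5)
  s <- cr_sample(tt, rep(1L, 1500))
  fits <- list(ll2 = fit_mle(s, "ll2"), ll4 = fit_mle(s, "ll4", n_starts = 12))
  cmp <- compare_models(fits, nesting = list(c("ll2", "ll4")))
  expect_identical(cmp$lrt$df, 2L)            # one fitted cause block
  expect_gt(cmp$lrt$chisq, qchisq(0.999, 2))
  expect_lt(cmp$lrt$p, 0.001)
  # self-comparison: chi-square 0, p = 1
  self <- compare_models(list(a = fits$ll2, b = fits$ll2),
                         nesting = list(c("a", "b")))
  expect_identical(self$lrt$chisq, 0)
  expect_identical(self$lrt$p, 1)
  # AIC and BIC order identically for equal parameter counts
  fits_eq <- c(fits["ll2"], list(wei = fit_mle(s, "weibull")))
  cmp_eq <- compare_models(fits_eq)
  expect_identical(cmp_eq$models$n_params[1], cmp_eq$models$n_params[2])
  expect_identical(order(cmp_eq$models$aic), order(cmp_eq$models$bic))
  # mismatched samples are refused
  s2 <- cr_sample(tt + 0.1, rep(1L, 1500))
  expect_error(compare_models(list(a = fits$ll2, b = fit_mle(s2, "ll2"))),
               "same sample")
})

test_that("four-parameter fits recover the generating parameters over replicates", {
  # recovery study: median absolute deviation of each natural-scale
  # parameter stays within 2 median standard errors
  set.seed(48)
  truth <- c(lambda = 0.4, tau = 2, theta = 0.8, alpha = 1.5)
  n_rep <- 50L
  est <- matrix(NA_real_, n_rep, 4)
  ses <- matrix(NA_real_, n_rep, 4)
  warm <- NULL
  for (j in seq_len(n_rep)) {
    tt <- r_ll4(2000, truth[1], truth[2], truth[3], truth[4])
    s <- cr_sample(tt, rep(1L, 2000))
    fit <- fit_mle(s, "ll4", n_starts = if (is.null(warm)) 12 else 2,
                   extra_starts = warm)
    est[j, ] <- fit$psi1
    ses[j, ] <- sqrt(diag(fit$vcov))[1:4]
    warm <- list(cause1 = fit$psi1)
  }
  bias <- abs(apply(est, 2, median) - truth)
  expect_true(all(bias < 2 * apply(ses, 2, median)))
})
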