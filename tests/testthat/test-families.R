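test_that("four-parameter family collapses to the two-parameter log-logistic at alpha = 1, theta = 1", {
  set.seed(11)
  grid <- seq(0, 20, length.out = 100)
  for (i in 1:5) {
    lam <- runif(1, 0.05, 3); tau <- runif(1, 0.3, 4)
    f4 <- llogis4(lam, tau, theta = 1, alpha = 1)
    f2 <- llogis2(lam, tau)
    expect_lt(max(abs(surv(f4, grid) - surv(f2, grid))), 1e-12)
    expect_lt(max(abs(haz(f4, grid[-1]) - haz(f2, grid[-1]))), 1e-10)
  }
})

test_that("survival functions are valid: S(0) = 1, non-increasing, in (0, 1]", {
  set.seed(12)
  grid <- c(0, sort(runif(60, 0, 30)))
  fams <- list()
  for (i in 1:8) {
    fams <- c(fams,
      list(llogis4(runif(1, .05, 2), runif(1, .3, 4), runif(1, .1, 3),
                   runif(1, -2, 3)),
           llogis2(runif(1, .05, 2), runif(1, .3, 4)),
           weibull2(runif(1, .3, 3), runif(1, .05, 2)),
           gompertz2(runif(1, .05, 2), runif(1, -1, 1))))
  }
  for (f in fams) {
    s <- surv(f, grid)
    expect_identical(s[1], 1)
    expect_true(all(diff(s) <= 1e-15))
    expect_true(all(s >= 0 & s <= 1))
    # strict positivity wherever the cumulative hazard is representable
    expect_true(all(s[cumhaz(f, grid) < 700] > 0))
  }
})

test_that("alpha < 0 gives an improper distribution with tail mass exp(theta^2/alpha)", {
  set.seed(13)
  for (i in 1:20) {
    th <- runif(1, 0.2, 2); al <- runif(1, -3, -0.1)
    f <- llogis4(runif(1, .05, 2), runif(1, .5, 3), th, al)
    # the limit itself; convergence in t is logarithmically slow, so the
    # limit is checked at t = Inf and the approach is checked as an
    # inequality along a long grid
    expect_lt(abs(surv(f, Inf) - exp(th^2 / al)), 1e-12)
    expect_equal(tail_mass(f), exp(th^2 / al))
    s <- surv(f, c(1e2, 1e4, 1e8))
    expect_true(all(diff(s) <= 0) && all(s >= exp(th^2 / al)))
  }
  f <- llogis4(0.5, 2, 1, -1)
  expect_equal(surv(f, Inf), exp(-1), tolerance = 1e-12)
  expect_identical(tail_mass(llogis2(0.3, 2.97)), 0)
})

test_that("alpha = 0 is handled as the analytic limit, continuously", {
  lam <- 0.4; tau <- 2; th <- 0.8
  grid <- c(0.1, 0.5, 1, 2, 5, 10)
  limit <- (1 + log1p(lam * grid^tau) / th)^(-th^2)
  expect_lt(max(abs(surv(llogis4(lam, tau, th, 1e-9), grid) - limit)), 1e-12)
  for (a in c(-1e-6, 1e-6))
    expect_lt(max(abs(surv(llogis4(lam, tau, th, a), grid) - limit)), 1e-6)
})

test_that("hazard equals -d log S/dt by central differences for every family", {
  fams <- list(llogis4(0.3, 2.97, 0.7, -0.5), llogis4(1, 0.8, 2, 2),
               llogis2(0.3, 2.97), weibull2(1.4, 0.45), gompertz2(0.5, 0.3),
               gompertz2(0.5, -0.4))
  for (f in fams) {
    for (t in c(0.5, 1, 2)) {
      h <- 1e-6 * t
      fd <- -(log(surv(f, t + h)) - log(surv(f, t - h))) / (2 * h)
      expect_lt(abs(haz(f, t) - fd) / abs(fd), 1e-5)
    }
  }
})

test_that("four-parameter hazard has the stated closed form at alpha = 1", {
  lam <- 0.7; tau <- 1.6; th <- 1.3
  t <- c(0.2, 1, 3)
  f <- llogis4(lam, tau, th, alpha = 1)
  expect_equal(haz(f, t), th * tau * lam * t^(tau - 1) / (1 + lam * t^tau),
               tolerance = 1e-12)
})

test_that("two-parameter log-logistic hazard shape follows tau", {
  grid <- seq(0.01, 20, length.out = 2000)
  # tau <= 1: monotone decreasing
  for (tau in c(0.5, 1)) {
    h <- haz(llogis2(0.3, tau), grid)
    expect_true(all(diff(h) <= 1e-12))
  }
  # tau > 1: unimodal (rises then falls)
  h <- haz(llogis2(0.3, 2.97), grid)
  peak <- which.max(h)
  expect_gt(peak, 1); expect_lt(peak, length(grid))
  expect_true(all(diff(h[1:peak]) >= -1e-12))
  expect_true(all(diff(h[peak:length(h)]) <= 1e-12))
})

test_that("density f = h S integrates to one minus the tail mass", {
  quadr <- function(f, upper = Inf)
    integrate(function(u) dens(f, u), 0, upper, rel.tol = 1e-9,
              subdivisions = 500L)$value
  expect_equal(quadr(llogis2(0.3, 2.97)), 1, tolerance = 1e-4)
  expect_equal(quadr(weibull2(1.4, 0.45)), 1, tolerance = 1e-4)
  # improper tail: mass accumulated by T equals 1 - S(T) (quadrature
  # consistency), and the total mass is 1 - exp(theta^2/alpha) in the limit
  f <- llogis4(0.5, 2, 1, -1)
  for (upper in c(5, 50, 1e3))
    expect_equal(quadr(f, upper), 1 - surv(f, upper), tolerance = 1e-6)
  expect_equal(1 - surv(f, Inf), 1 - exp(-1), tolerance = 1e-12)
  set.seed(14)
  for (i in 1:10) {
    f <- llogis4(runif(1, .1, 2), runif(1, .5, 3), runif(1, .2, 2),
                 runif(1, -2, 2))
    expect_true(all(dens(f, sort(runif(50, 0.01, 20))) >= 0))
  }
})

test_that("cumulative hazard is consistent with survival and known values", {
  f <- llogis2(0.3, 2.97)
  expect_identical(cumhaz(f, 0), 0)
  expect_equal(cumhaz(f, 2), log(1 + 0.3 * 2^2.97), tolerance = 1e-12)
  expect_equal(cumhaz(f, 2), 1.209142, tolerance = 1e-6)
  w <- weibull2(1.4, 0.45)
  expect_equal(cumhaz(w, 5), 2.25^1.4, tolerance = 1e-12)
  for (f in list(llogis4(0.3, 2.97, 0.7, -0.5), w, gompertz2(0.4, -0.2))) {
    t <- c(0, 0.5, 1, 4, 9)
    expect_lt(max(abs(exp(-cumhaz(f, t)) - surv(f, t)) / surv(f, t)), 1e-10)
    expect_true(all(diff(cumhaz(f, t)) >= 0))
  }
})

test_that("invalid parameters and domains are rejected with informative errors", {
  expect_error(llogis4(-1, 2, 1, 1), "lambda")
  expect_error(llogis4(1, 0, 1, 1), "tau")
  expect_error(llogis4(1, 2, -3, 1), "theta")
  expect_error(llogis4(1, 2, 1, Inf), "alpha")
  expect_error(weibull2(1, -2), "rate")
  expect_error(gompertz2(0, 1), "level")
  f <- llogis2(1, 0.5)
  expect_error(haz(f, 0), "positive")
  expect_error(dens(f, -1), "positive")
  expect_error(surv(f, -0.1), "non-negative")
})

test_that("families are addressable by string code", {
  f <- cr_family("ll2", c(lambda = 0.3, tau = 2.97))
  expect_identical(f, llogis2(0.3, 2.97))
  f4 <- cr_family("ll4", list(0.3, 2.97, 1, -0.5))
  expect_identical(f4$params[["alpha"]], -0.5)
  expect_identical(cr_family("weibull", c(shape = 1.4, rate = 0.45)),
                   weibull2(1.4, 0.45))
  expect_error(cr_family("sparling", c(1, 2)))
})
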