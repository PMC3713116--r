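#' Competing-risks simulation designs
#'
#' A design bundles the two cause-specific families, the sample size, the
#' marginal censoring probability and an optional seed.  Samples are drawn by
#' the cause-specific-hazard mechanism: an all-cause event time `T` solving
#' \eqn{S_1(T) S_2(T) = U} with \eqn{U \sim \mathrm{Unif}(0,1)} (inverse
#' transform of the all-cause distribution, whose hazard is
#' \eqn{h_1 + h_2}), followed by a binomial cause allocation with success
#' probability \eqn{h_1(T) / (h_1(T) + h_2(T))}, followed by independent
#' Bernoulli censoring.
#'
#' `design_loglogistic()` and `design_weibull()` are the two study designs
#' used throughout: two-parameter log-logistic causes with
#' \eqn{\lambda_1 = 0.3, \tau_1 = 2.97} and \eqn{\lambda_2 = 0.03,
#' \tau_2 = 1.1}, and Weibull causes with \eqn{k_1 = 1.4, p_1 = 0.45} and
#' \eqn{k_2 = 1.04, p_2 = 0.03}, both at `n = 1000` subjects and a 7\%
#' censoring level.
#'
#' @param cause1,cause2 `crfamily` objects.
#' @param n number of subjects.
#' @param censor_prob marginal censoring probability in `[0, 1)`.
#' @param seed optional integer seed; when set, [simulate_sample()] is
#'   bitwise reproducible.
#' @param horizon administrative censoring time for subjects whose event
#'   time is infinite (improper designs only).  Must be finite if either
#'   cause family is improper.
#' @return An object of class `cr_design`.
#' @examples
#' d <- design_loglogistic(n = 50, seed = 1)
#' simulate_sample(d)
#' @export
cr_design <- function(cause1, cause2, n = 1000L, censor_prob = 0.07,
                      seed = NULL, horizon = Inf) {
  stopifnot(inherits(cause1, "crfamily"), inherits(cause2, "crfamily"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer", call. = FALSE)
  if (!is.numeric(censor_prob) || censor_prob < 0 || censor_prob >= 1)
    stop("'censor_prob' must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(cause1 = cause1, cause2 = cause2, n = n,
                 censor_prob = censor_prob, seed = seed, horizon = horizon),
            class = "cr_design")
}

#' @rdname cr_design
#' @export
design_loglogistic <- function(n = 1000L, censor_prob = 0.07, seed = NULL) {
  d <- cr_design(llogis2(0.3, 2.97), llogis2(0.03, 1.1),
                 n = n, censor_prob = censor_prob, seed = seed)
  attr(d, "label") <- "log-logistic design"
  d
}

#' @rdname cr_design
#' @export
design_weibull <- function(n = 1000L, censor_prob = 0.07, seed = NULL) {
  d <- cr_design(weibull2(1.4, 0.45), weibull2(1.04, 0.03),
                 n = n, censor_prob = censor_prob, seed = seed)
  attr(d, "label") <- "Weibull design"
  d
}

#' Invert the all-cause survival function
#'
#' Solves \eqn{S_1(T) S_2(T) = u} for each uniform deviate `u` by monotone
#' bracketing and bisection (absolute tolerance `1e-10` in `t`).  For an
#' improper design a deviate below the joint tail mass has no finite
#' solution and `Inf` is returned; [simulate_sample()] records such subjects
#' as censored at the design horizon.
#'
#' @param design a `cr_design`.
#' @param u uniform deviates in `(0, 1)`.
#' @return Event times, possibly infinite.
#' @export
draw_all_cause_time <- function(design, u) {
  stopifnot(inherits(design, "cr_design"))
  if (any(u <= 0) || any(u >= 1))
    stop("'u' must lie strictly inside (0, 1)", call. = FALSE)
  s_all <- function(t) exp(log_surv(design$cause1, t) + log_surv(design$cause2, t))
  tail <- tail_mass(design$cause1) * tail_mass(design$cause2)
  out <- rep(Inf, length(u))
  solvable <- u > tail
  if (!any(solvable)) return(out)
  uu <- u[solvable]
  hi <- rep(1, length(uu)); lo <- rep(0, length(uu))
  repeat {
    open <- s_all(hi) > uu & is.finite(hi)
    if (!any(open)) break
    lo[open] <- hi[open]
    hi[open] <- hi[open] * 2
    # deviates marginally above an improper tail mass have finite but
    # astronomically large solutions; beyond 1e15 they are indistinguishable
    # from the immune fraction
    hi[hi > 1e15] <- Inf
  }
  fin <- is.finite(hi)
  lo <- lo[fin]; hi2 <- hi[fin]; uf <- uu[fin]
  for (i in 1:200) {
    if (!length(lo) || max(hi2 - lo) < 1e-10) break
    mid <- (lo + hi2) / 2
    up <- s_all(mid) > uf      # S decreasing: root above mid
    lo[up] <- mid[up]
    hi2[!up] <- mid[!up]
  }
  sol <- rep(Inf, length(uu))
  sol[fin] <- (lo + hi2) / 2
  out[solvable] <- sol
  out
}

#' Binomial cause allocation
#'
#' Assigns the event type at time `t`: cause 1 iff
#' `v < h1(t) / (h1(t) + h2(t))`.
#'
#' @param design a `cr_design`.
#' @param t positive event times.
#' @param v uniform deviates.
#' @return Integer codes 1 or 2.
#' @export
assign_cause <- function(design, t, v) {
  stopifnot(inherits(design, "cr_design"))
  check_times(t, zero_ok = FALSE)
  h1 <- exp(log_haz(design$cause1, t))
  h2 <- exp(log_haz(design$cause2, t))
  if (any(h1 + h2 == 0))
    stop("cause allocation undefined: both hazards vanish at some 't'",
         call. = FALSE)
  ifelse(v < h1 / (h1 + h2), 1L, 2L)
}

#' Independent Bernoulli censoring
#'
#' Each subject is independently flagged censored with probability
#' `censor_prob`; a censored subject's recorded time is drawn uniformly on
#' `(0, T)`.  The expected censored fraction equals `censor_prob`.  Uses the
#' current RNG state.
#'
#' @param time positive event times.
#' @param event integer cause codes (1/2).
#' @param censor_prob probability in `[0, 1)`.
#' @return A `cr_sample`.
#' @export
apply_censoring <- function(time, event, censor_prob) {
  if (censor_prob < 0 || censor_prob >= 1)
    stop("'censor_prob' must lie in [0, 1)", call. = FALSE)
  n <- length(time)
  flag <- stats::runif(n) < censor_prob
  frac <- stats::runif(n)
  time[flag] <- frac[flag] * time[flag]
  event[flag] <- 0L
  cr_sample(time, event)
}

#' Simulate a competing-risks sample from a design
#'
#' Composes [draw_all_cause_time()], [assign_cause()] and
#' [apply_censoring()].  With `design$seed` set the result is bitwise
#' reproducible.
#'
#' @param design a `cr_design`.
#' @return A `cr_sample` with `design$n` rows; the design is attached as
#'   attribute `"design"`.
#' @export
simulate_sample <- function(design) {
  stopifnot(inherits(design, "cr_design"))
  if (!is.null(design$seed)) set.seed(design$seed)
  n <- design$n
  u <- stats::runif(n)
  tt <- draw_all_cause_time(design, u)
  v <- stats::runif(n)
  ev <- rep(NA_integer_, n)
  fin <- is.finite(tt)
  if (!all(fin) && !is.finite(design$horizon))
    stop("improper design generated infinite event times; ",
         "set a finite 'horizon' in cr_design()", call. = FALSE)
  ev[fin] <- assign_cause(design, tt[fin], v[fin])
  ev[!fin] <- 0L
  tt[!fin] <- design$horizon
  out <- apply_censoring_keep_inf(tt, ev, fin, design$censor_prob)
  attr(out, "design") <- design
  out
}

# censoring applied to all subjects; administratively censored (infinite-time)
# subjects keep the horizon time and stay censored
apply_censoring_keep_inf <- function(time, event, fin, censor_prob) {
  n <- length(time)
  flag <- stats::runif(n) < censor_prob
  frac <- stats::runif(n)
  flag <- flag & fin
  time[flag] <- frac[flag] * time[flag]
  event[flag] <- 0L
  cr_sample(time, event)
}

#' @export
print.cr_design <- function(x, ...) {
  lab <- attr(x, "label")
  cat("<cr_design>", if (!is.null(lab)) lab else "", "\n")
  cat("  n =", x$n, " censor_prob =", x$censor_prob,
      if (!is.null(x$seed)) paste(" seed =", x$seed) else "", "\n")
  cat("  cause 1: ", x$cause1$name, " (",
      paste(names(x$cause1$params), signif(x$cause1$params, 4),
            sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  cause 2: ", x$cause2$name, " (",
      paste(names(x$cause2$params), signif(x$cause2$params, 4),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}
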