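#' The grid of report times used throughout the simulation studies
#'
#' @return `c(0.75, 1, 1.25, 1.5, 2, 3, 5)`.
#' @export
report_times <- function() c(0.75, 1, 1.25, 1.5, 2, 3, 5)

new_cif_curve <- function(times, values, cause, method, step) {
  tol <- 1e-9
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (any(values < -tol) || any(values > 1 + tol))
    stop("cumulative incidence values must lie in [0, 1]", call. = FALSE)
  if (any(diff(values) < -tol))
    stop("cumulative incidence must be non-decreasing", call. = FALSE)
  structure(list(times = times, values = pmin(pmax(values, 0), 1),
                 cause = cause, method = method, step = step),
            class = "cif_curve")
}

#' Parametric cumulative incidence by numerical integration
#'
#' Computes the cumulative incidence function of one cause in a two-cause
#' system, \eqn{F_k(t) = \int_0^t S(u)\, h_k(u)\, du}, where the overall
#' survival factorises into the product of the cause-specific survival
#' functions, \eqn{S(u) = S_1(u) S_2(u)}.  The integral is accumulated by
#' adaptive quadrature over consecutive grid cells, so monotonicity of the
#' returned curve holds by construction.
#'
#' @param cause1,cause2 `crfamily` objects for the cause-specific models.
#' @param cause which cumulative incidence to compute, 1 or 2.
#' @param times strictly increasing grid of non-negative times.
#' @param abs_tol absolute quadrature tolerance per cell.
#' @return A `cif_curve`.
#' @examples
#' # Two-parameter log-logistic causes; event-of-interest incidence
#' f <- parametric_cif(llogis2(0.3, 2.97), llogis2(0.03, 1.1),
#'                     cause = 1, times = report_times())
#' cif_at(f, 2)
#' @export
parametric_cif <- function(cause1, cause2, cause = 1L,
                           times = report_times(), abs_tol = 1e-8) {
  stopifnot(inherits(cause1, "crfamily"), inherits(cause2, "crfamily"))
  cause <- check_cause(cause)
  if (any(times < 0)) stop("time grid must be non-negative", call. = FALSE)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  hk <- if (cause == 1L) cause1 else cause2
  integrand <- function(u) exp(log_surv(cause1, u) + log_surv(cause2, u) +
                                 log_haz(hk, u))
  knots <- unique(c(0, times))
  inc <- numeric(length(knots) - 1L)
  for (i in seq_along(inc)) {
    q <- tryCatch(
      stats::integrate(integrand, knots[i], knots[i + 1L],
                       abs.tol = abs_tol, rel.tol = 1e-10,
                       stop.on.error = TRUE),
      error = function(e) stop("quadrature failed on (", knots[i], ", ",
                               knots[i + 1L], "]: ", conditionMessage(e),
                               call. = FALSE))
    inc[i] <- q$value
  }
  values <- if (times[1L] == 0) c(0, cumsum(inc)) else cumsum(inc)
  new_cif_curve(times, values, cause, "parametric", step = FALSE)
}

#' Kaplan-Meier estimate of all-cause survival
#'
#' Product-limit estimator over the all-cause (any `event > 0`) event times.
#' Ties between an event and a censoring at the same time are resolved with
#' events first: a subject censored at `t` remains in the risk set for events
#' at `t`.
#'
#' @param sample a `cr_sample`.
#' @return An object of class `km_curve` with the distinct observed times,
#'   risk-set sizes, event/censoring counts and the right-continuous survival
#'   estimate.
#' @export
kaplan_meier <- function(sample) {
  stopifnot(inherits(sample, "cr_sample"))
  tab <- risk_table(sample)
  s <- cumprod(1 - tab$d / tab$n_risk)
  structure(list(time = tab$time, n_risk = tab$n_risk, n_event = tab$d,
                 n_censor = tab$cns, surv = s),
            class = "km_curve")
}

# distinct-time risk table shared by the KM and Aalen-Johansen estimators
risk_table <- function(sample) {
  ut <- sort(unique(sample$time))
  f <- match(sample$time, ut)
  d1 <- tabulate(f[sample$event == 1L], nbins = length(ut))
  d2 <- tabulate(f[sample$event == 2L], nbins = length(ut))
  cns <- tabulate(f[sample$event == 0L], nbins = length(ut))
  n_at <- tabulate(f, nbins = length(ut))
  n_risk <- nrow(sample) - c(0, cumsum(n_at))[seq_along(ut)]
  list(time = ut, d1 = d1, d2 = d2, d = d1 + d2, cns = cns, n_risk = n_risk)
}

#' Nonparametric (Aalen-Johansen) cumulative incidence
#'
#' Estimates \eqn{F_k} by replacing the overall survival in
#' \eqn{F_k(t)=\int_0^t S\,h_k} with the Kaplan-Meier estimate and the
#' cause-specific cumulative hazard with its Nelson-Aalen increments:
#' \deqn{\hat F_k(t) = \sum_{t_i \le t} \hat S(t_i^-)\, d_{k,i}/n_i,}
#' summing over distinct event times \eqn{t_i}, with \eqn{d_{k,i}} the
#' cause-`k` event count and \eqn{n_i} the risk-set size.  The left limit
#' \eqn{\hat S(t_i^-)} is the Kaplan-Meier value strictly before \eqn{t_i};
#' causes tied at the same time share it and the risk set.  With a single
#' cause and no censoring the estimate reduces exactly to the empirical
#' distribution function.
#'
#' @inheritParams kaplan_meier
#' @param cause which cause to estimate, 1 or 2.
#' @return A step-function `cif_curve` over the distinct observed times.
#' @export
nonparametric_cif <- function(sample, cause = 1L) {
  stopifnot(inherits(sample, "cr_sample"))
  cause <- check_cause(cause)
  if (sum(sample$event == cause) == 0L)
    stop("cannot estimate cause ", cause,
         ": the sample contains no events of that cause", call. = FALSE)
  tab <- risk_table(sample)
  s <- cumprod(1 - tab$d / tab$n_risk)
  s_minus <- c(1, s[-length(s)])
  dk <- if (cause == 1L) tab$d1 else tab$d2
  values <- cumsum(s_minus * dk / tab$n_risk)
  new_cif_curve(tab$time, values, cause, "nonparametric", step = TRUE)
}

check_cause <- function(cause) {
  cause <- as.integer(cause)
  if (length(cause) != 1L || is.na(cause) || !cause %in% 1:2)
    stop("'cause' must be 1 or 2", call. = FALSE)
  cause
}

#' Evaluate a cumulative incidence curve at arbitrary times
#'
#' Step curves (nonparametric estimates) are evaluated right-continuously:
#' the value of the last jump at or before `t`, and 0 before the first
#' observed time.  Smooth parametric curves are interpolated linearly on
#' their grid.
#'
#' @param curve a `cif_curve` (or, for `step_at()`, a `km_curve`).
#' @param t evaluation times, non-negative.
#' @return Numeric vector the length of `t`.
#' @export
cif_at <- function(curve, t) {
  stopifnot(inherits(curve, "cif_curve"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (curve$step) return(step_at(curve, t))
  stats::approx(c(0, curve$times), c(0, curve$values), xout = t,
                rule = 2)$y
}

#' @rdname cif_at
#' @export
step_at <- function(curve, t) {
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  if (inherits(curve, "km_curve")) {
    init <- 1; times <- curve$time; values <- curve$surv
  } else {
    init <- 0; times <- curve$times; values <- curve$values
  }
  idx <- findInterval(t, times)
  c(init, values)[idx + 1L]
}

#' @export
print.cif_curve <- function(x, ...) {
  cat("<cif_curve> cause", x$cause, "-", x$method,
      if (x$step) "(step function)" else "(smooth)", "\n")
  n <- length(x$times)
  show <- if (n > 8L) unique(round(seq(1, n, length.out = 8L))) else seq_len(n)
  print(data.frame(time = x$times[show], cif = round(x$values[show], 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
plot.cif_curve <- function(x, ..., add = FALSE, col = 1, lty = 1) {
  if (x$step) {
    fn <- stats::stepfun(x$times, c(0, x$values))
    if (add) graphics::lines(fn, col = col, lty = lty, do.points = FALSE, ...)
    else plot(fn, do.points = FALSE, col = col, lty = lty,
              xlab = "time", ylab = "cumulative incidence",
              main = paste("Cause", x$cause), ...)
  } else {
    if (add) graphics::lines(x$times, x$values, col = col, lty = lty, ...)
    else plot(x$times, x$values, type = "l", col = col, lty = lty,
              xlab = "time", ylab = "cumulative incidence",
              main = paste("Cause", x$cause), ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Serialise cumulative incidence curves
#'
#' Curves write to delimited text with columns `time, cif, cause, method`.
#'
#' @param curve a `cif_curve`.
#' @param path file path.
#' @export
write_cif <- function(curve, path) {
  stopifnot(inherits(curve, "cif_curve"))
  utils::write.csv(data.frame(time = curve$times, cif = curve$values,
                              cause = curve$cause, method = curve$method),
                   path, row.names = FALSE, quote = FALSE)
  invisible(curve)
}
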