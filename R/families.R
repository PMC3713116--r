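#' Parametric cause-specific distribution families
#'
#' Constructors for the parametric families used as cause-specific models.
#' Each returns a `crfamily` object holding a validated, named parameter
#' vector; the evaluators [surv()], [haz()], [dens()] and [cumhaz()] dispatch
#' on it.
#'
#' The centrepiece is the four-parameter log-logistic family obtained by
#' running the two-parameter log-logistic cumulative hazard
#' \eqn{H(t) = \log(1 + \lambda t^\tau)} through the Hougaard stable
#' transformation and collapsing the frailty parameter via
#' \eqn{\upsilon = \theta^{2-\alpha}}:
#' \deqn{S(t) = \exp\{-\frac{\theta^2}{\alpha}[(H(t)/\theta + 1)^\alpha - 1]\}}
#' with \eqn{\lambda, \tau, \theta > 0} and \eqn{\alpha} unrestricted.  For
#' \eqn{\alpha < 0} the distribution is improper: a fraction
#' \eqn{\exp(\theta^2/\alpha)} of subjects never experiences the event, which
#' is precisely the behaviour wanted of a cause-specific model whose
#' cumulative incidence plateaus below one.  At \eqn{\alpha = 1, \theta = 1}
#' the family collapses back to the two-parameter log-logistic
#' \eqn{S(t) = 1/(1 + \lambda t^\tau)}.  \eqn{\alpha = 0} is a removable
#' singularity with limit \eqn{S(t) = (1 + H(t)/\theta)^{-\theta^2}}; the
#' evaluators switch to the limit form when \eqn{|\alpha| < 10^{-8}}.
#'
#' Conventions for the remaining families: Weibull
#' \eqn{S(t) = \exp\{-(p t)^k\}} with shape `k` and rate `p`; Gompertz hazard
#' \eqn{h(t) = a e^{b t}} with level \eqn{a > 0} and unrestricted shape `b`
#' (improper when \eqn{b < 0}).
#'
#' @param lambda,tau scale and shape of the log-logistic kernel; positive.
#' @param theta,alpha Hougaard-transformation parameters; `theta` positive,
#'   `alpha` any real.
#' @param shape,rate Weibull shape \eqn{k > 0} and rate \eqn{p > 0}.
#' @param level Gompertz baseline hazard \eqn{a > 0}.
#' @param bshape Gompertz exponential slope \eqn{b}, any real.
#'
#' @return An object of class `crfamily`.
#' @examples
#' f <- llogis4(lambda = 0.3, tau = 2.97, theta = 1, alpha = -0.5)
#' surv(f, c(0, 1, 5))
#' tail_mass(f)          # exp(theta^2 / alpha)
#' @seealso [cr_family()] to construct a family from its string code.
#' @export
llogis4 <- function(lambda, tau, theta, alpha) {
  check_pos(lambda, "lambda"); check_pos(tau, "tau"); check_pos(theta, "theta")
  check_real(alpha, "alpha")
  new_crfamily("ll4", c(lambda = lambda, tau = tau, theta = theta, alpha = alpha))
}

#' @rdname llogis4
#' @export
llogis2 <- function(lambda, tau) {
  check_pos(lambda, "lambda"); check_pos(tau, "tau")
  new_crfamily("ll2", c(lambda = lambda, tau = tau))
}

#' @rdname llogis4
#' @export
weibull2 <- function(shape, rate) {
  check_pos(shape, "shape"); check_pos(rate, "rate")
  new_crfamily("weibull", c(shape = shape, rate = rate))
}

#' @rdname llogis4
#' @export
gompertz2 <- function(level, bshape) {
  check_pos(level, "level"); check_real(bshape, "bshape")
  new_crfamily("gompertz", c(level = level, bshape = bshape))
}

#' Construct a family from its string code
#'
#' Families are addressable by short code, as used in fitting, the study
#' runner and the command-line interface: `"ll4"`, `"ll2"`, `"weibull"`,
#' `"gompertz"`.
#'
#' @param name family code.
#' @param params named numeric vector or list of parameters, in the
#'   constructor's argument order (names are checked when given).
#' @return A `crfamily` object.
#' @examples
#' cr_family("ll2", c(lambda = 0.3, tau = 2.97))
#' @export
cr_family <- function(name, params) {
  ctor <- switch(match.arg(name, family_codes()),
    ll4 = llogis4, ll2 = llogis2, weibull = weibull2, gompertz = gompertz2)
  params <- as.list(params)
  if (!is.null(names(params)) && any(nzchar(names(params))))
    do.call(ctor, params)
  else
    do.call(ctor, unname(params))
}

family_codes <- function() c("ll4", "ll2", "weibull", "gompertz")

new_crfamily <- function(name, params) {
  structure(list(name = name, params = params),
            class = c(paste0("crfamily_", name), "crfamily"))
}

check_pos <- function(x, sym) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop("parameter '", sym, "' must be a single positive finite number",
         call. = FALSE)
  invisible(x)
}

check_real <- function(x, sym) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("parameter '", sym, "' must be a single finite number", call. = FALSE)
  invisible(x)
}

#' @export
print.crfamily <- function(x, ...) {
  lab <- switch(x$name,
    ll4 = "four-parameter log-logistic",
    ll2 = "two-parameter log-logistic",
    weibull = "Weibull", gompertz = "Gompertz")
  cat("<crfamily> ", lab, " (", x$name, ")\n", sep = "")
  print(x$params)
  tm <- tail_mass(x)
  if (tm > 0)
    cat("improper: S(Inf) =", format(tm, digits = 6), "\n")
  invisible(x)
}

# ---- log-scale kernels -----------------------------------------------------
# All evaluators work in log space; the two-parameter log-logistic cumulative
# hazard H(t) = log(1 + lambda t^tau) and its derivative are shared by both
# log-logistic families.

ll2_H  <- function(t, lambda, tau) log1p(lambda * t^tau)
ll2_Hp <- function(t, lambda, tau) lambda * tau * t^(tau - 1) / (1 + lambda * t^tau)

# alpha = 0 is a removable singularity of the Hougaard form; below this
# threshold the analytic limit S = (1 + H/theta)^(-theta^2) is used.
.alpha_eps <- 1e-8

log_surv <- function(object, t) UseMethod("log_surv")
log_haz  <- function(object, t) UseMethod("log_haz")

#' @export
log_surv.crfamily_ll4 <- function(object, t) {
  p <- object$params
  # log z = log(1 + H/theta) and z^alpha - 1 = expm1(alpha log z), kept in
  # log1p/expm1 form so tiny H/theta never cancels to zero
  logz <- log1p(ll2_H(t, p[["lambda"]], p[["tau"]]) / p[["theta"]])
  a <- p[["alpha"]]
  if (abs(a) < .alpha_eps) -p[["theta"]]^2 * logz
  else -(p[["theta"]]^2 / a) * expm1(a * logz)
}

#' @export
log_haz.crfamily_ll4 <- function(object, t) {
  p <- object$params
  logz <- log1p(ll2_H(t, p[["lambda"]], p[["tau"]]) / p[["theta"]])
  log(p[["theta"]]) + log(ll2_Hp(t, p[["lambda"]], p[["tau"]])) +
    (p[["alpha"]] - 1) * logz
}

#' @export
log_surv.crfamily_ll2 <- function(object, t) {
  p <- object$params
  -ll2_H(t, p[["lambda"]], p[["tau"]])
}

#' @export
log_haz.crfamily_ll2 <- function(object, t) {
  p <- object$params
  log(p[["lambda"]] * p[["tau"]]) + (p[["tau"]] - 1) * log(t) -
    ll2_H(t, p[["lambda"]], p[["tau"]])
}

#' @export
log_surv.crfamily_weibull <- function(object, t) {
  p <- object$params
  -(p[["rate"]] * t)^p[["shape"]]
}

#' @export
log_haz.crfamily_weibull <- function(object, t) {
  p <- object$params
  log(p[["shape"]] * p[["rate"]]) + (p[["shape"]] - 1) * log(p[["rate"]] * t)
}

#' @export
log_surv.crfamily_gompertz <- function(object, t) {
  p <- object$params
  a <- p[["level"]]; b <- p[["bshape"]]
  if (abs(b) < 1e-12) -a * t else -a * expm1(b * t) / b
}

#' @export
log_haz.crfamily_gompertz <- function(object, t) {
  p <- object$params
  log(p[["level"]]) + p[["bshape"]] * t
}

# degenerate "no event" family used when a cause has no observed events:
# S == 1, h == 0.
null_family <- function() new_crfamily("none", numeric(0))
#' @export
log_surv.crfamily_none <- function(object, t) rep(0, length(t))
#' @export
log_haz.crfamily_none <- function(object, t) rep(-Inf, length(t))

# ---- public evaluators -----------------------------------------------------

#' Evaluate survival, hazard, density and cumulative hazard
#'
#' Vectorised evaluators for `crfamily` objects.  `surv()` and `cumhaz()`
#' accept `t >= 0`; `haz()` and `dens()` require `t > 0` (the hazard may be
#' singular at the origin when the shape parameter is below one).  The
#' density is defined as \eqn{f(t) = h(t) S(t)}; for an improper family it
#' integrates to \eqn{1 - S(\infty)}.
#'
#' @param object a `crfamily`.
#' @param t evaluation times.
#' @return Numeric vector the length of `t`.
#' @examples
#' f <- llogis2(0.3, 2.97)
#' cumhaz(f, 2)                     # log(1 + 0.3 * 2^2.97)
#' all.equal(exp(-cumhaz(f, 2)), surv(f, 2))
#' @export
surv <- function(object, t) UseMethod("surv")

#' @export
surv.crfamily <- function(object, t) {
  check_times(t, zero_ok = TRUE)
  exp(log_surv(object, t))
}

#' @rdname surv
#' @export
haz <- function(object, t) UseMethod("haz")

#' @export
haz.crfamily <- function(object, t) {
  check_times(t, zero_ok = FALSE)
  exp(log_haz(object, t))
}

#' @rdname surv
#' @export
dens <- function(object, t) UseMethod("dens")

#' @export
dens.crfamily <- function(object, t) {
  check_times(t, zero_ok = FALSE)
  exp(log_haz(object, t) + log_surv(object, t))
}

#' @rdname surv
#' @export
cumhaz <- function(object, t) UseMethod("cumhaz")

#' @export
cumhaz.crfamily <- function(object, t) {
  check_times(t, zero_ok = TRUE)
  -log_surv(object, t)
}

#' Mass at infinity of an improper family
#'
#' Returns \eqn{S(\infty)}: `exp(theta^2/alpha)` for the four-parameter
#' log-logistic with `alpha < 0`, `exp(level/bshape)` for the Gompertz with
#' `bshape < 0`, and 0 for every proper family.
#'
#' @param object a `crfamily`.
#' @return A probability in `[0, 1)`.
#' @export
tail_mass <- function(object) UseMethod("tail_mass")

#' @export
tail_mass.crfamily <- function(object) {
  p <- object$params
  switch(object$name,
    ll4 = if (p[["alpha"]] < 0) exp(p[["theta"]]^2 / p[["alpha"]]) else 0,
    gompertz = if (p[["bshape"]] < 0) exp(p[["level"]] / p[["bshape"]]) else 0,
    none = 1,
    0)
}

check_times <- function(t, zero_ok) {
  if (!is.numeric(t) || anyNA(t))
    stop("'t' must be numeric with no missing values", call. = FALSE)
  if (zero_ok) {
    if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  } else if (any(t <= 0)) {
    stop("'t' must be strictly positive (the hazard may be singular at 0)",
         call. = FALSE)
  }
  invisible(t)
}

n_params <- function(object) length(object$params)

param_names <- function(name) {
  switch(name,
    ll4 = c("lambda", "tau", "theta", "alpha"),
    ll2 = c("lambda", "tau"),
    weibull = c("shape", "rate"),
    gompertz = c("level", "bshape"))
}

# transform metadata for optimisation: which parameters live on the log scale
log_scale_idx <- function(name) {
  switch(name,
    ll4 = 1:3,       # lambda, tau, theta;  alpha free
    ll2 = 1:2,
    weibull = 1:2,
    gompertz = 1L,   # level;  bshape free
    integer(0))
}

# dispersed natural-scale start grid for multi-start maximum likelihood
family_start_grid <- function(name) {
  switch(name,
    ll4 = as.matrix(expand.grid(lambda = c(0.05, 0.3, 1, 3),
                                tau = c(0.5, 1, 3),
                                theta = c(0.05, 0.3, 1, 3),
                                alpha = c(-1, 0.5, 1, 2))),
    ll2 = as.matrix(expand.grid(lambda = c(0.05, 0.3, 1, 3),
                                tau = c(0.5, 1, 3))),
    weibull = as.matrix(expand.grid(shape = c(0.5, 1, 1.5, 3),
                                    rate = c(0.05, 0.3, 1, 3))),
    gompertz = as.matrix(expand.grid(level = c(0.05, 0.3, 1, 3),
                                     bshape = c(-0.5, -0.1, 0.1, 0.5))))
}
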