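#' Two-cause competing-risks log-likelihood
#'
#' Evaluates the cause-specific log-likelihood
#' \deqn{\ell(\psi_1,\psi_2) = \sum_i [\delta_{1i}\log f_1(t_i) +
#'   \delta_{2i}\log f_2(t_i) + (1-\delta_{1i})\log S_1(t_i) +
#'   (1-\delta_{2i})\log S_2(t_i)]}
#' computed in log space throughout.  Because the overall survival
#' factorises as \eqn{S = S_1 S_2}, the likelihood separates into one block
#' per cause.
#'
#' @param cause1,cause2 `crfamily` objects (the \eqn{\psi_1,\psi_2} models).
#' @param sample a `cr_sample`.
#' @return The log-likelihood, a single number.
#' @export
cr_loglik <- function(cause1, cause2, sample) {
  stopifnot(inherits(sample, "cr_sample"))
  contrib <- log_surv(cause1, sample$time) + log_surv(cause2, sample$time)
  e1 <- sample$event == 1L
  e2 <- sample$event == 2L
  contrib[e1] <- contrib[e1] + log_haz(cause1, sample$time[e1])
  contrib[e2] <- contrib[e2] + log_haz(cause2, sample$time[e2])
  bad <- which(!is.finite(contrib))
  if (length(bad))
    stop("non-finite log-likelihood contribution at row ", bad[1L],
         " (time = ", sample$time[bad[1L]], ")", call. = FALSE)
  sum(contrib)
}

# fast internal single-cause negative log-likelihood on the transformed
# (unconstrained) scale; returns a large penalty instead of NaN/Inf so that
# optim() always sees a finite objective
make_cause_negll <- function(code, time, is_event) {
  t_ev <- time[is_event]
  lidx <- log_scale_idx(code)
  nm <- param_names(code)
  function(x) {
    if (any(abs(x) > 250)) return(1e10)  # keep exp(x) well inside range
    nat <- x
    nat[lidx] <- exp(x[lidx])
    fam <- new_crfamily(code, stats::setNames(nat, nm))
    val <- tryCatch(
      -(sum(log_surv(fam, time)) + sum(log_haz(fam, t_ev))),
      error = function(e) NaN, warning = function(w) NaN)
    if (!is.finite(val)) 1e10 else val
  }
}

# analytic score of the single-cause log-likelihood on the natural scale;
# one row per parameter.  ell = sum_all log S + sum_events log h, so the
# score splits into a survival part (all subjects) and a hazard part
# (events of this cause only).
cause_score <- function(code, nat, time, t_ev) {
  switch(code,
    ll2 = {
      L <- nat[1L]; Tt <- nat[2L]
      dlogS <- function(t) {
        u <- t^Tt; w <- 1 + L * u
        c(sum(-u / w), sum(-L * u * log(t) / w))
      }
      dlogh <- function(t) {
        u <- t^Tt; w <- 1 + L * u; lt <- log(t)
        c(sum(1 / L - u / w), sum(1 / Tt + lt - L * u * lt / w))
      }
      dlogS(time) + dlogh(t_ev)
    },
    ll4 = {
      L <- nat[1L]; Tt <- nat[2L]; Th <- nat[3L]; A <- nat[4L]
      dlogS <- function(t) {
        u <- t^Tt; w <- 1 + L * u
        H <- log1p(L * u)
        logz <- log1p(H / Th)
        zAm1 <- exp((A - 1) * logz)
        E <- expm1(A * logz); zA <- E + 1
        dS_dH <- -Th * zAm1
        if (abs(A) < .alpha_eps) {
          dTh <- -2 * Th * logz + H * zAm1
          dA <- -Th^2 * logz^2 / 2
        } else {
          dTh <- -(2 * Th / A) * E + H * zAm1
          dA <- -Th^2 * (A * zA * logz - E) / A^2
        }
        c(sum(dS_dH * u / w), sum(dS_dH * L * u * log(t) / w),
          sum(dTh), sum(dA))
      }
      dlogh <- function(t) {
        u <- t^Tt; w <- 1 + L * u; lt <- log(t)
        H <- log1p(L * u)
        logz <- log1p(H / Th)
        q <- 1 / (Th + H)
        c(sum(1 / L - u / w + (A - 1) * q * (u / w)),
          sum(1 / Tt + lt - L * u * lt / w + (A - 1) * q * (L * u * lt / w)),
          sum(1 / Th - (A - 1) * (H / Th) * q),
          sum(logz))
      }
      dlogS(time) + dlogh(t_ev)
    },
    weibull = {
      k <- nat[1L]; p <- nat[2L]
      dlogS <- function(t) {
        lg <- log(p * t); g <- exp(k * lg)
        c(sum(-g * lg), sum(-k * g / p))
      }
      dlogh <- function(t) {
        lg <- log(p * t)
        c(sum(1 / k + lg), length(t) * k / p)
      }
      dlogS(time) + dlogh(t_ev)
    },
    gompertz = {
      a <- nat[1L]; b <- nat[2L]
      dlogS <- function(t) {
        if (abs(b) < 1e-12) c(sum(-t), sum(-a * t^2 / 2))
        else c(sum(-expm1(b * t) / b),
               sum(-a * (t * exp(b * t) * b - expm1(b * t)) / b^2))
      }
      dlogh <- function(t) c(length(t) / a, sum(t))
      dlogS(time) + dlogh(t_ev)
    })
}

# gradient of the transformed-scale negative log-likelihood
make_cause_grad <- function(code, time, is_event) {
  t_ev <- time[is_event]
  lidx <- log_scale_idx(code)
  function(x) {
    if (any(abs(x) > 250)) return(rep(0, length(x)))
    nat <- x
    nat[lidx] <- exp(x[lidx])
    g <- tryCatch(cause_score(code, nat, time, t_ev),
                  error = function(e) NULL, warning = function(w) NULL)
    if (is.null(g) || any(!is.finite(g))) return(rep(0, length(x)))
    g[lidx] <- g[lidx] * nat[lidx]   # chain rule for log-scale coordinates
    -g
  }
}

to_transformed <- function(code, nat) {
  lidx <- log_scale_idx(code)
  x <- nat
  x[lidx] <- log(nat[lidx])
  x
}

from_transformed <- function(code, x) {
  lidx <- log_scale_idx(code)
  nat <- x
  nat[lidx] <- exp(x[lidx])
  stats::setNames(nat, param_names(code))
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

# dispersed multi-start set: the documented grid, subsampled to n_starts
# (seedable), plus family-specific data-driven starts
start_matrix <- function(code, time, is_event, n_starts, start_seed) {
  grid <- family_start_grid(code)
  if (n_starts < nrow(grid)) {
    keep <- with_seed(start_seed, sample.int(nrow(grid), n_starts))
    grid <- grid[keep, , drop = FALSE]
  }
  extra <- NULL
  if (code == "ll4") {
    # the ll2 optimum lifted to the four-parameter family at its reduction
    # point (theta = 1, alpha = 1) is a guaranteed-good start
    pre <- fit_single_cause("ll2", time, is_event, rbind(c(1, 1), c(0.3, 3)))
    if (pre$converged)
      extra <- matrix(c(pre$psi[["lambda"]], pre$psi[["tau"]], 1, 1), 1)
  } else if (code == "weibull") {
    extra <- matrix(c(1, 1 / mean(time)), 1)
  } else if (code == "gompertz") {
    extra <- matrix(c(sum(is_event) / sum(time), 0.01), 1)
  } else if (code == "ll2") {
    extra <- matrix(c(1 / mean(time), 1), 1)
  }
  rbind(extra, grid)
}

# multi-start BFGS maximisation for one cause block
fit_single_cause <- function(code, time, is_event, starts) {
  negll <- make_cause_negll(code, time, is_event)
  grad <- make_cause_grad(code, time, is_event)
  best <- NULL
  diag_msgs <- character(0)
  for (i in seq_len(nrow(starts))) {
    x0 <- to_transformed(code, starts[i, ])
    res <- tryCatch(
      stats::optim(x0, negll, gr = grad, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res)) {
      diag_msgs <- c(diag_msgs, paste0("start ", i, ": optim error"))
      next
    }
    if (!is.finite(res$value) || res$value >= 1e10) {
      diag_msgs <- c(diag_msgs, paste0("start ", i, ": non-finite optimum"))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(list(converged = FALSE, diagnostics = diag_msgs))
  # polish: restarting BFGS from the incumbent resets its curvature
  # approximation, which rescues slow progress along weakly identified ridges
  tries <- 0L
  while (best$convergence != 0L && tries < 3L) {
    res <- tryCatch(
      stats::optim(best$par, negll, gr = grad, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value > best$value) break
    best <- res
    tries <- tries + 1L
  }
  list(converged = best$convergence == 0L,
       code = best$convergence,
       psi = from_transformed(code, best$par),
       x = best$par, loglik = -best$value, negll = negll,
       n_starts_used = nrow(starts), diagnostics = diag_msgs)
}

# central-difference Hessian, step 1e-4 * (1 + |x|) per coordinate
num_hessian <- function(fn, x, step = 1e-4 * (1 + abs(x))) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- fn(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, step[i])
    H[i, i] <- (fn(x + ei) - 2 * f0 + fn(x - ei)) / step[i]^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ej <- replace(numeric(p), j, step[j])
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * step[i] * step[j])
    }
  }
  H
}

# covariance on the natural scale via the delta method: for log-scale
# coordinates d(nat)/d(trans) = nat
cause_vcov <- function(code, cause_fit) {
  H <- num_hessian(cause_fit$negll, cause_fit$x)
  ct <- tryCatch(solve(H), error = function(e) NULL)
  p <- length(cause_fit$x)
  if (is.null(ct)) return(matrix(NA_real_, p, p))
  jac <- rep(1, p)
  lidx <- log_scale_idx(code)
  jac[lidx] <- cause_fit$psi[lidx]
  diag(jac, p) %*% ct %*% diag(jac, p)
}

#' Maximum-likelihood fit of cause-specific parametric models
#'
#' Fits one parametric family per cause by maximising the two-cause
#' likelihood, which separates into independent cause blocks.  Positive
#' parameters are optimised on the log scale (the four-parameter family's
#' \eqn{\alpha} stays untransformed); each block is maximised by BFGS from a
#' multi-start set: a dispersed grid subsampled to `n_starts` (seedable via
#' `start_seed`), family-specific data-driven starts, and any `extra_starts`
#' supplied by the caller.  For the four-parameter log-logistic the
#' two-parameter optimum lifted to \eqn{\theta = 1, \alpha = 1} is always
#' included, so the four-parameter fit can never fall below its nested
#' special case.  The covariance of the estimates is the inverse of the
#' observed (numerical, central-difference) information at the optimum,
#' mapped back to the natural scale by the delta method.
#'
#' A cause with no observed events is skipped with a warning flag recorded
#' in the result; its cumulative incidence is then estimated as zero.
#'
#' @param sample a `cr_sample` with at least one event.
#' @param family family code (see [cr_family()]) of length 1 (both causes)
#'   or 2 (per cause).
#' @param n_starts number of dispersed grid starts per cause block.
#' @param extra_starts optional list with components `cause1`/`cause2`,
#'   each a natural-scale parameter vector (or matrix of rows) of
#'   additional starts.
#' @param start_seed seed for the start-grid subsample; does not disturb
#'   the caller's RNG stream.
#' @return An object of class `cr_fit` with per-cause estimates `psi1`,
#'   `psi2`, the stacked natural-scale covariance `vcov`, `loglik`, `aic`,
#'   `bic`, a `converged` flag and per-cause diagnostics.
#' @examples
#' \donttest{
#' d <- design_loglogistic(n = 400, seed = 7)
#' fit <- fit_mle(simulate_sample(d), family = "ll2")
#' fit
#' }
#' @export
fit_mle <- function(sample, family = "ll4", n_starts = 20L,
                    extra_starts = NULL, start_seed = 1L) {
  stopifnot(inherits(sample, "cr_sample"))
  family <- rep_len(as.character(family), 2L)
  if (!all(family %in% family_codes()))
    stop("unknown family code; use one of: ",
         paste(family_codes(), collapse = ", "), call. = FALSE)
  if (all(sample$event == 0L))
    stop("sample contains no events; nothing to fit", call. = FALSE)
  res <- vector("list", 2L)
  for (k in 1:2) {
    is_ev <- sample$event == k
    if (!any(is_ev)) {
      res[[k]] <- list(skipped = TRUE, converged = TRUE, loglik = 0,
                       psi = NULL, npar = 0L)
      next
    }
    starts <- start_matrix(family[k], sample$time, is_ev, n_starts, start_seed)
    ex <- extra_starts[[paste0("cause", k)]]
    if (!is.null(ex)) {
      if (is.null(dim(ex))) ex <- matrix(ex, nrow = 1L)
      starts <- rbind(ex, starts)
    }
    cf <- fit_single_cause(family[k], sample$time, is_ev, starts)
    if (!cf$converged && is.null(cf$psi))
      stop("cause ", k, " fit failed from every start:\n  ",
           paste(cf$diagnostics, collapse = "\n  "), call. = FALSE)
    cf$skipped <- FALSE
    cf$npar <- length(cf$psi)
    cf$vcov <- cause_vcov(family[k], cf)
    res[[k]] <- cf
  }
  npar <- res[[1L]]$npar + res[[2L]]$npar
  loglik <- res[[1L]]$loglik + res[[2L]]$loglik
  n <- nrow(sample)
  vc <- matrix(0, npar, npar)
  nm <- character(0)
  at <- 0L
  for (k in 1:2) {
    if (res[[k]]$skipped) next
    p <- res[[k]]$npar
    vc[at + seq_len(p), at + seq_len(p)] <- res[[k]]$vcov
    nm <- c(nm, paste0("cause", k, ".", names(res[[k]]$psi)))
    at <- at + p
  }
  dimnames(vc) <- list(nm, nm)
  structure(list(
    family = family,
    psi1 = res[[1L]]$psi, psi2 = res[[2L]]$psi,
    vcov = vc, loglik = loglik,
    aic = -2 * loglik + 2 * npar,
    bic = -2 * loglik + log(n) * npar,
    npar = npar, n = n,
    converged = res[[1L]]$converged && res[[2L]]$converged,
    skipped = c(cause1 = res[[1L]]$skipped, cause2 = res[[2L]]$skipped),
    n_starts_used = max(res[[1L]]$n_starts_used %||% 0L,
                        res[[2L]]$n_starts_used %||% 0L),
    sample = sample), class = "cr_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cr_fit <- function(x, ...) {
  cat("<cr_fit> families:", paste(x$family, collapse = " / "),
      " n =", x$n, "\n")
  for (k in 1:2) {
    psi <- x[[paste0("psi", k)]]
    if (is.null(psi)) {
      cat("  cause ", k, ": no events (skipped)\n", sep = "")
    } else {
      se <- sqrt(diag(x$vcov))[paste0("cause", k, ".", names(psi))]
      cat("  cause ", k, ":\n", sep = "")
      print(round(rbind(estimate = psi, se = se), 4))
    }
  }
  cat("  logLik =", format(x$loglik, digits = 7),
      " AIC =", format(x$aic, digits = 7),
      " BIC =", format(x$bic, digits = 7), "\n")
  if (!x$converged) cat("  WARNING: not converged\n")
  invisible(x)
}

#' @export
logLik.cr_fit <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' Cumulative incidence from a fitted model
#'
#' By invariance of maximum likelihood, the cumulative incidence estimate is
#' the parametric integral evaluated at the estimates: this delegates
#' directly to [parametric_cif()] with \eqn{\hat\psi_1, \hat\psi_2}.  A cause
#' skipped for lack of events contributes survival 1 and hazard 0.
#'
#' @param fit a converged `cr_fit`.
#' @param cause 1 or 2.
#' @param times evaluation grid.
#' @return A `cif_curve`.
#' @export
cif_from_fit <- function(fit, cause = 1L, times = report_times()) {
  stopifnot(inherits(fit, "cr_fit"))
  if (!fit$converged)
    stop("fit did not converge; no CIF estimate available", call. = FALSE)
  fam <- lapply(1:2, function(k) {
    psi <- fit[[paste0("psi", k)]]
    if (is.null(psi)) null_family() else cr_family(fit$family[k], psi)
  })
  curve <- parametric_cif(fam[[1L]], fam[[2L]], cause = cause, times = times)
  if (fit$skipped[cause]) {
    warning("cause ", cause, " had no events; returning a zero curve")
    attr(curve, "degenerate") <- TRUE
  }
  curve$method <- paste0("mle-", fit$family[cause])
  curve
}

#' Model comparison: information criteria and likelihood-ratio tests
#'
#' Tabulates AIC and BIC for a set of fits on the same sample and computes
#' likelihood-ratio chi-square statistics for declared nested pairs, with
#' degrees of freedom equal to the difference in free parameter counts
#' (counted across both causes) and p-values from the upper chi-square tail.
#' The statistic is floored at zero.
#'
#' @param fits a named list of `cr_fit` objects sharing one sample.
#' @param nesting list of `c(reduced, full)` name pairs.
#' @return A list of class `cr_model_comparison` with elements `models`
#'   (AIC/BIC table) and `lrt` (likelihood-ratio tests, possibly empty).
#' @examples
#' \donttest{
#' s <- simulate_sample(design_loglogistic(n = 300, seed = 2))
#' fits <- list(ll2 = fit_mle(s, "ll2"), ll4 = fit_mle(s, "ll4"))
#' compare_models(fits, nesting = list(c("ll2", "ll4")))
#' }
#' @export
compare_models <- function(fits, nesting = NULL) {
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    stop("'fits' must be a named list", call. = FALSE)
  lapply(fits, function(f) stopifnot(inherits(f, "cr_fit")))
  ref <- fits[[1L]]$sample
  same <- vapply(fits, function(f)
    isTRUE(all.equal(f$sample$time, ref$time)) &&
      identical(f$sample$event, ref$event), logical(1))
  if (!all(same))
    stop("all fits must share the same sample", call. = FALSE)
  models <- data.frame(
    model = names(fits),
    n_params = vapply(fits, function(f) f$npar, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    row.names = NULL)
  lrt <- data.frame(reduced = character(0), full = character(0),
                    chisq = numeric(0), df = integer(0), p = numeric(0))
  for (pair in nesting) {
    r <- fits[[pair[1L]]]; f <- fits[[pair[2L]]]
    if (is.null(r) || is.null(f))
      stop("nesting pair refers to an unknown fit name", call. = FALSE)
    chisq <- max(0, 2 * (f$loglik - r$loglik))
    df <- f$npar - r$npar
    lrt <- rbind(lrt, data.frame(
      reduced = pair[1L], full = pair[2L], chisq = chisq, df = df,
      p = stats::pchisq(chisq, df = max(df, 1L), lower.tail = FALSE)))
  }
  # identical models: df 0 gives p from chisq == 0 -> report p = 1
  if (nrow(lrt)) lrt$p[lrt$chisq == 0] <- 1
  structure(list(models = models, lrt = lrt), class = "cr_model_comparison")
}

#' @export
print.cr_model_comparison <- function(x, ...) {
  cat("Model comparison\n")
  print(transform(x$models, loglik = round(loglik, 2), aic = round(aic, 1),
                  bic = round(bic, 1)), row.names = FALSE)
  if (nrow(x$lrt)) {
    cat("\nLikelihood-ratio tests\n")
    print(transform(x$lrt, chisq = round(chisq, 2),
                    p = signif(p, 3)), row.names = FALSE)
  }
  invisible(x)
}
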