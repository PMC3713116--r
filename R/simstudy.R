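#' Monte-Carlo bias/MSE study of cumulative incidence estimators
#'
#' Replicates the generate-estimate-tabulate loop: for each of `n_reps`
#' replicates a sample is simulated from `design`, every requested estimator
#' produces \eqn{\hat F_k} at the report times for both causes, and the
#' per-time summaries are aggregated as
#' \deqn{\mathrm{bias}_t = \sum_j \hat F_{kj}(t)/R - F_k(t), \qquad
#'       \mathrm{MSE}_t = \sum_j (F_k(t) - \hat F_{kj}(t))^2 / R,}
#' with \eqn{F_k(t)} the true cumulative incidence obtained by numerical
#' integration under the generating design and \eqn{R} the number of
#' replicates used.  Replicates on which an estimator fails (non-convergence,
#' or no events of a cause) are excluded from that estimator's aggregates and
#' counted; the study aborts if any estimator fails on more than 10\% of
#' replicates.
#'
#' Parametric estimators are refit per replicate by multi-start maximum
#' likelihood.  After the first successful replicate the previous optimum is
#' used as a warm start together with `warm_n_starts` dispersed grid starts
#' (replicates are i.i.d. draws from one design, so the previous optimum is
#' an excellent start); the first replicate uses the full `n_starts`.
#'
#' @param design a `cr_design`.
#' @param estimators character vector drawn from the family codes
#'   (`"ll4"`, `"ll2"`, `"weibull"`, `"gompertz"`), `"nonparametric"` and
#'   `"oracle"` (returns the truth; useful for checking the harness).
#' @param n_reps number of Monte-Carlo replicates.
#' @param times report grid.
#' @param seed integer seed governing the whole study.
#' @param n_starts multi-start size for the first replicate's fits.
#' @param warm_n_starts dispersed starts retained once a warm start exists.
#' @param progress print a line every 50 replicates.
#' @return An object of class `cr_study`: the true CIF, and per estimator
#'   the mean CIF, bias and MSE at each time for both causes, the number of
#'   replicates used and excluded, and the per-replicate estimates (array
#'   `reps`) from which the summaries are recomputable.
#' @examples
#' \donttest{
#' st <- run_study(design_loglogistic(n = 200), estimators = "nonparametric",
#'                 n_reps = 20, seed = 1)
#' st
#' }
#' @export
run_study <- function(design, estimators = c("ll4", "nonparametric"),
                      n_reps = 1000L, times = report_times(), seed = 1L,
                      n_starts = 20L, warm_n_starts = 4L, progress = FALSE) {
  stopifnot(inherits(design, "cr_design"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("'n_reps' must be at least 1", call. = FALSE)
  ok <- c(family_codes(), "nonparametric", "oracle")
  if (!all(estimators %in% ok))
    stop("unknown estimator; use one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  nt <- length(times)
  truth <- rbind(
    cause1 = parametric_cif(design$cause1, design$cause2, 1L, times)$values,
    cause2 = parametric_cif(design$cause1, design$cause2, 2L, times)$values)
  set.seed(seed)
  rep_design <- design
  rep_design$seed <- NULL
  store <- lapply(estimators, function(e) array(NA_real_, c(n_reps, nt, 2L)))
  names(store) <- estimators
  fails <- stats::setNames(integer(length(estimators)), estimators)
  warm <- stats::setNames(vector("list", length(estimators)), estimators)
  for (j in seq_len(n_reps)) {
    s <- simulate_sample(rep_design)
    for (e in estimators) {
      est <- estimate_replicate(e, s, times, truth, warm[[e]],
                                n_starts, warm_n_starts)
      if (is.null(est$values)) {
        fails[e] <- fails[e] + 1L
      } else {
        store[[e]][j, , ] <- est$values
        if (!is.null(est$warm)) warm[[e]] <- est$warm
      }
    }
    if (progress && j %% 50L == 0L)
      message("replicate ", j, "/", n_reps)
  }
  bad <- fails > 0.1 * n_reps
  if (any(bad))
    stop("estimator(s) ", paste(estimators[bad], collapse = ", "),
         " failed on more than 10% of replicates (",
         paste(fails[bad], collapse = ", "), " of ", n_reps, ")",
         call. = FALSE)
  results <- lapply(estimators, function(e) {
    a <- store[[e]]
    used <- which(!is.na(a[, 1L, 1L]))
    a <- a[used, , , drop = FALSE]
    m1 <- matrix(a[, , 1L], ncol = nt)
    m2 <- matrix(a[, , 2L], ncol = nt)
    mean_cif <- rbind(cause1 = colMeans(m1), cause2 = colMeans(m2))
    mse <- rbind(cause1 = colMeans(sweep(m1, 2, truth["cause1", ])^2),
                 cause2 = colMeans(sweep(m2, 2, truth["cause2", ])^2))
    colnames(mean_cif) <- colnames(mse) <- format(times)
    list(mean_cif = mean_cif, bias = mean_cif - truth, mse = mse,
         n_used = length(used), n_failed = fails[[e]], reps = a)
  })
  names(results) <- estimators
  colnames(truth) <- format(times)
  structure(list(label = attr(design, "label") %||% "custom design",
                 design = design, estimators = estimators, times = times,
                 true_cif = truth, results = results,
                 n_reps = n_reps, seed = seed),
            class = "cr_study")
}

# one estimator on one replicate; returns matrix times x 2 (or NULL failure)
estimate_replicate <- function(e, s, times, truth, warm,
                               n_starts, warm_n_starts) {
  if (e == "oracle")
    return(list(values = t(truth)))
  if (e == "nonparametric") {
    vals <- tryCatch(
      cbind(step_at(nonparametric_cif(s, 1L), times),
            step_at(nonparametric_cif(s, 2L), times)),
      error = function(err) NULL)
    return(list(values = vals))
  }
  ns <- if (is.null(warm)) n_starts else warm_n_starts
  fit <- tryCatch(
    fit_mle(s, family = e, n_starts = ns, extra_starts = warm),
    error = function(err) NULL)
  if (is.null(fit) || !fit$converged) return(list(values = NULL))
  vals <- tryCatch(
    cbind(cif_from_fit(fit, 1L, times)$values,
          cif_from_fit(fit, 2L, times)$values),
    error = function(err) NULL, warning = function(w) NULL)
  if (is.null(vals)) return(list(values = NULL))
  list(values = vals, warm = list(cause1 = fit$psi1, cause2 = fit$psi2))
}

#' Tabulate a study report
#'
#' Renders a `cr_study` in the conventional layout: one block per cause and
#' estimator with rows CIF (Monte-Carlo mean), Bias, and MSE scaled by
#' \eqn{10^2}, one column per report time, plus the true-value rows.  The
#' returned data frame writes to delimited text with [write_report()] and
#' round-trips through [read_report()].
#'
#' @param report a `cr_study`.
#' @return A data frame with columns `event`, `estimator`, `statistic` and
#'   one column per report time.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "cr_study"))
  tcols <- paste0("t", format(report$times, trim = TRUE))
  rows <- list()
  for (k in 1:2) {
    ck <- paste0("cause", k)
    rows[[length(rows) + 1L]] <- data.frame(
      event = k, estimator = "true", statistic = "CIF",
      rbind(report$true_cif[ck, ]))
    for (e in report$estimators) {
      r <- report$results[[e]]
      rows[[length(rows) + 1L]] <- data.frame(
        event = k, estimator = e,
        statistic = c("CIF", "Bias", "MSEx100"),
        rbind(r$mean_cif[ck, ], r$bias[ck, ], 100 * r$mse[ck, ]))
    }
  }
  out <- do.call(rbind, rows)
  names(out) <- c("event", "estimator", "statistic", tcols)
  rownames(out) <- NULL
  out
}

#' @rdname render_report
#' @param path file path for the delimited-text report.
#' @export
write_report <- function(report, path) {
  tab <- if (inherits(report, "cr_study")) render_report(report) else report
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}

#' @rdname render_report
#' @export
read_report <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' @export
print.cr_study <- function(x, ...) {
  cat("<cr_study>", x$label, "\n")
  cat("  n =", x$design$n, " censoring =", x$design$censor_prob,
      " replicates =", x$n_reps, " seed =", x$seed, "\n")
  for (e in x$estimators) {
    nf <- x$results[[e]]$n_failed
    if (nf > 0L) cat("  ", e, ": ", nf, " replicate(s) excluded\n", sep = "")
  }
  tab <- render_report(x)
  tab[, -(1:3)] <- round(tab[, -(1:3)], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
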