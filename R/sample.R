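#' Competing-risks samples
#'
#' A competing-risks sample is one row per subject: an observation time
#' `time > 0` and an event code `event` with 0 = censored, 1 = event of
#' interest, 2 = competing event.
#'
#' @param time positive observation times.
#' @param event integer codes in `{0, 1, 2}`.
#' @return A data frame of class `cr_sample` with columns `time` and `event`.
#' @examples
#' cr_sample(c(1, 2, 3), c(1, 2, 0))
#' @export
cr_sample <- function(time, event) {
  if (length(time) != length(event))
    stop("'time' and 'event' must have equal length", call. = FALSE)
  if (length(time) == 0L) stop("sample must be non-empty", call. = FALSE)
  if (!is.numeric(time) || anyNA(time) || any(time <= 0) || any(!is.finite(time)))
    stop("observation times must be positive and finite", call. = FALSE)
  event <- as.integer(event)
  if (anyNA(event) || !all(event %in% 0:2))
    stop("event codes must be 0 (censored), 1 or 2", call. = FALSE)
  structure(data.frame(time = as.numeric(time), event = event),
            class = c("cr_sample", "data.frame"))
}

#' Read / write a competing-risks sample
#'
#' Samples round-trip through delimited text with a `time,event` header.
#'
#' @param path file path.
#' @param x a `cr_sample`.
#' @return `read_cr_sample()` returns a `cr_sample`; `write_cr_sample()`
#'   returns `x` invisibly.
#' @export
read_cr_sample <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time", "event") %in% names(d)))
    stop("expected columns 'time' and 'event' in ", path, call. = FALSE)
  cr_sample(d$time, d$event)
}

#' @rdname read_cr_sample
#' @export
write_cr_sample <- function(x, path) {
  utils::write.csv(as.data.frame(x)[c("time", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(x)
}

event_counts <- function(sample) {
  c(censored = sum(sample$event == 0L),
    cause1 = sum(sample$event == 1L),
    cause2 = sum(sample$event == 2L))
}
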