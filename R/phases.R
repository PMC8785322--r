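#' Pandemic phase scheme
#'
#' An ordered set of non-overlapping, half-open calendar windows
#' `[start, end)` labelling the phases of the public-health emergency. A
#' timestamp falling exactly on a shared boundary belongs to the later
#' window.
#'
#' @param starts,ends vectors coercible with [as.POSIXct()] (local time);
#'   `ends[i]` is exclusive.
#' @param labels phase labels; defaults to `1..n`.
#' @return object of class `phase_scheme`: a data.frame with columns
#'   `phase`, `start`, `end`.
#' @export
phase_scheme <- function(starts, ends, labels = seq_along(starts)) {
  starts <- as.POSIXct(starts, tz = "UTC")
  ends <- as.POSIXct(ends, tz = "UTC")
  if (length(starts) != length(ends) || length(starts) < 1) {
    stop("`starts` and `ends` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(is.na(starts)) || any(is.na(ends))) {
    stop("phase boundaries must be parseable datetimes", call. = FALSE)
  }
  if (any(ends <= starts)) {
    stop("each phase must end strictly after it starts", call. = FALSE)
  }
  if (is.unsorted(as.numeric(starts), strictly = TRUE)) {
    stop("phase windows must be strictly ordered", call. = FALSE)
  }
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)])) {
    stop("phase windows must not overlap", call. = FALSE)
  }
  structure(data.frame(phase = labels, start = starts, end = ends),
            class = c("phase_scheme", "data.frame"))
}

#' Default four-phase scheme for the early COVID-19 period in China
#'
#' Shipped as an overridable assumption: pre-outbreak (Phase 1), outbreak
#' (Phase 2, ending at the Wuhan lockdown), gradual containment (Phase 3)
#' and initial victory (Phase 4). Only the overall start (2019-12-01), the
#' Phase 1/2 boundary (2019-12-27) and the overall end (late April 2020) are
#' firmly anchored by the study design; the interior boundaries are
#' documented assumptions and every function taking a scheme accepts a
#' custom one.
#'
#' @return a [phase_scheme()] with four phases.
#' @export
default_phase_scheme <- function() {
  phase_scheme(
    starts = c("2019-12-01", "2019-12-27", "2020-01-23", "2020-03-18"),
    ends   = c("2019-12-27", "2020-01-23", "2020-03-18", "2020-04-28"),
    labels = 1:4
  )
}

#' Locate timestamps in a phase scheme
#'
#' @param timestamps POSIXct (or coercible) vector.
#' @param scheme a [phase_scheme()].
#' @return integer vector of phase indices (position in `scheme`), `NA` for
#'   timestamps outside every window.
#' @export
phase_of <- function(timestamps, scheme) {
  stopifnot(inherits(scheme, "phase_scheme"))
  ts <- as.POSIXct(timestamps, tz = "UTC")
  idx <- rep(NA_integer_, length(ts))
  for (i in seq_len(nrow(scheme))) {
    idx[!is.na(ts) & ts >= scheme$start[i] & ts < scheme$end[i]] <- i
  }
  idx
}
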