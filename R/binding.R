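# Detection of spontaneous substrate-binding events from the d_nuc series
# and per-frame binding-phase labels, with the Gln-hG52 anchor hydrogen
# bond reported per event (reported, not gated: no unbinding rule is
# attached to it).

#' Detect substrate-binding events
#'
#' An event opens at the first frame entering \code{recognition} from
#' \code{unbound} and closes when the phase returns to \code{unbound}
#' (hysteresis at the recognition threshold) or at the trajectory end.
#' Events whose total \code{captured} + \code{catalytic} frame count is
#' below \code{min_capture_frames} are discarded; an event is
#' \code{productive} iff it contains at least one \code{catalytic} frame.
#'
#' @param d_nuc \code{ObservableSeries} or numeric distances (Angstrom).
#' @param phase_labels Per-frame phases from
#'   \code{\link{classify_binding_phase}}.
#' @param anchor_occupancy Optional per-frame logical (or 0/1) series of
#'   the anchoring Gln-hG52 hydrogen bond; its mean within each event is
#'   reported.
#' @param min_capture_frames Minimum captured+catalytic frames to keep an
#'   event (default 10).
#' @param times_ns Optional frame times for dwell reporting.
#' @return data.frame of events: start/end frame, per-phase dwell times,
#'   anchor occupancy, \code{productive}.
#' @export
detect_binding_events <- function(d_nuc, phase_labels,
                                  anchor_occupancy = NULL,
                                  min_capture_frames = 10,
                                  times_ns = NULL) {
  d <- if (inherits(d_nuc, "ObservableSeries")) d_nuc$values
       else as.numeric(d_nuc)
  if (inherits(d_nuc, "ObservableSeries") && is.null(times_ns))
    times_ns <- d_nuc$times_ns
  ph <- as.character(phase_labels)
  n <- length(d)
  if (length(ph) != n)
    stop("d_nuc and phase labels differ in length: ", n, " vs ", length(ph))
  if (!is.null(anchor_occupancy) && length(anchor_occupancy) != n)
    stop("anchor occupancy series misaligned with d_nuc")
  stopifnot(min_capture_frames >= 1)
  if (is.null(times_ns)) times_ns <- seq_len(n) - 1
  dt <- if (n > 1) stats::median(diff(times_ns)) else 1
  bound <- !is.na(ph) & ph != "unbound"
  open_at <- integer(0)
  close_at <- integer(0)
  in_ev <- FALSE
  for (k in seq_len(n)) {
    if (!in_ev && bound[k]) {
      open_at <- c(open_at, k)
      in_ev <- TRUE
    } else if (in_ev && !bound[k]) {
      close_at <- c(close_at, k - 1L)
      in_ev <- FALSE
    }
  }
  if (in_ev) close_at <- c(close_at, n)
  events <- list()
  for (e in seq_along(open_at)) {
    idx <- open_at[e]:close_at[e]
    pe <- ph[idx]
    ncap <- sum(pe %in% c("captured", "catalytic"))
    if (ncap < min_capture_frames) next
    events[[length(events) + 1]] <- data.frame(
      start = open_at[e], end = close_at[e],
      start_ns = times_ns[open_at[e]], end_ns = times_ns[close_at[e]],
      recognition_ns = sum(pe == "recognition") * dt,
      captured_ns = sum(pe == "captured") * dt,
      catalytic_ns = sum(pe == "catalytic") * dt,
      phase_sequence = paste(rle(pe)$values, collapse = ">"),
      anchor_occupancy = if (is.null(anchor_occupancy)) NA_real_
                         else mean(as.numeric(anchor_occupancy[idx])),
      productive = any(pe == "catalytic"))
  }
  if (length(events) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      start_ns = numeric(0), end_ns = numeric(0),
                      recognition_ns = numeric(0), captured_ns = numeric(0),
                      catalytic_ns = numeric(0),
                      phase_sequence = character(0),
                      anchor_occupancy = numeric(0),
                      productive = logical(0)))
  do.call(rbind, events)
}
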