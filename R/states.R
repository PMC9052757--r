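# Rule-based classification of oxyanion-strand conformational states
# (inactive-OxH / unblocked-OxH / active-OxH) from the phi dihedrals of
# hV51 and hG50, of substrate-binding phases from d_nuc, plus dwell-segment
# extraction and periodic population histograms.

#' Define a conformational state by periodic dihedral intervals
#'
#' Intervals are on the circle in degrees, closed on the lower edge and
#' open on the upper, except that the wrap point -180/180 belongs to an
#' interval whose upper edge is 180. An interval with \code{lo > hi} wraps
#' through 180/-180.
#'
#' @param name State name.
#' @param phi_v51 Length-2 interval for phi-hV51, or \code{NULL} for "any".
#' @param phi_g50 Length-2 interval for phi-hG50, or \code{NULL} for "any".
#' @return A \code{StateDefinition}.
#' @export
state_definition <- function(name, phi_v51 = NULL, phi_g50 = NULL) {
  for (iv in list(phi_v51, phi_g50))
    if (!is.null(iv)) stopifnot(length(iv) == 2, all(abs(iv) <= 180))
  structure(list(name = name, phi_v51 = phi_v51, phi_g50 = phi_g50),
            class = "StateDefinition")
}

#' Default oxyanion-strand state boxes
#'
#' The inactive-OxH phi-hV51 interval [-180, -100] and the active-OxH
#' position (phi-hV51 around 60 degrees) are the literature values; the
#' unblocked-OxH phi-hG50 band (0, 120] is a documented default guess, as
#' no numeric boundary for the partial phi-hG50 rotation has been
#' published. All boxes are overridable. The list order is the priority
#' order used for overlap resolution.
#'
#' @return Named list of \code{StateDefinition}s (inactive-OxH,
#'   unblocked-OxH, active-OxH).
#' @export
default_oxh_states <- function() {
  list(
    state_definition("inactive-OxH", phi_v51 = c(-180, -100),
                     phi_g50 = c(-180, 0)),
    state_definition("unblocked-OxH", phi_v51 = c(-180, -100),
                     phi_g50 = c(0, 120)),
    state_definition("active-OxH", phi_v51 = c(20, 100), phi_g50 = NULL)
  )
}

#' Interface-angle threshold for productive HisF:HisH closure (degrees)
#'
#' Frames with theta below this value are in the productively closed
#' interface state.
#'
#' @return 13 (degrees).
#' @export
productive_closure_threshold <- function() 13

# periodic interval membership: lower-closed, upper-open, wrap point 180
# belongs to intervals whose upper edge is 180 (or -180 lower edge).
in_periodic_interval <- function(x, iv) {
  if (is.null(iv)) return(rep(TRUE, length(x)))
  x <- wrap_angle(x)
  lo <- iv[1]
  hi <- iv[2]
  if (lo <= hi) {
    inside <- (x >= lo & x < hi) | (hi == 180 & x == 180)
    if (lo == -180) inside <- inside | x == 180  # -180 aliases 180
    inside
  } else {
    (x >= lo & x <= 180) | (x >= -180 & x < hi)
  }
}

#' Classify frames into oxyanion-strand states
#'
#' Each frame is labelled by the first matching definition in priority
#' order; frames matching none are \code{"unassigned"}; frames where either
#' dihedral is undefined (\code{NA}) are \code{NA}.
#'
#' @param phi_v51,phi_g50 \code{ObservableSeries} or numeric vectors of the
#'   two phi dihedrals (degrees), same length.
#' @param defs List of \code{StateDefinition}s, in priority order.
#' @return A \code{StateTrajectory}: list with per-frame \code{labels},
#'   \code{times_ns} and the definitions used.
#' @export
classify_states <- function(phi_v51, phi_g50, defs = default_oxh_states()) {
  t1 <- if (inherits(phi_v51, "ObservableSeries")) phi_v51$times_ns
  v51 <- if (inherits(phi_v51, "ObservableSeries")) phi_v51$values
         else as.numeric(phi_v51)
  g50 <- if (inherits(phi_g50, "ObservableSeries")) phi_g50$values
         else as.numeric(phi_g50)
  if (length(v51) != length(g50))
    stop("phi series differ in length: ", length(v51), " vs ", length(g50))
  nm <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("state names must be unique")
  labels <- rep("unassigned", length(v51))
  for (def in rev(defs)) {  # earlier definitions overwrite later ones
    hit <- in_periodic_interval(v51, def$phi_v51) &
      in_periodic_interval(g50, def$phi_g50)
    labels[hit] <- def$name
  }
  labels[is.na(v51) | is.na(g50)] <- NA
  if (is.null(t1)) t1 <- seq_along(labels) - 1
  structure(list(labels = labels, times_ns = t1, definitions = defs),
            class = "StateTrajectory")
}

#' @export
print.StateTrajectory <- function(x, ...) {
  tab <- table(x$labels, useNA = "ifany")
  cat("StateTrajectory:", length(x$labels), "frames\n")
  print(tab)
  invisible(x)
}

#' Define substrate-binding phase thresholds
#'
#' Defaults follow the published d_nuc semantics: unbound above 12 A,
#' captured below 6 A, catalytic below 3.5 A together with the active-OxH
#' conformation.
#'
#' @param recognition,capture,catalytic Distance thresholds in Angstrom,
#'   strictly decreasing.
#' @param required_state Conformational state required for the catalytic
#'   phase.
#' @return A \code{BindingPhaseDefinition}.
#' @export
binding_phase_definition <- function(recognition = 12, capture = 6,
                                     catalytic = 3.5,
                                     required_state = "active-OxH") {
  if (!(catalytic < capture && capture < recognition))
    stop("thresholds must satisfy catalytic < capture < recognition")
  structure(list(recognition = recognition, capture = capture,
                 catalytic = catalytic, required_state = required_state),
            class = "BindingPhaseDefinition")
}

#' Classify substrate-binding phases from d_nuc
#'
#' Per frame: \code{unbound} if d > recognition; \code{recognition} if
#' capture < d <= recognition; \code{captured} if catalytic < d <= capture,
#' or d <= catalytic without the required conformational state;
#' \code{catalytic} iff d <= catalytic and the state is the required one.
#'
#' @param d_nuc \code{ObservableSeries} or numeric vector of distances (A).
#' @param state_traj \code{StateTrajectory} (or character labels) aligned
#'   frame-wise with \code{d_nuc}.
#' @param defs A \code{BindingPhaseDefinition}.
#' @return Character vector of phase labels.
#' @export
classify_binding_phase <- function(d_nuc, state_traj,
                                   defs = binding_phase_definition()) {
  d <- if (inherits(d_nuc, "ObservableSeries")) d_nuc$values
       else as.numeric(d_nuc)
  st <- if (inherits(state_traj, "StateTrajectory")) state_traj$labels
        else as.character(state_traj)
  if (length(d) != length(st))
    stop("d_nuc and state labels differ in length")
  if (any(d < 0, na.rm = TRUE)) stop("negative distances in d_nuc")
  phase <- rep("unbound", length(d))
  phase[d <= defs$recognition] <- "recognition"
  phase[d <= defs$capture] <- "captured"
  phase[d <= defs$catalytic & !is.na(st) & st == defs$required_state] <-
    "catalytic"
  phase[is.na(d)] <- NA
  phase
}

#' Dwell segments and transition counts of a label series
#'
#' Runs shorter than \code{min_dwell_frames} are absorbed into a flanking
#' segment (the shorter neighbour is absorbed into the longer; on a tie the
#' preceding one wins), applied iteratively shortest-run first. The
#' transition matrix counts label changes at the surviving segment
#' boundaries.
#'
#' @param labels Character per-frame labels (e.g. from
#'   \code{\link{classify_states}}).
#' @param min_dwell_frames Minimum run length kept as a segment (>= 1).
#' @param times_ns Optional frame times for segment durations.
#' @return List with \code{labels} (filtered), \code{segments} (data.frame
#'   state/start/end/duration_ns) and \code{transitions} (count matrix).
#' @export
dwell_segments <- function(labels, min_dwell_frames = 1, times_ns = NULL) {
  if (inherits(labels, "StateTrajectory")) {
    if (is.null(times_ns)) times_ns <- labels$times_ns
    labels <- labels$labels
  }
  stopifnot(min_dwell_frames >= 1)
  n <- length(labels)
  if (is.null(times_ns)) times_ns <- seq_len(n) - 1
  # merge on the run-length encoding (cheap even for long label series):
  # repeatedly absorb the shortest under-minimum run into its longer
  # flanking run (tie: the preceding one), coalescing equal neighbours
  r <- rle(labels)
  repeat {
    if (length(r$lengths) == 1) break
    short <- which(r$lengths < min_dwell_frames)
    if (length(short) == 0) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) r$lengths[i - 1] else -Inf
    right <- if (i < length(r$lengths)) r$lengths[i + 1] else -Inf
    donor <- if (left >= right) i - 1 else i + 1
    r$values[i] <- r$values[donor]
    v1 <- r$values[-length(r$values)]
    v2 <- r$values[-1]
    same <- c(FALSE, (v1 == v2 & !is.na(v1) & !is.na(v2)) |
                (is.na(v1) & is.na(v2)))
    grp <- cumsum(!same)
    r <- list(lengths = as.integer(tapply(r$lengths, grp, sum)),
              values = r$values[!same])
  }
  lab <- inverse.rle(structure(r, class = "rle"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segments <- data.frame(state = r$values, start = starts, end = ends,
                         duration_ns = times_ns[ends] - times_ns[starts],
                         stringsAsFactors = FALSE)
  states <- sort(unique(lab))
  trans <- matrix(0L, length(states), length(states),
                  dimnames = list(from = states, to = states))
  if (length(r$values) > 1)
    for (k in seq_len(length(r$values) - 1)) {
      trans[r$values[k], r$values[k + 1]] <-
        trans[r$values[k], r$values[k + 1]] + 1L
    }
  list(labels = lab, segments = segments, transitions = trans)
}

#' 2D periodic population histogram of the two phi dihedrals
#'
#' Bins cover (-180, 180] on each axis; a value of exactly 180 falls in the
#' last bin and -180 wraps into that same bin. \code{NA} frames (undefined
#' geometry) are excluded.
#'
#' @param phi_v51,phi_g50 Series or numeric vectors (degrees).
#' @param bins Bins per axis (>= 4).
#' @return List with \code{counts} (bins x bins matrix, phi_v51 on rows),
#'   \code{centers} (bin centers) and \code{n_assigned}.
#' @export
landscape_histogram <- function(phi_v51, phi_g50, bins = 72) {
  stopifnot(bins >= 4)
  v <- if (inherits(phi_v51, "ObservableSeries")) phi_v51$values
       else as.numeric(phi_v51)
  g <- if (inherits(phi_g50, "ObservableSeries")) phi_g50$values
       else as.numeric(phi_g50)
  stopifnot(length(v) == length(g))
  ok <- !is.na(v) & !is.na(g)
  iv <- periodic_bin_index(v[ok], bins)
  ig <- periodic_bin_index(g[ok], bins)
  counts <- matrix(tabulate(iv + (ig - 1L) * bins, nbins = bins * bins),
                   bins, bins)
  w <- 360 / bins
  centers <- -180 + (seq_len(bins) - 0.5) * w
  list(counts = counts, centers = centers, n_assigned = sum(ok))
}

# bin index on (-180, 180], upper-edge-closed; -180 aliases 180 (last bin)
periodic_bin_index <- function(x, bins) {
  x <- wrap_angle(x)
  w <- 360 / bins
  i <- ceiling((x + 180) / w)
  i[i < 1] <- bins  # x == -180 wraps into the last bin
  pmin(i, bins)
}
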