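# Per-frame geometric order parameters: backbone phi dihedrals, the
# three-C-alpha HisF:HisH interface angle theta, pair distances (d_nuc) and
# hydrogen-bond occupancies. All angles in degrees, distances in Angstrom.

#' Resolve atoms by (chain, residue, atom name)
#'
#' @param model A \code{StructureModel}.
#' @param chain Chain tag(s).
#' @param resno Residue number(s); insertion codes may be appended, e.g.
#'   \code{"52A"}.
#' @param name Atom name(s), e.g. \code{"CA"}.
#' @param label Optional provenance string attached to the selection.
#' @return An \code{AtomSelection}: integer atom indices with a
#'   \code{provenance} attribute. Vector arguments are recycled in parallel,
#'   one atom per (chain, resno, name) triple, in input order.
#' @export
atom_select <- function(model, chain, resno, name, label = NULL) {
  stopifnot(inherits(model, "StructureModel"))
  n <- max(length(chain), length(resno), length(name))
  chain <- rep_len(chain, n)
  resno <- rep_len(as.character(resno), n)
  name <- rep_len(name, n)
  a <- model$atoms
  reskey <- paste0(a$resno, a$insert)
  idx <- integer(n)
  for (k in seq_len(n)) {
    hit <- which(a$chain == chain[k] & reskey == resno[k] &
                   a$elety == name[k])
    if (length(hit) != 1)
      stop("selection '", name[k], " of ", chain[k], ":", resno[k],
           "' matched ", length(hit), " atoms")
    idx[k] <- hit
  }
  if (is.null(label))
    label <- paste(name, "of", paste0(chain, ":", resno), collapse = "; ")
  structure(idx, provenance = label, class = "AtomSelection")
}

#' Atom quadruple defining the backbone phi dihedral of a residue
#'
#' phi(i) is the torsion C(i-1)-N(i)-CA(i)-C(i).
#'
#' @param model A \code{StructureModel}.
#' @param chain Chain tag.
#' @param resno Residue number of residue i.
#' @return An \code{AtomSelection} of 4 atoms.
#' @export
phi_selection <- function(model, chain, resno) {
  a <- model$atoms
  resno <- as.integer(resno)
  prev <- which(a$chain == chain & a$resno == resno - 1L & a$elety == "C")
  if (length(prev) != 1)
    stop("phi undefined: no unique C atom in preceding residue ", chain, ":",
         resno - 1L)
  sel <- atom_select(model, chain, c(resno, resno, resno), c("N", "CA", "C"))
  structure(c(prev, unclass(sel)),
            provenance = paste0("phi(", chain, ":", resno, ")"),
            class = "AtomSelection")
}

#' Construct an observable time series
#'
#' @param name Series name.
#' @param values Per-frame numeric values; \code{NA} marks frames where the
#'   geometry was degenerate (never silently imputed).
#' @param unit \code{"degrees"} or \code{"angstrom"}.
#' @param times_ns Frame times.
#' @param periodic Logical; \code{period} gives the period (360 for
#'   dihedrals).
#' @param period Period in the series' unit.
#' @return Object of class \code{ObservableSeries}.
#' @export
observable_series <- function(name, values, unit, times_ns,
                              periodic = FALSE, period = NA_real_) {
  stopifnot(length(values) == length(times_ns),
            unit %in% c("degrees", "angstrom"))
  structure(list(name = name, values = as.numeric(values), unit = unit,
                 times_ns = as.numeric(times_ns), periodic = periodic,
                 period = period),
            class = "ObservableSeries")
}

#' @export
print.ObservableSeries <- function(x, ...) {
  ok <- !is.na(x$values)
  cat(sprintf("ObservableSeries '%s' (%s): %d frames, range [%.3g, %.3g]%s\n",
              x$name, x$unit, length(x$values),
              if (any(ok)) min(x$values[ok]) else NA,
              if (any(ok)) max(x$values[ok]) else NA,
              if (any(!ok)) sprintf(", %d undefined", sum(!ok)) else ""))
  invisible(x)
}

#' @export
length.ObservableSeries <- function(x) length(x$values)

# coordinates of selected atoms: array [n_sel, 3, n_frames]
sel_coords <- function(traj, sel) {
  idx <- as.integer(sel)
  if (any(idx < 1 | idx > n_atoms(traj)))
    stop("selection indices outside topology")
  traj$coords[idx, , , drop = FALSE]
}

#' Signed dihedral (torsion) time series
#'
#' IUPAC sign convention, values in (-180, 180]. For the backbone phi of
#' residue i, pass the quadruple from \code{\link{phi_selection}}. Frames
#' with degenerate geometry (collinear triples) are flagged \code{NA}.
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param sel4 An \code{AtomSelection} of exactly 4 atoms.
#' @param name Series name.
#' @return An \code{ObservableSeries} in degrees, periodic with period 360.
#' @export
dihedral_series <- function(traj, sel4, name = "dihedral") {
  if (length(sel4) != 4) stop("dihedral needs exactly 4 atoms")
  xyz <- sel_coords(traj, sel4)
  nf <- dim(xyz)[3]
  vals <- vapply(seq_len(nf), function(k) torsion_angle(xyz[, , k]),
                 numeric(1))
  observable_series(name, vals, "degrees", traj$times_ns,
                    periodic = TRUE, period = 360)
}

# torsion of a 4x3 coordinate matrix, degrees in (-180, 180], NA if degenerate
torsion_angle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2^2))
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20 || nb2 < 1e-10)
    return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap angles into (-180, 180]
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360
  y[!is.na(y) & y <= 0] <- y[!is.na(y) & y <= 0] + 360
  y - 180
}

#' Planar angle time series
#'
#' Angle at the SECOND atom of the triad, in [0, 180]. This is the
#' HisF:HisH interface angle theta when the triad is the C-alpha atoms of
#' fF120 / hW123 / hG52.
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param sel3 An \code{AtomSelection} of exactly 3 atoms (vertex second).
#' @param name Series name.
#' @return An \code{ObservableSeries} in degrees.
#' @export
angle_series <- function(traj, sel3, name = "angle") {
  if (length(sel3) != 3) stop("angle needs exactly 3 atoms")
  xyz <- sel_coords(traj, sel3)
  nf <- dim(xyz)[3]
  vals <- vapply(seq_len(nf), function(k) {
    planar_angle(xyz[1, , k], xyz[2, , k], xyz[3, , k])
  }, numeric(1))
  observable_series(name, vals, "degrees", traj$times_ns)
}

planar_angle <- function(a, b, c) {
  v1 <- a - b
  v2 <- c - b
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-10 || n2 < 1e-10) return(NA_real_)
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Pair-distance time series
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param sel2 An \code{AtomSelection} of exactly 2 atoms.
#' @param name Series name (e.g. \code{"d_nuc"} for the hC84 thiol to
#'   glutamine amide-carbon distance).
#' @return An \code{ObservableSeries} in Angstrom.
#' @export
distance_series <- function(traj, sel2, name = "distance") {
  if (length(sel2) != 2) stop("distance needs exactly 2 atoms")
  xyz <- sel_coords(traj, sel2)
  d <- sqrt(colSums((matrix(xyz[1, , ], nrow = 3) -
                       matrix(xyz[2, , ], nrow = 3))^2))
  observable_series(name, d, "angstrom", traj$times_ns)
}

#' Hydrogen-bond occupancy
#'
#' Fraction of frames satisfying donor-acceptor distance <= \code{d_cut}
#' and donor-H...acceptor angle >= \code{angle_cut}. With
#' \code{heavy_only = TRUE} the angular criterion is dropped (backbone
#' H-bonds reported from heavy atoms only) and no hydrogen selection is
#' needed.
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param donor,hydrogen,acceptor Single-atom \code{AtomSelection}s;
#'   \code{hydrogen} may be \code{NULL} only with \code{heavy_only}.
#' @param d_cut Donor-acceptor cutoff, Angstrom (default 3.5).
#' @param angle_cut Donor-H-acceptor minimum angle, degrees (default 120).
#' @param heavy_only Use the distance criterion alone.
#' @return Fraction in [0, 1], with attribute \code{per_frame} (logical).
#' @export
hbond_occupancy <- function(traj, donor, hydrogen = NULL, acceptor,
                            d_cut = 3.5, angle_cut = 120,
                            heavy_only = FALSE) {
  stopifnot(length(donor) == 1, length(acceptor) == 1)
  if (is.null(hydrogen) && !heavy_only)
    stop("hydrogen selection absent; enable heavy_only for a ",
         "distance-only criterion")
  d <- distance_series(traj, structure(c(unclass(donor), unclass(acceptor)),
                                       class = "AtomSelection"))$values
  ok <- d <= d_cut
  if (!heavy_only) {
    stopifnot(length(hydrogen) == 1)
    xyz_d <- matrix(sel_coords(traj, donor)[1, , ], nrow = 3)
    xyz_h <- matrix(sel_coords(traj, hydrogen)[1, , ], nrow = 3)
    xyz_a <- matrix(sel_coords(traj, acceptor)[1, , ], nrow = 3)
    nf <- n_frames(traj)
    ang <- vapply(seq_len(nf), function(k)
      planar_angle(xyz_d[, k], xyz_h[, k], xyz_a[, k]), numeric(1))
    ok <- ok & !is.na(ang) & ang >= angle_cut
  }
  structure(mean(ok), per_frame = ok)
}
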