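# Structure / trajectory / metadynamics-record I/O and residue addressing.
# PDB parsing and writing are delegated to bio3d; HILLS/COLVAR use the
# PLUMED-style whitespace dialect with "#! FIELDS" headers.

#' Construct a structure model
#'
#' A light container for a molecular topology: an atom table, coordinates in
#' Angstrom, and a chain-to-subunit map used for HisF/HisH style addressing.
#'
#' @param atoms data.frame with columns \code{eleno}, \code{elety} (atom
#'   name), \code{resid} (residue name), \code{chain}, \code{resno},
#'   \code{insert} (insertion code, \code{""} if none), \code{elesy}
#'   (element symbol).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param subunit_map named character vector mapping chain tag to subunit
#'   label; chains absent from the map are labelled by their own tag.
#' @return Object of class \code{StructureModel}.
#' @export
structure_model <- function(atoms, xyz, subunit_map = NULL) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3,
            nrow(xyz) == nrow(atoms))
  if (!all(is.finite(xyz))) stop("structure coordinates must be finite")
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste(atoms$chain, paste0(atoms$resno, atoms$insert), atoms$elety)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom name) key: ",
         key[duplicated(key)][1])
  if (is.null(subunit_map)) {
    ch <- unique(atoms$chain)
    subunit_map <- setNames(ch, ch)
  }
  structure(list(atoms = atoms, xyz = xyz, subunit_map = subunit_map),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel: %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno,
                                  x$atoms$insert))),
              paste(unique(x$atoms$chain), collapse = ", ")))
  for (ch in names(x$subunit_map))
    cat(sprintf("  chain %s -> %s\n", ch, x$subunit_map[[ch]]))
  invisible(x)
}

#' Number of atoms in a model or ensemble
#' @param x \code{StructureModel} or \code{TrajectoryEnsemble}.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "StructureModel")) return(nrow(x$atoms))
  if (inherits(x, "TrajectoryEnsemble")) return(dim(x$coords)[1])
  stop("unsupported type")
}

#' Load a structure from a PDB file
#'
#' Reads the first MODEL of a PDB file (via bio3d), resolving alternate
#' locations to the highest-occupancy copy and dropping HETATM records unless
#' requested. Insertion codes are carried in the residue key.
#'
#' @param path Path to a PDB file.
#' @param format Only \code{"pdb"} is supported.
#' @param subunit_map Named character vector chain -> subunit label; defaults
#'   to the chain tags themselves.
#' @param include_hetatm Keep HETATM records (default \code{FALSE}).
#' @return A \code{StructureModel}.
#' @export
load_structure <- function(path, format = "pdb", subunit_map = NULL,
                           include_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- tolower(format)
  if (format != "pdb") stop("unsupported structure format: ", format)
  validate_pdb_lines(path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!include_hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  # altloc: keep the highest-occupancy alternative per atom key
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  if (anyDuplicated(key)) {
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i)
      i[which.max(occ[i])]), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  atoms <- data.frame(eleno = at$eleno, elety = at$elety, resid = at$resid,
                      chain = at$chain, resno = at$resno, insert = at$insert,
                      elesy = at$elesy, stringsAsFactors = FALSE)
  xyz <- cbind(at$x, at$y, at$z)
  colnames(xyz) <- c("x", "y", "z")
  structure_model(atoms, xyz, subunit_map)
}

# Light pre-scan so a malformed ATOM record fails with its line number,
# which bio3d does not report.
validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, " of ", path,
           ": shorter than 54 columns")
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("malformed ATOM record at line ", i, " of ", path,
           ": non-numeric coordinate field")
  }
  invisible(TRUE)
}

#' Write a structure model to PDB
#'
#' @param model A \code{StructureModel}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = as.vector(t(model$xyz)),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resid, eleno = a$eleno, elety = a$elety,
                   chain = a$chain, insert = ifelse(a$insert == "", NA,
                                                    a$insert),
                   elesy = a$elesy)
  invisible(path)
}

#' Construct a trajectory ensemble
#'
#' @param coords numeric array \code{[n_atoms, 3, n_frames]}, Angstrom.
#' @param times_ns strictly increasing frame times in ns.
#' @param topology the \code{StructureModel} the frames refer to.
#' @return Object of class \code{TrajectoryEnsemble}.
#' @export
trajectory_ensemble <- function(coords, times_ns, topology) {
  stopifnot(inherits(topology, "StructureModel"), length(dim(coords)) == 3,
            dim(coords)[2] == 3)
  if (dim(coords)[1] != n_atoms(topology))
    stop("frame atom count (", dim(coords)[1],
         ") does not match topology atom count (", n_atoms(topology), ")")
  if (length(times_ns) != dim(coords)[3])
    stop("timestamps length does not match frame count")
  if (any(diff(times_ns) <= 0))
    stop("timestamps must be strictly increasing")
  structure(list(coords = coords, times_ns = as.numeric(times_ns),
                 topology = topology),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms, %.3g-%.3g ns\n",
              n_frames(x), n_atoms(x), min(x$times_ns), max(x$times_ns)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param traj A \code{TrajectoryEnsemble}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Wrap a static structure as a single-frame ensemble
#' @param model A \code{StructureModel}.
#' @return A one-frame \code{TrajectoryEnsemble} at t = 0.
#' @export
as_trajectory <- function(model) {
  stopifnot(inherits(model, "StructureModel"))
  trajectory_ensemble(array(model$xyz, dim = c(nrow(model$xyz), 3, 1)),
                      0, model)
}

#' Subset frames of an ensemble
#' @param traj A \code{TrajectoryEnsemble}.
#' @param idx Frame indices to keep (in order).
#' @return A \code{TrajectoryEnsemble} with the selected frames.
#' @export
subset_frames <- function(traj, idx) {
  trajectory_ensemble(traj$coords[, , idx, drop = FALSE],
                      traj$times_ns[idx], traj$topology)
}

#' Load a coordinate trajectory
#'
#' Supports binary DCD (via bio3d) and plain-text multi-MODEL PDB
#' trajectories. DCD carries no time metadata, so frame times default to a
#' 1 ns stride starting at 0 unless \code{times_ns} is given.
#'
#' @param path Trajectory file (\code{.dcd} or multi-MODEL \code{.pdb}).
#' @param topology \code{StructureModel} with matching atom count.
#' @param stride_ns Time per frame in ns when the format has no time
#'   metadata.
#' @param times_ns Optional explicit per-frame times (overrides
#'   \code{stride_ns}).
#' @return A \code{TrajectoryEnsemble}.
#' @export
load_trajectory <- function(path, topology, stride_ns = 1, times_ns = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xtc", "trr"))
    stop("XTC/TRR reading is not supported; convert to DCD or multi-MODEL PDB")
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else stop("unsupported trajectory format: .", ext)
  nat <- ncol(xyz) / 3
  if (nat != n_atoms(topology))
    stop("trajectory atom count (", nat, ") does not match topology (",
         n_atoms(topology), ")")
  nf <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3, nat, nf)), c(2, 1, 3))
  if (is.null(times_ns)) times_ns <- (seq_len(nf) - 1) * stride_ns
  trajectory_ensemble(coords, times_ns, topology)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' Plain-text fixture writer; each frame becomes one MODEL block.
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "TrajectoryEnsemble"))
  a <- traj$topology$atoms
  nf <- n_frames(traj)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- traj$coords[, , k]
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$eleno, format_atom_name(a$elety), a$resid, a$chain, a$resno,
      ifelse(a$insert == "", " ", a$insert),
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$elesy)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# PDB column-13 convention: names of <4 chars start in column 14
format_atom_name <- function(x) {
  ifelse(nchar(x) >= 4, substr(x, 1, 4), paste0(" ", formatC(x, width = -3)))
}

#' Construct a metadynamics hill series
#'
#' One record per deposited Gaussian of a well-tempered metadynamics run:
#' deposition time (ps), per-CV centers and widths (degrees for dihedral
#' CVs), the already-tempered height (kcal/mol), and the bias factor gamma.
#'
#' @param times Deposition times, ps, non-decreasing within a walker.
#' @param centers matrix \code{[n_hills, n_cv]} of hill centers.
#' @param sigmas matrix \code{[n_hills, n_cv]} of Gaussian widths, all > 0.
#' @param heights deposited heights in kcal/mol, all > 0.
#' @param bias_factor gamma > 1.
#' @param cv_names character names of the collective variables.
#' @param cv_periods per-CV period (360 for dihedrals; \code{NA} for
#'   non-periodic CVs).
#' @param walker_id integer walker label (scalar or per-hill).
#' @return Object of class \code{HillSeries}.
#' @export
hill_series <- function(times, centers, sigmas, heights, bias_factor,
                        cv_names, cv_periods = NULL, walker_id = 1L) {
  centers <- as.matrix(centers)
  sigmas <- as.matrix(sigmas)
  n <- length(times)
  d <- ncol(centers)
  stopifnot(nrow(centers) == n, nrow(sigmas) == n, length(heights) == n,
            length(cv_names) == d)
  if (is.null(cv_periods)) cv_periods <- rep(360, d)
  if (n > 0) {
    if (any(heights <= 0)) stop("hill heights must be > 0")
    if (any(sigmas <= 0)) stop("hill widths must be > 0")
  }
  if (bias_factor <= 1) stop("bias factor gamma must be > 1")
  walker_id <- as.integer(walker_id)
  if (length(walker_id) == 1) walker_id <- rep(walker_id, n)
  for (w in unique(walker_id)) {
    tw <- times[walker_id == w]
    if (length(tw) > 1 && any(diff(tw) < 0))
      stop("hill times must be non-decreasing within walker ", w)
  }
  structure(list(times = as.numeric(times), centers = centers,
                 sigmas = sigmas, heights = as.numeric(heights),
                 bias_factor = bias_factor, cv_names = cv_names,
                 cv_periods = cv_periods, walker_id = walker_id),
            class = "HillSeries")
}

#' @export
print.HillSeries <- function(x, ...) {
  cat(sprintf("HillSeries: %d hills, CVs [%s], gamma = %g, %d walker(s)\n",
              length(x$times), paste(x$cv_names, collapse = ", "),
              x$bias_factor, length(unique(x$walker_id))))
  invisible(x)
}

#' @export
length.HillSeries <- function(x) length(x$times)

#' Write a hill series in PLUMED-style HILLS format
#'
#' @param hills A \code{HillSeries}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_hills <- function(hills, path) {
  stopifnot(inherits(hills, "HillSeries"))
  d <- length(hills$cv_names)
  hdr <- paste("#! FIELDS time", paste(hills$cv_names, collapse = " "),
               paste(paste0("sigma_", hills$cv_names), collapse = " "),
               "height biasf")
  tab <- cbind(hills$times, hills$centers, hills$sigmas, hills$heights,
               rep(hills$bias_factor, length(hills$times)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(tab) > 0)
    writeLines(apply(format(tab, digits = 10, scientific = FALSE,
                            trim = TRUE), 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a PLUMED-style HILLS file
#'
#' Expects a \code{#! FIELDS time <cv...> sigma_<cv...> height biasf}
#' header followed by whitespace-separated rows. Dihedral CVs (names
#' starting with \code{phi} or \code{psi}) get a 360-degree period.
#'
#' @param path HILLS file.
#' @param walker_id Walker label to attach (default parsed from a trailing
#'   integer in the filename, else 1).
#' @return A \code{HillSeries}.
#' @export
read_hills <- function(path, walker_id = NULL) {
  parsed <- read_plumed_table(path)
  if (is.null(walker_id)) {
    m <- regmatches(basename(path),
                    regexpr("[0-9]+(?=\\.[A-Za-z]+$|$)", basename(path),
                            perl = TRUE))
    walker_id <- if (length(m)) as.integer(m) else 1L
  }
  fields <- parsed$fields
  if (fields[1] != "time" || !("height" %in% fields) ||
      !("biasf" %in% fields))
    stop("not a HILLS header in ", path, ": ",
         paste(fields, collapse = " "))
  sig <- grep("^sigma_", fields)
  cvcols <- setdiff(seq_along(fields),
                    c(1, sig, match(c("height", "biasf"), fields)))
  cvn <- fields[cvcols]
  tab <- parsed$table
  if (nrow(tab) == 0) {
    warning("empty HILLS file: ", path)
    return(hill_series(numeric(0), matrix(numeric(0), 0, length(cvn)),
                       matrix(numeric(0), 0, length(cvn)), numeric(0),
                       bias_factor = 10, cv_names = cvn,
                       walker_id = walker_id))
  }
  gamma <- unique(tab[, match("biasf", fields)])
  if (length(gamma) != 1)
    stop("multiple bias factors within one HILLS file: ",
         paste(gamma, collapse = ", "))
  hill_series(times = tab[, 1],
              centers = tab[, cvcols, drop = FALSE],
              sigmas = tab[, sig, drop = FALSE],
              heights = tab[, match("height", fields)],
              bias_factor = gamma, cv_names = cvn,
              cv_periods = ifelse(grepl("^(phi|psi)", cvn), 360, NA),
              walker_id = walker_id)
}

#' Construct a collective-variable time series
#'
#' @param times Frame times in ns, non-decreasing.
#' @param values Named list or data.frame of equal-length numeric columns.
#' @return Object of class \code{CollectiveVariableSeries} (a data.frame
#'   with a \code{time} column first).
#' @export
colvar_series <- function(times, values) {
  values <- as.data.frame(values)
  if (nrow(values) != length(times))
    stop("CV columns and times differ in length")
  if (length(times) > 1 && any(diff(times) < 0))
    stop("times must be non-decreasing")
  out <- cbind(data.frame(time = as.numeric(times)), values)
  class(out) <- c("CollectiveVariableSeries", "data.frame")
  out
}

#' Write a COLVAR-style file
#' @param cvs A \code{CollectiveVariableSeries}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_colvar <- function(cvs, path) {
  hdr <- paste("#! FIELDS", paste(names(cvs), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(cvs) > 0)
    writeLines(apply(format(as.matrix(cvs), digits = 12,
                            scientific = FALSE, trim = TRUE),
                     1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a COLVAR-style file
#' @param path COLVAR file with a \code{#! FIELDS} header.
#' @return A \code{CollectiveVariableSeries}.
#' @export
read_colvar <- function(path) {
  parsed <- read_plumed_table(path)
  fields <- parsed$fields
  if (fields[1] != "time") stop("first COLVAR field must be time in ", path)
  tab <- parsed$table
  if (nrow(tab) == 0) {
    warning("empty COLVAR file: ", path)
    tab <- matrix(numeric(0), 0, length(fields))
  }
  vals <- as.data.frame(tab[, -1, drop = FALSE])
  names(vals) <- fields[-1]
  colvar_series(tab[, 1], vals)
}

# Shared PLUMED-dialect reader: "#! FIELDS ..." header, whitespace rows,
# '#' comments. Errors carry the 1-based data-row index.
read_plumed_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (length(hdr) == 0) stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", hdr[1]), "\\s+")[[1]]
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) == 0)
    return(list(fields = fields,
                table = matrix(numeric(0), 0, length(fields))))
  toks <- strsplit(trimws(data_lines), "\\s+")
  ncols <- lengths(toks)
  bad <- which(ncols != length(fields))
  if (length(bad))
    stop("row ", bad[1], " of ", path, " has ", ncols[bad[1]],
         " columns, expected ", length(fields))
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  nabad <- which(is.na(vals))
  if (length(nabad))
    stop("non-numeric token in row ", ceiling(nabad[1] / length(fields)),
         " of ", path)
  list(fields = fields,
       table = matrix(vals, ncol = length(fields), byrow = TRUE,
                      dimnames = list(NULL, fields)))
}
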