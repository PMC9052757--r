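# Synthetic-data generators: analytic periodic multi-well model potentials,
# overdamped Langevin and multi-walker well-tempered metadynamics sampling
# (C++ core), binding-distance traces, and correlated pseudo-C-alpha
# ensembles with a planted inter-subunit communication path. All generators
# are seed-deterministic.

#' Construct an analytic periodic model potential
#'
#' U(s) = -scale * ln(offset + sum_i a_i K_i(s)) with von-Mises-like
#' periodic Gaussian wells K_i(s) = prod_d exp(kappa_id (cos(s_d - c_id)
#' - 1)) (angles in degrees, energies kcal/mol). Minima and all pairwise
#' basin-to-basin barriers are located at construction by dense-grid
#' (0.5 degree) minimax-path refinement and stored on the object.
#'
#' @param centers Matrix \code{[n_wells, dim]} of well centers, degrees.
#' @param kappa Matrix of concentration parameters (width ~
#'   \code{(180/pi)/sqrt(kappa)} degrees).
#' @param amplitudes Positive well amplitudes (relative Boltzmann-like
#'   weights inside the log).
#' @param offset Positive background constant inside the log.
#' @param scale Energy scale in kcal/mol.
#' @param well_names Optional names of the first wells that are genuine
#'   basins (auxiliary "bridge" wells that only shape saddles are left
#'   unnamed and get no barrier entry).
#' @param resolution Dense-grid resolution (degrees) for minima/saddle
#'   refinement.
#' @return A \code{ModelPotential} with \code{minima} (data.frame) and
#'   \code{barriers} (data.frame from/to/barrier_kcal/saddle).
#' @export
model_potential <- function(centers, kappa, amplitudes, offset = 0.02,
                            scale = 1, well_names = NULL,
                            resolution = 0.5) {
  centers <- as.matrix(centers)
  kappa <- as.matrix(kappa)
  d <- ncol(centers)
  stopifnot(d %in% c(1, 2), all(amplitudes > 0), offset > 0, scale > 0,
            all(dim(kappa) == dim(centers)))
  pot <- structure(list(dim = d, centers = centers, kappa = kappa,
                        amplitudes = as.numeric(amplitudes),
                        offset = offset, scale = scale,
                        well_names = well_names),
                   class = "ModelPotential")
  if (!is.null(well_names)) {
    ref <- dense_grid_landscape(pot, resolution)
    nb <- length(well_names)
    minima <- data.frame(name = well_names,
                         matrix(NA_real_, nb, d), value = NA_real_)
    names(minima)[1 + seq_len(d)] <- paste0("s", seq_len(d))
    regions <- vector("list", nb)
    for (i in seq_len(nb)) {
      reg <- lapply(seq_len(d), function(dd)
        wrap_angle(centers[i, dd] + c(-30, 30)))
      regions[[i]] <- reg
      idx <- region_bins(ref, reg)
      jmin <- idx[which.min(ref$values[idx])]
      loc <- arrayInd(jmin, dim(ref$values))
      for (dd in seq_len(d))
        minima[i, 1 + dd] <- ref$centers[[dd]][loc[dd]]
      minima$value[i] <- ref$values[jmin]
    }
    pairs <- utils::combn(nb, 2)
    bars <- data.frame(from = character(0), to = character(0),
                       barrier_kcal = numeric(0))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      b <- barrier_between(ref, regions[[i]], regions[[j]])
      bars <- rbind(bars,
                    data.frame(from = well_names[i], to = well_names[j],
                               barrier_kcal = b$pass - minima$value[i]),
                    data.frame(from = well_names[j], to = well_names[i],
                               barrier_kcal = b$pass - minima$value[j]))
    }
    pot$minima <- minima
    pot$barriers <- bars
  }
  pot
}

# evaluate the potential on a dense periodic grid, returned as a
# min-shifted LandscapeGrid (used for construction-time refinement)
dense_grid_landscape <- function(pot, resolution = 0.5,
                                 temperature = 300) {
  bins <- round(360 / resolution)
  gx <- periodic_bin_centers(bins)
  if (pot$dim == 2) {
    pts <- as.matrix(expand.grid(gx, gx))
    U <- matrix(potential_value_cpp(pot, pts), bins, bins)
  } else {
    U <- matrix(potential_value_cpp(pot, matrix(gx, ncol = 1)), ncol = 1)
  }
  landscape_grid(U, rep(list(gx), pot$dim),
                 cv_names = paste0("s", seq_len(pot$dim)),
                 temperature = temperature, min_shift = TRUE)
}

#' @export
print.ModelPotential <- function(x, ...) {
  cat(sprintf("ModelPotential: %dD, %d wells, scale %g kcal/mol\n",
              x$dim, nrow(x$centers), x$scale))
  if (!is.null(x$barriers)) {
    cat("Stored barriers (kcal/mol):\n")
    print(x$barriers, row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a model potential
#' @param pot A \code{ModelPotential}.
#' @param s Numeric vector (one point) or matrix of points (degrees).
#' @return Potential values in kcal/mol.
#' @export
potential_value <- function(pot, s) {
  if (is.null(dim(s))) s <- matrix(s, ncol = pot$dim)
  potential_value_cpp(pot, as.matrix(s))
}

#' Analytic gradient of a model potential
#' @param pot A \code{ModelPotential}.
#' @param s Point(s), degrees.
#' @return Gradient matrix, kcal/mol/degree.
#' @export
potential_gradient <- function(pot, s) {
  if (is.null(dim(s))) s <- matrix(s, ncol = pot$dim)
  potential_gradient_cpp(pot, as.matrix(s))
}

#' Three-basin model of the oxyanion-strand landscape
#'
#' 2D periodic potential with basins at (-130, -70) "inactive-OxH",
#' (-130, 60) "unblocked-OxH" and (60, 60) "active-OxH", mimicking the
#' basin topology of the dihedral conformational landscape. Two shallow
#' bridge wells shape the passes so the default inter-basin barriers are
#' 4 kT and 8 kT at 300 K (inactive <-> unblocked, and unblocked <->
#' active, respectively); the exact dense-grid values are recorded in
#' \code{$barriers}.
#'
#' @param temperature Kelvin used to express the nominal kT (default 300).
#' @return A \code{ModelPotential}.
#' @export
make_triple_well <- function(temperature = 300) {
  # main wells (equal depth) + two bridge wells at the passes; bridge
  # amplitudes calibrated once against the dense-grid barriers so that
  # barrier(inactive<->unblocked) = 4 kT and barrier(unblocked<->active)
  # = 8 kT at 300 K
  centers <- rbind(c(-130, -70), c(-130, 60), c(60, 60),
                   c(-130, -5), c(145, 60))
  kappa <- rbind(c(8.2, 8.2), c(8.2, 8.2), c(8.2, 8.2),
                 c(5.3, 5.3), c(5.3, 5.3))
  amplitudes <- c(8, 8, 8, TRIPLE_WELL_BRIDGE[1], TRIPLE_WELL_BRIDGE[2])
  model_potential(centers, kappa, amplitudes, offset = 0.02, scale = 1,
                  well_names = c("inactive-OxH", "unblocked-OxH",
                                 "active-OxH"))
}

# bridge amplitudes, calibrated by bisection on the 0.5-degree dense grid
# (see tools in scratch; frozen here)
TRIPLE_WELL_BRIDGE <- c(0.580664, 0.039091)

#' Symmetric 1D double well with a 4 kT barrier
#'
#' Minima at -60 and 60 degrees; the stored barrier (close to 4 kT at
#' 300 K) is recorded on the object.
#'
#' @return A 1D \code{ModelPotential}.
#' @export
make_double_well <- function() {
  model_potential(centers = cbind(c(-60, 60)), kappa = cbind(c(8.2, 8.2)),
                  amplitudes = c(DOUBLE_WELL_AMP, DOUBLE_WELL_AMP),
                  offset = 0.02, scale = 1, well_names = c("left", "right"))
}

DOUBLE_WELL_AMP <- 0.307986

#' Overdamped Langevin sampling of a model potential
#'
#' Update s <- s - (D/kT) grad U dt + sqrt(2 D dt) eta, with periodic wrap
#' into (-180, 180]. Deterministic given the seed.
#'
#' @param pot A \code{ModelPotential}.
#' @param kT Thermal energy, kcal/mol (default kT at 300 K).
#' @param diffusion Diffusion coefficient, degrees^2/ns.
#' @param dt Timestep, ns.
#' @param nsteps Number of steps.
#' @param init Initial point, degrees (default: first stored minimum, or
#'   the first well center).
#' @param seed RNG seed.
#' @param record_stride Record every this many steps (default 10).
#' @return A \code{CollectiveVariableSeries} with columns s1 (, s2).
#' @export
langevin_sample <- function(pot, kT = kT_kcal(300), diffusion = 1500,
                            dt = 0.002, nsteps = 1e5, init = NULL,
                            seed = 1, record_stride = 10) {
  stopifnot(inherits(pot, "ModelPotential"), kT > 0, diffusion > 0,
            dt > 0, nsteps >= 1)
  init <- default_init(pot, init)
  set.seed(seed)
  out <- langevin_cpp(pot, init, kT, diffusion, dt, as.integer(nsteps),
                      as.integer(record_stride))
  vals <- as.data.frame(out)
  names(vals) <- paste0("s", seq_len(pot$dim))
  colvar_series((seq_len(nrow(out)) - 1) * dt * record_stride, vals)
}

default_init <- function(pot, init) {
  if (!is.null(init)) return(as.numeric(init))
  if (!is.null(pot$minima))
    return(as.numeric(pot$minima[1, 1 + seq_len(pot$dim)]))
  as.numeric(pot$centers[1, ])
}

#' Multi-walker well-tempered metadynamics sampling
#'
#' All walkers share one bias potential (multiple-walkers scheme) and
#' advance in lockstep; every \code{pace} steps each walker deposits a
#' Gaussian hill of tempered height h0 exp(-V(s) / ((gamma - 1) kT)) at
#' its current position. The bias and its gradient are accumulated on a
#' fine internal grid with analytic per-hill updates. The default hill
#' parameters (h0 = 0.5 kcal/mol, sigma = 10 degrees, pace = 500 steps,
#' gamma = 10) are desk-scale stand-ins.
#'
#' @param pot A \code{ModelPotential}.
#' @param n_walkers Number of walkers (default 10).
#' @param nsteps Steps per walker.
#' @param hill_height h0, kcal/mol.
#' @param hill_sigma Gaussian width, degrees (scalar or per-CV).
#' @param pace Steps between depositions.
#' @param gamma Bias factor (> 1).
#' @param kT,diffusion,dt,seed As in \code{\link{langevin_sample}}.
#' @param inits Matrix \code{[n_walkers, dim]} of starting points;
#'   default: spread over the stored minima.
#' @param bias_grid_n Internal bias grid points per axis (default 180,
#'   i.e. 2-degree spacing).
#' @param record_stride Record walker positions every this many steps.
#' @return List: \code{walkers} (list of \code{CollectiveVariableSeries}),
#'   \code{hills} (list of \code{HillSeries}, one per walker).
#' @export
wtmetad_sample <- function(pot, n_walkers = 10, nsteps = 1e5,
                           hill_height = 0.5, hill_sigma = 10, pace = 500,
                           gamma = 10, kT = kT_kcal(300), diffusion = 1500,
                           dt = 0.002, seed = 1, inits = NULL,
                           bias_grid_n = 180, record_stride = NULL) {
  stopifnot(inherits(pot, "ModelPotential"), gamma > 1, pace >= 1,
            hill_height > 0, all(hill_sigma > 0))
  d <- pot$dim
  sigma <- rep_len(hill_sigma, d)
  if (is.null(record_stride)) record_stride <- pace
  if (is.null(inits)) {
    anchors <- if (!is.null(pot$minima))
      as.matrix(pot$minima[, 1 + seq_len(d), drop = FALSE])
    else pot$centers[, seq_len(d), drop = FALSE]
    inits <- anchors[rep_len(seq_len(nrow(anchors)), n_walkers), ,
                     drop = FALSE]
  }
  inits <- as.matrix(inits)
  stopifnot(nrow(inits) == n_walkers, ncol(inits) == d)
  set.seed(seed)
  out <- wtmetad_cpp(pot, inits, kT, diffusion, dt, as.integer(nsteps),
                     as.integer(pace), hill_height, sigma, gamma,
                     as.integer(bias_grid_n), as.integer(record_stride))
  cv_names <- paste0("phi", seq_len(d))
  walkers <- lapply(out$walkers, function(m) {
    vals <- as.data.frame(m)
    names(vals) <- cv_names
    colvar_series((seq_len(nrow(m)) - 1) * dt * record_stride, vals)
  })
  h <- out$hills
  hills <- lapply(seq_len(n_walkers), function(w) {
    rows <- which(h[, 2 * d + 3] == w)
    hill_series(times = h[rows, 1],
                centers = h[rows, 1 + seq_len(d), drop = FALSE],
                sigmas = h[rows, 1 + d + seq_len(d), drop = FALSE],
                heights = h[rows, 2 * d + 2],
                bias_factor = gamma, cv_names = cv_names,
                cv_periods = rep(360, d), walker_id = w)
  })
  list(walkers = walkers, hills = hills)
}

#' Direct Boltzmann sampling of a model potential
#'
#' Draws i.i.d. CV samples from P(s) proportional to exp(-U(s)/kT),
#' discretized on a dense periodic grid with uniform jitter inside each
#' cell. Bypasses dynamics entirely, so populations are exact up to
#' multinomial noise.
#'
#' @param pot A \code{ModelPotential}.
#' @param n Number of samples.
#' @param temperature Kelvin.
#' @param seed RNG seed.
#' @param resolution Grid resolution in degrees (default 0.5).
#' @return Matrix \code{[n, dim]} of CV samples in degrees.
#' @export
boltzmann_sample <- function(pot, n, temperature = 300, seed = 1,
                             resolution = 0.5) {
  stopifnot(inherits(pot, "ModelPotential"), n >= 1)
  kT <- kT_kcal(temperature)
  bins <- round(360 / resolution)
  gx <- periodic_bin_centers(bins)
  pts <- if (pot$dim == 2) as.matrix(expand.grid(gx, gx))
         else matrix(gx, ncol = 1)
  U <- potential_value_cpp(pot, pts)
  w <- exp(-(U - min(U)) / kT)
  set.seed(seed)
  idx <- sample.int(nrow(pts), n, replace = TRUE, prob = w)
  jitter <- matrix(runif(n * pot$dim, -resolution / 2, resolution / 2),
                   n, pot$dim)
  s <- pts[idx, , drop = FALSE] + jitter
  wrap_angle(s)
}

#' Specification for a planted-network pseudo-C-alpha ensemble
#'
#' Two subunits, each a planar grid of pseudo-C-alpha sites (3.8 A spacing
#' within a row, 5 A between rows and across the inter-subunit gap, so a
#' 6 A contact cutoff yields a grid contact graph with a few crossing
#' edges). A planted communication path runs along one row from subunit A
#' into subunit B; consecutive path residues have displacement correlation
#' \code{rho_path}, all other pairs decay from \code{rho_bg} with
#' distance.
#'
#' @param ncol_per_subunit,nrow_grid Grid size per subunit (default 8 x 4,
#'   i.e. 32 residues per subunit).
#' @param path_row Row carrying the planted path (default 2).
#' @param path_half_length Residues of the path in each subunit (default
#'   4, i.e. |path| = 8 nodes / 7 edges).
#' @param rho_path,rho_bg Planted and background correlations
#'   (\code{rho_bg < rho_path <= 1}).
#' @param amplitude Per-residue RMS fluctuation, Angstrom.
#' @param n_frames Ensemble size.
#' @param decay_length Background distance-decay length, Angstrom.
#' @return A \code{PlantedNetworkSpec}.
#' @export
planted_network_spec <- function(ncol_per_subunit = 8, nrow_grid = 4,
                                 path_row = 2, path_half_length = 4,
                                 rho_path = 0.9, rho_bg = 0.1,
                                 amplitude = 0.5, n_frames = 5000,
                                 decay_length = 8) {
  stopifnot(rho_bg < rho_path, rho_path <= 1, amplitude > 0,
            n_frames >= 10, path_half_length <= ncol_per_subunit,
            path_row <= nrow_grid)
  structure(list(ncol_per_subunit = ncol_per_subunit,
                 nrow_grid = nrow_grid, path_row = path_row,
                 path_half_length = path_half_length, rho_path = rho_path,
                 rho_bg = rho_bg, amplitude = amplitude,
                 n_frames = n_frames, decay_length = decay_length),
            class = "PlantedNetworkSpec")
}

# backbone layout + path bookkeeping shared by the generator and tests
planted_geometry <- function(spec) {
  nc <- spec$ncol_per_subunit
  nr <- spec$nrow_grid
  pos <- NULL
  chain <- character(0)
  gap <- 5.0
  for (su in 1:2) {
    x0 <- (su - 1) * ((nc - 1) * 3.8 + gap)
    g <- expand.grid(col = seq_len(nc), row = seq_len(nr))
    pos <- rbind(pos, cbind(x0 + (g$col - 1) * 3.8, (g$row - 1) * 5.0, 0))
    chain <- c(chain, rep(c("A", "B")[su], nc * nr))
  }
  # residue index of (subunit, row, col); atoms ordered col-fastest
  ridx <- function(su, row, col) (su - 1) * nc * nr + (row - 1) * nc + col
  hl <- spec$path_half_length
  path <- c(ridx(1, spec$path_row, (nc - hl + 1):nc),
            ridx(2, spec$path_row, 1:hl))
  list(pos = pos, chain = chain, path = path,
       cross_edge = c(ridx(1, spec$path_row, nc), ridx(2, spec$path_row, 1)))
}

#' Generate a planted-network pseudo-C-alpha ensemble
#'
#' Frame displacements are zero-mean Gaussian with identical correlation
#' across the three Cartesian components, so the displacement dot-product
#' correlation matrix equals the target matrix in expectation. The target
#' has \code{rho_path^|i-j|} among path residues (\code{rho_path} between
#' consecutive ones) and a distance-decayed \code{rho_bg} background, and
#' is projected to the nearest positive-semidefinite correlation matrix
#' before sampling.
#'
#' @param spec A \code{PlantedNetworkSpec}.
#' @param seed RNG seed.
#' @param topology_path Optional path: write the pseudo-C-alpha topology
#'   as a PDB file.
#' @return A \code{TrajectoryEnsemble} with attributes
#'   \code{planted_path} (residue indices), \code{planted_edges}
#'   (matrix of consecutive path pairs), \code{cross_edge} (the
#'   inter-subunit pair) and \code{target_correlation}.
#' @export
planted_ensemble <- function(spec = planted_network_spec(), seed = 1,
                             topology_path = NULL) {
  stopifnot(inherits(spec, "PlantedNetworkSpec"))
  geo <- planted_geometry(spec)
  n <- nrow(geo$pos)
  R <- target_correlation(spec, geo)
  set.seed(seed)
  L <- chol(R)
  nf <- spec$n_frames
  coords <- array(0, dim = c(n, 3, nf))
  for (c3 in 1:3) {
    z <- matrix(rnorm(nf * n), nf, n) %*% L  # frames x residues
    for (k in seq_len(nf))
      coords[, c3, k] <- geo$pos[, c3] + spec$amplitude * z[k, ]
  }
  atoms <- data.frame(eleno = seq_len(n), elety = "CA", resid = "ALA",
                      chain = geo$chain,
                      resno = stats::ave(seq_len(n), geo$chain,
                                         FUN = seq_along),
                      insert = "", elesy = "C", stringsAsFactors = FALSE)
  topo <- structure_model(atoms, geo$pos,
                          subunit_map = c(A = "SubA", B = "SubB"))
  if (!is.null(topology_path)) write_structure(topo, topology_path)
  traj <- trajectory_ensemble(coords, seq_len(nf) - 1, topo)
  attr(traj, "planted_path") <- geo$path
  attr(traj, "planted_edges") <- cbind(geo$path[-length(geo$path)],
                                       geo$path[-1])
  attr(traj, "cross_edge") <- geo$cross_edge
  attr(traj, "target_correlation") <- R
  traj
}

target_correlation <- function(spec, geo) {
  n <- nrow(geo$pos)
  dm <- as.matrix(stats::dist(geo$pos))
  R <- spec$rho_bg * exp(-pmax(dm - 3.8, 0) / spec$decay_length)
  p <- geo$path
  for (i in seq_along(p))
    for (j in seq_along(p))
      if (i != j)
        R[p[i], p[j]] <- max(R[p[i], p[j]], spec$rho_path^abs(i - j))
  diag(R) <- 1
  nearest_psd_correlation(R)
}

# clip negative eigenvalues and renormalize to unit diagonal
nearest_psd_correlation <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -0.5)
    stop("target correlation too far from positive semidefinite")
  vals <- pmax(e$values, tol)
  R2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  D <- 1 / sqrt(diag(R2))
  R2 <- R2 * outer(D, D)
  (R2 + t(R2)) / 2
}

#' Synthetic substrate-binding distance trace
#'
#' Builds a noisy piecewise d_nuc series realizing a schedule of binding
#' phases, with per-phase target distances inside the published bands
#' (unbound > 12 A, recognition 6-12 A, captured 3.5-6 A, catalytic
#' < 3.5 A) and Gaussian noise (sigma 0.3 A). The conformational state is
#' active-OxH during catalytic dwells and inactive-OxH otherwise.
#'
#' @param schedule data.frame with columns \code{phase} (one of unbound /
#'   recognition / captured / catalytic) and \code{frames}, in order. A
#'   captured or catalytic dwell must be preceded by a recognition dwell
#'   since the last unbound stretch.
#' @param seed RNG seed.
#' @param noise_sd Noise standard deviation, Angstrom.
#' @param dt_ns Time per frame.
#' @return List: \code{d_nuc} (\code{ObservableSeries}), \code{states}
#'   (character labels), \code{schedule}.
#' @export
binding_trace <- function(schedule, seed = 1, noise_sd = 0.3, dt_ns = 0.1) {
  targets <- c(unbound = 14, recognition = 9, captured = 4.8,
               catalytic = 2.8)
  if (is.null(schedule) || nrow(as.data.frame(schedule)) == 0) {
    return(list(d_nuc = observable_series("d_nuc", numeric(0), "angstrom",
                                          numeric(0)),
                states = character(0), schedule = schedule))
  }
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("phase", "frames") %in% names(schedule)))
  if (!all(schedule$phase %in% names(targets)))
    stop("unknown phase in schedule: ",
         paste(setdiff(schedule$phase, names(targets)), collapse = ", "))
  seen_recognition <- FALSE
  for (ph in schedule$phase) {
    if (ph == "unbound") seen_recognition <- FALSE
    if (ph == "recognition") seen_recognition <- TRUE
    if (ph %in% c("captured", "catalytic") && !seen_recognition)
      stop("infeasible schedule: '", ph,
           "' before any recognition dwell")
  }
  set.seed(seed)
  d <- unlist(mapply(function(ph, nfr) {
    pmax(targets[ph] + rnorm(nfr, 0, noise_sd), 0)
  }, schedule$phase, schedule$frames, SIMPLIFY = FALSE))
  states <- unlist(mapply(function(ph, nfr) {
    rep(if (ph == "catalytic") "active-OxH" else "inactive-OxH", nfr)
  }, schedule$phase, schedule$frames, SIMPLIFY = FALSE))
  times <- (seq_along(d) - 1) * dt_ns
  list(d_nuc = observable_series("d_nuc", as.numeric(d), "angstrom", times),
       states = as.character(states), schedule = schedule)
}
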