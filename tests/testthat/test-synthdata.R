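test_that("the triple well stores self-consistent minima and barriers", {
  pot <- make_triple_well()
  # each declared center is the local minimum of its 5-degree neighborhood
  for (i in 1:3) {
    ctr <- as.numeric(pot$minima[i, c("s1", "s2")])
    nb <- as.matrix(expand.grid(ctr[1] + seq(-5, 5, by = 1),
                                ctr[2] + seq(-5, 5, by = 1)))
    vals <- potential_value(pot, nb)
    expect_equal(potential_value(pot, ctr), min(vals), tolerance = 1e-9)
  }
  # 360-degree periodicity
  s <- cbind(runif(20, -180, 180), runif(20, -180, 180))
  expect_equal(potential_value(pot, s),
               potential_value(pot, s + 360), tolerance = 1e-12)
  # stored barriers equal barrier_between() on the dense analytic grid
  ref <- allostate:::dense_grid_landscape(pot, 0.5)
  b <- barrier_between(ref, list(c(-160, -100), c(-100, -40)),
                       list(c(-160, -100), c(30, 90)))
  stored <- pot$barriers$barrier_kcal[
    pot$barriers$from == "inactive-OxH" &
      pot$barriers$to == "unblocked-OxH"]
  expect_equal(b$barrier, stored, tolerance = 1e-9)
  # nominal design values: 4 kT and 8 kT at 300 K
  kT <- kT_kcal(300)
  expect_equal(stored, 4 * kT, tolerance = 1e-3)
  high <- pot$barriers$barrier_kcal[
    pot$barriers$from == "unblocked-OxH" & pot$barriers$to == "active-OxH"]
  expect_equal(high, 8 * kT, tolerance = 1e-3)
})

test_that("analytic gradients match finite differences", {
  pot <- make_triple_well()
  set.seed(12)
  s <- cbind(runif(10, -180, 180), runif(10, -180, 180))
  g <- potential_gradient(pot, s)
  eps <- 1e-5
  for (d in 1:2) {
    sp <- s
    sm <- s
    sp[, d] <- sp[, d] + eps
    sm[, d] <- sm[, d] - eps
    fd <- (potential_value(pot, sp) - potential_value(pot, sm)) / (2 * eps)
    expect_equal(g[, d], fd, tolerance = 1e-6)
  }
})

test_that("Langevin sampling is deterministic and physically consistent", {
  pot <- make_triple_well()
  # near-zero-noise limit stays at the minimum (diffusion scaled with kT
  # as in the Einstein relation, so the drift stays resolvable)
  cold <- langevin_sample(pot, kT = 0.01, diffusion = 1, dt = 1e-4,
                          nsteps = 2000, seed = 3, record_stride = 100)
  start <- as.numeric(pot$minima[1, c("s1", "s2")])
  expect_true(max(abs(cold$s1 - start[1])) < 1)
  expect_true(max(abs(cold$s2 - start[2])) < 1)

  # same seed gives bit-identical output
  a <- langevin_sample(pot, nsteps = 5000, seed = 42)
  b <- langevin_sample(pot, nsteps = 5000, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, langevin_sample(pot, nsteps = 5000, seed = 43)))

  # near-harmonic 1D well: long-run variance = kT / k_eff
  kT <- kT_kcal(300)
  kappa <- 30
  hw <- model_potential(centers = cbind(0), kappa = cbind(kappa),
                        amplitudes = 1, offset = 1e-8, scale = 1)
  k_eff <- kappa * (pi / 180)^2  # kcal/mol/deg^2 curvature at the bottom
  cv <- langevin_sample(hw, kT = kT, nsteps = 4e5, dt = 0.001,
                        diffusion = 1500, init = 0, seed = 9,
                        record_stride = 20)
  v <- stats::var(cv$s1)
  batches <- split(cv$s1[1:20000], rep(1:20, each = 1000))
  bv <- vapply(batches, stats::var, numeric(1))
  se <- stats::sd(bv) / sqrt(length(bv))
  expect_true(abs(v - kT / k_eff) < 3 * se + 0.02 * kT / k_eff)

  # too-large timestep triggers the drift guard
  expect_error(langevin_sample(hw, kT = 0.01, dt = 50, nsteps = 100,
                               init = 90, seed = 1), "reduce dt")
})

test_that("Langevin populations match Boltzmann weights of the basins", {
  pot <- make_triple_well()
  kT <- kT_kcal(300)
  # analytic weights by dense integration, classified by the state boxes
  gx <- periodic_bin_centers_test(360)
  pts <- as.matrix(expand.grid(gx, gx))
  U <- potential_value(pot, pts)
  w <- exp(-(U - min(U)) / kT)
  lab <- classify_states(pts[, 1], pts[, 2])$labels
  w_state <- tapply(w, lab, sum)
  w_state <- w_state / sum(w_state)

  cv <- langevin_sample(pot, nsteps = 5e7, seed = 5, record_stride = 50)
  st <- classify_states(cv$s1, cv$s2)
  emp <- table(factor(st$labels, levels = names(w_state)))
  emp <- emp / sum(emp)
  # per-state effective sample size: number of genuine visits (runs after
  # blip merging), since successive frames are strongly correlated
  seg <- dwell_segments(st$labels, min_dwell_frames = 10)$segments
  for (s in c("inactive-OxH", "unblocked-OxH", "active-OxH")) {
    n_eff <- max(4, sum(seg$state == s))
    sigma <- sqrt(w_state[s] * (1 - w_state[s]) / n_eff)
    expect_true(abs(emp[s] - w_state[s]) < 3 * sigma,
                label = sprintf("%s: |%.3f - %.3f| < 3*%.3f", s, emp[s],
                                w_state[s], sigma))
  }
})

test_that("well-tempered deposition follows the tempering rule", {
  pot <- make_double_well()
  run <- wtmetad_sample(pot, n_walkers = 1, nsteps = 2e4, pace = 100,
                        gamma = 10, seed = 2)
  h <- run$hills[[1]]
  kT <- kT_kcal(300)
  # first hill is exactly h0 (no bias yet)
  expect_equal(h$heights[1], 0.5, tolerance = 1e-12)
  expect_true(all(h$heights <= 0.5 + 1e-12))
  # reconstruct V just before each deposition from the earlier hills and
  # check h = h0 exp(-V/((gamma-1) kT)) at the deposition point
  for (k in c(5, 50, 150)) {
    prev <- hill_series(h$times[1:(k - 1)],
                        h$centers[1:(k - 1), , drop = FALSE],
                        h$sigmas[1:(k - 1), , drop = FALSE],
                        h$heights[1:(k - 1)], h$bias_factor, h$cv_names)
    dmin <- abs(wrap_angle(h$centers[1:(k - 1), 1] - h$centers[k, 1]))
    V <- sum(prev$heights * exp(-dmin^2 / (2 * prev$sigmas[, 1]^2)))
    expect_equal(h$heights[k], 0.5 * exp(-V / (9 * kT)), tolerance = 0.05)
  }
  # determinism
  run2 <- wtmetad_sample(pot, n_walkers = 1, nsteps = 2e4, pace = 100,
                         gamma = 10, seed = 2)
  expect_identical(run$hills[[1]]$centers, run2$hills[[1]]$centers)
})

test_that("the planted ensemble behaves as specified under the null and signal", {
  # null: path correlation equal to background leaves no dominant edge
  null_spec <- planted_network_spec(rho_path = 0.1001, rho_bg = 0.1,
                                    n_frames = 800)
  tn <- planted_ensemble(null_spec, seed = 30)
  Cn <- correlation_matrix(tn)$values
  pe <- attr(tn, "planted_edges")
  off <- Cn[upper.tri(Cn)]
  expect_true(max(abs(Cn[pe] - mean(off))) < 0.25)

  # signal: planted edges rank in the top |path| widths
  traj <- planted_ensemble(planted_network_spec(), seed = 44)
  res <- spm(correlation_matrix(traj), contact_adjacency(traj, cutoff = 6))
  path <- attr(traj, "planted_path")
  e <- res$edges
  top <- e[order(-e$width)[seq_along(path)], ]
  pe <- attr(traj, "planted_edges")
  hits <- apply(pe, 1, function(p)
    any(top$i == min(p) & top$j == max(p)))
  expect_true(all(hits))

  # scale invariance: doubling the amplitude leaves correlations unchanged
  s1 <- planted_network_spec(n_frames = 1500, amplitude = 0.5)
  s2 <- planted_network_spec(n_frames = 1500, amplitude = 1.0)
  C1 <- correlation_matrix(planted_ensemble(s1, seed = 77))$values
  C2 <- correlation_matrix(planted_ensemble(s2, seed = 77))$values
  expect_true(max(abs(C1 - C2)) < 0.02)

  # determinism and readability of the written topology
  t1 <- planted_ensemble(planted_network_spec(n_frames = 20), seed = 5)
  t2 <- planted_ensemble(planted_network_spec(n_frames = 20), seed = 5)
  expect_identical(t1$coords, t2$coords)
  path_pdb <- withr::local_tempfile(fileext = ".pdb")
  expect_no_warning(planted_ensemble(planted_network_spec(n_frames = 20),
                                     seed = 5, topology_path = path_pdb))
  expect_no_warning(model <- load_structure(path_pdb))
  expect_equal(n_atoms(model), 64)
})

test_that("binding traces realize their schedules", {
  sched <- data.frame(phase = c("unbound", "recognition", "captured",
                                "catalytic"),
                      frames = c(100, 50, 60, 40))
  tr <- binding_trace(sched, seed = 6)
  expect_length(tr$d_nuc$values, 250)
  ph <- classify_binding_phase(tr$d_nuc, tr$states)
  ev <- detect_binding_events(tr$d_nuc, ph, min_capture_frames = 10)
  expect_equal(nrow(ev), 1)
  expect_true(ev$productive)

  # unbound-only schedule stays above threshold at the 3-sigma level
  un <- binding_trace(data.frame(phase = "unbound", frames = 500), seed = 2)
  expect_true(mean(un$d_nuc$values > 12) > 0.99)

  expect_error(binding_trace(data.frame(phase = c("unbound", "catalytic"),
                                        frames = c(10, 10))),
               "infeasible")
  empty <- binding_trace(data.frame(phase = character(0),
                                    frames = numeric(0)))
  expect_length(empty$d_nuc$values, 0)

  # same seed -> identical trace
  expect_identical(binding_trace(sched, seed = 6)$d_nuc$values,
                   tr$d_nuc$values)
})
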