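kT300 <- kT_kcal(300)

test_that("population landscapes obey F = -kT ln P", {
  # two bins with populations p and p/e differ by exactly kT
  x <- c(rep(-90, 2718), rep(90, 1000))
  g <- landscape_from_samples(x, bins = 4, temperature = 300)
  vals <- g$values[!is.na(g$values)]
  expect_equal(diff(range(vals)), kT300 * log(2.718), tolerance = 1e-3)

  # single occupied bin: F = 0 there, everything else masked
  g1 <- landscape_from_samples(rep(10, 100), bins = 36)
  expect_equal(sum(!is.na(g1$values)), 1)
  expect_equal(min(g1$values, na.rm = TRUE), 0)

  # uniform sampling: all bins within multinomial noise of zero
  set.seed(21)
  n <- 1e5
  gu <- landscape_from_samples(cbind(runif(n, -180, 180),
                                     runif(n, -180, 180)), bins = 6)
  p <- 1 / 36
  sigma_F <- kT300 * sqrt((1 - p) / (n * p))  # delta-method on ln count
  expect_true(max(gu$values, na.rm = TRUE) < 6 * sigma_F)

  # duplicating every sample leaves F unchanged
  s <- runif(2000, -180, 180)
  expect_equal(landscape_from_samples(s, bins = 36)$values,
               landscape_from_samples(c(s, s), bins = 36)$values)

  expect_error(landscape_from_samples(numeric(0)), "empty")
})

test_that("marginal profiles are Boltzmann sums, not minima", {
  # separable F(x,y) = f(x) + g(y): marginal equals f + const
  cx <- periodic_bin_centers_test(36)
  f <- 2 * (1 - cos(cx * pi / 180))
  gy <- 0.5 * (1 + sin(cx * pi / 180))
  F2 <- outer(f, rep(1, 36)) + outer(rep(1, 36), gy)
  grid <- landscape_grid(F2, list(cx, cx), temperature = 300)
  m <- marginal_profile(grid, 1)
  expect_equal(m$values[, 1] - min(m$values), f - min(f), tolerance = 1e-9)

  # commutation with direct projection of the samples
  set.seed(4)
  s <- cbind(rnorm(20000, 0, 40), rnorm(20000, 60, 25))
  m2 <- marginal_profile(landscape_from_samples(s, bins = 36), 1)
  direct <- landscape_from_samples(s[, 1], bins = 36)
  ok <- !is.na(m2$values) & !is.na(direct$values)
  expect_true(all(ok == (!is.na(direct$values))))
  expect_equal(m2$values[ok], direct$values[ok], tolerance = 1e-6)

  # a single unmasked row: marginal is that row, min-shifted
  F1 <- matrix(NA_real_, 36, 36)
  F1[7, ] <- f
  g1 <- landscape_grid(F1, list(cx, cx), temperature = 300)
  m1 <- marginal_profile(g1, 2)
  expect_equal(m1$values[, 1], f - min(f), tolerance = 1e-9)
})

test_that("hill sums reproduce single-Gaussian identities", {
  # hill centred exactly on a bin center: V there = h, one sigma away
  # V = h exp(-1/2)
  h <- hill_series(1, cbind(2.5, 2.5), cbind(10, 10), 0.5, 10,
                   c("phi1", "phi2"))
  b <- bias_from_hills(h, bins = 72)
  i0 <- which(b$centers[[1]] == 2.5)
  i1 <- which(b$centers[[1]] == 12.5)
  expect_equal(b$grid[i0, i0], 0.5, tolerance = 1e-12)
  expect_equal(b$grid[i1, i0], 0.5 * exp(-0.5), tolerance = 1e-12)

  # doubling the walker doubles V everywhere
  b2 <- bias_from_hills(list(h, h), bins = 72)
  b1 <- bias_from_hills(h, bins = 72)
  expect_equal(b2$grid, 2 * b1$grid)

  # periodic minimum image: a hill at 175 reaches -172.5 across the wrap
  # exactly as it reaches 162.5 on the near side (both 12.5 deg away)
  hp <- hill_series(1, cbind(175), cbind(10), 1, 10, "phi1")
  bp <- bias_from_hills(hp, bins = 72)
  at <- function(x) bp$grid[which(bp$centers[[1]] == x), 1]
  expect_equal(at(-172.5), at(162.5), tolerance = 1e-12)
  expect_equal(at(-172.5), exp(-12.5^2 / 200), tolerance = 1e-12)

  # mixed gamma across walkers is rejected
  hg <- hill_series(1, cbind(0), cbind(10), 1, 5, "phi1")
  expect_error(bias_from_hills(list(hp, hg)), "bias factor")
})

test_that("the WT-MetaD estimator rescales bias by gamma/(gamma-1)", {
  h <- hill_series(1:10, cbind(seq(-50, 40, by = 10)),
                   cbind(rep(10, 10)), rep(0.5, 10), 10, "phi1")
  b <- bias_from_hills(h, bins = 72)
  f10 <- fel_from_bias(b, gamma = 10)
  expect_equal(max(f10$values), (10 / 9) * diff(range(b$grid)),
               tolerance = 1e-9)
  fbig <- fel_from_bias(b, gamma = 1e6)
  expect_equal(max(fbig$values), diff(range(b$grid)), tolerance = 1e-4)
  expect_error(fel_from_bias(b, gamma = 1), "gamma")
})

test_that("barriers equal the lowest pass over the grid graph", {
  # 1D: [0, 5, 1] -> barrier 5 from bin 1 to bin 3
  g <- landscape_grid(c(0, 5, 1), list(c(-120, 0, 120)), min_shift = FALSE,
                      periodic = FALSE)
  b <- barrier_between(g, c(-150, -90), c(90, 150))
  expect_equal(b$barrier, 5)
  expect_equal(b$min_a, 0)

  # flat grid -> 0
  gf <- landscape_grid(matrix(1, 8, 8), rep(list(periodic_bin_centers_test(8)), 2))
  expect_equal(barrier_between(gf, list(c(-180, -90), c(-180, -90)),
                               list(c(90, 180), c(90, 180)))$barrier, 0)

  # random grids against the threshold-connectivity oracle
  set.seed(31)
  cx <- periodic_bin_centers_test(12)
  for (k in 1:12) {
    vals <- matrix(runif(144, 0, 10), 12, 12)
    if (k %% 3 == 0) vals[sample(144, 20)] <- NA  # masked patches
    g2 <- landscape_grid(vals, list(cx, cx))
    ra <- list(c(-180, -120), c(-180, -120))
    rb <- list(c(60, 120), c(60, 120))
    ia <- allostate:::region_bins(g2, ra)
    ib <- allostate:::region_bins(g2, rb)
    if (length(ia) == 0 || length(ib) == 0) next
    v <- g2$values
    v[is.na(v)] <- Inf
    expected_pass <- barrier_oracle(v, c(TRUE, TRUE), ia, ib)
    got <- tryCatch(barrier_between(g2, ra, rb),
                    error = function(e) NULL)
    if (is.na(expected_pass)) {
      expect_null(got)
    } else {
      expect_equal(got$pass, expected_pass)
      # symmetry of the pass: barrier differences equal min differences
      rev <- barrier_between(g2, rb, ra)
      expect_equal(got$barrier, rev$barrier + rev$min_a - got$min_a,
                   tolerance = 1e-12)
      expect_equal(rev$pass, got$pass)
    }
  }

  # disconnected through masked bins -> informative error
  vv <- matrix(NA_real_, 8, 8)
  vv[1, 1] <- 0
  vv[5, 5] <- 1
  gd <- landscape_grid(vv, rep(list(periodic_bin_centers_test(8)), 2))
  expect_error(barrier_between(gd, list(c(-180, -140), c(-180, -140)),
                               list(c(0, 30), c(0, 30))), "no path")
})
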