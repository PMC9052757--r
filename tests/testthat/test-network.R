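# helper: build a CorrelationMatrix object directly from a matrix
corr_obj <- function(C, chain = NULL) {
  n <- nrow(C)
  if (is.null(chain)) chain <- rep("A", n)
  structure(list(values = C,
                 residues = data.frame(chain = chain,
                                       resno = seq_len(n),
                                       subunit = chain,
                                       stringsAsFactors = FALSE),
                 atom_indices = seq_len(n)),
            class = "CorrelationMatrix")
}

test_that("displacement correlations recover perfect and planted signals", {
  set.seed(2)
  nf <- 200
  base <- rnorm(nf)
  # displacement pattern a = (1, -2, 1) along one direction: orthogonal to
  # all rigid-body modes, so the superposition fit is exactly the identity
  v <- c(0.3, 0.8, 0.52)
  a <- c(1, -2, 1)
  pts <- lapply(seq_len(nf), function(k) {
    rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)) + base[k] * outer(a, v)
  })
  traj <- point_traj(pts)
  # exact on the pre-aligned ensemble
  C0 <- correlation_matrix(traj, superpose = FALSE)$values
  expect_equal(C0[1, 3], 1, tolerance = 1e-9)   # copied displacements
  expect_equal(C0[1, 2], -1, tolerance = 1e-9)  # anti-phase
  # superposition leaves a rigid-mode-orthogonal field nearly unchanged
  C <- correlation_matrix(traj)$values
  expect_equal(C[1, 3], 1, tolerance = 0.05)
  expect_equal(C[1, 2], -1, tolerance = 0.05)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)

  # zero-variance residue errors unless masked
  frozen <- lapply(seq_len(nf), function(k) {
    p <- pts[[k]]
    rbind(p, c(0, 30, 0))
  })
  expect_error(correlation_matrix(point_traj(frozen)), "zero-variance")
  Cm <- correlation_matrix(point_traj(frozen), mask_zero_variance = TRUE)
  expect_equal(nrow(Cm$values), 3)

  # planted generator parameter recovery within +-0.05 at 5000 frames
  traj5 <- planted_ensemble(planted_network_spec(n_frames = 5000), seed = 8)
  got <- correlation_matrix(traj5)$values
  target <- attr(traj5, "target_correlation")
  pe <- attr(traj5, "planted_edges")
  expect_true(max(abs(got[pe] - target[pe])) < 0.05)
  ev <- eigen(got, symmetric = TRUE, only.values = TRUE)$values
  expect_true(min(ev) > -1e-8)
})

test_that("contact adjacency thresholds the mean distance", {
  two <- list(rbind(c(0, 0, 0), c(4, 0, 0)))
  tr <- point_traj(rep(two, 3))
  expect_true(contact_adjacency(tr, cutoff = 6)[1, 2])
  expect_false(contact_adjacency(tr, cutoff = 3)[1, 2])
  set.seed(14)
  pts <- lapply(1:5, function(k) matrix(runif(60, 0, 15), 20, 3))
  tr20 <- point_traj(pts)
  adj <- contact_adjacency(tr20, cutoff = 7)
  md <- Reduce(`+`, lapply(pts, function(p) as.matrix(dist(p)))) / 5
  expected <- md < 7
  diag(expected) <- FALSE
  expect_identical(adj, expected)
})

test_that("SPM edge usage matches exhaustive enumeration", {
  # 3-node chain: A-B-C with |C|=0.9 on both edges
  C <- diag(3)
  C[1, 2] <- C[2, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- 0.9
  C[1, 3] <- C[3, 1] <- 0.8
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- TRUE
  res <- spm(corr_obj(C), adj, threshold = 0.3)
  e <- res$edges
  expect_equal(e$usage[e$i == 1 & e$j == 2], 2)
  expect_equal(e$usage[e$i == 2 & e$j == 3], 2)
  expect_equal(e$width, c(1, 1))

  # a |C| = 1 edge has weight 0 and is always preferred
  C1 <- C
  C1[1, 2] <- C1[2, 1] <- 1
  res1 <- spm(corr_obj(C1), adj)
  expect_equal(res1$edges$weight[res1$edges$i == 1], 0)

  # random graphs up to 8 nodes vs the brute-force oracle
  set.seed(23)
  for (k in 1:25) {
    n <- sample(4:8, 1)
    adj <- matrix(FALSE, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      adj[i, j] <- adj[j, i] <- runif(1) < 0.5
    # keep a spanning chain so most pairs are reachable
    for (i in 1:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    Cr <- diag(n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      Cr[i, j] <- Cr[j, i] <- runif(1, 0.05, 0.95)
    got <- suppressWarnings(spm(corr_obj(Cr), adj))
    W <- -log(abs(Cr))
    expected <- spm_usage_oracle(W, adj)
    um <- matrix(0L, n, n)
    um[cbind(got$edges$i, got$edges$j)] <- got$edges$usage
    um <- um + t(um)
    expect_identical(um, expected)
  }
})

test_that("SPM is invariant to residue reordering", {
  set.seed(6)
  n <- 7
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj[1, 5] <- adj[5, 1] <- TRUE
  Cr <- diag(n)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    Cr[i, j] <- Cr[j, i] <- runif(1, 0.1, 0.9)
  perm <- sample(n)
  res <- spm(corr_obj(Cr), adj)
  resp <- spm(corr_obj(Cr[perm, perm]), adj[perm, perm])
  # map permuted edges back and compare usage
  u1 <- matrix(0L, n, n)
  u1[cbind(res$edges$i, res$edges$j)] <- res$edges$usage
  u1 <- u1 + t(u1)
  u2 <- matrix(0L, n, n)
  u2[cbind(resp$edges$i, resp$edges$j)] <- resp$edges$usage
  u2 <- u2 + t(u2)
  inv <- order(perm)
  expect_identical(u2[inv, inv], u1)
})

test_that("te-SPM windows follow the concatenated 600/300 bookkeeping", {
  w <- allostate:::te_spm_windows(1200, 600, 300)
  expect_equal(w$start, c(0, 300, 600))
  expect_equal(w$end, c(600, 900, 1200))
  expect_equal(nrow(allostate:::te_spm_windows(600, 600, 300)), 1)

  spec <- planted_network_spec(n_frames = 600)
  traj <- planted_ensemble(spec, seed = 5)
  # window == span: single window reproducing the global SPM
  tes <- te_spm(traj, window_ns = max(traj$times_ns), stride_ns = 300)
  expect_equal(nrow(tes$windows), 1)
  glob <- spm(correlation_matrix(traj), contact_adjacency(traj, cutoff = 6))
  expect_equal(tes$results[[1]]$edges$usage, glob$edges$usage)
  expect_error(te_spm(traj, window_ns = 1e6), "longer than")
})

test_that("planted-path switching is localized to overlapping windows", {
  spec <- planted_network_spec(n_frames = 1200, rho_path = 0.95,
                               rho_bg = 0.05)
  on_half <- planted_ensemble(spec, seed = 17)
  # replace first half with uncorrelated background: path "switches on"
  null_spec <- planted_network_spec(n_frames = 1200, rho_path = 0.052,
                                    rho_bg = 0.05)
  off_half <- planted_ensemble(null_spec, seed = 18)
  coords <- on_half$coords
  coords[, , 1:600] <- off_half$coords[, , 1:600]
  traj <- trajectory_ensemble(coords, on_half$times_ns, on_half$topology)
  tes <- te_spm(traj, window_ns = 599, stride_ns = 300, threshold = 0.3)
  pe <- attr(on_half, "planted_edges")
  cross <- attr(on_half, "cross_edge")
  hits <- vapply(tes$results, function(r) {
    e <- r$edges[r$edges$included, , drop = FALSE]
    sum(apply(pe, 1, function(p)
      any(e$i == min(p) & e$j == max(p))))
  }, numeric(1))
  # the last window (frames 601-1200, planted signal on) shows the whole
  # path in its SPM
  expect_equal(hits[length(hits)], nrow(pe))
  # the planted correlation itself is present only in windows overlapping
  # the second half (the null window's contact topology can still route
  # paths along the planted row, so inclusion alone is not diagnostic)
  corr_win <- function(idx) {
    mean(abs(correlation_matrix(subset_frames(traj, idx))$values[pe]))
  }
  expect_lt(corr_win(1:600), 0.3)
  expect_gt(corr_win(601:1200), 0.8)
})

test_that("subunit counts tally included residues per subunit", {
  C <- diag(5)
  C[1, 2] <- C[2, 1] <- 0.9
  C[2, 3] <- C[3, 2] <- 0.9
  C[3, 4] <- C[4, 3] <- 0.9
  C[4, 5] <- C[5, 4] <- 0.9
  adj <- matrix(FALSE, 5, 5)
  for (i in 1:4) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  res <- spm(corr_obj(C, chain = c("F", "F", "F", "H", "H")), adj,
             threshold = 0)
  counts <- subunit_counts(res)
  expect_equal(counts, c(F = 3L, H = 2L))
  expect_equal(sum(counts), sum(res$nodes$included))
  # relabelling chains to subunit names
  counts2 <- subunit_counts(res, subunit_map = c(F = "HisF", H = "HisH"))
  expect_equal(counts2, c(HisF = 3L, HisH = 2L))
})
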