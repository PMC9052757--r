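# In-code fixtures and independent oracles shared across the suite.

# small tripeptide-like model: 3 residues with N/CA/C (+ H on residue 2)
make_test_model <- function() {
  res <- rep(1:3, each = 3)
  ety <- rep(c("N", "CA", "C"), 3)
  # simple extended-chain geometry
  xyz <- cbind(seq(0, by = 1.3, length.out = 9),
               rep(c(0, 0.8, 0), 3),
               rep(0, 9))
  atoms <- data.frame(eleno = seq_len(10), elety = c(ety, "H"),
                      resid = "ALA", chain = "A",
                      resno = c(res, 2L), insert = "", elesy =
                        c(substr(ety, 1, 1), "H"),
                      stringsAsFactors = FALSE)
  xyz <- rbind(xyz, c(5.2, 1.8, 0))   # H on residue 2
  structure_model(atoms, xyz)
}

# trajectory with explicit per-frame coordinates built from a model
make_traj <- function(model, frames, times_ns = NULL) {
  nf <- length(frames)
  coords <- array(0, dim = c(nrow(model$xyz), 3, nf))
  for (k in seq_len(nf)) coords[, , k] <- frames[[k]]
  if (is.null(times_ns)) times_ns <- seq_len(nf) - 1
  trajectory_ensemble(coords, times_ns, model)
}

# trajectory holding arbitrary point sets (one CA pseudo-atom per point)
point_traj <- function(points_list, chain = NULL, times_ns = NULL) {
  n <- nrow(points_list[[1]])
  if (is.null(chain)) chain <- rep("A", n)
  atoms <- data.frame(eleno = seq_len(n), elety = "CA", resid = "ALA",
                      chain = chain,
                      resno = stats::ave(seq_len(n), chain, FUN = seq_along),
                      insert = "", elesy = "C", stringsAsFactors = FALSE)
  model <- structure_model(atoms, points_list[[1]])
  make_traj(model, points_list, times_ns)
}

periodic_bin_centers_test <- function(bins) {
  -180 + (seq_len(bins) - 0.5) * 360 / bins
}

random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# independent torsion oracle: arccos of plane normals with explicit sign
torsion_oracle <- function(p) {
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  ang <- acos(max(-1, min(1, sum(n1 * n2) /
                            sqrt(sum(n1^2) * sum(n2^2))))) * 180 / pi
  cr <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
          n1[1] * n2[2] - n1[2] * n2[1])
  if (sum(cr * b2) < 0) -ang else ang
}

# minimax-pass oracle: lowest threshold level at which the two regions are
# connected in the <=-level subgraph of the (periodic) grid graph
barrier_oracle <- function(values, periodic, region_a_idx, region_b_idx) {
  nx <- nrow(values)
  ny <- ncol(values)
  idx <- function(i, j) i + (j - 1) * nx
  edges <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) edges <- rbind(edges, c(idx(i, j), idx(i + 1, j)))
    else if (periodic[1] && nx > 2) edges <- rbind(edges, c(idx(i, j), idx(1, j)))
    if (ny > 1) {
      if (j < ny) edges <- rbind(edges, c(idx(i, j), idx(i, j + 1)))
      else if (periodic[2] && ny > 2) edges <- rbind(edges, c(idx(i, j), idx(i, 1)))
    }
  }
  v <- as.vector(values)
  levels <- sort(unique(v[is.finite(v)]))
  for (lev in levels) {
    keep <- which(v <= lev)
    if (!any(region_a_idx %in% keep) || !any(region_b_idx %in% keep)) next
    sub <- edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
    g <- igraph::graph_from_edgelist(matrix(as.character(sub), ncol = 2),
                                     directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(keep),
                                      igraph::V(g)$name))
    memb <- igraph::components(g)$membership
    ca <- memb[as.character(intersect(region_a_idx, keep))]
    cb <- memb[as.character(intersect(region_b_idx, keep))]
    if (length(intersect(ca, cb)) > 0) return(lev)
  }
  NA_real_
}

# exhaustive shortest-path edge-usage oracle for small graphs with unique
# shortest paths (weights in general position)
spm_usage_oracle <- function(W, adjacency) {
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  usage <- matrix(0L, n, n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- igraph::all_simple_paths(g, from = s, to = t)
    if (length(paths) == 0) next
    costs <- vapply(paths, function(p) {
      p <- as.integer(p)
      sum(W[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    best <- paths[[which.min(costs)]]
    p <- as.integer(best)
    for (k in seq_len(length(p) - 1)) {
      i <- min(p[k], p[k + 1])
      j <- max(p[k], p[k + 1])
      usage[i, j] <- usage[i, j] + 1L
    }
  }
  usage + t(usage)
}

# independent run-length filter: iteratively absorb the shortest
# under-minimum run into its longer flank (tie: preceding)
dwell_filter_oracle <- function(labels, min_dwell) {
  lab <- labels
  repeat {
    r <- rle(lab)
    if (length(r$lengths) == 1) break
    short <- which(r$lengths < min_dwell)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    ln <- if (i > 1) r$lengths[i - 1] else -Inf
    rn <- if (i < length(r$lengths)) r$lengths[i + 1] else -Inf
    src <- if (ln >= rn) i - 1 else i + 1
    r$values[i] <- r$values[src]
    lab <- inverse.rle(r)
  }
  lab
}
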