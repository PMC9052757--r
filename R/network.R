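# Dynamic-network analysis: C-alpha displacement cross-correlation after
# iterative superposition, shortest path map (SPM) graphs with
# -log|C| edge weights and shortest-path usage widths, sliding-window
# te-SPM, and per-subunit residue counts.

#' Indices of C-alpha atoms of a model
#' @param model A \code{StructureModel}.
#' @return Integer atom indices of all CA atoms, in atom order.
#' @export
calpha_indices <- function(model) which(model$atoms$elety == "CA")

#' Least-squares superposition onto the iterated mean structure
#'
#' Each frame is rigid-body fitted (Kabsch) onto the running mean
#' structure; the mean is recomputed and the fit repeated until the mean
#' moves by less than \code{tol} (RMS, Angstrom). Removes rigid-body drift
#' that would inflate correlations.
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param sel Atom indices to fit and keep (default: all atoms).
#' @param tol Convergence tolerance on the mean structure, Angstrom.
#' @param max_iter Iteration cap.
#' @return List: \code{coords} (array sel-atoms x 3 x frames, superposed),
#'   \code{mean} (matrix), \code{iterations}.
#' @export
superpose_frames <- function(traj, sel = NULL, tol = 1e-6, max_iter = 50) {
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  xyz <- traj$coords[sel, , , drop = FALSE]
  nf <- dim(xyz)[3]
  ref <- xyz[, , 1]
  it <- 0
  repeat {
    it <- it + 1
    refc <- scale(ref, scale = FALSE)
    for (k in seq_len(nf))
      xyz[, , k] <- kabsch_fit(xyz[, , k], refc)
    newmean <- apply(xyz, c(1, 2), mean)
    delta <- sqrt(mean((newmean - ref)^2))
    ref <- newmean
    if (delta < tol || it >= max_iter) break
  }
  list(coords = xyz, mean = ref, iterations = it)
}

# rigid-body fit of X (n x 3) onto centred reference refc (n x 3)
kabsch_fit <- function(x, refc) {
  xc <- scale(x, scale = FALSE)
  s <- svd(crossprod(xc, refc))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  xc %*% rot
}

#' C-alpha displacement cross-correlation matrix
#'
#' After iterative superposition, C_ij = <dr_i . dr_j> /
#' sqrt(<|dr_i|^2><|dr_j|^2>) with dr the displacement from the mean
#' position (Pearson correlation of the 3D displacement vectors).
#'
#' @param traj A \code{TrajectoryEnsemble} (>= 10 frames).
#' @param sel Atom indices of the residues' C-alpha atoms (default: all CA
#'   atoms of the topology; >= 2 required).
#' @param mask_zero_variance Drop zero-variance residues (rows/columns)
#'   instead of erroring.
#' @param superpose Remove rigid-body motion by iterative superposition
#'   first (default TRUE; disable for ensembles that are already aligned).
#' @return A \code{CorrelationMatrix}: list with \code{values} (n x n),
#'   \code{residues} (data.frame chain/resno/subunit).
#' @export
correlation_matrix <- function(traj, sel = NULL,
                               mask_zero_variance = FALSE,
                               superpose = TRUE) {
  if (is.null(sel)) sel <- calpha_indices(traj$topology)
  if (length(sel) < 2) stop("need at least 2 residues")
  if (n_frames(traj) < 10) stop("need at least 10 frames")
  sup <- if (superpose) superpose_frames(traj, sel)
         else {
           xyz <- traj$coords[sel, , , drop = FALSE]
           list(coords = xyz, mean = apply(xyz, c(1, 2), mean))
         }
  nf <- dim(sup$coords)[3]
  n <- length(sel)
  # displacements: frames x (n*3)
  disp <- t(matrix(sup$coords, nrow = n * 3)) -
    matrix(as.vector(sup$mean), nrow = nf, ncol = n * 3, byrow = TRUE)
  # inner products of 3D displacement vectors: sum over the 3 components
  G <- matrix(0, n, n)
  for (c3 in 1:3) {
    block <- disp[, ((c3 - 1) * n + 1):(c3 * n), drop = FALSE]
    G <- G + crossprod(block) / nf
  }
  v <- diag(G)
  zero <- v < 1e-12
  if (any(zero) && !mask_zero_variance)
    stop("zero-variance residue(s) at index ",
         paste(which(zero), collapse = ", "),
         "; set mask_zero_variance = TRUE to drop them")
  keep <- which(!zero)
  C <- G[keep, keep, drop = FALSE] /
    sqrt(outer(v[keep], v[keep]))
  diag(C) <- 1
  C <- (C + t(C)) / 2
  at <- traj$topology$atoms[sel[keep], , drop = FALSE]
  sm <- traj$topology$subunit_map
  res <- data.frame(chain = at$chain, resno = at$resno,
                    subunit = ifelse(at$chain %in% names(sm),
                                     sm[at$chain], at$chain),
                    stringsAsFactors = FALSE)
  structure(list(values = C, residues = res, atom_indices = sel[keep]),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix: %d residues, off-diagonal range [%.3f, %.3f]\n",
              nrow(x$values),
              min(x$values[upper.tri(x$values)]),
              max(x$values[upper.tri(x$values)])))
  invisible(x)
}

#' Mean-distance contact adjacency of C-alpha atoms
#'
#' Edge iff the mean C-alpha / C-alpha distance over frames is below
#' \code{cutoff}; no self-edges.
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param sel C-alpha atom indices (default all CA).
#' @param cutoff Distance cutoff, Angstrom (default 6).
#' @return Logical symmetric adjacency matrix.
#' @export
contact_adjacency <- function(traj, sel = NULL, cutoff = 6) {
  stopifnot(cutoff > 0)
  if (is.null(sel)) sel <- calpha_indices(traj$topology)
  xyz <- traj$coords[sel, , , drop = FALSE]
  nf <- dim(xyz)[3]
  n <- length(sel)
  md <- matrix(0, n, n)
  for (k in seq_len(nf))
    md <- md + as.matrix(stats::dist(xyz[, , k]))
  md <- md / nf
  adj <- md < cutoff
  diag(adj) <- FALSE
  adj
}

#' Shortest path map of a correlation network
#'
#' Edge weight d_ij = -log|C_ij| on contact edges (|C| clamped to
#' [1e-12, 1]); Dijkstra shortest paths for every residue pair with
#' deterministic lowest-index-predecessor tie-breaking; each edge's usage
#' is the number of pairs whose shortest path traverses it; widths are
#' usage / max usage; a node's importance is the sum of its incident
#' included-edge widths. The SPM proper is the subgraph of edges with
#' width >= \code{threshold}.
#'
#' @param corr A \code{CorrelationMatrix}.
#' @param adjacency Logical adjacency from \code{\link{contact_adjacency}}.
#' @param threshold Width inclusion threshold in [0, 1] (default 0.3).
#' @return An \code{SPMResult}: \code{nodes} (data.frame with importance
#'   and inclusion), \code{edges} (data.frame i/j/weight/usage/width/
#'   included), \code{threshold}, \code{n_components}, \code{ties}
#'   (whether equal-weight alternate paths were seen).
#' @export
spm <- function(corr, adjacency, threshold = 0.3) {
  stopifnot(inherits(corr, "CorrelationMatrix"))
  C <- corr$values
  n <- nrow(C)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  W <- -log(pmin(pmax(abs(C), 1e-12), 1))
  W[!adjacency] <- Inf
  diag(W) <- Inf
  usage <- matrix(0L, n, n)
  ties <- FALSE
  comp <- connected_components(adjacency)
  if (max(comp) > 1)
    warning("contact graph has ", max(comp), " connected components; ",
            "pairs without a path are skipped")
  for (s in seq_len(n - 1)) {
    dj <- dijkstra_lowidx(W, s)
    if (dj$ties) ties <- TRUE
    for (t in (s + 1):n) {
      if (!is.finite(dj$dist[t])) next
      cur <- t
      while (cur != s) {
        p <- dj$pred[cur]
        i <- min(p, cur)
        j <- max(p, cur)
        usage[i, j] <- usage[i, j] + 1L
        cur <- p
      }
    }
  }
  usage <- usage + t(usage)
  eidx <- which(upper.tri(adjacency) & adjacency, arr.ind = TRUE)
  umax <- max(usage[eidx], 1L)
  edges <- data.frame(i = eidx[, 1], j = eidx[, 2],
                      weight = W[eidx],
                      usage = usage[eidx],
                      width = usage[eidx] / umax)
  edges$included <- edges$width >= threshold
  importance <- numeric(n)
  inc <- edges[edges$included, , drop = FALSE]
  for (k in seq_len(nrow(inc))) {
    importance[inc$i[k]] <- importance[inc$i[k]] + inc$width[k]
    importance[inc$j[k]] <- importance[inc$j[k]] + inc$width[k]
  }
  nodes <- cbind(corr$residues,
                 data.frame(importance = importance,
                            included = importance > 0))
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 n_components = max(comp), ties = ties),
            class = "SPMResult")
}

#' @export
print.SPMResult <- function(x, ...) {
  cat(sprintf("SPMResult: %d nodes (%d included), %d edges (%d included), threshold %.2f\n",
              nrow(x$nodes), sum(x$nodes$included), nrow(x$edges),
              sum(x$edges$included), x$threshold))
  invisible(x)
}

# Dijkstra from source s on weight matrix W (Inf = no edge), deterministic:
# among equal (within 1e-12) tentative distances the lowest-index
# predecessor wins; returns dist, pred and whether ties occurred.
dijkstra_lowidx <- function(W, s) {
  n <- nrow(W)
  dist <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[s] <- 0
  tol <- 1e-12
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    nb <- which(is.finite(W[u, ]) & !done)
    for (v in nb) {
      alt <- dist[u] + W[u, v]
      if (alt < dist[v] - tol) {
        dist[v] <- alt
        pred[v] <- u
      } else if (abs(alt - dist[v]) <= tol) {
        # equal-length alternative: lowest-index predecessor wins
        if (!is.na(pred[v]) && u < pred[v]) pred[v] <- u
      }
    }
  }
  # note ties by re-scanning: any settled v with two predecessors at equal dist
  ties <- FALSE
  for (v in which(is.finite(dist) & !is.na(pred))) {
    alts <- which(is.finite(W[, v]))
    eq <- sum(abs(dist[alts] + W[alts, v] - dist[v]) <= tol)
    if (eq > 1) { ties <- TRUE; break }
  }
  list(dist = dist, pred = pred, ties = ties)
}

connected_components <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  igraph::components(g)$membership
}

#' Time-evolution SPM over sliding windows
#'
#' Windows are [k*stride, k*stride + window] in ns for k = 0, 1, ... while
#' the window end does not exceed the trajectory span; each window's SPM is
#' computed from the frames strictly inside it (boundary times inclusive).
#'
#' @param traj A \code{TrajectoryEnsemble}.
#' @param window_ns Window length, ns (e.g. 600).
#' @param stride_ns Window start spacing, ns (e.g. 300).
#' @param sel C-alpha selection (default all CA).
#' @param cutoff Contact cutoff, Angstrom.
#' @param threshold SPM width inclusion threshold.
#' @return A \code{TeSPMSeries}: \code{windows} (data.frame start/end ns),
#'   \code{results} (list of \code{SPMResult}), \code{subunit_counts}
#'   (matrix windows x subunits).
#' @export
te_spm <- function(traj, window_ns = 600, stride_ns = 300, sel = NULL,
                   cutoff = 6, threshold = 0.3) {
  stopifnot(stride_ns > 0)
  t0 <- min(traj$times_ns)
  span <- max(traj$times_ns) - t0
  if (window_ns > span)
    stop("window (", window_ns, " ns) longer than trajectory span (",
         span, " ns)")
  wins <- te_spm_windows(span, window_ns, stride_ns)
  results <- vector("list", nrow(wins))
  sc <- NULL
  for (k in seq_len(nrow(wins))) {
    idx <- which(traj$times_ns - t0 >= wins$start[k] &
                   traj$times_ns - t0 <= wins$end[k])
    sub <- subset_frames(traj, idx)
    corr <- correlation_matrix(sub, sel)
    adj <- contact_adjacency(sub, sel, cutoff)
    results[[k]] <- spm(corr, adj, threshold)
    cnt <- subunit_counts(results[[k]])
    if (is.null(sc)) sc <- matrix(0L, nrow(wins), length(cnt),
                                  dimnames = list(NULL, names(cnt)))
    sc[k, names(cnt)] <- cnt
  }
  structure(list(windows = wins, results = results, subunit_counts = sc),
            class = "TeSPMSeries")
}

# pure window bookkeeping, exposed for testing: spans [k*stride,
# k*stride+window] while end <= span
te_spm_windows <- function(span_ns, window_ns, stride_ns) {
  starts <- seq(0, span_ns, by = stride_ns)
  starts <- starts[starts + window_ns <= span_ns + 1e-9]
  data.frame(start = starts, end = starts + window_ns)
}

#' @export
print.TeSPMSeries <- function(x, ...) {
  cat(sprintf("TeSPMSeries: %d windows of %g ns\n", nrow(x$windows),
              x$windows$end[1] - x$windows$start[1]))
  print(cbind(x$windows, x$subunit_counts))
  invisible(x)
}

#' Residues included in an SPM, per subunit
#'
#' Counts nodes with at least one included edge, grouped by subunit label.
#'
#' @param spm_result An \code{SPMResult}.
#' @param subunit_map Optional chain -> subunit relabelling; by default the
#'   subunit tags already on the nodes are used.
#' @return Named integer vector of counts.
#' @export
subunit_counts <- function(spm_result, subunit_map = NULL) {
  stopifnot(inherits(spm_result, "SPMResult"))
  nodes <- spm_result$nodes
  su <- nodes$subunit
  if (!is.null(subunit_map)) su <- subunit_map[nodes$chain]
  if (any(is.na(su) | su == ""))
    stop("node(s) without a subunit tag")
  counts <- tapply(nodes$included, su, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Export an SPM as an igraph object / GraphML / edge list
#'
#' @param spm_result An \code{SPMResult}.
#' @param included_only Keep only included edges (default FALSE: full
#'   graph, with width attributes).
#' @return An igraph graph with node and edge attributes.
#' @export
spm_graph <- function(spm_result, included_only = FALSE) {
  e <- spm_result$edges
  if (included_only) e <- e[e$included, , drop = FALSE]
  nd <- spm_result$nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j, weight = e$weight, usage = e$usage,
               width = e$width, included = e$included),
    directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(nd)), chain = nd$chain,
                          resno = nd$resno, subunit = nd$subunit,
                          importance = nd$importance,
                          included = nd$included))
  g
}

#' @rdname spm_graph
#' @param path Output file (\code{.graphml} or \code{.csv} edge list).
#' @export
write_spm <- function(spm_result, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(spm_graph(spm_result), path, format = "graphml")
  } else {
    write.csv(spm_result$edges, path, row.names = FALSE)
  }
  invisible(path)
}
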