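# Free-energy landscape reconstruction: F = -kT ln P from sampled
# populations, Boltzmann 1D marginals, summed Gaussian bias from
# well-tempered metadynamics hills (multi-walker), the WT-MetaD estimator
# F = -(gamma/(gamma-1)) V, and minimax-path barriers between basins.

#' Construct a free-energy grid
#'
#' @param values Free energies, kcal/mol: a numeric vector (1D) or matrix
#'   (2D, first CV on rows). \code{NA} marks never-visited (masked) bins.
#' @param centers List of per-axis bin-center vectors (degrees).
#' @param cv_names Character CV names.
#' @param periodic Logical per axis.
#' @param temperature Kelvin.
#' @param min_shift Shift so the unmasked minimum is 0 (default TRUE).
#' @return Object of class \code{LandscapeGrid}.
#' @export
landscape_grid <- function(values, centers, cv_names = NULL,
                           periodic = NULL, temperature = 300,
                           min_shift = TRUE) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (!is.list(centers)) centers <- list(centers)
  d <- length(centers)
  stopifnot(d %in% c(1, 2), nrow(values) == length(centers[[1]]))
  if (d == 2) stopifnot(ncol(values) == length(centers[[2]]))
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  if (is.null(periodic)) periodic <- rep(TRUE, d)
  if (all(is.na(values))) stop("all grid bins are masked")
  if (min_shift) values <- values - min(values, na.rm = TRUE)
  structure(list(values = values, centers = centers, cv_names = cv_names,
                 periodic = periodic, temperature = temperature),
            class = "LandscapeGrid")
}

#' @export
print.LandscapeGrid <- function(x, ...) {
  dims <- vapply(x$centers, length, integer(1))
  cat(sprintf("LandscapeGrid: %s bins [%s], T = %g K, F range 0-%.3g kcal/mol, %d masked\n",
              paste(dims, collapse = " x "),
              paste(x$cv_names, collapse = ", "), x$temperature,
              max(x$values, na.rm = TRUE), sum(is.na(x$values))))
  invisible(x)
}

grid_dim <- function(grid) length(grid$centers)

# standard periodic bin centers for `bins` bins over (-180, 180]
periodic_bin_centers <- function(bins) -180 + (seq_len(bins) - 0.5) * 360 / bins

#' Free-energy landscape from sampled CV values
#'
#' F(bin) = -kT ln(count / N), min-shifted to 0; bins with zero counts are
#' masked (\code{NA}), never given a pseudo-count.
#'
#' @param samples Numeric vector (1D) or 2-column matrix/data.frame (2D) of
#'   CV samples in degrees; a \code{CollectiveVariableSeries} is accepted
#'   (its time column is dropped).
#' @param bins Bins per axis (default 72, i.e. 5-degree bins).
#' @param temperature Kelvin (default 300).
#' @param cv_names Optional CV names.
#' @return A \code{LandscapeGrid}.
#' @export
landscape_from_samples <- function(samples, bins = 72, temperature = 300,
                                   cv_names = NULL) {
  stopifnot(temperature > 0)
  if (inherits(samples, "CollectiveVariableSeries"))
    samples <- as.matrix(samples[, -1, drop = FALSE])
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  if (nrow(samples) == 0) stop("empty sample set")
  d <- ncol(samples)
  stopifnot(d %in% c(1, 2))
  if (is.null(cv_names))
    cv_names <- if (!is.null(colnames(samples))) colnames(samples)
                else paste0("cv", seq_len(d))
  kT <- kT_kcal(temperature)
  n <- nrow(samples)
  i1 <- periodic_bin_index(samples[, 1], bins)
  if (d == 2) {
    i2 <- periodic_bin_index(samples[, 2], bins)
    counts <- matrix(tabulate(i1 + (i2 - 1L) * bins, nbins = bins * bins),
                     bins, bins)
  } else {
    counts <- matrix(tabulate(i1, nbins = bins), ncol = 1)
  }
  F <- -kT * log(counts / n)
  F[counts == 0] <- NA
  landscape_grid(F, rep(list(periodic_bin_centers(bins)), d),
                 cv_names = cv_names, temperature = temperature)
}

#' 1D Boltzmann marginal of a 2D landscape
#'
#' P(x) = sum_y exp(-F(x,y)/kT) over unmasked bins; F1(x) = -kT ln P(x),
#' min-shifted. Rows (or columns) that are entirely masked stay masked.
#'
#' @param grid2d A 2D \code{LandscapeGrid}.
#' @param axis Axis to keep: 1 (first CV, rows) or 2.
#' @return A 1D \code{LandscapeGrid}.
#' @export
marginal_profile <- function(grid2d, axis = 1) {
  stopifnot(inherits(grid2d, "LandscapeGrid"), grid_dim(grid2d) == 2,
            axis %in% 1:2)
  kT <- kT_kcal(grid2d$temperature)
  P <- exp(-grid2d$values / kT)
  P[is.na(P)] <- 0
  p1 <- if (axis == 1) rowSums(P) else colSums(P)
  F1 <- ifelse(p1 > 0, -kT * log(p1), NA)
  landscape_grid(F1, grid2d$centers[axis], cv_names = grid2d$cv_names[axis],
                 periodic = grid2d$periodic[axis],
                 temperature = grid2d$temperature)
}

#' Accumulated metadynamics bias from hill records
#'
#' V(s) = sum_k w_k prod_d exp(-D_d(s, c_k)^2 / (2 sigma_kd^2)) with D_d
#' the minimum-image difference for periodic CVs. Hills from multiple
#' walkers are merged by concatenation sorted by deposition time (shared
#' bias, multiple-walkers scheme).
#'
#' @param hills A \code{HillSeries} or list of them (one per walker); all
#'   must share CV names, periods and bias factor.
#' @param bins Bins per axis for the evaluation grid (default 72).
#' @param temperature Kelvin, carried to downstream landscapes.
#' @return A \code{BiasPotential}: list with \code{grid} (bias values, same
#'   layout as a \code{LandscapeGrid}), \code{gamma}, \code{hills_per_walker}.
#' @export
bias_from_hills <- function(hills, bins = 72, temperature = 300) {
  if (inherits(hills, "HillSeries")) hills <- list(hills)
  gam <- unique(vapply(hills, `[[`, numeric(1), "bias_factor"))
  if (length(gam) != 1)
    stop("mixed bias factors across walkers: ", paste(gam, collapse = ", "))
  nm <- unique(lapply(hills, `[[`, "cv_names"))
  if (length(nm) != 1) stop("hill series disagree on CV names")
  d <- length(nm[[1]])
  stopifnot(d %in% c(1, 2))
  times <- unlist(lapply(hills, `[[`, "times"))
  centers <- do.call(rbind, lapply(hills, `[[`, "centers"))
  sigmas <- do.call(rbind, lapply(hills, `[[`, "sigmas"))
  heights <- unlist(lapply(hills, `[[`, "heights"))
  wk <- unlist(lapply(hills, `[[`, "walker_id"))
  ord <- order(times)
  centers <- centers[ord, , drop = FALSE]
  sigmas <- sigmas[ord, , drop = FALSE]
  heights <- heights[ord]
  gx <- periodic_bin_centers(bins)
  V <- matrix(0, bins, if (d == 2) bins else 1)
  for (k in seq_along(heights)) {
    g1 <- exp(-wrap_angle(gx - centers[k, 1])^2 / (2 * sigmas[k, 1]^2))
    if (d == 2) {
      g2 <- exp(-wrap_angle(gx - centers[k, 2])^2 / (2 * sigmas[k, 2]^2))
      V <- V + heights[k] * outer(g1, g2)
    } else {
      V <- V + heights[k] * g1
    }
  }
  structure(list(grid = V, centers = rep(list(gx), d),
                 cv_names = nm[[1]], gamma = gam,
                 temperature = temperature,
                 hills_per_walker = table(wk)),
            class = "BiasPotential")
}

#' @export
print.BiasPotential <- function(x, ...) {
  cat(sprintf("BiasPotential: %s grid, gamma = %g, V range %.3g-%.3g kcal/mol\n",
              paste(dim(x$grid), collapse = " x "), x$gamma,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' Free-energy landscape from a well-tempered bias
#'
#' The WT-MetaD estimator F(s) = -(gamma/(gamma-1)) V(s), min-shifted.
#'
#' @param bias A \code{BiasPotential}.
#' @param gamma Bias factor; defaults to the one recorded on \code{bias}.
#' @return A \code{LandscapeGrid}.
#' @export
fel_from_bias <- function(bias, gamma = NULL) {
  stopifnot(inherits(bias, "BiasPotential"))
  if (is.null(gamma)) gamma <- bias$gamma
  if (gamma <= 1) stop("bias factor gamma must be > 1")
  F <- -(gamma / (gamma - 1)) * bias$grid
  landscape_grid(F, bias$centers, cv_names = bias$cv_names,
                 temperature = bias$temperature)
}

# bin indices of a grid falling inside a CV box (periodic-aware intervals)
region_bins <- function(grid, region) {
  d <- grid_dim(grid)
  if (!is.list(region)) region <- list(region)
  stopifnot(length(region) == d)
  ok1 <- in_periodic_interval_num(grid$centers[[1]], region[[1]],
                                  grid$periodic[1])
  if (d == 1) {
    idx <- which(ok1 & !is.na(grid$values))
  } else {
    ok2 <- in_periodic_interval_num(grid$centers[[2]], region[[2]],
                                    grid$periodic[2])
    m <- outer(ok1, ok2) & !is.na(grid$values)
    idx <- which(m)
  }
  idx
}

in_periodic_interval_num <- function(x, iv, periodic = TRUE) {
  if (is.null(iv)) return(rep(TRUE, length(x)))
  stopifnot(length(iv) == 2)
  if (!periodic || iv[1] <= iv[2]) x >= iv[1] & x <= iv[2]
  else x >= iv[1] | x <= iv[2]
}

#' Barrier between two basins on a landscape grid
#'
#' The lowest pass is the min over all 4-connected grid paths from region A
#' to region B of the maximum F along the path (periodic axes wrap; masked
#' bins are impassable). The barrier is the pass height minus the minimum F
#' in region A.
#'
#' @param grid A \code{LandscapeGrid}.
#' @param region_a,region_b CV boxes: for 1D a length-2 interval, for 2D a
#'   list of two intervals (degrees; \code{NULL} = whole axis). Each must
#'   contain at least one unmasked bin.
#' @return List: \code{barrier} (kcal/mol), \code{pass} (pass height above
#'   the global minimum), \code{saddle} (CV coordinates of the pass bin),
#'   \code{min_a}, \code{min_b}.
#' @export
barrier_between <- function(grid, region_a, region_b) {
  stopifnot(inherits(grid, "LandscapeGrid"))
  ia <- region_bins(grid, region_a)
  ib <- region_bins(grid, region_b)
  if (length(ia) == 0) stop("region A contains no unmasked bin")
  if (length(ib) == 0) stop("region B contains no unmasked bin")
  v <- grid$values
  nx <- nrow(v)
  ny <- ncol(v)
  passable <- !is.na(v)
  Fv <- as.vector(v)
  Fv[!passable] <- Inf
  res <- minimax_pass_cpp(Fv, nx, ny, grid$periodic[1],
                          if (grid_dim(grid) == 2) grid$periodic[2] else FALSE,
                          as.integer(ia - 1L), as.integer(ib - 1L),
                          as.vector(passable))
  if (!res$connected)
    stop("no path: regions are disconnected through unmasked bins")
  sidx <- res$saddle
  si <- (sidx - 1) %% nx + 1
  sj <- (sidx - 1) %/% nx + 1
  saddle <- if (grid_dim(grid) == 2)
    c(grid$centers[[1]][si], grid$centers[[2]][sj])
  else grid$centers[[1]][si]
  min_a <- min(v[ia])
  list(barrier = res$pass - min_a, pass = res$pass, saddle = saddle,
       min_a = min_a, min_b = min(v[ib]))
}

#' Write a landscape grid as CSV
#'
#' Long format: one row per bin with bin centers, F (empty for masked bins)
#' and a mask column.
#'
#' @param grid A \code{LandscapeGrid}.
#' @param path Output CSV.
#' @return \code{path}, invisibly.
#' @export
write_landscape_csv <- function(grid, path) {
  d <- grid_dim(grid)
  if (d == 2) {
    df <- expand.grid(x = grid$centers[[1]], y = grid$centers[[2]])
    names(df) <- grid$cv_names
    df$free_energy <- as.vector(grid$values)
  } else {
    df <- data.frame(x = grid$centers[[1]],
                     free_energy = as.vector(grid$values))
    names(df)[1] <- grid$cv_names[1]
  }
  df$masked <- is.na(df$free_energy)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
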