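# pool all components of all bootstrap solutions into one matrix with a
# bootstrap-index column
poolComponents <- function(result) {
  mats <- lapply(seq_along(result@solutions), function(i) {
    p <- result@solutions[[i]]@params
    cbind(p, bootstrap = rep(i, nrow(p)))
  })
  do.call(rbind, mats)
}

# feature matrix used for clustering: Diso(w_ref), DDelta^2(w_ref), theta,
# phi, R1, R2, each normalized by its maximum over the pooled components
clusterFeatures <- function(comps, omega_ref) {
  sh <- componentSpectralShape(comps, omega_ref)
  f <- cbind(d_iso = sh$d_iso, d_delta_sq = sh$d_delta_sq,
             theta = comps[, "theta"], phi = comps[, "phi"],
             r1 = comps[, "r1"], r2 = comps[, "r2"])
  mx <- apply(abs(f), 2, max)
  mx[mx == 0] <- 1
  sweep(f, 2, mx, "/")
}

#' Cluster bootstrap components (L1 k-means)
#'
#' Groups the components pooled over all bootstrap solutions of a voxel by
#' Lloyd-style k-means with the L1 distance and coordinate-wise median
#' centroid updates, on features (Diso(omega_ref), DDelta^2(omega_ref),
#' theta, phi, R1, R2) normalized by their respective maxima. Deterministic
#' given the seed.
#'
#' @param result a \linkS4class{VoxelInversionResult}.
#' @param omega_ref angular frequency (rad/s) at which the spectral features
#'   are evaluated; defaults to the lowest protocol frequency 2 pi 6.6.
#' @param k number of clusters; default is the median number of
#'   positive-weight components per bootstrap solution.
#' @param seed integer seed for the initial centroid draw.
#' @param max_iter Lloyd iteration cap.
#' @return integer vector of cluster labels over the pooled components (in
#'   bootstrap order), with attribute \code{"pooled"} holding the pooled
#'   component matrix.
#' @export
clusterComponents <- function(result, omega_ref = 2 * pi * 6.6, k = NULL,
                              seed = 1L, max_iter = 100L) {
  pooled <- poolComponents(result)
  if (is.null(pooled) || nrow(pooled) == 0) stop("empty inversion result")
  if (is.null(k)) {
    k <- max(1L, as.integer(round(median(vapply(
      result@solutions, function(s) sum(s@params[, "weight"] > 0),
      numeric(1))))))
  }
  feat <- clusterFeatures(pooled, omega_ref)
  uniq <- unique(feat)
  if (k > nrow(uniq))
    stop(sprintf("k = %d exceeds the %d distinct components", k, nrow(uniq)))
  set.seed(seed)
  centers <- uniq[sample.int(nrow(uniq), k), , drop = FALSE]
  labels <- rep(1L, nrow(feat))
  for (it in seq_len(max_iter)) {
    # L1 distances to every centroid
    d <- sapply(seq_len(k), function(j)
      rowSums(abs(sweep(feat, 2, centers[j, ]))))
    if (k == 1L) d <- matrix(d, ncol = 1)
    new_labels <- max.col(-d, ties.method = "first")
    if (identical(new_labels, labels) && it > 1L) break
    labels <- new_labels
    for (j in seq_len(k)) {
      m <- labels == j
      if (any(m)) centers[j, ] <- apply(feat[m, , drop = FALSE], 2, median)
    }
  }
  attr(labels, "pooled") <- pooled
  labels
}

#' Consolidate clustered components into one distribution
#'
#' Collapses each cluster of pooled bootstrap components into a single
#' representative component: the weight-weighted mean of every parameter and
#' the median of the member weights. Empty clusters are skipped with a
#' message.
#'
#' @param result a \linkS4class{VoxelInversionResult}.
#' @param labels labels from \code{\link{clusterComponents}} (with the
#'   pooled matrix attached), or a plain label vector matching the pooled
#'   component order.
#' @return a \linkS4class{DRComponents} with one component per non-empty
#'   cluster.
#' @export
consolidate <- function(result, labels) {
  pooled <- attr(labels, "pooled")
  if (is.null(pooled)) pooled <- poolComponents(result)
  if (nrow(pooled) != length(labels))
    stop("labels do not cover the pooled components")
  ks <- sort(unique(labels))
  param_cols <- setdiff(compColumns, "weight")
  reps <- matrix(NA_real_, length(ks), length(compColumns),
                 dimnames = list(NULL, compColumns))
  ri <- 0L
  for (kk in ks) {
    m <- labels == kk
    if (!any(m)) { message("skipping empty cluster ", kk); next }
    ri <- ri + 1L
    w <- pooled[m, "weight"]
    if (sum(w) == 0) w <- rep(1, sum(m))
    for (cc in param_cols)
      reps[ri, cc] <- sum(pooled[m, cc] * w) / sum(w)
    reps[ri, "weight"] <- median(pooled[m, "weight"])
  }
  new("DRComponents", params = reps[seq_len(ri), , drop = FALSE])
}

meshAxisSpec <- function(name) {
  switch(name,
    d_iso = list(range = c(0.05, 5), log = TRUE),
    d_delta_sq = list(range = c(0, 1), log = FALSE),
    r1 = list(range = c(0.2, 2), log = TRUE),
    r2 = list(range = c(1, 30), log = TRUE),
    stop("unknown mesh axis: ", name))
}

planeAxes <- function(plane) {
  switch(plane,
    diso_ddelta2 = c("d_iso", "d_delta_sq"),
    diso_r1 = c("d_iso", "r1"),
    diso_r2 = c("d_iso", "r2"),
    ddelta2_r1 = c("d_delta_sq", "r1"),
    ddelta2_r2 = c("d_delta_sq", "r2"),
    stop("unknown projection plane: ", plane))
}

#' Project a distribution onto a 2D mesh
#'
#' Deposits each component's weight into the 64x64 mesh cell containing its
#' coordinates in the chosen plane (nearest-cell deposition; coordinates
#' beyond the axis range are clipped to the edge cells), then normalizes the
#' mesh to unit mass. Diso, R1 and R2 axes are logarithmic over the sampling
#' ranges; the DDelta^2 axis is linear on [0, 1].
#'
#' @param v a \linkS4class{DRComponents} (typically consolidated).
#' @param plane one of \code{"diso_ddelta2"}, \code{"diso_r1"},
#'   \code{"diso_r2"}, \code{"ddelta2_r1"}, \code{"ddelta2_r2"}.
#' @param omega_ref angular frequency (rad/s) for the spectral coordinates.
#' @param n mesh cells per axis.
#' @return a \linkS4class{ProjectionMesh}.
#' @export
project2D <- function(v, plane = "diso_ddelta2", omega_ref = 2 * pi * 6.6,
                      n = 64L) {
  comps <- components(v)
  axes <- planeAxes(plane)
  sh <- componentSpectralShape(comps, omega_ref)
  coord <- function(ax) switch(ax,
    d_iso = sh$d_iso, d_delta_sq = sh$d_delta_sq,
    r1 = comps[, "r1"], r2 = comps[, "r2"])
  cellIndex <- function(ax, x) {
    spec <- meshAxisSpec(ax)
    br <- if (spec$log) seq(log10(spec$range[1]), log10(spec$range[2]),
                            length.out = n + 1)
          else seq(spec$range[1], spec$range[2], length.out = n + 1)
    xx <- if (spec$log) log10(pmax(x, 1e-300)) else x
    pmin(pmax(findInterval(xx, br, rightmost.closed = TRUE), 1L), n)
  }
  ix <- cellIndex(axes[1], coord(axes[1]))
  iy <- cellIndex(axes[2], coord(axes[2]))
  grid <- matrix(0, n, n)
  w <- comps[, "weight"]
  for (i in seq_along(w)) grid[ix[i], iy[i]] <- grid[ix[i], iy[i]] + w[i]
  if (sum(grid) > 0) grid <- grid / sum(grid)
  mkBreaks <- function(ax) {
    spec <- meshAxisSpec(ax)
    if (spec$log) seq(log10(spec$range[1]), log10(spec$range[2]),
                      length.out = n + 1)
    else seq(spec$range[1], spec$range[2], length.out = n + 1)
  }
  new("ProjectionMesh", grid = grid, plane = plane,
      xbreaks = mkBreaks(axes[1]), ybreaks = mkBreaks(axes[2]),
      xlog = meshAxisSpec(axes[1])$log, ylog = meshAxisSpec(axes[2])$log)
}

#' ROI-characteristic distribution
#'
#' Averages per-voxel projection meshes into one characteristic mesh for a
#' region of interest: within each scan the voxel meshes are summed and
#' normalized, then the normalized per-scan meshes are averaged across
#' scans.
#'
#' @param meshes list of \linkS4class{ProjectionMesh} (one per ROI voxel,
#'   over all scans).
#' @param scan integer/character vector assigning each mesh to a scan.
#' @return a \linkS4class{ProjectionMesh}.
#' @export
roiCharacteristicDistribution <- function(meshes, scan) {
  if (length(meshes) == 0) stop("empty ROI: no meshes to average")
  stopifnot(length(meshes) == length(scan))
  proto <- meshes[[1]]
  per_scan <- lapply(split(seq_along(meshes), scan), function(idx) {
    g <- Reduce(`+`, lapply(meshes[idx], function(m) m@grid))
    if (sum(g) > 0) g / sum(g) else g
  })
  avg <- Reduce(`+`, per_scan) / length(per_scan)
  new("ProjectionMesh", grid = avg, plane = proto@plane,
      xbreaks = proto@xbreaks, ybreaks = proto@ybreaks,
      xlog = proto@xlog, ylog = proto@ylog)
}
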