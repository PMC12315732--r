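#' Spectral bin definition
#'
#' The three regions of the (Diso, DDelta^2) plane whose integrated weights
#' give the spectral-bin signal fractions: bin 1 (roughly white matter)
#' Diso < 2.5 um^2/ms and DDelta^2 > 0.25; bin 2 (roughly gray matter)
#' Diso < 2.5 and DDelta^2 < 0.25; bin 3 (roughly CSF / free water)
#' Diso > 2.5. Boundary values are assigned to the lower-index region
#' (Diso = 2.5 belongs to bins 1/2; DDelta^2 = 0.25 belongs to bin 2), so
#' the regions partition the plane and the fractions always sum to 1.
#'
#' @param diso_split Diso threshold (um^2/ms).
#' @param ddelta_sq_split DDelta^2 threshold.
#' @param omega_eval angular frequency (rad/s) at which Diso and DDelta^2
#'   are evaluated; default the lowest protocol frequency, 2 pi 6.6.
#' @return a list of class \code{"BinDefinition"}.
#' @export
binDefinition <- function(diso_split = 2.5, ddelta_sq_split = 0.25,
                          omega_eval = 2 * pi * 6.6) {
  structure(list(diso_split = diso_split, ddelta_sq_split = ddelta_sq_split,
                 omega_eval = omega_eval), class = "BinDefinition")
}

# bin index (1, 2, 3) per component at the bin evaluation frequency;
# boundary values go to the lower-index region (with a relative epsilon so
# exact-boundary components are not flipped by rounding)
binAssign <- function(comps, bins) {
  sh <- componentSpectralShape(comps, bins$omega_eval)
  eps <- 1e-9
  ifelse(sh$d_iso > bins$diso_split * (1 + eps), 3L,
         ifelse(sh$d_delta_sq > bins$ddelta_sq_split * (1 + eps), 1L, 2L))
}

#' Spectral-bin signal fractions
#'
#' Normalized component-weight sums over the three (Diso, DDelta^2) bins,
#' evaluated at the bin definition's frequency.
#'
#' @param v a \linkS4class{DRComponents} distribution.
#' @param bins a \code{\link{binDefinition}}.
#' @return numeric vector \code{c(fbin1, fbin2, fbin3)} summing to 1, or
#'   all-NA if the total weight is zero.
#' @export
binFractions <- function(v, bins = binDefinition()) {
  comps <- components(v)
  tot <- sum(comps[, "weight"])
  if (nrow(comps) == 0 || tot <= 0)
    return(c(fbin1 = NA_real_, fbin2 = NA_real_, fbin3 = NA_real_))
  idx <- binAssign(comps, bins)
  f <- vapply(1:3, function(b) sum(comps[idx == b, "weight"]) / tot,
              numeric(1))
  names(f) <- c("fbin1", "fbin2", "fbin3")
  f
}

#' Bin-resolved relaxation means
#'
#' Weight-weighted means of R1 and R2 restricted to the components of each
#' spectral bin. Empty bins yield NA (never zero).
#'
#' @param v a \linkS4class{DRComponents} distribution.
#' @param bins a \code{\link{binDefinition}}.
#' @return named numeric vector \code{er1_bin1..3, er2_bin1..3}.
#' @export
binResolvedRelaxation <- function(v, bins = binDefinition()) {
  comps <- components(v)
  idx <- if (nrow(comps)) binAssign(comps, bins) else integer(0)
  out <- rep(NA_real_, 6)
  names(out) <- c(paste0("er1_bin", 1:3), paste0("er2_bin", 1:3))
  for (b in 1:3) {
    m <- idx == b
    w <- comps[m, "weight"]
    if (any(m) && sum(w) > 0) {
      out[paste0("er1_bin", b)] <- sum(comps[m, "r1"] * w) / sum(w)
      out[paste0("er2_bin", b)] <- sum(comps[m, "r2"] * w) / sum(w)
    }
  }
  out
}

# per-solution scalar statistics at the two window endpoints
solutionStatistics <- function(comps, omega_low, omega_high, bins) {
  w <- comps[, "weight"]
  tot <- sum(w)
  if (nrow(comps) == 0 || tot <= 0) return(NULL)
  lo <- componentSpectralShape(comps, omega_low)
  hi <- componentSpectralShape(comps, omega_high)
  ew <- function(x) sum(x * w) / tot
  v <- new("DRComponents", params = comps)
  c(e_diso = ew(lo$d_iso), e_ddelta_sq = ew(lo$d_delta_sq),
    e_r1 = ew(comps[, "r1"]), e_r2 = ew(comps[, "r2"]),
    d_diso = ew(hi$d_iso) - ew(lo$d_iso),
    d_ddelta_sq = ew(hi$d_delta_sq) - ew(lo$d_delta_sq),
    binFractions(v, bins), binResolvedRelaxation(v, bins),
    total_weight = tot)
}

#' Per-voxel scalar statistics (median over bootstraps)
#'
#' Reduces a voxel's bootstrap solutions to the scalar map values: for each
#' bootstrap the weight-weighted means E[Diso], E[DDelta^2] (evaluated at
#' \code{omega_low}), E[R1], E[R2], the frequency-dependence differences
#' between the window endpoints (value at \code{omega_high} minus value at
#' \code{omega_low}), the spectral-bin fractions and the bin-resolved
#' relaxation means; the map value of every statistic is the median over
#' bootstrap replicas (bin-resolved means over the replicas where the bin
#' is occupied).
#'
#' @param result a \linkS4class{VoxelInversionResult}.
#' @param omega_low,omega_high window endpoints in rad/s (defaults
#'   2 pi 6.6 and 2 pi 21).
#' @param bins a \code{\link{binDefinition}}.
#' @return named numeric vector of 16 statistics (including
#'   \code{total_weight}); all-NA if no solution has positive weight.
#' @export
voxelStatistics <- function(result, omega_low = 2 * pi * 6.6,
                            omega_high = 2 * pi * 21,
                            bins = binDefinition()) {
  stats_list <- lapply(result@solutions, function(s)
    solutionStatistics(s@params, omega_low, omega_high, bins))
  stats_list <- stats_list[!vapply(stats_list, is.null, logical(1))]
  nm <- c("e_diso", "e_ddelta_sq", "e_r1", "e_r2", "d_diso", "d_ddelta_sq",
          "fbin1", "fbin2", "fbin3", paste0("er1_bin", 1:3),
          paste0("er2_bin", 1:3), "total_weight")
  if (length(stats_list) == 0)
    return(structure(rep(NA_real_, length(nm)), names = nm))
  M <- do.call(rbind, stats_list)
  apply(M[, nm, drop = FALSE], 2, median, na.rm = TRUE)
}

#' Parameter maps from per-voxel inversion results
#'
#' Applies \code{\link{voxelStatistics}} to a list of voxel results and
#' arranges each statistic as a volume.
#'
#' @param results list of \linkS4class{VoxelInversionResult} in voxel order.
#' @param dims integer volume dimensions; \code{prod(dims)} may exceed the
#'   number of results if \code{voxel_index} maps results into the volume.
#' @param voxel_index optional linear indices of each result's voxel.
#' @param ... passed to \code{\link{voxelStatistics}}.
#' @return named list of 3D arrays, one per statistic.
#' @export
computeParameterMaps <- function(results, dims, voxel_index = NULL, ...) {
  if (is.null(voxel_index)) voxel_index <- seq_along(results)
  stats0 <- voxelStatistics(results[[1]], ...)
  maps <- lapply(stats0, function(x) array(NA_real_, dims))
  for (i in seq_along(results)) {
    st <- voxelStatistics(results[[i]], ...)
    for (nm in names(st)) maps[[nm]][voxel_index[i]] <- st[[nm]]
  }
  maps
}

#' Majority-vote template ROI
#'
#' Builds a template region from per-scan ROI masks: a voxel belongs to the
#' template when at least the given fraction of the scans label it
#' (>= 50% agreement by default).
#'
#' @param masks list of logical/0-1 arrays of identical dimensions.
#' @param min_agreement minimum labelling fraction.
#' @return logical array.
#' @export
majorityVoteROI <- function(masks, min_agreement = 0.5) {
  stopifnot(length(masks) >= 1)
  s <- Reduce(`+`, lapply(masks, function(m) array(as.numeric(m != 0), dim(m))))
  s / length(masks) >= min_agreement
}

#' ROI mean with CSF exclusion
#'
#' Mean of a parameter map over each ROI label after removing voxels whose
#' estimated CSF signal fraction exceeds the threshold (fbin3 > 0.2 by
#' default).
#'
#' @param map_volume numeric array.
#' @param roi_labels integer array of ROI labels (0 = none).
#' @param fbin3_volume CSF signal-fraction array aligned with the map, or
#'   NULL to skip the exclusion.
#' @param fbin3_max exclusion threshold.
#' @return named numeric vector of per-ROI means; NA (with a message) for
#'   ROIs empty after filtering.
#' @export
roiReduce <- function(map_volume, roi_labels, fbin3_volume = NULL,
                      fbin3_max = 0.2) {
  stopifnot(all(dim(map_volume) == dim(roi_labels)))
  keep <- if (is.null(fbin3_volume)) rep(TRUE, length(map_volume))
          else !(fbin3_volume > fbin3_max) | is.na(fbin3_volume)
  labs <- sort(unique(roi_labels[roi_labels > 0]))
  out <- vapply(labs, function(l) {
    m <- roi_labels == l & keep
    if (!any(m, na.rm = TRUE)) {
      message("ROI ", l, " empty after CSF-fraction filtering")
      return(NA_real_)
    }
    mean(map_volume[m], na.rm = TRUE)
  }, numeric(1))
  names(out) <- as.character(labs)
  out
}
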