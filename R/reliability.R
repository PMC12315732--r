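#' Classify an ICC value
#'
#' Standard interpretation bands: poor (< 0.5), moderate [0.5, 0.75), good
#' [0.75, 0.9), excellent (>= 0.9).
#'
#' @param icc numeric ICC value.
#' @return character classification.
#' @export
classifyICC <- function(icc) {
  ifelse(icc < 0.5, "poor",
         ifelse(icc < 0.75, "moderate",
                ifelse(icc < 0.9, "good", "excellent")))
}

#' ICC(A,1): single-measurement absolute-agreement intraclass correlation
#'
#' Two-way ANOVA decomposition of an n subjects x k sessions table into
#' subject (rows), session (columns) and error mean squares, combined as
#' ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#' The raw value is returned together with a zero-clamped companion
#' (negative estimates are treated as zeros in summaries) and the
#' classification of the clamped value.
#'
#' @param values numeric matrix, subjects in rows, sessions in columns
#'   (n >= 2, k >= 2, finite).
#' @return list with \code{icc} (raw), \code{icc_clamped},
#'   \code{category}, and the mean squares \code{msr}, \code{msc},
#'   \code{mse}. \code{icc} is NA when the table has zero total variance.
#' @examples
#' iccA1(cbind(c(1, 2, 3), c(2, 3, 4)))$icc   # 2/3
#' @export
iccA1 <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 2, k >= 2, all(is.finite(values)))
  grand <- mean(values)
  row_m <- rowMeans(values)
  col_m <- colMeans(values)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((values - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (sst == 0 || denom == 0)
    return(list(icc = NA_real_, icc_clamped = NA_real_,
                category = NA_character_, msr = msr, msc = msc, mse = mse))
  icc <- (msr - mse) / denom
  cl <- max(0, icc)
  list(icc = icc, icc_clamped = cl, category = classifyICC(cl),
       msr = msr, msc = msc, mse = mse)
}

#' Within-subject coefficient of variation
#'
#' CVws = sqrt(within-subject mean squares) / |grand mean|, the repeatability
#' measure; 0 indicates perfect repeatability. The absolute value of the
#' mean is used because some map parameters (the frequency-dependence
#' differences) can be negative.
#'
#' @param values numeric matrix, subjects in rows, sessions in columns.
#' @return CVws as a dimensionless fraction (multiply by 100 for %).
#' @examples
#' cvWS(cbind(c(1, 2, 3), c(2, 3, 4)))   # sqrt(0.5)/2.5
#' @export
cvWS <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  stopifnot(n >= 2, k >= 2, all(is.finite(values)))
  grand <- mean(values)
  if (grand == 0)
    stop("grand mean is zero: CVws normalization is degenerate")
  msws <- sum((values - rowMeans(values))^2) / (n * (k - 1))
  sqrt(msws) / abs(grand)
}

#' Bland-Altman agreement summary
#'
#' Mean test-retest difference (bias), its 1.96 SD limits of agreement, and
#' the relative mean difference as a percentage of the grand mean over all
#' entries.
#'
#' @param test,retest numeric vectors of paired measurements.
#' @return list with \code{mean_difference}, \code{ci_low}, \code{ci_high},
#'   \code{sd_difference}, \code{relative_mean_difference_pct}.
#' @examples
#' blandAltman(c(1, 2), c(2, 3))   # bias -1, relative -50%
#' @export
blandAltman <- function(test, retest) {
  if (length(test) != length(retest))
    stop("test and retest vectors must have equal length")
  d <- test - retest
  bias <- mean(d)
  s <- if (length(d) > 1) sd(d) else 0
  grand <- mean(c(test, retest))
  list(mean_difference = bias,
       ci_low = bias - 1.96 * s, ci_high = bias + 1.96 * s,
       sd_difference = s,
       relative_mean_difference_pct = 100 * bias / grand)
}

#' Trim sparse tails of a CVws distribution
#'
#' Iteratively removes values lying in histogram bins holding less than a
#' given fraction (0.1% by default) of the current number of values, using
#' automatic bin selection (Freedman-Diaconis width, falling back to Sturges
#' for tiny samples). Applied only when the distribution contains values
#' above 1.0 (100%); otherwise returned unchanged.
#'
#' @param values numeric vector of CVws values (fractions).
#' @param density_frac bin-occupancy threshold as a fraction of the total.
#' @param max_iter iteration cap.
#' @return list with \code{values} (surviving entries) and \code{n_removed}.
#' @export
trimCVDistribution <- function(values, density_frac = 0.001,
                               max_iter = 100L) {
  values <- values[is.finite(values)]
  n0 <- length(values)
  if (n0 == 0 || max(values) <= 1)
    return(list(values = values, n_removed = 0L))
  for (it in seq_len(max_iter)) {
    n <- length(values)
    nb <- tryCatch(grDevices::nclass.FD(values), error = function(e) NA)
    if (!is.finite(nb) || nb < 1 || n < 8) nb <- grDevices::nclass.Sturges(values)
    h <- graphics::hist(values, breaks = nb, plot = FALSE)
    counts <- h$counts
    sparse <- counts > 0 & counts < density_frac * n
    if (!any(sparse)) break
    bin <- findInterval(values, h$breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    values <- values[!sparse[bin]]
    if (length(values) == 0) break
  }
  list(values = values, n_removed = n0 - length(values))
}

# dense band matrix applying a truncated 1D Gaussian along one axis
gaussBandMatrix <- function(n, sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(truncate * sigma_vox))
  kern <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  kern <- kern / sum(kern)
  M <- matrix(0, n, n)
  for (o in -r:r) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- kern[o + r + 1]
  }
  M
}

applyAlongAxis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  x <- aperm(arr, perm)
  dp <- dim(x)
  y <- M %*% matrix(x, nrow = d[axis])
  dim(y) <- dp
  aperm(y, order(perm))
}

#' Mask-aware Gaussian smoothing
#'
#' Smooths a volume with a separable Gaussian kernel of the given FWHM
#' (sigma = FWHM / (2 sqrt(2 ln 2)), truncated at 4 sigma) while excluding
#' any signal contribution from outside the mask: the result inside the
#' mask is (K * (v m)) / (K * m), which leaves constants exactly unchanged
#' under arbitrary masks; voxels outside the mask are set to NA.
#'
#' @param volume numeric 3D array.
#' @param mask logical/0-1 array of the same dimensions.
#' @param fwhm_mm kernel full width at half maximum (mm); must be positive.
#' @param voxel_size_mm voxel edge lengths (mm), scalar or length 3.
#' @return smoothed array (NA outside the mask).
#' @export
gaussianSmoothMasked <- function(volume, mask, fwhm_mm, voxel_size_mm = 2) {
  if (fwhm_mm <= 0) stop("FWHM must be positive")
  stopifnot(all(dim(volume) == dim(mask)))
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  m <- array(as.numeric(mask != 0), dim(mask))
  v <- volume
  v[m == 0 | is.na(v)] <- 0
  num <- v * m
  den <- m
  for (ax in 1:3) {
    M <- gaussBandMatrix(dim(volume)[ax], sigma_mm / voxel_size_mm[ax])
    num <- applyAlongAxis(num, M, ax)
    den <- applyAlongAxis(den, M, ax)
  }
  out <- array(NA_real_, dim(volume))
  inside <- m != 0 & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

#' Voxel-wise reliability maps and FWHM sweep
#'
#' Computes voxel-wise ICC(A,1) and CVws over a cohort of aligned parameter
#' volumes, optionally after mask-aware Gaussian smoothing, and supports
#' sweeping the smoothing FWHM to examine the median voxel-wise ICC as a
#' function of kernel width.
#'
#' @param volumes nested list \code{volumes[[subject]][[session]]} of
#'   aligned 3D arrays.
#' @param mask logical array of in-brain voxels.
#' @param fwhm_mm smoothing FWHM in mm (0 = none), possibly a vector for a
#'   sweep.
#' @param voxel_size_mm voxel size in mm.
#' @return for a single FWHM: list with \code{icc}, \code{cv} arrays and
#'   \code{median_icc}, \code{median_cv}; for a vector FWHM: data.frame of
#'   the medians per FWHM.
#' @export
voxelwiseReliability <- function(volumes, mask, fwhm_mm = 0,
                                 voxel_size_mm = 2) {
  if (length(fwhm_mm) > 1) {
    rows <- lapply(fwhm_mm, function(f) {
      r <- voxelwiseReliability(volumes, mask, f, voxel_size_mm)
      data.frame(fwhm_mm = f, median_icc = r$median_icc,
                 median_cv = r$median_cv)
    })
    return(do.call(rbind, rows))
  }
  n <- length(volumes); k <- length(volumes[[1]])
  sm <- lapply(volumes, function(subj) lapply(subj, function(vol) {
    if (fwhm_mm > 0) gaussianSmoothMasked(vol, mask, fwhm_mm, voxel_size_mm)
    else vol
  }))
  idx <- which(mask != 0)
  icc_map <- array(NA_real_, dim(mask))
  cv_map <- array(NA_real_, dim(mask))
  tab <- matrix(0, n, k)
  for (vx in idx) {
    for (i in seq_len(n)) for (j in seq_len(k)) tab[i, j] <- sm[[i]][[j]][vx]
    if (!all(is.finite(tab))) next
    icc_map[vx] <- iccA1(tab)$icc
    grand <- mean(tab)
    cv_map[vx] <- if (grand != 0) cvWS(tab) else NA_real_
  }
  list(icc = icc_map, cv = cv_map,
       median_icc = median(icc_map[idx], na.rm = TRUE),
       median_cv = median(cv_map[idx], na.rm = TRUE))
}
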