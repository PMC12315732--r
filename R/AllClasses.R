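#' Tensor-valued encoding power spectrum
#'
#' Frequency-resolved representation of one diffusion-encoding waveform: a
#' 3x3 symmetric spectral density tensor per angular-frequency sample whose
#' integral over frequency is the time-domain b-tensor.
#'
#' @slot omega numeric vector of angular frequency samples (rad/s),
#'   strictly increasing, typically symmetric about zero.
#' @slot density 3x3xN array; \code{density[,,k]} is the positive
#'   semidefinite spectral density tensor at \code{omega[k]}
#'   (ms/um^2 per rad/s).
#' @slot btensor 3x3 symmetric total b-tensor (ms/um^2).
#'
#' @export
setClass("BTensorSpectrum",
  representation(omega = "numeric", density = "array", btensor = "matrix"))

setValidity("BTensorSpectrum", function(object) {
  msgs <- character()
  n <- length(object@omega)
  if (!all(dim(object@density) == c(3, 3, n)))
    msgs <- c(msgs, "density must be a 3x3xlength(omega) array")
  if (n > 1 && any(diff(object@omega) <= 0))
    msgs <- c(msgs, "omega must be strictly increasing")
  if (length(msgs)) return(msgs)
  # frequency integral must reproduce the b-tensor
  B <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    B[i, j] <- trapzQuad(object@omega, object@density[i, j, ])
  nb <- sqrt(sum(object@btensor^2))
  if (nb > 0 && sqrt(sum((B - object@btensor)^2)) / nb > 1e-6)
    msgs <- c(msgs, "integral of density over omega does not match btensor")
  # spot-check positive semidefiniteness on a subsample of grid points
  idx <- unique(round(seq(1, n, length.out = min(n, 16))))
  for (k in idx) {
    ev <- eigen(object@density[, , k], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9 * max(abs(ev), 1e-300))
      msgs <- c(msgs, sprintf("density not PSD at omega[%d]", k))
  }
  if (length(msgs)) msgs else TRUE
})

#' Acquisition protocol for diffusion-relaxation MD-MRI
#'
#' Ordered table of measurements, each defined by b-tensor magnitude \code{b}
#' (ms/um^2), normalized anisotropy \code{b_delta} (-0.5 planar, 0 spherical,
#' 1 linear), symmetry-axis direction, centroid frequency of the encoding
#' spectrum (Hz, NA for b = 0), echo time (ms) and repetition time (s).
#' Full gridded spectra may be attached per measurement via
#' \code{spectrum_id}; otherwise the narrow-band (centroid frequency)
#' representation is used.
#'
#' @slot table data.frame with columns \code{b_ms_per_um2, b_delta, dir_x,
#'   dir_y, dir_z, f_cent_hz, te_ms, tr_s, spectrum_id}.
#' @slot spectra named list of \linkS4class{BTensorSpectrum}, keyed by
#'   \code{spectrum_id}.
#' @slot metadata free-form provenance list.
#'
#' @export
setClass("AcquisitionProtocol",
  representation(table = "data.frame", spectra = "list", metadata = "list"))

protocolColumns <- c("b_ms_per_um2", "b_delta", "dir_x", "dir_y", "dir_z",
                     "f_cent_hz", "te_ms", "tr_s", "spectrum_id")

setValidity("AcquisitionProtocol", function(object) {
  tb <- object@table
  msgs <- character()
  if (!all(protocolColumns %in% names(tb)))
    msgs <- c(msgs, "missing protocol columns")
  else {
    if (!any(tb$b_ms_per_um2 == 0))
      msgs <- c(msgs, "protocol must contain at least one b = 0 measurement")
    if (any(tb$b_ms_per_um2 < 0)) msgs <- c(msgs, "b must be >= 0")
    if (any(tb$te_ms <= 0) || any(tb$tr_s <= 0))
      msgs <- c(msgs, "TE and TR must be positive")
    dwi <- tb$b_ms_per_um2 > 0
    nrm <- sqrt(tb$dir_x^2 + tb$dir_y^2 + tb$dir_z^2)
    if (any(abs(nrm[dwi] - 1) > 1e-6))
      msgs <- c(msgs, "directions of diffusion-weighted rows must be unit vectors")
    if (any(tb$b_delta < -0.5 - 1e-9 | tb$b_delta > 1 + 1e-9))
      msgs <- c(msgs, "b_delta must lie in [-0.5, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Discrete diffusion-relaxation distribution components
#'
#' A voxel's nonparametric D(omega)-R1-R2 distribution as a weighted set of
#' axisymmetric Lorentzian components. Each row holds the zero-frequency
#' axial/radial diffusivities (um^2/ms), orientation angles (rad), the
#' high-frequency isotropic diffusivity D0 (um^2/ms), axial/radial
#' transition frequencies (rad/s), relaxation rates R1, R2 (1/s) and a
#' non-negative signal weight.
#'
#' @slot params numeric matrix with columns \code{d_par, d_perp, theta, phi,
#'   d0, gamma_par, gamma_perp, r1, r2, weight}.
#'
#' @export
setClass("DRComponents", representation(params = "matrix"))

setValidity("DRComponents", function(object) {
  p <- object@params
  if (!identical(colnames(p), compColumns))
    return("params must have the canonical component columns")
  if (nrow(p) == 0) return(TRUE)
  if (any(p[, c("d_par", "d_perp", "d0")] <= 0))
    return("diffusivities must be positive")
  if (any(p[, c("gamma_par", "gamma_perp", "r1", "r2")] <= 0))
    return("transition frequencies and relaxation rates must be positive")
  if (any(p[, "weight"] < 0)) return("weights must be non-negative")
  TRUE
})

#' Per-voxel Monte Carlo inversion result
#'
#' The set of bootstrap replicate solutions of the voxel's D(omega)-R1-R2
#' distribution, with the final fit residual of each replicate and the
#' per-generation residual trace of the quasi-genetic refinement.
#'
#' @slot solutions list of \linkS4class{DRComponents}, one per bootstrap.
#' @slot residuals numeric vector of final residual norms, one per bootstrap.
#' @slot residual_trace list of per-generation residual vectors.
#'
#' @export
setClass("VoxelInversionResult",
  representation(solutions = "list", residuals = "numeric",
                 residual_trace = "list"))

setValidity("VoxelInversionResult", function(object) {
  if (length(object@solutions) != length(object@residuals))
    return("one residual per bootstrap solution required")
  TRUE
})

#' 2D spectral projection mesh
#'
#' A 64x64 (by default) normalized weight mesh over one 2D projection plane
#' of the D(omega)-R1-R2 distribution.
#'
#' @slot grid numeric matrix of non-negative cell weights summing to 1.
#' @slot plane character, one of \code{"diso_ddelta2"}, \code{"diso_r1"},
#'   \code{"diso_r2"}, \code{"ddelta2_r1"}, \code{"ddelta2_r2"}.
#' @slot xbreaks,ybreaks cell edge vectors (length ncell + 1), on log10
#'   scale where the axis is logarithmic.
#' @slot xlog,ylog logical axis-scale flags.
#'
#' @export
setClass("ProjectionMesh",
  representation(grid = "matrix", plane = "character",
                 xbreaks = "numeric", ybreaks = "numeric",
                 xlog = "logical", ylog = "logical"))

setValidity("ProjectionMesh", function(object) {
  if (any(object@grid < 0)) return("mesh weights must be non-negative")
  s <- sum(object@grid)
  if (s > 0 && abs(s - 1) > 1e-9) return("mesh must be normalized to sum 1")
  if (length(object@xbreaks) != nrow(object@grid) + 1 ||
      length(object@ybreaks) != ncol(object@grid) + 1)
    return("break vectors must bound the grid cells")
  TRUE
})

#' Synthetic test-retest cohort
#'
#' Signals and ground truth for a simulated multi-subject, multi-session
#' phantom acquisition.
#'
#' @slot signals nested list \code{signals[[subject]][[session]]}: numeric
#'   matrix (voxels x measurements).
#' @slot labels integer 3D array of tissue region labels (0 = background).
#' @slot truth list per subject of per-region \linkS4class{DRComponents}
#'   (ground-truth distributions after subject perturbation).
#' @slot truth_maps named list of ground-truth parameter volumes for
#'   subject-average (unperturbed) archetypes.
#' @slot protocol the \linkS4class{AcquisitionProtocol} used.
#' @slot spec the generating cohort specification (list).
#'
#' @export
setClass("CohortDataset",
  representation(signals = "list", labels = "array", truth = "list",
                 truth_maps = "list", protocol = "AcquisitionProtocol",
                 spec = "list"))
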