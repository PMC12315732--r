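#' Tissue archetypes for the synthetic phantom
#'
#' Default pure-tissue voxel compositions used by the phantom generator.
#' Each archetype is a small multicomponent distribution chosen to land in
#' the expected spectral bin and inside the inversion sampling ranges:
#' \itemize{
#'   \item WM-like: a dominant anisotropic component (D_par 1.6, D_perp
#'     0.25 um^2/ms, Diso 0.7, DDelta^2 ~ 0.41, R1 0.6, R2 15) plus a minor
#'     low-anisotropy component;
#'   \item GM-like: a single low-anisotropy component (Diso ~ 0.8,
#'     DDelta^2 ~ 0.05, R1 0.45, R2 11);
#'   \item CSF-like: fast nearly isotropic free water (Diso 3.0,
#'     DDelta^2 ~ 0.005, R1 0.25, R2 2);
#'   \item mixed: 0.5 WM + 0.35 GM + 0.15 CSF by weight.
#' }
#' Restriction is encoded by D0 above the zero-frequency diffusivities with
#' transition frequencies inside or just above the 6.6-21 Hz window (in
#' rad/s), so the
#' anisotropy decreases and the isotropic diffusivity increases with
#' frequency in the WM- and GM-like tissues.
#'
#' @return named list of \linkS4class{DRComponents} (weights sum to 1).
#' @export
tissueArchetypes <- function() {
  wm <- drComponents(
    d_par = c(1.6, 0.9), d_perp = c(0.25, 0.7),
    theta = c(0.3, 1.1), phi = c(1.0, 2.5),
    d0 = c(1.8, 1.1), gamma_par = c(200, 60), gamma_perp = c(200, 60),
    r1 = c(0.6, 0.5), r2 = c(15, 12), weight = c(0.85, 0.15))
  gm <- drComponents(
    d_par = 1.158, d_perp = 0.621, theta = 1.2, phi = 4.0,
    d0 = 1.2, gamma_par = 70, gamma_perp = 70,
    r1 = 0.45, r2 = 11, weight = 1)
  csf <- drComponents(
    d_par = 3.424, d_perp = 2.788, theta = 0.7, phi = 0.5,
    d0 = 3.0, gamma_par = 50, gamma_perp = 50,
    r1 = 0.25, r2 = 2, weight = 1)
  mixed <- new("DRComponents", params = {
    p <- rbind(wm@params, gm@params, csf@params)
    p[, "weight"] <- p[, "weight"] * c(0.5, 0.5, 0.35, 0.15)
    p
  })
  list(wm = wm, gm = gm, csf = csf, mixed = mixed)
}

#' Cohort specification
#'
#' Shape, noise and variability settings of the synthetic test-retest
#' cohort: 10 subjects scanned twice, Rician session noise at SNR 50
#' (referenced to the b = 0, longest-TR, shortest-TE condition), and 5%
#' multiplicative log-normal between-subject spread on diffusivities,
#' transition frequencies and relaxation rates.
#'
#' @param n_subjects,n_sessions cohort shape (both >= 2).
#' @param dims phantom label-volume dimensions (4 x-slabs of tissue:
#'   WM, GM, CSF, mixed).
#' @param snr signal-to-noise ratio at the reference condition (Inf for
#'   noiseless).
#' @param noise_model \code{"rician"} or \code{"gaussian"}.
#' @param subject_cv between-subject log-normal sigma on scale parameters
#'   (0 disables subject variability).
#' @param seed master seed.
#' @return list of class \code{"CohortSpec"}.
#' @export
cohortSpec <- function(n_subjects = 10L, n_sessions = 2L,
                       dims = c(8L, 4L, 2L), snr = 50,
                       noise_model = c("rician", "gaussian"),
                       subject_cv = 0.05, seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_subjects >= 2, n_sessions >= 2, length(dims) == 3,
            all(dims >= c(4, 1, 1)), snr > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 dims = as.integer(dims), snr = snr,
                 noise_model = noise_model, subject_cv = subject_cv,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# deterministic slab geometry: the x axis is split into four equal slabs of
# WM (1), GM (2), CSF (3) and mixed (4) tissue
phantomLabels <- function(dims) {
  labels <- array(0L, dims)
  edges <- round(seq(0, dims[1], length.out = 5))
  for (r in 1:4)
    labels[(edges[r] + 1):edges[r + 1], , ] <- r
  labels
}

# ground-truth statistics of one distribution, via the map operators with a
# single trivial "bootstrap"
truthStatistics <- function(v, ...) {
  res <- new("VoxelInversionResult", solutions = list(v), residuals = 0,
             residual_trace = list(numeric(0)))
  voxelStatistics(res, ...)
}

#' Build the ground-truth phantom
#'
#' Deterministic label geometry (four tissue slabs: WM-like, GM-like,
#' CSF-like and mixed) with per-voxel ground-truth distributions from the
#' tissue archetypes, and ground-truth parameter maps computed through the
#' same statistics operators used on inversion output.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param archetypes archetype list as from \code{\link{tissueArchetypes}}.
#' @return list with \code{labels} (array), \code{distributions} (per-region
#'   \linkS4class{DRComponents}), \code{maps} (named list of truth volumes).
#' @export
buildPhantom <- function(spec = cohortSpec(),
                         archetypes = tissueArchetypes()) {
  labels <- phantomLabels(spec$dims)
  regions <- c("wm", "gm", "csf", "mixed")
  stats_by_region <- lapply(archetypes[regions], truthStatistics)
  nm <- names(stats_by_region[[1]])
  maps <- lapply(nm, function(s) {
    vol <- array(NA_real_, spec$dims)
    for (r in 1:4) vol[labels == r] <- stats_by_region[[r]][[s]]
    vol
  })
  names(maps) <- nm
  list(labels = labels, distributions = archetypes[regions], maps = maps)
}

# one subject's perturbed archetypes: a single multiplicative log-normal
# draw per scale parameter per component, shared across sessions
perturbArchetypes <- function(archetypes, subject_cv) {
  scale_cols <- c("d_par", "d_perp", "d0", "gamma_par", "gamma_perp",
                  "r1", "r2")
  lapply(archetypes, function(a) {
    p <- a@params
    for (cc in scale_cols)
      p[, cc] <- pmin(pmax(p[, cc] * exp(rnorm(nrow(p), 0, subject_cv)),
                           0.051), 4999)
    new("DRComponents", params = p)
  })
}

#' Add measurement noise to signals
#'
#' Default Rician model: each noisy signal is the magnitude of the complex
#' noiseless signal plus an independent zero-mean Gaussian pair of standard
#' deviation \code{ref_signal / snr}. A plain additive Gaussian option is
#' available.
#'
#' @param signals numeric vector/matrix of noiseless signals.
#' @param snr signal-to-noise ratio (Inf returns the input unchanged).
#' @param model \code{"rician"} or \code{"gaussian"}.
#' @param ref_signal reference amplitude defining the noise level (the
#'   phantom uses the mean b = 0, longest-TR, shortest-TE signal).
#' @return noisy signals, same shape as the input.
#' @export
addNoise <- function(signals, snr, model = c("rician", "gaussian"),
                     ref_signal = 1) {
  model <- match.arg(model)
  if (!is.finite(snr)) return(signals)
  sigma <- ref_signal / snr
  n <- length(signals)
  if (model == "rician") {
    out <- sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  } else {
    out <- signals + rnorm(n, 0, sigma)
  }
  if (!is.null(dim(signals))) dim(out) <- dim(signals)
  out
}

#' Simulate the test-retest cohort
#'
#' For every subject: draw the subject's archetype perturbation once (shared
#' across sessions); for every session: synthesize noiseless signals through
#' the forward model under the protocol, then add session noise. The noise
#' standard deviation is referenced to the cohort-mean signal at the b = 0,
#' longest-TR, shortest-TE measurement.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param archetypes archetype list (defaults to
#'   \code{\link{tissueArchetypes}}).
#' @return a \linkS4class{CohortDataset}.
#' @export
simulateCohort <- function(spec = cohortSpec(),
                           protocol = makeDefaultProtocol(spec$seed),
                           archetypes = tissueArchetypes()) {
  phantom <- buildPhantom(spec, archetypes)
  labels <- phantom$labels
  vox <- which(labels > 0)
  tb <- measurements(protocol)
  # reference condition: b = 0, longest TR, shortest TE
  b0 <- which(tb$b_ms_per_um2 == 0)
  ref_row <- b0[order(-tb$tr_s[b0], tb$te_ms[b0])][1]
  regions <- c("wm", "gm", "csf", "mixed")
  set.seed(subSeed(spec$seed, 999L))
  truth <- vector("list", spec$n_subjects)
  signals <- vector("list", spec$n_subjects)
  for (si in seq_len(spec$n_subjects)) {
    set.seed(subSeed(spec$seed, si))
    truth[[si]] <- perturbArchetypes(phantom$distributions, spec$subject_cv)
    clean <- sapply(regions, function(r) signalModel(truth[[si]][[r]], protocol))
    ref <- mean(clean[ref_row, ])
    signals[[si]] <- vector("list", spec$n_sessions)
    for (se in seq_len(spec$n_sessions)) {
      set.seed(subSeed(spec$seed, 10000L + si * 100L + se))
      S <- matrix(0, length(vox), nrow(tb))
      for (vi in seq_along(vox))
        S[vi, ] <- addNoise(clean[, labels[vox[vi]]], spec$snr,
                            spec$noise_model, ref)
      signals[[si]][[se]] <- S
    }
  }
  new("CohortDataset", signals = signals, labels = labels, truth = truth,
      truth_maps = phantom$maps, protocol = protocol, spec = unclass(spec))
}
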