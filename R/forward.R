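#' Frequency-dependent axis diffusivity (Lorentzian)
#'
#' One axis of the axisymmetric Lorentzian diffusion spectrum: the apparent
#' diffusivity rises from its zero-frequency value \code{d_zero} toward the
#' high-frequency isotropic diffusivity \code{d0} with corner (transition)
#' frequency \code{gamma},
#' D(omega) = d_zero + (d0 - d_zero) * omega^2 / (omega^2 + gamma^2).
#'
#' @param d_zero zero-frequency diffusivity (um^2/ms).
#' @param d0 high-frequency isotropic diffusivity (um^2/ms).
#' @param gamma transition frequency (rad/s).
#' @param omega angular frequency (rad/s), vectorized.
#' @return diffusivity in um^2/ms.
#' @examples
#' lorentzianAxis(0.5, 3, 100, c(0, 100, 1e9))  # 0.5, 1.75, ~3
#' @export
lorentzianAxis <- function(d_zero, d0, gamma, omega) {
  w2 <- omega^2
  d_zero + (d0 - d_zero) * w2 / (w2 + gamma^2)
}

# per-component axial/radial diffusivities, Diso and DDelta^2 at omega;
# comps: parameter matrix, omega: scalar (rad/s)
componentSpectralShape <- function(comps, omega) {
  col <- function(nm) as.vector(comps[, nm])
  dpar <- lorentzianAxis(col("d_par"), col("d0"), col("gamma_par"), omega)
  dperp <- lorentzianAxis(col("d_perp"), col("d0"), col("gamma_perp"), omega)
  diso <- (dpar + 2 * dperp) / 3
  ddelta <- (dpar - dperp) / (3 * diso)
  list(d_par = dpar, d_perp = dperp, d_iso = diso,
       d_delta = ddelta, d_delta_sq = ddelta^2)
}

#' Lab-frame diffusion tensor of a component at a frequency
#'
#' Evaluates the axial and radial Lorentzians of one component at angular
#' frequency omega and rotates the principal-frame tensor
#' diag(D_perp, D_perp, D_par) into the lab frame via the component's
#' (theta, phi) orientation. Also returns the isotropic diffusivity
#' Diso = (D_par + 2 D_perp)/3 and the squared normalized anisotropy
#' DDelta^2 with DDelta = (D_par - D_perp)/(3 Diso).
#'
#' @param comp one-row component matrix or named vector with the canonical
#'   component fields.
#' @param omega angular frequency (rad/s), scalar.
#' @return list with \code{tensor} (3x3), \code{d_iso}, \code{d_delta_sq}.
#' @export
componentTensorAt <- function(comp, omega) {
  if (is.null(dim(comp))) comp <- matrix(comp, 1, dimnames = list(NULL, names(comp)))
  sh <- componentSpectralShape(comp, omega)
  u <- drop(anglesToDir(comp[1, "theta"], comp[1, "phi"]))
  D <- diag(rep(sh$d_perp[1], 3)) +
    (sh$d_par[1] - sh$d_perp[1]) * tcrossprod(u)
  list(tensor = D, d_iso = sh$d_iso[1], d_delta_sq = sh$d_delta_sq[1])
}

#' Diffusion attenuation exponent of one component
#'
#' Evaluates beta = integral over omega of b(omega) : D_c(omega), the
#' generalized (Frobenius) inner product between the tensor-valued encoding
#' spectrum and the component's frequency-dependent diffusion tensor, by
#' trapezoidal quadrature on the spectrum's own grid. For a narrow-band
#' measurement (centroid-frequency representation) the closed form
#' beta = b * Diso(w) * (1 + 2 b_delta * DDelta(w) * P2(cos psi)) is used,
#' with psi the angle between the encoding and component symmetry axes.
#'
#' @param comp one-row component matrix or named vector.
#' @param spectrum a \linkS4class{BTensorSpectrum}, or a one-row measurement
#'   data.frame (protocol row) for the narrow-band path.
#' @return dimensionless attenuation exponent.
#' @export
attenuation <- function(comp, spectrum) {
  if (is.null(dim(comp))) comp <- matrix(comp, 1, dimnames = list(NULL, names(comp)))
  if (is(spectrum, "BTensorSpectrum")) {
    w <- spectrum@omega
    gmin <- min(comp[1, c("gamma_par", "gamma_perp")])
    if (length(w) > 1) {
      dw <- max(diff(w))
      span <- max(w) - min(w)
      if (gmin < span && dw > gmin / 2)
        warning("spectrum grid is coarse relative to the component's ",
                "transition frequency; attenuation quadrature may be inaccurate")
    }
    u <- drop(anglesToDir(comp[1, "theta"], comp[1, "phi"]))
    # b(w):D(w) = D_perp(w) tr b(w) + (D_par - D_perp)(w) u' b(w) u
    dpar <- lorentzianAxis(comp[1, "d_par"], comp[1, "d0"],
                           comp[1, "gamma_par"], abs(w))
    dperp <- lorentzianAxis(comp[1, "d_perp"], comp[1, "d0"],
                            comp[1, "gamma_perp"], abs(w))
    tr <- spectrum@density[1, 1, ] + spectrum@density[2, 2, ] +
      spectrum@density[3, 3, ]
    ubu <- numeric(length(w))
    for (i in 1:3) for (j in 1:3)
      ubu <- ubu + spectrum@density[i, j, ] * u[i] * u[j]
    return(trapzQuad(w, dperp * tr + (dpar - dperp) * ubu))
  }
  m <- spectrum
  b <- m$b_ms_per_um2
  if (b == 0) return(0)
  omega <- 2 * pi * m$f_cent_hz
  sh <- componentSpectralShape(comp, omega)
  u <- drop(anglesToDir(comp[1, "theta"], comp[1, "phi"]))
  cospsi <- sum(u * c(m$dir_x, m$dir_y, m$dir_z))
  b * sh$d_iso * (1 + 2 * m$b_delta * sh$d_delta * legendreP2(cospsi))
}

# design matrix of unit-weight forward signals: rows = measurements of
# `table` (protocol data.frame), columns = components. Narrow-band path,
# fully vectorized; the hot loop of the Monte Carlo inversion.
designMatrix <- function(comps, table) {
  nm <- nrow(table)
  na <- nrow(comps)
  omega <- 2 * pi * table$f_cent_hz
  omega[is.na(omega)] <- 0
  W2 <- matrix(omega^2, nm, na)
  rep_row <- function(v) matrix(v, nm, na, byrow = TRUE)
  dparm <- rep_row(comps[, "d_par"])
  dperpm <- rep_row(comps[, "d_perp"])
  d0m <- rep_row(comps[, "d0"])
  Dpar <- dparm + (d0m - dparm) * W2 / (W2 + rep_row(comps[, "gamma_par"])^2)
  Dperp <- dperpm + (d0m - dperpm) * W2 / (W2 + rep_row(comps[, "gamma_perp"])^2)
  Diso <- (Dpar + 2 * Dperp) / 3
  Ddelta <- (Dpar - Dperp) / (3 * Diso)
  U <- anglesToDir(comps[, "theta"], comps[, "phi"])
  cospsi <- cbind(table$dir_x, table$dir_y, table$dir_z) %*% t(U)
  beta <- table$b_ms_per_um2 * Diso *
    (1 + 2 * table$b_delta * Ddelta * legendreP2(cospsi))
  relax <- (1 - exp(-outer(table$tr_s, comps[, "r1"]))) *
    exp(-outer(table$te_ms / 1000, comps[, "r2"]))
  exp(-beta) * relax
}

#' Multicomponent diffusion-relaxation signal
#'
#' Evaluates the forward signal model
#' S = sum_c f_c exp(-int b(omega):D_c(omega) domega)
#'     (1 - exp(-TR R1_c)) exp(-TE R2_c)
#' for every measurement of a protocol.
#'
#' @param v a \linkS4class{DRComponents} voxel distribution.
#' @param protocol an \linkS4class{AcquisitionProtocol} (narrow-band
#'   evaluation via each measurement's centroid frequency).
#' @return numeric vector of signals, one per measurement.
#' @examples
#' comps <- drComponents(d_par = 1.6, d_perp = 0.3, theta = 0, phi = 0,
#'                       d0 = 1.8, gamma_par = 80, gamma_perp = 80,
#'                       r1 = 0.6, r2 = 15, weight = 1)
#' prot <- makeDefaultProtocol(1)
#' s <- signalModel(comps, prot)
#' @export
signalModel <- function(v, protocol) {
  comps <- components(v)
  if (nrow(comps) == 0) return(rep(0, nrow(measurements(protocol))))
  drop(designMatrix(comps, measurements(protocol)) %*% comps[, "weight"])
}

#' Construct a component set
#'
#' Convenience constructor for \linkS4class{DRComponents}; arguments are
#' recycled to a common length.
#'
#' @param d_par,d_perp zero-frequency axial/radial diffusivities (um^2/ms).
#' @param theta,phi orientation angles (rad).
#' @param d0 high-frequency isotropic diffusivity (um^2/ms).
#' @param gamma_par,gamma_perp transition frequencies (rad/s).
#' @param r1,r2 relaxation rates (1/s).
#' @param weight non-negative signal weights.
#' @return a \linkS4class{DRComponents}.
#' @export
drComponents <- function(d_par, d_perp, theta = 0, phi = 0, d0 = d_par,
                         gamma_par = 50, gamma_perp = 50, r1 = 0.5, r2 = 10,
                         weight = 1) {
  p <- cbind(d_par = d_par, d_perp = d_perp, theta = theta, phi = phi,
             d0 = d0, gamma_par = gamma_par, gamma_perp = gamma_perp,
             r1 = r1, r2 = r2, weight = weight)
  colnames(p) <- compColumns
  new("DRComponents", params = p)
}

#' Length scale probed by an oscillating encoding frequency
#'
#' For restricted diffusion in an impermeable compartment with intrinsic
#' diffusivity D, an encoding at angular frequency omega is most sensitive
#' to structure at the diffusion length l = sqrt(2 D / omega). At the
#' protocol's lowest centroid frequency (6.6 Hz) and an intracellular
#' diffusivity of 3.5 um^2/ms this gives approximately 13 um.
#'
#' @param d_intra intrinsic diffusivity (um^2/ms).
#' @param f_hz encoding frequency (Hz).
#' @return length scale in um.
#' @examples
#' restrictionLengthScale(3.5, 6.6)   # ~13 um
#' @export
restrictionLengthScale <- function(d_intra, f_hz) {
  stopifnot(d_intra > 0, f_hz > 0)
  sqrt(2 * d_intra * 1000 / (2 * pi * f_hz))
}
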