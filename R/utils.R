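#' @useDynLib mdmri, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats median rnorm runif sd aggregate
NULL

# unit vector from polar/azimuthal angles (theta from +z, phi from +x)
anglesToDir <- function(theta, phi) {
  cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

dirToAngles <- function(u) {
  u <- u / sqrt(rowSums(u^2))
  theta <- acos(pmin(1, pmax(-1, u[, 3])))
  phi <- atan2(u[, 2], u[, 1]) %% (2 * pi)
  cbind(theta = theta, phi = phi)
}

# trapezoidal quadrature (kept local so numerical contracts do not depend on
# an external default changing)
trapzQuad <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# second Legendre polynomial, the angular factor coupling axisymmetric
# b-tensor and diffusion-tensor anisotropies
legendreP2 <- function(x) (3 * x^2 - 1) / 2

# derive a reproducible 32-bit sub-seed from a master seed and an index
subSeed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647
  as.integer(s)
}

# cheap stable checksum of a config for provenance stamping
configHash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

compColumns <- c("d_par", "d_perp", "theta", "phi", "d0",
                 "gamma_par", "gamma_perp", "r1", "r2", "weight")
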