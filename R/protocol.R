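#' Spectral density of a gradient waveform
#'
#' Computes the tensor-valued encoding power spectrum b(omega) of a free
#' gradient waveform from the Fourier transform of its dephasing vector
#' q(t) = gamma * integral of g dt'. The spectrum is normalized so that its
#' frequency integral equals the time-domain b-tensor
#' B = integral of q(t) q(t)' dt, converted to ms/um^2.
#'
#' @param gradient numeric matrix (time samples x 3) of gradient amplitudes
#'   in T/m.
#' @param dt sampling interval in seconds.
#' @param gamma gyromagnetic ratio in rad/s/T (default: proton).
#' @param tol relative tolerance on the refocusing condition |q(end)| = 0.
#' @return a \linkS4class{BTensorSpectrum} on a two-sided angular-frequency
#'   grid.
#' @examples
#' wf <- cosineWaveform(f_hz = 15, n_periods = 3, axes = 1)
#' sp <- waveformToSpectrum(wf$gradient, wf$dt)
#' btensorShape(sp@btensor)
#' @export
waveformToSpectrum <- function(gradient, dt, gamma = 267.513e6, tol = 1e-6) {
  gradient <- as.matrix(gradient)
  stopifnot(ncol(gradient) == 3, dt > 0)
  nt <- nrow(gradient)
  q <- apply(gradient, 2, cumsum) * dt * gamma     # rad/m
  qmax <- max(sqrt(rowSums(q^2)), 0)
  qend <- sqrt(sum(q[nt, ]^2))
  if (qmax > 0 && qend > tol * qmax)
    stop(sprintf(
      "waveform is not refocused: |q(end)| = %.3g rad/m (%.2g of peak |q|)",
      qend, qend / qmax))
  # time-domain b-tensor in SI (s/m^2), then to ms/um^2
  B <- (t(q) %*% q) * dt * 1e-9
  # discrete Parseval normalization: density_k = Re(Q Q*') dt^2 / (2 pi),
  # rectangle-rule sum over the fft grid then reproduces B exactly
  Q <- stats::mvfft(q)
  n <- nt
  k <- seq_len(n) - 1L
  k[k >= n / 2] <- k[k >= n / 2] - n
  omega <- 2 * pi * k / (n * dt)
  ord <- order(omega)
  dens <- array(0, dim = c(3, 3, n))
  scale <- dt^2 / (2 * pi) * 1e-9
  for (i in 1:3) for (j in 1:3)
    dens[i, j, ] <- Re(Q[, i] * Conj(Q[, j]))[ord] * scale
  sp <- new("BTensorSpectrum", omega = omega[ord], density = dens, btensor = B)
  sp
}

#' Cosine-modulated gradient waveform
#'
#' Builds a refocused oscillating waveform whose dephasing vector is a sine
#' burst q(t) = q0 sin(2 pi f t) over an integer number of periods. With
#' two or three active axes the burst is modulated per axis by orthogonal
#' Walsh sign patterns (flipped over halves/quarters of the duration), so
#' the per-axis dephasing vectors are mutually orthogonal with equal power:
#' single-, double- and triple-axis combinations yield linear, planar and
#' spherical b-tensors with the same spectral magnitude near +/- f.
#'
#' @param f_hz modulation frequency (Hz).
#' @param n_periods number of full periods; rounded up to a multiple of 4
#'   when more than one axis is active (so the sign flips land on zeros of
#'   the burst).
#' @param axes integer vector of axes (subset of 1:3) carrying the burst.
#' @param q0 dephasing amplitude (rad/m).
#' @param samples_per_period time samples per period.
#' @return list with \code{gradient} (T/m matrix), \code{dt} (s).
#' @export
cosineWaveform <- function(f_hz, n_periods = 4, axes = 1L, q0 = 5e4,
                           samples_per_period = 64L) {
  stopifnot(f_hz > 0, n_periods >= 1, all(axes %in% 1:3))
  gamma <- 267.513e6
  if (length(axes) > 1) n_periods <- 4 * ceiling(n_periods / 4)
  nt <- as.integer(round(n_periods * samples_per_period))
  dt <- 1 / (f_hz * samples_per_period)
  t <- seq_len(nt) * dt
  burst <- q0 * sin(2 * pi * f_hz * t)
  quarter <- ceiling(4 * seq_len(nt) / nt)     # 1..4
  walsh <- list(rep(1, 4), c(1, 1, -1, -1), c(1, -1, -1, 1))
  q <- matrix(0, nt, 3)
  for (k in seq_along(axes))
    q[, axes[k]] <- burst * walsh[[k]][quarter]
  # gradient reproducing q exactly under discrete integration
  g <- apply(rbind(0, q), 2, diff) / (gamma * dt)
  list(gradient = g, dt = dt)
}

#' b-tensor magnitude and normalized anisotropy
#'
#' Decomposes an axisymmetric positive semidefinite b-tensor into its trace
#' b and normalized anisotropy b_delta (1 linear, 0 spherical, -0.5 planar).
#'
#' @param B 3x3 symmetric matrix (ms/um^2).
#' @param tol relative tolerance on axisymmetry of the two transverse
#'   eigenvalues.
#' @return list with elements \code{b}, \code{b_delta} and \code{axis}
#'   (unit eigenvector of the distinct eigenvalue).
#' @examples
#' btensorShape(diag(c(0, 0, 1)))   # linear: b = 1, b_delta = 1
#' @export
btensorShape <- function(B, tol = 1e-6) {
  stopifnot(all(dim(B) == c(3, 3)))
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ev <- e$values   # decreasing
  b <- sum(ev)
  if (b <= 0) return(list(b = 0, b_delta = 0, axis = c(0, 0, 1)))
  gaps <- c(ev[1] - ev[2], ev[2] - ev[3])
  # the distinct (axial) eigenvalue is the one farther from the other two
  if (gaps[1] >= gaps[2]) {  # largest is distinct (prolate/linear-like)
    ax <- 1; tr <- c(2, 3)
  } else {                   # smallest is distinct (oblate/planar-like)
    ax <- 3; tr <- c(1, 2)
  }
  spread <- abs(ev[tr[1]] - ev[tr[2]])
  if (spread > tol * max(abs(ev)) + tol)
    stop(sprintf(
      "b-tensor is not axisymmetric: transverse eigenvalue spread %.3g (values %s)",
      spread, paste(signif(ev, 6), collapse = ", ")))
  b_delta <- (ev[ax] - mean(ev[tr])) / b
  list(b = b, b_delta = b_delta, axis = e$vectors[, ax])
}

#' Centroid frequency of an encoding spectrum
#'
#' First moment of the trace of the spectral density over non-negative
#' frequencies divided by its zeroth moment, in Hz.
#'
#' @param object a \linkS4class{BTensorSpectrum}.
#' @param ... unused.
#' @return centroid frequency in Hz.
#' @name centroidFrequency
#' @export
setMethod("centroidFrequency", "BTensorSpectrum", function(object, ...) {
  tr <- object@density[1, 1, ] + object@density[2, 2, ] + object@density[3, 3, ]
  keep <- object@omega >= 0
  w <- object@omega[keep]
  s <- tr[keep]
  m0 <- trapzQuad(w, s)
  if (m0 <= 0) stop("spectrum has zero total b; centroid frequency undefined")
  trapzQuad(w, w * s) / m0 / (2 * pi)
})

# maximum attainable centroid frequency (Hz) as a function of b (ms/um^2):
# high b requires long low-frequency encodings, so the ceiling decreases
# with b; anchored at the protocol's printed (b, f_max) pairs
maxCentroidFreq <- function(b) {
  stats::approx(x = c(0.1, 0.5, 1.5, 3), y = c(21, 21, 15, 11),
                xout = pmin(pmax(b, 0.1), 3), rule = 2)$y
}

# deterministic quasi-uniform direction set (Fibonacci sphere)
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(r * cos(ga * i), r * sin(ga * i), z)
}

#' Build the default sparse MD-MRI protocol
#'
#' Constructs a 139-measurement diffusion-relaxation protocol with linear,
#' planar and spherical b-tensors (b_delta 1, -0.5, 0), b-values between 0.1
#' and 3 ms/um^2, centroid frequencies between 6.6 and 21 Hz subject to the
#' b-frequency coupling (the attainable frequency ceiling decreases with b:
#' 21 Hz at b = 0.5, 15 Hz at b = 1.5, 11 Hz at b = 3 ms/um^2), repetition
#' times from \{0.62, 1.75, 3.5, 5, 7, 7.6\} s and echo times from
#' \{40, 63, 83, 150\} ms. The per-cell allocation is deterministic given
#' the seed.
#'
#' @param seed integer seed controlling direction-set rotation and TE/TR
#'   interleaving.
#' @param spectra \code{"narrowband"} (default) stores only centroid
#'   frequencies; \code{"waveform"} additionally attaches full b(omega)
#'   spectra computed from cosine-modulated waveforms (single-, double- and
#'   triple-axis bursts for linear, planar and spherical shapes).
#' @return an \linkS4class{AcquisitionProtocol} with 139 measurements.
#' @examples
#' prot <- makeDefaultProtocol(seed = 1)
#' nrow(measurements(prot))   # 139
#' @export
makeDefaultProtocol <- function(seed = 1L,
                                spectra = c("narrowband", "waveform")) {
  spectra <- match.arg(spectra)
  trs <- c(0.62, 1.75, 3.5, 5, 7, 7.6)
  tes <- c(40, 63, 83, 150)
  rng <- local({ set.seed(subSeed(seed, 0L)); list(
    rotation = {
      # random rotation applied to the shared direction set
      z <- matrix(rnorm(9), 3); qr.Q(qr(z)) * sign(det(qr.Q(qr(z))))
    })})

  rows <- list()
  addRow <- function(b, bd, dir, f, te, tr)
    rows[[length(rows) + 1L]] <<- data.frame(
      b_ms_per_um2 = b, b_delta = bd, dir_x = dir[1], dir_y = dir[2],
      dir_z = dir[3], f_cent_hz = f, te_ms = te, tr_s = tr,
      spectrum_id = NA_character_)

  # b = 0 block: TR sweep at shortest TE, TE sweep at longest TR (9 rows)
  for (tr in trs) addRow(0, 0, c(0, 0, 0), NA, 40, tr)
  for (te in tes[-1]) addRow(0, 0, c(0, 0, 0), NA, te, 7.6)

  # diffusion-weighted cells: (b_delta, b, n directions)
  cells <- rbind(
    data.frame(bd = 1,    b = c(0.1, 0.5, 1, 1.5, 2, 2.5, 3),
               n = c(6, 10, 10, 12, 12, 6, 12)),
    data.frame(bd = 0,    b = c(0.1, 0.5, 1, 1.5, 2, 3),
               n = c(2, 6, 6, 6, 4, 6)),
    data.frame(bd = -0.5, b = c(0.5, 1, 1.5, 2, 3),
               n = c(6, 8, 6, 6, 6)))
  stopifnot(sum(cells$n) == 130)

  # TE/TR interleave pattern for diffusion rows: mostly short-TE/long-TR
  # with excursions that encode relaxation sensitivity
  tetr <- rbind(c(40, 7.6), c(40, 5), c(63, 7.6), c(40, 3.5),
                c(83, 7.6), c(40, 7), c(150, 7.6), c(40, 1.75))
  tt <- 0L
  for (ci in seq_len(nrow(cells))) {
    bd <- cells$bd[ci]; b <- cells$b[ci]; n <- cells$n[ci]
    fmax <- maxCentroidFreq(b)
    dirs <- fibonacciDirections(max(n, 3)) %*% t(rng$rotation)
    for (j in seq_len(n)) {
      # cycle each cell across three frequency levels up to the b-dependent cap
      lev <- (j - 1L) %% 3L
      f <- 6.6 + (fmax - 6.6) * lev / 2
      tt <- tt + 1L
      p <- tetr[(tt - 1L) %% nrow(tetr) + 1L, ]
      d <- dirs[j, ]
      addRow(b, bd, d / sqrt(sum(d^2)), f, p[1], p[2])
    }
  }
  tb <- do.call(rbind, rows)
  stopifnot(nrow(tb) == 139L)

  specs <- list()
  if (spectra == "waveform") {
    dwi <- which(tb$b_ms_per_um2 > 0)
    for (i in dwi) {
      axes <- switch(as.character(tb$b_delta[i]),
                     "1" = 1L, "-0.5" = 1:2, "0" = 1:3)
      wf <- cosineWaveform(tb$f_cent_hz[i], n_periods = 4, axes = axes)
      sp <- waveformToSpectrum(wf$gradient, wf$dt)
      # scale to the target b magnitude
      sc <- tb$b_ms_per_um2[i] / sum(diag(sp@btensor))
      sp@btensor <- sp@btensor * sc
      sp@density <- sp@density * sc
      id <- sprintf("s%03d", i)
      tb$spectrum_id[i] <- id
      specs[[id]] <- sp
    }
  }
  new("AcquisitionProtocol", table = tb, spectra = specs,
      metadata = list(seed = seed, spectra = spectra))
}

#' Read / write a protocol table
#'
#' The on-disk format is a TSV with columns \code{b_ms_per_um2, b_delta,
#' dir_x, dir_y, dir_z, f_cent_hz, te_ms, tr_s, spectrum_id}.
#'
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param path file path.
#' @return \code{readProtocol} returns an \linkS4class{AcquisitionProtocol};
#'   \code{writeProtocol} returns \code{path} invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  utils::write.table(protocol@table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(protocolColumns, names(tb))
  if (length(missing))
    stop("malformed protocol file: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!stats::complete.cases(tb[, c("b_ms_per_um2", "b_delta",
                                             "te_ms", "tr_s")]))
  if (length(bad))
    stop(sprintf("malformed protocol file: incomplete row %d", bad[1]))
  tb$spectrum_id <- as.character(tb$spectrum_id)
  new("AcquisitionProtocol", table = tb, spectra = list(),
      metadata = list(source = path))
}
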