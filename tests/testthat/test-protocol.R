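test_that("b-tensor shape metrics recover the canonical encodings", {
  lin <- btensorShape(diag(c(0, 0, 1)))
  expect_equal(lin$b, 1)
  expect_equal(lin$b_delta, 1)

  pla <- btensorShape(diag(c(0.5, 0.5, 0)))
  expect_equal(pla$b, 1)
  expect_equal(pla$b_delta, -0.5)

  sph <- btensorShape(diag(3) * 0.7 / 3)
  expect_equal(sph$b, 0.7)
  expect_equal(sph$b_delta, 0, tolerance = 1e-12)

  expect_error(btensorShape(diag(c(0.1, 0.5, 1))), "not axisymmetric")
})

test_that("zero waveform gives a zero spectrum and zero b", {
  sp <- waveformToSpectrum(matrix(0, 64, 3), dt = 1e-3)
  expect_equal(sum(abs(sp@btensor)), 0)
  expect_equal(sum(abs(sp@density)), 0)
})

test_that("non-refocused waveforms are rejected with the residual named", {
  g <- matrix(0, 64, 3)
  g[, 1] <- 0.01   # constant gradient never refocuses
  expect_error(waveformToSpectrum(g, dt = 1e-3), "not refocused")
})

test_that("cosine burst concentrates spectral power near its frequency", {
  wf <- cosineWaveform(f_hz = 15, n_periods = 4, axes = 1)
  sp <- waveformToSpectrum(wf$gradient, wf$dt)
  # power only on the driven axis
  expect_equal(sum(abs(sp@density[2:3, , ])), 0, tolerance = 1e-12)
  # most trace power within +/- 50% of f0
  tr <- sp@density[1, 1, ]
  f <- sp@omega / (2 * pi)
  inband <- abs(abs(f) - 15) < 7.5
  expect_gt(sum(tr[inband]) / sum(tr), 0.9)
  expect_equal(centroidFrequency(sp), 15, tolerance = 0.15)
})

test_that("frequency integral of the spectral density matches the time-domain b-tensor", {
  for (seed in 1:5) {
    wf <- randomWaveform(seed)
    q <- apply(wf$gradient, 2, cumsum) * wf$dt * 267.513e6
    B_time <- (t(q) %*% q) * wf$dt * 1e-9
    sp <- waveformToSpectrum(wf$gradient, wf$dt)
    # rectangle-rule integral on the fft grid (Parseval identity oracle)
    dw <- diff(sp@omega[1:2])
    B_freq <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      B_freq[i, j] <- sum(sp@density[i, j, ]) * dw
    expect_lt(max(abs(B_freq - B_time)) / sqrt(sum(B_time^2)), 1e-6)
    expect_equal(sp@btensor, B_time, tolerance = 1e-10)
  }
})

test_that("rotating a waveform rotates the b-tensor as R B R'", {
  wf <- randomWaveform(7)
  B <- waveformToSpectrum(wf$gradient, wf$dt)@btensor
  set.seed(3)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    Brot <- waveformToSpectrum(wf$gradient %*% t(R), wf$dt)@btensor
    expect_equal(Brot, R %*% B %*% t(R), tolerance = 1e-8)
  }
})

test_that("centroid frequency matches delta-band, flat-band and quadrature oracles", {
  mkspec <- function(f_hz, s_of_w) {
    w <- seq(0, 2 * pi * 40, length.out = 4001)
    s <- s_of_w(w)
    dens <- array(0, c(3, 3, length(w)))
    for (i in 1:3) dens[i, i, ] <- s / 3
    B <- diag(3) * trapzQuad_test(w, s) / 3
    new("BTensorSpectrum", omega = w, density = dens, btensor = B)
  }
  trapzQuad_test <- function(x, y) pracma::trapz(x, y)

  narrow <- mkspec(10, function(w)
    exp(-0.5 * ((w - 2 * pi * 10) / (2 * pi * 0.05))^2))
  expect_equal(centroidFrequency(narrow), 10, tolerance = 1e-3)

  flat <- mkspec(NA, function(w) as.numeric(w <= 2 * pi * 20))
  expect_equal(centroidFrequency(flat), 10, tolerance = 1e-2)

  arb <- mkspec(NA, function(w) w^2 * exp(-w / 30))
  w <- arb@omega
  s <- arb@density[1, 1, ] * 3
  oracle <- pracma::trapz(w, w * s) / pracma::trapz(w, s) / (2 * pi)
  expect_equal(centroidFrequency(arb), oracle, tolerance = 1e-8)

  zero <- mkspec(NA, function(w) rep(0, length(w)))
  expect_error(centroidFrequency(zero), "zero total b")
})

test_that("default protocol honors the printed counts, sets and couplings", {
  tb <- measurements(defaultProt)
  expect_identical(nrow(tb), 139L)
  expect_gte(sum(tb$b_ms_per_um2 == 0), 1)
  dwi <- tb$b_ms_per_um2 > 0
  expect_true(all(tb$b_ms_per_um2[dwi] >= 0.1 & tb$b_ms_per_um2[dwi] <= 3))
  expect_true(all(tb$b_delta[dwi] %in% c(-0.5, 0, 1)))
  expect_true(all(tb$te_ms %in% c(40, 63, 83, 150)))
  expect_true(all(tb$tr_s %in% c(0.62, 1.75, 3.5, 5, 7, 7.6)))
  f <- tb$f_cent_hz[dwi]
  expect_true(all(f >= 6.6 - 1e-9 & f <= 21 + 1e-9))
  # b-frequency coupling: the attainable ceiling decreases with b
  expect_lte(max(tb$f_cent_hz[tb$b_ms_per_um2 == 3], na.rm = TRUE), 11)
  expect_lte(max(tb$f_cent_hz[tb$b_ms_per_um2 == 1.5], na.rm = TRUE), 15)
  expect_equal(max(tb$f_cent_hz[tb$b_ms_per_um2 == 0.5], na.rm = TRUE), 21)
  # unit directions
  nrm <- with(tb[dwi, ], sqrt(dir_x^2 + dir_y^2 + dir_z^2))
  expect_equal(nrm, rep(1, sum(dwi)), tolerance = 1e-9)
})

test_that("default protocol is deterministic in the seed", {
  p1 <- makeDefaultProtocol(seed = 5)
  p2 <- makeDefaultProtocol(seed = 5)
  p3 <- makeDefaultProtocol(seed = 6)
  expect_identical(measurements(p1), measurements(p2))
  expect_false(identical(measurements(p1), measurements(p3)))
})

test_that("waveform-backed protocol spectra integrate to their b-tensors", {
  prot <- makeDefaultProtocol(seed = 2, spectra = "waveform")
  tb <- measurements(prot)
  ids <- tb$spectrum_id[!is.na(tb$spectrum_id)]
  expect_length(ids, sum(tb$b_ms_per_um2 > 0))
  for (id in ids[c(1, 50, 100)]) {
    sp <- prot@spectra[[id]]
    i <- which(tb$spectrum_id == id)
    expect_equal(sum(diag(sp@btensor)), tb$b_ms_per_um2[i], tolerance = 1e-9)
    sh <- btensorShape(sp@btensor, tol = 1e-4)
    expect_equal(sh$b_delta, tb$b_delta[i], tolerance = 1e-6)
  }
})

test_that("protocol TSV round-trips and malformed files are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeProtocol(defaultProt, path)
  back <- readProtocol(path)
  expect_equal(measurements(back)$b_ms_per_um2,
               measurements(defaultProt)$b_ms_per_um2)
  expect_equal(measurements(back)$f_cent_hz,
               measurements(defaultProt)$f_cent_hz, tolerance = 1e-12)

  tb <- measurements(defaultProt)
  tb$te_ms[17] <- NA
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(tb, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readProtocol(path2), "row 17")

  path3 <- tempfile(fileext = ".tsv")
  utils::write.table(tb[, 1:4], path3, sep = "\t", row.names = FALSE)
  expect_error(readProtocol(path3), "missing column")
})
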