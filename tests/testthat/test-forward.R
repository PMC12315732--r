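test_that("Lorentzian axis diffusivity has the stated limits and midpoint", {
  expect_equal(lorentzianAxis(0.5, 3.0, 100, 0), 0.5)
  expect_equal(lorentzianAxis(0.5, 3.0, 100, 100), 1.75)
  expect_equal(lorentzianAxis(0.5, 3.0, 100, 1e9), 3.0, tolerance = 1e-6)
  # monotone between the zero-frequency value and d0
  w <- seq(0, 1e4, length.out = 200)
  up <- lorentzianAxis(0.5, 3.0, 100, w)
  expect_true(all(diff(up) > 0))
  down <- lorentzianAxis(2.5, 1.0, 100, w)
  expect_true(all(diff(down) < 0))
})

test_that("component tensor evaluation matches the Diso/DDelta^2 conventions", {
  comp <- components(drComponents(2, 0.5, theta = 0, phi = 0, d0 = 2,
                                  gamma_par = 100, gamma_perp = 100))
  out <- componentTensorAt(comp, 0)
  expect_equal(out$tensor, diag(c(0.5, 0.5, 2)))
  expect_equal(out$d_iso, 1.0)
  expect_equal(out$d_delta_sq, 0.25)

  # trace (Diso) is invariant under any orientation
  set.seed(1)
  for (i in 1:10) {
    compr <- comp
    compr[, "theta"] <- runif(1, 0, pi)
    compr[, "phi"] <- runif(1, 0, 2 * pi)
    outr <- componentTensorAt(compr, 0)
    expect_equal(sum(diag(outr$tensor)) / 3, 1.0, tolerance = 1e-12)
    expect_equal(outr$d_iso, 1.0)
  }
})

test_that("attenuation factorizes for isotropic flat components and aligned linear encoding", {
  iso <- components(flatComponent(1, 0))
  expect_equal(attenuation(iso, measRow(1, b_delta = 0)), 1.0, tolerance = 1e-9)

  # flat D_par = 2 along z, linear encoding along z, b = 1 -> beta = 2
  lin <- components(drComponents(2, 0.5, theta = 0, phi = 0, d0 = 2,
                                 gamma_par = 1e7, gamma_perp = 1e7))
  expect_equal(attenuation(lin, measRow(1, b_delta = 1, dir = c(0, 0, 1))),
               2.0, tolerance = 1e-6)
})

test_that("narrow-band attenuation agrees with full-spectrum quadrature", {
  comp <- components(drComponents(1.6, 0.3, theta = 0.4, phi = 1.2, d0 = 2,
                                  gamma_par = 60, gamma_perp = 90))
  f0 <- 12
  # narrow Gaussian band around +/- f0, linear along a tilted axis
  w <- seq(-2 * pi * 40, 2 * pi * 40, length.out = 8001)
  u <- c(sin(0.7), 0, cos(0.7))
  s <- exp(-0.5 * ((abs(w) - 2 * pi * f0) / (2 * pi * 0.02))^2)
  b_target <- 1.5
  s <- s * b_target / pracma::trapz(w, s)
  dens <- array(0, c(3, 3, length(w)))
  for (i in 1:3) for (j in 1:3) dens[i, j, ] <- s * u[i] * u[j]
  B <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) B[i, j] <- pracma::trapz(w, dens[i, j, ])
  sp <- new("BTensorSpectrum", omega = w, density = dens, btensor = B)

  beta_full <- attenuation(comp, sp)
  # narrow-band closed form at the band frequency
  m <- measRow(b_target, b_delta = 1, dir = u, f = f0)
  beta_nb <- attenuation(comp, m)
  expect_equal(beta_full, beta_nb, tolerance = 1e-4)

  # independent oracle: direct B:D quadrature at 10x grid resolution
  w10 <- seq(-2 * pi * 40, 2 * pi * 40, length.out = 80001)
  s10 <- exp(-0.5 * ((abs(w10) - 2 * pi * f0) / (2 * pi * 0.02))^2)
  s10 <- s10 * b_target / pracma::trapz(w10, s10)
  dpar <- lorentzianAxis(1.6, 2, 60, abs(w10))
  dperp <- lorentzianAxis(0.3, 2, 90, abs(w10))
  ud <- drop(mdmri:::anglesToDir(0.4, 1.2))
  cpsi2 <- sum(u * ud)^2
  bd <- dperp * 1 + (dpar - dperp) * cpsi2   # u'Du per unit band mass
  oracle <- pracma::trapz(w10, s10 * bd)
  expect_equal(beta_full, oracle, tolerance = 1e-6)
})

test_that("attenuation warns when the grid is coarse relative to the transition", {
  comp <- components(drComponents(1, 0.5, d0 = 2, gamma_par = 5,
                                  gamma_perp = 5))
  w <- seq(-2 * pi * 40, 2 * pi * 40, length.out = 41)
  dens <- array(0, c(3, 3, length(w)))
  s <- rep(1e-3, length(w))
  for (i in 1:3) dens[i, i, ] <- s
  B <- matrix(0, 3, 3)
  for (i in 1:3) B[i, i] <- pracma::trapz(w, s)
  sp <- new("BTensorSpectrum", omega = w, density = dens, btensor = B)
  expect_warning(attenuation(comp, sp), "coarse")
})

test_that("signal equation matches direct scalar evaluation and is linear", {
  v <- drComponents(1, 1, d0 = 1, r1 = 0.5, r2 = 10, weight = 1)
  prot <- protFromTable(measRow(0, te = 40, tr = 7.6))
  s <- signalModel(v, prot)
  expect_equal(s, (1 - exp(-7.6 * 0.5)) * exp(-0.04 * 10), tolerance = 1e-12)

  # weight-conservation limit: b = 0, TR -> Inf, TE -> 0
  v2 <- drComponents(c(1, 2), c(1, 0.5), d0 = c(1, 2), r1 = c(0.5, 1),
                     r2 = c(10, 20), weight = c(0.3, 0.6))
  prot_lim <- protFromTable(measRow(0, te = 1e-9, tr = 1e6))
  expect_equal(signalModel(v2, prot_lim), 0.9, tolerance = 1e-9)

  # linearity over components
  tb <- measurements(defaultProt)
  one <- function(i) {
    p <- components(v2)[i, , drop = FALSE]
    signalModel(new("DRComponents", params = p), defaultProt)
  }
  expect_equal(signalModel(v2, defaultProt), one(1) + one(2),
               tolerance = 1e-12)
})

test_that("signals are bounded, monotone in b, TE, TR", {
  v <- drComponents(c(1.6, 0.9), c(0.25, 0.8), theta = c(0.3, 1),
                    phi = c(1, 2), d0 = c(1.8, 1.1),
                    gamma_par = c(80, 60), gamma_perp = c(80, 60),
                    r1 = c(0.6, 0.5), r2 = c(15, 12), weight = c(0.7, 0.3))
  s <- signalModel(v, defaultProt)
  expect_true(all(s > 0 & s <= 1))

  sweep_rows <- do.call(rbind, lapply(seq(0.1, 3, 0.2), function(b)
    measRow(b, b_delta = 1, dir = c(0, 0, 1), f = 8)))
  sb <- signalModel(v, protFromTable(sweep_rows))[seq_len(nrow(sweep_rows))]
  expect_true(all(diff(sb) < 0))

  te_rows <- do.call(rbind, lapply(c(40, 63, 83, 150), function(te)
    measRow(0.5, f = 8, te = te)))
  ste <- signalModel(v, protFromTable(te_rows))[1:4]
  expect_true(all(diff(ste) < 0))

  tr_rows <- do.call(rbind, lapply(c(0.62, 1.75, 3.5, 5, 7, 7.6), function(tr)
    measRow(0.5, f = 8, tr = tr)))
  str_ <- signalModel(v, protFromTable(tr_rows))[1:6]
  expect_true(all(diff(str_) > 0))
})

test_that("attenuation is equivariant under joint rotation of component and encoding", {
  set.seed(4)
  comp <- components(drComponents(1.7, 0.3, theta = 0.5, phi = 2.2, d0 = 2,
                                  gamma_par = 70, gamma_perp = 50))
  u_enc <- c(0.36, 0.48, 0.8)
  m <- measRow(1.2, b_delta = 1, dir = u_enc, f = 9)
  beta0 <- attenuation(comp, m)
  for (i in 1:5) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    u_comp <- drop(mdmri:::anglesToDir(comp[, "theta"], comp[, "phi"]))
    ang <- mdmri:::dirToAngles(matrix(drop(R %*% u_comp), 1))
    compr <- comp
    compr[, "theta"] <- ang[, "theta"]
    compr[, "phi"] <- ang[, "phi"]
    mr <- measRow(1.2, b_delta = 1, dir = drop(R %*% u_enc), f = 9)
    expect_equal(attenuation(compr, mr), beta0, tolerance = 1e-10)
  }
})

test_that("oscillating-encoding length scale reproduces the analytic figure", {
  expect_equal(restrictionLengthScale(3.5, 6.6), 13.0, tolerance = 0.05)
  # scales as sqrt(D/f)
  expect_equal(restrictionLengthScale(3.5, 26.4),
               restrictionLengthScale(3.5, 6.6) / 2, tolerance = 1e-12)
})
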