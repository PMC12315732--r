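# shared fixtures, built once per test run

defaultProt <- makeDefaultProtocol(seed = 1)

# component with prescribed Diso / DDelta^2 at all frequencies (transition
# frequencies far above the window, so the spectrum is flat there)
flatComponent <- function(diso, ddelta_sq, r1 = 0.5, r2 = 10, weight = 1,
                          theta = 0, phi = 0) {
  dd <- sqrt(ddelta_sq)
  drComponents(d_par = diso * (1 + 2 * dd), d_perp = diso * (1 - dd),
               theta = theta, phi = phi, d0 = diso,
               gamma_par = 1e7, gamma_perp = 1e7,
               r1 = r1, r2 = r2, weight = weight)
}

# one-row narrow-band measurement table
measRow <- function(b, b_delta = 0, dir = c(0, 0, 1), f = 10, te = 40,
                    tr = 7.6) {
  data.frame(b_ms_per_um2 = b, b_delta = b_delta, dir_x = dir[1],
             dir_y = dir[2], dir_z = dir[3],
             f_cent_hz = if (b > 0) f else NA, te_ms = te, tr_s = tr,
             spectrum_id = NA_character_)
}

protFromTable <- function(tb) {
  if (!any(tb$b_ms_per_um2 == 0)) tb <- rbind(tb, measRow(0))
  new("AcquisitionProtocol", table = tb, spectra = list(), metadata = list())
}

# smooth random refocused waveform: even-harmonic sine series per axis so
# the dephasing vector returns to zero at the end
randomWaveform <- function(seed, nt = 512, T = 0.05, n_harm = 4) {
  set.seed(seed)
  t <- seq_len(nt) * (T / nt)
  g <- matrix(0, nt, 3)
  for (ax in 1:3) {
    for (k in seq_len(n_harm))
      g[, ax] <- g[, ax] + rnorm(1, 0, 0.02) * sin(2 * pi * k * t / T)
  }
  list(gradient = g, dt = T / nt)
}

# fast inversion settings for unit tests
tinyConfig <- function(...) {
  args <- list(n_bootstrap = 4L, population_size = 60L,
               n_generations = 6L, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(inversionConfig, args)
}
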