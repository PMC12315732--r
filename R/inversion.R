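#' Monte Carlo inversion configuration
#'
#' Parameter ranges and algorithm controls for the per-voxel D(omega)-R1-R2
#' distribution inversion. Defaults follow the sampling ranges
#' 0.05 < D_par, D_perp, D0 < 5 um^2/ms, 0 < theta < pi, 0 < phi < 2 pi,
#' 0.2 < R1 < 2 1/s, 1 < R2 < 30 1/s, 0.01 < Gamma_par, Gamma_perp < 10000
#' rad/s, with up to 10 weighted components per solution and 300 bootstrap
#' replicates.
#'
#' @param d_range,d0_range diffusivity ranges (um^2/ms).
#' @param r1_range,r2_range relaxation-rate ranges (1/s).
#' @param gamma_range transition-frequency range (rad/s).
#' @param max_components maximum retained components per solution.
#' @param n_bootstrap number of bootstrap replicates.
#' @param population_size candidate dictionary size per generation.
#' @param n_generations quasi-genetic refinement generations.
#' @param mutation_scale log-normal multiplicative perturbation scale for
#'   survivor parameters (also the angular jitter scale, rad).
#' @param prune_frac components below this fraction of the total weight are
#'   dropped between generations.
#' @param seed master seed; per-voxel streams are derived from it.
#' @return a list of class \code{"InversionConfig"}.
#' @export
inversionConfig <- function(d_range = c(0.05, 5), d0_range = c(0.05, 5),
                            r1_range = c(0.2, 2), r2_range = c(1, 30),
                            gamma_range = c(0.01, 1e4),
                            max_components = 10L, n_bootstrap = 300L,
                            population_size = 200L, n_generations = 20L,
                            mutation_scale = 0.2, prune_frac = 1e-4,
                            seed = 1L) {
  stopifnot(d_range[1] > 0, r1_range[1] > 0, r2_range[1] > 0,
            gamma_range[1] > 0, max_components >= 1, n_bootstrap >= 1,
            population_size >= max_components, n_generations >= 0)
  structure(list(d_range = d_range, d0_range = d0_range,
                 r1_range = r1_range, r2_range = r2_range,
                 gamma_range = gamma_range,
                 max_components = as.integer(max_components),
                 n_bootstrap = as.integer(n_bootstrap),
                 population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 mutation_scale = mutation_scale, prune_frac = prune_frac,
                 seed = as.integer(seed)),
            class = "InversionConfig")
}

rlogunif <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Draw random dictionary components
#'
#' Samples candidate components for the Monte Carlo inversion: diffusivities,
#' transition frequencies and relaxation rates log-uniformly within the
#' configured ranges (scale parameters), orientations uniformly on the
#' sphere.
#'
#' @param n number of components.
#' @param cfg an \code{\link{inversionConfig}}.
#' @return parameter matrix with unit weights (canonical component columns).
#' @export
sampleComponents <- function(n, cfg) {
  u <- runif(n, -1, 1)
  p <- cbind(d_par = rlogunif(n, cfg$d_range),
             d_perp = rlogunif(n, cfg$d_range),
             theta = acos(u),
             phi = runif(n, 0, 2 * pi),
             d0 = rlogunif(n, cfg$d0_range),
             gamma_par = rlogunif(n, cfg$gamma_range),
             gamma_perp = rlogunif(n, cfg$gamma_range),
             r1 = rlogunif(n, cfg$r1_range),
             r2 = rlogunif(n, cfg$r2_range),
             weight = rep(1, n))
  colnames(p) <- compColumns
  p
}

#' Non-negative least-squares component weights
#'
#' Fits non-negative weights w minimizing ||A w - s||^2 where column c of A
#' is the unit-weight forward signal of dictionary component c under every
#' measurement of the protocol (Lawson-Hanson active-set solver).
#'
#' @param dictionary component parameter matrix or
#'   \linkS4class{DRComponents}.
#' @param signals measured signal vector.
#' @param protocol an \linkS4class{AcquisitionProtocol} or its measurement
#'   table.
#' @return non-negative weight vector, one entry per dictionary component.
#' @export
fitWeights <- function(dictionary, signals, protocol) {
  if (is(dictionary, "DRComponents")) dictionary <- components(dictionary)
  table <- if (is(protocol, "AcquisitionProtocol")) measurements(protocol)
           else protocol
  if (length(signals) != nrow(table))
    stop(sprintf("signal length (%d) does not match protocol length (%d)",
                 length(signals), nrow(table)))
  if (!all(is.finite(signals))) stop("signals must be finite")
  A <- designMatrix(dictionary, table)
  as.vector(.nnls_cpp(A, signals)$x)
}

# perturb survivor components multiplicatively (log-normal on positive
# scale parameters) and jitter orientations on the sphere; clamp to ranges
mutateComponents <- function(comps, cfg, scale = cfg$mutation_scale) {
  n <- nrow(comps)
  clamp <- function(x, r) pmin(pmax(x, r[1]), r[2])
  jit <- function(x, r) clamp(x * exp(rnorm(n, 0, scale)), r)
  out <- comps
  out[, "d_par"] <- jit(comps[, "d_par"], cfg$d_range)
  out[, "d_perp"] <- jit(comps[, "d_perp"], cfg$d_range)
  out[, "d0"] <- jit(comps[, "d0"], cfg$d0_range)
  out[, "gamma_par"] <- jit(comps[, "gamma_par"], cfg$gamma_range)
  out[, "gamma_perp"] <- jit(comps[, "gamma_perp"], cfg$gamma_range)
  out[, "r1"] <- jit(comps[, "r1"], cfg$r1_range)
  out[, "r2"] <- jit(comps[, "r2"], cfg$r2_range)
  u <- anglesToDir(comps[, "theta"], comps[, "phi"]) +
    matrix(rnorm(3 * n, 0, scale), n, 3)
  ang <- dirToAngles(u)
  out[, "theta"] <- ang[, "theta"]
  out[, "phi"] <- ang[, "phi"]
  out
}

# one quasi-genetic fit on a fixed (possibly resampled) measurement set.
# Each generation fits NNLS weights over the candidate population, prunes
# the positive-weight set to <= max_components largest-weight atoms and
# refits; the constrained solution replaces the incumbent only when its
# residual improves, so the residual trace is non-increasing by
# construction. Returns the incumbent plus the residual trace.
fitReplicate <- function(signals, table, cfg, init = NULL) {
  pop <- if (is.null(init)) sampleComponents(cfg$population_size, cfg)
         else rbind(init,
                    if (nrow(init) < cfg$population_size)
                      sampleComponents(cfg$population_size - nrow(init), cfg))
  incumbent <- list(comps = NULL, residual = Inf)
  trace <- numeric(0)

  constrainedFit <- function(cand) {
    # NNLS restricted to <= max_components atoms (drop smallest weights)
    if (nrow(cand) > cfg$max_components) {
      ord <- order(cand[, "weight"], decreasing = TRUE)
      cand <- cand[ord[seq_len(cfg$max_components)], , drop = FALSE]
    }
    fit <- .nnls_cpp(designMatrix(cand, table), signals)
    w <- as.vector(fit$x)
    keep <- w > 0
    if (!any(keep)) keep <- w == max(w)
    cand <- cand[keep, , drop = FALSE]
    cand[, "weight"] <- w[keep]
    list(comps = cand, residual = fit$residual)
  }

  for (gen in seq_len(max(cfg$n_generations, 1L))) {
    A <- designMatrix(pop, table)
    fit <- .nnls_cpp(A, signals)
    w <- as.vector(fit$x)
    keep <- w > cfg$prune_frac * sum(w)
    if (!any(keep)) keep <- w == max(w)
    cand <- pop[keep, , drop = FALSE]
    cand[, "weight"] <- w[keep]
    cand_fit <- constrainedFit(cand)
    if (cand_fit$residual < incumbent$residual) incumbent <- cand_fit
    trace <- c(trace, incumbent$residual)
    if (gen >= cfg$n_generations) break
    # next population: the full positive-weight set stays as the breeding
    # beam (diversity), plus annealed perturbed copies and fresh samples
    surv <- cand
    n_surv <- nrow(surv)
    scale <- cfg$mutation_scale *
      0.5^((gen - 1) / max(1, cfg$n_generations - 1) * 2)
    n_free <- max(0L, cfg$population_size - n_surv)
    n_mut <- min(as.integer(ceiling(n_free * 0.7)), 12L * n_surv)
    mut <- NULL
    if (n_mut > 0) {
      parents <- surv[rep_len(seq_len(n_surv), n_mut), , drop = FALSE]
      mut <- mutateComponents(parents, cfg, scale)
    }
    n_fresh <- max(0L, cfg$population_size - n_surv - n_mut)
    pop <- rbind(surv, mut,
                 if (n_fresh > 0) sampleComponents(n_fresh, cfg))
  }
  if (is.null(incumbent$comps)) incumbent <- constrainedFit(
    structure(sampleComponents(1L, cfg), dimnames = list(NULL, compColumns)))
  list(comps = incumbent$comps, residual = incumbent$residual, trace = trace)
}

#' Monte Carlo inversion of one voxel
#'
#' Estimates the voxel's D(omega)-R1-R2 distribution by repeated
#' non-negative least squares over randomly sampled component dictionaries
#' with quasi-genetic refinement (retain positive-weight components,
#' perturb survivors, resample the remainder) and bootstrap replication
#' (measurements resampled with replacement, full length, per replicate).
#' Each replicate is pruned to at most \code{max_components} largest-weight
#' components and refit.
#'
#' @param signals measured signal vector (one entry per protocol row).
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param cfg an \code{\link{inversionConfig}}.
#' @param bootstrap logical; set \code{FALSE} to fit every replicate on the
#'   original (unresampled) measurement set.
#' @param init optional component matrix (or \linkS4class{DRComponents})
#'   seeding the initial dictionary of every replicate; with
#'   \code{n_generations = 0} and a full dictionary this reduces the
#'   inversion to a plain non-negative least-squares fit on \code{init}.
#' @return a \linkS4class{VoxelInversionResult} with
#'   \code{cfg$n_bootstrap} solutions.
#' @export
invertVoxel <- function(signals, protocol, cfg = inversionConfig(),
                        bootstrap = TRUE, init = NULL) {
  if (is(init, "DRComponents")) init <- components(init)
  table <- measurements(protocol)
  if (length(signals) != nrow(table))
    stop("signal length does not match protocol length")
  if (!all(is.finite(signals))) stop("signals must be finite")
  if (all(signals == 0)) stop("all-zero signal cannot be inverted")
  # run on a private stream; restore the caller's RNG state on exit
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)
  sols <- vector("list", cfg$n_bootstrap)
  res <- numeric(cfg$n_bootstrap)
  traces <- vector("list", cfg$n_bootstrap)
  nm <- nrow(table)
  # warm start: converge once on the full measurement set; every bootstrap
  # replicate then seeds its population with these atoms (and continues its
  # own sampling/refinement on the resampled set)
  warm <- init
  if (is.null(warm)) {
    base_fit <- fitReplicate(signals, table, cfg)
    warm <- base_fit$comps
  }
  for (bi in seq_len(cfg$n_bootstrap)) {
    idx <- if (bootstrap) sample.int(nm, nm, replace = TRUE) else seq_len(nm)
    rep_fit <- fitReplicate(signals[idx], table[idx, , drop = FALSE], cfg, warm)
    sols[[bi]] <- new("DRComponents", params = rep_fit$comps)
    res[bi] <- rep_fit$residual
    traces[[bi]] <- rep_fit$trace
  }
  new("VoxelInversionResult", solutions = sols, residuals = res,
      residual_trace = traces)
}

#' Monte Carlo inversion of a set of voxels
#'
#' Applies \code{\link{invertVoxel}} to each row of a signal matrix. The
#' random stream of voxel i is derived from \code{(cfg$seed, i)}, so results
#' are independent of evaluation order.
#'
#' @param signal_matrix numeric matrix (voxels x measurements).
#' @param protocol an \linkS4class{AcquisitionProtocol}.
#' @param cfg an \code{\link{inversionConfig}}.
#' @param bootstrap passed to \code{\link{invertVoxel}}.
#' @return list of \linkS4class{VoxelInversionResult}, one per voxel.
#' @export
invertVolume <- function(signal_matrix, protocol, cfg = inversionConfig(),
                         bootstrap = TRUE) {
  out <- vector("list", nrow(signal_matrix))
  for (i in seq_len(nrow(signal_matrix))) {
    vcfg <- cfg
    vcfg$seed <- subSeed(cfg$seed, i)
    out[[i]] <- invertVoxel(signal_matrix[i, ], protocol, vcfg, bootstrap)
  }
  out
}
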