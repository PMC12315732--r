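#' Write / read a NIfTI volume
#'
#' Thin wrappers over RNifti preserving data and affine on round-trip.
#'
#' @param volume numeric array (3D or 4D).
#' @param path file path (.nii or .nii.gz).
#' @param voxel_size_mm voxel edge lengths for a fresh header.
#' @return \code{readVolume} returns the array with the image attributes;
#'   \code{writeVolume} returns \code{path} invisibly.
#' @export
writeVolume <- function(volume, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_size_mm, min(3, length(dim(volume))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) RNifti::readNifti(path)

#' Pipeline run configuration
#'
#' Bundles every setting of an end-to-end run. All randomness derives from
#' the single \code{seed}. The configuration hash is stamped into every
#' output for provenance.
#'
#' @param outdir output directory.
#' @param cohort a \code{\link{cohortSpec}}.
#' @param inversion an \code{\link{inversionConfig}}.
#' @param bins a \code{\link{binDefinition}}.
#' @param fwhm_mm voxel-wise analysis smoothing FWHM (mm).
#' @param voxel_size_mm voxel size (mm).
#' @param fbin3_max ROI CSF-exclusion threshold.
#' @param seed master seed (propagated into cohort and inversion configs).
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(outdir = tempfile("mdmri_run_"),
                      cohort = cohortSpec(seed = seed),
                      inversion = inversionConfig(seed = seed),
                      bins = binDefinition(), fwhm_mm = 4,
                      voxel_size_mm = 2, fbin3_max = 0.2, seed = 1L) {
  cfg <- list(outdir = outdir, cohort = cohort, inversion = inversion,
              bins = bins, fwhm_mm = fwhm_mm, voxel_size_mm = voxel_size_mm,
              fbin3_max = fbin3_max, seed = as.integer(seed))
  cfg$hash <- configHash(cfg[setdiff(names(cfg), "outdir")])
  class(cfg) <- "RunConfig"
  cfg
}

stagePath <- function(config, stage) file.path(config$outdir,
                                               paste0(stage, ".rds"))

loadStage <- function(config, stage) {
  p <- stagePath(config, stage)
  if (!file.exists(p)) return(NULL)
  obj <- readRDS(p)
  if (!identical(obj$hash, config$hash))
    stop("config hash mismatch on resume for stage '", stage,
         "': outputs in ", config$outdir, " were produced by a different ",
         "configuration")
  obj$value
}

saveStage <- function(config, stage, value) {
  saveRDS(list(hash = config$hash, value = value), stagePath(config, stage))
  value
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Orchestrates simulate -> invert -> maps -> reliability -> report:
#' generates the test-retest phantom cohort, inverts every labelled voxel of
#' every scan, reduces the bootstrap solutions to parameter maps, computes
#' voxel-wise (smoothed) and ROI-averaged ICC(A,1)/CVws plus Bland-Altman
#' summaries on the majority-vote template ROI, and writes parameter-map
#' NIfTIs, TSV tables and a JSON manifest. Each stage's output is cached in
#' \code{outdir} and reused on resume when the configuration hash matches.
#'
#' @param config a \code{\link{runConfig}}.
#' @param resume reuse cached stage outputs when present.
#' @return invisibly, a list with the cohort, maps, reliability tables and
#'   the manifest path.
#' @export
runPipeline <- function(config = runConfig(), resume = TRUE) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character()
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  # --- simulate ---------------------------------------------------------
  cohort <- if (resume) loadStage(config, "simulate") else NULL
  if (is.null(cohort)) {
    logmsg("simulate: cohort %d x %d, snr %.3g", config$cohort$n_subjects,
           config$cohort$n_sessions, config$cohort$snr)
    cohort <- simulateCohort(config$cohort)
    saveStage(config, "simulate", cohort)
  }
  labels <- cohort@labels
  vox <- which(labels > 0)
  dims <- dim(labels)

  # --- invert + maps ----------------------------------------------------
  maps <- if (resume) loadStage(config, "maps") else NULL
  if (is.null(maps)) {
    maps <- vector("list", config$cohort$n_subjects)
    for (si in seq_len(config$cohort$n_subjects)) {
      maps[[si]] <- vector("list", config$cohort$n_sessions)
      for (se in seq_len(config$cohort$n_sessions)) {
        cfg <- config$inversion
        cfg$seed <- subSeed(config$seed, si * 1000L + se)
        res <- invertVolume(cohort@signals[[si]][[se]], cohort@protocol, cfg)
        maps[[si]][[se]] <- computeParameterMaps(
          res, dims, voxel_index = vox, bins = config$bins)
        logmsg("invert+maps: subject %d session %d (%d voxels, %d bootstraps)",
               si, se, length(vox), cfg$n_bootstrap)
      }
    }
    saveStage(config, "maps", maps)
  }

  # --- reliability ------------------------------------------------------
  rel <- if (resume) loadStage(config, "reliability") else NULL
  if (is.null(rel)) {
    logmsg("reliability: voxel-wise (FWHM %.3g mm) and ROI tables",
           config$fwhm_mm)
    mask <- labels > 0
    map_names <- setdiff(names(maps[[1]][[1]]), "total_weight")
    voxelwise <- list(); roi_tab <- list(); ba <- list()
    template <- majorityVoteROI(rep(list(mask), 1))
    for (nm in map_names) {
      vols <- lapply(maps, function(subj) lapply(subj, `[[`, nm))
      voxelwise[[nm]] <- voxelwiseReliability(vols, mask, config$fwhm_mm,
                                              config$voxel_size_mm)
      # ROI-averaged table: subjects x sessions of per-label means
      labs <- sort(unique(labels[labels > 0]))
      for (l in labs) {
        tabm <- sapply(seq_len(config$cohort$n_sessions), function(se)
          vapply(seq_len(config$cohort$n_subjects), function(si)
            roiReduce(maps[[si]][[se]][[nm]], labels,
                      maps[[si]][[se]][["fbin3"]],
                      config$fbin3_max)[[as.character(l)]], numeric(1)))
        key <- sprintf("%s_roi%d", nm, l)
        icc <- if (all(is.finite(tabm))) iccA1(tabm)
               else list(icc = NA_real_, icc_clamped = NA_real_,
                         category = NA_character_)
        cv <- if (all(is.finite(tabm)))
          tryCatch(cvWS(tabm), error = function(e) NA_real_) else NA_real_
        roi_tab[[key]] <- data.frame(
          map = nm, roi = l, icc = icc$icc, icc_clamped = icc$icc_clamped,
          category = icc$category, cv_ws = cv)
      }
      # Bland-Altman over template-ROI voxels, sessions 1 vs 2
      tv <- which(template & mask)
      test <- unlist(lapply(maps, function(s) s[[1]][[nm]][tv]))
      retest <- unlist(lapply(maps, function(s) s[[2]][[nm]][tv]))
      ok <- is.finite(test) & is.finite(retest)
      ba[[nm]] <- blandAltman(test[ok], retest[ok])
    }
    rel <- list(voxelwise = voxelwise, roi = do.call(rbind, roi_tab),
                bland_altman = ba)
    saveStage(config, "reliability", rel)
  }

  # --- report -----------------------------------------------------------
  logmsg("report: writing outputs to %s", config$outdir)
  map_names <- names(maps[[1]][[1]])
  for (nm in map_names)
    writeVolume(maps[[1]][[1]][[nm]],
                file.path(config$outdir, sprintf("sub01_ses01_%s.nii.gz", nm)),
                config$voxel_size_mm)
  utils::write.table(rel$roi, file.path(config$outdir, "roi_reliability.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  vw <- data.frame(map = names(rel$voxelwise),
                   median_icc = vapply(rel$voxelwise, `[[`, numeric(1),
                                       "median_icc"),
                   median_cv = vapply(rel$voxelwise, `[[`, numeric(1),
                                      "median_cv"))
  utils::write.table(vw, file.path(config$outdir, "voxelwise_reliability.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(rel$bland_altman,
                       file.path(config$outdir, "bland_altman.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config_hash = config$hash, seed = config$seed,
    n_subjects = config$cohort$n_subjects,
    n_sessions = config$cohort$n_sessions,
    n_voxels = length(vox), n_measurements = nrow(cohort@protocol@table),
    n_bootstrap = config$inversion$n_bootstrap,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    log = log_lines)
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  writeProtocol(cohort@protocol, file.path(config$outdir, "protocol.tsv"))
  invisible(list(cohort = cohort, maps = maps, reliability = rel,
                 manifest = manifest_path))
}
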