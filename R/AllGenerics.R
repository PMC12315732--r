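#' @rdname centroidFrequency
#' @export
setGeneric("centroidFrequency", function(object, ...)
  standardGeneric("centroidFrequency"))

#' @rdname measurements
#' @export
setGeneric("measurements", function(object) standardGeneric("measurements"))

#' @rdname components
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname components
#' @export
setGeneric("weights<-", function(object, value) standardGeneric("weights<-"))

#' @rdname solutions
#' @export
setGeneric("solutions", function(object) standardGeneric("solutions"))

#' Accessors
#'
#' @param object an \linkS4class{AcquisitionProtocol}.
#' @return \code{measurements()} returns the protocol's measurement table
#'   (data.frame, one row per measurement).
#' @name measurements
#' @export
setMethod("measurements", "AcquisitionProtocol", function(object) object@table)

#' Component accessors
#'
#' @param object a \linkS4class{DRComponents}.
#' @param value replacement weight vector.
#' @return \code{components()} returns the component parameter matrix.
#' @name components
#' @export
setMethod("components", "DRComponents", function(object) object@params)

#' @name components
#' @export
setMethod("weights<-", "DRComponents", function(object, value) {
  object@params[, "weight"] <- value
  validObject(object)
  object
})

#' Result accessors
#'
#' @param object a \linkS4class{VoxelInversionResult}.
#' @return \code{solutions()} returns the list of bootstrap
#'   \linkS4class{DRComponents}.
#' @name solutions
#' @export
setMethod("solutions", "VoxelInversionResult", function(object) object@solutions)

setMethod("show", "BTensorSpectrum", function(object) {
  sh <- btensorShape(object@btensor)
  cat(sprintf(
    "BTensorSpectrum: %d frequency samples, b = %.3g ms/um^2, b_delta = %.3g\n",
    length(object@omega), sh$b, sh$b_delta))
})

setMethod("show", "AcquisitionProtocol", function(object) {
  tb <- object@table
  cat(sprintf("AcquisitionProtocol: %d measurements (%d with b = 0)\n",
              nrow(tb), sum(tb$b_ms_per_um2 == 0)))
  cat(sprintf("  b: %.3g-%.3g ms/um^2; b_delta in {%s}\n",
              min(tb$b_ms_per_um2[tb$b_ms_per_um2 > 0]), max(tb$b_ms_per_um2),
              paste(sort(unique(tb$b_delta)), collapse = ", ")))
  f <- tb$f_cent_hz[!is.na(tb$f_cent_hz)]
  if (length(f))
    cat(sprintf("  centroid frequencies: %.3g-%.3g Hz\n", min(f), max(f)))
  cat(sprintf("  TE in {%s} ms; TR in {%s} s\n",
              paste(sort(unique(tb$te_ms)), collapse = ", "),
              paste(sort(unique(tb$tr_s)), collapse = ", ")))
})

setMethod("show", "DRComponents", function(object) {
  p <- object@params
  cat(sprintf("DRComponents: %d components, total weight %.4g\n",
              nrow(p), if (nrow(p)) sum(p[, "weight"]) else 0))
})

setMethod("show", "VoxelInversionResult", function(object) {
  ns <- vapply(object@solutions, function(s) nrow(s@params), integer(1))
  cat(sprintf(
    "VoxelInversionResult: %d bootstrap solutions, %.1f components each (mean)\n",
    length(ns), mean(ns)))
})

setMethod("show", "ProjectionMesh", function(object) {
  cat(sprintf("ProjectionMesh [%s]: %dx%d, mass %.4g\n", object@plane,
              nrow(object@grid), ncol(object@grid), sum(object@grid)))
})

setMethod("show", "CohortDataset", function(object) {
  cat(sprintf(
    "CohortDataset: %d subjects x %d sessions, %d labelled voxels, %d measurements\n",
    length(object@signals), length(object@signals[[1]]),
    sum(object@labels > 0), nrow(object@protocol@table)))
})
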