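#' @include AllClasses.R AllGenerics.R units.R volumes.R phantom.R
NULL

#' Translation-only rigid registration by exhaustive integer search
#'
#' Finds the integer voxel shift (within a cubic search window) that
#' maximises the normalised cross-correlation between the shifted moving
#' volume and the reference, with zero fill outside the grid. Rotation is
#' not modelled: time points are assumed approximately aligned, and VOIs
#' defined on the reference are propagated with the recovered shift at
#' constant volume.
#'
#' @param moving,reference [ImageVolume]s on the same grid.
#' @param searchRadius maximum |shift| per axis, in voxels (default 5).
#' @return integer length-3 shift that aligns `moving` to `reference`
#'   (apply with [applyShift()]). Attributes: `score` (the NCC at the
#'   optimum) and `degenerate` (TRUE when either volume is constant, in
#'   which case the zero shift is returned with a warning).
#' @export
registerTranslation <- function(moving, reference, searchRadius = 5L) {
  .stopIfGeometryMismatch(moving, reference)
  stopifnot(searchRadius >= 0)
  r <- as.integer(searchRadius)
  ref <- voxelData(reference)
  mov <- voxelData(moving)
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    warning("degenerate (constant) volume: returning zero shift")
    out <- c(0L, 0L, 0L)
    attr(out, "score") <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  refc <- ref - mean(ref)
  refn <- sqrt(sum(refc^2))
  best <- c(0L, 0L, 0L); bestScore <- -Inf
  for (dz in -r:r) for (dy in -r:r) for (dx in -r:r) {
    sh <- shiftArray(mov, c(dx, dy, dz))
    shc <- sh - mean(sh)
    denom <- sqrt(sum(shc^2)) * refn
    score <- if (denom > 0) sum(shc * refc) / denom else -Inf
    ## strict > keeps the lexicographically-first (most negative) optimum;
    ## ties in practice only occur for the exact zero-shift identity
    if (score > bestScore + 1e-15) { bestScore <- score; best <- c(dx, dy, dz) }
  }
  out <- best
  attr(out, "score") <- bestScore
  attr(out, "degenerate") <- FALSE
  out
}

#' Apply an integer voxel shift to an ImageVolume
#'
#' @param x an [ImageVolume].
#' @param shift integer length-3 shift (as returned by
#'   [registerTranslation()]).
#' @return the shifted [ImageVolume] (zero fill).
#' @export
applyShift <- function(x, shift) {
  stopifnot(is(x, "ImageVolume"))
  ImageVolume(shiftArray(voxelData(x), shift), voxelSpacing(x), x@kind, x@time)
}

#' Per-organ activity from a count volume
#'
#' Converts total VOI counts to activity with the calibration factor
#' rescaled to the acquisition's duration: `activity = sum(counts) *
#' MBq_per_count`. The result is independent of the calibration factor's
#' unit kind and additive over disjoint VOIs.
#'
#' @param counts an [ImageVolume] of kind `"counts"`.
#' @param labels a [LabelMap] on the same grid.
#' @param cf a [CalibrationFactor].
#' @param acq the [AcquisitionMeta] of this acquisition; defaults to the
#'   calibration factor's own context.
#' @return data.frame with one row per catalogued organ: `organ`, `label`,
#'   `time_h`, `activity_MBq`, `voxels`, `mass_g`.
#' @export
voiActivity <- function(counts, labels, cf, acq = NULL) {
  stopifnot(is(counts, "ImageVolume"), is(labels, "LabelMap"),
            is(cf, "CalibrationFactor"))
  if (counts@kind != "counts")
    stop("voiActivity expects an ImageVolume of kind 'counts', got '",
         counts@kind, "'")
  .stopIfGeometryMismatch(counts, labels, "counts and labels")
  if (is.null(acq)) acq <- cf@context
  if (is.null(acq))
    stop("no acquisition metadata: supply acq or a calibration context")
  f <- mbqPerCount(cf, acq)
  lab <- voxelData(labels)
  cat_df <- organCatalogue(labels)
  cnt <- voxelData(counts)
  out <- data.frame(organ = cat_df$organ, label = cat_df$label,
                    time_h = counts@time, activity_MBq = NA_real_,
                    voxels = NA_integer_, mass_g = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cat_df))) {
    m <- lab == cat_df$label[i]
    out$voxels[i] <- sum(m)
    out$activity_MBq[i] <- sum(cnt[m]) * f
    out$mass_g[i] <- organMass(labels, cat_df$label[i])
  }
  out
}

#' Organ mass from a label map
#'
#' `mass = voxel count x voxel volume (cm^3) x density (g/cm^3)`, with the
#' density taken from the label catalogue (fixed per organ; no CT-number
#' conversion).
#'
#' @param labels a [LabelMap].
#' @param organ integer label or organ name.
#' @return mass in grams.
#' @export
organMass <- function(labels, organ) {
  stopifnot(is(labels, "LabelMap"))
  cat_df <- organCatalogue(labels)
  row <- if (is.character(organ)) match(organ, cat_df$organ)
         else match(as.integer(organ), cat_df$label)
  if (is.na(row))
    stop("unknown organ: ", organ)
  nvox <- sum(voxelData(labels) == cat_df$label[row])
  nvox * voxelVolumeCc(labels) * cat_df$density_gcc[row]
}

#' Assemble per-organ time-activity curves from quantified samples
#'
#' @param samples data.frame as returned by [voiActivity()] (rows from all
#'   time points concatenated).
#' @param A0 injected activity in MBq (time zero = injection).
#' @return named list of [TimeActivityCurve]s, one per organ.
#' @export
buildTac <- function(samples, A0) {
  stopifnot(all(c("organ", "time_h", "activity_MBq") %in% names(samples)))
  out <- list()
  for (og in unique(samples$organ)) {
    s <- samples[samples$organ == og, ]
    if (anyDuplicated(s$time_h))
      stop("duplicate acquisition times for organ '", og, "'")
    o <- order(s$time_h)
    out[[og]] <- new("TimeActivityCurve", organ = og,
                     times = s$time_h[o], activities = s$activity_MBq[o],
                     A0 = as.numeric(A0))
  }
  out
}

#' Construct a TimeActivityCurve directly
#'
#' @param organ organ name.
#' @param times hours post injection (sorted internally; duplicates are an
#'   error).
#' @param activities MBq.
#' @param A0 injected activity MBq.
#' @return a [TimeActivityCurve].
#' @export
TimeActivityCurve <- function(organ, times, activities, A0) {
  if (anyDuplicated(times)) stop("duplicate acquisition times")
  o <- order(times)
  new("TimeActivityCurve", organ = organ, times = as.numeric(times)[o],
      activities = as.numeric(activities)[o], A0 = as.numeric(A0))
}

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve '%s' (A0 = %g MBq):\n", object@organ,
              object@A0))
  print(data.frame(time_h = object@times, activity_MBq = object@activities),
        row.names = FALSE)
})
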