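#' @include AllClasses.R AllGenerics.R
NULL

## Decays per MBq h: 1e6 decays/s * 3600 s.
.DECAYS_PER_MBQH <- 3.6e9

#' Construct a Radionuclide
#'
#' @param name isotope name, e.g. `"Lu-177"`.
#' @param halfLife physical half-life in hours (Lu-177: 159.53 h).
#' @param localEnergyPerDecay locally deposited energy per nuclear
#'   transformation, in joules. Required by the LED and DVK dose engines;
#'   defaults to 0 for kinetics-only use.
#' @return a [Radionuclide].
#' @examples
#' Radionuclide("Lu-177", halfLife = 159.53, localEnergyPerDecay = 2.3697e-14)
#' @export
Radionuclide <- function(name, halfLife, localEnergyPerDecay = 0) {
  new("Radionuclide", name = name, halfLife = as.numeric(halfLife),
      localEnergyPerDecay = as.numeric(localEnergyPerDecay))
}

#' @rdname decayConstant
setMethod("decayConstant", "Radionuclide", function(x) {
  if (x@halfLife <= 0) stop("half-life must be positive")
  log(2) / x@halfLife
})

setMethod("show", "Radionuclide", function(object) {
  cat(sprintf("Radionuclide %s: T1/2 = %g h (lambda = %.6g 1/h), E_local = %g J\n",
              object@name, object@halfLife, decayConstant(object),
              object@localEnergyPerDecay))
})

#' Construct acquisition metadata
#'
#' @param nProjections number of projections.
#' @param secondsPerProjection seconds per projection.
#' @param timePostInjection hours post injection (`NA` for calibration scans).
#' @return an [AcquisitionMeta].
#' @examples
#' AcquisitionMeta(60, 45)          # patient protocol
#' AcquisitionMeta(60, 120)         # calibration phantom protocol
#' @export
AcquisitionMeta <- function(nProjections, secondsPerProjection,
                            timePostInjection = NA_real_) {
  new("AcquisitionMeta", nProjections = as.numeric(nProjections),
      secondsPerProjection = as.numeric(secondsPerProjection),
      timePostInjection = as.numeric(timePostInjection))
}

#' @rdname totalDuration
setMethod("totalDuration", "AcquisitionMeta", function(x)
  x@nProjections * x@secondsPerProjection)

setMethod("show", "AcquisitionMeta", function(object) {
  cat(sprintf("AcquisitionMeta: %g projections x %g s (total %g s)%s\n",
              object@nProjections, object@secondsPerProjection,
              totalDuration(object),
              if (is.na(object@timePostInjection)) "" else
                sprintf(", t = %g h p.i.", object@timePostInjection)))
})

#' Construct a calibration factor
#'
#' @param magnitude positive scalar.
#' @param unitKind `"cps_per_MBq"`, `"MBq_per_count"`, `"Bq_per_count"` or
#'   `"Bq_per_intensity"` (the last two are synonymous: "intensity" is
#'   reconstructed voxel counts).
#' @param context [AcquisitionMeta] of the scan the factor was measured on;
#'   mandatory for count-based unit kinds.
#' @return a [CalibrationFactor].
#' @examples
#' CalibrationFactor(13.6e-6, "MBq_per_count", AcquisitionMeta(60, 120))
#' @export
CalibrationFactor <- function(magnitude, unitKind, context = NULL) {
  cf <- new("CalibrationFactor", magnitude = as.numeric(magnitude),
            unitKind = unitKind, context = context)
  if (.cfCountBased(cf) && is.null(context))
    stop("count-based calibration factors need an AcquisitionMeta context")
  cf
}

.cfCountBased <- function(cf) cf@unitKind != "cps_per_MBq"

.cfDuration <- function(cf) {
  if (is.null(cf@context))
    stop("calibration factor has no acquisition-duration context")
  totalDuration(cf@context)
}

#' System sensitivity implied by a calibration factor
#'
#' Converts any calibration-factor unit kind to the duration-invariant
#' sensitivity in cps/MBq. For a factor of `m` MBq/count measured over a
#' total acquisition duration `T` seconds this is `1 / (m * T)`;
#' a `cps_per_MBq` factor is returned unchanged.
#'
#' @param cf a [CalibrationFactor].
#' @return sensitivity in cps/MBq.
#' @examples
#' cf <- CalibrationFactor(13.6e-6, "MBq_per_count", AcquisitionMeta(60, 120))
#' sensitivityCpsPerMBq(cf)   # 10.21 cps/MBq
#' @export
sensitivityCpsPerMBq <- function(cf) {
  stopifnot(is(cf, "CalibrationFactor"))
  switch(cf@unitKind,
    cps_per_MBq   = cf@magnitude,
    MBq_per_count = 1 / (cf@magnitude * .cfDuration(cf)),
    ## Bq/count and Bq/intensity: magnitude * 1e-6 is MBq/count
    1 / (cf@magnitude * 1e-6 * .cfDuration(cf)))
}

#' Convert a calibration factor to another unit kind
#'
#' Conversion is exact and invertible; the acquisition context is preserved.
#' Converting to a count-based kind requires a duration context.
#'
#' @param cf a [CalibrationFactor].
#' @param unitKind target unit kind.
#' @return a [CalibrationFactor] of the requested kind.
#' @export
convertCalibration <- function(cf, unitKind) {
  stopifnot(is(cf, "CalibrationFactor"), unitKind %in% .CF_KINDS)
  if (unitKind == cf@unitKind) return(cf)
  s <- sensitivityCpsPerMBq(cf)
  mag <- switch(unitKind,
    cps_per_MBq = s,
    MBq_per_count = 1 / (s * .cfDuration(cf)),
    1e6 / (s * .cfDuration(cf)))
  new("CalibrationFactor", magnitude = mag, unitKind = unitKind,
      context = cf@context)
}

#' Rescale a calibration factor to another acquisition duration
#'
#' Count-based factors were measured for a particular total acquisition
#' duration; applying them to a scan acquired for a different duration
#' requires scaling the magnitude by `context_duration / target_duration`
#' (e.g. a factor measured on a 60 x 120 s calibration scan applied to
#' 60 x 45 s patient scans). Sensitivities in cps/MBq are
#' duration-invariant and pass through unchanged apart from the context.
#'
#' @param cf a [CalibrationFactor].
#' @param target [AcquisitionMeta] of the scans the factor will be applied to.
#' @return a [CalibrationFactor] valid for `target`.
#' @export
rescaleForDuration <- function(cf, target) {
  stopifnot(is(cf, "CalibrationFactor"), is(target, "AcquisitionMeta"))
  if (totalDuration(target) <= 0) stop("target duration must be positive")
  if (!.cfCountBased(cf))
    return(new("CalibrationFactor", magnitude = cf@magnitude,
               unitKind = cf@unitKind, context = target))
  ratio <- .cfDuration(cf) / totalDuration(target)
  new("CalibrationFactor", magnitude = cf@magnitude * ratio,
      unitKind = cf@unitKind, context = target)
}

#' Activity conversion factor in MBq per count for a given acquisition
#'
#' The factor actually applied during quantification: the calibration factor
#' rescaled to the target acquisition's duration and expressed in MBq/count.
#'
#' @param cf a [CalibrationFactor].
#' @param acq target [AcquisitionMeta].
#' @return scalar MBq per count.
#' @export
mbqPerCount <- function(cf, acq) {
  stopifnot(is(acq, "AcquisitionMeta"))
  1 / (sensitivityCpsPerMBq(cf) * totalDuration(acq))
}

setMethod("show", "CalibrationFactor", function(object) {
  cat(sprintf("CalibrationFactor: %g %s", object@magnitude,
              gsub("_", " ", object@unitKind)))
  if (!is.null(object@context))
    cat(sprintf(" (measured over %g s)", totalDuration(object@context)))
  cat(sprintf(" [sensitivity %s cps/MBq]\n",
              tryCatch(format(sensitivityCpsPerMBq(object), digits = 4),
                       error = function(e) "?")))
})

#' Read a radionuclide from a plain-text (YAML) configuration
#'
#' The schema is a flat key-value mapping: `name`, `half_life_h`,
#' `local_energy_per_decay_J`. A Lu-177 configuration ships with the package
#' (`system.file("extdata", "lu177.yaml", package = "mirdose")`); its
#' half-life is 159.53 h and the locally deposited energy per decay must be
#' reviewed against the user's preferred decay-data compilation.
#'
#' @param path path to a YAML file.
#' @return a [Radionuclide].
#' @export
readNuclideConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "half_life_h")
  if (!all(need %in% names(cfg)))
    stop("nuclide config needs keys: ", paste(need, collapse = ", "))
  Radionuclide(cfg$name, cfg$half_life_h,
               if (is.null(cfg$local_energy_per_decay_J)) 0
               else cfg$local_energy_per_decay_J)
}
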