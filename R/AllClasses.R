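#' @import methods
NULL

## Central S4 containers for the dosimetry workflow. All physical quantities
## use the package's canonical units: MBq (activity), hours (time), seconds
## (acquisition durations only), grams (mass), Gy (dose), mm (length).

.VOLUME_KINDS <- c("counts", "activity", "tia", "dose", "density")
.CF_KINDS <- c("cps_per_MBq", "MBq_per_count", "Bq_per_count", "Bq_per_intensity")
.FIT_FAMILIES <- c("monoexp", "biexp", "powerexp", "trapezoid_tail")
.HEAD_RULES <- c("zero_line", "constant")

#' ImageVolume: a 3D scalar grid with voxel spacing and a semantic kind
#'
#' The one container every stage of the pipeline exchanges: reconstructed
#' counts, activity maps (MBq), time-integrated activity maps (MBq h), dose
#' maps (Gy) and density maps (g/cm^3) are all `ImageVolume`s distinguished by
#' their `kind` tag, so that a stage can refuse input produced by the wrong
#' upstream operation.
#'
#' @slot voxels numeric 3D array of voxel values.
#' @slot spacing numeric length-3 voxel spacing in mm (x, y, z).
#' @slot kind one of `"counts"`, `"activity"`, `"tia"`, `"dose"`, `"density"`.
#' @slot time acquisition time in hours post injection (`NA` when not
#'   applicable, e.g. for density maps).
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", kind = "character",
                 time = "numeric"),
  prototype(time = NA_real_))

setValidity("ImageVolume", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (mm)")
  if (length(object@kind) != 1L || !object@kind %in% .VOLUME_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(.VOLUME_KINDS, collapse = ", ")))
  if (length(object@time) != 1L)
    msg <- c(msg, "time must be a single value (hours, NA allowed)")
  if (length(msg)) msg else TRUE
})

#' LabelMap: integer organ labels on a voxel grid plus an organ catalogue
#'
#' Label 0 is reserved for background. Every non-zero label occurring in the
#' grid must be described in the catalogue, which maps a label to an organ
#' name and a mass density in g/cm^3 (fixed densities per organ, no HU
#' conversion).
#'
#' @slot voxels integer 3D array of labels (0 = background).
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot catalogue data.frame with columns `label`, `organ`, `density_gcc`.
#' @exportClass LabelMap
setClass("LabelMap",
  representation(voxels = "array", spacing = "numeric", catalogue = "data.frame"))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@voxels)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  need <- c("label", "organ", "density_gcc")
  if (!all(need %in% names(object@catalogue)))
    msg <- c(msg, "catalogue needs columns label, organ, density_gcc")
  else {
    if (any(object@catalogue$label == 0L))
      msg <- c(msg, "label 0 is reserved for background")
    if (anyDuplicated(object@catalogue$label))
      msg <- c(msg, "duplicate labels in catalogue")
    if (any(object@catalogue$density_gcc <= 0))
      msg <- c(msg, "densities must be positive")
    present <- setdiff(unique(as.integer(object@voxels)), 0L)
    missing <- setdiff(present, object@catalogue$label)
    if (length(missing))
      msg <- c(msg, sprintf("labels present in grid but not in catalogue: %s",
                            paste(missing, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Radionuclide: physical half-life and locally deposited energy per decay
#'
#' `localEnergyPerDecay` is the energy (J) assumed absorbed where it is
#' emitted — the non-penetrating emission energy used by the local-energy
#' deposition engine and for dose-voxel-kernel normalisation. It must come
#' from a decay-data compilation; the shipped Lu-177 configuration documents
#' the value used.
#'
#' @slot name character isotope name.
#' @slot halfLife physical half-life in hours.
#' @slot localEnergyPerDecay energy per nuclear transformation in joules.
#' @exportClass Radionuclide
setClass("Radionuclide",
  representation(name = "character", halfLife = "numeric",
                 localEnergyPerDecay = "numeric"))

setValidity("Radionuclide", function(object) {
  msg <- character()
  if (!length(object@halfLife) == 1L || !is.finite(object@halfLife) ||
      object@halfLife <= 0)
    msg <- c(msg, "halfLife must be a single positive number (hours)")
  if (!length(object@localEnergyPerDecay) == 1L ||
      is.na(object@localEnergyPerDecay) || object@localEnergyPerDecay < 0)
    msg <- c(msg, "localEnergyPerDecay must be a single non-negative number (J)")
  if (length(msg)) msg else TRUE
})

#' AcquisitionMeta: SPECT acquisition context
#'
#' @slot nProjections number of projections.
#' @slot secondsPerProjection seconds per projection.
#' @slot timePostInjection hours post injection (`NA` for calibration scans).
#' @exportClass AcquisitionMeta
setClass("AcquisitionMeta",
  representation(nProjections = "numeric", secondsPerProjection = "numeric",
                 timePostInjection = "numeric"),
  prototype(timePostInjection = NA_real_))

setValidity("AcquisitionMeta", function(object) {
  msg <- character()
  if (object@nProjections <= 0 || object@nProjections != round(object@nProjections))
    msg <- c(msg, "nProjections must be a positive whole number")
  if (!is.finite(object@secondsPerProjection) || object@secondsPerProjection <= 0)
    msg <- c(msg, "secondsPerProjection must be positive")
  if (!is.na(object@timePostInjection) && object@timePostInjection <= 0)
    msg <- c(msg, "timePostInjection must be positive (hours)")
  if (length(msg)) msg else TRUE
})

#' CalibrationFactor: converts reconstructed counts to activity
#'
#' A calibration factor is only meaningful together with the acquisition it
#' was measured on: count-based factors (MBq/count, Bq/count, Bq/intensity)
#' scale with total acquisition duration, while a sensitivity in cps/MBq is
#' duration-invariant. "Intensity" is treated as a synonym for reconstructed
#' voxel counts.
#'
#' @slot magnitude positive scalar in the units given by `unitKind`.
#' @slot unitKind one of `"cps_per_MBq"`, `"MBq_per_count"`, `"Bq_per_count"`,
#'   `"Bq_per_intensity"`.
#' @slot context the [AcquisitionMeta] of the phantom scan the factor was
#'   measured on; required for count-based unit kinds.
#' @exportClass CalibrationFactor
setClass("CalibrationFactor",
  representation(magnitude = "numeric", unitKind = "character",
                 context = "ANY"),
  prototype(context = NULL))

setValidity("CalibrationFactor", function(object) {
  msg <- character()
  if (!is.finite(object@magnitude) || object@magnitude <= 0)
    msg <- c(msg, "magnitude must be positive")
  if (!object@unitKind %in% .CF_KINDS)
    msg <- c(msg, sprintf("unitKind must be one of: %s",
                          paste(.CF_KINDS, collapse = ", ")))
  if (!is.null(object@context) && !is(object@context, "AcquisitionMeta"))
    msg <- c(msg, "context must be an AcquisitionMeta or NULL")
  if (length(msg)) msg else TRUE
})

#' TimeActivityCurve: per-organ (time, activity) samples
#'
#' @slot organ organ name.
#' @slot times hours post injection, strictly increasing.
#' @slot activities MBq, non-negative.
#' @slot A0 injected activity in MBq (time zero is the injection instant).
#' @exportClass TimeActivityCurve
setClass("TimeActivityCurve",
  representation(organ = "character", times = "numeric",
                 activities = "numeric", A0 = "numeric"))

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  if (length(object@times) < 1L)
    msg <- c(msg, "need at least one sample")
  if (length(object@times) != length(object@activities))
    msg <- c(msg, "times and activities differ in length")
  if (any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (any(object@activities < 0))
    msg <- c(msg, "activities must be non-negative")
  if (!is.finite(object@A0) || object@A0 <= 0)
    msg <- c(msg, "A0 must be positive (MBq)")
  if (length(msg)) msg else TRUE
})

#' FitResult: fitted time-activity model with TIA and TIAC
#'
#' @slot organ organ name.
#' @slot model fit family (`"monoexp"`, `"biexp"`, `"powerexp"`,
#'   `"trapezoid_tail"`).
#' @slot parameters named numeric parameter vector (empty for trapezoid).
#' @slot headRule trapezoid head rule (`"zero_line"` or `"constant"`; `NA`
#'   for exponential families).
#' @slot tailRate tail extrapolation rate in 1/h (`NA` for exponential
#'   families).
#' @slot tia time-integrated activity in MBq h (integral 0 to infinity).
#' @slot tiac time-integrated activity coefficient, `tia / A0`, in hours.
#' @slot A0 injected activity (MBq).
#' @slot goodness Spearman rank correlation between fitted and observed
#'   activities (`NA` when undefined).
#' @slot rss residual sum of squares.
#' @slot converged logical convergence flag.
#' @slot flags character vector of warnings (e.g. `"non_decaying"`).
#' @exportClass FitResult
setClass("FitResult",
  representation(organ = "character", model = "character",
                 parameters = "numeric", headRule = "character",
                 tailRate = "numeric", tia = "numeric", tiac = "numeric",
                 A0 = "numeric", goodness = "numeric", rss = "numeric",
                 converged = "logical", flags = "character"),
  prototype(headRule = NA_character_, tailRate = NA_real_,
            goodness = NA_real_, flags = character()))

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@model %in% .FIT_FAMILIES)
    msg <- c(msg, "unknown model family")
  if (is.finite(object@tia) && object@tia < 0)
    msg <- c(msg, "TIA must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SValueTable: source to target S values with reference masses
#'
#' S values are in Gy per MBq h of time-integrated activity in the source
#' region, tabulated for a reference anatomy whose organ masses are carried
#' in `refMass` (grams) so that patient-specific mass adjustment can be
#' applied to the self-dose term.
#'
#' @slot nuclide radionuclide name the table applies to.
#' @slot entries data.frame with columns `source`, `target`,
#'   `S_Gy_per_MBqh`.
#' @slot refMass named numeric vector of reference organ masses (g).
#' @slot provenance free-text provenance note.
#' @exportClass SValueTable
setClass("SValueTable",
  representation(nuclide = "character", entries = "data.frame",
                 refMass = "numeric", provenance = "character"),
  prototype(provenance = ""))

setValidity("SValueTable", function(object) {
  msg <- character()
  need <- c("source", "target", "S_Gy_per_MBqh")
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, "entries needs columns source, target, S_Gy_per_MBqh")
  else if (any(object@entries$S_Gy_per_MBqh < 0))
    msg <- c(msg, "S values must be non-negative")
  if (any(object@refMass <= 0))
    msg <- c(msg, "reference masses must be positive")
  if (length(msg)) msg else TRUE
})

#' DoseKernel: dose distribution around a unit source voxel
#'
#' An odd-sized 3D grid of Gy per MBq h for a point (voxel) source at the
#' centre, precomputed in a homogeneous medium (water). Convolving a TIA map
#' with the kernel gives a dose map; the kernel's spacing must match the TIA
#' map's exactly (no implicit resampling).
#'
#' @slot values odd-sized 3D array, Gy per MBq h; the central voxel holds the
#'   maximum.
#' @slot spacing voxel spacing in mm.
#' @slot medium medium label (`"water"`).
#' @slot energyFraction fraction of the nuclide's local energy contained in
#'   the truncated kernel (1 for radius 0).
#' @exportClass DoseKernel
setClass("DoseKernel",
  representation(values = "array", spacing = "numeric", medium = "character",
                 energyFraction = "numeric"),
  prototype(medium = "water", energyFraction = 1))

setValidity("DoseKernel", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L || any(d %% 2L == 0L))
    msg <- c(msg, "kernel must be a 3D array with odd dimensions")
  else {
    ctr <- (d + 1L) / 2L
    if (object@values[ctr[1], ctr[2], ctr[3]] < max(object@values))
      msg <- c(msg, "central voxel must hold the kernel maximum")
  }
  if (any(object@values < 0))
    msg <- c(msg, "kernel values must be non-negative")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' DoseReport: per-organ dosimetry summary from one dose engine
#'
#' @slot table data.frame with one row per organ: `organ`, `mass_g`,
#'   `tiac_h`, `mean_dose_Gy`, `engine`.
#' @slot engine engine id (`"svalue"`, `"led"`, `"dvk"`).
#' @slot doseMap optional dose [ImageVolume].
#' @slot dvh optional named list of DVHs (per organ: `dose_Gy` bin edges,
#'   `fraction` of VOI volume receiving at least that dose).
#' @exportClass DoseReport
setClass("DoseReport",
  representation(table = "data.frame", engine = "character",
                 doseMap = "ANY", dvh = "list"),
  prototype(doseMap = NULL, dvh = list()))

setValidity("DoseReport", function(object) {
  need <- c("organ", "mass_g", "tiac_h", "mean_dose_Gy", "engine")
  if (!all(need %in% names(object@table)))
    return("table needs columns organ, mass_g, tiac_h, mean_dose_Gy, engine")
  TRUE
})

#' PhantomSpec: specification of the synthetic digital phantom
#'
#' Defines the geometry (ellipsoidal organs on a voxel grid), per-organ
#' kinetics (sums of decaying exponentials as fractions of the injected
#' activity), the acquisition design (time points, projections, sensitivity)
#' and the noise model. A spec plus a seed fully determines the simulated
#' count volumes.
#'
#' @slot dim grid dimensions in voxels.
#' @slot spacing voxel spacing mm.
#' @slot organs list of organ definitions; each is a list with `label`,
#'   `name`, `center` (mm), `semiAxes` (mm), `density_gcc`, `kinetics`
#'   (list with `fractions`, `rates` in 1/h).
#' @slot background background kinetics (same shape as an organ `kinetics`
#'   entry; activity spread uniformly over unlabelled voxels), may be NULL.
#' @slot A0 injected activity MBq.
#' @slot times acquisition times, hours post injection.
#' @slot acq [AcquisitionMeta] of the emulated patient acquisitions.
#' @slot sensitivity system sensitivity in cps/MBq.
#' @slot nuclide [Radionuclide].
#' @slot noise `"none"` or `"poisson"`.
#' @slot shifts optional integer matrix (time points x 3) of voxel
#'   translations applied per time point; zero rows disable.
#' @slot seed integer seed governing the Poisson draws.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(dim = "integer", spacing = "numeric", organs = "list",
                 background = "ANY", A0 = "numeric", times = "numeric",
                 acq = "AcquisitionMeta", sensitivity = "numeric",
                 nuclide = "Radionuclide", noise = "character",
                 shifts = "matrix", seed = "integer"),
  prototype(background = NULL, noise = "poisson"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (length(object@dim) != 3L || any(object@dim < 1L))
    msg <- c(msg, "dim must be three positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values (mm)")
  if (!object@noise %in% c("none", "poisson"))
    msg <- c(msg, "noise must be 'none' or 'poisson'")
  if (object@A0 <= 0) msg <- c(msg, "A0 must be positive (MBq)")
  if (length(object@times) < 1L || any(object@times <= 0) ||
      any(diff(object@times) <= 0))
    msg <- c(msg, "times must be positive and strictly increasing (hours)")
  if (object@sensitivity <= 0) msg <- c(msg, "sensitivity must be positive")
  for (og in object@organs) {
    kin <- og$kinetics
    if (any(kin$rates <= 0) || length(kin$fractions) != length(kin$rates))
      msg <- c(msg, sprintf("organ '%s': kinetics need matched fractions and positive rates", og$name))
    if (any(vapply(object@times, function(t)
      sum(kin$fractions * exp(-kin$rates * t)), 0) < 0))
      msg <- c(msg, sprintf("organ '%s': negative activity at a requested time", og$name))
  }
  if (nrow(object@shifts) > 0 &&
      (nrow(object@shifts) != length(object@times) || ncol(object@shifts) != 3L))
    msg <- c(msg, "shifts must be a (n_times x 3) integer matrix or empty")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: analytic per-organ truth for a simulated phantom
#'
#' @slot organs data.frame: `organ`, `label`, `voxels`, `mass_g`,
#'   `tia_MBqh`, `tiac_h`, `mean_dose_Gy` (local-deposition assumption).
#' @slot activities matrix of analytic organ activities (MBq), organs x
#'   time points.
#' @slot times acquisition times (h).
#' @slot A0 injected activity (MBq).
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(organs = "data.frame", activities = "matrix",
                 times = "numeric", A0 = "numeric"))

#' StudyConfig: a fully reproducible dosimetry study definition
#'
#' @slot phantom a [PhantomSpec] (synthetic study), or NULL for file input.
#' @slot volumePaths character paths to per-time-point count volumes (NIfTI);
#'   ignored when `phantom` is set.
#' @slot labelPath path to the label-map volume; ignored for phantom studies.
#' @slot catalogue organ catalogue data.frame for file input.
#' @slot times acquisition times (h) for file input.
#' @slot calibration [CalibrationFactor].
#' @slot nuclide [Radionuclide].
#' @slot A0 injected activity MBq.
#' @slot acq patient [AcquisitionMeta].
#' @slot fitModel `"auto"` or one of the fit families, or a named list per
#'   organ.
#' @slot headRule trapezoid head rule.
#' @slot engine dose engine(s): subset of `"svalue"`, `"led"`, `"dvk"`.
#' @slot svalueTable [SValueTable] or NULL (required for the svalue engine).
#' @slot kernelRadius DVK radius in voxels.
#' @slot registration logical; run translation registration across time points.
#' @slot outputDir output/checkpoint directory (`NA` disables checkpointing).
#' @slot seed integer seed.
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(phantom = "ANY", volumePaths = "character",
                 labelPath = "character", catalogue = "data.frame",
                 times = "numeric", calibration = "CalibrationFactor",
                 nuclide = "Radionuclide", A0 = "numeric",
                 acq = "AcquisitionMeta", fitModel = "ANY",
                 headRule = "character", engine = "character",
                 svalueTable = "ANY", kernelRadius = "numeric",
                 registration = "logical", outputDir = "character",
                 seed = "integer"),
  prototype(phantom = NULL, volumePaths = character(), labelPath = NA_character_,
            times = numeric(), fitModel = "auto", headRule = "zero_line",
            engine = "led", svalueTable = NULL, kernelRadius = 0,
            registration = FALSE, outputDir = NA_character_, seed = 1L))
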