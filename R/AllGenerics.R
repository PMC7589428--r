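#' @include AllClasses.R
NULL

#' Physical decay constant of a radionuclide
#'
#' @param x a [Radionuclide].
#' @return decay rate in 1/h, `ln(2) / halfLife`.
#' @examples
#' lu177 <- Radionuclide("Lu-177", halfLife = 159.53)
#' decayConstant(lu177)
#' @export
setGeneric("decayConstant", function(x) standardGeneric("decayConstant"))

#' Total acquisition duration in seconds
#'
#' @param x an [AcquisitionMeta].
#' @return `nProjections * secondsPerProjection`, in seconds.
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' Voxel data of a volume-like object
#' @param x an [ImageVolume] or [LabelMap].
#' @return the underlying 3D array.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Voxel spacing in mm
#' @param x an [ImageVolume], [LabelMap] or [DoseKernel].
#' @return numeric length-3 spacing.
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))

#' Voxel volume in cm^3
#' @param x an [ImageVolume], [LabelMap] or [DoseKernel].
#' @return scalar voxel volume in cm^3.
#' @export
setGeneric("voxelVolumeCc", function(x) standardGeneric("voxelVolumeCc"))

#' Organ catalogue of a label map
#' @param x a [LabelMap].
#' @return data.frame with columns `label`, `organ`, `density_gcc`.
#' @export
setGeneric("organCatalogue", function(x) standardGeneric("organCatalogue"))

#' Time-integrated activity (MBq h) of a fit result
#' @param x a [FitResult].
#' @export
setGeneric("tia", function(x) standardGeneric("tia"))

#' Time-integrated activity coefficient (hours) of a fit result
#' @param x a [FitResult].
#' @export
setGeneric("tiac", function(x) standardGeneric("tiac"))

#' Per-organ summary table of a dose report
#' @param x a [DoseReport].
#' @return data.frame with `organ`, `mass_g`, `tiac_h`, `mean_dose_Gy`,
#'   `engine`.
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))
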