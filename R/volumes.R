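#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array.
#' @param spacing voxel spacing in mm; a scalar is recycled isotropically.
#' @param kind semantic tag: `"counts"`, `"activity"` (MBq), `"tia"` (MBq h),
#'   `"dose"` (Gy) or `"density"` (g/cm^3).
#' @param time hours post injection, where applicable.
#' @return an [ImageVolume].
#' @examples
#' v <- ImageVolume(array(0, c(8, 8, 8)), spacing = 4.42, kind = "counts")
#' voxelVolumeCc(v)
#' @export
ImageVolume <- function(voxels, spacing, kind, time = NA_real_) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      kind = kind, time = as.numeric(time))
}

#' Construct a LabelMap
#'
#' @param voxels 3D integer array (0 = background).
#' @param spacing voxel spacing in mm; scalar recycled.
#' @param catalogue data.frame with `label`, `organ`, `density_gcc`.
#' @return a [LabelMap].
#' @export
LabelMap <- function(voxels, spacing, catalogue) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  storage.mode(voxels) <- "integer"
  new("LabelMap", voxels = voxels, spacing = as.numeric(spacing),
      catalogue = catalogue)
}

#' @rdname voxelData
setMethod("voxelData", "ImageVolume", function(x) x@voxels)
#' @rdname voxelData
setMethod("voxelData", "LabelMap", function(x) x@voxels)

#' @rdname voxelSpacing
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "LabelMap", function(x) x@spacing)
#' @rdname voxelSpacing
setMethod("voxelSpacing", "DoseKernel", function(x) x@spacing)

#' @rdname voxelVolumeCc
setMethod("voxelVolumeCc", "ImageVolume", function(x) prod(x@spacing) / 1e3)
#' @rdname voxelVolumeCc
setMethod("voxelVolumeCc", "LabelMap", function(x) prod(x@spacing) / 1e3)

#' @rdname organCatalogue
setMethod("organCatalogue", "LabelMap", function(x) x@catalogue)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume [%s]: %d x %d x %d voxels @ %s mm%s\n",
              object@kind, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x "),
              if (is.na(object@time)) "" else
                sprintf(", t = %g h p.i.", object@time)))
  cat(sprintf("  range [%g, %g], sum %g\n", min(object@voxels),
              max(object@voxels), sum(object@voxels)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("LabelMap: %d x %d x %d voxels, %d organ(s)\n",
              d[1], d[2], d[3], nrow(object@catalogue)))
  if (nrow(object@catalogue)) print(object@catalogue, row.names = FALSE)
})

.sameGeometry <- function(a, b, tol = 1e-9) {
  identical(dim(voxelData(a)), dim(voxelData(b))) &&
    all(abs(voxelSpacing(a) - voxelSpacing(b)) <=
          tol * pmax(voxelSpacing(a), 1))
}

.stopIfGeometryMismatch <- function(a, b, what = "volumes") {
  if (!.sameGeometry(a, b))
    stop(what, " must share grid shape and voxel spacing")
  invisible(TRUE)
}

#' Write an ImageVolume or LabelMap to NIfTI-1
#'
#' Voxel spacing is carried in the NIfTI pixdim; the semantic kind and time
#' point are stored in the description field.
#'
#' @param x an [ImageVolume] or [LabelMap].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  arr <- voxelData(x)
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, voxelSpacing(x))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ImageVolume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param kind semantic tag to assign.
#' @param time hours post injection.
#' @return an [ImageVolume].
#' @export
readVolume <- function(path, kind = "counts", time = NA_real_) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  ImageVolume(array(as.numeric(img), dim = dim(img)[seq_len(3)]),
              spacing = sp, kind = kind, time = time)
}

#' Read a LabelMap from NIfTI-1 plus a catalogue
#'
#' @param path NIfTI file of integer labels.
#' @param catalogue data.frame (`label`, `organ`, `density_gcc`) or a path to
#'   a CSV file with those columns.
#' @return a [LabelMap].
#' @export
readLabelMap <- function(path, catalogue) {
  if (is.character(catalogue))
    catalogue <- utils::read.csv(catalogue, stringsAsFactors = FALSE)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[seq_len(3)]
  LabelMap(array(as.integer(round(img)), dim = dim(img)[seq_len(3)]),
           spacing = sp, catalogue = catalogue)
}
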