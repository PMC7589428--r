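#' @include AllClasses.R AllGenerics.R units.R volumes.R
NULL

#' Define an ellipsoidal phantom organ
#'
#' @param label positive integer label.
#' @param name organ name.
#' @param center ellipsoid centre in mm (voxel-centre world coordinates,
#'   0-based voxel indices times spacing).
#' @param semiAxes ellipsoid semi-axes in mm.
#' @param density_gcc mass density in g/cm^3.
#' @param fractions fractions of the injected activity in each kinetic
#'   component at time zero.
#' @param rates effective decay rates (biological + physical) in 1/h, one per
#'   component; one component gives mono-exponential kinetics, two give
#'   bi-exponential.
#' @return a list suitable for the `organs` slot of a [PhantomSpec].
#' @export
phantomOrgan <- function(label, name, center, semiAxes, density_gcc,
                         fractions, rates) {
  stopifnot(label > 0, length(center) == 3L, length(semiAxes) == 3L,
            all(semiAxes > 0), density_gcc > 0,
            length(fractions) == length(rates), all(rates > 0))
  list(label = as.integer(label), name = name, center = as.numeric(center),
       semiAxes = as.numeric(semiAxes), density_gcc = density_gcc,
       kinetics = list(fractions = as.numeric(fractions),
                       rates = as.numeric(rates)))
}

#' Specify a synthetic digital phantom study
#'
#' The defaults emulate a Lu-177 peptide-receptor-therapy acquisition design:
#' four SPECT/CT time points at 4/24/72/192 h post injection of 7200 MBq,
#' 4.42 mm isotropic voxels on a 128 x 128 x 96 grid, 60 projections of 45 s,
#' a system sensitivity of 10 cps/MBq, and Poisson counting noise. The
#' default anatomy is four ellipsoidal abdominal organs (liver and spleen at
#' 1.06 g/cm^3, two kidneys at 1.05 g/cm^3) with mono-exponential kinetics
#' giving organ TIACs of a few hours (kidney pair ~1.5 h).
#'
#' @param dim grid dimensions in voxels.
#' @param spacing voxel spacing in mm (scalar recycled).
#' @param organs list of [phantomOrgan()] definitions; `NULL` selects the
#'   default abdominal anatomy.
#' @param background background kinetics as `list(fractions=, rates=)`, or
#'   `NULL` for no background activity.
#' @param A0 injected activity in MBq.
#' @param times acquisition times in hours post injection.
#' @param acq patient [AcquisitionMeta].
#' @param sensitivity system sensitivity in cps/MBq.
#' @param nuclide [Radionuclide]; default Lu-177 with the shipped constants.
#' @param noise `"poisson"` or `"none"`.
#' @param shifts optional integer matrix (time points x 3) of voxel shifts
#'   applied to each time point's count volume, to exercise registration.
#' @param seed integer seed for the noise draws.
#' @return a [PhantomSpec].
#' @examples
#' spec <- PhantomSpec(dim = c(48, 48, 32), noise = "none")
#' @export
PhantomSpec <- function(dim = c(128L, 128L, 96L), spacing = 4.42,
                        organs = NULL, background = NULL,
                        A0 = 7200, times = c(4, 24, 72, 192),
                        acq = AcquisitionMeta(60, 45),
                        sensitivity = 10,
                        nuclide = defaultLu177(),
                        noise = "poisson",
                        shifts = NULL, seed = 1L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(organs))
    organs <- defaultAbdominalOrgans(dim, spacing)
  if (is.null(shifts)) shifts <- matrix(integer(), 0L, 3L)
  new("PhantomSpec", dim = as.integer(dim), spacing = as.numeric(spacing),
      organs = organs, background = background, A0 = as.numeric(A0),
      times = as.numeric(times), acq = acq,
      sensitivity = as.numeric(sensitivity), nuclide = nuclide,
      noise = noise, shifts = shifts, seed = as.integer(seed))
}

#' Lu-177 with the constants shipped in the package configuration
#' @return a [Radionuclide].
#' @export
defaultLu177 <- function() {
  readNuclideConfig(system.file("extdata", "lu177.yaml", package = "mirdose"))
}

#' Default abdominal anatomy for the synthetic phantom
#'
#' Four non-overlapping ellipsoids: liver (~1005 cm^3), spleen (~126 cm^3)
#' and two kidneys (~118 cm^3 each), with fixed densities of 1.06 g/cm^3
#' (liver, spleen) and 1.05 g/cm^3 (kidneys). Kinetics are mono-exponential
#' fractions of the injected activity chosen to give TIACs of clinical order:
#' liver 3.0 h, spleen 1.5 h, each kidney 0.75 h.
#'
#' @param dim,spacing grid geometry the organs must fit inside.
#' @return list of [phantomOrgan()] definitions.
#' @export
defaultAbdominalOrgans <- function(dim = c(128L, 128L, 96L), spacing = rep(4.42, 3)) {
  ext <- dim * spacing
  ## centres as fractions of the field of view; scaled so small test grids
  ## still contain all four organs (axes capped at 30% of the extent)
  sc <- min(1, min(ext / c(566, 566, 424)))
  ax <- function(a) pmin(a * sc, 0.30 * ext)
  list(
    phantomOrgan(1L, "liver", center = ext * c(0.30, 0.55, 0.50),
                 semiAxes = ax(c(80, 60, 50)), density_gcc = 1.06,
                 fractions = 0.030, rates = 0.010),
    phantomOrgan(2L, "spleen", center = ext * c(0.74, 0.55, 0.50),
                 semiAxes = ax(c(40, 30, 25)), density_gcc = 1.06,
                 fractions = 0.012, rates = 0.008),
    phantomOrgan(3L, "kidney_left", center = ext * c(0.32, 0.22, 0.35),
                 semiAxes = ax(c(45, 25, 25)), density_gcc = 1.05,
                 fractions = 0.0075, rates = 0.010),
    phantomOrgan(4L, "kidney_right", center = ext * c(0.70, 0.22, 0.35),
                 semiAxes = ax(c(45, 25, 25)), density_gcc = 1.05,
                 fractions = 0.0075, rates = 0.010))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %s voxels @ %s mm, A0 = %g MBq, %d time point(s), noise = %s\n",
              paste(object@dim, collapse = " x "),
              paste(format(object@spacing, digits = 4), collapse = " x "),
              object@A0, length(object@times), object@noise))
  for (og in object@organs)
    cat(sprintf("  [%d] %-14s TIAC %.3g h\n", og$label, og$name,
                sum(og$kinetics$fractions / og$kinetics$rates)))
})

## voxel-centre world coordinates along one axis (0-based index * spacing)
.axisCoords <- function(n, sp) (seq_len(n) - 1) * sp

#' Build the phantom label and density maps
#'
#' Rasterises the organ ellipsoids on the voxel grid (voxel-centre
#' convention). Overlapping organ definitions are a specification error.
#'
#' @param spec a [PhantomSpec].
#' @return list with elements `labels` (a [LabelMap]) and `density` (an
#'   [ImageVolume] of kind `"density"`, background at 1.0 g/cm^3).
#' @export
buildPhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  d <- spec@dim
  lab <- array(0L, d)
  dens <- array(1.0, d)
  cx <- .axisCoords(d[1], spec@spacing[1])
  cy <- .axisCoords(d[2], spec@spacing[2])
  cz <- .axisCoords(d[3], spec@spacing[3])
  for (og in spec@organs) {
    u2 <- ((cx - og$center[1]) / og$semiAxes[1])^2
    v2 <- ((cy - og$center[2]) / og$semiAxes[2])^2
    w2 <- ((cz - og$center[3]) / og$semiAxes[3])^2
    inside <- outer(outer(u2, v2, "+"), w2, "+") <= 1
    if (any(lab[inside] != 0L))
      stop(sprintf("phantom organs overlap: '%s' intersects label %d",
                   og$name, lab[inside][lab[inside] != 0L][1]))
    if (!any(inside))
      warning(sprintf("organ '%s' contains no voxels on this grid", og$name))
    lab[inside] <- og$label
    dens[inside] <- og$density_gcc
  }
  cat_df <- data.frame(
    label = vapply(spec@organs, `[[`, 0L, "label"),
    organ = vapply(spec@organs, `[[`, "", "name"),
    density_gcc = vapply(spec@organs, `[[`, 0, "density_gcc"),
    stringsAsFactors = FALSE)
  list(labels = LabelMap(lab, spec@spacing, cat_df),
       density = ImageVolume(dens, spec@spacing, "density"))
}

## analytic organ activity (MBq) at time t for kinetics k = list(fractions, rates)
.kineticActivity <- function(k, t, A0)
  A0 * sum(k$fractions * exp(-k$rates * t))

## analytic TIA (MBq h) on [0, Inf)
.kineticTia <- function(k, A0) A0 * sum(k$fractions / k$rates)

#' Simulate the phantom's SPECT count time series
#'
#' Counts are generated directly in image space (no projection or
#' reconstruction model): for each voxel, expected counts are voxel activity
#' (organ activity spread uniformly over the organ's voxels) times the system
#' sensitivity (cps/MBq) times the total acquisition duration (s). In
#' `"poisson"` mode each voxel draws from a Poisson with that mean,
#' reproducibly from the spec's seed; in `"none"` mode the expectation is
#' returned exactly.
#'
#' @param spec a [PhantomSpec].
#' @return list with `volumes` (list of count [ImageVolume]s, one per time
#'   point), `labels`, `density`, and `truth` (a [GroundTruth]).
#' @export
simulateTimepoints <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  ph <- buildPhantom(spec)
  lab <- voxelData(ph$labels)
  dur <- totalDuration(spec@acq)
  if (spec@sensitivity <= 0 || dur <= 0)
    stop("sensitivity and acquisition duration must be positive")
  nvox <- tabulate(lab[lab > 0L], nbins = max(c(1L, lab)))
  bgMask <- lab == 0L
  nbg <- sum(bgMask)
  if (spec@noise == "poisson") set.seed(spec@seed)
  truth <- phantomGroundTruth(spec, ph$labels)
  volumes <- vector("list", length(spec@times))
  for (i in seq_along(spec@times)) {
    t <- spec@times[i]
    mean_counts <- array(0, spec@dim)
    for (og in spec@organs) {
      a <- .kineticActivity(og$kinetics, t, spec@A0)
      if (a < 0) stop(sprintf("organ '%s': negative activity at t = %g h",
                              og$name, t))
      vox <- nvox[og$label]
      if (vox > 0)
        mean_counts[lab == og$label] <-
          (a / vox) * spec@sensitivity * dur
    }
    if (!is.null(spec@background) && nbg > 0) {
      ab <- .kineticActivity(spec@background, t, spec@A0)
      if (ab < 0) stop(sprintf("background: negative activity at t = %g h", t))
      mean_counts[bgMask] <- (ab / nbg) * spec@sensitivity * dur
    }
    counts <- if (spec@noise == "poisson")
      array(stats::rpois(length(mean_counts), mean_counts), spec@dim)
    else mean_counts
    if (nrow(spec@shifts) > 0)
      counts <- shiftArray(counts, spec@shifts[i, ])
    volumes[[i]] <- ImageVolume(counts, spec@spacing, "counts", time = t)
  }
  list(volumes = volumes, labels = ph$labels, density = ph$density,
       truth = truth)
}

#' Analytic ground truth for a phantom specification
#'
#' Per organ: mass, activity at each acquisition time, time-integrated
#' activity (closed form, sum of `fraction/rate` terms times A0), TIAC, and
#' the mean absorbed dose under the local-energy-deposition assumption
#' (`TIA x 3.6e9 decays/(MBq h) x E_local / mass`). All three dose engines
#' share this value when the S-value table is the matched local-deposition
#' table and the kernel deposits all energy inside the organ.
#'
#' @param spec a [PhantomSpec].
#' @param labels optional pre-built [LabelMap] (rebuilt from the spec when
#'   omitted).
#' @return a [GroundTruth].
#' @export
phantomGroundTruth <- function(spec, labels = NULL) {
  if (is.null(labels)) labels <- buildPhantom(spec)$labels
  lab <- voxelData(labels)
  voxcc <- voxelVolumeCc(labels)
  organs <- spec@organs
  nvox <- vapply(organs, function(og) sum(lab == og$label), 0)
  mass <- nvox * voxcc * vapply(organs, `[[`, 0, "density_gcc")
  tia <- vapply(organs, function(og) .kineticTia(og$kinetics, spec@A0), 0)
  E <- spec@nuclide@localEnergyPerDecay
  dose <- tia * .DECAYS_PER_MBQH * E / (mass / 1000)
  act <- matrix(0, length(organs), length(spec@times),
                dimnames = list(vapply(organs, `[[`, "", "name"), NULL))
  for (i in seq_along(organs))
    act[i, ] <- vapply(spec@times, function(t)
      .kineticActivity(organs[[i]]$kinetics, t, spec@A0), 0)
  new("GroundTruth",
      organs = data.frame(
        organ = vapply(organs, `[[`, "", "name"),
        label = vapply(organs, `[[`, 0L, "label"),
        voxels = as.integer(nvox),
        mass_g = mass,
        tia_MBqh = tia,
        tiac_h = tia / spec@A0,
        mean_dose_Gy = dose,
        stringsAsFactors = FALSE),
      activities = act, times = spec@times, A0 = spec@A0)
}

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d organ(s), A0 = %g MBq, times %s h\n",
              nrow(object@organs), object@A0,
              paste(object@times, collapse = "/")))
  print(object@organs, row.names = FALSE, digits = 4)
})

#' Shift a 3D array by an integer voxel offset with zero fill
#'
#' @param a 3D array.
#' @param shift integer length-3 offset (positive moves content towards
#'   higher indices).
#' @return shifted array of the same dimensions.
#' @export
shiftArray <- function(a, shift) {
  shift <- as.integer(round(shift))
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 3L)
  for (k in 1:3) {
    s <- shift[k]
    if (abs(s) >= d[k]) return(out)
    if (s >= 0) { src[[k]] <- seq_len(d[k] - s); dst[[k]] <- src[[k]] + s }
    else        { src[[k]] <- seq(1 - s, d[k]);  dst[[k]] <- src[[k]] + s }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}
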