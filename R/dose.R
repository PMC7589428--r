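#' @include AllClasses.R AllGenerics.R units.R volumes.R quantify.R
NULL

#' @rdname reportTable
setMethod("reportTable", "DoseReport", function(x) x@table)

setMethod("show", "DoseReport", function(object) {
  cat(sprintf("DoseReport [engine: %s], %d organ(s)%s\n", object@engine,
              nrow(object@table),
              if (is.null(object@doseMap)) "" else ", with dose map"))
  print(object@table, row.names = FALSE, digits = 4)
})

#' Construct an S-value table
#'
#' @param nuclide radionuclide name.
#' @param entries data.frame with `source`, `target`, `S_Gy_per_MBqh`.
#' @param refMass named numeric vector of reference organ masses (g).
#' @param provenance free-text provenance note.
#' @return an [SValueTable].
#' @export
SValueTable <- function(nuclide, entries, refMass, provenance = "") {
  new("SValueTable", nuclide = nuclide, entries = entries,
      refMass = refMass, provenance = provenance)
}

#' Read an S-value table from CSV
#'
#' Schema: columns `source`, `target`, `S_Gy_per_MBqh`, `ref_mass_g` (the
#' reference mass of the *target* organ, repeated across its rows).
#'
#' @param path CSV path.
#' @param nuclide radionuclide name the table applies to.
#' @return an [SValueTable].
#' @export
readSValueTable <- function(path, nuclide = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "S_Gy_per_MBqh", "ref_mass_g")
  if (!all(need %in% names(df)))
    stop("S-value CSV needs columns: ", paste(need, collapse = ", "))
  refMass <- tapply(df$ref_mass_g, df$target, `[`, 1)
  SValueTable(nuclide, df[c("source", "target", "S_Gy_per_MBqh")],
              stats::setNames(as.numeric(refMass), names(refMass)),
              provenance = path)
}

#' S-value table matched to a phantom's local-deposition assumption
#'
#' A self-dose-only table with `S(organ <- organ) = 3.6e9 x E_local / m_ref`
#' (Gy per MBq h) and zero cross terms, using the phantom organs' own masses
#' as reference masses. With patient masses equal to the reference masses the
#' S-value engine then reproduces the local-energy-deposition dose exactly —
#' the synthetic stand-in used because no published S-value compilation is
#' bundled.
#'
#' @param truth a [GroundTruth].
#' @param nuclide the [Radionuclide] (for `localEnergyPerDecay`).
#' @return an [SValueTable].
#' @export
matchedSValueTable <- function(truth, nuclide) {
  og <- truth@organs
  Sself <- .DECAYS_PER_MBQH * nuclide@localEnergyPerDecay / (og$mass_g / 1000)
  pairs <- expand.grid(source = og$organ, target = og$organ,
                       stringsAsFactors = FALSE)
  pairs$S_Gy_per_MBqh <- ifelse(pairs$source == pairs$target,
                                Sself[match(pairs$target, og$organ)], 0)
  SValueTable(nuclide@name, pairs,
              stats::setNames(og$mass_g, og$organ),
              provenance = "synthetic local-deposition table")
}

#' Organ mean dose from S values with patient mass adjustment
#'
#' Implements the organ-level MIRD sum: the mean dose to a target region is
#' `D(target) = sum over sources of A0 x TIAC(source) x S(target <- source)`,
#' with the self-dose term rescaled by `m_ref(target) / m_patient(target)`
#' (S values scale inversely with target mass for non-penetrating
#' emissions). Cross-dose terms are left unscaled by default; set
#' `crossMassScaling = "inverse"` to rescale them the same way.
#'
#' @param tiacs named numeric vector of TIACs in hours (names = source
#'   organs).
#' @param A0 injected activity MBq.
#' @param table an [SValueTable].
#' @param patientMasses named numeric vector of patient organ masses (g);
#'   organs absent from it fall back to the reference mass.
#' @param crossMassScaling `"none"` (default) or `"inverse"`.
#' @return a [DoseReport] (engine `"svalue"`).
#' @export
svalueDose <- function(tiacs, A0, table, patientMasses = numeric(),
                       crossMassScaling = c("none", "inverse")) {
  stopifnot(is(table, "SValueTable"), A0 > 0, all(tiacs >= 0))
  crossMassScaling <- match.arg(crossMassScaling)
  sources <- names(tiacs)
  if (is.null(sources)) stop("tiacs must be a named vector (source organs)")
  targets <- sources
  ent <- table@entries
  dose <- stats::setNames(numeric(length(targets)), targets)
  mass <- stats::setNames(numeric(length(targets)), targets)
  for (tgt in targets) {
    mref <- table@refMass[[tgt]]
    if (is.null(mref) || is.na(mref))
      stop("no reference mass for target organ '", tgt, "'")
    mpat <- if (tgt %in% names(patientMasses)) patientMasses[[tgt]] else mref
    if (mpat <= 0) stop("non-positive patient mass for '", tgt, "'")
    mass[tgt] <- mpat
    d <- 0
    for (src in sources) {
      if (tiacs[[src]] == 0) next
      row <- which(ent$source == src & ent$target == tgt)
      if (!length(row))
        stop(sprintf("S-value table has no entry for target '%s' <- source '%s'",
                     tgt, src))
      S <- ent$S_Gy_per_MBqh[row[1]]
      adj <- if (src == tgt || crossMassScaling == "inverse") mref / mpat else 1
      d <- d + A0 * tiacs[[src]] * S * adj
    }
    dose[tgt] <- d
  }
  new("DoseReport",
      table = data.frame(organ = targets, mass_g = unname(mass),
                         tiac_h = unname(tiacs[targets]),
                         mean_dose_Gy = unname(dose),
                         engine = "svalue", stringsAsFactors = FALSE),
      engine = "svalue")
}

## Gy per (MBq h per voxel) for local deposition in a medium of unit density:
## decays * E_local / voxel water mass. Shared by the LED engine and the
## DVK kernel normalisation so the two agree bit-for-bit in water.
.ledFactorWater <- function(E, voxcc) .DECAYS_PER_MBQH * E / (voxcc * 1e-3)

#' Voxel dose by local energy deposition with density correction
#'
#' Every decay's locally deposited energy is absorbed in the voxel where it
#' occurs: `dose = TIA x 3.6e9 decays/(MBq h) x E_local / voxel mass`, with
#' the voxel mass taken from the density map (`density x voxel volume`).
#'
#' @param tiaMap [ImageVolume] of kind `"tia"` (MBq h per voxel).
#' @param density [ImageVolume] of kind `"density"` (g/cm^3) on the same
#'   grid; must be positive wherever TIA is positive.
#' @param nuclide [Radionuclide] supplying `localEnergyPerDecay`.
#' @return dose [ImageVolume] (Gy).
#' @export
ledDose <- function(tiaMap, density, nuclide) {
  stopifnot(is(tiaMap, "ImageVolume"), is(density, "ImageVolume"),
            is(nuclide, "Radionuclide"))
  if (tiaMap@kind != "tia") stop("tiaMap must have kind 'tia'")
  if (density@kind != "density") stop("density must have kind 'density'")
  .stopIfGeometryMismatch(tiaMap, density, "TIA and density maps")
  tiaArr <- voxelData(tiaMap)
  rho <- voxelData(density)
  bad <- which(rho <= 0 & tiaArr > 0)
  if (length(bad))
    stop("zero/negative density with non-zero TIA at voxel index ", bad[1])
  f <- .ledFactorWater(nuclide@localEnergyPerDecay, voxelVolumeCc(tiaMap))
  dose <- (tiaArr * f) / rho
  dose[rho <= 0] <- 0
  ImageVolume(dose, voxelSpacing(tiaMap), "dose")
}

#' Build a water dose-voxel kernel
#'
#' Precomputes the dose (Gy per MBq h) around a unit source voxel in water on
#' the same voxel spacing as the TIA maps it will be convolved with. The
#' energy deposited per voxel is `E_local` times a deposition weight. With
#' the default isotropic exponential profile (`exp(-r / scale)`) the raw
#' per-voxel weights are integrated by midpoint subsampling and compared
#' against the analytic whole-space integral (`8 pi scale^3`): if the
#' truncated grid captures less than `1 - truncationTol` of the energy the
#' radius is too small and an error is raised. The accepted weights are then
#' renormalised to sum to one (the usual treatment of truncated dose-voxel
#' kernels), so convolution conserves the full `E_local` exactly; the raw
#' coverage is kept in the `energyFraction` slot. `radius = 0` yields the
#' pure local-deposition kernel with all energy in the centre voxel.
#'
#' The default e-folding length of 0.6 mm puts the mean deposition radius
#' of the profile (3 x scale = 1.8 mm) at about the maximum beta range of
#' Lu-177 in water, well below a 4.42 mm voxel — the regime in which
#' treating the emission as near-locally deposited is sensible at all.
#'
#' @param nuclide [Radionuclide].
#' @param spacing voxel spacing mm (scalar recycled) — must match the TIA
#'   map's.
#' @param radius kernel half-width in voxels (kernel is `(2 radius + 1)^3`).
#' @param profile `"exponential"`, or a function of radial distance r (mm)
#'   returning a non-negative deposition density, normalised over the
#'   truncated grid.
#' @param scale_mm e-folding length of the exponential profile, mm.
#' @param truncationTol error if the raw retained energy fraction falls
#'   below `1 - truncationTol` (default 0.5%).
#' @param subsamples per-axis subdivisions used to integrate the profile
#'   over each voxel.
#' @return a [DoseKernel].
#' @export
buildWaterKernel <- function(nuclide, spacing = 4.42, radius = 5L,
                             profile = "exponential", scale_mm = 0.6,
                             truncationTol = 0.005, subsamples = 8L) {
  stopifnot(is(nuclide, "Radionuclide"), radius >= 0)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be positive")
  r <- as.integer(radius)
  n <- 2L * r + 1L
  voxcc <- prod(spacing) / 1e3
  f0 <- .ledFactorWater(nuclide@localEnergyPerDecay, voxcc)
  if (r == 0L) {
    return(new("DoseKernel", values = array(f0, c(1L, 1L, 1L)),
               spacing = spacing, medium = "water", energyFraction = 1))
  }
  ## integrate the profile over each voxel by midpoint subsampling
  sub <- as.integer(subsamples)
  off <- (seq_len(sub) - 0.5) / sub - 0.5   # fractions of a voxel
  w <- array(0, c(n, n, n))
  centers <- (-r):r
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    xs <- (centers[i] + off) * spacing[1]
    ys <- (centers[j] + off) * spacing[2]
    zs <- (centers[k] + off) * spacing[3]
    rr <- sqrt(outer(outer(xs^2, ys^2, "+"), zs^2, "+"))
    p <- if (is.function(profile)) profile(rr) else exp(-rr / scale_mm)
    w[i, j, k] <- mean(p) * prod(spacing)   # integral over the voxel, mm^3
  }
  if (is.function(profile)) {
    frac <- 1
  } else {
    total <- 8 * pi * scale_mm^3            # analytic whole-space integral
    frac <- sum(w) / total
    if (frac > 1 + 1e-6)
      stop("profile integrates to more than the available energy")
    if (frac < 1 - truncationTol)
      stop(sprintf(
        "kernel radius %d retains only %.4f of the energy (tolerance %.4f): increase radius",
        r, frac, 1 - truncationTol))
  }
  w <- w / sum(w)                           # energy fractions per voxel
  new("DoseKernel", values = w * f0, spacing = spacing, medium = "water",
      energyFraction = frac)
}

setMethod("show", "DoseKernel", function(object) {
  d <- dim(object@values)
  cat(sprintf("DoseKernel (%s): %d x %d x %d @ %s mm, energy fraction %.5f\n",
              object@medium, d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x "),
              object@energyFraction))
})

## zero-padded linear 3D convolution via FFT (no wrap-around)
.convolve3d <- function(x, k) {
  dx <- dim(x); dk <- dim(k)
  dp <- dx + dk - 1L
  px <- array(0, dp); px[seq_len(dx[1]), seq_len(dx[2]), seq_len(dx[3])] <- x
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) / prod(dp)
  ctr <- (dk - 1L) / 2L
  full[ctr[1] + seq_len(dx[1]), ctr[2] + seq_len(dx[2]), ctr[3] + seq_len(dx[3])]
}

#' Voxel dose by dose-voxel-kernel convolution
#'
#' Convolves a TIA map with a precomputed water kernel (zero-padded linear
#' convolution, no periodic wrap-around). The kernel spacing must match the
#' TIA map's exactly; no resampling is performed. An optional first-order
#' density correction divides each voxel's dose by its density relative to
#' water. With a radius-0 kernel the result equals [ledDose()] in water
#' exactly.
#'
#' @param tiaMap [ImageVolume] of kind `"tia"`.
#' @param kernel a [DoseKernel].
#' @param density optional [ImageVolume] of kind `"density"` for the
#'   voxel-wise correction; `NULL` for homogeneous water.
#' @return dose [ImageVolume] (Gy).
#' @export
dvkDose <- function(tiaMap, kernel, density = NULL) {
  stopifnot(is(tiaMap, "ImageVolume"), is(kernel, "DoseKernel"))
  if (tiaMap@kind != "tia") stop("tiaMap must have kind 'tia'")
  if (any(abs(voxelSpacing(tiaMap) - kernel@spacing) > 1e-9))
    stop("kernel and TIA map voxel spacing differ: no resampling is implied")
  tiaArr <- voxelData(tiaMap)
  kv <- kernel@values
  dose <- if (all(dim(kv) == 1L)) tiaArr * kv[1L]
          else .convolve3d(tiaArr, kv)
  if (!is.null(density)) {
    if (density@kind != "density") stop("density must have kind 'density'")
    .stopIfGeometryMismatch(tiaMap, density, "TIA and density maps")
    rho <- voxelData(density)
    if (any(rho <= 0 & dose > 0))
      stop("zero/negative density where dose is non-zero")
    dose <- dose / rho
    dose[rho <= 0] <- 0
  }
  ImageVolume(dose, voxelSpacing(tiaMap), "dose")
}

#' Cumulative dose-volume histogram and mean dose for one organ
#'
#' @param doseMap [ImageVolume] of kind `"dose"`.
#' @param labels [LabelMap] on the same grid.
#' @param organ label or organ name.
#' @param binWidth DVH bin width in Gy (default 0.01).
#' @return list with `dose_Gy` (bin edges starting at 0), `fraction`
#'   (fraction of VOI volume receiving at least that dose; starts at 1,
#'   monotone non-increasing) and `mean_Gy` (voxel mean over the VOI,
#'   computed from the map, not the histogram).
#' @export
dvh <- function(doseMap, labels, organ, binWidth = 0.01) {
  stopifnot(is(doseMap, "ImageVolume"), is(labels, "LabelMap"), binWidth > 0)
  if (doseMap@kind != "dose") stop("doseMap must have kind 'dose'")
  .stopIfGeometryMismatch(doseMap, labels, "dose map and labels")
  cat_df <- organCatalogue(labels)
  lb <- if (is.character(organ)) cat_df$label[match(organ, cat_df$organ)]
        else as.integer(organ)
  if (is.na(lb) || !lb %in% cat_df$label) stop("unknown organ: ", organ)
  d <- voxelData(doseMap)[voxelData(labels) == lb]
  if (!length(d)) stop("empty VOI for organ: ", organ)
  edges <- seq(0, max(d) + binWidth, by = binWidth)
  sorted <- sort(d)
  ## fraction of voxels with dose >= edge
  frac <- 1 - (findInterval(edges, sorted, left.open = TRUE) / length(d))
  list(dose_Gy = edges, fraction = frac, mean_Gy = mean(d))
}

#' Build a TIA ImageVolume from organ-level fit results
#'
#' Spreads each organ's fitted TIA uniformly over its VOI voxels (the
#' organ-level counterpart of voxel-wise fitting); background voxels get 0.
#'
#' @param fits list of [FitResult]s named by organ.
#' @param labels a [LabelMap] cataloguing those organs.
#' @return [ImageVolume] of kind `"tia"` (MBq h per voxel).
#' @export
tiaMapFromFits <- function(fits, labels) {
  stopifnot(is(labels, "LabelMap"))
  lab <- voxelData(labels)
  cat_df <- organCatalogue(labels)
  arr <- array(0, dim(lab))
  for (f in fits) {
    lb <- cat_df$label[match(f@organ, cat_df$organ)]
    if (is.na(lb)) stop("organ '", f@organ, "' not in label catalogue")
    m <- lab == lb
    nv <- sum(m)
    if (nv > 0) arr[m] <- f@tia / nv
  }
  ImageVolume(arr, voxelSpacing(labels), "tia")
}

#' Voxel-wise trapezoid-with-tail TIA map
#'
#' Applies [integrateTrapezoidTail()] independently to every voxel of a
#' time series of activity maps (the voxel-level integration mode): head
#' rule on `[0, t1]`, trapezoids between time points, mono-exponential tail
#' after the last.
#'
#' @param activityMaps list of [ImageVolume]s of kind `"activity"`, one per
#'   time point, with `time` set and strictly increasing.
#' @param headRule `"zero_line"` or `"constant"`.
#' @param tailRate tail decay rate 1/h.
#' @return [ImageVolume] of kind `"tia"`.
#' @export
tiaMapVoxelTrapezoid <- function(activityMaps,
                                 headRule = c("zero_line", "constant"),
                                 tailRate = log(2) / 159.53) {
  headRule <- match.arg(headRule)
  stopifnot(length(activityMaps) >= 1L, tailRate > 0)
  times <- vapply(activityMaps, function(v) v@time, 0)
  if (any(is.na(times)) || any(diff(times) <= 0))
    stop("activity maps need strictly increasing time stamps")
  for (v in activityMaps) {
    if (v@kind != "activity") stop("expected ImageVolumes of kind 'activity'")
    .stopIfGeometryMismatch(v, activityMaps[[1]], "activity maps")
  }
  a1 <- voxelData(activityMaps[[1]])
  tiaArr <- if (headRule == "zero_line") 0.5 * times[1] * a1 else times[1] * a1
  if (length(times) > 1L) {
    for (i in seq_len(length(times) - 1L)) {
      tiaArr <- tiaArr + diff(times)[i] *
        (voxelData(activityMaps[[i]]) + voxelData(activityMaps[[i + 1L]])) / 2
    }
  }
  tiaArr <- tiaArr + voxelData(activityMaps[[length(times)]]) / tailRate
  ImageVolume(tiaArr, voxelSpacing(activityMaps[[1]]), "tia")
}

#' Convert a count volume to an activity map
#'
#' @param counts [ImageVolume] of kind `"counts"`.
#' @param cf [CalibrationFactor].
#' @param acq [AcquisitionMeta] of this acquisition (defaults to the
#'   factor's context).
#' @return [ImageVolume] of kind `"activity"` (MBq per voxel).
#' @export
countsToActivity <- function(counts, cf, acq = NULL) {
  stopifnot(is(counts, "ImageVolume"))
  if (counts@kind != "counts") stop("expected an ImageVolume of kind 'counts'")
  if (is.null(acq)) acq <- cf@context
  if (is.null(acq)) stop("no acquisition metadata")
  ImageVolume(voxelData(counts) * mbqPerCount(cf, acq),
              voxelSpacing(counts), "activity", time = counts@time)
}
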