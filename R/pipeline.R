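#' @include AllClasses.R AllGenerics.R units.R volumes.R phantom.R quantify.R kinetics.R dose.R
NULL

#' Construct a study configuration
#'
#' A `StudyConfig` fully determines a dosimetry run: the input data (a
#' [PhantomSpec] for synthetic studies, or NIfTI volume paths plus a label
#' map for file input), the calibration factor, radionuclide, injected
#' activity, the fit-model choice, the dose engine(s) and the seed. A run is
#' reproducible from the config alone.
#'
#' @param phantom [PhantomSpec] or `NULL`.
#' @param volumePaths,labelPath,catalogue,times file-study inputs: NIfTI
#'   count volumes (one per time point), integer label volume, organ
#'   catalogue data.frame, acquisition times (h).
#' @param calibration [CalibrationFactor].
#' @param nuclide [Radionuclide].
#' @param A0 injected activity MBq.
#' @param acq patient [AcquisitionMeta].
#' @param fitModel `"auto"`, a fit family, or a named list per organ.
#' @param headRule trapezoid head rule.
#' @param engine character vector of engines: `"svalue"`, `"led"`, `"dvk"`.
#' @param svalueTable [SValueTable] (needed for `"svalue"`); `NULL` lets a
#'   phantom study build the matched local-deposition table.
#' @param kernelRadius DVK kernel radius in voxels (0 = local deposition in
#'   water).
#' @param registration run translation registration of later time points
#'   onto the first.
#' @param outputDir directory for checkpoints and report files (`NA`
#'   disables writing).
#' @param seed integer seed (overrides the phantom's).
#' @return a [StudyConfig].
#' @export
StudyConfig <- function(phantom = NULL, volumePaths = character(),
                        labelPath = NA_character_,
                        catalogue = data.frame(), times = numeric(),
                        calibration = NULL, nuclide = defaultLu177(),
                        A0 = 7200, acq = AcquisitionMeta(60, 45),
                        fitModel = "auto", headRule = "zero_line",
                        engine = "led", svalueTable = NULL,
                        kernelRadius = 0, registration = FALSE,
                        outputDir = NA_character_, seed = 1L) {
  if (is.null(calibration))
    calibration <- CalibrationFactor(10, "cps_per_MBq")
  if (!is.null(phantom) && !is.na(seed)) phantom@seed <- as.integer(seed)
  new("StudyConfig", phantom = phantom, volumePaths = volumePaths,
      labelPath = labelPath, catalogue = catalogue, times = as.numeric(times),
      calibration = calibration, nuclide = nuclide, A0 = as.numeric(A0),
      acq = acq, fitModel = fitModel, headRule = headRule, engine = engine,
      svalueTable = svalueTable, kernelRadius = as.numeric(kernelRadius),
      registration = registration, outputDir = outputDir,
      seed = as.integer(seed))
}

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf("StudyConfig: %s study, A0 = %g MBq, fit = %s, engine(s) = %s, seed = %d\n",
              if (is.null(object@phantom)) "file" else "phantom",
              object@A0,
              if (is.character(object@fitModel)) object@fitModel else "per-organ",
              paste(object@engine, collapse = "+"), object@seed))
})

#' Read a study configuration from YAML
#'
#' Schema (keys in parentheses optional): `A0_MBq`, `acquisition`
#' (`n_projections`, `seconds_per_projection`), `calibration` (`magnitude`,
#' `unit_kind`, (`context_n_projections`, `context_seconds_per_projection`)),
#' `nuclide` (`name`, `half_life_h`, (`local_energy_per_decay_J`)),
#' (`phantom`: `dim`, `spacing_mm`, `noise`, (`times_h`)), (`volumes`,
#' `labels`, `catalogue_csv`, `times_h` for file studies), (`fit_model`),
#' (`head_rule`), (`engine`), (`kernel_radius`), (`registration`),
#' (`output_dir`), (`seed`).
#'
#' @param path YAML file.
#' @return a [StudyConfig].
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  acq <- AcquisitionMeta(y$acquisition$n_projections,
                         y$acquisition$seconds_per_projection)
  ctx <- if (!is.null(y$calibration$context_n_projections))
    AcquisitionMeta(y$calibration$context_n_projections,
                    y$calibration$context_seconds_per_projection)
  else acq
  cal <- CalibrationFactor(y$calibration$magnitude, y$calibration$unit_kind,
                           ctx)
  nuc <- Radionuclide(y$nuclide$name, y$nuclide$half_life_h,
                      if (is.null(y$nuclide$local_energy_per_decay_J)) 0
                      else y$nuclide$local_energy_per_decay_J)
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  phantom <- NULL
  if (!is.null(y$phantom)) {
    phantom <- PhantomSpec(
      dim = as.integer(y$phantom$dim),
      spacing = as.numeric(y$phantom$spacing_mm),
      A0 = y$A0_MBq,
      times = if (!is.null(y$phantom$times_h)) y$phantom$times_h
              else c(4, 24, 72, 192),
      acq = acq, sensitivity = sensitivityCpsPerMBq(cal),
      nuclide = nuc,
      noise = if (is.null(y$phantom$noise)) "poisson" else y$phantom$noise,
      seed = seed)
  }
  StudyConfig(
    phantom = phantom,
    volumePaths = if (is.null(y$volumes)) character() else unlist(y$volumes),
    labelPath = if (is.null(y$labels)) NA_character_ else y$labels,
    catalogue = if (is.null(y$catalogue_csv)) data.frame()
                else utils::read.csv(y$catalogue_csv, stringsAsFactors = FALSE),
    times = if (is.null(y$times_h)) numeric() else as.numeric(y$times_h),
    calibration = cal, nuclide = nuc, A0 = y$A0_MBq, acq = acq,
    fitModel = if (is.null(y$fit_model)) "auto" else y$fit_model,
    headRule = if (is.null(y$head_rule)) "zero_line" else y$head_rule,
    engine = if (is.null(y$engine)) "led" else unlist(y$engine),
    kernelRadius = if (is.null(y$kernel_radius)) 0 else y$kernel_radius,
    registration = isTRUE(y$registration),
    outputDir = if (is.null(y$output_dir)) NA_character_ else y$output_dir,
    seed = seed)
}

.loadStudyInputs <- function(config) {
  if (!is.null(config@phantom)) {
    sim <- simulateTimepoints(config@phantom)
    list(volumes = sim$volumes, labels = sim$labels, density = sim$density,
         truth = sim$truth)
  } else {
    if (!length(config@volumePaths) || is.na(config@labelPath))
      stop("file study needs volumePaths and labelPath")
    if (length(config@times) != length(config@volumePaths))
      stop("need one acquisition time per volume")
    labels <- readLabelMap(config@labelPath, config@catalogue)
    volumes <- Map(function(p, t) readVolume(p, "counts", t),
                   config@volumePaths, config@times)
    dens <- array(1.0, dim(voxelData(labels)))
    cat_df <- organCatalogue(labels)
    for (i in seq_len(nrow(cat_df)))
      dens[voxelData(labels) == cat_df$label[i]] <- cat_df$density_gcc[i]
    list(volumes = unname(volumes), labels = labels,
         density = ImageVolume(dens, voxelSpacing(labels), "density"),
         truth = NULL)
  }
}

#' Pre-flight sanity checks for a dosimetry study
#'
#' Verifies, before any computation: shared grid geometry across all time
#' points and the label map, strictly increasing acquisition times with no
#' duplicates, positive acquisition durations, calibration-factor unit and
#' context consistency, and label-catalogue completeness. The pipeline
#' refuses to run when any check fails.
#'
#' @param config a [StudyConfig].
#' @param inputs optional pre-loaded inputs (as produced internally); loaded
#'   from the config when omitted.
#' @return list with `pass` (logical) and `findings` (data.frame with
#'   `check`, `status`, `detail`).
#' @export
sanityCheck <- function(config, inputs = NULL) {
  findings <- data.frame(check = character(), status = character(),
                         detail = character(), stringsAsFactors = FALSE)
  add <- function(check, ok, detail = "") {
    findings[nrow(findings) + 1L, ] <<- list(check,
                                             if (ok) "pass" else "fail",
                                             detail)
  }
  if (is.null(inputs))
    inputs <- tryCatch(.loadStudyInputs(config), error = function(e) e)
  if (inherits(inputs, "error")) {
    add("load_inputs", FALSE, conditionMessage(inputs))
    return(list(pass = FALSE, findings = findings))
  }
  vols <- inputs$volumes
  times <- vapply(vols, function(v) v@time, 0)
  geomOk <- TRUE
  for (i in seq_along(vols)) {
    if (!.sameGeometry(vols[[i]], inputs$labels)) {
      geomOk <- FALSE
      add("geometry", FALSE,
          sprintf("time point %d (t = %g h) does not match the label-map grid",
                  i, times[i]))
    }
  }
  if (geomOk) add("geometry", TRUE)
  dup <- anyDuplicated(times) > 0L
  add("acquisition_times", !dup && all(diff(sort(times)) > 0) && all(times > 0),
      if (dup) sprintf("duplicate time %g h", times[anyDuplicated(times)])
      else "")
  add("acquisition_duration", totalDuration(config@acq) > 0)
  calOk <- tryCatch({
    sensitivityCpsPerMBq(config@calibration) > 0
  }, error = function(e) FALSE)
  add("calibration", calOk,
      if (!calOk) "calibration factor lacks a usable duration context" else "")
  lab <- voxelData(inputs$labels)
  present <- setdiff(unique(as.integer(lab)), 0L)
  missing <- setdiff(present, organCatalogue(inputs$labels)$label)
  add("label_catalogue", length(missing) == 0L,
      if (length(missing)) paste("uncatalogued labels:",
                                 paste(missing, collapse = ", ")) else "")
  if ("svalue" %in% config@engine && is.null(config@svalueTable) &&
      is.null(config@phantom))
    add("svalue_table", FALSE, "svalue engine selected but no table given")
  list(pass = all(findings$status == "pass"), findings = findings)
}

.writeCheckpoint <- function(dir, stage, payload) {
  if (is.na(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0("checkpoint_", stage, ".json"))
  ## digits = I(17): lossless round trip for doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a pipeline checkpoint
#'
#' @param dir the study's output directory.
#' @param stage one of `"quantified"`, `"fitted"`, `"dosed"`.
#' @return the deserialised stage payload (lists/data.frames).
#' @export
loadCheckpoint <- function(dir, stage) {
  path <- file.path(dir, paste0("checkpoint_", stage, ".json"))
  if (!file.exists(path)) stop("no checkpoint for stage '", stage, "'")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full dosimetry pipeline for one study
#'
#' Executes quantification (per-organ activity at each time point), kinetics
#' (time-activity-curve fitting to TIA/TIAC), and absorbed dose for every
#' configured engine, writing per-stage checkpoints and a per-organ report
#' table (`organ`, `mass_g`, `tiac_h`, `mean_dose_Gy`, `engine`) when an
#' output directory is set. Deterministic given the config (which carries
#' the seed).
#'
#' @param config a [StudyConfig].
#' @param resumeFrom optional stage to resume after (`"quantified"` or
#'   `"fitted"`): the stage's checkpoint is loaded from `outputDir` instead
#'   of being recomputed.
#' @return list with `reports` (named list of [DoseReport], one per engine),
#'   `fits`, `samples`, `tacs`, `truth` (phantom studies only) and
#'   `sanity`.
#' @export
runPipeline <- function(config, resumeFrom = NULL) {
  stopifnot(is(config, "StudyConfig"))
  inputs <- .loadStudyInputs(config)
  sanity <- sanityCheck(config, inputs)
  if (!sanity$pass) {
    print(sanity$findings)
    stop("sanity checks failed; pipeline refused to run")
  }
  outdir <- config@outputDir

  ## stage: quantify -------------------------------------------------------
  if (identical(resumeFrom, "quantified") || identical(resumeFrom, "fitted")) {
    samples <- as.data.frame(loadCheckpoint(outdir, "quantified"))
  } else {
    vols <- inputs$volumes
    if (config@registration && length(vols) > 1L) {
      for (i in seq_along(vols)[-1]) {
        sh <- registerTranslation(vols[[i]], vols[[1]])
        vols[[i]] <- applyShift(vols[[i]], sh)
      }
      inputs$volumes <- vols
    }
    samples <- do.call(rbind, lapply(vols, function(v)
      voiActivity(v, inputs$labels, config@calibration, config@acq)))
    .writeCheckpoint(outdir, "quantified", samples)
  }

  ## stage: kinetics -------------------------------------------------------
  lambdaPhys <- decayConstant(config@nuclide)
  if (identical(resumeFrom, "fitted")) {
    fitted <- loadCheckpoint(outdir, "fitted")
    tiacs <- stats::setNames(fitted$tiac_h, fitted$organ)
    tias <- stats::setNames(fitted$tia_MBqh, fitted$organ)
    tacs <- buildTac(samples, config@A0)
    fits <- NULL
  } else {
    tacs <- buildTac(samples, config@A0)
    fits <- lapply(tacs, function(tc) {
      model <- if (is.list(config@fitModel))
        config@fitModel[[tc@organ]] %||% "auto" else config@fitModel
      switch(model,
        auto = autoSelect(tc, headRule = config@headRule,
                          tailRate = lambdaPhys),
        monoexp = fitMonoexp(tc),
        biexp = fitBiexp(tc),
        powerexp = fitPowerexp(tc),
        trapezoid_tail = integrateTrapezoidTail(tc, config@headRule,
                                                lambdaPhys),
        stop("unknown fit model: ", model))
    })
    .writeCheckpoint(outdir, "fitted", fitSummary(fits))
    tiacs <- vapply(fits, tiac, 0)
    tias <- vapply(fits, tia, 0)
  }

  ## stage: dose -----------------------------------------------------------
  labels <- inputs$labels
  cat_df <- organCatalogue(labels)
  masses <- stats::setNames(
    vapply(cat_df$label, function(l) organMass(labels, l), 0), cat_df$organ)
  reports <- list()
  for (eng in config@engine) {
    if (eng == "svalue") {
      tbl <- config@svalueTable
      if (is.null(tbl)) {
        if (is.null(inputs$truth))
          stop("svalue engine needs an SValueTable for file studies")
        tbl <- matchedSValueTable(inputs$truth, config@nuclide)
      }
      reports[[eng]] <- svalueDose(tiacs[cat_df$organ], config@A0, tbl,
                                   patientMasses = masses)
    } else {
      tiaMap <- if (!is.null(fits)) tiaMapFromFits(fits, labels) else {
        arr <- array(0, dim(voxelData(labels)))
        for (og in names(tias)) {
          lb <- cat_df$label[match(og, cat_df$organ)]
          m <- voxelData(labels) == lb
          if (sum(m)) arr[m] <- tias[[og]] / sum(m)
        }
        ImageVolume(arr, voxelSpacing(labels), "tia")
      }
      doseMap <- if (eng == "led") {
        ledDose(tiaMap, inputs$density, config@nuclide)
      } else {
        kern <- buildWaterKernel(config@nuclide,
                                 spacing = voxelSpacing(labels),
                                 radius = config@kernelRadius)
        dvkDose(tiaMap, kern, density = inputs$density)
      }
      rows <- lapply(cat_df$organ, function(og) {
        h <- dvh(doseMap, labels, og)
        data.frame(organ = og, mass_g = masses[[og]], tiac_h = tiacs[[og]],
                   mean_dose_Gy = h$mean_Gy, engine = eng,
                   stringsAsFactors = FALSE)
      })
      dvhs <- lapply(stats::setNames(cat_df$organ, cat_df$organ),
                     function(og) dvh(doseMap, labels, og))
      reports[[eng]] <- new("DoseReport", table = do.call(rbind, rows),
                            engine = eng, doseMap = doseMap, dvh = dvhs)
    }
    if (!is.na(outdir))
      utils::write.csv(reportTable(reports[[eng]]),
                       file.path(outdir, paste0("report_", eng, ".csv")),
                       row.names = FALSE)
  }
  .writeCheckpoint(outdir, "dosed",
                   do.call(rbind, lapply(reports, reportTable)))
  list(reports = reports, fits = fits, samples = samples, tacs = tacs,
       truth = inputs$truth, sanity = sanity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dispersion statistics across dose reports
#'
#' For each organ present in all reports: mean, range, sample standard
#' deviation (n-1) and relative standard deviation (%) of the organ mass,
#' TIAC and mean dose across the reports — the cross-platform comparison
#' statistics applied to this package's engine/model variants.
#'
#' @param reports list of at least two [DoseReport]s over the same organs.
#' @return data.frame with one row per (organ, quantity).
#' @export
compareRuns <- function(reports) {
  if (length(reports) < 2L)
    stop("compareRuns needs at least two reports")
  tabs <- lapply(reports, reportTable)
  organs <- sort(unique(tabs[[1]]$organ))
  for (i in seq_along(tabs)) {
    oi <- sort(unique(tabs[[i]]$organ))
    if (!identical(oi, organs))
      stop("organ sets differ between reports: {",
           paste(organs, collapse = ","), "} vs {",
           paste(oi, collapse = ","), "}")
  }
  quantities <- c(mass_g = "mass_g", tiac_h = "tiac_h",
                  mean_dose_Gy = "mean_dose_Gy")
  rows <- list()
  for (og in organs) for (qn in names(quantities)) {
    vals <- vapply(tabs, function(tb) tb[[qn]][match(og, tb$organ)], 0)
    m <- mean(vals); s <- stats::sd(vals)
    rows[[length(rows) + 1L]] <- data.frame(
      organ = og, quantity = qn, n = length(vals), mean = m,
      min = min(vals), max = max(vals), sd = s,
      rsd_pct = if (m != 0) 100 * s / abs(m) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
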