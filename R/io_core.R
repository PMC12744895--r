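#' Read a 4D dynamic series from NIfTI with a timing sidecar
#'
#' The NIfTI time-step header cannot express the variable inter-frame spacing
#' of 3-9 s ultrafast protocols, so frame timing travels in a JSON sidecar
#' (fields `frame_times`, `unit` ("s" or "min"), `n_precontrast`) or is given
#' explicitly. Times are converted to minutes on read; internally the package
#' uses minutes everywhere (alpha, beta, Ktrans, Kep are per-minute).
#'
#' @param path path to a 4D NIfTI file.
#' @param timingPath path to the JSON timing sidecar; defaults to `path` with
#'   the NIfTI extension replaced by `.json`.
#' @param frameTimes,timeUnit,nPrecontrast explicit timing, overriding the
#'   sidecar: per-frame times, their unit, and the precontrast frame count.
#' @return A [DynamicSeries-class].
#' @export
readDynamicSeries <- function(path, timingPath = NULL, frameTimes = NULL,
                              timeUnit = c("min", "s"), nPrecontrast = NULL) {
  timeUnit <- match.arg(timeUnit)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4L)
    stop("expected a 4D NIfTI series, got ", length(dim(arr)), " dimensions")
  if (is.null(frameTimes)) {
    if (is.null(timingPath))
      timingPath <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(timingPath))
      stop("missing frame timing: no sidecar at ", timingPath,
           " and no frameTimes given")
    sidecar <- jsonlite::read_json(timingPath, simplifyVector = TRUE)
    if (is.null(sidecar$frame_times))
      stop("timing sidecar lacks a 'frame_times' field")
    frameTimes <- as.numeric(sidecar$frame_times)
    timeUnit <- if (is.null(sidecar$unit)) "min" else sidecar$unit
    if (is.null(nPrecontrast)) nPrecontrast <- sidecar$n_precontrast
  }
  if (is.null(nPrecontrast))
    stop("nPrecontrast must be given (argument or sidecar)")
  if (length(frameTimes) != dim(arr)[4L])
    stop("timing mismatch: ", length(frameTimes), " times for ",
         dim(arr)[4L], " frames")
  if (any(diff(frameTimes) <= 0))
    stop("frame times must be strictly increasing")
  vx <- RNifti::pixdim(img)
  vx <- if (length(vx) >= 3) vx[1:3] else c(1.5, 1.5, 3)
  DynamicSeries(arr, frameTimes, nPrecontrast, voxelSize = vx,
                timeUnit = if (timeUnit == "s") "s" else "min")
}

#' Write a DynamicSeries as NIfTI plus JSON timing sidecar
#'
#' @param series a [DynamicSeries-class].
#' @param path output NIfTI path (`.nii` or `.nii.gz`); the sidecar is
#'   written next to it with extension `.json`.
#' @return Invisibly, the two paths written.
#' @export
writeDynamicSeries <- function(series, path) {
  img <- RNifti::asNifti(seriesData(series),
                         pixdim = c(voxelSize(series), 1))
  RNifti::writeNifti(img, path)
  sidecarPath <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(frame_times = frameTimes(series), unit = "min",
         n_precontrast = nPrecontrast(series)),
    sidecarPath, auto_unbox = TRUE, digits = NA)
  invisible(c(series = path, timing = sidecarPath))
}

#' Read a region label map
#'
#' Validates that all codes belong to [REGION_CODES] and, when a reference
#' series is supplied, that the grids match. If the tumor centroid lies on
#' the opposite side of the left-right axis (array dimension 2; lower indices
#' are left) from the declared laterality, a warning is raised but the map is
#' accepted - laterality is clinical metadata the map cannot override.
#'
#' @param path path to a 3D integer NIfTI label map.
#' @param laterality `"left"` or `"right"`; side of the tumor-bearing breast.
#' @param series optional [DynamicSeries-class] to check the grid against.
#' @return A [RegionLabels-class].
#' @export
readRegionLabels <- function(path, laterality = c("left", "right"),
                             series = NULL) {
  laterality <- match.arg(laterality)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI label map, got ", length(dim(arr)),
         " dimensions")
  if (any(arr != round(arr)))
    stop("label map contains non-integer values")
  storage.mode(arr) <- "integer"
  if (!is.null(series)) {
    if (!all(dim(arr) == dim(seriesData(series))[1:3]))
      stop("label map grid ", paste(dim(arr), collapse = "x"),
           " does not match series grid ",
           paste(dim(seriesData(series))[1:3], collapse = "x"))
  }
  lab <- RegionLabels(arr, laterality)
  checkTumorSide(lab)
  lab
}

#' @keywords internal
checkTumorSide <- function(labels) {
  arr <- labelMap(labels)
  tum <- which(arr == REGION_CODES[["tumor"]], arr.ind = TRUE)
  if (nrow(tum) == 0L) return(invisible(NULL))
  mid <- (dim(arr)[2L] + 1) / 2
  side <- if (mean(tum[, 2L]) < mid) "left" else "right"
  if (side != laterality(labels))
    warning("tumor centroid lies on the ", side,
            " side but laterality is declared ", laterality(labels),
            call. = FALSE)
  invisible(side)
}

#' Write a region label map as NIfTI
#'
#' @param labels a [RegionLabels-class].
#' @param path output path.
#' @param voxelSize voxel size in mm recorded in the header.
#' @return Invisibly, `path`.
#' @export
writeRegionLabels <- function(labels, path, voxelSize = c(1.5, 1.5, 3)) {
  img <- RNifti::asNifti(labelMap(labels), pixdim = voxelSize,
                         datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write per-patient summaries to CSV and JSON
#'
#' Writes one long-format CSV row per patient per kinetic parameter
#' (`patient_summaries.csv`), one wide feature row per patient
#' (`cohort_features.csv`, the cohort-analysis input), and a JSON mirror of
#' the full summaries. Values round-trip losslessly at 10 significant digits.
#'
#' @param summaries non-empty list of patient summaries from
#'   [summarizePatient()] or [runPatient()].
#' @param path output directory (created if absent).
#' @param overwrite overwrite existing files? Default `FALSE` errors on
#'   collision.
#' @return Invisibly, the paths written.
#' @export
writeSummaryTables <- function(summaries, path, overwrite = FALSE) {
  if (length(summaries) == 0L)
    stop("empty summary collection")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- file.path(path, c("patient_summaries.csv", "cohort_features.csv",
                             "patient_summaries.json"))
  clash <- files[file.exists(files)]
  if (length(clash) && !overwrite)
    stop("output exists (use overwrite = TRUE): ",
         paste(basename(clash), collapse = ", "))
  long <- do.call(rbind, lapply(summaries, function(s) {
    cbind(patient = s$patient, s$parameters,
          tumor_volume_cm3 = s$tumorVolume)
  }))
  write.csv(format(long, digits = 10, trim = TRUE), files[1],
            row.names = FALSE, quote = FALSE)
  wide <- do.call(rbind, lapply(summaries, patientFeatureRow))
  write.csv(format(wide, digits = 10, trim = TRUE), files[2],
            row.names = FALSE, quote = FALSE)
  jsonlite::write_json(summaries, files[3], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(files)
}

#' Write cohort model reports as JSON
#'
#' Serializes the per-family model reports of [runCohort()] (family,
#' selected features, coefficients, apparent AUC with bootstrap CI, Youden
#' operating point, resample count) to one JSON file; the per-resample AUC
#' vectors are omitted as working data.
#'
#' @param models the `models` element of a [runCohort()] result.
#' @param path output JSON file path.
#' @param overwrite overwrite an existing file?
#' @return Invisibly, `path`.
#' @export
writeModelReports <- function(models, path, overwrite = FALSE) {
  if (length(models) == 0L) stop("empty model collection")
  if (file.exists(path) && !overwrite)
    stop("output exists (use overwrite = TRUE): ", basename(path))
  keep <- c("family", "features", "coefficients", "auc", "auc_ci",
            "sensitivity", "specificity", "accuracy", "nBoot")
  jsonlite::write_json(lapply(models, function(m) m[keep]), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back the long-format patient summary table
#'
#' @param path directory previously written by [writeSummaryTables()].
#' @return data.frame of per-patient per-parameter rows.
#' @export
readSummaryTables <- function(path) {
  f <- file.path(path, "patient_summaries.csv")
  if (!file.exists(f)) stop("no patient_summaries.csv under ", path)
  read.csv(f, stringsAsFactors = FALSE)
}

#' One wide feature row (kBPE I/C + kT features + covariates) per patient
#' @keywords internal
patientFeatureRow <- function(s) {
  p <- s$parameters
  row <- data.frame(patient = s$patient, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(p))) {
    row[[paste0("kbpe_ic_", p$parameter[i])]] <- p$kbpe_ic[i]
    row[[paste0("kt_", p$parameter[i])]] <- p$kt_ave[i]
  }
  row$tumor_volume_cm3 <- s$tumorVolume
  if (!is.null(s$covariates))
    for (nm in names(s$covariates)) row[[nm]] <- s$covariates[[nm]]
  row
}
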