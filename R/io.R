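# Plain-text and NIfTI I/O for the pipeline's data objects.

#' Write / read an EOG recording as TSV
#'
#' Tab-separated columns `time_s`, `veog_uv`, `heog_uv`; when the recording
#' carries synthetic ground truth it is stored in a JSON sidecar
#' (`<path>.truth.json`) and restored on read.
#'
#' @param rec an [EogRecording-class].
#' @param path output TSV path.
#' @return `writeEog` returns `path` invisibly; `readEog` returns an
#'   [EogRecording-class].
#' @export
writeEog <- function(rec, path) {
  stopifnot(is(rec, "EogRecording"))
  utils::write.table(
    data.frame(time_s = rec@time, veog_uv = rec@veog, heog_uv = rec@heog),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (length(rec@truth)) {
    tr <- rec@truth
    tr$saccadeIntervals <- as.data.frame(tr$saccadeIntervals)
    tr$saturatedIntervals <- as.data.frame(tr$saturatedIntervals)
    jsonlite::write_json(tr, paste0(path, ".truth.json"), digits = NA,
                         auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname writeEog
#' @export
readEog <- function(path) {
  df <- utils::read.delim(path)
  rate <- 1 / stats::median(diff(df$time_s))
  truth <- list()
  side <- paste0(path, ".truth.json")
  if (file.exists(side)) {
    truth <- jsonlite::read_json(side, simplifyVector = TRUE)
    asIv <- function(x)
      if (is.null(x) || !length(x)) matrix(numeric(), ncol = 2)
      else matrix(unlist(x), ncol = 2)
    truth$saccadeIntervals <- asIv(truth$saccadeIntervals)
    truth$saturatedIntervals <- asIv(truth$saturatedIntervals)
    truth$blinkOnsets <- as.numeric(unlist(truth$blinkOnsets))
    truth$blinkAmplitudes <- as.numeric(unlist(truth$blinkAmplitudes))
  }
  new("EogRecording", time = df$time_s, veog = df$veog_uv,
      heog = df$heog_uv, rate = round(rate, 6), truth = truth)
}

#' Write / read a time-activity curve as TSV
#'
#' Columns `frame_start_min`, `frame_end_min`, `activity`.
#'
#' @param tac a [TimeActivityCurve-class].
#' @param path TSV path.
#' @export
writeTac <- function(tac, path) {
  stopifnot(is(tac, "TimeActivityCurve"))
  utils::write.table(
    data.frame(frame_start_min = tac@frameStart,
               frame_end_min = tac@frameEnd, activity = tac@activity),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTac
#' @export
readTac <- function(path) {
  df <- utils::read.delim(path)
  new("TimeActivityCurve", frameStart = df$frame_start_min,
      frameEnd = df$frame_end_min, activity = df$activity)
}

#' Write / read a cohort table as CSV
#'
#' Columns `subject_id`, `group`, `age`, `sebr`, `ki`.
#'
#' @param cohort cohort data.frame.
#' @param path CSV path.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a 4-D dynamic volume as NIfTI with a frame-timing sidecar
#'
#' The volume goes to `<path>` (`.nii` / `.nii.gz`); frame timing goes to a
#' TSV sidecar `<path>.frames.tsv` with columns `frame_start_min`,
#' `frame_end_min`.
#'
#' @param volume 4-D array (x, y, z, frame).
#' @param frames frame-timing data.frame.
#' @param path NIfTI path.
#' @param voxelSize numeric(3) voxel edges in mm.
#' @return `writeDynamicVolume` returns `path` invisibly;
#'   `readDynamicVolume` a list `volume`, `frames`, `affine`.
#' @export
writeDynamicVolume <- function(volume, frames, path, voxelSize = c(4, 4, 5)) {
  stopifnot(length(dim(volume)) == 4)
  img <- RNifti::asNifti(volume, pixdim = c(voxelSize, 1))
  RNifti::writeNifti(img, path)
  utils::write.table(frames, paste0(path, ".frames.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDynamicVolume
#' @export
readDynamicVolume <- function(path) {
  img <- RNifti::readNifti(path)
  frames <- utils::read.delim(paste0(path, ".frames.tsv"))
  list(volume = array(as.numeric(img), dim(img)), frames = frames,
       affine = unclass(RNifti::xform(img)))
}

#' Write / read a Ki map as NIfTI
#'
#' @param kiVol a [KiVolume-class].
#' @param path NIfTI path.
#' @export
writeKiVolume <- function(kiVol, path) {
  stopifnot(is(kiVol, "KiVolume"))
  img <- RNifti::asNifti(kiVol@values, pixdim = kiVol@voxelSize)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeKiVolume
#' @export
readKiVolume <- function(path, voxelSize = NULL) {
  img <- RNifti::readNifti(path)
  pd <- attr(RNifti::niftiHeader(img), "pixdim") %||%
    RNifti::niftiHeader(img)$pixdim[2:4]
  vs <- voxelSize %||% RNifti::niftiHeader(img)$pixdim[2:4]
  new("KiVolume", values = array(as.numeric(img), dim(img)),
      voxelSize = vs, affine = unclass(RNifti::xform(img)))
}
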