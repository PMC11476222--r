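#' Centroided MS1 runs
#'
#' A `spectrum_run` holds an ordered list of centroided MS1 spectra:
#' retention times in minutes (strictly increasing) and, per spectrum, a
#' two-column matrix of (m/z, intensity) centroids sorted by m/z.
#'
#' @param rt Numeric vector of retention times (minutes), increasing.
#' @param peaks List of numeric matrices with columns `mz`, `intensity`.
#' @param polarity `"negative"` (the only supported mode) or `"positive"`.
#' @param metadata Optional list (ms level, scan range, provenance).
#' @return An object of class `spectrum_run`.
#' @export
spectrum_run <- function(rt, peaks, polarity = "negative", metadata = list()) {
  if (length(rt) != length(peaks)) {
    abort("`rt` and `peaks` must have the same length")
  }
  if (length(rt) > 1 && any(diff(rt) <= 0)) {
    abort("retention times must be strictly increasing")
  }
  peaks <- lapply(peaks, function(p) {
    p <- matrix(as.numeric(p), ncol = 2,
                dimnames = list(NULL, c("mz", "intensity")))
    p[order(p[, 1]), , drop = FALSE]
  })
  structure(list(rt = as.numeric(rt), peaks = peaks, polarity = polarity,
                 metadata = metadata),
            class = "spectrum_run")
}

#' @export
print.spectrum_run <- function(x, ...) {
  cat("<spectrum_run> ", length(x$rt), " MS1 spectra, ",
      sprintf("%.2f-%.2f", min(x$rt), max(x$rt)), " min, ",
      x$polarity, " mode\n", sep = "")
  invisible(x)
}

#' Read a centroided mzML run
#'
#' Reads MS1 spectra from an mzML file (via mzR), converting scan start
#' times to minutes. Profile-mode spectra are rejected: extraction
#' operates on detected centroid m/z values only.
#'
#' @param path Path to an mzML file.
#' @return A [spectrum_run()].
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  ms1 <- which(hdr$msLevel == 1L)
  if (length(ms1) == 0) abort(paste0("no MS1 spectra in ", path))
  if (any(!is.na(hdr$centroided[ms1]) & !hdr$centroided[ms1])) {
    abort(paste0(path, " contains profile-mode MS1 spectra; ",
                 "centroid the data before extraction"))
  }
  pks <- mzR::peaks(handle)
  if (is.matrix(pks)) pks <- list(pks)
  polarity <- if (all(hdr$polarity[ms1] <= 0, na.rm = TRUE)) {
    "negative"
  } else {
    "positive"
  }
  spectrum_run(
    rt = hdr$retentionTime[ms1] / 60,
    peaks = pks[ms1],
    polarity = polarity,
    metadata = list(
      source = path,
      scan_range = c(min(hdr$lowMZ[ms1], na.rm = TRUE),
                     max(hdr$highMZ[ms1], na.rm = TRUE))
    )
  )
}

#' Write a run to mzML
#'
#' Writes a [spectrum_run()] as centroided MS1 mzML (via mzR). Used by
#' the synthetic-run generator so fixtures exercise the same reader as
#' instrument data.
#'
#' @param run A [spectrum_run()].
#' @param path Output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "spectrum_run"))
  n <- length(run$rt)
  counts <- vapply(run$peaks, nrow, integer(1))
  lows <- vapply(run$peaks, function(p) if (nrow(p)) min(p[, 1]) else 0, 0)
  highs <- vapply(run$peaks, function(p) if (nrow(p)) max(p[, 1]) else 0, 0)
  bpi <- vapply(run$peaks, function(p) if (nrow(p)) max(p[, 2]) else 0, 0)
  bpm <- vapply(run$peaks, function(p) {
    if (nrow(p)) p[which.max(p[, 2]), 1] else 0
  }, 0)
  tic <- vapply(run$peaks, function(p) sum(p[, 2]), 0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = if (identical(run$polarity, "negative")) 0L else 1L,
    peaksCount = counts, totIonCurrent = tic,
    retentionTime = run$rt * 60,
    basePeakMZ = bpm, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = lows, highMZ = highs,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_
  )
  mzR::writeMSData(unname(run$peaks), path, header = hdr)
  invisible(path)
}
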