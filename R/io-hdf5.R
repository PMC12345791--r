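# HDF5 persistence for RF scans: dataset `rf` (samples x lines x frames,
# float), acquisition attributes, optional boolean ROI masks of matching
# shape (stored as 0/1 under `roi`).

#' Write / read an RF scan as HDF5
#'
#' @param scan An [rf_scan()].
#' @param path Output `.h5` path (overwritten).
#' @param roi Optional list of logical masks (one per plane).
#' @export
write_rf_scan <- function(scan, path, roi = NULL) {
  stopifnot(inherits(scan, "rf_scan"))
  if (file.exists(path)) unlink(path)
  fr1 <- scan$frames[[1]]
  arr <- array(0, c(nrow(fr1$rf), ncol(fr1$rf), length(scan$frames)))
  for (i in seq_along(scan$frames)) arr[, , i] <- scan$frames[[i]]$rf
  rhdf5::h5createFile(path)
  rhdf5::h5write(arr, path, "rf")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "rf")
  rhdf5::h5writeAttribute(fr1$sampling_rate, did, "fs_mhz")
  rhdf5::h5writeAttribute(fr1$sound_speed, did, "c_mps")
  rhdf5::h5writeAttribute(fr1$line_pitch_mm, did, "line_pitch_mm")
  rhdf5::h5writeAttribute(scan$plane_spacing_cm, did, "plane_spacing_cm")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  if (!is.null(roi)) {
    rarr <- array(0L, dim(arr))
    for (i in seq_along(roi)) rarr[, , i] <- roi[[i]] * 1L
    rhdf5::h5write(rarr, path, "roi")
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_rf_scan
#' @return `read_rf_scan`: list with `scan` ([rf_scan()]) and `roi` (list of
#'   logical masks or `NULL`).
#' @export
read_rf_scan <- function(path) {
  arr <- rhdf5::h5read(path, "rf")
  at <- rhdf5::h5readAttributes(path, "rf")
  frames <- lapply(seq_len(dim(arr)[3]), function(i)
    rf_frame(arr[, , i], as.numeric(at$fs_mhz), as.numeric(at$c_mps),
             as.numeric(at$line_pitch_mm)))
  scan <- rf_scan(frames, plane_spacing_cm = as.numeric(at$plane_spacing_cm))
  roi <- NULL
  if ("roi" %in% rhdf5::h5ls(path)$name) {
    rarr <- rhdf5::h5read(path, "roi")
    roi <- lapply(seq_len(dim(rarr)[3]), function(i) rarr[, , i] > 0)
  }
  rhdf5::h5closeAll()
  list(scan = scan, roi = roi)
}
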