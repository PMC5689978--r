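# CT series I/O.

IOP_AXIAL <- c(1, 0, 0, 0, 1, 0)

#' Write a CT volume as a DICOM series
#'
#' One file per slice (`ct_000k.dcm`), standard CT IOD fields, shared
#' study/series/frame-of-reference UIDs. Pixels are stored as HU + 1024 with
#' rescale slope 1 and intercept -1024, so the round trip is bit exact.
#'
#' @param vol A [ct_volume()]. Non-integer HU (e.g. after down-sampling) are
#'   rounded to the nearest integer on write.
#' @param directory Output directory (created if needed).
#' @param seed Integer seed for the deterministic UID stream.
#' @return Character vector of written file paths.
#' @export
write_ct_series <- function(vol, directory, seed = 1L) {
  validate_ct_volume(vol)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  uid <- dcm_uid_factory(seed)
  study <- uid(); series <- uid(); frame <- uid()
  d <- dim(vol$hu)
  intercept <- -1024
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- c(vol$origin[1], vol$origin[2],
             vol$origin[3] + (k - 1) * vol$spacing[3])
    stored <- as.integer(round(vol$hu[, , k])) - as.integer(intercept)
    px <- writeBin(stored, raw(), size = 2, endian = "little")
    els <- list(
      dcm_el(0x0008, 0x0016, "UI", SOP_CLASS[["ct"]]),
      dcm_el(0x0008, 0x0018, "UI", sop <- uid()),
      dcm_el(0x0008, 0x0060, "CS", "CT"),
      dcm_el(0x0018, 0x0050, "DS", vol$spacing[3]),
      dcm_el(0x0020, 0x000d, "UI", study),
      dcm_el(0x0020, 0x000e, "UI", series),
      dcm_el(0x0020, 0x0013, "IS", k),
      dcm_el(0x0020, 0x0032, "DS", ipp),
      dcm_el(0x0020, 0x0037, "DS", IOP_AXIAL),
      dcm_el(0x0020, 0x0052, "UI", frame),
      dcm_el(0x0028, 0x0002, "US", 1L),
      dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
      dcm_el(0x0028, 0x0010, "US", d[2]),            # rows
      dcm_el(0x0028, 0x0011, "US", d[1]),            # columns
      dcm_el(0x0028, 0x0030, "DS", c(vol$spacing[2], vol$spacing[1])),
      dcm_el(0x0028, 0x0100, "US", 16L),
      dcm_el(0x0028, 0x0101, "US", 16L),
      dcm_el(0x0028, 0x0102, "US", 15L),
      dcm_el(0x0028, 0x0103, "US", 1L),
      dcm_el(0x0028, 0x1052, "DS", intercept),
      dcm_el(0x0028, 0x1053, "DS", 1),
      dcm_el(0x7fe0, 0x0010, "OW", px)
    )
    files[k] <- file.path(directory, sprintf("ct_%04d.dcm", k))
    dcm_write_file(files[k], els, SOP_CLASS[["ct"]], sop)
  }
  files
}

#' Read a DICOM CT series from a directory
#'
#' Slices are sorted by position along the slice direction; the rescale
#' slope/intercept is applied; geometry is returned in the LPS frame with
#' voxel-center addressing. Mixed series and non-uniform slice spacing are
#' rejected.
#'
#' @param directory Directory containing the CT slices of one series.
#' @param tol Slice-position uniformity tolerance in mm.
#' @return A [ct_volume()].
#' @export
read_ct_series <- function(directory, tol = 1e-3) {
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    ds <- tryCatch(dcm_read_file(f), error = function(e) NULL)
    if (is.null(ds)) next
    if (!identical(dcm_get(ds, 0x0008, 0x0060), "CT")) next
    slices[[length(slices) + 1L]] <- ds
  }
  if (length(slices) == 0L)
    stop("no CT slices found in ", directory)
  series <- vapply(slices, function(ds)
    dcm_req(ds, 0x0020, 0x000e, "SeriesInstanceUID"), character(1))
  if (length(unique(series)) > 1L)
    stop("mixed series UIDs in CT directory: ",
         paste(unique(series), collapse = ", "))
  for (ds in slices) {
    iop <- dcm_req(ds, 0x0020, 0x0037, "ImageOrientationPatient")
    if (max(abs(iop - IOP_AXIAL)) > 1e-6)
      stop("oblique CT series not supported (non-axial orientation)")
  }
  z <- vapply(slices, function(ds)
    dcm_req(ds, 0x0020, 0x0032, "ImagePositionPatient")[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  nz <- length(slices)
  if (nz > 1L) {
    dz <- diff(z)
    step <- stats::median(dz)
    bad <- which(abs(dz - step) > tol)
    if (length(bad) > 0L)
      stop(sprintf(paste0(
        "non-uniform slice spacing: gap of %.3f mm between slices at ",
        "z = %.3f mm and z = %.3f mm (expected %.3f mm; missing slice near ",
        "index %d)"), dz[bad[1]], z[bad[1]], z[bad[1] + 1L], step, bad[1] + 1L))
  } else {
    step <- dcm_req(slices[[1]], 0x0018, 0x0050, "SliceThickness")
  }
  s1 <- slices[[1]]
  rows <- as.integer(dcm_req(s1, 0x0028, 0x0010, "Rows"))
  cols <- as.integer(dcm_req(s1, 0x0028, 0x0011, "Columns"))
  ps <- dcm_req(s1, 0x0028, 0x0030, "PixelSpacing")  # (row, col) spacing
  hu <- array(0L, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    ds <- slices[[k]]
    slope <- dcm_req(ds, 0x0028, 0x1053, "RescaleSlope")
    inter <- dcm_req(ds, 0x0028, 0x1052, "RescaleIntercept")
    px <- dcm_req(ds, 0x7fe0, 0x0010, "PixelData")
    vals <- readBin(px, integer(), n = rows * cols, size = 2,
                    signed = TRUE, endian = "little")
    hu[, , k] <- as.integer(round(vals * slope + inter))
  }
  ipp <- dcm_req(s1, 0x0020, 0x0032, "ImagePositionPatient")
  ct_volume(hu, origin = c(ipp[1], ipp[2], z[1]),
            spacing = c(ps[2], ps[1], step),
            rescale = c(slope = 1, intercept = -1024))
}
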