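# RT Dose I/O. Dose is stored as 32-bit integers times a DoseGridScaling
# factor chosen as max(dose)/(2^31 - 1), so write/read preserves values to
# better than 1e-9 relative.

#' Write a dose grid as a DICOM RT Dose file
#'
#' @param grid A [dose_grid()].
#' @param path Output file path.
#' @param seed Integer seed for the deterministic UID stream.
#' @return `path`, invisibly.
#' @export
write_rtdose <- function(grid, path, seed = 1L) {
  validate_dose_grid(grid)
  uid <- dcm_uid_factory(seed)
  study <- uid(); series <- uid(); sop <- uid()
  d <- dim(grid$values)
  maxv <- max(grid$values)
  scaling <- if (maxv > 0) maxv / 2147483000 else 1
  stored <- as.integer(round(grid$values / scaling))
  px <- writeBin(as.vector(stored), raw(), size = 4, endian = "little")
  gfov <- (seq_len(d[3]) - 1) * grid$spacing[3]
  els <- list(
    dcm_el(0x0008, 0x0016, "UI", SOP_CLASS[["rtdose"]]),
    dcm_el(0x0008, 0x0018, "UI", sop),
    dcm_el(0x0008, 0x0060, "CS", "RTDOSE"),
    dcm_el(0x0020, 0x000d, "UI", study),
    dcm_el(0x0020, 0x000e, "UI", series),
    dcm_el(0x0020, 0x0032, "DS", grid$origin),
    dcm_el(0x0020, 0x0037, "DS", IOP_AXIAL),
    dcm_el(0x0028, 0x0002, "US", 1L),
    dcm_el(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_el(0x0028, 0x0008, "IS", d[3]),
    dcm_el(0x0028, 0x0010, "US", d[2]),
    dcm_el(0x0028, 0x0011, "US", d[1]),
    dcm_el(0x0028, 0x0030, "DS", c(grid$spacing[2], grid$spacing[1])),
    dcm_el(0x0028, 0x0100, "US", 32L),
    dcm_el(0x0028, 0x0101, "US", 32L),
    dcm_el(0x0028, 0x0102, "US", 31L),
    dcm_el(0x0028, 0x0103, "US", 0L),
    dcm_el(0x3004, 0x0002, "CS", "GY"),
    dcm_el(0x3004, 0x0004, "CS", "PHYSICAL"),
    dcm_el(0x3004, 0x000a, "CS", "PLAN"),
    dcm_el(0x3004, 0x000c, "DS", gfov),
    dcm_el(0x3004, 0x000e, "DS", scaling),
    dcm_el(0x7fe0, 0x0010, "OW", px)
  )
  dcm_write_file(path, els, SOP_CLASS[["rtdose"]], sop)
}

#' Read a DICOM RT Dose file
#'
#' The dose grid scaling is applied on read; oblique grids are rejected.
#'
#' @param path RT Dose file path.
#' @return A [dose_grid()] in Gy.
#' @export
read_rtdose <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, 0x0008, 0x0060), "RTDOSE"))
    stop("not an RT Dose file: ", path)
  iop <- dcm_req(ds, 0x0020, 0x0037, "ImageOrientationPatient")
  if (max(abs(iop - IOP_AXIAL)) > 1e-6)
    stop("oblique dose grids not supported (axes must parallel the CT axes)")
  rows <- as.integer(dcm_req(ds, 0x0028, 0x0010, "Rows"))
  cols <- as.integer(dcm_req(ds, 0x0028, 0x0011, "Columns"))
  nf <- as.integer(dcm_req(ds, 0x0028, 0x0008, "NumberOfFrames"))
  ps <- dcm_req(ds, 0x0028, 0x0030, "PixelSpacing")
  gfov <- dcm_req(ds, 0x3004, 0x000c, "GridFrameOffsetVector")
  scaling <- dcm_req(ds, 0x3004, 0x000e, "DoseGridScaling")
  if (nf > 1L) {
    dzv <- diff(gfov)
    if (diff(range(dzv)) > 1e-6)
      stop("non-uniform dose frame offsets not supported")
    dz <- dzv[1]
  } else dz <- 1
  px <- dcm_req(ds, 0x7fe0, 0x0010, "PixelData")
  stored <- readBin(px, integer(), n = rows * cols * nf, size = 4,
                    endian = "little")
  values <- array(stored * scaling, dim = c(cols, rows, nf))
  ipp <- dcm_req(ds, 0x0020, 0x0032, "ImagePositionPatient")
  dose_grid(values, origin = ipp, spacing = c(ps[2], ps[1], dz))
}
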