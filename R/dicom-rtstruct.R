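# RT Structure Set I/O. Contours are closed planar polygons stored without a
# duplicated last vertex (closure is implicit), matching the container
# convention used throughout the package.

#' Write a structure set as a DICOM RT Structure Set file
#'
#' @param sset A [structure_set()].
#' @param path Output file path.
#' @param seed Integer seed for the deterministic UID stream.
#' @return `path`, invisibly.
#' @export
write_rtstruct <- function(sset, path, seed = 1L) {
  validate_structure_set(sset)
  uid <- dcm_uid_factory(seed)
  study <- uid(); series <- uid(); sop <- uid()
  rois <- list(); rcs <- list()
  for (i in seq_along(sset$structures)) {
    st <- sset$structures[[i]]
    rois[[i]] <- list(
      dcm_el(0x3006, 0x0022, "IS", i),
      dcm_el(0x3006, 0x0026, "LO", st$name))
    contours <- lapply(st$contours, function(cm) {
      list(
        dcm_el(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        dcm_el(0x3006, 0x0046, "IS", nrow(cm)),
        dcm_el(0x3006, 0x0050, "DS", as.numeric(t(cm))))
    })
    color <- if (is.null(st$color)) c(255L, 0L, 0L) else as.integer(st$color)
    rcs[[i]] <- list(
      dcm_el(0x3006, 0x002a, "IS", color),
      dcm_el(0x3006, 0x0040, "SQ", contours),
      dcm_el(0x3006, 0x0084, "IS", i))
  }
  els <- list(
    dcm_el(0x0008, 0x0016, "UI", SOP_CLASS[["rtstruct"]]),
    dcm_el(0x0008, 0x0018, "UI", sop),
    dcm_el(0x0008, 0x0060, "CS", "RTSTRUCT"),
    dcm_el(0x0020, 0x000d, "UI", study),
    dcm_el(0x0020, 0x000e, "UI", series),
    dcm_el(0x3006, 0x0002, "SH", "brachydeck"),
    dcm_el(0x3006, 0x0020, "SQ", rois),
    dcm_el(0x3006, 0x0039, "SQ", rcs)
  )
  dcm_write_file(path, els, SOP_CLASS[["rtstruct"]], sop)
}

#' Read a DICOM RT Structure Set file
#'
#' @param path RT Structure Set file path.
#' @return A [structure_set()]; contour vertices in mm, LPS.
#' @export
read_rtstruct <- function(path) {
  ds <- dcm_read_file(path)
  if (!identical(dcm_get(ds, 0x0008, 0x0060), "RTSTRUCT"))
    stop("not an RT Structure Set file: ", path)
  rois <- dcm_req(ds, 0x3006, 0x0020, "StructureSetROISequence")
  names_by_num <- list()
  for (item in rois) {
    num <- as.character(dcm_req(item, 0x3006, 0x0022, "ROINumber"))
    names_by_num[[num]] <- dcm_req(item, 0x3006, 0x0026, "ROIName")
  }
  rcs <- dcm_req(ds, 0x3006, 0x0039, "ROIContourSequence")
  structures <- lapply(rcs, function(item) {
    num <- as.character(dcm_req(item, 0x3006, 0x0084, "ReferencedROINumber"))
    color <- dcm_get(item, 0x3006, 0x002a)
    cseq <- dcm_get(item, 0x3006, 0x0040)
    contours <- lapply(cseq, function(cp) {
      dat <- dcm_req(cp, 0x3006, 0x0050, "ContourData")
      matrix(dat, ncol = 3, byrow = TRUE)
    })
    list(name = names_by_num[[num]], color = color, contours = contours)
  })
  structure_set(structures)
}

#' Locate one structure by name
#'
#' @param sset A [structure_set()].
#' @param name Structure name (exact match).
#' @return The structure (list with `name`, `color`, `contours`).
#' @export
get_structure <- function(sset, name) {
  for (st in sset$structures) if (identical(st$name, name)) return(st)
  stop("structure not found: ", name)
}
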