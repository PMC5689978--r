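# Minimal DICOM explicit-VR little-endian codec.
#
# The package reads and writes one documented encoding (the one produced by its
# own writers): explicit VR, little endian, defined lengths everywhere
# (including sequences and items). Files using other transfer syntaxes or
# undefined-length sequences are rejected with a clear message rather than
# guessed at, because RT plan layouts are not uniquely transferable between
# planning systems.

DCM_UID_ROOT <- "1.2.826.0.1.3680043.10.424."
UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

SOP_CLASS <- c(
  ct       = "1.2.840.10008.5.1.4.1.1.2",
  rtdose   = "1.2.840.10008.5.1.4.1.1.481.2",
  rtstruct = "1.2.840.10008.5.1.4.1.1.481.3",
  rtplan   = "1.2.840.10008.5.1.4.1.1.481.5"
)

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UN", "UT")
STRING_VRS <- c("AE", "AS", "CS", "DA", "DT", "LO", "LT", "PN", "SH", "ST",
                "TM", "UI")

#' Deterministic DICOM UID generator
#'
#' Returns a closure producing a fresh UID on each call. The stream is a pure
#' function of `seed`, so fixtures written twice with the same seed are
#' byte-identical.
#'
#' @param seed Integer seed for the UID stream.
#' @return A function of no arguments returning a UID string.
#' @export
dcm_uid_factory <- function(seed = 1L) {
  base <- sprintf("%s%d.", DCM_UID_ROOT, abs(as.integer(seed)) %% 1000000L)
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0(base, counter)
  }
}

dcm_el <- function(group, element, vr, value) {
  list(group = as.integer(group), element = as.integer(element),
       vr = vr, value = value)
}

.u16raw <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
.u32raw <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

# DS values must fit in 16 bytes; %.10g always does for our magnitudes
fmt_ds <- function(x) {
  s <- sprintf("%.10g", x)
  if (any(nchar(s) > 16)) s <- sprintf("%.8g", x)
  s
}

dcm_encode_value <- function(vr, value) {
  if (is.null(value)) return(raw(0))
  body <- switch(vr,
    DS = charToRaw(paste(fmt_ds(as.numeric(value)), collapse = "\\")),
    IS = charToRaw(paste(sprintf("%d", as.integer(value)), collapse = "\\")),
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    FL = writeBin(as.numeric(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.numeric(value), raw(), size = 8, endian = "little"),
    OW = ,
    OB = as.raw(value),
    {
      if (!vr %in% STRING_VRS)
        stop("unsupported VR for encoding: ", vr)
      charToRaw(paste(as.character(value), collapse = "\\"))
    }
  )
  if (length(body) %% 2L == 1L) {
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    body <- c(body, pad)
  }
  body
}

dcm_encode_element <- function(el) {
  vr <- el$vr
  if (vr == "SQ") {
    body <- raw(0)
    for (item in el$value) {
      ib <- dcm_encode_dataset(item)
      body <- c(body, .u16raw(0xFFFEL), .u16raw(0xE000L),
                .u32raw(length(ib)), ib)
    }
  } else {
    body <- dcm_encode_value(vr, el$value)
  }
  hdr <- c(.u16raw(el$group), .u16raw(el$element), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(hdr, raw(2), .u32raw(length(body)), body)
  } else {
    c(hdr, .u16raw(length(body)), body)
  }
}

dcm_encode_dataset <- function(elements) {
  parts <- lapply(elements, dcm_encode_element)
  do.call(c, c(list(raw(0)), parts))
}

#' Write a DICOM file (explicit VR little endian)
#'
#' @param path Output file path.
#' @param elements List of element specs (`dcm_el`) in ascending tag order.
#' @param sop_class,sop_instance UIDs for the file-meta group.
#' @return `path`, invisibly.
#' @keywords internal
dcm_write_file <- function(path, elements, sop_class, sop_instance) {
  body <- dcm_encode_dataset(elements)
  meta_el <- list(
    dcm_el(0x0002, 0x0001, "OB", as.raw(c(0L, 1L))),
    dcm_el(0x0002, 0x0002, "UI", sop_class),
    dcm_el(0x0002, 0x0003, "UI", sop_instance),
    dcm_el(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    dcm_el(0x0002, 0x0012, "UI", paste0(DCM_UID_ROOT, "1.1"))
  )
  mb <- dcm_encode_dataset(meta_el)
  meta <- c(dcm_encode_element(dcm_el(0x0002, 0x0000, "UL", length(mb))), mb)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

ru16 <- function(r, p) as.integer(r[p]) + 256L * as.integer(r[p + 1L])
ru32 <- function(r, p) {
  as.numeric(r[p]) + 256 * as.numeric(r[p + 1L]) +
    65536 * as.numeric(r[p + 2L]) + 16777216 * as.numeric(r[p + 3L])
}

dcm_parse_value <- function(vr, bytes) {
  if (length(bytes) == 0L) return(NULL)
  switch(vr,
    DS = as.numeric(strsplit(trim_dcm(rawToChar(bytes)), "\\", fixed = TRUE)[[1L]]),
    IS = as.integer(strsplit(trim_dcm(rawToChar(bytes)), "\\", fixed = TRUE)[[1L]]),
    US = readBin(bytes, integer(), n = length(bytes) / 2L, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(bytes, integer(), n = length(bytes) / 4L, size = 4,
                 endian = "little"),
    FL = readBin(bytes, numeric(), n = length(bytes) / 4L, size = 4,
                 endian = "little"),
    FD = readBin(bytes, numeric(), n = length(bytes) / 8L, size = 8,
                 endian = "little"),
    OW = ,
    OB = bytes,
    {
      s <- trim_dcm(rawToChar(bytes[bytes != as.raw(0L)]))
      strsplit(s, "\\", fixed = TRUE)[[1L]]
    }
  )
}

trim_dcm <- function(s) sub("[ ]+$", "", s)

# Parse a dataset from raw bytes in [pos, end]; returns list(ds, pos).
dcm_parse_dataset <- function(r, pos, end) {
  ds <- list()
  while (pos <= end) {
    if (pos + 7L > length(r) + 1L)
      stop("truncated DICOM stream: element header expected at byte ", pos,
           " but only ", length(r), " bytes present")
    group <- ru16(r, pos)
    elem <- ru16(r, pos + 2L)
    vr <- rawToChar(r[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop(sprintf(
        "unknown DICOM layout at tag (%04x,%04x): VR bytes are not explicit VR",
        group, elem))
    if (vr %in% LONG_VRS) {
      len <- ru32(r, pos + 8L)
      start <- pos + 12L
    } else {
      len <- ru16(r, pos + 6L)
      start <- pos + 8L
    }
    if (len == 4294967295)
      stop(sprintf(
        "undefined-length element (%04x,%04x) not supported by this reader",
        group, elem))
    if (start + len - 1L > length(r))
      stop(sprintf(
        "truncated DICOM stream in (%04x,%04x): expected %d value bytes, found %d",
        group, elem, len, length(r) - start + 1L))
    if (vr == "SQ") {
      items <- list()
      q <- start
      while (q < start + len) {
        if (ru16(r, q) != 0xFFFEL || ru16(r, q + 2L) != 0xE000L)
          stop("malformed sequence item tag")
        ilen <- ru32(r, q + 4L)
        if (ilen == 4294967295)
          stop("undefined-length sequence item not supported by this reader")
        res <- dcm_parse_dataset(r, q + 8L, q + 8L + ilen - 1L)
        items[[length(items) + 1L]] <- res$ds
        q <- q + 8L + ilen
      }
      value <- items
    } else {
      value <- if (len > 0) dcm_parse_value(vr, r[start:(start + len - 1L)])
               else NULL
    }
    ds[[sprintf("%04x%04x", group, elem)]] <- list(vr = vr, value = value)
    pos <- start + len
  }
  list(ds = ds, pos = pos)
}

#' Read a DICOM file written in explicit VR little endian
#'
#' @param path File path.
#' @return Named list of elements keyed by lowercase `gggg eeee` hex; sequence
#'   values are lists of item datasets of the same shape.
#' @keywords internal
dcm_read_file <- function(path) {
  n <- file.info(path)$size
  if (is.na(n) || n < 140)
    stop("not a DICOM file (too short): ", path)
  r <- readBin(path, "raw", n)
  if (rawToChar(r[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  meta <- dcm_parse_meta(r)
  ts <- meta$ds[["00020010"]]$value
  if (!identical(ts, UID_EXPLICIT_LE))
    stop("unsupported transfer syntax (only explicit VR little endian): ", ts)
  dcm_parse_dataset(r, meta$pos, length(r))$ds
}

dcm_parse_meta <- function(r) {
  pos <- 133L
  # group length element tells us where the meta group ends
  if (ru16(r, pos) != 2L || ru16(r, pos + 2L) != 0L)
    stop("missing file-meta group length")
  glen <- ru32(r, pos + 8L)
  end <- pos + 12L + glen - 1L
  res <- dcm_parse_dataset(r, pos + 12L, end)
  list(ds = res$ds, pos = end + 1L)
}

dcm_get <- function(ds, group, element) {
  x <- ds[[sprintf("%04x%04x", group, element)]]
  if (is.null(x)) NULL else x$value
}

dcm_req <- function(ds, group, element, what) {
  v <- dcm_get(ds, group, element)
  if (is.null(v))
    stop(sprintf("required DICOM element (%04x,%04x) [%s] missing",
                 group, element, what))
  v
}
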