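# CT-to-material-model conversion: HU-to-density calibration, truncation to
# two significant digits, 54-bin density binning, 23-row tissue composition
# lookup, in-plane down-sampling, and assembly of the per-voxel material
# model that the deck writer consumes.

extdata <- function(name) {
  system.file("extdata", name, package = "brachydeck", mustWork = TRUE)
}

#' HU-to-density calibration
#'
#' Piecewise-linear calibration of Hounsfield units versus mass density,
#' clamped to the end densities outside the anchor range.
#'
#' @param anchors Data frame with columns `hu` and `density` (g/cm3), HU
#'   strictly increasing. The default curve anchors air (-1000 HU, 0.0012
#'   g/cm3) and water (0 HU, 1.00 g/cm3) and is replaceable by a user file.
#' @return An object of class `hu_calibration`.
#' @export
hu_calibration <- function(anchors = NULL) {
  if (is.null(anchors)) {
    anchors <- data.frame(
      hu = c(-1000, -700, 0, 300, 1200, 3000),
      density = c(0.0012, 0.30, 1.00, 1.20, 1.85, 2.70))
  }
  if (any(diff(anchors$hu) <= 0))
    stop("calibration HU anchors must be strictly increasing")
  if (any(anchors$density <= 0))
    stop("calibration densities must be positive")
  structure(list(anchors = anchors), class = "hu_calibration")
}

#' Read a calibration from a CSV file with columns `hu`, `density`
#' @param path CSV path.
#' @return An `hu_calibration`.
#' @export
read_calibration_csv <- function(path) {
  hu_calibration(utils::read.csv(path))
}

#' Convert HU to mass density
#'
#' @param hu Numeric vector/array of Hounsfield units.
#' @param cal An [hu_calibration()].
#' @return Mass density in g/cm3, same shape as `hu`; values outside the
#'   anchor range clamp to the end densities.
#' @export
hu_to_density <- function(hu, cal = hu_calibration()) {
  out <- stats::approx(cal$anchors$hu, cal$anchors$density, xout = as.vector(hu),
                       rule = 2, ties = "ordered")$y
  if (!is.null(dim(hu))) dim(out) <- dim(hu)
  out
}

#' Truncate density to two significant digits
#'
#' Truncation toward zero (not rounding): 1.789 becomes 1.7.
#'
#' @param d Density in g/cm3 (vector/array, values > 0).
#' @return Truncated densities, same shape.
#' @export
truncate_density <- function(d) {
  out <- as.vector(d)
  pos <- out > 0
  e <- floor(log10(out[pos]))
  f <- 10^(e - 1)
  # small epsilon guards against 1.0/0.1 landing just under an integer in
  # floating point; it cannot promote x.x99.. across a digit boundary
  out[pos] <- floor(out[pos] / f + 1e-9) * f
  if (!is.null(dim(d))) dim(out) <- dim(d)
  out
}

#' Density binning scheme
#'
#' @param table Data frame with columns `low`, `high`, `representative`
#'   (g/cm3); contiguous bins, representatives inside their bins. The default
#'   is the shipped 54-bin scheme: 0.02 g/cm3 bins across the soft-tissue
#'   range 0.85-1.15 and coarser bins elsewhere, spanning 0.0012-3.0.
#' @return An object of class `binning_scheme`.
#' @export
binning_scheme <- function(table = NULL) {
  if (is.null(table)) table <- utils::read.csv(extdata("density_bins_54.csv"))
  if (any(table$low[-1] != table$high[-nrow(table)]))
    stop("binning scheme bins must be contiguous")
  if (any(table$representative < table$low |
          table$representative > table$high))
    stop("bin representatives must lie within their bins")
  structure(list(table = table), class = "binning_scheme")
}

#' Bin a density to its bin representative
#'
#' Returns the representative density of the bin containing each value; values
#' beyond either end clamp to the first/last bin.
#'
#' @param d Density in g/cm3 (vector/array).
#' @param scheme A [binning_scheme()].
#' @return Binned densities, same shape as `d`.
#' @export
bin_density <- function(d, scheme = binning_scheme()) {
  tb <- scheme$table
  edges <- c(tb$low[1], tb$high)
  i <- findInterval(as.vector(d), edges, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(tb))
  out <- tb$representative[i]
  if (!is.null(dim(d))) dim(out) <- dim(d)
  out
}

#' Tissue composition lookup table
#'
#' @param table Data frame with columns `low`, `high`, `name` and one column
#'   per element symbol holding mass fractions summing to 1. Ranges are
#'   half-open `[low, high)` with the last range closed. The default is the
#'   shipped 23-row table following the Schneider density-partition pattern
#'   (constructed values, user-replaceable).
#' @return An object of class `tissue_table`.
#' @export
tissue_table <- function(table = NULL) {
  if (is.null(table)) table <- utils::read.csv(extdata("tissues_23.csv"))
  elem_cols <- setdiff(names(table), c("low", "high", "name"))
  fr <- as.matrix(table[, elem_cols])
  if (any(abs(rowSums(fr) - 1) > 1e-6))
    stop("tissue mass fractions must sum to 1 within 1e-6")
  if (any(table$low[-1] != table$high[-nrow(table)]))
    stop("tissue density ranges must partition the domain without overlap")
  structure(list(table = table, elements = elem_cols, fractions = fr),
            class = "tissue_table")
}

#' Assign a tissue composition row to each density
#'
#' @param d Density in g/cm3 (vector/array).
#' @param table A [tissue_table()].
#' @return Integer row indices into the tissue table, same shape as `d`;
#'   out-of-domain densities clamp to the first/last row.
#' @export
assign_tissue <- function(d, table = tissue_table()) {
  tb <- table$table
  edges <- c(tb$low[1], tb$high)
  i <- findInterval(as.vector(d), edges, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(tb))
  if (!is.null(dim(d))) dim(i) <- dim(d)
  i
}

#' Down-sample the in-plane resolution of a CT volume
#'
#' Block-average pooling of HU over `factor` x `factor` in-plane blocks; the
#' in-plane spacing scales by `factor` and the slice count is unchanged. If
#' the in-plane matrix is not divisible by `factor`, the volume is padded with
#' air (-1000 HU) on the high-index side first. Pooled HU are generally
#' non-integer.
#'
#' @param ct A [ct_volume()].
#' @param factor Down-sampling factor: 2, 4 or 8.
#' @return A [ct_volume()] with reduced in-plane matrix.
#' @export
downsample_inplane <- function(ct, factor) {
  if (!factor %in% c(2L, 4L, 8L)) stop("factor must be 2, 4 or 8")
  d <- dim(ct$hu)
  hu <- ct$hu
  pad <- (factor - d[1:2] %% factor) %% factor
  if (any(pad > 0)) {
    nd <- d + c(pad, 0L)
    tmp <- array(-1000, dim = nd)
    tmp[seq_len(d[1]), seq_len(d[2]), ] <- hu
    hu <- tmp; d <- nd
  }
  nx <- d[1] %/% factor; ny <- d[2] %/% factor
  dim(hu) <- c(factor, nx, factor, ny, d[3])
  pooled <- colMeans(aperm(hu, c(1, 3, 2, 4, 5)), dims = 2)
  # voxel-center origin shifts by half the block growth
  new_origin <- ct$origin + c((factor - 1) / 2 * ct$spacing[1:2], 0)
  ct_volume(pooled, new_origin,
            c(ct$spacing[1:2] * factor, ct$spacing[3]),
            ct$orientation, ct$rescale)
}

#' Build the voxelized material model from a CT volume
#'
#' Per-voxel mass density (calibrated, truncated to two significant digits,
#' optionally binned) and tissue composition index. The number of lattice
#' elements equals the number of voxels in the CT stack.
#'
#' @param ct A [ct_volume()].
#' @param cal An [hu_calibration()].
#' @param scheme A [binning_scheme()], or `NULL` to skip binning.
#' @param table A [tissue_table()].
#' @return An object of class `material_model` with fields `density`,
#'   `material_index`, `origin`, `spacing`, `tissue_table` and `provenance`.
#' @export
build_material_model <- function(ct, cal = hu_calibration(),
                                 scheme = binning_scheme(),
                                 table = tissue_table()) {
  validate_ct_volume(ct)
  density <- truncate_density(hu_to_density(ct$hu, cal))
  binned <- !is.null(scheme)
  if (binned) density <- bin_density(density, scheme)
  material_index <- assign_tissue(density, table)
  structure(list(
    density = density, material_index = material_index,
    origin = ct$origin, spacing = ct$spacing,
    tissue_table = table,
    provenance = list(
      calibration = cal,
      binning = if (binned) "density_bins_54" else "none",
      tissue = "tissues_23")),
    class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  d <- dim(x$density)
  pairs <- length(unique(as.vector(x$material_index) * 1000 +
                           match(as.vector(x$density),
                                 sort(unique(as.vector(x$density))))))
  cat(sprintf(
    "<material_model> %dx%dx%d voxels, %d tissues present, %d (tissue, density) pairs\n",
    d[1], d[2], d[3], length(unique(as.vector(x$material_index))), pairs))
  invisible(x)
}
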