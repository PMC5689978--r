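# Core containers. All geometry is LPS patient frame, millimetres,
# voxel-center addressing. Arrays are indexed [x, y, z] where x runs along the
# in-plane column direction, y along the row direction and z along the slice
# direction; only axis-aligned volumes (identity orientation) are supported.

#' CT volume container
#'
#' @param hu 3D array of Hounsfield units, indexed `[x, y, z]`.
#' @param origin Length-3 position of the first voxel center (mm, LPS).
#' @param spacing Length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @param orientation 3x3 matrix whose columns are the x/y/z axis direction
#'   unit vectors; only the identity is accepted (axial, axis-aligned series).
#' @param rescale Named vector `c(slope=, intercept=)` recording the rescale
#'   applied on read.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(hu, origin, spacing, orientation = diag(3),
                      rescale = c(slope = 1, intercept = 0)) {
  v <- structure(
    list(hu = hu, origin = as.numeric(origin), spacing = as.numeric(spacing),
         orientation = orientation, rescale = rescale),
    class = "ct_volume")
  validate_ct_volume(v)
  v
}

validate_ct_volume <- function(v) {
  stopifnot(length(dim(v$hu)) == 3L, length(v$origin) == 3L,
            length(v$spacing) == 3L)
  if (any(v$spacing <= 0)) stop("ct_volume: spacing must be strictly positive")
  if (max(abs(crossprod(v$orientation) - diag(3))) > 1e-6)
    stop("ct_volume: orientation vectors must be orthonormal")
  if (max(abs(v$orientation - diag(3))) > 1e-6)
    stop("ct_volume: only axis-aligned (identity orientation) volumes supported")
  rng <- range(v$hu)
  if (rng[1] < -1024 || rng[2] > 3071)
    stop("ct_volume: HU outside [-1024, 3071]")
  invisible(v)
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$hu)
  cat(sprintf("<ct_volume> %dx%dx%d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; HU range [%d, %d]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$hu), max(x$hu)))
  invisible(x)
}

# voxel-center coordinates along axis i
grid_axis <- function(origin, spacing, n, i) {
  origin[i] + (seq_len(n) - 1) * spacing[i]
}

ct_axis <- function(v, i) grid_axis(v$origin, v$spacing, dim(v$hu)[i], i)

# center of the voxel grid (mm)
grid_center <- function(origin, spacing, dims) {
  origin + (dims - 1) / 2 * spacing
}

#' Dose grid container
#'
#' @param values 3D array of absorbed dose in Gy, indexed `[x, y, z]`.
#' @param origin,spacing As for [ct_volume()].
#' @param frame Patient frame label; always `"LPS"`.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, origin, spacing, frame = "LPS") {
  g <- structure(
    list(values = values, origin = as.numeric(origin),
         spacing = as.numeric(spacing), frame = frame),
    class = "dose_grid")
  validate_dose_grid(g)
  g
}

validate_dose_grid <- function(g) {
  stopifnot(length(dim(g$values)) == 3L, length(g$origin) == 3L)
  if (any(g$spacing <= 0)) stop("dose_grid: spacing must be strictly positive")
  if (any(g$values < 0)) stop("dose_grid: dose values must be >= 0")
  invisible(g)
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %dx%dx%d, max %.4g Gy\n", d[1], d[2], d[3],
              max(x$values)))
  invisible(x)
}

#' Structure set container
#'
#' @param structures List of structures; each a list with `name` (character),
#'   `color` (length-3 integer 0-255) and `contours` (list of Nx3 matrices of
#'   vertices in mm, closed planar polygons without a duplicated last vertex).
#' @return An object of class `structure_set`.
#' @export
structure_set <- function(structures) {
  s <- structure(list(structures = structures), class = "structure_set")
  validate_structure_set(s)
  s
}

validate_structure_set <- function(s) {
  for (st in s$structures) {
    stopifnot(is.character(st$name))
    for (cm in st$contours) {
      if (nrow(cm) < 3L)
        stop("structure_set: contour with fewer than 3 vertices in ", st$name)
      if (diff(range(cm[, 3])) > 0.1)
        stop("structure_set: contour not coplanar with its slice in ", st$name)
    }
  }
  invisible(s)
}

#' @export
print.structure_set <- function(x, ...) {
  for (st in x$structures)
    cat(sprintf("<structure> %s: %d contours\n", st$name, length(st$contours)))
  invisible(x)
}

#' Brachytherapy plan container
#'
#' @param source_id Source model identifier (e.g. `"mHDR-v2"`, `"VS2000"`).
#' @param catheters List of catheters, each `list(id=, control_points=)` with
#'   control points ordered tip first (Nx3 matrix, mm).
#' @param dwells Data frame with columns `catheter_id`, `x`, `y`, `z` (mm),
#'   `time` (s) and `index`.
#' @param prescription_dose Prescription dose in Gy.
#' @return An object of class `plan_model`; `total_time` (s) is derived as the
#'   sum of dwell times.
#' @export
plan_model <- function(source_id, catheters, dwells, prescription_dose = NA_real_) {
  p <- structure(
    list(source_id = source_id, catheters = catheters, dwells = dwells,
         prescription_dose = prescription_dose,
         total_time = sum(dwells$time)),
    class = "plan_model")
  validate_plan_model(p)
  p
}

validate_plan_model <- function(p) {
  ids <- vapply(p$catheters, function(ca) ca$id, integer(1))
  if (!all(p$dwells$catheter_id %in% ids))
    stop("plan_model: dwell references a non-existent catheter")
  if (any(p$dwells$time < 0)) stop("plan_model: negative dwell time")
  if (abs(p$total_time - sum(p$dwells$time)) > 1e-9)
    stop("plan_model: total_time inconsistent with dwell times")
  for (ca in p$catheters) {
    if (nrow(ca$control_points) < 2L)
      stop("plan_model: catheter with fewer than 2 control points")
    seg <- diff(ca$control_points)
    if (any(rowSums(seg^2) == 0))
      stop("plan_model: coincident consecutive control points")
  }
  invisible(p)
}

#' @export
print.plan_model <- function(x, ...) {
  cat(sprintf(
    "<plan_model> source %s: %d catheters, %d dwells, total time %.3f s\n",
    x$source_id, length(x$catheters), nrow(x$dwells), x$total_time))
  if (!is.na(x$prescription_dose))
    cat(sprintf("  prescription %.3g Gy\n", x$prescription_dose))
  invisible(x)
}

dwell_positions <- function(plan) {
  as.matrix(plan$dwells[, c("x", "y", "z")])
}

#' Export the parsed dwell table as CSV
#'
#' Writes one row per dwell: catheter id, x/y/z (mm) and dwell time (s).
#'
#' @param plan A [plan_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dwell_csv <- function(plan, path) {
  utils::write.csv(
    plan$dwells[, c("catheter_id", "x", "y", "z", "time")],
    path, row.names = FALSE)
  invisible(path)
}

# run code with a deterministic RNG state, restoring the caller's state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
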