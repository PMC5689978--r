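# Dose-grid comparison computations: percentage-difference maps and
# histograms, TG43 parameter extraction (radial dose function and 2D
# anisotropy function via the line-source approximation), cumulative DVHs
# from contours, and morphological skin derivation.

#' Trilinear sampling of a dose grid
#'
#' @param grid A [dose_grid()].
#' @param pts Nx3 matrix of sample points (mm, patient frame). Points outside
#'   the grid clamp to the boundary voxel centers.
#' @return Numeric vector of interpolated values.
#' @export
trilinear_sample <- function(grid, pts) {
  d <- dim(grid$values)
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2]
  fz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3]
  fx <- pmin(pmax(fx, 0), d[1] - 1)
  fy <- pmin(pmax(fy, 0), d[2] - 1)
  fz <- pmin(pmax(fz, 0), d[3] - 1)
  i0 <- pmin(floor(fx), d[1] - 2); j0 <- pmin(floor(fy), d[2] - 2)
  k0 <- pmin(floor(fz), d[3] - 2)
  if (d[1] < 2) i0 <- rep(0, length(fx))
  if (d[2] < 2) j0 <- rep(0, length(fy))
  if (d[3] < 2) k0 <- rep(0, length(fz))
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  v <- grid$values
  at <- function(di, dj, dk)
    v[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  (1 - wx) * (1 - wy) * (1 - wz) * at(0, 0, 0) +
    wx * (1 - wy) * (1 - wz) * at(1, 0, 0) +
    (1 - wx) * wy * (1 - wz) * at(0, 1, 0) +
    wx * wy * (1 - wz) * at(1, 1, 0) +
    (1 - wx) * (1 - wy) * wz * at(0, 0, 1) +
    wx * (1 - wy) * wz * at(1, 0, 1) +
    (1 - wx) * wy * wz * at(0, 1, 1) +
    wx * wy * wz * at(1, 1, 1)
}

#' Percentage dose-difference map
#'
#' `diff = 100 * (test - ref) / ref` on compared voxels. The mask excludes
#' reference-zero voxels and, when supplied, voxels outside the body contour
#' mask or with density below the air threshold. If the two grids are not
#' congruent the test grid is resampled onto the reference grid by trilinear
#' interpolation.
#'
#' @param test,ref [dose_grid()] objects.
#' @param body_mask Optional logical array congruent with `ref`.
#' @param density Optional density array (g/cm3) congruent with `ref`.
#' @param air_threshold Densities below this (g/cm3) are excluded.
#' @return An object of class `comparison_map`: `diff` (%, NA off-mask),
#'   `mask`, and `summary` (min, max, fraction within +/-2%).
#' @export
diff_map <- function(test, ref, body_mask = NULL, density = NULL,
                     air_threshold = 0.05) {
  congruent <- identical(dim(test$values), dim(ref$values)) &&
    max(abs(test$origin - ref$origin)) < 1e-6 &&
    max(abs(test$spacing - ref$spacing)) < 1e-6
  tvals <- if (congruent) ref_test_vals <- test$values else {
    d <- dim(ref$values)
    pts <- cbind(
      rep(ct_axis_grid(ref, 1), times = d[2] * d[3]),
      rep(rep(ct_axis_grid(ref, 2), each = d[1]), times = d[3]),
      rep(ct_axis_grid(ref, 3), each = d[1] * d[2]))
    array(trilinear_sample(test, pts), dim = d)
  }
  mask <- ref$values > 0
  if (!is.null(body_mask)) mask <- mask & body_mask
  if (!is.null(density)) mask <- mask & (density >= air_threshold)
  diff <- array(NA_real_, dim = dim(ref$values))
  diff[mask] <- 100 * (tvals[mask] - ref$values[mask]) / ref$values[mask]
  dm <- diff[mask]
  structure(list(
    diff = diff, mask = mask,
    summary = c(min = if (length(dm)) min(dm) else NA_real_,
                max = if (length(dm)) max(dm) else NA_real_,
                frac_within_2pct = if (length(dm)) mean(abs(dm) <= 2)
                                   else NA_real_)),
    class = "comparison_map")
}

ct_axis_grid <- function(g, i) grid_axis(g$origin, g$spacing, dim(g$values)[i], i)

#' @export
print.comparison_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<comparison_map> %d voxels compared; diff in [%.2f, %.2f]%%; %.1f%% within +/-2%%\n",
    sum(x$mask), s["min"], s["max"], 100 * s["frac_within_2pct"]))
  invisible(x)
}

#' Frequency histogram of percentage dose differences
#'
#' @param cmap A [diff_map()] result.
#' @param bin_width Bin width in percent.
#' @return Data frame `mid` (bin center, %) and `count`; counts sum to the
#'   mask size.
#' @export
diff_histogram <- function(cmap, bin_width = 1) {
  dm <- cmap$diff[cmap$mask]
  lo <- floor(min(dm) / bin_width) * bin_width
  hi <- ceiling(max(dm) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(dm, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  data.frame(mid = h$mids, count = h$counts)
}

# local-frame coordinates (mm) of all voxel centers of a grid
grid_local_coords <- function(grid, pose) {
  d <- dim(grid$values)
  px <- rep(ct_axis_grid(grid, 1), times = d[2] * d[3]) - pose$translation[1]
  py <- rep(rep(ct_axis_grid(grid, 2), each = d[1]), times = d[3]) -
    pose$translation[2]
  pz <- rep(ct_axis_grid(grid, 3), each = d[1] * d[2]) - pose$translation[3]
  R <- pose$rotation
  list(x = R[1, 1] * px + R[2, 1] * py + R[3, 1] * pz,
       y = R[1, 2] * px + R[2, 2] * py + R[3, 2] * pz,
       z = R[1, 3] * px + R[2, 3] * py + R[3, 3] * pz)
}

#' Extract the radial dose function from a dose grid
#'
#' `g_L(r) = [D(r,90)/D(1,90)] * [G_L(1,90)/G_L(r,90)]` using the line-source
#' approximation. The default `"gcorr"` method takes voxel centers within a
#' narrow cone about the transverse plane, divides the exact geometry factor
#' out of each grid value (grid values are exact at voxel centers, so the
#' steep inverse-square behaviour never passes through an interpolant), and
#' interpolates the smooth residual versus radius; `"trilinear"` samples the
#' dose by trilinear interpolation at transverse-plane points averaged over
#' the two opposite transverse directions.
#'
#' @param dose A [dose_grid()].
#' @param pose Source pose (list `rotation`, `translation`) in the grid frame.
#' @param L Active length in cm.
#' @param r_values Radii in cm at which to report g.
#' @param method `"gcorr"` (default) or `"trilinear"`.
#' @param theta_tol Cone half-width about the transverse plane in degrees
#'   (gcorr method).
#' @return Data frame `r_cm`, `g` with `g(1 cm) = 1` exactly.
#' @export
extract_g <- function(dose, pose, L, r_values, method = c("gcorr", "trilinear"),
                      theta_tol = 5) {
  method <- match.arg(method)
  if (method == "trilinear") {
    R <- pose$rotation
    xax <- R[, 1]
    sample_dir <- function(sgn) {
      pts <- sweep(outer(r_values * 10 * sgn, xax), 2, pose$translation, "+")
      trilinear_sample(dose, pts)
    }
    D <- (sample_dir(1) + sample_dir(-1)) / 2
    D1 <- (trilinear_sample(dose, matrix(pose$translation + 10 * xax, 1)) +
           trilinear_sample(dose, matrix(pose$translation - 10 * xax, 1))) / 2
    G <- geometry_factor(r_values, 90, L)
    G1 <- geometry_factor(1, 90, L)
    return(data.frame(r_cm = r_values, g = (D / D1) * (G1 / G)))
  }
  lc <- grid_local_coords(dose, pose)
  r_cm <- sqrt(lc$x^2 + lc$y^2 + lc$z^2) / 10
  cosv <- abs(lc$z / 10) / pmax(r_cm, 1e-12)
  sel <- which(cosv <= sin(theta_tol * pi / 180) &
                 r_cm >= max(min(c(r_values, 1)) - 0.1, L) &
                 r_cm <= max(c(r_values, 1)) + 0.1)
  if (length(sel) < 10L) stop("too few transverse-plane samples for extraction")
  rs <- r_cm[sel]
  th <- acos(pmin(lc$z[sel] / 10 / rs, 1)) * 180 / pi
  psi <- as.vector(dose$values)[sel] / geometry_factor(rs, th, L)
  o <- order(rs)
  est <- stats::approx(rs[o], psi[o], xout = c(r_values, 1), ties = mean)$y
  n <- length(r_values)
  data.frame(r_cm = r_values, g = est[seq_len(n)] / est[n + 1L])
}

#' Extract the 2D anisotropy function from a dose grid
#'
#' `F(r,theta) = [D(r,theta)/D(r,90)] * [G_L(r,90)/G_L(r,theta)]`. The
#' default `"gcorr"` method pools all voxel centers in a thin spherical shell
#' at radius `r`, divides the exact geometry factor out of each, averages in
#' 1-degree polar bins and interpolates versus theta; `"trilinear"` samples
#' the dose at points of the local x-z plane (averaged over the two opposite
#' azimuths).
#'
#' @param dose A [dose_grid()].
#' @param pose Source pose in the grid frame.
#' @param L Active length in cm.
#' @param r Radius in cm.
#' @param theta_values Polar angles in degrees.
#' @param method `"gcorr"` (default) or `"trilinear"`.
#' @param shell_halfwidth Shell half-thickness in cm (default 0.6 * max
#'   spacing).
#' @return Data frame `theta_deg`, `F` with `F(90 deg) = 1` exactly.
#' @export
extract_F <- function(dose, pose, L, r, theta_values,
                      method = c("gcorr", "trilinear"),
                      shell_halfwidth = NULL) {
  method <- match.arg(method)
  if (method == "trilinear") {
    R <- pose$rotation
    xax <- R[, 1]; zax <- R[, 3]
    smp <- function(theta, sgn) {
      th <- theta * pi / 180
      pts <- sweep(10 * (outer(r * sin(th) * sgn, xax) +
                           outer(r * cos(th), zax)),
                   2, pose$translation, "+")
      trilinear_sample(dose, pts)
    }
    D <- (smp(theta_values, 1) + smp(theta_values, -1)) / 2
    D90 <- (smp(90, 1) + smp(90, -1)) / 2
    G <- geometry_factor(rep(r, length(theta_values)), theta_values, L)
    G90 <- geometry_factor(r, 90, L)
    return(data.frame(theta_deg = theta_values, F = (D / D90) * (G90 / G)))
  }
  if (is.null(shell_halfwidth)) shell_halfwidth <- 0.06 * max(dose$spacing)
  lc <- grid_local_coords(dose, pose)
  r_cm <- sqrt(lc$x^2 + lc$y^2 + lc$z^2) / 10
  sel <- which(abs(r_cm - r) <= shell_halfwidth)
  if (length(sel) < 10L) stop("too few shell samples for extraction")
  rs <- r_cm[sel]
  th <- acos(pmin(pmax(lc$z[sel] / 10 / rs, -1), 1)) * 180 / pi
  psi <- as.vector(dose$values)[sel] / geometry_factor(rs, th, L)
  bin <- round(th)
  agg_psi <- tapply(psi, bin, mean)
  agg_th <- tapply(th, bin, mean)
  o <- order(agg_th)
  est <- stats::approx(agg_th[o], agg_psi[o], xout = c(theta_values, 90),
                       rule = 2, ties = mean)$y
  n <- length(theta_values)
  data.frame(theta_deg = theta_values, F = est[seq_len(n)] / est[n + 1L])
}

# even-odd (crossing number) point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a structure onto a dose grid
#'
#' Voxel-center rasterization of the per-slice closed contours by the
#' even-odd rule; contours sharing a slice combine by exclusive-or (so a
#' contour inside another cuts a hole).
#'
#' @param dose A [dose_grid()] (supplies the voxel lattice).
#' @param structure A structure (list with `name`, `contours`).
#' @return Logical array congruent with `dose$values`.
#' @export
rasterize_structure <- function(dose, structure) {
  d <- dim(dose$values)
  az <- ct_axis_grid(dose, 3)
  ax <- ct_axis_grid(dose, 1); ay <- ct_axis_grid(dose, 2)
  mask <- array(FALSE, dim = d)
  for (cm in structure$contours) {
    z <- cm[1, 3]
    k <- which.min(abs(az - z))
    if (abs(az[k] - z) > dose$spacing[3] / 2 + 1e-9) next
    xi <- which(ax >= min(cm[, 1]) - 1e-9 & ax <= max(cm[, 1]) + 1e-9)
    yi <- which(ay >= min(cm[, 2]) - 1e-9 & ay <= max(cm[, 2]) + 1e-9)
    if (!length(xi) || !length(yi)) next
    px <- rep(ax[xi], times = length(yi))
    py <- rep(ay[yi], each = length(xi))
    ins <- point_in_polygon(px, py, cm[, 1], cm[, 2])
    sub <- matrix(ins, length(xi), length(yi))
    mask[xi, yi, k] <- xor(mask[xi, yi, k], sub)
  }
  mask
}

#' Cumulative dose-volume histogram of a structure
#'
#' @param dose A [dose_grid()].
#' @param structure A structure (list with `name`, `contours`) or a logical
#'   mask array congruent with the dose grid.
#' @param bin_width Dose bin width in Gy.
#' @return An object of class `dvh_curve`: `dose_bins` (Gy, bin lower
#'   edges), `cumulative_volume` (% of structure volume receiving at least
#'   that dose; starts at 100, non-increasing, ends at 0), `voxel_count` and
#'   `voxel_volume_mm3`.
#' @export
compute_dvh <- function(dose, structure, bin_width = 0.1) {
  mask <- if (is.array(structure)) structure
          else rasterize_structure(dose, structure)
  dvals <- dose$values[mask]
  n <- length(dvals)
  if (n == 0L) stop("structure rasterizes to zero voxels on the dose grid")
  edges <- seq(0, max(dvals) + bin_width, by = bin_width)
  counts_ge <- vapply(edges, function(e) sum(dvals >= e), numeric(1))
  structure(list(
    structure = if (is.array(structure)) "mask" else structure$name,
    dose_bins = edges,
    cumulative_volume = 100 * counts_ge / n,
    voxel_count = n,
    voxel_volume_mm3 = prod(dose$spacing)), class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %d voxels (%.1f cm3), D_max bin %.3g Gy\n",
              x$structure, x$voxel_count,
              x$voxel_count * x$voxel_volume_mm3 / 1000,
              max(x$dose_bins)))
  invisible(x)
}

#' Derive a skin mask from a body mask
#'
#' Morphological derivation: per axial slice, `skin = dilate(body) & !erode(body)`
#' with a single pass of a 3x3 cross structuring element (the difference of
#' one-pass dilation and erosion outcomes). Morphology is 2D per slice
#' because contours are per-slice planar.
#'
#' @param body_mask 3D logical array.
#' @return 3D logical skin mask.
#' @export
derive_skin <- function(body_mask) {
  kern <- EBImage::makeBrush(3, shape = "diamond")
  out <- array(FALSE, dim = dim(body_mask))
  for (k in seq_len(dim(body_mask)[3])) {
    sl <- body_mask[, , k] * 1
    if (!any(sl > 0)) next
    dil <- EBImage::dilate(sl, kern) > 0.5
    ero <- EBImage::erode(sl, kern) > 0.5
    out[, , k] <- dil & !ero
  }
  out
}

#' Export a difference-map slice as PNG
#'
#' Static color-map export of one axial slice of a comparison map, with zero
#' marked; a lightweight replacement for interactive viewing.
#'
#' @param cmap A [diff_map()] result.
#' @param k Slice index.
#' @param path Output PNG path.
#' @param zlim Color scale limits in percent.
#' @return `path`, invisibly.
#' @export
export_diff_png <- function(cmap, k, path, zlim = c(-10, 10)) {
  sl <- cmap$diff[, , k]
  sl[is.na(sl)] <- 0
  sl <- pmin(pmax(sl, zlim[1]), zlim[2])
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  cols <- grDevices::hcl.colors(64, "Blue-Red 2")
  graphics::image(sl, zlim = zlim, col = cols, useRaster = TRUE,
                  main = sprintf("dose difference (%%), slice %d", k))
  invisible(path)
}
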