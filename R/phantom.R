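# Synthetic phantom and plan generators. These emulate the fixtures used to
# commission the pipeline: a binary water sphere in air rendered as a CT
# series, a single-dwell plan at its center, a synthetic multicatheter breast
# implant, and the "TG43 conditions" modification of a CT volume. Everything
# is deterministic under a fixed seed.

#' Generate a water-sphere-in-air CT volume
#'
#' A mathematical binary phantom: voxels whose centers lie within `radius` of
#' the volume center get `hu_inside` (water, 0 HU), all others `hu_outside`
#' (air, -1000 HU). Inside/outside is decided at voxel centers; there is no
#' partial-volume blending.
#'
#' @param radius Sphere radius in mm.
#' @param fov In-plane field of view in mm.
#' @param matrix In-plane matrix size (pixels per side).
#' @param slice_thickness Slice thickness in mm.
#' @param n_slices Number of slices (default covers the sphere plus a 1 cm
#'   margin).
#' @param hu_inside,hu_outside HU assigned inside/outside the sphere.
#' @return A [ct_volume()] centered on (0, 0, 0) mm.
#' @export
make_water_sphere_ct <- function(radius = 150, fov = 340, matrix = 256,
                                 slice_thickness = 1, n_slices = 320,
                                 hu_inside = 0L, hu_outside = -1000L) {
  px <- fov / matrix
  dims <- c(matrix, matrix, n_slices)
  spacing <- c(px, px, slice_thickness)
  if (radius > fov / 2 || 2 * radius > n_slices * slice_thickness)
    stop("sphere does not fit inside the volume")
  origin <- -(dims - 1) / 2 * spacing
  ax <- grid_axis(origin, spacing, dims[1], 1)
  ay <- grid_axis(origin, spacing, dims[2], 2)
  az <- grid_axis(origin, spacing, dims[3], 3)
  d2 <- outer(outer(ax^2, ay^2, "+"), az^2, "+")
  hu <- array(as.integer(hu_outside), dim = dims)
  hu[d2 <= radius^2] <- as.integer(hu_inside)
  ct_volume(hu, origin, spacing)
}

#' Single-dwell plan at a given position
#'
#' One straight catheter along +z through `center` with control points at
#' `center` +/- k * 5 mm (k = 1..3), ordered tip (largest z) first, and a
#' single dwell at `center`.
#'
#' @param center Dwell position (mm, length 3).
#' @param time Dwell time in seconds.
#' @param source_id Source model identifier.
#' @param prescription Prescription dose in Gy (optional).
#' @return A [plan_model()].
#' @export
make_single_dwell_plan <- function(center = c(0, 0, 0), time = 10,
                                   source_id = "mHDR-v2",
                                   prescription = NA_real_) {
  offs <- c(15, 10, 5, -5, -10, -15)
  cp <- cbind(center[1], center[2], center[3] + offs)
  dwells <- data.frame(catheter_id = 1L, x = center[1], y = center[2],
                       z = center[3], time = time, index = 1L)
  plan_model(source_id, list(list(id = 1L, control_points = cp)),
             dwells, prescription)
}

#' Synthetic multicatheter plan
#'
#' Parallel (or slightly fanned) catheters along +z arranged on a regular
#' in-plane grid, each carrying regularly spaced dwells. Emulates a
#' multicatheter breast implant at the geometry level; times are either
#' uniform or drawn reproducibly from the seed.
#'
#' @param n_catheters Number of catheters.
#' @param dwells_per_catheter Dwells per catheter.
#' @param spacing Dwell spacing along each catheter in mm.
#' @param time_profile `"uniform"` (10 s each) or `"random"` (uniform 5-15 s).
#' @param prescription Prescription dose in Gy (default 32).
#' @param seed Integer seed; identical seeds give identical plans.
#' @param pitch In-plane catheter spacing in mm.
#' @param center Implant center (mm).
#' @param arrangement `"parallel"` or `"fanned"` (outward tilt up to ~6 deg).
#' @param source_id Source model identifier.
#' @return A [plan_model()].
#' @export
make_multicatheter_plan <- function(n_catheters = 6, dwells_per_catheter = 10,
                                    spacing = 5, time_profile = "uniform",
                                    prescription = 32, seed = 1L,
                                    pitch = 15, center = c(0, 0, 0),
                                    arrangement = "parallel",
                                    source_id = "mHDR-v2") {
  arrangement <- match.arg(arrangement, c("parallel", "fanned"))
  time_profile <- match.arg(time_profile, c("uniform", "random"))
  ncol_grid <- ceiling(sqrt(n_catheters))
  ix <- (seq_len(n_catheters) - 1) %% ncol_grid
  iy <- (seq_len(n_catheters) - 1) %/% ncol_grid
  cx <- center[1] + (ix - mean(ix)) * pitch
  cy <- center[2] + (iy - mean(iy)) * pitch
  span <- (dwells_per_catheter - 1) * spacing
  times <- with_seed(seed, {
    if (time_profile == "uniform") rep(10, n_catheters * dwells_per_catheter)
    else stats::runif(n_catheters * dwells_per_catheter, 5, 15)
  })
  catheters <- list(); dwl <- list()
  for (k in seq_len(n_catheters)) {
    base <- c(cx[k], cy[k], center[3] - span / 2)
    dir <- c(0, 0, 1)
    if (arrangement == "fanned") {
      radial <- c(cx[k] - center[1], cy[k] - center[2], 0)
      nr <- sqrt(sum(radial^2))
      if (nr > 0) dir <- dir + 0.1 * radial / nr
      dir <- dir / sqrt(sum(dir^2))
    }
    # dwell centers along the catheter direction
    s_dw <- (seq_len(dwells_per_catheter) - 1) * spacing
    pts_dw <- sweep(outer(s_dw, dir), 2, base, "+")
    # path control points: tip first, extending 10 mm beyond each end
    s_cp <- seq(span + 10, -10, by = -10)
    cp <- sweep(outer(s_cp, dir), 2, base, "+")
    catheters[[k]] <- list(id = k, control_points = cp)
    t_k <- times[((k - 1) * dwells_per_catheter + 1):(k * dwells_per_catheter)]
    dwl[[k]] <- data.frame(catheter_id = k, x = pts_dw[, 1], y = pts_dw[, 2],
                           z = pts_dw[, 3], time = t_k)
  }
  dwells <- do.call(rbind, dwl)
  dwells$index <- seq_len(nrow(dwells))
  plan_model(source_id, catheters, dwells, prescription)
}

#' Apply TG43 reference conditions to a CT volume
#'
#' Sets HU = 0 (water) for voxels within `radius` of the unweighted centroid
#' of the plan's dwell positions and HU = -1000 (air) everywhere else, so the
#' computational model resembles the unbounded-water assumptions of the TG43
#' formalism. The operation is idempotent.
#'
#' @param ct A [ct_volume()].
#' @param plan A [plan_model()] with at least one dwell.
#' @param radius Water sphere radius in mm (default 150).
#' @return A modified [ct_volume()] containing exactly two HU values.
#' @export
make_tg43_conditions <- function(ct, plan, radius = 150) {
  if (nrow(plan$dwells) < 1L) stop("plan has no dwells")
  centroid <- colMeans(dwell_positions(plan))
  d <- dim(ct$hu)
  dx2 <- (ct_axis(ct, 1) - centroid[1])^2
  dy2 <- (ct_axis(ct, 2) - centroid[2])^2
  dz2 <- (ct_axis(ct, 3) - centroid[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  hu <- array(-1000L, dim = d)
  hu[d2 <= radius^2] <- 0L
  ct_volume(hu, ct$origin, ct$spacing, ct$orientation, ct$rescale)
}

circle_contour <- function(cx, cy, z, r, n = 96) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(a), cy + r * sin(a), z)
}

#' Derive BODY and PTV structures for a phantom study
#'
#' BODY is the phantom surface: the non-air mask is reduced to an equivalent
#' sphere (radius from the mask volume, center from its centroid) and contoured
#' analytically per slice. PTV is the union of dwell-centered spheres of
#' radius `ptv_margin`, contoured analytically for a single dwell and by
#' boundary tracing of the rasterized union otherwise.
#'
#' @param ct A [ct_volume()].
#' @param plan A [plan_model()].
#' @param ptv_margin PTV sphere radius around each dwell in mm.
#' @param body_threshold HU above which a voxel counts as body.
#' @param n_vertices Vertices per analytic contour.
#' @return A [structure_set()] with structures `BODY` and `PTV`.
#' @export
make_structures <- function(ct, plan, ptv_margin = 10, body_threshold = -400,
                            n_vertices = 96) {
  voxvol <- prod(ct$spacing)
  mask <- ct$hu > body_threshold
  nvox <- sum(mask)
  if (nvox == 0) stop("no body voxels above threshold")
  R <- (3 * nvox * voxvol / (4 * pi))^(1 / 3)
  ax <- ct_axis(ct, 1); ay <- ct_axis(ct, 2); az <- ct_axis(ct, 3)
  idx <- which(mask, arr.ind = TRUE)
  cen <- c(mean(ax[idx[, 1]]), mean(ay[idx[, 2]]), mean(az[idx[, 3]]))
  body_contours <- list()
  for (k in seq_along(az)) {
    h2 <- R^2 - (az[k] - cen[3])^2
    if (h2 <= (min(ct$spacing[1:2]) / 2)^2) next
    body_contours[[length(body_contours) + 1L]] <-
      circle_contour(cen[1], cen[2], az[k], sqrt(h2), n_vertices)
  }
  dw <- dwell_positions(plan)
  ptv_contours <- list()
  if (nrow(dw) == 1L) {
    for (k in seq_along(az)) {
      h2 <- ptv_margin^2 - (az[k] - dw[1, 3])^2
      if (h2 <= (min(ct$spacing[1:2]) / 2)^2) next
      ptv_contours[[length(ptv_contours) + 1L]] <-
        circle_contour(dw[1, 1], dw[1, 2], az[k], sqrt(h2), n_vertices)
    }
  } else {
    for (k in seq_along(az)) {
      dz2 <- (az[k] - dw[, 3])^2
      active <- which(dz2 < ptv_margin^2)
      if (length(active) == 0) next
      m <- matrix(FALSE, length(ax), length(ay))
      for (i in active) {
        r2 <- ptv_margin^2 - dz2[i]
        m <- m | (outer((ax - dw[i, 1])^2, (ay - dw[i, 2])^2, "+") <= r2)
      }
      polys <- mask_to_polygons(m, ax, ay)
      for (p in polys)
        ptv_contours[[length(ptv_contours) + 1L]] <- cbind(p, az[k])
    }
  }
  structure_set(list(
    list(name = "BODY", color = c(0L, 255L, 0L), contours = body_contours),
    list(name = "PTV", color = c(255L, 0L, 0L), contours = ptv_contours)
  ))
}

# trace object boundaries of a 2D mask; returns list of Nx2 matrices in mm
mask_to_polygons <- function(m, ax, ay) {
  lab <- EBImage::bwlabel(m * 1)
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(px) {
    # ocontour coordinates are 0-based pixel indices
    cbind(ax[px[, 1] + 1L], ay[px[, 2] + 1L])
  })
}
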