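# Dwell-position kinematics and phase-space source handling.
#
# The RT Plan stores only the source center at each planned position; the
# source orientation is reconstructed from the two catheter control points
# closest to the dwell. The source long axis (local +z) points tip-ward, i.e.
# along the unit vector from the higher-index to the lower-index of the two
# nearest control points (control points are ordered tip first). Rotation
# about the source axis is physically unconstrained (the source is
# axisymmetric), so the minimal rotation taking +z onto the axis is used.

#' Rigid transform placing the source at a dwell position
#'
#' @param dwell One row of a plan's dwell table (list/data.frame row with
#'   `x`, `y`, `z`).
#' @param cath Catheter (list with `control_points`, tip first).
#' @return List with `rotation` (3x3, orthonormal, det +1) and `translation`
#'   (mm); `rotation` maps local +z onto the tip-ward catheter direction.
#' @export
dwell_transform <- function(dwell, cath) {
  cp <- cath$control_points
  if (nrow(cp) < 2L) stop("catheter needs at least 2 control points")
  center <- c(dwell$x, dwell$y, dwell$z)
  d2 <- rowSums(sweep(cp, 2, center)^2)
  ord <- order(d2)
  i1 <- ord[1]; i2 <- ord[2]
  lo <- min(i1, i2); hi <- max(i1, i2)
  axis_vec <- cp[lo, ] - cp[hi, ]   # higher index -> lower index = tip-ward
  nv <- sqrt(sum(axis_vec^2))
  if (nv < 1e-9) stop("two nearest control points coincide")
  axis_vec <- axis_vec / nv
  list(rotation = rotation_z_to(axis_vec), translation = center)
}

# minimal rotation taking (0,0,1) onto unit vector d (Rodrigues, axis z x d)
rotation_z_to <- function(d) {
  z <- c(0, 0, 1)
  c_ <- sum(z * d)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about x
    return(diag(c(1, -1, -1)))
  }
  v <- c(z[2] * d[3] - z[3] * d[2],
         z[3] * d[1] - z[1] * d[3],
         z[1] * d[2] - z[2] * d[1])
  s <- sqrt(sum(v^2))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Per-dwell transforms for a whole plan
#'
#' @param plan A [plan_model()].
#' @return List of transforms (one per dwell, in dwell order).
#' @export
plan_transforms <- function(plan) {
  caths <- stats::setNames(plan$catheters,
                           vapply(plan$catheters, function(ca) as.character(ca$id),
                                  character(1)))
  lapply(seq_len(nrow(plan$dwells)), function(i) {
    dw <- plan$dwells[i, ]
    dwell_transform(dw, caths[[as.character(dw$catheter_id)]])
  })
}

#' Dwell sampling distribution
#'
#' Per-dwell probabilities proportional to dwell time (the fraction of each
#' dwell time to the total irradiation time), with the cumulative
#' distribution used to pick the transform applied to each phase-space photon.
#'
#' @param dwells Dwell table (data frame with a `time` column, seconds).
#' @return List with `p` (probabilities, sum 1) and `cdf`.
#' @export
sampling_table <- function(dwells) {
  t <- dwells$time
  total <- sum(t)
  if (total <= 0) stop("all dwell times are zero")
  p <- t / total
  list(p = p, cdf = cumsum(p))
}

#' Write the per-dwell transform/probability table as CSV
#'
#' Columns: dwell index, the 9 rotation entries (row-major `r11..r33`), the
#' translation (mm) and the sampling probability.
#'
#' @param transforms List of transforms from [plan_transforms()].
#' @param sampling A [sampling_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transform_csv <- function(transforms, sampling, path) {
  rows <- lapply(seq_along(transforms), function(i) {
    tr <- transforms[[i]]
    r <- t(tr$rotation)  # row-major flatten
    data.frame(dwell = i,
               r11 = r[1, 1], r12 = r[2, 1], r13 = r[3, 1],
               r21 = r[1, 2], r22 = r[2, 2], r23 = r[3, 2],
               r31 = r[1, 3], r32 = r[2, 3], r33 = r[3, 3],
               tx = tr$translation[1], ty = tr$translation[2],
               tz = tr$translation[3], p = sampling$p[i])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Phase-space container
#'
#' @param source_id Source identifier.
#' @param energy Photon energies in MeV, in (0, 1.4].
#' @param position Nx3 matrix, mm, source-local frame.
#' @param direction Nx3 matrix of unit vectors.
#' @param n_emitted Initially emitted photon count (>= record count).
#' @return An object of class `phase_space`.
#' @export
phase_space <- function(source_id, energy, position, direction, n_emitted) {
  ps <- structure(list(source_id = source_id, energy = energy,
                       position = position, direction = direction,
                       n_records = length(energy),
                       n_emitted = as.numeric(n_emitted)),
                  class = "phase_space")
  validate_phase_space(ps)
  ps
}

validate_phase_space <- function(ps) {
  if (any(ps$energy <= 0 | ps$energy > 1.4))
    stop("phase_space: energies must lie in (0, 1.4] MeV")
  nrm <- sqrt(rowSums(ps$direction^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("phase_space: directions must be unit vectors")
  if (ps$n_records > ps$n_emitted)
    stop("phase_space: more records than emitted photons")
  invisible(ps)
}

#' @export
print.phase_space <- function(x, ...) {
  cat(sprintf("<phase_space> %s: %d records of %g emitted\n",
              x$source_id, x$n_records, x$n_emitted))
  invisible(x)
}

#' Write a phase-space file
#'
#' Format: one text header line `PHSP1 <source_id> <n_records> <n_emitted>`
#' followed by binary little-endian float32 septets `(E, x, y, z, u, v, w)`
#' per record. The round trip is bit exact (values are stored as float32 on
#' both sides).
#'
#' @param ps A [phase_space()].
#' @param path Output `.phsp` path.
#' @return `path`, invisibly.
#' @export
write_phase_space <- function(ps, path) {
  validate_phase_space(ps)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- sprintf("PHSP1 %s %d %.0f\n", ps$source_id, ps$n_records, ps$n_emitted)
  writeBin(charToRaw(hdr), con)
  rec <- rbind(ps$energy, t(ps$position), t(ps$direction))
  writeBin(as.numeric(rec), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a phase-space file
#'
#' @param path `.phsp` file path.
#' @return A [phase_space()].
#' @export
read_phase_space <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readBin(con, "raw", 1)
    if (length(ch) == 0) stop("truncated phase-space file: no header")
    if (ch == charToRaw("\n")) break
    hdr <- c(hdr, rawToChar(ch))
  }
  parts <- strsplit(paste(hdr, collapse = ""), " +")[[1]]
  if (length(parts) != 4 || parts[1] != "PHSP1")
    stop("not a PHSP1 phase-space file")
  n <- as.integer(parts[3])
  n_emitted <- as.numeric(parts[4])
  dat <- readBin(con, numeric(), n = 7 * n + 7, size = 4, endian = "little")
  if (length(dat) != 7 * n)
    stop(sprintf(
      "truncated phase-space file: expected %d records (%d floats), found %d floats",
      n, 7 * n, length(dat)))
  m <- matrix(dat, nrow = 7)
  # re-store as float32 so equality with the written values is exact
  phase_space(parts[2], m[1, ], t(m[2:4, , drop = FALSE]),
              t(m[5:7, , drop = FALSE]), n_emitted)
}

#' Toy phase-space generator
#'
#' Emits photons from the lateral-plus-cap surface of a source-sized cylinder
#' (area-weighted), with isotropic directions and energies drawn from the
#' shipped Ir-192 line spectrum. A stand-in for precalculated source-specific
#' phase-space files; it carries no self-absorption or anisotropy.
#'
#' @param source_id Source identifier.
#' @param n_emitted Number of photons to emit (= number of records here).
#' @param seed Integer seed; output is reproducible.
#' @param diameter,length Active cylinder dimensions in mm.
#' @param spectrum Data frame `energy_mev`, `intensity`; default the shipped
#'   Ir-192 line table.
#' @return A [phase_space()].
#' @export
toy_phase_space <- function(source_id = "mHDR-v2", n_emitted = 1e4, seed = 1L,
                            diameter = 0.9, length = 3.6, spectrum = NULL) {
  if (is.null(spectrum))
    spectrum <- utils::read.csv(extdata("ir192_spectrum.csv"))
  n <- as.integer(n_emitted)
  with_seed(seed, {
    # energies: discrete line spectrum; store as float32-exact values
    p <- spectrum$intensity / sum(spectrum$intensity)
    energy <- sample(spectrum$energy_mev, n, replace = TRUE, prob = p)
    # surface sampling, area weighted between lateral surface and two caps
    rad <- diameter / 2
    a_lat <- 2 * pi * rad * length
    a_cap <- pi * rad^2
    u <- stats::runif(n)
    on_lat <- u < a_lat / (a_lat + 2 * a_cap)
    phi <- stats::runif(n, 0, 2 * pi)
    pos <- matrix(0, n, 3)
    zl <- stats::runif(n, -length / 2, length / 2)
    pos[on_lat, ] <- cbind(rad * cos(phi[on_lat]), rad * sin(phi[on_lat]),
                           zl[on_lat])
    ncap <- sum(!on_lat)
    if (ncap > 0) {
      rr <- rad * sqrt(stats::runif(ncap))
      zc <- ifelse(stats::runif(ncap) < 0.5, -length / 2, length / 2)
      pos[!on_lat, ] <- cbind(rr * cos(phi[!on_lat]), rr * sin(phi[!on_lat]), zc)
    }
    ct <- stats::runif(n, -1, 1)
    ph2 <- stats::runif(n, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    dir <- cbind(st * cos(ph2), st * sin(ph2), ct)
    f32 <- function(x) readBin(writeBin(as.numeric(x), raw(), size = 4,
                                        endian = "little"),
                               numeric(), n = base::length(x), size = 4,
                               endian = "little")
    # float32 storage perturbs unit norms by ~1e-7, within the container's
    # tolerance; no renormalization so the file round trip stays bit exact
    dirn <- matrix(f32(dir), n, 3)
    phase_space(source_id, f32(energy), matrix(f32(pos), n, 3), dirn, n)
  })
}

#' Apply a rigid transform to phase-space records
#'
#' Positions map to `R p + t`, directions to `R d`; energies are unchanged.
#'
#' @param rec List with `energy`, `position` (Nx3), `direction` (Nx3), or a
#'   [phase_space()].
#' @param transform List with `rotation`, `translation`.
#' @return The transformed records (same shape as the input list).
#' @export
transform_record <- function(rec, transform) {
  R <- transform$rotation
  tr <- transform$translation
  pos <- t(R %*% t(rec$position) + tr)
  dir <- t(R %*% t(rec$direction))
  out <- rec
  out$position <- pos
  out$direction <- dir
  out
}
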