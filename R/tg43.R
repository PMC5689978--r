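# TG43 line-source dose engine. Dose rate around a cylindrically symmetric
# source in water is
#   Ddot(r, theta) = Sk * Lambda * G_L(r,theta)/G_L(r0,theta0) * g_L(r) * F(r,theta)
# with r in cm from the source center, theta measured from the source long
# axis (+z, tip side; theta = 180 deg is the cable side), r0 = 1 cm and
# theta0 = 90 deg. The engine renders reference RT Dose grids (the in-repo
# stand-in for a TPS TG43 export) and supplies the geometry factor used by
# the benchmark extraction.

#' Line-source geometry factor
#'
#' `G_L(r, theta) = beta / (L r sin(theta))` with `beta` the angle subtended
#' by the active line at the point, computed in the numerically stable
#' two-angle arctangent difference form. On the long axis
#' (`sin(theta) < 1e-6`) the closed form `1 / (r^2 - L^2/4)` is used; `L = 0`
#' gives the point-source limit `1/r^2`.
#'
#' @param r Radial distance in cm (> 0), vectorized.
#' @param theta Polar angle in degrees, vectorized.
#' @param L Active length in cm.
#' @return Geometry factor in cm^-2.
#' @export
geometry_factor <- function(r, theta, L) {
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r <= 0)) stop("geometry_factor: r must be > 0")
  if (L == 0) return(1 / r^2)
  th <- theta * pi / 180
  x <- r * sin(th)       # perpendicular distance to the source axis
  z <- r * cos(th)
  on_axis <- abs(sin(th)) < 1e-6
  out <- numeric(n)
  if (any(on_axis)) {
    ra <- r[on_axis]
    if (any(ra <= L / 2))
      stop("geometry_factor: point on the long axis inside the source (r <= L/2)")
    out[on_axis] <- 1 / (ra^2 - L^2 / 4)
  }
  off <- !on_axis
  if (any(off)) {
    beta <- atan2(z[off] + L / 2, x[off]) - atan2(z[off] - L / 2, x[off])
    out[off] <- beta / (L * x[off])
  }
  out
}

#' TG43 source data container
#'
#' @param Lambda Dose-rate constant in cGy h^-1 U^-1.
#' @param L Active length in cm.
#' @param Sk Air-kerma strength in U.
#' @param g_table Data frame `r_cm`, `g` with `g(1 cm) = 1`.
#' @param F_table List with `theta_deg` (vector), `r_cm` (vector) and `F`
#'   (matrix, theta x r) with `F(r, 90 deg) = 1`.
#' @return An object of class `tg43_source_data`.
#' @export
tg43_source_data <- function(Lambda = 1.109, L = 0.36, Sk = 40800,
                             g_table = NULL, F_table = NULL) {
  if (is.null(g_table))
    g_table <- utils::read.csv(extdata("tg43_g_synthetic.csv"))
  if (is.null(F_table)) F_table <- read_f_table(extdata("tg43_F_synthetic.csv"))
  if (any(diff(g_table$r_cm) <= 0))
    stop("g table radii must be strictly increasing")
  i0 <- which(g_table$r_cm == 1)
  if (length(i0) != 1 || abs(g_table$g[i0] - 1) > 1e-9)
    stop("g table must contain g(1 cm) = 1")
  j0 <- which(F_table$theta_deg == 90)
  if (length(j0) != 1 || any(abs(F_table$F[j0, ] - 1) > 1e-9))
    stop("F table must have F(r, 90 deg) = 1 for all tabulated r")
  structure(list(Lambda = Lambda, L = L, Sk = Sk,
                 g_table = g_table, F_table = F_table,
                 r0 = 1, theta0 = 90),
            class = "tg43_source_data")
}

read_f_table <- function(path) {
  df <- utils::read.csv(path)
  r_cm <- as.numeric(sub("^r", "", names(df)[-1]))
  list(theta_deg = df$theta_deg, r_cm = r_cm,
       F = as.matrix(df[, -1, drop = FALSE]))
}

# g_L(r) by log-linear interpolation in r, clamped outside the table
interp_g <- function(r, data, warn = TRUE) {
  tb <- data$g_table
  if (warn && (any(r < min(tb$r_cm)) || any(r > max(tb$r_cm))))
    warning("g_L(r) extrapolation clamped to table range")
  stats::approx(log(tb$r_cm), tb$g, xout = log(pmax(r, 1e-12)),
                rule = 2, ties = "ordered")$y
}

# F(r, theta) by bilinear interpolation, clamped outside the table
interp_F <- function(r, theta, data, warn = TRUE) {
  ft <- data$F_table
  if (warn && (any(r < min(ft$r_cm)) || any(r > max(ft$r_cm)) ||
               any(theta < min(ft$theta_deg)) ||
               any(theta > max(ft$theta_deg))))
    warning("F(r, theta) extrapolation clamped to table range")
  rv <- pmin(pmax(r, min(ft$r_cm)), max(ft$r_cm))
  tv <- pmin(pmax(theta, min(ft$theta_deg)), max(ft$theta_deg))
  i <- findInterval(tv, ft$theta_deg, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(ft$theta_deg) - 1L)
  j <- findInterval(rv, ft$r_cm, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1L), length(ft$r_cm) - 1L)
  t1 <- ft$theta_deg[i]; t2 <- ft$theta_deg[i + 1L]
  r1 <- ft$r_cm[j]; r2 <- ft$r_cm[j + 1L]
  wt <- (tv - t1) / (t2 - t1)
  wr <- (rv - r1) / (r2 - r1)
  f11 <- ft$F[cbind(i, j)]; f21 <- ft$F[cbind(i + 1L, j)]
  f12 <- ft$F[cbind(i, j + 1L)]; f22 <- ft$F[cbind(i + 1L, j + 1L)]
  (1 - wt) * (1 - wr) * f11 + wt * (1 - wr) * f21 +
    (1 - wt) * wr * f12 + wt * wr * f22
}

#' TG43 dose rate at a point
#'
#' @param r Radial distance in cm, vectorized.
#' @param theta Polar angle in degrees, vectorized.
#' @param data A [tg43_source_data()].
#' @param warn Warn when g/F are clamped outside their tables.
#' @return Dose rate in cGy/h.
#' @export
dose_rate <- function(r, theta, data = tg43_source_data(), warn = TRUE) {
  G <- geometry_factor(r, theta, data$L)
  G0 <- geometry_factor(data$r0, data$theta0, data$L)
  data$Sk * data$Lambda * (G / G0) * interp_g(r, data, warn) *
    interp_F(r, theta, data, warn)
}

#' Render a dose grid from a plan with the TG43 engine
#'
#' Per-voxel dose is the sum over dwells of the TG43 dose rate at the voxel
#' center expressed in each dwell's source frame (via the dwell transforms),
#' times the dwell time; plan times are seconds and dose rate is per hour, so
#' a single 1/3600 conversion is applied. Radii are clamped to `r_min`
#' (voxels essentially inside the source, below the tabulated range).
#'
#' @param plan A [plan_model()].
#' @param data A [tg43_source_data()].
#' @param origin,spacing,dims Grid geometry (mm / voxel counts).
#' @param r_min Radius clamp in cm.
#' @return A [dose_grid()] in Gy.
#' @export
render_rtdose <- function(plan, data = tg43_source_data(),
                          origin = c(-100, -100, -100), spacing = c(1, 1, 1),
                          dims = c(201, 201, 201), r_min = 0.25) {
  transforms <- plan_transforms(plan)
  ax <- grid_axis(origin, spacing, dims[1], 1)
  ay <- grid_axis(origin, spacing, dims[2], 2)
  az <- grid_axis(origin, spacing, dims[3], 3)
  px <- rep(ax, times = dims[2] * dims[3])
  py <- rep(rep(ay, each = dims[1]), times = dims[3])
  pz <- rep(az, each = dims[1] * dims[2])
  dose <- numeric(prod(dims))
  for (i in seq_len(nrow(plan$dwells))) {
    tr <- transforms[[i]]
    t_i <- plan$dwells$time[i]
    if (t_i <= 0) next
    R <- tr$rotation; tl <- tr$translation
    lx <- R[1, 1] * (px - tl[1]) + R[2, 1] * (py - tl[2]) + R[3, 1] * (pz - tl[3])
    ly <- R[1, 2] * (px - tl[1]) + R[2, 2] * (py - tl[2]) + R[3, 2] * (pz - tl[3])
    lz <- R[1, 3] * (px - tl[1]) + R[2, 3] * (py - tl[2]) + R[3, 3] * (pz - tl[3])
    r_cm <- pmax(sqrt(lx^2 + ly^2 + lz^2) / 10, r_min)
    theta <- acos(pmin(pmax(lz / 10 / r_cm, -1), 1)) * 180 / pi
    dose <- dose + dose_rate(r_cm, theta, data, warn = FALSE) * t_i / 3600 / 100
  }
  dose_grid(array(dose, dim = dims), origin, spacing)
}
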