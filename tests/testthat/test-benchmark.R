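# Comparison maps, TG43 extraction, DVH, skin derivation.

test_that("difference maps satisfy the exact metric identities", {
  set.seed(4)
  ref <- dose_grid(array(runif(1000) + 0.5, c(10, 10, 10)), c(0, 0, 0),
                   c(1, 1, 1))
  same <- diff_map(ref, ref)
  expect_true(all(same$diff[same$mask] == 0))
  up <- dose_grid(ref$values * 1.02, ref$origin, ref$spacing)
  two <- diff_map(up, ref)
  expect_equal(unique(round(two$diff[two$mask], 10)), 2.0)
  # antisymmetry: swapping test/ref maps +x% to -100x/(100+x)%
  swapped <- diff_map(ref, up)
  expect_equal(swapped$diff[swapped$mask],
               rep(-100 * 2 / 102, sum(swapped$mask)), tolerance = 1e-9)
})

test_that("the mask excludes reference zeros, air and out-of-body voxels", {
  ct <- small_sphere_ct()
  vals <- array(1, dim(ct$hu))
  ref <- dose_grid(vals, ct$origin, ct$spacing)
  test <- dose_grid(vals * 1.01, ct$origin, ct$spacing)
  density <- hu_to_density(ct$hu)
  cm <- diff_map(test, ref, density = density)
  expect_equal(sum(cm$mask), sum(ct$hu == 0L))  # air excluded
  body <- ct$hu > -500
  body[, , 1:5] <- FALSE
  cm2 <- diff_map(test, ref, body_mask = body, density = density)
  expect_equal(sum(cm2$mask), sum(body & ct$hu == 0L))
})

test_that("difference histograms conserve counts and reflect symmetry", {
  set.seed(9)
  base <- array(1, c(8, 8, 8))
  pert <- runif(256, 0, 0.04)
  delta <- array(c(pert, -pert), c(8, 8, 8))
  ref <- dose_grid(base, c(0, 0, 0), c(1, 1, 1))
  test <- dose_grid(base * (1 + delta), c(0, 0, 0), c(1, 1, 1))
  cm <- diff_map(test, ref)
  h <- diff_histogram(cm, bin_width = 1)
  expect_equal(sum(h$count), sum(cm$mask))
  # mirrored field: counts symmetric about zero
  expect_equal(h$count, rev(h$count))
  # constant +2% map occupies a single bin
  h2 <- diff_histogram(diff_map(dose_grid(base * 1.02, c(0, 0, 0), c(1, 1, 1)),
                                ref), bin_width = 1)
  expect_equal(sum(h2$count > 0), 1)
})

test_that("extraction recovers flat g and F from a point-source render", {
  src <- flat_source(L = 0)
  plan <- make_single_dwell_plan(c(0, 0, 0))
  dose <- render_rtdose(plan, src, origin = c(-40, -40, -40),
                        dims = c(81, 81, 81))
  pose <- plan_transforms(plan)[[1]]
  g <- extract_g(dose, pose, L = 0, r_values = seq(0.5, 3, by = 0.25))
  expect_lt(max(abs(g$g - 1)), 0.005)
  expect_equal(g$g[g$r_cm == 1], 1)  # exact by construction
  Ft <- extract_F(dose, pose, L = 0, r = 2, theta_values = seq(10, 170, 10))
  expect_lt(max(abs(Ft$F - 1)), 0.01)
  F90 <- extract_F(dose, pose, L = 0, r = 2, theta_values = 90)
  expect_equal(F90$F, 1)
})

test_that("extraction round-trips the synthetic g and F tables", {
  src <- tg43_source_data()
  plan <- make_single_dwell_plan(c(0, 0, 0))
  dose <- render_rtdose(plan, src, origin = c(-40, -40, -40),
                        dims = c(81, 81, 81))
  pose <- plan_transforms(plan)[[1]]
  r_nodes <- src$g_table$r_cm[src$g_table$r_cm >= 0.5 & src$g_table$r_cm <= 3]
  g <- extract_g(dose, pose, L = src$L, r_values = r_nodes)
  g_true <- src$g_table$g[match(r_nodes, src$g_table$r_cm)]
  expect_lt(max(abs(g$g - g_true) / g_true), 0.005)
  th <- src$F_table$theta_deg[src$F_table$theta_deg >= 10 &
                                src$F_table$theta_deg <= 170]
  Ft <- extract_F(dose, pose, L = src$L, r = 2, theta_values = th)
  F_true <- src$F_table$F[match(th, src$F_table$theta_deg),
                          src$F_table$r_cm == 2]
  expect_lt(max(abs(Ft$F - F_true) / F_true), 0.01)
  # trilinear sampling agrees on the smooth transverse profile
  g_tri <- extract_g(dose, pose, L = src$L, r_values = c(1.5, 2, 2.5),
                     method = "trilinear")
  g_ref <- extract_g(dose, pose, L = src$L, r_values = c(1.5, 2, 2.5))
  expect_lt(max(abs(g_tri$g - g_ref$g)), 0.01)
})

test_that("DVH handles uniform dose and matches rasterization oracles", {
  ct <- small_sphere_ct(matrix = 40, n_slices = 40, slice = 1)
  ss <- make_structures(ct, make_single_dwell_plan(c(0, 0, 0)))
  body <- get_structure(ss, "BODY")
  dg <- dose_grid(array(5, dim(ct$hu)), ct$origin, ct$spacing)
  dvh <- compute_dvh(dg, body, bin_width = 0.5)
  expect_equal(dvh$cumulative_volume[1], 100)
  expect_true(all(diff(dvh$cumulative_volume) <= 0))
  expect_true(all(dvh$cumulative_volume[dvh$dose_bins <= 5] == 100))
  expect_true(all(dvh$cumulative_volume[dvh$dose_bins > 5] == 0))
  # voxel volume against the independent in-circle enumeration
  nv <- sum(ct$hu > -400)
  R <- (3 * nv * prod(ct$spacing) / (4 * pi))^(1 / 3)
  oracle <- brute_sphere_count(c(0, 0, 0), R, ct$origin, ct$spacing,
                               dim(ct$hu))
  expect_lt(abs(dvh$voxel_count - oracle) / oracle, 0.01)
})

test_that("rasterization agrees with an independent point-in-polygon test", {
  skip_if_not_installed("mgcv")
  ct <- small_sphere_ct(matrix = 24, n_slices = 10, radius = 8)
  ss <- make_structures(ct, make_single_dwell_plan(c(0, 0, 0)))
  cm <- get_structure(ss, "BODY")$contours[[5]]
  ax <- ct_axis(ct, 1); ay <- ct_axis(ct, 2)
  pts <- cbind(rep(ax, times = length(ay)), rep(ay, each = length(ax)))
  mine <- point_in_polygon(pts[, 1], pts[, 2], cm[, 1], cm[, 2])
  oracle <- mgcv::in.out(rbind(cm[, 1:2], cm[1, 1:2]), pts)
  expect_equal(mine, as.vector(oracle))
})

test_that("whole-grid DVH with fine bins reproduces the dose histogram", {
  set.seed(6)
  dg <- dose_grid(array(runif(512, 0, 10), c(8, 8, 8)), c(0, 0, 0),
                  c(1, 1, 1))
  mask <- array(TRUE, c(8, 8, 8))
  dvh <- compute_dvh(dg, mask, bin_width = 0.01)
  # cumulative volume at each edge equals the empirical survival function
  for (q in c(1, 2.5, 7)) {
    edge <- dvh$dose_bins[which.min(abs(dvh$dose_bins - q))]
    expect_equal(dvh$cumulative_volume[dvh$dose_bins == edge],
                 100 * mean(dg$values >= edge))
  }
})

test_that("skin is the one-pass dilation-minus-erosion shell", {
  m <- array(FALSE, c(14, 14, 2))
  m[3:12, 3:12, 1] <- TRUE
  sk <- derive_skin(m)
  # independent shift-based enumeration with the 3x3 cross
  sl <- m[, , 1]
  sh <- function(a, di, dj) {
    b <- array(FALSE, dim(a))
    is <- max(1, 1 + di):min(14, 14 + di)
    js <- max(1, 1 + dj):min(14, 14 + dj)
    b[is, js] <- a[is - di, js - dj]
    b
  }
  dil <- sl | sh(sl, 1, 0) | sh(sl, -1, 0) | sh(sl, 0, 1) | sh(sl, 0, -1)
  ero <- sl & sh(sl, 1, 0) & sh(sl, -1, 0) & sh(sl, 0, 1) & sh(sl, 0, -1)
  expect_identical(sk[, , 1], dil & !ero)
  # the ring is two pixels wide through the face centers
  expect_true(all(sk[2:3, 7, 1]))
  expect_true(all(!sk[4:11, 7, 1]))
  # empty slice stays empty; deep interior is never skin
  expect_false(any(sk[, , 2]))
  expect_false(any(sk[5:10, 5:10, 1]))
})
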