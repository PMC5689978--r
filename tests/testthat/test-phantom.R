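# Phantom and plan generators.

test_that("water sphere phantom is binary with correct HU placement", {
  ct <- small_sphere_ct()
  d <- dim(ct$hu)
  expect_equal(sort(unique(as.vector(ct$hu))), c(-1000L, 0L))
  # voxel nearest the volume center is water
  mid <- (d + 1) %/% 2
  expect_identical(ct$hu[mid[1], mid[2], mid[3]], 0L)
  # corner voxel is air
  expect_identical(ct$hu[1, 1, 1], -1000L)
  expect_error(make_water_sphere_ct(radius = 30, fov = 40, matrix = 16,
                                    slice_thickness = 1, n_slices = 10),
               "does not fit")
})

test_that("water-equivalent voxel count matches the analytic sphere volume", {
  ct <- small_sphere_ct(matrix = 64, n_slices = 64, slice = 0.5, fov = 40)
  vol <- sum(ct$hu == 0L) * prod(ct$spacing)
  oracle <- brute_sphere_count(c(0, 0, 0), 15, ct$origin, ct$spacing,
                               dim(ct$hu))
  expect_equal(sum(ct$hu == 0L), oracle)
  expect_lt(abs(vol - 4 / 3 * pi * 15^3) / (4 / 3 * pi * 15^3), 0.01)
})

test_that("single-dwell plan places the dwell and points the catheter tip-ward", {
  plan <- make_single_dwell_plan(c(1, -2, 3), time = 8)
  expect_equal(as.numeric(plan$dwells[1, c("x", "y", "z")]), c(1, -2, 3))
  expect_equal(plan$total_time, 8)
  # nearest-point search oracle: the two control points closest to the dwell
  cp <- plan$catheters[[1]]$control_points
  d2 <- rowSums(sweep(cp, 2, c(1, -2, 3))^2)
  two <- cp[order(d2)[1:2], ]
  dir <- two[which.max(two[, 3]), ] - two[which.min(two[, 3]), ]
  expect_equal(unname(dir / sqrt(sum(dir^2))), c(0, 0, 1))
  tr <- dwell_transform(plan$dwells[1, ], plan$catheters[[1]])
  expect_equal(unname(tr$rotation %*% c(0, 0, 1)), cbind(c(0, 0, 1)))
})

test_that("multicatheter plans are reproducible with requested dwell spacing", {
  p1 <- make_multicatheter_plan(6, 10, spacing = 5, seed = 42,
                                time_profile = "random")
  p2 <- make_multicatheter_plan(6, 10, spacing = 5, seed = 42,
                                time_profile = "random")
  expect_identical(p1$dwells, p2$dwells)
  expect_equal(nrow(p1$dwells), 60)
  expect_equal(p1$prescription_dose, 32)
  for (cid in 1:6) {
    dw <- as.matrix(p1$dwells[p1$dwells$catheter_id == cid, c("x", "y", "z")])
    steps <- sqrt(rowSums(diff(dw)^2))
    expect_lt(max(abs(steps - 5)), 1e-6)
  }
  p3 <- make_multicatheter_plan(6, 10, spacing = 5, seed = 43,
                                time_profile = "random")
  expect_false(identical(p1$dwells$time, p3$dwells$time))
  # fanned arrangement keeps spacing along oblique catheters
  pf <- make_multicatheter_plan(5, 8, spacing = 4, arrangement = "fanned")
  dw <- as.matrix(pf$dwells[pf$dwells$catheter_id == 2, c("x", "y", "z")])
  expect_lt(max(abs(sqrt(rowSums(diff(dw)^2)) - 4)), 1e-6)
})

test_that("TG43 conditions produce a binary water sphere around the dwell centroid", {
  ct <- small_sphere_ct()
  plan <- make_multicatheter_plan(4, 5, spacing = 2, pitch = 4)
  mod <- make_tg43_conditions(ct, plan, radius = 12)
  expect_setequal(unique(as.vector(mod$hu)), c(-1000L, 0L))
  centroid <- colMeans(as.matrix(plan$dwells[, c("x", "y", "z")]))
  ijk <- round((centroid - mod$origin) / mod$spacing) + 1
  expect_identical(mod$hu[ijk[1], ijk[2], ijk[3]], 0L)
  # a voxel far from the centroid is air even if it was water before
  expect_identical(mod$hu[1, 1, 10], -1000L)
  # idempotent
  mod2 <- make_tg43_conditions(mod, plan, radius = 12)
  expect_identical(mod2$hu, mod$hu)
  # single dwell: centroid equals the dwell position
  p1 <- make_single_dwell_plan(c(3, 1, -2))
  m1 <- make_tg43_conditions(ct, p1, radius = 10)
  ijk <- round((c(3, 1, -2) - m1$origin) / m1$spacing) + 1
  expect_identical(m1$hu[ijk[1], ijk[2], ijk[3]], 0L)
})

test_that("generated structures are closed, cover the dwells and match volume", {
  ct <- small_sphere_ct(matrix = 64, n_slices = 48, slice = 0.625, fov = 40)
  plan <- make_multicatheter_plan(4, 5, spacing = 2, pitch = 4)
  ss <- make_structures(ct, plan, ptv_margin = 6)
  body <- get_structure(ss, "BODY")
  for (cm in body$contours) {
    expect_gte(nrow(cm), 3)
    # closure convention: no duplicated last vertex
    expect_false(all(cm[1, ] == cm[nrow(cm), ]))
    expect_lt(diff(range(cm[, 3])), 0.1)
  }
  dg <- dose_grid(array(1, dim(ct$hu)), ct$origin, ct$spacing)
  m <- rasterize_structure(dg, body)
  vol <- sum(m) * prod(ct$spacing)
  expect_lt(abs(vol - 4 / 3 * pi * 15^3) / (4 / 3 * pi * 15^3), 0.01)
  # every dwell lies inside the PTV mask
  ptv <- rasterize_structure(dg, get_structure(ss, "PTV"))
  dw <- as.matrix(plan$dwells[, c("x", "y", "z")])
  for (i in seq_len(nrow(dw))) {
    ijk <- round((dw[i, ] - ct$origin) / ct$spacing) + 1
    expect_true(ptv[ijk[1], ijk[2], ijk[3]])
  }
})

test_that("generated DICOM fixtures re-read losslessly", {
  ct <- small_sphere_ct(matrix = 16, n_slices = 8, radius = 5, fov = 20)
  plan <- make_single_dwell_plan(c(0, 0, 0))
  d <- withr::local_tempdir()
  write_ct_series(ct, file.path(d, "ct"), seed = 3)
  write_rtplan(plan, file.path(d, "plan.dcm"), seed = 4)
  expect_identical(read_ct_series(file.path(d, "ct"))$hu, ct$hu)
  expect_equal(read_rtplan(file.path(d, "plan.dcm"))$dwells$time,
               plan$dwells$time, tolerance = 1e-9)
})
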