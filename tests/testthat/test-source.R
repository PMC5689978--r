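# Dwell transforms, sampling distribution, phase-space handling.

test_that("dwell transforms orient the source along the catheter", {
  plan <- make_single_dwell_plan(c(0, 0, 0))
  tr <- dwell_transform(plan$dwells[1, ], plan$catheters[[1]])
  expect_equal(tr$rotation, diag(3))
  expect_equal(tr$translation, c(0, 0, 0))
  # same catheter laid along +x: rotation maps (0,0,1) to (1,0,0)
  cp <- plan$catheters[[1]]$control_points[, c(3, 2, 1)]
  tr2 <- dwell_transform(list(x = 0, y = 0, z = 0),
                         list(id = 1L, control_points = cp))
  expect_equal(as.numeric(tr2$rotation %*% c(0, 0, 1)), c(1, 0, 0),
               tolerance = 1e-12)
  # coincident nearest control points are an error
  bad <- list(id = 1L, control_points = rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_error(dwell_transform(list(x = 0, y = 0, z = 1), bad), "coincide")
})

test_that("a dwell on a control point matches its perturbed neighbour", {
  plan <- make_single_dwell_plan(c(0, 0, 0))
  cath <- plan$catheters[[1]]
  on_cp <- cath$control_points[3, ]  # dwell exactly at a control point
  t1 <- dwell_transform(list(x = on_cp[1], y = on_cp[2], z = on_cp[3]), cath)
  t2 <- dwell_transform(list(x = on_cp[1], y = on_cp[2], z = on_cp[3] + 1e-6),
                        cath)
  expect_lt(max(abs(t1$rotation - t2$rotation)), 1e-9)
})

test_that("all plan transforms are orthonormal with determinant +1", {
  plan <- make_multicatheter_plan(5, 6, arrangement = "fanned")
  for (tr in plan_transforms(plan)) {
    R <- tr$rotation
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    v <- R %*% c(0.3, -0.5, 0.81)
    expect_equal(sum(v^2), 0.3^2 + 0.5^2 + 0.81^2, tolerance = 1e-12)
  }
})

test_that("sampling probabilities follow dwell-time fractions", {
  s <- sampling_table(data.frame(time = rep(2, 4)))
  expect_equal(s$p, rep(0.25, 4))
  s2 <- sampling_table(data.frame(time = c(1, 3)))
  expect_equal(s2$p, c(0.25, 0.75))
  expect_equal(sum(s2$p), 1, tolerance = 1e-12)
  # zero-time dwells get zero probability; all-zero is an error
  s3 <- sampling_table(data.frame(time = c(0, 5)))
  expect_equal(s3$p, c(0, 1))
  expect_error(sampling_table(data.frame(time = c(0, 0))), "zero")
  # invariance under uniform rescaling of times
  s4 <- sampling_table(data.frame(time = c(1, 3) * 7.3))
  expect_equal(s4$p, s2$p)
})

test_that("sampled dwell frequencies match probabilities within 3 sigma", {
  times <- c(1, 2, 3, 4)
  s <- sampling_table(data.frame(time = times))
  n <- 1e5
  draws <- withr::with_seed(99, sample.int(4, n, replace = TRUE, prob = s$p))
  freq <- tabulate(draws, 4) / n
  sigma <- sqrt(s$p * (1 - s$p) / n)
  expect_true(all(abs(freq - s$p) <= 3 * sigma))
})

test_that("phase-space files round-trip bit exactly and detect truncation", {
  ps <- toy_phase_space(n_emitted = 500, seed = 8)
  f <- withr::local_tempfile(fileext = ".phsp")
  write_phase_space(ps, f)
  back <- read_phase_space(f)
  expect_identical(back$energy, ps$energy)
  expect_identical(back$position, ps$position)
  expect_identical(back$direction, ps$direction)
  expect_equal(back$n_records, 500)
  expect_equal(back$n_emitted, 500)
  # truncated file reports expected vs found
  raw <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw[1:(length(raw) - 21)], f)
  expect_error(read_phase_space(f), "expected 500 records")
})

test_that("toy phase space is isotropic with spectrum-line energies", {
  spec <- read.csv(system.file("extdata", "ir192_spectrum.csv",
                               package = "brachydeck"))
  n <- 20000
  ps <- toy_phase_space(n_emitted = n, seed = 5)
  expect_identical(toy_phase_space(n_emitted = n, seed = 5)$position,
                   ps$position)
  expect_true(all(ps$energy %in%
                    brachydeck:::dcm_parse_value("FL", writeBin(
                      as.numeric(spec$energy_mev), raw(), size = 4,
                      endian = "little"))))
  # isotropy: mean direction components ~ N(0, 1/sqrt(3n))
  expect_true(all(abs(colMeans(ps$direction)) < 3 / sqrt(3 * n) * 1.8))
  # energy frequencies within 3 sigma multinomial
  p <- spec$intensity / sum(spec$intensity)
  f32e <- brachydeck:::dcm_parse_value("FL", writeBin(
    as.numeric(spec$energy_mev), raw(), size = 4, endian = "little"))
  freq <- vapply(f32e, function(e) mean(ps$energy == e), numeric(1))
  sigma <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(freq - p) <= 3 * sigma))
  # positions on the cylinder surface
  r <- sqrt(ps$position[, 1]^2 + ps$position[, 2]^2)
  on_lat <- abs(r - 0.45) < 1e-6
  on_cap <- abs(abs(ps$position[, 3]) - 1.8) < 1e-6
  expect_true(all(on_lat | on_cap))
})

test_that("record transforms preserve energy and norms and invert cleanly", {
  ps <- toy_phase_space(n_emitted = 200, seed = 2)
  ident <- list(rotation = diag(3), translation = c(0, 0, 0))
  same <- transform_record(ps, ident)
  expect_identical(same$position, ps$position)
  plan <- make_multicatheter_plan(3, 3, arrangement = "fanned")
  tr <- plan_transforms(plan)[[5]]
  moved <- transform_record(ps, tr)
  expect_identical(moved$energy, ps$energy)
  expect_equal(sqrt(rowSums(moved$direction^2)), rep(1, 200),
               tolerance = 1e-6)
  inv <- list(rotation = t(tr$rotation),
              translation = -as.numeric(t(tr$rotation) %*% tr$translation))
  back <- transform_record(moved, inv)
  expect_lt(max(abs(back$position - ps$position)), 1e-9)
  expect_lt(max(abs(back$direction - ps$direction)), 1e-12)
})
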