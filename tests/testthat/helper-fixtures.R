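# Shared small fixtures, built in code at test time.

small_sphere_ct <- function(matrix = 32, n_slices = 20, radius = 15,
                            fov = 40, slice = 2) {
  make_water_sphere_ct(radius = radius, fov = fov, matrix = matrix,
                       slice_thickness = slice, n_slices = n_slices)
}

# TG43 source data with flat g and F (pure geometry-factor field)
flat_source <- function(L = 0, Lambda = 1, Sk = 1000) {
  g_tab <- data.frame(r_cm = c(0.25, 0.5, 1, 2, 5, 12), g = 1)
  F_tab <- list(theta_deg = c(0, 90, 180), r_cm = c(0.25, 1, 12),
                F = matrix(1, 3, 3))
  tg43_source_data(Lambda = Lambda, L = L, Sk = Sk,
                   g_table = g_tab, F_table = F_tab)
}

# independent in/out-of-circle voxel enumeration for sphere volumes
brute_sphere_count <- function(center, radius, origin, spacing, dims) {
  count <- 0
  for (k in seq_len(dims[3])) {
    z <- origin[3] + (k - 1) * spacing[3]
    h2 <- radius^2 - (z - center[3])^2
    if (h2 <= 0) next
    xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1] - center[1]
    ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2] - center[2]
    count <- count + sum(outer(xs^2, ys^2, "+") <= h2)
  }
  count
}
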