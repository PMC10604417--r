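test_that("phantom generation is deterministic and labels every grain", {
  spec <- phantom_spec(grain_count = 8, seed = 7)
  ph1 <- generate_phantom(spec)
  ph2 <- generate_phantom(spec)
  expect_identical(ph1$volume$voxels, ph2$volume$voxels)
  expect_identical(ph1$truth, ph2$truth)
  labs <- setdiff(unique(as.integer(ph1$truth$label_volume)), 0L)
  expect_setequal(labs, 1:8)
  # grains fit in the volume and trait table matches the label volume
  expect_equal(ph1$truth$grains$n_voxels,
               as.integer(tabulate(ph1$truth$label_volume, nbins = 8)))
})

test_that("noiseless impurity-free rendering uses only the declared intensities", {
  spec <- phantom_spec(grain_count = 4, noise_sd = 0, seed = 2,
                       volume_dims = c(120, 102, 102))
  ph <- generate_phantom(spec)
  expect_true(all(unique(as.integer(ph$volume$voxels)) %in%
                    as.integer(spec$intensities)))
  # truth/volume coherence: every labeled voxel shows grain intensity
  lab <- ph$truth$label_volume > 0
  expect_true(all(ph$volume$voxels[lab] ==
                    as.integer(spec$intensities[["grain"]])))
})

test_that("rasterized grains match the per-voxel inclusion oracle", {
  spec <- phantom_spec(grain_count = 3, noise_sd = 0, seed = 5)
  ph <- generate_phantom(spec)
  tr <- ph$truth$grains
  for (g in seq_len(3)) {
    # independent enumeration over the bounding box of grain g
    az <- tr$azimuth_deg[g] * pi / 180
    ti <- tr$tilt_deg[g] * pi / 180
    u <- c(cos(az), sin(az))
    e1 <- c(cos(ti) * u, sin(ti))
    e2 <- c(-u[2], u[1], 0)
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    h <- ceiling(tr$a[g]) + 1
    grid <- expand.grid(z = floor(tr$cz[g] - h):ceiling(tr$cz[g] + h),
                        y = floor(tr$cy[g] - h):ceiling(tr$cy[g] + h),
                        x = floor(tr$cx[g] - h):ceiling(tr$cx[g] + h))
    d <- cbind(grid$x - tr$cx[g], grid$y - tr$cy[g], grid$z - tr$cz[g])
    q <- (d %*% e1 / tr$a[g])^2 + (d %*% e2 / tr$b[g])^2 +
      (d %*% e3 / tr$c[g])^2
    expect_identical(tr$n_voxels[g], sum(q <= 1))
    # rasterization consistency: within 3% of the analytic ellipsoid volume
    va <- 4 / 3 * pi * tr$a[g] * tr$b[g] * tr$c[g]
    expect_lt(abs(tr$n_voxels[g] - va) / va, 0.03)
  }
})

test_that("overlapping or out-of-bounds grains are rejected", {
  expect_error(generate_phantom(
    phantom_spec(grain_count = 6, axial_spacing = 2, seed = 1)),
    "overlap")
  expect_error(generate_phantom(
    phantom_spec(grain_count = 4, volume_dims = c(40, 102, 102), seed = 1)),
    "outside")
})

test_that("spec validation catches inconsistent parameters", {
  expect_error(phantom_spec(semi_axes_range = list(a = c(5, 6), b = c(4, 7),
                                                   c = c(2, 3))),
               "ordered")
  expect_error(phantom_spec(semi_axes_range = list(a = c(5, 6), b = c(4, 5),
                                                   c = c(1, 1.5))),
               "at least 2")
  expect_error(phantom_spec(intensities = c(background = 200, grain = 100,
                                            rachis = 50, holder = 230)),
               "exceed")
})

test_that("analytic measures reproduce the sphere and the mesh oracle", {
  sph <- analytic_grain_measures(25, 25, 25, pixel_size_um = 80)
  expect_equal(sph$volume_mm3, 4 / 3 * pi * 2^3, tolerance = 1e-6)
  expect_equal(sph$surface_mm2, 4 * pi * 2^2, tolerance = 1e-4)
  ell <- analytic_grain_measures(15, 10, 8, pixel_size_um = 100)
  mesh <- oracle_ellipsoid_mesh_area(15, 10, 8) * 100^2 / 1e6
  expect_lt(abs(ell$surface_mm2 - mesh) / mesh, 0.005)
  # Thomsen p = 1.6075 approximation as an independent sanity bound
  p <- 1.6075
  thom <- 4 * pi * ((15^p * 10^p + 15^p * 8^p + 10^p * 8^p) / 3)^(1 / p) *
    100^2 / 1e6
  expect_lt(abs(ell$surface_mm2 - thom) / thom, 0.012)
  expect_equal(unlist(ell[c("length_mm", "width_mm", "thickness_mm")],
                      use.names = FALSE), c(3, 2, 1.6))
})

test_that("slice stacks round-trip losslessly with sortable names", {
  spec <- micro_phantom_spec(seed = 3, nz = 50, grain_count = 6)
  ph <- generate_phantom(spec)
  dir <- withr::local_tempdir()
  files <- render_slice_stack(ph$volume, dir)
  expect_length(files, 50)
  expect_equal(basename(files[1]), "slice_0000.png")
  expect_equal(basename(files[50]), "slice_0049.png")
  back <- read_slice_stack(dir, pixel_size_um = 85)
  expect_identical(back$voxels, ph$volume$voxels)
  # per-slice identity: histogram of slice k equals histogram of volume[k]
  k <- 17
  img <- png::readPNG(files[k + 1]) * 255
  expect_identical(tabulate(as.integer(img) + 1L, 256),
                   tabulate(as.integer(ph$volume$voxels[k + 1, , ]) + 1L,
                            256))
})
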