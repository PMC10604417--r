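test_that("point cloud conversion counts foreground voxels exactly", {
  vol <- array(0L, c(10, 12, 14))
  vol[5, 6, 7] <- 1L
  pc <- volume_to_pointcloud(vol, 80)
  expect_equal(unname(pc$points[1, ]), c(5, 6, 7))
  cube <- array(1L, c(10, 10, 10))
  expect_equal(nrow(volume_to_pointcloud(cube, 80)$points), 1000)
  expect_error(volume_to_pointcloud(array(0L, c(4, 4, 4)), 80),
               "no spike")
  expect_error(volume_to_pointcloud(array(2L, c(2, 2, 2)), 80), "binary")
})

test_that("surface extraction keeps exactly the 6-exposed voxels", {
  vol <- array(0L, c(5, 5, 5))
  vol[2:4, 2:4, 2:4] <- 1L
  sh <- extract_surface_points(vol)
  expect_equal(nrow(sh), 26)
  expect_false(any(sh[, 1] == 3 & sh[, 2] == 3 & sh[, 3] == 3))
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_equal(unname(extract_surface_points(one)[1, ]), c(2, 2, 2))
  # shell of a rasterized sphere is one voxel thick: every returned point
  # has an exposed face (checked independently against the volume)
  n <- 31; ctr <- 16
  ix <- arrayInd(seq_len(n^3), rep(n, 3))
  vol2 <- array(0L, rep(n, 3))
  vol2[rowSums((ix - ctr)^2) <= 12^2] <- 1L
  sh2 <- extract_surface_points(vol2)
  for (r in sample(nrow(sh2), 50)) {
    p <- sh2[r, ]
    nb <- rbind(p + c(1, 0, 0), p - c(1, 0, 0), p + c(0, 1, 0),
                p - c(0, 1, 0), p + c(0, 0, 1), p - c(0, 0, 1))
    expect_true(any(vol2[nb] == 0L))
  }
})

test_that("density clustering separates blobs and matches the BFS oracle", {
  blob <- function(z0, y0, x0) as.matrix(expand.grid(z = z0:(z0 + 4),
                                                     y = y0:(y0 + 4),
                                                     x = x0:(x0 + 4)))
  two <- rbind(blob(1, 1, 1), blob(30, 1, 1))
  cl <- cluster_grains(two, cluster_config(eps = 4, min_points = 10,
                                           min_cluster_voxels = 20))
  expect_length(cl$grains, 2)
  one <- cluster_grains(blob(1, 1, 1), cluster_config(eps = 4,
                                                      min_points = 10,
                                                      min_cluster_voxels = 20))
  expect_length(one$grains, 1)
  # partition equality with the brute-force density-connectivity oracle
  for (seed in 1:8) {
    set.seed(seed)
    n <- 300
    pts <- cbind(rnorm(n, rep(c(0, 12), each = n / 2), 2),
                 rnorm(n, 5, 2), rnorm(n, 5, 2))
    eps <- runif(1, 1.2, 2.5)
    got <- spikeCT:::.dbscan_points(pts, eps, 5L)
    want <- oracle_dbscan(pts, eps, 5)
    expect_identical(as.integer(got), as.integer(want))
  }
  # conservation: cluster sizes + debris = cloud size
  set.seed(3)
  pts <- cbind(runif(500, 0, 30), runif(500, 0, 30), runif(500, 0, 30))
  cl2 <- cluster_grains(pts, cluster_config(eps = 4, min_points = 4,
                                            min_cluster_voxels = 10))
  expect_equal(sum(vapply(cl2$grains, nrow, integer(1))) +
                 nrow(cl2$debris), 500)
  expect_error(cluster_grains(pts, cluster_config(eps = 0.01,
                                                  min_points = 10)),
               "no grains")
})

test_that("grain volume follows the voxel-count formula", {
  expect_identical(grain_volume(1000, 100), 1)
  expect_identical(grain_volume(0, 100), 0)
  expect_equal(grain_volume(12345, 85), 12345 * 85^3 / 1e9)
})

test_that("surface areas: hull branch exact on the cube, scales as P^2", {
  cube <- as.matrix(expand.grid(1:10, 1:10, 1:10))
  s <- grain_surface(cube, alpha = 1e6, pixel_size_um = 100)
  expect_equal(s$mesh_area_voxel2, 486, tolerance = 1e-9)
  expect_equal(s$surface_mm2, 4.86, tolerance = 1e-9)
  s2 <- grain_surface(cube, alpha = 1e6, pixel_size_um = 200)
  expect_equal(s2$surface_mm2 / s$surface_mm2, 4, tolerance = 1e-12)
  expect_error(grain_surface(cbind(1:9, (1:9) * 2, (1:9) * 3), 12, 100),
               "degenerate")
  expect_error(grain_surface(cbind(1:9, 1:9, 0), 12, 100), "degenerate")
})

test_that("finite-alpha mesh covers both faces of a hollow shell", {
  n <- 29; ctr <- 15; r <- 12
  ix <- arrayInd(seq_len(n^3), rep(n, 3))
  vol <- array(0L, rep(n, 3))
  vol[rowSums((ix - ctr)^2) <= r^2] <- 1L
  sh <- extract_surface_points(vol)
  s <- grain_surface(sh, alpha = 7, pixel_size_um = 1000)
  two_sided <- 2 * 4 * pi * (r - 0.4)^2
  expect_gt(s$mesh_area_voxel2 / two_sided, 0.85)
  expect_lt(s$mesh_area_voxel2 / two_sided, 1.15)
})

test_that("oriented boxes recover axis-aligned and rotated extents", {
  box <- as.matrix(expand.grid(1:50, 1:20, 1:10))
  d <- grain_obb(box, pixel_size_um = 100)
  expect_equal(unname(d), c(5, 2, 1), tolerance = 1e-9)
  # rotate 30 degrees about the first axis
  th <- 30 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  rot <- box %*% t(R)
  dr <- grain_obb(rot, pixel_size_um = 100)
  expect_true(all(abs(dr - c(5, 2, 1)) / c(5, 2, 1) < 0.03))
  expect_true(all(diff(unname(d)) <= 0))  # sorted descending
  expect_error(grain_obb(matrix(1, 1, 3), 100), "at least 2")
})

test_that("grains are ordered bottom-up with deterministic ties", {
  cents <- rbind(c(90, 5, 5), c(10, 5, 5), c(50, 5, 5))
  expect_equal(order_grains(cents), c(3, 1, 2))
  ties <- rbind(c(10, 7, 2), c(10, 3, 9))
  expect_equal(order_grains(ties), c(2, 1))
  expect_equal(order_grains(ties[2:1, ]), c(1, 2))
  expect_equal(order_grains(cents, flip = TRUE), c(1, 3, 2))
})

test_that("spike records recover phantom structure and bookkeeping", {
  spec <- phantom_spec(grain_count = 6, seed = 12)
  ph <- generate_phantom(spec)
  bin <- (ph$truth$label_volume > 0) + 0L
  rec <- extract_grains(bin, spec$pixel_size_um,
                        cluster_config(eps = 4), compute_surface = FALSE)
  expect_s3_class(rec, "spike_record")
  expect_equal(rec$grain_count, 6)
  expect_setequal(rec$grains$position, 1:6)
  # recovered bottom-up order equals construction order along the rachis
  expect_equal(rec$grains$position[order(rec$grains$cz)], 1:6)
  expect_equal(rec$total_grain_volume_mm3, sum(rec$grains$volume_mm3))
  expect_equal(sum(rec$grains$n_voxels), sum(bin))
  # single grain: spike length equals the grain's own length
  single <- (ph$truth$label_volume == 1L) + 0L
  rs <- extract_grains(single, spec$pixel_size_um,
                       cluster_config(eps = 4), compute_surface = FALSE)
  expect_equal(rs$spike_length_mm, rs$grains$length_mm[1])
  # totals scale as P^3 under a pure pixel-size change
  rec2 <- extract_grains(bin, 2 * spec$pixel_size_um,
                         cluster_config(eps = 4), compute_surface = FALSE)
  expect_equal(rec2$total_grain_volume_mm3 / rec$total_grain_volume_mm3, 8,
               tolerance = 1e-12)
})

test_that("traits are invariant to a 90-degree rotation about the axis", {
  spec <- phantom_spec(grain_count = 5, seed = 14)
  ph <- generate_phantom(spec)
  bin <- (ph$truth$label_volume > 0) + 0L
  rot <- aperm(bin, c(1, 3, 2))[, , dim(bin)[2]:1]  # 90 deg about z
  r1 <- extract_grains(bin, 85, cluster_config(eps = 4),
                       compute_surface = FALSE)
  r2 <- extract_grains(rot, 85, cluster_config(eps = 4),
                       compute_surface = FALSE)
  expect_equal(r2$grain_count, r1$grain_count)
  expect_lt(abs(r2$total_grain_volume_mm3 - r1$total_grain_volume_mm3) /
              r1$total_grain_volume_mm3, 0.01)
  expect_lt(abs(r2$spike_length_mm - r1$spike_length_mm) /
              r1$spike_length_mm, 0.01)
})

test_that("positional profiles aggregate per group and position", {
  spec <- phantom_spec(grain_count = 5, seed = 15)
  ph <- generate_phantom(spec)
  bin <- (ph$truth$label_volume > 0) + 0L
  rec <- extract_grains(bin, 85, cluster_config(eps = 4),
                        compute_surface = FALSE, spike_id = "s1",
                        group = "wild")
  prof <- positional_profile(list(rec), "volume_mm3")
  ord <- rec$grains[order(rec$grains$position), ]
  expect_equal(prof$mean_value, ord$volume_mm3)
  expect_equal(prof$n_spikes, rep(1L, 5))
  two <- positional_profile(list(rec, rec), "volume_mm3")
  expect_equal(two$mean_value, ord$volume_mm3)
  expect_equal(two$n_spikes, rep(2L, 5))
  expect_error(positional_profile(list(rec), "no_such_trait"), "unknown")
})
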