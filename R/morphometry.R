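#' Convert a binary volume to a voxel-centre point cloud
#'
#' One point per foreground voxel, at the voxel centre, in `(z, y, x)`
#' voxel coordinates.
#'
#' @param vol binary 3D array `(z, y, x)` with values in `{0, 1}`, or a
#'   list with elements `voxels` and `pixel_size_um`.
#' @param pixel_size_um voxel size; required when `vol` is a bare array.
#' @return list of class `point_cloud` with `points` (n x 3 matrix, columns
#'   z, y, x) and `pixel_size_um`.
#' @export
volume_to_pointcloud <- function(vol, pixel_size_um = NULL) {
  if (is.list(vol)) {
    pixel_size_um <- vol$pixel_size_um
    vol <- vol$voxels
  }
  stopifnot(length(dim(vol)) == 3, !is.null(pixel_size_um))
  if (!all(vol %in% c(0, 1))) stop("volume is not binary {0,1}")
  idx <- which(vol == 1)
  if (length(idx) == 0) stop("no spike detected: empty foreground")
  pts <- arrayInd(idx, dim(vol))
  colnames(pts) <- c("z", "y", "x")
  structure(list(points = pts, pixel_size_um = pixel_size_um),
            class = "point_cloud")
}

#' Surface shell of a grain: voxels with an exposed face
#'
#' Returns the subset of foreground voxels having at least one 6-connected
#' background neighbour (faces only, not edges/corners) - the one-voxel
#' contour shell used as input to surface reconstruction.
#'
#' @param vol binary 3D array `(z, y, x)`.
#' @param grain_points optional n x 3 matrix restricting the result to one
#'   grain's voxels; by default all foreground voxels are considered.
#' @return n x 3 matrix of shell voxel coordinates `(z, y, x)`.
#' @export
extract_surface_points <- function(vol, grain_points = NULL) {
  stopifnot(length(dim(vol)) == 3)
  d <- dim(vol)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  core <- 2:(d[1] + 1)
  cy <- 2:(d[2] + 1)
  cx <- 2:(d[3] + 1)
  n6 <- pad[core - 1, cy, cx] + pad[core + 1, cy, cx] +
    pad[core, cy - 1, cx] + pad[core, cy + 1, cx] +
    pad[core, cy, cx - 1] + pad[core, cy, cx + 1]
  shell <- vol == 1 & n6 < 6
  if (is.null(grain_points)) {
    pts <- arrayInd(which(shell), d)
  } else {
    stopifnot(nrow(grain_points) >= 1)
    on_shell <- shell[grain_points]
    pts <- grain_points[on_shell, , drop = FALSE]
  }
  colnames(pts) <- c("z", "y", "x")
  pts
}

#' Clustering configuration for grain isolation
#'
#' @param eps DBSCAN neighbourhood radius in voxels (scans in the source
#'   protocol use 3--7; default 4).
#' @param min_points minimum closed-neighbourhood size for a core point.
#' @param min_cluster_voxels clusters smaller than this are discarded as
#'   debris (dust, awn fragments surviving segmentation).
#' @param alpha alpha-shape parameter in voxels for surface reconstruction.
#' @return list of class `cluster_config`.
#' @export
cluster_config <- function(eps = 4, min_points = 10,
                           min_cluster_voxels = 50, alpha = 12) {
  stopifnot(eps > 0, min_points >= 1, min_cluster_voxels >= 1, alpha > 0)
  structure(list(eps = eps, min_points = min_points,
                 min_cluster_voxels = min_cluster_voxels, alpha = alpha),
            class = "cluster_config")
}

#' Isolate grains by density clustering of the voxel point cloud
#'
#' DBSCAN over the foreground voxel centres: a point is a core point when
#' its closed `eps`-ball holds at least `min_points` points; clusters are
#' maximal density-connected sets, grown deterministically in ascending
#' point order. Noise points and clusters below `min_cluster_voxels` are
#' returned as debris.
#'
#' @param cloud a [volume_to_pointcloud()] result, or a bare n x 3 matrix.
#' @param cfg a [cluster_config()].
#' @return list with `grains` (list of point matrices, one per retained
#'   cluster, in discovery order) and `debris` (matrix of discarded
#'   points).
#' @export
cluster_grains <- function(cloud, cfg = cluster_config()) {
  pts <- if (inherits(cloud, "point_cloud")) cloud$points else cloud
  stopifnot(is.matrix(pts), ncol(pts) == 3, nrow(pts) >= 1)
  labels <- .dbscan_points(matrix(as.numeric(pts), nrow(pts), 3),
                           cfg$eps, as.integer(cfg$min_points))
  keep <- which(tabulate(labels[labels > 0]) >= cfg$min_cluster_voxels)
  if (length(keep) == 0)
    stop("clustering produced no grains; adjust eps or min_cluster_voxels")
  grains <- lapply(keep, function(k) pts[labels == k, , drop = FALSE])
  debris <- pts[!(labels %in% keep), , drop = FALSE]
  list(grains = grains, debris = debris)
}

#' Grain volume from its voxel count
#'
#' V = n P^3 / 10^9 mm^3 for n voxels of edge P micrometres.
#'
#' @param n voxel count (>= 0).
#' @param pixel_size_um voxel edge P in micrometres.
#' @return volume in mm^3.
#' @export
grain_volume <- function(n, pixel_size_um) {
  stopifnot(all(n >= 0), pixel_size_um > 0)
  n * pixel_size_um^3 / 1e9
}

#' Alpha-shape surface mesh and area of a grain
#'
#' Reconstructs a triangulated surface over the grain's shell points and
#' returns the mesh area m (voxel^2) and the physical surface
#' S = m P^2 / 10^6 mm^2. For `alpha` at least the point-set diameter the
#' alpha shape equals the convex hull, which is then computed directly;
#' otherwise boundary triangles are found by the empty-circumball
#' (alpha-exposed) test among candidate triangles with edges up to the
#' lattice chord length `2 * sqrt(2 * alpha)` (a ball of radius alpha
#' resting across unit voxel steps touches summits up to that far apart).
#' Where the alpha ball fits on both sides of the one-voxel-thick shell the
#' alpha shape is a thin slab and the mesh has an outer and an inner face,
#' so m approaches twice the one-sided geometric area - the usual behaviour
#' of alpha-shape reconstruction over contour point clouds; for small
#' convex grains whose interior cannot host the ball the mesh is
#' single-sided. The convex-hull branch is always single-sided.
#'
#' @param surface_points n x 3 matrix of shell voxel coordinates (>= 4
#'   non-coplanar points).
#' @param alpha alpha parameter in voxels.
#' @param pixel_size_um voxel edge P in micrometres.
#' @return list with `mesh_area_voxel2` (m), `surface_mm2` (S), and
#'   `triangles` (index triples into `surface_points`).
#' @export
grain_surface <- function(surface_points, alpha = 12, pixel_size_um = 85) {
  stopifnot(is.matrix(surface_points), ncol(surface_points) == 3,
            alpha > 0, pixel_size_um > 0)
  pts <- matrix(as.numeric(surface_points), nrow(surface_points), 3)
  if (nrow(pts) < 4) stop("degenerate grain geometry: fewer than 4 points")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("degenerate grain geometry: points are coplanar or collinear")
  diam <- sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
  res <- if (alpha >= diam) .quickhull3(pts) else
    .alpha_boundary(pts, alpha, edge_cap = max(3, 2 * sqrt(2 * alpha)))
  list(mesh_area_voxel2 = res$area,
       surface_mm2 = res$area * pixel_size_um^2 / 1e6,
       triangles = res$triangles)
}

#' Oriented bounding box dimensions of a point set
#'
#' Principal-axes box: the box axes are the eigenvectors of the point
#' covariance, the extent along each axis is
#' `(max - min projection + 1) * P / 1000` mm (the +1 voxel accounts for
#' the width of the voxels at both ends), and extents are returned sorted
#' descending as length >= width >= thickness.
#'
#' @param points n x 3 matrix of voxel coordinates (n >= 2).
#' @param pixel_size_um voxel edge P in micrometres.
#' @return named numeric vector `c(length_mm, width_mm, thickness_mm)`.
#' @export
grain_obb <- function(points, pixel_size_um) {
  pts <- if (inherits(points, "point_cloud")) points$points else points
  stopifnot(is.matrix(pts), ncol(pts) == 3)
  if (nrow(pts) < 2) stop("need at least 2 points for a bounding box")
  pts <- matrix(as.numeric(pts), nrow(pts), 3)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)$vectors
  proj <- pts %*% ev
  ext <- apply(proj, 2, max) - apply(proj, 2, min) + 1
  ext <- sort(ext, decreasing = TRUE) * pixel_size_um / 1e3
  c(length_mm = ext[1], width_mm = ext[2], thickness_mm = ext[3])
}

#' Order grains bottom-up along the spike axis
#'
#' Position index 1 is the bottom-most grain; grains are ranked by the
#' ascending projection of their centroid onto the spike axis, with exact
#' ties broken by `(y, x)` centroid order. The axis is oriented so that
#' "bottom" is the end with the smaller z coordinate (spikes are scanned
#' base-down in the holder); set `flip = TRUE` for base-up scans.
#'
#' @param centroids g x 3 matrix of grain centroids `(z, y, x)`.
#' @param axis spike axis direction; default the z axis. Typically the
#'   first principal axis of the full spike cloud.
#' @param flip reverse the bottom-to-top direction.
#' @return integer vector: `position[i]` is the bottom-up rank of grain i.
#' @export
order_grains <- function(centroids, axis = c(1, 0, 0), flip = FALSE) {
  stopifnot(is.matrix(centroids), ncol(centroids) == 3,
            nrow(centroids) >= 1)
  axis <- axis / sqrt(sum(axis^2))
  if (axis[1] < 0) axis <- -axis     # make projection increase with z
  if (flip) axis <- -axis
  h <- as.numeric(centroids %*% axis)
  ord <- order(h, centroids[, 2], centroids[, 3])
  pos <- integer(nrow(centroids))
  pos[ord] <- seq_len(nrow(centroids))
  pos
}

#' Measure every grain and assemble the spike record
#'
#' The full morphometric pass over a binary virtual spike: point cloud,
#' density clustering, then per grain the voxel count n, volume
#' V = n P^3/10^9, alpha-shape surface S = m P^2/10^6, oriented-box
#' length/width/thickness and bottom-up position, plus spike length (the
#' longest oriented-box extent of the whole cloud), grain count and
#' per-spike totals.
#'
#' @param vol binary 3D array `(z, y, x)` or list with `voxels` and
#'   `pixel_size_um`.
#' @param pixel_size_um voxel size, when `vol` is a bare array.
#' @param cfg a [cluster_config()].
#' @param compute_surface set `FALSE` to skip surface reconstruction (the
#'   slowest trait) when only counts/volumes/boxes are needed.
#' @param spike_id,group identifiers copied into the record.
#' @return list of class `spike_record`: `spike_id`, `group`,
#'   `spike_length_mm`, `grain_count`, `total_grain_volume_mm3`,
#'   `total_grain_surface_mm2`, `grains` (data frame, one row per grain),
#'   `debris_voxels`.
#' @export
extract_grains <- function(vol, pixel_size_um = NULL,
                           cfg = cluster_config(), compute_surface = TRUE,
                           spike_id = "spike", group = NA_character_) {
  cloud <- volume_to_pointcloud(vol, pixel_size_um)
  P <- cloud$pixel_size_um
  if (is.list(vol)) vol <- vol$voxels
  cl <- cluster_grains(cloud, cfg)
  g <- length(cl$grains)
  centroids <- t(vapply(cl$grains, colMeans, numeric(3)))
  spike_axis <- eigen(stats::cov(cloud$points),
                      symmetric = TRUE)$vectors[, 1]
  pos <- order_grains(centroids, axis = spike_axis)
  rows <- lapply(seq_len(g), function(i) {
    pts <- cl$grains[[i]]
    obb <- grain_obb(pts, P)
    n <- nrow(pts)
    surf <- NA_real_; mesh <- NA_real_
    if (compute_surface) {
      shell <- extract_surface_points(vol, pts)
      s <- grain_surface(shell, alpha = cfg$alpha, pixel_size_um = P)
      surf <- s$surface_mm2; mesh <- s$mesh_area_voxel2
    }
    data.frame(grain_id = i, position = pos[i],
               cz = centroids[i, 1], cy = centroids[i, 2],
               cx = centroids[i, 3], n_voxels = n,
               volume_mm3 = grain_volume(n, P),
               mesh_area_voxel2 = mesh, surface_mm2 = surf,
               length_mm = obb[["length_mm"]],
               width_mm = obb[["width_mm"]],
               thickness_mm = obb[["thickness_mm"]])
  })
  grains <- do.call(rbind, rows)
  spike_obb <- grain_obb(cloud$points, P)
  structure(list(spike_id = spike_id, group = group,
                 spike_length_mm = spike_obb[["length_mm"]],
                 grain_count = g,
                 total_grain_volume_mm3 = sum(grains$volume_mm3),
                 total_grain_surface_mm2 = sum(grains$surface_mm2),
                 grains = grains,
                 debris_voxels = nrow(cl$debris)),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf(paste0("spike_record '%s': %d grains, length %.2f mm, ",
                     "total grain volume %.2f mm3 (%d debris voxels)\n"),
              x$spike_id, x$grain_count, x$spike_length_mm,
              x$total_grain_volume_mm3, x$debris_voxels))
  invisible(x)
}

#' Along-spike trait profiles by group
#'
#' Mean of a per-grain trait at each bottom-up position, per group - the
#' along-spike distribution of grain morphology. Positions present in no
#' spike of a group are omitted; the number of contributing spikes is
#' reported.
#'
#' @param spikes list of `spike_record`s.
#' @param trait column of the per-grain table, e.g. `"volume_mm3"`,
#'   `"length_mm"`.
#' @return data frame with `group`, `position`, `mean_value`, `n_spikes`.
#' @export
positional_profile <- function(spikes, trait) {
  stopifnot(length(spikes) >= 1)
  if (!trait %in% names(spikes[[1]]$grains))
    stop("unknown trait: ", trait)
  rows <- do.call(rbind, lapply(spikes, function(s) {
    data.frame(group = if (is.na(s$group)) "all" else s$group,
               position = s$grains$position,
               value = s$grains[[trait]])
  }))
  agg <- stats::aggregate(value ~ group + position, rows,
                          function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(group = agg$group, position = agg$position,
                    mean_value = agg$value[, "mean"],
                    n_spikes = as.integer(agg$value[, "n"]))
  out[order(out$group, out$position), ]
}
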