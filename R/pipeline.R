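#' @title End-to-end pipeline runners
#' @description High-level wrappers that chain the package's stages the way
#'   the command-line interface does: phantom generation to disk, network
#'   training, slice-by-slice segmentation into a stacked NIfTI, trait
#'   extraction to CSV/PLY, and virtual-vs-manual validation. Each runner
#'   is deterministic for fixed inputs and seed.
#' @name pipeline
NULL

#' Generate a phantom scan to disk
#'
#' Renders the phantom, writes the slice stack (PNG), the ground-truth
#' label volume (NIfTI) and the per-grain analytic table (CSV).
#'
#' @param spec a [phantom_spec()].
#' @param out_dir output directory.
#' @return Invisibly, a list with the phantom and the file paths.
#' @export
run_phantom <- function(spec, out_dir) {
  ph <- generate_phantom(spec)
  slice_dir <- file.path(out_dir, "slices")
  files <- render_slice_stack(ph$volume, slice_dir)
  truth_nii <- file.path(out_dir, "truth_labels.nii.gz")
  truth_csv <- file.path(out_dir, "truth_grains.csv")
  write_phantom_truth(ph$truth, spec$pixel_size_um, truth_nii, truth_csv)
  invisible(list(phantom = ph, slice_dir = slice_dir, slices = files,
                 truth_nifti = truth_nii, truth_csv = truth_csv))
}

#' Train the segmentation network from a phantom or image pairs
#'
#' @param images,masks paired lists of slices and `{0, 1}` masks (see
#'   [train_unet()]).
#' @param cfg training config list.
#' @param checkpoint_path where to store the best model (`.rds`); the loss
#'   history is written alongside as CSV.
#' @return The [train_unet()] result, invisibly.
#' @export
run_train <- function(images, masks, cfg = list(), checkpoint_path) {
  fit <- train_unet(images, masks, cfg)
  save_unet(fit$model, checkpoint_path)
  utils::write.csv(data.frame(epoch = seq_along(fit$loss_history),
                              loss = fit$loss_history),
                   sub("\\.rds$", "_loss.csv", checkpoint_path),
                   row.names = FALSE)
  invisible(fit)
}

#' Segment a slice stack into a binary virtual-spike volume
#'
#' Per slice: holder removal, (optional) resize to the network input size,
#' network prediction, mask-assisted Otsu refinement, resize back; the
#' binarized slices are stacked and optionally written as NIfTI. With
#' `use_unet = FALSE` the network is skipped and each holder-removed slice
#' is binarized by plain Otsu thresholding - the comparison mode showing
#' what the network contributes (noise and impurities survive plain
#' thresholding).
#'
#' @param volume a `voxel_volume` (e.g. from [read_slice_stack()]).
#' @param model a trained `seg_model` (ignored when `use_unet = FALSE`).
#' @param roi holder ROI (`center_xy`, `radius`); `NULL` = auto-detect
#'   from the first slice via [detect_holder()].
#' @param input_size network input size (slices resized when different).
#' @param use_unet set `FALSE` for the direct-Otsu comparison path.
#' @param nifti_path optional output path for the stacked binary volume.
#' @return list with `voxels` (binary `(z, y, x)` array), `pixel_size_um`,
#'   and `fg_per_slice` (foreground pixel count per slice).
#' @export
run_segment <- function(volume, model = NULL, roi = NULL, input_size = NULL,
                        use_unet = TRUE, nifti_path = NULL) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (use_unet && is.null(model)) stop("missing segmentation model")
  vox <- volume$voxels
  nz <- dim(vox)[1]
  if (is.null(roi)) roi <- detect_holder(vox[1, , ])
  out <- array(0L, dim(vox))
  fg <- integer(nz)
  for (z in seq_len(nz)) {
    sl <- remove_holder(vox[z, , ], roi)
    if (use_unet) {
      pred <- predict_mask(model, sl, input_size = input_size)
      mask <- assisted_segment(sl, pred)
    } else {
      ot <- otsu_threshold(sl)
      mask <- if (ot$degenerate) sl * 0 else (sl > ot$threshold) + 0
    }
    out[z, , ] <- as.integer(mask)
    fg[z] <- sum(mask)
  }
  if (!is.null(nifti_path))
    stack_and_save(out, volume$pixel_size_um, nifti_path)
  list(voxels = out, pixel_size_um = volume$pixel_size_um,
       fg_per_slice = fg)
}

#' Extract traits from a stacked binary volume
#'
#' Runs [extract_grains()] on a NIfTI file or in-memory binary volume and
#' writes the per-grain CSV, the per-spike CSV, and a colored point-cloud
#' PLY for inspection.
#'
#' @param vol NIfTI path, or list with `voxels` + `pixel_size_um`.
#' @param out_dir output directory for `grains.csv`, `spike.csv`,
#'   `spike.ply`; `NULL` writes nothing.
#' @param cfg a [cluster_config()].
#' @param ... passed to [extract_grains()].
#' @return The `spike_record`.
#' @export
run_extract <- function(vol, out_dir = NULL, cfg = cluster_config(), ...) {
  if (is.character(vol)) vol <- load_volume(vol)
  rec <- extract_grains(vol, cfg = cfg, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rec$grains, file.path(out_dir, "grains.csv"),
                     row.names = FALSE)
    spike_df <- data.frame(spike_id = rec$spike_id, group = rec$group,
                           spike_length_mm = rec$spike_length_mm,
                           grain_count = rec$grain_count,
                           total_grain_volume_mm3 =
                             rec$total_grain_volume_mm3,
                           total_grain_surface_mm2 =
                             rec$total_grain_surface_mm2,
                           debris_voxels = rec$debris_voxels)
    utils::write.csv(spike_df, file.path(out_dir, "spike.csv"),
                     row.names = FALSE)
    cl <- cluster_grains(volume_to_pointcloud(vol), cfg)
    write_grain_ply(cl$grains, file.path(out_dir, "spike.ply"),
                    seed = 1L)
  }
  rec
}

#' Write clustered grains as a colored ASCII PLY point cloud
#'
#' One point per voxel, with a random color per grain for visual
#' inspection in any mesh viewer.
#'
#' @param grains list of n x 3 point matrices (e.g. from
#'   [cluster_grains()]).
#' @param path output `.ply` path.
#' @param seed seed for the random grain colors.
#' @return Invisibly, `path`.
#' @export
write_grain_ply <- function(grains, path, seed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  cols <- matrix(sample(40:255, 3 * length(grains), replace = TRUE),
                 ncol = 3)
  n <- sum(vapply(grains, nrow, integer(1)))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE, after = FALSE)
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", n),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue", "end_header"), con)
  for (i in seq_along(grains)) {
    p <- grains[[i]]
    # PLY is x y z: reverse the (z, y, x) columns
    writeLines(sprintf("%g %g %g %d %d %d", p[, 3], p[, 2], p[, 1],
                       cols[i, 1], cols[i, 2], cols[i, 3]), con)
  }
  invisible(path)
}

#' Validate virtual traits against manual measurements from CSV
#'
#' @param traits_csv,manual_csv CSV paths, each with a `spike_id` column
#'   and shared trait columns.
#' @return The [validate_traits()] data frame.
#' @export
run_validate <- function(traits_csv, manual_csv) {
  validate_traits(utils::read.csv(traits_csv),
                  utils::read.csv(manual_csv))
}
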