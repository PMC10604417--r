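#' @title Slice-stack and volume input/output
#' @description Helpers for reading ordered transaxial slice images into a
#'   voxel volume, masking out the specimen-holder ring, resizing slices for
#'   the segmentation network, and stacking binary masks into NIfTI volumes.
#'   The axis convention throughout the package is `(z, y, x)` with z the
#'   slice index in lexicographic filename order; voxels are isotropic cubes
#'   of edge `pixel_size_um`.
#' @name volume_io
NULL

# internal: write a (z, y, x) array to NIfTI as (x, y, z), spacing P/1000 mm
.write_nifti_zyx <- function(vox, pixel_size_um, path,
                             datatype = "uint8") {
  arr <- aperm(vox, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(pixel_size_um / 1000, 3)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an ordered slice stack into a voxel volume
#'
#' Reads every PNG in a directory as an 8-bit grayscale slice and stacks
#' them in lexicographic filename order (z index = position in the sorted
#' list). Filenames must be zero-padded so that lexicographic and numeric
#' order agree; a stack whose trailing slice numbers would sort differently
#' is rejected rather than silently scrambled.
#'
#' @param dir_path directory containing the slice images.
#' @param pixel_size_um isotropic voxel size in micrometres.
#' @param pattern filename regular expression.
#' @return A `voxel_volume`: list with `voxels` (integer array `(z, y, x)`,
#'   0..255), `pixel_size_um`, `source_id`.
#' @export
read_slice_stack <- function(dir_path, pixel_size_um,
                             pattern = "\\.png$") {
  stopifnot(dir.exists(dir_path), pixel_size_um > 0)
  files <- list.files(dir_path, pattern = pattern, full.names = FALSE)
  if (length(files) == 0) stop("no slice images found in ", dir_path)
  lex <- sort(files, method = "radix")
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)\\.[A-Za-z]+$", "\\1",
                                         lex)))
  if (!anyNA(num) && is.unsorted(num))
    stop("slice filenames are not zero-padded: lexicographic order ",
         "disagrees with their numeric order; pad slice numbers with zeros")
  slices <- lapply(file.path(dir_path, lex), function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) { # flatten RGB(A) written from gray data
      warning("non-grayscale slice ", basename(f), " converted to gray")
      img <- img[, , 1]
    }
    matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  })
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slice images have mixed dimensions")
  vox <- array(0L, c(length(slices), dims[1, 1], dims[2, 1]))
  for (z in seq_along(slices)) vox[z, , ] <- slices[[z]]
  structure(list(voxels = vox, pixel_size_um = pixel_size_um,
                 source_id = dir_path),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("voxel_volume:", paste(dim(x$voxels), collapse = " x "),
      "(z, y, x) at", x$pixel_size_um, "um/voxel [", x$source_id, "]\n")
  invisible(x)
}

#' Zero out everything at and beyond a circular region of interest
#'
#' The reconstructed slices show the plastic specimen holder as a bright
#' ring surrounding the spike. Pixels at distance >= `radius` from the ROI
#' centre are set to 0; interior pixels are untouched, so the operation is
#' idempotent and clips circles that extend past the image edge.
#'
#' @param slice 2D numeric matrix `(y, x)`.
#' @param roi list with `center_xy` (`c(x, y)` pixel coordinates) and
#'   `radius` (> 0).
#' @return The masked slice.
#' @seealso [detect_holder()] for estimating `roi` from the data.
#' @export
remove_holder <- function(slice, roi) {
  stopifnot(is.matrix(slice), roi$radius > 0, length(roi$center_xy) == 2)
  ny <- nrow(slice); nx <- ncol(slice)
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  d2 <- (xs - roi$center_xy[1])^2 + (ys - roi$center_xy[2])^2
  slice[d2 >= roi$radius^2] <- 0
  slice
}

#' Estimate the holder ring ROI from a slice
#'
#' Locates the bright holder ring by the radial intensity profile around the
#' image centre: mean intensity per integer radius bin, maximised over the
#' outer half of the image. The returned ROI radius sits `margin` pixels
#' inside the detected ring so that [remove_holder()] erases it entirely.
#'
#' @param slice 2D numeric matrix.
#' @param margin pixels subtracted from the detected ring radius.
#' @return list with `center_xy` and `radius`, usable as the `roi` of
#'   [remove_holder()].
#' @export
detect_holder <- function(slice, margin = 3) {
  ny <- nrow(slice); nx <- ncol(slice)
  ctr <- c((nx + 1) / 2, (ny + 1) / 2)
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  r <- round(sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2))
  prof <- tapply(as.numeric(slice), r, mean)
  radii <- as.numeric(names(prof))
  outer_half <- radii >= max(radii) / 2
  ring_r <- radii[outer_half][which.max(prof[outer_half])]
  list(center_xy = ctr, radius = ring_r - margin)
}

#' Resize a slice for network input or back to scan resolution
#'
#' Intensity slices are resampled bilinearly; masks use nearest-neighbour
#' interpolation so the `{0, 1}` value set is preserved exactly. Resizing a
#' predicted mask back to the original slice dimensions restores them.
#'
#' @param image 2D matrix.
#' @param target `c(h, w)` output dimensions.
#' @param mode `"intensity"` (bilinear) or `"mask"` (nearest-neighbour).
#' @return The resized matrix.
#' @export
resize_slice <- function(image, target, mode = c("intensity", "mask")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(image), length(target) == 2, all(target >= 1))
  if (all(dim(image) == target)) return(image)
  filt <- if (mode == "mask") "none" else "bilinear"
  out <- EBImage::resize(image, w = target[1], h = target[2], filter = filt)
  out <- matrix(as.numeric(out), target[1], target[2])
  if (mode == "mask") out <- (out > 0.5) + 0
  out
}

#' Stack binary masks into a NIfTI volume
#'
#' Writes the ordered per-slice masks as one integer NIfTI volume (the
#' "virtual spike"), with the voxel size recorded in the header as
#' `pixel_size_um / 1000` mm on each axis. The file stores axes as
#' `(x, y, z)`; [load_volume()] returns the package's `(z, y, x)` order and
#' reproduces voxels and pixel size exactly.
#'
#' @param masks list of equal-dimension 2D `{0, 1}` matrices, bottom slice
#'   first, or a 3D `(z, y, x)` array.
#' @param pixel_size_um voxel size in micrometres.
#' @param path output `.nii` / `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
stack_and_save <- function(masks, pixel_size_um, path) {
  if (is.list(masks)) {
    if (length(masks) == 0) stop("empty mask list")
    d <- dim(masks[[1]])
    if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
      stop("masks have mixed dimensions")
    vox <- array(0L, c(length(masks), d))
    for (z in seq_along(masks)) vox[z, , ] <- as.integer(masks[[z]])
  } else {
    stopifnot(length(dim(masks)) == 3)
    vox <- masks
  }
  if (!all(vox %in% c(0L, 1L) | vox %in% c(0, 1)))
    stop("masks must be binary {0,1}")
  .write_nifti_zyx(vox, pixel_size_um, path)
}

#' Load a stacked volume written by [stack_and_save()]
#'
#' @param path NIfTI file path.
#' @return list with `voxels` (integer array `(z, y, x)`) and
#'   `pixel_size_um` recovered from the header.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  vox <- aperm(array(as.integer(img), dim(img)), c(3, 2, 1))
  # header spacing is float32; 7 significant digits recovers the written P
  list(voxels = vox, pixel_size_um = signif(pd[1] * 1000, 7))
}
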