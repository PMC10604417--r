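# Shared phantom constructions for the tests. Sizes are scaled down so the
# full suite runs on one CPU: training phantoms are 64x64 slices, the tiny
# "micro" phantoms 32x32 for fast training-behaviour checks.

# 64x64 phantom used for network training and the end-to-end run
training_phantom_spec <- function(seed, nz = 210, noise_sd = 12,
                                  grain_count = 19) {
  phantom_spec(
    grain_count = grain_count,
    semi_axes_range = list(a = c(6, 7.5), b = c(4, 5), c = c(3.2, 4)),
    axial_spacing = 10, rachis_radius = 2.5, grain_tilt_deg = 8,
    holder = list(center_xy = NULL, radius = 28, ring_width = 2),
    noise_sd = noise_sd, volume_dims = c(nz, 64, 64),
    pixel_size_um = 85, seed = seed)
}

training_roi <- function() list(center_xy = c(32.5, 32.5), radius = 26)

# 32x32 phantom for very small training runs
micro_phantom_spec <- function(seed, nz = 96, noise_sd = 10,
                               grain_count = 12) {
  phantom_spec(
    grain_count = grain_count,
    semi_axes_range = list(a = c(3, 3.6), b = c(2.4, 2.9), c = c(2, 2.3)),
    axial_spacing = 7, rachis_radius = 1.5, grain_tilt_deg = 5,
    holder = list(center_xy = NULL, radius = 14, ring_width = 2),
    noise_sd = noise_sd, volume_dims = c(nz, 32, 32),
    pixel_size_um = 85, seed = seed)
}

micro_roi <- function() list(center_xy = c(16.5, 16.5), radius = 12)

# holder-removed slices + binary truth masks from a generated phantom
slices_and_masks <- function(ph, n, roi) {
  list(images = lapply(seq_len(n), function(z)
         remove_holder(ph$volume$voxels[z, , ], roi)),
       masks = lapply(seq_len(n), function(z)
         (ph$truth$label_volume[z, , ] > 0) + 0))
}

# one shared scaled-down training run (depth 4, base 16, 200 slices at
# 64x64, 10 epochs, fixed seed), cached across test files
.test_cache <- new.env(parent = emptyenv())

trained_phantom_model <- function() {
  if (is.null(.test_cache$fit)) {
    ph <- generate_phantom(training_phantom_spec(seed = 11))
    td <- slices_and_masks(ph, 200, training_roi())
    .test_cache$fit <- train_unet(td$images, td$masks,
                                  cfg = list(epochs = 10, batch_size = 4,
                                             input_size = 64, seed = 1))
  }
  .test_cache$fit
}
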