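#' Build the per-slice grain segmentation network
#'
#' Constructs a classic UNet: an encoder of `depth` levels (two 3x3
#' convolutions + ReLU per level, 2x2 max pooling between levels, channel
#' width doubling from `base_channels`), a two-convolution bottleneck, and
#' a mirrored decoder (nearest-neighbour 2x upsampling + convolution, skip
#' concatenation with the matching encoder level, two convolutions), ending
#' in a 1x1 convolution to a single logit channel. Input is one grayscale
#' channel; `sigmoid(logit) > 0.5` gives the grain mask. Weights are
#' He-initialised from a fixed seed, so two builds with the same arguments
#' are identical.
#'
#' @param depth number of resolution levels (>= 2); input height and width
#'   must be divisible by `2^depth`.
#' @param base_channels channel width of the first level (>= 4).
#' @param seed integer seed for weight initialisation.
#' @return A `seg_model` object (list of convolution parameters plus
#'   architecture metadata).
#' @export
build_unet <- function(depth = 4, base_channels = 16, seed = 1L) {
  stopifnot(depth >= 2, base_channels >= 4)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  ch <- base_channels * 2^(seq_len(depth) - 1)
  params <- list()
  mk3 <- function(cin, cout) {
    list(W = matrix(rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin))),
                    9 * cin, cout),
         b = rep(0, cout), kind = "conv3")
  }
  mk1 <- function(cin, cout) {
    list(W = matrix(rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
         b = rep(0, cout), kind = "conv1")
  }
  for (i in seq_len(depth)) {
    cin <- if (i == 1) 1 else ch[i - 1]
    params[[sprintf("enc%d_c1", i)]] <- mk3(cin, ch[i])
    params[[sprintf("enc%d_c2", i)]] <- mk3(ch[i], ch[i])
  }
  cb <- 2 * ch[depth]
  params[["bott_c1"]] <- mk3(ch[depth], cb)
  params[["bott_c2"]] <- mk3(cb, cb)
  for (i in rev(seq_len(depth))) {
    cab <- if (i == depth) cb else ch[i + 1]  # channels arriving from below
    params[[sprintf("dec%d_up", i)]] <- mk3(cab, ch[i])
    params[[sprintf("dec%d_c1", i)]] <- mk3(2 * ch[i], ch[i])
    params[[sprintf("dec%d_c2", i)]] <- mk3(ch[i], ch[i])
  }
  params[["final"]] <- mk1(ch[1], 1)
  structure(list(params = params, depth = depth,
                 base_channels = base_channels, seed = seed),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                   numeric(1)))
  cat("seg_model: UNet depth", x$depth, "base", x$base_channels,
      "-", format(np, big.mark = ","), "parameters\n")
  invisible(x)
}

#' Train the segmentation network on paired slices and masks
#'
#' Minimises mean binary cross-entropy on logits with the Adam optimiser,
#' shuffling the training pairs each epoch and averaging gradients over
#' mini-batches. The checkpoint with the smallest epoch loss is returned
#' (not the final epoch), together with the full loss history. Training is
#' deterministic for a fixed config and seed.
#'
#' @param images list of 2D slices, grey values 0..255 (normalised to 0..1
#'   internally).
#' @param masks list of `{0, 1}` matrices, one per image, same dimensions.
#' @param cfg list of training settings; unset entries take the defaults
#'   `epochs = 40`, `batch_size = 4`, `input_size = 512`, `lr = 1e-3`,
#'   `beta1 = 0.9`, `beta2 = 0.999`, `adam_eps = 1e-8`, `seed = 1`. Slices
#'   are resized to `input_size` (bilinear; masks nearest-neighbour) when
#'   their dimensions differ.
#' @param model optionally a pre-built [build_unet()] model to continue
#'   from; by default a fresh `depth = 4`, `base_channels = 16` UNet seeded
#'   from `cfg$seed`.
#' @return list with `model` (best checkpoint, a `seg_model`) and
#'   `loss_history` (numeric, one mean BCE per epoch).
#' @export
train_unet <- function(images, masks, cfg = list(), model = NULL) {
  defaults <- list(epochs = 40L, batch_size = 4L, input_size = 512L,
                   lr = 1e-3, beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                   seed = 1L, depth = 4L, base_channels = 16L)
  cfg <- utils::modifyList(defaults, cfg)
  stopifnot(cfg$epochs >= 1, cfg$batch_size >= 1, length(images) >= 1,
            length(images) == length(masks))
  for (k in seq_along(images)) {
    if (!identical(dim(images[[k]]), dim(masks[[k]])))
      stop("image/mask dimension mismatch at pair ", k)
    if (!all(masks[[k]] %in% c(0, 1)))
      stop("mask values outside {0,1} at pair ", k)
  }
  tgt <- c(cfg$input_size, cfg$input_size)
  xs <- lapply(images, function(im) {
    resize_slice(im, tgt, mode = "intensity") / 255
  })
  ys <- lapply(masks, function(mk) resize_slice(mk, tgt, mode = "mask"))

  if (is.null(model))
    model <- build_unet(cfg$depth, cfg$base_channels, seed = cfg$seed)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(cfg$seed + 1L)

  mstate <- vstate <- lapply(model$params, function(p)
    list(W = p$W * 0, b = p$b * 0))
  step <- 0L
  n <- length(xs)
  loss_history <- numeric(cfg$epochs)
  best_loss <- Inf
  best_params <- model$params

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_losses <- numeric(n)
    bstarts <- seq(1, n, by = cfg$batch_size)
    for (bs in bstarts) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1, n)]
      acc <- NULL
      for (k in idx) {
        r <- .unet_grad(model$params, model$depth, xs[[k]], ys[[k]])
        ep_losses[match(k, ord)] <- r$loss
        gr <- r$grads
        if (is.null(acc)) acc <- gr else {
          for (nm in names(gr)) {
            acc[[nm]]$W <- acc[[nm]]$W + gr[[nm]]$W
            acc[[nm]]$b <- acc[[nm]]$b + gr[[nm]]$b
          }
        }
      }
      scale <- 1 / length(idx)
      step <- step + 1L
      bc1 <- 1 - cfg$beta1^step
      bc2 <- 1 - cfg$beta2^step
      for (nm in names(model$params)) {
        for (f in c("W", "b")) {
          g <- acc[[nm]][[f]] * scale
          mstate[[nm]][[f]] <- cfg$beta1 * mstate[[nm]][[f]] +
            (1 - cfg$beta1) * g
          vstate[[nm]][[f]] <- cfg$beta2 * vstate[[nm]][[f]] +
            (1 - cfg$beta2) * g^2
          model$params[[nm]][[f]] <- model$params[[nm]][[f]] -
            cfg$lr * (mstate[[nm]][[f]] / bc1) /
              (sqrt(vstate[[nm]][[f]] / bc2) + cfg$adam_eps)
        }
      }
    }
    loss_history[ep] <- mean(ep_losses)
    if (loss_history[ep] < best_loss) {
      best_loss <- loss_history[ep]
      best_params <- model$params
    }
  }
  best <- model
  best$params <- best_params
  list(model = best, loss_history = loss_history)
}

#' Predict a binary grain mask for one slice
#'
#' Normalises the slice, resizes it to `input_size` if needed, runs the
#' network, thresholds `sigmoid(logits)` at 0.5 and resizes the mask back
#' to the original slice dimensions (nearest-neighbour).
#'
#' @param model a trained `seg_model`.
#' @param slice 2D matrix, grey values 0..255.
#' @param input_size network input size; `NULL` keeps the slice dimensions.
#' @return `{0, 1}` matrix with the dimensions of `slice`.
#' @export
predict_mask <- function(model, slice, input_size = NULL) {
  stopifnot(inherits(model, "seg_model"), is.matrix(slice))
  orig <- dim(slice)
  x <- slice
  if (!is.null(input_size) && !all(orig == input_size))
    x <- resize_slice(x, c(input_size, input_size), mode = "intensity")
  logits <- .unet_infer(model$params, model$depth, x / 255)
  mask <- (logits > 0) + 0   # sigmoid(l) > 0.5  <=>  l > 0
  if (!all(dim(mask) == orig))
    mask <- resize_slice(mask, orig, mode = "mask")
  mask
}

#' Save / load a network checkpoint
#'
#' Checkpoints embed the architecture and seed so a loaded model is
#' self-describing.
#'
#' @param model a `seg_model`.
#' @param path file path (`.rds`).
#' @return `save_unet` invisibly returns `path`; `load_unet` returns the
#'   `seg_model`.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "seg_model"))
  model
}
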