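test_that("Otsu separates a bimodal image and matches exhaustive search", {
  img <- matrix(c(rep(50, 128), rep(200, 128)), 16, 16)
  ot <- otsu_threshold(img)
  expect_false(ot$degenerate)
  bin <- (img > ot$threshold) + 0
  expect_identical(bin, (img == 200) + 0)
  set.seed(42)
  for (k in 1:30) {
    m <- matrix(sample(0:255, 256, replace = TRUE,
                       prob = runif(256)^2), 16, 16)
    expect_identical(otsu_threshold(m)$threshold, oracle_otsu(m))
  }
  expect_warning(res <- otsu_threshold(matrix(7, 5, 5)), "degenerate")
  expect_true(res$degenerate)
})

test_that("masked Otsu uses only in-mask pixels", {
  img <- matrix(0, 10, 10)
  mask <- matrix(0, 10, 10)
  img[1:5, ] <- c(rep(30, 25), rep(190, 25))
  mask[1:5, ] <- 1
  img[6:10, ] <- 255   # bright outside-mask pixels must not matter
  ot <- otsu_threshold(img, within_mask = mask)
  expect_identical(ot$threshold, oracle_otsu(img[1:5, ]))
})

test_that("segmentation metrics match the confusion-count oracle", {
  # worked half-vs-all example
  truth <- cbind(matrix(1, 10, 5), matrix(0, 10, 5))
  pred <- matrix(1, 10, 10)
  m <- seg_metrics(pred, truth)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 1.0)
  expect_equal(m$iou, 0.5)
  expect_equal(m$iou_background, 0.0)
  expect_equal(m$miou, 0.25)
  # direct confusion counts: TP=3 FP=1 FN=1
  p2 <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  t2 <- matrix(c(1, 1, 1, 0, 1, 0), 2, 3)
  m2 <- seg_metrics(p2, t2)
  expect_equal(m2$precision, 0.75)
  expect_equal(m2$recall, 0.75)
  expect_equal(m2$iou, 0.6)
  # identity
  mi <- seg_metrics(t2, t2)
  expect_equal(c(mi$precision, mi$recall, mi$miou, mi$mpa,
                 mi$pixel_accuracy), rep(1, 5))
  set.seed(7)
  for (k in 1:30) {
    a <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    b <- matrix(rbinom(256, 1, runif(1)), 16, 16)
    got <- seg_metrics(a, b)
    want <- oracle_seg_metrics(a, b)
    for (f in names(want)) expect_identical(got[[f]], want[[f]])
  }
  expect_error(seg_metrics(matrix(0, 2, 2), matrix(0, 3, 3)), "differ")
})

test_that("assisted segmentation refines but never grows the prediction", {
  expect_identical(assisted_segment(matrix(runif(64) * 255, 8, 8),
                                    matrix(0, 8, 8)),
                   matrix(0, 8, 8))
  # constant-bright region inside a partial mask: zeros anchor the dark
  # class, so the whole prediction survives
  img <- matrix(255, 8, 8)
  set.seed(5)
  pred <- matrix(rbinom(64, 1, 0.5), 8, 8)
  pred[1] <- 0; pred[2] <- 1
  expect_identical(assisted_segment(img, pred), pred)
  # all-ones prediction over a flat slice: degenerate, returned unchanged
  ones <- matrix(1, 8, 8)
  expect_warning(out <- assisted_segment(img, ones), "degenerate")
  expect_identical(out, ones)
  # an accurate mask over clean tissue passes through intact
  img2 <- matrix(20, 12, 12)
  img2[4:9, 4:9] <- 170
  acc <- matrix(0, 12, 12); acc[4:9, 4:9] <- 1
  expect_identical(assisted_segment(img2, acc), acc)
  set.seed(13)
  for (k in 1:20) {
    img <- matrix(sample(0:255, 400, TRUE), 20, 20)
    pred <- matrix(rbinom(400, 1, 0.4), 20, 20)
    out <- suppressWarnings(assisted_segment(img, pred))
    expect_true(all(out[pred == 0] == 0))   # subset of the prediction
  }
})

test_that("a dilated prediction is repaired toward the truth", {
  spec <- training_phantom_spec(seed = 9, nz = 32, grain_count = 2)
  ph <- generate_phantom(spec)
  z <- round(ph$truth$grains$cz[1])
  sl <- remove_holder(ph$volume$voxels[z, , ], training_roi())
  truth <- (ph$truth$label_volume[z, , ] > 0) + 0
  # dilate truth by ~3 px to mimic an over-segmenting network output
  kern <- EBImage::makeBrush(7, "disc")
  dil <- (EBImage::dilate(truth, kern) > 0) + 0
  out <- assisted_segment(sl, dil)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(iou(out, truth), iou(dil, truth))
})

test_that("network construction is deterministic with contract shapes", {
  m1 <- build_unet(depth = 3, base_channels = 8, seed = 5)
  m2 <- build_unet(depth = 3, base_channels = 8, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_unet(depth = 3, base_channels = 8, seed = 6)
  expect_false(identical(m1$params, m3$params))
  # logit map keeps spatial dims; indivisible dims are rejected
  x <- matrix(runif(64 * 64) * 255, 64, 64)
  mask <- predict_mask(m1, x)
  expect_equal(dim(mask), c(64, 64))
  expect_true(all(mask %in% c(0, 1)))
  m4 <- build_unet(depth = 4, base_channels = 4, seed = 1)
  expect_error(predict_mask(m4, matrix(0, 24, 24)), "divisible")
})

test_that("training is deterministic, validates masks, returns best epoch", {
  ph <- generate_phantom(micro_phantom_spec(seed = 21))
  td <- slices_and_masks(ph, 12, micro_roi())
  cfg <- list(epochs = 3, batch_size = 4, input_size = 32, depth = 2,
              base_channels = 4, seed = 2)
  f1 <- train_unet(td$images, td$masks, cfg)
  f2 <- train_unet(td$images, td$masks, cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_length(f1$loss_history, 3)
  expect_identical(f1$model$params, f2$model$params)
  bad <- td$masks
  bad[[3]][1, 1] <- 2
  expect_error(train_unet(td$images, bad, cfg), "outside")
  expect_error(train_unet(td$images, td$masks[-1], cfg))
})

test_that("a model trained on empty masks predicts background", {
  imgs <- lapply(1:8, function(i) matrix(runif(32 * 32) * 255, 32, 32))
  msks <- lapply(1:8, function(i) matrix(0, 32, 32))
  fit <- train_unet(imgs, msks, list(epochs = 30, batch_size = 4,
                                     input_size = 32, depth = 2,
                                     base_channels = 4, seed = 3,
                                     lr = 0.01))
  expect_identical(predict_mask(fit$model, imgs[[1]]),
                   matrix(0, 32, 32))
})

test_that("segmentation quality does not improve when noise is added", {
  cfg <- list(epochs = 6, batch_size = 4, input_size = 32, depth = 2,
              base_channels = 8, seed = 4)
  iou_at_noise <- function(noise_sd) {
    ph <- generate_phantom(micro_phantom_spec(seed = 31,
                                              noise_sd = noise_sd))
    td <- slices_and_masks(ph, 48, micro_roi())
    fit <- train_unet(td$images, td$masks, cfg)
    ph2 <- generate_phantom(micro_phantom_spec(seed = 32,
                                               noise_sd = noise_sd))
    held <- slices_and_masks(ph2, 48, micro_roi())
    pred <- lapply(held$images, function(s) predict_mask(fit$model, s))
    seg_metrics(array(unlist(pred), c(32, 32, 48)),
                array(unlist(held$masks), c(32, 32, 48)))$iou
  }
  expect_gte(iou_at_noise(0), iou_at_noise(20))
})
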