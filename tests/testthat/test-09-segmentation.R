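test_that("Dice and IoU follow the overlap definitions and conventions", {
  g <- as_label_mask(rbind(c(1L, 1L, 0L), c(0L, 0L, 0L), c(0L, 0L, 0L)))
  expect_equal(dice_iou(g, g, 1L), c(dsc = 1, iou = 1))
  p <- as_label_mask(rbind(c(0L, 0L, 0L), c(0L, 0L, 1L), c(0L, 1L, 0L)))
  expect_equal(dice_iou(p, g, 1L), c(dsc = 0, iou = 0))
  # |P| = 4, |G| = 2, overlap 2 -> DSC 2/3, IoU 1/2
  gg <- matrix(0L, 4, 4); gg[1, 1:2] <- 1L
  pp <- matrix(0L, 4, 4); pp[1, 1:4] <- 1L
  m <- dice_iou(as_label_mask(pp), as_label_mask(gg), 1L)
  expect_equal(m[["dsc"]], 2 / 3, tolerance = 1e-12)
  expect_equal(m[["iou"]], 1 / 2, tolerance = 1e-12)
  # empty-class conventions
  z <- as_label_mask(matrix(0L, 3, 3))
  expect_equal(dice_iou(z, z, 2L), c(dsc = 1, iou = 1))
  expect_equal(dice_iou(p, z, 1L), c(dsc = 0, iou = 0))
  expect_error(dice_iou(z, as_label_mask(matrix(0L, 2, 2)), 1L), "match")
})

test_that("DSC equals 2 IoU / (1 + IoU) across random mask pairs", {
  set.seed(41)
  for (i in 1:200) {
    a <- as_label_mask(matrix(sample(0:3, 64, replace = TRUE, prob = c(.55, .15, .15, .15)), 8, 8))
    b <- as_label_mask(matrix(sample(0:3, 64, replace = TRUE, prob = c(.55, .15, .15, .15)), 8, 8))
    for (k in 1:3) {
      m <- dice_iou(a, b, k)
      expect_equal(m[["dsc"]], 2 * m[["iou"]] / (1 + m[["iou"]]), tolerance = 1e-12)
    }
  }
})

test_that("spatial augmentations warp image and mask identically", {
  pair <- toy_phantoms(1L, grid = 32L)[[1]]
  # identity parameters reproduce the input exactly
  ident <- list(rot = c(0, 0), trans = c(0, 0), scale = c(1, 1), shear = c(0, 0))
  a0 <- affine_augment(pair, ident, seed = 1L)
  expect_equal(a0$image, pair$image)
  expect_identical(unclass(a0$mask), unclass(pair$mask))
  # 90-degree rotation about the center equals an index remap
  rot90 <- list(rot = c(90, 90), trans = c(0, 0), scale = c(1, 1), shear = c(0, 0))
  a9 <- affine_augment(pair, rot90, seed = 1L)
  H <- 32L
  want <- matrix(0, H, H)
  for (r in 1:H) for (cc in 1:H) {
    # inverse rotation by -90 about the center maps (r,c) to (c, H+1-r)
    want[r, cc] <- pair$image[cc, H + 1L - r]
  }
  expect_equal(a9$image, want, tolerance = 1e-9)
  # augmented masks remain valid label masks
  e <- elastic_augment(pair, sigma = 3, alpha = 2, seed = 2L)
  expect_true(all(e$mask %in% 0:3))
  expect_identical(dim(e$mask), dim(pair$mask))
  expect_identical(affine_augment(pair, seed = 5L)$image,
                   affine_augment(pair, seed = 5L)$image)
})

test_that("intensity augmentation changes only the image", {
  pair <- toy_phantoms(1L)[[1]]
  it <- intensity_augment(pair, seed = 3L)
  expect_identical(unclass(it$mask), unclass(pair$mask))
  expect_false(identical(it$image, pair$image))
  expect_true(all(abs(it$image) <= 1))
})

test_that("CutMix pastes the box region of B into A", {
  ps <- toy_phantoms(2L)
  a <- ps[[1]]; b <- ps[[2]]
  full <- cutmix_augment(a, b, box = c(1L, 32L, 1L, 32L))
  expect_equal(full$image, b$image)
  expect_identical(unclass(full$mask), unclass(b$mask))
  half <- cutmix_augment(a, b, box = c(1L, 16L, 1L, 32L))
  expect_equal(mean(half$image == b$image | half$image == a$image), 1)
  expect_equal(half$image[1:16, ], b$image[1:16, ])
  expect_equal(half$image[17:32, ], a$image[17:32, ])
  # mixed-pixel fraction is exactly the box area ratio
  expect_equal(mean(row(half$image) <= 16), 0.5)
  # random box: every pixel positionally traced to its source
  rb <- cutmix_augment(a, b, seed = 7L)
  box <- rb$provenance$box
  inside <- matrix(FALSE, 32, 32); inside[box[1]:box[2], box[3]:box[4]] <- TRUE
  expect_equal(rb$image[inside], b$image[inside])
  expect_equal(rb$image[!inside], a$image[!inside])
  expect_equal(unclass(rb$mask)[inside], unclass(b$mask)[inside])
  expect_error(cutmix_augment(a, b, box = c(5L, 4L, 1L, 2L)), "empty box")
})

test_that("the segmentation U-Net overfits a single pair and reproduces", {
  pair <- toy_phantoms(1L, noise_sd = 0.02)[[1]]
  cfg <- seg_config(n_levels = 3L, channels = c(8L, 16L, 32L), norm_groups = 4L,
                    epochs = 160L, batch_size = 1L, lr = 2e-3)
  m <- train_unet_seg(list(pair), list(pair), cfg, seed = 2L)
  pred <- predict_seg(m, list(pair$image))[[1]]
  expect_gt(seg_metrics(pred, pair$mask)[["mean_dice"]], 0.95)
  cfg_s <- seg_config(n_levels = 3L, channels = c(8L, 16L, 32L), norm_groups = 4L,
                      epochs = 4L, batch_size = 1L, lr = 2e-3)
  m1 <- train_unet_seg(list(pair), list(pair), cfg_s, seed = 3L)
  m2 <- train_unet_seg(list(pair), list(pair), cfg_s, seed = 3L)
  expect_identical(m1$val_history, m2$val_history)
  expect_error(train_unet_seg(list(), list(), cfg_s), "empty")
})

test_that("the experiment harness emits one metrics row per regime request", {
  ds <- list(train = toy_phantoms(6L, seed_base = 100L),
             val = toy_phantoms(2L, seed_base = 200L),
             test = toy_phantoms(3L, seed_base = 300L))
  cfg <- seg_config(n_levels = 2L, channels = c(8L, 16L), norm_groups = 4L,
                    epochs = 2L, batch_size = 4L, lr = 1e-3)
  tab <- run_experiment(ds, regimes = c("none", "none", "affine"), seg_cfg = cfg,
                        n_aug = 4L, seeds = 1L)
  expect_equal(nrow(tab), 3L)
  expect_identical(tab$regime, c("none", "none", "affine"))
  # duplicate regime reuses the cached run
  expect_identical(as.list(tab[1, -1]), as.list(tab[2, -1]))
  metric_cols <- setdiff(names(tab), c("regime", "seed"))
  expect_true(all(tab[, metric_cols] >= 0 & tab[, metric_cols] <= 1))
  # diffusion regime without checkpoints is a hard error
  expect_error(run_experiment(ds, regimes = "diffusion", seg_cfg = cfg),
               "checkpoint")
})
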