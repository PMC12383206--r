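test_that("nearest-neighbour mask resize replicates and subsamples as specified", {
  m <- as_label_mask(matrix(c(0L, 1L, 2L, 3L), 2, 2))
  oh <- encode_mask(m)
  up <- resize_mask_to(oh, c(4L, 4L))
  for (i in 1:2) for (j in 1:2)
    for (di in 0:1) for (dj in 0:1)
      expect_equal(up[2 * i - 1 + di, 2 * j - 1 + dj, ], oh[i, j, ])
  # downscale keeps the top-left pixel of each block
  m4 <- as_label_mask(matrix(sample(0:3, 16, replace = TRUE), 4, 4))
  oh4 <- encode_mask(m4)
  down <- resize_mask_to(oh4, c(2L, 2L))
  for (i in 1:2) for (j in 1:2)
    expect_equal(down[i, j, ], oh4[2 * i - 1, 2 * j - 1, ])
  # one-hotness is preserved by any power-of-2 resize
  for (target in list(c(8L, 8L), c(2L, 2L))) {
    r <- resize_mask_to(oh4, target)
    expect_true(all(apply(r == 1, c(1, 2), sum) == 1))
  }
  expect_error(resize_mask_to(oh4, c(3L, 3L)), "power of 2")
})

test_that("SPADE with zero-initialized heads is exactly group normalization", {
  set.seed(2)
  feats <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  mm <- matrix(0L, 8, 8)
  mm[3:6, 3:6] <- 2L; mm[4:5, 4:5] <- 1L; mm[3:4, 7] <- 3L
  mask <- encode_mask(as_label_mask(mm))
  head <- spade_head_params(4L, 16L, 8L, seed = 3L, zero_init = TRUE)
  out <- spade_modulate(feats, mask, head, groups = 4L)
  tp <- cardiacaug:::ad_tape()
  gn <- cardiacaug:::ad_groupnorm(tp, cardiacaug:::ad_leaf(tp, feats), 4L)$val
  expect_identical(out, gn)
  # constant features normalize to zero; a beta offset shifts the output to b
  headb <- head
  headb$sb_b <- rep(0.37, 8)
  cf <- array(5, c(8, 8, 8, 1))
  outb <- spade_modulate(cf, mask, headb, groups = 4L)
  expect_equal(outb, array(0.37, dim(cf)), tolerance = 1e-9)
  # shape contract on other sizes
  f2 <- array(rnorm(4 * 4 * 8 * 3), c(4, 4, 8, 3))
  expect_identical(dim(spade_modulate(f2, mask, head, groups = 2L)), dim(f2))
})

test_that("conditional backbone equals the unconditional one at initialization", {
  cfg_u <- toy_backbone_cfg(conditional = FALSE)
  cfg_c <- toy_backbone_cfg(conditional = TRUE)
  mu <- build_denoiser(cfg_u, seed = 44L)
  mc <- build_denoiser(cfg_c, seed = 44L)
  set.seed(3)
  x <- array(rnorm(32 * 32 * 4 * 2), c(32, 32, 4, 2))
  cond <- array(0, c(32, 32, 4, 2))
  for (i in 1:2)
    cond[, , , i] <- encode_mask(generate_phantom(phantom_spec(32L, seed = i))$mask)
  expect_equal(denoise(mc, x, 7L, cond), denoise(mu, x, 7L), tolerance = 1e-12)
})

test_that("conditional LDM training requires a trained autoencoder and descends", {
  pairs <- toy_phantoms(12L)
  cfg_c <- backbone_config(2L, c(8L, 16L), resblocks_per_level = 1L,
                           attention_levels = integer(0), norm_groups = 4L,
                           conditional = TRUE, in_channels = 4L, out_channels = 4L,
                           time_dim = 16L)
  expect_error(train_conditional_ldm(pairs, build_autoencoder(toy_ae_cfg()), cfg_c),
               "trained")
  ae <- train_autoencoder(lapply(pairs, `[[`, "image"), toy_ae_cfg(),
                          steps = 60L, lr = 2e-3, seed = 1L)
  m1 <- train_conditional_ldm(pairs, ae, cfg_c, make_schedule(), steps = 100L,
                              batch_size = 8L, lr = 1e-3, seed = 3L)
  expect_lt(mean(utils::tail(m1$loss_history, 40)),
            mean(utils::head(m1$loss_history, 40)))
  m2 <- train_conditional_ldm(pairs, ae, cfg_c, make_schedule(), steps = 100L,
                              batch_size = 8L, lr = 1e-3, seed = 3L)
  expect_identical(m1$loss_history, m2$loss_history)
})

test_that("dropping every condition makes real masks irrelevant", {
  pairs <- toy_phantoms(6L)
  ae <- train_autoencoder(lapply(pairs, `[[`, "image"), toy_ae_cfg(),
                          steps = 40L, lr = 2e-3, seed = 1L)
  cfg_c <- backbone_config(2L, c(8L, 16L), resblocks_per_level = 1L,
                           attention_levels = integer(0), norm_groups = 4L,
                           conditional = TRUE, in_channels = 4L, out_channels = 4L,
                           time_dim = 16L)
  # with p_uncond = 1 the same images with scrambled masks train identically
  pairs_scrambled <- lapply(pairs, function(p) {
    p$mask <- as_label_mask(matrix(sample(0:3, length(p$mask), replace = TRUE),
                                   nrow(p$mask)))
    p
  })
  a <- train_conditional_ldm(pairs, ae, cfg_c, make_schedule(), steps = 50L,
                             batch_size = 4L, lr = 1e-3, p_uncond = 1, seed = 5L)
  b <- train_conditional_ldm(pairs_scrambled, ae, cfg_c, make_schedule(),
                             steps = 50L, batch_size = 4L, lr = 1e-3,
                             p_uncond = 1, seed = 5L)
  expect_identical(a$loss_history, b$loss_history)
  expect_identical(a$params, b$params)
})

test_that("synthesis is deterministic, one image per mask, in decoder range", {
  pairs <- toy_phantoms(8L)
  ae <- train_autoencoder(lapply(pairs, `[[`, "image"), toy_ae_cfg(),
                          steps = 40L, lr = 2e-3, seed = 1L)
  cfg_c <- backbone_config(2L, c(8L, 16L), resblocks_per_level = 1L,
                           attention_levels = integer(0), norm_groups = 4L,
                           conditional = TRUE, in_channels = 4L, out_channels = 4L,
                           time_dim = 16L)
  ldm <- train_conditional_ldm(pairs, ae, cfg_c, make_schedule(), steps = 60L,
                               batch_size = 4L, lr = 1e-3, seed = 2L)
  masks <- lapply(pairs[1:3], `[[`, "mask")
  i1 <- synthesize_images(ldm, ae, masks, guidance_w = 1.5, n_steps = 6L, seed = 9L)
  i2 <- synthesize_images(ldm, ae, masks, guidance_w = 1.5, n_steps = 6L, seed = 9L)
  expect_identical(i1, i2)
  expect_length(i1, 3L)
  for (im in i1) {
    expect_identical(dim(im), c(32L, 32L))
    expect_true(all(abs(im) <= 1))
  }
  expect_error(synthesize_images(ldm, ae, masks, guidance_w = -1), ">= 0")
})

test_that("synthesized images are structurally aligned with their masks", {
  # toy-trained stack; two phantoms with clearly different LV areas
  ldm <- toy_ldm()
  ae <- toy_autoencoder()
  p1 <- generate_phantom(phantom_spec(grid_size = 32L, seed = 901L,
                                      lv_radius_range = c(0.17, 0.18)))
  p2 <- generate_phantom(phantom_spec(grid_size = 32L, seed = 902L,
                                      lv_radius_range = c(0.12, 0.13)))
  imgs <- synthesize_images(ldm, ae, list(p1$mask, p2$mask), guidance_w = 1.5,
                            n_steps = 50L, eta = 1, seed = 21L)
  means <- phantom_spec()$intensity_means
  for (i in 1:2) {
    msk <- list(p1$mask, p2$mask)[[i]]
    lv_mean <- mean(imgs[[i]][unclass(msk) == 1L])
    # inside the LV region, intensity resembles LV blood pool, not background
    expect_lt(abs(lv_mean - means[2]), abs(lv_mean - means[1]))
  }
})
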