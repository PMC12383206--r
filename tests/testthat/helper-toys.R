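# Shared toy fixtures: small phantoms and cached trained models so that
# expensive training runs are reused across test files within one session.

toy_backbone_cfg <- function(conditional = FALSE, in_channels = 4L) {
  backbone_config(n_levels = 3L, channels = c(8L, 16L, 32L),
                  resblocks_per_level = 1L, attention_levels = 3L,
                  norm_groups = 4L, conditional = conditional,
                  in_channels = in_channels, out_channels = in_channels)
}

toy_ae_cfg <- function() {
  ae_config(n_levels = 3L, channels = c(8L, 16L, 32L), f = 4L,
            latent_channels = 4L, norm_groups = 4L)
}

toy_phantoms <- function(n, grid = 32L, seed_base = 7000L, noise_sd = 0.05) {
  lapply(seq_len(n), function(i)
    generate_phantom(phantom_spec(grid_size = grid, noise_sd = noise_sd,
                                  seed = seed_base + i)))
}

.toy_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.toy_cache[[key]])) .toy_cache[[key]] <- force(expr)
  .toy_cache[[key]]
}

# The toy generative stack used by the heavier smoke/acceptance checks:
# mask DDPM on 200 phantom masks, autoencoder + conditional LDM on the
# training split of a 200-phantom dataset.
toy_mask_model <- function() cached("mask_ddpm", {
  masks <- lapply(toy_phantoms(200L), `[[`, "mask")
  train_mask_ddpm(masks, toy_backbone_cfg(), make_schedule(),
                  steps = 2000L, batch_size = 8L, lr = 1.5e-3, seed = 11L,
                  ema_decay = 0.997)
})

toy_memorization_model <- function() cached("memorization", {
  target <- generate_phantom(phantom_spec(grid_size = 32L, seed = 42L))$mask
  model <- train_mask_ddpm(rep(list(target), 4L), toy_backbone_cfg(),
                           make_schedule(), steps = 1500L, batch_size = 4L,
                           lr = 2e-3, seed = 3L, ema_decay = 0.995)
  list(model = model, target = target)
})

toy_dataset <- function() cached("dataset", {
  generate_dataset(200L, phantom_spec(grid_size = 32L), seed = 70L)
})

toy_autoencoder <- function() cached("autoencoder", {
  imgs <- lapply(toy_dataset()$train, `[[`, "image")
  train_autoencoder(imgs, toy_ae_cfg(), steps = 800L, batch_size = 8L,
                    lr = 1e-3, seed = 5L)
})

toy_ldm <- function() cached("ldm", {
  train_conditional_ldm(toy_dataset()$train, toy_autoencoder(),
                        backbone_config(n_levels = 2L, channels = c(32L, 64L),
                                        resblocks_per_level = 1L,
                                        attention_levels = 2L, norm_groups = 4L,
                                        conditional = TRUE, in_channels = 4L,
                                        out_channels = 4L),
                        make_schedule(), steps = 2500L, batch_size = 8L,
                        lr = 1e-3, p_uncond = 0.1, seed = 9L,
                        ema_decay = 0.997)
})
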