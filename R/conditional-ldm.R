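# ---------------------------------------------------------------------------
# Stage 2: mask-conditioned latent diffusion. The diffusion U-Net runs in
# the autoencoder's latent space; its decoder resblocks are modulated by
# SPADE so generated images align pixelwise with the conditioning mask.
# Classifier-free training drops the condition to an all-background null
# mask with probability p_uncond; sampling mixes conditional and
# unconditional predictions with a guidance weight.
# ---------------------------------------------------------------------------

#' Nearest-neighbour resize of a one-hot mask tensor
#'
#' Up- or downscales by a power-of-2 ratio. Upscaling replicates each pixel
#' into an `f x f` block; downscaling takes the top-left source pixel of
#' each block. Either way every output pixel equals some input pixel, so
#' one-hotness is preserved exactly.
#' @param mask_onehot `H x W x K` or `H x W x K x N` array.
#' @param target_hw integer vector `c(h, w)`.
#' @export
resize_mask_to <- function(mask_onehot, target_hw) {
  d <- dim(mask_onehot)
  th <- as.integer(target_hw[1]); tw <- as.integer(target_hw[2])
  ratio_ok <- function(a, b) {
    r <- max(a, b) / min(a, b)
    r == round(r) && bitwAnd(as.integer(r), as.integer(r) - 1L) == 0L
  }
  if (!ratio_ok(d[1], th) || !ratio_ok(d[2], tw))
    stop("resize ratio must be a power of 2")
  idx <- function(src, dst) {
    if (dst >= src) rep(seq_len(src), each = dst %/% src)
    else seq(1L, src, by = src %/% dst)
  }
  if (length(d) == 3) mask_onehot[idx(d[1], th), idx(d[2], tw), , drop = FALSE]
  else mask_onehot[idx(d[1], th), idx(d[2], tw), , , drop = FALSE]
}

#' Initialize a standalone SPADE modulation head
#'
#' A shared 3x3 convolution over the one-hot mask followed by SiLU, then two
#' 3x3 convolutions emitting the spatial scale (gamma) and shift (beta)
#' maps. With `zero_init = TRUE` (default) the gamma/beta convolutions are
#' exactly zero, so modulation is the identity on the normalized features.
#' @param cond_channels one-hot mask channels.
#' @param hidden hidden width.
#' @param c_features number of feature channels to modulate.
#' @param seed RNG seed for the shared convolution.
#' @param zero_init zero the gamma/beta emitting convolutions.
#' @export
spade_head_params <- function(cond_channels = 4L, hidden = 32L, c_features,
                              seed = 1L, zero_init = TRUE) {
  with_seed(seed, list(
    sh_w = init_conv(3, 3, cond_channels, hidden), sh_b = numeric(hidden),
    sg_w = if (zero_init) array(0, c(3, 3, hidden, c_features))
           else init_conv(3, 3, hidden, c_features),
    sg_b = numeric(c_features),
    sb_w = if (zero_init) array(0, c(3, 3, hidden, c_features))
           else init_conv(3, 3, hidden, c_features),
    sb_b = numeric(c_features)))
}

#' Spatially-adaptive (SPADE) modulation
#'
#' Normalizes `features` with parameter-free group normalization, then
#' applies `GN(h) * (1 + gamma(m)) + beta(m)` where the spatial gamma/beta
#' maps are produced from the one-hot mask by `params_head`.
#' @param features `H x W x C x N` array.
#' @param mask_onehot one-hot mask at (or resizable to) feature resolution.
#' @param params_head a [spade_head_params()] list.
#' @param groups group count for the normalization.
#' @return modulated features, same shape as the input.
#' @export
spade_modulate <- function(features, mask_onehot, params_head, groups = 4L) {
  d <- dim(features)
  if (length(dim(mask_onehot)) == 3)
    mask_onehot <- array(mask_onehot, c(dim(mask_onehot), d[4]))
  if (!all(dim(mask_onehot)[1:2] == d[1:2]))
    mask_onehot <- resize_mask_to(mask_onehot, d[1:2])
  if (!all(dim(mask_onehot)[1:2] == d[1:2]))
    stop("mask resolution does not match features after resize")
  tp <- ad_tape()
  h <- ad_groupnorm(tp, ad_leaf(tp, features), groups)
  Ph <- ad_params(tp, params_head)
  hid <- ad_silu(tp, ad_conv2d(tp, ad_leaf(tp, mask_onehot), Ph$sh_w, Ph$sh_b, 1L, 1L))
  gam <- ad_conv2d(tp, hid, Ph$sg_w, Ph$sg_b, 1L, 1L)
  bet <- ad_conv2d(tp, hid, Ph$sb_w, Ph$sb_b, 1L, 1L)
  ad_add(tp, ad_add(tp, h, ad_mul(tp, h, gam)), bet)$val
}

#' Train the mask-conditioned latent diffusion model
#'
#' Encodes each image with the frozen autoencoder (latent mean), diffuses
#' the latent, and trains the conditional U-Net on the epsilon-matching loss
#' with the one-hot mask (resized to latent resolution) injected through the
#' SPADE decoder blocks. With probability `p_uncond` the condition is
#' replaced by the all-background null mask (classifier-free training).
#'
#' @param pairs list of `(image, mask)` pairs (e.g. phantom pairs).
#' @param autoencoder a trained [train_autoencoder()] model; kept frozen.
#' @param backbone_cfg a conditional [backbone_config()].
#' @param sched a [make_schedule()].
#' @param steps,batch_size,lr Adam settings.
#' @param p_uncond condition dropout probability (default 0.1).
#' @param seed RNG seed.
#' @param ema_decay exponential-moving-average decay for the returned
#'   weights (0 = off).
#' @return a trained `conditional_ldm` model.
#' @export
train_conditional_ldm <- function(pairs, autoencoder, backbone_cfg,
                                  sched = make_schedule(), steps = 2000L,
                                  batch_size = 16L, lr = 1e-4, p_uncond = 0.1,
                                  seed = 1L, ema_decay = 0) {
  if (!isTRUE(autoencoder$trained)) stop("autoencoder must be trained first")
  if (!backbone_cfg$conditional) stop("backbone_cfg must be conditional")
  if (!length(pairs)) stop("empty training set")
  lat <- lapply(pairs, function(p) ae_encode(autoencoder, p$image)$tensor[, , , 1, drop = FALSE])
  lat <- lapply(lat, function(z) array(z, dim(z)[1:3]))
  # rescale latents to unit variance so the diffusion noise schedule sees
  # the signal-to-noise ratios it was designed for (the standard latent
  # scale factor); undone at decode time
  latent_scale <- 1 / stats::sd(unlist(lat))
  lat <- lapply(lat, function(z) z * latent_scale)
  hw <- dim(lat[[1]])[1:2]
  cond <- lapply(pairs, function(p) resize_mask_to(encode_mask(p$mask), hw))
  model <- build_denoiser(backbone_cfg, seed = seed)
  model <- train_diffusion(lat, model, sched, steps, batch_size, lr,
                           seed = seed, cond = cond, p_uncond = p_uncond,
                           ema_decay = ema_decay)
  model$sched <- sched
  model$latent_hw <- hw
  model$latent_scale <- latent_scale
  model$image_hw <- dim(pairs[[1]]$image)
  class(model) <- c("conditional_ldm", class(model))
  model
}

#' Synthesize images from masks
#'
#' For each mask, samples a latent with DDIM under classifier-free guidance
#' (`eps = eps_u + w (eps_c - eps_u)`) conditioned on the mask, then decodes
#' it with the autoencoder — one image per mask. Deterministic given the
#' seed at `eta = 0`.
#'
#' @param model a trained [train_conditional_ldm()] model.
#' @param autoencoder the trained autoencoder used for decoding.
#' @param masks a `pseudo_label_set` or list of label masks.
#' @param guidance_w guidance weight, `>= 0` (default 1.5).
#' @param n_steps DDIM subsequence length.
#' @param eta DDIM stochasticity.
#' @param seed RNG seed.
#' @return list of image matrices in `[-1, 1]`, one per mask.
#' @export
synthesize_images <- function(model, autoencoder, masks, guidance_w = 1.5,
                              n_steps = 50L, eta = 0, seed = 1L) {
  if (guidance_w < 0) stop("guidance_w must be >= 0")
  if (is.null(model$latent_hw)) stop("model is not a trained conditional LDM")
  mask_list <- if (inherits(masks, "pseudo_label_set")) masks$masks else masks
  n <- length(mask_list)
  hw <- model$latent_hw
  c_lat <- model$cfg$in_channels
  cond <- array(0, c(hw[1], hw[2], K_CLASSES, n))
  for (i in seq_len(n))
    cond[, , , i] <- resize_mask_to(encode_mask(mask_list[[i]]), hw)
  nullc <- null_condition(hw[1], hw[2], K_CLASSES, n)
  dfun <- function(x, t, cnd) {
    eps_c <- denoise(model, x, t, cond)
    if (guidance_w == 1) return(eps_c)
    eps_u <- denoise(model, x, t, nullc)
    cfg_combine(eps_u, eps_c, guidance_w)
  }
  z <- ddim_sample(dfun, model$sched, n_steps, eta = eta,
                   shape = c(hw[1], hw[2], c_lat, n), seed = seed)
  scale <- if (!is.null(model$latent_scale)) model$latent_scale else 1
  imgs <- ae_decode(autoencoder, z / scale)
  lapply(seq_len(n), function(i) imgs[, , 1, i])
}
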