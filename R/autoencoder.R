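# ---------------------------------------------------------------------------
# Perceptual-compression autoencoder: convolutional encoder/decoder with
# group-normalized residual blocks. The encoder emits a diagonal-Gaussian
# latent (mean + log-variance); training minimizes L1 reconstruction plus a
# tiny KL regularizer toward the standard normal, the regime in which the
# latent diffusion model is subsequently trained. The decoder ends in tanh,
# so reconstructions live in the data range [-1, 1].
# ---------------------------------------------------------------------------

#' Autoencoder configuration
#'
#' @param n_levels encoder/decoder depth.
#' @param channels per-level widths.
#' @param f spatial downsampling factor (a power of 2; the first `log2(f)`
#'   levels downsample). Default 8: a 128x128 image maps to a 16x16 latent.
#' @param latent_channels latent channel count c.
#' @param norm_groups group-normalization groups (64 at full scale).
#' @param in_channels image channels.
#' @param kl_weight weight of the KL regularizer.
#' @export
ae_config <- function(n_levels = 5L, channels = c(64L, 128L, 256L, 512L, 1024L),
                      f = 8L, latent_channels = 4L, norm_groups = 64L,
                      in_channels = 1L, kl_weight = 1e-6) {
  if (length(channels) != n_levels) stop("channels must have length n_levels")
  nd <- as.integer(round(log2(f)))
  if (2^nd != f) stop("f must be a power of 2")
  if (nd > n_levels - 1) stop("f too large for n_levels")
  structure(list(n_levels = as.integer(n_levels), channels = as.integer(channels),
                 f = as.integer(f), n_down = nd,
                 latent_channels = as.integer(latent_channels),
                 norm_groups = as.integer(norm_groups),
                 in_channels = as.integer(in_channels),
                 kl_weight = kl_weight),
            class = "ae_config")
}

ae_init_params <- function(cfg) {
  P <- list()
  addc <- function(name, kh, kw, cin, cout, gain = 1) {
    P[[paste0(name, "_w")]] <<- if (gain == 0) array(0, c(kh, kw, cin, cout))
      else init_conv(kh, kw, cin, cout, gain = gain)
    P[[paste0(name, "_b")]] <<- numeric(cout)
  }
  addaff <- function(name, c) {
    P[[paste0(name, "_g")]] <<- rep(1, c)
    P[[paste0(name, "_bt")]] <<- numeric(c)
  }
  rb <- function(prefix, cin, cout) {
    addaff(paste0(prefix, "_n1"), cin)
    addc(paste0(prefix, "_c1"), 3, 3, cin, cout)
    addaff(paste0(prefix, "_n2"), cout)
    addc(paste0(prefix, "_c2"), 3, 3, cout, cout, gain = 0.05)
    if (cin != cout) addc(paste0(prefix, "_sc"), 1, 1, cin, cout)
  }
  ch <- cfg$channels; L <- cfg$n_levels
  addc("enc_stem", 3, 3, cfg$in_channels, ch[1])
  for (l in seq_len(L)) {
    rb(sprintf("enc_l%d_rb1", l), if (l == 1) ch[1] else ch[l - 1], ch[l])
    rb(sprintf("enc_l%d_rb2", l), ch[l], ch[l])
    if (l <= cfg$n_down) addc(sprintf("enc_down_l%d", l), 3, 3, ch[l], ch[l])
  }
  addaff("enc_hn", ch[L])
  addc("enc_head", 3, 3, ch[L], 2L * cfg$latent_channels)
  addc("dec_stem", 3, 3, cfg$latent_channels, ch[L])
  for (l in seq(L, 1)) {
    rb(sprintf("dec_l%d_rb1", l), if (l == L) ch[L] else ch[l + 1], ch[l])
    rb(sprintf("dec_l%d_rb2", l), ch[l], ch[l])
    if (l <= cfg$n_down) addc(sprintf("dec_up_l%d", l), 3, 3, ch[l], ch[l])
  }
  addaff("dec_hn", ch[1])
  addc("dec_head", 3, 3, ch[1], cfg$in_channels)
  P
}

ae_rb <- function(tp, P, prefix, x, cfg) {
  cin <- dim(x$val)[3]
  cout <- dim(P[[paste0(prefix, "_c1_w")]]$val)[4]
  h <- ad_chaffine(tp, ad_groupnorm(tp, x, gn_groups(cfg, cin)),
                   P[[paste0(prefix, "_n1_g")]], P[[paste0(prefix, "_n1_bt")]])
  h <- ad_conv2d(tp, ad_silu(tp, h), P[[paste0(prefix, "_c1_w")]],
                 P[[paste0(prefix, "_c1_b")]], 1L, 1L)
  h <- ad_chaffine(tp, ad_groupnorm(tp, h, gn_groups(cfg, cout)),
                   P[[paste0(prefix, "_n2_g")]], P[[paste0(prefix, "_n2_bt")]])
  h <- ad_conv2d(tp, ad_silu(tp, h), P[[paste0(prefix, "_c2_w")]],
                 P[[paste0(prefix, "_c2_b")]], 1L, 1L)
  sc <- if (cin != cout)
    ad_conv2d(tp, x, P[[paste0(prefix, "_sc_w")]], P[[paste0(prefix, "_sc_b")]], 1L, 0L)
  else x
  ad_add(tp, h, sc)
}

ae_encode_fwd <- function(tp, P, cfg, x) {
  h <- ad_conv2d(tp, x, P$enc_stem_w, P$enc_stem_b, 1L, 1L)
  for (l in seq_len(cfg$n_levels)) {
    h <- ae_rb(tp, P, sprintf("enc_l%d_rb1", l), h, cfg)
    h <- ae_rb(tp, P, sprintf("enc_l%d_rb2", l), h, cfg)
    if (l <= cfg$n_down)
      h <- ad_conv2d(tp, h, P[[sprintf("enc_down_l%d_w", l)]],
                     P[[sprintf("enc_down_l%d_b", l)]], 2L, 1L)
  }
  h <- ad_chaffine(tp, ad_groupnorm(tp, h, gn_groups(cfg, dim(h$val)[3])),
                   P$enc_hn_g, P$enc_hn_bt)
  h <- ad_conv2d(tp, ad_silu(tp, h), P$enc_head_w, P$enc_head_b, 1L, 1L)
  c_lat <- cfg$latent_channels
  list(mu = ad_slice_ch(tp, h, 1L, c_lat),
       logvar = ad_slice_ch(tp, h, c_lat + 1L, 2L * c_lat))
}

ae_decode_fwd <- function(tp, P, cfg, z) {
  h <- ad_conv2d(tp, z, P$dec_stem_w, P$dec_stem_b, 1L, 1L)
  for (l in seq(cfg$n_levels, 1)) {
    h <- ae_rb(tp, P, sprintf("dec_l%d_rb1", l), h, cfg)
    h <- ae_rb(tp, P, sprintf("dec_l%d_rb2", l), h, cfg)
    if (l <= cfg$n_down) {
      h <- ad_upnearest(tp, h, 2L)
      h <- ad_conv2d(tp, h, P[[sprintf("dec_up_l%d_w", l)]],
                     P[[sprintf("dec_up_l%d_b", l)]], 1L, 1L)
    }
  }
  h <- ad_chaffine(tp, ad_groupnorm(tp, h, gn_groups(cfg, dim(h$val)[3])),
                   P$dec_hn_g, P$dec_hn_bt)
  ad_tanh(tp, ad_conv2d(tp, ad_silu(tp, h), P$dec_head_w, P$dec_head_b, 1L, 1L))
}

#' Build an untrained autoencoder
#' @param cfg an [ae_config()].
#' @param seed parameter-initialization seed.
#' @export
build_autoencoder <- function(cfg = ae_config(), seed = 1L) {
  params <- with_seed(seed, ae_init_params(cfg))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed),
                 trained = FALSE),
            class = "autoencoder")
}

# images may be matrices or H x W x C arrays; returns H x W x C array.
as_image_array <- function(x, cfg) {
  if (is.matrix(x)) array(x, c(nrow(x), ncol(x), cfg$in_channels)) else x
}

#' Train the autoencoder
#'
#' Minimizes L1 reconstruction error plus `kl_weight` times the KL of the
#' diagonal-Gaussian latent to the standard normal; latents are sampled with
#' the reparameterization trick during training. Deterministic given `seed`.
#'
#' @param images list of image matrices in `[-1, 1]`, uniform shapes.
#' @param cfg an [ae_config()].
#' @param steps,batch_size,lr Adam settings.
#' @param seed RNG seed.
#' @return a trained `autoencoder` with `loss_history`.
#' @export
train_autoencoder <- function(images, cfg = ae_config(), steps = 2000L,
                              batch_size = 8L, lr = 1e-4, seed = 1L) {
  if (!length(images)) stop("empty image set")
  ae <- build_autoencoder(cfg, seed = seed)
  data <- lapply(images, as_image_array, cfg = cfg)
  d3 <- dim(data[[1]])
  if (d3[1] %% cfg$f != 0 || d3[2] %% cfg$f != 0)
    stop("image size must be divisible by f = ", cfg$f)
  n <- length(data)
  params <- ae$params
  opt <- adam_new(params)
  history <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      idx <- sample.int(n, min(batch_size, n), replace = n < batch_size)
      N <- length(idx)
      x <- array(0, c(d3, N))
      for (j in seq_len(N)) x[, , , j] <- data[[idx[j]]]
      tp <- ad_tape()
      P <- ad_params(tp, params)
      enc <- ae_encode_fwd(tp, P, cfg, ad_leaf(tp, x))
      epsz <- array(stats::rnorm(length(enc$mu$val)), dim(enc$mu$val))
      std <- ad_exp(tp, ad_scale(tp, enc$logvar, 0.5))
      z <- ad_add(tp, enc$mu, ad_mul(tp, std, ad_leaf(tp, epsz)))
      recon <- ae_decode_fwd(tp, P, cfg, z)
      loss <- ad_sum2(tp, ad_mae(tp, recon, x),
                      ad_scale(tp, ad_kl_gauss(tp, enc$mu, enc$logvar), cfg$kl_weight))
      grads <- ad_backward(tp, loss)
      st <- adam_step(opt, params, grads, lr = lr_at_step(s, steps, lr))
      opt <- st$opt; params <- st$params
      history[s] <- loss$val
    }
  })
  ae$params <- params
  ae$loss_history <- history
  ae$trained <- TRUE
  ae
}

#' Encode images to latent space
#'
#' Deterministic encoding (the latent mean). Latent spatial dims are the
#' image dims divided exactly by `f`.
#' @param ae a trained or untrained `autoencoder`.
#' @param x image matrix, `H x W x C` array, or `H x W x C x N` batch.
#' @return a `latent_code`: list with `tensor` (`h x w x c x N`) and `f`.
#' @export
ae_encode <- function(ae, x) {
  cfg <- ae$cfg
  if (is.matrix(x) || length(dim(x)) == 3) x <- array(as_image_array(x, cfg),
                                                      c(dim(as_image_array(x, cfg)), 1L))
  if (dim(x)[1] %% cfg$f != 0 || dim(x)[2] %% cfg$f != 0)
    stop("image size must be divisible by f = ", cfg$f)
  tp <- ad_tape()
  P <- ad_params(tp, ae$params)
  enc <- ae_encode_fwd(tp, P, cfg, ad_leaf(tp, x))
  structure(list(tensor = enc$mu$val, f = cfg$f), class = "latent_code")
}

#' Decode latents to images
#' @param ae an `autoencoder`.
#' @param z a `latent_code` or raw `h x w x c x N` array.
#' @return image array `H x W x C x N` in `[-1, 1]`.
#' @export
ae_decode <- function(ae, z) {
  zt <- if (inherits(z, "latent_code")) z$tensor else z
  tp <- ad_tape()
  P <- ad_params(tp, ae$params)
  ae_decode_fwd(tp, P, ae$cfg, ad_leaf(tp, zt))$val
}
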