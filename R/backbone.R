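# ---------------------------------------------------------------------------
# Configurable U-Net noise predictor: residual blocks with timestep-embedding
# injection, single-head self-attention at selected levels, strided-conv
# downsampling, nearest+conv upsampling, channel-concatenated skips. The
# conditional variant swaps the decoder resblocks' normalization for SPADE
# modulation driven by the (resized) one-hot conditioning mask, with
# zero-initialized modulation heads so that at initialization the
# conditional and unconditional networks compute the same function.
# ---------------------------------------------------------------------------

#' Denoiser backbone configuration
#'
#' @param n_levels encoder/decoder depth (spatial size must be divisible by
#'   `2^(n_levels - 1)`).
#' @param channels per-level widths, length `n_levels`.
#' @param resblocks_per_level residual blocks per level.
#' @param attention_levels level indices (1-based, 1 = full resolution) that
#'   get a self-attention block in both encoder and decoder.
#' @param norm_groups group count for group normalization; must divide every
#'   level width.
#' @param conditional if `TRUE`, decoder resblocks use SPADE modulation from
#'   a one-hot mask condition.
#' @param in_channels,out_channels data channel counts.
#' @param cond_channels channels of the conditioning one-hot mask.
#' @param time_dim sinusoidal timestep embedding width (default
#'   `4 * channels[1]`).
#' @param spade_hidden hidden width of the SPADE modulation heads.
#' @export
backbone_config <- function(n_levels, channels, resblocks_per_level = 2L,
                            attention_levels = integer(0), norm_groups = 32L,
                            conditional = FALSE, in_channels = 4L,
                            out_channels = 4L, cond_channels = 4L,
                            time_dim = NULL, spade_hidden = 32L) {
  if (length(channels) != n_levels)
    stop("channels must have length n_levels")
  if (length(attention_levels) && !all(attention_levels %in% seq_len(n_levels)))
    stop("attention_levels must be a subset of 1..n_levels")
  if (any(channels %% norm_groups != 0))
    stop("norm_groups must divide every level width")
  if (is.null(time_dim)) time_dim <- 4L * channels[1]
  if (time_dim %% 2 != 0) stop("time_dim must be even")
  structure(list(n_levels = as.integer(n_levels), channels = as.integer(channels),
                 resblocks_per_level = as.integer(resblocks_per_level),
                 attention_levels = as.integer(attention_levels),
                 norm_groups = as.integer(norm_groups),
                 conditional = isTRUE(conditional),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 cond_channels = as.integer(cond_channels),
                 time_dim = as.integer(time_dim),
                 spade_hidden = as.integer(spade_hidden)),
            class = "backbone_config")
}

#' Default mask-model backbone (full scale)
#'
#' Six levels with widths 64, 128, 256, 512, 1024, 1024 (the five stated
#' widths completed monotonically to six levels), two resblocks per level,
#' attention in the last three levels.
#' @export
mask_backbone_config <- function() {
  backbone_config(n_levels = 6L, channels = c(64L, 128L, 256L, 512L, 1024L, 1024L),
                  resblocks_per_level = 2L, attention_levels = 4:6,
                  norm_groups = 32L, in_channels = 4L, out_channels = 4L)
}

#' Sinusoidal timestep embedding
#'
#' Standard transformer-style features: for half-dimension d = dim/2 and
#' frequencies \eqn{10000^{-i/d}} (i = 0..d-1), the embedding is
#' `c(sin(t * f), cos(t * f))`. At t = 0 the sine half is all zeros and the
#' cosine half all ones.
#' @param t nonnegative scalar or vector of timesteps.
#' @param dim even embedding width.
#' @return `dim x length(t)` matrix.
#' @export
timestep_embedding <- function(t, dim) {
  if (dim %% 2 != 0) stop("dim must be even")
  if (any(t < 0)) stop("t must be >= 0")
  half <- dim %/% 2
  freqs <- 10000^(-(seq_len(half) - 1) / half)
  args <- outer(freqs, as.numeric(t))
  rbind(sin(args), cos(args))
}

# --- parameter initialization ----------------------------------------------

bb_param_names <- function(cfg) names(bb_init_params(cfg, init = FALSE))

bb_init_params <- function(cfg, init = TRUE) {
  P <- list()
  # `gain = 0` means exact zeros (SPADE heads); small gains give near-identity
  # residual/attention/head outputs without blocking gradient flow.
  addc <- function(name, kh, kw, cin, cout, gain = 1) {
    P[[paste0(name, "_w")]] <<- if (!init || gain == 0) array(0, c(kh, kw, cin, cout))
      else init_conv(kh, kw, cin, cout, gain = gain)
    P[[paste0(name, "_b")]] <<- numeric(cout)
  }
  addl <- function(name, din, dout) {
    P[[paste0(name, "_w")]] <<- if (init) init_linear(din, dout) else matrix(0, dout, din)
    P[[paste0(name, "_b")]] <<- numeric(dout)
  }
  addaff <- function(name, c) {
    P[[paste0(name, "_g")]] <<- rep(1, c)
    P[[paste0(name, "_bt")]] <<- numeric(c)
  }
  ch <- cfg$channels; L <- cfg$n_levels; Dt <- cfg$time_dim
  spade <- function(prefix) cfg$conditional && startsWith(prefix, "dec")
  resblock <- function(prefix, cin, cout) {
    if (!spade(prefix)) addaff(paste0(prefix, "_n1"), cin)
    addc(paste0(prefix, "_c1"), 3, 3, cin, cout)
    addl(paste0(prefix, "_t"), Dt, cout)
    if (!spade(prefix)) addaff(paste0(prefix, "_n2"), cout)
    addc(paste0(prefix, "_c2"), 3, 3, cout, cout, gain = 0.05)
    if (cin != cout) addc(paste0(prefix, "_sc"), 1, 1, cin, cout)
  }
  attn <- function(prefix, c) {
    addaff(paste0(prefix, "_n"), c)
    addc(paste0(prefix, "_q"), 1, 1, c, c)
    addc(paste0(prefix, "_k"), 1, 1, c, c)
    addc(paste0(prefix, "_v"), 1, 1, c, c)
    addc(paste0(prefix, "_o"), 1, 1, c, c, gain = 0.05)
  }
  addl("temb1", Dt, Dt); addl("temb2", Dt, Dt)
  addc("stem", 3, 3, cfg$in_channels, ch[1])
  for (l in seq_len(L)) {
    cin <- if (l == 1) ch[1] else ch[l - 1]
    for (r in seq_len(cfg$resblocks_per_level)) {
      resblock(sprintf("enc_l%d_rb%d", l, r), if (r == 1) cin else ch[l], ch[l])
    }
    if (l %in% cfg$attention_levels) attn(sprintf("enc_l%d_at", l), ch[l])
    if (l < L) addc(sprintf("down_l%d", l), 3, 3, ch[l], ch[l])
  }
  resblock("mid_rb1", ch[L], ch[L])
  attn("mid_at", ch[L])
  resblock("mid_rb2", ch[L], ch[L])
  for (l in seq(L, 1)) {
    if (l < L) addc(sprintf("up_l%d", l), 3, 3, ch[l + 1], ch[l])
    for (r in seq_len(cfg$resblocks_per_level)) {
      cin <- if (r == 1) 2L * ch[l] else ch[l]
      resblock(sprintf("dec_l%d_rb%d", l, r), cin, ch[l])
    }
    if (l %in% cfg$attention_levels) attn(sprintf("dec_l%d_at", l), ch[l])
  }
  addaff("head_n", ch[1])
  addc("head", 3, 3, ch[1], cfg$out_channels, gain = 0.05)
  # SPADE modulation heads, appended after all shared parameters so that a
  # conditional build shares its RNG stream (hence its shared weights) with
  # an unconditional build from the same seed.
  if (cfg$conditional) {
    spade_head <- function(prefix, cnorm) {
      addc(paste0(prefix, "_sh"), 3, 3, cfg$cond_channels, cfg$spade_hidden)
      addc(paste0(prefix, "_sg"), 3, 3, cfg$spade_hidden, cnorm, gain = 0)
      addc(paste0(prefix, "_sb"), 3, 3, cfg$spade_hidden, cnorm, gain = 0)
    }
    for (l in seq(L, 1)) {
      for (r in seq_len(cfg$resblocks_per_level)) {
        cin <- if (r == 1) 2L * ch[l] else ch[l]
        prefix <- sprintf("dec_l%d_rb%d", l, r)
        spade_head(paste0(prefix, "_m1"), cin)
        spade_head(paste0(prefix, "_m2"), ch[l])
      }
    }
  }
  P
}

#' Build a U-Net denoiser
#'
#' Instantiates parameters for `cfg` with seeded He initialization. The
#' returned object is callable through [denoise()] and the training loops.
#' @param cfg a [backbone_config()].
#' @param seed RNG seed for the parameter draw; the same cfg + seed yields
#'   identical parameters. A conditional and an unconditional build from the
#'   same seed share their common weights.
#' @return an object of class `denoiser`.
#' @export
build_denoiser <- function(cfg, seed = 1L) {
  params <- with_seed(seed, bb_init_params(cfg))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "denoiser")
}

# --- forward pass -----------------------------------------------------------

bb_gnorm <- function(tp, P, prefix, x, cfg, cond = NULL) {
  h <- ad_groupnorm(tp, x, gn_groups(cfg, dim(x$val)[3]))
  if (!is.null(cond)) {
    # SPADE: (1 + gamma(m)) * GN(x) + beta(m), heads zero-initialized
    hid <- ad_silu(tp, ad_conv2d(tp, cond, P[[paste0(prefix, "_sh_w")]],
                                 P[[paste0(prefix, "_sh_b")]], 1L, 1L))
    gam <- ad_conv2d(tp, hid, P[[paste0(prefix, "_sg_w")]], P[[paste0(prefix, "_sg_b")]], 1L, 1L)
    bet <- ad_conv2d(tp, hid, P[[paste0(prefix, "_sb_w")]], P[[paste0(prefix, "_sb_b")]], 1L, 1L)
    ad_add(tp, ad_add(tp, h, ad_mul(tp, h, gam)), bet)
  } else {
    ad_chaffine(tp, h, P[[paste0(prefix, "_g")]], P[[paste0(prefix, "_bt")]])
  }
}

gn_groups <- function(cfg, c) {
  g <- min(cfg$norm_groups, c)
  while (c %% g != 0) g <- g - 1L
  g
}

bb_resblock <- function(tp, P, prefix, x, temb, cfg, cond = NULL) {
  cin <- dim(x$val)[3]
  cout <- dim(P[[paste0(prefix, "_c1_w")]]$val)[4]
  m1 <- if (!is.null(cond)) paste0(prefix, "_m1") else paste0(prefix, "_n1")
  m2 <- if (!is.null(cond)) paste0(prefix, "_m2") else paste0(prefix, "_n2")
  h <- bb_gnorm(tp, P, m1, x, cfg, cond)
  h <- ad_conv2d(tp, ad_silu(tp, h), P[[paste0(prefix, "_c1_w")]],
                 P[[paste0(prefix, "_c1_b")]], 1L, 1L)
  tb <- ad_linear(tp, temb, P[[paste0(prefix, "_t_w")]], P[[paste0(prefix, "_t_b")]])
  h <- ad_add_tbias(tp, h, tb)
  h <- bb_gnorm(tp, P, m2, h, cfg, cond)
  h <- ad_conv2d(tp, ad_silu(tp, h), P[[paste0(prefix, "_c2_w")]],
                 P[[paste0(prefix, "_c2_b")]], 1L, 1L)
  sc <- if (cin != cout)
    ad_conv2d(tp, x, P[[paste0(prefix, "_sc_w")]], P[[paste0(prefix, "_sc_b")]], 1L, 0L)
  else x
  ad_add(tp, h, sc)
}

bb_attention <- function(tp, P, prefix, x, cfg) {
  d <- dim(x$val)
  h <- ad_chaffine(tp, ad_groupnorm(tp, x, gn_groups(cfg, d[3])),
                   P[[paste0(prefix, "_n_g")]], P[[paste0(prefix, "_n_bt")]])
  q <- ad_tokens(tp, ad_conv2d(tp, h, P[[paste0(prefix, "_q_w")]], P[[paste0(prefix, "_q_b")]], 1L, 0L))
  k <- ad_tokens(tp, ad_conv2d(tp, h, P[[paste0(prefix, "_k_w")]], P[[paste0(prefix, "_k_b")]], 1L, 0L))
  v <- ad_tokens(tp, ad_conv2d(tp, h, P[[paste0(prefix, "_v_w")]], P[[paste0(prefix, "_v_b")]], 1L, 0L))
  att <- ad_softmax2(tp, ad_scale(tp, ad_bmm(tp, q, k, tb = TRUE), 1 / sqrt(d[3])))
  o <- ad_untokens(tp, ad_bmm(tp, att, v), d[1], d[2])
  o <- ad_conv2d(tp, o, P[[paste0(prefix, "_o_w")]], P[[paste0(prefix, "_o_b")]], 1L, 0L)
  ad_add(tp, x, o)
}

# Full forward pass on an existing tape. x: node [H,W,Cin,N]; t scalar or
# length-N vector; cond: NULL or node [H,W,cond_channels,N] (full resolution).
bb_forward <- function(tp, P, cfg, x, t, cond = NULL) {
  d <- dim(x$val)
  L <- cfg$n_levels
  if (d[1] %% 2^(L - 1) != 0 || d[2] %% 2^(L - 1) != 0)
    stop("spatial size must be divisible by 2^(n_levels - 1)")
  if (cfg$conditional && is.null(cond))
    cond <- ad_leaf(tp, null_condition(d[1], d[2], cfg$cond_channels, d[4]))
  if (!cfg$conditional) cond <- NULL
  tvec <- if (length(t) == 1) rep(t, d[4]) else t
  te <- ad_leaf(tp, timestep_embedding(tvec, cfg$time_dim))
  temb <- ad_linear(tp, ad_silu(tp, ad_linear(tp, te, P$temb1_w, P$temb1_b)),
                    P$temb2_w, P$temb2_b)
  conds <- NULL
  if (!is.null(cond)) {
    conds <- vector("list", L)
    conds[[1]] <- cond
    cv <- cond$val
    for (l in seq_len(L - 1)) {
      cv <- resize_mask_to(cv, dim(cv)[1:2] %/% 2L)
      conds[[l + 1]] <- ad_leaf(tp, cv)
    }
  }
  h <- ad_conv2d(tp, x, P$stem_w, P$stem_b, 1L, 1L)
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    for (r in seq_len(cfg$resblocks_per_level))
      h <- bb_resblock(tp, P, sprintf("enc_l%d_rb%d", l, r), h, temb, cfg)
    if (l %in% cfg$attention_levels)
      h <- bb_attention(tp, P, sprintf("enc_l%d_at", l), h, cfg)
    skips[[l]] <- h
    if (l < L)
      h <- ad_conv2d(tp, h, P[[sprintf("down_l%d_w", l)]],
                     P[[sprintf("down_l%d_b", l)]], 2L, 1L)
  }
  h <- bb_resblock(tp, P, "mid_rb1", h, temb, cfg)
  h <- bb_attention(tp, P, "mid_at", h, cfg)
  h <- bb_resblock(tp, P, "mid_rb2", h, temb, cfg)
  for (l in seq(L, 1)) {
    if (l < L) {
      h <- ad_upnearest(tp, h, 2L)
      h <- ad_conv2d(tp, h, P[[sprintf("up_l%d_w", l)]],
                     P[[sprintf("up_l%d_b", l)]], 1L, 1L)
    }
    h <- ad_concat_ch(tp, h, skips[[l]])
    cl <- if (!is.null(conds)) conds[[l]] else NULL
    for (r in seq_len(cfg$resblocks_per_level))
      h <- bb_resblock(tp, P, sprintf("dec_l%d_rb%d", l, r), h, temb, cfg, cond = cl)
    if (l %in% cfg$attention_levels)
      h <- bb_attention(tp, P, sprintf("dec_l%d_at", l), h, cfg)
  }
  h <- ad_chaffine(tp, ad_groupnorm(tp, h, gn_groups(cfg, cfg$channels[1])),
                   P$head_n_g, P$head_n_bt)
  ad_conv2d(tp, ad_silu(tp, h), P$head_w, P$head_b, 1L, 1L)
}

#' Run a denoiser on data
#'
#' Inference-mode forward pass: predicts the noise content of `x` at
#' timestep `t`, optionally conditioned on a one-hot mask tensor.
#' @param model a [build_denoiser()] object.
#' @param x array `H x W x C x N`.
#' @param t scalar or length-N vector of timesteps.
#' @param condition optional `H x W x cond_channels x N` one-hot tensor.
#' @return predicted-noise array shaped like `x`.
#' @export
denoise <- function(model, x, t, condition = NULL) {
  tp <- ad_tape()
  P <- ad_params(tp, model$params)
  cnd <- if (!is.null(condition)) ad_leaf(tp, condition) else NULL
  bb_forward(tp, P, model$cfg, ad_leaf(tp, x), t, cnd)$val
}

#' Number of parameters of a denoiser
#' @param model a `denoiser`.
#' @export
n_params <- function(model) sum(vapply(model$params, length, numeric(1)))

# All-background one-hot condition (null condition for classifier-free
# training/guidance): channel 1 = +1, others -1.
null_condition <- function(H, W, K = 4L, N = 1L) {
  z <- array(-1, c(H, W, K, N))
  z[, , 1, ] <- 1
  z
}
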