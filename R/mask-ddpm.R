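# ---------------------------------------------------------------------------
# Stage 1: unconditional diffusion over multi-class cardiac masks. Masks are
# lifted to a one-hot +/-1 encoding (no false ordinal metric between class
# indices), diffused with Gaussian noise, and a U-Net is trained on the
# epsilon-matching loss; sampling decodes by per-pixel argmax.
# ---------------------------------------------------------------------------

#' One-hot encode a label mask for diffusion
#'
#' Maps a `H x W` integer mask to a `H x W x K` tensor with value `+1` on
#' the pixel's class channel and `-1` elsewhere.
#' @param mask a label mask (values 0..3).
#' @export
encode_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask))
  if (any(m < 0L | m >= K_CLASSES)) stop("mask values out of range 0..", K_CLASSES - 1)
  out <- array(-1, c(nrow(m), ncol(m), K_CLASSES))
  for (k in seq_len(K_CLASSES)) out[, , k] <- ifelse(m == k - 1L, 1, -1)
  out
}

#' Decode a channel tensor to a label mask
#'
#' Per-pixel argmax over the K channels; ties break toward the lowest class
#' index (background-favoring).
#' @param tensor `H x W x K` array.
#' @export
decode_mask <- function(tensor) {
  d <- dim(tensor)
  if (length(d) != 3 || d[3] != K_CLASSES)
    stop("expected an H x W x ", K_CLASSES, " tensor")
  flat <- matrix(tensor, d[1] * d[2], d[3])
  as_label_mask(matrix(max.col(flat, ties.method = "first") - 1L, d[1], d[2]))
}

# Shared diffusion training loop (used by the mask DDPM and the latent
# diffusion model). data: list of H x W x C arrays. cond: optional list of
# matching one-hot condition arrays; conditions are dropped to the null
# (all-background) condition with probability p_uncond.
train_diffusion <- function(data, model, sched, steps, batch_size, lr,
                            seed = 1L, cond = NULL, p_uncond = 0,
                            eps_override = NULL, ema_decay = 0) {
  if (!length(data)) stop("empty training set")
  d3 <- dim(data[[1]])
  n <- length(data)
  params <- model$params
  ema <- if (ema_decay > 0) params else NULL
  opt <- adam_new(params)
  history <- numeric(steps)
  with_seed(seed, {
    for (s in seq_len(steps)) {
      idx <- sample.int(n, min(batch_size, n), replace = n < batch_size)
      N <- length(idx)
      y0 <- array(0, c(d3, N))
      for (j in seq_len(N)) y0[, , , j] <- data[[idx[j]]]
      tvec <- sample.int(sched$T, N, replace = TRUE)
      eps <- if (is.null(eps_override)) array(stats::rnorm(prod(d3) * N), c(d3, N))
             else array(eps_override, c(d3, N))
      ab <- sched$alpha_bars[tvec]
      yt <- y0
      for (j in seq_len(N))
        yt[, , , j] <- sqrt(ab[j]) * y0[, , , j] + sqrt(1 - ab[j]) * eps[, , , j]
      cnd_val <- NULL
      if (!is.null(cond)) {
        kc <- dim(cond[[1]])[3]
        cnd_val <- array(0, c(dim(cond[[1]]), N))
        for (j in seq_len(N)) {
          cnd_val[, , , j] <- if (stats::runif(1) < p_uncond)
            null_condition(dim(cond[[1]])[1], dim(cond[[1]])[2], kc, 1L)[, , , 1]
          else cond[[idx[j]]]
        }
      }
      tp <- ad_tape()
      P <- ad_params(tp, params)
      cnd <- if (!is.null(cnd_val)) ad_leaf(tp, cnd_val) else NULL
      pred <- bb_forward(tp, P, model$cfg, ad_leaf(tp, yt), tvec, cnd)
      loss <- ad_mse(tp, pred, eps)
      grads <- ad_backward(tp, loss)
      st <- adam_step(opt, params, grads, lr = lr_at_step(s, steps, lr))
      opt <- st$opt; params <- st$params
      if (!is.null(ema)) {
        for (nm in names(params))
          ema[[nm]] <- ema_decay * ema[[nm]] + (1 - ema_decay) * params[[nm]]
      }
      history[s] <- loss$val
    }
  })
  # with EMA enabled the averaged weights are the model; raw weights kept
  model$params <- if (!is.null(ema)) ema else params
  if (!is.null(ema)) model$raw_params <- params
  model$loss_history <- history
  model
}

#' Train the unconditional mask diffusion model
#'
#' Fits a U-Net noise predictor to one-hot encoded cardiac masks with the
#' simplified epsilon-matching loss, timesteps drawn uniformly per example.
#'
#' @param masks list of label masks (identical shapes).
#' @param backbone_cfg a [backbone_config()] (unconditional).
#' @param sched a [make_schedule()].
#' @param steps optimizer steps.
#' @param batch_size minibatch size (16 at full scale).
#' @param lr Adam learning rate (1e-4 at full scale).
#' @param seed RNG seed; the loss trajectory is reproducible bit-for-bit.
#' @param eps_override optional fixed noise value for harness/sanity runs.
#' @param ema_decay exponential-moving-average decay for the returned
#'   weights (0 = off; around 0.997 markedly improves sample quality from
#'   short training runs).
#' @return a trained `mask_ddpm` model (a `denoiser` carrying its schedule,
#'   grid size and loss history).
#' @export
train_mask_ddpm <- function(masks, backbone_cfg, sched = make_schedule(),
                            steps = 2000L, batch_size = 16L, lr = 1e-4,
                            seed = 1L, eps_override = NULL, ema_decay = 0) {
  if (!length(masks)) stop("empty mask set")
  dims <- vapply(masks, function(m) dim(m), integer(2))
  if (any(dims != dims[, 1])) stop("all masks must share one shape")
  data <- lapply(masks, encode_mask)
  model <- build_denoiser(backbone_cfg, seed = seed)
  model <- train_diffusion(data, model, sched, steps, batch_size, lr,
                           seed = seed, eps_override = eps_override,
                           ema_decay = ema_decay)
  model$sched <- sched
  model$grid_size <- dim(masks[[1]])
  class(model) <- c("mask_ddpm", class(model))
  model
}

#' Sample pseudo-label masks from a trained mask DDPM
#'
#' Runs the reverse process from Gaussian noise (DDIM by default, 1000 to 50
#' steps; or full ancestral DDPM) and decodes each sample by argmax.
#'
#' @param model a trained [train_mask_ddpm()] model.
#' @param n number of masks to draw.
#' @param sampler `"ddim"` or `"ddpm"`.
#' @param n_steps DDIM subsequence length (ignored for `"ddpm"`).
#' @param eta DDIM stochasticity (0 = deterministic given the seed).
#' @param seed RNG seed.
#' @return a `pseudo_label_set`: list of masks plus sampler provenance.
#' @export
sample_masks <- function(model, n, sampler = c("ddim", "ddpm"), n_steps = 50L,
                         eta = 0, seed = 1L) {
  sampler <- match.arg(sampler)
  if (is.null(model$sched) || is.null(model$grid_size))
    stop("model is not a trained mask diffusion model")
  H <- model$grid_size[1]; W <- model$grid_size[2]
  sched <- model$sched
  dfun <- function(x, t, cond) denoise(model, x, t, cond)
  shape <- c(H, W, K_CLASSES, n)
  x <- if (sampler == "ddim") {
    ddim_sample(dfun, sched, n_steps, eta = eta, shape = shape, seed = seed,
                clip_x0 = TRUE)
  } else {
    with_seed(seed, {
      xx <- array(stats::rnorm(prod(shape)), shape)
      for (t in seq(sched$T, 1)) {
        z <- array(stats::rnorm(prod(shape)), shape)
        xx <- ddpm_step(xx, dfun(xx, t, NULL), t, z, sched)
      }
      xx
    })
  }
  masks <- lapply(seq_len(n), function(i) decode_mask(x[, , , i, drop = TRUE]))
  structure(list(masks = masks,
                 sampler = sampler, n_steps = as.integer(n_steps),
                 eta = eta, seed = as.integer(seed)),
            class = "pseudo_label_set")
}
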