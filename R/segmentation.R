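# ---------------------------------------------------------------------------
# Downstream evaluation: Dice/IoU metrics, classical augmentation baselines
# (affine, elastic, intensity, CutMix), a U-Net segmenter trained with
# cross-entropy + soft-Dice, and the regime-comparison harness that pits
# diffusion-generated pairs against the baselines on a shared test split.
# ---------------------------------------------------------------------------

#' Dice and IoU for one class
#'
#' `DSC = 2|P∩G| / (|P|+|G|)`, `IoU = |P∩G| / |P∪G|` on the binarized
#' class. Both are defined as 1 when the class is empty in prediction and
#' ground truth alike, and 0 when it is empty in exactly one of them.
#' @param pred,gt label masks of identical shape.
#' @param class_id class to binarize (1 = LV, 2 = MYO, 3 = RV).
#' @return named vector `c(dsc, iou)`.
#' @export
dice_iou <- function(pred, gt, class_id) {
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes must match")
  p <- pred == class_id
  g <- gt == class_id
  np <- sum(p); ng <- sum(g)
  if (np == 0 && ng == 0) return(c(dsc = 1, iou = 1))
  inter <- sum(p & g)
  c(dsc = 2 * inter / (np + ng), iou = inter / (np + ng - inter))
}

#' Per-class and mean segmentation metrics
#' @inheritParams dice_iou
#' @return named vector with per-class and mean DSC/IoU.
#' @export
seg_metrics <- function(pred, gt) {
  m <- vapply(1:3, function(k) dice_iou(pred, gt, k), numeric(2))
  c(mean_dice = mean(m[1, ]), dice_lv = m[1, 1], dice_myo = m[1, 2], dice_rv = m[1, 3],
    mean_iou = mean(m[2, ]), iou_lv = m[2, 1], iou_myo = m[2, 2], iou_rv = m[2, 3])
}

# --- spatial warping --------------------------------------------------------

# Sample img at fractional coords (rr, cc) bilinearly, border-clamped.
# Output takes the shape of the coordinate matrices.
bilinear_sample <- function(img, rr, cc) {
  H <- nrow(img); W <- ncol(img)
  od <- dim(rr)
  rr <- pmin(pmax(as.vector(rr), 1), H); cc <- pmin(pmax(as.vector(cc), 1), W)
  r0 <- pmin(floor(rr), H - 1); c0 <- pmin(floor(cc), W - 1)
  fr <- rr - r0; fc <- cc - c0
  i00 <- img[cbind(r0, c0)]; i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]; i11 <- img[cbind(r0 + 1, c0 + 1)]
  v <- i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
       i01 * (1 - fr) * fc + i11 * fr * fc
  matrix(v, od[1], od[2])
}

nearest_sample <- function(m, rr, cc, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  ri <- round(as.vector(rr)); ci <- round(as.vector(cc))
  ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
  out <- matrix(fill, H, W)
  out[ok] <- m[cbind(ri[ok], ci[ok])]
  out
}

warp_pair <- function(pair, rr, cc, provenance) {
  structure(list(image = bilinear_sample(pair$image, rr, cc),
                 mask = as_label_mask(nearest_sample(unclass(pair$mask), rr, cc)),
                 provenance = provenance),
            class = "augmented_pair")
}

#' Affine augmentation
#'
#' Random rotation, translation, isotropic scale and shear about the image
#' center; the identical spatial transform is applied to the image
#' (bilinear) and the mask (nearest). Deterministic per seed.
#' @param pair a pair with `image` and `mask`.
#' @param params_range list with `rot` (degrees), `trans` (fraction of
#'   side), `scale`, `shear`; each a length-2 range.
#' @param seed RNG seed.
#' @export
affine_augment <- function(pair,
                           params_range = list(rot = c(-15, 15),
                                               trans = c(-0.05, 0.05),
                                               scale = c(0.9, 1.1),
                                               shear = c(-0.1, 0.1)),
                           seed = 1L) {
  H <- nrow(pair$image); W <- ncol(pair$image)
  p <- with_seed(seed, list(
    rot = stats::runif(1, params_range$rot[1], params_range$rot[2]) * pi / 180,
    tr = stats::runif(2, params_range$trans[1], params_range$trans[2]) * c(H, W),
    sc = stats::runif(1, params_range$scale[1], params_range$scale[2]),
    sh = stats::runif(1, params_range$shear[1], params_range$shear[2])))
  if (p$sc == 0) stop("degenerate transform: zero scale")
  # forward map: scale, shear, rotate, translate; sample with its inverse
  A <- matrix(c(cos(p$rot), sin(p$rot), -sin(p$rot), cos(p$rot)), 2) %*%
       matrix(c(p$sc, 0, p$sh * p$sc, p$sc), 2)
  Ainv <- solve(A)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  g <- .grid_coords(H)
  dr <- g$r - ctr[1] - p$tr[1]
  dc <- g$c - ctr[2] - p$tr[2]
  rr <- Ainv[1, 1] * dr + Ainv[1, 2] * dc + ctr[1]
  cc <- Ainv[2, 1] * dr + Ainv[2, 2] * dc + ctr[2]
  warp_pair(pair, rr, cc, list(kind = "affine", seed = seed, params = p))
}

# Gaussian-smoothed random displacement field (one channel), peak-normalized.
smooth_field <- function(H, W, sigma) {
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  g1 <- stats::dnorm(seq(-(k %/% 2), k %/% 2), sd = sigma)
  ker <- outer(g1, g1); ker <- ker / sum(ker)
  x <- array(stats::runif(H * W, -1, 1), c(H, W, 1, 1))
  sm <- conv2d_fw_cpp(x, array(ker, c(k, k, 1, 1)), 0, 1L, k %/% 2L)
  f <- matrix(sm, H, W)
  f / max(abs(f), 1e-12)
}

#' Elastic deformation augmentation
#'
#' Displaces sampling coordinates by two independent Gaussian-smoothed
#' random fields scaled to `alpha` pixels (smoothness `sigma` pixels);
#' image bilinear, mask nearest, same field for both.
#' @inheritParams affine_augment
#' @param sigma smoothing bandwidth of the displacement field, in pixels.
#' @param alpha peak displacement magnitude, in pixels.
#' @export
elastic_augment <- function(pair, sigma = 4, alpha = 3, seed = 1L) {
  H <- nrow(pair$image); W <- ncol(pair$image)
  f <- with_seed(seed, list(dr = smooth_field(H, W, sigma),
                            dc = smooth_field(H, W, sigma)))
  g <- .grid_coords(H)
  warp_pair(pair, g$r + alpha * f$dr, g$c + alpha * f$dc,
            list(kind = "elastic", seed = seed, sigma = sigma, alpha = alpha))
}

#' Pixel-intensity augmentation
#'
#' Random brightness shift, contrast scale and gamma applied to the image
#' only; the mask is returned bit-identical.
#' @inheritParams affine_augment
#' @export
intensity_augment <- function(pair, seed = 1L) {
  p <- with_seed(seed, list(bright = stats::runif(1, -0.15, 0.15),
                            contrast = stats::runif(1, 0.8, 1.2),
                            gamma = stats::runif(1, 0.8, 1.25)))
  x01 <- (pair$image + 1) / 2
  x01 <- pmin(pmax(x01^p$gamma * p$contrast + p$bright, 0), 1)
  structure(list(image = x01 * 2 - 1, mask = pair$mask,
                 provenance = list(kind = "intensity", seed = seed, params = p)),
            class = "augmented_pair")
}

#' CutMix augmentation
#'
#' Pastes the rectangular `box` region of `pairB` (image and mask) into
#' `pairA`; the mask is mixed spatially, never label-smoothed.
#' @param pairA,pairB pairs of identical shape.
#' @param box inclusive bounds `c(r1, r2, c1, c2)`; sampled if `NULL`.
#' @param seed RNG seed for box sampling.
#' @export
cutmix_augment <- function(pairA, pairB, box = NULL, seed = 1L) {
  if (!all(dim(pairA$image) == dim(pairB$image))) stop("pairs must share shape")
  H <- nrow(pairA$image); W <- ncol(pairA$image)
  if (is.null(box)) {
    box <- with_seed(seed, {
      bh <- as.integer(round(stats::runif(1, 0.3, 0.7) * H))
      bw <- as.integer(round(stats::runif(1, 0.3, 0.7) * W))
      r1 <- sample.int(H - bh + 1L, 1L)
      c1 <- sample.int(W - bw + 1L, 1L)
      c(r1, r1 + bh - 1L, c1, c1 + bw - 1L)
    })
  }
  if (box[2] < box[1] || box[4] < box[3]) stop("empty box")
  if (box[1] < 1 || box[2] > H || box[3] < 1 || box[4] > W) stop("box out of bounds")
  img <- pairA$image
  msk <- unclass(pairA$mask)
  img[box[1]:box[2], box[3]:box[4]] <- pairB$image[box[1]:box[2], box[3]:box[4]]
  msk[box[1]:box[2], box[3]:box[4]] <- unclass(pairB$mask)[box[1]:box[2], box[3]:box[4]]
  structure(list(image = img, mask = as_label_mask(msk),
                 provenance = list(kind = "cutmix", seed = seed, box = box)),
            class = "augmented_pair")
}

# --- segmentation U-Net -----------------------------------------------------

#' Segmentation training configuration
#'
#' The full-scale defaults follow the experimental setup: a four-level
#' U-Net trained with Adam (lr 1e-4, weight decay 1e-5); toy runs shrink
#' depth/width and epochs.
#' @param n_levels,channels,norm_groups U-Net shape.
#' @param epochs,batch_size,lr,weight_decay optimizer settings.
#' @param dice_weight weight of the soft-Dice term added to cross-entropy.
#' @param max_steps optional cap on total gradient steps (used by the
#'   harness to grant every regime an equal budget).
#' @export
seg_config <- function(n_levels = 4L, channels = c(64L, 128L, 256L, 512L),
                       norm_groups = 8L, epochs = 400L, batch_size = 8L,
                       lr = 1e-4, weight_decay = 1e-5, dice_weight = 1,
                       max_steps = Inf) {
  list(n_levels = as.integer(n_levels), channels = as.integer(channels),
       norm_groups = as.integer(norm_groups), epochs = as.integer(epochs),
       batch_size = as.integer(batch_size), lr = lr,
       weight_decay = weight_decay, dice_weight = dice_weight,
       max_steps = max_steps)
}

seg_backbone_cfg <- function(cfg) {
  backbone_config(n_levels = cfg$n_levels, channels = cfg$channels,
                  resblocks_per_level = 1L, attention_levels = integer(0),
                  norm_groups = cfg$norm_groups, in_channels = 1L,
                  out_channels = K_CLASSES, time_dim = 8L)
}

seg_forward_logits <- function(model, images) {
  N <- length(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, c(H, W, 1, N))
  for (j in seq_len(N)) x[, , 1, j] <- images[[j]]
  denoise(model, x, 0L)
}

#' Predict segmentation masks
#' @param model a trained [train_unet_seg()] model.
#' @param images list of image matrices.
#' @return list of label masks (per-pixel argmax of the logits).
#' @export
predict_seg <- function(model, images) {
  logits <- seg_forward_logits(model, images)
  lapply(seq_along(images), function(i) decode_mask(logits[, , , i]))
}

#' Train a U-Net segmenter
#'
#' Cross-entropy + soft-Dice loss, Adam with weight decay; after each epoch
#' the mean test-time Dice on the validation pairs is recorded and the
#' best-on-validation parameters are kept.
#' @param train_pairs,val_pairs lists of pairs with `image` and `mask`.
#' @param cfg a [seg_config()].
#' @param seed RNG seed; metric trajectory is reproducible.
#' @return a trained model with `val_history` and `best_val_dice`.
#' @export
train_unet_seg <- function(train_pairs, val_pairs, cfg = seg_config(), seed = 1L) {
  if (!length(train_pairs)) stop("empty training set")
  model <- build_denoiser(seg_backbone_cfg(cfg), seed = seed)
  n <- length(train_pairs)
  H <- nrow(train_pairs[[1]]$image)
  params <- model$params
  opt <- adam_new(params)
  val_hist <- numeric(0)
  best <- -Inf; best_params <- params
  steps_done <- 0L
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (b in seq_len(ceiling(n / cfg$batch_size))) {
        if (steps_done >= cfg$max_steps) break
        idx <- perm[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, n)]
        N <- length(idx)
        x <- array(0, c(H, H, 1, N))
        lab <- array(0L, c(H, H, N))
        for (j in seq_len(N)) {
          x[, , 1, j] <- train_pairs[[idx[j]]]$image
          lab[, , j] <- unclass(train_pairs[[idx[j]]]$mask)
        }
        tp <- ad_tape()
        P <- ad_params(tp, params)
        logits <- bb_forward(tp, P, model$cfg, ad_leaf(tp, x), 0L)
        loss <- ad_ce_dice(tp, logits, lab, dice_weight = cfg$dice_weight)
        grads <- ad_backward(tp, loss)
        total <- min(cfg$max_steps, cfg$epochs * ceiling(n / cfg$batch_size))
        st <- adam_step(opt, params, grads,
                        lr = lr_at_step(steps_done + 1L, total, cfg$lr),
                        weight_decay = cfg$weight_decay)
        opt <- st$opt; params <- st$params
        steps_done <- steps_done + 1L
      }
      if (length(val_pairs)) {
        model$params <- params
        preds <- predict_seg(model, lapply(val_pairs, `[[`, "image"))
        vd <- mean(vapply(seq_along(val_pairs), function(i)
          seg_metrics(preds[[i]], val_pairs[[i]]$mask)[["mean_dice"]], numeric(1)))
        val_hist <- c(val_hist, vd)
        if (vd > best) { best <- vd; best_params <- params }
      } else best_params <- params
      if (steps_done >= cfg$max_steps) break
    }
  })
  model$params <- best_params
  model$val_history <- val_hist
  model$best_val_dice <- best
  class(model) <- c("seg_unet", class(model))
  model
}

# --- experiment harness -----------------------------------------------------

# Returns the list of augmented pairs for one regime (real pairs excluded).
build_regime_pairs <- function(regime, train_pairs, n_aug, seed, checkpoints,
                               filter_cfg) {
  n <- length(train_pairs)
  switch(regime,
    none = list(),
    affine = lapply(seq_len(n_aug), function(i)
      affine_augment(train_pairs[[1 + (i - 1) %% n]], seed = seed * 1000L + i)),
    elastic = lapply(seq_len(n_aug), function(i)
      elastic_augment(train_pairs[[1 + (i - 1) %% n]], seed = seed * 1000L + i)),
    intensity = lapply(seq_len(n_aug), function(i)
      intensity_augment(train_pairs[[1 + (i - 1) %% n]], seed = seed * 1000L + i)),
    cutmix = lapply(seq_len(n_aug), function(i) with_seed(seed * 1000L + i, {
      ab <- sample.int(n, 2, replace = n < 2)
      cutmix_augment(train_pairs[[ab[1]]], train_pairs[[ab[2]]],
                     seed = seed * 1000L + i)
    })),
    diffusion = {
      if (is.null(checkpoints$mask_ddpm) || is.null(checkpoints$ldm) ||
          is.null(checkpoints$autoencoder))
        stop("diffusion regime requires mask_ddpm, ldm and autoencoder checkpoints")
      accepted <- list()
      tries <- 0L
      while (length(accepted) < n_aug && tries < 8L) {
        tries <- tries + 1L
        pls <- sample_masks(checkpoints$mask_ddpm, min(n_aug, 32L),
                            sampler = "ddim", n_steps = 50L, eta = 1,
                            seed = seed * 100L + tries)
        flt <- filter_labels(pls, filter_cfg)
        accepted <- c(accepted, flt$accepted$masks)
      }
      if (!length(accepted)) stop("label filter rejected every generated mask")
      accepted <- accepted[seq_len(min(n_aug, length(accepted)))]
      imgs <- synthesize_images(checkpoints$ldm, checkpoints$autoencoder,
                                accepted, eta = 1, seed = seed)
      lapply(seq_along(accepted), function(i)
        structure(list(image = imgs[[i]], mask = accepted[[i]],
                       provenance = list(kind = "diffusion", seed = seed)),
                  class = "augmented_pair"))
    },
    stop("unknown regime: ", regime))
}

#' Compare augmentation regimes on a shared test split
#'
#' Trains one segmenter per requested regime on the same real training data
#' plus regime-specific augmented pairs (equal gradient-step budgets),
#' evaluates every model on the shared held-out test pairs, and returns a
#' table of per-class and mean Dice/IoU. Duplicate regime requests reuse
#' the cached run.
#'
#' @param dataset a [generate_dataset()]-style list (`train`, `val`, `test`).
#' @param regimes character vector from
#'   `c("none","affine","elastic","intensity","cutmix","diffusion")`.
#' @param seg_cfg a [seg_config()].
#' @param n_aug generated/augmented pairs added per regime (default: as many
#'   as there are real training pairs).
#' @param n_real optional number of real labeled training pairs used per
#'   seed (a seeded subsample of the training split). Emulates the
#'   annotation-scarce setting that augmentation targets; default uses the
#'   whole training split.
#' @param seeds integer vector; the full comparison is repeated per seed.
#' @param checkpoints list with `mask_ddpm`, `ldm`, `autoencoder` (required
#'   for the diffusion regime).
#' @param filter_cfg a [filter_config()] screening generated masks.
#' @return data.frame, one row per regime x seed.
#' @export
run_experiment <- function(dataset, regimes = "none", seg_cfg = seg_config(),
                           n_aug = NULL, n_real = NULL, seeds = 1L,
                           checkpoints = list(),
                           filter_cfg = filter_config()) {
  if (is.null(n_aug)) n_aug <- length(dataset$train)
  rows <- list()
  # the synthetic pool is generated once and shared across seeds (one
  # generated dataset, several segmenter trainings); classical augmentations
  # are cheap and drawn per seed
  diffusion_pool <- NULL
  for (sd in seeds) {
    cache <- list()
    train_real <- if (is.null(n_real)) dataset$train
      else dataset$train[with_seed(sd * 7L + 1L,
                                   sample.int(length(dataset$train), n_real))]
    for (regime in regimes) {
      if (is.null(cache[[regime]])) {
        aug <- if (regime == "diffusion") {
          if (is.null(diffusion_pool))
            diffusion_pool <- build_regime_pairs("diffusion", train_real, n_aug,
                                                 seeds[1], checkpoints, filter_cfg)
          diffusion_pool
        } else {
          build_regime_pairs(regime, train_real, n_aug, sd, checkpoints,
                             filter_cfg)
        }
        pairs <- c(train_real, aug)
        model <- train_unet_seg(pairs, dataset$val, seg_cfg, seed = sd)
        preds <- predict_seg(model, lapply(dataset$test, `[[`, "image"))
        mm <- vapply(seq_along(dataset$test), function(i)
          seg_metrics(preds[[i]], dataset$test[[i]]$mask), numeric(8))
        cache[[regime]] <- rowMeans(mm)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(regime = regime, seed = sd, t(cache[[regime]]))
    }
  }
  do.call(rbind, rows)
}
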