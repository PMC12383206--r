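#' @useDynLib cardiacaug, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# A compact reverse-mode autodiff tape over dense arrays.
#
# All image tensors use dim = c(H, W, C, N); vectors/matrices are documented
# per op. Nodes are environments recorded on a tape in creation order;
# backward() walks the tape in reverse, accumulating gradients. Parameter
# leaves carry a name under which their gradient is collected.
# ---------------------------------------------------------------------------

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ad_node <- function(tp, val, parents = list(), backfn = NULL, pname = NULL) {
  # force arguments first: evaluating a nested op expression may create
  # parent nodes, which must receive ids BEFORE this node's id
  force(parents); force(val)
  nd <- new.env(parent = emptyenv())
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  nd$id <- tp$n
  nd$val <- val
  nd$parents <- parents
  nd$backfn <- backfn
  nd$pname <- pname
  tp$nodes[[tp$n]] <- nd
  nd
}

ad_leaf <- function(tp, val, pname = NULL) ad_node(tp, val, pname = pname)

# Lift every entry of a named parameter list onto the tape.
ad_params <- function(tp, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ad_leaf(tp, params[[nm]], pname = nm)
  out
}

# Backward pass from a scalar loss node; returns named gradient list.
ad_backward <- function(tp, loss) {
  grads <- vector("list", tp$n)
  grads[[loss$id]] <- 1
  pgrads <- list()
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- tp$nodes[[id]]
    if (!is.null(nd$pname)) {
      pgrads[[nd$pname]] <- if (is.null(pgrads[[nd$pname]])) g else pgrads[[nd$pname]] + g
    }
    if (length(nd$parents) && !is.null(nd$backfn)) {
      pg <- nd$backfn(g)
      for (k in seq_along(nd$parents)) {
        pid <- nd$parents[[k]]$id
        if (!is.null(pg[[k]])) {
          grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]] else grads[[pid]] + pg[[k]]
        }
      }
    }
    grads[id] <- list(NULL) # free memory without shifting list indices
  }
  pgrads
}

# ---- elementwise and shape ops --------------------------------------------

ad_add <- function(tp, a, b) {
  ad_node(tp, a$val + b$val, list(a, b), function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  ad_node(tp, a$val - b$val, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(tp, a, b) {
  av <- a$val; bv <- b$val
  ad_node(tp, av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(tp, a, s) {
  ad_node(tp, a$val * s, list(a), function(g) list(g * s))
}

ad_add_const <- function(tp, a, k) {
  ad_node(tp, a$val + k, list(a), function(g) list(g))
}

ad_silu <- function(tp, a) {
  x <- a$val
  sig <- 1 / (1 + exp(-x))
  ad_node(tp, x * sig, list(a), function(g) list(g * (sig * (1 + x * (1 - sig)))))
}

ad_exp <- function(tp, a) {
  y <- exp(a$val)
  ad_node(tp, y, list(a), function(g) list(g * y))
}

ad_tanh <- function(tp, a) {
  y <- tanh(a$val)
  ad_node(tp, y, list(a), function(g) list(g * (1 - y^2)))
}

# Channel slice of an HWCN tensor.
ad_slice_ch <- function(tp, a, from, to) {
  d <- dim(a$val)
  y <- a$val[, , from:to, , drop = FALSE]
  ad_node(tp, y, list(a), function(g) {
    gx <- array(0, d)
    gx[, , from:to, ] <- g
    list(gx)
  })
}

ad_concat_ch <- function(tp, a, b) {
  da <- dim(a$val); db <- dim(b$val)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$val
  y[, , da[3] + seq_len(db[3]), ] <- b$val
  ad_node(tp, y, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# ---- convolution / resampling ---------------------------------------------

ad_conv2d <- function(tp, x, w, b, stride = 1L, pad = 1L) {
  xv <- x$val; wv <- w$val
  y <- conv2d_fw_cpp(xv, wv, b$val, as.integer(stride), as.integer(pad))
  # data leaves (no parameters, no upstream ops) never need an input gradient
  want_gx <- !(is.null(x$backfn) && is.null(x$pname))
  ad_node(tp, y, list(x, w, b), function(g) {
    bw <- conv2d_bw_cpp(xv, wv, g, as.integer(stride), as.integer(pad), want_gx)
    list(if (want_gx) bw$gx else NULL, bw$gw, bw$gb)
  })
}

# Nearest-neighbour upsampling by integer factor f.
up_nearest <- function(x, f) {
  d <- dim(x)
  idx_h <- rep(seq_len(d[1]), each = f)
  idx_w <- rep(seq_len(d[2]), each = f)
  x[idx_h, idx_w, , , drop = FALSE]
}

ad_upnearest <- function(tp, a, f = 2L) {
  d <- dim(a$val)
  y <- up_nearest(a$val, f)
  ad_node(tp, y, list(a), function(g) {
    # sum each f x f block back onto the source pixel
    gh <- array(0, c(d[1], d[2] * f, d[3], d[4]))
    for (i in seq_len(f)) gh <- gh + g[seq(i, d[1] * f, by = f), , , , drop = FALSE]
    gx <- array(0, d)
    for (j in seq_len(f)) gx <- gx + gh[, seq(j, d[2] * f, by = f), , , drop = FALSE]
    list(gx)
  })
}

# ---- normalization ---------------------------------------------------------

# Parameter-free group normalization over (H, W, channels-in-group).
ad_groupnorm <- function(tp, a, groups, eps = 1e-5) {
  x <- a$val
  d <- dim(x)
  C <- d[3]; N <- d[4]
  stopifnot(C %% groups == 0)
  m <- d[1] * d[2] * (C %/% groups)
  xg <- matrix(x, m)                        # m x (groups*N)
  nc <- length(x) %/% m
  mu <- .colMeans(xg, m, nc)
  xc <- xg - rep(mu, each = m)
  v <- .colMeans(xc * xc, m, nc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(istd, each = m)
  y <- array(xhat, d)
  ad_node(tp, y, list(a), function(g) {
    gg <- matrix(g, m)
    gmean <- .colMeans(gg, m, nc)
    gxmean <- .colMeans(gg * xhat, m, nc)
    gx <- (gg - rep(gmean, each = m) - xhat * rep(gxmean, each = m)) *
      rep(istd, each = m)
    list(array(gx, d))
  })
}

# Per-channel affine y = x * gamma[c] + beta[c].
ad_chaffine <- function(tp, a, gamma, beta) {
  x <- a$val
  d <- dim(x)
  hw <- d[1] * d[2]
  gv <- gamma$val
  gfull <- rep(rep(gv, each = hw), times = d[4])
  bfull <- rep(rep(beta$val, each = hw), times = d[4])
  y <- array(x * gfull + bfull, d)
  nch <- length(x) %/% hw
  per_ch <- function(z) .rowSums(matrix(.colSums(z, hw, nch), d[3]), d[3], d[4])
  ad_node(tp, y, list(a, gamma, beta), function(g) {
    list(array(g * gfull, d), per_ch(g * x), per_ch(g))
  })
}

# Per-sample per-channel bias (timestep embedding injection): tb is C x N.
ad_add_tbias <- function(tp, a, tb) {
  d <- dim(a$val)
  hw <- d[1] * d[2]
  ad_node(tp, a$val + rep(tb$val, each = hw), list(a, tb), function(g) {
    list(g, matrix(.colSums(g, hw, d[3] * d[4]), d[3], d[4]))
  })
}

# ---- dense / attention -----------------------------------------------------

# x: D x N (samples as columns), W: O x D, b: O.
ad_linear <- function(tp, x, W, b) {
  xv <- x$val; Wv <- W$val
  y <- Wv %*% xv + b$val
  ad_node(tp, y, list(x, W, b), function(g) {
    list(crossprod(Wv, g), tcrossprod(g, xv), .rowSums(g, nrow(g), ncol(g)))
  })
}

# Reinterpret H x W x C x N as tokens (H*W) x C x N (pure dim change).
ad_tokens <- function(tp, a) {
  d <- dim(a$val)
  y <- a$val
  dim(y) <- c(d[1] * d[2], d[3], d[4])
  ad_node(tp, y, list(a), function(g) { dim(g) <- d; list(g) })
}

ad_untokens <- function(tp, a, H, W) {
  d <- dim(a$val)
  y <- a$val
  dim(y) <- c(H, W, d[2], d[3])
  ad_node(tp, y, list(a), function(g) { dim(g) <- d; list(g) })
}

# Batched matmul over 3rd dim: a (I x K x N), b (K x J x N) -> I x J x N.
ad_bmm <- function(tp, a, b, ta = FALSE, tb = FALSE) {
  av <- a$val; bv <- b$val
  N <- dim(av)[3]
  f <- function(m, t) if (t) t(m) else m
  I <- if (ta) dim(av)[2] else dim(av)[1]
  J <- if (tb) dim(bv)[1] else dim(bv)[2]
  y <- array(0, c(I, J, N))
  for (n in seq_len(N)) y[, , n] <- f(av[, , n], ta) %*% f(bv[, , n], tb)
  ad_node(tp, y, list(a, b), function(g) {
    ga <- array(0, dim(av)); gb <- array(0, dim(bv))
    for (n in seq_len(N)) {
      gn <- g[, , n, drop = TRUE]
      if (is.null(dim(gn))) gn <- matrix(gn, I, J)
      an <- f(av[, , n], ta); bn <- f(bv[, , n], tb)
      gan <- gn %*% t(bn); gbn <- t(an) %*% gn
      ga[, , n] <- if (ta) t(gan) else gan
      gb[, , n] <- if (tb) t(gbn) else gbn
    }
    list(ga, gb)
  })
}

# Softmax over the 2nd dim of an I x J x N array.
ad_softmax2 <- function(tp, a) {
  x <- a$val
  d <- dim(x)
  xm <- matrix(aperm(x, c(2, 1, 3)), d[2])  # J x (I*N)
  idx <- max.col(t(xm), ties.method = "first")
  mx <- xm[cbind(idx, seq_along(idx))]
  e <- exp(xm - rep(mx, each = d[2]))
  ym <- e / rep(.colSums(e, d[2], length(idx)), each = d[2])
  y <- aperm(array(ym, c(d[2], d[1], d[3])), c(2, 1, 3))
  ad_node(tp, y, list(a), function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3)), d[2])
    gx <- ym * (gm - rep(.colSums(gm * ym, d[2], ncol(gm)), each = d[2]))
    list(aperm(array(gx, c(d[2], d[1], d[3])), c(2, 1, 3)))
  })
}

# ---- losses ----------------------------------------------------------------

ad_mse <- function(tp, pred, target) {
  p <- pred$val
  r <- p - target
  n <- length(r)
  ad_node(tp, sum(r * r) / n, list(pred), function(g) list(g * 2 * r / n))
}

ad_mae <- function(tp, pred, target) {
  r <- pred$val - target
  n <- length(r)
  ad_node(tp, sum(abs(r)) / n, list(pred), function(g) list(g * sign(r) / n))
}

# KL( N(mu, exp(logvar)) || N(0, 1) ), mean over elements.
ad_kl_gauss <- function(tp, mu, logvar) {
  mv <- mu$val; lv <- logvar$val
  n <- length(mv)
  val <- 0.5 * sum(mv^2 + exp(lv) - 1 - lv) / n
  ad_node(tp, val, list(mu, logvar), function(g) {
    list(g * mv / n, g * 0.5 * (exp(lv) - 1) / n)
  })
}

ad_sum2 <- function(tp, a, b, c = NULL) {
  if (is.null(c)) {
    ad_node(tp, a$val + b$val, list(a, b), function(g) list(g, g))
  } else {
    ad_node(tp, a$val + b$val + c$val, list(a, b, c), function(g) list(g, g, g))
  }
}

# Cross-entropy + soft-Dice segmentation loss.
# logits: H x W x K x N; labels: H x W x N integer classes 0..K-1.
ad_ce_dice <- function(tp, logits, labels, dice_weight = 1, smooth = 1) {
  x <- logits$val
  d <- dim(x)
  K <- d[3]; npix <- d[1] * d[2] * d[4]
  mx <- apply(x, c(1, 2, 4), max)
  ex <- exp(x - aperm(array(mx, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3)))
  ssum <- apply(ex, c(1, 2, 4), sum)
  p <- ex / aperm(array(ssum, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
  onehot <- array(0, d)
  for (k in seq_len(K)) onehot[, , k, ] <- (labels == (k - 1)) * 1
  ce <- -sum(onehot * log(pmax(p, 1e-12))) / npix
  # soft dice per class over the whole batch
  inter <- num <- den <- numeric(K)
  for (k in seq_len(K)) {
    inter[k] <- sum(p[, , k, ] * onehot[, , k, ])
    num[k] <- 2 * inter[k] + smooth
    den[k] <- sum(p[, , k, ]) + sum(onehot[, , k, ]) + smooth
  }
  dice_loss <- 1 - mean(num / den)
  val <- ce + dice_weight * dice_loss
  ad_node(tp, val, list(logits), function(g) {
    # dL/dp
    gp <- -onehot / pmax(p, 1e-12) / npix
    for (k in seq_len(K)) {
      gp[, , k, ] <- gp[, , k, ] + dice_weight *
        (-(1 / K)) * (2 * onehot[, , k, ] * den[k] - num[k]) / den[k]^2
    }
    # chain through softmax: gx = p * (gp - sum_k gp_k p_k)
    dot <- apply(gp * p, c(1, 2, 4), sum)
    gx <- p * (gp - aperm(array(dot, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3)))
    list(g * gx)
  })
}

# ---- parameter init and Adam ----------------------------------------------

init_conv <- function(kh, kw, cin, cout, gain = 1) {
  fan_in <- kh * kw * cin
  array(stats::rnorm(kh * kw * cin * cout, 0, gain * sqrt(2 / fan_in)),
        c(kh, kw, cin, cout))
}

init_linear <- function(din, dout, gain = 1) {
  matrix(stats::rnorm(din * dout, 0, gain * sqrt(2 / din)), dout, din)
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(opt, params, grads, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

# Per-step learning rate: linear warmup to `lr` then cosine decay toward
# lr/50. The standard small-batch diffusion training recipe; `lr` is the
# peak rate.
lr_at_step <- function(step, total_steps, lr, warmup = NULL) {
  if (is.null(warmup)) warmup <- max(1L, min(100L, total_steps %/% 10L))
  if (step <= warmup) return(lr * step / warmup)
  frac <- (step - warmup) / max(1, total_steps - warmup)
  lr_min <- lr / 50
  lr_min + (lr - lr_min) * 0.5 * (1 + cos(pi * frac))
}

# Run code with a temporary RNG state seeded by `seed`, restoring afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}
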