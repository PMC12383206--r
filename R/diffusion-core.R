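# ---------------------------------------------------------------------------
# Diffusion machinery shared by the mask DDPM and the latent diffusion model:
# variance schedules, the closed-form forward process, the epsilon-matching
# loss, classifier-free guidance mixing, and DDPM/DDIM reverse samplers.
# ---------------------------------------------------------------------------

#' Build a diffusion noise schedule
#'
#' Constructs the per-step noise variances \eqn{\beta_t}, the signal
#' retentions \eqn{\alpha_t = 1 - \beta_t}, and their running product
#' \eqn{\bar\alpha_t = \prod_{i \le t} \alpha_i} used by the forward and
#' reverse diffusion processes.
#'
#' @param n_steps number of diffusion steps T.
#' @param beta_start,beta_end endpoints of the linearly interpolated
#'   variance schedule. Defaults follow the standard DDPM recipe
#'   (1e-4 to 0.02 over 1000 steps).
#' @param kind schedule family; only `"linear"` is provided.
#' @param sigma_kind reverse-step noise scale: `"beta"` uses
#'   \eqn{\sigma_t^2 = \beta_t}; `"posterior"` uses the forward-posterior
#'   variance \eqn{\tilde\beta_t = \beta_t (1-\bar\alpha_{t-1})/(1-\bar\alpha_t)}.
#'   Both are standard fixed-variance choices; the simplified training loss
#'   does not learn a variance head. The final reverse step is always
#'   deterministic (\eqn{\sigma_1 = 0}).
#' @return an object of class `noise_schedule` with fields `T`, `betas`,
#'   `alphas`, `alpha_bars`, `sigmas`.
#' @export
make_schedule <- function(n_steps = 1000L, beta_start = 1e-4, beta_end = 0.02,
                          kind = "linear", sigma_kind = c("beta", "posterior")) {
  sigma_kind <- match.arg(sigma_kind)
  kind <- match.arg(kind, "linear")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (!(beta_start >= 0 && beta_start <= beta_end && beta_end < 1))
    stop("require 0 <= beta_start <= beta_end < 1")
  betas <- if (n_steps == 1) beta_start else seq(beta_start, beta_end, length.out = n_steps)
  alphas <- 1 - betas
  alpha_bars <- cumprod(alphas)
  ab_prev <- c(1, alpha_bars[-n_steps])
  sigmas <- switch(sigma_kind,
    beta = sqrt(betas),
    posterior = sqrt(betas * (1 - ab_prev) / pmax(1 - alpha_bars, 1e-20)))
  sigmas[1] <- 0
  structure(list(T = as.integer(n_steps), betas = betas, alphas = alphas,
                 alpha_bars = alpha_bars, sigmas = sigmas,
                 beta_start = beta_start, beta_end = beta_end,
                 kind = kind, sigma_kind = sigma_kind),
            class = "noise_schedule")
}

# alpha_bar with the convention alpha_bar(0) = 1
.abar <- function(sched, t) if (t == 0) 1 else sched$alpha_bars[t]

check_t <- function(sched, t) {
  if (t < 1 || t > sched$T) stop("timestep t = ", t, " outside 1..", sched$T)
}

#' Closed-form forward diffusion
#'
#' Jumps directly from clean data to timestep `t`:
#' \eqn{y_t = \sqrt{\bar\alpha_t}\, y_0 + \sqrt{1-\bar\alpha_t}\, \epsilon}.
#'
#' @param y0 clean data array.
#' @param t target timestep in `1..T`.
#' @param eps Gaussian noise array, same shape as `y0`.
#' @param sched a [make_schedule()] object.
#' @export
forward_diffuse <- function(y0, t, eps, sched) {
  check_t(sched, t)
  if (!identical(dim(y0), dim(eps)) || length(y0) != length(eps))
    stop("eps shape must match y0")
  ab <- sched$alpha_bars[t]
  sqrt(ab) * y0 + sqrt(1 - ab) * eps
}

#' Stepwise forward diffusion (Markov form)
#'
#' Applies the one-step recursion
#' \eqn{y_t = \sqrt{\alpha_t}\, y_{t-1} + \sqrt{1-\alpha_t}\, \epsilon_{t-1}}
#' `t` times. Marginally equivalent to [forward_diffuse()].
#'
#' @param eps_sequence list of `t` noise arrays (used in order for steps 1..t).
#' @inheritParams forward_diffuse
#' @export
iterate_forward <- function(y0, t, eps_sequence, sched) {
  check_t(sched, t)
  if (length(eps_sequence) != t)
    stop("eps_sequence must have exactly t = ", t, " entries")
  y <- y0
  for (i in seq_len(t)) {
    a <- sched$alphas[i]
    y <- sqrt(a) * y + sqrt(1 - a) * eps_sequence[[i]]
  }
  y
}

#' Recover the clean-data estimate from a noise prediction
#'
#' Inverts the closed-form forward process:
#' \eqn{\hat y_0 = (y_t - \sqrt{1-\bar\alpha_t}\,\hat\epsilon)/\sqrt{\bar\alpha_t}}.
#' @inheritParams forward_diffuse
#' @param y_t noisy data at timestep `t`.
#' @param eps_hat predicted noise.
#' @export
predict_x0 <- function(y_t, eps_hat, t, sched) {
  check_t(sched, t)
  ab <- sched$alpha_bars[t]
  if (ab <= 0) stop("alpha_bar at t is zero; cannot invert")
  (y_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

#' One ancestral (DDPM) reverse step
#'
#' \eqn{y_{t-1} = \frac{1}{\sqrt{\alpha_t}}\left(y_t -
#' \frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\hat\epsilon\right) + \sigma_t z}.
#' At `t = 1` the noise term is dropped so the final sample is deterministic.
#'
#' @param z Gaussian noise array (ignored at `t = 1`).
#' @inheritParams predict_x0
#' @export
ddpm_step <- function(y_t, eps_hat, t, z, sched) {
  check_t(sched, t)
  a <- sched$alphas[t]
  ab <- sched$alpha_bars[t]
  mu <- (y_t - (1 - a) / sqrt(1 - ab) * eps_hat) / sqrt(a)
  if (t > 1) mu + sched$sigmas[t] * z else mu
}

#' Simplified diffusion training loss
#'
#' Mean squared error between true and predicted noise (mean over all
#' elements), the epsilon-matching objective used for both the mask DDPM
#' and the latent diffusion model.
#' @param eps,eps_hat arrays of identical shape.
#' @export
simple_loss <- function(eps, eps_hat) {
  if (length(eps) != length(eps_hat) || !identical(dim(eps), dim(eps_hat)))
    stop("eps and eps_hat shapes must match")
  mean((eps - eps_hat)^2)
}

#' Classifier-free guidance combination
#'
#' \eqn{\hat\epsilon = \hat\epsilon_u + w (\hat\epsilon_c - \hat\epsilon_u)}:
#' `w = 0` is unconditional, `w = 1` purely conditional, `w > 1` extrapolates
#' toward the condition.
#' @param eps_uncond,eps_cond unconditional / conditional noise predictions.
#' @param w guidance weight, `w >= 0`.
#' @export
cfg_combine <- function(eps_uncond, eps_cond, w) {
  if (w < 0) stop("guidance weight must be >= 0")
  if (length(eps_uncond) != length(eps_cond))
    stop("prediction shapes must match")
  eps_uncond + w * (eps_cond - eps_uncond)
}

# Evenly spaced decreasing timestep subsequence T = t_1 > ... > t_n >= 1.
ddim_timesteps <- function(T, n_steps) {
  if (n_steps > T) stop("n_steps must be <= T")
  unique(as.integer(round(seq(T, 1, length.out = n_steps))))
}

#' DDIM sampling
#'
#' Accelerated reverse sampling over an evenly spaced subsequence of the
#' diffusion timesteps. With `eta = 0` the trajectory is deterministic given
#' the initial noise (and condition); `eta = 1` over the full subsequence
#' recovers ancestral sampling with the forward-posterior variance.
#'
#' @param denoiser function `(x, t, condition)` returning a predicted-noise
#'   array shaped like `x`. `t` may be a scalar or per-sample vector.
#' @param sched a [make_schedule()] object.
#' @param n_steps length of the timestep subsequence (e.g. 50 of 1000).
#' @param eta stochasticity in `[0, 1]`.
#' @param shape dims `c(H, W, C, N)` of the sample tensor.
#' @param seed RNG seed for the initial noise and any per-step noise.
#' @param condition optional conditioning tensor forwarded to the denoiser.
#' @param x_init optional initial noise tensor (overrides seeded draw).
#' @param step_noise optional list of per-step noise arrays (for equivalence
#'   testing against [ddpm_step()]).
#' @param clip_x0 if `TRUE`, clamp the intermediate clean-data estimate to
#'   `[-1, 1]` at every step (the data range of masks and images); stabilizes
#'   sampling from lightly trained models.
#' @return array of `shape` at t = 0.
#' @export
ddim_sample <- function(denoiser, sched, n_steps, eta = 0, shape, seed = 1L,
                        condition = NULL, x_init = NULL, step_noise = NULL,
                        clip_x0 = FALSE) {
  ts <- ddim_timesteps(sched$T, n_steps)
  x <- x_init
  with_seed(seed, {
    if (is.null(x)) x <- array(stats::rnorm(prod(shape)), shape)
    for (i in seq_along(ts)) {
      t <- ts[i]
      t_prev <- if (i < length(ts)) ts[i + 1] else 0L
      eps_hat <- denoiser(x, t, condition)
      ab_t <- .abar(sched, t)
      ab_p <- .abar(sched, t_prev)
      x0 <- (x - sqrt(1 - ab_t) * eps_hat) / sqrt(ab_t)
      if (clip_x0) {
        x0 <- pmin(pmax(x0, -1), 1)
        eps_hat <- (x - sqrt(ab_t) * x0) / sqrt(1 - ab_t)
      }
      sigma <- eta * sqrt((1 - ab_p) / (1 - ab_t)) * sqrt(1 - ab_t / ab_p)
      if (!is.finite(sigma)) sigma <- 0
      dir_coef <- sqrt(max(1 - ab_p - sigma^2, 0))
      x <- sqrt(ab_p) * x0 + dir_coef * eps_hat
      if (sigma > 0 && t_prev > 0) {
        z <- if (!is.null(step_noise)) step_noise[[i]] else array(stats::rnorm(prod(shape)), shape)
        x <- x + sigma * z
      }
    }
  })
  x
}
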