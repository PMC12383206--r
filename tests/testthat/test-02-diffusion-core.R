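test_that("schedule construction matches direct products and invariants", {
  # two-step schedule with alpha = (0.9, 0.8)
  s2 <- make_schedule(2L, 0.1, 0.2)
  expect_equal(s2$alphas, c(0.9, 0.8))
  expect_equal(s2$alpha_bars, c(0.9, 0.72))
  # degenerate no-noise schedule
  s1 <- make_schedule(1L, 0, 0)
  expect_equal(s1$alpha_bars, 1)
  # full-length schedule vs an independent explicit product loop
  s <- make_schedule(1000L, 1e-4, 0.02)
  prod_loop <- 1
  betas <- seq(1e-4, 0.02, length.out = 1000)
  for (t in 1:1000) prod_loop <- prod_loop * (1 - betas[t])
  expect_equal(s$alpha_bars[1000], prod_loop, tolerance = 1e-12)
  # invariants: strictly decreasing, ratio recovers alpha
  expect_true(all(diff(s$alpha_bars) < 0))
  ratios <- s$alpha_bars / c(1, s$alpha_bars[-1000])
  expect_equal(ratios, s$alphas, tolerance = 1e-12)
  expect_error(make_schedule(10L, 0.5, 0.2), "beta")
  expect_error(make_schedule(10L, -0.1, 0.2), "beta")
})

test_that("closed-form forward diffusion is the stated affine combination", {
  s2 <- make_schedule(2L, 0.1, 0.2) # alpha_bar_2 = 0.72
  y0 <- array(rnorm(16), c(2, 2, 2, 2))
  z0 <- array(0, dim(y0))
  expect_equal(forward_diffuse(y0, 2L, z0, s2), sqrt(0.72) * y0)
  eps <- array(rnorm(16), dim(y0))
  expect_equal(forward_diffuse(z0, 2L, eps, s2), sqrt(1 - 0.72) * eps)
  expect_error(forward_diffuse(y0, 2L, array(0, c(2, 2, 2, 1)), s2), "shape")
  expect_error(forward_diffuse(y0, 3L, z0, s2), "timestep")
})

test_that("forward marginal moments match Monte-Carlo at alpha_bar = 0.5", {
  # find t where alpha_bar ~ 0.5 and check empirical mean/var over draws
  s <- make_schedule(1000L, 1e-4, 0.02)
  t <- which.min(abs(s$alpha_bars - 0.5))
  ab <- s$alpha_bars[t]
  y0 <- array(0.7, c(1, 1, 1, 1))
  set.seed(99)
  draws <- replicate(1e4, forward_diffuse(y0, t, array(rnorm(1), dim(y0)), s)[1])
  se_mean <- sqrt(1 - ab) / sqrt(1e4)
  expect_lt(abs(mean(draws) - sqrt(ab) * 0.7), 4 * se_mean)
  se_var <- (1 - ab) * sqrt(2 / (1e4 - 1))
  expect_lt(abs(var(draws) - (1 - ab)), 4 * se_var)
})

test_that("stepwise forward recursion telescopes and matches hand expansion", {
  s <- make_schedule(3L, 0.1, 0.3)
  y0 <- array(2, c(1, 1, 1, 1))
  e1 <- array(0.5, dim(y0)); e2 <- array(-1, dim(y0)); e3 <- array(0.25, dim(y0))
  # one step equals the closed form
  expect_equal(iterate_forward(y0, 1L, list(e1), s),
               forward_diffuse(y0, 1L, e1, s))
  # zero noise telescopes to sqrt(alpha_bar_t) y0
  z <- array(0, dim(y0))
  expect_equal(iterate_forward(y0, 3L, list(z, z, z), s),
               sqrt(s$alpha_bars[3]) * y0)
  # hand-expanded nested affine expression (scalar)
  a <- s$alphas
  expected <- sqrt(a[3]) * (sqrt(a[2]) * (sqrt(a[1]) * 2 + sqrt(1 - a[1]) * 0.5) +
                            sqrt(1 - a[2]) * (-1)) + sqrt(1 - a[3]) * 0.25
  expect_equal(iterate_forward(y0, 3L, list(e1, e2, e3), s)[1], expected,
               tolerance = 1e-12)
  expect_error(iterate_forward(y0, 3L, list(e1, e2), s), "entries")
})

test_that("predict_x0 inverts the forward process", {
  s <- make_schedule(100L, 1e-3, 0.05)
  y0 <- array(rnorm(64), c(4, 4, 4, 1))
  for (t in c(1L, 37L, 100L)) {
    eps <- array(rnorm(64), dim(y0))
    yt <- forward_diffuse(y0, t, eps, s)
    expect_lt(max(abs(predict_x0(yt, eps, t, s) - y0)), 1e-5)
  }
  # eps_hat = 0 returns y_t / sqrt(alpha_bar)
  yt <- array(1.5, c(1, 1, 1, 1))
  expect_equal(predict_x0(yt, yt * 0, 50L, s), yt / sqrt(s$alpha_bars[50]))
  # direct formula evaluation at alpha_bar = 0.36
  sd2 <- make_schedule(2L, 1 - 0.9, 1 - 0.4) # alphas 0.9, 0.4 -> abar2 = 0.36
  expect_equal(sd2$alpha_bars[2], 0.36, tolerance = 1e-12)
  yt <- array(c(0.3, -1.2), c(1, 1, 2, 1)); eh <- array(c(0.1, 0.7), dim(yt))
  expect_equal(predict_x0(yt, eh, 2L, sd2), (yt - sqrt(1 - 0.36) * eh) / 0.6,
               tolerance = 1e-12)
})

test_that("ddpm_step implements the ancestral update with deterministic last step", {
  sd2 <- make_schedule(2L, 1 - 0.9, 1 - 0.9) # alpha = 0.9 both steps
  y <- array(rnorm(8), c(2, 2, 2, 1))
  z <- array(rnorm(8), dim(y))
  # eps_hat = 0, z = 0: pure rescale
  expect_equal(ddpm_step(y, y * 0, 2L, z * 0, sd2), y / sqrt(0.9))
  # final step ignores z
  expect_equal(ddpm_step(y, y * 0, 1L, z, sd2), ddpm_step(y, y * 0, 1L, z * 0, sd2))
  # elementwise formula at alpha = 0.9, alpha_bar = 0.5, sigma = 0.1
  s <- make_schedule(3L, 0.05, 0.15)
  s$alphas[2] <- 0.9; s$alpha_bars[2] <- 0.5; s$sigmas[2] <- 0.1
  eh <- array(rnorm(8), dim(y))
  want <- (y - (1 - 0.9) / sqrt(1 - 0.5) * eh) / sqrt(0.9) + 0.1 * z
  expect_equal(ddpm_step(y, eh, 2L, z, s), want, tolerance = 1e-12)
  expect_error(ddpm_step(y, eh, 9L, z, s), "timestep")
})

test_that("DDIM is deterministic at eta = 0 and has the zero-denoiser closed form", {
  s <- make_schedule(100L, 1e-3, 0.05)
  zero_den <- function(x, t, cond) x * 0
  a <- ddim_sample(zero_den, s, 10L, eta = 0, shape = c(4, 4, 2, 1), seed = 21L)
  b <- ddim_sample(zero_den, s, 10L, eta = 0, shape = c(4, 4, 2, 1), seed = 21L)
  expect_identical(a, b)
  # trajectory under zero prediction: product of sqrt(abar_prev / abar_t)
  ts <- unique(as.integer(round(seq(100, 1, length.out = 10))))
  abar <- function(t) if (t == 0) 1 else s$alpha_bars[t]
  fac <- 1
  for (i in seq_along(ts)) {
    tprev <- if (i < length(ts)) ts[i + 1] else 0L
    fac <- fac * sqrt(abar(tprev) / abar(ts[i]))
  }
  x0 <- withr::with_seed(21L, array(rnorm(32), c(4, 4, 2, 1)))
  expect_equal(a, x0 * fac, tolerance = 1e-9)
  expect_error(ddim_sample(zero_den, s, 101L, 0, c(4, 4, 2, 1), 1L), "n_steps")
})

test_that("DDIM at eta = 1 over all steps equals ancestral sampling with posterior noise", {
  s <- make_schedule(20L, 1e-3, 0.05, sigma_kind = "posterior")
  zero_den <- function(x, t, cond) x * 0
  shape <- c(2, 2, 1, 1)
  set.seed(4)
  x0 <- array(rnorm(4), shape)
  zs <- lapply(1:20, function(i) array(rnorm(4), shape))
  dd <- ddim_sample(zero_den, s, 20L, eta = 1, shape = shape, seed = 1L,
                    x_init = x0, step_noise = zs)
  x <- x0
  for (i in 1:20) {
    t <- 21L - i
    z <- if (t > 1) zs[[i]] else array(0, shape)
    x <- ddpm_step(x, x * 0, t, z, s)
  }
  expect_equal(dd, x, tolerance = 1e-6)
})

test_that("simplified loss is the elementwise MSE with the stated properties", {
  e <- array(rnorm(16), c(2, 2, 2, 2))
  expect_equal(simple_loss(e, e), 0)
  expect_equal(simple_loss(e * 0, e * 0 + 1), 1)
  set.seed(8)
  a <- array(rnorm(16), c(4, 4)); b <- array(rnorm(16), c(4, 4))
  hand <- sum((a - b)^2) / 16
  expect_equal(simple_loss(a, b), hand, tolerance = 1e-12)
  expect_gte(simple_loss(a, b), 0)
  expect_error(simple_loss(a, array(0, c(2, 2))), "match")
})

test_that("classifier-free guidance mixes predictions linearly", {
  u <- array(rnorm(8), c(2, 2, 2, 1)); cnd <- array(rnorm(8), dim(u))
  expect_equal(cfg_combine(u, cnd, 1), cnd)
  expect_equal(cfg_combine(u, cnd, 0), u)
  expect_equal(cfg_combine(u * 0, cnd, 2), 2 * cnd, tolerance = 1e-12)
  expect_error(cfg_combine(u, cnd, -0.5), ">= 0")
})
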