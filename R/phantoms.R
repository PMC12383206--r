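# ---------------------------------------------------------------------------
# Seedable short-axis cardiac phantoms: an LV disk inside a myocardial ring
# with an attached RV crescent, class-dependent intensities, additive noise
# and a smooth polynomial bias field. Also generates deliberately malformed
# masks, one per screening rule, for testing the label filter.
# ---------------------------------------------------------------------------

K_CLASSES <- 4L # 0 background, 1 LV, 2 MYO, 3 RV

#' Validate and tag a label mask
#'
#' A label mask is an integer matrix with values in `{0, 1, 2, 3}`
#' (background, LV cavity, LV myocardium, RV cavity).
#' @param m integer matrix.
#' @export
as_label_mask <- function(m) {
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  if (anyNA(m) || any(m < 0L | m >= K_CLASSES))
    stop("label mask values must be integers in 0..", K_CLASSES - 1)
  structure(m, class = c("label_mask", "matrix"))
}

#' Phantom generator settings
#'
#' Geometric and photometric parameters of the synthetic short-axis slice.
#' Radii and thicknesses are fractions of the grid side; intensities live in
#' the diffusion model's data range `[-1, 1]`. The defaults emulate
#' center-cropped short-axis cine MR: bright blood pools (LV, RV), darker
#' myocardium, dark background, mild coil-inhomogeneity bias.
#'
#' @param grid_size pixels per side (128 full scale, 32 for toy runs).
#' @param lv_radius_range LV cavity radius as a fraction of the grid side.
#' @param myo_thickness_range myocardial ring thickness, same units.
#' @param rv_angle_span angular position spread (degrees) of the RV crescent.
#' @param intensity_means per-class mean intensity, length 4, in `[-1, 1]`.
#' @param noise_sd additive Gaussian noise scale.
#' @param bias_amplitude relative amplitude of the smooth multiplicative
#'   bias field (low-order 2D polynomial).
#' @param seed RNG seed; same spec + seed reproduces the phantom exactly.
#' @export
phantom_spec <- function(grid_size = 128L,
                         lv_radius_range = c(0.12, 0.18),
                         myo_thickness_range = c(0.08, 0.11),
                         rv_angle_span = 120,
                         intensity_means = c(-0.7, 0.6, -0.2, 0.45),
                         noise_sd = 0.05,
                         bias_amplitude = 0.15,
                         seed = 1L) {
  if (length(intensity_means) != K_CLASSES)
    stop("intensity_means must have exactly ", K_CLASSES, " entries")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (max(lv_radius_range) + max(myo_thickness_range) >= 0.5)
    stop("lv_radius + myo_thickness must be < grid_size/2")
  structure(list(grid_size = as.integer(grid_size),
                 lv_radius_range = lv_radius_range,
                 myo_thickness_range = myo_thickness_range,
                 rv_angle_span = rv_angle_span,
                 intensity_means = intensity_means,
                 noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared-distance helper grids
.grid_coords <- function(G) {
  r <- matrix(seq_len(G), G, G)
  list(r = r, c = t(r))
}

#' Generate one phantom image/mask pair
#'
#' Renders the LV disk, enclosing myocardial ring, and an RV crescent (an
#' ellipse hugging the outer ring boundary at a randomized lateral angle),
#' then composes the image as per-class mean intensity, a smooth
#' multiplicative polynomial bias field, and additive Gaussian noise,
#' clipped to `[-1, 1]`. The mask passes all four screening rules by
#' construction.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_pair`: list with `image` (numeric matrix), `mask`
#'   (label mask) and `spec_used`.
#' @export
generate_phantom <- function(spec) {
  G <- spec$grid_size
  with_seed(spec$seed, {
    r_lv <- stats::runif(1, spec$lv_radius_range[1], spec$lv_radius_range[2]) * G
    th <- stats::runif(1, spec$myo_thickness_range[1], spec$myo_thickness_range[2]) * G
    if (r_lv < 1.5 || th < 2)
      stop("sizing error: LV radius or ring thickness below 2 px on this grid")
    rv_extent <- th * 1.4
    if (r_lv + th + rv_extent + 1 >= G / 2)
      stop("sizing error: phantom geometry cannot fit in the grid")
    jit <- G * 0.04
    cx <- G / 2 + 0.5 + stats::runif(1, -jit, jit)
    cy <- G / 2 + 0.5 + stats::runif(1, -jit, jit)
    theta <- (stats::runif(1, -0.5, 0.5)) * spec$rv_angle_span * pi / 180 + pi
    co <- .grid_coords(G)
    d <- sqrt((co$r - cx)^2 + (co$c - cy)^2)
    mask <- matrix(0L, G, G)
    mask[d <= r_lv + th] <- 2L
    mask[d <= r_lv] <- 1L
    # RV: ellipse centered on the outer ring boundary; keep the part outside
    # the ring so it forms a crescent 8-adjacent to the myocardium.
    ex <- cx + (r_lv + th) * cos(theta)
    ey <- cy + (r_lv + th) * sin(theta)
    # tangential semi-axis a, radial semi-axis b
    a <- (r_lv + th) * 0.85
    b <- th * 1.4
    ux <- cos(theta); uy <- sin(theta)          # radial unit vector
    tx <- -uy; ty <- ux                          # tangential unit vector
    pr <- (co$r - ex) * ux + (co$c - ey) * uy
    pt <- (co$r - ex) * tx + (co$c - ey) * ty
    rv <- (pr / b)^2 + (pt / a)^2 <= 1 & d > r_lv + th
    mask[rv] <- 3L
    # image: class means * bias field + noise
    u <- (co$r - G / 2) / (G / 2)
    v <- (co$c - G / 2) / (G / 2)
    coef <- stats::runif(5, -1, 1)
    poly <- coef[1] * u + coef[2] * v + coef[3] * u * v + coef[4] * u^2 + coef[5] * v^2
    poly <- poly / max(abs(poly), 1e-12)
    img <- matrix(spec$intensity_means[mask + 1L], G, G)
    img <- img * (1 + spec$bias_amplitude * poly)
    if (spec$noise_sd > 0) img <- img + matrix(stats::rnorm(G * G, 0, spec$noise_sd), G, G)
    img <- pmin(pmax(img, -1), 1)
    structure(list(image = img, mask = as_label_mask(mask), spec_used = spec),
              class = "phantom_pair")
  })
}

#' Generate a mask violating exactly one screening rule
#'
#' Builds a canonical phantom mask and injects a controlled defect so that
#' exactly the requested rule fails while the other three pass:
#' \describe{
#'   \item{1}{a second LV blob embedded inside the myocardial band
#'     (fragmented LV, but still enclosed by MYO);}
#'   \item{2}{a radial gap cut through the ring, exposing the LV cavity to
#'     background;}
#'   \item{3}{a topologically valid but tiny structure occupying less than
#'     the minimum foreground fraction;}
#'   \item{4}{a canonical phantom plus many isolated single-pixel foreground
#'     speckles in the background.}
#' }
#' @param rule_id integer in 1..4.
#' @param seed RNG seed.
#' @param grid_size grid side in pixels.
#' @return a label mask.
#' @export
generate_malformed_mask <- function(rule_id, seed = 1L, grid_size = 64L) {
  if (!rule_id %in% 1:4) stop("unknown rule_id: ", rule_id, " (must be 1..4)")
  G <- as.integer(grid_size)
  spec <- phantom_spec(grid_size = G,
                       myo_thickness_range = c(0.09, 0.11),
                       noise_sd = 0, bias_amplitude = 0, seed = seed)
  if (rule_id == 3L) {
    # tiny but valid structure: LV d<=1, MYO 1<d<=3, small RV block
    co <- .grid_coords(G)
    cx <- G %/% 2; cy <- G %/% 2
    d <- sqrt((co$r - cx)^2 + (co$c - cy)^2)
    m <- matrix(0L, G, G)
    m[d <= 3] <- 2L
    m[d <= 1] <- 1L
    m[cx + (-1:1), cy + 4:5] <- 3L
    return(as_label_mask(m))
  }
  pair <- generate_phantom(spec)
  m <- unclass(pair$mask)
  co <- .grid_coords(G)
  # recover geometry from the rendered mask
  lv_idx <- which(m == 1L, arr.ind = TRUE)
  cx <- mean(lv_idx[, 1]); cy <- mean(lv_idx[, 2])
  d <- sqrt((co$r - cx)^2 + (co$c - cy)^2)
  r_lv <- max(d[m == 1L])
  r_out <- max(d[m == 2L])
  if (rule_id == 1L) {
    # second LV blob strictly inside the myocardial band
    ang <- with_seed(seed + 77L, stats::runif(1, 0, 2 * pi))
    bx <- cx + (r_lv + r_out) / 2 * cos(ang)
    by <- cy + (r_lv + r_out) / 2 * sin(ang)
    db <- sqrt((co$r - bx)^2 + (co$c - by)^2)
    blob <- db <= 1.5 & m == 2L
    m[blob] <- 1L
  } else if (rule_id == 2L) {
    # radial gap through the ring at an angle away from the RV
    rv_idx <- which(m == 3L, arr.ind = TRUE)
    rv_ang <- atan2(mean(rv_idx[, 2]) - cy, mean(rv_idx[, 1]) - cx)
    gap_ang <- rv_ang + pi
    ang <- atan2(co$c - cy, co$r - cx)
    dang <- abs(((ang - gap_ang + pi) %% (2 * pi)) - pi)
    half_width <- 2.5 / r_lv # ~2.5 px arc at the LV boundary
    m[m == 2L & dang < half_width] <- 0L
  } else {
    # rule 4: isolated single-pixel speckles far from the structure
    pos <- expand.grid(r = seq(3L, G - 2L, by = 4L), c = seq(3L, G - 2L, by = 4L))
    far <- sqrt((pos$r - cx)^2 + (pos$c - cy)^2) > r_out + 5
    pos <- pos[far, ][seq_len(25L), ]
    for (i in seq_len(nrow(pos)))
      m[pos$r[i], pos$c[i]] <- as.integer(1L + (i %% 3L))
  }
  as_label_mask(m)
}

#' Split phantoms into train/validation/test sets
#'
#' Generates `n` phantom pairs (per-case seeds derived from `seed`) and
#' splits them case-wise at the given ratio after a seeded shuffle. Split
#' sizes are `round(n * r1/s)`, `round(n * r2/s)`, and the remainder.
#'
#' @param n number of cases, at least 10.
#' @param spec template [phantom_spec()]; per-case seeds override `spec$seed`.
#' @param split_ratio three nonnegative weights, default `c(7, 1, 2)`.
#' @param seed seed controlling both per-case generation and the shuffle.
#' @return list with elements `train`, `val`, `test` (lists of phantom
#'   pairs) and `split_sizes`.
#' @export
generate_dataset <- function(n, spec = phantom_spec(), split_ratio = c(7, 1, 2),
                             seed = 1L) {
  if (n < 10) stop("n must be >= 10 to honor the split ratio")
  sizes <- split_sizes(n, split_ratio)
  pairs <- lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- as.integer(seed * 101L + i)
    generate_phantom(sp)
  })
  perm <- with_seed(seed, sample.int(n))
  idx_tr <- perm[seq_len(sizes[1])]
  idx_va <- perm[sizes[1] + seq_len(sizes[2])]
  idx_te <- perm[sizes[1] + sizes[2] + seq_len(sizes[3])]
  list(train = pairs[idx_tr], val = pairs[idx_va], test = pairs[idx_te],
       split_sizes = sizes)
}

#' Train/val/test sizes at a ratio
#'
#' @inheritParams generate_dataset
#' @return integer vector of three sizes summing to `n`.
#' @export
split_sizes <- function(n, split_ratio = c(7, 1, 2)) {
  s <- sum(split_ratio)
  n_tr <- round(n * split_ratio[1] / s)
  n_va <- round(n * split_ratio[2] / s)
  c(n_tr, n_va, n - n_tr - n_va)
}
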