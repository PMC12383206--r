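# ---------------------------------------------------------------------------
# Screening of generated pseudo-labels. Four rules reject implausible masks
# before image synthesis:
#   1. fragmented cardiac structures (a class splits into several components)
#   2. topology violating short-axis anatomy (LV not enclosed by MYO, or RV
#      detached from the myocardium)
#   3. vanishing foreground occupation
#   4. many stray speckle components in the background
# Rules 1-2 assess the cardiac structure proper and therefore operate on a
# despeckled view (components at or below `speckle_max_px` removed); rules
# 3-4 operate on the raw mask, so speckle noise is judged by rule 4 alone.
# ---------------------------------------------------------------------------

#' Label screening thresholds
#'
#' @param connectivity pixel connectivity for components and adjacency (4/8).
#' @param min_foreground_fraction minimum fraction of non-background pixels;
#'   below this (strictly) rule 3 fails.
#' @param max_background_components maximum allowed stray components beyond
#'   one per present class; rule 4 fails above this.
#' @param enclosure_tolerance number of LV boundary pixels allowed to touch
#'   something other than myocardium before rule 2 fails.
#' @param adjacency_required whether rule 2 demands RV-MYO adjacency when an
#'   RV component is present.
#' @param speckle_max_px components of at most this many pixels are treated
#'   as background speckle: ignored by the structural rules 1-2, counted by
#'   rule 4.
#' @export
filter_config <- function(connectivity = 8L,
                          min_foreground_fraction = 0.01,
                          max_background_components = 5L,
                          enclosure_tolerance = 0L,
                          adjacency_required = TRUE,
                          speckle_max_px = 4L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (min_foreground_fraction <= 0 || min_foreground_fraction >= 1)
    stop("min_foreground_fraction must be in (0, 1)")
  if (max_background_components < 0) stop("max_background_components must be >= 0")
  structure(list(connectivity = as.integer(connectivity),
                 min_foreground_fraction = min_foreground_fraction,
                 max_background_components = as.integer(max_background_components),
                 enclosure_tolerance = as.integer(enclosure_tolerance),
                 adjacency_required = isTRUE(adjacency_required),
                 speckle_max_px = as.integer(speckle_max_px)),
            class = "filter_config")
}

class_components <- function(mask, class_id, connectivity) {
  label_components_cpp(matrix(as.integer(mask), nrow(mask)), as.integer(class_id),
                       as.integer(connectivity))
}

despeckle_mask <- function(mask, cfg) {
  m <- matrix(as.integer(mask), nrow(mask))
  for (k in 1:(K_CLASSES - 1L)) {
    lab <- class_components(m, k, cfg$connectivity)
    if (!any(lab > 0L)) next
    sizes <- tabulate(lab)
    small <- which(sizes <= cfg$speckle_max_px)
    if (length(small)) m[lab %in% small] <- 0L
  }
  m
}

neighbors8 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                    c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))

# classes whose pixels 8-touch any pixel of `region` (logical matrix)
touching_classes <- function(mask, region) {
  H <- nrow(mask); W <- ncol(mask)
  out <- logical(K_CLASSES)
  idx <- which(region, arr.ind = TRUE)
  if (!nrow(idx)) return(out)
  for (d in seq_len(nrow(neighbors8))) {
    rr <- idx[, 1] + neighbors8[d, 1]
    cc <- idx[, 2] + neighbors8[d, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    vals <- mask[cbind(rr[ok], cc[ok])]
    out[vals + 1L] <- TRUE
  }
  out
}

#' Rule 1: per-class connectivity
#'
#' Fails iff any foreground class present in the (despeckled) mask has more
#' than one connected component. Absent classes count zero components and do
#' not fail the rule.
#' @param mask a label mask.
#' @param cfg a [filter_config()].
#' @return list with `pass` and per-class `counts` (LV, MYO, RV).
#' @export
rule1_connectivity <- function(mask, cfg = filter_config()) {
  rule1_impl(despeckle_mask(mask, cfg), cfg)
}

rule1_impl <- function(m, cfg) {
  counts <- vapply(1:3, function(k) max(class_components(m, k, cfg$connectivity)),
                   integer(1))
  names(counts) <- c("LV", "MYO", "RV")
  list(pass = all(counts <= 1L), counts = counts)
}

#' Rule 2: short-axis topology
#'
#' Operationalizes "clinical logic" for a short-axis slice: every LV
#' boundary pixel's 8-neighborhood outside the LV must contain only
#' myocardium (up to `enclosure_tolerance` violating pixels), and any RV
#' component must share at least one 8-adjacent pixel pair with the
#' myocardium. Fails vacuously if LV or MYO is absent.
#' @inheritParams rule1_connectivity
#' @export
rule2_topology <- function(mask, cfg = filter_config()) {
  rule2_impl(despeckle_mask(mask, cfg), cfg)
}

rule2_impl <- function(m, cfg) {
  if (!any(m == 1L) || !any(m == 2L)) return(list(pass = FALSE, violations = NA_integer_))
  H <- nrow(m); W <- ncol(m)
  idx <- which(m == 1L, arr.ind = TRUE)
  bad <- logical(nrow(idx))
  for (d in seq_len(nrow(neighbors8))) {
    rr <- idx[, 1] + neighbors8[d, 1]
    cc <- idx[, 2] + neighbors8[d, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    nb <- m[cbind(pmin(pmax(rr, 1L), H), pmin(pmax(cc, 1L), W))]
    bad <- bad | !ok | (ok & !(nb %in% c(1L, 2L)))
  }
  viol <- as.integer(sum(bad))
  pass <- viol <= cfg$enclosure_tolerance
  if (pass && cfg$adjacency_required && any(m == 3L)) {
    pass <- touching_classes(m, m == 3L)[3L]  # MYO is class 2 -> index 3
  }
  list(pass = pass, violations = viol)
}

#' Rule 3: minimum foreground occupation
#'
#' Fails iff the foreground fraction is strictly below
#' `min_foreground_fraction` (an at-threshold mask passes).
#' @inheritParams rule1_connectivity
#' @export
rule3_min_area <- function(mask, cfg = filter_config()) {
  frac <- mean(mask > 0L)
  list(pass = frac >= cfg$min_foreground_fraction, foreground_fraction = frac)
}

#' Rule 4: background speckle count
#'
#' Stray components = total per-class foreground components minus the number
#' of foreground classes present; fails iff this exceeds
#' `max_background_components`.
#' @inheritParams rule1_connectivity
#' @export
rule4_background_speckle <- function(mask, cfg = filter_config()) {
  m <- matrix(as.integer(mask), nrow(mask))
  total <- 0L; present <- 0L
  for (k in 1:3) {
    nc <- max(class_components(m, k, cfg$connectivity))
    total <- total + nc
    if (nc > 0L) present <- present + 1L
  }
  stray <- total - present
  list(pass = stray <= cfg$max_background_components, stray_count = stray)
}

#' Screen a mask against all four rules
#' @inheritParams rule1_connectivity
#' @return a `filter_report` with per-rule verdicts, component counts,
#'   foreground fraction, stray count and the overall `accepted` flag
#'   (the conjunction of the four verdicts).
#' @export
filter_report <- function(mask, cfg = filter_config()) {
  desp <- despeckle_mask(mask, cfg)
  r1 <- rule1_impl(desp, cfg)
  r2 <- rule2_impl(desp, cfg)
  r3 <- rule3_min_area(mask, cfg)
  r4 <- rule4_background_speckle(mask, cfg)
  structure(list(rule1 = r1$pass, rule2 = r2$pass, rule3 = r3$pass,
                 rule4 = r4$pass,
                 component_counts = r1$counts,
                 enclosure_violations = r2$violations,
                 foreground_fraction = r3$foreground_fraction,
                 stray_count = r4$stray_count,
                 accepted = r1$pass && r2$pass && r3$pass && r4$pass),
            class = "filter_report")
}

#' Filter a set of generated masks
#'
#' @param masks a `pseudo_label_set` or plain list of label masks.
#' @param cfg a [filter_config()].
#' @return list with `accepted` (same container type, order preserved) and
#'   `reports` (one [filter_report()] per input mask).
#' @export
filter_labels <- function(masks, cfg = filter_config()) {
  is_set <- inherits(masks, "pseudo_label_set")
  mask_list <- if (is_set) masks$masks else masks
  reports <- lapply(mask_list, filter_report, cfg = cfg)
  keep <- vapply(reports, `[[`, logical(1), "accepted")
  acc <- mask_list[keep]
  if (is_set) {
    out <- masks
    out$masks <- acc
  } else out <- acc
  list(accepted = out, reports = reports)
}
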