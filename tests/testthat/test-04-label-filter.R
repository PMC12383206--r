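canonical_mask <- function(seed) generate_phantom(
  phantom_spec(grid_size = 64L, seed = seed))$mask

test_that("rule 1 counts per-class components", {
  r <- rule1_connectivity(canonical_mask(1L))
  expect_true(r$pass)
  expect_equal(unname(r$counts), c(1L, 1L, 1L))
  r1 <- rule1_connectivity(generate_malformed_mask(1L, seed = 3L))
  expect_false(r1$pass)
  expect_equal(unname(r1$counts["LV"]), 2L)
  # all-background mask: vacuous pass (rejected by rule 3 instead)
  empty <- as_label_mask(matrix(0L, 16, 16))
  expect_true(rule1_connectivity(empty)$pass)
  expect_false(rule3_min_area(empty)$pass)
})

test_that("rule 2 checks LV enclosure and RV adjacency", {
  expect_true(rule2_topology(canonical_mask(2L))$pass)
  # gap cut through the ring exposes LV to background
  expect_false(rule2_topology(generate_malformed_mask(2L, seed = 4L))$pass)
  # RV translated away from the ring loses adjacency
  m <- unclass(canonical_mask(2L))
  rv <- which(m == 3L, arr.ind = TRUE)
  m[rv] <- 0L
  m[3:6, 3:6] <- 3L # far corner block
  expect_false(rule2_topology(as_label_mask(m))$pass)
  # missing LV or MYO fails vacuously
  expect_false(rule2_topology(as_label_mask(matrix(0L, 16, 16)))$pass)
})

test_that("rule 3 applies a strict minimum-occupancy threshold", {
  expect_equal(rule3_min_area(as_label_mask(matrix(0L, 8, 8)))$foreground_fraction, 0)
  half <- matrix(0L, 8, 8); half[1:4, ] <- 2L
  r <- rule3_min_area(as_label_mask(half))
  expect_true(r$pass); expect_equal(r$foreground_fraction, 0.5)
  # 10 foreground pixels on 32x32: 10/1024 < 0.01 fails
  m <- matrix(0L, 32, 32); m[1, 1:10] <- 1L
  r10 <- rule3_min_area(as_label_mask(m))
  expect_equal(r10$foreground_fraction, 10 / 1024)
  expect_false(r10$pass)
  # at-threshold passes (strict inequality below threshold only)
  m[1, 1:10] <- 0L; m[2, 1:11] <- 1L # 11/1024 > 0.01; construct exact threshold:
  cfg <- filter_config(min_foreground_fraction = 10 / 1024)
  m2 <- matrix(0L, 32, 32); m2[1, 1:10] <- 1L
  expect_true(rule3_min_area(as_label_mask(m2), cfg)$pass)
})

test_that("rule 4 counts stray background components", {
  expect_equal(rule4_background_speckle(canonical_mask(3L))$stray_count, 0L)
  m <- unclass(canonical_mask(3L))
  # exactly 5 isolated pixels at the default max of 5: still accepted
  spots <- cbind(seq(2, 18, by = 4), 2)
  for (i in 1:5) m[spots[i, 1], spots[i, 2]] <- 1L
  r5 <- rule4_background_speckle(as_label_mask(m))
  expect_equal(r5$stray_count, 5L)
  expect_true(r5$pass)
  # 25 speckles exceed the default
  r25 <- rule4_background_speckle(generate_malformed_mask(4L, seed = 1L))
  expect_equal(r25$stray_count, 25L)
  expect_false(r25$pass)
})

test_that("filter_labels screens the constructed 8-mask fixture exactly", {
  masks <- c(lapply(1:4, canonical_mask),
             lapply(1:4, function(r) generate_malformed_mask(r, seed = 6L)))
  res <- filter_labels(masks)
  expect_length(res$accepted, 4L)
  expect_length(res$reports, 8L)
  for (i in 1:4) expect_true(res$reports[[i]]$accepted)
  for (r in 1:4) {
    rep <- res$reports[[4L + r]]
    verdicts <- c(rep$rule1, rep$rule2, rep$rule3, rep$rule4)
    expect_identical(which(!verdicts), as.integer(r))
  }
  # empty input gives empty outputs
  res0 <- filter_labels(list())
  expect_length(res0$accepted, 0L)
  expect_length(res0$reports, 0L)
})

test_that("filtering is deterministic, idempotent and threshold-monotone", {
  masks <- lapply(201:240, canonical_mask)
  masks[[5]] <- generate_malformed_mask(3L, seed = 9L)
  masks[[10]] <- generate_malformed_mask(4L, seed = 9L)
  cfg <- filter_config()
  r1 <- filter_labels(masks, cfg)
  r2 <- filter_labels(masks, cfg)
  expect_identical(lapply(r1$reports, unclass), lapply(r2$reports, unclass))
  # idempotence
  again <- filter_labels(r1$accepted, cfg)
  expect_identical(lapply(again$accepted, unclass), lapply(r1$accepted, unclass))
  # monotonicity: loosening thresholds never shrinks the accepted set
  loose <- filter_config(min_foreground_fraction = 0.001,
                         max_background_components = 50L)
  rl <- filter_labels(masks, loose)
  expect_gte(length(rl$accepted), length(r1$accepted))
  accepted_ids <- function(res) which(vapply(res$reports, `[[`, logical(1), "accepted"))
  expect_true(all(accepted_ids(r1) %in% accepted_ids(rl)))
})
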