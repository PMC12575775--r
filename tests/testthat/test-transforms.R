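# Sector transforms: identity cases, geometric oracles, label safety.

test_that("identity parameters reproduce the input exactly", {
  s <- phantom256()
  for (res in list(depth_increase(s, 0), tilt(s, 0), width_adjust(s, 1))) {
    expect_identical(res$sample$image, s$image)
    expect_identical(res$sample$mask, s$mask)
    expect_identical(res$sample$spacing, s$spacing)
  }
  tr <- translate(s, 45, 0)
  expect_identical(tr$sample$image, s$image)
  nw <- narrow_width_pretrain(s$image, s$geometry, 0)
  expect_identical(nw$image, s$image)
})

test_that("depth increase: area scaling, spacing bookkeeping, range errors", {
  s <- phantom256()
  d <- depth_increase(s, 128)
  ratio <- sum(d$sample$mask == 1) / sum(s$mask == 1)
  expect_lt(abs(ratio / (256 / 384)^2 - 1), 0.05)
  d150 <- depth_increase(s, 150)
  expect_equal(d150$sample$spacing, s$spacing * 406 / 256)
  expect_error(depth_increase(s, 151), class = "echosynth_invalid_argument")
  expect_error(depth_increase(s, -1), class = "echosynth_invalid_argument")
  # physical LV area is invariant under depth increase (within discretization)
  area0 <- sum(s$mask == 1) * prod(s$spacing)
  area1 <- sum(d$sample$mask == 1) * prod(d$sample$spacing)
  expect_lt(abs(area1 / area0 - 1), 0.05)
})

test_that("tilt: round trip, label safety, range errors", {
  s <- phantom256()
  t1 <- tilt(s, 20)
  t2 <- tilt(t1$sample, -20)
  expect_gte(dice(t2$sample$mask, s$mask, 1), 0.98)
  expect_error(tilt(s, 30), class = "echosynth_invalid_argument")
  set.seed(8)
  for (i in 1:10) {
    th <- runif(1, -29.9, 29.9)
    r <- tilt(s, th)
    expect_true(all(r$keep_mask[r$sample$mask > 0] == 1))
  }
})

test_that("width adjustment: angle and area oracles", {
  s <- phantom256()
  w <- width_adjust(s, 0.51)
  # measured support angle vs atan-scaled prediction
  pred_angle <- 2 * atan(0.51 * tan(s$geometry$opening_angle / 2 * pi / 180)) * 180 / pi
  det <- detect_sector(ifelse(sector_support(w$sample$geometry, dim(s$image)), 0.5, 0))
  expect_lt(abs(det$geometry$opening_angle - pred_angle), 2)
  # LV pixel count scales with the single-axis factor
  expect_lt(abs(sum(w$sample$mask == 1) / sum(s$mask == 1) / 0.51 - 1), 0.05)
  # column spacing divided by the factor, row spacing untouched
  expect_equal(w$sample$spacing, c(s$spacing[1], s$spacing[2] / 0.51))
  expect_error(width_adjust(s, 0.5), class = "echosynth_invalid_argument")
  expect_error(width_adjust(s, 1.5), class = "echosynth_invalid_argument")
})

test_that("translation: exact index arithmetic and cropping monotonicity", {
  s <- phantom256()
  dn <- translate(s, 270, 10)   # straight down
  H <- nrow(s$mask)
  expect_identical(dn$sample$mask[11:H, ], s$mask[1:(H - 10), ])
  expect_true(all(dn$sample$mask[1:10, ] == 0))
  set.seed(12)
  for (i in 1:10) {
    r <- translate(s, runif(1, 0, 360), runif(1, 0, 50))
    expect_lte(sum(r$sample$mask > 0), sum(s$mask > 0))
    expect_true(all(r$keep_mask[r$sample$mask > 0] == 1))
  }
  expect_error(translate(s, 0, 51), class = "echosynth_invalid_argument")
})

test_that("combine: forced draws, sequential equivalence, frequencies", {
  s <- phantom256()
  cfg_off <- augmentation_config(combination_probability = 0)
  r <- combine_transforms(s, cfg_off, seed = 1)
  expect_identical(r$sample$image, s$image)
  expect_identical(r$sample$mask, s$mask)

  cfg_on <- augmentation_config(combination_probability = 1)
  r1 <- combine_transforms(s, cfg_on, seed = 33)
  p <- r1$provenance
  expect_true(p$depth && p$tilt && p$width && p$translate)
  manual <- depth_increase(s, p$lambda_px)
  manual <- tilt(manual$sample, p$theta_deg, manual$keep_mask)
  manual <- width_adjust(manual$sample, p$factor, manual$keep_mask)
  manual <- translate(manual$sample, p$angle_deg, p$length_px, manual$keep_mask)
  expect_identical(r1$sample$image, manual$sample$image)
  expect_identical(r1$sample$mask, manual$sample$mask)
  expect_identical(r1$keep_mask, manual$keep_mask)

  # application frequency of each transform is ~0.5 (draws on a tiny
  # sample so 1e4 repetitions stay cheap)
  tiny <- labeled_sample(matrix(0.5, 4, 4), matrix(0L, 4, 4),
                         sector_geometry(c(1, 2.5), 60, 3.5), c(1, 1))
  cfg <- augmentation_config(depth_lambda_range = c(0, 2),
                             translation_length_range = c(0, 1))
  counts <- c(depth = 0, tilt = 0, width = 0, translate = 0)
  n <- 1e4
  for (i in seq_len(n)) {
    pr <- combine_transforms(tiny, cfg, seed = i)$provenance
    counts <- counts + c(pr$depth, pr$tilt, pr$width, pr$translate)
  }
  expect_true(all(counts / n >= 0.48 & counts / n <= 0.52))
})

test_that("blackout baseline equals combine with a blacked repaint region", {
  s <- phantom256()
  cfg <- augmentation_config()
  b <- blackout_baseline(s, cfg, seed = 77)
  cmb <- combine_transforms(s, cfg, seed = 77)
  expect_true(all(b$image[cmb$keep_mask == 0] == 0))
  expect_identical(b$image[cmb$keep_mask == 1],
                   cmb$sample$image[cmb$keep_mask == 1])
  expect_identical(b$mask, cmb$sample$mask)
  # identity draw leaves the sample unchanged inside the sector
  b0 <- blackout_baseline(s, augmentation_config(combination_probability = 0),
                          seed = 1)
  expect_identical(b0$mask, s$mask)
})

test_that("sector narrowing: geometry oracle and full-width property", {
  s <- phantom256()
  delta <- 20
  nw <- narrow_width_pretrain(s$image, s$geometry, delta)
  f <- tan(s$geometry$opening_angle / 2 * pi / 180) /
       tan((s$geometry$opening_angle - delta) / 2 * pi / 180)
  H <- nrow(s$image)
  g <- echosynth:::out_grid(H, H)
  unstretched <- echosynth:::warp_bilinear(
    nw$image, g$r, s$geometry$apex[2] + (g$c - s$geometry$apex[2]) * f)
  meas <- detect_sector(unstretched)$geometry$opening_angle
  expect_lt(abs(meas - (s$geometry$opening_angle - delta)), 2)
  # stretched output reaches at least the original lateral extent
  supp_out <- nw$image > 0.02
  supp_in <- s$image > 0.02
  expect_gte(max(which(colSums(supp_out) > 0)), max(which(colSums(supp_in) > 0)) - 1)
  expect_error(narrow_width_pretrain(s$image, s$geometry, 21),
               class = "echosynth_invalid_argument")
})

test_that("stride subsampling: bounds, single frame, determinism", {
  frames <- as.list(1:100)
  k <- subsample_every_nth(frames, seed = 3)
  expect_gte(length(k), 9); expect_lte(length(k), 13)
  expect_equal(k[1], 1L)
  expect_true(all(diff(k) >= 8 & diff(k) <= 12))
  expect_identical(k, subsample_every_nth(frames, seed = 3))
  expect_identical(subsample_every_nth(list("a"), seed = 1), 1L)
  expect_error(subsample_every_nth(list()), class = "echosynth_invalid_argument")
})

test_that("label-safety assertion fires on a constructed violation", {
  mask <- matrix(0L, 4, 4); mask[2, 2] <- 1L
  keep <- matrix(1, 4, 4); keep[2, 2] <- 0
  expect_error(echosynth:::assert_label_safety(mask, keep),
               class = "echosynth_label_safety_error")
  expect_true(echosynth:::assert_label_safety(mask, matrix(1, 4, 4)))
})

test_that("augment_dataset emits 6x samples with untouched labels", {
  ck <- tiny_ckpt32()
  cfg <- aug_config_scaled(32L, n_aug = 5L)
  out <- augment_dataset(ck$samples[1:2], ck$predictor, ck$schedule, cfg,
                         seed = 9, jump_length = 5, n_resample = 1)
  expect_length(out, 12)
  expect_identical(out[[1]]$image, ck$samples[[1]]$image)
  # determinism under the master seed
  out2 <- augment_dataset(ck$samples[1:2], ck$predictor, ck$schedule, cfg,
                          seed = 9, jump_length = 5, n_resample = 1)
  expect_identical(lapply(out, `[[`, "image"), lapply(out2, `[[`, "image"))
})
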