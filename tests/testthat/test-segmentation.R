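test_that("colour augmentation is identity at zero ranges and seeded otherwise", {
  s <- small_slide(seed = 21)
  cfg0 <- segmenter_config(augmentation = list(hue = 0, sat = 0, bright = 0))
  expect_identical(augment_colour(s$image, cfg0, seed = 3), s$image)
  cfg <- segmenter_config(augmentation = list(hue = 0.05, sat = 0.2, bright = 0.2))
  a1 <- augment_colour(s$image, cfg, seed = 3)
  a2 <- augment_colour(s$image, cfg, seed = 3)
  expect_identical(a1, a2)
  a3 <- augment_colour(s$image, cfg, seed = 4)
  expect_false(identical(a1, a3))
  # nonzero jitter shifts the channel statistics
  means_in <- apply(s$image, 3, mean)
  means_out <- apply(a1, 3, mean)
  expect_gt(max(abs(means_in - means_out)), 1e-4)
  expect_error(augment_colour(matrix(0.5, 4, 4), cfg), "RGB")
})

test_that("reference segmenter learns synthetic myxoid texture", {
  train <- lapply(1:2, small_slide)
  cfg <- segmenter_config(samples_per_image = 1500L, seed = 7)
  seg <- train_reference_segmenter(lapply(train, `[[`, "image"),
                                   lapply(train, `[[`, "mask"), cfg)
  held <- small_slide(seed = 31)
  p <- predict_probability(seg, held$image)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(dim(p), dim(held$mask))
  acc <- mean((p >= 0.5) == held$mask)
  expect_gt(acc, 0.9)
  # probability separates the classes
  expect_gt(mean(p[held$mask]), mean(p[!held$mask]))
})

test_that("training is deterministic for a fixed seed", {
  train <- lapply(4:5, small_slide)
  cfg <- segmenter_config(samples_per_image = 800L, seed = 11)
  s1 <- train_reference_segmenter(lapply(train, `[[`, "image"),
                                  lapply(train, `[[`, "mask"), cfg)
  s2 <- train_reference_segmenter(lapply(train, `[[`, "image"),
                                  lapply(train, `[[`, "mask"), cfg)
  probe <- small_slide(seed = 32)$image
  expect_identical(predict_probability(s1, probe), predict_probability(s2, probe))
})

test_that("degenerate training classes and untrained handles are rejected", {
  s <- small_slide(seed = 22)
  empty <- matrix(FALSE, nrow(s$mask), ncol(s$mask))
  expect_error(train_reference_segmenter(list(s$image), list(empty)),
               "both myxoid and non-myxoid")
  expect_error(predict_probability(structure(list(), class = "dr_segmenter"),
                                   s$image), "trained")
})

test_that("constant-colour input yields a spatially constant probability map", {
  train <- lapply(6:7, small_slide)
  seg <- train_reference_segmenter(lapply(train, `[[`, "image"),
                                   lapply(train, `[[`, "mask"),
                                   segmenter_config(samples_per_image = 800L))
  flat <- array(0.6, dim = c(20, 20, 3))
  p <- predict_probability(seg, flat)
  expect_equal(max(p) - min(p), 0, tolerance = 1e-12)
})

test_that("probability threshold is boundary-inclusive and monotone", {
  p <- matrix(c(0.79, 0.80, 0.81, 0.2), 2, 2)
  m <- threshold_mask(p, segmenter_config(probability_threshold = 0.80))
  expect_identical(as.vector(m), c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(threshold_mask(matrix(0, 3, 3)), matrix(FALSE, 3, 3))
  # raising the threshold never adds foreground
  pr <- matrix(runif(400, 0, 1), 20, 20)
  thr <- sort(runif(5))
  masks <- lapply(thr, function(t) threshold_mask(pr, t))
  for (i in seq_len(4)) expect_true(all(masks[[i]][masks[[i + 1]]]))
  expect_error(threshold_mask(pr, 1.2), "\\[0, 1\\]")
})

test_that("minimum-object filter drops small components, keeps boundary ties", {
  res <- resolution(10)  # 1 px = 100 um^2 so 0.1 mm^2 = 1000 px
  m <- matrix(FALSE, 80, 80)
  m[2:31, 2:31] <- TRUE          # 900 px = 0.09 mm^2 -> removed
  f <- filter_min_size(m, segmenter_config(), res)
  expect_equal(sum(f), 0)
  m2 <- matrix(FALSE, 80, 80)
  m2[2:41, 2:26] <- TRUE         # 1000 px = exactly 0.1 mm^2 -> retained
  f2 <- filter_min_size(m2, segmenter_config(), res)
  expect_identical(f2, m2)
  expect_identical(filter_min_size(matrix(FALSE, 5, 5), segmenter_config(), res),
                   matrix(FALSE, 5, 5))
})

test_that("size filter is idempotent and never adds foreground", {
  set.seed(99)
  for (i in 1:5) {
    m <- matrix(runif(2500) < 0.3, 50, 50)
    f1 <- filter_min_size(m, 0.00002, resolution(1))
    expect_true(all(m[f1]))            # subset of input
    f2 <- filter_min_size(f1, 0.00002, resolution(1))
    expect_identical(f1, f2)           # idempotent
  }
})
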