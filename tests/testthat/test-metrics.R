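test_that("confusion counts equal a per-voxel loop and partition the volume", {
  for (seed in 1:3) {
    pred <- random_labels(4, seed = seed)
    truth <- random_labels(4, seed = seed + 100)
    for (cl in 0:3) {
      cc <- confusion(pred, truth, cl)
      oc <- oracle_confusion(pred, truth, cl)
      expect_identical(cc[c("tp", "fp", "tn", "fn")], oc[c("tp", "fp", "tn", "fn")])
      expect_equal(cc$tp + cc$fp + cc$tn + cc$fn, 64L)
    }
  }
  expect_error(confusion(random_labels(4), random_labels(5), 1), "grid")

  # identical maps: no errors of either kind
  p <- random_labels(4, seed = 5)
  cc <- confusion(p, p, 2)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 0L)
})

test_that("recall / precision / dice / lfpr follow the defining ratios", {
  cc <- structure(list(tp = 2, fp = 1, tn = 60, fn = 1),
                  class = "confusion_counts")
  expect_equal(recall(cc), 2 / 3)
  expect_equal(precision(cc), 2 / 3)
  expect_equal(dice(cc), 4 / 6)
  expect_equal(lfpr(cc), 1 / 61)

  perfect <- structure(list(tp = 10, fp = 0, tn = 54, fn = 0),
                       class = "confusion_counts")
  expect_equal(recall(perfect), 1)
  expect_equal(precision(perfect), 1)
  expect_equal(dice(perfect), 1)
  expect_equal(lfpr(perfect), 0)

  expect_error(recall(list(tp = -1, fp = 0, tn = 0, fn = 1)), "non-negative")
})

test_that("dice is the harmonic mean of precision and recall", {
  for (seed in 1:10) {
    set.seed(seed)
    cc <- list(tp = sample(0:20, 1), fp = sample(0:20, 1),
               tn = sample(0:200, 1), fn = sample(0:20, 1))
    p <- precision(cc); r <- recall(cc)
    if (is.finite(p) && is.finite(r) && p + r > 0)
      expect_equal(dice(cc), 2 * p * r / (p + r))
  }
})

test_that("zero-denominator conventions hold", {
  # empty prediction, nonempty truth: 0 / 0 / 0 (the printed-table convention)
  cc <- confusion(array(0L, c(3, 3, 3)),
                  array(c(rep(1L, 5), rep(0L, 22)), c(3, 3, 3)), 1L)
  expect_equal(cc$tp, 0L); expect_equal(cc$fn, 5L)
  expect_equal(recall(cc), 0)
  expect_equal(precision(cc), 0)
  expect_equal(dice(cc), 0)

  # class absent from both: recall and dice undefined, not zero
  none <- confusion(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2)), 3L)
  expect_true(is.nan(recall(none)))
  expect_true(is.nan(dice(none)))
  expect_equal(precision(none), 0)

  # no negatives anywhere: LFPR undefined
  all1 <- confusion(array(1L, c(2, 2, 2)), array(1L, c(2, 2, 2)), 1L)
  expect_true(is.nan(lfpr(all1)))
})

test_that("average volume difference matches hand evaluation", {
  expect_equal(avd(list(c(100, 100), c(7, 7)))$avd, 0)
  expect_equal(avd(list(c(150, 100)))$avd, 0.5)
  expect_equal(avd(list(c(50, 100), c(200, 100)))$avd, 0.75)
  r <- avd(list(c(10, 0), c(30, 20)))
  expect_equal(r$n_excluded, 1L)
  expect_equal(r$avd, 0.5)
  expect_true(is.nan(avd(list(c(5, 0)))$avd))
})

test_that("surface extraction follows the 6-neighbor border rule", {
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  expect_equal(nrow(surface_points(m1)), 1L)

  cube3 <- array(FALSE, c(5, 5, 5)); cube3[2:4, 2:4, 2:4] <- TRUE
  expect_equal(nrow(surface_points(cube3)), 26L)

  cube5 <- array(TRUE, c(5, 5, 5))  # border counts as outside
  expect_equal(nrow(surface_points(cube5)), 5^3 - 3^3)

  expect_equal(nrow(surface_points(array(FALSE, c(3, 3, 3)))), 0L)
})

test_that("assd matches the all-pairs brute force and is symmetric", {
  for (seed in 1:4) {
    a <- random_mask(6, p = 0.25, seed = seed)
    b <- random_mask(6, p = 0.25, seed = seed + 50)
    if (!any(a) || !any(b)) next
    expect_equal(assd(a, b), oracle_assd(a, b), tolerance = 1e-9)
    expect_equal(assd(a, b), assd(b, a))
  }

  # two single voxels 3 apart on one axis at unit spacing
  a <- array(FALSE, c(8, 8, 8)); a[2, 4, 4] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[5, 4, 4] <- TRUE
  expect_equal(assd(a, b), 3.0)

  m <- random_mask(6, seed = 3)
  expect_equal(assd(m, m), 0)
  expect_true(is.nan(assd(array(FALSE, c(4, 4, 4)), m[1:4, 1:4, 1:4])))
})

test_that("doubling spacing doubles assd and leaves overlap metrics alone", {
  a <- random_mask(6, p = 0.3, seed = 9)
  b <- random_mask(6, p = 0.3, seed = 10)
  expect_equal(assd(a, b, spacing = c(2, 2, 2)), 2 * assd(a, b))
  cc1 <- confusion(a, b, TRUE)
  expect_equal(dice(cc1), dice(confusion(a, b, TRUE)))  # spacing-free
})

test_that("metric values stay in range on random inputs", {
  for (seed in 1:5) {
    pred <- random_labels(5, seed = seed)
    truth <- random_labels(5, seed = seed + 7)
    rep <- evaluate_subject(pred, truth)
    for (m in c("recall", "precision", "dice", "lfpr")) {
      v <- rep[[m]]
      expect_true(all(is.nan(v) | (v >= 0 & v <= 1)))
    }
    expect_true(all(is.nan(rep$avd) | rep$avd >= 0))
    expect_true(all(is.nan(rep$assd) | rep$assd >= 0))
  }
})

test_that("cohort aggregation uses population SD and excludes NaN", {
  r1 <- data.frame(subregion = "ED", recall = 0.5, precision = 0.5,
                   dice = 0.5, lfpr = 0.01, avd = 0.2, assd = 1.0)
  r2 <- r1; r2$recall <- 0.7; r2$assd <- NaN
  rep <- evaluate_cohort(list(r1, r2), method = "m")
  expect_equal(rep$recall_mean, 0.6)
  expect_equal(rep$recall_sd, 0.1)  # population formula: sqrt(mean sq dev)
  expect_equal(rep$assd_mean, 1.0)  # NaN subject dropped
  expect_equal(rep$assd_n_excluded, 1L)

  # single subject: SD 0
  rep1 <- evaluate_cohort(list(r1), method = "m")
  expect_equal(rep1$recall_sd, 0)

  # all-undefined metric aggregates to NaN marker
  r3 <- r1; r3$assd <- NaN
  repn <- evaluate_cohort(list(r3), method = "m")
  expect_true(is.nan(repn$assd_mean))
  expect_equal(repn$assd, "NaN")
})

test_that("metric report round-trips through CSV", {
  r1 <- data.frame(subregion = c("NC", "ED"), recall = c(0.4, 0.8),
                   precision = c(0.5, 0.7), dice = c(0.44, 0.75),
                   lfpr = c(0.01, 0.02), avd = c(0.3, 0.2),
                   assd = c(2.0, 1.0))
  rep <- evaluate_cohort(list(r1), method = "FusionNet-A")
  path <- tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$dice_mean, rep$dice_mean)
  expect_true(all(c("method", "subregion", "recall", "recall_mean",
                    "recall_sd") %in% names(back)))
})
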