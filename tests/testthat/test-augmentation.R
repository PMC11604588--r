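make_sample <- function(edge = c(6, 6, 4), nmod = 2, seed = 1, cubic = FALSE) {
  set.seed(seed)
  if (cubic) edge <- rep(edge[1], 3)
  stack <- array(stats::rnorm(prod(edge) * nmod), c(edge, nmod))
  labels <- array(sample(0:3, prod(edge), replace = TRUE), edge)
  mri_sample(stack, labels, c("FLAIR", "ceT1")[seq_len(nmod)],
             subject_id = paste0("S", seed))
}

test_that("padding centers content with the extra voxel on the high side", {
  s <- make_sample(edge = c(6, 6, 3))
  p <- pad_to_cube(s, 8)
  expect_equal(dim(p$labels), rep(8L, 3))
  mg <- attr(p, "pad_margins")
  expect_equal(mg[1, ], c(lo = 1L, hi = 1L))
  expect_equal(mg[3, ], c(lo = 2L, hi = 3L))  # odd margin: extra on high side

  # the native-resolution case: 240x240x155 -> 256 gives (8,8),(8,8),(50,51)
  expect_equal(fusionseg:::pad_margins(240L, 256L), c(lo = 8L, hi = 8L))
  expect_equal(fusionseg:::pad_margins(155L, 256L), c(lo = 50L, hi = 51L))

  # intensity sum preserved; labels padded with background
  expect_equal(sum(p$stack), sum(s$stack))
  expect_equal(sum(p$labels != 0), sum(s$labels != 0))

  # already-cubic input at the target edge is unchanged
  c8 <- make_sample(edge = 8, cubic = TRUE)
  expect_equal(pad_to_cube(c8, 8)$stack, c8$stack)

  expect_error(pad_to_cube(s, 4), "exceeds")
})

test_that("padding is reversible at the recorded margins", {
  s <- make_sample(edge = c(5, 7, 3))
  p <- pad_to_cube(s, 8)
  back <- crop_to_margins(p)
  expect_identical(back$stack, s$stack)
  expect_identical(back$labels, s$labels)
})

test_that("transforms form the expected group and act jointly", {
  s <- make_sample(edge = 6, cubic = TRUE)

  # involutions and group properties
  expect_equal(apply_transform(apply_transform(s, "hflip"), "hflip")$stack,
               s$stack)
  expect_equal(apply_transform(apply_transform(s, "vflip"), "vflip")$stack,
               s$stack)
  r <- s
  for (i in 1:4) r <- apply_transform(r, "rot90")
  expect_equal(r$stack, s$stack)
  expect_equal(r$labels, s$labels)

  # rot180 = hflip o vflip (verified elementwise on a random volume)
  expect_equal(apply_transform(s, "rot180")$labels,
               apply_transform(apply_transform(s, "vflip"), "hflip")$labels)
  # rot270 undoes rot90
  expect_equal(apply_transform(apply_transform(s, "rot90"), "rot270")$labels,
               s$labels)

  # identical permutation on every channel and the labels: transforming a
  # label map equals transforming the encoded volume (pure index shuffle)
  t1 <- apply_transform(s, "rot90")
  enc <- s; enc$stack[, , , 1] <- s$labels  # ride labels through a channel
  t2 <- apply_transform(enc, "rot90")
  expect_equal(t2$stack[, , , 1], array(as.numeric(t1$labels), dim = dim(t1$labels)))
})

test_that("transforms preserve per-class voxel counts and slice axis", {
  s <- make_sample(edge = 6, cubic = TRUE, seed = 4)
  for (tag in c("hflip", "vflip", "rot90", "rot180", "rot270")) {
    t <- apply_transform(s, tag)
    expect_equal(table(t$labels), table(s$labels))
    expect_equal(t$transform_tag, tag)
    # axial (z) slices keep their content as sets: the slice axis never flips
    for (z in 1:6)
      expect_equal(sort(as.vector(t$labels[, , z])),
                   sort(as.vector(s$labels[, , z])))
  }
  expect_error(apply_transform(s, "transpose"), "unknown transform")

  ns <- make_sample(edge = c(4, 6, 4))
  expect_error(apply_transform(ns, "rot90"), "square")
})

test_that("training-set expansion is exactly sixfold with provenance", {
  originals <- lapply(1:3, function(i) make_sample(edge = 4, cubic = TRUE,
                                                   seed = i))
  out <- expand_training_set(originals)
  expect_length(out, 18L)
  tags <- vapply(out, `[[`, character(1), "transform_tag")
  expect_equal(sort(unique(tags)), sort(fusionseg:::TRANSFORM_TAGS))
  expect_equal(sum(tags == "original"), 3L)

  expect_length(expand_training_set(list()), 0L)
  expect_length(expand_training_set(originals[1]), 6L)

  dup <- c(originals, originals[1])
  expect_error(expand_training_set(dup), "duplicate")

  flipped <- apply_transform(originals[[1]], "hflip")
  expect_error(expand_training_set(list(flipped)), "original")
})
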