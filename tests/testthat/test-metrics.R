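test_that("argmax takes the most probable class, ties to the lowest", {
  p <- array(0, c(1, 2, 3))
  p[1, 1, ] <- c(0.1, 0.7, 0.2)
  p[1, 2, ] <- c(1, 1, 1) / 3
  expect_identical(argmax_classes(p), matrix(c(1L, 0L), 1, 2))
  onehot <- array(0, c(2, 2, 3))
  m <- matrix(c(0L, 2L, 1L, 0L), 2, 2)
  for (i in 1:2) for (j in 1:2) onehot[i, j, m[i, j] + 1] <- 1
  expect_identical(argmax_classes(onehot), m)
})

test_that("metric examples match manual pixel counts", {
  perfect <- matrix(c(0L, 1L, 2L, 0L), 2, 2)
  expect_equal(dice_error(perfect, perfect), 0)
  expect_equal(weed_recall(perfect, perfect), 100)
  expect_equal(weed_precision(perfect, perfect), 100)
  expect_equal(crop_as_weed(perfect, perfect), 0)

  # weed: 4 label px, 4 predicted px, 2 overlapping -> Dice 0.5;
  # soil fills the rest (overlap 10 of 12+12); crop absent -> Dice 1
  E <- matrix(0L, 4, 4); E[1, 1:4] <- 2L
  P <- matrix(0L, 4, 4); P[1, 3:4] <- 2L; P[2, 1:2] <- 2L
  expect_equal(dice_error(P, E),
               100 * (1 - (0.5 + 20 / 24 + 1) / 3), tolerance = 1e-10)
  # ignored label pixels drop out of every count: weed |E|=3, |P|=4,
  # overlap 2; soil |E|=12, |P|=11, overlap 10; crop absent
  Ei <- E; Ei[1, 1] <- 255L
  expect_equal(dice_error(P, Ei),
               100 * (1 - (4 / 7 + 20 / 23 + 1) / 3), tolerance = 1e-10)

  # pooled ratios
  E2 <- matrix(0L, 5, 5); P2 <- matrix(0L, 5, 5)
  E2[1:2, 1:5] <- 2L             # 10 weed pixels
  P2[1, 1:5] <- 2L; P2[2, 1] <- 2L # 6 of them predicted weed
  expect_equal(weed_recall(P2, E2), 60)
  E4 <- matrix(0L, 5, 5); E4[1:2, 1:3] <- 2L # 6 true weed pixels
  P3 <- matrix(0L, 5, 5); P3[1:2, 1:4] <- 2L # 8 predicted, 6 correct
  expect_equal(weed_precision(P3, E4), 75)
  E3 <- matrix(1L, 4, 5) # 20 crop pixels
  P4 <- matrix(1L, 4, 5); P4[1, 1] <- 2L
  expect_equal(crop_as_weed(P4, E3), 5)
  expect_equal(crop_as_weed(matrix(2L, 4, 5), E3), 100)
})

test_that("degenerate denominators give NA, disjoint regions give 100%", {
  E <- matrix(0L, 3, 3)
  P <- matrix(0L, 3, 3); P[1, 1] <- 2L
  expect_warning(r <- weed_recall(P, E), "undefined")
  expect_true(is.na(r))
  expect_equal(weed_precision(P, E), 0)
  # label weed never predicted
  E2 <- matrix(0L, 3, 3); E2[1, ] <- 2L
  expect_equal(weed_recall(matrix(0L, 3, 3), E2), 0)
  # disjoint class regions score Dice 0, i.e. 100% error for that class
  Ew <- matrix(0L, 2, 2); Ew[1, 1] <- 1L
  Pw <- matrix(0L, 2, 2); Pw[2, 2] <- 1L
  # crop disjoint (0), soil overlaps partially, weed absent (1)
  soil_dice <- 2 * 2 / (3 + 3)
  expect_equal(dice_error(Pw, Ew), 100 * (1 - (soil_dice + 0 + 1) / 3))
})

test_that("all four metrics agree with brute-force counting", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(1:3, 1)
    h <- sample(3:16, 1); w <- sample(3:16, 1)
    labels <- replicate(n, random_mask(h, w, with_ignore = TRUE),
                        simplify = FALSE)
    preds <- replicate(n, random_mask(h, w, with_ignore = FALSE),
                       simplify = FALSE)
    ref <- oracle_metrics(preds, labels)
    expect_equal(dice_error(preds, labels), ref$e_dice, tolerance = 1e-12)
    expect_equal(suppressWarnings(weed_recall(preds, labels)), ref$r_weed)
    expect_equal(suppressWarnings(weed_precision(preds, labels)),
                 ref$p_weed)
    expect_equal(suppressWarnings(crop_as_weed(preds, labels)),
                 ref$m_crop_as_weed)
  }
})

test_that("metrics are invariant under a common spatial permutation", {
  set.seed(11)
  E <- random_mask(8, 8); P <- random_mask(8, 8, with_ignore = FALSE)
  perm <- sample(64)
  Ep <- matrix(E[perm], 8, 8); Pp <- matrix(P[perm], 8, 8)
  expect_equal(dice_error(P, E), dice_error(Pp, Ep))
  expect_equal(suppressWarnings(weed_recall(P, E)),
               suppressWarnings(weed_recall(Pp, Ep)))
  expect_equal(suppressWarnings(weed_precision(P, E)),
               suppressWarnings(weed_precision(Pp, Ep)))
})

test_that("zero error and perfect weed scores hold exactly at equality", {
  set.seed(12)
  masks <- replicate(3, random_mask(6, 6, with_ignore = FALSE),
                     simplify = FALSE)
  expect_equal(dice_error(masks, masks), 0)
  expect_equal(weed_recall(masks, masks), 100)
  expect_equal(weed_precision(masks, masks), 100)
  # a single flipped non-weed pixel breaks e_dice = 0 but not weed scores
  m2 <- masks
  soilpx <- which(m2[[1]] == 0L)[1]
  m2[[1]][soilpx] <- 1L
  expect_gt(dice_error(m2, masks), 0)
  expect_equal(weed_recall(m2, masks), 100)
})

test_that("reports assemble all metrics with per-image breakdown", {
  set.seed(13)
  labels <- replicate(2, random_mask(6, 6), simplify = FALSE)
  preds <- replicate(2, random_mask(6, 6, with_ignore = FALSE),
                     simplify = FALSE)
  rep <- suppressWarnings(segmentation_report(preds, labels,
                                              per_image = TRUE))
  expect_s3_class(rep, "metrics_report")
  expect_identical(rep$n_images, 2L)
  expect_identical(nrow(rep$per_image), 2L)
  expect_output(print(rep), "e_dice")
  expect_error(segmentation_report(list(), list()), "non-empty")
  expect_error(segmentation_report(preds[[1]], matrix(0L, 3, 3)),
               "shapes differ")
})
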