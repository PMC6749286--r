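test_that("border exclusion removes exactly the contested band", {
  m <- matrix(1L, 6, 6); m[, 4:6] <- 2L
  out <- exclude_borders(m, 1L)
  expect_identical(sum(out == 255L), 12L)       # the two central columns
  expect_true(all(out[, 3:4] == 255L))
  expect_true(all(out[, c(1:2, 5:6)] != 255L))
  # identity cases
  expect_identical(exclude_borders(m, 0L), m)
  uni <- matrix(2L, 5, 5)
  expect_identical(exclude_borders(uni, 3L), uni)
})

test_that("border exclusion is idempotent and monotone in radius", {
  set.seed(21)
  m <- random_mask(12, 12)
  for (r in 0:3) {
    e1 <- exclude_borders(m, r)
    expect_identical(exclude_borders(e1, r), e1)
  }
  prev <- m
  for (r in 0:3) {
    cur <- exclude_borders(m, r)
    expect_true(all(cur[prev == 255L] == 255L)) # ignore set only grows
    prev <- cur
  }
})

test_that("mask downsampling is a majority vote with ties to ignore", {
  m <- matrix(0L, 8, 8)
  m[1:4, 1:4] <- 1L              # pure crop cell
  m[1:4, 5:6] <- 2L              # half weed / half soil cell -> tie
  m[5:8, 1:2] <- 255L            # half ignored -> soil wins remaining
  m[5:8, 5:8] <- 255L            # fully ignored cell
  d <- downsample_mask(m, 4L)
  expect_identical(d, matrix(c(1L, 0L, 255L, 255L), 2, 2))
  expect_error(downsample_mask(matrix(0L, 6, 6), 4L))
})

test_that("augmentation is seeded, clipped and invertible", {
  img <- random_image(16, 16)
  msk <- random_mask(4, 4)
  set.seed(31); a1 <- augment_pair(img, msk)
  set.seed(31); a2 <- augment_pair(img, msk)
  expect_identical(a1, a2)
  expect_true(all(a1$image >= 0 & a1$image <= 1))
  # identity transform
  set.seed(31)
  id <- augment_pair(img, msk, brightness = c(1, 1), saturation = c(1, 1),
                     flip = FALSE)
  expect_equal(id$image, img, tolerance = 1e-12)
  expect_identical(id$mask, msk)
  # flips are involutions: undo them using the drawn parameters
  set.seed(99)
  fl <- augment_pair(img, msk, brightness = c(1, 1), saturation = c(1, 1))
  undo <- function(x, p) {
    ri <- if (p$flip_v) rev(seq_len(dim(x)[1])) else seq_len(dim(x)[1])
    ci <- if (p$flip_h) rev(seq_len(dim(x)[2])) else seq_len(dim(x)[2])
    if (is.matrix(x)) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
  }
  expect_equal(undo(fl$image, fl$params), img, tolerance = 1e-12)
  expect_identical(undo(fl$mask, fl$params), msk)
  expect_error(augment_pair(img, matrix(0L, 5, 4)), "correspond")
})

test_that("hard training memorizes a single field and is reproducible", {
  cfg <- weedseg:::desk_field_config(1)
  f <- generate_field(cfg, seed = 2)
  m0 <- init_weights(build_stationary(weedseg:::desk_stationary_config()),
                     seed = 1)
  tc <- train_config(epochs = 30L, batch_size = 1L, seed = 5L,
                     augment = FALSE, border_radius = 0L)
  m1 <- train_hard(m0, list(f), tc)
  h1 <- attr(m1, "history")
  expect_lt(h1[length(h1)], h1[1]) # smoke contract: loss decreases
  m2 <- train_hard(m0, list(f), tc)
  expect_identical(h1, attr(m2, "history")) # seeded run repeats exactly
  expect_identical(m1$weights, m2$weights)
  # longer run drives the training loss near zero (memorization)
  m3 <- train_hard(m1, list(f), train_config(epochs = 220L,
                                             batch_size = 1L, seed = 6L,
                                             augment = FALSE,
                                             border_radius = 0L))
  h3 <- attr(m3, "history")
  expect_lt(h3[length(h3)], 0.1)
})

test_that("ignore-only labels contribute nothing, empty datasets error", {
  cfg <- weedseg:::desk_field_config(1)
  f <- generate_field(cfg, seed = 3)
  blank <- list(image = f$image, mask = matrix(255L, 12L, 12L))
  m0 <- init_weights(build_stationary(weedseg:::desk_stationary_config()),
                     seed = 1)
  expect_error(train_hard(m0, list(blank), train_config(epochs = 1L)),
               "non-ignore")
  # mixed batch: the ignore-only image changes nothing
  tc <- train_config(epochs = 2L, batch_size = 2L, seed = 3L,
                     augment = FALSE, border_radius = 0L)
  m_with <- train_hard(m0, list(f, blank), tc)
  m_without <- train_hard(m0, list(f, f), tc)
  # per-step gradients from the blank image are zero, so the trained
  # weights depend only on the labelled image
  fw1 <- run_graph(m_with, f$image)
  expect_true(all(is.finite(fw1$out)))
  expect_true(all(vapply(names(m_with$weights), function(id) {
    all(is.finite(unlist(m_with$weights[[id]])))
  }, logical(1))))
})

test_that("soft-target cross-entropy is bounded below by teacher entropy", {
  set.seed(41)
  for (i in 1:25) {
    p <- matrix(stats::rexp(30), 10, 3); p <- p / rowSums(p)
    q <- matrix(stats::rexp(30), 10, 3); q <- q / rowSums(q)
    ce_pq <- weedseg:::loss_soft(q, p)$loss
    ent_p <- weedseg:::loss_soft(p, p)$loss
    expect_gte(ce_pq, ent_p - 1e-12)
  }
  p <- matrix(stats::rexp(30), 10, 3); p <- p / rowSums(p)
  expect_equal(weedseg:::loss_soft(p, p)$loss,
               -mean(rowSums(p * log(p))))
})

test_that("a student equal to its teacher is a distillation fixed point", {
  # no batch norm, so training-mode and inference-mode outputs coincide
  m <- init_weights(build_mobile(mobile_config(alpha = 0.3,
                                               use_bn = FALSE)),
                    seed = 9)
  img <- random_image(16, 16)
  soft <- predict_probmap(m, img)
  trained <- train_distill(m, list(list(image = img, soft = soft)),
                           train_config(epochs = 3L, batch_size = 1L,
                                        seed = 1L, augment = FALSE))
  expect_equal(trained$weights, m$weights, tolerance = 1e-12)
  h <- attr(trained, "history")
  expect_equal(h, rep(-mean(log(soft) * soft) * 3, 3), tolerance = 1e-6)
})

test_that("uniform soft labels pull the student toward uniform output", {
  m <- init_weights(build_mobile(mobile_config(alpha = 0.3,
                                               use_bn = FALSE)),
                    seed = 10)
  img <- random_image(16, 16)
  soft <- array(1 / 3, c(4, 4, 3))
  before <- mean(abs(predict_probmap(m, img) - 1 / 3))
  t1 <- train_distill(m, list(list(image = img, soft = soft)),
                      train_config(epochs = 120L, batch_size = 1L,
                                   seed = 2L, augment = FALSE))
  after <- mean(abs(predict_probmap(t1, img) - 1 / 3))
  expect_lt(after, before / 4)
  expect_lt(after, 0.02)
})

test_that("malformed soft labels are rejected", {
  m <- init_weights(build_mobile(mobile_config(alpha = 0.3)), seed = 1)
  img <- random_image(16, 16)
  bad <- array(0.5, c(4, 4, 3))
  expect_error(train_distill(m, list(list(image = img, soft = bad)),
                             train_config(epochs = 1L)),
               "probability distributions")
})
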