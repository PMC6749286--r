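test_that("separable conv fragment has the documented shape and cost", {
  g <- build_separable_conv(8, 16, stride = 1)
  sh <- propagate_shapes(g, c(10, 10, 8))
  expect_identical(sh[[graph_output(g)]], c(10L, 10L, 16L))
  expect_equal(count_macs(g, c(10, 10, 8)), 20000)

  g2 <- build_separable_conv(8, 16, stride = 2)
  expect_identical(propagate_shapes(g2, c(10, 10, 8))[[graph_output(g2)]],
                   c(5L, 5L, 16L))
  g3 <- build_separable_conv(1, 1, stride = 1)
  expect_equal(count_macs(g3, c(6, 6, 1)), 36 * 9 + 36)
  expect_error(build_separable_conv(8, 16, stride = 3), "stride")
})

test_that("both block variants conserve channels and halve when reducing", {
  for (variant in c("naive", "custom")) {
    g <- build_dense_mobile(block_spec(3, 8, FALSE, variant, 16))
    sh <- propagate_shapes(g, c(40, 30, 16))
    expect_identical(sh[[graph_output(g)]], c(40L, 30L, 40L))
    gr <- build_dense_mobile(block_spec(3, 8, TRUE, variant, 16))
    shr <- propagate_shapes(gr, c(40, 30, 16))
    expect_identical(shr[[graph_output(gr)]], c(20L, 15L, 40L))
  }
  # minimal block: one stage is one separable conv plus the concat
  g1 <- build_dense_mobile_naive(depthwise_layers = 1, growth = 4,
                                 in_channels = 4)
  expect_identical(propagate_shapes(g1, c(8, 8, 4))$out_cat,
                   c(8L, 8L, 8L))
  kinds <- vapply(g1$nodes, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "depthwise_conv2d"), 1L)
})

test_that("custom blocks filter every channel exactly once", {
  for (reduce in c(FALSE, TRUE)) for (L in 1:3) {
    g <- build_dense_mobile(block_spec(L, 8, reduce, "custom", 16))
    counts <- depthwise_channel_counts(g)
    expect_true(all(counts$n_depthwise <= 1))
    # all channels consumed by a pointwise stage are filtered exactly once
    consumed <- counts$n_depthwise[grepl("^input|^s[0-9]+_pw",
                                         counts$channel)]
    consumed <- counts[counts$channel %in%
      c(paste0("input:", 1:16),
        if (L > 1) unlist(lapply(seq_len(L - 1), function(i) {
          paste0(sprintf("s%d_pw", i), ":", 1:8)
        }))), "n_depthwise"]
    expect_true(all(consumed == 1))
  }
  # the naive reference block re-filters early channels at every stage
  gn <- build_dense_mobile_naive(depthwise_layers = 3, growth = 8,
                                 in_channels = 16)
  cn <- depthwise_channel_counts(gn)
  expect_identical(max(cn$n_depthwise), 3L)
})

test_that("custom wiring never costs more MACs, strictly less when it can", {
  for (L in 1:3) for (growth in c(4L, 8L, 16L)) {
    for (in_ch in c(8L, 16L, 32L)) for (reduce in c(FALSE, TRUE)) {
      gn <- build_dense_mobile(block_spec(L, growth, reduce, "naive", in_ch))
      gc <- build_dense_mobile(block_spec(L, growth, reduce, "custom",
                                          in_ch))
      mn <- count_macs(gn, c(24, 24, in_ch))
      mc <- count_macs(gc, c(24, 24, in_ch))
      info <- sprintf("L=%d g=%d in=%d reduce=%s", L, growth, in_ch, reduce)
      expect_lte(mc, mn, label = info)
      if (L >= 2 || reduce) expect_lt(mc, mn, label = info)
    }
  }
})

test_that("tied naive block equals the custom block numerically", {
  set.seed(42)
  naive <- init_weights(
    build_dense_mobile_naive(depthwise_layers = 3, growth = 8,
                             in_channels = 16), seed = 11)
  tied <- tie_depthwise_weights(naive)
  custom <- custom_model_from_naive(tied)
  worst <- 0
  for (i in 1:100) {
    x <- random_image(10, 10, 16)
    worst <- max(worst, max(abs(run_graph(tied, x)$out -
                                  run_graph(custom, x)$out)))
  }
  expect_lte(worst, 1e-5)
  # untied weights do NOT agree (the oracle is not vacuous)
  custom_untied <- custom_model_from_naive(naive)
  x <- random_image(10, 10, 16)
  expect_gt(max(abs(run_graph(naive, x)$out -
                      run_graph(custom_untied, x)$out)), 1e-3)
})

test_that("tying is idempotent and a no-op for one stage", {
  one <- init_weights(build_dense_mobile_naive(depthwise_layers = 1,
                                               growth = 4,
                                               in_channels = 4), seed = 2)
  expect_identical(tie_depthwise_weights(one)$weights, one$weights)
  three <- init_weights(build_dense_mobile_naive(depthwise_layers = 3,
                                                 growth = 8,
                                                 in_channels = 16),
                        seed = 3)
  t1 <- tie_depthwise_weights(three)
  expect_identical(tie_depthwise_weights(t1)$weights, t1$weights)
  custom <- init_weights(build_dense_mobile_custom(in_channels = 8),
                         seed = 1)
  expect_error(tie_depthwise_weights(custom), "naive")
})
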