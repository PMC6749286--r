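#' DenseNet-Mobile block specification
#'
#' A DenseNet block concatenates the block input with the output of every
#' stage, each stage adding `growth` channels. The mobile adaptation
#' replaces the full convolution of each stage with a depthwise 3 x 3
#' convolution followed by a pointwise (1 x 1) convolution. Two wirings
#' are provided:
#'
#' * `naive` — each stage depthwise-filters its *entire* concatenated
#'   input, so a channel produced early in the block is re-filtered by
#'   every later stage; a reducing block runs all stages at the input
#'   resolution and average-pools the concatenated output.
#' * `custom` — every channel is depthwise-filtered exactly once, when it
#'   first enters the block (the block input at stage 1, each stage's new
#'   channels right after they are produced); later stages read the
#'   cached filtered maps. A reducing block average-pools the input
#'   *before* any convolution, so all block computation runs at the
#'   reduced resolution.
#'
#' Both wirings emit `in_channels + depthwise_layers * growth` channels,
#' and with per-channel depthwise kernels shared across stages (see
#' [tie_depthwise_weights()]) the non-reducing forms compute identical
#' functions; the custom form simply never repeats a depthwise pass.
#'
#' @param depthwise_layers Number of growth stages (reference value 3).
#' @param growth Channels added per stage.
#' @param reduce Halve the spatial resolution?
#' @param variant `"naive"` or `"custom"`.
#' @param in_channels Channels entering the block.
#' @param use_bn Insert batch normalization after each pointwise stage?
#' @return A `block_spec` list.
#' @export
block_spec <- function(depthwise_layers = 3L, growth = 8L, reduce = FALSE,
                       variant = c("naive", "custom"), in_channels = 16L,
                       use_bn = TRUE) {
  variant <- match.arg(variant)
  stopifnot(depthwise_layers >= 1, growth >= 1, in_channels >= 1)
  structure(list(depthwise_layers = as.integer(depthwise_layers),
                 growth = as.integer(growth), reduce = isTRUE(reduce),
                 variant = variant, in_channels = as.integer(in_channels),
                 use_bn = isTRUE(use_bn)),
            class = "block_spec")
}

#' Depthwise-separable convolution fragment
#'
#' A depthwise 3 x 3 convolution (channel multiplier 1) followed by a
#' pointwise convolution, each followed by batch normalization and ReLU.
#'
#' @param in_channels,out_channels Channel counts.
#' @param stride 1 or 2 (applied in the depthwise node).
#' @param use_bn Insert batch normalization nodes?
#' @param prefix Node id prefix.
#' @return A `network_graph` fragment whose input is the fragment input.
#' @export
build_separable_conv <- function(in_channels, out_channels, stride = 1L,
                                 use_bn = TRUE, prefix = "sep") {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  g <- graph_new(in_channels)
  g <- graph_add(g, paste0(prefix, "_dw"), "depthwise_conv2d",
                 inputs = "input", kernel = 3L, stride = as.integer(stride))
  if (use_bn) g <- graph_add(g, paste0(prefix, "_dw_bn"), "batch_norm")
  g <- graph_add(g, paste0(prefix, "_dw_relu"), "relu")
  g <- graph_add(g, paste0(prefix, "_pw"), "pointwise_conv2d",
                 out_channels = out_channels)
  if (use_bn) g <- graph_add(g, paste0(prefix, "_pw_bn"), "batch_norm")
  g <- graph_add(g, paste0(prefix, "_pw_relu"), "relu")
  g
}

#' Build a DenseNet-Mobile block
#'
#' @param spec A [block_spec()].
#' @return A `network_graph` fragment; its `block_spec` attribute records
#'   the spec.
#' @export
build_dense_mobile <- function(spec) {
  stopifnot(inherits(spec, "block_spec"))
  g <- switch(spec$variant,
              naive = build_dense_mobile_naive_(spec),
              custom = build_dense_mobile_custom_(spec))
  attr(g, "block_spec") <- spec
  g
}

#' @rdname build_dense_mobile
#' @param ... Passed to [block_spec()].
#' @export
build_dense_mobile_naive <- function(...) {
  build_dense_mobile(block_spec(..., variant = "naive"))
}

#' @rdname build_dense_mobile
#' @export
build_dense_mobile_custom <- function(...) {
  build_dense_mobile(block_spec(..., variant = "custom"))
}

# Stage tail shared by both variants: pointwise -> (bn) -> relu.
add_stage_tail <- function(g, i, growth, use_bn, from) {
  g <- graph_add(g, sprintf("s%d_pw", i), "pointwise_conv2d",
                 inputs = from, out_channels = growth)
  if (use_bn) g <- graph_add(g, sprintf("s%d_bn", i), "batch_norm")
  g <- graph_add(g, sprintf("s%d_relu", i), "relu")
  g
}

build_dense_mobile_naive_ <- function(spec) {
  L <- spec$depthwise_layers
  g <- graph_new(spec$in_channels)
  feeds <- "input" # block input plus earlier stage outputs
  for (i in seq_len(L)) {
    stage_in <- if (length(feeds) == 1L) feeds else {
      g <- graph_add(g, sprintf("s%d_in", i), "concat", inputs = feeds)
      sprintf("s%d_in", i)
    }
    g <- graph_add(g, sprintf("s%d_dw", i), "depthwise_conv2d",
                   inputs = stage_in, kernel = 3L)
    g <- add_stage_tail(g, i, spec$growth, spec$use_bn, sprintf("s%d_dw", i))
    feeds <- c(feeds, sprintf("s%d_relu", i))
  }
  g <- graph_add(g, "out_cat", "concat", inputs = feeds)
  if (spec$reduce) g <- graph_add(g, "out_pool", "avg_pool2x2")
  g
}

build_dense_mobile_custom_ <- function(spec) {
  L <- spec$depthwise_layers
  g <- graph_new(spec$in_channels)
  base <- "input"
  if (spec$reduce) {
    g <- graph_add(g, "pre_pool", "avg_pool2x2", inputs = "input")
    base <- "pre_pool"
  }
  g <- graph_add(g, "dw0", "depthwise_conv2d", inputs = base, kernel = 3L)
  cached <- "dw0" # depthwise-filtered maps of every channel seen so far
  outs <- character(0)
  for (i in seq_len(L)) {
    stage_in <- if (length(cached) == 1L) cached else {
      g <- graph_add(g, sprintf("s%d_in", i), "concat", inputs = cached)
      sprintf("s%d_in", i)
    }
    g <- add_stage_tail(g, i, spec$growth, spec$use_bn, stage_in)
    outs <- c(outs, sprintf("s%d_relu", i))
    if (i < L) {
      g <- graph_add(g, sprintf("s%d_cache", i), "depthwise_conv2d",
                     inputs = sprintf("s%d_relu", i), kernel = 3L)
      cached <- c(cached, sprintf("s%d_cache", i))
    }
  }
  g <- graph_add(g, "out_cat", "concat", inputs = c(base, outs))
  g
}

#' Count depthwise filterings per originating channel
#'
#' Traces channel provenance through a graph: channels are created by the
#' input and by full/pointwise convolutions; concatenation merges
#' provenance, and depthwise/normalization/activation/resampling nodes
#' preserve it. For each originating channel the number of depthwise
#' convolutions it passes through is counted — the quantity the custom
#' DenseNet-Mobile block drives down to one.
#'
#' @param graph A `network_graph`.
#' @return A data.frame with columns `channel` (provenance label,
#'   `"<node>:<k>"`) and `n_depthwise`.
#' @export
depthwise_channel_counts <- function(graph) {
  labels <- list(input = paste0("input:", seq_len(graph$input_channels)))
  counts <- new.env(parent = emptyenv())
  for (lb in labels$input) assign(lb, 0L, envir = counts)
  for (nd in graph$nodes) {
    inlab <- labels[[nd$inputs[1]]]
    labels[[nd$id]] <- switch(nd$kind,
      conv2d = , pointwise_conv2d = {
        fresh <- paste0(nd$id, ":", seq_len(nd$out_channels))
        for (lb in fresh) assign(lb, 0L, envir = counts)
        fresh
      },
      depthwise_conv2d = {
        for (lb in inlab) assign(lb, get(lb, envir = counts) + 1L,
                                 envir = counts)
        inlab
      },
      concat = unlist(lapply(nd$inputs, function(i) labels[[i]])),
      add = inlab,
      inlab)
  }
  lbs <- ls(counts)
  out <- data.frame(channel = lbs,
                    n_depthwise = vapply(lbs, get, integer(1),
                                         envir = counts),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$channel), , drop = FALSE]
}

## Weight tying and transfer ----------------------------------------------

naive_block_layout <- function(spec) {
  # Channel layout of stage i's depthwise input: block input channels
  # first, then each earlier stage's growth channels in order.
  L <- spec$depthwise_layers
  lapply(seq_len(L), function(i) {
    sizes <- c(spec$in_channels, rep(spec$growth, i - 1L))
    ends <- cumsum(sizes)
    lapply(seq_along(sizes), function(j) (ends[j] - sizes[j] + 1L):ends[j])
  })
}

#' Share depthwise kernels across the stages of a naive block
#'
#' In a naive DenseNet-Mobile block a channel that enters at stage 1 is
#' depthwise-filtered again by every later stage, each time with its own
#' kernel. This transform copies, for every channel, the kernel (and
#' bias) of the *first* depthwise node that filters it into every later
#' depthwise slice acting on the same channel. After tying, a naive block
#' computes the same function as the custom depthwise-cached block with
#' matched weights (non-reducing case), which is the correctness oracle
#' for the custom wiring. The transform is idempotent.
#'
#' @param model A `seg_model` whose graph was built by
#'   [build_dense_mobile_naive()].
#' @return The model with tied depthwise weights.
#' @export
tie_depthwise_weights <- function(model) {
  spec <- attr(model$graph, "block_spec")
  if (is.null(spec) || spec$variant != "naive") {
    stop("tie_depthwise_weights() expects a naive DenseNet-Mobile block",
         call. = FALSE)
  }
  lay <- naive_block_layout(spec)
  L <- spec$depthwise_layers
  # canonical kernels: group g (0 = input, j = stage j output) is first
  # filtered by depthwise stage g + 1
  canon <- lapply(seq_len(L) - 1L, function(gix) {
    first <- sprintf("s%d_dw", gix + 1L)
    sl <- lay[[gix + 1L]][[gix + 1L]]
    list(W = model$weights[[first]]$W[, , sl, drop = FALSE],
         b = model$weights[[first]]$b[sl])
  })
  for (i in seq_len(L)) {
    id <- sprintf("s%d_dw", i)
    for (gix in seq_len(i) - 1L) {
      sl <- lay[[i]][[gix + 1L]]
      model$weights[[id]]$W[, , sl] <- canon[[gix + 1L]]$W
      model$weights[[id]]$b[sl] <- canon[[gix + 1L]]$b
    }
  }
  model
}

#' Map the weights of a tied naive block onto the custom block
#'
#' Builds the weight set under which the custom (depthwise-cached) block
#' reproduces a tied naive block exactly in the non-reducing case: the
#' shared per-channel depthwise kernels become the single cached
#' depthwise nodes, and pointwise/batch-norm parameters transfer
#' unchanged (the cached concatenation preserves channel order).
#'
#' @param naive_model A tied naive-block `seg_model`.
#' @return A `seg_model` for the matching custom block.
#' @export
custom_model_from_naive <- function(naive_model) {
  spec <- attr(naive_model$graph, "block_spec")
  if (is.null(spec) || spec$variant != "naive") {
    stop("expected a naive DenseNet-Mobile block model", call. = FALSE)
  }
  cspec <- spec; cspec$variant <- "custom"
  cgraph <- build_dense_mobile(block_spec(
    depthwise_layers = spec$depthwise_layers, growth = spec$growth,
    reduce = spec$reduce, variant = "custom",
    in_channels = spec$in_channels, use_bn = spec$use_bn))
  cmodel <- init_weights(cgraph, seed = 0L)
  lay <- naive_block_layout(spec)
  L <- spec$depthwise_layers
  grab <- function(gix) { # first-use kernel of channel group gix
    first <- sprintf("s%d_dw", gix + 1L)
    sl <- lay[[gix + 1L]][[gix + 1L]]
    list(W = naive_model$weights[[first]]$W[, , sl, drop = FALSE],
         b = naive_model$weights[[first]]$b[sl])
  }
  k0 <- grab(0L)
  cmodel$weights$dw0 <- list(W = array(k0$W, c(3L, 3L, spec$in_channels)),
                             b = k0$b)
  for (i in seq_len(L)) {
    cmodel$weights[[sprintf("s%d_pw", i)]] <-
      naive_model$weights[[sprintf("s%d_pw", i)]]
    if (spec$use_bn) {
      bid <- sprintf("s%d_bn", i)
      cmodel$weights[[bid]] <- naive_model$weights[[bid]]
      cmodel$bn[[bid]] <- naive_model$bn[[bid]]
    }
    if (i < L) {
      ki <- grab(i)
      cmodel$weights[[sprintf("s%d_cache", i)]] <-
        list(W = array(ki$W, c(3L, 3L, spec$growth)), b = ki$b)
    }
  }
  cmodel
}
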