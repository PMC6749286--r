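#' Model configurations
#'
#' `stationary_config()` parameterizes the stationary U-Net teacher: a
#' 4-level encoder of full 3 x 3 convolutions whose widths are the base
#' widths scaled by the MobileNets schedule, 2 x 2 average pooling
#' between levels, and a decoder that upscales only back to 1/4 of the
#' input resolution (two decoder levels with skip concatenations),
#' ending in a pointwise projection to the class count and a softmax.
#' The coarse output (about 9 mm/pixel at the nominal camera geometry)
#' is sufficient for weeding-tool control and keeps inference cheap.
#'
#' `mobile_config()` parameterizes the mobile hybrid: a stride-2 stem
#' convolution to width A, a reducing DenseNet-Mobile block transitioned
#' to width B, a reducing block transitioned to width C, a non-reducing
#' block at width C, then a nearest-neighbour upscale, a skip
#' concatenation from the width-B stage, `n_residual` separable residual
#' units, and the terminal pointwise + softmax. (A, B, C) come from
#' [channel_triple()]. Total downsampling factor is 4 for both models.
#'
#' @param alpha Width multiplier.
#' @param base_widths Stationary encoder base widths (reference
#'   64, 128, 256, 512), strictly increasing.
#' @param n_classes Segmentation classes (3: soil, crop, weed).
#' @param channel_variant `"mobilenet"` or `"mod8"` schedule for the
#'   mobile model's width triple.
#' @param block_variant `"naive"` or `"custom"` DenseNet-Mobile wiring.
#' @param n_residual Number of final residual units (reference 2).
#' @param use_bn Insert batch normalization?
#' @return A config list of the matching class.
#' @export
stationary_config <- function(alpha = 1.0,
                              base_widths = c(64L, 128L, 256L, 512L),
                              n_classes = 3L, use_bn = TRUE) {
  check_schedule_args(1L, alpha)
  stopifnot(length(base_widths) == 4L, all(diff(base_widths) > 0),
            n_classes >= 2)
  structure(list(alpha = alpha, base_widths = as.integer(base_widths),
                 n_classes = as.integer(n_classes), use_bn = isTRUE(use_bn)),
            class = "stationary_config")
}

#' @rdname stationary_config
#' @export
mobile_config <- function(alpha = 1.0,
                          channel_variant = c("mod8", "mobilenet"),
                          block_variant = c("custom", "naive"),
                          n_residual = 2L, n_classes = 3L, use_bn = TRUE) {
  check_schedule_args(1L, alpha)
  channel_variant <- match.arg(channel_variant)
  block_variant <- match.arg(block_variant)
  stopifnot(n_residual >= 0, n_classes >= 2)
  structure(list(alpha = alpha, channel_variant = channel_variant,
                 block_variant = block_variant,
                 n_residual = as.integer(n_residual),
                 n_classes = as.integer(n_classes), use_bn = isTRUE(use_bn)),
            class = "mobile_config")
}

conv_bn_relu <- function(g, id, inputs, out_channels, use_bn,
                         stride = 1L) {
  g <- graph_add(g, id, "conv2d", inputs = inputs,
                 out_channels = out_channels, kernel = 3L, stride = stride)
  if (use_bn) g <- graph_add(g, paste0(id, "_bn"), "batch_norm")
  graph_add(g, paste0(id, "_relu"), "relu")
}

#' Build the stationary U-Net segmentation graph
#'
#' @param config A [stationary_config()].
#' @return A `network_graph` mapping `h x w x 3` inputs (h, w divisible
#'   by 16) to `h/4 x w/4 x n_classes` per-pixel class probabilities.
#' @examples
#' g <- build_stationary(stationary_config(alpha = 0.5))
#' propagate_shapes(g, c(240, 320))$softmax  # 60 80 3
#' @export
build_stationary <- function(config) {
  stopifnot(inherits(config, "stationary_config"))
  wds <- vapply(config$base_widths, f_mobilenet, integer(1),
                alpha = config$alpha)
  g <- graph_new(3L)
  g <- conv_bn_relu(g, "enc1", "input", wds[1], config$use_bn)
  g <- graph_add(g, "pool1", "avg_pool2x2")
  g <- conv_bn_relu(g, "enc2", "pool1", wds[2], config$use_bn)
  g <- graph_add(g, "pool2", "avg_pool2x2")
  g <- conv_bn_relu(g, "enc3", "pool2", wds[3], config$use_bn)
  g <- graph_add(g, "pool3", "avg_pool2x2")
  g <- conv_bn_relu(g, "enc4", "pool3", wds[4], config$use_bn)
  g <- graph_add(g, "pool4", "avg_pool2x2")
  g <- conv_bn_relu(g, "bott", "pool4", wds[4], config$use_bn)
  g <- graph_add(g, "up1", "upscale2x", inputs = "bott_relu")
  g <- graph_add(g, "skip1", "concat", inputs = c("up1", "enc4_relu"))
  g <- conv_bn_relu(g, "dec1", "skip1", wds[3], config$use_bn)
  g <- graph_add(g, "up2", "upscale2x", inputs = "dec1_relu")
  g <- graph_add(g, "skip2", "concat", inputs = c("up2", "enc3_relu"))
  g <- conv_bn_relu(g, "dec2", "skip2", wds[2], config$use_bn)
  g <- graph_add(g, "head", "pointwise_conv2d", inputs = "dec2_relu",
                 out_channels = config$n_classes)
  g <- graph_add(g, "softmax", "softmax")
  attr(g, "model_config") <- config
  g
}

#' Build the mobile hybrid segmentation graph
#'
#' @param config A [mobile_config()].
#' @return A `network_graph` mapping `h x w x 3` inputs (h, w divisible
#'   by 8) to `h/4 x w/4 x n_classes` probabilities.
#' @examples
#' g <- build_mobile(mobile_config(alpha = 1.0, channel_variant = "mod8"))
#' propagate_shapes(g, c(112, 320))$softmax  # 28 80 3
#' @export
build_mobile <- function(config) {
  stopifnot(inherits(config, "mobile_config"))
  tr <- channel_triple(config$alpha, config$channel_variant)
  A <- tr[["A"]]; B <- tr[["B"]]; C <- tr[["C"]]
  growth_of <- function(ch) max(1L, ch %/% 2L)
  g <- graph_new(3L)
  g <- conv_bn_relu(g, "stem", "input", A, config$use_bn, stride = 2L)

  blk <- function(g, name, in_ch, reduce, attach) {
    frag <- build_dense_mobile(block_spec(
      depthwise_layers = 3L, growth = growth_of(in_ch), reduce = reduce,
      variant = config$block_variant, in_channels = in_ch,
      use_bn = config$use_bn))
    graph_splice(g, frag, name, attach)
  }
  tail_of <- function(name, reduce) {
    if (config$block_variant == "naive" && reduce) {
      paste0(name, "/out_pool")
    } else paste0(name, "/out_cat")
  }

  g <- blk(g, "blk1", A, TRUE, "stem_relu")                  # -> 1/4
  g <- graph_add(g, "tr1", "pointwise_conv2d",
                 inputs = tail_of("blk1", TRUE), out_channels = B)
  if (config$use_bn) g <- graph_add(g, "tr1_bn", "batch_norm")
  g <- graph_add(g, "tr1_relu", "relu")
  g <- blk(g, "blk2", B, TRUE, "tr1_relu")                   # -> 1/8
  g <- graph_add(g, "tr2", "pointwise_conv2d",
                 inputs = tail_of("blk2", TRUE), out_channels = C)
  if (config$use_bn) g <- graph_add(g, "tr2_bn", "batch_norm")
  g <- graph_add(g, "tr2_relu", "relu")
  g <- blk(g, "blk3", C, FALSE, "tr2_relu")                  # stays 1/8
  g <- graph_add(g, "tr3", "pointwise_conv2d",
                 inputs = tail_of("blk3", FALSE), out_channels = C)
  if (config$use_bn) g <- graph_add(g, "tr3_bn", "batch_norm")
  g <- graph_add(g, "tr3_relu", "relu")

  g <- graph_add(g, "up", "upscale2x", inputs = "tr3_relu")  # -> 1/4
  g <- graph_add(g, "skip", "concat", inputs = c("up", "tr1_relu"))
  g <- graph_add(g, "fuse", "pointwise_conv2d", out_channels = B)
  if (config$use_bn) g <- graph_add(g, "fuse_bn", "batch_norm")
  g <- graph_add(g, "fuse_relu", "relu")
  prev <- "fuse_relu"
  for (r in seq_len(config$n_residual)) {
    frag <- build_separable_conv(B, B, stride = 1L, use_bn = config$use_bn,
                                 prefix = "sep")
    g <- graph_splice(g, frag, sprintf("res%d", r), prev)
    g <- graph_add(g, sprintf("res%d_add", r), "add",
                   inputs = c(prev, sprintf("res%d/sep_pw_relu", r)))
    prev <- sprintf("res%d_add", r)
  }
  g <- graph_add(g, "head", "pointwise_conv2d", inputs = prev,
                 out_channels = config$n_classes)
  g <- graph_add(g, "softmax", "softmax")
  attr(g, "model_config") <- config
  g
}

#' Attach deterministic random weights to a graph
#'
#' Fan-in-scaled (He) normal initialization for every convolution, zero
#' biases, unit-gain batch normalization with zero-mean/unit-variance
#' running statistics.
#'
#' @param graph A `network_graph`.
#' @param seed Integer seed; the same seed yields identical weights.
#' @return A `seg_model`: list with `graph`, `weights` (per node) and
#'   `bn` (running statistics per batch-norm node).
#' @export
init_weights <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "network_graph"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  weights <- list()
  bn <- list()
  for (nd in graph$nodes) {
    weights[[nd$id]] <- switch(nd$kind,
      conv2d = {
        k <- nd$kernel; cin <- nd$in_channels[1]; cout <- nd$out_channels
        list(W = array(stats::rnorm(k * k * cin * cout,
                                    sd = sqrt(2 / (k * k * cin))),
                       c(k, k, cin, cout)),
             b = numeric(cout))
      },
      depthwise_conv2d = {
        k <- nd$kernel; ch <- nd$out_channels
        list(W = array(stats::rnorm(k * k * ch, sd = sqrt(2 / (k * k))),
                       c(k, k, ch)),
             b = numeric(ch))
      },
      pointwise_conv2d = {
        cin <- nd$in_channels[1]; cout <- nd$out_channels
        list(W = matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)),
                        cin, cout),
             b = numeric(cout))
      },
      batch_norm = {
        bn[[nd$id]] <- list(mean = numeric(nd$out_channels),
                            var = rep(1, nd$out_channels))
        list(gamma = rep(1, nd$out_channels),
             beta = numeric(nd$out_channels))
      },
      NULL)
  }
  structure(list(graph = graph, weights = weights, bn = bn, seed = seed),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  np <- sum(vapply(x$weights, function(w) {
    sum(vapply(w, length, integer(1)))
  }, numeric(1)))
  cat(sprintf("<seg_model> %d nodes, %s parameters\n",
              length(x$graph$nodes), format(np, big.mark = ",")))
  invisible(x)
}

#' Per-pixel class probabilities for one image
#'
#' Runs the model in inference mode and reshapes the terminal softmax
#' activations to a probability map.
#'
#' @param model A `seg_model`.
#' @param image `h x w x 3` array in `[0, 1]`.
#' @return An `h/4 x w/4 x n_classes` array; per-pixel values sum to 1.
#' @export
predict_probmap <- function(model, image) {
  fw <- run_graph(model, image, training = FALSE)
  array(fw$out, c(fw$dims[1], fw$dims[2], ncol(fw$out)))
}

#' Save / load a segmentation model
#'
#' The checkpoint is an RDS archive of the weight and batch-norm arrays
#' keyed by node id; the graph is additionally stored as its plain-text
#' serialization next to it (`<path>.graph.txt`) so the architecture is
#' inspectable without loading R objects.
#'
#' @param model A `seg_model`.
#' @param path Checkpoint path.
#' @return `load_model()` returns the `seg_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  serialize_graph(model$graph, paste0(path, ".graph.txt"))
  saveRDS(list(weights = model$weights, bn = model$bn, seed = model$seed,
               config = attr(model$graph, "model_config"),
               block_spec = attr(model$graph, "block_spec")), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  graph <- deserialize_graph(paste0(path, ".graph.txt"))
  attr(graph, "model_config") <- obj$config
  attr(graph, "block_spec") <- obj$block_spec
  structure(list(graph = graph, weights = obj$weights, bn = obj$bn,
                 seed = obj$seed), class = "seg_model")
}
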