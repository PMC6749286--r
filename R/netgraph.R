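#' Convolutional computation graphs
#'
#' A `network_graph` is an ordered, shape-checked description of a
#' convolutional network: a list of nodes (convolutions, pooling,
#' rescaling, concatenation, addition, batch normalization, activations)
#' wired by node identifiers, plus the channel count of the single input.
#' The description is execution-agnostic: it can be shape-propagated,
#' audited for multiply-accumulate (MAC) cost, serialized to text, and
#' executed by [run_graph()] once weights are attached.
#'
#' Node kinds and conventions:
#' * `conv2d` — full k x k convolution, same padding, stride 1 or 2.
#' * `depthwise_conv2d` — per-channel k x k convolution (channel
#'   multiplier `mult`, usually 1), same padding.
#' * `pointwise_conv2d` — 1 x 1 cross-channel convolution.
#' * `avg_pool2x2` — 2 x 2 average pooling, stride 2.
#' * `upscale2x` — nearest-neighbour duplication to double height and
#'   width (the cheap replacement for a transposed convolution).
#' * `concat` — channel concatenation of equal-resolution inputs.
#' * `add` — elementwise sum of identically shaped inputs.
#' * `batch_norm`, `relu`, `softmax` — per-channel normalization,
#'   rectifier, per-pixel class softmax.
#'
#' Spatial shapes are `(height, width)`, origin top-left; downsampling
#' happens only through stride 2 or 2 x 2 pooling, so an input divisible
#' by the total downsampling factor maps to an exact integer output
#' resolution.
#'
#' @param input_channels Channels of the graph input (3 for RGB).
#' @return `graph_new()` returns an empty `network_graph`.
#' @name network_graph
NULL

GRAPH_KINDS <- c("conv2d", "depthwise_conv2d", "pointwise_conv2d",
                 "avg_pool2x2", "upscale2x", "concat", "add",
                 "batch_norm", "relu", "softmax")

#' @rdname network_graph
#' @export
graph_new <- function(input_channels = 3L) {
  stopifnot(is.numeric(input_channels), input_channels >= 1)
  structure(list(nodes = list(), input_channels = as.integer(input_channels)),
            class = "network_graph")
}

node_channels <- function(graph, id) {
  if (id == "input") return(graph$input_channels)
  nd <- graph$nodes[[id]]
  if (is.null(nd)) stop(sprintf("unknown node '%s'", id), call. = FALSE)
  nd$out_channels
}

#' Append a node to a network graph
#'
#' @param graph A [graph_new()] object.
#' @param id Unique node identifier.
#' @param kind One of the node kinds listed in [network_graph].
#' @param inputs Character vector of upstream node ids (`"input"` for the
#'   graph input). Defaults to the most recently added node.
#' @param out_channels Output channels (required for `conv2d` and
#'   `pointwise_conv2d`).
#' @param kernel Odd kernel side length for spatial convolutions.
#' @param stride 1 or 2 (conv kinds only).
#' @param mult Channel multiplier for depthwise nodes.
#' @return The graph with the node appended.
#' @export
graph_add <- function(graph, id, kind, inputs = NULL, out_channels = NULL,
                      kernel = 3L, stride = 1L, mult = 1L) {
  stopifnot(inherits(graph, "network_graph"))
  if (!kind %in% GRAPH_KINDS) {
    stop(sprintf("unknown node kind '%s'", kind), call. = FALSE)
  }
  if (id == "input" || id %in% names(graph$nodes)) {
    stop(sprintf("duplicate or reserved node id '%s'", id), call. = FALSE)
  }
  if (is.null(inputs)) {
    inputs <- if (length(graph$nodes)) names(graph$nodes)[length(graph$nodes)]
              else "input"
  }
  for (inp in inputs) node_channels(graph, inp) # existence check
  in_ch <- vapply(inputs, function(i) node_channels(graph, i), integer(1))

  if (kind %in% c("conv2d", "depthwise_conv2d", "pointwise_conv2d")) {
    if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
    if (kind == "pointwise_conv2d") kernel <- 1L
    if (kernel %% 2 != 1 || kernel < 1) {
      stop("kernel side must be odd and positive", call. = FALSE)
    }
  } else {
    kernel <- NA_integer_; stride <- 1L
  }

  out <- switch(kind,
    conv2d = ,
    pointwise_conv2d = {
      if (is.null(out_channels)) stop("out_channels required", call. = FALSE)
      if (length(inputs) != 1L) stop("conv takes one input", call. = FALSE)
      as.integer(out_channels)
    },
    depthwise_conv2d = {
      if (length(inputs) != 1L) stop("conv takes one input", call. = FALSE)
      if (mult < 1 || mult != floor(mult)) {
        stop("depthwise multiplier must be a positive integer", call. = FALSE)
      }
      as.integer(in_ch[[1]] * mult)
    },
    concat = as.integer(sum(in_ch)),
    add = {
      if (length(unique(in_ch)) != 1L) {
        stop(sprintf("add node '%s' requires equal input channels", id),
             call. = FALSE)
      }
      as.integer(in_ch[[1]])
    },
    {
      if (length(inputs) != 1L) {
        stop(sprintf("%s takes one input", kind), call. = FALSE)
      }
      as.integer(in_ch[[1]])
    })

  graph$nodes[[id]] <- list(id = id, kind = kind, inputs = inputs,
                            in_channels = as.integer(in_ch),
                            out_channels = out,
                            kernel = as.integer(kernel),
                            stride = as.integer(stride),
                            mult = as.integer(mult))
  graph
}

#' Terminal node of a graph
#' @param graph A `network_graph`.
#' @return The id of the last node.
#' @export
graph_output <- function(graph) {
  stopifnot(length(graph$nodes) > 0)
  names(graph$nodes)[length(graph$nodes)]
}

#' Splice one graph into another as a subgraph
#'
#' Appends every node of `fragment` to `graph`, prefixing node ids with
#' `prefix` and rewiring the fragment's `"input"` references to `attach`.
#'
#' @param graph Host graph.
#' @param fragment Fragment graph whose input channel count must match
#'   the channels of `attach`.
#' @param prefix Id prefix (a `/` separator is inserted).
#' @param attach Host node id the fragment input is wired to.
#' @return The host graph with the fragment spliced in; the fragment's
#'   terminal node becomes `<prefix>/<terminal>`.
#' @export
graph_splice <- function(graph, fragment, prefix, attach) {
  stopifnot(inherits(fragment, "network_graph"))
  if (node_channels(graph, attach) != fragment$input_channels) {
    stop("fragment input channels do not match attachment node", call. = FALSE)
  }
  for (nd in fragment$nodes) {
    inputs <- ifelse(nd$inputs == "input", attach,
                     paste0(prefix, "/", nd$inputs))
    graph <- graph_add(graph, paste0(prefix, "/", nd$id), nd$kind,
                       inputs = inputs, out_channels = nd$out_channels,
                       kernel = if (is.na(nd$kernel)) 3L else nd$kernel,
                       stride = nd$stride, mult = nd$mult)
  }
  graph
}

#' Propagate tensor shapes through a graph
#'
#' Assigns every node an output shape for a given input resolution,
#' checking divisibility wherever the graph downsamples. Spatial
#' convolutions use same padding, so stride-1 nodes preserve resolution
#' and stride-2 nodes halve it exactly.
#'
#' @param graph A `network_graph`.
#' @param input_shape Integer vector `c(height, width)` or
#'   `c(height, width, channels)`; a supplied channel count must match
#'   the graph's input channels.
#' @return Named list mapping node id (plus `"input"`) to
#'   `c(height, width, channels)`.
#' @export
propagate_shapes <- function(graph, input_shape) {
  stopifnot(inherits(graph, "network_graph"))
  input_shape <- as.integer(input_shape)
  if (length(input_shape) == 2L) {
    input_shape <- c(input_shape, graph$input_channels)
  }
  stopifnot(length(input_shape) == 3L, all(input_shape >= 1))
  if (input_shape[3] != graph$input_channels) {
    stop("input channel count does not match graph", call. = FALSE)
  }
  shapes <- list(input = input_shape)
  for (nd in graph$nodes) {
    ins <- lapply(nd$inputs, function(i) shapes[[i]])
    hw <- ins[[1]][1:2]
    if (length(ins) > 1L) {
      for (s in ins) {
        if (!identical(s[1:2], hw)) {
          stop(sprintf("node '%s': input resolutions differ", nd$id),
               call. = FALSE)
        }
      }
    }
    hw_out <- switch(nd$kind,
      conv2d = , depthwise_conv2d = , pointwise_conv2d = {
        if (nd$stride == 2L && any(hw %% 2L != 0L)) {
          stop(sprintf("node '%s': %dx%d not divisible by stride 2",
                       nd$id, hw[1], hw[2]), call. = FALSE)
        }
        hw %/% nd$stride
      },
      avg_pool2x2 = {
        if (any(hw %% 2L != 0L)) {
          stop(sprintf("node '%s': %dx%d not divisible by 2x2 pooling",
                       nd$id, hw[1], hw[2]), call. = FALSE)
        }
        hw %/% 2L
      },
      upscale2x = hw * 2L,
      hw)
    shapes[[nd$id]] <- c(hw_out, nd$out_channels)
  }
  shapes
}

#' Multiply-accumulate (MAC) cost of a graph
#'
#' A hardware-independent proxy for inference time: full convolutions
#' cost output positions x kernel^2 x in x out, depthwise convolutions
#' output positions x kernel^2 x channels, pointwise convolutions output
#' positions x in x out; pooling, rescaling, concatenation, addition,
#' normalization and activations are free.
#'
#' @inheritParams propagate_shapes
#' @return Total MAC count as a double.
#' @export
count_macs <- function(graph, input_shape) {
  shapes <- propagate_shapes(graph, input_shape)
  total <- 0
  for (nd in graph$nodes) {
    out <- shapes[[nd$id]]
    pos <- as.numeric(out[1]) * out[2]
    total <- total + switch(nd$kind,
      conv2d = pos * nd$kernel^2 * nd$in_channels[1] * nd$out_channels,
      depthwise_conv2d = pos * nd$kernel^2 * nd$out_channels,
      pointwise_conv2d = pos * nd$in_channels[1] * nd$out_channels,
      0)
  }
  total
}

#' Serialize a graph to plain text (one node per line)
#'
#' @param graph A `network_graph`.
#' @param path Optional file to write to.
#' @return Invisibly, the character vector of lines.
#' @export
serialize_graph <- function(graph, path = NULL) {
  header <- sprintf("netgraph input_channels=%d", graph$input_channels)
  lines <- vapply(graph$nodes, function(nd) {
    sprintf("%s kind=%s kernel=%s stride=%d mult=%d out=%d inputs=%s",
            nd$id, nd$kind,
            ifelse(is.na(nd$kernel), "-", as.character(nd$kernel)),
            nd$stride, nd$mult, nd$out_channels,
            paste(nd$inputs, collapse = ","))
  }, character(1))
  out <- c(header, unname(lines))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Rebuild a graph from its text serialization
#' @param lines Character vector as produced by [serialize_graph()], or
#'   a file path of length one ending in a readable file.
#' @return A `network_graph`.
#' @export
deserialize_graph <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  stopifnot(grepl("^netgraph ", lines[1]))
  in_ch <- as.integer(sub("^netgraph input_channels=", "", lines[1]))
  g <- graph_new(in_ch)
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
    id <- parts[1]
    kv <- strsplit(parts[-1], "=", fixed = TRUE)
    vals <- stats::setNames(vapply(kv, `[`, character(1), 2),
                            vapply(kv, `[`, character(1), 1))
    g <- graph_add(g, id, vals[["kind"]],
                   inputs = strsplit(vals[["inputs"]], ",")[[1]],
                   out_channels = as.integer(vals[["out"]]),
                   kernel = if (vals[["kernel"]] == "-") 3L
                            else as.integer(vals[["kernel"]]),
                   stride = as.integer(vals[["stride"]]),
                   mult = as.integer(vals[["mult"]]))
  }
  g
}

#' Tabular view of a graph's nodes
#' @param x A `network_graph`.
#' @param row.names,optional,... Passed over (base generic signature).
#' @return A data.frame with one row per node.
#' @export
as.data.frame.network_graph <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    id = vapply(x$nodes, `[[`, character(1), "id"),
    kind = vapply(x$nodes, `[[`, character(1), "kind"),
    kernel = vapply(x$nodes, `[[`, integer(1), "kernel"),
    stride = vapply(x$nodes, `[[`, integer(1), "stride"),
    out_channels = vapply(x$nodes, `[[`, integer(1), "out_channels"),
    inputs = vapply(x$nodes, function(n) paste(n$inputs, collapse = ","),
                    character(1)),
    row.names = row.names, stringsAsFactors = FALSE)
}

#' @export
print.network_graph <- function(x, ...) {
  cat(sprintf("<network_graph> %d nodes, %d input channels\n",
              length(x$nodes), x$input_channels))
  if (length(x$nodes)) print(as.data.frame(x))
  invisible(x)
}
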