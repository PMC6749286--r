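## Graph execution engine.
##
## Activations are stored channel-last: a batch of n maps of height h and
## width w with C channels is a (h*w*n) x C matrix whose rows are ordered
## h-fastest, then w, then image index. Spatial operations (same-padded
## convolution taps, pooling, nearest upscaling, stride-2 subsampling)
## then become cached row-index gathers, and every convolution reduces to
## a handful of BLAS matrix products ("shift-and-add"). This keeps both
## the forward and the backward pass fully vectorized in plain R.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  v <- .idx_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = .idx_cache)
  }
  v
}

# Row indices implementing a spatial shift by (dy, dx) with zero padding
# (NA marks out-of-image source positions), expanded over a batch of n.
shift_index <- function(h, w, n, dy, dx) {
  cache_get(sprintf("sh:%d:%d:%d:%d:%d", h, w, n, dy, dx), function() {
    i <- rep.int(seq_len(h), w)
    j <- rep(seq_len(w), each = h)
    si <- i + dy; sj <- j + dx
    idx <- si + (sj - 1L) * h
    idx[si < 1L | si > h | sj < 1L | sj > w] <- NA_integer_
    if (n > 1L) idx <- rep.int(idx, n) +
      rep(seq.int(0L, n - 1L) * (h * w), each = h * w)
    idx
  })
}

# Rows at odd (i, j) positions: output of a same-padded stride-2 conv.
stride2_index <- function(h, w, n) {
  cache_get(sprintf("st:%d:%d:%d", h, w, n), function() {
    base <- as.vector(outer(seq(1L, h, 2L), (seq(1L, w, 2L) - 1L) * h, "+"))
    m <- length(base)
    if (n > 1L) base <- rep.int(base, n) +
      rep(seq.int(0L, n - 1L) * (h * w), each = m)
    base
  })
}

# The four source-row selections of 2x2 average pooling, a,b in {0,1}.
pool_index <- function(h, w, n, a, b) {
  cache_get(sprintf("pl:%d:%d:%d:%d:%d", h, w, n, a, b), function() {
    base <- as.vector(outer(seq(1L, h, 2L) + a,
                            (seq(1L, w, 2L) + b - 1L) * h, "+"))
    m <- length(base)
    if (n > 1L) base <- rep.int(base, n) +
      rep(seq.int(0L, n - 1L) * (h * w), each = m)
    base
  })
}

# Source rows for nearest-neighbour 2x upscaling of an h x w map.
upscale_index <- function(h, w, n) {
  cache_get(sprintf("up:%d:%d:%d", h, w, n), function() {
    H <- 2L * h
    i <- rep.int(ceiling(seq_len(H) / 2), 2L * w)
    j <- rep(ceiling(seq_len(2L * w) / 2), each = H)
    idx <- i + (j - 1L) * h
    if (n > 1L) idx <- rep.int(idx, n) +
      rep(seq.int(0L, n - 1L) * (h * w), each = 4L * h * w)
    idx
  })
}

# Output rows of the upscaled map whose source parity is (a, b); each
# selection is ordered like the source map, so summing the four gathers
# of an output-gradient matrix is the exact upscale adjoint.
upscale_back_index <- function(h, w, n, a, b) {
  cache_get(sprintf("ub:%d:%d:%d:%d:%d", h, w, n, a, b), function() {
    H <- 2L * h
    base <- as.vector(outer(seq(1L + a, H, 2L),
                            (seq(1L + b, 2L * w, 2L) - 1L) * H, "+"))
    m <- length(base)
    if (n > 1L) base <- rep.int(base, n) +
      rep(seq.int(0L, n - 1L) * (4L * h * w), each = m)
    base
  })
}

gather0 <- function(x, idx) {
  out <- matrix(0, length(idx), ncol(x))
  ok <- which(!is.na(idx))
  out[ok, ] <- x[idx[ok], , drop = FALSE]
  out
}

kernel_offsets <- function(k) seq_len(k) - (k + 1L) %/% 2L

conv_forward <- function(x, W, b, h, w, n, stride) {
  k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
  offs <- kernel_offsets(k)
  y <- matrix(0, nrow(x), cout)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    xs <- gather0(x, shift_index(h, w, n, offs[a], offs[bb]))
    y <- y + xs %*% matrix(W[a, bb, , ], cin, cout)
  }
  y <- y + rep(b, each = nrow(y))
  if (stride == 2L) y <- y[stride2_index(h, w, n), , drop = FALSE]
  y
}

depthwise_forward <- function(x, W, b, h, w, n, stride) {
  k <- dim(W)[1]
  offs <- kernel_offsets(k)
  y <- matrix(0, nrow(x), ncol(x))
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    xs <- gather0(x, shift_index(h, w, n, offs[a], offs[bb]))
    y <- y + xs * rep(W[a, bb, ], each = nrow(xs))
  }
  y <- y + rep(b, each = nrow(y))
  if (stride == 2L) y <- y[stride2_index(h, w, n), , drop = FALSE]
  y
}

row_softmax <- function(x) {
  rm <- do.call(pmax, lapply(seq_len(ncol(x)), function(j) x[, j]))
  e <- exp(x - rm)
  e / rowSums(e)
}

## Forward pass ------------------------------------------------------------

#' Execute a weighted graph on a batch of images
#'
#' @param model A `seg_model` from [init_weights()].
#' @param images A single `h x w x channels` array or a list of such
#'   arrays of identical shape, values typically in `[0, 1]`.
#' @param training Logical; `TRUE` uses batch statistics in
#'   `batch_norm` nodes (and updates the model's running statistics),
#'   `FALSE` uses the stored running statistics.
#' @return A list with `out` (activation matrix of the terminal node,
#'   rows ordered h-fastest then w then image), `dims = c(h, w, n)` of
#'   the terminal node, `acts` (all node activations), `model` (with
#'   refreshed batch-norm state), and backward caches.
#' @keywords internal
#' @export
run_graph <- function(model, images, training = FALSE) {
  stopifnot(inherits(model, "seg_model"))
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  h <- dim(images[[1]])[1]; w <- dim(images[[1]])[2]
  cin <- dim(images[[1]])[3]; n <- length(images)
  if (cin != model$graph$input_channels) {
    stop("image channel count does not match model input", call. = FALSE)
  }
  propagate_shapes(model$graph, c(h, w, cin)) # validate divisibility early
  x <- do.call(rbind, lapply(images, function(im) matrix(im, h * w, cin)))

  acts <- list(input = x)
  dims <- list(input = c(h, w, n))
  bncache <- list()
  for (nd in model$graph$nodes) {
    xin <- acts[[nd$inputs[1]]]
    d <- dims[[nd$inputs[1]]]
    wts <- model$weights[[nd$id]]
    out <- switch(nd$kind,
      conv2d = conv_forward(xin, wts$W, wts$b, d[1], d[2], d[3], nd$stride),
      depthwise_conv2d = depthwise_forward(xin, wts$W, wts$b,
                                           d[1], d[2], d[3], nd$stride),
      pointwise_conv2d = xin %*% wts$W + rep(wts$b, each = nrow(xin)),
      avg_pool2x2 = {
        (xin[pool_index(d[1], d[2], d[3], 0L, 0L), , drop = FALSE] +
         xin[pool_index(d[1], d[2], d[3], 1L, 0L), , drop = FALSE] +
         xin[pool_index(d[1], d[2], d[3], 0L, 1L), , drop = FALSE] +
         xin[pool_index(d[1], d[2], d[3], 1L, 1L), , drop = FALSE]) / 4
      },
      upscale2x = xin[upscale_index(d[1], d[2], d[3]), , drop = FALSE],
      concat = do.call(cbind, lapply(nd$inputs, function(i) acts[[i]])),
      add = Reduce(`+`, lapply(nd$inputs, function(i) acts[[i]])),
      relu = pmax(xin, 0),
      softmax = row_softmax(xin),
      batch_norm = {
        st <- model$bn[[nd$id]]
        if (training) {
          mu <- colMeans(xin)
          v <- colMeans(xin^2) - mu^2
          mom <- 0.1
          st$mean <- (1 - mom) * st$mean + mom * mu
          st$var <- (1 - mom) * st$var + mom * v
          model$bn[[nd$id]] <- st
        } else {
          mu <- st$mean; v <- st$var
        }
        invstd <- 1 / sqrt(v + 1e-5)
        xhat <- (xin - rep(mu, each = nrow(xin))) *
          rep(invstd, each = nrow(xin))
        bncache[[nd$id]] <- list(xhat = xhat, invstd = invstd)
        xhat * rep(wts$gamma, each = nrow(xin)) +
          rep(wts$beta, each = nrow(xin))
      },
      stop(sprintf("unsupported kind '%s'", nd$kind), call. = FALSE))
    dims[[nd$id]] <- switch(nd$kind,
      conv2d = , depthwise_conv2d = c(d[1:2] %/% nd$stride, d[3]),
      avg_pool2x2 = c(d[1:2] %/% 2L, d[3]),
      upscale2x = c(d[1:2] * 2L, d[3]),
      d)
    acts[[nd$id]] <- out
  }
  last <- graph_output(model$graph)
  list(out = acts[[last]], dims = dims[[last]], acts = acts,
       node_dims = dims, bncache = bncache, model = model,
       training = training)
}

## Backward pass -----------------------------------------------------------

# dlogits is the loss gradient at the *input* of the terminal softmax
# node. Returns per-node parameter gradients (same nesting as weights).
backprop_graph <- function(model, fw, dlogits) {
  graph <- model$graph
  nodes <- graph$nodes
  last <- graph_output(graph)
  stopifnot(nodes[[last]]$kind == "softmax")
  acc <- list()
  acc[[nodes[[last]]$inputs[1]]] <- dlogits
  grads <- list()

  for (nd in rev(nodes[names(nodes) != last])) {
    g <- acc[[nd$id]]
    if (is.null(g)) next
    d_in <- fw$node_dims[[nd$inputs[1]]]
    xin <- fw$acts[[nd$inputs[1]]]
    wts <- model$weights[[nd$id]]
    push <- function(id, val) {
      acc[[id]] <<- if (is.null(acc[[id]])) val else acc[[id]] + val
    }
    switch(nd$kind,
      conv2d = {
        k <- nd$kernel; offs <- kernel_offsets(k)
        cin <- dim(wts$W)[3]; cout <- dim(wts$W)[4]
        if (nd$stride == 2L) {
          gf <- matrix(0, nrow(xin), cout)
          gf[stride2_index(d_in[1], d_in[2], d_in[3]), ] <- g
        } else gf <- g
        dW <- array(0, dim(wts$W))
        dx <- matrix(0, nrow(xin), cin)
        for (a in seq_len(k)) for (bb in seq_len(k)) {
          idx <- shift_index(d_in[1], d_in[2], d_in[3], offs[a], offs[bb])
          xs <- gather0(xin, idx)
          dW[a, bb, , ] <- crossprod(xs, gf)
          back <- gf %*% t(matrix(wts$W[a, bb, , ], cin, cout))
          dx <- dx + gather0(back, shift_index(d_in[1], d_in[2], d_in[3],
                                               -offs[a], -offs[bb]))
        }
        grads[[nd$id]] <- list(W = dW, b = colSums(g))
        push(nd$inputs[1], dx)
      },
      depthwise_conv2d = {
        k <- nd$kernel; offs <- kernel_offsets(k)
        if (nd$stride == 2L) {
          gf <- matrix(0, nrow(xin), ncol(xin))
          gf[stride2_index(d_in[1], d_in[2], d_in[3]), ] <- g
        } else gf <- g
        dW <- array(0, dim(wts$W))
        dx <- matrix(0, nrow(xin), ncol(xin))
        for (a in seq_len(k)) for (bb in seq_len(k)) {
          idx <- shift_index(d_in[1], d_in[2], d_in[3], offs[a], offs[bb])
          xs <- gather0(xin, idx)
          dW[a, bb, ] <- colSums(xs * gf)
          back <- gf * rep(wts$W[a, bb, ], each = nrow(gf))
          dx <- dx + gather0(back, shift_index(d_in[1], d_in[2], d_in[3],
                                               -offs[a], -offs[bb]))
        }
        grads[[nd$id]] <- list(W = dW, b = colSums(g))
        push(nd$inputs[1], dx)
      },
      pointwise_conv2d = {
        grads[[nd$id]] <- list(W = crossprod(xin, g), b = colSums(g))
        push(nd$inputs[1], g %*% t(wts$W))
      },
      avg_pool2x2 = {
        dx <- matrix(0, nrow(xin), ncol(xin))
        for (a in 0:1) for (bb in 0:1) {
          idx <- pool_index(d_in[1], d_in[2], d_in[3], a, bb)
          dx[idx, ] <- dx[idx, ] + g / 4
        }
        push(nd$inputs[1], dx)
      },
      upscale2x = {
        dx <- 0
        for (a in 0:1) for (bb in 0:1) {
          dx <- dx + g[upscale_back_index(d_in[1], d_in[2], d_in[3], a, bb),
                       , drop = FALSE]
        }
        push(nd$inputs[1], dx)
      },
      concat = {
        off <- 0L
        for (i in seq_along(nd$inputs)) {
          ci <- nd$in_channels[i]
          push(nd$inputs[i], g[, off + seq_len(ci), drop = FALSE])
          off <- off + ci
        }
      },
      add = for (i in nd$inputs) push(i, g),
      relu = push(nd$inputs[1], g * (xin > 0)),
      batch_norm = {
        cc <- fw$bncache[[nd$id]]
        m <- nrow(g)
        dgamma <- colSums(g * cc$xhat)
        dbeta <- colSums(g)
        scale <- wts$gamma * cc$invstd
        dx <- if (isTRUE(fw$training)) {
          # batch statistics depend on the input
          (g - rep(dbeta / m, each = m) -
             cc$xhat * rep(dgamma / m, each = m)) * rep(scale, each = m)
        } else {
          g * rep(scale, each = m) # running statistics are constants
        }
        grads[[nd$id]] <- list(gamma = dgamma, beta = dbeta)
        push(nd$inputs[1], dx)
      },
      softmax = stop("interior softmax is not supported", call. = FALSE))
  }
  grads
}

## Losses ------------------------------------------------------------------

# Per-pixel cross-entropy against hard integer labels with 255 = ignore.
# Returns loss and the gradient at the softmax input.
loss_hard <- function(probs, targets) {
  keep <- which(targets != 255L)
  if (length(keep) == 0L) {
    stop("no non-ignore pixels in batch", call. = FALSE)
  }
  rows <- cbind(keep, targets[keep] + 1L)
  loss <- -sum(log(pmax(probs[rows], 1e-12))) / length(keep)
  dlog <- probs
  dlog[rows] <- dlog[rows] - 1
  dlog[targets == 255L, ] <- 0
  list(loss = loss, dlogits = dlog / length(keep), n_pixels = length(keep))
}

# Soft-target cross-entropy (teacher distribution T per row).
loss_soft <- function(probs, targets) {
  stopifnot(identical(dim(probs), dim(targets)))
  loss <- -mean(rowSums(targets * log(pmax(probs, 1e-12))))
  list(loss = loss, dlogits = (probs - targets) / nrow(probs))
}

## Adam --------------------------------------------------------------------

adam_new <- function() {
  e <- new.env(parent = emptyenv())
  e$m <- list(); e$v <- list(); e$t <- 0L
  e
}

adam_step <- function(opt, model, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (id in names(grads)) {
    for (p in names(grads[[id]])) {
      key <- paste0(id, "/", p)
      g <- grads[[id]][[p]]
      m <- opt$m[[key]]; v <- opt$v[[key]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      opt$m[[key]] <- m; opt$v[[key]] <- v
      model$weights[[id]][[p]] <- model$weights[[id]][[p]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  model
}
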