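#' Mark class-border pixels as ignore
#'
#' Manual labels are least reliable exactly at class borders, so border
#' pixels are excluded from training: every pixel within Chebyshev
#' distance `radius` of a differently labelled (non-ignore) pixel
#' becomes the ignore value 255. Radius 0 is the identity. The operation
#' is idempotent at fixed radius and the ignore set grows with radius.
#'
#' @param mask Integer matrix over \{0 soil, 1 crop, 2 weed, 255 ignore\}.
#' @param radius Non-negative integer radius in mask pixels.
#' @return The mask with border pixels set to 255.
#' @export
exclude_borders <- function(mask, radius = 1L) {
  stopifnot(is.matrix(mask), radius >= 0)
  check_mask_values(mask)
  if (radius == 0L) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  bad <- matrix(FALSE, H, W)
  for (dy in -radius:radius) for (dx in -radius:radius) {
    if (dy == 0L && dx == 0L) next
    ri <- max(1L, 1L - dy):min(H, H - dy)
    ci <- max(1L, 1L - dx):min(W, W - dx)
    a <- mask[ri, ci, drop = FALSE]
    b <- mask[ri + dy, ci + dx, drop = FALSE]
    bad[ri, ci] <- bad[ri, ci] | (a != 255L & b != 255L & a != b)
  }
  mask[bad] <- 255L
  mask
}

check_mask_values <- function(mask) {
  vals <- unique(as.vector(mask))
  bad <- setdiff(vals, c(0L, 1L, 2L, 255L))
  if (length(bad)) {
    stop(sprintf("mask contains invalid value(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Downsample a full-resolution mask to the output grid
#'
#' Majority vote over each `factor x factor` cell; ignore pixels do not
#' vote, ties (and all-ignore cells) become ignore.
#'
#' @param mask Integer label matrix.
#' @param factor Integer downsampling factor (4 matches the models).
#' @return Integer matrix of size `dim(mask) / factor`.
#' @export
downsample_mask <- function(mask, factor = 4L) {
  stopifnot(is.matrix(mask), all(dim(mask) %% factor == 0))
  check_mask_values(mask)
  H <- nrow(mask); W <- ncol(mask)
  gr <- rep(seq_len(H %/% factor), each = factor)
  gc <- rep(seq_len(W %/% factor), each = factor)
  blocksum <- function(ind) {
    t(rowsum(t(rowsum(ind, gr)), gc))
  }
  cnt <- lapply(0:2, function(cl) blocksum((mask == cl) * 1L))
  top <- pmax(cnt[[1]], cnt[[2]], cnt[[3]])
  nmax <- (cnt[[1]] == top) + (cnt[[2]] == top) + (cnt[[3]] == top)
  out <- (cnt[[2]] == top) * 1L + (cnt[[3]] == top) * 2L
  out[top == 0 | nmax > 1] <- 255L
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Random photometric and flip augmentation of an image/label pair
#'
#' Draws a brightness scale and a saturation scale uniformly from the
#' given ranges (image only) and applies horizontal and vertical flips
#' each with probability 1/2 jointly to image and label. Pixel values
#' are clipped to `[0, 1]`. Uses the current RNG state, so a seeded
#' caller gets a reproducible transform sequence.
#'
#' @param image `h x w x 3` array in `[0, 1]`.
#' @param mask Optional label matrix (hard labels) or `h' x w' x C`
#'   array (soft labels) whose spatial dims are `1:1` or `4:1` with the
#'   image.
#' @param brightness,saturation Scale ranges.
#' @param flip Allow flips?
#' @return List with `image`, `mask` and the drawn `params`.
#' @export
augment_pair <- function(image, mask = NULL, brightness = c(0.7, 1.3),
                         saturation = c(0.7, 1.3), flip = TRUE) {
  stopifnot(length(dim(image)) == 3L)
  if (!is.null(mask)) {
    md <- if (is.matrix(mask)) dim(mask) else dim(mask)[1:2]
    rat <- dim(image)[1:2] / md
    if (!all(rat == rat[1]) || !rat[1] %in% c(1, 4)) {
      stop("image/mask dims must correspond 1:1 or 4:1", call. = FALSE)
    }
  }
  b <- stats::runif(1, brightness[1], brightness[2])
  s <- stats::runif(1, saturation[1], saturation[2])
  fh <- flip && stats::runif(1) < 0.5
  fv <- flip && stats::runif(1) < 0.5
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  img <- image
  for (ch in 1:3) img[, , ch] <- gray + s * (image[, , ch] - gray)
  img <- pmin(pmax(img * b, 0), 1)
  flip_idx <- function(n, rev) if (rev) rev(seq_len(n)) else seq_len(n)
  if (fh || fv) {
    img <- img[flip_idx(dim(img)[1], fv), flip_idx(dim(img)[2], fh), ,
               drop = FALSE]
    if (!is.null(mask)) {
      if (is.matrix(mask)) {
        mask <- mask[flip_idx(nrow(mask), fv), flip_idx(ncol(mask), fh),
                     drop = FALSE]
      } else {
        mask <- mask[flip_idx(dim(mask)[1], fv),
                     flip_idx(dim(mask)[2], fh), , drop = FALSE]
      }
    }
  }
  list(image = img, mask = mask,
       params = list(brightness = b, saturation = s, flip_h = fh,
                     flip_v = fv))
}

#' Training configuration
#'
#' @param epochs,batch_size Positive integers.
#' @param learning_rate Adam step size.
#' @param seed RNG seed for shuffling and augmentation draws.
#' @param augment Apply [augment_pair()] to every training sample?
#' @param border_radius Border-exclusion radius (output-grid pixels)
#'   applied to hard labels before training.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 20L, batch_size = 4L,
                         learning_rate = 1e-3, seed = 1L, augment = TRUE,
                         border_radius = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            border_radius >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 augment = isTRUE(augment),
                 border_radius = as.integer(border_radius)),
            class = "train_config")
}

prepare_hard_masks <- function(dataset, config) {
  lapply(dataset, function(item) {
    m <- item$mask
    stopifnot(is.matrix(m))
    if (all(dim(m) == dim(item$image)[1:2])) m <- downsample_mask(m, 4L)
    item$mask <- exclude_borders(m, config$border_radius)
    item
  })
}

run_training <- function(model, dataset, config, target_fun) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  opt <- adam_new()
  history <- numeric(config$epochs)
  n <- length(dataset)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c(); weights <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n)]
      items <- dataset[ids]
      if (config$augment) {
        items <- lapply(items, function(it) {
          a <- augment_pair(it$image, it$mask)
          list(image = a$image, mask = a$mask)
        })
      }
      fw <- run_graph(model, lapply(items, `[[`, "image"), training = TRUE)
      model$bn <- fw$model$bn
      ls <- target_fun(fw$out, items)
      if (is.null(ls)) next # e.g. a batch with only ignore pixels
      grads <- backprop_graph(model, fw, ls$dlogits)
      model <- adam_step(opt, model, grads, lr = config$learning_rate)
      losses <- c(losses, ls$loss); weights <- c(weights, length(ids))
    }
    history[ep] <- if (length(losses)) {
      sum(losses * weights) / sum(weights)
    } else NA_real_
  }
  attr(model, "history") <- history
  model
}

#' Train a model on hard per-pixel labels
#'
#' Minimizes mean per-pixel cross-entropy over non-ignore pixels with
#' Adam. Masks may be given at the output resolution or at the image
#' resolution (then they are majority-vote downsampled by 4); border
#' exclusion with `config$border_radius` is applied either way.
#'
#' @param model A `seg_model` whose terminal node is a softmax.
#' @param dataset List of `list(image = , mask = )` items.
#' @param config A [train_config()].
#' @return The trained model; `attr(, "history")` holds per-epoch mean
#'   losses.
#' @export
train_hard <- function(model, dataset, config = train_config()) {
  stopifnot(length(dataset) >= 1)
  dataset <- prepare_hard_masks(dataset, config)
  total_live <- sum(vapply(dataset, function(it) sum(it$mask != 255L),
                           numeric(1)))
  if (total_live == 0) {
    stop("dataset has no non-ignore pixels after border exclusion",
         call. = FALSE)
  }
  run_training(model, dataset, config, function(probs, items) {
    targets <- unlist(lapply(items, function(it) as.integer(it$mask)))
    if (all(targets == 255L)) return(NULL)
    loss_hard(probs, targets)
  })
}

#' Train a student on soft teacher labels (knowledge distillation)
#'
#' The student minimizes the per-pixel cross-entropy between the
#' teacher's full output distribution and its own softmax output
#' (temperature 1); this equals the KL divergence up to the constant
#' teacher entropy. Every pixel participates — soft labels carry no
#' ignore value — which is what lets distillation exploit arbitrary
#' unlabeled imagery.
#'
#' @param student A `seg_model`.
#' @param dataset List of `list(image = , soft = )` items, `soft` an
#'   `h/4 x w/4 x n_classes` probability array.
#' @param config A [train_config()]; `border_radius` is unused here.
#' @return The trained student with a loss `history` attribute.
#' @export
train_distill <- function(student, dataset, config = train_config()) {
  stopifnot(length(dataset) >= 1)
  for (it in dataset) {
    s <- it$soft
    stopifnot(length(dim(s)) == 3L)
    rs <- apply(s, c(1, 2), sum)
    if (any(abs(rs - 1) > 1e-4) || any(s < -1e-9)) {
      stop("soft labels are not per-pixel probability distributions",
           call. = FALSE)
    }
  }
  dataset <- lapply(dataset, function(it) {
    list(image = it$image, mask = it$soft)
  })
  run_training(student, dataset, config, function(probs, items) {
    targets <- do.call(rbind, lapply(items, function(it) {
      matrix(it$mask, prod(dim(it$mask)[1:2]), dim(it$mask)[3])
    }))
    loss_soft(probs, targets)
  })
}
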