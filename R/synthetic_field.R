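#' Synthetic field-image configuration
#'
#' The generator emulates top-down row-crop imagery: a brown soil
#' background with low-frequency value noise, a single crop row running
#' vertically down the image center (rosettes of overlapping green
#' ellipses), smaller irregular weed blobs scattered uniformly, and an
#' optional harsh diagonal lighting band with a hard shadow, as produced
#' by direct sun and the camera casing. Crops and weeds differ by size,
#' shape regularity and a small hue offset — color alone is deliberately
#' not sufficient when `hue_offset = 0` ("hard mode"), mirroring why
#' shape and context matter in the field.
#'
#' @param height,width Image size in pixels.
#' @param n_crops Crop plants per image.
#' @param crop_radius_range,weed_radius_range Plant radius intervals
#'   (pixels).
#' @param weed_density Expected weeds per image (Poisson).
#' @param row_jitter Std-dev (pixels) of crop center offsets from the
#'   row line.
#' @param shadow_prob Probability of the lighting band/shadow.
#' @param hue_offset Weed hue shift from the crop green, in degrees
#'   toward yellow-green.
#' @param seed Base RNG seed.
#' @return A `field_config` list.
#' @export
field_config <- function(height = 240L, width = 320L, n_crops = 3L,
                         crop_radius_range = c(20, 40), weed_density = 6,
                         weed_radius_range = c(4, 12), row_jitter = 8,
                         shadow_prob = 0.3, hue_offset = 15, seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_crops >= 0, weed_density >= 0,
            all(crop_radius_range > 0), all(weed_radius_range > 0),
            shadow_prob >= 0, shadow_prob <= 1)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_crops = as.integer(n_crops),
                 crop_radius_range = crop_radius_range,
                 weed_density = weed_density,
                 weed_radius_range = weed_radius_range,
                 row_jitter = row_jitter, shadow_prob = shadow_prob,
                 hue_offset = hue_offset, seed = as.integer(seed)),
            class = "field_config")
}

paint_ellipse <- function(canvas, mask, cy, cx, a, b, theta, rgb, class) {
  H <- nrow(mask); W <- ncol(mask)
  r <- max(a, b)
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (length(ys) == 0L || length(xs) == 0L) {
    return(list(canvas = canvas, mask = mask))
  }
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- dy * cos(theta) + dx * sin(theta)
  v <- -dy * sin(theta) + dx * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(inside)) return(list(canvas = canvas, mask = mask))
  for (ch in 1:3) {
    sub <- canvas[ys, xs, ch]
    sub[inside] <- rgb[ch]
    canvas[ys, xs, ch] <- sub
  }
  msub <- mask[ys, xs]
  msub[inside] <- class
  mask[ys, xs] <- msub
  list(canvas = canvas, mask = mask)
}

plant_color <- function(hue_deg, sd_deg = 4) {
  h <- (hue_deg + stats::rnorm(1, sd = sd_deg)) / 360
  h <- min(max(h, 0.18), 0.45) # stays green-dominant
  grDevices::col2rgb(grDevices::hsv(h, stats::runif(1, 0.5, 0.75),
                                    stats::runif(1, 0.35, 0.6)))[, 1] / 255
}

draw_plant <- function(canvas, mask, cy, cx, radius, n_lobes, hue_deg,
                       class) {
  for (l in seq_len(n_lobes)) {
    th <- 2 * pi * (l - 1) / n_lobes + stats::rnorm(1, sd = 0.25)
    off <- radius * stats::runif(1, 0.3, 0.5)
    ea <- radius * stats::runif(1, 0.5, 0.75)
    eb <- ea * stats::runif(1, 0.35, 0.6)
    res <- paint_ellipse(canvas, mask,
                         cy + off * cos(th), cx + off * sin(th),
                         ea, eb, th, plant_color(hue_deg), class)
    canvas <- res$canvas; mask <- res$mask
  }
  list(canvas = canvas, mask = mask)
}

#' Generate one synthetic field image with exact ground truth
#'
#' Plants are drawn back-to-front (crops, then weeds), later plants
#' occluding earlier ones; the mask assigns every pixel the class of its
#' topmost plant, else soil. Identical config and seed give an identical
#' image/mask pair. In the no-shadow regime every plant pixel is
#' green-dominant, so a trivial color threshold is a meaningful
#' baseline; shadows and the zero hue-offset mode break that.
#'
#' @param config A [field_config()].
#' @param seed Seed for this image (defaults to `config$seed`).
#' @return List with `image` (`h x w x 3` array in `[0, 1]`) and `mask`
#'   (integer matrix, 0 soil / 1 crop / 2 weed; never ignore).
#' @export
generate_field <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "field_config"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  H <- config$height; W <- config$width

  base <- c(0.42, 0.31, 0.19) # dry soil
  coarse <- matrix(stats::runif(ceiling(H / 8) * ceiling(W / 8),
                                -0.08, 0.08),
                   ceiling(H / 8), ceiling(W / 8))
  vf <- 1 + coarse[cbind(rep(ceiling(seq_len(H) / 8), W),
                         rep(ceiling(seq_len(W) / 8), each = H))] +
    stats::runif(H * W, -0.03, 0.03)
  canvas <- array(0, c(H, W, 3))
  for (ch in 1:3) canvas[, , ch] <- base[ch] * matrix(vf, H, W)
  mask <- matrix(0L, H, W)

  if (config$n_crops > 0) {
    for (k in seq_len(config$n_crops)) {
      cy <- (k - 0.5) * H / config$n_crops +
        stats::rnorm(1, sd = config$row_jitter)
      cx <- W / 2 + stats::rnorm(1, sd = config$row_jitter)
      r <- stats::runif(1, config$crop_radius_range[1],
                        config$crop_radius_range[2])
      res <- draw_plant(canvas, mask, cy, cx, r, sample(5:9, 1), 120, 1L)
      canvas <- res$canvas; mask <- res$mask
    }
  }
  n_weeds <- stats::rpois(1, config$weed_density)
  for (k in seq_len(n_weeds)) {
    cy <- stats::runif(1, 1, H); cx <- stats::runif(1, 1, W)
    r <- stats::runif(1, config$weed_radius_range[1],
                      config$weed_radius_range[2])
    res <- draw_plant(canvas, mask, cy, cx, r, sample(2:4, 1),
                      120 - config$hue_offset, 2L)
    canvas <- res$canvas; mask <- res$mask
  }

  if (stats::runif(1) < config$shadow_prob) {
    d <- outer(seq_len(H), seq_len(W), `+`)
    c0 <- stats::runif(1, 0.3, 0.7) * (H + W)
    bw <- 0.2 * min(H, W)
    light <- matrix(1, H, W)
    light[abs(d - c0) <= bw] <- 1.6
    light[d > c0 + bw] <- 0.5
    for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] * light
  }
  canvas <- pmin(pmax(canvas, 0), 1)
  list(image = canvas, mask = mask)
}

#' Write a synthetic dataset to disk
#'
#' Writes `images/img_####.png` (8-bit RGB) and `masks/mask_####.png`
#' (grayscale-coded labels) in the training layout, plus a
#' `manifest.yaml` recording the full configuration and seeds, so the
#' identical dataset can be regenerated from the manifest alone.
#'
#' With `stride` set (pixels, less than the image height), frames are
#' cut from one long field canvas at vertical offsets `0, stride, ...`,
#' emulating the strongly overlapping frames of a camera driving along
#' the crop row.
#'
#' @param config A [field_config()].
#' @param n_images Number of image/mask pairs.
#' @param out_dir Output directory (created if needed).
#' @param stride Optional frame stride for overlapping-frame mode.
#' @return Invisibly, the manifest path.
#' @export
generate_dataset <- function(config, n_images, out_dir, stride = NULL) {
  stopifnot(inherits(config, "field_config"), n_images >= 1)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  pairs <- generate_field_set(config, n_images, stride)
  for (i in seq_len(n_images)) {
    write_image(pairs[[i]]$image,
                file.path(out_dir, "images", sprintf("img_%04d.png", i)))
    write_mask(pairs[[i]]$mask,
               file.path(out_dir, "masks", sprintf("mask_%04d.png", i)))
  }
  manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    generator = "weedseg synthetic_field",
    version = as.character(utils::packageVersion("weedseg")),
    n_images = n_images,
    stride = if (is.null(stride)) NULL else as.integer(stride),
    seeds = if (is.null(stride)) config$seed + seq_len(n_images) else
      config$seed,
    config = unclass(config)), manifest)
  invisible(manifest)
}

# In-memory dataset generation shared by generate_dataset and the desk
# studies; per-image seeds are config$seed + 1..n.
generate_field_set <- function(config, n_images, stride = NULL) {
  if (is.null(stride)) {
    return(lapply(seq_len(n_images), function(i) {
      generate_field(config, seed = config$seed + i)
    }))
  }
  stopifnot(stride >= 1, stride < config$height)
  big <- config
  big$height <- as.integer(config$height + (n_images - 1L) * stride)
  scale <- big$height / config$height
  big$n_crops <- as.integer(ceiling(config$n_crops * scale))
  big$weed_density <- config$weed_density * scale
  canvas <- generate_field(field_config(
    height = big$height, width = big$width, n_crops = big$n_crops,
    crop_radius_range = big$crop_radius_range,
    weed_density = big$weed_density,
    weed_radius_range = big$weed_radius_range,
    row_jitter = big$row_jitter, shadow_prob = big$shadow_prob,
    hue_offset = big$hue_offset, seed = big$seed))
  lapply(seq_len(n_images), function(i) {
    off <- (i - 1L) * stride
    rows <- (off + 1L):(off + config$height)
    list(image = canvas$image[rows, , , drop = FALSE],
         mask = canvas$mask[rows, , drop = FALSE])
  })
}

#' Load a dataset directory written by [generate_dataset()]
#'
#' @param dir Dataset directory containing `images/` and `masks/`.
#' @return List of `list(image = , mask = )` items, sorted by filename.
#' @export
read_dataset <- function(dir) {
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  msks <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  stopifnot(length(imgs) == length(msks), length(imgs) > 0)
  lapply(seq_along(imgs), function(i) {
    list(image = read_image(imgs[i]), mask = read_mask(msks[i]))
  })
}

#' Regenerate a dataset from its manifest
#'
#' @param manifest_path Path to a `manifest.yaml`.
#' @param out_dir Target directory.
#' @return Invisibly, the new manifest path.
#' @export
regenerate_dataset <- function(manifest_path, out_dir) {
  man <- yaml::read_yaml(manifest_path)
  cfg <- do.call(field_config, man$config)
  generate_dataset(cfg, man$n_images, out_dir, stride = man$stride)
}
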