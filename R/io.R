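#' Read and write images and label masks
#'
#' Images are 8-bit RGB PNGs with values mapped to `[0, 1]`. Masks are
#' 8-bit grayscale PNGs whose raw byte values are the class codes
#' \{0 soil, 1 crop, 2 weed, 255 ignore\}; the round trip is lossless.
#' `read_mask()` can also import legacy RGB-coded masks (the green /
#' red / brown display convention) when given an exact color table.
#'
#' @param path PNG file path.
#' @param rgb_map Optional 4 x 3 integer matrix of 0-255 RGB rows named
#'   `soil`, `crop`, `weed`, `ignore` (see [mask_color_table()]);
#'   required to import an RGB-coded mask.
#' @return `read_mask()`: integer label matrix. `read_image()`:
#'   `h x w x 3` array in `[0, 1]`.
#' @export
read_mask <- function(path, rgb_map = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L) {
    if (is.null(rgb_map)) {
      stop("RGB-coded mask: supply `rgb_map` with the exact color table",
           call. = FALSE)
    }
    rgb <- round(px[, , 1:3] * 255)
    key <- rgb[, , 1] * 65536 + rgb[, , 2] * 256 + rgb[, , 3]
    codes <- c(soil = 0L, crop = 1L, weed = 2L, ignore = 255L)
    mkey <- rgb_map[, 1] * 65536 + rgb_map[, 2] * 256 + rgb_map[, 3]
    out <- matrix(NA_integer_, nrow(key), ncol(key))
    for (i in seq_along(mkey)) {
      out[key == mkey[i]] <- codes[[rownames(rgb_map)[i]]]
    }
    if (anyNA(out)) {
      bad <- which(is.na(out), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "mask '%s': unknown color rgb(%d,%d,%d) at row %d, col %d",
        path, rgb[bad[1], bad[2], 1], rgb[bad[1], bad[2], 2],
        rgb[bad[1], bad[2], 3], bad[1], bad[2]), call. = FALSE)
    }
    return(out)
  }
  if (length(dim(px)) == 3L) px <- px[, , 1]
  m <- round(px * 255)
  bad <- which(!(m %in% c(0, 1, 2, 255)))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(m))
    stop(sprintf("mask '%s': invalid value %d at row %d, col %d",
                 path, m[bad[1]], ij[1], ij[2]), call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mask
#' @param mask Integer label matrix over \{0, 1, 2, 255\}.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  check_mask_values(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' @rdname read_mask
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
  px[, , 1:3, drop = FALSE]
}

#' @rdname read_mask
#' @param image `h x w x 3` array in `[0, 1]`.
#' @export
write_image <- function(image, path) {
  stopifnot(length(dim(image)) == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Display color table for mask classes
#'
#' The conventional display colors: crops green, weeds red, soil brown,
#' ignore white. Used for overlays and legacy RGB mask import.
#'
#' @return A 4 x 3 integer matrix with rows soil/crop/weed/ignore.
#' @export
mask_color_table <- function() {
  matrix(c(139L, 90L, 43L,
           0L, 200L, 0L,
           200L, 0L, 0L,
           255L, 255L, 255L),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("soil", "crop", "weed", "ignore"),
                         c("r", "g", "b")))
}

#' Blend a class mask over an image for visual inspection
#'
#' The mask (typically at 1/4 resolution) is nearest-neighbour upscaled
#' to the image size and alpha-blended using [mask_color_table()].
#'
#' @param image `h x w x 3` array.
#' @param mask Label matrix whose dims divide the image dims.
#' @param alpha Blend weight of the class color.
#' @return `h x w x 3` array.
#' @export
overlay_mask <- function(image, mask, alpha = 0.45) {
  H <- dim(image)[1]; W <- dim(image)[2]
  f <- H / nrow(mask)
  stopifnot(f == W / ncol(mask), f == as.integer(f))
  big <- mask[rep(seq_len(nrow(mask)), each = f),
              rep(seq_len(ncol(mask)), each = f), drop = FALSE]
  tab <- mask_color_table() / 255
  out <- image
  classes <- c(soil = 0L, crop = 1L, weed = 2L, ignore = 255L)
  for (nm in names(classes)) {
    sel <- big == classes[[nm]]
    if (!any(sel)) next
    for (ch in 1:3) {
      pl <- out[, , ch]
      pl[sel] <- (1 - alpha) * pl[sel] + alpha * tab[nm, ch]
      out[, , ch] <- pl
    }
  }
  out
}

#' Save / load teacher soft labels
#'
#' Soft labels are per-image `h/4 x w/4 x C` probability arrays, stored
#' as a named list in an RDS archive.
#'
#' @param soft Named list of probability arrays.
#' @param path Archive path.
#' @return `load_soft_labels()` returns the named list.
#' @export
save_soft_labels <- function(soft, path) {
  stopifnot(is.list(soft))
  saveRDS(soft, path)
  invisible(path)
}

#' @rdname save_soft_labels
#' @export
load_soft_labels <- function(path) readRDS(path)
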