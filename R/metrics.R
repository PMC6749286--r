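#' Hard class assignment from a probability map
#'
#' @param probs `h x w x C` probability array.
#' @return Integer matrix of per-pixel argmax class indices (0-based);
#'   ties break toward the lowest class index (soil < crop < weed).
#' @export
argmax_classes <- function(probs) {
  stopifnot(length(dim(probs)) == 3L)
  h <- dim(probs)[1]; w <- dim(probs)[2]
  m <- matrix(probs, h * w, dim(probs)[3])
  matrix(max.col(m, ties.method = "first") - 1L, h, w)
}

as_mask_list <- function(x) {
  if (is.matrix(x)) list(x) else x
}

check_pair_lists <- function(preds, labels) {
  preds <- as_mask_list(preds); labels <- as_mask_list(labels)
  if (length(preds) == 0L || length(preds) != length(labels)) {
    stop("preds and labels must be equal-length non-empty lists",
         call. = FALSE)
  }
  for (i in seq_along(preds)) {
    if (!all(dim(preds[[i]]) == dim(labels[[i]]))) {
      stop(sprintf("pair %d: prediction and label shapes differ", i),
           call. = FALSE)
    }
  }
  list(preds = preds, labels = labels)
}

#' Dice segmentation error
#'
#' 100% minus the mean, over images and the three classes, of the Dice
#' coefficient `2|E n P| / (|E| + |P|)` between the label region E and
#' the predicted region P of each class. Pixels labelled ignore (255)
#' are excluded from every count. A class absent from both the label and
#' the prediction of an image contributes Dice 1 by default ("no error
#' where nothing exists"); `absent = "skip"` drops such image/class
#' pairs from the average instead.
#'
#' @param preds,labels Label matrices or equal-length lists of them
#'   (values 0/1/2, labels may contain 255).
#' @param absent `"one"` or `"skip"`: convention for classes absent from
#'   both label and prediction.
#' @return Error percentage in `[0, 100]`; 0 iff predictions equal
#'   labels on all non-ignore pixels.
#' @export
dice_error <- function(preds, labels, absent = c("one", "skip")) {
  absent <- match.arg(absent)
  pl <- check_pair_lists(preds, labels)
  dices <- c()
  for (i in seq_along(pl$preds)) {
    keep <- pl$labels[[i]] != 255L
    p <- pl$preds[[i]][keep]; e <- pl$labels[[i]][keep]
    for (cl in 0:2) {
      ec <- sum(e == cl); pc <- sum(p == cl)
      if (ec + pc == 0L) {
        if (absent == "one") dices <- c(dices, 1)
      } else {
        dices <- c(dices, 2 * sum(e == cl & p == cl) / (ec + pc))
      }
    }
  }
  if (length(dices) == 0L) {
    stop("no image/class pairs to average", call. = FALSE)
  }
  100 * (1 - mean(dices))
}

pooled_counts <- function(preds, labels) {
  pl <- check_pair_lists(preds, labels)
  e <- unlist(lapply(seq_along(pl$preds), function(i) {
    pl$labels[[i]][pl$labels[[i]] != 255L]
  }))
  p <- unlist(lapply(seq_along(pl$preds), function(i) {
    pl$preds[[i]][pl$labels[[i]] != 255L]
  }))
  list(e = e, p = p)
}

#' Weed detection recall, precision and crop-as-weed misclassification
#'
#' Pooled over all non-ignore pixels of the evaluation set:
#' * recall `r_weed = 100 |E_weed n P_weed| / |E_weed|` — the share of
#'   true weed area that is detected (what the weeding tool can act on);
#' * precision `p_weed = 100 |E_weed n P_weed| / |P_weed|` — the share
#'   of predicted weed area that really is weed (pesticide waste);
#' * `m_crop_as_weed = 100 |E_crop n P_weed| / |E_crop|` — the share of
#'   crop area misclassified as weed (direct yield damage).
#'
#' An empty denominator makes the metric undefined: `NA` is returned
#' with a warning, deliberately distinct from 0.
#'
#' @inheritParams dice_error
#' @return A percentage in `[0, 100]`, or `NA` if undefined.
#' @export
weed_recall <- function(preds, labels) {
  ct <- pooled_counts(preds, labels)
  ratio_metric(sum(ct$e == 2L & ct$p == 2L), sum(ct$e == 2L), "r_weed")
}

#' @rdname weed_recall
#' @export
weed_precision <- function(preds, labels) {
  ct <- pooled_counts(preds, labels)
  ratio_metric(sum(ct$e == 2L & ct$p == 2L), sum(ct$p == 2L), "p_weed")
}

#' @rdname weed_recall
#' @export
crop_as_weed <- function(preds, labels) {
  ct <- pooled_counts(preds, labels)
  ratio_metric(sum(ct$e == 1L & ct$p == 2L), sum(ct$e == 1L),
               "m_crop_as_weed")
}

ratio_metric <- function(num, den, name) {
  if (den == 0L) {
    warning(sprintf("%s is undefined: empty denominator", name),
            call. = FALSE)
    return(NA_real_)
  }
  100 * num / den
}

#' Full segmentation metrics report
#'
#' @inheritParams dice_error
#' @param per_image Also compute a per-image breakdown?
#' @return A `metrics_report` list with `e_dice`, `r_weed`, `p_weed`,
#'   `m_crop_as_weed`, `n_images`, and optionally `per_image`
#'   (a data.frame).
#' @export
segmentation_report <- function(preds, labels, per_image = FALSE,
                                absent = "one") {
  pl <- check_pair_lists(preds, labels)
  rep <- structure(list(
    e_dice = dice_error(pl$preds, pl$labels, absent = absent),
    r_weed = weed_recall(pl$preds, pl$labels),
    p_weed = weed_precision(pl$preds, pl$labels),
    m_crop_as_weed = crop_as_weed(pl$preds, pl$labels),
    n_images = length(pl$preds)), class = "metrics_report")
  if (per_image) {
    rep$per_image <- do.call(rbind, lapply(seq_along(pl$preds), function(i) {
      suppressWarnings(data.frame(
        image = i,
        e_dice = dice_error(pl$preds[[i]], pl$labels[[i]], absent = absent),
        r_weed = weed_recall(pl$preds[[i]], pl$labels[[i]]),
        p_weed = weed_precision(pl$preds[[i]], pl$labels[[i]]),
        m_crop_as_weed = crop_as_weed(pl$preds[[i]], pl$labels[[i]])))
    }))
  }
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Segmentation metrics over %d image(s):\n", x$n_images))
  for (m in c("e_dice", "r_weed", "p_weed", "m_crop_as_weed")) {
    cat(sprintf("  %-15s %s\n", m,
                ifelse(is.na(x[[m]]), "undefined",
                       sprintf("%6.2f%%", x[[m]]))))
  }
  invisible(x)
}
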