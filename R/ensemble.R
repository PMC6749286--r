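#' Ensemble teacher of independently trained models
#'
#' Single stationary models segment mostly correctly but noisily;
#' averaging the per-pixel class-probability predictions of many
#' independently initialized and trained instances suppresses that
#' noise, and the combined map then serves as the soft-label teacher for
#' knowledge distillation. The per-class marginal median is available as
#' an alternative combiner (historically slightly less accurate than the
#' mean); median output is renormalized per pixel since marginal medians
#' need not sum to 1.
#'
#' @param members Non-empty list of `seg_model`s sharing output shape
#'   and class count.
#' @param combine `"mean"` or `"median"`.
#' @return An `ensemble_teacher`.
#' @export
ensemble_teacher <- function(members, combine = c("mean", "median")) {
  combine <- match.arg(combine)
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, logical(1), "seg_model")))
  structure(list(members = members, combine = combine),
            class = "ensemble_teacher")
}

#' Combine per-pixel class-probability maps
#'
#' @param maps Non-empty list of identically shaped `h x w x C`
#'   probability arrays.
#' @param method `"mean"` or `"median"`; the median is the per-class
#'   marginal median, renormalized per pixel.
#' @return An `h x w x C` probability array.
#' @export
combine_probmaps <- function(maps, method = c("mean", "median")) {
  method <- match.arg(method)
  if (!is.list(maps) || length(maps) == 0L) {
    stop("`maps` must be a non-empty list of probability arrays",
         call. = FALSE)
  }
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) {
      stop("probability maps have mismatched shapes", call. = FALSE)
    }
  }
  if (method == "mean") {
    return(Reduce(`+`, maps) / length(maps))
  }
  flat <- vapply(maps, as.vector, numeric(prod(d)))
  med <- array(apply(flat, 1, stats::median), d)
  tot <- apply(med, c(1, 2), sum)
  med / array(rep(tot, d[3]), d)
}

#' Teacher prediction for one image
#'
#' Runs every ensemble member and combines the probability maps.
#'
#' @param teacher An [ensemble_teacher()].
#' @param image `h x w x 3` array.
#' @param spread Also return the per-pixel across-member standard
#'   deviation (averaged over classes) as attribute `"spread"`?
#' @return Combined `h/4 x w/4 x C` probability array.
#' @export
teacher_predict <- function(teacher, image, spread = FALSE) {
  stopifnot(inherits(teacher, "ensemble_teacher"))
  maps <- lapply(teacher$members, predict_probmap, image = image)
  out <- combine_probmaps(maps, teacher$combine)
  if (spread) {
    mu <- combine_probmaps(maps, "mean")
    v <- Reduce(`+`, lapply(maps, function(m) (m - mu)^2)) / length(maps)
    attr(out, "spread") <- apply(sqrt(v), c(1, 2), mean)
  }
  out
}

#' Half-ensemble disagreement
#'
#' Splits the members into first and second half, combines each half
#' with the teacher's method, and reports the Dice error between the two
#' halves' argmax segmentations over a set of images. A stable ensemble
#' size is one where this disagreement is small — the criterion used to
#' settle on the ensemble size in the first place.
#'
#' @param teacher An [ensemble_teacher()] with at least 2 members.
#' @param images List of `h x w x 3` arrays.
#' @return Disagreement as an `e_dice` percentage in `[0, 100]`.
#' @export
ensemble_stability <- function(teacher, images) {
  stopifnot(inherits(teacher, "ensemble_teacher"))
  n <- length(teacher$members)
  if (n < 2L) stop("stability needs at least 2 members", call. = FALSE)
  if (is.array(images)) images <- list(images)
  h1 <- ensemble_teacher(teacher$members[seq_len(n %/% 2L)],
                         teacher$combine)
  h2 <- ensemble_teacher(teacher$members[(n %/% 2L + 1L):n],
                         teacher$combine)
  a <- lapply(images, function(im) argmax_classes(teacher_predict(h1, im)))
  b <- lapply(images, function(im) argmax_classes(teacher_predict(h2, im)))
  dice_error(a, b)
}

#' Write / read a teacher manifest
#'
#' The manifest is a YAML file listing the ordered member checkpoint
#' paths and the combine method, so a teacher is reproducible from its
#' saved members.
#'
#' @param teacher An [ensemble_teacher()].
#' @param member_paths Checkpoint paths, one per member (written by
#'   [save_model()]).
#' @param path Manifest file path.
#' @return `read_teacher_manifest()` returns the reassembled teacher.
#' @export
write_teacher_manifest <- function(teacher, member_paths, path) {
  stopifnot(length(member_paths) == length(teacher$members))
  yaml::write_yaml(list(combine = teacher$combine,
                        members = as.list(member_paths)), path)
  invisible(path)
}

#' @rdname write_teacher_manifest
#' @export
read_teacher_manifest <- function(path) {
  man <- yaml::read_yaml(path)
  ensemble_teacher(lapply(unlist(man$members), load_model), man$combine)
}
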