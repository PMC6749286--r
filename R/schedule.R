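#' Width-multiplier channel schedules
#'
#' Convolutional layer widths are scaled by a single width multiplier
#' `alpha`, trading accuracy for inference cost. Two schedules are
#' supported: the MobileNets-style schedule, which floors the scaled
#' width and clamps it below at one channel, and a multiples-of-8
#' schedule that quantizes every width to a multiple of 8 (never fewer
#' than 8 channels). The quantized schedule exists because ARM-class
#' inference kernels run markedly faster when channel counts are sums of
#' few powers of two; scaling 64 channels to 62 can be *slower* than 64.
#'
#' @param x Positive integer base channel count.
#' @param alpha Positive width multiplier (dimensionless). Values in
#'   `[0.15, 1]` are the practically useful range; any positive value is
#'   accepted.
#' @return A positive integer channel count. `f_mod8()` always returns a
#'   multiple of 8.
#' @examples
#' f_mobilenet(64, 0.5) # 32
#' f_mod8(64, 0.5)      # 32
#' f_mod8(16, 0.3)      # 8 (clamped)
#' @seealso [channel_triple()] for the (A, B, C) width triple used by
#'   the mobile architecture.
#' @export
f_mobilenet <- function(x, alpha) {
  check_schedule_args(x, alpha)
  # the epsilon keeps exact rational boundaries (e.g. 40 * 0.15 = 6)
  # from falling below the floor through binary rounding
  pmax(1L, as.integer(floor(x * alpha + 1e-9)))
}

#' @rdname f_mobilenet
#' @export
f_mod8 <- function(x, alpha) {
  check_schedule_args(x, alpha)
  pmax(8L, 8L * as.integer(floor(x * alpha / 8 + 1e-9)))
}

check_schedule_args <- function(x, alpha) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) ||
      any(x < 1) || any(x != floor(x))) {
    stop("`x` must be a positive integer channel count", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a positive real width multiplier", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validated width-multiplier parameters
#'
#' @param alpha Positive width multiplier.
#' @param variant `"mobilenet"` or `"mod8"`.
#' @return An `alpha_params` list with elements `alpha` and `variant`.
#' @export
alpha_params <- function(alpha, variant = c("mobilenet", "mod8")) {
  variant <- match.arg(variant)
  check_schedule_args(1L, alpha)
  structure(list(alpha = alpha, variant = variant), class = "alpha_params")
}

#' Stage width triple (A, B, C) for the mobile architecture
#'
#' Applies the selected schedule to the base widths 16, 32 and 64, giving
#' the channel counts of the mobile network's three encoder stages.
#'
#' @param params An [alpha_params()] object, or a positive `alpha` when
#'   `variant` is supplied directly.
#' @param variant Schedule variant, used when `params` is a bare number.
#' @return A named integer vector `c(A = , B = , C = )`.
#' @examples
#' channel_triple(alpha_params(1.0, "mod8"))  # 16 32 64
#' channel_triple(0.3, "mod8")                # 8 8 16
#' @export
channel_triple <- function(params, variant = c("mobilenet", "mod8")) {
  if (!inherits(params, "alpha_params")) {
    params <- alpha_params(params, match.arg(variant))
  }
  f <- switch(params$variant, mobilenet = f_mobilenet, mod8 = f_mod8)
  c(A = f(16L, params$alpha), B = f(32L, params$alpha),
    C = f(64L, params$alpha))
}
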