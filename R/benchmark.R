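#' Inference benchmarking harness
#'
#' Times repeated forward passes of a model on a random input and
#' reports wall-clock statistics together with the graph's MAC count.
#' Wall-clock times are hardware-dependent and informational only; the
#' MAC count is the portable cost measure, so accuracy-versus-cost
#' curves over the width multiplier can be drawn machine-independently.
#'
#' @param model A `seg_model`.
#' @param input_shape `c(height, width)` of the benchmark input.
#' @param n_repeats Timed repeats (at least 3).
#' @param warmup Untimed warm-up runs.
#' @param seed Seed for the random input.
#' @return A `benchmark_result` list: `median_s`, `iqr_s`, `times_s`,
#'   `macs`, `input_shape`, `n_repeats`.
#' @export
benchmark_model <- function(model, input_shape, n_repeats = 5L,
                            warmup = 1L, seed = 1L) {
  stopifnot(inherits(model, "seg_model"), n_repeats >= 3L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  img <- array(stats::runif(prod(input_shape) * 3),
               c(input_shape[1], input_shape[2], 3))
  for (i in seq_len(warmup)) run_graph(model, img)
  times <- vapply(seq_len(n_repeats), function(i) {
    unname(system.time(run_graph(model, img))["elapsed"])
  }, numeric(1))
  structure(list(median_s = stats::median(times),
                 iqr_s = unname(diff(stats::quantile(times, c(0.25, 0.75)))),
                 times_s = times,
                 macs = count_macs(model$graph,
                                   c(input_shape[1], input_shape[2], 3)),
                 input_shape = as.integer(input_shape),
                 n_repeats = as.integer(n_repeats)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Inference benchmark (%dx%d input, %d repeats):\n",
              x$input_shape[1], x$input_shape[2], x$n_repeats))
  cat(sprintf("  median %.4f s, IQR %.4f s\n", x$median_s, x$iqr_s))
  cat(sprintf("  MACs   %s\n", format(x$macs, big.mark = ",")))
  invisible(x)
}
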