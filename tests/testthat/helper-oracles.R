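# Independent oracles used across the suite. Each recomputes a quantity
# by direct enumeration, deliberately sharing no code with the package
# implementation it checks.

# Width schedules in exact integer (rational) arithmetic: alpha = p / q.
oracle_mobilenet <- function(x, p, q) {
  as.integer(max(1, (as.integer(x) * p) %/% q))
}
oracle_mod8 <- function(x, p, q) {
  as.integer(max(8, 8 * ((as.integer(x) * p) %/% (8 * q))))
}

# MAC count by literal enumeration: walk every output position and every
# multiply a direct convolution implementation would perform (same
# padding multiplies the padded zeros too, as an im2col kernel does).
oracle_macs <- function(graph, input_shape) {
  shapes <- propagate_shapes(graph, input_shape)
  total <- 0
  for (nd in graph$nodes) {
    if (!nd$kind %in% c("conv2d", "depthwise_conv2d", "pointwise_conv2d")) {
      next
    }
    out <- shapes[[nd$id]]
    k <- nd$kernel
    for (i in seq_len(out[1])) for (j in seq_len(out[2])) {
      total <- total + switch(nd$kind,
        conv2d = k * k * nd$in_channels[1] * nd$out_channels,
        depthwise_conv2d = k * k * nd$out_channels,
        pointwise_conv2d = nd$in_channels[1] * nd$out_channels)
    }
  }
  total
}

# The four segmentation metrics by per-pixel loops and explicit set
# counting over a list of prediction/label matrix pairs.
oracle_metrics <- function(preds, labels) {
  dices <- c()
  n_ew <- n_pw <- n_epw <- n_ec <- n_ecpw <- 0
  for (i in seq_along(preds)) {
    P <- preds[[i]]; E <- labels[[i]]
    for (cl in 0:2) {
      e_set <- p_set <- inter <- 0
      for (r in seq_len(nrow(E))) for (cc in seq_len(ncol(E))) {
        if (E[r, cc] == 255) next
        ee <- E[r, cc] == cl
        pp <- P[r, cc] == cl
        e_set <- e_set + ee
        p_set <- p_set + pp
        inter <- inter + (ee && pp)
      }
      dices <- c(dices,
                 if (e_set + p_set == 0) 1 else 2 * inter / (e_set + p_set))
    }
    for (r in seq_len(nrow(E))) for (cc in seq_len(ncol(E))) {
      if (E[r, cc] == 255) next
      ew <- E[r, cc] == 2; pw <- P[r, cc] == 2; ec <- E[r, cc] == 1
      n_ew <- n_ew + ew
      n_pw <- n_pw + pw
      n_epw <- n_epw + (ew && pw)
      n_ec <- n_ec + ec
      n_ecpw <- n_ecpw + (ec && pw)
    }
  }
  list(e_dice = 100 * (1 - mean(dices)),
       r_weed = if (n_ew == 0) NA_real_ else 100 * n_epw / n_ew,
       p_weed = if (n_pw == 0) NA_real_ else 100 * n_epw / n_pw,
       m_crop_as_weed = if (n_ec == 0) NA_real_ else 100 * n_ecpw / n_ec)
}

random_mask <- function(h, w, with_ignore = TRUE) {
  vals <- if (with_ignore) c(0L, 1L, 2L, 255L) else c(0L, 1L, 2L)
  matrix(sample(vals, h * w, replace = TRUE,
                prob = if (with_ignore) c(0.45, 0.25, 0.2, 0.1)
                       else c(0.5, 0.3, 0.2)),
         h, w)
}

random_image <- function(h, w, ch = 3L) {
  array(stats::runif(h * w * ch), c(h, w, ch))
}
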