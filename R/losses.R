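# ---------------------------------------------------------------------------
# Edge ground truth, edge-pixel weight map, and the hybrid loss:
#   L_total = L_edge + L_seg^w,   L_seg^w = (wBCE + wIoU) / 2
# where the per-pixel weights W = alpha + beta * |Gs - meanpool(Gs)| emphasize
# pixels near the mask boundary.  All loss terms accept plain arrays or
# autograd nodes for the prediction, so the same code scores and trains.
# ---------------------------------------------------------------------------

#' Loss configuration
#'
#' @param alpha Baseline pixel weight (default 1).
#' @param beta Edge emphasis (default 5); edge pixels get weights up to
#'   `alpha + beta`.
#' @param pool_size Odd side length of the mean-pool neighbourhood used to
#'   localize edges (pixels; default 31).
#' @param epsilon Clipping bound for log arguments.
#' @param deep_supervision Also supervise the upsampled coarse map fg.
#' @export
loss_config <- function(alpha = 1, beta = 5, pool_size = 31L,
                        epsilon = 1e-7, deep_supervision = TRUE) {
  pool_size <- as.integer(pool_size)
  if (pool_size < 1L || pool_size %% 2L == 0L) {
    stop("pool_size must be odd and >= 1")
  }
  structure(list(alpha = alpha, beta = beta, pool_size = pool_size,
                 epsilon = epsilon, deep_supervision = deep_supervision),
            class = "loss_config")
}

check_binary <- function(m, what = "mask") {
  u <- unique(as.vector(ag_value(m)))
  if (!all(u %in% c(0, 1))) stop(what, " must be binary (0/1)")
  invisible(TRUE)
}

# mean over a k x k window, same-size output, symmetric (reflective) padding
boxmean2d <- function(m, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(m)
  n1 <- nrow(m); n2 <- ncol(m)
  pi <- c(rev(seq_len(min(r, n1))), seq_len(n1), n1 + 1L - seq_len(min(r, n1)))
  pj <- c(rev(seq_len(min(r, n2))), seq_len(n2), n2 + 1L - seq_len(min(r, n2)))
  # if r exceeds the image size, recycle reflections until wide enough
  while (length(pi) < n1 + 2L * r) pi <- c(rev(pi[seq_len(r)]), pi, rev(pi)[seq_len(r)])
  while (length(pj) < n2 + 2L * r) pj <- c(rev(pj[seq_len(r)]), pj, rev(pj)[seq_len(r)])
  pi <- pi[seq_len(n1 + 2L * r)]; pj <- pj[seq_len(n2 + 2L * r)]
  P <- m[pi, pj, drop = FALSE]
  # zero-augmented 2-D integral image
  A <- matrix(0, nrow(P) + 1L, ncol(P) + 1L)
  A[-1, -1] <- apply(apply(P, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(n1); j <- seq_len(n2)
  (A[i + k, j + k, drop = FALSE] - A[i, j + k, drop = FALSE] -
     A[i + k, j, drop = FALSE] + A[i, j, drop = FALSE]) / (k * k)
}

map_mask_slices <- function(m, fn) {
  d <- dim(m)
  if (is.null(d) || length(d) == 2L) return(fn(as.matrix(m)))
  out <- m
  if (length(d) == 3L) {
    for (k in seq_len(d[3])) out[, , k] <- fn(m[, , k])
  } else {
    for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
      out[, , c, n] <- fn(m[, , c, n])
    }
  }
  out
}

#' Edge ground truth from a binary mask
#'
#' Morphological gradient: 3x3 dilation minus 3x3 erosion (replicate padding
#' at the borders), so the edge band straddles the mask boundary.
#'
#' @param gs Binary mask (matrix or (H, W, C, N) array).
#' @return Binary edge map of the same shape.
#' @export
edge_gt <- function(gs) {
  check_binary(gs, "ground-truth mask")
  morph31 <- function(m, op) {
    n1 <- nrow(m); n2 <- ncol(m)
    pi <- c(1L, seq_len(n1), n1); pj <- c(1L, seq_len(n2), n2)
    P <- m[pi, pj, drop = FALSE]
    acc <- NULL
    for (di in 0:2) for (dj in 0:2) {
      S <- P[di + seq_len(n1), dj + seq_len(n2), drop = FALSE]
      acc <- if (is.null(acc)) S else op(acc, S)
    }
    acc
  }
  map_mask_slices(gs, function(m) morph31(m, pmax) - morph31(m, pmin))
}

#' Edge-pixel weight map
#'
#' `W = alpha + beta * |Gs - meanpool(Gs, pool_size)|`: pixels whose local
#' neighbourhood is mixed (i.e. near the boundary) receive weights up to
#' `alpha + beta`, constant regions exactly `alpha`.
#'
#' @param gs Binary ground-truth mask.
#' @param cfg A [loss_config()].
#' @return Object of class `edge_weight_map`: the weight array `W` with
#'   attributes `alpha`, `beta`, `pool_size`.
#' @export
edge_weights <- function(gs, cfg = loss_config()) {
  check_binary(gs)
  if (cfg$pool_size %% 2L == 0L) stop("pool_size must be odd")
  W <- map_mask_slices(ag_value(gs), function(m) {
    cfg$alpha + cfg$beta * abs(m - boxmean2d(m, cfg$pool_size))
  })
  structure(W, alpha = cfg$alpha, beta = cfg$beta,
            pool_size = cfg$pool_size, class = "edge_weight_map")
}

as_weight_array <- function(w) {
  if (inherits(w, "edge_weight_map")) unclass(w) else w
}

check_same_shape <- function(a, b) {
  da <- dim(ag_value(a)); db <- dim(ag_value(b))
  if (!identical(as.integer(da), as.integer(db))) {
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  }
}

#' Weighted binary cross-entropy
#'
#' `-sum(W * (Gs log Ps + (1 - Gs) log(1 - Ps))) / sum(W)`; with `W == 1`
#' this is the ordinary mean BCE.
#'
#' @param ps Predicted probabilities in `[0, 1]` (array or autograd node).
#' @param gs Binary ground truth.
#' @param w Weight map ([edge_weights()] or plain array); default all ones.
#' @param epsilon Log clipping bound.
#' @return Scalar loss (autograd node if `ps` is taped).
#' @export
weighted_bce <- function(ps, gs, w = NULL, epsilon = 1e-7) {
  gs <- ag_value(gs)
  if (is.null(w)) w <- array(1, dim(gs))
  w <- as_weight_array(w)
  check_same_shape(ps, gs); check_same_shape(ps, w)
  psc <- ag_clamp(ps, epsilon, 1 - epsilon)
  pos <- t_mul(w * gs, ag_log(psc))
  neg <- t_mul(w * (1 - gs), ag_log(ag_affine(psc, -1, 1)))
  ag_affine(ag_sum(t_add(pos, neg)), -1 / sum(w), 0)
}

#' Weighted IoU loss
#'
#' `1 - sum(W Ps Gs) / sum(W (Ps + Gs - Ps Gs))`: a global, structure-level
#' complement to the pixel-level BCE.
#'
#' @inheritParams weighted_bce
#' @export
weighted_iou <- function(ps, gs, w = NULL) {
  gs <- ag_value(gs)
  if (is.null(w)) w <- array(1, dim(gs))
  w <- as_weight_array(w)
  check_same_shape(ps, gs); check_same_shape(ps, w)
  inter <- ag_sum(t_mul(w * gs, ps))
  psgs <- t_mul(ps, gs)
  # union = sum(w * (ps + gs - ps*gs))
  un <- ag_sum(t_add(t_mul(w, t_add(ps, gs)), ag_affine(t_mul(w, psgs), -1, 0)))
  if (ag_value(un) == 0) {
    warning("weighted_iou: empty ground truth and empty prediction; loss 0")
    return(0)
  }
  ag_affine(ag_div(inter, un), -1, 1)
}

#' Joint segmentation loss (wBCE + wIoU) / 2
#' @inheritParams weighted_bce
#' @export
seg_loss <- function(ps, gs, w = NULL, epsilon = 1e-7) {
  b <- weighted_bce(ps, gs, w, epsilon)
  i <- weighted_iou(ps, gs, w)
  ag_affine(t_add(b, i), 0.5, 0)
}

#' Edge supervision loss
#'
#' Mean binary cross-entropy between the predicted edge probability map and
#' the edge ground truth.
#'
#' @param edge_prob Predicted edge probabilities.
#' @param ge Binary edge map ([edge_gt()]).
#' @param epsilon Log clipping bound.
#' @export
edge_loss <- function(edge_prob, ge, epsilon = 1e-7) {
  weighted_bce(edge_prob, ge, w = NULL, epsilon = epsilon)
}

#' Total hybrid loss
#'
#' `L_total = L_edge + L_seg^w`, with the edge ground truth computed at the
#' edge head's resolution (nearest-neighbour downsampled mask, re-thinned by
#' the morphological gradient).  With `cfg$deep_supervision` an additional
#' segmentation term supervises the sigmoid of the coarse map fg upsampled to
#' input resolution.
#'
#' @param pred Prediction set from [model_forward()].
#' @param gs Binary ground-truth mask at input resolution, shaped like the
#'   model input.
#' @param cfg A [loss_config()].
#' @return List with `total` and the per-term breakdown (`edge`, `seg`,
#'   `deep`); entries are autograd nodes when `pred` is taped.
#' @export
total_loss <- function(pred, gs, cfg = loss_config()) {
  gs <- as_t4(ag_value(gs))
  check_binary(gs)
  W <- edge_weights(gs, cfg)
  de <- t_shape(pred$edge_prob)
  gs_e <- nn_resize(gs, de[1], de[2])
  ge <- edge_gt(gs_e)
  le <- edge_loss(pred$edge_prob, ge, cfg$epsilon)
  ls <- seg_loss(pred$seg_prob, gs, W, cfg$epsilon)
  total <- t_add(le, ls)
  ld <- NULL
  if (isTRUE(cfg$deep_supervision)) {
    dg <- dim(gs)
    fg_up <- if (is_ag(pred$coarse)) {
      ag_resize_bilinear(pred$coarse, dg[1], dg[2])
    } else t_resize_like(pred$coarse, gs)
    ld <- seg_loss(t_sigmoid(fg_up), gs, W, cfg$epsilon)
    total <- t_add(total, ld)
  }
  list(total = total, edge = le, seg = ls, deep = ld)
}
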