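#' @useDynLib noduleseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode autograd over dense arrays.
#
# Values are plain R arrays with dim (H, W, C, N).  Every op accepts either a
# plain array or an `ag` node; a node is only created when some input carries
# requires_grad, so the same code path serves inference (plain arrays) and
# training (taped graph).  This is deliberately small: just the ops the
# segmentation network needs.
# ---------------------------------------------------------------------------

.ag_state <- new.env(parent = emptyenv())
.ag_state$counter <- 0L

#' Create an autograd node
#'
#' Wraps a numeric array as a node on the reverse-mode tape. Leaf nodes with
#' `requires_grad = TRUE` accumulate gradients in `$grad` after
#' [ag_backward()].
#'
#' @param value Numeric array (any shape) or scalar.
#' @param parents List of parent `ag` nodes.
#' @param backfn Function taking the output gradient and returning a list of
#'   gradients, one per parent.
#' @param requires_grad Force gradient tracking for a leaf.
#' @return An object of class `ag`.
#' @keywords internal
ag <- function(value, parents = list(), backfn = NULL, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backfn <- backfn
  e$requires_grad <- requires_grad ||
    any(vapply(parents, function(p) p$requires_grad, logical(1)))
  e$grad <- NULL
  .ag_state$counter <- .ag_state$counter + 1L
  e$id <- .ag_state$counter
  class(e) <- "ag"
  e
}

is_ag <- function(x) inherits(x, "ag")

#' @keywords internal
ag_value <- function(x) if (is_ag(x)) x$value else x

needs_grad <- function(x) is_ag(x) && x$requires_grad

# Build a node only if some input requires grad; `ins` is the full input list
# (arrays or nodes) and `back(g)` must return one gradient per input (NULL ok).
mk_node <- function(value, ins, back) {
  live <- vapply(ins, needs_grad, logical(1))
  if (!any(live)) return(value)
  ag(value, parents = ins[live], backfn = function(g) back(g)[live])
}

#' Run backpropagation from a scalar (or seeded) node
#'
#' @param root Output `ag` node.
#' @param seed Gradient seeded at the root; defaults to 1 for scalars.
#' @keywords internal
ag_backward <- function(root, seed = NULL) {
  stopifnot(is_ag(root))
  if (is.null(seed)) {
    seed <- if (is.null(dim(root$value))) 1 else array(1, dim(root$value))
  }
  # iterative post-order topological sort over grad-requiring nodes
  topo <- vector("list", 64L); nt <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, expanded = FALSE))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- fr$node
    key <- as.character(n$id)
    if (fr$expanded) {
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- n
      next
    }
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    stack[[length(stack) + 1L]] <- list(node = n, expanded = TRUE)
    for (p in n$parents) {
      if (p$requires_grad && is.null(seen[[as.character(p$id)]])) {
        stack[[length(stack) + 1L]] <- list(node = p, expanded = FALSE)
      }
    }
  }
  root$grad <- seed
  for (i in seq_len(nt)) {
    n <- topo[[nt - i + 1L]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      g <- gs[[k]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# --- elementwise ops --------------------------------------------------------

ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk_node(va + vb, list(a, b), function(g) list(g, g))
}

ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk_node(va * vb, list(a, b), function(g) list(g * vb, g * va))
}

# a*x + b with scalar a, b
ag_affine <- function(x, a = 1, b = 0) {
  vx <- ag_value(x)
  mk_node(a * vx + b, list(x), function(g) list(a * g))
}

ag_relu <- function(x) {
  vx <- ag_value(x)
  v <- vx * (vx > 0)
  mk_node(v, list(x), function(g) list(g * (vx > 0)))
}

ag_sigmoid <- function(x) {
  vx <- ag_value(x)
  y <- 1 / (1 + exp(-vx))
  mk_node(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_log <- function(x) {
  vx <- ag_value(x)
  mk_node(log(vx), list(x), function(g) list(g / vx))
}

ag_clamp <- function(x, lo, hi) {
  vx <- ag_value(x)
  v <- pmin(pmax(vx, lo), hi)
  mk_node(v, list(x), function(g) list(g * (vx > lo & vx < hi)))
}

ag_sum <- function(x) {
  vx <- ag_value(x)
  d <- dim(vx)
  mk_node(sum(vx), list(x), function(g) list(array(g, d)))
}

ag_mean <- function(x) {
  vx <- ag_value(x)
  d <- dim(vx); n <- length(vx)
  mk_node(mean(vx), list(x), function(g) list(array(g / n, d)))
}

# scalar / scalar
ag_div <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  mk_node(va / vb, list(a, b),
          function(g) list(g / vb, -g * va / (vb * vb)))
}

# --- shape ops --------------------------------------------------------------

as_t4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a bare vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 2-4 dimensional array")
  x
}

# concatenate along the channel axis (dim 3)
ag_concat <- function(xs) {
  vals <- lapply(xs, ag_value)
  d1 <- dim(vals[[1]])
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (v in vals) {
    out[, , off + seq_len(dim(v)[3]), ] <- v
    off <- off + dim(v)[3]
  }
  mk_node(out, xs, function(g) {
    off <- 0L
    lapply(cs, function(ck) {
      gg <- g[, , off + seq_len(ck), , drop = FALSE]
      off <<- off + ck
      gg
    })
  })
}

# channel slice (dim 3)
ag_slice_c <- function(x, idx) {
  vx <- ag_value(x)
  v <- vx[, , idx, , drop = FALSE]
  d <- dim(vx)
  mk_node(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , idx, ] <- g
    list(gx)
  })
}

# --- conv2d -----------------------------------------------------------------

#' 2-D convolution with autograd support
#'
#' @param x Input array (H, W, Cin, N) or `ag` node.
#' @param w Weights (kh, kw, Cin, Cout).
#' @param b Bias vector of length Cout, or NULL.
#' @param stride,dilation Integer scalars or length-2 (h, w) vectors.
#' @param pad "same" (stride-1 odd kernels) or explicit c(ph, pw).
#' @keywords internal
ag_conv2d <- function(x, w, b = NULL, stride = 1, pad = "same", dilation = 1) {
  vx <- ag_value(x); vw <- ag_value(w)
  vb <- if (is.null(b)) numeric(0) else ag_value(b)
  s <- rep_len(as.integer(stride), 2L)
  d <- rep_len(as.integer(dilation), 2L)
  kd <- dim(vw)
  if (identical(pad, "same")) {
    p <- as.integer(c(((kd[1] - 1L) * d[1]) %/% 2L, ((kd[2] - 1L) * d[2]) %/% 2L))
  } else {
    p <- rep_len(as.integer(pad), 2L)
  }
  has_b <- length(vb) > 0
  v <- conv2d_fwd_cpp(vx, vw, as.numeric(vb), has_b, s[1], s[2], p[1], p[2], d[1], d[2])
  ins <- list(x, w, b)
  mk_node(v, ins, function(g) {
    bw <- conv2d_bwd_cpp(vx, vw, g, has_b, s[1], s[2], p[1], p[2], d[1], d[2])
    list(bw$gx, bw$gw, if (has_b) bw$gb else NULL)
  })
}

# --- batch normalization (batch statistics) ---------------------------------

ag_bn <- function(x, gamma, beta, eps = 1e-5) {
  vx <- ag_value(x); vg <- ag_value(gamma); vb <- ag_value(beta)
  d <- dim(vx)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  xm <- aperm(vx, c(1, 2, 4, 3))
  dim(xm) <- c(n, C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  ym <- sweep(sweep(xhat, 2, vg, `*`), 2, vb, `+`)
  y <- ym
  dim(y) <- c(d[1], d[2], d[4], C)
  y <- aperm(y, c(1, 2, 4, 3))
  mk_node(y, list(x, gamma, beta), function(g) {
    gm <- aperm(g, c(1, 2, 4, 3))
    dim(gm) <- c(n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, vg, `*`)
    # dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    t1 <- n * dxhat
    t2 <- matrix(colSums(dxhat), n, C, byrow = TRUE)
    t3 <- xhat * matrix(colSums(dxhat * xhat), n, C, byrow = TRUE)
    dxm <- sweep(t1 - t2 - t3, 2, istd / n, `*`)
    dx <- dxm
    dim(dx) <- c(d[1], d[2], d[4], C)
    dx <- aperm(dx, c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

# --- bilinear resize --------------------------------------------------------

.interp_cache <- new.env(parent = emptyenv())

#' Bilinear interpolation matrix
#'
#' Row-stochastic matrix mapping a length-`n_in` signal to length `n_out`
#' (half-pixel centers, clamped at the borders); constants are preserved
#' exactly.
#' @keywords internal
interp_matrix <- function(n_out, n_in) {
  key <- paste0(n_out, "_", n_in)
  hit <- .interp_cache[[key]]
  if (!is.null(hit)) return(hit)
  L <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    L[, 1] <- 1
  } else {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    src <- pmin(pmax(src, 0), n_in - 1)
    lo <- floor(src)
    frac <- src - lo
    hi <- pmin(lo + 1, n_in - 1)
    for (i in seq_len(n_out)) {
      L[i, lo[i] + 1] <- L[i, lo[i] + 1] + (1 - frac[i])
      L[i, hi[i] + 1] <- L[i, hi[i] + 1] + frac[i]
    }
  }
  .interp_cache[[key]] <- L
  L
}

bilinear_apply <- function(v, oh, ow) {
  d <- dim(v)
  if (d[1] == oh && d[2] == ow) return(v)
  Lh <- interp_matrix(oh, d[1])
  Lw <- interp_matrix(ow, d[2])
  out <- array(0, c(oh, ow, d[3], d[4]))
  for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
    out[, , c, n] <- Lh %*% v[, , c, n] %*% t(Lw)
  }
  out
}

ag_resize_bilinear <- function(x, oh, ow) {
  vx <- ag_value(x)
  d <- dim(vx)
  if (d[1] == oh && d[2] == ow) return(x)
  v <- bilinear_apply(vx, oh, ow)
  mk_node(v, list(x), function(g) {
    Lh <- interp_matrix(oh, d[1])
    Lw <- interp_matrix(ow, d[2])
    gx <- array(0, d)
    for (n in seq_len(d[4])) for (c in seq_len(d[3])) {
      gx[, , c, n] <- t(Lh) %*% g[, , c, n] %*% Lw
    }
    list(gx)
  })
}

# ---------------------------------------------------------------------------
# Dispatching helpers used by the block algebra: accept ag nodes or plain
# arrays/matrices and stay in whichever world the inputs live in.
# ---------------------------------------------------------------------------

t_add <- function(a, b) if (is_ag(a) || is_ag(b)) ag_add(a, b) else a + b
t_mul <- function(a, b) if (is_ag(a) || is_ag(b)) ag_mul(a, b) else a * b
t_sigmoid <- function(x) if (is_ag(x)) ag_sigmoid(x) else 1 / (1 + exp(-x))

t_shape <- function(x) dim(ag_value(x))

# resize x (bilinear) to the spatial size of `like`
t_resize_like <- function(x, like) {
  dl <- t_shape(like)
  dx <- t_shape(x)
  if (identical(dx[1:2], dl[1:2])) return(x)
  if (is_ag(x)) return(ag_resize_bilinear(x, dl[1], dl[2]))
  if (length(dx) == 2L) {
    return(bilinear_apply(as_t4(x), dl[1], dl[2])[, , 1, 1])
  }
  out <- bilinear_apply(as_t4(x), dl[1], dl[2])
  if (length(dx) == 3L) dim(out) <- dim(out)[1:3]
  out
}

t_concat <- function(xs) {
  if (any(vapply(xs, is_ag, logical(1)))) return(ag_concat(lapply(xs, function(x) if (is_ag(x)) x else as_t4(x))))
  xs4 <- lapply(xs, as_t4)
  ag_concat(xs4)  # no grad inputs -> returns a plain array
}

#' Nearest-neighbour resize (masks)
#'
#' @param m Matrix or (H, W, C, N) array with values to resample.
#' @param oh,ow Output size.
#' @return Same type as the input; binary inputs stay binary.
#' @export
nn_resize <- function(m, oh, ow) {
  d <- dim(m)
  h <- d[1]; w <- d[2]
  if (h == oh && w == ow) return(m)
  ri <- pmin(h, pmax(1L, ceiling((seq_len(oh) - 0.5) * h / oh)))
  ci <- pmin(w, pmax(1L, ceiling((seq_len(ow) - 0.5) * w / ow)))
  if (length(d) == 2L) return(m[ri, ci, drop = FALSE])
  if (length(d) == 3L) return(m[ri, ci, , drop = FALSE])
  m[ri, ci, , , drop = FALSE]
}

#' Bilinear resize for images
#'
#' Constant-preserving bilinear resampling with half-pixel alignment; the same
#' interpolation the network decoder uses.
#'
#' @param m Matrix or (H, W, C, N) array.
#' @param oh,ow Output size.
#' @export
bilinear_resize <- function(m, oh, ow) {
  d <- dim(m)
  if (length(d) == 2L) {
    x <- m; dim(x) <- c(d, 1L, 1L)
    y <- bilinear_apply(x, oh, ow)
    return(y[, , 1, 1])
  }
  y <- bilinear_apply(as_t4(m), oh, ow)
  if (length(d) == 3L) dim(y) <- dim(y)[1:3]
  y
}
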