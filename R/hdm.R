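# ---------------------------------------------------------------------------
# High-level decoder: MF blocks refine f3/f4/f5 into 32-channel
# multi-receptive-field features; the MD block aggregates them across scales
# into a coarse nodule logit map fg at f3 resolution.
#
# Every convolution in the block algebra is an injectable "operator slot", so
# the cross-scale arithmetic can be verified with identity or averaging stubs
# independently of learned weights.  The trained model supplies slots that
# close over its registered conv layers.
# ---------------------------------------------------------------------------

#' Operator chain of one multi-receptive-field branch
#'
#' Branch 0 is a single 1x1 convolution.  Branch m >= 1 is 1x1, then a
#' factorized 1x(2m+1) and (2m+1)x1 pair, then a 3x3 convolution with
#' dilation rate 2m+1; all stride 1.
#'
#' @param m Branch index 0..3.
#' @return Data frame with per-operator kernel extents `kh`, `kw` and
#'   dilation `d`.
#' @export
mf_branch_ops <- function(m) {
  stopifnot(length(m) == 1L, m %in% 0:3)
  m <- as.integer(m)
  if (m == 0L) {
    return(data.frame(kh = 1L, kw = 1L, d = 1L))
  }
  k <- 2L * m + 1L
  data.frame(kh = c(1L, 1L, k, 3L),
             kw = c(1L, k, 1L, 3L),
             d  = c(1L, 1L, 1L, k))
}

#' Effective receptive field of an MF-block branch
#'
#' Composes kernel extents along the stride-1 operator chain: the receptive
#' field grows by (k - 1) * d per layer, per axis.  The factorized
#' 1x(2m+1)/(2m+1)x1 pair therefore contributes a (2m+1)-pixel extent on each
#' axis, and the dilated 3x3 adds 2*(2m+1).
#'
#' @param m Branch index 0..3.
#' @return Receptive field in input pixels (square; one integer).
#' @export
branch_receptive_field <- function(m) {
  if (length(m) != 1L || is.na(m) || !(m %in% 0:3)) {
    stop("branch index m must be a single integer in 0..3")
  }
  ops <- mf_branch_ops(m)
  rf_h <- 1L + sum((ops$kh - 1L) * ops$d)
  rf_w <- 1L + sum((ops$kw - 1L) * ops$d)
  stopifnot(rf_h == rf_w)
  as.integer(rf_h)
}

#' Identity operator slots for an MF block
#' @export
mf_identity_slots <- function() {
  list(branches = replicate(4, identity, simplify = FALSE),
       reduce = identity, shortcut = identity)
}

#' Multi-receptive-field (MF) block
#'
#' Four cascade branches (see [mf_branch_ops()]) are applied to the input,
#' concatenated along channels, reduced by a 3x3 convolution slot, and an
#' elementwise shortcut of the 1x1-projected input is added.  Output spatial
#' size equals input spatial size.
#'
#' @param f Input feature map, (H, W, C, N) array or autograd node.
#' @param slots List with `branches` (4 functions), `reduce`, `shortcut`.
#' @return 32-channel refined feature (same spatial size) under the model's
#'   slots; under identity slots, the plain branch algebra.
#' @export
mf_block <- function(f, slots = mf_identity_slots()) {
  outs <- lapply(slots$branches, function(fn) fn(f))
  y <- slots$reduce(t_concat(outs))
  t_add(y, slots$shortcut(f))
}

# slots closing over the registered conv layers of a built model
mf_slots <- function(net, level, p) {
  pre <- paste0("mf", level)
  branches <- lapply(0:3, function(m) {
    force(m)
    if (m == 0L) {
      function(x) conv_apply(net, paste0(pre, ".b0"), x, p)
    } else {
      function(x) {
        y <- conv_apply(net, paste0(pre, ".b", m, ".p"), x, p)
        y <- conv_apply(net, paste0(pre, ".b", m, ".h"), y, p)
        y <- conv_apply(net, paste0(pre, ".b", m, ".v"), y, p)
        conv_apply(net, paste0(pre, ".b", m, ".d"), y, p)
      }
    }
  })
  list(branches = branches,
       reduce = function(x) conv_apply(net, paste0(pre, ".red"), x, p),
       shortcut = function(x) conv_apply(net, paste0(pre, ".sc"), x, p))
}

register_mf <- function(net, level, cin, cdec = 32L) {
  pre <- paste0("mf", level)
  add_conv(net, paste0(pre, ".b0"), cin, cdec, 1L, 1L, act = "relu")
  for (m in 1:3) {
    k <- 2L * m + 1L
    add_conv(net, paste0(pre, ".b", m, ".p"), cin, cdec, 1L, 1L, act = "relu")
    add_conv(net, paste0(pre, ".b", m, ".h"), cdec, cdec, 1L, k, act = "relu")
    add_conv(net, paste0(pre, ".b", m, ".v"), cdec, cdec, k, 1L, act = "relu")
    add_conv(net, paste0(pre, ".b", m, ".d"), cdec, cdec, 3L, 3L,
             dilation = k, act = "relu")
  }
  add_conv(net, paste0(pre, ".red"), 4L * cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, paste0(pre, ".sc"), cin, cdec, 1L, 1L)
  invisible(net)
}

#' Identity operator slots for the MD block
#' @export
md_identity_slots <- function() {
  list(conv54 = identity, conv43 = identity, conv53 = identity,
       head = identity)
}

#' Cross-scale multi-scale decoder (MD) block
#'
#' Progressive weighted aggregation of the refined high-level features: the
#' deepest level passes through unchanged (f5'' = f5'); each shallower level
#' is multiplied elementwise by convolved, bilinearly upsampled copies of all
#' deeper levels; the three aligned maps are concatenated at f3 resolution
#' and sent through the head slot (in the model: two 3x3 convolutions and one
#' 1x1 convolution producing a 1-channel coarse logit map).
#'
#' @param f3p,f4p,f5p Refined features for levels 3, 4, 5.
#' @param slots List with `conv54`, `conv43`, `conv53`, `head`.
#' @return The coarse map at f3's spatial size.
#' @export
md_block <- function(f3p, f4p, f5p, slots = md_identity_slots()) {
  f5pp <- f5p
  f4pp <- t_mul(f4p, slots$conv54(t_resize_like(f5p, f4p)))
  f3pp <- t_mul(t_mul(f3p, slots$conv43(t_resize_like(f4p, f3p))),
                slots$conv53(t_resize_like(f5p, f3p)))
  agg <- t_concat(list(f3pp,
                       t_resize_like(f4pp, f3p),
                       t_resize_like(f5pp, f3p)))
  slots$head(agg)
}

md_slots <- function(net, p) {
  list(conv54 = function(x) conv_apply(net, "md.c54", x, p),
       conv43 = function(x) conv_apply(net, "md.c43", x, p),
       conv53 = function(x) conv_apply(net, "md.c53", x, p),
       head = function(x) {
         y <- conv_apply(net, "md.h1", x, p)
         y <- conv_apply(net, "md.h2", y, p)
         conv_apply(net, "md.out", y, p)
       })
}

register_md <- function(net, cdec = 32L) {
  # 3x3 conv with BN on each upsampled factor (no activation: the
  # multiplicative gating stays signed)
  add_conv(net, "md.c54", cdec, cdec, 3L, 3L, bn = TRUE)
  add_conv(net, "md.c43", cdec, cdec, 3L, 3L, bn = TRUE)
  add_conv(net, "md.c53", cdec, cdec, 3L, 3L, bn = TRUE)
  add_conv(net, "md.h1", 3L * cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "md.h2", cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "md.out", cdec, 1L, 1L, 1L)
  invisible(net)
}
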