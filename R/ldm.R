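# ---------------------------------------------------------------------------
# Low-level decoder: fuse the two shallow, edge-rich features f1 and f2 into
# an initial edge feature map fE at f2's resolution (stride 4); f1 is pooled
# down rather than f2 upsampled, keeping the edge path cheap.
# ---------------------------------------------------------------------------

#' Identity operator slots for the LE block
#' @export
le_identity_slots <- function() {
  list(proj1 = identity, proj2 = identity, post = identity)
}

#' Low-level edge (LE) block
#'
#' Computes `fE = f2 + f1 * f2` elementwise after aligning f1 to f2: the
#' addition keeps features the two levels do not share, the multiplication
#' amplifies the edges they agree on.  In the model, `proj1`/`proj2` are 1x1
#' convolutions onto the 32-channel decoder width (f1 additionally bilinearly
#' downsampled to f2's grid) and `post` is a 3x3 convolution.
#'
#' @param f1,f2 Low-level feature maps from one forward pass.
#' @param slots List with `proj1`, `proj2`, `post`.
#' @return Edge feature map at f2's spatial size.
#' @export
le_block <- function(f1, f2, slots = le_identity_slots()) {
  p1 <- t_resize_like(slots$proj1(f1), f2)
  p2 <- slots$proj2(f2)
  d1 <- t_shape(p1); d2 <- t_shape(p2)
  if (!identical(d1, d2)) {
    stop("le_block: aligned features disagree in shape (",
         paste(d1, collapse = "x"), " vs ", paste(d2, collapse = "x"), ")")
  }
  slots$post(t_add(p2, t_mul(p1, p2)))
}

le_slots <- function(net, p) {
  list(proj1 = function(x) conv_apply(net, "le.p1", x, p),
       proj2 = function(x) conv_apply(net, "le.p2", x, p),
       post = function(x) conv_apply(net, "le.post", x, p))
}

register_le <- function(net, c1, c2, cdec = 32L) {
  add_conv(net, "le.p1", c1, cdec, 1L, 1L, act = "relu")
  add_conv(net, "le.p2", c2, cdec, 1L, 1L, act = "relu")
  add_conv(net, "le.post", cdec, cdec, 3L, 3L, act = "relu")
  invisible(net)
}
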