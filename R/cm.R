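# ---------------------------------------------------------------------------
# Complementary module: location fusion (LF) injects the high-level location
# signal into the edge feature; edge fusion (EF) refines the coarse map with
# the final edge guidance; a 1-channel sigmoid head exposes the edge
# prediction used for edge supervision.
# ---------------------------------------------------------------------------

#' Identity operator slots for location fusion
#' @export
lf_identity_slots <- function() {
  list(convs5 = identity, conv5 = identity, convE = identity)
}

#' Location fusion (LF)
#'
#' `fE^ = convE( fE + Up( f4' * sigmoid(Up(conv5(convs5(f5')) -> f4')) -> fE ) )`;
#' the deepest refined feature gates f4' multiplicatively (through a sigmoid,
#' so the gate lies in (0,1)), the gated location map is bilinearly resized
#' onto the edge grid and added pointwise to the original edge feature.
#'
#' @param f4p,f5p Refined high-level features (levels 4 and 5).
#' @param fE Edge feature from [le_block()].
#' @param slots List with `convs5` (two 3x3 conv+ReLU in the model), `conv5`
#'   (one 3x3 conv+ReLU) and `convE` (3x3 conv+ReLU).
#' @return Final edge guidance `fE^` at fE's spatial size.
#' @export
location_fusion <- function(f4p, f5p, fE, slots = lf_identity_slots()) {
  gate <- t_sigmoid(t_resize_like(slots$conv5(slots$convs5(f5p)), f4p))
  loc <- t_mul(f4p, gate)
  slots$convE(t_add(fE, t_resize_like(loc, fE)))
}

lf_slots <- function(net, p) {
  list(convs5 = function(x) {
         y <- conv_apply(net, "lf.s1", x, p)
         conv_apply(net, "lf.s2", y, p)
       },
       conv5 = function(x) conv_apply(net, "lf.c", x, p),
       convE = function(x) conv_apply(net, "lf.e", x, p))
}

register_lf <- function(net, cdec = 32L) {
  add_conv(net, "lf.s1", cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "lf.s2", cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "lf.c", cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "lf.e", cdec, cdec, 3L, 3L, act = "relu")
  invisible(net)
}

#' Identity operator slots for edge fusion
#' @export
ef_identity_slots <- function() {
  list(convsg = identity, convg = identity, out = NULL)
}

#' Edge fusion (EF)
#'
#' Pre-sigmoid refinement `Ps_raw = fE^ + Up(convg(convsg(fg)) -> fE^)`: the
#' convolved coarse map is bilinearly upsampled onto the edge grid and added
#' to the final edge guidance (logit-space addition).  When an `out` slot is
#' supplied (1x1 convolution in the model) the raw map is projected to one
#' channel, bilinearly upsampled to `out_size`, and squashed by a sigmoid to
#' give the segmentation probability map Ps.
#'
#' @param fg Coarse logit map from [md_block()].
#' @param fE_hat Edge guidance from [location_fusion()].
#' @param slots List with `convsg`, `convg` and optionally `out`.
#' @param out_size Output (H, W) for the probability map; default the raw size.
#' @return List with `raw` (pre-sigmoid fusion at fE^'s resolution) and
#'   `prob` (sigmoid probability map in `[0, 1]` at `out_size`).
#' @export
edge_fusion <- function(fg, fE_hat, slots = ef_identity_slots(), out_size = NULL) {
  raw <- t_add(fE_hat, t_resize_like(slots$convg(slots$convsg(fg)), fE_hat))
  head <- if (is.null(slots$out)) raw else slots$out(raw)
  if (!is.null(out_size)) {
    dh <- t_shape(head)
    if (!identical(as.integer(dh[1:2]), as.integer(out_size))) {
      head <- if (is_ag(head)) ag_resize_bilinear(head, out_size[1], out_size[2])
              else t_resize_like(head, array(0, c(out_size, 1, 1)))
    }
  }
  list(raw = raw, prob = t_sigmoid(head))
}

ef_slots <- function(net, p) {
  list(convsg = function(x) {
         y <- conv_apply(net, "ef.s1", x, p)
         conv_apply(net, "ef.s2", y, p)
       },
       convg = function(x) conv_apply(net, "ef.c", x, p),
       out = function(x) conv_apply(net, "ef.out", x, p))
}

register_ef <- function(net, cdec = 32L) {
  add_conv(net, "ef.s1", 1L, cdec, 3L, 3L, act = "relu")
  add_conv(net, "ef.s2", cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "ef.c", cdec, cdec, 3L, 3L, act = "relu")
  add_conv(net, "ef.out", cdec, 1L, 1L, 1L)
  invisible(net)
}

#' Edge probability head
#'
#' Projects the edge guidance to one channel (1x1 convolution slot in the
#' model) and applies a sigmoid; this is the map compared against the edge
#' ground truth during training.
#'
#' @param fE_hat Edge guidance feature.
#' @param head Projection slot (default identity).
#' @return Edge probability map in (0, 1) at fE^'s resolution.
#' @export
edge_probability <- function(fE_hat, head = identity) {
  t_sigmoid(head(fE_hat))
}
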