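# ---------------------------------------------------------------------------
# Full segmentation model: backbone + MF/MD high-level decoder + LE edge
# decoder + complementary fusion.  The forward pass returns the prediction
# set (segmentation probability, edge probability, coarse logits, edge
# guidance) and runs identically on plain arrays (inference) or on the
# autograd tape (training).
# ---------------------------------------------------------------------------

#' Model configuration
#'
#' @param width Backbone channel width multiplier.
#' @param blocks Bottleneck counts of the four backbone stages.
#' @param seed Integer seed used for weight initialization.
#' @param pretrained_path Optional RDS of externally supplied backbone weights.
#' @param dec_channels Decoder channel width (refined features and edge
#'   features; 32 throughout).
#' @return A list of class `model_config`.
#' @export
model_config <- function(width = 1, blocks = c(3L, 4L, 6L, 3L), seed = 1L,
                         pretrained_path = NULL, dec_channels = 32L) {
  structure(list(width = width, blocks = as.integer(blocks),
                 seed = as.integer(seed), pretrained_path = pretrained_path,
                 dec_channels = as.integer(dec_channels)),
            class = "model_config")
}

#' Build the full segmentation network
#'
#' @param config A [model_config()].
#' @return A `nodule_net` with backbone and decoder parameters; weight
#'   initialization is deterministic in `config$seed`.
#' @export
build_model <- function(config = model_config()) {
  bb <- backbone_config(width = config$width, blocks = config$blocks,
                        pretrained_path = config$pretrained_path)
  net <- withr::with_seed(config$seed, {
    net <- new_net(list(backbone = bb, model = config))
    ch <- register_backbone(net, bb)
    net$meta <- ch
    cd <- config$dec_channels
    register_mf(net, 3L, ch$outs[2], cd)
    register_mf(net, 4L, ch$outs[3], cd)
    register_mf(net, 5L, ch$outs[4], cd)
    register_md(net, cd)
    register_le(net, ch$stem, ch$outs[1], cd)
    register_lf(net, cd)
    register_ef(net, cd)
    add_conv(net, "eh", cd, 1L, 1L, 1L)
    net
  })
  maybe_load_pretrained(net, config$pretrained_path)
  net
}

#' Forward pass of the full model
#'
#' @param net A model from [build_model()].
#' @param x Input image(s): (H, W) matrix or (H, W, 1, N) array, values in
#'   `[0, 1]`; any size >= 32 works (feature levels follow ceil(H / stride),
#'   and the decoder realigns scales by bilinear resampling), which is what
#'   lets multi-scale jitter feed 72- and 120-pixel inputs to the same
#'   network.
#' @param p Parameter list; pass `wrap_params(net)` for a taped (trainable)
#'   pass, default the plain arrays.
#' @return List with `seg_prob` (1-channel, input resolution, in `[0, 1]`),
#'   `edge_prob` (stride-4 resolution), `coarse` (fg logits at stride 8),
#'   `edge_guidance` (fE^) and `seg_raw` (pre-sigmoid fusion).
#' @export
model_forward <- function(net, x, p = net$par) {
  x <- as_t4(x)
  d <- dim(x)
  if (min(d[1:2]) < 32L) {
    stop("input size ", d[1], "x", d[2], " is too small (need >= 32)")
  }
  fs <- backbone_forward(net, x, p)
  f3p <- mf_block(fs$f3, mf_slots(net, 3L, p))
  f4p <- mf_block(fs$f4, mf_slots(net, 4L, p))
  f5p <- mf_block(fs$f5, mf_slots(net, 5L, p))
  fg <- md_block(f3p, f4p, f5p, md_slots(net, p))
  fE <- le_block(fs$f1, fs$f2, le_slots(net, p))
  fE_hat <- location_fusion(f4p, f5p, fE, lf_slots(net, p))
  ef <- edge_fusion(fg, fE_hat, ef_slots(net, p), out_size = d[1:2])
  list(seg_prob = ef$prob,
       edge_prob = edge_probability(fE_hat,
                                    head = function(z) conv_apply(net, "eh", z, p)),
       coarse = fg,
       edge_guidance = fE_hat,
       seg_raw = ef$raw)
}
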