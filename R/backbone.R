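# ---------------------------------------------------------------------------
# Five-level feature extractor, Res2Net50-style with a modified stem: the
# usual 7x7 stem convolution is replaced by three consecutive 3x3 conv+ReLU
# layers (the first with stride 2) and there is no global pooling or
# classification head.  Taps f1..f5 sit at strides (2, 4, 8, 16, 32).
# ---------------------------------------------------------------------------

#' Backbone configuration
#'
#' @param width Channel width multiplier; 1 gives the full-size network,
#'   small values (e.g. 1/16) give a desk-scale network for tests.
#' @param blocks Integer vector of bottleneck counts for the four residual
#'   stages (default the 50-layer layout 3, 4, 6, 3).
#' @param pretrained_path Optional path to an RDS file of named parameter
#'   arrays (externally supplied weights). If given and the file is missing,
#'   building the backbone is an error - never a silent random init.
#' @return A list of class `backbone_config`.
#' @export
backbone_config <- function(width = 1, blocks = c(3L, 4L, 6L, 3L),
                            pretrained_path = NULL) {
  stopifnot(width > 0, length(blocks) == 4L, all(blocks >= 1L))
  structure(list(width = width, blocks = as.integer(blocks),
                 pretrained_path = pretrained_path),
            class = "backbone_config")
}

backbone_channels <- function(width) {
  outs <- pmax(16L, as.integer(round(width * c(256, 512, 1024, 2048) / 16) * 16))
  list(stem = max(8L, as.integer(round(64 * width))), outs = outs, mids = outs %/% 4L)
}

reg_bottleneck <- function(net, name, cin, cout, mid, stride) {
  add_conv(net, paste0(name, ".r"), cin, mid, 1L, 1L, bn = TRUE, act = "relu")
  if (stride == 1L) {
    gc <- mid %/% 4L
    for (j in 2:4) {
      add_conv(net, paste0(name, ".g", j), gc, gc, 3L, 3L, bn = TRUE, act = "relu")
    }
  } else {
    add_conv(net, paste0(name, ".m"), mid, mid, 3L, 3L, stride = 2L,
             bn = TRUE, act = "relu")
  }
  add_conv(net, paste0(name, ".e"), mid, cout, 1L, 1L, bn = TRUE)
  if (cin != cout || stride != 1L) {
    add_conv(net, paste0(name, ".s"), cin, cout, 1L, 1L, stride = stride, bn = TRUE)
  }
  net$layers[[paste0(name, ".r")]]$block_stride <- stride
  invisible(net)
}

fwd_bottleneck <- function(net, name, x, p) {
  stride <- net$layers[[paste0(name, ".r")]]$block_stride
  y <- conv_apply(net, paste0(name, ".r"), x, p)
  if (stride == 1L) {
    mid <- net$layers[[paste0(name, ".r")]]$cout
    gc <- mid %/% 4L
    xs <- lapply(0:3, function(j) ag_slice_c(y, j * gc + seq_len(gc)))
    y2 <- conv_apply(net, paste0(name, ".g2"), xs[[2]], p)
    y3 <- conv_apply(net, paste0(name, ".g3"), t_add(xs[[3]], y2), p)
    y4 <- conv_apply(net, paste0(name, ".g4"), t_add(xs[[4]], y3), p)
    y <- ag_concat(list(xs[[1]], y2, y3, y4))
  } else {
    y <- conv_apply(net, paste0(name, ".m"), y, p)
  }
  y <- conv_apply(net, paste0(name, ".e"), y, p)
  sh <- if (!is.null(net$layers[[paste0(name, ".s")]])) {
    conv_apply(net, paste0(name, ".s"), x, p)
  } else x
  ag_relu(t_add(y, sh))
}

register_backbone <- function(net, cfg) {
  ch <- backbone_channels(cfg$width)
  add_conv(net, "stem.c1", 1L, ch$stem, 3L, 3L, stride = 2L, act = "relu")
  add_conv(net, "stem.c2", ch$stem, ch$stem, 3L, 3L, act = "relu")
  add_conv(net, "stem.c3", ch$stem, ch$stem, 3L, 3L, act = "relu")
  cin <- ch$stem
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks[s])) {
      reg_bottleneck(net, sprintf("bb.s%d.b%d", s, b), cin,
                     ch$outs[s], ch$mids[s], if (b == 1L) 2L else 1L)
      cin <- ch$outs[s]
    }
  }
  ch
}

#' Build the five-tap feature extractor
#'
#' @param config A [backbone_config()].
#' @return A `nodule_net` exposing exactly five feature taps via
#'   [extract_features()]; it contains no pooling tail and no fully-connected
#'   head.
#' @export
build_backbone <- function(config = backbone_config()) {
  net <- new_net(list(backbone = config))
  net$meta <- register_backbone(net, config)
  maybe_load_pretrained(net, config$pretrained_path)
  net
}

maybe_load_pretrained <- function(net, path) {
  if (is.null(path)) return(invisible(net))
  if (!file.exists(path)) {
    stop("pretrained weight file not found: ", path,
         " (refusing to fall back to random initialization)")
  }
  w <- readRDS(path)
  for (k in names(w)) {
    if (!is.null(net$par[[k]])) {
      if (!identical(dim(net$par[[k]]), dim(w[[k]])) &&
          length(net$par[[k]]) != length(w[[k]])) {
        stop("pretrained parameter ", k, " has incompatible shape")
      }
      net$par[[k]] <- w[[k]]
    }
  }
  invisible(net)
}

backbone_strides <- function() c(2L, 4L, 8L, 16L, 32L)

backbone_forward <- function(net, x, p = net$par) {
  y <- conv_apply(net, "stem.c1", x, p)
  y <- conv_apply(net, "stem.c2", y, p)
  f1 <- conv_apply(net, "stem.c3", y, p)
  feats <- list(f1 = f1)
  y <- f1
  cfg <- net$config$backbone
  for (s in 1:4) {
    for (b in seq_len(cfg$blocks[s])) {
      y <- fwd_bottleneck(net, sprintf("bb.s%d.b%d", s, b), y, p)
    }
    feats[[paste0("f", s + 1L)]] <- y
  }
  feats
}

#' Extract the feature pyramid for an image
#'
#' @param backbone A network from [build_backbone()] (or a full model from
#'   [build_model()]).
#' @param image Matrix (H, W) in `[0, 1]`, or an (H, W, 1, N) array.
#' @return A list `f1..f5` of (H_i, W_i, C_i, N) arrays with a `strides`
#'   attribute `c(2, 4, 8, 16, 32)`; `H_i = H / stride_i`.
#' @export
extract_features <- function(backbone, image) {
  x <- as_t4(image)
  d <- dim(x)
  s5 <- backbone_strides()[5]
  if (d[1] %% s5 != 0 || d[2] %% s5 != 0) {
    stop("input size ", d[1], "x", d[2], " must be divisible by ", s5)
  }
  fs <- backbone_forward(backbone, x, backbone$par)
  attr(fs, "strides") <- backbone_strides()
  fs
}
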