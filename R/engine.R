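# ---------------------------------------------------------------------------
# Training and inference orchestration: patient-level split, multi-scale
# input jitter, Adam with step decay, early stopping on validation Dice,
# checkpointing and batch prediction.
# ---------------------------------------------------------------------------

#' Training configuration
#'
#' @param lr0 Initial Adam learning rate (default 1e-4).
#' @param lr_decay Multiplicative decay applied every `lr_step` epochs
#'   (default 0.9, i.e. a 10% drop).
#' @param lr_step Epoch interval of the decay (default 30).
#' @param batch_size Mini-batch size (default 4).
#' @param max_epochs Upper limit on epochs (default 60).
#' @param patience Early-stopping patience in epochs without validation-Dice
#'   improvement (default 10).
#' @param scales Multi-scale jitter ratios; must contain 1 (default
#'   0.75, 1, 1.25). One scale is drawn per training step and the whole batch
#'   is resampled (images bilinear, masks nearest-neighbour); evaluation
#'   always runs at scale 1.
#' @param input_size Patch side length fed to the network (default 96).
#' @param seed Seed for split-independent training randomness (shuffling,
#'   scale draws, weight init).
#' @param threshold Binarization threshold for validation Dice.
#' @param width,blocks Backbone size (see [backbone_config()]).
#' @param loss A [loss_config()].
#' @export
train_config <- function(lr0 = 1e-4, lr_decay = 0.9, lr_step = 30L,
                         batch_size = 4L, max_epochs = 60L, patience = 10L,
                         scales = c(0.75, 1, 1.25), input_size = 96L,
                         seed = 1L, threshold = 0.5,
                         width = 1, blocks = c(3L, 4L, 6L, 3L),
                         loss = loss_config()) {
  stopifnot(batch_size >= 1L, 1 %in% scales, all(scales > 0))
  structure(list(lr0 = lr0, lr_decay = lr_decay, lr_step = as.integer(lr_step),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), scales = scales,
                 input_size = as.integer(input_size), seed = as.integer(seed),
                 threshold = threshold, width = width,
                 blocks = as.integer(blocks), loss = loss),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr0 * lr_decay^floor((epoch - 1) / lr_step)`; with the
#' defaults the rate drops by 10% at epochs 31, 61, ...
#'
#' @param config A [train_config()].
#' @param epoch 1-based epoch index.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr0 * config$lr_decay^((epoch - 1L) %/% config$lr_step)
}

#' Patient-level train/test split
#'
#' All crops of one patient land on the same side; with ten patients and the
#' default ratio the split is 9:1.
#'
#' @param manifest Tibble with a `patient_id` column.
#' @param train_frac Fraction of patients assigned to training (default 0.9).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return List with `train` and `test` manifests.
#' @export
split_patients <- function(manifest, train_frac = 0.9, seed = 1L) {
  pids <- sort(unique(manifest$patient_id))
  if (length(pids) < 2L) stop("need at least 2 patients to split")
  n_test <- max(1L, round((1 - train_frac) * length(pids)))
  test_pids <- withr::with_seed(seed, sample(pids, n_test))
  list(train = dplyr::filter(manifest, !.data$patient_id %in% test_pids),
       test = dplyr::filter(manifest, .data$patient_id %in% test_pids))
}

#' Rescale a batch of square patches
#'
#' Images are resampled bilinearly, masks by nearest neighbour (so they stay
#' binary); scale 1 is a bit-identical passthrough.
#'
#' @param images (H, W, 1, N) array.
#' @param masks (H, W, 1, N) binary array.
#' @param scale Positive ratio; output side is `round(H * scale)`.
#' @return List with rescaled `images` and `masks`.
#' @export
multiscale_batch <- function(images, masks, scale) {
  if (scale <= 0) stop("scale must be positive")
  if (scale == 1) return(list(images = images, masks = masks))
  d <- dim(images)
  oh <- as.integer(round(d[1] * scale)); ow <- as.integer(round(d[2] * scale))
  list(images = bilinear_resize(images, oh, ow),
       masks = nn_resize(masks, oh, ow))
}

stack_patches <- function(rows) {
  n <- nrow(rows)
  d <- dim(rows$image[[1]])
  imgs <- array(0, c(d[1], d[2], 1L, n))
  msks <- array(0, c(d[1], d[2], 1L, n))
  for (i in seq_len(n)) {
    imgs[, , 1, i] <- rows$image[[i]]
    msks[, , 1, i] <- rows$mask[[i]]
  }
  list(images = imgs, masks = msks)
}

need_patch_columns <- function(manifest, data_dir) {
  if (!all(c("image", "mask") %in% names(manifest))) {
    if (is.null(data_dir)) {
      stop("manifest has no image/mask list-columns; supply data_dir")
    }
    manifest <- load_patches(manifest, data_dir)
  }
  manifest
}

mean_val_dsc <- function(net, rows, threshold) {
  dscs <- vapply(seq_len(nrow(rows)), function(i) {
    x <- rows$image[[i]]
    pr <- model_forward(net, x)$seg_prob
    sb <- (pr[, , 1, 1] > threshold) * 1
    region_metrics(sb, rows$mask[[i]])$DSC
  }, numeric(1))
  mean(dscs)
}

#' Train the segmentation network
#'
#' Optimizes the total hybrid loss (edge supervision + edge-weighted
#' BCE/IoU, with deep supervision of the coarse map) with Adam, multi-scale
#' input jitter, step learning-rate decay, and early stopping on the
#' validation-set mean Dice.  Reproducible end to end under
#' `config$seed`.
#'
#' @param train_manifest Manifest tibble; either with `image`/`mask`
#'   list-columns or with paths resolvable against `data_dir`.
#' @param val_manifest Optional validation manifest (same format); when
#'   absent, early stopping is disabled and the final weights are kept.
#' @param config A [train_config()].
#' @param data_dir Dataset directory for path-only manifests.
#' @param net Optionally a pre-built model (e.g. to continue training).
#' @param min_iterations Train at least this many optimizer steps even if
#'   `max_epochs` would stop earlier (0 = off).
#' @param verbose Print one line per epoch.
#' @return A `nodule_fit`: list with the trained `net` (best weights),
#'   per-epoch `log` tibble, `best_epoch`, `best_val_dsc`, `config`.
#' @export
fit_model <- function(train_manifest, val_manifest = NULL,
                      config = train_config(), data_dir = NULL, net = NULL,
                      min_iterations = 0L, verbose = FALSE) {
  train_rows <- need_patch_columns(train_manifest, data_dir)
  if (nrow(train_rows) == 0L) stop("empty training manifest")
  val_rows <- if (!is.null(val_manifest)) need_patch_columns(val_manifest, data_dir)
  if (is.null(net)) {
    net <- build_model(model_config(width = config$width, blocks = config$blocks,
                                    seed = config$seed))
  }
  lcfg <- config$loss
  opt <- adam_init(net$par)
  best <- list(dsc = -Inf, par = net$par, epoch = 0L)
  log_rows <- list()
  n <- nrow(train_rows)
  iter <- 0L
  stall <- 0L
  epoch <- 0L
  aborted <- FALSE
  withr::with_seed(config$seed + 1L, {
    repeat {
      epoch <- epoch + 1L
      if (epoch > config$max_epochs &&
          (min_iterations <= 0L || iter >= min_iterations)) break
      lr <- lr_at_epoch(config, epoch)
      t0 <- proc.time()[3]
      ord <- sample.int(n)
      ep_loss <- c(total = 0, edge = 0, seg = 0, deep = 0)
      nb <- 0L
      for (b0 in seq(1L, n, by = config$batch_size)) {
        rows <- train_rows[ord[b0:min(n, b0 + config$batch_size - 1L)], ]
        batch <- stack_patches(rows)
        sc <- config$scales[sample.int(length(config$scales), 1L)]
        batch <- multiscale_batch(batch$images, batch$masks, sc)
        p <- wrap_params(net)
        pred <- model_forward(net, batch$images, p)
        L <- total_loss(pred, batch$masks, lcfg)
        lv <- ag_value(L$total)
        if (!is.finite(lv)) {
          net$par <- best$par
          warning("non-finite loss at iteration ", iter + 1L,
                  "; aborting with last best checkpoint")
          aborted <- TRUE
          break
        }
        ag_backward(L$total)
        upd <- adam_step(net$par, collect_grads(p), opt, lr)
        net$par <- upd$par; opt <- upd$state
        iter <- iter + 1L; nb <- nb + 1L
        ep_loss <- ep_loss + c(lv, ag_value(L$edge), ag_value(L$seg),
                               if (is.null(L$deep)) 0 else ag_value(L$deep))
      }
      if (aborted || nb == 0L) break
      ep_loss <- ep_loss / nb
      vd <- if (!is.null(val_rows)) mean_val_dsc(net, val_rows, config$threshold) else NA_real_
      log_rows[[epoch]] <- tibble::tibble(
        epoch = epoch, lr = lr, iterations = iter,
        loss_total = ep_loss[["total"]], loss_edge = ep_loss[["edge"]],
        loss_seg = ep_loss[["seg"]], loss_deep = ep_loss[["deep"]],
        val_dsc = vd, seconds = proc.time()[3] - t0)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f  val DSC %s",
                        epoch, lr, ep_loss[["total"]],
                        ifelse(is.na(vd), "-", sprintf("%.3f", vd))))
      }
      if (!is.na(vd)) {
        if (vd > best$dsc + 1e-9) {
          best <- list(dsc = vd, par = net$par, epoch = epoch)
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config$patience &&
              (min_iterations <= 0L || iter >= min_iterations)) break
        }
      } else {
        best <- list(dsc = NA_real_, par = net$par, epoch = epoch)
      }
      if (epoch >= config$max_epochs &&
          (min_iterations <= 0L || iter >= min_iterations)) break
    }
  })
  net$par <- best$par
  structure(list(net = net, log = dplyr::bind_rows(log_rows),
                 best_epoch = best$epoch, best_val_dsc = best$dsc,
                 iterations = iter, config = config),
            class = "nodule_fit")
}

#' @export
print.nodule_fit <- function(x, ...) {
  cat("<nodule_fit> ", nrow(x$log), " epochs, ", x$iterations,
      " iterations; best val DSC ",
      ifelse(is.na(x$best_val_dsc), "-", sprintf("%.3f", x$best_val_dsc)),
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Per-epoch training log
#' @param x A `nodule_fit`.
#' @param ... Unused.
#' @export
tidy.nodule_fit <- function(x, ...) x$log

#' One-row summary of a fit
#' @param x A `nodule_fit`.
#' @param ... Unused.
#' @export
glance.nodule_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), iterations = x$iterations,
                 best_epoch = x$best_epoch, best_val_dsc = x$best_val_dsc,
                 final_loss = if (nrow(x$log)) x$log$loss_total[nrow(x$log)] else NA_real_,
                 parameters = n_parameters(x$net))
}

#' Plot the training curves
#' @param object A `nodule_fit`.
#' @param ... Unused.
#' @export
autoplot.nodule_fit <- function(object, ...) {
  long <- object$log |>
    dplyr::select("epoch", "loss_total", "val_dsc") |>
    tidyr::pivot_longer(-"epoch", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_bw()
}

CKPT_VERSION <- "noduleseg-checkpoint-1"

#' Save model weights to an RDS checkpoint
#' @param x A `nodule_fit` or `nodule_net`.
#' @param path Output file.
#' @export
save_checkpoint <- function(x, path) {
  net <- if (inherits(x, "nodule_fit")) x$net else x
  saveRDS(list(version = CKPT_VERSION, par = net$par,
               config = net$config, meta = net$meta,
               layers = net$layers), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path Checkpoint file.
#' @return A `nodule_net` with the stored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$version, CKPT_VERSION)) {
    stop("incompatible checkpoint (version ",
         if (is.null(ck$version)) "missing" else ck$version,
         ", expected ", CKPT_VERSION, ")")
  }
  net <- new_net(ck$config)
  net$layers <- ck$layers
  net$par <- ck$par
  net$meta <- ck$meta
  net
}

#' Predict probability maps and masks for images
#'
#' @param net A trained `nodule_net` (or `nodule_fit`).
#' @param images A matrix, an (H, W, 1, N) array, or a list of matrices.
#' @param threshold Binarization threshold; the mask is 1 where the
#'   probability strictly exceeds it.
#' @return List of per-image lists with `prob` and `mask` matrices.
#' @export
predict_masks <- function(net, images, threshold = 0.5) {
  if (inherits(net, "nodule_fit")) net <- net$net
  if (is.matrix(images)) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4L) {
    images <- lapply(seq_len(dim(images)[4]), function(i) images[, , 1, i])
  }
  lapply(images, function(x) {
    pr <- model_forward(net, x)$seg_prob[, , 1, 1]
    list(prob = pr, mask = (pr > threshold) * 1)
  })
}

#' Predict over a directory of PNG patches
#'
#' Writes `<name>.png` probability maps (8-bit grayscale) and
#' `<name>.png` binary masks under `out_dir/prob` and `out_dir/mask`.
#'
#' @param net Trained network or fit.
#' @param in_dir Directory of input grayscale PNGs.
#' @param out_dir Output directory.
#' @param threshold Binarization threshold.
#' @return Tibble of input/output paths.
#' @export
predict_dir <- function(net, in_dir, out_dir, threshold = 0.5) {
  files <- sort(list.files(in_dir, pattern = "\\.png$"))
  if (!length(files)) stop("no PNG files in ", in_dir)
  for (d in file.path(out_dir, c("prob", "mask"))) {
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
  }
  rows <- lapply(files, function(f) {
    x <- read_gray_png(file.path(in_dir, f))
    out <- predict_masks(net, x, threshold)[[1]]
    write_gray_png(out$prob, file.path(out_dir, "prob", f))
    write_gray_png(out$mask, file.path(out_dir, "mask", f))
    tibble::tibble(input = f,
                   prob_path = file.path("prob", f),
                   mask_path = file.path("mask", f))
  })
  dplyr::bind_rows(rows)
}
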