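# ---------------------------------------------------------------------------
# Evaluation suite: region overlap (DSC, JA, SE, SP), 95th-percentile
# Hausdorff distance, structure measure (Sm), enhanced-alignment measure
# (Em), and mean absolute error, plus dataset-level tidy reporting with
# mean +/- SD and a normal-approximation 95% CI.
# ---------------------------------------------------------------------------

as_mask <- function(m, what = "mask") {
  m <- ag_value(m)
  d <- dim(m)
  if (length(d) == 4L) m <- m[, , 1, 1]
  if (length(d) == 3L) m <- m[, , 1]
  check_binary(m, what)
  m
}

#' Region overlap metrics
#'
#' Dice `2|S&GT| / (|S| + |GT|)`, Jaccard `|S&GT| / |S|GT|union`, sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)` from the pixel confusion counts.
#' Empty-vs-empty masks score DSC = JA = 1; SE is undefined (NA) for an empty
#' ground truth, SP for an all-positive one.
#'
#' @param s Binary segmentation mask.
#' @param gt Binary ground-truth mask of the same shape.
#' @return Named list with `DSC`, `JA`, `SE`, `SP` and the confusion counts.
#' @export
region_metrics <- function(s, gt) {
  s <- as_mask(s, "segmentation"); gt <- as_mask(gt, "ground truth")
  check_same_shape(s, gt)
  tp <- sum(s == 1 & gt == 1)
  fp <- sum(s == 1 & gt == 0)
  fn <- sum(s == 0 & gt == 1)
  tn <- sum(s == 0 & gt == 0)
  dsc <- if (sum(s) + sum(gt) == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  ja <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  se <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  sp <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  list(DSC = dsc, JA = ja, SE = se, SP = sp,
       TP = tp, FP = fp, FN = fn, TN = tn)
}

#' 95th-percentile Hausdorff distance
#'
#' Pools the directed point-to-set Euclidean distances in both directions
#' (each mask pixel to the nearest pixel of the other mask, via an exact
#' distance transform) and takes the 95th percentile; symmetric in its
#' arguments, and equal to the classical Hausdorff distance at percentile
#' 100.
#'
#' @param s,gt Non-empty binary masks of the same shape.
#' @param spacing Isotropic pixel spacing (default 1).
#' @param percentile Percentile of the pooled distances (default 95).
#' @return Distance in pixel units (`NA` with a warning if a mask is empty).
#' @export
hd95 <- function(s, gt, spacing = 1, percentile = 95) {
  s <- as_mask(s, "segmentation"); gt <- as_mask(gt, "ground truth")
  check_same_shape(s, gt)
  if (sum(s) == 0 || sum(gt) == 0) {
    warning("hd95: empty mask; distance undefined")
    return(NA_real_)
  }
  dist_to <- function(target) {
    # distance of every pixel to the nearest pixel of `target`
    EBImage::distmap(1 - target, metric = "euclidean")
  }
  d_sg <- dist_to(gt)[s == 1]
  d_gs <- dist_to(s)[gt == 1]
  spacing * stats::quantile(c(d_sg, d_gs), percentile / 100, names = FALSE)
}

# --- structure measure (object + region aware structural similarity) --------

ssim_block <- function(p, g) {
  n <- length(p)
  if (n <= 1) return(1)
  x <- mean(p); y <- mean(g)
  sx <- sum((p - x)^2) / (n - 1)
  sy <- sum((g - y)^2) / (n - 1)
  sxy <- sum((p - x) * (g - y)) / (n - 1)
  a <- 4 * x * y * sxy
  b <- (x^2 + y^2) * (sx + sy)
  if (a != 0) a / (b + .Machine$double.eps)
  else if (a == 0 && b == 0) 1
  else 0
}

s_object_half <- function(p, g) {
  v <- p[g == 1]
  if (length(v) == 0) return(0)
  x <- mean(v)
  sx <- stats::sd(v); if (is.na(sx)) sx <- 0
  2 * x / (x^2 + 1 + sx + .Machine$double.eps)
}

s_object <- function(p, gt) {
  u <- mean(gt)
  ofg <- s_object_half(p * gt, gt)
  obg <- s_object_half((1 - p) * (1 - gt), 1 - gt)
  u * ofg + (1 - u) * obg
}

s_region <- function(p, gt) {
  rows <- nrow(gt); cols <- ncol(gt)
  if (sum(gt) == 0) {
    X <- round(cols / 2); Y <- round(rows / 2)
  } else {
    idx <- which(gt == 1, arr.ind = TRUE)
    Y <- round(mean(idx[, 1])); X <- round(mean(idx[, 2]))
  }
  Y <- max(1, min(Y, rows)); X <- max(1, min(X, cols))
  area <- rows * cols
  w1 <- (X * Y) / area
  w2 <- ((cols - X) * Y) / area
  w3 <- (X * (rows - Y)) / area
  w4 <- 1 - w1 - w2 - w3
  blocks <- function(m) list(m[seq_len(Y), seq_len(X), drop = FALSE],
                             m[seq_len(Y), X + seq_len(cols - X), drop = FALSE],
                             m[Y + seq_len(rows - Y), seq_len(X), drop = FALSE],
                             m[Y + seq_len(rows - Y), X + seq_len(cols - X), drop = FALSE])
  bp <- blocks(p); bg <- blocks(gt)
  q <- mapply(function(pp, gg) ssim_block(as.vector(pp), as.vector(gg)), bp, bg)
  sum(c(w1, w2, w3, w4) * q)
}

#' Structure measure (Sm)
#'
#' Structural similarity between a (possibly soft) segmentation map and the
#' binary ground truth: the mean of an object-aware term (foreground and
#' background compared through their means and dispersions) and a
#' region-aware term (block-wise SSIM around the ground-truth centroid), with
#' balance coefficient 0.5.  Degenerate ground truths fall back to intensity
#' agreement.
#'
#' @param p Prediction map in `[0, 1]`.
#' @param gt Binary ground truth.
#' @param alpha Balance between object- and region-aware terms (0.5).
#' @return Sm in `[0, 1]`.
#' @export
s_measure <- function(p, gt, alpha = 0.5) {
  gt <- as_mask(gt, "ground truth")
  p <- ag_value(p)
  d <- dim(p)
  if (length(d) == 4L) p <- p[, , 1, 1] else if (length(d) == 3L) p <- p[, , 1]
  check_same_shape(p, gt)
  stopifnot(min(p) >= 0, max(p) <= 1)
  y <- mean(gt)
  if (y == 0) return(max(0, 1 - mean(p)))
  if (y == 1) return(max(0, mean(p)))
  q <- alpha * s_object(p, gt) + (1 - alpha) * s_region(p, gt)
  max(0, min(1, q))
}

#' Enhanced-alignment measure (Em)
#'
#' Mean over pixels of the enhanced alignment term built from the
#' mean-centered binary prediction and ground truth:
#' `phi = 2 dS dGT / (dS^2 + dGT^2)`, enhanced as `((phi + 1)^2) / 4`.
#' Degenerate ground truths reduce to pixel agreement.
#'
#' @param s_bin Binary prediction mask.
#' @param gt Binary ground truth.
#' @return Em in `[0, 1]`.
#' @export
e_measure <- function(s_bin, gt) {
  s <- as_mask(s_bin, "segmentation"); gt <- as_mask(gt, "ground truth")
  check_same_shape(s, gt)
  if (mean(gt) == 0) {
    enh <- 1 - s
  } else if (mean(gt) == 1) {
    enh <- s
  } else {
    ds <- s - mean(s)
    dg <- gt - mean(gt)
    align <- 2 * ds * dg / (ds^2 + dg^2 + .Machine$double.eps)
    enh <- ((align + 1)^2) / 4
  }
  mean(enh)
}

#' Mean absolute error
#'
#' @param p Prediction map in `[0, 1]`.
#' @param gt Ground truth in `[0, 1]`.
#' @export
mae <- function(p, gt) {
  p <- ag_value(p); gt <- ag_value(gt)
  check_same_shape(p, gt)
  mean(abs(p - gt))
}

#' Evaluate a directory of predictions against ground truth
#'
#' Pairs probability-map PNGs with ground-truth mask PNGs by file name,
#' binarizes the predictions at `threshold` for the region metrics, HD95 and
#' Em, and uses the raw probabilities for Sm and MAE.
#'
#' @param pred_dir Directory of prediction PNGs (8-bit grayscale, 0-255
#'   mapped to probability 0-1).
#' @param gt_dir Directory of ground-truth mask PNGs (0/255).
#' @param threshold Binarization threshold (default 0.5).
#' @param out_csv Optional path; per-image rows plus an aggregate mean row
#'   are written as CSV.
#' @return A `metrics_report`: list with `per_image` (tibble, one row per
#'   image) and `summary` (tibble with mean, SD and 95% CI per metric).
#' @export
evaluate_dataset <- function(pred_dir, gt_dir, threshold = 0.5, out_csv = NULL) {
  preds <- sort(list.files(pred_dir, pattern = "\\.png$"))
  gts <- sort(list.files(gt_dir, pattern = "\\.png$"))
  unmatched <- c(setdiff(preds, gts), setdiff(gts, preds))
  if (length(unmatched)) {
    stop("unpaired files between prediction and ground-truth directories: ",
         paste(unmatched, collapse = ", "))
  }
  if (!length(preds)) stop("no PNG pairs found")
  rows <- purrr::map(preds, function(f) {
    p <- read_gray_png(file.path(pred_dir, f))
    g <- read_gray_png(file.path(gt_dir, f))
    g <- (g > 0.5) * 1
    image_metrics(p, g, threshold = threshold, image_id = sub("\\.png$", "", f))
  })
  per_image <- dplyr::bind_rows(rows)
  report <- new_metrics_report(per_image)
  if (!is.null(out_csv)) write_metrics_csv(report, out_csv)
  report
}

#' Metrics for one prediction/ground-truth pair
#'
#' @param p Probability map in `[0, 1]`.
#' @param gt Binary ground truth.
#' @param threshold Binarization threshold for DSC/JA/SE/SP/HD95/Em.
#' @param image_id Identifier carried into the report row.
#' @return One-row tibble.
#' @export
image_metrics <- function(p, gt, threshold = 0.5, image_id = "image") {
  sb <- (ag_value(p) >= threshold) * 1
  rm <- region_metrics(sb, gt)
  hd <- if (sum(sb) == 0 || sum(ag_value(gt)) == 0) {
    warning("empty mask for ", image_id, "; HD95 recorded as NA")
    NA_real_
  } else hd95(sb, gt)
  tibble::tibble(image_id = image_id,
                 DSC = rm$DSC, JA = rm$JA, HD95 = hd,
                 SE = rm$SE, SP = rm$SP,
                 Sm = s_measure(p, gt),
                 Em = e_measure(sb, gt),
                 MAE = mae(p, gt))
}

new_metrics_report <- function(per_image) {
  long <- tidyr::pivot_longer(per_image, -"image_id",
                              names_to = "metric", values_to = "value")
  summary <- long |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::mutate(
      sd = dplyr::if_else(is.na(.data$sd), 0, .data$sd),
      ci_lo = .data$mean - 1.96 * .data$sd / sqrt(pmax(.data$n, 1)),
      ci_hi = .data$mean + 1.96 * .data$sd / sqrt(pmax(.data$n, 1)))
  metric_order <- c("DSC", "JA", "HD95", "SE", "SP", "Sm", "Em", "MAE")
  summary <- summary[match(metric_order, summary$metric), ]
  structure(list(per_image = per_image, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", nrow(x$per_image), " images\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-5s %.4f +/- %.4f (%.4f-%.4f)\n", s$metric[i],
                s$mean[i], s$sd[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}

write_metrics_csv <- function(report, path) {
  per <- report$per_image
  agg <- c(image_id = "aggregate_mean",
           as.list(colMeans(per[, -1], na.rm = TRUE)))
  out <- dplyr::bind_rows(per, tibble::as_tibble(agg))
  readr::write_csv(out, path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-image rows of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) x$per_image

#' One-row aggregate view of a metrics report
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
glance.metrics_report <- function(x, ...) {
  s <- x$summary
  out <- as.list(s$mean)
  names(out) <- s$metric
  tibble::as_tibble(c(out, list(n_images = nrow(x$per_image))))
}

#' Plot the per-image metric distributions
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @export
autoplot.metrics_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image, -"image_id",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~.data$metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-image segmentation metrics") +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
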