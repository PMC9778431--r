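# Independent oracle implementations used to cross-check the package:
# written as direct, loop-style transcriptions of the underlying
# definitions, deliberately sharing no code with the implementation.

ns <- asNamespace("noduleseg")

# exhaustive all-pairs directed point-to-set distances, then percentile
oracle_hd <- function(s, gt, q = 0.95) {
  sp <- which(s == 1, arr.ind = TRUE)
  gp <- which(gt == 1, arr.ind = TRUE)
  cross <- sqrt(outer(sp[, 1], gp[, 1], "-")^2 + outer(sp[, 2], gp[, 2], "-")^2)
  d_sg <- apply(cross, 1, min)
  d_gs <- apply(cross, 2, min)
  stats::quantile(c(d_sg, d_gs), q, names = FALSE)
}

# sliding-window mean with symmetric (mirror) boundary handling
reflect_idx <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

oracle_boxmean <- function(m, k) {
  r <- (k - 1L) %/% 2L
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r) {
      acc <- acc + m[reflect_idx(i + di, nrow(m)), reflect_idx(j + dj, ncol(m))]
    }
    out[i, j] <- acc / (k * k)
  }
  out
}

# 3x3 morphological gradient with replicate borders, by direct loops
oracle_morph_gradient <- function(m) {
  clampi <- function(i, n) min(max(i, 1L), n)
  out <- m * 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    vals <- numeric(0)
    for (di in -1:1) for (dj in -1:1) {
      vals <- c(vals, m[clampi(i + di, nrow(m)), clampi(j + dj, ncol(m))])
    }
    out[i, j] <- max(vals) - min(vals)
  }
  out
}

# --- structure measure reference (object + region aware, balance 0.5) -------

.ref_object_score <- function(pred, region) {
  v <- pred[region == 1]
  if (!length(v)) return(0)
  x <- mean(v)
  sx <- if (length(v) > 1) stats::sd(v) else 0
  2 * x / (x * x + 1 + sx + .Machine$double.eps)
}

.ref_ssim <- function(p, g) {
  N <- length(p)
  if (N <= 1) return(1)
  x <- sum(p) / N; y <- sum(g) / N
  sx2 <- sum((p - x)^2) / (N - 1)
  sy2 <- sum((g - y)^2) / (N - 1)
  sxy <- sum((p - x) * (g - y)) / (N - 1)
  num <- 4 * x * y * sxy
  den <- (x * x + y * y) * (sx2 + sy2)
  if (num != 0) num / (den + .Machine$double.eps)
  else if (den == 0) 1 else 0
}

ref_s_measure <- function(p, gt) {
  y <- mean(gt)
  if (y == 0) return(max(0, 1 - mean(p)))
  if (y == 1) return(max(0, mean(p)))
  # object-aware
  so <- y * .ref_object_score(p * gt, gt) +
    (1 - y) * .ref_object_score((1 - p) * (1 - gt), 1 - gt)
  # region-aware: split at the ground-truth centroid
  idx <- which(gt == 1, arr.ind = TRUE)
  Y <- min(max(round(mean(idx[, 1])), 1), nrow(gt))
  X <- min(max(round(mean(idx[, 2])), 1), ncol(gt))
  qs <- 0; ws <- 0
  for (blk in list(c(1, Y, 1, X), c(1, Y, X + 1, ncol(gt)),
                   c(Y + 1, nrow(gt), 1, X), c(Y + 1, nrow(gt), X + 1, ncol(gt)))) {
    if (blk[2] < blk[1] || blk[4] < blk[3]) next
    pp <- as.vector(p[blk[1]:blk[2], blk[3]:blk[4]])
    gg <- as.vector(gt[blk[1]:blk[2], blk[3]:blk[4]])
    w <- length(pp) / length(gt)
    qs <- qs + w * .ref_ssim(pp, gg)
    ws <- ws + w
  }
  max(0, min(1, 0.5 * so + 0.5 * qs))
}

# --- enhanced-alignment measure reference -----------------------------------

ref_e_measure <- function(s, gt) {
  if (mean(gt) == 0) return(mean(1 - s))
  if (mean(gt) == 1) return(mean(s))
  phi <- s * 0
  ms <- mean(s); mg <- mean(gt)
  for (i in seq_along(s)) {
    a <- s[i] - ms; b <- gt[i] - mg
    align <- 2 * a * b / (a * a + b * b + .Machine$double.eps)
    phi[i] <- ((align + 1)^2) / 4
  }
  mean(phi)
}

# random blob-ish binary mask for fuzzing
random_mask <- function(h, w, p = 0.3) {
  matrix(as.numeric(stats::runif(h * w) < p), h, w)
}
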