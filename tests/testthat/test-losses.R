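test_that("edge ground truth is the 3x3 morphological gradient", {
  # constant masks have no edge
  expect_equal(edge_gt(matrix(0, 6, 6)), matrix(0, 6, 6))
  expect_equal(edge_gt(matrix(1, 6, 6)), matrix(0, 6, 6))

  # single pixel: dilation is the 3x3 block, erosion empty
  m <- matrix(0, 7, 7); m[4, 4] <- 1
  ge <- edge_gt(m)
  expect_equal(sum(ge), 9)
  expect_equal(ge[3:5, 3:5], matrix(1, 3, 3))

  # matches the loop oracle on random masks, and the set-theoretic bounds
  set.seed(10)
  for (i in 1:5) {
    m <- random_mask(9, 11)
    expect_equal(edge_gt(m), oracle_morph_gradient(m))
  }
  expect_error(edge_gt(matrix(0.5, 3, 3)), "binary")
})

test_that("edge weights: alpha + beta * |Gs - local mean|, bounded in [alpha, alpha+beta]", {
  # constant masks weigh alpha everywhere; pool 1 degenerates likewise
  expect_equal(as.vector(edge_weights(matrix(1, 5, 5))), rep(1, 25))
  m <- random_mask(6, 6)
  expect_equal(as.vector(edge_weights(m, loss_config(pool_size = 1))), rep(1, 36))

  # 5x5 with the left two columns set: boundary-column pixel has 3x3 mean 2/3
  m <- matrix(0, 5, 5); m[, 1:2] <- 1
  W <- edge_weights(m, loss_config(pool_size = 3))
  expect_equal(W[3, 2], 1 + 5 * (1 / 3), tolerance = 1e-12)

  # matches the sliding-window oracle
  set.seed(11)
  m <- random_mask(8, 8)
  Wg <- edge_weights(m, loss_config(pool_size = 5))
  expect_equal(unclass(Wg), 1 + 5 * abs(m - oracle_boxmean(m, 5)),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(edge_weights(m, loss_config(pool_size = 4)), "odd")
})

test_that("edge weights stay within [alpha, alpha + beta] over many random masks", {
  set.seed(12)
  for (i in 1:200) {
    m <- random_mask(12, 12, p = stats::runif(1, 0.05, 0.95))
    W <- edge_weights(m)
    expect_gte(min(W), 1 - 1e-12)
    expect_lte(max(W), 6 + 1e-12)
  }
})

test_that("weighted BCE: closed forms and the unweighted reduction identity", {
  # single pixel, Gs=1, Ps=0.5, W=2 -> ln 2
  ps <- const4(0.5, 1, 1); gs <- const4(1, 1, 1); w <- const4(2, 1, 1)
  expect_equal(weighted_bce(ps, gs, w), log(2), tolerance = 1e-12)

  # perfect binary prediction ~ 0
  set.seed(13)
  gs <- ns$as_t4(random_mask(6, 6))
  expect_lt(weighted_bce(gs, gs, NULL), 2e-7)

  # W == 1 equals plain mean BCE
  ps <- array(stats::runif(36, 0.05, 0.95), c(6, 6, 1, 1))
  plain <- -mean(gs * log(ps) + (1 - gs) * log(1 - ps))
  expect_equal(weighted_bce(ps, gs, NULL), plain, tolerance = 1e-6)
  expect_equal(edge_loss(ps, gs), plain, tolerance = 1e-6)
  expect_error(weighted_bce(ps, const4(1, 3, 3), NULL), "mismatch")
})

test_that("weighted IoU: perfect, inverted, and the 4-pixel hand case", {
  set.seed(15)
  gs <- ns$as_t4(random_mask(6, 6))
  expect_equal(weighted_iou(gs, gs, NULL), 0)
  expect_equal(weighted_iou(1 - gs, gs, NULL), 1)

  gs4 <- array(c(1, 1, 0, 0), c(4, 1, 1, 1))
  ps4 <- array(0.5, c(4, 1, 1, 1))
  expect_equal(weighted_iou(ps4, gs4, NULL), 2 / 3, tolerance = 1e-12)

  expect_warning(z <- weighted_iou(const4(0, 3, 3), const4(0, 3, 3), NULL),
                 "empty")
  expect_equal(z, 0)
})

test_that("seg_loss is the mean of its two terms; total_loss decomposes", {
  gs4 <- array(c(1, 1, 0, 0), c(4, 1, 1, 1))
  ps4 <- array(0.5, c(4, 1, 1, 1))
  w1 <- array(1, c(4, 1, 1, 1))
  expect_equal(seg_loss(ps4, gs4, w1), (log(2) + 2 / 3) / 2, tolerance = 1e-9)
  expect_equal(seg_loss(ps4, gs4, w1),
               (weighted_bce(ps4, gs4, w1) + weighted_iou(ps4, gs4, w1)) / 2)

  # edge_prob == 0.5 everywhere -> edge loss ln 2 regardless of Ge
  ep <- const4(0.5, 8, 8)
  expect_equal(edge_loss(ep, ns$as_t4(random_mask(8, 8))), log(2),
               tolerance = 1e-12)

  # total = edge + seg (+ deep); all terms non-negative
  gs <- matrix(0, 96, 96); gs[30:60, 30:60] <- 1
  net <- build_model(tiny_model_config())
  pred <- model_forward(net, matrix(stats::runif(96 * 96), 96, 96))
  L0 <- total_loss(pred, gs, loss_config(deep_supervision = FALSE))
  expect_equal(L0$total, L0$edge + L0$seg, tolerance = 1e-12)
  L1 <- total_loss(pred, gs, loss_config(deep_supervision = TRUE))
  expect_equal(L1$total, L1$edge + L1$seg + L1$deep, tolerance = 1e-12)
  expect_true(all(c(L1$edge, L1$seg, L1$deep) >= 0))
  expect_gte(L1$total, max(L1$edge, L1$seg, L1$deep))
})

test_that("one gradient step on a free logit map decreases the hybrid loss", {
  set.seed(14)
  gs <- array(0, c(12, 12, 1, 1)); gs[4:9, 4:9, , ] <- 1
  z <- array(stats::rnorm(144, 0, 0.5), c(12, 12, 1, 1))
  W <- edge_weights(gs)
  zn <- ns$ag(z, requires_grad = TRUE)
  L <- seg_loss(ns$ag_sigmoid(zn), gs, W)
  l0 <- ns$ag_value(L)
  ns$ag_backward(L)
  # finite-difference agreement at a few pixels
  for (i in sample(144, 4)) {
    zp <- z; zp[i] <- zp[i] + 1e-6
    zm <- z; zm[i] <- zm[i] - 1e-6
    fd <- (ns$ag_value(seg_loss(ns$t_sigmoid(zp), gs, W)) -
           ns$ag_value(seg_loss(ns$t_sigmoid(zm), gs, W))) / 2e-6
    expect_equal(zn$grad[i], fd, tolerance = 1e-5)
  }
  l1 <- ns$ag_value(seg_loss(ns$t_sigmoid(z - 0.5 * zn$grad), gs, W))
  expect_lt(l1, l0)
})
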