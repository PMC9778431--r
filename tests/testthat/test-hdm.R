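test_that("branch receptive fields compose to 1, 9, 15, 21", {
  expect_identical(vapply(0:3, branch_receptive_field, integer(1)),
                   c(1L, 9L, 15L, 21L))
  expect_error(branch_receptive_field(4), "0..3")
  expect_error(branch_receptive_field(-1), "0..3")
  # chain structure: branch m >= 1 is 1x1, 1xk, kx1, dilated 3x3
  ops <- mf_branch_ops(2)
  expect_identical(ops$kh, c(1L, 1L, 5L, 3L))
  expect_identical(ops$kw, c(1L, 5L, 1L, 3L))
  expect_identical(ops$d, c(1L, 1L, 1L, 5L))
})

test_that("mf_block keeps spatial size and yields 32 channels in the model", {
  net <- build_model(tiny_model_config())
  f3 <- const4(0.3, 12, 12, net$meta$outs[2])
  out <- mf_block(f3, ns$mf_slots(net, 3, net$par))
  expect_identical(dim(out), c(12L, 12L, 32L, 1L))
  expect_true(all(is.finite(out)))
})

test_that("mf_block with mean-preserving averaging slots doubles a constant input", {
  # every conv slot becomes an averaging kernel (zero bias, reflective
  # padding): each branch path reproduces the constant, the shortcut adds it
  avg3 <- function(x) {
    out <- x
    for (c in seq_len(dim(x)[3])) for (n in seq_len(dim(x)[4])) {
      out[, , c, n] <- oracle_boxmean(x[, , c, n], 3)
    }
    out
  }
  chan_mean <- function(x) {
    out <- array(0, c(dim(x)[1], dim(x)[2], 1L, dim(x)[4]))
    for (n in seq_len(dim(x)[4])) {
      out[, , 1, n] <- apply(x[, , , n, drop = FALSE], c(1, 2), mean)
    }
    out
  }
  cc <- 1.7
  f <- const4(cc, 8, 8)
  slots <- list(
    branches = replicate(4, function(x) avg3(x), simplify = FALSE),
    reduce = function(x) avg3(chan_mean(x)),
    shortcut = function(x) avg3(x))
  out <- mf_block(f, slots)
  expect_equal(out[3:6, 3:6, 1, 1], matrix(2 * cc, 4, 4), tolerance = 1e-12)
})

test_that("md_block reproduces the cross-scale product algebra", {
  # identity conv slots, all-ones deeper features: f3'' == f3'
  f3p <- array(stats::rnorm(4 * 4), c(4, 4, 1, 1))
  ones4 <- const4(1, 2, 2); ones5 <- const4(1, 1, 1)
  got <- md_block(f3p, ones4, ones5,
                  slots = list(conv54 = identity, conv43 = identity,
                               conv53 = identity,
                               head = function(x) ns$ag_slice_c(x, 1L)))
  expect_equal(got, f3p, tolerance = 1e-12)

  # constant features: f3''=2*3*4, f4''=3*4, concat (24,12,4), head sums to 40
  f3p <- const4(2, 4, 4); f4p <- const4(3, 2, 2); f5p <- const4(4, 1, 1)
  chan_sum <- function(x) {
    out <- array(0, c(dim(x)[1], dim(x)[2], 1L, dim(x)[4]))
    out[, , 1, 1] <- apply(x[, , , 1, drop = FALSE], c(1, 2), sum)
    out
  }
  slots <- md_identity_slots(); slots$head <- identity
  agg <- md_block(f3p, f4p, f5p, slots)
  expect_identical(dim(agg), c(4L, 4L, 3L, 1L))
  expect_equal(unique(as.vector(agg[, , 1, ])), 24)
  expect_equal(unique(as.vector(agg[, , 2, ])), 12)
  expect_equal(unique(as.vector(agg[, , 3, ])), 4)
  slots$head <- chan_sum
  fg <- md_block(f3p, f4p, f5p, slots)
  expect_equal(unique(as.vector(fg)), 40)
})

test_that("deepest-level fixpoint holds and fg sits at f3 resolution in the model", {
  net <- build_model(tiny_model_config())
  img <- matrix(stats::runif(96 * 96), 96, 96)
  pred <- model_forward(net, img)
  expect_identical(dim(pred$coarse)[1:2], c(12L, 12L))  # 96 / 8
  # fixpoint f5'' = f5' is structural: md_block never transforms f5p before
  # the concat; verify by tracing a tagged constant through identity slots
  f5p <- const4(0.37, 1, 1)
  slots <- md_identity_slots(); slots$head <- identity
  agg <- md_block(const4(1, 4, 4), const4(1, 2, 2), f5p, slots)
  expect_equal(unique(as.vector(agg[, , 3, ])), 0.37)
})

test_that("mf_block is translation-equivariant away from borders", {
  net <- build_model(tiny_model_config())
  set.seed(4)
  base <- array(stats::rnorm(36 * 36 * net$meta$outs[2]),
                c(36, 36, net$meta$outs[2], 1))
  a <- mf_block(base[1:32, 1:32, , , drop = FALSE], ns$mf_slots(net, 3, net$par))
  b <- mf_block(base[3:34, 3:34, , , drop = FALSE], ns$mf_slots(net, 3, net$par))
  # shift 2 px; compare interiors clear of the 21-px receptive field edge
  expect_equal(b[14:16, 14:16, , , drop = FALSE],
               a[16:18, 16:18, , , drop = FALSE], tolerance = 1e-8)
})
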