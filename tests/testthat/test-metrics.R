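test_that("region metrics on a hand-counted toy pair", {
  # 4x4 field, |S|=6, |GT|=4, |S & GT|=3
  gt <- matrix(0, 4, 4); gt[1:2, 1:2] <- 1
  s <- matrix(0, 4, 4); s[1, 1:2] <- 1; s[2, 1] <- 1
  s[3, 3:4] <- 1; s[4, 3] <- 1
  rm <- region_metrics(s, gt)
  expect_equal(rm$DSC, 0.6)
  expect_equal(rm$JA, 3 / 7)
  expect_equal(rm$SE, 0.75)
  expect_equal(rm$SP, 9 / 12)
  expect_equal(rm$TP + rm$FP + rm$FN + rm$TN, 16)
})

test_that("perfect overlap and empty-vs-empty conventions", {
  set.seed(20)
  m <- random_mask(8, 8)
  rm <- region_metrics(m, m)
  expect_equal(c(rm$DSC, rm$JA, rm$SE), c(1, 1, 1))
  z <- matrix(0, 5, 5)
  rm0 <- region_metrics(z, z)
  expect_equal(c(rm0$DSC, rm0$JA), c(1, 1))
  expect_true(is.na(rm0$SE))
})

test_that("JA = DSC / (2 - DSC) holds over random mask pairs", {
  set.seed(21)
  for (i in 1:100) {
    s <- random_mask(10, 10); g <- random_mask(10, 10)
    rm <- region_metrics(s, g)
    expect_equal(rm$JA, rm$DSC / (2 - rm$DSC), tolerance = 1e-12)
  }
})

test_that("hd95: identity, singleton distance, symmetry, and the all-pairs oracle", {
  set.seed(22)
  m <- random_mask(10, 10)
  expect_equal(hd95(m, m), 0)

  a <- matrix(0, 6, 6); a[1, 1] <- 1
  b <- matrix(0, 6, 6); b[4, 5] <- 1  # offset (3, 4) -> distance 5
  expect_equal(hd95(a, b), 5)

  for (i in 1:50) {
    s <- random_mask(12, 12); g <- random_mask(12, 12)
    if (sum(s) == 0 || sum(g) == 0) next
    expect_equal(hd95(s, g), oracle_hd(s, g), tolerance = 1e-9)
    expect_equal(hd95(s, g), hd95(g, s))
    expect_lte(hd95(s, g), oracle_hd(s, g, q = 1) + 1e-12)
  }
  expect_warning(v <- hd95(matrix(0, 10, 10), m), "empty")
  expect_true(is.na(v))
})

test_that("S-measure and E-measure match independent references on toy maps", {
  set.seed(23)
  for (i in 1:20) {
    gt <- random_mask(16, 16, p = stats::runif(1, 0.1, 0.9))
    p <- matrix(stats::runif(256), 16, 16)
    sb <- random_mask(16, 16)
    expect_equal(s_measure(p, gt), ref_s_measure(p, gt), tolerance = 1e-6)
    expect_equal(e_measure(sb, gt), ref_e_measure(sb, gt), tolerance = 1e-6)
    expect_gte(e_measure(sb, gt), 0)
    expect_lte(e_measure(sb, gt), 1)
  }
  # perfect structural match
  gt <- matrix(0, 16, 16); gt[5:11, 4:12] <- 1
  expect_gte(s_measure(gt, gt), 0.99)
  expect_equal(e_measure(gt, gt), 1, tolerance = 1e-6)
  # degenerate ground truths
  expect_equal(s_measure(matrix(0.2, 8, 8), matrix(0, 8, 8)), 0.8)
  expect_equal(e_measure(matrix(1, 8, 8), matrix(1, 8, 8)), 1)
})

test_that("MAE closed forms", {
  gt <- matrix(0, 8, 8); gt[2:5, 2:5] <- 1
  expect_equal(mae(gt, gt), 0)
  expect_equal(mae(1 - gt, gt), 1)
  expect_equal(mae(matrix(0.25, 8, 8), matrix(0, 8, 8)), 0.25)
})

test_that("evaluate_dataset: perfect predictions, aggregates, and pairing errors", {
  pd <- withr::local_tempdir(); gd <- withr::local_tempdir()
  set.seed(24)
  for (i in 1:10) {
    m <- matrix(0, 32, 32)
    r0 <- sample(4:12, 1); m[r0:(r0 + 10), r0:(r0 + 8)] <- 1
    write_gray_png(m, file.path(pd, sprintf("im%02d.png", i)))
    write_gray_png(m, file.path(gd, sprintf("im%02d.png", i)))
  }
  rep <- evaluate_dataset(pd, gd)
  g <- glance(rep)
  expect_equal(unname(unlist(g[c("DSC", "JA", "Em")])), c(1, 1, 1),
               tolerance = 1e-6)
  expect_gte(g$Sm, 0.99)
  expect_equal(unname(unlist(g[c("HD95", "MAE")])), c(0, 0))
  expect_equal(rep$summary$sd[rep$summary$metric == "DSC"], 0)
  expect_equal(nrow(tidy(rep)), 10)

  # aggregate mean equals the hand-averaged per-image column
  expect_equal(g$DSC, mean(tidy(rep)$DSC))

  # CSV round trip carries the aggregate row
  csv <- withr::local_tempfile(fileext = ".csv")
  ns$write_metrics_csv(rep, csv)
  tab <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(tab), 11)
  expect_equal(tab$DSC[11], mean(tab$DSC[1:10]))

  file.remove(file.path(pd, "im01.png"))
  expect_error(evaluate_dataset(pd, gd), "im01")
})

test_that("bounded metrics stay in [0,1] under mask fuzzing", {
  set.seed(25)
  for (i in 1:200) {
    s <- random_mask(9, 9, p = stats::runif(1, 0.02, 0.98))
    g <- random_mask(9, 9, p = stats::runif(1, 0.02, 0.98))
    rm <- region_metrics(s, g)
    vals <- c(rm$DSC, rm$JA, s_measure(s, g), e_measure(s, g), mae(s, g))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})
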