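test_that("patient-level split is 9:1, disjoint, crop-preserving and seeded", {
  man <- tibble::tibble(patient_id = rep(sprintf("P%02d", 1:10), each = 5),
                        crop_index = rep(0:4, 10))
  sp <- split_patients(man, seed = 3)
  expect_equal(length(unique(sp$train$patient_id)), 9)
  expect_equal(length(unique(sp$test$patient_id)), 1)
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), 50)
  # all 5 crops of the held-out patient moved together
  expect_equal(nrow(sp$test), 5)
  sp2 <- split_patients(man, seed = 3)
  expect_identical(sp$test$patient_id, sp2$test$patient_id)
  expect_error(split_patients(man[man$patient_id == "P01", ]), "2 patients")
})

test_that("learning-rate schedule drops 10% every 30 epochs", {
  tc <- train_config()
  expect_equal(lr_at_epoch(tc, 1), 1e-4)
  expect_equal(lr_at_epoch(tc, 30), 1e-4)
  expect_equal(lr_at_epoch(tc, 31), 0.9e-4)
  expect_equal(lr_at_epoch(tc, 61), 0.81e-4)
})

test_that("multi-scale batches resize as specified and keep masks binary", {
  set.seed(30)
  imgs <- array(stats::runif(96 * 96 * 2), c(96, 96, 1, 2))
  msks <- array(0, c(96, 96, 1, 2)); msks[30:60, 30:60, , ] <- 1
  b <- multiscale_batch(imgs, msks, 0.75)
  expect_identical(dim(b$images)[1:2], c(72L, 72L))
  expect_true(all(b$masks %in% c(0, 1)))
  b2 <- multiscale_batch(imgs, msks, 1.25)
  expect_identical(dim(b2$images)[1:2], c(120L, 120L))
  # scale 1 is a bit-identical passthrough
  b1 <- multiscale_batch(imgs, msks, 1)
  expect_identical(b1$images, imgs)
  expect_error(multiscale_batch(imgs, msks, 0), "positive")
})

test_that("short training runs are reproducible and logged", {
  rows <- tiny_patch_set(n_patients = 2, n_crops = 2)
  tc <- tiny_train_config(max_epochs = 2L)
  f1 <- fit_model(rows, config = tc)
  f2 <- fit_model(rows, config = tc)
  expect_equal(f1$log$loss_total, f2$log$loss_total, tolerance = 1e-12)
  expect_equal(nrow(f1$log), 2)
  expect_true(all(diff(f1$log$epoch) > 0))
  expect_true(all(diff(f1$log$iterations) > 0))
  expect_named(glance(f1),
               c("epochs", "iterations", "best_epoch", "best_val_dsc",
                 "final_loss", "parameters"))
})

test_that("checkpoint round trip reproduces validation Dice exactly", {
  rows <- tiny_patch_set(n_patients = 3, n_crops = 2)
  sp <- list(train = rows[1:4, ], test = rows[5:6, ])
  tc <- tiny_train_config(max_epochs = 2L)
  fit <- fit_model(sp$train, sp$test, config = tc)
  expect_false(is.na(fit$best_val_dsc))
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, ck)
  net2 <- load_checkpoint(ck)
  dsc <- vapply(seq_len(nrow(sp$test)), function(i) {
    pr <- predict_masks(net2, sp$test$image[[i]],
                        threshold = tc$threshold)[[1]]
    region_metrics(pr$mask, sp$test$mask[[i]])$DSC
  }, numeric(1))
  expect_equal(mean(dsc), fit$best_val_dsc, tolerance = 1e-6)

  # version guard
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(version = "something-else"), bad)
  expect_error(load_checkpoint(bad), "incompatible")
})

test_that("prediction is deterministic, size-preserving, and threshold 0 floods", {
  net <- build_model(tiny_model_config())
  img <- matrix(stats::runif(96 * 96), 96, 96)
  a <- predict_masks(net, img)[[1]]
  b <- predict_masks(net, img)[[1]]
  expect_identical(a$prob, b$prob)
  expect_identical(dim(a$prob), dim(img))
  z <- predict_masks(net, img, threshold = 0)[[1]]
  expect_true(all(z$mask[z$prob > 0] == 1))
  expect_true(all(z$mask == 1))  # sigmoid output is strictly positive
})

test_that("predict_dir writes paired probability and mask PNGs", {
  net <- build_model(tiny_model_config())
  ind <- withr::local_tempdir(); outd <- withr::local_tempdir()
  set.seed(31)
  for (f in c("a.png", "b.png")) {
    write_gray_png(matrix(stats::runif(96 * 96), 96, 96), file.path(ind, f))
  }
  res <- predict_dir(net, ind, outd)
  expect_equal(nrow(res), 2)
  for (f in c("a.png", "b.png")) {
    pr <- read_gray_png(file.path(outd, "prob", f))
    mk <- read_gray_png(file.path(outd, "mask", f))
    expect_identical(dim(pr), c(96L, 96L))
    expect_true(all(mk %in% c(0, 1)))
  }
})
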