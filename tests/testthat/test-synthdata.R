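test_that("identical specs render bit-identical scenes", {
  sp <- nodule_spec("isolated", 20, seed = 7)
  a <- make_nodule_scene(sp)
  b <- make_nodule_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("mask area stays within [0.5, 1.5] of the nominal disc area", {
  for (seed in 1:8) {
    sc <- make_nodule_scene(nodule_spec("isolated", 20, seed = seed))
    area <- sum(sc$mask)
    disc <- pi * 10^2
    expect_gt(area, 0.5 * disc)
    expect_lt(area, 1.5 * disc)
  }
})

test_that("juxta-pleural masks touch the wall band (8-connectivity scan)", {
  sc <- make_nodule_scene(nodule_spec("juxta_pleural", 16, seed = 1))
  n <- nrow(sc$mask)
  wb <- max(4L, round(n / 16))  # wall occupies the first wb columns
  # brute-force adjacency: some mask pixel has an 8-neighbour in the wall
  touching <- FALSE
  for (i in seq_len(n)) for (j in seq_len(ncol(sc$mask))) {
    if (sc$mask[i, j] == 1 && j <= wb + 1L) touching <- TRUE
  }
  expect_true(touching)
  expect_gt(mean(sc$image[, seq_len(wb)]), 0.7)  # bright wall
})

test_that("type fidelity: ggo low contrast, cavitary interior hole, calcified bright", {
  ggo <- make_nodule_scene(nodule_spec("ggo", 20, seed = 3))
  gap <- mean(ggo$image[ggo$mask == 1]) - mean(ggo$image[ggo$mask == 0])
  expect_lte(gap, 0.3)

  cav <- make_nodule_scene(nodule_spec("cavitary", 24, seed = 3))
  vals <- cav$image[cav$mask == 1]
  expect_gt(max(vals) - min(vals), 0.25)  # interior intensity minimum
  expect_true(all(cav$mask %in% c(0, 1)))  # mask stays filled/binary

  cal <- make_nodule_scene(nodule_spec("calcified", 20, seed = 3))
  expect_gt(mean(cal$image[cal$mask == 1]), 0.9)

  jv <- make_nodule_scene(nodule_spec("juxta_vascular", 20, seed = 4))
  expect_gt(sum(jv$image > 0.55 & jv$mask == 0), 20)  # bright tube outside nodule
})

test_that("degenerate and invalid specs are rejected", {
  expect_error(nodule_spec("isolated", 2), "degenerate")
  expect_error(nodule_spec("weird_type", 20), "unknown")
  expect_error(nodule_spec("ggo", 20, contrast = 0.6), "contrast")
  expect_error(nodule_spec("isolated", 20, scene_size = 30), "scene_size")
})

test_that("crop variants contain the full mask, vary in shape, and are seeded", {
  sc <- make_nodule_scene(nodule_spec("isolated", 20, seed = 5))
  cr <- crop_variants(sc$image, sc$mask, n = 5, seed = 9)
  expect_equal(nrow(cr), 5L)
  expect_identical(cr$crop_index, 0:4)
  for (i in 1:5) {
    expect_equal(sum(cr$mask[[i]]), sum(sc$mask))  # containment
    d <- dim(cr$mask[[i]])
    rr <- range(which(rowSums(cr$mask[[i]]) > 0))
    cc <- range(which(colSums(cr$mask[[i]]) > 0))
    expect_gte(min(rr[1] - 1, cc[1] - 1, d[1] - rr[2], d[2] - cc[2]), 4)
  }
  aspects <- vapply(cr$image, function(m) nrow(m) / ncol(m), numeric(1))
  expect_gte(length(unique(round(aspects, 6))), 2L)
  offs <- vapply(cr$mask, function(m) min(which(rowSums(m) > 0)), numeric(1))
  expect_gte(length(unique(offs)), 2L)  # nodule position varies
  cr2 <- crop_variants(sc$image, sc$mask, n = 5, seed = 9)
  expect_identical(cr, cr2)
  expect_error(crop_variants(sc$image, sc$mask, n = 2, min_margin = 500),
               "too small")
})

test_that("build_dataset writes 96x96 binary-mask pairs and a reproducible manifest", {
  cfg <- synth_config(n_patients = 3, seed = 21)
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  m1 <- build_dataset(cfg, td1)
  m2 <- build_dataset(cfg, td2)
  expect_equal(nrow(m1), 3L * 5L)
  expect_identical(
    unname(tools::md5sum(file.path(td1, "manifest.csv"))),
    unname(tools::md5sum(file.path(td2, "manifest.csv"))))
  hdr <- readLines(file.path(td1, "manifest.csv"), n = 1)
  expect_identical(hdr, "patient_id,nodule_id,crop_index,image_path,mask_path")
  for (p in m1$mask_path[1:5]) {
    msk <- read_gray_png(file.path(td1, p))
    expect_identical(dim(msk), c(96L, 96L))
    expect_true(all(unique(as.vector(msk)) %in% c(0, 1)))
  }
  img <- read_gray_png(file.path(td1, m1$image_path[1]))
  expect_true(min(img) >= 0 && max(img) <= 1)
  rt <- read_manifest(td1)
  expect_equal(as.data.frame(rt), as.data.frame(m1))
  # disjoint per-patient seed ranges
  expect_false(any(duplicated(cfg$seed)))
})
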