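# ---------------------------------------------------------------------------
# Deterministic synthetic CT-like nodule phantoms.
#
# Scenes emulate the variability seen in thoracic CT patches: star-convex
# (radially perturbed) nodules of configurable size and contrast on a dark,
# noisy parenchyma background, with type variants for wall-attached
# (juxta-pleural), vessel-attached (juxta-vascular), ground-glass (low
# contrast), cavitary (interior intensity hole, mask filled per clinical
# convention) and calcified (near-saturating contrast) nodules.  Everything
# is reproducible bit-for-bit from the spec's seed.
# ---------------------------------------------------------------------------

NODULE_TYPES <- c("isolated", "juxta_pleural", "juxta_vascular",
                  "ggo", "cavitary", "calcified")

default_contrast <- function(type) {
  switch(type,
         isolated = 0.6, juxta_pleural = 0.55, juxta_vascular = 0.55,
         ggo = 0.25, cavitary = 0.5, calcified = 0.95)
}

#' Specification of one synthetic nodule scene
#'
#' @param nodule_type One of `r paste(NODULE_TYPES, collapse = ", ")`.
#' @param diameter_px Nominal nodule diameter in pixels (>= 3).
#' @param contrast Nodule-background intensity gap in (0, 1]; defaults by
#'   type (ground-glass 0.25, calcified 0.95, otherwise ~0.55).
#' @param scene_size Square scene side before cropping; must be at least
#'   twice the diameter.
#' @param seed Integer seed; identical specs render bit-identical scenes.
#' @param noise_sd Additive Gaussian background noise (default 0.05).
#' @return Object of class `nodule_spec`.
#' @export
nodule_spec <- function(nodule_type, diameter_px, contrast = NULL,
                        scene_size = NULL, seed = 1L, noise_sd = 0.05) {
  if (!nodule_type %in% NODULE_TYPES) {
    stop("unknown nodule_type: ", nodule_type)
  }
  diameter_px <- as.integer(diameter_px)
  if (diameter_px < 3L) stop("degenerate nodule: diameter_px must be >= 3")
  if (is.null(contrast)) contrast <- default_contrast(nodule_type)
  if (contrast <= 0 || contrast > 1) stop("contrast must lie in (0, 1]")
  if (nodule_type == "ggo" && contrast > 0.3) {
    stop("ground-glass nodules require contrast <= 0.3")
  }
  if (nodule_type == "calcified" && contrast < 0.8) {
    stop("calcified nodules require contrast >= 0.8")
  }
  if (is.null(scene_size)) scene_size <- max(72L, 4L * diameter_px)
  scene_size <- as.integer(scene_size)
  if (scene_size < 2L * diameter_px) {
    stop("scene_size must be at least 2 * diameter_px")
  }
  structure(list(nodule_type = nodule_type, diameter_px = diameter_px,
                 contrast = contrast, scene_size = scene_size,
                 seed = as.integer(seed), noise_sd = noise_sd),
            class = "nodule_spec")
}

# star-convex radial profile: R * (1 + sum_j a_j cos(j theta + phi_j));
# amplitudes decay as 1/j^2 so the rendered area stays within
# [0.5, 1.5] * pi R^2
star_radius_fn <- function(R) {
  a <- stats::runif(4, 0, 0.3 / (2:5)^2)
  phi <- stats::runif(4, 0, 2 * pi)
  function(theta) {
    pert <- rep(1, length(theta))
    for (j in seq_along(a)) pert <- pert + a[j] * cos((j + 1) * theta + phi[j])
    R * pert
  }
}

render_star <- function(n, cx, cy, rfun, frac = 1) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  dx <- xs - cx; dy <- ys - cy
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  (rho <= frac * rfun(theta)) * 1
}

#' Render a synthetic nodule scene
#'
#' @param spec A [nodule_spec()].
#' @return List with `image` (scene_size x scene_size matrix in `[0, 1]`)
#'   and `mask` (binary matrix of the nodule region; cavitary nodules have a
#'   filled mask even though their interior intensity drops).
#' @export
make_nodule_scene <- function(spec) {
  stopifnot(inherits(spec, "nodule_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$scene_size
    base <- 0.15
    img <- matrix(base + stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    R <- spec$diameter_px / 2
    rfun <- star_radius_fn(R)
    jit <- round(stats::runif(2, -0.08, 0.08) * n)
    cy <- n / 2 + jit[1]; cx <- n / 2 + jit[2]
    wall_cols <- integer(0)

    if (spec$nodule_type == "juxta_pleural") {
      wb <- max(4L, round(n / 16))
      wall_cols <- seq_len(wb)
      img[, wall_cols] <- 0.85 + stats::rnorm(n * wb, 0, spec$noise_sd / 2)
      cx <- wb + rfun(pi) + 0.5  # leftmost lobe lands on the wall
    }
    if (spec$nodule_type == "juxta_vascular") {
      ang <- stats::runif(1, 0, pi)
      xs <- matrix(rep(seq_len(n), each = n), n, n)
      ys <- matrix(rep(seq_len(n), times = n), n, n)
      d_line <- abs(cos(ang) * (ys - cy) - sin(ang) * (xs - cx))
      vessel <- d_line <= 1.5
      img[vessel] <- 0.7 + stats::rnorm(sum(vessel), 0, spec$noise_sd / 2)
    }

    mask <- render_star(n, cx, cy, rfun)
    if (spec$nodule_type == "juxta_pleural" && length(wall_cols)) {
      # guarantee 8-connectivity with the wall band
      mincol <- min(which(colSums(mask) > 0))
      shift <- mincol - (max(wall_cols) + 1L)
      if (shift > 0) {
        mask <- render_star(n, cx - shift, cy, rfun)
      }
    }
    if (sum(mask) == 0) stop("degenerate nodule: empty rendered mask")

    nod_val <- base + spec$contrast
    img[mask == 1] <- nod_val + stats::rnorm(sum(mask), 0, 0.02)
    if (spec$nodule_type == "cavitary") {
      hole <- render_star(n, cx, cy, rfun, frac = 0.45)
      hole <- hole * mask
      img[hole == 1] <- base + stats::rnorm(sum(hole), 0, spec$noise_sd)
    }
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask)
  })
}

#' One CT patch record
#'
#' @param image Matrix in `[0, 1]`.
#' @param mask Binary matrix of the same shape.
#' @param patient_id,nodule_id Identifiers.
#' @param crop_index Integer crop index (0-based).
#' @return Object of class `ct_patch`.
#' @export
ct_patch <- function(image, mask, patient_id = "P000", nodule_id = "N0",
                     crop_index = 0L) {
  if (!identical(dim(image), dim(mask))) {
    stop("image and mask must have identical shape")
  }
  check_binary(mask)
  if (min(image) < 0 || max(image) > 1) stop("image intensities must lie in [0, 1]")
  structure(list(image = image, mask = mask, patient_id = patient_id,
                 nodule_id = nodule_id, crop_index = as.integer(crop_index)),
            class = "ct_patch")
}

#' Crop several non-centered, non-square patches around a nodule
#'
#' Draws `n` crop rectangles that each contain the entire mask with at least
#' `min_margin` pixels of margin on every side; offsets and aspect ratios
#' vary between crops, so the nodule position within the crop is not fixed.
#'
#' @param image Scene image matrix.
#' @param mask Binary nodule mask (non-empty).
#' @param n Number of crops (default 5).
#' @param min_margin Minimum background margin around the mask (pixels).
#' @param seed Integer seed.
#' @param patient_id,nodule_id Identifiers carried into the records.
#' @return Tibble with one row per crop: `patient_id`, `nodule_id`,
#'   `crop_index` (0-based) and list-columns `image`, `mask`.
#' @export
crop_variants <- function(image, mask, n = 5L, min_margin = 4L, seed = 1L,
                          patient_id = "P000", nodule_id = "N0") {
  stopifnot(n >= 1L)
  if (sum(mask) == 0) stop("mask is empty")
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  avail <- c(top = rr[1] - 1L, bottom = nrow(mask) - rr[2],
             left = cc[1] - 1L, right = ncol(mask) - cc[2])
  if (any(avail < min_margin)) {
    stop("scene too small to honor a ", min_margin, "-pixel margin ",
         "(available: ", paste(avail, collapse = "/"), ")")
  }
  withr::with_seed(seed, {
    rects <- list()
    tries <- 0L
    while (length(rects) < n) {
      tries <- tries + 1L
      if (tries > 200L) stop("cannot generate ", n, " distinct crops")
      m <- vapply(avail, function(a) {
        v <- seq.int(min_margin, a)
        v[sample.int(length(v), 1L)]
      }, integer(1))
      r <- c(rr[1] - m[["top"]], rr[2] + m[["bottom"]],
             cc[1] - m[["left"]], cc[2] + m[["right"]])
      key <- paste(r, collapse = "_")
      if (!key %in% names(rects)) rects[[key]] <- r
    }
    rows <- purrr::imap(unname(rects), function(r, i) {
      tibble::tibble(patient_id = patient_id, nodule_id = nodule_id,
                     crop_index = i - 1L,
                     image = list(image[r[1]:r[2], r[3]:r[4], drop = FALSE]),
                     mask = list(mask[r[1]:r[2], r[3]:r[4], drop = FALSE]))
    })
    dplyr::bind_rows(rows)
  })
}

#' Configuration tibble for a synthetic dataset
#'
#' One nodule per row; seed ranges are disjoint per patient so a
#' patient-level split never shares generator state across the split.
#'
#' @param n_patients Number of synthetic patients.
#' @param nodules_per_patient Nodules per patient.
#' @param types Nodule types cycled across nodules.
#' @param diameter_range Min/max diameter in pixels.
#' @param seed Base seed.
#' @return Tibble with columns `patient_id`, `nodule_id`, `nodule_type`,
#'   `diameter_px`, `seed`.
#' @export
synth_config <- function(n_patients = 10L, nodules_per_patient = 1L,
                         types = NODULE_TYPES, diameter_range = c(12L, 28L),
                         seed = 20L) {
  grid <- tidyr::expand_grid(p = seq_len(n_patients),
                             k = seq_len(nodules_per_patient))
  withr::with_seed(seed, {
    grid |>
      dplyr::mutate(
        patient_id = sprintf("P%03d", .data$p),
        nodule_id = sprintf("N%d", .data$k - 1L),
        nodule_type = types[((.data$p - 1L) * nodules_per_patient + .data$k - 1L) %%
                              length(types) + 1L],
        diameter_px = sample(seq.int(diameter_range[1], diameter_range[2]),
                             dplyr::n(), replace = TRUE),
        seed = seed + .data$p * 1000L + .data$k) |>
      dplyr::select("patient_id", "nodule_id", "nodule_type",
                    "diameter_px", "seed")
  })
}

#' Build a synthetic dataset on disk
#'
#' Renders every configured nodule, takes `n_crops` crops around it, resizes
#' all patches to `size` x `size` (bilinear for images, nearest-neighbour for
#' masks so they stay binary) and writes 8-bit grayscale PNG pairs plus a
#' CSV manifest.
#'
#' @param config Tibble from [synth_config()] (columns `patient_id`,
#'   `nodule_id`, `nodule_type`, `diameter_px`, optionally `contrast`, `seed`).
#' @param out_dir Output directory (created; subdirectories `images/`,
#'   `masks/`).
#' @param size Output patch side length (default 96).
#' @param n_crops Crops per nodule (default 5).
#' @param min_margin Minimum crop margin in pixels.
#' @param write_nifti Also write `.nii.gz` pairs (requires RNifti).
#' @return The manifest tibble (`patient_id`, `nodule_id`, `crop_index`,
#'   `image_path`, `mask_path`; paths relative to `out_dir`), also written to
#'   `out_dir/manifest.csv`.
#' @export
build_dataset <- function(config, out_dir, size = 96L, n_crops = 5L,
                          min_margin = 4L, write_nifti = FALSE) {
  for (d in file.path(out_dir, c("images", "masks"))) {
    if (!dir.exists(d) && !dir.create(d, recursive = TRUE)) {
      stop("cannot create output directory: ", d)
    }
  }
  rows <- purrr::pmap(config, function(patient_id, nodule_id, nodule_type,
                                       diameter_px, seed, contrast = NULL, ...) {
    spec <- nodule_spec(nodule_type, diameter_px, contrast = contrast, seed = seed)
    sc <- make_nodule_scene(spec)
    crops <- crop_variants(sc$image, sc$mask, n = n_crops,
                           min_margin = min_margin, seed = seed + 500L,
                           patient_id = patient_id, nodule_id = nodule_id)
    purrr::pmap(crops, function(patient_id, nodule_id, crop_index, image, mask) {
      img96 <- pmin(pmax(bilinear_resize(image, size, size), 0), 1)
      msk96 <- nn_resize(mask, size, size)
      stem <- sprintf("%s_%s_c%d.png", patient_id, nodule_id, crop_index)
      ip <- file.path("images", stem)
      mp <- file.path("masks", stem)
      write_gray_png(img96, file.path(out_dir, ip))
      write_gray_png(msk96, file.path(out_dir, mp))
      if (isTRUE(write_nifti)) {
        if (!requireNamespace("RNifti", quietly = TRUE)) {
          stop("write_nifti = TRUE requires the RNifti package")
        }
        RNifti::writeNifti(img96, file.path(out_dir, sub("\\.png$", ".nii.gz", ip)))
        RNifti::writeNifti(msk96, file.path(out_dir, sub("\\.png$", ".nii.gz", mp)))
      }
      tibble::tibble(patient_id = patient_id, nodule_id = nodule_id,
                     crop_index = crop_index, image_path = ip, mask_path = mp)
    }) |> dplyr::bind_rows()
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Read a dataset manifest
#' @param dir Dataset directory containing `manifest.csv`.
#' @export
read_manifest <- function(dir) {
  readr::read_csv(file.path(dir, "manifest.csv"),
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    nodule_id = readr::col_character(),
                    crop_index = readr::col_integer(),
                    image_path = readr::col_character(),
                    mask_path = readr::col_character()))
}

#' Load manifest rows into memory
#'
#' @param manifest Manifest tibble.
#' @param dir Dataset directory the paths are relative to.
#' @return The manifest with list-columns `image` and `mask` added.
#' @export
load_patches <- function(manifest, dir) {
  manifest |>
    dplyr::mutate(
      image = purrr::map(.data$image_path,
                         function(p) read_gray_png(file.path(dir, p))),
      mask = purrr::map(.data$mask_path,
                        function(p) (read_gray_png(file.path(dir, p)) > 0.5) * 1))
}
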