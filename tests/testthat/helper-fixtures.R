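# Shared fixtures: a desk-scale model configuration and small in-memory
# datasets built from the synthetic generator.

tiny_model_config <- function(seed = 3L) {
  model_config(width = 1 / 16, blocks = c(1L, 1L, 1L, 1L), seed = seed)
}

tiny_train_config <- function(seed = 42L, ...) {
  train_config(lr0 = 1e-3, batch_size = 4L, width = 1 / 16,
               blocks = c(1L, 1L, 1L, 1L), seed = seed, ...)
}

# n_patients nodules (one each), n_crops crops, resized to `size`
tiny_patch_set <- function(n_patients = 4L, n_crops = 4L, size = 96L, seed = 11L) {
  cfg <- synth_config(n_patients = n_patients, seed = seed)
  rows <- dplyr::bind_rows(lapply(seq_len(nrow(cfg)), function(i) {
    sp <- nodule_spec(cfg$nodule_type[i], cfg$diameter_px[i], seed = cfg$seed[i])
    sc <- make_nodule_scene(sp)
    crop_variants(sc$image, sc$mask, n = n_crops, seed = cfg$seed[i] + 500L,
                  patient_id = cfg$patient_id[i], nodule_id = cfg$nodule_id[i])
  }))
  rows$image <- lapply(rows$image, function(m) {
    pmin(pmax(bilinear_resize(m, size, size), 0), 1)
  })
  rows$mask <- lapply(rows$mask, function(m) nn_resize(m, size, size))
  rows
}

# constant 4-D tensor helper
const4 <- function(v, h, w, c = 1L, n = 1L) array(v, c(h, w, c, n))
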