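# Memoised phantom fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

.phantom_cache <- new.env(parent = emptyenv())

phantom256 <- function(seed = 5) {
  key <- sprintf("p256_%d", seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_sample(phantom_config("hunt4like"), seed = seed)
  .phantom_cache[[key]]
}

phantom_small <- function(seed = 1, size = 32L) {
  key <- sprintf("p%d_%d", size, seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_sample(
      phantom_config("hunt4like", image_size = size), seed = seed)
  .phantom_cache[[key]]
}

# a small trained checkpoint on 32 px phantoms, for augment smoke tests
tiny_ckpt32 <- function() {
  if (is.null(.phantom_cache$ckpt32)) {
    samples <- lapply(1:4, phantom_small)
    lat <- do.call(rbind, lapply(samples, function(s)
      as.numeric(image_to_latent(s$image))))
    sch <- build_cosine_schedule(60L)
    cfg <- training_config(T_steps = 60L, d = ncol(lat), hidden = 48L,
                           batch_size = 16L, n_steps = 300L, seed = 11L)
    .phantom_cache$ckpt32 <- list(predictor = train_ddpm(lat, cfg, sch),
                                  schedule = sch, samples = samples)
  }
  .phantom_cache$ckpt32
}

# scaled augmentation config for small frames (pixel ranges defined at 256)
aug_config_scaled <- function(size, n_aug = 5L) {
  sc <- size / 256
  augmentation_config(depth_lambda_range = c(0, 150) * sc,
                      translation_length_range = c(0, 50) * sc,
                      n_augment_per_image = n_aug)
}
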