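# Pipeline stages and the YAML config runner.
#
# Every stage takes a named parameter list and a seed; all randomness is
# derived from the stage seed via derive_seed(), so rerunning a config
# reproduces every artifact bit for bit.

stage_param_names <- list(
  "phantom" = c("stage", "seed", "preset", "count", "image_size", "out"),
  "train-ddpm" = c("stage", "seed", "data", "out", "T_steps", "image_size",
                   "hidden", "n_steps", "batch_size", "lr", "vlb_weight"),
  "augment" = c("stage", "seed", "data", "ckpt", "out", "n_aug",
                "jump_length", "n_resample", "no_repaint"),
  "evaluate-seg" = c("stage", "seed", "pred", "ref", "label", "out"),
  "ef" = c("stage", "seed", "a2c", "a4c", "n_discs", "out"),
  "survey-stats" = c("stage", "seed", "responses", "out"))

#' Run a pipeline configuration
#'
#' Executes the stages of a YAML config in order. Recognised stages:
#' `phantom`, `train-ddpm`, `augment`, `evaluate-seg`, `ef`,
#' `survey-stats`; every stage carries its own `seed`. Unknown stages or
#' parameter keys raise a validation error naming the offender. Rerunning
#' the same config reproduces identical artifacts.
#'
#' @param config path to a YAML file, or an equivalent list.
#' @param base_dir directory against which relative paths are resolved
#'   (defaults to the config file's directory, or the working directory).
#' @return list of per-stage results, invisibly.
#' @export
run_config <- function(config, base_dir = NULL) {
  if (is.character(config)) {
    if (is.null(base_dir)) base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (is.null(config$stages))
    abort_invalid("config must contain a `stages` list",
                  class = "echosynth_validation_error")
  results <- vector("list", length(config$stages))
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    name <- st$stage
    if (is.null(name) || !name %in% names(stage_param_names))
      abort_invalid(sprintf("stage %d: unknown stage `%s`", i,
                            name %||% "<missing>"),
                    class = "echosynth_validation_error")
    extra <- setdiff(names(st), stage_param_names[[name]])
    if (length(extra))
      abort_invalid(sprintf("stage `%s`: unknown key(s): %s", name,
                            paste(extra, collapse = ", ")),
                    class = "echosynth_validation_error")
    if (is.null(st$seed)) st$seed <- 1L
    results[[i]] <- run_stage(name, st, base_dir)
  }
  invisible(results)
}

run_stage <- function(name, p, base_dir) {
  rp <- function(x) if (is.null(x) || grepl("^/", x)) x else file.path(base_dir, x)
  switch(name,
    "phantom" = stage_phantom(p, rp),
    "train-ddpm" = stage_train(p, rp),
    "augment" = stage_augment(p, rp),
    "evaluate-seg" = stage_evaluate_seg(p, rp),
    "ef" = stage_ef(p, rp),
    "survey-stats" = stage_survey(p, rp))
}

stage_phantom <- function(p, rp) {
  cfg <- phantom_config(p$preset %||% "hunt4like",
                        image_size = p$image_size %||% 256L)
  n <- p$count %||% 10L
  samples <- lapply(seq_len(n), function(i)
    generate_sample(cfg, seed = derive_seed(p$seed, paste0("phantom/", i))))
  manifest <- write_augmented_dataset(samples, rp(p$out), force = TRUE)
  list(manifest = manifest, n = n)
}

stage_train <- function(p, rp) {
  samples <- read_dataset(file.path(rp(p$data), "manifest.json"))
  size <- p$image_size %||% nrow(samples[[1]]$image)
  lat <- do.call(rbind, lapply(samples, function(s)
    as.numeric(image_to_latent(resize_image(s$image, c(size, size))))))
  cfg <- training_config(
    T_steps = as.integer(p$T_steps %||% 1000L), d = ncol(lat),
    hidden = as.integer(unlist(p$hidden %||% c(96, 96))),
    batch_size = as.integer(p$batch_size %||% 32L),
    lr = p$lr %||% 1e-3, n_steps = as.integer(p$n_steps %||% 2000L),
    vlb_weight = p$vlb_weight %||% 0.001, seed = p$seed)
  schedule <- build_cosine_schedule(cfg$T_steps)
  predictor <- train_ddpm(lat, cfg, schedule)
  cfg$image_size <- size
  save_checkpoint(predictor, schedule, cfg, rp(p$out))
  log_df <- attr(predictor, "training_log")
  utils::write.csv(log_df, paste0(rp(p$out), ".log.csv"), row.names = FALSE)
  list(checkpoint = rp(p$out), final_loss = utils::tail(log_df$loss, 1))
}

stage_augment <- function(p, rp) {
  samples <- read_dataset(file.path(rp(p$data), "manifest.json"))
  ck <- load_checkpoint(rp(p$ckpt))
  H <- nrow(samples[[1]]$image)
  if (!is.null(ck$config$image_size) && ck$config$image_size != H)
    abort_invalid(sprintf("checkpoint expects %d px frames, data has %d",
                          ck$config$image_size, H))
  # pixel ranges are defined at the 256 px reference scale
  sc <- H / 256
  acfg <- augmentation_config(
    depth_lambda_range = c(0, 150) * sc,
    translation_length_range = c(0, 50) * sc,
    n_augment_per_image = as.integer(p$n_aug %||% 5L))
  if (isTRUE(p$no_repaint)) {
    out <- list()
    for (i in seq_along(samples)) {
      s <- samples[[i]]
      out <- c(out, list(s), lapply(seq_len(acfg$n_augment_per_image), function(j)
        blackout_baseline(s, acfg,
                          seed = derive_seed(p$seed, sprintf("blackout/%d/%d", i, j)))))
    }
  } else {
    out <- augment_dataset(samples, ck$predictor, ck$schedule, acfg,
                           seed = p$seed,
                           jump_length = as.integer(p$jump_length %||% 10L),
                           n_resample = as.integer(p$n_resample %||% 10L))
  }
  manifest <- write_augmented_dataset(out, rp(p$out), force = TRUE)
  list(manifest = manifest, n = length(out))
}

stage_evaluate_seg <- function(p, rp) {
  pred <- read_dataset(file.path(rp(p$pred), "manifest.json"))
  ref <- read_dataset(file.path(rp(p$ref), "manifest.json"))
  if (length(pred) != length(ref))
    abort_invalid("prediction and reference datasets differ in size")
  lab <- as.integer(p$label %||% 1L)
  rows <- lapply(seq_along(pred), function(i) {
    hd <- tryCatch(hausdorff_mm(pred[[i]]$mask, ref[[i]]$mask, lab,
                                ref[[i]]$spacing),
                   echosynth_undefined_metric = function(e) NA_real_)
    data.frame(id = attr(ref[[i]], "record")$id %||% i,
               dice = dice(pred[[i]]$mask, ref[[i]]$mask, lab),
               hausdorff_mm = hd)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, rp(p$out), row.names = FALSE)
  list(metrics = rp(p$out), mean_dice = mean(df$dice),
       mean_hausdorff = mean(df$hausdorff_mm, na.rm = TRUE))
}

stage_ef <- function(p, rp) {
  load_cycles <- function(dir) {
    samples <- read_dataset(file.path(rp(dir), "manifest.json"))
    recs <- lapply(samples, attr, "record")
    cyc <- unique(vapply(recs, function(r) r$cycle %||% 1L, 1L))
    lapply(cyc, function(ci) {
      in_c <- vapply(recs, function(r) identical(r$cycle %||% 1L, ci), TRUE)
      role <- vapply(recs, function(r) r$frame_role %||% "", "")
      list(ed = samples[in_c & role == "ED"][[1]]$mask,
           es = samples[in_c & role == "ES"][[1]]$mask,
           spacing = samples[in_c & role == "ED"][[1]]$spacing)
    })
  }
  a2c <- load_cycles(p$a2c); a4c <- load_cycles(p$a4c)
  res <- biplane_ef_from_masks(a2c, a4c, a2c[[1]]$spacing, a4c[[1]]$spacing,
                               n_discs = as.integer(p$n_discs %||% 20L))
  utils::write.csv(res$per_pair, rp(p$out), row.names = FALSE)
  list(ef_percent = 100 * res$ef, table = rp(p$out))
}

stage_survey <- function(p, rp) {
  df <- utils::read.csv(rp(p$responses), stringsAsFactors = FALSE)
  need <- c("item", "rater", "group", "selection", "correct")
  if (!all(need %in% names(df)))
    abort_invalid(sprintf("responses CSV must have columns: %s",
                          paste(need, collapse = ", ")),
                  class = "echosynth_validation_error")
  groups <- split(df, df$group)
  acc <- lapply(groups, function(g)
    list(k = sum(g$correct), n = nrow(g), accuracy = mean(g$correct),
         p_binomial = binomial_test(sum(g$correct), nrow(g))))
  ratings_by_group <- lapply(groups, function(g) {
    g <- g[order(g$item), ]
    lapply(split(g, g$rater), function(r) r$selection[order(r$item)])
  })
  gn <- names(ratings_by_group)
  kap <- list()
  for (i in seq_along(gn)) for (j in i:length(gn)) {
    key <- paste(gn[i], gn[j], sep = "|")
    kap[[key]] <- if (i == j) {
      if (length(ratings_by_group[[i]]) >= 2)
        average_pairwise_kappa(ratings_by_group[[i]]) else NA_real_
    } else
      average_pairwise_kappa(ratings_by_group[[i]], ratings_by_group[[j]])
  }
  out <- list(accuracy = acc, average_kappa = kap)
  if (!is.null(p$out))
    jsonlite::write_json(out, rp(p$out), auto_unbox = TRUE, digits = NA)
  out
}
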