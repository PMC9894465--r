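## Experiment orchestration: configuration, cohort-to-feature plumbing and the
## three experiment levels (face-analysis features, action-unit adaptation,
## Parkinson-domain triplet embeddings).

#' Default pipeline configuration
#'
#' Study-scale defaults: a 54-subject cohort (30 patients, 24 controls), five
#' 6-second 15 fps expression clips per subject, 64x64 rendering, a
#' 1000-image AU training set, the full SVM grid and 5-fold
#' subject-independent nested CV, and the default hypomimia constants
#' (`A0 = 0.9`, `beta = 0.5`, `gamma = 1`, `sigma_j = 0.02`, `tau0 = 0.5` s).
#'
#' @param seed master seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = NULL,
    cohort = list(n_pd = 30L, n_hc = 24L, fps = 15, duration_s = 6,
                  size = 64L, constants = hypomimia_constants()),
    au_data = list(n_images = 1000L,
                   split_fracs = c(train = 0.8, val = 0.1, test = 0.1),
                   thresholds = 0.5),
    stages = list(min_amplitude = 0.05),
    train = list(epochs = 30L, lr = 1e-3, batch = 32L, augment_deg = 10,
                 patience = 5L),
    freeze_fractions = c(0.5, 0.75),
    triplet = list(margin = 0.2, d_out = 128L, n_triplets = 256L,
                   epochs = 20L, lr = 1e-3, normalize = TRUE),
    cv = list(k = 5L, val_frac = 0.2),
    compare = list(n_reps = 25L, family_alpha = 0.05),
    exp1_kinds = c("single_N", "single_On", "single_A", "single_Off",
                   "NOnA", "AOffN", "NOnAOffN"),
    exp2_kinds = c("NOnA", "AOffN", "NOnAOffN"),
    exp3_freeze_triplets = TRUE,
    fusion = "concat")
}

#' Reduced-scale configuration
#'
#' A small configuration (12 subjects, 32x32 rendering, short training) used
#' for fast end-to-end runs of the full pipeline; the statistical conditions
#' (hypomimia constants, grids, CV protocol) are unchanged.
#'
#' @param seed master seed.
#' @return configuration list.
#' @export
smoke_config <- function(seed = 1L) {
  cfg <- default_config(seed)
  cfg$cohort$n_pd <- 6L
  cfg$cohort$n_hc <- 6L
  cfg$cohort$size <- 32L
  cfg$au_data$n_images <- 240L
  cfg$train$epochs <- 5L
  cfg$train$augment_deg <- 0
  cfg$triplet$epochs <- 8L
  cfg$triplet$n_triplets <- 128L
  cfg$triplet$d_out <- 32L
  cfg$compare$n_reps <- 10L
  cfg$exp1_kinds <- c("single_A", "NOnAOffN")
  cfg$exp3_freeze_triplets <- FALSE
  cfg
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(f))
}

#' Stage-sequence features for a whole cohort
#'
#' Detects stages on every clip, extracts the frames demanded by `kind`, runs
#' them through the model's feature extractor (batched) and fuses each clip's
#' frames into one sample. Optional rotation augmentation adds `n_aug` fused
#' copies per clip (marked `is_aug` so cross-validation uses them for
#' training only).
#'
#' @param cohort an `hm_cohort`.
#' @param model an `hm_model` (or an [embedding_transform()] in network mode).
#' @param kind sequence kind, see [extract_sequence()].
#' @param fusion `"concat"` or `"mean_score"`.
#' @param n_aug augmented copies per clip.
#' @param augment_deg rotation range (degrees) for augmentation.
#' @param seed seed for augmentation angles.
#' @param batch feature-extraction batch size.
#' @param min_amplitude stage-detection threshold.
#' @return list with `features` (matrix for concat, list of score groups for
#'   mean_score), `meta` (one row per sample) and `domain`.
#' @export
cohort_stage_features <- function(cohort, model, kind = "NOnAOffN",
                                  fusion = "concat", n_aug = 0L,
                                  augment_deg = 10, seed = 1L, batch = 64L,
                                  min_amplitude = 0.05) {
  if (inherits(model, "embedding_transform")) {
    stopifnot(model$mode == "network_phi")
    transform <- model
    model <- transform$model
  } else transform <- NULL
  k <- length(sequence_kind_tags(kind))
  n_clip <- length(cohort$clips)
  size <- cohort$size
  n_samp <- n_clip * (1L + n_aug)
  frames <- array(0, c(size, size, 1L, n_samp * k))
  meta <- vector("list", n_samp)
  pos <- 0L
  ang_rng <- withr::with_seed(seed, stats::runif(n_clip * max(1L, n_aug),
                                                 -augment_deg, augment_deg))
  grp <- stats::setNames(cohort$subjects$group, cohort$subjects$subject_id)
  for (ci in seq_len(n_clip)) {
    clip <- cohort$clips[[ci]]
    sq <- extract_sequence(clip, detect_stages(clip$activation,
                                               min_amplitude), kind)
    for (a in 0:n_aug) {
      pos <- pos + 1L
      fr <- sq$frames
      if (a > 0) {
        ang <- ang_rng[(ci - 1L) * n_aug + a]
        for (j in seq_len(k)) {
          fr[, , 1L, j] <- rotate_image(fr[, , 1L, j], ang)
        }
      }
      frames[, , , (pos - 1L) * k + seq_len(k)] <- fr
      meta[[pos]] <- data.frame(
        subject_id = clip$subject_id, group = unname(grp[clip$subject_id]),
        expression = clip$expression, kind = kind, is_aug = a > 0,
        frame_count = k)
    }
  }
  meta <- do.call(rbind, meta)
  ## batched feature extraction over all frames at once
  feats <- NULL
  for (start in seq(1L, dim(frames)[4], by = batch)) {
    ii <- start:min(start + batch - 1L, dim(frames)[4])
    fv <- if (is.null(transform)) {
      extract_features(model, frames[, , , ii, drop = FALSE])$values
    } else {
      embed_apply(transform, frames[, , , ii, drop = FALSE])
    }
    feats <- cbind(feats, fv)
  }
  per_sample <- lapply(seq_len(n_samp), function(si) {
    feats[, (si - 1L) * k + seq_len(k), drop = FALSE]
  })
  if (fusion == "concat") {
    features <- vapply(per_sample, as.numeric, numeric(nrow(feats) * k))
    if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  } else {
    features <- lapply(per_sample, fuse_sequence, mode = "mean_score")
  }
  list(features = features, meta = meta, domain = model$domain)
}

#' Run one experiment level end-to-end
#'
#' `exp1_face`: extracts face-analysis features (`x_FA`, frozen ResNet50) for
#' single-frame and multi-frame sequence kinds and classifies PD vs HC with
#' the nested-CV SVM protocol. `exp2_au`: adapts the backbone to the 8-AU
#' task (frozen baseline, Freeze 75, Freeze 50) and trains VGG-8 / ResNet-7
#' from scratch, reports per-AU AUC/EER, then classifies PD with the adapted
#' features (`x_AU`). `exp3_pd`: trains triplet embeddings (Triplet-VGG8,
#' Triplet-ResNet7) on the cohort (`x_PD`), classifies, and compares the
#' face-analysis, action-unit and triplet models by repeated CV with
#' Kruskal-Wallis and Bonferroni-corrected Mann-Whitney tests.
#'
#' @param config configuration list from [default_config()] or
#'   [smoke_config()].
#' @param which `"exp1_face"`, `"exp2_au"` or `"exp3_pd"`.
#' @return a report bundle (list); also written as CSV/JSON under
#'   `config$out_dir` when set.
#' @export
run_experiment <- function(config = default_config(),
                           which = c("exp1_face", "exp2_au", "exp3_pd")) {
  which <- match.arg(which)
  seed <- config$seed
  cohort <- do.call(simulate_cohort,
                    c(config$cohort, list(seed = child_seed(seed, 1L))))
  bundle <- switch(which,
    exp1_face = run_exp1(config, cohort),
    exp2_au = run_exp2(config, cohort),
    exp3_pd = run_exp3(config, cohort))
  bundle$config_hash <- config_hash(config)
  bundle$seed <- seed
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir, which)
  invisible(bundle)
}

#' Batch-norm calibration images
#'
#' Faces rendered at random expressions, activation levels and identities,
#' independent of any cohort — used with [calibrate_bn()] to give a randomly
#' initialised backbone data-driven normalisation statistics.
#'
#' @param size image side in pixels.
#' @param n number of images.
#' @param seed integer seed.
#' @return array `[size, size, 1, n]`.
#' @export
bn_calibration_images <- function(size, n = 32L, seed = 99L) {
  withr::with_seed(seed, {
    x <- array(0, c(size, size, 1L, n))
    for (i in seq_len(n)) {
      expr <- sample(EXPRESSIONS, 1)
      a <- stats::runif(1, -1, 1) * expression_sign(expr)
      idv <- draw_identity()
      x[, , 1L, i] <- render_face(expression_face_params(expr, abs(a)), size,
                                  identity = idv$identity)
    }
    x
  })
}

pipeline_backbone <- function(config) {
  m <- build_resnet50(input_size = config$cohort$size, channels_in = 1L,
                      seed = child_seed(config$seed, 50L))
  calibrate_bn(m, bn_calibration_images(config$cohort$size,
                                        seed = child_seed(config$seed, 51L)))
}

run_exp1 <- function(config, cohort) {
  model <- pipeline_backbone(config)
  plan <- make_cv_plan(cohort$subjects, k = config$cv$k,
                       val_frac = config$cv$val_frac,
                       seed = child_seed(config$seed, 2L))
  reports <- list()
  for (kind in config$exp1_kinds) {
    cf <- cohort_stage_features(cohort, model, kind, fusion = config$fusion,
                                seed = child_seed(config$seed, 3L),
                                min_amplitude = config$stages$min_amplitude)
    reports[[kind]] <- run_nested_cv(cf$features, cf$meta, plan)
  }
  list(experiment = "exp1_face", reports = reports)
}

adapted_models <- function(config, train_dataset) {
  tcfg <- config$train
  seed <- config$seed
  out <- list()
  base <- pipeline_backbone(config)
  mk_frozen <- function(fraction) {
    m <- attach_au_head(base, seed = child_seed(seed, 51L))
    boundary <- if (fraction < 1) calibrated_freeze_boundary(base, fraction)
                else NULL
    m <- freeze_layers(m, fraction, boundary = boundary)
    train_au(m, train_dataset, epochs = tcfg$epochs, lr = tcfg$lr,
             batch = tcfg$batch, augment_deg = tcfg$augment_deg,
             patience = tcfg$patience, seed = child_seed(seed, 52L))$model
  }
  out$baseline <- mk_frozen(1.0)
  for (fr in sort(config$freeze_fractions, decreasing = TRUE)) {
    out[[sprintf("freeze%.0f", 100 * fr)]] <- mk_frozen(fr)
  }
  sz <- config$cohort$size
  vg <- build_vgg8(backbone_spec("vgg8", input_size = sz,
                                 channel_widths = default_vgg8_spec()$channel_widths,
                                 fc_top = default_vgg8_spec()$fc_top),
                   seed = child_seed(seed, 53L))
  rn <- build_resnet7(default_resnet7_spec(), seed = child_seed(seed, 54L))
  out$vgg8 <- train_au(vg, train_dataset, epochs = tcfg$epochs, lr = tcfg$lr,
                       batch = tcfg$batch, augment_deg = tcfg$augment_deg,
                       patience = tcfg$patience,
                       seed = child_seed(seed, 55L))$model
  out$resnet7 <- train_au(rn, train_dataset, epochs = tcfg$epochs,
                          lr = tcfg$lr, batch = tcfg$batch,
                          augment_deg = tcfg$augment_deg,
                          patience = tcfg$patience,
                          seed = child_seed(seed, 56L))$model
  out
}

run_exp2 <- function(config, cohort) {
  audata <- do.call(make_au_dataset,
                    c(list(n_images = config$au_data$n_images,
                           seed = child_seed(config$seed, 4L),
                           split_fracs = config$au_data$split_fracs,
                           size = config$cohort$size,
                           thresholds = config$au_data$thresholds)))
  models <- adapted_models(config, audata)
  au_reports <- lapply(models, evaluate_au, dataset = audata)
  plan <- make_cv_plan(cohort$subjects, k = config$cv$k,
                       val_frac = config$cv$val_frac,
                       seed = child_seed(config$seed, 2L))
  pd_reports <- list()
  for (nm in names(models)) {
    for (kind in config$exp2_kinds) {
      cf <- cohort_stage_features(cohort, models[[nm]], kind,
                                  fusion = config$fusion,
                                  seed = child_seed(config$seed, 3L),
                                  min_amplitude = config$stages$min_amplitude)
      pd_reports[[paste(nm, kind, sep = ".")]] <-
        run_nested_cv(cf$features, cf$meta, plan)
    }
  }
  list(experiment = "exp2_au", au_reports = au_reports,
       pd_reports = pd_reports, models = models)
}

#' Per-frame sample table for triplet training
#'
#' The stage frames of every clip of the given subjects, with class,
#' expression and subject labels — the sample set over which
#' expression-constrained triplets are mined.
#'
#' @param cohort an `hm_cohort`.
#' @param subject_ids subjects to include (training subjects only, so test
#'   identities stay unseen by the embedding).
#' @param kind sequence kind whose stage frames are used.
#' @param min_amplitude stage-detection threshold.
#' @return list with `x` (image array), `y` (group), `e` (expression),
#'   `subject`.
#' @export
cohort_triplet_samples <- function(cohort, subject_ids, kind = "NOnAOffN",
                                   min_amplitude = 0.05) {
  keep <- vapply(cohort$clips, function(cl) cl$subject_id %in% subject_ids,
                 logical(1))
  clips <- cohort$clips[keep]
  k <- length(sequence_kind_tags(kind))
  size <- cohort$size
  x <- array(0, c(size, size, 1L, length(clips) * k))
  y <- character(length(clips) * k)
  e <- character(length(clips) * k)
  subj <- character(length(clips) * k)
  grp <- stats::setNames(cohort$subjects$group, cohort$subjects$subject_id)
  for (ci in seq_along(clips)) {
    clip <- clips[[ci]]
    sq <- extract_sequence(clip, detect_stages(clip$activation,
                                               min_amplitude), kind)
    ii <- (ci - 1L) * k + seq_len(k)
    x[, , , ii] <- sq$frames
    y[ii] <- unname(grp[clip$subject_id])
    e[ii] <- clip$expression
    subj[ii] <- clip$subject_id
  }
  list(x = x, y = y, e = e, subject = subj)
}

run_exp3 <- function(config, cohort) {
  seed <- config$seed
  tcfg <- config$triplet
  plan <- make_cv_plan(cohort$subjects, k = config$cv$k,
                       val_frac = config$cv$val_frac,
                       seed = child_seed(seed, 2L))
  ## embedding and from-scratch training use the first fold's train+val
  ## subjects; test subjects stay unseen
  train_subjects <- c(plan$folds[[1]]$train, plan$folds[[1]]$val)
  samples <- cohort_triplet_samples(cohort, train_subjects,
                                    min_amplitude = config$stages$min_amplitude)
  spec <- triplet_spec(margin = tcfg$margin, n_triplets = tcfg$n_triplets,
                       seed = child_seed(seed, 60L))
  mk_triplet <- function(base_model) {
    m <- attach_embed_head(base_model, d_out = tcfg$d_out,
                           seed = child_seed(seed, 61L))
    train_triplet(samples, spec, model = m, normalize = tcfg$normalize,
                  epochs = tcfg$epochs, lr = tcfg$lr,
                  seed = child_seed(seed, 62L))$transform
  }
  vgg_spec <- backbone_spec("vgg8", input_size = cohort$size,
                            channel_widths = default_vgg8_spec()$channel_widths,
                            fc_top = default_vgg8_spec()$fc_top)
  trip_vgg <- mk_triplet(build_vgg8(vgg_spec, seed = child_seed(seed, 63L)))
  trip_rn7 <- mk_triplet(build_resnet7(default_resnet7_spec(),
                                       seed = child_seed(seed, 64L)))

  ## deep-learning baseline: compact networks trained from scratch on the
  ## Parkinson labels, evaluated on the first fold's test subjects
  tcfg_tr <- config$train
  scratch_reports <- list()
  test_samples <- cohort_triplet_samples(cohort, plan$folds[[1]]$test,
                                         min_amplitude =
                                           config$stages$min_amplitude)
  clip_of <- rep(seq_len(length(test_samples$y) %/% 5L), each = 5L)
  for (nm in c("vgg8", "resnet7")) {
    base <- if (nm == "vgg8") build_vgg8(vgg_spec, seed = child_seed(seed, 65L))
            else build_resnet7(default_resnet7_spec(),
                               seed = child_seed(seed, 66L))
    fit <- train_pd(base, samples, epochs = tcfg_tr$epochs, lr = tcfg_tr$lr,
                    batch = tcfg_tr$batch, augment_deg = tcfg_tr$augment_deg,
                    patience = tcfg_tr$patience, seed = child_seed(seed, 67L))
    sc <- predict_pd(fit$model, test_samples$x, clip_of)
    y_clip <- test_samples$y[seq(1L, length(test_samples$y), by = 5L)]
    scratch_reports[[nm]] <-
      if (length(unique(y_clip)) > 1L) {
        classification_metrics(sc - 0.5, y_clip)
      } else NULL
  }

  reports <- list()
  sets <- list()
  fa_model <- pipeline_backbone(config)
  srcs <- list(fa_resnet50 = fa_model, triplet_vgg8 = trip_vgg,
               triplet_resnet7 = trip_rn7)
  ## optional frozen-backbone triplet variants (embedding heads on the
  ## AU-adapted Freeze models, frozen layers kept frozen)
  if (isTRUE(config$exp3_freeze_triplets)) {
    audata <- make_au_dataset(config$au_data$n_images,
                              seed = child_seed(seed, 4L),
                              split_fracs = config$au_data$split_fracs,
                              size = cohort$size,
                              thresholds = config$au_data$thresholds)
    adapted <- adapted_models(config, audata)
    for (nm in intersect(names(adapted), c("freeze75", "freeze50"))) {
      srcs[[paste0("triplet_", nm)]] <- mk_triplet(adapted[[nm]])
    }
  }
  for (nm in names(srcs)) {
    cf <- cohort_stage_features(cohort, srcs[[nm]], "NOnAOffN",
                                fusion = config$fusion,
                                seed = child_seed(seed, 3L),
                                min_amplitude = config$stages$min_amplitude)
    rep_ <- run_nested_cv(cf$features, cf$meta, plan)
    reports[[nm]] <- rep_
    sets[[nm]] <- list(features = cf$features, meta = cf$meta,
                       params = as.list(rep_$best_params))
  }
  comparison <- compare_models(
    sets[c("fa_resnet50", "triplet_vgg8", "triplet_resnet7")],
    cohort$subjects, n_reps = config$compare$n_reps, k = config$cv$k,
    family_alpha = config$compare$family_alpha,
    seed = child_seed(seed, 70L))
  list(experiment = "exp3_pd", reports = reports,
       from_scratch = scratch_reports, comparison = comparison)
}

write_bundle <- function(bundle, out_dir, which) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(experiment = which, seed = bundle$seed,
               config_hash = bundle$config_hash)
  jsonlite::write_json(meta, file.path(out_dir, paste0(which, "_meta.json")),
                       auto_unbox = TRUE)
  dump_report <- function(rep_, name) {
    utils::write.csv(rep_$per_fold,
                     file.path(out_dir, paste0(name, "_folds.csv")),
                     row.names = FALSE)
  }
  for (nm in names(bundle$reports %||% list())) {
    dump_report(bundle$reports[[nm]], paste0(which, "_", nm))
  }
  for (nm in names(bundle$pd_reports %||% list())) {
    dump_report(bundle$pd_reports[[nm]], paste0(which, "_", nm))
  }
  for (nm in names(bundle$au_reports %||% list())) {
    utils::write.csv(bundle$au_reports[[nm]],
                     file.path(out_dir, paste0(which, "_", nm, "_au.csv")),
                     row.names = FALSE)
  }
  if (!is.null(bundle$comparison)) {
    utils::write.csv(bundle$comparison$pairwise,
                     file.path(out_dir, paste0(which, "_pairwise.csv")),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
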