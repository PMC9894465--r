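## Action-unit domain adaptation: layer freezing, AU head, multi-label
## training, and AUC / equal-error-rate evaluation.

#' The selected action units
#'
#' The eight action units used throughout: 1 (inner brow raiser), 2 (outer
#' brow raiser), 4 (brow lowerer), 5 (upper-lid raiser), 6 (cheek raiser),
#' 12 (lip-corner puller), 25 (lips part), 26 (jaw drop) — covering the
#' anger (4, 5, 25, 26), smile (6, 12, 25) and surprise (1, 2, 5, 25, 26)
#' expression groups.
#' @return integer vector of AU ids in canonical order.
#' @export
select_aus <- function() c(1L, 2L, 4L, 5L, 6L, 12L, 25L, 26L)

#' Freeze a leading fraction of a model's layers
#'
#' Freezes the first `ceiling(fraction * L)` parameter-bearing layers of the
#' trunk in forward order (L layers in total; within a residual block the main
#' path precedes the shortcut). The attached head, if any, is always
#' trainable, so `fraction = 1` with a head is the frozen-backbone baseline
#' where only the head trains. An explicit `boundary` overrides the default
#' rule (see [calibrated_freeze_boundary()] for the ResNet50 calibration).
#'
#' @param model an `hm_model`.
#' @param fraction fraction of layers to freeze, in (0, 1].
#' @param boundary optional explicit boundary layer index (layers 1..boundary
#'   are frozen).
#' @return the model with trainable flags set and a `freeze_plan` attached
#'   (`fraction`, `boundary_layer`, `trainable_count`, `frozen_count`).
#' @export
freeze_layers <- function(model, fraction, boundary = NULL) {
  if (fraction <= 0 || fraction > 1) {
    stop_validation("fraction must be in (0, 1]")
  }
  paths <- nn_param_paths(model$trunk)
  L <- length(paths)
  boundary <- as.integer(boundary %||% ceiling(fraction * L))
  for (i in seq_along(paths)) {
    lay <- nn_get_layer(model$trunk, paths[[i]])
    lay$trainable <- i > boundary
    model$trunk <- nn_set_layer(model$trunk, paths[[i]], lay)
  }
  if (!is.null(model$head)) model$head$trainable <- TRUE
  model$freeze_plan <- list(
    fraction = fraction, boundary_layer = boundary, n_layers = L,
    trainable_count = count_parameters(model, trainable_only = TRUE),
    frozen_count = count_parameters(model) -
      count_parameters(model, trainable_only = TRUE))
  model
}

#' Calibrated freeze boundary for a model
#'
#' The freezing percentages in the source framework are reported together
#' with resulting trainable-parameter counts; a plain layer-count rule does
#' not land on those totals exactly, so the boundary is calibrated once per
#' (model, fraction): among all prefix boundaries, pick the one whose
#' trainable count is closest to `target_trainable`. Default targets follow
#' the reported 20.5M (50% frozen) and 16.0M (75% frozen) for ResNet50.
#'
#' @param model an `hm_model`.
#' @param fraction freeze fraction (used to look up the default target).
#' @param target_trainable target trainable parameter count.
#' @return integer boundary layer index for [freeze_layers()].
#' @export
calibrated_freeze_boundary <- function(model, fraction,
                                       target_trainable = NULL) {
  if (is.null(target_trainable)) {
    target_trainable <- switch(as.character(fraction),
                               "0.5" = 20.5e6, "0.75" = 16.0e6, NULL)
    if (is.null(target_trainable)) {
      stop_validation("no default trainable-count target for fraction ",
                      fraction, "; supply target_trainable")
    }
  }
  paths <- nn_param_paths(model$trunk)
  counts <- vapply(paths, function(p) {
    nn_layer_param_count(nn_get_layer(model$trunk, p))
  }, numeric(1))
  head_count <- if (is.null(model$head)) 0 else nn_layer_param_count(model$head)
  total <- sum(counts) + head_count
  trainable_at <- total - cumsum(counts)
  which.min(abs(trainable_at - target_trainable))
}

#' Attach an action-unit classification head
#'
#' Replaces the model's head by a fully-connected sigmoid layer of width
#' `n_aus` on top of the feature tap. The head is always trainable.
#'
#' @param model an `hm_model` (feature mode or with an existing head).
#' @param n_aus number of action units (default 8).
#' @param seed optional seed for head initialisation.
#' @return the model with the new head.
#' @export
attach_au_head <- function(model, n_aus = 8L, seed = NULL) {
  tap <- model$feature_tap %||% length(model$trunk)
  model$trunk <- model$trunk[seq_len(tap)]
  model$feature_tap <- tap
  mk <- function() layer_dense(model$feature_dim, as.integer(n_aus))
  model$head <- if (is.null(seed)) mk() else withr::with_seed(seed, mk())
  model$head$trainable <- TRUE
  model$head_activation <- "sigmoid"
  model
}

## Multi-label binary cross-entropy on logits; returns loss and logit grad.
bce_loss <- function(z, t) {
  o <- stats::plogis(z)
  eps <- 1e-12
  loss <- -mean(t * log(o + eps) + (1 - t) * log(1 - o + eps))
  list(loss = loss, dz = (o - t) / length(z), scores = o)
}

## Rotate a grayscale image matrix about its centre, bilinear, zero fill.
rotate_image <- function(img, angle) {
  out <- as.matrix(EBImage::rotate(img, angle, output.dim = dim(img),
                                   bg.col = 0))
  pmin(pmax(out, 0), 1)
}

augment_batch <- function(xb, augment_deg) {
  if (augment_deg <= 0) return(xb)
  for (j in seq_len(dim(xb)[4])) {
    ang <- stats::runif(1, -augment_deg, augment_deg)
    xb[, , 1L, j] <- rotate_image(xb[, , 1L, j], ang)
  }
  xb
}

#' Train a model on an action-unit dataset
#'
#' Minimises the per-AU sigmoid binary cross-entropy (averaged over AUs and
#' images) over the trainable layers only, with Adam, optional random-rotation
#' augmentation of the training images, and early stopping on validation
#' loss. Frozen layers are untouched (bit-identical parameters before and
#' after; frozen batchnorm runs in inference mode).
#'
#' @param model an `hm_model` with an AU head ([attach_au_head()] or a
#'   from-scratch compact architecture).
#' @param dataset an `hm_au_dataset` with non-empty train and val splits.
#' @param epochs,lr,batch optimisation settings (defaults 30, 1e-3, 32).
#' @param augment_deg rotation augmentation range in degrees (uniform in
#'   `[-augment_deg, augment_deg]`; 0 disables).
#' @param patience early-stopping patience on validation loss.
#' @param seed integer seed controlling shuffling, dropout and augmentation.
#' @param verbose print per-epoch losses.
#' @return list with `model` (best validation weights, domain `"AU"`) and
#'   `history` (data frame epoch / train_loss / val_loss).
#' @export
train_au <- function(model, dataset, epochs = 30L, lr = 1e-3, batch = 32L,
                     augment_deg = 10, patience = 5L, seed = 1L,
                     verbose = FALSE) {
  tr <- which(dataset$split == "train")
  va <- which(dataset$split == "val")
  if (!length(tr) || !length(va)) {
    stop_validation("dataset needs non-empty train and val splits")
  }
  x_tr <- dataset$images[, , , tr, drop = FALSE]
  t_tr <- t(dataset$labels[tr, , drop = FALSE])
  x_va <- dataset$images[, , , va, drop = FALSE]
  t_va <- t(dataset$labels[va, , drop = FALSE])
  res <- withr::with_seed(seed, train_loop_bce(
    model, x_tr, t_tr, x_va, t_va, epochs = epochs, lr = lr, batch = batch,
    augment_deg = augment_deg, patience = patience, verbose = verbose))
  res$model$domain <- "AU"
  res
}

## Shared BCE training loop (AU heads and binary PD heads). The frozen
## prefix of the network is a fixed function (frozen batchnorm runs in
## inference mode), so when no augmentation perturbs the inputs its outputs
## are precomputed once and only the trainable tail iterates.
train_loop_bce <- function(model, x_tr, t_tr, x_va, t_va, epochs, lr, batch,
                           augment_deg, patience, verbose = FALSE) {
  layers <- c(model$trunk, list(model$head))
  nt <- length(model$trunk)
  split <- nn_frozen_prefix(layers)
  prefix <- layers[seq_len(split)]
  tail_l <- layers[(split + 1L):length(layers)]
  prefix_fwd <- function(x) {
    if (split == 0L) return(x)
    out <- NULL
    n <- dim(x)[4]
    for (start in seq(1L, n, by = 64L)) {
      ii <- start:min(start + 63L, n)
      y <- nn_forward_layers(prefix, x[, , , ii, drop = FALSE],
                             train = FALSE)$y
      out <- if (is.matrix(y)) cbind(out, y) else {
        if (is.null(out)) y else {
          d <- dim(out); d[4] <- d[4] + dim(y)[4]
          array(c(out, y), d)
        }
      }
    }
    out
  }
  cache_prefix <- augment_deg <= 0
  if (cache_prefix) {
    z_tr <- prefix_fwd(x_tr)
    z_va <- prefix_fwd(x_va)
  } else {
    z_va <- prefix_fwd(x_va)
  }
  state <- adam_init()
  n <- dim(x_tr)[4]
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(val = Inf, tail = tail_l, epoch = 0L)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, n, by = batch)) {
      ii <- ord[start:min(start + batch - 1L, n)]
      zb <- if (cache_prefix) {
        nn_slice_samples(z_tr, ii)
      } else {
        prefix_fwd(augment_batch(x_tr[, , , ii, drop = FALSE], augment_deg))
      }
      tb <- t_tr[, ii, drop = FALSE]
      fw <- nn_forward_layers(tail_l, zb, train = TRUE)
      lb <- bce_loss(fw$y, tb)
      if (!is.finite(lb$loss)) {
        stop("training aborted: non-finite loss at epoch ", ep,
             " (learning rate too high or degenerate inputs)")
      }
      bw <- nn_backward_layers(fw$layers, fw$caches, lb$dz)
      st <- adam_step(fw$layers, bw$grads, state, lr = lr)
      tail_l <- st$layers
      state <- st$state
      ep_loss <- ep_loss + lb$loss
      nb <- nb + 1L
    }
    val <- bce_loss(nn_forward_layers(tail_l, z_va, train = FALSE)$y,
                    t_va)$loss
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = val))
    if (verbose) {
      message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss / nb, val))
    }
    if (val < best$val - 1e-9) {
      best <- list(val = val, tail = tail_l, epoch = ep)
    } else if (ep - best$epoch >= patience) break
  }
  layers <- c(prefix, best$tail)
  model$trunk <- layers[seq_len(nt)]
  model$head <- layers[[nt + 1L]]
  list(model = model, history = history)
}

#' Predict action-unit probabilities
#'
#' @param model trained `hm_model` with sigmoid AU head.
#' @param images image array (`[H, W, 1, N]` or compatible).
#' @param batch forward batch size.
#' @return matrix `n_aus` x N of sigmoid scores in (0, 1).
#' @export
predict_au <- function(model, images, batch = 64L) {
  x <- as_image_batch(images, model$spec$channels_in)
  n <- dim(x)[4]
  layers <- c(model$trunk, list(model$head))
  out <- NULL
  for (start in seq(1L, n, by = batch)) {
    ii <- start:min(start + batch - 1L, n)
    y <- nn_forward_layers(layers, x[, , , ii, drop = FALSE], train = FALSE)$y
    out <- cbind(out, y)
  }
  stats::plogis(out)
}

#' Equal error rate of a score vector
#'
#' The operating point where the false-positive rate equals the false-negative
#' rate as the decision threshold sweeps the scores; when no threshold attains
#' exact equality the crossing is linearly interpolated between the two
#' adjacent thresholds. Symmetric under relabelling classes with score
#' negation.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1, logical, or a 2-level factor where the
#'   second level is positive).
#' @return EER in percent.
#' @export
compute_eer <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L) {
    stop_validation("both classes must be present to compute an EER")
  }
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  ## sweep thresholds from +Inf down through each distinct score
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  keep <- c(diff(scores[ord]) != 0, TRUE)   # last index of each tied block
  fpr <- c(0, fp[keep] / n_neg)
  fnr <- c(1, 1 - tp[keep] / n_pos)
  k <- which(fnr <= fpr)[1]
  if (fnr[k] == fpr[k]) return(100 * fpr[k])
  ## interpolate between points k-1 (fnr > fpr) and k (fnr < fpr)
  dfn <- fnr[k] - fnr[k - 1]
  dfp <- fpr[k] - fpr[k - 1]
  t <- (fpr[k - 1] - fnr[k - 1]) / (dfn - dfp)
  100 * (fpr[k - 1] + t * dfp)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) as.integer(labels == levels(labels)[2L])
  else if (is.logical(labels)) as.integer(labels)
  else as.integer(labels != 0)
}

#' Evaluate action-unit detection
#'
#' Per-AU ROC-AUC over the sigmoid scores and equal error rate on a dataset
#' split. AUs with single-class labels in the split are reported as undefined
#' (`defined = FALSE`) rather than dropped.
#'
#' @param model trained `hm_model` with AU head.
#' @param dataset an `hm_au_dataset`.
#' @param split which split to evaluate (default `"test"`).
#' @return data frame with columns `au`, `auc`, `eer`, `n_pos`, `n_neg`,
#'   `defined`.
#' @export
evaluate_au <- function(model, dataset, split = "test") {
  ii <- which(dataset$split == split)
  if (!length(ii)) stop_validation("empty split: ", split)
  scores <- predict_au(model, dataset$images[, , , ii, drop = FALSE])
  labels <- dataset$labels[ii, , drop = FALSE]
  aus <- select_aus()
  out <- data.frame(au = aus, auc = NA_real_, eer = NA_real_,
                    n_pos = colSums(labels), n_neg = colSums(1 - labels),
                    defined = FALSE)
  for (j in seq_along(aus)) {
    y <- labels[, j]
    if (length(unique(y)) < 2L) next
    out$auc[j] <- as.numeric(pROC::auc(
      pROC::roc(y, scores[j, ], direction = "<", quiet = TRUE)))
    out$eer[j] <- compute_eer(scores[j, ], y)
    out$defined[j] <- TRUE
  }
  out
}

#' Train a binary Parkinson classifier from scratch
#'
#' Trains a network with a 1-unit sigmoid head to discriminate patients from
#' controls directly from stage frames (binary cross-entropy, Adam), the
#' deep-learning baseline that bypasses feature extraction + SVM. Per-clip
#' scores at prediction time are the mean of the per-frame probabilities.
#'
#' @param model an `hm_model` (the head is replaced by a 1-unit head).
#' @param samples training samples from [cohort_triplet_samples()] (`x`
#'   images, `y` group labels); an inner validation split is carved off by
#'   subject.
#' @param epochs,lr,batch,augment_deg,patience,seed as in [train_au()].
#' @param val_frac fraction of training subjects held out for early
#'   stopping.
#' @return list with `model` (domain `"PD"`) and `history`.
#' @export
train_pd <- function(model, samples, epochs = 30L, lr = 1e-3, batch = 32L,
                     augment_deg = 10, patience = 5L, val_frac = 0.2,
                     seed = 1L) {
  tap <- model$feature_tap %||% length(model$trunk)
  model$trunk <- model$trunk[seq_len(tap)]
  mk <- function() layer_dense(model$feature_dim, 1L)
  model$head <- withr::with_seed(child_seed(seed, 1L), mk())
  model$head$trainable <- TRUE
  model$head_activation <- "sigmoid"
  subj <- unique(samples$subject)
  va_subj <- withr::with_seed(child_seed(seed, 2L), {
    unlist(lapply(split(subj, samples$y[match(subj, samples$subject)]),
                  function(ids) {
                    sample(ids, max(1L, round(val_frac * length(ids))))
                  }), use.names = FALSE)
  })
  va <- samples$subject %in% va_subj
  t_all <- matrix(as.numeric(samples$y == "PD"), nrow = 1L)
  res <- withr::with_seed(child_seed(seed, 3L), train_loop_bce(
    model,
    samples$x[, , , !va, drop = FALSE], t_all[, !va, drop = FALSE],
    samples$x[, , , va, drop = FALSE], t_all[, va, drop = FALSE],
    epochs = epochs, lr = lr, batch = batch, augment_deg = augment_deg,
    patience = patience))
  res$model$domain <- "PD"
  res
}

#' Per-clip Parkinson scores from a trained classifier
#'
#' @param model model from [train_pd()].
#' @param x image array of stage frames.
#' @param clip_of integer clip index per frame; per-clip scores are the mean
#'   frame probability.
#' @return numeric vector of per-clip scores in (0, 1).
#' @export
predict_pd <- function(model, x, clip_of) {
  p <- predict_au(model, x)   # 1 x N sigmoid scores
  as.numeric(tapply(as.numeric(p), clip_of, mean))
}
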