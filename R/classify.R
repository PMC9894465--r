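## PD vs HC classification: sequence feature fusion, SVM grid search under
## nested subject-independent cross-validation, metrics, and the repeated-CV
## statistical comparison of models.

#' The SVM hyper-parameter grid
#'
#' Linear and Gaussian kernels with `C` in 10^-4..10^3 (8 points) and, for the
#' Gaussian kernel, `gamma` in 10^-4..10^3 (8 points): 64 Gaussian + 8 linear
#' configurations.
#'
#' @return data frame with columns `kernel`, `C`, `gamma` (NA for linear), in
#'   canonical order (linear first, then Gaussian; C ascending, then gamma).
#' @export
svm_grid <- function() {
  cc <- 10^(-4:3)
  rad <- expand.grid(kernel = "radial", C = cc, gamma = cc,
                     stringsAsFactors = FALSE)
  rad <- rad[order(rad$C, rad$gamma), ]
  out <- rbind(data.frame(kernel = "linear", C = cc, gamma = NA_real_), rad)
  rownames(out) <- NULL
  out
}

#' Fuse per-frame features of a sequence
#'
#' `concat` concatenates the per-frame vectors in temporal order into one
#' `n_frames * d` vector; `mean_score` defers fusion to decision time (the
#' per-frame SVM scores of the group are averaged), returning a marker.
#'
#' @param frame_features d x k matrix (columns = frames, temporal order) or an
#'   `hm_features` object.
#' @param mode `"concat"` or `"mean_score"`.
#' @return for `concat`, a numeric vector of length `k * d`; for
#'   `mean_score`, an object of class `hm_score_group` carrying the per-frame
#'   features.
#' @export
fuse_sequence <- function(frame_features, mode = c("concat", "mean_score")) {
  mode <- match.arg(mode)
  m <- if (inherits(frame_features, "hm_features")) frame_features$values
       else as.matrix(frame_features)
  if (ncol(m) < 1L) stop_validation("need at least one frame feature")
  if (mode == "concat") return(as.numeric(m))
  structure(list(frames = m), class = "hm_score_group")
}

#' Subject-independent nested cross-validation plan
#'
#' Subjects are split into `k` outer test folds, stratified by class; within
#' each fold the remaining subjects are split into train and validation sets
#' (fraction `val_frac` to validation, stratified). All splits are at the
#' subject level so no identity crosses partitions.
#'
#' @param subjects data frame with `subject_id` and `group` columns (an
#'   `hm_cohort$subjects` works directly).
#' @param k number of outer folds (default 5).
#' @param val_frac fraction of non-test subjects used for validation.
#' @param seed integer seed.
#' @return a `cv_plan`: list of folds, each with `train`, `val`, `test`
#'   subject-id vectors.
#' @export
make_cv_plan <- function(subjects, k = 5L, val_frac = 0.2, seed = 1L) {
  if (inherits(subjects, "hm_cohort")) subjects <- subjects$subjects
  groups <- split(subjects$subject_id, subjects$group)
  if (any(vapply(groups, length, numeric(1)) < k)) {
    stop_validation("each class needs at least k subjects")
  }
  build <- function() {
    chunks <- lapply(groups, function(ids) {
      ids <- sample(ids)
      split(ids, rep_len(seq_len(k), length(ids)))
    })
    folds <- lapply(seq_len(k), function(i) {
      test <- unlist(lapply(chunks, `[[`, i), use.names = FALSE)
      rest <- setdiff(subjects$subject_id, test)
      val <- unlist(lapply(groups, function(ids) {
        pool <- sample(intersect(ids, rest))
        pool[seq_len(max(1L, round(val_frac * length(pool))))]
      }), use.names = FALSE)
      list(train = setdiff(rest, val), val = val, test = test)
    })
    folds
  }
  structure(list(folds = withr::with_seed(seed, build()), k = as.integer(k),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

#' Audit a cross-validation plan for subject leakage
#'
#' Verifies that within every fold the train/val/test subject sets are
#' pairwise disjoint, that the test sets across folds partition all subjects,
#' and (when sample metadata is supplied) that every sample follows its
#' subject. Called internally by every [run_nested_cv()] execution.
#'
#' @param plan a `cv_plan`.
#' @param meta optional sample metadata with `subject_id`.
#' @return TRUE invisibly; stops with a descriptive error on violation.
#' @export
audit_cv_plan <- function(plan, meta = NULL) {
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  if (anyDuplicated(all_test)) {
    stop("subject leakage: a subject appears in multiple test folds")
  }
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    ov <- c(intersect(f$train, f$val), intersect(f$train, f$test),
            intersect(f$val, f$test))
    if (length(ov)) {
      stop("subject leakage in fold ", i, ": ", paste(ov, collapse = ", "))
    }
    if (!is.null(meta)) {
      unknown <- setdiff(unique(meta$subject_id),
                         c(f$train, f$val, f$test))
      if (length(unknown)) {
        stop("fold ", i, " does not cover subjects: ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' Classification metrics with PD as the positive class
#'
#' Accuracy, sensitivity (PD recall), specificity (HC recall) and F1 in
#' percent, plus threshold-free ROC-AUC over the decision scores.
#'
#' @param scores signed decision scores (higher = more PD-like).
#' @param labels 2-level labels; `"PD"` (or the second factor level) is
#'   positive.
#' @param threshold decision threshold on the score (default 0).
#' @return named list `acc`, `sens`, `spec`, `f1` (percent), `auc` (0..1).
#' @export
classification_metrics <- function(scores, labels, threshold = 0) {
  y <- as_pd_labels(labels)
  if (length(unique(y)) < 2L) {
    stop_validation("both classes must be present in labels")
  }
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- tp / (tp + fn)
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  auc <- as.numeric(pROC::auc(pROC::roc(y, scores, direction = "<",
                                        quiet = TRUE)))
  list(acc = 100 * (tp + tn) / length(y), sens = 100 * rec,
       spec = 100 * tn / (tn + fp), f1 = 100 * f1, auc = auc)
}

as_pd_labels <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2L]))
  if (is.character(labels)) return(as.integer(labels == "PD"))
  as.integer(labels != 0)
}

## SVM machinery on precomputed kernel matrices. Features are standardised
## with fitting-set statistics once per phase; the Gram and squared-distance
## matrices are then reused across the whole hyper-parameter grid, which makes
## the 72-point grid search cheap.
svm_phase <- function(x_fit, x_eval) {
  mu <- rowMeans(x_fit)
  sd_ <- sqrt(pmax(rowMeans(x_fit^2) - mu^2, 0))
  sd_[sd_ < 1e-12] <- 1
  zf <- (x_fit - mu) / sd_
  ze <- (x_eval - mu) / sd_
  gff <- crossprod(zf)
  gef <- crossprod(ze, zf)
  nf2 <- diag(gff)
  ne2 <- colSums(ze^2)
  list(gff = gff, gef = gef,
       d2ff = pmax(outer(nf2, nf2, `+`) - 2 * gff, 0),
       d2ef = pmax(outer(ne2, nf2, `+`) - 2 * gef, 0))
}

## Signed PD-positive decision scores for one grid configuration.
svm_kernel_decision <- function(phase, y_fit, kernel, C, gamma = NULL) {
  if (kernel == "linear") {
    kff <- phase$gff; kef <- phase$gef
  } else {
    kff <- exp(-gamma * phase$d2ff); kef <- exp(-gamma * phase$d2ef)
  }
  y <- factor(y_fit, levels = c("HC", "PD"))
  fit <- try(kernlab::ksvm(kernlab::as.kernelMatrix(kff), y, type = "C-svc",
                           C = C, fit = FALSE), silent = TRUE)
  if (inherits(fit, "try-error")) return(rep(0, nrow(kef)))
  sv <- kernlab::SVindex(fit)
  dec <- function(k) {
    as.numeric(kernlab::predict(
      fit, kernlab::as.kernelMatrix(k[, sv, drop = FALSE]),
      type = "decision"))
  }
  ## align the decision sign empirically so that positive = PD
  dfit <- dec(kff)
  sgn <- if (mean(dfit[y == "PD"]) >= mean(dfit[y == "HC"])) 1 else -1
  sgn * dec(kef)
}

#' Nested cross-validation with SVM grid search
#'
#' For every outer fold: each grid configuration is fit on the training
#' subjects and scored on the validation subjects; the best configuration
#' (highest validation accuracy, ties broken towards linear kernel, then
#' smaller C, then smaller gamma) is refit on train+validation and evaluated
#' on the test subjects. Augmented samples (metadata `is_aug`) are used for
#' fitting only, never for validation or test scoring. A subject-leakage
#' audit runs on every call.
#'
#' @param features d x n matrix, one column per sample, or a list of
#'   `hm_score_group` objects (mean-score fusion).
#' @param meta data frame with one row per sample: `subject_id`, `group`
#'   (`"PD"`/`"HC"`), optionally `is_aug` and `frame_count`.
#' @param plan a [make_cv_plan()] plan covering the subjects.
#' @param grid hyper-parameter grid, default [svm_grid()].
#' @return an `hm_metrics_report`: per-fold metrics, aggregate mean/sd,
#'   selected hyper-parameters per fold and their mode.
#' @export
run_nested_cv <- function(features, meta, plan, grid = svm_grid()) {
  audit_cv_plan(plan, meta)
  score_groups <- is.list(features) && !is.matrix(features)
  if (score_groups) {
    frame_mat <- do.call(cbind, lapply(features, function(g) g$frames))
    frames_per <- vapply(features, function(g) ncol(g$frames), numeric(1))
    group_of_frame <- rep(seq_along(features), frames_per)
  }
  is_aug <- meta$is_aug %||% rep(FALSE, nrow(meta))
  fold_rows <- list()
  selections <- list()
  for (fi in seq_along(plan$folds)) {
    f <- plan$folds[[fi]]
    idx_of <- function(ids, allow_aug) {
      which(meta$subject_id %in% ids & (allow_aug | !is_aug))
    }
    tr <- idx_of(f$train, TRUE)
    va <- idx_of(f$val, FALSE)
    te <- idx_of(f$test, FALSE)
    make_phase <- function(fit_idx, eval_idx) {
      if (!score_groups) {
        ph <- svm_phase(features[, fit_idx, drop = FALSE],
                        features[, eval_idx, drop = FALSE])
        ph$y_fit <- meta$group[fit_idx]
        ph$agg <- NULL
      } else {
        ## mean-score fusion: per-frame SVM, scores averaged per group
        fit_fr <- which(group_of_frame %in% fit_idx)
        eval_fr <- which(group_of_frame %in% eval_idx)
        ph <- svm_phase(frame_mat[, fit_fr, drop = FALSE],
                        frame_mat[, eval_fr, drop = FALSE])
        ph$y_fit <- meta$group[group_of_frame[fit_fr]]
        ph$agg <- group_of_frame[eval_fr]
      }
      ph
    }
    get_scores <- function(ph, kernel, C, gamma) {
      sc <- svm_kernel_decision(ph, ph$y_fit, kernel, C, gamma)
      if (!is.null(ph$agg)) sc <- as.numeric(tapply(sc, ph$agg, mean))
      sc
    }
    ph_sel <- make_phase(tr, va)
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      g <- grid[gi, ]
      sc <- get_scores(ph_sel, g$kernel, g$C, g$gamma)
      acc <- mean((sc > 0) == (as_pd_labels(meta$group[va]) == 1))
      if (is.null(best) || acc > best$acc + 1e-12) {
        best <- list(acc = acc, kernel = g$kernel, C = g$C, gamma = g$gamma)
      }
    }
    selections[[fi]] <- data.frame(kernel = best$kernel, C = best$C,
                                   gamma = best$gamma)
    ph_fin <- make_phase(c(tr, va), te)
    sc_te <- get_scores(ph_fin, best$kernel, best$C, best$gamma)
    y_te <- meta$group[te]
    if (length(unique(y_te)) < 2L) {
      warning("fold ", fi, " has a single-class test set; excluded from ",
              "averages")
      fold_rows[fi] <- list(NULL)
      next
    }
    m <- classification_metrics(sc_te, y_te)
    fold_rows[[fi]] <- data.frame(fold = fi, acc = m$acc, sens = m$sens,
                                  spec = m$spec, f1 = m$f1, auc = m$auc,
                                  n_test = length(te))
  }
  per_fold <- do.call(rbind, fold_rows)
  sel <- do.call(rbind, selections)
  agg <- list(
    acc = c(mean = mean(per_fold$acc), sd = stats::sd(per_fold$acc)),
    sens = c(mean = mean(per_fold$sens), sd = stats::sd(per_fold$sens)),
    spec = c(mean = mean(per_fold$spec), sd = stats::sd(per_fold$spec)),
    f1 = c(mean = mean(per_fold$f1), sd = stats::sd(per_fold$f1)),
    auc = c(mean = mean(per_fold$auc), sd = stats::sd(per_fold$auc)))
  structure(list(per_fold = per_fold, aggregate = agg, selections = sel,
                 best_params = mode_hyperparams(sel)),
            class = "hm_metrics_report")
}

#' Mode of per-fold hyper-parameter selections
#'
#' The most frequent (kernel, C, gamma) tuple across folds; ties are broken
#' towards the smallest C, then the smallest gamma (linear kernel sorts
#' before Gaussian on residual ties).
#'
#' @param selections data frame with columns `kernel`, `C`, `gamma`.
#' @return single-row data frame.
#' @export
mode_hyperparams <- function(selections) {
  if (!nrow(selections)) stop_validation("need at least one fold selection")
  key <- paste(selections$kernel, selections$C, selections$gamma)
  tab <- table(key)
  cand <- selections[key %in% names(tab)[tab == max(tab)], , drop = FALSE]
  cand <- cand[order(cand$C, cand$gamma, cand$kernel,
                     na.last = FALSE), , drop = FALSE]
  cand[1, , drop = FALSE]
}

#' Compare classification models by repeated cross-validation
#'
#' Runs `n_reps` re-seeded subject-independent cross-validations per model
#' with fixed hyper-parameters, collects per-repetition mean accuracies, and
#' tests for differences with a Kruskal-Wallis test followed by pairwise
#' Mann-Whitney U tests under Bonferroni correction
#' (`alpha_cor = family_alpha / n_pairs`).
#'
#' @param model_sets named list; each element is a list with `features`
#'   (d x n matrix), `meta` (sample metadata as in [run_nested_cv()]) and
#'   `params` (list `kernel`, `C`, `gamma`).
#' @param subjects subject data frame used to build the CV plans.
#' @param n_reps repetitions (default 25).
#' @param k folds per repetition.
#' @param family_alpha family-wise significance level (default 0.05).
#' @param seed integer seed; repetition r uses a child seed.
#' @return an `hm_comparison_report`: accuracy matrix (reps x models),
#'   Kruskal-Wallis p, pairwise table with Mann-Whitney p-values, `alpha_cor`
#'   and reject flags.
#' @export
compare_models <- function(model_sets, subjects, n_reps = 25L, k = 5L,
                           family_alpha = 0.05, seed = 1L) {
  if (length(model_sets) < 2L) stop_validation("need at least two models")
  if (n_reps < 2L) stop_validation("n_reps must be >= 2")
  nm <- names(model_sets) %||% paste0("model", seq_along(model_sets))
  accs <- matrix(NA_real_, n_reps, length(model_sets),
                 dimnames = list(NULL, nm))
  for (r in seq_len(n_reps)) {
    plan <- make_cv_plan(subjects, k = k, seed = child_seed(seed, r))
    for (mi in seq_along(model_sets)) {
      ms <- model_sets[[mi]]
      audit_cv_plan(plan, ms$meta)
      fold_acc <- vapply(plan$folds, function(f) {
        is_aug <- ms$meta$is_aug %||% rep(FALSE, nrow(ms$meta))
        tr <- which(ms$meta$subject_id %in% c(f$train, f$val))
        te <- which(ms$meta$subject_id %in% f$test & !is_aug)
        if (length(unique(ms$meta$group[te])) < 2L) return(NA_real_)
        ph <- svm_phase(ms$features[, tr, drop = FALSE],
                        ms$features[, te, drop = FALSE])
        sc <- svm_kernel_decision(ph, ms$meta$group[tr], ms$params$kernel,
                                  ms$params$C, ms$params$gamma)
        100 * mean((sc > 0) == (as_pd_labels(ms$meta$group[te]) == 1))
      }, numeric(1))
      accs[r, mi] <- mean(fold_acc, na.rm = TRUE)
    }
  }
  groups <- factor(rep(nm, each = n_reps), levels = nm)
  kw <- stats::kruskal.test(as.numeric(accs), groups)
  pairs <- utils::combn(nm, 2)
  alpha_cor <- family_alpha / ncol(pairs)
  pw <- data.frame(model_a = pairs[1, ], model_b = pairs[2, ],
                   p_value = NA_real_, reject = NA)
  for (j in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(accs[, pairs[1, j]],
                                              accs[, pairs[2, j]]))
    pw$p_value[j] <- wt$p.value
    pw$reject[j] <- wt$p.value < alpha_cor
  }
  structure(list(accuracies = accs, kruskal_p = kw$p.value,
                 pairwise = pw, alpha_cor = alpha_cor,
                 family_alpha = family_alpha),
            class = "hm_comparison_report")
}

#' @export
print.hm_metrics_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Acc %.1f+/-%.1f  Sens %.1f+/-%.1f  Spec %.1f+/-%.1f  F1 %.1f+/-%.1f  AUC %.2f\n",
              a$acc[1], a$acc[2], a$sens[1], a$sens[2], a$spec[1], a$spec[2],
              a$f1[1], a$f1[2], a$auc[1]))
  bp <- x$best_params
  cat(sprintf("selected: %s kernel, C=%g%s\n", bp$kernel, bp$C,
              if (is.na(bp$gamma)) "" else sprintf(", gamma=%g", bp$gamma)))
  invisible(x)
}

#' @export
print.hm_comparison_report <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis p = %.3g; alpha_cor = %.3g\n", x$kruskal_p,
              x$alpha_cor))
  print(x$pairwise)
  invisible(x)
}
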