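## Independent brute-force oracles used to validate the package's vectorised
## implementations. These deliberately use the slowest, most literal
## formulation of each definition.

## EER by explicit threshold sweep: walk every distinct score as a threshold,
## record (FPR, FNR), return the crossing (interpolated between the adjacent
## thresholds straddling the sign change of FNR - FPR), in percent.
oracle_eer <- function(scores, labels) {
  y <- as.integer(labels != 0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  fpr <- numeric(length(thr))
  fnr <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    fpr[i] <- sum(pred & y == 0) / sum(y == 0)
    fnr[i] <- sum(!pred & y == 1) / sum(y == 1)
  }
  k <- which(fnr <= fpr)[1]
  if (fnr[k] == fpr[k]) return(100 * fpr[k])
  t <- (fpr[k - 1] - fnr[k - 1]) /
    ((fnr[k] - fnr[k - 1]) - (fpr[k] - fpr[k - 1]))
  100 * (fpr[k - 1] + t * (fpr[k] - fpr[k - 1]))
}

## Triplet loss by a plain per-triplet loop.
oracle_triplet_loss <- function(features, triplets, T_mat, alpha) {
  total <- 0
  for (i in seq_len(nrow(triplets))) {
    a <- features[, triplets$a[i]]
    p <- features[, triplets$p[i]]
    n <- features[, triplets$n[i]]
    d_ap <- sum((T_mat %*% a - T_mat %*% p)^2)
    d_an <- sum((T_mat %*% a - T_mat %*% n)^2)
    total <- total + max(d_ap - d_an + alpha, 0)
  }
  total
}

## Count of valid triplets by exhaustive triple loop: anchor/positive share
## the class but not the expression; the negative is the other class.
oracle_triplet_count <- function(y, e) {
  n <- length(y)
  count <- 0L
  for (a in seq_len(n)) for (p in seq_len(n)) for (ng in seq_len(n)) {
    if (a != p && y[a] == y[p] && e[a] != e[p] && y[ng] != y[a]) {
      count <- count + 1L
    }
  }
  count
}

## Parameter count by walking every layer's parameter tensors and summing
## their lengths (independent of count_parameters's own bookkeeping).
oracle_param_count <- function(model) {
  walk <- function(layers) {
    total <- 0
    for (lay in layers) {
      if (identical(lay$type, "resblock")) {
        total <- total + walk(lay$main)
        if (!is.null(lay$shortcut)) total <- total + walk(lay$shortcut)
      } else {
        for (nm in c("W", "b", "gamma", "beta")) {
          if (!is.null(lay[[nm]])) total <- total + length(lay[[nm]])
        }
      }
    }
    total
  }
  walk(model$trunk) + if (is.null(model$head)) 0 else {
    length(model$head$W) + length(model$head$b)
  }
}

## Confusion-matrix metrics by direct counting.
oracle_metrics <- function(scores, labels, threshold = 0) {
  y <- as.integer(labels == "PD")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred & y); fn <- sum(!pred & y)
  tn <- sum(!pred & !y); fp <- sum(pred & !y)
  prec <- if (tp + fp) tp / (tp + fp) else 0
  rec <- tp / (tp + fn)
  list(acc = 100 * (tp + tn) / length(y),
       sens = 100 * rec,
       spec = 100 * tn / (tn + fp),
       f1 = 100 * if (prec + rec) 2 * prec * rec / (prec + rec) else 0)
}

## Small synthetic feature set with controllable class separation:
## `n_subj` subjects per class, `per_subj` samples each, features are
## subject-level gaussian noise plus `sep` times a class direction.
toy_feature_set <- function(n_subj = 8, per_subj = 5, d = 6, sep = 4,
                            seed = 1) {
  withr::with_seed(seed, {
    subj <- rep(sprintf("S%02d", seq_len(2 * n_subj)), each = per_subj)
    grp <- rep(c("PD", "HC"), each = n_subj * per_subj)
    n <- length(subj)
    x <- matrix(stats::rnorm(d * n), d, n)
    x[1, grp == "PD"] <- x[1, grp == "PD"] + sep
    meta <- data.frame(subject_id = subj, group = grp,
                       expression = rep_len(c("smile", "anger", "surprise",
                                              "wink_l", "wink_r"), n))
    list(features = x, meta = meta,
         subjects = data.frame(subject_id = unique(subj),
                               group = rep(c("PD", "HC"), each = n_subj)))
  })
}
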