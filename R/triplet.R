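## Triplet-loss metric learning for the Parkinson domain ----------------------
##
## The learned similarity is a Mahalanobis-form squared distance
## d^2(x_i, x_j) = (x_i - x_j)' M (x_i - x_j) with M = T'T positive
## semi-definite, equivalently ||T x_i - T x_j||^2; the linear map T
## generalises to a network embedding Phi. Training minimises the hinge
## triplet loss sum [d^2(a, p) - d^2(a, n) + alpha]_+ over triplets whose
## anchor and positive share the class but differ in expression, and whose
## negative comes from the other class.

#' Embedding transform
#'
#' Either a linear map `T` (mode `"linear_T"`, so the metric matrix is
#' `M = T'T`) or a network with an embedding head (mode `"network_phi"`).
#' Embeddings can optionally be L2-normalised before distances are taken.
#'
#' @param mode `"linear_T"` or `"network_phi"`.
#' @param T d_out x d_in matrix (linear mode).
#' @param model `hm_model` with embedding head (network mode).
#' @param normalize L2-normalise embeddings before distance computation.
#' @return an `embedding_transform`.
#' @export
embedding_transform <- function(mode = c("linear_T", "network_phi"), T = NULL,
                                model = NULL, normalize = FALSE) {
  mode <- match.arg(mode)
  if (mode == "linear_T" && is.null(T)) stop_validation("linear mode needs T")
  if (mode == "network_phi" && is.null(model)) {
    stop_validation("network mode needs a model")
  }
  structure(list(mode = mode, T = T, model = model, normalize = normalize),
            class = "embedding_transform")
}

l2_normalize_cols <- function(e) {
  nrm <- sqrt(colSums(e^2))
  nrm[nrm < 1e-12] <- 1
  sweep(e, 2L, nrm, `/`)
}

## Apply a transform to columns of x (features d_in x N, or an image batch in
## network mode). NULL transform = identity.
embed_apply <- function(transform, x) {
  if (is.null(transform)) return(as.matrix(x))
  if (is.function(transform)) return(transform(x))
  if (is.matrix(transform)) return(transform %*% x)
  if (inherits(transform, "embedding_transform")) {
    e <- if (transform$mode == "linear_T") transform$T %*% x
         else extract_features(transform$model, x)$values
    if (transform$normalize) e <- l2_normalize_cols(e)
    return(e)
  }
  stop_validation("unsupported transform")
}

#' Mahalanobis-form squared distance between two samples
#'
#' `||Phi(x_i) - Phi(x_j)||^2`, which for a linear `Phi = T` equals
#' `(x_i - x_j)' T'T (x_i - x_j)`. Symmetric, non-negative, and zero iff the
#' embeddings coincide.
#'
#' @param x_i,x_j numeric vectors of equal length.
#' @param transform `NULL` (identity), a matrix `T`, a function, or an
#'   [embedding_transform()].
#' @return non-negative squared distance.
#' @export
mahalanobis_distance <- function(x_i, x_j, transform = NULL) {
  if (length(x_i) != length(x_j)) {
    stop_validation("x_i and x_j must have the same dimension")
  }
  e <- embed_apply(transform, cbind(as.numeric(x_i), as.numeric(x_j)))
  sum((e[, 1] - e[, 2])^2)
}

#' Triplet specification
#'
#' @param margin hinge margin alpha >= 0 (default 0.2).
#' @param n_triplets triplets drawn per epoch in random mining.
#' @param mining `"random"` (uniform draws from the valid set) or `"all"`
#'   (full enumeration).
#' @param same_subject_positives restrict anchor/positive pairs to the same
#'   subject.
#' @param seed seed for random mining.
#' @return a `triplet_spec`.
#' @export
triplet_spec <- function(margin = 0.2, n_triplets = 256L,
                         mining = c("random", "all"),
                         same_subject_positives = FALSE, seed = 1L) {
  if (margin < 0) stop_validation("margin must be >= 0")
  structure(list(margin = margin, n_triplets = as.integer(n_triplets),
                 mining = match.arg(mining),
                 same_subject_positives = same_subject_positives,
                 seed = as.integer(seed)),
            class = "triplet_spec")
}

#' Mine expression-constrained triplets
#'
#' Valid triplets (a, p, n) satisfy: anchor and positive share the class
#' label but differ in expression; the negative has a different class. With
#' `mining = "all"` the full valid set is enumerated ((a, p) ordered, so each
#' sample anchors its own triplets); with `"random"`, `n_triplets` are drawn
#' uniformly (seeded).
#'
#' @param samples data frame with columns `y` (class), `e` (expression) and
#'   optionally `subject` (required when `same_subject_positives`).
#' @param spec a [triplet_spec()].
#' @return data frame with columns `a`, `p`, `n` (row indices into `samples`).
#' @export
mine_triplets <- function(samples, spec = triplet_spec()) {
  y <- samples$y
  e <- samples$e
  n <- length(y)
  if (length(unique(y)) < 2L) {
    stop_validation("no valid triplet: need at least two classes for a negative")
  }
  ## valid ordered anchor/positive pairs: same class, different expression
  pairs <- which(outer(y, y, `==`) & outer(e, e, `!=`), arr.ind = TRUE)
  if (isTRUE(spec$same_subject_positives)) {
    keep <- samples$subject[pairs[, 1]] == samples$subject[pairs[, 2]]
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    stop_validation("no valid triplet: no same-class pair with different ",
                    "expression exists")
  }
  negs_by_class <- lapply(unique(y), function(cl) which(y != cl))
  names(negs_by_class) <- as.character(unique(y))
  n_negs <- vapply(as.character(y[pairs[, 1]]),
                   function(cl) length(negs_by_class[[cl]]), numeric(1))
  total <- sum(n_negs)
  if (spec$mining == "all") {
    a <- rep.int(pairs[, 1], n_negs)
    p <- rep.int(pairs[, 2], n_negs)
    ng <- unlist(lapply(seq_len(nrow(pairs)), function(i) {
      negs_by_class[[as.character(y[pairs[i, 1]])]]
    }))
    return(data.frame(a = a, p = p, n = ng))
  }
  draw <- function() {
    ti <- sample.int(total, spec$n_triplets, replace = TRUE)
    cum <- cumsum(n_negs)
    pi_ <- findInterval(ti - 1L, c(0, cum), rightmost.closed = FALSE)
    within <- ti - c(0, cum)[pi_]
    a <- pairs[pi_, 1]
    data.frame(a = a, p = pairs[pi_, 2],
               n = vapply(seq_along(ti), function(j) {
                 negs_by_class[[as.character(y[a[j]])]][within[j]]
               }, numeric(1)))
  }
  withr::with_seed(spec$seed, draw())
}

#' Hinge triplet loss
#'
#' `L = sum over triplets of [d^2(a, p) - d^2(a, n) + alpha]_+`. Zero iff
#' every triplet's positive sits at least `alpha` closer (in squared
#' distance) than its negative.
#'
#' @param features d x N matrix of sample features (columns indexed by the
#'   triplet data frame).
#' @param triplets data frame from [mine_triplets()].
#' @param transform embedding transform (see [mahalanobis_distance()]).
#' @param alpha margin, >= 0.
#' @return non-negative scalar loss.
#' @export
triplet_loss <- function(features, triplets, transform = NULL, alpha = 0.2) {
  if (alpha < 0) stop_validation("alpha must be >= 0")
  e <- embed_apply(transform, features)
  d_ap <- colSums((e[, triplets$a, drop = FALSE] -
                   e[, triplets$p, drop = FALSE])^2)
  d_an <- colSums((e[, triplets$a, drop = FALSE] -
                   e[, triplets$n, drop = FALSE])^2)
  sum(pmax(d_ap - d_an + alpha, 0))
}

#' Attach an embedding head
#'
#' Replaces the model's output head with a linear embedding head of dimension
#' `d_out` on top of the feature tap, turning the network into the embedding
#' function Phi.
#'
#' @param model an `hm_model`.
#' @param d_out embedding dimension (default 128).
#' @param seed optional seed for head initialisation.
#' @return the model with embedding head (`head_activation = "none"`).
#' @export
attach_embed_head <- function(model, d_out = 128L, seed = NULL) {
  tap <- model$feature_tap %||% length(model$trunk)
  model$trunk <- model$trunk[seq_len(tap)]
  model$feature_tap <- tap
  mk <- function() layer_dense(model$feature_dim, as.integer(d_out))
  model$head <- if (is.null(seed)) mk() else withr::with_seed(seed, mk())
  model$head$trainable <- TRUE
  model$head_activation <- "none"
  model
}

## Gradient of the triplet loss w.r.t. the embedding columns.
triplet_embedding_grad <- function(e, triplets, alpha) {
  d_ap <- colSums((e[, triplets$a, drop = FALSE] -
                   e[, triplets$p, drop = FALSE])^2)
  d_an <- colSums((e[, triplets$a, drop = FALSE] -
                   e[, triplets$n, drop = FALSE])^2)
  act <- which(d_ap - d_an + alpha > 0)
  g <- matrix(0, nrow(e), ncol(e))
  loss <- sum(pmax(d_ap - d_an + alpha, 0))
  for (t in act) {
    a <- triplets$a[t]; p <- triplets$p[t]; ng <- triplets$n[t]
    g[, a] <- g[, a] + 2 * (e[, ng] - e[, p])
    g[, p] <- g[, p] - 2 * (e[, a] - e[, p])
    g[, ng] <- g[, ng] + 2 * (e[, a] - e[, ng])
  }
  list(grad = g, loss = loss, n_active = length(act))
}

## Backprop through optional L2 normalisation u = e / ||e||.
l2_normalize_grad <- function(e, u, du) {
  nrm <- sqrt(colSums(e^2))
  nrm[nrm < 1e-12] <- 1
  sweep(du - sweep(u, 2L, colSums(du * u), `*`), 2L, nrm, `/`)
}

#' Train an embedding with the triplet loss
#'
#' Network mode (`model` given): attaches/uses an embedding head and
#' minimises the triplet loss by backprop through the trainable layers only
#' (frozen layers from a freeze plan stay frozen). Linear mode (`model =
#' NULL`): optimises the linear map `T` directly on the supplied features.
#' Each epoch draws a fresh random set of valid triplets (seeded).
#'
#' @param samples list with `x` (images array for network mode, or d x N
#'   feature matrix for linear mode) and data frame columns `y`, `e`,
#'   `subject` (as in [mine_triplets()]).
#' @param spec a [triplet_spec()].
#' @param model `hm_model` with embedding head, or `NULL` for linear mode.
#' @param d_out embedding dimension for linear mode.
#' @param normalize L2-normalise embeddings before the loss.
#' @param epochs,lr optimisation settings.
#' @param batch triplets per optimisation step.
#' @param seed integer seed.
#' @return list with `transform` (an [embedding_transform()], domain `"PD"`
#'   for network mode) and `history` (per-epoch loss).
#' @export
train_triplet <- function(samples, spec = triplet_spec(), model = NULL,
                          d_out = 128L, normalize = TRUE, epochs = 20L,
                          lr = 1e-3, batch = 64L, seed = 1L) {
  meta <- data.frame(y = samples$y, e = samples$e,
                     subject = samples$subject %||% seq_along(samples$y))
  run <- function() {
    if (is.null(model)) {
      train_triplet_linear(samples$x, meta, spec, d_out, normalize, epochs,
                           lr, batch)
    } else {
      train_triplet_network(samples$x, meta, spec, model, normalize, epochs,
                            lr, batch)
    }
  }
  withr::with_seed(seed, run())
}

train_triplet_linear <- function(x, meta, spec, d_out, normalize, epochs, lr,
                                 batch) {
  d_in <- nrow(x)
  T <- matrix(nn_init_weights(d_out * d_in, d_in), nrow = d_out)
  state <- adam_init()
  tlay <- layer_dense(d_in, d_out, bias = FALSE)
  tlay$W <- T
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    trip <- mine_triplets(meta, triplet_spec(spec$margin, spec$n_triplets,
                                             "random",
                                             spec$same_subject_positives,
                                             seed = sample.int(2^30, 1)))
    ep_loss <- 0
    for (start in seq(1L, nrow(trip), by = batch)) {
      tb <- trip[start:min(start + batch - 1L, nrow(trip)), ]
      e <- tlay$W %*% x
      u <- if (normalize) l2_normalize_cols(e) else e
      tg <- triplet_embedding_grad(u, tb, spec$margin)
      du <- tg$grad
      de <- if (normalize) l2_normalize_grad(e, u, du) else du
      gW <- de %*% t(x)
      st <- adam_step(list(tlay), list(list(W = gW)), state, lr = lr)
      tlay <- st$layers[[1]]
      state <- st$state
      ep_loss <- ep_loss + tg$loss
    }
    history <- c(history, ep_loss)
  }
  list(transform = embedding_transform("linear_T", T = tlay$W,
                                       normalize = normalize),
       history = data.frame(epoch = seq_along(history), loss = history))
}

train_triplet_network <- function(x, meta, spec, model, normalize, epochs, lr,
                                  batch) {
  if (is.null(model$head) || model$head_activation != "none") {
    stop_validation("model needs an embedding head; call attach_embed_head()")
  }
  layers <- c(model$trunk, list(model$head))
  nt <- length(model$trunk)
  split <- nn_frozen_prefix(layers)
  prefix <- layers[seq_len(split)]
  tail_l <- layers[(split + 1L):length(layers)]
  ## the frozen prefix is a fixed function: precompute its outputs once
  z <- if (split == 0L) x else {
    out <- NULL
    for (start in seq(1L, dim(x)[4], by = 64L)) {
      ii <- start:min(start + 63L, dim(x)[4])
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
  state <- adam_init()
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    trip <- mine_triplets(meta, triplet_spec(spec$margin, spec$n_triplets,
                                             "random",
                                             spec$same_subject_positives,
                                             seed = sample.int(2^30, 1)))
    ep_loss <- 0
    for (start in seq(1L, nrow(trip), by = batch)) {
      tb <- trip[start:min(start + batch - 1L, nrow(trip)), ]
      uniq <- sort(unique(c(tb$a, tb$p, tb$n)))
      remap <- match(c(tb$a, tb$p, tb$n), uniq)
      tb2 <- data.frame(a = remap[seq_len(nrow(tb))],
                        p = remap[nrow(tb) + seq_len(nrow(tb))],
                        n = remap[2 * nrow(tb) + seq_len(nrow(tb))])
      xb <- nn_slice_samples(z, uniq)
      fw <- nn_forward_layers(tail_l, xb, train = TRUE)
      e <- fw$y
      u <- if (normalize) l2_normalize_cols(e) else e
      tg <- triplet_embedding_grad(u, tb2, spec$margin)
      if (!is.finite(tg$loss)) {
        stop("triplet training aborted: non-finite loss at epoch ", ep)
      }
      de <- if (normalize) l2_normalize_grad(e, u, tg$grad) else tg$grad
      ep_loss <- ep_loss + tg$loss
      if (tg$n_active > 0) {
        bw <- nn_backward_layers(fw$layers, fw$caches, de)
        st <- adam_step(fw$layers, bw$grads, state, lr = lr)
        tail_l <- st$layers
        state <- st$state
      } else {
        tail_l <- fw$layers
      }
    }
    history <- c(history, ep_loss)
  }
  layers <- c(prefix, tail_l)
  model$trunk <- layers[seq_len(nt)]
  model$head <- layers[[nt + 1L]]
  model$domain <- "PD"
  list(transform = embedding_transform("network_phi", model = model,
                                       normalize = normalize),
       history = data.frame(epoch = seq_along(history), loss = history))
}
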