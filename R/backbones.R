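## Network architectures: ResNet50 face backbone, compact VGG-8 and ResNet-7
## action-unit detectors, parameter counting and feature extraction.

#' Architecture specification for a backbone
#'
#' Describes one of the three supported families. For `vgg8` the network is
#' four groups of two 3x3 convolutions (each group followed by 2x2 max-pooling
#' and dropout), a six-layer fully-connected stack whose widths halve from
#' `fc_top`, and an 8-unit sigmoid output. For `resnet7` it is seven residual
#' blocks (alternating dimension-changing conv-blocks and identity blocks,
#' starting with a conv-block), global average pooling and an 8-unit output.
#' `resnet50` is the standard 50-layer bottleneck residual network and takes no
#' free widths.
#'
#' The literature this package follows prints total parameter counts for the
#' compact models but not their convolutional channel widths, so the default
#' widths are recovered by [search_channel_config()], which finds the exact
#' configuration matching the printed totals.
#'
#' @param family one of `"resnet50"`, `"vgg8"`, `"resnet7"`.
#' @param input_size input image side in pixels (images are square).
#' @param channels_in 1 (grayscale) or 3 (RGB).
#' @param channel_widths integer widths of the four conv groups (vgg8) or the
#'   four block stages (resnet7); ignored for resnet50.
#' @param fc_top top width of the six-layer halving FC stack (vgg8 only).
#' @param dropout_rate dropout probability used after each pooling stage.
#' @return a `backbone_spec` list.
#' @export
backbone_spec <- function(family = c("resnet50", "vgg8", "resnet7"),
                          input_size = 64L, channels_in = 1L,
                          channel_widths = NULL, fc_top = NULL,
                          dropout_rate = 0.25) {
  family <- match.arg(family)
  if (family == "vgg8" && !is.null(fc_top) && bitwAnd(fc_top, 31L) != 0L) {
    stop_validation("fc_top must be divisible by 32 so six halvings stay integral")
  }
  structure(list(family = family, input_size = as.integer(input_size),
                 channels_in = as.integer(channels_in),
                 channel_widths = as.integer(channel_widths %||% integer(0)),
                 fc_top = if (is.null(fc_top)) NULL else as.integer(fc_top),
                 dropout_rate = dropout_rate),
            class = "backbone_spec")
}

vgg8_fc_widths <- function(fc_top) as.integer(fc_top / 2^(0:5))

## ---- closed-form parameter counts (used by the constraint search) ----------

vgg8_count_formula <- function(cw, fc_top, input_size = 64L, channels_in = 1L) {
  flat_cells <- (input_size %/% 16L)^2
  p <- 0
  cin <- channels_in
  for (cc in cw) {
    p <- p + (9 * cin * cc + cc) + (9 * cc * cc + cc)
    cin <- cc
  }
  fin <- flat_cells * cw[4]
  for (w in vgg8_fc_widths(fc_top)) {
    p <- p + fin * w + w
    fin <- w
  }
  p + fin * 8 + 8
}

resnet7_count_formula <- function(cw, channels_in = 1L) {
  ident <- function(c) 2 * 9 * c * c + 4 * c
  convb <- function(ci, co) 9 * ci * co + 9 * co * co + ci * co + 6 * co
  c1 <- cw[1]; c2 <- cw[2]; c3 <- cw[3]; c4 <- cw[4]
  convb(channels_in, c1) + ident(c1) + convb(c1, c2) + ident(c2) +
    convb(c2, c3) + ident(c3) + convb(c3, c4) + (8 * c4 + 8)
}

#' Search channel configurations matching a target parameter count
#'
#' The compact architectures are described in the literature by their layer
#' structure and total parameter count only; the convolutional channel widths
#' are unstated. This operation recovers them: it enumerates a finite space of
#' monotone non-decreasing 4-stage width plans (and, for `vgg8`, the top width
#' of the halving FC stack) and returns the configuration whose exact total
#' parameter count equals `target_count`. Ties are broken by returning the
#' lexicographically smallest tuple `(c1, c2, c3, c4, fc_top)`.
#'
#' @param family `"vgg8"` or `"resnet7"`.
#' @param target_count exact total parameter count to match.
#' @param search_space list with `c_min`, `c_max` (channel range, default
#'   8..256) and for vgg8 `fc_top` candidates (default 32, 64, ..., 1024).
#' @param input_size,channels_in input geometry (affects the vgg8 flatten).
#' @return a [backbone_spec()] whose built model has exactly `target_count`
#'   parameters.
#' @export
search_channel_config <- function(family = c("vgg8", "resnet7"), target_count,
                                  search_space = list(), input_size = 64L,
                                  channels_in = 1L) {
  family <- match.arg(family)
  c_min <- search_space$c_min %||% 8L
  c_max <- search_space$c_max %||% 256L
  fc_tops <- search_space$fc_top %||% as.integer(32 * 2^(0:5))
  if (c_max < c_min) stop_validation("empty channel search space")

  ## Enumerate monotone triples (c1 <= c2 <= c3) and solve the quadratic in c4.
  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || lex_less(cand, best)) best <<- cand
  }
  lex_less <- function(a, b) {
    ka <- c(a$cw, a$fc %||% 0L); kb <- c(b$cw, b$fc %||% 0L)
    d <- ka - kb
    nz <- which(d != 0)
    length(nz) > 0 && d[nz[1]] < 0
  }
  solve_c4 <- function(a, b, cst) {
    ## a*c4^2 + b*c4 + cst = 0, integer positive roots only
    disc <- b * b - 4 * a * cst
    out <- rep(NA_real_, length(b))
    ok <- disc >= 0
    r <- sqrt(disc[ok])
    cand <- (-b[ok] + r) / (2 * a)
    cand[abs(cand - round(cand)) > 1e-6] <- NA
    out[ok] <- round(cand)
    out
  }

  cs <- seq.int(c_min, c_max)
  grid3 <- expand.grid(c1 = cs, c2 = cs, c3 = cs)
  grid3 <- grid3[grid3$c1 <= grid3$c2 & grid3$c2 <= grid3$c3, ]

  if (family == "vgg8") {
    flat_cells <- (input_size %/% 16L)^2
    conv_a <- function(ci, co) (9 * ci * co + co) + (9 * co * co + co)
    A <- conv_a(channels_in, grid3$c1) + conv_a(grid3$c1, grid3$c2) +
      conv_a(grid3$c2, grid3$c3)
    for (fc in sort(fc_tops)) {
      ws <- vgg8_fc_widths(fc)
      fcp <- sum(ws[-1] * ws[-6] + ws[-1]) + ws[1] + ws[6] * 8 + 8
      b <- 9 * grid3$c3 + 2 + flat_cells * fc
      c4 <- solve_c4(9, b, A + fcp - target_count)
      hit <- which(!is.na(c4) & c4 >= grid3$c3 & c4 <= c_max)
      for (i in hit) {
        cw <- c(grid3$c1[i], grid3$c2[i], grid3$c3[i], c4[i])
        if (vgg8_count_formula(cw, fc, input_size, channels_in) == target_count) {
          consider(list(cw = as.integer(cw), fc = fc))
        }
      }
    }
  } else {
    ident <- function(c) 2 * 9 * c * c + 4 * c
    convb <- function(ci, co) 9 * ci * co + 9 * co * co + ci * co + 6 * co
    A <- convb(channels_in, grid3$c1) + ident(grid3$c1) +
      convb(grid3$c1, grid3$c2) + ident(grid3$c2) +
      convb(grid3$c2, grid3$c3) + ident(grid3$c3)
    b <- 10 * grid3$c3 + 14
    c4 <- solve_c4(9, b, A + 8 - target_count)
    hit <- which(!is.na(c4) & c4 >= grid3$c3 & c4 <= c_max)
    for (i in hit) {
      cw <- c(grid3$c1[i], grid3$c2[i], grid3$c3[i], c4[i])
      if (resnet7_count_formula(cw, channels_in) == target_count) {
        consider(list(cw = as.integer(cw), fc = NULL))
      }
    }
  }
  if (is.null(best)) {
    stop(structure(class = c("hm_no_config_found", "error", "condition"),
                   list(message = paste0("no ", family, " configuration in the ",
                                         "search space has exactly ",
                                         target_count, " parameters"),
                        call = sys.call())))
  }
  backbone_spec(family, input_size = input_size, channels_in = channels_in,
                channel_widths = best$cw, fc_top = best$fc)
}

## Printed totals for the two compact AU architectures.
VGG8_TARGET_PARAMS <- 295448L
RESNET7_TARGET_PARAMS <- 366626L

#' Default specs for the compact architectures
#'
#' Runs [search_channel_config()] against the published totals (295,448 for
#' VGG-8; 366,626 for ResNet-7) over the default search space.
#' @name default_specs
#' @export
default_vgg8_spec <- function() {
  search_channel_config("vgg8", VGG8_TARGET_PARAMS)
}

#' @rdname default_specs
#' @export
default_resnet7_spec <- function() {
  search_channel_config("resnet7", RESNET7_TARGET_PARAMS)
}

## ---- builders ---------------------------------------------------------------

new_model <- function(family, spec, trunk, head, head_activation, feature_dim,
                      domain = "FA", feature_tap = length(trunk)) {
  structure(list(family = family, spec = spec, trunk = trunk, head = head,
                 head_activation = head_activation, feature_dim = feature_dim,
                 feature_tap = feature_tap, domain = domain,
                 freeze_plan = NULL),
            class = "hm_model")
}

#' Build the ResNet50 face-analysis backbone
#'
#' Standard 50-layer bottleneck residual network: a 7x7/2 stem, four stages of
#' 3/4/6/3 bottleneck blocks (widths 64/128/256/512, expansion 4), global
#' average pooling and a 1000-way decision layer; 25,557,032 parameters in
#' total (25.6M). Feature extraction removes the decision layer and exposes the
#' 2048-dimensional pooled vector. Weights are randomly initialised; a
#' face-recognition checkpoint can be loaded with [load_model()] if available.
#'
#' @param input_size input side in pixels; any size >= 32 works because pooling
#'   is global.
#' @param channels_in 1 or 3.
#' @param seed optional integer seed for reproducible initialisation.
#' @return an `hm_model`.
#' @export
build_resnet50 <- function(input_size = 224L, channels_in = 3L, seed = NULL) {
  build <- function() {
    bottleneck <- function(c_in, planes, stride, downsample) {
      main <- list(
        layer_conv(c_in, planes, k = 1L, stride = 1L, pad = 0L, bias = FALSE),
        layer_bn(planes), layer_relu(),
        layer_conv(planes, planes, k = 3L, stride = stride, pad = 1L, bias = FALSE),
        layer_bn(planes), layer_relu(),
        layer_conv(planes, planes * 4L, k = 1L, stride = 1L, pad = 0L, bias = FALSE),
        layer_bn(planes * 4L))
      shortcut <- NULL
      if (downsample) {
        shortcut <- list(
          layer_conv(c_in, planes * 4L, k = 1L, stride = stride, pad = 0L,
                     bias = FALSE),
          layer_bn(planes * 4L))
      }
      layer_resblock(main, shortcut)
    }
    trunk <- list(
      layer_conv(channels_in, 64L, k = 7L, stride = 2L, pad = 3L, bias = FALSE),
      layer_bn(64L), layer_relu(),
      layer_maxpool(k = 3L, stride = 2L, pad = 1L))
    cin <- 64L
    stages <- list(c(64L, 3L, 1L), c(128L, 4L, 2L), c(256L, 6L, 2L),
                   c(512L, 3L, 2L))
    for (st in stages) {
      planes <- st[1]; nb <- st[2]; stride <- st[3]
      for (b in seq_len(nb)) {
        trunk[[length(trunk) + 1L]] <-
          bottleneck(cin, planes, if (b == 1L) stride else 1L, b == 1L)
        cin <- planes * 4L
      }
    }
    trunk[[length(trunk) + 1L]] <- layer_gap()
    head <- layer_dense(2048L, 1000L)
    spec <- backbone_spec("resnet50", input_size = input_size,
                          channels_in = channels_in,
                          channel_widths = c(64L, 128L, 256L, 512L))
    new_model("resnet50", spec, trunk, head, "none", 2048L, domain = "FA")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Build the compact VGG-8 action-unit network
#'
#' Eight 3x3 convolutional layers in four groups of two, each group followed by
#' 2x2 max-pooling and dropout, then a six-layer fully-connected stack with
#' halving widths and an 8-unit sigmoid output (one unit per selected action
#' unit). With the default spec the total parameter count is exactly 295,448.
#'
#' @param spec a [backbone_spec()]; default [default_vgg8_spec()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return an `hm_model`.
#' @export
build_vgg8 <- function(spec = default_vgg8_spec(), seed = NULL) {
  if (spec$family != "vgg8") stop_validation("spec$family must be 'vgg8'")
  if (length(spec$channel_widths) != 4L || is.null(spec$fc_top)) {
    stop_validation("vgg8 spec needs 4 channel widths and fc_top")
  }
  build <- function() {
    trunk <- list()
    cin <- spec$channels_in
    for (cc in spec$channel_widths) {
      trunk <- c(trunk, list(
        layer_conv(cin, cc, k = 3L, stride = 1L, pad = 1L, bias = TRUE),
        layer_relu(),
        layer_conv(cc, cc, k = 3L, stride = 1L, pad = 1L, bias = TRUE),
        layer_relu(),
        layer_maxpool(2L),
        layer_dropout(spec$dropout_rate)))
      cin <- cc
    }
    trunk[[length(trunk) + 1L]] <- layer_flatten()
    fin <- (spec$input_size %/% 16L)^2 * cin
    tap <- NULL
    for (w in vgg8_fc_widths(spec$fc_top)) {
      trunk <- c(trunk, list(layer_dense(fin, w), layer_relu()))
      ## feature tap: the 32-unit fully-connected layer (after its ReLU)
      if (w == 32L) tap <- length(trunk)
      fin <- w
    }
    head <- layer_dense(fin, 8L)
    new_model("vgg8", spec, trunk, head, "sigmoid",
              if (is.null(tap)) fin else 32L, domain = "AU",
              feature_tap = tap %||% length(trunk))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Build the compact ResNet-7 action-unit network
#'
#' Seven residual blocks alternating between dimension-changing conv-blocks
#' (convolutional shortcut) and identity blocks (plain shortcut), starting with
#' a conv-block, followed by global average pooling and an 8-unit sigmoid
#' output. With the default spec the total parameter count is exactly 366,626.
#'
#' @inheritParams build_vgg8
#' @return an `hm_model`.
#' @export
build_resnet7 <- function(spec = default_resnet7_spec(), seed = NULL) {
  if (spec$family != "resnet7") stop_validation("spec$family must be 'resnet7'")
  if (length(spec$channel_widths) != 4L) {
    stop_validation("resnet7 spec needs 4 channel widths")
  }
  build <- function() {
    basic_conv_block <- function(c_in, c_out, stride) {
      layer_resblock(
        main = list(
          layer_conv(c_in, c_out, k = 3L, stride = stride, pad = 1L, bias = FALSE),
          layer_bn(c_out), layer_relu(),
          layer_conv(c_out, c_out, k = 3L, stride = 1L, pad = 1L, bias = FALSE),
          layer_bn(c_out)),
        shortcut = list(
          layer_conv(c_in, c_out, k = 1L, stride = stride, pad = 0L, bias = FALSE),
          layer_bn(c_out)))
    }
    basic_identity_block <- function(c) {
      layer_resblock(
        main = list(
          layer_conv(c, c, k = 3L, stride = 1L, pad = 1L, bias = FALSE),
          layer_bn(c), layer_relu(),
          layer_conv(c, c, k = 3L, stride = 1L, pad = 1L, bias = FALSE),
          layer_bn(c)))
    }
    cw <- spec$channel_widths
    trunk <- list(
      basic_conv_block(spec$channels_in, cw[1], 1L),
      basic_identity_block(cw[1]),
      basic_conv_block(cw[1], cw[2], 2L),
      basic_identity_block(cw[2]),
      basic_conv_block(cw[2], cw[3], 2L),
      basic_identity_block(cw[3]),
      basic_conv_block(cw[3], cw[4], 2L),
      layer_gap())
    head <- layer_dense(cw[4], 8L)
    new_model("resnet7", spec, trunk, head, "sigmoid", cw[4], domain = "AU")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

## ---- parameter counting -----------------------------------------------------

#' Count model parameters
#'
#' Exact count of scalar parameters (convolution and dense weights and biases,
#' batch-norm scale and shift; running statistics are buffers, not parameters).
#'
#' @param model an `hm_model`.
#' @param trainable_only if TRUE, count only layers whose trainable flag is set
#'   (the attached head is always trainable).
#' @param include_head whether to include the attached head layer.
#' @return integer-valued count.
#' @export
count_parameters <- function(model, trainable_only = FALSE, include_head = TRUE) {
  assert_flag(trainable_only, "trainable_only")
  total <- 0
  for (path in nn_param_paths(model$trunk)) {
    lay <- nn_get_layer(model$trunk, path)
    if (trainable_only && !isTRUE(lay$trainable)) next
    total <- total + nn_layer_param_count(lay)
  }
  if (include_head && !is.null(model$head)) {
    if (!trainable_only || isTRUE(model$head$trainable)) {
      total <- total + nn_layer_param_count(model$head)
    }
  }
  total
}

## Forward through the trunk only (feature extractor mode).
model_trunk_forward <- function(model, x, train = FALSE) {
  nn_forward_layers(model$trunk, x, train = train)
}

## Full forward: trunk + head (+ head activation unless raw logits requested).
model_forward <- function(model, x, train = FALSE, logits = FALSE) {
  r <- nn_forward_layers(model$trunk, x, train = train)
  model$trunk <- r$layers
  y <- r$y
  head_cache <- NULL
  if (!is.null(model$head)) {
    rh <- nn_leaf_forward(model$head, y, train)
    head_cache <- rh$cache
    y <- rh$y
    if (!logits && model$head_activation == "sigmoid") y <- stats::plogis(y)
  }
  list(y = y, trunk_caches = r$caches, head_cache = head_cache, model = model)
}

#' Extract feature vectors from a model
#'
#' Runs the model in feature-extractor mode (decision/output head removed) and
#' returns one column per image. Taps: ResNet50 and ResNet-7 use the pooled
#' vector after global average pooling; VGG-8 uses the last (32-unit by
#' default) fully-connected layer.
#'
#' @param model an `hm_model`.
#' @param images array `[H, W, C, N]` (or `[H, W, N]` for grayscale, or a
#'   single `[H, W]` image) with values in `[0, 1]`.
#' @return an `hm_features` object: list with `values` (d x N matrix), `domain`
#'   (`"FA"`, `"AU"` or `"PD"`) and `dim`.
#' @export
extract_features <- function(model, images) {
  x <- as_image_batch(images, model$spec$channels_in)
  if (dim(x)[3] != model$spec$channels_in) {
    stop_validation("image channel count does not match the model")
  }
  tap <- model$feature_tap %||% length(model$trunk)
  y <- nn_forward_layers(model$trunk[seq_len(tap)], x, train = FALSE)$y
  if (!is.matrix(y)) y <- matrix(y, ncol = dim(x)[4])
  structure(list(values = y, domain = model$domain, dim = nrow(y)),
            class = "hm_features")
}

## Coerce images to a [H, W, C, N] batch.
as_image_batch <- function(images, channels = 1L) {
  if (is.list(images)) {
    images <- simplify2array(images)
  }
  d <- dim(images)
  if (is.null(d)) stop_validation("images must be an array")
  if (length(d) == 2L) dim(images) <- c(d, 1L, 1L)
  else if (length(d) == 3L) {
    ## [H, W, N] grayscale stack
    dim(images) <- c(d[1], d[2], 1L, d[3])
  } else if (length(d) != 4L) stop_validation("images must have 2-4 dimensions")
  images
}

#' Calibrate batch-normalisation statistics
#'
#' Runs forward passes in training mode over the supplied images so that the
#' batch-norm running means/variances reflect the data distribution. Needed
#' before feature extraction from a randomly initialised residual backbone
#' (whose running statistics would otherwise still be the 0/1 init); training
#' performs the same adaptation implicitly. Weights are not modified.
#'
#' @param model an `hm_model`.
#' @param images calibration images (a few dozen suffice).
#' @param passes forward passes over the batch (running stats are an
#'   exponential moving average, so a few passes converge them).
#' @return the model with updated batch-norm buffers.
#' @export
calibrate_bn <- function(model, images, passes = 8L) {
  x <- as_image_batch(images, model$spec$channels_in)
  ## temporarily mark everything trainable so batch statistics are used
  paths <- nn_param_paths(model$trunk)
  saved <- vapply(paths, function(p) {
    isTRUE(nn_get_layer(model$trunk, p)$trainable)
  }, logical(1))
  for (p in paths) {
    lay <- nn_get_layer(model$trunk, p)
    lay$trainable <- TRUE
    model$trunk <- nn_set_layer(model$trunk, p, lay)
  }
  for (i in seq_len(passes)) {
    model$trunk <- nn_forward_layers(model$trunk, x, train = TRUE)$layers
  }
  for (i in seq_along(paths)) {
    lay <- nn_get_layer(model$trunk, paths[[i]])
    lay$trainable <- saved[i]
    model$trunk <- nn_set_layer(model$trunk, paths[[i]], lay)
  }
  model
}

## ---- checkpoint I/O ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file RDS checkpoint with the architecture spec embedded as JSON, so a
#' checkpoint is self-describing.
#' @param model an `hm_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "hypomimia-model-v1",
               spec_json = jsonlite::toJSON(unclass(model$spec), auto_unbox = TRUE),
               model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "hypomimia-model-v1")) {
    stop_validation("not a hypomimia model checkpoint: ", path)
  }
  obj$model
}

#' @export
print.hm_model <- function(x, ...) {
  cat(sprintf("<hm_model %s> input %dx%dx%d, features %d, head %s, domain %s\n",
              x$family, x$spec$input_size, x$spec$input_size,
              x$spec$channels_in, x$feature_dim,
              if (is.null(x$head)) "none" else paste0(x$head$d_out, "-unit"),
              x$domain))
  cat(sprintf("  parameters: %s total, %s trainable\n",
              format(count_parameters(x), big.mark = ","),
              format(count_parameters(x, trainable_only = TRUE),
                     big.mark = ",")))
  invisible(x)
}
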