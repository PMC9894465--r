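## Synthetic face cohorts with controllable hypomimia -------------------------
##
## Faces are procedural 2-D grayscale renderings (smooth head template with
## ellipse/curve features), parameterised by the geometric substrate of the
## eight action units used downstream (AU1/2 inner/outer brow raiser, AU4 brow
## lowerer, AU5 upper-lid raiser, AU6 cheek raiser, AU12 lip-corner puller,
## AU25 lips part, AU26 jaw drop). Rendering is a pure function of the
## parameters and the image size, so every downstream stage is testable
## without any real face data.

#' Facial configuration parameters
#'
#' Unitless intensities of the elementary facial movements the renderer
#' understands. All fields live in `[0, 1]` except `lip_corner_pull` in
#' `[-1, 1]` (negative values pull the mouth corners down, as in anger). The
#' all-zero configuration renders the neutral face.
#'
#' @param brow_inner_raise,brow_outer_raise,brow_lower,lid_raise,cheek_raise
#'   intensities in `[0, 1]`.
#' @param lip_corner_pull intensity in `[-1, 1]`.
#' @param lips_part,jaw_drop,eye_close_left,eye_close_right intensities in
#'   `[0, 1]`. Left/right refer to image coordinates (the left eye is in the
#'   left half of the rendered image).
#' @return a `face_params` list.
#' @export
face_params <- function(brow_inner_raise = 0, brow_outer_raise = 0,
                        brow_lower = 0, lid_raise = 0, cheek_raise = 0,
                        lip_corner_pull = 0, lips_part = 0, jaw_drop = 0,
                        eye_close_left = 0, eye_close_right = 0) {
  p <- list(brow_inner_raise = brow_inner_raise,
            brow_outer_raise = brow_outer_raise,
            brow_lower = brow_lower, lid_raise = lid_raise,
            cheek_raise = cheek_raise, lip_corner_pull = lip_corner_pull,
            lips_part = lips_part, jaw_drop = jaw_drop,
            eye_close_left = eye_close_left,
            eye_close_right = eye_close_right)
  for (nm in names(p)) {
    lo <- if (nm == "lip_corner_pull") -1 else 0
    assert_range(p[[nm]], lo, 1, nm)
  }
  structure(p, class = "face_params")
}

#' Render a synthetic face
#'
#' Deterministically renders a grayscale face image from a [face_params()]
#' configuration. The output is a `size` x `size` matrix in `[0, 1]` (row 1 is
#' the top of the face).
#'
#' @param params a [face_params()].
#' @param size image side in pixels, at least 32.
#' @param identity optional [face_identity()] with per-person geometry
#'   (head proportions, eye spacing and size, mouth width and position,
#'   brow height, skin tone); `NULL` renders the template identity.
#' @return numeric matrix `size` x `size` in `[0, 1]`.
#' @export
render_face <- function(params, size = 64L, identity = NULL) {
  if (!inherits(params, "face_params")) params <- do.call(face_params, params)
  id <- identity %||% face_identity()
  size <- as.integer(size)
  if (size < 32L) stop_validation("size must be >= 32")
  ## normalised coordinates: x in [-1, 1] left->right, y in [-1, 1] top->bottom
  gx <- matrix(rep((seq_len(size) - 0.5) / size * 2 - 1, each = size),
               size, size)
  gy <- matrix(rep((seq_len(size) - 0.5) / size * 2 - 1, times = size),
               size, size)
  img <- matrix(0, size, size)

  ## head: soft-edged ellipse
  r2 <- (gx / (0.80 * id$head_rx))^2 + (gy / (0.95 * id$head_ry))^2
  img <- img + (0.55 + id$tone) * pmin(1, pmax(0, (1.08 - r2) / 0.16))

  ## brows: one arc per side; raising moves them up, lowering down and inward
  bir <- params$brow_inner_raise; bor <- params$brow_outer_raise
  bl <- params$brow_lower
  for (s in c(-1, 1)) {
    xr <- s * gx                      # distance from centre toward this side
    in_x <- xr > 0.10 & xr < 0.56
    t <- pmin(1, pmax(0, (xr - 0.12) / 0.40))   # 0 inner -> 1 outer
    yb <- -0.42 + id$brow_y - 0.04 * sin(pi * t) -
      0.16 * ((1 - t) * bir + t * bor) + 0.14 * bl
    hit <- in_x & abs(gy - yb) < (0.035 + 0.015 * bl)
    img[hit] <- 0.08
  }

  ## eyes: aperture controlled by lid raise (opens), cheek raise (squeezes)
  ## and per-side closure (wink)
  for (s in c(-1, 1)) {
    closed <- if (s < 0) params$eye_close_left else params$eye_close_right
    ## eye proportions kept large enough that lid movements remain legible
    ## at the smallest supported render size (32 px)
    ry <- 0.095 * id$eye_rx * (1 + 0.9 * params$lid_raise) *
      (1 - 0.35 * params$cheek_raise) * (1 - closed)
    cx <- s * (0.33 + id$eye_dx)
    cy <- -0.22 + id$eye_y
    if (ry > 0.008) {
      hit <- ((gx - cx) / (0.17 * id$eye_rx))^2 + ((gy - cy) / ry)^2 <= 1
      img[hit] <- 0.05
    } else {
      ## closed eye: thin lid line
      hit <- abs(gx - cx) < 0.15 & abs(gy - cy) < 0.015
      img[hit] <- 0.20
    }
  }

  ## cheeks: AU6 brightening blobs under the eyes
  if (params$cheek_raise > 0) {
    for (s in c(-1, 1)) {
      img <- img + 0.30 * params$cheek_raise *
        exp(-(((gx - s * 0.40)^2 + (gy - 0.08)^2) / 0.015))
    }
  }

  ## mouth: lip line with corner pull; opening from lips part and jaw drop
  lcp <- params$lip_corner_pull
  mw <- 0.30 * id$mouth_w
  my <- 0.45 + id$mouth_y
  ym <- my - 0.20 * lcp * (gx / mw)^2
  in_mx <- abs(gx) <= mw
  aperture <- 0.06 * params$lips_part + 0.12 * params$jaw_drop
  if (aperture > 0.005) {
    open_hit <- in_mx & gy >= ym & gy <= ym + aperture *
      sqrt(pmax(0, 1 - (gx / mw)^2))
    img[open_hit] <- 0.06
  }
  lip_hit <- in_mx & abs(gy - ym) < 0.022
  img[lip_hit] <- 0.10

  pmin(pmax(img, 0), 1)
}

#' Per-person facial geometry
#'
#' Identity parameters of the renderer: head proportions, eye spacing,
#' height and size, brow height, mouth width and position, and skin tone.
#' Real face corpora vary far more across identities than across
#' expressions, so cohort simulation draws one identity per subject.
#'
#' @param head_rx,head_ry head width/height multipliers (around 1).
#' @param eye_dx,eye_y eye spacing / height offsets (normalised units).
#' @param eye_rx eye size multiplier.
#' @param brow_y brow baseline offset.
#' @param mouth_w mouth width multiplier.
#' @param mouth_y mouth vertical offset.
#' @param tone skin-tone (brightness) offset.
#' @return a `face_identity` list.
#' @export
face_identity <- function(head_rx = 1, head_ry = 1, eye_dx = 0, eye_y = 0,
                          eye_rx = 1, brow_y = 0, mouth_w = 1, mouth_y = 0,
                          tone = 0) {
  structure(list(head_rx = head_rx, head_ry = head_ry, eye_dx = eye_dx,
                 eye_y = eye_y, eye_rx = eye_rx, brow_y = brow_y,
                 mouth_w = mouth_w, mouth_y = mouth_y, tone = tone),
            class = "face_identity")
}

## Draw a random identity plus individual expressivity (amplitude multiplier)
## and tempo (rise-time multiplier); both groups share these individual
## differences, on top of which severity acts. `scale` multiplies all
## inter-subject variability (0 = every subject is the template face with
## unit expressivity and tempo).
draw_identity <- function(scale = 1) {
  u <- function(half) stats::runif(1, -half * scale, half * scale)
  list(identity = face_identity(
         head_rx = 1 + u(0.10), head_ry = 1 + u(0.10),
         eye_dx = u(0.03), eye_y = u(0.04),
         eye_rx = 1 + u(0.15), brow_y = u(0.04),
         mouth_w = 1 + u(0.15), mouth_y = u(0.04),
         tone = u(0.06)),
       expressivity = min(1.3, max(0.7, stats::rnorm(1, 1, 0.12 * scale))),
       tempo = 1 + u(0.15))
}

## Expressions supported by the cohort generator.
EXPRESSIONS <- c("wink_r", "wink_l", "smile", "anger", "surprise")

## Valence sign: anger is a negative-valence expression, smile positive; the
## remaining tasks use activation magnitude.
expression_sign <- function(expression) {
  if (expression == "anger") -1 else 1
}

## Map an activation value to the facial configuration of an expression.
## `a` is the signed activation in [-1, 1]; intensity uses |a|.
expression_face_params <- function(expression, a) {
  m <- min(1, abs(a))
  switch(expression,
    smile = face_params(lip_corner_pull = m, cheek_raise = 0.6 * m,
                        lips_part = 0.35 * m),
    anger = face_params(brow_lower = m, lid_raise = 0.5 * m,
                        lip_corner_pull = -0.5 * m, lips_part = 0.35 * m,
                        jaw_drop = 0.3 * m),
    surprise = face_params(brow_inner_raise = m, brow_outer_raise = m,
                           lid_raise = 0.8 * m, lips_part = 0.6 * m,
                           jaw_drop = 0.6 * m),
    wink_r = face_params(eye_close_right = m),
    wink_l = face_params(eye_close_left = m),
    stop_validation("unknown expression: ", expression))
}

## Default hypomimia model constants. Amplitude shrinks as A0*(1 - beta*s) and
## the 10->90% rise time stretches as tau0*(1 + gamma*s) with severity s.
hypomimia_constants <- function(A0 = 0.9, beta = 0.5, gamma = 1.0,
                                sigma_j = 0.02, tau0 = 0.5, hold_s = 1.2) {
  list(A0 = A0, beta = beta, gamma = gamma, sigma_j = sigma_j, tau0 = tau0,
       hold_s = hold_s)
}

#' Synthesise an elicited-expression activation curve
#'
#' Produces the per-frame activation (valence-like) curve of one elicited
#' expression: baseline, a rising onset, an apex plateau, a falling offset and
#' a return to baseline. Hypomimia enters through the severity `s`: the apex
#' amplitude is `A0 * (1 - beta * s)` and the 10->90% rise time is
#' `tau0 * (1 + gamma * s)` seconds, reproducing the reduced-amplitude,
#' slowed-onset phenotype. Negative-valence expressions (anger) have a
#' negative apex.
#'
#' @param expression one of `r paste(EXPRESSIONS, collapse=", ")`.
#' @param severity hypomimia severity in `[0, 1]` (0 = healthy).
#' @param fps frames per second.
#' @param duration_s clip duration in seconds.
#' @param seed optional seed for the additive jitter.
#' @param constants model constants, see `hypomimia_constants()` defaults:
#'   `A0 = 0.9`, `beta = 0.5`, `gamma = 1`, `sigma_j = 0.02`, `tau0 = 0.5` s,
#'   apex hold `1.2` s.
#' @return an `activation_curve`: list with `values` (one per frame, in
#'   `[-1, 1]`) and `fps`.
#' @export
activation_profile <- function(expression, severity = 0, fps = 15,
                               duration_s = 6, seed = NULL,
                               constants = hypomimia_constants()) {
  expression <- match.arg(expression, EXPRESSIONS)
  assert_range(severity, 0, 1, "severity")
  if (duration_s <= 0) stop_validation("duration_s must be positive")
  k <- constants
  A <- k$A0 * (1 - k$beta * severity)
  ramp <- k$tau0 * (1 + k$gamma * severity) / 0.8  # full 0->A ramp duration
  if (duration_s < 2 * ramp + k$hold_s + 0.4) {
    stop_validation("duration too short to fit rise, hold and fall at this ",
                    "severity (needs >= ", round(2 * ramp + k$hold_s + 0.4, 2),
                    " s)")
  }
  n <- round(fps * duration_s)
  t <- (seq_len(n) - 1) / fps
  lead <- (duration_s - 2 * ramp - k$hold_s) / 2
  up <- pmin(1, pmax(0, (t - lead) / ramp))
  down <- pmin(1, pmax(0, (t - lead - ramp - k$hold_s) / ramp))
  v <- A * (up - down)
  if (k$sigma_j > 0) {
    jit <- function() stats::rnorm(n, 0, k$sigma_j)
    v <- v + if (is.null(seed)) jit() else withr::with_seed(seed, jit())
  }
  v <- pmin(1, pmax(-1, v)) * expression_sign(expression)
  structure(list(values = v, fps = fps), class = "activation_curve")
}

#' Simulate a synthetic Parkinson/control cohort
#'
#' Builds a cohort mirroring the structure of a clinical elicited-expression
#' corpus: `n_pd + n_hc` subjects, five expression tasks each (right eye wink,
#' left eye wink, smile, anger, surprise), one clip per task at `fps` frames/s
#' for `duration_s` seconds. Patient severities are drawn from
#' Uniform(0.4, 1.0); controls have severity 0. Frames are rendered lazily
#' with [clip_frames()] (the clip stores its activation curve and render
#' parameters), so large cohorts stay cheap until pixels are needed.
#'
#' @param n_pd,n_hc numbers of patients and controls (each >= 1).
#' @param fps frames per second (default 15).
#' @param duration_s clip duration in seconds (default 6).
#' @param seed integer seed; the whole cohort is a pure function of the
#'   arguments and this seed.
#' @param size rendered image side in pixels.
#' @param constants hypomimia model constants, see [activation_profile()].
#' @param subject_variability scale of inter-subject variability (facial
#'   geometry, individual expressivity and tempo); 1 = realistic default,
#'   0 = identical template subjects (useful for separability checks).
#' @return an `hm_cohort`: list with `subjects` (data frame), `clips` (list of
#'   `expression_clip`), `seed`, `size`.
#' @export
simulate_cohort <- function(n_pd, n_hc, fps = 15, duration_s = 6, seed = 1L,
                            size = 64L, constants = hypomimia_constants(),
                            subject_variability = 1) {
  if (n_pd < 1 || n_hc < 1) stop_validation("n_pd and n_hc must be >= 1")
  subjects <- data.frame(
    subject_id = c(sprintf("PD%03d", seq_len(n_pd)),
                   sprintf("HC%03d", seq_len(n_hc))),
    group = c(rep("PD", n_pd), rep("HC", n_hc)),
    stringsAsFactors = FALSE)
  subjects$severity <- withr::with_seed(child_seed(seed, 0L), c(
    stats::runif(n_pd, 0.4, 1.0), rep(0, n_hc)))
  identities <- lapply(seq_len(nrow(subjects)), function(i) {
    withr::with_seed(child_seed(seed, 20000L + i),
                     draw_identity(subject_variability))
  })
  clips <- list()
  k <- 0L
  for (i in seq_len(nrow(subjects))) {
    idv <- identities[[i]]
    subj_constants <- constants
    subj_constants$A0 <- constants$A0 * idv$expressivity
    subj_constants$tau0 <- constants$tau0 * idv$tempo
    for (expr in EXPRESSIONS) {
      k <- k + 1L
      clip_seed <- child_seed(seed, k)
      curve <- activation_profile(expr, subjects$severity[i], fps, duration_s,
                                  seed = clip_seed,
                                  constants = subj_constants)
      clips[[k]] <- structure(list(
        subject_id = subjects$subject_id[i], expression = expr, fps = fps,
        severity = subjects$severity[i], activation = curve,
        identity = idv$identity, n_frames = length(curve$values), size = size,
        noise_seed = clip_seed, subject_seed = child_seed(seed, 10000L + i),
        frame_dir = NULL), class = "expression_clip")
    }
  }
  structure(list(subjects = subjects, clips = clips, seed = as.integer(seed),
                 size = as.integer(size)),
            class = "hm_cohort")
}

#' Materialise frames of an expression clip
#'
#' Renders the requested frames of a clip (all frames by default). Each frame
#' is the deterministic rendering of the expression at that frame's activation
#' value, plus a fixed per-subject texture field (identity) and light
#' per-frame sensor noise, both seeded, so repeated calls return identical
#' pixels. If the clip was read from disk ([read_cohort()]), frames are loaded
#' from its PNG files instead.
#'
#' @param clip an `expression_clip`.
#' @param idx frame indices (1-based); default all.
#' @return array `[size, size, 1, length(idx)]` in `[0, 1]`.
#' @export
clip_frames <- function(clip, idx = NULL) {
  idx <- if (is.null(idx)) seq_len(clip$n_frames) else as.integer(idx)
  if (any(idx < 1L | idx > clip$n_frames)) {
    stop_validation("frame index out of range")
  }
  size <- clip$size
  out <- array(0, c(size, size, 1L, length(idx)))
  if (!is.null(clip$frame_dir)) {
    for (j in seq_along(idx)) {
      f <- file.path(clip$frame_dir, sprintf("frame_%04d.png", idx[j]))
      a <- png::readPNG(f)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      out[, , 1L, j] <- a[seq_len(size), seq_len(size)]
    }
    return(out)
  }
  id_field <- withr::with_seed(clip$subject_seed,
                               matrix(stats::rnorm(size * size, 0, 0.02),
                                      size, size))
  frame_noise <- withr::with_seed(child_seed(clip$noise_seed, 1L),
                                  stats::rnorm(size * size * clip$n_frames,
                                               0, 0.01))
  for (j in seq_along(idx)) {
    i <- idx[j]
    img <- render_face(expression_face_params(clip$expression,
                                              clip$activation$values[i]),
                       size, identity = clip$identity)
    nz <- frame_noise[((i - 1) * size * size + 1):(i * size * size)]
    out[, , 1L, j] <- pmin(1, pmax(0, img + id_field + nz))
  }
  out
}

#' Action-unit groups per expression
#'
#' The action units relevant to the elicited tasks: AUs 4, 5, 25 and 26 relate
#' to anger; AUs 6, 12 and 25 to smile; AUs 1, 2, 5, 25 and 26 to surprise.
#' Wink tasks have no assigned AU from the selected set.
#' @return named list of integer AU id vectors, one per expression.
#' @export
au_groups <- function() {
  list(wink_r = integer(0), wink_l = integer(0),
       smile = c(6L, 12L, 25L),
       anger = c(4L, 5L, 25L, 26L),
       surprise = c(1L, 2L, 5L, 25L, 26L))
}

#' Binary action-unit labels for an expression at an activation level
#'
#' An AU bit is set iff the AU belongs to the expression's group (see
#' [au_groups()]) and the absolute activation reaches that AU's threshold.
#'
#' @param expression expression name.
#' @param activation_value signed activation in `[-1, 1]`.
#' @param thresholds scalar or named vector (names `"au1"`, `"au2"`, ...) of
#'   on-thresholds in `[0, 1]`; default 0.5.
#' @return named integer vector of length 8 in AU order 1, 2, 4, 5, 6, 12,
#'   25, 26.
#' @export
au_labels_for <- function(expression, activation_value, thresholds = 0.5) {
  if (!expression %in% EXPRESSIONS) {
    stop_validation("unknown expression: ", expression)
  }
  assert_range(activation_value, -1, 1, "activation_value")
  aus <- select_aus()
  nm <- paste0("au", aus)
  thr <- if (length(thresholds) == 1L) stats::setNames(rep(thresholds, 8L), nm)
         else thresholds[nm]
  grp <- au_groups()[[expression]]
  bits <- as.integer(aus %in% grp & abs(activation_value) >= thr)
  stats::setNames(bits, nm)
}

#' Generate a synthetic action-unit image dataset
#'
#' Renders faces across the five expressions at random activation magnitudes
#' and labels them with [au_labels_for()], producing a stand-in for a large
#' AU-annotated corpus. Splits are stratified by expression.
#'
#' @param n_images number of images (>= 10).
#' @param seed integer seed.
#' @param split_fracs named fractions for train/val/test; must sum to 1.
#' @param size image side in pixels.
#' @param thresholds AU on-thresholds, see [au_labels_for()].
#' @return an `hm_au_dataset`: `images` array `[size, size, 1, n]`, `labels`
#'   n x 8 matrix, `expression`, `activation`, `split` (factor), `seed`.
#' @export
make_au_dataset <- function(n_images, seed = 1L,
                            split_fracs = c(train = 0.8, val = 0.1, test = 0.1),
                            size = 64L, thresholds = 0.5) {
  if (n_images < 10) stop_validation("n_images must be >= 10")
  if (abs(sum(split_fracs) - 1) > 1e-8) {
    stop_validation("split_fracs must sum to 1")
  }
  gen <- function() {
    expr <- sample(EXPRESSIONS, n_images, replace = TRUE)
    mag <- stats::runif(n_images)
    act <- mag * vapply(expr, expression_sign, numeric(1))
    images <- array(0, c(size, size, 1L, n_images))
    labels <- matrix(0L, n_images, 8L,
                     dimnames = list(NULL, paste0("au", select_aus())))
    noise <- matrix(stats::rnorm(size * size * n_images, 0, 0.02), ncol = n_images)
    for (i in seq_len(n_images)) {
      img <- render_face(expression_face_params(expr[i], act[i]), size)
      images[, , 1L, i] <- pmin(1, pmax(0, img + matrix(noise[, i], size, size)))
      labels[i, ] <- au_labels_for(expr[i], act[i], thresholds)
    }
    ## stratified split: per-expression quotas by largest remainder, with
    ## global partition sizes met exactly
    split <- character(n_images)
    targets <- floor(split_fracs * n_images)
    rem <- n_images - sum(targets)
    if (rem > 0) {
      o <- order(split_fracs * n_images - targets, decreasing = TRUE)
      targets[o[seq_len(rem)]] <- targets[o[seq_len(rem)]] + 1
    }
    exprs <- unique(expr)
    pools <- lapply(exprs, function(e) sample(which(expr == e)))
    names(pools) <- exprs
    taken <- stats::setNames(rep(0L, length(exprs)), exprs)
    for (sname in names(split_fracs)) {
      quota <- vapply(exprs, function(e) {
        length(pools[[e]]) * split_fracs[[sname]]
      }, numeric(1))
      alloc <- floor(quota)
      extra <- targets[[sname]] - sum(alloc)
      if (extra > 0) {
        o <- order(quota - alloc, decreasing = TRUE)
        alloc[o[seq_len(extra)]] <- alloc[o[seq_len(extra)]] + 1
      } else if (extra < 0) {
        o <- order(quota - alloc)
        alloc[o[seq_len(-extra)]] <- alloc[o[seq_len(-extra)]] - 1
      }
      for (e in exprs) {
        k <- alloc[[e]]
        if (k > 0) {
          ii <- pools[[e]][taken[[e]] + seq_len(k)]
          split[ii] <- sname
          taken[[e]] <- taken[[e]] + k
        }
      }
    }
    ## any residue from rounding interplay goes to the last split
    split[split == ""] <- names(split_fracs)[length(split_fracs)]
    list(expr = expr, act = act, images = images, labels = labels,
         split = split)
  }
  g <- withr::with_seed(seed, gen())
  if (any(table(factor(g$split, levels = names(split_fracs))) == 0)) {
    stop_validation("split fractions produce an empty partition")
  }
  structure(list(images = g$images, labels = g$labels, expression = g$expr,
                 activation = g$act,
                 split = factor(g$split, levels = names(split_fracs)),
                 thresholds = thresholds, seed = as.integer(seed),
                 size = as.integer(size)),
            class = "hm_au_dataset")
}

## ---- cohort I/O -------------------------------------------------------------

#' Write / read a cohort to disk
#'
#' `write_cohort()` materialises a cohort as PNG frames
#' (`<subject>/<expression>/frame_%04d.png`), one activation CSV per clip
#' (`frame_index,value`, 1-based) and a JSON manifest. `read_cohort()` loads
#' the manifest back; frames are then read lazily from the PNGs.
#'
#' @param cohort an `hm_cohort`.
#' @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cohort$seed, size = cohort$size,
                   subjects = cohort$subjects, clips = list())
  for (ci in seq_along(cohort$clips)) {
    clip <- cohort$clips[[ci]]
    cdir <- file.path(dir, clip$subject_id, clip$expression)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    frames <- clip_frames(clip)
    for (i in seq_len(clip$n_frames)) {
      png::writePNG(frames[, , 1L, i],
                    file.path(cdir, sprintf("frame_%04d.png", i)))
    }
    utils::write.csv(data.frame(frame_index = seq_len(clip$n_frames),
                                value = clip$activation$values),
                     file.path(cdir, "activation.csv"), row.names = FALSE)
    manifest$clips[[ci]] <- list(
      subject_id = clip$subject_id, expression = clip$expression,
      fps = clip$fps, severity = clip$severity, n_frames = clip$n_frames,
      dir = file.path(clip$subject_id, clip$expression))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- as.data.frame(manifest$subjects, stringsAsFactors = FALSE)
  clips <- lapply(seq_along(manifest$clips$subject_id), function(ci) {
    cdir <- file.path(dir, manifest$clips$dir[ci])
    act <- utils::read.csv(file.path(cdir, "activation.csv"))
    structure(list(
      subject_id = manifest$clips$subject_id[ci],
      expression = manifest$clips$expression[ci],
      fps = manifest$clips$fps[ci],
      severity = manifest$clips$severity[ci],
      activation = structure(list(values = act$value,
                                  fps = manifest$clips$fps[ci]),
                             class = "activation_curve"),
      n_frames = manifest$clips$n_frames[ci], size = manifest$size,
      noise_seed = NA_integer_, subject_seed = NA_integer_,
      frame_dir = cdir), class = "expression_clip")
  })
  structure(list(subjects = subjects, clips = clips, seed = manifest$seed,
                 size = manifest$size),
            class = "hm_cohort")
}

#' @export
print.hm_cohort <- function(x, ...) {
  cat(sprintf("<hm_cohort> %d subjects (%d PD, %d HC), %d clips, %dx%d px\n",
              nrow(x$subjects), sum(x$subjects$group == "PD"),
              sum(x$subjects$group == "HC"), length(x$clips), x$size, x$size))
  invisible(x)
}
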