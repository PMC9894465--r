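## Expression stage detection on activation curves and multi-frame sequence
## assembly (N, On, A, Off, N and the NOnA / AOffN / NOnAOffN subsequences).

SEQUENCE_KINDS <- c("single_N", "single_On", "single_A", "single_Off",
                    "NOnA", "AOffN", "NOnAOffN")

## Stage tags per sequence kind, in temporal order.
sequence_kind_tags <- function(kind) {
  switch(kind,
    single_N = "N", single_On = "On", single_A = "A", single_Off = "Off",
    NOnA = c("N", "On", "A"),
    AOffN = c("A", "Off", "N"),
    NOnAOffN = c("N", "On", "A", "Off", "N"),
    stop_validation("unknown sequence kind: ", kind))
}

stage_for_tag <- function(stages, tags) {
  ## the leading neutral maps to neutral1, the trailing one to neutral2
  idx <- integer(length(tags))
  seen_apex <- FALSE
  for (i in seq_along(tags)) {
    idx[i] <- switch(tags[i],
      N = if (seen_apex) stages$neutral2 else stages$neutral1,
      On = stages$onset, A = stages$apex, Off = stages$offset)
    if (tags[i] == "A") seen_apex <- TRUE
  }
  ## a single trailing N (kind single_N) refers to the first neutral frame
  idx
}

#' Detect the five expression stages on an activation curve
#'
#' Works on the absolute activation so positive (smile) and negative (anger)
#' valence are handled identically. The apex is the first index attaining the
#' maximum absolute activation; onset and offset are the first/last crossings
#' of 50% of the apex amplitude on the rising/falling side; the two neutral
#' frames are the last index before onset and the first index after offset at
#' or below 10% of the apex amplitude (falling back to the clip ends).
#'
#' @param curve an `activation_curve` (list with `values`, `fps`) or a numeric
#'   vector of activations.
#' @param min_amplitude minimum apex amplitude; flatter curves raise a
#'   degenerate-curve error (condition class `hm_degenerate_error`).
#' @return a `stage_indices` list with 1-based frame indices `neutral1 <=
#'   onset <= apex <= offset <= neutral2`.
#' @export
detect_stages <- function(curve, min_amplitude = 0.05) {
  v <- if (inherits(curve, "activation_curve")) curve$values else curve
  if (length(v) < 5L) stop_validation("curve must have at least 5 frames")
  if (anyNA(v) || any(!is.finite(v))) stop_validation("curve must be finite")
  a <- abs(v)
  apex <- which.max(a)            # first occurrence on plateaus
  amp <- a[apex]
  if (amp < min_amplitude) {
    stop_degenerate("flat activation curve: apex amplitude ", signif(amp, 3),
                    " is below ", min_amplitude)
  }
  onset <- which(a[seq_len(apex)] >= 0.5 * amp)[1]
  offset <- apex - 1L + max(which(a[apex:length(a)] >= 0.5 * amp))
  pre <- which(a[seq_len(onset)] <= 0.1 * amp)
  neutral1 <- if (length(pre)) max(pre) else 1L
  post <- which(a[offset:length(a)] <= 0.1 * amp)
  neutral2 <- if (length(post)) offset - 1L + min(post) else length(a)
  structure(list(neutral1 = as.integer(neutral1), onset = as.integer(onset),
                 apex = as.integer(apex), offset = as.integer(offset),
                 neutral2 = as.integer(neutral2)),
            class = "stage_indices")
}

#' Extract a stage frame sequence from a clip
#'
#' Materialises the frames demanded by `kind` (a single stage frame, or the
#' 3/5-frame subsequences) at the detected stage indices, in temporal order
#' and tagged with their stage.
#'
#' @param clip an `expression_clip`.
#' @param stages a `stage_indices` from [detect_stages()]; computed from the
#'   clip's own curve when omitted.
#' @param kind one of `single_N`, `single_On`, `single_A`, `single_Off`,
#'   `NOnA`, `AOffN`, `NOnAOffN`.
#' @return a `frame_sequence`: `frames` array `[H, W, 1, k]`, `stage_tags`,
#'   `indices`, `subject_id`, `expression`, `kind`.
#' @export
extract_sequence <- function(clip, stages = NULL, kind = "NOnAOffN") {
  if (!kind %in% SEQUENCE_KINDS) stop_validation("unknown sequence kind: ", kind)
  if (is.null(stages)) stages <- detect_stages(clip$activation)
  if (with(stages, !(neutral1 <= onset && onset <= apex && apex <= offset &&
                     offset <= neutral2))) {
    stop_validation("stage indices are not temporally ordered")
  }
  if (stages$neutral2 > clip$n_frames) {
    stop_validation("stage indices exceed clip length")
  }
  tags <- sequence_kind_tags(kind)
  idx <- stage_for_tag(stages, tags)
  structure(list(subject_id = clip$subject_id, expression = clip$expression,
                 kind = kind, frames = clip_frames(clip, idx),
                 stage_tags = tags, indices = idx),
            class = "frame_sequence")
}

#' Total frame count of a cohort under a sequence kind
#'
#' Sums, over all clips with detectable stages, the number of frames each
#' extracted sequence contributes (5 per clip for `NOnAOffN`, 3 for
#' `NOnA`/`AOffN`, 1 for single-frame kinds). Degenerate curves propagate as
#' errors.
#'
#' @param cohort an `hm_cohort`.
#' @param kind sequence kind, default `NOnAOffN`.
#' @param min_amplitude passed to [detect_stages()].
#' @return integer frame count.
#' @export
cohort_frame_count <- function(cohort, kind = "NOnAOffN",
                               min_amplitude = 0.05) {
  if (!kind %in% SEQUENCE_KINDS) stop_validation("unknown sequence kind: ", kind)
  per <- length(sequence_kind_tags(kind))
  for (clip in cohort$clips) detect_stages(clip$activation, min_amplitude)
  per * length(cohort$clips)
}

#' @export
print.stage_indices <- function(x, ...) {
  cat(sprintf("<stages> N1=%d On=%d A=%d Off=%d N2=%d\n", x$neutral1, x$onset,
              x$apex, x$offset, x$neutral2))
  invisible(x)
}
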