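## Closed-form stage indices of a symmetric triangle curve (1-based):
## v rises linearly 0 -> 1 over frames 1..(m+1) and falls back to 0 at
## 2m+1; crossings of level q sit at 1 + q*m (rising) and 2m+1 - q*m
## (falling).
triangle_curve <- function(m) {
  c(seq(0, 1, length.out = m + 1), seq(1, 0, length.out = m + 1)[-1])
}

test_that("stage detection matches the closed-form triangle solution", {
  m <- 40
  st <- detect_stages(triangle_curve(m))
  expect_equal(st$apex, m + 1)
  expect_equal(st$onset, 1 + ceiling(0.5 * m))         # first |v| >= 0.5
  expect_equal(st$offset, 2 * m + 1 - ceiling(0.5 * m)) # last |v| >= 0.5
  expect_equal(st$neutral1, 1 + floor(0.1 * m))        # last |v| <= 0.1
  expect_equal(st$neutral2, 2 * m + 1 - floor(0.1 * m))
  ## negative-valence curve gives identical stages
  stn <- detect_stages(-triangle_curve(m))
  expect_identical(unclass(st), unclass(stn))
})

test_that("degenerate and plateau curves are handled as specified", {
  expect_error(detect_stages(rep(0, 50)), class = "hm_degenerate_error")
  expect_error(detect_stages(rep(0.01, 50)), class = "hm_degenerate_error")
  expect_error(detect_stages(c(0, 1)), "5")
  ## plateau at the maximum: apex is the first index attaining it
  v <- c(seq(0, 1, length.out = 31), rep(1, 20), seq(1, 0, length.out = 31))
  st <- detect_stages(v)
  apex_oracle <- which(v == max(v))[1]   # brute-force first-occurrence argmax
  expect_equal(st$apex, apex_oracle)
  expect_true(st$apex >= 31 && st$apex <= 51)
})

test_that("stage ordering holds on random jittered profiles", {
  for (s in 1:25) {
    cv <- activation_profile(sample(c("smile", "anger", "surprise"), 1),
                             stats::runif(1), fps = 15, duration_s = 6,
                             seed = s)
    st <- detect_stages(cv)
    expect_true(st$neutral1 <= st$onset && st$onset <= st$apex &&
                  st$apex <= st$offset && st$offset <= st$neutral2)
  }
})

test_that("higher severity slows the detected onset transition", {
  k <- hypomimia_constants(sigma_j = 0)
  onset_time <- function(sev) {
    cv <- activation_profile("smile", sev, fps = 15, duration_s = 6,
                             constants = k)
    st <- detect_stages(cv)
    (st$onset - st$neutral1) / cv$fps
  }
  expect_gte(onset_time(1), onset_time(0))
  expect_gte(onset_time(0.8), onset_time(0.2))
})

test_that("sequence extraction returns the demanded stage frames", {
  co <- simulate_cohort(1, 1, seed = 5, size = 32)
  clip <- co$clips[[3]]
  st <- detect_stages(clip$activation)
  lens <- c(single_N = 1, single_On = 1, single_A = 1, single_Off = 1,
            NOnA = 3, AOffN = 3, NOnAOffN = 5)
  for (kind in names(lens)) {
    sq <- extract_sequence(clip, st, kind)
    expect_equal(dim(sq$frames)[4], unname(lens[kind]))
  }
  sq <- extract_sequence(clip, st, "NOnA")
  expect_identical(sq$stage_tags, c("N", "On", "A"))
  expect_identical(sq$indices, c(st$neutral1, st$onset, st$apex))
  sqA <- extract_sequence(clip, st, "single_A")
  expect_identical(sqA$indices, st$apex)
  expect_identical(sqA$frames, clip_frames(clip, st$apex))
  ## the five-frame sequence shares frames with its subsequences and
  ## re-extraction is byte-identical
  sq5 <- extract_sequence(clip, st, "NOnAOffN")
  expect_identical(sq5$frames[, , , 1:3], sq$frames[, , , 1:3])
  expect_identical(sq5$frames, extract_sequence(clip, st, "NOnAOffN")$frames)
  expect_error(extract_sequence(clip, st, "apex_only"), "kind")
})

test_that("cohort frame counts follow kind arithmetic", {
  co54 <- simulate_cohort(30, 24, seed = 9, size = 32)
  expect_equal(cohort_frame_count(co54, "NOnAOffN"), 1350)
  expect_equal(cohort_frame_count(co54, "NOnA"), 810)
  co1 <- simulate_cohort(1, 1, seed = 9, size = 32)
  expect_equal(cohort_frame_count(co1, "NOnAOffN"), 50)
  ## one subject's five clips carry 25 five-stage frames
  one <- co1
  one$clips <- one$clips[1:5]
  expect_equal(cohort_frame_count(one, "NOnAOffN"), 25)
  ## degenerate curves propagate
  co1$clips[[1]]$activation$values <- rep(0, 90)
  expect_error(cohort_frame_count(co1), class = "hm_degenerate_error")
})
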