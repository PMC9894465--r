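test_that("rendering is deterministic and the neutral face is the template", {
  img1 <- render_face(face_params(), size = 64)
  img2 <- render_face(face_params(), size = 64)
  expect_identical(img1, img2)
  expect_true(all(img1 >= 0 & img1 <= 1))
  expect_equal(dim(img1), c(64L, 64L))
  expect_error(render_face(face_params(), size = 16), "size")
  expect_error(render_face(list(lip_corner_pull = 2)), "lip_corner_pull")
})

test_that("lip corner pull changes only lower-face pixels", {
  neutral <- render_face(face_params(), 64)
  smile <- render_face(face_params(lip_corner_pull = 1), 64)
  diffmask <- abs(smile - neutral) > 0
  expect_gt(mean(abs(smile - neutral)), 0)
  ## brute-force row check: all changed pixels are in the lower face
  changed_rows <- which(apply(diffmask, 1, any))
  expect_true(all(changed_rows > 32))
  ## monotone response: stronger pull changes more than weaker pull
  half <- render_face(face_params(lip_corner_pull = 0.5), 64)
  expect_false(identical(half, smile))
})

test_that("closing the left eye darkens only the left-eye region", {
  neutral <- render_face(face_params(), 64)
  wink <- render_face(face_params(eye_close_left = 1), 64)
  diff <- abs(wink - neutral)
  ## region-wise comparison: all change confined to the left half
  expect_gt(sum(diff[, 1:32]), 0)
  expect_lt(max(diff[, 33:64]), 1e-6)
})

test_that("noise-free activation profiles are trapezoids with the stated apex", {
  k <- hypomimia_constants(sigma_j = 0)
  cv <- activation_profile("smile", severity = 0, fps = 15, duration_s = 6,
                           constants = k)
  expect_length(cv$values, 90)
  expect_equal(max(cv$values), k$A0, tolerance = 1e-12)
  expect_lt(abs(cv$values[1]), 0.1 * k$A0)
  expect_lt(abs(cv$values[90]), 0.1 * k$A0)
  ## anger has a negative apex
  ang <- activation_profile("anger", 0, 15, 6, constants = k)
  expect_equal(min(ang$values), -k$A0, tolerance = 1e-12)
  ## determinism of the noise-free curve
  expect_identical(cv$values,
                   activation_profile("smile", 0, 15, 6, constants = k)$values)
})

test_that("apex amplitude shrinks with severity as A0 * (1 - beta * s)", {
  k <- hypomimia_constants(beta = 0.5, sigma_j = 0.02)
  ## measure max |v| over 100 seeds at severity 1
  apexes <- vapply(1:100, function(s) {
    max(abs(activation_profile("smile", 1, 15, 6, seed = s,
                               constants = k)$values))
  }, numeric(1))
  expect_lt(abs(mean(apexes) - 0.5 * k$A0), 3 * k$sigma_j)
  ## noise-free monotonicity over a severity grid
  k0 <- hypomimia_constants(sigma_j = 0)
  amps <- vapply(seq(0, 1, by = 0.1), function(s) {
    max(abs(activation_profile("smile", s, 15, 6, constants = k0)$values))
  }, numeric(1))
  expect_true(all(diff(amps) <= 1e-12))
})

test_that("rise time stretches with severity as tau0 * (1 + gamma * s)", {
  k <- hypomimia_constants(gamma = 1, sigma_j = 0)
  rise_time <- function(s) {
    v <- abs(activation_profile("smile", s, fps = 1000, duration_s = 6,
                                constants = k)$values)
    a <- max(v)
    (which(v >= 0.9 * a)[1] - which(v >= 0.1 * a)[1]) / 1000
  }
  expect_equal(rise_time(1) / rise_time(0), 2, tolerance = 0.02)
  ## non-decreasing over a severity grid
  rts <- vapply(seq(0, 1, by = 0.25), rise_time, numeric(1))
  expect_true(all(diff(rts) >= -1e-9))
  ## too-short clips are rejected
  expect_error(activation_profile("smile", 1, 15, duration_s = 1.5),
               "duration")
})

test_that("simulated cohorts have the expected structure and reproduce", {
  co <- simulate_cohort(30, 24, fps = 15, duration_s = 6, seed = 7, size = 32)
  expect_equal(nrow(co$subjects), 54)
  expect_length(co$clips, 270)
  expect_true(all(vapply(co$clips, `[[`, numeric(1), "n_frames") == 90))
  expect_true(all(co$subjects$severity[co$subjects$group == "HC"] == 0))
  expect_true(all(co$subjects$severity[co$subjects$group == "PD"] >= 0.4))
  ## each subject has exactly one clip per expression
  tab <- table(vapply(co$clips, `[[`, character(1), "subject_id"),
               vapply(co$clips, `[[`, character(1), "expression"))
  expect_true(all(tab == 1))
  ## minimal cohort
  expect_length(simulate_cohort(1, 1, seed = 1, size = 32)$clips, 10)
  ## determinism: same seed gives identical curves and frames
  co2 <- simulate_cohort(30, 24, fps = 15, duration_s = 6, seed = 7,
                         size = 32)
  expect_identical(co$subjects, co2$subjects)
  expect_identical(co$clips[[13]]$activation$values,
                   co2$clips[[13]]$activation$values)
  expect_identical(clip_frames(co$clips[[13]], 1:3),
                   clip_frames(co2$clips[[13]], 1:3))
})

test_that("AU labels follow the expression groups and threshold", {
  expect_identical(unname(au_labels_for("smile", 1.0)),
                   as.integer(select_aus() %in% c(6, 12, 25)))
  expect_identical(unname(au_labels_for("anger", 1.0)),
                   as.integer(select_aus() %in% c(4, 5, 25, 26)))
  expect_identical(unname(au_labels_for("anger", -1.0)),
                   as.integer(select_aus() %in% c(4, 5, 25, 26)))
  expect_identical(unname(au_labels_for("smile", 0.0)), rep(0L, 8))
  ## sub-threshold activation switches every bit off
  expect_identical(unname(au_labels_for("smile", 0.49)), rep(0L, 8))
  expect_error(au_labels_for("frown", 1.0), "expression")
  ## the groups cover all 8 selected AUs
  expect_setequal(unique(unlist(au_groups())), select_aus())
  ## deterministic
  expect_identical(au_labels_for("surprise", 0.7),
                   au_labels_for("surprise", 0.7))
})

test_that("AU datasets split exactly, label consistently and reproduce", {
  ds <- make_au_dataset(1000, seed = 3, size = 32)
  expect_equal(as.vector(table(ds$split)), c(800, 100, 100))
  ds2 <- make_au_dataset(1000, seed = 3, size = 32)
  expect_identical(ds$labels, ds2$labels)
  expect_identical(ds$split, ds2$split)
  ## generator bookkeeping: AU12-positive images come from smiles at or
  ## above the activation threshold (lip corner pull engaged)
  au12 <- ds$labels[, "au12"] == 1
  expect_true(all(ds$expression[au12] == "smile"))
  expect_true(all(abs(ds$activation[au12]) >= 0.5))
  expect_error(make_au_dataset(5), "n_images")
  expect_error(make_au_dataset(100, split_fracs = c(train = 0.5, val = 0.3)),
               "sum")
})

test_that("cohorts round-trip through disk", {
  co <- simulate_cohort(1, 1, seed = 3, size = 32)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$subjects), 2)
  expect_length(back$clips, 10)
  expect_equal(back$clips[[2]]$activation$values,
               co$clips[[2]]$activation$values, tolerance = 1e-12)
  ## PNG round-trip quantises to 8 bits
  expect_equal(clip_frames(back$clips[[2]], 5), clip_frames(co$clips[[2]], 5),
               tolerance = 1 / 200)
})
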