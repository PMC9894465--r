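test_that("the hyper-parameter grid is exactly the printed powers of ten", {
  g <- svm_grid()
  expect_equal(nrow(g), 72)                        # 64 Gaussian + 8 linear
  expect_equal(sum(g$kernel == "linear"), 8)
  expect_equal(sum(g$kernel == "radial"), 64)
  expect_setequal(unique(g$C), 10^(-4:3))
  expect_setequal(unique(g$gamma[g$kernel == "radial"]), 10^(-4:3))
  expect_true(all(is.na(g$gamma[g$kernel == "linear"])))
  ## 8 x 8 Gaussian grid: every (C, gamma) combination exactly once
  expect_equal(anyDuplicated(g[g$kernel == "radial", c("C", "gamma")]), 0)
})

test_that("sequence fusion concatenates in temporal order or defers to scores", {
  f3 <- matrix(as.numeric(seq_len(3 * 2048)), 2048, 3)
  expect_length(fuse_sequence(f3, "concat"), 6144)
  f5 <- matrix(stats::rnorm(5 * 2048), 2048, 5)
  expect_length(fuse_sequence(f5, "concat"), 10240)
  ## temporal order preserved: first block is the first frame
  expect_identical(fuse_sequence(f3, "concat")[1:2048], f3[, 1])
  sg <- fuse_sequence(f3, "mean_score")
  expect_s3_class(sg, "hm_score_group")
  expect_identical(sg$frames, f3)
  ## averaging identical per-frame scores returns that score
  expect_equal(mean(rep(0.37, 5)), 0.37)
})

test_that("cross-validation plans are subject-disjoint and stratified", {
  subjects <- data.frame(
    subject_id = c(sprintf("PD%02d", 1:30), sprintf("HC%02d", 1:24)),
    group = rep(c("PD", "HC"), c(30, 24)))
  plan <- make_cv_plan(subjects, k = 5, seed = 3)
  sizes <- sort(vapply(plan$folds, function(f) length(f$test), numeric(1)))
  expect_equal(sizes, c(10, 11, 11, 11, 11))
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")),
                  subjects$subject_id)
  expect_silent(audit_cv_plan(plan))
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val, f$test), subjects$subject_id)
  }
  ## determinism and the small-class guard
  expect_identical(make_cv_plan(subjects, k = 5, seed = 3), plan)
  tiny <- subjects[c(1:3, 31:34), ]
  expect_error(make_cv_plan(tiny, k = 5), "k subjects")
  ## the audit catches injected leakage
  broken <- plan
  broken$folds[[1]]$train <- c(broken$folds[[1]]$train,
                               broken$folds[[1]]$test[1])
  expect_error(audit_cv_plan(broken), "leakage")
})

test_that("classification metrics match confusion-matrix arithmetic", {
  y <- rep(c("PD", "HC"), c(30, 24))
  perfect <- ifelse(y == "PD", 1, -1)
  m <- classification_metrics(perfect, y)
  expect_equal(unlist(m[c("acc", "sens", "spec", "f1")]),
               c(acc = 100, sens = 100, spec = 100, f1 = 100))
  expect_equal(m$auc, 1.0)
  ## predicting everyone as PD on a 30/24 cohort
  all_pd <- classification_metrics(rep(1, 54), y)
  expect_equal(all_pd$sens, 100)
  expect_equal(all_pd$spec, 0)
  expect_equal(all_pd$acc, 100 * 30 / 54, tolerance = 1e-9)
  ## random instances vs the hand-computed confusion matrix
  for (s in 1:20) {
    sc <- withr::with_seed(s, stats::rnorm(40))
    yy <- withr::with_seed(s + 30,
                           sample(c("PD", "HC"), 40, replace = TRUE,
                                  prob = c(0.6, 0.4)))
    if (length(unique(yy)) < 2) next
    got <- classification_metrics(sc, yy)
    want <- oracle_metrics(sc, yy)
    expect_equal(got[c("acc", "sens", "spec", "f1")], want, tolerance = 1e-9)
  }
  expect_error(classification_metrics(1:3, c("PD", "PD", "PD")), "classes")
})

test_that("hyper-parameter modes follow the frequency-then-smallest rule", {
  sel <- data.frame(kernel = rep("linear", 5),
                    C = c(0.1, 0.1, 0.1, 0.01, 0.01),
                    gamma = NA_real_)
  expect_equal(mode_hyperparams(sel)$C, 0.1)
  ## all distinct: smallest C wins
  sel2 <- data.frame(kernel = "radial", C = c(10, 0.001, 1),
                     gamma = c(1, 1, 1))
  expect_equal(mode_hyperparams(sel2)$C, 0.001)
  ## equals a brute-force frequency count on random selections
  for (s in 1:10) {
    cs <- withr::with_seed(s, sample(10^(-2:2), 7, replace = TRUE))
    sel3 <- data.frame(kernel = "linear", C = cs, gamma = NA_real_)
    tab <- sort(table(cs), decreasing = TRUE)
    best <- as.numeric(names(tab)[tab == max(tab)])
    expect_equal(mode_hyperparams(sel3)$C, min(best))
  }
})

test_that("nested CV is perfect on separable features and near chance on noise", {
  toy <- toy_feature_set(n_subj = 8, sep = 6, seed = 5)
  plan <- make_cv_plan(toy$subjects, k = 5, seed = 6)
  rep_ <- run_nested_cv(toy$features, toy$meta, plan)
  expect_equal(rep_$aggregate$acc[["mean"]], 100)
  expect_equal(rep_$aggregate$acc[["sd"]], 0)
  ## sample conservation: every fold sees every sample exactly once
  expect_equal(sum(rep_$per_fold$n_test), ncol(toy$features))
  ## label-shuffled features hover around chance (reduced grid: shuffled
  ## labels make large-C fits expensive without changing the conclusion)
  perm_grid <- svm_grid()[c(2, 4, 6, 12, 30, 44, 58), ]
  accs <- vapply(1:10, function(s) {
    perm <- withr::with_seed(s, sample(unique(toy$meta$subject_id)))
    relab <- toy
    new_groups <- stats::setNames(toy$subjects$group,
                                  perm)[toy$meta$subject_id]
    relab$meta$group <- unname(new_groups)
    relab$subjects$group <- unname(stats::setNames(toy$subjects$group,
                                                   perm)[toy$subjects$subject_id])
    p <- make_cv_plan(relab$subjects, k = 5, seed = s)
    run_nested_cv(relab$features, relab$meta, p,
                  grid = perm_grid)$aggregate$acc[["mean"]]
  }, numeric(1))
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("the selected configuration equals the exhaustive-grid argmax", {
  toy <- toy_feature_set(n_subj = 6, sep = 1.2, seed = 9)
  plan <- make_cv_plan(toy$subjects, k = 3, seed = 10)
  grid <- svm_grid()[c(2, 5, 12, 30, 55), ]
  rep_ <- run_nested_cv(toy$features, toy$meta, plan, grid = grid)
  for (fi in seq_along(plan$folds)) {
    f <- plan$folds[[fi]]
    tr <- which(toy$meta$subject_id %in% f$train)
    va <- which(toy$meta$subject_id %in% f$val)
    ph <- hypomimia:::svm_phase(toy$features[, tr, drop = FALSE],
                                toy$features[, va, drop = FALSE])
    accs <- vapply(seq_len(nrow(grid)), function(gi) {
      sc <- hypomimia:::svm_kernel_decision(ph, toy$meta$group[tr],
                                            grid$kernel[gi], grid$C[gi],
                                            grid$gamma[gi])
      mean((sc > 0) == (toy$meta$group[va] == "PD"))
    }, numeric(1))
    best <- which(accs > max(accs) - 1e-12)[1]   # first-best tie rule
    expect_equal(rep_$selections$C[fi], grid$C[best])
    expect_equal(rep_$selections$kernel[fi], grid$kernel[best])
  }
})

test_that("mean-score fusion averages per-frame decisions per sequence", {
  toy <- toy_feature_set(n_subj = 6, per_subj = 5, sep = 5, seed = 12)
  groups <- lapply(seq_len(ncol(toy$features) / 5), function(i) {
    fuse_sequence(toy$features[, (i - 1) * 5 + 1:5], "mean_score")
  })
  meta5 <- toy$meta[seq(1, nrow(toy$meta), by = 5), ]
  plan <- make_cv_plan(toy$subjects, k = 3, seed = 13)
  rep_ <- run_nested_cv(groups, meta5, plan)
  expect_equal(rep_$aggregate$acc[["mean"]], 100)
})

test_that("repeated-CV model comparison applies the corrected tests", {
  good <- toy_feature_set(n_subj = 6, sep = 5, seed = 20)
  noise <- toy_feature_set(n_subj = 6, sep = 0, seed = 21)
  sets <- list(
    strong = list(features = good$features, meta = good$meta,
                  params = list(kernel = "linear", C = 0.1, gamma = NA)),
    weak = list(features = noise$features, meta = noise$meta,
                params = list(kernel = "linear", C = 0.1, gamma = NA)),
    weak2 = list(features = noise$features, meta = noise$meta,
                 params = list(kernel = "linear", C = 0.1, gamma = NA)))
  cmp <- compare_models(sets, good$subjects, n_reps = 25, k = 3, seed = 22)
  expect_equal(cmp$alpha_cor, 0.05 / 3)
  expect_equal(dim(cmp$accuracies), c(25L, 3L))
  ## the 30-point separability advantage is detected at alpha_cor
  expect_gt(mean(cmp$accuracies[, "strong"]) -
              mean(cmp$accuracies[, "weak"]), 30)
  pw <- cmp$pairwise
  expect_true(pw$reject[pw$model_a == "strong" & pw$model_b == "weak"])
  ## identical models under the same seed stream: p near 1, no rejection
  same <- pw[pw$model_a == "weak" & pw$model_b == "weak2", ]
  expect_gt(same$p_value, 0.9)
  expect_false(same$reject)
  expect_error(compare_models(sets, good$subjects, n_reps = 1), "n_reps")
  expect_error(compare_models(sets["strong"], good$subjects), "two models")
})
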