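test_that("the Mahalanobis-form distance matches its matrix formulation", {
  ## identity transform reduces to squared Euclidean distance
  expect_equal(mahalanobis_distance(c(1, 0), c(0, 0), diag(2)), 1)
  expect_equal(mahalanobis_distance(c(1, 2, 3), c(1, 2, 3), NULL), 0)
  ## random T: ||T(x_i - x_j)||^2 == (x_i - x_j)' (T'T) (x_i - x_j)
  for (s in 1:20) {
    d_in <- withr::with_seed(s, sample(2:8, 1))
    T_mat <- withr::with_seed(s + 50, matrix(stats::rnorm(3 * d_in), 3, d_in))
    xi <- withr::with_seed(s + 100, stats::rnorm(d_in))
    xj <- withr::with_seed(s + 150, stats::rnorm(d_in))
    M <- t(T_mat) %*% T_mat
    expect_equal(mahalanobis_distance(xi, xj, T_mat),
                 drop(t(xi - xj) %*% M %*% (xi - xj)), tolerance = 1e-9)
    ## symmetry and non-negativity
    expect_equal(mahalanobis_distance(xi, xj, T_mat),
                 mahalanobis_distance(xj, xi, T_mat), tolerance = 1e-12)
    expect_gte(mahalanobis_distance(xi, xj, T_mat), 0)
  }
  expect_error(mahalanobis_distance(1:3, 1:4), "dimension")
})

test_that("triplet mining enforces both constraints", {
  ## 2 PD samples with different expressions + 1 HC: exactly 2 triplets
  samples <- data.frame(y = c("PD", "PD", "HC"),
                        e = c("smile", "anger", "smile"))
  tr <- mine_triplets(samples, triplet_spec(mining = "all"))
  expect_equal(nrow(tr), 2)
  expect_setequal(tr$a, c(1, 2))
  expect_true(all(tr$n == 3))
  ## every returned triplet satisfies the constraints
  expect_true(all(samples$y[tr$a] == samples$y[tr$p]))
  expect_true(all(samples$e[tr$a] != samples$e[tr$p]))
  expect_true(all(samples$y[tr$a] != samples$y[tr$n]))
  ## all PD samples sharing one expression: no valid positive pair
  bad <- data.frame(y = c("PD", "PD", "HC", "HC"),
                    e = c("smile", "smile", "smile", "anger"))
  expect_error(mine_triplets(bad[bad$y == "PD" | bad$e == "smile", ]),
               "different expression")
  ## single class: no negative exists
  expect_error(mine_triplets(data.frame(y = c("PD", "PD"),
                                        e = c("smile", "anger"))),
               "classes")
  ## seeded random mining reproduces
  big <- data.frame(y = rep(c("PD", "HC"), each = 10),
                    e = rep_len(c("smile", "anger", "surprise"), 20))
  sp <- triplet_spec(n_triplets = 40, mining = "random", seed = 9)
  expect_identical(mine_triplets(big, sp), mine_triplets(big, sp))
})

test_that("full mining enumerates exactly the brute-force triplet set", {
  for (s in 1:5) {
    n <- withr::with_seed(s, sample(10:40, 1))
    y <- withr::with_seed(s + 10, sample(c("PD", "HC"), n, replace = TRUE))
    e <- withr::with_seed(s + 20,
                          sample(c("smile", "anger", "wink_l"), n,
                                 replace = TRUE))
    ok <- tryCatch({
      tr <- mine_triplets(data.frame(y = y, e = e),
                          triplet_spec(mining = "all"))
      expect_equal(nrow(tr), oracle_triplet_count(y, e))
      expect_equal(anyDuplicated(tr), 0)
      TRUE
    }, error = function(err) FALSE)
    if (!ok) expect_equal(oracle_triplet_count(y, e), 0)
  }
})

test_that("the hinge triplet loss matches a per-triplet loop", {
  ## hand arithmetic on fixed distances via 1-d features
  f <- matrix(c(0, 1, 2), 1)          # d2(1,2) = 1, d2(1,3) = 4
  one <- data.frame(a = 1, p = 2, n = 3)
  expect_equal(triplet_loss(f, one, NULL, alpha = 0.2), 0)
  rev_ <- data.frame(a = 1, p = 3, n = 2)  # d2(a,p) = 4, d2(a,n) = 1
  expect_equal(triplet_loss(f, rev_, NULL, alpha = 0.2), 3.2)
  ## batch of 100 random triplets vs the loop oracle
  feats <- withr::with_seed(1, matrix(stats::rnorm(5 * 30), 5, 30))
  T_mat <- withr::with_seed(2, matrix(stats::rnorm(3 * 5), 3, 5))
  trip <- withr::with_seed(3, data.frame(a = sample(30, 100, TRUE),
                                         p = sample(30, 100, TRUE),
                                         n = sample(30, 100, TRUE)))
  expect_equal(triplet_loss(feats, trip, T_mat, 0.2),
               oracle_triplet_loss(feats, trip, T_mat, 0.2),
               tolerance = 1e-9)
  ## margin monotonicity: loss is non-decreasing in alpha
  losses <- vapply(c(0, 0.1, 0.5, 1, 2), function(a) {
    triplet_loss(feats, trip, T_mat, a)
  }, numeric(1))
  expect_true(all(diff(losses) >= 0))
  expect_error(triplet_loss(feats, trip, T_mat, -1), "alpha")
})

test_that("satisfied triplets produce zero loss and zero gradient", {
  ## embeddings already separated by more than the margin
  e <- cbind(c(0, 0), c(0.1, 0), c(5, 5))
  trip <- data.frame(a = 1, p = 2, n = 3)
  tg <- hypomimia:::triplet_embedding_grad(e, trip, alpha = 0.2)
  expect_equal(tg$loss, 0)
  expect_equal(tg$n_active, 0)
  expect_true(all(tg$grad == 0))
})

test_that("linear triplet training separates classes in the learned metric", {
  ## two gaussian classes along one axis, expressions alternating
  set.seed(10)
  n <- 60
  x <- rbind(matrix(stats::rnorm(2 * n), 2),
             c(rep(2.5, n / 2), rep(-2.5, n / 2)))
  meta_y <- rep(c("PD", "HC"), each = n / 2)
  samples <- list(x = x, y = meta_y,
                  e = rep_len(c("smile", "anger", "surprise"), n),
                  subject = seq_len(n))
  res <- train_triplet(samples, triplet_spec(margin = 0.2, n_triplets = 120),
                       model = NULL, d_out = 2, normalize = TRUE,
                       epochs = 15, lr = 0.02, seed = 11)
  expect_s3_class(res$transform, "embedding_transform")
  emb <- hypomimia:::embed_apply(res$transform, x)
  dmat <- as.matrix(stats::dist(t(emb)))^2
  same <- outer(meta_y, meta_y, `==`)
  intra <- stats::median(dmat[same & upper.tri(dmat)])
  inter <- stats::median(dmat[!same & upper.tri(dmat)])
  expect_lt(intra, inter)
  ## loss does not increase over training (it may already start at zero)
  expect_lte(utils::tail(res$history$loss, 1), res$history$loss[1])
  ## seed-fixed reruns give identical histories
  res2 <- train_triplet(samples, triplet_spec(margin = 0.2,
                                              n_triplets = 120),
                        model = NULL, d_out = 2, normalize = TRUE,
                        epochs = 3, lr = 0.02, seed = 11)
  res3 <- train_triplet(samples, triplet_spec(margin = 0.2,
                                              n_triplets = 120),
                        model = NULL, d_out = 2, normalize = TRUE,
                        epochs = 3, lr = 0.02, seed = 11)
  expect_identical(res2$history, res3$history)
})

test_that("network-mode training respects frozen layers and tags the domain", {
  co <- simulate_cohort(2, 2, seed = 21, size = 32)
  samples <- cohort_triplet_samples(co, co$subjects$subject_id, "NOnA")
  m <- build_resnet7(default_resnet7_spec(), seed = 22)
  m <- attach_embed_head(m, d_out = 8, seed = 23)
  m <- freeze_layers(m, 0.5)
  before <- hypomimia:::nn_param_checksum(m$trunk, frozen_only = TRUE)
  res <- train_triplet(samples,
                       triplet_spec(margin = 0.2, n_triplets = 32),
                       model = m, epochs = 2, lr = 1e-3, seed = 24)
  tm <- res$transform$model
  expect_identical(hypomimia:::nn_param_checksum(tm$trunk,
                                                 frozen_only = TRUE),
                   before)
  expect_identical(tm$domain, "PD")
  x <- samples$x[, , , 1:2, drop = FALSE]
  expect_identical(extract_features(tm, x)$domain, "PD")
})
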