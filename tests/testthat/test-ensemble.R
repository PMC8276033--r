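test_that("a one-member ensemble scores exactly like its member", {
  d <- tiny_dataset()
  ens <- train_ensemble(d, n_models = 1L, config = tiny_config(),
                        base_seed = 31L)
  tails <- random_tails(8L, seed = 1L)
  pred <- ensemble_predict(ens, tails)
  expect_equal(pred$score, predict(ens$members[[1L]], tails))
  expect_identical(pred$sd, rep(0, 8L))
})

test_that("ensembles are seed-deterministic and extendable", {
  d <- tiny_dataset()
  e1 <- train_ensemble(d, n_models = 4L, config = tiny_config(),
                       base_seed = 50L)
  e2 <- train_ensemble(d, n_models = 4L, config = tiny_config(),
                       base_seed = 50L)
  expect_identical(lapply(e1$members, `[[`, "params"),
                   lapply(e2$members, `[[`, "params"))
  # member i trains with base_seed + i - 1, so a larger pool reuses members
  e6 <- train_ensemble(d, n_models = 6L, config = tiny_config(),
                       base_seed = 50L)
  expect_identical(e6$members[[3L]]$params, e1$members[[3L]]$params)
})

test_that("the ensemble mean equals the brute-force member average", {
  d <- tiny_dataset()
  ens <- train_ensemble(d, n_models = 5L, config = tiny_config(),
                        base_seed = 7L)
  tails <- random_tails(11L, seed = 3L)
  pred <- ensemble_predict(ens, tails)
  by_hand <- rowMeans(vapply(ens$members, predict, numeric(length(tails)),
                             tails = tails))
  expect_equal(pred$score, by_hand)
  expect_true(all(pred$score >= 0))
})

test_that("copies of one model give zero spread", {
  m <- train_model(tiny_dataset(), tiny_config())
  ens <- structure(list(members = list(m, m, m), base_seed = 1L,
                        config = tiny_config()), class = "ers_ensemble")
  pred <- ensemble_predict(ens, random_tails(6L, seed = 5L))
  expect_identical(pred$sd, rep(0, 6L))
  expect_equal(pred$score, predict(m, random_tails(6L, seed = 5L)))
})

test_that("averaging an ensemble does not hurt held-out error", {
  gt <- default_ground_truth(1L)
  train <- sample_dataset(gt, n = 60L, seed = 41L)
  test <- sample_dataset(gt, n = 60L, seed = 42L)
  ens <- train_ensemble(train, n_models = 8L,
                        config = tiny_config(iterations = 150L),
                        base_seed = 60L)
  P <- vapply(ens$members, predict, numeric(nrow(test)), tails = test$tail)
  member_mse <- apply(P, 2L, function(p) mean((p - test$response)^2))
  ensemble_mse <- mean((rowMeans(P) - test$response)^2)
  expect_lte(ensemble_mse, stats::median(member_mse))
})

test_that("bootstrap spread vanishes at the full pool and for identical members", {
  d <- tiny_dataset(n = 25L, seed = 9L)
  pool <- train_ensemble(d, n_models = 6L, config = tiny_config(),
                         base_seed = 70L)
  curve <- convergence_analysis(pool, d, n_bootstrap = 40L, rng_seed = 5L)
  expect_identical(nrow(curve), 6L)
  expect_identical(curve$sd_r[6L], 0)
  expect_true(all(is.finite(curve$mean_r)))
  # identical members: no inter-model variance at any k, convergence at k = 1
  m <- pool$members[[1L]]
  clones <- structure(list(members = list(m, m, m, m), base_seed = 1L,
                           config = tiny_config()), class = "ers_ensemble")
  flat <- convergence_analysis(clones, d, n_bootstrap = 20L, rng_seed = 2L)
  expect_identical(flat$sd_r, rep(0, 4L))
  expect_identical(attr(flat, "k_converged"), 1L)
})

test_that("convergence analysis rejects degenerate evaluation data", {
  d <- tiny_dataset(n = 20L)
  pool <- train_ensemble(d, n_models = 2L, config = tiny_config(),
                         base_seed = 80L)
  flat <- d
  flat$response <- rep(2, nrow(d))
  expect_error(convergence_analysis(pool, flat, rng_seed = 1L),
               "distinct")
  single <- structure(list(members = pool$members[1L], base_seed = 1L,
                           config = tiny_config()), class = "ers_ensemble")
  expect_error(convergence_analysis(single, d, rng_seed = 1L), "at least 2")
})

test_that("cross-validation partitions the data and prefers trained models", {
  d <- tiny_dataset(n = 10L, seed = 15L)
  # every record validated exactly once with 2 folds
  cv <- crossvalidate(d, folds = 2L, grid = list(tiny_config()), seed = 3L)
  expect_identical(sort(unique(cv$fold_id)), 1:2)
  expect_identical(length(cv$fold_id), 10L)
  expect_identical(cv$best_config, tiny_config())
  # an untrained configuration loses to a trained one
  d2 <- tiny_dataset(n = 24L, seed = 16L)
  grid <- list(tiny_config(iterations = 0L), tiny_config(iterations = 150L))
  cv2 <- crossvalidate(d2, folds = 3L, grid = grid, seed = 4L)
  expect_identical(cv2$best_config$iterations, 150L)
  expect_lt(cv2$scores$mean_mse[2L], cv2$scores$mean_mse[1L])
})

test_that("cross-validation rejects impossible settings", {
  d <- tiny_dataset(n = 5L)
  expect_error(crossvalidate(d, folds = 6L, grid = list(tiny_config())),
               "exceed")
  expect_error(crossvalidate(d, folds = 2L, grid = list()), "empty")
})

test_that("evaluation reports value and rank correlations", {
  obs <- c(1.2, 3.4, 2.2, 5.0)
  r <- evaluate(obs, obs)
  expect_equal(r$value_correlation, 1)
  expect_equal(r$rank_correlation, 1)
  # perfect anti-ranking
  r2 <- evaluate(rev(sort(obs)), sort(obs))
  expect_equal(r2$rank_correlation, -1)
  # hand-expanded Pearson for (1,2,3,5) vs (2,4,6,8)
  x <- c(1, 2, 3, 5); y <- c(2, 4, 6, 8)
  by_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r3 <- evaluate(x, y)
  expect_equal(r3$value_correlation, by_hand)
  expect_equal(r3$rank_correlation, 1)
  # tie-corrected ranks agree with the Spearman shortcut
  set.seed(8)
  a <- round(runif(20), 1); b <- round(runif(20), 1)
  expect_equal(evaluate(a, b)$rank_correlation,
               stats::cor(a, b, method = "spearman"))
})

test_that("evaluation enforces its preconditions", {
  expect_error(evaluate(1:3, 1:4), "length mismatch")
  expect_error(evaluate(1:2, 1:2), "at least 3")
  expect_error(evaluate(1:4, rep(2, 4)), "constant")
})

test_that("ensembles round-trip through the directory format", {
  d <- tiny_dataset()
  ens <- train_ensemble(d, n_models = 3L, config = tiny_config(iterations = 10L),
                        base_seed = 90L)
  dir <- file.path(tempdir(), "ens-roundtrip")
  write_ensemble(ens, dir)
  back <- read_ensemble(dir)
  tails <- random_tails(5L, seed = 30L)
  expect_equal(ensemble_predict(back, tails), ensemble_predict(ens, tails),
               tolerance = 1e-12)
  expect_identical(back$base_seed, 90L)
  unlink(dir, recursive = TRUE)
})
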