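#' Train an ensemble of independently seeded LSTM regressors
#'
#' All members see the identical training set and configuration and differ
#' only in their seed: member `i` trains with seed `base_seed + i - 1`, so an
#' ensemble can be extended without retraining existing members. The
#' ensemble prediction ("RNN score") is the arithmetic mean of the member
#' predictions; 32 members is the default operating point for scoring, and a
#' 64-member pool is used for convergence studies.
#'
#' @param data Training `data.frame` (`tail`, `response`).
#' @param n_models Number of members (>= 1).
#' @param config Shared [model_config()]; its `seed` field is superseded by
#'   the per-member seeds.
#' @param base_seed Integer seed of the first member.
#' @return Object of class `ers_ensemble`: list with `members`, `base_seed`,
#'   `config`.
#' @export
train_ensemble <- function(data, n_models = 32L, config = model_config(),
                           base_seed = 1L) {
  n_models <- as.integer(n_models)
  base_seed <- as.integer(base_seed)
  stopifnot(n_models >= 1L, !is.na(base_seed))
  members <- lapply(seq_len(n_models) - 1L, function(i) {
    cfg <- config
    cfg$seed <- base_seed + i
    train_model(data, cfg)
  })
  structure(list(members = members, base_seed = base_seed, config = config),
            class = "ers_ensemble")
}

#' @export
print.ers_ensemble <- function(x, ...) {
  cat(sprintf("LSTM ensemble: %d members, base seed %d, hidden %d\n",
              length(x$members), x$base_seed, x$config$hidden_size))
  invisible(x)
}

# n_tails x n_members matrix of member predictions
member_prediction_matrix <- function(ensemble, tails) {
  vapply(ensemble$members, predict, numeric(length(tails)), tails = tails)
}

#' Ensemble prediction with member spread
#'
#' @param ensemble A non-empty `ers_ensemble`.
#' @param tails Character vector of valid tails.
#' @return `data.frame` with columns `tail`, `score` (mean over members, the
#'   RNN score) and `sd` (standard deviation across members; 0 for a
#'   single-member ensemble).
#' @export
ensemble_predict <- function(ensemble, tails) {
  stopifnot(inherits(ensemble, "ers_ensemble"))
  if (length(ensemble$members) == 0L) stop("ensemble has no members", call. = FALSE)
  tails <- validate_tail(tails)
  P <- matrix(member_prediction_matrix(ensemble, tails),
              nrow = length(tails))
  sds <- if (ncol(P) == 1L) rep(0, nrow(P)) else apply(P, 1L, stats::sd)
  data.frame(tail = tails, score = rowMeans(P), sd = sds,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Bootstrap convergence analysis of ensemble size
#'
#' How many models does the ensemble mean need before its agreement with
#' observed responses stabilises? For every ensemble size `k` from 1 to the
#' pool size, `n_bootstrap` random `k`-subsets of the pool are drawn
#' (without replacement within a draw, with replacement available via
#' `replace = TRUE`), the Pearson correlation between each subset's mean
#' prediction and the observed responses is computed, and the mean and
#' standard deviation of those correlations are recorded. Convergence is
#' declared at the smallest `k` whose local slope of the SD-versus-k curve
#' (forward first difference) falls below `slope_threshold` in absolute
#' value; the default threshold 0.0003 is the criterion under which the
#' 64-model pool converged beyond 15 models and a 32-member operating point
#' was adopted.
#'
#' @param pool An `ers_ensemble` with at least 2 members.
#' @param eval_data `data.frame` (`tail`, `response`) with at least 3
#'   distinct response values.
#' @param n_bootstrap Draws per ensemble size (default 100).
#' @param rng_seed Seed for the subset draws.
#' @param slope_threshold Convergence threshold on |SD slope| (default 3e-4).
#' @param smooth_window Width of the moving-average window applied to the SD
#'   curve before the slope is taken: 1 (no smoothing, the default) or an
#'   odd width such as 3 to damp Monte-Carlo noise in the first difference.
#' @param replace Sample members with replacement within a draw.
#' @return Object of class `ers_convergence`: `data.frame` with columns `k`,
#'   `mean_r`, `sd_r`, `slope` (forward difference of `sd_r`, `NA` at the
#'   last `k`), plus attributes `k_converged`, `slope_threshold`,
#'   `n_bootstrap`.
#' @export
convergence_analysis <- function(pool, eval_data, n_bootstrap = 100L,
                                 rng_seed = 1L, slope_threshold = 3e-4,
                                 smooth_window = 1L, replace = FALSE) {
  stopifnot(inherits(pool, "ers_ensemble"))
  K <- length(pool$members)
  if (K < 2L) stop("convergence analysis needs a pool of at least 2 models",
                   call. = FALSE)
  tails <- validate_tail(eval_data$tail)
  obs <- as.numeric(eval_data$response)
  if (length(unique(obs)) < 3L) {
    stop("evaluation responses must have at least 3 distinct values",
         call. = FALSE)
  }
  P <- member_prediction_matrix(pool, tails)
  set.seed(as.integer(rng_seed))
  mean_r <- sd_r <- numeric(K)
  for (k in seq_len(K)) {
    rs <- vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(K, k, replace = replace)
      pm <- rowMeans(P[, idx, drop = FALSE])
      # a degenerate subset (constant predictions) has no defined Pearson R
      if (stats::sd(pm) == 0) NA_real_ else stats::cor(pm, obs)
    }, numeric(1L))
    mean_r[k] <- mean(rs)
    sd_r[k] <- stats::sd(rs)
  }
  smoothed <- sd_r
  if (smooth_window > 1L && K >= smooth_window) {
    half <- (as.integer(smooth_window) - 1L) %/% 2L
    smoothed <- vapply(seq_len(K), function(k) {
      mean(sd_r[max(1L, k - half):min(K, k + half)])
    }, numeric(1L))
  }
  slope <- c(diff(smoothed), NA_real_)
  converged <- which(abs(slope) < slope_threshold)
  out <- data.frame(k = seq_len(K), mean_r = mean_r, sd_r = sd_r,
                    slope = slope)
  attr(out, "k_converged") <- if (length(converged)) min(converged) else NA_integer_
  attr(out, "slope_threshold") <- slope_threshold
  attr(out, "n_bootstrap") <- as.integer(n_bootstrap)
  class(out) <- c("ers_convergence", "data.frame")
  out
}

#' Write a convergence curve as TSV
#'
#' @param curve An `ers_convergence` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_convergence_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' K-fold cross-validation over a configuration grid
#'
#' Deterministic seeded fold assignment (a balanced random partition: every
#' record is validated exactly once). Each configuration is scored by its
#' mean validation MSE across folds; the best configuration is the one with
#' the lowest mean, ties resolved in grid order.
#'
#' @param data Training `data.frame` (`tail`, `response`).
#' @param folds Number of folds (default 10; must not exceed the sample
#'   count).
#' @param grid Non-empty list of [model_config()] objects.
#' @param seed Seed for the fold assignment.
#' @return List with `best_config`, `scores` (`data.frame`: `config`,
#'   `hidden_size`, `fc_width`, `dropout_rate`, `iterations`, `mean_mse`) and
#'   `fold_id`.
#' @export
crossvalidate <- function(data, folds = 10L, grid = default_cv_grid(),
                          seed = 1L) {
  stopifnot(is.data.frame(data))
  folds <- as.integer(folds)
  n <- nrow(data)
  if (length(grid) == 0L) stop("configuration grid is empty", call. = FALSE)
  if (folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (folds > n) {
    stop(sprintf("folds (%d) exceed the sample count (%d)", folds, n),
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), n))
  mean_mse <- vapply(grid, function(cfg) {
    mse <- vapply(seq_len(folds), function(f) {
      train <- data[fold_id != f, , drop = FALSE]
      val <- data[fold_id == f, , drop = FALSE]
      fit <- train_model(train, cfg)
      mean((predict(fit, val$tail) - val$response)^2)
    }, numeric(1L))
    mean(mse)
  }, numeric(1L))
  scores <- data.frame(
    config = seq_along(grid),
    hidden_size = vapply(grid, `[[`, integer(1L), "hidden_size"),
    fc_width = vapply(grid, `[[`, integer(1L), "fc_width"),
    dropout_rate = vapply(grid, `[[`, numeric(1L), "dropout_rate"),
    iterations = vapply(grid, `[[`, integer(1L), "iterations"),
    mean_mse = mean_mse)
  list(best_config = grid[[which.min(mean_mse)]], scores = scores,
       fold_id = fold_id)
}

#' Default cross-validation grid
#'
#' A small scaffold grid around the default configuration; the searched
#' space is a package choice, not a fixed property of the method.
#'
#' @param iterations Training iterations used for every grid point.
#' @param seed Seed shared by every grid point.
#' @return List of [model_config()] objects.
#' @export
default_cv_grid <- function(iterations = 3000L, seed = 1L) {
  grid <- expand.grid(hidden = c(32L, 64L), fc = c(8L, 16L),
                      dropout = c(0, 0.2))
  lapply(seq_len(nrow(grid)), function(i) {
    model_config(hidden_size = grid$hidden[i], fc_width = grid$fc[i],
                 dropout_rate = grid$dropout[i], iterations = iterations,
                 seed = seed)
  })
}

#' Evaluate predictions against observed responses
#'
#' Reports the Pearson correlation on the raw values and the Pearson
#' correlation on the rank vectors (average ranks for ties, i.e. Spearman's
#' rho), mirroring how predicted RNN scores are compared with measured Tg
#' responses by value and by ranking.
#'
#' @param predicted,observed Numeric vectors of equal length >= 3;
#'   `observed` must not be constant.
#' @return Object of class `ers_evaluation`: list with `value_correlation`,
#'   `rank_correlation`, `n`.
#' @export
evaluate <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop(sprintf("length mismatch: %d predicted vs %d observed",
                 length(predicted), length(observed)), call. = FALSE)
  }
  if (length(observed) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(observed) == 0) {
    stop("observed responses are constant; correlation undefined", call. = FALSE)
  }
  structure(list(
    value_correlation = stats::cor(predicted, observed),
    rank_correlation = stats::cor(rank(predicted), rank(observed)),
    n = length(observed)), class = "ers_evaluation")
}

#' @export
print.ers_evaluation <- function(x, ...) {
  cat(sprintf("Evaluation on %d tails: value r = %.3f, rank r = %.3f\n",
              x$n, x$value_correlation, x$rank_correlation))
  invisible(x)
}

#' Save / load an ensemble as a directory of member files plus a manifest
#'
#' Each member is written with [write_model()] as `member_###.json`; the
#' manifest records the member count, base seed, shared configuration and
#' alphabet ordering.
#'
#' @param ensemble An `ers_ensemble`.
#' @param dir Directory path (created if missing).
#' @return `dir` (or the ensemble, for the reader), invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "ers_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ensemble$members)) {
    write_model(ensemble$members[[i]],
                file.path(dir, sprintf("member_%03d.json", i)))
  }
  jsonlite::write_json(
    list(format = "ersnet-ensemble-1", n_models = length(ensemble$members),
         base_seed = ensemble$base_seed, config = unclass(ensemble$config),
         alphabet = ers_alphabet()),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(as.character(manifest$alphabet), ers_alphabet())) {
    stop("ensemble manifest uses a different alphabet ordering", call. = FALSE)
  }
  members <- lapply(seq_len(manifest$n_models), function(i) {
    read_model(file.path(dir, sprintf("member_%03d.json", i)))
  })
  cfg <- manifest$config
  structure(list(members = members,
                 base_seed = as.integer(manifest$base_seed),
                 config = model_config(cfg$hidden_size, cfg$fc_width,
                                       cfg$dropout_rate, cfg$learning_rate,
                                       cfg$iterations, cfg$seed)),
            class = "ers_ensemble")
}
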