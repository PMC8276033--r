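#' Model hyperparameter configuration
#'
#' The defaults are the configuration the prediction pipeline was built
#' around, selected by 10-fold cross-validation on the original 95-tail
#' training batch: one LSTM layer with a 64-unit hidden state, dropout rate
#' 0.2 on the LSTM output, Adam at learning rate 0.001, and 3,000 full-batch
#' iterations on the mean-squared-error cost. The width of the fully
#' connected layer between the final LSTM state and the single ReLU output
#' node (16) is a package choice, exposed here.
#'
#' @param hidden_size LSTM hidden-state size (default 64).
#' @param fc_width Width of the dense layer feeding the output node
#'   (default 16).
#' @param dropout_rate Dropout rate in `[0, 1)` applied to the LSTM output
#'   during training only (default 0.2).
#' @param learning_rate Adam learning rate (default 0.001). Remaining Adam
#'   settings are the usual defaults (beta1 0.9, beta2 0.999, eps 1e-8).
#' @param iterations Number of full-batch gradient steps (default 3000).
#' @param seed Integer seed driving weight initialisation and dropout masks.
#' @return Object of class `ers_model_config`.
#' @export
model_config <- function(hidden_size = 64L, fc_width = 16L, dropout_rate = 0.2,
                         learning_rate = 0.001, iterations = 3000L, seed = 1L) {
  hidden_size <- as.integer(hidden_size)
  fc_width <- as.integer(fc_width)
  iterations <- as.integer(iterations)
  seed <- as.integer(seed)
  stopifnot(hidden_size >= 1L, fc_width >= 1L, iterations >= 0L,
            dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            !is.na(seed))
  structure(list(hidden_size = hidden_size, fc_width = fc_width,
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 iterations = iterations, seed = seed),
            class = "ers_model_config")
}

#' @export
print.ers_model_config <- function(x, ...) {
  cat(sprintf(paste0("LSTM regressor config: hidden %d, fc %d, dropout %.2f, ",
                     "lr %g, %d iterations, seed %d\n"),
              x$hidden_size, x$fc_width, x$dropout_rate, x$learning_rate,
              x$iterations, x$seed))
  invisible(x)
}

#' Train a single LSTM secretion-response regressor
#'
#' One-hot encodes the tails (7 x 20 per tail), feeds positions -7 through
#' -1 in natural reading order through a single LSTM layer, and regresses
#' the final hidden state -- via a dense ReLU layer and a single ReLU output
#' node -- onto the observed Tg-induced secretion response. Training runs
#' `config$iterations` full-batch Adam steps on the mean-squared-error cost
#' with inverted dropout on the LSTM output; prediction uses all parameters.
#' Every source of randomness (initial weights, dropout masks) derives from
#' `config$seed`, so the trained parameters are bit-reproducible.
#'
#' @param data `data.frame` with columns `tail` (valid 7-mers) and `response`
#'   (finite, non-negative).
#' @param config An [model_config()] object.
#' @return Object of class `ers_model`: list with `params` (named weight
#'   matrices), `config`, `loss_trace` (training MSE at each iteration; empty
#'   when `iterations = 0`), and `alphabet`.
#' @export
train_model <- function(data, config = model_config()) {
  stopifnot(inherits(config, "ers_model_config"), is.data.frame(data))
  if (nrow(data) == 0L) stop("training data is empty", call. = FALSE)
  tails <- validate_tail(data$tail)
  check_responses(data$response)
  X <- encode_design(tails)
  fit <- cpp_lstm_fit(X, as.numeric(data$response),
                      config$hidden_size, config$fc_width,
                      config$dropout_rate, config$learning_rate,
                      config$iterations, config$seed, 20L)
  structure(list(params = fit$params, config = config,
                 loss_trace = as.numeric(fit$loss_trace),
                 alphabet = ers_alphabet()),
            class = "ers_model")
}

#' @export
print.ers_model <- function(x, ...) {
  final <- if (length(x$loss_trace)) sprintf("final training MSE %.4g",
                                             x$loss_trace[length(x$loss_trace)])
           else "untrained (0 iterations)"
  cat(sprintf("LSTM secretion-response regressor (hidden %d, seed %d): %s\n",
              x$config$hidden_size, x$config$seed, final))
  invisible(x)
}

#' Predict secretion responses for tails
#'
#' Deterministic forward pass with dropout disabled; the ReLU output node
#' guarantees every score is non-negative, matching the fold-change scale of
#' the training responses.
#'
#' @param object A trained `ers_model`.
#' @param tails Character vector of valid tails.
#' @param ... Unused.
#' @return Numeric vector of non-negative scores, one per tail, in input
#'   order.
#' @export
predict.ers_model <- function(object, tails, ...) {
  tails <- validate_tail(tails)
  as.numeric(cpp_lstm_predict(object$params, encode_design(tails), 20L))
}

#' Serialize a model to a single JSON file
#'
#' The file carries all learned parameters, the full configuration and the
#' alphabet ordering the one-hot columns assume. [read_model()] refuses a
#' file whose alphabet does not match the package's, since predictions would
#' silently permute residues otherwise.
#'
#' @param model An `ers_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ers_model"))
  payload <- list(
    format = "ersnet-model-1",
    alphabet = model$alphabet,
    config = unclass(model$config),
    loss_trace = model$loss_trace,
    params = model$params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(payload$alphabet), ers_alphabet())) {
    stop(sprintf("model file '%s' uses alphabet ordering '%s', not '%s'",
                 path, paste(payload$alphabet, collapse = ""),
                 paste(ers_alphabet(), collapse = "")), call. = FALSE)
  }
  cfg <- payload$config
  config <- model_config(cfg$hidden_size, cfg$fc_width, cfg$dropout_rate,
                         cfg$learning_rate, cfg$iterations, cfg$seed)
  params <- payload$params
  params$bL <- as.numeric(params$bL)
  params$b1 <- as.numeric(params$b1)
  params$b2 <- as.numeric(params$b2)
  params$W2 <- matrix(params$W2, ncol = 1L)
  structure(list(params = params, config = config,
                 loss_trace = as.numeric(payload$loss_trace),
                 alphabet = ers_alphabet()),
            class = "ers_model")
}
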