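# shared fixtures and independent oracles for the test suite

# uniformly random valid tails
random_tails <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste(sample(ers_alphabet(), tail_length(), replace = TRUE),
                     collapse = ""))
}

# small, fast model configuration for tests that only need the mechanics
tiny_config <- function(seed = 1L, iterations = 40L) {
  model_config(hidden_size = 8L, fc_width = 4L, dropout_rate = 0.2,
               learning_rate = 0.01, iterations = iterations, seed = seed)
}

# a small noisy training set from the default generator
tiny_dataset <- function(n = 30L, seed = 1L, noise_fraction = 0.2) {
  gt <- default_ground_truth(1L, noise_fraction = noise_fraction)
  sample_dataset(gt, n = n, seed = seed)
}

# Independent oracle: per-position substitution lookup and summation written
# as an explicit loop, separate from the vectorised implementation.
oracle_similarity <- function(a, b, matrix) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  total <- 0L
  for (p in seq_len(7L)) total <- total + matrix[ca[p], cb[p]]
  total
}

# Independent oracle: Cartesian product by nested loops (recursion), most
# significant position first, each position's set pre-sorted.
oracle_enumerate <- function(sets) {
  sets <- lapply(sets, sort)
  out <- ""
  for (p in seq_along(sets)) {
    out <- as.vector(vapply(out, function(prefix) paste0(prefix, sets[[p]]),
                            character(length(sets[[p]]))))
  }
  out
}

# Independent oracle: plain-R replica of the LSTM forward pass (dropout off),
# used to cross-check the compiled prediction path.
oracle_forward <- function(params, tails) {
  A <- ers_alphabet()
  WL <- params$WL
  bL <- as.numeric(params$bL)
  W1 <- params$W1
  b1 <- as.numeric(params$b1)
  W2 <- matrix(params$W2, ncol = 1L)
  b2 <- as.numeric(params$b2)
  D <- 20L
  H <- nrow(W1)
  Wh <- WL[(D + 1L):(D + H), , drop = FALSE]
  sig <- function(x) 1 / (1 + exp(-x))
  vapply(tails, function(tail) {
    ch <- strsplit(tail, "")[[1L]]
    h <- numeric(H); cc <- numeric(H)
    for (t in 1:7) {
      g <- WL[match(ch[t], A), ] + as.numeric(h %*% Wh) + bL
      gi <- sig(g[1:H]); gf <- sig(g[(H + 1):(2 * H)])
      gc <- tanh(g[(2 * H + 1):(3 * H)]); go <- sig(g[(3 * H + 1):(4 * H)])
      cc <- gf * cc + gi * gc
      h <- go * tanh(cc)
    }
    a1 <- pmax(0, as.numeric(h %*% W1) + b1)
    max(0, sum(a1 * W2) + b2)
  }, numeric(1L), USE.NAMES = FALSE)
}

# write a FASTA file from named sequences, wrapping one entry to exercise
# multi-line parsing
write_fasta_fixture <- function(seqs, path, wrap_first = FALSE) {
  lines <- character(0L)
  for (i in seq_along(seqs)) {
    lines <- c(lines, paste0(">", names(seqs)[i]))
    s <- seqs[[i]]
    if (wrap_first && i == 1L && nchar(s) > 10L) {
      lines <- c(lines, substr(s, 1L, 10L), substr(s, 11L, nchar(s)))
    } else {
      lines <- c(lines, s)
    }
  }
  writeLines(lines, path)
  path
}

example_fasta <- function() {
  system.file("extdata", "example_proteins.fasta", package = "ersnet",
              mustWork = TRUE)
}
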