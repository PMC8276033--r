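#' Per-position high-frequency residue sets
#'
#' For each of the seven positions, the set of residues whose relative
#' frequency in the supplied batch is at least `threshold`. These sets drive
#' permutation candidate generation: the number of enumerable candidates is
#' the product of the set sizes. There is no default threshold -- the choice
#' materially changes the candidate space, so it must be stated.
#'
#' @param records `data.frame` with a `tail` column, or a character vector of
#'   tails.
#' @param threshold Relative frequency cutoff in `(0, 1]`.
#' @return Object of class `ers_residue_sets`: list with `sets` (list of 7
#'   alphabetically sorted character vectors, positions -7..-1),
#'   `threshold`, and `n_candidates` (product of set sizes).
#' @export
high_frequency_sets <- function(records, threshold) {
  tails <- validate_tail(if (is.data.frame(records)) records$tail else records)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  chars <- matrix(unlist(strsplit(tails, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(tails), byrow = TRUE)
  sets <- lapply(seq_len(tail_length()), function(p) {
    freq <- table(factor(chars[, p], levels = ers_alphabet())) / length(tails)
    keep <- names(freq)[freq >= threshold]
    if (length(keep) == 0L) {
      stop(sprintf(
        "no residue reaches frequency %g at position %s; lower the threshold",
        threshold, position_labels()[p]), call. = FALSE)
    }
    sort(keep)
  })
  new_residue_sets(sets, threshold)
}

new_residue_sets <- function(sets, threshold = NA_real_) {
  stopifnot(length(sets) == tail_length())
  sets <- lapply(sets, function(s) {
    s <- sort(unique(as.character(s)))
    if (length(s) == 0L || !all(s %in% ers_alphabet())) {
      stop("each position's residue set must be a non-empty subset of the alphabet",
           call. = FALSE)
    }
    s
  })
  names(sets) <- position_labels()
  structure(list(sets = sets, threshold = threshold,
                 n_candidates = prod(lengths(sets))),
            class = "ers_residue_sets")
}

#' @export
print.ers_residue_sets <- function(x, ...) {
  cat(sprintf("Per-position residue sets (threshold %s): %s candidates\n",
              format(x$threshold), format(x$n_candidates, big.mark = ",")))
  for (p in names(x$sets)) {
    cat(sprintf("  %2s: %s\n", p, paste(x$sets[[p]], collapse = "")))
  }
  invisible(x)
}

#' Read/write residue sets as JSON (list of 7 strings, positions -7..-1)
#'
#' @param sets An `ers_residue_sets` object.
#' @param path File path.
#' @return The sets (reader) or `path` (writer), invisibly.
#' @export
write_residue_sets <- function(sets, path) {
  jsonlite::write_json(vapply(sets$sets, paste, character(1L), collapse = ""),
                       path)
  invisible(path)
}

#' @rdname write_residue_sets
#' @export
read_residue_sets <- function(path) {
  strings <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(strings) != tail_length()) {
    stop(sprintf("'%s' must list exactly %d residue strings", path,
                 tail_length()), call. = FALSE)
  }
  new_residue_sets(strsplit(toupper(strings), "", fixed = TRUE))
}

#' Enumerate permutation candidates from residue sets
#'
#' Yields the full Cartesian product of the per-position sets, each tail
#' exactly once, in deterministic lexicographic order with position -7 most
#' significant (each position's set is kept alphabetically sorted). The
#' enumeration is indexed, so any contiguous slice can be produced without
#' materialising the whole product: `from`/`n` select candidates
#' `from .. from + n - 1` of the `sets$n_candidates` total, which is how
#' proteome-scale spaces are streamed in chunks.
#'
#' @param sets An `ers_residue_sets` object.
#' @param from 1-based index of the first candidate to emit.
#' @param n Number of candidates to emit (default: all remaining).
#' @return Character vector of tails.
#' @export
enumerate_candidates <- function(sets, from = 1L, n = Inf) {
  stopifnot(inherits(sets, "ers_residue_sets"), from >= 1L)
  total <- sets$n_candidates
  if (from > total) return(character(0L))
  upto <- min(total, from + n - 1L)
  idx0 <- seq(from - 1L, upto - 1L)  # 0-based candidate indices
  sizes <- lengths(sets$sets)
  # mixed-radix decomposition, most significant digit = position -7
  suffix <- rev(cumprod(rev(c(sizes[-1L], 1L))))
  cols <- lapply(seq_len(tail_length()), function(p) {
    digit <- (idx0 %/% suffix[p]) %% sizes[p]
    sets$sets[[p]][digit + 1L]
  })
  do.call(paste0, cols)
}

#' Score and rank candidate tails by ensemble prediction
#'
#' Candidates are scored by the ensemble mean ("RNN score") and sorted in
#' descending order, ties broken lexicographically, so ranking is stable
#' across runs. Scoring proceeds in chunks to keep memory flat on large
#' candidate streams.
#'
#' @param candidates Character vector of valid tails (no duplicates
#'   required, but duplicates rank adjacently with identical scores).
#' @param ensemble A trained `ers_ensemble`.
#' @param top_n Keep only the `top_n` highest-scoring rows (default: all).
#' @param chunk_size Number of candidates scored per prediction call.
#' @return `data.frame` with columns `tail`, `score`, sorted.
#' @export
rank_candidates <- function(candidates, ensemble, top_n = Inf,
                            chunk_size = 10000L) {
  candidates <- validate_tail(candidates)
  scores <- numeric(length(candidates))
  starts <- seq(1L, length(candidates), by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, length(candidates))
    scores[idx] <- ensemble_predict(ensemble, candidates[idx])$score
  }
  ord <- order(-scores, candidates)
  out <- data.frame(tail = candidates[ord], score = scores[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  out
}

#' Assemble a validation batch of strong and weak candidates
#'
#' Mirrors how a second experimental batch is put together from a ranked
#' candidate table: previously assayed tails are excluded, each remaining
#' candidate is labelled `artificial` (absent from the supplied proteome
#' tail catalog) or `human-proteome` (present), and two strata are filled --
#' `n_strong` tails with score >= `strong_cutoff`, taken from the top of the
#' ranking down, and `n_weak` tails with score <= `weak_cutoff`, taken from
#' the bottom up. Within each stratum the artificial/human split follows
#' `artificial_fraction` as closely as integer rounding allows; if a stratum
#' cannot supply its quota the error names the stratum and source. Judgments
#' with no computational counterpart (e.g. synthesis feasibility) enter only
#' through `exclude`, an optional user-supplied tail list.
#'
#' @param ranked `data.frame` from [rank_candidates()] (`tail`, `score`,
#'   descending).
#' @param proteome_tails An `ers_tail_catalog` used to label sources.
#' @param first_batch Character vector of previously assayed tails to
#'   exclude.
#' @param n_strong,n_weak Stratum sizes.
#' @param strong_cutoff,weak_cutoff Score cutoffs; `strong_cutoff` must
#'   exceed `weak_cutoff`.
#' @param artificial_fraction Fraction of each stratum drawn from artificial
#'   tails (default 0.5).
#' @param exclude Optional additional tails to exclude.
#' @return Object of class `ers_candidate_batch`: `data.frame` with columns
#'   `tail`, `score`, `source` (`artificial`/`human-proteome`), `class`
#'   (`strong`/`weak`); selection parameters kept as attributes.
#' @export
assemble_validation_batch <- function(ranked, proteome_tails, first_batch,
                                      n_strong, n_weak, strong_cutoff,
                                      weak_cutoff, artificial_fraction = 0.5,
                                      exclude = character(0L)) {
  stopifnot(is.data.frame(ranked), all(c("tail", "score") %in% names(ranked)),
            inherits(proteome_tails, "ers_tail_catalog"))
  if (!(strong_cutoff > weak_cutoff)) {
    stop("strong_cutoff must be greater than weak_cutoff", call. = FALSE)
  }
  if (artificial_fraction < 0 || artificial_fraction > 1) {
    stop("artificial_fraction must lie in [0, 1]", call. = FALSE)
  }
  drop <- toupper(c(first_batch, exclude))
  pool <- ranked[!toupper(ranked$tail) %in% drop & !duplicated(ranked$tail), ,
                 drop = FALSE]
  pool$source <- ifelse(pool$tail %in% names(proteome_tails$entries),
                        "human-proteome", "artificial")

  pick_stratum <- function(rows, n_total, label) {
    n_art <- as.integer(floor(artificial_fraction * n_total + 0.5))
    n_hum <- n_total - n_art
    art <- rows[rows$source == "artificial", , drop = FALSE]
    hum <- rows[rows$source == "human-proteome", , drop = FALSE]
    if (nrow(art) < n_art) {
      stop(sprintf(
        "cannot fill the %s stratum: need %d artificial tails, only %d available",
        label, n_art, nrow(art)), call. = FALSE)
    }
    if (nrow(hum) < n_hum) {
      stop(sprintf(
        "cannot fill the %s stratum: need %d human-proteome tails, only %d available",
        label, n_hum, nrow(hum)), call. = FALSE)
    }
    out <- rbind(utils::head(art, n_art), utils::head(hum, n_hum))
    out <- out[order(-out$score, out$tail), , drop = FALSE]
    out$class <- label
    out
  }

  strong_pool <- pool[pool$score >= strong_cutoff, , drop = FALSE]
  weak_pool <- pool[pool$score <= weak_cutoff, , drop = FALSE]
  # weak tails are taken from the bottom of the ranking up
  weak_pool <- weak_pool[order(weak_pool$score, weak_pool$tail), , drop = FALSE]
  batch <- rbind(pick_stratum(strong_pool, n_strong, "strong"),
                 pick_stratum(weak_pool, n_weak, "weak"))
  rownames(batch) <- NULL
  attr(batch, "selection") <- list(
    n_strong = n_strong, n_weak = n_weak, strong_cutoff = strong_cutoff,
    weak_cutoff = weak_cutoff, artificial_fraction = artificial_fraction)
  class(batch) <- c("ers_candidate_batch", "data.frame")
  batch
}

#' Write a candidate batch (or ranked table) as TSV
#'
#' @param batch `data.frame` with at least `tail` and `score` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(batch, path) {
  utils::write.table(as.data.frame(batch), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
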