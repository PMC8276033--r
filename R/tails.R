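#' @useDynLib ersnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' The 20-letter natural amino-acid alphabet
#'
#' Column ordering of every one-hot matrix, position probability matrix and
#' serialized model in this package: alphabetical one-letter codes
#' `ACDEFGHIKLMNPQRSTVWY`. The ordering is part of the model serialization
#' contract, so it is fixed here once.
#'
#' @return Character vector of the 20 one-letter residue codes.
#' @export
ers_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Length of a C-terminal tail
#'
#' The assay this package models fixes tails at seven residues, labelled by
#' position -7 (N-terminal end of the tail) through -1 (the C-terminal
#' residue, the last character of the string).
#' @return The integer 7.
#' @export
tail_length <- function() 7L

# position labels "-7".."-1" for a tail of length L
position_labels <- function(L = tail_length()) {
  as.character(seq(-L, -1L))
}

#' Validate seven-residue C-terminal tails
#'
#' Uppercases its input, then checks that every element is exactly seven
#' characters long and drawn from the 20 natural amino acids
#' ([ers_alphabet()]). Anything else -- wrong length, `B/J/O/U/X/Z`, stop
#' symbols, gaps -- is an error naming the offending tail and character:
#' unnatural residues are rejected, never recoded.
#'
#' @param raw Character vector of candidate tails.
#' @return The validated tails, uppercased, invisibly classifiable as plain
#'   character strings.
#' @examples
#' validate_tail("TAEKDEL")
#' validate_tail(c("kdelkde", "LIGSLEL"))
#' @export
validate_tail <- function(raw) {
  if (!is.character(raw) || length(raw) == 0L) {
    stop("tails must be a non-empty character vector", call. = FALSE)
  }
  if (anyNA(raw)) stop("tails contain NA", call. = FALSE)
  tails <- toupper(raw)
  len <- nchar(tails)
  if (any(len != tail_length())) {
    bad <- which(len != tail_length())[1L]
    stop(sprintf("tail '%s' has length %d; expected exactly %d residues",
                 raw[bad], len[bad], tail_length()), call. = FALSE)
  }
  chars <- strsplit(tails, "", fixed = TRUE)
  ok <- vapply(chars, function(x) all(x %in% ers_alphabet()), logical(1L))
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    offending <- setdiff(chars[[bad]], ers_alphabet())[1L]
    stop(sprintf(
      "tail '%s' contains unnatural residue '%s'; allowed residues are %s",
      raw[bad], offending, paste(ers_alphabet(), collapse = "")),
      call. = FALSE)
  }
  tails
}

#' Test tails for validity without erroring
#'
#' Vectorised predicate used by the extraction and filtering steps, where
#' invalid tails are counted rather than raised.
#'
#' @param raw Character vector.
#' @return Logical vector, `TRUE` where the element is a valid 7-mer over the
#'   natural alphabet (after uppercasing).
#' @export
is_valid_tail <- function(raw) {
  if (length(raw) == 0L) return(logical(0L))
  up <- toupper(raw)
  ok <- !is.na(up) & nchar(up) == tail_length()
  ok[ok] <- !grepl(sprintf("[^%s]", paste(ers_alphabet(), collapse = "")), up[ok])
  ok
}

#' One-hot encode a tail as a 7 x 20 binary matrix
#'
#' Row `i` encodes the residue at string index `i` (position label `-8 + i`);
#' the single 1 in each row sits in the column of that residue, columns
#' ordered as [ers_alphabet()]. Row and column names carry the position
#' labels and residue codes.
#'
#' @param tail A single valid tail (validated on entry).
#' @return Integer matrix, 7 rows x 20 columns, each row summing to 1.
#' @examples
#' m <- encode_one_hot("TAEKDEL")
#' rowSums(m)  # all 1
#' @export
encode_one_hot <- function(tail) {
  tail <- validate_tail(tail)
  if (length(tail) != 1L) stop("encode_one_hot() takes a single tail", call. = FALSE)
  chars <- strsplit(tail, "", fixed = TRUE)[[1L]]
  m <- matrix(0L, nrow = tail_length(), ncol = 20L,
              dimnames = list(position_labels(), ers_alphabet()))
  m[cbind(seq_len(tail_length()), match(chars, ers_alphabet()))] <- 1L
  m
}

#' Decode a one-hot matrix back to its tail
#'
#' Inverse of [encode_one_hot()]: checks the 7 x 20 shape and that every row
#' contains exactly one 1 (all other entries 0), then reads the residues off
#' the columns.
#'
#' @param matrix Numeric or integer 7 x 20 matrix.
#' @return The decoded tail string.
#' @export
decode_one_hot <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != tail_length() || ncol(matrix) != 20L) {
    stop(sprintf("expected a %d x 20 matrix", tail_length()), call. = FALSE)
  }
  if (!all(matrix %in% c(0, 1))) {
    stop("one-hot matrix entries must all be 0 or 1", call. = FALSE)
  }
  rs <- rowSums(matrix)
  if (any(rs != 1)) {
    stop(sprintf("row %d of the one-hot matrix sums to %g, not 1",
                 which(rs != 1)[1L], rs[which(rs != 1)[1L]]), call. = FALSE)
  }
  paste(ers_alphabet()[apply(matrix, 1L, which.max)], collapse = "")
}

# flatten n tails into an n x (7*20) design matrix; position blocks -7..-1
encode_design <- function(tails) {
  tails <- validate_tail(tails)
  n <- length(tails)
  chars <- matrix(unlist(strsplit(tails, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  X <- matrix(0, nrow = n, ncol = tail_length() * 20L)
  for (p in seq_len(tail_length())) {
    col <- (p - 1L) * 20L + match(chars[, p], ers_alphabet())
    X[cbind(seq_len(n), col)] <- 1
  }
  X
}

#' Read tails from a plain-text or TSV file
#'
#' Accepts either one 7-mer per line or a tab-separated table with a `tail`
#' column; every tail is validated.
#'
#' @param path File path.
#' @return Character vector of validated tails.
#' @export
read_tails <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first) || identical(first, "tail")) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"tail" %in% names(df)) {
      stop(sprintf("'%s' has no 'tail' column", path), call. = FALSE)
    }
    tails <- df[["tail"]]
  } else {
    tails <- readLines(path)
    tails <- tails[nzchar(tails)]
  }
  validate_tail(tails)
}

#' Read a tail/response training table
#'
#' Tab-separated file with header columns `tail` and `response`; tails are
#' validated and responses must be finite and non-negative (the assay scale
#' is a fold change relative to vehicle, so negative values are a format
#' error, not data).
#'
#' @param path File path.
#' @return `data.frame` with character `tail` and numeric `response`.
#' @export
read_training_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("tail", "response")) {
    if (!col %in% names(df)) {
      stop(sprintf("'%s' has no '%s' column", path, col), call. = FALSE)
    }
  }
  out <- data.frame(tail = validate_tail(as.character(df$tail)),
                    response = as.numeric(df$response),
                    stringsAsFactors = FALSE)
  check_responses(out$response)
  out
}

check_responses <- function(response) {
  if (length(response) == 0L) stop("no records supplied", call. = FALSE)
  if (any(!is.finite(response))) {
    stop("responses must all be finite", call. = FALSE)
  }
  if (any(response < 0)) {
    stop("responses must be non-negative (fold change relative to vehicle)",
         call. = FALSE)
  }
  invisible(response)
}

#' Write a tail/response table as TSV
#'
#' @param data `data.frame` with `tail` and `response` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_training_table <- function(data, path) {
  utils::write.table(data[, c("tail", "response")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
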