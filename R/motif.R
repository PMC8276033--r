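# cache for the bundled PAM250 table
.ersnet_env <- new.env(parent = emptyenv())

#' Read a substitution matrix in square text format
#'
#' Parses the standard square-matrix layout distributed with alignment
#' toolkits: `#` comment lines, a header row of residue codes, then one
#' labelled row of integer scores per residue. The matrix must be complete
#' over the 20 natural amino acids and symmetric on them.
#'
#' @param path Path to the matrix file.
#' @param name Identifier attached to the matrix (attribute `name`).
#' @return Integer matrix with residue dimnames (at least the 20 natural
#'   amino acids; extra rows/columns such as `B`, `Z`, `X`, `*` are kept but
#'   unused by the similarity scorer).
#' @export
read_substitution_matrix <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(sprintf("'%s' is not a matrix file", path), call. = FALSE)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[`, character(1L), 1L)
  m <- t(vapply(rows, function(r) as.integer(r[-1L]), integer(length(header))))
  dimnames(m) <- list(labels, header)
  missing <- setdiff(ers_alphabet(), intersect(rownames(m), colnames(m)))
  if (length(missing)) {
    stop(sprintf("substitution matrix '%s' lacks entries for: %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  core <- m[ers_alphabet(), ers_alphabet()]
  if (!isTRUE(all.equal(core, t(core), check.attributes = FALSE))) {
    stop(sprintf("substitution matrix '%s' is not symmetric", path), call. = FALSE)
  }
  attr(m, "name") <- name
  m
}

#' The bundled PAM250 substitution matrix
#'
#' The standard integer log-odds PAM250 table (Dayhoff mutation model at 250
#' accepted point mutations per 100 residues, NCBI scaling), shipped as
#' plain text in `inst/extdata/PAM250.txt` and cached after first load.
#'
#' @return Integer substitution matrix (see [read_substitution_matrix()]).
#' @export
pam250 <- function() {
  if (is.null(.ersnet_env$pam250)) {
    .ersnet_env$pam250 <- read_substitution_matrix(
      system.file("extdata", "PAM250.txt", package = "ersnet", mustWork = TRUE),
      name = "PAM250")
  }
  .ersnet_env$pam250
}

#' Position-wise substitution similarity between two tails
#'
#' The similarity of two aligned seven-residue tails is the sum over
#' positions -7..-1 of the substitution score of the paired residues.
#' Because the matrix is symmetric, so is the score.
#'
#' @param a,b Valid tails.
#' @param matrix Substitution matrix (default [pam250()]).
#' @return Integer similarity score.
#' @examples
#' similarity_score("TAEKDEL", "KKKKDEL")  # 18 under PAM250
#' @export
similarity_score <- function(a, b, matrix = pam250()) {
  a <- validate_tail(a); b <- validate_tail(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sum(matrix[cbind(ca, cb)])
}

#' Rank tails by divergence from a reference motif
#'
#' Scores every tail against the reference with [similarity_score()] and
#' sorts ascending (most divergent first), ties broken lexicographically.
#' The default reference `KKKKDEL` is the per-position most-probable motif of
#' the original training batch.
#'
#' @param tails Non-empty character vector of valid tails.
#' @param reference Reference tail (default `"KKKKDEL"`).
#' @param matrix Substitution matrix (default [pam250()]).
#' @return `data.frame` with columns `tail`, `score`, ascending by score.
#' @export
rank_by_divergence <- function(tails, reference = "KKKKDEL", matrix = pam250()) {
  tails <- validate_tail(tails)
  reference <- validate_tail(reference)
  scores <- vapply(tails, similarity_score, numeric(1L), b = reference,
                   matrix = matrix, USE.NAMES = FALSE)
  ord <- order(scores, tails)
  data.frame(tail = tails[ord], score = scores[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Position probability matrix of a tail set
#'
#' Per-position relative residue frequencies across the supplied tails --
#' the data behind a probability-unit sequence logo. Rows are positions
#' -7..-1, columns the 20 residues; every row sums to 1.
#'
#' @param tails Non-empty character vector of valid tails.
#' @return Numeric 7 x 20 matrix with attribute `n_sequences`.
#' @export
position_probability_matrix <- function(tails) {
  tails <- validate_tail(tails)
  chars <- matrix(unlist(strsplit(tails, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(tails), byrow = TRUE)
  ppm <- t(vapply(seq_len(tail_length()), function(p) {
    as.numeric(table(factor(chars[, p], levels = ers_alphabet()))) / length(tails)
  }, numeric(20L)))
  dimnames(ppm) <- list(position_labels(), ers_alphabet())
  attr(ppm, "n_sequences") <- length(tails)
  ppm
}

#' Write a position probability matrix as TSV
#'
#' Positions as rows (first column `position`, labels -7..-1), residues as
#' columns -- a plain tabular layout consumable by logo renderers.
#'
#' @param ppm Matrix from [position_probability_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(ppm, path) {
  df <- data.frame(position = rownames(ppm), ppm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
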