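#' Read a protein FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning one row per
#' entry with the accession (first whitespace-delimited token of the header),
#' the remaining description, and the sequence with whitespace removed.
#' Sequences may contain unnatural characters and a trailing stop symbol;
#' filtering happens later, in [extract_tails()]. Duplicate accessions are an
#' error, because the tail-to-protein map must be unambiguous.
#'
#' @param source Path to a protein FASTA file.
#' @return `data.frame` with columns `id`, `description`, `sequence`, in file
#'   order.
#' @export
read_protein_fasta <- function(source) {
  set <- Biostrings::readAAStringSet(source)
  headers <- names(set)
  if (is.null(headers)) headers <- character(0L)
  id <- sub("\\s.*$", "", headers)
  if (length(id) && (anyNA(id) || any(!nzchar(id)))) {
    stop(sprintf("malformed FASTA header in '%s': empty id", source), call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate FASTA id '%s' in '%s'",
                 id[duplicated(id)][1L], source), call. = FALSE)
  }
  description <- sub("^\\S+\\s*", "", headers)
  data.frame(id = id, description = description,
             sequence = gsub("\\s", "", as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Extract C-terminal tails from protein records
#'
#' For each protein, a trailing stop symbol `*` is stripped and the last
#' `tail_length` residues are taken. Records shorter than `tail_length` are
#' rejected and counted; extracted tails containing characters outside the
#' 20-letter natural alphabet are rejected and counted (the filter applies to
#' the extracted 7-mer only -- an ambiguous residue elsewhere in the protein
#' does not discard a clean tail). Surviving tails are uppercased and
#' aggregated into a catalog mapping each unique tail to the proteins that
#' carry it.
#'
#' @param records `data.frame` from [read_protein_fasta()] (columns `id`,
#'   `sequence`).
#' @param tail_len Number of C-terminal residues to extract (default 7).
#' @return An object of class `ers_tail_catalog`: list with `entries` (named
#'   list, tail -> character vector of protein ids, in input order) and
#'   `counters` (`n_input`, `retained`, `unique_tails`, `rejected_length`,
#'   `rejected_alphabet`).
#' @export
extract_tails <- function(records, tail_len = tail_length()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(new_tail_catalog(list(), n_input = 0L,
                            rejected_length = 0L, rejected_alphabet = 0L))
  }
  seqs <- sub("\\*$", "", records$sequence)
  long_enough <- nchar(seqs) >= tail_len
  tails <- toupper(substr(seqs[long_enough],
                          nchar(seqs[long_enough]) - tail_len + 1L,
                          nchar(seqs[long_enough])))
  natural <- !grepl(sprintf("[^%s]", paste(ers_alphabet(), collapse = "")), tails)
  kept_tails <- tails[natural]
  kept_ids <- records$id[long_enough][natural]
  entries <- split(kept_ids, factor(kept_tails, levels = unique(kept_tails)))
  new_tail_catalog(as.list(entries), n_input = nrow(records),
                   rejected_length = sum(!long_enough),
                   rejected_alphabet = sum(!natural))
}

new_tail_catalog <- function(entries, n_input, rejected_length, rejected_alphabet) {
  structure(
    list(entries = entries,
         counters = list(
           n_input = as.integer(n_input),
           retained = as.integer(sum(lengths(entries))),
           unique_tails = length(entries),
           rejected_length = as.integer(rejected_length),
           rejected_alphabet = as.integer(rejected_alphabet))),
    class = "ers_tail_catalog")
}

#' @export
print.ers_tail_catalog <- function(x, ...) {
  ct <- x$counters
  cat(sprintf(paste0("C-terminal tail catalog: %d proteins in, %d tails retained",
                     " (%d unique), %d rejected by length, %d by alphabet\n"),
              ct$n_input, ct$retained, ct$unique_tails,
              ct$rejected_length, ct$rejected_alphabet))
  invisible(x)
}

#' Tabulate a tail catalog
#'
#' One row per unique tail, ordered by descending protein count with
#' lexicographic tie-break, so repeated runs are byte-identical.
#'
#' @param catalog An `ers_tail_catalog`.
#' @return `data.frame` with columns `tail`, `n_proteins`, `protein_ids`
#'   (semicolon-separated).
#' @export
catalog_to_table <- function(catalog) {
  stopifnot(inherits(catalog, "ers_tail_catalog"))
  if (length(catalog$entries) == 0L) {
    return(data.frame(tail = character(0L), n_proteins = integer(0L),
                      protein_ids = character(0L), stringsAsFactors = FALSE))
  }
  tail <- names(catalog$entries)
  n_proteins <- lengths(catalog$entries)
  ord <- order(-n_proteins, tail)
  data.frame(
    tail = tail[ord],
    n_proteins = as.integer(n_proteins[ord]),
    protein_ids = vapply(catalog$entries[ord], paste, character(1L),
                         collapse = ";"),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Rebuild a tail catalog from its TSV form
#'
#' Inverse of [write_tail_catalog()] for the mapping itself. The rejection
#' counters are not recoverable from the table and are set to zero;
#' `n_input` equals the retained count.
#'
#' @param path TSV written by [write_tail_catalog()].
#' @return An `ers_tail_catalog`.
#' @export
read_tail_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("tail", "protein_ids")) {
    if (!col %in% names(df)) {
      stop(sprintf("'%s' has no '%s' column", path, col), call. = FALSE)
    }
  }
  tails <- validate_tail(as.character(df$tail))
  entries <- strsplit(as.character(df$protein_ids), ";", fixed = TRUE)
  names(entries) <- tails
  new_tail_catalog(entries, n_input = sum(lengths(entries)),
                   rejected_length = 0L, rejected_alphabet = 0L)
}

#' Write a tail catalog as TSV (plus optional JSON counter summary)
#'
#' @param catalog An `ers_tail_catalog`.
#' @param path Output TSV path (`tail`, `n_proteins`, `protein_ids` columns).
#' @param summary_path Optional path for a JSON dump of the counters.
#' @return `path`, invisibly.
#' @export
write_tail_catalog <- function(catalog, path, summary_path = NULL) {
  utils::write.table(catalog_to_table(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(catalog$counters, summary_path, auto_unbox = TRUE)
  }
  invisible(path)
}
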