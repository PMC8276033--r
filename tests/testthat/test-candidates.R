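test_that("high-frequency residue sets follow per-position frequencies", {
  sets <- high_frequency_sets(rep("TAEKDEL", 10L), threshold = 0.5)
  expect_identical(unname(lengths(sets$sets)), rep(1L, 7L))
  expect_identical(sets$n_candidates, 1)
  expect_identical(sets$sets[["-1"]], "L")
  # -1 residues {L, L, L, V}: only L reaches frequency 0.5
  tails <- c("TAEKDEL", "KAEKDEL", "TAEKDEL", "TAEKDEV")
  sets2 <- high_frequency_sets(tails, threshold = 0.5)
  expect_identical(sets2$sets[["-1"]], "L")
  expect_identical(sets2$sets[["-7"]], "T")
  # threshold 1 on a position with disagreement names the position
  expect_error(high_frequency_sets(c("TAEKDEL", "TAEKDEV"), threshold = 1),
               "position -1")
})

test_that("residue sets round-trip through JSON", {
  sets <- high_frequency_sets(c("TAEKDEL", "KAEKDEL"), threshold = 0.4)
  path <- tempfile(fileext = ".json")
  write_residue_sets(sets, path)
  back <- read_residue_sets(path)
  expect_identical(back$sets, sets$sets)
  short <- tempfile(fileext = ".json")
  jsonlite::write_json(list("A"), short)
  expect_error(read_residue_sets(short), "exactly 7")
})

test_that("enumeration matches the nested-loop oracle on small instances", {
  singleton <- ersnet:::new_residue_sets(
    list("T", "A", "E", "K", "D", "E", "L"))
  expect_identical(enumerate_candidates(singleton), "TAEKDEL")
  # seven sets of size 2: 2^7 distinct tails
  two <- ersnet:::new_residue_sets(
    list(c("A", "C"), c("D", "E"), c("F", "G"), c("H", "I"),
         c("K", "L"), c("M", "N"), c("P", "Q")))
  all128 <- enumerate_candidates(two)
  expect_identical(length(all128), 128L)
  expect_identical(anyDuplicated(all128), 0L)
  expect_identical(all128, oracle_enumerate(two$sets))
  # sizes (3,2,1,1,1,1,4): 24 tails, content equality with the oracle
  mixed <- ersnet:::new_residue_sets(
    list(c("A", "C", "D"), c("E", "F"), "G", "H", "I", "K",
         c("L", "M", "N", "P")))
  got <- enumerate_candidates(mixed)
  expect_identical(length(got), 24L)
  expect_identical(got, oracle_enumerate(mixed$sets))
})

test_that("enumeration order is lexicographic and slices stream the product", {
  sets <- ersnet:::new_residue_sets(
    list(c("A", "K"), "A", "A", "A", "A", "A", c("A", "D", "L")))
  full <- enumerate_candidates(sets)
  expect_identical(full, c("AAAAAAA", "AAAAAAD", "AAAAAAL",
                           "KAAAAAA", "KAAAAAD", "KAAAAAL"))
  expect_identical(full, sort(full))
  # chunked streaming reconstructs the same enumeration
  chunks <- c(enumerate_candidates(sets, from = 1, n = 2),
              enumerate_candidates(sets, from = 3, n = 2),
              enumerate_candidates(sets, from = 5, n = 10))
  expect_identical(chunks, full)
  expect_identical(enumerate_candidates(sets, from = 7), character(0L))
})

test_that("ranking is a stable descending sort with lexicographic ties", {
  d <- tiny_dataset()
  ens <- train_ensemble(d, n_models = 2L, config = tiny_config(),
                        base_seed = 3L)
  cands <- random_tails(40L, seed = 17L)
  ranked <- rank_candidates(cands, ens)
  expect_setequal(ranked$tail, cands)  # permutation, no loss or duplication
  expect_true(all(diff(ranked$score) <= 0))
  full_order <- order(-ranked$score, ranked$tail)
  expect_identical(full_order, seq_len(nrow(ranked)))
  # top_n agrees with taking the head of the full sort
  top <- rank_candidates(cands, ens, top_n = 10L)
  expect_identical(top, utils::head(ranked, 10L))
  # identical calls are identical; chunked scoring agrees to float precision
  expect_identical(rank_candidates(cands, ens), ranked)
  chunked <- rank_candidates(cands, ens, chunk_size = 7L)
  expect_identical(chunked$tail, ranked$tail)
  expect_equal(chunked$score, ranked$score, tolerance = 1e-5)
})

make_catalog <- function(tails) {
  ersnet:::new_tail_catalog(stats::setNames(as.list(paste0("p", seq_along(tails))),
                                            tails),
                            n_input = length(tails), rejected_length = 0L,
                            rejected_alphabet = 0L)
}

test_that("batch assembly applies the selection rules exactly", {
  ranked <- data.frame(
    tail = c("AAAAAAL", "CAAAAAL", "DAAAAAL", "EAAAAAL", "FAAAAAL", "GAAAAAL"),
    score = c(5.0, 4.5, 4.2, 1.5, 1.0, 0.5),
    stringsAsFactors = FALSE)
  catalog <- make_catalog(c("CAAAAAL", "FAAAAAL"))  # the human-proteome tails
  # strong cutoff 4, weak cutoff 2; one artificial + one human per stratum
  batch <- assemble_validation_batch(
    ranked, catalog, first_batch = character(0L),
    n_strong = 2L, n_weak = 2L, strong_cutoff = 4, weak_cutoff = 2,
    artificial_fraction = 0.5)
  strong <- batch[batch$class == "strong", ]
  # top-ranked artificial is AAAAAAL, top-ranked human is CAAAAAL
  expect_setequal(strong$tail, c("AAAAAAL", "CAAAAAL"))
  weak <- batch[batch$class == "weak", ]
  # weakest artificial is GAAAAAL, weakest human is FAAAAAL
  expect_setequal(weak$tail, c("GAAAAAL", "FAAAAAL"))
  expect_identical(batch$source[batch$tail == "CAAAAAL"], "human-proteome")
  expect_identical(batch$source[batch$tail == "AAAAAAL"], "artificial")
})

test_that("batch assembly excludes the first batch and reports infeasibility", {
  ranked <- data.frame(tail = c("AAAAAAL", "CAAAAAL", "DAAAAAL", "FAAAAAL"),
                       score = c(5, 4.5, 0.5, 0.4), stringsAsFactors = FALSE)
  catalog <- make_catalog(c("CAAAAAL", "FAAAAAL"))
  batch <- assemble_validation_batch(
    ranked, catalog, first_batch = "AAAAAAL",
    n_strong = 1L, n_weak = 1L, strong_cutoff = 4, weak_cutoff = 1,
    artificial_fraction = 0)
  expect_false("AAAAAAL" %in% batch$tail)  # excluded despite top rank
  expect_identical(batch$tail[batch$class == "strong"], "CAAAAAL")
  expect_identical(batch$tail[batch$class == "weak"], "FAAAAAL")
  # a stratum whose quota cannot be met names the stratum and source
  expect_error(assemble_validation_batch(
    ranked, catalog, first_batch = character(0L),
    n_strong = 1L, n_weak = 2L, strong_cutoff = 4, weak_cutoff = 1,
    artificial_fraction = 1),
    "weak stratum.*artificial")
  expect_error(assemble_validation_batch(
    ranked, catalog, first_batch = character(0L),
    n_strong = 1L, n_weak = 1L, strong_cutoff = 1, weak_cutoff = 4),
    "strong_cutoff")
})
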