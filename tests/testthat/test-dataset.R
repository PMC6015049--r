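# helpers building small structure corpora entirely in code

toy_corpus <- function(seeds, planted = c(3, 7)) {
  lapply(seeds, function(s) {
    validate_complex(generate_toy_complex(toy_complex_spec(
      planted_contacts = planted, source_id = sprintf("C%03d", s),
      seed = s)))
  })
}

test_that("positive pairs are deduplicated by exact sequence tuples", {
  # same seed twice -> identical sequences -> duplicate pair collapses
  cxs <- c(toy_corpus(c(1, 5)), toy_corpus(1))
  pos <- build_positive_set(cxs)
  expect_equal(nrow(pos$pairs), 2)
  expect_true(all(pos$pairs$label == "positive"))
  # first-seen source kept
  expect_equal(pos$pairs$source_complex, c("C001", "C005"))

  expect_warning(empty <- build_positive_set(list()), "no interacting")
  expect_equal(nrow(empty$pairs), 0)
})

test_that("monomeric complexes cross-pair into negative candidates", {
  cxs <- toy_corpus(c(2, 3))
  cand <- generate_negative_candidates(cxs)
  expect_equal(nrow(cand), 2)  # (Ra,Pb) and (Rb,Pa)
  expect_setequal(cand$source_complex, c("C002xC003", "C003xC002"))
  expect_true(all(cand$label == "negative"))

  expect_equal(nrow(generate_negative_candidates(toy_corpus(2))), 0)
})

test_that("multimeric complexes contribute the within-complex swap", {
  # R1-P1 and R2-P2 interact; the far pairs do not
  r1 <- make_chain("R1", "rna", random_rna(15), origin = c(0, 0, 0))
  p1 <- make_chain("P1", "protein", random_protein(25), origin = c(0, 6, 0))
  r2 <- make_chain("R2", "rna", random_rna(15), origin = c(0, 500, 0))
  p2 <- make_chain("P2", "protein", random_protein(25), origin = c(0, 506, 0))
  cx <- make_complex("MULTI", list(r1, p1, r2, p2))
  cand <- generate_negative_candidates(list(cx))
  expect_equal(nrow(cand), 2)
  got <- sort(paste(cand$rna_id, cand$protein_id))
  expect_equal(got, sort(c("MULTI_R1 MULTI_P2", "MULTI_R2 MULTI_P1")))
})

test_that("percent identity matches hand-derived values", {
  expect_equal(sequence_identity("ACDEFGHIK", "ACDEFGHIK"), 100)
  expect_equal(sequence_identity("ACDEFGHIK", "ACDEFGHIW"), 100 * 8 / 9)
  expect_equal(sequence_identity("AAAA", "CCCC", kind = "rna"), 0)
  expect_error(sequence_identity("ACGU", "MKWDF"), "mixed molecule kinds")
})

test_that("alignment scores agree with an affine-gap dynamic-programming oracle", {
  # identity uses the alignment the optimal score induces; check the score
  # itself against an independent Gotoh implementation
  set.seed(31)
  for (i in 1:12) {
    a <- random_protein(sample(5:10, 1))
    b <- random_protein(sample(5:10, 1))
    letters_ab <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
    sub <- matrix(0, length(letters_ab), length(letters_ab),
                  dimnames = list(letters_ab, letters_ab))
    diag(sub) <- 1
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = sub,
                                         gapOpening = 10, gapExtension = 1)
    expect_equal(Biostrings::score(aln), bf_nw_score(a, b))
  }
})

test_that("negative filters enforce the three construction rules", {
  positives <- make_corpus(rbind(
    pair_row("r1", "p1", "ACGUACGUACGUACG", strrep("MKWDE", 6),
             label = "positive", source_complex = "POS1"),
    pair_row("r2", "p2", "GGGGCCCCAAAAUUU", strrep("HLYTS", 6),
             label = "positive", source_complex = "POS2")))

  cand <- rbind(
    # rule 1: exact positive pair
    pair_row("r1", "px1", "ACGUACGUACGUACG", strrep("MKWDE", 6)),
    # rule 2: protein nearly identical to r1's positive partner
    pair_row("r1", "px2", "ACGUACGUACGUACG",
             paste0(strrep("MKWDE", 5), "MKWDA")),
    # passes: unrelated protein, unrelated RNA
    pair_row("r3", "px3", "UUUUAAGGCAUCGAU", strrep("PQNFC", 6)))
  kept <- filter_negatives(cand, positives)
  expect_equal(kept$protein_id, "px3")

  audit <- audit_negatives(kept, positives)
  expect_true(all(audit))
})

test_that("rule 3 keeps the first of two mutually similar negatives", {
  positives <- make_corpus(pair_row("r1", "p1", "ACGUACGUACGUACG",
                                    strrep("MKWDE", 6), label = "positive",
                                    source_complex = "POS1"))
  shared_rna <- "UUUUAAGGCAUCGAU"
  twin <- strrep("PQNFC", 6)
  cand <- rbind(
    pair_row("rx", "pa", shared_rna, twin, source_complex = "S1"),
    pair_row("rx", "pb", shared_rna, paste0(substr(twin, 1, 29), "W"),
             source_complex = "S2"))
  kept <- filter_negatives(cand, positives)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$source_complex, "S1")  # deterministic first-kept-wins
})

test_that("rules 1-2 are monotone in the similarity threshold", {
  set.seed(8)
  positives <- make_corpus(do.call(rbind, lapply(1:3, function(i) {
    pair_row(paste0("r", i), paste0("p", i), random_rna(20),
             random_protein(30), label = "positive",
             source_complex = paste0("POS", i))
  })))
  # candidates with unique partners so rule 3 is vacuous
  cand <- do.call(rbind, lapply(1:10, function(i) {
    pair_row(paste0("nr", i), paste0("np", i), random_rna(20),
             random_protein(30), source_complex = sprintf("N%02d", i))
  }))
  kept_lo <- filter_negatives(cand, positives, sim_threshold = 15)
  kept_hi <- filter_negatives(cand, positives, sim_threshold = 45)
  expect_true(all(kept_lo$protein_id %in% kept_hi$protein_id))
})

test_that("balancing matches the positive chain ratio deterministically", {
  cxs <- toy_corpus(1:10)
  pos <- build_positive_set(cxs)
  cand <- generate_negative_candidates(cxs)
  neg <- filter_negatives(cand, pos)
  expect_gte(nrow(neg), nrow(pos$pairs))

  b1 <- balance_subset(neg, pos, seed = 4)
  b2 <- balance_subset(neg, pos, seed = 4)
  expect_identical(b1$pairs, b2$pairs)
  expect_equal(nrow(b1$pairs), nrow(pos$pairs))

  ratio <- function(p) length(unique(p$protein_seq)) /
    length(unique(p$rna_seq))
  expect_lt(abs(ratio(b1$pairs) - ratio(pos$pairs)) / ratio(pos$pairs), 0.10)

  # no choice when counts already match
  expect_identical(balance_subset(neg[seq_len(nrow(pos$pairs)), ], pos,
                                  seed = 1)$pairs[, "protein_id"],
                   neg$protein_id[seq_len(nrow(pos$pairs))])
  expect_warning(balance_subset(neg[1, ], pos, seed = 1), "fewer negatives")
})

test_that("labels never overlap and the pipeline is seed-reproducible", {
  cxs <- toy_corpus(1:8)
  c1 <- build_training_corpus(cxs, seed = 9)
  c2 <- build_training_corpus(cxs, seed = 9)
  expect_identical(c1$pairs, c2$pairs)

  key <- function(p) paste(p$rna_seq, p$protein_seq)
  pos_keys <- key(c1$pairs[c1$pairs$label == "positive", ])
  neg_keys <- key(c1$pairs[c1$pairs$label == "negative", ])
  expect_length(intersect(pos_keys, neg_keys), 0)
  expect_false(any(duplicated(pos_keys)) || any(duplicated(neg_keys)))
})

test_that("a corpus round-trips through FASTA plus pair table", {
  corpus <- generate_motif_corpus(motif_corpus_spec(
    n_positive = 5, n_negative = 5, seed = 2))
  prefix <- file.path(tempdir(), "corpus_rt")
  write_corpus(corpus, prefix)
  back <- read_corpus(prefix)
  expect_equal(back$pairs$protein_seq, corpus$pairs$protein_seq)
  expect_equal(back$pairs$rna_seq, corpus$pairs$rna_seq)
  expect_equal(back$pairs$label, corpus$pairs$label)
})
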