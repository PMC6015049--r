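test_that("interacting-pair detection uses a strict 8 A cutoff", {
  # single-atom chains at controlled separations
  far <- make_complex("FAR", list(
    make_chain("A", "protein", random_protein(25), origin = c(0, 0, 0)),
    make_chain("B", "rna", random_rna(15), origin = c(0, 100, 0))))
  expect_equal(nrow(find_interacting_pairs(far)), 0)

  near <- make_complex("NEAR", list(
    make_chain("A", "protein", random_protein(25), origin = c(0, 0, 0)),
    make_chain("B", "rna", random_rna(15), origin = c(0, 7.9, 0))))
  expect_equal(nrow(find_interacting_pairs(near)), 1)

  boundary <- make_complex("EDGE", list(
    make_chain("A", "protein", random_protein(25), origin = c(0, 0, 0)),
    make_chain("B", "rna", random_rna(15), origin = c(0, 8.0, 0))))
  expect_equal(nrow(find_interacting_pairs(boundary)), 0)
})

test_that("planted contacts are recovered as interface residues", {
  spec <- toy_complex_spec(planted_contacts = c(3, 7), seed = 11)
  cx <- generate_toy_complex(spec)
  cm <- interface_residues(cx, "B", "A")
  expect_equal(cm$interface_protein_positions, c(3L, 7L))
  expect_error(interface_residues(cx, "B", "Q"), "unknown chain")
})

test_that("contact detection agrees with a brute-force all-pairs scan", {
  set.seed(20)
  for (s in 1:8) {
    spec <- toy_complex_spec(
      protein_length = sample(25:40, 1), rna_length = sample(15:25, 1),
      planted_contacts = sample(1:15, sample(1:4, 1)), seed = s)
    cx <- generate_toy_complex(spec)
    prot <- cx$chains[[1]]; rna <- cx$chains[[2]]
    cm <- interface_residues(cx, "B", "A")
    expect_equal(cm$interface_protein_positions,
                 bf_interface_positions(prot, rna, 5.0))
    expect_equal(cm$interface_rna_positions,
                 bf_interface_positions(rna, prot, 5.0))
    bf_min <- bf_min_distance(as.matrix(prot$atoms[, c("x", "y", "z")]),
                              as.matrix(rna$atoms[, c("x", "y", "z")]))
    ip <- find_interacting_pairs(cx)
    expect_equal(nrow(ip) == 1, bf_min < 8.0)
  }
})

test_that("interface segments follow the three-intervening-residue rule", {
  # positions 5 and 9 alone: one interface of extent five
  seg <- interface_segments(c(5, 9))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$start, 5)
  expect_equal(seg$end, 9)
  expect_equal(seg$extent, 5)

  expect_equal(interface_segments(4)$extent, 1)

  seg <- interface_segments(c(2, 7, 9))
  expect_equal(seg$start, c(2, 7))
  expect_equal(seg$end, c(2, 9))
  expect_equal(seg$extent, c(1, 3))

  expect_equal(nrow(interface_segments(integer(0))), 0)
})

test_that("segments are sorted, non-overlapping, and idempotent", {
  set.seed(77)
  for (i in 1:25) {
    pos <- sort(sample(1:80, sample(1:20, 1)))
    seg <- interface_segments(pos)
    expect_true(all(seg$start <= seg$end))
    expect_true(all(diff(seg$start) > 0))
    if (nrow(seg) > 1) expect_true(all(seg$start[-1] > seg$end[-nrow(seg)]))
    expect_true(all(pos >= seg$start[1] & pos <= seg$end[nrow(seg)]))
    # bordering positions interact; re-running on the positions reproduces
    expect_true(all(seg$start %in% pos) && all(seg$end %in% pos))
    expect_identical(interface_segments(pos), seg)
  }
})

test_that("propensities reproduce the ratio formula on a hand example", {
  # chain RRRGR with interacting {1, 5}: segment [1,5], non-interacting RRG
  ch <- make_chain("A", "protein", "RRRGR")
  cmap <- structure(list(rna_chain_id = "B", protein_chain_id = "A",
                         interface_rna_positions = integer(0),
                         interface_protein_positions = c(1L, 5L),
                         min_distance = 4, cutoff = 5),
                    class = "contact_map")
  tab <- compute_propensities(list(cmap), list(A = ch))
  expect_equal(attr(tab, "I_n"), 2)
  expect_equal(attr(tab, "N_n"), 3)
  r <- tab[tab$aa == "R", ]
  expect_equal(r$I_j, 2); expect_equal(r$N_j, 2)
  expect_equal(r$P_j, (2 / 2) / (2 / 3))       # = 1.5
  g <- tab[tab$aa == "G", ]
  expect_equal(g$P_j, 0)                       # I_j = 0
  expect_equal(sum(tab$I_j), attr(tab, "I_n"))
  expect_equal(sum(tab$N_j), attr(tab, "N_n"))
})

test_that("propensity edge cases: infinity sentinel and undefined totals", {
  ch <- make_chain("A", "protein", "RGRGR")
  cmap <- structure(list(rna_chain_id = "B", protein_chain_id = "A",
                         interface_rna_positions = integer(0),
                         interface_protein_positions = c(1L, 3L, 5L),
                         min_distance = 4, cutoff = 5),
                    class = "contact_map")
  expect_warning(tab <- compute_propensities(list(cmap), list(A = ch)),
                 "\\+Inf")
  expect_equal(tab$P_j[tab$aa == "R"], Inf)

  # adjacent-only interface: no admitted non-interacting residues
  cmap$interface_protein_positions <- c(1L, 2L)
  expect_error(compute_propensities(list(cmap), list(A = ch)),
               "undefined propensities")
})

test_that("planted class-0 contacts yield propensities above one", {
  maps <- list(); chains <- list()
  basics <- c("R", "K", "H")
  for (s in 1:15) {
    cx <- generate_toy_complex(toy_complex_spec(
      planted_contacts = c(3, 7), contact_residue = basics[(s %% 3) + 1],
      source_id = paste0("T", s), seed = 100 + s))
    cm <- interface_residues(cx, "B", "A")
    cm$protein_chain_id <- paste0("A", s)
    ch <- cx$chains[[1]]; ch$chain_id <- paste0("A", s)
    maps[[s]] <- cm
    chains[[paste0("A", s)]] <- ch
  }
  tab <- compute_propensities(maps, chains)
  expect_true(all(tab$P_j[tab$aa %in% basics] > 1))
  expect_true(all(tab$P_j[!tab$aa %in% basics] < 1))
  expect_equal(sum(tab$I_j), attr(tab, "I_n"))
  expect_equal(sum(tab$N_j), attr(tab, "N_n"))
})

test_that("the reduced alphabet partitions the 20 amino acids into 4 classes", {
  cls <- amino_acid_classes
  expect_length(cls, 4)
  expect_equal(lengths(cls, use.names = FALSE), c(3L, 8L, 2L, 7L))
  all_aa <- sort(unlist(cls, use.names = FALSE))
  expect_equal(all_aa, sort(names(protein_class_map())))
  expect_length(unique(unlist(cls)), 20)

  expect_equal(amino_acid_class("R"), 0L)
  expect_equal(amino_acid_class(c("K", "H")), c(0L, 0L))
  expect_equal(amino_acid_class("D"), 1L)
  expect_equal(amino_acid_class(c("C", "E")), c(2L, 2L))
  expect_equal(amino_acid_class("N"), 3L)
  expect_error(amino_acid_class("B"), "non-standard")
})

test_that("propensity and segment reports are written as TSV", {
  ch <- make_chain("A", "protein", "RRRGR")
  cmap <- structure(list(rna_chain_id = "B", protein_chain_id = "A",
                         interface_rna_positions = integer(0),
                         interface_protein_positions = c(1L, 5L),
                         min_distance = 4, cutoff = 5),
                    class = "contact_map")
  tab <- compute_propensities(list(cmap), list(A = ch))
  tf <- tempfile(fileext = ".tsv")
  write_propensity_table(tab, tf)
  back <- utils::read.delim(tf, comment.char = "#")
  expect_equal(nrow(back), 20)
  expect_equal(back$P_j[back$aa == "R"], 1.5)

  sf <- tempfile(fileext = ".tsv")
  write_segments(interface_segments(c(5, 9)), "A", sf)
  lines <- readLines(sf)
  expect_match(lines[1], "1-based inclusive")
  expect_equal(strsplit(lines[2], "\t")[[1]], c("A", "5", "9", "5"))
})
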