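toy_inteins <- list(int_c = "MVKVIGRR", int_n = "AEYCLSFG")

test_that("circular permutation rotates and linearizes", {
  core <- residue_seq("ACDEF", "circular")
  expect_identical(circular_permute(core, 3)$residues, "DEFAC")
  p1 <- circular_permute(core, 1)
  expect_identical(p1$residues, "ACDEF")
  expect_identical(p1$topology, "linear")
  expect_error(circular_permute(core, 0), "split_position")
  expect_error(circular_permute(core, 6), "split_position")
  expect_error(circular_permute(residue_seq("ACDEF"), 2), "circular")
})

test_that("permutations compose back to the identity", {
  set.seed(61)
  for (n in 2:10) {
    s <- rand_aa(n)
    core <- residue_seq(s, "circular")
    for (k in seq_len(n)) {
      once <- circular_permute(core, k)
      back <- circular_permute(residue_seq(once$residues, "circular"),
                               (n - k + 2L - 1L) %% n + 1L)
      expect_identical(back$residues, s)
    }
  }
})

test_that("SIML designs open the published split sites", {
  p <- reference_panel()
  pum <- residue_seq(p$circular[["pumilarin_synthetic"]], "circular")
  d <- build_siml_protein(pum, 37L, toy_inteins)
  pc <- d$permuted_core$residues
  expect_identical(nchar(pc), 70L)
  expect_identical(substr(pc, 1, 1), "S")
  expect_identical(substr(pc, 70, 70), "G")
  alt <- residue_seq(p$circular[["altitudin_A_synthetic"]], "circular")
  d2 <- build_siml_protein(alt, 8L, toy_inteins)
  pc2 <- d2$permuted_core$residues
  expect_identical(nchar(pc2), 65L)
  expect_identical(substr(pc2, 1, 1), "S")
  expect_identical(substr(pc2, 65, 65), "I")
  # part order and total length
  expect_identical(names(d$parts),
                   c("int_c", "permuted_core", "int_n", "ssra_tag"))
  expect_identical(seq_length(d$protein),
                   sum(nchar(unlist(d$parts))))
  # disabling the tag removes only the last part
  d3 <- build_siml_protein(pum, 37L, toy_inteins, tag = NULL)
  expect_identical(names(d3$parts), c("int_c", "permuted_core", "int_n"))
  expect_error(build_siml_protein(pum, 37L, list(int_c = "M")), "int_n")
})

test_that("reverse translation round-trips under both strategies", {
  tab <- read_codon_usage()
  expect_identical(reverse_translate("M", tab), "ATG")
  set.seed(62)
  for (i in 1:200) {
    p <- rand_aa(sample(1:60, 1))
    expect_identical(translate_dna(reverse_translate(p, tab)), p)
    expect_identical(translate_dna(reverse_translate(p, tab, "weighted",
                                                     seed = i)), p)
  }
  # weighted strategy is seed-reproducible
  p <- rand_aa(50)
  expect_identical(reverse_translate(p, tab, "weighted", seed = 7),
                   reverse_translate(p, tab, "weighted", seed = 7))
  bad <- read_codon_usage()
  bad[["W"]] <- NULL
  expect_error(reverse_translate("W", bad), "absent from codon table")
})

test_that("expression cassettes are annotated and reject in-frame stops", {
  cas <- build_expression_cassette("GGT")
  expect_true(grepl("ATGGGTTAA", cas$sequence, fixed = TRUE))
  expect_identical(length(cas$features), 3L)
  cds <- cas$features[[2]]
  expect_identical(substr(cas$sequence, cds$start, cds$start + 2), "ATG")
  expect_identical(substr(cas$sequence, cds$end - 2, cds$end), "TAA")
  # TAA is codon 3 after the ATG is prepended
  expect_error(build_expression_cassette("GGTTAAGGT"),
               "stop codon TAA at codon 3")
  # a full SIML construct emits exactly one CDS spanning start to stop
  p <- reference_panel()
  d <- build_siml_protein(residue_seq(p$circular[["pumilarin_synthetic"]],
                                      "circular"), 37L, toy_inteins)
  cas2 <- build_expression_cassette(
    reverse_translate(d$protein, read_codon_usage()))
  keys <- vapply(cas2$features, function(f) f$key, "")
  expect_identical(sum(keys == "CDS"), 1L)
  f <- tempfile(fileext = ".gb")
  write_genbank(cas2, f)
  back <- read_genbank_features(f)
  expect_identical(back$protein, d$protein$residues)
})

test_that("linear T7 templates satisfy the primer invariants", {
  tab <- read_codon_usage()
  p <- reference_panel()
  clb <- p$linear[["closticin_574_synthetic"]]
  tpl <- build_linear_t7_template(clb, tab)
  expect_identical(nchar(tpl$coding), 3L * nchar(clb))
  expect_true(startsWith(tpl$amplicon, tpl$forward_primer))
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_true(endsWith(tpl$amplicon, rc(tpl$reverse_primer)))
  # amplicon = promoter + ATG + coding + TAA + terminator
  body <- nchar(tpl$amplicon) -
    nchar(circbact:::T7_PROMOTER) - nchar(circbact:::T7_TERMINATOR)
  expect_identical(body, 3L * nchar(clb) + 6L)
  expect_error(build_linear_t7_template("MGK", tab, primer_core_len = 24L),
               "too short")
})

test_that("re-circularized permuted cores digest identically to the original", {
  p <- reference_panel()
  core <- residue_seq(p$circular[["altitudin_A_synthetic"]], "circular")
  ref <- sort(digest_circular(core, max_missed = 1L)$sequence)
  for (k in c(1L, 8L, 20L, 40L, 65L)) {
    perm <- circular_permute(core, k)
    again <- residue_seq(perm$residues, "circular")
    expect_identical(sort(digest_circular(again, max_missed = 1L)$sequence),
                     ref)
  }
})
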