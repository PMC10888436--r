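test_that("ORF finding translates both strands with bacterial starts", {
  d <- find_orfs("ATGGGTAAATAA", min_len = 1L)
  expect_identical(nrow(d), 1L)
  expect_identical(d$protein, "MGK")
  expect_identical(c(d$start, d$end), c(1L, 12L))
  expect_identical(d$strand, "+")
  # GTG start translates as M
  g <- find_orfs("GTGGGTAAATAA", min_len = 1L)
  expect_identical(g$protein, "MGK")
  # no start codon anywhere -> nothing
  expect_identical(nrow(find_orfs("CCCCCACCCCCACCC", min_len = 1L)), 0L)
})

test_that("ORF discovery is strand-symmetric", {
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  orf <- "ATGGGTAAAGGTTTCTGGTAA"
  d <- find_orfs(orf, min_len = 1L)
  drc <- find_orfs(rc(orf), min_len = 1L)
  expect_setequal(d$protein, drc$protein)
  expect_identical(drc$strand[drc$protein == "MGKGFW"], "-")
  set.seed(31)
  for (i in 1:5) {
    dna <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
    expect_setequal(find_orfs(dna, 10L)$protein,
                    find_orfs(rc(dna), 10L)$protein)
  }
  expect_error(find_orfs("ACGU"), "non-nucleotide")
})

test_that("role classification is a deterministic cascade", {
  expect_identical(classify_gene_role(strrep("A", 50),
                                      "stage II sporulation protein M"),
                   "spoIIM_duf95")
  expect_identical(classify_gene_role(strrep("A", 50),
                                      "ABC transporter ATP-binding protein"),
                   "abc_atp_binding")
  expect_identical(classify_gene_role(strrep("A", 50), "immunity protein"),
                   "immunity")
  # Walker A + downstream hydrophobic-D Walker B block, no annotation
  walker <- paste0(strrep("S", 40), "GPSGSGKS", strrep("T", 30), "IILVD",
                   strrep("S", 40))
  expect_identical(classify_gene_role(walker, ""), "abc_atp_binding")
  # two long hydrophobic stretches, length in the membrane window
  memb <- paste0(strrep("S", 20), strrep("L", 25), strrep("S", 20),
                 strrep("I", 25), strrep("S", 30))
  expect_identical(classify_gene_role(memb, ""), "membrane")
  expect_identical(classify_gene_role(strrep("S", 120), ""), "unknown")
  # purity: identical input, identical output
  expect_identical(classify_gene_role(memb, ""),
                   classify_gene_role(memb, ""))
})

test_that("percent identity matches hand counts and an independent aligner", {
  expect_identical(percent_identity("LVWY", "LVWY"), 100)
  expect_identical(percent_identity("AAAA", "AATA"), 75)
  p <- reference_panel()
  a <- p$circular[["enterocin_AS48"]]
  b <- p$circular[["enterocin_NKR53B_synthetic"]]
  # frozen from Biopython PairwiseAligner, BLOSUM62, open -11 / extend -1
  expect_identical(percent_identity(a, b, "global"), 20.3)
  expect_identical(percent_identity(a, b, "local"), 25.5)
  expect_error(percent_identity("", "AA"), "empty")
})

test_that("a panel core behind a synthetic leader is recovered exactly", {
  p <- reference_panel()
  core <- p$circular[["pumilarin_synthetic"]]
  leader <- "MNTSDKFEELSATDLEQIQGG"  # 21 aa, no L/V/W near the boundary
  feats <- data.frame(id = "g1", contig = "c", start = 1L,
                      end = 3L * (nchar(leader) + nchar(core)),
                      strand = "+", protein = paste0(leader, core),
                      annotation = "", role = "unknown",
                      stringsAsFactors = FALSE)
  models <- find_precursor_candidates(feats)
  expect_length(models, 1L)
  pm <- models[[1]]
  expect_identical(pm$leader_len, nchar(leader))
  expect_identical(pm$core$residues, core)
  expect_identical(pm$core$topology, "circular")
  expect_identical(pm$homology_support$identity, 100)
  expect_identical(seq_length(pm$precursor),
                   pm$leader_len + seq_length(pm$core))
})

test_that("shuffled random proteins yield no precursor candidate", {
  set.seed(32)
  for (i in 1:5) {
    prot <- rand_aa(100)
    feats <- data.frame(id = "g1", contig = "c", start = 1L, end = 300L,
                        strand = "+", protein = prot, annotation = "",
                        role = "unknown", stringsAsFactors = FALSE)
    expect_length(find_precursor_candidates(feats), 0L)
  }
  expect_error(find_precursor_candidates(feats, panel = list(circular =
                                                               character())),
               "no circular cores")
})

test_that("precursor models enforce leader/core geometry and terminal rule", {
  expect_error(precursor_model("LAKW", 4), "leader_len")
  expect_error(precursor_model(paste0("MA", "AAKGW"), 2),
               "terminal rule")
  pm <- precursor_model("MALAKGW", 2)
  expect_identical(pm$core$residues, "LAKGW")
})

test_that("cluster calls score context-role completeness within the window", {
  g <- gen_cluster(41)
  f <- tempfile(fileext = ".gbk")
  write_genbank(g$record, f)
  calls <- call_clusters(read_genome_features(f))
  circ <- Filter(function(x) x$type == "circular", calls)
  expect_length(circ, 1L)
  expect_identical(circ[[1]]$completeness, 3L)
  expect_identical(circ[[1]]$precursor_model$leader_len, 49L)
  # the same cluster with all context genes far outside the window
  feats <- read_genome_features(f)
  prec_id <- find_precursor_candidates(feats)[[1]]$source_id
  prec <- feats[feats$id == prec_id, ]
  others <- feats[feats$id != prec_id, ]
  others$start <- others$start + 50000L
  others$end <- others$end + 50000L
  far <- rbind(prec, others)
  calls_far <- call_clusters(far)
  circ_far <- Filter(function(x) x$type == "circular", calls_far)
  expect_identical(circ_far[[1]]$completeness, 0L)
})

test_that("closticin-type proteins are reported as linear candidates", {
  p <- reference_panel()
  clb <- p$linear[["closticin_574_synthetic"]]
  feats <- data.frame(id = "g1", contig = "c", start = 10L,
                      end = 10L + 3L * nchar(clb), strand = "+",
                      protein = clb, annotation = "", role = "unknown",
                      stringsAsFactors = FALSE)
  calls <- call_clusters(feats)
  expect_length(calls, 1L)
  expect_identical(calls[[1]]$type, "linear_like")
  expect_null(calls[[1]]$precursor_model)
})

test_that("GenBank records round-trip coordinates, strand and translation", {
  g <- gen_cluster(42)
  f <- tempfile(fileext = ".gbk")
  write_genbank(g$record, f)
  feats <- read_genbank_features(f)
  expect_identical(nrow(feats), nrow(g$features))
  expect_identical(feats$start, g$features$start)
  expect_identical(feats$end, g$features$end)
  expect_identical(feats$strand, g$features$strand)
  expect_setequal(feats$protein, g$features$protein)
})
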