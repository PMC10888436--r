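theo_one <- function(seqs, junction = FALSE) {
  structure(data.frame(sequence = seqs, start = seq_along(seqs),
                       length = nchar(seqs), missed = 0L,
                       junction = rep_len(junction, length(seqs)),
                       specificity = "full", stringsAsFactors = FALSE),
            parent_length = sum(nchar(seqs)), parent_topology = "circular",
            class = c("digest_peptides", "data.frame"))
}

test_that("fragment matching finds published peaks at ppm tolerance", {
  th <- theo_one("YAAEWLATNLGISR")
  pk <- peak_list(782.9106, kind = "fragment_lcmsms")
  m <- match_fragments(th, pk, charges = 2L, tol_ppm = 20)
  expect_identical(nrow(m), 1L)
  expect_identical(m$charge, 2L)
  expect_lt(abs(m$error_ppm), 2)
  # the same peak is out of reach at 0.01 ppm
  m0 <- match_fragments(th, pk, charges = 2L, tol_ppm = 0.01)
  expect_identical(nrow(m0), 0L)
  # empty peak list: empty result, not an error
  m2 <- match_fragments(th, peak_list(numeric(0), kind = "fragment_lcmsms"))
  expect_identical(nrow(m2), 0L)
  expect_error(match_fragments(th[0, ], pk), "empty theoretical")
  expect_error(match_fragments(th, peak_list(1, kind = "intact_maldi")),
               "fragment_lcmsms")
})

test_that("variable Met oxidation is searched when requested", {
  th <- theo_one("GTGLVTAAMVATAK")
  pk <- peak_list(653.8569, kind = "fragment_lcmsms")
  m <- match_fragments(th, pk, charges = 2L)
  expect_identical(nrow(m), 1L)
  expect_identical(m$n_ox, 1L)
  expect_identical(nrow(match_fragments(th, pk, charges = 2L,
                                        variable_mods = FALSE)), 0L)
})

test_that("the match set grows monotonically with tolerance", {
  set.seed(51)
  seqs <- vapply(1:8, function(i) rand_aa(sample(6:15, 1)), "")
  th <- theo_one(seqs)
  mz <- mz_for_charge(vapply(seqs, peptide_mass, 1), 2L) *
    (1 + rnorm(8, 0, 10) * 1e-6)
  pk <- peak_list(c(mz, runif(10, 300, 900)), kind = "fragment_lcmsms")
  key <- function(m) paste(m$sequence, m$charge, m$observed_mz)
  for (tols in list(c(2, 10), c(5, 20), c(10, 50))) {
    a <- match_fragments(th, pk, tol_ppm = tols[1])
    b <- match_fragments(th, pk, tol_ppm = tols[2])
    expect_true(all(key(a) %in% key(b)))
    expect_true(all(abs(a$error_ppm) <= tols[1]))
  }
  # peak order does not matter: the list is normalized on construction
  perm <- sample(length(pk$mz))
  pk2 <- peak_list(pk$mz[perm], pk$intensity[perm], "fragment_lcmsms")
  expect_identical(match_fragments(th, pk2), match_fragments(th, pk))
})

test_that("intact dehydration check reproduces the published mass pairs", {
  # altitudin A: deduced linear 6615.93 Da vs observed 6598.93 Da
  r <- intact_cyclic_check(6615.93, peak_list(6598.93,
                                              kind = "intact_maldi"))
  expect_true(r$cyclic_pass)
  expect_lte(abs(r$delta), 0.05)
  expect_false(r$linear_pass)
  # pumilarin: 7105.42 Da deduced vs 7089.15 Da observed (~0.7 Da off,
  # inside the 1.5 Da linear-mode window)
  r2 <- intact_cyclic_check(7105.42, peak_list(7089.15,
                                               kind = "intact_maldi"))
  expect_true(r2$cyclic_pass)
  expect_lte(abs(r2$delta), 1.5)
  # the nominal closure shift is one water, 18 Da to integer rounding
  expect_identical(round(mass_constants()$water_mono), 18)
  # a linear (non-dehydrated) species is recognized as such
  r3 <- intact_cyclic_check(6615.93,
                            peak_list(6615.93 + mass_constants()$proton,
                                      kind = "intact_maldi"))
  expect_true(r3$linear_pass)
  expect_false(r3$cyclic_pass)
  r4 <- intact_cyclic_check(6615.93, peak_list(numeric(0),
                                               kind = "intact_maldi"))
  expect_identical(r4$status, "no_peaks")
  expect_error(intact_cyclic_check(6615.93,
                                   peak_list(1, kind = "fragment_lcmsms")),
               "intact_maldi")
})

test_that("evidence assembly renders the three verdicts", {
  p <- reference_panel()
  pm <- precursor_model(paste0("MSTDNQE", p$circular[["pumilarin_synthetic"]]),
                        7L)
  peps <- semi_specific_expand(digest_circular(pm$core))
  k <- mass_constants()
  lin_avg <- peptide_mass(residue_seq(pm$core$residues), NULL, "average")
  cyc_peak <- peak_list(lin_avg - k$water_avg + k$proton,
                        kind = "intact_maldi")
  lin_peak <- peak_list(lin_avg + k$proton, kind = "intact_maldi")
  # junction fragment AVIAWLAK observed: core ends ...AVIAW, starts LAK...
  jx_mz <- mz_for_charge(peptide_mass("AVIAWLAK"), 2L)
  frag <- peak_list(jx_mz, kind = "fragment_lcmsms")
  m <- match_fragments(peps, frag)
  expect_true(any(m$junction & m$sequence == "AVIAWLAK"))
  ev <- assemble_evidence(pm, m, intact_cyclic_check(pm, cyc_peak))
  expect_identical(ev$verdict, "circular_supported")
  expect_true(all(ev$junction_matches$junction))
  # intact pass but no junction-covering fragment: not enough
  m_int <- m[!m$junction, , drop = FALSE]
  ev2 <- assemble_evidence(pm, m_int, intact_cyclic_check(pm, cyc_peak))
  expect_identical(ev2$verdict, "insufficient")
  # intact matches the linear species instead
  ev3 <- assemble_evidence(pm, m_int, intact_cyclic_check(pm, lin_peak))
  expect_identical(ev3$verdict, "linear_only")
  # no peaks at all
  ev4 <- assemble_evidence(pm, m[0, , drop = FALSE],
                           intact_cyclic_check(pm, peak_list(
                             numeric(0), kind = "intact_maldi")))
  expect_identical(ev4$verdict, "insufficient")
})

test_that("peak lists load from two-column text and minimal MGF", {
  f <- tempfile()
  writeLines(c("# mz intensity", "500.25 120", "400.1,7", "600.5"), f)
  pk <- read_peak_list(f)
  expect_identical(pk$mz, c(400.1, 500.25, 600.5))
  expect_identical(pk$intensity, c(7, 120, 1))
  g <- tempfile()
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=782.91", "782.9106 55",
               "400.2 3", "END IONS"), g)
  mgf <- read_peak_list(g)
  expect_identical(mgf$mz, c(400.2, 782.9106))
  expect_identical(mgf$intensity, c(3, 55))
  # round trip through the plain-text writer
  h <- tempfile()
  write_peak_list(pk, h)
  again <- read_peak_list(h)
  expect_equal(again$mz, pk$mz, tolerance = 1e-6)
  expect_error(peak_list(c(-1, 2)), "positive")
})
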