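# Deterministic synthetic genomes, clusters and peak lists with known
# ground truth. All randomness flows through R's Mersenne-Twister via a
# single integer seed per artifact, so regeneration is byte-identical.

rand_protein <- function(n, alphabet = AA_ALPHABET, prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# Hydrophilic-biased alphabet for leaders and loop regions.
POLAR_AA <- c("A", "S", "T", "N", "Q", "E", "D", "G", "P", "H")

#' Generate a synthetic circular-bacteriocin gene cluster
#'
#' Builds a toy contig emulating the canonical cluster architecture: a
#' precursor CDS (leader + mature core, the core derived from a
#' reference panel entry by seeded point substitutions so that
#' homology mining can find it), plus requested context genes -- an
#' ATP-binding gene carrying a Walker A/B motif pair, a membrane gene
#' with at least two hydrophobic 19-mers, a SpoIIM/DUF95-annotated
#' gene and optionally an immunity gene -- separated by random
#' spacers. Coordinates are 1-based inclusive and include the stop
#' codon.
#'
#' @param seed Integer seed; the same seed reproduces the cluster
#'   byte-identically.
#' @param leader_len Leader length in residues (default 49).
#' @param context_roles Context genes to include (default all three
#'   scored roles).
#' @param base_core Mature core to mutate (default: the bundled
#'   65-residue altitudin-A-like synthetic panel core).
#' @param mutation_rate Per-residue substitution probability applied
#'   to interior core positions (default 0.15); termini are preserved
#'   so the terminal-residue rule keeps holding.
#' @param circular Ground-truth topology of the secreted peptide
#'   (default TRUE). `FALSE` models a maturation failure: peak lists
#'   generated from such truth present the linear species.
#' @return List with `record` (a GenBank-writable record), `features`
#'   (the true gene layout) and `truth` (core, leader, layout, seed,
#'   parameters).
#' @export
gen_cluster <- function(seed, leader_len = 49L,
                        context_roles = c("membrane", "abc_atp_binding",
                                          "spoIIM_duf95"),
                        base_core = NULL, mutation_rate = 0.15,
                        circular = TRUE) {
  withr_seed(seed, {
    if (is.null(base_core)) {
      panel <- reference_panel()
      base_core <- unname(panel$circular[["altitudin_A_synthetic"]])
    }
    n <- nchar(base_core)
    if (leader_len < 1L) stop("leader_len must be >= 1", call. = FALSE)
    chars <- strsplit(base_core, "")[[1L]]
    interior <- 2:(n - 1L)
    flip <- interior[stats::runif(length(interior)) < mutation_rate]
    for (p in flip) chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
    core <- paste(chars, collapse = "")
    # leader: starts with M, last 3 residues never L/V/W so boundary
    # snapping cannot slip into the leader
    leader <- paste0("M", rand_protein(leader_len - 4L),
                     rand_protein(3L, POLAR_AA))
    precursor <- paste0(leader, core)
    tab <- read_codon_usage()
    proteins <- list(precursor = precursor)
    annotations <- c(precursor = "hypothetical bacteriocin precursor")
    if ("membrane" %in% context_roles) {
      repeat {
        p <- paste0("M", rand_protein(30L, POLAR_AA),
                    rand_protein(30L, c("A", "I", "L", "V", "F")),
                    rand_protein(25L, POLAR_AA),
                    rand_protein(30L, c("A", "I", "L", "V", "F")),
                    rand_protein(14L, POLAR_AA))
        if (classify_gene_role(p, "") == "membrane") break
      }
      proteins$membrane <- p
      annotations["membrane"] <- "putative membrane protein"
    }
    if ("abc_atp_binding" %in% context_roles) {
      proteins$abc_atp_binding <- paste0(
        "M", rand_protein(40L), "GPSGSGKS", rand_protein(60L, POLAR_AA),
        "ILVFD", rand_protein(60L))
      annotations["abc_atp_binding"] <- "ABC transporter ATP-binding protein"
    }
    if ("spoIIM_duf95" %in% context_roles) {
      proteins$spoIIM_duf95 <- paste0(
        "M", rand_protein(20L, POLAR_AA),
        paste(replicate(4L, paste0(rand_protein(25L, c("A", "I", "L", "V",
                                                       "F")),
                                   rand_protein(12L, POLAR_AA))),
              collapse = ""))
      annotations["spoIIM_duf95"] <-
        "stage II sporulation protein M (SpoIIM/DUF95)"
    }
    if ("immunity" %in% context_roles) {
      proteins$immunity <- paste0("M", rand_protein(70L))
      annotations["immunity"] <- "putative immunity protein"
    }
    # assemble the contig: spacer, genes in a fixed role order, spacer
    order_roles <- intersect(c("membrane", "abc_atp_binding", "precursor",
                               "spoIIM_duf95", "immunity"),
                             names(proteins))
    strands <- stats::setNames(rep("+", length(order_roles)), order_roles)
    if ("membrane" %in% order_roles) strands["membrane"] <- "-"
    contig <- rand_dna(200L + sample(100L, 1L))
    layout <- list()
    features <- list()
    for (role in order_roles) {
      cds <- paste0(reverse_translate(proteins[[role]], tab,
                                      "max_frequency"), "TAA")
      start <- nchar(contig) + 1L
      insert <- if (strands[role] == "-") revcomp(cds) else cds
      contig <- paste0(contig, insert)
      end <- nchar(contig)
      layout[[role]] <- data.frame(role = role, start = start, end = end,
                                   strand = unname(strands[role]),
                                   protein = proteins[[role]],
                                   stringsAsFactors = FALSE)
      features[[length(features) + 1L]] <- list(
        key = "CDS", start = start, end = end,
        strand = unname(strands[role]),
        qualifiers = c(product = unname(annotations[role]),
                       translation = proteins[[role]]))
      contig <- paste0(contig, rand_dna(150L + sample(250L, 1L)))
    }
    layout <- do.call(rbind, layout)
    rownames(layout) <- NULL
    truth <- list(core = residue_seq(core, "circular"), leader = leader,
                  precursor = residue_seq(precursor), layout = layout,
                  circular = circular, seed = seed,
                  leader_len = nchar(leader), mutation_rate = mutation_rate)
    record <- list(locus = sprintf("synth_%d", seed),
                   definition = "synthetic circular-bacteriocin cluster",
                   sequence = contig, features = features)
    list(record = record, features = layout, truth = truth)
  })
}

#' Generate fragment and intact peak lists from a synthetic truth
#'
#' Fragment peaks are the doubly-protonated monoisotopic m/z of the
#' core's tryptic digest (circular or linear per the ground truth),
#' perturbed by Gaussian ppm error; the intact peak is the average
#' [M+H]+ of the cyclized (dehydrated) or linear species perturbed on
#' the Dalton scale. Decoy peaks are drawn uniformly over the observed
#' m/z range but at least 50 ppm away from every true peak, so decoy
#' contamination and matching tolerance remain distinguishable.
#'
#' @param truth Truth record from [gen_cluster].
#' @param seed Integer seed.
#' @param ppm_sigma Fragment m/z error s.d. in ppm (default 5).
#' @param decoy_frac Fraction of fragment peaks that are decoys
#'   (default 0.3).
#' @param intact_sigma Intact-mass error s.d. in Da (default 0.3).
#' @param met_ox_prob Probability that a Met-containing peptide also
#'   emits its oxidized form (default 0.2).
#' @param max_missed,semi Digest settings (defaults 2, TRUE).
#' @return List with `fragments` and `intact` peak lists and
#'   `provenance` (peptide or decoy origin of every fragment peak).
#' @export
gen_peaklists <- function(truth, seed, ppm_sigma = 5, decoy_frac = 0.3,
                          intact_sigma = 0.3, met_ox_prob = 0.2,
                          max_missed = 2L, semi = TRUE) {
  if (ppm_sigma < 0 || intact_sigma < 0)
    stop("noise sigmas must be non-negative", call. = FALSE)
  if (decoy_frac < 0 || decoy_frac >= 1)
    stop("decoy_frac must be in [0, 1)", call. = FALSE)
  withr_seed(seed, {
    k <- mass_constants()
    core <- truth$core
    peps <- if (truth$circular) digest_circular(core, max_missed = max_missed)
            else digest_linear(residue_seq(core$residues), max_missed =
                                 max_missed)
    if (semi) peps <- semi_specific_expand(peps)
    mz <- numeric(); origin <- character()
    for (r in seq_len(nrow(peps))) {
      m <- peptide_mass(peps$sequence[r])
      theo <- mz_for_charge(m, 2L)
      mz <- c(mz, theo * (1 + stats::rnorm(1L, 0, ppm_sigma) * 1e-6))
      origin <- c(origin, peps$sequence[r])
      if (grepl("M", peps$sequence[r]) &&
          stats::runif(1L) < met_ox_prob) {
        theo_ox <- mz_for_charge(m + k$met_oxidation, 2L)
        mz <- c(mz, theo_ox * (1 + stats::rnorm(1L, 0, ppm_sigma) * 1e-6))
        origin <- c(origin, paste0(peps$sequence[r], "+ox"))
      }
    }
    n_true <- length(mz)
    n_decoy <- round(decoy_frac / (1 - decoy_frac) * n_true)
    lo <- min(mz) * 0.9; hi <- max(mz) * 1.1
    decoys <- numeric()
    while (length(decoys) < n_decoy) {
      cand <- stats::runif(1L, lo, hi)
      if (all(abs(1e6 * (cand - mz) / mz) >= 50)) decoys <- c(decoys, cand)
    }
    frag <- peak_list(c(mz, decoys),
                      c(stats::runif(n_true, 0.5, 1),
                        stats::runif(n_decoy, 0.01, 0.3)),
                      "fragment_lcmsms")
    lin_avg <- peptide_mass(residue_seq(core$residues), NULL, "average")
    intact_true <- if (truth$circular) lin_avg - k$water_avg + k$proton
                   else lin_avg + k$proton
    intact <- peak_list(intact_true + stats::rnorm(1L, 0, intact_sigma),
                        1, "intact_maldi")
    list(fragments = frag, intact = intact,
         provenance = data.frame(
           mz = c(mz, decoys),
           origin = c(origin, rep("decoy", n_decoy)),
           stringsAsFactors = FALSE))
  })
}
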