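# Defaults for the expression cassette. The promoter and terminator
# segments are the constant regions of the T7 PCR primers used for
# linear expression templates; both are overridable everywhere.
T7_PROMOTER <- "GCGAATTAATACGACTCACTATAGGG"
T7_TERMINATOR <- "CTAGCATAACCCCTCTCTAAACGGAGGGGTTT"

# Canonical E. coli SsrA degradation tag.
SSRA_TAG <- "AANDENYALAA"

#' Open a circular peptide at a chosen split position
#'
#' Returns the rotation of the circular core that starts at
#' `split_position`; the result is linear and ends at the residue
#' preceding the split (wrapping). Split position 1 is the identity on
#' residue order.
#'
#' @param core Circular [residue_seq].
#' @param split_position 1-based position on the core chosen as the
#'   new linear N-terminus.
#' @return Linear [residue_seq].
#' @examples
#' circular_permute(residue_seq("LATNW", "circular"), 3)
#' @export
circular_permute <- function(core, split_position) {
  core <- as_residue_seq(core)
  if (!is_circular(core))
    stop("`core` must have circular topology", call. = FALSE)
  n <- seq_length(core)
  if (!is.numeric(split_position) || length(split_position) != 1L ||
      split_position < 1L || split_position > n ||
      split_position != as.integer(split_position))
    stop(sprintf("split_position must be an integer in 1..%d", n),
         call. = FALSE)
  k <- as.integer(split_position)
  s <- core$residues
  rotated <- paste0(substring(s, k), substring(s, 1L, k - 1L))
  residue_seq(rotated, "linear")
}

#' Load a split-intein pair from a YAML config
#'
#' The SIML design needs the C-intein (IntC) and N-intein (IntN)
#' amino-acid sequences of a naturally split intein such as Npu DnaE.
#' These are configuration inputs: the package ships a file of short
#' synthetic placeholder sequences (clearly named as such) that
#' exercises the construct logic; substitute the real intein
#' sequences from a curated source for actual synthesis orders.
#'
#' @param path YAML file with keys `int_c` and `int_n` (defaults to
#'   the bundled synthetic placeholders).
#' @return List with `int_c` and `int_n` strings.
#' @export
load_intein_pair <- function(path = NULL) {
  path <- path %||% system.file("extdata", "inteins_synthetic.yaml",
                                package = "circbact")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$int_c) || is.null(cfg$int_n))
    stop("intein config must define `int_c` and `int_n` (see ",
         "inst/extdata/inteins_synthetic.yaml)", call. = FALSE)
  lapply(cfg[c("int_c", "int_n")], function(s) residue_seq(s)$residues)
}

#' Assemble a split-intein-mediated-ligation (SIML) fusion protein
#'
#' Orders the parts IntC, circularly permuted core, IntN, degradation
#' tag: on trans-splicing the intein halves excise themselves and
#' ligate the permuted core's ends, regenerating the head-to-tail
#' circle; the SsrA tag marks unspliced product for degradation.
#'
#' @param core Circular [residue_seq] of the mature bacteriocin.
#' @param split_position Position opened as the linear N-terminus
#'   (the paper-style S37 / S8 choice is expressed in the core's own
#'   1-based numbering).
#' @param intein_pair List with `int_c`, `int_n` ([load_intein_pair]).
#' @param tag C-terminal degradation tag; `NULL` or `""` disables it.
#' @return A `siml_design` object: list with `core`, `split_position`,
#'   `permuted_core`, `parts` (named, ordered) and `protein`.
#' @export
build_siml_protein <- function(core, split_position,
                               intein_pair = load_intein_pair(),
                               tag = SSRA_TAG) {
  if (is.null(intein_pair$int_c) || is.null(intein_pair$int_n))
    stop("intein_pair must provide `int_c` and `int_n`", call. = FALSE)
  core <- as_residue_seq(core)
  permuted <- circular_permute(core, split_position)
  parts <- list(int_c = intein_pair$int_c,
                permuted_core = permuted$residues,
                int_n = intein_pair$int_n)
  if (!is.null(tag) && nzchar(tag)) parts$ssra_tag <- tag
  protein <- residue_seq(paste(unlist(parts), collapse = ""))
  structure(list(core = core, split_position = as.integer(split_position),
                 permuted_core = permuted, parts = parts,
                 protein = protein),
            class = "siml_design")
}

#' @export
print.siml_design <- function(x, ...) {
  cat(sprintf(
    "<siml_design: split %d, core %d aa, fusion %d aa (%s)>\n",
    x$split_position, seq_length(x$core), seq_length(x$protein),
    paste(names(x$parts), collapse = " + ")))
  invisible(x)
}

#' Read a codon-usage table
#'
#' Plain-text format: one `codon amino_acid frequency` triple per
#' line, `#` comments allowed; frequencies are per-amino-acid relative
#' usage and are renormalized to sum to one. A bundled Escherichia
#' coli K-12 usage table is the default.
#'
#' @param path Table file (default: bundled E. coli table).
#' @return A `codon_usage` object: list of data frames (codon,
#'   frequency) keyed by amino-acid one-letter code plus `*` for stop.
#' @export
read_codon_usage <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ecoli_codon_usage.txt",
                                package = "circbact")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  df <- data.frame(codon = toupper(vapply(parts, `[`, "", 1L)),
                   aa = toupper(vapply(parts, `[`, "", 2L)),
                   freq = as.numeric(vapply(parts, `[`, "", 3L)),
                   stringsAsFactors = FALSE)
  tab <- split(df[c("codon", "freq")], df$aa)
  tab <- lapply(tab, function(d) {
    d$freq <- d$freq / sum(d$freq)
    d[order(-d$freq, d$codon), , drop = FALSE]
  })
  missing <- setdiff(c(AA_ALPHABET, "*"), names(tab))
  if (length(missing))
    stop("codon table lacks entries for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(tab, class = "codon_usage")
}

#' Reverse-translate a protein using a codon-usage table
#'
#' `"max_frequency"` always picks the organism's most-used codon
#' (deterministic); `"weighted"` samples codons proportionally to
#' usage, reproducibly for a given seed. The round trip
#' `translate(reverse_translate(p)) == p` holds for both strategies.
#'
#' @param protein Protein string or [residue_seq].
#' @param table A `codon_usage` table ([read_codon_usage]).
#' @param strategy `"max_frequency"` (default) or `"weighted"`.
#' @param seed Integer seed for the weighted strategy.
#' @return Nucleotide string, length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, table = read_codon_usage(),
                              strategy = c("max_frequency", "weighted"),
                              seed = 1L) {
  strategy <- match.arg(strategy)
  chars <- seq_chars(as_residue_seq(protein))
  miss <- setdiff(unique(chars), names(table))
  if (length(miss))
    stop("residues absent from codon table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (strategy == "max_frequency") {
    codons <- vapply(chars, function(a) table[[a]]$codon[1L], "")
  } else {
    codons <- withr_seed(seed, vapply(chars, function(a) {
      d <- table[[a]]
      sample(d$codon, 1L, prob = d$freq)
    }, ""))
  }
  paste(codons, collapse = "")
}

# Evaluate expr under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Translate a coding DNA string (standard code)
#'
#' @param dna Nucleotide string, length divisible by 3; a trailing
#'   stop codon is dropped.
#' @return Protein string.
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  if (nchar(dna) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  tab <- codon_table()
  pos <- seq(1L, nchar(dna) - 2L, by = 3L)
  aa <- unname(tab[substring(dna, pos, pos + 2L)])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

check_no_internal_stop <- function(coding) {
  pos <- seq(1L, nchar(coding) - 2L, by = 3L)
  codons <- substring(coding, pos, pos + 2L)
  bad <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(bad))
    stop(sprintf("in-frame stop codon %s at codon %d", codons[bad[1L]],
                 bad[1L]), call. = FALSE)
  invisible(NULL)
}

#' Build an annotated T7 expression cassette
#'
#' Flanks a coding sequence with the T7 promoter and terminator,
#' prepending ATG and appending TAA where absent, and emits an
#' annotated record writable as GenBank via [write_genbank], with one
#' CDS feature spanning start to stop.
#'
#' @param coding_dna Coding sequence (length divisible by 3, no
#'   in-frame stop).
#' @param promoter,terminator Flanking segments (package defaults are
#'   the primer constant regions).
#' @param locus Record name.
#' @return An `expression_cassette`: list with `sequence` and
#'   `features` (promoter, CDS, terminator, 1-based inclusive).
#' @export
build_expression_cassette <- function(coding_dna, promoter = T7_PROMOTER,
                                      terminator = T7_TERMINATOR,
                                      locus = "cassette") {
  coding_dna <- toupper(coding_dna)
  if (nchar(coding_dna) %% 3L != 0L)
    stop("coding sequence length must be divisible by 3", call. = FALSE)
  if (!startsWith(coding_dna, "ATG")) coding_dna <- paste0("ATG", coding_dna)
  check_no_internal_stop(coding_dna)
  coding_dna <- paste0(coding_dna, "TAA")
  seqs <- paste0(promoter, coding_dna, terminator)
  np <- nchar(promoter); nc <- nchar(coding_dna)
  features <- list(
    list(key = "regulatory", start = 1L, end = np, strand = "+",
         qualifiers = c(regulatory_class = "promoter",
                        note = "T7 promoter")),
    list(key = "CDS", start = np + 1L, end = np + nc, strand = "+",
         qualifiers = c(product = "SIML fusion",
                        translation = translate_dna(coding_dna))),
    list(key = "regulatory", start = np + nc + 1L,
         end = nchar(seqs), strand = "+",
         qualifiers = c(regulatory_class = "terminator",
                        note = "T7 terminator")))
  structure(list(locus = locus, sequence = seqs, features = features),
            class = c("expression_cassette", "list"))
}

#' Design a linear T7 PCR expression template
#'
#' Reverse-translates the target protein, assembles the amplicon
#' `promoter + ATG + coding + TAA + terminator`, and derives the PCR
#' primers: forward = promoter + ATG + the first `primer_core_len`
#' coding nucleotides; reverse = reverse complement of (last
#' `primer_core_len` coding nucleotides + TAA + terminator). The
#' forward primer is an exact prefix of the amplicon and the reverse
#' complement of the reverse primer an exact suffix.
#'
#' @param protein Target mature peptide (string or [residue_seq]).
#' @param table Codon-usage table.
#' @param promoter,terminator Constant flanks.
#' @param primer_core_len Number of target-specific coding
#'   nucleotides per primer (default 24).
#' @return A `linear_t7_template`: list with `protein`, `coding`,
#'   `amplicon`, `forward_primer`, `reverse_primer`.
#' @export
build_linear_t7_template <- function(protein, table = read_codon_usage(),
                                     promoter = T7_PROMOTER,
                                     terminator = T7_TERMINATOR,
                                     primer_core_len = 24L) {
  protein <- as_residue_seq(protein)
  if (seq_length(protein) * 3L < primer_core_len)
    stop("protein too short for the requested primer core length",
         call. = FALSE)
  coding <- reverse_translate(protein, table, "max_frequency")
  check_no_internal_stop(coding)
  amplicon <- paste0(promoter, "ATG", coding, "TAA", terminator)
  fwd <- paste0(promoter, "ATG", substr(coding, 1L, primer_core_len))
  tail <- paste0(substr(coding, nchar(coding) - primer_core_len + 1L,
                        nchar(coding)), "TAA", terminator)
  rev <- revcomp(tail)
  structure(list(protein = protein, coding = coding, amplicon = amplicon,
                 forward_primer = fwd, reverse_primer = rev),
            class = "linear_t7_template")
}
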