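# Codon -> amino acid lookup (standard code); bacterial initiation is
# handled by forcing the first residue of an ORF to M.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
}

revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Find open reading frames on both strands
#'
#' Scans all six frames for maximal ORFs starting at ATG, GTG or TTG
#' and ending at a standard stop codon. Coordinates are 1-based
#' inclusive on the input strand and include the stop codon; the
#' bacterial initiator is translated as M regardless of start codon.
#' ORFs whose span contains an N are rejected.
#'
#' @param dna Nucleotide string over A, C, G, T, N.
#' @param min_len Minimum protein length in residues (default 10).
#' @param contig Contig id recorded on each feature.
#' @return Data frame of gene features: `id`, `contig`, `start`, `end`,
#'   `strand`, `protein`, `annotation`, `role` (initially `"unknown"`).
#' @examples
#' find_orfs("ATGGGTAAATAA", min_len = 1)
#' @export
find_orfs <- function(dna, min_len = 10L, contig = "contig1") {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("non-nucleotide character in input sequence", call. = FALSE)
  tab <- codon_table()
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  scan_strand <- function(s, strand, n_input) {
    n <- nchar(s)
    res <- list()
    for (frame in 0:2) {
      pos <- seq(frame + 1L, n - 2L, by = 3L)
      codons <- substring(s, pos, pos + 2L)
      open_at <- NA_integer_  # index into `pos` of current ORF start
      for (i in seq_along(codons)) {
        cd <- codons[i]
        if (is.na(open_at) && cd %in% starts) open_at <- i
        if (!is.na(open_at) && cd %in% stops) {
          a <- pos[open_at]; b <- pos[i] + 2L
          aa_len <- i - open_at  # residues excluding stop
          if (aa_len >= min_len) {
            cds <- codons[open_at:(i - 1L)]
            if (!any(grepl("N", cds, fixed = TRUE))) {
              prot <- paste(tab[cds], collapse = "")
              substr(prot, 1L, 1L) <- "M"
              se <- if (strand == "+") c(a, b)
                    else c(n_input - b + 1L, n_input - a + 1L)
              res[[length(res) + 1L]] <- data.frame(
                start = se[1L], end = se[2L], strand = strand,
                protein = prot, stringsAsFactors = FALSE)
            }
          }
          open_at <- NA_integer_
        }
      }
    }
    res
  }
  n <- nchar(dna)
  hits <- c(scan_strand(dna, "+", n), scan_strand(revcomp(dna), "-", n))
  if (!length(hits)) {
    return(gene_features(data.frame(start = integer(), end = integer(),
                                    strand = character(),
                                    protein = character(),
                                    stringsAsFactors = FALSE), contig))
  }
  df <- do.call(rbind, hits)
  df <- df[order(df$start, df$end), , drop = FALSE]
  gene_features(df, contig)
}

gene_features <- function(df, contig = "contig1") {
  n <- nrow(df)
  out <- data.frame(
    id = if (n) sprintf("orf_%03d", seq_len(n)) else character(),
    contig = rep_len(contig, n),
    start = as.integer(df$start), end = as.integer(df$end),
    strand = as.character(df$strand), protein = as.character(df$protein),
    annotation = if ("annotation" %in% names(df)) df$annotation
                 else rep_len("", n),
    role = rep_len("unknown", n),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
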