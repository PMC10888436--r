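blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

align_pair <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 1,
    type = if (mode == "global") "global" else "local")
}

#' Percent identity between two protein sequences
#'
#' BLOSUM62 alignment with gap open 10 and gap extension 1. Identity is
#' identical columns over alignment columns: gap columns count in the
#' denominator for global (Needleman-Wunsch) alignments and are
#' excluded for local (Smith-Waterman) ones. Reported to one decimal.
#'
#' @param a,b Protein strings or [residue_seq] objects (linearized).
#' @param mode `"global"` (default) or `"local"`.
#' @return Percent identity, one decimal.
#' @examples
#' percent_identity("AAAA", "AATA")  # 75.0
#' @export
percent_identity <- function(a, b, mode = c("global", "local")) {
  mode <- match.arg(mode)
  a <- as_residue_seq(a)$residues; b <- as_residue_seq(b)$residues
  pa <- align_pair(a, b, mode)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  ident <- sum(p == s & p != "-")
  denom <- if (mode == "global") length(p) else sum(p != "-" & s != "-")
  round(100 * ident / denom, 1)
}

#' Bundled reference panel of bacteriocin sequences
#'
#' Mature circular-bacteriocin cores and linear bacteriocins used as
#' homology anchors by the miner. Enterocin AS-48 is the public mature
#' sequence; the remaining entries are synthetic stand-ins (marked
#' `_synthetic` in their names and stored in files named accordingly)
#' constructed to carry the family's hallmark features, and can be
#' replaced by user-supplied FASTA files.
#'
#' @param circular_fasta,linear_fasta Optional paths to replacement
#'   FASTA files.
#' @return List with elements `circular` and `linear`, each a named
#'   character vector of sequences.
#' @export
reference_panel <- function(circular_fasta = NULL, linear_fasta = NULL) {
  cf <- circular_fasta %||% system.file("extdata",
          "reference_cores_synthetic.fasta", package = "circbact")
  lf <- linear_fasta %||% system.file("extdata",
          "reference_linear_synthetic.fasta", package = "circbact")
  read_fa <- function(path) {
    x <- Biostrings::readAAStringSet(path)
    out <- as.character(x)
    names(out) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
    out
  }
  panel <- list(circular = read_fa(cf), linear = read_fa(lf))
  for (s in c(panel$circular, panel$linear)) residue_seq(s)  # validate
  panel
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Classify the functional role of a gene feature
#'
#' Deterministic cascade: (1) case-insensitive annotation keywords
#' (SpoIIM/DUF95, ABC/ATP-binding, immunity); (2) sequence heuristics
#' when the annotation is silent -- a Walker A motif
#' (`[AG]xxxxGK[ST]`) with a downstream Walker B (`hhhhD`) marks an
#' ATP-binding protein; Kyte-Doolittle transmembrane segment counts
#' and length windows separate membrane, SpoIIM/DUF95-like and
#' immunity candidates; (3) otherwise `"unknown"`. Precursors are
#' assigned only by [find_precursor_candidates], never here.
#'
#' @param protein Protein string or [residue_seq].
#' @param annotation Free-text product/note annotation (may be empty).
#' @return One of `"spoIIM_duf95"`, `"abc_atp_binding"`, `"immunity"`,
#'   `"membrane"`, `"unknown"`.
#' @export
classify_gene_role <- function(protein, annotation = "") {
  ann <- tolower(annotation %||% "")
  if (grepl("spoiim|duf95|sporulation protein m", ann)) return("spoIIM_duf95")
  if (grepl("abc|atp-binding", ann)) return("abc_atp_binding")
  if (grepl("immunity", ann)) return("immunity")
  p <- as_residue_seq(protein)$residues
  len <- nchar(p)
  walker_a <- grepl("[AG].{4}GK[ST]", p)
  if (walker_a) {
    a_end <- attr(regexpr("[AG].{4}GK[ST]", p), "match.length") +
      regexpr("[AG].{4}GK[ST]", p) - 1L
    walker_b <- grepl("[ILVFM]{4}D", substr(p, a_end + 1L, len))
    if (walker_b) return("abc_atp_binding")
  }
  tm <- tm_segment_count(p)
  if (tm >= 4L && len >= 150L && len <= 400L && ann == "")
    return("spoIIM_duf95")
  if (tm >= 2L && len >= 100L && len <= 250L) return("membrane")
  if (len <= 150L && tm >= 1L && tm <= 2L) return("immunity")
  "unknown"
}

#' Construct a precursor maturation model
#'
#' A precursor is the linear translation product; the leader is its
#' N-terminal `leader_len` residues, removed during maturation; the
#' remainder is the mature core, carried with circular topology
#' because maturation closes it head-to-tail.
#'
#' @param precursor Linear precursor string or [residue_seq].
#' @param leader_len Leader length in residues (0 <= leader_len <
#'   precursor length).
#' @param source_id Id of the genomic feature the model derives from.
#' @param homology_support List with `name` and `identity` of the best
#'   reference-panel hit (optional).
#' @param low_confidence Set when the terminal-residue rule
#'   (N-terminus L/V/W, C-terminus W/Y/F) is not met.
#' @return A `precursor_model` object.
#' @export
precursor_model <- function(precursor, leader_len, source_id = NA_character_,
                            homology_support = NULL,
                            low_confidence = FALSE) {
  precursor <- as_residue_seq(precursor)
  n <- seq_length(precursor)
  leader_len <- as.integer(leader_len)
  if (leader_len < 0L || leader_len >= n)
    stop("leader_len must satisfy 0 <= leader_len < precursor length",
         call. = FALSE)
  core_str <- substr(precursor$residues, leader_len + 1L, n)
  core <- residue_seq(core_str, "circular")
  if (!low_confidence) {
    first <- substr(core_str, 1L, 1L)
    last <- substr(core_str, nchar(core_str), nchar(core_str))
    if (!(first %in% c("L", "V", "W")) || !(last %in% c("W", "Y", "F")))
      stop(sprintf(
        "core termini %s...%s violate the circular-bacteriocin terminal rule",
        first, last), call. = FALSE)
  }
  structure(list(precursor = precursor, leader_len = leader_len,
                 core = core, source_id = source_id,
                 homology_support = homology_support,
                 low_confidence = low_confidence),
            class = "precursor_model")
}

#' @export
print.precursor_model <- function(x, ...) {
  hs <- if (is.null(x$homology_support)) ""
        else sprintf(" [%s, %.1f%% id]", x$homology_support$name,
                     x$homology_support$identity)
  cat(sprintf("<precursor_model: %d aa precursor = %d leader + %d core%s%s>\n",
              seq_length(x$precursor), x$leader_len, seq_length(x$core),
              hs, if (x$low_confidence) " (low confidence)" else ""))
  invisible(x)
}

#' Predict circular-bacteriocin precursors by panel homology
#'
#' Every protein of length 40-150 is aligned locally (Smith-Waterman,
#' BLOSUM62, gap 10/1) against each circular reference core. A hit
#' with identity at least `min_identity` percent over at least half
#' the panel core defines the putative core start at the first aligned
#' precursor position; boundaries are then snapped to the family's
#' terminal-residue rule (N-terminal L/V/W within 3 residues of the
#' aligned start; C-terminal W/Y/F at or within 3 residues of the
#' precursor C-terminus). Candidates that cannot be snapped are kept
#' only when `strict_termini = FALSE`, flagged low-confidence.
#'
#' @param features Gene-feature data frame ([find_orfs] /
#'   [read_genome_features]).
#' @param panel Output of [reference_panel].
#' @param min_identity Minimum local percent identity (default 30).
#' @param min_coverage Minimum fraction of the panel core covered
#'   (default 0.5).
#' @param strict_termini Drop candidates violating the terminal rule
#'   (default TRUE).
#' @return List of `precursor_model` objects.
#' @export
find_precursor_candidates <- function(features, panel = reference_panel(),
                                      min_identity = 30,
                                      min_coverage = 0.5,
                                      strict_termini = TRUE) {
  if (is.null(features) || nrow(features) == 0L)
    stop("`features` is empty", call. = FALSE)
  if (!length(panel$circular))
    stop("reference panel has no circular cores", call. = FALSE)
  out <- list()
  for (r in seq_len(nrow(features))) {
    prot <- features$protein[r]
    len <- nchar(prot)
    if (len < 40L || len > 150L) next
    best <- NULL
    for (nm in names(panel$circular)) {
      ref <- panel$circular[[nm]]
      pa <- align_pair(prot, ref, "local")
      cov <- nchar(gsub("-", "", as.character(
        Biostrings::alignedSubject(pa)))) / nchar(ref)
      if (cov < min_coverage) next
      idt <- percent_identity(prot, ref, "local")
      if (idt < min_identity) next
      if (is.null(best) || idt > best$identity)
        best <- list(name = nm, identity = idt,
                     aln_start = Biostrings::start(Biostrings::pattern(pa)))
    }
    if (is.null(best)) next
    cand <- snap_core_boundaries(prot, best$aln_start)
    if (is.null(cand)) {
      if (strict_termini) next
      out[[length(out) + 1L]] <- precursor_model(
        prot, best$aln_start - 1L, features$id[r],
        best[c("name", "identity")], low_confidence = TRUE)
      next
    }
    if (cand$core_end < len) next  # C-terminal overhang: not modelled
    out[[length(out) + 1L]] <- precursor_model(
      prot, cand$core_start - 1L, features$id[r],
      best[c("name", "identity")])
  }
  out
}

# Snap (core_start, core_end) to the terminal-residue rule. Returns NULL
# when no admissible snap exists.
snap_core_boundaries <- function(prot, aln_start) {
  len <- nchar(prot)
  chars <- strsplit(prot, "")[[1L]]
  cand_n <- aln_start + c(0L, -1L, 1L, -2L, 2L, -3L, 3L)
  cand_n <- cand_n[cand_n >= 1L & cand_n <= len]
  core_start <- NA_integer_
  for (p in cand_n) if (chars[p] %in% c("L", "V", "W")) {
    core_start <- p; break
  }
  if (is.na(core_start)) return(NULL)
  cand_c <- len - 0:3
  cand_c <- cand_c[cand_c > core_start]
  core_end <- NA_integer_
  for (p in cand_c) if (chars[p] %in% c("W", "Y", "F")) {
    core_end <- p; break
  }
  if (is.na(core_end)) return(NULL)
  list(core_start = core_start, core_end = core_end)
}

#' Call bacteriocin gene clusters from classified features
#'
#' One cluster call per predicted circular precursor, its span
#' extended to every feature within `window` bp of the precursor gene;
#' the completeness score counts the distinct context roles
#' (SpoIIM/DUF95, ABC ATP-binding, membrane) found in the span.
#' Proteins matching a linear panel entry at `linear_min_identity`
#' percent local identity are additionally reported as
#' closticin-type linear candidates that carry no cyclization claim.
#'
#' @inheritParams find_precursor_candidates
#' @param window Neighbourhood distance in bp (default 6000).
#' @param linear_min_identity Identity threshold for linear candidates
#'   (default 40).
#' @return List of `cluster_call` objects, sorted by contig then start.
#' @export
call_clusters <- function(features, panel = reference_panel(),
                          window = 6000L, min_identity = 30,
                          linear_min_identity = 40,
                          strict_termini = TRUE) {
  features <- features[order(features$contig, features$start), , drop = FALSE]
  rownames(features) <- NULL
  for (r in seq_len(nrow(features))) {
    if (features$role[r] == "unknown")
      features$role[r] <- classify_gene_role(features$protein[r],
                                             features$annotation[r])
  }
  models <- tryCatch(
    find_precursor_candidates(features, panel, min_identity,
                              strict_termini = strict_termini),
    error = function(e) list())
  calls <- list()
  for (pm in models) {
    idx <- match(pm$source_id, features$id)
    f <- features[idx, ]
    same <- features[features$contig == f$contig, , drop = FALSE]
    near <- same[pmax(same$start, f$start) - pmin(same$end, f$end) <=
                   window, , drop = FALSE]
    features$role[features$id == pm$source_id] <- "precursor"
    near$role[near$id == pm$source_id] <- "precursor"
    ctx <- intersect(unique(near$role),
                     c("spoIIM_duf95", "abc_atp_binding", "membrane"))
    calls[[length(calls) + 1L]] <- structure(
      list(contig = f$contig, span = c(min(near$start), max(near$end)),
           genes = near, precursor_model = pm,
           completeness = length(ctx), type = "circular"),
      class = "cluster_call")
  }
  # closticin-type linear candidates
  if (length(panel$linear)) {
    for (r in seq_len(nrow(features))) {
      prot <- features$protein[r]
      if (nchar(prot) < 40L || nchar(prot) > 400L) next
      if (features$role[r] == "precursor") next
      for (nm in names(panel$linear)) {
        idt <- percent_identity(prot, panel$linear[[nm]], "local")
        cov <- {
          pa <- align_pair(prot, panel$linear[[nm]], "local")
          nchar(gsub("-", "", as.character(
            Biostrings::alignedSubject(pa)))) / nchar(panel$linear[[nm]])
        }
        if (idt >= linear_min_identity && cov >= 0.5) {
          f <- features[r, ]
          features$role[r] <- "bacteriocin_like_linear"
          g <- f; g$role <- "bacteriocin_like_linear"
          calls[[length(calls) + 1L]] <- structure(
            list(contig = f$contig, span = c(f$start, f$end),
                 genes = g, precursor_model = NULL,
                 completeness = 0L, type = "linear_like"),
            class = "cluster_call")
          break
        }
      }
    }
  }
  if (length(calls) > 1L) {
    o <- order(vapply(calls, function(x) x$contig, ""),
               vapply(calls, function(x) x$span[1L], numeric(1)))
    calls <- calls[o]
  }
  calls
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf("<cluster_call %s %s:%d-%d, %d genes, completeness %d>\n",
              x$type, x$contig, x$span[1L], x$span[2L], nrow(x$genes),
              x$completeness))
  invisible(x)
}

#' Read gene features from a genome file
#'
#' GenBank flat files contribute their annotated CDS features
#' (coordinates, strand, product text, translation); plain FASTA
#' triggers de novo ORF finding via [find_orfs].
#'
#' @param path Genome file (GenBank `.gb`/`.gbk` or FASTA).
#' @param min_len Minimum ORF length for FASTA input (default 50).
#' @return Gene-feature data frame.
#' @export
read_genome_features <- function(path, min_len = 50L) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "LOCUS")) return(read_genbank_features(path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(seqs)) {
    contig <- strsplit(names(seqs)[i], "\\s+")[[1L]][1L]
    out[[i]] <- find_orfs(as.character(seqs[[i]]), min_len, contig)
  }
  df <- do.call(rbind, out)
  df$id <- sprintf("orf_%04d", seq_len(nrow(df)))
  df
}
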