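#' Protease cleavage rule
#'
#' Cleavage occurs after a residue in `cleave_after` unless the next
#' residue (wrapping circularly for circular substrates) is in
#' `blocked_by_next`. The default is trypsin: after K or R, blocked by
#' a following proline.
#'
#' @param name Rule name.
#' @param cleave_after Character vector of residues cut C-terminally.
#' @param blocked_by_next Residues that suppress cleavage when next.
#' @export
protease_rule <- function(name = "trypsin", cleave_after = c("K", "R"),
                          blocked_by_next = "P") {
  cleave_after <- toupper(cleave_after)
  blocked_by_next <- toupper(blocked_by_next)
  stopifnot(all(cleave_after %in% AA_ALPHABET),
            all(blocked_by_next %in% AA_ALPHABET))
  structure(list(name = name, cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next),
            class = "protease_rule")
}

#' Cleavage sites of a protease on a linear or circular sequence
#'
#' Returns 1-based positions `p` such that the bond after residue `p`
#' is cut. For circular topology the successor of position `n` is
#' position 1, so position `n` is eligible and its blocking residue is
#' residue 1.
#'
#' @param seq A [residue_seq] or string (linear).
#' @param rule A [protease_rule].
#' @return Sorted integer vector of cleavage positions.
#' @examples
#' cleavage_sites("AKPGR", protease_rule())          # 5 (K2 blocked by P3)
#' cleavage_sites(residue_seq("ACKDEFRGH", "circular"), protease_rule())
#' @export
cleavage_sites <- function(seq, rule = protease_rule()) {
  seq <- as_residue_seq(seq)
  chars <- seq_chars(seq)
  n <- length(chars)
  sites <- integer(0)
  for (p in seq_len(n)) {
    if (!(chars[p] %in% rule$cleave_after)) next
    nxt <- if (p < n) chars[p + 1L]
           else if (is_circular(seq)) chars[1L]
           else NA_character_
    if (!is.na(nxt) && nxt %in% rule$blocked_by_next) next
    sites <- c(sites, p)
  }
  sites
}

digest_frame <- function(sequence = character(), start = integer(),
                         length = integer(), missed = integer(),
                         junction = logical(), specificity = character(),
                         parent) {
  out <- data.frame(sequence = sequence, start = as.integer(start),
                    length = as.integer(length), missed = as.integer(missed),
                    junction = junction, specificity = specificity,
                    stringsAsFactors = FALSE)
  attr(out, "parent_length") <- seq_length(parent)
  attr(out, "parent_topology") <- as_residue_seq(parent)$topology
  class(out) <- c("digest_peptides", "data.frame")
  out
}

order_digest <- function(df) {
  o <- order(df$start, df$length)
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico digestion of a linear peptide
#'
#' Enumerates all fragments between consecutive cleavage sites and all
#' joins of up to `max_missed` adjacent fragments, in deterministic
#' order (by start, then length).
#'
#' @param seq Linear [residue_seq] or string.
#' @param rule A [protease_rule].
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return A `digest_peptides` data frame with columns `sequence`,
#'   `start`, `length`, `missed`, `junction` (always `FALSE` here) and
#'   `specificity` (`"full"`).
#' @export
digest_linear <- function(seq, rule = protease_rule(), max_missed = 2L) {
  seq <- as_residue_seq(seq)
  if (is_circular(seq))
    stop("digest_linear requires linear topology; use digest_circular",
         call. = FALSE)
  chars <- seq_chars(seq)
  n <- length(chars)
  bounds <- unique(c(0L, cleavage_sites(seq, rule), n))
  k <- length(bounds) - 1L  # number of non-empty pieces
  seqs <- character(); starts <- integer(); lens <- integer(); mis <- integer()
  for (i in seq_len(k)) {
    for (m in 0:max_missed) {
      j <- i + m + 1L
      if (j > k + 1L) break
      a <- bounds[i] + 1L
      b <- bounds[j]
      seqs <- c(seqs, paste(chars[a:b], collapse = ""))
      starts <- c(starts, a)
      lens <- c(lens, b - a + 1L)
      mis <- c(mis, m)
    }
  }
  order_digest(digest_frame(seqs, starts, lens, mis,
                            rep(FALSE, length(seqs)),
                            rep("full", length(seqs)), seq))
}

#' In-silico digestion of a head-to-tail circular peptide
#'
#' Enumerates tryptic (or other protease) fragments of a circular core
#' over the doubled sequence, restricted to fragments of length at most
#' `n` starting in the first copy. Fragments that wrap the covalent
#' n-to-1 junction carry `junction = TRUE`; their detection in a real
#' digest is direct evidence of circularity. A core with no cleavage
#' site at all is returned as a single undigestible record flagged as
#' junction-spanning. Repeated sequences arising from sequence repeats
#' are retained as distinct records (distinct `start`).
#'
#' @param core Circular [residue_seq].
#' @inheritParams digest_linear
#' @return A `digest_peptides` data frame (see [digest_linear]); `start`
#'   is 1-based on the core and a fragment wraps iff
#'   `start + length - 1 > n`.
#' @examples
#' digest_circular(residue_seq("ACKDEFRGH", "circular"), max_missed = 0)
#' @export
digest_circular <- function(core, rule = protease_rule(), max_missed = 2L) {
  core <- as_residue_seq(core)
  if (!is_circular(core))
    stop("digest_circular requires circular topology; use digest_linear",
         call. = FALSE)
  chars <- seq_chars(core)
  n <- length(chars)
  sites <- cleavage_sites(core, rule)
  if (length(sites) == 0L) {
    return(digest_frame(core$residues, 1L, n, 0L, TRUE, "full", core))
  }
  doubled <- c(chars, chars)
  k <- length(sites)
  seqs <- character(); starts <- integer(); lens <- integer(); mis <- integer()
  for (i in seq_len(k)) {
    start <- sites[i] %% n + 1L  # first residue after the cut, wrapped
    for (m in 0:max_missed) {
      if (m + 1L > k) break     # joining all k pieces already spans the core
      endsite <- sites[(i + m) %% k + 1L]
      len <- (endsite - start) %% n + 1L
      seqs <- c(seqs, paste(doubled[start:(start + len - 1L)], collapse = ""))
      starts <- c(starts, start)
      lens <- c(lens, len)
      mis <- c(mis, m)
    }
  }
  junction <- starts + lens - 1L > n
  order_digest(digest_frame(seqs, starts, lens, mis, junction,
                            rep("full", length(seqs)), core))
}

#' Digest dispatching on topology
#'
#' @inheritParams digest_linear
#' @export
digest <- function(seq, rule = protease_rule(), max_missed = 2L) {
  seq <- as_residue_seq(seq)
  if (is_circular(seq)) digest_circular(seq, rule, max_missed)
  else digest_linear(seq, rule, max_missed)
}

#' Semi-specific expansion of a fully-specific digest
#'
#' For every fully-specific peptide, adds all prefixes and suffixes of
#' length at least `min_len` with `specificity = "semi"`. These model
#' the ragged, single-tryptic-terminus fragments that de novo
#' sequencing recovers alongside fully tryptic ones. The
#' junction-spanning flag is recomputed from coordinates, not
#' inherited: a truncation may lose the wrap.
#'
#' @param peptides A `digest_peptides` data frame.
#' @param min_len Minimum semi-fragment length (default 6).
#' @return The input rows plus the semi-specific rows, deduplicated on
#'   (sequence, start, length, specificity).
#' @export
semi_specific_expand <- function(peptides, min_len = 6L) {
  stopifnot(inherits(peptides, "digest_peptides"))
  n <- attr(peptides, "parent_length")
  circ <- identical(attr(peptides, "parent_topology"), "circular")
  full <- peptides[peptides$specificity == "full", , drop = FALSE]
  seqs <- character(); starts <- integer(); lens <- integer(); mis <- integer()
  for (r in seq_len(nrow(full))) {
    pep <- full$sequence[r]; s0 <- full$start[r]; L <- full$length[r]
    if (L <= min_len) next
    for (l in seq(min_len, L - 1L)) {
      # prefix of length l
      seqs <- c(seqs, substr(pep, 1L, l)); starts <- c(starts, s0)
      lens <- c(lens, l); mis <- c(mis, full$missed[r])
      # suffix of length l
      s1 <- s0 + (L - l)
      if (circ) s1 <- (s1 - 1L) %% n + 1L
      seqs <- c(seqs, substr(pep, L - l + 1L, L)); starts <- c(starts, s1)
      lens <- c(lens, l); mis <- c(mis, full$missed[r])
    }
  }
  junction <- if (circ) starts + lens - 1L > n else rep(FALSE, length(starts))
  semi <- digest_frame(seqs, starts, lens, mis, junction,
                       rep("semi", length(seqs)), parent_stub(peptides))
  out <- rbind(as.data.frame(peptides), as.data.frame(semi))
  out <- out[!duplicated(out[, c("sequence", "start", "length",
                                 "specificity")]), , drop = FALSE]
  out <- out[order(out$start, out$length, out$specificity), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("parent_length", "parent_topology")] <-
    attributes(peptides)[c("parent_length", "parent_topology")]
  class(out) <- c("digest_peptides", "data.frame")
  out
}

# Minimal stand-in carrying length/topology for digest_frame attrs.
parent_stub <- function(peptides) {
  structure(list(residues = strrep("A", attr(peptides, "parent_length")),
                 topology = attr(peptides, "parent_topology")),
            class = "residue_seq")
}
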