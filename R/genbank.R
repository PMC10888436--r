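# Minimal GenBank flat-file support: enough of the format to round-trip
# the CDS features this package produces and consumes (LOCUS, FEATURES
# with location, /product, /note, /translation qualifiers, ORIGIN).
# Compound locations other than complement(a..b) are not supported.

#' Read CDS features from a GenBank flat file
#'
#' @param path GenBank file.
#' @return Gene-feature data frame (see [find_orfs]); proteins come
#'   from `/translation` qualifiers, or are translated from the origin
#'   sequence when absent.
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[grepl("^LOCUS", lines)][1L])
  # ORIGIN sequence
  oi <- which(grepl("^ORIGIN", lines))
  seqstr <- ""
  if (length(oi)) {
    end <- which(grepl("^//", lines))
    end <- if (length(end)) end[end > oi[1L]][1L] else length(lines) + 1L
    body <- lines[(oi[1L] + 1L):(end - 1L)]
    seqstr <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
  }
  fi <- which(grepl("^FEATURES", lines))
  if (!length(fi)) stop("no FEATURES section in ", path, call. = FALSE)
  stop_at <- if (length(oi)) oi[1L] else length(lines) + 1L
  block <- lines[(fi[1L] + 1L):(stop_at - 1L)]
  feats <- list()
  cur <- NULL
  flush <- function(cur) {
    if (!is.null(cur) && cur$key == "CDS") feats[[length(feats) + 1L]] <<- cur
  }
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {             # new feature
      flush(cur)
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(substring(ln, 22L))
      cur <- list(key = key, loc = loc, quals = character())
    } else if (!is.null(cur)) {
      cur$quals <- c(cur$quals, trimws(ln))
    }
  }
  flush(cur)
  parse_qual <- function(quals, name) {
    txt <- paste(quals, collapse = " ")
    pat <- sprintf('/%s="([^"]*)"', name)
    m <- regmatches(txt, regexec(pat, txt))[[1L]]
    if (length(m) == 2L) m[2L] else ""
  }
  rows <- list()
  for (f in feats) {
    strand <- if (grepl("^complement", f$loc)) "-" else "+"
    nums <- as.integer(regmatches(f$loc, gregexpr("[0-9]+", f$loc))[[1L]])
    if (length(nums) < 2L) next
    start <- min(nums); end <- max(nums)
    prot <- gsub(" ", "", parse_qual(f$quals, "translation"))
    if (prot == "" && nzchar(seqstr)) {
      cds <- substr(seqstr, start, end)
      if (strand == "-") cds <- revcomp(cds)
      prot <- translate_cds(cds)
    }
    product <- parse_qual(f$quals, "product")
    note <- parse_qual(f$quals, "note")
    ann <- trimws(paste(product, note))
    rows[[length(rows) + 1L]] <- data.frame(
      start = start, end = end, strand = strand, protein = prot,
      annotation = ann, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(gene_features(data.frame(start = integer(), end = integer(),
                                    strand = character(),
                                    protein = character(),
                                    annotation = character(),
                                    stringsAsFactors = FALSE), locus))
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end), , drop = FALSE]
  gene_features(df, locus)
}

# Translate a CDS (drops the stop codon, bacterial initiator -> M).
translate_cds <- function(cds) {
  tab <- codon_table()
  n <- nchar(cds) - nchar(cds) %% 3L
  pos <- seq(1L, n - 2L, by = 3L)
  aa <- tab[substring(cds, pos, pos + 2L)]
  aa <- aa[!is.na(aa)]
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  p <- paste(aa, collapse = "")
  if (nchar(p)) substr(p, 1L, 1L) <- "M"
  p
}

#' Write a GenBank flat file
#'
#' @param record List with `locus`, `sequence` (DNA string) and
#'   `features`: a list of lists with `key`, `start`, `end`, `strand`
#'   and a named `qualifiers` character vector.
#' @param path Output path.
#' @export
write_genbank <- function(record, path) {
  n <- nchar(record$sequence)
  out <- c(sprintf("LOCUS       %s %d bp    DNA     linear   SYN",
                   record$locus, n),
           sprintf("DEFINITION  %s.", record$definition %||% record$locus),
           "FEATURES             Location/Qualifiers")
  for (f in record$features) {
    loc <- sprintf("%d..%d", f$start, f$end)
    if (identical(f$strand, "-")) loc <- sprintf("complement(%s)", loc)
    out <- c(out, sprintf("     %-16s%s", f$key, loc))
    for (qn in names(f$qualifiers)) {
      val <- sprintf('/%s="%s"', qn, f$qualifiers[[qn]])
      # wrap at 58 chars into the 21-column qualifier field
      while (nchar(val) > 58L) {
        out <- c(out, paste0(strrep(" ", 21L), substr(val, 1L, 58L)))
        val <- substring(val, 59L)
      }
      out <- c(out, paste0(strrep(" ", 21L), val))
    }
  }
  out <- c(out, "ORIGIN")
  s <- tolower(record$sequence)
  for (i in seq(1L, n, by = 60L)) {
    chunk <- substr(s, i, min(i + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                           nchar(chunk)))
    out <- c(out, sprintf("%9d %s", i, paste(tens, collapse = " ")))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
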