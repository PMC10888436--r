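#' @keywords internal
"_PACKAGE"

# The 20 standard one-letter codes. Ambiguity codes (B, J, O, U, X, Z) are
# rejected everywhere: mass targets are exact and averaging is never safe.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid sequence with explicit topology
#'
#' The universal peptide/protein carrier of the package. A
#' `residue_seq` is a validated string over the 20 standard one-letter
#' amino-acid codes together with a topology flag. For `"circular"`
#' topology residue `n` is covalently adjacent to residue 1
#' (head-to-tail amide bond); positions are 1-based throughout.
#'
#' @param residues Single string of one-letter amino-acid codes
#'   (upper- or lower-case; stored upper-case). Ambiguity codes
#'   B, J, O, U, X, Z are rejected.
#' @param topology `"linear"` (default) or `"circular"`. Circular
#'   sequences must have length >= 2.
#' @return An object of class `residue_seq` with fields `residues`
#'   and `topology`.
#' @examples
#' residue_seq("LATNLGISR", "circular")
#' @export
residue_seq <- function(residues, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("`residues` must be a single string", call. = FALSE)
  residues <- toupper(residues)
  if (nchar(residues) == 0L)
    stop("empty residue sequence", call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("invalid residue character '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  }
  if (topology == "circular" && length(chars) < 2L)
    stop("circular topology requires length >= 2", call. = FALSE)
  structure(list(residues = residues, topology = topology),
            class = "residue_seq")
}

#' @export
print.residue_seq <- function(x, ...) {
  cat(sprintf("<residue_seq %s, %d aa>\n%s\n",
              x$topology, seq_length(x), x$residues))
  invisible(x)
}

#' @export
as.character.residue_seq <- function(x, ...) x$residues

# Coerce strings (assumed linear) and residue_seq transparently.
as_residue_seq <- function(x, topology = "linear") {
  if (inherits(x, "residue_seq")) x else residue_seq(x, topology)
}

seq_length <- function(x) nchar(as_residue_seq(x)$residues)

seq_chars <- function(x) strsplit(as_residue_seq(x)$residues, "",
                                  fixed = TRUE)[[1L]]

is_circular <- function(x) as_residue_seq(x)$topology == "circular"
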