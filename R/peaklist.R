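#' Construct a peak list
#'
#' @param mz Numeric vector of m/z values (must be positive).
#' @param intensity Numeric vector of intensities (recycled; default 1).
#' @param kind `"fragment_lcmsms"` (high-resolution fragment peaks) or
#'   `"intact_maldi"` (linear-mode intact masses).
#' @return A `peak_list` object, sorted ascending by m/z.
#' @export
peak_list <- function(mz, intensity = 1,
                      kind = c("fragment_lcmsms", "intact_maldi")) {
  kind <- match.arg(kind)
  mz <- as.numeric(mz)
  if (length(mz) && any(!is.finite(mz) | mz <= 0))
    stop("all m/z values must be positive and finite", call. = FALSE)
  intensity <- rep_len(as.numeric(intensity), length(mz))
  if (length(intensity) && any(intensity < 0))
    stop("intensities must be >= 0", call. = FALSE)
  o <- order(mz)
  structure(list(mz = mz[o], intensity = intensity[o], kind = kind),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list %s, %d peaks>\n", x$kind, length(x$mz)))
  invisible(x)
}

#' Read a peak list from text
#'
#' Accepts either plain one- or two-column text (m/z, optional
#' intensity; whitespace-, comma- or tab-separated; `#` comments
#' allowed) or a minimal MGF file (`BEGIN IONS` / peak lines /
#' `END IONS`, one or more blocks pooled).
#'
#' @param path File path.
#' @param kind Passed to [peak_list].
#' @param format `"auto"` (default), `"table"` or `"mgf"`.
#' @return A `peak_list`.
#' @export
read_peak_list <- function(path,
                           kind = c("fragment_lcmsms", "intact_maldi"),
                           format = c("auto", "table", "mgf")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto")
    format <- if (any(grepl("^BEGIN IONS", lines))) "mgf" else "table"
  if (format == "mgf") {
    inblock <- FALSE
    mz <- numeric(); int <- numeric()
    for (ln in lines) {
      ln <- trimws(ln)
      if (ln == "BEGIN IONS") { inblock <- TRUE; next }
      if (ln == "END IONS") { inblock <- FALSE; next }
      if (!inblock || ln == "" || grepl("=", ln, fixed = TRUE)) next
      parts <- strsplit(ln, "[,\t ]+")[[1L]]
      mz <- c(mz, as.numeric(parts[1L]))
      int <- c(int, if (length(parts) > 1L) as.numeric(parts[2L]) else 1)
    }
    return(peak_list(mz, int, kind))
  }
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  mz <- numeric(); int <- numeric()
  for (ln in lines) {
    parts <- strsplit(ln, "[,\t ]+")[[1L]]
    mz <- c(mz, as.numeric(parts[1L]))
    int <- c(int, if (length(parts) > 1L) as.numeric(parts[2L]) else 1)
  }
  peak_list(mz, int, kind)
}

#' Write a peak list as two-column text
#'
#' @param x A `peak_list`.
#' @param path Output path.
#' @export
write_peak_list <- function(x, path) {
  stopifnot(inherits(x, "peak_list"))
  writeLines(sprintf("%.6f\t%.6g", x$mz, x$intensity), path)
  invisible(path)
}
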