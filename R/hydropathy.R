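# Kyte-Doolittle hydropathy index.
KD_INDEX <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

#' Predict transmembrane segments by Kyte-Doolittle hydropathy
#'
#' Sliding-window mean hydropathy (window 19), positions above the
#' threshold grouped into segments, segments separated by fewer than
#' `merge_gap` positions merged, segments shorter than `min_seg`
#' dropped. Textbook settings; all configurable.
#'
#' @param protein Protein string or [residue_seq].
#' @param window Window size (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @param min_seg Minimum segment length in residues spanned (default
#'   17); a run of above-threshold window centres spans
#'   `run + window - 1` residues.
#' @param merge_gap Merge segments separated by gaps shorter than this
#'   (default 5).
#' @return Integer count of predicted transmembrane segments.
#' @export
tm_segment_count <- function(protein, window = 19L, threshold = 1.6,
                             min_seg = 17L, merge_gap = 5L) {
  chars <- seq_chars(as_residue_seq(protein))
  n <- length(chars)
  if (n < window) return(0L)
  h <- KD_INDEX[chars]
  cs <- c(0, cumsum(h))
  centre_n <- n - window + 1L
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:centre_n]) / window
  hot <- means > threshold
  if (!any(hot)) return(0L)
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- cbind(starts[r$values], ends[r$values])
  # merge segments separated by short gaps
  if (nrow(segs) > 1L) {
    merged <- segs[1L, , drop = FALSE]
    for (i in 2:nrow(segs)) {
      if (segs[i, 1L] - merged[nrow(merged), 2L] - 1L < merge_gap)
        merged[nrow(merged), 2L] <- segs[i, 2L]
      else merged <- rbind(merged, segs[i, ])
    }
    segs <- merged
  }
  sum(segs[, 2L] - segs[, 1L] + window >= min_seg)
}
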