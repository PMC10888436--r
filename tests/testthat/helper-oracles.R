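# Independent oracles and shared fixtures. Everything here is written
# without calling the package functions it is used to check.

# --- published tryptic-fragment table -------------------------------------
# sequence, theoretical MH+ (Da), number of oxidized Met, detected m/z
# (doubly protonated) for both purified fractions.
table1 <- data.frame(
  sequence = c("YAAEWLATNLGISR", "AAEWLATNLGISR", "AEWLATNLGISR",
               "YAAEWLATNLGIS", "ATNLGISR", "YAAEWLATNL", "TNLGISR",
               "WLATNLGISR", "YLKNEIK",
               "GLSLIAAAGK", "AVIAWLAK", "YLKNEIK", "YAAEWLATNLGISR",
               "LATNLGISR", "TNLGISR", "GTGLVTAAMVATAK", "ATNLGISR",
               "YAAEWLAT", "TGLVTAAMVATAK", "LVTAAMVATAK", "YAAEWLATNL"),
  mh = c(1564.8118, 1401.7484, 1330.7113, 1408.7107, 831.4682, 1151.5731,
         760.4311, 1130.6316, 907.5247,
         900.5512, 871.5400, 907.5247, 1564.8118, 944.5523, 760.4311,
         1306.7035, 831.4682, 924.4461, 1249.6820, 1091.6129, 1151.5731),
  n_ox = c(0, 0, 0, 0, 0, 0, 0, 0, 0,
           0, 0, 0, 0, 0, 0, 1, 0, 0, 1, 1, 0),
  detected_mz = c(782.9106, 701.3768, 665.8602, 704.8593, 416.2385,
                  576.2907, 380.7194, 565.8204, 454.2659,
                  450.7803, 436.2736, 454.2661, 782.9104, 472.7805,
                  380.7193, 653.8569, 416.2401, 462.7273, 625.3439,
                  546.3106, 576.2930),
  stringsAsFactors = FALSE)

# --- naive protease oracle -------------------------------------------------
# Trypsin sites by direct scan; independent of cleavage_sites().
oracle_sites <- function(chars, circular) {
  n <- length(chars)
  out <- integer()
  for (p in seq_len(n)) {
    if (!(chars[p] %in% c("K", "R"))) next
    nxt <- if (p < n) chars[p + 1L] else if (circular) chars[1L] else NA
    if (!is.na(nxt) && nxt == "P") next
    out <- c(out, p)
  }
  out
}

# Linear digest by direct piece enumeration.
oracle_linear_digest <- function(s, max_missed) {
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  cuts <- unique(c(0L, oracle_sites(chars, FALSE), n))
  cuts <- cuts[cuts <= n]
  k <- length(cuts) - 1L
  out <- list()
  for (i in seq_len(k)) for (m in 0:max_missed) {
    j <- i + m + 1L
    if (j > k + 1L) next
    a <- cuts[i] + 1L; b <- cuts[j]
    out[[length(out) + 1L]] <- data.frame(
      sequence = paste(chars[a:b], collapse = ""), start = a,
      length = b - a + 1L, missed = m, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Circular digest oracle: union over linearizations at every true
# cleavage site of that rotation's linear digest, mapped back to the
# core's coordinates; wrapped fragments are marked. A site-free core is
# one undigestible junction-spanning record.
oracle_circular_digest <- function(s, max_missed) {
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  sites <- oracle_sites(chars, TRUE)
  if (!length(sites)) {
    return(data.frame(sequence = s, start = 1L, length = n, missed = 0L,
                      junction = TRUE, stringsAsFactors = FALSE))
  }
  out <- list()
  for (scut in sites) {
    rot <- paste(chars[c(seq_len(n) + scut - 1L) %% n + 1L], collapse = "")
    ld <- oracle_linear_digest(rot, max_missed)
    for (r in seq_len(nrow(ld))) {
      cs <- (scut + ld$start[r] - 1L) %% n + 1L
      out[[length(out) + 1L]] <- data.frame(
        sequence = ld$sequence[r], start = cs, length = ld$length[r],
        missed = ld$missed[r], junction = cs + ld$length[r] - 1L > n,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df <- df[df$length <= n, , drop = FALSE]
  df <- df[!duplicated(df[, c("start", "length", "missed")]), , drop = FALSE]
  df <- df[order(df$start, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random valid amino-acid string.
rand_aa <- function(n, kr_bias = 0.15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  w <- rep((1 - kr_bias) / 18, 20)
  w[aa %in% c("K", "R")] <- kr_bias / 2
  paste(sample(aa, n, replace = TRUE, prob = w), collapse = "")
}

# Shared digest comparison: same multiset of (sequence, start, length,
# missed, junction).
expect_same_digest <- function(got, want) {
  cols <- c("sequence", "start", "length", "missed", "junction")
  g <- got[do.call(order, got[cols]), cols, drop = FALSE]
  w <- want[do.call(order, want[cols]), cols, drop = FALSE]
  rownames(g) <- rownames(w) <- NULL
  expect_equal(g, w, ignore_attr = TRUE)
}
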