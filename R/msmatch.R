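#' Match a theoretical digest against an observed fragment peak list
#'
#' Every combination of peptide, variable-modification state, and
#' charge whose theoretical m/z lies within `tol_ppm` of an observed
#' peak is reported. One observed peak may support several peptides;
#' the ambiguity is preserved. Variable methionine oxidation
#' (+15.994915 Da, at most `max_ox` per peptide) is searched when
#' `variable_mods` is `TRUE`.
#'
#' @param theoretical A `digest_peptides` data frame ([digest_circular],
#'   [digest_linear], [semi_specific_expand]).
#' @param peaks A `peak_list` of kind `"fragment_lcmsms"`.
#' @param charges Integer charge states to consider (default 1:2).
#' @param tol_ppm Match tolerance in ppm (default 20).
#' @param variable_mods Search Met oxidation as a variable modification.
#' @param max_ox Maximum oxidations per peptide (default 1).
#' @return Data frame with columns `sequence`, `start`, `junction`,
#'   `specificity`, `n_ox`, `charge`, `theoretical_mz`, `observed_mz`,
#'   `error_ppm`, sorted by absolute error.
#' @export
match_fragments <- function(theoretical, peaks, charges = c(1L, 2L),
                            tol_ppm = 20, variable_mods = TRUE,
                            max_ox = 1L) {
  if (is.null(theoretical) || nrow(theoretical) == 0L)
    stop("empty theoretical peptide set", call. = FALSE)
  stopifnot(inherits(peaks, "peak_list"))
  if (peaks$kind != "fragment_lcmsms")
    stop("fragment matching requires a fragment_lcmsms peak list",
         call. = FALSE)
  if (tol_ppm <= 0) stop("`tol_ppm` must be positive", call. = FALSE)
  shift <- mass_constants()$met_oxidation
  base <- vapply(theoretical$sequence, peptide_mass, numeric(1),
                 USE.NAMES = FALSE)
  n_met <- vapply(gregexpr("M", theoretical$sequence, fixed = TRUE),
                  function(x) sum(x > 0L), integer(1))
  # expand (peptide x oxidation-state x charge) into parallel vectors
  ox_max <- if (variable_mods) pmin(max_ox, n_met) else rep(0L, length(base))
  idx <- rep(seq_along(base), ox_max + 1L)
  n_ox <- sequence(ox_max + 1L) - 1L
  nz <- length(charges)
  idx <- rep(idx, each = nz)
  n_ox <- rep(n_ox, each = nz)
  z <- rep(as.integer(charges), times = length(idx) / nz)
  theo <- (base[idx] + n_ox * shift + z * mass_constants()$proton) / z
  # window query on the sorted peak vector
  lo <- findInterval(theo * (1 - tol_ppm * 1e-6), peaks$mz,
                     left.open = TRUE) + 1L
  hi <- findInterval(theo * (1 + tol_ppm * 1e-6), peaks$mz)
  nhit <- pmax(hi - lo + 1L, 0L)
  keep <- which(nhit > 0L)
  rows <- rep(keep, nhit[keep])
  obs_i <- unlist(lapply(keep, function(i) lo[i]:hi[i]), use.names = FALSE)
  res <- data.frame(
    sequence = theoretical$sequence[idx[rows]],
    start = theoretical$start[idx[rows]],
    junction = theoretical$junction[idx[rows]],
    specificity = theoretical$specificity[idx[rows]],
    n_ox = n_ox[rows], charge = z[rows],
    theoretical_mz = theo[rows],
    observed_mz = peaks$mz[obs_i],
    error_ppm = ppm_error(peaks$mz[obs_i], theo[rows]),
    stringsAsFactors = FALSE)
  res <- res[abs(res$error_ppm) <= tol_ppm, , drop = FALSE]
  res <- res[order(abs(res$error_ppm), res$sequence, res$charge), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Intact-mass dehydration check against a MALDI peak list
#'
#' Tests whether an intact (linear-mode MALDI) peak list contains the
#' singly-protonated head-to-tail cyclized species: expected observed
#' mass is the deduced linear average mass minus one average water
#' (the amide-bond closure) plus one proton. The non-dehydrated linear
#' [M+H]+ hypothesis is evaluated alongside, so that a later verdict
#' can distinguish "circular", "still linear" and "no evidence".
#'
#' Average masses and a Dalton-scale tolerance are used because
#' linear-mode MALDI of intact peptides is calibrated far more coarsely
#' than high-resolution fragment data.
#'
#' @param model A `precursor_model` (its core supplies the deduced
#'   linear mass) or a numeric deduced linear average mass in Da.
#' @param peaks A `peak_list` of kind `"intact_maldi"`.
#' @param tol_da Tolerance in Da (default 1.5).
#' @return A list with elements `deduced_linear_avg`,
#'   `expected_cyclic_mh`, `matched_peak`, `delta`, `cyclic_pass`,
#'   `expected_linear_mh`, `linear_delta`, `linear_pass`, `status`.
#' @examples
#' pk <- peak_list(6598.93, kind = "intact_maldi")
#' intact_cyclic_check(6615.93, pk)
#' @export
intact_cyclic_check <- function(model, peaks, tol_da = 1.5) {
  stopifnot(inherits(peaks, "peak_list"))
  if (peaks$kind != "intact_maldi")
    stop("intact check requires an intact_maldi peak list", call. = FALSE)
  if (tol_da <= 0) stop("`tol_da` must be positive", call. = FALSE)
  k <- mass_constants()
  if (inherits(model, "precursor_model")) {
    lin <- residue_seq(model$core$residues, "linear")
    deduced <- peptide_mass(lin, NULL, "average")
  } else if (is.numeric(model) && length(model) == 1L) {
    deduced <- as.numeric(model)
  } else {
    stop("`model` must be a precursor_model or a deduced linear mass",
         call. = FALSE)
  }
  expected_cyc <- deduced - k$water_avg + k$proton
  expected_lin <- deduced + k$proton
  if (length(peaks$mz) == 0L) {
    return(list(deduced_linear_avg = deduced,
                expected_cyclic_mh = expected_cyc, matched_peak = NA_real_,
                delta = NA_real_, cyclic_pass = FALSE,
                expected_linear_mh = expected_lin,
                linear_delta = NA_real_, linear_pass = FALSE,
                status = "no_peaks"))
  }
  nearest <- function(target) {
    i <- which.min(abs(peaks$mz - target))
    c(peak = peaks$mz[i], delta = peaks$mz[i] - target)
  }
  cy <- nearest(expected_cyc)
  li <- nearest(expected_lin)
  list(deduced_linear_avg = deduced,
       expected_cyclic_mh = expected_cyc,
       matched_peak = unname(cy["peak"]), delta = unname(cy["delta"]),
       cyclic_pass = unname(abs(cy["delta"]) <= tol_da),
       expected_linear_mh = expected_lin,
       linear_delta = unname(li["delta"]),
       linear_pass = unname(abs(li["delta"]) <= tol_da),
       status = "ok")
}

#' Combine fragment and intact evidence into a circularity verdict
#'
#' The verdict is `"circular_supported"` iff the intact dehydration
#' check passes and at least one junction-spanning fragment matched;
#' `"linear_only"` iff the intact peak instead matches the
#' non-dehydrated linear [M+H]+; otherwise `"insufficient"`. Junction
#' matches are listed first in the report.
#'
#' @param model The `precursor_model` (or deduced mass) the evidence
#'   concerns.
#' @param fragment_matches Output of [match_fragments] on the model's
#'   circular digest.
#' @param intact Output of [intact_cyclic_check] on the same model.
#' @return A `circularity_evidence` object: list with `candidate`,
#'   `intact_check`, `junction_matches`, `internal_matches`, `verdict`.
#' @export
assemble_evidence <- function(model, fragment_matches, intact) {
  jm <- fragment_matches[fragment_matches$junction, , drop = FALSE]
  im <- fragment_matches[!fragment_matches$junction, , drop = FALSE]
  verdict <- if (isTRUE(unname(intact$cyclic_pass)) && nrow(jm) >= 1L)
    "circular_supported"
  else if (isTRUE(unname(intact$linear_pass)))
    "linear_only"
  else
    "insufficient"
  structure(list(candidate = model, intact_check = intact,
                 junction_matches = jm, internal_matches = im,
                 verdict = verdict),
            class = "circularity_evidence")
}

#' @export
print.circularity_evidence <- function(x, ...) {
  cat(sprintf("<circularity_evidence: %s>\n", x$verdict))
  cat(sprintf("  intact: deduced linear %.2f Da, expected cyclic MH+ %.2f, delta %s\n",
              x$intact_check$deduced_linear_avg,
              x$intact_check$expected_cyclic_mh,
              ifelse(is.na(x$intact_check$delta), "NA",
                     sprintf("%+.2f", x$intact_check$delta))))
  cat(sprintf("  junction matches: %d; internal matches: %d\n",
              nrow(x$junction_matches), nrow(x$internal_matches)))
  invisible(x)
}
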