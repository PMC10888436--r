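#' Default pipeline configuration
#'
#' All tunables of the mine-digest-match-design pipeline with their
#' defaults; a run report embeds the exact configuration used.
#'
#' @param ... Overrides for any default field.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    genome = NULL, fragments = NULL, intact = NULL,
    out_dir = NULL, seed = 1L,
    min_identity = 30, window = 6000L, min_orf_len = 50L,
    strict_termini = TRUE,
    max_missed = 2L, semi = TRUE, semi_min_len = 6L,
    tol_ppm = 20, tol_da = 1.5, charges = c(1L, 2L),
    design_split = NULL, intein_config = NULL)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  utils::modifyList(cfg, over)
}

#' Run the full discovery-and-verification pipeline
#'
#' Mines a genome for circular-bacteriocin clusters, digests each
#' predicted core in silico, matches the theoretical fragments and the
#' intact cyclic mass against the supplied peak lists, renders a
#' circularity verdict per candidate, and optionally designs a SIML
#' construct. Stages degrade gracefully: absent peak lists leave the
#' verdict `"insufficient"` rather than failing the run.
#'
#' @param config A list from [pipeline_config], or a YAML file path.
#' @return A `pipeline_report`: list with `config`, `clusters` (one
#'   entry per cluster call: genes, precursor model, evidence,
#'   optional design) and `n_clusters`. Written as JSON to
#'   `out_dir/report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  if (!is.null(config$genome) && !file.exists(config$genome))
    stop("genome file not found: ", config$genome, call. = FALSE)
  features <- read_genome_features(config$genome, config$min_orf_len)
  calls <- call_clusters(features, window = config$window,
                         min_identity = config$min_identity,
                         strict_termini = config$strict_termini)
  frag_peaks <- if (!is.null(config$fragments))
    read_or_pass(config$fragments, "fragment_lcmsms") else NULL
  intact_peaks <- if (!is.null(config$intact))
    read_or_pass(config$intact, "intact_maldi") else NULL
  clusters <- lapply(calls, function(cl) {
    entry <- list(type = cl$type, contig = cl$contig, span = cl$span,
                  completeness = cl$completeness,
                  genes = cl$genes[, c("id", "start", "end", "strand",
                                       "role")],
                  precursor_model = cl$precursor_model)
    if (cl$type == "circular" && !is.null(cl$precursor_model)) {
      pm <- cl$precursor_model
      entry$evidence <- evaluate_candidate(pm, frag_peaks, intact_peaks,
                                           config)
      if (!is.null(config$design_split)) {
        pair <- load_intein_pair(config$intein_config)
        entry$design <- build_siml_protein(pm$core, config$design_split,
                                           pair)
      }
    }
    entry
  })
  report <- structure(list(config = config, clusters = clusters,
                           n_clusters = length(clusters)),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

read_or_pass <- function(x, kind) {
  if (inherits(x, "peak_list")) x else read_peak_list(x, kind)
}

# digest + match + intact check + verdict for one precursor model
evaluate_candidate <- function(pm, frag_peaks, intact_peaks, config) {
  peps <- digest_circular(pm$core, max_missed = config$max_missed)
  if (config$semi) peps <- semi_specific_expand(peps, config$semi_min_len)
  matches <- if (!is.null(frag_peaks) && length(frag_peaks$mz))
    match_fragments(peps, frag_peaks, config$charges, config$tol_ppm)
  else match_fragments(peps, peak_list(numeric(0),
                                       kind = "fragment_lcmsms"),
                       config$charges, config$tol_ppm)
  intact <- intact_cyclic_check(
    pm, intact_peaks %||% peak_list(numeric(0), kind = "intact_maldi"),
    config$tol_da)
  assemble_evidence(pm, matches, intact)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report: %d cluster call(s)>\n", x$n_clusters))
  for (cl in x$clusters) {
    v <- if (!is.null(cl$evidence)) cl$evidence$verdict else "-"
    cat(sprintf("  %s %s:%d-%d completeness %s verdict %s\n",
                cl$type, cl$contig, cl$span[1L], cl$span[2L],
                if (cl$type == "circular") cl$completeness else "-", v))
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- serialize_report(report)
  jsonlite::write_json(ser, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(file.path(out_dir, "report.json"))
}

serialize_report <- function(report) {
  cfg <- report$config[!vapply(report$config, is.null, TRUE)]
  cfg <- lapply(cfg, function(x) {
    if (inherits(x, "peak_list"))
      sprintf("<in-memory peak_list %s, %d peaks>", x$kind, length(x$mz))
    else x
  })
  list(
    config = cfg,
    n_clusters = report$n_clusters,
    clusters = lapply(report$clusters, function(cl) {
      out <- list(type = cl$type, contig = cl$contig,
                  span = cl$span, completeness = cl$completeness,
                  genes = cl$genes)
      if (!is.null(cl$precursor_model)) {
        pm <- cl$precursor_model
        out$precursor <- list(
          sequence = pm$precursor$residues, leader_len = pm$leader_len,
          core = pm$core$residues, source_id = pm$source_id,
          homology = pm$homology_support,
          low_confidence = pm$low_confidence)
      }
      if (!is.null(cl$evidence)) {
        ev <- cl$evidence
        out$evidence <- list(
          verdict = ev$verdict,
          intact = ev$intact_check[c("deduced_linear_avg",
                                     "expected_cyclic_mh", "matched_peak",
                                     "delta", "cyclic_pass",
                                     "linear_pass", "status")],
          junction_matches = ev$junction_matches,
          n_internal_matches = nrow(ev$internal_matches))
      }
      if (!is.null(cl$design))
        out$design <- list(split_position = cl$design$split_position,
                           permuted_core = cl$design$permuted_core$residues,
                           protein = cl$design$protein$residues)
      out
    }))
}
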