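#' Numeric thresholds used throughout the pipeline
#'
#' Bundles every numeric cutoff of the analysis: the differential-abundance
#' gates (raw ANOVA P, absolute relative fold-change, unique-peptide count),
#' the transcript differential-expression gates, the log2 fold-change
#' difference that attributes a protein change to autophagy-mediated turnover,
#' and the majority fraction for the aggregated process trend.
#'
#' Senses match the printed rules exactly: the P gate is strict (`p <
#' p_max`), the fold-change and peptide gates are inclusive (`>=`), the
#' transcript gates are inclusive, the turnover rule is strict (`delta >
#' delta_log2fc`), and the trend rule is strict (`fraction > trend_threshold`;
#' exactly 70\% is dual modulation).
#'
#' @param p_max ANOVA p-value gate for differential abundance (strict `<`).
#' @param abs_fc_min minimum absolute relative fold-change (inclusive `>=`).
#' @param min_peptides minimum unique-peptide count (inclusive `>=`).
#' @param transcript_abs_log2fc_min minimum absolute transcript log2
#'   fold-change for differential expression (inclusive).
#' @param transcript_q_max transcript q-value gate (inclusive).
#' @param delta_log2fc log2 fold-change difference above which (strict) a
#'   protein change is attributed to turnover rather than transcription.
#' @param trend_threshold majority fraction for calling a process trend
#'   up- or downregulated (strict `>`); must lie in (0.5, 1).
#' @return An object of class `filter_config` (a named list).
#' @export
#' @examples
#' filter_config()
#' filter_config(p_max = 0.01)
filter_config <- function(p_max = 0.05,
                          abs_fc_min = 2,
                          min_peptides = 2L,
                          transcript_abs_log2fc_min = 1,
                          transcript_q_max = 0.05,
                          delta_log2fc = 0.7,
                          trend_threshold = 0.70) {
  cfg <- list(
    p_max = as.numeric(p_max),
    abs_fc_min = as.numeric(abs_fc_min),
    min_peptides = as.integer(min_peptides),
    transcript_abs_log2fc_min = as.numeric(transcript_abs_log2fc_min),
    transcript_q_max = as.numeric(transcript_q_max),
    delta_log2fc = as.numeric(delta_log2fc),
    trend_threshold = as.numeric(trend_threshold)
  )
  for (nm in names(cfg)) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("filter_config: '", nm, "' must be a single positive number")
  }
  if (cfg$trend_threshold <= 0.5 || cfg$trend_threshold >= 1)
    stop("filter_config: 'trend_threshold' must lie in (0.5, 1)")
  structure(cfg, class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("Pipeline thresholds:\n")
  cat(sprintf("  differential:  p < %g, |FC| >= %g, peptides >= %d\n",
              x$p_max, x$abs_fc_min, x$min_peptides))
  cat(sprintf("  transcript DE: |log2FC| >= %g, q <= %g\n",
              x$transcript_abs_log2fc_min, x$transcript_q_max))
  cat(sprintf("  turnover:      |protein - transcript log2FC| > %g\n",
              x$delta_log2fc))
  cat(sprintf("  trend:         majority fraction > %g\n", x$trend_threshold))
  invisible(x)
}

#' Full pipeline configuration
#'
#' Collects the file paths of the eight input tables plus the FASTA of
#' protein sequences, the receptor identifiers, the motif definitions for the
#' sequence-scan channels, thresholds, seed and output directory.
#'
#' The p62 recognition motif has no authoritative built-in default (its
#' published definition is not bundled); supply one via `p62_motif`, e.g.
#' `parse_motif("[RK][RK]x[WFY][LIV]")`. When `NULL` the p62 motif-scan
#' channel is skipped with a note.
#'
#' @param abundance,transcripts,orthologs,domains,ddi,effects,markers paths
#'   to the corresponding TSV tables.
#' @param interactors named list of per-receptor experimental interactor TSV
#'   paths (names must be the receptor identifiers).
#' @param fasta path to protein sequences (FASTA, human accessions).
#' @param lir_list optional path to an iLIR-style list of known LIR proteins
#'   (one accession per line); `NULL` to rely on motif scanning alone.
#' @param receptors receptor identifiers, in the fixed order p62, LC3,
#'   ATG16L1.
#' @param atg16l1_id accession under which ATG16L1's own domains are found in
#'   the domain table (query domains for DDI prediction).
#' @param lir_motif [motif_definition()] used for the LC3 channel; defaults
#'   to the extended xLIR definition.
#' @param p62_motif [motif_definition()] for the p62 channel, or `NULL`.
#' @param filters a [filter_config()].
#' @param min_confidence minimum orthologue confidence retained.
#' @param seed integer seed recorded in the run log (the pipeline itself is
#'   deterministic; the seed matters for fixture generation).
#' @param outdir output directory for stage result files.
#' @param abundance_dialect column mapping for the abundance table, see
#'   [abundance_dialect()].
#' @return An object of class `pipeline_config`.
#' @seealso [run_pipeline()], [write_fixture_set()] which emits a ready-made
#'   configuration for synthetic fixtures.
#' @export
pipeline_config <- function(abundance, transcripts, orthologs, interactors,
                            fasta, domains, ddi, effects, markers,
                            lir_list = NULL,
                            receptors = c("p62", "LC3", "ATG16L1"),
                            atg16l1_id = "ATG16L1",
                            lir_motif = xlir_motif(),
                            p62_motif = NULL,
                            filters = filter_config(),
                            min_confidence = 1.0,
                            seed = 1L,
                            outdir = tempfile("panethnet_out_"),
                            abundance_dialect = panethnet::abundance_dialect()) {
  stopifnot(is.list(interactors), !is.null(names(interactors)))
  if (length(receptors) != 3L)
    stop("pipeline_config: exactly three receptor identifiers are expected")
  cfg <- structure(list(
    paths = list(abundance = abundance, transcripts = transcripts,
                 orthologs = orthologs, interactors = interactors,
                 fasta = fasta, domains = domains, ddi = ddi,
                 effects = effects, markers = markers, lir_list = lir_list),
    receptors = receptors,
    atg16l1_id = atg16l1_id,
    lir_motif = lir_motif,
    p62_motif = p62_motif,
    filters = filters,
    min_confidence = min_confidence,
    seed = as.integer(seed),
    outdir = outdir,
    abundance_dialect = abundance_dialect
  ), class = "pipeline_config")
  cfg
}

# Check that every referenced input path exists; returns invisibly or stops
# naming the offender and the stage that would need it.
validate_pipeline_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  flat <- config$paths
  flat$interactors <- NULL
  flat <- c(flat, config$paths$interactors)
  for (nm in names(flat)) {
    p <- flat[[nm]]
    if (is.null(p)) next
    if (!file.exists(p))
      stop("pipeline_config: input '", nm, "' does not exist: ", p)
  }
  invisible(config)
}
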