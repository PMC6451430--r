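#' Run the full integrative pipeline
#'
#' Executes the stages in order — differential-abundance filter, mouse to
#' human orthologue mapping, autophagy-target evidence collection, process
#' trend aggregation, proteome-transcriptome concordance, marker
#' enrichment, network export — writing every stage's table to the output
#' directory plus a plain-text run log of the summary counts. Any stage
#' failure aborts with the stage name and cause. Given identical inputs
#' and configuration the outputs are byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return object of class `panethnet_result`: list with `differential`,
#'   `mapping`, `evidence`, `overlap`, `trends`, `concordance`,
#'   `enrichment`, `network`, `summary` (named counts) and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(f) file.path(config$outdir, f)
  log_lines <- c(sprintf("panethnet run (seed %d)", config$seed))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## filter ---------------------------------------------------------------
  differential <- stage("filter", {
    ab <- read_abundance_table(config$paths$abundance,
                               config$abundance_dialect)
    filter_differential(ab, config$filters)
  })
  write_tsv_table(differential, out("differential.tsv"))
  note("filter: %d differential (%d up, %d down) of %d proteins",
       nrow(differential), sum(differential$direction == "up"),
       sum(differential$direction == "down"),
       nrow(attr(differential, "annotated")))

  ## orthology ------------------------------------------------------------
  mapping <- stage("orthology", {
    pairs <- read_ortholog_table(config$paths$orthologs)
    map_to_human(differential, pairs, config$min_confidence)
  })
  write_tsv_table(mapping$mapped, out("differential_human.tsv"))
  write_id_list(mapping$unmapped, out("unmapped.tsv"))
  note("orthology: %d human orthologues, %d unmapped, %d collapsed",
       nrow(mapping$mapped), length(mapping$unmapped),
       nrow(mapping$collapsed))

  ## targets --------------------------------------------------------------
  targets <- stage("targets", {
    seqs <- read_protein_fasta(config$paths$fasta)
    inter <- lapply(config$paths$interactors, read_id_list)
    lir <- if (!is.null(config$paths$lir_list))
      read_id_list(config$paths$lir_list) else NULL
    domains <- read_domain_table(config$paths$domains)
    ddi <- read_ddi_table(config$paths$ddi)
    ev <- collect_evidence(mapping$mapped, sequences = seqs,
                           interactors = inter, lir_list = lir,
                           lir_motif = config$lir_motif,
                           p62_motif = config$p62_motif,
                           domains = domains, ddi = ddi,
                           receptors = config$receptors,
                           atg16l1_id = config$atg16l1_id)
    list(evidence = ev, overlap = overlap_partition(ev, config$receptors))
  })
  write_evidence_table(targets$evidence, out("evidence.tsv"))
  venn <- data.frame(cell = names(targets$overlap$cells),
                     count = as.integer(targets$overlap$cells),
                     stringsAsFactors = FALSE)
  write_tsv_table(venn, out("venn.tsv"))
  note("targets: %d targeted proteins, fraction multi-targeted %.3f",
       targets$overlap$n_targeted, targets$overlap$fraction_multi)

  targeted_ids <- unique(targets$evidence$human_id)
  targeted <- mapping$mapped[mapping$mapped$human_id %in% targeted_ids, ,
                             drop = FALSE]

  ## trends ---------------------------------------------------------------
  effects <- stage("trends", read_effect_table(config$paths$effects))
  trends <- stage("trends",
                  classify_all_processes(targeted, effects, config$filters))
  write_tsv_table(trends, out("trends.tsv"))
  for (cls in c("upregulated", "downregulated", "dual"))
    note("trends: %d %s", sum(trends$classification == cls), cls)

  ## cross-omics ----------------------------------------------------------
  concordance <- stage("crossomics", {
    tr <- read_transcript_table(config$paths$transcripts)
    concordance_table(targeted, tr, id_map = NULL, cfg = config$filters)
  })
  write_tsv_table(concordance, out("concordance.tsv"))
  cs <- attr(concordance, "summary")
  note(paste("crossomics: %d proteins, %d with transcript,",
             "%d DE transcript, %d turnover"),
       cs$n_input, cs$n_with_transcript, cs$n_de_transcript, cs$n_turnover)

  ## enrichment -----------------------------------------------------------
  enrichment <- stage("enrich", {
    tr <- read_transcript_table(config$paths$transcripts)
    markers <- read_id_list(config$paths$markers)
    de <- tr$gene_id[classify_de_transcript(tr$log2fc, tr$q_value,
                                            config$filters)]
    marker_enrichment(markers, de, tr$gene_id)
  })
  write_tsv_table(data.frame(overlap_k = enrichment$overlap_k,
                             markers_K = enrichment$markers_K,
                             list_n = enrichment$list_n,
                             universe_N = enrichment$universe_N,
                             p_value = enrichment$p_value),
                  out("enrichment.tsv"))
  note("enrich: %d/%d markers in DE list of %d (universe %d), P = %.3g",
       enrichment$overlap_k, enrichment$markers_K, enrichment$list_n,
       enrichment$universe_N, enrichment$p_value)

  ## export ---------------------------------------------------------------
  network <- stage("export", {
    eff_t <- effects[effects$protein_id %in% targeted$human_id, ,
                     drop = FALSE]
    g <- build_network(targets$evidence, eff_t, targeted, trends)
    export_network(g, file.path(config$outdir, "network"))
    g
  })

  summary_counts <- list(
    n_proteins = nrow(attr(differential, "annotated")),
    n_differential = nrow(differential),
    n_up = sum(differential$direction == "up"),
    n_down = sum(differential$direction == "down"),
    n_human = nrow(mapping$mapped),
    n_up_human = sum(mapping$mapped$direction == "up"),
    n_down_human = sum(mapping$mapped$direction == "down"),
    n_unmapped = length(mapping$unmapped),
    n_targeted = targets$overlap$n_targeted,
    fraction_multi = targets$overlap$fraction_multi,
    n_processes = nrow(trends),
    n_with_transcript = cs$n_with_transcript,
    n_de_transcript = cs$n_de_transcript,
    n_turnover = cs$n_turnover,
    enrichment_p = enrichment$p_value)
  writeLines(log_lines, out("run_log.txt"))

  structure(list(differential = differential, mapping = mapping,
                 evidence = targets$evidence, overlap = targets$overlap,
                 trends = trends, concordance = concordance,
                 enrichment = enrichment, network = network,
                 summary = summary_counts, outdir = config$outdir,
                 config = config),
            class = "panethnet_result")
}

#' @export
print.panethnet_result <- function(x, ...) {
  s <- x$summary
  cat("panethnet pipeline result\n")
  cat(sprintf("  differential: %d of %d proteins (%d up / %d down)\n",
              s$n_differential, s$n_proteins, s$n_up, s$n_down))
  cat(sprintf("  human orthologues: %d (%d unmapped)\n",
              s$n_human, s$n_unmapped))
  cat(sprintf("  autophagy-targeted: %d (%.0f%% multi-receptor)\n",
              s$n_targeted, 100 * s$fraction_multi))
  cat(sprintf("  processes classified: %d\n", s$n_processes))
  cat(sprintf("  concordance: %d with transcript, %d DE, %d turnover\n",
              s$n_with_transcript, s$n_de_transcript, s$n_turnover))
  cat(sprintf("  marker enrichment P = %.3g\n", s$enrichment_p))
  cat("  outputs in ", x$outdir, "\n", sep = "")
  invisible(x)
}

#' @export
summary.panethnet_result <- function(object, ...) {
  trends <- object$trends
  cat("Per-process aggregated trends:\n")
  print(trends[, c("process_id", "process_label", "n_stimulatory",
                   "n_inhibitory", "classification")], row.names = FALSE)
  cat("\nVenn partition of targeted proteins:\n")
  print(object$overlap$cells)
  invisible(object$summary)
}
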