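# Synthetic fixture generator: emits all eight input tables plus a FASTA,
# internally consistent, with planted ground truth recorded alongside so
# every pipeline stage can be checked against known truth with no download.

sample_vec <- function(x, k, replace = FALSE) {
  x[sample.int(length(x), k, replace = replace)]
}

#' Scenario specification for the synthetic-data generator
#'
#' Defaults state the world the pipeline was built for: 2,000 quantified
#' proteins with 283 planted differential (70\% up), one mouse protein with
#' two human orthologues (283 -> 284), 41\% of the human differential set
#' targeted by p62/LC3/ATG16L1 with 19\% of targets multi-receptor, 16
#' curated processes with planted stimulatory majorities (8 up, 2 down, 6
#' dual), 66/116 of targets annotated with process effects, transcripts for
#' all differential genes with a planted turnover subset whose protein
#' log2FC exceeds the transcript log2FC by `turnover_delta`, and an
#' 83-marker list of which 56 are planted in the differentially expressed
#' transcript set. Three replicates per condition.
#'
#' @param n_proteins quantified mouse proteins.
#' @param n_differential planted differentially abundant proteins.
#' @param frac_up fraction of differential proteins more abundant on
#'   autophagy impairment.
#' @param frac_targeted fraction of human differential proteins targeted by
#'   at least one receptor.
#' @param frac_multi_targeted fraction of targeted proteins targeted by
#'   more than one receptor.
#' @param frac_annotated fraction of targeted proteins carrying curated
#'   process-effect annotations.
#' @param n_processes number of curated processes.
#' @param process_majorities per-process planted stimulatory fractions
#'   (length `n_processes`).
#' @param frac_no_transcript fraction of annotated proteins with no
#'   measured transcript.
#' @param turnover_fraction fraction of annotated-with-transcript proteins
#'   planted as turnover (protein change not explained by transcription).
#' @param turnover_delta planted log2FC difference for turnover genes; must
#'   exceed the 0.7 attribution cutoff.
#' @param noise_sd replicate noise, standard deviation of log2 intensities.
#' @param n_replicates replicates per condition.
#' @param planted_lfc_range magnitude range of planted protein log2
#'   fold-changes (chosen to pass the differential gates at `noise_sd`).
#' @param frac_peptide_fail fraction (of `n_differential`) of extra
#'   proteins planted to pass the statistical gates but fail only the
#'   unique-peptide filter.
#' @param n_markers size of the marker gene list.
#' @param markers_in_de markers planted inside the differentially expressed
#'   transcript set.
#' @param n_extra_de_transcripts additional differentially expressed
#'   transcripts planted among non-differential genes.
#' @param seed integer seed governing all randomness.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_proteins = 2000L,
                          n_differential = 283L,
                          frac_up = 0.70,
                          frac_targeted = 0.41,
                          frac_multi_targeted = 0.19,
                          frac_annotated = 66 / 116,
                          n_processes = 16L,
                          process_majorities = c(rep(0.8, 8),
                                                 rep(0.2, 2),
                                                 rep(0.5, 6)),
                          frac_no_transcript = 0.10,
                          turnover_fraction = 40 / 44,
                          turnover_delta = 1.5,
                          noise_sd = 0.25,
                          n_replicates = 3L,
                          planted_lfc_range = c(2.2, 4.2),
                          frac_peptide_fail = 0.05,
                          n_markers = 83L,
                          markers_in_de = 56L,
                          n_extra_de_transcripts = 120L,
                          seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               n_differential = as.integer(n_differential),
               frac_up = frac_up, frac_targeted = frac_targeted,
               frac_multi_targeted = frac_multi_targeted,
               frac_annotated = frac_annotated,
               n_processes = as.integer(n_processes),
               process_majorities = process_majorities,
               frac_no_transcript = frac_no_transcript,
               turnover_fraction = turnover_fraction,
               turnover_delta = turnover_delta,
               noise_sd = noise_sd,
               n_replicates = as.integer(n_replicates),
               planted_lfc_range = planted_lfc_range,
               frac_peptide_fail = frac_peptide_fail,
               n_markers = as.integer(n_markers),
               markers_in_de = as.integer(markers_in_de),
               n_extra_de_transcripts = as.integer(n_extra_de_transcripts),
               seed = as.integer(seed))
  fracs <- c("frac_up", "frac_targeted", "frac_multi_targeted",
             "frac_annotated", "frac_no_transcript", "turnover_fraction",
             "frac_peptide_fail")
  for (nm in fracs)
    if (any(spec[[nm]] < 0 | spec[[nm]] > 1))
      stop("scenario_spec: '", nm, "' must lie in [0, 1]")
  if (any(spec$process_majorities < 0 | spec$process_majorities > 1))
    stop("scenario_spec: process majorities must lie in [0, 1]")
  if (length(spec$process_majorities) != spec$n_processes)
    stop("scenario_spec: need one majority fraction per process")
  if (spec$n_differential > spec$n_proteins)
    stop("scenario_spec: more differential proteins than proteins")
  if (spec$markers_in_de > spec$n_markers)
    stop("scenario_spec: markers_in_de exceeds n_markers")
  if (spec$turnover_delta <= 0)
    stop("scenario_spec: turnover_delta must be positive")
  if (spec$noise_sd < 0 || spec$n_replicates < 2L)
    stop("scenario_spec: need noise_sd >= 0 and >= 2 replicates")
  structure(spec, class = "scenario_spec")
}

# synthetic stand-in for the (unpublished here) p62 recognition motif; used
# only by generated fixtures, never presented as the authoritative pattern
p62_synthetic_motif <- function() {
  parse_motif("[RK][RK]x[WFY][LIV]", name = "p62-synthetic",
              source = "synthetic stand-in pattern")
}

random_aa_sequence <- function(length) {
  paste(sample_vec(AA_ALPHABET, length, replace = TRUE), collapse = "")
}

motif_instance <- function(motif) {
  paste(vapply(motif$pattern, function(p) sample_vec(p, 1L), character(1)),
        collapse = "")
}

# Sequence with the wanted motifs present and the unwanted ones absent,
# by rejection sampling over background + planted insertions.
plant_sequence <- function(length, motifs, want) {
  rx <- vapply(motifs, motif_regex, character(1))
  for (attempt in 1:200) {
    seq <- random_aa_sequence(length)
    if (any(vapply(rx, grepl, logical(1), x = seq))) next
    for (nm in names(motifs)[want]) {
      ins <- motif_instance(motifs[[nm]])
      pos <- sample.int(length - nchar(ins) + 1L, 1L)
      substr(seq, pos, pos + nchar(ins) - 1L) <- ins
    }
    hits <- vapply(rx, grepl, logical(1), x = seq)
    if (identical(unname(hits), unname(want))) return(seq)
  }
  stop("plant_sequence: rejection sampling failed; motifs too permissive")
}

#' Generate a complete synthetic fixture bundle with planted ground truth
#'
#' Emits internally consistent versions of all eight pipeline inputs
#' (abundance, transcripts, orthologues, per-receptor interactor lists,
#' FASTA, domains, interacting-domain pairs, process effects, markers)
#' together with the ground truth planted into them. Differential proteins
#' have group means separated to pass the abundance gates at the requested
#' noise level; non-differential proteins are mean-matched. Motifs are
#' inserted only into designated targets, with rejection sampling keeping
#' every other sequence motif-free. Identical seeds give identical bundles.
#'
#' @param spec a [scenario_spec()].
#' @return list of class `fixture_bundle`: `abundance` (an
#'   `abundance_table`), `transcripts`, `orthologs`, `interactors` (named
#'   list), `lir_list`, `sequences` (named character), `domains`, `ddi`,
#'   `effects`, `markers`, `motifs` (the LIR and p62 definitions used),
#'   `truth` (ground-truth bookkeeping) and `spec`.
#' @export
generate_scenario <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  n <- spec$n_proteins
  r <- spec$n_replicates
  mouse_ids <- sprintf("M%05d", seq_len(n))
  human_ids <- sprintf("H%05d", seq_len(n))

  ## ---- differential plan ------------------------------------------------
  n_diff <- spec$n_differential
  n_pepfail <- round(spec$frac_peptide_fail * n_diff)
  planted <- sample_vec(seq_len(n), n_diff + n_pepfail)
  diff_idx <- planted[seq_len(n_diff)]
  pepfail_idx <- planted[-seq_len(n_diff)]

  n_up <- round(spec$frac_up * n_diff)
  direction <- rep(NA_character_, n)
  up_idx <- sample_vec(diff_idx, n_up)
  direction[diff_idx] <- "down"
  direction[up_idx] <- "up"
  direction[pepfail_idx] <- sample_vec(c("up", "down"),
                                       length(pepfail_idx), replace = TRUE)

  lfc <- rep(0, n)
  sep_idx <- c(diff_idx, pepfail_idx)
  mag <- runif(length(sep_idx), spec$planted_lfc_range[1],
               spec$planted_lfc_range[2])
  lfc[sep_idx] <- ifelse(direction[sep_idx] == "up", mag, -mag)

  ## ---- abundance table --------------------------------------------------
  base_mu <- runif(n, 18, 26)
  noise <- function() matrix(rnorm(n * r, 0, spec$noise_sd), n, r)
  wt <- 2^(base_mu + noise())
  ko <- 2^(base_mu + lfc + noise())
  peptides <- sample_vec(2:15, n, replace = TRUE)
  peptides[pepfail_idx] <- 1L
  abundance <- data.frame(protein_id = mouse_ids,
                          unique_peptides = peptides,
                          stringsAsFactors = FALSE)
  abundance$wt <- matrix(wt, n, r, dimnames = list(NULL, paste0("wt_", 1:r)))
  abundance$ko <- matrix(ko, n, r, dimnames = list(NULL, paste0("ko_", 1:r)))
  abundance$anova_p <- rep(NA_real_, n)
  abundance$rel_fc <- rep(NA_real_, n)
  abundance$log2fc <- rep(NA_real_, n)
  class(abundance) <- c("abundance_table", "data.frame")

  # log2 fold-change the pipeline will observe (ratio of arithmetic means);
  # transcripts are planted relative to this so the concordance rule is
  # deterministic on the emitted values at any noise level
  obs_lfc <- log2(rowMeans(ko) / rowMeans(wt))

  ## ---- orthologue table: 1:1 plus exactly one 1:2 expansion -------------
  expanded_mouse <- if (n_diff) mouse_ids[diff_idx[1]] else character()
  extra_human <- if (n_diff) paste0(human_ids[diff_idx[1]], "B")
                 else character()
  orthologs <- data.frame(mouse_id = mouse_ids, human_id = human_ids,
                          confidence = rep(1.0, n), stringsAsFactors = FALSE)
  if (n_diff)
    orthologs <- rbind(orthologs,
                       data.frame(mouse_id = expanded_mouse,
                                  human_id = extra_human, confidence = 1.0,
                                  stringsAsFactors = FALSE))
  nondiff <- setdiff(seq_len(n), diff_idx)
  decoy_m <- sample_vec(nondiff, min(20L, length(nondiff)))
  if (length(decoy_m))
    orthologs <- rbind(orthologs,
                       data.frame(mouse_id = mouse_ids[decoy_m],
                                  human_id = sprintf("HLOW%04d",
                                                     seq_along(decoy_m)),
                                  confidence = 0.5, stringsAsFactors = FALSE))
  orthologs <- orthologs[order(orthologs$mouse_id, orthologs$human_id), ]
  rownames(orthologs) <- NULL

  # the human-side differential list (e.g. 283 mouse -> 284 human)
  human_diff <- c(human_ids[diff_idx], extra_human)
  h_direction <- c(direction[diff_idx],
                   if (n_diff) direction[diff_idx[1]])
  h_lfc <- c(obs_lfc[diff_idx], if (n_diff) obs_lfc[diff_idx[1]])
  names(h_direction) <- names(h_lfc) <- human_diff

  ## ---- targeting plan ---------------------------------------------------
  receptors <- c("p62", "LC3", "ATG16L1")
  n_targeted <- round(spec$frac_targeted * length(human_diff))
  n_multi <- round(spec$frac_multi_targeted * n_targeted)
  targeted <- sample_vec(human_diff, n_targeted)
  multi <- targeted[seq_len(n_multi)]
  target_sets <- setNames(vector("list", n_targeted), targeted)
  for (id in targeted) {
    if (id %in% multi) {
      sz <- sample_vec(c(2L, 3L), 1L)  # mostly pairs, occasional triples
      if (sz == 3L && runif(1) > 0.15) sz <- 2L
      target_sets[[id]] <- sort(sample_vec(receptors, sz))
    } else {
      target_sets[[id]] <- sample_vec(receptors, 1L)
    }
  }

  # evidence channel per (protein, receptor)
  channels <- list()
  for (id in targeted) {
    for (rec in target_sets[[id]]) {
      ch <- switch(rec,
        p62 = sample_vec(c("experimental", "p62_motif"), 1L),
        LC3 = sample_vec(c("experimental", "database_list", "lir_motif"), 1L),
        ATG16L1 = sample_vec(c("experimental", "ddi"), 1L))
      channels[[length(channels) + 1L]] <- data.frame(
        human_id = id, receptor = rec, channel = ch,
        stringsAsFactors = FALSE)
    }
  }
  channels <- do.call(rbind, channels)

  ## ---- interactor lists and LIR database list ---------------------------
  non_diff_human <- setdiff(human_ids, human_diff)
  n_decoy <- min(30L, length(non_diff_human))
  interactors <- lapply(receptors, function(rec) {
    planted <- if (is.null(channels)) character() else
      channels$human_id[channels$receptor == rec &
                          channels$channel == "experimental"]
    sort(c(planted, sample_vec(non_diff_human, n_decoy)))
  })
  names(interactors) <- receptors
  lir_db <- if (is.null(channels)) character() else
    channels$human_id[channels$channel == "database_list"]
  lir_list <- sort(c(lir_db, sample_vec(non_diff_human, n_decoy)))

  ## ---- sequences with planted motifs ------------------------------------
  motifs <- list(lir = xlir_motif(), p62 = p62_synthetic_motif())
  lir_planted <- channels$human_id[channels$channel == "lir_motif"]
  p62_planted <- channels$human_id[channels$channel == "p62_motif"]
  sequences <- setNames(vapply(human_diff, function(id) {
    plant_sequence(120L, motifs,
                   want = c(lir = id %in% lir_planted,
                            p62 = id %in% p62_planted))
  }, character(1)), human_diff)

  ## ---- domains and interacting-domain pairs -----------------------------
  query_domains <- c("WD40", "ATG_N")
  ddi_planted <- channels$human_id[channels$channel == "ddi"]
  domains <- data.frame(protein_id = "ATG16L1",
                        domain_accession = query_domains,
                        stringsAsFactors = FALSE)
  ddi <- data.frame(domain_a = character(), domain_b = character(),
                    stringsAsFactors = FALSE)
  if (length(ddi_planted)) {
    partner <- sprintf("PF%04d", seq_along(ddi_planted))
    domains <- rbind(domains,
                     data.frame(protein_id = ddi_planted,
                                domain_accession = partner,
                                stringsAsFactors = FALSE))
    ddi <- rbind(ddi, data.frame(
      domain_a = sample_vec(query_domains, length(partner), replace = TRUE),
      domain_b = partner, stringsAsFactors = FALSE))
  }
  # decoys: non-targeted differential proteins carry domains that pair with
  # nothing ATG16L1 has; plus inert pairs among decoy domains
  decoy_prot <- sample_vec(setdiff(human_diff, ddi_planted),
                           min(40L, length(setdiff(human_diff, ddi_planted))))
  decoy_dom <- sprintf("PFD%04d", seq_along(decoy_prot))
  domains <- rbind(domains,
                   data.frame(protein_id = decoy_prot,
                              domain_accession = decoy_dom,
                              stringsAsFactors = FALSE))
  if (length(decoy_dom) >= 4L) {
    ddi <- rbind(ddi, data.frame(
      domain_a = decoy_dom[1:2],
      domain_b = sprintf("PFX%04d", 1:2),  # domains no candidate carries
      stringsAsFactors = FALSE))
  }
  domains <- unique(domains[order(domains$protein_id,
                                  domains$domain_accession), ])
  rownames(domains) <- NULL
  ddi <- canonicalize_ddi(ddi)

  ## ---- process effects with planted majorities --------------------------
  n_annot <- round(spec$frac_annotated * n_targeted)
  annotated <- sample_vec(targeted, n_annot)
  eff_rows <- list()
  proc_truth <- list()
  for (j in seq_len(if (n_annot >= 5L) spec$n_processes else 0L)) {
    pid <- sprintf("GO:%07d", j)
    plab <- sprintf("process_%02d", j)
    n_j <- sample_vec(5:min(20L, n_annot), 1L)
    members <- sample_vec(annotated, n_j)
    n_stim <- round(spec$process_majorities[j] * n_j)
    sign <- rep(c("stimulatory", "inhibitory"), c(n_stim, n_j - n_stim))
    dirs <- h_direction[members]
    effect <- ifelse(sign == "stimulatory",
                     ifelse(dirs == "up", "activation", "inhibition"),
                     ifelse(dirs == "up", "inhibition", "activation"))
    eff_rows[[j]] <- data.frame(protein_id = members, process_id = pid,
                                process_label = plab, effect = effect,
                                in_context = TRUE, stringsAsFactors = FALSE)
    f_s <- n_stim / n_j
    proc_truth[[j]] <- data.frame(
      process_id = pid, process_label = plab,
      n_stimulatory = n_stim, n_inhibitory = n_j - n_stim,
      classification = if (f_s > 0.70) "upregulated"
                       else if (1 - f_s > 0.70) "downregulated"
                       else "dual",
      stringsAsFactors = FALSE)
  }
  empty_eff <- data.frame(protein_id = character(), process_id = character(),
                          process_label = character(), effect = character(),
                          in_context = logical(), stringsAsFactors = FALSE)
  effects <- if (length(eff_rows)) do.call(rbind, eff_rows) else empty_eff
  if (n_annot) {
    # out-of-context rows exercising the context filter
    effects <- rbind(effects, data.frame(
      protein_id = sample_vec(annotated, min(10L, n_annot)),
      process_id = "GO:9999999", process_label = "non_intestinal_process",
      effect = "activation", in_context = FALSE, stringsAsFactors = FALSE))
  }
  effects <- effects[order(effects$process_id, effects$protein_id), ,
                     drop = FALSE]
  rownames(effects) <- NULL
  proc_truth <- if (length(proc_truth)) do.call(rbind, proc_truth) else
    data.frame(process_id = character(), process_label = character(),
               n_stimulatory = integer(), n_inhibitory = integer(),
               classification = character(), stringsAsFactors = FALSE)

  ## ---- transcripts with planted turnover subset -------------------------
  n_no_tr <- round(spec$frac_no_transcript * n_annot)
  no_transcript <- sample_vec(annotated, n_no_tr)
  with_tr <- setdiff(annotated, no_transcript)
  n_turn <- round(spec$turnover_fraction * length(with_tr))
  turnover <- sample_vec(with_tr, n_turn)

  tr_genes <- setdiff(c(human_ids, extra_human), no_transcript)
  t_lfc <- setNames(rnorm(length(tr_genes), 0, 0.3), tr_genes)
  t_q <- setNames(runif(length(tr_genes), 0.06, 1), tr_genes)
  diff_tr <- setdiff(human_diff, no_transcript)
  t_lfc[diff_tr] <- h_lfc[diff_tr] + runif(length(diff_tr), -0.2, 0.2)
  t_q[diff_tr] <- runif(length(diff_tr), 0.001, 0.049)
  t_lfc[turnover] <- h_lfc[turnover] - spec$turnover_delta
  extra_pool <- setdiff(tr_genes, human_diff)
  extra_de <- sample_vec(extra_pool, min(spec$n_extra_de_transcripts,
                                         length(extra_pool)))
  t_lfc[extra_de] <- sample_vec(c(-1, 1), length(extra_de), replace = TRUE) *
    runif(length(extra_de), 1.2, 3)
  t_q[extra_de] <- runif(length(extra_de), 0.001, 0.049)
  transcripts <- data.frame(gene_id = tr_genes, log2fc = unname(t_lfc),
                            q_value = unname(t_q), stringsAsFactors = FALSE)

  ## ---- markers ----------------------------------------------------------
  de_genes <- transcripts$gene_id[classify_de_transcript(
    transcripts$log2fc, transcripts$q_value, filter_config())]
  non_de <- setdiff(tr_genes, de_genes)
  if (spec$markers_in_de > length(de_genes) ||
      spec$n_markers - spec$markers_in_de > length(non_de))
    stop("scenario infeasible: marker plan exceeds available DE/non-DE genes")
  markers <- sort(c(sample_vec(de_genes, spec$markers_in_de),
                    sample_vec(non_de, spec$n_markers - spec$markers_in_de)))

  ## ---- ground truth ------------------------------------------------------
  targeted_by <- vapply(human_diff, function(id)
    paste(target_sets[[id]] %||% character(), collapse = "+"), character(1))
  attribution <- ifelse(targeted %in% no_transcript, "no_transcript",
                        ifelse(targeted %in% turnover, "turnover",
                               "transcriptional"))
  truth <- list(
    differential_mouse = sort(mouse_ids[diff_idx]),
    peptide_fail_mouse = sort(mouse_ids[pepfail_idx]),
    proteins = data.frame(human_id = human_diff,
                          mouse_id = c(mouse_ids[diff_idx],
                                       expanded_mouse),
                          direction = unname(h_direction),
                          log2fc = unname(h_lfc),
                          targeted_by = unname(targeted_by),
                          annotated = human_diff %in% annotated,
                          stringsAsFactors = FALSE),
    target_sets = target_sets,
    processes = proc_truth,
    concordance = data.frame(id = targeted, attribution = attribution,
                             stringsAsFactors = FALSE),
    counts = list(
      n_differential = n_diff,
      n_up = sum(direction[diff_idx] == "up"),
      n_down = sum(direction[diff_idx] == "down"),
      n_human = length(human_diff),
      n_up_human = sum(h_direction == "up"),
      n_down_human = sum(h_direction == "down"),
      n_targeted = n_targeted,
      n_multi = n_multi,
      fraction_multi = if (n_targeted) n_multi / n_targeted else 0,
      n_annotated = n_annot,
      n_with_transcript = n_targeted - sum(targeted %in% no_transcript),
      n_turnover = n_turn,
      marker_k = spec$markers_in_de,
      marker_K = spec$n_markers,
      de_list_n = length(de_genes),
      universe_N = nrow(transcripts)))

  structure(list(abundance = abundance, transcripts = transcripts,
                 orthologs = orthologs, interactors = interactors,
                 lir_list = lir_list, sequences = sequences,
                 domains = domains, ddi = ddi, effects = effects,
                 markers = markers, motifs = motifs, truth = truth,
                 spec = spec),
            class = "fixture_bundle")
}

#' Write a fixture bundle to disk
#'
#' Materializes every table of a [generate_scenario()] bundle in exactly
#' the dialects the package readers consume, and returns a ready-made
#' [pipeline_config()] pointing at the files (reading them back reproduces
#' the bundle).
#'
#' @param bundle a `fixture_bundle`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with `paths` (named file paths) and `config`
#'   (a `pipeline_config` for [run_pipeline()]).
#' @export
write_fixture_set <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_abundance_table(bundle$abundance, p("abundance.tsv"))
  write_transcript_table(bundle$transcripts, p("transcripts.tsv"))
  write_ortholog_table(bundle$orthologs, p("orthologs.tsv"))
  inter_paths <- list()
  for (rec in names(bundle$interactors)) {
    inter_paths[[rec]] <- p(sprintf("interactors_%s.tsv", rec))
    write_id_list(bundle$interactors[[rec]], inter_paths[[rec]])
  }
  write_id_list(bundle$lir_list, p("lir_list.tsv"))
  write_protein_fasta(bundle$sequences, p("sequences.fasta"))
  write_domain_table(bundle$domains, p("domains.tsv"))
  write_ddi_table(bundle$ddi, p("ddi.tsv"))
  write_effect_table(bundle$effects, p("effects.tsv"))
  write_id_list(bundle$markers, p("markers.tsv"))

  paths <- c(list(abundance = p("abundance.tsv"),
                  transcripts = p("transcripts.tsv"),
                  orthologs = p("orthologs.tsv"),
                  lir_list = p("lir_list.tsv"),
                  fasta = p("sequences.fasta"),
                  domains = p("domains.tsv"), ddi = p("ddi.tsv"),
                  effects = p("effects.tsv"), markers = p("markers.tsv")),
             interactors = list(inter_paths))
  config <- pipeline_config(
    abundance = paths$abundance, transcripts = paths$transcripts,
    orthologs = paths$orthologs, interactors = inter_paths,
    fasta = paths$fasta, domains = paths$domains, ddi = paths$ddi,
    effects = paths$effects, markers = paths$markers,
    lir_list = paths$lir_list,
    lir_motif = bundle$motifs$lir, p62_motif = bundle$motifs$p62,
    seed = bundle$spec$seed,
    outdir = file.path(outdir, "results"))
  invisible(list(paths = paths, config = config))
}
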