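#' Predict targets by domain-domain interaction inference
#'
#' A candidate protein is predicted to interact with the query (ATG16L1)
#' when it carries at least one domain forming a known interacting pair with
#' one of the query's domains. Candidates with no domain annotation are
#' simply never predicted.
#'
#' @param query_domains character vector of the query protein's domain
#'   accessions.
#' @param candidates domain annotation table (`protein_id`,
#'   `domain_accession`), see [read_domain_table()].
#' @param ddi canonicalized interacting-domain-pair table
#'   (`domain_a`, `domain_b`), see [read_ddi_table()].
#' @return character vector of predicted protein accessions (sorted,
#'   unique).
#' @export
predict_ddi_targets <- function(query_domains, candidates, ddi) {
  ddi <- canonicalize_ddi(ddi)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  pairs <- key(ddi$domain_a, ddi$domain_b)
  if (!length(query_domains) || !nrow(candidates)) return(character())
  hits <- vapply(seq_len(nrow(candidates)), function(i) {
    any(key(query_domains, candidates$domain_accession[i]) %in% pairs)
  }, logical(1))
  sort(unique(candidates$protein_id[hits]))
}

#' Collect autophagy-targeting evidence for differential proteins
#'
#' Decides, for each human-mapped differential protein, whether it is a
#' potential target of p62, LC3 and/or ATG16L1, pooling four evidence
#' channels: membership in per-receptor experimental interactor lists
#' (ARN-style), membership in a LIR-protein list (iLIR-style), sequence
#' motif scans (LIR motif for LC3; a user-supplied recognition motif for
#' p62) and domain-domain interaction inference for ATG16L1. Rows are
#' deduplicated on (protein, receptor, evidence type, detail).
#'
#' Proteins in the differential list but absent from the FASTA are logged
#' and skipped by the motif channels only.
#'
#' @param proteins data frame with a `human_id` column (the human-mapped
#'   differential proteins).
#' @param sequences named character vector of protein sequences (or `NULL`
#'   to skip motif channels).
#' @param interactors named list of character vectors of experimental
#'   interactor accessions, one per receptor; names must be the receptor
#'   identifiers.
#' @param lir_list character vector of known LIR-containing proteins
#'   (`NULL` to skip).
#' @param lir_motif motif for the LC3 channel, default [xlir_motif()].
#' @param p62_motif motif for the p62 channel, or `NULL` to skip (no
#'   authoritative default is bundled).
#' @param domains,ddi domain annotations and interacting pairs for the
#'   ATG16L1 channel (`NULL` to skip).
#' @param receptors the three receptor identifiers, in the order p62, LC3,
#'   ATG16L1.
#' @param atg16l1_id accession whose rows in `domains` are ATG16L1's own
#'   (query) domains.
#' @return evidence data frame (`human_id`, `receptor`, `evidence_type`,
#'   `detail`), sorted; attribute `"no_sequence"` lists proteins missing
#'   from the FASTA.
#' @export
collect_evidence <- function(proteins, sequences = NULL,
                             interactors = list(),
                             lir_list = NULL,
                             lir_motif = xlir_motif(),
                             p62_motif = NULL,
                             domains = NULL, ddi = NULL,
                             receptors = c("p62", "LC3", "ATG16L1"),
                             atg16l1_id = "ATG16L1") {
  ids <- unique(proteins$human_id)
  p62 <- receptors[1]; lc3 <- receptors[2]; atg16 <- receptors[3]
  n_sources <- sum(length(interactors), !is.null(lir_list),
                   !is.null(p62_motif), !is.null(lir_motif),
                   !is.null(domains))
  if (n_sources == 0L)
    stop("collect_evidence: no evidence source configured")

  rows <- list()
  add <- function(human_id, receptor, evidence_type, detail) {
    if (!length(human_id)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      human_id = human_id, receptor = receptor,
      evidence_type = evidence_type, detail = detail,
      stringsAsFactors = FALSE)
  }

  for (rec in intersect(receptors, names(interactors))) {
    hits <- intersect(ids, interactors[[rec]])
    add(hits, rec, "experimental", "ARN")
  }
  if (!is.null(lir_list)) {
    add(intersect(ids, lir_list), lc3, "database_list", "iLIR")
  }

  no_seq <- character()
  if (!is.null(sequences)) {
    no_seq <- setdiff(ids, names(sequences))
    if (length(no_seq))
      message("collect_evidence: ", length(no_seq),
              " protein(s) absent from FASTA; motif channels skipped")
    for (id in intersect(ids, names(sequences))) {
      if (!is.null(lir_motif)) {
        h <- scan_motif(sequences[[id]], lir_motif)
        if (nrow(h))
          add(id, lc3, "lir_motif",
              paste0(lir_motif$name, ":", h$start, ":", h$match))
      }
      if (!is.null(p62_motif)) {
        h <- scan_motif(sequences[[id]], p62_motif)
        if (nrow(h))
          add(id, p62, "p62_motif",
              paste0(p62_motif$name, ":", h$start, ":", h$match))
      }
    }
  }

  if (!is.null(domains) && !is.null(ddi)) {
    query <- domains$domain_accession[domains$protein_id == atg16l1_id]
    cand <- domains[domains$protein_id %in% ids, , drop = FALSE]
    pred <- predict_ddi_targets(query, cand, ddi)
    if (length(pred)) {
      # record which candidate domain pairs with a query domain
      ddi_c <- canonicalize_ddi(ddi)
      pairkey <- paste(ddi_c$domain_a, ddi_c$domain_b, sep = "\r")
      for (id in pred) {
        doms <- cand$domain_accession[cand$protein_id == id]
        grid <- expand.grid(q = query, d = doms, stringsAsFactors = FALSE)
        hit <- grid[paste(pmin(grid$q, grid$d), pmax(grid$q, grid$d),
                          sep = "\r") %in% pairkey, , drop = FALSE]
        add(rep(id, nrow(hit)), atg16, "ddi",
            paste0(hit$q, "-", hit$d))
      }
    }
  }

  if (length(rows)) {
    out <- unique(do.call(rbind, rows))
    out <- out[order(out$human_id, out$receptor, out$evidence_type,
                     out$detail), , drop = FALSE]
  } else {
    out <- data.frame(human_id = character(), receptor = character(),
                      evidence_type = character(), detail = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "no_sequence") <- no_seq
  out
}

#' Venn partition of the targeted protein set
#'
#' Partitions the distinct targeted proteins into the seven disjoint cells
#' of the three-receptor Venn diagram and reports the fraction targeted by
#' more than one receptor.
#'
#' @param evidence evidence data frame from [collect_evidence()].
#' @param receptors the three receptor identifiers.
#' @return list with `cells` (named integer vector over the 7 cells, names
#'   like `"p62"`, `"p62+LC3"`, `"p62+LC3+ATG16L1"`), `n_targeted`,
#'   `fraction_multi` (0 with `empty = TRUE` flag when nothing is
#'   targeted).
#' @export
overlap_partition <- function(evidence,
                              receptors = c("p62", "LC3", "ATG16L1")) {
  sets <- lapply(receptors, function(r)
    unique(evidence$human_id[evidence$receptor == r]))
  names(sets) <- receptors
  all_ids <- unique(unlist(sets))
  combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  cell_name <- vapply(combos, function(ix)
    paste(receptors[ix], collapse = "+"), character(1))
  membership <- vapply(all_ids, function(id)
    paste(which(vapply(sets, function(s) id %in% s, logical(1))),
          collapse = ","), character(1))
  combo_key <- vapply(combos, paste, character(1), collapse = ",")
  cells <- setNames(integer(length(combos)), cell_name)
  if (length(all_ids)) {
    tab <- table(factor(membership, levels = combo_key))
    cells[] <- as.integer(tab)
  }
  n_multi <- sum(cells[vapply(combos, length, integer(1)) >= 2L])
  list(cells = cells,
       n_targeted = length(all_ids),
       fraction_multi = if (length(all_ids)) n_multi / length(all_ids) else 0,
       empty = length(all_ids) == 0L)
}

#' Exploratory enrichment of the targeted set
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' number of targeted proteins among the differential set, against a
#' user-supplied background of targetable proteins within a universe. The
#' published analysis does not state its background universe, so this is
#' reported as exploratory.
#'
#' @param targeted,differential,targetable_background,universe character
#'   vectors of protein accessions.
#' @return an `enrichment_result` as from [marker_enrichment()].
#' @export
target_enrichment <- function(targeted, differential,
                              targetable_background, universe) {
  marker_enrichment(markers = targetable_background,
                    de_genes = intersect(differential, universe),
                    universe = universe)
}
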