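#' Transcript differential-expression call
#'
#' A transcript is differentially expressed when its absolute log2
#' fold-change is at least `transcript_abs_log2fc_min` and its q-value at
#' most `transcript_q_max` — both bounds inclusive.
#'
#' @param log2fc,q_value numeric vectors.
#' @param cfg a [filter_config()].
#' @return logical vector.
#' @export
#' @examples
#' classify_de_transcript(c(1.0, 0.99, -3), c(0.05, 0.001, 0.2))
classify_de_transcript <- function(log2fc, q_value, cfg = filter_config()) {
  abs(log2fc) >= cfg$transcript_abs_log2fc_min &
    q_value <= cfg$transcript_q_max
}

#' Attribute a protein abundance change to turnover or transcription
#'
#' When the protein-level and transcript-level log2 fold-changes differ by
#' strictly more than `delta_log2fc` (default 0.7), the protein change
#' cannot be explained by gene expression and is attributed to impaired
#' autophagy-mediated turnover; otherwise it is transcriptional. Missing
#' transcripts yield `"no_transcript"`. The comparison is on signed values,
#' so negating both fold-changes preserves the attribution.
#'
#' @param protein_log2fc numeric vector.
#' @param transcript_log2fc numeric vector, `NA` where no transcript was
#'   measured.
#' @param cfg a [filter_config()].
#' @return character vector over `"turnover"`, `"transcriptional"`,
#'   `"no_transcript"`.
#' @export
#' @examples
#' attribute_change(3.0, 1.0)  # turnover (delta 2.0)
#' attribute_change(1.7, 1.0)  # transcriptional (delta 0.7, not strict)
attribute_change <- function(protein_log2fc, transcript_log2fc,
                             cfg = filter_config()) {
  delta <- abs(protein_log2fc - transcript_log2fc)
  out <- ifelse(is.na(transcript_log2fc), "no_transcript",
                ifelse(delta > cfg$delta_log2fc, "turnover",
                       "transcriptional"))
  out
}

#' Pair protein and transcript fold-changes
#'
#' Builds one concordance record per input protein: the paired transcript
#' log2 fold-change and q-value (through an optional protein-to-gene
#' identifier map), the transcript differential-expression flag, the
#' absolute log2 fold-change difference and the turnover attribution.
#' Transcripts failing the DE thresholds still contribute to the delta;
#' they are merely flagged.
#'
#' @param proteins data frame with `human_id` and `log2fc` (the targeted
#'   differential proteins).
#' @param transcripts transcript table from [read_transcript_table()].
#' @param id_map optional data frame with columns `protein_id`, `gene_id`
#'   mapping protein accessions to transcript identifiers; `NULL` means the
#'   identifiers coincide.
#' @param cfg a [filter_config()].
#' @return data frame of class `concordance_table` with columns `id`,
#'   `protein_log2fc`, `transcript_log2fc`, `transcript_q`,
#'   `transcript_de`, `delta`, `attribution`; summary counts in attribute
#'   `"summary"` (`n_input`, `n_with_transcript`, `n_de_transcript`,
#'   `n_turnover`).
#' @export
concordance_table <- function(proteins, transcripts, id_map = NULL,
                              cfg = filter_config()) {
  if (anyDuplicated(transcripts$gene_id)) {
    dup <- unique(transcripts$gene_id[duplicated(transcripts$gene_id)])
    stop("concordance_table: duplicated transcript keys: ",
         paste(head(dup, 5), collapse = ", "))
  }
  keys <- proteins$human_id
  if (!is.null(id_map))
    keys <- id_map$gene_id[match(keys, id_map$protein_id)]
  ix <- match(keys, transcripts$gene_id)
  t_lfc <- transcripts$log2fc[ix]
  t_q <- transcripts$q_value[ix]
  de <- ifelse(is.na(t_lfc), FALSE,
               classify_de_transcript(t_lfc, t_q, cfg))
  out <- data.frame(
    id = proteins$human_id,
    protein_log2fc = proteins$log2fc,
    transcript_log2fc = t_lfc,
    transcript_q = t_q,
    transcript_de = de,
    delta = abs(proteins$log2fc - t_lfc),
    attribution = attribute_change(proteins$log2fc, t_lfc, cfg),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    n_input = nrow(out),
    n_with_transcript = sum(!is.na(out$transcript_log2fc)),
    n_de_transcript = sum(out$transcript_de),
    n_turnover = sum(out$attribution == "turnover"))
  class(out) <- c("concordance_table", "data.frame")
  out
}
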