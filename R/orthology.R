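#' Map mouse differential proteins to human orthologues
#'
#' Expands each mouse protein to all of its human orthologues at or above
#' the confidence cutoff, copying `log2fc` and `direction` unchanged, so the
#' output may contain more rows than the input (one-to-many orthology).
#' Mouse proteins absent from the mapping are reported, never silently
#' dropped. When several mouse proteins collapse onto one human accession
#' the representative with the largest `abs(log2fc)` is kept and the
#' collapse is recorded in the report.
#'
#' @param proteins `differential_proteins` from [filter_differential()] (any
#'   data frame with `protein_id`, `log2fc`, `direction` works).
#' @param pairs orthologue pair table from [read_ortholog_table()].
#' @param min_confidence minimum confidence retained (default 1.0, the
#'   seed-orthologue score).
#' @return list with elements `mapped` (data frame: `human_id` plus the
#'   input columns, one row per retained (mouse, human) pair after
#'   collapses), `unmapped` (character vector of mouse accessions) and
#'   `collapsed` (data frame of many-to-one collapses, possibly empty).
#' @export
map_to_human <- function(proteins, pairs, min_confidence = 1.0) {
  if (!nrow(pairs) && nrow(proteins))
    stop("map_to_human: empty orthologue mapping table")
  pairs <- pairs[pairs$confidence >= min_confidence, , drop = FALSE]
  if (anyDuplicated(pairs[, c("mouse_id", "human_id")]))
    stop("map_to_human: mapping pairs must be deduplicated")

  merged <- merge(proteins, pairs[, c("mouse_id", "human_id")],
                  by.x = "protein_id", by.y = "mouse_id", sort = FALSE)
  unmapped <- setdiff(proteins$protein_id, pairs$mouse_id)

  collapsed <- data.frame(human_id = character(), kept_mouse_id = character(),
                          dropped_mouse_id = character(),
                          stringsAsFactors = FALSE)
  if (nrow(merged)) {
    # deterministic order before resolving many-to-one collapses
    merged <- merged[order(merged$human_id, -abs(merged$log2fc),
                           merged$protein_id), , drop = FALSE]
    dup <- duplicated(merged$human_id)
    if (any(dup)) {
      kept <- merged[!dup, c("human_id", "protein_id")]
      lost <- merged[dup, c("human_id", "protein_id")]
      collapsed <- data.frame(
        human_id = lost$human_id,
        kept_mouse_id = kept$protein_id[match(lost$human_id, kept$human_id)],
        dropped_mouse_id = lost$protein_id, stringsAsFactors = FALSE)
      message("map_to_human: ", nrow(collapsed),
              " many-to-one collapse(s); kept extreme |log2fc| representative")
      merged <- merged[!dup, , drop = FALSE]
    }
    merged <- merged[order(match(merged$protein_id, proteins$protein_id),
                           merged$human_id), , drop = FALSE]
  }
  mapped <- merged[, c("human_id",
                       setdiff(names(proteins), "human_id")), drop = FALSE]
  names(mapped)[names(mapped) == "protein_id"] <- "mouse_id"
  rownames(mapped) <- NULL
  list(mapped = mapped, unmapped = unmapped, collapsed = collapsed)
}
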