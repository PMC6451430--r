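#' Sign of a protein's contribution to a process
#'
#' Combines the protein's abundance direction with its curated effect on
#' the process: a more-abundant activator or a less-abundant inhibitor
#' pushes the process up (stimulatory); a more-abundant inhibitor or a
#' less-abundant activator pushes it down (inhibitory).
#'
#' @param direction `"up"` or `"down"` (abundance in autophagy-impaired vs
#'   wild type).
#' @param effect `"activation"` or `"inhibition"` (curated effect on the
#'   process).
#' @return `"stimulatory"` or `"inhibitory"` (vectorized).
#' @export
#' @examples
#' contribution_sign("up", "activation")    # stimulatory
#' contribution_sign("down", "activation")  # inhibitory
contribution_sign <- function(direction, effect) {
  stopifnot(all(direction %in% c("up", "down")),
            all(effect %in% c("activation", "inhibition")))
  ifelse((direction == "up") == (effect == "activation"),
         "stimulatory", "inhibitory")
}

#' Aggregate per-process contribution signs into a trend call
#'
#' A process is upregulated when strictly more than `threshold` of its
#' contributions are stimulatory, downregulated when strictly more than
#' `threshold` are inhibitory, and dually modulated otherwise — so a
#' fraction of exactly 70\% is dual.
#'
#' @param contributions character vector of `"stimulatory"` /
#'   `"inhibitory"`.
#' @param threshold majority fraction, default 0.70.
#' @return list with `n_stimulatory`, `n_inhibitory`,
#'   `fraction_stimulatory` and `classification` (`"upregulated"`,
#'   `"downregulated"` or `"dual"`).
#' @export
#' @examples
#' aggregate_trend(rep(c("inhibitory", "stimulatory"), c(19, 6)))
aggregate_trend <- function(contributions, threshold = 0.70) {
  if (!length(contributions))
    stop("aggregate_trend: no contributions (no-evidence)")
  stopifnot(all(contributions %in% c("stimulatory", "inhibitory")))
  n_s <- sum(contributions == "stimulatory")
  n_i <- length(contributions) - n_s
  f_s <- n_s / (n_s + n_i)
  cls <- if (f_s > threshold) "upregulated"
         else if (1 - f_s > threshold) "downregulated"
         else "dual"
  list(n_stimulatory = n_s, n_inhibitory = n_i,
       fraction_stimulatory = f_s, classification = cls)
}

#' Classify the aggregated trend of every annotated process
#'
#' Restricts the curated effect table to in-context rows and to proteins in
#' the supplied (targeted differential) list, forms one contribution per
#' (protein, process) link via [contribution_sign()], and calls each
#' process's trend with [aggregate_trend()]. A protein annotated on several
#' processes contributes once to each; receptor multiplicity does not
#' multiply contributions.
#'
#' @param proteins data frame with columns `human_id` and `direction`.
#' @param effects effect table from [read_effect_table()] (protein ids in
#'   the human space).
#' @param cfg a [filter_config()] (supplies `trend_threshold`).
#' @return data frame of class `trend_results` with one row per process
#'   (`process_id`, `process_label`, `n_stimulatory`, `n_inhibitory`,
#'   `fraction_stimulatory`, `classification`), sorted by `process_id`.
#'   Attribute `"unannotated"` lists proteins with no in-context effect
#'   annotation.
#' @export
classify_all_processes <- function(proteins, effects, cfg = filter_config()) {
  eff <- effects[effects$in_context &
                   effects$protein_id %in% proteins$human_id, , drop = FALSE]
  unannotated <- setdiff(proteins$human_id, eff$protein_id)
  if (!nrow(eff)) {
    out <- data.frame(process_id = character(), process_label = character(),
                      n_stimulatory = integer(), n_inhibitory = integer(),
                      fraction_stimulatory = numeric(),
                      classification = character(), stringsAsFactors = FALSE)
    attr(out, "unannotated") <- unannotated
    class(out) <- c("trend_results", "data.frame")
    return(out)
  }
  dir <- proteins$direction[match(eff$protein_id, proteins$human_id)]
  eff$sign <- contribution_sign(dir, eff$effect)

  out <- do.call(rbind, lapply(split(eff, eff$process_id), function(g) {
    tr <- aggregate_trend(g$sign, threshold = cfg$trend_threshold)
    data.frame(process_id = g$process_id[1],
               process_label = g$process_label[1],
               n_stimulatory = tr$n_stimulatory,
               n_inhibitory = tr$n_inhibitory,
               fraction_stimulatory = tr$fraction_stimulatory,
               classification = tr$classification, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$process_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unannotated") <- unannotated
  class(out) <- c("trend_results", "data.frame")
  out
}
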