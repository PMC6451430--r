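#' One-factor (one-way) ANOVA p-value
#'
#' Classic equal-variance one-way ANOVA across replicate groups. For two
#' groups the p-value equals that of the equal-variance two-sample t-test
#' (F = t^2). Intensities should normally be log-transformed upstream (see
#' [filter_differential()]).
#'
#' Degenerate inputs follow fixed conventions: if the within-group variance
#' is zero in every group, p is 1 when all group means coincide and 0
#' otherwise (perfect separation passes any alpha).
#'
#' @param groups list of numeric vectors, one per condition, each of length
#'   at least 2.
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' one_factor_anova(list(c(4.1, 4.3, 4.2), c(5.0, 5.2, 5.1)))
one_factor_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  n <- lengths(groups)
  if (any(n < 2L))
    stop("one_factor_anova: each group needs >= 2 replicates")
  k <- length(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw <= 0) {
    return(if (ssb <= 0) 1 else 0)
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  stats::pf(f, k - 1, N - k, lower.tail = FALSE)
}

#' Signed relative fold-change
#'
#' Progenesis-style convention: the ratio of condition means, reported with
#' magnitude at least 1 and a direction sign. Returns `KO/WT` when the
#' knockout mean is at least the wild-type mean, and `-(WT/KO)` otherwise,
#' so `+2` means twice as abundant on autophagy impairment and `-2` half.
#'
#' @param mean_wt,mean_ko positive condition means (after any intensity
#'   floor).
#' @return signed numeric with `abs(value) >= 1`.
#' @export
#' @examples
#' relative_fold_change(10, 20)  # +2
#' relative_fold_change(20, 10)  # -2
relative_fold_change <- function(mean_wt, mean_ko) {
  if (any(mean_wt <= 0) || any(mean_ko <= 0))
    stop("relative_fold_change: condition means must be positive")
  ifelse(mean_ko >= mean_wt, mean_ko / mean_wt, -(mean_wt / mean_ko))
}

#' Identify differentially abundant proteins
#'
#' Applies the differential-abundance filter to an abundance table: raw
#' one-way ANOVA `p < p_max` (strict), absolute relative fold-change
#' `>= abs_fc_min` (inclusive) and unique peptides `>= min_peptides`
#' (inclusive). No multiple-testing correction is applied at this stage.
#'
#' Statistics are computed here when absent from the table: the ANOVA on
#' log2-transformed intensities by default (a configurable intensity floor —
#' half the smallest nonzero intensity in the table — guards zeros), the
#' fold-change on arithmetic means of the untransformed normalized
#' intensities. Pre-computed `anova_p` / `rel_fc` columns are respected.
#'
#' @param records an `abundance_table` from [read_abundance_table()].
#' @param cfg a [filter_config()].
#' @param anova_scale `"log2"` (default) or `"raw"` intensities for the
#'   ANOVA.
#' @param floor intensity floor; default half the smallest nonzero intensity
#'   in the table.
#' @return data frame of class `differential_proteins` with columns
#'   `protein_id`, `log2fc`, `direction` (`"up"`/`"down"`), `anova_p`,
#'   `rel_fc`, `unique_peptides`, in input order. The full annotated input
#'   (all proteins with computed statistics) is attached as attribute
#'   `"annotated"`.
#' @export
filter_differential <- function(records, cfg = filter_config(),
                                anova_scale = c("log2", "raw"),
                                floor = NULL) {
  stopifnot(inherits(records, "abundance_table"))
  anova_scale <- match.arg(anova_scale)
  wt <- unclass(records$wt)
  ko <- unclass(records$ko)
  n <- nrow(records)

  if (is.null(floor)) {
    pos <- c(wt, ko)
    pos <- pos[pos > 0]
    floor <- if (length(pos)) min(pos) / 2 else 1
  }
  wt_f <- pmax(wt, floor)
  ko_f <- pmax(ko, floor)

  anova_p <- records$anova_p
  need_p <- which(is.na(anova_p))
  if (length(need_p)) {
    tw <- if (anova_scale == "log2") log2(wt_f) else wt_f
    tk <- if (anova_scale == "log2") log2(ko_f) else ko_f
    anova_p[need_p] <- vapply(need_p, function(i)
      one_factor_anova(list(tw[i, ], tk[i, ])), numeric(1))
  }

  rel_fc <- records$rel_fc
  need_fc <- which(is.na(rel_fc))
  if (length(need_fc)) {
    rel_fc[need_fc] <- relative_fold_change(rowMeans(wt_f)[need_fc],
                                            rowMeans(ko_f)[need_fc])
  }
  log2fc <- sign(rel_fc) * log2(abs(rel_fc))

  annotated <- data.frame(protein_id = records$protein_id,
                          anova_p = anova_p, rel_fc = rel_fc,
                          log2fc = log2fc,
                          unique_peptides = records$unique_peptides,
                          stringsAsFactors = FALSE)

  keep <- anova_p < cfg$p_max &
    abs(rel_fc) >= cfg$abs_fc_min &
    records$unique_peptides >= cfg$min_peptides
  out <- annotated[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- out[, c("protein_id", "log2fc", "direction", "anova_p", "rel_fc",
                 "unique_peptides")]
  rownames(out) <- NULL
  attr(out, "annotated") <- annotated
  class(out) <- c("differential_proteins", "data.frame")
  out
}
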