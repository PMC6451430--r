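# Shared fixture builders. A single small planted scenario is generated once
# and reused across test files; its size keeps the whole suite fast while
# still exercising every channel.

small_spec <- function(seed = 11L, ...) {
  scenario_spec(n_proteins = 150L, n_differential = 40L,
                n_processes = 6L,
                process_majorities = c(0.8, 0.8, 0.2, 0.2, 0.5, 0.5),
                n_markers = 20L, markers_in_de = 12L,
                n_extra_de_transcripts = 30L, seed = seed, ...)
}

small_bundle_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(small_bundle_cache$b))
    small_bundle_cache$b <- generate_scenario(small_spec())
  small_bundle_cache$b
}

# abundance table built directly in code (no file round trip)
make_abundance <- function(protein_id, wt, ko, unique_peptides,
                           anova_p = NA_real_, rel_fc = NA_real_) {
  n <- length(protein_id)
  out <- data.frame(protein_id = protein_id,
                    unique_peptides = as.integer(unique_peptides),
                    stringsAsFactors = FALSE)
  out$wt <- wt
  out$ko <- ko
  out$anova_p <- rep_len(anova_p, n)
  out$rel_fc <- rep_len(rel_fc, n)
  out$log2fc <- rep(NA_real_, n)
  class(out) <- c("abundance_table", "data.frame")
  out
}

# independent naive motif oracle: explicit per-window membership loop
naive_motif_scan <- function(sequence, motif) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  m <- length(motif$pattern)
  hits <- integer()
  if (length(chars) >= m) {
    for (s in 1:(length(chars) - m + 1)) {
      ok <- TRUE
      for (j in 1:m) {
        p <- motif$pattern[[j]]
        unrestricted <- length(p) == 20L
        res <- chars[s + j - 1]
        if (!(res %in% p || (unrestricted && res == "X"))) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, s)
    }
  }
  hits
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
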