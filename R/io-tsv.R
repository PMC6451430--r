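# Readers and writers for every table the pipeline touches. All files are
# tab-separated with a header row and a fixed column order; doubles are
# written with "%.17g" so every writer/reader pair round-trips bit-losslessly.

fmt_double <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Deterministic TSV writer: doubles via fmt_double, everything else as-is.
write_tsv_table <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- fmt_double(out[[nm]])
  }
  ok <- tryCatch({
    write.table(out, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

read_tsv_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, colClasses = "character",
                   na.strings = NULL)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("table '", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  df
}

# Convert a character column to numeric; cells that are not parseable numbers
# (including literal "NA" / empty) raise an error citing the 1-based data row
# unless na_ok, in which case they become NA.
as_numeric_col <- function(x, col, path, na_ok = FALSE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) && !na_ok) {
    stop("non-numeric value '", x[bad[1]], "' in column '", col,
         "' of '", path, "' at row ", bad[1])
  }
  out
}

#' Column-name mapping for abundance tables
#'
#' Label-free exports differ in column naming; the mapping is explicit
#' configuration, never sniffed. With `wt`/`ko` left `NULL` the intensity
#' columns are taken to be those named `wt_1, wt_2, ...` and `ko_1, ko_2,
#' ...`.
#'
#' @param protein_id,unique_peptides column names.
#' @param wt,ko character vectors naming the per-replicate intensity columns
#'   of each condition, or `NULL` for prefix autodetection.
#' @param missing `"strict"` rejects missing/non-numeric intensity cells with
#'   a parse error citing the row; `"impute"` replaces missing cells with
#'   half the smallest nonzero intensity in the table.
#' @return A list of class `abundance_dialect`.
#' @export
abundance_dialect <- function(protein_id = "protein_id",
                              wt = NULL, ko = NULL,
                              unique_peptides = "unique_peptides",
                              missing = c("strict", "impute")) {
  structure(list(protein_id = protein_id, wt = wt, ko = ko,
                 unique_peptides = unique_peptides,
                 missing = match.arg(missing)),
            class = "abundance_dialect")
}

#' Read a quantified protein abundance table
#'
#' One row per protein: accession, per-replicate normalized intensities for
#' the wild-type and knockout conditions, and the unique-peptide count.
#' Optional pre-computed `anova_p`, `rel_fc` and `log2fc` columns are kept
#' when present (e.g. from a Progenesis-style export); otherwise
#' [filter_differential()] computes them.
#'
#' @param path TSV file with a header row.
#' @param dialect an [abundance_dialect()] mapping column names.
#' @return A data frame of class `abundance_table` with columns
#'   `protein_id`, `unique_peptides`, matrix columns `wt` and `ko`
#'   (replicates as matrix columns), and `anova_p`, `rel_fc`, `log2fc`
#'   (NA when absent from the file).
#' @export
read_abundance_table <- function(path, dialect = abundance_dialect()) {
  df <- read_tsv_table(path, required = c(dialect$protein_id,
                                          dialect$unique_peptides))
  wt_cols <- dialect$wt %||% grep("^wt_", names(df), value = TRUE)
  ko_cols <- dialect$ko %||% grep("^ko_", names(df), value = TRUE)
  if (!length(wt_cols) || !length(ko_cols))
    stop("table '", path, "' lacks mandatory column(s): ",
         "wild-type and/or knockout intensity columns (dialect wt/ko)")
  missing <- setdiff(c(wt_cols, ko_cols), names(df))
  if (length(missing))
    stop("table '", path, "' lacks mandatory column(s): ",
         paste(missing, collapse = ", "))

  strict <- identical(dialect$missing, "strict")
  wt <- do.call(cbind, lapply(wt_cols, function(cl)
    as_numeric_col(df[[cl]], cl, path, na_ok = !strict)))
  ko <- do.call(cbind, lapply(ko_cols, function(cl)
    as_numeric_col(df[[cl]], cl, path, na_ok = !strict)))
  dimnames(wt) <- list(NULL, wt_cols)
  dimnames(ko) <- list(NULL, ko_cols)
  if (!strict && (anyNA(wt) || anyNA(ko))) {
    floor_val <- min(c(wt, ko)[c(wt, ko) > 0], na.rm = TRUE) / 2
    wt[is.na(wt)] <- floor_val
    ko[is.na(ko)] <- floor_val
  }
  if (any(wt < 0, na.rm = TRUE) || any(ko < 0, na.rm = TRUE))
    stop("negative intensity in '", path, "'")

  opt <- function(col) {
    if (col %in% names(df)) as_numeric_col(df[[col]], col, path, na_ok = TRUE)
    else rep(NA_real_, nrow(df))
  }
  out <- data.frame(protein_id = df[[dialect$protein_id]],
                    unique_peptides = as.integer(
                      as_numeric_col(df[[dialect$unique_peptides]],
                                     dialect$unique_peptides, path)),
                    stringsAsFactors = FALSE)
  out$wt <- wt
  out$ko <- ko
  out$anova_p <- opt("anova_p")
  out$rel_fc <- opt("rel_fc")
  out$log2fc <- opt("log2fc")
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Write an abundance table
#'
#' Inverse of [read_abundance_table()] under the default dialect: matrix
#' columns are flattened to `wt_1..wt_r` / `ko_1..ko_r`.
#'
#' @param x an `abundance_table`.
#' @param path output TSV path.
#' @export
write_abundance_table <- function(x, path) {
  stopifnot(inherits(x, "abundance_table"))
  flat <- data.frame(protein_id = x$protein_id, stringsAsFactors = FALSE)
  wt <- unclass(x$wt); ko <- unclass(x$ko)
  colnames(wt) <- paste0("wt_", seq_len(ncol(wt)))
  colnames(ko) <- paste0("ko_", seq_len(ncol(ko)))
  flat <- cbind(flat, as.data.frame(wt), as.data.frame(ko))
  flat$unique_peptides <- x$unique_peptides
  flat$anova_p <- x$anova_p
  flat$rel_fc <- x$rel_fc
  flat$log2fc <- x$log2fc
  write_tsv_table(flat, path)
}

#' Read a transcript differential-expression table
#'
#' Sleuth-style output: gene identifier, log2 fold-change and q-value.
#'
#' @param path TSV with columns `gene_id`, `log2fc`, `q_value`.
#' @return data frame with those columns, q-values validated to lie in
#'   `[0, 1]`.
#' @export
read_transcript_table <- function(path) {
  df <- read_tsv_table(path, required = c("gene_id", "log2fc", "q_value"))
  out <- data.frame(gene_id = df$gene_id,
                    log2fc = as_numeric_col(df$log2fc, "log2fc", path,
                                            na_ok = TRUE),
                    q_value = as_numeric_col(df$q_value, "q_value", path,
                                             na_ok = TRUE),
                    stringsAsFactors = FALSE)
  bad <- which(!is.na(out$q_value) & (out$q_value < 0 | out$q_value > 1))
  if (length(bad))
    stop("q_value outside [0, 1] in '", path, "' at row ", bad[1])
  out
}

#' @rdname read_transcript_table
#' @param x data frame to write.
#' @export
write_transcript_table <- function(x, path) {
  write_tsv_table(x[, c("gene_id", "log2fc", "q_value")], path)
}

#' Read an orthologue mapping table
#'
#' InParanoid-style mouse-to-human pairs with a confidence score in
#' `[0, 1]`. Duplicate (mouse, human) pairs are rejected.
#'
#' @param path TSV with columns `mouse_id`, `human_id`, `confidence`.
#' @return data frame with those columns.
#' @export
read_ortholog_table <- function(path) {
  df <- read_tsv_table(path, required = c("mouse_id", "human_id",
                                          "confidence"))
  out <- data.frame(mouse_id = df$mouse_id, human_id = df$human_id,
                    confidence = as_numeric_col(df$confidence, "confidence",
                                                path),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[, c("mouse_id", "human_id")]))
    stop("duplicate (mouse_id, human_id) pairs in '", path, "'")
  if (any(out$confidence < 0 | out$confidence > 1))
    stop("confidence outside [0, 1] in '", path, "'")
  out
}

#' @rdname read_ortholog_table
#' @param x data frame to write.
#' @export
write_ortholog_table <- function(x, path) {
  write_tsv_table(x[, c("mouse_id", "human_id", "confidence")], path)
}

#' Read a one-column protein or gene list
#'
#' Accepts either a one-identifier-per-line file (an optional `protein_id` /
#' `gene_id` header line is skipped) or a single GMT-style line
#' (`name<TAB>description<TAB>id1<TAB>id2...`).
#'
#' @param path input file.
#' @return character vector of identifiers, duplicates removed, order kept.
#' @export
read_id_list <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 1L && length(strsplit(lines, "\t")[[1]]) >= 3L) {
    ids <- strsplit(lines, "\t")[[1]][-(1:2)]
  } else {
    ids <- sub("\t.*$", "", lines)
    ids <- ids[!ids %in% c("protein_id", "gene_id", "id")]
  }
  unique(ids)
}

#' @rdname read_id_list
#' @param ids character vector to write (one per line, `protein_id` header).
#' @export
write_id_list <- function(ids, path) {
  writeLines(c("protein_id", ids), path)
  invisible(path)
}

#' Read a protein domain annotation table
#'
#' UniProt/Pfam-style annotations; duplicate (protein, domain) pairs are
#' collapsed.
#'
#' @param path TSV with columns `protein_id`, `domain_accession`.
#' @return data frame with those columns, unique rows.
#' @export
read_domain_table <- function(path) {
  df <- read_tsv_table(path, required = c("protein_id", "domain_accession"))
  unique(df[, c("protein_id", "domain_accession")])
}

#' @rdname read_domain_table
#' @param x data frame to write.
#' @export
write_domain_table <- function(x, path) {
  write_tsv_table(x[, c("protein_id", "domain_accession")], path)
}

#' Read a domain-domain interaction pair list
#'
#' DOMINE-style pairs; stored canonicalized (unordered, `domain_a <=
#' domain_b` lexicographically) and unique.
#'
#' @param path TSV with columns `domain_a`, `domain_b`.
#' @return data frame with canonicalized unique pairs.
#' @export
read_ddi_table <- function(path) {
  df <- read_tsv_table(path, required = c("domain_a", "domain_b"))
  canonicalize_ddi(df)
}

#' @rdname read_ddi_table
#' @param x data frame to write.
#' @export
write_ddi_table <- function(x, path) {
  write_tsv_table(canonicalize_ddi(x), path)
}

canonicalize_ddi <- function(ddi) {
  a <- pmin(ddi$domain_a, ddi$domain_b)
  b <- pmax(ddi$domain_a, ddi$domain_b)
  unique(data.frame(domain_a = a, domain_b = b, stringsAsFactors = FALSE))
}

#' Read a curated process-effect annotation table
#'
#' One row per (protein, GO biological process) link with the curated effect
#' (activation or inhibition) and the intestinal-context keep/discard flag.
#'
#' @param path TSV with columns `protein_id`, `process_id`, `process_label`,
#'   `effect`, `in_context`.
#' @return data frame; `in_context` is logical, `effect` one of
#'   `"activation"`/`"inhibition"` (required for in-context rows).
#' @export
read_effect_table <- function(path) {
  df <- read_tsv_table(path, required = c("protein_id", "process_id",
                                          "process_label", "effect",
                                          "in_context"))
  df$in_context <- df$in_context %in% c("TRUE", "true", "1", "yes")
  bad <- which(df$in_context & !df$effect %in% c("activation", "inhibition"))
  if (length(bad))
    stop("effect must be activation/inhibition for in-context rows; '",
         path, "' row ", bad[1])
  if (anyDuplicated(df[, c("protein_id", "process_id")]))
    stop("duplicate (protein_id, process_id) rows in '", path, "'")
  df[, c("protein_id", "process_id", "process_label", "effect", "in_context")]
}

#' @rdname read_effect_table
#' @param x data frame to write.
#' @export
write_effect_table <- function(x, path) {
  write_tsv_table(x[, c("protein_id", "process_id", "process_label",
                        "effect", "in_context")], path)
}

#' Read/write autophagy-target evidence tables
#'
#' One row per (protein, receptor, evidence type, detail) targeting
#' assertion. The writer emits a fixed column order sorted by
#' `(human_id, receptor, evidence_type, detail)` so identical evidence sets
#' produce byte-identical files; write-then-read is the identity.
#'
#' @param path TSV path.
#' @return `read_evidence_table()`: data frame with columns `human_id`,
#'   `receptor`, `evidence_type`, `detail`.
#' @export
read_evidence_table <- function(path) {
  df <- read_tsv_table(path, required = c("human_id", "receptor",
                                          "evidence_type", "detail"))
  df[, c("human_id", "receptor", "evidence_type", "detail")]
}

#' @rdname read_evidence_table
#' @param x evidence data frame (possibly zero rows).
#' @export
write_evidence_table <- function(x, path) {
  cols <- c("human_id", "receptor", "evidence_type", "detail")
  if (nrow(x)) {
    x <- x[order(x$human_id, x$receptor, x$evidence_type, x$detail), cols,
           drop = FALSE]
  } else {
    x <- x[, cols, drop = FALSE]
  }
  write_tsv_table(x, path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences.
#' @return named character vector (names truncated at the first whitespace).
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (file.size(path) == 0) return(setNames(character(), character()))
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' @rdname read_protein_fasta
#' @param seqs named character vector of sequences.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(seqs), filepath = path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
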