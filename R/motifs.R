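# Short-linear-motif definitions and scanning over the 20-letter amino-acid
# alphabet. A motif is a list of positional alphabets; "x" positions accept
# any standard residue. The ambiguity character X in a sequence is legal but
# never satisfies a restricted position.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Define a position-restricted sequence motif
#'
#' @param name motif name.
#' @param pattern list of character vectors, one per position: the residues
#'   allowed there. A vector equal to the full 20-letter alphabet (or the
#'   string `"x"`) is an unrestricted position.
#' @param source free-text provenance note.
#' @return object of class `motif_definition`.
#' @seealso [parse_motif()] for the bracket syntax, [scan_motif()].
#' @export
motif_definition <- function(name, pattern, source = "") {
  stopifnot(is.list(pattern), length(pattern) >= 3L)
  pattern <- lapply(pattern, function(p) {
    if (identical(p, "x")) return(AA_ALPHABET)
    p <- sort(unique(toupper(p)))
    if (!all(p %in% AA_ALPHABET))
      stop("motif_definition: positional alphabet outside the amino-acid ",
           "alphabet: ", paste(setdiff(p, AA_ALPHABET), collapse = ""))
    p
  })
  structure(list(name = name, pattern = pattern, source = source),
            class = "motif_definition")
}

#' Parse a bracket-syntax motif string
#'
#' `"[WFY]xx[LIV]"` denotes a 4-position motif with restricted first and
#' last positions; lower-case `x` is an unrestricted position.
#'
#' @param text motif string.
#' @inheritParams motif_definition
#' @return a [motif_definition()].
#' @export
#' @examples
#' parse_motif("[WFY]xx[LIV]", name = "LIR-core")
parse_motif <- function(text, name = text, source = "") {
  chars <- strsplit(text, "")[[1]]
  pattern <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= length(chars) && chars[j] != "]") j <- j + 1L
      if (j > length(chars)) stop("parse_motif: unclosed '[' in ", text)
      pattern[[length(pattern) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else if (ch %in% c("x", "X", ".")) {
      pattern[[length(pattern) + 1L]] <- "x"
      i <- i + 1L
    } else {
      pattern[[length(pattern) + 1L]] <- ch
      i <- i + 1L
    }
  }
  motif_definition(name, pattern, source)
}

#' The canonical LIR core motif [WFY]xx[LIV]
#'
#' The minimal LC3-interacting-region core: an aromatic residue followed two
#' positions later by a large hydrophobic residue.
#' @return a [motif_definition()].
#' @export
lir_core_motif <- function() {
  parse_motif("[WFY]xx[LIV]", name = "LIR-core", source = "canonical core")
}

#' The extended xLIR motif
#'
#' The six-position extended LIR definition used by iLIR-style scans:
#' `[ADEFGLPRSK][DEGMSTV][WFY][DEILQTV][ADEFHIKLMPSTV][ILV]`.
#' @return a [motif_definition()].
#' @export
xlir_motif <- function() {
  parse_motif("[ADEFGLPRSK][DEGMSTV][WFY][DEILQTV][ADEFHIKLMPSTV][ILV]",
              name = "xLIR", source = "extended LIR definition")
}

#' Scan a protein sequence for a motif
#'
#' Reports every (possibly overlapping) window whose residues all belong to
#' the motif's positional alphabets, in ascending start position. The
#' ambiguity residue `X` is accepted in the sequence but only matches
#' unrestricted positions.
#'
#' @param sequence amino-acid string.
#' @param motif a [motif_definition()].
#' @return data frame with columns `start` (1-based) and `match`; zero rows
#'   when the sequence is shorter than the motif or has no hit.
#' @export
#' @examples
#' scan_motif("AAWEELAA", lir_core_motif())  # start 3, "WEEL"
scan_motif <- function(sequence, motif) {
  stopifnot(inherits(motif, "motif_definition"))
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET, "X"))
  if (length(bad))
    stop("illegal sequence character '", chars[bad[1]], "' at position ",
         bad[1])
  m <- length(motif$pattern)
  L <- length(chars)
  empty <- data.frame(start = integer(), match = character(),
                      stringsAsFactors = FALSE)
  if (L < m) return(empty)
  starts <- seq_len(L - m + 1L)
  ok <- rep(TRUE, length(starts))
  for (j in seq_len(m)) {
    allowed <- motif$pattern[[j]]
    res <- chars[starts + j - 1L]
    hit <- res %in% allowed
    if (length(allowed) == length(AA_ALPHABET)) hit <- hit | res == "X"
    ok <- ok & hit
  }
  if (!any(ok)) return(empty)
  st <- starts[ok]
  data.frame(start = st,
             match = vapply(st, function(s)
               paste(chars[s:(s + m - 1L)], collapse = ""), character(1)),
             stringsAsFactors = FALSE)
}

# Translate a motif to a base-R regular expression (used for rejection
# sampling in the generator; the scanner itself never goes through regex).
motif_regex <- function(motif) {
  paste0(vapply(motif$pattern, function(p) {
    if (length(p) == length(AA_ALPHABET)) "." else
      paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
}
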