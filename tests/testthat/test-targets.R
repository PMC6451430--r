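test_that("motif scanning matches the worked examples", {
  hits <- scan_motif("AAWEELAA", lir_core_motif())
  expect_equal(hits$start, 3L)
  expect_equal(hits$match, "WEEL")

  # every residue of EDYVVL belongs to the matching xLIR positional alphabet
  hits2 <- scan_motif("EDYVVL", xlir_motif())
  expect_equal(hits2$start, 1L)
  expect_equal(hits2$match, "EDYVVL")

  expect_equal(nrow(scan_motif("", lir_core_motif())), 0L)
  expect_equal(nrow(scan_motif("WEL", lir_core_motif())), 0L)  # too short
  expect_error(scan_motif("AAW3EL", lir_core_motif()), "position 4")
  # X is legal but never matches a restricted position
  expect_equal(nrow(scan_motif("AAXEELAA", lir_core_motif())), 0L)
  expect_equal(scan_motif("AWXXLA", lir_core_motif())$start, 2L)
})

test_that("overlapping matches are all reported in ascending order", {
  hits <- scan_motif("WAALWAAL", lir_core_motif())
  expect_equal(hits$start, c(1L, 5L))
  hits2 <- scan_motif("WWILIV", lir_core_motif())
  expect_equal(hits2$start, c(1L, 2L))
})

test_that("motif parser handles brackets, x positions and bad alphabets", {
  m <- parse_motif("[WFY]x[DE]L")
  expect_length(m$pattern, 4L)
  expect_equal(m$pattern[[3]], c("D", "E"))
  expect_equal(m$pattern[[4]], "L")
  expect_length(m$pattern[[2]], 20L)
  expect_error(parse_motif("[WBZ]xx[LIV]"), "alphabet")
  expect_error(motif_definition("short", list("W", "x")), ">= 3")
})

test_that("DDI prediction follows the shared-pair definition", {
  cand <- data.frame(protein_id = c("P1", "P2"),
                     domain_accession = c("PF_X", "PF_Y"),
                     stringsAsFactors = FALSE)
  ddi <- data.frame(domain_a = "WD40", domain_b = "PF_X",
                    stringsAsFactors = FALSE)
  expect_equal(predict_ddi_targets("WD40", cand, ddi), "P1")
  # unordered pairs: reversed storage predicts the same target
  ddi_rev <- data.frame(domain_a = "PF_X", domain_b = "WD40",
                        stringsAsFactors = FALSE)
  expect_equal(predict_ddi_targets("WD40", cand, ddi_rev), "P1")
  # candidates with no domains are never predicted, without error
  expect_equal(predict_ddi_targets("WD40", cand[0, ], ddi), character())
})

test_that("DDI prediction equals an exhaustive double-loop oracle", {
  set.seed(5)
  doms <- sprintf("D%02d", 1:12)
  cand <- data.frame(
    protein_id = rep(sprintf("P%02d", 1:20), times = sample(0:3, 20, TRUE)),
    stringsAsFactors = FALSE)
  cand$domain_accession <- sample(doms, nrow(cand), replace = TRUE)
  cand <- unique(cand)
  ddi <- unique(data.frame(domain_a = sample(doms, 15, TRUE),
                           domain_b = sample(doms, 15, TRUE),
                           stringsAsFactors = FALSE))
  query <- sample(doms, 3)

  oracle <- character()
  for (p in unique(cand$protein_id)) {
    pdoms <- cand$domain_accession[cand$protein_id == p]
    found <- FALSE
    for (q in query) for (d in pdoms) for (r in seq_len(nrow(ddi))) {
      pair <- sort(c(ddi$domain_a[r], ddi$domain_b[r]))
      if (identical(sort(c(q, d)), pair)) found <- TRUE
    }
    if (found) oracle <- c(oracle, p)
  }
  expect_equal(predict_ddi_targets(query, cand, ddi), sort(oracle))
})

test_that("evidence collection unions channels and deduplicates", {
  prot <- data.frame(human_id = c("A", "B", "C"), stringsAsFactors = FALSE)
  # A only in the LC3 experimental list
  ev <- collect_evidence(prot, interactors = list(LC3 = "A"))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$receptor, "LC3")
  expect_equal(ev$evidence_type, "experimental")
  # C in no source: zero rows
  expect_false("C" %in% ev$human_id)

  # planted xLIR motif plus a WD40-partner domain: two channels fire
  seqs <- c(B = "AAAAEDYVVLAAAA")
  domains <- data.frame(protein_id = c("ATG16L1", "B"),
                        domain_accession = c("WD40", "PF_B"),
                        stringsAsFactors = FALSE)
  ddi <- data.frame(domain_a = "WD40", domain_b = "PF_B",
                    stringsAsFactors = FALSE)
  ev2 <- collect_evidence(prot, sequences = seqs,
                          interactors = list(LC3 = "A"),
                          domains = domains, ddi = ddi)
  b_rows <- ev2[ev2$human_id == "B", ]
  expect_gte(nrow(b_rows), 2L)
  expect_setequal(b_rows$evidence_type, c("lir_motif", "ddi"))
  expect_setequal(b_rows$receptor, c("LC3", "ATG16L1"))

  # no configured source at all is an error
  expect_error(collect_evidence(prot, sequences = NULL, lir_motif = NULL),
               "no evidence source")
})

test_that("adding an evidence source never shrinks any receptor set", {
  b <- small_bundle()
  prot <- data.frame(human_id = b$truth$proteins$human_id,
                     stringsAsFactors = FALSE)
  base <- collect_evidence(prot, interactors = b$interactors)
  more <- collect_evidence(prot, sequences = b$sequences,
                           interactors = b$interactors,
                           lir_list = b$lir_list,
                           lir_motif = b$motifs$lir,
                           p62_motif = b$motifs$p62,
                           domains = b$domains, ddi = b$ddi)
  for (rec in c("p62", "LC3", "ATG16L1")) {
    s0 <- unique(base$human_id[base$receptor == rec])
    s1 <- unique(more$human_id[more$receptor == rec])
    expect_true(all(s0 %in% s1))
  }
})

test_that("Venn partition cells are disjoint, exhaustive and correct", {
  ev <- data.frame(human_id = c("A", "B", "B"),
                   receptor = c("p62", "LC3", "ATG16L1"),
                   evidence_type = "experimental", detail = "x",
                   stringsAsFactors = FALSE)
  ov <- overlap_partition(ev)
  expect_equal(unname(ov$cells["p62"]), 1L)
  expect_equal(unname(ov$cells["LC3+ATG16L1"]), 1L)
  expect_equal(sum(ov$cells), 2L)
  expect_equal(ov$fraction_multi, 0.5)

  empty <- overlap_partition(ev[0, ])
  expect_equal(sum(empty$cells), 0L)
  expect_equal(empty$fraction_multi, 0)
  expect_true(empty$empty)
})

test_that("Venn cells match brute-force set algebra on random evidence", {
  set.seed(9)
  recs <- c("p62", "LC3", "ATG16L1")
  ev <- unique(data.frame(
    human_id = sample(sprintf("P%02d", 1:50), 120, replace = TRUE),
    receptor = sample(recs, 120, replace = TRUE),
    evidence_type = "experimental", detail = "x", stringsAsFactors = FALSE))
  ov <- overlap_partition(ev)
  sets <- lapply(recs, function(r) unique(ev$human_id[ev$receptor == r]))
  names(sets) <- recs
  ids <- unique(ev$human_id)
  # oracle: classify every protein by its exact membership signature
  sig <- sapply(ids, function(id)
    paste(recs[vapply(sets, function(s) id %in% s, logical(1))],
          collapse = "+"))
  oracle <- table(sig)
  for (cell in names(ov$cells)) {
    expect_equal(unname(ov$cells[cell]),
                 if (cell %in% names(oracle)) unname(as.integer(oracle[cell]))
                 else 0L)
  }
  expect_equal(sum(ov$cells), length(ids))
  expect_equal(ov$fraction_multi,
               sum(grepl("\\+", sig)) / length(ids))
})
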