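test_that("scenario validation rejects infeasible specifications", {
  expect_error(scenario_spec(frac_targeted = 1.2), "\\[0, 1\\]")
  expect_error(scenario_spec(n_differential = 50, n_proteins = 40),
               "more differential")
  expect_error(scenario_spec(markers_in_de = 90, n_markers = 83),
               "markers_in_de")
  expect_error(scenario_spec(process_majorities = c(0.5, 0.5)),
               "one majority fraction per process")
  expect_error(scenario_spec(turnover_delta = -1), "positive")
})

test_that("generation is deterministic given the seed", {
  b1 <- generate_scenario(small_spec(seed = 99))
  b2 <- generate_scenario(small_spec(seed = 99))
  expect_identical(b1$abundance, b2$abundance)
  expect_identical(b1$sequences, b2$sequences)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_scenario(small_spec(seed = 100))
  expect_false(identical(b1$abundance, b3$abundance))
})

test_that("fixture sets round-trip through the package readers", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(b, dir)
  expect_identical(read_transcript_table(fx$paths$transcripts),
                   b$transcripts)
  expect_identical(read_ortholog_table(fx$paths$orthologs), b$orthologs)
  expect_identical(read_protein_fasta(fx$paths$fasta), b$sequences)
  expect_identical(read_id_list(fx$paths$markers), b$markers)
  for (rec in names(b$interactors))
    expect_identical(read_id_list(fx$paths$interactors[[rec]]),
                     b$interactors[[rec]])
})

test_that("non-target sequences carry no accidental motifs", {
  b <- small_bundle()
  ev_motif <- collect_evidence(
    data.frame(human_id = names(b$sequences), stringsAsFactors = FALSE),
    sequences = b$sequences, interactors = list(),
    lir_motif = b$motifs$lir, p62_motif = b$motifs$p62)
  lir_hits <- unique(ev_motif$human_id[ev_motif$evidence_type == "lir_motif"])
  p62_hits <- unique(ev_motif$human_id[ev_motif$evidence_type == "p62_motif"])
  truth <- b$truth$proteins
  planted_lir <- truth$human_id[grepl("LC3", truth$targeted_by)]
  planted_p62 <- truth$human_id[grepl("p62", truth$targeted_by)]
  # every motif hit is a planted target of the matching receptor; never a
  # bystander (the planted sets are wider: some use list/DDI channels)
  expect_true(all(lir_hits %in% planted_lir))
  expect_true(all(p62_hits %in% planted_p62))
})

test_that("zero replicate noise gives exact planted recovery", {
  b0 <- generate_scenario(small_spec(seed = 5, noise_sd = 0))
  out <- filter_differential(b0$abundance)
  expect_identical(sort(out$protein_id), b0$truth$differential_mouse)
})

test_that("the empty scenario yields valid files and zero counts", {
  sp <- scenario_spec(n_proteins = 0, n_differential = 0, n_markers = 0,
                      markers_in_de = 0, n_extra_de_transcripts = 0,
                      seed = 2)
  b <- generate_scenario(sp)
  dir <- withr::local_tempdir()
  fx <- write_fixture_set(b, dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  res <- suppressMessages(run_pipeline(fx$config))
  expect_equal(res$summary$n_differential, 0L)
  expect_equal(res$summary$n_targeted, 0L)
  expect_equal(res$summary$n_turnover, 0L)
})

test_that("planted direction fraction is recovered within the binomial CI", {
  b <- small_bundle()
  out <- filter_differential(b$abundance)
  n <- nrow(out)
  phat <- mean(out$direction == "up")
  ci <- stats::binom.test(round(0.70 * n), n)$conf.int
  expect_gte(phat, ci[1])
  expect_lte(phat, ci[2])
})
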