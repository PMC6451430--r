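test_that("abundance reader parses well-formed tables and rejects bad ones", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\twt_1\twt_2\tko_1\tko_2\tunique_peptides",
               "P1\t10\t12\t40\t44\t3",
               "P2\t5\t6\t5.5\t6.5\t2",
               "P3\t100\t90\t20\t22\t7"), path)
  tab <- read_abundance_table(path)
  expect_s3_class(tab, "abundance_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$protein_id, c("P1", "P2", "P3"))
  expect_equal(unclass(tab$wt)[1, ], c(wt_1 = 10, wt_2 = 12))
  expect_equal(tab$unique_peptides, c(3L, 2L, 7L))

  # missing mandatory column is a configuration error naming the column
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\twt_1\twt_2\tko_1\tko_2",
               "P1\t1\t2\t3\t4"), path2)
  expect_error(read_abundance_table(path2), "unique_peptides")

  # non-numeric intensity under the strict dialect cites the data row
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\twt_1\twt_2\tko_1\tko_2\tunique_peptides",
               "P1\t1\t2\t3\t4\t2",
               "P2\t1\tNA\t3\t4\t2"), path3)
  expect_error(read_abundance_table(path3), "row 2")

  # the impute dialect fills missing cells with half the smallest nonzero
  tab3 <- read_abundance_table(path3,
                               abundance_dialect(missing = "impute"))
  expect_equal(unname(unclass(tab3$wt)[2, 2]), 0.5)
})

test_that("reader/writer pairs round-trip losslessly", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  p <- function(f) file.path(dir, f)

  write_abundance_table(b$abundance, p("a.tsv"))
  back <- read_abundance_table(p("a.tsv"))
  expect_identical(unclass(back$wt), unclass(b$abundance$wt))
  expect_identical(back$protein_id, b$abundance$protein_id)
  expect_identical(back$unique_peptides, b$abundance$unique_peptides)

  write_transcript_table(b$transcripts, p("t.tsv"))
  expect_identical(read_transcript_table(p("t.tsv")), b$transcripts)

  write_ortholog_table(b$orthologs, p("o.tsv"))
  expect_identical(read_ortholog_table(p("o.tsv")), b$orthologs)

  write_domain_table(b$domains, p("d.tsv"))
  expect_identical(read_domain_table(p("d.tsv")), b$domains)

  write_ddi_table(b$ddi, p("ddi.tsv"))
  expect_identical(read_ddi_table(p("ddi.tsv")), b$ddi)

  write_effect_table(b$effects, p("e.tsv"))
  expect_identical(read_effect_table(p("e.tsv")), b$effects)

  write_id_list(b$markers, p("m.tsv"))
  expect_identical(read_id_list(p("m.tsv")), b$markers)

  write_protein_fasta(b$sequences, p("s.fa"))
  expect_identical(read_protein_fasta(p("s.fa")), b$sequences)
})

test_that("evidence writer sorts deterministically and round-trips", {
  ev <- data.frame(
    human_id = c("H2", "H1"), receptor = c("LC3", "p62"),
    evidence_type = c("experimental", "p62_motif"),
    detail = c("ARN", "m:3:RKAWL"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_table(ev, path)
  back <- read_evidence_table(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$human_id, c("H1", "H2"))  # sorted on write
  # write-then-read is the identity on the sorted form
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_table(back, path2)
  expect_identical(read_evidence_table(path2), back)

  # empty list gives a header-only file that reads back as zero rows
  path3 <- withr::local_tempfile(fileext = ".tsv")
  write_evidence_table(ev[0, ], path3)
  expect_equal(length(readLines(path3)), 1L)
  expect_equal(nrow(read_evidence_table(path3)), 0L)
})

test_that("DDI pairs are canonicalized on read", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_a\tdomain_b", "ZZ\tAA", "AA\tZZ", "AA\tBB"), path)
  ddi <- read_ddi_table(path)
  expect_equal(nrow(ddi), 2L)
  expect_true(all(ddi$domain_a <= ddi$domain_b))
})

test_that("GMT-style marker lines are accepted", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines("paneth_markers\tcurated\tLYZ1\tDEFA5\tMMP7", path)
  expect_equal(read_id_list(path), c("LYZ1", "DEFA5", "MMP7"))
})
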