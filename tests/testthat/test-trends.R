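test_that("contribution sign is the direction/effect product", {
  expect_equal(contribution_sign("up", "activation"), "stimulatory")
  expect_equal(contribution_sign("down", "inhibition"), "stimulatory")
  expect_equal(contribution_sign("up", "inhibition"), "inhibitory")
  expect_equal(contribution_sign("down", "activation"), "inhibitory")
  expect_error(contribution_sign("sideways", "activation"))
})

test_that("aggregated trend reproduces the published worked examples", {
  # apoptosis: 19 of 25 inhibitory (76%) -> downregulated
  apoptosis <- rep(c("inhibitory", "stimulatory"), c(19, 6))
  tr <- aggregate_trend(apoptosis)
  expect_equal(tr$n_inhibitory, 19L)
  expect_equal(tr$fraction_stimulatory, 6 / 25)
  expect_equal(tr$classification, "downregulated")

  # DNA repair: 5 of 7 stimulatory (>71%) -> upregulated
  dna_repair <- rep(c("stimulatory", "inhibitory"), c(5, 2))
  expect_equal(aggregate_trend(dna_repair)$classification, "upregulated")

  # exactly 70% is NOT "more than 70%": dual modulation
  boundary <- rep(c("stimulatory", "inhibitory"), c(7, 3))
  expect_equal(aggregate_trend(boundary)$classification, "dual")

  expect_error(aggregate_trend(character()), "no-evidence")
})

test_that("flipping every contribution swaps up/down and fixes dual", {
  set.seed(3)
  flip <- c(stimulatory = "inhibitory", inhibitory = "stimulatory")
  swap <- c(upregulated = "downregulated", downregulated = "upregulated",
            dual = "dual")
  for (i in 1:50) {
    n <- sample(1:15, 1)
    contrib <- sample(c("stimulatory", "inhibitory"), n, replace = TRUE)
    a <- aggregate_trend(contrib)$classification
    b <- aggregate_trend(unname(flip[contrib]))$classification
    expect_equal(unname(swap[a]), b)
  }
})

test_that("per-process classification handles the small worked cases", {
  cfg <- filter_config()
  prot <- data.frame(human_id = c("A", "B"), direction = c("up", "down"),
                     stringsAsFactors = FALSE)
  eff1 <- data.frame(protein_id = "A", process_id = "GO:1",
                     process_label = "secretion", effect = "activation",
                     in_context = TRUE, stringsAsFactors = FALSE)
  out <- classify_all_processes(prot, eff1, cfg)
  expect_equal(out$classification, "upregulated")  # 1/1 > 0.7
  expect_equal(attr(out, "unannotated"), "B")

  # two proteins opposing on one process: 0.5 each, dual
  # (B is less abundant, so its activation link is an inhibitory push)
  eff2 <- rbind(eff1, data.frame(protein_id = "B", process_id = "GO:1",
                                 process_label = "secretion",
                                 effect = "activation", in_context = TRUE))
  expect_equal(classify_all_processes(prot, eff2, cfg)$classification,
               "dual")

  # out-of-context rows are discarded before counting
  eff3 <- eff2
  eff3$in_context[2] <- FALSE
  expect_equal(classify_all_processes(prot, eff3, cfg)$classification,
               "upregulated")
})

test_that("planted per-process majorities are recovered exactly", {
  b <- small_bundle()
  prot <- b$truth$proteins[b$truth$proteins$targeted_by != "", ]
  out <- classify_all_processes(
    data.frame(human_id = prot$human_id, direction = prot$direction,
               stringsAsFactors = FALSE),
    b$effects)
  truth <- b$truth$processes
  expect_equal(nrow(out), nrow(truth))
  m <- merge(out, truth, by = "process_id")
  expect_equal(m$classification.x, m$classification.y)
  expect_equal(m$n_stimulatory.x, m$n_stimulatory.y)
  expect_equal(m$n_inhibitory.x, m$n_inhibitory.y)
})

test_that("network is tripartite with the expected counts", {
  ev <- data.frame(human_id = "P", receptor = "LC3",
                   evidence_type = "experimental", detail = "ARN",
                   stringsAsFactors = FALSE)
  eff <- data.frame(protein_id = "P", process_id = "GO:1",
                    process_label = "exocytosis", effect = "activation",
                    in_context = TRUE, stringsAsFactors = FALSE)
  prot <- data.frame(human_id = "P", direction = "down",
                     stringsAsFactors = FALSE)
  trends <- classify_all_processes(prot, eff)
  g <- build_network(ev, eff, prot, trends)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)

  # a protein targeted by two receptors has in-degree 2
  ev2 <- rbind(ev, data.frame(human_id = "P", receptor = "p62",
                              evidence_type = "p62_motif", detail = "m"))
  g2 <- build_network(ev2, eff, prot, trends)
  expect_equal(unname(igraph::degree(g2, "P", mode = "in")), 2L)

  # dangling protein reference is a consistency error naming the id
  bad_eff <- eff
  bad_eff$protein_id <- "GHOST"
  expect_error(build_network(ev, bad_eff, prot, trends), "GHOST")
})

test_that("full synthetic network matches the counting oracle", {
  b <- small_bundle()
  prot_all <- b$truth$proteins
  targeted <- prot_all[prot_all$targeted_by != "", ]
  prot <- data.frame(human_id = targeted$human_id,
                     direction = targeted$direction,
                     stringsAsFactors = FALSE)
  ev <- collect_evidence(prot, sequences = b$sequences,
                         interactors = b$interactors,
                         lir_list = b$lir_list, lir_motif = b$motifs$lir,
                         p62_motif = b$motifs$p62,
                         domains = b$domains, ddi = b$ddi)
  eff <- b$effects[b$effects$protein_id %in% prot$human_id, ]
  trends <- classify_all_processes(prot, eff)
  g <- build_network(ev, eff, prot, trends)

  eff_ctx <- eff[eff$in_context, ]
  n_receptors <- length(unique(ev$receptor))
  n_prots <- length(unique(c(ev$human_id, eff_ctx$protein_id)))
  n_procs <- length(unique(eff_ctx$process_id))
  expect_equal(igraph::vcount(g), n_receptors + n_prots + n_procs)
  expect_equal(igraph::ecount(g),
               nrow(unique(ev[, c("receptor", "human_id")])) +
                 nrow(unique(eff_ctx[, c("protein_id", "process_id")])))

  # tripartite: no receptor-process or protein-protein edges
  el <- igraph::as_data_frame(g, "edges")
  type <- igraph::V(g)$type
  names(type) <- igraph::V(g)$name
  expect_true(all((type[el$from] == "receptor" & type[el$to] == "protein") |
                    (type[el$from] == "protein" & type[el$to] == "process")))

  # exports are written and the SIF has one line per edge
  prefix <- file.path(withr::local_tempdir(), "net")
  paths <- export_network(g, prefix)
  expect_true(all(file.exists(paths)))
  expect_equal(length(readLines(paths["sif"])), igraph::ecount(g))
})
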