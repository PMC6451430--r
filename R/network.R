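#' Build the tripartite receptor-protein-process network
#'
#' Receptor nodes connect to targeted protein nodes (relation `"targets"`,
#' one edge per distinct receptor-protein pair regardless of how many
#' evidence rows support it); protein nodes connect to process nodes with
#' the curated relation (`"activates"` / `"inhibits"`). Protein nodes carry
#' the abundance direction, process nodes the aggregated trend. The graph
#' never contains receptor-process or protein-protein edges.
#'
#' @param evidence evidence table from [collect_evidence()].
#' @param effects in-context effect table rows for the targeted proteins.
#' @param proteins data frame with `human_id` and `direction`.
#' @param trends trend table from [classify_all_processes()].
#' @return an [igraph::graph][igraph] object with vertex attributes `type`
#'   (`receptor` / `protein` / `process`), `direction`, `trend`, `label`,
#'   and edge attribute `relation`.
#' @export
build_network <- function(evidence, effects, proteins, trends) {
  eff <- effects[effects$in_context, , drop = FALSE]
  bad <- setdiff(eff$protein_id, proteins$human_id)
  if (length(bad))
    stop("build_network: effect row references unknown protein id: ",
         bad[1])
  bad <- setdiff(evidence$human_id, proteins$human_id)
  if (length(bad))
    stop("build_network: evidence row references unknown protein id: ",
         bad[1])

  rp <- unique(evidence[, c("receptor", "human_id")])
  pp <- unique(eff[, c("protein_id", "process_id", "effect")])

  receptors <- sort(unique(rp$receptor))
  prot_ids <- sort(unique(c(rp$human_id, pp$protein_id)))
  proc_ids <- sort(unique(pp$process_id))

  vertices <- data.frame(
    name = c(receptors, prot_ids, proc_ids),
    type = rep(c("receptor", "protein", "process"),
               c(length(receptors), length(prot_ids), length(proc_ids))),
    stringsAsFactors = FALSE)
  vertices$direction <- rep(NA_character_, nrow(vertices))
  vertices$trend <- rep(NA_character_, nrow(vertices))
  vertices$label <- vertices$name
  ix <- match(prot_ids, proteins$human_id)
  vertices$direction[vertices$type == "protein"] <- proteins$direction[ix]
  if (nrow(trends)) {
    tx <- match(proc_ids, trends$process_id)
    vertices$trend[vertices$type == "process"] <- trends$classification[tx]
    vertices$label[vertices$type == "process"] <-
      ifelse(is.na(tx), proc_ids, trends$process_label[tx])
  }

  edges <- rbind(
    data.frame(from = rp$receptor, to = rp$human_id,
               relation = rep("targets", nrow(rp)),
               stringsAsFactors = FALSE),
    data.frame(from = pp$protein_id, to = pp$process_id,
               relation = ifelse(pp$effect == "activation",
                                 "activates", "inhibits"),
               stringsAsFactors = FALSE))
  edges <- edges[order(edges$from, edges$relation, edges$to), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

#' Export a network for Cytoscape
#'
#' Writes the graph as SIF (`node<TAB>relation<TAB>node`), GraphML and a
#' node-attribute TSV, with deterministic row order.
#'
#' @param graph graph from [build_network()].
#' @param prefix output path prefix; files `<prefix>.sif`,
#'   `<prefix>.graphml` and `<prefix>_nodes.tsv` are written.
#' @return invisibly, the three paths.
#' @export
export_network <- function(graph, prefix) {
  el <- igraph::as_data_frame(graph, what = "edges")
  sif <- sprintf("%s\t%s\t%s", el$from, el$relation, el$to)
  sif_path <- paste0(prefix, ".sif")
  writeLines(sif[order(sif)], sif_path)

  graphml_path <- paste0(prefix, ".graphml")
  igraph::write_graph(graph, graphml_path, format = "graphml")

  nodes <- igraph::as_data_frame(graph, what = "vertices")
  nodes <- nodes[order(nodes$type, nodes$name),
                 c("name", "type", "direction", "trend", "label")]
  nodes_path <- paste0(prefix, "_nodes.tsv")
  write_tsv_table(nodes, nodes_path)
  invisible(c(sif = sif_path, graphml = graphml_path, nodes = nodes_path))
}
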