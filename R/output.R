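# Cytoscape-importable outputs. All writers are deterministic: rows are
# explicitly sorted and numbers formatted with fixed rules, so identical
# inputs yield byte-identical files.

.fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "", sprintf(paste0("%.", digits, "g"), x))
}

#' Write the directed sub-graph network (SIF)
#'
#' Emits every induced directed edge of every reported sub-graph in simple
#' interaction format (`from<TAB>directed<TAB>to`), grouped under one
#' comment header per sub-graph carrying its id, size and combined p-value.
#' The file imports directly into Cytoscape.
#'
#' @param subgraphs List of finalized `msf_subgraph` objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_subgraph_network <- function(subgraphs, path) {
  lines <- character(0)
  for (sg in subgraphs) {
    lines <- c(lines, sprintf(
      "# subgraph %d\tsize=%d\tcombined_p=%s",
      sg$id, length(sg$genes), .fmt_num(sg$score$combined_p)
    ))
    e <- sg$induced_edges
    if (nrow(e)) {
      e <- e[order(e$from, e$to), , drop = FALSE]
      lines <- c(lines, sprintf("%s\tdirected\t%s", e$from, e$to))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the Cytoscape node-attribute table
#'
#' One row per gene per sub-graph: gene id, sub-graph id, log-fold change,
#' source/sink flags, and (for sources) impact score and reliability
#' p-value. Genes present in a sub-graph but absent from the DGEA get an
#' empty log-fold-change field, with a warning.
#'
#' @param subgraphs List of finalized `msf_subgraph` objects.
#' @param dgea The [dgea_table()].
#' @param annotations Data frame from [annotate_subgraphs()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_node_attributes <- function(subgraphs, dgea, annotations, path) {
  s <- dgea$stats
  lines <- "gene_id\tsubgraph_id\tlog_fc\tis_source\tis_sink\timpact_score\treliability_p"
  n_absent <- 0L
  for (sg in subgraphs) {
    ann <- annotations[annotations$subgraph_id %in% sg$id, , drop = FALSE]
    src <- ann$gene_id[ann$role == "source"]
    snk <- ann$gene_id[ann$role == "sink"]
    for (g in sort(sg$genes)) {
      i <- match(g, s$gene_id)
      lfc <- if (is.na(i)) NA_real_ else s$log_fc[i]
      if (is.na(i)) n_absent <- n_absent + 1L
      is_src <- g %in% src
      ai <- if (is_src) which(ann$gene_id == g & ann$role == "source")[1] else NA_integer_
      lines <- c(lines, sprintf(
        "%s\t%d\t%s\t%s\t%s\t%s\t%s",
        g, sg$id, .fmt_num(lfc),
        tolower(is_src), tolower(g %in% snk),
        if (is_src) .fmt_num(ann$impact_score[ai]) else "",
        if (is_src) .fmt_num(ann$reliability_p[ai]) else ""
      ))
    }
  }
  if (n_absent > 0L) {
    warning("write_node_attributes: ", n_absent,
            " sub-graph gene(s) absent from the DGEA; log_fc left empty")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the sources and sinks report
#'
#' One row per source (gene, sub-graph, impact score, reliability t and p)
#' and one per sink (gene, sub-graph). Within each sub-graph sources come
#' first, ordered by descending impact score; sinks follow alphabetically.
#' An empty annotation set yields a header-only file.
#'
#' @param annotations Data frame from [annotate_subgraphs()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sources_sinks <- function(annotations, path) {
  lines <- "role\tgene_id\tsubgraph_id\timpact_score\treliability_t\treliability_p"
  if (nrow(annotations)) {
    a <- annotations[order(
      annotations$subgraph_id,
      match(annotations$role, c("source", "sink")),
      -ifelse(is.na(annotations$impact_score), -Inf, annotations$impact_score),
      annotations$gene_id
    ), , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\t%s\t%d\t%s\t%s\t%s",
      a$role, a$gene_id, a$subgraph_id,
      .fmt_num(a$impact_score), .fmt_num(a$reliability_t),
      .fmt_num(a$reliability_p)
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
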