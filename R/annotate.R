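# Step 4 post-processing: perturbation entry/end points of each sub-graph.

# out- and in-adjacency lists of a sub-graph's induced edges, keyed by gene
.sg_adjacency <- function(sg) {
  stopifnot(!is.null(sg$induced_edges))
  e <- sg$induced_edges
  out_adj <- split(e$to, factor(e$from, levels = sg$genes))
  in_adj <- split(e$from, factor(e$to, levels = sg$genes))
  list(out = out_adj, `in` = in_adj)
}

# genes reachable from `gene` via directed induced edges, excluding itself
.reachable_from <- function(sg, gene) {
  adj <- .sg_adjacency(sg)$out
  seen <- character(0)
  frontier <- unique(adj[[gene]])
  while (length(frontier)) {
    seen <- c(seen, frontier)
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, c(seen, gene))
  }
  setdiff(unique(seen), gene)
}

#' Find the sources and sinks of a sub-graph
#'
#' Within a sub-graph's induced directed edges, a **source** is a member with
#' no incoming and at least one outgoing edge (a candidate perturbation
#' entry point) and a **sink** is a member with no outgoing and at least one
#' incoming edge. Members isolated within the sub-graph are neither. Because
#' of cycles, a sub-graph may have no sources and no sinks at all.
#'
#' @param sg A finalized `msf_subgraph` (with `induced_edges`).
#' @return Data frame with columns `gene_id` and `role`
#'   (`"source"`/`"sink"`), zero rows when none exist.
#' @export
find_sources_sinks <- function(sg) {
  stopifnot(inherits(sg, "msf_subgraph"), !is.null(sg$induced_edges))
  e <- sg$induced_edges
  outdeg <- table(factor(e$from, levels = sg$genes))
  indeg <- table(factor(e$to, levels = sg$genes))
  sources <- sg$genes[indeg == 0 & outdeg > 0]
  sinks <- sg$genes[outdeg == 0 & indeg > 0]
  data.frame(
    gene_id = c(sources, sinks),
    role = rep(c("source", "sink"), c(length(sources), length(sinks))),
    stringsAsFactors = FALSE
  )
}

#' Impact score of a source
#'
#' The percentage of the sub-graph's other members lying downstream of the
#' source: `100 * n_down / (|genes| - 1)`, where `n_down` counts the genes
#' reachable from the source along directed induced edges
#' (`impact = "reachable"`, the default) or only its direct targets
#' (`impact = "immediate"`). Interpreted as an upper bound on how much of
#' the sub-graph's perturbation the source could have introduced.
#'
#' @param gene A source gene of `sg` (contract violation otherwise).
#' @param sg A finalized `msf_subgraph` with more than one gene.
#' @param impact Reachability mode, see [msf_config()].
#' @return Impact score in `(0, 100]`.
#' @export
impact_score <- function(gene, sg, impact = c("reachable", "immediate")) {
  impact <- match.arg(impact)
  roles <- find_sources_sinks(sg)
  if (!gene %in% roles$gene_id[roles$role == "source"]) {
    stop("gene '", gene, "' is not a source of this sub-graph")
  }
  if (length(sg$genes) < 2L) stop("impact score undefined for singletons")
  down <- if (impact == "reachable") {
    .reachable_from(sg, gene)
  } else {
    unique(sg$induced_edges$to[sg$induced_edges$from == gene])
  }
  100 * length(down) / (length(sg$genes) - 1)
}

#' Reliability t-test of a source
#'
#' Tests whether a source really marks the border between two regulation
#' regimes: Welch's two-sample t-test on natural-log-transformed p-values of
#' the genes just downstream versus just upstream of the source. The
#' downstream group holds the source's direct targets within the sub-graph
#' (or its full reachable set with `reliability_group = "reachable"`); the
#' upstream group holds its direct regulators in the **global** network that
#' carry a DGEA p-value — inside the sub-graph a source has no upstream
#' genes by definition. The test is invariant to the base of the logarithm.
#' When either group has fewer than two members (or the values are
#' constant), the result is flagged not computable rather than raised as an
#' error.
#'
#' @param gene A source gene of `sg`.
#' @param sg A finalized `msf_subgraph`.
#' @param network The full [interaction_network()].
#' @param dgea The [dgea_table()].
#' @param reliability_group Downstream group definition, see [msf_config()].
#' @return List with `computable` (logical), `t` (Welch t-statistic),
#'   `p` (two-sided p-value), `n_down`, `n_up` (group sizes).
#' @export
source_reliability <- function(gene, sg, network, dgea,
                               reliability_group = c("immediate", "reachable")) {
  reliability_group <- match.arg(reliability_group)
  roles <- find_sources_sinks(sg)
  if (!gene %in% roles$gene_id[roles$role == "source"]) {
    stop("gene '", gene, "' is not a source of this sub-graph")
  }
  s <- dgea$stats[!dgea$stats$missing, , drop = FALSE]
  down_genes <- if (reliability_group == "immediate") {
    unique(sg$induced_edges$to[sg$induced_edges$from == gene])
  } else {
    .reachable_from(sg, gene)
  }
  up_genes <- unique(network$edges$from[network$edges$to == gene])
  down <- log(s$p_value[match(intersect(down_genes, s$gene_id), s$gene_id)])
  up <- log(s$p_value[match(intersect(up_genes, s$gene_id), s$gene_id)])
  not_computable <- list(
    computable = FALSE, t = NA_real_, p = NA_real_,
    n_down = length(down), n_up = length(up)
  )
  if (length(down) < 2L || length(up) < 2L) return(not_computable)
  tt <- tryCatch(
    stats::t.test(down, up, var.equal = FALSE),
    error = function(e) NULL # constant data
  )
  if (is.null(tt)) return(not_computable)
  list(
    computable = TRUE, t = unname(tt$statistic), p = tt$p.value,
    n_down = length(down), n_up = length(up)
  )
}

#' Annotate all sub-graphs with sources, sinks and source statistics
#'
#' Runs [find_sources_sinks()] on every reported sub-graph and, for each
#' source, computes its [impact_score()] and [source_reliability()].
#'
#' @param subgraphs List of finalized `msf_subgraph` objects.
#' @param network The full [interaction_network()].
#' @param dgea The [dgea_table()].
#' @param config An [msf_config()] (supplies `impact` and
#'   `reliability_group`).
#' @return Data frame with one row per source or sink: columns `gene_id`,
#'   `subgraph_id`, `role`, `impact_score`, `reliability_t`, `reliability_p`,
#'   `n_down`, `n_up` (NA where not applicable or not computable). Within
#'   each sub-graph, sources are ordered by descending impact score, then
#'   gene id; sinks follow in lexicographic order.
#' @export
annotate_subgraphs <- function(subgraphs, network, dgea, config = msf_config()) {
  rows <- list()
  for (sg in subgraphs) {
    roles <- find_sources_sinks(sg)
    src <- roles$gene_id[roles$role == "source"]
    snk <- roles$gene_id[roles$role == "sink"]
    if (length(src)) {
      imp <- vapply(src, function(g) impact_score(g, sg, config$impact), numeric(1))
      rel <- lapply(src, function(g) {
        source_reliability(g, sg, network, dgea, config$reliability_group)
      })
      ord <- order(-imp, src)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = src[ord], subgraph_id = sg$id, role = "source",
        impact_score = imp[ord],
        reliability_t = vapply(rel[ord], `[[`, numeric(1), "t"),
        reliability_p = vapply(rel[ord], `[[`, numeric(1), "p"),
        n_down = vapply(rel[ord], `[[`, numeric(1), "n_down"),
        n_up = vapply(rel[ord], `[[`, numeric(1), "n_up"),
        stringsAsFactors = FALSE
      )
    }
    if (length(snk)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = sort(snk), subgraph_id = sg$id, role = "sink",
        impact_score = NA_real_, reliability_t = NA_real_,
        reliability_p = NA_real_, n_down = NA_real_, n_up = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      gene_id = character(0), subgraph_id = integer(0), role = character(0),
      impact_score = numeric(0), reliability_t = numeric(0),
      reliability_p = numeric(0), n_down = numeric(0), n_up = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
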