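# Planted-module simulator: synthetic directed networks and DGEA tables
# with a known connected module of low p-values, used to benchmark recall
# under score-level noise and to compare against naive p-value thresholding.

#' Generate a planted-module instance
#'
#' Draws a directed random network, selects a connected module of
#' `module_size` genes by a random walk on the undirected view, and assigns
#' p-values: planted genes draw from `Beta(signal_beta_a, 1)`
#' (`signal_beta_a << 1` concentrates mass near 0; `signal_beta_a = 1` is
#' the uniform null, i.e. no signal), background genes from `Uniform(0,1)`.
#' Log-fold changes are `Normal(0,1)` for background and `Normal(+/-2, 1)`
#' (random sign per gene) for planted genes. Fully reproducible from
#' `rng_seed`.
#'
#' @param n_nodes Number of genes in the network.
#' @param topology `"erdos_renyi"` (directed G(n,p), default) or
#'   `"preferential"` (directed preferential attachment).
#' @param module_size Number of planted genes (< `n_nodes`).
#' @param signal_beta_a Beta shape parameter in `(0, 1]` for planted
#'   p-values.
#' @param rng_seed Integer seed.
#' @param edge_prob Edge probability for `erdos_renyi`; default `3/n_nodes`
#'   (mean out-degree 3, total degree about 6, in the range of curated
#'   functional-interaction networks).
#' @param attach_degree Out-degree per node for `preferential`; default 3.
#' @return Object of class `msf_instance`: list with `network`
#'   (`msf_network`), `dgea` (`msf_dgea`), `planted_genes` (character) and
#'   `params` (the generator arguments).
#' @export
#' @examples
#' inst <- generate_instance(60, module_size = 8, signal_beta_a = 0.1, rng_seed = 1)
#' length(inst$planted_genes)
generate_instance <- function(n_nodes,
                              topology = c("erdos_renyi", "preferential"),
                              module_size,
                              signal_beta_a = 0.1,
                              rng_seed = 1L,
                              edge_prob = NULL,
                              attach_degree = 3L) {
  topology <- match.arg(topology)
  if (module_size >= n_nodes) stop("module_size must be smaller than n_nodes")
  if (signal_beta_a <= 0 || signal_beta_a > 1) stop("signal_beta_a must be in (0, 1]")
  if (is.null(edge_prob)) edge_prob <- 3 / n_nodes
  withr::with_seed(as.integer(rng_seed), {
    g <- switch(topology,
      erdos_renyi = igraph::sample_gnp(n_nodes, edge_prob, directed = TRUE),
      preferential = igraph::sample_pa(n_nodes, m = attach_degree, directed = TRUE)
    )
    ids <- sprintf("g%0*d", nchar(n_nodes), seq_len(n_nodes))
    el <- igraph::as_edgelist(g, names = FALSE)
    network <- interaction_network(ids[el[, 1]], ids[el[, 2]], nodes = ids)

    planted_idx <- .walk_module(g, module_size)
    planted <- ids[planted_idx]

    p <- stats::runif(n_nodes)
    p[planted_idx] <- stats::rbeta(module_size, signal_beta_a, 1)
    lfc <- stats::rnorm(n_nodes, 0, 1)
    sign <- sample(c(-2, 2), module_size, replace = TRUE)
    lfc[planted_idx] <- stats::rnorm(module_size, sign, 1)
    dgea <- dgea_table(ids, p, lfc)
  })
  out <- list(
    network = network, dgea = dgea, planted_genes = sort(planted),
    params = list(
      n_nodes = n_nodes, topology = topology, module_size = module_size,
      signal_beta_a = signal_beta_a, rng_seed = as.integer(rng_seed),
      edge_prob = edge_prob, attach_degree = attach_degree
    )
  )
  class(out) <- "msf_instance"
  out
}

# random-walk module selection on the undirected view; retries with fresh
# starts when the walk gets stuck (sparse or disconnected graphs)
.walk_module <- function(g, module_size) {
  gu <- igraph::as_undirected(g, mode = "collapse")
  n <- igraph::vcount(gu)
  for (attempt in seq_len(100L)) {
    cur <- sample.int(n, 1L)
    visited <- cur
    steps <- 0L
    max_steps <- 200L * module_size
    while (length(visited) < module_size && steps < max_steps) {
      nb <- as.integer(igraph::neighbors(gu, cur))
      if (!length(nb)) break
      cur <- nb[sample.int(length(nb), 1L)]
      visited <- union(visited, cur)
      steps <- steps + 1L
    }
    if (length(visited) == module_size) return(visited)
  }
  stop("could not embed a connected module of size ", module_size,
       " after 100 attempts; network too sparse")
}

#' Perturb an instance's p-values in normal-score space
#'
#' Adds independent `Normal(0, noise_sd)` noise to every gene's normal score
#' and re-derives the p-value as `1 - pnorm(score + noise)`. `noise_sd = 0`
#' is the identity. This is the score-level analogue of re-running a DGEA on
#' noise-injected counts: it perturbs p-values across their whole range
#' while preserving the planted/background structure.
#'
#' @param instance An `msf_instance` from [generate_instance()].
#' @param noise_sd Standard deviation of the score noise (>= 0).
#' @param rng_seed Integer seed.
#' @return A new `msf_instance` with perturbed `dgea`.
#' @export
perturb_pvalues <- function(instance, noise_sd, rng_seed = 1L) {
  stopifnot(inherits(instance, "msf_instance"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  s <- instance$dgea$stats
  if (noise_sd == 0) return(instance)
  p_new <- s$p_value
  ok <- !s$missing
  withr::with_seed(as.integer(rng_seed), {
    noise <- stats::rnorm(sum(ok), 0, noise_sd)
  })
  p_new[ok] <- stats::pnorm(s$normal_score[ok] + noise, lower.tail = FALSE)
  out <- instance
  out$dgea <- dgea_table(s$gene_id, p_new, s$log_fc, dialect = instance$dgea$dialect)
  out$params$noise_sd <- noise_sd
  out
}

#' Planted-gene recall of a detection result
#'
#' Fraction of the planted genes covered by the union of all detected
#' sub-graphs' genes.
#'
#' @param detected List of `msf_subgraph` objects (or any list with a
#'   `genes` element).
#' @param planted_genes Non-empty character vector of planted gene ids.
#' @return Recall in `[0, 1]`.
#' @export
recall <- function(detected, planted_genes) {
  if (!length(planted_genes)) stop("planted gene set must be non-empty")
  hit <- unique(unlist(lapply(detected, `[[`, "genes")))
  length(intersect(hit, planted_genes)) / length(planted_genes)
}

#' Connected components of significance thresholding
#'
#' The naive comparator to the sub-graph search: keep the genes with
#' `p <= alpha`, induce the undirected sub-network on them, and return its
#' connected components (including singletons). Thresholding fragments a
#' modulated region whenever an interior gene narrowly misses the cutoff;
#' counting its components against the search's sub-graph count quantifies
#' that fragmentation.
#'
#' @param network An [interaction_network()].
#' @param dgea A [dgea_table()].
#' @param alpha P-value cutoff in `(0, 1)`.
#' @return List of character vectors, one per component; empty list when no
#'   gene passes the cutoff.
#' @export
threshold_baseline <- function(network, dgea, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- dgea$stats[!dgea$stats$missing, , drop = FALSE]
  keep <- intersect(network$nodes, s$gene_id[s$p_value <= alpha])
  if (!length(keep)) return(list())
  g <- igraph::induced_subgraph(
    igraph::as_undirected(.as_igraph(network), mode = "collapse"),
    keep
  )
  comp <- igraph::components(g)
  unname(split(names(comp$membership), comp$membership))
}

#' @export
print.msf_instance <- function(x, ...) {
  cat(sprintf(
    "Planted instance: %d genes (%s), module of %d, Beta(%g, 1) signal, seed %d\n",
    x$params$n_nodes, x$params$topology, x$params$module_size,
    x$params$signal_beta_a, x$params$rng_seed
  ))
  invisible(x)
}
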