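# End-to-end orchestration: parse -> search -> annotate -> write, plus the
# planted-module benchmark. These are the programmatic equivalents of the
# command-line entry points in inst/cli/msf.R.

.write_manifest <- function(path, entries) {
  lines <- c("key\tvalue", sprintf("%s\t%s", names(entries),
                                   vapply(entries, as.character, character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis on input files
#'
#' Reads a DGEA table and a directed edge list, runs the four-step sub-graph
#' search, annotates sources and sinks, and writes four files into
#' `out_dir`: `subgraph_network.sif`, `node_attributes.tsv`,
#' `sources_sinks.tsv` and `run_manifest.tsv` (inputs, configuration,
#' package version, wall-clock time and per-step sub-graph counts —
#' everything needed to reproduce the run). Per-step counts are also logged
#' as messages. The pipeline is deterministic: identical inputs and
#' configuration give byte-identical outputs.
#'
#' @param dgea_path Path to the DGEA table (see [read_dgea()]).
#' @param network_path Path to the edge list (see [read_network()]).
#' @param out_dir Output directory (created if needed).
#' @param config An [msf_config()].
#' @param dialect DGEA dialect override, default `"auto"`.
#' @return Invisibly, a list with `subgraphs`, `annotations`, `counts` and
#'   the output `paths`.
#' @export
msf_run <- function(dgea_path, network_path, out_dir,
                    config = msf_config(), dialect = "auto") {
  t0 <- Sys.time()
  dgea <- read_dgea(dgea_path, dialect)
  network <- read_network(network_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  res <- msf_search(network, dgea, config)
  message(sprintf(
    "msf: %d sub-graph(s) initialized, %d after merging, %d reported",
    res$counts[["initialized"]], res$counts[["merged"]], res$counts[["reported"]]
  ))
  if (res$counts[["reported"]] == 0L) {
    message("msf: no modulated sub-graphs at the configured thresholds")
  }
  annotations <- annotate_subgraphs(res$subgraphs, network, dgea, config)

  paths <- list(
    network = file.path(out_dir, "subgraph_network.sif"),
    attributes = file.path(out_dir, "node_attributes.tsv"),
    sources_sinks = file.path(out_dir, "sources_sinks.tsv"),
    manifest = file.path(out_dir, "run_manifest.tsv")
  )
  write_subgraph_network(res$subgraphs, paths$network)
  write_node_attributes(res$subgraphs, dgea, annotations, paths$attributes)
  write_sources_sinks(annotations, paths$sources_sinks)
  .write_manifest(paths$manifest, c(
    tool = "msfinder",
    version = as.character(utils::packageVersion("msfinder")),
    dgea_path = dgea_path,
    network_path = network_path,
    dialect = dgea$dialect,
    unclass(config)[c(
      "max_extension_len", "max_connector_len", "report_min_size",
      "report_alpha", "seed_alpha", "neighbor_rule", "impact",
      "reliability_group"
    )],
    n_initialized = res$counts[["initialized"]],
    n_extended = res$counts[["extended"]],
    n_merged = res$counts[["merged"]],
    n_reported = res$counts[["reported"]],
    wall_clock_s = sprintf("%.2f", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ))
  invisible(list(
    subgraphs = res$subgraphs, annotations = annotations,
    counts = res$counts, paths = paths
  ))
}

#' Planted-module recovery benchmark
#'
#' Generates `replicates` planted instances, optionally perturbs their
#' p-values with score-level noise, runs the full search on each, and
#' scores planted-gene recall together with the connected-unit count of the
#' p-value thresholding baseline at `report_alpha`.
#'
#' @param n_nodes,module_size,signal_beta_a,topology Passed to
#'   [generate_instance()].
#' @param noise_sd Score-noise level passed to [perturb_pvalues()] (0 =
#'   none).
#' @param replicates Number of independent instances.
#' @param rng_seed Base seed; replicate `i` uses `rng_seed + i - 1`.
#' @param out_dir Optional: write `recall_per_replicate.tsv` and
#'   `simulation_summary.tsv` there.
#' @param config An [msf_config()].
#' @return Invisibly, a list with `per_replicate` (data.frame: replicate,
#'   seed, n_subgraphs, recall, n_baseline_units, baseline_recall) and
#'   `summary` (named numeric: median/mean recall, median sub-graph count,
#'   median baseline units).
#' @export
msf_simulate <- function(n_nodes = 500L, module_size = 40L,
                         signal_beta_a = 0.1, noise_sd = 0,
                         replicates = 10L, rng_seed = 1L,
                         out_dir = NULL, config = msf_config(),
                         topology = "erdos_renyi") {
  per <- vector("list", replicates)
  for (i in seq_len(replicates)) {
    seed_i <- as.integer(rng_seed) + i - 1L
    inst <- generate_instance(
      n_nodes, topology, module_size, signal_beta_a, rng_seed = seed_i
    )
    if (noise_sd > 0) inst <- perturb_pvalues(inst, noise_sd, rng_seed = seed_i + 10000L)
    res <- msf_search(inst$network, inst$dgea, config)
    base <- threshold_baseline(inst$network, inst$dgea, config$report_alpha)
    per[[i]] <- data.frame(
      replicate = i, seed = seed_i,
      n_subgraphs = res$counts[["reported"]],
      recall = recall(res$subgraphs, inst$planted_genes),
      n_baseline_units = length(base),
      baseline_recall = length(intersect(unlist(base), inst$planted_genes)) /
        length(inst$planted_genes)
    )
  }
  per <- do.call(rbind, per)
  summ <- c(
    median_recall = stats::median(per$recall),
    mean_recall = mean(per$recall),
    median_n_subgraphs = stats::median(per$n_subgraphs),
    median_baseline_units = stats::median(per$n_baseline_units),
    median_baseline_recall = stats::median(per$baseline_recall)
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(per, file.path(out_dir, "recall_per_replicate.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    .write_manifest(
      file.path(out_dir, "simulation_summary.tsv"),
      c(
        n_nodes = n_nodes, module_size = module_size,
        signal_beta_a = signal_beta_a, noise_sd = noise_sd,
        replicates = replicates, rng_seed = rng_seed,
        sapply(summ, function(v) sprintf("%.6g", v))
      )
    )
  }
  invisible(list(per_replicate = per, summary = summ))
}
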