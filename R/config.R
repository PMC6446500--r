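#' Search configuration
#'
#' All tunables of the sub-graph search in one validated object.
#'
#' @param max_extension_len Maximum number of genes in an extension path
#'   (1-3). Default 2: extension bridges gaps of up to two genes without a
#'   clear differential signal.
#' @param max_connector_len Maximum number of connector genes allowed when
#'   merging two sub-graphs (0 means only directly adjacent sub-graphs merge;
#'   1-3 allowed). Default 2.
#' @param report_min_size Minimum number of genes for a sub-graph to be
#'   reported. Default 2: singletons are plain significant genes, not
#'   modules.
#' @param report_alpha Combined p-value threshold for reporting. Default 0.05.
#' @param seed_alpha Individual p-value threshold for a gene to seed a new
#'   sub-graph. Default 0.05. Without this gate every gene would eventually
#'   seed a singleton.
#' @param neighbor_rule `"first"` (default): during initialization, accept
#'   the first improving neighbor in ascending (p-value, gene id) order;
#'   `"best"`: evaluate all neighbors and accept the one giving the lowest
#'   combined p-value.
#' @param impact `"reachable"` (default): a source's impact score counts all
#'   genes reachable from it by directed edges within the sub-graph;
#'   `"immediate"`: counts only its direct targets.
#' @param reliability_group `"immediate"` (default): the downstream group of
#'   the source reliability t-test is the source's direct targets within the
#'   sub-graph; `"reachable"`: its full downstream set.
#' @return Object of class `msf_config` (a named list).
#' @export
#' @examples
#' msf_config(max_extension_len = 3)
msf_config <- function(max_extension_len = 2L,
                       max_connector_len = 2L,
                       report_min_size = 2L,
                       report_alpha = 0.05,
                       seed_alpha = 0.05,
                       neighbor_rule = c("first", "best"),
                       impact = c("reachable", "immediate"),
                       reliability_group = c("immediate", "reachable")) {
  max_extension_len <- as.integer(max_extension_len)
  max_connector_len <- as.integer(max_connector_len)
  report_min_size <- as.integer(report_min_size)
  if (!max_extension_len %in% 1:3) stop("max_extension_len must be 1, 2 or 3")
  if (!max_connector_len %in% 0:3) stop("max_connector_len must be 0, 1, 2 or 3")
  if (report_min_size < 1L) stop("report_min_size must be >= 1")
  if (!is.numeric(report_alpha) || report_alpha <= 0 || report_alpha > 1) {
    stop("report_alpha must be in (0, 1]")
  }
  if (!is.numeric(seed_alpha) || seed_alpha <= 0 || seed_alpha > 1) {
    stop("seed_alpha must be in (0, 1]")
  }
  out <- list(
    max_extension_len = max_extension_len,
    max_connector_len = max_connector_len,
    report_min_size = report_min_size,
    report_alpha = report_alpha,
    seed_alpha = seed_alpha,
    neighbor_rule = match.arg(neighbor_rule),
    impact = match.arg(impact),
    reliability_group = match.arg(reliability_group)
  )
  class(out) <- "msf_config"
  out
}

#' @export
print.msf_config <- function(x, ...) {
  cat("MSF search configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
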