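#' Construct a differential-expression table
#'
#' Programmatic constructor for the per-gene evidence consumed by the
#' sub-graph search: one row per gene with its p-value and log2 fold change.
#' P-values are clamped to `[1e-15, 1 - 1e-15]` and the normal score
#' \eqn{\Phi^{-1}(1 - p)} is precomputed. Genes whose p-value is missing are
#' kept but flagged: they are invisible to the search (they contribute no
#' evidence) while still being legal network nodes.
#'
#' @param gene_id Character vector of unique, non-empty gene identifiers.
#' @param p_value Numeric vector of p-values (NA allowed, flagged missing).
#' @param log_fc Numeric vector of log2 fold changes (NA allowed).
#' @param dialect Provenance of the table: `"edgeR"`, `"DESeq2"` or
#'   `"generic"`.
#' @return Object of class `msf_dgea`: list with `stats` (data.frame with
#'   columns `gene_id`, `p_value`, `log_fc`, `normal_score`, `missing`) and
#'   `dialect`.
#' @export
#' @examples
#' dgea_table(c("g1", "g2"), c(0.01, 0.5), c(2, 0))
dgea_table <- function(gene_id, p_value, log_fc = rep(NA_real_, length(gene_id)),
                       dialect = "generic") {
  gene_id <- as.character(gene_id)
  if (any(is.na(gene_id)) || any(!nzchar(gene_id))) {
    stop("gene ids must be non-empty")
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop("duplicate gene id in DGEA table: ", dup[1])
  }
  if (length(p_value) != length(gene_id) || length(log_fc) != length(gene_id)) {
    stop("gene_id, p_value and log_fc must have equal length")
  }
  p_value <- as.numeric(p_value)
  bad_range <- which(!is.na(p_value) & (p_value < 0 | p_value > 1))
  if (length(bad_range)) {
    stop("p-value out of [0, 1] for gene ", gene_id[bad_range[1]])
  }
  missing <- !is.finite(p_value)
  p_clamped <- ifelse(missing, NA_real_, clamp_pvalues(p_value))
  stats_df <- data.frame(
    gene_id = gene_id,
    p_value = p_clamped,
    log_fc = as.numeric(log_fc),
    normal_score = ifelse(missing, NA_real_, normal_score(ifelse(missing, 0.5, p_clamped))),
    missing = missing,
    stringsAsFactors = FALSE
  )
  out <- list(stats = stats_df, dialect = match.arg(dialect, c("generic", "edgeR", "DESeq2")))
  class(out) <- "msf_dgea"
  out
}

#' Read a differential-expression result table
#'
#' Reads the tabular output of a differential gene expression analysis. The
#' column dialect is auto-detected case-insensitively from the header:
#' * **DESeq2**: columns `log2FoldChange` and `pvalue`;
#' * **edgeR**: columns `logFC` and `PValue`;
#' * **generic**: columns `gene`, `p_value` and `log_fc`.
#'
#' The gene identifier is taken from a column named `gene`, `gene_id`,
#' `genes`, `symbol` or `id` (case-insensitive); failing that, the first
#' column is used when it is non-numeric (the usual shape of an edgeR
#' `topTags` or DESeq2 `results` table written with row names). The field
#' separator (tab or comma) is sniffed from the header line.
#'
#' Unparseable p-values (e.g. the `NA`s DESeq2 emits for independent-filtered
#' genes) flag the gene as missing, with a warning; such genes carry no
#' evidence but remain valid network nodes. A duplicated gene id or an absent
#' p-value column is a fatal format error.
#'
#' @param path Path to the TSV/CSV file (header required).
#' @param dialect `"auto"` (default) or one of `"edgeR"`, `"DESeq2"`,
#'   `"generic"` to override detection.
#' @return An [dgea_table()] object with `dialect` set to the detected or
#'   forced dialect.
#' @export
read_dgea <- function(path, dialect = c("auto", "edgeR", "DESeq2", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("DGEA file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header)) stop("DGEA file '", path, "' is empty")
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else ""
  df <- utils::read.table(path,
    header = TRUE, sep = sep, quote = "\"",
    stringsAsFactors = FALSE, check.names = FALSE, comment.char = ""
  )
  lower <- tolower(names(df))

  if (dialect == "auto") {
    dialect <- if (all(c("log2foldchange", "pvalue") %in% lower)) {
      "DESeq2"
    } else if (all(c("logfc", "pvalue") %in% lower)) {
      "edgeR"
    } else if ("p_value" %in% lower) {
      "generic"
    } else {
      stop(
        "cannot detect DGEA dialect of '", path,
        "': no p-value column (expected PValue, pvalue or p_value)"
      )
    }
  }

  pick <- function(nm) {
    i <- match(tolower(nm), lower)
    if (is.na(i)) NULL else df[[i]]
  }
  p <- switch(dialect,
    DESeq2 = pick("pvalue"),
    edgeR = pick("pvalue"),
    generic = pick("p_value")
  )
  if (is.null(p)) {
    stop("DGEA file '", path, "' lacks the p-value column required by dialect ", dialect)
  }
  lfc <- switch(dialect,
    DESeq2 = pick("log2foldchange"),
    edgeR = pick("logfc"),
    generic = pick("log_fc")
  )
  if (is.null(lfc)) lfc <- rep(NA_real_, nrow(df))

  gene_col <- intersect(c("gene", "gene_id", "genes", "symbol", "id"), lower)
  gene <- if (length(gene_col)) {
    df[[match(gene_col[1], lower)]]
  } else if (!is.numeric(df[[1]])) {
    df[[1]]
  } else {
    stop("DGEA file '", path, "' has no recognizable gene identifier column")
  }

  p_num <- suppressWarnings(as.numeric(p))
  n_bad <- sum(!is.finite(p_num))
  if (n_bad > 0) {
    warning(
      "read_dgea: ", n_bad, " gene(s) with unparseable p-value flagged missing in '",
      path, "'"
    )
  }
  dgea_table(gene, p_num, suppressWarnings(as.numeric(lfc)), dialect = dialect)
}

#' Write a differential-expression table in the generic dialect
#'
#' Emits a tab-separated `gene`, `p_value`, `log_fc` table that
#' [read_dgea()] reads back (generic dialect). Used by the simulator so that
#' generated fixtures exercise the same file formats as real inputs.
#'
#' @param dgea An `msf_dgea` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_dgea <- function(dgea, path) {
  stopifnot(inherits(dgea, "msf_dgea"))
  s <- dgea$stats
  lines <- c(
    "gene\tp_value\tlog_fc",
    sprintf(
      "%s\t%s\t%s", s$gene_id,
      ifelse(s$missing, "NA", sprintf("%.17g", s$p_value)),
      ifelse(is.na(s$log_fc), "NA", sprintf("%.17g", s$log_fc))
    )
  )
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.msf_dgea <- function(x, ...) {
  cat(sprintf(
    "DGEA table (%s dialect): %d genes, %d with missing p-value\n",
    x$dialect, nrow(x$stats), sum(x$stats$missing)
  ))
  invisible(x)
}
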