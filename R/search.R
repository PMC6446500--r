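# Core search: deterministic seed / extend / merge heuristic over the
# undirected view of the interaction network, scored by the Hartung combiner.
#
# Membership decisions use undirected adjacency (statistical evidence of
# co-regulation has no direction); edge directions are preserved and used
# only by the topology annotation. All improvement comparisons are strict
# and made on log combined p-values, which guarantees termination and keeps
# deeply significant sub-graphs strictly ordered even where the p-value
# itself underflows.

# ---- internal search context -------------------------------------------

# Genes visible to the search are those present in BOTH the network and the
# DGEA with a usable p-value: every member must contribute evidence to the
# combined score. Everything is integer-indexed against the sorted gene
# vector for speed; index order equals lexicographic gene order.
.msf_context <- function(network, dgea) {
  stopifnot(inherits(network, "msf_network"), inherits(dgea, "msf_dgea"))
  s <- dgea$stats[!dgea$stats$missing, , drop = FALSE]
  genes <- intersect(network$nodes, s$gene_id) # sorted: network$nodes is sorted
  n <- length(genes)
  p <- s$p_value[match(genes, s$gene_id)]
  score <- s$normal_score[match(genes, s$gene_id)]
  e <- network$edges
  keep <- e$from %in% genes & e$to %in% genes
  ef <- match(e$from[keep], genes)
  et <- match(e$to[keep], genes)
  a <- c(ef, et)
  b <- c(et, ef)
  adj <- vector("list", n)
  if (length(a)) {
    spl <- split(b, a)
    idx <- as.integer(names(spl))
    for (k in seq_along(idx)) adj[[idx[k]]] <- sort(unique(spl[[k]]))
  }
  for (k in seq_len(n)) if (is.null(adj[[k]])) adj[[k]] <- integer(0)
  list(
    genes = genes, n = n, p = p, score = score,
    logp1 = log(p), # singleton log combined p (p already clamped)
    adj = adj, ef = ef, et = et
  )
}

# log combined p of an integer gene-index set under the context
.ctx_logp <- function(ctx, idx) {
  if (length(idx) == 1L) ctx$logp1[idx] else .logp_scores(ctx$score[idx])
}

# internal working sub-graph: integer member indices + cached log p
.wsub <- function(idx, lp) list(idx = idx, lp = lp)

# convert internal working list -> user-facing msf_subgraph list
.wsub_export <- function(ctx, ws) {
  lapply(ws, function(w) {
    g <- sort(ctx$genes[w$idx])
    sg <- list(
      id = NA_integer_, genes = g, induced_edges = NULL,
      score = combine_pvalues(ctx$p[match(g, ctx$genes)])
    )
    class(sg) <- "msf_subgraph"
    sg
  })
}

# convert user-facing sub-graphs -> internal working list
.wsub_import <- function(ctx, subgraphs) {
  lapply(subgraphs, function(sg) {
    idx <- match(sg$genes, ctx$genes)
    if (any(is.na(idx))) {
      stop("sub-graph member absent from the search context: ",
           sg$genes[which(is.na(idx))[1]])
    }
    idx <- sort(idx)
    .wsub(idx, .ctx_logp(ctx, idx))
  })
}

.assigned_of <- function(ctx, ws) {
  assigned <- logical(ctx$n)
  assigned[unlist(lapply(ws, `[[`, "idx"))] <- TRUE
  assigned
}

# ---- step 1: initialize -------------------------------------------------

#' Initialize modulated sub-graphs from significant seeds
#'
#' Repeatedly seeds a new sub-graph at the unassigned gene with the smallest
#' p-value (ties broken lexicographically by gene id), provided that p-value
#' passes `seed_alpha`. Each sub-graph then grows greedily: among the
#' unassigned immediate neighbors (undirected view) of its current members,
#' sorted by ascending (p-value, gene id), the first (or, with
#' `neighbor_rule = "best"`, the best) neighbor whose addition strictly
#' lowers the combined p-value is added; growth stops when no neighbor
#' improves. Members of a recorded sub-graph are never reconsidered.
#'
#' Only genes present in both the network and the DGEA with a usable p-value
#' participate: every member must contribute evidence to the combined score.
#'
#' @param network An [interaction_network()].
#' @param dgea A [dgea_table()].
#' @param config An [msf_config()].
#' @return List of `msf_subgraph` objects (ids unset until
#'   [finalize_subgraphs()]).
#' @seealso [extend_subgraphs()], [merge_subgraphs()], [msf_search()]
#' @export
initialize_subgraphs <- function(network, dgea, config = msf_config()) {
  ctx <- .msf_context(network, dgea)
  if (ctx$n == 0L) {
    warning("network and DGEA share no scored genes; no sub-graphs")
    return(list())
  }
  assigned <- logical(ctx$n)
  seed_order <- order(ctx$p, seq_len(ctx$n))
  first_rule <- config$neighbor_rule == "first"
  ws <- list()
  for (seed in seed_order) {
    if (assigned[seed] || ctx$p[seed] > config$seed_alpha) next
    S <- seed
    lp <- ctx$logp1[seed]
    repeat {
      nb <- unique(unlist(ctx$adj[S]))
      nb <- nb[!assigned[nb] & !(nb %in% S)]
      if (!length(nb)) break
      nb <- nb[order(ctx$p[nb], nb)]
      accepted <- FALSE
      if (first_rule) {
        for (v in nb) {
          cand_lp <- .ctx_logp(ctx, c(S, v))
          if (cand_lp < lp) {
            S <- c(S, v); lp <- cand_lp; accepted <- TRUE
            break
          }
        }
      } else {
        cand_lp <- vapply(nb, function(v) .ctx_logp(ctx, c(S, v)), numeric(1))
        best <- which.min(cand_lp) # first minimum: lowest (p, id) on ties
        if (cand_lp[best] < lp) {
          S <- c(S, nb[best]); lp <- cand_lp[best]; accepted <- TRUE
        }
      }
      if (!accepted) break
    }
    S <- sort(S)
    assigned[S] <- TRUE
    ws[[length(ws) + 1L]] <- .wsub(S, lp)
  }
  .wsub_export(ctx, ws)
}

# ---- step 2: extend -----------------------------------------------------

# enumerate simple extension paths of 1..maxlen unassigned genes starting at
# a neighbor of the sub-graph; paths never touch assigned genes or members
.enum_paths <- function(ctx, S, assigned, maxlen) {
  inS <- logical(ctx$n)
  inS[S] <- TRUE
  free <- function(v) !assigned[v] & !inS[v]
  starts <- unique(unlist(ctx$adj[S]))
  starts <- sort(starts[free(starts)])
  paths <- vector("list", 0L)
  for (x in starts) {
    paths[[length(paths) + 1L]] <- x
    if (maxlen >= 2L) {
      ys <- ctx$adj[[x]]
      ys <- ys[free(ys) & ys != x]
      for (y in ys) {
        paths[[length(paths) + 1L]] <- c(x, y)
        if (maxlen >= 3L) {
          zs <- ctx$adj[[y]]
          zs <- zs[free(zs) & zs != x & zs != y]
          for (z in zs) paths[[length(paths) + 1L]] <- c(x, y, z)
        }
      }
    }
  }
  paths
}

# order candidate paths by (own combined p, lexicographic gene sequence)
.order_paths <- function(ctx, paths) {
  if (!length(paths)) return(paths)
  own <- vapply(paths, function(pt) .ctx_logp(ctx, pt), numeric(1))
  key <- vapply(paths, function(pt) paste(ctx$genes[pt], collapse = "\r"), character(1))
  paths[order(own, key)]
}

#' Extend sub-graphs across short unsignificant gaps
#'
#' For each sub-graph, enumerates all simple paths of 1 to
#' `max_extension_len` unassigned genes starting from any member (undirected
#' adjacency; a path may not touch a member of any sub-graph — reaching
#' another sub-graph is the merge step's job). Candidate paths are evaluated
#' in ascending order of their own combined p-value (ties by lexicographic
#' gene sequence); a path is accepted iff adding all its genes strictly
#' lowers the sub-graph's combined p-value, and enumeration restarts after
#' each acceptance. The whole pass is iterated until no sub-graph accepts a
#' path. This is what bridges small gaps of genes without a clear
#' differential signal.
#'
#' @inheritParams initialize_subgraphs
#' @param subgraphs List of `msf_subgraph` from [initialize_subgraphs()].
#' @return List of `msf_subgraph` with possibly enlarged gene sets.
#' @export
extend_subgraphs <- function(subgraphs, network, dgea, config = msf_config()) {
  if (!length(subgraphs)) return(subgraphs)
  ctx <- .msf_context(network, dgea)
  ws <- .wsub_import(ctx, subgraphs)
  assigned <- .assigned_of(ctx, ws)
  # deterministic processing order: ascending combined p, ties by first gene
  proc <- order(vapply(ws, `[[`, numeric(1), "lp"),
                vapply(ws, function(w) w$idx[1], integer(1)))
  repeat {
    any_accept <- FALSE
    for (si in proc) {
      repeat {
        paths <- .order_paths(ctx, .enum_paths(ctx, ws[[si]]$idx, assigned,
                                               config$max_extension_len))
        accepted <- FALSE
        for (pt in paths) {
          cand <- c(ws[[si]]$idx, pt)
          cand_lp <- .ctx_logp(ctx, cand)
          if (cand_lp < ws[[si]]$lp) {
            ws[[si]] <- .wsub(sort(cand), cand_lp)
            assigned[pt] <- TRUE
            accepted <- TRUE
            any_accept <- TRUE
            break
          }
        }
        if (!accepted) break
      }
    }
    if (!any_accept) break
  }
  .wsub_export(ctx, ws)
}

# ---- step 3: merge ------------------------------------------------------

# all connector paths of 0..maxlen unassigned genes linking a member of A to
# a member of B (bounded-depth search in the undirected view). Returns a
# list of integer vectors (length 0 = sub-graphs directly adjacent).
.enum_connectors <- function(ctx, A, B, assigned, maxlen) {
  inA <- logical(ctx$n); inA[A] <- TRUE
  inB <- logical(ctx$n); inB[B] <- TRUE
  free <- function(v) !assigned[v]
  out <- vector("list", 0L)
  nbA <- unique(unlist(ctx$adj[A]))
  if (any(inB[nbA])) out[[length(out) + 1L]] <- integer(0)
  if (maxlen < 1L) return(out)
  xs <- sort(nbA[free(nbA)])
  for (x in xs) {
    nx <- ctx$adj[[x]]
    if (any(inB[nx])) out[[length(out) + 1L]] <- x
    if (maxlen >= 2L) {
      ys <- nx[free(nx) & nx != x]
      for (y in ys) {
        ny <- ctx$adj[[y]]
        if (any(inB[ny])) out[[length(out) + 1L]] <- c(x, y)
        if (maxlen >= 3L) {
          zs <- ny[free(ny) & ny != x & ny != y]
          for (z in zs) if (any(inB[ctx$adj[[z]]])) out[[length(out) + 1L]] <- c(x, y, z)
        }
      }
    }
  }
  out
}

# best merge candidate for a pair: minimize merged log p, ties by shorter
# connector, then lexicographic connector sequence. NULL when no connector.
.best_merge <- function(ctx, A, B, assigned, maxlen) {
  conns <- .enum_connectors(ctx, A, B, assigned, maxlen)
  if (!length(conns)) return(NULL)
  lp <- vapply(conns, function(cn) .ctx_logp(ctx, c(A, B, cn)), numeric(1))
  len <- lengths(conns)
  key <- vapply(conns, function(cn) paste(ctx$genes[cn], collapse = "\r"), character(1))
  best <- order(lp, len, key)[1L]
  list(lp = lp[best], connector = conns[[best]])
}

#' Merge sub-graphs through short connectors
#'
#' Tests every unordered pair of sub-graphs for a merge: a bounded-depth
#' search in the undirected view looks for connector paths of 0 to
#' `max_connector_len` unassigned genes linking the two; the merge candidate
#' is the union of both sub-graphs plus the connector. Among a pair's
#' connectors the one minimizing the merged combined p-value is taken (ties:
#' shortest, then lexicographic); the merge is accepted iff the merged
#' combined p-value is strictly below **both** parents'. Pairs are processed
#' in ascending order of their better parent's combined p-value, the pair
#' list is rebuilt after every acceptance, and the step iterates until no
#' pair merges.
#'
#' The returned list carries a `merge_log` attribute (one row per accepted
#' merge with both parents' and the merged combined p-value) for auditing
#' the strict-improvement guarantee.
#'
#' @inheritParams extend_subgraphs
#' @param subgraphs List of `msf_subgraph` from [extend_subgraphs()].
#' @return List of `msf_subgraph` (pairwise disjoint gene sets), with
#'   attribute `merge_log`.
#' @export
merge_subgraphs <- function(subgraphs, network, dgea, config = msf_config()) {
  log_df <- data.frame(
    parent_a_p = numeric(0), parent_b_p = numeric(0),
    merged_p = numeric(0), connector_len = integer(0)
  )
  if (length(subgraphs) < 2L) {
    attr(subgraphs, "merge_log") <- log_df
    return(subgraphs)
  }
  ctx <- .msf_context(network, dgea)
  ws <- .wsub_import(ctx, subgraphs)
  assigned <- .assigned_of(ctx, ws)
  uid <- seq_along(ws) # stable ids for the evaluation cache
  next_uid <- length(ws) + 1L
  cache <- new.env(parent = emptyenv())

  repeat {
    k <- length(ws)
    if (k < 2L) break
    lps <- vapply(ws, `[[`, numeric(1), "lp")
    firsts <- vapply(ws, function(w) w$idx[1], integer(1))
    pairs <- utils::combn(k, 2L)
    minlp <- pmin(lps[pairs[1, ]], lps[pairs[2, ]])
    maxlp <- pmax(lps[pairs[1, ]], lps[pairs[2, ]])
    tie <- pmin(firsts[pairs[1, ]], firsts[pairs[2, ]])
    ord <- order(minlp, maxlp, tie)
    accepted <- FALSE
    for (pi in ord) {
      i <- pairs[1, pi]; j <- pairs[2, pi]
      ck <- paste0(min(uid[i], uid[j]), ":", max(uid[i], uid[j]))
      hit <- if (exists(ck, envir = cache)) get(ck, envir = cache) else NULL
      # a cached result stays valid while both parents are unchanged and its
      # connector genes are still unassigned (options only ever shrink)
      if (!is.null(hit) && (is.null(hit$best) || !any(assigned[hit$best$connector]))) {
        best <- hit$best
      } else {
        best <- .best_merge(ctx, ws[[i]]$idx, ws[[j]]$idx, assigned,
                            config$max_connector_len)
        assign(ck, list(best = best), envir = cache)
      }
      if (is.null(best)) next
      if (best$lp < ws[[i]]$lp && best$lp < ws[[j]]$lp) {
        log_df <- rbind(log_df, data.frame(
          parent_a_p = exp(ws[[i]]$lp), parent_b_p = exp(ws[[j]]$lp),
          merged_p = exp(best$lp), connector_len = length(best$connector)
        ))
        merged <- sort(c(ws[[i]]$idx, ws[[j]]$idx, best$connector))
        assigned[best$connector] <- TRUE
        ws[[i]] <- .wsub(merged, best$lp)
        uid[i] <- next_uid
        next_uid <- next_uid + 1L
        ws[[j]] <- NULL
        uid <- uid[-j]
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
  }
  out <- .wsub_export(ctx, ws)
  attr(out, "merge_log") <- log_df
  out
}

# ---- step 4 (reporting): finalize --------------------------------------

#' Filter, rank and materialize the reported sub-graphs
#'
#' Keeps sub-graphs with at least `report_min_size` genes and combined
#' p-value at most `report_alpha`, renumbers them `1..k` in ascending
#' combined p-value (ties by first gene id), and attaches each sub-graph's
#' induced directed edges from the full network.
#'
#' @param subgraphs List of `msf_subgraph` from [merge_subgraphs()].
#' @param network The full [interaction_network()] (source of the induced
#'   directed edges).
#' @param config An [msf_config()].
#' @return List of finalized `msf_subgraph` objects with `id` and
#'   `induced_edges` set.
#' @export
finalize_subgraphs <- function(subgraphs, network, config = msf_config()) {
  if (!length(subgraphs)) return(list())
  keep <- vapply(subgraphs, function(sg) {
    length(sg$genes) >= config$report_min_size &&
      sg$score$combined_p <= config$report_alpha
  }, logical(1))
  kept <- subgraphs[keep]
  if (!length(kept)) return(list())
  ord <- order(
    vapply(kept, function(sg) sg$score$log_p, numeric(1)),
    vapply(kept, function(sg) sg$genes[1], character(1))
  )
  kept <- kept[ord]
  for (i in seq_along(kept)) {
    kept[[i]]$id <- i
    e <- network$edges
    sel <- e$from %in% kept[[i]]$genes & e$to %in% kept[[i]]$genes
    kept[[i]]$induced_edges <- e[sel, , drop = FALSE]
    rownames(kept[[i]]$induced_edges) <- NULL
  }
  kept
}

#' Run the full modulated sub-graph search
#'
#' Convenience wrapper chaining [initialize_subgraphs()],
#' [extend_subgraphs()], [merge_subgraphs()] and [finalize_subgraphs()].
#'
#' @inheritParams initialize_subgraphs
#' @return List with elements `subgraphs` (finalized list), `counts` (named
#'   integer vector of sub-graph counts after each step) and `merge_log`
#'   (data.frame of accepted merges).
#' @export
#' @examples
#' net <- interaction_network(c("a", "b", "x"), c("b", "x", "c"))
#' dg <- dgea_table(c("a", "b", "x", "c"), c(0.001, 0.002, 0.6, 0.0005))
#' res <- msf_search(net, dg)
#' res$counts
msf_search <- function(network, dgea, config = msf_config()) {
  init <- initialize_subgraphs(network, dgea, config)
  ext <- extend_subgraphs(init, network, dgea, config)
  mrg <- merge_subgraphs(ext, network, dgea, config)
  fin <- finalize_subgraphs(mrg, network, config)
  list(
    subgraphs = fin,
    counts = c(
      initialized = length(init), extended = length(ext),
      merged = length(mrg), reported = length(fin)
    ),
    merge_log = attr(mrg, "merge_log")
  )
}

#' @export
print.msf_subgraph <- function(x, ...) {
  cat(sprintf(
    "Modulated sub-graph%s: %d genes, combined p = %.4g\n",
    if (is.na(x$id)) "" else paste0(" #", x$id),
    length(x$genes), x$score$combined_p
  ))
  cat("  genes:", paste(utils::head(x$genes, 12), collapse = ", "),
      if (length(x$genes) > 12) "..." else "", "\n")
  invisible(x)
}
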