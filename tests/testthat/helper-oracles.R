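# Independent oracles and fixture builders shared across the suite.
# Oracles re-derive expected values from first principles (direct formula
# transcription, exhaustive enumeration, closed forms) and never call the
# package's internal scorer.

# direct transcription of the weighted inverse-normal statistic
oracle_statistic <- function(scores, weights, rho) {
  num <- 0
  for (i in seq_along(scores)) num <- num + weights[i] * scores[i]
  sl <- 0
  sl2 <- 0
  for (i in seq_along(weights)) {
    sl <- sl + weights[i]
    sl2 <- sl2 + weights[i]^2
  }
  num / sqrt((1 - rho) * sl2 + rho * sl^2)
}

# combined log p of a p-value set, written independently of the package:
# normal scores, Hartung variance estimator floored at 0, inverse-normal
# combination, upper tail
oracle_logp <- function(p) {
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  # upper-tail quantile: Phi^{-1}(1 - p) evaluated without the cancellation
  # that computing the literal difference 1 - p would cost at tiny p
  t <- qnorm(pc, lower.tail = FALSE)
  n <- length(t)
  if (n == 1) return(log(pc))
  rho <- 1 - sum((t - mean(t))^2) / (n - 1)
  rho <- min(max(rho, 0), 1)
  stat <- sum(t) / sqrt((1 - rho) * n + rho * n^2)
  pnorm(stat, lower.tail = FALSE, log.p = TRUE)
}
oracle_p <- function(p) exp(oracle_logp(p))

# exhaustive optimum over all connected subsets (undirected view) that
# contain at least one seed-eligible gene -- the feasible set of the search.
# Returns +Inf when no such subset exists.
oracle_best_logp <- function(net, dgea, seed_alpha = 0.05) {
  g <- net$nodes
  n <- length(g)
  stopifnot(n <= 12)
  s <- dgea$stats
  p <- s$p_value[match(g, s$gene_id)]
  adj <- matrix(FALSE, n, n)
  if (nrow(net$edges)) {
    fi <- match(net$edges$from, g)
    ti <- match(net$edges$to, g)
    for (k in seq_along(fi)) {
      adj[fi[k], ti[k]] <- TRUE
      adj[ti[k], fi[k]] <- TRUE
    }
  }
  best <- Inf
  for (mask in seq_len(2^n - 1)) {
    mem <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0)
    if (!any(p[mem] <= seed_alpha)) next
    if (length(mem) > 1) {
      seen <- mem[1]
      frontier <- mem[1]
      while (length(frontier)) {
        nxt <- setdiff(intersect(which(colSums(adj[frontier, , drop = FALSE]) > 0), mem), seen)
        seen <- c(seen, nxt)
        frontier <- nxt
      }
      if (length(seen) < length(mem)) next
    }
    lp <- oracle_logp(p[mem])
    if (lp < best) best <- lp
  }
  best
}

# directed reachability by explicit transitive closure (matrix powers)
oracle_reachable <- function(edges, genes, from) {
  n <- length(genes)
  A <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  for (k in seq_len(nrow(edges))) A[edges$from[k], edges$to[k]] <- TRUE
  R <- A
  for (step in seq_len(n)) R <- R | (R %*% A > 0)
  setdiff(genes[R[from, ]], from)
}

# the worked chain a - b - x - c with a gap gene x
chain_fixture <- function() {
  list(
    network = interaction_network(c("a", "b", "x"), c("b", "x", "c")),
    dgea = dgea_table(c("a", "b", "x", "c"), c(0.001, 0.002, 0.6, 0.0005),
                      c(1.5, 1.2, 0.1, -2))
  )
}

# small random directed instance for search property tests; a few genes get
# boosted significance so that seeds usually exist
random_small_instance <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:8, 1)
  m <- max(1, rbinom(1, n * (n - 1), 0.18))
  from <- sample(1:n, m, replace = TRUE)
  to <- sample(1:n, m, replace = TRUE)
  ids <- letters[1:n]
  keep <- from != to
  net <- interaction_network(ids[from[keep]], ids[to[keep]], nodes = ids)
  p <- runif(n)
  sig <- sample(1:n, sample(1:3, 1))
  p[sig] <- rbeta(length(sig), 0.2, 1)
  list(network = net, dgea = dgea_table(ids, p))
}

expect_connected_undirected <- function(sg) {
  g <- igraph::graph_from_data_frame(sg$induced_edges,
    directed = FALSE,
    vertices = data.frame(name = sg$genes)
  )
  expect_true(igraph::is_connected(g))
}
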