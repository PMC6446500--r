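# Sources, sinks, impact scores and the reliability t-test.

make_sg <- function(from, to, p = NULL, id = 1L) {
  genes <- sort(unique(c(from, to)))
  if (is.null(p)) p <- rep(0.01, length(genes))
  sg <- list(
    id = id, genes = genes,
    induced_edges = data.frame(from = from, to = to, stringsAsFactors = FALSE),
    score = combine_pvalues(p)
  )
  class(sg) <- "msf_subgraph"
  sg
}

test_that("chains, cycles and stars get the expected sources and sinks", {
  chain <- make_sg(c("a", "b"), c("b", "c"))
  r <- find_sources_sinks(chain)
  expect_identical(r$gene_id[r$role == "source"], "a")
  expect_identical(r$gene_id[r$role == "sink"], "c")

  cyc <- make_sg(c("a", "b", "c"), c("b", "c", "a"))
  expect_identical(nrow(find_sources_sinks(cyc)), 0L) # loops: no sources, no sinks

  star <- make_sg(c("a", "a", "a"), c("b", "c", "d"))
  rs <- find_sources_sinks(star)
  expect_identical(rs$gene_id[rs$role == "source"], "a")
  expect_identical(sort(rs$gene_id[rs$role == "sink"]), c("b", "c", "d"))
})

test_that("impact score is the percentage of members downstream of the source", {
  chain <- make_sg(c("a", "b"), c("b", "c"))
  expect_equal(impact_score("a", chain), 100) # full reach: 2 of 2
  vee <- make_sg(c("a", "c"), c("b", "b")) # a -> b <- c
  expect_equal(impact_score("a", vee), 50) # 1 of 2 others
  expect_equal(impact_score("c", vee), 50)
  expect_error(impact_score("b", vee), "not a source")
  # immediate mode counts direct targets only
  chain3 <- make_sg(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(impact_score("a", chain3), 100)
  expect_equal(impact_score("a", chain3, impact = "immediate"), 100 * 1 / 3)
})

test_that("reachability agrees with a transitive-closure oracle on random DAG-ish graphs", {
  set.seed(88)
  for (i in 1:25) {
    n <- sample(4:10, 1)
    genes <- paste0("g", 1:n)
    m <- sample(3:14, 1)
    from <- sample(genes, m, replace = TRUE)
    to <- sample(genes, m, replace = TRUE)
    keep <- from != to
    if (!any(keep)) next
    e <- unique(data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE))
    sg <- make_sg(e$from, e$to)
    roles <- find_sources_sinks(sg)
    for (src in roles$gene_id[roles$role == "source"]) {
      expected <- oracle_reachable(sg$induced_edges, sg$genes, src)
      expect_equal(
        impact_score(src, sg),
        100 * length(expected) / (length(sg$genes) - 1),
        tolerance = 1e-12
      )
    }
  }
})

test_that("impact scores are not normalized across sources", {
  # two sources sharing downstream genes: reaches may sum past |genes| - 1
  sg <- make_sg(c("a", "c", "b"), c("b", "b", "d")) # a->b, c->b, b->d
  expect_equal(impact_score("a", sg), 100 * 2 / 3)
  expect_equal(impact_score("c", sg), 100 * 2 / 3)
  total_reach <- 2 + 2
  expect_gt(total_reach, length(sg$genes) - 1)
})

test_that("source reliability separates distinct regulation regimes", {
  # source s: three downstream members with tiny p, three global upstream
  # regulators with large p
  net <- interaction_network(
    c("s", "s", "s", "u1", "u2", "u3"),
    c("d1", "d2", "d3", "s", "s", "s")
  )
  dg <- dgea_table(
    c("s", "d1", "d2", "d3", "u1", "u2", "u3"),
    c(1e-5, 0.001, 0.002, 0.001, 0.9, 0.85, 0.95)
  )
  sg <- make_sg(c("s", "s", "s"), c("d1", "d2", "d3"),
                p = c(1e-5, 0.001, 0.002, 0.001))
  rel <- source_reliability("s", sg, net, dg)
  expect_true(rel$computable)
  expect_lt(rel$t, 0) # downstream ln p far below upstream ln p
  expect_lt(rel$p, 0.05)
  expect_identical(rel$n_down, 3L)
  expect_identical(rel$n_up, 3L)
  # oracle: Welch t on the natural-log values by the standard formula
  down <- log(c(0.001, 0.002, 0.001))
  up <- log(c(0.9, 0.85, 0.95))
  se <- sqrt(var(down) / 3 + var(up) / 3)
  expect_equal(rel$t, (mean(down) - mean(up)) / se, tolerance = 1e-10)
})

test_that("the reliability test is invariant to the log base", {
  # changing base rescales both groups by the same constant; Welch's t is
  # scale-invariant, so p must be unchanged -- checked via direct formula
  down <- log(c(0.001, 0.03, 0.01))
  up <- log(c(0.4, 0.9, 0.2))
  t_nat <- t.test(down, up)$statistic
  t_10 <- t.test(down / log(10), up / log(10))$statistic
  expect_equal(unname(t_nat), unname(t_10), tolerance = 1e-12)
})

test_that("degenerate reliability groups are flagged, not raised", {
  net <- interaction_network(c("s", "s"), c("d1", "d2")) # no global upstream
  dg <- dgea_table(c("s", "d1", "d2"), c(0.001, 0.01, 0.02))
  sg <- make_sg(c("s", "s"), c("d1", "d2"), p = c(0.001, 0.01, 0.02))
  rel <- source_reliability("s", sg, net, dg)
  expect_false(rel$computable)
  expect_true(is.na(rel$t))
  expect_identical(rel$n_up, 0L)
})

test_that("annotate_subgraphs assembles ordered per-sub-graph annotation rows", {
  fx <- chain_fixture()
  res <- msf_search(fx$network, fx$dgea)
  ann <- annotate_subgraphs(res$subgraphs, fx$network, fx$dgea)
  expect_identical(ann$gene_id[ann$role == "source"], "a")
  expect_identical(ann$gene_id[ann$role == "sink"], "c")
  expect_equal(ann$impact_score[ann$role == "source"], 100)
  # a has no upstream regulators in this network: not computable
  expect_true(is.na(ann$reliability_p[ann$role == "source"]))
})
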