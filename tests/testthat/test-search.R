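# Seed / extend / merge / finalize heuristic. Expected combined p-values in
# the worked examples are frozen from oracle_p() (independent re-derivation
# of the scorer), not from the implementation.

test_that("initialization seeds at the smallest p and grows only on strict improvement", {
  # star around s: strong seed plus one discordant-but-informative neighbor.
  # oracle_p(c(1e-4, 0.03)) = 2.58e-5 < 1e-4 -> n1 joins;
  # adding n2 = 0.3 afterwards fails to improve -> stops at 2 genes.
  net <- interaction_network(c("s", "s"), c("n1", "n2"))
  dg <- dgea_table(c("s", "n1", "n2"), c(1e-4, 0.03, 0.3))
  sgs <- initialize_subgraphs(net, dg)
  expect_identical(length(sgs), 1L) # n2 (p = 0.3) never seeds
  expect_identical(sgs[[1]]$genes, c("n1", "s"))
  expect_equal(sgs[[1]]$score$combined_p, oracle_p(c(1e-4, 0.03)), tolerance = 1e-12)
})

test_that("concordant near-equal p-values do not combine (rho penalty)", {
  # both genes strongly significant and nearly identical: estimated rho ~ 1,
  # the combined statistic collapses to the mean score and cannot beat the
  # seed alone
  net <- interaction_network("a", "b")
  dg <- dgea_table(c("a", "b"), c(0.001, 0.002))
  sgs <- initialize_subgraphs(net, dg)
  expect_identical(length(sgs), 2L)
  expect_identical(sgs[[1]]$genes, "a")
  expect_identical(sgs[[2]]$genes, "b")
  expect_gt(oracle_p(c(0.001, 0.002)), 0.001) # why: no improvement
})

test_that("isolated significant genes become singletons and null instances yield no seeds", {
  net <- interaction_network("x", "y", nodes = c("g", "x", "y"))
  dg <- dgea_table(c("g", "x", "y"), c(0.01, 0.5, 0.6))
  sgs <- initialize_subgraphs(net, dg)
  expect_identical(length(sgs), 1L)
  expect_identical(sgs[[1]]$genes, "g")
  # no gene below seed_alpha -> no sub-graphs at all
  dg2 <- dgea_table(c("g", "x", "y"), c(0.5, 0.5, 0.5))
  expect_identical(length(initialize_subgraphs(net, dg2)), 0L)
  # disjoint network and DGEA -> empty with a warning
  dg3 <- dgea_table("zzz", 0.001)
  expect_warning(res <- initialize_subgraphs(net, dg3), "share no")
  expect_identical(length(res), 0L)
})

test_that("extension bridges a two-gene gap that a one-gene path cannot", {
  fx <- chain_fixture()
  # seed gate set between p(c) = 5e-4 and p(a) = 1e-3 so that only c seeds
  # and the whole gap-bridging burden falls on the extension step
  cfg2 <- msf_config(seed_alpha = 7e-4, max_extension_len = 2)
  cfg1 <- msf_config(seed_alpha = 7e-4, max_extension_len = 1)
  init2 <- initialize_subgraphs(fx$network, fx$dgea, cfg2)
  expect_identical(length(init2), 1L)
  expect_identical(init2[[1]]$genes, "c") # only c passes the seed gate;
  # its immediate neighbor x alone does not improve: oracle_p(c(5e-4, 0.6)) = 0.0159
  ext2 <- extend_subgraphs(init2, fx$network, fx$dgea, cfg2)
  expect_identical(ext2[[1]]$genes, c("a", "b", "c", "x"))
  # path [x, b] accepted (oracle_p(c(5e-4, .6, .002)) = 3.19e-4 < 5e-4),
  # then [a] from b; frozen end point:
  expect_equal(ext2[[1]]$score$combined_p,
               oracle_p(c(0.001, 0.002, 0.6, 5e-4)), tolerance = 1e-12)

  init1 <- initialize_subgraphs(fx$network, fx$dgea, cfg1)
  ext1 <- extend_subgraphs(init1, fx$network, fx$dgea, cfg1)
  expect_identical(ext1[[1]]$genes, "c") # no single-gene path improves
})

test_that("extension never touches genes already assigned to another sub-graph", {
  # chain s1 - m - s2: both ends seed separately; m stays free after
  # initialization (adding it improves neither singleton), so each end may
  # only reach m itself, never the other sub-graph's member
  net <- interaction_network(c("s1", "m"), c("m", "s2"))
  dg <- dgea_table(c("s1", "m", "s2"), c(0.002, 0.5, 0.003))
  cfg <- msf_config(max_extension_len = 2)
  init <- initialize_subgraphs(net, dg, cfg)
  expect_identical(length(init), 2L)
  ext <- extend_subgraphs(init, net, dg, cfg)
  all_genes <- lapply(ext, `[[`, "genes")
  expect_false(any(duplicated(unlist(all_genes))))
})

test_that("merging joins two sub-graphs through a connector when both improve", {
  # s1 - m - s2 again: extension cannot merge them, the merge step can.
  # oracle_p(c(0.002, 0.5, 0.003)) = 5.8e-4 < both 0.002 and 0.003.
  net <- interaction_network(c("s1", "m"), c("m", "s2"))
  dg <- dgea_table(c("s1", "m", "s2"), c(0.002, 0.5, 0.003))
  init <- initialize_subgraphs(net, dg)
  mrg <- merge_subgraphs(init, net, dg)
  expect_identical(length(mrg), 1L)
  expect_identical(mrg[[1]]$genes, c("m", "s1", "s2"))
  expect_equal(mrg[[1]]$score$combined_p, oracle_p(c(0.002, 0.5, 0.003)),
               tolerance = 1e-12)
  log <- attr(mrg, "merge_log")
  expect_identical(nrow(log), 1L)
  expect_lt(log$merged_p, log$parent_a_p)
  expect_lt(log$merged_p, log$parent_b_p)
})

test_that("merging respects the connector length bound", {
  # three mildly informative intermediates (p = 0.15) between the seeds:
  # the 5-gene union scores 1.9e-4 < both parents, but the connector needs
  # 3 genes and is out of reach at the default bound of 2
  net <- interaction_network(c("s1", "m1", "m2", "m3"), c("m1", "m2", "m3", "s2"))
  dg <- dgea_table(c("s1", "m1", "m2", "m3", "s2"), c(0.002, 0.15, 0.15, 0.15, 0.003))
  expect_lt(oracle_p(c(0.002, 0.15, 0.15, 0.15, 0.003)), 0.002)
  init <- initialize_subgraphs(net, dg)
  expect_identical(length(init), 2L) # immediate growth refused on both ends
  mrg <- merge_subgraphs(init, net, dg, msf_config(max_connector_len = 2))
  expect_identical(length(mrg), 2L)
  mrg3 <- merge_subgraphs(init, net, dg, msf_config(max_connector_len = 3))
  expect_identical(length(mrg3), 1L)
  expect_identical(mrg3[[1]]$genes, c("m1", "m2", "m3", "s1", "s2"))
})

test_that("a merge improving only one parent is rejected", {
  # s1 = 0.002, s2 = 0.04 adjacent: union p beats s2 but not s1
  net <- interaction_network("s1", "s2")
  dg <- dgea_table(c("s1", "s2"), c(0.002, 0.04))
  union_p <- oracle_p(c(0.002, 0.04))
  expect_lt(union_p, 0.04)
  expect_gt(union_p, 0.002)
  init <- initialize_subgraphs(net, dg)
  expect_identical(length(init), 2L) # growth also refused it (same comparison)
  mrg <- merge_subgraphs(init, net, dg)
  expect_identical(length(mrg), 2L)
})

test_that("finalize filters by size and alpha, ranks by combined p and induces edges", {
  fake <- function(genes, p) {
    sg <- list(id = NA_integer_, genes = genes, induced_edges = NULL,
               score = combine_pvalues(p))
    class(sg) <- "msf_subgraph"
    sg
  }
  net <- interaction_network(c("a", "b", "d"), c("b", "c", "e"))
  sgs <- list(
    fake("z", 0.01),                       # singleton: dropped at min size 2
    fake(c("a", "b", "c"), c(0.3, 0.3, 0.35)), # combined p above alpha: dropped
    fake(c("a", "b", "c"), c(1e-4, 0.03, 0.04)),
    fake(c("d", "e"), c(1e-6, 0.01))
  )
  fin <- finalize_subgraphs(sgs, net, msf_config())
  expect_identical(length(fin), 2L)
  expect_identical(vapply(fin, `[[`, integer(1), "id"), 1:2)
  # ranked ascending by combined p
  expect_lt(fin[[1]]$score$combined_p, fin[[2]]$score$combined_p)
  abc <- fin[[which(vapply(fin, function(s) "a" %in% s$genes, logical(1)))]]
  expect_identical(nrow(abc$induced_edges), 2L) # a->b and b->c from the full network
})

test_that("the search terminates with disjoint, connected sub-graphs and improving merges", {
  set.seed(421)
  for (i in 1:40) {
    inst <- random_small_instance()
    res <- msf_search(inst$network, inst$dgea,
                      msf_config(report_min_size = 1, report_alpha = 1))
    genes <- unlist(lapply(res$subgraphs, `[[`, "genes"))
    expect_false(any(duplicated(genes)))
    for (sg in res$subgraphs) expect_connected_undirected(sg)
    if (nrow(res$merge_log)) {
      expect_true(all(res$merge_log$merged_p < res$merge_log$parent_a_p))
      expect_true(all(res$merge_log$merged_p < res$merge_log$parent_b_p))
    }
  }
})

test_that("extension and merging only ever lower a sub-graph's combined p", {
  set.seed(517)
  for (i in 1:25) {
    inst <- random_small_instance()
    cfg <- msf_config(report_min_size = 1, report_alpha = 1)
    init <- initialize_subgraphs(inst$network, inst$dgea, cfg)
    if (!length(init)) next
    ext <- extend_subgraphs(init, inst$network, inst$dgea, cfg)
    expect_lte(min(vapply(ext, function(s) s$score$log_p, numeric(1))),
               min(vapply(init, function(s) s$score$log_p, numeric(1))) + 1e-12)
    mrg <- merge_subgraphs(ext, inst$network, inst$dgea, cfg)
    expect_lte(length(mrg), length(ext))
  }
})

test_that("repeated runs on the same input are identical", {
  inst <- generate_instance(120, module_size = 15, signal_beta_a = 0.1, rng_seed = 5)
  r1 <- msf_search(inst$network, inst$dgea)
  r2 <- msf_search(inst$network, inst$dgea)
  expect_identical(
    lapply(r1$subgraphs, `[[`, "genes"),
    lapply(r2$subgraphs, `[[`, "genes")
  )
  expect_identical(r1$counts, r2$counts)
})
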