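graph_from_edges <- function(vertices, edges) {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(vertices)
  if (length(edges)) g <- g + igraph::edges(edges)
  g
}

test_that("correlation_with_pvalue matches hand computation and edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_with_pvalue(x, 2 * x + 3)$r, 1)
  expect_equal(correlation_with_pvalue(x, 2 * x + 3)$p, 0)
  expect_equal(correlation_with_pvalue(x, -x)$r, -1)
  # hand computation: cov/(sd*sd) for y = (2,1,4,3,6)
  y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - 3.2)) /
    sqrt(sum((x - 3)^2) * sum((y - 3.2)^2))
  got <- correlation_with_pvalue(x, y)
  expect_equal(got$r, r_hand)
  expect_equal(got$r, 10 / sqrt(10 * 14.8))   # = 0.8220 by hand
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(got$p, 2 * stats::pt(abs(t_hand), 3, lower.tail = FALSE))
  # degenerate input: zero variance leaves r undefined
  expect_true(is.na(correlation_with_pvalue(rep(1, 5), y)$r))
  expect_error(correlation_with_pvalue(1:2, 1:2), "3")
  expect_error(correlation_with_pvalue(1:4, 1:5), "length")
})

test_that("co-expression network reproduces planted condition-specific modules", {
  p <- sim_params(n_genes = 300L, n_per_group = 20L, baseline_mean = 1000,
                  dispersion = 0.01, frac_up = 0.05, frac_down = 0.05,
                  lfc_magnitude = 1.5, module_sizes = 10L,
                  module_condition = "treated", seed = 71L)
  sim <- generate_counts(p)
  mod <- sim$truth$module_members[[1]]$genes
  degs <- c(sim$truth$de_genes_up, sim$truth$de_genes_down)
  expr <- compute_rpkm(sim$counts)[degs, ]
  net_c <- build_coexpression_network(expr, sim$counts$design, "control")
  net_t <- build_coexpression_network(expr, sim$counts$design, "treated")
  deg_c <- node_degree(net_c); deg_t <- node_degree(net_t)
  # module genes: near-clique in treated, isolated in control
  expect_true(all(deg_t[mod] >= 5))
  expect_true(all(deg_c[mod] <= 1))
  # metadata records the selection rule
  expect_equal(igraph::graph_attr(net_t, "min_abs_r"), 0.8)
  expect_equal(igraph::graph_attr(net_t, "alpha"), 0.05)
  # symmetry: undirected graph, edge (g,h) <=> edge (h,g)
  expect_false(igraph::is_directed(net_t))
})

test_that("null expression yields few edges; identical rows give r = 1 edges", {
  set.seed(81)
  expr <- matrix(rnorm(50 * 20), nrow = 50,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  design <- data.frame(sample_id = paste0("s", 1:20),
                       condition = rep(c("control", "treated"), each = 10))
  net <- build_coexpression_network(expr, design, "control",
                                    min_abs_r = 0, alpha = 0.05)
  # with min_abs_r = 0 the rule is p < alpha alone: null edge density ~ alpha
  dens <- igraph::ecount(net) / choose(50, 2)
  expect_lt(dens, 0.05 * 2.5)
  # duplicated gene rows correlate exactly
  expr2 <- expr
  expr2["g2", ] <- 2 * expr2["g1", ]
  net2 <- build_coexpression_network(expr2, design, "control")
  expect_true(igraph::are_adjacent(net2, "g1", "g2"))
  w <- igraph::E(net2)$weight[igraph::get_edge_ids(net2, c("g1", "g2"))]
  expect_equal(w, 1)
  # < 3 samples errors, < 5 warns
  design3 <- data.frame(sample_id = paste0("s", 1:4),
                        condition = c("control", "control",
                                      "treated", "treated"))
  expect_error(build_coexpression_network(expr[, 1:4], design3, "control"),
               "fewer than 3")
  design8 <- data.frame(sample_id = paste0("s", 1:8),
                        condition = rep(c("control", "treated"), each = 4))
  expect_warning(build_coexpression_network(expr[, 1:8], design8, "control"),
                 "little power")
})

test_that("degree and handshake hold on known graphs", {
  g <- graph_from_edges(c("a", "b", "c", "iso"),
                        c("a", "b", "b", "c", "a", "c"))
  d <- node_degree(g)
  expect_equal(unname(d["iso"]), 0L)
  expect_equal(sum(d), 2L * igraph::ecount(g))
  # complete graph on 39 nodes: every degree 38 (the printed maximum)
  k39 <- igraph::make_full_graph(39)
  igraph::V(k39)$name <- paste0("n", 1:39)
  expect_true(all(node_degree(k39) == 38L))
})

test_that("k-core peeling matches known values and the exhaustive oracle", {
  tri <- graph_from_edges(c("a", "b", "c"),
                          c("a", "b", "b", "c", "a", "c"))
  expect_true(all(core_number(tri) == 2L))
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  expect_true(all(core_number(star) == 1L))
  # exhaustive: all labelled graphs on <= 4 nodes
  for (n in 2:4) {
    pairs <- utils::combn(n, 2)
    for (mask in 0:(2^ncol(pairs) - 1)) {
      on <- which(bitwAnd(mask, 2^(seq_len(ncol(pairs)) - 1)) > 0)
      adj <- matrix(0L, n, n)
      for (k in on) {
        adj[pairs[1, k], pairs[2, k]] <- 1L
        adj[pairs[2, k], pairs[1, k]] <- 1L
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      igraph::V(g)$name <- paste0("v", seq_len(n))
      expect_identical(unname(core_number(g)), oracle_core_number(adj))
    }
  }
  # random graphs with 5-8 nodes against the same oracle
  set.seed(91)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    rg <- random_graph(n, runif(1, 0.2, 0.8))
    got <- core_number(rg$graph)
    expect_identical(unname(got), oracle_core_number(rg$adj))
    # core number never exceeds degree
    expect_true(all(got <= node_degree(rg$graph)))
  }
})

test_that("differential topology reproduces the printed worked examples", {
  topo <- utils::read.delim(extdata("topology_examples.tsv"),
                            stringsAsFactors = FALSE)
  ranked <- rank_topology_table(topo)
  row <- function(g) ranked[ranked$gene == g, ]
  # STAR: degree 6 -> 37, k-core 4 -> 32 => dif 31 / 28
  expect_equal(row("STAR")$dif_degree, 31L)
  expect_equal(row("STAR")$dif_kcore, 28L)
  # DHCR7: k-core 21 -> 32 => dif 11
  expect_equal(row("DHCR7")$dif_kcore, 11L)
  expect_equal(row("DHCR7")$dif_degree, 15L)
  expect_equal(row("FA2H")$dif_degree, 22L)
  # the four degree-0 -> 38 genes share the top |dif_degree| ranks
  expect_setequal(ranked$gene[1:4], c("G0S2", "HSD11B1", "HSD3B2", "CXCL5"))
})

test_that("differential_topology handles disjoint node sets and ties", {
  net_c <- graph_from_edges(c("a", "b", "c"), c("a", "b"))
  net_t <- graph_from_edges(c("b", "c", "d"),
                            c("b", "c", "c", "d", "b", "d"))
  topo <- differential_topology(net_c, net_t)
  expect_setequal(topo$gene, c("a", "b", "c", "d"))
  r <- function(g) topo[topo$gene == g, ]
  expect_equal(r("a")$degree_treated, 0L)   # absent => degree 0
  expect_equal(r("d")$degree_control, 0L)
  expect_equal(r("d")$dif_degree, 2L)
  expect_equal(r("a")$dif_degree, -1L)      # signed treated - control
  expect_identical(topo$rank, seq_len(4L))
  # identical networks: all differences zero
  z <- differential_topology(net_t, net_t)
  expect_true(all(z$dif_degree == 0L & z$dif_kcore == 0L))
  # deterministic tie-break by gene id at equal |dif|s
  expect_identical(z$gene, sort(z$gene))
})

test_that("gene-act network induces modules from the background relations", {
  rel <- graph_from_edges(
    c("HSD11B1", "AKR1C4", "SRD5A3", "HSD3B2", "x", "y", "z"),
    c("HSD11B1", "AKR1C4", "HSD11B1", "SRD5A3", "HSD11B1", "HSD3B2",
      "AKR1C4", "SRD5A3", "AKR1C4", "HSD3B2", "SRD5A3", "HSD3B2",
      "x", "y"))
  degs <- c("HSD11B1", "AKR1C4", "SRD5A3", "HSD3B2", "x", "y", "z", "absent")
  res <- gene_act_network(degs, rel)
  # 4-clique module reported first, largest-first ordering
  expect_length(res$modules, 2)
  expect_setequal(res$modules[[1]],
                  c("AKR1C4", "HSD11B1", "HSD3B2", "SRD5A3"))
  expect_setequal(res$modules[[2]], c("x", "y"))
  # module list invariant to DEG order
  res2 <- gene_act_network(rev(degs), rel)
  expect_identical(res$modules, res2$modules)
  # DEGs sharing no relation: no edges
  res3 <- gene_act_network(c("x", "z"), rel)
  expect_equal(igraph::ecount(res3$graph), 0)
  expect_length(res3$modules, 0)
})

test_that("pathway-act network links pathways by shared genes and ranks hubs", {
  sets <- list(p1 = c("a", "b", "c"), p2 = c("c", "d"), p3 = c("c", "e"),
               p4 = c("x", "y"))
  res <- pathway_act_network(c("p1", "p2", "p3", "p4"), sets,
                             min_shared = 1L)
  # p1-p2-p3 triangle through shared gene c; p4 disjoint
  expect_equal(unname(node_degree(res$graph)[c("p1", "p2", "p3", "p4")]),
               c(2L, 2L, 2L, 0L))
  expect_identical(res$hubs$pathway[4], "p4")
  # disjoint pathways: empty graph
  res2 <- pathway_act_network(c("p1", "p4"), sets)
  expect_equal(igraph::ecount(res2$graph), 0)
  # a pathway overlapping five others is the top hub
  sets3 <- c(list(hub = letters[1:5]),
             stats::setNames(lapply(letters[1:5], function(x) c(x, "zz")),
                             paste0("q", 1:5)))
  res3 <- pathway_act_network(names(sets3), sets3, min_shared = 1L)
  expect_identical(res3$hubs$pathway[1], "hub")
  expect_equal(res3$hubs$degree[1], 5L)
  expect_error(pathway_act_network("nope", sets), "nope")
})
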