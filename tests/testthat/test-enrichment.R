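chain_dag <- function() {
  # root <- A <- B, gene g annotated to B
  ontology_dag(terms = data.frame(term_id = c("root", "A", "B"),
                                  term_name = c("root", "A", "B")),
               edges = data.frame(child = c("A", "B"),
                                  parent = c("root", "A")),
               annotations = list(B = "g"))
}

test_that("true-path closure propagates annotations up chains and diamonds", {
  closed <- propagate_annotations(chain_dag())
  expect_identical(closed$annotations$B, "g")
  expect_identical(closed$annotations$A, "g")
  expect_identical(closed$annotations$root, "g")
  # diamond: two paths leaf -> root, gene counted once at the root
  dia <- ontology_dag(
    terms = data.frame(term_id = c("root", "L", "R", "leaf"),
                       term_name = c("root", "L", "R", "leaf")),
    edges = data.frame(child = c("L", "R", "leaf", "leaf"),
                       parent = c("root", "root", "L", "R")),
    annotations = list(leaf = c("g1", "g2")))
  closed <- propagate_annotations(dia)
  expect_identical(closed$annotations$root, c("g1", "g2"))
  expect_length(closed$annotations$root, 2)   # set semantics
})

test_that("closure matches the brute-force reachability oracle on random DAGs", {
  set.seed(99)
  genes <- sprintf("g%02d", 1:25)
  for (rep in 1:10) {
    ont <- generate_ontology(sample(5:20, 1), max_parents = 3L,
                             annotation_rate = 0.5, genes = genes,
                             seed = 100L + rep)
    closed <- propagate_annotations(ont$dag)
    oracle <- oracle_closure(ont$dag$edges, ont$dag$annotations,
                             ont$dag$terms$term_id)
    for (t in ont$dag$terms$term_id) {
      got <- closed$annotations[[t]]
      expect_identical(if (is.null(got)) character(0) else got,
                       oracle[[t]])
    }
    # closure monotonicity: parent's closed set contains each child's
    for (i in seq_len(nrow(ont$dag$edges))) {
      ch <- closed$annotations[[ont$dag$edges$child[i]]]
      pa <- closed$annotations[[ont$dag$edges$parent[i]]]
      expect_true(all(ch %in% pa))
    }
  }
})

test_that("cycles are detected and the offending edge named", {
  cyc <- chain_dag()
  cyc$edges <- rbind(cyc$edges, data.frame(child = "root", parent = "B"))
  expect_error(propagate_annotations(cyc), "cycle")
})

test_that("enrichment ratio Re is the exact ratio of proportions", {
  # worked example: n_f = 15, n = 122, N_f = 149, N = 20000 (assumed N)
  expect_equal(enrichment_ratio(15, 122, 149, 20000),
               (15 / 122) / (149 / 20000))
  expect_equal(enrichment_ratio(15, 122, 149, 20000), 16.50, tolerance = 0.01)
  expect_equal(enrichment_ratio(5, 50, 10, 100), 1)     # equal proportions
  expect_equal(enrichment_ratio(7, 7, 100, 100), 1)     # n_f=n, N_f=N
  expect_true(is.na(enrichment_ratio(0, 0, 10, 100)))   # empty category
  expect_true(is.na(enrichment_ratio(0, 5, 0, 100)))    # no DEGs
  # Re > 1 iff the in-category DEG proportion beats the global one
  set.seed(12)
  for (i in 1:50) {
    N <- sample(20:200, 1); N_f <- sample(1:N, 1)
    n <- sample(1:N, 1); n_f <- sample(0:min(n, N_f), 1)
    re <- enrichment_ratio(n_f, n, N_f, N)
    expect_identical(re > 1, (n_f / n) > (N_f / N))
  }
})

test_that("chi-square 2x2 is uncorrected Pearson with the zero-marginal rule", {
  res <- chi_square_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  # hand computation: table (20,5;5,20), all expected = 12.5,
  # statistic = 4 * 7.5^2 / 12.5 = 18 ... per-cell (O-E)^2/E = 4.5 => 18
  res2 <- chi_square_2x2(matrix(c(20, 5, 5, 20), 2))
  expect_equal(res2$statistic, 4 * (7.5^2) / 12.5)
  expect_equal(res2$p, stats::pchisq(18, 1, lower.tail = FALSE))
  # row swap leaves p unchanged
  res3 <- chi_square_2x2(matrix(c(5, 20, 20, 5), 2))
  expect_equal(res3$p, res2$p)
  expect_warning(z <- chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
  expect_equal(z$p, 1)
})

test_that("one-sided Fisher p equals the hypergeometric tail everywhere", {
  # worked example: N=20, N_f=5, n=4, n_f=4 -> C(5,4)*C(15,0)/C(20,4)
  res <- fisher_enrichment("d1", c("d1", paste0("u", 1:19)),
                           list(t1 = "d1"))
  expect_equal(res$fisher_p, 1 / 20)
  p_example <- oracle_fisher_tail(4, 4, 5, 20)
  expect_equal(p_example, 5 / 4845)
  expect_equal(p_example, 1.032e-3, tolerance = 1e-3)
  # exhaustive sweep over all 2x2 tables with N <= 30
  for (N in 1:30) for (N_f in 0:N) for (n in 0:N) {
    n_f <- max(0, n + N_f - N):min(n, N_f)
    got <- coexdiff:::hyper_tail_p(n_f, n, N_f, N)
    want <- vapply(n_f, oracle_fisher_tail, 0, n = n, N_f = N_f, N = N)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("fisher_enrichment builds the right table per term", {
  universe <- paste0("g", 1:20)
  degs <- paste0("g", 1:5)
  sets <- list(hit = paste0("g", 1:4),          # n_f=4, n=4
               cold = paste0("g", 10:15),       # n_f=0
               mixed = paste0("g", 4:9))        # n_f=2, n=6
  res <- fisher_enrichment(degs, universe, sets)
  expect_identical(res$n_f, c(4L, 0L, 2L))
  expect_identical(res$n, c(4L, 6L, 6L))
  expect_true(all(res$N == 20 & res$N_f == 5))
  # n_f = 0 => one-sided p = 1
  expect_equal(res$fisher_p[res$term_id == "cold"], 1)
  expect_equal(res$fisher_p[res$term_id == "hit"],
               oracle_fisher_tail(4, 4, 5, 20))
  expect_identical(res$genes[res$term_id == "mixed"], "g4;g5")
  expect_equal(res$fdr, bh_fdr(res$fisher_p))
  expect_equal(res$Re, enrichment_ratio(res$n_f, res$n, res$N_f, res$N))
  # invariants n_f <= min(n, N_f), n <= N
  expect_true(all(res$n_f <= pmin(res$n, res$N_f) & res$n <= res$N))
  # monotonicity: padding a term with non-DEG genes cannot lower fisher_p
  res_pad <- fisher_enrichment(degs, universe,
                               list(hit = c(sets$hit, "g16", "g17")))
  expect_gte(res_pad$fisher_p, res$fisher_p[res$term_id == "hit"])
  # empty DEG set: p = 1, Re missing, with a warning
  expect_warning(res0 <- fisher_enrichment(character(0), universe, sets),
                 "empty")
  expect_true(all(res0$fisher_p == 1) && all(is.na(res0$Re)))
})

test_that("filter_enriched keeps p < 0.05 and fdr < 0.05, sorted by p", {
  res <- data.frame(term_id = c("a", "b", "c", "d"),
                    fisher_p = c(0.04, 6.79e-12, 0.2, 0.01),
                    fdr = c(0.06, 1e-10, 0.3, 0.04))
  out <- filter_enriched(res)
  # (p=0.04, fdr=0.06) dropped; tiny p kept; sorted ascending by p
  expect_identical(out$term_id, c("b", "d"))
  expect_identical(nrow(filter_enriched(res[0, , drop = FALSE])), 0L)
})

test_that("GO tree includes ancestors and labels regulation", {
  dag <- ontology_dag(
    terms = data.frame(term_id = c("root", "A", "B", "C"),
                       term_name = c("root", "A", "B", "C")),
    edges = data.frame(child = c("A", "B", "C"),
                       parent = c("root", "A", "A")),
    annotations = list(B = c("up1", "up2"), C = c("dn1", "up1")))
  degs <- data.frame(gene = c("up1", "up2", "dn1"),
                     call = c("up", "up", "down"))
  # only B enriched: its ancestors A and root must appear anyway
  tree <- build_go_tree("B", dag, degs)
  expect_setequal(igraph::V(tree)$name, c("B", "A", "root"))
  reg <- stats::setNames(igraph::V(tree)$regulation, igraph::V(tree)$name)
  expect_identical(unname(reg["B"]), "up")          # all members up
  expect_identical(unname(reg["A"]), "ambiguous")   # up + down after closure
  # all-down term labels down; majority rule flips mixed-majority terms
  tree2 <- build_go_tree(c("B", "C"), dag, degs)
  reg2 <- stats::setNames(igraph::V(tree2)$regulation,
                          igraph::V(tree2)$name)
  expect_identical(unname(reg2["C"]), "ambiguous")
  tree3 <- build_go_tree("A", dag, degs, rule = "majority")
  reg3 <- stats::setNames(igraph::V(tree3)$regulation,
                          igraph::V(tree3)$name)
  expect_identical(unname(reg3["A"]), "up")   # 2 up vs 1 down
  expect_error(build_go_tree("missing", dag, degs), "missing")
  # DAG edges of the induced tree stay acyclic
  expect_true(igraph::is_dag(tree2))
})

test_that("enrichment table writer keeps counts consistent with gene lists", {
  universe <- paste0("g", 1:30)
  sets <- list(t1 = paste0("g", 1:10), t2 = paste0("g", 5:25))
  res <- fisher_enrichment(paste0("g", 1:8), universe, sets)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_tsv(res, path)
  back <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_identical(count_listed_genes(back$genes), back$significant_nf)
})
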