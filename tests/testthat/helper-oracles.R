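# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force / closed form, deliberately avoiding the package's
# own code path.

# one-sided hypergeometric tail by explicit sum of choose() terms
oracle_fisher_tail <- function(n_f, n, N_f, N) {
  ks <- n_f:min(n, N_f)
  sum(choose(N_f, ks) * choose(N - N_f, n - ks)) / choose(N, n)
}

# BH step-up: q_i = min_{j >= i} m * p_(j) / j, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- rev(cummin(rev(m * p[ord] / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# core number by exhaustive search: max over induced subgraphs containing v
# of the subgraph's minimum degree. adj = adjacency matrix (0/1, symmetric).
oracle_core_number <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  for (i in seq_len(nrow(subsets))) {
    keep <- which(unlist(subsets[i, ]))
    if (!length(keep)) next
    sub <- adj[keep, keep, drop = FALSE]
    mindeg <- as.integer(min(rowSums(sub)))
    core[keep] <- pmax(core[keep], mindeg)
  }
  core
}

# ancestor closure of annotations by per-gene DFS over the parent relation
oracle_closure <- function(edges, annotations, term_ids) {
  parents_of <- split(edges$parent, edges$child)
  reach_up <- function(t) {
    seen <- character(0); stack <- t
    while (length(stack)) {
      x <- stack[1]; stack <- stack[-1]
      if (x %in% seen) next
      seen <- c(seen, x)
      stack <- c(stack, parents_of[[x]])
    }
    seen
  }
  closed <- stats::setNames(vector("list", length(term_ids)), term_ids)
  for (t in names(annotations)) {
    for (anc in reach_up(t))
      closed[[anc]] <- union(closed[[anc]], annotations[[t]])
  }
  lapply(closed, function(g) sort(as.character(g)))
}

# random simple undirected igraph on n named nodes
random_graph <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(n))
  list(graph = g, adj = adj)
}

extdata <- function(name) {
  system.file("extdata", name, package = "coexdiff", mustWork = TRUE)
}
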