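# Term-level over-representation: true-path annotation propagation, Fisher /
# chi-square tests on the 2x2 membership table, the enrichment ratio Re,
# significance filtering, and GO-tree construction with regulation labels.

# Topological order of terms (children before parents). Errors on a cycle,
# naming one offending edge.
topo_order <- function(dag) {
  ids <- dag$terms$term_id
  kids <- split(dag$edges$child, dag$edges$parent)   # parent -> children
  n_unresolved <- stats::setNames(
    vapply(ids, function(t) length(kids[[t]]), 1L), ids)
  queue <- ids[n_unresolved == 0]                    # leaves first
  parents_of <- split(dag$edges$parent, dag$edges$child)
  order <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    order <- c(order, t)
    for (pa in parents_of[[t]]) {
      n_unresolved[pa] <- n_unresolved[pa] - 1L
      if (n_unresolved[pa] == 0L) queue <- c(queue, pa)
    }
  }
  if (length(order) < length(ids)) {
    stuck <- ids[!ids %in% order]
    bad <- dag$edges[dag$edges$child %in% stuck & dag$edges$parent %in% stuck, ]
    stop("ontology contains a cycle through edge ",
         bad$child[1], " -> ", bad$parent[1])
  }
  order
}

#' True-path annotation propagation
#'
#' Closes the ontology's annotations upward: after closure each term's gene
#' set is the union of its direct annotations and the closed sets of all its
#' children (equivalently, of all descendants), with set semantics so a gene
#' reachable along several paths counts once.
#'
#' @param dag an [ontology_dag()] with direct annotations.
#' @return the same ontology with closed annotation sets (`closed = TRUE`).
#' @export
propagate_annotations <- function(dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  order <- topo_order(dag)   # children before parents; also checks acyclicity
  kids <- split(dag$edges$child, dag$edges$parent)
  closed <- dag$annotations
  for (t in order) {
    sets <- c(closed[t], closed[kids[[t]]])
    merged <- unique(unlist(sets, use.names = FALSE))
    if (length(merged)) closed[[t]] <- sort(merged)
  }
  out <- dag
  out$annotations <- closed
  out$closed <- TRUE
  out
}

#' Enrichment ratio Re
#'
#' `Re = (n_f / n) / (N_f / N)`: the DEG proportion inside a category
#' relative to the global DEG proportion. Undefined (NA) when the category
#' is empty (n = 0) or there are no DEGs (N_f = 0).
#'
#' @param n_f DEGs inside the category.
#' @param n universe genes inside the category.
#' @param N_f total DEGs.
#' @param N universe size.
#' @return numeric Re (vectorized), NA where undefined.
#' @export
enrichment_ratio <- function(n_f, n, N_f, N) {
  if (any(N <= 0)) stop("`N` must be positive")
  re <- (n_f / n) / (N_f / N)
  re[n == 0 | N_f == 0] <- NA_real_
  re
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction) Pearson statistic on 1 df,
#' upper-tail p. A table with a zero row or column marginal carries no
#' association information: p = 1 by convention, with a warning.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0))
    stop("`tab` must be a non-negative 2x2 table")
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("zero marginal in 2x2 table; p = 1 by convention")
    return(list(statistic = 0, p = 1))
  }
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# one-sided (over-representation) hypergeometric tail P(X >= n_f)
hyper_tail_p <- function(n_f, n, N_f, N) {
  stats::phyper(n_f - 1, N_f, N - N_f, n, lower.tail = FALSE)
}

#' Over-representation test across term gene sets
#'
#' For each term builds the 2x2 table (DEG in term, DEG outside, non-DEG in
#' term, non-DEG outside) and reports the one-sided Fisher p (hypergeometric
#' tail `P(X >= n_f)`), the uncorrected chi-square p, the enrichment ratio
#' Re, and BH-FDR across all tested terms.
#'
#' @param deg_set character vector of DEG ids (subset of `universe`).
#' @param universe character vector, the gene universe N.
#' @param term_sets named list of character gene vectors (each a subset of
#'   `universe`); closed sets if the true-path rule is wanted.
#' @param two_sided use the two-sided Fisher test instead of the default
#'   one-sided over-representation test.
#' @return data.frame with one row per term: term_id, term_name, n_f, n,
#'   N_f, N, Re, fisher_p, chisq_p, fdr, genes (semicolon-joined DEGs in
#'   the term).
#' @export
fisher_enrichment <- function(deg_set, universe, term_sets,
                              two_sided = FALSE) {
  deg_set <- unique(as.character(deg_set))
  universe <- unique(as.character(universe))
  if (!all(deg_set %in% universe))
    stop("`deg_set` must be a subset of `universe`")
  N <- length(universe); N_f <- length(deg_set)
  if (N_f == 0)
    warning("empty DEG set: all fisher_p = 1, Re undefined")
  rows <- lapply(names(term_sets), function(id) {
    members <- intersect(term_sets[[id]], universe)
    hits <- intersect(members, deg_set)
    n <- length(members); n_f <- length(hits)
    fp <- if (N_f == 0) 1
          else if (two_sided)
            stats::fisher.test(matrix(c(n_f, n - n_f, N_f - n_f,
                                        N - n - N_f + n_f), 2))$p.value
          else hyper_tail_p(n_f, n, N_f, N)
    cp <- withCallingHandlers(
      chi_square_2x2(matrix(c(n_f, n - n_f, N_f - n_f,
                              N - n - N_f + n_f), 2))$p,
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(term_id = id, n_f = n_f, n = n, N_f = N_f, N = N,
               Re = enrichment_ratio(n_f, n, N_f, N),
               fisher_p = fp, chisq_p = cp,
               genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(term_id = character(0), n_f = integer(0),
                      n = integer(0), N_f = integer(0), N = integer(0),
                      Re = numeric(0), fisher_p = numeric(0),
                      chisq_p = numeric(0), genes = character(0),
                      stringsAsFactors = FALSE)
  out$fdr <- if (nrow(out)) bh_fdr(out$fisher_p) else numeric(0)
  nm <- attr(term_sets, "descriptions")
  out$term_name <- if (!is.null(nm) && all(out$term_id %in% names(nm)))
    unname(nm[out$term_id]) else out$term_id
  out[, c("term_id", "term_name", "n_f", "n", "N_f", "N", "Re",
          "fisher_p", "chisq_p", "fdr", "genes")]
}

#' Filter enrichment results on raw p and FDR
#'
#' Keeps terms with `fisher_p < p_max` and `fdr < fdr_max` (both strict),
#' sorted ascending by fisher_p.
#'
#' @param results data.frame from [fisher_enrichment()].
#' @param p_max,fdr_max thresholds (defaults 0.05 and 0.05).
#' @return the filtered, sorted data.frame.
#' @export
filter_enriched <- function(results, p_max = 0.05, fdr_max = 0.05) {
  keep <- !is.na(results$fisher_p) & results$fisher_p < p_max &
    !is.na(results$fdr) & results$fdr < fdr_max
  out <- results[keep, , drop = FALSE]
  out[order(out$fisher_p, out$term_id), , drop = FALSE]
}

# all ancestors (transitive parents) of the given terms
ancestors_of <- function(terms, dag) {
  parents_of <- split(dag$edges$parent, dag$edges$child)
  seen <- character(0)
  frontier <- terms
  while (length(frontier)) {
    pa <- setdiff(unique(unlist(parents_of[frontier], use.names = FALSE)),
                  seen)
    seen <- c(seen, pa)
    frontier <- pa
  }
  seen
}

#' Build the GO tree of enriched terms
#'
#' The induced sub-DAG over the enriched terms plus all their ancestors,
#' with a per-node regulation label derived from the DEGs annotated (after
#' closure) to the term: `up` if every annotated DEG is up-regulated,
#' `down` if every one is down-regulated, otherwise `ambiguous`. Under
#' `rule = "majority"` the label follows the strict majority instead, with
#' ties ambiguous.
#'
#' @param enriched_terms character vector of enriched term ids.
#' @param dag an [ontology_dag()]; closed automatically if not already.
#' @param deg_records data.frame with columns gene and call (from
#'   [screen_degs()]).
#' @param rule labelling rule, `"all"` (default) or `"majority"`.
#' @return directed igraph (edges child -> parent) with vertex attributes
#'   `regulation`, `enriched` and `term_name`.
#' @export
build_go_tree <- function(enriched_terms, dag, deg_records,
                          rule = c("all", "majority")) {
  rule <- match.arg(rule)
  stopifnot(inherits(dag, "ontology_dag"))
  missing <- setdiff(enriched_terms, dag$terms$term_id)
  if (length(missing))
    stop("term(s) absent from the ontology: ",
         paste(missing, collapse = ", "))
  if (!dag$closed) dag <- propagate_annotations(dag)
  keep <- unique(c(enriched_terms, ancestors_of(enriched_terms, dag)))
  edges <- dag$edges[dag$edges$child %in% keep & dag$edges$parent %in% keep, ]
  up <- deg_records$gene[deg_records$call == "up"]
  down <- deg_records$gene[deg_records$call == "down"]
  label <- vapply(keep, function(t) {
    g <- dag$annotations[[t]]
    nu <- length(intersect(g, up)); nd <- length(intersect(g, down))
    if (nu + nd == 0) return("ambiguous")
    if (rule == "all") {
      if (nd == 0) "up" else if (nu == 0) "down" else "ambiguous"
    } else {
      if (nu > nd) "up" else if (nd > nu) "down" else "ambiguous"
    }
  }, character(1))
  nm <- stats::setNames(dag$terms$term_name, dag$terms$term_id)
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(keep, regulation = unname(label),
                     enriched = keep %in% enriched_terms,
                     term_name = unname(nm[keep]))
  if (nrow(edges))
    g <- g + igraph::edges(as.vector(t(as.matrix(edges))))
  g
}
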