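# Network analysis: per-condition Pearson co-expression networks, degree and
# k-core, differential topology ranking of key regulatory genes, and the
# gene-act / pathway-act networks on a background relation graph.

#' Pearson correlation with a t-distribution p-value
#'
#' Two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom; |r| = 1 gives p = 0. Zero variance in either vector leaves the
#' correlation undefined (NA, NA).
#'
#' @param x,y numeric vectors of equal length >= 3, finite values.
#' @return list with `r` and `p`.
#' @export
correlation_with_pvalue <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_))
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-12) return(list(r = sign(r), p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE))
}

#' Build a per-condition co-expression network
#'
#' One node per gene in `expr` (typically the DEGs); an edge joins genes g
#' and h iff `|r| >= min_abs_r` and `p < alpha` for the Pearson correlation
#' of their expression across the condition's samples. Edge attribute
#' `weight` stores the signed r. The selection rule and condition are
#' recorded as graph attributes.
#'
#' @param expr numeric matrix (genes x samples), e.g. RPKM restricted to
#'   DEGs.
#' @param design design data.frame with sample_id, condition.
#' @param condition the condition whose samples are used.
#' @param min_abs_r,alpha edge selection rule (defaults 0.8 and 0.05).
#' @return undirected igraph over the genes of `expr`.
#' @export
build_coexpression_network <- function(expr, design, condition,
                                       min_abs_r = 0.8, alpha = 0.05) {
  samples <- condition_samples(design, condition)
  if (length(samples) < 3)
    stop("condition ", condition,
         " has fewer than 3 samples; correlation undefined")
  if (length(samples) < 5)
    warning("condition ", condition, " has only ", length(samples),
            " samples; correlation p-values have little power")
  m <- t(expr[, samples, drop = FALSE])
  n <- nrow(m)
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  cc[sds == 0, ] <- NA; cc[, sds == 0] <- NA
  r <- cc
  r[r > 1] <- 1; r[r < -1] <- -1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-12] <- 0
  sel <- !is.na(r) & abs(r) >= min_abs_r & p < alpha
  sel[lower.tri(sel, diag = TRUE)] <- FALSE
  idx <- which(sel, arr.ind = TRUE)
  genes <- rownames(expr)
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(genes)
  if (nrow(idx))
    g <- g + igraph::edges(rbind(genes[idx[, 1]], genes[idx[, 2]]),
                           weight = r[idx])
  g <- igraph::set_graph_attr(g, "condition", condition)
  g <- igraph::set_graph_attr(g, "min_abs_r", min_abs_r)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g
}

#' Node degree
#'
#' @param net an igraph.
#' @return named integer vector, edges incident to each node.
#' @export
node_degree <- function(net) {
  d <- igraph::degree(net, loops = FALSE)
  stats::setNames(as.integer(d), igraph::V(net)$name)
}

#' Core number (k-core index) by minimum-degree peeling
#'
#' The core number of a node is the largest k such that it belongs to a
#' maximal subgraph of minimum degree >= k. Computed by iteratively peeling
#' nodes of minimum remaining degree, the standard O(E) decomposition.
#'
#' @param net an undirected simple igraph.
#' @return named integer vector of core numbers.
#' @export
core_number <- function(net) {
  nms <- igraph::V(net)$name
  n <- length(nms)
  if (n == 0) return(stats::setNames(integer(0), character(0)))
  adj <- igraph::as_adj_list(net, mode = "all")
  adj <- lapply(adj, function(v) unique(as.integer(v)))
  deg <- vapply(adj, length, 1L)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(alive)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    alive[v] <- FALSE
    for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
  }
  stats::setNames(core, nms)
}

#' Rank genes by degree and k-core differences between conditions
#'
#' Produces the key-regulatory-gene table: per gene, degree and core number
#' in each condition (treated minus control differences, signed) and a rank.
#' Ranking is by |dif_degree| descending, ties by |dif_kcore| descending,
#' then gene id.
#'
#' @param topo data.frame with columns gene, degree_control,
#'   degree_treated, kcore_control, kcore_treated.
#' @return the table with added columns dif_degree, dif_kcore, rank, sorted
#'   by rank.
#' @export
rank_topology_table <- function(topo) {
  need <- c("gene", "degree_control", "degree_treated",
            "kcore_control", "kcore_treated")
  if (!all(need %in% names(topo)))
    stop("`topo` needs columns ", paste(need, collapse = ", "))
  topo$dif_degree <- topo$degree_treated - topo$degree_control
  topo$dif_kcore <- topo$kcore_treated - topo$kcore_control
  ord <- order(-abs(topo$dif_degree), -abs(topo$dif_kcore), topo$gene)
  topo <- topo[ord, , drop = FALSE]
  topo$rank <- seq_len(nrow(topo))
  rownames(topo) <- NULL
  topo
}

#' Differential co-expression topology between two condition networks
#'
#' Takes the control and treated co-expression networks, computes per-gene
#' degree and core number in each (genes absent from one network contribute
#' degree 0 and core 0 there), and ranks genes with
#' [rank_topology_table()].
#'
#' @param net_control,net_treated undirected igraphs.
#' @return data.frame: gene, degree_control, degree_treated, kcore_control,
#'   kcore_treated, dif_degree, dif_kcore, rank.
#' @export
differential_topology <- function(net_control, net_treated) {
  genes <- union(igraph::V(net_control)$name, igraph::V(net_treated)$name)
  fill <- function(v) {
    out <- stats::setNames(integer(length(genes)), genes)
    out[names(v)] <- v
    out
  }
  dc <- fill(node_degree(net_control)); dt <- fill(node_degree(net_treated))
  kc <- fill(core_number(net_control)); kt <- fill(core_number(net_treated))
  rank_topology_table(data.frame(
    gene = genes,
    degree_control = unname(dc[genes]), degree_treated = unname(dt[genes]),
    kcore_control = unname(kc[genes]), kcore_treated = unname(kt[genes]),
    stringsAsFactors = FALSE))
}

#' Gene-act network: DEGs on a background relation graph
#'
#' Induces the subgraph of the background relation graph on the DEG ids and
#' reports its connected modules (components of size >= 2), largest first.
#'
#' @param deg_genes character vector of DEG ids.
#' @param relations undirected simple igraph of background gene relations.
#' @return list with `graph` (the induced igraph) and `modules` (list of
#'   character vectors, sorted by decreasing size then first gene id).
#' @export
gene_act_network <- function(deg_genes, relations) {
  present <- intersect(unique(deg_genes), igraph::V(relations)$name)
  g <- igraph::induced_subgraph(relations, present)
  comp <- igraph::components(g)
  modules <- split(igraph::V(g)$name, comp$membership)
  modules <- lapply(modules, sort)
  modules <- modules[vapply(modules, length, 1L) >= 2]
  ord <- order(-vapply(modules, length, 1L),
               vapply(modules, `[[`, "", 1L))
  list(graph = g, modules = unname(modules[ord]))
}

#' Pathway-act network: enriched pathways linked by shared genes
#'
#' An edge joins two enriched pathways iff they share at least `min_shared`
#' genes; edge attribute `shared` stores the overlap count. Hub pathways are
#' ranked by degree (descending, ties by pathway id).
#'
#' @param enriched_pathways character vector of pathway ids (must all be
#'   keys of `pathway_sets`).
#' @param pathway_sets named list of character gene vectors.
#' @param min_shared minimum shared-gene count for an edge (default 1).
#' @return list with `graph` (undirected igraph over the pathways) and
#'   `hubs` (data.frame pathway, degree, sorted).
#' @export
pathway_act_network <- function(enriched_pathways, pathway_sets,
                                min_shared = 1L) {
  missing <- setdiff(enriched_pathways, names(pathway_sets))
  if (length(missing))
    stop("enriched pathway(s) absent from `pathway_sets`: ",
         paste(missing, collapse = ", "))
  ids <- unique(enriched_pathways)
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  if (length(ids) >= 2) {
    pairs <- utils::combn(ids, 2)
    shared <- apply(pairs, 2, function(pr)
      length(intersect(pathway_sets[[pr[1]]], pathway_sets[[pr[2]]])))
    keep <- shared >= min_shared
    if (any(keep))
      g <- g + igraph::edges(pairs[, keep, drop = FALSE],
                             shared = shared[keep])
  }
  deg <- node_degree(g)
  hubs <- data.frame(pathway = names(deg), degree = unname(deg),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$pathway), , drop = FALSE]
  rownames(hubs) <- NULL
  list(graph = g, hubs = hubs)
}
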