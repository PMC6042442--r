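# Readers/writers for the pipeline's plain-text dialects: counts+design TSV,
# GMT term sets, OBO-lite ontology TSV, SIF relation graphs, GraphML.

#' Write a count matrix as counts + design TSV
#'
#' The counts TSV carries sidecar columns `gene_id` and `length_bp` followed
#' by one integer column per sample; the design TSV has columns `sample_id`
#' and `condition`.
#'
#' @param cm a [count_matrix()].
#' @param counts_path,design_path output file paths.
#' @export
write_counts_tsv <- function(cm, counts_path, design_path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts),
                   length_bp = unname(cm$lengths),
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cm$design, design_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, design_path))
}

#' Read a counts + design TSV pair into a count matrix
#'
#' @param counts_path TSV with columns gene_id, length_bp, then one column
#'   per sample.
#' @param design_path TSV with columns sample_id, condition.
#' @param control,treated optional condition labels (see [count_matrix()]).
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, design_path,
                              control = NULL, treated = NULL) {
  df <- utils::read.delim(counts_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% names(df)))
    stop("malformed counts TSV ", counts_path,
         ": need columns gene_id and length_bp")
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length_bp")),
                         drop = FALSE])
  rownames(counts) <- df$gene_id
  count_matrix(counts, stats::setNames(df$length_bp, df$gene_id), design,
               control = control, treated = treated)
}

#' Write gene sets in GMT format
#'
#' One line per set: `set_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param sets named list of character gene vectors.
#' @param descriptions optional named character vector of set descriptions.
#' @param path output file.
#' @export
write_gmt <- function(sets, descriptions = NULL, path) {
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && id %in% names(descriptions))
      descriptions[[id]] else "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file.
#' @return named list of character gene vectors; set descriptions are kept
#'   in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3L)
  if (length(bad))
    stop("malformed GMT ", path, ": line ", bad[1],
         " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write ontology edges as OBO-lite TSV
#'
#' Columns `child_id`, `parent_id`, `term_name` (the child's name).
#'
#' @param dag an [ontology_dag()].
#' @param path output file.
#' @export
write_ontology_tsv <- function(dag, path) {
  stopifnot(inherits(dag, "ontology_dag"))
  nm <- stats::setNames(dag$terms$term_name, dag$terms$term_id)
  df <- data.frame(child_id = dag$edges$child,
                   parent_id = dag$edges$parent,
                   term_name = unname(nm[dag$edges$child]),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ontology from OBO-lite TSV edges plus a GMT of annotations
#'
#' @param ontology_path TSV with columns child_id, parent_id, term_name.
#' @param gmt_path GMT file of direct term annotations (optional).
#' @return an [ontology_dag()] with direct (unclosed) annotations.
#' @export
read_ontology <- function(ontology_path, gmt_path = NULL) {
  df <- utils::read.delim(ontology_path, stringsAsFactors = FALSE)
  if (!all(c("child_id", "parent_id") %in% names(df)))
    stop("malformed ontology TSV ", ontology_path,
         ": need columns child_id and parent_id")
  ann <- if (is.null(gmt_path)) list() else read_gmt(gmt_path)
  ids <- unique(c(df$child_id, df$parent_id, names(ann)))
  nm <- stats::setNames(ids, ids)
  if ("term_name" %in% names(df))
    nm[df$child_id] <- df$term_name
  desc <- attr(ann, "descriptions")
  if (!is.null(desc)) {
    keep <- names(desc)[desc != "na"]
    nm[keep] <- desc[keep]
  }
  ontology_dag(terms = data.frame(term_id = ids, term_name = unname(nm[ids]),
                                  stringsAsFactors = FALSE),
               edges = data.frame(child = df$child_id, parent = df$parent_id,
                                  stringsAsFactors = FALSE),
               annotations = ann, closed = FALSE)
}

#' Write an undirected graph in SIF format
#'
#' Edge lines `a<TAB>rel<TAB>b`; isolated vertices are written as bare
#' single-field lines so the vertex set round-trips.
#'
#' @param graph an igraph with vertex names.
#' @param path output file.
#' @param relation relation label for the middle SIF column.
#' @export
write_sif <- function(graph, path, relation = "pp") {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el)) paste(el[, 1], relation, el[, 2], sep = "\t")
           else character(0)
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read an undirected simple graph from a SIF file
#'
#' @param path SIF file.
#' @return an undirected simple igraph.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- vapply(parts, length, 1L)
  if (any(!n_fields %in% c(1L, 3L)))
    stop("malformed SIF ", path, ": line ",
         which(!n_fields %in% c(1L, 3L))[1], " has ",
         n_fields[!n_fields %in% c(1L, 3L)][1], " fields")
  edges <- do.call(rbind, lapply(parts[n_fields == 3L],
                                 function(p) p[c(1, 3)]))
  iso <- unlist(parts[n_fields == 1L])
  verts <- unique(c(as.vector(edges), iso))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(verts)
  if (!is.null(edges)) g <- g + igraph::edges(t(edges))
  igraph::simplify(g)
}

#' Write a graph as GraphML
#'
#' @param graph an igraph (node/edge attributes are preserved).
#' @param path output file.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Write an enrichment result table as TSV
#'
#' Column layout mirrors a published GO/pathway table: term_id, term_name,
#' total_n (universe genes in the term), significant_nf (DEGs in the term),
#' Re, fisher_p, chisq_p, fdr, genes (semicolon-joined member DEGs).
#'
#' @param results data.frame from [fisher_enrichment()].
#' @param path output file.
#' @export
write_enrichment_tsv <- function(results, path) {
  out <- data.frame(term_id = results$term_id,
                    term_name = results$term_name,
                    total_n = results$n,
                    significant_nf = results$n_f,
                    Re = results$Re,
                    fisher_p = results$fisher_p,
                    chisq_p = results$chisq_p,
                    fdr = results$fdr,
                    genes = results$genes,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count the genes listed in an enrichment table's `genes` column
#'
#' Helper for consistency checks between the `significant_nf` count column
#' and the semicolon-joined member list the table writer emits.
#'
#' @param genes_field character vector of semicolon-joined gene lists.
#' @return integer vector of list lengths (0 for empty fields).
#' @export
count_listed_genes <- function(genes_field) {
  vapply(strsplit(as.character(genes_field), ";", fixed = TRUE),
         function(g) sum(nzchar(trimws(g))), 1L)
}
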