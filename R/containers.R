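#' Construct a count matrix with gene lengths and a two-group design
#'
#' The central input container of the pipeline: an integer gene-by-sample
#' read-count matrix together with per-gene transcript lengths (bp) and a
#' sample-to-condition design with exactly two conditions.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All entries must be >= 0.
#' @param lengths named integer vector of gene lengths in bp, one per gene,
#'   all > 0.
#' @param design data.frame with columns `sample_id` and `condition`; every
#'   column of `counts` must appear exactly once.
#' @param control,treated the condition labels taken as baseline and exposed
#'   group. Defaults to the first and second condition in `design`.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths, design,
                         control = NULL, treated = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("`counts` must be non-negative")
  if (is.null(names(lengths))) stop("`lengths` must be named by gene id")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths)) stop("`lengths` missing for some genes in `counts`")
  if (any(lengths <= 0)) stop("`lengths` must be positive")
  if (!all(c("sample_id", "condition") %in% names(design)))
    stop("`design` needs columns sample_id and condition")
  design <- data.frame(sample_id = as.character(design$sample_id),
                       condition = as.character(design$condition),
                       stringsAsFactors = FALSE)
  if (!setequal(design$sample_id, colnames(counts)) ||
      anyDuplicated(design$sample_id))
    stop("every sample in `counts` must appear exactly once in `design`")
  conds <- unique(design$condition)
  if (length(conds) != 2L)
    stop("`design` must contain exactly two conditions, got: ",
         paste(conds, collapse = ", "))
  if (is.null(control)) control <- conds[1L]
  if (is.null(treated)) treated <- setdiff(conds, control)
  if (!all(c(control, treated) %in% conds) || control == treated)
    stop("`control`/`treated` must name the two design conditions")
  n_per <- table(design$condition)
  if (any(n_per < 2L))
    stop("need >= 2 samples per condition for testing; got ",
         paste(names(n_per), n_per, sep = "=", collapse = ", "))
  structure(list(counts = counts,
                 lengths = lengths,
                 design = design,
                 control = control,
                 treated = treated),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("  conditions:", x$control, "(control) vs", x$treated, "(treated)\n")
  tab <- table(x$design$condition)
  cat("  replicates:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# samples belonging to one condition, in design order
condition_samples <- function(cm_or_design, condition) {
  design <- if (inherits(cm_or_design, "count_matrix")) cm_or_design$design
            else cm_or_design
  design$sample_id[design$condition == condition]
}

#' Construct an ontology DAG with direct term annotations
#'
#' A GO-style ontology: terms, is_a style child-to-parent edges forming a
#' rooted DAG, and per-term directly annotated gene sets. Annotations are
#' *direct*: use [propagate_annotations()] to apply the true-path rule before
#' enrichment counting.
#'
#' @param terms data.frame with columns `term_id` and `term_name`.
#' @param edges data.frame with columns `child` and `parent` (term ids).
#' @param annotations named list (by term id) of character gene vectors;
#'   terms absent from the list hold no direct annotations.
#' @param closed logical, whether `annotations` are already true-path closed.
#' @return an object of class `ontology_dag`.
#' @export
ontology_dag <- function(terms, edges, annotations, closed = FALSE) {
  if (!all(c("term_id", "term_name") %in% names(terms)))
    stop("`terms` needs columns term_id and term_name")
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  unknown <- setdiff(c(edges$child, edges$parent), terms$term_id)
  if (length(unknown))
    stop("edge references unknown term(s): ", paste(unknown, collapse = ", "))
  bad <- setdiff(names(annotations), terms$term_id)
  if (length(bad))
    stop("annotations for unknown term(s): ", paste(bad, collapse = ", "))
  structure(list(terms = data.frame(term_id = as.character(terms$term_id),
                                    term_name = as.character(terms$term_name),
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 annotations = lapply(annotations, as.character),
                 closed = isTRUE(closed)),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", nrow(x$terms), "terms,", nrow(x$edges), "edges,",
      length(x$annotations), "annotated terms",
      if (x$closed) "(true-path closed)" else "(direct annotations)", "\n")
  invisible(x)
}
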