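#' Simulation parameters for the synthetic RNA-seq experiment
#'
#' The generator emulates a two-condition exposure experiment: negative
#' binomial counts (variance mu + phi * mu^2), a minority of genes planted as
#' differentially expressed at a fixed |log2 fold change|, and gene modules
#' that co-express only in one condition (a shared latent factor on the log
#' scale), the pattern behind condition-specific network connectivity.
#'
#' @param n_genes number of genes (> 0).
#' @param n_per_group replicates per condition (>= 3).
#' @param baseline_mean expected count per gene per sample (> 0).
#' @param dispersion NB dispersion phi >= 0 in var = mu + phi * mu^2;
#'   0 means Poisson.
#' @param frac_up,frac_down fractions of genes planted up-/down-regulated,
#'   each in [0, 1) with sum < 1.
#' @param lfc_magnitude planted |log2 fold change| (> 0.585, i.e. beyond the
#'   1.5x screening threshold).
#' @param module_sizes integer vector of planted co-expression module sizes
#'   (each >= 3 and <= n_genes).
#' @param module_condition character vector, same length as `module_sizes`,
#'   naming the condition ("control"/"treated") each module is active in.
#' @param seed RNG seed (integer).
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000L, n_per_group = 3L,
                       baseline_mean = 100, dispersion = 0.1,
                       frac_up = 0.02, frac_down = 0.04,
                       lfc_magnitude = 1.5,
                       module_sizes = 10L,
                       module_condition = "treated",
                       seed = 1L) {
  chk <- function(ok, field, why) if (!ok) stop("invalid `", field, "`: ", why)
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be a positive count")
  chk(is.numeric(n_per_group) && n_per_group >= 3, "n_per_group", "must be >= 3")
  chk(baseline_mean > 0, "baseline_mean", "must be positive")
  chk(dispersion >= 0, "dispersion", "must be >= 0")
  chk(frac_up >= 0 && frac_up < 1, "frac_up", "must be in [0, 1)")
  chk(frac_down >= 0 && frac_down < 1, "frac_down", "must be in [0, 1)")
  chk(frac_up + frac_down < 1, "frac_up",
      "frac_up + frac_down must be < 1")
  if (frac_up + frac_down > 0)
    chk(lfc_magnitude > 0.585, "lfc_magnitude",
        "must exceed 0.585 (the log2 of the 1.5x screen threshold)")
  module_sizes <- as.integer(module_sizes)
  if (length(module_sizes)) {
    chk(all(module_sizes >= 3) && all(module_sizes <= n_genes),
        "module_sizes", "each module must have >= 3 and <= n_genes genes")
    chk(length(module_condition) == length(module_sizes),
        "module_condition", "one active condition per module")
    chk(all(module_condition %in% c("control", "treated")),
        "module_condition", "must be 'control' or 'treated'")
    chk(sum(module_sizes) <= n_genes, "module_sizes",
        "modules are disjoint; total size must be <= n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 frac_up = frac_up, frac_down = frac_down,
                 lfc_magnitude = lfc_magnitude,
                 module_sizes = module_sizes,
                 module_condition = as.character(module_condition),
                 seed = as.integer(seed)),
            class = "sim_params")
}

# 31-bit per-gene seed derived from the master seed: counts for gene i do not
# move when parameters of other genes change.
gene_seed <- function(master, i) {
  as.integer((as.numeric(master %% 2147483647L) * 1103515245 + i * 12345) %%
               2147483647)
}

#' Generate synthetic counts with planted truth
#'
#' Draws a gene-by-sample negative binomial count matrix under the design in
#' `params`, plants up/down-regulated genes at `2^(+/-lfc_magnitude)` group
#' mean ratios, and injects condition-specific co-expression modules via a
#' shared standard-normal latent factor added on the log2 scale (loading
#' `factor_loading`, mean-corrected so module membership does not shift the
#' expected count). Gene lengths are uniform integers on [500, 5000] bp.
#'
#' @param params a [sim_params()] object.
#' @param factor_loading loading of the module latent factor on the log2
#'   scale (default 0.9).
#' @return list with elements `counts` (a [count_matrix()]) and `truth`
#'   (planted DE gene sets, module memberships, true log2 fold changes).
#' @export
generate_counts <- function(params, factor_loading = 0.9) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  genes <- sprintf("gene_%04d", seq_len(p$n_genes))
  samples <- c(sprintf("control_%d", seq_len(p$n_per_group)),
               sprintf("treated_%d", seq_len(p$n_per_group)))
  design <- data.frame(sample_id = samples,
                       condition = rep(c("control", "treated"),
                                       each = p$n_per_group),
                       stringsAsFactors = FALSE)

  set.seed(p$seed)
  n_up <- round(p$frac_up * p$n_genes)
  n_down <- round(p$frac_down * p$n_genes)
  de_idx <- sample.int(p$n_genes, n_up + n_down)
  up_idx <- de_idx[seq_len(n_up)]
  down_idx <- setdiff(de_idx, up_idx)
  # modules drawn from the planted DE genes first (the co-expression network
  # downstream is built on DEGs, so planted topology must live among them),
  # topping up from non-DE genes only when the DE pool runs out
  shuffle <- function(v) if (length(v) > 1) sample(v) else v
  pool <- c(shuffle(de_idx), shuffle(setdiff(seq_len(p$n_genes), de_idx)))
  module_idx <- list()
  for (m in seq_along(p$module_sizes)) {
    take <- pool[seq_len(p$module_sizes[m])]
    module_idx[[m]] <- sort(take)
    pool <- pool[-seq_len(p$module_sizes[m])]
  }
  # per-sample latent factor per module, drawn from the master stream
  latent <- lapply(seq_along(p$module_sizes), function(m)
    stats::setNames(stats::rnorm(length(samples)), samples))

  true_lfc <- stats::setNames(numeric(p$n_genes), genes)
  true_lfc[up_idx] <- p$lfc_magnitude
  true_lfc[down_idx] <- -p$lfc_magnitude

  gene_module <- stats::setNames(rep(NA_integer_, p$n_genes), genes)
  for (m in seq_along(module_idx)) gene_module[module_idx[[m]]] <- m

  treated <- design$condition == "treated"
  # E[2^(a Z)] = exp((a ln2)^2 / 2); divide out so modules keep mean mu
  mean_corr <- exp((factor_loading * log(2))^2 / 2)

  counts <- matrix(0L, p$n_genes, length(samples),
                   dimnames = list(genes, samples))
  lengths <- stats::setNames(integer(p$n_genes), genes)
  for (i in seq_len(p$n_genes)) {
    set.seed(gene_seed(p$seed, i))
    lengths[i] <- sample(500:5000, 1L)
    mu <- rep(p$baseline_mean, length(samples))
    if (true_lfc[i] != 0)
      mu[treated] <- mu[treated] * 2^true_lfc[i]
    m <- gene_module[i]
    if (!is.na(m)) {
      active <- design$condition == p$module_condition[m]
      mu[active] <- mu[active] *
        2^(factor_loading * latent[[m]][active]) / mean_corr
    }
    counts[i, ] <- as.integer(round(
      if (p$dispersion == 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / p$dispersion)))
  }
  storage.mode(counts) <- "integer"

  truth <- list(
    de_genes_up = genes[sort(up_idx)],
    de_genes_down = genes[sort(down_idx)],
    module_members = lapply(seq_along(module_idx), function(m)
      list(genes = genes[module_idx[[m]]],
           condition = p$module_condition[m])),
    true_lfc = true_lfc)
  list(counts = count_matrix(counts, lengths, design,
                             control = "control", treated = "treated"),
       truth = truth)
}

#' Generate a random rooted ontology DAG with leaf annotations
#'
#' Term 1 is the single root; every later term picks 1..`max_parents` parents
#' among earlier terms, which guarantees acyclicity and a path to the root.
#' Only leaf terms (terms with no children) carry direct annotations: each
#' gene is annotated to each leaf independently with probability
#' `annotation_rate`. The returned annotations are deliberately *not*
#' true-path closed; closure is the enrichment module's job.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_parents maximum parents per non-root term (>= 1).
#' @param annotation_rate per-gene, per-leaf direct annotation probability.
#' @param genes character vector, the gene universe to annotate.
#' @param seed RNG seed.
#' @return list with `dag` (an [ontology_dag()], direct annotations) and
#'   `term_sets` (the same direct annotation list).
#' @export
generate_ontology <- function(n_terms, max_parents = 2L,
                              annotation_rate = 0.3, genes, seed = 1L) {
  if (n_terms < 2) stop("invalid `n_terms`: must be >= 2")
  if (max_parents < 1) stop("invalid `max_parents`: must be >= 1")
  if (annotation_rate <= 0 || annotation_rate > 1)
    stop("invalid `annotation_rate`: must be in (0, 1]")
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_terms))
  child <- character(0); parent <- character(0)
  for (i in 2:n_terms) {
    k <- sample.int(min(max_parents, i - 1L), 1L)
    pa <- if (i == 2L) 1L else sample.int(i - 1L, k)
    child <- c(child, rep(ids[i], length(pa)))
    parent <- c(parent, ids[pa])
  }
  leaves <- setdiff(ids, parent)
  ann <- lapply(leaves, function(t)
    genes[stats::runif(length(genes)) < annotation_rate])
  names(ann) <- leaves
  ann <- ann[vapply(ann, length, 1L) > 0]
  dag <- ontology_dag(
    terms = data.frame(term_id = ids,
                       term_name = paste("synthetic process", seq_len(n_terms)),
                       stringsAsFactors = FALSE),
    edges = data.frame(child = child, parent = parent,
                       stringsAsFactors = FALSE),
    annotations = ann, closed = FALSE)
  list(dag = dag, term_sets = ann)
}

#' Generate an Erdos-Renyi background relation graph over genes
#'
#' Stand-in for a curated pathway-derived gene relation network: an
#' undirected simple G(n, p) graph whose vertices are the gene universe.
#'
#' @param gene_universe character vector of gene ids.
#' @param edge_density edge probability in (0, 1).
#' @param seed RNG seed.
#' @return an undirected `igraph` with vertex names = gene ids.
#' @export
generate_relation_graph <- function(gene_universe, edge_density, seed = 1L) {
  if (edge_density <= 0 || edge_density >= 1)
    stop("invalid `edge_density`: must be in (0, 1)")
  set.seed(seed)
  g <- igraph::sample_gnp(length(gene_universe), edge_density, directed = FALSE)
  igraph::V(g)$name <- gene_universe
  g
}

#' Generate a synthetic qPCR Ct table from planted truth
#'
#' Ct values are constructed so that the expected ddCt of gene g equals
#' minus its planted log2 fold change (one PCR cycle per doubling), with
#' i.i.d. Gaussian well noise. The reference gene is flat across conditions.
#'
#' @param truth the `truth` element of [generate_counts()].
#' @param ref_gene reference gene id (must not be a planted DE gene).
#' @param ct_noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param seed RNG seed.
#' @param genes genes to assay; defaults to all planted DE genes.
#' @param n_replicates wells per gene x condition.
#' @return data.frame with columns gene, sample, condition, ct.
#' @export
generate_qpcr <- function(truth, ref_gene = "GAPDH", ct_noise_sd = 0.15,
                          seed = 1L, genes = NULL, n_replicates = 3L) {
  de <- c(truth$de_genes_up, truth$de_genes_down)
  if (ref_gene %in% de)
    stop("invalid `ref_gene`: ", ref_gene, " is a planted DE gene")
  if (is.null(genes)) genes <- de
  set.seed(seed)
  conds <- c("control", "treated")
  base_ct <- stats::setNames(stats::runif(length(genes), 22, 30), genes)
  rows <- list()
  for (g in c(ref_gene, genes)) {
    lfc <- if (g %in% names(truth$true_lfc)) truth$true_lfc[[g]] else 0
    mu0 <- if (g == ref_gene) 20 else base_ct[[g]]
    for (cond in conds) {
      # expression up by lfc in treated => Ct lower by lfc cycles
      mu <- mu0 - if (cond == "treated" && g != ref_gene) lfc else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g,
        sample = paste(cond, seq_len(n_replicates), sep = "_"),
        condition = cond,
        ct = mu + stats::rnorm(n_replicates, 0, ct_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic dose-response viability table
#'
#' Samples the four-parameter logistic curve
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)` at the
#' given doses with additive Gaussian noise. Defaults mirror a CCK-8
#' viability assay read in percent on a 2-fold dose grid from 25 to
#' 3200 ug/ml.
#'
#' @param top,bottom upper/lower asymptotes (top > bottom).
#' @param ic50 half-maximal inhibitory concentration (> 0).
#' @param hill Hill slope (> 0 for a decreasing viability curve).
#' @param doses numeric vector of >= 4 distinct positive doses.
#' @param noise_sd additive Gaussian noise sd (response units).
#' @param n_replicates replicate wells per dose.
#' @param seed RNG seed.
#' @return data.frame with columns dose, response.
#' @export
generate_dose_response <- function(top = 100, bottom = 0, ic50 = 120,
                                   hill = 1,
                                   doses = c(25, 50, 100, 200, 400, 800,
                                             1600, 3200),
                                   noise_sd = 2, n_replicates = 1L,
                                   seed = 1L) {
  if (top <= bottom) stop("invalid `top`: must exceed `bottom`")
  if (ic50 <= 0) stop("invalid `ic50`: must be positive")
  if (length(unique(doses)) < 4)
    stop("invalid `doses`: need at least 4 distinct doses")
  if (any(doses <= 0)) stop("invalid `doses`: must be positive")
  set.seed(seed)
  d <- rep(doses, each = n_replicates)
  mu <- bottom + (top - bottom) / (1 + (d / ic50)^hill)
  data.frame(dose = d,
             response = mu + stats::rnorm(length(d), 0, noise_sd))
}

#' Write a full synthetic input bundle to disk
#'
#' Generates counts + design, an ontology (edges TSV + GMT), a background
#' relation graph (SIF), a qPCR Ct table, a dose-response table and the
#' ground-truth JSON, all reproducible from one seed.
#'
#' @param dir output directory (created if missing).
#' @param params a [sim_params()] object; its seed drives every generator.
#' @param n_terms,edge_density knobs passed through to the ontology and
#'   relation-graph generators.
#' @return invisibly, a named list of the file paths written plus the
#'   in-memory planted truth as element `ground_truth`.
#' @export
write_synthetic_bundle <- function(dir, params = sim_params(),
                                   n_terms = 30L, edge_density = 0.02) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_counts(params)
  genes <- rownames(sim$counts$counts)
  ont <- generate_ontology(n_terms, genes = genes, seed = params$seed + 1L)
  rel <- generate_relation_graph(genes, edge_density, seed = params$seed + 2L)
  qpcr <- generate_qpcr(sim$truth, ref_gene = genes[
    !genes %in% c(sim$truth$de_genes_up, sim$truth$de_genes_down)][1],
    seed = params$seed + 3L)
  dose <- generate_dose_response(seed = params$seed + 4L)

  paths <- list(
    counts = file.path(dir, "counts.tsv"),
    design = file.path(dir, "design.tsv"),
    gmt = file.path(dir, "annotations.gmt"),
    ontology = file.path(dir, "ontology.tsv"),
    relations = file.path(dir, "relations.sif"),
    ct = file.path(dir, "qpcr_ct.tsv"),
    dose_response = file.path(dir, "dose_response.tsv"),
    truth = file.path(dir, "ground_truth.json"))
  write_counts_tsv(sim$counts, paths$counts, paths$design)
  write_gmt(ont$term_sets,
            stats::setNames(ont$dag$terms$term_name, ont$dag$terms$term_id),
            paths$gmt)
  write_ontology_tsv(ont$dag, paths$ontology)
  write_sif(rel, paths$relations)
  utils::write.table(qpcr, paths$ct, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dose, paths$dose_response, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(ground_truth = sim$truth)))
}
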