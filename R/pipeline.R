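# End-to-end orchestration: one config drives DEG screening, enrichment,
# networks and assays, writing plain-text artifacts, a JSONL event log and a
# machine-readable JSON report.

#' Pipeline configuration
#'
#' Collects input file paths, the screening and network thresholds (defaults
#' are the published criteria), the seed and the output directory. Only
#' counts + design are mandatory; stages whose inputs are absent are skipped
#' and logged.
#'
#' @param counts,design required counts/design TSV paths.
#' @param gmt,ontology,relations,ct,dose_response optional stage inputs
#'   (GMT term sets, OBO-lite ontology TSV, SIF relation graph, Ct TSV,
#'   dose-response TSV).
#' @param out_dir artifact directory.
#' @param fc_up,fc_down,deg_fdr DEG screen thresholds (FC > 1.50 or
#'   FC < 0.67, FDR < 0.05).
#' @param enrich_p,enrich_fdr enrichment reporting thresholds.
#' @param min_abs_r,corr_alpha co-expression edge rule.
#' @param min_shared pathway-act minimum shared genes.
#' @param control,treated condition labels.
#' @param seed integer seed for every random stage.
#' @param force recompute artifacts even when present (FALSE reuses them).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, design, gmt = NULL, ontology = NULL,
                            relations = NULL, ct = NULL,
                            dose_response = NULL,
                            out_dir = "coexdiff_out",
                            fc_up = 1.50, fc_down = 0.67, deg_fdr = 0.05,
                            enrich_p = 0.05, enrich_fdr = 0.05,
                            min_abs_r = 0.8, corr_alpha = 0.05,
                            min_shared = 1L,
                            control = "control", treated = "treated",
                            seed = 1L, force = TRUE) {
  if (!(fc_up > 1 && 1 > fc_down && fc_down > 0))
    stop("thresholds must satisfy fc_up > 1 > fc_down > 0")
  for (a in c(deg_fdr, enrich_p, enrich_fdr, corr_alpha))
    if (a <= 0 || a >= 1) stop("significance levels must lie in (0, 1)")
  if (min_abs_r < 0 || min_abs_r > 1)
    stop("`min_abs_r` must lie in [0, 1]")
  structure(list(counts = counts, design = design, gmt = gmt,
                 ontology = ontology, relations = relations, ct = ct,
                 dose_response = dose_response, out_dir = out_dir,
                 fc_up = fc_up, fc_down = fc_down, deg_fdr = deg_fdr,
                 enrich_p = enrich_p, enrich_fdr = enrich_fdr,
                 min_abs_r = min_abs_r, corr_alpha = corr_alpha,
                 min_shared = as.integer(min_shared),
                 control = control, treated = treated,
                 seed = as.integer(seed), force = isTRUE(force)),
            class = "pipeline_config")
}

# atomic-ish write: to a temp file in the same dir, then rename
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

log_event <- function(log_path, stage, status, detail = NULL) {
  ev <- list(stage = stage, status = status)
  if (!is.null(detail)) ev$detail <- detail
  cat(jsonlite::toJSON(ev, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  message("[", stage, "] ", status,
          if (!is.null(detail)) paste0(": ", detail) else "")
}

#' Run the full pipeline from a configuration
#'
#' Stage order: DEG screen, enrichment (GMT and, when an ontology is given,
#' true-path closure plus GO tree), networks (co-expression differential
#' topology plus gene-act / pathway-act when a relation graph is given),
#' assays (qPCR relative expression + concordance, 4PL IC50). Stages with
#' missing inputs are skipped and logged. Artifacts and the `report.json`
#' land in `config$out_dir`; identical config + seed reproduce identical
#' results.
#'
#' @param config a [pipeline_config()].
#' @return the report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "events.jsonl")
  if (cfg$force && file.exists(log_path)) unlink(log_path)
  report <- list(config = unclass(cfg),
                 version = as.character(utils::packageVersion("coexdiff")),
                 stages = list())
  set.seed(cfg$seed)

  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- expr
    list(value = value, seconds = proc.time()[["elapsed"]] - t0)
  }
  artifact <- function(name) file.path(cfg$out_dir, name)
  reuse <- function(name) !cfg$force && file.exists(artifact(name))

  ## stage: DEG screen -------------------------------------------------
  deg_path <- artifact("degs.tsv")
  st <- timed({
    cm <- read_count_matrix(cfg$counts, cfg$design,
                            control = cfg$control, treated = cfg$treated)
    if (reuse("degs.tsv")) {
      degs <- utils::read.delim(deg_path, stringsAsFactors = FALSE)
      attr(degs, "rpkm") <- compute_rpkm(cm)
      log_event(log_path, "deg", "reused")
    } else {
      degs <- run_deg_screen(cm, fc_up = cfg$fc_up, fc_down = cfg$fc_down,
                             max_fdr = cfg$deg_fdr)
      write_atomic(function(p) utils::write.table(
        degs, p, sep = "\t", quote = FALSE, row.names = FALSE), deg_path)
      log_event(log_path, "deg", "complete",
                paste0(deg_counts(degs)[["n_total"]], " DEGs"))
    }
    degs
  })
  degs <- st$value
  cnt <- deg_counts(degs)
  report$stages$deg <- list(status = "complete", seconds = st$seconds,
                            n_up = unname(cnt[["n_up"]]),
                            n_down = unname(cnt[["n_down"]]),
                            n_total = unname(cnt[["n_total"]]),
                            artifact = deg_path)
  deg_genes <- degs$gene[degs$call != "ns"]
  rpkm <- attr(degs, "rpkm")
  cm <- read_count_matrix(cfg$counts, cfg$design,
                          control = cfg$control, treated = cfg$treated)

  ## stage: enrichment -------------------------------------------------
  if (is.null(cfg$gmt)) {
    report$stages$enrichment <- list(status = "skipped",
                                     reason = "no GMT input")
    log_event(log_path, "enrichment", "skipped", "no GMT input")
    enriched <- NULL
  } else {
    st <- timed({
      term_sets <- read_gmt(cfg$gmt)
      dag <- NULL
      if (!is.null(cfg$ontology)) {
        dag <- read_ontology(cfg$ontology, cfg$gmt)
        dag <- propagate_annotations(dag)
        term_sets2 <- dag$annotations
        attr(term_sets2, "descriptions") <- attr(term_sets, "descriptions")
        term_sets <- term_sets2
      }
      universe <- intersect(
        unique(unlist(term_sets, use.names = FALSE)), rownames(cm$counts))
      res <- fisher_enrichment(intersect(deg_genes, universe), universe,
                               lapply(term_sets, intersect, universe))
      nm <- attr(read_gmt(cfg$gmt), "descriptions")
      res$term_name <- ifelse(res$term_id %in% names(nm) &
                                nm[res$term_id] != "na",
                              nm[res$term_id], res$term_id)
      kept <- filter_enriched(res, cfg$enrich_p, cfg$enrich_fdr)
      write_atomic(function(p) write_enrichment_tsv(kept, p),
                   artifact("enrichment.tsv"))
      if (!is.null(dag) && nrow(kept)) {
        tree <- build_go_tree(kept$term_id, dag, degs)
        write_atomic(function(p) write_graphml(tree, p),
                     artifact("go_tree.graphml"))
      }
      list(results = res, kept = kept, term_sets = term_sets)
    })
    enriched <- st$value
    report$stages$enrichment <- list(
      status = "complete", seconds = st$seconds,
      n_tested = nrow(enriched$results), n_enriched = nrow(enriched$kept),
      artifact = artifact("enrichment.tsv"))
    log_event(log_path, "enrichment", "complete",
              paste0(nrow(enriched$kept), " enriched terms"))
  }

  ## stage: networks ---------------------------------------------------
  if (length(deg_genes) < 2) {
    report$stages$networks <- list(status = "skipped",
                                   reason = "fewer than 2 DEGs")
    log_event(log_path, "networks", "skipped", "fewer than 2 DEGs")
  } else {
    st <- timed({
      expr <- rpkm[deg_genes, , drop = FALSE]
      net_c <- build_coexpression_network(expr, cm$design, cfg$control,
                                          cfg$min_abs_r, cfg$corr_alpha)
      net_t <- build_coexpression_network(expr, cm$design, cfg$treated,
                                          cfg$min_abs_r, cfg$corr_alpha)
      topo <- differential_topology(net_c, net_t)
      write_atomic(function(p) utils::write.table(
        topo, p, sep = "\t", quote = FALSE, row.names = FALSE),
        artifact("differential_topology.tsv"))
      write_atomic(function(p) write_graphml(net_c, p),
                   artifact("coexpression_control.graphml"))
      write_atomic(function(p) write_graphml(net_t, p),
                   artifact("coexpression_treated.graphml"))
      gact <- NULL
      if (!is.null(cfg$relations)) {
        rel <- read_sif(cfg$relations)
        gact <- gene_act_network(deg_genes, rel)
        write_atomic(function(p) write_graphml(gact$graph, p),
                     artifact("gene_act.graphml"))
      }
      pact <- NULL
      if (!is.null(enriched) && nrow(enriched$kept) >= 2) {
        pact <- pathway_act_network(enriched$kept$term_id,
                                    enriched$term_sets, cfg$min_shared)
        write_atomic(function(p) write_graphml(pact$graph, p),
                     artifact("pathway_act.graphml"))
      }
      list(topo = topo, net_control = net_c, net_treated = net_t,
           gene_act = gact, pathway_act = pact)
    })
    nets <- st$value
    report$stages$networks <- list(
      status = "complete", seconds = st$seconds,
      n_nodes = nrow(nets$topo),
      edges_control = igraph::ecount(nets$net_control),
      edges_treated = igraph::ecount(nets$net_treated),
      top_genes = utils::head(nets$topo$gene, 10),
      artifact = artifact("differential_topology.tsv"))
    log_event(log_path, "networks", "complete",
              paste0(igraph::ecount(nets$net_treated), " treated edges"))
  }

  ## stage: assays -----------------------------------------------------
  if (is.null(cfg$ct) && is.null(cfg$dose_response)) {
    report$stages$assays <- list(status = "skipped",
                                 reason = "no Ct or dose-response input")
    log_event(log_path, "assays", "skipped", "no Ct or dose-response input")
  } else {
    st <- timed({
      out <- list()
      if (!is.null(cfg$ct)) {
        ct <- utils::read.delim(cfg$ct, stringsAsFactors = FALSE)
        refs <- setdiff(unique(ct$gene), degs$gene[degs$call != "ns"])
        ref <- refs[1]
        rel <- relative_expression_table(ct, ref, cfg$control, cfg$treated)
        write_atomic(function(p) utils::write.table(
          rel, p, sep = "\t", quote = FALSE, row.names = FALSE),
          artifact("qpcr_relative_expression.tsv"))
        shared <- intersect(rel$gene, degs$gene)
        out$qpcr <- list(n_genes = nrow(rel), reference = ref)
        if (length(shared) >= 3) {
          cc <- concordance(
            stats::setNames(degs$log2fc, degs$gene),
            stats::setNames(rel$log2_ratio, rel$gene))
          out$concordance <- cc[c("slope", "intercept", "r", "n")]
        }
      }
      if (!is.null(cfg$dose_response)) {
        dr <- utils::read.delim(cfg$dose_response, stringsAsFactors = FALSE)
        fit <- fit_4pl(dr$dose, dr$response)
        write_atomic(function(p) jsonlite::write_json(
          unclass(fit)[c("top", "bottom", "ic50", "hill", "rss",
                         "converged", "method")],
          p, auto_unbox = TRUE, digits = NA), artifact("dose_fit.json"))
        out$dose_response <- list(ic50 = fit$ic50, hill = fit$hill)
      }
      out
    })
    report$stages$assays <- c(list(status = "complete",
                                   seconds = st$seconds), st$value)
    log_event(log_path, "assays", "complete")
  }

  write_atomic(function(p) jsonlite::write_json(
    report, p, auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE), artifact("report.json"))
  invisible(report)
}

#' One-command synthetic demonstration run
#'
#' Generates a synthetic bundle under `dir`, runs the full pipeline on it,
#' and prints the top 10 key regulatory genes (degree / k-core differential
#' topology table). All randomness flows from `seed`.
#'
#' @param seed integer seed.
#' @param dir working directory (default a tempdir subdirectory).
#' @param params optional [sim_params()]; its seed is overridden by `seed`.
#' @return invisibly, list with `report`, `truth` and `status` (0 on
#'   success).
#' @export
run_demo <- function(seed = 7L, dir = file.path(tempdir(), "coexdiff_demo"),
                     params = NULL) {
  # module-bearing scenario: counts deep enough (baseline 1000, phi 0.01)
  # that the 0.9-loading latent factor dominates NB noise and the planted
  # module forms a near-clique under the |r| >= 0.8 edge rule (expected
  # within-module r ~ 0.97; see the methods vignette for the noise budget)
  if (is.null(params))
    params <- sim_params(n_genes = 400L, n_per_group = 20L,
                         baseline_mean = 1000, dispersion = 0.01,
                         module_sizes = 10L, module_condition = "treated",
                         seed = seed)
  else
    params$seed <- as.integer(seed)
  bundle <- write_synthetic_bundle(dir, params)
  cfg <- pipeline_config(counts = bundle$counts, design = bundle$design,
                         gmt = bundle$gmt, ontology = bundle$ontology,
                         relations = bundle$relations, ct = bundle$ct,
                         dose_response = bundle$dose_response,
                         out_dir = file.path(dir, "out"), seed = seed)
  report <- run_pipeline(cfg)
  topo <- utils::read.delim(file.path(dir, "out",
                                      "differential_topology.tsv"),
                            stringsAsFactors = FALSE)
  cat("Top 10 key regulatory genes (treated - control topology):\n")
  print(utils::head(topo, 10), row.names = FALSE)
  invisible(list(report = report, truth = bundle$ground_truth, status = 0L))
}
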