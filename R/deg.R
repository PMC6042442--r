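# DEG screening: RPKM normalization, fold change, per-gene testing, BH-FDR,
# and the published screening criteria (FC > 1.50 or FC < 0.67, FDR < 0.05).

#' Reads per kilobase per million mapped reads
#'
#' `RPKM(g, s) = 1e9 * c(g, s) / (T(s) * L(g))` with `T(s)` the total mapped
#' reads of sample s (the column sum) and `L(g)` the gene length in bp.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of RPKM values with the per-sample totals in the
#'   `"totals"` attribute.
#' @export
compute_rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- colSums(cm$counts)
  if (any(totals == 0))
    stop("zero total mapped reads in sample(s): ",
         paste(names(totals)[totals == 0], collapse = ", "))
  rpkm <- 1e9 * sweep(cm$counts, 2, totals, "/") / cm$lengths
  attr(rpkm, "totals") <- totals
  rpkm
}

#' Group-mean fold change on RPKM
#'
#' Fold change is treated over control on RPKM group means, with a guard
#' pseudocount `eps` (RPKM units) added to both means so genes silent in one
#' group get a finite ratio:
#' `FC = (mean treated + eps) / (mean control + eps)`.
#'
#' @param rpkm RPKM matrix (genes x samples), e.g. from [compute_rpkm()].
#' @param design design data.frame with sample_id, condition.
#' @param control,treated condition labels.
#' @param eps pseudocount in RPKM units (default 1).
#' @return data.frame with columns gene, mean_control, mean_treated,
#'   fold_change, log2fc.
#' @export
fold_change <- function(rpkm, design, control = "control",
                        treated = "treated", eps = 1) {
  cs <- condition_samples(design, control)
  ts <- condition_samples(design, treated)
  if (!length(cs) || !length(ts))
    stop("conditions ", control, "/", treated, " not both present in design")
  mc <- rowMeans(rpkm[, cs, drop = FALSE])
  mt <- rowMeans(rpkm[, ts, drop = FALSE])
  fc <- (mt + eps) / (mc + eps)
  data.frame(gene = rownames(rpkm),
             mean_control = unname(mc), mean_treated = unname(mt),
             fold_change = unname(fc), log2fc = unname(log2(fc)),
             stringsAsFactors = FALSE)
}

#' Per-gene two-sample test on log2(RPKM + 1)
#'
#' Stand-in differential test behind a single pluggable interface. The
#' default, `method = "moderated"`, is an empirical-Bayes moderated t:
#' per-gene pooled variances are shrunk toward a common prior
#' (limma's `squeezeVar`) and the t statistic uses the posterior variance
#' on augmented degrees of freedom — the variance-sharing idea of the
#' empirical-Bayes engines usually applied to such screens, which plain
#' per-gene tests lack the power to replace at 3-5 replicates.
#' `method = "welch"` is Welch's unequal-variance t.
#'
#' Degenerate genes follow explicit conventions: a gene constant across all
#' samples gives p = 1 under either method; under `"welch"`, both group
#' variances zero with different means gives p = 0.
#'
#' @param rpkm RPKM matrix (genes x samples).
#' @param design design data.frame with sample_id, condition.
#' @param control,treated condition labels.
#' @param method `"moderated"` (default) or `"welch"`.
#' @return named numeric vector of two-sided p-values in [0, 1].
#' @export
differential_test <- function(rpkm, design, control = "control",
                              treated = "treated",
                              method = c("moderated", "welch")) {
  method <- match.arg(method)
  cs <- condition_samples(design, control)
  ts <- condition_samples(design, treated)
  if (length(cs) < 2 || length(ts) < 2)
    stop("need >= 2 replicates per condition")
  x <- log2(rpkm[, cs, drop = FALSE] + 1)
  y <- log2(rpkm[, ts, drop = FALSE] + 1)
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  flat <- v1 == 0 & v2 == 0 & m1 == m2
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tt <- (m2 - m1) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    sq <- limma::squeezeVar(s2, df = d)
    se2 <- sq$var.post * (1 / n1 + 1 / n2)
    tt <- (m2 - m1) / sqrt(se2)
    p <- 2 * stats::pt(abs(tt), d + sq$df.prior, lower.tail = FALSE)
    p[flat] <- 1
  }
  stats::setNames(pmin(pmax(p, 0), 1), rownames(rpkm))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues numeric vector of p-values, all in [0, 1].
#' @return adjusted values (q-values), same order and names as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must all lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen differentially expressed genes by the published criteria
#'
#' `call = up` iff fold change > `fc_up` and FDR < `max_fdr`;
#' `call = down` iff fold change < `fc_down` and FDR < `max_fdr`;
#' otherwise `ns`. All inequalities strict.
#'
#' @param fc_table data.frame from [fold_change()] (needs columns gene and
#'   fold_change; log2fc/pvalue carried through when present).
#' @param fdr named numeric vector of adjusted p-values covering the same
#'   genes, e.g. from [bh_fdr()].
#' @param pvalues optional named vector of raw p-values to carry through.
#' @param fc_up,fc_down,max_fdr screening thresholds.
#' @return data.frame with columns gene, log2fc, fold_change, pvalue, fdr,
#'   call; the summary counts are in attribute `"counts"` (n_up, n_down,
#'   n_total) and via [deg_counts()].
#' @export
screen_degs <- function(fc_table, fdr, pvalues = NULL,
                        fc_up = 1.50, fc_down = 0.67, max_fdr = 0.05) {
  if (!all(c("gene", "fold_change") %in% names(fc_table)))
    stop("`fc_table` needs columns gene and fold_change")
  g <- fc_table$gene
  if (!all(g %in% names(fdr)))
    stop("`fdr` missing for some genes in `fc_table`")
  q <- unname(fdr[g])
  p <- if (!is.null(pvalues)) unname(pvalues[g])
       else if ("pvalue" %in% names(fc_table)) fc_table$pvalue
       else NA_real_
  fc <- fc_table$fold_change
  call <- ifelse(fc > fc_up & q < max_fdr, "up",
                 ifelse(fc < fc_down & q < max_fdr, "down", "ns"))
  out <- data.frame(gene = g,
                    log2fc = if ("log2fc" %in% names(fc_table))
                      fc_table$log2fc else log2(fc),
                    fold_change = fc, pvalue = p, fdr = q, call = call,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(n_up = sum(call == "up"),
                           n_down = sum(call == "down"),
                           n_total = sum(call != "ns"))
  out
}

#' Summary counts of a DEG table
#'
#' @param degs data.frame from [screen_degs()] (any data.frame with a
#'   `call` column works).
#' @return named integer vector n_up, n_down, n_total.
#' @export
deg_counts <- function(degs) {
  c(n_up = sum(degs$call == "up"),
    n_down = sum(degs$call == "down"),
    n_total = sum(degs$call %in% c("up", "down")))
}

#' Full DEG screen from a count matrix
#'
#' Convenience wrapper: RPKM, fold change, Welch test on log2(RPKM + 1),
#' BH-FDR, then [screen_degs()].
#'
#' @param cm a [count_matrix()].
#' @inheritParams screen_degs
#' @param eps fold-change pseudocount in RPKM units.
#' @param method differential test variant, see [differential_test()].
#' @return the [screen_degs()] table with the RPKM matrix attached as
#'   attribute `"rpkm"`.
#' @export
run_deg_screen <- function(cm, fc_up = 1.50, fc_down = 0.67,
                           max_fdr = 0.05, eps = 1,
                           method = c("moderated", "welch")) {
  rpkm <- compute_rpkm(cm)
  fc <- fold_change(rpkm, cm$design, cm$control, cm$treated, eps = eps)
  p <- differential_test(rpkm, cm$design, cm$control, cm$treated,
                         method = method)
  q <- bh_fdr(p)
  degs <- screen_degs(fc, q, pvalues = p, fc_up = fc_up,
                      fc_down = fc_down, max_fdr = max_fdr)
  attr(degs, "rpkm") <- rpkm
  degs
}
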