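# Wet-lab companion analyses: 2^-ddCt qPCR relative quantification,
# RNA-seq/qPCR concordance, and four-parameter logistic IC50 fitting.

#' Relative expression by the 2^-ddCt method
#'
#' Replicate Ct values are aggregated by arithmetic mean per gene and
#' condition; then
#' `dCt(cond) = mean Ct(gene, cond) - mean Ct(ref, cond)`,
#' `ddCt = dCt(treated) - dCt(control)`, relative expression `2^-ddCt`,
#' log2 ratio `-ddCt`. Assumes perfect amplification efficiency (doubling
#' per cycle).
#'
#' @param ct data.frame with columns gene, condition, ct (one row per well).
#' @param gene target gene id.
#' @param ref_gene reference (housekeeping) gene id, e.g. GAPDH.
#' @param control,treated condition labels.
#' @return list with `ddct`, `relative_expression` (2^-ddCt) and
#'   `log2_ratio` (-ddCt).
#' @export
delta_delta_ct <- function(ct, gene, ref_gene,
                           control = "control", treated = "treated") {
  need <- c("gene", "condition", "ct")
  if (!all(need %in% names(ct)))
    stop("`ct` needs columns ", paste(need, collapse = ", "))
  mean_ct <- function(g, cond) {
    v <- ct$ct[ct$gene == g & ct$condition == cond]
    if (g == ref_gene && !length(v))
      stop("no reference-gene (", ref_gene, ") wells in condition ", cond)
    if (!length(v))
      stop("no wells for gene ", g, " in condition ", cond)
    mean(v)
  }
  dct_c <- mean_ct(gene, control) - mean_ct(ref_gene, control)
  dct_t <- mean_ct(gene, treated) - mean_ct(ref_gene, treated)
  ddct <- dct_t - dct_c
  list(ddct = ddct, relative_expression = 2^(-ddct), log2_ratio = -ddct)
}

#' 2^-ddCt table for every assayed gene
#'
#' @inheritParams delta_delta_ct
#' @return data.frame with columns gene, ddct, relative_expression,
#'   log2_ratio (reference gene excluded).
#' @export
relative_expression_table <- function(ct, ref_gene,
                                      control = "control",
                                      treated = "treated") {
  genes <- setdiff(unique(ct$gene), ref_gene)
  rows <- lapply(genes, function(g) {
    r <- delta_delta_ct(ct, g, ref_gene, control, treated)
    data.frame(gene = g, ddct = r$ddct,
               relative_expression = r$relative_expression,
               log2_ratio = r$log2_ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' RNA-seq vs qPCR concordance by linear regression
#'
#' Ordinary least squares of qPCR log2 fold changes on RNA-seq log2 fold
#' changes over the shared genes, with the Pearson correlation coefficient.
#'
#' @param rnaseq_lfc,qpcr_lfc named numeric vectors of log2 fold changes.
#' @return list with `slope`, `intercept`, `r` and `n` (shared genes).
#' @export
concordance <- function(rnaseq_lfc, qpcr_lfc) {
  shared <- intersect(names(rnaseq_lfc), names(qpcr_lfc))
  if (length(shared) < 3)
    stop("need >= 3 shared genes, got ", length(shared))
  x <- unname(rnaseq_lfc[shared]); y <- unname(qpcr_lfc[shared])
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), n = length(shared))
}

# 4PL mean curve
four_pl <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)`.
#' Initialization: top and bottom from the response extremes, ic50 at the
#' geometric-mean dose, hill = 1. The ic50 and hill are optimized on the
#' log scale, which keeps both positive. Tries `nls` (port algorithm)
#' first and falls back to Nelder-Mead on the residual sum of squares; if
#' neither converges the error carries the best parameters so far in its
#' `fit` field.
#'
#' @param doses numeric vector of >= 4 distinct positive doses.
#' @param responses numeric vector, same length.
#' @return object of class `dose_response_fit`: top, bottom, ic50, hill,
#'   rss, fitted (per input dose), converged, method.
#' @export
fit_4pl <- function(doses, responses) {
  if (length(doses) != length(responses))
    stop("`doses` and `responses` must have equal length")
  if (length(unique(doses)) < 4)
    stop("need at least 4 distinct doses")
  if (any(doses <= 0)) stop("doses must be positive")
  start <- list(top = max(responses), bottom = min(responses),
                lic50 = mean(log(doses)), lhill = 0)
  if (start$top <= start$bottom) start$top <- start$bottom + 1
  df <- data.frame(dose = doses, response = responses)

  fit <- NULL; method <- "nls"
  try({
    m <- stats::nls(
      response ~ bottom + (top - bottom) / (1 + (dose / exp(lic50))^exp(lhill)),
      data = df, start = start, algorithm = "port",
      control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
    cf <- stats::coef(m)
    fit <- list(top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                ic50 = exp(unname(cf["lic50"])),
                hill = exp(unname(cf["lhill"])),
                rss = sum(stats::resid(m)^2), converged = TRUE)
  }, silent = TRUE)

  if (is.null(fit)) {
    method <- "nelder-mead"
    rss_fn <- function(par)
      sum((responses - four_pl(doses, par[1], par[2],
                               exp(par[3]), exp(par[4])))^2)
    opt <- stats::optim(unlist(start), rss_fn, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    fit <- list(top = opt$par[[1]], bottom = opt$par[[2]],
                ic50 = exp(opt$par[[3]]), hill = exp(opt$par[[4]]),
                rss = opt$value, converged = opt$convergence == 0)
    if (!fit$converged) {
      err <- simpleError("4PL fit did not converge")
      err$fit <- fit
      stop(err)
    }
  }
  fit$fitted <- four_pl(doses, fit$top, fit$bottom, fit$ic50, fit$hill)
  fit$method <- method
  class(fit) <- "dose_response_fit"
  fit
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("4PL fit (%s): IC50 = %.4g, hill = %.3g, ",
                     "top = %.4g, bottom = %.4g, RSS = %.4g\n"),
              x$method, x$ic50, x$hill, x$top, x$bottom, x$rss))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, doses, ...) {
  four_pl(doses, object$top, object$bottom, object$ic50, object$hill)
}
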