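---
title: "Methods: differential co-expression topology for cytotoxicity transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential co-expression topology for cytotoxicity transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

# The analysis

`coexdiff` implements the computational arm of a classic two-condition
cytotoxicity transcriptome study: cells exposed to an agent (for example, a
cationic liposome formulation at its IC50) versus untreated controls, with
bulk RNA-seq read counts per gene, three or more replicates per condition.
The pipeline asks three questions in sequence: *which genes respond*
(differential expression), *what biology do they represent* (gene-set
over-representation), and *how does their co-regulation rewire*
(differential network topology). Two wet-lab companions — qPCR relative
quantification and dose–response IC50 fitting — close the loop between the
sequencing analysis and the bench.

# Models and statistics

## RPKM and DEG screening

Counts are normalized within sample to reads per kilobase per million
mapped reads,

$$\mathrm{RPKM}_{gs} = \frac{10^9\, c_{gs}}{T_s\, L_g},$$

with $T_s$ the sample's total mapped reads and $L_g$ the gene length in bp.
The fold change is the ratio of RPKM group means, treated over control,
with a pseudocount of $\varepsilon = 1$ RPKM added to both means so genes
silent in one condition get a finite, conservative ratio. A gene is called
**up** when FC $> 1.50$ and FDR $< 0.05$, **down** when FC $< 0.67$ and FDR
$< 0.05$ (all inequalities strict), and **ns** otherwise; FDR is
Benjamini–Hochberg across all genes.

The original analysis engine for such screens is an empirical-Bayes count
model; the screening *criteria*, not the engine, are the reproduced
content, so the per-gene test sits behind a pluggable interface
(`differential_test(method = ...)`). The default is a **moderated t** on
$\log_2(\mathrm{RPKM} + 1)$: per-gene pooled variances are shrunk toward a
common prior (`limma::squeezeVar`) and the statistic is referred to a t
distribution on augmented degrees of freedom. We originally specified a
plain Welch t here, but at realistic depths it cannot recover planted
signal at 3–5 replicates: at planted $|\log_2\mathrm{FC}| = 1.5$, $n =
5$/group, dispersion $\varphi = 0.1$, Welch reaches sensitivity 0.55 where
the moderated t reaches 0.98 at equal empirical FDR, which is precisely the
variance-sharing advantage the empirical-Bayes engines exist to provide.
Welch remains available as `method = "welch"`, with explicit degenerate
conventions (all-equal gene: $p = 1$; zero variance with unequal means:
$p = 0$).

## Over-representation and the enrichment ratio

For a term with $n$ annotated genes in a universe of $N$, of which $n_f$
of the $N_f$ DEGs fall inside, significance is the one-sided Fisher test —
the hypergeometric tail $P(X \ge n_f)$ — plus an uncorrected Pearson
$\chi^2$ on the same $2\times 2$ table reported alongside (the two tests
are named together in this literature without arbitration; Fisher drives
filtering and FDR). The effect size is the enrichment ratio

$$R_e = \frac{n_f / n}{N_f / N},$$

the in-term DEG proportion over the global one; $R_e > 1$ iff the term is
over-represented. Terms are reported when raw $p < 0.05$ **and** BH-FDR
$< 0.05$.

Ontology annotations follow the **true-path rule**: a term's gene set is
closed over all descendants before counting, with set semantics, which is
the convention DAG-based GO counting requires (a no-closure mode exists
for sensitivity checks). The universe $N$ is deliberately explicit — all
annotated genes present in the count matrix — because published analyses
of this type rarely state it; it is configurable. The GO tree is the
induced sub-DAG over enriched terms plus all ancestors, each node labelled
**up**/**down** when *every* closed-annotated DEG shares that direction and
**ambiguous** otherwise (a majority rule sits behind a flag; the "all
members" rule is the default because it never overstates directionality).

## Networks and key-gene ranking

Per condition, the co-expression network joins DEG pairs whose Pearson
correlation across that condition's samples satisfies $|r| \ge 0.8$ and
$p < 0.05$, with $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df. Edges
keep the signed $r$ (anti-correlated pairs count as edges); topology
ignores sign. Degree is the incident-edge count; the core number is
computed by the standard minimum-degree peeling decomposition. **Key
regulatory genes** are ranked by the signed treated-minus-control
differences in degree and core number: by $|\Delta\mathrm{degree}|$
descending, ties by $|\Delta k\text{-core}|$, then gene id. Genes absent
from one condition's network contribute degree 0 and core 0 there — the
"0 → 38" signature of genes whose co-regulation exists only under
exposure.

With only 3 replicates per condition, correlation p-values are nearly
powerless; the builder warns below $n = 5$ rather than refusing, since the
published analyses it mirrors did run at $n = 3$.

The gene-act network is the induced subgraph of a background relation
graph (curated pathway relations, read from SIF) on the DEG set, reported
as connected modules of size ≥ 2; the pathway-act network joins enriched
pathways sharing at least `min_shared` genes, with hubs ranked by degree.

## Assays

qPCR relative expression uses $2^{-\Delta\Delta C_t}$ with replicate
$C_t$ values aggregated by arithmetic mean before differencing, a
housekeeping reference (e.g. GAPDH), and the classic perfect-efficiency
assumption (one doubling per cycle; efficiency correction is out of
scope). RNA-seq/qPCR concordance is OLS of qPCR on RNA-seq
$\log_2$ fold changes plus Pearson r. Dose–response fitting is the
four-parameter logistic

$$y = b + \frac{t - b}{1 + (d/\mathrm{IC}_{50})^h},$$

fit by least squares with $\mathrm{IC}_{50}$ and $h$ parameterized on the
log scale (keeping both positive), initialized from the response extremes,
the geometric-mean dose and $h = 1$, via `nls` (port) with a Nelder–Mead
fallback; non-convergence raises an error carrying the best-so-far fit.

# The synthetic world

Every stage is exercised on generated data whose statistical structure
states, explicitly, what the pipeline assumes:

- **Counts**: negative binomial with $\mathrm{var} = \mu + \varphi\mu^2$
  ($\varphi$ = `dispersion`; $\varphi = 0$ means Poisson), two conditions,
  default 3 replicates each — the replication of the emulated study
  design. Default baseline mean 100 counts/gene and $\varphi = 0.1$ are
  ordinary bulk RNA-seq magnitudes. A minority of genes (defaults 2% up,
  4% down, mirroring a down-dominated screen of a few hundred DEGs) get
  group-mean ratios $2^{\pm\mathrm{lfc}}$ with lfc = 1.5, safely beyond
  the 1.5× screening threshold.
- **Modules**: each planted module shares a standard-normal per-sample
  latent factor added on the $\log_2$ scale with loading 0.9, *only* in
  the module's active condition, and mean-corrected by
  $E[2^{0.9Z}] = e^{(0.9\ln 2)^2/2}$ so membership does not shift
  expected counts. Module members are drawn from the planted DE genes,
  because the downstream network is built on DEGs. The expected
  within-module correlation on the log scale is
  $r \approx 0.81 / (0.81 + v)$ where $v$ is the NB noise variance in
  $\log_2^2$ units ($v \approx (1/\mu + \varphi)/(\ln 2)^2$). At the
  package's default depth this gives $r \approx 0.78$ — *below* the 0.8
  edge rule — so module-bearing demonstrations use deep counts (baseline
  1000, $\varphi = 0.01$, $r \approx 0.97$), a derived noise budget, not a
  tuned knob.
- **Gene lengths**: uniform integers on [500, 5000] bp, recorded in the
  counts sidecar.
- **Ontology**: single-rooted random DAG (each non-root term picks 1–3
  earlier parents), annotations on leaves only and deliberately *not*
  closed, so closure is observably the enrichment module's work.
- **qPCR**: $C_t$ values constructed so the expected $\Delta\Delta C_t$
  equals minus the planted lfc, Gaussian well noise.
- **Dose–response**: the 4PL curve sampled on the emulated assay's 2-fold
  grid (25–3200 µg/ml), default top 100 / bottom 0 / IC50 120 µg/ml /
  hill 1, additive noise 2% of top.

Reproducibility: one master seed drives condition-level draws; per-gene
31-bit sub-seeds derived from it keep each gene's counts stable when
unrelated parameters change. Identical parameters and seed give
byte-identical outputs.

**What a green test does not establish.** The generator has no batch
effects, GC or length bias, library-composition artifacts, isoform
structure, or outlier samples; group means are exactly the planted ratios.
Recovery results on this world demonstrate algorithmic correctness and
statistical calibration under the stated model, not robustness to the
failure modes of real libraries.

# Numerical choices and edge cases

- Fold change uses $\varepsilon = 1$ RPKM on both group means; zero-total
  samples are a hard error naming the sample.
- BH ties are handled by the step-up itself (adjusted values are invariant
  to tie order); screening inequalities are strict, matching the stated
  criteria.
- $\chi^2$ with a zero marginal returns $p = 1$ with a warning; Fisher
  with an empty DEG set returns $p = 1$ and undefined $R_e$ (NA) with a
  warning.
- Correlation of a zero-variance vector is NA, never an edge; $|r| = 1$
  maps to $p = 0$.
- k-core peeling is validated against an exhaustive induced-subgraph
  oracle (all labelled graphs on ≤ 4 nodes; seeded random graphs on 5–8
  nodes — the full enumeration at 8 nodes is $2^{28}$ graphs and is not
  attempted).
- IC50 identifiability: on the emulated assay's own grid the lowest dose
  is $0.2\times$ IC50, the top plateau is extrapolated, and the intrinsic
  least-squares IC50 error at 2%-of-top noise with six replicate wells is
  ≈ 5.4% median — a property of the design, not the optimizer (verified
  with truth-started fits). The fitter-recovery property test therefore
  uses a 2-fold grid centred on the true IC50 ($0.125\times$–$16\times$),
  where the same fitter achieves ≈ 3.4% median error. Fits on the assay
  grid remain supported; their IC50 uncertainty is simply larger.
- Ranking tie-break (|Δdegree|, then |Δk-core|, then gene id) is exact and
  documented because planted near-cliques produce many exact ties.

# Known limitations

- The differential test operates on log-RPKM, not a count model; at very
  low counts a dedicated count-based engine remains preferable.
- The enrichment universe excludes unannotated genes by default, which
  inflates $R_e$ relative to a whole-genome universe; both the universe
  and closure behaviour are configurable but defaults matter when
  comparing against published tables.
- Pearson co-expression at $n = 3$ per condition (the emulated study's
  replication) is essentially descriptive; the pipeline warns but
  proceeds.
- Signed edges mean strongly anti-correlated gene pairs join the network;
  on small DEG sets an occasional background gene can tie into a planted
  module's clique (observed at one master seed in 300-gene worlds as a
  3.6σ sampling event).
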