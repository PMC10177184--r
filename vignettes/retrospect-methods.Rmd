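---
title: "Methods: two-axis evolutionary profiling of genes and pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-axis evolutionary profiling of genes and pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrospect)
```

## The two axes

The package scores gene evolution along two axes. The structural axis is
dN/dS: the ratio of nonsynonymous to synonymous substitution rates, taken
as an input (gene → value table) because its estimation from alignments
is a separate, well-served problem. The regulatory axis is NGRE, a
measure of how much of a gene's regulatory apparatus is built from
retroelements. Retroelements (LINEs, SINEs/Alu, LTR elements) are the
dominant source of novel regulatory sequence in mammals; a gene whose
promoter-proximal peaks are rich in RE-derived sequence, relative to how
much RE sequence its neighbourhood offers, has been accumulating
regulatory novelty faster than one whose peaks avoid REs.

### NGRE

For a gene $g$, functional tag $t$ and cell line $c$:

$$\mathrm{NGRE}(g,t,c) \;=\; \frac{n_{\mathrm{linked}}/n_{\mathrm{total}}}{f_{\mathrm{RE}}}$$

* the scoring frame is the `frame_size` = 10,000 b window centered on
  the canonical TSS (clipped at the chromosome origin; strand ignored —
  the frame is symmetric);
* $n_{\mathrm{total}}$ counts peaks overlapping the frame by at least
  one base. Peaks are **not** merged: each peak is one regulatory
  element, even if peaks overlap;
* $n_{\mathrm{linked}}$ counts peaks sharing at least `min_overlap`
  (default 1) bases with the **union** of RE intervals; a peak touching
  several REs counts once;
* $f_{\mathrm{RE}}$ is the RE base-coverage fraction of the frame,
  overlapping REs merged first.

Degenerate cases are scored, not erred: an empty frame gives NGRE = 0
with `is_zero = TRUE` (these zeros feed the weighting below, which is why
they must be stored); a frame with peaks but no RE content gives 0 (no RE
content implies no RE linkage, avoiding 0/0). All coordinates are 0-based
half-open throughout the package, so touching intervals share no base.

The normalization by $f_{\mathrm{RE}}$ is a quotient; ranks are what
every downstream step consumes (Spearman, quantile groups), so any
monotone variant of the normalization would leave the downstream results
unchanged. `normalize = FALSE` gives the plain RE-linked fraction.

### Aggregation

Per (tag, cell line) profile the zero fraction $z$ over the whole gene
universe gives the data-quality weight $W = (1-z)^3$: profiles dominated
by empty frames carry little information and the cubic sharply
down-weights them. Per-tag scores are the convex combination
$\sum W_i x_i / \sum W_i$ (zeros included — they are real "no linkage"
observations). Tags combine as fixed-weight means:
$\mathrm{NGRE}_{ac}$ over H3K9ac, H3K27ac, H3K4me3, H3K4me1 (H3K4me1 is
treated as a potentially-active-chromatin tag);
$\mathrm{NGRE}_{hc}$ over H3K27me3, H3K9me3; and
$\mathrm{NGRE}_{AGG} = (\mathrm{NGRE}_{hc} + \mathrm{NGRE}_{ac} +
\mathrm{NGRE}_{TFBS})/3$. A missing component leaves the aggregate
missing — no silent renormalization, so a gene's NGRE_AGG always means
the same three-way average.

### Pathway level

`dnds_pw` is the unweighted mean over member genes that carry a dN/dS
value (members without one are excluded and counted; a pathway with none
is unscorable). NPII is the member mean NGRE over the background mean of
the same profile, making 1.0 the neutral value — the whole-universe
pathway scores exactly 1 for every profile. NPII profiles aggregate with
the *gene-level* cell-line weights and the same class structure, giving
`NPII_AGG`. Node-level chart scores are plain member means of dN/dS and
of gene-level NGRE_AGG (no re-normalization at node level), with
missing-metric flags so charts can draw "no data" nodes distinctly.

## Stratification, enrichment, deviation

Quantile thresholds use linear interpolation at position $1 + q(n-1)$
(the common statistical-software default, `type = 7`); at least 3
non-missing values are required. "High" means strictly above the 0.8
threshold, "low" strictly below the 0.2 threshold — ties at a threshold
fall in neither tail, and a constant metric leaves everything unassigned
with a warning. The four groups are the four intersections; entities
missing either metric are unassigned. Because thresholds are rank-based,
the grouping is invariant under monotone transforms of either metric.
The threshold pair is configurable (e.g. sweeps over
0.2/0.1/0.05/0.01).

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ with universe size $N$, annotated $K$, group size $n$,
observed $k$, then Benjamini–Hochberg across reported terms, significant
at adjusted p < 0.05. Terms with $k = 0$ are skipped by default
(reported with p = 1 on request). The universe is the set of genes
entering the stratification (both metrics present), the standard ORA
convention; `filter_shared_terms()` optionally drops terms significant
in all four groups, which discriminate nothing.

The deviation test asks whether one gene's per-profile NGRE values sit
systematically below (or above) the global mean: an exact one-sided sign
test per direction, values equal to the mean dropped, genes with fewer
than 5 usable values skipped, BH adjustment per direction across genes.
The sign test was chosen over signed-rank because it needs no symmetry
assumption about the (strongly skewed) NGRE distribution. Note that with
many profiles per gene and strong between-gene heterogeneity, a large
fraction of genes can legitimately be flagged: the test detects
consistent displacement, however small.

Spearman correlations use mid-ranks for ties and the large-sample
$t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ (exact permutation
would be pointless at thousands of genes); pairs with a missing side are
dropped pairwise, which maximizes the usable pairs per cell of the
metric–metric matrix. The reporting order of correlation matrices comes
from Ward.D2 clustering on distance $1 - \rho$.

## The synthetic-data generator

`simulate_inputs()` builds every input the pipeline reads. One latent
$u_g \sim N(0,1)$ per gene drives both axes:

* each peak in $g$'s frame overlaps an RE with probability
  $\sigma(\theta_0 + \theta_1 u_g)$ (defaults $-1$, $2$);
* $\log \mathrm{dN/dS}_g = \mu + \sigma_d(\rho_\ell u_g +
  \sqrt{1-\rho_\ell^2}\, e_g)$, strictly positive with rank coupling set
  by `rho_latent`.

Geometry: TSSs every 20 kb on one chromosome (frames provably disjoint),
peaks 200 b wide, frames empty with probability `zero_rate` = 0.2 and
otherwise holding $1 + \mathrm{Pois}(6)$ peaks — roughly the peak
densities of promoter-proximal ChIP-seq. Cell-line counts default to 5
per histone tag and 13 for TFBS, the panel sizes typical of public
ChIP-seq compendia. Every frame is guaranteed `frame_re_count` = 2
retroelements of width U(600, 1000) b, and intergenic gaps are filled
with U(150, 6000) b elements (Alu-to-L1 scale) until genome-wide union
coverage sits within 0.01 of `re_coverage` = 0.25. Two design points
deserve note: (i) guaranteed per-frame RE content keeps the
normalization defined for every gene — real promoter neighbourhoods
essentially always contain some RE sequence; (ii) the narrow per-frame
width range bounds the variance of $f_{\mathrm{RE}}$, so the
normalization does not drown the per-gene linkage signal that the
generator plants — a generator whose own normalization noise hides its
planted signal cannot certify signal recovery.

Pathway membership is sampled *coherently*: genes are ordered by a noisy
copy of the latent, $s_g = \alpha u_g + \sqrt{1-\alpha^2} w_g$
(`pathway_coherence` = $\alpha$), and each pathway takes a 50-gene run
at a start position stratified over the ordering. This is deliberate and
load-bearing. With independent random pathways, the correlation between
pathway means mathematically equals the gene-level correlation (all
variance components shrink by $1/m$ together), so the empirically
observed pattern — weak gene-level, strong pathway-level coupling —
cannot arise. Functional coherence of pathways (genes in one pathway
share evolutionary regime) is the minimal structure that produces it,
and is biologically what pathway databases encode. Pathways are distinct
but overlap, like real collections; 500 disjoint 50-gene pathways do not
exist in a 5,000-gene universe.

Calibration (fixed once at design time): `rho_latent` = 0.10 puts the
gene-level Spearman between NGRE_AGG and dN/dS near 0.10 — the
attenuation through NGRE measurement is small (rank correlation of
NGRE_AGG with $u$ is about 0.97 with 43 tracks averaged), so the latent
weight maps nearly one-to-one to the observed correlation.
`pathway_coherence` = 0.75 puts the pathway-level correlation near 0.45.
A lower coherence (0.65) reproduces a ~0.4 pathway correlation on
average, but the seed-to-seed spread of the pathway estimate is
structurally large: a 5,000-gene universe contains only ~$n/m$ = 100
effectively independent 50-gene windows, so the estimate carries a
standard deviation near 0.075 regardless of how many (overlapping)
pathways are drawn. The default keeps the qualitative contrast — an
order-of-magnitude amplification over the gene level — clear of that
noise floor. The planted gene set (100 genes, latent shifted by +3)
gives a recovery benchmark: planted genes should populate the top-20%
NGRE_AGG tail and be recovered by ORA as the top term.

What the generator does **not** emulate: real RE family structure and
phylogeny, GC/sequence composition, peak width and density
heterogeneity between marks, inter-chromosomal structure, tissue
specificity of tracks, and the hierarchical redundancy of real pathway
databases. Tests passing on synthetic data certify the *machinery* —
interval arithmetic, weighting, normalization identities, calibration of
the statistical tests, signal recovery at a known effect size — not that
any particular biological dataset will show a given effect.

## Numerical conventions and problem sizes

* Intervals 0-based half-open everywhere; IRanges (1-based closed) is
  used internally with a fixed conversion at the boundary.
* Exact-string, case-sensitive gene matching between score tables,
  dN/dS and pathways; unmatched genes are dropped per metric and
  counted, never imputed.
* Score tables round-trip through TSV at better than 12 significant
  digits; missing is the literal `NA`.
* Outputs are deterministic given inputs and config; `manifest.json`
  records input MD5s, config and filtering counts, and reruns are
  checksum-identical.
* The test suite exercises the statistical properties at desk scale:
  200 random frames against a per-base oracle; 10,000-entity
  stratification null; 20-seed correlation-amplification runs at the
  full default geometry (5,000 genes, 43 tracks, 500 pathways);
  100-replicate nulls for the ORA FDR and the sign-test level (2,000
  genes × 13 lines each); exhaustive hypergeometric enumeration for
  universes up to 12 plus a closed-form spot value at 20. These sizes
  were chosen so each property is measured within a few Monte-Carlo
  standard errors while the whole suite stays interactive.

## Limitations

The NGRE normalization form is one of several monotone-equivalent
choices; absolute NGRE values are therefore not comparable across
studies using different variants, though ranks are. The fixed 10-kb
symmetric frame ignores strand and long-range enhancer–gene links.
Per-TF resolution is deliberately absent: TFBS peaks are pooled per cell
line. The deviation test treats profiles as exchangeable observations of
one gene, ignoring the correlation between tags measured in the same
cell line, so its per-gene p-values are anticonservative to the degree
that profiles covary; the pipeline-level use (ranking and FDR selection of
extreme genes) is robust to this, but the individual p-values should not
be over-read.
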