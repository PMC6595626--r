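---
title: "Methods: stage-resolved transcriptome-metabolome integration"
author: "germOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved transcriptome-metabolome integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germOmics)
```

`germOmics` analyses a six-stage seed germination design: stage 1 is
the dry seed, stages 2-3 are delimited by the rapid and slow phases of
the water-uptake curve, and stages 4-6 run from radicle protrusion to
the first true leaf. Expression is sampled at 3 replicates per stage
(18 samples), metabolites at 6 (36 samples). This vignette records the
statistical models, the defaults and why they hold, the numerical
choices, and what the synthetic-data generator does and does not
emulate.

## Stage definition from the imbibition curve

The fresh-weight series is modeled as a continuous piecewise-linear
function of time, `w(t) = a + s1 t + (s2-s1)(t-b1)+ + (s3-s2)(t-b2)+`.
`fitPhaseBreakpoints()` restricts breakpoints to the observed time
grid and searches all admissible combinations exhaustively, so the
reported fit is the global least-squares optimum over the grid and
fully deterministic. Each candidate segment must contain at least two
observations (slope identifiability); ties in residual sum of squares
resolve to the lexicographically smallest breakpoints. Exhaustive
search costs O(n^2) linear fits for three segments, which is
negligible for the short series this assay produces (we use about a
hundred points at a 10-minute spacing); a heuristic segmentation would
save nothing and lose the optimality guarantee. How the original
rapid/slow boundary was drawn from the published curve is not
documented; the breakpoint fit is this package's formalization of that
step.

## Differential expression: the noise-probability statistic

FPKM (`1e9 c / (N L)`) is the expression unit throughout. For a
comparison of stages A and B, every within-stage replicate pair
contributes one `(|M|, D)` point per gene to a pooled noise cloud,
where `M` is the log2 ratio and `D` the absolute difference after a
pseudocount. The signal pair for a gene uses the two stage means, and

    q = #{ noise points with |M_n| < |M| and D_n < D } / #noise,

with ties counting against the gene. A gene is called when
`fold-change >= 2` and `q >= 0.8`, both inclusive as printed in the
thresholds this pipeline adopts.

Choices made here: the pseudocount is 0.5 (keeps `M` finite and
symmetric under stage swap; the reference method's zero-handling
varies by version); noise is pooled across genes and both conditions
(the "real replicates" flavor — a simulated-replicate variant is not
implemented); both comparison modes (each stage vs stage 1,
successive stages) are provided as a switch because stage-1-referenced
and successive-stage counts answer different questions. `q` is a
probability-like rank statistic, not a frequentist p-value; no
multiple-testing control is applied to DE calls, by design.

## Stage clustering

Clustering operates on per-gene stage means of `log2(FPKM + 1)`,
z-scored across the six stages. The z-scoring departs from clustering
raw FPKM: Euclidean K-means on the raw scale groups genes by magnitude
rather than shape, and the stage-peaked patterns of interest are
shapes. A `scale = FALSE` escape hatch restores raw profiles.
Zero-variance (flat) genes cannot be standardized and are dropped with
a warning.

K-means uses `stats::kmeans` with 10 restarts under a fixed seed
(deterministic; restart handling and empty-cluster recovery are
delegated to the stock implementation). K defaults to 24, the cluster
count this design was originally summarized with; no data-driven K
selection is attempted. Each cluster is assigned the stage where its
centroid peaks, earliest stage on exact ties (logged). Superclusters
merge centroids by average-linkage under `1 - cor` distance, cut to a
configured count (default 9); the correlation distance makes the merge
scale-invariant. The original supercluster rule is undocumented, so
this explicit, deterministic criterion is the package's choice.
Single-stage genes are those with stage-mean FPKM at or above
`tau = 1` in exactly one stage.

## Coexpression core

The weighted-network core is implemented from its defining formulas
(adjacency, topological overlap, eigengenes), not wrapped from an
existing package, and is validated in the test suite against
independent oracles (triple-loop TOM, power-iteration PCA).

- Adjacency: unsigned, `a_ij = |cor(x_i, x_j)|^beta` on
  `log2(FPKM+1)` values; correlations on the raw FPKM scale are
  dominated by the most abundant samples. A signed variant is a flag;
  the original analysis does not state which was used, and unsigned is
  that tool's default. Zero-variance genes are dropped; any residual
  undefined correlation is defined as 0.
- Soft threshold: smallest `beta` in 1..20 whose binned log-log
  connectivity fit reaches R^2 >= 0.8 with negative slope, else the
  argmax with a warning. Planted module structure is not scale-free,
  so on synthetic data the fallback warning is expected and pinning
  `beta` in the pipeline config is legitimate.
- TOM: `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`; the
  matrix form subtracts the two diagonal terms from `(A^2)_ij` to get
  `L_ij`. Values are clamped at 0 against `-1e-16`-scale rounding.
- Modules: average-linkage clustering of `1 - TOM`, static cut at
  height 0.25, minimum size 30, smaller branches grey. A static cut is
  deterministic and sufficient for planted-block recovery; dynamic
  tree cutting is out of scope. Labels follow the conventional color
  order by decreasing size, size ties broken by smallest member id so
  labels are independent of gene input order. Note the interaction
  between the cut height and `beta`: at within-module correlation
  around 0.9, `1 - TOM` falls below 0.25 only for small `beta`
  (about 2); the generator's planted modules are tighter (around
  0.99) and survive `beta = 6`.
- Eigengene: leading right singular vector of the row-standardized
  module submatrix (unit norm per sample vector), sign-oriented so the
  average gene-eigengene correlation is positive; variance explained
  is the leading eigenvalue share.
- Module-stage statistics: Pearson `r` between the eigengene and the
  one-hot indicator of each stage over all 18 samples;
  `p = 2 P(T_{16} <= -|r| sqrt(16) / sqrt(1 - r^2))`. This one-hot
  encoding reproduces the printed arithmetic of the motivating study:
  r = 0.75 at n = 18 gives p = 3.4e-4 (printed 3e-4 to one
  significant figure), and r = 0.92 gives p in the 1e-7 to 1e-8
  decade. The thresholds `r >= 0.75`, `p <= 0.05` flag module-stage
  associations downstream.
- Hubs: intramodular connectivity `k_within(i) = sum_j a_ij` over
  module co-members; top 10 by `k_within`, ties by gene id.

## Enrichment

Over/under-representation of annotation bins is the exact
hypergeometric tail pair (`p_over = P(X >= k)`, `p_under = P(X <= k)`),
evaluated with `stats::phyper`. Significance is a raw `p <= 0.05` on
the smaller tail — deliberately uncorrected, matching the screening
use of the original analysis — with Benjamini-Hochberg available as an
option. Both tails are always reported because over- and
under-represented categories are both of interest. Note
`p_over + p_under >= 1` (shared point mass): the two tails are not
complementary.

## Metabolite significance

Two steps per comparison (each stage vs the dry seed by default;
successive mode available since the original comparison scheme is
unstated): a single-component projection-to-latent-structures VIP
filter, then an equal-variance Student t-test. With one component the
VIP formula collapses to `VIP_j = sqrt(P) |w_j|` with
`w = X' y / ||X' y||` on column-autoscaled data, so
`sum(VIP^2) = P` holds by construction and is asserted to 1e-9 in the
tests. Abundances are log2-transformed before autoscaling
(multiplicative noise model). Thresholds are strict — `VIP > 1.0`,
`p < 0.05` — resolving an ambiguous published phrasing by its
conventional reading: variables with `p >= 0.05` are discarded.
Multi-component VIP and orthogonalized variants are out of scope.

## TCNA

Expression (18 samples) and metabolomics (36 samples) share only the
stage axis, so all TCNA correlations are computed between 6-point
stage-mean trajectories. Spearman's rho uses average ranks; its
two-sided p at n <= 8 is computed by full enumeration of all n!
permutations (720 at n = 6), where the t-approximation is unreliable
and exactness costs microseconds. A consequence the test suite
verifies by enumeration: no n = 6 edge can reach p <= 0.05 below
|rho| = 0.886, so the display threshold `r_min = 0.25` never removes a
significant edge — it only prunes weak dashed ones. The published
description contains a contradiction (`p >= 0.05` in one place,
`p <= 0.05` marking significant edges in the figure legend); the
figure reading is adopted. All computed family edges stay in the graph
object so that every member can be ranked (the exports write edges at
`|rho| >= r_min`); ranking is by `|rho|` descending with ties broken
by smaller p, then gene id. Pathway adjacency is an input edge list,
not hard-coded biology.

## The synthetic-data generator

`generateDataset()` plants, under one master seed with an independent
child stream per table (so enlarging one table does not perturb
another):

- stage-peaked clusters: Gaussian bumps over the stage index
  (amplitude 3 log2 units, width 0.75) on gene-specific baselines —
  the single-peak centroid shapes the clustering stage expects;
- coexpression modules: each module shares a latent built as
  `r z + sqrt(1-r^2) e` with `z` the standardized one-hot of the
  target stage and `e` orthogonalized noise, so the latent's sample
  correlation with the stage indicator is exactly `moduleStageR`;
  genes load on it with amplitude 2 plus log-normal noise;
- a bin over-represented in planted cluster 1 by `enrichmentFold`;
- single-stage transcription factors (30 FPKM in one stage, 0.02
  elsewhere);
- metabolite trajectories as smooth random stage responses, chained
  into pathway triples that share latents (blend weight 0.95), giving
  positive backbone edges;
- one causal enzyme-family member per metabolite whose trajectory
  blends with the metabolite's latent; `causalGeneRho` is a *target
  Spearman*, so the Pearson blend weight is obtained by inverting the
  finite-n bivariate-normal rank-correlation expectation
  `E[rho_s] = 6/(pi(n+1)) (asin r + (n-2) asin(r/2))` at n = 6. A
  naive blend at weight `rho` would systematically under-deliver the
  requested rank correlation. Decoy members receive independent
  per-stage expression levels (iid stage effects) rather than smooth
  trajectories: two independent smooth 6-point curves correlate
  spuriously in rank space, which would make causal-member recovery
  ill-posed no matter the method;
- all abundances are `2^(log2 mean + N(0, noiseSd))`, hence strictly
  positive with the multiplicative heteroscedasticity the M statistic
  assumes.

What it does not emulate: count-level sampling noise (FPKM is
generated directly), gene-length and GC effects, batch structure,
missing metabolite values, or correlated replicate effects. Passing
the planted-recovery tests therefore demonstrates correctness of the
algorithms under the assumed generative model, not robustness to every
artifact of real data.

`generateImbibitionSeries()` produces the triphasic fresh-weight curve
(defaults: breakpoints 120 and 600 min, slopes 0.004/0.001/0.003
g/min, 109 points over 18 h, additive noise 0.001 g) — rapid uptake,
plateau, renewed uptake — continuous at the breakpoints by
construction.

## Validation set-up and problem sizes

The suite checks every statistic against an independent route: TOM vs
a triple-loop evaluation (1e-12), Fisher tails vs direct summation of
hypergeometric point masses on universes up to 200, Spearman (rho, p)
vs an independently coded enumeration of all 720 permutations and R's
exact test, VIP vs a NIPALS-style iterative fit (1e-8), eigengenes vs
power iteration (|cor| > 0.999), and the module-stage p-value vs
`cor.test`. Recovery studies use desk-scale problems chosen to keep
the full suite under a minute while leaving comfortable statistical
margins: 100-seed studies with 160-200 genes for module-stage
correlation (target 0.9 recovered within 0.1) and TCNA top-1 ranking
(target rho 0.9, noise 0.3, 4 decoys), a 400-gene K-means recovery at
noise 0.1, 200-seed Fisher null calibration compared against the
exact discrete null rate, and matched null/planted DE simulations.

## Known limitations

- The coexpression core is dense (O(n^2) memory); it targets the
  10^2-10^4 gene range of DEG sets, not whole-genome matrices.
- Static tree cutting can split a module that dynamic cutting would
  keep; cut height and minimum size are exposed for that reason.
- The exact Spearman enumeration is limited to n <= 8 by design;
  larger designs fall back to the t-approximation.
- `q` thresholds are not error-rate calibrated (inherent to the
  method); the null-vs-planted calibration test documents the
  behavior rather than a false-discovery guarantee.
- The pipeline is an R API (plus YAML configs); there is no shell
  executable, as the intended users drive analyses from R.
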