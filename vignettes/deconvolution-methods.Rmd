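---
title: "Immune cell deconvolution: model, signature construction, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune cell deconvolution: model, signature construction, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunofrac)
```

## The deconvolution model

A bulk transcriptome is modelled as a weighted sum of cell-type
expression profiles. Given a mixture vector $M_g$ over the signature
genes present in the data ($g \in G^*$) and a signature matrix
$S_{gc}$ of median expression profiles for $C = 10$ immune cell types,
the cell fractions $F_c$ solve

$$\min_F \; \lVert S F - M \rVert^2
\quad \text{s.t.} \quad F_c \ge 0, \; \sum_{c=1}^{C} F_c \le 1 .$$

Because the fraction sum may be *below* one, the remainder
$F_\mathrm{other} = 1 - \sum_c F''_c$ estimates the uncharacterized
cells (in tumors, mostly malignant and stromal cells). This makes the
estimates absolute — comparable across samples and across cell types —
rather than relative to the immune compartment only.

Both $M$ and $S$ live on the TPM scale, renormalized so that every
library sums to $10^6$ over the full gene universe:
$x_{gl} = \mathrm{TPM}_{gl} \cdot 10^6 / \sum_i \mathrm{TPM}_{il}$.
Keeping mixture and signature on one normalization convention is what
makes the regression coefficients interpretable as mRNA proportions.

### The solver

The inequality-constrained least-squares problem is solved exactly by
the classical active-set route: Lawson–Hanson non-negative least
squares, used inside a least-distance-programming (LDP) step, reached
from the general problem by an SVD change of variables (LSI). The
solver is deterministic, has no random initialization, and its
optimality is cross-checked in the test suite against an independent
accelerated projected-gradient oracle on hundreds of random instances
(worst objective gap in the 1e-13 range). Near-zero singular values
(relative tolerance 1e-12) are truncated with a warning; mixtures of
all zeros return the zero fraction vector directly.

### mRNA-content correction

Cell types differ in average mRNA content, so mRNA proportions
over-represent mRNA-rich cells. Each raw fraction is divided by a
per-type scaling factor $n_c$, then rescaled to preserve the total:

$$F'_c = F_c / n_c, \qquad F''_c = F'_c \cdot f / f',
\quad f = \sum_c F_c, \; f' = \sum_c F'_c .$$

$n_c$ is proxied by the median expression of the PSMB2 housekeeping
gene per cell type in a labeled compendium
(`mrna_scaling_factors()`). The factors shipped with the package are
derived from the bundled *synthetic* compendium and are placeholders
for demonstration; real analyses should supply factors computed from a
real compendium, or disable scaling. The `Other` fraction is never
rescaled: the uncharacterized population has unknown mRNA content.

When the true fractions of a benchmark are themselves mRNA fractions —
as in every simulation in this package, where mixtures are TPM-weighted
sums — deconvolution must run with `mrna_scale = FALSE`; enabling the
correction there would *introduce* a bias rather than remove one.

### The Treg dropout heuristic

Treg and non-regulatory CD4$^+$ T cell signatures are highly collinear,
which drives low-abundance Treg estimates to zero. When the initial
estimate $F^1_\mathrm{reg} < 0.02$, the system is re-solved without the
CD4 column, giving $F^2_\mathrm{reg}$, and

$$F_\mathrm{reg} = \mathrm{mean}(F^1_\mathrm{reg}, F^2_\mathrm{reg}),
\qquad F_\mathrm{CD4} = \max(F^1_\mathrm{CD4} - F_\mathrm{reg},\, 0).$$

The adjustment changes the immune sum, so a renormalization is needed.
Renormalizing *all* fractions to sum to one would destroy the
absolute-fraction semantics (it would force $F_\mathrm{other} = 0$), so
this package rescales the adjusted immune fractions to the
pre-adjustment immune sum, leaving `Other` consistent. The pre-rescale
values ($F^1_\mathrm{reg}$, $F^2_\mathrm{reg}$, $F_\mathrm{reg}$,
$F_\mathrm{CD4}$) are kept in the audit attribute of every fraction
table.

The heuristic runs on the raw regression fractions, before mRNA
scaling, because it repairs a regression artifact (collinearity), not a
biological one. Note a deliberate consequence: on noiseless data with
true Treg fractions below the 0.02 trigger, the heuristic biases the
Treg/CD4 estimates slightly. Exact-recovery properties therefore hold
at the regression level; end-to-end accuracy is asserted at realistic
tolerances.

## Input preparation

* RNA-seq input is TPM; microarray input is detected as log2 when the
  maximum intensity is below 50 (linear intensities always exceed
  this), unlogged, quantile-normalized onto the mean order-statistic
  profile across samples (ties averaged; delegated to
  `limma::normalizeQuantiles`), probe-collapsed keeping the probe with
  the highest mean across samples, then TPM-renormalized.
* Gene symbols are mapped through a user-supplied alias table; rows
  sharing a final symbol are collapsed to their per-sample median
  (midpoint convention for even counts).
* For microarrays the full signature is recommended
  (`rmgenes = "none"`), since arrays often lack signature genes; for
  RNA-seq the curated 17-gene blacklist is removed by default, and
  `tumor = TRUE` additionally removes 17 genes over-expressed in bulk
  tumors. These flag defaults are applied by `deconvolute()` unless
  overridden.

## Signature construction

`build_signature()` distils a labeled compendium (ten immune types,
several libraries each, optionally a tumor library) into the signature
matrix through a filter cascade:

1. **Detection**: genes detected (value > 0) in at least two immune
   libraries.
2. **Quantization**: per gene, libraries are binned low/medium/high.
   The reference method for this step is not fully specified in the
   literature it descends from, so the package uses a deterministic
   definition: the two thresholds minimizing the within-bin sum of
   squares of $\log_2(x+1)$, found by exhaustive search; constant genes
   are all-low. Bins are monotone in expression by construction.
3. **Cell-specific selection**: a candidate for type $c$ must be high
   in *all* libraries of $c$ and at most medium everywhere else — which
   also makes ownership unique.
4. **Tumor expression**: drop genes with median log2 expression above 7
   in *all* provided cancer cell lines, and genes with mean bulk-tumor
   expression below 1 TPM. These summaries are injected as plain
   tables, so no external downloads are required.
5. **Specificity**: drop genes listed in a gene set tagged with a
   different cell type; CD4 sets are not used against Treg candidates
   (FOXP3-like markers legitimately appear in both).
6. **Range**: drop genes exceeding 700 TPM in any library (strict
   inequality), which would otherwise dominate the objective.
7. **Fraction correlation**: using simulated mixtures with known
   composition, keep genes whose expression correlates with their own
   type's true fraction at $r \ge 0.6$.
8. **Restricted expression**: in external labeled data sets, rank genes
   by the median (across data sets) of the in-type/out-type median
   expression ratio; keep the top 30 per type with median ratio
   $\ge 2$. Ties at the boundary break lexicographically for
   determinism. Treg candidates exclude CD4 libraries from the
   denominator and must additionally pass a Treg-vs-CD4 ratio of
   $\ge 1$.

Profiles are medians over the libraries of each type. The condition
number (ratio of extreme singular values of the linear-scale matrix —
the scale deconvolution actually operates on) summarizes how well-posed
the regression is; removing the curated variable-expression genes
lowers it.

## The synthetic data generator

No real compendium or published signature ships with the package; all
test data are synthetic and generated in code.

`make_fixtures()` emulates a marker-gene compendium: 3 libraries per
type plus one tumor library; 12 planted markers per type (in-type
levels 150–400 TPM with 0.25 log2-sd noise, out-type levels spread over
0.016–2 TPM); decoy genes targeting each filter (cross-listed in
foreign gene sets, peaks above 700 TPM, high cancer-cell-line
expression, sub-1-TPM bulk support); the curated blacklist symbols as
genuine type-specific genes; ~300 background genes; a handful of
highly expressed housekeeping-like genes carrying most of the TPM mass
(so renormalization barely rescales planted levels); and a PSMB2 gene
encoding per-type mRNA content. The wide low/narrow high design is
what makes the three-bin quantizer cut between background and marker
expression rather than inside the marker cluster.

`til10_synthetic()` is a deterministic synthetic stand-in for a
published ten-type signature: 170 genes, including all curated and
tumor blacklist symbols, with blacklist genes carrying a shared
moderate cross-type component (emulating their documented variable
expression) so that their removal measurably improves conditioning.
Its numerical condition numbers are properties of the synthetic
construction, not of any published matrix.

What the synthetic data do **not** emulate: correlated biological
variation between related cell types (beyond the planted Treg/CD4
structure), platform batch effects, compositional interference between
markers, or realistic transcriptome-wide expression distributions.
Passing tests therefore demonstrate correctness of the algorithms
under the stated generative model, not field performance on real
cohorts.

## Simulation and validation design

Mixtures are TPM-weighted sums of per-type profiles. Sequencing depth
is emulated by multinomial resampling of `depth` read counts over the
expected profile, then converting back to TPM — this preserves the
depth-noise structure without touching raw reads. Note that on the TPM
scale the per-gene sampling noise is $\sqrt{x \cdot 10^6/\mathrm{depth}}$,
so highly expressed genes keep double-digit TPM fluctuations even at
$10^8$ reads; convergence to the exact mixture is therefore checked
statistically, not with a fixed small bound.

Immune fractions are drawn uniform on $[0,1]$ and renormalized to sum
to $1 - \mathrm{purity}$ (a composition is required; truncation would
not give one). The benchmark design crosses 100 mixtures with 11
purities (0–100% in steps of 10) at the base depth of $10^6$ read
pairs, plus 6 further depths (2, 5, 10, 20, 50, 100 million) at the
60% purity anchor — 1700 data sets, with the base-depth anchor counted
once.

Leave-K-out validation rebuilds the signature for every mixture from
the libraries *not* used to compose it, using the compendium-intrinsic
criteria (detection, quantization, cell-specific selection, range,
profiles). The external-resource filters are not re-run per exclusion:
their inputs (cell-line summaries, gene sets, external data sets) are
not part of the held-out libraries, so re-applying them would not
change what the held-out test measures, at several hundred times the
cost. The acceptance run uses 30 mixtures at $10^6$ read pairs and 60%
purity; per-type correlations with truth exceed 0.95 on the default
fixture.

## Scores

The lymphocyte fraction sums B, NK, CD4, CD8 and Treg fractions. The
deconvolution-based immunoscore dichotomizes CD3 (= CD8 + CD4 + Treg)
and CD8 fractions at their medians across patients (per cancer type
when a grouping is given): `Hi-Hi` means both strictly above, `Lo-Lo`
both at or below. The TB score does the same with B and CD8 fractions.
Samples in mixed states are labelled `unclassified` and are meant to be
excluded from two-group survival comparisons; survival fitting itself
is left to the standard survival packages.

## Numerical choices and limitations

* Solver optimality tolerance is driven by machine epsilon in the
  active-set steps; tiny negative fractions are clipped to zero and
  sums marginally above one renormalized.
* `Other` is clipped at zero against roundoff.
* Problem sizes in tests and the acceptance script (200 solver
  instances, 100 recovery mixtures, 30 leave-K-out mixtures, 20-sample
  closure runs) were chosen as the smallest sizes at which the
  measured quantities are stable across seeds.
* The restricted-expression and quantization searches are exhaustive
  and deterministic; both are quadratic in the library count per gene,
  which is negligible at compendium scale (tens of libraries).
* Absolute fractions depend on the mRNA scaling factors; with the
  shipped synthetic defaults the corrected fractions are only
  illustrative. This is the main gap between the package as tested and
  a production analysis on real cohorts.
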