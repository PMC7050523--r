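---
title: "Models and methods behind tnxpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnxpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnxpress)
```

# The screen this package analyses

Transposon directed insertion-site sequencing (TraDIS/Tn-seq) saturates a
bacterial genome with transposon insertions — ideally one unique insertion
site every few bp — and sequences the transposon–genome junctions of the
pooled mutant library before and after growth under a stress. Genes whose
mutants die out under stress are conditionally important; genes that
tolerate no insertions at all are essential. When the transposon carries an
*outward-facing inducible promoter*, an insertion next to a gene does more
than disrupt its neighbourhood: depending on its orientation it can drive
the gene up (promoter pointing into the gene from the upstream side) or
knock it down through an interfering antisense transcript (promoter
pointing backwards across the gene from the downstream side). Orientation
of each insertion is therefore information, and the package keeps two read
channels per base throughout: *forward* (outward promoter transcribing in
increasing-coordinate direction) and *reverse*. Read mapping orientation is
used as the proxy for promoter orientation; this convention is stated here
once because plot files themselves do not record it.

# Data model

A replicon is represented as an `InsertionProfile`: two integer vectors,
one entry per base, holding forward- and reverse-channel junction read
counts. Genes are a `GRanges` with a `gene_id` column (GFF3 in and out via
rtracklayer, so coordinate conventions are handled by the container).
Per-sample counts over gene regions live in a `RegionCountTable`, a
`SummarizedExperiment` whose rows are (gene, region, channel) triples and
whose assays are junction *reads* (the modelled quantity) and unique
*sites* (reported only).

Each gene contributes three regions: the gene body and flanking windows of
at most 198 bp upstream and downstream. Windows are clamped at replicon
ends and strand-flipped for minus-strand genes, so "upstream" always means
the promoter-proximal side of the gene itself. The 198 bp width matches
the window used by established screens of this design and is exposed as a
parameter (`window`).

# Essentiality from the bimodal insertion index

The insertion index of a gene is its count of unique interior insertion
sites divided by gene length (sites/bp). Across genes this distribution is
bimodal: an essential mode at (near-)zero and a permissive bulk around the
library's site density. `fitBimodal()` fits, by EM, the mixture

$$f(x) = w\,\lambda_e e^{-\lambda_e x} + (1-w)\,\mathrm{Gamma}(x; k, \theta),$$

with an exponential essential component and a gamma non-essential
component. Numerical choices that matter:

* **Zero floor.** Indices of exactly 0 are floored at `1e-6` before
  fitting so both densities stay finite; a floored zero still sits far
  below any permissive index, so classification of true zeros is
  unambiguous.
* **Identifiability constraint.** The essential component's mean is capped
  at one fifth of the overall mean index. Without it, on genuinely
  unimodal data the exponential drifts into the gamma's left flank and
  retains weight; with it, unimodal data collapses to a negligible
  essential weight, which the fit reports as a `unimodal` flag
  (threshold `w <= 0.02`). Real saturating libraries place the essential
  mode orders of magnitude below the bulk, so the constraint is inactive
  whenever a genuine essential mode exists.
* **Deterministic initialization.** EM runs from a fixed grid of
  split-point initializations (5th/10th/20th/35th percentiles) and keeps
  the highest-likelihood fit; the result depends only on the data.
* **Short genes.** Genes under 100 bp have noisy indices; they are
  excluded from fitting but still classified.

`classifyEssentiality()` scores each gene by the log-odds of non-essential
versus essential component density at its index and applies a symmetric
cut (default 2, about $e^2$:1 odds): below $-2$ essential, above $+2$
non-essential, ambiguous between. Log-odds are monotone in the index for
any sensible fit, so the three classes are ordered along the index axis.

# Comparative analysis

For each (gene, region, channel) row the package asks whether insertion
abundance changed between condition and control:

1. **Equalization.** Each sample's counts are scaled by (geometric-mean
   library size) / (its library size), then summed within group and
   rounded. A group of $n$ equalized replicates with per-replicate mean
   $\mu$ and dispersion $\phi$ is modelled as NB with mean $n\mu$ and
   dispersion $\phi/n$.
2. **Conditional exact test.** Conditioning on the row total $t$, the
   split between groups follows a beta-binomial with parameters
   $n_A/\phi$ and $n_B/\phi$ (binomial with $p = n_A/(n_A+n_B)$ in the
   Poisson limit $\phi = 0$). The two-sided p-value sums the
   probabilities of all splits as or less probable than the observed one;
   ties are admitted within a relative tolerance of `1e-8` to guard
   floating-point equality.
3. **Dispersion.** A single common $\phi$ is estimated by conditional
   maximum likelihood on the *within-group* replicate splits: given a
   row's within-group total, the split among replicates is a symmetric
   Dirichlet-multinomial with per-replicate size $1/\phi$, free of both
   the row mean and any treatment effect. This matters in practice:
   selection reshapes library composition and enriches true targets, and
   an estimator that conditions on the between-group split absorbs those
   effects into $\phi$ and destroys power. Only the combined-channel rows
   enter the estimate (forward and reverse rows duplicate their
   information). Unreplicated designs fall back to between-group
   conditioning, valid only when most rows are non-differential, and say
   so. The estimate returns 0 at the Poisson boundary; when fewer than
   two usable rows exist a configurable default (0.1) is used with a
   warning.
4. **Effect sizes and filters.** `logFC` is the log2 ratio of
   prior-augmented equalized group sums (prior 0.5, so zeros stay
   finite; with unequal replicate numbers this simple form is biased and
   balanced designs are recommended). `logCPM` is the mean over samples
   of `log2((count + prior)/(libsize + 2 prior) * 1e6)`. BH adjustment
   runs jointly across all rows of one comparison — one family per
   condition-vs-control, nine rows per gene. A row is significant when
   `q <= 0.05`, `|logFC| >= 1` and `logCPM > 8` (all three exposed as
   parameters; the defaults are the established cut-offs for this screen
   design).

# From signals to biology

`classifyEffects()` translates significant rows into calls, after mapping
the reference-oriented channels to gene-relative orientation via strand:

* gene body (combined channel) enriched → `inactivation_advantage`;
  depleted → `inactivation_cost`;
* upstream window, toward-gene channel enriched and *not mirrored* in the
  opposite channel → `increased_expression_advantage`;
* downstream window, antisense channel enriched →
  `decreased_expression_advantage`;
* any other significant row → `unclassified`, with the rows attached.

"Not mirrored" is operationalized as: the opposite upstream channel is
non-significant, or its logFC is below half the signal channel's. The
rules are strand-equivariant by construction: mirroring the genome
(reversing coordinates, swapping channels and strands) permutes rows but
leaves every call invariant, and the test suite asserts exact set
equality under that transformation.

`buildMatrix()` and `buildNetwork()` aggregate conditions: a gene x
condition matrix of strongest significant logFC (0 elsewhere, rows ordered
by call count then name — deterministic without clustering), and a
bipartite gene–condition graph exported as GraphML and edge-list TSV.

# The simulator and what passing tests mean

`simulateLibrary()` emulates the screen at desk scale. Defaults are the
study conditions used throughout the tests: a 60 kb replicon, 300
non-overlapping genes (one per 200 bp slot, lengths 100–140 bp), 10%
essential, one unique site per 6 permissive bp, mean 10 reads per site,
NB dispersion 0.1. Site read counts are drawn as a *shifted* NB,
$1 + \mathrm{NB}(\mu - 1, \phi)$: every existing site has at least one
read and the mean is exactly $\mu$, which keeps the degenerate limits and
the expected-scaling checks exact. The site pool is fixed at library
creation — one biological pool split across conditions — and
`applyCondition()` only re-draws abundances: untouched sites with the
shifted NB at unchanged mean, selection-touched sites with an unshifted NB
at scaled mean (so a multiplier of 0 is lethal and yields zero reads).
Effects scale exactly the positions and channel their kind designates,
using the same 198 bp window constant as the analysis so recovery tests
are exact.

The simulator reproduces the features the analysis relies on — orientation
balance, essential-gene zero interiors, NB read noise, orientation-biased
flanking effects, selection-driven composition shift — and deliberately
omits sequence-level realism: no read errors, no insertion-site sequence
bias, no chromosomal position effects, no operon structure (so polar
effects on neighbours are absent), and gene spacing is more regular than
in a real genome, where flanking windows routinely overlap neighbouring
genes. Passing recovery tests therefore demonstrates that the statistics
recover designed signals under the stated noise model, not that every
biological confounder of a real library is handled.

Problem sizes in the shipped tests and the acceptance script (300 genes,
two replicates per group, 10,000-row null calibrations, exact-test
enumeration to totals of 200) were chosen as the smallest scales at which
the binomial/NB expectations used by the oracles are tight.

# Growth-curve fitness scoring

`iauc()` integrates, by trapezoid, the optical density above the curve's
own first reading, clamped at zero. Self-baselining to the first reading
of the same well (rather than a blank) removes inoculum differences; the
clamp prevents evaporation dips from contributing negative area. The
fitness ratio of a strain on a plate is iAUC at the treated concentration
(default 0.125 mg/L) over the mean iAUC at the references (0 and
0.015 mg/L), clamped to [0, 1] and flagged when clamping occurred or the
references were flat. `shiftRatios()` adds the smallest nonzero ratio of
the data set to every value so downstream beta-family models see strictly
positive responses; hierarchical modelling itself is out of scope — the
package emits the shifted table ready for it, plus a descriptive
per-strain comparison against the parent (difference in mean ratio,
flagged beyond 20% of the parent mean).

# Reproducibility

All randomness in the simulator flows through explicit seeds; the
analysis itself is deterministic. `runPipeline()` validates inputs before
any stage runs, stages outputs in a temporary directory, and stamps every
TSV with the package version, a hash of the analysis parameters (the
output location is excluded, so runs into different directories remain
byte-identical), and the seed.

# Known limitations

* The exact test enumerates all splits of a row total, O(t) per row;
  totals in the multi-million range would warrant a saddlepoint or
  mid-p shortcut that is not implemented.
* The common dispersion is a single screen-wide value; tagwise or trended
  dispersion, and GLM designs with covariates, are out of scope.
* `logFC` on group sums is biased for unbalanced replicate numbers.
* Effect classification is per gene; polar effects across operons are not
  propagated.
* The essentiality mixture is a declared, simulation-validated
  realization; thresholds of other toolchains will not be reproduced
  numerically.

```{r example, eval = FALSE}
# a complete desk-scale run
eff <- data.frame(condition = "drug",
                  gene_id = c("gene0010", "gene0020", "gene0030"),
                  effect_kind = c("knockout_fitness", "upstream_promoter",
                                  "downstream_antisense"),
                  multiplier = 8)
sim <- simulateLibrary(simConfig(seed = 1), effects = eff)
profiles <- list(c1 = applyCondition(sim, "control", 11),
                 c2 = applyCondition(sim, "control", 12),
                 d1 = applyCondition(sim, "drug", 21),
                 d2 = applyCondition(sim, "drug", 22))
rct <- regionCountTable(profiles, sim$genes)
rec <- compareCondition(rct, c("c1", "c2"), c("d1", "d2"))
classifyEffects(rec, sim$genes, "drug")
```
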