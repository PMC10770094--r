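---
title: "Models and methods: context methylomes and multiplicative epistasis"
author: "methylepi authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: context methylomes and multiplicative epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylepi)
```

## Scope

`methylepi` quantifies how a DNA replication defect modifies the phenotype
and the methylome of a DNA-maintenance-methylation mutant. It has two
scientific cores: a **multiplicative genetic-interaction model** applied to
per-animal phenotype measurements, and a **context-resolved methylome
summarization** (CG, CHG, CHH) with site filters, union/intersection
statistics, a restoration metric for double mutants, and a transparent
DMR caller. A synthetic-data module supplies genotype-structured inputs
with known ground truth, so every downstream claim the test suite makes is
a parameter-recovery statement.

## The multiplicative interaction model

Per fish, the thymopoietic index is the area of the rag1 in-situ signal
divided by the area of the gh (growth hormone, hypophysis) signal; gh acts
as an internal control for staining efficiency and tissue specificity, so
the index is dimensionless. Fish whose control channel fails
(`gh_area <= 0`) are excluded with a warning rather than imputed.

Fitness `W` of a genotype is the mean of its per-fish metric values after
dividing by the wild-type mean, so `W_wt = 1` by construction and `delta`
is the sample standard deviation of the normalized values. Under the
multiplicative null, the expected double-mutant fitness is
`E = W_x * W_y`, and the interaction score is `I = log2(W_xy / E)`:
positive `I` is alleviating (less severe than expected), negative is
synthetic.

The propagated error of `E` uses first-order propagation for a product,

```
epsilon = W_x * W_y * sqrt((delta_x / W_x)^2 + (delta_y / W_y)^2)
```

A published variant of this formula raises the bracketed sum to the power
−2 instead of 1/2; evaluated literally that maps relative errors of
20–40 % to propagated errors of ~25 on a fitness scale of 1, which cannot
be a standard deviation. We treat the exponent as a typographical error
for the square root and default to the standard rule, but keep the
literal expression behind `mode = "as_printed"` so the computation can be
audited either way.

No significance procedure coupling observed and expected fitness is
prescribed by the model itself; the design was open. We adopt a z test,

```
z = (W_xy - E) / sqrt(delta_xy^2 / n_xy + epsilon^2)
```

which charges the comparison with both the double mutant's standard error
and the (much larger) propagated uncertainty of the expectation. This is
deliberately conservative: with default noise the propagated term
dominates and the null is retained essentially always, which matches the
intuition that a claim of epistasis should survive the uncertainty of the
single-mutant estimates. Calls at `alpha = 0.05`: `alleviating` if
`p <= alpha` and `I > 0`, `synthetic` if `p <= alpha` and `I < 0`, else
`non_interacting`. Multi-pair screens are reported per pair without
cross-pair multiplicity correction; users can apply `p.adjust` on the
returned p-values when they prefer family-wise control.

## Context classification and filters

Contexts are read on the cytosine's own strand: `CG*`, `CHG`, `CHH` with
H one of A/C/T; minus-strand cytosines are read leftward on the reverse
complement. Windows containing N, or truncated by a sequence edge, yield
no context — a conservative choice that simply removes such sites from
analysis. Symmetric CG pairs are destranded by summing counts onto the
forward-strand C of the dinucleotide (`[c, c+2)`), the usual
merge-context convention; the operation is idempotent and
count-conserving. CHG sites, though partially palindromic, are **not**
merged: per-strand CHG records are what extraction emits, and the
per-strand counts are what the summaries tally. Hemimethylation is
invisible at this level: a merged CG record cannot distinguish a
hemimethylated from a fully methylated site.

Site filters mirror a conventional extraction setup: depth >= 4,
illegitimate-base (SNP) allelic fraction < 0.25 with the denominator
being all reads at the site, and exclusion of ratio-0 sites before
building pooled ratio matrices (otherwise the huge mass of never-
methylated non-CG sites dominates every distribution). An optional
high-stringency filter removes sites below 25 % methylation; we
implement it as exclusion of the low-ratio band (keep ratio >= 0.25),
the reading consistent with removing fixed-value artefacts between 0 and
25 %. The alternative reading (retain only sites *below* 25 %) can be
emulated by filtering on the returned ratios.

Two set conventions coexist deliberately: **site counts** use the union
of replicates per condition (a site methylated in any replicate counts),
while **ratio statistics** use the intersection across all replicates of
all conditions (only jointly assayable sites enter the pooled matrix).
Counts are reported normalized so the wild type is exactly 100. The
m.a.d. uses the 1.4826 normal-consistency constant (the statistical
environment's default); `mad_constant = 1` gives the raw value. The
even-length median is the mean of the two middle values.

## Restoration fraction

For a double mutant, `restoration_fraction(m_wt, m_single, m_double)`
returns `(m_double - m_single) / (m_wt - m_single)`: 0 means the double
mutant is as affected as the single, 1 means fully restored to wild
type, and values above 1 indicate over-restoration, which genuinely
occurs at CHH where the replication-mutant gain pushes doubles above
wild type. The statistic is invariant under affine transformations of
the ratio scale, so it does not matter whether it is computed on ratios
or percentages. Whether published restoration claims were computed on
exactly this intersected-site operationalization is not documented
anywhere we know of; this formula is our explicit, tested definition.

## DMR caller

The caller is deliberately **not** a reimplementation of any published
segmentation tool; it is a transparent procedure honoring the same
parameter semantics (`max_dist = 300`, `min_cpgs = 10`,
`min_coverage = 5`, `min_meth_diff = 0.1`, `fdr = 0.1`):

1. restrict to CG sites with depth >= `min_coverage` in **every** sample
   of both groups (intersection semantics, ratio-0 sites retained);
2. partition sites into maximal runs with consecutive gaps
   <= `max_dist`, dropping runs below `min_cpgs`;
3. recursively segment each run on the per-site mean difference: emit a
   block whole when `|mean difference| >= min_meth_diff`, otherwise
   split at the maximal CUSUM contrast (leftmost on ties, never leaving
   fewer than `min_cpgs` sites on a side) and recurse;
4. per candidate, a two-sided Mann–Whitney U test on the pooled per-site
   ratios of the two groups, Benjamini–Hochberg correction across
   candidates (the threshold is named FDR, hence BH and not Bonferroni),
   retaining `q <= fdr`.

The emit-when-qualifying rule means a strongly differential run flanked
by nulls can carry a short null shoulder when the enclosing block still
clears the effect-size threshold; the suite therefore tests exact
recovery on instances whose null flanks are wide enough to dilute any
shoulder-extended window, and tests soundness (every emitted region
re-verified against the planted differences) on irregular instances.
Counts of DMRs on real data depend on the original deposited data and
tool internals and are out of scope here.

## The synthetic generator

The generator is the package's study-conditions statement, not a tuning
knob. Wild-type sites are methylated with context-specific probability
(`0.80` for CG — vertebrate genomes are heavily CG-methylated — and
`0.05` for CHG/CHH, which are rare) and methylated sites draw ratios
from a Beta centred on `mu` (`0.80` CG, `0.25` non-CG) with
concentration 20, giving broad unimodal violins. The
maintenance-methylase mutant scales all ratios by `hypo_factor = 0.5`
(global hypomethylation) and additionally loses methylated CHG/CHH
sites with probability 0.5/0.3 — the direction, not magnitude, of
non-CG site loss is the constraint, since no quantitative site-loss
rates are published. The replication mutant scales ratios by 1.15
(capped at 1) and gains non-CG sites with small probabilities; the
double mutant restores a fraction `rho = 0.75` of the hypomethylation
(the headline three-quarters restoration) and then applies the CHH gain
step, so doubles can exceed wild type at CHH. Observed data add
Poisson coverage (zero-depth sites are emitted on purpose to exercise
the depth filter), binomial bisulfite counts with conversion-error
mixing, and binomial illegitimate-base counts at a 1 % site subset.
Each (genotype, replicate) pair owns an RNG stream derived from the
seed, so adding replicates never perturbs existing ones, and identical
configurations are bit-identical.

Latent ratios are stored next to observed counts because the package's
acceptance story is parameter recovery: recovering `rho`, the true
interaction `epsilon`, and DMR directionality from the generator's
ground truth. What passing these tests does **not** show: fidelity to
real bisulfite data's spatial autocorrelation of methylation, batch
effects, CNVs, alignment artefacts, or read-level errors — the
generator works at site level by design.

The phenotype generator draws the control area from a truncated normal
(mean 100, sd 15 area units), multiplies by `index_scale = 0.8`, the
genotype fitness (`W_xy = W_x W_y 2^epsilon_true`) and lognormal noise
with coefficient of variation 0.2 — the scale of variability visible in
per-fish index scatter plots. Defaults `W_x = 0.4`, `W_y = 0.2`,
`epsilon_true = 1` describe a severely lymphopenic pair with strong
alleviation; eye-size parameters describe a replication mutant with a
smaller eye cup and mild alleviation.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere internally (bedGraph
  convention); merged CG records span 2 bp.
- Ratios are computed from counts only; the bedGraph percent column is
  written rounded for compatibility but never read back into analysis.
- TSS profile bins are half-open `[a, a + bin)` over `[-3000, +3000)`
  by default; minus-strand genes are mirrored before binning; a site at
  distance 0 falls in the first downstream bin; empty bins report
  `n = 0` with an undefined mean.
- Degenerate interaction inputs (zero variance and zero propagated
  error) get an exact-equality p-value (1 if observed equals expected,
  0 otherwise) and a `degenerate` flag instead of a 0/0.
- CUSUM ties split at the leftmost index, making segmentation
  deterministic; swapping groups negates differences and preserves
  regions exactly.
- Filters reject rather than coerce: malformed bedGraph rows fail with
  file and line, unknown configuration keys fail before any
  computation.

## Problem sizes used by the test suite

The suite and the acceptance script regenerate all inputs at run time:
a ~50,000-site methylome at coverage 50 for restoration recovery
(`rho` recovered within ±0.05), 200 phenotype simulations per condition
at 30 fish/genotype for score recovery (mean `I` within ±0.1 of the
truth for `epsilon_true` in {−1, 0, +1}) and type-I control (>= 90 %
non-interacting calls under the null), an 8-chromosome hypomethylation
scenario for DMR directionality (>= 90 % negative differences), and
10^4-record instances for the brute-force filter/intersection oracles.
These sizes make the full suite run in well under a minute while
keeping Monte-Carlo error far below every tolerance tested.

## Known limitations

- CHG destranding is not offered; only CG pairs merge.
- The DMR caller's statistic is a pooled-site rank test, not a
  spatially aware two-dimensional statistic; very long blocks with
  compensating sub-signals can mask short DMRs below the block mean.
- The interaction z test treats the propagated error as independent of
  the double-mutant estimate; fish measured in the same clutch violate
  independence in ways the model does not represent.
- Eye-size analyses reuse the thymopoietic machinery with a different
  column; no allometric normalization is attempted.

## A worked example

```{r example}
cfg <- synthetic_config(seed = 3, genome_length = 5000, coverage_mean = 20)
ref <- generate_reference(cfg)
sim <- simulate_methylome_set(cfg, ref)
summ <- summarize_contexts(sim$methylomes, reference = "wt")
summ[summ$context == "CG", c("genotype", "normalized_count", "mean_ratio")]

m <- setNames(summ$mean_ratio[summ$context == "CG"],
              summ$genotype[summ$context == "CG"])
restoration_fraction(m[["wt"]], m[["dnmt1"]], m[["double"]])

ph <- simulate_phenotypes(phenotype_config(seed = 2))
interaction_analysis(ph)
```
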