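---
title: "Discovering mutually exclusive aberration modules: model and design notes"
author: "rmemod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering mutually exclusive aberration modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmemod)
```

## The pattern and the data

The input is a binary aberration matrix $X$ with $k$ tumor samples in rows
and genes in columns; $x_{ij} = 1$ records any qualifying somatic event of
gene $j$ in sample $i$ — a validated non-synonymous point mutation or a
gene-level copy-number alteration, with the direction of the copy-number
change deliberately not encoded. Two descriptive statistics characterise a
gene set $M$ of size $m$:

* **coverage** — the fraction of samples with at least one aberration in $M$;
* **exclusivity** — among covered samples, the fraction with exactly one.

A recurrent, mutually exclusive (RME) module has high values of both: one hit
per tumor is common, two are rare, the signature of genes whose disruption is
functionally interchangeable. The discovery pipeline in `rme()` /
`run_discovery()` has four stages — recurrence filter, Winnow exclusivity
network, exhaustive connected-subgraph search, and a compression-based
significance test — each described below with the choices we had to make and
why.

## Recurrence filter

Genes altered in fewer than `min_recurrence` of samples (default 10%,
inclusive comparison on frequencies) are removed before network construction:
with one or two aberrations there is no meaningful exclusivity signal, only
noise for the learner. The pre-filter gene count $n$ is carried along
(attribute `n_total`) because the significance test must pay for naming the
module genes out of the *full* universe searched, not the filtered one.

## Winnow exclusivity network

A dense all-pairs exclusivity network (the ratio of exactly-one to
at-least-one samples, available as `pairwise_exclusivity()` for diagnostics)
is too densely connected to search. Instead each gene serves once as the
classifier in two complementary runs of Winnow2, a mistake-driven online
linear-threshold learner that is robust to many irrelevant attributes:

* run 1: features are the *complemented* columns of all other genes, the
  label is the classifier's status — an aberration should predict
  non-aberration elsewhere;
* run 2: features are the original columns, the label is the complement of
  the classifier's status.

The directed weight $w(g \to j)$ is the arithmetic mean of the two runs'
final weights for $j$ (symmetric in the runs and scale-stable). Training
parameters — promotion/demotion factor $\alpha = 2$, threshold $\theta$ at
half the feature count, 10 epochs, samples visited in input order — are
standard Winnow2 settings chosen for determinism; all are exposed in
`winnow_config()` and the planted-pair recovery property in the test suite is
the guard that they work at cohort scale (the pair's edge survives pruning in
at least 95% of seeded 145 × 50 simulations).

Because each classifier's weight scale depends on how fast it converges, no
absolute cutoff is used: each classifier retains outgoing edges with weight
at least its second-highest outgoing weight (ties included). An undirected
edge survives when either endpoint retained it, with the maximum retained
weight — the union preserves signal found from one direction only.

## Search

Every gene seeds an exhaustive enumeration of the connected subgraphs of the
pruned graph up to `max_module_size` (default 5, inclusive). Internally the
pipeline enumerates each connected set exactly once by anchoring it at its
smallest vertex and growing only with larger-id neighbours; the per-seed view
is exported as `enumerate_connected()`. Duplicate sets reached from several
seeds are collapsed before scoring.

## Algorithmic significance

Whether a candidate's pattern is surprising is decided by a minimum
description length argument: encode the module submatrix with an encoder that
*believes* in the RME pattern and with a null encoder, and count the bits
saved. The null encoder assumes every cell is an independent Bernoulli draw
at the background rate $p_{null}$ — total aberrations over total cells,
estimated on the matrix *before* the recurrence filter (equivalently, mean
aberrant genes per sample divided by the gene universe; the filtered matrix
is several-fold denser and would destroy the contrast the test measures).
`d_score()` accepts an explicit `p_null` override.

The RME encoder first sorts samples and genes by their aberration counts
and then scans the submatrix row by row, left to right. For each cell it
computes the probability of a 1 by a posterior that expects one aberration
per sample: if the row has already shown a 1, or the gene or the sample has
no unobserved aberrations left, the probability collapses to a floor
$\varepsilon$; otherwise the expected single aberration lands on gene $j$
with probability proportional to $j$'s remaining count among the row's
unobserved cells, clamped into $[\varepsilon, 1-\varepsilon]$. The floor
defaults to $1/(10\,k\,m)$ — small enough to be "very low", scaled to the
submatrix so that penalties stay finite and comparable across sizes. Each
cell contributes $\log_2 P_{RME}(x)/P_{null}(x)$ to the gain $d'$.

From $d'$ the description costs are subtracted:

$$d = d' - m\log_2 n - k\log^*(m) - m\log^*(k) - \text{sort bits},$$

where $\log^*$ is the iterated-logarithm universal code length
($\log_2 c + \log_2 x + \log_2\log_2 x + \dots$ over the positive terms, with
the standard constant $c = 2.865064$). The $m\log_2 n$ term pays for naming
the module genes out of all $n$ assayed — an implicit multiple-testing
correction — and the $\log^*$ terms for transmitting the per-sample and
per-gene counts. Module significance is $2^{-d}$, capped at 1 when
$d \le 0$ since a code that saves nothing is no evidence. The default
reporting threshold $d \ge 50$ ($2^{-50} \approx 8.9\times10^{-16}$) is
appropriate at cohort scale; a sensible threshold grows with the input size.

**Sorted-order accounting.** Three conventions are implemented
(`sort_penalty_mode`). The default, `"counts"`, charges zero extra bits: the
per-sample and per-gene counts are already transmitted and the tie-break is
deterministic, so the decoder reconstructs the sorted order from information
it has. `"tie_groups"` charges $\sum \log_2(\text{group size}!)$ over groups
of equal counts — the cost of recovering the original within-tie order — and
`"full_permutation"` charges $\log_2 k! + \log_2 m!$. The cheap default is
not merely a convenience: a full-coverage, fully exclusive module has *all*
row counts equal, so a within-tie charge of $\log_2 k!$ (837 bits at
$k = 145$) would exceed the entire gain of a perfect module and no module
could ever reach the reporting threshold; under the zero-cost convention the
test behaves as the threshold semantics require. The other two modes are
kept for sensitivity analysis.

**Canonical sorting.** Rows are ordered by decreasing count, columns by
decreasing count; ties are resolved by content (count-weighted signatures,
then full bit patterns, choosing the lexicographically extremal matrix among
admissible column orders). The result — and therefore $d$ — depends only on
the matrix content, never on the input ordering of samples or genes.

**Calibration.** The test inherits the universal-coding guarantee: for any
null distribution matched by the null encoder, $P(d \ge d_0) \le 2^{-d_0}$.
The suite verifies this empirically on 10,000 null 100 × 3 matrices at the
background rate; in practice penalties dominate on null data and $d$ stays
far below zero.

## Selection

Candidates at or above the threshold are binned by size; repeatedly the
largest bin's highest-d candidate is emitted (ties broken by
lexicographically smallest gene list, purely for determinism) and every
remaining candidate sharing a gene with it is discarded. Larger modules are
preferred deliberately: a strong pair inside a significant triple is treated
as partial evidence for the triple, not as a rival. The pre-selection
thresholded candidate list is kept on the fitted object (`$scored`) because
nested candidates carry information the disjoint report collapses.

## Baseline statistics

For comparison, `likelihood_ratio()` computes $f_{12}/(f_1 f_2)$ — the
empirical co-mutation frequency against independence, where 0 is "maximal"
exclusivity no matter how few mutations are involved — and
`hypergeom_exclusivity_p()` the probability of at most the observed overlap
when the two genes' sample sets are placed at random.
`permutation_correction()` builds null matrices by permuting each gene column
independently (preserving per-gene frequencies, breaking inter-gene
dependence). Two corrections are available: the default `"per_pair"`
(fraction of permutations in which the same pair is at least as extreme) and
`"max"` (family-wise, against the best statistic over all pairs per
permutation). The family-wise variant is kept for completeness but is
uninformative for the likelihood ratio, whose best permuted value is 0
whenever any permuted pair happens to be disjoint — which at cohort scale is
essentially always.

## Synthetic data and benchmark

`sample_background()` assigns each gene a target frequency and fills columns
with independent Bernoulli draws. Two frequency models:

* `binned_empirical` (default) summarises a source frequency distribution
  into bins — 1%-wide up to 10%, 5%-wide above, reflecting the heavy
  low-frequency skew of real panels — and draws new frequencies within the
  source's range per bin. The packaged source
  (`synthetic_gbm_frequencies()`) is a *synthetic* stand-in for a
  glioblastoma cohort's empirical distribution: 1290 gene frequencies as
  counts out of 145 samples, about 20 genes above the 10% recurrence level,
  averaging 13.38 aberrant genes per sample. Any user matrix's `colMeans`
  can be supplied instead.
* `large_panel` models future wide panels: 0.1% of genes above frequency
  0.2 (uniform in (0.2, 0.3]), 0.9% in (0.1, 0.2], 99% below 0.1 (uniform
  down to $1/k$).

`plant_module()` replaces the chosen gene columns entirely and assigns each
covered sample exactly one module gene, so planted exclusivity is exactly 1
and coverage exactly $\lceil c\,k\rceil / k$; per-gene counts are drawn
uniformly over the compositions that respect the recurrence floor (a
stars-and-bars draw — the exact uniform distribution, with no rejection
step). Replacing rather than overlaying is the literal reading of 100%
exclusivity.

What the generator does *not* emulate: co-occurring (non-exclusive) modules,
subclonal structure, per-sample mutation-rate covariates, segmentation noise
in copy-number calls, or correlated passenger events. Passing benchmarks on
this generator therefore shows the method detects clean RME signal against
independent background at realistic frequencies — not that it is robust to
every artefact of real cohorts.

`run_benchmark()` simulates, runs a detector, and scores:

* **sensitivity** — the planted gene set itself attains $d \ge$ threshold
  among the evaluated candidates ("detected above the significance
  threshold");
* **precision** — in the final disjoint report, the module carrying the
  planted genes is strictly the most significant. Around a strong planted
  module, nested candidates also clear the threshold (a high-coverage subset
  pair of a planted triple can outscore the triple, because the
  $k\log^*(m)$ penalty grows faster with $m$ than a low-frequency third
  gene's contribution; a planted pair's superset with one passenger attached
  can also pass), and the size-binned selection is what resolves them — so
  precision is judged on which surviving module the planted genes ended up
  in.

For the baseline detectors, detection requires per-pair corrected
significance ≤ 0.05 and precision requires the planted pair's *raw*
statistic to be strictly more extreme than every other pair's — the
statistic is the method's significance measure, and its saturation at 0 (any
chance-disjoint pair ties a perfectly exclusive planted pair) is precisely
the likelihood ratio's documented failure mode. The hypergeometric p of a
high-coverage planted pair, by contrast, is essentially unbeatable by
chance, so its precision under this reading stays high.

## Problem sizes and determinism

The shipped checks use 100 simulation runs for the 3-gene discovery
benchmark, 50 runs for the three-method comparison with 200 permutations per
correction, and 10,000 draws for the null calibration — sizes chosen to make
the binomial noise on the reported rates a few percent while keeping the
default check run comfortably interactive. Everything downstream of a seed
is deterministic: simulation functions take explicit seeds and restore the
caller's RNG state, discovery itself contains no randomness, and
`run_benchmark()` derives one seed per run from `base_seed`.

## Known limitations

* The per-cell posterior is one concrete reading of the exclusivity
  assumption (the row's single expected aberration lands on a gene in
  proportion to its remaining count); it is isolated behind
  `rme_cell_probability()` so alternatives can be swapped and compared.
* $p_{null}$ is a single genome-wide rate; hypermutated samples or
  covariate-dependent rates are not modelled and inflate apparent
  exclusivity of nothing in particular — inspect coverage/exclusivity of
  reported modules, not only $d$.
* Winnow's training schedule (epochs, threshold) is not identifiable from
  first principles; the defaults are validated by recovery properties, not
  derived.
* Exhaustive connected enumeration is exponential in `max_module_size`;
  the default cap of 5 with second-highest-weight pruning keeps it trivial,
  but dense graphs with a high cap will blow up.
* Co-occurrence information is ignored by design.
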