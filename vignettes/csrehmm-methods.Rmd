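---
title: "Methods: comparative segmentation for cell type-specific regulatory elements"
author: "csrehmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative segmentation for cell type-specific regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csrehmm)
```

## The problem and the model

Chromatin-state segmentations built per epigenome describe what a region
is (promoter-like, enhancer-like, ...) but not which cell types make it
different. `csrehmm` compares epigenomes directly. Its input is, per
chromatin mark $m$, a binary $N \times T$ peak matrix over $N$ cell types
and $T$ 200-bp genome bins. Three ingestion routes produce these matrices:

* **aligned reads**: each read is extended 200 bp from its 5' end in the
  3' direction, assigned to the bin containing the extended-fragment
  midpoint, and the count track is binarized against a Poisson background
  with $\lambda$ equal to the genome-wide mean count and tail threshold
  $\alpha = 10^{-4}$ (a bin is a peak iff
  $P(X \ge c) < \alpha$ first holds at its count $c$);
* **signal tracks** (e.g. $-\log_{10} P$ from a peak caller): averaged
  length-weighted onto bins and binarized at an inclusive threshold of 2;
* **pre-called peaks** in BED, rasterized to bins by $\ge$ 1 bp overlap.

The *specificity transform* zeroes every bin column where more than $s$
cell types share a peak (default $s = 2$; configurable, e.g. $s = 5$ for
very large panels). What remains is, per bin, the small set of cell types
that differ from the rest — the comparative signal. Stacking the $M$
transformed matrices gives the $R \times T$ observation matrix
($R = MN$ cell-mark combinations). Modelling each combination with one
Bernoulli emission parameter per state keeps the parameter count at
$K R$ instead of one parameter per possible observation vector
($(\sum_{i \le s} \binom{N}{i})^M$, about $3.4 \times 10^{16}$ for
$N = 9$, $s = 2$, $M = 10$ — `observation_space_size()` evaluates this
exactly with digit-vector arithmetic).

The hidden chain runs along each chromosome independently with shared
parameters: initial distribution $\pi$, transitions $a_{ij}$, emissions
$p_{kr}$. All inference is in scaled/log space (per-column max-shifted
emission likelihoods plus per-step normalization), so sequences of
millions of bins with $R$ of order 100 do not underflow.

## Training

`em_fit()` offers two modes:

* **batch** — standard Baum-Welch: one E-step over all chromosomes, one
  M-step. This is the reference mode with the exact monotonicity
  guarantee, which the test suite asserts per iteration.
* **incremental** (default) — after each chromosome's E-step, that
  chromosome's previous sufficient-statistic contribution is replaced and
  the parameters re-estimated immediately (the Neal–Hinton incremental
  view of EM). On multi-sequence genomes this usually needs fewer sweeps;
  its "iteration" log-likelihood is the sum of the per-chromosome values
  computed during the sweep, so it is an approximation while parameters
  move. Tests treat batch mode as ground truth and check that both modes
  reach the same likelihood on well-separated data.

Numerical choices: emission sufficient statistics get a Beta-style
pseudocount of $10^{-2}$ (added to the success count, twice to the total)
and the emissions are clamped to $[10^{-6}, 1 - 10^{-6}]$, so no
probability degenerates to 0/1 and log-likelihoods stay finite. A
transition row that receives no expected mass keeps its previous value.
Convergence is declared when the relative log-likelihood change drops
below `tol` ($10^{-6}$), but only after `min_iter = 20` sweeps: on this
model EM routinely crosses a long flat stretch before states
differentiate (per-iteration gains of order $10^{-2}$ for the first few
sweeps, rising by three orders of magnitude once a state splits off), and
a bare relative-change rule stops there. The iteration cap defaults to
300, within which all configurations exercised by the tests converge.

### Initialization

Random restarts (`init_random()`: emissions uniform on $(0.1, 0.9)$,
$\pi$ and transition rows Dirichlet(1), fully seed-reproducible) are
available, but the default is a deterministic entropy-based scheme
(`init_entropy()`) so that models with different $K$ start from nested,
comparable segmentations. Starting from one cluster holding every bin, we
repeatedly split the cluster with the largest **total** binary entropy —
cluster size times the sum of per-feature entropies of its feature means,
i.e. the bits needed to encode the cluster — on its highest-entropy
feature. Weighting by cluster size matters: choosing by per-feature
entropy alone lets a tiny, noisy intersection cluster outrank the large
heterogeneous background cluster, which can leave a planted state
unsplit at small $K$ and strand EM in the corresponding local optimum (we
observed exactly this at $K = 4$ before adopting the weighted criterion).
Ties break on the lowest cluster/feature index; emissions are the cluster
feature means; $\pi$ and transitions come from the induced hard labelling
with a $10^{-2}$ smoothing count. If fewer than $K$ splittable clusters
exist, remaining states start at the global mean plus a tiny
deterministic offset.

### Decoding

Per-bin posterior decoding is the default: CSREs are defined bin-wise, so
the bin-marginal argmax is the natural labelling; Viterbi is available by
flag for users who want the single most probable path. All ties resolve
to the lowest state index, making decodes reproducible.

## Specific states and CSREs

For one state's emission row, sort decreasingly, find the largest gap
between consecutive values, and call $p_s$ the value just above it. A
combination is *specific* iff its probability is $\ge p_s$ **and**
$> p_0 = 0.3$. Boundary semantics are deliberate: $p_s$ itself is
included ("the probability above the gap"), the $p_0$ floor is strict,
and a tie among gaps takes the earliest (fewer, stronger combinations).
For a perfectly flat row every gap is 0, the gap rule degenerates to the
maximum, and the $p_0$ floor alone decides — flat low rows are
non-specific. Specific states are named by their cell types in
observation order joined with underscores plus an ordinal
(`H1_1`, `NHEK_HMEC_1`); non-specific states get the `Non` prefix.
Specificity in a whole-cell-extract control track flags copy-number or
repeat artifacts; such states are reported with a `contains_wce` flag
rather than dropped, so the user sees them.

CSREs are maximal runs of bins decoded to one specific state,
run-length-encoded per chromosome; abutting runs of different specific
states remain separate elements, and single-bin elements are kept (no
minimum length is imposed). Base pairs are conserved: the union of a
state's CSREs is exactly its decoded bins.

## Model selection and robustness

`n_parameters()` counts $(K-1) + K(K-1) + KNM$ free parameters;
`bic()`/`aic()` evaluate $\ln(\#\text{bins}) \cdot \#\text{par} - 2\ell$
and $2\#\text{par} - 2\ell$. Both typically decrease monotonically in $K$
on real-size data, so the package reports a score table and leaves the
choice of $K$ to inspection rather than auto-selecting. Robustness of a
state across refits is its *recovery score*: the maximum Pearson
correlation between its emission row and any state of another model
(constant rows contribute 0, logged). Across ten random-initialization
refits of a well-separated synthetic model, planted specific states score
higher on average than the non-specific state — the robustness property
the acceptance script quantifies as `recovery_score_gap`.

## Downstream characterization

* **Feature classes**: promoter ($\pm$ 2000 bp of the strand-aware TSS,
  inclusive interval rendered half-open) > 5'UTR > 3'UTR > exon > intron >
  intergenic; each CSRE gets the highest-priority class it overlaps by
  $\ge$ 1 bp. Transcripts without annotated CDS contribute exon/intron
  classes only. Gene models come from GTF/GFF3 or BED12 via rtracklayer,
  with an optional transcript-accession prefix filter (e.g. `NM`).
* **Proximal genes**: a gene qualifies for a state when some transcript's
  promoter-plus-body region contains a contiguous $\ge$ 3-kb stretch
  covered by that state's CSREs (any transcript suffices; the criterion
  is deliberately stringent).
* **TSS distances**: intergenic CSREs are measured edge-to-nearest-TSS,
  against per-element random controls of the same length on the same
  chromosome (seeded).
* **Peak-overlap enrichment**: the observed statistic is the number of
  CSREs overlapping $\ge$ 1 peak bp ("how many elements hit a peak", not
  bp of overlap); 1000 null sets reposition every CSRE uniformly on its
  own chromosome with length preserved. Both a one-sample Wilcoxon
  signed-rank p of (null − observed) and the empirical
  $(1 + \#\{null \ge obs\})/(n_{sim}+1)$ are reported; the empirical p is
  super-uniform under the null by construction (property-tested). The
  null counter uses sorted-boundary bisection rather than per-simulation
  interval objects, keeping 1000 resamples fast.
* **Expression specificity**: quantile normalization (rank means, ties
  averaged — via limma) then per-gene z-scores with the sample (n−1) SD;
  constant genes become zero rows. Group differences use the two-sample
  Wilcoxon test, exact when both samples are small and untied.
* **Gene sets**: one-sided Fisher exact tests per term after restricting
  to the universe and filtering terms to 5–500 genes, BH-corrected within
  each query (per state/cell type).

## The synthetic-data generator

`sim_config()`/`simulate_dataset()` define the study conditions for all
tests: $N = 4$ cell types, $M = 3$ marks, $K = 4$ states over two 5-Mb
chromosomes (50,000 bins of 200 bp). State 1 is background with peak
probability 0.05 everywhere; each other state carries planted (cell,
mark) pairs at probability 0.9 — one single-cell pair per state, plus one
two-cell state to exercise shared naming. Specific segments are geometric
with mean 5 bins ($\approx$ 1 kb, near the sub-kb median element length
typical of such maps); background segments mean 20 bins, so specific
states jointly cover about 20% of the genome. A small co-occurrence rate
(0.002) sets a mark in every cell at random bins to exercise the
specificity zeroing path. Read-level emission places
Poisson($\mu_{fg} = 50$) fragments per peak bin versus
$\mu_{bg} = 0.5$ elsewhere, with fragment centres uniform in the bin and
5' ends half an extension upstream, so the extension-midpoint rule
recovers the planted bins. Companion generators lay out toy gene models
whose bodies cover long planted CSREs, an expression matrix elevated in
the planted cells, per-cell peak files co-located with the planted
elements, and a GMT whose planted terms equal the planted proximal genes
— so every downstream operation can be validated end to end. All
generators are pure functions of (config, seed).

What the generator does *not* emulate: mappability and copy-number
artifacts, correlated marks within a state, non-geometric segment
lengths, and replicate structure. Passing tests therefore demonstrate
correctness of the algorithms under the model's own assumptions, not
performance on real epigenomes.

### What recovery can and cannot reach

With foreground peak probability 0.9, about 10% of specific bins emit no
peak for their planted pair and are indistinguishable from background at
segment edges (interior gaps are bridged by the transition prior, since
leaving and re-entering a specific state is much less likely than
staying). Decoding with the *generating* parameters themselves — the
best any method can do — therefore recovers planted CSRE base pairs at a
Jaccard of roughly 0.82 under the default conditions, and the fitted
model attains that ceiling (the acceptance tests compare the two
directly, and the acceptance script reports the fitted value as
`csre_bp_jaccard`). Planted (cell, mark) combinations, by contrast, are
recovered exactly: combination identity depends on the emission matrix,
which is estimated from tens of thousands of bins.

## Problem sizes used by the checks

The test suite and acceptance script use 50,000-bin genomes for parameter
recovery and end-to-end runs, 20,000 bins for the ten-refit robustness
experiment, 10,000 bins for pipeline round-trips, and exhaustive
enumeration oracles only where the state space is tiny ($K^T \le 3^6$ for
forward-backward, universes $\le 30$ for Fisher). These sizes were chosen
so each check runs in seconds to a few minutes on one CPU while keeping
sampling error far below the asserted tolerances.

## Known limitations

* One global $s$ per run (no per-mark caps).
* The incremental-EM sweep likelihood is approximate while parameters
  move; use batch mode when exact monotonicity matters.
* BIC/AIC are reported, not used to auto-select $K$.
* No minimum CSRE length; single-bin elements may warrant filtering
  downstream.
* Enrichment nulls preserve length and chromosome but not local GC or
  mappability structure.
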