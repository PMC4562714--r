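---
title: "Selecting and validating stable reference genes with stableref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating stable reference genes with stableref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stableref)
```

## The problem

Relative quantification by RT-qPCR normalizes a target gene's cycle
threshold (Ct) against reference genes assumed to be constant across
samples. When that assumption fails, every downstream fold change is biased.
`stableref` treats reference-gene discovery as a model-selection problem on
RNA-Seq counts: find the per-sample scale (size factors) and the subset of
genes whose scaled expression fluctuates like Gaussian noise around a common
mean, then validate shortlisted candidates on qPCR data.

## Angular-regression normalization

Each gene is a point in sample space; if a set of genes is truly stable,
their expression vectors all point along a common direction whose components
are the relative library sizes. The reference direction r maximizes the sum
of cosines between itself and the gene vectors,

$$L(\mathbf r) = \sum_i \frac{\mathbf r\cdot\mathbf v_i}{|\mathbf v_i|},
\qquad |\mathbf r| = 1 .$$

Because L is linear in r on the unit sphere, the Lagrange condition gives the
closed form $\mathbf r \propto \mathbf R$ with $R_k = \sum_i v_{ik}/|\mathbf
v_i|$ — no iteration, one global optimum (the acceptance checks verify this
against a brute-force search over a million random directions). Normalizing
each gene vector first gives every gene equal weight regardless of its
expression level, which is what distinguishes this estimator from a simple
column mean.

Only the ratios of size factors matter downstream, so their overall scale is
a convention. We fix $s_k = \sqrt m \, R_k/|\mathbf R|$, the unique scaling
under which identical libraries get $s_k = 1$ and $\sum_k s_k^2 = m$. The
raw $R_k$ and unit $r_k$ are kept on the returned object so any other
convention can be applied. All-zero gene rows carry no directional
information and are dropped from the sums with a warning rather than an
error, since real count matrices contain them.

## The two-state likelihood model

After normalization ($w_{ik} = v_{ik}/s_k$) and per-gene rescaling
($u_{ik} = w_{ik}/\bar w_i$, unit row means), all entries are pooled into
moments $\mu$ and $\sigma$ ($\mu = 1$ analytically, asserted to $10^{-9}$).
A stable gene's entries should be small-|z| draws, so the stable state is
scored by the two-sided tail probability $P = 2\Phi(-|z|)$, which is near 1
at $u = \mu$ and decays with distance; the unstable state takes the
complement. The total fit quality is
$\sum_i \log_{10} \prod_k P_{ik}$ with size factors recomputed from the
stable set — membership and normalization are estimated jointly.

Numerical choices:

* **Probability floor.** The unstable-state P is exactly 0 at $u = \mu$, so
  probabilities are clamped to $[10^{-12}, 1]$ before the log. The floor is
  a config parameter (`p_floor`); its value only matters for genes in the
  deep tail of the "wrong" state and does not affect the ranking of flips
  near the decision boundary.
* **Moment pooling.** Moments are pooled over *all* genes by default — the
  model describes the whole matrix, with unstable genes contributing to
  $\sigma$. A `pool = "stable"` switch restricts pooling to the current
  stable set; that variant concentrates $\sigma$ and can collapse to very
  small sets (a shrinking $\sigma$ rewards further shrinkage), which is why
  it is not the default.
* **Degenerate input.** A matrix whose rescaled entries are all identical
  has $\sigma = 0$ and no meaningful model; this is a hard error rather
  than a fallback.

## The two-phase search

Phase 1 (greedy elimination) starts from the all-stable model and, per
round, recomputes size factors from the current stable set and removes the
stable gene with the smallest per-gene log likelihood, recording (set size,
likelihood) down to a single gene; the best-likelihood size wins. Phase 2
(refinement) repeatedly flips the state of the gene with the smallest
per-gene log likelihood — over *all* genes, so eliminated genes can re-enter
— keeping a flip only if the total likelihood strictly increases and
stopping at the first rejected flip (`scan_all = TRUE` instead tries every
gene in ascending order before giving up). Strict increase over a finite
state space guarantees termination; both phases are deterministic, and ties
in the "smallest likelihood" choice break by input gene order (covered by a
permutation-invariance test for the no-ties case).

Greedy elimination costs $O(n^2 m)$ with vectorized per-round recomputation
(about one second at n = 500, m = 8); a `drop_fraction` accelerator can
remove the worst fraction per round for larger matrices, at the cost of a
coarser trace. On small instances (n ≤ 12) the search provably attains the
global optimum: the test suite enumerates all $2^n$ memberships on 20
planted instances and the two-phase result matches the maximum every time.

## Candidate filtering

Stability alone does not make a usable reference gene; the filter adds
distributional screening per sequencing-quality group: coefficient of
variation below a cap, and at least one of two normality tests (Shapiro-Wilk,
Kolmogorov-Smirnov) with a p-value above a floor, required in *every* group.
The shipped defaults (CoV < 0.2, p > 0.6; CoV < 0.24, p > 0.45 for the
noisier group) reproduce, on the package's bundled 19-locus evaluation
table, the published pass/fail split: 7 candidates pass, all 12
commonly-used reference-gene loci fail at least one clause. Inequalities are
strict, so boundary values fail. The KS test estimates the Gaussian's
parameters from the same data (the common statistics-package usage); this is
anti-conservative in the Lilliefors sense, and a corrected variant
(`lilliefors = TRUE`, via nortest) is available but off by default to match
standard practice. No multiple-testing correction is applied: the thresholds
are selection heuristics, not inference.

## qPCR consensus ranking

Replicate-level Ct tables are aggregated hierarchically — technical repeats
averaged within each biological replicate, then biological-replicate means
averaged — so unbalanced designs weight biological replicates equally.
Quantities are $q = E^{-\Delta Ct}$ with efficiency E = 2 by default
(configurable globally or per gene; no dilution-series estimation is
attempted). Four stability statistics are computed: comparative ΔCt (mean
pairwise SD of Ct differences), BestKeeper (Ct SD; MAD and the correlation
with the per-sample index are reported, and `bestkeeper_metric = "mad"`
switches the ranking), NormFinder in its group-free form (SD of
sample-centred log₂ quantities — the full intra/inter-group variance
decomposition is deliberately not implemented, since the consensus here is
applied to pooled samples; a `groups` argument is reserved), and geNorm
(pairwise M with stepwise exclusion; the final pair shares ranks 1–2, and
the pairwise-variation V values are reported but unused in ranking).

The consensus is the geometric mean of the four within-method ranks
(average ranks for ties, undefined statistics ranked last, residual ties
broken alphabetically); `use_values = TRUE` aggregates the raw stability
values instead, for comparison. At E = 2 the comparative-ΔCt statistic and
full-set geNorm M coincide algebraically (log₂ quantities are affine in
Ct); they are retained as separate methods because geNorm's ranking comes
from its exclusion sequence, not the initial M.

## In-silico PCR

Primer specificity is screened by scanning transcripts for the forward
primer on the sense strand and the reverse complement of the reverse primer
downstream within a product cap (5 kb default), plus the role-swapped
orientation, since published primer pairs are sometimes recorded against the
antisense strand. Matching is IUPAC-aware via bitmask intersection
(degenerate primer codes match their expansions); the default is exact
matching (`max_mismatches = 0`) because validated primers are designed as
perfect matches, with an optional mismatch budget whose 3'-terminal 3 bases
must always match exactly (mismatches there abolish extension). Coordinates
are 0-based half-open and amplicon length includes both primer footprints.
Transcript isoforms are collapsed to their parent locus (stripping the final
".n" suffix) so multi-isoform hits are not mistaken for multi-gene
targeting; a primer set is flagged when it hits multiple loci, yields
distinct product sizes, or yields no product. The scan is a naive
per-position comparison, O(total bases × primer length): transcriptome-scale
inputs complete in seconds and need no index.

## What the simulators emulate

`simulate_counts()` generates the data the model assumes: stable genes are
lognormal noise (τ_s, default 0.05) around gene mean × planted size factor;
unstable genes additionally get a signed fold effect of scale τ_u (default
0.7 on the log scale) in a random proper subset of samples — skewed,
sample-specific deviations, matching the model's view of unstable genes as
outliers. Values are continuous because nothing in the model requires
integers; `integerize` rounds them. `simulate_ct()` mirrors the validation
design: per-gene baselines in 22–30 cycles, per-sample Gaussian noise
(0.2 cycles), condition shifts of 2 cycles for unstable genes, and
2 biological × 3 technical replicates with small replicate jitter; fold
effects are multiplicative in expression and additive in Ct, keeping the two
simulators consistent (1 log₂ fold = 1 cycle at E = 2).
`simulate_transcriptome()` plants primer binding sites at known coordinates,
including multi-locus and two-size configurations and decoy primer sets, so
the isPCR engine can be checked against construction.

Defaults represent the intended study scale: 500 genes × 8 samples with 80%
stable genes for count simulations, 4 + 4 genes × 12 samples for Ct
simulations, and n ≤ 12 instances where exhaustive enumeration is the
oracle. What passing these tests does *not* show: real RNA-Seq counts are
overdispersed counts with gene-length and GC effects, isoform ambiguity and
zero inflation, none of which the lognormal generator produces (an optional
Poisson layer exists for robustness checks); real Ct data carry
plate/batch effects and efficiency differences between primers. Results on
simulated data bound what the method can do when its assumptions hold, not
its field performance.

## A small end-to-end run

```{r example}
counts <- simulate_counts(n_genes = 80, m_samples = 8, seed = 11)
fit <- select_stable_genes(counts$matrix)
summary(fit)

ct <- simulate_ct(seed = 11)
rank_stability(aggregate_replicates(ct$records))
```

## Known limitations

* The likelihood treats samples as exchangeable; systematic condition
  structure inside the "stable" set (e.g. batch effects aligned with
  groups) is absorbed into σ rather than flagged.
* The greedy-plus-refinement search is exact on small instances but carries
  no global-optimality guarantee at scale; the exhaustive oracle is only
  feasible for n ≤ ~14.
* NormFinder's grouped decomposition and per-primer efficiency estimation
  are out of scope; rankings on strongly grouped designs should be read
  accordingly.
* The in-silico PCR engine models primer annealing as (mis)match counting —
  no melting temperature or thermodynamics — and transcript templates only,
  so intron-spanning genomic products are invisible.
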