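---
title: "Methods: exact-match indexing and Bayesian fusion of variant call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact-match indexing and Bayesian fusion of variant call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varfuse)
```

# Scope

varfuse is a desk-scale toolkit for ensemble tumour variant detection. It
covers three layers:

1. **Exact-match index structures** — the Burrows–Wheeler transform (BWT),
   suffix array, suffix tree, FM-index with backward search, and a base-4
   k-mer hash index. These are the primitives behind short-read aligners;
   here they are first-class, testable objects.
2. **Ensemble fusion** — consensus voting over alignment sets produced by
   several aligners, and Bayesian evidence fusion of variant call sets
   produced by several callers, after a GATK-style hard filter.
3. **Simulation and evaluation** — generators for references, implanted
   SNP/indel truth sets, reads, and per-caller call sets, plus a
   depth-series driver measuring precision and recall of every caller and
   of the fused method.

Nothing here launches an external aligner or caller; the simulated caller
panel stands in for them, and the package evaluates the *fusion logic*, not
third-party binaries.

# Index structures

## Conventions

All orderings use `$ < A < C < G < T`, with the terminator `$` appended
exactly once. Two coordinate conventions coexist deliberately and are
converted only at module boundaries:

* **FM-index / suffix-array side: 0-based.** The worked arithmetic this
  layer reproduces (row intervals, `S[4] = 0`) is 0-based, so the API keeps
  it.
* **Hash-index side: 1-based.** Seed postings are `(sequence id, 1-based
  start)`, the natural convention for seed tables.

The occurrence table uses the prefix convention `occ(c, i)` = number of `c`
in `bwt[0 .. i-1]`, so `occ(c, 0) = 0` and one backward-search step is
`lo' = oc(c) + occ(c, lo)`, `hi' = oc(c) + occ(c, hi + 1) - 1`. This is the
convention under which all the classic worked numbers (interval (6,7) for
`C`, (3,4) for `AC`, (10,10) for `TAC` on `ACGTACAAAT$`) come out exactly.

## Construction choices

The suffix array is built by a direct radix-order sort of the enumerated
suffixes, O(n² log n) worst case. At the scales this package targets
(texts up to ~10⁵ bases; the test-suite uses up to 10³) this is faster to
verify and entirely adequate; the contract permits swapping in a
linear-time builder without any API change. The BWT is derived from the
suffix array (`bwt[i] = text[(sa[i] - 1) mod (n+1)]`) — the rotation matrix
is never materialised. The suffix tree is built by naive suffix insertion
with edge compression (no Ukkonen construction); its DFS leaf order equals
the suffix array by construction, which the tests exploit as a
cross-structure consistency check.

k-mer codes read the seed as a base-4 number with **the first character as
the most significant digit** (A=0, C=1, G=2, T=3), e.g. `TA` = 12,
`AT` = 3. Sequences may contain non-ACGT characters; seeds overlapping
them are skipped with a warning rather than failing a whole reference.
The index-side alphabet is strictly `{A,C,G,T}`: IUPAC ambiguity codes are
rejected, because the BWT/FM machinery is defined over the 4-letter
alphabet plus terminator. The seed length `k` is a free parameter
(classically 4 or 8; the CLI defaults to 8 as a convention).

# Bayesian fusion of call sets

## Model

Each candidate site carries a hypothesis pair {VARIANT, NO_VARIANT} with
prior `P(VARIANT)`. Caller `i` "fires" (reports the site) with probability
`P(B_i | A_j)` under hypothesis `A_j`; callers are conditionally
independent, so the joint evidence likelihood is the product of per-caller
terms (firing probability for a caller that fired, its complement for one
that did not). The posterior follows from Bayes' rule with the
total-probability denominator; the maximum-a-posteriori hypothesis is
selected, and a site is *accepted* iff MAP = VARIANT and its posterior
reaches the decision threshold `Po`.

Defaults, exposed as parameters:

* `prior_variant = 0.001` for the standalone model — the order of SNV
  density in a genome (variants are under 0.1 % of sites).
* `Po = 0.5` — accept whenever VARIANT is the MAP hypothesis with any
  majority of posterior mass.

## Fitting, and why the experiment uses an empirical prior

In simulation mode the likelihoods are fitted from a truth set over the
*candidate-site universe*: the union of all callers' calls plus the truth
set. `P(fire | VARIANT)` is the detected truth fraction;
`P(fire | NO_VARIANT)` is false calls over candidate non-variant sites.
The experiment driver also uses the *empirical* prior
`|truth| / |universe|` rather than the genomic 0.001: likelihoods fitted on
the candidate universe and a prior defined on the whole genome live on
different sample spaces, and mixing them systematically under-weights the
VARIANT hypothesis. Keeping both on the candidate universe makes the
posterior a coherent probability on that space.

Fitted probabilities are clamped to `[10⁻⁶, 1 − 10⁻⁶]` inside the driver
so a caller that detects everything (or nothing) cannot yield an exactly
zero joint probability; `fit_caller_profiles()` itself returns the raw
confusion fractions.

Indel representations are trimmed (shared prefix/suffix) and, when a
reference is supplied, left-aligned before merging — without this,
representation differences between callers break key-based deduplication.
The hard filter is strict (`depth > 10` and `qual > 30`), applied before
merging, matching the usual post-calling thresholds.

## Alignment-set consensus

For alignment sets, consensus is voted on the exact placement key
`(read_id, seq_id, pos)`; MAPQ and CIGAR are deliberately ignored (the
strictest testable reading of "the same sequence appears"). With `n`
sources: `n` votes accept outright; `n−1` accept (optionally gated on a
minimum MAPQ — the "frequency is quite high" qualifier is not quantified
in the field, so the gate defaults to off); `n−2` accept only when the
read sequence occurs verbatim in a trusted (PCR) panel sequence; anything
less is rejected. The verdicts partition the placements, and adding
agreement can never downgrade a verdict.

# Sparse model

The variant-incidence matrix cuts the genome into equal-length regions
(rows) and marks variant offsets with 1; at realistic densities (< 0.1 %)
this is an extremely sparse system, the regime where `min ‖x‖₀ s.t.
y = Ax` is meaningful. The solver is greedy orthogonal matching pursuit
with least-squares refits; because greedy selection alone can overshoot
the minimal support, small dictionaries (`n ≤ 25`) get an exhaustive
fallback over supports up to size 3, which makes the returned solution the
exact L0 minimiser whenever the spark uniqueness condition
`2‖x‖₀ ≤ spark(A)` holds in that range. `spark()` is an exhaustive
subset-rank search (`n ≤ 20`, returning `n + 1` when no dependent subset
exists), and the restricted-isometry constant uses the two-sided
single-constant form `(1 − μ)‖x‖² ≤ ‖Ax‖² ≤ μ‖x‖²`, so an orthonormal
frame has μ = 1 and a duplicated unit column drives μ to 2.

The scatter (divergence) statistics compute `S_b` and `S_w` first, then
`η = trace(S_b)/trace(S_w)`, then `S_t = S_b − η·S_w`. Defining `S_t`
through `η` while `η` is defined from the traces is circular if read
simultaneously; this sequential resolution is the only consistent order,
and an `eta_override` argument supports the alternative
"adjustment-parameter" reading (it is also the only way to obtain `S_t`
when `trace(S_w) = 0`, which otherwise raises a degenerate-divergence
error naming the offending class).

# The synthetic data generators

Every generator is a pure function of its parameters and one explicit
integer seed (RNG state is saved and restored around each call), so all
fixtures are reproducible and built at test time.

**Study conditions.** The simulated study design is: reference with GC
0.49 (typical tumour exome material); implanted truth sets of SNVs and
2–10 bp insertions/deletions (split ~50/50) at a 3:2 SNV:indel ratio;
single-end 75 bp reads at depths 50–300×; sequencing error rate 0 (so
reads are exact substrings, and detection performance isolates the callers
rather than the sequencer). Implanted variants are homozygous — zygosity
is not modelled. Variant anchors keep ≥ 12 bp spacing so a 10 bp deletion
can never overlap its neighbour. The scaled-down grid used throughout the
package (200 kb genome, 300 SNVs + 200 indels, depths
{50,100,150,200,250,300}, 20 seeds) preserves the variant density and the
full depth range of the full-size design at 1/10 the truth-set size — the
problem size was chosen so the whole study reruns comfortably on a laptop
while keeping binomial noise well below the effect sizes being asserted.

**Caller panel.** Four profiles named after the archetypes they emulate
(gatk, varscan2, bcftools, freebayes). Sensitivity is linear in depth
between 50× and 300× anchors and clamped outside: SNV sensitivity spans
0.78→0.94 down to 0.66→0.83 in the order gatk > varscan2 > bcftools >
freebayes, indels ~6 points lower. Two further choices matter and are the
generator's own calibration, made once:

* **False-call rates are heavy-tailed across callers** (20/30/40/120 per
  Mb at 50×). Permissive callers inflate raw call counts far beyond
  conservative ones; concentrating the false-call burden in the most
  permissive profile is what gives the fitted fusion model
  caller-identity signal — it learns to reject sites supported only by
  the permissive caller while keeping sites supported only by a strict
  one. With a flat false-call profile, a single-caller site carries no
  identity information and fusion degenerates to vote counting.
* **False calls attenuate with depth** as `min(1, 50/depth)`: stochastic
  miscalls are suppressed as pileups deepen. This is what makes
  *precision* (not just recall) genuinely improve with depth, the
  qualitative behaviour the study design emulates.

Emitted QUAL rises with depth for true calls (mean `45 + depth/10`,
sd 10) and sits lower for false ones (mean 38, sd 8); DP is Poisson at
the target depth (0.6× for false calls). Hence the strict `qual > 30`
filter removes a few true calls at 50× and almost none at 300×,
reinforcing the depth trend. False calls are 80 % SNVs / 20 % indels, so
indel precision is a non-degenerate metric.

**What the generator does *not* model** — and therefore what passing
tests do and do not show: no quality decay along the read, no indel
sequencing errors, no paired-end insert-size structure, no CNV/SV, no
mapping ambiguity (call sets are simulated from the truth, not called
from reads), no inter-caller error correlation (the independence the
fusion model assumes is true *by construction* in the simulator, so the
study validates the fusion machinery under its own assumptions, not the
robustness of those assumptions on real data).

# Evaluation

A call is a true positive iff its normalised `(chrom, pos, ref, alt)` key
exactly matches a truth record. `recall = TP/(TP+FN)`;
`precision = TP/(TP+FP)`. The benchmark-style grids this package emulates
label their headline metric "accuracy" without defining it; varfuse
reports precision in that role and says so. Undefined 0/0 ratios are
reported as `NA`, never 0. Results are reported as mean ± sd over seeds
(single-seed runs warn); depth trends are summarised by the Spearman
correlation between depth and the seed-averaged metric. Per-method trend
assertions pool the SNV and indel classes: for low-false-call callers the
per-class false-positive count is 0–3, and the sign of a precision trend
on such counts is not statistically identifiable at this scale, while the
pooled counts are.

Exact benchmark figures obtained with the real aligner/caller binaries on
real tumour accessions are out of scope by design: they depend on
third-party executables and data the package does not ship. The
reproduced surface is the qualitative one — rising precision and recall
with depth for every method, and a fused method that dominates each
individual caller's recall while never falling below the weakest caller's
precision.

# Numerical and degenerate-input policy

* Posterior computation is done in the log domain and normalised; a joint
  probability of exactly zero under both hypotheses raises a
  degenerate-evidence error rather than returning NaN.
* Posterior sums are asserted to 1 within 10⁻⁹; scatter-trace /
  eigenvalue identities within 10⁻⁹; sparse-recovery residuals use
  `max(epsilon, 10⁻¹⁰)` as the working zero.
* `spark` of a full-column-rank matrix returns `n + 1` by convention.
* Matrix ranks use QR with tolerance 10⁻⁹.
* Empty intervals, empty read sets, empty call sets and zero-variant
  truth sets all have defined behaviour (empty results or informative
  errors), exercised in the tests.

# Known limitations

* Index structures are plain (no sampled suffix array, no checkpointed
  occurrence table, no bidirectional FM-index) and exact-match only.
* The fusion model treats callers as conditionally independent; real
  callers share aligned input and error modes, so real-data posteriors
  will be overconfident.
* `spark`/`rip_constant` are exhaustive and limited to small dictionaries.
* The consensus layer never re-aligns; it only votes on placements.
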