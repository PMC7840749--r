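---
title: "Models and methods behind boranekit"
author: "boranekit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boranekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boranekit)
```

## The chemistry model

The borane-reduction sequencing family detects cytosine modifications
directly: the targeted states are converted to dihydrouracil and read as T
after PCR, while unmodified cytosine stays C. The five assays differ in
which states they convert:

| state | TAPS | TAPSβ | CAPS | PS | PS-c |
|-------|------|-------|------|----|------|
| C     | C    | C     | C    | C  | C    |
| 5mC   | **T**| **T** | C    | C  | C    |
| 5hmC  | **T**| C     | **T**| C  | C    |
| 5fC   | T    | T     | T    | **T** | C |
| 5caC  | T    | T     | T    | **T** | **T** |

Bold transitions are the states an assay is designed to read as modified
(`assay_design()`); the plain-T entries are conversions that occur but are
not the assay's target. `boranekit` models each assay as a
`chemistry_profile()`: a per-state probability that a cytosine of that state
is read as T. Conversion is a single per-state Bernoulli event per
sequenced molecule; partial-oxidation intermediates are not modelled as
separate processes.

### Default rates and how gaps were filled

The defaults in `default_profile()` are the rates measured on spike-in
controls: TAPSβ converts 5mC at 0.976 with a 0.0024 false-positive rate and
only 0.019 on (glucosyl-protected) 5hmC; CAPS converts 5hmC at 0.831 with a
0.0072 false-positive rate; PS converts 5fC/5caC at 0.768/0.938 with 0.0027
background; PS-c suppresses 5fC to 0.152 while keeping 5caC at 0.953 and
background at 0.0022; TAPS converts 5mC/5hmC at 0.965/0.891 over a 0.0023
background.

Some cells of the table have no published number and are filled by
mechanistic analogy, as package defaults rather than measured values:

* CAPS on 5mC: the ruthenate oxidant does not act on 5mC and pic-borane does
  not reduce it, so `conv[mC]` is set to the CAPS false-positive rate.
* CAPS on 5fC/5caC: borane reduces both regardless of the oxidation step,
  so the PS rates are borrowed.
* PS and PS-c on 5mC/5hmC: no oxidant is present, so both fall back to the
  background rate.
* TAPS on 5fC/5caC: reduced directly but not separately quantified; set to
  0.95, the magnitude of the neighbouring measured conversions.

`seq_error` (a uniform substitution applied on top of conversion) defaults
to 0 so that simulated chemistry is exactly the conversion model and QC
recovery tests are sharp; it can be raised for realism, in which case the
per-read T probability becomes `conv * (1 - e) + e/3`. At cytosine sites the
non-T outcome is emitted as C; the three-way substitution channel is only
applied at non-cytosine positions, a simplification that leaves the T/(C+T)
signal exact.

## The synthetic methylome and read simulator

`generate_reference()` draws i.i.d. bases at a target GC fraction; spike-in
contigs are random sequences at GC 0.5 whose *truth* structure mirrors the
standard control set: a fully CpG-methylated lambda-like contig, an
unmodified 2-kb contig, an oligo carrying 5mC and 5hmC on alternating CpG
dyads, an all-5fC oligo (emulating extension with 5-formyl-dCTP), and a
CpG-methylated-then-fully-oxidised 5caC contig. These are synthetic
stand-ins — the real spike-in sequences are not shipped — so sequence-specific
effects (e.g. the true lambda CpG landscape) are not reproduced, only the
modification truth that QC needs.

`generate_methylome()` emulates a mammalian (mESC-like) methylome:

* CpG 5mC levels are drawn per dyad from a U-shaped Beta(0.6, 0.15)
  (bimodal, mean 0.8 — most dyads near fully methylated or unmethylated);
* 5hmC occupies a sparse 10% of dyads at Beta-distributed levels with mean
  0.2, reflecting its much lower abundance than 5mC in non-neuronal cells;
* 5fC/5caC occupy trace disjoint subsets (0.1% of dyads each, level 0.2);
* non-CpG cytosines are unmodified;
* oxidised states consume existing 5mC mass at their sites (oxidation acts
  on 5mC), which keeps level sums within 1 by construction; configurations
  that still overflow are rescaled with a warning.

By default both cytosines of a dyad share one level draw
(`symmetric_cpg = TRUE`); switching it off exercises strand-resolved
calling.

`simulate_reads()` models a double-stranded library: each fragment is
assigned an original strand uniformly, every cytosine of that strand is read
as T with the site's level-weighted readout probability, and the mate is the
exact reverse complement (a PCR copy carrying the same conversion outcomes).
Reads are emitted both as FASTQ and as pre-aligned SAM records (FLAGs 99/147
for original-top pairs, 83/163 for original-bottom; all-match CIGARs;
constant Phred 37 qualities, since quality modelling is out of scope), so
the caller can be tested without an aligner. Per-molecule state draws are
collapsed to the marginal per-read T probability, which is an exact
simplification because draws are independent across molecules. Coordinates
are 0-based half-open internally; the SAM writer converts to 1-based.

What the simulator does **not** emulate: indels, PCR duplicates,
quality-score error profiles, adapter read-through, M-bias, coverage
biases, CpG depletion or other non-i.i.d. base composition, and the
single-strand degradation of the CAPS denaturation step. Passing recovery
tests therefore demonstrates correctness of the counting and estimation
machinery under the chemistry model, not robustness to real-library
artefacts — those are the aligner's and the upstream QC's problem.

## The modification caller

`call_mods()` is a strand-aware pileup: original-top read pairs contribute
C/T evidence at top-strand cytosines, original-bottom pairs G/A evidence at
bottom-strand cytosines (in top-strand coordinates), with orientation taken
from the FLAG fields. Filters follow common practice for this assay family:
alignments below MAPQ 10 are excluded, as are unmapped, secondary,
supplementary, QC-fail and duplicate-flagged records (duplicates are assumed
marked upstream; there is no internal dedup). The base-quality floor
defaults to Phred 13; only MAPQ is a hard convention of the pipeline, so the
base-quality cut is documented and configurable. Where mates overlap, the
molecule is counted once and the first mate wins, avoiding
pseudo-replication of a single fragment.

The emitted `signal` is the *converted* fraction T/(C+T) — in borane
chemistry the modified base reads as T. Deamination-based assays use the
opposite convention (retained C fraction); `bin_signal(convention =
"retained")` exposes it explicitly for cross-assay comparisons rather than
silently flipping anything. Records with zero coverage are not emitted.
`merge_cpg_strands()` (pooling the two cytosines of a dyad) is optional and
off by default, since strand pooling before correlation is an analysis
choice, not a property of the data.

## Spike-in QC

`conversion_report()` pools counts over all truth sites of a pure state and
divides once, rather than averaging per-site signals: the pooled ratio is
the coverage-weighted mean of per-site signals (an identity asserted in the
test suite) and is robust when individual sites are shallow. QC is
restricted to CpG sites for the lambda-like control (M.SssI methylates CpG
only) and uses all cytosines of the unmodified control for the
false-positive rate.

## 5hmC significance calling

`binomial_mod_test()` computes the upper-tail probability P(X ≥ k) under
Binomial(n, p0) with p0 the assay's false-positive rate (0.0072 for the
5hmC chemistry). `call_hmc()` tests only sites with at least 5 informative
reads, applies Benjamini–Hochberg within exactly the tested set, and calls
sites with q < 0.05. The coverage floor of 5 is the point at which a single
converted read is already nominally significant at p0 = 0.0072
(p ≈ 0.035), so shallower sites carry no usable evidence.

## Joint maximum-likelihood estimation of (u, 5mC, 5hmC)

Each assay observes k converted reads out of n with success probability
equal to the sum of true levels over its measured states. 5fC and 5caC are
fixed at 0 in the likelihood — their genomic abundance is orders of
magnitude below 5mC/5hmC — with a documented option to fold them in for
simulation studies. Two design classes admit closed forms
(`mle_two_assay()`):

* **nested** (mC+hmC assay with an mC-only assay): if p₁ ≥ p₂ the MLE is
  m = p₂, h = p₁ − p₂; otherwise the unconstrained solution has h < 0, the
  constrained optimum sits on the h = 0 boundary with
  m = (k₁+k₂)/(n₁+n₂), and the site is flagged as a conflict;
* **disjoint** (mC-only with hmC-only): m = p₁, h = p₂ when p₁ + p₂ ≤ 1,
  else the u = 0 boundary with m = (k₁+n₂−k₂)/(n₁+n₂).

Both are verified in the test suite against a brute-force grid search of
the joint binomial log-likelihood over the simplex at step 1e-4 (the
log-likelihood is concave in (m, h), so a coarse-to-fine/prefix-argmax
search finds the global grid optimum). `mle_multi_assay()` generalises to
any identifying design set by EM on the latent per-read state, converging
to the same constrained optimum (parameter-change tolerance 1e-8, capped at
10⁴ iterations; two-assay agreement within 1e-6).

Conflicts are flagged per site, not silently dropped; the standard
downstream filter excludes them. For multi-assay designs `n_conflicts`
counts the violated pairwise simplex constraints (superset proportion below
subset proportion; disjoint proportions summing above 1) — a per-site
convention, documented here because conflict bookkeeping differs between
implementations of this estimator family.

`subtract_estimate()` implements the two-assay subtraction for comparison;
it preserves and flags negative values. At matched truth and total depth
its Monte-Carlo variance strictly exceeds that of the direct 5hmC readout
(the subtraction accumulates the sampling noise of two assays), which is
the quantitative reason the subtraction-free design is preferred for a mark
as sparse as 5hmC.

## Region statistics

All interval logic is 0-based half-open; bins are fixed-origin tiles
`[i·b, (i+1)·b)`. `pearson_at_depth()` correlates per-site signals over the
intersection of sites with ≥ 10 informative reads in both datasets (the
conventional depth floor for correlation analyses). `enrichment()` compares
the density of called sites per bp of each region class against 10 random
draws of equally many sites from the covered-CG universe; sampling is
without replacement (a documented choice — the background describes the
finite site universe, not an infinite population), class footprints are
union-reduced, and normalisation is by class bp with CG-count available as
an option. The first-match partition for single-membership summaries takes
an explicit class-precedence order (`site_class_partition()`), since any
partition of overlapping annotation classes is a convention.
`metaplot()` tiles ±3 kb around centers into 100-bp bins (60 bins) and
averages per-site signals, flipping the axis for minus-strand centers.
`island_coverage_profile()` bins island bodies into 10 windows and 4-kb
flanks into 20, and rescales the second dataset by the overall coverage
ratio so depth differences cancel; islands shorter than the bin count are
binned proportionally with a warning.

## Problem sizes and numerical choices

The shipped analyses run at desk scale, chosen so that every pooled
rate estimate rests on at least 10⁴ observations — and for the low-rate
quantities (false-positive rates of order 10⁻³, blocked-5hmC conversion of
order 10⁻²) enough observations that 3 binomial SE stays within about 10%
of the rate itself, i.e. several × 10⁵: spike-in contigs of 0.4–5 kb at
fold-coverages of 50–5000, and joint-estimation studies over ≥ 10⁴ CpGs at
depth 100. At these sizes every printed chemistry rate is recovered within
3 binomial standard errors through the full simulate → call → QC pipeline.
Because a strand-specific site draws evidence only from fragments of its
own original strand, pooled observations per site are about half the
nominal fold-coverage — the depth multipliers in the QC defaults account
for this.

Degenerate inputs are handled explicitly: contigs shorter than the read
length are skipped with a warning; zero-coverage records are not emitted;
correlation over fewer than two shared sites is reported as undefined;
empty masks are no-ops; a background smaller than the site set is an error.
Every stochastic function takes an explicit seed and is byte-reproducible
under it.

## Known limitations

* The caller handles the CIGAR alphabet (M/=/X/I/D/N/S/H/P) but performs no
  local realignment and no indel-aware context shifting; contexts come from
  the reference top strand.
* Conversion-efficiency bias is not corrected in estimates: signals are
  raw, so a 0.976-efficiency assay under-reports 5mC by ~2% of the level.
  This mirrors how such data are conventionally reported and is visible in
  the joint-estimation recovery results.
* The simulator's i.i.d. base model has no CpG islands unless you provide
  real sequence; region-level functions accept any reference, but the
  shipped fixtures exercise geometry, not biology.
* No differential analysis between samples, no smoothing, no bigWig export
  (bedGraph is provided; conversion is a one-liner with external tools).
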