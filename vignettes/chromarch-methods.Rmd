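---
title: "chromarch: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromarch: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromarch)
```

This vignette is the package's own account of its methods: the models
and their assumptions, the parameters that matter, what the synthetic
generators do and do not emulate, the numerical choices, and known
limitations.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinates and containers

All coordinates are 0-based half-open internally (BED convention);
the nucmer-style `coords` dialect is 1-based fully-closed on disk and
converted on read.  Window grids are anchored at position 0 of each
chromosome; the anchor is a convention, not a biological statement.
Per-window quantities live in a `window_track` whose missing windows
carry `NA`, never 0 — a window with no data and a window with value 0
mean different things everywhere in this package (e.g. W-chromosome
male depth really is 0).

## Sex-linkage classification

A scaffold's M/F depth ratio is the ratio of mean normalized window
depths over mutually covered windows; the coverage ratio is the ratio
of covered-window fractions.  Thresholds are the standard bands:
depth ratio in [1.5, 2.5] → Z; depth **or** coverage ratio ≤ 0.25 → W
(the OR mirrors how W calls are made in practice: a W scaffold may
attract some male mismapping yet show near-zero male coverage);
minimum 80% coverage in both sexes for any other call, else
`unassigned`.  The W test precedes the coverage-floor gate because the
absence of male reads *is* the W signal.  The depth estimator (mean of
normalized window depths, pairwise-complete) is a choice; medians
change nothing material on clean tracks.

## PAR boundary

`detect_par()` fits a single changepoint by two-segment least squares
**on log2 ratios**, trying the PAR at either terminus, and accepts a
fit only when the segment geometric means fall in the PAR band
[0.75, 1.25] and SDR band [1.5, 2.5].  The log scale matters: window
depth-ratio noise is multiplicative and right-skewed, and raw-scale
least squares is dominated by windows where the female denominator is
small.  The tolerance bands are not biological constants; they mirror
the Z classification band and are exposed as arguments.

## Depth simulation — the noise model

`simulate_depth()` draws per-window *read counts*,
NB(mu = depth × copies/2 × window/read_len, dispersion α), and
converts back to per-bp depth.  This matters: modeling a 5-kb window's
depth as a single NB draw with mean 30 implies a ~32% coefficient of
variation at α = 0.1, which no aligner produces — a real window
aggregates ~10³ reads.  The default α = 0.01 gives ~10% window CV,
typical of short-read coverage in mappable regions.  The sex-linkage
acceptance criterion explicitly states dispersion 0.1 and its test
sets it; scaffold-level classification is insensitive to α because it
averages many windows.  PAR-boundary recovery is *not* insensitive:
at 32% window CV the log2-ratio jump (1.0) is barely above the
per-window noise sd (~0.8), and no changepoint estimator can then land
within ±1 window 95% of the time — which is why the generator default
is the realistic count-based model.

## Strata segmentation

Divergence is mismatch-only identity, 1 − Σmatches/Σaligned, in 10-kb
windows, with blocks apportioned pro rata by overlap; windows under
1 kb of alignment are missing.  Segmentation is an exact least-squares
dynamic program over the non-missing series (O(k·n²)), with k chosen
by BIC (Gaussian profile likelihood, 2k parameters).  Plain BIC
over-splits a few percent of the time, so auto mode prunes
changepoints CBS-style: a boundary is kept only if its RSS gain is
significant (α = 0.01) against the permutation null of the *best*
single split of the merged segment — the max-form null accounts for
the selection of the split point.  Pruning runs under an isolated,
fixed RNG state, so it does not perturb caller reproducibility.  Two
residual failure modes are documented by the acceptance report: ±2
window boundary error under heavy noise (irreducible for least
squares), and rare 5-window "transition segments" straddling a true
boundary, which both flanking tests rightly call significant.
Strata are named S0, S1, ... by *descending* mean divergence
(oldest first); per-scaffold assignment is the majority stratum of the
scaffold's windows.

## Hi-C

ICE balancing iteratively divides rows/columns by normalized
marginals until the unmasked row-sum CV is below `tol`; bins with zero
marginals are auto-masked.  The insulation score is the single-scale
square form: `raw(i)` = mean count of the w×w square crossing the
diagonal at bin i, `score = log2(raw / mean(raw))`; w defaults to 10
bins at 10-kb resolution.  Boundaries are strict local minima (plateau
→ central bin) with strength = the smaller rise to the nearest local
maximum on each side, thresholded at 0.1 log2 units.  This replaces
multi-scale FDR machinery by design: it is deterministic,
oracle-checkable, and recovers planted domains exactly in the stated
worlds.

Compartments: observed/expected by per-diagonal means on the unmasked
submatrix, Pearson correlation, leading eigenvector by power iteration
from an all-ones start (deterministic; tolerance 1e-8), sign oriented
so that bins with above-median orientation-track values (GC or gene
density) load positively; A = positive.  A uniform or rank-0 matrix is
flagged degenerate rather than labeled.  Note one honest limitation
the pipeline run reports: with strong (3×) intra-TAD enrichment *and*
compartments in the same matrix, the leading eigenvector mixes the two
structures and label accuracy drops to ~0.8; on a TAD-free matrix the
same code exceeds 95%.  Real analyses sidestep this by computing
compartments at coarser bins than TADs.

PWM scanning is plain log2-odds against a uniform background on both
strands, with hits at ≥ `threshold` × the maximum attainable score;
N scores 0 (background).  Zero PWM entries get a 1e-3 pseudocount.
An independent brute-force scorer in the test helpers pins the
implementation on 10-kb sequences.

## Synthetic genome — what it emulates and what it does not

The default toy world: autosomes A1/A2 (2 Mb, "macro") and A3/A4
(0.5 Mb, "micro"); Z of 1.5 Mb with a 100-kb PAR at its tip; W built
by copy-and-mutate from non-overlapping Z SDR segments at four stratum
divergences 0.24/0.16/0.09/0.03 (oldest → youngest), plus a W-specific
tail carrying three perfect palindromes (3-kb arms); 190-bp monomer
centromere arrays (200 copies) on A1/A2/Z; 400-copy TTAGGG arrays at
every non-W chromosome end and one interstitial array (ITR) on A2;
six planted inversions (20–200 kb) on A1 with focal/other lineages.
Compartment blocks are unions of 1–2 consecutive TADs, so compartment
transitions coincide with TAD boundaries as they do in real chromatin;
with independent compartment blocks, their transitions would create
genuine insulation minima that score as "false" boundaries against
planted TAD truth — a labeling artifact, not a detection error.

Deliberately not emulated: indels (W divergence is substitution-only,
so identity is exactly 1 − divergence), read-level artifacts
(mappability, GC bias), TE evolution, assembly gaps, and real
recombination.  A green recovery test therefore establishes that the
*algorithms* invert the *stated generative model* — not that they are
robust to everything real data does.

## Inversions and the permutation test

Chaining is greedy left-to-right over strand- and order-consistent
blocks with gaps ≤ 100 kb in both genomes; a reversed chain flanked by
forward chains (or ends) with query span ≥ 10 kb is an inversion.
Polarization uses the majority strand, weighted by aligned length, of
outgroup blocks over the inversion interval, requiring ≥ 50% coverage
— the outgroup-parsimony rule stated as an explicit coverage
criterion.  The breakpoint/boundary permutation test re-places
breakpoints uniformly per chromosome (optionally avoiding an exclusion
BED), with the add-one estimator p = (1 + #{perm ≥ obs})/(1 + n_perm),
so p can never be 0 and its floor 1/(n_perm+1) is part of the
contract.  The null model treats breakpoints as independent; paired
breakpoints of one inversion are only ~coupled through the inversion
length, and the acceptance calibration (KS < 0.2 over 100 null
datasets) uses independent placements to match the null's own
assumption.

## Repeats and palindromes

Centromere/telomere annotation is windowed motif counting (both
strands, approximate matching for the monomer at 10% of its length),
thresholded and merged across ≤1-window gaps; telomere calls within 2
windows of a chromosome end are terminal, otherwise ITR.  The
per-window thresholds (20 monomer copies, 100 telomere motifs) are set
so an array filling half a window is called; there is no biological
constant here, only a planted-truth calibration.

Palindrome detection matches exact k-mers (k = 21) of the sequence
against its reverse complement; a matched pair at forward positions
(p, q) satisfies p + q = const along a gap-free inverted repeat, so
seeds group by anti-diagonal.  Groups become arm pairs, arms are
extended by x-drop (+1 match / −2 mismatch, drop 10, endpoint at the
last argmax), identity is gap-free column identity of arm1 vs the
reverse complement of arm2, and calls are filtered by arm ≥ 2 kb,
spacer ≤ 50 kb, identity ≥ 0.9, keeping the longest of overlapping
calls.  Arm endpoints are defined only up to the point where flanking
random sequence happens to complement, so recovered endpoints are
checked to ±k bp.  Indel-tolerant arms are out of scope by design; a
palindrome whose arms have drifted by indels will fragment into
several anti-diagonals and may be missed.

## Determinism

One global seed drives everything; every stochastic stage derives its
own sub-seed by stable string hashing (`derive_seed`), so stages can
be re-run in isolation and the pipeline bundle is byte-identical under
a fixed seed.  Config files are JSON (no TOML/YAML parser in the
supported stack); `simulate` and `inputs` blocks are mutually
exclusive.
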