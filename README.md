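# chromarch

Chromosome-architecture analyses for highly differentiated (avian-style
ZW) sex chromosomes, built as a tested, reusable pipeline whose every
stage can be exercised on synthetic genomes with planted, recorded
truth.

## What it does, and for whom

Genome projects on birds and other ZW taxa repeatedly need the same
chain of analyses after assembly:

1. **Sex-linkage classification** — scaffolds are called Z-linked,
   W-linked or autosomal from male/female read-depth tracks: with
   window depths normalized by each sex's genome-wide per-bp median,
   the male/female (M/F) depth ratio is ~2 for the Z-specific region
   (males ZZ, females ZW), ~0 for the W, and ~1 for autosomes.  The
   standard bands are M/F in [1.5, 2.5] → Z; depth **or** coverage
   ratio in [0, 0.25] → W; a minimum 80% read coverage in both sexes is
   required for any other call.
2. **PAR detection** — the pseudoautosomal region at the Z tip is the
   terminal segment with M/F ≈ 1; `detect_par()` fits a two-segment
   least-squares changepoint to the log2 ratio track.
3. **Evolutionary strata** — W scaffolds are placed on the (outgroup) Z
   by best unique alignment, Z/W divergence is computed in 10-kb
   windows as 1 − Σmatches/Σaligned, and the series is segmented into
   strata by an exact least-squares dynamic program with BIC model
   selection and CBS-style changepoint pruning.
4. **Hi-C architecture** — ICE matrix balancing; the insulation score
   `score(i) = log2(raw(i)/mean raw)` with `raw(i)` the mean contact
   count in a w×w square crossing the diagonal; TAD boundaries as
   strict local minima with a strength threshold; A/B compartments from
   the leading eigenvector of the observed/expected correlation matrix,
   oriented by GC or gene density; CTCF PWM scanning and convergent
   ("loop anchor") pair counting.
5. **Inversions** — alignment blocks are chained into strand-consistent
   syntenic runs; a reversed run flanked by forward runs (≥10 kb) is an
   inversion, polarized to a lineage with an outgroup; breakpoint /
   TAD-boundary association is tested by a uniform-replacement
   permutation test, `p = (1 + #{perm ≥ obs}) / (1 + n_perm)`.
6. **Repeat annotation** — putative centromeres from 190-bp monomer
   counts in 50-kb windows; telomeres from TTAGGG/CCCTAA counts,
   classified terminal vs interstitial (ITR); W palindromes (large
   inverted repeats) by k-mer seeded self-comparison with x-drop arm
   extension.
7. **Expression statistics** — per-gene M/F expression ratios
   (Z genes are expressed ~2× in males absent global dosage
   compensation) and the tissue-specificity index
   τ = Σ(1 − x_i/x_max)/(n − 1).

The `simulate_*` generators produce a toy genome (macro/micro
autosomes, Z with terminal PAR, W with four planted strata, planted
centromere/telomere/ITR arrays and palindromes), sexed depth tracks,
Hi-C matrices with distance decay + TADs + compartments, alignment
blocks with polarizable inversions, and expression matrices — all with
a truth record, so each analysis is scored by parameter recovery.

## Worked example

```r
library(chromarch)
bundle <- run_pipeline(list(simulate = list(), seed = 3))
str(bundle$recovery)
```

```
List of 10
 $ sexlink_label_accuracy    : num 0.986
 $ par_boundary_error_windows: num 0
 $ strata_k                  : int 4
 $ tad_boundary_f1           : num 1
 $ compartment_accuracy      : num 0.805
 $ inversions_called         : int 6
 $ inversions_true           : int 6
 $ palindromes_called        : int 3
 $ palindromes_true          : int 3
 $ itr_called                : int 1
```

Reading: 98.6% of scaffolds got their true Z/W/autosomal label; the planted
100-kb PAR boundary was recovered exactly; four strata were found; all
six planted inversions (and all three W palindromes) were recovered.
TAD-boundary F1 is 1.0 against planted truth; compartment label
accuracy on the full matrix is lower (~0.8) because the 3-fold
intra-TAD enrichment competes with the compartment signal in the
leading eigenvector — on a TAD-free matrix the same code scores >95%
(see the acceptance report).  Outputs (BED/bedGraph/TSV/JSON) land in
`bundle$out_dir`.

The same pipeline runs on real files via an `inputs` config block, or
from the command line:

```sh
Rscript inst/cli/chromarch.R run --config config.json --seed 1 --out results/
```

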