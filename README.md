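# offtargetr

Machine-learning assessment of CRISPR-Cas9 cleavage propensity: given a
single guide RNA (sgRNA) and a genomic site, how likely is Cas9 to cut
there? The package is aimed at genome-engineering researchers who need to
rank candidate on-targets, anticipate off-target cleavage, and probe which
sequence and genomic-context attributes drive Cas9 activity.

## What it computes

**Bulge-aware alignment.** Cas9 tolerates mismatches *and* single-base
bulges between the 20-nt spacer and the protospacer. The aligner is a
Needleman-Wunsch variant with a hard gap budget: at most 3 single-column
indels over the whole alignment, scored

```
S = match · #matches + mismatch · #mismatches + gap · #bulges
```

with optimized defaults `match = 1`, `mismatch = 0`, `gap = -1.25`. Because
gaps change the protospacer length, seven windows (17–23 nt, anchored at
the PAM-proximal end) are aligned and the best score kept. A gap in the
guide row is a DNA bulge, a gap in the target row an RNA bulge.
`optimize_params()` re-derives the penalties from data by maximizing the
per-guide averaged Pearson r² between alignment scores and cleavage
intensities; `relocate_pam()` re-evaluates non-canonical PAMs by searching
±2 nt for an NGG (then NAG) motif.

**Cleavage propensity.** A regression target in [0, 1] is built from raw
read counts of genome-wide cleavage assays: counts are log-transformed,
every study is calibrated onto the reference scale by OLS over shared
guide/site pairs (`fit_calibration()`), and values are divided by the
dataset maximum. An ensemble of random-forest regressors — one per
class-balanced bootstrap round (cleaved sites oversampled 2×, an equal
number of mined uncleaved sites drawn per guide) — is trained on a
registry of ~80 features: alignment score and decomposition, per-position
mismatch indicators, mismatch chemistry (wobble rG·dT / rU·dG,
purine–purine, pyrimidine–pyrimidine, transversion), PAM type,
position-specific nucleotide identities, GC content, nearest-neighbor
duplex enthalpy over the 223-nt context, DNA-shape lookups, and genomic
annotations (DNase hypersensitivity, exon, CpG island, expression). The
predicted propensity is the member mean.

**Evaluation and mechanism.** `loso_cv()` implements leave-one-sgRNA-out
cross-validation with per-fold re-optimization of the alignment
parameters; `leave_study_out()` holds out whole studies and reports
unique-/common-guide metrics; `metric_suite()` provides r², Spearman rho,
ROC-AUC and PRC-AUC; `forward_select()` runs greedy forward feature
selection under cross-validated r²; `wobble_enrichment_test()` and
`enthalpy_tail_permutation_test()` are the two mechanism-probing tests.
`simulate_dataset()` generates seeded synthetic genomes with planted
on/off-targets and multi-study read counts for end-to-end validation.

## Worked example

```r
library(offtargetr)

guide <- guide_rna("EMX1", "GAGTCCGAGCAGAAGAAGAA")
site  <- "GAGTCCGAGCAGTAAGAAGAA"   # 21 nt: carries one extra DNA base
align_best_window(guide, site)
#> <guide_target_alignment> score 18.75 (20M 0X 1 DNAb 0 RNAb, window 21)
#>  guide :  GAGTCCGAGCAG-AAGAAGAA
#>  target:  GAGTCCGAGCAGTAAGAAGAA
```

All 20 spacer bases pair, the extra DNA base is absorbed as a DNA bulge in
a 21-nt window, and the score is 20 matches − 1.25 gap = 18.75 — higher
than any gapless 20-nt interpretation of the same locus.

Mining a genome for candidate off-targets (here one planted perfect site
and one 1-mismatch site with an NAG PAM):

```r
hits <- mine_negatives(guide, genome, min_score = 14.75)
hits[, c("start", "strand", "site_seq", "pam", "score")]
#>   start strand             site_seq pam score
#> 1   300      + GAGTCCGAGCAGAAGAAGAA TGG 20.00
#> 2   302      + GTCCGAGCAGAAGAAGAATG GAG 17.50
#> 3   303      + TCCGAGCAGAAGAAGAATGG AGG 16.25
#> 4   623      + GAGTCCGAGCAGAATAAGAA AAG 19.00
#> 5   624      + AGTCCGAGCAGAATAAGAAA AGG 17.75
```

Scores are the best-of-seven-window alignment scores; sites above the
mining threshold (strictly greater than 14.75, i.e. roughly 16.7 matched
bases on average among cleaved sites) enter the uncleaved training pool.

A shell entry point wrapping the same functions lives at
`inst/cli/offtargetr` (`align`, `mine`, `score-pairs`, `rank-within`,
`simulate`).

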