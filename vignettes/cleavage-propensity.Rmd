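---
title: "Modeling CRISPR-Cas9 cleavage propensity with bulge-aware alignment and forest ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CRISPR-Cas9 cleavage propensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A Cas9 ribonucleoprotein programmed with a 20-nt spacer cleaves genomic
sites that are *similar enough* to the spacer and carry a protospacer
adjacent motif (PAM; canonically NGG, alternatively NAG) at their 3' end.
Similarity is not just mismatch counting: single-base bulges on either
side of the RNA:DNA heteroduplex are tolerated, and genome-wide
double-strand-break profiling (GUIDE-seq, HTGTS, BLESS) shows that the
genomic context of a site — openness, composition, duplex geometry —
modulates cleavage beyond what pairwise similarity explains. `offtargetr`
models the *cleavage propensity* of a (guide, site) pair: a continuous
score in [0, 1] that is a proxy for the max-normalized, harmonized log
read count a genome-wide assay would report.

## The alignment model

The aligner is a global Needleman-Wunsch variant with two modifications.

1. **Gap budget.** At most `max_gaps = 3` single-column indels over the
   whole alignment. Each gap column consumes one unit of the budget;
   adjacent gap columns are allowed but each is counted (no affine
   extension). A gap in the guide row represents a DNA bulge (an unpaired
   genomic base), a gap in the target row an RNA bulge (an unpaired spacer
   base).
2. **Window search.** Because indels change the protospacer length, the
   site is extended or shortened by up to three nucleotides at its
   PAM-distal end and seven alignments (window lengths 17–23 nt anchored
   at the PAM-proximal end) are computed; the best score is kept.

The score is `match·M + mismatch·X + gap·G` with defaults
`(1, 0, −1.25)`. These defaults are themselves the output of
`optimize_params()`: a sweep of the (mismatch, gap) grid — match fixed at
1, mismatch in {0, −0.25, …, −1.5}, gap in {−0.25, …, −3} in steps of
0.25 — selecting the point that maximizes the per-guide averaged Pearson
r² between alignment score and cleavage intensity, after removing
exact-match targets (their score is maximal by construction and would
inflate the correlation). With a mismatch penalty of 0, mismatches are not
explicitly punished but matches are still rewarded, so longer
complementarity wins; a bulge is only introduced when the matches it
recovers outweigh 1.25 score units.

Numerical determinism: the dynamic program ranks states by score, then
fewer gaps, then fewer mismatches; at exact ties the traceback places gap
columns closest to the PAM-proximal end. Grid ties in `optimize_params()`
break toward the least-negative gap, then least-negative mismatch — the
least-punitive model consistent with the data.

One caveat worth recording: replacing a matched target base with a
mismatching one can *raise* the optimal gapped score (a different
alignment may pair the substituted base as a new match, gaining up to
`match − mismatch`). The intuitive monotonicity property holds only for
the gapless aligner, and the test suite asserts exactly that version.

### PAM relocation

Site coordinates lifted from mismatch-only read mapping can place a bulged
site's PAM one or two bases off, making a canonical site look like a
non-NGG one. `relocate_pam()` searches shifts of 0, +1, −1, +2, −2 (in the
site's own orientation, downstream first at equal distance) for an NGG,
then the same order for an NAG, and otherwise preserves the original PAM.
Whether the original implementation preferred downstream or upstream at
equal distance is not documented; the order here is fixed and recorded so
it can be revisited.

## Features

`feature_registry()` defines ~80 named features per (guide, site,
alignment) triple, in four families: pairwise similarity (score, window,
match/mismatch/bulge counts, per-position mismatch indicators numbered
1–20 from the PAM-proximal base, counts of the four mismatch chemistry
classes), PAM (NGG/NAG/other one-hot), site sequence (nucleotide one-hots
at PAM-proximal positions 2, 4–5 and 20 and the five bases downstream of
the PAM; GC of the site and of each 100-nt flank), and context
thermodynamics/geometry (nearest-neighbor duplex enthalpy over the 223-nt
window spanning site + PAM + 100 nt each side; minor groove width averaged
over the PAM-centered 6-mer from a user-supplied pentamer table; bending
stiffness from a dinucleotide table) plus genomic annotations (DNase
hypersensitivity, exon on either strand, CpG island, expression level) and
an sgRNA folding-energy hook.

Wobble orientation is fixed as rG·dT and rU·dG in the heteroduplex — the
spacer base is listed first and the opposing target-strand base is the
complement of the site base. The enthalpy table is the unified
nearest-neighbor stacking set (10 unique dinucleotide ΔH values in
kcal/mol, expanded to 16 by reverse-complement symmetry; initiation terms
excluded), embedded as versioned constants so that feature values are
reproducible independent of any external resource.

Pluggable features without a provider (shape tables, annotations, folding)
are **NA-flagged, never silently zero**; at training time
`impute_features()` replaces NA with the training median and adds a
`miss_*` indicator column, so missingness itself remains visible to the
forests.

## Harmonization

Read counts from different platforms are not comparable. Counts are
transformed as `log10(reads + 1)` (base and pseudocount configurable —
the base only rescales the subsequent linear fit), each study is regressed
onto the reference study over shared guide/site pairs (identical guide,
overlapping interval within ±2 nt to absorb PAM relocation shifts), and
the fitted line maps the rest of that study's records onto the reference
scale. The regression target is the harmonized value divided by the
maximum over cleaved records, clamped at 0, so uncleaved sites sit at
exactly 0 and the strongest site at 1. Max-normalization happens after
calibration, over the combined cleaved set.

## Training-set assembly and imbalance

Uncleaved candidate sites are mined by exhaustively scanning both genome
strands for NGG/NAG motifs and keeping sites whose best-window score is
strictly greater than 14.75 (the level that ~95% of cleaved sites exceed,
averaging 16.7 matched bases), excluding anything overlapping a known
cleaved interval for that guide. Guides profiled in several studies keep
only the reference study's collection; incompatible studies can be
excluded outright.

Uncleaved sites outnumber cleaved ones by orders of magnitude, so each
training round under-samples the majority class and over-samples the
minority class: per guide, cleaved records are bootstrapped to twice their
original count and an equal number of uncleaved records is drawn without
replacement (re-drawn each round). One forest is trained per round — 100
rounds by default — and the ensemble mean is the propensity. Forest
hyperparameters are not dictated by the method and are fully exposed:
100 trees per member and `mtry = floor(p/3)` (the classical
regression-forest default) are the package defaults, recorded in the model
metadata.

## Cross-validation

Leave-one-sgRNA-out: each fold excludes every record of one guide,
re-optimizes the alignment parameters *on the training guides only*,
recomputes alignment-derived features for training and test, builds the
balanced rounds, trains, and scores the held-out guide's cleaved sites
against an equal-sized random draw of its uncleaved sites (drawn once per
fold with the fold seed). Pooled and per-guide metrics are reported; the
per-guide average is the mean of individually computed per-guide metrics,
never a pooling shortcut. Leave-study-out excludes whole studies (without
per-fold re-optimization, mirroring the original protocol) and reports
guides profiled in one study ("unique") separately from guides profiled in
several ("common"). ROC-AUC is computed as the normalized Mann-Whitney
statistic (identical to the trapezoidal curve area with score thresholds);
PRC-AUC is the trapezoid over distinct-threshold precision/recall points.
`negative_fraction_sweep()` re-computes the per-guide averaged r² while
shrinking the uncleaved test draw from 100% to 0% of the cleaved-set size.

Forward selection evaluates candidate features by leave-one-sgRNA-out r²
and adjoins the best one per iteration (15 by default). A full-budget CV
per candidate per step is quadratic in cost, so candidate scoring runs a
reduced configuration (few rounds, fixed alignment parameters) that is
exposed in `cv_config`; the selected trace can be re-scored at full
budget. Importances come from a single forest on the selected set.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a multi-study genome-wide
compendium with known ground truth: an i.i.d. genome at 41% GC (human-like);
five guides; 100 cleaved sites per guide whose mismatch load is skewed
toward 2–4 mismatches (mean ≈ 2.6, echoing the 3.36 average of real
off-target compendia once bulge correction is applied) with a bulge in 18%
of sites; 320 uncleaved decoys per guide at 3–5 mismatches. Bulges are
planted at interior duplex positions (5–16): within ~4 nt of either end an
indel is cheaper to explain as terminal mismatches, i.e. it is not
identifiable by any scorer, so edge bulges would only blur the ground
truth. The decoy count is set so that, after the strict mining threshold
removes heavily bulged 4–5-mismatch decoys (legitimately below 14.75), at
least twice the cleaved-set size survives per guide — the hard
precondition of the balanced sampler.

The latent cleavage intensity is a linear effect model on standardized
alignment score, site GC and context enthalpy (defaults 1.5, 0.25, 0.25)
plus Gaussian log-scale noise (sd 0.3) — an intentionally simple stand-in
for the unknown true generative process, chosen because parameter-recovery
tests need a known truth. Study counts arise by inverting each study's
planted calibration. What passing tests on these fixtures demonstrate is
that the machinery recovers planted signal and planted calibrations under
controlled conditions; they do not certify accuracy on real data, where
effects are weaker, correlated and non-linear, and where the genome is not
i.i.d. For calibration-recovery checks the simulated read depth is raised
(`read_mu = 3.1`) so that integer rounding of counts — which is not
mean-zero noise and attenuates OLS slopes — stays negligible next to the
planted study noise.

Problem sizes used by the test suite and the acceptance script — 1000
random pairs for the aligner oracle, the 5-guide/100-positive simulation
for end-to-end recovery, 1000 replicates for the type-I calibration of the
mechanism tests — were chosen as the smallest sizes at which the checked
quantities are statistically stable.

## Numerical and design choices

* Coordinates are 0-based half-open on the forward strand; minus-strand
  sites store the reverse-complemented protospacer; mismatch and bulge
  positions are numbered 1–20 from the PAM-proximal base.
* The mining threshold uses the strict inequality (`> 14.75`) as stated.
* `log10`, pseudocount 1 for the read transform (configurable).
* Permutation p-values use the add-one convention `(k + 1)/(n + 1)`,
  avoiding p = 0; the enthalpy test is one-sided for *low* mean frequency
  in the union of the ≤5th and ≥95th enthalpy percentiles.
* Chi-square contingency bins with expected counts below 1 are merged
  upward with a warning.
* Score thresholds for binary decisions are quantile cutoffs of the
  cleaved-set score distribution (e.g. the value exceeded by 95% of
  cleaved sites as a lenient threshold, by 50% as a strict one).
* Degenerate inputs fail loudly: fewer than two shared targets for a
  calibration, constant scores across a whole parameter grid, a guide
  without the 2× uncleaved pool, empty cleaved sets.

## Known limitations

* The exhaustive genome scan is exact but desk-scale; scanning a
  mammalian genome calls for a seeded approximate pre-filter, which is
  deliberately out of scope.
* DNA-shape and annotation features depend on user-supplied tables; the
  package ships none and NA-flags those features instead.
* The classification mode mirrors the regression mode (binary labels,
  probability averaging) and is expected to rank similarly but slightly
  worse; both are exposed.
* Statistics reported by the examples and tests are computed on synthetic
  data at the sizes stated above; nothing in this vignette asserts an
  empirical result that the test suite or acceptance script does not
  itself compute.
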