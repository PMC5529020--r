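---
title: "Methods: linear epitope mapping from high-density peptide arrays"
author: "epimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linear epitope mapping from high-density peptide arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimap)
```

## The measurement model

A high-density peptide microarray displays every overlapping 15-mer of a
collection of protein sequences (here: snake-venom toxins), each peptide in
five replicate fields at random array positions. The array is read twice:
first after incubation with naive (pre-immune) IgG, then after incubation
with the antibody preparation of interest (an antivenom). A true linear
epitope element — typically 4 to 12 contiguous residues — elevates the
antivenom signal of *every* 15-mer containing it, producing a plateau of
high signals across consecutive overlapping peptides; unspecific binding
does not have this structure. The analysis exploits exactly that
redundancy.

Three artefacts have to be removed before signals are comparable:

1. **Field noise and outliers.** The five replicate fields of a peptide are
   collapsed to their median in each channel, which is insensitive to single
   defective fields.
2. **The re-incubation effect.** The second incubation inflates the signal
   of peptides prone to unspecific binding, because antivenom antibodies can
   bind secondary antibodies already attached during the first incubation
   and free peptide left over from it. The inflation is estimated from a
   dedicated control: a lysine/arginine-rich "corner" peptide
   (`KKKRKKKRKKKRKKK`) synthesised in hundreds of fields, which binds
   antibodies almost indiscriminately. The factor is the ratio of the median
   corner signal in the second recording to that in the first, and the
   corrected score of a peptide is
   `antivenom_median - factor * background_median`. We implement the factor
   as a ratio (not a difference) because it is applied multiplicatively;
   this is the only reading that makes the correction dimensionally
   consistent. Corrected scores may be negative and are deliberately not
   clamped — the significance test needs the full null distribution.
3. **Positional noise.** Per-toxin profiles (score indexed by the 15-mer's
   N-terminal residue) are smoothed with a 3-point running median, replacing
   each score by the median of itself and its two overlapping neighbours.
   True epitopes survive this filter; isolated spikes do not.

### Terminal positions

The running median is undefined as a 3-window at the two profile ends. We
use the median of the two available values (their mean) there, which
preserves profile length. The alternative — dropping terminal positions —
would make the "two successive significant peptides" recognition rule
inapplicable within 15 residues of either terminus, a worse trade.

## Significance calling

Corrected running-median scores of unspecifically binding peptides are
modelled as normal with mean zero and a standard deviation `sigma`
estimated by a parametric-free bootstrap from the corner-control fields, a
deliberately *conservative* choice: corner fields show the strongest
unspecific binding on the array, so a null calibrated on them is wider than
the true null of typical peptides.

One bootstrap repetition mirrors every transformation applied to a real
score: for each of three neighbouring pseudo-peptides, draw `replicates`
values with replacement from each channel's empirical corner distribution,
take channel medians, form the corrected score, then take the running
median of the three (the centre value). `sigma` is the standard deviation
over 50,000 repetitions (default). The exact resampling unit is a design
choice — we resample field intensities rather than precomputed medians
because that is the level at which the array is actually noisy.

Scores become one-sided upper-tail Z-test p-values, and the
Benjamini-Hochberg step-up rule at `alpha = 0.05` is applied over the
family of *unique (peptide, running-median score) pairs* — a peptide shared
by several toxins is tested once per distinct smoothed score, not once per
toxin position, which keeps the family honest under the heavy sequence
redundancy of toxin isoforms. Because the p-value is monotone in the score,
the BH rejection set is equivalently described by a single score threshold
(the smallest significant score); all downstream logic uses that threshold.
A toxin is *recognized* when at least two successive 15-mers are
significant — one significant peptide alone is never called.

## Epitope segments, core motifs and similarity sums

Per-toxin profiles are anchored to a per-subfamily multiple sequence
alignment (computed externally; the package consumes aligned FASTA or
Clustal) by placing the score of the 15-mer starting at ungapped position
*i* at the alignment column of residue *i*; gap columns carry no value.
A column qualifies when at least `min_share` toxins (default 10) are
significant there; maximal runs of qualifying columns are the shared
*epitope segments*. The source material uses "more than ten" and "ten or
more" interchangeably; we expose the knob and default to a count of at
least 10.

Within a segment, the member with the highest peak anchors the *core
motif*: its maximal run of consecutive significant 15-mers overlapping the
segment shares exactly `15 - run + 1` residues (the intersection of the
sliding windows), and those residues are the core. Ties on the peak break
by accession order; when the anchor has several runs, the one containing
its peak is used. Note the arithmetic: a run of 13 peptides shares 3
residues, a run of 14 shares 2. The intersection law is asserted for every
extracted core in the test suite.

Per-toxin binding to the motif is then aggregated mismatch-tolerantly:
every alignment row's residues *at the core's alignment columns* are
compared with the core (anchored comparison, not free sliding — the logo
and association analyses reason column-wise, and the comparison must match
them); rows within Hamming distance `max_mismatch` (default 3, gaps count
as mismatches) contribute the sum of running-median scores of all their
15-mers containing the matched window. All matching 15-mers are summed,
significant or not: the sum is a *quantitative* binding measure and the
non-recognized matches are exactly the informative ones for the
association analysis. Toxins beyond the mismatch radius are excluded.

## Residue-association logos

Two per-position summaries are built over the core window:

* **Shannon logos**: information content `log2(20) - H` (bits) with
  residue frequencies computed over non-gap symbols; letter height is
  frequency times position information. Computed both for all aligned
  toxins and for recognized toxins only.
* **Rank-based association Z-scores**: toxins are ranked by their core
  score sums (average ranks on ties); residue *r* at position *p*, present
  in `n_r` of `N` rows, gets the Wilcoxon rank-sum statistic
  `Z = (W - n_r(N+1)/2) / sqrt(n_r (N-n_r)(N+1)/12)`, positive when the
  residue associates with high binding. A fully conserved residue is found
  at the top and the bottom of the ranking alike and gets no Z — the logo
  and the association matrix must be read together. Gaps form a 21st
  category (a deletion can itself associate with weak binding) but are
  excluded from logo frequencies. Two-sided normal p-values are BH-corrected
  across all defined (position, residue) pairs at `alpha = 0.05`; which
  correction the original rank-logo tool applies is not documented, so the
  family and correction are chosen here and stated as such.

Degenerate input (constant sums) makes every rank statistic undefined; the
function warns and returns all-NA rather than fabricating zeros.

## Structure painting

Summed recognition scores are projected per residue onto a PDB file:
residues covered by a recognised core receive the series' score sum,
overlaps resolve by maximum, everything else is 0. Values are linearly
rescaled to [0, 99.99] and written into the temperature-factor column
(columns 61–66) of the selected chain's ATOM records; every other byte of
the file is preserved, so the output stays valid for any viewer. Residue
numbering maps to toxin positions via a user-supplied offset
(`toxin_position = resseq + offset`), since structure numbering rarely
matches mature-sequence numbering.

## The synthetic-array generator

The generator produces data with the statistical structure the analysis
assumes, so every stage is testable without experimental data:

* random sequences over the 20 standard residues, 15-mer-tiled and
  deduplicated exactly like real input;
* per-field unspecific binding drawn log-normal (non-negative fluorescence,
  heavy right tail; default `meanlog log(50), sdlog 0.4`); the law itself is
  a modelling choice — any heavy-tailed non-negative law would serve, and
  nothing downstream depends on log-normality;
* corner-control fields drawn from a stickier, heavier-tailed log-normal
  (default `meanlog log(100), sdlog 0.5`);
* a multiplicative re-incubation factor (default 4.3, the experimentally
  observed magnitude) applied to an *independent* unspecific draw in the
  antivenom channel — independent rather than paired, because the
  correction uses channel medians, not per-field pairing, and independence
  is the conservative model;
* planted epitope motifs (length 4–12) inserted verbatim at one shared
  position across all carriers — homologous toxins carry homologous
  epitopes at aligned positions, which also makes the identity alignment of
  equal-length synthetic toxins a valid MSA for recovery tests — with a
  constant signal elevation (default 1000 units, roughly eight times the
  default null width) added to every 15-mer containing the motif.

Under these defaults the bootstrap null width comes out near 10² units, so
default planted effects are unambiguous, as strong epitopes are on real
arrays. What the generator does *not* emulate: spatial intensity gradients,
print-tip/block effects, scanner saturation, per-peptide variance
heterogeneity (real replicate error grows with signal strength — the
corner-based null absorbs this conservatively rather than modelling it),
and sequence-composition-dependent stickiness. Passing tests therefore
demonstrate the correctness and calibration of the *pipeline logic* under
its stated assumptions, not robustness to every artefact of real scanner
data.

## Problem sizes used by the test suite

The statistical guarantees are exercised at sizes chosen to make the
relevant estimates stable: FDR control on 200 null arrays of ~100 toxins /
2,000 unique peptides / 200 corner fields each; re-incubation recovery for
true factors {2, 3, 4.3, 6} over 100 seeds at 852 corner fields; bootstrap
sigma against a 10⁶-repetition oracle of the same resampling scheme;
planted-epitope recovery (effect five times the null width, 12 of 40
carriers) over 100 simulations with a ≥95% recovery requirement; and exact
brute-force oracle equivalence for the step-up rule, the running median and
the Hamming similarity scan.

## Known limitations

* The pipeline detects *linear* epitope elements only; conformational
  epitopes with no sufficiently long linear stretch are invisible, so a
  non-recognized toxin is not evidence of absent antibodies.
* `sigma` is global; there is no per-peptide variance model.
* The alignment is consumed, not computed; segment coordinates inherit any
  alignment errors.
* The similarity sum counts all matching 15-mers whether or not they are
  individually significant; with `max_mismatch = 3` on highly redundant
  families this can include genuinely unbound peptides, which is intended
  (they anchor the low end of the ranking) but means the sums are not
  purely "significant mass".

## A minimal run

```{r, eval = FALSE}
cfg <- epimap_config(
  out_dir = "run1", seed = 1, corner_field_count = 200, n_boot = 10000,
  simulate = list(n_toxins = 40, length_range = c(40, 40),
                  n_epitopes = 1, n_carriers = 12))
res <- run_pipeline(cfg)
res$model                      # sigma and the BH score threshold
sum(res$calls$recognized)      # toxins with >= 2 successive significant peptides
```
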