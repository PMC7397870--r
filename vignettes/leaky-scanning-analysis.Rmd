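---
title: "Kozak context strength and the first downstream AUG: methods"
author: "leakyscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kozak context strength and the first downstream AUG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leakyscan)
```

## The biological question

Translation initiation on most eukaryotic mRNAs proceeds by scanning: the
preinitiation complex (PIC) loads at the cap, moves 5′→3′ along the leader,
and initiates at an AUG codon with a probability that depends on the
surrounding sequence — the Kozak context, here taken as positions −6..−1
and +4..+5 around the AUG (+1 is the A). When the annotated start codon
(sAUG) sits in a weak context, a fraction of PICs scans past it ("leaky
scanning") and can initiate at the first downstream AUG (fdAUG). If the
fdAUG is in frame with the sAUG, the product is an N-terminally truncated
proteoform; if it is out of frame, a nested ORF is translated instead.

`leakyscan` packages the comparative analysis of this phenomenon: it
annotates sAUG/fdAUG pairs in a transcript catalog, contrasts strong- and
weak-context cohorts (fdAUG frame proportions, spacer distances, nested ORF
lengths, fdAUG context strength), quantifies evolutionary selection on
context strength with a per-gene score over ortholog panels, measures
initiation downstream of the sAUG in ribosome-profiling footprint tracks,
and evaluates proteomic support for truncated proteoforms by in-silico
tryptic digestion. A synthetic-data generator with exported ground truth
closes the loop: every stage can be tested for parameter recovery end to
end.

## Context strength: TIE tables and the synthetic context model

Context strength is a translation initiation efficiency (TIE): a positive
scalar per 11-nt context, on an arbitrary linear scale. Measured tables
(e.g. from FACS-seq experiments) are loaded from two-column TSV
(`context<TAB>tie`); lookups of absent contexts are explicit misses (`NA`),
never silently zero, so downstream stages can count and drop them the same
way catalog filtering drops flank-deficient starts.

For simulation and self-contained testing the package ships a
deterministic parametric model: `TIE = base × ∏ w[position, nucleotide]`
over the eight flank positions (−6..−1, +4, +5), with multipliers in
(0, 1]. The default weights are a modeling choice constrained by two
published facts: the strongest contexts form the degenerate pattern
`RYMRMVAUGGC`, and the −3 and +4 positions dominate the dynamic range. We
therefore give every nucleotide consistent with the optimum a multiplier of
1 and assign the smallest multipliers at −3 (down to 0.45) and +4 (down to
0.6); the remaining positions vary mildly (0.75–1). `base = 150` sets the
scale of the optimal context. The arg-max set of the model over all 4^8
flank combinations equals the degenerate optimum exactly, a property the
test suite verifies by exhaustive enumeration. The weights are
configuration, not truth: any 8×4 matrix satisfying the invariants can be
supplied.

## Catalog annotation

Coordinates are 0-based half-open throughout; 1-based numbers appear only
in rendered reports. Filtering applies, in order: an AUG must sit at the
annotated CDS start; at least 6 nt of leader must precede it (the context
window requires it); an fdAUG must exist inside the CDS, where "inside"
means the codon fits fully before the CDS end (`p + 3 ≤ cds_end`) — the
strictest reading of "in the CDS"; and within each gene, transcripts whose
stretch from 6 nt upstream of the sAUG through 15 nt past the fdAUG codon
is identical are collapsed to the longest (ties broken by lexicographically
smallest id, for determinism). A CDS whose length is not divisible by 3 is
malformed input and is rejected with its own reason rather than silently
truncated. Whether "15 nt downstream of the fdAUG" counts from the A or
from the end of the codon is not fixed by convention; we count from the end
of the codon.

The spacer is the A-to-A distance `fdaug_pos − saug_pos`, which makes
`frame = spacer mod 3` an identity rather than an approximation. The
distance from an fdAUG to its stop codon counts coding nucleotides only and
scans to the transcript end, not the CDS end, because out-of-frame nested
ORFs legitimately terminate inside the 3′ UTR. Transcripts whose CDS
contains no AUG after the sAUG can instead be scanned for the first AUG at
or beyond the CDS end (`scan_downstream_of_cds`), the rare
fdAUG-in-3′-UTR configuration.

## Cohorts and comparisons

Strong and weak cohorts are the top and bottom `round(fraction × N)`
transcripts by sAUG TIE (round half away from zero: a catalog of 18,297
gives cohorts of exactly 1830). Ties are broken by transcript id so that
membership is a pure function of the data.

Statistical choices, where the convention is not forced:

* The frame-0 enrichment test is a 2×2 chi-squared (frame 0 vs not,
  strong vs weak) without continuity correction. A 2×3 test would dilute
  the single contrast of interest; this is flagged as an interpretation.
* Rank-sum comparisons (spacer distances, ORF lengths, window densities,
  TIESS strata) are two-sided Mann–Whitney U tests: exact when both sides
  have ≤ 50 observations and no ties, otherwise the normal approximation
  with tie correction. Degenerate all-equal input returns p = 1.
* The fdAUG context-strength comparison is Welch's unequal-variance t-test:
  cohort variances are not known to be equal, so the pooled-variance form
  would assume too much.

Distance distributions are heavy-tailed; plots use log10 axes, but the rank
tests are invariant to that transform, so the choice affects only display.

## The selection score over ortholog panels

For a gene with ortholog contexts *i* = 1..n (reference included by
default; `exclude_reference` removes it), the score is

TIESS = Σᵢ log₁₀(TIEᵢ / TIE̅),

where TIE̅ is the arithmetic mean TIE over *all* scoreable (gene, species)
contexts in the collection — a mean of TIEs, not of their logs. The score
is strongly positive when a gene's context is consistently stronger than
average across the phylogeny, strongly negative when consistently weaker,
and near zero when average or inconsistent. An ortholog contributes only
when its aligned position carries an intact AUG and an ungapped 11-mer that
the TIE table resolves; anything else is skipped and excluded from the
ortholog count, and a gene with no scoreable ortholog is absent, never
scored 0. The raw sum is the score — its magnitude grows with ortholog
count, which is intentional (more species agreeing is more evidence) — but
`mean_log_dev = TIESS / n_orthologs` is reported alongside as a
size-independent diagnostic, and `min_orthologs` (default 1) gates scoring
rather than hard-coding a panel-size policy.

Conserved-strong and conserved-weak sets are the top and bottom score
deciles, by the same mechanics as the TIE cohorts. The frame-stratified
comparison then asks, within a conserved set, whether genes with in-frame
fdAUGs score differently from genes with out-of-frame fdAUGs (two-sided
rank-sum); strata smaller than 3 genes are skipped with a logged reason.

## Metagene analysis of footprint tracks

Tracks are per-nt counts in transcript coordinates with reads already
assigned to A-site (elongating) or P-site (initiating) positions.
Normalization is per transcript: counts are binned into codons phased from
the anchor AUG (offset 0 = the anchor codon; the phasing convention is
ours, as codon binning is not otherwise anchored), then divided by the
transcript's average CDS density per codon, so 1 means "average CDS
density". Whether normalization precedes or follows binning is
mathematically irrelevant under this convention. Inclusion requires a CDS
of ≥ 200 nt, ≥ 200 total footprints, and — per anchor — a leader of
≥ 45 nt (sAUG) or a spacer strictly greater than 40 nt (fdAUG, so that
upstream-window density is not contaminated by initiation at the sAUG).
A transcript with zero CDS counts cannot be normalized and is excluded
with its own reason. Profiles are per-offset medians across transcripts;
density windows are −15..−3 codons (upstream) and +10..+44 codons
(downstream), averaged per transcript first and then compared across
cohorts by rank-sum — the reading of "merged from all genes" that keeps
transcripts exchangeable units. In initiating mode the same machinery
applies and the offset-0 peak height is additionally reported, since the
peak at the AUG is the informative feature there.

The `step_change` diagnostic divides the downstream-window mean by the
upstream-window mean, both re-anchored at the fdAUG. Under the leak model
the expectation is `(flux_s + flux_fd) / flux_s`, but only when both
windows lie inside the two constant-flux regions; transcripts whose spacer
is shorter than the upstream window reach (45 nt at the default window)
are flagged `clean = FALSE` and excluded from pooled estimates — a
validity condition of the closed form, not a data-quality judgement. The
pooled estimator takes means across transcripts before the ratio, avoiding
the small-count bias of averaging per-transcript ratios.

## Proteoform support by in-silico digestion

The long proteoform is translated from the sAUG with the standard code;
trypsin cleaves after K or R except before P, with zero missed cleavages
by default (`missed_cleavages` adds concatenations of adjacent fragments).
A peptide is unique to the long form iff its span includes any residue
upstream of the fdAUG-encoded Met — straddling peptides are therefore
unique — and shared otherwise. Detectability is a length window, default
7–30 residues, the common mass-spectrometry heuristic; the criterion is
configurable because no single rule is canonical. The truncated form's own
N-terminal peptide differs from the long form's covering peptide and is
not forced into either class. Observation-frequency summaries report the
median and maximum per class and the shared-to-unique median ratio; a
zero unique median yields an explicit infinity flag.

## The synthetic data generator

The generator's defaults are the study conditions the analysis assumes,
fixed once:

* `p_weak = 0.5`: balanced strong/weak classes.
* `p_frame0_given_weak = 0.524`, `p_frame0_given_strong = 0.380`: the
  observed in-frame fdAUG proportions of the weak and strong decile sets,
  used as generating probabilities so that recovery is testable against
  known truth. Out-of-frame mass splits 80/20 between frames 1 and 2,
  reflecting frame-2 depletion (an A after a frame-2 fdAUG creates a
  frame-0 UGA, which coding sequence avoids).
* Spacers are geometric above a 4-nt minimum with means 60 nt (weak) and
  90 nt (strong); leaders are ≥ 45 nt with geometric excess (mean +25);
  CDS tails after the fdAUG average ~110 codons, placing CDS lengths near
  the human median of roughly 400 codons; 3′ UTRs average ~100 nt.
* Ortholog panels: 50 species, conservation probability `c = 0.9`, 5%
  missing entries. With probability `c` a species draws its context from
  the gene's own stratum (the strong or weak decile pool for
  sAUG-anchored panels; a ±10-percentile band around the reference
  context's rank for fdAUG-anchored panels, where the reference is
  usually mid-distribution), otherwise from the background distribution.
* The leak model is `P_init(TIE) = min(1, TIE / TIE_ref)` with
  `TIE_ref = 150` (the scheme base), so the optimal context captures every
  scanning PIC. Downstream flux is
  `flux_fd = (1 − P_init(sAUG)) × P_init(fdAUG)`.
* Footprint counts are Poisson per nt (negative binomial available via
  `nb_size`; aggregated public data mix many studies, so no single noise
  law is privileged), with expected density `flux_s` between sAUG and
  fdAUG and `flux_s + flux_fd` from fdAUG to the stop, over a small
  uniform background, rescaled per transcript so `depth` (default 0.5) is
  the expected reads per CDS nt. The rescaling is invisible to every
  normalized output and keeps the footprint-count filter comparable
  across flux levels.

Transcripts are built by implanting the sampled contexts and engineered
fdAUG into random sequence, then repairing violations: any AUG between the
sAUG and the engineered fdAUG (in any frame), and any premature in-frame
stop, is broken by setting one non-implanted position to C — a letter that
can participate in neither an AUG nor a stop codon, so repairs cannot
cascade. A final end-to-end verification re-annotates the transcript and
redraws the gene if the engineered structure is not recovered exactly; an
AUG lying wholly inside the sampled sAUG upstream flank is kept, as a
legitimate uAUG that is part of the context itself. At spacers below
~10 nt the sAUG and fdAUG context windows overlap; the fdAUG core wins and
the truth table records the realized contexts and TIEs, so ground truth
remains exact.

What the generator does *not* emulate: uORF regulation, non-AUG starts,
reinitiation, ribosome queueing, codon-level elongation heterogeneity,
species phylogeny (ortholog draws are independent given the gene), and
alignment artifacts. Passing recovery tests therefore demonstrates that
the pipeline measures what the model generates — not that real transcripts
obey the model.

## Problem sizes and numerical conventions

The test suite exercises recovery at the scales the analyses are designed
for: frame-proportion recovery over 20 seeds of 4,000 genes
(cohorts of 2,000 per side, the largest disjoint split), conservation
recovery with 500 + 500 genes × 50 species, metagene recovery with
500-transcript pooled step estimates and 300-per-side cohort contrasts at
0.5 reads per CDS nt, and null calibration of the rank-sum machinery over
1,000 replicates. Cohort sizing uses round-half-away-from-zero (the only
rule consistent with 18,297 → 1,830); all tie-breaks are lexicographic;
comparisons are bit-reproducible given identical inputs, and every
simulation is a pure function of its config seed (panels and the two track
modes derive fixed offsets from it, so stages are independently
reproducible).

## A worked run

```{r example, eval = FALSE}
out <- file.path(tempdir(), "demo")
report <- run_pipeline(out, sim_config(n_genes = 200, seed = 5),
                       fraction = 0.25)
report$fig1a$chi2      # frame-0 enrichment, strong vs weak
report$fig3            # TIESS comparisons by fdAUG frame
report$fig2a$downstream_weak_vs_strong
```

The output directory then contains every intermediate artifact —
`transcripts.fa`, `cds.tsv`, `start_pairs.tsv`, `tiess_*.tsv`, metagene
profiles and `report.json` keyed by figure panel — and re-running with the
same config reproduces all of them byte for byte.

## Known limitations

* The synthetic TIE model is ordinal, not calibrated: it preserves the
  published optimum and position dominance but not measured values, so
  absolute TIE magnitudes carry no units.
* TIESS treats species as exchangeable; branch lengths and phylogenetic
  correlation are out of scope, so the score overweights clades of
  similar genomes in real alignments.
* Footprint tracks must arrive site-assigned; offset calibration from raw
  reads is a separate upstream problem.
* The fdAUG search excludes AUGs overlapping the stop codon boundary
  (`p + 3 ≤ cds_end`); annotations that intend such AUGs to count will
  disagree by at most one codon.
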