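# leakyscan

Coevolution of start-codon Kozak context strength and the position of the
first downstream AUG in mRNA transcripts.

## The problem

Scanning preinitiation complexes do not recognize every AUG they meet: when
the annotated start codon (**sAUG**) sits in a weak Kozak context
(positions −6..−1 and +4..+5 around the AUG; +1 is the A), a fraction of
ribosomes scans past it and can initiate at the **first downstream AUG
(fdAUG)**. Whether the fdAUG lies in frame with the sAUG decides the
outcome — an N-terminally truncated proteoform (in frame) or a nested ORF
in another reading frame. If truncated proteoforms matter, selection should
favour in-frame fdAUGs downstream of weak sAUGs, keep weak contexts weak
where the downstream product is useful, and weaken out-of-frame fdAUG
contexts where it is harmful.

`leakyscan` is an R toolkit for testing these predictions on a transcript
catalog. For researchers in translation regulation it provides:

* **Annotation** — catalog filtering (AUG at the CDS start, ≥ 6 nt leader
  flank, fdAUG inside the CDS, per-gene deduplication by sequence stretch)
  and sAUG/fdAUG pair statistics: frame (`(fdAUG − sAUG) mod 3`), spacer,
  context strings, translation-initiation-efficiency (TIE) lookups,
  fdAUG-to-stop distances.
* **Cohorts** — strong/weak context deciles by sAUG TIE and the standard
  contrasts: frame-0 proportions (2×2 χ², no continuity correction),
  spacer and nested-ORF-length distributions (two-sided Mann–Whitney U),
  fdAUG context strength (Welch's t).
* **Conservation** — a per-gene selection score over ortholog context
  panels,

  `TIESS = Σ_i log10(TIE_i / TIE̅)`,

  summed over orthologs *i*, with TIE̅ the arithmetic mean TIE over all
  sAUG contexts in the collection; conserved-strong/weak decile sets and
  frame-stratified comparisons.
* **Metagene analysis** — per-transcript-normalized, codon-binned
  ribosome-footprint densities anchored at the sAUG or fdAUG (1 = average
  CDS density), median profiles, −15..−3 / +10..+44 codon window means,
  and a leak-model step-change diagnostic at the fdAUG.
* **Proteoform support** — in-silico tryptic digestion (cleave after K/R
  except before P) and classification of peptides as unique to the long
  proteoform or shared with the truncated one.
* **Synthetic data** — a seeded generator for transcripts, ortholog panels
  and footprint tracks under a leaky-scanning model
  (`P_init = min(1, TIE/TIE_ref)`), with exported ground truth for
  end-to-end parameter-recovery testing.

## A worked example

Score a Kozak context and run the whole pipeline on a small synthetic
catalog:

```r
library(leakyscan)

# the 11-nt context around an AUG at 0-based position 9
seq <- "GGCACCGCCAUGGCGAAGCGAUGGCUAA"
ctx <- extract_context(seq, 9)
ctx
#> [1] "ACCGCCAUGGC"
synthetic_tie(ctx)
#> [1] 150        # matches the optimal pattern RYMRMVAUGGC at every position

rep <- run_pipeline(file.path(tempdir(), "demo"),
                    sim_config(n_genes = 200, seed = 5), fraction = 0.25)
str(rep$fig1a$chi2)
#> List of 6
#>  $ test     : chr "chi2_2x2"
#>  $ statistic: num 0.167
#>  $ p_value  : num 0.683
#>  $ n1       : int 50
#>  $ n2       : int 50
str(rep$fig2a$downstream_weak_vs_strong)
#> List of 6
#>  $ test     : chr "rank_sum_two_sided"
#>  $ statistic: num 433
#>  $ p_value  : num 6e-04
#>  $ n1       : int 23
#>  $ n2       : int 24
```

The report keys mirror the analysis panels: `fig1a` (frame proportions and
the χ² contrast), `fig1b`/`fig1c` (spacer and in-frame ORF-length rank
tests), `fig1d` (fdAUG context strength), `supp_s1` (nested ORF lengths),
`fig2a`/`fig2b` (elongating/initiating window-density contrasts), `fig3`
(TIESS by fdAUG frame within conserved sets), `fig4e` (peptide
classification counts). At 200 genes the χ² is underpowered (p = 0.68, as
printed above) — the frame-0 effect needs thousands of transcripts, which
is what the acceptance script runs — while the footprint-density contrast
downstream of the fdAUG is already detected (p = 6e-04): the weak-sAUG
cohort shows the higher downstream density, the signature of leaky
scanning. The output directory holds every intermediate file
(`transcripts.fa`, `cds.tsv`, `start_pairs.tsv`, `tiess_*.tsv`, metagene
profiles, `report.json`); re-running with the same config reproduces them
byte for byte.

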