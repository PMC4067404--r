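---
title: "Methods: simulating, annotating and comparing tissue antibody repertoires"
author: "tissuerep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, annotating and comparing tissue antibody repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissuerep)
```

## The problem

Expressed antibody heavy-chain repertoires differ between body compartments:
mucosal tissues (gut, lung, stomach) harbour B-cell populations whose V(D)J
gene usage, somatic hypermutation (SHM) load, HCDR3 geometry and
hypermutation-associated (SHA) indel burden depart from what circulating
blood B cells show. Quantifying those contrasts from amplicon sequencing of
pooled tissue RNA requires a chain of steps — germline gene assignment,
sequencing-error correction, antibody-specific quality filtering, duplicate
collapse, descriptive repertoire metrics, and cross-sample statistics —
each of which this package implements as a tested, reusable unit. Because
the motivating kind of raw 454 data is not generally obtainable, the
package also ships a synthetic repertoire generator that produces read
pools with the same statistical structure *plus per-read ground truth*, so
every stage of the pipeline can be validated by recovery rather than by
eyeballing.

## The synthetic generator

`simulate_repertoire()` draws, per read:

1. **Recombination** — V, D and J genes from configurable usage vectors;
   exonuclease trimming of the V 3' end (0–6 nt), both D ends (0–3 nt each)
   and the J 5' end (0–9 nt); untemplated N regions (0–6 nt each side).
   Junction frame is controlled: clean reads are padded to an in-frame
   junction, reads labelled `frameshift` get a broken frame.
2. **SHM** — per-base substitutions at per-region rates (FR1/CDR1/FR2/
   CDR2/FR3), with a configurable `naive_fraction` of unmutated reads
   producing the bimodal mutation-load shape of blood (naive-rich) versus
   mucosa (almost none unmutated).
3. **SHA indels** — whole-codon insertions/deletions at codon boundaries,
   at per-codon per-region rates biased into CDR1/CDR2. Codon-length events
   keep the reading frame, which is what distinguishes them from
   sequencing artifacts.
4. **Sequencing noise** — 454-style homopolymer over/under-calls: one
   extra or one missing base in runs of ≥3 identical bases, at a
   per-eligible-run probability (default 0.0017, roughly one error per
   2 kb of run sequence; the real error rate of the platform is not a
   published constant, so this is a config choice).
5. **Defects** — fractions of reads made too short (truncated to 150–295
   nt), junction-frameshifted, or carrying an ambiguous `N` in the
   junction; defaults (2.5/2.5/1.5%) put the failing fraction near the
   6–8% seen in real tissue pools.

The default study conditions used by the tests and the acceptance script
are: 7 V families × 3 genes, 10 D, 6 J (the toy reference of
`build_toy_germline_set()`), pools of 10,000 reads for recovery checks and
20,000 for positional indel recovery, and per-tissue presets
(`tissue_sim_configs()`) whose naive fractions (30.6% blood, 7% lymphoid,
1.4% mucosa), V-family biases, N-length shifts and indel multipliers move
each metric in the direction reported for the respective tissue classes.
Preset magnitudes are qualitative emulations, not fits.

### Truth identifiability

Ground truth is only meaningful if an optimal aligner can in principle
recover it. Three generator rules guarantee that, and all three are
deliberate design choices rather than simplifications of convenience:

* SHA indels are planted only at sites where no shift-equivalent gap
  placement exists (the flanking germline bases differ across the event
  window), inserted codons are resampled until they cannot slide, and two
  events never sit in adjacent codons (an insertion next to a deletion is
  indistinguishable from three substitutions).
* Substitutions are not planted in the codon carrying, or adjacent to, an
  indel event.
* Homopolymer errors are planted only in runs that are germline-templated
  (V or J portion of the read), untouched by SHM within a 4-base flank —
  an error in the untemplated junction has no germline reference against
  which any codon-based correction could operate, and an SHM mutation near
  a run lets an aligner re-parse error+mutation as a single indel at the
  mutation site (an equal-score tie).

What passing recovery tests therefore show is that the annotator inverts
the generator exactly on identifiable reads; they do not show that real
454 data is free of intrinsically ambiguous alignments — it is not, and on
real data the corresponding reads would simply fail filters or carry a
slightly wrong mutation count. The generator also omits clonal lineage
structure, quality scores, chimeric PCR artifacts and SHM hotspot motifs
(substitutions are uniform over the three alternative bases).

## Annotation

`annotate_reads()` is a self-contained stand-in for a web-service
annotator. Per read:

* **V call** — best affine-gap local alignment (match +2, mismatch −2, gap
  open 6, gap extend 1; a gap of length L costs `open + L·ext`) over all V
  genes, computed in C++; minimum overlap 100 nt and minimum score 100,
  otherwise the read's reverse complement is tried and failing both the
  V call is absent. Ties break by identity, then alignment length, then
  name. The alignment is extended leftwards 1:1 to the read/gene start
  (recombination never trims the V 5' end, so terminal mismatches are
  real mutations, not clippable overhang).
* **Homopolymer correction** — a single-nucleotide gap inside a germline
  run of ≥3 identical bases is corrected back to the germline run length
  (such gaps shift the reading frame; codon-length gaps are never
  touched). Applied to the V and J alignments; corrections are counted
  per read.
* **J call** — same search over J genes, restricted to the read 3' of the
  V alignment (minimum overlap 20, score 30). The J alignment is extended
  to the read 3' end by a global alignment of the remainders: the J 3'
  side is never trimmed by recombination, so trailing read sequence is J
  template and a terminal homopolymer error must surface as a gap rather
  than be clipped.
* **D call** — longest ungapped exact match (≥5 nt) between the junction
  interior and each D gene.
* **Junction/CDR3** — the conserved Cys and Trp anchor codons are part of
  the germline annotation and are projected through the alignments;
  `in_frame` requires junction length divisible by 3 *and* no residual
  frameshift in the V alignment; CDR3 is translated only for in-frame,
  `N`-free junctions. Whether "in-frame" should additionally require
  absence of stop codons is left open by the source conventions; the
  package computes `productive_stop_free` and reports it but does not
  filter on it.
* **Mutations and SHA indels** — counted on the corrected alignment,
  substitutions only, within the FR/CDR intervals of the germline region
  map (the junction is excluded — the region-resolved analysis covers
  FR1–FR3/CDR1–2 only, and junction-proximal mismatches are dominated by
  junctional diversity, not SHM). Gap runs that are a positive multiple
  of 3 become SHA indel events at their 1-based V-codon start; all gaps
  are left-normalized first so shift-equivalent placements report
  identically; other gap lengths set a frameshift flag.

Genuinely ambiguous blind spots remain at the trimmed edges (V 3', J 5'):
a 1-nt error within ~3 nt of a local-alignment edge can be clipped instead
of gapped. These edges are a few nucleotides of a ~340-nt templated span,
which is why the correction-recovery criterion is set at 95% rather
than 100%.

## Filtering and collapse

A read passes iff length > 300 nt (strict), V, D and J are all assigned,
the junction is in frame, and the junction has no ambiguous base. Failing
reads are tallied under their *first* failing reason in the fixed order
short → no V → no D → no J → out of frame → ambiguous junction, making
reports reproducible. Identical full-length sequences are then collapsed
per sample to one representative with a copy count; sequences differing at
a single base are deliberately kept (plasma-cell transcripts resequenced
with errors cannot be distinguished from true variants at this stage).
Percentages are rounded half-up to two decimals, and the bundled
`tissue_read_counts()` table reproduces the published per-tissue and total
percentages exactly from raw counts.

## Metrics

All metrics run on the unique (collapsed) set. Usage tables
(`usage_frequencies()`) are counts column-normalized per sample at the
V-family, D-family, J-gene or V(D)J-combination level. Mutation profiles
report a width-1 histogram of total mutation counts (the alternative
x-axis, percent identity, is also derivable from the reported per-region
frequencies), the fraction of sequences with fewer than 5 mutations, and
mean per-base mutation frequency per region. HCDR3 profiles split at 14/15
aa (≤14 short, ≥15 long), and report pooled residue-class frequencies with
explicit, overridable sets — hydrophobic {A,C,F,I,L,M,V,W,Y} (Kyte–
Doolittle-positive plus aromatics) and charged {D,E,H,K,R} (ionizable side
chains); the sets are echoed in the output because no single convention is
universal. Positional indel maps count, per V codon, the percent of
sequences with an event *starting* there (multi-codon events contribute
once, at their start, to avoid double counting), with an optional
elementwise difference against a reference repertoire.

## Cross-sample comparison

Features are first filtered (total count ≥ 10 and frequency variance
strictly > 0 by default — the thresholds are config since "low counts of
low variation" is not a number). Distances are 1 − Pearson r, clustered by
complete linkage (`stats::hclust`); a brute-force merge enumeration serves
as the test oracle. Heatmap values are per-feature z-scores with the
population (denominator-n) standard deviation, truncated to [−3, 3].

Differential V(D)J usage uses a negative-binomial log-linear model with
library-size offsets: for feature f, `y_fj ~ NB(s_j · m_g(j), phi_f)`,
tested by the likelihood-ratio statistic of the two-group model against a
common mean, against chi-square with 1 df. Dispersion is estimated per
feature by maximizing the Cox–Reid adjusted profile likelihood on a
log-spaced grid, with weighted-likelihood shrinkage toward the common
curve: the maximized criterion is `APL_f(phi) + (prior_df / resid_df) ·
mean APL(phi)`, prior_df = 10 by default. This is a deliberately simpler,
self-contained empirical-Bayes scheme in the spirit of the standard count
GLM packages; it is calibrated by simulation (null rejection 0.044 at
nominal 0.05 with 1,000 features, 2×4 samples, dispersion 0.1) and
cross-checked against edgeR at fixed dispersion in the test suite. Designs
without replication cannot estimate dispersion: it is then fixed at a
config value (0.1) with a loud warning. Fold changes are reported as group
2 over group 1 from fitted mean counts at the geometric-mean library size
with a 0.5 pseudo-count (reporting only, so zero counts stay finite), in
log2 and log10. BH q-values come from `stats::p.adjust`.

## Numerical choices and degenerate inputs

* Alignment scoring and thresholds are config (`align_params()`); the
  defaults above are stringent at 454 read lengths.
* Gap left-normalization is the single tie-break convention shared by
  generator and annotator.
* A constant feature row reaching heatmap standardization is an error
  (`zero_variance_row`), not a silent NaN; the feature filter removes such
  rows upstream.
* All-zero count features are reported as NA by the NB test.
* Empty filter input yields a zero report, not an error; collapse of an
  empty set is empty.
* Every simulation is a pure function of its config (one RNG stream per
  pool, seeded from the config; the caller's RNG state is restored).

## Problem sizes

The test suite simulates pools of 150–600 reads for unit checks, one
shared pool of 10,000 annotated reads for the at-scale recovery checks,
and 20,000 generator-level reads for positional indel recovery; the
differential-usage calibration uses 1,000 features × 8 samples. The
analysis drivers under `analysis/` use 1,500 reads per tissue across six
tissues. These sizes give the Monte-Carlo checks standard errors an order
of magnitude below their tolerances while keeping a full run of tests plus
acceptance script in a few minutes on one CPU.

## Known limitations

* The annotator is a stand-in: no IMGT unique numbering, no allele-level
  calls, no clonal clustering, no isotype assignment.
* The toy germline reference is synthetic; real references are supplied as
  FASTA + region table (`load_germline_set()`), with allele nomenclature
  and pseudogene handling out of scope.
* Tissue presets reproduce directions and rough magnitudes of published
  tissue contrasts, not their exact percentages — the underlying raw data
  has no public accession, so those numbers are not reproducible targets.
* Single-sample-per-group differential tests depend entirely on the
  assumed dispersion; treat their p-values as descriptive.
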