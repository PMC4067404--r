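# tissuerep

Analysis pipeline for expressed antibody heavy-chain variable-gene
repertoires from tissue RNA pools, for immunologists comparing B-cell
repertoires across body compartments (peripheral blood, bone marrow,
mucosal and lymphoid tissues). The package covers the full chain from
reads to cross-tissue statistics, and ships a synthetic repertoire
generator with per-read ground truth so every stage is validated by
recovery.

## What it computes

* **Germline reference** — V/D/J segments with FR1–FR3/CDR1–2 region maps
  and conserved Cys/Trp anchor codons (`load_germline_set()`, or the
  deterministic toy reference `build_toy_germline_set()`).
* **Simulation** — V(D)J recombination with trimming and N regions,
  per-region somatic hypermutation (SHM), codon-length SHM-associated
  (SHA) indels, 454-style homopolymer errors, and defective reads, with a
  ground-truth record per read (`simulate_repertoire()`, per-tissue
  presets in `tissue_sim_configs()`).
* **Annotation** — affine-gap local alignment (C++ core) for V/J calls,
  ungapped-core D calls, codon-based homopolymer error correction,
  junction/CDR3 extraction from anchor codons, per-region mutation counts
  and SHA indel events (`annotate_reads()`).
* **Quality filtering** — reads pass iff length > 300 nt, V, D and J
  assigned, in-frame junction, no ambiguous junction base; first-reason
  failure tallies; duplicate collapse to unique sequences
  (`apply_filters()`, `collapse_identical()`).
* **Repertoire metrics** — gene-family usage tables, mutation-load
  profiles (fraction with < 5 mutations, per-region mutation frequency),
  HCDR3 length split at 14/15 aa with hydrophobic/charged residue
  frequencies, and per-codon SHA indel maps with differences against a
  reference repertoire.
* **Comparison** — for feature-by-sample count matrices: low-count/
  low-variation filtering, Pearson correlation distance d = 1 − r,
  complete-linkage clustering of features and samples, row-standardized
  heatmap values truncated to [−3, 3], and differential V(D)J usage by a
  negative-binomial GLM likelihood-ratio test,
  `y_fj ~ NB(s_j · m_g(j), phi_f)`, with adjusted-profile-likelihood
  dispersion estimates shrunk toward the common dispersion, chi-square
  (1 df) p-values and Benjamini–Hochberg FDR (`nb_glm_lrt()`, `bh_fdr()`,
  `compare_repertoires()`).

The methods vignette (`vignettes/tissuerep-methods.Rmd`) documents the
models, the generator's truth-identifiability rules, parameter defaults
and known limitations.

## Worked example

Simulate a blood-like and a gut-like pool, annotate, filter and profile:

```r
library(tissuerep)
gl <- build_toy_germline_set(7, 3, 10, 6, seed = 1)
cfgs <- tissue_sim_configs(gl, n_reads = 500,
                           tissues = c("peripheral_blood", "small_intestine"),
                           seed = 1)
for (tissue in names(cfgs)) {
  pool <- simulate_repertoire(cfgs[[tissue]], gl)
  ann  <- annotate_reads(pool$reads, gl)
  fl   <- apply_filters(ann, sample_name = tissue)
  print(fl$report)
  uniq <- collapse_identical(fl$passed)
  mp <- mutation_profile(uniq); cp <- cdr3_profile(uniq)
  cat(sprintf("  <5 mutations: %.1f%%   mean HCDR3: %.1f aa   long (>=15 aa): %.1f%%\n",
              100 * mp$low_mutation_fraction, cp$mean_length, 100 * cp$long_fraction))
}
```

```
peripheral_blood: 478/500 reads pass (95.60% high quality)
  failures: short=7, out_of_frame=6, ambiguous_junction=9
  <5 mutations: 59.0%   mean HCDR3: 11.4 aa   long (>=15 aa): 8.2%
small_intestine: 463/500 reads pass (92.60% high quality)
  failures: short=13, out_of_frame=17, ambiguous_junction=7
  <5 mutations: 10.8%   mean HCDR3: 12.9 aa   long (>=15 aa): 25.5%
```

Reading this: ~93–96% of reads survive the antibody-specific filters
(defective reads fail under their first failing reason); the blood pool is
naive-rich (59% of unique sequences carry fewer than 5 mutations) while
the gut pool is heavily mutated (11%), and gut HCDR3s run longer — the
directional contrasts the per-tissue presets plant.

The numbered drivers under `analysis/` run the same pipeline as a
narrative workflow over six tissue pools (simulate → annotate/filter →
metrics → compare) and write their tables under `results/`.

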