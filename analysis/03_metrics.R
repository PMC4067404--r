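#!/usr/bin/env Rscript
# Stage 3: per-tissue descriptive repertoire features — V-family usage,
# mutation-load profiles, HCDR3 length/physicochemistry, positional SHA
# indel maps with peripheral blood as the reference repertoire.

library(tissuerep)

files <- list.files("results/annotations", pattern = "_unique\\.tsv$", full.names = TRUE)
anns <- lapply(files, read.delim, stringsAsFactors = FALSE)
names(anns) <- sub("_unique\\.tsv$", "", basename(files))
dir.create("results/metrics", showWarnings = FALSE)

pooled <- do.call(rbind, anns)

# family usage across tissues
u <- usage_frequencies(pooled, "v_family")
write.csv(cbind(family = rownames(u$freq), as.data.frame(round(u$freq, 4))),
          "results/metrics/v_family_usage.csv", row.names = FALSE)
message("V-family usage (columns sum to 1):")
print(round(u$freq, 3))

# mutation profiles
mut <- t(vapply(anns, function(a) {
  mp <- mutation_profile(a)
  c(low_mutation_fraction = mp$low_mutation_fraction, mp$region_mean_freq)
}, numeric(6)))
write.csv(cbind(tissue = rownames(mut), as.data.frame(round(mut, 4))),
          "results/metrics/mutation_profiles.csv", row.names = FALSE)
message("fraction of sequences with <5 mutations, per tissue:")
print(round(mut[, "low_mutation_fraction"], 3))

# HCDR3 profiles
cdr3 <- t(vapply(anns, function(a) {
  cp <- cdr3_profile(a)
  c(mean_length = cp$mean_length, short = cp$short_fraction,
    long = cp$long_fraction, hydrophobic = cp$hydrophobic_residue_freq,
    charged = cp$charged_residue_freq)
}, numeric(5)))
write.csv(cbind(tissue = rownames(cdr3), as.data.frame(round(cdr3, 4))),
          "results/metrics/cdr3_profiles.csv", row.names = FALSE)
message("HCDR3 long fraction (>= 15 aa), per tissue:")
print(round(cdr3[, "long"], 3))

# positional indel maps, differenced against peripheral blood
ref <- indel_positional_profile(anns$peripheral_blood, v_codon_count = 96)
for (tissue in setdiff(names(anns), "peripheral_blood")) {
  ip <- indel_positional_profile(anns[[tissue]], 96, reference = ref)
  write.csv(data.frame(codon = 1:96,
                       insertion_freq = ip$insertion_freq,
                       deletion_freq = ip$deletion_freq,
                       insertion_diff_vs_blood = ip$insertion_diff,
                       deletion_diff_vs_blood = ip$deletion_diff),
            sprintf("results/metrics/indel_profile_%s.csv", tissue),
            row.names = FALSE)
}
tot <- vapply(anns, function(a) {
  ip <- indel_positional_profile(a, 96)
  sum(ip$insertion_freq) + sum(ip$deletion_freq)
}, 0)
message("total SHA indel burden (% sequences, summed over codons):")
print(round(tot, 2))
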