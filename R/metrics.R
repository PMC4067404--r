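#' Gene-usage count and frequency table
#'
#' Tallies usage over unique (collapsed) sequences at the requested level:
#' V family, D family, J gene, or full V(D)J gene combination. Sequences
#' lacking a call at the level are dropped. Frequencies are column-
#' normalized per sample.
#'
#' @param unique_set data.frame of collapsed annotations, optionally with a
#'   `sample` column (a single unnamed sample is assumed otherwise).
#' @param level One of `"v_family"`, `"d_family"`, `"j_gene"`,
#'   `"vdj_combo"`.
#' @return Object of class `usage_table`: `list(level, counts, freq)` with
#'   features in rows and samples in columns.
#' @export
usage_frequencies <- function(unique_set,
                              level = c("v_family", "d_family", "j_gene", "vdj_combo")) {
  level <- match.arg(level)
  feature <- switch(level,
    v_family = unique_set$v_family,
    d_family = unique_set$d_family,
    j_gene = unique_set$j_call,
    vdj_combo = ifelse(is.na(unique_set$v_call) | is.na(unique_set$d_call) |
                         is.na(unique_set$j_call), NA,
                       paste(unique_set$v_call, unique_set$d_call,
                             unique_set$j_call, sep = "_")))
  sample <- if ("sample" %in% names(unique_set)) unique_set$sample
            else rep("sample", nrow(unique_set))
  keep <- !is.na(feature)
  tab <- table(feature = feature[keep], sample = sample[keep])
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  freq <- sweep(counts, 2, pmax(colSums(counts), 1), "/")
  structure(list(level = level, counts = counts, freq = freq),
            class = "usage_table")
}

#' @export
print.usage_table <- function(x, ...) {
  cat("usage_table (", x$level, "): ", nrow(x$counts), " features x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Mutation-load profile of a repertoire
#'
#' Histogram of sequences per total-mutation-count bin, the fraction of
#' sequences with fewer than `low_threshold` mutations (a proxy for naive
#' B-cell content), and the mean per-base mutation frequency for each V
#' region (region mismatches divided by aligned region length, averaged
#' over sequences).
#'
#' @param unique_set data.frame of collapsed annotations.
#' @param low_threshold Count below which a sequence is "low mutation"
#'   (strict: the default 5 counts 0-4).
#' @param bin_width Histogram bin width in mutation counts.
#' @return Object of class `mutation_profile`: `list(histogram,
#'   low_mutation_fraction, region_mean_freq, n)`.
#' @export
mutation_profile <- function(unique_set, low_threshold = 5, bin_width = 1) {
  tm <- unique_set$total_mutations
  tm <- tm[!is.na(tm)]
  n <- length(tm)
  bin <- (tm %/% bin_width) * bin_width
  histogram <- table(factor(bin, levels = seq(0, max(c(bin, 0)), by = bin_width)))
  region_cols <- c(FR1 = "mut_fr1", CDR1 = "mut_cdr1", FR2 = "mut_fr2",
                   CDR2 = "mut_cdr2", FR3 = "mut_fr3")
  len_cols <- c(FR1 = "len_fr1", CDR1 = "len_cdr1", FR2 = "len_fr2",
                CDR2 = "len_cdr2", FR3 = "len_fr3")
  region_mean_freq <- vapply(names(region_cols), function(r) {
    m <- unique_set[[region_cols[[r]]]]
    l <- unique_set[[len_cols[[r]]]]
    ok <- !is.na(m) & !is.na(l) & l > 0
    if (!any(ok)) return(NA_real_)
    mean(m[ok] / l[ok])
  }, 0)
  structure(list(
    histogram = histogram,
    low_mutation_fraction = if (n > 0) mean(tm < low_threshold) else NA_real_,
    region_mean_freq = region_mean_freq,
    n = n
  ), class = "mutation_profile")
}

#' Default HCDR3 residue classes
#'
#' Hydrophobic residues follow a Kyte-Doolittle-positive convention plus
#' the aromatics; charged residues are those with ionizable side chains
#' (histidine included). Both sets are overridable wherever they are used
#' and are echoed in profile output so the convention is always explicit.
#'
#' @export
hydrophobic_residues <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

#' @rdname hydrophobic_residues
#' @export
charged_residues <- c("D", "E", "H", "K", "R")

#' HCDR3 length and physicochemical profile
#'
#' Computed over in-frame, ambiguity-free CDR3 amino-acid sequences only.
#' The repertoire is split at `short_max`: short CDR3s have length <=
#' `short_max`, long ones length >= `short_max + 1`, so
#' `short_fraction + long_fraction = 1`. Residue-class frequencies are
#' pooled over all CDR3 residues.
#'
#' @param unique_set data.frame of collapsed annotations.
#' @param short_max Largest length (aa) still counted as short.
#' @param hydrophobic_set,charged_set Residue classes, echoed in the output.
#' @return Object of class `cdr3_profile`: length histogram, mean length,
#'   short/long fractions, residue-class frequencies, `n`, and the residue
#'   sets used.
#' @export
cdr3_profile <- function(unique_set, short_max = 14,
                         hydrophobic_set = hydrophobic_residues,
                         charged_set = charged_residues) {
  aa <- unique_set$cdr3_aa
  aa <- aa[!is.na(aa) & nzchar(aa)]
  len <- nchar(aa)
  n <- length(aa)
  residues <- unlist(strsplit(aa, ""))
  structure(list(
    length_histogram = table(factor(len, levels = seq(0, max(c(len, 0))))),
    mean_length = if (n > 0) mean(len) else NA_real_,
    short_fraction = if (n > 0) mean(len <= short_max) else NA_real_,
    long_fraction = if (n > 0) mean(len > short_max) else NA_real_,
    hydrophobic_residue_freq = if (length(residues))
      mean(residues %in% hydrophobic_set) else NA_real_,
    charged_residue_freq = if (length(residues))
      mean(residues %in% charged_set) else NA_real_,
    n = n,
    hydrophobic_set = hydrophobic_set,
    charged_set = charged_set
  ), class = "cdr3_profile")
}

#' Positional SHA indel profile
#'
#' For each V-local codon position, the percentage of sequences carrying at
#' least one insertion (resp. deletion) event starting at that codon; an
#' event contributes at its start codon only. Optionally also returns the
#' elementwise difference against a reference repertoire's profile (tissue
#' minus reference).
#'
#' @param unique_set data.frame of collapsed annotations with encoded
#'   `sha_indel_events`.
#' @param v_codon_count Number of V codons to profile over.
#' @param reference Optional `indel_profile` to difference against.
#' @return Object of class `indel_profile`: `insertion_freq` and
#'   `deletion_freq` (percent, length `v_codon_count`), `n`, and, when a
#'   reference is supplied, `insertion_diff`/`deletion_diff`.
#' @export
indel_positional_profile <- function(unique_set, v_codon_count, reference = NULL) {
  n <- nrow(unique_set)
  ins <- numeric(v_codon_count)
  del <- numeric(v_codon_count)
  if (n > 0) {
    for (i in seq_len(n)) {
      ev <- decode_indels(unique_set$sha_indel_events[i])
      if (nrow(ev) == 0) next
      for (ty in c("insertion", "deletion")) {
        codons <- unique(ev$codon[ev$type == ty & ev$codon <= v_codon_count])
        if (length(codons)) {
          if (ty == "insertion") ins[codons] <- ins[codons] + 1
          else del[codons] <- del[codons] + 1
        }
      }
    }
    ins <- 100 * ins / n
    del <- 100 * del / n
  }
  out <- list(insertion_freq = ins, deletion_freq = del, n = n)
  if (!is.null(reference)) {
    out$insertion_diff <- ins - reference$insertion_freq
    out$deletion_diff <- del - reference$deletion_freq
  }
  structure(out, class = "indel_profile")
}
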