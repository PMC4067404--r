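#' Apply antibody-specific quality filters
#'
#' A read passes iff its length exceeds `min_length` (strictly: 301 passes,
#' 300 fails), V, D and J calls are all present, the junction is in frame,
#' and the junction contains no ambiguous nucleotide. Each failing read is
#' tallied under its first failing reason, in the fixed order
#' short, no_v, no_d, no_j, out_of_frame, ambiguous_junction, which makes
#' the report deterministic. Reads with an absent junction count as
#' out_of_frame. Filtering is idempotent.
#'
#' @param annotations data.frame from [annotate_reads()].
#' @param min_length Minimum read length, exclusive (default 300).
#' @param sample_name Label carried into the report.
#' @return `list(passed, report)`: the passing subset of `annotations` and
#'   a `filter_report` (n_raw, n_pass, pct_high_quality, per-reason counts).
#' @export
apply_filters <- function(annotations, min_length = 300, sample_name = "sample") {
  n <- nrow(annotations)
  reasons <- c("short", "no_v", "no_d", "no_j", "out_of_frame", "ambiguous_junction")
  if (n == 0) {
    report <- structure(list(sample = sample_name, n_raw = 0L, n_pass = 0L,
                             pct_high_quality = NA_real_,
                             failures = setNames(integer(6), reasons)),
                        class = "filter_report")
    return(list(passed = annotations, report = report))
  }
  fail_reason <- rep(NA_character_, n)
  mark <- function(cond, reason) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(fail_reason) & cond, reason, fail_reason)
  }
  fail_reason <- mark(annotations$read_length <= min_length, "short")
  fail_reason <- mark(is.na(annotations$v_call), "no_v")
  fail_reason <- mark(is.na(annotations$d_call), "no_d")
  fail_reason <- mark(is.na(annotations$j_call), "no_j")
  fail_reason <- mark(!annotations$in_frame, "out_of_frame")
  fail_reason <- mark(annotations$has_ambiguous_junction, "ambiguous_junction")
  passed <- annotations[is.na(fail_reason), , drop = FALSE]
  rownames(passed) <- NULL
  tab <- table(factor(fail_reason, levels = reasons))
  report <- structure(list(
    sample = sample_name, n_raw = n, n_pass = nrow(passed),
    pct_high_quality = round_half_up(100 * nrow(passed) / n, 2),
    failures = setNames(as.integer(tab), reasons)
  ), class = "filter_report")
  list(passed = passed, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("%s: %d/%d reads pass (%.2f%% high quality)\n",
              x$sample, x$n_pass, x$n_raw, x$pct_high_quality))
  f <- x$failures[x$failures > 0]
  if (length(f)) cat("  failures:", paste(names(f), f, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Collapse identical sequences
#'
#' Reduces reads with byte-identical full-length nucleotide sequence to one
#' representative (the first occurrence) with its multiplicity, limiting the
#' repertoire-skewing effect of high copy-number plasma-cell transcripts.
#' Sequences differing at even one base are kept separate. Collapse is
#' per-sample.
#'
#' @param passed data.frame of passing annotations (needs a `sequence`
#'   column).
#' @return The unique subset with an added `copy_count` column.
#' @export
collapse_identical <- function(passed) {
  if (nrow(passed) == 0) {
    passed$copy_count <- integer(0)
    return(passed)
  }
  grp <- match(passed$sequence, unique(passed$sequence))
  keep <- !duplicated(grp)
  out <- passed[keep, , drop = FALSE]
  out$copy_count <- as.integer(table(grp)[as.character(grp[keep])])
  rownames(out) <- NULL
  out
}

#' Build a per-sample read-statistics table
#'
#' One row per sample with raw and passing read counts and the percentage of
#' high-quality reads, plus a Total row summing counts with the percentage
#' recomputed from the totals. Percentages are rounded half-up to 2
#' decimals.
#'
#' @param reports Either a list of `filter_report` objects or a data.frame
#'   with columns `sample`, `n_raw`, `n_pass`.
#' @return data.frame with columns `sample`, `n_raw`, `n_pass`,
#'   `pct_high_quality`.
#' @export
build_read_stats_table <- function(reports) {
  if (is.data.frame(reports)) {
    tab <- reports[, c("sample", "n_raw", "n_pass")]
  } else {
    tab <- do.call(rbind, lapply(reports, function(r)
      data.frame(sample = r$sample, n_raw = r$n_raw, n_pass = r$n_pass,
                 stringsAsFactors = FALSE)))
  }
  tab$pct_high_quality <- round_half_up(100 * tab$n_pass / tab$n_raw, 2)
  total <- data.frame(sample = "Total",
                      n_raw = sum(tab$n_raw), n_pass = sum(tab$n_pass))
  total$pct_high_quality <- round_half_up(100 * total$n_pass / total$n_raw, 2)
  out <- rbind(tab, total)
  rownames(out) <- NULL
  out
}

#' Bundled tissue read-count table
#'
#' Raw and quality-passing read counts for nine pooled-donor human tissue
#' RNA antibody amplicon libraries sequenced by 454 pyrosequencing, as used
#' for demonstrating [build_read_stats_table()]. Counts were transcribed
#' from the survey's published summary; two thousands-separator typos were
#' normalized and one internally inconsistent pass count was reconstructed
#' from the published total.
#'
#' @return data.frame with columns `sample`, `n_raw`, `n_pass`.
#' @export
tissue_read_counts <- function() {
  path <- system.file("extdata", "tissue_read_counts.tsv", package = "tissuerep")
  read.delim(path, stringsAsFactors = FALSE)
}
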