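#' Alignment and annotation parameters
#'
#' Scoring follows the gapOpening/gapExtension convention of Biostrings: a
#' gap of length L costs `gap_open + L * gap_extend`. Defaults are chosen to
#' be stringent at pyrosequencing read lengths; all values are overridable.
#'
#' @param match,mismatch,gap_open,gap_extend Alignment scores (costs given
#'   as positive numbers).
#' @param min_v_overlap Minimum aligned columns for a V call.
#' @param min_v_score Minimum local alignment score for a V call (also the
#'   threshold below which the reverse complement is tried).
#' @param min_j_overlap,min_j_score Same for the J call.
#' @param min_d_core Minimum ungapped exact match (nt) for a D call.
#' @return List of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -2, gap_open = 6, gap_extend = 1,
                         min_v_overlap = 100, min_v_score = 100,
                         min_j_overlap = 20, min_j_score = 30,
                         min_d_core = 5) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_v_overlap = min_v_overlap,
                 min_v_score = min_v_score, min_j_overlap = min_j_overlap,
                 min_j_score = min_j_score, min_d_core = min_d_core),
            class = "align_params")
}

sw_scores <- function(read, refs, params) {
  .sw_score_multi(read, refs, params$match, params$mismatch,
                  params$gap_open, params$gap_extend)
}

sw_pair <- function(read, ref, params) {
  a <- .sw_align(read, ref, params$match, params$mismatch,
                 params$gap_open, params$gap_extend)
  a$aligned_read <- strsplit(a$aligned_read, "")[[1]]
  a$aligned_ref <- strsplit(a$aligned_ref, "")[[1]]
  a
}

# Extend a local alignment leftwards to the start of read and reference,
# pairing bases 1:1 (the read is expected to begin at the gene 5' end, so
# terminal mismatches clipped by the local aligner are reclaimed rather
# than lost from the mutation tally).
extend_left <- function(aln, read, ref) {
  ext <- min(aln$read_start, aln$ref_start) - 1L
  if (ext > 0) {
    rs <- aln$read_start - ext
    fs <- aln$ref_start - ext
    aln$aligned_read <- c(strsplit(substr(read, rs, aln$read_start - 1L), "")[[1]],
                          aln$aligned_read)
    aln$aligned_ref <- c(strsplit(substr(ref, fs, aln$ref_start - 1L), "")[[1]],
                         aln$aligned_ref)
    aln$read_start <- rs
    aln$ref_start <- fs
  }
  aln
}

# Extend an alignment rightwards by globally aligning the unaligned read
# and reference remainders (both consumed entirely). Used for the J 3' end:
# recombination never trims the J 3' side, so any read sequence beyond the
# local alignment is J template and terminal indels (e.g. homopolymer
# errors near the read end) must be represented as gaps, not clipped.
extend_right_global <- function(aln, read, ref, params, max_rem = 80) {
  r_rem <- nchar(read) - aln$read_end
  f_rem <- nchar(ref) - aln$ref_end
  if (r_rem <= 0 || f_rem <= 0 || r_rem > max_rem || f_rem > max_rem) return(aln)
  nw <- .nw_align(substr(read, aln$read_end + 1, nchar(read)),
                  substr(ref, aln$ref_end + 1, nchar(ref)),
                  params$match, params$mismatch, params$gap_open, params$gap_extend)
  aln$aligned_read <- c(aln$aligned_read, strsplit(nw$aligned_a, "")[[1]])
  aln$aligned_ref <- c(aln$aligned_ref, strsplit(nw$aligned_b, "")[[1]])
  aln$read_end <- nchar(read)
  aln$ref_end <- nchar(ref)
  aln
}

# Canonical leftmost placement for every gap run. Shifting a gap in X one
# column left is allowed while the base of X entering the gap's right edge
# still matches its new partner, which makes shift-equivalent placements
# collapse to a unique form shared with the simulator's truth convention.
normalize_gaps <- function(x, y) {
  shift_runs <- function(x, y) {
    changed <- FALSE
    i <- 1L
    n <- length(x)
    while (i <= n) {
      if (x[i] == "-") {
        j <- i
        while (j < n && x[j + 1L] == "-") j <- j + 1L
        while (i > 1L && x[i - 1L] != "-" && y[i - 1L] != "-" &&
               x[i - 1L] == y[j]) {
          x[j] <- x[i - 1L]
          x[i - 1L] <- "-"
          i <- i - 1L; j <- j - 1L
          changed <- TRUE
        }
        i <- j + 1L
      } else i <- i + 1L
    }
    list(x = x, y = y, changed = changed)
  }
  for (iter in 1:10) {
    a <- shift_runs(x, y); x <- a$x; y <- a$y
    b <- shift_runs(y, x); y <- b$x; x <- b$y
    if (!a$changed && !b$changed) break
  }
  list(x = x, y = y)
}

aln_normalize <- function(aln) {
  z <- normalize_gaps(aln$aligned_read, aln$aligned_ref)
  aln$aligned_read <- z$x
  aln$aligned_ref <- z$y
  aln
}

# Per-column reference/read positions (NA at gap columns), 1-based.
aln_positions <- function(aln) {
  rgap <- aln$aligned_read == "-"
  fgap <- aln$aligned_ref == "-"
  read_pos <- ifelse(rgap, NA_integer_, cumsum(!rgap) + aln$read_start - 1L)
  ref_pos <- ifelse(fgap, NA_integer_, cumsum(!fgap) + aln$ref_start - 1L)
  list(read = read_pos, ref = ref_pos)
}

aln_identity <- function(aln) {
  both <- aln$aligned_read != "-" & aln$aligned_ref != "-"
  if (!any(both)) return(0)
  mean(aln$aligned_read[both] == aln$aligned_ref[both])
}

#' Correct homopolymer-induced single-nucleotide indels
#'
#' Applies codon-based correction to a read/germline alignment: a
#' single-nucleotide gap (in either sequence) lying inside a germline
#' homopolymer run of >= 3 identical bases is corrected back to the germline
#' run length — a missing base is restored from the germline, an extra base
#' is removed. Such 1-nt gaps shift the reading frame, so each correction
#' restores it; codon-length gaps (SHA indels) are never altered.
#'
#' @param aln Alignment as produced internally (list with `aligned_read`,
#'   `aligned_ref` character vectors and 1-based `read_start`/`ref_start`).
#' @param ref_seq Full germline sequence the alignment refers to.
#' @return `list(aln, n_corrections)`: the corrected alignment (gap columns
#'   from removed insertions are dropped; restored deletions become match
#'   columns) and the number of corrections applied.
#' @export
correct_homopolymer_indels <- function(aln, ref_seq) {
  gchars <- strsplit(ref_seq, "")[[1]]
  run_len_at <- function(pos, base) {
    if (pos < 1 || pos > length(gchars)) return(0L)
    if (gchars[pos] != base) return(0L)
    l <- pos
    while (l > 1 && gchars[l - 1] == base) l <- l - 1
    r <- pos
    while (r < length(gchars) && gchars[r + 1] == base) r <- r + 1
    r - l + 1L
  }
  x <- aln$aligned_read
  y <- aln$aligned_ref
  pos <- aln_positions(aln)
  n <- length(x)
  fix_read_gap <- integer(0)   # columns where read gap is filled from germline
  drop_col <- integer(0)       # insertion columns to remove
  i <- 1L
  while (i <= n) {
    if (x[i] == "-" || y[i] == "-") {
      j <- i
      gap_in_read <- x[i] == "-"
      while (j < n && (if (gap_in_read) x[j + 1L] == "-" else y[j + 1L] == "-")) j <- j + 1L
      if (j == i) {  # single-nucleotide gap
        if (gap_in_read) {
          b <- y[i]
          if (run_len_at(pos$ref[i], b) >= 3) fix_read_gap <- c(fix_read_gap, i)
        } else {
          b <- x[i]
          # germline run flanking the insertion point
          left <- if (i > 1) pos$ref[max(which(!is.na(pos$ref[1:(i - 1)])))] else NA
          rl <- 0L
          if (!is.na(left)) rl <- run_len_at(left, b)
          if (rl == 0L) {
            right_idx <- which(!is.na(pos$ref) & seq_len(n) > i)
            if (length(right_idx)) rl <- run_len_at(pos$ref[right_idx[1]], b)
          }
          if (rl >= 3) drop_col <- c(drop_col, i)
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  n_corr <- length(fix_read_gap) + length(drop_col)
  if (length(fix_read_gap)) x[fix_read_gap] <- y[fix_read_gap]
  if (length(drop_col)) {
    x <- x[-drop_col]
    y <- y[-drop_col]
  }
  aln$aligned_read <- x
  aln$aligned_ref <- y
  # read coordinates shrink/grow; read_end is recomputed by the caller from
  # the degapped read
  list(aln = aln, n_corrections = n_corr)
}

aln_read_seq <- function(aln) paste(aln$aligned_read[aln$aligned_read != "-"], collapse = "")
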