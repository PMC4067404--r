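#' Assign V, D and J segments to one read
#'
#' V is the highest-scoring affine-gap local alignment among V genes; J is
#' sought in the read 3' of the V alignment; D is sought only in the
#' junction interior between the V and J alignments and requires a minimum
#' ungapped exact match (`min_d_core`). Score ties are broken by higher
#' percent identity, then longer alignment, then lexicographic gene name.
#' If the forward-strand V score is below `min_v_score`, the reverse
#' complement is tried. A V alignment below the minimum score or overlap
#' yields an absent `v_call` (the read will fail downstream filters); same
#' for J; D may be absent.
#'
#' @param read Nucleotide string over A/C/G/T/N.
#' @param germline A [germline_set()].
#' @param params An [align_params()].
#' @return List with `v_call`, `d_call`, `j_call` (NA when absent),
#'   `v_aln`, `j_aln` alignment objects, and `rev_comp` flag.
#' @export
assign_segments <- function(read, germline, params = align_params()) {
  ctx <- build_annot_ctx(germline, params)
  ann <- annotate_one(read, ctx)
  ann[c("v_call", "d_call", "j_call", "v_aln", "j_aln", "rev_comp")]
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

translate_nt <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    as.character(Biostrings::translate(Biostrings::DNAString(s)))
  }, "", USE.NAMES = FALSE)
}

# Precomputed lookup tables so the per-read path stays cheap.
build_annot_ctx <- function(germline, params = align_params()) {
  vg <- segment_genes(germline, "V")
  jg <- segment_genes(germline, "J")
  dg <- segment_genes(germline, "D")
  list(vg = vg, jg = jg, dg = dg,
       v_seqs = vapply(vg, `[[`, "", "sequence"),
       j_seqs = vapply(jg, `[[`, "", "sequence"),
       d_names = sort(names(dg)),
       params = params)
}

# Pick the best gene by score with deterministic tie-breaks:
# identity, then aligned length, then name. Returns index.
pick_best <- function(scores, names, read, seqs, params) {
  best <- max(scores)
  cand <- which(scores == best)
  if (length(cand) > 1) {
    alns <- lapply(cand, function(k) sw_pair(read, seqs[[k]], params))
    idt <- vapply(alns, aln_identity, 0)
    len <- vapply(alns, function(a) length(a$aligned_read), 0L)
    ord <- order(-idt, -len, names[cand])
    cand <- cand[ord]
  }
  cand[1]
}

annotate_one <- function(read, ctx, read_id = NA_character_) {
  params <- ctx$params
  read <- toupper(read)
  orig_read <- read
  out <- list(read_id = read_id, sequence = orig_read,
              read_length = nchar(orig_read), rev_comp = FALSE,
              v_call = NA_character_, v_family = NA_character_,
              d_call = NA_character_, d_family = NA_character_,
              j_call = NA_character_,
              v_score = NA_real_, v_identity = NA_real_,
              junction_nt = NA_character_, junction_length = NA_integer_,
              cdr3_nt = NA_character_, cdr3_aa = NA_character_,
              cdr3_length = NA_integer_, span_nt = NA_character_,
              in_frame = NA, has_ambiguous_junction = NA,
              productive_stop_free = NA,
              mut_fr1 = NA_integer_, mut_cdr1 = NA_integer_,
              mut_fr2 = NA_integer_, mut_cdr2 = NA_integer_,
              mut_fr3 = NA_integer_,
              total_mutations = NA_integer_,
              len_fr1 = NA_integer_, len_cdr1 = NA_integer_,
              len_fr2 = NA_integer_, len_cdr2 = NA_integer_,
              len_fr3 = NA_integer_,
              sha_indel_events = "", v_frameshift = FALSE,
              homopolymer_corrections = 0L,
              v_aln = NULL, j_aln = NULL, error = NA_character_)

  vs <- sw_scores(read, ctx$v_seqs, params)
  if (max(vs) < params$min_v_score) {
    rc <- revcomp(read)
    vs_rc <- sw_scores(rc, ctx$v_seqs, params)
    if (max(vs_rc) > max(vs)) {
      read <- rc
      vs <- vs_rc
      out$rev_comp <- TRUE
    }
  }
  vi <- pick_best(vs, names(ctx$vg), read, ctx$v_seqs, params)
  v_aln <- sw_pair(read, ctx$v_seqs[[vi]], params)
  v_aln$ref_name <- names(ctx$vg)[vi]
  n_cols <- sum(v_aln$aligned_read != "-" & v_aln$aligned_ref != "-")
  if (v_aln$score < params$min_v_score || n_cols < params$min_v_overlap) {
    out$error <- if (n_cols < params$min_v_overlap) "short_alignment" else "low_score"
    return(out)
  }
  v_gene <- ctx$vg[[vi]]
  v_aln <- extend_left(v_aln, read, v_gene$sequence)

  # codon-based homopolymer correction on the V alignment, then rebuild the
  # working read so downstream coordinates refer to the corrected sequence
  corr <- correct_homopolymer_indels(v_aln, v_gene$sequence)
  v_aln <- corr$aln
  n_corr <- corr$n_corrections
  if (n_corr > 0) {
    v_body <- aln_read_seq(v_aln)
    read <- paste0(substr(read, 1, v_aln$read_start - 1), v_body,
                   substr(read, v_aln$read_end + 1, nchar(read)))
    v_aln$read_end <- v_aln$read_start + nchar(v_body) - 1L
  }
  v_aln <- aln_normalize(v_aln)

  out$v_call <- v_gene$name
  out$v_family <- v_gene$family
  out$v_score <- v_aln$score
  out$v_identity <- aln_identity(v_aln)

  # J: search 3' of the V alignment
  j_offset <- v_aln$read_end
  tail_seq <- substr(read, j_offset + 1, nchar(read))
  j_aln <- NULL
  j_gene <- NULL
  if (nchar(tail_seq) >= params$min_j_overlap) {
    js <- sw_scores(tail_seq, ctx$j_seqs, params)
    ji <- pick_best(js, names(ctx$jg), tail_seq, ctx$j_seqs, params)
    j_aln <- sw_pair(tail_seq, ctx$j_seqs[[ji]], params)
    j_cols <- sum(j_aln$aligned_read != "-" & j_aln$aligned_ref != "-")
    if (j_aln$score < params$min_j_score || j_cols < params$min_j_overlap) {
      j_aln <- NULL
    } else {
      j_gene <- ctx$jg[[ji]]
      j_aln$ref_name <- j_gene$name
      j_aln <- extend_right_global(j_aln, tail_seq, j_gene$sequence, params)
      jcorr <- correct_homopolymer_indels(j_aln, j_gene$sequence)
      j_aln <- jcorr$aln
      if (jcorr$n_corrections > 0) {
        j_body <- aln_read_seq(j_aln)
        tail_new <- paste0(substr(tail_seq, 1, j_aln$read_start - 1), j_body,
                           substr(tail_seq, j_aln$read_end + 1, nchar(tail_seq)))
        j_aln$read_end <- j_aln$read_start + nchar(j_body) - 1L
        read <- paste0(substr(read, 1, j_offset), tail_new)
        n_corr <- n_corr + jcorr$n_corrections
      }
      j_aln <- aln_normalize(j_aln)
      # shift coordinates into full-read space
      j_aln$read_start <- j_aln$read_start + j_offset
      j_aln$read_end <- j_aln$read_end + j_offset
      out$j_call <- j_gene$name
    }
  }
  out$homopolymer_corrections <- n_corr
  out$v_aln <- v_aln
  out$j_aln <- j_aln

  # mutation counts and SHA indels on the corrected, normalized V alignment
  mm <- count_mutations(v_aln, v_gene$region_map)
  out[c("mut_fr1", "mut_cdr1", "mut_fr2", "mut_cdr2", "mut_fr3")] <-
    as.list(mm$counts)
  out[c("len_fr1", "len_cdr1", "len_fr2", "len_cdr2", "len_fr3")] <-
    as.list(mm$aligned_lengths)
  out$total_mutations <- sum(mm$counts)
  sha <- detect_sha_indels(v_aln, v_gene$region_map)
  out$sha_indel_events <- encode_indels(sha$events)
  out$v_frameshift <- sha$frameshift

  # D: junction interior between V and J alignments
  if (!is.null(j_aln)) {
    interior <- substr(read, v_aln$read_end + 1, j_aln$read_start - 1)
    if (nchar(interior) >= params$min_d_core) {
      best_len <- 0L; best_d <- NA_character_
      for (dn in ctx$d_names) {
        hit <- .lcs_substring(interior, ctx$dg[[dn]]$sequence)
        if (hit$length > best_len) { best_len <- hit$length; best_d <- dn }
      }
      if (best_len >= params$min_d_core) {
        out$d_call <- best_d
        out$d_family <- ctx$dg[[best_d]]$family
      }
    }
  }

  # junction and CDR3 from the conserved anchors
  if (!is.null(j_aln)) {
    jx <- extract_junction_cdr3(v_aln, j_aln,
                                cys_start = v_gene$anchor_start,
                                trp_start = j_gene$anchor_start,
                                read = read, translate = FALSE)
    out[names(jx)] <- jx
  }
  out
}

#' Extract junction and CDR3 from anchored alignments
#'
#' The junction runs from (and including) the conserved Cys codon at the V
#' 3' end to (and including) the conserved Trp codon of J; both anchor
#' positions are part of the germline annotation and are projected through
#' the alignments onto the read. `in_frame` requires the junction length to
#' be divisible by 3 and the V reading frame to be preserved into J (no
#' residual frameshift in the V alignment). The CDR3 (between, exclusive of,
#' the anchors) is translated only for in-frame junctions free of ambiguous
#' bases.
#'
#' @param v_aln,j_aln Alignment objects (J in full-read coordinates).
#' @param cys_start,trp_start 0-based anchor codon starts on the germline
#'   V and J sequences.
#' @param read The (corrected) read the alignments refer to.
#' @param translate Translate the CDR3 and the stop-codon span (single-read
#'   use; [annotate_reads()] defers translation and batches it).
#' @return List with `junction_nt`, `junction_length`, `cdr3_nt`,
#'   `cdr3_aa`, `cdr3_length`, `span_nt`, `in_frame`,
#'   `has_ambiguous_junction`, `productive_stop_free`.
#' @export
extract_junction_cdr3 <- function(v_aln, j_aln, cys_start, trp_start, read,
                                  translate = TRUE) {
  out <- list(junction_nt = NA_character_, junction_length = NA_integer_,
              cdr3_nt = NA_character_, cdr3_aa = NA_character_,
              cdr3_length = NA_integer_, span_nt = NA_character_,
              in_frame = NA, has_ambiguous_junction = NA,
              productive_stop_free = NA)
  vp <- aln_positions(v_aln)
  jp <- aln_positions(j_aln)
  cys_col <- which(!is.na(vp$ref) & vp$ref == cys_start + 1L)
  trp_col <- which(!is.na(jp$ref) & jp$ref == trp_start + 3L)
  if (length(cys_col) != 1 || is.na(vp$read[cys_col]) ||
      length(trp_col) != 1 || is.na(jp$read[trp_col]))
    return(out)  # anchor not covered -> junction absent
  jstart <- vp$read[cys_col]
  jend <- jp$read[trp_col]
  if (jend <= jstart) return(out)
  junction <- substr(read, jstart, jend)
  out$junction_nt <- junction
  out$junction_length <- nchar(junction)
  # net indel in the V alignment 5' of the junction
  vcols <- seq_along(v_aln$aligned_read) < cys_col
  net_v <- sum(v_aln$aligned_ref[vcols] == "-") - sum(v_aln$aligned_read[vcols] == "-")
  out$in_frame <- nchar(junction) %% 3L == 0L && net_v %% 3L == 0L
  out$has_ambiguous_junction <- grepl("N", junction, fixed = TRUE)
  if (isTRUE(out$in_frame) && !out$has_ambiguous_junction && nchar(junction) >= 9) {
    out$cdr3_nt <- substr(junction, 4L, nchar(junction) - 3L)
    out$cdr3_length <- nchar(out$cdr3_nt) %/% 3L
  }
  if (isTRUE(out$in_frame)) {
    # translation span from the first aligned V codon through the Trp anchor
    vstart_col <- which(!is.na(vp$ref) & vp$ref == 1L)
    if (length(vstart_col) == 1 && !is.na(vp$read[vstart_col])) {
      span <- substr(read, vp$read[vstart_col], jend)
      span <- gsub("N", "A", span, fixed = TRUE)  # N never creates a stop call
      if (nchar(span) %% 3L == 0L) out$span_nt <- span
    }
  }
  if (translate) {
    if (!is.na(out$cdr3_nt)) out$cdr3_aa <- translate_nt(out$cdr3_nt)
    if (!is.na(out$span_nt))
      out$productive_stop_free <- !grepl("*", translate_nt(out$span_nt), fixed = TRUE)
  }
  out
}

#' Count point mutations per V region
#'
#' Counts substitution columns (both sequences aligned, bases differ, read
#' base not N) between read and germline within each projected FR/CDR
#' interval of the region map. Gap columns — and therefore all positions
#' inside SHA indels — are excluded. Also reports the aligned (non-gap)
#' length of each region for per-base frequency calculations.
#'
#' @param aln Corrected V alignment object.
#' @param region_map Region map of the aligned V gene.
#' @return `list(counts, aligned_lengths)`, both named by region.
#' @export
count_mutations <- function(aln, region_map) {
  pos <- aln_positions(aln)
  both <- aln$aligned_read != "-" & aln$aligned_ref != "-"
  mismatch <- both & aln$aligned_read != aln$aligned_ref & aln$aligned_read != "N"
  counts <- integer(nrow(region_map))
  lens <- integer(nrow(region_map))
  for (r in seq_len(nrow(region_map))) {
    in_region <- !is.na(pos$ref) & pos$ref > region_map$start[r] &
      pos$ref <= region_map$end[r]
    counts[r] <- sum(mismatch & in_region)
    lens[r] <- sum(both & in_region)
  }
  list(counts = setNames(counts, region_map$region),
       aligned_lengths = setNames(lens, region_map$region))
}

#' Detect codon-length (SHA) indels in a V alignment
#'
#' Contiguous gap runs whose length is a positive multiple of 3 and which
#' start 5' of the conserved Cys codon are reported as single events: a gap
#' in the germline is an insertion, a gap in the read a deletion; the
#' position is the 1-based V-local codon index of the event start and the
#' length is in codons. Gap runs that are not a multiple of 3 set the
#' `frameshift` flag and are not SHA indels. Gaps are left-normalized before
#' calling so shift-equivalent placements give identical events.
#'
#' @param aln Corrected, normalized V alignment object.
#' @param region_map Region map of the V gene (its end bounds the V region).
#' @return `list(events, frameshift)`: events data.frame (`type`, `codon`,
#'   `length_codons`) and logical frameshift flag.
#' @export
detect_sha_indels <- function(aln, region_map) {
  v_end <- max(region_map$end)  # Cys codon starts here (0-based)
  pos <- aln_positions(aln)
  x <- aln$aligned_read
  y <- aln$aligned_ref
  n <- length(x)
  events <- list()
  frameshift <- FALSE
  i <- 1L
  while (i <= n) {
    if (x[i] == "-" || y[i] == "-") {
      gap_in_read <- x[i] == "-"
      j <- i
      while (j < n && (if (gap_in_read) x[j + 1L] == "-" else y[j + 1L] == "-")) j <- j + 1L
      len <- j - i + 1L
      # 0-based germline position of the gap start: number of ref bases
      # consumed before this column
      prev_ref <- if (i > 1) pos$ref[1:(i - 1)] else integer(0)
      ref0 <- if (length(prev_ref) && any(!is.na(prev_ref)))
        max(prev_ref, na.rm = TRUE) else aln$ref_start - 1L
      if (ref0 < v_end) {
        if (len %% 3L == 0L) {
          events[[length(events) + 1]] <- data.frame(
            type = if (gap_in_read) "deletion" else "insertion",
            codon = ref0 %/% 3L + 1L,
            length_codons = len %/% 3L)
        } else {
          frameshift <- TRUE
        }
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), codon = integer(0), length_codons = integer(0))
  list(events = events, frameshift = frameshift)
}

#' Annotate a pool of reads
#'
#' Runs segment assignment, homopolymer correction, junction/CDR3
#' extraction, per-region mutation counting and SHA indel detection on each
#' read, returning one row per read in an AIRR-flavoured flat table
#' (indel events encoded as `"type:codon:length"` strings; see
#' [decode_indels()]). CDR3 and stop-codon-span translation is batched over
#' the pool.
#'
#' @param reads Named character vector of reads.
#' @param germline A [germline_set()].
#' @param params An [align_params()].
#' @return data.frame of annotations.
#' @export
annotate_reads <- function(reads, germline, params = align_params()) {
  ids <- names(reads) %||% sprintf("read%06d", seq_along(reads))
  ctx <- build_annot_ctx(germline, params)
  scalar_cols <- c("read_id", "sequence", "read_length", "rev_comp",
                   "v_call", "v_family", "d_call", "d_family", "j_call",
                   "v_score", "v_identity",
                   "junction_nt", "junction_length", "cdr3_nt", "cdr3_length",
                   "span_nt",
                   "in_frame", "has_ambiguous_junction",
                   "mut_fr1", "mut_cdr1", "mut_fr2", "mut_cdr2", "mut_fr3",
                   "total_mutations",
                   "len_fr1", "len_cdr1", "len_fr2", "len_cdr2", "len_fr3",
                   "sha_indel_events", "v_frameshift",
                   "homopolymer_corrections", "error")
  rows <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    ann <- annotate_one(reads[[i]], ctx, read_id = ids[i])
    rows[[i]] <- ann[scalar_cols]
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  # batched translation
  out$cdr3_aa <- NA_character_
  has_cdr3 <- !is.na(out$cdr3_nt)
  if (any(has_cdr3)) {
    aas <- Biostrings::translate(Biostrings::DNAStringSet(out$cdr3_nt[has_cdr3]))
    out$cdr3_aa[has_cdr3] <- as.character(aas)
  }
  out$productive_stop_free <- NA
  has_span <- !is.na(out$span_nt)
  if (any(has_span)) {
    sp <- Biostrings::translate(Biostrings::DNAStringSet(out$span_nt[has_span]))
    out$productive_stop_free[has_span] <- !grepl("*", as.character(sp), fixed = TRUE)
  }
  out$span_nt <- NULL
  out
}

#' Write annotations as an AIRR-style TSV
#'
#' @param annotations data.frame from [annotate_reads()].
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
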