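# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are memoized for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

shared_germline <- function() {
  memo("gl", build_toy_germline_set(7, 3, 10, 6, seed = 1))
}

# Construct an alignment object directly from gapped strings (1-based
# starts), for unit tests of column-walking operations.
make_aln <- function(aligned_read, aligned_ref, read_start = 1L, ref_start = 1L) {
  x <- strsplit(aligned_read, "")[[1]]
  y <- strsplit(aligned_ref, "")[[1]]
  stopifnot(length(x) == length(y))
  list(aligned_read = x, aligned_ref = y,
       read_start = read_start, ref_start = ref_start,
       read_end = read_start + sum(x != "-") - 1L,
       ref_end = ref_start + sum(y != "-") - 1L,
       score = NA_real_)
}

# Assemble a clean recombinant read by hand from named genes.
build_recombinant <- function(gl, v, d, j, n1 = "", n2 = "",
                              trim_v = 0, trim_d5 = 0, trim_d3 = 0, trim_j = 0) {
  vs <- gl$genes[[v]]$sequence
  ds <- gl$genes[[d]]$sequence
  js <- gl$genes[[j]]$sequence
  paste0(substr(vs, 1, nchar(vs) - trim_v), n1,
         substr(ds, trim_d5 + 1, nchar(ds) - trim_d3), n2,
         substr(js, trim_j + 1, nchar(js)))
}

# Independent local-alignment score oracle (Biostrings; same gap-cost
# convention: a gap of length L costs gapOpening + L * gapExtension).
biostrings_local_score <- function(read, ref, match = 2, mismatch = -2,
                                   gap_open = 6, gap_ext = 1) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch)
  Biostrings::pairwiseAlignment(read, ref, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = gap_open, gapExtension = gap_ext,
                                scoreOnly = TRUE)
}

# Brute-force complete-linkage oracle: greedy merges recomputing the
# maximum cross-pair distance between clusters at every step, ties broken
# by the smallest index pair. Returns merge heights and the cophenetic
# distance matrix.
oracle_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cd <- max(d[clusters[[i]], clusters[[j]]])
      if (cd < best - 1e-12) { best <- cd; bi <- i; bj <- j }
    }
    heights[step] <- best
    for (a in clusters[[bi]]) for (b in clusters[[bj]]) {
      coph[a, b] <- best; coph[b, a] <- best
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# Hand-built annotation rows for filter tests.
fake_annotation <- function(read_length = 350, v = "VH1-1", d = "D1", j = "J1",
                            in_frame = TRUE, ambiguous = FALSE,
                            sequence = NULL, total_mutations = 0) {
  data.frame(read_id = "r", sequence = sequence %||% paste(rep("A", read_length), collapse = ""),
             read_length = read_length,
             v_call = v, v_family = if (is.na(v)) NA_character_ else sub("-.*", "", v),
             d_call = d, d_family = d, j_call = j,
             in_frame = in_frame, has_ambiguous_junction = ambiguous,
             total_mutations = total_mutations,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
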