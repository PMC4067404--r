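#' Simulation configuration for a synthetic repertoire pool
#'
#' Describes one tissue pool: gene usage, junction geometry, somatic
#' hypermutation (SHM), codon-length SHM-associated (SHA) indels,
#' pyrosequencing homopolymer errors and defective-read fractions.
#'
#' Distributions over small non-negative integers (trim lengths, N-region
#' lengths) are given as probability vectors where element `i` is the
#' probability of the value `i - 1`.
#'
#' @param germline A [germline_set()] the usage vectors refer to.
#' @param n_reads Number of reads to simulate (>= 1).
#' @param v_usage,d_usage,j_usage Named probability vectors over gene names
#'   (default: uniform over the segment's genes). Must sum to 1.
#' @param trim_v_dist,trim_d_dist,trim_j_dist Exonuclease trim-length
#'   distributions for the V 3' end, both D ends (drawn independently per
#'   end) and the J 5' end.
#' @param n_insertion_dist N-region length distribution (drawn independently
#'   for N1 and N2).
#' @param shm_rate_per_region Per-base substitution probability for FR1,
#'   CDR1, FR2, CDR2, FR3 (named). CDR rates may exceed FR rates.
#' @param naive_fraction Fraction of reads drawn from unmutated (naive)
#'   B cells: these receive no SHM point mutations and no SHA indels.
#' @param sha_indel_rate_per_codon Per-codon probability of a codon-length
#'   indel, per region (named as above).
#' @param homopolymer_error_rate Per-eligible-run probability of a 1-nt
#'   sequencing insertion/deletion. Runs are >= 3 identical consecutive
#'   bases in the germline-templated (V or J) portion of the read.
#' @param defect_fractions Named fractions `short`, `frameshift`,
#'   `ambiguous` of deliberately defective reads.
#' @param enforce_frame Control junction frame per read (pad N2 so clean
#'   reads are in frame, break frame for `frameshift` reads). Disable to
#'   get raw concatenations whose frame is left to chance.
#' @param seed Integer RNG seed for the pool.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(germline, n_reads,
                       v_usage = NULL, d_usage = NULL, j_usage = NULL,
                       trim_v_dist = rep(1/7, 7),
                       trim_d_dist = rep(1/4, 4),
                       trim_j_dist = rep(1/10, 10),
                       n_insertion_dist = rep(1/7, 7),
                       shm_rate_per_region = c(FR1 = 0.02, CDR1 = 0.04,
                                               FR2 = 0.02, CDR2 = 0.04,
                                               FR3 = 0.02),
                       naive_fraction = 0.1,
                       sha_indel_rate_per_codon = c(FR1 = 1e-4, CDR1 = 2e-3,
                                                    FR2 = 1e-4, CDR2 = 2e-3,
                                                    FR3 = 1e-4),
                       homopolymer_error_rate = 0.0017,
                       defect_fractions = c(short = 0.025, frameshift = 0.025,
                                            ambiguous = 0.015),
                       enforce_frame = TRUE,
                       seed = 1) {
  stopifnot(inherits(germline, "germline_set"), n_reads >= 1)
  uniform_usage <- function(segment) {
    nm <- names(segment_genes(germline, segment))
    setNames(rep(1 / length(nm), length(nm)), nm)
  }
  v_usage <- v_usage %||% uniform_usage("V")
  d_usage <- d_usage %||% uniform_usage("D")
  j_usage <- j_usage %||% uniform_usage("J")
  check_usage <- function(u, segment) {
    nm <- names(segment_genes(germline, segment))
    if (is.null(names(u)) || !all(names(u) %in% nm))
      stop("usage vector for segment ", segment,
           " references unknown genes: ",
           paste(setdiff(names(u), nm), collapse = ", "))
    if (any(u < 0 | u > 1) || abs(sum(u) - 1) > 1e-9)
      stop("usage vector for segment ", segment, " must be probabilities summing to 1")
    u
  }
  check_dist <- function(d, what) {
    if (any(d < 0) || abs(sum(d) - 1) > 1e-9)
      stop(what, " must be a probability vector summing to 1")
    d
  }
  check_rates <- function(r, what) {
    if (!setequal(names(r), v_region_names))
      stop(what, " must be named FR1, CDR1, FR2, CDR2, FR3")
    if (any(r < 0 | r > 1)) stop(what, " must be probabilities")
    r[v_region_names]
  }
  if (!setequal(names(defect_fractions), c("short", "frameshift", "ambiguous")))
    stop("defect_fractions must be named short, frameshift, ambiguous")
  if (any(defect_fractions < 0) || sum(defect_fractions) > 1)
    stop("defect_fractions must be non-negative and sum to <= 1")
  stopifnot(naive_fraction >= 0, naive_fraction <= 1,
            homopolymer_error_rate >= 0, homopolymer_error_rate <= 1)
  structure(list(
    n_reads = as.integer(n_reads),
    v_usage = check_usage(v_usage, "V"),
    d_usage = check_usage(d_usage, "D"),
    j_usage = check_usage(j_usage, "J"),
    trim_v_dist = check_dist(trim_v_dist, "trim_v_dist"),
    trim_d_dist = check_dist(trim_d_dist, "trim_d_dist"),
    trim_j_dist = check_dist(trim_j_dist, "trim_j_dist"),
    n_insertion_dist = check_dist(n_insertion_dist, "n_insertion_dist"),
    shm_rate_per_region = check_rates(shm_rate_per_region, "shm_rate_per_region"),
    naive_fraction = naive_fraction,
    sha_indel_rate_per_codon = check_rates(sha_indel_rate_per_codon,
                                           "sha_indel_rate_per_codon"),
    homopolymer_error_rate = homopolymer_error_rate,
    defect_fractions = defect_fractions,
    enforce_frame = isTRUE(enforce_frame),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Spread family-level usage weights over individual genes
#'
#' Converts a named vector of family weights into a per-gene usage vector,
#' splitting each family's mass equally among its members.
#'
#' @param germline A [germline_set()].
#' @param family_weights Named non-negative weights over families of one
#'   segment type (normalized internally).
#' @param segment Segment type the families belong to.
#' @return Named per-gene probability vector suitable for [sim_config()].
#' @export
family_usage_vector <- function(germline, family_weights, segment = "V") {
  idx <- germline$index[germline$index$segment == segment, ]
  if (!all(names(family_weights) %in% idx$family))
    stop("unknown families: ",
         paste(setdiff(names(family_weights), idx$family), collapse = ", "))
  w <- family_weights / sum(family_weights)
  out <- setNames(numeric(nrow(idx)), idx$name)
  for (f in names(w)) {
    members <- idx$name[idx$family == f]
    out[members] <- w[[f]] / length(members)
  }
  out
}

draw_dist <- function(dist, n) sample(seq_along(dist) - 1L, n, replace = TRUE, prob = dist)

# ---- indel event encoding shared by simulator and annotator -----------------

#' Encode / decode SHA indel event lists
#'
#' Events are stored in flat tables as strings like
#' `"deletion:27:1;insertion:58:2"` (type, 1-based V codon of the event
#' start, length in codons).
#'
#' @param events Data frame with columns `type`, `codon`, `length_codons`.
#' @return `encode_indels()`: a single string (`""` for no events);
#'   `decode_indels()`: the data frame.
#' @export
encode_indels <- function(events) {
  if (is.null(events) || nrow(events) == 0) return("")
  ord <- order(events$codon, events$type)
  paste(sprintf("%s:%d:%d", events$type[ord], events$codon[ord],
                events$length_codons[ord]), collapse = ";")
}

#' @rdname encode_indels
#' @param x Encoded string.
#' @export
decode_indels <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(type = character(0), codon = integer(0),
                      length_codons = integer(0)))
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(type = vapply(parts, `[`, "", 1),
             codon = as.integer(vapply(parts, `[`, "", 2)),
             length_codons = as.integer(vapply(parts, `[`, "", 3)))
}

# ---- recombination ----------------------------------------------------------

#' Simulate clean V(D)J recombinants
#'
#' Draws genes per the configured usage vectors, applies exonuclease
#' trimming and N-region insertion, and assembles each read as
#' `V[1..len-trimV] + N1 + D[trimD5+1..len-trimD3] + N2 + J[trimJ+1..len]`.
#' Junction frame is controlled per read: reads destined to be clean (or
#' short/ambiguous) get an in-frame junction by padding N2 up to the next
#' codon boundary; reads labelled `frameshift` get a junction length not
#' divisible by 3. Reads labelled `ambiguous` are guaranteed N1 >= 1 so an
#' ambiguous base can later be planted in untemplated sequence. No mutation
#' process is applied here; see [apply_shm()] and [apply_sequencing_noise()].
#'
#' Uses the current RNG state; [simulate_repertoire()] seeds it from the
#' config.
#'
#' @param config A [sim_config()].
#' @param germline The [germline_set()].
#' @return `list(reads, truth)`: named character vector of reads and a truth
#'   data.frame (one row per read) with the drawn genes, trims, N lengths,
#'   junction coordinates (1-based, on the current read) and defect label.
#' @export
simulate_recombination <- function(config, germline) {
  n <- config$n_reads
  vg <- segment_genes(germline, "V")
  dg <- segment_genes(germline, "D")
  jg <- segment_genes(germline, "J")
  true_v <- sample(names(config$v_usage), n, replace = TRUE, prob = config$v_usage)
  true_d <- sample(names(config$d_usage), n, replace = TRUE, prob = config$d_usage)
  true_j <- sample(names(config$j_usage), n, replace = TRUE, prob = config$j_usage)
  trim_v <- draw_dist(config$trim_v_dist, n)
  trim_d5 <- draw_dist(config$trim_d_dist, n)
  trim_d3 <- draw_dist(config$trim_d_dist, n)
  trim_j <- draw_dist(config$trim_j_dist, n)
  n1 <- draw_dist(config$n_insertion_dist, n)
  n2 <- draw_dist(config$n_insertion_dist, n)

  defect <- sample(c("none", names(config$defect_fractions)), n, replace = TRUE,
                   prob = c(1 - sum(config$defect_fractions), config$defect_fractions))
  n1[defect == "ambiguous" & n1 == 0] <- 1L

  v_len <- vapply(vg[true_v], function(g) nchar(g$sequence), 0L)
  d_len <- vapply(dg[true_d], function(g) nchar(g$sequence), 0L)
  j_len <- vapply(jg[true_j], function(g) nchar(g$sequence), 0L)
  cys_start <- vapply(vg[true_v], `[[`, 0L, "anchor_start")   # 0-based
  trp_start <- vapply(jg[true_j], `[[`, 0L, "anchor_start")   # 0-based

  # junction: Cys codon .. Trp codon inclusive
  junc_len <- (v_len - cys_start - trim_v) + n1 +
    (d_len - trim_d5 - trim_d3) + n2 + trp_start - trim_j + 3L
  if (config$enforce_frame) {
    pad <- (3L - junc_len %% 3L) %% 3L
    pad[defect == "frameshift"] <- 0L
    n2 <- n2 + pad
    junc_len <- junc_len + pad
    shift <- defect == "frameshift" & junc_len %% 3L == 0L
    bump <- integer(n); bump[shift] <- sample(1:2, sum(shift), replace = TRUE)
    n2 <- n2 + bump
    junc_len <- junc_len + bump
  }

  bases <- c("A", "C", "G", "T")
  rand_nt <- function(len) {
    vapply(len, function(l) if (l == 0) "" else
      paste(sample(bases, l, replace = TRUE), collapse = ""), "")
  }
  v_part <- substr(vapply(vg[true_v], `[[`, "", "sequence"), 1L, v_len - trim_v)
  d_part <- substr(vapply(dg[true_d], `[[`, "", "sequence"),
                   trim_d5 + 1L, d_len - trim_d3)
  j_part <- substr(vapply(jg[true_j], `[[`, "", "sequence"), trim_j + 1L, j_len)
  reads <- paste0(v_part, rand_nt(n1), d_part, rand_nt(n2), j_part)
  ids <- sprintf("read%06d", seq_len(n))
  names(reads) <- ids

  truth <- data.frame(
    read_id = ids, true_v = true_v, true_d = true_d, true_j = true_j,
    trim_v = trim_v, trim_d5 = trim_d5, trim_d3 = trim_d3, trim_j = trim_j,
    n1_len = n1, n2_len = n2,
    v_part_end = nchar(v_part),
    junction_start = cys_start + 1L,
    junction_length = junc_len,
    defect = defect,
    naive = FALSE,
    mut_fr1 = 0L, mut_cdr1 = 0L, mut_fr2 = 0L, mut_cdr2 = 0L, mut_fr3 = 0L,
    total_mutations = 0L,
    mut_positions = "", sha_indel_events = "",
    n_seq_errors = 0L, seq_error_positions = "",
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(reads = reads, truth = truth)
}

# Deletion of the codon starting at 0-based nt p is only planted where no
# shift-equivalent gap placement exists (flanking bases differ across the
# window), so the alignment-recovered event position is unambiguous.
deletion_eligible <- function(seq_chars, p) {
  if (p < 1 || p + 3 >= length(seq_chars)) return(FALSE)
  seq_chars[p] != seq_chars[p + 3] && seq_chars[p + 1] != seq_chars[p + 4]
}

#' Apply somatic hypermutation and SHA indels
#'
#' Plants per-region point substitutions at the configured rates and
#' codon-length (frame-preserving) insertions/deletions at codon boundaries
#' in the V portion of each read, updating the truth record. Reads marked
#' naive (drawn per `naive_fraction`) are left untouched.
#'
#' To keep the ground truth recoverable by alignment, indels are planted
#' only at sites without a shift-equivalent placement (flanking germline
#' bases differ), inserted codons are resampled to avoid creating one, and
#' substitutions are not planted in the codon carrying, or adjacent to, an
#' indel.
#'
#' @param reads Named character vector from [simulate_recombination()].
#' @param truth Matching truth data.frame (modified and returned).
#' @param config A [sim_config()].
#' @param germline The [germline_set()].
#' @return `list(reads, truth)` with mutated reads and updated truth
#'   (per-region counts, mutation positions in V-local nucleotide
#'   coordinates, encoded indel events, shifted junction coordinates).
#' @export
apply_shm <- function(reads, truth, config, germline) {
  vg <- segment_genes(germline, "V")
  bases <- c("A", "C", "G", "T")
  n <- length(reads)
  truth$naive <- runif(n) < config$naive_fraction
  rates <- config$shm_rate_per_region
  irates <- config$sha_indel_rate_per_codon
  region_cols <- c(FR1 = "mut_fr1", CDR1 = "mut_cdr1", FR2 = "mut_fr2",
                   CDR2 = "mut_cdr2", FR3 = "mut_fr3")
  for (i in seq_len(n)) {
    if (truth$naive[i]) next
    gene <- vg[[truth$true_v[i]]]
    gchars <- strsplit(gene$sequence, "")[[1]]
    rm <- gene$region_map
    chars <- strsplit(reads[i], "")[[1]]

    # 1. draw indel events per region codon
    events <- list()
    for (r in seq_len(nrow(rm))) {
      codons <- (rm$start[r] / 3L + 1L):(rm$end[r] / 3L)  # 1-based codon idx
      hit <- codons[runif(length(codons)) < irates[[rm$region[r]]]]
      for (cd in hit) {
        type <- sample(c("insertion", "deletion"), 1)
        p <- 3L * (cd - 1L)  # 0-based nt of codon start
        if (type == "deletion" && !deletion_eligible(gchars, p)) next
        events[[length(events) + 1]] <- list(type = type, codon = cd, region = rm$region[r])
      }
    }
    # adjacent events (e.g. an insertion next to a deletion) cancel into
    # plain substitutions under alignment, losing their identity; enforce a
    # one-codon gap between events
    if (length(events) > 1) {
      cds <- vapply(events, `[[`, 0, "codon")
      keep <- rep(TRUE, length(events))
      last_kept <- cds[1]
      for (k in 2:length(events)) {
        if (cds[k] - last_kept <= 1) keep[k] <- FALSE else last_kept <- cds[k]
      }
      events <- events[keep]
    }
    ev_codons <- vapply(events, `[[`, 0, "codon")

    # 2. substitutions, excluding codons within 1 of an indel event
    mut_pos <- integer(0)
    for (r in seq_len(nrow(rm))) {
      pos <- (rm$start[r] + 1L):rm$end[r]  # 1-based V-local nt
      pos <- pos[runif(length(pos)) < rates[[rm$region[r]]]]
      if (length(ev_codons))
        pos <- pos[!((pos - 1L) %/% 3L + 1L) %in%
                     c(ev_codons - 1L, ev_codons, ev_codons + 1L)]
      if (length(pos)) {
        for (p in pos) chars[p] <- sample(setdiff(bases, gchars[p]), 1)
        truth[[region_cols[[rm$region[r]]]]][i] <- length(pos)
        mut_pos <- c(mut_pos, pos)
      }
    }

    # 3. apply indels 3' -> 5' so earlier positions stay valid
    if (length(events)) {
      ord <- order(-ev_codons)
      for (e in events[ord]) {
        p <- 3L * (e$codon - 1L)  # 0-based
        if (e$type == "deletion") {
          chars <- chars[-((p + 1L):(p + 3L))]
        } else {
          repeat {
            ins <- sample(bases, 3, replace = TRUE)
            # block shift-equivalent placements on either side
            if ((p == 0 || ins[3] != gchars[p]) && ins[1] != gchars[p + 1]) break
          }
          chars <- append(chars, ins, after = p)
        }
      }
      net <- 3L * (sum(vapply(events, `[[`, "", "type") == "insertion") -
                     sum(vapply(events, `[[`, "", "type") == "deletion"))
      truth$v_part_end[i] <- truth$v_part_end[i] + net
      truth$junction_start[i] <- truth$junction_start[i] + net
      truth$sha_indel_events[i] <- encode_indels(data.frame(
        type = vapply(events, `[[`, "", "type"),
        codon = ev_codons,
        length_codons = 1L))
    }
    truth$mut_positions[i] <- paste(sort(mut_pos), collapse = ",")
    reads[i] <- paste(chars, collapse = "")
  }
  truth$total_mutations <- truth$mut_fr1 + truth$mut_cdr1 + truth$mut_fr2 +
    truth$mut_cdr2 + truth$mut_fr3
  list(reads = reads, truth = truth)
}

#' Apply pyrosequencing homopolymer indel errors
#'
#' With probability `homopolymer_error_rate` per eligible run, inserts an
#' extra copy of the run base or deletes one base. Eligible runs are >= 3
#' identical consecutive bases lying entirely in the germline-templated
#' portion of the read (the V part, excluding positions altered by SHM, or
#' the J part): only there does a germline reference exist against which a
#' codon-based correction can operate, which mirrors the correction's actual
#' reach; untemplated junction sequence is left error-free.
#'
#' @inheritParams apply_shm
#' @return `list(reads, truth)` with noisy reads; `n_seq_errors` and
#'   `seq_error_positions` (type:read-position pairs, post-edit coordinates)
#'   updated, and junction coordinates shifted for edits 5' of the junction.
#' @export
apply_sequencing_noise <- function(reads, truth, config, germline) {
  rate <- config$homopolymer_error_rate
  if (rate == 0) return(list(reads = reads, truth = truth))
  jg <- segment_genes(germline, "J")
  for (i in seq_along(reads)) {
    chars <- strsplit(reads[i], "")[[1]]
    len <- length(chars)
    v_end <- truth$v_part_end[i]
    j_start <- len - (nchar(jg[[truth$true_j[i]]]$sequence) - truth$trim_j[i]) + 1L
    mut_pos <- if (nzchar(truth$mut_positions[i]))
      as.integer(strsplit(truth$mut_positions[i], ",")[[1]]) else integer(0)
    # positions whose base still matches the germline template
    indels <- decode_indels(truth$sha_indel_events[i])
    templated <- rep(FALSE, len)
    templated[seq_len(v_end)] <- TRUE
    if (j_start <= len) templated[j_start:len] <- TRUE
    templated[mut_pos] <- FALSE
    if (nrow(indels)) {
      # conservatively exclude a window around each indel event
      for (k in seq_len(nrow(indels))) {
        ctr <- 3L * (indels$codon[k] - 1L)
        win <- max(1L, ctr - 3L):min(len, ctr + 3L * indels$length_codons[k] + 3L)
        templated[win] <- FALSE
      }
    }
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_idx <- which(r$lengths >= 3)
    edits <- list()
    for (k in run_idx) {
      # the run plus a small flank on each side must be cleanly templated:
      # an SHM substitution near the run lets an aligner re-parse the
      # error+mutation combination as a single indel at the substitution
      # site (an equal-score tie), so the error would not be attributable
      # to the germline homopolymer by any corrector
      lo <- max(1L, starts[k] - 4L)
      hi <- min(len, ends[k] + 4L)
      if (!all(templated[lo:hi])) next
      if (runif(1) >= rate) next
      edits[[length(edits) + 1]] <- list(
        pos = starts[k],
        type = sample(c("ins", "del"), 1),
        base = r$values[k])
    }
    if (!length(edits)) next
    ord <- order(-vapply(edits, `[[`, 0L, "pos"))
    for (e in edits[ord]) {
      if (e$type == "ins") chars <- append(chars, e$base, after = e$pos)
      else chars <- chars[-e$pos]
    }
    delta <- vapply(edits, function(e) if (e$type == "ins") 1L else -1L, 0L)
    pos <- vapply(edits, `[[`, 0L, "pos")
    before <- pos <= v_end
    truth$junction_start[i] <- truth$junction_start[i] + sum(delta[before])
    truth$v_part_end[i] <- truth$v_part_end[i] + sum(delta[before])
    truth$n_seq_errors[i] <- truth$n_seq_errors[i] + length(edits)
    # report final (post-edit) coordinates: each position shifts by the net
    # indel length of all edits 5' of it
    asc <- order(pos)
    shift <- c(0L, cumsum(delta[asc]))[seq_along(asc)]
    final_pos <- pos[asc] + shift
    truth$seq_error_positions[i] <- paste(
      c(if (nzchar(truth$seq_error_positions[i])) truth$seq_error_positions[i],
        sprintf("%s:%d", vapply(edits[asc], `[[`, "", "type"), final_pos)),
      collapse = ";")
    reads[i] <- paste(chars, collapse = "")
  }
  list(reads = reads, truth = truth)
}

#' Simulate a complete tissue read pool
#'
#' Runs the full generator chain — [simulate_recombination()], [apply_shm()],
#' [apply_sequencing_noise()], then defect finalization (truncation of
#' `short` reads to 150-295 nt; an `N` planted in the untemplated N1 region
#' of `ambiguous` reads) — under the config seed. Identical config gives
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @param germline The [germline_set()].
#' @return `list(reads, truth)`.
#' @export
simulate_repertoire <- function(config, germline) {
  with_seed(config$seed, {
    pool <- simulate_recombination(config, germline)
    pool <- apply_shm(pool$reads, pool$truth, config, germline)
    pool <- apply_sequencing_noise(pool$reads, pool$truth, config, germline)
    reads <- pool$reads; truth <- pool$truth
    short_i <- which(truth$defect == "short")
    if (length(short_i)) {
      newlen <- sample(150:295, length(short_i), replace = TRUE)
      reads[short_i] <- substr(reads[short_i], 1L, newlen)
    }
    amb_i <- which(truth$defect == "ambiguous")
    for (i in amb_i) {
      p <- truth$v_part_end[i] + 1L  # first N1 base: untemplated by construction
      substr(reads[i], p, p) <- "N"
    }
    list(reads = reads, truth = truth)
  })
}

#' Write / read a simulated pool
#'
#' `write_pool()` writes the reads as FASTA and the truth table as TSV with
#' matching ids; `read_pool()` and `read_truth()` read them back (sequences
#' round-trip exactly).
#'
#' @param reads Named character vector of reads.
#' @param truth Truth data.frame.
#' @param fasta_path,truth_path Output paths.
#' @export
write_pool <- function(reads, truth, fasta_path, truth_path) {
  stopifnot(identical(names(reads), truth$read_id))
  x <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(x, fasta_path)
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' @rdname write_pool
#' @export
read_pool <- function(fasta_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  setNames(as.character(x), names(x))
}

#' @rdname write_pool
#' @export
read_truth <- function(truth_path) {
  read.delim(truth_path, stringsAsFactors = FALSE,
             colClasses = list(mut_positions = "character",
                               sha_indel_events = "character",
                               seq_error_positions = "character"))
}
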