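#' Germline gene segment
#'
#' A single V, D or J germline reference segment. V genes carry a region map
#' giving the framework (FR1-FR3) and complementarity-determining (CDR1,
#' CDR2) intervals in gene-local, 0-based half-open nucleotide coordinates;
#' the five intervals must tile the gene contiguously from position 0, appear
#' in order, and each be a whole number of codons. The region map ends where
#' the junction begins, i.e. at the first base of the conserved cysteine
#' codon. J genes carry the position of the conserved tryptophan codon
#' (`anchor_start`, 0-based) that closes the junction.
#'
#' @param name Unique gene identifier.
#' @param segment One of `"V"`, `"D"`, `"J"`.
#' @param family Family label (e.g. `"VH3"`); must be non-empty.
#' @param sequence Nucleotide string over A/C/G/T (lowercase accepted and
#'   uppercased).
#' @param region_map For V genes, a data.frame with columns `region`,
#'   `start`, `end` covering FR1, CDR1, FR2, CDR2, FR3.
#' @param anchor_start For J genes, 0-based start of the conserved Trp codon.
#' @return An object of class `germline_gene`.
#' @export
germline_gene <- function(name, segment, family, sequence,
                          region_map = NULL, anchor_start = NULL) {
  stopifnot(is.character(name), nzchar(name), segment %in% c("V", "D", "J"))
  if (!nzchar(family)) stop("germline gene '", name, "': family must be non-empty")
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || grepl("[^ACGT]", sequence))
    stop("germline gene '", name, "': sequence must be non-empty over A/C/G/T")
  g <- structure(list(name = name, segment = segment, family = family,
                      sequence = sequence, region_map = NULL,
                      anchor_start = NULL),
                 class = "germline_gene")
  if (segment == "V") {
    if (is.null(region_map)) stop("germline gene '", name, "': V genes need a region map")
    g$region_map <- validate_region_map(region_map, name, nchar(sequence))
    g$anchor_start <- max(g$region_map$end)  # conserved Cys codon starts here
  }
  if (segment == "J") {
    if (is.null(anchor_start)) stop("germline gene '", name, "': J genes need anchor_start")
    anchor_start <- as.integer(anchor_start)
    if (anchor_start < 0 || anchor_start + 3 > nchar(sequence))
      stop("germline gene '", name, "': Trp anchor outside sequence")
    g$anchor_start <- anchor_start
  }
  g
}

v_region_names <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")

validate_region_map <- function(rm, gene_name, seq_len) {
  rm <- as.data.frame(rm)
  need <- c("region", "start", "end")
  if (!all(need %in% names(rm)))
    stop("region map for '", gene_name, "' must have columns region, start, end")
  if (!setequal(rm$region, v_region_names))
    stop("region map for '", gene_name, "' must cover exactly FR1, CDR1, FR2, CDR2, FR3")
  rm <- rm[match(v_region_names, rm$region), need]
  rm$start <- as.integer(rm$start); rm$end <- as.integer(rm$end)
  if (rm$start[1] != 0L)
    stop("region map for '", gene_name, "': FR1 must start at 0")
  for (i in seq_len(nrow(rm))) {
    if (rm$end[i] <= rm$start[i])
      stop("region map for '", gene_name, "': empty or inverted interval for ", rm$region[i])
    if ((rm$end[i] - rm$start[i]) %% 3L != 0L)
      stop("region map for '", gene_name, "': length of ", rm$region[i],
           " is not a whole number of codons")
    if (i > 1 && rm$start[i] != rm$end[i - 1])
      stop("region map for '", gene_name, "': ", rm$region[i],
           " does not start where ", rm$region[i - 1], " ends (overlap or gap)")
  }
  if (max(rm$end) + 3L > seq_len)
    stop("region map for '", gene_name, "': no room for the conserved Cys codon after FR3")
  rownames(rm) <- NULL
  rm
}

#' Germline reference set
#'
#' Container for a collection of [germline_gene()] objects with lookup by
#' name, segment and family. At least one gene per segment type is required
#' and names must be unique.
#'
#' @param genes List of `germline_gene` objects.
#' @return An object of class `germline_set` with elements `genes` (named
#'   list) and `index` (data.frame of name, segment, family, length).
#' @export
germline_set <- function(genes) {
  stopifnot(length(genes) > 0)
  nm <- vapply(genes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate gene names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(genes) <- nm
  seg <- vapply(genes, `[[`, "", "segment")
  if (!all(c("V", "D", "J") %in% seg))
    stop("germline set must contain at least one V, one D and one J gene")
  idx <- data.frame(name = nm, segment = seg,
                    family = vapply(genes, `[[`, "", "family"),
                    length = vapply(genes, function(g) nchar(g$sequence), 0L),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(genes = genes, index = idx), class = "germline_set")
}

#' @export
print.germline_set <- function(x, ...) {
  tab <- table(x$index$segment)
  cat("germline_set:", paste(tab, names(tab), collapse = ", "), "genes\n")
  invisible(x)
}

#' Genes of one segment type
#'
#' @param set A `germline_set`.
#' @param segment `"V"`, `"D"` or `"J"`.
#' @return Named list of `germline_gene` objects.
#' @export
segment_genes <- function(set, segment) {
  set$genes[set$index$segment == segment]
}

gene_seqs <- function(set, segment) {
  vapply(segment_genes(set, segment), `[[`, "", "sequence")
}

#' Load a germline reference from FASTA plus a region table
#'
#' The FASTA header of each record is `name|segment|family`. The region table
#' is tab-separated with columns `gene`, `region`, `start`, `end` (0-based
#' half-open, gene-local): V genes require rows FR1, CDR1, FR2, CDR2, FR3;
#' J genes require a single `TRP` row locating the conserved tryptophan
#' codon. Parsing is strict: a missing or invalid region row is an error
#' naming the offending gene. Lowercase bases are accepted and uppercased.
#'
#' @param fasta_path Path to the germline FASTA.
#' @param region_table_path Path to the region table TSV.
#' @return A [germline_set()].
#' @export
load_germline_set <- function(fasta_path, region_table_path) {
  if (!file.exists(fasta_path)) stop("no such file: ", fasta_path)
  if (!file.exists(region_table_path)) stop("no such file: ", region_table_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  regions <- read.delim(region_table_path, stringsAsFactors = FALSE)
  need <- c("gene", "region", "start", "end")
  if (!all(need %in% names(regions)))
    stop("region table must have columns gene, region, start, end")
  genes <- lapply(seq_along(seqs), function(i) {
    hdr <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1]]
    if (length(hdr) != 3)
      stop("malformed FASTA header (need name|segment|family): ", names(seqs)[i])
    name <- hdr[1]; segment <- hdr[2]; family <- hdr[3]
    rrows <- regions[regions$gene == name, , drop = FALSE]
    if (segment == "V") {
      if (nrow(rrows) == 0) stop("no region rows for V gene '", name, "'")
      germline_gene(name, segment, family, as.character(seqs[[i]]),
                    region_map = rrows[, c("region", "start", "end")])
    } else if (segment == "J") {
      trp <- rrows[rrows$region == "TRP", , drop = FALSE]
      if (nrow(trp) != 1) stop("J gene '", name, "' needs exactly one TRP region row")
      germline_gene(name, segment, family, as.character(seqs[[i]]),
                    anchor_start = trp$start)
    } else {
      germline_gene(name, segment, family, as.character(seqs[[i]]))
    }
  })
  germline_set(genes)
}

#' Write a germline set to FASTA plus a region table
#'
#' Inverse of [load_germline_set()]: a round trip reproduces the set exactly.
#'
#' @param set A `germline_set`.
#' @param fasta_path,region_table_path Output paths.
#' @export
write_germline_set <- function(set, fasta_path, region_table_path) {
  seqs <- Biostrings::DNAStringSet(vapply(set$genes, `[[`, "", "sequence"))
  names(seqs) <- vapply(set$genes, function(g)
    paste(g$name, g$segment, g$family, sep = "|"), "")
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- lapply(set$genes, function(g) {
    if (g$segment == "V")
      cbind(gene = g$name, g$region_map)
    else if (g$segment == "J")
      data.frame(gene = g$name, region = "TRP", start = g$anchor_start,
                 end = g$anchor_start + 3L)
    else NULL
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  write.table(tab, region_table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

# Toy V region lengths (nt): 96 codons in total, close to a real IGHV gene,
# with CDR1/CDR2 placed at codons 26-33 and 51-58.
toy_v_region_lengths <- c(FR1 = 75L, CDR1 = 24L, FR2 = 51L, CDR2 = 24L, FR3 = 114L)

#' Build a deterministic toy germline reference
#'
#' Generates a synthetic germline set with `n_v_families` V-gene families of
#' `genes_per_family` members each, plus `n_d` D and `n_j` J genes. Family
#' members are derived from a common founder by ~6% point substitution so
#' that within-family identity stays >= 85% while unrelated families stay
#' <= 70% identical, keeping gene assignment well-posed. All V genes share a
#' fixed FR1 start (so local alignments anchor at the gene start) and end
#' with the conserved Cys codon (TGT) followed by a 6-nt junction-proximal
#' tail that recombination may trim. J genes are 48 nt with the conserved
#' Trp codon (TGG) at offset 12.
#'
#' @param n_v_families,genes_per_family,n_d,n_j Counts, all >= 1.
#' @param seed Integer seed; the result is a pure function of the arguments.
#' @return A [germline_set()].
#' @export
build_toy_germline_set <- function(n_v_families = 7, genes_per_family = 3,
                                   n_d = 10, n_j = 6, seed = 1) {
  stopifnot(n_v_families >= 1, genes_per_family >= 1, n_d >= 1, n_j >= 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rseq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    mutate_seq <- function(s, rate, protect = integer(0)) {
      x <- strsplit(s, "")[[1]]
      hit <- which(runif(length(x)) < rate)
      hit <- setdiff(hit, protect)
      for (i in hit) x[i] <- sample(setdiff(bases, x[i]), 1)
      paste(x, collapse = "")
    }
    fr1_start <- "CAGGTGCAGCTG"  # shared FR1 start, 12 nt
    region_len <- toy_v_region_lengths
    core_len <- sum(region_len)  # 288
    rm <- data.frame(region = names(region_len),
                     start = cumsum(c(0L, unname(region_len[-5]))),
                     end = cumsum(unname(region_len)))
    genes <- list()
    for (f in seq_len(n_v_families)) {
      founder <- paste0(fr1_start, rseq(core_len - nchar(fr1_start)), "TGT", rseq(6))
      for (k in seq_len(genes_per_family)) {
        s <- if (k == 1) founder else
          mutate_seq(founder, 0.06, protect = c(1:12, (core_len + 1):(core_len + 3)))
        genes[[length(genes) + 1]] <- germline_gene(
          name = sprintf("VH%d-%d", f, k), segment = "V",
          family = sprintf("VH%d", f), sequence = s, region_map = rm)
      }
    }
    for (d in seq_len(n_d)) {
      len <- sample(15:27, 1)
      genes[[length(genes) + 1]] <- germline_gene(
        name = sprintf("D%d", d), segment = "D", family = sprintf("D%d", d),
        sequence = rseq(len))
    }
    for (j in seq_len(n_j)) {
      genes[[length(genes) + 1]] <- germline_gene(
        name = sprintf("J%d", j), segment = "J", family = sprintf("J%d", j),
        sequence = paste0(rseq(12), "TGG", rseq(33)), anchor_start = 12L)
    }
    germline_set(genes)
  })
}
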