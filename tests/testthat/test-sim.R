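degenerate_config <- function(gl, n = 10, seed = 1, ...) {
  sim_config(gl, n,
             trim_v_dist = 1, trim_d_dist = 1, trim_j_dist = 1,
             n_insertion_dist = 1,
             shm_rate_per_region = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0, FR3 = 0),
             naive_fraction = 0,
             sha_indel_rate_per_codon = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0, FR3 = 0),
             homopolymer_error_rate = 0,
             defect_fractions = c(short = 0, frameshift = 0, ambiguous = 0),
             seed = seed, ...)
}

test_that("degenerate config yields exact V+D+J concatenations", {
  gl <- shared_germline()
  cfg <- degenerate_config(gl, n = 30, enforce_frame = FALSE)
  pool <- simulate_repertoire(cfg, gl)
  tr <- pool$truth
  expected <- vapply(seq_len(nrow(tr)), function(i)
    paste0(gl$genes[[tr$true_v[i]]]$sequence,
           gl$genes[[tr$true_d[i]]]$sequence,
           gl$genes[[tr$true_j[i]]]$sequence), "")
  expect_identical(unname(pool$reads), expected)
  # with frame control on, clean junctions come out in frame instead
  cfg2 <- degenerate_config(gl, n = 30)
  pool2 <- simulate_repertoire(cfg2, gl)
  expect_true(all(pool2$truth$junction_length %% 3 == 0))
  expect_true(all(pool2$truth$n2_len <= 2))
})

test_that("simulation is byte-identical for identical config and seed", {
  gl <- shared_germline()
  cfg <- sim_config(gl, 200, seed = 42)
  p1 <- simulate_repertoire(cfg, gl)
  p2 <- simulate_repertoire(cfg, gl)
  expect_identical(p1$reads, p2$reads)
  expect_identical(p1$truth, p2$truth)
  p3 <- simulate_repertoire(sim_config(gl, 200, seed = 43), gl)
  expect_false(identical(p1$reads, p3$reads))
})

test_that("planted family mass is recovered by the generator (binomial interval)", {
  gl <- shared_germline()
  vu <- family_usage_vector(gl, c(VH3 = 0.40, VH1 = 0.10, VH2 = 0.10, VH4 = 0.10,
                                  VH5 = 0.10, VH6 = 0.10, VH7 = 0.10))
  cfg <- sim_config(gl, 10000, v_usage = vu, seed = 5)
  pool <- simulate_recombination(cfg, gl)
  fam <- gl$index$family[match(pool$truth$true_v, gl$index$name)]
  # binomial 99% interval at n = 10,000 and p = 0.40 is well within +/- 0.015
  expect_lt(abs(mean(fam == "VH3") - 0.40), 0.015)
})

test_that("usage vectors naming unknown genes are rejected", {
  gl <- shared_germline()
  expect_error(sim_config(gl, 10, v_usage = c(NOPE = 1)), "unknown genes")
  expect_error(sim_config(gl, 10, v_usage = setNames(
    rep(0.5, 2), c("VH1-1", "VH1-2"))), NA)  # partial support is fine if it sums to 1
})

test_that("zero-rate SHM leaves reads untouched; recorded events match read edits", {
  gl <- shared_germline()
  cfg <- degenerate_config(gl, n = 20, seed = 8)
  pool <- simulate_recombination(cfg, gl)
  shm <- apply_shm(pool$reads, pool$truth, cfg, gl)
  expect_identical(shm$reads, pool$reads)
  expect_true(all(shm$truth$total_mutations == 0))
  expect_true(all(shm$truth$sha_indel_events == ""))

  cfg2 <- sim_config(gl, 400,
                     shm_rate_per_region = c(FR1 = 0.02, CDR1 = 0.04, FR2 = 0.02,
                                             CDR2 = 0.04, FR3 = 0.02),
                     naive_fraction = 0,
                     sha_indel_rate_per_codon = c(FR1 = 0, CDR1 = 0.02, FR2 = 0,
                                                  CDR2 = 0.02, FR3 = 0),
                     homopolymer_error_rate = 0,
                     defect_fractions = c(short = 0, frameshift = 0, ambiguous = 0),
                     seed = 9)
  pool2 <- simulate_recombination(cfg2, gl)
  clean_len <- nchar(pool2$reads)
  shm2 <- apply_shm(pool2$reads, pool2$truth, cfg2, gl)
  ev <- lapply(shm2$truth$sha_indel_events, decode_indels)
  net <- vapply(ev, function(e)
    3 * (sum(e$type == "insertion") - sum(e$type == "deletion")), 0)
  expect_equal(unname(nchar(shm2$reads) - clean_len), net)
  # events land inside CDR codons only (CDR1 codons 26-33, CDR2 51-58)
  all_ev <- do.call(rbind, ev)
  expect_true(all(all_ev$codon %in% c(26:33, 51:58)))
  expect_true(all(all_ev$length_codons >= 1))
})

test_that("per-region substitution counts match configured binomial means within 3 SE", {
  gl <- shared_germline()
  rates <- c(FR1 = 0.02, CDR1 = 0.04, FR2 = 0.02, CDR2 = 0.04, FR3 = 0.02)
  cfg <- sim_config(gl, 4000, shm_rate_per_region = rates, naive_fraction = 0,
                    sha_indel_rate_per_codon = c(FR1 = 0, CDR1 = 0, FR2 = 0,
                                                 CDR2 = 0, FR3 = 0),
                    homopolymer_error_rate = 0,
                    defect_fractions = c(short = 0, frameshift = 0, ambiguous = 0),
                    seed = 3)
  pool <- simulate_repertoire(cfg, gl)
  lens <- c(FR1 = 75, CDR1 = 24, FR2 = 51, CDR2 = 24, FR3 = 114)
  cols <- c(FR1 = "mut_fr1", CDR1 = "mut_cdr1", FR2 = "mut_fr2",
            CDR2 = "mut_cdr2", FR3 = "mut_fr3")
  n <- nrow(pool$truth)
  for (r in names(lens)) {
    exp_mean <- lens[[r]] * rates[[r]]
    se <- sqrt(lens[[r]] * rates[[r]] * (1 - rates[[r]]) / n)
    expect_lt(abs(mean(pool$truth[[cols[[r]]]]) - exp_mean), 3 * se)
  }
})

test_that("homopolymer noise: rate zero is identity; errors hit runs at the recorded positions", {
  gl <- shared_germline()
  cfg0 <- sim_config(gl, 50, homopolymer_error_rate = 0, seed = 4,
                     defect_fractions = c(short = 0, frameshift = 0, ambiguous = 0))
  pool0 <- simulate_repertoire(cfg0, gl)
  expect_true(all(pool0$truth$n_seq_errors == 0))

  cfg1 <- sim_config(gl, 150, homopolymer_error_rate = 1, naive_fraction = 0,
                     shm_rate_per_region = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0, FR3 = 0),
                     sha_indel_rate_per_codon = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0, FR3 = 0),
                     defect_fractions = c(short = 0, frameshift = 0, ambiguous = 0),
                     seed = 4)
  pool1 <- simulate_repertoire(cfg1, gl)
  tr <- pool1$truth
  expect_true(all(tr$n_seq_errors > 0))  # every read has >= 1 eligible run
  for (i in seq_len(10)) {
    edits <- strsplit(tr$seq_error_positions[i], ";")[[1]]
    pos <- as.integer(sub(".*:", "", edits))
    ty <- sub(":.*", "", edits)
    chars <- strsplit(pool1$reads[i], "")[[1]]
    for (k in seq_along(pos)) {
      # the recorded (post-edit) position sits in/at a homopolymer run
      window <- chars[max(1, pos[k] - 1):min(length(chars), pos[k] + 3)]
      expect_gte(max(rle(window)$lengths), 2)
    }
  }
})

test_that("realized homopolymer error count tracks an independent run census within 3 SE", {
  gl <- shared_germline()
  rate <- 0.02
  cfg <- sim_config(gl, 2000, homopolymer_error_rate = rate, naive_fraction = 0,
                    shm_rate_per_region = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0, FR3 = 0),
                    sha_indel_rate_per_codon = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0, FR3 = 0),
                    defect_fractions = c(short = 0, frameshift = 0, ambiguous = 0),
                    seed = 12)
  # independent census of eligible runs on the clean (noise-free) pool
  cfg0 <- cfg; cfg0$homopolymer_error_rate <- 0
  clean <- simulate_repertoire(cfg0, gl)
  n_runs <- 0
  for (i in seq_len(nrow(clean$truth))) {
    tr <- clean$truth[i, ]
    read <- clean$reads[i]
    v_span <- substr(read, 1, tr$v_part_end)
    j_len <- nchar(gl$genes[[tr$true_j]]$sequence) - tr$trim_j
    j_span <- substr(read, nchar(read) - j_len + 1, nchar(read))
    for (sp in c(v_span, j_span)) {
      r <- rle(strsplit(sp, "")[[1]])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      # 4-base templated flank within the span
      n_runs <- n_runs + sum(r$lengths >= 3 & starts - 4 >= 1 & ends + 4 <= nchar(sp))
    }
  }
  noisy <- simulate_repertoire(cfg, gl)
  observed <- sum(noisy$truth$n_seq_errors)
  expected <- rate * n_runs
  expect_lt(abs(observed - expected), 3 * sqrt(expected) + 3)
})

test_that("defect fractions are realized within 3 SE and truth invariants hold", {
  gl <- shared_germline()
  cfg <- sim_config(gl, 10000,
                    defect_fractions = c(short = 0.02, frameshift = 0.02, ambiguous = 0.02),
                    seed = 6)
  pool <- simulate_repertoire(cfg, gl)
  tab <- table(pool$truth$defect)
  se <- sqrt(10000 * 0.02 * 0.98)
  for (d in c("short", "frameshift", "ambiguous"))
    expect_lt(abs(tab[[d]] - 200), 3 * se)
  clean <- pool$truth$defect == "none"
  expect_true(all(pool$truth$junction_length[clean] %% 3 == 0))
  expect_false(any(grepl("N", pool$reads[clean], fixed = TRUE)))
  expect_true(all(nchar(pool$reads[pool$truth$defect == "short"]) <= 295))
  expect_true(all(pool$truth$junction_length[pool$truth$defect == "frameshift"] %% 3 != 0))
  amb <- pool$truth$defect == "ambiguous"
  expect_true(all(grepl("N", pool$reads[amb], fixed = TRUE)))
})

test_that("write_pool/read_pool round-trips sequences and truth exactly", {
  gl <- shared_germline()
  pool <- simulate_repertoire(sim_config(gl, 3, seed = 2), gl)
  fa <- tempfile(fileext = ".fasta"); tt <- tempfile(fileext = ".tsv")
  write_pool(pool$reads, pool$truth, fa, tt)
  reads2 <- read_pool(fa)
  truth2 <- read_truth(tt)
  expect_identical(unname(reads2), unname(pool$reads))
  expect_identical(names(reads2), names(pool$reads))
  expect_equal(truth2$read_id, pool$truth$read_id)
  expect_equal(truth2$sha_indel_events, pool$truth$sha_indel_events)
  expect_equal(nrow(truth2), 3)
})
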