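test_that("exact germline recombinants get the true calls at 100% V identity", {
  gl <- shared_germline()
  read <- build_recombinant(gl, "VH3-2", "D4", "J2", n1 = "GG", n2 = "T")
  ann <- tissuerep:::annotate_one(read, tissuerep:::build_annot_ctx(gl))
  expect_equal(ann$v_call, "VH3-2")
  expect_equal(ann$d_call, "D4")
  expect_equal(ann$j_call, "J2")
  expect_equal(ann$v_identity, 1)
  expect_equal(ann$total_mutations, 0L)
  expect_equal(ann$sha_indel_events, "")
})

test_that("reads are orientation-checked via reverse complement", {
  gl <- shared_germline()
  read <- build_recombinant(gl, "VH2-1", "D2", "J3")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", read), "")[[1]]), collapse = "")
  a <- assign_segments(rc, gl)
  expect_true(a$rev_comp)
  expect_equal(a$v_call, "VH2-1")
  expect_equal(a$j_call, "J3")
})

test_that("a 40-nt read yields no V call with a short_alignment error", {
  gl <- shared_germline()
  read <- substr(gl$genes[["VH1-1"]]$sequence, 1, 40)
  ann <- tissuerep:::annotate_one(read, tissuerep:::build_annot_ctx(gl))
  expect_true(is.na(ann$v_call))
  expect_equal(ann$error, "short_alignment")
})

test_that("local alignment scores match the Biostrings oracle", {
  gl <- shared_germline()
  set.seed(31)
  v_seqs <- vapply(segment_genes(gl, "V"), `[[`, "", "sequence")[1:5]
  cfg <- sim_config(gl, 6, seed = 77,
                    v_usage = setNames(rep(0.2, 5), names(v_seqs)))
  pool <- simulate_repertoire(cfg, gl)
  for (read in pool$reads[1:4]) {
    mine <- tissuerep:::.sw_score_multi(read, unname(v_seqs), 2L, -2L, 6L, 1L)
    oracle <- vapply(v_seqs, function(s) biostrings_local_score(read, s), 0)
    expect_equal(unname(mine), unname(oracle))
    expect_equal(which.max(mine), unname(which.max(oracle)))
  }
})

test_that("homopolymer correction fixes frameshifting run gaps and nothing else", {
  # extra A in a germline AAA run (frameshifting insertion): corrected
  aln <- make_aln("CAAAAG", "CAAA-G")
  out <- correct_homopolymer_indels(aln, "CAAAG")
  expect_equal(out$n_corrections, 1L)
  expect_equal(tissuerep:::aln_read_seq(out$aln), "CAAAG")
  # missing base in a run (gap in read): restored from the germline
  aln2 <- make_aln("CAA-G", "CAAAG")
  out2 <- correct_homopolymer_indels(aln2, "CAAAG")
  expect_equal(out2$n_corrections, 1L)
  expect_equal(tissuerep:::aln_read_seq(out2$aln), "CAAAG")
  # 1-nt gap outside any run >= 3: untouched
  aln3 <- make_aln("CAT-G", "CATTG")
  out3 <- correct_homopolymer_indels(aln3, "CATTG")
  expect_equal(out3$n_corrections, 0L)
  # codon-length gaps are never altered, even inside a long run
  aln4 <- make_aln("C---AAAG", "CAAAAAAG")
  out4 <- correct_homopolymer_indels(aln4, "CAAAAAAG")
  expect_equal(out4$n_corrections, 0L)
})

test_that("junction extraction: frame, ambiguity and CDR3 arithmetic", {
  gl <- shared_germline()
  ctx <- tissuerep:::build_annot_ctx(gl)
  # junction length = 24 + n1 + |D core| + n2 (no trims, anchors included);
  # pick a D long enough to trim its core to 16 nt -> junction 42 with n1=2
  didx <- gl$index[gl$index$segment == "D", ]
  dname <- didx$name[didx$length >= 17][1]
  trim <- didx$length[didx$name == dname] - 16L
  read42 <- build_recombinant(gl, "VH1-1", dname, "J1", n1 = "GG",
                              trim_d5 = trim %/% 2, trim_d3 = trim - trim %/% 2)
  ann <- tissuerep:::annotate_one(read42, ctx)
  expect_equal(ann$junction_length, 42L)
  expect_true(ann$in_frame)
  expect_false(ann$has_ambiguous_junction)
  aa <- extract_junction_cdr3(ann$v_aln, ann$j_aln,
                              cys_start = gl$genes[["VH1-1"]]$anchor_start,
                              trp_start = gl$genes[["J1"]]$anchor_start,
                              read = read42)
  expect_equal(nchar(aa$cdr3_aa), 12L)  # 42/3 - 2 anchors
  # one extra junction base: out of frame
  read43 <- build_recombinant(gl, "VH1-1", dname, "J1", n1 = "GGA",
                              trim_d5 = trim %/% 2, trim_d3 = trim - trim %/% 2)
  ann43 <- tissuerep:::annotate_one(read43, ctx)
  expect_equal(ann43$junction_length, 43L)
  expect_false(ann43$in_frame)
  # an N in the junction: flagged ambiguous, still in frame
  readN <- build_recombinant(gl, "VH1-1", dname, "J1", n1 = "GN",
                             trim_d5 = trim %/% 2, trim_d3 = trim - trim %/% 2)
  annN <- tissuerep:::annotate_one(readN, ctx)
  expect_true(annN$has_ambiguous_junction)
  expect_true(annN$in_frame)
  expect_true(is.na(annN$cdr3_nt))
})

test_that("mutation counting is per region, substitutions only", {
  gl <- shared_germline()
  g <- gl$genes[["VH1-1"]]
  s <- g$sequence
  aln <- make_aln(s, s)
  mm <- count_mutations(aln, g$region_map)
  expect_equal(unname(mm$counts), c(0L, 0L, 0L, 0L, 0L))
  expect_equal(unname(mm$aligned_lengths), c(75L, 24L, 51L, 24L, 114L))
  # two substitutions inside FR3 (0-based interval [174, 288))
  chars <- strsplit(s, "")[[1]]
  for (p in c(200, 240)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  mm2 <- count_mutations(make_aln(paste(chars, collapse = ""), s), g$region_map)
  expect_equal(unname(mm2$counts), c(0L, 0L, 0L, 0L, 2L))
  # gap columns are excluded from counts and lengths
  aln3 <- make_aln(paste(c(chars[1:90], "-", "-", "-", chars[94:length(chars)]), collapse = ""), s)
  mm3 <- count_mutations(aln3, g$region_map)
  expect_equal(unname(mm3$aligned_lengths)[2], 21L)  # CDR1 lost one codon
})

test_that("SHA indel detection reports codon-length events; 1-nt gaps flag frameshift", {
  gl <- shared_germline()
  g <- gl$genes[["VH1-1"]]
  s <- g$sequence
  ctx <- tissuerep:::build_annot_ctx(gl)
  # deletion of one CDR1 codon (codons 26-33) at a site without a
  # shift-equivalent placement; reported at that codon
  gchars <- strsplit(s, "")[[1]]
  cdl <- Filter(function(cd) tissuerep:::deletion_eligible(gchars, 3L * (cd - 1L)), 26:33)
  cd <- cdl[[1]]
  p0 <- 3L * (cd - 1L)  # 0-based nt of the codon start
  del_read <- paste0(substr(s, 1, p0), substr(s, p0 + 4, nchar(s)))
  aln <- tissuerep:::sw_pair(del_read, s, align_params())
  aln <- tissuerep:::aln_normalize(aln)
  sha <- detect_sha_indels(aln, g$region_map)
  expect_equal(nrow(sha$events), 1L)
  expect_equal(sha$events$type, "deletion")
  expect_equal(sha$events$codon, cd)
  expect_equal(sha$events$length_codons, 1L)
  expect_false(sha$frameshift)
  # 6-nt insertion before codon 58 (0-based nt 171), chosen to not slide
  p <- 171
  ins6 <- paste(rep(setdiff(c("A", "C", "G", "T"), c(gchars[p], gchars[p + 1]))[1:2], 3), collapse = "")
  ins_read <- paste0(substr(s, 1, p), ins6, substr(s, p + 1, nchar(s)))
  aln2 <- tissuerep:::aln_normalize(tissuerep:::sw_pair(ins_read, s, align_params()))
  sha2 <- detect_sha_indels(aln2, g$region_map)
  expect_equal(nrow(sha2$events), 1L)
  expect_equal(sha2$events$type, "insertion")
  expect_equal(sha2$events$codon, 58L)
  expect_equal(sha2$events$length_codons, 2L)
  # a single-nucleotide gap is a frameshift, not an SHA indel
  fs <- make_aln(paste0(substr(s, 1, 100), "-", substr(s, 102, nchar(s))), s)
  sha3 <- detect_sha_indels(fs, g$region_map)
  expect_equal(nrow(sha3$events), 0L)
  expect_true(sha3$frameshift)
})

test_that("clean simulated reads are recovered exactly; annotation is deterministic", {
  gl <- shared_germline()
  cfg <- sim_config(gl, 300, seed = 21)
  pool <- simulate_repertoire(cfg, gl)
  ann <- annotate_reads(pool$reads, gl)
  tr <- pool$truth
  clean <- tr$defect == "none" & tr$n_seq_errors == 0
  expect_gt(sum(clean), 200)
  expect_true(all(ann$v_call[clean] == tr$true_v[clean]))
  expect_true(all(ann$d_call[clean] == tr$true_d[clean]))
  expect_true(all(ann$j_call[clean] == tr$true_j[clean]))
  mut_cols <- c("mut_fr1", "mut_cdr1", "mut_fr2", "mut_cdr2", "mut_fr3")
  tr_cols <- c("mut_fr1", "mut_cdr1", "mut_fr2", "mut_cdr2", "mut_fr3")
  expect_true(all(ann[clean, mut_cols] == tr[clean, tr_cols]))
  expect_true(all(ann$sha_indel_events[clean] == tr$sha_indel_events[clean]))
  expect_true(all(ann$total_mutations[clean] ==
                    rowSums(ann[clean, mut_cols])))
  ann2 <- annotate_reads(pool$reads, gl)
  expect_identical(ann, ann2)
})
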