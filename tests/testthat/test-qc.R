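make_pair <- function(template, l1 = 250, l2 = 250, qv1 = 35, qv2 = 30) {
  L <- nchar(template)
  fwd <- reads_with_qv(substr(template, 1, l1), qv = qv1, ids = "p1")
  rev_seq <- metabarmock:::.revcomp(substr(template, L - l2 + 1, L))
  rev <- reads_with_qv(rev_seq, qv = qv2, ids = "p1")
  list(fwd = fwd, rev = rev)
}

test_that("mates merge at the true overlap", {
  # 250 bp mates over a 400 bp template: overlap 100, merged length 400
  tpl <- random_dna(400, seed = 1)
  pr <- make_pair(tpl)
  m <- merge_paired_reads(pr$fwd, pr$rev)
  expect_equal(m$n_unmerged, 0)
  expect_equal(nchar(m$reads$seq), 400)
  expect_equal(m$reads$seq, tpl)
})

test_that("overlap boundary rules are enforced", {
  # overlap 19 (< 20): rejected
  tpl <- random_dna(2 * 250 - 19, seed = 2)
  pr <- make_pair(tpl)
  m <- merge_paired_reads(pr$fwd, pr$rev)
  expect_equal(m$n_unmerged, 1)
  expect_equal(nrow(m$reads), 0)

  # overlap exactly 20 with 2 mismatches (10%): accepted
  tpl <- random_dna(2 * 250 - 20, seed = 3)
  pr <- make_pair(tpl)
  ov_start <- 250 - 20 + 1
  fwd2 <- pr$fwd
  fwd2$seq <- paste0(substr(fwd2$seq, 1, ov_start - 1),
                     mutate_k(substr(fwd2$seq, ov_start, 250), 2, seed = 4))
  expect_equal(merge_paired_reads(fwd2, pr$rev)$n_unmerged, 0)

  # 3 mismatches (15% > 10%): rejected
  fwd3 <- pr$fwd
  fwd3$seq <- paste0(substr(fwd3$seq, 1, ov_start - 1),
                     mutate_k(substr(fwd3$seq, ov_start, 250), 3, seed = 5))
  expect_equal(merge_paired_reads(fwd3, pr$rev)$n_unmerged, 1)
})

test_that("overlap conflicts resolve to the higher-QV base", {
  tpl <- random_dna(400, seed = 6)
  pr <- make_pair(tpl, qv1 = 20, qv2 = 38)   # reverse mate is better
  ov_start <- 400 - 250 + 1                   # overlap covers 151..250 of fwd
  pr$fwd$seq <- paste0(substr(pr$fwd$seq, 1, 199),
                       mutate_k(substr(pr$fwd$seq, 200, 200), 1),
                       substr(pr$fwd$seq, 201, 250))
  m <- merge_paired_reads(pr$fwd, pr$rev)
  expect_equal(m$reads$seq, tpl)              # reverse base wins
})

test_that("mate-count mismatch errors", {
  pr <- make_pair(random_dna(400, seed = 7))
  expect_error(merge_paired_reads(pr$fwd, pr$rev[c(1, 1), ]), "mismatch")
})

test_that("qv_filter applies the three rules in order", {
  th <- qc_thresholds(407)
  expect_true(qv_filter(reads_with_qv(random_dna(100), qv = 30), th)$pass)

  r <- qv_filter(reads_with_qv(random_dna(100), qv = 19), th)
  expect_false(r$pass)
  expect_equal(r$reason, "mean_qv")

  # 74 bases Q30 + 26 bases Q15: mean 26.1 passes, 26% < Q20 trips rule 2
  rs <- reads_with_qv(random_dna(100), qv = 30)
  rs$qual <- paste0(strrep(rawToChar(as.raw(30 + 33)), 74),
                    strrep(rawToChar(as.raw(15 + 33)), 26))
  r <- qv_filter(rs, th)
  expect_false(r$pass)
  expect_equal(r$reason, "frac_q20")

  # 6% of bases below Q10 trips rule 3 (mean and Q20-fraction both fine)
  rs$qual <- paste0(strrep(rawToChar(as.raw(35 + 33)), 94),
                    strrep(rawToChar(as.raw(5 + 33)), 6))
  r <- qv_filter(rs, th)
  expect_equal(r$reason, "frac_q10")

  expect_error(qv_filter(reads_with_qv(character(0)), th), "empty")
})

test_that("rules 2 and 3 are position-invariant", {
  th <- qc_thresholds(407)
  qual_sorted <- paste0(strrep(rawToChar(as.raw(30 + 33)), 70),
                        strrep(rawToChar(as.raw(15 + 33)), 30))
  perm <- sample(strsplit(qual_sorted, "")[[1]])
  rs1 <- reads_with_qv(random_dna(100)); rs1$qual <- qual_sorted
  rs2 <- rs1; rs2$qual <- paste(perm, collapse = "")
  expect_equal(qv_filter(rs1, th)$reason, qv_filter(rs2, th)$reason)
})

test_that("trim and length filter follow the class rules", {
  th <- qc_thresholds(407)
  # 500 bp -> trim 30 -> truncate to 407
  r <- trim_and_length_filter(reads_with_qv(random_dna(500)), th)
  expect_equal(nchar(r$reads$seq), 407)
  # 335 bp -> 305 bp, retained (>= 300)
  r <- trim_and_length_filter(reads_with_qv(random_dna(335)), th)
  expect_equal(nchar(r$reads$seq), 305)
  # 320 bp -> 290 bp, discarded
  r <- trim_and_length_filter(reads_with_qv(random_dna(320)), th)
  expect_equal(nrow(r$reads), 0)
  expect_equal(r$n_discarded, 1)
  # 463 class uses the 350 bp floor
  th463 <- qc_thresholds(463)
  r <- trim_and_length_filter(reads_with_qv(random_dna(375)), th463)
  expect_equal(r$n_discarded, 1)
  # quality string is trimmed in register with the sequence
  rs <- reads_with_qv(random_dna(500))
  r <- trim_and_length_filter(rs, th)
  expect_equal(nchar(r$reads$qual), nchar(r$reads$seq))
})

test_that("truncation to the target length is idempotent", {
  th <- qc_thresholds(407)
  r1 <- trim_and_length_filter(reads_with_qv(random_dna(600)), th)$reads
  # a second truncation pass has nothing left to remove
  expect_equal(substr(r1$seq, 1, th$target_length), r1$seq)
})

test_that("the QC report conserves counts on mixed-quality input", {
  set.seed(31)
  n <- 60
  seqs <- vapply(sample(c(250, 320, 380, 460), n, TRUE), random_dna,
                 character(1))
  qvs <- sample(c(8, 15, 19, 25, 35), n, TRUE)
  rs <- reads_with_qv(seqs, qv = 30)
  rs$qual <- vapply(seq_len(n), function(i) {
    strrep(rawToChar(as.raw(qvs[i] + 33L)), nchar(seqs[i]))
  }, character(1))
  res <- run_qc(rs, qc_thresholds(407))
  rp <- res$report
  expect_equal(rp$n_in,
               rp$n_fail_mean_qv + rp$n_fail_frac_q20 + rp$n_fail_frac_q10 +
                 rp$n_short + rp$n_retained + rp$n_unmerged)
  expect_true(all(nchar(res$reads$seq) >= 300))
})
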