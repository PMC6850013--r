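test_that("generate_community honours its contract", {
  spec <- community_spec(n_species = 5, min_pairwise_divergence = 0.02,
                         seed = 1)
  cm <- generate_community(spec)
  expect_equal(nrow(cm), 5)
  # all 10 pairwise uncorrected distances exceed the floor
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gt(hamming_p(cm$barcode_seq[i], cm$barcode_seq[j]), 0.02)
  }
  expect_true(all(nchar(cm$barcode_seq) == 658))
  expect_true(all(grepl("^[ACGT]+$", cm$barcode_seq)))
  expect_true(all(cm$mass_mg > 0))
})

test_that("same spec and seed give byte-identical communities", {
  spec <- community_spec(n_species = 5, seed = 9)
  cm1 <- generate_community(spec)
  cm2 <- generate_community(spec)
  expect_identical(cm1, cm2)
})

test_that("gc column is recomputable from the barcode", {
  cm <- small_community()
  gc <- vapply(strsplit(cm$barcode_seq, ""), function(ch) {
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  expect_equal(cm$gc, gc)
})

test_that("mass range spans the requested ratio", {
  cm <- small_community(n = 30, seed = 3)
  r <- attr(cm, "spec")$mass_ratio
  expect_equal(max(cm$mass_mg) / min(cm$mass_mg), r, tolerance = 0.01)
})

test_that("true mismatch counts are recomputable from the site sequences", {
  cm <- small_community()
  mr <- mismatch_report(cm)
  expect_equal(mr$fwd_mismatches_407, cm$fwd_mismatches_407)
  expect_equal(mr$fwd_mismatches_463, cm$fwd_mismatches_463)
  expect_equal(mr$rev_mismatches, cm$rev_mismatches)
})

test_that("mismatch counts follow the requested profile", {
  # one-point profiles pin every species to a fixed count
  prof <- list(fwd_407 = c(`2` = 1), fwd_463 = c(`0` = 1), rev = c(`1` = 1))
  cm <- generate_community(community_spec(n_species = 8, seed = 5,
                                          mismatch_profile = prof))
  expect_true(all(cm$fwd_mismatches_407 == 2))
  expect_true(all(cm$fwd_mismatches_463 == 0))
  expect_true(all(cm$rev_mismatches == 1))
})

test_that("an over-constrained spec fails with an explicit error", {
  expect_error(
    generate_community(community_spec(n_species = 10,
                                      min_pairwise_divergence = 0.6,
                                      seed = 1),
                       mutation_rate = 0.01, max_tries = 3),
    "divergence"
  )
})

test_that("template pooling follows mass^b with exact uniform limit", {
  cm <- small_community()
  uni <- simulate_template_pool(cm, treatment_model("single_leg",
                                                    pool_noise_cv = 0))
  expect_equal(unname(uni), rep(1 / nrow(cm), nrow(cm)))

  m <- treatment_model("bulk_abdomen", pool_noise_cv = 0)
  sh <- simulate_template_pool(cm, m)
  expect_equal(sum(sh), 1)
  expect_equal(unname(sh), unname(cm$mass_mg^0.66 / sum(cm$mass_mg^0.66)))
  # share ratio equals mass_ratio^b exactly when noise is off
  expect_equal(max(sh) / min(sh),
               (max(cm$mass_mg) / min(cm$mass_mg))^0.66)
})

test_that("two-species allometric shares match hand arithmetic", {
  cm <- small_community(n = 2, seed = 11)
  cm$mass_mg <- c(1, 8)
  sh <- simulate_template_pool(
    cm, treatment_model("bulk_abdomen", mass_exponent = 2 / 3,
                        pool_noise_cv = 0))
  expect_equal(unname(sh), c(1 / 5, 4 / 5))  # 8^(2/3) = 4
})

test_that("PCR amplification bias follows the efficiency model", {
  m <- treatment_model("bulk_abdomen", pcr_cycles = 10, max_efficiency = 1,
                       mismatch_penalty = 0.5)
  a <- simulate_amplicon_pool(c(0.5, 0.5), c(0L, 2L), m)
  expect_equal(sum(a), 1)
  # independent evaluation: (1+1)^10 vs (1+0.5^2)^10
  expect_equal(unname(a[1] / a[2]), (2 / 1.25)^10)

  # penalty 1: amplification is mismatch-blind
  m1 <- treatment_model("bulk_abdomen", mismatch_penalty = 1)
  tmpl <- c(0.2, 0.3, 0.5)
  expect_equal(unname(simulate_amplicon_pool(tmpl, c(0L, 3L, 7L), m1)), tmpl)

  # strictly decreasing in mismatch count at equal template
  m2 <- treatment_model("bulk_abdomen")
  a2 <- simulate_amplicon_pool(rep(0.2, 5), 0:4, m2)
  expect_true(all(diff(a2) < 0))
})

test_that("read simulation is deterministic and truth-labelled", {
  cm <- small_community()
  sh <- stats::setNames(rep(1 / nrow(cm), nrow(cm)), cm$bin_id)
  pf <- platform_profile("s5_like", sub_rate = 0, indel_rate = 0,
                         read_length_sd = 0)
  r1 <- simulate_reads(sh, cm, 200, pf, 407, seed = 3)
  r2 <- simulate_reads(sh, cm, 200, pf, 407, seed = 3)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 200)
  # error-free reads are exact substrings of their source amplicon
  amps <- amplicon_sequences(cm, 407)
  truth <- read_truth(r1)
  hits <- mapply(function(s, b) grepl(s, amps[[b]], fixed = TRUE),
                 r1$seq, truth)
  expect_true(all(hits))
})

test_that("multinomial read counts match the share vector (GOF)", {
  cm <- small_community(n = 10, seed = 2)
  sh <- stats::setNames((1:10) / sum(1:10), cm$bin_id)
  pf <- platform_profile("s5_like", sub_rate = 0, indel_rate = 0)
  rd <- simulate_reads(sh, cm, 1e4, pf, 407, seed = 8)
  obs <- table(factor(read_truth(rd), levels = cm$bin_id))
  p <- stats::chisq.test(obs, p = sh)$p.value
  expect_gt(p, 0.001)
})

test_that("paired profiles emit mate files with matching ids", {
  cm <- small_community(n = 5, seed = 6)
  sh <- stats::setNames(rep(0.2, 5), cm$bin_id)
  rd <- simulate_reads(sh, cm, 50, platform_profile("miseq_like"), 407,
                       seed = 1)
  expect_named(rd, c("R1", "R2"))
  expect_identical(rd$R1$id, rd$R2$id)
})

test_that("reference library and manifest round-trip", {
  cm <- small_community(n = 8, seed = 13)
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  write_reference_library(cm, fa)
  write_manifest(cm, tsv)
  lib <- read_reference_library(fa)
  expect_identical(unname(lib), cm$barcode_seq)
  expect_identical(names(lib), cm$bin_id)
  mf <- read_manifest(tsv)
  expect_equal(mf$bin_id, cm$bin_id)
  expect_equal(mf$gc, cm$gc, tolerance = 1e-12)
  expect_equal(mf$fwd_mismatches_407, cm$fwd_mismatches_407)
  # manifest GC equals GC recomputed from the FASTA
  gc2 <- vapply(strsplit(unname(lib), ""), function(ch) {
    mean(ch %in% c("G", "C"))
  }, numeric(1))
  expect_equal(mf$gc, gc2, tolerance = 1e-12)
  unlink(c(fa, tsv))
})

test_that("empty community writes valid empty files with a warning", {
  cm <- small_community(n = 2, seed = 1)[0, ]
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  expect_warning(write_reference_library(cm, fa), "empty")
  expect_warning(write_manifest(cm, tsv), "empty")
  expect_length(read_reference_library(fa), 0)
  expect_equal(nrow(read_manifest(tsv)), 0)
  unlink(c(fa, tsv))
})

test_that("FASTQ round-trips through Phred+33", {
  rs <- reads_with_qv(c("ACGTACGTAC", "TTTTGGGGCC"), qv = 27)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(rs, fq)
  back <- read_fastq(fq)
  expect_equal(back$seq, rs$seq)
  expect_equal(back$qual, rs$qual)
  unlink(fq)
})
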