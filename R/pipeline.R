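# End-to-end convenience wrapper: community -> template pool -> PCR ->
# reads -> QC -> assignment -> counts, with the ground truth carried
# alongside.

#' Simulate one sequencing sample of the mock community
#'
#' Runs the generative chain for one treatment, platform and amplicon
#' class: template pooling (mass-scaled with noise), PCR amplification
#' biased by the true primer-mismatch counts (forward best-of-cocktail
#' plus reverse), and read simulation under the platform profile.
#'
#' @param community A `mock_community`.
#' @param treatment Treatment label (see [treatment_model()]).
#' @param platform Platform label (see [platform_profile()]).
#' @param amplicon_class 407 or 463.
#' @param depth Number of reads (or pairs).
#' @param seed Integer seed for the whole sample.
#' @param model Optional [treatment_model()] overriding the defaults.
#' @param profile Optional [platform_profile()] overriding the defaults.
#' @return List with `reads` (a `read_set` or `R1`/`R2` list),
#'   `template_shares`, `amplicon_shares`, `mismatch_counts` and the
#'   arguments used.
#' @export
simulate_sample <- function(community, treatment = "bulk_abdomen",
                            platform = "s5_like", amplicon_class = 407,
                            depth = 10000L, seed = 1L,
                            model = NULL, profile = NULL) {
  if (is.null(model)) model <- treatment_model(treatment)
  if (is.null(profile)) profile <- platform_profile(platform)
  set.seed(seed)
  shares <- simulate_template_pool(community, model)
  mcol <- if (as.integer(amplicon_class) == 407L) "fwd_mismatches_407"
          else "fwd_mismatches_463"
  m <- community[[mcol]] + community$rev_mismatches
  amp <- simulate_amplicon_pool(shares, m, model)
  reads <- simulate_reads(amp, community, depth, profile, amplicon_class)
  list(reads = reads, template_shares = shares, amplicon_shares = amp,
       mismatch_counts = stats::setNames(m, community$bin_id),
       treatment = treatment, platform = platform,
       amplicon_class = as.integer(amplicon_class), depth = depth,
       seed = seed)
}

#' QC, assign and count one simulated sample
#'
#' @param sample Output of [simulate_sample()].
#' @param community The `mock_community` used to simulate it.
#' @param threshold Assignment distance threshold.
#' @param otu_threshold OTU clustering threshold for unmatched reads.
#' @return List with `counts` (named vector over bin ids and OTU ids),
#'   `qc_report`, `assignments` and `otus`.
#' @export
analyze_sample <- function(sample, community, threshold = 0.03,
                           otu_threshold = 0.02) {
  paired <- !is.data.frame(sample$reads)
  th <- qc_thresholds(sample$amplicon_class)
  qc <- run_qc(sample$reads, th, paired = paired)
  lib <- stats::setNames(community$barcode_seq, community$bin_id)
  asg <- assign_reads(qc$reads, lib, threshold = threshold)
  matched <- !is.na(asg$bin_id)
  counts <- table(factor(asg$bin_id[matched], levels = community$bin_id))
  counts <- stats::setNames(as.integer(counts), community$bin_id)
  otus <- cluster_unmatched(asg$seq[!matched], threshold = otu_threshold)
  if (nrow(otus) > 0)
    counts <- c(counts, stats::setNames(otus$size, otus$otu_id))
  list(counts = counts, qc_report = qc$report, assignments = asg,
       otus = otus)
}
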