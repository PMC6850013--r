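# Read simulation and FASTA/FASTQ/manifest I/O.
#
# A read set is a plain data.frame (class "read_set") with columns
# id / seq / qual (Phred+33 string).  The truth label (source bin_id) is
# carried in the read identifier as "<bin_id>|read<n>".

#' Platform profile
#'
#' Caricature of a sequencing platform's read-length and quality
#' behaviour: an Illumina-like instrument produces paired reads of fixed
#' length with near-flat quality, while ion-semiconductor-like instruments
#' produce single-end reads of variable length whose quality declines
#' towards the 3' end, with more indels.  The numeric defaults are free
#' parameters of the simulator, not measured values.
#'
#' @param platform `"miseq_like"`, `"pgm_like"` or `"s5_like"`.
#' @param read_length_mean,read_length_sd Gaussian read-length model,
#'   truncated to `[30, amplicon length]`.
#' @param qv_start Quality value at the first base.
#' @param qv_slope Per-base change in quality value (about 0 for
#'   `miseq_like`, negative otherwise).
#' @param sub_rate,indel_rate Per-base substitution and indel rates.
#' @param paired Emit mate pairs?
#' @return List of class `platform_profile`.
#' @export
platform_profile <- function(platform = c("miseq_like", "pgm_like", "s5_like"),
                             read_length_mean = NULL, read_length_sd = NULL,
                             qv_start = NULL, qv_slope = NULL,
                             sub_rate = NULL, indel_rate = NULL,
                             paired = NULL) {
  platform <- match.arg(platform)
  d <- list(
    miseq_like = list(len = 250, sd = 0,  q0 = 36, qs = 0,
                      sub = 0.003, ind = 5e-05, paired = TRUE),
    s5_like    = list(len = 480, sd = 25, q0 = 32, qs = -0.020,
                      sub = 0.005, ind = 1e-03, paired = FALSE),
    pgm_like   = list(len = 450, sd = 40, q0 = 31, qs = -0.028,
                      sub = 0.007, ind = 2e-03, paired = FALSE)
  )[[platform]]
  p <- list(platform = platform,
            read_length_mean = read_length_mean %||% d$len,
            read_length_sd = read_length_sd %||% d$sd,
            qv_start = qv_start %||% d$q0,
            qv_slope = qv_slope %||% d$qs,
            sub_rate = sub_rate %||% d$sub,
            indel_rate = indel_rate %||% d$ind,
            paired = paired %||% d$paired)
  stopifnot(p$sub_rate >= 0, p$indel_rate >= 0, p$read_length_mean > 0)
  structure(p, class = "platform_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.amplicon_start <- function(amplicon_class) {
  switch(as.character(amplicon_class),
         "407" = .FWD407_START,
         "463" = .FWD463_START,
         stop("amplicon_class must be 407 or 463"))
}

#' Full amplicon sequences of a community
#'
#' The amplicon of a class is the suffix of the barcode starting at that
#' class's forward-primer site and running to the 3' end (both classes
#' share the reverse primer at the barcode's end).
#'
#' @param community A `mock_community`.
#' @param amplicon_class 407 or 463.
#' @return Named character vector of amplicon sequences.
#' @export
amplicon_sequences <- function(community, amplicon_class = 407) {
  st <- .amplicon_start(amplicon_class)
  stats::setNames(substr(community$barcode_seq, st, .BARCODE_LEN),
                  community$bin_id)
}

# memoized quality string for a given length under a linear QV trajectory
.qual_string <- function(len, qv_start, qv_slope, cache) {
  key <- as.character(len)
  if (!is.null(cache[[key]])) return(cache[[key]])
  qv <- pmin(40L, pmax(2L, as.integer(round(qv_start + qv_slope * (seq_len(len) - 1)))))
  s <- intToUtf8(qv + 33L)
  assign(key, s, envir = cache)
  s
}

# apply substitutions and indels to one sequence (character scalar)
.corrupt_seq <- function(s, n_sub, n_ind) {
  ch <- strsplit(s, "")[[1]]
  if (n_sub > 0) {
    pos <- sample.int(length(ch), min(n_sub, length(ch)))
    for (i in pos) ch[i] <- sample(setdiff(.DNA, ch[i]), 1)
  }
  if (n_ind > 0) {
    for (k in seq_len(n_ind)) {
      if (stats::runif(1) < 0.5 && length(ch) > 1) {       # deletion
        ch <- ch[-sample.int(length(ch), 1)]
      } else {                                             # insertion
        at <- sample.int(length(ch) + 1L, 1)
        ch <- append(ch, sample(.DNA, 1), after = at - 1L)
      }
    }
  }
  paste(ch, collapse = "")
}

.apply_errors <- function(seqs, sub_rate, indel_rate) {
  lens <- nchar(seqs)
  n_sub <- stats::rbinom(length(seqs), lens, sub_rate)
  n_ind <- stats::rbinom(length(seqs), lens, indel_rate)
  todo <- which(n_sub + n_ind > 0)
  for (i in todo) seqs[i] <- .corrupt_seq(seqs[i], n_sub[i], n_ind[i])
  seqs
}

.make_read_set <- function(id, seq, qual) {
  structure(data.frame(id = id, seq = seq, qual = qual,
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Simulate an amplicon read set
#'
#' Draws `depth` reads multinomially from the amplicon shares, takes each
#' read from the 5' end of its source amplicon (plus the reverse-complement
#' 3' mate for paired platforms), applies the platform's substitution /
#' indel error model and assigns per-base quality strings from the linear
#' QV trajectory.  The source bin id is recorded in each read identifier.
#'
#' @param shares Amplicon share vector (named by bin id, sums to 1).
#' @param community The `mock_community` the shares refer to.
#' @param depth Number of reads (or read pairs) to simulate.
#' @param profile A [platform_profile()].
#' @param amplicon_class 407 or 463.
#' @param seed Optional integer seed.
#' @return For single-end profiles a `read_set`; for paired profiles a
#'   list with elements `R1` and `R2`.
#' @export
simulate_reads <- function(shares, community, depth,
                           profile = platform_profile("miseq_like"),
                           amplicon_class = 407, seed = NULL) {
  stopifnot(depth > 0)
  if (!is.null(seed)) set.seed(seed)
  amps <- amplicon_sequences(community, amplicon_class)
  stopifnot(length(shares) == length(amps))
  idx <- sample.int(length(shares), depth, replace = TRUE, prob = shares)
  src <- amps[idx]
  amp_len <- nchar(src)
  rl <- as.integer(round(stats::rnorm(depth, profile$read_length_mean,
                                      profile$read_length_sd)))
  rl <- pmin(pmax(rl, 30L), amp_len)
  ids <- sprintf("%s|read%06d", community$bin_id[idx], seq_len(depth))
  cache <- new.env(parent = emptyenv())
  if (profile$paired) {
    r1 <- substr(src, 1L, rl)
    r2 <- vapply(substr(src, amp_len - rl + 1L, amp_len), .revcomp,
                 character(1), USE.NAMES = FALSE)
    r1 <- .apply_errors(r1, profile$sub_rate, profile$indel_rate)
    r2 <- .apply_errors(r2, profile$sub_rate, profile$indel_rate)
    q1 <- vapply(nchar(r1), .qual_string, character(1),
                 qv_start = profile$qv_start, qv_slope = profile$qv_slope,
                 cache = cache)
    q2 <- vapply(nchar(r2), .qual_string, character(1),
                 qv_start = profile$qv_start, qv_slope = profile$qv_slope,
                 cache = cache)
    list(R1 = .make_read_set(ids, r1, q1), R2 = .make_read_set(ids, r2, q2))
  } else {
    rd <- substr(src, 1L, rl)
    rd <- .apply_errors(rd, profile$sub_rate, profile$indel_rate)
    qs <- vapply(nchar(rd), .qual_string, character(1),
                 qv_start = profile$qv_start, qv_slope = profile$qv_slope,
                 cache = cache)
    .make_read_set(ids, rd, qs)
  }
}

#' Truth labels of a read set
#'
#' @param reads A `read_set` (or its `id` column).
#' @return Character vector of source bin ids parsed from the identifiers.
#' @export
read_truth <- function(reads) {
  ids <- if (is.data.frame(reads)) reads$id else reads
  sub("\\|read.*$", "", ids)
}

# ---- I/O ------------------------------------------------------------------

#' Write the reference barcode library as FASTA
#'
#' @param community A `mock_community`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_library <- function(community, path) {
  if (nrow(community) == 0) warning("writing an empty reference library")
  dna <- Biostrings::DNAStringSet(stats::setNames(community$barcode_seq,
                                                  community$bin_id))
  Biostrings::writeXStringSet(dna, filepath = path)
  invisible(path)
}

#' Read a reference library
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_reference_library <- function(path) {
  if (!file.exists(path)) stop("no such reference library: ", path)
  dna <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dna), names(dna))
}

.MANIFEST_COLS <- c("bin_id", "order", "mass_mg", "gc",
                    "fwd_mismatches_407", "fwd_mismatches_463",
                    "rev_mismatches", "rev_site_known")

#' Write the community manifest as TSV
#'
#' Fixed columns: bin_id, order, mass_mg, gc, fwd_mismatches_407,
#' fwd_mismatches_463, rev_mismatches, rev_site_known.
#'
#' @param community A `mock_community`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(community, path) {
  if (nrow(community) == 0) warning("writing an empty manifest")
  utils::write.table(as.data.frame(community)[, .MANIFEST_COLS,
                                              drop = FALSE],
                     file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a community manifest
#'
#' @param path TSV path.
#' @return `data.frame` with the fixed manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a read set as FASTQ (Phred+33)
#'
#' @param reads A `read_set`, or a list with `R1`/`R2` for mates (written
#'   with `_R1`/`_R2` inserted before the extension).
#' @param path Output FASTQ path.
#' @return Path(s) written, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (is.data.frame(reads)) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$id)),
      Biostrings::PhredQuality(reads$qual))
    Biostrings::writeQualityScaledXStringSet(x, filepath = path)
    return(invisible(path))
  }
  stopifnot(all(c("R1", "R2") %in% names(reads)))
  p1 <- sub("(\\.[^.]+)$", "_R1\\1", path)
  p2 <- sub("(\\.[^.]+)$", "_R2\\1", path)
  write_fastq(reads$R1, p1)
  write_fastq(reads$R2, p2)
  invisible(c(p1, p2))
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such FASTQ: ", path)
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  .make_read_set(names(x), as.character(x),
                 as.character(Biostrings::quality(x)))
}
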