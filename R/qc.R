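# Read QC: paired-end merging, quality filtering, head trim and length
# filtering.  Thresholds mirror the hosted-pipeline defaults: reads fail on
# mean QV < 20, >25% of bases below Q20, or >5% below Q10 (strict
# comparisons, checked in that order); retained reads lose 30 bp at the 5'
# end (forward primer), are truncated to the amplicon class length, and are
# discarded below the class-specific minimum length.

#' QC thresholds
#'
#' @param amplicon_class 407 or 463; selects the target length (407/463)
#'   and minimum retained length (300/350).
#' @param min_mean_qv Minimum arithmetic mean per-base quality value.
#' @param max_frac_below_q20 Maximum tolerated fraction of bases with
#'   QV < 20 (strict).
#' @param max_frac_below_q10 Maximum tolerated fraction of bases with
#'   QV < 10 (strict).
#' @param head_trim_bp Bases removed from the 5' end (forward primer).
#' @param merge_min_overlap Minimum mate overlap for pair merging.
#' @param merge_max_diff_frac Maximum mismatch fraction in the overlap.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(amplicon_class = 407,
                          min_mean_qv = 20,
                          max_frac_below_q20 = 0.25,
                          max_frac_below_q10 = 0.05,
                          head_trim_bp = 30L,
                          merge_min_overlap = 20L,
                          merge_max_diff_frac = 0.10) {
  amplicon_class <- as.integer(amplicon_class)
  if (!amplicon_class %in% c(407L, 463L))
    stop("amplicon_class must be 407 or 463")
  target_length <- amplicon_class
  min_length <- if (amplicon_class == 407L) 300L else 350L
  stopifnot(min_mean_qv > 0, max_frac_below_q20 > 0, max_frac_below_q10 > 0,
            head_trim_bp > 0, min_length < target_length)
  structure(list(amplicon_class = amplicon_class,
                 min_mean_qv = min_mean_qv,
                 max_frac_below_q20 = max_frac_below_q20,
                 max_frac_below_q10 = max_frac_below_q10,
                 head_trim_bp = as.integer(head_trim_bp),
                 target_length = target_length,
                 min_length = min_length,
                 merge_min_overlap = as.integer(merge_min_overlap),
                 merge_max_diff_frac = merge_max_diff_frac),
            class = "qc_thresholds")
}

.qual_ints <- function(qual) {
  # one C-level pass over the concatenated quality strings
  lens <- nchar(qual)
  ints <- as.integer(charToRaw(paste(qual, collapse = ""))) - 33L
  list(ints = ints, grp = rep.int(seq_along(qual), lens), lens = lens)
}

#' Quality-filter a single read
#'
#' Applies the three QV rules in printed order (mean, fraction below Q20,
#' fraction below Q10); the reason names the first rule tripped.
#'
#' @param read One-row `read_set` or a list with `seq`/`qual`.
#' @param thresholds A [qc_thresholds()].
#' @return List with `pass` (logical) and `reason` (`NA`, `"mean_qv"`,
#'   `"frac_q20"` or `"frac_q10"`).
#' @export
qv_filter <- function(read, thresholds = qc_thresholds()) {
  qual <- read$qual
  if (length(qual) != 1 || nchar(qual) == 0) stop("empty read")
  qv <- as.integer(charToRaw(qual)) - 33L
  reason <- NA_character_
  if (mean(qv) < thresholds$min_mean_qv) {
    reason <- "mean_qv"
  } else if (mean(qv < 20) > thresholds$max_frac_below_q20) {
    reason <- "frac_q20"
  } else if (mean(qv < 10) > thresholds$max_frac_below_q10) {
    reason <- "frac_q10"
  }
  list(pass = is.na(reason), reason = reason)
}

# vectorized three-rule QV classification; returns factor-like character
.qv_classify <- function(qual, thresholds) {
  qi <- .qual_ints(qual)
  mean_qv <- rowsum(qi$ints, qi$grp, reorder = TRUE)[, 1] / qi$lens
  f20 <- rowsum(as.integer(qi$ints < 20L), qi$grp, reorder = TRUE)[, 1] / qi$lens
  f10 <- rowsum(as.integer(qi$ints < 10L), qi$grp, reorder = TRUE)[, 1] / qi$lens
  reason <- rep(NA_character_, length(qual))
  reason[f10 > thresholds$max_frac_below_q10] <- "frac_q10"
  reason[f20 > thresholds$max_frac_below_q20] <- "frac_q20"
  reason[mean_qv < thresholds$min_mean_qv] <- "mean_qv"
  reason
}

#' Trim and length-filter a read set
#'
#' Removes `head_trim_bp` bases from the 5' end, truncates to the class
#' target length, and discards reads shorter than the class minimum.
#'
#' @param reads A `read_set`.
#' @param thresholds A [qc_thresholds()].
#' @return List with `reads` (trimmed, retained) and `n_discarded`.
#' @export
trim_and_length_filter <- function(reads, thresholds = qc_thresholds()) {
  ht <- thresholds$head_trim_bp
  tl <- thresholds$target_length
  seq2 <- substr(reads$seq, ht + 1L, ht + tl)
  qual2 <- substr(reads$qual, ht + 1L, ht + tl)
  keep <- nchar(seq2) >= thresholds$min_length
  out <- .make_read_set(reads$id[keep], seq2[keep], qual2[keep])
  list(reads = out, n_discarded = sum(!keep))
}

#' Merge index-matched mate pairs
#'
#' Reverse-complements the reverse mate and joins it to the forward mate at
#' the best overlap: among overlaps of at least `merge_min_overlap` bases,
#' the one with the lowest mismatch fraction (longest wins ties).  Pairs
#' whose best overlap exceeds `merge_max_diff_frac` mismatches are dropped.
#' At overlap disagreements the base with the higher quality value is kept.
#'
#' @param fwd,rev `read_set`s of equal length with matching order.
#' @param thresholds A [qc_thresholds()].
#' @return List with `reads` (merged `read_set`) and `n_unmerged`.
#' @export
merge_paired_reads <- function(fwd, rev, thresholds = qc_thresholds()) {
  if (nrow(fwd) != nrow(rev))
    stop("mate count mismatch: ", nrow(fwd), " forward vs ",
         nrow(rev), " reverse reads")
  min_o <- thresholds$merge_min_overlap
  max_d <- thresholds$merge_max_diff_frac
  ids <- character(0); seqs <- character(0); quals <- character(0)
  n_unmerged <- 0L
  for (i in seq_len(nrow(fwd))) {
    f <- fwd$seq[i]; fq <- fwd$qual[i]
    r <- .revcomp(rev$seq[i])
    rq <- intToUtf8(base::rev(utf8ToInt(rev$qual[i])))
    l1 <- nchar(f); l2 <- nchar(r)
    fr <- charToRaw(f); rr <- charToRaw(r)
    best_o <- 0L; best_frac <- Inf
    if (min(l1, l2) < min_o) {
      n_unmerged <- n_unmerged + 1L
      next
    }
    for (o in seq(min(l1, l2), min_o)) {
      mm <- sum(fr[(l1 - o + 1L):l1] != rr[1:o])
      frac <- mm / o
      if (frac < best_frac) {       # longest-first scan: ties keep longest
        best_frac <- frac
        best_o <- o
        if (mm == 0L) break
      }
    }
    if (best_o >= min_o && best_frac <= max_d) {
      o <- best_o
      fqv <- as.integer(charToRaw(fq)) - 33L
      rqv <- as.integer(charToRaw(rq)) - 33L
      ov_f <- (l1 - o + 1L):l1
      ov_r <- 1:o
      take_r <- rqv[ov_r] > fqv[ov_f]
      ov_seq <- fr[ov_f]
      ov_seq[take_r] <- rr[ov_r][take_r]
      ov_qv <- pmax(fqv[ov_f], rqv[ov_r])
      merged_seq <- paste0(substr(f, 1L, l1 - o), rawToChar(ov_seq),
                           substr(r, o + 1L, l2))
      merged_qv <- c(fqv[seq_len(l1 - o)], ov_qv,
                     rqv[seq_len(l2)[-(1:o)]])
      ids <- c(ids, fwd$id[i])
      seqs <- c(seqs, merged_seq)
      quals <- c(quals, intToUtf8(merged_qv + 33L))
    } else {
      n_unmerged <- n_unmerged + 1L
    }
  }
  list(reads = .make_read_set(ids, seqs, quals), n_unmerged = n_unmerged)
}

#' Run the full QC stage on a read set
#'
#' Optionally merges mates, then applies the QV rules, the 5' trim and the
#' length filter, and returns the retained reads with a count-conserving
#' report.
#'
#' @param reads A `read_set`, or a list with `R1`/`R2` when `paired`.
#' @param thresholds A [qc_thresholds()].
#' @param paired Merge mates first?
#' @return List with `reads` and `report` (a one-row `data.frame`: n_in,
#'   n_unmerged, n_fail_mean_qv, n_fail_frac_q20, n_fail_frac_q10,
#'   n_short, n_retained).
#' @export
run_qc <- function(reads, thresholds = qc_thresholds(), paired = FALSE) {
  if (paired) {
    n_in <- nrow(reads$R1)
    m <- merge_paired_reads(reads$R1, reads$R2, thresholds)
    reads <- m$reads
    n_unmerged <- m$n_unmerged
  } else {
    n_in <- nrow(reads)
    n_unmerged <- 0L
  }
  if (nrow(reads) > 0) {
    reason <- .qv_classify(reads$qual, thresholds)
  } else {
    reason <- character(0)
  }
  pass <- is.na(reason)
  tlf <- trim_and_length_filter(reads[pass, , drop = FALSE], thresholds)
  report <- data.frame(
    n_in = n_in,
    n_unmerged = n_unmerged,
    n_fail_mean_qv = sum(reason == "mean_qv", na.rm = TRUE),
    n_fail_frac_q20 = sum(reason == "frac_q20", na.rm = TRUE),
    n_fail_frac_q10 = sum(reason == "frac_q10", na.rm = TRUE),
    n_short = tlf$n_discarded,
    n_retained = nrow(tlf$reads)
  )
  list(reads = tlf$reads, report = report)
}
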