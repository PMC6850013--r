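# Distance-based assignment of QC-passed reads to reference barcodes and
# greedy centroid clustering of the unmatched remainder.

#' Assign one read to a reference library
#'
#' Computes the distance to every reference and returns the
#' minimum-distance reference if that distance is below the threshold
#' (ties broken by library order); otherwise the read is unmatched.
#'
#' @param read DNA string.
#' @param library Named character vector of reference sequences.
#' @param threshold Maximum (exclusive) distance for a match.
#' @param model Distance model, `"p"` or `"k2p"`.
#' @return List with `bin_id` (`NA` if unmatched) and `distance`.
#' @export
assign_read <- function(read, library, threshold = 0.03, model = "p") {
  if (length(library) == 0) stop("empty reference library")
  d <- .dist_to_refs(read, library, model)
  i <- which.min(d)  # which.min returns the first minimum: library order
  if (d[i] < threshold) {
    list(bin_id = names(library)[i], distance = d[i])
  } else {
    list(bin_id = NA_character_, distance = d[i])
  }
}

# k-mer presence prescreen: shared 6-mer counts between each unique read
# and each reference, used to shortlist candidate references.
.kmer_presence <- function(seqs, width = 6L) {
  x <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::oligonucleotideFrequency(x, width = width)
  Matrix::Matrix(f > 0, sparse = TRUE) * 1
}

#' Assign a read set to a reference library
#'
#' Vectorized assignment: reads are dereplicated, candidate references are
#' shortlisted by shared 6-mer content, and alignment distances are
#' computed only against the shortlist (all references when `prescreen`
#' is off).  With the community's guaranteed inter-reference divergence
#' the shortlist virtually always contains the true nearest reference;
#' `prescreen = FALSE` gives the exact exhaustive behaviour of
#' [assign_read()].
#'
#' @param reads A `read_set` or character vector of sequences.
#' @param library Named character vector of reference sequences.
#' @param threshold Maximum (exclusive) distance for a match.
#' @param model Distance model.
#' @param prescreen Use the k-mer shortlist?
#' @param top_n Candidates retained per read by the prescreen.
#' @return `data.frame` with `id`, `bin_id` (`NA` = unmatched),
#'   `distance`, `seq`.
#' @export
assign_reads <- function(reads, library, threshold = 0.03, model = "p",
                         prescreen = TRUE, top_n = 8L) {
  if (length(library) == 0) stop("empty reference library")
  seqs <- if (is.data.frame(reads)) reads$seq else reads
  ids <- if (is.data.frame(reads)) reads$id else names(reads) %||%
    sprintf("read%06d", seq_along(reads))
  uniq <- unique(seqs)
  u_of <- match(seqs, uniq)
  nref <- length(library)
  top_n <- min(top_n, nref)

  cand <- if (prescreen && nref > top_n) {
    pr <- .kmer_presence(uniq)
    pf <- .kmer_presence(library)
    sc <- as.matrix(pr %*% Matrix::t(pf))             # uniques x refs
    t(apply(sc, 1, function(s) order(s, decreasing = TRUE)[seq_len(top_n)]))
  } else {
    matrix(rep(seq_len(nref), each = length(uniq)), nrow = length(uniq))
  }

  u_dist <- rep(Inf, length(uniq))
  u_bin <- rep(NA_integer_, length(uniq))
  rows_for_ref <- split(rep(seq_len(nrow(cand)), ncol(cand)),
                        as.vector(cand))
  # batch alignments by reference, in ascending library order so that a
  # strictly-better update rule yields first-in-library tie-breaking
  for (r in sort(as.integer(names(rows_for_ref)))) {
    rows <- unique(rows_for_ref[[as.character(r)]])
    d <- .dists_many_to_one(uniq[rows], library[[r]], model)
    upd <- d < u_dist[rows] - 1e-12
    u_dist[rows[upd]] <- d[upd]
    u_bin[rows[upd]] <- r
  }
  matched <- u_dist < threshold
  u_bin[!matched] <- NA_integer_
  data.frame(id = ids,
             bin_id = names(library)[u_bin[u_of]],
             distance = u_dist[u_of],
             seq = seqs,
             stringsAsFactors = FALSE)
}

#' Greedy centroid clustering of unmatched reads
#'
#' Dereplicates the input, orders uniques by descending abundance (ties by
#' lexicographic sequence), and processes them greedily: a sequence joins
#' the first (oldest) centroid within the threshold, otherwise it founds a
#' new OTU.
#'
#' @param seqs Character vector of unmatched read sequences.
#' @param threshold Maximum (inclusive) joining distance.
#' @param model Distance model.
#' @return `data.frame` with `otu_id`, `size`, `centroid`; attribute
#'   `membership` maps each input read to its OTU.
#' @export
cluster_unmatched <- function(seqs, threshold = 0.02, model = "p") {
  if (length(seqs) == 0) {
    out <- data.frame(otu_id = character(0), size = integer(0),
                      centroid = character(0), stringsAsFactors = FALSE)
    attr(out, "membership") <- character(0)
    return(out)
  }
  tab <- table(seqs)
  uniq <- names(tab)
  cnt <- as.integer(tab)
  ord <- order(-cnt, uniq)
  uniq <- uniq[ord]; cnt <- cnt[ord]

  centroids <- character(0)
  otu_of_uniq <- integer(length(uniq))
  sizes <- integer(0)
  for (i in seq_along(uniq)) {
    hit <- 0L
    if (length(centroids) > 0) {
      for (j in seq_along(centroids)) {
        if (pairwise_distance(uniq[i], centroids[j], model) <= threshold) {
          hit <- j
          break
        }
      }
    }
    if (hit == 0L) {
      centroids <- c(centroids, uniq[i])
      sizes <- c(sizes, cnt[i])
      otu_of_uniq[i] <- length(centroids)
    } else {
      sizes[hit] <- sizes[hit] + cnt[i]
      otu_of_uniq[i] <- hit
    }
  }
  otu_ids <- sprintf("OTU%04d", seq_along(centroids))
  out <- data.frame(otu_id = otu_ids, size = sizes, centroid = centroids,
                    stringsAsFactors = FALSE)
  attr(out, "membership") <- otu_ids[otu_of_uniq[match(seqs, uniq)]]
  out
}

#' Build a merged abundance table
#'
#' Merges per-sample count vectors into one rows-by-samples matrix with
#' zeros for absent rows, and appends an in-silico pooled column for every
#' treatment-platform-amplicon group with more than one replicate.
#'
#' @param sample_counts Named list of named integer vectors (names = row
#'   ids); list names are sample ids.
#' @param metadata Optional `data.frame` with one row per sample
#'   (`sample_id`, `treatment`, `replicate`, `platform`, `amplicon`).
#' @return Integer matrix with `metadata` attached as attribute
#'   `"metadata"` (pooled columns get `replicate = "pooled"`).
#' @export
build_abundance_table <- function(sample_counts, metadata = NULL) {
  sids <- names(sample_counts)
  if (is.null(sids) || anyDuplicated(sids))
    stop("sample ids must be unique and named")
  rows <- sort(unique(unlist(lapply(sample_counts, names))))
  tab <- matrix(0L, nrow = length(rows), ncol = length(sids),
                dimnames = list(rows, sids))
  for (s in sids) {
    v <- sample_counts[[s]]
    tab[names(v), s] <- as.integer(v)
  }
  if (!is.null(metadata)) {
    stopifnot(all(c("sample_id", "treatment", "replicate") %in%
                    names(metadata)))
    md <- metadata[match(sids, metadata$sample_id), , drop = FALSE]
    grp_cols <- intersect(c("treatment", "platform", "amplicon"), names(md))
    grp <- interaction(md[, grp_cols, drop = FALSE], drop = TRUE)
    pooled_md <- NULL
    for (g in levels(grp)) {
      members <- sids[grp == g]
      if (length(members) < 2) next
      pid <- paste0(g, ".pooled")
      tab <- cbind(tab, rowSums(tab[, members, drop = FALSE]))
      colnames(tab)[ncol(tab)] <- pid
      row0 <- md[md$sample_id == members[1], , drop = FALSE]
      row0$sample_id <- pid
      row0$replicate <- "pooled"
      pooled_md <- rbind(pooled_md, row0)
    }
    attr(tab, "metadata") <- rbind(md, pooled_md)
  }
  storage.mode(tab) <- "integer"
  tab
}
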