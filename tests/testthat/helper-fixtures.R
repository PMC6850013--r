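# Shared fixtures, built once per test run.  Communities are small so
# every file stays fast; the acceptance tests build their own full-size
# community.

fixture_env <- new.env(parent = emptyenv())

small_community <- function(n = 20, seed = 42) {
  key <- sprintf("cm_%d_%d", n, seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_community(
      community_spec(n_species = n, seed = seed))
  }
  fixture_env[[key]]
}

community_library <- function(cm) {
  stats::setNames(cm$barcode_seq, cm$bin_id)
}

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a read_set built from explicit sequences and a uniform quality value
reads_with_qv <- function(seqs, qv = 30, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  structure(data.frame(
    id = ids, seq = seqs,
    qual = vapply(nchar(seqs),
                  function(l) strrep(rawToChar(as.raw(qv + 33L)), l),
                  character(1)),
    stringsAsFactors = FALSE
  ), class = c("read_set", "data.frame"))
}

# mutate exactly k positions of a sequence (substitutions only)
mutate_k <- function(seq, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# independent p-distance for equal-length, gapless sequences
hamming_p <- function(a, b) {
  mean(charToRaw(a) != charToRaw(b))
}
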