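# Pairwise sequence distance on a semi-global (end-gap-free) alignment.
# Reads are truncated amplicon substrings, so end gaps carry no signal;
# distance is computed over aligned columns where both sequences carry an
# unambiguous base.  The alignment kernel is compiled (src/align.cpp);
# the uncorrected p distance is the default, with the Kimura
# two-parameter correction available where transition / transversion
# structure matters.

.TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

.dist_from_stats <- function(stats_row, model) {
  stats_row <- as.numeric(stats_row)
  n <- stats_row[1]
  if (n == 0) return(Inf)
  if (model == "p") return(stats_row[2] / n)
  P <- stats_row[3] / n
  Q <- (stats_row[2] - stats_row[3]) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(Inf)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise distance between two DNA sequences
#'
#' Aligns the two sequences semi-globally (end gaps free; match +1,
#' mismatch -1, gap -2) and computes a distance over the aligned columns
#' in which both sequences have a plain `A`/`C`/`G`/`T` base.  Model
#' `"p"` is the mismatch fraction; `"k2p"` is the Kimura two-parameter
#' distance \eqn{-\frac12\ln(1-2P-Q) - \frac14\ln(1-2Q)} with `P`/`Q`
#' the transition/transversion fractions.  Where the k2p logarithms are
#' undefined (saturation) the sentinel `Inf` is returned.
#'
#' @param a,b DNA strings (nonempty).
#' @param model `"p"` (uncorrected, default) or `"k2p"`.
#' @return Nonnegative distance (p in `[0, 1]`; k2p may exceed it, `Inf`
#'   at saturation).
#' @export
pairwise_distance <- function(a, b, model = c("p", "k2p")) {
  model <- match.arg(model)
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be nonempty")
  st <- .align_stats_cpp(a, b)
  .dist_from_stats(st[1, ], model)
}

# distances from one query to a set of references
.dist_to_refs <- function(query, refs, model = "p") {
  vapply(refs, function(r) {
    .dist_from_stats(.align_stats_cpp(query, r)[1, ], model)
  }, numeric(1), USE.NAMES = FALSE)
}

# distances from many queries to a single reference (vectorized in C++)
.dists_many_to_one <- function(queries, ref, model = "p") {
  st <- .align_stats_cpp(queries, ref)
  apply(st, 1, .dist_from_stats, model = model)
}
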