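# IUPAC-aware primer--template mismatch scoring.
# Mismatches are substitution-only at fixed mapped coordinates: a template
# base compatible with a degenerate primer symbol counts as a match.

#' IUPAC degeneracy sets
#'
#' @return Named list mapping each of the 15 IUPAC DNA symbols to the set
#'   of plain bases it stands for.
#' @export
iupac_degeneracy_sets <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"),
       H = c("A", "C", "T"), V = c("A", "C", "G"),
       N = c("A", "C", "G", "T"))
}

#' Does a primer symbol match a template base?
#'
#' @param primer_symbol Single IUPAC symbol.
#' @param template_base Single base in `A`, `C`, `G`, `T`.
#' @return `TRUE` iff the base is in the symbol's degeneracy set.
#' @export
iupac_match <- function(primer_symbol, template_base) {
  sets <- iupac_degeneracy_sets()
  if (is.null(sets[[primer_symbol]]))
    stop("not an IUPAC DNA symbol: ", primer_symbol)
  template_base %in% sets[[primer_symbol]]
}

#' Count primer--template mismatches
#'
#' Number of positions of the template site incompatible with the primer's
#' degeneracy sets.  Primer and site must already be mapped to the same
#' coordinates and have equal length; no indels are considered.
#'
#' @param primer IUPAC DNA string.
#' @param template_site Plain DNA string of the same length.
#' @return Integer mismatch count.
#' @export
count_mismatches <- function(primer, template_site) {
  if (nchar(primer) != nchar(template_site))
    stop("primer and template site must have equal length (",
         nchar(primer), " vs ", nchar(template_site), ")")
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template_site, "")[[1]]
  pi <- match(p, rownames(.IUPAC_OK))
  ti <- match(t, colnames(.IUPAC_OK))
  if (anyNA(pi)) stop("not an IUPAC DNA symbol: ",
                      paste(unique(p[is.na(pi)]), collapse = ", "))
  if (anyNA(ti)) stop("template must be plain A/C/G/T, got: ",
                      paste(unique(t[is.na(ti)]), collapse = ", "))
  sum(!.IUPAC_OK[cbind(pi, ti)])
}

# primer symbol x template base compatibility lookup
.IUPAC_OK <- local({
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  m <- matrix(FALSE, length(sets), 4,
              dimnames = list(names(sets), c("A", "C", "G", "T")))
  for (s in names(sets)) m[s, sets[[s]]] <- TRUE
  m
})

#' Best mismatch count across a primer cocktail
#'
#' A template's mismatch count against a cocktail is taken from the member
#' with the best (fewest-mismatch) correspondence.
#'
#' @param cocktail Character vector of IUPAC primers (nonempty).
#' @param template_site Plain DNA string.
#' @return Minimum mismatch count over cocktail members.
#' @export
best_cocktail_mismatch <- function(cocktail, template_site) {
  if (length(cocktail) == 0) stop("empty primer cocktail")
  min(vapply(cocktail, count_mismatches, integer(1),
             template_site = template_site))
}

#' Combined forward + reverse mismatch count
#'
#' The summed 5' + 3' mismatch count is only defined for species whose
#' reverse primer-binding site sequence is available.
#'
#' @param fwd_count,rev_count Integer mismatch counts.
#' @param rev_known Logical; is the reverse site sequence available?
#' @return `fwd_count + rev_count`, or `NA_integer_` when `rev_known` is
#'   `FALSE`.
#' @export
combined_mismatch <- function(fwd_count, rev_count, rev_known) {
  ifelse(rev_known, fwd_count + rev_count, NA_integer_)
}

#' Default primer set
#'
#' Synthetic stand-ins for the degenerate COI primer cocktails: two forward
#' primers for the short (407 bp) amplicon class, one for the long (463 bp)
#' class, and a shared two-member reverse cocktail.  The sequences are
#' invented 26-mers with degenerate third-codon-like positions; they are
#' not published primers, only carriers for the mismatch machinery.
#'
#' @return List of class `primer_set` with elements `forward_407`,
#'   `forward_463`, `reverse` (character vectors of IUPAC primers).
#' @export
default_primer_set <- function() {
  structure(list(
    forward_407 = c(
      "GGDACWGGHTGAACWGTWTACCCYCC",
      "GGAACWGGATGRACWGTNTACCCNCC"
    ),
    forward_463 = c(
      "ATYCAYGGWATTACYATRGAYYTAGC"
    ),
    reverse = c(
      "TAWACYTCWGGRTGWCCRAARAAYCA",
      "TANACYTCNGGRTGNCCAAARAATCA"
    )
  ), class = "primer_set")
}

#' Per-species mismatch report
#'
#' Recomputes best-of-cocktail forward mismatches per amplicon class, the
#' reverse mismatch count, and the combined 5' + 3' count (defined only for
#' species with a known reverse site) from the primer-binding site
#' sequences of a community.
#'
#' @param community A `mock_community`.
#' @param primers A `primer_set`.
#' @return `data.frame` keyed by `bin_id` with columns
#'   `fwd_mismatches_407`, `fwd_mismatches_463`, `rev_mismatches`,
#'   `combined_407`, `combined_463`.
#' @export
mismatch_report <- function(community, primers = default_primer_set()) {
  f407 <- vapply(community$fwd_site_407, best_cocktail_mismatch,
                 integer(1), cocktail = primers$forward_407,
                 USE.NAMES = FALSE)
  f463 <- vapply(community$fwd_site_463, best_cocktail_mismatch,
                 integer(1), cocktail = primers$forward_463,
                 USE.NAMES = FALSE)
  rev_m <- vapply(community$rev_site, function(s) {
    best_cocktail_mismatch(primers$reverse, .revcomp(s))
  }, integer(1), USE.NAMES = FALSE)
  data.frame(
    bin_id = community$bin_id,
    fwd_mismatches_407 = f407,
    fwd_mismatches_463 = f463,
    rev_mismatches = rev_m,
    combined_407 = combined_mismatch(f407, rev_m, community$rev_site_known),
    combined_463 = combined_mismatch(f463, rev_m, community$rev_site_known),
    stringsAsFactors = FALSE
  )
}

#' Mismatch-class abundance profile
#'
#' Summarizes read counts by primer-mismatch class: for each class 0, 1,
#' 2, ..., the number of species, the median read count and the median
#' relative abundance.
#'
#' @param counts Named integer vector of read counts (names = bin ids).
#' @param mismatches Named integer vector of mismatch counts covering the
#'   same ids; `NA` entries (undefined combined counts) are dropped.
#' @return `data.frame` with columns `mismatch_class`, `n`,
#'   `median_count`, `median_rel_abundance`, ordered by class.
#' @export
mismatch_abundance_profile <- function(counts, mismatches) {
  if (length(counts) == 0 || sum(counts) == 0)
    stop("empty abundance table")
  ids <- intersect(names(counts), names(mismatches))
  m <- mismatches[ids]
  keep <- !is.na(m)
  ids <- ids[keep]
  m <- m[keep]
  cts <- counts[ids]
  rel <- cts / sum(counts)
  cls <- sort(unique(m))
  out <- do.call(rbind, lapply(cls, function(k) {
    sel <- m == k
    data.frame(mismatch_class = k,
               n = sum(sel),
               median_count = stats::median(cts[sel]),
               median_rel_abundance = stats::median(rel[sel]))
  }))
  rownames(out) <- NULL
  out
}
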