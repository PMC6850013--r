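# Diversity, evenness, recovery and dissimilarity statistics.  Indices are
# computed on relative abundances after the low-frequency floor (rows at
# or below 0.01% of a sample's reads are dropped); natural logarithms
# throughout.

#' Apply the low-abundance floor to a table
#'
#' Per column, zeroes every row whose share of the column total is at or
#' below `min_frac` (the retention rule is strictly greater-than).
#'
#' @param table Count matrix (rows = taxa, columns = samples) or a single
#'   count vector.
#' @param min_frac Abundance floor as a fraction (default `1e-4`, i.e.
#'   0.01%).
#' @return Object of the same shape with sub-floor entries set to zero.
#' @export
abundance_floor <- function(table, min_frac = 1e-4) {
  if (is.null(dim(table))) {
    tot <- sum(table)
    if (tot <= 0) stop("column sum must be positive")
    table[table / tot <= min_frac] <- 0L
    return(table)
  }
  if (any(colSums(table) <= 0)) stop("column sums must be positive")
  apply(table, 2, function(x) {
    x[x / sum(x) <= min_frac] <- 0L
    x
  })
}

#' Renyi entropy
#'
#' \eqn{H_a = \frac{1}{1-a}\ln\sum_i p_i^a}, with the Shannon limit at
#' `a = 1` and `-ln(max p)` at `a = Inf`.
#'
#' @param p Proportion vector (positive entries summing to 1).
#' @param alpha Vector of orders.
#' @return Named numeric vector of entropies.
#' @export
renyi_entropy <- function(p, alpha) {
  p <- p[p > 0]
  h <- vapply(alpha, function(a) {
    if (is.infinite(a)) return(-log(max(p)))
    if (abs(a - 1) < 1e-12) return(-sum(p * log(p)))
    log(sum(p^a)) / (1 - a)
  }, numeric(1))
  stats::setNames(h, as.character(alpha))
}

#' Diversity indices for one sample
#'
#' Shannon \eqn{H = -\sum p\ln p}, Simpson \eqn{D = 1 - \sum p^2}, inverse
#' Simpson \eqn{1/\sum p^2}, Pielou \eqn{J = H/\ln S} and Renyi entropy on
#' an order grid, computed on the proportions of the included (nonzero)
#' rows.
#'
#' @param counts Count (or proportion) vector for one sample; zeros are
#'   excluded from `S`.
#' @param renyi_alphas Renyi order grid.
#' @return List with `richness`, `shannon`, `simpson`, `inv_simpson`,
#'   `pielou` (`NA` when `S = 1`) and `renyi`.
#' @export
diversity_indices <- function(counts,
                              renyi_alphas = c(0, 0.25, 0.5, 1, 2, 4, 8,
                                               16, 32, 64, Inf)) {
  counts <- counts[counts > 0]
  S <- length(counts)
  if (S == 0) stop("no taxa with positive abundance")
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  sum_p2 <- sum(p^2)
  list(richness = S,
       shannon = H,
       simpson = 1 - sum_p2,
       inv_simpson = 1 / sum_p2,
       pielou = if (S == 1) NA_real_ else H / log(S),
       renyi = renyi_entropy(p, renyi_alphas))
}

#' Per-sample diversity report
#'
#' Applies the abundance floor, then computes the index set, the
#' coefficient of variation and both recovery criteria for every column.
#'
#' @param table Count matrix.
#' @param expected_ids Row ids expected in every sample (for recovery).
#' @param min_frac Abundance floor.
#' @return `data.frame`, one row per sample.
#' @export
diversity_report <- function(table, expected_ids = rownames(table),
                             min_frac = 1e-4) {
  fl <- abundance_floor(table, min_frac)
  rec_any <- recovery_rate(table, expected_ids, "any_read")
  rec_flr <- recovery_rate(table, expected_ids, "frac_gt_1e-4",
                           min_frac = min_frac)
  rows <- lapply(seq_len(ncol(table)), function(j) {
    di <- diversity_indices(fl[, j])
    data.frame(sample = colnames(table)[j],
               richness = di$richness,
               shannon = di$shannon,
               simpson = di$simpson,
               inv_simpson = di$inv_simpson,
               pielou = di$pielou,
               cv = coefficient_of_variation(table[, j], min_frac),
               recovery_any_read = rec_any[j],
               recovery_floor = rec_flr[j],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recovery rate of expected taxa
#'
#' Fraction of the expected row ids that meet the detection criterion in
#' each sample: at least one read (`"any_read"`) or a share of the
#' sample's reads strictly above the floor (`"frac_gt_1e-4"`).
#'
#' @param table Count matrix (or named vector for one sample).
#' @param expected_ids Nonempty character vector of row ids.
#' @param criterion `"any_read"` or `"frac_gt_1e-4"`.
#' @param min_frac Floor used by the fractional criterion.
#' @return Named numeric vector of recovery fractions per sample.
#' @export
recovery_rate <- function(table, expected_ids,
                          criterion = c("any_read", "frac_gt_1e-4"),
                          min_frac = 1e-4) {
  criterion <- match.arg(criterion)
  if (length(expected_ids) == 0) stop("expected_ids is empty")
  if (is.null(dim(table))) table <- cbind(sample = table)
  present <- matrix(0, nrow = length(expected_ids), ncol = ncol(table),
                    dimnames = list(expected_ids, colnames(table)))
  found <- intersect(expected_ids, rownames(table))
  sub <- table[found, , drop = FALSE]
  if (criterion == "any_read") {
    present[found, ] <- sub >= 1
  } else {
    shares <- sweep(sub, 2, colSums(table), "/")
    present[found, ] <- shares > min_frac
  }
  colMeans(present)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between every
#' pair of columns.
#'
#' @param table Count matrix with at least two columns.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  if (ncol(table) < 2) stop("need at least two samples")
  if (any(colSums(table) == 0)) stop("all-zero sample column")
  n <- ncol(table)
  d <- matrix(0, n, n, dimnames = list(colnames(table), colnames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      x <- table[, i]; y <- table[, j]
      d[i, j] <- d[j, i] <- sum(abs(x - y)) / sum(x + y)
    }
  }
  d
}

#' Single-linkage dendrogram from a dissimilarity matrix
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @return An `ape::phylo` tree with branch heights from the
#'   agglomeration.
#' @export
single_link_tree <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  ape::as.phylo(hc)
}

#' Write a tree in Newick format
#'
#' @param tree An `ape::phylo`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Kendall rank correlation (tau-b) with normal-approximation p-value
#'
#' Tie-corrected tau-b; the p-value uses the normal approximation with the
#' standard tie-corrected variance of `C - D`.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return List with `tau` and `p_value` (`NA` sentinels when either
#'   variable is constant).
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("constant input: tau undefined")
    return(list(tau = NA_real_, p_value = NA_real_))
  }
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- (C - D) / sqrt((n0 - n1) * (n0 - n2))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- (C - D) / sqrt(varS)
  list(tau = tau, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Coefficient of variation of a sample's counts
#'
#' Sample standard deviation over the mean, computed on the rows retained
#' by the abundance floor.
#'
#' @param counts Count vector.
#' @param min_frac Abundance floor.
#' @return Nonnegative real.
#' @export
coefficient_of_variation <- function(counts, min_frac = 1e-4) {
  if (length(counts) == 0) stop("empty counts")
  x <- abundance_floor(counts, min_frac)
  x <- x[x > 0]
  if (length(x) < 2) stop("fewer than two taxa above the floor")
  stats::sd(x) / mean(x)
}
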