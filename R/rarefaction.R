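# Rarefaction by repeated random subsampling without replacement, and the
# asymptote criterion: consecutive depth-grid points whose slope falls
# below 0.01 new taxa per read indicate saturation.

#' Rarefaction configuration
#'
#' @param depth_grid Ordered read-depth grid; default the eight intervals
#'   `10^2, 10^3, 10^3.5, ..., 10^6` (half powers rounded to integers).
#' @param n_replicates Random subsamples per depth.
#' @param slope_threshold Slope below which an asymptote is declared.
#' @param slope_axis Axis on which the slope denominator is measured:
#'   `"linear"` (reads; default) or `"log10"`.
#' @param seed Optional seed.
#' @return List of class `rarefaction_config`.
#' @export
rarefaction_config <- function(depth_grid = round(10^c(2, 3, 3.5, 4, 4.5,
                                                       5, 5.5, 6)),
                               n_replicates = 10000L,
                               slope_threshold = 0.01,
                               slope_axis = c("linear", "log10"),
                               seed = NULL) {
  slope_axis <- match.arg(slope_axis)
  depth_grid <- as.integer(depth_grid)
  if (any(diff(depth_grid) <= 0)) stop("depth grid must be strictly increasing")
  stopifnot(all(depth_grid > 0), slope_threshold > 0, n_replicates > 0)
  structure(list(depth_grid = depth_grid,
                 n_replicates = as.integer(n_replicates),
                 slope_threshold = slope_threshold,
                 slope_axis = slope_axis,
                 seed = seed),
            class = "rarefaction_config")
}

#' Rarefied richness at one depth
#'
#' Draws `depth` reads without replacement from the observed counts and
#' scores the number of distinct rows hit, repeated `n_replicates` times.
#' The replicate draws are exact multivariate-hypergeometric samples
#' (sequential hypergeometric conditioning), vectorized across replicates.
#'
#' @param counts Nonnegative integer count vector.
#' @param depth Subsample size; if it is at least the total count the full
#'   richness is returned with a warning and zero spread.
#' @param n_replicates Number of replicates.
#' @param seed Optional seed.
#' @return List with `mean` and `sd` of replicate richness.
#' @export
subsample_richness <- function(counts, depth, n_replicates = 10000L,
                               seed = NULL) {
  if (any(counts < 0)) stop("negative counts")
  counts <- as.numeric(counts)
  total <- sum(counts)
  if (total == 0) stop("all counts are zero")
  if (!is.null(seed)) set.seed(seed)
  if (depth >= total) {
    if (depth > total)
      warning("depth ", depth, " exceeds total count ", total,
              "; returning richness at full depth")
    return(list(mean = sum(counts > 0), sd = 0))
  }
  nz <- counts[counts > 0]
  reps <- as.integer(n_replicates)
  rich <- integer(reps)
  left_n <- total
  left_d <- rep(as.numeric(depth), reps)
  for (i in seq_along(nz)) {
    if (i == length(nz)) {
      x <- left_d                       # remainder forced into last class
    } else {
      x <- stats::rhyper(reps, m = nz[i], n = left_n - nz[i], k = left_d)
    }
    rich <- rich + (x > 0L)
    left_d <- left_d - x
    left_n <- left_n - nz[i]
  }
  list(mean = mean(rich), sd = stats::sd(rich))
}

#' Closed-form expected rarefied richness
#'
#' Hypergeometric expectation
#' \eqn{E[S_d] = \sum_i \big(1 - \binom{N-n_i}{d}\big/\binom{N}{d}\big)},
#' used as the analytic reference for the Monte-Carlo subsampler.
#'
#' @param counts Count vector.
#' @param depth Subsample size.
#' @return Expected richness.
#' @export
expected_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (depth >= total) return(length(counts))
  # log-space ratio: C(N-n_i, d) / C(N, d)
  lr <- lchoose(total - counts, depth) - lchoose(total, depth)
  sum(1 - exp(lr))
}

#' Taxon accumulation curve over a depth grid
#'
#' @param counts Count vector.
#' @param config A [rarefaction_config()].
#' @return `data.frame` of class `rarefaction_curve` with columns `depth`,
#'   `mean`, `sd` and `slope` (slope of the segment ending at that depth,
#'   on the configured axis; `NA` for the first point).
#' @export
accumulation_curve <- function(counts, config = rarefaction_config()) {
  if (length(counts) == 0 || sum(counts) == 0)
    stop("counts are empty or all zero")
  if (!is.null(config$seed)) set.seed(config$seed)
  grid <- config$depth_grid[config$depth_grid <= sum(counts)]
  if (length(grid) == 0)
    stop("no grid depth is within the total read count (", sum(counts), ")")
  res <- lapply(grid, function(d) {
    subsample_richness(counts, d, config$n_replicates)
  })
  mean_r <- vapply(res, `[[`, numeric(1), "mean")
  sd_r <- vapply(res, `[[`, numeric(1), "sd")
  xs <- if (config$slope_axis == "log10") log10(grid) else grid
  slope <- c(NA_real_, diff(mean_r) / diff(xs))
  out <- data.frame(depth = grid, mean = mean_r, sd = sd_r, slope = slope)
  class(out) <- c("rarefaction_curve", "data.frame")
  attr(out, "config") <- config
  out
}

#' Asymptote depth of an accumulation curve
#'
#' Returns the left endpoint of the first consecutive grid pair whose
#' slope (new taxa per unit of the configured depth axis) is below the
#' threshold, or `NA` if the curve never flattens.
#'
#' @param curve A `rarefaction_curve`.
#' @param config A [rarefaction_config()]; defaults to the curve's own.
#' @return Depth (integer) or `NA`.
#' @export
asymptote_depth <- function(curve, config = attr(curve, "config")) {
  if (is.null(config)) config <- rarefaction_config()
  if (nrow(curve) < 2) stop("need at least two grid points")
  xs <- if (config$slope_axis == "log10") log10(curve$depth) else curve$depth
  slopes <- diff(curve$mean) / diff(xs)
  hit <- which(slopes < config$slope_threshold)
  if (length(hit) == 0) return(NA_integer_)
  curve$depth[hit[1]]
}

#' Export a rarefaction curve as TSV
#'
#' @param curve A `rarefaction_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rarefaction_tsv <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
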