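# Sequencing-depth requirements for PCR-free metabarcoding.
#
# A random genomic read is informative only if it covers the barcode
# region: the retained fraction is the product of the barcode's share of
# the mitogenome (~5%) and the mitogenome's share of cellular DNA (~1%),
# about 1 read in 2,000.  Recovering most species then becomes a
# coupon-collector problem, and body-size variation inflates the answer
# further because template copy number scales allometrically with mass.

#' Depth-model parameters
#'
#' @param n_species Number of species `N` in the assemblage.
#' @param coverage Target fraction `q` of species to recover.
#' @param coi_fraction Barcode share of the mitochondrial genome.
#' @param mito_fraction Mitochondrial share of total cellular DNA.
#' @param mass_exponent Allometric exponent `b` of template copy number
#'   versus body mass.
#' @param mass_ratio Body-mass ratio `R` between the largest and smallest
#'   species.
#' @return List of class `depth_model_params`.
#' @export
depth_model_params <- function(n_species = 374L, coverage = 0.95,
                               coi_fraction = 0.05, mito_fraction = 0.01,
                               mass_exponent = 0.66, mass_ratio = 7500) {
  stopifnot(n_species >= 1, coverage > 0, coverage <= 1,
            coi_fraction > 0, mito_fraction > 0,
            mass_ratio >= 1)
  structure(list(n_species = as.integer(n_species), coverage = coverage,
                 coi_fraction = coi_fraction, mito_fraction = mito_fraction,
                 mass_exponent = mass_exponent, mass_ratio = mass_ratio),
            class = "depth_model_params")
}

#' Fraction of random genomic reads covering the barcode
#'
#' @param coi_fraction Barcode share of the mitogenome.
#' @param mito_fraction Mitochondrial share of cellular DNA.
#' @return The product; its reciprocal is the "1 in X" read cost.
#' @export
retained_fraction <- function(coi_fraction = 0.05, mito_fraction = 0.01) {
  coi_fraction * mito_fraction
}

#' Expected draws to collect k of N equally likely coupons
#'
#' Standard coupon-collector expectation
#' \eqn{E = \sum_{i=0}^{k-1} N/(N-i)} for the number of uniform draws with
#' replacement needed to observe `k` distinct of `N` categories.
#'
#' @param N Number of categories.
#' @param k Distinct categories to observe (`1 <= k <= N`).
#' @return Expected number of draws.
#' @export
expected_draws <- function(N, k) {
  if (k > N) stop("k must not exceed N")
  if (k < 1) stop("k must be at least 1")
  i <- 0:(k - 1)
  sum(N / (N - i))
}

#' Average draws per species for a coverage target
#'
#' `round(expected_draws(N, ceiling(q * N)) / N)`: with `N = 374` and
#' `q = 0.95` this is 3 sequences per species.
#'
#' @param N Number of species.
#' @param q Coverage fraction.
#' @return Integer draws per species.
#' @export
draws_per_species <- function(N, q) {
  k <- ceiling(q * N)
  # at least one retained read per recovered species is always needed
  max(1L, as.integer(round(expected_draws(N, k) / N)))
}

#' Reads needed to retain one barcode read per species
#'
#' @param N Number of species.
#' @param retained Retained fraction of random reads.
#' @return List with `raw` (`N / retained`) and `rounded` (two
#'   significant figures, the headline convention).
#' @export
reads_for_first_copies <- function(N, retained = retained_fraction()) {
  raw <- N / retained
  list(raw = raw, rounded = signif(raw, 2))
}

#' Reads needed to recover a coverage fraction of species
#'
#' Chains the rounded one-copy requirement with the per-species
#' coupon-collector multiplier (the raw value chains the unrounded
#' factors).
#'
#' @param N Number of species.
#' @param q Coverage fraction.
#' @param retained Retained fraction of random reads.
#' @return List with `raw` and `rounded` read totals.
#' @export
reads_for_coverage <- function(N, q = 0.95, retained = retained_fraction()) {
  fc <- reads_for_first_copies(N, retained)
  k <- ceiling(q * N)
  list(raw = fc$raw * expected_draws(N, k) / N,
       rounded = fc$rounded * draws_per_species(N, q))
}

#' Template-copy ratio across the body-mass range
#'
#' `R^b`: the fold difference in target template between the largest and
#' smallest species when mass spans `R`-fold and copy number scales as
#' mass^`b`.  The rounded value follows the headline convention of the
#' worked example (nearest ten: 7500^0.66 -> 360, 178^0.66 -> 30).
#'
#' @param R Mass ratio.
#' @param b Allometric exponent.
#' @return List with `raw` and `rounded` ratios.
#' @export
template_ratio <- function(R, b = 0.66) {
  raw <- R^b
  list(raw = raw, rounded = round(raw / 10) * 10)
}

#' Reads needed under biomass-driven template skew
#'
#' Worst-case multiplier model: the rarest species holds `1/R^b` of the
#' template of the largest, so the coverage requirement is multiplied by
#' the (rounded) template ratio.
#'
#' @param N Number of species.
#' @param q Coverage fraction.
#' @param retained Retained fraction of random reads.
#' @param R Mass ratio.
#' @param b Allometric exponent.
#' @return List with `raw` and `rounded` read totals.
#' @export
reads_with_biomass <- function(N, q = 0.95, retained = retained_fraction(),
                               R = 7500, b = 0.66) {
  cov <- reads_for_coverage(N, q, retained)
  tr <- template_ratio(R, b)
  list(raw = cov$raw * tr$raw, rounded = cov$rounded * tr$rounded)
}

#' Monte-Carlo coupon collector
#'
#' Simulates draws with replacement under arbitrary species weights until
#' `ceiling(q * N)` distinct species have been seen, and reports the mean
#' and standard deviation of the number of draws over `n_runs` runs.
#'
#' @param N Number of species.
#' @param weights Nonnegative weight per species (uniform by default).
#' @param q Coverage fraction.
#' @param n_runs Number of simulation runs.
#' @param seed Optional seed.
#' @param chunk Draws sampled per batch.
#' @return List with `mean`, `sd` and the per-run draw counts (`draws`).
#' @export
simulate_coupon <- function(N, weights = NULL, q = 0.95, n_runs = 1000L,
                            seed = NULL, chunk = 4096L) {
  if (is.null(weights)) weights <- rep(1, N)
  if (length(weights) != N) stop("weights must have length N")
  if (any(weights < 0) || all(weights == 0))
    stop("weights must be nonnegative and not all zero")
  if (!is.null(seed)) set.seed(seed)
  k <- ceiling(q * N)
  draws <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    seen <- logical(N)
    n_seen <- 0L
    total <- 0
    repeat {
      s <- sample.int(N, chunk, replace = TRUE, prob = weights)
      new <- !duplicated(s) & !seen[s]
      cum <- n_seen + cumsum(new)
      hit <- which(cum >= k)
      if (length(hit) > 0) {
        draws[r] <- total + hit[1]
        break
      }
      seen[s] <- TRUE
      n_seen <- cum[chunk]
      total <- total + chunk
    }
  }
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws)
}

#' Depth-model worked-example table
#'
#' Evaluates the full chain of the depth model for a parameter set:
#' retained fraction, per-species coupon-collector multiplier, one-copy
#' and coverage read totals, the biomass template ratio and the
#' biomass-adjusted total, each as raw and headline-rounded values.
#'
#' @param params A [depth_model_params()].
#' @return `data.frame` with columns `quantity`, `raw`, `rounded`.
#' @export
depth_model_table <- function(params = depth_model_params()) {
  f <- retained_fraction(params$coi_fraction, params$mito_fraction)
  fc <- reads_for_first_copies(params$n_species, f)
  cv <- reads_for_coverage(params$n_species, params$coverage, f)
  tr <- template_ratio(params$mass_ratio, params$mass_exponent)
  bm <- reads_with_biomass(params$n_species, params$coverage, f,
                           params$mass_ratio, params$mass_exponent)
  k <- ceiling(params$coverage * params$n_species)
  ed <- expected_draws(params$n_species, k)
  data.frame(
    quantity = c("retained_fraction", "one_in_reads",
                 "expected_draws_total", "draws_per_species",
                 "reads_one_copy_each", "reads_for_coverage",
                 "template_ratio", "reads_with_biomass"),
    raw = c(f, 1 / f, ed, ed / params$n_species, fc$raw, cv$raw,
            tr$raw, bm$raw),
    rounded = c(f, 1 / f, ed, draws_per_species(params$n_species,
                                                params$coverage),
                fc$rounded, cv$rounded, tr$rounded, bm$rounded),
    stringsAsFactors = FALSE
  )
}
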