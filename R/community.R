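.DNA <- c("A", "C", "G", "T")

# Fixed coordinates (1-based, on the 658 bp barcode) of the primer-binding
# regions and the two nested amplicons.  Both amplicons share the reverse
# primer at the 3' end of the barcode; the two forward primers sit at
# different internal positions so that, after the 30 bp head trim of the
# QC stage, the retained inserts are exactly 407 and 463 bp.
.BARCODE_LEN <- 658L
.PRIMER_LEN <- 26L
.FWD407_START <- 222L   # amplicon 222..658 = 437 bp; minus 30 bp trim = 407
.FWD463_START <- 166L   # amplicon 166..658 = 493 bp; minus 30 bp trim = 463
.REV_START <- 633L      # reverse primer binds the minus strand of 633..658

#' Community specification
#'
#' Parameters of the simulated mock community: number of species, the
#' minimum pairwise barcode divergence enforced between any two members,
#' the body-mass range and distribution, and the per-primer distributions
#' of primer--template mismatch counts.
#'
#' @param n_species Number of species (BINs) in the community.
#' @param min_pairwise_divergence Minimum uncorrected (p) distance required
#'   between every pair of barcodes.
#' @param mass_ratio Ratio of the largest to the smallest abdominal mass;
#'   realized exactly by pinning one species to each extreme.
#' @param mass_distribution `"log_uniform"` or `"log_normal"` placement of
#'   the remaining species between the mass extremes.
#' @param min_mass_mg Smallest abdominal mass in milligrams.
#' @param gc_range Interval of admissible GC fractions for the ancestral
#'   barcode composition.
#' @param mismatch_profile Named list with elements `fwd_407`, `fwd_463`
#'   and `rev`, each a probability vector over mismatch counts 0,1,2,...
#'   (names are the counts). Each must sum to 1.
#' @param rev_site_known_fraction Probability that the reverse
#'   primer-binding site of a species is available to the analyst
#'   (it is always known to the simulator).
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A list of class `community_spec`.
#' @export
community_spec <- function(n_species = 374L,
                           min_pairwise_divergence = 0.02,
                           mass_ratio = 7500,
                           mass_distribution = c("log_uniform", "log_normal"),
                           min_mass_mg = 0.01,
                           gc_range = c(0.30, 0.45),
                           mismatch_profile = default_mismatch_profile(),
                           rev_site_known_fraction = 203 / 369,
                           seed = 1L) {
  mass_distribution <- match.arg(mass_distribution)
  stopifnot(n_species >= 1, mass_ratio >= 1, min_mass_mg > 0,
            min_pairwise_divergence >= 0, min_pairwise_divergence < 1,
            length(gc_range) == 2, gc_range[1] <= gc_range[2],
            gc_range[1] >= 0, gc_range[2] <= 1,
            rev_site_known_fraction >= 0, rev_site_known_fraction <= 1)
  for (nm in c("fwd_407", "fwd_463", "rev")) {
    p <- mismatch_profile[[nm]]
    if (is.null(p) || abs(sum(p) - 1) > 1e-8 || any(p < 0))
      stop("mismatch_profile$", nm, " must be a probability vector summing to 1")
  }
  structure(list(n_species = as.integer(n_species),
                 min_pairwise_divergence = min_pairwise_divergence,
                 mass_ratio = mass_ratio,
                 mass_distribution = mass_distribution,
                 min_mass_mg = min_mass_mg,
                 gc_range = gc_range,
                 mismatch_profile = mismatch_profile,
                 rev_site_known_fraction = rev_site_known_fraction,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Default primer--template mismatch-count distributions
#'
#' One distribution per primer (the two forward primers of the short and
#' long amplicon classes and the shared reverse primer).  The forward
#' profile of the short (407 bp) class puts roughly 17% of species at four
#' or more mismatches and the long (463 bp) class roughly 5%, matching the
#' observed contrast in primer--template correspondence between the two
#' amplicons; the reverse primer is intermediate.
#'
#' @return Named list of probability vectors (names = mismatch counts).
#' @export
default_mismatch_profile <- function() {
  list(
    fwd_407 = c(`0` = 0.25, `1` = 0.22, `2` = 0.20, `3` = 0.16,
                `4` = 0.10, `5` = 0.05, `6` = 0.02),
    fwd_463 = c(`0` = 0.40, `1` = 0.30, `2` = 0.15, `3` = 0.10,
                `4` = 0.04, `5` = 0.01),
    rev     = c(`0` = 0.45, `1` = 0.30, `2` = 0.15, `3` = 0.07, `4` = 0.03)
  )
}

# p-distance between two equal-length gapless sequences held as raw bytes
.hamming_frac <- function(a, b) mean(a != b)

.random_dna <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(.DNA, len, replace = TRUE, prob = p), collapse = "")
}

.mutate_seq <- function(chars, rate) {
  n <- length(chars)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(chars)
  pos <- sample.int(n, k)
  for (i in pos) {
    chars[i] <- sample(setdiff(.DNA, chars[i]), 1)
  }
  chars
}

# Generate a primer-binding site whose best-of-cocktail mismatch count is
# exactly m.  The site is realized from the first cocktail member; rejection
# guards against another member matching the template better.
.site_with_mismatches <- function(cocktail, m, max_tries = 100L,
                                  revcomp_primer = FALSE) {
  ref <- cocktail[[1]]
  sets <- iupac_degeneracy_sets()
  syms <- strsplit(ref, "")[[1]]
  L <- length(syms)
  if (m > L) stop("requested mismatch count exceeds primer length")
  for (try in seq_len(max_tries)) {
    tmpl <- vapply(syms, function(s) {
      opts <- sets[[s]]
      opts[sample.int(length(opts), 1)]
    }, character(1), USE.NAMES = FALSE)
    if (m > 0) {
      pos <- sample.int(L, m)
      for (i in pos) {
        bad <- setdiff(.DNA, sets[[syms[i]]])
        if (length(bad) == 0) next  # N position cannot mismatch; retry below
        tmpl[i] <- bad[sample.int(length(bad), 1)]
      }
    }
    site <- paste(tmpl, collapse = "")
    got <- best_cocktail_mismatch(cocktail, site)
    if (got == m) {
      if (revcomp_primer) site <- .revcomp(site)
      return(site)
    }
  }
  stop("could not realize a primer site with exactly ", m,
       " mismatches against the cocktail after ", max_tries, " attempts")
}

# reverse complement on plain character vectors (IUPAC-aware); avoids
# per-call S4 dispatch, which dominates run time in tight loops
.revcomp <- function(s) {
  vapply(s, function(x) {
    chartr("ACGTRYSWKMBDHVNacgt",
           "TGCAYRSWMKVHDBNtgca",
           rawToChar(rev(charToRaw(x))))
  }, character(1), USE.NAMES = FALSE)
}

.draw_mismatch <- function(profile, n) {
  counts <- as.integer(names(profile))
  counts[sample.int(length(counts), n, replace = TRUE, prob = profile)]
}

#' Generate a mock community
#'
#' Builds `n_species` barcode records by mutating a random ancestral 658 bp
#' sequence until every pair of barcodes differs by more than the minimum
#' pairwise divergence (rejection sampling), then splices primer-binding
#' sites carrying known mismatch counts into fixed coordinates and assigns
#' body masses spanning the requested mass ratio.
#'
#' @param spec A [community_spec()].
#' @param primers A primer set as returned by [default_primer_set()].
#' @param mutation_rate Per-site substitution probability applied to the
#'   ancestor for each species (controls typical pairwise divergence).
#' @param max_tries Rejection-sampling attempts per species before failing.
#' @return A `data.frame` of class `mock_community` with one row per
#'   species: `bin_id`, `order`, `barcode_seq`, `mass_mg`, `gc`,
#'   `fwd_site_407`, `fwd_site_463`, `rev_site`, true mismatch counts per
#'   primer, and the `rev_site_known` flag.
#' @examples
#' cm <- generate_community(community_spec(n_species = 5, seed = 1))
#' nrow(cm)
#' @export
generate_community <- function(spec = community_spec(),
                               primers = default_primer_set(),
                               mutation_rate = 0.08,
                               max_tries = 200L) {
  set.seed(spec$seed)
  n <- spec$n_species
  gc_mid <- mean(spec$gc_range)
  ancestor <- strsplit(.random_dna(.BARCODE_LEN, gc_mid), "")[[1]]

  m407 <- .draw_mismatch(spec$mismatch_profile$fwd_407, n)
  m463 <- .draw_mismatch(spec$mismatch_profile$fwd_463, n)
  mrev <- .draw_mismatch(spec$mismatch_profile$rev, n)

  accepted <- vector("list", n)
  barcodes <- character(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- .mutate_seq(ancestor, mutation_rate)
      # splice primer sites (plus strand) at their fixed coordinates
      f407 <- .site_with_mismatches(primers$forward_407, m407[i])
      f463 <- .site_with_mismatches(primers$forward_463, m463[i])
      rsit <- .site_with_mismatches(primers$reverse, mrev[i],
                                    revcomp_primer = TRUE)
      cand[.FWD407_START:(.FWD407_START + .PRIMER_LEN - 1L)] <-
        strsplit(f407, "")[[1]]
      cand[.FWD463_START:(.FWD463_START + .PRIMER_LEN - 1L)] <-
        strsplit(f463, "")[[1]]
      cand[.REV_START:(.REV_START + .PRIMER_LEN - 1L)] <-
        strsplit(rsit, "")[[1]]
      cr <- charToRaw(paste(cand, collapse = ""))
      clash <- FALSE
      if (i > 1) {
        for (j in seq_len(i - 1L)) {
          if (.hamming_frac(cr, accepted[[j]]) <= spec$min_pairwise_divergence) {
            clash <- TRUE
            break
          }
        }
      }
      if (!clash) {
        accepted[[i]] <- cr
        barcodes[i] <- rawToChar(cr)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("rejection sampling failed: could not place species ", i,
           " with pairwise divergence > ", spec$min_pairwise_divergence,
           " after ", max_tries, " attempts (sequence space too constrained)")
  }

  # body masses: pin the extremes so max/min equals mass_ratio exactly
  u <- if (spec$mass_distribution == "log_uniform") {
    stats::runif(n)
  } else {
    x <- stats::rnorm(n)
    (x - min(x)) / (max(x) - min(x))
  }
  if (n >= 2) {
    ext <- sample.int(n, 2)
    u[ext[1]] <- 0
    u[ext[2]] <- 1
  }
  mass <- spec$min_mass_mg * spec$mass_ratio^u

  orders <- c("Lepidoptera", "Diptera", "Hymenoptera", "Coleoptera",
              "Hemiptera", "Orthoptera", "Araneae", "Trichoptera",
              "Psocodea", "Dermaptera")
  ow <- c(30, 25, 15, 12, 8, 3, 3, 2, 1.5, 0.5)
  order_label <- sample(orders, n, replace = TRUE, prob = ow)

  gc <- vapply(accepted, function(r) {
    mean(r == charToRaw("G") | r == charToRaw("C"))
  }, numeric(1))

  rev_known <- stats::rbinom(n, 1, spec$rev_site_known_fraction) == 1

  cm <- data.frame(
    bin_id = sprintf("MOCK.%04d", seq_len(n)),
    order = order_label,
    barcode_seq = barcodes,
    mass_mg = mass,
    gc = gc,
    fwd_site_407 = substr(barcodes, .FWD407_START,
                          .FWD407_START + .PRIMER_LEN - 1L),
    fwd_site_463 = substr(barcodes, .FWD463_START,
                          .FWD463_START + .PRIMER_LEN - 1L),
    rev_site = substr(barcodes, .REV_START, .REV_START + .PRIMER_LEN - 1L),
    fwd_mismatches_407 = m407,
    fwd_mismatches_463 = m463,
    rev_mismatches = mrev,
    rev_site_known = rev_known,
    stringsAsFactors = FALSE
  )
  attr(cm, "spec") <- spec
  attr(cm, "primers") <- primers
  class(cm) <- c("mock_community", "data.frame")
  cm
}

#' Treatment model for template pooling and PCR bias
#'
#' Describes how per-species template shares are formed under one of the
#' four pooling regimes and how PCR amplifies them.  Template share is
#' proportional to `mass^mass_exponent` times multiplicative lognormal
#' noise; the single-leg regime ignores mass entirely.  Amplification
#' multiplies each template by `(1 + max_efficiency *
#' mismatch_penalty^m)^pcr_cycles` where `m` is the species'
#' primer--template mismatch count.
#'
#' @param treatment One of `"bulk_abdomen"`, `"bulk_leg"`,
#'   `"composite_leg"`, `"single_leg"`.
#' @param mass_exponent Allometric exponent `b` in template share
#'   proportional to mass^b; defaults per treatment (0.66 for bulk abdomen,
#'   0 for single leg).
#' @param pool_noise_cv Coefficient of variation of the lognormal pooling
#'   noise.
#' @param pcr_cycles Total PCR cycles (two rounds of 20 by default).
#' @param max_efficiency Per-cycle amplification efficiency of a
#'   perfectly matched template, in (0, 1].
#' @param mismatch_penalty Multiplicative efficiency factor per primer
#'   mismatch, in (0, 1].
#' @return A list of class `treatment_model`.
#' @export
treatment_model <- function(treatment = c("bulk_abdomen", "bulk_leg",
                                          "composite_leg", "single_leg"),
                            mass_exponent = NULL,
                            pool_noise_cv = NULL,
                            pcr_cycles = 40L,
                            max_efficiency = 0.12,
                            mismatch_penalty = 0.85) {
  treatment <- match.arg(treatment)
  defaults <- list(
    bulk_abdomen  = list(b = 0.66, cv = 0.30),
    bulk_leg      = list(b = 0.50, cv = 0.40),
    composite_leg = list(b = 0.33, cv = 0.50),
    single_leg    = list(b = 0.00, cv = 0.20)
  )[[treatment]]
  if (is.null(mass_exponent)) mass_exponent <- defaults$b
  if (is.null(pool_noise_cv)) pool_noise_cv <- defaults$cv
  stopifnot(pool_noise_cv >= 0, pcr_cycles >= 0,
            max_efficiency > 0, max_efficiency <= 1,
            mismatch_penalty > 0, mismatch_penalty <= 1)
  structure(list(treatment = treatment,
                 mass_exponent = mass_exponent,
                 pool_noise_cv = pool_noise_cv,
                 pcr_cycles = as.integer(pcr_cycles),
                 max_efficiency = max_efficiency,
                 mismatch_penalty = mismatch_penalty),
            class = "treatment_model")
}

#' Simulate per-species template shares
#'
#' @param community A `mock_community`.
#' @param model A [treatment_model()].
#' @param seed Optional integer seed for the pooling noise.
#' @return Numeric vector of shares (named by `bin_id`) summing to 1.
#' @export
simulate_template_pool <- function(community, model, seed = NULL) {
  if (nrow(community) == 0) stop("community is empty")
  if (!is.null(seed)) set.seed(seed)
  b <- model$mass_exponent
  w <- community$mass_mg^b
  if (model$pool_noise_cv > 0) {
    sigma <- sqrt(log(1 + model$pool_noise_cv^2))
    w <- w * exp(stats::rnorm(length(w), -sigma^2 / 2, sigma))
  }
  stats::setNames(w / sum(w), community$bin_id)
}

#' Simulate PCR amplification of a template pool
#'
#' Applies exponential amplification with a per-mismatch geometric penalty
#' on efficiency: `amplicon_i` proportional to
#' `template_i * (1 + max_efficiency * mismatch_penalty^m_i)^pcr_cycles`.
#' Computed in log space to avoid overflow at many cycles.
#'
#' @param template_shares Nonnegative shares summing to 1.
#' @param mismatch_counts Integer mismatch count per species (same length).
#' @param model A [treatment_model()].
#' @return Amplicon share vector summing to 1.
#' @export
simulate_amplicon_pool <- function(template_shares, mismatch_counts, model) {
  stopifnot(length(template_shares) == length(mismatch_counts))
  if (abs(sum(template_shares) - 1) > 1e-6)
    stop("template shares must sum to 1")
  lf <- model$pcr_cycles *
    log1p(model$max_efficiency * model$mismatch_penalty^mismatch_counts)
  la <- log(template_shares) + lf
  la <- la - max(la[is.finite(la)])
  a <- exp(la)
  a[template_shares == 0] <- 0
  stats::setNames(a / sum(a), names(template_shares))
}
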