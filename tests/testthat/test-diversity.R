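test_that("abundance floor applies the strict retention rule", {
  counts <- c(a = 100L, b = 99L, c = 101L, d = 999700L)
  floored <- abundance_floor(counts)        # total 10^6
  expect_equal(unname(floored[c("a", "b")]), c(0L, 0L))   # <= 0.01% out
  expect_equal(unname(floored["c"]), 101L)                # > 0.01% kept
  # all rows >= 1%: unchanged
  even <- c(x = 50L, y = 50L)
  expect_equal(abundance_floor(even), even)
  expect_error(abundance_floor(c(0L, 0L)), "positive")
})

test_that("diversity indices match hand-computed values", {
  di <- diversity_indices(c(0.5, 0.5))
  expect_equal(di$shannon, log(2))
  expect_equal(di$simpson, 0.5)
  expect_equal(di$inv_simpson, 2)
  expect_equal(di$pielou, 1)

  di1 <- diversity_indices(c(1))
  expect_equal(di1$shannon, 0)
  expect_equal(di1$simpson, 0)
  expect_true(is.na(di1$pielou))           # S = 1 sentinel

  expect_error(diversity_indices(c(0, 0)), "positive")
})

test_that("index identities hold on random compositions", {
  set.seed(1)
  for (i in 1:10) {
    p <- stats::rgamma(sample(3:40, 1), 1)
    p <- p / sum(p)
    di <- diversity_indices(p)
    # renyi at a = 2 equals ln inverse-Simpson
    expect_equal(unname(di$renyi["2"]), log(di$inv_simpson),
                 tolerance = 1e-10)
    # renyi at a = 0 is ln richness; non-increasing in alpha
    expect_equal(unname(di$renyi["0"]), log(di$richness))
    expect_true(all(diff(di$renyi) <= 1e-10))
    expect_true(di$pielou >= 0 && di$pielou <= 1)
    expect_true(di$inv_simpson >= 1 && di$inv_simpson <= di$richness + 1e-9)
  }
})

test_that("indices agree with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(2)
  x <- stats::rpois(20, 50) + 1
  di <- diversity_indices(x)
  expect_equal(di$shannon, unname(vegan::diversity(x, "shannon")))
  expect_equal(di$simpson, unname(vegan::diversity(x, "simpson")))
  expect_equal(di$inv_simpson, unname(vegan::diversity(x, "invsimpson")))
  rv <- vegan::renyi(x, scales = c(0, 1, 2, 8))
  expect_equal(unname(di$renyi[c("0", "1", "2", "8")]),
               unname(unlist(rv)), tolerance = 1e-10)
})

test_that("recovery rates honour both criteria", {
  ids <- sprintf("B%03d", 1:374)
  full <- stats::setNames(rep(30L, 374), ids)
  expect_equal(unname(recovery_rate(full, ids, "any_read")), 1)
  one_out <- full[-10]
  expect_equal(unname(recovery_rate(one_out, ids, "any_read")), 373 / 374)
  # floored criterion never exceeds the any-read criterion
  set.seed(3)
  tab <- matrix(stats::rnbinom(374 * 2, mu = 40, size = 0.3),
                nrow = 374, dimnames = list(ids, c("s1", "s2")))
  expect_true(all(recovery_rate(tab, ids, "frac_gt_1e-4") <=
                    recovery_rate(tab, ids, "any_read")))
  expect_error(recovery_rate(full, character(0)), "empty")
})

test_that("bray-curtis matches hand arithmetic and its invariants", {
  tab <- cbind(a = c(2, 1), b = c(1, 2))
  expect_equal(bray_curtis(tab)["a", "b"], 1 / 3)
  same <- cbind(x = c(3, 4), y = c(3, 4))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disjoint <- cbind(x = c(5, 0), y = c(0, 5))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  set.seed(4)
  m <- matrix(stats::rpois(30, 10), nrow = 6,
              dimnames = list(NULL, sprintf("s%d", 1:5)))
  d <- bray_curtis(m)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(cbind(a = c(1, 2), b = c(0, 0))), "zero")
})

test_that("bray-curtis agrees with the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(stats::rpois(40, 20), nrow = 8,
              dimnames = list(NULL, sprintf("s%d", 1:5)))
  expect_equal(c(as.dist(bray_curtis(m))), c(vegan::vegdist(t(m), "bray")),
               tolerance = 1e-12)
})

test_that("single-linkage trees are valid and deterministic", {
  set.seed(6)
  m <- matrix(stats::rpois(60, 15), nrow = 10,
              dimnames = list(NULL, sprintf("s%d", 1:6)))
  tree <- single_link_tree(bray_curtis(m))
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, colnames(m))
  nwk <- tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  back <- ape::read.tree(nwk)
  expect_equal(ape::write.tree(back), ape::write.tree(tree))
  unlink(nwk)
})

test_that("kendall tau matches enumeration and the cor.test oracle", {
  expect_equal(kendall_tau(1:6, 1:6)$tau, 1)
  expect_equal(kendall_tau(1:6, 6:1)$tau, -1)
  # enumerated: C = 5, D = 1 -> tau = 2/3
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4))$tau, 2 / 3)

  set.seed(7)
  x <- stats::rpois(30, 6)            # ties present
  y <- x + stats::rpois(30, 4)
  kt <- kendall_tau(x, y)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
  expect_equal(kt$tau, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(kt$p_value, ct$p.value, tolerance = 1e-6)

  expect_warning(out <- kendall_tau(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out$tau))
  expect_error(kendall_tau(1:3, 1:4), "equal length")
})

test_that("coefficient of variation matches hand arithmetic", {
  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), stats::sd(c(1, 3)) / 2)
  expect_error(coefficient_of_variation(numeric(0)), "empty")
})
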