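test_that("Bonferroni thresholds are exact", {
  expect_identical(bonferroni(0.05, 4), 0.0125)
  expect_identical(bonferroni(0.05, 2), 0.025)
  expect_identical(bonferroni(0.05, 1), 0.05)
  expect_error(bonferroni(1.2, 4))
})

test_that("Kruskal-Wallis reproduces the rank-formula value", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 3.857, tolerance = 5e-4)
  expect_equal(res$direction, "b larger")
  # identical groups: H = 0
  res0 <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$statistic, 0)
  # permuting values within groups leaves H unchanged
  res_p <- kruskal_wallis(c(3, 1, 2, 6, 4, 5), rep(c("a", "b"), each = 3))
  expect_equal(res_p$statistic, res$statistic)
  # degenerate: all values identical
  expect_warning(resd <- kruskal_wallis(rep(5, 6), rep(c("a", "b"), each = 3)),
                 "identical")
  expect_equal(resd$p_value, 1)
})

test_that("global permutation test is deterministic, calibrated at the tails", {
  set.seed(71)
  a <- rnorm(12); b <- rnorm(12)
  r1 <- permutation_test_global(a, b, n_perm = 500, seed = 7)
  r2 <- permutation_test_global(a, b, n_perm = 500, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(attr(r1, "null_dist"), attr(r2, "null_dist"))
  # a 5 SD shift at n = 12 per group is decisively detected
  shift <- permutation_test_global(rnorm(12), rnorm(12) + 5, n_perm = 1000,
                                   seed = 8)
  expect_lte(shift$p_value, 0.01)
  expect_equal(shift$direction, "B larger")
  # identical samples: p at the top of the scale
  same <- permutation_test_global(1:10, 1:10, n_perm = 500, seed = 9)
  expect_gte(same$p_value, 1 - 1 / 501)
  expect_warning(permutation_test_global(a, b, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(72)
  pvals <- vapply(1:400, function(i) {
    permutation_test_global(rnorm(10), rnorm(10), n_perm = 200)$p_value
  }, numeric(1))
  # super-uniformity: empirical CDF at alpha never far above alpha
  for (al in c(0.05, 0.1, 0.25)) {
    expect_lt(mean(pvals <= al), al + 3 * sqrt(al * (1 - al) / 400))
  }
})

test_that("power never decreases with planted effect size", {
  set.seed(73)
  power_at <- function(delta) {
    mean(vapply(1:120, function(i) {
      permutation_test_global(rnorm(12), rnorm(12) + delta,
                              n_perm = 200)$p_value < 0.05
    }, logical(1)))
  }
  pw <- vapply(c(0, 1, 2), power_at, numeric(1))
  expect_true(all(diff(pw) >= -0.05))
  expect_gt(pw[3], pw[1])
})

test_that("bootstrap resampling variant is available", {
  set.seed(74)
  r <- permutation_test_global(rnorm(12), rnorm(12) + 5, n_perm = 500,
                               seed = 10, method = "bootstrap")
  expect_lt(r$p_value, 0.05)
  expect_match(r$method, "bootstrap")
})

test_that("tidy and glance summarize permutation results", {
  r <- permutation_test_global(rnorm(8), rnorm(8), n_perm = 300, seed = 11,
                               measure = "LF", band = "theta")
  td <- generics::tidy(r)
  expect_equal(td$measure, "LF")
  expect_equal(td$p.value, r$p_value)
  gl <- generics::glance(r)
  expect_equal(gl$n.perm, 300)
  expect_equal(gl$p.resolution, 1 / 301)
})

test_that("cluster permutation recovers a planted contiguous effect", {
  mon <- load_montage()
  planted <- c("P3", "Pz", "P4", "PO3", "PO4")
  set.seed(75)
  hits <- vapply(1:25, function(r) {
    vals <- matrix(rnorm(24 * 40), 24, 40,
                   dimnames = list(NULL, mon$channels$label))
    vals[13:24, planted] <- vals[13:24, planted] + 2
    groups <- rep(c("a", "b"), each = 12)
    cl <- cluster_permutation_local(vals, groups, mon, n_perm = 250,
                                    seed = r, corrected_alpha = 0.025)
    sig <- cl[cl$significant, ]
    nrow(sig) >= 1 && length(intersect(unlist(sig$channels), planted)) >= 3
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("cluster permutation controls family-wise error under the null", {
  mon <- load_montage()
  set.seed(76)
  fp <- vapply(1:100, function(r) {
    vals <- matrix(rnorm(24 * 40), 24, 40,
                   dimnames = list(NULL, mon$channels$label))
    cl <- cluster_permutation_local(vals, rep(c("a", "b"), each = 12), mon,
                                    n_perm = 250, seed = 10000 + r,
                                    corrected_alpha = 0.05)
    any(cl$significant)
  }, logical(1))
  expect_lte(mean(fp), 0.1)
})

test_that("an isolated suprathreshold channel forms a singleton cluster", {
  mon <- load_montage()
  set.seed(77)
  vals <- matrix(rnorm(24 * 40, 0, 0.01), 24, 40,
                 dimnames = list(NULL, mon$channels$label))
  vals[13:24, "Cz"] <- vals[13:24, "Cz"] + 5
  cl <- cluster_permutation_local(vals, rep(c("a", "b"), each = 12), mon,
                                  n_perm = 200, seed = 5)
  expect_gte(nrow(cl), 1)
  expect_true("Cz" %in% unlist(cl$channels))
  top <- cl[cl$cluster == 1, ]
  expect_equal(top$size, 1)
  td <- generics::tidy(cl)
  expect_true(all(c("mass", "p.value", "channels") %in% names(td)))
})

test_that("hub distribution comparison reports direction and degenerates", {
  set.seed(78)
  a <- replicate(10, runif(3, 0.4, 0.6), simplify = FALSE)
  b <- lapply(a, function(v) v * 2)
  res <- compare_hub_distributions(a, b)
  expect_equal(res$direction, "B larger")
  # identical groups: p near 1
  res_same <- compare_hub_distributions(a, a)
  expect_gt(res_same$p_value, 0.9)
  # a group with no hubs is flagged and skipped
  none <- replicate(10, numeric(0), simplify = FALSE)
  res_skip <- compare_hub_distributions(a, none)
  expect_match(res_skip$method, "skipped")
  expect_true(is.na(res_skip$p_value))
})

test_that("hub comparison is calibrated under the null", {
  set.seed(79)
  pv <- vapply(1:200, function(i) {
    a <- replicate(12, runif(3), simplify = FALSE)
    b <- replicate(12, runif(3), simplify = FALSE)
    compare_hub_distributions(a, b)$p_value
  }, numeric(1))
  expect_lt(mean(pv < 0.05), 0.1)
})

test_that("variation report tallies pairwise differences by RT stratum", {
  set.seed(80)
  # homogeneous subgroup: proportions near the nominal alpha
  subj <- rep(sprintf("s%02d", 1:8), each = 20)
  per_trial <- tibble::tibble(
    subject = subj, subgroup = "control_boy",
    value = rnorm(length(subj)), vrt_ms = rlnorm(length(subj), 6.7, 0.1))
  rep1 <- variation_report(per_trial, n_perm = 200, seed = 3)
  expect_true(all(rep1$proportion <= 0.25))
  # one planted deviant subject drives a nonzero proportion
  per_trial$value[per_trial$subject == "s01"] <-
    per_trial$value[per_trial$subject == "s01"] + 3
  rep2 <- variation_report(per_trial, n_perm = 200, seed = 3)
  expect_gt(sum(rep2$n_significant), 0)
  # an empty subgroup yields an empty row set
  rep3 <- variation_report(per_trial, comparisons = list("dd_girl"),
                           n_perm = 100, seed = 1)
  expect_equal(nrow(rep3), 0)
})
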