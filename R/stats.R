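#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise alpha in (0, 1).
#' @param k Number of comparisons (>= 1).
#' @return `alpha / k`; e.g. `bonferroni(0.05, 4) = 0.0125` for the four
#'   global tree measures, `bonferroni(0.05, 2) = 0.025` for the two local
#'   hub measures.
#' @export
bonferroni <- function(alpha, k) {
  stopifnot(alpha > 0, alpha < 1, k >= 1)
  alpha / k
}

# assemble a one-row comparison tibble with the shared result contract
comparison_result <- function(measure, band, groups, statistic, p_value,
                              corrected_alpha, direction, method) {
  tibble::tibble(
    measure = measure, band = band, groups = groups,
    statistic = statistic, p_value = p_value,
    corrected_alpha = corrected_alpha,
    significant = p_value < corrected_alpha,
    direction = direction, method = method
  )
}

#' Kruskal-Wallis comparison of behavioral or network measures
#'
#' Rank-based H statistic with tie correction, referred to the chi-square
#' distribution (via [stats::kruskal.test()]). With all observations
#' identical the test is degenerate: H = 0 and p = 1, with a warning.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (>= 2 groups, each with >= 2 values).
#' @param measure,band Labels carried into the result.
#' @param corrected_alpha Significance threshold for the `significant`
#'   flag.
#' @return A one-row comparison tibble (`measure, band, groups, statistic,
#'   p_value, corrected_alpha, significant, direction, method`).
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups, measure = "value", band = NA_character_,
                           corrected_alpha = 0.05) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  gl <- paste(levels(groups), collapse = " vs ")
  med <- tapply(values, groups, stats::median)
  direction <- paste0(names(med)[which.max(med)], " larger")
  if (length(unique(values)) == 1) {
    warning("all observations identical; degenerate Kruskal-Wallis (p = 1)")
    return(comparison_result(measure, band, gl, 0, 1, corrected_alpha,
                             "none", "kruskal-wallis"))
  }
  kt <- stats::kruskal.test(values, groups)
  comparison_result(measure, band, gl, unname(kt$statistic), kt$p.value,
                    corrected_alpha, direction, "kruskal-wallis")
}

#' Permutation test for a global tree measure
#'
#' Two-sided non-parametric test of a group difference. The observed
#' statistic is the difference of group means of the per-subject values;
#' the null distribution is built by `n_perm` random relabelings of the
#' pooled sample (or, with `method = "bootstrap"`, by resampling with
#' replacement within the pooled sample). The p-value uses the add-one
#' convention `p = (1 + #{|null| >= |obs|}) / (1 + n_perm)`, so its
#' resolution is `1 / (n_perm + 1)`. Deterministic given `seed`.
#'
#' @param a,b Numeric vectors of per-subject values for the two groups.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed; the caller's RNG stream is left untouched.
#' @param measure,band Labels carried into the result.
#' @param corrected_alpha Threshold for the `significant` flag (e.g.
#'   `bonferroni(0.05, 4)`).
#' @param method `"permutation"` (label permutation) or `"bootstrap"`.
#' @return A one-row comparison tibble of class `eegmst_perm` with the
#'   null distribution in the `null_dist` attribute.
#' @examples
#' permutation_test_global(rnorm(12), rnorm(12, 2), n_perm = 500, seed = 1)
#' @export
permutation_test_global <- function(a, b, n_perm = 1000, seed = NULL,
                                    measure = "value", band = NA_character_,
                                    corrected_alpha = 0.05,
                                    method = c("permutation", "bootstrap")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (n_perm < 100) warning("n_perm < 100 gives very coarse p-value resolution")
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  obs <- mean(a) - mean(b)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- if (method == "permutation") sample.int(n, na)
             else sample.int(n, na, replace = TRUE)
      rest <- if (method == "permutation") pool[-idx]
              else pool[sample.int(n, n - na, replace = TRUE)]
      mean(pool[idx]) - mean(rest)
    }, numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm)
  res <- comparison_result(measure, band, "A vs B", obs, p, corrected_alpha,
                           if (obs > 0) "A larger" else if (obs < 0) "B larger" else "none",
                           paste0(method, " (", n_perm, ")"))
  attr(res, "null_dist") <- null
  class(res) <- c("eegmst_perm", class(res))
  res
}

# per-channel Wilcoxon rank-sum z statistics (normal approximation with
# tie correction), vectorized across channels given precomputed ranks
ranksum_z <- function(ranks, idx_a, tie_sigma, n) {
  na <- length(idx_a); nb <- n - na
  W <- colSums(ranks[idx_a, , drop = FALSE])
  mu <- na * (n + 1) / 2
  (W - mu) / tie_sigma
}

#' Cluster-based permutation test on per-channel metrics
#'
#' Compares a per-channel measure (e.g. node betweenness or degree)
#' between two groups of subjects while controlling the family-wise error
#' over channels. Channel-wise two-sample rank-sum statistics are
#' thresholded at an uncorrected two-sided `cluster_forming_p`;
#' suprathreshold channels with the same sign are grouped into spatially
#' contiguous clusters under the montage neighbor relation; each cluster's
#' mass is the sum of its |z| statistics; and the family-wise p-value of
#' each observed cluster is the proportion of label permutations whose
#' maximum cluster mass reaches it (add-one convention).
#'
#' @param values Numeric matrix, subjects x channels (column names =
#'   channel labels in montage order).
#' @param groups Two-level grouping vector over subjects.
#' @param montage An `eeg_montage` supplying the neighbor relation.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param cluster_forming_p Uncorrected two-sided threshold for
#'   cluster membership (default 0.05).
#' @param corrected_alpha Threshold for the `significant` flag (e.g.
#'   `bonferroni(0.05, 2)`).
#' @return A tibble of class `eegmst_clusters`, one row per cluster
#'   (possibly empty): `cluster, channels` (list), `size, mass, p_value,
#'   significant, direction, hemisphere`, ranked by mass.
#' @export
cluster_permutation_local <- function(values, groups, montage, n_perm = 1000,
                                      seed = NULL, cluster_forming_p = 0.05,
                                      corrected_alpha = 0.05) {
  stopifnot(is.matrix(values))
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  n <- nrow(values); nch <- ncol(values)
  if (!is.null(colnames(values))) {
    stopifnot(identical(colnames(values), montage$channels$label))
  }
  idx_a <- which(groups == levels(groups)[1])
  na <- length(idx_a); nb <- n - na
  ranks <- apply(values, 2, rank)
  # tie-corrected rank-sum SD per channel
  tie_sigma <- vapply(seq_len(nch), function(c) {
    t <- table(values[, c])
    correction <- sum(t^3 - t) / ((n) * (n - 1))
    sqrt(na * nb / 12 * ((n + 1) - correction))
  }, numeric(1))
  tie_sigma[tie_sigma == 0] <- Inf
  zcrit <- stats::qnorm(1 - cluster_forming_p / 2)
  nbrs <- lapply(seq_len(nch), function(i) which(montage$adjacency[i, ]))

  find_clusters <- function(z) {
    supra <- which(abs(z) >= zcrit)
    if (!length(supra)) return(list())
    seen <- logical(nch)
    clusters <- list()
    for (s in supra) {
      if (seen[s]) next
      sgn <- sign(z[s])
      members <- integer(0); queue <- s; seen[s] <- TRUE
      while (length(queue)) {
        v <- queue[[1]]; queue <- queue[-1]
        members <- c(members, v)
        for (u in nbrs[[v]]) {
          if (!seen[u] && abs(z[u]) >= zcrit && sign(z[u]) == sgn) {
            seen[u] <- TRUE; queue <- c(queue, u)
          }
        }
      }
      clusters[[length(clusters) + 1]] <- members
    }
    clusters
  }

  z_obs <- ranksum_z(ranks, idx_a, tie_sigma, n)
  obs_clusters <- find_clusters(z_obs)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, na)
      z <- ranksum_z(ranks, idx, tie_sigma, n)
      cl <- find_clusters(z)
      if (!length(cl)) 0 else max(vapply(cl, function(m) sum(abs(z[m])), numeric(1)))
    }, numeric(1))
  })
  if (!length(obs_clusters)) {
    out <- tibble::tibble(cluster = integer(), channels = list(),
                          size = integer(), mass = numeric(),
                          p_value = numeric(), significant = logical(),
                          direction = character(), hemisphere = character())
  } else {
    mass <- vapply(obs_clusters, function(m) sum(abs(z_obs[m])), numeric(1))
    ord <- order(-mass)
    labels <- montage$channels$label
    hemis <- montage$channels$hemisphere
    out <- purrr::map_dfr(seq_along(ord), function(r) {
      m <- obs_clusters[[ord[r]]]
      this_mass <- mass[ord[r]]
      tibble::tibble(
        cluster = r,
        channels = list(labels[m]),
        size = length(m),
        mass = this_mass,
        p_value = (1 + sum(null_max >= this_mass)) / (1 + n_perm),
        direction = if (z_obs[m[1]] > 0)
          paste(levels(groups)[1], "larger") else paste(levels(groups)[2], "larger"),
        hemisphere = paste(sort(unique(hemis[m])), collapse = "+")
      )
    })
    out$significant <- out$p_value < corrected_alpha
    out <- out[, c("cluster", "channels", "size", "mass", "p_value",
                   "significant", "direction", "hemisphere")]
  }
  attr(out, "z") <- z_obs
  attr(out, "null_max") <- null_max
  attr(out, "corrected_alpha") <- corrected_alpha
  class(out) <- c("eegmst_clusters", class(out))
  out
}

#' Compare hub-metric distributions between groups
#'
#' Reduces each subject's hub metric values (e.g. the BC of their hub
#' nodes) to the subject median, then applies the rank-based chi-square
#' comparison of [kruskal_wallis()]. A group in which no subject has any
#' hub cannot be compared: the result is flagged and the test skipped.
#'
#' @param hubs_a,hubs_b Lists of per-subject numeric vectors of hub
#'   metric values (empty vectors allowed for hubless subjects).
#' @param measure,band,corrected_alpha As in [kruskal_wallis()].
#' @return A one-row comparison tibble; when a group has no hubs at all,
#'   `statistic`/`p_value` are NA and `method = "skipped (no hubs)"`.
#' @export
compare_hub_distributions <- function(hubs_a, hubs_b, measure = "hub_bc",
                                      band = NA_character_,
                                      corrected_alpha = 0.05) {
  med_a <- vapply(hubs_a, function(v) if (length(v)) stats::median(v) else NA_real_, numeric(1))
  med_b <- vapply(hubs_b, function(v) if (length(v)) stats::median(v) else NA_real_, numeric(1))
  med_a <- med_a[!is.na(med_a)]; med_b <- med_b[!is.na(med_b)]
  if (length(med_a) < 2 || length(med_b) < 2) {
    return(comparison_result(measure, band, "A vs B", NA_real_, NA_real_,
                             corrected_alpha, "none", "skipped (no hubs)"))
  }
  res <- kruskal_wallis(c(med_a, med_b),
                        rep(c("A", "B"), c(length(med_a), length(med_b))),
                        measure = measure, band = band,
                        corrected_alpha = corrected_alpha)
  res$direction <- if (stats::median(med_a) > stats::median(med_b)) "A larger"
                   else if (stats::median(med_a) < stats::median(med_b)) "B larger"
                   else "none"
  res
}

#' Interindividual variation report
#'
#' Tallies, within (or between) subgroups, the fraction of subject pairs
#' whose trial-level network measure differs significantly, stratified by
#' whether the pair's reaction times are similar (rank-sum p >= 0.05) or
#' different (p < 0.05). Each pair is tested with a trial-level
#' permutation test on the network measure.
#'
#' @param per_trial A tibble with columns `subject`, `subgroup`, `value`
#'   (the per-trial network measure) and `vrt_ms` (per-trial vocal
#'   reaction time).
#' @param comparisons A list of character vectors, each of length 1
#'   (within-subgroup pairs) or 2 (between-subgroup pairs); default: every
#'   subgroup within itself.
#' @param n_perm,seed,alpha Test parameters.
#' @return A tibble `comparison, rt_stratum, n_pairs, n_significant,
#'   proportion`.
#' @export
variation_report <- function(per_trial, comparisons = NULL, n_perm = 500,
                             seed = NULL, alpha = 0.05) {
  stopifnot(all(c("subject", "subgroup", "value", "vrt_ms") %in% names(per_trial)))
  subgroups <- unique(per_trial$subgroup)
  comparisons <- comparisons %||% as.list(subgroups)
  with_seed(seed, {
    purrr::map_dfr(comparisons, function(cmp) {
      name <- paste(cmp, collapse = " vs ")
      if (length(cmp) == 1) {
        subs <- unique(per_trial$subject[per_trial$subgroup == cmp])
        pairs <- if (length(subs) >= 2) utils::combn(subs, 2, simplify = FALSE) else list()
      } else {
        s1 <- unique(per_trial$subject[per_trial$subgroup == cmp[1]])
        s2 <- unique(per_trial$subject[per_trial$subgroup == cmp[2]])
        grid <- expand.grid(a = s1, b = s2, stringsAsFactors = FALSE)
        pairs <- purrr::map2(grid$a, grid$b, c)
      }
      if (!length(pairs)) {
        return(tibble::tibble(comparison = name, rt_stratum = character(),
                              n_pairs = integer(), n_significant = integer(),
                              proportion = numeric()))
      }
      res <- purrr::map_dfr(pairs, function(p) {
        d1 <- per_trial[per_trial$subject == p[1], ]
        d2 <- per_trial[per_trial$subject == p[2], ]
        rt_p <- suppressWarnings(
          stats::wilcox.test(d1$vrt_ms, d2$vrt_ms, exact = FALSE)$p.value)
        net_p <- permutation_test_global(d1$value, d2$value,
                                         n_perm = n_perm)$p_value
        tibble::tibble(rt_stratum = if (rt_p >= 0.05) "similar_rt" else "different_rt",
                       significant = net_p < alpha)
      })
      res |>
        dplyr::group_by(.data$rt_stratum) |>
        dplyr::summarise(n_pairs = dplyr::n(),
                         n_significant = sum(.data$significant),
                         proportion = mean(.data$significant),
                         .groups = "drop") |>
        dplyr::mutate(comparison = name, .before = 1)
    })
  })
}
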