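test_that("build_mst keeps the strongest couplings (3-node enumeration)", {
  m <- sanitize_adjacency(matrix(c(0, 0.9, 0.5,
                                   0.9, 0, 0.8,
                                   0.5, 0.8, 0), 3))
  tree <- build_mst(m)
  expect_equal(nrow(tree$edges), 2)
  got <- paste(tree$edges$from, tree$edges$to, sep = "-")
  expect_setequal(got, c("1-2", "2-3"))
})

test_that("build_mst recovers a planted star and is deterministic on ties", {
  tree <- build_mst(sanitize_adjacency(star_matrix(5)))
  deg <- node_metrics(tree)$degree
  expect_equal(deg, c(4, 1, 1, 1, 1))
  # all-equal weights: identical tree across runs
  u <- sanitize_adjacency(matrix(0.5, 4, 4))
  expect_identical(build_mst(u)$edges, build_mst(u)$edges)
})

test_that("build_mst matches brute-force enumeration on random graphs", {
  set.seed(11)
  for (r in 1:30) {
    n <- sample(3:7, 1)
    m <- sanitize_adjacency(random_similarity(n))
    tree <- build_mst(m)
    expect_equal(sum(tree$edges$weight), max_tree_weight_bruteforce(unclass(m)),
                 tolerance = 1e-12)
  }
})

test_that("build_mst agrees with igraph's MST on the cost graph", {
  set.seed(12)
  for (r in 1:10) {
    m <- sanitize_adjacency(random_similarity(10))
    tree <- build_mst(m)
    g <- igraph::graph_from_adjacency_matrix(1 - unclass(m), mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ig <- igraph::mst(g)
    expect_equal(sum(tree$edges$weight),
                 sum(1 - igraph::E(ig)$weight), tolerance = 1e-10)
  }
})

test_that("disconnected positive-weight graphs are rejected with components", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.5
  m[3, 4] <- m[4, 3] <- 0.5
  rownames(m) <- colnames(m) <- c("a", "b", "c", "d")
  expect_error(build_mst(sanitize_adjacency(m)), "disconnected.*a,b.*c,d")
})

test_that("tie-break is stable under label permutation for distinct weights", {
  set.seed(13)
  m <- sanitize_adjacency(random_similarity(8))
  tree <- build_mst(m)
  perm <- sample(8)
  mp <- unclass(m)[perm, perm]
  treep <- build_mst(sanitize_adjacency(mp))
  # un-permute and compare edge sets
  unperm <- order(perm)
  e1 <- apply(cbind(tree$edges$from, tree$edges$to), 1,
              function(e) paste(sort(e), collapse = "-"))
  e2 <- apply(cbind(perm[treep$edges$from], perm[treep$edges$to]), 1,
              function(e) paste(sort(e), collapse = "-"))
  expect_setequal(e1, e2)
})

test_that("degrees satisfy textbook identities", {
  star <- build_mst(sanitize_adjacency(star_matrix(5)))
  expect_equal(node_metrics(star)$degree, c(4, 1, 1, 1, 1))
  path <- build_mst(sanitize_adjacency(path_matrix(5)))
  expect_equal(node_metrics(path)$degree, c(1, 2, 2, 2, 1))
  set.seed(14)
  rnd <- build_mst(sanitize_adjacency(random_similarity(12)))
  expect_equal(sum(node_metrics(rnd)$degree), 2 * (12 - 1))  # handshake
})

test_that("betweenness matches closed forms and leaves are zero", {
  star <- build_mst(sanitize_adjacency(star_matrix(5)))
  bc <- node_metrics(star)$bc
  expect_equal(bc[1], 1.0)
  expect_equal(bc[2:5], rep(0, 4))
  path <- build_mst(sanitize_adjacency(path_matrix(5)))
  expect_equal(node_metrics(path)$bc[3], 2 / 3)
})

test_that("betweenness agrees with all-pairs path enumeration on random trees", {
  set.seed(15)
  for (r in 1:20) {
    n <- sample(4:8, 1)
    edges <- random_tree_edges(n)
    tree <- tree_from_edges(edges, n)
    expect_equal(node_metrics(tree)$bc, bc_bruteforce(edges, n),
                 tolerance = 1e-12)
  }
})

test_that("global metrics reproduce star/path closed forms", {
  star <- tree_metrics(build_mst(sanitize_adjacency(star_matrix(5))))
  expect_equal(star$LF, 0.8)
  expect_equal(star$D, 0.5)
  expect_equal(star$K, 2.5)
  expect_equal(star$TH, 0.5)
  path <- tree_metrics(build_mst(sanitize_adjacency(path_matrix(5))))
  expect_equal(path$LF, 0.4)
  expect_equal(path$D, 1.0)
  expect_equal(path$K, 1.75)
  expect_equal(path$TH, 0.375)
  # two-node tree: D = LF = 1, TH undefined
  two <- build_mst(sanitize_adjacency(matrix(c(0, .5, .5, 0), 2)))
  expect_warning(m2 <- tree_metrics(two), "undefined")
  expect_equal(m2$D, 1)
  expect_equal(m2$LF, 1)
  expect_true(is.na(m2$TH))
})

test_that("kappa is bounded below by the mean degree", {
  set.seed(16)
  for (n in c(5, 9, 15)) {
    tree <- build_mst(sanitize_adjacency(random_similarity(n)))
    expect_gte(tree_metrics(tree)$K, 2 * (n - 1) / n - 1e-12)
  }
})

test_that("star and path are the topological extremes at fixed N", {
  for (n in c(5, 10, 40)) {
    ms <- tree_metrics(build_mst(sanitize_adjacency(star_matrix(n))))
    mp <- tree_metrics(build_mst(sanitize_adjacency(path_matrix(n))))
    expect_gt(ms$LF, mp$LF)
    expect_gt(ms$K, mp$K)
    expect_gt(ms$bc_max, mp$bc_max - 1e-12)
    expect_lt(ms$D, mp$D)
  }
})

test_that("leaf fraction supports the links denominator variant", {
  star <- build_mst(sanitize_adjacency(star_matrix(5)))
  expect_equal(tree_metrics(star, leaf_denominator = "links")$LF, 1.0)
})

test_that("hub identification applies the mean + 1 SD rule", {
  # star degrees: mean 1.6, population SD 1.2, threshold 2.8
  hubs <- identify_hubs(c(4, 1, 1, 1, 1), criterion = "degree")
  expect_equal(attr(hubs, "threshold"), 2.8)
  expect_equal(hubs$label, "1")
  # 3-node path: degrees (1, 2, 1), threshold 4/3 + sd
  h3 <- identify_hubs(setNames(c(1, 2, 1), c("a", "b", "c")),
                      criterion = "degree")
  expect_equal(h3$label, "b")
  expect_equal(attr(h3, "threshold"), 4 / 3 + sqrt(2 / 9), tolerance = 1e-10)
  # zero dispersion: no hubs
  expect_equal(nrow(identify_hubs(rep(2, 40), "degree")), 0)
})

test_that("strong edges require mean + 1 SD and vanish for uniform weights", {
  m <- matrix(0.2, 40, 40); diag(m) <- 0
  m[3, 17] <- m[17, 3] <- 0.9
  se <- strong_edges(sanitize_adjacency(m))
  expect_equal(nrow(se), 1)
  expect_equal(c(se$from, se$to), c(3, 17))
  # direct recomputation of the threshold
  w <- unclass(sanitize_adjacency(m))[upper.tri(m)]
  expect_equal(attr(se, "threshold"), mean(w) + sqrt(mean((w - mean(w))^2)))
  # uniform weights: empty
  u <- matrix(0.3, 10, 10); diag(u) <- 0
  expect_equal(nrow(strong_edges(sanitize_adjacency(u))), 0)
  # always a subset of positive entries
  expect_true(all(se$weight > 0))
})

test_that("subject summaries average metrics across trials, keeping them", {
  tm <- tibble::tibble(trial = 1:3, D = c(0.5, 0.7, 0.9),
                       LF = c(0.4, 0.4, 0.4), TH = c(0.3, 0.5, 0.4),
                       K = c(2, 3, 4))
  s <- summarize_subject(tm)
  expect_equal(s$summary$D, 0.7)
  expect_equal(s$summary$K, 3)
  expect_equal(s$summary$n_trials, 3)
  expect_identical(s$per_trial, tm)
  # single trial: summary equals the trial
  s1 <- summarize_subject(tm[1, ])
  expect_equal(s1$summary$D, 0.5)
  # duplicating a balanced set leaves means unchanged
  s2 <- summarize_subject(dplyr::bind_rows(tm, tm))
  expect_equal(s2$summary$D, s$summary$D)
})
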