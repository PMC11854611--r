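#' Maximum-similarity spanning tree of a connectivity matrix
#'
#' Builds the spanning tree that retains the strongest couplings: the
#' minimum spanning tree of the wiring cost `1 - w`, which is equivalent to
#' the maximum-total-weight spanning tree of the similarity matrix `w`.
#' Kruskal's algorithm with lexicographic `(i, j)` tie-breaking makes the
#' result deterministic even with tied weights; no randomness is involved.
#'
#' @param m A sanitized symmetric non-negative matrix (see
#'   [sanitize_adjacency()]); only strictly positive entries are usable
#'   edges, and their graph must be connected.
#' @param provenance Optional named list (subject, trial, band) carried on
#'   the result.
#' @return An `mst_tree`: list with `n`, `labels`, `edges` (tibble
#'   `from, to, weight` with `n - 1` rows, `from < to` as indices).
#' @examples
#' m <- sanitize_adjacency(matrix(c(0, .9, .5, .9, 0, .8, .5, .8, 0), 3))
#' build_mst(m)$edges
#' @export
build_mst <- function(m, provenance = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  m <- unclass(m)
  n <- nrow(m)
  labels <- rownames(m) %||% as.character(seq_len(n))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]; w <- w[pos]
  ord <- order(-w, ut[, 1], ut[, 2])      # strongest first; lexicographic ties
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  ei <- integer(n - 1); ej <- integer(n - 1); ew <- numeric(n - 1)
  k <- 0L
  for (e in ord) {
    a <- find(ut[e, 1]); b <- find(ut[e, 2])
    if (a != b) {
      parent[a] <- b
      k <- k + 1L
      ei[k] <- ut[e, 1]; ej[k] <- ut[e, 2]; ew[k] <- w[e]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) {
    comp <- vapply(seq_len(n), find, integer(1))
    parts <- split(labels, comp)
    stop("positive-weight graph is disconnected; components: ",
         paste(vapply(parts, paste, "", collapse = ","), collapse = " | "))
  }
  structure(
    list(n = n, labels = labels,
         edges = tibble::tibble(from = ei, to = ej, weight = ew),
         provenance = provenance),
    class = "mst_tree"
  )
}

#' @export
print.mst_tree <- function(x, ...) {
  cat("<mst_tree> ", x$n, " nodes, ", nrow(x$edges), " edges, total weight ",
      round(sum(x$edges$weight), 3), "\n", sep = "")
  invisible(x)
}

# igraph view of an mst_tree (unweighted)
tree_igraph <- function(tree) {
  igraph::graph_from_edgelist(
    cbind(tree$edges$from, tree$edges$to), directed = FALSE)
}

#' Per-node degree and betweenness centrality of a tree
#'
#' Degree is the unweighted edge count per node; the weighted degree (sum
#' of incident similarity weights) is returned as an auxiliary column.
#' Betweenness centrality is the fraction of ordered pairs `(h, j)`,
#' `h != j`, both different from `i`, whose (unique) tree path passes
#' through `i`, normalized by `(n - 1)(n - 2)` so that `BC` lies in
#' `[0, 1]`; leaves have `BC = 0`. In a tree every pair has a unique
#' path, so the path-count ratio per pair is 0 or 1.
#'
#' @param tree An `mst_tree`.
#' @return A tibble `node, label, degree, degree_w, bc`.
#' @examples
#' m <- sanitize_adjacency(matrix(c(0, .9, .5, .9, 0, .8, .5, .8, 0), 3))
#' node_metrics(build_mst(m))
#' @export
node_metrics <- function(tree) {
  stopifnot(inherits(tree, "mst_tree"))
  n <- tree$n
  deg <- tabulate(c(tree$edges$from, tree$edges$to), nbins = n)
  degw <- numeric(n)
  for (k in seq_len(nrow(tree$edges))) {
    degw[tree$edges$from[k]] <- degw[tree$edges$from[k]] + tree$edges$weight[k]
    degw[tree$edges$to[k]]   <- degw[tree$edges$to[k]]   + tree$edges$weight[k]
  }
  bc <- numeric(n)
  if (n > 2) {
    # igraph counts unordered pairs; the ordered-pair normalization
    # doubles it
    bc <- 2 * igraph::betweenness(tree_igraph(tree), directed = FALSE,
                                  weights = NA) / ((n - 1) * (n - 2))
  }
  tibble::tibble(node = seq_len(n), label = tree$labels,
                 degree = deg, degree_w = degw, bc = bc)
}

#' Global topology metrics of a spanning tree
#'
#' * `D` — diameter: the longest path between any two nodes, in links,
#'   normalized by the number of links `n - 1`; low `D` marks an
#'   integrated, star-like topology.
#' * `LF` — leaf fraction: number of degree-1 nodes over the
#'   denominator `leaf_denominator` (`"nodes"`, the default, or
#'   `"links"`).
#' * `TH` — tree hierarchy: `L / (2 * M * BC_max)` with `L` leaves,
#'   `M = n - 1` links and `BC_max` the maximum normalized betweenness;
#'   undefined (NA, with a warning) for `n = 2` where `BC_max = 0`.
#' * `K` — degree divergence (kappa): `mean(k^2) / mean(k)` over the
#'   degree sequence; larger values mark broader degree distributions.
#'
#' @param tree An `mst_tree`.
#' @param leaf_denominator `"nodes"` or `"links"`.
#' @return A one-row tibble `D, LF, TH, K, bc_max, n_leaves`.
#' @examples
#' star <- build_mst(sanitize_adjacency(
#'   { m <- matrix(0.1, 5, 5); m[1, ] <- m[, 1] <- 0.9; m }))
#' tree_metrics(star) # D 0.5, LF 0.8, TH 0.5, K 2.5
#' @export
tree_metrics <- function(tree, leaf_denominator = c("nodes", "links")) {
  stopifnot(inherits(tree, "mst_tree"))
  leaf_denominator <- match.arg(leaf_denominator)
  n <- tree$n
  nm <- node_metrics(tree)
  deg <- nm$degree
  L <- sum(deg == 1)
  M <- n - 1
  lf <- L / if (leaf_denominator == "nodes") n else M
  D <- tree_diameter_links(tree) / M
  K <- mean(deg^2) / mean(deg)
  bc_max <- max(nm$bc)
  TH <- if (n < 3 || bc_max == 0) {
    warning("tree hierarchy undefined for n < 3 (BC_max = 0)")
    NA_real_
  } else {
    L / (2 * M * bc_max)
  }
  tibble::tibble(D = D, LF = lf, TH = TH, K = K, bc_max = bc_max, n_leaves = L)
}

# longest path in links (exact on trees)
tree_diameter_links <- function(tree) {
  igraph::diameter(tree_igraph(tree), weights = NA)
}

#' Identify hub nodes
#'
#' A node is a hub when its metric (degree or betweenness centrality) is
#' at least one standard deviation above the across-node mean. The SD is
#' the population SD over the nodes; when it is zero (all nodes equal)
#' there are no hubs.
#'
#' @param metrics A tibble from [node_metrics()], or a named numeric
#'   vector.
#' @param criterion `"bc"` or `"degree"`.
#' @return A tibble `label, value` of hubs (possibly empty), with the
#'   threshold in the `threshold` attribute.
#' @export
identify_hubs <- function(metrics, criterion = c("bc", "degree")) {
  criterion <- match.arg(criterion)
  if (is.numeric(metrics)) {
    vals <- unname(metrics)
    labels <- names(metrics) %||% as.character(seq_along(metrics))
  } else {
    vals <- metrics[[criterion]]
    labels <- metrics$label
  }
  n <- length(vals)
  mu <- mean(vals)
  sdev <- sqrt(mean((vals - mu)^2))   # population SD across nodes
  thr <- mu + sdev
  hubs <- if (sdev == 0) integer(0) else which(vals >= thr)
  out <- tibble::tibble(label = labels[hubs], value = vals[hubs])
  attr(out, "threshold") <- thr
  attr(out, "criterion") <- criterion
  out
}

#' Strong connections of a weighted adjacency matrix
#'
#' Returns the upper-triangle off-diagonal entries whose weight is at
#' least one (population) standard deviation above the mean of all such
#' entries. With zero dispersion (uniform weights) the set is empty.
#'
#' @param m A sanitized connectivity matrix.
#' @return A tibble `from, to, weight` (indices `from < to`), with the
#'   threshold in the `threshold` attribute.
#' @export
strong_edges <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  m <- unclass(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  mu <- mean(w); sdev <- sqrt(mean((w - mu)^2))
  keep <- if (sdev == 0) integer(0) else which(w >= mu + sdev)
  out <- tibble::tibble(from = unname(ut[keep, 1]), to = unname(ut[keep, 2]),
                        weight = w[keep])
  if (!is.null(rownames(m))) {
    out$from_label <- rownames(m)[out$from]
    out$to_label <- rownames(m)[out$to]
  }
  attr(out, "threshold") <- mu + sdev
  out
}

#' Summarize per-trial tree metrics for one subject
#'
#' Global measures are computed separately per trial (per realization);
#' the subject-level summary is the mean across trials of each measure
#' (metrics are averaged, not trees). Per-trial values are preserved so
#' that trial-resolved statistics remain possible.
#'
#' @param trial_metrics A tibble of per-trial global metrics with a
#'   `trial` column (e.g. rows of [tree_metrics()] bound together).
#' @return A list with `per_trial` (the input) and `summary` (one row of
#'   trial-averaged measures plus `n_trials`).
#' @export
summarize_subject <- function(trial_metrics) {
  stopifnot(nrow(trial_metrics) >= 1)
  meas <- dplyr::select(trial_metrics, dplyr::any_of(c("D", "LF", "TH", "K")))
  summary <- dplyr::summarise(meas, dplyr::across(
    dplyr::everything(), ~ mean(.x, na.rm = TRUE)))
  summary$n_trials <- nrow(trial_metrics)
  list(per_trial = trial_metrics, summary = tibble::as_tibble(summary))
}

#' Serialize a tree as an edge-list CSV
#'
#' @param tree An `mst_tree`.
#' @param path Output path.
#' @export
write_tree_csv <- function(tree, path) {
  df <- tree$edges
  df$from_label <- tree$labels[df$from]
  df$to_label <- tree$labels[df$to]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
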