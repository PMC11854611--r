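# Independent oracles and fixture builders, deliberately written with
# different algorithms than the package (enumeration / brute force).

# similarity matrix of a star: node `center` coupled to all others
star_matrix <- function(n, center = 1, strong = 0.9, weak = 0.1) {
  m <- matrix(weak, n, n)
  m[center, ] <- m[, center] <- strong
  diag(m) <- 0
  m
}

# similarity matrix whose unique maximum spanning tree is the path 1-2-...-n
path_matrix <- function(n, strong = 0.9, weak = 0.05) {
  m <- matrix(weak, n, n)
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- strong
  diag(m) <- 0
  m
}

# decode a Pruefer sequence into a tree edge list (n = length(seq) + 2)
prufer_decode <- function(pruefer, n) {
  degree <- rep(1L, n)
  for (v in pruefer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0L
  for (v in pruefer) {
    leaf <- which(degree == 1L)[1]
    k <- k + 1L
    edges[k, ] <- c(leaf, v)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# brute-force maximum total-similarity spanning tree weight over ALL
# labeled trees on n nodes (Cayley enumeration via Pruefer sequences)
max_tree_weight_bruteforce <- function(m) {
  n <- nrow(m)
  if (n == 2) return(m[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_decode(seqs[r, ], n)
    w <- sum(m[cbind(e[, 1], e[, 2])])
    if (w > best) best <- w
  }
  best
}

# brute-force normalized betweenness on a tree: enumerate every ordered
# pair's unique path via DFS and count interior visits
bc_bruteforce <- function(edges, n) {
  adj <- lapply(seq_len(n), function(i) {
    c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1])
  })
  path_between <- function(a, b) {
    # DFS with parent tracking
    parent <- rep(NA_integer_, n)
    stack <- a
    seen <- logical(n); seen[a] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (u in adj[[v]]) if (!seen[u]) {
        seen[u] <- TRUE; parent[u] <- v; stack <- c(stack, u)
      }
    }
    path <- b
    while (path[1] != a) path <- c(parent[path[1]], path)
    path
  }
  counts <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    p <- path_between(h, j)
    interior <- setdiff(p, c(h, j))
    counts[interior] <- counts[interior] + 1
  }
  counts / ((n - 1) * (n - 2))
}

# random connected weighted similarity matrix with distinct weights
random_similarity <- function(n) {
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- sample(seq_len(sum(ut))) / (sum(ut) + 1)
  w + t(w)
}

# random labeled tree on n nodes via a random Pruefer sequence
random_tree_edges <- function(n) {
  if (n == 2) return(matrix(c(1L, 2L), 1))
  prufer_decode(sample.int(n, n - 2, replace = TRUE), n)
}

# mst_tree object from a plain edge matrix (unit weights)
tree_from_edges <- function(edges, n) {
  m <- matrix(0, n, n)
  m[edges] <- 1; m[edges[, c(2, 1), drop = FALSE]] <- 1
  eegmst::build_mst(eegmst::sanitize_adjacency(m))
}

# two-channel epoch with a constant phase lag plus independent noise
lagged_pair_epoch <- function(n_samples = 1000, srate = 250, freq = 6,
                              lag = pi / 2, noise = 0.05) {
  t <- (seq_len(n_samples) - 1) / srate
  rbind(a = cos(2 * pi * freq * t) + rnorm(n_samples, 0, noise),
        b = cos(2 * pi * freq * t - lag) + rnorm(n_samples, 0, noise))
}
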