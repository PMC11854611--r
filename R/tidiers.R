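#' Tidy a permutation test result
#'
#' @param x An `eegmst_perm` object from [permutation_test_global()].
#' @param ... Unused.
#' @return A one-row tibble with `measure`, `band`, `estimate` (observed
#'   mean difference), `p.value`, `corrected.alpha`, `significant` and
#'   `method`.
#' @export
tidy.eegmst_perm <- function(x, ...) {
  tibble::tibble(measure = x$measure, band = x$band, estimate = x$statistic,
                 p.value = x$p_value, corrected.alpha = x$corrected_alpha,
                 significant = x$significant, method = x$method)
}

#' @rdname tidy.eegmst_perm
#' @export
glance.eegmst_perm <- function(x, ...) {
  null <- attr(x, "null_dist")
  tibble::tibble(n.perm = length(null), null.sd = stats::sd(null),
                 p.resolution = 1 / (length(null) + 1))
}

#' Tidy a cluster-based permutation result
#'
#' @param x An `eegmst_clusters` object from
#'   [cluster_permutation_local()].
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, `mass`, `p.value`,
#'   `significant`, `direction`, `hemisphere`, `channels` (collapsed).
#' @export
tidy.eegmst_clusters <- function(x, ...) {
  if (!nrow(x)) {
    return(tibble::tibble(cluster = integer(), size = integer(),
                          mass = numeric(), p.value = numeric(),
                          significant = logical(), direction = character(),
                          hemisphere = character(), channels = character()))
  }
  tibble::tibble(cluster = x$cluster, size = x$size, mass = x$mass,
                 p.value = x$p_value, significant = x$significant,
                 direction = x$direction, hemisphere = x$hemisphere,
                 channels = vapply(x$channels, paste, "", collapse = ";"))
}

#' @rdname tidy.eegmst_clusters
#' @export
glance.eegmst_clusters <- function(x, ...) {
  tibble::tibble(n.clusters = nrow(x),
                 n.significant = sum(x$significant %||% logical(0)),
                 n.perm = length(attr(x, "null_max")),
                 corrected.alpha = attr(x, "corrected_alpha"))
}
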