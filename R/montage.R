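#' The 40-channel sensor montage
#'
#' Loads a scalp montage: channel labels, unit-sphere 3-D positions
#' (x = right, y = anterior, z = superior), hemisphere tags and a spatial
#' neighbor relation used by the cluster-based permutation test and the
#' BrainNet exports.
#'
#' The built-in default (`load_montage()`) is the 40-channel 10-10/10-20
#' layout: AF3/AF4, F7/F8, FT9/FT10, FC3/FC4, FC5/FC6, C1/C2, C5/C6,
#' CP1/CP2, CP3/CP4, TP7/TP8, P7/P8, PO3/PO4, PO7/PO8, Fz, F3/F4, C3/C4,
#' Cz, T7/T8, P3/P4, Pz, O1/O2, Oz, with standard 10-10 positions projected
#' to the unit sphere. `F9`/`F10` are accepted as aliases for `FT9`/`FT10`
#' in montage files, a common labelling inconsistency for that position.
#'
#' Two channels are neighbors when the great-circle (angular) distance
#' between their unit-sphere positions is at most `neighbor_dist` radians.
#' The default (0.72 rad) gives 4-8 neighbors per sensor on this layout,
#' comparable to the immediate-surround adjacency used in sensor-space
#' cluster statistics.
#'
#' @param file Optional path to a montage CSV with columns
#'   `label,x,y,z,hemisphere`. When `NULL`, the packaged default is used.
#' @param neighbor_dist Angular distance threshold (radians) for the
#'   neighbor relation.
#' @return An object of class `eeg_montage`: a list with `channels`
#'   (a tibble `label,x,y,z,hemisphere`), `n`, `adjacency` (logical
#'   `n x n` matrix) and `neighbors` (named list of neighbor labels).
#' @examples
#' mon <- load_montage()
#' mon$n
#' head(mon$channels)
#' @export
load_montage <- function(file = NULL, neighbor_dist = 0.72) {
  path <- file %||% system.file("extdata", "montage40.csv", package = "eegmst")
  ch <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  required <- c("label", "x", "y", "z", "hemisphere")
  if (!all(required %in% names(ch))) {
    stop("montage file must have columns: ", paste(required, collapse = ", "))
  }
  alias <- c(F9 = "FT9", F10 = "FT10")
  ch$label <- ifelse(ch$label %in% names(alias), alias[ch$label], ch$label)
  if (anyDuplicated(ch$label)) {
    stop("duplicate channel labels in montage: ",
         paste(unique(ch$label[duplicated(ch$label)]), collapse = ", "))
  }
  missing <- setdiff(montage_labels(), ch$label)
  if (is.null(file) && length(missing)) {
    stop("default montage is missing channels: ", paste(missing, collapse = ", "))
  }
  # validate hemisphere tags against 10-20 odd/even/z naming
  expected <- hemisphere_from_label(ch$label)
  bad <- which(ch$hemisphere != expected)
  if (length(bad)) {
    stop("hemisphere tag inconsistent with label naming for: ",
         paste(ch$label[bad], collapse = ", "))
  }
  pos <- as.matrix(ch[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  ch$x <- pos[, 1]; ch$y <- pos[, 2]; ch$z <- pos[, 3]
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  ang <- acos(cosang)
  adj <- ang <= neighbor_dist
  diag(adj) <- FALSE
  dimnames(adj) <- list(ch$label, ch$label)
  neighbors <- lapply(seq_len(nrow(ch)), function(i) ch$label[adj[i, ]])
  names(neighbors) <- ch$label
  structure(
    list(channels = ch, n = nrow(ch), adjacency = adj, neighbors = neighbors,
         neighbor_dist = neighbor_dist),
    class = "eeg_montage"
  )
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", x$n, " channels; mean neighbors ",
      round(mean(rowSums(x$adjacency)), 1), "\n", sep = "")
  invisible(x)
}

# canonical label order of the default 40-channel montage
montage_labels <- function() {
  c("AF3", "AF4", "F7", "F8", "FT9", "FT10", "FC3", "FC4", "FC5", "FC6",
    "C1", "C2", "C5", "C6", "CP1", "CP2", "CP3", "CP4", "TP7", "TP8",
    "P7", "P8", "PO3", "PO4", "PO7", "PO8", "Fz", "F3", "F4", "C3", "C4",
    "Cz", "T7", "T8", "P3", "P4", "Pz", "O1", "O2", "Oz")
}

# left/right/midline from trailing digit parity ("z" = midline)
hemisphere_from_label <- function(labels) {
  last <- sub("^.*?([0-9]+|z)$", "\\1", labels)
  ifelse(last == "z", "midline",
         ifelse(as.integer(suppressWarnings(as.integer(last))) %% 2 == 1,
                "left", "right"))
}

# 2-D top-view projection for plotting and exports (azimuthal equidistant)
montage_projection_2d <- function(montage) {
  pos <- as.matrix(montage$channels[, c("x", "y", "z")])
  inc <- acos(pmin(1, pmax(-1, pos[, 3])))     # angle from vertex
  az <- atan2(pos[, 2], pos[, 1])              # 0 = right ear, pi/2 = nasion
  tibble::tibble(label = montage$channels$label,
                 px = inc * cos(az), py = inc * sin(az))
}
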