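#' Analytic signal via the Hilbert transform
#'
#' Returns the complex analytic representation of each row of a
#' band-limited channels x samples matrix: the real part equals the input
#' and the imaginary part is its Hilbert transform, so instantaneous phase
#' and amplitude are defined per sample.
#'
#' @param x Numeric matrix (channels x samples) or vector of band-limited
#'   real data.
#' @return Complex matrix of the same shape.
#' @examples
#' t <- seq(0, 1, length.out = 250)
#' z <- analytic_signal(cos(2 * pi * 10 * t))
#' @export
analytic_signal <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  X <- t(apply(x, 1, fft))
  if (nrow(x) == 1) X <- matrix(X, nrow = 1)
  Z <- sweep(X, 2, h, `*`)
  z <- t(apply(Z, 1, function(r) fft(r, inverse = TRUE))) / n
  if (nrow(x) == 1) z <- matrix(z, nrow = 1)
  dimnames(z) <- dimnames(x)
  if (vec) z[1, ] else z
}

#' Weighted (and unweighted) phase lag index
#'
#' For every channel pair, the weighted phase lag index over the epoch:
#' `wPLI = |mean(Im X)| / mean(|Im X|)`, where `X(t)` is the per-sample
#' cross-spectral term `z_i(t) * Conj(z_j(t))` between the analytic
#' signals. Pairs with `mean(|Im X|) = 0` (e.g. identical, zero-lag
#' channels) are set to 0 by the 0/0 convention: a phase-lag statistic is
#' by construction blind to zero-lag coupling. The unweighted variant
#' (`method = "pli"`) is `|mean(sign(Im X))|`.
#'
#' @param x Band-limited epoch data, channels x samples (>= 2 channels,
#'   >= 8 samples).
#' @param method `"wpli"` (default) or `"pli"`.
#' @return A symmetric non-negative matrix in `[0, 1]` with zero diagonal,
#'   of class `wpli_matrix`.
#' @examples
#' t <- seq(0, 4, by = 1 / 250)
#' x <- rbind(A = cos(2 * pi * 6 * t), B = sin(2 * pi * 6 * t))
#' wpli(x)["A", "B"] # constant quarter-cycle lag -> close to 1
#' @export
wpli <- function(x, method = c("wpli", "pli")) {
  method <- match.arg(method)
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (ncol(x) < 8) stop("wPLI undefined for epochs shorter than 8 samples")
  z <- analytic_signal(x)
  re <- Re(z); im <- Im(z)
  nch <- nrow(x)
  # Im(z_i Conj(z_j)) per sample = im_i * re_j - re_i * im_j, all pairs at once
  ii <- rep(seq_len(nch), each = nch)
  jj <- rep(seq_len(nch), times = nch)
  imx <- im[ii, , drop = FALSE] * re[jj, , drop = FALSE] -
         re[ii, , drop = FALSE] * im[jj, , drop = FALSE]
  if (method == "wpli") {
    num <- abs(rowMeans(imx))
    den <- rowMeans(abs(imx))
    val <- ifelse(den > 0, num / den, 0)
  } else {
    val <- abs(rowMeans(sign(imx)))
  }
  m <- matrix(val, nch, nch, dimnames = list(rownames(x), rownames(x)))
  m <- (m + t(m)) / 2      # numerically symmetric
  diag(m) <- 0
  m[m > 1] <- 1
  class(m) <- c("wpli_matrix", class(m))
  m
}

#' Sanitize a connectivity matrix for graph analysis
#'
#' Removes self-connections (diagonal forced to zero) and negative
#' entries (functional anticorrelations, forced to zero), then
#' symmetrizes as `(M + t(M)) / 2`. Idempotent.
#'
#' @param m A square numeric matrix.
#' @return A `wpli_matrix`.
#' @export
sanitize_adjacency <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("input must be a square matrix")
  m <- unclass(m)
  m[m < 0] <- 0
  m <- (m + t(m)) / 2
  diag(m) <- 0
  class(m) <- c("wpli_matrix", class(m))
  m
}

#' Per-trial, per-band connectivity matrices
#'
#' For each requested band, band-pass filters the continuous recording
#' (so that narrow bands are estimated without epoch-edge distortion),
#' re-cuts the retained epochs, and computes one sanitized wPLI matrix per
#' retained trial. Trials flagged as rejected contribute nothing.
#'
#' @param recording The (notch-filtered, broadband) continuous
#'   `eeg_recording` the epochs were cut from.
#' @param epochs The `eeg_epochs` carrying retention flags and onsets.
#' @param bands A band table from [band_specs()] (default: all seven).
#' @param method Passed to [wpli()].
#' @return A tibble with columns `band`, `trial`, `matrix` (list of
#'   `wpli_matrix`), one row per retained trial per band.
#' @export
per_trial_matrices <- function(recording, epochs, bands = band_specs(),
                               method = "wpli") {
  stopifnot(inherits(recording, "eeg_recording"), inherits(epochs, "eeg_epochs"))
  keep <- epochs$metadata[epochs$metadata$retained, ]
  if (nrow(keep) == 0) stop("no retained trials")
  nsamp <- round(epochs$epoch_length * epochs$srate)
  out <- purrr::map_dfr(seq_len(nrow(bands)), function(b) {
    rec_b <- bandpass(recording, bands[b, ])
    purrr::map_dfr(seq_len(nrow(keep)), function(k) {
      s <- keep$onset_sample[k]
      seg <- rec_b$data[, s:(s + nsamp - 1), drop = FALSE]
      tibble::tibble(band = bands$band[b], trial = keep$trial[k],
                     matrix = list(sanitize_adjacency(wpli(seg, method = method))))
    })
  })
  out
}

#' Average connectivity matrices across trials
#'
#' Element-wise mean of a list of sanitized matrices (e.g. all retained
#' trials of one subject in one band). Averaging across trials washes out
#' the short-epoch sampling noise of the per-trial estimates, so the mean
#' matrix is the stable carrier of a subject's coupling topology, used
#' for hub maps and local statistics.
#'
#' @param matrices List of `wpli_matrix` objects of equal dimension.
#' @return A `wpli_matrix`.
#' @export
average_matrices <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  sanitize_adjacency(Reduce(`+`, lapply(matrices, unclass)) / length(matrices))
}

#' Write a connectivity matrix as plain-text CSV
#'
#' @param m A `wpli_matrix` (or any square matrix).
#' @param path Output path.
#' @export
write_matrix_csv <- function(m, path) {
  write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}
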