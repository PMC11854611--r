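#' Frequency band definitions
#'
#' The seven canonical analysis bands: delta (1.5-4 Hz), theta (4-8),
#' alpha (8-13), beta1 (13-20), beta2 (20-30), gamma1 (30-48) and
#' gamma2 (52-70). gamma2 deliberately sits above the 50 Hz mains notch.
#'
#' @param names Optional character vector to subset/reorder the bands.
#' @return A tibble with columns `band`, `low_hz`, `high_hz`.
#' @examples
#' band_specs()
#' band_specs(c("theta", "alpha"))
#' @export
band_specs <- function(names = NULL) {
  b <- tibble::tibble(
    band    = c("delta", "theta", "alpha", "beta1", "beta2", "gamma1", "gamma2"),
    low_hz  = c(1.5, 4, 8, 13, 20, 30, 52),
    high_hz = c(4, 8, 13, 20, 30, 48, 70)
  )
  if (is.null(names)) return(b)
  unknown <- setdiff(names, b$band)
  if (length(unknown)) stop("unknown band(s): ", paste(unknown, collapse = ", "))
  b[match(names, b$band), ]
}

#' Construct a continuous multichannel recording
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row names
#'   are channel labels.
#' @param srate Sampling rate in Hz.
#' @param events Tibble/data frame with column `onset_sample` (1-based) and
#'   optionally `label`; may be empty.
#' @return An `eeg_recording` object.
#' @export
new_recording <- function(data, srate, events = NULL) {
  stopifnot(is.matrix(data), is.numeric(data), srate > 0)
  if (is.null(rownames(data))) {
    stop("recording data must have channel labels as row names")
  }
  events <- tibble::as_tibble(events %||%
    tibble::tibble(onset_sample = integer(), label = character()))
  if (!"label" %in% names(events)) events$label <- rep("stim", nrow(events))
  if (nrow(events)) {
    if (any(events$onset_sample < 1 | events$onset_sample > ncol(data))) {
      stop("event onset samples outside recording bounds")
    }
    events <- events[order(events$onset_sample), ]
  }
  structure(list(data = data, srate = srate, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz; ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

# shared forward-backward filter over the rows of a channels x samples matrix
filtfilt_rows <- function(flt, data) {
  out <- t(apply(data, 1, function(ch) signal::filtfilt(flt, ch)))
  dimnames(out) <- dimnames(data)
  out
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass, 4th order per pass.
#' Zero-phase filtering preserves the cross-channel phase relations on which
#' the phase-lag connectivity estimators depend.
#'
#' @param recording An `eeg_recording`.
#' @param band A one-row band definition as returned by [band_specs()], or a
#'   band name.
#' @param order Butterworth order per pass.
#' @return The filtered `eeg_recording` (same length, same events).
#' @examples
#' rec <- new_recording(matrix(rnorm(2 * 1000), 2,
#'                      dimnames = list(c("Cz", "Pz"), NULL)), srate = 250)
#' theta <- bandpass(rec, "theta")
#' @export
bandpass <- function(recording, band, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.character(band)) band <- band_specs(band)
  stopifnot(nrow(band) == 1, band$low_hz > 0, band$low_hz < band$high_hz)
  nyq <- recording$srate / 2
  if (band$high_hz >= nyq) {
    stop("band ", band$band, " upper edge (", band$high_hz,
         " Hz) at or above Nyquist (", nyq, " Hz)")
  }
  flt <- signal::butter(order, c(band$low_hz, band$high_hz) / nyq, type = "pass")
  recording$data <- filtfilt_rows(flt, recording$data)
  recording$band <- band$band
  recording
}

#' 50 Hz mains notch filter
#'
#' Zero-phase 2nd-order Butterworth band-stop at 48-52 Hz. Attenuates a
#' 50 Hz component by well over 20 dB while leaving 45/55 Hz neighbors
#' essentially untouched (< 3 dB).
#'
#' @param recording An `eeg_recording` with sampling rate above 100 Hz.
#' @return The filtered recording.
#' @export
notch_50hz <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (recording$srate <= 100) stop("sampling rate must exceed 100 Hz for a 50 Hz notch")
  nyq <- recording$srate / 2
  flt <- signal::butter(2, c(48, 52) / nyq, type = "stop")
  recording$data <- filtfilt_rows(flt, recording$data)
  recording
}

#' Broadband pre-filter
#'
#' The 1-70 Hz zero-phase Butterworth band-pass applied before band
#' decomposition.
#'
#' @inheritParams notch_50hz
#' @param low_hz,high_hz Band edges in Hz.
#' @export
broadband <- function(recording, low_hz = 1, high_hz = 70) {
  bandpass(recording,
           tibble::tibble(band = "broadband", low_hz = low_hz, high_hz = high_hz))
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one fixed-length window per event, starting at the event sample.
#' At 250 Hz the default 0.8 s window is exactly 200 samples. Events whose
#' window would run past the end of the recording are dropped and recorded
#' in the `dropped` attribute.
#'
#' @param recording An `eeg_recording`.
#' @param events Optional event table overriding `recording$events`.
#' @param epoch_length Window length in seconds.
#' @param metadata Optional per-event tibble (e.g. behavioral records) whose
#'   rows align with `events`; carried into the epoch metadata.
#' @return An `eeg_epochs` object: `data` (trials x channels x samples
#'   array), `srate`, `channels`, and `metadata` (tibble with `trial`,
#'   `onset_sample`, `retained`, `rejection_reason`, plus any metadata
#'   columns).
#' @examples
#' rec <- new_recording(matrix(rnorm(1000), 1, dimnames = list("Cz", NULL)),
#'                      srate = 250,
#'                      events = data.frame(onset_sample = c(1, 301)))
#' ep <- epoch_recording(rec)
#' dim(ep$data)
#' @export
epoch_recording <- function(recording, events = NULL, epoch_length = 0.8,
                            metadata = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (ncol(recording$data) == 0) stop("empty recording")
  events <- tibble::as_tibble(events %||% recording$events)
  nsamp <- round(epoch_length * recording$srate)
  if (!is.null(metadata)) {
    metadata <- tibble::as_tibble(metadata)
    stopifnot(nrow(metadata) == nrow(events))
  }
  fits <- events$onset_sample + nsamp - 1 <= ncol(recording$data)
  dropped <- events[!fits, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "window exceeds recording end"
  keep <- which(fits)
  nch <- nrow(recording$data)
  data <- array(NA_real_, dim = c(length(keep), nch, nsamp),
                dimnames = list(NULL, rownames(recording$data), NULL))
  for (k in seq_along(keep)) {
    s <- events$onset_sample[keep[k]]
    data[k, , ] <- recording$data[, s:(s + nsamp - 1)]
  }
  meta <- tibble::tibble(
    trial = seq_along(keep),
    onset_sample = events$onset_sample[keep],
    retained = rep(TRUE, length(keep)),
    rejection_reason = rep(NA_character_, length(keep))
  )
  if (!is.null(metadata)) {
    extra <- metadata[keep, setdiff(names(metadata), names(meta)), drop = FALSE]
    meta <- dplyr::bind_cols(meta, extra)
  }
  structure(
    list(data = data, srate = recording$srate, epoch_length = epoch_length,
         channels = rownames(recording$data), metadata = meta,
         dropped = dropped, band = recording$band %||% NA_character_),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat("<eeg_epochs> ", dim(x$data)[1], " trials x ", dim(x$data)[2],
      " channels x ", dim(x$data)[3], " samples @ ", x$srate, " Hz (",
      sum(x$metadata$retained), " retained)\n", sep = "")
  invisible(x)
}

#' Amplitude-based artifact rejection
#'
#' Flags every trial in which any sample on any channel strictly exceeds
#' the threshold in absolute value (default +/- 200 microvolts). Sample
#' data are never modified, only the `retained` / `rejection_reason`
#' metadata flags; a trial peaking at exactly the threshold is retained.
#'
#' @param epochs An `eeg_epochs` object with calibrated microvolt data.
#' @param threshold_uV Rejection threshold in microvolts.
#' @return The `eeg_epochs` with updated metadata.
#' @export
reject_artifacts <- function(epochs, threshold_uV = 200) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  peak <- apply(abs(epochs$data), 1, max)
  bad <- peak > threshold_uV
  epochs$metadata$retained <- epochs$metadata$retained & !bad
  epochs$metadata$rejection_reason <- ifelse(
    bad, "amplitude", epochs$metadata$rejection_reason)
  epochs
}

#' Signal-to-noise ratio of the evoked response
#'
#' Per channel, across retained trials: the mean event-related potential
#' (ERP) is computed; `A` is its peak-to-peak amplitude; the noise residual
#' of each trial is the trial minus the mean ERP; `sd_noise` is the
#' standard deviation of the pooled residual samples; and
#' `snr = A / (2 * sd_noise)`. A zero residual (identical trials) is
#' reported as infinite SNR with `degenerate = TRUE`. The subject-level
#' summary is the median across channels.
#'
#' @param epochs An `eeg_epochs` with at least 2 retained trials.
#' @return A tibble with one row per channel (`channel`, `A`, `sd_noise`,
#'   `snr`, `degenerate`) and attributes `snr_subject` (median channel SNR)
#'   and `n_trials`.
#' @export
compute_snr <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  keep <- which(epochs$metadata$retained)
  if (length(keep) < 2) stop("SNR requires at least 2 retained trials")
  x <- epochs$data[keep, , , drop = FALSE]
  erp <- apply(x, c(2, 3), mean)                   # channels x samples
  A <- apply(erp, 1, function(v) max(v) - min(v))
  resid <- sweep(x, c(2, 3), erp)                  # trial - mean ERP
  sd_noise <- apply(resid, 2, stats::sd)           # pooled over trials, samples
  degenerate <- sd_noise == 0
  snr <- ifelse(degenerate, Inf, A / (2 * sd_noise))
  out <- tibble::tibble(channel = epochs$channels, A = A,
                        sd_noise = sd_noise, snr = snr,
                        degenerate = degenerate)
  attr(out, "snr_subject") <- stats::median(snr)
  attr(out, "n_trials") <- length(keep)
  out
}

#' Select analyzable trials
#'
#' Keeps trials that are (still) retained, have a correct behavioral
#' response, and whose subject-level SNR (median channel SNR across
#' retained trials, from [compute_snr()]) meets `snr_min`.
#'
#' @param epochs An `eeg_epochs` whose metadata has a logical `correct`
#'   column.
#' @param snr_min Minimum acceptable subject-level SNR (0 disables the
#'   criterion).
#' @return The `eeg_epochs` with updated retention flags; the subject SNR
#'   is stored in the `snr_subject` attribute.
#' @export
select_trials <- function(epochs, snr_min = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (!"correct" %in% names(epochs$metadata)) {
    stop("trial metadata must contain a `correct` column")
  }
  snr_subject <- if (snr_min > 0 && sum(epochs$metadata$retained) >= 2) {
    attr(compute_snr(epochs), "snr_subject")
  } else {
    Inf
  }
  bad_correct <- epochs$metadata$retained & !epochs$metadata$correct
  epochs$metadata$retained <- epochs$metadata$retained &
    epochs$metadata$correct & (snr_subject >= snr_min)
  epochs$metadata$rejection_reason <- dplyr::case_when(
    !is.na(epochs$metadata$rejection_reason) ~ epochs$metadata$rejection_reason,
    bad_correct ~ "incorrect",
    !epochs$metadata$retained ~ "low_snr",
    TRUE ~ NA_character_
  )
  attr(epochs, "snr_subject") <- snr_subject
  epochs
}
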