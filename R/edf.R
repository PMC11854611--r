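# Minimal EDF+ (European Data Format) I/O: 16-bit data records plus an
# "EDF Annotations" signal carrying stimulus-onset markers as time-stamped
# annotation lists (TALs). Covers exactly what the pipeline needs: fixed
# srate, one annotation per event, microvolt signals.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = -width)
}

fmt_num <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, digits = 10)
}

# largest divisor of n that is <= cap (record size constraint)
largest_divisor <- function(n, cap) {
  for (d in seq(min(cap, n), 1)) if (n %% d == 0) return(d)
  1L
}

#' Write a recording to an EDF+ file
#'
#' Writes a continuous multichannel recording as EDF+ with 16-bit samples
#' at 0.1 microvolt resolution and an annotation track holding the
#' stimulus-onset events. Signals exceeding the declared physical range
#' raise an error rather than being silently clipped.
#'
#' @param recording An `eeg_recording` (see [new_recording()]).
#' @param path Output path.
#' @param physical_max Declared physical range (+/- microvolts).
#' @return `path`, invisibly.
#' @examples
#' rec <- new_recording(matrix(sin(1:500), 1, dimnames = list("Cz", NULL)),
#'                      srate = 250,
#'                      events = data.frame(onset_sample = 100L))
#' f <- tempfile(fileext = ".edf")
#' write_edf(rec, f)
#' rt <- read_edf(f)
#' @export
write_edf <- function(recording, path, physical_max = 3276.7) {
  stopifnot(inherits(recording, "eeg_recording"))
  data <- recording$data
  srate <- recording$srate
  nch <- nrow(data); n <- ncol(data)
  if (max(abs(data)) > physical_max) {
    stop("signal exceeds declared physical range of +/-", physical_max,
         " uV; not clipping")
  }
  gain <- physical_max / 32767
  digital <- round(data / gain)
  spr <- largest_divisor(n, max(1, floor(61440 / (2 * nch))))
  nrec <- n %/% spr
  rec_dur <- spr / srate

  # annotation TALs per record: timekeeping TAL + any events in the record
  ev_sec <- (recording$events$onset_sample - 1) / srate
  ev_rec <- pmin(nrec, floor(ev_sec / rec_dur) + 1)
  tals <- lapply(seq_len(nrec), function(r) {
    t0 <- (r - 1) * rec_dur
    s <- paste0("+", fmt_num(t0), "\x14\x14")
    for (k in which(ev_rec == r)) {
      s <- paste0(s, "+", fmt_num(ev_sec[k]), "\x14",
                  recording$events$label[k], "\x14")
    }
    charToRaw(s)
  })
  ann_bytes <- max(16, max(vapply(tals, length, integer(1))) + 1)
  if (ann_bytes %% 2) ann_bytes <- ann_bytes + 1
  spr_ann <- ann_bytes / 2

  ns <- nch + 1
  header <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate 01-JAN-2026 X X X", 80),
    "01.01.26", "00.00.00",
    pad_field((ns + 1) * 256, 8), pad_field("EDF+C", 44),
    pad_field(nrec, 8), pad_field(fmt_num(rec_dur), 8), pad_field(ns, 4)
  )
  sig_field <- function(vals, width) {
    paste(vapply(vals, pad_field, "", width = width), collapse = "")
  }
  labels <- c(rownames(data), "EDF Annotations")
  header <- paste0(
    header,
    sig_field(labels, 16),
    sig_field(rep("", ns), 80),
    sig_field(c(rep("uV", nch), ""), 8),
    sig_field(c(rep(fmt_num(-physical_max), nch), "-1"), 8),
    sig_field(c(rep(fmt_num(physical_max), nch), "1"), 8),
    sig_field(c(rep("-32767", nch), "-32768"), 8),
    sig_field(c(rep("32767", nch), "32767"), 8),
    sig_field(rep("", ns), 80),
    sig_field(c(rep(spr, nch), spr_ann), 8),
    sig_field(rep("", ns), 32)
  )

  # record-major int vector: records x signals x samples
  arr <- array(as.integer(digital), c(nch, spr, nrec))
  dint <- as.vector(aperm(arr, c(2, 1, 3)))       # sample, signal, record
  rd <- writeBin(dint, raw(), size = 2, endian = "little")
  rmat <- matrix(rd, nrow = 2 * spr * nch, ncol = nrec)
  amat <- vapply(tals, function(tl) {
    c(tl, raw(ann_bytes - length(tl)))
  }, raw(ann_bytes))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(as.vector(rbind(rmat, amat)), con)
  invisible(path)
}

#' Read an EDF+ file written by [write_edf()]
#'
#' Reconstructs the channel data (within the 0.1 microvolt quantization of
#' the 16-bit encoding) and the stimulus-onset events from the annotation
#' track.
#'
#' @param path Path to an EDF/EDF+ file with a uniform sampling rate.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(width) trimws(rawToChar(readBin(con, raw(), width)))
  rd_str(8)                                  # version
  rd_str(80); rd_str(80); rd_str(8); rd_str(8)
  rd_str(8)                                  # header bytes
  rd_str(44)
  nrec <- as.integer(rd_str(8))
  rec_dur <- as.numeric(rd_str(8))
  ns <- as.integer(rd_str(4))
  labels <- vapply(seq_len(ns), function(i) rd_str(16), "")
  for (i in seq_len(ns)) rd_str(80)          # transducer
  for (i in seq_len(ns)) rd_str(8)           # dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd_str(8)), 0)
  for (i in seq_len(ns)) rd_str(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd_str(8)), 0L)
  for (i in seq_len(ns)) rd_str(32)
  is_ann <- labels == "EDF Annotations"
  rec_len <- sum(spr)
  allraw <- readBin(con, raw(), 2 * rec_len * nrec)
  rawmat <- matrix(allraw, nrow = 2 * rec_len, ncol = nrec)
  offsets <- c(0, cumsum(spr))
  chans <- which(!is_ann)
  srate <- spr[chans[1]] / rec_dur
  data <- matrix(0, length(chans), spr[chans[1]] * nrec)
  for (ci in seq_along(chans)) {
    s <- chans[ci]
    rows <- (2 * offsets[s] + 1):(2 * offsets[s + 1])
    ints <- readBin(as.vector(rawmat[rows, ]), integer(),
                    n = spr[s] * nrec, size = 2, endian = "little")
    gain <- (phys_max[s] - phys_min[s]) / (dig_max[s] - dig_min[s])
    data[ci, ] <- phys_min[s] + gain * (ints - dig_min[s])
  }
  rownames(data) <- labels[chans]
  events <- tibble::tibble(onset_sample = integer(), label = character())
  if (any(is_ann)) {
    s <- which(is_ann)[1]
    rows <- (2 * offsets[s] + 1):(2 * offsets[s + 1])
    annraw <- as.vector(rawmat[rows, ])
    txt <- rawToChar(annraw[annraw != as.raw(0)])
    Encoding(txt) <- "bytes"
    tals <- strsplit(txt, "\x14\x14", useBytes = TRUE)[[1]]
    ev <- list()
    for (tal in tals) {
      parts <- strsplit(tal, "\x14", useBytes = TRUE)[[1]]
      # pairs of (onset, label) after each timekeeping stamp
      k <- 1
      while (k + 1 <= length(parts)) {
        onset <- suppressWarnings(as.numeric(sub("\x15.*$", "", parts[k])))
        lab <- parts[k + 1]
        if (!is.na(onset) && nzchar(lab)) {
          ev[[length(ev) + 1]] <- tibble::tibble(
            onset_sample = as.integer(round(onset * srate) + 1), label = lab)
        }
        k <- k + 2
      }
    }
    if (length(ev)) events <- dplyr::bind_rows(ev)
  }
  new_recording(data, srate, events = events)
}
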