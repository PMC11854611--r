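#' Default behavioral parameters per subgroup
#'
#' Location/scale parameters for vocal reaction time (vRT), word reading
#' duration (dRT), reading speed and success probability, per subgroup.
#' Group-level means and standard errors follow the published behavioral
#' table for dyslexic (DD) and control readers (vRT 1093.8 +/- 19.48 ms vs
#' 865.48 +/- 14.22 ms, and so on); standard deviations are recovered from
#' the standard errors at the reported group size (n = 24). Both sexes
#' within a group share parameters. Reaction times and durations are drawn
#' from log-normal distributions (right-skewed, strictly positive) whose
#' meanlog/sdlog are moment-matched to these means and SDs; success is a
#' per-trial Bernoulli draw.
#'
#' @param subject_cv Between-subject coefficient of variation applied as a
#'   multiplicative log-normal subject effect on the time measures.
#' @return A tibble with one row per subgroup.
#' @export
default_behavior_params <- function(subject_cv = 0.05) {
  n_ref <- 24  # group size behind the reported standard errors
  dd <- list(vrt_mean = 1093.8, vrt_sd = 19.48 * sqrt(n_ref),
             drt_mean = 734.46, drt_sd = 26.76 * sqrt(n_ref),
             speed_mean = 21.74, speed_sd = 2.28 * sqrt(n_ref),
             success_p = 0.7074)
  ct <- list(vrt_mean = 865.48, vrt_sd = 14.22 * sqrt(n_ref),
             drt_mean = 579.39, drt_sd = 30.21 * sqrt(n_ref),
             speed_mean = 39.65, speed_sd = 3.07 * sqrt(n_ref),
             success_p = 0.9932)
  purrr::map_dfr(
    c("control_boy", "control_girl", "dd_boy", "dd_girl"),
    function(sg) {
      p <- if (startsWith(sg, "dd")) dd else ct
      tibble::tibble(subgroup = sg, !!!p, subject_cv = subject_cv)
    })
}

#' Build a coupling matrix from an edge list
#'
#' @param montage An `eeg_montage`.
#' @param edges Tibble/data frame with columns `from`, `to` (channel
#'   labels) and `coupling` in `[0, 1]`.
#' @return A symmetric zero-diagonal `n x n` matrix.
#' @export
coupling_matrix <- function(montage, edges = NULL) {
  n <- montage$n
  m <- matrix(0, n, n, dimnames = list(montage$channels$label,
                                       montage$channels$label))
  if (!is.null(edges) && nrow(edges)) {
    stopifnot(all(edges$from %in% rownames(m)), all(edges$to %in% rownames(m)),
              all(edges$coupling >= 0 & edges$coupling <= 1))
    for (k in seq_len(nrow(edges))) {
      m[edges$from[k], edges$to[k]] <- edges$coupling[k]
      m[edges$to[k], edges$from[k]] <- edges$coupling[k]
    }
  }
  m
}

#' Star-shaped coupling around a hub channel
#'
#' @param montage An `eeg_montage`.
#' @param hub Hub channel label.
#' @param leaves Leaf channel labels.
#' @param coupling Coupling strength in `[0, 1]` for each hub-leaf edge.
#' @export
star_coupling <- function(montage, hub, leaves, coupling) {
  coupling_matrix(montage, tibble::tibble(
    from = hub, to = leaves, coupling = coupling))
}

# default planted coupling networks per subgroup and band: a left-frontal
# reading-network star shared by everyone in the theta band, plus a
# stronger posterior theta star (hub Pz) in the dd_girl subgroup carrying
# the planted sex effect within the DD group
default_band_coupling <- function(montage) {
  frontal <- star_coupling(montage, "F3",
                           c("AF3", "F7", "FC5", "Fz", "FC3", "C3"), 0.45)
  posterior <- star_coupling(montage, "Pz",
                             c("P3", "P4", "PO3", "PO4", "PO7", "PO8",
                               "O1", "O2", "Oz"), 0.9)
  base <- list(theta = frontal)
  list(control_boy = base, control_girl = base, dd_boy = base,
       dd_girl = list(theta = frontal + posterior))
}

#' Specify a synthetic EEG cohort
#'
#' Bundles and validates everything [generate_cohort()] needs: subgroup
#' sizes, trial structure, sampling parameters, planted per-band coupling
#' networks, noise and artifact levels, and behavioral distributions.
#' Defaults mirror the emulated study: 4 subgroups (control/DD x
#' boy/girl) of 12 subjects, blocks of 40 word trials, 250 Hz sampling,
#' 800 ms post-stimulus epochs, 1.5-2.5 s inter-stimulus intervals, and
#' the seven standard frequency bands.
#'
#' @param n_per_subgroup Subjects per subgroup (>= 1).
#' @param subgroups Subgroup labels.
#' @param trials_per_subject Word trials per subject.
#' @param sampling_rate Hz.
#' @param epoch_length Seconds.
#' @param iti_range Inter-stimulus interval range (s), drawn uniformly.
#' @param montage An `eeg_montage` (default [load_montage()]).
#' @param band_coupling Named list `subgroup -> band -> n x n` coupling
#'   matrix with entries in `[0, 1]`, symmetric, zero diagonal. See
#'   [coupling_matrix()]; default [`default_band_coupling`] structure.
#' @param coupling_lag Phase lag (radians) between coupled channels
#'   (default `pi / 2`; zero-lag coupling is invisible to wPLI by
#'   construction).
#' @param band_rms Named per-band RMS amplitude (microvolts) of the
#'   background oscillations.
#' @param noise_sd White measurement noise SD (microvolts).
#' @param artifact_rate Per-trial probability of an injected artifact
#'   (300 microvolt square pulse, 100 ms, random channel and position).
#' @param behavior_params Tibble as from [default_behavior_params()].
#' @param seed Mandatory integer seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_subgroup = 12,
                        subgroups = c("control_boy", "control_girl",
                                      "dd_boy", "dd_girl"),
                        trials_per_subject = 40,
                        sampling_rate = 250,
                        epoch_length = 0.8,
                        iti_range = c(1.5, 2.5),
                        montage = load_montage(),
                        band_coupling = NULL,
                        coupling_lag = pi / 2,
                        band_rms = c(delta = 6, theta = 5, alpha = 5,
                                     beta1 = 3, beta2 = 2, gamma1 = 1.5,
                                     gamma2 = 1),
                        noise_sd = 2,
                        artifact_rate = 0.05,
                        behavior_params = default_behavior_params(),
                        seed) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed")
  stopifnot(n_per_subgroup >= 1, trials_per_subject >= 1,
            sampling_rate > 0, epoch_length > 0,
            artifact_rate >= 0, artifact_rate <= 1, noise_sd >= 0)
  band_coupling <- band_coupling %||% default_band_coupling(montage)
  for (sg in names(band_coupling)) {
    for (bd in names(band_coupling[[sg]])) {
      m <- band_coupling[[sg]][[bd]]
      if (!is.matrix(m) || any(dim(m) != montage$n)) {
        stop("coupling matrix for ", sg, "/", bd,
             " must be ", montage$n, " x ", montage$n)
      }
      if (max(abs(m - t(m))) > 1e-12 || any(diag(m) != 0)) {
        stop("coupling matrix for ", sg, "/", bd,
             " must be symmetric with zero diagonal")
      }
      if (any(m < 0 | m > 1)) {
        stop("coupling values for ", sg, "/", bd, " must lie in [0, 1]")
      }
    }
  }
  stopifnot(all(subgroups %in% behavior_params$subgroup),
            all(behavior_params$success_p >= 0 & behavior_params$success_p <= 1),
            all(behavior_params$vrt_sd > 0), all(behavior_params$drt_sd > 0))
  unknown <- setdiff(unlist(lapply(band_coupling, names)), band_specs()$band)
  if (length(unknown)) stop("unknown band(s) in band_coupling: ",
                            paste(unique(unknown), collapse = ", "))
  structure(
    list(n_per_subgroup = n_per_subgroup, subgroups = subgroups,
         trials_per_subject = trials_per_subject,
         sampling_rate = sampling_rate, epoch_length = epoch_length,
         iti_range = iti_range, montage = montage,
         band_coupling = band_coupling, coupling_lag = coupling_lag,
         band_rms = band_rms, noise_sd = noise_sd,
         artifact_rate = artifact_rate, behavior_params = behavior_params,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# moment-matched log-normal parameters for mean m and SD s
lnorm_params <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# unit-SD narrowband Gaussian processes, one per column, synthesized in the
# frequency domain: white Gaussian noise shaped by a squared order-2
# Butterworth band-pass magnitude response (the zero-phase equivalent).
narrowband_noise_matrix <- function(n, ncol, low, high, srate) {
  nf <- stats::nextn(n, c(2, 3, 5))             # FFT-friendly length
  f <- (seq_len(nf) - 1) / nf * srate
  f <- pmin(f, srate - f)                       # two-sided frequency axis
  w0 <- sqrt(low * high); bw <- high - low
  s <- (f^2 - w0^2) / pmax(f * bw, 1e-12)
  H <- 1 / (1 + s^4)                            # |butter(2)|^2, filtfilt-like
  x <- matrix(stats::rnorm(nf * ncol), nf, ncol)
  X <- stats::mvfft(x) * H
  y <- Re(stats::mvfft(X, inverse = TRUE)) / nf
  y <- y[seq_len(n), , drop = FALSE]
  sweep(y, 2, apply(y, 2, stats::sd), `/`)
}

narrowband_noise <- function(n, low, high, srate) {
  narrowband_noise_matrix(n, 1, low, high, srate)[, 1]
}

# a narrowband driver plus its phase-rotated copy, consistent to the end
# of the (possibly FFT-unfriendly) requested length
driver_pair <- function(n, low, high, srate, lag) {
  nf <- stats::nextn(n, c(2, 3, 5))
  d <- narrowband_noise(nf, low, high, srate)
  lagged <- Re(analytic_signal(d) * exp(-1i * lag))
  list(driver = d[seq_len(n)], lagged = lagged[seq_len(n)])
}

# draw one subject's behavioral records (uses the ambient RNG stream)
draw_behavior <- function(params, trials, subject_id, subgroup) {
  vp <- lnorm_params(params$vrt_mean, params$vrt_sd)
  dp <- lnorm_params(params$drt_mean, params$drt_sd)
  sp <- lnorm_params(params$speed_mean, params$speed_sd)
  subj_shift <- stats::rnorm(1, 0, params$subject_cv)
  correct <- stats::rbinom(trials, 1, params$success_p) == 1
  tibble::tibble(
    subject = subject_id, subgroup = subgroup, trial = seq_len(trials),
    correct = correct,
    vrt_ms = stats::rlnorm(trials, vp$meanlog + subj_shift, vp$sdlog),
    drt_ms = stats::rlnorm(trials, dp$meanlog + subj_shift, dp$sdlog),
    speed = stats::rlnorm(1, sp$meanlog, sp$sdlog),
    omitted = !correct
  )
}

#' Draw behavioral records for a whole cohort
#'
#' Per-trial vocal reaction times, reading durations, per-subject reading
#' speed and per-trial correctness for every subject of the specified
#' cohort, without generating any EEG signal. Subgroup means converge to
#' the configured values as the cohort grows. Deterministic given the
#' spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble, one row per subject per trial.
#' @export
generate_behavior <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 1L, {
    purrr::map_dfr(spec$subgroups, function(sg) {
      params <- spec$behavior_params[spec$behavior_params$subgroup == sg, ]
      purrr::map_dfr(seq_len(spec$n_per_subgroup), function(i) {
        draw_behavior(params, spec$trials_per_subject,
                      sprintf("%s_%02d", sg, i), sg)
      })
    })
  })
}

# synthesize one subject's continuous recording with planted coupling.
# Coupling semantics: each connected component of a band's coupling graph
# shares one narrowband driver. The component's source node (max coupling
# degree, ties to the lowest index) carries the driver at lag 0; every
# other member receives it rotated by `coupling_lag`. A node's driver
# amplitude is sqrt(c_max) with c_max its strongest incident coupling, and
# its independent background is scaled by sqrt(1 - c_max), so expected
# wPLI on a source-member edge grows monotonically with c.
synthesize_recording <- function(spec, subgroup, onsets, n_samples) {
  mon <- spec$montage
  nch <- mon$n
  srate <- spec$sampling_rate
  bands <- band_specs()
  coupling <- spec$band_coupling[[subgroup]] %||% list()
  data <- matrix(0, nch, n_samples,
                 dimnames = list(mon$channels$label, NULL))
  for (b in seq_len(nrow(bands))) {
    bd <- bands$band[b]
    rms <- spec$band_rms[[bd]] %||% 0
    if (rms <= 0) next
    gain <- rep(1, nch)        # background scaling per channel
    contrib <- matrix(0, nch, n_samples)
    C <- coupling[[bd]]
    if (!is.null(C) && any(C > 0)) {
      g <- igraph::graph_from_adjacency_matrix(C > 0, mode = "undirected")
      comp <- igraph::components(g)$membership
      for (cid in unique(comp[colSums(C) > 0])) {
        members <- which(comp == cid & colSums(C) > 0)
        if (length(members) < 2) next
        cdeg <- colSums(C[, members, drop = FALSE] > 0)
        source <- members[order(-cdeg, members)][1]
        dp <- driver_pair(n_samples, bands$low_hz[b], bands$high_hz[b],
                          srate, spec$coupling_lag)
        driver <- dp$driver; lagged <- dp$lagged
        for (i in members) {
          cmax <- max(C[i, members])
          contrib[i, ] <- sqrt(cmax) *
            (if (i == source) driver else lagged)
          gain[i] <- sqrt(1 - cmax)
        }
      }
    }
    own <- t(narrowband_noise_matrix(n_samples, nch, bands$low_hz[b],
                                     bands$high_hz[b], srate))
    data <- data + rms * (own * gain + contrib)
  }
  if (spec$noise_sd > 0) {
    data <- data + matrix(stats::rnorm(nch * n_samples, 0, spec$noise_sd),
                          nch, n_samples)
  }
  # artifact injection: 300 uV square pulse, 100 ms, within the epoch window
  nsamp_ep <- round(spec$epoch_length * srate)
  pulse_len <- round(0.1 * srate)
  artifact <- stats::runif(length(onsets)) < spec$artifact_rate
  for (k in which(artifact)) {
    ch <- sample.int(nch, 1)
    at <- onsets[k] + sample.int(max(1, nsamp_ep - pulse_len), 1) - 1
    idx <- at:min(at + pulse_len - 1, n_samples)
    data[ch, idx] <- data[ch, idx] + 300
  }
  list(data = data, artifact = artifact)
}

#' Generate a synthetic EEG cohort
#'
#' Produces, per subject, a continuous multichannel recording (sum of
#' per-band narrowband Gaussian oscillations, planted phase-lag coupling,
#' white measurement noise and occasional suprathreshold artifacts) with
#' stimulus-onset event markers, plus per-trial behavioral records.
#' Bit-identical given the same spec and seed.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per subject: `subject`, `subgroup`,
#'   `group`, `sex`, `recording` (list of [new_recording()] objects with
#'   events) and `behavior` (list of per-trial tibbles, including an
#'   `artifact_injected` flag).
#' @examples
#' spec <- cohort_spec(n_per_subgroup = 1, trials_per_subject = 4,
#'                     subgroups = "control_boy", seed = 7)
#' cohort <- generate_cohort(spec)
#' cohort$recording[[1]]
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  srate <- spec$sampling_rate
  nsamp_ep <- round(spec$epoch_length * srate)
  pad <- round(2 * srate)
  with_seed(spec$seed, {
    purrr::map_dfr(spec$subgroups, function(sg) {
      params <- spec$behavior_params[spec$behavior_params$subgroup == sg, ]
      purrr::map_dfr(seq_len(spec$n_per_subgroup), function(i) {
        id <- sprintf("%s_%02d", sg, i)
        behavior <- draw_behavior(params, spec$trials_per_subject, id, sg)
        iti <- round(stats::runif(spec$trials_per_subject,
                                  spec$iti_range[1], spec$iti_range[2]) * srate)
        onsets <- pad + cumsum(c(1, (nsamp_ep + iti)[-spec$trials_per_subject]))
        n_samples <- onsets[length(onsets)] + nsamp_ep + pad
        syn <- synthesize_recording(spec, sg, onsets, n_samples)
        behavior$artifact_injected <- syn$artifact
        rec <- new_recording(
          syn$data, srate,
          events = tibble::tibble(onset_sample = onsets, label = "stim"))
        tibble::tibble(
          subject = id, subgroup = sg,
          group = if (startsWith(sg, "dd")) "dd" else "control",
          sex = if (endsWith(sg, "girl")) "girl" else "boy",
          recording = list(rec), behavior = list(behavior))
      })
    })
  })
}
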