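# simple FNV-1a hash of a string, for config fingerprints in the manifest
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h %% 2^31, b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Default demo run configuration
#'
#' A small synthetic run: 4 subgroups x 4 subjects, 8 trials each, theta
#' and alpha bands, comparing boys vs girls within each group. Completes
#' in a few minutes on one CPU while exercising every pipeline stage.
#'
#' @param seed Integer seed.
#' @param out_dir Optional output directory.
#' @return A run-configuration list for [run_pipeline()].
#' @export
demo_config <- function(seed = 1, out_dir = NULL) {
  list(
    synthetic = list(n_per_subgroup = 4, trials_per_subject = 8),
    bands = c("theta", "alpha"),
    reject_uv = 200, snr_min = 0, epoch_length = 0.8,
    n_perm = 500, alpha = 0.05,
    comparisons = list(c("dd_boy", "dd_girl"), c("control_boy", "control_girl")),
    hub_criterion = "bc",
    seed = seed, out_dir = out_dir
  )
}

# preprocess one subject end to end; returns NULL when nothing is retained
process_subject <- function(rec, behavior, bands, config) {
  rec <- notch_50hz(rec)
  rec <- broadband(rec)
  ep <- epoch_recording(rec, epoch_length = config$epoch_length %||% 0.8,
                        metadata = behavior)
  ep <- reject_artifacts(ep, threshold_uV = config$reject_uv %||% 200)
  ep <- select_trials(ep, snr_min = config$snr_min %||% 0)
  counts <- list(
    events = nrow(rec$events),
    dropped = nrow(ep$dropped),
    rejected = sum(!ep$metadata$retained),
    retained = sum(ep$metadata$retained)
  )
  if (counts$retained == 0) return(list(counts = counts, matrices = NULL))
  mats <- per_trial_matrices(rec, ep, bands = bands)
  list(counts = counts, matrices = mats, epochs = ep)
}

# per-trial global tree metrics for one subject's matrices tibble
subject_tree_metrics <- function(mats, subject, subgroup) {
  purrr::map_dfr(seq_len(nrow(mats)), function(k) {
    tree <- build_mst(mats$matrix[[k]],
                      provenance = list(subject = subject,
                                        trial = mats$trial[k],
                                        band = mats$band[k]))
    gm <- tree_metrics(tree)
    tibble::tibble(subject = subject, subgroup = subgroup,
                   band = mats$band[k], trial = mats$trial[k],
                   D = gm$D, LF = gm$LF, TH = gm$TH, K = gm$K)
  })
}

# subject-level node metrics: MST of the trial-averaged matrix per band
subject_node_metrics <- function(mats, subject, subgroup) {
  purrr::map_dfr(unique(mats$band), function(bd) {
    avg <- average_matrices(mats$matrix[mats$band == bd])
    nm <- node_metrics(build_mst(avg, provenance = list(subject = subject,
                                                        band = bd)))
    tibble::tibble(subject = subject, subgroup = subgroup, band = bd,
                   label = nm$label, degree = nm$degree,
                   degree_w = nm$degree_w, bc = nm$bc)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthetic-cohort generation (or EDF input), preprocessing
#' (notch, broadband, epoching, amplitude rejection, SNR-based trial
#' selection), per-trial wPLI connectivity in each requested band,
#' spanning-tree metrics, hub identification, and subgroup statistics
#' (permutation tests on the four global measures at Bonferroni
#' alpha / 4; cluster-based permutation on node betweenness at
#' alpha / 2), writing tables, BrainNet exports and a machine-readable
#' manifest when `out_dir` is set. Rerunning with the same config and
#' seed reproduces identical outputs.
#'
#' @param config A configuration list (see [demo_config()]) or the path
#'   to a JSON file of the same structure. `seed` is mandatory. Input is
#'   either `synthetic` (arguments for [cohort_spec()]) or `edf` (a data
#'   frame/list with `path` and `subgroup` per subject, plus per-trial
#'   `correct` flags supplied as `behavior`).
#' @return An `eegmst_run` list: `subjects` (per-subject summary tibble),
#'   `per_trial` (global metrics per trial), `node_summaries` (subject x
#'   band x channel means), `hubs`, `global_tests`, `cluster_tests`,
#'   `behavior_tests`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config$seed is mandatory")
  bands <- band_specs(config$bands %||% band_specs()$band)
  montage <- load_montage()
  alpha <- config$alpha %||% 0.05
  n_perm <- config$n_perm %||% 1000

  # --- input stage -----------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- do.call(cohort_spec, c(config$synthetic,
                                   list(seed = config$seed, montage = montage)))
    cohort <- generate_cohort(spec)
  } else if (!is.null(config$edf)) {
    edf <- tibble::as_tibble(config$edf)
    cohort <- purrr::map_dfr(seq_len(nrow(edf)), function(i) {
      rec <- read_edf(edf$path[i])
      beh <- tibble::tibble(correct = rep(TRUE, nrow(rec$events)),
                            vrt_ms = NA_real_)
      tibble::tibble(subject = edf$subject[i] %||% basename(edf$path[i]),
                     subgroup = edf$subgroup[i],
                     recording = list(rec), behavior = list(beh))
    })
  } else {
    stop("config must provide either `synthetic` or `edf` input")
  }

  # --- per-subject preprocessing + connectivity + trees ----------------
  stage_log <- list()
  per_trial <- list()
  node_rows <- list()
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$subject[i]
    res <- process_subject(cohort$recording[[i]], cohort$behavior[[i]],
                           bands, config)
    stage_log[[sid]] <- res$counts
    if (is.null(res$matrices)) {
      message("subject ", sid, ": no retained trials; skipped")
      next
    }
    per_trial[[sid]] <- subject_tree_metrics(res$matrices, sid,
                                             cohort$subgroup[i])
    node_rows[[sid]] <- subject_node_metrics(res$matrices, sid,
                                             cohort$subgroup[i])
  }
  if (!length(per_trial)) stop("pipeline: no subject produced any retained trial")
  per_trial <- dplyr::bind_rows(per_trial)
  node_summaries <- dplyr::bind_rows(node_rows)
  subjects <- per_trial |>
    dplyr::group_by(.data$subject, .data$subgroup, .data$band) |>
    dplyr::summarise(dplyr::across(c("D", "LF", "TH", "K"),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_trials = dplyr::n(), .groups = "drop")

  # --- hubs per subgroup and band --------------------------------------
  hub_criterion <- config$hub_criterion %||% "bc"
  hubs <- node_summaries |>
    dplyr::group_by(.data$subgroup, .data$band, .data$label) |>
    dplyr::summarise(degree = mean(.data$degree), bc = mean(.data$bc),
                     .groups = "drop") |>
    dplyr::group_by(.data$subgroup, .data$band) |>
    dplyr::group_modify(~ identify_hubs(.x, criterion = hub_criterion)) |>
    dplyr::ungroup()

  # --- statistics ------------------------------------------------------
  comparisons <- config$comparisons %||% list()
  # JSON/YAML round trips may deliver pairs as a matrix or data frame
  if (is.matrix(comparisons)) {
    comparisons <- split(comparisons, seq_len(nrow(comparisons)))
  } else if (is.data.frame(comparisons)) {
    comparisons <- apply(comparisons, 1, as.character, simplify = FALSE)
  }
  alpha_global <- bonferroni(alpha, 4)
  alpha_local <- bonferroni(alpha, 2)
  global_tests <- list(); cluster_tests <- list()
  for (cmp in comparisons) {
    for (bd in bands$band) {
      sa <- subjects[subjects$subgroup == cmp[1] & subjects$band == bd, ]
      sb <- subjects[subjects$subgroup == cmp[2] & subjects$band == bd, ]
      if (!nrow(sa) || !nrow(sb)) next
      for (meas in c("D", "LF", "TH", "K")) {
        res <- permutation_test_global(
          sa[[meas]], sb[[meas]], n_perm = n_perm,
          seed = config$seed + fnv_seed(paste(cmp[1], cmp[2], bd, meas)),
          measure = meas, band = bd, corrected_alpha = alpha_global)
        res$groups <- paste(cmp, collapse = " vs ")
        global_tests[[length(global_tests) + 1]] <- res
      }
      vals <- node_summaries |>
        dplyr::filter(.data$subgroup %in% cmp, .data$band == bd)
      wide <- tidyr::pivot_wider(vals, id_cols = c("subject", "subgroup"),
                                 names_from = "label", values_from = "bc")
      mat <- as.matrix(wide[, montage$channels$label])
      cl <- cluster_permutation_local(
        mat, wide$subgroup, montage, n_perm = n_perm,
        seed = config$seed + fnv_seed(paste(cmp[1], cmp[2], bd, "cluster")),
        corrected_alpha = alpha_local)
      if (nrow(cl)) {
        cl$groups <- paste(cmp, collapse = " vs ")
        cl$band <- bd
        cluster_tests[[length(cluster_tests) + 1]] <- cl
      }
    }
  }
  global_tests <- dplyr::bind_rows(global_tests)
  cluster_tests <- if (length(cluster_tests)) dplyr::bind_rows(cluster_tests)
                   else tibble::tibble()

  behavior_tests <- tibble::tibble()
  if (!is.null(config$synthetic)) {
    beh <- dplyr::bind_rows(cohort$behavior)
    grp <- ifelse(startsWith(beh$subgroup, "dd"), "dd", "control")
    if (length(unique(grp)) >= 2) {
      behavior_tests <- purrr::map_dfr(c("vrt_ms", "drt_ms"), function(v) {
        kruskal_wallis(beh[[v]], grp, measure = v)
      })
    }
  }

  manifest <- list(
    config_hash = fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE)),
    seed = config$seed,
    bands = bands$band,
    n_subjects = nrow(cohort),
    stage_counts = stage_log
  )
  run <- structure(
    list(subjects = subjects, per_trial = per_trial,
         node_summaries = node_summaries, hubs = hubs,
         global_tests = global_tests, cluster_tests = cluster_tests,
         behavior_tests = behavior_tests, manifest = manifest,
         montage = montage, config = config),
    class = "eegmst_run")
  out_dir <- config$out_dir
  if (length(out_dir) == 1 && is.character(out_dir)) write_run(run, out_dir)
  run
}

# deterministic small seed offset from a label
fnv_seed <- function(s) as.integer(strtoi(substr(fnv1a(s), 1, 5), 16L))

#' @export
print.eegmst_run <- function(x, ...) {
  cat("<eegmst_run> ", x$manifest$n_subjects, " subjects, bands: ",
      paste(x$manifest$bands, collapse = ", "), "\n", sep = "")
  cat("  global tests: ", nrow(x$global_tests), " (",
      sum(x$global_tests$significant %||% logical(0)), " significant)\n", sep = "")
  invisible(x)
}

# write tables, exports and the manifest of a finished run
write_run <- function(run, out_dir) {
  dir.create(file.path(out_dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "exports"), showWarnings = FALSE)
  wr <- function(df, name) {
    write.csv(as.data.frame(df), file.path(out_dir, "tables", name),
              row.names = FALSE)
  }
  wr(run$subjects, "subject_metrics.csv")
  wr(run$per_trial, "per_trial_metrics.csv")
  wr(run$node_summaries, "node_metrics.csv")
  wr(run$hubs, "hubs.csv")
  if (nrow(run$global_tests)) wr(run$global_tests, "global_tests.csv")
  if (nrow(run$cluster_tests)) {
    ct <- run$cluster_tests
    ct$channels <- vapply(ct$channels, paste, "", collapse = ";")
    wr(ct, "cluster_tests.csv")
  }
  if (nrow(run$behavior_tests)) wr(run$behavior_tests, "behavior_tests.csv")
  for (sg in unique(run$hubs$subgroup %||% character(0))) {
    for (bd in unique(run$hubs$band[run$hubs$subgroup == sg])) {
      nm <- run$node_summaries |>
        dplyr::filter(.data$subgroup == sg, .data$band == bd) |>
        dplyr::group_by(.data$label) |>
        dplyr::summarise(degree = mean(.data$degree), bc = mean(.data$bc),
                         .groups = "drop")
      nm <- nm[match(run$montage$channels$label, nm$label), ]
      hub_labels <- run$hubs$label[run$hubs$subgroup == sg & run$hubs$band == bd]
      export_brainnet(
        nm, hub_labels, NULL, run$montage,
        node_path = file.path(out_dir, "exports",
                              paste0(sg, "_", bd, ".node")))
    }
  }
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Export node/edge files for BrainNet Viewer
#'
#' Writes the whitespace-delimited `.node` file (x y z color size label,
#' one row per channel; color 2 marks hubs, 1 non-hubs; size is the
#' chosen node metric) and optionally the `.edge` file (n x n matrix
#' containing the strong edges, zeros elsewhere).
#'
#' @param node_metrics Tibble with `label` and a metric column (`bc` or
#'   `degree`) in montage order.
#' @param hub_labels Character vector of hub channel labels.
#' @param edge_matrix Optional n x n matrix of strong-edge weights (e.g.
#'   built from [strong_edges()]); `NULL` skips the `.edge` file.
#' @param montage An `eeg_montage`.
#' @param node_path,edge_path Output paths.
#' @param size_metric Column of `node_metrics` used for node size.
#' @return Invisibly, the paths written.
#' @export
export_brainnet <- function(node_metrics, hub_labels, edge_matrix, montage,
                            node_path, edge_path = NULL,
                            size_metric = "bc") {
  stopifnot(nrow(node_metrics) == montage$n)
  if (!identical(node_metrics$label, montage$channels$label)) {
    stop("node metrics must be in montage order")
  }
  size <- node_metrics[[size_metric]]
  color <- ifelse(node_metrics$label %in% hub_labels, 2, 1)
  pos <- round(80 * as.matrix(montage$channels[, c("x", "y", "z")]), 2)
  lines <- sprintf("%.2f\t%.2f\t%.2f\t%d\t%.4f\t%s",
                   pos[, 1], pos[, 2], pos[, 3], color, size,
                   node_metrics$label)
  writeLines(lines, node_path)
  paths <- node_path
  if (!is.null(edge_matrix) && !is.null(edge_path)) {
    stopifnot(all(dim(edge_matrix) == montage$n))
    write.table(format(unclass(edge_matrix), digits = 4),
                edge_path, row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    paths <- c(paths, edge_path)
  }
  invisible(paths)
}
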