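# End-to-end orchestration: behavior pipeline (saccades -> sleep states ->
# occupancy) and neural pipeline (post-processing -> encoding -> ramps ->
# enrichment -> dynamics), with a run manifest and structured stage logs.

#' Run the behavior pipeline
#'
#' Detects saccades on the eye-angle trace, finds sleep periods in the
#' speed trace, bins and featurizes them, fits (or loads) the substate
#' mixture, classifies bins, and writes `events.csv`, `features.csv`,
#' `labels.csv`, `occupancy.csv`, a raster figure and a run manifest to
#' `out_dir`.
#'
#' @param behavior_csv path to a behavior CSV (see [write_behavior_csv()])
#' @param out_dir output directory
#' @param variant detection variant: `"multi"` or `"single"`
#' @param gmm_file optional path to a frozen substate mixture JSON; when
#'   NULL the mixture is fitted on this recording's bins
#' @param seed integer seed
#' @return invisible list with `events`, `features`, `labels`, `occupancy`,
#'   `gmm`, `manifest`
#' @export
run_behavior_pipeline <- function(behavior_csv, out_dir,
                                  variant = c("multi", "single"),
                                  gmm_file = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (!file.exists(behavior_csv))
    stop("missing input file: ", behavior_csv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  beh <- read_behavior_csv(behavior_csv)
  fs_b <- beh$trace$fs_hz
  duration_s <- max(beh$trace$t_s) + 1 / fs_b

  periods <- detect_sleep(beh$speed$speed_mm_s, fs_b)
  message(sprintf("[states] %d sleep periods", nrow(periods)))
  events <- detect_saccades(beh$trace, variant,
                            period_ends_s = periods$end_s)
  message(sprintf("[saccades] %d accepted saccades", nrow(events)))

  bins <- do.call(rbind, lapply(seq_len(nrow(periods)), function(i)
    bin_period(periods$start_s[i], periods$end_s[i])))
  feats <- if (!is.null(bins)) featurize(bins, events) else
    data.frame(start_s = numeric(), end_s = numeric(), count = integer(),
               mean_slope_deg_s = numeric(), mean_fixation_s = numeric())
  message(sprintf("[states] %d sleep bins (%d with saccades)",
                  nrow(feats), sum(feats$count >= 1)))

  gmm <- if (!is.null(gmm_file)) read_substate_gmm(gmm_file)
  else fit_substate_gmm(feats, seed = seed)
  classified <- classify_bins(feats, gmm)
  labels <- label_series(classified, duration_s)
  occ <- compute_occupancy(labels)

  write_events_csv(events, file.path(out_dir, "events.csv"))
  data.table::fwrite(classified, file.path(out_dir, "features.csv"))
  write_labels_csv(labels, file.path(out_dir, "labels.csv"))
  data.table::fwrite(occ, file.path(out_dir, "occupancy.csv"))
  plot_state_raster(labels, file.path(out_dir, "raster.png"))
  manifest <- list(stage = "behavior", variant = variant, seed = seed,
                   input = basename(behavior_csv),
                   fs_hz = fs_b, n_periods = nrow(periods),
                   n_events = nrow(events), n_bins = nrow(feats),
                   version = as.character(utils::packageVersion("sleepscope")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(events = events, features = classified, labels = labels,
                 occupancy = occ, gmm = gmm, manifest = manifest))
}

#' Run the neural pipeline
#'
#' Post-processes a neuron bundle, then computes per-neuron encoding
#' statistics, ramp fits, anatomical enrichment of QEM-1-flagged neurons,
#' state PCA with entanglement, and relative-time decoding.
#'
#' @param neuron_dir path to a neuron bundle (see [write_neuron_bundle()])
#' @param labels_csv path to a label-series CSV
#' @param out_dir output directory
#' @param behavior optional list of behavior series on the neural grid
#'   (`speed`, `roll`, `pitch`, `left_eye`, `right_eye`, `heading`);
#'   encoding is skipped when absent
#' @param seed integer seed
#' @param decode logical: run the relative-time decoder (default TRUE)
#' @return invisible list of result tables
#' @export
run_neural_pipeline <- function(neuron_dir, labels_csv, out_dir,
                                behavior = NULL, seed = 1L, decode = TRUE) {
  for (p in c(neuron_dir, labels_csv))
    if (!file.exists(p)) stop("missing input: ", p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  nm <- read_neuron_bundle(neuron_dir)
  labels <- read_labels_csv(labels_csv)
  lab_end <- max(labels$end_s)
  neu_end <- ncol(nm$F) / nm$fs_hz
  if (abs(lab_end - neu_end) > 120)
    stop("label/neural time-base mismatch (", lab_end, " vs ", neu_end,
         " s); resample the labels onto the neural grid")
  clean <- neuro_prep(nm)
  message(sprintf("[neuro] %d/%d neurons after cleanup",
                  nrow(clean$F), nrow(nm$F)))
  t_s <- (seq_len(ncol(clean$F)) - 1L) / clean$fs_hz

  results <- list()
  # ramp fits per neuron
  ramps <- lapply(seq_len(nrow(clean$F)), function(i)
    fit_ramps(clean$F[i, ], t_s, labels))
  results$ramps <- data.frame(
    neuron = seq_along(ramps),
    model = vapply(ramps, function(r) if (isTRUE(r$undefined)) NA_character_
                   else r$model, character(1)),
    b = vapply(ramps, function(r) if (isTRUE(r$undefined)) NA_real_
               else r$b, numeric(1)),
    r2 = vapply(ramps, function(r) if (isTRUE(r$undefined)) NA_real_
                else r$r2, numeric(1)))
  data.table::fwrite(results$ramps, file.path(out_dir, "ramps.csv"))

  # encoding (needs behavior)
  if (!is.null(behavior)) {
    X <- build_regressors(behavior, labels, t_s, clean$fs_hz)
    enc <- lapply(seq_len(nrow(clean$F)), function(i)
      fit_encoding(clean$F[i, ], X, seed = seed + i))
    results$encoding <- data.frame(
      neuron = seq_along(enc),
      r2 = vapply(enc, `[[`, numeric(1), "r2"),
      sig_eyes = vapply(enc, function(e) e$partial$eyes$significant, logical(1)),
      sig_turn = vapply(enc, function(e) e$partial$turn_bias$significant, logical(1)),
      sig_qem1 = vapply(enc, function(e) e$partial$qem1$significant, logical(1)))
    data.table::fwrite(results$encoding, file.path(out_dir, "encoding.csv"))
    positive <- results$encoding$sig_qem1
  } else {
    positive <- !is.na(results$ramps$model)
  }

  # enrichment
  if (all(clean$regions == "unassigned")) {
    warning("no region labels; enrichment skipped")
  } else {
    results$enrichment <- enrichment(positive, clean$regions, seed = seed)
    data.table::fwrite(results$enrichment,
                       file.path(out_dir, "enrichment.csv"))
  }

  # dynamics
  pca <- state_pca(interpolate_missing(clean), labels, "QEM1")
  results$entanglement <- state_entanglement(pca)
  data.table::fwrite(results$entanglement,
                     file.path(out_dir, "entanglement.csv"))
  if (decode) {
    dec <- tryCatch(decode_relative_time(clean, labels, "QEM1", seed = seed),
                    error = function(e) NULL)
    if (!is.null(dec)) {
      results$decoder <- data.frame(r2 = dec$r2, n_periods = dec$n_periods)
      data.table::fwrite(results$decoder, file.path(out_dir, "decoder.csv"))
    }
  }
  manifest <- list(stage = "neural", seed = seed,
                   n_neurons_in = nrow(nm$F), n_neurons = nrow(clean$F),
                   version = as.character(utils::packageVersion("sleepscope")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Raster plot of a label series
#' @param labels label series (or list of them, one row per fish)
#' @param png_path output path
#' @export
plot_state_raster <- function(labels, png_path) {
  if (is.data.frame(labels)) labels <- list(labels)
  cols <- c(Wake = "grey85", QEM1 = "#e75480", QEM2 = "#2e8b57",
            QEM3 = "#808000", QNEM = "#4169e1", Unlabeled = "white")
  grDevices::png(png_path, width = 900, height = 60 + 24 * length(labels))
  op <- graphics::par(mar = c(3, 3, 1, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  xmax <- max(vapply(labels, function(l) max(l$end_s), numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax / 3600),
                 ylim = c(0, length(labels)), xlab = "time (h)",
                 ylab = "fish", yaxt = "n")
  for (i in seq_along(labels)) {
    l <- labels[[i]]
    graphics::rect(l$start_s / 3600, i - 1, l$end_s / 3600, i,
                   col = cols[l$label], border = NA)
  }
  invisible(png_path)
}
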