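#' Pipeline configuration
#'
#' Bundles every tunable of the simulate -> preprocess -> detect -> sort ->
#' summarize pipeline. A config round-trips through [jsonlite] serialization
#' unchanged apart from class attributes.
#'
#' @param genotype,drug condition (see [build_preset()]).
#' @param n_slices number of slices to simulate.
#' @param seed base seed; slice `i` uses `seed + i`.
#' @param filter a `vh_filter_spec`.
#' @param multiplier detection threshold multiple of delta.
#' @param dead_time_ms detector dead time in ms.
#' @param window snippet window in samples.
#' @param criterion a `vh_activity_criterion`.
#' @param spc a `vh_spc_config`.
#' @param sort run spike sorting on active electrodes.
#' @param noise a `vh_noise`.
#' @param duration_s,fs segment duration (s) and sampling rate (Hz).
#' @param out_dir optional output directory for artifacts.
#' @return An object of class `vh_config`.
#' @export
pipeline_config <- function(genotype = "control", drug = "basal",
                            n_slices = 12, seed = 1,
                            filter = filter_spec(), multiplier = 4.5,
                            dead_time_ms = 1, window = 64,
                            criterion = activity_criterion(),
                            spc = spc_config(), sort = FALSE,
                            noise = noise_model(), duration_s = 50,
                            fs = 20000, out_dir = NULL) {
  structure(
    list(genotype = genotype, drug = drug, n_slices = as.integer(n_slices),
         seed = as.integer(seed), filter = filter, multiplier = multiplier,
         dead_time_ms = dead_time_ms, window = as.integer(window),
         criterion = criterion, spc = spc, sort = isTRUE(sort),
         noise = noise, duration_s = duration_s, fs = fs,
         out_dir = out_dir),
    class = "vh_config"
  )
}

#' Analyze one recording segment end to end
#'
#' Preprocess (band-pass + detrend), detect spikes and classify active
#' electrodes, optionally sort each active electrode's waveforms into
#' units, and summarize the slice.
#'
#' @param segment a raw `vh_segment`.
#' @param config a `vh_config`.
#' @return List with `summary` (one row, see [summarize_slice()]),
#'   `detection` (a `vh_detection`), `n_units` (per electrode, NA where not
#'   sorted), `active_freq_obs` (frequency observations pooled over active
#'   electrodes).
#' @export
analyze_slice <- function(segment, config = pipeline_config()) {
  seg <- preprocess_segment(segment, config$filter)
  det <- detect_segment(seg, multiplier = config$multiplier,
                        dead_time_ms = config$dead_time_ms,
                        window = config$window,
                        criterion = config$criterion)
  n_units <- rep(NA_real_, length(det$counts))
  if (config$sort) {
    for (e in which(det$active)) {
      n_units[e] <- tryCatch(
        sort_electrode(det$waves[[e]], config$spc)$n_units,
        error = function(err) NA_real_)
    }
  }
  summary <- summarize_slice(det$counts, det$active, det$freq,
                             duration_s = segment$duration_s,
                             n_units = n_units,
                             condition = c(segment$condition,
                                           list(slice_id = segment$slice_id)))
  list(summary = summary, detection = det, n_units = n_units,
       active_freq_obs = as.numeric(t(det$freq[det$active, , drop = FALSE])))
}

#' Simulate and analyze all slices of one condition
#'
#' Renders `n_slices` synthetic slices under the condition preset and runs
#' the full analysis on each, collecting per-slice summaries, pooled
#' active-electrode frequency observations and (optionally) per-electrode
#' sorted unit counts. Slices are processed one at a time so memory stays
#' bounded.
#'
#' @param genotype,drug condition.
#' @param n_slices number of slices.
#' @param seed base seed (slice `i` is rendered with `seed + i`).
#' @param sort run spike sorting on active electrodes.
#' @param config optional `vh_config` overriding the remaining settings.
#' @param progress print one line per slice.
#' @return An object of class `vh_condition_run`: list with `summaries`
#'   (data.frame, one row per slice), `freq_obs` (per-slice vectors of
#'   active-electrode 25-s observations), `unit_counts` (pooled over active
#'   electrodes of all slices; NULL unless `sort`), `condition`.
#' @export
run_condition <- function(genotype = "control", drug = "basal",
                          n_slices = 12, seed = 1, sort = FALSE,
                          config = NULL, progress = FALSE) {
  if (is.null(config))
    config <- pipeline_config(genotype = genotype, drug = drug,
                              n_slices = n_slices, seed = seed, sort = sort)
  preset <- build_preset(config$genotype, config$drug)
  geometry <- array_geometry()
  summaries <- vector("list", config$n_slices)
  freq_obs <- vector("list", config$n_slices)
  unit_counts <- numeric(0)
  for (i in seq_len(config$n_slices)) {
    rec <- render_recording(geometry, preset, config$noise,
                            duration_s = config$duration_s, fs = config$fs,
                            seed = config$seed + i, slice_id = i)
    res <- analyze_slice(rec$segment, config)
    summaries[[i]] <- res$summary
    freq_obs[[i]] <- res$active_freq_obs
    if (config$sort)
      unit_counts <- c(unit_counts, res$n_units[res$detection$active])
    if (progress)
      message(sprintf("slice %d/%d: %d active, %.2f Hz", i, config$n_slices,
                      res$summary$n_active, res$summary$mean_frequency_hz))
    rm(rec, res)
  }
  structure(
    list(summaries = do.call(rbind, summaries), freq_obs = freq_obs,
         unit_counts = if (config$sort) unit_counts else NULL,
         condition = list(genotype = config$genotype, drug = config$drug),
         config = config),
    class = "vh_condition_run"
  )
}

#' Run the full pipeline from a configuration
#'
#' Simulates and analyzes the configured condition, writes the per-slice
#' summary CSV, a JSON report and a run manifest (config, per-stage
#' timings, seeds, package version) when `out_dir` is set, and returns all
#' three. The report is a pure function of the config, so identical configs
#' produce byte-identical reports.
#'
#' @param config a `vh_config`.
#' @return List with `summaries`, `report`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  t0 <- proc.time()[["elapsed"]]
  run <- run_condition(config = config)
  elapsed <- proc.time()[["elapsed"]] - t0
  s <- run$summaries
  report <- list(
    condition = run$condition,
    n_slices = nrow(s),
    n_active = list(mean = mean(s$n_active),
                    sem = sd(s$n_active) / sqrt(nrow(s))),
    frequency_hz = list(mean = mean(s$mean_frequency_hz),
                        sem = sd(s$mean_frequency_hz) / sqrt(nrow(s))),
    spikes_per_min = list(mean = mean(s$spikes_per_min),
                          sem = sd(s$spikes_per_min) / sqrt(nrow(s))),
    mean_units = if (config$sort) mean(run$unit_counts, na.rm = TRUE) else NULL,
    dispersion = "SEM"
  )
  manifest <- list(
    package = "vhmea",
    version = as.character(utils::packageVersion("vhmea")),
    seed = config$seed,
    slice_seeds = config$seed + seq_len(config$n_slices),
    elapsed_s = elapsed
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(s, file.path(config$out_dir, "summaries.csv"), row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(summaries = s, report = report, manifest = manifest)
}
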