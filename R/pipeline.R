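#' @title Reproducible experiment runs
#' @description Orchestrates generate -> burst detection -> metric panel ->
#' normalisation -> group statistics (and optionally the waveform path)
#' over several simulated cultures per treatment arm, writing CSV/JSON
#' outputs to a run directory. A run is reproducible from its config and
#' seed alone; a config hash is embedded in every output file header.
#' @name pipeline
NULL

# small deterministic config checksum (polynomial rolling hash, hex)
.config_hash <- function(x) {
  s <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 536870909
  sprintf("%08x", as.integer(h))
}

#' Run configuration
#'
#' @param seed Master seed; per-culture seeds are derived from it.
#' @param arms Named integer vector of simulated cultures per treatment
#'   arm; names must match [builtin_presets()] (default the 12 sham /
#'   15 RF / 8 MU design).
#' @param protocol A [mea_protocol()].
#' @param model A [network_model()].
#' @param burst_params A [burst_params()].
#' @param bin_width Time-course bin width, seconds.
#' @param mode `"events"` (spike times only; default) or `"waveforms"`
#'   (additionally renders short raw segments and runs the waveform path).
#' @param waveform_channels,waveform_phase_duration,waveform_cultures
#'   Waveform-mode problem size: channels rendered, seconds per phase,
#'   cultures per arm.
#' @return Object of class `mea_run_config`.
#' @export
run_config <- function(seed = 1,
                       arms = c(sham = 12, rf = 15, mu = 8),
                       protocol = mea_protocol(),
                       model = network_model(),
                       burst_params = NULL,
                       bin_width = 60,
                       mode = c("events", "waveforms"),
                       waveform_channels = 8,
                       waveform_phase_duration = 300,
                       waveform_cultures = 2) {
  mode <- match.arg(mode)
  if (is.null(burst_params))
    burst_params <- get("burst_params", mode = "function")()
  presets <- builtin_presets()
  if (!all(names(arms) %in% names(presets)))
    stop("unknown arm preset(s): ",
         paste(setdiff(names(arms), names(presets)), collapse = ", "),
         call. = FALSE)
  structure(list(seed = as.integer(seed), arms = arms, protocol = protocol,
                 model = model, burst_params = burst_params,
                 bin_width = bin_width, mode = mode,
                 waveform_channels = waveform_channels,
                 waveform_phase_duration = waveform_phase_duration,
                 waveform_cultures = waveform_cultures),
            class = "mea_run_config")
}

#' Read a flat key-value run config file
#'
#' Lines of the form `key = value` (comments with `#`). Recognised keys:
#' `seed`, `mode`, `bin_width`, `arms.<preset>` (culture counts),
#' `protocol.<field>`, `model.<field>`, `waveform_channels`,
#' `waveform_phase_duration`, `waveform_cultures`.
#'
#' @param path Config file path.
#' @return An [run_config()] object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  num <- suppressWarnings(as.numeric(vals))

  arg <- list()
  proto_args <- list(); model_args <- list(); arms <- c()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (startsWith(k, "arms.")) {
      arms[sub("^arms\\.", "", k)] <- num[i]
    } else if (startsWith(k, "protocol.")) {
      proto_args[[sub("^protocol\\.", "", k)]] <- num[i]
    } else if (startsWith(k, "model.")) {
      model_args[[sub("^model\\.", "", k)]] <- num[i]
    } else if (k == "mode") {
      arg$mode <- vals[i]
    } else {
      arg[[k]] <- num[i]
    }
  }
  if (length(arms)) arg$arms <- arms
  if (length(proto_args)) arg$protocol <- do.call(mea_protocol, proto_args)
  if (length(model_args)) arg$model <- do.call(network_model, model_args)
  do.call(run_config, arg)
}

.write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", hash), con)
  close(con)
  data.table::fwrite(df, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Derived per-culture seed
#' @param seed Master seed.
#' @param arm_index Arm number (1-based).
#' @param culture Culture number within the arm (1-based).
#' @return Integer seed below 2^31.
#' @export
culture_seed <- function(seed, arm_index, culture) {
  ((abs(as.integer(seed)) %% 1000003L) * 1000L +
     (arm_index - 1L) * 100L + culture) %% .Machine$integer.max
}

#' Run a full simulated experiment
#'
#' Executes, per arm and per simulated culture: spike-train generation,
#' burst detection, the metric panel with baseline normalisation,
#' synchrony CVs, time courses, initial inhibitory rate and PIR; then
#' between-arm group statistics with compact letters. In waveform mode a
#' reduced raw rendering per arm additionally yields AP feature ratios.
#' Outputs (CSV/JSON, each headed by the config hash) are written to
#' `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with `metrics` (per-culture data.frame),
#'   `stats` (per-metric `group_comparison`s), `timecourses`, and in
#'   waveform mode `waveforms`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "mea_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config[setdiff(names(config), "burst_params")])
  presets <- builtin_presets()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  rows <- list(); tcs <- list()
  for (ai in seq_along(config$arms)) {
    arm <- names(config$arms)[ai]
    for (ci in seq_len(config$arms[[ai]])) {
      sd_i <- culture_seed(config$seed, ai, ci)
      sim <- stage("generate", generate_spike_trains(
        config$protocol, config$model, presets[[arm]], seed = sd_i))
      cm <- stage("metrics", culture_metrics(
        sim$trains, config$protocol, config$burst_params, config$bin_width))
      pooled <- cm$normalized[cm$normalized$level == "pooled", ]
      R <- stats::setNames(pooled$R, pooled$metric)
      cvr <- cm$cv[, "exposure"] / cm$cv[, "baseline"]
      rows[[length(rows) + 1]] <- data.frame(
        arm = arm, culture = ci, seed = sd_i,
        n_active = length(cm$active),
        R_mbr = R[["mbr"]], R_ibi = R[["ibi"]], R_bd = R[["bd"]],
        R_ibsr = R[["ibsr"]], R_msr = R[["msr"]],
        cv_ibi_ratio = cvr[["ibi"]], cv_bd_ratio = cvr[["bd"]],
        cv_ibsr_ratio = cvr[["ibsr"]],
        iir_br = cm$iir_br, iir_sr = cm$iir_sr,
        pir_br = cm$pir_br, pir_sr = cm$pir_sr)
      tcs[[paste(arm, ci)]] <- data.frame(
        arm = arm, culture = ci, t_mid = cm$tc_br$t_mid,
        norm_br = cm$tc_br$norm, norm_sr = cm$tc_sr$norm)
    }
  }
  metrics <- do.call(rbind, rows)
  .write_csv_hashed(metrics, file.path(out_dir, "normalized_metrics.csv"), hash)

  tc_all <- do.call(rbind, tcs)
  for (arm in names(config$arms)) {
    sub <- tc_all[tc_all$arm == arm, ]
    agg <- stats::aggregate(cbind(norm_br, norm_sr) ~ t_mid, sub, mean)
    .write_csv_hashed(agg, file.path(out_dir,
                                     sprintf("timecourse_%s.csv", arm)), hash)
  }

  stats_out <- list()
  if (length(config$arms) >= 2 && all(config$arms >= 2)) {
    for (m in c("R_mbr", "R_msr", "R_ibi", "R_bd", "R_ibsr",
                "pir_br", "iir_br")) {
      gc <- stage("stats", group_compare(metrics[[m]], metrics$arm))
      stats_out[[m]] <- list(
        H = gc$omnibus$H, p = gc$omnibus$p_value,
        epsilon_squared = gc$epsilon_squared,
        letters = as.list(gc$letters),
        medians = as.list(gc$medians),
        pairwise_p = gc$pairwise)
    }
  }

  wf_out <- NULL
  if (config$mode == "waveforms") {
    wf_proto <- mea_protocol(config$waveform_phase_duration,
                             config$waveform_phase_duration,
                             max(60, config$waveform_phase_duration / 5),
                             n_channels = config$waveform_channels,
                             sampling_rate = config$protocol$sampling_rate)
    bank <- default_waveform_bank(config$waveform_channels,
                                  seed = config$seed)
    wf_rows <- list()
    for (ai in seq_along(config$arms)) {
      arm <- names(config$arms)[ai]
      for (ci in seq_len(min(config$arms[[ai]], config$waveform_cultures))) {
        sd_i <- culture_seed(config$seed, ai, ci) + 500L
        sim <- stage("generate", generate_spike_trains(
          wf_proto, config$model, presets[[arm]], seed = sd_i))
        rec <- stage("render", render_raw_recording(
          sim$trains, bank, wf_proto, presets[[arm]], seed = sd_i))
        wa <- stage("waveforms", analyze_waveforms(rec, wf_proto))
        if (!is.null(wa$mea))
          wf_rows[[length(wf_rows) + 1]] <- cbind(
            data.frame(arm = arm, culture = ci),
            as.data.frame(as.list(wa$mea)))
      }
    }
    if (length(wf_rows)) {
      wf_out <- do.call(rbind, wf_rows)
      .write_csv_hashed(wf_out, file.path(out_dir, "waveform_ratios.csv"),
                        hash)
    }
  }

  summary <- list(
    config_hash = hash,
    seed = config$seed,
    arms = as.list(config$arms),
    median_R = lapply(split(metrics, metrics$arm), function(df)
      lapply(df[c("R_mbr", "R_msr", "R_ibi", "R_bd", "R_ibsr")],
             stats::median)),
    stats = stats_out)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, stats = stats_out,
                 timecourses = tc_all, waveforms = wf_out, hash = hash))
}
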