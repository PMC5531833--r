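#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order and writes a JSON
#' report recording every parameter and seed used, so any output is
#' reproducible from the configuration alone. Stages:
#'
#' \describe{
#'   \item{`simulate`}{generate pacemaker traces (and ground truth)}
#'   \item{`dff`}{baseline estimation and dF/F0 on the traces}
#'   \item{`cycles`}{Fourier cycle-length summary of the traces}
#'   \item{`kymo`}{generate (or load) a kymograph}
#'   \item{`arrests`}{arrest-interval detection + arrest rate on the kymograph}
#'   \item{`modules`}{planted-connectome generation + module detection}
#'   \item{`stats`}{Wilcoxon signed-rank test of the per-trace dF/F0 peaks}
#' }
#'
#' `simulate` feeds `dff`, `cycles` and `stats`; `kymo` feeds `arrests`.
#' Requesting a stage without its input (and without `simulate`/`kymo` or
#' an input file) fails before any computation. Traces may also be supplied
#' from a CSV trace table via `config$traces_csv`.
#'
#' @param config list (or path to a JSON/YAML-less JSON file) with fields:
#'   `stages` (character vector), `seed`, `out_dir`, optional `traces_csv`,
#'   and per-stage parameter lists `simulate` (`n_sync`, `n_anti`,
#'   `period`, `duty`, `rate`, `tau`, `noise_sd`, `duration`), `dff`
#'   (`window`), `cycles` (`band`), `kymo` (`beat_hz`, `rate`, `n_frames`,
#'   `noise_sd`, `arrest_start`, `arrest_end`), `arrests` (`std_window`,
#'   `threshold`), `modules` (`sizes`, `resolution`, `n_restarts`)
#' @return invisibly, the report list (also written to
#'   `out_dir/report.json`)
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  valid <- c("simulate", "dff", "cycles", "kymo", "arrests", "modules",
             "stats")
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    stop_validation("config$stages is empty; valid stages: ",
                    paste(valid, collapse = ", "))
  unknown <- setdiff(stages, valid)
  if (length(unknown))
    stop_validation("unknown stage '", unknown[1], "'; valid stages: ",
                    paste(valid, collapse = ", "))
  have_traces <- any(c("simulate") %in% stages) ||
    !is.null(config$traces_csv)
  for (st in intersect(stages, c("dff", "cycles", "stats")))
    if (!have_traces)
      stop_validation("stage '", st, "' needs traces: request 'simulate' ",
                      "or set traces_csv")
  if ("arrests" %in% stages && !("kymo" %in% stages))
    stop_validation("stage 'arrests' needs a kymograph: request 'kymo'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  p <- function(stage, name, default) {
    v <- config[[stage]][[name]]
    if (is.null(v)) default else v
  }
  report <- list(package = "ciliomotor",
                 version = as.character(utils::packageVersion("ciliomotor")),
                 seed = seed, stages = stages, parameters = list(),
                 results = list())
  traces <- NULL; truth <- NULL

  if ("simulate" %in% stages) {
    prm <- list(n_sync = p("simulate", "n_sync", 4),
                n_anti = p("simulate", "n_anti", 2),
                period = p("simulate", "period", 71),
                duty = p("simulate", "duty", 0.5),
                rate = p("simulate", "rate", 1.5),
                tau = p("simulate", "tau", 1.5),
                noise_sd = p("simulate", "noise_sd", 2),
                duration = p("simulate", "duration", 6 * 71),
                seed = seed)
    sim <- do.call(gen_pacemaker_traces, prm)
    traces <- sim$traces; truth <- sim$truth
    report$parameters$simulate <- prm
    report$results$simulate <- list(n_traces = length(traces),
                                    n_frames = length(traces[[1]]$values))
    if (!is.null(out_dir))
      write_trace_table(traces, file.path(out_dir, "traces.csv"))
  } else if (!is.null(config$traces_csv)) {
    traces <- read_trace_table(config$traces_csv)
  }

  if ("dff" %in% stages) {
    window <- p("dff", "window", 10)
    dffs <- lapply(traces, dff, window = window)
    report$parameters$dff <- list(window = window)
    report$results$dff <- list(
      f0 = vapply(dffs, function(d) d$f0, numeric(1)),
      peak_dff = vapply(dffs, function(d) max(d$values), numeric(1)))
    if ("stats" %in% stages) {
      peaks <- report$results$dff$peak_dff
      wt <- wilcoxon_signed_rank(peaks)
      report$results$stats <- list(method = wt$method, W = wt$statistic,
                                   p_value = wt$p_value, n = wt$n)
    }
  } else if ("stats" %in% stages) {
    stop_validation("stage 'stats' needs 'dff' (it tests the dF/F0 peaks)")
  }

  if ("cycles" %in% stages) {
    band <- p("cycles", "band", c(50, 100))
    cyc <- cycle_length_summary(traces, band = band)
    report$parameters$cycles <- list(band = band)
    report$results$cycles <- list(median_period = cyc$median_period,
                                  fraction_in_band = cyc$fraction_in_band,
                                  n = cyc$n)
  }

  if ("kymo" %in% stages) {
    prm <- list(beat_hz = p("kymo", "beat_hz", 15),
                rate = p("kymo", "rate", 60),
                n_frames = p("kymo", "n_frames", 600),
                noise_sd = p("kymo", "noise_sd", 5),
                arrest_start = p("kymo", "arrest_start", 200),
                arrest_end = p("kymo", "arrest_end", 320))
    kg <- gen_kymograph(beat_hz = prm$beat_hz, rate = prm$rate,
                        n_frames = prm$n_frames, noise_sd = prm$noise_sd,
                        arrests = data.frame(start = prm$arrest_start,
                                             end = prm$arrest_end),
                        seed = seed)
    report$parameters$kymo <- prm
    if (!is.null(out_dir))
      write_kymograph_csv(kg$kymograph, file.path(out_dir, "kymograph.csv"))
    if ("arrests" %in% stages) {
      std_window <- p("arrests", "std_window", 9)
      threshold <- p("arrests", "threshold", 0.25)
      det <- detect_arrests(kg$kymograph, std_window = std_window,
                            threshold = threshold)
      report$parameters$arrests <- list(std_window = std_window,
                                        threshold = threshold)
      report$results$arrests <- list(
        n_intervals = nrow(det$intervals),
        arrests_per_min = arrest_rate(det, prm$n_frames / prm$rate),
        intervals = det$intervals)
      if (!is.null(out_dir))
        write_intervals_csv(det, file.path(out_dir, "arrests.csv"))
    }
  }

  if ("modules" %in% stages) {
    sizes <- p("modules", "sizes", c(10, 10, 10))
    resolution <- p("modules", "resolution", 1.4)
    n_restarts <- p("modules", "n_restarts", 20)
    pc <- gen_planted_connectome(sizes, seed = seed)
    part <- detect_modules(pc$network, resolution = resolution, seed = seed,
                           n_restarts = n_restarts)
    report$parameters$modules <- list(sizes = sizes, resolution = resolution,
                                      n_restarts = n_restarts)
    report$results$modules <- list(n_modules = part$n_modules,
                                   modularity = part$modularity_score)
    if (!is.null(out_dir))
      write_partition_csv(part, file.path(out_dir, "modules.csv"))
  }

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
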