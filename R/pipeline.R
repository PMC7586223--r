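#' Run the full single-molecule kinetics pipeline
#'
#' Drives every analysis stage from one configuration: (optionally) simulate
#' synthetic movies per construct, estimate per-fibril binding rate constants
#' and their Gaussian peaks, fit dwell-time distributions (single vs double
#' exponential with automatic selection), analyse trajectories (translational
#' rates, moving-time constants, processivity), fit bulk Michaelis-Menten
#' data, and assemble the kinetic summary table.  Results are returned as a
#' report list and, when `out_dir` is given, written as `report.json` and
#' `kinetic_table.csv`.
#'
#' The configuration is a named list (or the path of a YAML/JSON file) with
#' sections:
#' \describe{
#'   \item{`seed`}{integer master seed; per-construct seeds are derived from
#'     it, so the same configuration and seed reproduce the same report.}
#'   \item{`simulate`}{`field` (arguments of [make_fibril_field()]),
#'     `conditions` (arguments of [imaging_conditions()] for binding movies),
#'     optional `motion_conditions` (defaults: 1 fps, higher laser power),
#'     `n_tracks`, `frac_processive`.}
#'   \item{`constructs`}{named list; each construct has a `truth` list
#'     (arguments of [ground_truth()]) for simulation, or `events_csv` /
#'     `trajectories_csv` paths for real data; optional logical `motion`.}
#'   \item{`kon`}{`max_components`, `bin_width`.}
#'   \item{`koff`}{`components` (1, 2 or `"auto"`), `min_frames`,
#'     `bleach_rate`.}
#'   \item{`motion`}{`min_frames`, `static_mult`, `tail_threshold`,
#'     `bin_width`.}
#'   \item{`mm`}{optional: `substrate_concs`, `noise_sd`, `n_reps` to
#'     simulate and fit a bulk assay, or `csv` with columns conc, rate.}
#' }
#'
#' @param config named list or path to a YAML/JSON configuration file.
#' @param out_dir optional output directory.
#' @return a report list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort_invalid("`config` must be a list or a file path")
  config <- coerce_config_numbers(config)
  seed <- if (is.null(config$seed)) 1L else check_count(config$seed, "seed", min = 0L)
  if (is.null(config$constructs) || !length(config$constructs))
    abort_incomplete("stage config: no constructs defined")

  sim <- config$simulate
  cond <- do.call(imaging_conditions, as.list(sim$conditions %||% list()))
  field <- if (!is.null(sim$field)) {
    fargs <- as.list(sim$field)
    if (!is.null(fargs$bundle_weights))
      fargs$bundle_weights <- unlist(fargs$bundle_weights)
    fargs$seed <- fargs$seed %||% seed
    do.call(make_fibril_field, fargs)
  } else {
    NULL
  }
  kon_opts <- config$kon %||% list()
  koff_opts <- config$koff %||% list()
  motion_opts <- config$motion %||% list()

  constructs <- config$constructs
  results <- list()
  table_inputs <- list()
  for (i in seq_along(constructs)) {
    nm <- names(constructs)[i]
    cc <- constructs[[i]]
    cseed <- seed + 7L * i

    # --- events ---
    if (!is.null(cc$truth)) {
      truth <- do.call(ground_truth, as.list(cc$truth))
      if (is.null(field))
        abort_incomplete(sprintf("stage kon (%s): simulate.field missing", nm))
      events <- simulate_binding(truth, field, cond, seed = cseed)
      ev_field <- field
    } else if (!is.null(cc$events_csv)) {
      truth <- NULL
      events <- read_event_table(cc$events_csv)
      if (is.null(cc$field_csv))
        abort_incomplete(sprintf("stage kon (%s): field_csv missing", nm))
      ev_field <- read_fibril_field(cc$field_csv)
    } else {
      abort_incomplete(sprintf(
        "stage kon (%s): neither `truth` nor `events_csv` given", nm))
    }

    # --- kon ---
    sample <- kon_per_fibril(events, ev_field, cond)
    kon_fit <- fit_kon_distribution(
      sample,
      bin_width = kon_opts$bin_width,
      max_components = kon_opts$max_components %||% 3,
      improvement = kon_opts$improvement %||% 0.01)
    kon_est <- smallest_peak(kon_fit)

    # --- koff ---
    dwells <- collect_dwells(events, cond,
                             min_frames = koff_opts$min_frames %||% 1L)
    components <- koff_opts$components %||% "auto"
    if (identical(components, "auto")) {
      f1 <- fit_exponential(dwells, 1L)
      f2 <- fit_exponential(dwells, 2L)
      dwell_fit <- select_decay_model(f1, f2,
                                      koff_opts$tie_tolerance %||% 0.005)
    } else {
      dwell_fit <- fit_exponential(dwells, as.integer(components))
    }
    if ((koff_opts$bleach_rate %||% 0) > 0)
      dwell_fit <- bleach_correct(dwell_fit, koff_opts$bleach_rate)

    res <- list(
      construct = nm,
      n_events = nrow(events),
      kon = list(smallest_peak = kon_est, peaks = kon_fit$peaks,
                 k = kon_fit$k, r_squared = kon_fit$r_squared),
      koff = list(n_components = dwell_fit$n_components,
                  rates = dwell_fit$rates,
                  fractions = dwell_fit$fractions,
                  r_squared = dwell_fit$r_squared,
                  bleach_corrected = dwell_fit$bleach_corrected,
                  n_dwells = length(dwells$dwells),
                  n_censored = dwells$n_censored)
    )

    # --- motion (optional) ---
    if (isTRUE(cc$motion)) {
      mcond <- do.call(imaging_conditions, as.list(
        sim$motion_conditions %||%
          list(frame_rate = 1, duration = cond$duration,
               enzyme_conc = cond$enzyme_conc)))
      if (!is.null(cc$trajectories_csv)) {
        traj <- read_trajectory_table(cc$trajectories_csv)
      } else if (!is.null(truth) && !is.null(sim$n_tracks)) {
        traj <- simulate_trajectories(truth, field, mcond,
                                      n_tracks = sim$n_tracks,
                                      frac_processive = sim$frac_processive %||% 1,
                                      seed = cseed + 3L)
      } else {
        abort_incomplete(sprintf(
          "stage motion (%s): no trajectory source (trajectories_csv or simulate.n_tracks)",
          nm))
      }
      tracks <- load_tracks(traj,
                            min_frames = motion_opts$min_frames %||% 2L,
                            static_threshold_mult = motion_opts$static_mult %||% 3,
                            cond = mcond)
      msum <- translational_rates(tracks)
      ktr_fit <- fit_ktr_distribution(msum,
                                      max_components = motion_opts$max_components %||% 2,
                                      bin_width = motion_opts$bin_width)
      tail_fit <- fit_moving_time(msum$moving_time, "tail_gt_threshold",
                                  threshold = motion_opts$tail_threshold %||% 10,
                                  bin_width = motion_opts$time_bin_width %||% 1)
      full_fit <- fit_moving_time(msum$moving_time, "full_excl_first_bin",
                                  bin_width = motion_opts$time_bin_width %||% 1)
      v_slow <- min(ktr_fit$peaks)
      proc_tail <- processivity(v_slow, tail_fit$tau)
      proc_full <- processivity(v_slow, full_fit$tau)
      res$motion <- list(
        n_tracks = nrow(msum),
        n_static = attr(tracks, "n_static"),
        ktr_peaks = ktr_fit$peaks, ktr_k = ktr_fit$k,
        ktr_r_squared = ktr_fit$r_squared,
        tau_full = full_fit$tau, tau_tail = tail_fit$tau,
        v_slow = v_slow,
        processivity = proc_tail$value,
        processivity_reported = proc_tail$reported,
        processivity_full = proc_full$value,
        single_molecule_rate = single_molecule_rate(v_slow))
    }

    results[[nm]] <- res
    if (dwell_fit$n_components == 2L) {
      table_inputs[[nm]] <- list(kon_total = kon_est, fit = dwell_fit)
    }
  }

  report <- list(package = "cbhkin",
                 version = as.character(utils::packageVersion("cbhkin")),
                 seed = seed,
                 constructs = results)

  if (length(table_inputs)) {
    ktab <- build_kinetic_table(table_inputs)
    report$kinetic_table <- ktab$rows
    report$kinetic_table_rendered <- ktab$rendered
  }

  if (!is.null(config$mm)) {
    mm <- config$mm
    mm_data <- if (!is.null(mm$csv)) {
      utils::read.csv(mm$csv)
    } else {
      truth0 <- do.call(ground_truth, as.list(constructs[[1]]$truth))
      simulate_mm(truth0,
                  substrate_concs = unlist(mm$substrate_concs %||% c(0.3, 1, 3, 5)),
                  noise_sd = mm$noise_sd %||% 0,
                  n_reps = mm$n_reps %||% 1L,
                  seed = seed + 991L)
    }
    mm_fit <- fit_michaelis_menten(mm_data)
    report$mm <- list(kcat = mm_fit$kcat, Km = mm_fit$Km,
                      r_squared = mm_fit$r_squared)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(report$kinetic_table_rendered))
      utils::write.csv(report$kinetic_table_rendered[
        , c("construct", "component", "koff", "fraction_pct",
            "kon_component", "Kd")],
        file.path(out_dir, "kinetic_table.csv"), row.names = FALSE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# YAML 1.1 reads unsigned scientific notation ("4.3e8") as a string; coerce
# numeric-looking character scalars anywhere in a config tree.
coerce_config_numbers <- function(x) {
  if (is.list(x)) return(lapply(x, coerce_config_numbers))
  if (is.character(x) && length(x) >= 1L) {
    y <- suppressWarnings(as.numeric(x))
    if (!anyNA(y)) return(y)
  }
  x
}
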