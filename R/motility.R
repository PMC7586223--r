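#' Build per-track records from a trajectory table
#'
#' Splits a trajectory table into tracks, validates that frames increase
#' strictly within each track, drops tracks with fewer than `min_frames`
#' samples, and classifies as static (excluded from translational-rate
#' analysis) any track whose net first-to-last displacement does not exceed
#' `static_threshold_mult` times the pooled localization precision
#' (`sqrt((sx^2 + sy^2) / 2)`).
#'
#' @param traj a trajectory table (see [simulate_trajectories()] /
#'   [read_trajectory_table()]).
#' @param min_frames minimum samples per track (>= 2).
#' @param static_threshold_mult displacement threshold in units of pooled
#'   localization precision (default 3).
#' @param cond [imaging_conditions()] supplying the localization precision.
#' @return a list of class `track_list`; each element has `track_id`, `t`,
#'   `x`, `y`, `n_frames`, `moving_time`, `net_displacement`.  Attributes
#'   `n_static` and `n_short` count excluded tracks.
#' @export
load_tracks <- function(traj, min_frames = 2L, static_threshold_mult = 3,
                        cond = imaging_conditions(frame_rate = 1)) {
  stopifnot(inherits(cond, "imaging_conditions"))
  min_frames <- check_count(min_frames, "min_frames", min = 2L)
  check_nonneg(static_threshold_mult, "static_threshold_mult")
  if (!is.data.frame(traj) || !all(c("track_id", "frame", "t", "x", "y") %in% names(traj)))
    abort_invalid("`traj` must have columns track_id, frame, t, x, y")
  pooled <- sqrt((cond$loc_precision_x^2 + cond$loc_precision_y^2) / 2)
  threshold <- static_threshold_mult * pooled
  pieces <- split(traj, traj$track_id)
  n_short <- 0L
  n_static <- 0L
  tracks <- list()
  for (p in pieces) {
    p <- p[order(p$frame), ]
    if (any(diff(p$frame) <= 0))
      abort_parse(sprintf("track %s: frames not strictly increasing",
                          p$track_id[1]))
    if (nrow(p) < min_frames) {
      n_short <- n_short + 1L
      next
    }
    net <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
    if (net <= threshold) {
      n_static <- n_static + 1L
      next
    }
    tracks[[length(tracks) + 1L]] <-
      list(track_id = p$track_id[1], t = p$t, x = p$x, y = p$y,
           n_frames = nrow(p),
           moving_time = p$t[nrow(p)] - p$t[1],
           net_displacement = net)
  }
  structure(tracks, class = "track_list",
            n_static = n_static, n_short = n_short,
            static_threshold = threshold)
}

#' Per-track translational rates
#'
#' The translational rate of a track is the Euclidean distance between its
#' first and last positions divided by its moving time (the span of the
#' track).  Net displacement — not path length — is used, so purely
#' diffusive tracks yield fast apparent rates.
#'
#' @param tracks a `track_list` from [load_tracks()].
#' @return a data.frame of class `motion_summary` with columns `track_id`,
#'   `n_frames`, `moving_time`, `net_displacement`, `k_tr` (nm s^-1).
#' @export
translational_rates <- function(tracks) {
  stopifnot(inherits(tracks, "track_list"))
  if (length(tracks) == 0L) abort_empty("no tracks retained")
  out <- data.frame(
    track_id = vapply(tracks, `[[`, numeric(1), "track_id"),
    n_frames = vapply(tracks, `[[`, numeric(1), "n_frames"),
    moving_time = vapply(tracks, `[[`, numeric(1), "moving_time"),
    net_displacement = vapply(tracks, `[[`, numeric(1), "net_displacement")
  )
  out$k_tr <- out$net_displacement / out$moving_time
  class(out) <- c("motion_summary", "data.frame")
  out
}

#' Fit Gaussian peaks to a translational-rate distribution
#'
#' Same histogram least-squares machinery as [fit_kon_distribution()],
#' applied to per-track `k_tr` values.  With two components the lower peak is
#' read as the processive (catalysis-coupled) speed and the upper peak as
#' apparent surface diffusion.
#'
#' @param summary a `motion_summary` from [translational_rates()], or a
#'   numeric vector of rates.
#' @param max_components maximum number of Gaussian components (1 or 2).
#' @param bin_width histogram bin width (nm s^-1); Freedman-Diaconis by
#'   default.
#' @param improvement minimum R-squared gain an extra component must deliver.
#' @param alpha significance level of the nested-model F-test for adding a
#'   component (see [fit_kon_distribution()]).
#' @return a `gaussian_mixture_fit` with peaks sorted ascending.
#' @export
fit_ktr_distribution <- function(summary, max_components = 2,
                                 bin_width = NULL, improvement = 0.01,
                                 alpha = 0.01) {
  values <- if (is.data.frame(summary)) summary$k_tr else as.numeric(summary)
  if (length(values) < 30L)
    abort_invalid("need at least 30 tracks to fit a k_tr distribution")
  fit_gaussian_mixture(values, bin_width = bin_width,
                       max_components = max_components,
                       improvement = improvement, alpha = alpha)
}

# Single-exponential LS fit y = A exp(-t / tau) on selected histogram bins.
fit_single_exp_hist <- function(mids, counts, tau0) {
  fit <- try(minpack.lm::nls.lm(
    par = c(max(counts), tau0), lower = c(1e-12, 1e-9),
    fn = function(p) counts - p[1] * exp(-mids / p[2]),
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4))
    abort_fit("moving-time exponential fit did not converge")
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((counts - mean(counts))^2)
  list(amplitude = fit$par[1], tau = fit$par[2],
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Fit a single exponential to a moving-time distribution
#'
#' Histograms the moving times and fits `A exp(-t / tau)` by least squares.
#' Two modes mirror the two published fitting ranges: the full histogram with
#' the first bin excluded (`"full_excl_first_bin"` — the first bin is
#' contaminated by tracks at the visibility limit), or only bins whose lower
#' edge is at or above `threshold` (`"tail_gt_threshold"` — long runs, which
#' isolate the processively moving population, e.g. > 10 s).
#'
#' @param times moving times in s.
#' @param mode `"full_excl_first_bin"` or `"tail_gt_threshold"`.
#' @param threshold tail threshold in s (default 10).
#' @param bin_width histogram bin width in s (default 1).
#' @return an object of class `moving_time_fit`: `mode`, `tau` (s),
#'   `amplitude`, `threshold`, `r_squared`, `n`.
#' @export
fit_moving_time <- function(times,
                            mode = c("full_excl_first_bin", "tail_gt_threshold"),
                            threshold = 10, bin_width = 1) {
  mode <- match.arg(mode)
  check_positive(bin_width, "bin_width")
  check_positive(threshold, "threshold")
  times <- times[is.finite(times) & times > 0]
  if (mode == "full_excl_first_bin") {
    if (length(times) < 10L)
      abort_insufficient("need at least 10 moving times for the full-range fit")
  } else {
    if (sum(times >= threshold) < 5L)
      abort_insufficient("need at least 5 moving times at or above the threshold")
  }
  h <- grid_hist(times, bin_width)
  keep <- if (mode == "full_excl_first_bin") {
    seq_along(h$counts) > 1L
  } else {
    h$edges[-length(h$edges)] >= threshold
  }
  mids <- h$mids[keep]
  counts <- h$counts[keep]
  fit <- fit_single_exp_hist(mids, counts, tau0 = max(mean(times), bin_width))
  structure(list(mode = mode, tau = fit$tau, amplitude = fit$amplitude,
                 threshold = if (mode == "tail_gt_threshold") threshold else NA_real_,
                 r_squared = fit$r_squared, n = length(times),
                 histogram = h),
            class = "moving_time_fit")
}

#' Processivity from translational rate and moving time
#'
#' The number of catalytic steps per productive binding: the processive speed
#' multiplied by the moving-time constant, divided by the length of the
#' reaction product (cellobiose, ~1.0 nm, so that each step advances the
#' enzyme by one product length).
#'
#' @param v_slow processive translational rate, nm s^-1 (> 0).
#' @param tau moving-time constant, s (> 0).
#' @param product_length product length, nm (default 1.0).
#' @return a list with `value` (unrounded) and `reported` (nearest integer).
#' @examples
#' processivity(11.6, 4.6)$reported  # 53
#' processivity(8.8, 7.7)$reported   # 68
#' @export
processivity <- function(v_slow, tau, product_length = 1.0) {
  check_positive(v_slow, "v_slow")
  check_positive(tau, "tau")
  check_positive(product_length, "product_length")
  value <- v_slow * tau / product_length
  list(value = value, reported = round(value))
}

#' Per-molecule hydrolytic rate of a productively bound enzyme
#'
#' A processively moving cellobiohydrolase advances one product length per
#' catalytic event, so its single-molecule hydrolytic rate is the processive
#' speed divided by the product length.
#'
#' @inheritParams processivity
#' @return rate in s^-1.
#' @examples
#' single_molecule_rate(11.6)  # 11.6 s^-1
#' @export
single_molecule_rate <- function(v_slow, product_length = 1.0) {
  check_positive(v_slow, "v_slow")
  check_positive(product_length, "product_length")
  v_slow / product_length
}
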