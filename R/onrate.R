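#' Per-fibril binding rate constants
#'
#' The binding rate constant of a fibril is the number of molecules observed
#' to bind it, divided by enzyme concentration, fibril length and observation
#' time (units M^-1 um^-1 s^-1), then divided by the labeling ratio so that
#' invisible unlabeled molecules are accounted for.  Fibrils with no events
#' are kept as `kon = 0` rows: dropping them would bias the lowest
#' (single-bundle) peak of the distribution upward.
#'
#' @param events an event table (see [simulate_binding()] /
#'   [read_event_table()]).
#' @param field the fibril field the events were observed on.
#' @param cond [imaging_conditions()] supplying `enzyme_conc`, `duration` and
#'   `labeling_ratio`.
#' @return a data.frame of class `onrate_sample` with columns `fibril_id`,
#'   `n_events`, `kon`, plus attributes `enzyme_conc`, `duration`,
#'   `labeling_ratio`.
#' @export
kon_per_fibril <- function(events, field, cond) {
  stopifnot(inherits(cond, "imaging_conditions"))
  field <- as_fibril_field(field)
  unknown <- setdiff(unique(events$fibril_id), field$fibril_id)
  if (length(unknown))
    abort_consistency(sprintf("events reference unknown fibril ids: %s",
                              paste(utils::head(unknown, 5), collapse = ", ")))
  n <- as.integer(table(factor(events$fibril_id, levels = field$fibril_id)))
  kon <- n / (cond$enzyme_conc * field$length_um * cond$duration *
                cond$labeling_ratio)
  out <- data.frame(fibril_id = field$fibril_id, n_events = n, kon = kon)
  attr(out, "enzyme_conc") <- cond$enzyme_conc
  attr(out, "duration") <- cond$duration
  attr(out, "labeling_ratio") <- cond$labeling_ratio
  class(out) <- c("onrate_sample", "data.frame")
  out
}

#' Fit Gaussian peaks to a binding-rate distribution
#'
#' Histograms the per-fibril `kon` values and fits sums of 1 to
#' `max_components` Gaussians by least squares; the returned model is the
#' smallest component count whose R-squared is within `improvement` of the
#' next larger model's.  Multiple peaks are interpreted as fibril-bundle
#' multiplicity, so the lowest peak estimates the single-bundle binding rate
#' constant.
#'
#' @param sample an `onrate_sample` from [kon_per_fibril()], or a numeric
#'   vector of `kon` values.
#' @param bin_width histogram bin width; default is the Freedman-Diaconis
#'   width of the sample.
#' @param max_components maximum number of Gaussian components (1-3).
#' @param improvement minimum R-squared gain an extra component must deliver
#'   (default 0.01).
#' @param alpha significance level of the nested-model F-test an extra
#'   component must also pass (default 0.01); guards against reading sampling
#'   bumps of the histogram as peaks.
#' @return a `gaussian_mixture_fit`: component `peaks` (ascending), `widths`,
#'   `amplitudes`, `r_squared`, the histogram, and `k`.
#' @seealso [smallest_peak()]
#' @export
fit_kon_distribution <- function(sample, bin_width = NULL, max_components = 3,
                                 improvement = 0.01, alpha = 0.01) {
  values <- if (is.data.frame(sample)) sample$kon else as.numeric(sample)
  if (length(values) < 10L)
    abort_invalid("need at least 10 fibrils to fit a kon distribution")
  fit_gaussian_mixture(values, bin_width = bin_width,
                       max_components = max_components,
                       improvement = improvement, alpha = alpha)
}

#' Lowest peak of a Gaussian mixture fit
#'
#' Returns the smallest peak position, interpreted as the single-bundle
#' binding rate constant when applied to a `kon` distribution.
#'
#' @param fit a `gaussian_mixture_fit`.
#' @return the lowest peak position (numeric scalar).
#' @export
smallest_peak <- function(fit) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (length(fit$peaks) < 1L) abort_invalid("fit has no components")
  min(fit$peaks)
}
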