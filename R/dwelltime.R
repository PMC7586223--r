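#' Collect dwell (binding) times from an event table
#'
#' Dwell time is `t_end - t_bind`.  Events censored by the movie end are
#' excluded from the dwell list (they carry no complete dwell) and counted as
#' censored; events spanning fewer than `min_frames` frame intervals are
#' below the visibility threshold and discarded.  The retained dwells are
#' histogrammed in bins of one frame interval, with left-closed bins whose
#' edges are multiples of the frame interval.
#'
#' @param events an event table.
#' @param cond [imaging_conditions()]; supplies the frame interval.
#' @param min_frames minimum number of frame intervals an event must span
#'   (>= 1).
#' @return an object of class `dwell_data`: list with `dwells`, `n_censored`,
#'   `n_discarded`, `frame_interval`, and `histogram` (`edges`, `mids`,
#'   `counts`).
#' @export
collect_dwells <- function(events, cond, min_frames = 1L) {
  stopifnot(inherits(cond, "imaging_conditions"))
  min_frames <- check_count(min_frames, "min_frames")
  fi <- 1 / cond$frame_rate
  complete <- events$end_cause != "movie_end"
  dwell <- events$t_end[complete] - events$t_bind[complete]
  keep <- dwell >= min_frames * fi
  dwells <- dwell[keep]
  if (length(dwells) == 0L)
    abort_empty("no complete dwell exceeds the visibility threshold")
  h <- grid_hist(dwells, fi)
  structure(list(dwells = dwells,
                 n_censored = sum(!complete),
                 n_discarded = sum(!keep),
                 frame_interval = fi,
                 histogram = h),
            class = "dwell_data")
}

#' Build a dwell dataset from a pre-binned histogram
#'
#' For fitting published binding-time histograms (or exact model curves)
#' directly, without access to individual events.
#'
#' @param edges bin edges (ascending, regular spacing equal to the frame
#'   interval).
#' @param counts bin counts (`length(edges) - 1`, may be non-integer for
#'   model curves).
#' @param frame_interval frame interval in s.
#' @return a `dwell_data` object with an empty dwell list.
#' @export
dwell_histogram <- function(edges, counts, frame_interval) {
  check_positive(frame_interval, "frame_interval")
  if (length(counts) != length(edges) - 1L)
    abort_invalid("`counts` must have one entry per bin")
  structure(list(dwells = numeric(0), n_censored = 0L, n_discarded = 0L,
                 frame_interval = frame_interval,
                 histogram = list(edges = edges,
                                  mids = (edges[-1] + edges[-length(edges)]) / 2,
                                  counts = counts,
                                  width = edges[2] - edges[1])),
            class = "dwell_data")
}

# Sum-of-exponentials least squares on histogram counts:
# y(t) = sum_i A_i exp(-k_i t), positivity-constrained.
fit_exp_sum <- function(x, y, n_components, rate_init) {
  A0 <- rep(max(y), n_components)
  par0 <- as.numeric(rbind(A0, rate_init))
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = rep(1e-12, 2 * n_components),
    fn = function(p) {
      yy <- numeric(length(x))
      for (i in seq_len(n_components))
        yy <- yy + p[2 * i - 1] * exp(-p[2 * i] * x)
      y - yy
    },
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  ), silent = TRUE)
  if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) return(NULL)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  list(par = fit$par, r_squared = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Fit a single or double exponential decay to a dwell-time histogram
#'
#' Unweighted least squares of `y(t) = sum_i A_i exp(-k_i t)` to the
#' histogram counts, with all amplitudes and rates constrained positive.
#' For two components the faster rate is labeled `fast`.  Component
#' fractions are area fractions: `f_i = (A_i / k_i) / sum_j (A_j / k_j)`,
#' the integral of each decay over `[0, Inf)`.  If the fitted rates are
#' separated by less than a factor of 2 an `ill_separated` flag is set.
#'
#' @param data a `dwell_data` object.
#' @param n_components 1 or 2.
#' @return an object of class `exp_decay_fit`: `n_components`, `amplitudes`
#'   and `rates` (fast first), `fractions`, `r_squared`, `ill_separated`,
#'   `bleach_corrected`, `n` (events behind the histogram).
#' @export
fit_exponential <- function(data, n_components = 2L) {
  stopifnot(inherits(data, "dwell_data"))
  n_components <- check_count(n_components, "n_components")
  if (!n_components %in% 1:2) abort_invalid("`n_components` must be 1 or 2")
  h <- data$histogram
  nonzero <- sum(h$counts > 0)
  if (nonzero < 5L)
    abort_insufficient("need at least 5 nonzero histogram bins")
  x <- h$mids
  y <- h$counts
  k0 <- 1 / max(stats::weighted.mean(x, y), h$width)
  rate_init <- if (n_components == 1L) k0 else c(4 * k0, 0.4 * k0)
  fit <- fit_exp_sum(x, y, n_components, rate_init)
  if (is.null(fit) && n_components == 2L)  # retry from a wider split
    fit <- fit_exp_sum(x, y, 2L, c(10 * k0, 0.1 * k0))
  if (is.null(fit))
    abort_fit(sprintf("exponential fit (%d component(s)) did not converge",
                      n_components))
  A <- fit$par[seq(1, 2 * n_components, by = 2)]
  k <- fit$par[seq(2, 2 * n_components, by = 2)]
  ord <- order(k, decreasing = TRUE)  # fast first
  A <- A[ord]; k <- k[ord]
  areas <- A / k
  structure(list(n_components = n_components,
                 amplitudes = A, rates = k,
                 fractions = areas / sum(areas),
                 r_squared = fit$r_squared,
                 ill_separated = n_components == 2L && k[1] / k[2] < 2,
                 bleach_corrected = FALSE,
                 bleach_warning = FALSE,
                 n = sum(y),
                 histogram = h),
            class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  lab <- if (x$n_components == 2L) c("fast", "slow") else "single"
  cat(sprintf("Exponential decay fit (%d component(s)), R^2 = %.3f%s\n",
              x$n_components, x$r_squared,
              if (x$bleach_corrected) ", bleach-corrected" else ""))
  for (i in seq_len(x$n_components))
    cat(sprintf("  %s: k = %.4g s^-1, fraction = %.1f%%\n",
                lab[i], x$rates[i], 100 * x$fractions[i]))
  if (x$ill_separated)
    cat("  warning: rates separated by less than a factor of 2\n")
  invisible(x)
}

#' Area fractions of fitted decay components
#'
#' The fraction of events in each kinetic component is the area of its
#' fitted decay, `A_i / k_i`, normalized over components.
#'
#' @param fit an `exp_decay_fit`.
#' @return numeric vector of fractions summing to 1 (fast first for two
#'   components).
#' @export
component_fractions <- function(fit) {
  stopifnot(inherits(fit, "exp_decay_fit"))
  if (any(fit$rates <= 0)) abort_invalid("fit has non-positive rates")
  areas <- fit$amplitudes / fit$rates
  areas / sum(areas)
}

#' Choose between single- and double-exponential dwell models
#'
#' Prefers the double-exponential model when its R-squared is higher, and
#' also on ties (within `tie_tolerance`) — matching the convention of
#' resolving equal-quality fits in favour of the two-mode model so that mode
#' fractions can be reported.  The double model is only eligible when it is
#' resolved: its rates must differ by at least a factor of 2 (no
#' `ill_separated` flag) and each component must hold at least `min_fraction`
#' of the fitted area — a "mode" carrying a few percent of the events is a
#' fit artifact of the histogram, not an observed kinetic population (all
#' published minority modes of this system hold 19% or more).
#'
#' @param fit1 single-exponential `exp_decay_fit`.
#' @param fit2 double-exponential `exp_decay_fit`.
#' @param tie_tolerance R-squared difference treated as a tie (default
#'   0.005).
#' @param min_fraction smallest area fraction a resolved component may hold
#'   (default 0.15).
#' @return the chosen fit.
#' @export
select_decay_model <- function(fit1, fit2, tie_tolerance = 0.005,
                               min_fraction = 0.15) {
  stopifnot(inherits(fit1, "exp_decay_fit"), inherits(fit2, "exp_decay_fit"))
  check_nonneg(tie_tolerance, "tie_tolerance")
  check_fraction(min_fraction, "min_fraction")
  better <- fit2$r_squared > fit1$r_squared + tie_tolerance
  tie <- abs(fit2$r_squared - fit1$r_squared) <= tie_tolerance
  resolved <- !isTRUE(fit2$ill_separated) &&
    min(fit2$fractions) >= min_fraction
  if ((better || tie) && resolved) fit2 else fit1
}

#' Correct fitted dissociation rates for photobleaching
#'
#' An observed disappearance rate is the sum of true dissociation and
#' photobleaching rates (competing exponential risks), so each fitted rate is
#' reduced by `bleach_rate`, floored at `1e-6` s^-1.  Fractions are
#' recomputed from the corrected areas.  If `bleach_rate` is not well below
#' the slow observed rate the correction is unreliable and a warning flag is
#' attached.
#'
#' @param fit an `exp_decay_fit`.
#' @param bleach_rate photobleaching rate constant, s^-1 (>= 0).
#' @return a corrected `exp_decay_fit` with `bleach_corrected = TRUE`.
#' @export
bleach_correct <- function(fit, bleach_rate) {
  stopifnot(inherits(fit, "exp_decay_fit"))
  check_nonneg(bleach_rate, "bleach_rate")
  if (bleach_rate == 0) return(fit)
  out <- fit
  out$rates <- pmax(fit$rates - bleach_rate, 1e-6)
  areas <- out$amplitudes / out$rates
  out$fractions <- areas / sum(areas)
  out$bleach_corrected <- TRUE
  out$bleach_warning <- bleach_rate >= min(fit$rates)
  if (out$bleach_warning)
    warning("bleach_rate is not below the slowest observed rate; ",
            "correction unreliable", call. = FALSE)
  out
}
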