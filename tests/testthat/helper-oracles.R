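# Independent oracles used to cross-check the package's estimators.
# These deliberately take different routes than the implementation
# (likelihood instead of histogram least squares, grid search instead of
# Levenberg-Marquardt, quadrature instead of simulation).

# Maximum-likelihood fit of a two-component exponential mixture to dwell
# times left-truncated at t0 (the visibility threshold).
mle_exp_mixture <- function(dwells, t0 = 0) {
  nll <- function(par) {
    p <- stats::plogis(par[1])
    k1 <- exp(par[2]); k2 <- exp(par[3])
    dens <- p * k1 * exp(-k1 * dwells) + (1 - p) * k2 * exp(-k2 * dwells)
    norm <- p * exp(-k1 * t0) + (1 - p) * exp(-k2 * t0)
    -sum(log(dens / norm))
  }
  k0 <- 1 / mean(dwells - t0)
  fit <- stats::optim(c(0, log(4 * k0), log(0.4 * k0)), nll,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  k1 <- exp(fit$par[2]); k2 <- exp(fit$par[3])
  p1 <- stats::plogis(fit$par[1])
  if (k1 >= k2) {
    list(rates = c(k1, k2), frac_fast = p1)
  } else {
    list(rates = c(k2, k1), frac_fast = 1 - p1)
  }
}

# Quadrature oracle: expected fraction of fast-mode events among events that
# end by true dissociation, under competing photobleaching and movie-end
# censoring with uniform arrival times.
expected_fast_fraction <- function(frac_fast, koff_fast, koff_slow,
                                   bleach_rate, duration) {
  p_mode <- function(f, k) {
    g <- function(u) (k / (k + bleach_rate)) *
      (1 - exp(-(k + bleach_rate) * (duration - u)))
    f * stats::integrate(g, 0, duration)$value / duration
  }
  pf <- p_mode(frac_fast, koff_fast)
  ps <- p_mode(1 - frac_fast, koff_slow)
  pf / (pf + ps)
}

# Two-stage grid-search minimizer for the Michaelis-Menten model.
grid_mm <- function(data) {
  sse <- function(a, b) sum((data$rate - a * data$conc / (b + data$conc))^2)
  search <- function(kc, km) {
    best <- c(kc[1], km[1]); best_sse <- Inf
    for (a in kc) for (b in km) {
      s <- sse(a, b)
      if (s < best_sse) { best_sse <- s; best <- c(a, b) }
    }
    best
  }
  b1 <- search(seq(0.5 * max(data$rate), 4 * max(data$rate), length.out = 150),
               seq(1e-3, 5 * max(data$conc), length.out = 150))
  b2 <- search(seq(b1[1] * 0.93, b1[1] * 1.07, length.out = 150),
               seq(b1[2] * 0.85, b1[2] * 1.15, length.out = 150))
  list(kcat = b2[1], Km = b2[2])
}

# Convenience: simulate a dwell sample directly from a two-mode mixture with
# an event count large enough for recovery tests.
simulate_intact_dwell_fit <- function(n_fibrils, seed, duration = 400,
                                      bleach_rate = 0, min_frames = 1) {
  truth <- cfcel6b_truth("Intact")
  cond <- imaging_conditions(frame_rate = 5, duration = duration,
                             bleach_rate = bleach_rate, enzyme_conc = 5e-11)
  field <- make_fibril_field(n_fibrils, 5, 1, c("1" = 1), seed = seed)
  events <- simulate_binding(truth, field, cond, seed = seed + 1L)
  dwells <- collect_dwells(events, cond, min_frames = min_frames)
  list(truth = truth, cond = cond, events = events, dwells = dwells)
}
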