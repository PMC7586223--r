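# Least-squares fitting of a sum of Gaussians to a histogram, with component
# number chosen by R-squared improvement.  Used for both the binding-rate
# (k_on) and translational-rate (k_tr) distributions; multi-peak k_on
# distributions are read as fibril bundle multiplicity.

gauss_mix_curve <- function(par, x, k) {
  y <- numeric(length(x))
  for (i in seq_len(k)) {
    A <- par[3 * i - 2]; mu <- par[3 * i - 1]; s <- par[3 * i]
    y <- y + A * exp(-(x - mu)^2 / (2 * s^2))
  }
  y
}

# Multi-start Levenberg-Marquardt: one kmeans-seeded start plus random
# restarts, keeping the lowest-RSS solution.  A single start is prone to
# local minima (e.g. a narrow component parked on one noisy bin).
fit_gauss_k <- function(x, y, k, values, bin_width, n_restarts = 8) {
  if (length(x) < 3 * k + 1) return(NULL)  # under-determined
  mu0 <- if (k == 1) mean(values) else {
    km <- try(stats::kmeans(values, centers = k, nstart = 5), silent = TRUE)
    if (inherits(km, "try-error")) NULL else sort(as.numeric(km$centers))
  }
  s_all <- stats::sd(values)
  starts <- list()
  if (!is.null(mu0))
    starts[[1]] <- as.numeric(rbind(rep(max(y) * 0.9, k), mu0,
                                    rep(max(s_all / k, bin_width / 2), k)))
  rng <- range(values)
  for (i in seq_len(if (k == 1) 2 else n_restarts)) {
    mu_r <- sort(stats::runif(k, rng[1], rng[2]))
    s_r <- stats::runif(k, bin_width / 2, max(s_all, bin_width))
    a_r <- stats::runif(k, max(y) * 0.2, max(y))
    starts[[length(starts) + 1]] <- as.numeric(rbind(a_r, mu_r, s_r))
  }
  # a histogram cannot resolve structure narrower than its bin
  lower <- rep(c(1e-12, -Inf, bin_width / 2), k)
  best <- NULL
  for (par0 in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = par0, lower = lower,
      fn = function(p) y - gauss_mix_curve(p, x, k),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ), silent = TRUE)
    if (inherits(fit, "try-error") || !(fit$info %in% 1:4)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
  }
  if (is.null(best)) return(NULL)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) return(NULL)
  list(par = best$par, r_squared = 1 - best$rss / tss, rss = best$rss,
       n_bins = length(y))
}

# Number of local maxima of the fitted sum-of-Gaussians curve.
count_modes <- function(par, k, lo, hi) {
  x <- seq(lo, hi, length.out = 2048)
  y <- gauss_mix_curve(par, x, k)
  d <- diff(y)
  sum(d[-length(d)] > 0 & d[-1] <= 0)
}

# Sequential nested-model comparison: accept k+1 components over k only when
# (i) the F-test on the residual sums of squares is significant at `alpha`,
# (ii) the R^2 gain exceeds `improvement` (practical significance), and
# (iii) the larger model's curve actually exhibits one mode per component —
# a "peak" that is not a local maximum of the fitted distribution is a shape
# correction, not a resolved population.  A fixed R^2 threshold alone accepts
# sampling bumps of the histogram as extra peaks.
accept_larger_model <- function(smaller, larger, alpha, improvement) {
  if (larger$r_squared - smaller$r_squared <= improvement) return(FALSE)
  k_larger <- length(larger$par) / 3
  mus <- larger$par[seq(2, length(larger$par), by = 3)]
  sds <- abs(larger$par[seq(3, length(larger$par), by = 3)])
  if (count_modes(larger$par, k_larger,
                  min(mus) - 4 * max(sds), max(mus) + 4 * max(sds)) < k_larger)
    return(FALSE)
  extra <- 3 * ((length(larger$par) - length(smaller$par)) / 3)
  df2 <- larger$n_bins - length(larger$par)
  if (df2 < 1) return(FALSE)
  f_stat <- ((smaller$rss - larger$rss) / extra) / (larger$rss / df2)
  if (!is.finite(f_stat)) return(FALSE)
  stats::pf(f_stat, extra, df2, lower.tail = FALSE) < alpha
}

# values: raw sample; returns object of class gaussian_mixture_fit
fit_gaussian_mixture <- function(values, bin_width = NULL, max_components = 3,
                                 improvement = 0.01, alpha = 0.01) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || stats::sd(values) == 0)
    abort_fit("degenerate sample: all values identical, Gaussian width undefined")
  max_components <- check_count(max_components, "max_components")
  if (max_components > 3L) abort_invalid("`max_components` must be 1-3")
  if (is.null(bin_width)) bin_width <- fd_bin_width(values)
  check_positive(bin_width, "bin_width")
  # random restarts run under a private, fixed RNG stream so that fitting is
  # deterministic and leaves the caller's RNG state untouched
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(285714L)
  h <- grid_hist(values, bin_width)
  fits <- lapply(seq_len(max_components), function(k)
    fit_gauss_k(h$mids, h$counts, k, values, bin_width))
  ok <- which(!vapply(fits, is.null, logical(1)))
  if (!length(ok))
    abort_fit(sprintf(
      "Gaussian fit failed to converge for all k in 1..%d (n = %d, bin_width = %g)",
      max_components, length(values), bin_width))
  r2 <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$r_squared,
               numeric(1))
  # forward selection: grow the component count only while each step is both
  # statistically (F-test) and practically (R^2 gain) justified
  choose_k <- ok[1]
  for (k_next in ok[-1]) {
    if (accept_larger_model(fits[[choose_k]], fits[[k_next]],
                            alpha, improvement)) {
      choose_k <- k_next
    } else {
      break
    }
  }
  par <- fits[[choose_k]]$par
  comp <- matrix(par, ncol = 3, byrow = TRUE)
  ordp <- order(comp[, 2])
  structure(list(
    k = choose_k,
    peaks = comp[ordp, 2],
    widths = abs(comp[ordp, 3]),
    amplitudes = comp[ordp, 1],
    r_squared = r2[choose_k],
    r_squared_all = r2,
    bin_width = bin_width,
    histogram = h,
    n = length(values)
  ), class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("Gaussian mixture fit: %d component(s), R^2 = %.3f, n = %d\n",
              x$k, x$r_squared, x$n))
  for (i in seq_len(x$k))
    cat(sprintf("  peak %d: %.4g (width %.3g, amplitude %.3g)\n",
                i, x$peaks[i], x$widths[i], x$amplitudes[i]))
  invisible(x)
}
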