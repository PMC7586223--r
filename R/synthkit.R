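#' Imaging conditions for a simulated or real single-molecule movie
#'
#' Bundles the acquisition parameters of a TIRF-style single-molecule movie:
#' frame rate, movie duration, fluorophore photobleaching rate, localization
#' precision, enzyme concentration, and the fraction of enzyme molecules that
#' carry a dye (labeling ratio).  Defaults reflect typical binding-movie
#' conditions: 5 fps, 400 s, Cy3 bleaching at 0.053 s^-1, ~4.5 nm localization
#' precision, 50 pM enzyme, full labeling.
#'
#' @param frame_rate frames per second (> 0).
#' @param duration movie length in seconds; must be at least two frame
#'   intervals.
#' @param bleach_rate photobleaching rate constant in s^-1 (>= 0).
#' @param loc_precision_x,loc_precision_y localization precision (SD of the
#'   Gaussian localization error) along x and y, in nm (>= 0).
#' @param enzyme_conc enzyme concentration in molar (> 0).
#' @param labeling_ratio fraction of molecules carrying a fluorophore, in
#'   (0, 1].
#' @return an object of class `imaging_conditions` (a named list).
#' @export
imaging_conditions <- function(frame_rate = 5, duration = 400,
                               bleach_rate = 0.053,
                               loc_precision_x = 4.5, loc_precision_y = 4.6,
                               enzyme_conc = 50e-12, labeling_ratio = 1) {
  check_positive(frame_rate, "frame_rate")
  check_positive(duration, "duration")
  if (duration < 2 / frame_rate)
    abort_invalid("`duration` must cover at least two frame intervals")
  check_nonneg(bleach_rate, "bleach_rate")
  check_nonneg(loc_precision_x, "loc_precision_x")
  check_nonneg(loc_precision_y, "loc_precision_y")
  check_positive(enzyme_conc, "enzyme_conc")
  check_fraction(labeling_ratio, "labeling_ratio", open_left = TRUE)
  structure(list(frame_rate = frame_rate, duration = duration,
                 bleach_rate = bleach_rate,
                 loc_precision_x = loc_precision_x,
                 loc_precision_y = loc_precision_y,
                 enzyme_conc = enzyme_conc, labeling_ratio = labeling_ratio),
            class = "imaging_conditions")
}

#' Ground-truth kinetic parameters for a simulated enzyme construct
#'
#' Collects the true kinetic parameters a synthetic experiment is generated
#' from, so that downstream estimators can be validated by parameter recovery:
#' the per-bundle binding rate constant, the fast/slow dissociation mixture,
#' processive and diffusive translational speeds, the moving-time constant,
#' and bulk Michaelis-Menten parameters.
#'
#' @param kon_total binding rate constant per bundle, M^-1 um^-1 s^-1 (> 0).
#' @param frac_fast fraction of binding events in the fast-dissociating mode.
#' @param koff_fast,koff_slow dissociation rate constants, s^-1; must satisfy
#'   `koff_fast > koff_slow > 0`.
#' @param v_proc processive translational speed along the fibril axis, nm s^-1
#'   (>= 0; 0 gives static tracks).
#' @param v_diff apparent first-to-last displacement rate of the diffusive
#'   population, nm s^-1 (>= 0).
#' @param tau_move mean moving time of processive tracks, s (> 0).
#' @param kcat bulk turnover number, s^-1 (> 0).
#' @param Km bulk Michaelis constant, mg ml^-1 (> 0).
#' @param frac_slow slow fraction; defaults to `1 - frac_fast` and must agree
#'   with it to 1e-12.
#' @return an object of class `ground_truth` (a named list).
#' @seealso [cfcel6b_truth()] for published parameter sets.
#' @export
ground_truth <- function(kon_total, frac_fast, koff_fast, koff_slow,
                         v_proc = 11.6, v_diff = 25.3, tau_move = 4.6,
                         kcat = 2.4, Km = 0.51, frac_slow = 1 - frac_fast) {
  check_positive(kon_total, "kon_total")
  check_fraction(frac_fast, "frac_fast")
  check_fraction(frac_slow, "frac_slow")
  if (abs(frac_fast + frac_slow - 1) > 1e-12)
    abort_invalid("`frac_fast` and `frac_slow` must sum to 1")
  check_positive(koff_fast, "koff_fast")
  check_positive(koff_slow, "koff_slow")
  if (koff_fast <= koff_slow)
    abort_invalid("`koff_fast` must exceed `koff_slow`")
  check_nonneg(v_proc, "v_proc")
  check_nonneg(v_diff, "v_diff")
  check_positive(tau_move, "tau_move")
  check_positive(kcat, "kcat")
  check_positive(Km, "Km")
  structure(list(kon_total = kon_total, frac_fast = frac_fast,
                 frac_slow = frac_slow, koff_fast = koff_fast,
                 koff_slow = koff_slow, v_proc = v_proc, v_diff = v_diff,
                 tau_move = tau_move, kcat = kcat, Km = Km),
            class = "ground_truth")
}

#' Published kinetic parameters of CfCel6B constructs
#'
#' `cfcel6b_reference()` returns the published single-molecule kinetic summary
#' for the four CfCel6B constructs (full-length "Intact", catalytic domain
#' "CD", linker plus binding domain "FN3s-CBD", and binding domain "CBD"):
#' total binding rate constant, fast/slow dissociation rate constants and
#' their area fractions.  `cfcel6b_truth()` converts one construct's row into
#' a [ground_truth()] object for simulation; the motility and bulk parameters
#' (measured only for the full-length enzyme) default to the Intact values.
#'
#' @param construct one of `"Intact"`, `"CD"`, `"FN3s-CBD"`, `"CBD"`.
#' @return `cfcel6b_reference()`: a data.frame with columns `construct`,
#'   `kon_total`, `koff_fast`, `koff_slow`, `frac_fast`, `frac_slow`.
#'   `cfcel6b_truth()`: a `ground_truth` object.
#' @examples
#' cfcel6b_reference()
#' cfcel6b_truth("Intact")
#' @export
cfcel6b_reference <- function() {
  data.frame(
    construct = c("Intact", "CD", "FN3s-CBD", "CBD"),
    kon_total = c(4.3e8, 1.7e7, 2.0e8, 1.5e8),
    koff_fast = c(0.85, 1.7, 2.7, 3.1),
    koff_slow = c(0.086, 0.13, 0.29, 0.47),
    frac_fast = c(0.33, 0.81, 0.26, 0.30),
    frac_slow = c(0.67, 0.19, 0.74, 0.70),
    stringsAsFactors = FALSE
  )
}

#' @rdname cfcel6b_reference
#' @export
cfcel6b_truth <- function(construct = c("Intact", "CD", "FN3s-CBD", "CBD")) {
  construct <- match.arg(construct)
  ref <- cfcel6b_reference()
  row <- ref[ref$construct == construct, ]
  ground_truth(kon_total = row$kon_total, frac_fast = row$frac_fast,
               koff_fast = row$koff_fast, koff_slow = row$koff_slow,
               frac_slow = row$frac_slow)
}

#' Generate a field of cellulose microfibrils
#'
#' Lays out `n_fibrils` straight microfibril segments in a square field
#' (emulating crystalline cellulose spin-coated on a cover glass).  Lengths
#' are drawn from a normal distribution truncated at zero; each fibril is
#' assigned a bundle multiplicity drawn from `bundle_weights` (microfibrils
#' often deposit as bundles of several elementary fibrils, which multiplies
#' the apparent binding rate).
#'
#' @param n_fibrils number of fibrils (>= 1).
#' @param length_mean,length_sd mean and SD of fibril length, um; `length_sd
#'   = 0` gives all lengths exactly `length_mean`.
#' @param bundle_weights named numeric vector of probabilities; names are
#'   bundle counts (e.g. `c("1" = 0.6, "2" = 0.4)`).  Must sum to 1.
#' @param seed integer seed; the result is reproducible for a fixed seed.
#' @param field_size side of the square field, um (default 80).
#' @return a data.frame of class `fibril_field` with columns `fibril_id`,
#'   `length_um`, `n_bundles`, `x1`, `y1`, `x2`, `y2` (endpoint coordinates
#'   in nm).
#' @export
make_fibril_field <- function(n_fibrils, length_mean, length_sd = 0,
                              bundle_weights = c("1" = 1), seed = 1L,
                              field_size = 80) {
  check_count(n_fibrils, "n_fibrils")
  check_positive(length_mean, "length_mean")
  check_nonneg(length_sd, "length_sd")
  w <- as.numeric(bundle_weights)
  counts <- as.integer(names(bundle_weights))
  if (length(w) == 0L || any(!is.finite(w)) || any(w < 0) ||
      abs(sum(w) - 1) > 1e-9 || any(is.na(counts)) || any(counts < 1L))
    abort_invalid("`bundle_weights` must be named probabilities over bundle counts >= 1 summing to 1")
  set.seed(seed)
  lengths <- numeric(n_fibrils)
  todo <- seq_len(n_fibrils)
  while (length(todo)) {  # truncate at zero by resampling
    lengths[todo] <- stats::rnorm(length(todo), length_mean, length_sd)
    todo <- todo[lengths[todo] <= 0]
  }
  n_bundles <- counts[sample.int(length(counts), n_fibrils, replace = TRUE,
                                 prob = w)]
  theta <- stats::runif(n_fibrils, 0, pi)
  cx <- stats::runif(n_fibrils, 0, field_size) * 1000
  cy <- stats::runif(n_fibrils, 0, field_size) * 1000
  half <- lengths * 1000 / 2
  out <- data.frame(
    fibril_id = seq_len(n_fibrils),
    length_um = lengths,
    n_bundles = n_bundles,
    x1 = cx - half * cos(theta), y1 = cy - half * sin(theta),
    x2 = cx + half * cos(theta), y2 = cy + half * sin(theta)
  )
  class(out) <- c("fibril_field", "data.frame")
  out
}

#' Simulate binding and dissociation events on a fibril field
#'
#' Generates one synthetic binding movie.  Per fibril, labeled-molecule
#' arrivals are Poisson with rate `kon_total x n_bundles x enzyme_conc x
#' length` (s^-1), thinned by `labeling_ratio` (unlabeled molecules are
#' invisible), homogeneous in time.  Each event is fast-mode with probability
#' `frac_fast`; its true dwell is exponential with the mode's dissociation
#' rate, and an independent exponential photobleaching clock competes with
#' dissociation.  Events still bound at the end of the movie are censored
#' (`end_cause = "movie_end"` with `t_end = duration`).
#'
#' @param truth a [ground_truth()] object.
#' @param field a [make_fibril_field()] data.frame.
#' @param cond an [imaging_conditions()] object.
#' @param seed integer seed.
#' @return a data.frame of class `event_table` with columns `fibril_id`,
#'   `molecule_id`, `t_bind`, `t_end`, `end_cause` (one of `dissociation`,
#'   `bleach`, `movie_end`) and `mode` (ground-truth `fast`/`slow`).
#' @export
simulate_binding <- function(truth, field, cond, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cond, "imaging_conditions"))
  field <- as_fibril_field(field)
  set.seed(seed)
  rates <- truth$kon_total * field$n_bundles * cond$enzyme_conc * field$length_um
  n_arr <- stats::rpois(nrow(field), rates * cond$duration)
  fib_id <- rep(field$fibril_id, n_arr)
  n <- length(fib_id)
  if (n > 0 && cond$labeling_ratio < 1) {
    keep <- stats::runif(n) < cond$labeling_ratio
    fib_id <- fib_id[keep]
    n <- length(fib_id)
  }
  if (n == 0L) {
    out <- data.frame(fibril_id = integer(), molecule_id = integer(),
                      t_bind = numeric(), t_end = numeric(),
                      end_cause = character(), mode = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("event_table", "data.frame")
    return(out)
  }
  t_bind <- stats::runif(n, 0, cond$duration)
  mode <- ifelse(stats::runif(n) < truth$frac_fast, "fast", "slow")
  dwell <- stats::rexp(n, ifelse(mode == "fast", truth$koff_fast, truth$koff_slow))
  bleach <- if (cond$bleach_rate > 0) stats::rexp(n, cond$bleach_rate) else rep(Inf, n)
  t_off <- pmin(dwell, bleach)
  end_cause <- ifelse(t_bind + t_off >= cond$duration, "movie_end",
                      ifelse(dwell <= bleach, "dissociation", "bleach"))
  t_end <- pmin(t_bind + t_off, cond$duration)
  ord <- order(fib_id, t_bind)
  out <- data.frame(fibril_id = fib_id[ord], molecule_id = seq_len(n),
                    t_bind = t_bind[ord], t_end = t_end[ord],
                    end_cause = end_cause[ord], mode = mode[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Simulate localized trajectories of moving molecules
#'
#' Generates `n_tracks` tracks sampled at the movie frame rate.  A fraction
#' `frac_processive` of tracks moves processively: at constant speed `v_proc`
#' along the axis of a randomly chosen fibril, for a run time drawn from an
#' exponential distribution with mean `tau_move`.  The remaining tracks
#' perform an unbiased 2-D random walk whose per-frame step SD is set, per
#' track, so that the expected first-to-last displacement rate equals
#' `v_diff` (fast surface diffusion appears in first-to-last analysis as a
#' fast apparent rate).  Every sampled position receives independent Gaussian
#' localization noise.  Run times are discretized to the frame grid with a
#' minimum of two frames (a shorter event is not a track).
#'
#' @inheritParams simulate_binding
#' @param n_tracks number of tracks (>= 1).
#' @param frac_processive fraction of tracks that are processive, in [0, 1].
#' @param tau_move_diffusive mean run time of diffusive tracks, s (default 2).
#' @return a data.frame of class `trajectory_table` with columns `track_id`,
#'   `frame`, `t`, `x`, `y`, `truth_state` (`processive`, `diffusive`, or
#'   `static` when the relevant true speed is zero).
#' @export
simulate_trajectories <- function(truth, field, cond, n_tracks,
                                  frac_processive, seed = 1L,
                                  tau_move_diffusive = 2) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cond, "imaging_conditions"))
  field <- as_fibril_field(field)
  check_count(n_tracks, "n_tracks")
  check_fraction(frac_processive, "frac_processive")
  check_positive(tau_move_diffusive, "tau_move_diffusive")
  set.seed(seed)
  dt <- 1 / cond$frame_rate
  pieces <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    proc <- stats::runif(1) < frac_processive
    fi <- field[sample.int(nrow(field), 1L), ]
    axis <- c(fi$x2 - fi$x1, fi$y2 - fi$y1)
    axis <- axis / sqrt(sum(axis^2))
    s0 <- stats::runif(1)
    start <- c(fi$x1, fi$y1) + s0 * c(fi$x2 - fi$x1, fi$y2 - fi$y1)
    tau <- if (proc) truth$tau_move else tau_move_diffusive
    run <- stats::rexp(1, 1 / tau)
    nf <- max(2L, floor(run / dt) + 1L)
    tt <- (seq_len(nf) - 1) * dt
    if (proc) {
      dir <- sample(c(-1, 1), 1L)
      x <- start[1] + dir * truth$v_proc * tt * axis[1]
      y <- start[2] + dir * truth$v_proc * tt * axis[2]
      state <- if (truth$v_proc > 0) "processive" else "static"
    } else {
      nstep <- nf - 1L
      sigma <- truth$v_diff * dt * sqrt(2 * nstep / pi)
      x <- start[1] + c(0, cumsum(stats::rnorm(nstep, 0, sigma)))
      y <- start[2] + c(0, cumsum(stats::rnorm(nstep, 0, sigma)))
      state <- if (truth$v_diff > 0) "diffusive" else "static"
    }
    x <- x + stats::rnorm(nf, 0, cond$loc_precision_x)
    y <- y + stats::rnorm(nf, 0, cond$loc_precision_y)
    pieces[[i]] <- data.frame(track_id = i, frame = seq_len(nf) - 1L,
                              t = tt, x = x, y = y, truth_state = state,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("trajectory_table", "data.frame")
  out
}

#' Simulate a bulk Michaelis-Menten hydrolysis assay
#'
#' Hydrolysis rate at each substrate concentration is
#' `kcat * S / (Km + S)` plus Gaussian noise, clipped at zero.
#'
#' @inheritParams simulate_binding
#' @param substrate_concs substrate concentrations, mg ml^-1 (all > 0).
#' @param noise_sd SD of the Gaussian measurement noise, s^-1 (>= 0).
#' @param n_reps replicates per concentration (>= 1).
#' @return a data.frame with columns `conc` (mg ml^-1) and `rate` (s^-1).
#' @export
simulate_mm <- function(truth, substrate_concs = c(0.3, 1, 3, 5),
                        noise_sd = 0, n_reps = 1L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(substrate_concs) == 0L)
    abort_invalid("`substrate_concs` must not be empty")
  if (any(!is.finite(substrate_concs)) || any(substrate_concs <= 0))
    abort_invalid("`substrate_concs` must all be positive")
  check_nonneg(noise_sd, "noise_sd")
  check_count(n_reps, "n_reps")
  set.seed(seed)
  conc <- rep(substrate_concs, each = n_reps)
  rate <- truth$kcat * conc / (truth$Km + conc)
  if (noise_sd > 0) rate <- pmax(rate + stats::rnorm(length(conc), 0, noise_sd), 0)
  data.frame(conc = conc, rate = rate)
}

as_fibril_field <- function(field) {
  need <- c("fibril_id", "length_um", "n_bundles", "x1", "y1", "x2", "y2")
  if (!is.data.frame(field) || !all(need %in% names(field)))
    abort_invalid("`field` must be a fibril_field data.frame (see make_fibril_field)")
  if (any(field$length_um <= 0)) abort_invalid("fibril lengths must be positive")
  field
}
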