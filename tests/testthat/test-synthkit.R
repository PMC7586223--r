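test_that("zero-variance fibril field is exact, consistent and seed-deterministic", {
  f <- make_fibril_field(1, length_mean = 5, length_sd = 0,
                         bundle_weights = c("1" = 1), seed = 0)
  expect_equal(nrow(f), 1L)
  expect_equal(f$length_um, 5)
  expect_equal(f$n_bundles, 1L)
  seg <- sqrt((f$x2 - f$x1)^2 + (f$y2 - f$y1)^2)
  expect_lt(abs(seg - 5000) / 5000, 1e-3)

  f1 <- make_fibril_field(50, 5, 1, c("1" = 0.5, "2" = 0.5), seed = 7)
  f2 <- make_fibril_field(50, 5, 1, c("1" = 0.5, "2" = 0.5), seed = 7)
  expect_identical(f1, f2)
  seg <- sqrt((f1$x2 - f1$x1)^2 + (f1$y2 - f1$y1)^2)
  expect_true(all(abs(seg - f1$length_um * 1000) / (f1$length_um * 1000) < 1e-3))

  expect_error(make_fibril_field(0, 5), class = "cbhkin_invalid_parameter")
  expect_error(make_fibril_field(5, -1), class = "cbhkin_invalid_parameter")
  expect_error(make_fibril_field(5, 5, bundle_weights = c("1" = 0.6)),
               class = "cbhkin_invalid_parameter")
})

test_that("bundle counts follow the requested weights (binomial oracle)", {
  f <- make_fibril_field(1000, 5, 1, c("1" = 0.5, "2" = 0.5), seed = 1)
  p_hat <- mean(f$n_bundles == 1L)
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("binding arrivals are Poisson with rate kon x bundles x conc x length", {
  truth <- cfcel6b_truth("Intact")
  cond <- imaging_conditions(frame_rate = 5, duration = 400, bleach_rate = 0,
                             enzyme_conc = 50e-12, labeling_ratio = 1)
  field <- make_fibril_field(1, 5, 0, c("1" = 1), seed = 3)
  lambda <- 4.3e8 * 50e-12 * 5 * 400  # 43 expected events
  # one movie: count within 3 sqrt(lambda)
  ev <- simulate_binding(truth, field, cond, seed = 11)
  expect_lt(abs(nrow(ev) - lambda), 3 * sqrt(lambda))
  # 200 replicate movies: mean within 3 SE, including labeling-ratio thinning
  cond_half <- imaging_conditions(frame_rate = 5, duration = 400,
                                  bleach_rate = 0, enzyme_conc = 50e-12,
                                  labeling_ratio = 0.5)
  counts <- vapply(1:200, function(s)
    nrow(simulate_binding(truth, field, cond_half, seed = 1000 + s)),
    numeric(1))
  mu <- lambda * 0.5
  se <- sqrt(mu / 200)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  # vanishing concentration: no events
  cond0 <- imaging_conditions(frame_rate = 5, duration = 400,
                              enzyme_conc = 1e-30)
  expect_equal(nrow(simulate_binding(truth, field, cond0, seed = 1)), 0L)
  # determinism
  expect_identical(simulate_binding(truth, field, cond, seed = 5),
                   simulate_binding(truth, field, cond, seed = 5))
})

test_that("single-mode dwells are exponential and end causes are consistent", {
  truth <- ground_truth(kon_total = 4.3e8, frac_fast = 0, koff_fast = 1,
                        koff_slow = 0.3)
  cond <- imaging_conditions(frame_rate = 5, duration = 2000, bleach_rate = 0,
                             enzyme_conc = 2e-10)
  field <- make_fibril_field(40, 5, 0, c("1" = 1), seed = 2)
  ev <- simulate_binding(truth, field, cond, seed = 21)
  expect_gt(nrow(ev), 1e4)
  expect_true(all(ev$end_cause %in% c("dissociation", "movie_end")))
  expect_true(all(ev$mode == "slow"))
  expect_true(all(ev$t_bind >= 0 & ev$t_bind < ev$t_end & ev$t_end <= 2000))
  expect_true(all(ev$t_end[ev$end_cause == "movie_end"] == 2000))
  d <- ev$t_end[ev$end_cause == "dissociation"] - ev$t_bind[ev$end_cause == "dissociation"]
  expect_lt(abs(mean(d) - 1 / 0.3), 3 * stats::sd(d) / sqrt(length(d)))
})

test_that("photobleaching competes with dissociation (survival-rate oracle)", {
  koff <- 0.2; bleach <- 0.053
  truth <- ground_truth(kon_total = 4.3e8, frac_fast = 0, koff_fast = 1,
                        koff_slow = koff)
  cond <- imaging_conditions(frame_rate = 5, duration = 1000,
                             bleach_rate = bleach, enzyme_conc = 2e-10)
  field <- make_fibril_field(30, 5, 0, c("1" = 1), seed = 4)
  ev <- simulate_binding(truth, field, cond, seed = 31)
  expect_true(any(ev$end_cause == "bleach"))
  fit <- fit_exponential(collect_dwells(ev, cond), n_components = 1)
  expect_lt(abs(fit$rates - (koff + bleach)) / (koff + bleach), 0.05)
  # and the bleach fraction among completed events matches the risk ratio
  done <- ev$end_cause != "movie_end"
  p_bleach <- mean(ev$end_cause[done] == "bleach")
  expect_lt(abs(p_bleach - bleach / (koff + bleach)), 0.03)
})

test_that("observed fast fraction matches the quadrature oracle", {
  truth <- cfcel6b_truth("Intact")
  cond <- imaging_conditions(frame_rate = 5, duration = 400,
                             bleach_rate = 0.053, enzyme_conc = 2e-10)
  field <- make_fibril_field(60, 5, 0, c("1" = 1), seed = 5)
  ev <- simulate_binding(truth, field, cond, seed = 41)
  diss <- ev$end_cause == "dissociation"
  observed <- mean(ev$mode[diss] == "fast")
  predicted <- expected_fast_fraction(truth$frac_fast, truth$koff_fast,
                                      truth$koff_slow, 0.053, 400)
  n <- sum(diss)
  expect_lt(abs(observed - predicted), 3 * sqrt(predicted * (1 - predicted) / n))
})

test_that("trajectory kinematics: processive speed, sampling grid, mixtures", {
  truth <- ground_truth(kon_total = 4.3e8, frac_fast = 0.33, koff_fast = 0.85,
                        koff_slow = 0.086, v_proc = 10, tau_move = 5)
  cond <- imaging_conditions(frame_rate = 1, duration = 400,
                             loc_precision_x = 0, loc_precision_y = 0,
                             enzyme_conc = 5e-11)
  field <- make_fibril_field(10, 5, 0, c("1" = 1), seed = 6)
  traj <- simulate_trajectories(truth, field, cond, n_tracks = 40,
                                frac_processive = 1, seed = 51)
  expect_true(all(traj$truth_state == "processive"))
  for (p in split(traj, traj$track_id)) {
    expect_true(all(diff(p$frame) == 1L))
    expect_equal(p$t, p$frame / 1, tolerance = 1e-12)
    net <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
    span <- p$t[nrow(p)] - p$t[1]
    expect_equal(net / span, 10, tolerance = 1e-9)  # noise-free kinematics
  }
  # degenerate mixture: no processive tracks
  traj0 <- simulate_trajectories(truth, field, cond, n_tracks = 30,
                                 frac_processive = 0, seed = 52)
  expect_false(any(traj0$truth_state == "processive"))
  expect_error(simulate_trajectories(truth, field, cond, 0, 1),
               class = "cbhkin_invalid_parameter")
  expect_identical(
    simulate_trajectories(truth, field, cond, 20, 0.5, seed = 3),
    simulate_trajectories(truth, field, cond, 20, 0.5, seed = 3))
})

test_that("static tracks reproduce the localization precision (Gaussian SD oracle)", {
  truth <- ground_truth(kon_total = 4.3e8, frac_fast = 0.33, koff_fast = 0.85,
                        koff_slow = 0.086, v_proc = 1, v_diff = 0)
  cond <- imaging_conditions(frame_rate = 1, duration = 400,
                             loc_precision_x = 4.5, loc_precision_y = 4.6,
                             enzyme_conc = 5e-11)
  field <- make_fibril_field(5, 5, 0, c("1" = 1), seed = 8)
  traj <- simulate_trajectories(truth, field, cond, n_tracks = 400,
                                frac_processive = 0, seed = 61,
                                tau_move_diffusive = 5)
  expect_true(all(traj$truth_state == "static"))
  res_x <- unlist(lapply(split(traj$x, traj$track_id), function(v) v - mean(v)))
  res_y <- unlist(lapply(split(traj$y, traj$track_id), function(v) v - mean(v)))
  expect_gt(length(res_x), 1000)
  expect_lt(abs(stats::sd(res_x) - 4.5) / 4.5, 0.1)
  expect_lt(abs(stats::sd(res_y) - 4.6) / 4.6, 0.1)
})

test_that("diffusive first-to-last displacement rate targets v_diff", {
  truth <- ground_truth(kon_total = 4.3e8, frac_fast = 0.33, koff_fast = 0.85,
                        koff_slow = 0.086, v_diff = 30)
  cond <- imaging_conditions(frame_rate = 1, duration = 400,
                             loc_precision_x = 0, loc_precision_y = 0,
                             enzyme_conc = 5e-11)
  field <- make_fibril_field(5, 5, 0, c("1" = 1), seed = 9)
  traj <- simulate_trajectories(truth, field, cond, n_tracks = 800,
                                frac_processive = 0, seed = 71,
                                tau_move_diffusive = 6)
  rates <- vapply(split(traj, traj$track_id), function(p) {
    net <- sqrt((p$x[nrow(p)] - p$x[1])^2 + (p$y[nrow(p)] - p$y[1])^2)
    net / (p$t[nrow(p)] - p$t[1])
  }, numeric(1))
  se <- stats::sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 30), 3 * se)
})

test_that("bulk Michaelis-Menten simulation obeys the rate law", {
  truth <- cfcel6b_truth("Intact")  # kcat 2.4, Km 0.51
  expect_equal(simulate_mm(truth, substrate_concs = 0.51)$rate, 2.4 / 2)
  expect_lt(abs(simulate_mm(truth, substrate_concs = 510)$rate - 2.4) / 2.4,
            1e-3)
  expect_equal(simulate_mm(truth, substrate_concs = 1.0)$rate,
               2.4 * 1.0 / (0.51 + 1.0), tolerance = 1e-12)
  expect_error(simulate_mm(truth, substrate_concs = numeric(0)),
               class = "cbhkin_invalid_parameter")
  noisy <- simulate_mm(truth, noise_sd = 5, n_reps = 50, seed = 2)
  expect_true(all(noisy$rate >= 0))  # clipped at zero
})

test_that("tables round-trip through their CSV dialects", {
  truth <- cfcel6b_truth("Intact")
  cond <- imaging_conditions(enzyme_conc = 5e-11, bleach_rate = 0)
  field <- make_fibril_field(5, 5, 1, c("1" = 1), seed = 12)
  ev <- simulate_binding(truth, field, cond, seed = 13)
  traj <- simulate_trajectories(truth, field,
                                imaging_conditions(frame_rate = 1,
                                                   enzyme_conc = 5e-11),
                                n_tracks = 3, frac_processive = 1, seed = 14)
  tmp <- withr::local_tempdir()
  pf <- file.path(tmp, "field.csv")
  pe <- file.path(tmp, "events.csv")
  pt <- file.path(tmp, "traj.csv")
  write_fibril_field(field, pf)
  write_event_table(ev, pe)
  write_trajectory_table(traj, pt)
  expect_identical(readLines(pe, n = 1),
                   "fibril_id,molecule_id,t_bind,t_end,end_cause,mode")
  expect_identical(readLines(pt, n = 1), "track_id,frame,t,x,y,truth_state")
  expect_identical(readLines(pf, n = 1),
                   "fibril_id,length_um,n_bundles,x1,y1,x2,y2")
  f2 <- read_fibril_field(pf)
  e2 <- read_event_table(pe)
  t2 <- read_trajectory_table(pt)
  expect_equal(f2$length_um, field$length_um, tolerance = 1e-12)
  expect_equal(e2$t_bind, ev$t_bind, tolerance = 1e-12)
  expect_equal(t2$x, traj$x, tolerance = 1e-12)
})
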