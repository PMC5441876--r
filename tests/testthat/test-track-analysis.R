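test_that("kinematics: straight motion has zero angular velocity", {
  kin <- compute_kinematics(straight_trajectory())
  expect_equal(max(abs(kin$omega_frame), na.rm = TRUE), 0)
  expect_equal(kin$speed, rep(20, 60), tolerance = 1e-9)
})

test_that("kinematics: circular motion recovers the angular rate on interior frames", {
  Omega <- 2.5
  kin <- compute_kinematics(circular_trajectory(Omega = Omega))
  interior <- 3:85
  expect_equal(kin$omega[interior], rep(Omega, length(interior)),
               tolerance = 0.01)
})

test_that("kinematics agrees with a brute-force per-frame angle computation", {
  gen <- gen_run_tumble_trajectory(motility_gen_params(duration = 10, seed = 21))
  d <- gen$trajectory
  kin <- compute_kinematics(d)
  n <- nrow(d)
  dt <- 1 / 30
  # independent re-implementation: explicit loops, angle via acos with
  # clamped cosine
  vx <- vy <- numeric(n)
  for (k in 2:(n - 1)) {
    vx[k] <- (d$x_um[k + 1] - d$x_um[k - 1]) / (2 * dt)
    vy[k] <- (d$y_um[k + 1] - d$y_um[k - 1]) / (2 * dt)
  }
  vx[1] <- (d$x_um[2] - d$x_um[1]) / dt; vy[1] <- (d$y_um[2] - d$y_um[1]) / dt
  vx[n] <- (d$x_um[n] - d$x_um[n - 1]) / dt
  vy[n] <- (d$y_um[n] - d$y_um[n - 1]) / dt
  om <- rep(NA_real_, n)
  for (k in 1:(n - 1)) {
    co <- (vx[k] * vx[k + 1] + vy[k] * vy[k + 1]) /
      (sqrt(vx[k]^2 + vy[k]^2) * sqrt(vx[k + 1]^2 + vy[k + 1]^2))
    om[k] <- acos(pmin(pmax(co, -1), 1))
  }
  expect_equal(kin$omega_frame[1:(n - 1)], om[1:(n - 1)], tolerance = 1e-12)
})

test_that("non-uniform timestamps are rejected", {
  d <- straight_trajectory()
  d$time_s[10] <- d$time_s[10] + 0.01
  expect_error(compute_kinematics(d), "non-uniform")
})

test_that("straight trajectory segments as one run with zero tumble bias", {
  seg <- segment_runs_tumbles(straight_trajectory(n = 120))
  expect_equal(nrow(seg$runs), 1)
  expect_equal(nrow(seg$tumbles), 0)
  st <- motility_stats(list(seg))
  expect_equal(st$tumble_bias, 0)
  expect_equal(st$tumble_frequency, 0)
})

test_that("classifier recovers programmed tumbles and the threshold iteration converges", {
  # low-noise generator cell with a known number of tumbles
  p <- motility_gen_params(mean_run_duration = 1.2, mean_tumble_duration = 0.15,
                           centroid_noise_sd = 0.05, run_speed_sd = 0,
                           duration = 30, chamber_radius = 1e6, seed = 31)
  gen <- gen_run_tumble_trajectory(p)
  n_true <- sum(gen$labels$events$type == "tumble")
  seg <- segment_runs_tumbles(gen$trajectory)
  match <- match_tumble_events(seg, gen$labels)
  expect_lte(abs(match$n_detected - n_true), 2)
  expect_gte(match$n_matched, n_true - 2)
  # threshold trace converged
  expect_true(seg$converged)
  tr <- seg$alpha_trace
  expect_lt(abs(tr[length(tr)] - tr[length(tr) - 1]) / tr[length(tr)], 0.05)
})

test_that("labels partition frames and per-cell fractions sum to one", {
  for (seed in c(1, 2, 3)) {
    gen <- gen_run_tumble_trajectory(
      motility_gen_params(duration = 20, chamber_radius = 60, seed = seed))
    seg <- segment_runs_tumbles(gen$trajectory)
    n <- length(seg$labels)
    counts <- table(factor(seg$labels,
                           c("run", "tumble", "boundary", "unclassified")))
    expect_equal(sum(counts), n)
    expect_true(all(seg$runs$end - seg$runs$start + 1 >= 4))
  }
})

test_that("pooled statistics: two cells with equal observation time average their biases", {
  mk <- function(bias, id) {
    # synthetic segmentation stub: 3000 frames at 30 fps, tumbling
    # split into short 3-frame events so the cell passes the
    # sustained-tumbler exclusion
    n <- 3000
    nt <- round(bias * n)
    n_ev <- nt %/% 3
    labels <- c(rep("tumble", nt), rep("run", n - nt))
    structure(list(labels = labels,
                   runs = data.frame(start = nt + 1, end = n,
                                     duration_s = (n - nt) / 30,
                                     speed_um_s = 20,
                                     arc_length_um = 20 * (n - nt) / 30,
                                     boundary_interrupted = FALSE),
                   tumbles = data.frame(start = 3 * seq_len(n_ev) - 2,
                                        end = 3 * seq_len(n_ev),
                                        duration_s = rep(0.1, n_ev)),
                   alpha_f = 1, alpha_f_rad_s = 30, alpha_trace = c(1, 1),
                   converged = TRUE, flagged = FALSE, frame_rate = 30,
                   cell_id = id),
              class = "segmentation")
  }
  st <- motility_stats(list(mk(0.1, "a"), mk(0.3, "b")))
  expect_equal(st$tumble_bias, 0.2, tolerance = 1e-3)
})

test_that("sustained tumblers are excluded and empty ensembles error", {
  p <- motility_gen_params(mean_run_duration = 0.8, mean_tumble_duration = 0.9,
                           duration = 30, chamber_radius = 1e6, seed = 77)
  gen <- gen_run_tumble_trajectory(p)
  seg_bad <- segment_runs_tumbles(gen$trajectory)
  expect_error(motility_stats(list(seg_bad)), "excluded")
})

test_that("pooled run-duration mean tracks the generator over an ensemble", {
  ens <- gen_ensemble(motility_gen_params(mean_run_duration = 0.66,
                                          run_speed_mean = 18.7,
                                          centroid_noise_sd = 0.05,
                                          duration = 60, seed = 500), 30)
  segs <- lapply(ens, function(g) segment_runs_tumbles(g$trajectory))
  st <- motility_stats(segs)
  truth <- mean(unlist(lapply(ens, function(g) {
    ev <- g$labels$events
    r <- ev[ev$type == "run", ]
    r$t_end - r$t_start
  })))
  expect_lt(abs(st$mean_run_s / truth - 1), 0.15)
})

test_that("permuting cell order changes no pooled statistic", {
  ens <- gen_ensemble(motility_gen_params(duration = 20, seed = 900), 8)
  segs <- lapply(ens, function(g) segment_runs_tumbles(g$trajectory))
  s1 <- motility_stats(segs)
  s2 <- motility_stats(rev(segs))
  for (f in c("mean_run_s", "mean_tumble_s", "tumble_bias", "tumble_frequency")) {
    expect_equal(s1[[f]], s2[[f]])
  }
  expect_equal(sort(s1$run_durations), sort(s2$run_durations))
})

test_that("ccdf follows the counting definition and is monotone", {
  cc <- ccdf(c(1, 2, 3), tau = c(0, 1, 2.5, 3), n_boot = 0)
  expect_equal(cc$ccdf, c(1, 2 / 3, 1 / 3, 0))
  expect_error(ccdf(c(1, -2)), "negative")
  # monotone non-increasing for arbitrary input
  set.seed(4)
  cc2 <- ccdf(rexp(500, 2), n_boot = 50, seed = 5)
  expect_true(all(diff(cc2$ccdf) <= 0))
  expect_true(all(cc2$lo <= cc2$ccdf + 1e-12 & cc2$ccdf <= cc2$hi + 1e-12))
})

test_that("ccdf of a large exponential sample matches the closed form", {
  set.seed(8)
  d <- rexp(1e4, 1 / 0.6)
  cc <- ccdf(d, tau = seq(0, 3, by = 0.05), n_boot = 0)
  expect_lt(max(abs(cc$ccdf - exp(-cc$tau / 0.6))), 0.02)
})
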