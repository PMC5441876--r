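test_that("background subtraction zeroes constant stacks and preserves later rings", {
  p <- colony_image_gen_params(true_front_speed = 0, ring_amplitude = 0,
                               noise_sd = 0, n_frames = 8, nx = 64, ny = 64)
  st <- gen_colony_image_series(p)
  bs <- background_subtract(st)
  expect_equal(max(vapply(bs$frames, max, numeric(1))), 0)
  # ring appearing after the background window survives subtraction
  p2 <- colony_image_gen_params(true_front_speed = 0.25, r0 = 0.05,
                                ring_amplitude = 100, background_level = 30,
                                noise_sd = 0.5, frame_interval = 10,
                                n_frames = 24, nx = 128, ny = 128,
                                pixels_per_cm = 50, seed = 2)
  st2 <- gen_colony_image_series(p2)
  bs2 <- background_subtract(st2)
  late <- bs2$frames[[24]]
  expect_gt(max(late), 90)  # ring amplitude preserved within noise
  expect_lt(mean(bs2$frames[[2]]), 1)  # background frames ~ 0
  expect_error(background_subtract(st2, n_background = 30), "frames")
})

test_that("background uses the median: one outlier background frame has no effect", {
  bg <- matrix(20, 64, 64); bg[30:34, 30:34] <- 60  # static blob
  frames <- c(replicate(6, bg, simplify = FALSE),
              list(bg + 40 * matrix(runif(64 * 64) < 0.1, 64, 64)))
  st <- image_stack(frames, timestamps_min = seq(0, 60, by = 10),
                    pixels_per_cm = 50)
  st_out <- st
  st_out$frames[[2]] <- st_out$frames[[2]] + 1000  # corrupted frame
  b1 <- background_subtract(st, 6)
  b2 <- background_subtract(st_out, 6)
  expect_identical(b1$frames[[7]], b2$frames[[7]])
  # a mean projection would have been shifted by the outlier
  expect_equal(max(b1$frames[[3]]), 0)
})

test_that("Hough center finding is accurate and translation-equivariant", {
  p <- colony_image_gen_params(true_front_speed = 0, r0 = 0.8,
                               center = c(256, 300), nx = 512, ny = 512,
                               pixels_per_cm = 100, noise_sd = 1,
                               n_frames = 1, seed = 4)
  st <- gen_colony_image_series(p)
  res <- find_center(st$frames[[1]])
  expect_lte(abs(res$center[["cx"]] - 256), 2)
  expect_lte(abs(res$center[["cy"]] - 300), 2)
  # translation by (dx, dy) moves the center accordingly
  p2 <- p; p2$center <- c(236, 320)
  st2 <- gen_colony_image_series(p2)
  res2 <- find_center(st2$frames[[1]])
  expect_lte(abs((res2$center[["cx"]] - res$center[["cx"]]) - (-20)), 2)
  expect_lte(abs((res2$center[["cy"]] - res$center[["cy"]]) - 20), 2)
  # blank frame: no colony
  expect_error(find_center(matrix(0, 128, 128)), "no colony")
})

test_that("front radius: noiseless ring found in both modes, outermost ring wins", {
  p <- colony_image_gen_params(true_front_speed = 0, r0 = 1.5,
                               nx = 400, ny = 400, pixels_per_cm = 100,
                               noise_sd = 0, n_frames = 1)
  st <- gen_colony_image_series(p)
  ctr <- c(200.5, 200.5)
  r_rich <- front_radius(st$frames[[1]], ctr, 100, mode = "rich")
  expect_lt(abs(r_rich - 1.5), 0.011)
  r_min <- front_radius(st$frames[[1]], ctr, 100, mode = "minimal")
  expect_lt(abs(r_min - 1.5), 0.025)
  # two concentric rings, inner brighter: outermost returned
  xs <- matrix(rep(1:400, each = 400), 400, 400)
  ys <- matrix(rep(1:400, times = 400), 400, 400)
  rr <- sqrt((xs - 200.5)^2 + (ys - 200.5)^2) / 100
  two <- 200 * exp(-(rr - 0.8)^2 / 0.08^2) + 80 * exp(-(rr - 1.6)^2 / 0.08^2)
  expect_lt(abs(front_radius(two, ctr, 100, mode = "rich") - 1.6), 0.011)
})

test_that("low-SNR minimal-medium-like stacks still yield mostly accurate radii", {
  p <- colony_image_gen_params(true_front_speed = 0.1, r0 = 0.6,
                               ring_amplitude = 10, background_level = 20,
                               noise_sd = 5,  # SNR 2
                               frame_interval = 60, n_frames = 10,
                               nx = 256, ny = 256, pixels_per_cm = 60,
                               seed = 6)
  st <- gen_colony_image_series(p)
  bs <- background_subtract(st, 2)
  hits <- 0
  for (k in 3:10) {
    r <- front_radius(bs$frames[[k]], c(128.5, 128.5), 60, mode = "minimal")
    if (is.finite(r) && abs(r - st$truth$radius_cm[k]) * 60 <= 3) hits <- hits + 1
  }
  expect_gte(hits / 8, 0.9)
})

test_that("front speed recovery: programmed speeds recovered within 2% at SNR >= 5", {
  for (speed in c(0.1, 0.3, 0.6)) {
    # frame interval scaled so the ring sweeps the same radial span
    p <- colony_image_gen_params(true_front_speed = speed, r0 = 0.3,
                                 ring_amplitude = 50, background_level = 20,
                                 noise_sd = 10,  # SNR 5
                                 frame_interval = round(3 / speed / 16 * 60),
                                 n_frames = 16, nx = 420, ny = 420,
                                 pixels_per_cm = 55, seed = 7)
    st <- gen_colony_image_series(p)
    tr <- front_trace_from_stack(st, mode = "rich", n_background = 2,
                                 center = c(210.5, 210.5))
    fit <- front_speed(tr, window = 0.8)
    expect_lt(abs(fit$s / speed - 1), 0.02, label = sprintf("speed %g", speed))
  }
})

test_that("front speed degenerate cases: zero speed and exact linear traces", {
  tr0 <- data.frame(time_min = seq(0, 120, by = 10), radius_cm = 1.2)
  expect_equal(front_speed(tr0)$s, 0)
  trl <- data.frame(time_min = seq(0, 300, by = 15),
                    radius_cm = 0.5 + 0.3 * seq(0, 300, by = 15) / 60)
  fit <- front_speed(trl, window = 1)
  expect_equal(fit$s, 0.3, tolerance = 1e-12)
  expect_equal(fit$se, 0, tolerance = 1e-10)
})

test_that("calibration round-trips pixels to cm and back", {
  px <- c(10, 118, 731)
  cm <- px / 118
  expect_equal(cm * 118, px, tolerance = 1e-12)
})
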