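# Generators for labeled synthetic inputs: run-and-tumble trajectories,
# colony image stacks, and phenotype populations. Every downstream stage
# of the pipeline can be tested against the ground truth these carry.

#' Evaluate a function with a private, restored RNG state
#' @noRd
local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Parameters for the run-and-tumble trajectory generator
#'
#' Defaults emulate the founder strain swimming in rich medium inside a
#' 200-um-diameter circular chamber imaged at 30 frames/s: mean run
#' duration 0.66 s at 18.7 +/- 7.1 um/s, mean tumble duration 0.18 s.
#' Run and tumble durations are exponential (only their means are
#' constrained by measurement); tumble turn angles follow a wrapped
#' normal with configurable mean and spread.
#'
#' @param mean_run_duration mean run duration, s.
#' @param mean_tumble_duration mean tumble duration, s. `0` gives
#'   uninterrupted straight swimming.
#' @param run_speed_mean,run_speed_sd per-run speed distribution
#'   (normal, truncated at 0), um/s.
#' @param turn_angle_mean,turn_angle_sd tumble reorientation angle
#'   (wrapped normal, random sign), degrees.
#' @param frame_rate sampling rate, frames/s.
#' @param centroid_noise_sd additive centroid localization noise, um.
#' @param chamber_radius circular chamber radius, um.
#' @param duration trajectory length, s.
#' @param seed integer seed; every draw of the generator derives from it.
#' @return a `motility_gen_params` object.
#' @export
motility_gen_params <- function(mean_run_duration = 0.66,
                                mean_tumble_duration = 0.18,
                                run_speed_mean = 18.7, run_speed_sd = 7.1,
                                turn_angle_mean = 68, turn_angle_sd = 36,
                                frame_rate = 30, centroid_noise_sd = 0.1,
                                chamber_radius = 100, duration = 300,
                                seed = 1) {
  stopifnot(mean_run_duration > 0, mean_tumble_duration >= 0,
            run_speed_mean > 0, run_speed_sd >= 0,
            frame_rate > 0, centroid_noise_sd >= 0,
            chamber_radius > 0, duration > 0)
  if (duration * frame_rate < 2) stop("duration shorter than 2 frames")
  structure(as.list(environment()), class = "motility_gen_params")
}

#' Generate one run-and-tumble trajectory with ground-truth labels
#'
#' Simulates alternating run and tumble intervals in continuous time
#' (exponential durations), samples the centroid at the frame rate, and
#' returns both the trajectory and the ground truth that downstream
#' classifiers are scored against. During a run the cell moves along a
#' fixed heading at a per-run speed; during a tumble the centroid stays
#' in place (up to noise) and the heading is redrawn by adding a
#' wrapped-normal turn angle of random sign. The cell reflects
#' specularly off the circular chamber wall; frames within
#' `boundary_margin` of the wall are flagged so boundary exclusion can
#' be tested.
#'
#' @param params a [motility_gen_params()] object.
#' @param cell_id identifier stored in the trajectory.
#' @param boundary_margin distance from the wall (um) within which a
#'   frame is flagged `at_boundary`.
#' @return list with `trajectory` (a `swim_trajectory`: data frame
#'   `frame`, `time_s`, `x_um`, `y_um`, `cell_id`, plus `frame_rate`
#'   and `chamber_radius` attributes) and `labels` (a
#'   `ground_truth_labels`: per-frame `state` run/tumble,
#'   `at_boundary` flag, and an `events` data frame with
#'   `type`, `t_start`, `t_end`, `frame_start`, `frame_end`,
#'   `turn_angle_deg`).
#' @export
gen_run_tumble_trajectory <- function(params, cell_id = "cell1",
                                      boundary_margin = 5) {
  stopifnot(inherits(params, "motility_gen_params"))
  p <- params
  n_frames <- floor(p$duration * p$frame_rate) + 1L
  if (n_frames < 2) stop("duration shorter than 2 frames")

  local_seed(p$seed, {
    # 1. event sequence in continuous time (run first)
    t_ev <- 0; types <- character(); starts <- numeric(); ends <- numeric()
    turns <- numeric()
    while (t_ev < p$duration) {
      run_d <- if (p$mean_tumble_duration == 0 && length(types) == 0)
        Inf else stats::rexp(1, 1 / p$mean_run_duration)
      types <- c(types, "run"); starts <- c(starts, t_ev)
      t_ev <- t_ev + run_d; ends <- c(ends, t_ev); turns <- c(turns, NA_real_)
      if (t_ev >= p$duration) break
      tum_d <- if (p$mean_tumble_duration > 0)
        stats::rexp(1, 1 / p$mean_tumble_duration) else 0
      if (tum_d > 0) {
        ang <- sample(c(-1, 1), 1) *
          stats::rnorm(1, p$turn_angle_mean, p$turn_angle_sd)
        ang <- ((ang + 180) %% 360) - 180  # wrap to (-180, 180]
        types <- c(types, "tumble"); starts <- c(starts, t_ev)
        t_ev <- t_ev + tum_d; ends <- c(ends, t_ev); turns <- c(turns, ang)
      }
    }
    ends[length(ends)] <- min(ends[length(ends)], p$duration)

    # 2. per-frame state from the event list (right-open intervals)
    tt <- (seq_len(n_frames) - 1L) / p$frame_rate
    ev_idx <- findInterval(tt, starts)
    state <- types[pmax(ev_idx, 1L)]

    # 3. per-run speeds and headings
    n_runs <- sum(types == "run")
    speeds <- pmax(stats::rnorm(n_runs, p$run_speed_mean, p$run_speed_sd), 0)
    heading0 <- stats::runif(1, 0, 2 * pi)

    # 4. frame-by-frame kinematics with specular wall reflection
    x <- numeric(n_frames); y <- numeric(n_frames)
    at_boundary <- logical(n_frames)
    heading <- heading0
    run_no <- cumsum(types == "run")  # event index -> run index
    cur_ev <- max(ev_idx[1], 1L)
    dt <- 1 / p$frame_rate
    for (k in seq_len(n_frames)) {
      ev <- max(ev_idx[k], 1L)
      if (ev != cur_ev) {
        # heading updates take effect when a tumble completes
        for (e in seq(cur_ev + 1L, ev)) {
          if (types[e] == "run" && e > 1 && types[e - 1] == "tumble") {
            heading <- heading + turns[e - 1] * pi / 180
          }
        }
        cur_ev <- ev
      }
      if (k > 1) {
        if (state[k] == "run") {
          v <- speeds[run_no[ev]]
          xn <- x[k - 1] + v * cos(heading) * dt
          yn <- y[k - 1] + v * sin(heading) * dt
          rad <- sqrt(xn^2 + yn^2)
          if (rad > p$chamber_radius) {
            # specular reflection off the circular wall
            nx <- xn / rad; ny <- yn / rad
            dxv <- cos(heading); dyv <- sin(heading)
            dot <- dxv * nx + dyv * ny
            heading <- atan2(dyv - 2 * dot * ny, dxv - 2 * dot * nx)
            xn <- nx * (2 * p$chamber_radius - rad)
            yn <- ny * (2 * p$chamber_radius - rad)
          }
          x[k] <- xn; y[k] <- yn
        } else {
          x[k] <- x[k - 1]; y[k] <- y[k - 1]
        }
      }
      at_boundary[k] <- sqrt(x[k]^2 + y[k]^2) >
        p$chamber_radius - boundary_margin
    }

    xo <- x + stats::rnorm(n_frames, 0, p$centroid_noise_sd)
    yo <- y + stats::rnorm(n_frames, 0, p$centroid_noise_sd)

    traj <- data.frame(frame = seq_len(n_frames) - 1L, time_s = tt,
                       x_um = xo, y_um = yo,
                       cell_id = cell_id, stringsAsFactors = FALSE)
    attr(traj, "frame_rate") <- p$frame_rate
    attr(traj, "chamber_radius") <- p$chamber_radius
    class(traj) <- c("swim_trajectory", "data.frame")

    events <- data.frame(type = types, t_start = starts, t_end = ends,
                         frame_start = findInterval(starts, tt),
                         frame_end = pmin(findInterval(ends - 1e-12, tt),
                                          n_frames) - 1L,
                         turn_angle_deg = c(turns[-1], NA_real_)[
                           seq_along(types)] * NA^0,  # placeholder fixed below
                         stringsAsFactors = FALSE)
    events$turn_angle_deg <- ifelse(types == "tumble", turns, NA_real_)
    events$frame_start <- pmax(events$frame_start - 1L, 0L)
    labels <- structure(list(state = state, at_boundary = at_boundary,
                             events = events, frame_rate = p$frame_rate),
                        class = "ground_truth_labels")
    list(trajectory = traj, labels = labels)
  })
}

#' Generate an ensemble of labeled trajectories
#'
#' @param params a [motility_gen_params()] template; `seed` is advanced
#'   per cell so the ensemble is reproducible as a whole.
#' @param n_cells number of cells.
#' @param ... forwarded to [gen_run_tumble_trajectory()].
#' @return list of `list(trajectory, labels)` entries.
#' @export
gen_ensemble <- function(params, n_cells, ...) {
  lapply(seq_len(n_cells), function(i) {
    p <- params
    p$seed <- params$seed + i - 1L
    gen_run_tumble_trajectory(p, cell_id = sprintf("cell%03d", i), ...)
  })
}

#' Parameters for the colony image-series generator
#'
#' @param true_front_speed programmed front speed, cm/h.
#' @param ring_width Gaussian 1/e half-width of the annular front, cm.
#' @param r0 initial front radius, cm.
#' @param center ring center, pixel coordinates `c(cx, cy)`.
#' @param pixels_per_cm spatial calibration.
#' @param nx,ny image size, pixels.
#' @param ring_amplitude peak ring intensity above background.
#' @param background_level constant background intensity.
#' @param noise_sd additive Gaussian pixel noise.
#' @param frame_interval time between frames, minutes.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return a `colony_image_gen_params` object.
#' @export
colony_image_gen_params <- function(true_front_speed = 0.3, ring_width = 0.08,
                                    r0 = 0.5, center = NULL,
                                    pixels_per_cm = 60, nx = 480, ny = 480,
                                    ring_amplitude = 100,
                                    background_level = 20, noise_sd = 2,
                                    frame_interval = 10, n_frames = 24,
                                    seed = 1) {
  stopifnot(true_front_speed >= 0, pixels_per_cm > 0, ring_width > 0,
            r0 >= 0, n_frames >= 1, frame_interval > 0)
  if (is.null(center)) center <- c((nx + 1) / 2, (ny + 1) / 2)
  structure(as.list(environment()), class = "colony_image_gen_params")
}

#' Generate a radially expanding ring-shaped image series
#'
#' Each frame is `background + A * exp(-(r - r_f(t))^2 / ring_width^2)
#' + noise`, with the ground-truth front radius `r_f(t) = r0 +
#' true_front_speed * t` expanding at the programmed constant speed.
#'
#' @param params a [colony_image_gen_params()] object.
#' @return an `image_stack`: list with `frames` (list of `ny x nx`
#'   matrices, row = y), `timestamps_min`, `pixels_per_cm`, and
#'   `truth` (data frame `frame`, `time_min`, `radius_cm`, plus the
#'   true `center`).
#' @export
gen_colony_image_series <- function(params) {
  stopifnot(inherits(params, "colony_image_gen_params"))
  p <- params
  t_min <- (seq_len(p$n_frames) - 1L) * p$frame_interval
  radii <- p$r0 + p$true_front_speed * t_min / 60
  max_r_px <- radii * p$pixels_per_cm
  lim <- min(p$center[1] - 1, p$nx - p$center[1],
             p$center[2] - 1, p$ny - p$center[2])
  bad <- which(max_r_px > lim)
  if (length(bad)) {
    stop(sprintf("front radius %.3g cm exceeds image bounds at frame %d",
                 radii[bad[1]], bad[1]))
  }
  xs <- matrix(rep(seq_len(p$nx), each = p$ny), p$ny, p$nx)
  ys <- matrix(rep(seq_len(p$ny), times = p$nx), p$ny, p$nx)
  rpx <- sqrt((xs - p$center[1])^2 + (ys - p$center[2])^2)
  rcm <- rpx / p$pixels_per_cm
  local_seed(p$seed, {
    frames <- lapply(seq_len(p$n_frames), function(k) {
      img <- p$background_level +
        p$ring_amplitude * exp(-(rcm - radii[k])^2 / p$ring_width^2)
      if (p$noise_sd > 0) img <- img + stats::rnorm(length(img), 0, p$noise_sd)
      matrix(img, p$ny, p$nx)
    })
    structure(list(frames = frames, timestamps_min = t_min,
                   pixels_per_cm = p$pixels_per_cm,
                   truth = data.frame(frame = seq_len(p$n_frames),
                                      time_min = t_min, radius_cm = radii),
                   center = p$center),
              class = "image_stack")
  })
}

#' Draw a phenotype population from the G-matrix model
#'
#' `n` draws from the bivariate normal `N(mean, G)` over the
#' founder-normalized phenotype vector (run speed, growth rate).
#'
#' @param mean length-2 phenotype mean (founder = `c(1, 1)`).
#' @param G a [g_matrix()] or 2x2 positive-semidefinite matrix.
#' @param n number of draws.
#' @param seed integer seed.
#' @return `n x 2` matrix with columns `vr_tilde`, `kg_tilde`.
#' @export
gen_phenotype_population <- function(mean, G, n, seed = 1) {
  Gm <- as_gmatrix(G)
  stopifnot(length(mean) == 2, n >= 1)
  local_seed(seed, {
    draws <- if (all(Gm == 0)) {
      matrix(rep(mean, each = n), n, 2)
    } else {
      MASS::mvrnorm(n, mu = mean, Sigma = Gm)
    }
    if (n == 1) draws <- matrix(draws, 1, 2)
    colnames(draws) <- c("vr_tilde", "kg_tilde")
    draws
  })
}

#' Write / read trajectory CSV pairs
#'
#' Trajectories are exchanged as plain CSV (`frame`, `time_s`, `x_um`,
#' `y_um`, `cell_id`); ground-truth labels as a parallel CSV (`frame`,
#' `state`, `at_boundary`).
#'
#' @param traj a `swim_trajectory`.
#' @param labels optional `ground_truth_labels`.
#' @param path output CSV path; labels go to `<path>_labels.csv`.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, labels = NULL) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  if (!is.null(labels)) {
    lab_path <- sub("\\.csv$", "_labels.csv", path)
    utils::write.csv(data.frame(frame = traj$frame, state = labels$state,
                                at_boundary = labels$at_boundary),
                     lab_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param frame_rate frames/s of the stored trajectory.
#' @param chamber_radius chamber radius, um (optional, enables boundary
#'   flagging downstream).
#' @export
read_trajectory_csv <- function(path, frame_rate = 30, chamber_radius = NA) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(d, "frame_rate") <- frame_rate
  attr(d, "chamber_radius") <- chamber_radius
  class(d) <- c("swim_trajectory", "data.frame")
  d
}

#' Write an image stack as multi-page TIFF
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly. Requires the `tiff` package.
#' @export
write_image_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF stacks")
  }
  mx <- max(vapply(stack$frames, max, numeric(1)))
  tiff::writeTIFF(lapply(stack$frames, function(f) f / mx), path)
  invisible(path)
}
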