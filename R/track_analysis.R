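# Run-tumble segmentation of single-cell swimming trajectories with an
# iterative adaptive angular-velocity threshold, and the motility
# statistics built on top of it.

#' Velocity and angular velocity of a trajectory
#'
#' Computes the velocity by central differences (one-sided at the two
#' endpoints, which are flagged) and the angular velocity as the angle
#' between adjacent velocity vectors divided by the frame interval.
#'
#' @param traj a `swim_trajectory` (columns `time_s`, `x_um`, `y_um`;
#'   attribute `frame_rate`).
#' @return list with `v` (n x 2 matrix, um/s), `speed` (um/s), `omega`
#'   (rad/s, length n, `NA` at the last frame), `omega_frame` (rad per
#'   frame interval), `dt` (s), and `endpoint` (logical flag for
#'   one-sided-difference frames).
#' @export
compute_kinematics <- function(traj) {
  t <- traj$time_s
  n <- length(t)
  if (n < 5) stop("compute_kinematics: need at least 5 frames")
  dts <- diff(t)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > 1e-3 * dt) {
    stop("compute_kinematics: non-uniform timestamps")
  }
  x <- traj$x_um; y <- traj$y_um
  vx <- c(diff(x)[1], (x[3:n] - x[1:(n - 2)]) / 2, diff(x)[n - 1]) / dt
  vy <- c(diff(y)[1], (y[3:n] - y[1:(n - 2)]) / 2, diff(y)[n - 1]) / dt
  # angle between v(t) and v(t+1), in [0, pi]
  dotp <- vx[-n] * vx[-1] + vy[-n] * vy[-1]
  crossp <- vx[-n] * vy[-1] - vy[-n] * vx[-1]
  ang <- atan2(abs(crossp), dotp)
  ang[!is.finite(ang)] <- 0
  omega_frame <- c(ang, NA_real_)
  list(v = cbind(vx, vy), speed = sqrt(vx^2 + vy^2),
       omega = omega_frame / dt, omega_frame = omega_frame, dt = dt,
       endpoint = c(TRUE, rep(FALSE, n - 2), TRUE))
}

#' Angle between the two-frame displacement vectors around t
#'
#' The angle between x(t-2) - x(t) and x(t) - x(t+2), used by the
#' one-frame-tumble rule to catch reorientations faster than the frame
#' interval.
#' @noRd
displacement_angle <- function(x, y) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < 5) return(out)
  idx <- 3:(n - 2)
  ax <- x[idx - 2] - x[idx]; ay <- y[idx - 2] - y[idx]
  bx <- x[idx] - x[idx + 2]; by <- y[idx] - y[idx + 2]
  # angle between -a and b = deviation from straight continuation
  dotp <- (-ax) * bx + (-ay) * by
  crossp <- (-ax) * by - (-ay) * bx
  out[idx] <- atan2(abs(crossp), dotp)
  out
}

#' Segment a trajectory into runs and tumbles
#'
#' Implements the iterative adaptive-threshold classifier. With `omega`
#' the angular velocity and `alpha` the threshold (expressed internally
#' as an angle per frame so the angular-velocity and
#' displacement-angle comparisons are dimensionally uniform):
#' a tumble is initiated when `omega(t)` and `omega(t+1)` both exceed
#' `alpha`, or when `omega(t)` exceeds `alpha` and the angle between
#' the displacement vectors `x(t-2) - x(t)` and `x(t) - x(t+2)`
#' exceeds `alpha` (the one-frame-tumble rule); a run is initiated only
#' when `omega(t)`, `omega(t+1)` and `omega(t+2)` all lie at or below
#' `alpha`. Consequently tumbles can be instantaneous while runs span a
#' minimum of four frames (enforced). The threshold is updated for
#' `n_iter` iterations as `c_mult * median(omega over run frames)`,
#' typically converging in fewer than five; if an iteration finds no
#' run frames the previous threshold is kept and the cell is flagged.
#'
#' Frames inside the boundary margin of the chamber wall are labeled
#' `boundary`; a run containing any such frame is marked
#' `boundary_interrupted` so it can be excluded from run statistics.
#'
#' @param traj a `swim_trajectory`.
#' @param c_mult threshold multiplier (`alpha = c_mult * median`).
#' @param n_iter number of threshold iterations.
#' @param alpha0_init initial threshold, rad per frame.
#' @param boundary_margin wall margin, um (used when the trajectory
#'   carries a finite `chamber_radius` attribute).
#' @param circling_filter optional function `(traj, kin) ->` logical
#'   per-frame mask of frames to exclude as wall-induced circling;
#'   the default `NULL` applies no filter.
#' @return a `segmentation`: list with per-frame `labels` (`run`,
#'   `tumble`, `boundary`, `unclassified`), `runs` and `tumbles` event
#'   data frames, final threshold `alpha_f` (rad/frame) and
#'   `alpha_f_rad_s`, the `alpha_trace`, `converged`/`flagged` status,
#'   and `frame_rate`.
#' @export
segment_runs_tumbles <- function(traj, c_mult = 5, n_iter = 10,
                                 alpha0_init = 2, boundary_margin = 5,
                                 circling_filter = NULL) {
  kin <- compute_kinematics(traj)
  n <- nrow(traj)
  om <- kin$omega_frame                  # rad per frame, NA at frame n
  disp_ang <- displacement_angle(traj$x_um, traj$y_um)

  chamber <- attr(traj, "chamber_radius")
  near_wall <- if (!is.null(chamber) && is.finite(chamber)) {
    sqrt(traj$x_um^2 + traj$y_um^2) > chamber - boundary_margin
  } else rep(FALSE, n)
  if (!is.null(circling_filter)) {
    near_wall <- near_wall | circling_filter(traj, kin)
  }

  classify <- function(alpha) {
    labels <- rep("unclassified", n)
    state <- "unclassified"
    om1 <- c(om[-1], NA); om2 <- c(om[-(1:2)], NA, NA)
    gt <- function(z) !is.na(z) & z > alpha
    le <- function(z) !is.na(z) & z <= alpha
    tumble_start <- (gt(om) & gt(om1)) |
      (gt(om) & !is.na(disp_ang) & disp_ang > alpha)
    run_start <- le(om) & le(om1) & le(om2)
    for (k in seq_len(n)) {
      if (tumble_start[k]) state <- "tumble"
      else if (run_start[k]) state <- "run"
      labels[k] <- state
    }
    labels
  }

  alpha <- alpha0_init
  alpha_trace <- numeric(0)
  flagged <- FALSE
  labels <- classify(alpha)
  for (i in seq_len(n_iter)) {
    run_frames <- labels == "run" & !is.na(om)
    if (!any(run_frames)) {
      flagged <- TRUE
      break
    }
    alpha_new <- c_mult * stats::median(om[run_frames])
    alpha_trace <- c(alpha_trace, alpha_new)
    alpha <- alpha_new
    labels <- classify(alpha)
  }

  # boundary overrides, then enforce the 4-frame run minimum
  labels[near_wall] <- "boundary"
  ev <- rle(labels)
  ends <- cumsum(ev$lengths); starts <- ends - ev$lengths + 1L
  for (j in seq_along(ev$values)) {
    if (ev$values[j] == "run" && ev$lengths[j] < 4) {
      labels[starts[j]:ends[j]] <- "unclassified"
    }
  }

  # event extraction
  ev <- rle(labels)
  ends <- cumsum(ev$lengths); starts <- ends - ev$lengths + 1L
  dt <- kin$dt
  step <- sqrt(diff(traj$x_um)^2 + diff(traj$y_um)^2)
  runs <- tumbles <- list()
  for (j in seq_along(ev$values)) {
    i1 <- starts[j]; i2 <- ends[j]
    if (ev$values[j] == "run") {
      seg_steps <- if (i2 > i1) step[i1:(i2 - 1)] else numeric(0)
      interrupted <- (j > 1 && ev$values[j - 1] == "boundary") ||
        (j < length(ev$values) && ev$values[j + 1] == "boundary")
      runs[[length(runs) + 1]] <- data.frame(
        start = i1, end = i2, duration_s = (i2 - i1 + 1) * dt,
        speed_um_s = mean(seg_steps) / dt,
        arc_length_um = sum(seg_steps),
        boundary_interrupted = interrupted)
    } else if (ev$values[j] == "tumble") {
      tumbles[[length(tumbles) + 1]] <- data.frame(
        start = i1, end = i2, duration_s = (i2 - i1 + 1) * dt)
    }
  }
  bind0 <- function(l, cols) if (length(l)) do.call(rbind, l) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  runs <- bind0(runs, c("start", "end", "duration_s", "speed_um_s",
                        "arc_length_um", "boundary_interrupted"))
  tumbles <- bind0(tumbles, c("start", "end", "duration_s"))

  conv <- length(alpha_trace) >= 2 &&
    abs(diff(utils::tail(alpha_trace, 2))) / utils::tail(alpha_trace, 1) < 0.05
  structure(list(labels = labels, runs = runs, tumbles = tumbles,
                 alpha_f = alpha, alpha_f_rad_s = alpha / dt,
                 alpha_trace = alpha_trace, converged = conv,
                 flagged = flagged, frame_rate = 1 / dt,
                 cell_id = traj$cell_id[1]),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation of %s: %d runs, %d tumbles, alpha_f = %.3g rad/frame (%.3g rad/s)%s\n",
              x$cell_id, nrow(x$runs), nrow(x$tumbles), x$alpha_f,
              x$alpha_f_rad_s, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Pooled motility statistics over an ensemble of segmentations
#'
#' Per-cell and pooled summaries of the run-tumble statistics. Cells
#' with mean tumble duration above `max_mean_tumble_s` (sustained
#' tumblers) are excluded; boundary-interrupted runs are excluded from
#' run statistics; tumble bias is the fraction of bulk (non-boundary,
#' classified) time spent tumbling; tumble frequency is the bulk tumble
#' count over the bulk swim time.
#'
#' @param segmentations list of `segmentation` objects.
#' @param max_mean_tumble_s exclusion threshold on a cell's mean tumble
#'   duration, s.
#' @return a `motility_stats`: list with `per_cell` data frame
#'   (`cell_id`, `n_runs`, `mean_run_s`, `mean_tumble_s`,
#'   `mean_speed_um_s`, `tumble_bias`, `tumble_frequency`,
#'   `excluded`), pooled means (`mean_run_s`, `mean_tumble_s`,
#'   `mean_speed_um_s`, `tumble_bias`, `tumble_frequency`), pooled
#'   `run_durations` and `run_speeds` vectors, and exclusion counts.
#' @export
motility_stats <- function(segmentations, max_mean_tumble_s = 0.4) {
  if (!length(segmentations)) stop("motility_stats: no segmentations")
  per <- lapply(segmentations, function(sg) {
    dt <- 1 / sg$frame_rate
    runs_ok <- sg$runs[!sg$runs$boundary_interrupted, , drop = FALSE]
    bulk <- sg$labels %in% c("run", "tumble")
    bulk_time <- sum(bulk) * dt
    tumble_time <- sum(sg$labels == "tumble") * dt
    data.frame(cell_id = sg$cell_id %||% NA_character_,
               n_runs = nrow(runs_ok),
               mean_run_s = mean(runs_ok$duration_s),
               mean_tumble_s = if (nrow(sg$tumbles)) mean(sg$tumbles$duration_s) else 0,
               mean_speed_um_s = mean(runs_ok$speed_um_s),
               tumble_bias = if (bulk_time > 0) tumble_time / bulk_time else NA_real_,
               tumble_frequency = if (bulk_time > 0) nrow(sg$tumbles) / bulk_time else NA_real_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per$excluded <- per$mean_tumble_s > max_mean_tumble_s
  keep <- per[!per$excluded, , drop = FALSE]
  if (!nrow(keep)) {
    stop(sprintf("motility_stats: all %d cells excluded (%d by tumble-duration rule)",
                 nrow(per), sum(per$excluded)))
  }
  kept_segs <- segmentations[!per$excluded]
  run_durations <- unlist(lapply(kept_segs, function(sg)
    sg$runs$duration_s[!sg$runs$boundary_interrupted]))
  run_speeds <- unlist(lapply(kept_segs, function(sg)
    sg$runs$speed_um_s[!sg$runs$boundary_interrupted]))
  structure(list(per_cell = per,
                 mean_run_s = mean(run_durations),
                 mean_tumble_s = mean(keep$mean_tumble_s),
                 mean_speed_um_s = mean(run_speeds),
                 tumble_bias = mean(keep$tumble_bias, na.rm = TRUE),
                 tumble_frequency = mean(keep$tumble_frequency, na.rm = TRUE),
                 run_durations = run_durations, run_speeds = run_speeds,
                 n_cells = nrow(per), n_excluded = sum(per$excluded)),
            class = "motility_stats")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.motility_stats <- function(x, ...) {
  cat(sprintf("motility_stats: %d cells (%d excluded), %d runs\n",
              x$n_cells, x$n_excluded, length(x$run_durations)))
  cat(sprintf("  mean run %.3g s at %.3g um/s; mean tumble %.3g s\n",
              x$mean_run_s, x$mean_speed_um_s, x$mean_tumble_s))
  cat(sprintf("  tumble bias %.3g, tumble frequency %.3g /s\n",
              x$tumble_bias, x$tumble_frequency))
  invisible(x)
}

#' Complementary cumulative distribution of run durations
#'
#' The empirical survival function `c(tau) = fraction of runs strictly
#' longer than tau` (right-open convention), with a percentile
#' bootstrap confidence band.
#'
#' @param durations positive run durations, s.
#' @param tau evaluation grid; defaults to the sorted unique durations
#'   prepended with 0.
#' @param conf confidence level for the bootstrap band.
#' @param n_boot bootstrap replicates (0 disables the band).
#' @param seed seed for the bootstrap resampling.
#' @return data frame `tau`, `ccdf`, and (when `n_boot > 0`) `lo`,
#'   `hi`.
#' @export
ccdf <- function(durations, tau = NULL, conf = 0.95, n_boot = 1000, seed = 1) {
  if (!length(durations)) stop("ccdf: no durations")
  if (any(durations < 0)) stop("ccdf: negative duration")
  if (is.null(tau)) tau <- c(0, sort(unique(durations)))
  surv <- function(d) vapply(tau, function(z) mean(d > z), numeric(1))
  out <- data.frame(tau = tau, ccdf = surv(durations))
  if (n_boot > 0) {
    bs <- local_seed(seed, {
      replicate(n_boot, surv(sample(durations, replace = TRUE)))
    })
    a <- (1 - conf) / 2
    out$lo <- apply(bs, 1, stats::quantile, probs = a)
    out$hi <- apply(bs, 1, stats::quantile, probs = 1 - a)
  }
  out
}

#' Match recovered tumble events against ground truth
#'
#' Greedy matching of classifier tumble events to ground-truth tumble
#' events by temporal overlap; used to score classifier recovery on
#' generator output.
#'
#' @param seg a `segmentation`.
#' @param labels the generator's `ground_truth_labels`.
#' @return list with `n_true`, `n_detected`, `n_matched`.
#' @export
match_tumble_events <- function(seg, labels) {
  true_ev <- labels$events[labels$events$type == "tumble", , drop = FALSE]
  det <- seg$tumbles
  matched <- 0L
  if (nrow(det) && nrow(true_ev)) {
    used <- rep(FALSE, nrow(det))
    for (i in seq_len(nrow(true_ev))) {
      f1 <- true_ev$frame_start[i]; f2 <- true_ev$frame_end[i]
      ov <- which(!used & det$start - 1 <= f2 + 1 & det$end - 1 >= f1 - 1)
      if (length(ov)) {
        used[ov[1]] <- TRUE
        matched <- matched + 1L
      }
    }
  }
  list(n_true = nrow(true_ev), n_detected = nrow(det), n_matched = matched)
}
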