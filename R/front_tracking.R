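# Image-based measurement of colony front position and migration
# speed: median background subtraction, gradient edge detection with a
# circular Hough transform for center (and, in minimal-medium mode,
# front) finding, sector-wise radial intensity profiles, and linear
# regression of front radius on time.

#' Construct an image stack from frames
#'
#' @param frames list of equally sized numeric matrices (row = y).
#' @param timestamps_min frame acquisition times, minutes (increasing).
#' @param pixels_per_cm spatial calibration.
#' @return an `image_stack`.
#' @export
image_stack <- function(frames, timestamps_min, pixels_per_cm) {
  stopifnot(length(frames) == length(timestamps_min),
            all(diff(timestamps_min) > 0), pixels_per_cm > 0)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("image_stack: all frames must have the same shape")
  }
  structure(list(frames = frames, timestamps_min = timestamps_min,
                 pixels_per_cm = pixels_per_cm),
            class = "image_stack")
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file.
#' @param timestamps_min frame times, minutes.
#' @param pixels_per_cm spatial calibration.
#' @return an `image_stack`. Requires the `tiff` package.
#' @export
read_image_stack_tiff <- function(path, timestamps_min, pixels_per_cm) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF stacks")
  }
  frames <- tiff::readTIFF(path, all = TRUE)
  image_stack(frames, timestamps_min, pixels_per_cm)
}

#' Median background subtraction
#'
#' Builds a background image as the per-pixel median of the first
#' `n_background` frames (acquired before significant growth) and
#' subtracts it from every frame, clipping negative values to zero.
#'
#' @param stack an `image_stack`.
#' @param n_background number of leading frames in the median
#'   projection.
#' @return an `image_stack` of background-subtracted frames.
#' @export
background_subtract <- function(stack, n_background = 6) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < n_background) {
    stop(sprintf("background_subtract: need >= %d frames, have %d",
                 n_background, length(stack$frames)))
  }
  bg_arr <- simplify2array(stack$frames[seq_len(n_background)])
  bg <- apply(bg_arr, c(1, 2), stats::median)
  out <- stack
  out$frames <- lapply(stack$frames, function(f) pmax(f - bg, 0))
  out
}

#' Gradient edge map (Sobel magnitude with hysteresis thresholds)
#'
#' Smooths lightly, computes Sobel gradient magnitude, and keeps
#' strong-edge pixels plus weak-edge pixels connected to them through
#' an 8-neighborhood dilation pass — a compact stand-in for the Canny
#' chain used to seed the Hough transform.
#'
#' @param frame numeric matrix.
#' @param low,high hysteresis thresholds as quantiles of the nonzero
#'   gradient magnitude.
#' @return logical matrix of edge pixels.
#' @export
edge_map <- function(frame, low = 0.90, high = 0.97) {
  f <- frame
  ny <- nrow(f); nx <- ncol(f)
  pad <- function(m) m[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
  p <- pad(f)
  sm <- (p[1:ny, 1:nx] + p[1:ny, 2:(nx + 1)] + p[1:ny, 3:(nx + 2)] +
         p[2:(ny + 1), 1:nx] + p[2:(ny + 1), 2:(nx + 1)] + p[2:(ny + 1), 3:(nx + 2)] +
         p[3:(ny + 2), 1:nx] + p[3:(ny + 2), 2:(nx + 1)] + p[3:(ny + 2), 3:(nx + 2)]) / 9
  p <- pad(sm)
  gx <- (p[1:ny, 3:(nx + 2)] - p[1:ny, 1:nx]) +
    2 * (p[2:(ny + 1), 3:(nx + 2)] - p[2:(ny + 1), 1:nx]) +
    (p[3:(ny + 2), 3:(nx + 2)] - p[3:(ny + 2), 1:nx])
  gy <- (p[3:(ny + 2), 1:nx] - p[1:ny, 1:nx]) +
    2 * (p[3:(ny + 2), 2:(nx + 1)] - p[1:ny, 2:(nx + 1)]) +
    (p[3:(ny + 2), 3:(nx + 2)] - p[1:ny, 3:(nx + 2)])
  g <- sqrt(gx^2 + gy^2)
  nz <- g[g > 0]
  if (!length(nz)) return(matrix(FALSE, ny, nx))
  thr_lo <- stats::quantile(nz, low)
  thr_hi <- stats::quantile(nz, high)
  strong <- g >= thr_hi
  weak <- g >= thr_lo
  # grow strong edges into connected weak pixels (few dilation passes)
  dil8 <- function(m) {
    p <- m[c(1, seq_len(ny), ny), c(1, seq_len(nx), nx)]
    (p[1:ny, 1:nx] | p[1:ny, 2:(nx + 1)] | p[1:ny, 3:(nx + 2)] |
     p[2:(ny + 1), 1:nx] | p[2:(ny + 1), 3:(nx + 2)] |
     p[3:(ny + 2), 1:nx] | p[3:(ny + 2), 2:(nx + 1)] | p[3:(ny + 2), 3:(nx + 2)] |
     m)
  }
  out <- strong
  for (i in 1:10) {
    grown <- dil8(out) & weak
    if (identical(grown, out)) break
    out <- grown
  }
  out
}

#' Locate the colony center by circular Hough transform
#'
#' Edge pixels vote for circle centers over a radius search range; the
#' highest-vote accumulator cell gives the center (and best radius).
#'
#' @param frame background-subtracted numeric matrix.
#' @param radii candidate circle radii, pixels; default spans 10-90%
#'   of the half-image.
#' @param min_votes minimum accumulator score (fraction of a full
#'   circle's perimeter votes concentrated in one cell) below which no
#'   colony is declared.
#' @param edges optional precomputed logical edge map.
#' @return list with `center` (`c(cx, cy)`, pixel column/row), `radius`
#'   (pixels), and `score`.
#' @export
find_center <- function(frame, radii = NULL, min_votes = 0.1, edges = NULL) {
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(radii)) {
    rmax <- floor(min(nx, ny) / 2)
    radii <- seq(max(4, round(0.1 * rmax)), round(0.9 * rmax), by = 2)
  }
  if (is.null(edges)) edges <- edge_map(frame)
  idx <- which(edges, arr.ind = TRUE)
  if (!nrow(idx)) stop("no colony detected: empty edge map")
  acc <- .hough_circle_cpp(as.integer(idx[, 2]), as.integer(idx[, 1]),
                           nx, ny, as.numeric(radii))
  best <- which.max(acc)
  score <- acc[best]
  if (score < min_votes) stop("no colony detected: best Hough score ", signif(score, 3))
  ijk <- arrayInd(best, dim(acc))
  list(center = c(cx = ijk[1], cy = ijk[2]), radius = radii[ijk[3]],
       score = score)
}

#' Front radius of one frame
#'
#' Rich-medium mode: radial intensity profiles are measured from the
#' center in azimuthal sectors (no full azimuthal averaging, to respect
#' departures from circularity); the outermost local maximum above the
#' noise floor gives each sector's front radius, and the sector median
#' is reported. Minimal-medium mode (low signal-to-background): a
#' circular Hough transform locates the front circle directly and its
#' radius is reported.
#'
#' @param frame background-subtracted numeric matrix.
#' @param center `c(cx, cy)` in pixels (column, row).
#' @param pixels_per_cm calibration.
#' @param mode `"rich"` (sector radial profiles) or `"minimal"`
#'   (Hough circle).
#' @param n_sectors number of azimuthal sectors (rich mode).
#' @param floor_frac noise floor as a fraction of the frame's maximum
#'   profile intensity; peaks below it are ignored.
#' @param radii Hough radius search range, pixels (minimal mode).
#' @return front radius in cm, or `NA` (flagged frame) when no peak
#'   clears the floor.
#' @export
front_radius <- function(frame, center, pixels_per_cm,
                         mode = c("rich", "minimal"), n_sectors = 36,
                         floor_frac = 0.2, radii = NULL) {
  mode <- match.arg(mode)
  ny <- nrow(frame); nx <- ncol(frame)
  xs <- matrix(rep(seq_len(nx), each = ny), ny, nx) - center[1]
  ys <- matrix(rep(seq_len(ny), times = nx), ny, nx) - center[2]
  rpx <- sqrt(xs^2 + ys^2)
  if (mode == "minimal") {
    res <- tryCatch(find_center(frame, radii = radii),
                    error = function(e) NULL)
    if (is.null(res)) return(NA_real_)
    # the Hough radius locks onto the ring's edges (gradient maxima);
    # refine to the intensity peak of the full azimuthal mean profile
    # in a window around the Hough circle
    rbin <- pmax(round(rpx), 1)
    prof <- vapply(split(frame, rbin), mean, numeric(1))
    rr <- as.numeric(names(prof))
    ord <- order(rr); prof <- prof[ord]; rr <- rr[ord]
    win <- which(abs(rr - res$radius) <= max(6, 0.25 * res$radius))
    if (length(win) < 3) return(res$radius / pixels_per_cm)
    i <- win[which.max(prof[win])]
    # parabolic sub-pixel interpolation around the peak
    if (i > 1 && i < length(prof)) {
      y1 <- prof[i - 1]; y2 <- prof[i]; y3 <- prof[i + 1]
      den <- y1 - 2 * y2 + y3
      shift <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
      return((rr[i] + max(min(shift, 1), -1)) / pixels_per_cm)
    }
    return(rr[i] / pixels_per_cm)
  }
  theta <- atan2(ys, xs)
  sector <- pmin(floor((theta + pi) / (2 * pi) * n_sectors) + 1, n_sectors)
  rbin <- pmax(round(rpx), 1)
  # profiles end at the inscribed circle: beyond it (image corners)
  # radius bins hold too few pixels to average the noise down
  r_ins <- floor(min(center[1] - 1, nx - center[1],
                     center[2] - 1, ny - center[2]))
  keep <- rbin <= r_ins
  floor_abs <- floor_frac * max(frame)
  sector_radius <- rep(NA_real_, n_sectors)
  for (s in seq_len(n_sectors)) {
    sel <- keep & sector == s
    prof <- vapply(split(frame[sel], rbin[sel]), mean, numeric(1))
    rr <- as.numeric(names(prof))
    ord <- order(rr)
    prof <- prof[ord]; rr <- rr[ord]
    np <- length(prof)
    if (np < 5) next
    prof_sm <- stats::filter(prof, rep(1 / 3, 3))  # light smoothing
    prof_sm[c(1, np)] <- prof[c(1, np)]
    loc_max <- which(prof_sm[2:(np - 1)] >= prof_sm[1:(np - 2)] &
                     prof_sm[2:(np - 1)] >= prof_sm[3:np] &
                     prof_sm[2:(np - 1)] > floor_abs) + 1
    if (length(loc_max)) sector_radius[s] <- rr[max(loc_max)]
  }
  if (all(is.na(sector_radius))) return(NA_real_)
  stats::median(sector_radius, na.rm = TRUE) / pixels_per_cm
}

#' Measure the front radius trace of a stack
#'
#' Applies [background_subtract()], finds the center on the brightest
#' late frame, measures every frame's front radius, and returns the
#' per-frame trace (flagged frames carry `NA`).
#'
#' @param stack an `image_stack`.
#' @param mode `"rich"` or `"minimal"` (see [front_radius()]).
#' @param n_background frames in the background median.
#' @param center optional known center `c(cx, cy)` (skips detection).
#' @param ... forwarded to [front_radius()].
#' @return data frame `frame`, `time_min`, `radius_cm`, `ok`.
#' @export
front_trace_from_stack <- function(stack, mode = c("rich", "minimal"),
                                   n_background = 6, center = NULL, ...) {
  mode <- match.arg(mode)
  bs <- background_subtract(stack, n_background)
  if (is.null(center)) {
    ref <- bs$frames[[length(bs$frames)]]
    center <- find_center(ref)$center
  }
  radius <- vapply(bs$frames, function(f)
    front_radius(f, center, stack$pixels_per_cm, mode = mode, ...),
    numeric(1))
  data.frame(frame = seq_along(bs$frames),
             time_min = stack$timestamps_min,
             radius_cm = radius, ok = is.finite(radius))
}

#' Front migration speed from a measured radius trace
#'
#' Linear regression of front radius on time over the late-time
#' window, sharing the contract of [migration_rate()]. Flagged frames
#' are dropped rather than interpolated. Background (pre-front) frames
#' where no radius was detected do not enter the fit.
#'
#' @param trace data frame with `time_min` (or `t` in hours) and
#'   `radius_cm` (or `radius`), optionally `ok`.
#' @param window regression window (see [migration_rate()]).
#' @return as [migration_rate()]: `s` (cm/h), `se`, `r2`, `n`,
#'   `window`.
#' @export
front_speed <- function(trace, window = 0.5) {
  d <- as.data.frame(trace)
  if (!is.null(d[["time_min"]]) && is.null(d[["t"]])) d$t <- d[["time_min"]] / 60
  if (!is.null(d[["radius_cm"]]) && is.null(d[["radius"]])) {
    d$radius <- d[["radius_cm"]]
  }
  migration_rate(d[, c("t", "radius", intersect("ok", names(d)))],
                 window = window)
}
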