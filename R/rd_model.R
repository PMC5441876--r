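#' Monod growth term
#'
#' Local growth rate of the bacterial density field,
#' `g(rho, c) = kg * rho * c / (Kg + c)`, saturating in nutrient
#' concentration. Defined as 0 at `c = 0`.
#'
#' @param rho cell density, cells/mL.
#' @param c nutrient concentration, mM.
#' @param kg maximum growth rate, 1/h.
#' @param Kg half-saturation concentration, mM.
#' @return growth rate, cells/mL/h (vectorized).
#' @export
growth_term <- function(rho, c, kg, Kg) {
  ifelse(c > 0, kg * rho * c / (Kg + c), 0)
}

#' Nutrient consumption term
#'
#' Identical in form to [growth_term()] divided by the constant yield
#' `Y` (cells produced per mM nutrient): `f = g / Y`, in mM/h.
#'
#' @inheritParams growth_term
#' @param Y yield, cells/mL/mM.
#' @return consumption rate, mM/h.
#' @export
consumption_term <- function(rho, c, kg, Kg, Y) {
  growth_term(rho, c, kg, Kg) / Y
}

#' Reaction-diffusion model parameters
#'
#' Full parameter vector for one medium: transport (`Db`, `k0`, `Dc`),
#' receptor binding (`KD`), Monod growth (`kg`, `Kg`, `Y`), initial
#' nutrient `c0`, agar concentration `C`, the inoculum (total cells
#' spread uniformly over a central disc of radius `inoculum_radius` and
#' effective depth `depth`), and the plate (domain) radius.
#'
#' @param Db bacterial diffusion constant, cm^2/h.
#' @param Dc nutrient diffusion constant, cm^2/h.
#' @param k0 chemotactic coefficient, cm^2/h.
#' @param KD receptor-nutrient binding constant, mM.
#' @param kg maximum growth rate, 1/h.
#' @param Kg Monod half-saturation concentration, mM.
#' @param Y yield, cells/mL/mM.
#' @param c0 initial nutrient concentration, mM.
#' @param C agar concentration, % w/v (bookkeeping only; transport
#'   coefficients already include the agar correction).
#' @param inoculum_cells total cells inoculated.
#' @param inoculum_radius radius of the inoculation disc, cm.
#' @param depth effective plate depth, cm (converts total cells to
#'   density).
#' @param domain_radius plate radius, cm.
#' @param medium `"rich"` or `"minimal"` tag.
#' @return an `rd_params` object.
#' @export
rd_params <- function(Db, Dc = 0.036, k0, KD, kg, Kg, Y, c0, C = 0.3,
                      inoculum_cells = 1e6, inoculum_radius = 0.25,
                      depth = 0.4, domain_radius = 7.5,
                      medium = c("rich", "minimal")) {
  medium <- match.arg(medium)
  p <- list(Db = Db, Dc = Dc, k0 = k0, KD = KD, kg = kg, Kg = Kg, Y = Y,
            c0 = c0, C = C, inoculum_cells = inoculum_cells,
            inoculum_radius = inoculum_radius, depth = depth,
            domain_radius = domain_radius, medium = medium)
  num <- p[c("Dc", "KD", "Kg", "Y", "c0", "inoculum_cells",
             "inoculum_radius", "depth", "domain_radius")]
  if (any(unlist(num) <= 0)) stop("rd_params: all physical scales must be positive")
  if (Db < 0 || k0 < 0 || kg < 0) stop("rd_params: Db, k0, kg must be non-negative")
  structure(p, class = "rd_params")
}

#' @export
print.rd_params <- function(x, ...) {
  cat(sprintf("Reaction-diffusion parameters (%s medium)\n", x$medium))
  cat(sprintf("  Db = %g, Dc = %g, k0 = %g cm^2/h; KD = %g mM\n",
              x$Db, x$Dc, x$k0, x$KD))
  cat(sprintf("  kg = %g 1/h, Kg = %g mM, Y = %g cells/mL/mM, c0 = %g mM\n",
              x$kg, x$Kg, x$Y, x$c0))
  cat(sprintf("  inoculum %g cells in r <= %g cm, plate R = %g cm\n",
              x$inoculum_cells, x$inoculum_radius, x$domain_radius))
  invisible(x)
}

#' Load a shipped parameter preset
#'
#' Presets `"rich_medium_founder"` and `"minimal_medium_founder"`
#' transcribe the founder-strain parameter sets (agar-corrected
#' transport plus growth/receptor physiology) from YAML files shipped
#' with the package.
#'
#' @param name preset name.
#' @return an `rd_params` object.
#' @export
rd_params_preset <- function(name = c("rich_medium_founder",
                                      "minimal_medium_founder")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"),
                      package = "chemomigrate", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  do.call(rd_params, y)
}

#' Integrate the chemotaxis-growth reaction-diffusion model
#'
#' Integrates the axisymmetric 1-D reduction of the Keller-Segel model
#' with Monod growth and nutrient consumption over `[0, t_end]` hours,
#' with no-flux boundaries at the plate center and edge. The
#' chemotactic flux uses the receptor law
#' `chi(c) = k0 * KD / (KD + c)^2`. Initial condition: the inoculum
#' spread uniformly over the central disc, nutrient uniform at `c0`.
#'
#' @param params an [rd_params()] object.
#' @param t_end final time, h.
#' @param dr radial grid spacing, cm (default 50 um).
#' @param save_dt interval between saved snapshots, h.
#' @param cfl stability safety factor for the explicit stepper.
#' @param geometry `"radial"` (axisymmetric, default) or `"planar"`
#'   (1-D slab; useful for traveling-wave limits).
#' @param stop_early stop integrating once the leading density tail
#'   (1e3 cells/mL) reaches the outermost grid cell; from then on the
#'   front position would be distorted by the no-flux wall and is
#'   discarded by [front_position()] anyway.
#' @return an `rd_solution`: list with radial grid `r` (cm), saved
#'   times `t` (h), matrices `rho` and `c` (`length(r)` x `length(t)`),
#'   the `params`, and stepper metadata.
#' @export
rd_simulate <- function(params, t_end, dr = 0.005, save_dt = 0.25, cfl = 0.4,
                        geometry = c("radial", "planar"), stop_early = TRUE) {
  geometry <- match.arg(geometry)
  stopifnot(inherits(params, "rd_params"), t_end > 0, dr > 0)
  R <- params$domain_radius
  N <- ceiling(R / dr)
  r <- (seq_len(N) - 0.5) * dr
  rho0 <- numeric(N)
  disc <- r <= params$inoculum_radius
  vol_disc <- pi * params$inoculum_radius^2 * params$depth  # mL (cm^3)
  rho0[disc] <- params$inoculum_cells / vol_disc
  c0 <- rep(params$c0, N)
  save_times <- unique(c(seq(0, t_end, by = save_dt), t_end))

  out <- .rd_integrate_cpp(rho0, c0, dr, t_end,
                           params$Db, params$Dc, params$k0, params$KD,
                           params$kg, params$Kg, params$Y,
                           save_times, cfl, radial = (geometry == "radial"),
                           stop_rho = if (stop_early) 1e3 else -1)
  rho <- out$rho; cc <- out$c
  if (min(rho) < -1e-9 * max(rho)) {
    stop("negative cell density beyond tolerance: min rho = ", min(rho))
  }
  structure(list(r = r, t = out$t, rho = rho, c = cc, params = params,
                 meta = list(scheme = "explicit FV, central diffusion, upwind chemotaxis",
                             dr = dr, steps = out$steps, cfl = cfl,
                             geometry = geometry,
                             stopped_early = isTRUE(out$stopped_early))),
            class = "rd_solution")
}

#' @export
print.rd_solution <- function(x, ...) {
  cat(sprintf("rd_solution: %d radial points (dr = %g cm), %d snapshots to t = %g h (%g steps)\n",
              length(x$r), x$meta$dr, length(x$t), max(x$t), x$meta$steps))
  invisible(x)
}

#' Extract the colony front position over time
#'
#' The front at each saved time is the outermost radius at which the
#' cell density crosses a threshold, located by linear interpolation
#' between grid points. By default the threshold is a fraction of the
#' instantaneous spatial maximum; an absolute density may be supplied
#' instead.
#'
#' @param sol an `rd_solution`.
#' @param threshold_frac threshold as a fraction of `max(rho(., t))`.
#' @param absolute absolute density threshold (cells/mL); overrides
#'   `threshold_frac` when non-`NULL`.
#' @param wall_margin width of the zone next to the no-flux domain edge
#'   (cm) within which front positions are flagged invalid: once the
#'   front enters it, the boundary distorts the profile and the trace
#'   no longer measures free migration.
#' @return a `front_trace` data frame with columns `t` (h), `radius`
#'   (cm) and `ok` (front found and away from the domain edge). Times
#'   where no crossing exists are flagged `ok = FALSE` with `NA`
#'   radius.
#' @export
front_position <- function(sol, threshold_frac = 0.1, absolute = NULL,
                           wall_margin = 0.5) {
  stopifnot(inherits(sol, "rd_solution"))
  nt <- length(sol$t)
  radius <- rep(NA_real_, nt)
  ok <- logical(nt)
  for (j in seq_len(nt)) {
    prof <- sol$rho[, j]
    thr <- if (is.null(absolute)) threshold_frac * max(prof) else absolute
    if (thr <= 0 || all(prof < thr)) next
    above <- which(prof >= thr)
    i <- max(above)
    if (i == length(prof)) {
      radius[j] <- sol$r[i]
    } else {
      # interpolate the outermost downward crossing
      r1 <- sol$r[i]; r2 <- sol$r[i + 1]
      p1 <- prof[i]; p2 <- prof[i + 1]
      radius[j] <- r1 + (p1 - thr) / (p1 - p2) * (r2 - r1)
    }
    ok[j] <- TRUE
  }
  wall <- max(sol$r) - wall_margin
  hit <- !is.na(radius) & radius > wall
  if (any(hit)) ok[min(which(hit)):length(ok)] <- FALSE
  structure(data.frame(t = sol$t, radius = radius, ok = ok),
            class = c("front_trace", "data.frame"))
}

#' Migration rate from a front trace
#'
#' Ordinary least-squares slope of front radius against time over a
#' late-time window, excluding the initial growth phase. The default
#' window is the last 50% of (valid) time points.
#'
#' @param trace a `front_trace` (or any data frame with columns `t`,
#'   `radius`, and optionally `ok`).
#' @param window fraction of the trace (from the end) used for the
#'   regression, or a length-2 numeric `c(t_min, t_max)` in hours.
#' @return list with slope `s` (cm/h), its standard error `se`, `r2`,
#'   the number of points `n`, and the fitted window.
#' @export
migration_rate <- function(trace, window = 0.5) {
  d <- as.data.frame(trace)
  if (!is.null(d$ok)) d <- d[d$ok, ]
  d <- d[is.finite(d$radius), ]
  if (length(window) == 2) {
    d <- d[d$t >= window[1] & d$t <= window[2], ]
  } else {
    keep <- max(5, ceiling(nrow(d) * window))
    d <- utils::tail(d, keep)
  }
  if (nrow(d) < 5) stop("migration_rate: window too short (", nrow(d), " points)")
  fit <- stats::lm(radius ~ t, data = d)
  sm <- suppressWarnings(summary(fit))  # exact linear traces are legitimate
  list(s = unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, 2],
       r2 = sm$r.squared,
       n = nrow(d),
       window = range(d$t))
}

#' Migration rate for one parameter set (convenience wrapper)
#'
#' Simulate, extract the front, and regress, in one call.
#'
#' @inheritParams rd_simulate
#' @param threshold_frac front-detection threshold fraction.
#' @param window regression window (see [migration_rate()]).
#' @return as [migration_rate()].
#' @export
simulate_migration_rate <- function(params, t_end, dr = 0.005, save_dt = 0.25,
                                    threshold_frac = 0.1, window = 0.5) {
  sol <- rd_simulate(params, t_end, dr = dr, save_dt = save_dt)
  migration_rate(front_position(sol, threshold_frac), window = window)
}

#' Migration-rate landscape over run speed and growth rate
#'
#' For each grid pair (run speed `vr`, maximum growth rate `kg`): map
#' the swimming statistics (at fixed tumble frequency `alpha0` and agar
#' concentration) to agar-corrected transport coefficients with
#' [agar_transport()], integrate the reaction-diffusion model, and
#' regress the late-time front position. Returns the migration-rate
#' matrix plus a founder-normalized copy (both rate and axes divided by
#' their founder values).
#'
#' @param base an [rd_params()] object; growth/receptor physiology and
#'   geometry are taken from it, transport is recomputed per grid cell.
#' @param vr_grid run speeds, um/s.
#' @param kg_grid maximum growth rates, 1/h.
#' @param alpha0 tumble frequency held fixed across the grid, 1/s.
#' @param founder list with founder `vr` (um/s) and `kg` (1/h) used for
#'   normalization; the founder point is simulated with the same
#'   pipeline.
#' @param t_end,dr,save_dt,threshold_frac,window forwarded to the
#'   single-cell simulation (see [simulate_migration_rate()]).
#' @param liquid_ref liquid reference for the transport mapping.
#' @return a `landscape_grid`: list with `vr`, `kg`, matrix `s`
#'   (`length(vr)` x `length(kg)`, cm/h), normalized `vr_tilde`,
#'   `kg_tilde`, `s_tilde`, the founder rate `s_founder`, and a logical
#'   matrix `failed` flagging any grid cell whose simulation failed.
#' @export
migration_landscape <- function(base, vr_grid, kg_grid, alpha0,
                                founder, t_end, dr = 0.005, save_dt = 0.25,
                                threshold_frac = 0.1, window = 0.5,
                                liquid_ref = liquid_transport()) {
  stopifnot(length(vr_grid) >= 1, length(kg_grid) >= 1,
            all(vr_grid > 0), all(kg_grid > 0))
  one <- function(vr, kg) {
    tp <- agar_transport(swim_summary(vr = vr, alpha0 = alpha0), C = base$C,
                         liquid_ref = liquid_ref)
    p <- base
    p$Db <- tp$Db; p$k0 <- tp$k0; p$kg <- kg
    simulate_migration_rate(p, t_end, dr = dr, save_dt = save_dt,
                            threshold_frac = threshold_frac, window = window)$s
  }
  s <- matrix(NA_real_, length(vr_grid), length(kg_grid),
              dimnames = list(vr = signif(vr_grid, 4), kg = signif(kg_grid, 4)))
  failed <- matrix(FALSE, length(vr_grid), length(kg_grid))
  for (i in seq_along(vr_grid)) {
    for (j in seq_along(kg_grid)) {
      res <- tryCatch(one(vr_grid[i], kg_grid[j]), error = function(e) e)
      if (inherits(res, "error")) failed[i, j] <- TRUE else s[i, j] <- res
    }
  }
  s_f <- tryCatch(one(founder$vr, founder$kg), error = function(e) NA_real_)
  structure(list(vr = vr_grid, kg = kg_grid, s = s,
                 vr_tilde = vr_grid / founder$vr,
                 kg_tilde = kg_grid / founder$kg,
                 s_tilde = s / s_f, s_founder = s_f,
                 founder = founder, alpha0 = alpha0, failed = failed),
            class = "landscape_grid")
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("Migration-rate landscape: %d x %d grid, founder s = %.3g cm/h, %d failed cells\n",
              length(x$vr), length(x$kg), x$s_founder, sum(x$failed)))
  invisible(x)
}

#' Migration rate as a function of tumble frequency
#'
#' Sweeps the tumble frequency at fixed run speed, remapping transport
#' coefficients at each point, and reports the migration-rate curve
#' plus the maximum relative gain over the founder tumble frequency.
#'
#' @inheritParams migration_landscape
#' @param alpha0_grid tumble frequencies to sweep, 1/s.
#' @param vr run speed held fixed, um/s.
#' @param alpha0_founder founder tumble frequency (for the gain), 1/s.
#' @return list with `alpha0`, `s` (cm/h), `s_founder`, and `max_gain`
#'   (max over the sweep of `s / s_founder - 1`).
#' @export
tumble_frequency_sweep <- function(base, alpha0_grid, vr, alpha0_founder,
                                   t_end, dr = 0.005, save_dt = 0.25,
                                   threshold_frac = 0.1, window = 0.5,
                                   liquid_ref = liquid_transport()) {
  one <- function(a0) {
    tp <- agar_transport(swim_summary(vr = vr, alpha0 = a0), C = base$C,
                         liquid_ref = liquid_ref)
    p <- base
    p$Db <- tp$Db; p$k0 <- tp$k0
    simulate_migration_rate(p, t_end, dr = dr, save_dt = save_dt,
                            threshold_frac = threshold_frac, window = window)$s
  }
  s <- vapply(alpha0_grid, one, numeric(1))
  s_f <- one(alpha0_founder)
  list(alpha0 = alpha0_grid, s = s, s_founder = s_f,
       max_gain = max(s / s_f - 1))
}
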