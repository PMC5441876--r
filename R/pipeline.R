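# End-to-end reproduction presets: each executes one named experiment
# of the study pipeline on deterministic settings and reports computed
# vs expected values with pass/fail at the stated tolerance.

#' Published swimming statistics and transport coefficients by strain
#'
#' The measured tumble frequency (`alpha0`, 1/s) and run speed (`vr`,
#' um/s) for founder and evolved strains in both media at 0.3% w/v
#' agar, together with the published agar-corrected transport
#' coefficients (`Db`, `k0`, cm^2/h) they map to.
#'
#' @return data frame with one row per strain.
#' @export
strain_transport_table <- function() {
  data.frame(
    medium = c("rich", "rich", "rich", "rich", "minimal", "minimal", "minimal"),
    strain = c("founder", "round5", "round10", "round15",
               "founder", "round5", "round10"),
    alpha0 = c(1.45, 1.56, 1.72, 1.54, 2, 2.5, 3),
    vr = c(18.7, 24.9, 27.6, 28.7, 20.7, 11.2, 13.3),
    Db = c(0.02, 0.027, 0.029, 0.031, 0.021, 0.011, 0.011),
    k0 = c(0.65, 0.90, 1.04, 1.04, 0.66, 0.39, 0.5),
    stringsAsFactors = FALSE)
}

#' Default settings of the reproduction protocol
#'
#' Problem sizes and measurement choices used by [run_reproduction()]
#' and the acceptance experiments: grid spacing 0.01 cm (fitted rates
#' change by < 0.1% on halving), snapshots every 0.25 h, front
#' threshold 0.1 x max, and regression over the final quarter of the
#' front trace (the axisymmetric curvature transient persists beyond
#' half the trace; see the methods vignette).
#'
#' @return list of settings.
#' @export
repro_settings <- function() {
  list(dr = 0.01, save_dt = 0.25, threshold_frac = 0.1, window = 0.25,
       t_end_rich = 12, t_end_minimal = 48,
       landscape_n = 5,
       # landscape grids span founder-to-evolved phenotypes in each medium
       rich_vr_range = c(18.7, 28.7), rich_kg_range = c(1.1, 1.23),
       minimal_vr_range = c(11.2, 20.7), minimal_kg_range = c(0.125, 0.375),
       founder_rich = list(vr = 18.7, kg = 1.23, alpha0 = 1.45),
       founder_minimal = list(vr = 20.7, kg = 0.125, alpha0 = 2))
}

#' Run a named reproduction experiment
#'
#' Presets:
#' \describe{
#'   \item{`founder_rich_s`}{simulate the founder rich-medium
#'     parameter set for 12 h; compare the fitted migration rate
#'     against 0.61 cm/h (tolerance 0.03).}
#'   \item{`founder_minimal_s`}{minimal-medium founder for 48 h;
#'     compare against 0.08 cm/h (tolerance 0.015; the companion
#'     tabulated value 0.09 lies inside the band).}
#'   \item{`table3_transport`}{map all published strain swimming
#'     statistics through [agar_transport()]; require every `Db` and
#'     `k0` within 10% of its published value.}
#'   \item{`beta_vectors`}{build both landscapes, fit selection
#'     gradients; compare unit vectors against (0.78, 0.61) (rich,
#'     tolerance 0.05) and (0.87, 0.49) (minimal, tolerance 0.08).}
#'   \item{`kg_transition`}{sweep the minimal-medium growth rate over
#'     0.05 to 0.4 /h; the steepest change in migration rate must lie
#'     at 0.2 +/- 0.05 /h.}
#'   \item{`classifier_recovery`}{segment a seeded 200-cell synthetic
#'     ensemble spanning run durations 0.3-1.0 s; recovered mean run
#'     duration and tumble frequency within 15% of the generator
#'     truth.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed for any stochastic preset.
#' @param out_dir optional directory; when given, the report is also
#'   written as JSON to `<out_dir>/<name>.json`.
#' @param settings protocol settings, see [repro_settings()].
#' @return a `repro_report`: list with `name`, `seed`, per-quantity
#'   `checks` (data frame: quantity, computed, expected, tolerance,
#'   pass) and overall `pass`.
#' @export
run_reproduction <- function(name = c("founder_rich_s", "founder_minimal_s",
                                      "table3_transport", "beta_vectors",
                                      "kg_transition", "classifier_recovery"),
                             seed = 1, out_dir = NULL,
                             settings = repro_settings()) {
  name <- match.arg(name)
  st <- settings
  checks <- switch(name,
    founder_rich_s = {
      res <- simulate_migration_rate(rd_params_preset("rich_medium_founder"),
                                     t_end = st$t_end_rich, dr = st$dr,
                                     save_dt = st$save_dt,
                                     threshold_frac = st$threshold_frac,
                                     window = st$window)
      data.frame(quantity = "s_rich_founder_cm_h", computed = res$s,
                 expected = 0.61, tolerance = 0.03)
    },
    founder_minimal_s = {
      res <- simulate_migration_rate(rd_params_preset("minimal_medium_founder"),
                                     t_end = st$t_end_minimal, dr = st$dr,
                                     save_dt = st$save_dt,
                                     threshold_frac = st$threshold_frac,
                                     window = st$window)
      data.frame(quantity = "s_minimal_founder_cm_h", computed = res$s,
                 expected = 0.08, tolerance = 0.015)
    },
    table3_transport = {
      tab <- strain_transport_table()
      est <- lapply(seq_len(nrow(tab)), function(i)
        agar_transport(swim_summary(vr = tab$vr[i], alpha0 = tab$alpha0[i]),
                       C = 0.3))
      data.frame(
        quantity = c(paste0("Db_", tab$medium, "_", tab$strain),
                     paste0("k0_", tab$medium, "_", tab$strain)),
        computed = c(vapply(est, `[[`, numeric(1), "Db"),
                     vapply(est, `[[`, numeric(1), "k0")),
        expected = c(tab$Db, tab$k0),
        tolerance = 0.1 * c(tab$Db, tab$k0))
    },
    beta_vectors = {
      bR <- fit_selection_gradient(repro_landscape("rich", st))
      bM <- fit_selection_gradient(repro_landscape("minimal", st))
      data.frame(
        quantity = c("beta_hat_rich_vr", "beta_hat_rich_kg",
                     "beta_hat_minimal_vr", "beta_hat_minimal_kg"),
        computed = c(bR$beta_hat, bM$beta_hat),
        expected = c(0.78, 0.61, 0.87, 0.49),
        tolerance = c(0.05, 0.05, 0.08, 0.08))
    },
    kg_transition = {
      sw <- kg_sweep_minimal(settings = st)
      data.frame(quantity = "kg_transition_h", computed = sw$kg_transition,
                 expected = 0.2, tolerance = 0.05)
    },
    classifier_recovery = {
      rec <- classifier_recovery_ensemble(n_cells = 200, seed = seed)
      data.frame(
        quantity = c("run_duration_rel_err", "tumble_frequency_rel_err"),
        computed = c(rec$run_duration_rel_err, rec$tumble_frequency_rel_err),
        expected = c(0, 0), tolerance = c(0.15, 0.15))
    })
  checks$pass <- abs(checks$computed - checks$expected) <= checks$tolerance
  report <- structure(list(name = name, seed = seed, checks = checks,
                           pass = all(checks$pass)),
                      class = "repro_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(name = name, seed = seed, pass = report$pass, checks = checks),
      file.path(out_dir, paste0(name, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.repro_report <- function(x, ...) {
  cat(sprintf("reproduction '%s' (seed %d): %s\n", x$name, x$seed,
              if (x$pass) "PASS" else "FAIL"))
  print(x$checks, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Landscape of one medium under the reproduction protocol
#'
#' @param medium `"rich"` or `"minimal"`.
#' @param settings see [repro_settings()].
#' @return a `landscape_grid`.
#' @export
repro_landscape <- function(medium = c("rich", "minimal"),
                            settings = repro_settings()) {
  medium <- match.arg(medium)
  st <- settings
  if (medium == "rich") {
    migration_landscape(rd_params_preset("rich_medium_founder"),
      vr_grid = seq(st$rich_vr_range[1], st$rich_vr_range[2],
                    length.out = st$landscape_n),
      kg_grid = seq(st$rich_kg_range[1], st$rich_kg_range[2],
                    length.out = st$landscape_n),
      alpha0 = st$founder_rich$alpha0, founder = st$founder_rich,
      t_end = st$t_end_rich, dr = st$dr, save_dt = st$save_dt,
      threshold_frac = st$threshold_frac, window = st$window)
  } else {
    migration_landscape(rd_params_preset("minimal_medium_founder"),
      vr_grid = seq(st$minimal_vr_range[1], st$minimal_vr_range[2],
                    length.out = st$landscape_n),
      kg_grid = seq(st$minimal_kg_range[1], st$minimal_kg_range[2],
                    length.out = st$landscape_n),
      alpha0 = st$founder_minimal$alpha0, founder = st$founder_minimal,
      t_end = st$t_end_minimal, dr = st$dr, save_dt = st$save_dt,
      threshold_frac = st$threshold_frac, window = st$window)
  }
}

#' Growth-rate sweep locating the minimal-medium migration transition
#'
#' Sweeps the maximum growth rate at founder transport parameters in
#' the minimal-medium model and locates the growth rate of steepest
#' change in migration rate (max |ds/dkg|), the transition from
#' diffusion-dominated expansion to a traveling wave.
#'
#' @param kg_grid growth rates to sweep, 1/h.
#' @param settings see [repro_settings()].
#' @return list with `kg`, `s`, and `kg_transition` (midpoint of the
#'   steepest-change interval).
#' @export
kg_sweep_minimal <- function(kg_grid = seq(0.05, 0.4, by = 0.05),
                             settings = repro_settings()) {
  st <- settings
  base <- rd_params_preset("minimal_medium_founder")
  s <- vapply(kg_grid, function(kg) {
    p <- base; p$kg <- kg
    simulate_migration_rate(p, st$t_end_minimal, dr = st$dr,
                            save_dt = st$save_dt,
                            threshold_frac = st$threshold_frac,
                            window = st$window)$s
  }, numeric(1))
  slope <- abs(diff(s) / diff(kg_grid))
  i <- which.max(slope)
  list(kg = kg_grid, s = s,
       kg_transition = mean(kg_grid[c(i, i + 1)]))
}

#' Classifier recovery on a seeded synthetic ensemble
#'
#' Generates an ensemble of labeled run-and-tumble trajectories with
#' run durations spanning `tau_range`, segments them with
#' [segment_runs_tumbles()], and compares recovered pooled statistics
#' against the generator truth.
#'
#' @param n_cells ensemble size.
#' @param tau_range range of mean run durations across cells, s.
#' @param duration per-cell trajectory length, s.
#' @param seed integer seed.
#' @return list with generator truth, recovered values, and relative
#'   errors for mean run duration and tumble frequency.
#' @export
classifier_recovery_ensemble <- function(n_cells = 200,
                                         tau_range = c(0.3, 1.0),
                                         duration = 60, seed = 1) {
  taus <- seq(tau_range[1], tau_range[2], length.out = n_cells)
  segs <- vector("list", n_cells)
  true_run <- true_tumble <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    gp <- motility_gen_params(mean_run_duration = taus[i],
                              duration = duration, seed = seed + i)
    gen <- gen_run_tumble_trajectory(gp, cell_id = sprintf("cell%03d", i))
    segs[[i]] <- segment_runs_tumbles(gen$trajectory)
    ev <- gen$labels$events
    true_run[i] <- mean(ev$t_end[ev$type == "run"] -
                        ev$t_start[ev$type == "run"])
    true_tumble[i] <- sum(ev$type == "tumble") / duration
  }
  stats <- motility_stats(segs)
  truth_run <- mean(true_run)
  truth_freq <- mean(true_tumble)
  list(truth_mean_run_s = truth_run,
       recovered_mean_run_s = stats$mean_run_s,
       truth_tumble_frequency = truth_freq,
       recovered_tumble_frequency = stats$tumble_frequency,
       run_duration_rel_err = stats$mean_run_s / truth_run - 1,
       tumble_frequency_rel_err = stats$tumble_frequency / truth_freq - 1,
       stats = stats)
}
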