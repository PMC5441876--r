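# Lande-style model of correlated-trait evolution: selection gradient
# from a migration-rate landscape, G-matrix response prediction,
# direction-agreement sweeps, and stochastic rounds-of-selection
# simulations.

#' Genetic variance-covariance matrix of the two traits
#'
#' `G = [[sigma_vr^2, rho sigma_vr sigma_kg],
#'       [rho sigma_vr sigma_kg, sigma_kg^2]]` over the
#' founder-normalized phenotype vector (run speed, growth rate). The
#' diagonal describes the capacity of mutations to vary each trait,
#' the off-diagonal their capacity to vary both (the trade-off has
#' `rho_G < 0`).
#'
#' @param sigma_vr,sigma_kg fractional standard deviations of the two
#'   traits (dimensionless).
#' @param rho_G trait correlation, in `[-1, 1]`.
#' @return 2x2 matrix of class `g_matrix`.
#' @export
g_matrix <- function(sigma_vr, sigma_kg, rho_G) {
  stopifnot(sigma_vr >= 0, sigma_kg >= 0)
  if (abs(rho_G) > 1) stop("g_matrix: |rho_G| must be <= 1")
  G <- matrix(c(sigma_vr^2, rho_G * sigma_vr * sigma_kg,
                rho_G * sigma_vr * sigma_kg, sigma_kg^2), 2, 2)
  dimnames(G) <- list(c("vr_tilde", "kg_tilde"), c("vr_tilde", "kg_tilde"))
  class(G) <- c("g_matrix", class(G))
  G
}

#' @noRd
as_gmatrix <- function(G) {
  G <- unclass(G)
  stopifnot(is.matrix(G), all(dim(G) == 2))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-12 * max(abs(ev), 1)) {
    stop("G must be positive semidefinite")
  }
  G
}

#' Selection gradient from a migration-rate landscape
#'
#' Least-squares plane fit of the founder-normalized migration rate
#' (or its log) against the founder-normalized phenotypes
#' `(vr_tilde, kg_tilde)`. The gradient of the fitted plane is the
#' selection gradient `beta`; its unit-normalized copy gives the
#' direction of selection.
#'
#' @param grid a `landscape_grid` from [migration_landscape()] (or any
#'   list with `vr_tilde`, `kg_tilde`, `s_tilde`).
#' @param use_log fit `log(s_tilde)` instead of `s_tilde`. Near the
#'   founder, where `s_tilde = 1`, the two gradients coincide to first
#'   order.
#' @return a `selection_gradient`: list with `beta` (length 2),
#'   `beta_hat` (unit norm), `use_log`, `residual_norm`, `r2`, and the
#'   fitted model's coefficients.
#' @export
fit_selection_gradient <- function(grid, use_log = FALSE) {
  d <- expand.grid(vr_tilde = grid$vr_tilde, kg_tilde = grid$kg_tilde)
  d$s <- as.vector(grid$s_tilde)
  d <- d[is.finite(d$s), , drop = FALSE]
  if (nrow(d) < 3 || length(unique(d$vr_tilde)) < 2 ||
      length(unique(d$kg_tilde)) < 2) {
    stop("fit_selection_gradient: need a grid of at least 3 points spanning both axes")
  }
  if (use_log) {
    if (any(d$s <= 0)) stop("fit_selection_gradient: non-positive rates under use_log")
    d$s <- log(d$s)
  }
  fit <- stats::lm(s ~ vr_tilde + kg_tilde, data = d)
  beta <- unname(stats::coef(fit)[c("vr_tilde", "kg_tilde")])
  if (any(!is.finite(beta))) stop("fit_selection_gradient: rank-deficient design")
  nrm <- sqrt(sum(beta^2))
  structure(list(beta = beta, beta_hat = beta / nrm, use_log = use_log,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 coefficients = stats::coef(fit)),
            class = "selection_gradient")
}

#' @export
print.selection_gradient <- function(x, ...) {
  cat(sprintf("selection gradient%s: beta = [%.3f, %.3f], beta_hat = [%.3f, %.3f]\n",
              if (x$use_log) " (log rate)" else "",
              x$beta[1], x$beta[2], x$beta_hat[1], x$beta_hat[2]))
  cat(sprintf("  residual norm %.3g, R^2 = %.3f\n", x$residual_norm, x$r2))
  invisible(x)
}

#' Predicted response to selection
#'
#' The Lande response `phi = G beta + phi0`: the mean phenotype after
#' one episode of selection with gradient `beta` acting on genetic
#' covariance `G`, starting from `phi0`.
#'
#' @param G a [g_matrix()].
#' @param beta a `selection_gradient` or length-2 numeric.
#' @param phi0 starting mean phenotype (founder = `c(1, 1)`).
#' @return list with `phi` (predicted mean), `response` (`G beta`),
#'   and `phi_hat_pred` (unit vector along `G beta`).
#' @export
predict_response <- function(G, beta, phi0 = c(1, 1)) {
  Gm <- as_gmatrix(G)
  b <- if (inherits(beta, "selection_gradient")) beta$beta else beta
  stopifnot(length(b) == 2, length(phi0) == 2)
  resp <- unname(drop(Gm %*% b))
  nrm <- sqrt(sum(resp^2))
  if (nrm == 0) stop("no predicted response: G beta = 0")
  list(phi = phi0 + resp, response = resp, phi_hat_pred = resp / nrm)
}

#' Direction-agreement sweep over genetic variances
#'
#' For each combination of trait standard deviations and correlation,
#' computes the predicted direction of evolution `G beta / |G beta|`
#' and its dot product with the observed direction. Because the
#' predicted direction depends on the variances only through their
#' ratio, the agreement boundary is reported, per correlation value, as
#' the `sigma_vr / sigma_kg` ratio at which the dot product crosses the
#' agreement threshold.
#'
#' @param beta a `selection_gradient` or length-2 numeric.
#' @param phi_obs_hat observed unit direction of phenotypic evolution.
#' @param sigma_vr_grid,sigma_kg_grid trait standard deviations to
#'   sweep.
#' @param rho_list trait correlations to sweep.
#' @param threshold dot-product value counted as agreement.
#' @return a `direction_sweep`: list with `dot` array
#'   (`sigma_vr x sigma_kg x rho`), the grids, and per-rho
#'   `boundaries` (data frame `rho_G`, `ratio_boundary`, the smallest
#'   swept ratio with agreement, or `NA` when none agrees).
#' @export
direction_agreement_sweep <- function(beta, phi_obs_hat,
                                      sigma_vr_grid, sigma_kg_grid,
                                      rho_list, threshold = 0.95) {
  b <- if (inherits(beta, "selection_gradient")) beta$beta else beta
  stopifnot(length(phi_obs_hat) == 2)
  if (abs(sqrt(sum(phi_obs_hat^2)) - 1) > 1e-6) {
    stop("phi_obs_hat must be unit-normalized")
  }
  if (!length(sigma_vr_grid) || !length(sigma_kg_grid)) stop("empty grids")
  dims <- c(length(sigma_vr_grid), length(sigma_kg_grid), length(rho_list))
  dot <- array(NA_real_, dims,
               dimnames = list(signif(sigma_vr_grid, 4),
                               signif(sigma_kg_grid, 4), rho_list))
  for (i in seq_along(sigma_vr_grid)) {
    for (j in seq_along(sigma_kg_grid)) {
      for (k in seq_along(rho_list)) {
        G <- g_matrix(sigma_vr_grid[i], sigma_kg_grid[j], rho_list[k])
        resp <- drop(unclass(G) %*% b)
        nrm <- sqrt(sum(resp^2))
        dot[i, j, k] <- if (nrm > 0) sum(resp * phi_obs_hat) / nrm else NA_real_
      }
    }
  }
  # agreement depends on sigma_vr/sigma_kg only: scan the ratio axis
  ratios <- sort(unique(round(as.vector(outer(sigma_vr_grid, sigma_kg_grid, "/")), 10)))
  boundaries <- do.call(rbind, lapply(rho_list, function(rho) {
    ag <- vapply(ratios, function(rt) {
      resp <- drop(unclass(g_matrix(rt, 1, rho)) %*% b)
      nrm <- sqrt(sum(resp^2))
      nrm > 0 && sum(resp * phi_obs_hat) / nrm >= threshold
    }, logical(1))
    data.frame(rho_G = rho,
               ratio_boundary = if (any(ag)) min(ratios[ag]) else NA_real_,
               ratio_max_agree = if (any(ag)) max(ratios[ag]) else NA_real_)
  }))
  structure(list(dot = dot, sigma_vr = sigma_vr_grid,
                 sigma_kg = sigma_kg_grid, rho = rho_list,
                 threshold = threshold, boundaries = boundaries),
            class = "direction_sweep")
}

#' Bilinear interpolation on a landscape grid
#'
#' Evaluates the founder-normalized migration rate at arbitrary
#' phenotypes by bilinear interpolation inside the grid and
#' nearest-edge clamping outside (clamped points are flagged).
#'
#' @param grid a `landscape_grid`.
#' @param phi matrix (n x 2) of phenotypes `(vr_tilde, kg_tilde)`.
#' @return list with `s_tilde` (length n) and `clamped` (logical).
#' @export
landscape_interpolate <- function(grid, phi) {
  vx <- grid$vr_tilde; kx <- grid$kg_tilde
  S <- grid$s_tilde
  phi <- matrix(phi, ncol = 2)
  v <- pmin(pmax(phi[, 1], min(vx)), max(vx))
  k <- pmin(pmax(phi[, 2], min(kx)), max(kx))
  clamped <- v != phi[, 1] | k != phi[, 2]
  iv <- pmin(pmax(findInterval(v, vx), 1), length(vx) - 1)
  ik <- pmin(pmax(findInterval(k, kx), 1), length(kx) - 1)
  tv <- (v - vx[iv]) / (vx[iv + 1] - vx[iv])
  tk <- (k - kx[ik]) / (kx[ik + 1] - kx[ik])
  s <- (1 - tv) * (1 - tk) * S[cbind(iv, ik)] +
    tv * (1 - tk) * S[cbind(iv + 1, ik)] +
    (1 - tv) * tk * S[cbind(iv, ik + 1)] +
    tv * tk * S[cbind(iv + 1, ik + 1)]
  list(s_tilde = s, clamped = clamped)
}

#' Stochastic rounds-of-selection simulation
#'
#' Simulates repeated rounds of truncation selection for faster
#' migration on a phenotype landscape: each round draws `n_pop`
#' phenotypes from `N(phi_t, G)`, scores them by the interpolated
#' normalized migration rate, keeps the fastest `select_fraction`, and
#' takes their mean as the next round's mean phenotype.
#'
#' @param landscape a `landscape_grid`.
#' @param G a [g_matrix()].
#' @param phi0 starting mean phenotype.
#' @param n_pop population size per round.
#' @param select_fraction fraction retained each round.
#' @param n_rounds number of selection rounds.
#' @param seed integer seed.
#' @return a `(n_rounds + 1) x 2` matrix of mean phenotypes (row 1 =
#'   `phi0`), with attribute `clamped_fraction` (fraction of draws
#'   evaluated outside the landscape, by round).
#' @export
stochastic_selection <- function(landscape, G, phi0 = c(1, 1), n_pop = 1000,
                                 select_fraction = 0.1, n_rounds = 10,
                                 seed = 1) {
  Gm <- as_gmatrix(G)
  stopifnot(n_pop >= 2, select_fraction > 0, select_fraction <= 1)
  traj <- matrix(NA_real_, n_rounds + 1, 2,
                 dimnames = list(NULL, c("vr_tilde", "kg_tilde")))
  traj[1, ] <- phi0
  clamped_frac <- numeric(n_rounds)
  local_seed(seed, {
    for (r in seq_len(n_rounds)) {
      draws <- if (all(Gm == 0)) {
        matrix(rep(traj[r, ], each = n_pop), n_pop, 2)
      } else {
        MASS::mvrnorm(n_pop, mu = traj[r, ], Sigma = Gm)
      }
      sc <- landscape_interpolate(landscape, draws)
      if (all(sc$clamped)) stop("stochastic_selection: all draws outside the landscape")
      clamped_frac[r] <- mean(sc$clamped)
      n_keep <- max(1, round(select_fraction * n_pop))
      keep <- order(sc$s_tilde, decreasing = TRUE)[seq_len(n_keep)]
      traj[r + 1, ] <- colMeans(draws[keep, , drop = FALSE])
    }
  })
  attr(traj, "clamped_fraction") <- clamped_frac
  traj
}
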