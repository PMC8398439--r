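#' Simulate a Transwell dissolution / diffusion experiment
#'
#' Integrates the coupled particle-dissolution / membrane-diffusion system
#' between sampling events and applies the discrete sampling-and-replacement
#' jumps. Per particle bin i the Nernst-Brunner rate (with correction
#' factor F) is
#' \deqn{dX_i/dt = -F D\, SA_i(t)\, (C_s - X_d/V_d)/r_i(t)}
#' with radius and surface area recomputed from the remaining bin mass at
#' every step; the dissolved donor amount and the receptor amount follow
#' \deqn{dX_d/dt = \sum_i (-dX_i/dt) - P\,SM\,(X_d/V_d - Y/V_r)}
#' \deqn{dY/dt = P\,SM\,(X_d/V_d - Y/V_r).}
#' At each scheduled sampling time an aliquot \eqn{V_s} is withdrawn
#' (\eqn{Y \to Y - Y V_s/V_r}, the removed amount accumulating in S) and
#' replaced by fresh medium, so \eqn{V_r} is constant. The observed profile
#' reproduces the bench readout: cumulative transferred percent at sampling
#' time \eqn{t_k} is \eqn{100\,(Y(t_k^-) + S(t_k^-))/X_{initial}}, i.e. the
#' receptor content just before the sample plus everything removed by
#' earlier samples.
#'
#' Units are ug, mL, cm and hours internally; times are reported in minutes.
#' Below 1e-6 of its initial mass a bin's rate is tapered linearly to zero
#' (the raw rate scales as \eqn{X^{1/3}} near exhaustion, which is
#' non-Lipschitz), so exhausted bins decay smoothly to a negligible frozen
#' residual instead of hitting the \eqn{1/r} singularity; the residual stays
#' in the state so the mass balance
#' \eqn{X_d + Y + S + \sum_i X_i = X_{initial}} stays exact.
#'
#' @param config An \code{\link{experiment_config}}. When \code{config$psd}
#'   is \code{NULL} the entire initial amount starts dissolved in the donor
#'   (solution run).
#' @return An object of class \code{"transwell_sim"}: a list with
#'   \code{time_min}, \code{donor_dissolved}, \code{receptor_amount},
#'   \code{removed_cumulative}, \code{per_bin_mass} (matrix, or \code{NULL}
#'   for solution runs), \code{donor_concentration},
#'   \code{cumulative_percent} (dense \eqn{100(Y+S)/X_0}),
#'   \code{observed} (a \code{\link{transfer_profile}} at the sampling
#'   times) and \code{config}.
#' @examples
#' cfg <- experiment_config(initial_amount = 100, receptor_volume = 1.5,
#'                          schedule = diffusion_schedule())
#' sim <- transwell_sim(cfg)
#' sim$observed
#' @export
transwell_sim <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  .integrate_transwell(config, engine = "lsoda")
}

#' Fixed-step explicit-Euler reference integration
#'
#' Brute-force oracle for \code{\link{transwell_sim}}: the same model
#' stepped with a small fixed explicit-Euler step. Dissolution rates are
#' limited so a step can never drive a bin mass negative. Intended for
#' verification, not production use.
#'
#' @param config An \code{\link{experiment_config}}.
#' @param dt_min Euler step, minutes.
#' @return A \code{"transwell_sim"} object.
#' @export
transwell_sim_euler <- function(config, dt_min = 0.01) {
  stopifnot(inherits(config, "experiment_config"))
  .integrate_transwell(config, engine = "euler", dt_min = dt_min)
}

# shared driver: piecewise integration between sampling events
.integrate_transwell <- function(config, engine, dt_min = 0.01) {
  sch <- config$schedule
  X0 <- config$initial_amount
  Vd <- config$donor_volume; Vr <- config$receptor_volume
  Vs <- sch$sample_volume
  p <- list(
    F = config$correction_factor,
    D = config$drug$diffusion_coefficient,   # cm^2/h
    P = config$drug$permeability,            # cm/h
    SM = config$geometry$membrane_area,
    Cs = config$medium$solubility,
    Vd = Vd, Vr = Vr,
    rho = config$drug$density
  )
  if (is.null(config$psd)) {
    n_bins <- 0L
    p$N <- numeric(0); p$X0bins <- numeric(0)
    state <- c(Xd = X0, Y = 0, S = 0)
  } else {
    bins <- config$psd$bins
    n_bins <- nrow(bins)
    p$N <- bins$particle_count
    p$X0bins <- bins$mass_ug
    state <- c(Xd = 0, Y = 0, S = 0, bins$mass_ug)
  }
  p$freeze <- 1e-6 * pmax(p$X0bins, .Machine$double.eps)

  t_events_h <- sch$times / 60
  dense_h <- sort(unique(c(seq(0, max(sch$times), by = config$solver$dense_dt),
                           sch$times))) / 60

  rows <- matrix(state, nrow = 1)
  times_out <- 0
  obs_pct <- numeric(length(t_events_h))
  t_prev <- 0
  for (k in seq_along(t_events_h)) {
    tk <- t_events_h[k]
    grid <- dense_h[dense_h > t_prev + 1e-12 & dense_h <= tk + 1e-12]
    grid <- unique(c(t_prev, grid, tk))
    seg <- if (engine == "lsoda") {
      .segment_lsoda(state, grid, p, config$solver)
    } else {
      .segment_euler(state, grid, p, dt_min / 60)
    }
    rows <- rbind(rows, seg[-1, , drop = FALSE])
    times_out <- c(times_out, grid[-1])
    state <- seg[nrow(seg), ]
    # bench readout just before the sample, then the sampling jump
    obs_pct[k] <- 100 * (state[2] + state[3]) / X0
    removed <- state[2] / Vr * Vs
    state[2] <- state[2] - removed
    state[3] <- state[3] + removed
    t_prev <- tk
  }

  if (min(rows) < -1e-6 * X0)
    stop("internal consistency error: negative state beyond tolerance (min = ",
         signif(min(rows), 3), " ug)")

  time_min <- times_out * 60
  res <- list(
    time_min = time_min,
    donor_dissolved = unname(rows[, 1]),
    receptor_amount = unname(rows[, 2]),
    removed_cumulative = unname(rows[, 3]),
    per_bin_mass = if (n_bins > 0) unname(rows[, -(1:3), drop = FALSE]) else NULL,
    donor_concentration = unname(rows[, 1]) / Vd,
    cumulative_percent = 100 * unname(rows[, 2] + rows[, 3]) / X0,
    observed = transfer_profile(sch$times, obs_pct),
    config = config,
    engine = engine
  )
  class(res) <- "transwell_sim"
  res
}

.transwell_rhs <- function(t, state, p) {
  Xd <- state[1]; Y <- state[2]
  flux <- p$P * p$SM * (Xd / p$Vd - Y / p$Vr)   # ug/h, donor -> receptor
  if (length(p$N) == 0)
    return(list(c(-flux, flux, 0)))
  X <- pmax(state[-(1:3)], 0)
  g <- .bin_geometry(X, p$N, p$rho)
  active <- X > 0 & p$N > 0
  dXi <- numeric(length(X))
  # taper the rate linearly below the freeze threshold: the 1/r Nernst-
  # Brunner rate scales as X^(1/3) near exhaustion (non-Lipschitz), which
  # would stall the integrator; the taper makes the decay exponential there
  w <- pmin(1, X / p$freeze)
  dXi[active] <- -w[active] * p$F * p$D * g$surface_area_cm2[active] *
    (p$Cs - Xd / p$Vd) / g$radius_cm[active]
  list(c(-sum(dXi) - flux, flux, 0, dXi))
}

.segment_lsoda <- function(state, grid, p, solver) {
  out <- deSolve::ode(y = state, times = grid, func = .transwell_rhs,
                      parms = p, method = solver$method,
                      rtol = solver$rtol, atol = solver$atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE integration failed (istate = ", attr(out, "istate")[1], ")")
  unname(out[, -1, drop = FALSE])
}

.segment_euler <- function(state, grid, p, dt_h) {
  out <- matrix(NA_real_, length(grid), length(state))
  out[1, ] <- state
  t <- grid[1]
  for (j in seq_along(grid)[-1]) {
    tend <- grid[j]
    while (t < tend - 1e-12) {
      h <- min(dt_h, tend - t)
      d <- .transwell_rhs(t, state, p)[[1]]
      if (length(state) > 3) {
        # rate limiting: a step may not drive a bin below zero
        Xb <- state[-(1:3)]
        db <- pmax(d[-(1:3)], -Xb / h)
        d[1] <- d[1] + (sum(d[-(1:3)]) - sum(db))  # keep the mass balance
        d[-(1:3)] <- db
      }
      state <- state + h * d
      t <- t + h
    }
    out[j, ] <- state
  }
  out
}

#' Piecewise closed-form solution for solution (diffusion-only) runs
#'
#' With no particles the system is linear: between sampling events the total
#' dissolved amount \eqn{A = X_d + Y} is constant and the receptor amount
#' relaxes exponentially towards its equilibrium share,
#' \deqn{Y(t) = A\frac{V_r}{V_d+V_r} + \left(Y_0 - A\frac{V_r}{V_d+V_r}\right)
#'   e^{-\kappa (t - t_0)}, \quad \kappa = P\,SM\,(1/V_d + 1/V_r).}
#' Sampling jumps are applied exactly. Serves as an independent oracle for
#' \code{\link{transwell_sim}} on solution configurations.
#'
#' @param config An \code{\link{experiment_config}} with \code{psd = NULL}.
#' @return A \code{"transwell_sim"} object.
#' @export
solution_closed_form <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$psd))
    stop("solution_closed_form applies only to solution runs (psd = NULL)")
  sch <- config$schedule
  X0 <- config$initial_amount
  Vd <- config$donor_volume; Vr <- config$receptor_volume
  kappa <- config$drug$permeability * config$geometry$membrane_area *
    (1 / Vd + 1 / Vr)
  w <- Vr / (Vd + Vr)

  dense_h <- sort(unique(c(seq(0, max(sch$times), by = config$solver$dense_dt),
                           sch$times))) / 60
  t_events_h <- sch$times / 60
  Xd <- X0; Y <- 0; S <- 0; t_prev <- 0
  times_out <- 0; Xd_out <- Xd; Y_out <- Y; S_out <- S
  obs_pct <- numeric(length(t_events_h))
  for (k in seq_along(t_events_h)) {
    tk <- t_events_h[k]
    grid <- dense_h[dense_h > t_prev + 1e-12 & dense_h <= tk + 1e-12]
    grid <- unique(c(grid, tk))
    A <- Xd + Y
    Yt <- A * w + (Y - A * w) * exp(-kappa * (grid - t_prev))
    times_out <- c(times_out, grid)
    Xd_out <- c(Xd_out, A - Yt)
    Y_out <- c(Y_out, Yt)
    S_out <- c(S_out, rep(S, length(grid)))
    Yk <- Yt[length(Yt)]
    obs_pct[k] <- 100 * (Yk + S) / X0
    removed <- Yk / Vr * sch$sample_volume
    Y <- Yk - removed; S <- S + removed; Xd <- A - Yk
    t_prev <- tk
  }
  res <- list(
    time_min = times_out * 60,
    donor_dissolved = Xd_out,
    receptor_amount = Y_out,
    removed_cumulative = S_out,
    per_bin_mass = NULL,
    donor_concentration = Xd_out / Vd,
    cumulative_percent = 100 * (Y_out + S_out) / X0,
    observed = transfer_profile(sch$times, obs_pct),
    config = config,
    engine = "closed_form"
  )
  class(res) <- "transwell_sim"
  res
}

#' @export
print.transwell_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Transwell %s run (%s)\n",
              if (is.null(cfg$psd)) "solution" else "dissolution", x$engine))
  cat(sprintf("  X0 = %.4g ug, Vd = %.3g mL, Vr = %.4g mL, Vs = %.3g mL, Cs = %.4g ug/mL\n",
              cfg$initial_amount, cfg$donor_volume, cfg$receptor_volume,
              cfg$schedule$sample_volume, cfg$medium$solubility))
  n <- length(x$observed$time_min)
  cat(sprintf("  observed transfer: %.1f%% at %g min (final of %d samples)\n",
              x$observed$cumulative_percent[n], x$observed$time_min[n], n))
  invisible(x)
}

#' @export
summary.transwell_sim <- function(object, ...) {
  bal <- object$donor_dissolved + object$receptor_amount +
    object$removed_cumulative +
    (if (is.null(object$per_bin_mass)) 0 else rowSums(object$per_bin_mass))
  out <- list(
    final_percent = object$observed$cumulative_percent[
      length(object$observed$cumulative_percent)],
    peak_donor_concentration = max(object$donor_concentration),
    mass_balance_error = max(abs(bal - object$config$initial_amount)) /
      object$config$initial_amount,
    n_times = length(object$time_min)
  )
  class(out) <- "summary.transwell_sim"
  out
}

#' @export
print.summary.transwell_sim <- function(x, ...) {
  cat(sprintf("final transfer          : %.2f %%\n", x$final_percent))
  cat(sprintf("peak donor concentration: %.4g ug/mL\n",
              x$peak_donor_concentration))
  cat(sprintf("max mass-balance error  : %.2e (relative)\n",
              x$mass_balance_error))
  invisible(x)
}

#' @export
plot.transwell_sim <- function(x, which = c("transfer", "donor"), ...) {
  which <- match.arg(which)
  if (which == "transfer") {
    plot(x$time_min, x$cumulative_percent, type = "l",
         xlab = "time (min)", ylab = "cumulative transferred (%)",
         ylim = c(0, 100), ...)
    points(x$observed$time_min, x$observed$cumulative_percent, pch = 16)
  } else {
    plot(x$time_min, x$donor_concentration, type = "l",
         xlab = "time (min)", ylab = "donor concentration (ug/mL)", ...)
    abline(h = x$config$medium$solubility, lty = 2)
  }
  invisible(x)
}

#' @export
as.data.frame.transwell_sim <- function(x, ...) {
  df <- data.frame(time_min = x$time_min,
                   donor_dissolved_ug = x$donor_dissolved,
                   receptor_ug = x$receptor_amount,
                   removed_ug = x$removed_cumulative,
                   donor_conc_ug_ml = x$donor_concentration,
                   cumulative_percent = x$cumulative_percent)
  if (!is.null(x$per_bin_mass)) {
    bins <- as.data.frame(x$per_bin_mass)
    names(bins) <- paste0("bin", x$config$psd$bins$stage, "_ug")
    df <- cbind(df, bins)
  }
  df
}
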