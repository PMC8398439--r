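#' Estimate membrane permeability from a solution transfer profile
#'
#' One-parameter least squares: the solution-only simulation is run at
#' candidate permeabilities (log-parameterized to enforce positivity) and
#' the unweighted SSE between simulated and observed cumulative-percent
#' values at the observed timepoints is minimized by Brent's method on the
#' log scale (which enforces positivity). The relative standard error comes
#' from the linearized covariance at the optimum.
#'
#' @param observed A \code{\link{transfer_profile}} (or compatible data
#'   frame) of a solution experiment. Its timepoints must be a subset of
#'   the configuration's sampling schedule.
#' @param config An \code{\link{experiment_config}} with \code{psd = NULL};
#'   its \code{drug$permeability} is ignored and re-estimated.
#' @return An object of class \code{"fit_report"}: \code{parameter_name},
#'   \code{estimate}, \code{relative_standard_error} (percent),
#'   \code{residual_sse}, \code{iterations}, \code{fitted_profile}.
#' @export
fit_permeability <- function(observed, config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!is.null(config$psd))
    stop("permeability is fitted on solution runs; config$psd must be NULL")
  .fit_one_parameter(
    observed, config, name = "permeability",
    apply_par = function(cfg, v) { cfg$drug$permeability <- v; cfg })
}

#' Estimate the Nernst-Brunner correction factor F
#'
#' One-dimensional least squares over F > 0 for a particle run, with the
#' permeability fixed (previously fitted or supplied). If the observed
#' profile transfers faster than the solution-limited curve (the F -> Inf
#' limit, in which dissolution is instantaneous and only membrane
#' diffusion limits transfer), no finite F can explain it and an error is
#' raised rather than returning a boundary estimate.
#'
#' @param observed Observed dissolution profile.
#' @param config An \code{\link{experiment_config}} carrying the PSD; its
#'   \code{correction_factor} is ignored and re-estimated.
#' @return A \code{"fit_report"}.
#' @export
fit_correction_factor <- function(observed, config) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(config$psd))
    stop("fitting F requires a particle configuration (psd supplied)")
  pr <- .as_profile(observed)
  # feasibility: compare against the solution-limited (instantaneous
  # dissolution) profile
  sol_cfg <- config; sol_cfg$psd <- NULL
  lim <- transwell_sim(sol_cfg)$observed
  common <- intersect(pr$time_min, lim$time_min)
  if (length(common) >= 3) {
    d <- pr$cumulative_percent[match(common, pr$time_min)] -
      lim$cumulative_percent[match(common, lim$time_min)]
    if (mean(d) > 0.5)
      stop("observed profile is faster than the solution-limited (F -> Inf) ",
           "curve; no finite correction factor can fit it")
  }
  rep <- .fit_one_parameter(
    observed, config, name = "correction_factor",
    apply_par = function(cfg, v) { cfg$correction_factor <- v; cfg })
  if (rep$estimate > 100)
    stop("correction-factor fit ran to the solution-limited boundary; ",
         "the data carry no dissolution information")
  rep
}

# shared 1-D driver: golden-section/parabolic (Brent) search for the SSE
# minimum on the log scale (positivity by construction, scale-free steps),
# with the relative standard error from the linearized Jacobian at the
# optimum
.fit_one_parameter <- function(observed, config, name, apply_par,
                               bracket = c(1e-5, 1e3)) {
  pr <- .as_profile(observed)
  sched <- config$schedule$times
  if (!all(pr$time_min %in% sched))
    stop("observed timepoints must be a subset of the configured schedule")
  idx <- match(pr$time_min, sched)
  n_eval <- 0L
  resid_fn <- function(lp) {
    sim <- transwell_sim(apply_par(config, exp(lp)))
    sim$observed$cumulative_percent[idx] - pr$cumulative_percent
  }
  sse_fn <- function(lp) { n_eval <<- n_eval + 1L; sum(resid_fn(lp)^2) }
  opt <- stats::optimize(sse_fn, interval = log(bracket), tol = 1e-6)
  lp <- opt$minimum
  if (min(abs(lp - log(bracket))) < 1e-2)
    stop(name, " estimate ran to the search boundary; the data are not ",
         "informative about it")
  est <- exp(lp)
  n <- nrow(pr)
  h <- 1e-4  # central difference on the log scale
  J <- (resid_fn(lp + h) - resid_fn(lp - h)) / (2 * h)
  jtj <- sum(J^2)
  se_log <- if (jtj > 0) sqrt(opt$objective / max(n - 1, 1) / jtj) else Inf
  # se on the log scale ~ relative se of the estimate
  if (!is.finite(se_log) || se_log > 10)
    stop(name, " is not identifiable from these data (flat objective)")
  structure(list(parameter_name = name,
                 estimate = unname(est),
                 relative_standard_error = 100 * se_log,
                 residual_sse = opt$objective,
                 iterations = n_eval,
                 fitted_profile = transwell_sim(apply_par(config, est))$observed),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("%s = %.4g (+/- %.3g%% RSE), SSE = %.3g, %d iterations\n",
              x$parameter_name, x$estimate, x$relative_standard_error,
              x$residual_sse, x$iterations))
  invisible(x)
}

#' Generate noisy replicate profiles
#'
#' Emulates replicate bench profiles by applying independent multiplicative
#' lognormal noise to every observation of a simulated profile. The noise
#' factor has mean exactly 1 (\eqn{e^{\sigma Z - \sigma^2/2}} with
#' \eqn{\sigma^2 = \log(1 + cv^2)}), so the mean replicate profile
#' converges to the input as the number of replicates grows.
#'
#' @param x A \code{"transwell_sim"} or transfer profile.
#' @param cv Coefficient of variation, percent.
#' @param n_replicates Number of replicates.
#' @param seed Optional integer seed; a fixed seed gives bit-identical
#'   output.
#' @return A list of \code{\link{transfer_profile}} objects.
#' @export
generate_noisy_profiles <- function(x, cv, n_replicates, seed = NULL) {
  pr <- .as_profile(x)
  if (!is.finite(cv) || cv < 0) stop("cv must be non-negative")
  if (n_replicates < 1) stop("n_replicates must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sig <- sqrt(log(1 + (cv / 100)^2))
  lapply(seq_len(n_replicates), function(i) {
    fac <- if (cv == 0) 1 else
      exp(stats::rnorm(nrow(pr), -sig^2 / 2, sig))
    y <- pmin(pmax(pr$cumulative_percent * fac, 0), 110)
    transfer_profile(pr$time_min, y)
  })
}

#' Mean of replicate profiles
#'
#' @param profiles List of profiles sharing the same timepoints.
#' @return A \code{\link{transfer_profile}} of pointwise means.
#' @export
mean_profile <- function(profiles) {
  prs <- lapply(profiles, .as_profile)
  t0 <- prs[[1]]$time_min
  if (!all(vapply(prs, function(p) identical(p$time_min, t0), logical(1))))
    stop("replicate profiles must share identical timepoints")
  transfer_profile(t0, rowMeans(vapply(prs, function(p) p$cumulative_percent,
                                       numeric(length(t0)))))
}
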