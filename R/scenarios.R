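#' Scenario sweeps for Transwell assay optimization
#'
#' Scripted parameter sweeps over the simulation model. Each runner takes a
#' base configuration, varies one experimental factor while holding
#' everything else fixed, and summarizes every run by its Weibull MDT
#' (plus f1/f2 verdicts where a solution reference is meaningful). Runners
#' never mutate the base configuration.
#'
#' @param config Base \code{\link{experiment_config}} (with a PSD, except
#'   where noted).
#' @param solubilities Solubilities to sweep, ug/mL.
#' @return An object of class \code{"scenario_result"}: list with
#'   \code{scenario_name}, \code{sweep_variable}, \code{sweep_values},
#'   \code{mdt_hours}, \code{profiles} and scenario-specific extras.
#' @name scenarios
NULL

.scenario_result <- function(name, variable, values, mdt_hours, profiles, ...) {
  stopifnot(length(values) == length(mdt_hours), all(mdt_hours > 0))
  structure(list(scenario_name = name, sweep_variable = variable,
                 sweep_values = values, mdt_hours = mdt_hours,
                 profiles = profiles, ...),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: %s (sweep over %s)\n", x$scenario_name,
              x$sweep_variable))
  df <- data.frame(value = x$sweep_values, mdt_h = signif(x$mdt_hours, 4))
  if (!is.null(x$verdicts)) {
    df$f1 <- signif(vapply(x$verdicts, `[[`, numeric(1), "f1"), 3)
    df$f2 <- signif(vapply(x$verdicts, `[[`, numeric(1), "f2"), 3)
    df$verdict <- vapply(x$verdicts, `[[`, character(1), "verdict")
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname scenarios
#' @details \code{solubility_sweep} identifies the solubility below which
#'   particle transfer profiles become distinguishable from the matched
#'   solution (diffusion-only) profile: each particle run is compared with
#'   the solution run by f1/f2.
#' @export
solubility_sweep <- function(config, solubilities = c(40, 60, 80, 100, 250, 500)) {
  stopifnot(inherits(config, "experiment_config"), !is.null(config$psd))
  sol_cfg <- config; sol_cfg$psd <- NULL
  reference <- transwell_sim(sol_cfg)$observed
  runs <- lapply(solubilities, function(cs) {
    cfg <- config; cfg$medium$solubility <- cs
    transwell_sim(cfg)
  })
  profiles <- lapply(runs, `[[`, "observed")
  names(profiles) <- paste0("Cs", solubilities)
  .scenario_result(
    "solubility", "solubility (ug/mL)", solubilities,
    vapply(runs, function(s) fit_weibull(s)$mdt_hours, numeric(1)),
    profiles,
    verdicts = lapply(profiles, function(p) f1_f2(reference, p)),
    reference = reference,
    reference_mdt_hours = fit_weibull(reference)$mdt_hours)
}

#' @rdname scenarios
#' @param donor_volumes Donor volumes to sweep, mL; the receptor volume is
#'   hydrostatically matched to each via \code{\link{match_receptor_volume}}.
#' @export
volume_sweep <- function(config, donor_volumes = c(0.1, 0.2, 0.5, 1, 2, 3)) {
  stopifnot(inherits(config, "experiment_config"))
  runs <- lapply(donor_volumes, function(vd) {
    cfg <- config
    cfg$donor_volume <- vd
    cfg$receptor_volume <- match_receptor_volume(vd, cfg$geometry)
    transwell_sim(cfg)
  })
  .scenario_result(
    "donor/receptor volumes", "donor volume (mL)", donor_volumes,
    vapply(runs, function(s) fit_weibull(s)$mdt_hours, numeric(1)),
    stats::setNames(lapply(runs, `[[`, "observed"),
                    paste0("Vd", donor_volumes)),
    receptor_volumes = vapply(runs, function(s) s$config$receptor_volume,
                              numeric(1)),
    peak_donor_concentration = vapply(runs, function(s)
      max(s$donor_concentration), numeric(1)))
}

#' @rdname scenarios
#' @param sampling_volumes Sampling volumes to sweep, mL (0 = observation
#'   without removal).
#' @export
sampling_volume_sweep <- function(config,
                                  sampling_volumes = c(0.1, 0.2, 0.5, 1, 1.5, 2)) {
  stopifnot(inherits(config, "experiment_config"))
  runs <- lapply(sampling_volumes, function(vs) {
    cfg <- config
    cfg$schedule <- sampling_schedule(cfg$schedule$times, vs)
    if (vs > cfg$receptor_volume)
      stop("sampling volume ", vs, " mL exceeds the receptor volume")
    transwell_sim(cfg)
  })
  .scenario_result(
    "sampling volume", "sampling volume (mL)", sampling_volumes,
    vapply(runs, function(s) fit_weibull(s)$mdt_hours, numeric(1)),
    stats::setNames(lapply(runs, `[[`, "observed"),
                    paste0("Vs", sampling_volumes)),
    peak_donor_concentration = vapply(runs, function(s)
      max(s$donor_concentration), numeric(1)))
}

#' @rdname scenarios
#' @param scale_factors Diameter multipliers applied to the base PSD.
#' @details \code{psd_resolution_study} measures how well the assay
#'   separates formulations that differ only in particle size, as a
#'   function of medium solubility: for each solubility it simulates the
#'   base PSD scaled by each factor and reports the MDT matrix together
#'   with the relative MDT spread (max - min over the factors, divided by
#'   the unscaled MDT) — larger spread means better size resolution.
#' @export
psd_resolution_study <- function(config, scale_factors = c(0.5, 1, 2),
                                 solubilities = c(5.3, 19.12)) {
  stopifnot(inherits(config, "experiment_config"), !is.null(config$psd))
  mdt <- matrix(NA_real_, length(scale_factors), length(solubilities),
                dimnames = list(paste0("x", scale_factors), solubilities))
  profiles <- list()
  for (j in seq_along(solubilities)) for (i in seq_along(scale_factors)) {
    cfg <- config
    cfg$medium$solubility <- solubilities[j]
    cfg$psd <- scale_psd(config$psd, scale_factors[i])
    sim <- transwell_sim(cfg)
    mdt[i, j] <- fit_weibull(sim)$mdt_hours
    profiles[[paste0("x", scale_factors[i], "_Cs", solubilities[j])]] <-
      sim$observed
  }
  base_row <- which(scale_factors == 1)
  spread <- apply(mdt, 2, function(col)
    (max(col) - min(col)) / if (length(base_row)) col[base_row] else mean(col))
  .scenario_result(
    "PSD resolution", "solubility (ug/mL)", solubilities,
    if (length(base_row)) mdt[base_row, ] else colMeans(mdt),
    profiles, mdt_matrix = mdt, scale_factors = scale_factors,
    relative_spread = spread)
}

#' Default mass-effect scenario volume sets
#'
#' Four donor/receptor/sampling volume combinations used to study how the
#' apparent MDT grows with the deposited dose (the "mass effect"):
#' scenario 1 is the small-volume bench default; scenarios 2-4 enlarge the
#' compartments and then the sampling volume.
#' @return A data frame with columns \code{scenario}, \code{donor_volume},
#'   \code{receptor_volume}, \code{sample_volume}.
#' @export
mass_effect_scenarios <- function() {
  data.frame(scenario = 1:4,
             donor_volume = c(0.58, 3, 3, 3),
             receptor_volume = c(1.5, 3.31, 3.31, 3.31),
             sample_volume = c(0.5, 0.5, 1, 2))
}

#' @rdname scenarios
#' @param doses Initial drug amounts to sweep, ug.
#' @param scenarios Volume sets, as from \code{\link{mass_effect_scenarios}}.
#' @details \code{mass_effect_study} quantifies the mass effect per volume
#'   scenario as the MDT(30 ug)/MDT(10 ug) ratio (when both doses are in
#'   the sweep).
#' @export
mass_effect_study <- function(config, doses = c(10, 20, 30, 40, 50, 60),
                              scenarios = mass_effect_scenarios()) {
  stopifnot(inherits(config, "experiment_config"), !is.null(config$psd))
  mdt <- matrix(NA_real_, length(doses), nrow(scenarios),
                dimnames = list(doses, paste0("scenario", scenarios$scenario)))
  profiles <- list()
  for (j in seq_len(nrow(scenarios))) for (i in seq_along(doses)) {
    cfg <- experiment_config(
      initial_amount = doses[i],
      donor_volume = scenarios$donor_volume[j],
      receptor_volume = scenarios$receptor_volume[j],
      psd = config$psd,
      correction_factor = config$correction_factor,
      drug = config$drug, medium = config$medium,
      schedule = sampling_schedule(config$schedule$times,
                                   scenarios$sample_volume[j]),
      geometry = config$geometry, solver = config$solver)
    sim <- transwell_sim(cfg)
    mdt[i, j] <- fit_weibull(sim)$mdt_hours
    profiles[[paste0("s", scenarios$scenario[j], "_", doses[i], "ug")]] <-
      sim$observed
  }
  ratios <- if (all(c(10, 30) %in% doses))
    mdt[as.character(30), ] / mdt[as.character(10), ] else NULL
  .scenario_result(
    "mass effect", "dose (ug)", doses, rowMeans(mdt), profiles,
    mdt_matrix = mdt, scenarios = scenarios, ratio_30_10 = ratios)
}
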