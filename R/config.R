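#' Hayduk-Laudie estimate of the aqueous diffusion coefficient
#'
#' \deqn{D = 13.26\times 10^{-5} / (\eta^{1.14} V_M^{0.589})} in cm^2/s,
#' with \eqn{\eta} the water viscosity in cP and \eqn{V_M} the solute molar
#' volume in cm^3/mol; the result is returned in cm^2/h (the unit the
#' simulator uses). The viscosity exponent defaults to the literature value
#' 1.14 but is configurable.
#'
#' @param eta Water viscosity at the working temperature, cP.
#' @param molecular_volume Solute molar volume, cm^3/mol.
#' @param exponent Viscosity exponent.
#' @return Diffusion coefficient, cm^2/h.
#' @examples
#' hayduk_laudie_D(0.6913, 313.5)  # ~0.02 cm^2/h at 37 C
#' @export
hayduk_laudie_D <- function(eta, molecular_volume, exponent = 1.14) {
  if (!is.finite(eta) || eta <= 0 || !is.finite(molecular_volume) ||
      molecular_volume <= 0)
    stop("eta and molecular_volume must be strictly positive")
  13.26e-5 / (eta^exponent * molecular_volume^0.589) * 3600
}

#' Drug transport and particle properties
#'
#' @param permeability Membrane permeability coefficient P, cm/h. The
#'   calibrated default (0.289 cm/h) is for fluticasone propionate across a
#'   stirred 0.4 um polycarbonate Transwell membrane.
#' @param diffusion_coefficient Aqueous diffusion coefficient D, cm^2/h.
#'   Default 0.022284 cm^2/h (0.0003714 cm^2/min). If \code{NULL}, it is
#'   computed by \code{\link{hayduk_laudie_D}} from \code{water_viscosity}
#'   and \code{molecular_volume}.
#' @param water_viscosity Water viscosity, cP (used only when
#'   \code{diffusion_coefficient} is \code{NULL}).
#' @param molecular_volume Molar volume, cm^3/mol (idem).
#' @param density Particle density, g/cm^3.
#' @param shape_factor Dynamic shape factor.
#' @return An object of class \code{"drug_properties"}.
#' @export
drug_properties <- function(permeability = 0.289,
                            diffusion_coefficient = 0.022284,
                            water_viscosity = NULL,
                            molecular_volume = NULL,
                            density = 1.37,
                            shape_factor = 1) {
  if (is.null(diffusion_coefficient)) {
    if (is.null(water_viscosity) || is.null(molecular_volume))
      stop("give diffusion_coefficient, or both water_viscosity and molecular_volume")
    diffusion_coefficient <- hayduk_laudie_D(water_viscosity, molecular_volume)
  }
  vals <- c(diffusion_coefficient = diffusion_coefficient,
            density = density, shape_factor = shape_factor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all drug properties must be strictly positive")
  # P = 0 is a valid degenerate case (impermeable membrane)
  if (!is.finite(permeability) || permeability < 0)
    stop("permeability must be non-negative")
  structure(list(permeability = permeability,
                 diffusion_coefficient = diffusion_coefficient,
                 water_viscosity = water_viscosity,
                 molecular_volume = molecular_volume,
                 density = density, shape_factor = shape_factor),
            class = "drug_properties")
}

#' Dissolution-medium properties
#'
#' @param solubility Saturation solubility of the drug in the medium, ug/mL.
#' @param label Free-text medium description (e.g. "0.5% Tween 80").
#' @return An object of class \code{"medium_properties"}.
#' @export
medium_properties <- function(solubility, label = "") {
  if (!is.finite(solubility) || solubility <= 0)
    stop("solubility must be strictly positive")
  structure(list(solubility = solubility, label = label),
            class = "medium_properties")
}

#' Sampling schedules
#'
#' At each scheduled time a fixed aliquot \code{sample_volume} is withdrawn
#' from the receptor and replaced with the same volume of fresh medium, so
#' the receptor volume stays constant while drug is removed from the system.
#' \code{dissolution_schedule} is the 13-point 24 h bench schedule;
#' \code{diffusion_schedule} the 9-point 4 h schedule used for solution
#' (diffusion-only) experiments; \code{hourly_schedule} the denser variant
#' with hourly sampling from 2 h onward.
#'
#' @param times Strictly increasing positive sampling times, minutes.
#' @param sample_volume Aliquot volume Vs, mL (0 disables removal).
#' @param replacement_volume Fresh-medium volume returned after each sample,
#'   mL; must equal \code{sample_volume} (replacement keeps the receptor
#'   volume constant).
#' @return An object of class \code{"sampling_schedule"}.
#' @export
sampling_schedule <- function(times = c(10, 20, 30, 45, 60, 90, 120, 180,
                                        240, 360, 480, 720, 1440),
                              sample_volume = 0.5,
                              replacement_volume = sample_volume) {
  if (length(times) < 1 || any(!is.finite(times)) || any(times <= 0) ||
      any(diff(times) <= 0))
    stop("sampling times must be strictly increasing and positive")
  if (!is.finite(sample_volume) || sample_volume < 0)
    stop("sample_volume must be non-negative")
  if (!isTRUE(all.equal(replacement_volume, sample_volume)))
    stop("replacement_volume must equal sample_volume (constant receptor volume)")
  structure(list(times = as.numeric(times), sample_volume = sample_volume,
                 replacement_volume = replacement_volume),
            class = "sampling_schedule")
}

#' @rdname sampling_schedule
#' @export
diffusion_schedule <- function(sample_volume = 0.5)
  sampling_schedule(c(10, 20, 30, 45, 60, 90, 120, 180, 240), sample_volume)

#' @rdname sampling_schedule
#' @export
hourly_schedule <- function(sample_volume = 0.5)
  sampling_schedule(c(10, 20, 30, 45, 60, 90, seq(120, 1440, by = 60)),
                    sample_volume)

#' Transwell experiment configuration
#'
#' Bundles everything one simulated dissolution (or diffusion) run needs.
#' When \code{psd} is \code{NULL} the run is a solution experiment: the whole
#' \code{initial_amount} starts dissolved in the donor. Otherwise the
#' amount starts as undissolved particles distributed over the PSD bins (the
#' PSD is rescaled to \code{initial_amount} if needed).
#'
#' @param initial_amount Drug amount placed in the donor at t = 0, ug.
#' @param donor_volume Donor medium volume Vd, mL.
#' @param receptor_volume Receptor medium volume Vr, mL; if \code{NULL} it is
#'   hydrostatically matched via \code{\link{match_receptor_volume}}.
#' @param psd A \code{\link{build_psd}} object, or \code{NULL} for a solution
#'   run.
#' @param correction_factor Multiplicative correction F on the
#'   Nernst-Brunner dissolution rate, absorbing stagnant-layer,
#'   surface-accessibility and agglomeration effects of the filter-sandwich
#'   geometry. The calibrated default is 0.0244.
#' @param drug A \code{\link{drug_properties}}.
#' @param medium A \code{\link{medium_properties}}.
#' @param schedule A \code{\link{sampling_schedule}}.
#' @param geometry An \code{\link{apparatus_geometry}}.
#' @param solver List of solver settings: \code{method} (deSolve method),
#'   \code{rtol}, \code{atol}, \code{dense_dt} (dense output step, minutes).
#' @return An object of class \code{"experiment_config"}.
#' @examples
#' cfg <- experiment_config(initial_amount = 100, donor_volume = 0.58,
#'                          receptor_volume = 1.5,
#'                          medium = medium_properties(5.3),
#'                          schedule = diffusion_schedule())
#' @export
experiment_config <- function(initial_amount,
                              donor_volume = 0.58,
                              receptor_volume = NULL,
                              psd = NULL,
                              correction_factor = 0.0244,
                              drug = drug_properties(),
                              medium = medium_properties(5.3, "0.5% Tween 80"),
                              schedule = sampling_schedule(),
                              geometry = apparatus_geometry(),
                              solver = list()) {
  stopifnot(inherits(drug, "drug_properties"),
            inherits(medium, "medium_properties"),
            inherits(schedule, "sampling_schedule"),
            inherits(geometry, "apparatus_geometry"))
  if (!is.finite(initial_amount) || initial_amount <= 0)
    stop("initial_amount must be strictly positive")
  if (!is.finite(donor_volume) || donor_volume <= 0)
    stop("donor_volume must be strictly positive")
  if (is.null(receptor_volume))
    receptor_volume <- match_receptor_volume(donor_volume, geometry)
  if (!is.finite(receptor_volume) || receptor_volume <= 0)
    stop("receptor_volume must be strictly positive")
  if (schedule$sample_volume > receptor_volume)
    stop("sample_volume exceeds the receptor volume")
  if (!is.finite(correction_factor) || correction_factor <= 0)
    stop("correction_factor must be strictly positive")
  if (!is.null(psd)) {
    stopifnot(inherits(psd, "psd"))
    if (abs(psd$total_mass - initial_amount) > 1e-9 * initial_amount) {
      scale <- initial_amount / psd$total_mass
      psd$bins$mass_ug <- psd$bins$mass_ug * scale
      psd$bins$particle_count <- psd$bins$particle_count * scale
      psd$total_mass <- initial_amount
    }
  }
  sv <- list(method = "lsoda", rtol = 1e-9, atol = 1e-9, dense_dt = 1)
  sv[names(solver)] <- solver
  structure(list(initial_amount = initial_amount,
                 donor_volume = donor_volume,
                 receptor_volume = receptor_volume,
                 psd = psd,
                 correction_factor = correction_factor,
                 drug = drug, medium = medium, schedule = schedule,
                 geometry = geometry, solver = sv),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Transwell experiment configuration\n")
  cat(sprintf("  initial amount : %.4g ug (%s)\n", x$initial_amount,
              if (is.null(x$psd)) "solution" else
                sprintf("particles, %d bins", nrow(x$psd$bins))))
  cat(sprintf("  volumes        : Vd = %.3g mL, Vr = %.4g mL, Vs = %.3g mL\n",
              x$donor_volume, x$receptor_volume, x$schedule$sample_volume))
  cat(sprintf("  medium         : Cs = %.4g ug/mL %s\n", x$medium$solubility,
              x$medium$label))
  cat(sprintf("  drug           : P = %.4g cm/h, D = %.4g cm2/h, rho = %.3g g/cm3\n",
              x$drug$permeability, x$drug$diffusion_coefficient,
              x$drug$density))
  cat(sprintf("  correction F   : %.4g\n", x$correction_factor))
  cat(sprintf("  sampling       : %d timepoints, %g to %g min\n",
              length(x$schedule$times), min(x$schedule$times),
              max(x$schedule$times)))
  invisible(x)
}

#' Read an experiment configuration from a YAML or JSON file
#'
#' The file may contain sections \code{run}, \code{drug}, \code{medium},
#' \code{schedule} and \code{geometry}; each maps directly onto the
#' arguments of the corresponding constructor, and missing fields fall back
#' to the constructor defaults. The \code{run} section holds
#' \code{initial_amount}, \code{donor_volume}, optional
#' \code{receptor_volume}, \code{correction_factor}, optional
#' \code{stage_table} (path to a stage-deposition CSV, resolved relative to
#' the config file) and optional \code{solver} settings.
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @param psd Optional \code{"psd"} object overriding any stage table named
#'   in the file.
#' @return An \code{"experiment_config"}.
#' @export
read_experiment_config <- function(path, psd = NULL) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  run <- cfg$run %||% list()
  drug <- do.call(drug_properties, cfg$drug %||% list())
  med <- if (is.null(cfg$medium)) medium_properties(5.3, "0.5% Tween 80")
         else do.call(medium_properties, cfg$medium)
  sch <- if (is.null(cfg$schedule)) sampling_schedule()
         else do.call(sampling_schedule, cfg$schedule)
  geo <- do.call(apparatus_geometry, cfg$geometry %||% list())
  if (is.null(psd) && !is.null(run$stage_table)) {
    st <- run$stage_table
    if (!file.exists(st)) st <- file.path(dirname(path), st)
    psd <- build_psd(read_stage_table(st),
                     delivered_mass = run$initial_amount,
                     density = drug$density, shape_factor = drug$shape_factor)
  }
  experiment_config(
    initial_amount = run$initial_amount %||% stop("run$initial_amount is required"),
    donor_volume = run$donor_volume %||% 0.58,
    receptor_volume = run$receptor_volume,
    psd = psd,
    correction_factor = run$correction_factor %||% 0.0244,
    drug = drug, medium = med, schedule = sch, geometry = geo,
    solver = run$solver %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
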