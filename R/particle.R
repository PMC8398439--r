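#' Convert aerodynamic to geometric particle diameter
#'
#' Impactor stages classify particles by aerodynamic diameter; dissolution is
#' governed by the physical (geometric) size. For a sphere of density
#' \eqn{\rho} (g/cm^3) and dynamic shape factor \eqn{k},
#' \eqn{d_{geo} = d_{aero}\sqrt{k/\rho}} with \eqn{\rho} relative to unit
#' (water) density.
#'
#' @param d_aero Aerodynamic diameter (any length unit; output in the same
#'   unit).
#' @param shape_factor Dynamic shape factor \eqn{k}; 1 for spheres.
#' @param density Particle density in g/cm^3.
#' @return Geometric diameter, same unit as \code{d_aero}.
#' @examples
#' aero_to_geometric_diameter(3.7, 1, 1.37)  # 3.161 um
#' @export
aero_to_geometric_diameter <- function(d_aero, shape_factor = 1, density = 1.37) {
  if (any(!is.finite(d_aero)) || any(d_aero <= 0) ||
      !is.finite(shape_factor) || shape_factor <= 0 ||
      !is.finite(density) || density <= 0)
    stop("d_aero, shape_factor and density must all be strictly positive")
  d_aero * sqrt(shape_factor / density)
}

# radius (cm) and total surface area (cm^2) of a bin holding `mass_ug`
# spread over `n` identical spheres of density `density` (g/cm^3)
.bin_geometry <- function(mass_ug, n, density) {
  r <- ifelse(mass_ug > 0 & n > 0,
              (3 * (mass_ug * 1e-6) / (4 * pi * density * pmax(n, 1)))^(1 / 3),
              0)
  list(radius_cm = r, surface_area_cm2 = n * 4 * pi * r^2)
}

#' Radius and surface area of a particle bin at a given remaining mass
#'
#' The bin's particle count is fixed at initialization; as the bin dissolves,
#' every particle shrinks, so radius scales with the cube root of the
#' remaining mass: \eqn{r = (3X/(4\pi\rho N))^{1/3}}, \eqn{SA = 4\pi N r^2}.
#' An exhausted bin (zero mass) has zero radius and surface area.
#'
#' @param psd A \code{\link{build_psd}} object.
#' @param mass_remaining Remaining mass per bin in ug; defaults to the
#'   initial bin masses.
#' @return A data frame with columns \code{radius_cm} and
#'   \code{surface_area_cm2}, one row per bin.
#' @export
bin_geometry_at_mass <- function(psd, mass_remaining = psd$bins$mass_ug) {
  stopifnot(inherits(psd, "psd"))
  if (length(mass_remaining) != nrow(psd$bins) || any(mass_remaining < -1e-12))
    stop("mass_remaining must be one non-negative value per bin")
  g <- .bin_geometry(pmax(mass_remaining, 0), psd$bins$particle_count, psd$density)
  data.frame(radius_cm = g$radius_cm, surface_area_cm2 = g$surface_area_cm2)
}

#' Build a polydisperse particle-size distribution from stage depositions
#'
#' Each impactor stage becomes one monodisperse bin whose diameter is the
#' stage's calibrated aerodynamic cut-off converted to geometric diameter.
#' Stage masses are rescaled proportionally so that they sum to the amount of
#' drug actually delivered to the dissolution experiment (which preserves the
#' measured size-distribution shape), and a fixed particle count per bin is
#' derived from the initial bin mass and particle volume.
#'
#' @param stages A data frame with columns \code{stage} (integer index),
#'   \code{cutoff_um} (aerodynamic cut-off diameter, um, strictly decreasing
#'   with stage) and \code{mass_ug} (deposited mass, ug).
#' @param delivered_mass Total drug mass (ug) used in the dissolution
#'   experiment; stage masses are rescaled to sum to it. Defaults to the sum
#'   of the stage masses (no rescaling).
#' @param density Particle density, g/cm^3.
#' @param shape_factor Dynamic shape factor.
#' @return An object of class \code{"psd"}: a list with elements
#'   \code{bins} (data frame: stage, cutoff_um, geo_diameter_um,
#'   geo_radius_cm, mass_ug, particle_count), \code{total_mass} (ug),
#'   \code{density}, \code{shape_factor}.
#' @examples
#' stages <- data.frame(stage = 1:3, cutoff_um = c(4.46, 2.82, 1.66),
#'                      mass_ug = c(5, 10, 5))
#' build_psd(stages, delivered_mass = 23)
#' @export
build_psd <- function(stages, delivered_mass = NULL, density = 1.37,
                      shape_factor = 1) {
  req <- c("stage", "cutoff_um", "mass_ug")
  if (!is.data.frame(stages) || !all(req %in% names(stages)))
    stop("stages must be a data frame with columns stage, cutoff_um, mass_ug")
  stages <- stages[order(stages$stage), , drop = FALSE]
  if (any(diff(stages$cutoff_um) >= 0))
    stop("cut-off diameters must be strictly decreasing with stage index")
  if (any(stages$mass_ug < 0) || any(stages$cutoff_um <= 0))
    stop("cut-offs must be positive and masses non-negative")
  if (all(stages$mass_ug == 0))
    stop("degenerate input: all stage masses are zero")
  if (is.null(delivered_mass)) delivered_mass <- sum(stages$mass_ug)
  if (!is.finite(delivered_mass) || delivered_mass <= 0)
    stop("delivered_mass must be strictly positive")

  mass <- stages$mass_ug * delivered_mass / sum(stages$mass_ug)
  d_geo_um <- aero_to_geometric_diameter(stages$cutoff_um, shape_factor, density)
  r0 <- d_geo_um * 1e-4 / 2  # um -> cm
  n <- ifelse(mass > 0, (mass * 1e-6) / ((4 / 3) * pi * r0^3 * density), 0)

  structure(list(
    bins = data.frame(stage = stages$stage,
                      cutoff_um = stages$cutoff_um,
                      geo_diameter_um = d_geo_um,
                      geo_radius_cm = r0,
                      mass_ug = mass,
                      particle_count = n),
    total_mass = delivered_mass,
    density = density,
    shape_factor = shape_factor
  ), class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf(
    "Particle size distribution: %d bins, %.4g ug total (rho = %.3g g/cm^3, k = %.3g)\n",
    nrow(x$bins), x$total_mass, x$density, x$shape_factor))
  df <- x$bins
  df$particle_count <- signif(df$particle_count, 4)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Scale a particle-size distribution
#'
#' Produces a hypothetical formulation whose particles are \code{factor}
#' times the diameter of the input at the same bin masses; particle counts
#' rescale by \code{factor^-3} so bin masses are conserved.
#'
#' @param psd A \code{"psd"} object.
#' @param factor Positive diameter multiplier.
#' @return A \code{"psd"} object.
#' @export
scale_psd <- function(psd, factor) {
  stopifnot(inherits(psd, "psd"))
  if (!is.finite(factor) || factor <= 0) stop("factor must be > 0")
  psd$bins$cutoff_um <- psd$bins$cutoff_um * factor
  psd$bins$geo_diameter_um <- psd$bins$geo_diameter_um * factor
  psd$bins$geo_radius_cm <- psd$bins$geo_radius_cm * factor
  psd$bins$particle_count <- psd$bins$particle_count / factor^3
  psd
}

#' Default NGI stage cut-off diameters
#'
#' Calibrated cut-off diameters (um) of Next-Generation Impactor stages 1-7
#' at a 60 L/min flow rate.
#' @return Numeric vector of 7 strictly decreasing cut-offs.
#' @export
ngi_cutoffs <- function() c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34)

#' Synthetic lognormal stage-deposition pattern
#'
#' Generates the stage masses an impactor would collect from an aerosol with
#' a lognormal aerodynamic mass distribution (mass-median aerodynamic
#' diameter \code{mmad}, geometric standard deviation \code{gsd}): the
#' lognormal mass density is integrated analytically between consecutive
#' cut-offs (stage i collects the mass between its own cut-off and the next
#' larger one; stage 1 collects everything above its cut-off; mass below the
#' last cut-off is treated as lost to the micro-orifice collector and
#' excluded), then normalized to \code{total_mass}. The result is
#' deterministic; optional multiplicative jitter emulates between-run
#' deposition noise.
#'
#' @param mmad Mass-median aerodynamic diameter, um.
#' @param gsd Geometric standard deviation (> 1).
#' @param cutoffs Strictly decreasing stage cut-offs, um.
#' @param total_mass Total deposited mass, ug.
#' @param density,shape_factor Passed to \code{\link{build_psd}}.
#' @param jitter_cv Coefficient of variation (percent) of multiplicative
#'   lognormal jitter applied to stage masses before normalization; 0 (the
#'   default) disables jitter.
#' @param seed Integer seed, used only when \code{jitter_cv > 0}.
#' @return A \code{"psd"} object.
#' @examples
#' psd <- synthetic_psd(mmad = 3.7, gsd = 1.8, total_mass = 23)
#' psd_mmad(psd)
#' @export
synthetic_psd <- function(mmad = 3.7, gsd = 1.8, cutoffs = ngi_cutoffs(),
                          total_mass = 23, density = 1.37, shape_factor = 1,
                          jitter_cv = 0, seed = NULL) {
  if (!is.finite(mmad) || mmad <= 0) stop("mmad must be > 0")
  if (!is.finite(gsd) || gsd <= 1) stop("gsd must be > 1")
  if (length(cutoffs) < 2 || any(diff(cutoffs) >= 0) || any(cutoffs <= 0))
    stop("cutoffs must be at least two strictly decreasing positive diameters")
  mu <- log(mmad); sdl <- log(gsd)
  upper <- c(Inf, cutoffs[-length(cutoffs)])
  frac <- stats::plnorm(upper, mu, sdl) - stats::plnorm(cutoffs, mu, sdl)
  if (jitter_cv > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    sig <- sqrt(log(1 + (jitter_cv / 100)^2))
    frac <- frac * exp(stats::rnorm(length(frac), -sig^2 / 2, sig))
  }
  stages <- data.frame(stage = seq_along(cutoffs), cutoff_um = cutoffs,
                       mass_ug = frac)
  build_psd(stages, delivered_mass = total_mass, density = density,
            shape_factor = shape_factor)
}

#' Mass-median aerodynamic diameter of a binned distribution
#'
#' Interpolates the cumulative mass-undersize curve at the stage cut-offs on
#' a log-diameter scale (the standard impactor reduction) and returns the
#' 50\% diameter.
#'
#' @param psd A \code{"psd"} object.
#' @return MMAD in um.
#' @export
psd_mmad <- function(psd) {
  stopifnot(inherits(psd, "psd"))
  b <- psd$bins[order(psd$bins$cutoff_um), ]
  # cumulative fraction strictly below each cut-off, smallest first
  under <- c(0, cumsum(b$mass_ug))[seq_len(nrow(b))] / sum(b$mass_ug)
  ok <- !duplicated(under)
  if (sum(ok) < 2 || max(under) < 0.5)
    stop("cannot interpolate the 50% diameter from this distribution")
  exp(stats::approx(under[ok], log(b$cutoff_um[ok]), xout = 0.5)$y)
}

#' Read / write stage-deposition tables
#'
#' CSV format with exactly the columns \code{stage}, \code{cutoff_um},
#' \code{mass_ug}.
#'
#' @param path File path.
#' @return \code{read_stage_table}: a data frame suitable for
#'   \code{\link{build_psd}}.
#' @export
read_stage_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("stage", "cutoff_um", "mass_ug")))
    stop("stage table must have header: stage,cutoff_um,mass_ug")
  df
}

#' @rdname read_stage_table
#' @param psd A \code{"psd"} object to serialize.
#' @export
write_stage_table <- function(psd, path) {
  stopifnot(inherits(psd, "psd"))
  utils::write.csv(
    data.frame(stage = psd$bins$stage, cutoff_um = psd$bins$cutoff_um,
               mass_ug = psd$bins$mass_ug),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
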