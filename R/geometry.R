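#' Transwell apparatus geometry
#'
#' Dimensional constants of the 24 mm Transwell insert/well system used to
#' relate fluid volumes to fluid heights in the two compartments. The donor
#' compartment (insert) fills at \code{donor_vol_per_mm} mL per mm of fluid
#' rise; the receptor annulus (the well space above the level of the insert
#' membrane) fills at \code{receptor_annulus_vol_per_mm} mL per mm;
#' \code{receptor_min_volume} is the dead volume below the membrane that must
#' be filled before the receptor fluid contacts the insert.
#'
#' @param membrane_area Insert membrane area in cm^2.
#' @param donor_vol_per_mm Donor fill rate, mL per mm of height.
#' @param receptor_annulus_vol_per_mm Receptor fill rate above the membrane
#'   level, mL per mm of height.
#' @param receptor_min_volume Receptor dead volume below the membrane, mL.
#' @param filter_volume Volume of the particle-collection filter paper placed
#'   in the donor compartment, mL. May be zero when no filter is used.
#' @param membrane_wetting_volume Volume needed to wet the polycarbonate
#'   membrane, mL. May be zero.
#' @param donor_max_volume,receptor_max_volume Compartment capacities, mL.
#'
#' @return An object of class \code{"apparatus_geometry"}.
#' @examples
#' geom <- apparatus_geometry()
#' match_receptor_volume(0.58, geom)
#' @export
apparatus_geometry <- function(membrane_area = 4.52,
                               donor_vol_per_mm = 0.47,
                               receptor_annulus_vol_per_mm = 0.35,
                               receptor_min_volume = 0.86,
                               filter_volume = 0.118,
                               membrane_wetting_volume = 0.1,
                               donor_max_volume = 4.52,
                               receptor_max_volume = 4.18) {
  g <- list(
    membrane_area = membrane_area,
    donor_vol_per_mm = donor_vol_per_mm,
    receptor_annulus_vol_per_mm = receptor_annulus_vol_per_mm,
    receptor_min_volume = receptor_min_volume,
    filter_volume = filter_volume,
    membrane_wetting_volume = membrane_wetting_volume,
    donor_max_volume = donor_max_volume,
    receptor_max_volume = receptor_max_volume
  )
  for (nm in names(g)) {
    v <- g[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("geometry field '", nm, "' must be a single finite number")
  }
  # filter paper and wetting volume may legitimately be absent (zero)
  strict <- setdiff(names(g), c("filter_volume", "membrane_wetting_volume"))
  if (any(unlist(g[strict]) <= 0))
    stop("geometry dimensions must be strictly positive")
  if (g$filter_volume < 0 || g$membrane_wetting_volume < 0)
    stop("filter_volume and membrane_wetting_volume must be non-negative")
  structure(g, class = "apparatus_geometry")
}

#' @export
print.apparatus_geometry <- function(x, ...) {
  cat("Transwell apparatus geometry\n")
  cat(sprintf("  membrane area        : %.3g cm^2\n", x$membrane_area))
  cat(sprintf("  donor fill rate      : %.3g mL/mm (max %.3g mL)\n",
              x$donor_vol_per_mm, x$donor_max_volume))
  cat(sprintf("  receptor fill rate   : %.3g mL/mm above %.3g mL minimum (max %.3g mL)\n",
              x$receptor_annulus_vol_per_mm, x$receptor_min_volume,
              x$receptor_max_volume))
  cat(sprintf("  filter / wetting vol : %.3g / %.3g mL\n",
              x$filter_volume, x$membrane_wetting_volume))
  invisible(x)
}

#' Hydrostatically matched receptor volume
#'
#' Computes the receptor-compartment volume that puts the receptor fluid
#' level at the same height as the donor fluid level, so that no hydrostatic
#' pressure difference drives bulk flow across the membrane:
#' \deqn{V_r = \frac{V_d + V_f}{q_d} q_r + V_{r,min} + W_v}
#' where \eqn{q_d} and \eqn{q_r} are the donor and receptor fill rates
#' (mL/mm), \eqn{V_f} the filter-paper volume and \eqn{W_v} the membrane
#' wetting volume. The donor fluid height is \eqn{(V_d + V_f)/q_d} mm; the
#' matched receptor holds its dead volume, the wetting volume, and the same
#' height of annulus fill.
#'
#' @param donor_volume Donor medium volume \eqn{V_d} in mL (>= 0).
#' @param geometry An \code{\link{apparatus_geometry}}.
#' @return Matched receptor volume in mL.
#' @examples
#' match_receptor_volume(0.58)  # ~1.48 mL; used with 1.5 mL at the bench
#' match_receptor_volume(3.0)   # ~3.28 mL
#' @export
match_receptor_volume <- function(donor_volume, geometry = apparatus_geometry()) {
  stopifnot(inherits(geometry, "apparatus_geometry"))
  if (!is.numeric(donor_volume) || any(!is.finite(donor_volume)) ||
      any(donor_volume < 0))
    stop("donor_volume must be non-negative")
  if (any(donor_volume + geometry$filter_volume > geometry$donor_max_volume + 1e-12))
    stop("donor compartment capacity exceeded (", geometry$donor_max_volume,
         " mL including filter volume)")
  vr <- (donor_volume + geometry$filter_volume) / geometry$donor_vol_per_mm *
    geometry$receptor_annulus_vol_per_mm +
    geometry$receptor_min_volume + geometry$membrane_wetting_volume
  if (any(vr > geometry$receptor_max_volume + geometry$membrane_wetting_volume + 1e-12))
    stop("matched receptor volume ", round(max(vr), 3),
         " mL exceeds receptor capacity")
  vr
}
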