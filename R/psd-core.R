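# Lognormal particle-size distributions and diameter/density conversions.

#' Lognormal particle-size distribution
#'
#' Constructs a lognormal PSD described by its median diameter and geometric
#' standard deviation (GSD). The `basis` records whether the distribution
#' weights particle number or particle mass, and `diameter_kind` whether the
#' diameter scale is physical or aerodynamic. A mass-basis aerodynamic
#' distribution is the usual (MMAD, GSD) pair reported for impactor data; a
#' number-basis physical distribution is the (CMD, GSD) pair reported by
#' mobility sizers.
#'
#' @param median_diameter Median diameter in micrometres (> 0).
#' @param gsd Geometric standard deviation, dimensionless (>= 1); 1 denotes a
#'   monodisperse aerosol.
#' @param basis `"number"` or `"mass"`.
#' @param diameter_kind `"physical"` or `"aerodynamic"`.
#'
#' @return An object of class `"lognormal_psd"`.
#' @examples
#' lognormal_psd(0.93, 1.43, basis = "mass", diameter_kind = "aerodynamic")
#' @export
lognormal_psd <- function(median_diameter, gsd,
                          basis = c("mass", "number"),
                          diameter_kind = c("aerodynamic", "physical")) {
  check_scalar_positive(median_diameter, "median_diameter")
  if (!is.numeric(gsd) || length(gsd) != 1L || is.na(gsd) || gsd < 1) {
    abort_invalid("`gsd` must be a single number >= 1")
  }
  basis <- match.arg(basis)
  diameter_kind <- match.arg(diameter_kind)
  structure(
    list(median_diameter = median_diameter, gsd = gsd,
         basis = basis, diameter_kind = diameter_kind),
    class = "lognormal_psd"
  )
}

#' @export
print.lognormal_psd <- function(x, ...) {
  label <- if (x$basis == "mass") {
    if (x$diameter_kind == "aerodynamic") "MMAD" else "MMD"
  } else {
    "CMD"
  }
  cat(sprintf("Lognormal PSD (%s basis, %s diameter)\n", x$basis, x$diameter_kind))
  cat(sprintf("  %s = %.4g um, GSD = %.4g\n", label, x$median_diameter, x$gsd))
  invisible(x)
}

#' E-liquid formulation descriptor
#'
#' Describes an e-liquid by its propylene glycol (PG) and vegetable glycerin
#' (VG) humectant mass fractions, an additive flag, and the effective droplet
#' density used for aerodynamic conversion. Additives present at a few
#' percent (nicotine, flavourings, water/ethanol) are folded into the
#' humectant fractions.
#'
#' @param pg_fraction,vg_fraction Humectant mass fractions in `[0, 1]`; must
#'   sum to 1 within `tol`.
#' @param additive One of `"none"`, `"flavorings"`, `"nicotine"`.
#' @param effective_density Droplet density in g/cm^3; defaults to the
#'   fraction-weighted humectant density via [humectant_density()].
#' @param tol Tolerance on the fraction sum.
#'
#' @return An object of class `"eliquid"`.
#' @examples
#' eliquid(0.3, 0.7)                       # 30:70 PG:VG, density 1.19 g/cm3
#' eliquid(0.7, 0.3, additive = "nicotine")
#' @export
eliquid <- function(pg_fraction, vg_fraction,
                    additive = c("none", "flavorings", "nicotine"),
                    effective_density = NULL, tol = 0.05) {
  additive <- match.arg(additive)
  if (abs(pg_fraction + vg_fraction - 1) > tol) {
    abort_invalid("`pg_fraction` and `vg_fraction` must sum to 1")
  }
  if (is.null(effective_density)) {
    effective_density <- humectant_density(pg_fraction, vg_fraction)
  }
  check_scalar_positive(effective_density, "effective_density")
  structure(
    list(pg_fraction = pg_fraction, vg_fraction = vg_fraction,
         additive = additive, effective_density = effective_density),
    class = "eliquid"
  )
}

#' @export
print.eliquid <- function(x, ...) {
  cat(sprintf("E-liquid %d:%d PG:VG%s, effective density %.3f g/cm3\n",
              round(100 * x$pg_fraction), round(100 * x$vg_fraction),
              if (x$additive == "none") "" else paste0(" w/", x$additive),
              x$effective_density))
  invisible(x)
}

#' Hatch-Choate conversion from count median to mass median diameter
#'
#' Converts the count median diameter (CMD) of a lognormal distribution to
#' the median diameter of its b-th moment-weighted distribution:
#' `CMD * exp(b * ln(GSD)^2)`. With the default moment order `b = 3` this is
#' the mass median diameter (MMD), since particle mass scales with the cube
#' of diameter.
#'
#' @param cmd Count median diameter, micrometres (> 0).
#' @param gsd Geometric standard deviation (>= 1).
#' @param b Moment order; 3 (mass weighting) by default.
#'
#' @return Moment-median diameter in micrometres.
#' @examples
#' hatch_choate_mmd(0.132, 2.6)   # SMPS-style CMD/GSD -> MMD
#' @export
hatch_choate_mmd <- function(cmd, gsd, b = 3) {
  check_scalar_positive(cmd, "cmd")
  if (!is.numeric(gsd) || length(gsd) != 1L || is.na(gsd) || gsd < 1) {
    abort_invalid("`gsd` must be a single number >= 1")
  }
  cmd * exp(b * log(gsd)^2)
}

#' Convert a physical mass median diameter to aerodynamic
#'
#' For compact droplets the aerodynamic diameter is the physical diameter
#' multiplied by the square root of the particle density (in g/cm^3).
#'
#' @param mmd Physical mass median diameter, micrometres (> 0).
#' @param density Droplet density, g/cm^3 (> 0).
#'
#' @return Mass median aerodynamic diameter (MMAD), micrometres.
#' @examples
#' mmd_to_mmad(2.043, 1.19)
#' @export
mmd_to_mmad <- function(mmd, density) {
  check_scalar_positive(mmd, "mmd")
  check_scalar_positive(density, "density")
  mmd * sqrt(density)
}

#' Weighted-average humectant density
#'
#' Fraction-weighted average of the propylene glycol and vegetable glycerin
#' component densities. The defaults (PG 1.040, VG 1.261 g/cm^3, standard
#' handbook values near room temperature) give 1.11 g/cm^3 for a 70:30 and
#' 1.19 g/cm^3 for a 30:70 PG:VG mixture at two decimals.
#'
#' @param pg_fraction,vg_fraction Mass fractions summing to 1 within `tol`.
#' @param pg_density,vg_density Component densities, g/cm^3.
#' @param tol Tolerance on the fraction sum.
#'
#' @return Effective density in g/cm^3.
#' @examples
#' humectant_density(0.70, 0.30)  # 1.11
#' humectant_density(0.30, 0.70)  # 1.19
#' @export
humectant_density <- function(pg_fraction, vg_fraction,
                              pg_density = 1.040, vg_density = 1.261,
                              tol = 0.05) {
  if (abs(pg_fraction + vg_fraction - 1) > tol) {
    abort_invalid("`pg_fraction` and `vg_fraction` must sum to 1")
  }
  check_scalar_positive(pg_density, "pg_density")
  check_scalar_positive(vg_density, "vg_density")
  pg_fraction * pg_density + vg_fraction * vg_density
}

#' Mass fraction of a lognormal PSD between two diameters
#'
#' Evaluates the cumulative lognormal between `d_lo` and `d_hi` for a
#' mass-basis distribution: `pnorm(log(d_hi / MMAD) / log(GSD)) -
#' pnorm(log(d_lo / MMAD) / log(GSD))`. `d_lo = 0` and `d_hi = Inf` are
#' allowed and denote the open tails.
#'
#' @param psd A mass-basis [lognormal_psd()].
#' @param d_lo,d_hi Interval bounds in micrometres, `0 <= d_lo < d_hi`.
#'
#' @return Mass fraction in `[0, 1]`.
#' @examples
#' psd <- lognormal_psd(0.93, 1.43)
#' mass_fraction_between(psd, 0.32, 1.8)
#' @export
mass_fraction_between <- function(psd, d_lo, d_hi) {
  stopifnot(inherits(psd, "lognormal_psd"))
  if (psd$basis != "mass") {
    abort_invalid("`psd` must be on the mass basis")
  }
  if (!is.numeric(d_lo) || !is.numeric(d_hi) || d_lo < 0 || d_lo >= d_hi) {
    abort_invalid("need 0 <= d_lo < d_hi")
  }
  lg <- log(psd$gsd)
  z <- function(d) {
    if (d == 0) return(-Inf)
    if (!is.finite(d)) return(Inf)
    if (lg == 0) return(if (d >= psd$median_diameter) Inf else -Inf)
    log(d / psd$median_diameter) / lg
  }
  stats::pnorm(z(d_hi)) - stats::pnorm(z(d_lo))
}
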