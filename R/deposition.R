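# Regional respiratory-tract deposition of a lognormal aerosol.
#
# Generation-by-generation march of one tidal breath through a symmetric
# 24-generation airway tree (Yeh/Schum-type whole-lung typical-path
# morphometry), with inertial impaction at bifurcations, gravitational
# sedimentation in inclined tubes, and laminar diffusion (Gormley-Kennedy),
# combined per generation as complements of survival products. Head
# (extrathoracic) deposition uses empirical oral/nasal efficiency curves
# blended by the oral ventilation fraction. Exhaled = 1 - total.

# ---- aerosol mechanics -----------------------------------------------------

#' Particle transport properties
#'
#' Cunningham slip correction, Stokes terminal settling velocity, and
#' Stokes-Einstein diffusion coefficient for a spherical particle at the
#' given conditions (defaults: body temperature, sea-level pressure). With
#' the default unit density the diameter is interpreted as an aerodynamic
#' diameter.
#'
#' @param d_aero Particle diameter, micrometres (vectorised).
#' @param density Particle density, g/cm^3 (1 for aerodynamic diameter).
#' @param temperature Air temperature, K.
#' @param pressure Air pressure, kPa.
#'
#' @return A list with `slip_factor` (dimensionless), `settling_velocity`
#'   (cm/s) and `diffusion_coefficient` (cm^2/s), each the length of
#'   `d_aero`.
#' @examples
#' particle_transport(1)    # ~1.18 slip, ~3.4e-3 cm/s, ~2.8e-7 cm2/s
#' @export
particle_transport <- function(d_aero, density = 1,
                               temperature = 310, pressure = 101.325) {
  if (any(!is.finite(d_aero)) || any(d_aero <= 0)) {
    abort_invalid("`d_aero` must be positive")
  }
  check_scalar_positive(density, "density")
  # mean free path of air, um: 0.0664 um at 293.15 K / 101.325 kPa,
  # scaled with Sutherland temperature dependence
  T0 <- 293.15; P0 <- 101.325
  lambda <- 0.0664 * (P0 / pressure) * (temperature / T0) *
    (1 + 110 / T0) / (1 + 110 / temperature)
  kn <- 2 * lambda / d_aero
  slip <- 1 + kn * (1.257 + 0.4 * exp(-1.1 / kn))
  mu <- 1.458e-5 * temperature^1.5 / (temperature + 110.4)   # poise (g/cm/s)
  d_cm <- d_aero * 1e-4
  v_s <- density * d_cm^2 * 981 * slip / (18 * mu)           # cm/s
  kB <- 1.380649e-16                                          # erg/K
  D <- kB * temperature * slip / (3 * pi * mu * d_cm)         # cm^2/s
  list(slip_factor = slip, settling_velocity = v_s, diffusion_coefficient = D)
}

# Inertial impaction probability at a bifurcation entered with Stokes number
# `stk` at branching angle `theta` (radians):
# 1 - (2/pi) acos(theta*stk) - (1/pi) sin(2 acos(theta*stk)), saturating at 1.
impaction_probability <- function(stk, theta) {
  x <- pmin(theta * stk, 1)
  p <- 1 - (2 / pi) * acos(x) - (1 / pi) * sin(2 * acos(x))
  pmin(pmax(p, 0), 1)
}

# Sedimentation in a tube of diameter D inclined at gravity angle phi for a
# residence time t (Pich inclined-tube form, also valid quiescent):
# 1 - exp(-(4 v_s t cos(phi)) / (pi D)).
sedimentation_probability <- function(v_s, t, diameter, phi) {
  1 - exp(-(4 * v_s * t * cos(phi)) / (pi * diameter))
}

# Gormley-Kennedy diffusional deposition for fully developed laminar tube
# flow, as a function of mu = D * L / q (q = flow through one tube, cm^3/s).
gormley_kennedy <- function(mu) {
  small <- mu < 0.009
  eta <- numeric(length(mu))
  eta[small] <- 5.50 * mu[small]^(2 / 3) - 3.77 * mu[small]
  m <- mu[!small]
  eta[!small] <- 1 - 0.819 * exp(-11.5 * m) - 0.0975 * exp(-70.1 * m) -
    0.0325 * exp(-179 * m)
  pmin(pmax(eta, 0), 1)
}

# Quiescent diffusional deposition in a tube cross-section over time t:
# leading eigenmode of radial diffusion, exp(-j01^2 D t / R^2), j01 = 2.405.
quiescent_diffusion_probability <- function(D, t, diameter) {
  1 - exp(-23.14 * D * t / diameter^2)
}

# ---- head (extrathoracic) efficiencies -------------------------------------

# Empirical aerodynamic + diffusional collection efficiencies for the oral
# and nasal routes, as functions of aerodynamic diameter (um), flow
# (cm^3/s) and diffusion coefficient (cm^2/s). Impaction terms use the
# familiar 1 - 1/(1 + a (d^2 Q)^p) saturating form; diffusion terms a
# 1 - exp(-c D^(1/2) Q^(-1/8)) scaling. Constants chosen to reproduce the
# classic efficiency curves: nasal inspiratory collection ~10% at
# d_ae^2 Q = 250 um^2 cm^3/s, oral collection much weaker below ~3 um and
# rising steeply above.
head_efficiency <- function(d_aero, Q, D, route = c("oral", "nasal")) {
  route <- match.arg(route)
  if (route == "nasal") {
    q <- d_aero^2 * Q                                  # um^2 cm^3/s
    imp <- 1 - 1 / (1 + 3.0e-4 * q) / (1 + 5.5e-5 * q^1.17)
    diff <- 1 - exp(-9.0 * sqrt(D) * Q^(-1 / 8))
  } else {
    q <- d_aero^2 * (Q * 6e-2)                         # um^2 L/min
    imp <- 1 - 1 / (1 + 1.1e-4 * q^1.4)
    diff <- 1 - exp(-5.0 * sqrt(D) * Q^(-1 / 8))
  }
  1 - (1 - imp) * (1 - diff)
}

# ---- lung model ------------------------------------------------------------

# Symmetric whole-lung typical-path morphometry: 24 generations from the
# trachea down, airway counts doubling at each bifurcation. Lengths and
# diameters in cm at the reference (near-total-lung-capacity) inflation;
# branching and gravity angles in degrees. Generations 1-16 are ciliated
# conducting airways (tracheobronchial region); 17-24 are respiratory
# airways (pulmonary region), with the alveolar volume carried distally.
yeh_schum_table <- function() {
  data.frame(
    generation = 1:24,
    region = c(rep("TB", 16), rep("P", 8)),
    count = 2^(0:23),
    length_cm = c(10.0, 4.36, 1.78, 0.965, 0.995, 1.01, 0.890, 0.962,
                  0.867, 0.667, 0.556, 0.446, 0.359, 0.275, 0.212, 0.168,
                  0.134, 0.120, 0.092, 0.080, 0.070, 0.063, 0.057, 0.053),
    diameter_cm = c(2.01, 1.56, 1.13, 0.827, 0.651, 0.574, 0.435, 0.373,
                    0.322, 0.257, 0.198, 0.156, 0.118, 0.092, 0.073, 0.060,
                    0.054, 0.050, 0.047, 0.045, 0.044, 0.044, 0.043, 0.043),
    branching_deg = c(0, 33, 34, 22, 20, 18, 19, 22, 28, 22, 33, 34,
                      37, 39, 39, 51, 45, 45, 45, 45, 45, 45, 45, 45),
    gravity_deg = c(0, 20, 31, 43, 39, 39, 40, 36, 39, 45, 43, 45,
                    45, 60, 60, 60, 60, 60, 60, 60, 60, 60, 60, 60)
  )
}

#' Symmetric airway-tree lung model
#'
#' Builds the symmetric 24-generation whole-lung morphometry used by the
#' deposition model, uniformly scaled so that the total model volume
#' (airways plus alveolar volume) matches the functional residual capacity.
#'
#' @param frc Functional residual capacity, cm^3.
#' @param reference_volume Total volume of the embedded morphometry at its
#'   reference inflation, cm^3.
#' @param alveolar_dimension_cm Characteristic alveolar dimension (alveolar
#'   duct/sac diameter) at the reference inflation, cm; governs
#'   sedimentation and diffusion of air residing in the alveolar volume.
#'
#' @return An object of class `"lung_model"`: the generation table with
#'   scaled dimensions, per-generation volumes, and the scaled alveolar
#'   volume.
#' @export
lung_model <- function(frc = 3300, reference_volume = 5600,
                       alveolar_dimension_cm = 0.028) {
  check_scalar_positive(frc, "frc")
  tab <- yeh_schum_table()
  airway_vol_ref <- sum(tab$count * tab$length_cm * pi * tab$diameter_cm^2 / 4)
  if (reference_volume <= airway_vol_ref) {
    abort_invalid("`reference_volume` must exceed the airway volume")
  }
  alveolar_ref <- reference_volume - airway_vol_ref
  s <- (frc / reference_volume)^(1 / 3)       # uniform linear scale factor
  tab$length_cm <- tab$length_cm * s
  tab$diameter_cm <- tab$diameter_cm * s
  tab$volume_cm3 <- tab$count * tab$length_cm * pi * tab$diameter_cm^2 / 4
  structure(
    list(generations = tab,
         alveolar_volume = alveolar_ref * s^3,
         alveolar_dimension = alveolar_dimension_cm * s,
         scale_factor = s, frc = frc),
    class = "lung_model"
  )
}

#' @export
print.lung_model <- function(x, ...) {
  cat(sprintf("Symmetric %d-generation lung model, FRC %g cm3\n",
              nrow(x$generations), x$frc))
  cat(sprintf("  airway volume %.0f cm3, alveolar volume %.0f cm3\n",
              sum(x$generations$volume_cm3), x$alveolar_volume))
  invisible(x)
}

#' Breathing pattern
#'
#' Ventilation parameters of the modelled breather. Defaults are standard
#' resting adult values: 625 cm^3 tidal volume, 12 breaths/min, half-cycle
#' inspiration, 3,300 cm^3 FRC, 50 cm^3 upper-airway (extrathoracic) volume.
#' `mouth_fraction` is the fraction of ventilation taken orally; the default
#' 0.6 represents an oronasal mouth breather at rest (the remainder passes
#' through the nose).
#'
#' @param tidal_volume Tidal volume, cm^3.
#' @param breathing_frequency Breaths per minute.
#' @param inspiratory_fraction Fraction of the cycle spent inhaling.
#' @param functional_residual_capacity FRC, cm^3.
#' @param upper_airway_volume Extrathoracic dead-space volume, cm^3.
#' @param mouth_fraction Oral share of ventilation in `[0, 1]`.
#'
#' @return An object of class `"breathing_pattern"`.
#' @export
breathing_pattern <- function(tidal_volume = 625, breathing_frequency = 12,
                              inspiratory_fraction = 0.5,
                              functional_residual_capacity = 3300,
                              upper_airway_volume = 50,
                              mouth_fraction = 0.6) {
  check_scalar_positive(tidal_volume, "tidal_volume")
  check_scalar_positive(breathing_frequency, "breathing_frequency")
  if (inspiratory_fraction <= 0 || inspiratory_fraction >= 1) {
    abort_invalid("`inspiratory_fraction` must be in (0, 1)")
  }
  check_scalar_positive(functional_residual_capacity, "functional_residual_capacity")
  check_scalar_positive(upper_airway_volume, "upper_airway_volume")
  if (mouth_fraction < 0 || mouth_fraction > 1) {
    abort_invalid("`mouth_fraction` must be in [0, 1]")
  }
  structure(
    list(tidal_volume = tidal_volume,
         breathing_frequency = breathing_frequency,
         inspiratory_fraction = inspiratory_fraction,
         functional_residual_capacity = functional_residual_capacity,
         upper_airway_volume = upper_airway_volume,
         mouth_fraction = mouth_fraction),
    class = "breathing_pattern"
  )
}

#' @export
print.breathing_pattern <- function(x, ...) {
  cat(sprintf(
    "Breathing pattern: VT %g cm3, %g breaths/min, %.0f%% oral (FRC %g cm3)\n",
    x$tidal_volume, x$breathing_frequency, 100 * x$mouth_fraction,
    x$functional_residual_capacity))
  invisible(x)
}

deposition_result <- function(head, tb, p, meta = NULL) {
  total <- head + tb + p
  structure(
    list(head_fraction = head, tracheobronchial_fraction = tb,
         pulmonary_fraction = p, total_fraction = total,
         exhaled_fraction = 1 - total, meta = meta),
    class = "deposition_result"
  )
}

#' @export
print.deposition_result <- function(x, ...) {
  cat("Regional deposition (mass fractions of inhaled aerosol)\n")
  cat(sprintf("  head %.3f | tracheobronchial %.3f | pulmonary %.3f\n",
              x$head_fraction, x$tracheobronchial_fraction, x$pulmonary_fraction))
  cat(sprintf("  total %.3f, exhaled %.3f\n", x$total_fraction, x$exhaled_fraction))
  invisible(x)
}

# ---- single-size deposition ------------------------------------------------

#' Regional deposition of a monodisperse aerosol
#'
#' Marches one pause-free tidal breath through the airway tree. The tidal
#' volume is discretised into plug-flow slices; each slice penetrates to the
#' depth set by its position in the breath, traverses the generations on the
#' way in and out, and deposits by impaction (inspiratory pass, at
#' bifurcations), sedimentation and diffusion, combined per generation as
#' `1 - prod(1 - p_i)`. Air reaching the alveolar volume deposits by
#' quiescent sedimentation and diffusion during its residence there. Head
#' deposition applies empirical oral and nasal efficiency curves, blended by
#' `mouth_fraction`, on both passes. Exhaled is `1 - total` by construction.
#'
#' @param d_aero Aerodynamic diameter, micrometres.
#' @param lung A [lung_model()].
#' @param breathing A [breathing_pattern()].
#' @param n_slices Number of plug-flow slices of the tidal volume.
#'
#' @return A `"deposition_result"`: head, tracheobronchial, pulmonary,
#'   total and exhaled mass fractions, summing to 1 with the exhaled
#'   fraction.
#' @examples
#' monodisperse_deposition(1, lung_model(), breathing_pattern())
#' @export
monodisperse_deposition <- function(d_aero, lung = lung_model(),
                                    breathing = breathing_pattern(),
                                    n_slices = 40) {
  stopifnot(inherits(lung, "lung_model"), inherits(breathing, "breathing_pattern"))
  check_scalar_positive(d_aero, "d_aero")

  tp <- particle_transport(d_aero)
  mu_air <- 1.458e-5 * 310^1.5 / (310 + 110.4)               # poise
  gen <- lung$generations
  ng <- nrow(gen)
  vt <- breathing$tidal_volume
  period <- 60 / breathing$breathing_frequency
  q_in <- vt / (period * breathing$inspiratory_fraction)     # cm^3/s at mouth
  q_ex <- vt / (period * (1 - breathing$inspiratory_fraction))

  # distal-flow taper: flow through a generation is proportional to the
  # expanding (alveolar) volume at and distal to it; alveolar volume is
  # spread over the respiratory generations in proportion to airway count
  alv_gen <- numeric(ng)
  resp <- gen$region == "P"
  alv_gen[resp] <- lung$alveolar_volume * gen$count[resp] / sum(gen$count[resp])
  flow_frac <- rev(cumsum(rev(alv_gen))) / sum(alv_gen)

  area <- pi * gen$diameter_cm^2 / 4
  theta <- gen$branching_deg * pi / 180
  phi <- gen$gravity_deg * pi / 180

  # sedimentation length scale: the duct lumen in conducting airways, but in
  # the alveolated respiratory generations a settling particle only crosses
  # the alveolar sleeve dimension before reaching a septal wall
  d_sed <- gen$diameter_cm
  d_sed[gen$region == "P"] <- pmin(d_sed[gen$region == "P"], lung$alveolar_dimension)

  # per-generation mechanism probabilities for a pass at mouth flow q_mouth;
  # `frac` scales tube length (and hence residence) for partial traversal
  sed_dif <- function(q_mouth, frac = 1) {
    qg <- q_mouth * flow_frac
    t <- frac * gen$volume_cm3 / qg
    p_sed <- sedimentation_probability(tp$settling_velocity, t, d_sed, phi)
    p_dif <- gormley_kennedy(tp$diffusion_coefficient * frac * gen$length_cm /
                               (qg / gen$count))
    1 - (1 - p_sed) * (1 - p_dif)
  }
  qg_in <- q_in * flow_frac
  u_in <- qg_in / (gen$count * area)
  stk <- tp$slip_factor * (d_aero * 1e-4)^2 * u_in / (18 * mu_air * gen$diameter_cm)
  p_imp <- impaction_probability(stk, theta)

  p_in_full <- 1 - (1 - p_imp) * (1 - sed_dif(q_in))
  p_ex_full <- sed_dif(q_ex)

  # transit times per generation: the flow feeding a generation tapers as
  # air is stored in the expanding alveolar volume along the way, so distal
  # transits lengthen; a slice's penetration is set by its time budget
  t_in <- gen$volume_cm3 / qg_in
  t_ex <- gen$volume_cm3 / (q_ex * flow_frac)
  v_ua <- breathing$upper_airway_volume
  t_ua_in <- v_ua / q_in
  period_in <- period * breathing$inspiratory_fraction

  blend_head <- function(Q) {
    breathing$mouth_fraction *
      head_efficiency(d_aero, Q, tp$diffusion_coefficient, "oral") +
      (1 - breathing$mouth_fraction) *
      head_efficiency(d_aero, Q, tp$diffusion_coefficient, "nasal")
  }
  eta_head_in <- blend_head(q_in)
  eta_head_out <- blend_head(q_ex)

  d_alv <- lung$alveolar_dimension
  # alveolar residence: quiescent settling + diffusion in alveolar dimensions
  p_alveolar <- function(t) {
    1 - (1 - sedimentation_probability(tp$settling_velocity, t, d_alv, phi[ng])) *
      (1 - quiescent_diffusion_probability(tp$diffusion_coefficient, t, d_alv))
  }
  # fraction of the duct stream branching into alveolar storage at each
  # respiratory generation (volume conservation with the flow taper)
  ff_next <- c(flow_frac[-1], 0)
  store_frac <- ifelse(flow_frac > 0, (flow_frac - ff_next) / flow_frac, 0)
  store_frac[gen$region == "TB"] <- 0

  head_tot <- 0
  tb_tot <- 0
  p_tot <- 0
  w <- 1 / n_slices
  # inspiratory time budget per slice: air inhaled later has less time to
  # travel before flow reversal
  entry_time <- (seq_len(n_slices) - 0.5) / n_slices * period_in
  cum_t_in <- cumsum(t_in)
  is_tb <- gen$region == "TB"

  for (k in seq_len(n_slices)) {
    budget <- period_in - entry_time[k] - t_ua_in
    if (budget <= 0) {
      # slice stays within the upper airway; only head collection applies
      head_tot <- head_tot + w * (1 - (1 - eta_head_in) * (1 - eta_head_out))
      next
    }
    deepest <- findInterval(budget, cum_t_in) + 1L   # generation it ends in
    frac <- rep(0, ng)
    if (deepest > ng) {
      reached <- seq_len(ng)
      frac[reached] <- 1
      t_rest <- 2 * (budget - cum_t_in[ng])          # in and back out
    } else {
      reached <- seq_len(deepest)
      frac[reached] <- 1
      frac[deepest] <- (budget - c(0, cum_t_in)[deepest]) / t_in[deepest]
      t_rest <- 0
    }

    p_in <- p_in_full
    p_ex <- p_ex_full
    if (deepest <= ng && frac[deepest] < 1) {
      # impaction at entry plus sed/diffusion over the traversed portion
      pp_in <- sed_dif(q_in, frac)
      pp_ex <- sed_dif(q_ex, frac)
      p_in[deepest] <- 1 - (1 - p_imp[deepest]) * (1 - pp_in[deepest])
      p_ex[deepest] <- pp_ex[deepest]
    }

    alive <- 1
    dep_gen <- numeric(ng)
    stored <- numeric(ng)

    head_k <- alive * eta_head_in
    alive <- alive - head_k

    for (j in reached) {                    # inspiratory pass, proximal first
      dep_gen[j] <- dep_gen[j] + alive * p_in[j]
      alive <- alive * (1 - p_in[j])
      if (store_frac[j] > 0 && frac[j] >= 1 && j < deepest) {
        # part of the stream is drawn into the expanding alveoli here and
        # resides until exhalation draws it back into the stream
        s <- alive * store_frac[j]
        alive <- alive - s
        t_store <- max(0, 2 * (budget - cum_t_in[j]))
        pa <- p_alveolar(t_store)
        dep_gen[j] <- dep_gen[j] + s * pa
        stored[j] <- s * (1 - pa)
      }
    }

    if (t_rest > 0) {
      # residence in the alveolar volume beyond the last generation
      pa <- p_alveolar(t_rest)
      dep_gen[ng] <- dep_gen[ng] + alive * pa
      alive <- alive * (1 - pa)
    }

    for (j in rev(reached)) {               # expiratory pass, distal first
      alive <- alive + stored[j]            # alveolar air rejoins the stream
      dep_gen[j] <- dep_gen[j] + alive * p_ex[j]
      alive <- alive * (1 - p_ex[j])
    }

    head_k <- head_k + alive * eta_head_out
    alive <- alive * (1 - eta_head_out)

    head_tot <- head_tot + w * head_k
    tb_tot <- tb_tot + w * sum(dep_gen[is_tb])
    p_tot <- p_tot + w * sum(dep_gen[!is_tb])
  }

  deposition_result(head_tot, tb_tot, p_tot,
                    meta = list(d_aero = d_aero, n_slices = n_slices))
}

# ---- polydisperse deposition -----------------------------------------------

#' Regional deposition of a lognormal aerosol
#'
#' Mass-weighted integration of [monodisperse_deposition()] over a
#' mass-basis aerodynamic lognormal distribution, using log-spaced
#' quadrature nodes spanning +/- 4 ln(GSD) around the MMAD with renormalised
#' lognormal mass weights. A GSD of 1 collapses to a single node at the
#' MMAD.
#'
#' @param psd A mass-basis aerodynamic [lognormal_psd()].
#' @param lung A [lung_model()].
#' @param breathing A [breathing_pattern()].
#' @param n_quadrature Number of quadrature nodes (>= 8).
#' @param n_slices Passed to [monodisperse_deposition()].
#'
#' @return A `"deposition_result"`.
#' @examples
#' polydisperse_deposition(lognormal_psd(0.93, 1.43))
#' @export
polydisperse_deposition <- function(psd, lung = lung_model(),
                                    breathing = breathing_pattern(),
                                    n_quadrature = 64, n_slices = 40) {
  stopifnot(inherits(psd, "lognormal_psd"))
  if (psd$basis != "mass" || psd$diameter_kind != "aerodynamic") {
    abort_invalid("`psd` must be mass-basis with aerodynamic diameters")
  }
  if (n_quadrature < 8 && psd$gsd > 1) {
    abort_invalid("`n_quadrature` must be >= 8")
  }
  lg <- log(psd$gsd)
  if (lg == 0) {
    res <- monodisperse_deposition(psd$median_diameter, lung, breathing, n_slices)
    res$meta <- list(psd = psd, n_quadrature = 1)
    return(res)
  }
  z <- seq(-4, 4, length.out = n_quadrature)
  wts <- stats::dnorm(z)
  wts <- wts / sum(wts)
  d <- psd$median_diameter * exp(z * lg)
  acc <- c(head = 0, tb = 0, p = 0)
  for (i in seq_along(d)) {
    r <- monodisperse_deposition(d[i], lung, breathing, n_slices)
    acc <- acc + wts[i] * c(r$head_fraction, r$tracheobronchial_fraction,
                            r$pulmonary_fraction)
  }
  deposition_result(unname(acc["head"]), unname(acc["tb"]), unname(acc["p"]),
                    meta = list(psd = psd, n_quadrature = n_quadrature))
}

#' Exhaled mass fraction
#'
#' The fraction of inhaled aerosol mass that is breathed back out,
#' `1 - total deposited fraction`; the indicator of secondhand-exposure
#' potential.
#'
#' @param result A `"deposition_result"`.
#' @return The exhaled fraction in `[0, 1]`.
#' @export
exhaled_fraction <- function(result) {
  stopifnot(inherits(result, "deposition_result"))
  1 - result$total_fraction
}
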