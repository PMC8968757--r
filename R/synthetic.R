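# Synthetic study-shaped data with known truth: impactor trials with
# gravimetric rounding noise, mobility scans with dilution-driven
# evaporative shrink, and full multi-formulation study sets.

#' Evaporation model for diluted mobility sampling
#'
#' One-parameter description of the evaporative bias introduced by diluting
#' volatile droplets before mobility sizing: a fraction `volatile_fraction`
#' of each droplet's volume is lost before measurement, shrinking every
#' diameter by `(1 - volatile_fraction)^(1/3)`; `gsd_inflation` optionally
#' widens the spread.
#'
#' @param volatile_fraction Volume fraction lost, in `[0, 1)`.
#' @param gsd_inflation Multiplier (>= 1) applied to the GSD.
#' @return An object of class `"evaporation_model"`.
#' @examples
#' evaporation_model(0.999)   # shrinks diameters to 10% of their size
#' @export
evaporation_model <- function(volatile_fraction = 0, gsd_inflation = 1) {
  if (volatile_fraction < 0 || volatile_fraction >= 1) {
    abort_invalid("`volatile_fraction` must be in [0, 1)")
  }
  if (gsd_inflation < 1) abort_invalid("`gsd_inflation` must be >= 1")
  structure(list(volatile_fraction = volatile_fraction,
                 gsd_inflation = gsd_inflation),
            class = "evaporation_model")
}

#' Diameter shrink factor of an evaporation model
#'
#' @param evap An [evaporation_model()].
#' @return `(1 - volatile_fraction)^(1/3)`.
#' @export
shrink_factor <- function(evap) {
  stopifnot(inherits(evap, "evaporation_model"))
  (1 - evap$volatile_fraction)^(1 / 3)
}

#' Simulate a gravimetric impactor trial from a known PSD
#'
#' Allocates `total_mass` to the impactor stages under the ideal sharp-cut
#' model: the stage with cut-point `d50[j]` collects the lognormal mass
#' between `d50[j]` and the next larger cut-point (the top stage is open
#' above; the backup filter collects everything below the smallest cut).
#' Substrate tare masses are drawn once and both pre- and post-sampling
#' masses are rounded to the balance resolution, which is the only noise
#' source. Deterministic given `seed`.
#'
#' @param truth A mass-basis aerodynamic [lognormal_psd()].
#' @param total_mass Total collected mass, mg.
#' @param cutpoints Stage cut-points, micrometres, descending.
#' @param balance_resolution Balance resolution, mg (0 for noise-free).
#' @param puff_count,puff_volume Puff topography metadata.
#' @param consumed_mass E-liquid reservoir consumption over the trial, mg
#'   (`NA` to omit reservoir masses).
#' @param seed Integer seed; `NULL` leaves the RNG stream untouched.
#' @param id Optional trial identifier.
#'
#' @return An [impactor_trial()] with a weighed backup filter.
#' @examples
#' tr <- simulate_impactor_trial(lognormal_psd(0.93, 1.43), total_mass = 7)
#' coef(fit_probit_psd(tr))[c("mmad", "gsd")]
#' @export
simulate_impactor_trial <- function(truth, total_mass,
                                    cutpoints = lfci_cutpoints(),
                                    balance_resolution = 0.1,
                                    puff_count = 2, puff_volume = 55,
                                    consumed_mass = NA_real_,
                                    seed = 1, id = NULL) {
  stopifnot(inherits(truth, "lognormal_psd"))
  check_scalar_positive(total_mass, "total_mass")
  asc <- sort(cutpoints)                       # ascending for interval bounds
  upper <- c(asc[-1], Inf)
  frac <- vapply(seq_along(asc), function(j) {
    mass_fraction_between(truth, asc[j], upper[j])
  }, numeric(1))
  backup_frac <- mass_fraction_between(truth, 0, asc[1])
  stage_mass <- total_mass * frac              # mg, exact allocation
  backup_mass <- total_mass * backup_frac

  with_seed(seed, {
    # substrate tare masses; in the perfect-balance limit net masses are
    # exact, so tares (which would otherwise swamp sub-resolution stage
    # masses in floating point) are omitted
    tare <- if (balance_resolution > 0) stats::runif(length(asc), 40, 80) else numeric(length(asc))
    snap <- function(x) {
      if (balance_resolution > 0) round(x / balance_resolution) * balance_resolution else x
    }
    pre <- snap(tare)
    post <- snap(tare + stage_mass)
    bf <- snap(backup_mass)
    # reorder to descending cut-point for the trial constructor
    o <- order(asc, decreasing = TRUE)
    impactor_trial(
      d50 = asc[o], pre_mass = pre[o], post_mass = post[o],
      backup_filter_mass = bf,
      puff_count = puff_count, puff_volume = puff_volume,
      eliquid_mass_pre = if (is.na(consumed_mass)) NA_real_ else snap(1200),
      eliquid_mass_post = if (is.na(consumed_mass)) NA_real_ else snap(1200 - consumed_mass),
      balance_resolution = max(balance_resolution, 0.1),
      id = id
    )
  })
}

#' Simulate a mobility-sizer scan from a known PSD
#'
#' Applies the evaporative shrink to the true number distribution (CMD
#' multiplied by the cube-root volume-retention factor, GSD multiplied by
#' `gsd_inflation`), then bins the resulting lognormal number distribution
#' onto the channel grid. With `counting_noise = TRUE` channel
#' concentrations get Poisson counting noise; otherwise the scan is the
#' exact binned expectation. Deterministic given `seed`.
#'
#' @param truth A number-basis [lognormal_psd()] (physical diameters, um).
#' @param evap An [evaporation_model()].
#' @param channel_bounds Vector of channel edges in nm, ascending (length
#'   `n_channels + 1`); defaults to 32 log-spaced channels over 6-560 nm.
#' @param total_conc Total number concentration, particles/cm^3.
#' @param instrument Instrument tag for the scan.
#' @param counting_noise Add Poisson noise to channel counts?
#' @param seed Integer seed (used only when `counting_noise = TRUE`).
#'
#' @return A [mobility_scan()].
#' @export
simulate_mobility_scan <- function(truth, evap = evaporation_model(),
                                   channel_bounds = fmps_channel_bounds(),
                                   total_conc = 1e6,
                                   instrument = c("other", "smps", "fmps"),
                                   counting_noise = FALSE, seed = 1) {
  stopifnot(inherits(truth, "lognormal_psd"))
  if (truth$basis != "number") abort_invalid("`truth` must be number-basis")
  instrument <- match.arg(instrument)
  cmd_nm <- truth$median_diameter * 1000 * shrink_factor(evap)
  gsd <- max(truth$gsd * evap$gsd_inflation, 1)
  lo <- channel_bounds[-length(channel_bounds)]
  hi <- channel_bounds[-1]
  p <- if (gsd > 1) {
    stats::pnorm(log(hi / cmd_nm) / log(gsd)) - stats::pnorm(log(lo / cmd_nm) / log(gsd))
  } else {
    as.numeric(lo <= cmd_nm & cmd_nm < hi)
  }
  conc <- total_conc * p
  if (counting_noise) {
    conc <- with_seed(seed, stats::rpois(length(conc), conc))
  }
  mobility_scan(lo, hi, conc, instrument = instrument)
}

#' Default 32-channel grid spanning 6-560 nm
#'
#' Log-spaced channel edges emulating a fast mobility sizer's resolution.
#'
#' @param n_channels Number of channels.
#' @param d_min,d_max Grid bounds, nm.
#' @return Vector of `n_channels + 1` edges.
#' @export
fmps_channel_bounds <- function(n_channels = 32, d_min = 6, d_max = 560) {
  exp(seq(log(d_min), log(d_max), length.out = n_channels + 1))
}

#' 128-channel grid spanning 2-1000 nm
#'
#' Log-spaced channel edges emulating a scanning mobility sizer's full range.
#'
#' @return Vector of 129 edges in nm.
#' @export
smps_channel_bounds <- function() {
  fmps_channel_bounds(n_channels = 128, d_min = 2, d_max = 1000)
}

#' Study design for the synthetic generator
#'
#' @param formulations A data frame with one row per formulation and columns
#'   `name`, `pg_fraction`, `vg_fraction`, `additive`, `true_mmad`,
#'   `true_gsd`, `total_mass_mg` (collected per trial), `consumed_mg`
#'   (reservoir loss per trial), `n_trials`. Defaults to
#'   [reference_formulations()].
#' @param balance_resolution Balance resolution, mg.
#' @param mmad_jitter Lognormal coefficient of variation of the per-trial
#'   true MMAD around the formulation truth (trial-to-trial variability).
#' @param seed Integer master seed.
#'
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(formulations = reference_formulations(),
                         balance_resolution = 0.1,
                         mmad_jitter = 0.02, seed = 1) {
  need <- c("name", "pg_fraction", "vg_fraction", "additive",
            "true_mmad", "true_gsd", "total_mass_mg", "consumed_mg", "n_trials")
  if (!all(need %in% names(formulations))) {
    abort_invalid(paste("`formulations` must have columns:",
                        paste(need, collapse = ", ")))
  }
  if (any(formulations$n_trials < 1)) abort_invalid("trial counts must be >= 1")
  if (any(formulations$total_mass_mg <= 0)) abort_invalid("total mass must be > 0")
  structure(list(formulations = formulations,
                 balance_resolution = balance_resolution,
                 mmad_jitter = mmad_jitter, seed = seed),
            class = "study_design")
}

#' Built-in six-formulation study design
#'
#' The default synthetic study: two humectant ratios (30:70 and 70:30
#' PG:VG), each plain, with flavourings, and with nicotine, six trials per
#' formulation, with per-formulation true (MMAD, GSD) and per-trial
#' collected/consumed masses matching a two-puff low-flow-impactor protocol
#' (55 cm^3 puffs, 110 cm^3 sampled volume).
#'
#' @return A data frame suitable for [study_design()].
#' @export
reference_formulations <- function() {
  data.frame(
    name = c("30:70 PG:VG", "30:70 PG:VG w/flavorings", "30:70 PG:VG w/nicotine",
             "70:30 PG:VG", "70:30 PG:VG w/flavorings", "70:30 PG:VG w/nicotine"),
    pg_fraction = c(0.3, 0.3, 0.3, 0.7, 0.7, 0.7),
    vg_fraction = c(0.7, 0.7, 0.7, 0.3, 0.3, 0.3),
    additive = c("none", "flavorings", "nicotine",
                 "none", "flavorings", "nicotine"),
    true_mmad = c(0.93, 0.88, 0.86, 1.00, 0.93, 0.91),
    true_gsd = c(1.43, 1.38, 1.36, 1.43, 1.36, 1.38),
    total_mass_mg = c(7.41, 5.61, 9.30, 5.69, 8.67, 9.93),
    consumed_mg = c(7.81, 5.16, 6.54, 7.86, 6.66, 7.19),
    n_trials = 6L
  )
}

#' Simulate a full study
#'
#' Generates, per formulation and trial, one impactor trial plus three
#' paired mobility scans — an undiluted impactor-like reference (no
#' evaporation), an SMPS-like scan (moderate dilution, mild evaporation) and
#' an FMPS-like scan (high dilution, near-complete evaporation of the
#' volatile fraction) — along with a truth ledger for recovery testing.
#' Fully reproducible from the design seed.
#'
#' @param design A [study_design()].
#' @param smps_evap,fmps_evap [evaporation_model()]s for the two diluted
#'   instruments. The FMPS-like default shrinks ~0.9 um droplets to ~70 nm.
#'
#' @return An object of class `"aerosol_study"`: lists `trials` and `scans`
#'   plus a `truth` data frame (formulation, trial, true MMAD/GSD, seed).
#' @export
simulate_study <- function(design = study_design(),
                           smps_evap = evaporation_model(0.5, gsd_inflation = 1.8),
                           fmps_evap = evaporation_model(0.99953)) {
  stopifnot(inherits(design, "study_design"))
  fm <- design$formulations
  trials <- list()
  scans <- list()
  truth_rows <- list()
  k <- 0L
  for (i in seq_len(nrow(fm))) {
    liq <- eliquid(fm$pg_fraction[i], fm$vg_fraction[i], additive = fm$additive[i])
    for (tr in seq_len(fm$n_trials[i])) {
      k <- k + 1L
      s <- child_seed(design$seed, k)
      jit <- if (design$mmad_jitter > 0) {
        with_seed(s, exp(stats::rnorm(1, 0, design$mmad_jitter)))
      } else 1
      mmad_t <- fm$true_mmad[i] * jit
      psd_mass <- lognormal_psd(mmad_t, fm$true_gsd[i],
                                basis = "mass", diameter_kind = "aerodynamic")
      id <- sprintf("%s_trial%02d", gsub("[^0-9A-Za-z]+", "-", fm$name[i]), tr)
      trials[[id]] <- simulate_impactor_trial(
        psd_mass, total_mass = fm$total_mass_mg[i],
        balance_resolution = design$balance_resolution,
        consumed_mass = fm$consumed_mg[i],
        seed = child_seed(s, 1), id = id)

      # number-basis physical-diameter truth for the mobility instruments:
      # invert the density scaling then the Hatch-Choate mass weighting
      mmd <- mmad_t / sqrt(liq$effective_density)
      cmd <- mmd * exp(-3 * log(fm$true_gsd[i])^2)
      psd_num <- lognormal_psd(cmd, fm$true_gsd[i],
                               basis = "number", diameter_kind = "physical")
      scans[[paste0(id, "_lfci")]] <- simulate_mobility_scan(
        psd_num, evaporation_model(0),
        channel_bounds = fmps_channel_bounds(64, 6, 5000),
        seed = child_seed(s, 2))
      scans[[paste0(id, "_smps")]] <- simulate_mobility_scan(
        psd_num, smps_evap, channel_bounds = smps_channel_bounds(),
        instrument = "smps", seed = child_seed(s, 3))
      scans[[paste0(id, "_fmps")]] <- simulate_mobility_scan(
        psd_num, fmps_evap, channel_bounds = fmps_channel_bounds(),
        instrument = "fmps", seed = child_seed(s, 4))

      truth_rows[[k]] <- data.frame(
        formulation = fm$name[i], trial = tr, id = id,
        true_mmad_um = mmad_t, true_gsd = fm$true_gsd[i], seed = s)
    }
  }
  structure(list(design = design, trials = trials, scans = scans,
                 truth = do.call(rbind, truth_rows)),
            class = "aerosol_study")
}

#' @export
print.aerosol_study <- function(x, ...) {
  cat(sprintf("Synthetic aerosol study: %d formulations, %d impactor trials, %d scans\n",
              nrow(x$design$formulations), length(x$trials), length(x$scans)))
  invisible(x)
}
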