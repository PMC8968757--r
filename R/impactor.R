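# Cascade-impactor data structures and reduction metrics.

# Default stage cut-points (um) of the low-flow cascade impactor, descending.
#' Default low-flow cascade-impactor cut-points
#'
#' The ten d50 cut-points (micrometres) of the low-flow cascade impactor, in
#' descending order: 10, 5.6, 3.2, 1.8, 1.0, 0.56, 0.32, 0.18, 0.1, 0.056.
#'
#' @return Numeric vector of cut-points in descending order.
#' @export
lfci_cutpoints <- function() {
  c(10, 5.6, 3.2, 1.8, 1.0, 0.56, 0.32, 0.18, 0.1, 0.056)
}

#' Cascade-impactor trial
#'
#' Bundles the per-stage gravimetric record of one impactor trial with its
#' puff metadata. Stages must be ordered by strictly decreasing d50
#' cut-point. `ecag_volume` is the total aerosol-laden volume sampled during
#' collection (defaults to `puff_count * puff_volume`), the divisor of the
#' per-stage concentration calculation.
#'
#' @param d50 Stage cut-points, micrometres, strictly decreasing.
#' @param pre_mass,post_mass Substrate masses before/after sampling, mg.
#' @param backup_filter_mass Net mass on the backup filter (mg), collected
#'   below the smallest cut-point; `NA` if no backup filter was weighed.
#' @param puff_count Number of puffs in the trial.
#' @param puff_volume Volume per puff, cm^3.
#' @param ecag_volume Total sampled aerosol volume, cm^3.
#' @param eliquid_mass_pre,eliquid_mass_post E-liquid reservoir mass before
#'   and after the trial, mg (optional, for consumption metrics).
#' @param balance_resolution Balance resolution, mg.
#' @param id Optional trial identifier.
#'
#' @return An object of class `"impactor_trial"`.
#' @export
impactor_trial <- function(d50, pre_mass, post_mass,
                           backup_filter_mass = NA_real_,
                           puff_count = 2, puff_volume = 55,
                           ecag_volume = puff_count * puff_volume,
                           eliquid_mass_pre = NA_real_,
                           eliquid_mass_post = NA_real_,
                           balance_resolution = 0.1,
                           id = NULL) {
  if (length(d50) < 1L || any(d50 <= 0)) {
    abort_invalid("`d50` cut-points must be positive")
  }
  if (any(diff(d50) >= 0)) {
    abort_invalid("`d50` cut-points must be strictly decreasing")
  }
  if (length(pre_mass) != length(d50) || length(post_mass) != length(d50)) {
    abort_invalid("`pre_mass` and `post_mass` must match `d50` in length")
  }
  if (any(pre_mass < 0) || any(post_mass < 0)) {
    abort_invalid("substrate masses must be non-negative")
  }
  if (any(post_mass < pre_mass - balance_resolution - 1e-9)) {
    warning("post-sampling mass below pre-sampling mass beyond balance resolution",
            call. = FALSE)
  }
  if (puff_count < 1) abort_invalid("`puff_count` must be >= 1")
  check_scalar_positive(ecag_volume, "ecag_volume")
  structure(
    list(stages = data.frame(d50 = d50, pre_mass = pre_mass, post_mass = post_mass),
         backup_filter_mass = backup_filter_mass,
         puff_count = puff_count, puff_volume = puff_volume,
         ecag_volume = ecag_volume,
         eliquid_mass_pre = eliquid_mass_pre,
         eliquid_mass_post = eliquid_mass_post,
         balance_resolution = balance_resolution,
         id = id),
    class = "impactor_trial"
  )
}

#' @export
print.impactor_trial <- function(x, ...) {
  cat(sprintf("Impactor trial%s: %d stages, %g puffs x %g cm3 (V = %g cm3)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              nrow(x$stages), x$puff_count, x$puff_volume, x$ecag_volume))
  m <- stage_masses(x)
  cat(sprintf("  collected mass %.2f mg%s\n", sum(m$mass),
              if (is.na(x$backup_filter_mass)) "" else
                sprintf(" (+%.2f mg backup filter)", x$backup_filter_mass)))
  invisible(x)
}

# Net per-stage masses (mg), with negative differences within one balance
# resolution clamped to zero. Differences more negative than that are also
# clamped, with a warning, so downstream fractions stay in [0, 1].
stage_masses <- function(trial, clamp = TRUE) {
  d <- trial$stages$post_mass - trial$stages$pre_mass
  if (clamp && any(d < 0)) {
    if (any(d < -trial$balance_resolution - 1e-9)) {
      warning("negative stage mass beyond balance resolution clamped to 0",
              call. = FALSE)
    }
    d <- pmax(d, 0)
  }
  data.frame(d50 = trial$stages$d50, mass = d)
}

#' Per-stage aerosol mass concentration
#'
#' Concentration collected on one stage: net stage mass (post minus pre, mg)
#' converted to micrograms and divided by the sampled aerosol volume.
#' Negative mass differences within the balance resolution are treated as
#' zero.
#'
#' @param post_mass,pre_mass Substrate masses, mg.
#' @param ecag_volume Sampled aerosol volume, cm^3 (> 0).
#' @param balance_resolution Balance resolution, mg.
#'
#' @return Concentration in ug/cm^3 (vectorised over stages).
#' @examples
#' stage_concentration(10.5, 10.0, 110)  # 4.545 ug/cm3
#' @export
stage_concentration <- function(post_mass, pre_mass, ecag_volume,
                                balance_resolution = 0.1) {
  check_scalar_positive(ecag_volume, "ecag_volume")
  d <- post_mass - pre_mass
  d <- pmax(d, 0)
  d * 1000 / ecag_volume
}

#' Total aerosol mass concentration of a trial
#'
#' Sum of [stage_concentration()] over all stages (and the backup filter when
#' present), in ug/cm^3 of sampled aerosol.
#'
#' @param trial An [impactor_trial()].
#' @return Total concentration, ug/cm^3.
#' @export
total_concentration <- function(trial) {
  stopifnot(inherits(trial, "impactor_trial"))
  m <- stage_masses(trial)$mass
  extra <- if (is.na(trial$backup_filter_mass)) 0 else max(trial$backup_filter_mass, 0)
  (sum(m) + extra) * 1000 / trial$ecag_volume
}

#' E-liquid consumed per puff
#'
#' Reservoir mass lost over the trial divided by the puff count, in ug/puff.
#' A consumption more negative than the balance resolution triggers a
#' data-quality warning and is reported as is.
#'
#' @param trial An [impactor_trial()] with reservoir masses recorded.
#' @return Consumption in ug/puff.
#' @examples
#' tr <- impactor_trial(c(1, 0.5), c(50, 50), c(53, 54.8),
#'                      eliquid_mass_pre = 1207.8, eliquid_mass_post = 1200.0)
#' consumed_per_puff(tr)  # 3900 ug/puff over 2 puffs
#' @export
consumed_per_puff <- function(trial) {
  stopifnot(inherits(trial, "impactor_trial"))
  if (is.na(trial$eliquid_mass_pre) || is.na(trial$eliquid_mass_post)) {
    abort_invalid("trial has no e-liquid reservoir masses")
  }
  d <- trial$eliquid_mass_pre - trial$eliquid_mass_post
  if (d < -trial$balance_resolution) {
    warning("negative e-liquid consumption beyond balance resolution",
            call. = FALSE)
  }
  d * 1000 / trial$puff_count
}

#' Evaporative mass-loss quality control
#'
#' Percent mass loss of repeated substrate weighings relative to the first
#' reading, used to verify that gravimetric analysis was fast enough that
#' evaporation did not bias the size distribution.
#'
#' @param minutes Times of the readings (minutes); the first must be the
#'   earliest.
#' @param mass_mg Masses at those times, mg.
#' @param threshold Percent loss above which a reading is flagged.
#'
#' @return A data frame with columns `minutes`, `mass_mg`, `loss_percent`,
#'   `flagged`.
#' @examples
#' mass_loss_qc(c(1, 5, 15), c(5.00, 4.90, 4.60))
#' @export
mass_loss_qc <- function(minutes, mass_mg, threshold = 10) {
  if (length(minutes) < 2L || length(mass_mg) != length(minutes)) {
    abort_invalid("need >= 2 (minutes, mass) readings of equal length")
  }
  if (any(minutes[-1] <= minutes[1])) {
    abort_invalid("the first reading must be the earliest")
  }
  if (mass_mg[1] <= 0) abort_invalid("first mass must be positive")
  loss <- 100 * (mass_mg[1] - mass_mg) / mass_mg[1]
  data.frame(minutes = minutes, mass_mg = mass_mg,
             loss_percent = loss, flagged = loss > threshold)
}
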