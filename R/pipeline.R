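# End-to-end study orchestration and formulation-comparison statistics.

#' Compare formulations with Tukey HSD and a compact letter display
#'
#' Fits a one-way fixed-effects least-squares model (formulation as the
#' factor) to trial-level values, runs Tukey HSD pairwise comparisons at
#' `alpha`, and derives a compact letter display in which groups sharing a
#' letter are not significantly different.
#'
#' @param values_by_group Named list mapping group name to a numeric vector
#'   of trial values; at least 2 values per group when there are >= 2
#'   groups. A single group returns letter "A" with no tests.
#' @param alpha Significance level.
#'
#' @return An object of class `"formulation_comparison"` with `omnibus_p`,
#'   a `pairwise` data frame (difference, adjusted p, significance), and
#'   `letters` (named character vector).
#' @examples
#' compare_formulations(list(a = c(1, 2, 3), b = c(10, 11, 12)))
#' @export
compare_formulations <- function(values_by_group, alpha = 0.05) {
  if (!is.list(values_by_group) || is.null(names(values_by_group)) ||
      any(names(values_by_group) == "")) {
    abort_invalid("`values_by_group` must be a named list")
  }
  groups <- names(values_by_group)
  if (length(groups) == 1L) {
    return(structure(list(omnibus_p = NA_real_, pairwise = NULL,
                          letters = stats::setNames("A", groups),
                          alpha = alpha),
                     class = "formulation_comparison"))
  }
  if (any(vapply(values_by_group, length, 1L) < 2L)) {
    abort_invalid("each group needs >= 2 values for pairwise comparison")
  }
  df <- data.frame(
    value = unlist(values_by_group, use.names = FALSE),
    group = factor(rep(groups, vapply(values_by_group, length, 1L)),
                   levels = groups)
  )
  fit <- stats::aov(value ~ group, data = df)
  omnibus_p <- stats::anova(fit)[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  pairs <- utils::combn(groups, 2)           # matches TukeyHSD row order
  pairwise <- data.frame(comparison = rownames(tk),
                         group1 = pairs[2, ], group2 = pairs[1, ],
                         difference = tk[, "diff"],
                         p_adjusted = tk[, "p adj"],
                         significant = tk[, "p adj"] < alpha,
                         row.names = NULL)
  # letters derived from the same Tukey significance matrix as `pairwise`,
  # so the display is always consistent with the reported comparisons
  letters <- compact_letters(groups, pairwise)
  structure(list(omnibus_p = omnibus_p, pairwise = pairwise,
                 letters = letters, alpha = alpha),
            class = "formulation_comparison")
}

# Insert-and-absorb compact letter display: groups sharing a letter are not
# significantly different under the supplied pairwise significance calls.
compact_letters <- function(groups, pairwise) {
  sets <- list(groups)                       # letter sets, each a char vector
  sig <- which(pairwise$significant)
  for (row in sig) {
    a <- pairwise$group1[row]; b <- pairwise$group2[row]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets wholly contained in another
    keep <- vapply(seq_along(new_sets), function(i) {
      !any(vapply(seq_along(new_sets), function(j) {
        i != j && all(new_sets[[i]] %in% new_sets[[j]]) &&
          (length(new_sets[[j]]) > length(new_sets[[i]]) || j < i)
      }, logical(1)))
    }, logical(1))
    sets <- new_sets[keep]
  }
  labels <- vapply(groups, function(g) {
    paste(LETTERS[which(vapply(sets, function(s) g %in% s, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(labels, groups)
}

#' @export
print.formulation_comparison <- function(x, ...) {
  cat("Formulation comparison (one-way least squares + Tukey HSD)\n")
  if (!is.na(x$omnibus_p)) {
    cat(sprintf("  omnibus p = %.4g (alpha = %g)\n", x$omnibus_p, x$alpha))
  }
  cat("  letters: ",
      paste(sprintf("%s=%s", names(x$letters), x$letters), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Run the full study pipeline
#'
#' Fits every impactor trial by log-probit regression, aggregates per-puff
#' consumption, per-puff mass concentration and fitted (MMAD, GSD) per
#' formulation, compares formulations on MMAD and concentration with Tukey
#' HSD, and computes regional lung deposition for each formulation's mean
#' fitted PSD. Trials that fail to fit are skipped and logged; a
#' formulation in which every trial fails is an error.
#'
#' @param input One of: an `"aerosol_study"` from [simulate_study()], a
#'   [study_design()] (simulated on the fly), a path to a YAML config file,
#'   or a config list. A config may contain `seed`, `n_trials`,
#'   `balance_resolution`, `mmad_jitter`, `alpha`, a `breathing` block
#'   (tidal_volume, breathing_frequency, functional_residual_capacity,
#'   upper_airway_volume, mouth_fraction), `n_quadrature`, and either
#'   `synthetic: true` or a `trial_files` list of impactor CSV paths.
#' @param breathing A [breathing_pattern()] for the deposition stage.
#' @param lung A [lung_model()].
#' @param alpha Significance level for the comparisons.
#' @param n_quadrature Quadrature size for [polydisperse_deposition()].
#'
#' @return An object of class `"study_result"`: `table` (one row per
#'   formulation with mean/SD/CV of consumption and concentration, mean
#'   MMAD/GSD and Tukey letters), `comparisons` (MMAD and concentration),
#'   `deposition` (one `"deposition_result"` per formulation), `log`, and
#'   reconciling `counts` (read / fitted / skipped).
#' @export
run_study <- function(input = study_design(),
                      breathing = breathing_pattern(), lung = lung_model(),
                      alpha = 0.05, n_quadrature = 64) {
  cfg <- NULL
  if (is.character(input) && length(input) == 1L) {
    cfg <- yaml::read_yaml(input)
  } else if (is.list(input) && !inherits(input, c("aerosol_study", "study_design"))) {
    cfg <- input
  }
  if (!is.null(cfg)) {
    if (!is.null(cfg$alpha)) alpha <- cfg$alpha
    if (!is.null(cfg$n_quadrature)) n_quadrature <- cfg$n_quadrature
    if (!is.null(cfg$breathing)) {
      breathing <- do.call(breathing_pattern, cfg$breathing)
    }
  }

  trials <- NULL
  formulation_of <- NULL
  if (inherits(input, "aerosol_study")) {
    trials <- input$trials
    formulation_of <- stats::setNames(input$truth$formulation, input$truth$id)
  } else if (inherits(input, "study_design")) {
    study <- simulate_study(input)
    trials <- study$trials
    formulation_of <- stats::setNames(study$truth$formulation, study$truth$id)
  } else if (!is.null(cfg$trial_files)) {
    trials <- list()
    formulation_of <- character()
    for (f in unlist(cfg$trial_files)) {
      tr <- read_impactor_csv(f)
      id <- tr$id %||% basename(f)
      trials[[id]] <- tr
      formulation_of[id] <- attr(tr, "formulation") %||% "unlabelled"
    }
  } else if (!is.null(cfg)) {
    fm <- reference_formulations()
    if (!is.null(cfg$n_trials)) fm$n_trials <- as.integer(cfg$n_trials)
    design <- study_design(
      fm,
      balance_resolution = cfg$balance_resolution %||% 0.1,
      mmad_jitter = cfg$mmad_jitter %||% 0.02,
      seed = cfg$seed %||% 1)
    study <- simulate_study(design)
    trials <- study$trials
    formulation_of <- stats::setNames(study$truth$formulation, study$truth$id)
  } else {
    abort_invalid("unrecognised `input`")
  }

  log <- character()
  rows <- list()
  for (id in names(trials)) {
    tr <- trials[[id]]
    fit <- tryCatch(fit_probit_psd(tr), aerodose_degenerate_fit = function(e) e)
    if (inherits(fit, "condition")) {
      log <- c(log, sprintf("skipped %s: %s", id, conditionMessage(fit)))
      rows[[id]] <- data.frame(id = id, formulation = formulation_of[[id]],
                               mmad = NA_real_, gsd = NA_real_,
                               consumed_ug_puff = NA_real_, conc_ug_cm3 = NA_real_,
                               fitted = FALSE)
      next
    }
    consumed <- if (!is.na(tr$eliquid_mass_pre) && !is.na(tr$eliquid_mass_post)) {
      consumed_per_puff(tr)
    } else NA_real_
    rows[[id]] <- data.frame(id = id, formulation = formulation_of[[id]],
                             mmad = fit$mmad, gsd = fit$gsd,
                             consumed_ug_puff = consumed,
                             conc_ug_cm3 = total_concentration(tr),
                             fitted = TRUE)
  }
  per_trial <- do.call(rbind, rows)
  rownames(per_trial) <- NULL
  fitted <- per_trial[per_trial$fitted, ]
  if (nrow(fitted) == 0L) abort_invalid("no trial could be fitted")
  for (fmname in unique(per_trial$formulation)) {
    if (!any(fitted$formulation == fmname)) {
      abort(sprintf("all trials of formulation '%s' failed to fit", fmname),
            "aerodose_io_error")
    }
  }

  agg <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x, na.rm = TRUE))
  fms <- unique(fitted$formulation)
  tab <- do.call(rbind, lapply(fms, function(fmname) {
    d <- fitted[fitted$formulation == fmname, ]
    cons <- agg(d$consumed_ug_puff); conc <- agg(d$conc_ug_cm3)
    data.frame(formulation = fmname, n_trials = nrow(d),
               consumed_mean = cons["mean"], consumed_sd = cons["sd"],
               consumed_cv = 100 * cons["sd"] / cons["mean"],
               conc_mean = conc["mean"], conc_sd = conc["sd"],
               conc_cv = 100 * conc["sd"] / conc["mean"],
               mmad_mean = mean(d$mmad), gsd_mean = mean(d$gsd))
  }))
  rownames(tab) <- NULL

  split_vals <- function(col) {
    out <- split(fitted[[col]], fitted$formulation)[fms]
    out[vapply(out, function(v) sum(!is.na(v)) >= 2, TRUE)]
  }
  cmp_mmad <- if (length(fms) >= 2) compare_formulations(split_vals("mmad"), alpha) else NULL
  conc_groups <- split_vals("conc_ug_cm3")
  cmp_conc <- if (length(conc_groups) >= 2) compare_formulations(conc_groups, alpha) else NULL
  tab$mmad_letters <- if (!is.null(cmp_mmad)) unname(cmp_mmad$letters[tab$formulation]) else "A"
  tab$conc_letters <- if (!is.null(cmp_conc)) unname(cmp_conc$letters[tab$formulation]) else "A"

  deposition <- lapply(fms, function(fmname) {
    d <- tab[tab$formulation == fmname, ]
    polydisperse_deposition(
      lognormal_psd(d$mmad_mean, max(d$gsd_mean, 1),
                    basis = "mass", diameter_kind = "aerodynamic"),
      lung, breathing, n_quadrature = n_quadrature)
  })
  names(deposition) <- fms

  structure(
    list(table = tab, per_trial = per_trial,
         comparisons = list(mmad = cmp_mmad, concentration = cmp_conc),
         deposition = deposition, log = log,
         counts = c(read = nrow(per_trial), fitted = nrow(fitted),
                    skipped = nrow(per_trial) - nrow(fitted)),
         breathing = breathing),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Study result: %d formulations (%d trials read, %d fitted, %d skipped)\n\n",
              nrow(x$table), x$counts["read"], x$counts["fitted"], x$counts["skipped"]))
  show <- x$table[, c("formulation", "consumed_mean", "conc_mean",
                      "mmad_mean", "gsd_mean", "mmad_letters")]
  show$consumed_mean <- round(show$consumed_mean)
  show$conc_mean <- round(show$conc_mean, 1)
  show$mmad_mean <- round(show$mmad_mean, 2)
  show$gsd_mean <- round(show$gsd_mean, 2)
  print(show, row.names = FALSE)
  cat("\nDeposition (total | exhaled):\n")
  for (fmname in names(x$deposition)) {
    r <- x$deposition[[fmname]]
    cat(sprintf("  %-28s %.3f | %.3f\n", fmname, r$total_fraction, r$exhaled_fraction))
  }
  invisible(x)
}

#' Write study results to disk
#'
#' @param result A `"study_result"`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"json"`.
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir, format = c("csv", "json")) {
  stopifnot(inherits(result, "study_result"))
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dep <- do.call(rbind, lapply(names(result$deposition), function(fmname) {
    r <- result$deposition[[fmname]]
    data.frame(formulation = fmname, head = r$head_fraction,
               tracheobronchial = r$tracheobronchial_fraction,
               pulmonary = r$pulmonary_fraction,
               total = r$total_fraction, exhaled = r$exhaled_fraction)
  }))
  if (format == "csv") {
    utils::write.csv(result$table, file.path(dir, "formulations.csv"), row.names = FALSE)
    utils::write.csv(result$per_trial, file.path(dir, "trials.csv"), row.names = FALSE)
    utils::write.csv(dep, file.path(dir, "deposition.csv"), row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(formulations = result$table, trials = result$per_trial,
           deposition = dep, counts = as.list(result$counts), log = result$log),
      file.path(dir, "study_result.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (length(result$log)) writeLines(result$log, file.path(dir, "pipeline.log"))
  invisible(dir)
}
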