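# Plain-text CSV dialects for impactor trials and mobility scans.
#
# Both formats carry trial/scan metadata as leading comment lines of the
# form "# key: value", followed by a regular CSV table.

read_metadata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

meta_num <- function(meta, key, default = NA_real_) {
  if (is.null(meta[[key]]) || meta[[key]] == "") default else as.numeric(meta[[key]])
}

#' Read an impactor trial from CSV
#'
#' Expects columns `stage_id`, `d50_um`, `pre_mass_mg`, `post_mass_mg`; an
#' optional backup-filter row has an empty `d50_um`. Trial metadata (puff
#' count and volume, sampled volume, reservoir masses, balance resolution,
#' formulation) is carried in `# key: value` comment lines.
#'
#' @param path File path.
#' @return An [impactor_trial()]; the formulation label, if present, is
#'   attached as attribute `"formulation"`.
#' @export
read_impactor_csv <- function(path) {
  meta <- read_metadata(path)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(stage_id = "character"))
  backup <- NA_real_
  is_backup <- is.na(df$d50_um)
  if (any(is_backup)) {
    b <- df[is_backup, ][1, ]
    backup <- b$post_mass_mg - b$pre_mass_mg
    df <- df[!is_backup, ]
  }
  o <- order(df$d50_um, decreasing = TRUE)
  trial <- impactor_trial(
    d50 = df$d50_um[o], pre_mass = df$pre_mass_mg[o], post_mass = df$post_mass_mg[o],
    backup_filter_mass = backup,
    puff_count = meta_num(meta, "puff_count", 2),
    puff_volume = meta_num(meta, "puff_volume_cm3", 55),
    ecag_volume = meta_num(meta, "ecag_volume_cm3",
                           meta_num(meta, "puff_count", 2) *
                             meta_num(meta, "puff_volume_cm3", 55)),
    eliquid_mass_pre = meta_num(meta, "eliquid_mass_pre_mg"),
    eliquid_mass_post = meta_num(meta, "eliquid_mass_post_mg"),
    balance_resolution = meta_num(meta, "balance_resolution_mg", 0.1),
    id = meta[["id"]]
  )
  attr(trial, "formulation") <- meta[["formulation"]]
  trial
}

#' Write an impactor trial to CSV
#'
#' @param trial An [impactor_trial()].
#' @param path File path.
#' @param formulation Optional formulation label stored in the metadata.
#' @return `path`, invisibly.
#' @export
write_impactor_csv <- function(trial, path, formulation = NULL) {
  stopifnot(inherits(trial, "impactor_trial"))
  meta <- c(
    if (!is.null(trial$id)) sprintf("# id: %s", trial$id),
    if (!is.null(formulation)) sprintf("# formulation: %s", formulation),
    sprintf("# puff_count: %g", trial$puff_count),
    sprintf("# puff_volume_cm3: %g", trial$puff_volume),
    sprintf("# ecag_volume_cm3: %g", trial$ecag_volume),
    if (!is.na(trial$eliquid_mass_pre))
      sprintf("# eliquid_mass_pre_mg: %g", trial$eliquid_mass_pre),
    if (!is.na(trial$eliquid_mass_post))
      sprintf("# eliquid_mass_post_mg: %g", trial$eliquid_mass_post),
    sprintf("# balance_resolution_mg: %g", trial$balance_resolution)
  )
  df <- data.frame(stage_id = sprintf("stage%02d", seq_len(nrow(trial$stages))),
                   d50_um = trial$stages$d50,
                   pre_mass_mg = trial$stages$pre_mass,
                   post_mass_mg = trial$stages$post_mass)
  if (!is.na(trial$backup_filter_mass)) {
    df <- rbind(df, data.frame(stage_id = "backup_filter", d50_um = NA,
                               pre_mass_mg = 0,
                               post_mass_mg = trial$backup_filter_mass))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mobility scan from CSV
#'
#' Expects columns `channel_lo_nm`, `channel_hi_nm`, `conc_per_cm3`, with
#' instrument metadata in `# key: value` comment lines.
#'
#' @param path File path.
#' @return A [mobility_scan()].
#' @export
read_mobility_csv <- function(path) {
  meta <- read_metadata(path)
  df <- utils::read.csv(path, comment.char = "#")
  instr <- tolower(meta[["instrument"]] %||% "other")
  if (!instr %in% c("smps", "fmps", "other")) instr <- "other"
  mobility_scan(df$channel_lo_nm, df$channel_hi_nm, df$conc_per_cm3,
                instrument = instr,
                sample_flow = meta_num(meta, "sample_flow_lpm"),
                dilution_factor = meta_num(meta, "dilution_factor", 1),
                integration_time = meta_num(meta, "integration_time_s"))
}

#' Write a mobility scan to CSV
#'
#' @param scan A [mobility_scan()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mobility_csv <- function(scan, path) {
  stopifnot(inherits(scan, "mobility_scan"))
  meta <- c(sprintf("# instrument: %s", scan$instrument),
            if (!is.na(scan$sample_flow))
              sprintf("# sample_flow_lpm: %g", scan$sample_flow),
            sprintf("# dilution_factor: %g", scan$dilution_factor),
            if (!is.na(scan$integration_time))
              sprintf("# integration_time_s: %g", scan$integration_time))
  df <- data.frame(channel_lo_nm = scan$channels$d_lo,
                   channel_hi_nm = scan$channels$d_hi,
                   conc_per_cm3 = scan$channels$concentration)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory of CSV files
#'
#' Emits one impactor CSV per trial, one mobility CSV per scan, and a
#' `truth.csv` ledger (formulation, trial, true MMAD/GSD, seed).
#'
#' @param study An `"aerosol_study"` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "aerosol_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- study$truth
  for (id in names(study$trials)) {
    fm <- truth$formulation[truth$id == id][1]
    write_impactor_csv(study$trials[[id]],
                       file.path(dir, paste0(id, ".csv")), formulation = fm)
  }
  for (id in names(study$scans)) {
    write_mobility_csv(study$scans[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
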