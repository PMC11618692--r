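# CSV dialects, run configuration, and report assembly. Plain RFC-4180
# CSV with '.' decimals everywhere: one file per sensor deployment
# (time_s,p1_hPa,p2_hPa,p3_hPa) plus a metadata table, and one fish
# table. All stage counts (channels dropped, fish removed, deployments
# failed) are reported so the accounting mirrors the field protocol's.

#' Default run configuration
#'
#' All pipeline constants with their defaults: the injection threshold
#' (1005 hPa), nadir search windows (3-75 s pump / 5-75 s control),
#' nadir change criterion (20 hPa within 0.1 s), Savitzky-Golay settings
#' (order 2, window 11), acclimation pressure (1000 hPa), strain
#' threshold (500 1/s) and calibration anchor (3.45 hPa at 5 m/s and
#' 4.5 degC), and sampling rate (100 Hz).
#'
#' @param ... Named overrides of any default.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- list(
    fs = 100,
    acclimation_hPa = 1000,
    injection_threshold_hPa = 1005,
    nadir_change_hPa = 20,
    nadir_horizon_s = 0.1,
    nadir_window_pump_s = c(3, 75),
    nadir_window_control_s = c(5, 75),
    sg_order = 2L,
    sg_window = 11L,
    roc_half_width_s = 0.5,
    exit_band_hPa = 5,
    exit_dwell_s = 1,
    strain_threshold = 500,
    velocity_ms = 5,
    water_temp_C = 4.5,
    anchor = list(velocity_ms = 5, tempC = 4.5, dp_hPa = 3.45, strain = 500),
    outlier_fence_k = 3,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  attr(cfg, "overridden") <- names(overrides)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  ov <- attr(x, "overridden")
  for (nm in names(x)) {
    val <- x[[nm]]
    if (is.list(val)) val <- paste(names(val), unlist(val), sep = "=")
    cat(sprintf("  %-24s %s%s\n", nm, paste(format(val), collapse = " "),
                if (nm %in% ov) "   [override]" else ""))
  }
  invisible(x)
}

#' Write / read sensor deployments
#'
#' One CSV per deployment with columns `time_s,p1_hPa,p2_hPa,p3_hPa`
#' and a shared metadata CSV with columns
#' `deployment,pump,rpm,sensor_id,water_temp_C,fs,t_exit_manual_s`.
#'
#' @param deployments Named list of [pressure_trace()] objects (or of
#'   lists holding a `trace` element, as produced by [gen_bds_batch()]).
#' @param dir Directory for the per-deployment CSVs.
#' @param meta_file Path of the metadata CSV.
#' @return `write_deployments()` returns the metadata table invisibly;
#'   `read_deployments()` returns a named list of traces, with any
#'   manual exit times attached as `attr(trace, "t_exit_manual_s")`.
#' @export
write_deployments <- function(deployments, dir, meta_file) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_rows <- list()
  for (nm in names(deployments)) {
    tr <- deployments[[nm]]
    if (!inherits(tr, "pressure_trace")) tr <- tr$trace
    df <- data.frame(time_s = tr$time, tr$channels)
    names(df) <- c("time_s", paste0("p", seq_len(ncol(tr$channels)), "_hPa"))
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    meta_rows[[nm]] <- data.frame(
      deployment = nm, pump = tr$meta$pump, rpm = tr$meta$rpm,
      sensor_id = tr$meta$sensor_id, water_temp_C = tr$meta$water_temp_C,
      fs = tr$fs, t_exit_manual_s = NA_real_
    )
  }
  meta <- do.call(rbind, meta_rows)
  utils::write.csv(meta, meta_file, row.names = FALSE)
  invisible(meta)
}

#' @rdname write_deployments
#' @export
read_deployments <- function(dir, meta_file) {
  meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
  need <- c("deployment", "pump", "rpm", "sensor_id", "fs")
  if (!all(need %in% names(meta))) {
    stop("MissingMeta: metadata lacks column(s) ",
         paste(setdiff(need, names(meta)), collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (r in seq_len(nrow(meta))) {
    path <- file.path(dir, paste0(meta$deployment[r], ".csv"))
    if (!file.exists(path)) {
      stop("ParseError: missing deployment file ", path, call. = FALSE)
    }
    df <- utils::read.csv(path)
    pcols <- grep("^p\\d+_hPa$", names(df), value = TRUE)
    if (!"time_s" %in% names(df) || length(pcols) == 0L) {
      stop("ParseError: ", path, " lacks time_s/p*_hPa columns", call. = FALSE)
    }
    bad <- which(diff(df$time_s) <= 0)
    if (length(bad)) {
      stop("ParseError: non-monotone time in ", path, " at line(s) ",
           paste(utils::head(bad + 2L, 5L), collapse = ", "),
           " (1-based incl. header)", call. = FALSE)
    }
    wt <- if ("water_temp_C" %in% names(meta)) meta$water_temp_C[r] else 4.5
    ch <- as.matrix(df[pcols])
    colnames(ch) <- sub("_hPa$", "", pcols)
    tr <- pressure_trace(
      ch, fs = meta$fs[r],
      meta = deployment_meta(meta$pump[r], rpm = meta$rpm[r],
                             sensor_id = meta$sensor_id[r],
                             water_temp_C = wt),
      time = df$time_s
    )
    if ("t_exit_manual_s" %in% names(meta)) {
      attr(tr, "t_exit_manual_s") <- meta$t_exit_manual_s[r]
    }
    out[[meta$deployment[r]]] <- tr
  }
  out
}

#' Write / read fish record tables
#'
#' Columns: `id,species,scenario_theoretical,scenario_observed,type,rpm,`
#' `length_mm,mass_g,condition,injury_codes,delayed_dead_24h,`
#' `delayed_dead_48h` with `injury_codes` a `";"`-separated code string
#' (empty = injury free). Unknown injury codes are rejected on read.
#'
#' @param records Fish record data frame.
#' @param file CSV path.
#' @return `read_fish()` returns the typed record table.
#' @export
write_fish <- function(records, file) {
  utils::write.csv(records, file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname write_fish
#' @export
read_fish <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(injury_codes = "character"))
  need <- c("id", "species", "scenario_theoretical", "type", "condition",
            "injury_codes")
  if (!all(need %in% names(df))) {
    stop("ParseError: fish table lacks column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  known <- injury_codes()$code
  for (i in seq_len(nrow(df))) {
    codes <- parse_injury_codes(df$injury_codes[i])
    if (length(codes) && !all(round(codes, 1) %in% known)) {
      stop("UnknownCode: row ", i, " has injury code(s) ",
           paste(setdiff(round(codes, 1), known), collapse = ", "),
           call. = FALSE)
    }
  }
  for (fl in c("delayed_dead_24h", "delayed_dead_48h")) {
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  }
  df
}

#' Process a batch of deployments into parameters and strain summaries
#'
#' Runs [process_deployment()] and the strain chain over every trace,
#' collecting failures instead of aborting (mirroring the field
#' accounting of lost sensors and unusable datasets).
#'
#' @param traces Named list of [pressure_trace()] objects.
#' @param config A [run_config()].
#' @return List with `params` (data frame: deployment, scenario, nadir,
#'   lrp, roc, landmark times), `strain` (data frame: deployment,
#'   scenario, duration_above_s, mean/max strain), `failed` (named
#'   character vector of error messages) and `n_in` / `n_out`.
#' @export
process_batch <- function(traces, config = run_config()) {
  ctx <- calibrated_context(config$velocity_ms, config$water_temp_C,
                            anchor = config$anchor)
  params <- list(); strains <- list(); failed <- character(0)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    # accept gen_bds_batch() elements (trace + ground truth) directly
    if (!inherits(tr, "pressure_trace") && is.list(tr) && !is.null(tr$trace)) {
      tr <- tr$trace
    }
    res <- tryCatch({
      bp <- process_deployment(
        tr, manual_exit_s = attr(tr, "t_exit_manual_s"),
        change_threshold_hPa = config$nadir_change_hPa,
        horizon_s = config$nadir_horizon_s,
        sg_order = config$sg_order, sg_window = config$sg_window
      )
      clean <- remove_outlier_channels(tr)
      ss <- strain_series(clean, ctx)
      tt <- (seq_len(length(ss$eps_mean)) - 1L) / tr$fs
      win <- which(tt >= bp$marks$t_nadir - config$roc_half_width_s &
                   tt <= bp$marks$t_nadir + config$roc_half_width_s)
      sm <- threshold_exceedance(ss$eps_mean, fs = tr$fs,
                                 threshold = config$strain_threshold,
                                 window_idx = win)
      list(bp = bp, sm = sm)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) { failed[nm] <- res; next }
    bp <- res$bp
    params[[nm]] <- data.frame(
      deployment = nm, scenario = scenario_label(bp),
      nadir_hPa = bp$nadir, lrp = bp$lrp, roc_hPa_s = bp$roc,
      t_injection = bp$marks$t_injection, t_nadir = bp$marks$t_nadir,
      t_exit = bp$marks$t_exit
    )
    strains[[nm]] <- data.frame(
      deployment = nm, scenario = scenario_label(bp),
      duration_above_s = res$sm$duration_above_s,
      mean_strain = res$sm$mean_strain, max_strain = res$sm$max_strain,
      velocity_assumed = config$velocity_ms
    )
  }
  list(
    params = if (length(params)) do.call(rbind, c(params, make.row.names = FALSE)) else NULL,
    strain = if (length(strains)) do.call(rbind, c(strains, make.row.names = FALSE)) else NULL,
    failed = failed, n_in = length(traces), n_out = length(params)
  )
}

#' Assemble the scenario report
#'
#' Bundles the sensor ensemble table, the cohort table and model
#' summaries with provenance (configuration, seed, package version,
#' content hash). Deterministic given identical inputs.
#'
#' @param bds Output of [process_batch()] (requires its `params`).
#' @param strain Strain data frame (defaults to `bds$strain`).
#' @param cohort A [recapture_table()].
#' @param models Optional named list of model fits.
#' @param config The [run_config()] used.
#' @return Object of class `scenario_report`.
#' @export
build_report <- function(bds, strain = bds$strain, cohort, models = list(),
                         config = run_config()) {
  if (is.null(bds) || is.null(bds$params)) {
    stop("MissingStage: bds_signal parameters absent", call. = FALSE)
  }
  if (is.null(strain)) stop("MissingStage: strain summaries absent", call. = FALSE)
  if (missing(cohort) || is.null(cohort)) {
    stop("MissingStage: fish cohort table absent", call. = FALSE)
  }
  ens <- ensemble_stats(data.frame(scenario = bds$params$scenario,
                                   nadir = bds$params$nadir_hPa,
                                   lrp = bds$params$lrp,
                                   roc = bds$params$roc_hPa_s))
  payload <- list(ensemble = ens, strain = strain, cohort = cohort,
                  models = names(models))
  tf <- tempfile(); on.exit(unlink(tf))
  saveRDS(payload, tf)   # scratch only: hashed, then deleted
  structure(
    list(ensemble = ens, strain = strain, cohort = cohort, models = models,
         provenance = list(
           config = unclass(config), seed = config$seed,
           package_version = as.character(utils::packageVersion("pumppass")),
           content_hash = unname(tools::md5sum(tf))
         )),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("== Sensor ensemble (mean +- SD per scenario) ==\n")
  print(x$ensemble, digits = 4)
  cat("\n== Cohort table ==\n")
  print(as.data.frame(x$cohort), digits = 4)
  if (length(x$models)) {
    cat("\n== Models ==\n")
    cat(paste(names(x$models), collapse = ", "), "\n")
  }
  cat(sprintf("\nprovenance: pumppass %s, seed %s, hash %s\n",
              x$provenance$package_version, x$provenance$seed,
              substr(x$provenance$content_hash, 1, 8)))
  invisible(x)
}
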