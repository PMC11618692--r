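# Signal processing for barotrauma detection sensor traces: injection /
# nadir / exit detection, Savitzky-Golay smoothing, and the three
# decompression metrics (nadir, LRP, ROC).

#' Passage landmarks of one pump passage
#'
#' @param t_injection,t_nadir,t_exit Landmark times in seconds from record
#'   start; must be ordered `t_injection < t_nadir < t_exit`.
#' @param nadir_pressure Minimum total pressure at the impeller, hPa.
#' @return An object of class `passage_marks`.
#' @export
passage_marks <- function(t_injection, t_nadir, t_exit, nadir_pressure) {
  if (!(t_injection < t_nadir && t_nadir < t_exit)) {
    stop("InvalidMarks: need t_injection < t_nadir < t_exit", call. = FALSE)
  }
  structure(
    list(t_injection = t_injection, t_nadir = t_nadir, t_exit = t_exit,
         nadir_pressure = nadir_pressure),
    class = "passage_marks"
  )
}

#' @export
print.passage_marks <- function(x, ...) {
  cat(sprintf(
    "<passage_marks> injection %.2f s, nadir %.2f s (%.1f hPa), exit %.2f s\n",
    x$t_injection, x$t_nadir, x$nadir_pressure, x$t_exit
  ))
  invisible(x)
}

#' Detect the moment of injection into the pumping station
#'
#' Injection is the first pressure reading exceeding 1005 hPa: dropping the
#' sensor into the inlet adds hydrostatic pressure on top of the 1000 hPa
#' in-air reference.
#'
#' @param p Mean pressure series, hPa.
#' @param fs Sampling rate, Hz.
#' @param threshold_hPa Injection threshold (default 1005).
#' @return Injection time in seconds from record start (sample k at time
#'   `(k - 1) / fs`).
#' @export
detect_injection <- function(p, fs, threshold_hPa = 1005) {
  idx <- which(p > threshold_hPa)
  if (length(idx) == 0L) {
    stop("NoInjection: pressure never exceeds ", threshold_hPa, " hPa",
         call. = FALSE)
  }
  (idx[1L] - 1L) / fs
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial filter. Interior points use the central
#' convolution weights; within half a window of either edge the polynomial
#' is fit to the first (last) full window and evaluated at the edge
#' positions, so polynomials up to `order` are reproduced exactly
#' everywhere.
#'
#' @param p Numeric series.
#' @param order Polynomial order (default 2).
#' @param window Odd window length in samples, `> order` (default 11).
#' @return Smoothed series, same length as `p`.
#' @export
smooth_sg <- function(p, order = 2L, window = 11L) {
  n <- length(p)
  if (window %% 2L != 1L || window <= order) {
    stop("BadWindow: window must be odd and greater than order", call. = FALSE)
  }
  if (n < window) {
    stop("BadWindow: series shorter than filter window", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  x <- seq.int(-half, half)
  V <- outer(x, 0:order, `^`)                 # window x (order+1) Vandermonde
  # row e of H evaluates the LS polynomial at offset x[e] from window centre
  H <- V %*% solve(crossprod(V), t(V))
  centre_w <- H[half + 1L, ]
  out <- as.numeric(stats::filter(p, rev(centre_w), sides = 2))
  out[seq_len(half)] <- (H %*% p[seq_len(window)])[seq_len(half)]
  out[seq.int(n - half + 1L, n)] <-
    (H %*% p[seq.int(n - window + 1L, n)])[seq.int(half + 2L, window)]
  out
}

#' Detect the pressure nadir of a passage
#'
#' For pump passages the nadir is a sudden sub-second pressure drop at the
#' impeller, searched between 3 and 75 s after injection: the series is
#' Savitzky-Golay smoothed (order 2, window 11) and samples qualifying as
#' nadir candidates are those whose smoothed pressure changes by more than
#' 20 hPa over any lag shorter than the 0.1 s detection horizon; the lowest
#' smoothed pressure among candidates is the nadir. Control drifts have no
#' impeller transient: the raw minimum between 5 and 75 s after injection
#' is taken, with no smoothing.
#'
#' @param p Mean pressure series, hPa.
#' @param t_injection Injection time, s (see [detect_injection()]).
#' @param fs Sampling rate, Hz.
#' @param mode `"pump"` or `"control"`.
#' @param change_threshold_hPa Smoothed-pressure change qualifying a sample
#'   as a nadir candidate (default 20, pump mode only).
#' @param horizon_s Detection horizon: lags strictly below this are
#'   examined for the change criterion (default 0.1 s).
#' @param window_s Search window relative to injection; defaults to
#'   `c(3, 75)` for pumps and `c(5, 75)` for controls.
#' @param sg_order,sg_window Savitzky-Golay settings (pump mode).
#' @return List with `t_nadir` (s) and `nadir_pressure` (hPa; smoothed
#'   value in pump mode, raw in control mode).
#' @export
detect_nadir <- function(p, t_injection, fs, mode = c("pump", "control"),
                         change_threshold_hPa = 20, horizon_s = 0.1,
                         window_s = NULL, sg_order = 2L, sg_window = 11L) {
  mode <- match.arg(mode)
  n <- length(p)
  tt <- (seq_len(n) - 1L) / fs
  if (is.null(window_s)) {
    window_s <- if (mode == "pump") c(3, 75) else c(5, 75)
  }
  in_win <- which(tt >= t_injection + window_s[1L] &
                  tt <= t_injection + window_s[2L])
  if (length(in_win) == 0L) {
    stop("NoNadir: search window lies outside the record", call. = FALSE)
  }

  if (mode == "control") {
    i <- in_win[which.min(p[in_win])]
    return(list(t_nadir = tt[i], nadir_pressure = p[i]))
  }

  ps <- smooth_sg(p, order = sg_order, window = sg_window)
  max_lag <- max(1L, ceiling(horizon_s * fs) - 1L)   # lags k/fs < horizon_s
  candidate <- logical(n)
  for (k in seq_len(max_lag)) {
    j <- seq.int(k + 1L, n)
    hit <- abs(ps[j] - ps[j - k]) > change_threshold_hPa
    candidate[j][hit] <- TRUE
    # a change marks both endpoints of the lag pair: the nadir sample
    # itself sits on the steep flank
    candidate[j - k][hit] <- TRUE
  }
  cand <- in_win[candidate[in_win]]
  if (length(cand) == 0L) {
    stop("NoNadir: no sample meets the ", change_threshold_hPa,
         " hPa change criterion", call. = FALSE)
  }
  i <- cand[which.min(ps[cand])]
  list(t_nadir = tt[i], nadir_pressure = ps[i])
}

#' Detect the exit into the tailwater
#'
#' Regions of interest were marked by eye in the original field protocol;
#' here the exit is found automatically as the first time after the nadir
#' at which the smoothed series settles onto its terminal plateau: within
#' `band_hPa` of the median over the final `tail_s` seconds, and staying
#' inside that band for `dwell_s` seconds. A manually identified exit time
#' can be supplied instead and is returned unchanged.
#'
#' @param p Mean pressure series, hPa.
#' @param t_nadir Nadir time, s.
#' @param fs Sampling rate, Hz.
#' @param manual_exit_s Optional manual override, s.
#' @param band_hPa Plateau tolerance band (default 5 hPa).
#' @param dwell_s Required dwell inside the band (default 1 s).
#' @param tail_s Length of the terminal segment defining the plateau level
#'   (default 1 s).
#' @return Exit time in seconds.
#' @export
detect_exit <- function(p, t_nadir, fs, manual_exit_s = NULL,
                        band_hPa = 5, dwell_s = 1, tail_s = 1) {
  if (!is.null(manual_exit_s) && !is.na(manual_exit_s)) {
    return(as.numeric(manual_exit_s))
  }
  n <- length(p)
  tt <- (seq_len(n) - 1L) / fs
  ps <- smooth_sg(p)
  tail_n <- max(2L, round(tail_s * fs))
  plateau <- stats::median(ps[seq.int(n - tail_n + 1L, n)])
  inside <- abs(ps - plateau) <= band_hPa
  dwell_n <- max(1L, round(dwell_s * fs))
  start <- which(tt > t_nadir)[1L]
  if (is.na(start)) stop("NoExit: nadir at end of record", call. = FALSE)
  # first index >= start from which `inside` holds for dwell_n samples
  run <- 0L
  for (i in seq.int(start, n)) {
    run <- if (inside[i]) run + 1L else 0L
    if (run >= dwell_n) return(tt[i - dwell_n + 1L])
  }
  stop("NoExit: no terminal plateau found after the nadir", call. = FALSE)
}

#' Log ratio pressure change (LRP)
#'
#' `LRP = ln(acclimation / nadir)`, dimensionless; larger values mean a
#' deeper decompression relative to the pressure the fish (or sensor) was
#' acclimated to. The acclimation pressure is taken as 1000 hPa.
#'
#' @param nadir_hPa Nadir pressure(s), hPa; must be positive.
#' @param acclimation_hPa Acclimation pressure, hPa (default 1000).
#' @return Numeric LRP value(s).
#' @export
compute_lrp <- function(nadir_hPa, acclimation_hPa = 1000) {
  if (any(nadir_hPa <= 0) || any(acclimation_hPa <= 0)) {
    stop("NonPositivePressure: nadir and acclimation must be > 0",
         call. = FALSE)
  }
  log(acclimation_hPa / nadir_hPa)
}

#' Maximal rate of pressure change (ROC) near the nadir
#'
#' Maximum absolute one-sample rate `|dP| * fs` of the smoothed series
#' inside a window around the nadir, where the decompression transient at
#' the impeller lives.
#'
#' @param p Mean pressure series, hPa.
#' @param marks A [passage_marks()] object.
#' @param fs Sampling rate, Hz.
#' @param half_width_s Half-width of the nadir window (default 0.5 s).
#' @param smooth Smooth with [smooth_sg()] first (default TRUE).
#' @return ROC in hPa/s (non-negative).
#' @export
compute_roc <- function(p, marks, fs, half_width_s = 0.5, smooth = TRUE) {
  stopifnot(inherits(marks, "passage_marks"))
  ps <- if (smooth) smooth_sg(p) else p
  n <- length(ps)
  tt <- (seq_len(n) - 1L) / fs
  win <- which(tt >= marks$t_nadir - half_width_s &
               tt <= marks$t_nadir + half_width_s)
  if (length(win) < 2L) return(0)
  max(abs(diff(ps[win]))) * fs
}

#' Time-normalized passage profile
#'
#' Registers a passage onto the normalized time axis `u` in `[0, 1]` with
#' landmarks pinned at u = 0 (injection), u = 0.5 (nadir) and u = 1 (exit):
#' 500 equally spaced points between injection and nadir, 500 between nadir
#' and exit, plus the three landmark points themselves (1001 grid points).
#' Pressure is linearly interpolated.
#'
#' @param p Mean pressure series, hPa.
#' @param marks A [passage_marks()] object.
#' @param fs Sampling rate, Hz.
#' @return An object of class `normalized_trace`: list with `u` (length
#'   1001) and `p` (hPa).
#' @export
normalize_time <- function(p, marks, fs) {
  stopifnot(inherits(marks, "passage_marks"))
  n <- length(p)
  tt <- (seq_len(n) - 1L) / fs
  if (marks$t_exit > tt[n] + 1e-9) {
    stop("InvalidMarks: exit beyond end of record", call. = FALSE)
  }
  u <- seq(0, 1, length.out = 1001L)
  t_of_u <- ifelse(
    u <= 0.5,
    marks$t_injection + (u / 0.5) * (marks$t_nadir - marks$t_injection),
    marks$t_nadir + ((u - 0.5) / 0.5) * (marks$t_exit - marks$t_nadir)
  )
  pv <- stats::approx(tt, p, xout = t_of_u, rule = 2)$y
  structure(list(u = u, p = pv), class = "normalized_trace")
}

#' @export
plot.normalized_trace <- function(x, ...,
                                  xlab = "normalized passage time",
                                  ylab = "pressure (hPa)", type = "l") {
  graphics::plot(x$u, x$p, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = 0.5, lty = 3)
  invisible(x)
}

#' Process one deployment end to end
#'
#' Runs the full per-deployment chain: drop failed channels, average, find
#' injection / nadir / exit, and compute nadir, LRP and ROC.
#'
#' @param trace A [pressure_trace()].
#' @param manual_exit_s Optional manually identified exit time, s.
#' @param ... Passed on to [detect_nadir()].
#' @return An object of class `barotrauma_params`: list with `nadir`,
#'   `lrp`, `roc`, `marks`, `meta`.
#' @export
process_deployment <- function(trace, manual_exit_s = NULL, ...) {
  trace <- remove_outlier_channels(trace)
  p <- mean_pressure(trace)
  fs <- trace$fs
  mode <- if (trace$meta$pump == "control") "control" else "pump"
  t_inj <- detect_injection(p, fs)
  nad <- detect_nadir(p, t_inj, fs, mode = mode, ...)
  t_exit <- detect_exit(p, nad$t_nadir, fs, manual_exit_s = manual_exit_s)
  marks <- passage_marks(t_inj, nad$t_nadir, t_exit, nad$nadir_pressure)
  structure(
    list(
      nadir = nad$nadir_pressure,
      lrp = compute_lrp(nad$nadir_pressure, trace$meta$acclimation_hPa),
      roc = compute_roc(p, marks, fs),
      marks = marks,
      meta = trace$meta
    ),
    class = "barotrauma_params"
  )
}

#' @export
print.barotrauma_params <- function(x, ...) {
  cat(sprintf(
    "<barotrauma_params> nadir %.1f hPa, LRP %.3f, ROC %.0f hPa/s (%s%s)\n",
    x$nadir, x$lrp, x$roc, x$meta$pump,
    if (!is.na(x$meta$rpm)) sprintf(" %d rpm", x$meta$rpm) else ""
  ))
  invisible(x)
}

#' Scenario label of a deployment
#'
#' @param meta A [deployment_meta()] (or `barotrauma_params`) object.
#' @return Character scenario label, e.g. `"FNAFP_468"`, `"control_550"`.
#' @export
scenario_label <- function(meta) {
  if (inherits(meta, "barotrauma_params")) meta <- meta$meta
  if (is.na(meta$rpm)) meta$pump else paste(meta$pump, meta$rpm, sep = "_")
}

#' Ensemble statistics of barotrauma parameters per scenario
#'
#' @param params List of `barotrauma_params` objects, or a data frame with
#'   columns `scenario`, `nadir`, `lrp`, `roc`.
#' @return Data frame with one row per scenario: `n` and mean / SD of
#'   nadir, LRP and ROC. The SD of a single-deployment scenario is reported
#'   as `NA`, not 0.
#' @export
ensemble_stats <- function(params) {
  if (!is.data.frame(params)) {
    stopifnot(length(params) >= 1L)
    params <- data.frame(
      scenario = vapply(params, scenario_label, character(1)),
      nadir = vapply(params, `[[`, numeric(1), "nadir"),
      lrp = vapply(params, `[[`, numeric(1), "lrp"),
      roc = vapply(params, `[[`, numeric(1), "roc")
    )
  }
  if (nrow(params) == 0L) stop("EmptyScenario: no deployments", call. = FALSE)
  sd_or_na <- function(x) if (length(x) > 1L) stats::sd(x) else NA_real_
  out <- do.call(rbind, lapply(split(params, params$scenario), function(d) {
    data.frame(
      scenario = d$scenario[1L], n = nrow(d),
      nadir_mean = mean(d$nadir), nadir_sd = sd_or_na(d$nadir),
      lrp_mean = mean(d$lrp), lrp_sd = sd_or_na(d$lrp),
      roc_mean = mean(d$roc), roc_sd = sd_or_na(d$roc)
    )
  }))
  rownames(out) <- NULL
  out
}
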