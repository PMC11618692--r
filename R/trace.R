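#' Deployment metadata for a barotrauma sensor trace
#'
#' Describes the conditions of one sensor deployment: which pump (or a
#' control drift without pump passage), the impeller speed, and the
#' acclimation pressure against which decompression is measured.
#'
#' @param pump One of `"FNAFP"` (the fish-friendly axial flow pump),
#'   `"CAFP"` (the conventional axial flow pump) or `"control"`.
#' @param rpm Impeller speed in revolutions per minute (468, 550 or 585).
#'   Must be `NA` for controls and present for pump deployments.
#' @param sensor_id Label of the physical sensor.
#' @param water_temp_C Water temperature during deployment, degrees Celsius.
#' @param acclimation_hPa Acclimation (reference) pressure in hPa; the
#'   sensors are zeroed to 1000 hPa in air before deployment.
#' @return An object of class `deployment_meta`.
#' @export
deployment_meta <- function(pump = c("FNAFP", "CAFP", "control"),
                            rpm = NA_integer_,
                            sensor_id = "BDS",
                            water_temp_C = 4.5,
                            acclimation_hPa = 1000) {
  pump <- match.arg(pump)
  if (pump == "control") {
    if (!is.na(rpm)) {
      # controls carry the rpm of the concurrent scenario only as a label
      rpm <- as.integer(rpm)
    }
  } else {
    if (is.na(rpm)) stop("rpm is required for pump deployments", call. = FALSE)
    rpm <- as.integer(rpm)
  }
  stopifnot(acclimation_hPa > 0)
  structure(
    list(pump = pump, rpm = rpm, sensor_id = as.character(sensor_id),
         water_temp_C = water_temp_C, acclimation_hPa = acclimation_hPa),
    class = "deployment_meta"
  )
}

#' Three-channel pressure trace from a barotrauma detection sensor
#'
#' The sensor logs total water pressure (atmospheric + hydrostatic +
#' hydrodynamic) on three redundant channels at a fixed sampling rate,
#' nominally 100 Hz, in hPa.
#'
#' @param channels Numeric matrix, one column per pressure channel (hPa).
#'   A vector is treated as a single channel.
#' @param fs Sampling rate in Hz (default 100).
#' @param meta A [deployment_meta()] object.
#' @param time Optional time vector in seconds; defaults to a uniform grid
#'   starting at 0. Must be uniform and strictly increasing.
#' @return An object of class `pressure_trace` with fields `time`,
#'   `channels`, `fs`, `meta`.
#' @export
pressure_trace <- function(channels, fs = 100, meta = deployment_meta("control"),
                           time = NULL) {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  n <- nrow(channels)
  if (n < 2L) stop("trace must contain at least 2 samples", call. = FALSE)
  stopifnot(fs > 0)
  if (is.null(time)) {
    time <- (seq_len(n) - 1L) / fs
  } else {
    if (length(time) != n) stop("time and channels lengths differ", call. = FALSE)
    dt <- diff(time)
    if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
    if (diff(range(dt)) > 1e-6 / fs + 1e-9) {
      stop("time grid must be uniform", call. = FALSE)
    }
  }
  if (is.null(colnames(channels))) {
    colnames(channels) <- paste0("p", seq_len(ncol(channels)))
  }
  structure(
    list(time = as.numeric(time), channels = channels, fs = fs, meta = meta),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf(
    "<pressure_trace> %d samples x %d channels @ %g Hz (%.1f s), %s%s\n",
    nrow(x$channels), ncol(x$channels), x$fs,
    nrow(x$channels) / x$fs, x$meta$pump,
    if (!is.na(x$meta$rpm)) sprintf(" %d rpm", x$meta$rpm) else ""
  ))
  invisible(x)
}

#' Drop failed pressure channels
#'
#' A failed channel reports a saturated average pressure of 1e5 hPa; such
#' channels are removed before the trace is averaged. It is an error for
#' every channel to be failed.
#'
#' @param trace A [pressure_trace()].
#' @param limit_hPa Mean-pressure threshold marking a channel as failed
#'   (default `1e5`).
#' @return The trace with outlier channels removed.
#' @export
remove_outlier_channels <- function(trace, limit_hPa = 1e5) {
  stopifnot(inherits(trace, "pressure_trace"))
  means <- colMeans(trace$channels)
  keep <- is.finite(means) & means < limit_hPa
  if (!any(keep)) {
    stop("AllChannelsInvalid: every channel has mean pressure >= ",
         format(limit_hPa), " hPa", call. = FALSE)
  }
  trace$channels <- trace$channels[, keep, drop = FALSE]
  trace
}

#' Average the surviving pressure channels
#'
#' @param trace A [pressure_trace()] after [remove_outlier_channels()].
#' @return Numeric vector: pointwise mean pressure in hPa.
#' @export
mean_pressure <- function(trace) {
  stopifnot(inherits(trace, "pressure_trace"))
  rowMeans(trace$channels)
}
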