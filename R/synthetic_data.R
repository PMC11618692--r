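# Seeded generators for ground-truthed sensor traces and fish cohorts.
# These state the world the rest of the package is tested against: a
# pump passage is an injection step onto a hydrostatic level, a single
# sharp sub-second nadir dip at the impeller, recovery, and an exit step
# to a tailwater plateau; fish cohorts carry length-, rpm- and
# species-dependent survival with near-injury-free controls and a
# lingering fraction that slips into the next scenario.

#' Scenario description for a synthetic sensor trace
#'
#' @param kind `"pump"` or `"control"`.
#' @param baseline_hPa In-air / pre-injection pressure (default 1000).
#' @param hydrostatic_rise_hPa Pressure added on injection into the pump
#'   cellar (default 30 hPa, about 0.3 m of water).
#' @param nadir_depth_hPa Depth of the impeller dip below the pre-nadir
#'   level (pump only; default 100, must exceed the 20 hPa detection
#'   criterion to be detectable).
#' @param nadir_width_s Gaussian sigma of the dip (default 0.05 s: the
#'   transient is sub-second, inside the 0.1 s detection horizon).
#' @param t_injection_s,t_nadir_s,t_exit_s Landmark times (defaults 5,
#'   25, 45 s).
#' @param duration_s Record length (default 60 s).
#' @param tailwater_hPa Terminal plateau level (default 1010).
#' @param noise_sd_hPa Per-channel iid Gaussian sensor noise (default 1;
#'   the sensors are accurate to about 1 hPa).
#' @param dp_pulse_hPa,dp_pulse_width_s Lateral differential pulse near
#'   the nadir, split antisymmetrically across the side channels
#'   (defaults 4 hPa, 0.2 s).
#' @param fs Sampling rate (default 100 Hz).
#' @return An object of class `trace_scenario` (a validated list).
#' @export
trace_scenario <- function(kind = c("pump", "control"),
                           baseline_hPa = 1000, hydrostatic_rise_hPa = 30,
                           nadir_depth_hPa = 100, nadir_width_s = 0.05,
                           t_injection_s = 5, t_nadir_s = 25, t_exit_s = 45,
                           duration_s = 60, tailwater_hPa = 1010,
                           noise_sd_hPa = 1,
                           dp_pulse_hPa = 4, dp_pulse_width_s = 0.2,
                           fs = 100) {
  kind <- match.arg(kind)
  if (!(t_injection_s < t_nadir_s && t_nadir_s < t_exit_s &&
        t_exit_s < duration_s)) {
    stop("BadScenario: need t_injection < t_nadir < t_exit < duration",
         call. = FALSE)
  }
  if (kind == "pump" && nadir_depth_hPa <= 20) {
    stop("BadScenario: pump nadir_depth_hPa must exceed the 20 hPa",
         " detection criterion", call. = FALSE)
  }
  structure(as.list(environment()), class = "trace_scenario")
}

# deterministic mean pressure shape of a scenario, evaluated at times tt
trace_shape <- function(scn, tt) {
  level <- scn$baseline_hPa + scn$hydrostatic_rise_hPa
  p <- numeric(length(tt))
  pre <- tt < scn$t_injection_s
  p[pre] <- scn$baseline_hPa
  # injection step, then a short settle onto the hydrostatic level
  mid <- !pre & tt < scn$t_exit_s
  p[mid] <- level
  post <- tt >= scn$t_exit_s
  p[post] <- scn$tailwater_hPa
  if (scn$kind == "pump") {
    dip <- scn$nadir_depth_hPa *
      exp(-0.5 * ((tt - scn$t_nadir_s) / scn$nadir_width_s)^2)
    p <- p - ifelse(mid, dip, 0)
  } else {
    # broad drift over tens of seconds, no sub-second transient; deep
    # enough that the passage minimum stays below the tailwater level
    sag <- 25 * exp(-0.5 * ((tt - scn$t_nadir_s) / 6)^2)
    p <- p - ifelse(mid, sag, 0)
  }
  p
}

#' Generate a three-channel sensor trace with known ground truth
#'
#' Channels share the scenario's mean shape, plus independent Gaussian
#' noise, plus (near the nadir) a lateral differential pulse added to one
#' side channel and subtracted from the other.
#'
#' @param scn A [trace_scenario()].
#' @param seed Integer seed; the trace is bit-reproducible given the
#'   seed.
#' @return List with `trace` (a [pressure_trace()]), `truth` (a
#'   [passage_marks()] holding the true landmark times and the analytic
#'   nadir pressure) and `scenario`.
#' @export
gen_pressure_trace <- function(scn, seed = 1L) {
  stopifnot(inherits(scn, "trace_scenario"))
  n <- round(scn$duration_s * scn$fs)
  tt <- (seq_len(n) - 1L) / scn$fs
  shape <- trace_shape(scn, tt)
  set.seed(seed)
  noise <- matrix(stats::rnorm(3L * n, sd = scn$noise_sd_hPa), n, 3L)
  pulse <- scn$dp_pulse_hPa / 2 *
    exp(-0.5 * ((tt - scn$t_nadir_s) / scn$dp_pulse_width_s)^2)
  channels <- shape + noise
  channels[, 1L] <- channels[, 1L] + pulse   # left
  channels[, 3L] <- channels[, 3L] - pulse   # right
  colnames(channels) <- c("p1", "p2", "p3")
  meta <- if (scn$kind == "control") deployment_meta("control")
          else deployment_meta("FNAFP", rpm = 468L)
  nadir_true <- if (scn$kind == "pump") {
    scn$baseline_hPa + scn$hydrostatic_rise_hPa - scn$nadir_depth_hPa
  } else {
    # a control "nadir" is just the raw minimum over the detector's
    # 5-75 s post-injection search window
    win <- tt >= scn$t_injection_s + 5 & tt <= scn$t_injection_s + 75
    min(trace_shape(scn, tt)[win])
  }
  list(
    trace = pressure_trace(channels, fs = scn$fs, meta = meta),
    truth = passage_marks(scn$t_injection_s, scn$t_nadir_s, scn$t_exit_s,
                          nadir_true),
    scenario = scn
  )
}

#' Scenario description for a synthetic fish cohort
#'
#' Defaults state a world qualitatively matching the field study without
#' claiming its printed magnitudes: eel survive essentially always,
#' roach mostly, bream mostly not; survival declines with length and
#' with impeller speed; the conventional pump is worse than the
#' fish-friendly one; controls are near injury-free.
#'
#' @param species Species name (`"bream"`, `"roach"`, `"eel"`).
#' @param n_per_scenario Named integer vector: fish released per
#'   scenario (names like `"FNAFP_468"`, `"FNAFP_550"`, `"control_468"`,
#'   `"CAFP_585"`).
#' @param length_mean_mm,length_sd_mm Length distribution; defaults per
#'   species anchor on the study's population means (bream 374 mm,
#'   roach 168 mm, eel 636 mm).
#' @param beta0 Survival log-odds intercept at the species' mean length
#'   under the 468 rpm pump scenario.
#' @param beta_length Log-odds change per mm of length (negative: larger
#'   fish fare worse).
#' @param beta_rpm Log-odds offset of the 550 rpm scenario.
#' @param beta_cafp Log-odds offset of the conventional pump.
#' @param control_injury_prob Probability a control fish shows any
#'   injury (handling damage; default 0.01).
#' @param severe_weights,slight_weights Multinomial weights over severe
#'   (3.x) and slight (2.x) codes, defaults shaped like the observed
#'   distributions (3.2 dominant among severe, 2.3 among slight).
#' @param lingering_prob Probability a fish released for one pump
#'   scenario passes during the next one (default 0).
#' @param delayed_mort_prob Probability an otherwise surviving fish dies
#'   in the 24-48 h holding period (default 0.01).
#' @return An object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(species = "roach",
                            n_per_scenario = c(FNAFP_468 = 100, FNAFP_550 = 100,
                                               control_468 = 25, control_550 = 25),
                            length_mean_mm = NULL, length_sd_mm = NULL,
                            beta0 = NULL, beta_length = -0.01,
                            beta_rpm = -0.5, beta_cafp = -2,
                            control_injury_prob = 0.01,
                            severe_weights = c("3.1" = 0.15, "3.2" = 0.5,
                                               "3.5" = 0.13, "3.6" = 0.22),
                            slight_weights = c("2.1" = 0.02, "2.2" = 0.02,
                                               "2.3" = 0.96),
                            lingering_prob = 0,
                            delayed_mort_prob = 0.01) {
  defaults <- list(
    bream = list(len = 374, sd = 40, b0 = -0.8),
    roach = list(len = 168, sd = 25, b0 = 1.2),
    eel   = list(len = 636, sd = 60, b0 = 6)
  )
  dft <- defaults[[species]]
  if (is.null(length_mean_mm)) length_mean_mm <- if (!is.null(dft)) dft$len else 200
  if (is.null(length_sd_mm)) length_sd_mm <- if (!is.null(dft)) dft$sd else 30
  if (is.null(beta0)) beta0 <- if (!is.null(dft)) dft$b0 else 0.5
  stopifnot(all(n_per_scenario >= 0), control_injury_prob >= 0,
            control_injury_prob <= 1, lingering_prob >= 0, lingering_prob <= 1)
  structure(as.list(environment())[setdiff(ls(), c("defaults", "dft"))],
            class = "cohort_scenario")
}

scenario_next <- function(scenarios, s) {
  # the scenario lingering fish end up in: the next pump scenario in order
  pumps <- scenarios[grepl("^FNAFP|^CAFP", scenarios)]
  i <- match(s, pumps)
  if (!is.na(i) && i < length(pumps)) pumps[i + 1L] else s
}

#' Generate a fish cohort with latent truth
#'
#' Lengths are Gaussian; survival of pump-passage fish is Bernoulli with
#' the scenario's logistic model (centred at the species mean length);
#' injuries are drawn conditional on the outcome (dead fish carry a
#' severe code, surviving fish none or a slight code); controls are near
#' injury-free and survive unless injured severely. A lingering fraction
#' is released for one scenario but observed in the next.
#'
#' @param scn A [cohort_scenario()].
#' @param seed Integer seed.
#' @return Data frame of fish records (columns as [read_fish()]), with
#'   the latent generator parameters in `attr(, "latent")` and the
#'   per-scenario release counts in `attr(, "starts")`.
#' @export
gen_fish_cohort <- function(scn, seed = 1L) {
  stopifnot(inherits(scn, "cohort_scenario"))
  set.seed(seed)
  scens <- names(scn$n_per_scenario)
  rows <- list()
  fish_id <- 0L
  for (s in scens) {
    n <- scn$n_per_scenario[[s]]
    if (n == 0L) next
    is_control <- grepl("^control", s)
    is_cafp <- grepl("^CAFP", s)
    rpm <- as.integer(sub("^.*_", "", s))
    len <- round(stats::rnorm(n, scn$length_mean_mm, scn$length_sd_mm))
    len <- pmax(len, 30L)

    observed <- rep(s, n)
    if (!is_control && scn$lingering_prob > 0) {
      linger <- stats::runif(n) < scn$lingering_prob
      observed[linger] <- scenario_next(scens, s)
    }
    obs_rpm <- as.integer(sub("^.*_", "", observed))

    if (is_control) {
      injured <- stats::runif(n) < scn$control_injury_prob
      codes <- ifelse(injured, "2.3", "")
      dead <- rep(FALSE, n)
    } else {
      eta <- scn$beta0 +
        scn$beta_length * (len - scn$length_mean_mm) +
        scn$beta_rpm * (obs_rpm == 550) +
        scn$beta_cafp * is_cafp
      dead <- stats::runif(n) >= stats::plogis(eta)
      codes <- character(n)
      codes[dead] <- sample(names(scn$severe_weights), sum(dead),
                            replace = TRUE, prob = scn$severe_weights)
      alive_injured <- !dead & stats::runif(n) < 0.3
      codes[alive_injured] <- sample(names(scn$slight_weights),
                                     sum(alive_injured), replace = TRUE,
                                     prob = scn$slight_weights)
    }
    delayed <- !dead & !grepl("^3", codes) &
      stats::runif(n) < scn$delayed_mort_prob
    decapitated <- grepl("3.2", codes, fixed = TRUE) & stats::runif(n) < 0.2
    # cube-law mass; eels are elongated, hence the smaller condition factor
    log_cond <- if (scn$species == "eel") -13.3 else -11
    mass <- round(exp(log_cond) * len^3 + stats::rnorm(n, 0, 2), 1)
    rows[[s]] <- data.frame(
      id = sprintf("%s_%s_%04d", scn$species, s, fish_id + seq_len(n)),
      species = scn$species,
      scenario_theoretical = s,
      scenario_observed = observed,
      type = ifelse(is_control, "control", "pump"),
      rpm = obs_rpm,
      length_mm = ifelse(decapitated, NA_integer_, len),
      mass_g = ifelse(decapitated, NA_real_, mass),
      condition = ifelse(dead, "dead", "alive"),
      injury_codes = codes,
      delayed_dead_24h = delayed,
      delayed_dead_48h = FALSE,
      intact = !decapitated
    )
    fish_id <- fish_id + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "latent") <- scn
  attr(out, "starts") <- data.frame(
    species = scn$species, scenario = scens,
    n_start = as.integer(scn$n_per_scenario)
  )
  out
}

#' Generate a batch of sensor deployments shaped like the field campaign
#'
#' One trace per deployment, with group sizes defaulting to the field
#' study's (6 conventional-pump, 64 and 51 fish-friendly-pump at 468 and
#' 550 rpm, 15 + 15 controls) and per-scenario nadir levels drawn around
#' configurable targets (defaults anchor on the reported ensemble means:
#' 854, 964 and 933 hPa).
#'
#' @param n Named integer vector of deployments per scenario.
#' @param nadir_targets,nadir_sds Named numeric vectors: mean and SD of
#'   the per-deployment nadir pressure (hPa) for the pump scenarios.
#' @param noise_sd_hPa Sensor noise (default 1).
#' @param seed Integer seed.
#' @return List of per-deployment lists as returned by
#'   [gen_pressure_trace()], with scenario labels in `names()`.
#' @export
gen_bds_batch <- function(n = c(CAFP_585 = 6, FNAFP_468 = 64, FNAFP_550 = 51,
                                control_468 = 15, control_550 = 15),
                          nadir_targets = c(CAFP_585 = 854, FNAFP_468 = 964,
                                            FNAFP_550 = 933),
                          nadir_sds = c(CAFP_585 = 60, FNAFP_468 = 40,
                                        FNAFP_550 = 45),
                          noise_sd_hPa = 1, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (s in names(n)) {
    for (i in seq_len(n[[s]])) {
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      is_control <- grepl("^control", s)
      if (is_control) {
        scn <- trace_scenario("control", noise_sd_hPa = noise_sd_hPa)
      } else {
        level <- 1030
        target <- stats::rnorm(1L, nadir_targets[[s]], nadir_sds[[s]])
        target <- min(target, level - 30)   # keep the dip detectable
        scn <- trace_scenario("pump", nadir_depth_hPa = level - target,
                              noise_sd_hPa = noise_sd_hPa)
      }
      dep <- gen_pressure_trace(scn, seed = sub_seed)
      rpm <- as.integer(sub("^.*_", "", s))
      pump <- sub("_.*$", "", s)
      dep$trace$meta <- deployment_meta(
        if (is_control) "control" else pump,
        rpm = rpm, sensor_id = sprintf("%s_%02d", s, i)
      )
      out[[length(out) + 1L]] <- dep
      names(out)[length(out)] <- sprintf("%s_%02d", s, i)
    }
  }
  out
}
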