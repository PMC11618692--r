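# Shared fixtures, built in code at test time.

# a quiet three-channel trace around a given mean series
make_trace <- function(p_mean, fs = 100, noise = 0, seed = 1,
                       meta = deployment_meta("FNAFP", rpm = 468)) {
  set.seed(seed)
  n <- length(p_mean)
  ch <- matrix(p_mean, n, 3) + matrix(rnorm(3 * n, sd = noise), n, 3)
  pressure_trace(ch, fs = fs, meta = meta)
}

# Table 2 of the field campaign: start / end counts per species and
# scenario (end counts after lingering fish were reassigned)
field_cohort_counts <- function() {
  data.frame(
    species = rep(c("bream", "eel", "roach"), each = 4),
    scenario = rep(c("control_468", "pump_468", "control_550", "pump_550"), 3),
    n_start = c(50, 155, 45, 52,   50, 300, 50, 300,   100, 400, 50, 500),
    n_end   = c(50,  97, 44, 109,  47, 256, 47, 267,    97, 343, 41, 428)
  )
}

# expand the end counts into a minimal coded fish table
field_cohort_records <- function() {
  cc <- field_cohort_counts()
  data.frame(
    species = rep(cc$species, cc$n_end),
    scenario = rep(cc$scenario, cc$n_end),
    scenario_theoretical = rep(cc$scenario, cc$n_end),
    length_mm = NA_real_, mass_g = NA_real_
  )
}
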