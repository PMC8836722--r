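#' Configuration for a synthetic neuromonitoring recording
#'
#' Parameters of the trend-series generator. The model is additive: MAP
#' carries a slow vasogenic oscillation in the Lundberg-B band plus white
#' measurement noise; ICP couples a fraction (`reactivity_gain`) of the MAP
#' slow wave — the mechanism the pressure reactivity index detects — plus an
#' independent B-wave of its own and noise. AMP follows the exponential
#' pressure-volume relation `amp_baseline * exp(elastance_coeff * (ICP -
#' icp_baseline))` while ICP is below `icp_critical`, and declines linearly
#' above it, emulating the exhausted-compensation regime where pulse
#' amplitude falls as ICP keeps rising. A fixed fraction of samples is
#' flagged invalid to emulate probe artifacts.
#'
#' Defaults emulate a standard postoperative monitoring course: 3 days at
#' 3-second sampling.
#'
#' @param duration_hours recording length, hours (default 72).
#' @param sample_interval_s sampling interval, seconds (default 3).
#' @param icp_baseline,map_baseline baseline pressures, mmHg.
#' @param slow_wave_amplitude amplitude of the shared MAP slow wave, mmHg.
#' @param slow_wave_period_s period of the shared slow wave, seconds
#'   (Lundberg-B range 30-120 s).
#' @param reactivity_gain dimensionless coupling of the MAP slow wave into
#'   ICP; its sign and magnitude steer PRx.
#' @param elastance_coeff exponent of the AMP-ICP relation, per mmHg; steers
#'   the RAP regime.
#' @param icp_critical mmHg; above this turning point AMP declines linearly.
#' @param amp_baseline pulse amplitude at baseline ICP, mmHg.
#' @param bwave_amplitude,bwave_period_s ICP's independent B-wave (set the
#'   amplitude to 0 for a purely coupled ICP).
#' @param noise_sd_icp,noise_sd_map,noise_sd_amp white-noise SDs, mmHg.
#' @param dropout_fraction proportion of samples flagged invalid, in `[0, 1)`.
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   series exactly.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(duration_hours = 72, sample_interval_s = 3,
                       icp_baseline = 15, map_baseline = 90,
                       slow_wave_amplitude = 3, slow_wave_period_s = 60,
                       reactivity_gain = 0.3, elastance_coeff = 0.15,
                       icp_critical = 30, amp_baseline = 2,
                       bwave_amplitude = 1.5, bwave_period_s = 90,
                       noise_sd_icp = 1.5, noise_sd_map = 2,
                       noise_sd_amp = 0.3,
                       dropout_fraction = 0.02, seed = 1L) {
  cfg <- list(duration_hours = duration_hours,
              sample_interval_s = sample_interval_s,
              icp_baseline = icp_baseline, map_baseline = map_baseline,
              slow_wave_amplitude = slow_wave_amplitude,
              slow_wave_period_s = slow_wave_period_s,
              reactivity_gain = reactivity_gain,
              elastance_coeff = elastance_coeff,
              icp_critical = icp_critical, amp_baseline = amp_baseline,
              bwave_amplitude = bwave_amplitude,
              bwave_period_s = bwave_period_s,
              noise_sd_icp = noise_sd_icp, noise_sd_map = noise_sd_map,
              noise_sd_amp = noise_sd_amp,
              dropout_fraction = dropout_fraction, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_scalar(cfg$duration_hours, "duration_hours", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$sample_interval_s, "sample_interval_s", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$icp_baseline, "icp_baseline")
  check_scalar(cfg$map_baseline, "map_baseline")
  check_scalar(cfg$slow_wave_amplitude, "slow_wave_amplitude", lower = 0)
  check_scalar(cfg$slow_wave_period_s, "slow_wave_period_s", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$reactivity_gain, "reactivity_gain")
  check_scalar(cfg$elastance_coeff, "elastance_coeff")
  check_scalar(cfg$icp_critical, "icp_critical")
  check_scalar(cfg$amp_baseline, "amp_baseline", lower = 0)
  check_scalar(cfg$bwave_amplitude, "bwave_amplitude", lower = 0)
  check_scalar(cfg$bwave_period_s, "bwave_period_s", lower = 0, strict_lower = TRUE)
  check_scalar(cfg$noise_sd_icp, "noise_sd_icp", lower = 0)
  check_scalar(cfg$noise_sd_map, "noise_sd_map", lower = 0)
  check_scalar(cfg$noise_sd_amp, "noise_sd_amp", lower = 0)
  check_scalar(cfg$dropout_fraction, "dropout_fraction", lower = 0,
               upper = 1, strict_upper = TRUE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop_field("seed", "must be a single finite number")
  invisible(cfg)
}

amp_from_icp <- function(icp, cfg) {
  d <- icp - cfg$icp_baseline
  below <- cfg$amp_baseline * exp(cfg$elastance_coeff * d)
  a_crit <- cfg$amp_baseline *
    exp(cfg$elastance_coeff * (cfg$icp_critical - cfg$icp_baseline))
  above <- a_crit - cfg$elastance_coeff * a_crit * (icp - cfg$icp_critical)
  pmax(ifelse(icp <= cfg$icp_critical, below, above), 0)
}

#' Simulate one patient's neuromonitoring trend recording
#'
#' Generates a [trend_series()] under the additive slow-wave model described
#' in [sim_config()]. The output is deterministic given the config (including
#' its seed); the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return a [trend_series()] of `floor(duration_hours * 3600 /
#'   sample_interval_s)` samples with exactly
#'   `round(dropout_fraction * n)` samples flagged invalid.
#' @export
#' @examples
#' ts <- simulate_patient(sim_config(duration_hours = 1, seed = 7))
#' hourly_indices(ts)
simulate_patient <- function(config) {
  validate_sim_config(config)
  n <- floor(config$duration_hours * 3600 / config$sample_interval_s)
  if (n < 1L) stop_field("duration_hours", "yields an empty series")
  with_seed(config$seed, {
    tt <- (seq_len(n) - 1) * config$sample_interval_s
    ph <- stats::runif(2, 0, 2 * pi)
    sw <- config$slow_wave_amplitude *
      sin(2 * pi * tt / config$slow_wave_period_s + ph[1])
    bw <- config$bwave_amplitude *
      sin(2 * pi * tt / config$bwave_period_s + ph[2])
    map <- config$map_baseline + sw + stats::rnorm(n, 0, config$noise_sd_map)
    icp <- config$icp_baseline + config$reactivity_gain * sw + bw +
      stats::rnorm(n, 0, config$noise_sd_icp)
    amp <- pmax(amp_from_icp(icp, config) +
                  stats::rnorm(n, 0, config$noise_sd_amp), 0)
    valid <- rep(TRUE, n)
    k <- round(config$dropout_fraction * n)
    if (k > 0) valid[sample.int(n, k)] <- FALSE
    trend_series(icp = icp, map = map, amp = amp, valid = valid,
                 sample_interval_s = config$sample_interval_s)
  })
}

# Variance bookkeeping for the window-correlation calibration. Within a
# correlation window the slow wave contributes ~A^2/2 of variance to both
# channels; inverting the Pearson formula gives the coupling gain that
# produces a target PRx, and the (linearised) elastance that produces a
# target RAP. Used by simulate_cohort() to hit group-level index targets.
gain_for_prx <- function(r, cfg) {
  if (r == 0) return(0)
  S <- cfg$slow_wave_amplitude^2 / 2
  P <- S + cfg$noise_sd_map^2
  Q <- cfg$bwave_amplitude^2 / 2 + cfg$noise_sd_icp^2
  r_max <- sqrt(S / P)
  r <- sign(r) * min(abs(r), 0.98 * r_max)
  sign(r) * sqrt(r^2 * P * Q / (S * (S - r^2 * P)))
}

elastance_for_rap <- function(r, cfg, gain) {
  if (r == 0) return(0)
  r <- sign(r) * min(abs(r), 0.98)
  S <- cfg$slow_wave_amplitude^2 / 2
  Q <- cfg$bwave_amplitude^2 / 2 + cfg$noise_sd_icp^2
  sigma_icp <- sqrt(gain^2 * S + Q)
  cfg$noise_sd_amp * r / (cfg$amp_baseline * sigma_icp * sqrt(1 - r^2))
}

#' Per-group template for a synthetic cohort
#'
#' Covariate distributions and patient-level index targets for one prognosis
#' group. Per patient, the generator draws a target mean ICP, CPP, PRx and
#' RAP from these (truncated) normal distributions, then derives a
#' [sim_config()] whose coupling gain and elastance are calibrated to hit
#' the PRx/RAP targets; the supra-threshold dose DICP is emergent from the
#' ICP level relative to the 20 mmHg threshold.
#'
#' @param age_mean,age_sd age distribution, years.
#' @param male_prop proportion of male patients.
#' @param gcs_levels,gcs_probs admission Glasgow coma scale support and
#'   probabilities.
#' @param hematoma_mean,hematoma_sd hematoma volume, mL.
#' @param gos_levels,gos_probs Glasgow outcome scale support and
#'   probabilities for the group.
#' @param icp_mean,icp_sd,cpp_mean,cpp_sd,prx_mean,prx_sd,rap_mean,rap_sd
#'   patient-level index target distributions.
#' @param sim base [sim_config()] template (duration, sampling, waves,
#'   noise, dropout) shared by the group.
#' @return an object of class `group_spec`.
#' @export
group_spec <- function(age_mean, age_sd, male_prop,
                       gcs_levels, gcs_probs,
                       hematoma_mean, hematoma_sd,
                       gos_levels, gos_probs,
                       icp_mean, icp_sd, cpp_mean, cpp_sd,
                       prx_mean, prx_sd, rap_mean, rap_sd,
                       sim = sim_config()) {
  check_scalar(male_prop, "male_prop", lower = 0, upper = 1)
  for (f in c("age_sd", "hematoma_sd", "icp_sd", "cpp_sd", "prx_sd", "rap_sd"))
    check_scalar(get(f), f, lower = 0)
  structure(list(
    age_mean = age_mean, age_sd = age_sd, male_prop = male_prop,
    gcs_levels = gcs_levels, gcs_probs = gcs_probs,
    hematoma_mean = hematoma_mean, hematoma_sd = hematoma_sd,
    gos_levels = gos_levels, gos_probs = gos_probs,
    icp_mean = icp_mean, icp_sd = icp_sd,
    cpp_mean = cpp_mean, cpp_sd = cpp_sd,
    prx_mean = prx_mean, prx_sd = prx_sd,
    rap_mean = rap_mean, rap_sd = rap_sd,
    sim = sim), class = "group_spec")
}

#' Group templates calibrated to the published two-group baseline table
#'
#' Ready-made [group_spec()]s for the good-prognosis (GOS IV-V) and
#' poor-prognosis (GOS I-III) groups of a 53-patient hypertensive
#' intracerebral hemorrhage cohort; see [cohort_spec()].
#'
#' @param sim base [sim_config()] shared by the group's patients.
#' @return a [group_spec()].
#' @export
default_good_group <- function(sim = sim_config()) {
  group_spec(age_mean = 63.67, age_sd = 11.84, male_prop = 14 / 27,
             gcs_levels = 4:9, gcs_probs = c(1, 1, 2, 3, 2, 1),
             hematoma_mean = 35.41, hematoma_sd = 6.63,
             gos_levels = 4:5, gos_probs = c(0.5, 0.5),
             icp_mean = 10.12, icp_sd = 4.37,
             cpp_mean = 73.65, cpp_sd = 8.27,
             prx_mean = 0.05, prx_sd = 0.098,
             rap_mean = 0.14, rap_sd = 0.10,
             sim = sim)
}

#' @rdname default_good_group
#' @export
default_poor_group <- function(sim = sim_config()) {
  group_spec(age_mean = 64.58, age_sd = 13.62, male_prop = 13 / 26,
             gcs_levels = 4:9, gcs_probs = c(2, 3, 3, 2, 1, 1),
             hematoma_mean = 37.38, hematoma_sd = 6.40,
             gos_levels = 1:3, gos_probs = c(0.08, 0.08, 0.84),
             icp_mean = 27.68, icp_sd = 13.17,
             cpp_mean = 55.88, cpp_sd = 14.68,
             prx_mean = 0.34, prx_sd = 0.12,
             rap_mean = 0.37, rap_sd = 0.12,
             sim = sim)
}

#' Specification of a two-group synthetic cohort
#'
#' Default group templates are calibrated to the published baseline table of
#' a 53-patient hypertensive intracerebral hemorrhage cohort (27 good
#' prognosis, GOS IV-V; 26 poor prognosis, GOS I-III): group means/SDs of
#' age, hematoma volume, mean ICP, CPP, PRx and RAP, sex ratios 14:13 and
#' 13:13, and admission GCS between 4 and 9.
#'
#' @param n_good,n_poor group sizes (each `>= 2`).
#' @param good,poor [group_spec()] templates.
#' @param seed master integer seed; per-patient seeds are derived from it
#'   deterministically.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_good = 27, n_poor = 26,
                        good = default_good_group(),
                        poor = default_poor_group(),
                        seed = 1L) {
  if (!is.numeric(n_good) || n_good < 2) stop_field("n_good", "must be >= 2")
  if (!is.numeric(n_poor) || n_poor < 2) stop_field("n_poor", "must be >= 2")
  stopifnot(inherits(good, "group_spec"), inherits(poor, "group_spec"))
  structure(list(n_good = as.integer(n_good), n_poor = as.integer(n_poor),
                 good = good, poor = poor, seed = seed),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lower), upper)
}

draw_group_patients <- function(gs, n, group, seeds, ids) {
  icp_t <- rtrunc_norm(n, gs$icp_mean, gs$icp_sd, lower = 4)
  cpp_t <- rtrunc_norm(n, gs$cpp_mean, gs$cpp_sd, lower = 20)
  prx_t <- rtrunc_norm(n, gs$prx_mean, gs$prx_sd, lower = -0.65, upper = 0.65)
  rap_t <- rtrunc_norm(n, gs$rap_mean, gs$rap_sd, lower = -0.8, upper = 0.9)
  age <- round(rtrunc_norm(n, gs$age_mean, gs$age_sd, lower = 18, upper = 95))
  sex <- ifelse(stats::runif(n) < gs$male_prop, "male", "female")
  gcs <- sample(gs$gcs_levels, n, replace = TRUE, prob = gs$gcs_probs)
  vol <- rtrunc_norm(n, gs$hematoma_mean, gs$hematoma_sd, lower = 20, upper = 50)
  gos <- sample(gs$gos_levels, n, replace = TRUE, prob = gs$gos_probs)
  lapply(seq_len(n), function(i) {
    cfg <- gs$sim
    cfg$icp_baseline <- icp_t[i]
    cfg$map_baseline <- icp_t[i] + cpp_t[i]
    cfg$reactivity_gain <- gain_for_prx(prx_t[i], gs$sim)
    cfg$elastance_coeff <- elastance_for_rap(rap_t[i], gs$sim,
                                             cfg$reactivity_gain)
    # keep the exhausted-compensation turning point out of the calibrated
    # operating range so RAP follows the elastance target
    cfg$icp_critical <- icp_t[i] + 25
    cfg$seed <- seeds[i]
    list(patient_id = ids[i], group = group,
         age = age[i], sex = sex[i], gcs = gcs[i],
         hematoma_ml = vol[i], gos = gos[i], config = cfg)
  })
}

#' Simulate a two-group cohort of monitored patients
#'
#' Draws covariates and per-patient index targets for each group, derives a
#' calibrated [sim_config()] per patient, and (optionally) attaches the
#' simulated [trend_series()]. All randomness flows from the master seed:
#' per-patient seeds are drawn once from it, so the same spec and seed
#' reproduce the cohort exactly, element for element.
#'
#' @param spec a [cohort_spec()].
#' @param keep_series attach each patient's simulated series (default TRUE;
#'   set FALSE to defer simulation — each record's `config` can be passed to
#'   [simulate_patient()] later).
#' @return list of patient records: `patient_id`, `group` ("good"/"poor"),
#'   `age`, `sex`, `gcs`, `hematoma_ml`, `gos`, `config`, and `series` when
#'   `keep_series`.
#' @export
simulate_cohort <- function(spec, keep_series = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_good + spec$n_poor
  records <- with_seed(spec$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    ids <- sprintf("P%03d", seq_len(n))
    c(draw_group_patients(spec$good, spec$n_good, "good",
                          seeds[seq_len(spec$n_good)],
                          ids[seq_len(spec$n_good)]),
      draw_group_patients(spec$poor, spec$n_poor, "poor",
                          seeds[spec$n_good + seq_len(spec$n_poor)],
                          ids[spec$n_good + seq_len(spec$n_poor)]))
  })
  if (keep_series)
    records <- lapply(records, function(r) {
      r$series <- simulate_patient(r$config)
      r
    })
  records
}

#' Covariate table of a simulated cohort
#' @param cohort list of records from [simulate_cohort()].
#' @return data.frame `patient_id, age, sex, gcs, hematoma_ml, gos, group`.
#' @export
cohort_covariates <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r)
    data.frame(patient_id = r$patient_id, age = r$age, sex = r$sex,
               gcs = r$gcs, hematoma_ml = r$hematoma_ml, gos = r$gos,
               group = r$group)))
}

#' Patient-level indices for a whole cohort
#'
#' Runs [hourly_indices()] and [patient_indices()] for every patient and
#' joins the results to the covariate table. Patients whose recording yields
#' no analysable segment are excluded with a warning; their ids and reasons
#' are returned in the `excluded` attribute.
#'
#' @param cohort list of records from [simulate_cohort()] (with series), or
#'   records whose `config` will be simulated on the fly.
#' @param ... passed to [hourly_indices()].
#' @return data.frame: covariates plus `mean_icp`, `mean_cpp`, `mean_prx`,
#'   `mean_rap`, `total_dicp`, `n_segments`.
#' @export
cohort_indices <- function(cohort, ...) {
  excluded <- list()
  rows <- lapply(cohort, function(r) {
    series <- r$series %||% simulate_patient(r$config)
    hi <- hourly_indices(series, ...)
    pi_ <- withCallingHandlers(
      patient_indices(hi),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(pi_)) {
      excluded[[length(excluded) + 1L]] <<-
        list(patient_id = r$patient_id,
             reason = "no segment reached the minimum valid fraction")
      return(NULL)
    }
    cbind(data.frame(patient_id = r$patient_id, group = r$group,
                     age = r$age, sex = r$sex, gcs = r$gcs,
                     hematoma_ml = r$hematoma_ml, gos = r$gos),
          pi_)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(excluded))
    warning(sprintf("%d patient(s) excluded (no analysable segment)",
                    length(excluded)), call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "excluded") <- excluded
  out
}
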