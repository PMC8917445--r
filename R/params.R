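#' Parameters for the fast-start trial generator
#'
#' Defaults emulate the fast-start assay conditions: 207 newborn fish filmed
#' in 35 mm dishes, up to 3 startle trials each with a usable-recording yield
#' giving roughly 270 trials overall, about one third of which are true
#' responses. Speeds are centroid speeds in mm/s; the frame interval defaults
#' to 0.017/6 s so that 7 frames span exactly 0.017 s (the 0.103-0.120 s
#' classification window).
#'
#' @param n_fish number of fish.
#' @param trials_per_fish maximum startle trials per fish (1-3).
#' @param trial_retention probability that a scheduled trial yields a usable
#'   recording (default `270/621`, the study-scale trial yield).
#' @param responder_fraction probability a trial is a true response.
#' @param responder_peak_speed,nonresponder_peak_speed `list(mean=, sd=)`
#'   peak-speed distributions in mm/s. Responder mean must exceed
#'   non-responder mean.
#' @param latency `list(mean=, sd=)` stimulus-to-pulse-onset latency in s.
#' @param pulse_shape `list(rise=, decay=)` rise time and decay constant of
#'   the speed pulse, seconds.
#' @param baseline_speed slow pre-response drift speed, mm/s.
#' @param speed_jitter SD of the frame-to-frame speed variability added to
#'   the deterministic pulse (locomotor and measurement variability; speeds
#'   are truncated at zero), mm/s. This is what spreads the pooled
#'   instantaneous-speed histogram into two broad modes rather than
#'   spikes.
#' @param acclimation_s length of pre-stimulus footage included in the
#'   clip, s (stimulus at t = 0; the recording starts at `-acclimation_s`).
#'   During acclimation the fish cruises and settles towards the baseline
#'   drift, which also gives background estimation the fish motion it
#'   needs.
#' @param cruise_speed spontaneous cruising speed early in the acclimation
#'   segment, mm/s.
#' @param frame_rate frames per second.
#' @param duration post-stimulus trial length in s; must cover the response
#'   window (0.157 s).
#' @param dish_diameter_mm arena diameter (35 mm fast-start dishes).
#' @param seed integer root seed.
#' @return a validated list of class `faststart_sim_params`.
#' @export
fast_start_sim_params <- function(n_fish = 207,
                                  trials_per_fish = 3,
                                  trial_retention = 270 / 621,
                                  responder_fraction = 0.33,
                                  responder_peak_speed = list(mean = 200, sd = 40),
                                  nonresponder_peak_speed = list(mean = 20, sd = 8),
                                  latency = list(mean = 0.09, sd = 0.008),
                                  pulse_shape = list(rise = 0.02, decay = 0.04),
                                  baseline_speed = 3,
                                  speed_jitter = 4,
                                  acclimation_s = 0.5,
                                  cruise_speed = 30,
                                  frame_rate = 6 / 0.017,
                                  duration = 0.17,
                                  dish_diameter_mm = 35,
                                  seed = 1L) {
  assert_pos(n_fish, "n_fish")
  stopifnot(trials_per_fish >= 1, trials_per_fish <= 3)
  assert_prob(trial_retention, "trial_retention")
  assert_prob(responder_fraction, "responder_fraction")
  assert_dist(responder_peak_speed, "responder_peak_speed")
  assert_dist(nonresponder_peak_speed, "nonresponder_peak_speed")
  assert_dist(latency, "latency")
  assert_pos(pulse_shape$rise, "pulse_shape$rise")
  assert_pos(pulse_shape$decay, "pulse_shape$decay")
  assert_pos(baseline_speed, "baseline_speed", strict = FALSE)
  assert_pos(speed_jitter, "speed_jitter", strict = FALSE)
  assert_pos(acclimation_s, "acclimation_s", strict = FALSE)
  assert_pos(cruise_speed, "cruise_speed", strict = FALSE)
  assert_pos(frame_rate, "frame_rate")
  assert_pos(dish_diameter_mm, "dish_diameter_mm")
  if (duration < 0.157) {
    stop("`duration` must cover the 0-0.157 s response window", call. = FALSE)
  }
  if (responder_peak_speed$mean <= nonresponder_peak_speed$mean) {
    stop("responder peak-speed mean must exceed the non-responder mean", call. = FALSE)
  }
  structure(
    list(n_fish = as.integer(n_fish), trials_per_fish = as.integer(trials_per_fish),
         trial_retention = trial_retention, responder_fraction = responder_fraction,
         responder_peak_speed = responder_peak_speed,
         nonresponder_peak_speed = nonresponder_peak_speed,
         latency = latency, pulse_shape = pulse_shape,
         baseline_speed = baseline_speed, speed_jitter = speed_jitter,
         acclimation_s = acclimation_s,
         cruise_speed = cruise_speed, frame_rate = frame_rate,
         duration = duration, dish_diameter_mm = dish_diameter_mm,
         seed = as.integer(seed)),
    class = "faststart_sim_params")
}

#' Default feeding bout-speed distributions by treatment and age
#'
#' Bout peak speeds (mm/s) rise with age in both maternal-food treatments,
#' with the high-food (HF) improvement outpacing low-food (LF) by day 7 --
#' the ontogenetic pattern the feeding assay is designed to detect.
#'
#' @param treatment `"LF"` or `"HF"`.
#' @param age_days 0, 2 or 7.
#' @return `list(mean=, sd=)` in mm/s.
#' @export
default_bout_speed <- function(treatment = c("LF", "HF"), age_days = 0) {
  treatment <- match.arg(treatment)
  stopifnot(age_days %in% c(0, 2, 7))
  base <- c(`0` = 20, `2` = 28, `7` = 35)[[as.character(age_days)]]
  gain <- if (treatment == "HF") c(`0` = 0, `2` = 4, `7` = 12)[[as.character(age_days)]] else 0
  list(mean = base + gain, sd = 6)
}

#' Parameters for the feeding-session generator
#'
#' A session is 5 min without food (control), a short food-supply interval
#' containing experimenter disturbance, then 5 min with food (feeding).
#' Swimming is modelled as discrete bouts arriving homogeneously in time;
#' between bouts the fish is still.
#'
#' @param control_duration,feeding_duration segment lengths, s (default 300).
#' @param supply_gap food-supply interval length, s.
#' @param bout_rate_control,bout_rate_feeding bout arrival rates, bouts/s.
#' @param bout_speed `list(mean=, sd=)` bout peak speed, mm/s; defaults to
#'   [default_bout_speed()] for the given treatment and age.
#' @param bout_shape `list(rise=, decay=)` bout pulse shape, s.
#' @param disturbance_speed `list(mean=, sd=)` apparent speed injected during
#'   the supply interval (experimenter disturbance), mm/s.
#' @param treatment,age_days,experimental_day session metadata.
#' @param frame_rate frames per second.
#' @param seed integer root seed.
#' @return a validated list of class `feeding_sim_params`.
#' @export
feeding_sim_params <- function(control_duration = 300,
                               feeding_duration = 300,
                               supply_gap = 20,
                               bout_rate_control = 0.05,
                               bout_rate_feeding = 0.25,
                               bout_speed = NULL,
                               bout_shape = list(rise = 0.15, decay = 0.35),
                               disturbance_speed = list(mean = 40, sd = 15),
                               treatment = c("LF", "HF"),
                               age_days = 0,
                               experimental_day = 1,
                               frame_rate = 50,
                               seed = 1L) {
  treatment <- match.arg(treatment)
  assert_pos(control_duration, "control_duration")
  assert_pos(feeding_duration, "feeding_duration")
  assert_pos(supply_gap, "supply_gap", strict = FALSE)
  assert_pos(bout_rate_control, "bout_rate_control", strict = FALSE)
  assert_pos(bout_rate_feeding, "bout_rate_feeding", strict = FALSE)
  stopifnot(age_days %in% c(0, 2, 7))
  if (is.null(bout_speed)) bout_speed <- default_bout_speed(treatment, age_days)
  assert_dist(bout_speed, "bout_speed")
  assert_dist(disturbance_speed, "disturbance_speed")
  assert_pos(frame_rate, "frame_rate")
  structure(
    list(control_duration = control_duration, feeding_duration = feeding_duration,
         supply_gap = supply_gap, bout_rate_control = bout_rate_control,
         bout_rate_feeding = bout_rate_feeding, bout_speed = bout_speed,
         bout_shape = bout_shape, disturbance_speed = disturbance_speed,
         treatment = treatment, age_days = age_days,
         experimental_day = experimental_day,
         frame_rate = frame_rate, seed = as.integer(seed)),
    class = "feeding_sim_params")
}

#' Parameters for the offspring-cohort generator
#'
#' Traits follow a linear fixed-effect surface in treatment (LF = 0, HF = 1),
#' experimental day of birth (1-51), day squared, age at measurement (0 or
#' 7 days) and the treatment x day / treatment x age interactions, plus a
#' maternal random intercept and residual noise. Dry mass and sqrt-scale
#' body fat are generated from their models (fat squared back afterwards);
#' lean dry mass is the implied difference, which keeps
#' `lean_mass <= dry_mass` and `body_fat >= 0` structurally.
#'
#' Default dry-mass day slopes are -0.010 mg/day (LF) and -0.003 mg/day
#' (HF), i.e. a treatment x day coefficient of +0.007.
#'
#' @param n_mothers total mothers, split evenly LF/HF.
#' @param offspring_per_mother offspring per mother over the experiment.
#' @param beta named list of fixed-effect vectors, one per generated trait
#'   (`dry_mass` in mg, `sqrt_body_fat` in sqrt(mg)); each has elements
#'   intercept, treatment, day, day2, age, treatment_day, treatment_age.
#' @param sigma_mother,sigma_resid named numeric vectors of maternal-
#'   intercept and residual SDs per generated trait.
#' @param alive_intercept,alive_decay logit-scale intercept and per-day slope
#'   of the probability that an offspring is found alive (default slope
#'   -0.065/day).
#' @param prop_age7 fraction of offspring measured at age 7 instead of 0.
#' @param day_range experimental-day range for births.
#' @param food_rations metadata: liver-paste ration per feeding, ul.
#' @param seed integer root seed.
#' @return a validated list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_mothers = 50,
                              offspring_per_mother = 12,
                              beta = list(
                                dry_mass = c(intercept = 1.20, treatment = 0.05,
                                             day = -0.010, day2 = 0, age = 0.02,
                                             treatment_day = 0.007, treatment_age = 0.005),
                                sqrt_body_fat = c(intercept = 0.45, treatment = 0.01,
                                                  day = -0.001, day2 = 0, age = 0.005,
                                                  treatment_day = 0, treatment_age = 0.010)),
                              sigma_mother = c(dry_mass = 0.05, sqrt_body_fat = 0.02),
                              sigma_resid = c(dry_mass = 0.05, sqrt_body_fat = 0.03),
                              alive_intercept = 4,
                              alive_decay = -0.065,
                              prop_age7 = 0.2,
                              day_range = c(1, 51),
                              food_rations = c(LF = 25, HF = 100),
                              seed = 1L) {
  assert_pos(n_mothers, "n_mothers")
  assert_pos(offspring_per_mother, "offspring_per_mother")
  needed <- c("intercept", "treatment", "day", "day2", "age",
              "treatment_day", "treatment_age")
  for (tr in c("dry_mass", "sqrt_body_fat")) {
    if (!tr %in% names(beta) || !all(needed %in% names(beta[[tr]]))) {
      stop(sprintf("`beta$%s` must contain: %s", tr, paste(needed, collapse = ", ")),
           call. = FALSE)
    }
    assert_pos(sigma_mother[[tr]], sprintf("sigma_mother[%s]", tr), strict = FALSE)
    assert_pos(sigma_resid[[tr]], sprintf("sigma_resid[%s]", tr), strict = FALSE)
  }
  assert_prob(prop_age7, "prop_age7")
  stopifnot(length(day_range) == 2, day_range[1] >= 1, day_range[2] <= 51,
            day_range[1] <= day_range[2])
  structure(
    list(n_mothers = as.integer(n_mothers),
         offspring_per_mother = as.integer(offspring_per_mother),
         beta = beta, sigma_mother = sigma_mother, sigma_resid = sigma_resid,
         alive_intercept = alive_intercept, alive_decay = alive_decay,
         prop_age7 = prop_age7, day_range = day_range,
         food_rations = food_rations, seed = as.integer(seed)),
    class = "cohort_sim_params")
}

#' Parameters for the frame renderer
#'
#' Frames are rendered as greyscale matrices in `[0, 1]`: uniform dish
#' background, an ellipse-shaped fish silhouette centred on the true centroid
#' and oriented along the instantaneous heading, and additive Gaussian pixel
#' noise. Newborns average ~7 mm body length.
#'
#' @param fish_length_mm silhouette major axis, mm.
#' @param fish_aspect minor/major axis ratio.
#' @param background_grey,fish_grey grey levels in `[0, 1]`.
#' @param pixel_noise_sd additive noise SD in grey-level units.
#' @param seed integer root seed.
#' @return a validated list of class `render_params`.
#' @export
render_params <- function(fish_length_mm = 7,
                          fish_aspect = 0.25,
                          background_grey = 0.85,
                          fish_grey = 0.25,
                          pixel_noise_sd = 0,
                          seed = 1L) {
  assert_pos(fish_length_mm, "fish_length_mm")
  stopifnot(fish_aspect > 0, fish_aspect <= 1)
  for (g in c(background_grey, fish_grey)) {
    if (g < 0 || g > 1) stop("grey levels must lie in [0, 1]", call. = FALSE)
  }
  assert_pos(pixel_noise_sd, "pixel_noise_sd", strict = FALSE)
  structure(
    list(fish_length_mm = fish_length_mm, fish_aspect = fish_aspect,
         background_grey = background_grey, fish_grey = fish_grey,
         pixel_noise_sd = pixel_noise_sd, seed = as.integer(seed)),
    class = "render_params")
}
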