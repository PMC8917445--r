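#' Simulate an offspring cohort with maternal random intercepts
#'
#' Generates one offspring-trait table under the maternal food-restriction
#' design: mothers split evenly between low-food (LF) and high-food (HF)
#' rations, offspring born across the experimental-day range and measured at
#' age 0 or 7 days. Dry mass (mg) and sqrt-scale body fat follow their
#' linear fixed-effect surfaces plus a per-mother random intercept and
#' residual noise; body fat is squared back to mg and lean dry mass is the
#' implied difference `dry_mass - body_fat`, so `lean_mass <= dry_mass` and
#' `body_fat >= 0` hold by construction. The alive/dead flag follows a
#' logistic decline in experimental day and is carried as a covariate only
#' (it never censors traits).
#'
#' @param params a [cohort_sim_params()] object.
#' @return a list of class `cohort_sim` with elements
#'   \describe{
#'     \item{records}{tibble: `mother_id`, `offspring_id`, `treatment`,
#'       `experimental_day`, `age_days`, `dry_mass`, `lean_mass`,
#'       `body_fat` (mg), `alive`.}
#'     \item{mother_effects}{tibble of the true maternal intercepts per
#'       trait.}
#'     \item{params}{the input parameters (the true betas).}
#'   }
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  n_m <- params$n_mothers
  treatments <- rep(c("LF", "HF"), length.out = n_m)

  set.seed(derive_seed(params$seed, "cohort", "mothers"))
  mother_effects <- tibble::tibble(
    mother_id = seq_len(n_m),
    treatment = treatments,
    u_dry_mass = stats::rnorm(n_m, 0, params$sigma_mother[["dry_mass"]]),
    u_sqrt_body_fat = stats::rnorm(n_m, 0, params$sigma_mother[["sqrt_body_fat"]]))

  surface <- function(beta, trt01, day, age) {
    beta[["intercept"]] + beta[["treatment"]] * trt01 + beta[["day"]] * day +
      beta[["day2"]] * day^2 + beta[["age"]] * age +
      beta[["treatment_day"]] * trt01 * day + beta[["treatment_age"]] * trt01 * age
  }

  recs <- lapply(seq_len(n_m), function(m) {
    set.seed(derive_seed(params$seed, "cohort", "offspring", m))
    k <- params$offspring_per_mother
    day <- sample(seq(params$day_range[1], params$day_range[2]), k, replace = TRUE)
    age <- ifelse(stats::runif(k) < params$prop_age7, 7, 0)
    trt01 <- as.integer(treatments[m] == "HF")

    dry <- surface(params$beta$dry_mass, trt01, day, age) +
      mother_effects$u_dry_mass[m] +
      stats::rnorm(k, 0, params$sigma_resid[["dry_mass"]])
    sqfat <- surface(params$beta$sqrt_body_fat, trt01, day, age) +
      mother_effects$u_sqrt_body_fat[m] +
      stats::rnorm(k, 0, params$sigma_resid[["sqrt_body_fat"]])
    fat <- pmax(sqfat, 0)^2
    fat <- pmin(fat, pmax(dry, 0)) # body fat can never exceed total dry mass

    alive <- stats::runif(k) <
      stats::plogis(params$alive_intercept + params$alive_decay * day)

    tibble::tibble(
      mother_id = m,
      offspring_id = paste0("M", m, "_O", seq_len(k)),
      treatment = treatments[m],
      experimental_day = day, age_days = age,
      dry_mass = dry, lean_mass = dry - fat, body_fat = fat,
      alive = alive)
  })

  structure(
    list(records = dplyr::bind_rows(recs),
         mother_effects = mother_effects,
         params = params),
    class = "cohort_sim")
}
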