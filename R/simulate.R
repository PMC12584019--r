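# Synthetic cohort generator: study-matched marginals with a plantable
# monotone admission-score -> TD-level link.

#' Simulation parameters for synthetic cohorts
#'
#' Defaults reproduce the reference inpatient rehabilitation cohort:
#' n = 270; admission ClinFIT mean 165.3 (SD 59.4); mean pre/post
#' improvement 67.8 points (SD 57.5, implying a paired effect size of
#' about 1.18); 54.1% male; age 62.9 (SD 14.3); diagnosis mix stroke
#' 33.0% / MSK 21.1% / cancer 23.3% / other 22.6%.
#'
#' The score -> intensity link is a latent-band model: three ascending
#' planted thresholds t1 < t2 < t3 partition the 0-300 scale into four
#' bands, and the latent TD level of a patient is the number of
#' thresholds at or below their admission score. The observed TD level is
#' the latent one perturbed by +/-1 with probability `td_noise` (clipped
#' to 0-3). Default thresholds (142, 198, 260) are the normal quantiles
#' of the configured admission distribution matching the reference TD
#' marginals 34.4/36.3/23.7/5.6%.
#'
#' @param n cohort size.
#' @param admission_mean,admission_sd admission-score distribution moments
#'   (scores are drawn normal, rounded, clipped to 0-300).
#' @param discharge_mean_improvement,improvement_sd moments of the
#'   admission-minus-discharge improvement draw (points; positive =
#'   functional gain).
#' @param td_thresholds three ascending planted thresholds in \[0, 300\].
#' @param td_noise probability (at most 0.5) that an observed TD level is
#'   perturbed one level up or down from its latent band.
#' @param sex_male_prop proportion male.
#' @param age_mean,age_sd age distribution moments (years; draws are
#'   floored at 18, the adult inclusion bound).
#' @param diagnosis_props named proportions over
#'   stroke/msk/cancer/other; must sum to 1.
#' @param seed RNG seed; two runs with the same params are identical.
#' @return a `clinstage_sim_params` list.
#' @export
simulation_params <- function(n = 270,
                              admission_mean = 165.3, admission_sd = 59.4,
                              discharge_mean_improvement = 67.8,
                              improvement_sd = 57.5,
                              td_thresholds = c(142, 198, 260),
                              td_noise = 0.05,
                              sex_male_prop = 0.541,
                              age_mean = 62.9, age_sd = 14.3,
                              diagnosis_props = c(stroke = 0.330, msk = 0.211,
                                                  cancer = 0.233, other = 0.226),
                              seed = 1L) {
  p <- list(n = n, admission_mean = admission_mean, admission_sd = admission_sd,
            discharge_mean_improvement = discharge_mean_improvement,
            improvement_sd = improvement_sd,
            td_thresholds = as.numeric(td_thresholds), td_noise = td_noise,
            sex_male_prop = sex_male_prop, age_mean = age_mean, age_sd = age_sd,
            diagnosis_props = diagnosis_props, seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "clinstage_sim_params")
}

validate_sim_params <- function(p) {
  if (!is_count1(p$n) || p$n < 1) stopf("n must be a positive integer",
                                        class = "clinstage_param_error")
  t <- p$td_thresholds
  if (length(t) != 3 || any(is.na(t)) || any(diff(t) <= 0) ||
      t[1] < 0 || t[3] > SCORE_MAX) {
    stopf("td_thresholds must satisfy 0 <= t1 < t2 < t3 <= %d", SCORE_MAX,
          class = "clinstage_param_error")
  }
  if (!is.numeric(p$td_noise) || p$td_noise < 0 || p$td_noise > 0.5) {
    stopf("td_noise must lie in [0, 0.5]", class = "clinstage_param_error")
  }
  dp <- p$diagnosis_props
  if (!setequal(names(dp), DIAGNOSIS_LEVELS) || abs(sum(dp) - 1) > 1e-6) {
    stopf("diagnosis_props must be named over %s and sum to 1",
          paste(DIAGNOSIS_LEVELS, collapse = "/"),
          class = "clinstage_param_error")
  }
  if (p$sex_male_prop < 0 || p$sex_male_prop > 1) {
    stopf("sex_male_prop must lie in [0, 1]", class = "clinstage_param_error")
  }
  if (p$admission_sd <= 0 || p$improvement_sd < 0 || p$age_sd <= 0) {
    stopf("scale parameters must be positive", class = "clinstage_param_error")
  }
  invisible(p)
}

#' Latent TD level of a score under planted thresholds
#'
#' The number of thresholds at or below the score: below t1 -> 0, at or
#' above t3 -> 3.
#'
#' @param score integer score vector.
#' @param thresholds three ascending thresholds.
#' @return integer TD levels 0-3.
#' @export
latent_td_level <- function(score, thresholds) {
  findInterval(score, sort(thresholds))
}

#' Simulate a synthetic patient cohort
#'
#' Admission scores are drawn normal with the configured moments, rounded
#' and clipped to 0-300; TD levels follow the latent-band model of
#' [simulation_params()]; discharge = admission minus an improvement draw,
#' rounded and clipped to 0-300; demographics are drawn independently
#' from the configured marginals. Fully reproducible from the seed.
#'
#' @param params a [simulation_params()].
#' @return a [cohort()] of `params$n` patients.
#' @export
#' @examples
#' simulate_cohort(simulation_params(n = 20, seed = 42))
simulate_cohort <- function(params = simulation_params()) {
  if (!inherits(params, "clinstage_sim_params")) params <- do.call(simulation_params, params)
  validate_sim_params(params)
  p <- params
  withr::with_seed(p$seed, {
    adm <- as.integer(clip(round(rnorm(p$n, p$admission_mean, p$admission_sd)),
                           0, SCORE_MAX))
    td <- latent_td_level(adm, p$td_thresholds)
    if (p$td_noise > 0) {
      flip <- runif(p$n) < p$td_noise
      direction <- ifelse(runif(p$n) < 0.5, -1L, 1L)
      td <- ifelse(flip, clip(td + direction, 0L, 3L), td)
    }
    improvement <- rnorm(p$n, p$discharge_mean_improvement, p$improvement_sd)
    dis <- as.integer(clip(round(adm - improvement), 0, SCORE_MAX))
    sex <- ifelse(runif(p$n) < p$sex_male_prop, "male", "female")
    age <- pmax(18, round(rnorm(p$n, p$age_mean, p$age_sd)))
    diagnosis <- sample(names(p$diagnosis_props), p$n, replace = TRUE,
                        prob = p$diagnosis_props)
    cohort(
      tibble::tibble(
        patient_id = sprintf("S%05d", seq_len(p$n)),
        age_years = age, sex = sex, diagnosis = diagnosis,
        clinfit_admission = adm, clinfit_discharge = dis,
        td_level = as.integer(td)
      ),
      provenance = sprintf("synthetic seed=%d", p$seed)
    )
  })
}

#' Read simulation parameters from a YAML or JSON config
#'
#' @param path config file; top-level keys are [simulation_params()]
#'   arguments (unknown keys are an error).
#' @return a `clinstage_sim_params` list.
#' @export
read_simulation_params <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path, class = "clinstage_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(raw), names(formals(simulation_params)))
  if (length(unknown) > 0) {
    stopf("unknown simulation parameter(s): %s", paste(unknown, collapse = ", "),
          class = "clinstage_param_error")
  }
  if (!is.null(raw$diagnosis_props)) raw$diagnosis_props <- unlist(raw$diagnosis_props)
  do.call(simulation_params, raw)
}
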