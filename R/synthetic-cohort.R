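# Seedable synthetic two-group cohorts with the statistical structure of a
# prolonged-weaning SBT study: ventilator primitives and blood gases drawn
# per outcome group from truncated normals, comorbidity flags as Bernoulli
# draws, and a post-SBT observation constructed so the outcome
# classification rule reproduces the intended group label. Derived indices
# are never stored: they are always recomputed from the primitives, so the
# algebraic identities among them hold on generated data by construction.

# Inverse-CDF truncated normal draw (uses the current RNG stream).
rtruncnorm_ <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (phi <= plo) stop("empty truncation interval")
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# (mean, sd, lower, upper) description of one truncated-normal primitive.
tn_ <- function(mean, sd, lower = mean - 3 * sd, upper = mean + 3 * sd) {
  list(mean = mean, sd = sd, lower = lower, upper = upper)
}

#' Specification of a synthetic weaning cohort
#'
#' Builds the parameter set for [generate_cohort()]. The defaults encode the
#' two-group structure of a 130-patient prolonged-weaning cohort: 100 SBT
#' successes and 30 failures, group-wise means and SDs for the ventilator
#' primitives and blood gases, comorbidity prevalences, group-specific
#' post-SBT PaCO2 shifts (+2.4 +/- 4.4 mmHg in success, +10.2 +/- 7.2 in
#' failure), and seven failure patients whose end-of-trial blood gas is
#' missing because distress forced immediate reconnection. Screening bounds
#' constrain the draws (FiO2 <= 0.40, PEEP <= 8 cmH2O, PaCO2 on the
#' ventilator <= 45 mmHg); other truncation defaults to mean +/- 3 SD.
#'
#' Respiratory rate is not specified directly: minute ventilation and tidal
#' volume are drawn and RR = 1000 x MV / VT, which reproduces the observed
#' mean rate (~16.5/min) together with the covariance that links MV, VT and
#' mechanical power. The obesity flag is derived from a drawn BMI
#' (P(BMI >= 30) matches the group prevalences 0.28/0.40) so that body mass,
#' height and the flag stay mutually consistent.
#'
#' @param n_success,n_failure Group sizes (defaults 100 and 30).
#' @param n_missing_post_abg Number of failure-group patients with a missing
#'   post-SBT blood gas (default 7); these fail on a vital-sign criterion.
#' @param success,failure Named lists of truncated-normal parameters
#'   (`mean`, `sd`, `lower`, `upper`) for the per-group primitives;
#'   entries given here override the defaults.
#' @param prevalence_success,prevalence_failure Named comorbidity
#'   prevalences (copd, smoking, malignancy) per group.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_success = 100, n_failure = 30,
                        n_missing_post_abg = 7,
                        success = list(), failure = list(),
                        prevalence_success = c(copd = 0.16, smoking = 0.29,
                                               malignancy = 0.05),
                        prevalence_failure = c(copd = 0.467, smoking = 0.633,
                                               malignancy = 0.167)) {
  if (n_success < 1 || n_failure < 1) stop("group sizes must be positive")
  if (n_missing_post_abg > n_failure) {
    stop("n_missing_post_abg cannot exceed n_failure")
  }
  if (any(c(prevalence_success, prevalence_failure) < 0) ||
      any(c(prevalence_success, prevalence_failure) > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  base_success <- list(
    tidal_volume = tn_(547, 83, lower = 250),
    minute_ventilation = tn_(9.0, 2.0, lower = 4),
    peep = tn_(6.0, 0.9, lower = 3, upper = 8),
    pmax = tn_(22.8, 4.1, lower = 12),
    paco2_mv = tn_(33.9, 4.8),
    pao2_mv = tn_(85.0, 15.9, lower = 45),
    ph_mv = tn_(7.50, 0.05),
    fio2 = tn_(0.27, 0.05, lower = 0.21, upper = 0.40),
    age = tn_(68, 12, lower = 18, upper = 95),
    bmi = tn_(26.5, 6.0, lower = 15, upper = 55),
    height_male = tn_(175, 7),
    height_female = tn_(162, 7),
    p_male = list(mean = 0.66),
    post_paco2_shift = tn_(2.4, 4.4),
    post_bf = tn_(24, 5, lower = 8, upper = 35),
    post_hr = tn_(95, 15, lower = 45, upper = 130),
    post_sbp = tn_(128, 15, lower = 85, upper = 160),
    post_spo2 = tn_(95, 2, lower = 88, upper = 100),
    sbt_duration = tn_(30, 0)
  )
  base_failure <- utils::modifyList(base_success, list(
    tidal_volume = tn_(547, 97, lower = 250),
    minute_ventilation = tn_(9.0, 1.7, lower = 4),
    peep = tn_(6.0, 0.8, lower = 3, upper = 8),
    pmax = tn_(26.3, 3.5, lower = 12),
    paco2_mv = tn_(38.8, 4.5),
    pao2_mv = tn_(79.4, 15.5, lower = 45),
    ph_mv = tn_(7.48, 0.05),
    fio2 = tn_(0.28, 0.04, lower = 0.21, upper = 0.40),
    age = tn_(69, 8, lower = 18, upper = 95),
    bmi = tn_(28.3, 6.7, lower = 15, upper = 55),
    p_male = list(mean = 0.533),
    post_paco2_shift = tn_(10.2, 7.2),
    sbt_duration = tn_(22, 8, lower = 5, upper = 30)
  ))
  spec <- list(
    n_success = n_success, n_failure = n_failure,
    n_missing_post_abg = n_missing_post_abg,
    success = utils::modifyList(base_success, success),
    failure = utils::modifyList(base_failure, failure),
    prevalence_success = prevalence_success,
    prevalence_failure = prevalence_failure
  )
  structure(spec, class = "cohort_spec")
}

# Draw one group's worth of patients; post-SBT fields are made consistent
# with the intended label under classify_sbt_outcome.
draw_group_ <- function(n, pars, prev, outcome, n_missing_abg = 0,
                        max_redraws = 1000) {
  draw <- function(p, m = n) rtruncnorm_(m, p$mean, p$sd, p$lower, p$upper)
  gender <- ifelse(stats::runif(n) < pars$p_male$mean, "male", "female")
  height <- ifelse(gender == "male",
                   draw(pars$height_male), draw(pars$height_female))
  bmi <- draw(pars$bmi)
  tidal_volume <- draw(pars$tidal_volume)
  minute_ventilation <- draw(pars$minute_ventilation)
  peep <- draw(pars$peep)
  # redraw pmax until it clears PEEP by > 2 cmH2O (physiologic floor for a
  # pressure-controlled breath), rather than constraining the marginals
  pmax <- draw(pars$pmax)
  tries <- 0
  repeat {
    bad <- pmax <= peep + 2
    if (!any(bad)) break
    tries <- tries + 1
    if (tries > max_redraws) stop("could not satisfy pmax > PEEP + 2")
    pmax[bad] <- draw(pars$pmax, sum(bad))
  }
  paco2_mv <- draw(pars$paco2_mv)

  post_bf <- draw(pars$post_bf)
  post_hr <- draw(pars$post_hr)
  post_sbp <- draw(pars$post_sbp)
  post_spo2 <- draw(pars$post_spo2)
  post_paco2 <- paco2_mv + draw(pars$post_paco2_shift)
  missing_abg <- rep(FALSE, n)

  if (outcome == "success") {
    # success requires every criterion clear: cap post PaCO2 at 45 by redraw
    tries <- 0
    repeat {
      bad <- post_paco2 > 45
      if (!any(bad)) break
      tries <- tries + 1
      if (tries > max_redraws) stop("could not draw label-consistent success")
      post_paco2[bad] <- paco2_mv[bad] + draw(pars$post_paco2_shift, sum(bad))
    }
  } else {
    # failure: hypercapnia is the canonical trigger; patients whose drawn
    # post PaCO2 stays <= 45 fail on tachypnoea instead
    need_vital <- post_paco2 <= 45
    if (n_missing_abg > 0) {
      missing_abg[seq_len(n_missing_abg)] <- TRUE
      need_vital[seq_len(n_missing_abg)] <- TRUE
      post_paco2[missing_abg] <- NA_real_
    }
    post_bf[need_vital] <- rtruncnorm_(sum(need_vital), 42, 4, 36.5, 60)
  }

  data.frame(
    gender = gender,
    age = draw(pars$age),
    height = height,
    body_mass = bmi * (height / 100)^2,
    tidal_volume = tidal_volume,
    respiratory_rate = 1000 * minute_ventilation / tidal_volume,
    minute_ventilation = minute_ventilation,
    peep = peep,
    pmax = pmax,
    fio2 = draw(pars$fio2),
    paco2_mv = paco2_mv,
    pao2_mv = draw(pars$pao2_mv),
    ph_mv = draw(pars$ph_mv),
    copd = stats::runif(n) < prev[["copd"]],
    smoking = stats::runif(n) < prev[["smoking"]],
    malignancy = stats::runif(n) < prev[["malignancy"]],
    obesity = bmi >= 30,
    post_breathing_frequency = post_bf,
    post_heart_rate = post_hr,
    post_systolic_bp = post_sbp,
    post_spo2 = post_spo2,
    post_paco2 = post_paco2,
    post_ph = draw(pars$ph_mv) - ifelse(outcome == "failure", 0.08, 0.02),
    sbt_duration = draw(pars$sbt_duration),
    sbt_outcome = outcome,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic weaning cohort
#'
#' Draws a cohort of patient records according to a [cohort_spec()]:
#' primitives from group-wise truncated normals, pmax redrawn until it
#' exceeds PEEP by more than 2 cmH2O, comorbidity flags from the group
#' prevalences, and a post-SBT observation built so that
#' [classify_sbt_outcome()] applied to it reproduces the intended group
#' label (failure records get hypercapnia and/or tachypnoea; records with a
#' missing post-SBT blood gas fail on the vital sign alone). Derived indices
#' are not stored; compute them with [compute_panel()].
#'
#' @param spec A `cohort_spec` object.
#' @param seed Integer seed; the same seed yields an identical cohort.
#' @return Data frame of patient records, one row per patient, with a
#'   `patient_id` column and the `sbt_outcome` label.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' table(cohort$sbt_outcome)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  succ <- draw_group_(spec$n_success, spec$success, spec$prevalence_success,
                      "success")
  fail <- draw_group_(spec$n_failure, spec$failure, spec$prevalence_failure,
                      "failure", n_missing_abg = spec$n_missing_post_abg)
  cohort <- rbind(succ, fail)
  cohort <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(cohort))),
                  cohort, stringsAsFactors = FALSE)
  # label consistency is a construction invariant; verify it before returning
  lab <- classify_sbt_outcome(cohort$post_breathing_frequency,
                              cohort$post_heart_rate,
                              cohort$post_systolic_bp,
                              cohort$post_spo2,
                              cohort$post_paco2)
  if (!identical(lab, cohort$sbt_outcome)) {
    stop("internal error: generated labels inconsistent with outcome rule")
  }
  attr(cohort, "seed") <- seed
  cohort
}

#' Simulate index values with a known logistic outcome mechanism
#'
#' Draws an index (e.g. a power-index value) from a normal distribution and
#' the binary SBT outcome from Bernoulli(plogis(beta0 + beta1 x index)).
#' Used for parameter-recovery checks of the logistic regression stage,
#' where the generating mechanism must be known exactly.
#'
#' @param n Number of observations.
#' @param beta0 Intercept on the log-odds scale.
#' @param beta1 Slope per unit of the index.
#' @param mean,sd Normal parameters of the index distribution.
#' @param seed Integer seed.
#' @return Data frame with columns `index` and `outcome` (0/1).
#' @export
generate_logistic_cohort <- function(n, beta0, beta1, mean, sd, seed = 1L) {
  if (n < 1) stop("n must be positive")
  if (sd <= 0) stop("sd must be positive")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  index <- stats::rnorm(n, mean, sd)
  p <- stats::plogis(beta0 + beta1 * index)
  data.frame(index = index, outcome = stats::rbinom(n, 1, p))
}
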