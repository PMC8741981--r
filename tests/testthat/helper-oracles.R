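# Independent oracles used across the suite; deliberately naive
# implementations that share no code with the package internals.

# AUROC by exhaustive pair counting (ties count one half).
brute_force_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# SBT failure rule as a plain disjunction over present fields.
disjunction_outcome <- function(bf, hr, sbp, spo2, paco2) {
  checks <- c(
    if (!is.na(bf)) bf > 35,
    if (!is.na(hr)) hr > 130,
    if (!is.na(sbp)) sbp > 160,
    if (!is.na(spo2)) spo2 < 88,
    if (!is.na(paco2)) paco2 > 45
  )
  if (any(checks)) "failure" else "success"
}

# Youden-optimal threshold by enumeration over attained scores; J compared
# in integer arithmetic (same denominator n_pos * n_neg for all thresholds).
brute_force_youden <- function(scores, labels) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    sum(scores[labels == 1] >= t) * nneg - sum(scores[labels == 0] >= t) * npos
  }, numeric(1))
  max(thr[j == max(j)]) # tie toward higher specificity
}

# Small fixed cohort exercising every index; one row per patient.
toy_cohort <- function() {
  data.frame(
    patient_id = c("A", "B", "C"),
    gender = c("male", "female", "male"),
    age = c(70, 65, 60),
    height = c(175, 160, 180),
    body_mass = c(80, 60, 90),
    tidal_volume = c(547, 450, 600),
    respiratory_rate = c(16.5, 18, 14),
    minute_ventilation = c(9.0, 8.1, 8.4),
    peep = c(6, 5, 7),
    pmax = c(23.6, 20, 28),
    fio2 = c(0.27, 0.3, 0.25),
    paco2_mv = c(35, 33, 40),
    pao2_mv = c(85, 90, 75),
    ph_mv = c(7.5, 7.48, 7.46),
    stringsAsFactors = FALSE
  )
}
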