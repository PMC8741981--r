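# Per-patient candidate predictors of weaning readiness, computed from a
# one-time pre-SBT readout of ventilator settings and arterial blood gas.
# All pressures in cmH2O, volumes in mL at the interface (litres internally
# for power), PaCO2 in mmHg. The energy conversion constant is fixed at
# 0.098 J per cmH2O*L everywhere so that the mechanical-power and
# compliance-normalization routes cancel exactly.

.J_PER_CMH2O_L <- 0.098
.PACO2_TARGET <- 45.0
.VR_PACO2_IDEAL <- 37.5

#' Dynamic driving pressure
#'
#' Driving pressure under pressure-controlled ventilation, defined as the
#' pre-set peak inspiratory pressure minus PEEP.
#'
#' @param pmax Peak (pre-set) inspiratory pressure, cmH2O.
#' @param peep Positive end-expiratory pressure, cmH2O.
#' @return Driving pressure in cmH2O.
#' @examples
#' dynamic_driving_pressure(23.6, 6.0)
#' @export
dynamic_driving_pressure <- function(pmax, peep) {
  stopifnot(is.numeric(pmax), is.numeric(peep))
  if (any(peep < 0)) stop("PEEP must be non-negative")
  if (any(pmax <= peep)) {
    stop("pmax must exceed PEEP (driving pressure must be positive)")
  }
  pmax - peep
}

#' Dynamic lung-thorax compliance
#'
#' Tidal volume delivered per unit of dynamic driving pressure.
#'
#' @param tidal_volume Tidal volume, mL.
#' @param delta_paw Dynamic driving pressure, cmH2O.
#' @return Compliance in mL/cmH2O.
#' @export
dynamic_compliance <- function(tidal_volume, delta_paw) {
  if (any(tidal_volume <= 0)) stop("tidal_volume must be positive")
  if (any(delta_paw <= 0)) stop("delta_paw must be positive")
  tidal_volume / delta_paw
}

#' Mechanical power of ventilation (simplified pressure-controlled form)
#'
#' Energy transferred from the ventilator to the respiratory system per
#' minute, using the simplified formula for pressure-controlled ventilation:
#' 0.098 x RR x VT x Pmax, with Pmax = PEEP + inspiratory driving pressure.
#'
#' @param respiratory_rate Breaths per minute.
#' @param tidal_volume Tidal volume in litres.
#' @param pmax Peak inspiratory pressure, cmH2O.
#' @return Mechanical power in J/min.
#' @examples
#' mechanical_power(16.5, 0.547, 23.6)
#' @export
mechanical_power <- function(respiratory_rate, tidal_volume, pmax) {
  if (any(respiratory_rate <= 0) || any(tidal_volume <= 0) || any(pmax <= 0)) {
    stop("all mechanical power inputs must be positive")
  }
  if (any(tidal_volume > 3)) {
    warning("tidal_volume > 3 L: input may be in mL rather than litres")
  }
  .J_PER_CMH2O_L * respiratory_rate * tidal_volume * pmax
}

#' Mechanical power from minute ventilation
#'
#' Equivalent form of [mechanical_power()] using minute ventilation
#' (RR x VT) directly: 0.098 x MV x Pmax.
#'
#' @param minute_ventilation Minute ventilation, L/min.
#' @param pmax Peak inspiratory pressure, cmH2O.
#' @return Mechanical power in J/min.
#' @export
mechanical_power_mv <- function(minute_ventilation, pmax) {
  if (any(minute_ventilation <= 0) || any(pmax <= 0)) {
    stop("all mechanical power inputs must be positive")
  }
  .J_PER_CMH2O_L * minute_ventilation * pmax
}

#' Predicted body weight
#'
#' Height/gender-based predicted body weight, a surrogate of the lung size of
#' a healthy individual (ARDSNet formula).
#'
#' @param gender "male" or "female" (vectorised).
#' @param height Body height, cm.
#' @return Predicted body weight in kg.
#' @export
predicted_body_weight <- function(gender, height) {
  gender <- as.character(gender)
  if (!all(gender %in% c("male", "female"))) {
    stop("gender must be 'male' or 'female'")
  }
  if (any(height < 120 | height > 220)) {
    warning("height outside 120-220 cm: check units")
  }
  base <- ifelse(gender == "male", 50.0, 45.5)
  base + 0.91 * (height - 152.4)
}

#' Mechanical power normalized to predicted body weight
#'
#' @param mp Mechanical power, J/min.
#' @param pbw Predicted body weight, kg.
#' @return Power per kg of predicted body weight, J/min/kg.
#' @export
pbw_normalized_mp <- function(mp, pbw) {
  if (any(mp <= 0) || any(pbw <= 0)) stop("mp and pbw must be positive")
  mp / pbw
}

#' Mechanical power normalized to dynamic compliance
#'
#' Mechanical power per unit of dynamic lung-thorax compliance, a surrogate
#' of stress intensity (power per unit of actually ventilated lung volume).
#' With compliance in mL/cmH2O this equals mp / (0.098 * ltc_dyn / 1000),
#' and when `mp` comes from [mechanical_power()] it is algebraically
#' RR x Pmax x delta_Paw (the 0.098 factors cancel), in cmH2O^2/min.
#'
#' @param mp Mechanical power, J/min.
#' @param ltc_dyn Dynamic compliance, mL/cmH2O.
#' @return Compliance-normalized power, cmH2O^2/min.
#' @export
ltc_normalized_mp <- function(mp, ltc_dyn) {
  if (any(mp <= 0) || any(ltc_dyn <= 0)) stop("mp and ltc_dyn must be positive")
  mp / (.J_PER_CMH2O_L * ltc_dyn / 1000)
}

#' Power index of the respiratory system
#'
#' Compliance-normalized mechanical power rescaled by (PaCO2 / target)^k to
#' simulate isocapnic conditions at the target PaCO2 (45 mmHg by default),
#' making patients with different respiratory rate and pressure settings
#' comparable. The exponent is an explicit parameter; the variants reported
#' alongside the index use k = 1 and k = 2.
#'
#' @param ltcdyn_mp Compliance-normalized mechanical power, cmH2O^2/min.
#' @param paco2_mv PaCO2 on mechanical ventilation, mmHg.
#' @param exponent Exponent k applied to the PaCO2 ratio (default 1).
#' @param target_paco2 Isocapnic target, mmHg (default 45).
#' @return Power index in cmH2O^2/min.
#' @examples
#' power_index(6853.44, 35, exponent = 1)
#' power_index(6853.44, 45, exponent = 2) # isocapnic fixpoint
#' @export
power_index <- function(ltcdyn_mp, paco2_mv, exponent = 1,
                        target_paco2 = .PACO2_TARGET) {
  if (any(ltcdyn_mp <= 0) || any(paco2_mv <= 0) || any(target_paco2 <= 0)) {
    stop("ltcdyn_mp, paco2_mv and target_paco2 must be positive")
  }
  if (any(exponent < 0)) stop("exponent must be non-negative")
  ltcdyn_mp * (paco2_mv / target_paco2)^exponent
}

#' Ventilatory ratio
#'
#' Dead-space surrogate: measured minute ventilation times measured PaCO2,
#' relative to the predicted minute ventilation (100 mL/kg PBW) times an
#' ideal PaCO2 of 37.5 mmHg.
#'
#' @param minute_ventilation Minute ventilation, L/min.
#' @param paco2_mv PaCO2 on mechanical ventilation, mmHg.
#' @param pbw Predicted body weight, kg.
#' @return Dimensionless ventilatory ratio.
#' @export
ventilatory_ratio <- function(minute_ventilation, paco2_mv, pbw) {
  if (any(minute_ventilation <= 0) || any(paco2_mv <= 0) || any(pbw <= 0)) {
    stop("all ventilatory ratio inputs must be positive")
  }
  (1000 * minute_ventilation * paco2_mv) / (pbw * 100 * .VR_PACO2_IDEAL)
}

#' Compute the full index panel for a cohort
#'
#' Derives all candidate predictors from the primitive ventilator settings
#' and pre-SBT blood gas of each patient: dynamic driving pressure, dynamic
#' compliance, mechanical power, predicted body weight, the power
#' normalizations, both power-index variants, and the ventilatory ratio.
#' Minute ventilation is taken from the `minute_ventilation` column when
#' present and finite, otherwise reconstructed as RR x VT / 1000.
#'
#' @param cohort Data frame with one row per patient; required columns
#'   `patient_id`, `gender`, `height`, `tidal_volume` (mL),
#'   `respiratory_rate`, `peep`, `pmax`, `paco2_mv`; optional
#'   `minute_ventilation` (L/min).
#' @return Data frame with `patient_id` and columns `delta_paw`, `ltc_dyn`,
#'   `mp`, `pbw`, `pbw_mp`, `ltcdyn_mp`, `pi_1`, `pi_2`, `vr`.
#' @export
compute_panel <- function(cohort) {
  required <- c("patient_id", "gender", "height", "tidal_volume",
                "respiratory_rate", "peep", "pmax", "paco2_mv")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  panel_row <- function(rec) {
    out <- try({
      delta_paw <- dynamic_driving_pressure(rec$pmax, rec$peep)
      ltc_dyn <- dynamic_compliance(rec$tidal_volume, delta_paw)
      mp <- mechanical_power(rec$respiratory_rate, rec$tidal_volume / 1000,
                             rec$pmax)
      pbw <- predicted_body_weight(rec$gender, rec$height)
      mv <- rec$minute_ventilation
      if (is.null(mv) || !is.finite(mv)) {
        mv <- rec$respiratory_rate * rec$tidal_volume / 1000
      }
      ltcdyn_mp <- ltc_normalized_mp(mp, ltc_dyn)
      data.frame(
        patient_id = rec$patient_id,
        delta_paw = delta_paw,
        ltc_dyn = ltc_dyn,
        mp = mp,
        pbw = pbw,
        pbw_mp = pbw_normalized_mp(mp, pbw),
        ltcdyn_mp = ltcdyn_mp,
        pi_1 = power_index(ltcdyn_mp, rec$paco2_mv, exponent = 1),
        pi_2 = power_index(ltcdyn_mp, rec$paco2_mv, exponent = 2),
        vr = ventilatory_ratio(mv, rec$paco2_mv, pbw),
        stringsAsFactors = FALSE
      )
    }, silent = TRUE)
    if (inherits(out, "try-error")) {
      stop("index computation failed for patient '", rec$patient_id, "': ",
           attr(out, "condition")$message, call. = FALSE)
    }
    out
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) panel_row(cohort[i, ]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the outcome of a spontaneous breathing trial
#'
#' A trial fails if any objective sign of respiratory failure appears at the
#' end of the trial: breathing frequency > 35/min, heart rate > 130 bpm,
#' systolic blood pressure > 160 mmHg, SpO2 < 88 %, or hypercapnia
#' (PaCO2 > 45.0 mmHg) when an end-of-trial blood gas is available. All
#' cut-offs are strict inequalities; pH is recorded but acidosis alone is
#' not an independent failure trigger (it accompanies hypercapnia).
#'
#' @param breathing_frequency Breaths/min at end of trial (NA if missing).
#' @param heart_rate Heart rate, bpm.
#' @param systolic_bp Systolic blood pressure, mmHg.
#' @param spo2 Peripheral oxygen saturation, percent.
#' @param paco2 End-of-trial PaCO2, mmHg (NA when the blood gas is missing).
#' @return "failure" or "success" (vectorised over the inputs).
#' @export
classify_sbt_outcome <- function(breathing_frequency = NA, heart_rate = NA,
                                 systolic_bp = NA, spo2 = NA, paco2 = NA) {
  n <- max(length(breathing_frequency), length(heart_rate),
           length(systolic_bp), length(spo2), length(paco2))
  bf <- rep_len(breathing_frequency, n)
  hr <- rep_len(heart_rate, n)
  sbp <- rep_len(systolic_bp, n)
  sp <- rep_len(spo2, n)
  pc <- rep_len(paco2, n)
  all_missing <- is.na(bf) & is.na(hr) & is.na(sbp) & is.na(sp) & is.na(pc)
  if (any(all_missing)) {
    stop("cannot classify SBT outcome: every decision field is missing")
  }
  if (any(sp > 100, na.rm = TRUE)) stop("spo2 must be <= 100")
  fail <- (!is.na(bf) & bf > 35) |
    (!is.na(hr) & hr > 130) |
    (!is.na(sbp) & sbp > 160) |
    (!is.na(sp) & sp < 88) |
    (!is.na(pc) & pc > 45.0)
  ifelse(fail, "failure", "success")
}
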