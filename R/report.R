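# Cohort I/O and end-to-end orchestration: read or simulate a cohort,
# derive the index panel, and emit the standard report tables (group
# summary, cross-validated metric battery, whole-cohort AUROCs, logistic
# regressions, correlations) plus a ROC comparison figure. CSV is the
# single interchange format: UTF-8, dot decimal, units fixed by the column
# schema below. Rounding happens only at presentation; machine-readable
# outputs keep full precision.

.cohort_columns <- c(
  "patient_id", "gender", "age", "height", "body_mass",
  "tidal_volume", "respiratory_rate", "minute_ventilation",
  "peep", "pmax", "fio2", "paco2_mv", "pao2_mv", "ph_mv",
  "copd", "smoking", "malignancy", "obesity",
  "post_breathing_frequency", "post_heart_rate", "post_systolic_bp",
  "post_spo2", "post_paco2", "post_ph", "sbt_duration", "sbt_outcome"
)

# Index columns of the panel that are evaluated as failure predictors,
# with display names.
.default_indices <- c(
  paco2_mv = "PaCO2 on MV", vr = "Ventilatory ratio", ltc_dyn = "LTC_dyn",
  mp = "Mechanical power", pbw_mp = "PBW-MP", ltcdyn_mp = "LTC_dyn-MP",
  pi_1 = "Power index (k=1)", pi_2 = "Power index (k=2)"
)

#' Write a cohort to CSV
#'
#' @param cohort Cohort data frame (as from [generate_cohort()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, intersect(.cohort_columns, names(cohort))],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Reads a per-patient cohort table, checks the header, and validates
#' every row against the physiologic invariants (positive tidal volume and
#' respiratory rate, pmax > PEEP, FiO2 in [0.21, 1], positive PaCO2).
#' All offending rows are reported together; empty cells are missing
#' values (allowed only for the post-SBT fields and minute ventilation).
#'
#' @param path CSV file path.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(.cohort_columns,
                      c("minute_ventilation", "post_breathing_frequency",
                        "post_heart_rate", "post_systolic_bp", "post_spo2",
                        "post_paco2", "post_ph", "sbt_outcome"))
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("malformed header: missing columns ",
         paste(missing_cols, collapse = ", "))
  }
  problems <- character(0)
  bad <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) {
      problems <<- c(problems,
                     paste0("row ", paste(rows, collapse = ","), ": ", msg))
    }
  }
  bad(!cohort$gender %in% c("male", "female"), "gender must be male/female")
  bad(is.na(cohort$tidal_volume) | cohort$tidal_volume <= 0,
      "tidal_volume must be positive")
  bad(is.na(cohort$respiratory_rate) | cohort$respiratory_rate <= 0,
      "respiratory_rate must be positive")
  bad(is.na(cohort$peep) | cohort$peep < 0, "peep must be non-negative")
  bad(is.na(cohort$pmax) | cohort$pmax <= cohort$peep,
      "pmax must exceed peep")
  bad(is.na(cohort$fio2) | cohort$fio2 < 0.21 | cohort$fio2 > 1,
      "fio2 must lie in [0.21, 1]")
  bad(is.na(cohort$paco2_mv) | cohort$paco2_mv <= 0,
      "paco2_mv must be positive")
  bad(!is.na(cohort$post_spo2) & cohort$post_spo2 > 100, "spo2 must be <= 100")
  if (length(problems)) {
    stop("invalid cohort file:\n  ", paste(problems, collapse = "\n  "))
  }
  for (v in c("copd", "smoking", "malignancy", "obesity")) {
    cohort[[v]] <- as.logical(cohort[[v]])
  }
  cohort
}

#' ROC comparison plot
#'
#' Overlays the ROC curves of several indices for visual comparison of
#' their discrimination of SBT failure.
#'
#' @param rocs Named list of `roc_curve` objects.
#' @return A ggplot object.
#' @export
plot_roc_comparison <- function(rocs) {
  dat <- do.call(rbind, lapply(names(rocs), function(nm) {
    d <- as.data.frame(rocs[[nm]])
    d$index <- sprintf("%s (AUROC %.2f)", nm, rocs[[nm]]$auroc)
    d
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = fpr, y = tpr, colour = index)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  title = "ROC comparison: predicting SBT failure") +
    ggplot2::theme_minimal()
}

#' Run the full weaning-readiness analysis
#'
#' End-to-end pipeline on a real or synthetic cohort: computes the index
#' panel, the between-group comparison of ventilatory variables, the
#' cross-validated diagnostic metric battery per index, whole-cohort
#' AUROCs, univariable logistic regressions for the power indices, and the
#' correlations of each index with SBT duration and end-of-trial PaCO2.
#' All outputs are written to `outdir` as CSV (full precision), together
#' with a ROC comparison figure and a JSON metadata record of the seed and
#' configuration. The run is deterministic for a fixed seed.
#'
#' @param cohort Cohort data frame; if `NULL`, a synthetic cohort is
#'   generated from `spec` with `seed`.
#' @param spec A [cohort_spec()] used when `cohort` is NULL.
#' @param indices Named character vector of panel/record columns to
#'   evaluate (default [.default_indices]).
#' @param k,repeats Cross-validation layout (defaults 2 and 2).
#' @param seed Integer seed for simulation and partitioning.
#' @param outdir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with `cohort`, `panel`, `group_comparison`,
#'   `cv_metrics`, `auroc`, `regression`, `correlations`, `rocs`.
#' @export
run_analysis <- function(cohort = NULL, spec = cohort_spec(),
                         indices = .default_indices,
                         k = 2, repeats = 2, seed = 1L, outdir = NULL) {
  if (is.null(cohort)) {
    message("simulating cohort: seed ", seed)
    cohort <- generate_cohort(spec, seed = seed)
  }
  if (is.null(cohort$sbt_outcome)) {
    cohort$sbt_outcome <- classify_sbt_outcome(
      cohort$post_breathing_frequency, cohort$post_heart_rate,
      cohort$post_systolic_bp, cohort$post_spo2, cohort$post_paco2)
  }
  y <- as.integer(cohort$sbt_outcome == "failure")
  message(sprintf("cohort: n = %d (%d success / %d failure)",
                  nrow(cohort), sum(y == 0), sum(y)))
  panel <- compute_panel(cohort)
  scores_of <- function(v) {
    if (v %in% names(panel)) panel[[v]] else cohort[[v]]
  }

  # group comparison of the ventilatory variables and indices
  cmp_vars <- c("tidal_volume", "minute_ventilation", "peep", "pmax",
                "paco2_mv", names(indices))
  cmp_vars <- unique(cmp_vars)
  group_comparison <- do.call(rbind, lapply(cmp_vars, function(v) {
    vals <- scores_of(v)
    cr <- compare_groups(vals, cohort$sbt_outcome, "continuous")
    data.frame(variable = v, test = cr$test, p_value = cr$p_value,
               mean_success = mean(vals[y == 0]),
               sd_success = stats::sd(vals[y == 0]),
               mean_failure = mean(vals[y == 1]),
               sd_failure = stats::sd(vals[y == 1]))
  }))

  # cross-validated battery and whole-cohort ROC per index
  rocs <- list()
  cv_rows <- list()
  auroc_rows <- list()
  for (v in names(indices)) {
    s <- scores_of(v)
    rocs[[indices[[v]]]] <- roc_curve(s, y)
    cv <- run_cv(s, y, k = k, repeats = repeats, seed = seed)
    sm <- cv$summary
    cv_rows[[v]] <- data.frame(
      index = indices[[v]], mean_threshold = cv$mean_threshold,
      sens = sm$sens, sens_lo = sm$sens_lo, sens_hi = sm$sens_hi,
      spec = sm$spec, spec_lo = sm$spec_lo, spec_hi = sm$spec_hi,
      ppv = sm$ppv, npv = sm$npv, accuracy = sm$accuracy,
      plr = sm$plr, nlr = sm$nlr, dor = sm$dor, f1 = sm$f1, mcc = sm$mcc)
    rc <- rocs[[indices[[v]]]]
    auroc_rows[[v]] <- data.frame(
      index = indices[[v]], auroc = rc$auroc,
      ci_lo = rc$auroc_ci[1], ci_hi = rc$auroc_ci[2], p_value = rc$p_value)
  }
  cv_metrics <- do.call(rbind, cv_rows)
  auroc_tab <- do.call(rbind, auroc_rows)
  rownames(cv_metrics) <- rownames(auroc_tab) <- NULL

  # univariable logistic regressions per 1000 cmH2O^2/min for the power
  # indices, per unit otherwise
  reg_data <- data.frame(pi_1 = panel$pi_1, pi_2 = panel$pi_2,
                         ltcdyn_mp = panel$ltcdyn_mp, mp = panel$mp,
                         paco2_mv = cohort$paco2_mv)
  unit_scale <- c(pi_1 = 1000, pi_2 = 1000, ltcdyn_mp = 1000,
                  mp = 1, paco2_mv = 1)
  regression <- do.call(rbind, lapply(names(reg_data), function(v) {
    f <- fit_logistic(reg_data, y, covariates = v, unit_scale = unit_scale)
    cbind(data.frame(model = "univariable"), f$odds_ratios,
          data.frame(nagelkerke_r2 = f$nagelkerke_r2))
  }))

  # correlations of each index with SBT duration and post-SBT PaCO2
  correlations <- do.call(rbind, lapply(names(indices), function(v) {
    s <- scores_of(v)
    cd <- pearson_with_ci(s, cohort$sbt_duration)
    cp <- pearson_with_ci(s, cohort$post_paco2)
    data.frame(index = indices[[v]],
               r_duration = cd$r, p_duration = cd$p_value,
               r_post_paco2 = cp$r, p_post_paco2 = cp$p_value,
               n_post_paco2 = cp$n)
  }))

  out <- list(cohort = cohort, panel = panel,
              group_comparison = group_comparison,
              cv_metrics = cv_metrics, auroc = auroc_tab,
              regression = regression, correlations = correlations,
              rocs = rocs, seed = seed)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(outdir, "cohort.csv"))
    utils::write.csv(panel, file.path(outdir, "index_panel.csv"),
                     row.names = FALSE)
    utils::write.csv(group_comparison,
                     file.path(outdir, "group_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(cv_metrics, file.path(outdir, "cv_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(auroc_tab, file.path(outdir, "auroc.csv"),
                     row.names = FALSE)
    utils::write.csv(regression, file.path(outdir, "regression.csv"),
                     row.names = FALSE)
    utils::write.csv(correlations, file.path(outdir, "correlations.csv"),
                     row.names = FALSE)
    grDevices::pdf(file.path(outdir, "roc_comparison.pdf"), width = 6,
                   height = 5)
    print(plot_roc_comparison(rocs))
    grDevices::dev.off()
    jsonlite::write_json(
      list(seed = seed, n = nrow(cohort), n_failure = sum(y),
           indices = as.list(indices), k = k, repeats = repeats),
      file.path(outdir, "run_metadata.json"), auto_unbox = TRUE)
    message("report written to ", outdir)
  }
  invisible(out)
}
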