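#' Quality-control filter for ambulatory readings
#'
#' Applies the monitor manufacturer's exclusion rule: a reading is rejected
#' iff SBP > 220 or SBP < 80 mmHg, or DBP > 130 or DBP < 40 mmHg. The
#' inequalities are strict, so boundary readings (SBP 220 or 80, DBP 130 or
#' 40) are retained.
#'
#' @param readings data frame with numeric `sbp` and `dbp` columns.
#' @return list with `retained` and `rejected` data frames; their union is
#'   the input.
#' @export
qc_filter <- function(readings) {
  stopifnot(is.data.frame(readings), nrow(readings) > 0,
            all(c("sbp", "dbp") %in% names(readings)))
  bad <- readings$sbp > 220 | readings$sbp < 80 |
    readings$dbp > 130 | readings$dbp < 40
  bad[is.na(bad)] <- TRUE
  list(retained = readings[!bad, , drop = FALSE],
       rejected = readings[bad, , drop = FALSE])
}

#' Compliance check for an ambulatory report
#'
#' The monitor is programmed for three readings per waking hour and two per
#' sleeping hour over 19 h, so the number of potential readings is
#' `3 * awake_hours + 2 * (19 - awake_hours)`. A report is acceptable if at
#' least 80% of potential readings were obtained. The comparison is on the
#' exact fraction; no rounding in the subject's favour (43 of 54 fails).
#'
#' @param readings ambulatory-phase readings for one subject and condition
#'   (a data frame; only the row count is used), or a single count.
#' @param awake_hours number of waking hours, between 0 and 19.
#' @return list with `n_potential`, `n_obtained`, `fraction`, `acceptable`.
#' @export
compliance_check <- function(readings, awake_hours) {
  if (!is.numeric(awake_hours) || awake_hours < 0 || awake_hours > 19) {
    stop("awake_hours must be between 0 and 19")
  }
  n_obtained <- if (is.data.frame(readings)) nrow(readings) else as.integer(readings)
  n_potential <- 3L * awake_hours + 2L * (19L - awake_hours)
  fraction <- n_obtained / n_potential
  list(n_potential = n_potential, n_obtained = n_obtained,
       fraction = fraction, acceptable = fraction >= 0.80)
}

#' Hourly binning of ambulatory readings
#'
#' Averages retained readings into 19 hourly values. Hour h covers elapsed
#' minutes in the half-open window `[60(h-1), 60h)`, so a reading at exactly
#' 60 min belongs to hour 2. Hours with no retained readings are `NA`
#' (missing), never zero.
#'
#' @param readings ambulatory-phase readings for one subject and condition,
#'   with `elapsed_min`, `sbp`, `dbp`.
#' @return data frame with `hour` (1..19), `sbp`, `dbp` hourly means.
#' @export
hourly_bin <- function(readings) {
  stopifnot(is.data.frame(readings),
            all(c("elapsed_min", "sbp", "dbp") %in% names(readings)))
  hour <- floor(readings$elapsed_min / 60) + 1
  ok <- hour >= 1 & hour <= 19
  hour <- hour[ok]
  out <- data.frame(hour = 1:19, sbp = NA_real_, dbp = NA_real_)
  if (any(ok)) {
    sbp_means <- tapply(readings$sbp[ok], hour, mean)
    dbp_means <- tapply(readings$dbp[ok], hour, mean)
    h <- as.integer(names(sbp_means))
    out$sbp[h] <- as.numeric(sbp_means)
    out$dbp[h] <- as.numeric(dbp_means)
  }
  out
}

#' Baseline blood pressure for one subject and condition
#'
#' Pre-experiment BP was measured every 2 min for 20 min and averaged as the
#' baseline; this is the arithmetic mean of the baseline-phase readings.
#'
#' @param readings baseline-phase readings (data frame with `sbp`, `dbp`).
#' @return named numeric vector `c(sbp = , dbp = )`.
#' @export
baseline_mean <- function(readings) {
  stopifnot(is.data.frame(readings))
  if (nrow(readings) == 0) stop("no baseline readings; condition unusable")
  c(sbp = mean(readings$sbp), dbp = mean(readings$dbp))
}

#' Hourly blood pressure response
#'
#' The response at hour h is the change from baseline following exercise
#' minus the change from baseline following control:
#' `(E_h - E_base) - (C_h - C_base)`. Hours missing in either condition are
#' missing in the output.
#'
#' @param exercise_hourly,control_hourly outputs of [hourly_bin()].
#' @param exercise_base,control_base outputs of [baseline_mean()].
#' @return data frame with `hour`, `sbp`, `dbp` responses (mmHg) and
#'   attribute `mean_19h`, the per-phenotype mean over available hours.
#' @export
bp_response <- function(exercise_hourly, exercise_base,
                        control_hourly, control_base) {
  stopifnot(identical(exercise_hourly$hour, control_hourly$hour))
  out <- data.frame(
    hour = exercise_hourly$hour,
    sbp = (exercise_hourly$sbp - exercise_base[["sbp"]]) -
      (control_hourly$sbp - control_base[["sbp"]]),
    dbp = (exercise_hourly$dbp - exercise_base[["dbp"]]) -
      (control_hourly$dbp - control_base[["dbp"]])
  )
  if (all(is.na(out$sbp)) && all(is.na(out$dbp))) {
    stop("no common hours between exercise and control")
  }
  attr(out, "mean_19h") <- c(sbp = mean(out$sbp, na.rm = TRUE),
                             dbp = mean(out$dbp, na.rm = TRUE))
  out
}

#' Ambulatory arterial stiffness index
#'
#' AASI is one minus the ordinary least squares slope of DBP regressed on SBP
#' across the retained ambulatory readings of the monitoring period
#' (conventionally the control condition). Values outside `[0, 1]` are
#' mathematically possible and produce a plausibility warning, not an error.
#'
#' @param readings data frame of retained ambulatory readings (`sbp`, `dbp`).
#' @return numeric AASI.
#' @export
aasi <- function(readings) {
  stopifnot(is.data.frame(readings), all(c("sbp", "dbp") %in% names(readings)))
  if (nrow(readings) < 3) stop("need at least 3 readings for AASI")
  if (stats::var(readings$sbp) <= 0) stop("zero SBP variance; AASI undefined")
  slope <- stats::cov(readings$dbp, readings$sbp) / stats::var(readings$sbp)
  out <- 1 - slope
  if (out < 0 || out > 1) {
    warning("AASI ", format(out, digits = 3), " outside the plausible [0, 1] range")
  }
  out
}

#' Build hourly response series from reading-level data
#'
#' Runs the full phenotyping chain for every subject and exercise intensity:
#' QC filtering, hourly binning of the ambulatory phase, baseline averaging,
#' and exercise-minus-control differencing.
#'
#' @param readings reading-level data frame with columns `subject_id`,
#'   `condition` (CONTROL/MODERATE/VIGOROUS), `phase` (baseline/ambulatory),
#'   `elapsed_min`, `sbp`, `dbp`, `awake`.
#' @param intensities exercise conditions to difference against CONTROL.
#' @return list with `responses`, a tidy data frame (`subject_id`,
#'   `intensity`, `phenotype`, `hour`, `response`), and `mean_19h`, one row
#'   per subject/intensity/phenotype with the 19-h-averaged response.
#' @export
compute_responses <- function(readings, intensities = c("MODERATE", "VIGOROUS")) {
  stopifnot(all(c("subject_id", "condition", "phase", "elapsed_min",
                  "sbp", "dbp") %in% names(readings)))
  readings <- qc_filter(readings)$retained
  subjects <- unique(readings$subject_id)
  resp_list <- list()
  mean_list <- list()
  for (sid in subjects) {
    sub <- readings[readings$subject_id == sid, , drop = FALSE]
    ctrl_amb <- sub[sub$condition == "CONTROL" & sub$phase == "ambulatory", ]
    ctrl_base <- sub[sub$condition == "CONTROL" & sub$phase == "baseline", ]
    if (nrow(ctrl_amb) == 0 || nrow(ctrl_base) == 0) next
    c_hr <- hourly_bin(ctrl_amb)
    c_b <- baseline_mean(ctrl_base)
    for (intensity in intensities) {
      ex_amb <- sub[sub$condition == intensity & sub$phase == "ambulatory", ]
      ex_base <- sub[sub$condition == intensity & sub$phase == "baseline", ]
      if (nrow(ex_amb) == 0 || nrow(ex_base) == 0) next
      resp <- bp_response(hourly_bin(ex_amb), baseline_mean(ex_base), c_hr, c_b)
      for (phen in c("sbp", "dbp")) {
        vals <- resp[[phen]]
        resp_list[[length(resp_list) + 1L]] <- data.frame(
          subject_id = sid, intensity = intensity,
          phenotype = toupper(phen), hour = resp$hour, response = vals)
        mean_list[[length(mean_list) + 1L]] <- data.frame(
          subject_id = sid, intensity = intensity, phenotype = toupper(phen),
          mean_19h = mean(vals, na.rm = TRUE))
      }
    }
  }
  responses <- do.call(rbind, resp_list)
  responses <- responses[!is.na(responses$response), , drop = FALSE]
  rownames(responses) <- NULL
  list(responses = responses, mean_19h = do.call(rbind, mean_list))
}

#' AASI per subject from control-condition ambulatory readings
#'
#' @param readings reading-level data frame (see [compute_responses()]).
#' @param condition monitoring period to use; the control experiment by
#'   default (an orientation-session recording can be passed instead).
#' @return data frame with `subject_id` and `aasi`.
#' @export
aasi_by_subject <- function(readings, condition = "CONTROL") {
  amb <- readings[readings$condition == condition & readings$phase == "ambulatory", ]
  amb <- qc_filter(amb)$retained
  subjects <- unique(amb$subject_id)
  data.frame(
    subject_id = subjects,
    aasi = vapply(subjects, function(sid) {
      aasi(amb[amb$subject_id == sid, , drop = FALSE])
    }, numeric(1))
  )
}
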