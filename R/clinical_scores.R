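#' Sign-oriented per-patient outcome changes
#'
#' Computes, per patient and instrument, `orientation * (value_T10M -
#' value_T0)`, so a positive change always means improved health status.
#' Control-flagged instruments (e.g. resting activity, a trial control
#' parameter) are dropped. A missing timepoint gives a missing delta.
#'
#' @param outcomes Long outcome table: `patient_id`, `measure_id`,
#'   `timepoint` (`"T0"`/`"T10M"`), `value`.
#' @param measures Instrument metadata: `measure_id`, `orientation`
#'   (+1/-1), `is_control` (0/1).
#' @return Patient x measure matrix of oriented deltas (NA where a
#'   timepoint is missing).
#' @export
oriented_deltas <- function(outcomes, measures) {
  unknown <- setdiff(unique(outcomes$measure_id), measures$measure_id)
  if (length(unknown)) {
    stop("measures present in the data but absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  key <- paste(outcomes$patient_id, outcomes$measure_id, outcomes$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (patient, measure, timepoint) rows in outcome table",
         call. = FALSE)
  }
  keep_measures <- measures$measure_id[measures$is_control == 0]
  patients <- unique(outcomes$patient_id)
  delta <- matrix(NA_real_, length(patients), length(keep_measures),
                  dimnames = list(patients, keep_measures))
  t0 <- outcomes[outcomes$timepoint == "T0", ]
  t1 <- outcomes[outcomes$timepoint == "T10M", ]
  m0 <- delta; m0[cbind(t0$patient_id, t0$measure_id)[t0$measure_id %in% keep_measures, , drop = FALSE]] <-
    t0$value[t0$measure_id %in% keep_measures]
  m1 <- delta; m1[cbind(t1$patient_id, t1$measure_id)[t1$measure_id %in% keep_measures, , drop = FALSE]] <-
    t1$value[t1$measure_id %in% keep_measures]
  orient <- measures$orientation[match(keep_measures, measures$measure_id)]
  sweep(m1 - m0, 2, as.numeric(orient), `*`)
}

#' Scale a vector by its uncentered root mean square
#'
#' Divides by `sqrt(sum(x^2) / (n - 1))` over non-missing entries (the
#' uncentered behaviour of the base scaling routine), so instruments on
#' different raw scales become comparable. Missing values stay missing.
#'
#' @param x Numeric vector, NA allowed.
#' @param label Name used in error messages (typically the instrument id).
#' @return Scaled vector.
#' @export
scale_rms <- function(x, label = "column") {
  ok <- !is.na(x)
  if (sum(ok) < 2) {
    stop("fewer than 2 non-missing values in ", label, call. = FALSE)
  }
  rms <- sqrt(sum(x[ok]^2) / (sum(ok) - 1))
  if (rms == 0) stop("all-zero values in ", label, call. = FALSE)
  x / rms
}

#' Per-patient compound response scores
#'
#' The compound response is the mean over instruments of the RMS-scaled,
#' sign-oriented outcome changes; it summarises a patient's overall therapy
#' response on a common scale where positive means improvement.
#'
#' @param deltas Patient x measure matrix of oriented deltas (from
#'   [oriented_deltas()]).
#' @return A data frame of class `response_scores`: `patient_id`,
#'   `compound_response`, `n_measures_used`; the scaled delta matrix is kept
#'   in attribute `"scaled"` for audit.
#' @export
compound_response <- function(deltas) {
  scaled <- deltas
  for (m in colnames(deltas)) scaled[, m] <- scale_rms(deltas[, m], label = m)
  n_used <- rowSums(!is.na(scaled))
  if (any(n_used == 0)) {
    stop("patients with zero usable measures: ",
         paste(rownames(scaled)[n_used == 0], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    patient_id = rownames(scaled),
    compound_response = rowMeans(scaled, na.rm = TRUE),
    n_measures_used = as.integer(n_used),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "scaled") <- scaled
  class(out) <- c("response_scores", class(out))
  out
}
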