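#' Cohort-level lactate and glucose thresholds
#'
#' Quantiles of the pooled measurement-level distributions across all
#' patients' ICU stays (linear-interpolation quantile definition): the
#' lactate median and the glucose 25th/50th/75th percentiles, which anchor
#' the five metabolic profiles.
#'
#' @param lactate all lactate measurements (mmol/L), pooled.
#' @param glucose all glucose measurements (mmol/L), pooled.
#' @return list of class `metabolic_thresholds`: `lactate_median`,
#'   `glucose_q25`, `glucose_q50`, `glucose_q75`.
#' @export
compute_metabolic_thresholds <- function(lactate, glucose) {
  lactate <- lactate[is.finite(lactate)]
  glucose <- glucose[is.finite(glucose)]
  if (length(glucose) < 4 || length(lactate) < 2)
    stop("compute_metabolic_thresholds: insufficient measurements")
  q <- stats::quantile(glucose, c(0.25, 0.50, 0.75), names = FALSE, type = 7)
  structure(list(lactate_median = stats::median(lactate),
                 glucose_q25 = q[1], glucose_q50 = q[2], glucose_q75 = q[3]),
            class = "metabolic_thresholds")
}

#' Names of the five metabolic profiles, in tie-breaking order
#' @export
metabolic_profiles <- function() {
  c("baseline", "impaired_metabolism", "isolated_hyperglycaemia",
    "isolated_hypoglycaemia", "stress_response")
}

#' Classify one paired lactate/glucose measurement into a metabolic profile
#'
#' Five-state rule against cohort thresholds, with "above" meaning >= and
#' the baseline profile closing the glucose gap at \[q25, q75):
#' \itemize{
#'   \item stress_response: lactate >= median and glucose >= q75
#'   \item impaired_metabolism: lactate >= median and glucose < q75
#'   \item isolated_hyperglycaemia: lactate < median and glucose >= q75
#'   \item isolated_hypoglycaemia: lactate < median and glucose < q25
#'   \item baseline: lactate < median and glucose in \[q25, q75)
#' }
#'
#' @param lactate,glucose finite measurement values (vectorized).
#' @param thr a `metabolic_thresholds`.
#' @return character vector of profile names.
#' @export
classify_metabolic_state <- function(lactate, glucose, thr) {
  stopifnot(inherits(thr, "metabolic_thresholds"),
            length(lactate) == length(glucose))
  high_lac <- lactate >= thr$lactate_median
  ifelse(high_lac & glucose >= thr$glucose_q75, "stress_response",
  ifelse(high_lac, "impaired_metabolism",
  ifelse(glucose >= thr$glucose_q75, "isolated_hyperglycaemia",
  ifelse(glucose < thr$glucose_q25, "isolated_hypoglycaemia", "baseline"))))
}

#' Relative time per metabolic profile over an ICU stay
#'
#' Step-function occupancy: each measurement's profile holds from its
#' timestamp until the next measurement; the last profile holds until ICU
#' discharge and the interval before the first measurement is assigned to
#' the first profile. Relative times are occupancies divided by the ICU
#' length of stay; the dominant profile is the one with the largest
#' relative time (ties broken by the order of [metabolic_profiles()]).
#'
#' @param time measurement times (days), strictly increasing.
#' @param lactate,glucose paired measurements at those times.
#' @param thr a `metabolic_thresholds`.
#' @param icu_admission,icu_discharge ICU interval (days).
#' @return list of class `metabolic_summary`: `relative_time` (named,
#'   sums to 1), `dominant`.
#' @export
metabolic_summary <- function(time, lactate, glucose, thr,
                              icu_admission, icu_discharge) {
  stopifnot(length(time) >= 1, icu_discharge > icu_admission)
  inside <- time >= icu_admission & time <= icu_discharge
  time <- time[inside]; lactate <- lactate[inside]; glucose <- glucose[inside]
  if (length(time) == 0)
    stop("metabolic_summary: no measurement inside the ICU interval")
  if (any(diff(time) <= 0))
    stop("metabolic_summary: times must be strictly increasing")
  prof <- classify_metabolic_state(lactate, glucose, thr)
  bounds <- c(icu_admission, time[-1], icu_discharge)
  # interval i: profile prof[i] holds over [bounds[i], bounds[i+1])
  dur <- diff(bounds)
  levels <- metabolic_profiles()
  occ <- vapply(levels, function(p) sum(dur[prof == p]), numeric(1))
  rel <- occ / (icu_discharge - icu_admission)
  dominant <- levels[which.max(rel)]
  structure(list(relative_time = rel, dominant = dominant),
            class = "metabolic_summary")
}
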