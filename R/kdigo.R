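#' Creatinine trajectory constructor
#'
#' @param id patient identifier.
#' @param time measurement times in decimal days from hospital admission
#'   (strictly increasing).
#' @param creatinine serum creatinine in umol/L (> 0).
#' @param rrt logical: renal replacement therapy given.
#' @param rrt_start,rrt_end RRT interval in days (NA if none; `rrt_end`
#'   NA while ongoing).
#' @param icu_admission,icu_discharge ICU interval in days.
#' @return list of class `creatinine_trajectory`; baseline creatinine is
#'   the first value recorded after hospital admission.
#' @export
creatinine_trajectory <- function(id, time, creatinine, rrt = FALSE,
                                  rrt_start = NA_real_, rrt_end = NA_real_,
                                  icu_admission = NA_real_,
                                  icu_discharge = NA_real_) {
  stopifnot(length(time) == length(creatinine), length(time) >= 1)
  if (any(diff(time) <= 0)) stop("creatinine_trajectory: times must be strictly increasing")
  if (any(creatinine <= 0)) stop("creatinine_trajectory: creatinine must be > 0")
  structure(list(id = id, time = time, creatinine = creatinine,
                 baseline = creatinine[1], rrt = isTRUE(rrt),
                 rrt_start = rrt_start, rrt_end = rrt_end,
                 icu_admission = icu_admission,
                 icu_discharge = icu_discharge),
            class = "creatinine_trajectory")
}

#' Detect AKI from a creatinine trajectory (KDIGO creatinine criteria)
#'
#' AKI is flagged at the first measurement time t where creatinine is at
#' least 1.5-fold the minimum value over the preceding 7 days, or exceeds
#' that minimum over the preceding 48 h by more than 26.4 umol/L. Reference
#' windows are half-open (t - w, t\] rolling minima over recorded values,
#' the KDIGO-consistent reading of a moving reference. Both reference
#' series are returned for audit.
#'
#' @param traj a `creatinine_trajectory`.
#' @return list: `aki` (logical), `onset` (time, NA if no AKI),
#'   `criterion` ("ratio", "absolute" or NA), `ref7`, `ref48` (rolling
#'   reference minima per measurement).
#' @export
detect_aki <- function(traj) {
  stopifnot(inherits(traj, "creatinine_trajectory"))
  tt <- traj$time
  cc <- traj$creatinine
  n <- length(tt)
  ref7 <- ref48 <- numeric(n)
  for (i in seq_len(n)) {
    w7 <- cc[tt > tt[i] - 7 & tt <= tt[i]]
    w48 <- cc[tt > tt[i] - 2 & tt <= tt[i]]
    ref7[i] <- min(w7)
    ref48[i] <- min(w48)
  }
  ratio_hit <- cc >= 1.5 * ref7
  abs_hit <- cc >= ref48 + 26.4
  hit <- which(ratio_hit | abs_hit)
  if (length(hit) == 0)
    return(list(aki = FALSE, onset = NA_real_, criterion = NA_character_,
                ref7 = ref7, ref48 = ref48))
  first <- hit[1]
  list(aki = TRUE, onset = tt[first],
       criterion = if (ratio_hit[first]) "ratio" else "absolute",
       ref7 = ref7, ref48 = ref48)
}

#' KDIGO severity staging of an AKI episode
#'
#' Maximum stage over the stay from the ratio of peak creatinine to
#' baseline (the first value after hospital admission): stage 1 for a
#' ratio in \[1.5, 2) or when only the absolute 26.4 umol/L criterion
#' fired; stage 2 for \[2, 3); stage 3 for a ratio >= 3 or a peak of at
#' least 353.6 umol/L. Stage 3 is split by the need for renal replacement
#' therapy, which dominates all creatinine criteria ("3-RRT").
#'
#' @param traj a `creatinine_trajectory`.
#' @param detection optional result of [detect_aki()] (recomputed if NULL).
#' @return list of class `kdigo_result`: `aki`, `onset`, `stage` (one of
#'   "0", "1", "2", "3-noRRT", "3-RRT"), `peak_ratio`.
#' @export
stage_kdigo <- function(traj, detection = NULL) {
  stopifnot(inherits(traj, "creatinine_trajectory"))
  if (is.null(detection)) detection <- detect_aki(traj)
  peak <- max(traj$creatinine)
  ratio <- peak / traj$baseline
  if (traj$rrt && !detection$aki) {
    warning("stage_kdigo: RRT given without creatinine-detected AKI; staging 3-RRT")
    return(structure(list(aki = TRUE, onset = traj$rrt_start,
                          stage = "3-RRT", peak_ratio = ratio),
                     class = "kdigo_result"))
  }
  if (!detection$aki)
    return(structure(list(aki = FALSE, onset = NA_real_, stage = "0",
                          peak_ratio = ratio), class = "kdigo_result"))
  stage <- if (traj$rrt) "3-RRT"
  else if (ratio >= 3 || peak >= 353.6) "3-noRRT"
  else if (ratio >= 2) "2"
  else "1"
  structure(list(aki = TRUE, onset = detection$onset, stage = stage,
                 peak_ratio = ratio), class = "kdigo_result")
}

#' Renal recovery after an AKI episode
#'
#' Recovery is reached at the first post-onset measurement with serum
#' creatinine below 1.5 times the baseline and no ongoing renal
#' replacement therapy; otherwise the patient is censored at the last
#' measurement.
#'
#' @param traj a `creatinine_trajectory`.
#' @param kdigo a `kdigo_result` with `aki = TRUE`.
#' @return list: `recovered` (logical), `time` (recovery or censoring
#'   time, measured from AKI onset), `abs_time` (clock time of the event).
#' @export
assess_recovery <- function(traj, kdigo) {
  stopifnot(inherits(kdigo, "kdigo_result"))
  if (!kdigo$aki) stop("assess_recovery: no AKI episode")
  tt <- traj$time
  cc <- traj$creatinine
  post <- which(tt > kdigo$onset)
  rrt_ongoing <- function(t) {
    traj$rrt && !is.na(traj$rrt_start) && t >= traj$rrt_start &&
      (is.na(traj$rrt_end) || t < traj$rrt_end)
  }
  for (i in post) {
    if (cc[i] < 1.5 * traj$baseline && !rrt_ongoing(tt[i]))
      return(list(recovered = TRUE, time = tt[i] - kdigo$onset,
                  abs_time = tt[i]))
  }
  list(recovered = FALSE, time = max(tt) - kdigo$onset, abs_time = max(tt))
}
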