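#' Configuration of the synthetic ICU cohort generator
#'
#' Defines a cohort with the statistical structure the pipeline assumes:
#' covariates with realistic marginals, an additive nonlinear AKI risk
#' mechanism over seven factors, planted phenotype groups each dominated by
#' a distinct risk factor, KDIGO-consistent creatinine trajectories,
#' group-specific lactate/glucose regimes and group-specific recovery and
#' mortality hazards. The defaults emulate a severe-COVID-19 ICU cohort:
#' ~40% AKI incidence, AKI onset 1-6 days after ICU admission, three
#' phenotype groups dominated respectively by a nephrotoxic drug exposure
#' (`lpv_r`), low baseline kidney function without the protective drug
#' (`egfr` / `dexamethasone`), and high illness severity (`apache`).
#'
#' @param n_patients cohort size.
#' @param n_groups number of planted phenotype groups (default 3).
#' @param covariates data.frame: name, kind ("binary"/"continuous"),
#'   p (binary prevalence), mean, sd, lower, upper (continuous, truncated
#'   normal).
#' @param risk_coefficients data.frame: name, beta (logit scale per sd),
#'   shape ("linear", "u_shape", "saturating").
#' @param group_pattern n_groups x covariates matrix of distribution
#'   shifts: log-odds shifts for binary covariates, mean shifts in sd
#'   units for continuous ones.
#' @param group_probs prior membership probabilities of the phenotype
#'   groups (default: sized so the AKI-restricted groups come out roughly
#'   balanced under the default risk pattern).
#' @param target_aki_rate marginal AKI proportion the intercept is
#'   calibrated to (default 0.4).
#' @param stage_probs n_groups x 4 matrix of KDIGO stage probabilities
#'   (stage 1, 2, 3-noRRT, 3-RRT) given AKI.
#' @param recovery_hazard_ratio per-group multiplier on the base renal
#'   recovery hazard (base rate 0.10/day).
#' @param mortality_rate per-group hospital mortality among AKI patients.
#' @param mortality_rate_no_aki mortality among non-AKI patients.
#' @param missingness_rate covariate missingness injected by the pipeline
#'   (0 = complete).
#' @param metabolic_interval hours between paired lactate/glucose
#'   measurements (default 4 h).
#' @param seed integer seed; fully determines the cohort.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 248,
                             n_groups = 3,
                             covariates = default_covariates(),
                             risk_coefficients = default_risk_coefficients(),
                             group_pattern = default_group_pattern(),
                             group_probs = NULL,
                             target_aki_rate = 0.4,
                             stage_probs = default_stage_probs(),
                             recovery_hazard_ratio = c(1.0, 1.0, 1.6),
                             mortality_rate = c(0.20, 0.25, 0.55),
                             mortality_rate_no_aki = 0.25,
                             missingness_rate = 0,
                             metabolic_interval = 4,
                             seed = 1L) {
  if (is.null(group_probs))
    group_probs <- if (n_groups == 3) c(0.40, 0.33, 0.27)
                   else rep(1 / n_groups, n_groups)
  stopifnot(n_patients >= 1, n_groups >= 1,
            target_aki_rate > 0, target_aki_rate < 1,
            missingness_rate >= 0, missingness_rate < 1,
            all(recovery_hazard_ratio > 0),
            all(mortality_rate >= 0), all(mortality_rate <= 1),
            nrow(group_pattern) == n_groups,
            length(group_probs) == n_groups,
            abs(sum(group_probs) - 1) < 1e-9,
            nrow(stage_probs) == n_groups,
            length(recovery_hazard_ratio) == n_groups,
            length(mortality_rate) == n_groups,
            all(abs(rowSums(stage_probs) - 1) < 1e-9))
  structure(list(n_patients = n_patients, n_groups = n_groups,
                 covariates = covariates,
                 risk_coefficients = risk_coefficients,
                 group_pattern = group_pattern,
                 group_probs = group_probs,
                 target_aki_rate = target_aki_rate,
                 stage_probs = stage_probs,
                 recovery_hazard_ratio = recovery_hazard_ratio,
                 mortality_rate = mortality_rate,
                 mortality_rate_no_aki = mortality_rate_no_aki,
                 missingness_rate = missingness_rate,
                 metabolic_interval = metabolic_interval,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_covariates <- function() {
  data.frame(
    name = c("lpv_r", "diabetes", "dexamethasone", "mech_vent",
             "egfr", "apache", "fio2"),
    kind = c("binary", "binary", "binary", "binary",
             "continuous", "continuous", "continuous"),
    p = c(0.15, 0.32, 0.47, 0.85, NA, NA, NA),
    mean = c(NA, NA, NA, NA, 60, 22, 60),
    sd = c(NA, NA, NA, NA, 25, 8, 18),
    lower = c(NA, NA, NA, NA, 5, 2, 21),
    upper = c(NA, NA, NA, NA, 150, 55, 100))
}

#' @rdname generator_config
#' @export
default_risk_coefficients <- function() {
  data.frame(
    name = c("lpv_r", "diabetes", "dexamethasone", "mech_vent",
             "egfr", "apache", "fio2"),
    beta = c(2.8, 0, -1.2, 0, -1.6, 1.4, 0.4),
    shape = c("linear", "linear", "linear", "linear",
              "saturating", "saturating", "linear"))
}

#' @rdname generator_config
#' @export
default_group_pattern <- function() {
  m <- rbind(
    c(lpv_r = 3.1, diabetes = 0, dexamethasone = 3.6, mech_vent = 0,
      egfr = 1.2, apache = -1.2, fio2 = 0),
    c(lpv_r = -2.0, diabetes = 0, dexamethasone = -3.5, mech_vent = 0,
      egfr = -2.5, apache = -2.5, fio2 = 0),
    c(lpv_r = -2.0, diabetes = 0, dexamethasone = 3.6, mech_vent = 0,
      egfr = -1.8, apache = 2.5, fio2 = 0))
  rownames(m) <- paste0("group", 1:3)
  m
}

#' @rdname generator_config
#' @export
default_stage_probs <- function() {
  rbind(c(0.52, 0.18, 0.08, 0.22),
        c(0.55, 0.17, 0.08, 0.20),
        c(0.78, 0.16, 0.03, 0.03))
}

# Nonlinear effect shapes on the standardized covariate z:
# linear beta*z; u_shape beta*(z^2 - 1) (centered quadratic); saturating
# beta*(2*plogis(3 z) - 1) (bounded logistic ramp through 0, plateaued
# beyond |z| ~ 1.5 so that shifted phenotype groups sit on flat regions).
risk_shape <- function(z, beta, shape) {
  switch(shape,
         linear = beta * z,
         u_shape = beta * (z^2 - 1),
         saturating = beta * (2 * stats::plogis(3 * z) - 1),
         stop("unknown risk shape: ", shape))
}

#' Generate a synthetic ICU cohort with ground truth
#'
#' Draws covariates per marginal spec with planted group shifts, assigns
#' AKI from the additive nonlinear logistic risk (intercept calibrated by
#' bisection so the mean simulated probability matches the target rate to
#' 1e-4), builds creatinine trajectories whose KDIGO scoring reproduces
#' the planted AKI status and stage, draws paired lactate/glucose series
#' from group-specific regimes, and draws recovery times from exponential
#' hazards with the configured group ratios and deaths with the configured
#' group rates. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_cohort`: `patients` (covariates +
#'   `aki` label), `trajectories` (list of `creatinine_trajectory`),
#'   `metabolic` (data.frame id/time/lactate/glucose), `icu` (data.frame
#'   id/admission/discharge), `ground_truth` (data.frame), `intercept`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  rng <- local_rng(config$seed)
  on.exit(restore_rng(rng))
  n <- config$n_patients
  cov <- config$covariates
  rc <- config$risk_coefficients
  gp <- config$group_pattern

  group <- sample.int(config$n_groups, n, replace = TRUE,
                      prob = config$group_probs)

  ## ---- covariates with group shifts ----
  X <- data.frame(row.names = seq_len(n))
  Z <- data.frame(row.names = seq_len(n))   # standardized versions
  for (i in seq_len(nrow(cov))) {
    nm <- cov$name[i]
    shift <- if (nm %in% colnames(gp)) gp[group, nm] else rep(0, n)
    if (cov$kind[i] == "binary") {
      p <- stats::plogis(stats::qlogis(cov$p[i]) + shift)
      x <- as.integer(stats::runif(n) < p)
      X[[nm]] <- x
      Z[[nm]] <- x - cov$p[i]               # centered at the base prevalence
    } else {
      x <- stats::rnorm(n, cov$mean[i] + shift * cov$sd[i], cov$sd[i])
      x <- pmin(pmax(x, cov$lower[i]), cov$upper[i])
      X[[nm]] <- x
      Z[[nm]] <- (x - cov$mean[i]) / cov$sd[i]
    }
  }

  ## ---- additive nonlinear risk and calibrated intercept ----
  risk <- rep(0, n)
  for (i in seq_len(nrow(rc))) {
    nm <- rc$name[i]
    risk <- risk + risk_shape(Z[[nm]], rc$beta[i], rc$shape[i])
  }
  intercept <- calibrate_intercept(risk, config$target_aki_rate)
  logit <- intercept + risk
  p_aki <- stats::plogis(logit)
  aki <- stats::runif(n) < p_aki

  ## ---- KDIGO stage given AKI (group-specific severity) ----
  stage_lab <- c("1", "2", "3-noRRT", "3-RRT")
  stage <- rep("0", n)
  for (i in which(aki)) {
    stage[i] <- sample(stage_lab, 1, prob = config$stage_probs[group[i], ])
  }

  ## ---- timing, outcomes ----
  icu_adm <- round(stats::runif(n, 0, 1.5) * 2) / 2
  icu_los <- pmax(3, stats::rlnorm(n, log(12), 0.4))
  icu_los <- pmin(icu_los, 28)
  onset_icu <- stats::runif(n, 1, 6)               # days after ICU admission
  onset <- round((icu_adm + onset_icu) * 2) / 2    # snapped to sampling grid
  base_rec_rate <- 0.10
  rec_time <- stats::rexp(n, base_rec_rate * config$recovery_hazard_ratio[group])
  death <- ifelse(aki,
                  stats::runif(n) < config$mortality_rate[group],
                  stats::runif(n) < config$mortality_rate_no_aki)
  hosp_end <- icu_adm + icu_los + pmax(2, stats::rlnorm(n, log(8), 0.5))
  death_time <- ifelse(death,
                       pmin(icu_adm + 2 + stats::rexp(n, 1 / 12), hosp_end),
                       hosp_end)
  follow_up <- pmin(ifelse(death, death_time, hosp_end), 35)

  ## ---- creatinine trajectories ----
  # peak-to-baseline ratios drawn inside each stage band, kept clear of the
  # 1.5/2/3 boundaries and (stages 1-2) of the 353.6 umol/L absolute
  # threshold so that staging round-trips exactly
  draw_ratio <- function(stage_i, baseline_i) {
    switch(stage_i,
           "1" = stats::runif(1, 1.55, min(1.95, 350 / baseline_i)),
           "2" = stats::runif(1, 2.05, min(2.90, 350 / baseline_i)),
           stats::runif(1, 3.10, 4.50))
  }
  # capped so a stage-2 peak (2.2x) stays below the 353.6 umol/L absolute
  # stage-3 threshold and staging round-trips exactly
  baseline <- pmin(pmax(stats::rlnorm(n, log(80), 0.25), 45), 150)
  trajectories <- vector("list", n)
  for (i in seq_len(n)) {
    tt <- seq(0, max(follow_up[i], 3), by = 0.5)
    noise <- stats::runif(length(tt), 0.97, 1.03)
    cc <- baseline[i] * noise
    cc[1] <- baseline[i]
    rrt <- FALSE; rrt_start <- NA_real_; rrt_end <- NA_real_
    if (aki[i]) {
      ratio <- draw_ratio(stage[i], baseline[i])
      peak_t <- min(onset[i], max(tt))
      rise_t <- max(peak_t - 1, 0.5)
      peak <- ratio * baseline[i]
      recovered_at <- peak_t + rec_time[i]
      for (k in seq_along(tt)) {
        t <- tt[k]
        if (t >= rise_t && t <= peak_t) {
          frac <- if (peak_t > rise_t) (t - rise_t) / (peak_t - rise_t) else 1
          cc[k] <- baseline[i] + frac * (peak - baseline[i])
        } else if (t > peak_t) {
          if (t < recovered_at) {
            # plateau with slow drift toward 1.6x baseline, never below it
            drift <- (t - peak_t) / 20
            cc[k] <- max(peak - drift * (peak - 1.6 * baseline[i]),
                         1.6 * baseline[i])
          } else {
            # recovered: settle just under the recovery threshold, then to
            # baseline
            settle <- (t - recovered_at) / 10
            cc[k] <- max(1.45 * baseline[i] - settle * 0.4 * baseline[i],
                         1.05 * baseline[i])
          }
        }
      }
      if (stage[i] == "3-RRT") {
        rrt <- TRUE
        rrt_start <- peak_t
        rrt_end <- if (recovered_at <= max(tt)) recovered_at - 0.25
                   else NA_real_
      }
    }
    trajectories[[i]] <- creatinine_trajectory(
      id = i, time = tt, creatinine = cc, rrt = rrt,
      rrt_start = rrt_start, rrt_end = rrt_end,
      icu_admission = icu_adm[i],
      icu_discharge = min(icu_adm[i] + icu_los[i], follow_up[i]))
  }

  ## ---- metabolic series (group-specific regimes) ----
  lac_meanlog <- log(c(1.1, 1.2, 2.0))[group]
  glu_meanlog <- log(c(8.0, 8.3, 7.6))[group]
  met <- do.call(rbind, lapply(seq_len(n), function(i) {
    adm <- icu_adm[i]
    dis <- min(adm + icu_los[i], follow_up[i])
    tt <- seq(adm, dis, by = config$metabolic_interval / 24)
    data.frame(id = i, time = tt,
               lactate = stats::rlnorm(length(tt), lac_meanlog[i], 0.30),
               glucose = stats::rlnorm(length(tt), glu_meanlog[i], 0.18))
  }))

  patients <- data.frame(patient_id = seq_len(n), X,
                         aki = as.integer(aki))
  ground_truth <- data.frame(
    patient_id = seq_len(n), group = group, true_logit = logit,
    true_p = p_aki, true_aki = as.integer(aki), true_stage = stage,
    recovery_time = rec_time, death = as.integer(death),
    death_time = death_time, follow_up = follow_up,
    baseline_creatinine = baseline)
  if (config$missingness_rate > 0) {
    patients <- inject_missingness(
      patients, config$missingness_rate, mechanism = "MCAR",
      protect = c("patient_id", "aki"),
      seed = child_seed(config$seed, 99))
  }
  structure(list(patients = patients, trajectories = trajectories,
                 metabolic = met,
                 icu = data.frame(id = seq_len(n), admission = icu_adm,
                                  discharge = pmin(icu_adm + icu_los,
                                                   follow_up)),
                 ground_truth = ground_truth, intercept = intercept,
                 config = config),
            class = "synthetic_cohort")
}

# Bisection on the intercept so that mean(plogis(intercept + risk)) hits the
# target marginal AKI rate to 1e-4.
calibrate_intercept <- function(risk, target, tol = 1e-4) {
  lo <- -20; hi <- 20
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    m <- mean(stats::plogis(mid + risk))
    if (abs(m - target) < tol) return(mid)
    if (m < target) lo <- mid else hi <- mid
  }
  mid
}

#' Write a synthetic cohort as delimited text tables
#'
#' Emits `patients.csv` (covariates + AKI label), `creatinine.csv`
#' (id/time/creatinine/rrt columns), `metabolic.csv`
#' (id/time/lactate/glucose), `icu.csv` and `ground_truth.csv` in `dir`.
#' Timestamps are decimal days from hospital admission.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  creat <- do.call(rbind, lapply(cohort$trajectories, function(tr) {
    data.frame(id = tr$id, time = tr$time, creatinine = tr$creatinine,
               rrt = as.integer(tr$rrt), rrt_start = tr$rrt_start,
               rrt_end = tr$rrt_end, icu_admission = tr$icu_admission,
               icu_discharge = tr$icu_discharge)
  }))
  utils::write.csv(creat, file.path(dir, "creatinine.csv"), row.names = FALSE)
  utils::write.csv(cohort$metabolic, file.path(dir, "metabolic.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$icu, file.path(dir, "icu.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates timestamps (strictly increasing per patient) and positivity of
#' creatinine, naming the offending patient on failure.
#'
#' @param dir directory holding the cohort tables.
#' @return a `synthetic_cohort`-shaped list (without `ground_truth` if the
#'   file is absent).
#' @export
read_cohort <- function(dir) {
  patients <- utils::read.csv(file.path(dir, "patients.csv"))
  creat <- utils::read.csv(file.path(dir, "creatinine.csv"))
  met <- utils::read.csv(file.path(dir, "metabolic.csv"))
  icu <- utils::read.csv(file.path(dir, "icu.csv"))
  if (any(creat$creatinine <= 0)) {
    bad <- creat$id[creat$creatinine <= 0][1]
    stop("read_cohort: non-positive creatinine for patient ", bad)
  }
  trajectories <- lapply(split(creat, creat$id), function(d) {
    d <- d[order(d$time), ]
    if (any(diff(d$time) <= 0))
      stop("read_cohort: non-monotone timestamps for patient ", d$id[1])
    creatinine_trajectory(
      id = d$id[1], time = d$time, creatinine = d$creatinine,
      rrt = d$rrt[1] == 1, rrt_start = d$rrt_start[1],
      rrt_end = d$rrt_end[1], icu_admission = d$icu_admission[1],
      icu_discharge = d$icu_discharge[1])
  })
  trajectories <- trajectories[order(as.integer(names(trajectories)))]
  gt_path <- file.path(dir, "ground_truth.csv")
  out <- list(patients = patients, trajectories = unname(trajectories),
              metabolic = met, icu = icu,
              ground_truth = if (file.exists(gt_path))
                utils::read.csv(gt_path) else NULL)
  class(out) <- "synthetic_cohort"
  out
}
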