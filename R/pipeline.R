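#' Pipeline configuration
#'
#' Declarative configuration of the full three-step analysis. Every
#' stochastic stage has an explicit seed derived from the master seed.
#'
#' @param screen_alpha univariable screening threshold (default 0.2).
#' @param select_alpha backward-selection retention threshold (default 0.05).
#' @param forced covariates never dropped by selection (default "apache",
#'   the severity adjustment).
#' @param shap_approach value function for the Shapley stage.
#' @param shap_sigma kernel bandwidth for the empirical-conditional value
#'   function.
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1).
#' @param eps,min_pts DBSCAN parameters (defaults 1 and 5).
#' @param run_svm run the SVM separability validation stage.
#' @param n_boot bootstrap resamples for evaluation, SVM validation and
#'   posterior inference.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(screen_alpha = 0.2, select_alpha = 0.05,
                            forced = "apache",
                            shap_approach = "marginal",
                            shap_sigma = 0.1,
                            n_neighbors = 15, min_dist = 0.1,
                            eps = 1, min_pts = 5,
                            run_svm = FALSE, n_boot = 2000, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the three-step AKI sub-phenotyping pipeline
#'
#' Executes, on a cohort (typically from [generate_cohort()] or
#' [read_cohort()]): preprocessing (Yeo-Johnson normalization of continuous
#' covariates, bagged-tree imputation if cells are missing, collinearity
#' pruning at |r| > 0.8); univariable spline screening and the
#' multivariable additive logistic model with supervised backward selection
#' (severity forced); model evaluation (AUC, Hosmer-Lemeshow); exact
#' Shapley attribution of the selected factors restricted to AKI patients;
#' UMAP embedding and DBSCAN clustering of the attribution matrix with
#' per-cluster risk-factor profiles (optionally SVM separability
#' validation); and outcome comparison across clusters (KDIGO stage,
#' renal recovery, dominant metabolic pattern, mortality) via Naive-Bayes
#' posteriors and Cox models.
#'
#' @param cohort a `synthetic_cohort` (or the same shape from
#'   [read_cohort()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every intermediate table
#'   and a manifest are written as delimited text.
#' @return list of class `aki_pipeline_result` with elements `screen`,
#'   `model`, `selected`, `evaluation`, `shap`, `embedding`, `labels`,
#'   `profiles`, `svm` (NULL unless requested), `outcomes`, `config`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  patients <- cohort$patients
  covars <- setdiff(names(patients), c("patient_id", "aki"))
  y <- patients$aki

  ## ---- step 1: preprocessing ----
  dat <- patients[covars]
  norm <- fit_normalization(dat)
  dat <- apply_normalization(norm, dat)
  if (anyNA(dat))
    dat <- bagged_impute(dat, seed = child_seed(config$seed, 1))
  prune <- prune_collinear(dat, threshold = 0.8)
  dat <- dat[prune$kept]

  ## ---- step 1: risk model ----
  screen <- univariable_screen(dat, y, alpha = config$screen_alpha)
  kept <- screen$variable[screen$keep]
  if (length(kept) == 0) stop("run_pipeline: no variable passed screening")
  is_bin <- vapply(kept, function(v) length(unique(dat[[v]])) <= 2, logical(1))
  forced <- intersect(config$forced, kept)
  if (length(setdiff(config$forced, kept))) {
    # a forced severity covariate enters the multivariable model even if it
    # misses the screen
    extra <- setdiff(config$forced, kept)
    kept <- c(kept, extra)
    is_bin <- c(is_bin, vapply(extra, function(v)
      length(unique(dat[[v]])) <= 2, logical(1)))
    forced <- config$forced
  }
  sel <- stepwise_select(dat, y,
                         smooth_vars = kept[!is_bin],
                         linear_vars = kept[is_bin],
                         forced = forced, alpha = config$select_alpha)
  model <- sel$model
  prob <- predict(model, dat, type = "response")
  evaluation <- evaluate_model(prob, y, n_boot = config$n_boot,
                               seed = child_seed(config$seed, 2))

  ## ---- step 2: attribution, embedding, clustering ----
  sc <- shap_config(background = dat[, sel$selected, drop = FALSE],
                    approach = config$shap_approach,
                    sigma = config$shap_sigma)
  sm <- shap_matrix(model, dat, sc, restrict = y == 1)
  emb <- umap_embed(sm$phi, n_neighbors = config$n_neighbors,
                    min_dist = config$min_dist,
                    seed = child_seed(config$seed, 3))
  labels <- dbscan_cluster(emb, eps = config$eps, min_pts = config$min_pts)
  profiles <- if (max(labels) >= 1) cluster_profiles(sm, labels) else NULL
  svm <- NULL
  if (config$run_svm && length(unique(labels[labels != 0])) >= 2) {
    svm <- svm_validate(emb, labels, n_boot = config$n_boot,
                        seed = child_seed(config$seed, 4))
  }

  ## ---- step 3: outcomes ----
  outcomes <- NULL
  if (!is.null(cohort$trajectories) && max(labels) >= 2) {
    aki_rows <- sm$row_ids                      # indices into patients
    scored <- lapply(cohort$trajectories[aki_rows], function(tr) {
      kd <- stage_kdigo(tr)
      rec <- if (kd$aki) assess_recovery(tr, kd) else
        list(recovered = FALSE, time = NA_real_)
      list(kdigo = kd, recovery = rec,
           ratio = max(tr$creatinine) / tr$baseline)
    })
    stage <- vapply(scored, function(s) s$kdigo$stage, character(1))
    recovered <- vapply(scored, function(s) s$recovery$recovered, logical(1))
    rec_time <- vapply(scored, function(s)
      max(s$recovery$time, 0.25), numeric(1))
    ratio <- vapply(scored, function(s) s$ratio, numeric(1))
    thr <- compute_metabolic_thresholds(cohort$metabolic$lactate,
                                        cohort$metabolic$glucose)
    dominant <- vapply(aki_rows, function(i) {
      m <- cohort$metabolic[cohort$metabolic$id == i, ]
      icu <- cohort$icu[cohort$icu$id == i, ]
      metabolic_summary(m$time, m$lactate, m$glucose, thr,
                        icu$admission, icu$discharge)$dominant
    }, character(1))
    gt_death <- if (!is.null(cohort$ground_truth))
      cohort$ground_truth$death[aki_rows] else rep(NA_integer_, length(aki_rows))
    death_time <- if (!is.null(cohort$ground_truth))
      cohort$ground_truth$death_time[aki_rows] else rep(NA_real_, length(aki_rows))
    post_seed <- child_seed(config$seed, 5)
    outcomes <- list(
      kdigo_stage = stage, recovered = recovered, ratio = ratio,
      dominant_pattern = dominant, thresholds = thr,
      posterior_stage = posterior_by_cluster(labels, stage,
                                             n_boot = config$n_boot,
                                             seed = post_seed),
      posterior_pattern = posterior_by_cluster(labels, dominant,
                                               n_boot = config$n_boot,
                                               seed = post_seed + 1L),
      posterior_death = if (!anyNA(gt_death))
        posterior_by_cluster(labels, gt_death, n_boot = config$n_boot,
                             seed = post_seed + 2L) else NULL,
      cox_recovery = cox_compare(rec_time, recovered, labels),
      cox_mortality = if (!anyNA(gt_death))
        cox_compare(death_time, gt_death, labels) else NULL,
      severity_mortality = if (!anyNA(gt_death))
        suppressWarnings(severity_mortality_curve(labels, pmax(ratio, 1),
                                                  gt_death)) else NULL)
  }

  result <- structure(list(screen = screen, prune = prune, model = model,
                           selected = sel$selected, trace = sel$trace,
                           evaluation = evaluation, shap = sm,
                           embedding = emb, labels = labels,
                           profiles = profiles, svm = svm,
                           outcomes = outcomes, normalization = norm,
                           data = dat, config = config),
                      class = "aki_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

# Persist the main pipeline artifacts as delimited text plus a manifest.
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  w(result$screen, "screen.csv")
  write_shap_matrix(result$shap, file.path(out_dir, "shap_matrix.csv"))
  w(data.frame(result$embedding, cluster = result$labels), "embedding.csv")
  if (!is.null(result$profiles)) {
    w(data.frame(cluster = rownames(result$profiles$mean_phi),
                 result$profiles$mean_phi, check.names = FALSE),
      "cluster_mean_phi.csv")
  }
  ev <- result$evaluation
  writeLines(c(sprintf("auc\t%.6f", ev$auc),
               sprintf("auc_ci\t%.6f\t%.6f", ev$auc_ci[1], ev$auc_ci[2]),
               sprintf("hl_stat\t%.6f", ev$hl$statistic),
               sprintf("hl_p\t%.6f", ev$hl$p),
               paste0("selected\t", paste(result$selected, collapse = ","))),
             file.path(out_dir, "model_report.txt"))
  cfg <- result$config
  manifest <- c(sprintf("seed\t%d", cfg$seed),
                sprintf("screen_alpha\t%g", cfg$screen_alpha),
                sprintf("select_alpha\t%g", cfg$select_alpha),
                sprintf("eps\t%g", cfg$eps),
                sprintf("min_pts\t%d", as.integer(cfg$min_pts)),
                sprintf("n_clusters\t%d", max(result$labels)))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
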