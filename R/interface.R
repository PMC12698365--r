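#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. The eligibility
#' threshold defaults to a minimum one-day collected volume of 254 mL
#' (children below it are excluded; exactly 254 mL is retained).
#'
#' @param seed master seed; every stage derives from it.
#' @param n cohort size for simulation.
#' @param methods battery methods to evaluate (closed-form A-K and/or
#'   "M1".."M10", "M1R"). Method H stays in the table but yields an NA
#'   row unless registered.
#' @param uv24_unit method-I volume unit ("dL" or "mL").
#' @param min_volume_ml eligibility threshold on one-day volume.
#' @param include_muscle add muscle mass to the feature table.
#' @param cv_folds CV folds for model development.
#' @param split training fraction for the train/test evaluation.
#' @param model_features features of the primary fitted model.
#' @param candidates candidate set for the subset search.
#' @param sex_coding numeric sex coding.
#' @param params optional \code{\link{cohort_params}} override (its
#'   \code{n}/\code{seed} are taken from this config).
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L, n = 204L,
                            methods = c(cre_methods(), "M1", "M1R"),
                            uv24_unit = "dL",
                            min_volume_ml = 254,
                            include_muscle = FALSE,
                            cv_folds = 20L,
                            split = 0.8,
                            model_features = c("sex", "age", "bsa"),
                            candidates = c("sex", "age", "bh", "bsa",
                                           "cre_f_per_h"),
                            sex_coding = c(boy = 1, girl = 2),
                            params = NULL) {
  stopifnot(min_volume_ml >= 0, n >= 0)
  cfg <- as.list(environment())
  if (is.null(cfg$params)) {
    cfg$params <- cohort_params(n = n, seed = seed, sex_coding = sex_coding)
  } else {
    cfg$params$n <- n
    cfg$params$seed <- seed
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Apply eligibility filtering
#'
#' Removes children with a one-day collected volume below the threshold
#' (strictly less than; the boundary value is retained), unknown age, or
#' unrecorded void times (which make spot designation impossible). Every
#' exclusion is logged with its reason.
#'
#' @param children child table.
#' @param composites \code{\link{composite_24h}} output.
#' @param voids void records (used to detect missing timestamps).
#' @param min_volume_ml threshold, mL (default 254).
#' @return list: \code{children} (filtered), \code{exclusions}
#'   (data.frame \code{child_id, reason}).
#' @export
apply_eligibility <- function(children, composites, voids = NULL,
                              min_volume_ml = 254) {
  uv <- composites$uv24_ml[match(children$id, composites$child_id)]
  reasons <- rep(NA_character_, nrow(children))
  reasons[is.na(children$age_years)] <- "age"
  if (!is.null(voids)) {
    bad_time <- unique(voids$child_id[is.na(voids$timestamp)])
    reasons[is.na(reasons) & children$id %in% bad_time] <- "time"
  }
  reasons[is.na(reasons) & (is.na(uv) | uv < min_volume_ml)] <- "volume"
  excl <- !is.na(reasons)
  list(
    children = children[!excl, , drop = FALSE],
    exclusions = data.frame(child_id = children$id[excl],
                            reason = reasons[excl],
                            stringsAsFactors = FALSE)
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or accepts) a cohort, derives the 24-hour composites, spot
#' designations and feature table, applies eligibility filtering,
#' evaluates the configured estimator battery with Bland-Altman
#' agreement per method against the measured composite excretion, runs
#' the model-development stage (Lasso ranking, subset search, OLS fit,
#' train/test evaluation), fits and applies the trend-bias
#' recalibration, and estimates sodium excretion from all three spot
#' types. Fully deterministic for a fixed config.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param cohort optional pre-built \code{cre_cohort} (skips simulation).
#' @return list of class \code{pipeline_report}.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    cohort <- .stage("simulate", simulate_cohort(config$params))
  }
  composites <- .stage("composite", composite_24h(cohort$voids))
  spots <- .stage("spots", designate_spots(cohort$voids))
  elig <- .stage("eligibility",
                 apply_eligibility(cohort$children, composites,
                                   cohort$voids, config$min_volume_ml))
  children <- elig$children
  composites <- composites[composites$child_id %in% children$id, ]
  spots <- spots[spots$child_id %in% children$id, ]
  features <- .stage("features",
                     build_feature_table(children, spots,
                                         include_muscle = config$include_muscle,
                                         sex_coding = config$sex_coding))

  inputs <- .stage("battery",
                   battery_inputs(children, spots, composites))
  inputs$cre_f_per_h <- features$cre_f_per_h[
    match(inputs$child_id, features$child_id)]
  estimates <- .stage("battery",
                      cre_battery(inputs, methods = config$methods,
                                  uv24_unit = config$uv24_unit))
  agreement <- .stage("agreement",
                      battery_agreement(estimates, composites,
                                        measured_col = "cre24_mg_day"))

  y <- composites$cre24_mg_day[match(features$child_id,
                                     composites$child_id)]
  ranking <- .stage("model_dev",
                    lasso_rank(features, y, cv_folds = config$cv_folds,
                               seed = config$seed + 10L))
  comparison <- .stage("model_dev",
                       subset_search(features, y, config$candidates,
                                     cv_folds = config$cv_folds,
                                     seed = config$seed + 11L,
                                     must_include_any = config$candidates))
  fitted <- .stage("model_dev",
                   fit_cre_model(features, config$model_features, y,
                                 label = "fitted",
                                 sex_coding = config$sex_coding))
  tts <- .stage("model_dev",
                train_test_split_eval(features, y,
                                      split = config$split,
                                      cv_folds = config$cv_folds,
                                      seed = config$seed + 12L))

  pred <- predict(fitted, features)
  recal <- .stage("recalibration", fit_recalibration(pred, y))
  recal_model <- apply_recalibration(fitted, recal)
  pred_r <- predict(recal_model, features)
  post_ba <- bland_altman(pred_r, y)

  cre_for_na <- data.frame(child_id = features$child_id,
                           cre24_pred_mg_day = pred_r,
                           stringsAsFactors = FALSE)
  meas_na <- composites[c("child_id", "na24_meq_day")]
  sodium <- .stage("sodium", lapply(c("FVU", "SVU", "TVU"), function(st) {
    suppressMessages(
      sodium_agreement(spots, cre_for_na, meas_na, spot_type = st))
  }))
  names(sodium) <- c("FVU", "SVU", "TVU")

  structure(list(
    seed = config$seed,
    n_simulated = nrow(cohort$children),
    n_eligible = nrow(children),
    exclusions = elig$exclusions,
    method_agreement = agreement,
    ranking = as.data.frame(ranking),
    selected = attr(ranking, "selected"),
    comparison = as.data.frame(comparison),
    fitted_model = list(label = fitted$label,
                        intercept = fitted$intercept,
                        coef = as.list(fitted$coef),
                        adj_r2 = fitted$adj_r2),
    split_eval = tts,
    recalibration = list(t = recal$t, c = recal$c),
    recalibrated_model = list(intercept = recal_model$intercept,
                              coef = as.list(recal_model$coef)),
    post_recal_agreement = list(mean_diff = post_ba$mean_diff,
                                trend_slope = post_ba$trend_slope,
                                loa_low = post_ba$loa_low,
                                loa_high = post_ba$loa_high),
    model_1r = list(intercept = cre_model_1r()$intercept,
                    coef = as.list(cre_model_1r()$coef)),
    sodium = lapply(sodium, function(s) {
      list(spot = s$spot_type, n_used = s$n_used, n_skipped = s$n_skipped,
           mean_diff = s$ba$mean_diff, ci_low = s$ba$ci_low,
           ci_high = s$ba$ci_high, trend_slope = s$ba$trend_slope,
           trend_p = s$ba$trend_p, loa_low = s$ba$loa_low,
           loa_high = s$ba$loa_high)
    }),
    tables = list(features = features, estimates = estimates,
                  composites = composites)
  ), class = "pipeline_report")
}

#' @export
#' @method print pipeline_report
print.pipeline_report <- function(x, ...) {
  cat("Creatinine-excretion pipeline report (seed", x$seed, ")\n")
  cat(sprintf("  cohort: %d simulated, %d eligible (%d excluded)\n",
              x$n_simulated, x$n_eligible, nrow(x$exclusions)))
  cat("  method agreement:\n")
  print(x$method_agreement[c("method", "n", "mean_diff", "trend_slope",
                             "loa_low", "loa_high")], digits = 3)
  cat(sprintf("  fitted model adj R^2: %.3f; recalibration t = %.3f, c = %.1f\n",
              x$fitted_model$adj_r2, x$recalibration$t, x$recalibration$c))
  cat(sprintf("  split eval: train CV R^2 %.3f, test R^2 %.3f\n",
              x$split_eval$train_cv_r2, x$split_eval$test_r2))
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes \code{report.json} plus \code{features.csv},
#' \code{estimates.csv} and \code{composites.csv} under \code{dir}.
#'
#' @param report a \code{pipeline_report}.
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_pipeline_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(report$tables)) {
    utils::write.csv(report$tables[[nm]],
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  json <- report[setdiff(names(report), "tables")]
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
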