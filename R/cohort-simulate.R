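#' Simulation parameters for a synthetic schoolchild cohort
#'
#' Bundles every knob of the synthetic cohort generator. Defaults are
#' calibrated so that, over a large cohort, the anthropometric marginals
#' match a Japanese elementary-school reference population (age 8.7 +/- 1.5
#' years, height 131.3 +/- 10.9 cm, weight 28.6 +/- 7.2 kg, BSA 1.02 m^2,
#' 55.4% boys) and the true one-day creatinine excretion follows the
#' reference linear model in sex, age and BSA with a residual SD of
#' 69 mg/day.
#'
#' Height and weight are drawn from an age- and sex-conditional bivariate
#' normal: conditional means move linearly with exact age (slopes
#' \code{bh_slope_cm_per_yr}, \code{bw_slope_kg_per_yr}); sex offsets are
#' derived from the boy-girl gaps so the sex-weighted mean offset is zero;
#' within-cell residual SDs are back-computed so the marginal SDs hit
#' their targets; \code{bh_bw_cor} is the within-cell correlation.
#'
#' @param n number of children.
#' @param seed integer seed used by the generators.
#' @param p_boy probability a child is a boy.
#' @param age_probs probabilities for integer ages 6..12.
#' @param bh_mean_cm,bh_sd_cm,bw_mean_kg,bw_sd_kg marginal targets.
#' @param bh_gap_cm,bw_gap_kg boy-minus-girl mean gaps.
#' @param bh_slope_cm_per_yr,bw_slope_kg_per_yr growth slopes per exact year.
#' @param bh_bw_cor within age/sex cell height-weight correlation.
#' @param bh_bounds_cm,bw_bounds_kg physiologic clamping bounds.
#' @param true_coef named vector (intercept, sex, age, bsa) of the
#'   generative creatinine model, mg/day scale, sex coded boy=1/girl=2.
#' @param residual_sd residual SD of true cre24, mg/day.
#' @param cre24_floor lower truncation for true cre24, mg/day.
#' @param uv24_meanlog,uv24_sdlog lognormal parameters of daily urine
#'   volume (mL); defaults reproduce a 686 mL median with the observed
#'   interquartile spread.
#' @param uv24_min_ml hard floor on daily volume (mL).
#' @param voids_day1_min,voids_day1_extra_lambda day-1 collected voids are
#'   \code{min + Poisson(lambda)}.
#' @param fvu_conc_factor overnight concentration factor of the day-2
#'   first void relative to the pooled daily concentration (default
#'   104/71.87, the ratio of the reference FVU and pooled medians).
#' @param amt_noise_sdlog lognormal SD of per-void creatinine amount
#'   weights (within-day excretion-rate variation; conserves the daily
#'   total exactly, so it perturbs spot concentrations but not the
#'   composite).
#' @param spot_noise_cv multiplicative CV of per-measurement assay noise
#'   on reported concentrations (does not conserve; a pooled composite
#'   inherits only the volume-weighted average of it).
#' @param volume_noise_shape gamma shape for per-void volume jitter.
#' @param na24_medlog,na24_sdlog lognormal parameters of true one-day
#'   sodium excretion (mEq/day); default median 148.5 x 686/1000.
#' @param k24_medlog,k24_sdlog same for potassium.
#' @param elec_void_sdlog per-void lognormal spread of electrolyte amounts.
#' @param sg_per_cre specific-gravity rise per mg/dL creatinine.
#' @param sg_noise_sd additive SG noise.
#' @param sex_coding named vector, numeric codes used downstream.
#' @return a list of class \code{cohort_params}.
#' @export
cohort_params <- function(n = 204,
                          seed = 1L,
                          p_boy = 113 / 204,
                          age_probs = .default_age_probs(),
                          bh_mean_cm = 131.3, bh_sd_cm = 10.9,
                          bw_mean_kg = 28.6, bw_sd_kg = 7.2,
                          bh_gap_cm = 2.7, bw_gap_kg = 1.7,
                          bh_slope_cm_per_yr = 5.8,
                          bw_slope_kg_per_yr = 3.2,
                          bh_bw_cor = 0.8,
                          bh_bounds_cm = c(90, 180),
                          bw_bounds_kg = c(12, 80),
                          true_coef = c(intercept = -198.96, sex = -38.54,
                                        age = 15.43, bsa = 633.73),
                          residual_sd = 69,
                          cre24_floor = 50,
                          uv24_meanlog = log(686), uv24_sdlog = 0.41,
                          uv24_min_ml = 100,
                          voids_day1_min = 3,
                          voids_day1_extra_lambda = 1.3,
                          fvu_conc_factor = 104 / 71.87,
                          amt_noise_sdlog = 0.25,
                          spot_noise_cv = 0.05,
                          volume_noise_shape = 6,
                          na24_medlog = log(148.5 * 686 / 1000),
                          na24_sdlog = 0.35,
                          k24_medlog = log(42.5 * 686 / 1000),
                          k24_sdlog = 0.35,
                          elec_void_sdlog = 0.3,
                          sg_per_cre = 2.7e-4,
                          sg_noise_sd = 0.0015,
                          sex_coding = c(boy = 1, girl = 2)) {
  p <- as.list(environment())
  p$age_probs <- p$age_probs / sum(p$age_probs)
  .validate_cohort_params(p)
  class(p) <- "cohort_params"
  p
}

# discretized normal over integer ages 6..12 (marginal mean 8.7, SD 1.5)
.default_age_probs <- function() {
  p <- stats::dnorm(6:12, 8.6, 1.7)
  p / sum(p)
}

.validate_cohort_params <- function(p) {
  sds <- c(p$bh_sd_cm, p$bw_sd_kg, p$residual_sd, p$uv24_sdlog,
           p$spot_noise_cv, p$na24_sdlog, p$k24_sdlog, p$sg_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) {
    stop("cohort_params: all dispersion parameters must be finite and >= 0",
         call. = FALSE)
  }
  if (p$bh_bw_cor < -1 || p$bh_bw_cor > 1) {
    stop("cohort_params: bh_bw_cor must lie in [-1, 1]", call. = FALSE)
  }
  if (p$n < 0) stop("cohort_params: n must be >= 0", call. = FALSE)
  if (p$cre24_floor <= 0) {
    stop("cohort_params: cre24_floor must be > 0", call. = FALSE)
  }
  invisible(TRUE)
}

# moments of the exact-age distribution implied by age_probs
# (integer years + uniform month offset)
.age_moments <- function(p) {
  ages <- 6:12
  m <- sum(p$age_probs * ages) + 0.5 - 1 / 24  # mean of (months/12)
  v <- sum(p$age_probs * ages^2) - sum(p$age_probs * ages)^2 + 1 / 12
  list(mean = m, var = v)
}

#' Generate a synthetic cohort of children
#'
#' Draws \code{params$n} children with sex, integer age (years and
#' months), height, weight, and derived BMI and Mosteller BSA, plus
#' muscle mass and fat percentage. Deterministic for a fixed
#' \code{params$seed}.
#'
#' @param params a \code{\link{cohort_params}} object.
#' @return data.frame with columns \code{id, sex, age_years, age_months,
#'   bh_cm, bw_kg, bmi, bsa_m2, muscle_kg, fat_pct}.
#' @examples
#' ch <- simulate_children(cohort_params(n = 5, seed = 42))
#' ch$bsa_m2 - sqrt(ch$bh_cm * ch$bw_kg / 3600)  # zero by construction
#' @export
simulate_children <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  .validate_cohort_params(params)
  n <- params$n
  if (n == 0) {
    return(data.frame(id = character(), sex = character(),
                      age_years = integer(), age_months = integer(),
                      bh_cm = numeric(), bw_kg = numeric(), bmi = numeric(),
                      bsa_m2 = numeric(), muscle_kg = numeric(),
                      fat_pct = numeric(), stringsAsFactors = FALSE))
  }
  set.seed(params$seed)
  sex <- ifelse(stats::runif(n) < params$p_boy, "boy", "girl")
  age_years <- sample(6:12, n, replace = TRUE, prob = params$age_probs)
  age_months <- age_years * 12L + sample(0:11, n, replace = TRUE)
  age_exact <- age_months / 12 + stats::runif(n, 0, 1 / 12)

  am <- .age_moments(params)
  q_boy <- 1 - params$p_boy
  # sex offsets with zero sex-weighted mean, reproducing the boy-girl gap
  off_bh <- ifelse(sex == "boy", params$bh_gap_cm * q_boy,
                   -params$bh_gap_cm * params$p_boy)
  off_bw <- ifelse(sex == "boy", params$bw_gap_kg * q_boy,
                   -params$bw_gap_kg * params$p_boy)
  var_off_bh <- params$p_boy * q_boy * params$bh_gap_cm^2
  var_off_bw <- params$p_boy * q_boy * params$bw_gap_kg^2

  within_bh <- sqrt(max(
    params$bh_sd_cm^2 - params$bh_slope_cm_per_yr^2 * am$var - var_off_bh, 1))
  within_bw <- sqrt(max(
    params$bw_sd_kg^2 - params$bw_slope_kg_per_yr^2 * am$var - var_off_bw, 0.5))

  mu_bh <- params$bh_mean_cm + params$bh_slope_cm_per_yr * (age_exact - am$mean) + off_bh
  mu_bw <- params$bw_mean_kg + params$bw_slope_kg_per_yr * (age_exact - am$mean) + off_bw

  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- params$bh_bw_cor
  bh <- mu_bh + within_bh * z1
  bw <- mu_bw + within_bw * (rho * z1 + sqrt(1 - rho^2) * z2)
  bh <- pmin(pmax(bh, params$bh_bounds_cm[1]), params$bh_bounds_cm[2])
  bw <- pmin(pmax(bw, params$bw_bounds_kg[1]), params$bw_bounds_kg[2])

  muscle <- 0.55 * bw + ifelse(sex == "boy", 7.6, 6.7) + stats::rnorm(n, 0, 1.5)
  fat <- ifelse(sex == "boy", stats::rnorm(n, 13.8, 7.9),
                stats::rnorm(n, 15.7, 4.7))
  fat <- pmin(pmax(fat, 3), 45)

  data.frame(
    id = sprintf("C%04d", seq_len(n)),
    sex = sex,
    age_years = as.integer(age_years),
    age_months = as.integer(age_months),
    bh_cm = bh,
    bw_kg = bw,
    bmi = bw / (bh / 100)^2,
    bsa_m2 = bsa_mosteller(bh, bw),
    muscle_kg = muscle,
    fat_pct = fat,
    stringsAsFactors = FALSE
  )
}

#' Assign ground-truth one-day excretions
#'
#' True one-day creatinine excretion is linear in sex code, age (integer
#' years) and BSA plus Gaussian noise, truncated below at
#' \code{params$cre24_floor}; true sodium and potassium excretions are
#' lognormal. These ground-truth values stand in for measured 24-hour
#' excretion when evaluating estimators on synthetic data.
#'
#' @param children output of \code{\link{simulate_children}}.
#' @param params a \code{\link{cohort_params}} object.
#' @param seed optional seed override (defaults to \code{params$seed + 1}).
#' @return data.frame \code{child_id, true_cre24_mg_day, true_na24_meq_day,
#'   true_k24_meq_day}.
#' @export
assign_true_cre24 <- function(children, params = cohort_params(),
                              seed = params$seed + 1L) {
  if (nrow(children) == 0) stop("assign_true_cre24: empty cohort")
  .validate_cohort_params(params)
  set.seed(seed)
  b <- params$true_coef
  lin <- b[["intercept"]] +
    b[["sex"]] * sex_code(children$sex, params$sex_coding) +
    b[["age"]] * children$age_years +
    b[["bsa"]] * children$bsa_m2
  cre <- lin + stats::rnorm(nrow(children), 0, params$residual_sd)
  cre <- pmax(cre, params$cre24_floor)
  data.frame(
    child_id = children$id,
    true_cre24_mg_day = cre,
    true_na24_meq_day = stats::rlnorm(nrow(children), params$na24_medlog,
                                      params$na24_sdlog),
    true_k24_meq_day = stats::rlnorm(nrow(children), params$k24_medlog,
                                     params$k24_sdlog),
    stringsAsFactors = FALSE
  )
}

# hour offsets of one child's voids: day-1 collected voids end with a
# bedtime void; the day-2 first void (FVU) is the last record. A minimum
# inter-void gap of 30 min is enforced (physiologic; also keeps per-hour
# spot features finite and well-scaled).
.draw_void_hours <- function(n_day1, min_gap = 0.5) {
  bedtime <- 21 + stats::runif(1, 0, 1.5)
  mids <- numeric(0)
  if (n_day1 > 1) {
    for (try in 1:50) {
      mids <- sort(stats::runif(n_day1 - 1, 7.6, bedtime - 0.7))
      if (min(diff(c(7, mids, bedtime))) >= min_gap) break
    }
    if (min(diff(c(7, mids, bedtime))) < min_gap) {
      mids <- seq(7.6, bedtime - 0.7, length.out = n_day1 - 1)
    }
  }
  fvu <- 24 + 6 + stats::runif(1, 0, 1.5)
  c(mids, bedtime, fvu)
}

#' Simulate per-void urine records for a cohort
#'
#' Emulates the one-day collection protocol: the day-1 first void is not
#' collected (records start at the day's second void), every later day-1
#' void is collected, and the day-2 first void (FVU) completes the 24-hour
#' collection. Per-void creatinine amounts are proportional to the time
#' elapsed since the previous void, jittered by conserving
#' excretion-rate noise (\code{amt_noise_sdlog}), so with zero assay
#' noise (\code{spot_noise_cv = 0}) the volume-weighted composite
#' reproduces the true one-day excretion exactly. The overnight FVU is more concentrated than the
#' daily pool by \code{fvu_conc_factor}. Specific gravity rises linearly
#' with creatinine concentration.
#'
#' @param children,truth outputs of \code{\link{simulate_children}} and
#'   \code{\link{assign_true_cre24}}.
#' @param params a \code{\link{cohort_params}} object.
#' @param seed seed (defaults to \code{params$seed + 2}).
#' @param origin date-time anchoring day 1 at 00:00.
#' @return data.frame \code{child_id, timestamp, volume_ml, cre_mg_dl,
#'   na_meq_l, k_meq_l, sg} sorted by child and time.
#' @export
simulate_voids <- function(children, truth, params = cohort_params(),
                           seed = params$seed + 2L,
                           origin = as.POSIXct("2022-06-01 00:00:00",
                                               tz = "UTC")) {
  if (nrow(children) == 0) stop("simulate_voids: empty cohort")
  .validate_cohort_params(params)
  stopifnot(all(truth$true_cre24_mg_day > 0))
  set.seed(seed)
  out <- vector("list", nrow(children))
  for (i in seq_len(nrow(children))) {
    uv24 <- max(stats::rlnorm(1, params$uv24_meanlog, params$uv24_sdlog),
                params$uv24_min_ml)
    if (uv24 <= 0) stop("simulate_voids: sampled daily volume is zero")
    n_day1 <- params$voids_day1_min +
      stats::rpois(1, params$voids_day1_extra_lambda)
    hours <- .draw_void_hours(n_day1)
    k <- length(hours)
    gaps <- diff(c(7, hours))  # uncollected day-1 FVU anchored at 07:00
    w_amt <- gaps * stats::rlnorm(k, 0, params$amt_noise_sdlog)
    w_amt <- w_amt / sum(w_amt)
    fvu_fac <- c(rep(1, k - 1), params$fvu_conc_factor)
    w_vol <- (w_amt / fvu_fac) * stats::rgamma(k, params$volume_noise_shape,
                                               params$volume_noise_shape)
    vol <- uv24 * w_vol / sum(w_vol)

    cre_amt <- truth$true_cre24_mg_day[i] * w_amt
    sn <- params$spot_noise_cv
    noise <- if (sn > 0) {
      sl <- sqrt(log(1 + sn^2))
      stats::rlnorm(k, -sl^2 / 2, sl)
    } else rep(1, k)
    cre_conc <- cre_amt * 100 / vol * noise

    w_na <- w_amt * stats::rlnorm(k, 0, params$elec_void_sdlog)
    w_na <- w_na / sum(w_na)
    w_k <- w_amt * stats::rlnorm(k, 0, params$elec_void_sdlog)
    w_k <- w_k / sum(w_k)
    na_conc <- truth$true_na24_meq_day[i] * w_na * 1000 / vol
    k_conc <- truth$true_k24_meq_day[i] * w_k * 1000 / vol

    sg <- 1 + params$sg_per_cre * cre_conc +
      stats::rnorm(k, 0, params$sg_noise_sd)
    sg <- pmin(pmax(sg, 1.001), 1.06)

    out[[i]] <- data.frame(
      child_id = children$id[i],
      timestamp = origin + hours * 3600,
      volume_ml = vol,
      cre_mg_dl = cre_conc,
      na_meq_l = na_conc,
      k_meq_l = k_conc,
      sg = sg,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate a complete cohort: children, ground truth and void records
#'
#' @param params a \code{\link{cohort_params}} object.
#' @return list of class \code{cre_cohort} with elements \code{children},
#'   \code{truth}, \code{voids} and \code{params}.
#' @examples
#' coh <- simulate_cohort(cohort_params(n = 8, seed = 3))
#' nrow(coh$children)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  children <- simulate_children(params)
  truth <- assign_true_cre24(children, params)
  voids <- simulate_voids(children, truth, params)
  structure(list(children = children, truth = truth, voids = voids,
                 params = params),
            class = "cre_cohort")
}

#' @export
#' @method print cre_cohort
print.cre_cohort <- function(x, ...) {
  cat("Synthetic schoolchild cohort\n")
  cat(sprintf("  children: %d (%d boys, %d girls), ages %d-%d\n",
              nrow(x$children), sum(x$children$sex == "boy"),
              sum(x$children$sex == "girl"),
              min(x$children$age_years), max(x$children$age_years)))
  cat(sprintf("  voids: %d records\n", nrow(x$voids)))
  cat(sprintf("  true cre24: mean %.1f mg/day (SD %.1f)\n",
              mean(x$truth$true_cre24_mg_day),
              stats::sd(x$truth$true_cre24_mg_day)))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes \code{children.csv}, \code{voids.csv} (ISO-8601 timestamps) and
#' \code{ground_truth.csv} under \code{dir}. UTF-8, header row, "."
#' decimal separator.
#'
#' @param cohort a \code{cre_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cre_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("children.csv", "voids.csv", "ground_truth.csv"))
  utils::write.csv(cohort$children, paths[1], row.names = FALSE)
  v <- cohort$voids
  v$timestamp <- format(v$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(v, paths[2], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort back from CSV files
#'
#' @param dir directory holding \code{children.csv}, \code{voids.csv} and
#'   \code{ground_truth.csv}.
#' @return a \code{cre_cohort} (with \code{params = NULL}).
#' @export
read_cohort_csv <- function(dir) {
  children <- utils::read.csv(file.path(dir, "children.csv"),
                              stringsAsFactors = FALSE)
  voids <- utils::read.csv(file.path(dir, "voids.csv"),
                           stringsAsFactors = FALSE)
  voids$timestamp <- as.POSIXct(voids$timestamp,
                                format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  truth <- utils::read.csv(file.path(dir, "ground_truth.csv"),
                           stringsAsFactors = FALSE)
  structure(list(children = children, truth = truth, voids = voids,
                 params = NULL),
            class = "cre_cohort")
}
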