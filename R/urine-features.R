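#' Mosteller body surface area
#'
#' BSA (m^2) = sqrt(height_cm x weight_kg / 3600).
#'
#' @param bh_cm body height, cm.
#' @param bw_kg body weight, kg.
#' @return body surface area in m^2; vectorized.
#' @examples
#' bsa_mosteller(131.3, 28.6)  # ~1.02
#' @export
bsa_mosteller <- function(bh_cm, bw_kg) {
  if (any(!is.finite(bh_cm)) || any(!is.finite(bw_kg)) ||
      any(bh_cm <= 0) || any(bw_kg <= 0)) {
    stop("bsa_mosteller: height and weight must be positive", call. = FALSE)
  }
  sqrt(bh_cm * bw_kg / 3600)
}

#' LMS growth-reference z-score
#'
#' Converts a measurement into a z-score against an age/sex-specific LMS
#' reference (skewness L, median M, coefficient of variation S):
#' z = ((x/M)^L - 1) / (L S) for L != 0, and z = ln(x/M)/S in the L -> 0
#' limit.
#'
#' @param x measurement (> 0); vectorized.
#' @param l,m,s LMS parameters (M > 0, S > 0), recycled against \code{x}.
#' @return z-score(s).
#' @export
lms_zscore <- function(x, l, m, s) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("lms_zscore: x must be positive", call. = FALSE)
  }
  stopifnot(all(m > 0), all(s > 0))
  n <- max(length(x), length(l), length(m), length(s))
  x <- rep_len(x, n); l <- rep_len(l, n)
  m <- rep_len(m, n); s <- rep_len(s, n)
  ifelse(abs(l) < 1e-8,
         log(x / m) / s,
         ((x / m)^l - 1) / (l * s))
}

#' Synthetic LMS reference table
#'
#' Smooth synthetic L/M/S curves for height, weight and BMI by sex and
#' age in months, spanning 60-167 months. These are NOT national growth
#' references: they are a self-consistent synthetic stand-in shipped so
#' z-score plumbing is testable. Real reference tables are supplied by
#' the user via \code{\link{read_lms_reference}}.
#'
#' @return data.frame \code{sex, age_months, measure, l, m, s} with
#'   measure in \{BH, BW, BMI\}.
#' @export
synthetic_lms_reference <- function() {
  months <- 60:167
  grid <- expand.grid(sex = c("boy", "girl"), age_months = months,
                      measure = c("BH", "BW", "BMI"),
                      stringsAsFactors = FALSE)
  y <- grid$age_months / 12
  boy <- grid$sex == "boy"
  m <- numeric(nrow(grid))
  l <- numeric(nrow(grid))
  s <- numeric(nrow(grid))
  i <- grid$measure == "BH"
  m[i] <- ifelse(boy[i], 116.5 + 5.90 * (y[i] - 6),
                 115.6 + 6.05 * (y[i] - 6))
  l[i] <- 1; s[i] <- 0.040
  i <- grid$measure == "BW"
  m[i] <- ifelse(boy[i], 21.5 * exp(0.1034 * (y[i] - 6)),
                 20.8 * exp(0.1080 * (y[i] - 6)))
  l[i] <- -0.8; s[i] <- 0.14
  i <- grid$measure == "BMI"
  m[i] <- ifelse(boy[i], 15.5 + 0.36 * (y[i] - 6),
                 15.3 + 0.37 * (y[i] - 6))
  l[i] <- -1.6; s[i] <- 0.095
  grid$l <- l; grid$m <- m; grid$s <- s
  grid
}

#' Read an LMS reference table from CSV
#'
#' Expected columns: \code{sex} (boy/girl), \code{age_months},
#' \code{measure} (BH/BW/BMI), \code{l}, \code{m}, \code{s}.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  .need_cols(ref, c("sex", "age_months", "measure", "l", "m", "s"),
             "read_lms_reference")
  if (any(ref$m <= 0) || any(ref$s <= 0)) {
    stop("read_lms_reference: M and S must be positive", call. = FALSE)
  }
  ref
}

# z-score of one measure against a reference, nearest-month lookup
.lms_lookup_z <- function(x, sex, age_months, ref, measure) {
  sub <- ref[ref$measure == measure, , drop = FALSE]
  z <- rep(NA_real_, length(x))
  for (sx in unique(sex)) {
    rs <- sub[sub$sex == sx, , drop = FALSE]
    if (nrow(rs) == 0) next
    idx <- which(sex == sx)
    pos <- vapply(age_months[idx],
                  function(a) which.min(abs(rs$age_months - a)), integer(1))
    z[idx] <- lms_zscore(x[idx], rs$l[pos], rs$m[pos], rs$s[pos])
  }
  z
}

#' Pool voids into a 24-hour composite
#'
#' Reconstructs the 24-hour urine from per-void records exactly as a
#' laboratory pooling the same percentage of each void would: pooled
#' concentration is the volume-weighted mean, total volume the sum, and
#' daily excretions follow as concentration x volume (mg/day =
#' mg/dL x mL / 100; mEq/day = mEq/L x mL / 1000).
#'
#' @param voids data.frame with columns \code{child_id, volume_ml,
#'   cre_mg_dl, na_meq_l, k_meq_l, sg} (one collection day per child).
#' @return data.frame, one row per child: \code{child_id, uv24_ml,
#'   creu24_mg_dl, nau24_meq_l, ku24_meq_l, sg24, cre24_mg_day,
#'   na24_meq_day, k24_meq_day}.
#' @examples
#' v <- data.frame(child_id = "a", volume_ml = c(300, 500),
#'                 cre_mg_dl = c(80, 50), na_meq_l = 0, k_meq_l = 0, sg = 1.02)
#' composite_24h(v)$cre24_mg_day  # 490
#' @export
composite_24h <- function(voids) {
  .need_cols(voids, c("child_id", "volume_ml", "cre_mg_dl", "na_meq_l",
                      "k_meq_l", "sg"), "composite_24h")
  if (nrow(voids) == 0) stop("composite_24h: no voids", call. = FALSE)
  if (any(voids$volume_ml < 0)) {
    stop("composite_24h: negative void volume", call. = FALSE)
  }
  ids <- unique(voids$child_id)
  res <- lapply(ids, function(id) {
    v <- voids[voids$child_id == id, , drop = FALSE]
    uv <- sum(v$volume_ml)
    if (uv <= 0) {
      stop("composite_24h: zero total volume for child ", id, call. = FALSE)
    }
    w <- v$volume_ml / uv
    data.frame(
      child_id = id,
      uv24_ml = uv,
      creu24_mg_dl = sum(w * v$cre_mg_dl),
      nau24_meq_l = sum(w * v$na_meq_l),
      ku24_meq_l = sum(w * v$k_meq_l),
      sg24 = sum(w * v$sg),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$cre24_mg_day <- out$creu24_mg_dl * out$uv24_ml / 100
  out$na24_meq_day <- out$nau24_meq_l * out$uv24_ml / 1000
  out$k24_meq_day <- out$ku24_meq_l * out$uv24_ml / 1000
  out
}

#' Designate the FVU, SVU and TVU spot samples
#'
#' From one child's collected voids (day-1 first void absent by protocol):
#' the first record of day 1 is the SVU (the day's second void, first
#' collected); the first void of day 2 is the FVU; the TVU is the
#' earliest day-1 void at or after 15:00 not already designated.
#' \code{interval_fvu_h} is the overnight span from the last day-1 void
#' to the FVU; \code{interval_tvu_h} the span from the preceding void to
#' the TVU. A child with no eligible post-15:00 void gets NA TVU fields
#' (flagged, not fatal).
#'
#' @param voids void records for one or more children, columns
#'   \code{child_id, timestamp, volume_ml, cre_mg_dl, na_meq_l, k_meq_l, sg}.
#' @return data.frame, one row per child, with per-spot concentration,
#'   SG and Na/K columns plus the two intervals and a \code{tvu_missing}
#'   flag.
#' @export
designate_spots <- function(voids) {
  .need_cols(voids, c("child_id", "timestamp", "volume_ml", "cre_mg_dl",
                      "na_meq_l", "k_meq_l", "sg"), "designate_spots")
  ids <- unique(voids$child_id)
  res <- lapply(ids, function(id) {
    v <- voids[voids$child_id == id, , drop = FALSE]
    if (any(is.na(v$timestamp))) {
      stop("designate_spots: missing timestamps for child ", id,
           call. = FALSE)
    }
    if (is.unsorted(as.numeric(v$timestamp), strictly = TRUE)) {
      stop("designate_spots: timestamps not strictly increasing for child ",
           id, call. = FALSE)
    }
    day1 <- as.Date(v$timestamp[1], tz = "UTC")
    vdate <- as.Date(v$timestamp, tz = "UTC")
    is_day2 <- vdate > day1
    if (!any(is_day2)) {
      stop("designate_spots: no day-2 first void for child ", id,
           call. = FALSE)
    }
    i_fvu <- which(is_day2)[1]
    d1 <- which(!is_day2)
    i_svu <- d1[1]
    hour <- as.numeric(format(v$timestamp, "%H")) +
      as.numeric(format(v$timestamp, "%M")) / 60
    cand <- setdiff(d1[hour[d1] >= 15], c(i_svu))
    i_tvu <- if (length(cand)) min(cand) else NA_integer_
    last_d1 <- d1[length(d1)]
    hrs <- function(a, b) as.numeric(difftime(b, a, units = "hours"))
    spot <- function(i, pre) {
      if (is.na(i)) {
        stats::setNames(rep(NA_real_, 5),
                        paste0(c("cre_", "na_", "k_", "sg_", "vol_"), pre))
      } else {
        stats::setNames(c(v$cre_mg_dl[i], v$na_meq_l[i], v$k_meq_l[i],
                          v$sg[i], v$volume_ml[i]),
                        paste0(c("cre_", "na_", "k_", "sg_", "vol_"), pre))
      }
    }
    row <- c(spot(i_fvu, "f"), spot(i_svu, "s"), spot(i_tvu, "t"))
    data.frame(
      child_id = id,
      t(row),
      interval_fvu_h = hrs(v$timestamp[last_d1], v$timestamp[i_fvu]),
      interval_tvu_h = if (is.na(i_tvu)) NA_real_ else
        hrs(v$timestamp[i_tvu - 1], v$timestamp[i_tvu]),
      tvu_missing = is.na(i_tvu),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Build the modelling feature table
#'
#' Derives the 25-feature set used for creatinine model development:
#' demographics and anthropometry (sex code, age, BH, BW, BMI, BSA),
#' LMS z-scores (BH, BW, BMI), spot concentrations (CreF/S/T, NaF, KF),
#' specific gravities (SGF/S/T), the overnight interval to the FVU,
#' per-hour rates (concentration / interval) and per-SG ratios
#' (concentration / SG). With \code{include_muscle = TRUE} muscle mass
#' is appended as a 26th feature. TVU-derived features are NA for
#' children whose TVU is missing; missingness propagates.
#'
#' @param children child table (\code{\link{simulate_children}} schema).
#' @param spots output of \code{\link{designate_spots}}.
#' @param lms_ref LMS reference table; defaults to the shipped synthetic
#'   reference.
#' @param include_muscle append muscle mass as a feature?
#' @param sex_coding numeric sex coding.
#' @return data.frame with \code{child_id} plus 25 (or 26) feature
#'   columns.
#' @export
build_feature_table <- function(children, spots,
                                lms_ref = synthetic_lms_reference(),
                                include_muscle = FALSE,
                                sex_coding = .sex_default_code) {
  .need_cols(children, c("id", "sex", "age_years", "age_months", "bh_cm",
                         "bw_kg", "bmi", "bsa_m2"), "build_feature_table")
  m <- match(children$id, spots$child_id)
  if (any(is.na(m))) {
    stop("build_feature_table: no spot vector for child(ren) ",
         paste(children$id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  sp <- spots[m, , drop = FALSE]
  out <- data.frame(
    child_id = children$id,
    sex = sex_code(children$sex, sex_coding),
    age = children$age_years,
    bh = children$bh_cm,
    bsa = children$bsa_m2,
    cre_f_per_h = sp$cre_f / sp$interval_fvu_h,
    cre_t_per_h_per_sg = sp$cre_t / sp$interval_tvu_h / sp$sg_t,
    cre_f_per_h_per_sg = sp$cre_f / sp$interval_fvu_h / sp$sg_f,
    cre_s_per_sg = sp$cre_s / sp$sg_s,
    cre_t_per_sg = sp$cre_t / sp$sg_t,
    cre_f_per_sg = sp$cre_f / sp$sg_f,
    cre_t_per_h = sp$cre_t / sp$interval_tvu_h,
    cre_f = sp$cre_f,
    k_f = sp$k_f,
    na_f = sp$na_f,
    bmi = children$bmi,
    bw = children$bw_kg,
    bh_z = .lms_lookup_z(children$bh_cm, children$sex, children$age_months,
                         lms_ref, "BH"),
    interval_fvu = sp$interval_fvu_h,
    bw_z = .lms_lookup_z(children$bw_kg, children$sex, children$age_months,
                         lms_ref, "BW"),
    sg_f = sp$sg_f,
    bmi_z = .lms_lookup_z(children$bmi, children$sex, children$age_months,
                          lms_ref, "BMI"),
    cre_s = sp$cre_s,
    sg_t = sp$sg_t,
    sg_s = sp$sg_s,
    cre_t = sp$cre_t,
    stringsAsFactors = FALSE
  )
  if (include_muscle) {
    .need_cols(children, "muscle_kg", "build_feature_table")
    out$muscle <- children$muscle_kg
  }
  out
}
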