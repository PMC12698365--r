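# Battery of published closed-form estimators of one-day creatinine
# excretion (methods A-K) plus the fitted linear models 1-10 and the
# recalibrated model 1R. All outputs are mg/day.

.battery_required <- list(
  A = "bw", B = c("sex", "bw"), C = c("sex", "bw"), D = character(),
  E = c("sex", "age", "bw", "bh"), F = c("cre_f", "sg_f"),
  G = c("cre_f", "sg_f"), H = NULL,  # registry-resolved
  I = c("sex", "uv24"), J = c("sex", "bh"), K = c("sex", "bh", "bw")
)

.crekid_env <- new.env(parent = emptyenv())

#' Register the method-H estimator
#'
#' Method H of the battery refers to an externally published estimation
#' procedure whose formula is not reproduced here; the battery exposes a
#' hook instead. The callable receives the battery input data.frame and
#' must return mg/day per row.
#'
#' @param fun function(data) -> numeric, or NULL to unregister.
#' @return invisibly, the previous registration.
#' @export
register_method_h <- function(fun) {
  stopifnot(is.null(fun) || is.function(fun))
  old <- .crekid_env$method_h
  .crekid_env$method_h <- fun
  invisible(old)
}

#' Battery method identifiers
#' @return character vector of closed-form method ids A-K.
#' @export
cre_methods <- function() names(.battery_required)

#' Assemble battery inputs from cohort tables
#'
#' Joins the child table with (optionally) spot designations and day
#' composites into the canonical battery input frame with columns
#' \code{sex, age, bh, bw, bsa, cre_f, sg_f, uv24}.
#'
#' @param children child table.
#' @param spots optional \code{\link{designate_spots}} output.
#' @param composites optional \code{\link{composite_24h}} output.
#' @return data.frame keyed by \code{child_id}.
#' @export
battery_inputs <- function(children, spots = NULL, composites = NULL) {
  out <- data.frame(child_id = children$id,
                    sex = children$sex,
                    age = children$age_years,
                    bh = children$bh_cm,
                    bw = children$bw_kg,
                    bsa = children$bsa_m2,
                    stringsAsFactors = FALSE)
  if (!is.null(spots)) {
    m <- match(out$child_id, spots$child_id)
    out$cre_f <- spots$cre_f[m]
    out$sg_f <- spots$sg_f[m]
    out$cre_f_per_h <- spots$cre_f[m] / spots$interval_fvu_h[m]
  }
  if (!is.null(composites)) {
    m <- match(out$child_id, composites$child_id)
    out$uv24 <- composites$uv24_ml[m]
  }
  out
}

#' Evaluate one closed-form battery method
#'
#' Implements the printed formulas verbatim, with the child's sex branch
#' where the method is sex-specific. Notes on individual methods:
#' \itemize{
#'   \item Method D is the fixed value 800 mg/day.
#'   \item Methods F/G divide the FVU creatinine concentration by
#'     (SG - 1); SG = 1 is a domain error.
#'   \item Method H delegates to \code{\link{register_method_h}} and
#'     errors when unconfigured.
#'   \item Method I multiplies daily urine volume by a per-volume
#'     constant; as printed the volume unit is ambiguous, so the unit is
#'     an option (default "dL", i.e. mL/100, which yields physiologic
#'     values) and a message is emitted on every use.
#'   \item Method K's boys branch is implemented verbatim but is negative
#'     for all plausible heights; every evaluation emits a
#'     suspect-formula warning rather than silently "fixing" it.
#' }
#' Non-positive results are returned but flagged with a warning.
#'
#' @param method one of \code{cre_methods()}.
#' @param data battery input frame (see \code{\link{battery_inputs}}).
#' @param uv24_unit unit in which method I interprets \code{uv24}
#'   ("dL" or "mL"; input column is always mL).
#' @return numeric vector of mg/day estimates.
#' @examples
#' cre_estimate("A", data.frame(bw = 28.6))        # 592.02
#' cre_estimate("D", data.frame(x = 1:3))          # 800 800 800
#' @export
cre_estimate <- function(method, data, uv24_unit = c("dL", "mL")) {
  method <- match.arg(method, cre_methods())
  uv24_unit <- match.arg(uv24_unit)
  req <- .battery_required[[method]]
  if (method != "H") {
    .need_cols(data, req, paste0("cre_estimate [", method, "]"))
  }
  boy <- if ("sex" %in% names(data)) {
    tolower(as.character(data$sex)) %in% c("boy", "1")
  } else NULL
  est <- switch(
    method,
    A = data$bw * 20.7,
    B = ifelse(boy, data$bw * 23, data$bw * 18),
    C = ifelse(boy, data$bw * 20, data$bw * 16),
    D = rep(800, max(nrow(data), 1)),
    E = ifelse(boy,
               data$age * (-12.63) + data$bw * 15.12 + data$bh * 7.39 - 79.9,
               data$age * (-4.72) + data$bw * 8.58 + data$bh * 5.09 - 74.95),
    F = {
      if (any(data$sg_f == 1, na.rm = TRUE)) {
        stop("cre_estimate [F]: SGF = 1 makes the denominator zero",
             call. = FALSE)
      }
      data$cre_f * 0.015 / (data$sg_f - 1)
    },
    G = {
      if (any(data$sg_f == 1, na.rm = TRUE)) {
        stop("cre_estimate [G]: SGF = 1 makes the denominator zero",
             call. = FALSE)
      }
      data$cre_f * 0.022 / (data$sg_f - 1)
    },
    H = {
      if (is.null(.crekid_env$method_h)) {
        stop("cre_estimate [H]: method H is not configured; ",
             "register an estimator with register_method_h()", call. = FALSE)
      }
      .crekid_env$method_h(data)
    },
    I = {
      message("cre_estimate [I]: interpreting 24-h urine volume in ",
              uv24_unit, " (printed source is ambiguous)")
      uv <- if (uv24_unit == "dL") data$uv24 / 100 else data$uv24
      ifelse(boy, uv * 104.4, uv * 99.48)
    },
    J = ifelse(boy,
               data$bh * 1.085 * ((data$bh - 168) * 0.0564 + 6.265),
               data$bh * 1.085 * 2.045 * exp((data$bh - 90) * 0.01552)),
    K = {
      if (any(boy)) {
        warning("cre_estimate [K]: boys branch evaluated verbatim is ",
                "negative for plausible heights (suspect source formula)",
                call. = FALSE)
      }
      ifelse(boy, -221 - 0.94 * data$bh + 35,
             -330 + 2.74 * data$bh + 19.57 * data$bw)
    }
  )
  est <- as.numeric(est)
  if (any(est <= 0, na.rm = TRUE)) {
    warning(sprintf("cre_estimate [%s]: %d non-positive estimate(s)",
                    method, sum(est <= 0, na.rm = TRUE)), call. = FALSE)
  }
  est
}

#' Run the full estimator battery over a cohort
#'
#' Evaluates every requested method (closed-form A-K and/or fitted
#' models "M1".."M10", "M1R") and returns a long table. Failures and
#' warnings are captured per method rather than aborting the battery.
#'
#' @param data battery input frame; fitted models additionally need
#'   their feature columns (e.g. \code{bsa}, \code{cre_f_per_h}).
#' @param methods character vector of method ids.
#' @param uv24_unit passed to method I.
#' @return data.frame \code{child_id, method, cre24_pred_mg_day, note}.
#' @export
cre_battery <- function(data, methods = setdiff(cre_methods(), "H"),
                        uv24_unit = "dL") {
  rows <- lapply(methods, function(m) {
    notes <- character()
    est <- withCallingHandlers(
      tryCatch({
        if (m %in% cre_methods()) {
          suppressMessages(cre_estimate(m, data, uv24_unit = uv24_unit))
        } else if (grepl("^M", m)) {
          mod <- if (identical(m, "M1R")) cre_model_1r() else
            cre_model_published(as.integer(sub("^M", "", m)))
          predict(mod, data)
        } else stop("unknown method id: ", m)
      }, error = function(e) {
        notes <<- c(notes, conditionMessage(e))
        rep(NA_real_, nrow(data))
      }),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    data.frame(child_id = data$child_id, method = m,
               cre24_pred_mg_day = est,
               note = paste(unique(notes), collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Printed coefficients of fitted linear models 1-10
# (sex coded boy=1, girl=2)
.table5 <- list(
  list(i = -198.96, sex = -38.54, age = 15.43, bsa = 633.73, r2 = 0.764),
  list(i = -220.22, sex = -37.96, age = 13.77, bsa = 642.37,
       cre_f_per_h = 2.39, r2 = 0.769),
  list(i = -186.30, sex = -35.72, bsa = 748.55, r2 = 0.755),
  list(i = -211.97, sex = -35.39, bsa = 744.37, cre_f_per_h = 2.7, r2 = 0.763),
  list(i = -291.47, sex = -37.61, age = 11.84, bh = 1.37, bsa = 576.72,
       r2 = 0.764),
  list(i = -342.59, sex = -36.70, age = 9.01, bh = 1.79, bsa = 568.59,
       cre_f_per_h = 2.6, r2 = 0.771),
  list(i = -369.21, sex = -35.18, bh = 2.63, bsa = 588.61, r2 = 0.761),
  list(i = -404.67, sex = -34.82, bh = 2.75, bsa = 576.55,
       cre_f_per_h = 2.8, r2 = 0.769),
  list(i = -267.86, age = 13.42, bsa = 663.72, r2 = 0.747),
  list(i = -288.84, age = 11.74, bsa = 672.22, cre_f_per_h = 2.5, r2 = 0.753)
)

#' Published linear creatinine models 1-10
#'
#' Returns one of the ten published least-squares models of one-day
#' creatinine excretion on subsets of \{sex, age, BH, BSA, CreF/h\},
#' with sex coded boy = 1, girl = 2.
#'
#' @param model_no integer 1-10.
#' @param sex_coding numeric sex coding.
#' @return a \code{\link{cre_model}}.
#' @examples
#' predict(cre_model_published(1),
#'         data.frame(sex = "boy", age = 9, bsa = 1))  # 535.10
#' @export
cre_model_published <- function(model_no, sex_coding = .sex_default_code) {
  stopifnot(length(model_no) == 1, model_no %in% 1:10)
  spec <- .table5[[model_no]]
  cf <- unlist(spec[setdiff(names(spec), c("i", "r2"))])
  cre_model(intercept = spec$i, coef = cf,
            label = paste0("M", model_no), adj_r2 = spec$r2,
            sex_coding = sex_coding)
}

#' The recalibrated reference model (Model 1R)
#'
#' Model 1 with its proportional trend bias corrected: every coefficient
#' scaled by (1 + 0.15) and 49 mg/day subtracted from the intercept,
#' giving sex -44.32, age +17.74, BSA +728.79. The published equation
#' prints the intercept as -277.40 while the construction
#' (-198.96 x 1.15 - 49) gives -277.80; the constructed value is the
#' default and the printed one is available via
#' \code{intercept = "printed"}.
#'
#' @param intercept "constructed" (default) or "printed".
#' @param sex_coding numeric sex coding (boy = 1, girl = 2 default).
#' @return a \code{\link{cre_model}} labelled "M1R".
#' @examples
#' coef(cre_model_1r())
#' @export
cre_model_1r <- function(intercept = c("constructed", "printed"),
                         sex_coding = .sex_default_code) {
  intercept <- match.arg(intercept)
  base <- cre_model_published(1, sex_coding = sex_coding)
  out <- apply_recalibration(base, recalibration_params(t = 0.15, c = 49))
  out$label <- "M1R"
  out$adj_r2 <- NA_real_
  if (intercept == "printed") {
    out$intercept <- -277.40
    out$coef <- c(sex = -44.32, age = 17.74, bsa = 728.79)
    out$features <- names(out$coef)
  }
  out
}
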