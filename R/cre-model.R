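#' Construct a linear creatinine-excretion model
#'
#' A \code{cre_model} is a linear estimator of one-day creatinine
#' excretion (mg/day): intercept + sum(coefficient x feature), with sex
#' entering as a numeric code (boy = 1, girl = 2 by default). Fitted
#' models carry their \code{lm} object; published models carry printed
#' coefficients only.
#'
#' @param intercept intercept, mg/day.
#' @param coef named numeric vector of feature coefficients; recognised
#'   feature names are \code{sex, age, bh, bsa, cre_f_per_h} plus any
#'   column of the feature table.
#' @param label short identifier (e.g. "M1", "M1R").
#' @param adj_r2 adjusted R-squared, if known.
#' @param pvalues named vector of coefficient p-values, if known.
#' @param sex_coding numeric sex coding used when predicting from
#'   character/factor sex.
#' @param fit optional underlying \code{lm} fit.
#' @return object of class \code{cre_model}.
#' @export
cre_model <- function(intercept, coef, label = "custom", adj_r2 = NA_real_,
                      pvalues = NULL, sex_coding = .sex_default_code,
                      fit = NULL) {
  coef <- unlist(coef)
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coef), !is.null(names(coef)), all(nzchar(names(coef))))
  structure(list(intercept = unname(intercept), coef = coef,
                 features = names(coef), label = label, adj_r2 = adj_r2,
                 pvalues = pvalues, sex_coding = sex_coding, fit = fit),
            class = "cre_model")
}

#' @export
coef.cre_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coef)
}

#' @export
#' @method print cre_model
print.cre_model <- function(x, ...) {
  cat(sprintf("One-day creatinine excretion model [%s]\n", x$label))
  terms <- paste(sprintf("%+.4g*%s", x$coef, x$features), collapse = " ")
  cat(sprintf("  cre24 (mg/day) = %.4g %s\n", x$intercept, terms))
  cat(sprintf("  sex coding: boy=%g, girl=%g\n",
              x$sex_coding[["boy"]], x$sex_coding[["girl"]]))
  if (is.finite(x$adj_r2)) cat(sprintf("  adjusted R^2: %.3f\n", x$adj_r2))
  invisible(x)
}

# children.csv schema -> feature-table naming
.feature_aliases <- c(age_years = "age", bh_cm = "bh", bw_kg = "bw",
                      bsa_m2 = "bsa", muscle_kg = "muscle")

.canonical_features <- function(newdata) {
  for (nm in names(.feature_aliases)) {
    tgt <- .feature_aliases[[nm]]
    if (nm %in% names(newdata) && !tgt %in% names(newdata)) {
      newdata[[tgt]] <- newdata[[nm]]
    }
  }
  newdata
}

#' Predict one-day creatinine excretion
#'
#' @param object a \code{cre_model}.
#' @param newdata data.frame holding the model's features; the
#'   children-table names (\code{age_years}, \code{bh_cm}, \code{bw_kg},
#'   \code{bsa_m2}) are accepted as aliases; \code{sex} may be
#'   "boy"/"girl" or already numeric.
#' @param ... unused.
#' @return numeric vector, mg/day.
#' @export
predict.cre_model <- function(object, newdata, ...) {
  newdata <- .canonical_features(newdata)
  .need_cols(newdata, object$features, paste0("predict [", object$label, "]"))
  acc <- rep(object$intercept, nrow(newdata))
  for (f in object$features) {
    v <- if (f == "sex") sex_code(newdata$sex, object$sex_coding)
         else as.numeric(newdata[[f]])
    acc <- acc + object$coef[[f]] * v
  }
  acc
}

#' @export
#' @method summary cre_model
summary.cre_model <- function(object, ...) {
  if (!is.null(object$fit)) return(summary(object$fit))
  print(object)
  if (!is.null(object$pvalues)) {
    cat("  p-values:\n")
    print(object$pvalues)
  }
  invisible(object)
}

#' @export
residuals.cre_model <- function(object, ...) {
  if (is.null(object$fit)) {
    stop("residuals: model was not fitted to data", call. = FALSE)
  }
  stats::residuals(object$fit)
}

#' Fit a creatinine model by ordinary least squares
#'
#' Least-squares fit of one-day creatinine excretion on a set of feature
#' columns, returning a \code{\link{cre_model}} with coefficient
#' p-values and adjusted R-squared
#' (1 - (1 - R^2)(n - 1)/(n - p - 1)).
#'
#' @param data data.frame containing the feature columns (feature-table
#'   naming; sex must already be numeric or "boy"/"girl").
#' @param features character vector of feature column names.
#' @param target numeric response (mg/day), or the name of a column of
#'   \code{data}.
#' @param label model label.
#' @param sex_coding numeric sex coding applied if \code{sex} is
#'   character.
#' @return a fitted \code{cre_model}.
#' @examples
#' coh <- simulate_cohort(cohort_params(n = 60, seed = 2))
#' d <- merge(coh$children, coh$truth, by.x = "id", by.y = "child_id")
#' m <- fit_cre_model(d, c("sex", "age_years", "bsa_m2"),
#'                    "true_cre24_mg_day")
#' coef(m)
#' @export
fit_cre_model <- function(data, features, target, label = "fitted",
                          sex_coding = .sex_default_code) {
  data <- .canonical_features(data)
  y <- if (is.character(target) && length(target) == 1) {
    .need_cols(data, target, "fit_cre_model")
    data[[target]]
  } else as.numeric(target)
  features <- unname(vapply(features, function(f) {
    if (f %in% names(.feature_aliases)) .feature_aliases[[f]] else f
  }, character(1)))
  .need_cols(data, features, "fit_cre_model")
  x <- data[features]
  if ("sex" %in% features) x$sex <- sex_code(x$sex, sex_coding)
  x <- as.data.frame(lapply(x, as.numeric))
  keep <- stats::complete.cases(x) & is.finite(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  n <- nrow(x); p <- length(features)
  if (n <= p + 1) stop("fit_cre_model: need n > p + 1", call. = FALSE)
  df <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = df)
  if (fit$rank < p + 1) {
    al <- stats::alias(fit)$Complete
    bad <- if (!is.null(al)) rownames(al) else
      names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("fit_cre_model: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  cf <- stats::coef(fit)
  cre_model(intercept = cf[["(Intercept)"]],
            coef = cf[-1],
            label = label,
            adj_r2 = sm$adj.r.squared,
            pvalues = sm$coefficients[, "Pr(>|t|)"],
            sex_coding = sex_coding,
            fit = fit)
}
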