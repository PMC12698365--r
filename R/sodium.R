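#' Tanaka spot-urine sodium excretion estimate
#'
#' Power-law estimator of one-day sodium excretion from a spot sample:
#' scale x (spot_Na / (spot_Cre x 10) x pred_cre24)^exponent, with
#' defaults scale 21.98 and exponent 0.392. The inner term is the spot
#' sodium-to-creatinine ratio rescaled by the child's predicted one-day
#' creatinine excretion; the exponent below 1 compresses the range, so
#' high intakes are pulled toward the centre.
#'
#' @param spot_na spot sodium concentration, mEq/L.
#' @param spot_cre spot creatinine concentration, mg/dL.
#' @param pred_cre24 predicted one-day creatinine excretion, mg/day.
#' @param scale,exponent power-law parameters (> 0).
#' @return predicted one-day sodium excretion, mEq/day; vectorized.
#' @examples
#' tanaka_sodium(148.5, 71.87, 500)  # ~135.4
#' tanaka_sodium(10, 1, 1)           # 21.98 (unit base)
#' @export
tanaka_sodium <- function(spot_na, spot_cre, pred_cre24,
                          scale = 21.98, exponent = 0.392) {
  stopifnot(scale > 0, exponent > 0)
  if (any(!is.finite(spot_na) | spot_na <= 0) ||
      any(!is.finite(spot_cre) | spot_cre <= 0) ||
      any(!is.finite(pred_cre24) | pred_cre24 <= 0)) {
    stop("tanaka_sodium: all inputs must be positive", call. = FALSE)
  }
  scale * (spot_na / (spot_cre * 10) * pred_cre24)^exponent
}

#' Sodium-excretion agreement for one spot type
#'
#' Predicts one-day sodium excretion per child from the designated spot
#' (FVU, SVU or TVU) with \code{\link{tanaka_sodium}}, driven by a
#' supplied one-day creatinine prediction, and assesses agreement
#' against measured sodium excretion with \code{\link{bland_altman}}.
#' Children whose spot (or creatinine prediction) is missing are skipped
#' and counted.
#'
#' @param spots \code{\link{designate_spots}} output (needs the per-spot
#'   \code{na_*} and \code{cre_*} columns).
#' @param pred_cre24 data.frame \code{child_id, cre24_pred_mg_day}.
#' @param measured data.frame \code{child_id} + measured sodium column.
#' @param spot_type "FVU", "SVU" or "TVU".
#' @param measured_col measured column name (mEq/day).
#' @param scale,exponent passed to \code{\link{tanaka_sodium}}.
#' @return list: \code{ba} (a \code{bland_altman}), \code{n_used},
#'   \code{n_skipped}, \code{predictions} (per-child table).
#' @export
sodium_agreement <- function(spots, pred_cre24, measured,
                             spot_type = c("FVU", "SVU", "TVU"),
                             measured_col = "na24_meq_day",
                             scale = 21.98, exponent = 0.392) {
  spot_type <- match.arg(spot_type)
  suf <- c(FVU = "f", SVU = "s", TVU = "t")[[spot_type]]
  .need_cols(spots, c("child_id", paste0("na_", suf), paste0("cre_", suf)),
             "sodium_agreement")
  .need_cols(pred_cre24, c("child_id", "cre24_pred_mg_day"),
             "sodium_agreement")
  .need_cols(measured, c("child_id", measured_col), "sodium_agreement")
  na_sp <- spots[[paste0("na_", suf)]]
  cre_sp <- spots[[paste0("cre_", suf)]]
  cre24 <- pred_cre24$cre24_pred_mg_day[
    match(spots$child_id, pred_cre24$child_id)]
  meas <- measured[[measured_col]][match(spots$child_id, measured$child_id)]
  ok <- is.finite(na_sp) & na_sp > 0 & is.finite(cre_sp) & cre_sp > 0 &
    is.finite(cre24) & cre24 > 0 & is.finite(meas)
  if (sum(!ok)) {
    message("sodium_agreement [", spot_type, "]: skipping ", sum(!ok),
            " child(ren) with missing spot or prediction")
  }
  pred <- tanaka_sodium(na_sp[ok], cre_sp[ok], cre24[ok],
                        scale = scale, exponent = exponent)
  ba <- bland_altman(pred, meas[ok])
  list(ba = ba, n_used = sum(ok), n_skipped = sum(!ok),
       spot_type = spot_type,
       predictions = data.frame(child_id = spots$child_id[ok],
                                na24_pred_meq_day = pred,
                                na24_meas_meq_day = meas[ok],
                                stringsAsFactors = FALSE))
}

#' Convert sodium excretion to salt intake
#'
#' Optional convenience conversion: 1 mEq sodium = 23 mg Na = 58.5 mg
#' NaCl, i.e. grams of salt = mEq x 0.0585.
#'
#' @param na_meq_day sodium excretion, mEq/day.
#' @return salt, g/day.
#' @export
sodium_to_salt_g <- function(na_meq_day) na_meq_day * 0.0585
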