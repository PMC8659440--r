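#' Grade a model from its RPD
#'
#' RPD (prediction-set reference standard deviation over RMSEP) above 2 marks
#' an accurate model, 1.4-1.8 a rough one, anything else (including the
#' 1.8-2 gap) inadequate.
#' @param rpd numeric.
#' @return character grade.
#' @export
rpd_grade <- function(rpd) {
  dplyr::case_when(
    rpd > 2 ~ "accurate",
    rpd >= 1.4 & rpd <= 1.8 ~ "rough",
    TRUE ~ "inadequate"
  )
}

#' Evaluate a calibration model on calibration and prediction sets
#'
#' Computes the standard chemometric report row: Pearson correlations between
#' reference and predicted values on both sets (Rc, Rp), the prediction-set
#' RMSEP, and RPD = sd(reference) / RMSEP with its qualitative grade. A
#' perfect prediction (RMSEP = 0) flags an infinite RPD with a warning and
#' grades "accurate".
#'
#' @param model fitted model with a `predict` method (`tea_pls`, `tea_elm`,
#'   `tea_svr`, ...).
#' @param cal_x,cal_y calibration inputs and reference values.
#' @param pred_x,pred_y prediction-set inputs and reference values
#'   (non-empty, sd(pred_y) > 0).
#' @param rmsecv optional cross-validation RMSE to carry into the row.
#' @param pcs optional component count to carry into the row.
#' @return one-row tibble: pcs, rc, rmsecv, rp, rmsep, rpd, grade.
#' @export
evaluate_model <- function(model, cal_x, cal_y, pred_x, pred_y,
                           rmsecv = NA_real_, pcs = NA_integer_) {
  if (length(pred_y) == 0 || stats::sd(pred_y) == 0) {
    stop("prediction set must be non-empty with sd > 0.", call. = FALSE)
  }
  cal_hat <- predict(model, as.matrix(cal_x))
  pred_hat <- predict(model, as.matrix(pred_x))
  rmsep <- sqrt(mean((pred_hat - pred_y)^2))
  rpd <- if (rmsep == 0) {
    warning("RMSEP is zero; RPD is infinite.", call. = FALSE)
    Inf
  } else stats::sd(pred_y) / rmsep
  tibble::tibble(
    pcs = as.integer(pcs),
    rc = stats::cor(cal_y, cal_hat),
    rmsecv = rmsecv,
    rp = stats::cor(pred_y, pred_hat),
    rmsep = rmsep,
    rpd = rpd,
    grade = rpd_grade(rpd)
  )
}
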