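#' Residual prediction deviation (RPD)
#'
#' Ratio of the standard deviation of the reference values (n-1 denominator)
#' to the prediction RMSE. By the usual reading, RPD > 2 marks a model with
#' good and RPD > 6 one with excellent predictive ability.
#'
#' @param y_true Reference concentration vector.
#' @param rmse Root-mean-square error of the predictions (>= 0).
#' @return The RPD; `Inf` when `rmse` is 0 (perfect predictions).
#' @examples
#' rpd(c(0, 10, 20), 2)
#' @export
rpd <- function(y_true, rmse) {
  if (rmse < 0) stop("rmse must be >= 0", call. = FALSE)
  if (rmse == 0) return(Inf)
  sd(y_true) / rmse
}

#' Prediction bias
#'
#' Mean signed residual, `mean(predicted - true)`; positive values indicate
#' systematic overestimation.
#'
#' @param pred Predicted values.
#' @param true Reference values, same length.
#' @return Numeric scalar.
#' @export
prediction_bias <- function(pred, true) {
  if (length(pred) != length(true)) {
    stop("pred and true must have the same length", call. = FALSE)
  }
  mean(pred - true)
}

new_validation_report <- function(analyte, scheme, rank, pred, true, n_samples) {
  resid <- pred - true
  rmse <- sqrt(mean(resid^2))
  sstot <- sum((true - mean(true))^2)
  r2 <- 1 - sum(resid^2) / sstot
  structure(list(
    analyte = analyte, scheme = scheme, rank = rank,
    R2 = r2, RMSE = rmse, RPD = rpd(true, rmse),
    bias = prediction_bias(pred, true),
    n = length(true), n_samples = n_samples,
    predictions = data.frame(true = true, predicted = pred)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report %s [%s]: rank %d, R2 = %.3f, %s = %.3g, RPD = %.2f, bias = %.3g, n = %d>\n",
    x$analyte, x$scheme, x$rank, x$R2,
    if (x$scheme == "external") "RMSEP" else "RMSECV",
    x$RMSE, x$RPD, x$bias, x$n))
  invisible(x)
}

#' Grouped k-fold cross-validation of a PLS1 model
#'
#' Assembles out-of-fold predictions over the whole data set and reports
#' RMSECV (n denominator), R2 = 1 - SSres/SStot on the out-of-fold pairs,
#' bias, and RPD = sd(y) / RMSECV (n-1 denominator for the sd). Replicate
#' scans never straddle folds: fold assignment is by sample id, stratified
#' over the concentration range (see [select_rank()] for the same engine).
#'
#' Note that because the sd uses n-1 and RMSECV uses n, the identity
#' RPD = 1/sqrt(1 - R2) holds only up to a factor sqrt(n/(n-1)).
#'
#' @param X Preprocessed spectra matrix (one scan per row).
#' @param y Reference concentrations per scan.
#' @param sample_ids Sample identifier per scan; defaults to one scan = one
#'   sample.
#' @param k Number of folds, default 5.
#' @param rank Number of latent variables; `NULL` (default) selects the rank
#'   by nested application of the same CV folds via [select_rank()].
#' @param max_rank Search bound when `rank` is `NULL`.
#' @param seed Seed for the fold assignment.
#' @param analyte Label carried into the report.
#' @return A `validation_report` (scheme `"cross"`).
#' @export
kfold_cv <- function(X, y, sample_ids = seq_len(nrow(X)), k = 5L,
                     rank = NULL, max_rank = 10L, seed = 1L,
                     analyte = NA_character_) {
  X <- as.matrix(X)
  top <- if (is.null(rank)) max_rank else rank
  cvp <- cv_predictions(X, y, sample_ids, k = k, max_rank = top, seed = seed)
  if (is.null(rank)) {
    rmse <- sqrt(colMeans((cvp - y)^2))
    rank <- which.min(rmse)
  }
  new_validation_report(analyte, "cross", as.integer(rank),
                        pred = cvp[, rank], true = y,
                        n_samples = length(unique(sample_ids)))
}

#' External validation on a held-out sample set
#'
#' Fits the calibration on the calibration set only (spectra already passed
#' through the analyte's preprocessing chain) and evaluates R2p, RMSEP, RPDp
#' and bias on the validation set. Sample ids must be disjoint between the
#' two sets.
#'
#' @param X_cal,y_cal Calibration spectra and reference values.
#' @param X_val,y_val Validation spectra and reference values.
#' @param rank Number of latent variables for the calibration fit.
#' @param cal_ids,val_ids Sample ids of the scans in each set.
#' @param analyte Label carried into the report.
#' @return A `validation_report` (scheme `"external"`) with the fitted model
#'   attached as attribute `"model"`.
#' @export
external_validation <- function(X_cal, y_cal, X_val, y_val, rank,
                                cal_ids = seq_len(nrow(X_cal)),
                                val_ids = nrow(X_cal) + seq_len(nrow(X_val)),
                                analyte = NA_character_) {
  overlap <- intersect(unique(cal_ids), unique(val_ids))
  if (length(overlap)) {
    stop("calibration and validation sets share sample ids: ",
         paste(utils::head(overlap, 3L), collapse = ", "), call. = FALSE)
  }
  fit <- fit_pls1(X_cal, y_cal, rank = rank)
  pred <- predict(fit, X_val)
  rep <- new_validation_report(analyte, "external", fit$rank,
                               pred = pred, true = y_val,
                               n_samples = length(unique(val_ids)))
  attr(rep, "model") <- fit
  rep
}
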