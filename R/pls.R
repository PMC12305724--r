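#' Fit a PLS1 calibration model by NIPALS
#'
#' Single-response partial least squares regression on column-centred spectra
#' and centred response, by NIPALS deflation. Each latent variable extracts a
#' weight vector `w = X'y / ||X'y||`, scores `t = Xw`, X-loading
#' `p = X't / t't` and y-loading `q = y't / t't`, then deflates `X` and `y`.
#' Regression coefficients for any rank `a <= rank` are
#' `B_a = W_a (P_a' W_a)^{-1} q_a`, and predictions are
#' `yhat = ybar + (x - xbar) B_a`.
#'
#' For a single response the NIPALS component iteration converges in one pass;
#' the iteration loop is retained with a score-change tolerance for
#' robustness.
#'
#' @param X Numeric matrix, one (preprocessed) spectrum per row.
#' @param y Numeric response vector, `length(y) == nrow(X)`.
#' @param rank Number of latent variables (>= 1).
#' @param tol Score-change convergence tolerance (default 1e-12).
#' @param maxit Maximum NIPALS iterations per component (default 500).
#' @return Object of class `pls1_model`: centering vectors, `W`, `P`, `q`,
#'   score matrix `Tscores`, per-rank coefficient matrix `B` (one column per
#'   rank) and intercepts, plus the achieved `rank`.
#' @seealso [predict.pls1_model()], [select_rank()]
#' @export
fit_pls1 <- function(X, y, rank, tol = 1e-12, maxit = 500L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows(X) must equal length(y)", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (rank < 1L) {
    stop("rank must be >= 1 (use mean(y) directly for a mean-only model)",
         call. = FALSE)
  }
  if (n < rank + 1L) stop("need at least rank + 1 samples", call. = FALSE)

  xmeans <- colMeans(X)
  ymean <- mean(y)
  Xc <- sweep(X, 2L, xmeans)
  yc <- y - ymean

  W <- P <- matrix(0, p, rank)
  Tsc <- matrix(0, n, rank)
  q <- numeric(rank)
  achieved <- 0L
  for (a in seq_len(rank)) {
    w <- drop(crossprod(Xc, yc))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14 * max(1, sqrt(sum(yc^2)))) break  # X exhausted or y fitted
    w <- w / wn
    tt <- drop(Xc %*% w)
    for (it in seq_len(maxit)) {      # converges first pass for univariate y
      w_new <- drop(crossprod(Xc, yc))
      w_new <- w_new / sqrt(sum(w_new^2))
      t_new <- drop(Xc %*% w_new)
      if (sqrt(sum((t_new - tt)^2)) < tol * max(1, sqrt(sum(tt^2)))) {
        w <- w_new; tt <- t_new; break
      }
      w <- w_new; tt <- t_new
      if (it == maxit) warning("NIPALS component ", a, " did not converge")
    }
    tsq <- sum(tt^2)
    if (tsq < 1e-28) break
    pvec <- drop(crossprod(Xc, tt)) / tsq
    qa <- sum(yc * tt) / tsq
    Xc <- Xc - tcrossprod(tt, pvec)
    yc <- yc - tt * qa
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa; Tsc[, a] <- tt
    achieved <- a
  }
  if (achieved == 0L) {
    stop("no PLS component could be extracted (X'y is numerically zero)",
         call. = FALSE)
  }
  if (achieved < rank) {
    message("PLS1: requested rank ", rank, ", achieved rank ", achieved,
            " (X/y exhausted)")
    W <- W[, seq_len(achieved), drop = FALSE]
    P <- P[, seq_len(achieved), drop = FALSE]
    Tsc <- Tsc[, seq_len(achieved), drop = FALSE]
    q <- q[seq_len(achieved)]
  }
  # coefficients for every nested rank 1..achieved
  B <- matrix(0, p, achieved)
  for (a in seq_len(achieved)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)])
  }
  structure(list(
    xmeans = xmeans, ymean = ymean,
    W = W, P = P, q = q, Tscores = Tsc, B = B,
    intercepts = ymean - drop(crossprod(xmeans, B)),
    rank = achieved, n = n, p = p
  ), class = "pls1_model")
}

#' Predict concentrations from a PLS1 model
#'
#' @param object A `pls1_model`.
#' @param newdata Matrix of preprocessed spectra (rows) on the training grid,
#'   or a single spectrum vector.
#' @param rank Number of latent variables to use (default: the model's rank).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls1_model <- function(object, newdata, rank = object$rank, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != object$p) {
    stop("newdata has ", ncol(newdata), " channels; model was trained on ",
         object$p, call. = FALSE)
  }
  if (rank < 1L || rank > object$rank) {
    stop("rank must be in 1..", object$rank, call. = FALSE)
  }
  drop(newdata %*% object$B[, rank]) + object$intercepts[rank]
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("<pls1_model: rank %d, %d channels, n = %d>\n",
              x$rank, x$p, x$n))
  invisible(x)
}

#' Select the PLS rank by grouped k-fold cross-validation
#'
#' Runs grouped, concentration-stratified k-fold cross-validation (see
#' [kfold_cv()]) for every rank from 1 to `max_rank` and returns the rank
#' minimising RMSECV, with ties broken toward the smaller rank. All replicate
#' scans of a sample are kept in the same fold.
#'
#' @param X Preprocessed spectra matrix.
#' @param y Reference concentrations.
#' @param sample_ids Sample identifier per row (replicates share an id).
#' @param k Number of folds (default 5).
#' @param max_rank Largest rank tried (default 10).
#' @param seed Integer seed for the fold assignment.
#' @return Integer rank; the per-rank RMSECV profile is attached as attribute
#'   `"rmsecv"`.
#' @export
select_rank <- function(X, y, sample_ids = seq_len(nrow(X)), k = 5L,
                        max_rank = 10L, seed = 1L) {
  if (max_rank < 1L) stop("max_rank must be >= 1", call. = FALSE)
  cvp <- cv_predictions(X, y, sample_ids, k = k, max_rank = max_rank,
                        seed = seed)
  rmse <- sqrt(colMeans((cvp - y)^2))
  best <- which.min(rmse)   # which.min returns the first (smallest) index on ties
  structure(as.integer(best), rmsecv = rmse)
}

# out-of-fold predictions for ranks 1..max_rank; one PLS fit per fold at
# max_rank, nested-rank predictions read off the coefficient columns
cv_predictions <- function(X, y, sample_ids, k, max_rank, seed) {
  X <- as.matrix(X)
  folds <- make_folds(sample_ids, y, k = k, seed = seed)
  preds <- matrix(NA_real_, nrow(X), max_rank)
  for (f in seq_len(k)) {
    hold <- folds == f
    # probing up to max_rank may exhaust the data rank; that is expected here
    fit <- suppressMessages(
      fit_pls1(X[!hold, , drop = FALSE], y[!hold],
               rank = min(max_rank, sum(!hold) - 1L, ncol(X))))
    for (a in seq_len(max_rank)) {
      preds[hold, a] <- predict(fit, X[hold, , drop = FALSE],
                                rank = min(a, fit$rank))
    }
  }
  preds
}

# grouped, stratified fold assignment: samples (not scans) are ordered by
# their mean y, then fold labels are assigned within consecutive blocks of k
# samples in a seeded random order — every fold sees the whole concentration
# range, and all replicates of a sample land in one fold
make_folds <- function(sample_ids, y, k, seed) {
  ids <- unique(sample_ids)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > length(ids)) {
    stop("more folds (", k, ") than distinct samples (", length(ids), ")",
         call. = FALSE)
  }
  ymean <- vapply(ids, function(i) mean(y[sample_ids == i]), numeric(1))
  ord <- order(ymean, as.character(ids))       # deterministic tie-break
  fold_of <- with_seed(seed, {
    fo <- integer(length(ids))
    for (b in seq_len(ceiling(length(ids) / k))) {
      idx <- ((b - 1L) * k + 1L):min(b * k, length(ids))
      fo[ord[idx]] <- sample(k)[seq_along(idx)]
    }
    fo
  })
  fold_of[match(sample_ids, ids)]
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
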