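#' Standard normal variate (SNV)
#'
#' Centres and scales each spectrum to zero mean and unit standard deviation
#' across its own wavenumber channels. SNV removes, per spectrum, any additive
#' offset and multiplicative scaling — the dominant scatter artefacts of
#' diffuse-reflectance FT-NIR on powders.
#'
#' @param x Numeric vector (one spectrum) or matrix with one spectrum per row.
#' @return Transformed vector or matrix of the same shape.
#' @examples
#' snv(c(1, 2, 3))
#' @export
snv <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, snv)))
  if (length(x) < 2L) stop("SNV needs at least 2 points", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("SNV undefined for a constant spectrum", call. = FALSE)
  (x - mean(x)) / s
}

#' Multiplicative scatter correction (MSC)
#'
#' Regresses each spectrum on a reference spectrum by ordinary least squares
#' (intercept + slope) and returns `(spectrum - intercept) / slope`. The
#' reference defaults to the mean spectrum of the supplied set; at prediction
#' time the reference stored during calibration must be reused (see
#' [fit_chain()]).
#'
#' @param x Numeric matrix (spectra in rows) or a single spectrum vector.
#' @param reference Reference spectrum on the same grid, or `"mean"` to use
#'   the row mean of `x`.
#' @return Corrected matrix (or vector), with the reference attached as
#'   attribute `"reference"`.
#' @export
msc <- function(x, reference = "mean") {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (identical(reference, "mean")) {
    if (nrow(x) < 2L) {
      stop("MSC with reference = 'mean' needs at least 2 spectra", call. = FALSE)
    }
    reference <- colMeans(x)
  }
  if (length(reference) != ncol(x)) {
    stop("MSC reference is not on the same grid as the spectra", call. = FALSE)
  }
  if (sd(reference) == 0) stop("MSC reference must not be constant", call. = FALSE)
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  out <- x
  for (i in seq_len(nrow(x))) {
    slope <- sum(rc * (x[i, ] - mean(x[i, ]))) / denom
    if (abs(slope) < 1e-12) {
      stop("MSC slope ~ 0 for spectrum ", i, "; cannot correct", call. = FALSE)
    }
    intercept <- mean(x[i, ]) - slope * mean(reference)
    out[i, ] <- (x[i, ] - intercept) / slope
  }
  if (vec) out <- drop(out)
  attr(out, "reference") <- reference
  out
}

#' Savitzky-Golay first derivative
#'
#' First derivative with respect to channel index using a Savitzky-Golay
#' polynomial filter ([signal::sgolayfilt()]). Output has the same length as
#' the input: the filter's asymmetric end rows extend the local polynomial fit
#' to the edges, so downstream window masks stay aligned with the grid.
#'
#' @param x Numeric vector or matrix (spectra in rows).
#' @param window Odd filter length, default 17 channels.
#' @param polyorder Polynomial order, default 2; must be `< window`.
#' @return Derivative spectrum/spectra, same shape as `x`.
#' @export
first_derivative <- function(x, window = 17L, polyorder = 2L) {
  if (is.matrix(x)) {
    return(t(apply(x, 1, first_derivative, window = window, polyorder = polyorder)))
  }
  if (window %% 2L == 0L) stop("derivative window must be odd", call. = FALSE)
  if (window > length(x)) {
    stop("derivative window (", window, ") exceeds spectrum length (",
         length(x), ")", call. = FALSE)
  }
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  signal::sgolayfilt(x, p = polyorder, n = window, m = 1L)
}

#' Euclidean vector normalisation
#'
#' Scales a spectrum to unit Euclidean norm, preserving direction; used with
#' the first derivative in the Cy3XFGG chain.
#'
#' @param x Numeric vector or matrix (spectra in rows).
#' @return Normalised vector/matrix.
#' @export
vector_normalize <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, vector_normalize)))
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("cannot normalise a zero spectrum", call. = FALSE)
  x / nrm
}

#' Restrict spectra to wavenumber windows
#'
#' Keeps the grid points falling inside any of the supplied closed intervals
#' (cm^-1), preserving order.
#'
#' @param x Matrix (spectra in rows) or vector.
#' @param grid Wavenumber vector (cm^-1) matching the columns of `x`.
#' @param windows Two-column matrix or list of `c(lo, hi)` pairs.
#' @return List with `x` (restricted spectra), `grid` (restricted grid) and
#'   the logical `mask` used.
#' @export
select_windows <- function(x, grid, windows) {
  mask <- window_mask(grid, windows)
  if (!any(mask)) stop("windows select zero grid points", call. = FALSE)
  if (is.matrix(x)) {
    list(x = x[, mask, drop = FALSE], grid = grid[mask], mask = mask)
  } else {
    list(x = x[mask], grid = grid[mask], mask = mask)
  }
}

window_mask <- function(grid, windows) {
  windows <- as_window_matrix(windows)
  mask <- rep(FALSE, length(grid))
  for (i in seq_len(nrow(windows))) {
    mask <- mask | (grid >= windows[i, 1] & grid <= windows[i, 2])
  }
  mask
}

as_window_matrix <- function(windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2L)
  if (!nrow(windows)) stop("empty window list", call. = FALSE)
  if (any(windows[, 1] >= windows[, 2])) {
    stop("each window must satisfy lo < hi", call. = FALSE)
  }
  windows
}

# ---- preprocessing chains ----------------------------------------------

#' Build a preprocessing chain
#'
#' A chain is an ordered list of operator descriptors applied before PLS1
#' calibration. Supported steps: `"snv"`, `"msc"`, `"derivative"` (options
#' `window`, `polyorder`), `"vecnorm"`, and `"windows"` (option `windows`, a
#' list of `c(lo, hi)` cm^-1 intervals). At most one window step is allowed
#' and it is always applied last.
#'
#' @param ... Step descriptors: bare strings for parameter-free steps, or
#'   `list(op = "derivative", window = 17, polyorder = 2)` style lists.
#' @param analyte Optional analyte name the chain serves.
#' @return Object of class `preprocess_chain`.
#' @examples
#' preprocess_chain("snv", list(op = "windows",
#'                              windows = list(c(8925.6, 12489.7))))
#' @export
preprocess_chain <- function(..., analyte = NA_character_) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) s <- list(op = s)
    stopifnot(is.list(s), !is.null(s$op))
    s
  })
  ops <- vapply(steps, `[[`, "", "op")
  known <- c("snv", "msc", "derivative", "vecnorm", "windows")
  if (any(!ops %in% known)) {
    stop("unknown preprocessing op: ", paste(setdiff(ops, known), collapse = ", "),
         call. = FALSE)
  }
  nw <- sum(ops == "windows")
  if (nw > 1L) stop("at most one window-selection step per chain", call. = FALSE)
  if (nw == 1L && ops[length(ops)] != "windows") {
    stop("window selection must be the last step of a chain", call. = FALSE)
  }
  for (s in steps[ops == "derivative"]) {
    w <- s$window %||% 17L
    p <- s$polyorder %||% 2L
    if (w %% 2L == 0L || w < p + 2L) {
      stop("derivative window must be odd and >= polyorder + 2", call. = FALSE)
    }
  }
  structure(list(analyte = analyte, steps = steps, fitted = FALSE),
            class = "preprocess_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a chain on calibration spectra
#'
#' Applies the chain to the calibration set and freezes every data-dependent
#' statistic it needs at prediction time (the MSC reference spectrum and the
#' window mask), so that new spectra are always transformed with
#' calibration-set statistics, never their own.
#'
#' @param chain A [preprocess_chain()].
#' @param x Calibration spectra matrix (spectra in rows).
#' @param grid Wavenumber vector matching `ncol(x)`.
#' @return The fitted chain, with the transformed matrix in `$x` and the
#'   (possibly restricted) grid in `$grid`.
#' @export
fit_chain <- function(chain, x, grid) {
  stopifnot(inherits(chain, "preprocess_chain"), is.matrix(x),
            length(grid) == ncol(x))
  for (i in seq_along(chain$steps)) {
    s <- chain$steps[[i]]
    switch(s$op,
      snv = { x <- snv(x) },
      vecnorm = { x <- vector_normalize(x) },
      derivative = {
        x <- first_derivative(x, s$window %||% 17L, s$polyorder %||% 2L)
      },
      msc = {
        x <- msc(x, reference = s$reference %||% "mean")
        chain$steps[[i]]$reference <- attr(x, "reference")
        attr(x, "reference") <- NULL
      },
      windows = {
        sel <- select_windows(x, grid, s$windows)
        x <- sel$x; grid <- sel$grid
        chain$steps[[i]]$mask <- sel$mask
      })
  }
  chain$fitted <- TRUE
  chain$x <- x
  chain$grid <- grid
  chain
}

#' Apply a fitted chain to new spectra
#'
#' @param chain A chain returned by [fit_chain()].
#' @param x New spectra matrix on the chain's original full grid.
#' @return Transformed matrix on the chain's retained grid.
#' @export
apply_chain <- function(chain, x) {
  stopifnot(inherits(chain, "preprocess_chain"))
  if (!isTRUE(chain$fitted)) stop("chain has not been fitted", call. = FALSE)
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  for (s in chain$steps) {
    switch(s$op,
      snv = { x <- snv(x) },
      vecnorm = { x <- vector_normalize(x) },
      derivative = {
        x <- first_derivative(x, s$window %||% 17L, s$polyorder %||% 2L)
      },
      msc = {
        x <- msc(x, reference = s$reference)
        attr(x, "reference") <- NULL
      },
      windows = { x <- x[, s$mask, drop = FALSE] })
  }
  x
}

#' @export
print.preprocess_chain <- function(x, ...) {
  ops <- vapply(x$steps, `[[`, "", "op")
  cat("<preprocess_chain", if (!is.na(x$analyte)) paste0("[", x$analyte, "]"),
      paste(ops, collapse = " -> "),
      if (isTRUE(x$fitted)) sprintf("(fitted, %d channels)", length(x$grid)),
      "\n")
  invisible(x)
}

#' Default per-analyte preprocessing chains
#'
#' The operator chains and analyte-correlated wavenumber windows used for the
#' ten modelled responses. Totals and individual anthocyanins use SNV with
#' their reported windows; Cy3XFGG uses first derivative + vector
#' normalisation; total phenolic acids use first derivative + MSC; chlorogenic
#' and caffeic acid use first derivative + SNV. Operator order is fixed as
#' derivative, then scatter correction, then window restriction.
#'
#' @param analytes Which analytes to return chains for (default all ten).
#' @return Named list of [preprocess_chain()] objects.
#' @export
default_chains <- function(analytes = analyte_names()) {
  W <- function(...) list(op = "windows", windows = list(...))
  acn_win <- W(c(8925.6, 12489.7), c(4482.1, 7159))
  chains <- list(
    "Total_ACN"  = preprocess_chain("snv", acn_win, analyte = "Total_ACN"),
    "Total_AcA"  = preprocess_chain("snv", acn_win, analyte = "Total_AcA"),
    "Total_PHEN" = preprocess_chain(list(op = "derivative"), "msc",
                                    W(c(4597.8, 9403.9)), analyte = "Total_PHEN"),
    "Cy3XSGG"    = preprocess_chain("snv",
                                    W(c(9820.5, 10715.5), c(4482.1, 6264.1)),
                                    analyte = "Cy3XSGG"),
    "Cy3XFGG"    = preprocess_chain(list(op = "derivative"), "vecnorm",
                                    W(c(8925.6, 12489.7), c(7151.3, 8046.2),
                                      c(5369.2, 6264.1)), analyte = "Cy3XFGG"),
    "Cy3XCGG"    = preprocess_chain("snv",
                                    W(c(11594.8, 12489.7), c(7151.3, 10715.4),
                                      c(4482.1, 5377)), analyte = "Cy3XCGG"),
    "Cy3XG"      = preprocess_chain("snv",
                                    W(c(11594.8, 12489.7), c(8038.4, 10715.4)),
                                    analyte = "Cy3XG"),
    "Cy3XGG"     = preprocess_chain("snv",
                                    W(c(11594.8, 12489.7), c(8038.4, 10715.4)),
                                    analyte = "Cy3XGG"),
    "3CQA"       = preprocess_chain(list(op = "derivative"), "snv",
                                    W(c(6819.6, 9403.9), c(3610.4, 4242.9)),
                                    analyte = "3CQA"),
    "CA"         = preprocess_chain(list(op = "derivative"), "snv",
                                    W(c(8887, 9403.9), c(7336.4, 7861),
                                      c(4752.9, 6827.3)), analyte = "CA")
  )
  chains[analytes]
}
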