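#' Degree of acylation
#'
#' Percentage of the cyanidin pool carrying an aromatic acyl group:
#' `100 * AcA / (AcA + NAA)` by concentration. Undefined (NA) when both pools
#' are zero.
#'
#' @param aca Acylated anthocyanin concentration(s), >= 0.
#' @param naa Non-acylated anthocyanin concentration(s), >= 0.
#' @return Percentage(s) in `[0, 100]`, vectorised.
#' @examples
#' degree_of_acylation(900, 100)
#' @export
degree_of_acylation <- function(aca, naa) {
  if (any(aca < 0, na.rm = TRUE) || any(naa < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  total <- aca + naa
  out <- 100 * aca / total
  out[total == 0] <- NA_real_
  out
}

#' Per-sample anthocyanin composition table
#'
#' Degree of acylation and each pigment's percentage share of total
#' anthocyanin. Samples whose total ACN falls below `floor` (trace /
#' non-detected material) get NA shares and are thereby excluded from
#' downstream percentage and correlation computations.
#'
#' @param profiles A `metabolite_table`.
#' @param floor Detection floor on total ACN (ug/100 g dw), default 1.
#' @return Data frame with `sample_id`, `phenotype`, `pct_acylation` and one
#'   `pct_*` column per pigment; shares sum to 100 where defined.
#' @export
composition_table <- function(profiles, floor = 1) {
  pig <- as.matrix(profiles[, pigment_names(), drop = FALSE])
  total <- rowSums(pig)
  ok <- total >= floor & total > 0
  shares <- 100 * sweep(pig, 1L, total, "/")
  shares[!ok, ] <- NA_real_
  acyl <- degree_of_acylation(rowSums(pig[, 1:3, drop = FALSE]),
                              rowSums(pig[, 4:5, drop = FALSE]))
  acyl[!ok] <- NA_real_
  colnames(shares) <- paste0("pct_", pigment_names())
  data.frame(sample_id = profiles$sample_id, phenotype = profiles$phenotype,
             pct_acylation = acyl, shares,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation and its two-sided p-value from the
#' t-distribution with n-2 degrees of freedom (via [stats::cor.test()]).
#' Incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return List with elements `r`, `p` and `n`.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Principal component summary of a metabolite/phenotype matrix
#'
#' Centred (optionally unit-variance scaled) PCA via singular value
#' decomposition ([stats::prcomp()]).
#'
#' @param x Numeric matrix or data frame of numeric columns, samples in rows.
#' @param scale Scale columns to unit variance? Default `FALSE`.
#' @return List with `variance_explained` (percentages summing to 100),
#'   `loadings` (rotation matrix) and `scores`.
#' @export
pca_summary <- function(x, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  }
  if (anyNA(x)) stop("missing values are not allowed", call. = FALSE)
  pc <- prcomp(x, center = TRUE, scale. = scale)
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  list(variance_explained = ve, loadings = pc$rotation, scores = pc$x)
}

#' Colour density and hue of a pigment extract
#'
#' Colour density `CD = (A420 - A700) + (A520 - A700)` measures colour
#' intensity (oxidised plus non-oxidised anthocyanin); hue
#' `H = (A520 - A700) / (A420 - A700)` indexes browning/oxidation (lower
#' means browner). Hue is undefined (NA) when `A420 == A700`.
#'
#' @param a420,a520,a700 Absorbances at 420, 520 and 700 nm (>= 0),
#'   vectorised.
#' @return Numeric vector.
#' @examples
#' color_density(0.5, 1.0, 0.1)   # 1.3
#' hue(0.5, 1.0, 0.1)             # 2.25
#' @export
color_density <- function(a420, a520, a700) {
  check_absorbances(a420, a520, a700)
  (a420 - a700) + (a520 - a700)
}

#' @rdname color_density
#' @export
hue <- function(a420, a520, a700) {
  check_absorbances(a420, a520, a700)
  denom <- a420 - a700
  out <- (a520 - a700) / denom
  out[denom == 0] <- NA_real_
  out
}

check_absorbances <- function(a420, a520, a700) {
  if (any(c(a420, a520, a700) < 0, na.rm = TRUE)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Extraction efficiency
#'
#' Concentration in the steeped colour extract as a percentage of the
#' concentration in the freeze-dried puree. Values above 100 % are possible
#' under measurement noise; they are kept but flagged via the
#' `"over_100"` attribute.
#'
#' @param extract_conc Extract concentration(s), >= 0.
#' @param puree_conc Puree concentration(s), > 0.
#' @return Percentage(s), with attribute `over_100` (logical vector).
#' @export
extraction_efficiency <- function(extract_conc, puree_conc) {
  if (any(puree_conc <= 0)) {
    stop("puree concentration must be > 0", call. = FALSE)
  }
  if (any(extract_conc < 0)) {
    stop("extract concentration must be >= 0", call. = FALSE)
  }
  out <- 100 * extract_conc / puree_conc
  attr(out, "over_100") <- out > 100
  out
}

#' Per-group summary of a metabolite table
#'
#' Mean, median, minimum and maximum of each analyte within each phenotype
#' group, groups ordered by code.
#'
#' @param profiles A `metabolite_table`.
#' @param analytes Analyte columns to summarise (default all ten).
#' @return Long-format data frame: `phenotype`, `analyte`, `n`, `mean`,
#'   `median`, `min`, `max`.
#' @export
group_summary <- function(profiles, analytes = analyte_names()) {
  analytes <- intersect(analytes, names(profiles))
  codes <- sort(unique(profiles$phenotype))
  out <- do.call(rbind, lapply(codes, function(cd) {
    sub <- profiles[profiles$phenotype == cd, , drop = FALSE]
    do.call(rbind, lapply(analytes, function(a) {
      v <- sub[[a]]
      data.frame(phenotype = cd, analyte = a, n = length(v),
                 mean = mean(v), median = median(v),
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
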