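#' Parameters of one phenotype group of the synthetic cohort
#'
#' Describes the concentration law of one binary root-colour phenotype group.
#' Per-sample totals are log-normal (mean parameterised directly, so the
#' configured `acn_mean` is the expected group mean); total cyanidin mass is
#' split into acylated/non-acylated fractions by a Beta draw, the acylated
#' mass among Cy3XSGG/Cy3XFGG/Cy3XCGG by a Dirichlet draw, and the
#' non-acylated mass between Cy3XG and Cy3XGG by a second Beta draw. Total
#' phenolic acids share a latent log-scale factor with total anthocyanins
#' (loading `phen_link`), which is what produces the cohort-level PHEN-ACN
#' correlation.
#'
#' @param code 4-bit phenotype code (e.g. `":1111"`).
#' @param n Number of samples to draw for the group.
#' @param acn_mean Expected total anthocyanin concentration (ug/100 g dw).
#' @param acyl_mean Expected acylated fraction of total ACN (0-1).
#' @param phen_mean Expected total phenolic acid concentration (ug/100 g dw).
#' @param acn_sdlog,phen_sdlog Log-scale standard deviations of the totals.
#' @param acyl_kappa Beta concentration of the acylated-fraction draw.
#' @param naa_g_mean Expected share of the non-acylated mass that is Cy3XG.
#' @param naa_kappa Beta concentration of the Cy3XG share draw.
#' @param aca_alpha Dirichlet shape vector (Cy3XSGG, Cy3XFGG, Cy3XCGG).
#' @param phen_split_alpha Dirichlet shape vector (3CQA, CA, other phenolics).
#' @param phen_link Latent-factor loading (0-1) tying log PHEN to log ACN.
#' @return Object of class `phenotype_group_params`.
#' @export
group_params <- function(code, n, acn_mean, acyl_mean, phen_mean,
                         acn_sdlog = 0.65, phen_sdlog = 0.45,
                         acyl_kappa = 12, naa_g_mean = 0.862, naa_kappa = 1.5,
                         aca_alpha = c(1.00, 0.95, 0.05),
                         phen_split_alpha = c(0.87, 0.06, 0.07) * 50,
                         phen_link = 0.37) {
  parse_phenotype(code)   # validates; errors on a malformed code
  if (n < 0) stop("n must be >= 0", call. = FALSE)
  if (acn_mean <= 0 || phen_mean <= 0 || acn_sdlog <= 0 || phen_sdlog <= 0) {
    stop("location/scale parameters must be > 0", call. = FALSE)
  }
  if (acyl_mean <= 0 || acyl_mean >= 1 || naa_g_mean <= 0 || naa_g_mean >= 1) {
    stop("fraction means must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (acyl_kappa <= 0 || naa_kappa <= 0 || any(aca_alpha <= 0) ||
      any(phen_split_alpha <= 0)) {
    stop("Beta/Dirichlet shape parameters must be > 0", call. = FALSE)
  }
  if (abs(phen_link) > 1) stop("phen_link must be in [-1, 1]", call. = FALSE)
  structure(list(code = format(parse_phenotype(code)), n = as.integer(n),
                 acn_mean = acn_mean, acyl_mean = acyl_mean,
                 phen_mean = phen_mean, acn_sdlog = acn_sdlog,
                 phen_sdlog = phen_sdlog, acyl_kappa = acyl_kappa,
                 naa_g_mean = naa_g_mean, naa_kappa = naa_kappa,
                 aca_alpha = aca_alpha, phen_split_alpha = phen_split_alpha,
                 phen_link = phen_link),
            class = "phenotype_group_params")
}

#' Default parameters for the seven phenotype groups
#'
#' The default cohort: 461 samples, of which 165 are purple in at least one
#' tissue, across the seven observed phenotype combinations. Group means of
#' total anthocyanins, degree of acylation and total phenolic acids are
#' anchored at the reported group summaries (fully purple roots averaging
#' 1799.7 ug/100 g dw total ACN with 69.5 % acylation; purple-periderm-only
#' roots 94.6 % acylation; phenolic acids peaking at 308.2 ug/100 g dw in
#' the :1101 group and lowest, 69 ug/100 g dw, in :1000); unreported
#' intermediate group means are interpolated between those anchors.
#'
#' @return Named list of [group_params()] objects, ordered by code.
#' @export
default_group_params <- function() {
  gp <- list(
    group_params(":1111", 60, acn_mean = 1799.7, acyl_mean = 0.695,
                 phen_mean = 280),
    group_params(":1110", 25, acn_mean = 1100,   acyl_mean = 0.80,
                 phen_mean = 230),
    group_params(":1101", 15, acn_mean = 950,    acyl_mean = 0.82,
                 phen_mean = 308.2),
    group_params(":1100", 30, acn_mean = 550,    acyl_mean = 0.86,
                 phen_mean = 200),
    group_params(":1001", 10, acn_mean = 300,    acyl_mean = 0.90,
                 phen_mean = 150),
    group_params(":1000", 25, acn_mean = 130,    acyl_mean = 0.946,
                 phen_mean = 69),
    group_params(":0000", 296, acn_mean = 0.5,   acyl_mean = 0.60,
                 phen_mean = 170, acn_sdlog = 0.8)
  )
  names(gp) <- vapply(gp, `[[`, "", "code")
  gp
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic metabolite table
#'
#' Draws per-sample concentrations of the ten modelled responses for the
#' supplied phenotype groups. `Total_ACN` is by construction the sum of the
#' five cyanidin glycosides and `Total_AcA` the sum of the three acylated
#' ones; pigment draws below the detection floor are zeroed (the
#' detection-limit behaviour of trace analytes in non-purple roots) and the
#' totals recomputed. Deterministic given `seed`.
#'
#' @param groups List of [group_params()]; default [default_group_params()].
#' @param seed Integer seed.
#' @param detection_floor Concentration (ug/100 g dw) below which an
#'   individual pigment is recorded as 0. Default 0.05.
#' @return A `metabolite_table`: data frame with `sample_id`, `phenotype`,
#'   the five pigments, `3CQA`, `CA`, `Total_ACN`, `Total_AcA`, `Total_NAA`
#'   and `Total_PHEN`.
#' @examples
#' head(generate_metabolite_profiles(seed = 1))
#' @export
generate_metabolite_profiles <- function(groups = default_group_params(),
                                         seed = 1L, detection_floor = 0.05) {
  for (g in groups) {
    if (!inherits(g, "phenotype_group_params")) {
      stop("groups must be a list of group_params() objects", call. = FALSE)
    }
  }
  with_seed(seed, {
    rows <- vector("list", length(groups))
    offset <- 0L
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      n <- g$n
      if (n == 0L) next
      z <- rnorm(n)                         # shared latent factor
      eta <- rnorm(n)
      acn <- exp(log(g$acn_mean) - g$acn_sdlog^2 / 2 + g$acn_sdlog * z)
      phen <- exp(log(g$phen_mean) - g$phen_sdlog^2 / 2 +
                    g$phen_sdlog * (g$phen_link * z +
                                      sqrt(1 - g$phen_link^2) * eta))
      a <- rbeta(n, g$acyl_mean * g$acyl_kappa,
                 (1 - g$acyl_mean) * g$acyl_kappa)
      v <- rdirichlet(n, g$aca_alpha)       # within-AcA split
      wg <- rbeta(n, g$naa_g_mean * g$naa_kappa,
                  (1 - g$naa_g_mean) * g$naa_kappa)
      ps <- rdirichlet(n, g$phen_split_alpha)
      pig <- cbind(
        Cy3XSGG = acn * a * v[, 1],
        Cy3XFGG = acn * a * v[, 2],
        Cy3XCGG = acn * a * v[, 3],
        Cy3XG   = acn * (1 - a) * wg,
        Cy3XGG  = acn * (1 - a) * (1 - wg)
      )
      pig[pig < detection_floor] <- 0
      df <- data.frame(
        sample_id = sprintf("S%03d", offset + seq_len(n)),
        phenotype = g$code,
        pig,
        `3CQA` = phen * ps[, 1],
        CA = phen * ps[, 2],
        PHEN_other = phen * ps[, 3],
        Total_ACN = rowSums(pig),
        Total_AcA = rowSums(pig[, 1:3, drop = FALSE]),
        Total_NAA = rowSums(pig[, 4:5, drop = FALSE]),
        Total_PHEN = phen,
        check.names = FALSE, stringsAsFactors = FALSE
      )
      offset <- offset + n
      rows[[gi]] <- df
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("metabolite_table", "data.frame")
    out
  })
}

#' Default purple calibration cohort
#'
#' The purple subset of the default cohort (all groups except `:0000`),
#' rescaled to a requested total size with the default group proportions —
#' the sample set on which FT-NIR calibrations are built, since only purple
#' roots carry quantifiable anthocyanin.
#'
#' @param n_samples Total number of purple samples (default 160).
#' @param seed Integer seed.
#' @param ... Passed on to [generate_metabolite_profiles()].
#' @return A `metabolite_table`.
#' @export
generate_purple_cohort <- function(n_samples = 160L, seed = 1L, ...) {
  gp <- default_group_params()
  gp <- gp[names(gp) != ":0000"]
  n0 <- vapply(gp, `[[`, 1L, "n")
  n <- floor(n0 / sum(n0) * n_samples)
  rem <- n_samples - sum(n)
  if (rem > 0) {   # hand leftovers to the largest groups, deterministically
    add <- order(n0 / sum(n0) * n_samples - n, decreasing = TRUE)[seq_len(rem)]
    n[add] <- n[add] + 1L
  }
  for (i in seq_along(gp)) gp[[i]]$n <- as.integer(n[i])
  generate_metabolite_profiles(groups = gp, seed = seed, ...)
}

# ---- spectra -----------------------------------------------------------

#' Default FT-NIR wavenumber grid
#'
#' Ascending wavenumber grid from 3594 to 12489.7 cm^-1. The default spacing
#' of 7.7 cm^-1 (1156 points) is the digitisation step used throughout the
#' package; the instrument scan range fixes only the end points.
#'
#' @param from,to Grid limits in cm^-1.
#' @param by Spacing in cm^-1.
#' @return Numeric vector.
#' @export
nir_grid <- function(from = 3594, to = 12489.7, by = 7.7) {
  seq(from, to, by = by)
}

#' Evaluate pure-component spectra as Gaussian band superpositions
#'
#' @param components Named list: per analyte, a numeric matrix with columns
#'   `center` (cm^-1), `width` (Gaussian sigma, cm^-1) and `amp`
#'   (absorbance per unit concentration), one row per band. A zero-row
#'   matrix yields an all-zero spectrum.
#' @param grid Strictly increasing wavenumber vector.
#' @return Matrix, one row per analyte, one column per grid point.
#' @export
simulate_pure_spectra <- function(components, grid) {
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  out <- matrix(0, length(components), length(grid),
                dimnames = list(names(components), NULL))
  for (i in seq_along(components)) {
    b <- components[[i]]
    if (is.null(dim(b))) b <- matrix(b, ncol = 3L)
    if (!nrow(b)) next
    colnames(b) <- c("center", "width", "amp")
    if (any(b[, "center"] < min(grid) | b[, "center"] > max(grid))) {
      stop("band center outside grid range for component ",
           names(components)[i] %||% i, call. = FALSE)
    }
    if (any(b[, "width"] <= 0) || any(b[, "amp"] < 0)) {
      stop("band widths must be > 0 and amplitudes >= 0", call. = FALSE)
    }
    for (j in seq_len(nrow(b))) {
      out[i, ] <- out[i, ] +
        b[j, "amp"] * exp(-0.5 * ((grid - b[j, "center"]) / b[j, "width"])^2)
    }
  }
  out
}

#' Default pure-component band set and shared matrix background
#'
#' Each analyte carries 2-4 Gaussian bands centred inside its
#' analyte-correlated wavenumber windows; a shared background of broad
#' water/carbohydrate matrix bands, common to all samples, is roughly ten
#' times stronger than a typical analyte contribution. Amplitudes are per
#' unit concentration (ug/100 g dw).
#'
#' @param grid Wavenumber vector (default [nir_grid()]).
#' @return Object of class `pure_components`: list with the analyte `bands`
#'   list, the evaluated `components` matrix, the `background` spectrum and
#'   the `grid`.
#' @export
default_pure_components <- function(grid = nir_grid()) {
  B <- function(...) matrix(c(...), ncol = 3L, byrow = TRUE)
  bands <- list(
    Cy3XSGG = B(10200, 180, 1.0e-4,  9950, 120, 0.7e-4,  5300, 150, 0.8e-4),
    Cy3XFGG = B(11800, 200, 1.0e-4,  7600, 150, 0.7e-4,  5800, 140, 0.8e-4),
    Cy3XCGG = B(12000, 180, 1.0e-4,  8800, 160, 0.8e-4,  4900, 130, 0.9e-4),
    Cy3XG   = B(11900, 150, 0.9e-4,  9400, 170, 1.0e-4,  8200, 140, 0.6e-4),
    Cy3XGG  = B(12200, 160, 1.0e-4, 10100, 150, 0.9e-4,  8600, 130, 0.7e-4),
    `3CQA`  = B( 7100, 150, 2.5e-4,  9100, 160, 2.0e-4,  3900, 120, 2.0e-4),
    CA      = B( 9200, 120, 1.5e-3,  7700, 130, 1.2e-3,  5500, 140, 1.3e-3),
    PHEN_other = B(8700, 150, 1.2e-3, 6500, 160, 1.0e-3, 4800, 140, 1.0e-3)
  )
  matrix_bands <- B(6900, 400, 0.45, 5200, 300, 0.55, 4400, 250, 0.35,
                    8500, 600, 0.15, 10500, 1500, 0.05)
  comp <- simulate_pure_spectra(bands, grid)
  bg <- drop(simulate_pure_spectra(list(matrix = matrix_bands), grid))
  structure(list(bands = bands, components = comp, background = bg,
                 grid = grid),
            class = "pure_components")
}

#' Scatter and noise model for simulated spectra
#'
#' Replicate-level multiplicative slope (mean 1), additive baseline (offset +
#' linear tilt in wavenumber) and white noise, plus a sample-level
#' log-normal jitter of the matrix background amplitude. Defaults emulate
#' benchtop FT-NIR scan-to-scan variability (temperature/humidity drift and
#' detector noise). Set all spreads to zero (see `scatter_off()`) for the
#' exact-linear forward model.
#'
#' @param slope_sd SD of the multiplicative slope around 1.
#' @param offset_mean,offset_sd Baseline offset law (absorbance units).
#' @param tilt_sd SD of the baseline tilt (absorbance per cm^-1).
#' @param noise_sd White-noise SD (absorbance units).
#' @param matrix_jitter_sd Log-scale SD of the per-sample matrix amplitude.
#' @return Object of class `scatter_noise_model`.
#' @export
scatter_noise_model <- function(slope_sd = 0.05, offset_mean = 0.02,
                                offset_sd = 0.01, tilt_sd = 3e-7,
                                noise_sd = 1e-3, matrix_jitter_sd = 0.02) {
  if (noise_sd < 0 || slope_sd < 0 || offset_sd < 0 || tilt_sd < 0 ||
      matrix_jitter_sd < 0) {
    stop("spread parameters must be >= 0", call. = FALSE)
  }
  structure(list(slope_sd = slope_sd, offset_mean = offset_mean,
                 offset_sd = offset_sd, tilt_sd = tilt_sd,
                 noise_sd = noise_sd, matrix_jitter_sd = matrix_jitter_sd),
            class = "scatter_noise_model")
}

#' @rdname scatter_noise_model
#' @export
scatter_off <- function() {
  scatter_noise_model(slope_sd = 0, offset_mean = 0, offset_sd = 0,
                      tilt_sd = 0, noise_sd = 0, matrix_jitter_sd = 0)
}

#' Simulate replicate FT-NIR spectra for a metabolite table
#'
#' Beer-Lambert forward model: for each scan,
#' `A(v) = slope * (sum_k c_k e_k(v) + m * bg(v) + baseline(v)) + noise`,
#' where `e_k` are the unit-concentration pure-component spectra, `bg` the
#' shared matrix background with per-sample amplitude `m`, and slope,
#' baseline and noise are drawn per replicate from the scatter model.
#' Replicates of a sample differ only in those scatter/noise draws. Negative
#' absorbances (possible under extreme baseline draws) are clipped to zero
#' and counted.
#'
#' @param profiles A `metabolite_table` containing the seven mixture
#'   components (five pigments, `3CQA`, `CA`).
#' @param pure A [default_pure_components()]-style object.
#' @param scatter A [scatter_noise_model()].
#' @param replicates Scans per sample (default 3).
#' @param seed Integer seed.
#' @return A `spectra_set`: list with `grid`, absorbance matrix `A` (one scan
#'   per row, named `sample.rep`), `sample_id`, `replicate`, and the clip
#'   count `clipped`.
#' @export
simulate_spectra <- function(profiles, pure = default_pure_components(),
                             scatter = scatter_noise_model(),
                             replicates = 3L, seed = 1L) {
  stopifnot(inherits(pure, "pure_components"),
            inherits(scatter, "scatter_noise_model"))
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  comps <- rownames(pure$components)
  missing_cols <- setdiff(comps, names(profiles))
  if (length(missing_cols)) {
    stop("profiles lack mixture components: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  conc <- as.matrix(profiles[, comps, drop = FALSE])
  if (any(conc < 0)) stop("negative concentrations", call. = FALSE)
  grid <- pure$grid
  p <- length(grid)
  ns <- nrow(conc)
  with_seed(seed, {
    signal_part <- conc %*% pure$components     # ns x p
    m <- exp(rnorm(ns, 0, scatter$matrix_jitter_sd))
    A <- matrix(0, ns * replicates, p)
    sample_id <- character(ns * replicates)
    replicate <- integer(ns * replicates)
    row <- 0L
    for (i in seq_len(ns)) {
      base_i <- signal_part[i, ] + m[i] * pure$background
      for (r in seq_len(replicates)) {
        row <- row + 1L
        slope <- max(1 + rnorm(1, 0, scatter$slope_sd), 0.01)
        offset <- scatter$offset_mean + rnorm(1, 0, scatter$offset_sd)
        tilt <- rnorm(1, 0, scatter$tilt_sd)
        baseline <- offset + tilt * (grid - grid[1])
        A[row, ] <- slope * (base_i + baseline) +
          rnorm(p, 0, scatter$noise_sd)
        sample_id[row] <- as.character(profiles$sample_id[i])
        replicate[row] <- r
      }
    }
    clipped <- sum(A < 0)
    A[A < 0] <- 0
    rownames(A) <- paste0(sample_id, ".", replicate)
    structure(list(grid = grid, A = A, sample_id = sample_id,
                   replicate = replicate, clipped = clipped),
              class = "spectra_set")
  })
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set: %d scans (%d samples) x %d channels, %.1f-%.1f cm^-1>\n",
              nrow(x$A), length(unique(x$sample_id)), length(x$grid),
              min(x$grid), max(x$grid)))
  invisible(x)
}

# ---- extracts ----------------------------------------------------------

#' Parameters of the steeping-extract simulation
#'
#' Mean extraction efficiencies anchor at the reported fully-purple values
#' (Cy3XGG 98 %, Cy3XFGG 82.3 %, Cy3XSGG 79 %, Cy3XCGG 78 %); absorbance
#' response coefficients map extracted pigment concentration to the
#' pigment-specific A520 signal, with Cy3XSGG the strongest chromophore, and
#' a browning term raises A420 independently of pigment.
#'
#' @param eff_mean Named mean efficiencies (%) for the seven components.
#' @param eff_sd Efficiency spread (percentage points).
#' @param a520_coef Named A520 response per extracted ug/100 g dw (pigments).
#' @param a420_ratio Pigment contribution to A420 as a fraction of its A520
#'   contribution.
#' @param browning_mean,browning_sd Browning absorbance at 420 nm.
#' @param a700_mean,a700_sd Haze/turbidity absorbance at 700 nm.
#' @param noise_sd Absorbance measurement noise.
#' @return Object of class `extract_sim_params`.
#' @export
extract_sim_params <- function(
    eff_mean = c(Cy3XSGG = 79, Cy3XFGG = 82.3, Cy3XCGG = 78, Cy3XG = 85,
                 Cy3XGG = 98, `3CQA` = 70, CA = 70),
    eff_sd = 6,
    a520_coef = c(Cy3XSGG = 0.028, Cy3XFGG = 0.018, Cy3XCGG = 0.020,
                  Cy3XG = 0.019, Cy3XGG = 0.021),
    a420_ratio = 0.30, browning_mean = 0.2, browning_sd = 0.08,
    a700_mean = 0.05, a700_sd = 0.02, noise_sd = 0.01) {
  if (any(eff_mean < 0) || any(eff_mean > 110)) {
    stop("mean efficiencies must lie in [0, 110] %", call. = FALSE)
  }
  if (any(a520_coef < 0) || a420_ratio < 0) {
    stop("response coefficients must be >= 0", call. = FALSE)
  }
  if (which.max(a520_coef[pigment_names()]) != 1L) {
    stop("the Cy3XSGG A520 response must be the largest", call. = FALSE)
  }
  structure(list(eff_mean = eff_mean, eff_sd = eff_sd, a520_coef = a520_coef,
                 a420_ratio = a420_ratio, browning_mean = browning_mean,
                 browning_sd = browning_sd, a700_mean = a700_mean,
                 a700_sd = a700_sd, noise_sd = noise_sd),
            class = "extract_sim_params")
}

#' @rdname extract_sim_params
#' @export
extract_noise_off <- function() {
  extract_sim_params(eff_sd = 0, browning_sd = 0, a700_sd = 0, noise_sd = 0)
}

#' Simulate steeping-extract records
#'
#' For each sample, draws per-analyte extraction efficiencies, converts puree
#' concentrations to extract concentrations, and generates the A420/A520/A700
#' absorbance triple from which colour density and hue are computed
#' downstream. `A520 - A700` increases monotonically with the total extracted
#' cyanidin signal. Deterministic given `seed`.
#'
#' @param profiles A `metabolite_table` with the five pigment columns.
#' @param params An [extract_sim_params()].
#' @param seed Integer seed.
#' @return An `extract_records` data frame: absorbances plus per-component
#'   `puree_*`, `extract_*` and `efficiency_*` columns.
#' @export
simulate_extracts <- function(profiles, params = extract_sim_params(),
                              seed = 1L) {
  stopifnot(inherits(params, "extract_sim_params"))
  comps <- names(params$eff_mean)
  missing_cols <- setdiff(comps, names(profiles))
  if (length(missing_cols)) {
    stop("profiles lack components: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  puree <- as.matrix(profiles[, comps, drop = FALSE])
  n <- nrow(puree)
  with_seed(seed, {
    eff <- matrix(rnorm(n * length(comps),
                        mean = rep(params$eff_mean, each = n),
                        sd = params$eff_sd), n, length(comps),
                  dimnames = list(NULL, comps))
    n_neg <- sum(eff < 0)
    if (n_neg) warning(n_neg, " negative efficiency draw(s) clipped to 0")
    eff[eff < 0] <- 0
    eff[eff > 110] <- 110
    extr <- puree * eff / 100
    pig520 <- drop(extr[, names(params$a520_coef), drop = FALSE] %*%
                     params$a520_coef)
    a700 <- abs(rnorm(n, params$a700_mean, params$a700_sd))
    brown <- abs(rnorm(n, params$browning_mean, params$browning_sd))
    a520 <- a700 + pig520 + rnorm(n, 0, params$noise_sd)
    a420 <- a700 + params$a420_ratio * pig520 + brown +
      rnorm(n, 0, params$noise_sd)
    out <- data.frame(sample_id = profiles$sample_id,
                      phenotype = profiles$phenotype,
                      A420 = pmax(a420, 0), A520 = pmax(a520, 0),
                      A700 = a700, check.names = FALSE,
                      stringsAsFactors = FALSE)
    colnames(puree) <- paste0("puree_", comps)
    colnames(extr) <- paste0("extract_", comps)
    colnames(eff) <- paste0("efficiency_", comps)
    out <- cbind(out, puree, extr, eff)
    class(out) <- c("extract_records", "data.frame")
    out
  })
}
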