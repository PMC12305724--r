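#' Default pipeline configuration
#'
#' Settings for the end-to-end workflow: a purple calibration cohort of 160
#' samples scanned in triplicate, 5-fold grouped cross-validation with a rank
#' search up to 10 latent variables, and a 50/100 calibration/validation
#' split for the external check of the total-anthocyanin model.
#'
#' @param seed Master seed; every stage derives its stream from it.
#' @param n_purple Purple cohort size.
#' @param replicates Scans per sample.
#' @param k Cross-validation folds.
#' @param max_rank Rank search bound.
#' @param external_split `c(cal, val)` sample counts for external validation.
#' @param external_analytes Analytes to validate externally.
#' @param analytes Analytes to calibrate.
#' @param scatter A [scatter_noise_model()].
#' @param chains Named list of chains, default [default_chains()].
#' @param out_dir Optional output directory for report files.
#' @return A `run_config` list.
#' @export
default_config <- function(seed = 1L, n_purple = 160L, replicates = 3L,
                           k = 5L, max_rank = 10L,
                           external_split = c(cal = 50L, val = 100L),
                           external_analytes = "Total_ACN",
                           analytes = analyte_names(),
                           scatter = scatter_noise_model(),
                           chains = default_chains(),
                           out_dir = NULL) {
  stopifnot(k >= 2L, all(external_split > 0), all(analytes %in% analyte_names()))
  structure(list(seed = as.integer(seed), n_purple = as.integer(n_purple),
                 replicates = as.integer(replicates), k = as.integer(k),
                 max_rank = as.integer(max_rank),
                 external_split = external_split,
                 external_analytes = external_analytes,
                 analytes = analytes, scatter = scatter, chains = chains,
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  stripped <- config[setdiff(names(config), "out_dir")]
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(rapply(stripped, unclass, how = "replace"), f,
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full calibration pipeline
#'
#' Simulates the purple cohort and its triplicate spectra, fits and
#' cross-validates one PLS1 calibration per analyte behind its default
#' preprocessing chain, externally validates the configured analytes on a
#' disjoint sample split, and computes the downstream composition and
#' colour-extract statistics. Identical config and seed give identical
#' output.
#'
#' @param config A [default_config()] object.
#' @return A report bundle: list with `profiles`, `cv_reports` (one
#'   `validation_report` per analyte), `external_reports`, `ranks`,
#'   `composition`, `group_summary`, `extracts`, `color`, and the
#'   `config_hash`. If `config$out_dir` is set, the per-analyte metric table,
#'   model files and a manifest are written there.
#' @export
run_pipeline <- function(config = default_config()) {
  stopifnot(inherits(config, "run_config"))
  profiles <- generate_purple_cohort(config$n_purple, seed = config$seed)
  pure <- default_pure_components()
  spectra <- simulate_spectra(profiles, pure, config$scatter,
                              replicates = config$replicates,
                              seed = config$seed + 1L)
  scan_of <- match(spectra$sample_id, profiles$sample_id)

  cv_reports <- list()
  models <- list()
  fitted_chains <- list()
  for (an in config$analytes) {
    y <- profiles[[an]][scan_of]
    chain <- fit_chain(config$chains[[an]], spectra$A, spectra$grid)
    Xp <- chain$x
    rep <- kfold_cv(Xp, y, sample_ids = spectra$sample_id, k = config$k,
                    max_rank = config$max_rank, seed = config$seed + 2L,
                    analyte = an)
    chain$x <- NULL
    cv_reports[[an]] <- rep
    fitted_chains[[an]] <- chain
    models[[an]] <- fit_pls1(Xp, y, rank = rep$rank)
  }

  # external validation on a disjoint, seeded sample split
  external_reports <- list()
  ids <- unique(spectra$sample_id)
  need <- sum(config$external_split)
  if (need > length(ids)) {
    stop("external validation split needs ", need, " samples; cohort has ",
         length(ids), call. = FALSE)
  }
  split_ids <- with_seed(config$seed + 3L, sample(ids, need))
  cal_ids <- split_ids[seq_len(config$external_split[1])]
  val_ids <- split_ids[config$external_split[1] + seq_len(config$external_split[2])]
  in_cal <- spectra$sample_id %in% cal_ids
  in_val <- spectra$sample_id %in% val_ids
  for (an in config$external_analytes) {
    y <- profiles[[an]][scan_of]
    chain <- fit_chain(config$chains[[an]], spectra$A[in_cal, , drop = FALSE],
                       spectra$grid)
    X_cal <- chain$x
    X_val <- apply_chain(chain, spectra$A[in_val, , drop = FALSE])
    rank <- cv_reports[[an]]$rank
    external_reports[[an]] <- external_validation(
      X_cal, y[in_cal], X_val, y[in_val], rank = rank,
      cal_ids = spectra$sample_id[in_cal], val_ids = spectra$sample_id[in_val],
      analyte = an)
  }

  composition <- composition_table(profiles)
  extracts <- simulate_extracts(profiles, seed = config$seed + 4L)
  cd <- color_density(extracts$A420, extracts$A520, extracts$A700)
  hu <- hue(extracts$A420, extracts$A520, extracts$A700)
  color <- data.frame(sample_id = extracts$sample_id,
                      phenotype = extracts$phenotype,
                      CD = cd, hue = hu, stringsAsFactors = FALSE)

  bundle <- list(
    profiles = profiles,
    spectra_dim = dim(spectra$A),
    cv_reports = cv_reports,
    external_reports = external_reports,
    ranks = vapply(cv_reports, `[[`, 1L, "rank"),
    models = models,
    chains = fitted_chains,
    composition = composition,
    group_summary = group_summary(profiles),
    extracts = extracts,
    color = color,
    config_hash = config_hash(config)
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, spectra, config)
  bundle
}

metrics_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(analyte = r$analyte, scheme = r$scheme, rank = r$rank,
               R2 = r$R2, RMSE = r$RMSE, RPD = r$RPD, bias = r$bias,
               n = r$n, stringsAsFactors = FALSE)
  }))
}

write_bundle <- function(bundle, spectra, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  tab <- metrics_table(c(bundle$cv_reports, bundle$external_reports))
  tab$config_hash <- bundle$config_hash
  write.csv(tab, p("validation_metrics.csv"), row.names = FALSE)
  write.csv(bundle$profiles, p("metabolite_table.csv"), row.names = FALSE)
  write.csv(bundle$composition, p("composition.csv"), row.names = FALSE)
  write.csv(bundle$group_summary, p("group_summary.csv"), row.names = FALSE)
  write.csv(bundle$color, p("color.csv"), row.names = FALSE)
  for (an in names(bundle$models)) {
    save_model(bundle$models[[an]], bundle$chains[[an]], spectra$grid,
               p(paste0("model_", gsub("[^A-Za-z0-9_]", "", an), ".json")))
  }
  jsonlite::write_json(
    list(config_hash = bundle$config_hash, seed = config$seed,
         n_scans = bundle$spectra_dim[1], n_channels = bundle$spectra_dim[2],
         analytes = names(bundle$models)),
    p("manifest.json"), auto_unbox = TRUE)
  invisible(NULL)
}

#' Window-only (linear) variants of the default chains
#'
#' The default chains with their per-spectrum scatter-correction steps (SNV,
#' MSC, vector normalisation) removed, keeping derivatives and window
#' restriction — every remaining operator is linear in the spectra. Used to
#' study the noiseless limit, where the forward model is exactly linear and
#' the PLS core must reproduce the reference values to machine precision.
#'
#' @param analytes Which analytes to return chains for.
#' @return Named list of [preprocess_chain()] objects.
#' @export
linear_chains <- function(analytes = analyte_names()) {
  lapply(default_chains(analytes), function(ch) {
    keep <- vapply(ch$steps, function(s) s$op %in% c("derivative", "windows"),
                   logical(1))
    do.call(preprocess_chain, c(ch$steps[keep], list(analyte = ch$analyte)))
  })
}
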