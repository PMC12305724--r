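test_that("metabolite generation is deterministic and structurally sound", {
  a <- generate_metabolite_profiles(seed = 123)
  b <- generate_metabolite_profiles(seed = 123)
  expect_identical(a, b)                          # bitwise reproducibility
  c <- generate_metabolite_profiles(seed = 124)
  expect_false(identical(a, c))

  expect_identical(nrow(a), 461L)
  # totals are sums of their components by construction
  pig <- as.matrix(a[, pigment_names()])
  expect_equal(a$Total_ACN, rowSums(pig), tolerance = 1e-12)
  expect_equal(a$Total_AcA, rowSums(pig[, 1:3]), tolerance = 1e-12)
  expect_equal(a$Total_NAA, rowSums(pig[, 4:5]), tolerance = 1e-12)
  expect_true(all(pig >= 0))
  # generating must not disturb the caller's RNG stream
  set.seed(55); before <- rnorm(3)
  set.seed(55); invisible(generate_metabolite_profiles(seed = 9))
  expect_identical(rnorm(3), before)
})

test_that("group means calibrate to their configured values", {
  # across seeds, each group's sample mean stays within 3 standard errors
  # of the configured mean
  gp <- default_group_params()
  for (s in c(2, 7)) {
    prof <- generate_metabolite_profiles(groups = gp, seed = s)
    for (g in gp) {
      v <- prof$Total_ACN[prof$phenotype == g$code]
      se <- sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - g$acn_mean), 3 * se + 0.05 * g$acn_mean)
    }
  }
})

test_that("non-purple samples carry only trace anthocyanin", {
  prof <- generate_metabolite_profiles(seed = 6)
  np <- prof$Total_ACN[prof$phenotype == ":0000"]
  expect_lt(mean(np), 1.5)
  expect_gt(mean(np), 0.1)
  expect_true(all(np < 20))
})

test_that("parameter validation rejects impossible group settings", {
  expect_error(group_params(":10x0", 5, 100, 0.5, 50), "position")
  expect_error(group_params(":1111", -1, 100, 0.5, 50), ">= 0")
  expect_error(group_params(":1111", 5, -100, 0.5, 50), "> 0")
  expect_error(group_params(":1111", 5, 100, 1.5, 50), "inside")
  expect_error(group_params(":1111", 5, 100, 0.5, 50, acyl_kappa = 0), "> 0")
})

test_that("pure spectra are Gaussian band superpositions", {
  grid <- nir_grid()
  # single band peaks at the grid point nearest its centre
  one <- simulate_pure_spectra(list(x = c(9000, 100, 1)), grid)
  expect_equal(grid[which.max(one)], grid[which.min(abs(grid - 9000))])
  # empty band list gives the zero spectrum
  none <- simulate_pure_spectra(list(x = matrix(numeric(0), 0, 3)), grid)
  expect_true(all(none == 0))
  # additivity against direct evaluation of the Gaussian formula
  b1 <- c(9000, 100, 1); b2 <- c(5000, 200, 0.5)
  two <- simulate_pure_spectra(list(x = rbind(b1, b2)), grid)
  oracle <- b1[3] * exp(-0.5 * ((grid - b1[1]) / b1[2])^2) +
    b2[3] * exp(-0.5 * ((grid - b2[1]) / b2[2])^2)
  expect_equal(drop(two), oracle, tolerance = 1e-12)
  expect_true(all(two >= 0))

  expect_error(simulate_pure_spectra(list(x = c(99999, 10, 1)), grid),
               "outside grid")
  expect_error(simulate_pure_spectra(list(x = c(9000, -1, 1)), grid), "> 0")
  expect_error(simulate_pure_spectra(list(x = c(9000, 10, 1)), rev(grid)),
               "increasing")
})

test_that("the spectral forward model is exactly linear without noise", {
  prof <- generate_purple_cohort(6, seed = 3)
  pure <- default_pure_components()
  off <- scatter_off()

  base <- simulate_spectra(prof, pure, off, replicates = 1, seed = 1)
  # zero concentrations leave only the matrix background
  prof0 <- prof
  prof0[, anthoNIR:::mixture_components()] <- 0
  bg <- simulate_spectra(prof0, pure, off, replicates = 1, seed = 1)
  expect_equal(bg$A[1, ], pure$background, tolerance = 1e-12)

  # doubling all concentrations doubles (spectrum - background)
  prof2 <- prof
  prof2[, anthoNIR:::mixture_components()] <-
    2 * prof[, anthoNIR:::mixture_components()]
  dbl <- simulate_spectra(prof2, pure, off, replicates = 1, seed = 1)
  expect_equal(dbl$A - rep(1, nrow(dbl$A)) %o% pure$background,
               2 * (base$A - rep(1, nrow(base$A)) %o% pure$background),
               tolerance = 1e-9)

  # superposition: mixture = sum of single-component spectra minus the
  # (k-1) extra background copies
  comps <- anthoNIR:::mixture_components()
  singles <- lapply(comps, function(cn) {
    pr <- prof0
    pr[[cn]] <- prof[[cn]]
    simulate_spectra(pr, pure, off, replicates = 1, seed = 1)$A
  })
  summed <- Reduce(`+`, singles)
  oracle <- summed - (length(comps) - 1) *
    (rep(1, nrow(base$A)) %o% pure$background)
  expect_equal(base$A, oracle, tolerance = 1e-9)
})

test_that("replicates differ only by scatter/noise and output is clipped", {
  prof <- generate_purple_cohort(10, seed = 2)
  sp <- simulate_spectra(prof, replicates = 3, seed = 11)
  expect_identical(nrow(sp$A), 30L)
  expect_true(all(sp$A >= 0))
  expect_true(is.numeric(sp$clipped))
  expect_identical(sp$sample_id[1:3], rep(prof$sample_id[1], 3))
  # same seed reproduces the scan matrix bitwise
  sp2 <- simulate_spectra(prof, replicates = 3, seed = 11)
  expect_identical(sp$A, sp2$A)
  # replicate scans of one sample are near, but not equal
  expect_false(identical(sp$A[1, ], sp$A[2, ]))
  expect_lt(max(abs(sp$A[1, ] - sp$A[2, ])), 0.5)

  expect_error(simulate_spectra(prof[, 1:4], replicates = 1, seed = 1),
               "lack mixture components")
  pr <- prof; pr$Cy3XG[1] <- -1
  expect_error(simulate_spectra(pr, replicates = 1, seed = 1), "negative")
})

test_that("extract simulation produces the expected colour behaviour", {
  prof <- generate_metabolite_profiles(seed = 21)
  g1111 <- prof[prof$phenotype == ":1111", ]

  # zero pigment: colour density indistinguishable from browning floor
  zero <- g1111[1:5, ]
  zero[, anthoNIR:::mixture_components()] <- 0
  ex0 <- simulate_extracts(zero, extract_noise_off(), seed = 1)
  expect_equal(ex0$A520 - ex0$A700, rep(0, 5), tolerance = 1e-12)
  cd0 <- color_density(ex0$A420, ex0$A520, ex0$A700)
  expect_true(all(cd0 < 0.5))

  # monotonicity sweep: CD strictly increases with Cy3XSGG (noise off)
  sweep_prof <- zero[rep(1, 8), ]
  sweep_prof$Cy3XSGG <- seq(100, 1500, length.out = 8)
  exs <- simulate_extracts(sweep_prof, extract_noise_off(), seed = 1)
  cds <- color_density(exs$A420, exs$A520, exs$A700)
  expect_true(all(diff(cds) > 0))

  # default fully-purple cohort: CD of the right order of magnitude
  ex <- simulate_extracts(g1111, seed = 2)
  cd <- color_density(ex$A420, ex$A520, ex$A700)
  expect_gt(mean(cd), 15)
  expect_lt(mean(cd), 90)
  expect_gt(max(cd), 40)

  # determinism
  expect_identical(ex, simulate_extracts(g1111, seed = 2))
})
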