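test_that("SNV standardises, is idempotent and matches the formula oracle", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))

  set.seed(7)
  x <- rnorm(10, mean = 3, sd = 0.4)
  expect_equal(snv(x), (x - mean(x)) / sd(x), tolerance = 1e-12)
  expect_lt(abs(mean(snv(x))), 1e-10)
  expect_equal(sd(snv(x)), 1, tolerance = 1e-10)

  z <- snv(x)
  expect_equal(snv(z), z, tolerance = 1e-12)   # idempotence
  expect_error(snv(rep(2, 5)), "constant")

  # matrix form operates row-wise
  M <- rbind(x, 2 * x + 1)
  expect_equal(snv(M)[1, ], snv(x))
  expect_equal(snv(M)[2, ], snv(x))            # affine-equivalent rows agree
})

test_that("MSC removes affine scatter and matches a least-squares oracle", {
  set.seed(11)
  ref <- abs(rnorm(40, 0.5, 0.1)) + sin(seq(0, 3, length.out = 40))
  # spectrum equal to reference is unchanged
  out <- msc(ref, reference = ref)
  expect_equal(unname(out), ref, tolerance = 1e-12, ignore_attr = TRUE)
  # affine distortion 2*ref + 3 corrects back to the reference exactly
  out <- msc(2 * ref + 3, reference = ref)
  expect_equal(as.numeric(out), ref, tolerance = 1e-10, ignore_attr = TRUE)

  # random spectra: intercept/slope must match lm() normal equations
  X <- t(replicate(4, 0.7 * ref + rnorm(1, 0, 0.5) + rnorm(40, 0, 0.02)))
  corrected <- msc(X, reference = ref)
  for (i in 1:4) {
    fit <- lm(X[i, ] ~ ref)
    expect_equal(as.numeric(corrected[i, ]),
                 (X[i, ] - coef(fit)[1]) / coef(fit)[2], tolerance = 1e-10)
  }
  expect_error(msc(X, reference = rep(1, 40)), "constant")
})

test_that("Savitzky-Golay first derivative matches analytic derivatives", {
  i <- seq_len(50)
  expect_equal(first_derivative(3 + 2 * i), rep(2, 50), tolerance = 1e-8)
  expect_equal(first_derivative(rep(5, 50)), rep(0, 50), tolerance = 1e-10)

  # quadratic: derivative 2*i at interior points (window 7, order 2)
  d <- first_derivative(i^2, window = 7L, polyorder = 2L)
  interior <- 4:47
  expect_equal(d[interior], 2 * i[interior], tolerance = 1e-8)

  expect_error(first_derivative(i, window = 8L), "odd")
  expect_error(first_derivative(1:5, window = 7L), "exceeds")
})

test_that("vector normalisation is unit-norm, scale-invariant, idempotent", {
  expect_equal(vector_normalize(c(3, 4)), c(0.6, 0.8))
  set.seed(3)
  for (k in 1:5) {
    x <- rnorm(30)
    v <- vector_normalize(x)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
    expect_equal(vector_normalize(10 * x), v, tolerance = 1e-12)
    expect_equal(vector_normalize(v), v, tolerance = 1e-12)
  }
  expect_error(vector_normalize(rep(0, 4)), "zero")
})

test_that("window selection matches per-point interval membership", {
  grid <- nir_grid()
  X <- matrix(rnorm(2 * length(grid)), 2)

  # full-span window is the identity
  full <- select_windows(X, grid, list(c(min(grid), max(grid))))
  expect_identical(full$x, X)

  # the total-ACN windows keep 9000 cm-1 and drop 8000 cm-1
  wins <- list(c(8925.6, 12489.7), c(4482.1, 7159))
  sel <- select_windows(X, grid, wins)
  near <- function(v, g) g[which.min(abs(g - v))]
  expect_true(near(9000, grid) %in% sel$grid)
  expect_false(near(8000, grid) %in% sel$grid)

  # brute-force membership oracle on disjoint windows
  wins2 <- list(c(4000, 4500), c(9100, 9700), c(12000, 12400))
  sel2 <- select_windows(X, grid, wins2)
  member <- vapply(grid, function(g) {
    any(vapply(wins2, function(w) g >= w[1] && g <= w[2], logical(1)))
  }, logical(1))
  expect_identical(sel2$mask, member)
  expect_identical(ncol(sel2$x), sum(member))

  expect_error(select_windows(X, grid, list(c(1, 2))), "zero grid points")
  expect_error(select_windows(X, grid, list(c(5000, 4000))), "lo < hi")
})

test_that("fitted chains replay bitwise and reuse calibration statistics", {
  set.seed(21)
  prof <- generate_purple_cohort(20, seed = 5)
  sp <- simulate_spectra(prof, replicates = 2, seed = 6)
  for (an in c("Total_ACN", "Total_PHEN", "Cy3XFGG", "CA")) {
    chain <- fit_chain(default_chains(an)[[1]], sp$A, sp$grid)
    # replay on the calibration set reproduces the stored matrix bitwise
    expect_identical(apply_chain(chain, sp$A), chain$x)
  }

  # MSC at prediction time must use the stored calibration reference,
  # not the statistics of the prediction set
  chain <- fit_chain(default_chains("Total_PHEN")[[1]], sp$A, sp$grid)
  msc_step <- Filter(function(s) s$op == "msc", chain$steps)[[1]]
  one <- apply_chain(chain, sp$A[1, , drop = FALSE])
  expect_identical(one, chain$x[1, , drop = FALSE])
  expect_length(msc_step$reference, length(sp$grid))
})

test_that("chain construction enforces its structural invariants", {
  expect_error(preprocess_chain("windows_last", "snv"), "unknown")
  expect_error(
    preprocess_chain(list(op = "windows", windows = list(c(1, 2))), "snv"),
    "last step")
  expect_error(preprocess_chain(list(op = "derivative", window = 4)), "odd")
  ch <- default_chains()
  expect_named(ch, analyte_names())
})
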