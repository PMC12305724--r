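test_that("degree of acylation follows its defining ratio", {
  expect_equal(degree_of_acylation(900, 100), 90)
  expect_equal(degree_of_acylation(0, 50), 0)
  expect_true(is.na(degree_of_acylation(0, 0)))
  expect_error(degree_of_acylation(-1, 5), ">= 0")

  # complementarity: acylated + non-acylated shares sum to exactly 100
  set.seed(2)
  aca <- runif(20, 0, 1000); naa <- runif(20, 0, 500)
  expect_equal(degree_of_acylation(aca, naa) + 100 * naa / (aca + naa),
               rep(100, 20), tolerance = 1e-12)
})

test_that("composition table gives shares summing to 100 and honours the floor", {
  prof <- generate_metabolite_profiles(seed = 14)
  comp <- composition_table(prof, floor = 1)
  ok <- !is.na(comp$pct_acylation)
  shares <- as.matrix(comp[ok, paste0("pct_", pigment_names())])
  expect_equal(unname(rowSums(shares)), rep(100, sum(ok)), tolerance = 1e-6)
  # sub-floor samples are flagged undefined
  low <- prof$Total_ACN < 1
  expect_true(all(is.na(comp$pct_acylation[low])))
})

test_that("purple cohort acylation spans the 40-100 % band", {
  vals <- unlist(lapply(1:5, function(s) {
    prof <- generate_metabolite_profiles(seed = s)
    comp <- composition_table(prof)
    comp$pct_acylation[prof$phenotype != ":0000"]
  }))
  vals <- vals[!is.na(vals)]
  q <- quantile(vals, c(0.02, 0.98))
  expect_gt(q[1], 40)
  expect_lte(q[2], 100)
  expect_true(all(vals >= 20 & vals <= 100))
})

test_that("pearson_cor matches the textbook formula and is symmetric", {
  expect_equal(pearson_cor(1:10, 1:10)$r, 1)
  expect_equal(pearson_cor(1:10, -(1:10))$r, -1)

  set.seed(6)
  x <- rnorm(10); y <- 0.4 * x + rnorm(10)
  got <- pearson_cor(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_stat <- r_oracle * sqrt(8 / (1 - r_oracle^2))
  p_oracle <- 2 * pt(-abs(t_stat), df = 8)
  expect_equal(got$r, r_oracle, tolerance = 1e-10)
  expect_equal(got$p, p_oracle, tolerance = 1e-10)

  # symmetry and affine invariance
  swapped <- pearson_cor(y, x)
  expect_equal(swapped$r, got$r, tolerance = 1e-12)
  scaled <- pearson_cor(5 * x - 2, y)
  expect_equal(scaled$r, got$r, tolerance = 1e-12)

  expect_error(pearson_cor(1:2, 1:2), "3 complete pairs")
  expect_error(pearson_cor(rep(1, 5), 1:5), "constant")
})

test_that("PCA variance and loadings match an eigendecomposition oracle", {
  # collinear two-column data: PC1 carries everything
  x <- cbind(1:6, 2 * (1:6))
  pc <- pca_summary(x)
  expect_equal(pc$variance_explained[1], 100, tolerance = 1e-10)

  set.seed(10)
  m <- matrix(rnorm(24), 6, 4)
  pc <- pca_summary(m)
  ev <- eigen(cov(m))$values
  expect_equal(pc$variance_explained, 100 * ev / sum(ev), tolerance = 1e-8)
  expect_equal(sum(pc$variance_explained), 100, tolerance = 1e-10)

  # full cohort, unscaled: PC1 is dominated by the anthocyanin totals
  prof <- generate_metabolite_profiles(seed = 3)
  num <- prof[, c(analyte_names(), "Total_NAA")]
  pc <- pca_summary(num)
  l1 <- abs(pc$loadings[, 1])
  expect_true(all(rank(-l1)[c("Total_ACN", "Total_AcA")] <= 3))
  expect_error(pca_summary(matrix(1:3, 3, 1)), "2 rows and 2 columns")
})

test_that("colour density and hue follow the printed formulas", {
  expect_equal(color_density(0.5, 1.0, 0.1), 1.3)
  expect_equal(hue(0.5, 1.0, 0.1), 2.25)
  expect_equal(color_density(0.3, 0.3, 0.3), 0)
  expect_true(is.na(hue(0.3, 0.7, 0.3)))

  set.seed(5)
  a420 <- runif(20); a520 <- runif(20); a700 <- runif(20, 0, 0.2)
  expect_equal(color_density(a420, a520, a700),
               (a420 - a700) + (a520 - a700), tolerance = 1e-12)
  expect_equal(hue(a420, a520, a700),
               (a520 - a700) / (a420 - a700), tolerance = 1e-12)
  expect_error(color_density(-0.1, 0.5, 0.1), ">= 0")
})

test_that("extraction efficiency is a guarded ratio with >100 flags", {
  eff <- extraction_efficiency(50, 100)
  expect_equal(as.numeric(eff), 50, ignore_attr = TRUE)
  expect_error(extraction_efficiency(50, 0), "> 0")
  over <- extraction_efficiency(c(80, 120), c(100, 100))
  expect_identical(attr(over, "over_100"), c(FALSE, TRUE))

  # fully purple simulation recovers the configured Cy3XGG efficiency
  prof <- generate_metabolite_profiles(seed = 8)
  g <- prof[prof$phenotype == ":1111", ]
  ex <- simulate_extracts(g, seed = 3)
  ex <- ex[ex$puree_Cy3XGG > 0, ]   # flooring zeroes trace Cy3XGG draws
  eff_gg <- extraction_efficiency(ex$extract_Cy3XGG, ex$puree_Cy3XGG)
  expect_lt(abs(mean(eff_gg) - 98), 3)
})

test_that("group summaries are deterministic and ordered, :1111 richest", {
  tiny <- data.frame(sample_id = paste0("S", 1:4),
                     phenotype = c(":1000", ":1000", ":1111", ":0000"),
                     Total_ACN = c(10, 30, 500, 1),
                     stringsAsFactors = FALSE)
  gs <- group_summary(tiny, analytes = "Total_ACN")
  expect_identical(gs$phenotype, sort(unique(tiny$phenotype)))
  expect_equal(gs$mean[gs$phenotype == ":1000"], 20)
  expect_equal(gs$median[gs$phenotype == ":1000"], 20)
  one <- gs[gs$phenotype == ":1111", ]
  expect_equal(one$mean, one$median)
  expect_equal(one$min, one$max)

  prof <- generate_metabolite_profiles(seed = 17)
  gs <- group_summary(prof, analytes = "Total_ACN")
  expect_identical(gs$phenotype[which.max(gs$mean)], ":1111")
})
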