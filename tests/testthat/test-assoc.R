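test_that("bh_fdr reproduces the hand-executed step-up and the
          brute-force oracle on a grid", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.73), 0.73)
  expect_equal(bh_fdr(numeric()), numeric())
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")

  grid <- c(0.001, 0.01, 0.049, 0.05, 0.2, 0.5, 0.77, 1)
  # exhaustive on short vectors
  for (n in 1:3) {
    combs <- expand.grid(rep(list(grid), n))
    for (i in seq_len(nrow(combs))) {
      p <- as.numeric(combs[i, ])
      expect_equal(bh_fdr(p), bh_oracle(p))
    }
  }
  # random longer vectors, including ties
  withr::with_seed(5, {
    for (i in 1:200) {
      p <- sample(grid, sample(4:8, 1), replace = TRUE)
      expect_equal(bh_fdr(p), bh_oracle(p))
    }
  })
})

test_that("bh_fdr is permutation-consistent and monotone", {
  p <- c(0.3, 0.001, 0.2, 0.001, 0.9)
  q <- bh_fdr(p)
  perm <- c(4, 2, 5, 1, 3)
  expect_equal(bh_fdr(p[perm]), q[perm])
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  expect_true(all(q >= p))
})

test_that("genomic inflation: exact null median, uniform calibration,
          directional response, guards", {
  expect_equal(genomic_inflation(rep(0.5, 11)), 1.0)
  withr::with_seed(2, {
    p <- runif(10000)
    expect_lt(abs(genomic_inflation(p) - 1), 0.05)
    strong <- c(runif(9500), 10^-runif(500, 4, 8))
    expect_gt(genomic_inflation(strong), 1)
  })
  expect_error(genomic_inflation(c(0.5, 0)), "quantile is infinite")
  expect_error(genomic_inflation(numeric()), "no p-values")
  expect_equal(genomic_inflation(rep(0.3, 5), literal = TRUE), 0.6)
})

test_that("fit_marker matches independent lm() fits: F-test p, additive
          beta/SE, and the Var% identity", {
  withr::with_seed(8, {
    n <- 120
    breed <- rep(c("b1", "b2", "b3"), each = 40)
    g <- sample(0:2, n, replace = TRUE)
    y <- rnorm(n) + 0.4 * g + rep(c(0, 1, 3), each = 40)
    rec <- fit_marker(y, breed, g, marker_id = "mx", trait = "t")

    full <- stats::lm(y ~ factor(breed) + factor(g))
    red <- stats::lm(y ~ factor(breed))
    an <- stats::anova(red, full)
    expect_equal(rec$p, an$`Pr(>F)`[2], tolerance = 1e-12)
    rss_f <- sum(stats::residuals(full)^2)
    rss_r <- sum(stats::residuals(red)^2)
    expect_equal(rec$var_pct, 100 * (rss_r - rss_f) / rss_r,
                 tolerance = 1e-12)
    add <- summary(stats::lm(y ~ factor(breed) + g))$coefficients
    expect_equal(rec$beta, add["g", "Estimate"], tolerance = 1e-12)
    expect_equal(rec$se, add["g", "Std. Error"], tolerance = 1e-12)
    expect_equal(rec[, c("n0", "n1", "n2")],
                 tibble::tibble(n0 = sum(g == 0), n1 = sum(g == 1),
                                n2 = sum(g == 2)))
  })
})

test_that("Var% for reduced RSS 100 and full RSS 84 is 16", {
  expect_equal(100 * (100 - 84) / 100, 16)
  # the same identity through fit_marker on data engineered to known RSS:
  # covered by the lm() cross-check above; this pins the formula's scale
})

test_that("degenerate markers are flagged, not fit", {
  y <- rnorm(20)
  breed <- rep(c("b1", "b2"), each = 10)
  rec <- fit_marker(y, breed, rep(1L, 20))
  expect_equal(rec$note, "single_class")
  expect_true(is.na(rec$p))
  # genotype constant within every breed -> collinear with breed
  g <- rep(c(0L, 2L), each = 10)
  rec <- fit_marker(y, breed, g)
  expect_equal(rec$note, "collinear_with_breed")
  expect_true(is.na(rec$p))
})

test_that("missing dosage and trait values are dropped pairwise", {
  withr::with_seed(13, {
    y <- rnorm(60); breed <- rep(c("b1", "b2"), 30)
    g <- sample(0:2, 60, replace = TRUE)
    y[1:3] <- NA; g[4:6] <- NA
    rec <- fit_marker(y, breed, g)
    expect_equal(rec$n, 54L)
    keep <- !is.na(y) & !is.na(g)
    ref <- fit_marker(y[keep], breed[keep], g[keep])
    expect_equal(rec$p, ref$p)
    expect_equal(rec$beta, ref$beta)
  })
})

test_that("null markers give uniform p-values (KS) and the scan table is
          well-formed", {
  sim <- simulate_panel(null_config(seed = 55, n_markers = 400))
  corrected <- sex_correct(sim$traits, sim$geno$samples)
  scan <- assoc_scan(sim$geno, corrected)
  expect_equal(nrow(scan), 400L)
  expect_true(all(scan$q >= scan$p, na.rm = TRUE))
  ks <- stats::ks.test(scan$p[!is.na(scan$p)], "punif")
  expect_gt(ks$p.value, 0.01)
  expect_true(all(c("chromosome", "position_bp", "maf", "var_pct")
                  %in% names(scan)))
})

test_that("a planted effect is recovered by the scan with the breed
          covariate in place", {
  cfg <- sim_config(panel_breeds(), 50, c(chr1 = 1e7),
                    f_type = 0.1, f_breed = 0.05,
                    causal_loci = tibble::tibble(
                      marker = 25L, trait = "body_weight_kg", effect = 1),
                    breed_effects = tidyr::expand_grid(
                      breed = panel_breeds()$breed,
                      trait = "body_weight_kg") |>
                      dplyr::mutate(baseline = 3, sex_effect = 0.4),
                    residual_sd = c(body_weight_kg = 1), seed = 60)
  sim <- simulate_panel(cfg)
  corrected <- sex_correct(sim$traits, sim$geno$samples)
  scan <- assoc_scan(sim$geno, corrected)
  top <- scan[which.min(scan$p), ]
  expect_equal(top$marker_id, sim$truth$causal$marker_id)
  expect_lt(abs(top$beta - sim$truth$causal$effect_minor), 2.5 * top$se)
})
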