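complete_sim <- function(seed, n_markers = 150, ...) {
  sim <- simulate_panel(null_config(seed = seed, n_markers = n_markers,
                                    missing_rate = 0, ...))
  complete_case_markers(filter_markers(sim$geno)$geno)
}

test_that("two-sample PCA places scores at plus/minus half the pairwise
          distance", {
  ds <- tiny_geno(rbind(c(0L, 0L, 1L), c(2L, 2L, 0L)))
  m <- run_pca(ds)
  d <- sqrt(sum((ds$dosage[1, ] - ds$dosage[2, ])^2))
  expect_equal(unname(sort(abs(m$scores[, 1]))), rep(d / 2, 2))
  expect_equal(sum(abs(m$scores[, -1])), 0)
})

test_that("rank-1 hand matrix: PC1 loading proportional to (1,1)/sqrt(2),
          second component has zero variance", {
  ds <- tiny_geno(rbind(c(1L, 1L), c(0L, 0L), c(2L, 2L), c(0L, 0L)))
  m <- run_pca(ds)
  expect_equal(abs(unname(m$rotation[, 1])), rep(1 / sqrt(2), 2))
  expect_equal(m$sdev[2], 0)
  expect_error(contributions(m, 2), "zero standard deviation")
})

test_that("total PCA variance equals the sum of marker column variances
          and the centered matrix is reconstructed", {
  ds <- complete_sim(41)
  m <- run_pca(ds)
  expect_equal(sum(m$sdev^2), sum(apply(ds$dosage, 2, stats::var)))
  centered <- scale(ds$dosage, center = TRUE, scale = FALSE)
  expect_equal(m$scores %*% t(m$rotation), unclass(centered),
               ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("degenerate PCA inputs are rejected", {
  ds <- tiny_geno(rbind(c(0L, NA), c(1L, 1L), c(2L, 0L)))
  expect_error(run_pca(ds), "missing genotype calls")
  ds2 <- tiny_geno(rbind(c(0L, 1L), c(0L, 0L), c(0L, 2L)))
  expect_error(run_pca(ds2), "constant marker")
})

test_that("contributions sum to 100, follow the loading-squared identity,
          and split evenly under symmetry", {
  ds <- complete_sim(42)
  m <- run_pca(ds)
  rec <- contributions(m, 1)
  expect_equal(sum(rec$contribution), 100, tolerance = 1e-6)
  expect_equal(rec$cos2, rec$var_cor^2)
  # sdev factors cancel: contribution = 100 * loading^2 / sum(loading^2)
  expect_equal(rec$contribution,
               100 * rec$loading^2 / sum(rec$loading^2))

  ds_eq <- tiny_geno(rbind(c(1L, 1L), c(0L, 0L), c(2L, 2L), c(1L, 1L)))
  rec_eq <- contributions(run_pca(ds_eq), 1)
  expect_equal(rec_eq$contribution, c(50, 50))
})

test_that("pcaDObs p-values follow the fitted normal: capped at the mean,
          0.05 at the 1.96-sigma point, symmetric toys share one p", {
  # records labelled synthetic: built directly, not from a genotype PCA
  mk_rec <- function(loading, contribution) {
    tibble::tibble(marker_id = sprintf("m%02d", seq_along(loading)),
                   chromosome = "chr1",
                   position_bp = seq_along(loading) * 1000L,
                   loading = loading, var_cor = loading,
                   cos2 = loading^2, contribution = contribution)
  }
  # the vector (2, 2.5, 3, 3.5, 9) has mean 4; appending a marker whose
  # pcaDObs is exactly 4 keeps the mean at 4, so its upper tail is 0.5
  # and the doubled, capped p is 1
  d <- c(2, 2.5, 3, 3.5, 9)
  at_mean <- pcadobs_significance(mk_rec(rep(1, 6), c(d, mean(d))))
  expect_equal(at_mean$p[6], 1)

  # large symmetric base: appending one marker at mean + 1.96 sd barely
  # moves the fitted moments, so its raw p sits at 0.05
  base <- rep(c(-1, 1, -2, 2), 250)
  x <- mean(base) + stats::qnorm(0.975) * stats::sd(base)
  rec <- pcadobs_significance(mk_rec(sign(c(base, x)), abs(c(base, x))))
  expect_equal(rec$p[1001], 0.05, tolerance = 2e-2)

  sym <- pcadobs_significance(mk_rec(c(-1, -1, 1, 1), rep(3, 4)))
  expect_equal(mean(sym$pcadobs), 0)
  expect_length(unique(round(sym$p, 12)), 1L)
})

test_that("selection is invariant to component orientation", {
  ds <- complete_sim(43)
  m <- run_pca(ds)
  m_flip <- m
  m_flip$rotation[, 1] <- -m_flip$rotation[, 1]
  m_flip$scores[, 1] <- -m_flip$scores[, 1]
  a <- pcadobs_significance(contributions(m, 1))
  b <- pcadobs_significance(contributions(m_flip, 1))
  expect_equal(b$pcadobs, -a$pcadobs)
  expect_equal(b$p, a$p)
  expect_equal(b$p_bonf, a$p_bonf)
  expect_equal(b$selected, a$selected)
})

test_that("records are invariant to sample reordering", {
  ds <- complete_sim(44)
  perm <- withr::with_seed(9, sample(n_samples(ds)))
  a <- pcadobs_significance(contributions(run_pca(ds), 1))
  b <- pcadobs_significance(contributions(run_pca(
    subset_geno(ds, samples = perm)), 1))
  # orientation of a component is arbitrary; compare magnitudes and p's
  expect_equal(abs(b$pcadobs), abs(a$pcadobs), tolerance = 1e-8)
  expect_equal(b$p, a$p, tolerance = 1e-8)
})

test_that("sigma = 0 and out-of-range components are rejected", {
  rec <- tibble::tibble(marker_id = c("a", "b"), chromosome = "chr1",
                        position_bp = c(1L, 2L), loading = c(1, 1),
                        var_cor = c(1, 1), cos2 = c(1, 1),
                        contribution = c(50, 50))
  expect_error(pcadobs_significance(rec), "zero SD")
  ds <- complete_sim(45)
  expect_error(contributions(run_pca(ds), 10^4), "out of range")
})

test_that("PC-trait correlation: monotone transforms give rho 1, flipping
          the component flips the sign, null traits stay small", {
  ds <- complete_sim(46)
  m <- run_pca(ds)
  traits <- tibble::tibble(sample_id = ds$samples$sample_id,
                           trait = "body_weight_kg",
                           value = exp(m$scores[, 1] / 50))
  ct <- pc_trait_correlation(m, traits)
  expect_equal(ct$rho, 1)
  m_flip <- m
  m_flip$scores[, 1] <- -m_flip$scores[, 1]
  expect_equal(pc_trait_correlation(m_flip, traits)$rho, -1)
  # constant trait -> missing rho
  const <- dplyr::mutate(traits, value = 5)
  expect_true(is.na(pc_trait_correlation(m, const)$rho))

  withr::with_seed(31, {
    small <- vapply(1:200, function(i) {
      tr <- dplyr::mutate(traits, value = rnorm(dplyr::n()))
      abs(pc_trait_correlation(m, tr)$rho)
    }, numeric(1))
    expect_gte(mean(small < 0.2), 0.95)
  })
})

test_that("pca_scan wires selection into distance regions", {
  cfg <- sim_config(panel_breeds(), 400,
                    c(chr1 = 50e6, chr2 = 50e6),
                    f_type = 0.1, f_breed = 0.1,
                    differentiated_loci = tibble::tibble(
                      marker = c(100L, 101L, 102L),
                      freq_game = 0.9, freq_bantam = 0.1),
                    missing_rate = 0, seed = 70)
  sim <- simulate_panel(cfg)
  ds <- complete_case_markers(filter_markers(sim$geno)$geno)
  sc <- pca_scan(ds)
  expect_true(all(sc$records$marker_id[sc$records$selected] %in%
                    unlist(sc$regions$marker_ids)))
  expect_true(all(grepl("^pca:PC1$", sc$regions$source)))
  # PC1 separates the types
  pc1 <- tidy(sc$model, n_components = 1)
  rng_game <- range(pc1$PC1[pc1$type == "game"])
  rng_bantam <- range(pc1$PC1[pc1$type == "bantam"])
  expect_true(rng_game[2] < rng_bantam[1] || rng_bantam[2] < rng_game[1])
})
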