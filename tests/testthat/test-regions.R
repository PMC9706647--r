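# dataset whose LD structure is controlled by duplicating columns:
# markers 1-2 identical (r^2 = 1), marker 3 independent, markers 3-4
# identical; positions ascending on one chromosome
ld_fixture <- function(seed = 1, n = 400) {
  withr::with_seed(seed, {
    a <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    b <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    tiny_geno(cbind(a, a, b, b), positions = c(100, 200, 300, 400) * 1000L)
  })
}

sig_tbl <- function(ds, p = c(1e-8, 1e-6, 1e-7, 1e-9)) {
  tibble::tibble(marker_id = ds$markers$marker_id,
                 chromosome = ds$markers$chromosome,
                 position_bp = ds$markers$position_bp, p = p)
}

test_that("consecutive significant markers chain through strong LD and
          break where LD drops", {
  ds <- ld_fixture()
  reg <- merge_ld_regions(sig_tbl(ds), ds, r2_min = 0.5, source = "assoc:t")
  # A-B joined (r^2 = 1), B-C broken (independent), C-D joined
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$start_bp, c(100000L, 300000L))
  expect_equal(reg$end_bp, c(200000L, 400000L))
  expect_equal(reg$n_markers, c(2L, 2L))
  # top marker = lowest raw p within each region
  expect_equal(reg$top_marker, c("m001", "m004"))
  # every member is itself significant (members come from the input)
  expect_setequal(unlist(reg$marker_ids), ds$markers$marker_id)
})

test_that("the LD join is strict: r^2 equal to the threshold does not
          merge", {
  ds <- ld_fixture()
  r2_ab <- ld_r2(ds$dosage[, 1], ds$dosage[, 2])
  reg <- merge_ld_regions(sig_tbl(ds)[1:2, ], ds, r2_min = r2_ab)
  expect_equal(nrow(reg), 2L)
  reg2 <- merge_ld_regions(sig_tbl(ds)[1:2, ], ds,
                           r2_min = r2_ab - 1e-9)
  expect_equal(nrow(reg2), 1L)
})

test_that("markers on different chromosomes never merge", {
  withr::with_seed(2, {
    a <- sample(0:2, 300, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    ds <- tiny_geno(cbind(a, a), positions = c(1000L, 2000L))
    ds$markers$chromosome <- c("chr1", "chr2")
    sig <- sig_tbl(ds, p = c(1e-8, 1e-8))
    reg <- merge_ld_regions(sig, ds)
    expect_equal(nrow(reg), 2L)
  })
})

test_that("empty significant sets produce empty region tables", {
  ds <- ld_fixture()
  expect_equal(nrow(merge_ld_regions(sig_tbl(ds)[0, ], ds)), 0L)
  expect_equal(nrow(merge_distance_regions(sig_tbl(ds)[0, ])), 0L)
})

test_that("distance merging: gaps at most 2 Mb chain, larger gaps split,
          and chains can exceed 2 Mb end to end", {
  base <- tibble::tibble(
    marker_id = c("a", "b"), chromosome = "chr1",
    position_bp = c(1000000L, 2500000L), p = c(1e-8, 1e-7))
  expect_equal(nrow(merge_distance_regions(base)), 1L)
  base$position_bp[2] <- 3500000L
  expect_equal(nrow(merge_distance_regions(base)), 2L)

  chain <- tibble::tibble(
    marker_id = c("a", "b", "c"), chromosome = "chr1",
    position_bp = c(1000000L, 2800000L, 4600000L), p = c(1e-6, 1e-8, 1e-7))
  reg <- merge_distance_regions(chain)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_bp, 1000000L)
  expect_equal(reg$end_bp, 4600000L)
  expect_equal(reg$top_marker, "b")
})

test_that("region merging is invariant to marker input order", {
  chain <- tibble::tibble(
    marker_id = c("a", "b", "c", "d"), chromosome = c("chr1", "chr1",
                                                      "chr2", "chr1"),
    position_bp = c(1000000L, 2800000L, 500000L, 9000000L),
    p = c(1e-6, 1e-8, 1e-7, 1e-5))
  perm <- chain[c(3, 1, 4, 2), ]
  expect_equal(merge_distance_regions(chain), merge_distance_regions(perm))
})

test_that("interval overlap: 1-based inclusive arithmetic and absence of
          disjoint pairs", {
  regions <- tibble::tibble(chromosome = "chr1", start_bp = 100L,
                            end_bp = 200L, source = "assoc:t")
  known <- tibble::tibble(chromosome = "chr1", start_bp = c(150L, 300L),
                          end_bp = c(300L, 400L),
                          label = c("qtl1", "qtl2"))
  ov <- overlap_regions(regions, known)
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$label, "qtl1")
  expect_equal(ov$overlap_bp, 51L)
})

test_that("overlap report matches a brute-force all-pairs oracle", {
  withr::with_seed(17, {
    rand_iv <- function(n, chroms) {
      s <- sample.int(5000, n, replace = TRUE)
      tibble::tibble(chromosome = sample(chroms, n, replace = TRUE),
                     start_bp = s, end_bp = s + sample.int(800, n, TRUE))
    }
    regions <- rand_iv(50, c("chr1", "chr2", "chr3")) |>
      dplyr::mutate(source = "assoc:t")
    known <- rand_iv(200, c("chr1", "chr2", "chr4")) |>
      dplyr::mutate(label = sprintf("q%03d", dplyr::row_number()))
    got <- overlap_regions(regions, known)
    oracle <- 0L
    for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(known))) {
      if (regions$chromosome[i] == known$chromosome[j]) {
        ov <- min(regions$end_bp[i], known$end_bp[j]) -
          max(regions$start_bp[i], known$start_bp[j]) + 1L
        if (ov >= 1) {
          oracle <- oracle + 1L
          hit <- got[got$chromosome == regions$chromosome[i] &
                       got$start_bp == regions$start_bp[i] &
                       got$end_bp == regions$end_bp[i] &
                       got$label == known$label[j], ]
          expect_equal(hit$overlap_bp, ov)
        }
      }
    }
    expect_equal(nrow(got), oracle)
  })
})
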