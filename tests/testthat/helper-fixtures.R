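# shared fixture builders; everything is generated in code

# minimal hand-built dataset: explicit dosage matrix, single chromosome
tiny_geno <- function(dosage, positions = NULL, breeds = NULL,
                      types = NULL, sexes = NULL, chromosome = "chr1") {
  n <- nrow(dosage); m <- ncol(dosage)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  if (is.null(breeds)) breeds <- rep("b1", n)
  if (is.null(types)) {
    types <- ifelse(grepl("^g", breeds), "game", "bantam")
  }
  if (is.null(sexes)) sexes <- rep(c("male", "female"), length.out = n)
  geno_data(
    dosage,
    markers = tibble::tibble(
      marker_id = sprintf("m%03d", seq_len(m)), chromosome = chromosome,
      position_bp = as.integer(positions),
      allele_a = "A", allele_b = "C"),
    samples = tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(n)), breed = breeds,
      type = types, sex = sexes))
}

# 9-breed / 2-type roster matching the panel structure (201 birds)
panel_breeds <- function() {
  tibble::tibble(
    breed = c("game1", "game2", "game3", "game4",
              "bantam1", "bantam2", "bantam3", "bantam4", "bantam5"),
    type = rep(c("game", "bantam"), c(4, 5)),
    n_male = c(9, 15, 12, 10, 10, 13, 10, 8, 10),
    n_female = c(10, 15, 13, 10, 12, 16, 10, 10, 8))
}

# small drifted panel with no planted signal (null scans)
null_config <- function(seed, n_markers = 500, missing_rate = 0,
                        f_type = 0.15, f_breed = 0.1,
                        traits = "body_weight_kg") {
  sim_config(panel_breeds(), n_markers,
             c(chr1 = 100e6, chr2 = 100e6, chr3 = 100e6),
             f_type = f_type, f_breed = f_breed,
             breed_effects = tidyr::expand_grid(
               breed = panel_breeds()$breed, trait = traits) |>
               dplyr::mutate(baseline = 2, sex_effect = 0.5),
             residual_sd = stats::setNames(rep(1, length(traits)), traits),
             missing_rate = missing_rate, seed = seed)
}

# brute-force BH step-up: q_(i) = min over j >= i of min(1, p_(j) * m / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  po <- p[o]
  q <- vapply(seq_len(n), function(i) {
    min(1, min(po[i:n] * n / (i:n)))
  }, numeric(1))
  out <- numeric(n)
  out[o] <- q
  out
}

# brute-force pairwise-complete rescaled Euclidean distance
dist_oracle <- function(x) {
  n <- nrow(x); m <- ncol(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ok <- !is.na(x[i, ]) & !is.na(x[j, ])
    d[i, j] <- sqrt(sum((x[i, ok] - x[j, ok])^2) * m / sum(ok))
  }
  d
}
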