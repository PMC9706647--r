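#' Build a simulation configuration
#'
#' Describes a hierarchical-drift genotype/phenotype panel: breeds nested in
#' types, per-marker allele frequencies drifting from an ancestral
#' population first to the type level and then to the breed level
#' (Balding-Nichols Beta drift), planted trait-affecting loci, planted
#' type-differentiated loci, and additive phenotypes with breed baselines,
#' sex effects and Gaussian noise.
#'
#' @param breeds Tibble with columns `breed`, `type`, `n_male`, `n_female`.
#' @param n_markers Number of biallelic markers.
#' @param chromosome_lengths Named numeric vector, chromosome -> length in
#'   bp. Markers are placed uniformly at random (proportionally to length)
#'   and sorted by position; placement is fixed by `seed` at config time so
#'   planted locus indices are stable.
#' @param f_type,f_breed Drift coefficients in `[0, 1)`: dispersion of the
#'   type-level frequency around the ancestral one, and of the breed-level
#'   frequency around its type. `0` passes frequencies through unchanged.
#' @param causal_loci Tibble `marker` (index), `trait`, `effect` (trait
#'   units per copy of the simulated B allele); may be empty.
#' @param differentiated_loci Tibble `marker` (index) plus one frequency
#'   column per type, named `freq_<type>`; these override the drawn
#'   type-level frequencies.
#' @param breed_effects Tibble `breed`, `trait`, `baseline`, `sex_effect`
#'   (added for males; trait units).
#' @param residual_sd Named numeric vector, trait -> residual standard
#'   deviation (> 0).
#' @param missing_rate Fraction of genotype calls dropped uniformly at
#'   random, in `[0, 1)`.
#' @param seed Integer seed driving all randomness of the panel.
#' @param markers Optional explicit marker map (`marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`, sorted by chromosome then
#'   position) overriding the random placement.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(breeds, n_markers, chromosome_lengths,
                       f_type = 0.1, f_breed = 0.05,
                       causal_loci = NULL, differentiated_loci = NULL,
                       breed_effects = NULL, residual_sd = NULL,
                       missing_rate = 0, seed = 1L, markers = NULL) {
  stopifnot(is.data.frame(breeds),
            all(c("breed", "type", "n_male", "n_female") %in% names(breeds)))
  if (f_type < 0 || f_type >= 1 || f_breed < 0 || f_breed >= 1) {
    stop("drift coefficients must lie in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  if (is.null(causal_loci)) {
    causal_loci <- tibble::tibble(marker = integer(), trait = character(),
                                  effect = numeric())
  }
  if (is.null(differentiated_loci)) {
    differentiated_loci <- tibble::tibble(marker = integer())
  }
  types <- unique(breeds$type)
  if (nrow(differentiated_loci)) {
    need <- paste0("freq_", types)
    if (!all(need %in% names(differentiated_loci))) {
      stop("differentiated_loci needs columns: ", paste(need, collapse = ", "))
    }
    fr <- as.matrix(differentiated_loci[, paste0("freq_", types)])
    if (any(fr < 0 | fr > 1)) stop("differentiated frequencies outside [0, 1]")
  }
  if (nrow(causal_loci) &&
      any(causal_loci$marker < 1 | causal_loci$marker > n_markers)) {
    stop("causal locus index outside 1..n_markers")
  }
  if (nrow(differentiated_loci) &&
      any(differentiated_loci$marker < 1 |
          differentiated_loci$marker > n_markers)) {
    stop("differentiated locus index outside 1..n_markers")
  }
  traits <- unique(c(causal_loci$trait,
                     if (!is.null(breed_effects)) breed_effects$trait,
                     names(residual_sd)))
  if (!length(traits)) traits <- trait_names()
  if (is.null(residual_sd)) {
    residual_sd <- stats::setNames(rep(1, length(traits)), traits)
  }
  if (any(residual_sd <= 0)) stop("residual_sd must be > 0")
  if (is.null(breed_effects)) {
    breed_effects <- tidyr::expand_grid(breed = breeds$breed, trait = traits) |>
      dplyr::mutate(baseline = 0, sex_effect = 0)
  }

  # marker map fixed at config time so planted indices are reproducible
  marker_map <- if (!is.null(markers)) {
    stopifnot(nrow(markers) == n_markers)
    tibble::as_tibble(markers)
  } else withr::with_seed(seed, {
    chrom <- sample(names(chromosome_lengths), n_markers, replace = TRUE,
                    prob = chromosome_lengths / sum(chromosome_lengths))
    pos <- floor(stats::runif(n_markers, 1, chromosome_lengths[chrom])) + 0
    ord <- order(match(chrom, names(chromosome_lengths)), pos)
    bases <- c("A", "C", "G", "T")
    ab <- t(replicate(n_markers, sample(bases, 2)))
    tibble::tibble(
      marker_id = sprintf("m%06d", seq_len(n_markers)),
      chromosome = chrom[ord], position_bp = as.integer(pos[ord]),
      allele_a = ab[, 1], allele_b = ab[, 2])
  })

  structure(list(
    breeds = tibble::as_tibble(breeds), types = types,
    n_markers = n_markers, chromosome_lengths = chromosome_lengths,
    markers = marker_map,
    f_type = f_type, f_breed = f_breed,
    causal_loci = tibble::as_tibble(causal_loci),
    differentiated_loci = tibble::as_tibble(differentiated_loci),
    breed_effects = tibble::as_tibble(breed_effects),
    residual_sd = residual_sd, traits = traits,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
}

# one Balding-Nichols drift step: Beta around p with dispersion f
drift <- function(p, f) {
  if (f == 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a genotype/phenotype panel
#'
#' Draws ancestral allele frequencies `p ~ Uniform(0.1, 0.9)` per marker,
#' drifts them to type level and then breed level with Beta
#' (Balding-Nichols) steps, overrides type-level frequencies at planted
#' differentiated loci, draws genotypes `Binomial(2, breed frequency)` per
#' individual, and builds trait values as breed baseline + sex effect +
#' sum of planted additive effects times dosage + Gaussian noise. Calls are
#' then dropped uniformly at the configured missing rate and dosages are
#' oriented to the dataset-wide minor allele.
#'
#' The same seed gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A list with `geno` ([geno_data()]), `traits` (trait table:
#'   `sample_id`, `trait`, `value`) and `truth` (truth ledger: list of
#'   `markers` — ancestral/type/breed frequencies of the simulated B allele
#'   and whether minor-orientation flipped the column; `causal` — planted
#'   effects, both per B allele and per minor allele; `differentiated`).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    M <- config$n_markers
    types <- config$types
    breeds <- config$breeds

    p_anc <- stats::runif(M, 0.1, 0.9)
    type_freq <- vapply(types, function(t) drift(p_anc, config$f_type),
                        numeric(M))
    if (nrow(config$differentiated_loci)) {
      d <- config$differentiated_loci
      for (t in types) {
        type_freq[d$marker, t] <- d[[paste0("freq_", t)]]
      }
    }
    breed_freq <- vapply(breeds$breed, function(b) {
      t <- breeds$type[breeds$breed == b]
      drift(type_freq[, t], config$f_breed)
    }, numeric(M))

    samples <- purrr::pmap_dfr(breeds, function(breed, type, n_male,
                                                n_female, ...) {
      tibble::tibble(breed = breed, type = type,
                     sex = c(rep("male", n_male), rep("female", n_female)))
    }) |>
      dplyr::mutate(sample_id = sprintf("s%03d", dplyr::row_number()),
                    .before = 1)

    N <- nrow(samples)
    dosage <- matrix(0L, N, M)
    for (b in breeds$breed) {
      rows <- which(samples$breed == b)
      dosage[rows, ] <- matrix(
        stats::rbinom(length(rows) * M, 2,
                      rep(breed_freq[, b], each = length(rows))),
        nrow = length(rows))
    }

    # phenotypes from the complete (pre-missingness) dosage of the B allele
    eff <- config$breed_effects
    traits_tbl <- tidyr::expand_grid(sample_id = samples$sample_id,
                                     trait = config$traits) |>
      dplyr::left_join(samples[, c("sample_id", "breed", "sex")],
                       by = "sample_id") |>
      dplyr::left_join(eff, by = c("breed", "trait")) |>
      dplyr::mutate(
        value = .data$baseline +
          ifelse(.data$sex == "male", .data$sex_effect, 0))
    if (nrow(config$causal_loci)) {
      for (k in seq_len(nrow(config$causal_loci))) {
        cl <- config$causal_loci[k, ]
        idx <- traits_tbl$trait == cl$trait
        add <- cl$effect * dosage[, cl$marker]
        traits_tbl$value[idx] <- traits_tbl$value[idx] +
          add[match(traits_tbl$sample_id[idx], samples$sample_id)]
      }
    }
    traits_tbl$value <- traits_tbl$value +
      stats::rnorm(nrow(traits_tbl), 0,
                   config$residual_sd[traits_tbl$trait])
    traits_tbl <- traits_tbl[, c("sample_id", "trait", "value")]

    if (config$missing_rate > 0) {
      drop <- stats::runif(length(dosage)) < config$missing_rate
      dosage[drop] <- NA_integer_
    }

    ds <- geno_data(dosage, config$markers,
                    samples[, c("sample_id", "breed", "type", "sex")])
    ds <- orient_minor(ds)
    flipped <- ds$markers$minor_allele == config$markers$allele_a

    truth_markers <- dplyr::bind_cols(
      config$markers[, c("marker_id", "chromosome", "position_bp")],
      tibble::tibble(p_ancestral = p_anc),
      tibble::as_tibble(type_freq, .name_repair = "minimal") |>
        stats::setNames(paste0("freq_", types)),
      tibble::as_tibble(breed_freq, .name_repair = "minimal") |>
        stats::setNames(paste0("freq_", breeds$breed)),
      tibble::tibble(flipped = flipped))
    truth_causal <- config$causal_loci |>
      dplyr::mutate(marker_id = config$markers$marker_id[.data$marker],
                    effect_minor = ifelse(flipped[.data$marker],
                                          -.data$effect, .data$effect))
    truth_diff <- config$differentiated_loci |>
      dplyr::mutate(marker_id = config$markers$marker_id[.data$marker])

    list(geno = ds, traits = traits_tbl,
         truth = list(markers = truth_markers, causal = truth_causal,
                      differentiated = truth_diff))
  })
}

#' Panel-scale default configuration
#'
#' A configuration that emulates the structure of a diversity panel of 201
#' chickens: 9 breeds (4 game-type, 5 bantam-type) with per-breed sample
#' sizes 19, 30, 25, 20 and 22, 29, 20, 18, 18, near sex-balanced; 6,000
#' markers over 5 chromosomes; the two types differing on all five
#' body-size traits; a handful of planted additive loci per trait; ~30
#' planted type-differentiated loci (frequencies 0.9 vs 0.1), including a
#' cluster on chromosome 4 in which one locus is simultaneously causal for
#' keel length and body weight — a region detectable by both the
#' association scan and the PCA contribution scan.
#'
#' @param seed Integer seed.
#' @param n_markers Number of markers (default 6000).
#' @return A [sim_config()].
#' @export
sim_config_panel <- function(seed = 1L, n_markers = 6000L) {
  breeds <- tibble::tibble(
    breed = c("game1", "game2", "game3", "game4",
              "bantam1", "bantam2", "bantam3", "bantam4", "bantam5"),
    type = rep(c("game", "bantam"), c(4, 5)),
    n_male = c(9, 15, 12, 10, 10, 13, 10, 8, 10),
    n_female = c(10, 15, 13, 10, 12, 16, 10, 10, 8))

  chrom_len <- c(chr1 = 196e6, chr2 = 150e6, chr3 = 110e6,
                 chr4 = 91e6, chrZ = 82e6)

  type_baseline <- tibble::tribble(
    ~trait,               ~game, ~bantam, ~sex_effect, ~sd,
    "wing_length_cm",      24.0,    16.0,         2.0, 1.00,
    "shank_length_cm",     11.0,     5.5,         1.0, 0.60,
    "shank_thickness_mm",  16.0,    10.0,         1.5, 0.90,
    "keel_length_cm",      14.0,     8.0,         1.0, 0.80,
    "body_weight_kg",       3.2,     0.9,         0.4, 0.25)

  breed_effects <- withr::with_seed(seed + 1000L, {
    tidyr::expand_grid(breed = breeds$breed, trait = type_baseline$trait) |>
      dplyr::left_join(breeds[, c("breed", "type")], by = "breed") |>
      dplyr::left_join(type_baseline, by = "trait") |>
      dplyr::mutate(
        base_type = ifelse(.data$type == "game", .data$game, .data$bantam),
        baseline = .data$base_type *
          (1 + stats::runif(dplyr::n(), -0.05, 0.05))) |>
      dplyr::select("breed", "trait", "baseline", "sex_effect")
  })
  residual_sd <- stats::setNames(type_baseline$sd, type_baseline$trait)

  cfg0 <- sim_config(breeds, n_markers, chrom_len,
                     f_type = 0.10, f_breed = 0.10,
                     breed_effects = breed_effects,
                     residual_sd = residual_sd,
                     missing_rate = 0.002, seed = seed)

  # plant loci on the fixed marker map; guarantee a 5-marker cluster in
  # the chromosome-4 window by relocating the nearest chr4 markers there
  map <- cfg0$markers
  chr4 <- which(map$chromosome == "chr4")
  if (length(chr4) < 25) {
    stop("too few markers on chr4 for the planted window")
  }
  win_pos <- seq(17.4e6, 21.0e6, by = 0.15e6)  # 25 markers, causal mid
  move <- chr4[order(abs(map$position_bp[chr4] - 19e6))[1:25]]
  map$position_bp[move] <- as.integer(win_pos)
  ord <- order(match(map$chromosome, names(chrom_len)), map$position_bp)
  map <- map[ord, ]
  map$marker_id <- sprintf("m%06d", seq_len(n_markers))
  pick <- function(chrom, lo, hi, n) {
    cand <- which(map$chromosome == chrom & map$position_bp >= lo &
                    map$position_bp <= hi)
    cand[seq_len(min(n, length(cand)))]
  }
  # chromosome-4 window mirroring the dual-detection region: the middle
  # marker is causal for keel length and body weight and segregates within
  # breeds (the association scan needs within-breed variance), while its
  # neighbours are strongly type-differentiated (what the PCA
  # contribution scan detects); the two scans' regions overlap there
  win <- which(map$chromosome == "chr4" &
                 map$position_bp %in% as.integer(win_pos))
  coincident <- win[13]

  planted <- function(chrom, lo, hi, n, trait, effects) {
    idx <- pick(chrom, lo, hi, n)
    tibble::tibble(marker = idx, trait = trait,
                   effect = effects[seq_along(idx)])
  }
  causal <- dplyr::bind_rows(
    tibble::tibble(marker = coincident, trait = "keel_length_cm",
                   effect = -0.9),
    tibble::tibble(marker = coincident, trait = "body_weight_kg",
                   effect = 0.25),
    planted("chr1", 60e6, 90e6, 1, "wing_length_cm", 1.1),
    planted("chr2", 25e6, 60e6, 2, "shank_thickness_mm", c(1.0, -0.9)),
    planted("chr1", 140e6, 160e6, 1, "body_weight_kg", 0.28),
    planted("chr3", 5e6, 40e6, 1, "keel_length_cm", 0.85),
    planted("chrZ", 50e6, 70e6, 1, "shank_length_cm", 0.7))

  diff_idx <- withr::with_seed(seed + 2000L, {
    others <- setdiff(seq_len(n_markers), c(causal$marker, win))
    sort(sample(others, 26))
  })
  # frequency control: flanking chr4 markers strongly differentiated
  # between types (the region driving the main body-size contrast) while
  # keeping the heterozygote class above the masking floor; the causal
  # marker held at 0.15 in both types so it segregates within every
  # breed; the background set differentiated but less extreme
  flank <- setdiff(win, coincident)
  differentiated <- tibble::tibble(
    marker = c(flank, coincident, diff_idx),
    freq_game = c(rep(0.93, length(flank)), 0.25,
                  rep(0.9, length(diff_idx))),
    freq_bantam = c(rep(0.07, length(flank)), 0.25,
                    rep(0.1, length(diff_idx))))

  sim_config(breeds, n_markers, chrom_len,
             f_type = 0.10, f_breed = 0.10,
             causal_loci = causal,
             differentiated_loci = differentiated,
             breed_effects = breed_effects,
             residual_sd = residual_sd,
             missing_rate = 0.002, seed = seed, markers = map)
}

#' Write a truth ledger to TSV files
#'
#' @param truth The `truth` element of a [simulate_panel()] result.
#' @param stem Output path stem.
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, stem) {
  paths <- paste0(stem, c("_truth_markers.tsv", "_truth_causal.tsv",
                          "_truth_differentiated.tsv"))
  readr::write_tsv(truth$markers, paths[1])
  readr::write_tsv(truth$causal, paths[2])
  readr::write_tsv(truth$differentiated, paths[3])
  invisible(paths)
}
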