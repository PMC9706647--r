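#' Minor allele frequency from genotype-class counts
#'
#' @param n_aa,n_ab,n_bb Individuals counted in the three genotype classes
#'   (homozygous A, heterozygous, homozygous B); missing individuals are
#'   excluded from the counts.
#' @param allele_a,allele_b Allele labels for naming the minor allele.
#'
#' @return A one-row tibble with `minor_allele` and `maf`, where
#'   `maf = (2 n_minor_hom + n_het) / (2 n_total)`, always at most 0.5.
#'   With both alleles at frequency 0.5 the lexicographically smaller
#'   label is reported as minor.
#'
#' @examples
#' compute_maf(15, 18, 167, "C", "T")  # minor C, MAF 0.12
#' @export
compute_maf <- function(n_aa, n_ab, n_bb, allele_a = "A", allele_b = "B") {
  n_total <- n_aa + n_ab + n_bb
  if (n_total == 0) stop("no genotyped individuals (all counts zero)")
  f_b <- (2 * n_bb + n_ab) / (2 * n_total)
  minor <- if (f_b < 0.5) allele_b
           else if (f_b > 0.5) allele_a
           else min(allele_a, allele_b)
  tibble::tibble(minor_allele = minor, maf = min(f_b, 1 - f_b))
}

# per-marker call rate relative to the full sample roster
call_rates <- function(ds) colMeans(!is.na(ds$dosage))

# per-marker polymorphism among non-missing calls
is_polymorphic <- function(ds) {
  rng <- apply(ds$dosage, 2, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) > 1
  })
  rng
}

#' Marker filter cascade: call rate, monomorphism, MAF
#'
#' Removes, in this order: markers with call rate strictly below
#' `call_rate_min`; markers monomorphic among non-missing calls; markers
#' with minor allele frequency strictly below `maf_min`. Boundary values
#' (call rate exactly `call_rate_min`, MAF exactly `maf_min`) are kept.
#'
#' @param ds A [geno_data()] object.
#' @param call_rate_min Minimum call rate kept (default 0.95).
#' @param maf_min Minimum MAF kept (default 0.05).
#'
#' @return A list with `geno` (the filtered dataset) and `report`, a
#'   tibble with one row per rule: `rule`, `n_input`, `n_removed`,
#'   `n_survivors`.
#' @export
filter_markers <- function(ds, call_rate_min = 0.95, maf_min = 0.05) {
  report <- list()
  n0 <- n_markers(ds)

  keep <- call_rates(ds) >= call_rate_min
  report$call_rate <- tibble::tibble(
    rule = "call_rate", n_input = n0,
    n_removed = sum(!keep), n_survivors = sum(keep))
  ds <- subset_geno(ds, markers = keep)

  keep <- is_polymorphic(ds)
  report$monomorphic <- tibble::tibble(
    rule = "monomorphic", n_input = n_markers(ds) + 0L,
    n_removed = sum(!keep), n_survivors = sum(keep))
  report$monomorphic$n_input <- report$call_rate$n_survivors
  ds <- subset_geno(ds, markers = keep)

  keep <- marker_maf(ds)$maf >= maf_min
  report$maf <- tibble::tibble(
    rule = "maf", n_input = report$monomorphic$n_survivors,
    n_removed = sum(!keep), n_survivors = sum(keep))
  ds <- subset_geno(ds, markers = keep)

  list(geno = ds, report = dplyr::bind_rows(report))
}

#' Mask small genotype classes, then re-filter
#'
#' Per marker, any genotype class (dosage 0, 1 or 2) observed in strictly
#' fewer than `min_class` individuals has those calls set to missing —
#' small classes drive spurious associations. The marker filter cascade is
#' then re-applied with the same thresholds, since masking can push a
#' marker below the call-rate floor or make it monomorphic.
#'
#' @param ds A [geno_data()] object that already passed [filter_markers()].
#' @param min_class Minimum class size kept intact (default 10; a class of
#'   exactly `min_class` is untouched).
#' @param call_rate_min,maf_min Thresholds for the re-applied filter.
#'
#' @return A list with `geno` and `report` (the re-filter report plus a
#'   leading row `rule = "mask"` whose `n_removed` is the count of masked
#'   genotype calls, not markers).
#' @export
mask_small_genotype_classes <- function(ds, min_class = 10,
                                        call_rate_min = 0.95,
                                        maf_min = 0.05) {
  dosage <- ds$dosage
  masked <- 0L
  for (j in seq_len(ncol(dosage))) {
    g <- dosage[, j]
    tab <- tabulate(g + 1L, nbins = 3L)
    small <- which(tab > 0 & tab < min_class) - 1L
    if (length(small)) {
      hit <- !is.na(g) & g %in% small
      dosage[hit, j] <- NA_integer_
      masked <- masked + sum(hit)
    }
  }
  ds2 <- geno_data(dosage, ds$markers, ds$samples)
  ref <- filter_markers(ds2, call_rate_min = call_rate_min,
                        maf_min = maf_min)
  mask_row <- tibble::tibble(rule = "mask", n_input = n_markers(ds),
                             n_removed = masked,
                             n_survivors = n_markers(ds))
  list(geno = ref$geno, report = dplyr::bind_rows(mask_row, ref$report))
}

#' Keep only markers with complete genotype data
#'
#' Principal component analysis needs a complete matrix; markers with any
#' missing call are dropped.
#'
#' @param ds A [geno_data()] object.
#' @return A `geno_data` whose every marker has call rate exactly 1.
#' @export
complete_case_markers <- function(ds) {
  keep <- colSums(is.na(ds$dosage)) == 0
  subset_geno(ds, markers = keep)
}
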