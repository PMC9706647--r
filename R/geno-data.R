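#' Genotype dataset container
#'
#' A `geno_data` object bundles a sample-by-marker dosage matrix with its
#' marker map and sample metadata. Dosages count copies of the dataset-wide
#' minor allele of each marker (0, 1, 2), with missing calls stored as `NA`.
#'
#' @param dosage Integer matrix, samples in rows and markers in columns.
#'   Values must be 0, 1, 2 or `NA`. Row names are ignored; sample order is
#'   taken from `samples`.
#' @param markers A data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b` (and optionally `minor_allele`),
#'   one row per dosage column, in column order.
#' @param samples A data frame with columns `sample_id`, `breed`, `type`,
#'   `sex`, one row per dosage row, in row order.
#'
#' @return An object of class `geno_data`: a list with elements `dosage`
#'   (matrix), `markers` (tibble) and `samples` (tibble).
#'
#' @details Marker ids must be unique, positions non-negative and the two
#'   alleles of a marker distinct; every sample's breed must map to exactly
#'   one type. Construction fails otherwise. Use [orient_minor()] to flip
#'   dosages so that each column counts the dataset-wide minor allele.
#'
#' @examples
#' ds <- geno_data(
#'   dosage  = matrix(c(0L, 1L, 2L, 0L), nrow = 2),
#'   markers = data.frame(marker_id = c("m1", "m2"), chromosome = "1",
#'                        position_bp = c(100L, 200L),
#'                        allele_a = "A", allele_b = "C"),
#'   samples = data.frame(sample_id = c("s1", "s2"), breed = "B1",
#'                        type = "T1", sex = c("male", "female"))
#' )
#' ds
#' @export
geno_data <- function(dosage, markers, samples) {
  markers <- tibble::as_tibble(markers)
  samples <- tibble::as_tibble(samples)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"

  need_m <- c("marker_id", "chromosome", "position_bp", "allele_a", "allele_b")
  need_s <- c("sample_id", "breed", "type", "sex")
  if (!all(need_m %in% names(markers))) {
    stop("`markers` must have columns: ", paste(need_m, collapse = ", "))
  }
  if (!all(need_s %in% names(samples))) {
    stop("`samples` must have columns: ", paste(need_s, collapse = ", "))
  }
  if (nrow(samples) != nrow(dosage) || nrow(markers) != ncol(dosage)) {
    stop("dosage is ", nrow(dosage), " x ", ncol(dosage),
         " but there are ", nrow(samples), " samples and ",
         nrow(markers), " markers")
  }
  if (anyDuplicated(markers$marker_id)) stop("duplicated marker_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  if (any(markers$position_bp < 0)) stop("negative position_bp")
  if (any(markers$allele_a == markers$allele_b)) {
    stop("marker with identical alleles: ",
         markers$marker_id[markers$allele_a == markers$allele_b][1])
  }
  bt <- unique(samples[, c("breed", "type")])
  if (anyDuplicated(bt$breed)) {
    stop("breed mapped to more than one type: ",
         bt$breed[duplicated(bt$breed)][1])
  }
  bad <- dosage[!is.na(dosage) & !(dosage %in% 0:2)]
  if (length(bad)) stop("dosage values must be 0, 1, 2 or NA")

  dimnames(dosage) <- list(samples$sample_id, markers$marker_id)
  structure(list(dosage = dosage, markers = markers, samples = samples),
            class = "geno_data")
}

#' @export
print.geno_data <- function(x, ...) {
  cat("<geno_data> ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " markers\n", sep = "")
  cat("  breeds: ", paste(levels(factor(x$samples$breed)), collapse = ", "),
      "\n", sep = "")
  cat("  types:  ", paste(levels(factor(x$samples$type)), collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_data <- function(x) dim(x$dosage)

#' Number of samples / markers in a genotype dataset
#' @param ds A [geno_data()] object.
#' @return An integer count.
#' @export
n_samples <- function(ds) nrow(ds$dosage)

#' @rdname n_samples
#' @export
n_markers <- function(ds) ncol(ds$dosage)

#' Subset a genotype dataset by marker or sample index
#'
#' @param ds A [geno_data()] object.
#' @param markers,samples Logical or integer index into markers / samples;
#'   `NULL` keeps all.
#' @return A `geno_data` with the selected rows/columns.
#' @export
subset_geno <- function(ds, markers = NULL, samples = NULL) {
  if (is.null(markers)) markers <- seq_len(n_markers(ds))
  if (is.null(samples)) samples <- seq_len(n_samples(ds))
  geno_data(ds$dosage[samples, markers, drop = FALSE],
            ds$markers[markers, , drop = FALSE],
            ds$samples[samples, , drop = FALSE])
}

#' Orient dosages to the dataset-wide minor allele
#'
#' Flips each marker's dosage column so that it counts copies of the allele
#' that is rarer across the whole dataset. Ties (allele frequency exactly
#' 0.5) are oriented to the lexicographically smaller allele label. The
#' `minor_allele` column of the marker map is set accordingly.
#'
#' @param ds A [geno_data()] object whose dosages count `allele_b`.
#' @return A `geno_data` whose dosages count the minor allele, with
#'   `minor_allele` filled in the marker map.
#' @export
orient_minor <- function(ds) {
  freq_b <- colMeans(ds$dosage, na.rm = TRUE) / 2
  flip <- freq_b > 0.5 |
    (abs(freq_b - 0.5) < 1e-12 & ds$markers$allele_a < ds$markers$allele_b)
  dosage <- ds$dosage
  dosage[, flip] <- 2L - dosage[, flip, drop = FALSE]
  markers <- ds$markers
  markers$minor_allele <- unname(
    ifelse(flip, markers$allele_a, markers$allele_b))
  geno_data(dosage, markers, ds$samples)
}

#' Per-marker minor allele frequency of a genotype dataset
#'
#' @param ds A [geno_data()] object (minor-allele dosage coding).
#' @return A tibble with `marker_id` and `maf` (frequency of the rarer
#'   allele among non-missing calls, always at most 0.5).
#' @export
marker_maf <- function(ds) {
  f <- colMeans(ds$dosage, na.rm = TRUE) / 2
  tibble::tibble(marker_id = ds$markers$marker_id, maf = pmin(f, 1 - f))
}
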