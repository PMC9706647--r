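#' Canonical body-size trait names
#'
#' The five traits the pipeline measures, with units in the name.
#' @return Character vector of trait names.
#' @export
trait_names <- function() {
  c("wing_length_cm", "shank_length_cm", "shank_thickness_mm",
    "keel_length_cm", "body_weight_kg")
}

#' Read genotypes from VCF or a dosage-table trio
#'
#' Reads biallelic SNP genotypes into a [geno_data()] object with dosages
#' oriented to the dataset-wide minor allele. Missing calls are preserved
#' as `NA`.
#'
#' @param path For `format = "vcf"`, path to a VCF file. For
#'   `format = "dosage_table"`, path to a TSV with a header row of marker
#'   ids and one row per sample (first column `sample_id`); the marker map
#'   and sample metadata are read from `map_path` / `samples_path`.
#' @param format `"vcf"` or `"dosage_table"`.
#' @param samples_path TSV with columns `sample_id`, `breed`, `type`,
#'   `sex`. Required for both formats (a VCF does not carry breed labels).
#' @param map_path TSV with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`. Required for `dosage_table`.
#'
#' @return A [geno_data()] object.
#' @export
read_genotypes <- function(path, format = c("dosage_table", "vcf"),
                           samples_path = NULL, map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(samples_path) || !file.exists(samples_path)) {
    stop("sample metadata file required (samples_path)")
  }
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)

  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                           stringsAsFactors = FALSE))
    multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
    if (any(multi)) {
      stop("non-biallelic-SNP record: ",
           paste(fix$ID[multi][seq_len(min(3, sum(multi)))], collapse = ", "))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    # dosage of ALT allele; accept phased or unphased separators
    alt_count <- function(x) {
      a <- strsplit(x, "[/|]")
      vapply(a, function(al) {
        if (any(al == ".") || length(al) != 2) return(NA_integer_)
        sum(al == "1")
      }, integer(1))
    }
    dos <- apply(gt, 2, alt_count)
    if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1)
    dos <- t(dos)  # samples x markers
    markers <- tibble::tibble(
      marker_id = fix$ID, chromosome = fix$CHROM,
      position_bp = as.integer(fix$POS),
      allele_a = fix$REF, allele_b = fix$ALT)
    vcf_samples <- colnames(gt)
    missing_meta <- setdiff(vcf_samples, samples$sample_id)
    if (length(missing_meta)) {
      stop("sample metadata missing samples: ",
           paste(missing_meta, collapse = ", "))
    }
    samples <- samples[match(vcf_samples, samples$sample_id), ]
    ds <- geno_data(dos, markers, samples)
    return(orient_minor(ds))
  }

  if (is.null(map_path) || !file.exists(map_path)) {
    stop("marker map file required (map_path) for dosage_table format")
  }
  markers <- readr::read_tsv(map_path, show_col_types = FALSE)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(tab)[1] != "sample_id") {
    stop("dosage table must have sample_id as its first column")
  }
  ids <- tab$sample_id
  dos <- as.matrix(tab[, -1, drop = FALSE])
  if (ncol(dos) != nrow(markers)) {
    stop("dosage table has ", ncol(dos), " marker columns but the marker ",
         "map has ", nrow(markers), " rows")
  }
  if (!identical(colnames(dos), markers$marker_id)) {
    stop("dosage table marker columns do not match the marker map order")
  }
  missing_meta <- setdiff(ids, samples$sample_id)
  if (length(missing_meta)) {
    stop("sample metadata missing samples: ",
         paste(missing_meta, collapse = ", "))
  }
  samples <- samples[match(ids, samples$sample_id), ]
  ds <- geno_data(dos, markers, samples)
  orient_minor(ds)
}

#' Write a genotype dataset as a dosage-table trio
#'
#' Writes three TSV files: the dosage table (`<stem>_dosage.tsv`), the
#' marker map (`<stem>_markers.tsv`) and the sample metadata
#' (`<stem>_samples.tsv`). Reading them back with [read_genotypes()]
#' reproduces the dataset exactly.
#'
#' @param ds A [geno_data()] object.
#' @param stem Output path stem (directory + file prefix).
#' @return Invisibly, the three paths written.
#' @export
write_genotypes <- function(ds, stem) {
  paths <- paste0(stem, c("_dosage.tsv", "_markers.tsv", "_samples.tsv"))
  dos <- tibble::as_tibble(ds$dosage, .name_repair = "minimal")
  names(dos) <- ds$markers$marker_id
  dos <- dplyr::bind_cols(tibble::tibble(sample_id = ds$samples$sample_id), dos)
  readr::write_tsv(dos, paths[1])
  readr::write_tsv(ds$markers, paths[2])
  readr::write_tsv(ds$samples, paths[3])
  invisible(paths)
}

#' Read a phenotype table
#'
#' Expects a TSV with `sample_id`, `sex` and one column per trait. Any of
#' the canonical traits ([trait_names()]) that are absent are skipped with
#' a warning. Non-numeric cells become missing values.
#'
#' @param path TSV file path.
#' @return A trait table: tibble with `sample_id`, `trait`, `value` (raw,
#'   in trait units), one row per sample per available trait.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (anyDuplicated(tab$sample_id)) {
    stop("duplicated sample_id in phenotype file: ",
         tab$sample_id[duplicated(tab$sample_id)][1])
  }
  have <- intersect(trait_names(), names(tab))
  absent <- setdiff(trait_names(), names(tab))
  if (length(absent)) {
    warning("phenotype file missing trait column(s): ",
            paste(absent, collapse = ", "))
  }
  tab |>
    dplyr::select(dplyr::all_of(c("sample_id", have))) |>
    tidyr::pivot_longer(dplyr::all_of(have),
                        names_to = "trait", values_to = "value") |>
    dplyr::mutate(value = suppressWarnings(as.numeric(.data$value)))
}

#' Write a phenotype table
#'
#' Inverse of [read_phenotypes()]: pivots the long trait table to one
#' column per trait. If `samples` is supplied a `sex` column is included.
#'
#' @param traits Trait table (`sample_id`, `trait`, `value`).
#' @param path Output TSV path.
#' @param samples Optional sample metadata with `sample_id`, `sex`.
#' @return Invisibly, `path`.
#' @export
write_phenotypes <- function(traits, path, samples = NULL) {
  wide <- tidyr::pivot_wider(traits[, c("sample_id", "trait", "value")],
                             names_from = "trait", values_from = "value")
  if (!is.null(samples)) {
    wide <- dplyr::left_join(wide,
                             dplyr::select(samples, "sample_id", "sex"),
                             by = "sample_id") |>
      dplyr::relocate("sex", .after = "sample_id")
  }
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write merged regions as BED plus a statistics sidecar
#'
#' Internal coordinates are 1-based inclusive; the BED file is written
#' 0-based half-open (start decremented by one). A TSV sidecar at
#' `<path>.tsv` carries the top-marker statistics. Regions are sorted by
#' chromosome then start.
#'
#' @param regions Region tibble as produced by [merge_ld_regions()] or
#'   [merge_distance_regions()]; must have `chromosome`, `start_bp`,
#'   `end_bp`, `top_marker`, `source`.
#' @param path Output BED path.
#' @return Invisibly, `path`.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) > 0 && any(regions$start_bp > regions$end_bp)) {
    stop("region with start > end")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname (0-based half-open)", con)
  if (nrow(regions) > 0) {
    out <- regions |>
      dplyr::arrange(.data$chromosome, .data$start_bp) |>
      dplyr::mutate(bed_start = .data$start_bp - 1L,
                    name = paste0(.data$source, ":", .data$top_marker))
    writeLines(paste(out$chromosome, out$bed_start, out$end_bp, out$name,
                     sep = "\t"), con)
  }
  side <- regions |>
    dplyr::select(-dplyr::any_of("marker_ids")) |>
    dplyr::arrange(.data$chromosome, .data$start_bp)
  readr::write_tsv(side, paste0(path, ".tsv"))
  invisible(path)
}

#' Read a labelled interval file (BED)
#'
#' Reads a BED file (0-based half-open) with an optional fourth label
#' column into 1-based inclusive internal coordinates. Comment lines
#' starting with `#` are skipped.
#'
#' @param path BED file path.
#' @return Tibble with `chromosome`, `start_bp`, `end_bp` (1-based
#'   inclusive) and `label`.
#' @export
read_intervals <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (!length(lines)) {
    return(tibble::tibble(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), label = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(parts)
  bad <- which(n < 3)
  if (length(bad)) stop("malformed BED line ", line_no[bad[1]])
  start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  end0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  if (anyNA(start0) || anyNA(end0)) {
    stop("malformed BED line ",
         line_no[which(is.na(start0) | is.na(end0))[1]])
  }
  tibble::tibble(
    chromosome = vapply(parts, `[`, "", 1),
    start_bp = start0 + 1L,
    end_bp = end0,
    label = ifelse(n >= 4, vapply(parts, function(p) p[4], ""), NA_character_))
}
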