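#' Run the full dual genome scan in memory
#'
#' Orchestrates the analysis stages in the canonical order: marker filter
#' cascade; hierarchical clustering on the post-filter (pre-masking)
#' marker set; small genotype-class masking and re-filter; within-breed
#' sex correction and type comparison of phenotypes; per-trait breed-
#' adjusted association scan with BH-FDR and LD region merging; complete-
#' case reduction and the PCA contribution scan with distance-based
#' region merging. When a trait yields more than `strict_over`
#' FDR-significant markers, the stricter `fdr_strict` screen is applied to
#' that trait before region merging (the secondary screen used when one
#' trait dominates the scan).
#'
#' @param ds A [geno_data()] object (raw, minor-allele coded).
#' @param traits Trait table (`sample_id`, `trait`, `value`).
#' @param known Optional tibble of known labelled intervals (see
#'   [read_intervals()]) for overlap reporting.
#' @param call_rate_min,maf_min,min_class QC thresholds (defaults 0.95,
#'   0.05, 10).
#' @param fdr_threshold,fdr_strict,strict_over Association significance
#'   screens (defaults 0.05, 0.01, 100).
#' @param r2_min LD region-merging threshold (default 0.5).
#' @param component,bonferroni_alpha,max_gap PCA scan settings (defaults
#'   1, 0.05, 2e6).
#' @param cluster_k Flat clusters for outlier flagging (default: number
#'   of breeds).
#' @return A `size_scan` list: `qc_filter`, `qc_mask` (reports),
#'   `cluster` (assignments tibble), `tree` (`hclust`),
#'   `pheno_comparison`, `traits_corrected`, `assoc` (per-marker tibble),
#'   `assoc_summary`, `assoc_regions`, `pca` (records), `pca_model`,
#'   `pca_regions`, `pc_trait_cor`, `overlap` (or `NULL`), and `log`
#'   (per-stage marker counts).
#' @export
run_scan <- function(ds, traits, known = NULL,
                     call_rate_min = 0.95, maf_min = 0.05, min_class = 10,
                     fdr_threshold = 0.05, fdr_strict = 0.01,
                     strict_over = 100, r2_min = 0.5,
                     component = 1, bonferroni_alpha = 0.05, max_gap = 2e6,
                     cluster_k = NULL) {
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, n_markers_in = n_in, n_markers_out = n_out)
  }

  n_raw <- n_markers(ds)
  flt <- filter_markers(ds, call_rate_min, maf_min)
  note("filter_markers", n_raw, n_markers(flt$geno))

  if (is.null(cluster_k)) cluster_k <- dplyr::n_distinct(ds$samples$breed)
  tree <- complete_linkage(genotype_distance(flt$geno))
  clus <- cluster_assignments(tree, flt$geno$samples, k = cluster_k)
  note("cluster", n_markers(flt$geno), n_markers(flt$geno))

  msk <- mask_small_genotype_classes(flt$geno, min_class,
                                     call_rate_min, maf_min)
  note("mask_small_genotype_classes", n_markers(flt$geno),
       n_markers(msk$geno))
  gwas_ds <- msk$geno

  corrected <- sex_correct(traits, ds$samples)
  comparison <- compare_types(traits, ds$samples)

  scan <- assoc_scan(gwas_ds, corrected)
  summ <- scan_summary(scan)
  sig <- scan |>
    dplyr::filter(!is.na(.data$q), .data$q < fdr_threshold) |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) > strict_over) {
        g <- dplyr::filter(g, .data$q < fdr_strict)
      }
      g
    }) |>
    dplyr::ungroup()
  assoc_regions <- purrr::map_dfr(unique(sig$trait), function(tr) {
    merge_ld_regions(dplyr::filter(sig, .data$trait == tr), gwas_ds,
                     r2_min = r2_min, source = paste0("assoc:", tr))
  })
  note("assoc_scan", n_markers(gwas_ds), n_markers(gwas_ds))

  pca_ds <- complete_case_markers(gwas_ds)
  note("complete_case_markers", n_markers(gwas_ds), n_markers(pca_ds))
  pca <- pca_scan(pca_ds, component = component, alpha = bonferroni_alpha,
                  max_gap = max_gap)
  note("pca_scan", n_markers(pca_ds), n_markers(pca_ds))
  pc_cor <- pc_trait_correlation(pca$model, traits, component = component)

  all_regions <- dplyr::bind_rows(assoc_regions, pca$regions)
  overlap <- if (!is.null(known)) overlap_regions(all_regions, known)

  structure(list(
    qc_filter = flt$report, qc_mask = msk$report,
    cluster = clus, tree = tree,
    pheno_comparison = comparison, traits_corrected = corrected,
    assoc = scan, assoc_summary = summ, assoc_regions = assoc_regions,
    pca = pca$records, pca_model = pca$model, pca_regions = pca$regions,
    pc_trait_cor = pc_cor, overlap = overlap,
    log = dplyr::bind_rows(log)), class = "size_scan")
}

#' @export
print.size_scan <- function(x, ...) {
  cat("<size_scan>\n")
  cat("  stages:\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("    %-28s %6d -> %6d markers\n", x$log$stage[i],
                x$log$n_markers_in[i], x$log$n_markers_out[i]))
  }
  cat("  association regions: ", nrow(x$assoc_regions),
      "; PCA regions: ", nrow(x$pca_regions), "\n", sep = "")
  invisible(x)
}

#' Run the pipeline from files and write every output
#'
#' File-level wrapper around [run_scan()]: reads the genotype trio (or
#' VCF), the phenotype table and an optional known-interval BED, runs the
#' scan, and writes corrected phenotypes, the type comparison, cluster
#' assignments (TSV + Newick tree), the full per-marker association
#' table, the PCA records and scores, both region sets (BED + TSV
#' sidecars), the overlap report and the stage log into `out_dir`.
#' Identical inputs give identical outputs (the analysis is
#' deterministic). On a stage failure a `FAILED` sentinel file naming the
#' stage is left in `out_dir` and the error is rethrown.
#'
#' @param genotypes Path stem of a dosage-table trio (as written by
#'   [write_genotypes()]) or a VCF path.
#' @param phenotypes Phenotype TSV path.
#' @param out_dir Output directory (created if needed).
#' @param samples Sample metadata TSV path.
#' @param format `"dosage_table"` or `"vcf"`.
#' @param known Optional BED path of known labelled intervals.
#' @param ... Thresholds passed to [run_scan()].
#' @return Invisibly, the [run_scan()] result.
#' @export
run_all <- function(genotypes, phenotypes, out_dir, samples = NULL,
                    format = "dosage_table", known = NULL, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  res <- tryCatch({
    ds <- if (format == "dosage_table") {
      read_genotypes(paste0(genotypes, "_dosage.tsv"),
                     format = "dosage_table",
                     samples_path = if (is.null(samples))
                       paste0(genotypes, "_samples.tsv") else samples,
                     map_path = paste0(genotypes, "_markers.tsv"))
    } else {
      read_genotypes(genotypes, format = "vcf", samples_path = samples)
    }
    traits <- read_phenotypes(phenotypes)
    known_tbl <- if (!is.null(known)) read_intervals(known)
    stage <- "scan"
    run_scan(ds, traits, known = known_tbl, ...)
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(e)
  })

  out <- function(f) file.path(out_dir, f)
  readr::write_tsv(res$traits_corrected, out("phenotypes_corrected.tsv"))
  readr::write_tsv(res$pheno_comparison, out("type_comparison.tsv"))
  readr::write_tsv(res$cluster, out("cluster_assignments.tsv"))
  write_newick(res$tree, out("dendrogram.nwk"))
  readr::write_tsv(res$assoc, out("assoc_scan.tsv"))
  readr::write_tsv(res$assoc_summary, out("assoc_summary.tsv"))
  readr::write_tsv(res$pca, out("pca_records.tsv"))
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(sample_id = res$pca_model$samples$sample_id),
                     tibble::as_tibble(res$pca_model$scores[, 1:min(5,
                       ncol(res$pca_model$scores)), drop = FALSE])),
    out("pca_scores.tsv"))
  readr::write_tsv(res$pc_trait_cor, out("pc_trait_correlation.tsv"))
  write_regions(res$assoc_regions, out("assoc_regions.bed"))
  write_regions(res$pca_regions, out("pca_regions.bed"))
  if (!is.null(res$overlap)) {
    readr::write_tsv(res$overlap, out("region_overlap.tsv"))
  }
  readr::write_tsv(dplyr::bind_rows(res$qc_filter, res$qc_mask),
                   out("qc_report.tsv"))
  readr::write_tsv(res$log, out("stage_log.tsv"))
  invisible(res)
}
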