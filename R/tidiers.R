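#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PCA model: per-sample component coordinates
#'
#' @param x A [run_pca()] fit.
#' @param n_components Components to keep (default 5).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `breed`, `type` and one `PC<k>`
#'   column per kept component.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, n_components = 5, ...) {
  k <- min(n_components, ncol(x$scores))
  dplyr::bind_cols(
    x$samples[, c("sample_id", "breed", "type")],
    tibble::as_tibble(x$scores[, seq_len(k), drop = FALSE]))
}

#' Glance at a PCA model: component variance summary
#'
#' @param x A [run_pca()] fit.
#' @param ... Unused.
#' @return One-row tibble: `n_samples`, `n_markers`, `pc1_var_pct`,
#'   `pc2_var_pct`.
#' @method glance pca_model
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores), n_markers = nrow(x$rotation),
    pc1_var_pct = 100 * x$var_explained[1],
    pc2_var_pct = 100 * x$var_explained[2])
}

#' Tidy a pipeline run: all merged regions
#'
#' @param x A [run_scan()] result.
#' @param ... Unused.
#' @return Tibble of association and PCA regions.
#' @method tidy size_scan
#' @export
tidy.size_scan <- function(x, ...) {
  dplyr::bind_rows(x$assoc_regions, x$pca_regions)
}

#' Glance at a pipeline run
#'
#' @param x A [run_scan()] result.
#' @param ... Unused.
#' @return One-row tibble: marker counts per stage, region counts, the
#'   lambda range over traits and PC1 variance.
#' @method glance size_scan
#' @export
glance.size_scan <- function(x, ...) {
  tibble::tibble(
    n_markers_filtered = x$log$n_markers_out[x$log$stage == "filter_markers"],
    n_markers_gwas =
      x$log$n_markers_out[x$log$stage == "mask_small_genotype_classes"],
    n_markers_pca = x$log$n_markers_out[x$log$stage == "complete_case_markers"],
    n_assoc_regions = nrow(x$assoc_regions),
    n_pca_regions = nrow(x$pca_regions),
    lambda_min = min(x$assoc_summary$lambda),
    lambda_max = max(x$assoc_summary$lambda),
    pc1_var_pct = 100 * x$pca_model$var_explained[1])
}
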