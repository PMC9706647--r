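#' Principal component analysis of a complete-case genotype matrix
#'
#' Singular value decomposition of the column-centered (not scaled) dosage
#' matrix, as `stats::prcomp` computes it. Scores are the sample
#' coordinates, the rotation holds the per-marker loading factors
#' (orthonormal columns) and `sdev` the component standard deviations
#' (variances use the n - 1 denominator).
#'
#' @param ds A [geno_data()] with no missing calls (use
#'   [complete_case_markers()] first) and no constant marker.
#' @param scale. Scale columns to unit variance before the decomposition
#'   (default `FALSE`).
#' @return A `pca_model` object wrapping the `prcomp` fit, with `scores`,
#'   `rotation`, `sdev`, `var_explained` (fraction per component) and the
#'   marker/sample tables.
#' @export
run_pca <- function(ds, scale. = FALSE) {
  if (anyNA(ds$dosage)) {
    stop("missing genotype calls: run complete_case_markers() first")
  }
  if (n_samples(ds) < 2 || n_markers(ds) < 2) {
    stop("need at least 2 samples and 2 markers")
  }
  v <- apply(ds$dosage, 2, stats::var)
  if (any(v == 0)) {
    stop("constant marker column (should have been removed by QC): ",
         ds$markers$marker_id[v == 0][1])
  }
  fit <- stats::prcomp(ds$dosage, center = TRUE, scale. = scale.)
  structure(list(
    scores = fit$x, rotation = fit$rotation, sdev = fit$sdev,
    center = fit$center,
    var_explained = fit$sdev^2 / sum(fit$sdev^2),
    markers = ds$markers, samples = ds$samples),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", nrow(x$scores), " samples, ", nrow(x$rotation),
      " markers\n", sep = "")
  k <- min(5, length(x$sdev))
  cat("  variance explained: ",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * x$var_explained[seq_len(k)]),
             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Per-marker contributions to a principal component
#'
#' The variable correlation of a marker with a component is its loading
#' factor times the component standard deviation; its squared value
#' (cos-squared) measures the quality of representation; and the
#' contribution is that cos-squared as a percentage of the component's
#' total over all markers (contributions sum to 100).
#'
#' @param model A [run_pca()] fit.
#' @param component Component index (default 1).
#' @return Tibble per marker: `marker_id`, `chromosome`, `position_bp`,
#'   `loading`, `var_cor`, `cos2`, `contribution`.
#' @export
contributions <- function(model, component = 1) {
  stopifnot(inherits(model, "pca_model"))
  if (component < 1 || component > length(model$sdev)) {
    stop("component out of range")
  }
  if (model$sdev[component] <= 1e-10 * model$sdev[1]) {
    stop("component ", component, " has zero standard deviation")
  }
  loading <- model$rotation[, component]
  var_cor <- loading * model$sdev[component]
  cos2 <- var_cor^2
  tibble::tibble(
    marker_id = model$markers$marker_id,
    chromosome = model$markers$chromosome,
    position_bp = model$markers$position_bp,
    loading = unname(loading), var_cor = unname(var_cor),
    cos2 = unname(cos2),
    contribution = unname(100 * cos2 / sum(cos2)))
}

# sign with the 0 -> +1 convention (zero-loading markers contribute 0)
sign1 <- function(x) ifelse(x >= 0, 1, -1)

#' pcaDObs significance of marker contributions
#'
#' The signed contribution statistic: the sign of the marker's loading on
#' the component times its percentage contribution
#' (`pcaDObs = sign(loading) x contribution`). Treating the empirical
#' pcaDObs distribution as normal with its own mean and (sample) SD, the
#' raw p-value of a marker is twice the upper-tail probability of its
#' `|pcaDObs|`, capped at 1; Bonferroni multiplies by the number of
#' markers tested. Markers with `p_bonf < alpha` are selected.
#'
#' The sign of a principal component is arbitrary, so the normal fit uses
#' the orientation in which the pcaDObs mean is nonnegative; this makes
#' the p-values and the selected set invariant to component orientation
#' while the reported `pcadobs` keeps the orientation of the model passed
#' in.
#'
#' @param records Contribution tibble from [contributions()].
#' @param alpha Bonferroni family alpha for the `selected` flag
#'   (default 0.05).
#' @return `records` with added `pcadobs`, `p`, `p_bonf`, `selected`.
#' @export
pcadobs_significance <- function(records, alpha = 0.05) {
  if (nrow(records) < 2) stop("need at least 2 markers")
  d <- sign1(records$loading) * records$contribution
  mu <- abs(mean(d))
  sdv <- stats::sd(d)
  if (sdv == 0) stop("degenerate pcaDObs distribution (zero SD)")
  p <- pmin(1, 2 * stats::pnorm(abs(d), mean = mu, sd = sdv,
                                lower.tail = FALSE))
  records |>
    dplyr::mutate(pcadobs = d, p = p,
                  p_bonf = pmin(1, p * nrow(records)),
                  selected = .data$p_bonf < alpha)
}

#' Full PCA contribution scan
#'
#' Convenience wrapper: [run_pca()] on the complete-case dataset,
#' [contributions()] + [pcadobs_significance()] on the chosen component,
#' and [merge_distance_regions()] over the selected markers.
#'
#' @param ds Complete-case [geno_data()].
#' @param component Component to scan (default 1).
#' @param alpha Bonferroni alpha (default 0.05).
#' @param max_gap Region chaining gap in bp (default 2,000,000).
#' @param scale. Passed to [run_pca()].
#' @return List with `model` (the [run_pca()] fit), `records` (per-marker
#'   tibble) and `regions` (region tibble, `source = "pca:PC<k>"`).
#' @export
pca_scan <- function(ds, component = 1, alpha = 0.05, max_gap = 2e6,
                     scale. = FALSE) {
  model <- run_pca(ds, scale. = scale.)
  records <- pcadobs_significance(contributions(model, component),
                                  alpha = alpha)
  regions <- merge_distance_regions(
    dplyr::filter(records, .data$selected), max_gap = max_gap,
    source = paste0("pca:PC", component))
  list(model = model, records = records, regions = regions)
}

#' Spearman correlation of component scores with traits
#'
#' Rank correlation of the sample coordinates on a component against each
#' trait's raw values, with the large-sample p-value. A constant trait
#' yields a missing correlation.
#'
#' @param model A [run_pca()] fit.
#' @param traits Trait table (`sample_id`, `trait`, `value`).
#' @param component Component index (default 1).
#' @return Tibble per trait: `rho`, `p`, `n`.
#' @export
pc_trait_correlation <- function(model, traits, component = 1) {
  sc <- model$scores[, component]
  ids <- model$samples$sample_id
  traits |>
    dplyr::group_by(.data$trait) |>
    dplyr::group_modify(function(g, key) {
      y <- g$value[match(ids, g$sample_id)]
      ok <- !is.na(y)
      if (sum(ok) < 3 || stats::sd(y[ok]) == 0) {
        return(tibble::tibble(rho = NA_real_, p = NA_real_, n = sum(ok)))
      }
      ct <- suppressWarnings(
        stats::cor.test(sc[ok], y[ok], method = "spearman", exact = FALSE))
      tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
    }) |>
    dplyr::ungroup()
}
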