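#' Euclidean genotype distance between individuals
#'
#' Pairwise Euclidean distance over dosage vectors with pairwise-complete
#' handling of missing calls: the sum of squared differences over the
#' markers non-missing in both individuals is rescaled by `M / M_ij`
#' (total markers over pairwise-complete markers) before the square root,
#' keeping distances comparable across pairs with different missingness.
#'
#' @param ds A [geno_data()] object.
#' @return A `stats::dist` object over the samples, with sample ids as
#'   labels.
#' @export
genotype_distance <- function(ds) {
  d <- stats::dist(ds$dosage, method = "euclidean")
  if (anyNA(d)) {
    m <- as.matrix(d)
    bad <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)[1, ]
    stop("no shared non-missing markers for pair ",
         rownames(m)[bad[1]], " / ", colnames(m)[bad[2]])
  }
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering in which the distance between two clusters is
#' the maximum pairwise distance between their members; merge heights are
#' therefore monotone nondecreasing.
#'
#' @param d A `stats::dist` object, e.g. from [genotype_distance()].
#' @return A `stats::hclust` tree.
#' @export
complete_linkage <- function(d) {
  stats::hclust(d, method = "complete")
}

#' Flag individuals clustering with the wrong breed
#'
#' Cuts the tree into `k` flat clusters and flags every sample whose
#' cluster's majority breed differs from its own breed label. A cluster
#' whose majority breed is tied is excluded from outlier calls with a
#' warning.
#'
#' @param tree An `hclust` tree over the samples.
#' @param samples Sample metadata tibble with `sample_id` and `breed`,
#'   ordered as the tree's leaves were ordered at build time.
#' @param k Number of flat clusters (default: number of breeds).
#' @return Character vector of outlier sample ids (possibly empty).
#' @export
flag_outliers <- function(tree, samples, k = dplyr::n_distinct(samples$breed)) {
  stopifnot(k <= nrow(samples))
  cl <- stats::cutree(tree, k = k)
  out <- character()
  for (g in unique(cl)) {
    idx <- which(cl == g)
    tab <- sort(table(samples$breed[idx]), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      warning("cluster ", g, " has a tied majority breed; skipped")
      next
    }
    maj <- names(tab)[1]
    bad <- idx[samples$breed[idx] != maj]
    out <- c(out, samples$sample_id[bad])
  }
  out
}

#' Flat cluster assignments as a tibble
#'
#' @param tree An `hclust` tree.
#' @param samples Sample metadata (`sample_id`, `breed`, `type`).
#' @param k Number of clusters.
#' @return Tibble `sample_id`, `breed`, `type`, `cluster`, `outlier`.
#' @export
cluster_assignments <- function(tree, samples,
                                k = dplyr::n_distinct(samples$breed)) {
  cl <- stats::cutree(tree, k = k)
  out <- flag_outliers(tree, samples, k)
  tibble::tibble(sample_id = samples$sample_id, breed = samples$breed,
                 type = samples$type, cluster = unname(cl),
                 outlier = samples$sample_id %in% out)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are derived from merge heights so that leaf depth equals
#' the height at which a sample last merges.
#'
#' @param tree An `hclust` tree.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  build <- function(i, parent_h) {
    if (i < 0) {  # leaf
      lab <- tree$labels[-i]
      paste0(lab, ":", format(parent_h, digits = 10))
    } else {
      h <- tree$height[i]
      paste0("(", build(tree$merge[i, 1], h), ",",
             build(tree$merge[i, 2], h), "):",
             format(parent_h - h, digits = 10))
    }
  }
  n <- length(tree$height)
  txt <- paste0("(", build(tree$merge[n, 1], tree$height[n]), ",",
                build(tree$merge[n, 2], tree$height[n]), ");")
  writeLines(txt, path)
  invisible(path)
}
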