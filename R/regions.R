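# assemble a region tibble from a per-marker table with a grouping id
build_regions <- function(sig, region_id, top_order, source) {
  sig$.region <- region_id
  sig |>
    dplyr::group_by(.data$chromosome, .data$.region) |>
    dplyr::group_modify(function(g, key) {
      top <- g[top_order(g), ][1, ]
      tibble::tibble(
        start_bp = min(g$position_bp), end_bp = max(g$position_bp),
        n_markers = nrow(g),
        marker_ids = list(g$marker_id[order(g$position_bp)]),
        top_marker = top$marker_id, top_p = top$p)
    }) |>
    dplyr::ungroup() |>
    dplyr::select(-".region") |>
    dplyr::mutate(source = source) |>
    dplyr::arrange(.data$chromosome, .data$start_bp)
}

#' Merge significant markers into regions by linkage disequilibrium
#'
#' Walks the significant markers of each chromosome in position order and
#' joins two consecutive ones into the same region iff their
#' EM-estimated `r^2` ([ld_r2()]) is strictly greater than `r2_min`;
#' regions are the transitive closure of these adjacent joins. Region
#' bounds are the outermost member positions (1-based inclusive); the top
#' marker is the member with the lowest raw p (ties broken by lowest
#' position).
#'
#' @param sig Tibble of significant association records with `marker_id`,
#'   `chromosome`, `position_bp`, `p` (e.g. a filtered [assoc_scan()]
#'   result for one trait).
#' @param ds The [geno_data()] the scan ran on (dosages are needed for
#'   `r^2`).
#' @param r2_min LD threshold (default 0.5, strict inequality).
#' @param source Label recorded on each region (e.g. `"assoc:trait"`).
#' @return Region tibble: `chromosome`, `start_bp`, `end_bp`, `n_markers`,
#'   `marker_ids` (list column), `top_marker`, `top_p`, `source`.
#' @export
merge_ld_regions <- function(sig, ds, r2_min = 0.5, source = "assoc") {
  if (!nrow(sig)) {
    return(tibble::tibble(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), n_markers = integer(),
                          marker_ids = list(), top_marker = character(),
                          top_p = numeric(), source = character()))
  }
  sig <- dplyr::arrange(sig, .data$chromosome, .data$position_bp)
  col <- match(sig$marker_id, ds$markers$marker_id)
  if (anyNA(col)) stop("significant marker absent from dataset: ",
                       sig$marker_id[is.na(col)][1])
  new_region <- logical(nrow(sig))
  new_region[1] <- TRUE
  for (i in seq_len(nrow(sig))[-1]) {
    if (sig$chromosome[i] != sig$chromosome[i - 1]) {
      new_region[i] <- TRUE
    } else {
      r2 <- tryCatch(
        ld_r2(ds$dosage[, col[i - 1]], ds$dosage[, col[i]]),
        error = function(e) 0)
      new_region[i] <- !(r2 > r2_min)
    }
  }
  build_regions(sig, cumsum(new_region),
                top_order = function(g) order(g$p, g$position_bp),
                source = source)
}

#' Merge selected markers into regions by genomic distance
#'
#' Single-pass chaining: a marker joins the current region iff it sits on
#' the same chromosome and within `max_gap` base pairs of the previous
#' member. The top marker is the member with the smallest raw p, ties
#' broken by the most extreme `|pcaDObs|`, then by lowest position.
#'
#' @param selected Tibble of selected markers with `marker_id`,
#'   `chromosome`, `position_bp`, `p` and optionally `pcadobs`.
#' @param max_gap Maximum gap between consecutive members in bp
#'   (default 2,000,000).
#' @param source Label recorded on each region (e.g. `"pca:PC1"`).
#' @return Region tibble as in [merge_ld_regions()].
#' @export
merge_distance_regions <- function(selected, max_gap = 2e6,
                                   source = "pca") {
  if (!nrow(selected)) {
    return(tibble::tibble(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), n_markers = integer(),
                          marker_ids = list(), top_marker = character(),
                          top_p = numeric(), source = character()))
  }
  selected <- dplyr::arrange(selected, .data$chromosome, .data$position_bp)
  gap_break <- c(TRUE,
                 selected$chromosome[-1] != selected$chromosome[-nrow(selected)] |
                   diff(selected$position_bp) > max_gap)
  top_order <- if ("pcadobs" %in% names(selected)) {
    function(g) order(g$p, -abs(g$pcadobs), g$position_bp)
  } else {
    function(g) order(g$p, g$position_bp)
  }
  build_regions(selected, cumsum(gap_break), top_order, source)
}

#' Overlap regions with a set of known labelled intervals
#'
#' Reports every (region, known interval) pair sharing at least one base
#' pair on the same chromosome, with the overlap length in bp (1-based
#' inclusive arithmetic).
#'
#' @param regions Region tibble (from [merge_ld_regions()] /
#'   [merge_distance_regions()]).
#' @param known Tibble of known intervals with `chromosome`, `start_bp`,
#'   `end_bp` (1-based inclusive), `label` — e.g. from [read_intervals()].
#' @return Tibble with one row per overlapping pair: the region key
#'   columns, `label`, `known_start_bp`, `known_end_bp`, `overlap_bp`.
#' @export
overlap_regions <- function(regions, known) {
  empty <- tibble::tibble(chromosome = character(), start_bp = integer(),
                          end_bp = integer(), source = character(),
                          label = character(), known_start_bp = integer(),
                          known_end_bp = integer(), overlap_bp = integer())
  if (!nrow(regions) || !nrow(known)) return(empty)
  out <- purrr::map_dfr(unique(regions$chromosome), function(chr) {
    r <- regions[regions$chromosome == chr, ]
    k <- known[known$chromosome == chr, ]
    if (!nrow(k)) return(empty)
    ir_r <- IRanges::IRanges(start = r$start_bp, end = r$end_bp)
    ir_k <- IRanges::IRanges(start = k$start_bp, end = k$end_bp)
    hits <- IRanges::findOverlaps(ir_r, ir_k)
    if (!length(hits)) return(empty)
    qi <- as.data.frame(hits)$queryHits
    si <- as.data.frame(hits)$subjectHits
    ov <- IRanges::width(IRanges::pintersect(ir_r[qi], ir_k[si]))
    tibble::tibble(chromosome = chr,
                   start_bp = r$start_bp[qi], end_bp = r$end_bp[qi],
                   source = r$source[qi], label = k$label[si],
                   known_start_bp = k$start_bp[si],
                   known_end_bp = k$end_bp[si],
                   overlap_bp = as.integer(ov))
  })
  dplyr::arrange(out, .data$chromosome, .data$start_bp, .data$known_start_bp)
}
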