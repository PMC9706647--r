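# OLS via QR on an explicit design; returns rss, rank, and optionally the
# coefficient and SE of the last column
ols_fit <- function(X, y, want_last = FALSE) {
  qr_x <- qr(X)
  res <- qr.resid(qr_x, y)
  rss <- sum(res^2)
  out <- list(rss = rss, rank = qr_x$rank, n = length(y))
  if (want_last) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    p_last <- ncol(X)
    if (!(p_last %in% keep)) {
      out$beta <- NA_real_
      out$se <- NA_real_
    } else {
      coefs <- qr.coef(qr_x, y)
      sigma2 <- rss / (length(y) - qr_x$rank)
      R <- qr.R(qr_x)[seq_len(qr_x$rank), seq_len(qr_x$rank), drop = FALSE]
      xtxinv <- chol2inv(R)
      pos <- match(p_last, keep)
      out$beta <- unname(coefs[p_last])
      out$se <- sqrt(sigma2 * xtxinv[pos, pos])
    }
  }
  out
}

#' Single-marker association with a breed covariate
#'
#' Tests one marker against a sex-corrected trait with the nested model
#' comparison: full model `Y' ~ breed + genotype class` against the
#' reduced model `Y' ~ breed`, by F test. The genotype enters the test as
#' an unordered factor (up to 2 df), while the reported effect size `beta`
#' and its SE come from a second fit in which the genotype factor is
#' replaced by the 0/1/2 minor-allele dosage — `beta` is the additive
#' effect of one minor-allele copy. The share of residual variance
#' explained is `100 (RSS_reduced - RSS_full) / RSS_reduced`.
#'
#' @param y Numeric vector of sex-corrected trait values.
#' @param breed Breed labels, same length as `y`.
#' @param g Integer dosages 0/1/2 (minor-allele copies), `NA` allowed.
#' @param marker_id,trait Labels copied into the output.
#' @param .X0 Optional precomputed reduced design `model.matrix(~ breed)`
#'   over the full (unmasked) sample vector; used by [assoc_scan()] to
#'   avoid rebuilding it per marker.
#' @return One-row tibble: `marker_id`, `trait`, `n`, `n0`, `n1`, `n2`
#'   (class counts), `maf`, `p`, `beta`, `se`, `var_pct`, `note`
#'   (`NA`, `"single_class"` or `"collinear_with_breed"`; in both failure
#'   cases `p` is `NA`).
#' @export
fit_marker <- function(y, breed, g, marker_id = NA_character_,
                       trait = NA_character_, .X0 = NULL) {
  if (is.null(.X0)) .X0 <- stats::model.matrix(~factor(breed))
  v <- fit_marker_core(y, .X0, g)
  tibble::tibble(marker_id = marker_id, trait = trait,
                 n = as.integer(v[["n"]]), n0 = as.integer(v[["n0"]]),
                 n1 = as.integer(v[["n1"]]), n2 = as.integer(v[["n2"]]),
                 maf = v[["maf"]], p = v[["p"]], beta = v[["beta"]],
                 se = v[["se"]], var_pct = v[["var_pct"]],
                 note = switch(v[["note"]] + 1L, NA_character_,
                               "single_class", "collinear_with_breed"))
}

# numeric workhorse behind fit_marker / assoc_scan; note: 0 ok,
# 1 single genotype class, 2 genotype collinear with breed
fit_marker_core <- function(y, X0_full, g) {
  ok <- !is.na(y) & !is.na(g)
  X0 <- X0_full[ok, , drop = FALSE]
  y <- y[ok]; g <- g[ok]
  counts <- tabulate(g + 1L, nbins = 3L)
  maf <- if (length(g)) sum(g) / (2 * length(g)) else NA_real_
  maf <- min(maf, 1 - maf)
  out <- c(n = length(y), n0 = counts[1], n1 = counts[2], n2 = counts[3],
           maf = maf, p = NA_real_, beta = NA_real_, se = NA_real_,
           var_pct = NA_real_, note = 0)
  classes <- sort(unique(g))
  if (length(classes) < 2) {
    out[["note"]] <- 1
    return(out)
  }
  # genotype-class indicators (first class absorbed by the intercept)
  Xg <- cbind(X0, vapply(classes[-1], function(cl) as.numeric(g == cl),
                         numeric(length(g))))
  fit0 <- ols_fit(X0, y)
  fit1 <- ols_fit(Xg, y)
  df1 <- fit1$rank - fit0$rank
  if (df1 < 1) {
    out[["note"]] <- 2
    return(out)
  }
  df2 <- fit1$n - fit1$rank
  fstat <- ((fit0$rss - fit1$rss) / df1) / (fit1$rss / df2)
  out[["p"]] <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  out[["var_pct"]] <- 100 * (fit0$rss - fit1$rss) / fit0$rss
  add <- ols_fit(cbind(X0, dosage = as.numeric(g)), y, want_last = TRUE)
  out[["beta"]] <- add$beta
  out[["se"]] <- add$se
  out
}

#' Genome-wide association scan over all markers and traits
#'
#' Runs [fit_marker()] for every marker x trait pair and attaches the
#' per-trait Benjamini-Hochberg FDR (`q`, computed across all testable
#' markers of that trait) together with marker map columns.
#'
#' @param ds A [geno_data()] object after QC (filtering + class masking).
#' @param traits Sex-corrected trait table (with a `corrected` column,
#'   from [sex_correct()]).
#' @param traits_use Traits to scan (default: all traits present).
#' @return Tibble of per-marker records (one row per marker x trait),
#'   including `chromosome`, `position_bp`, `p`, `q`, `beta`, `se`,
#'   `var_pct`.
#' @export
assoc_scan <- function(ds, traits, traits_use = NULL) {
  if (!"corrected" %in% names(traits)) {
    stop("traits must be sex-corrected first (see sex_correct())")
  }
  if (is.null(traits_use)) traits_use <- unique(traits$trait)
  breed <- ds$samples$breed
  X0 <- stats::model.matrix(~factor(breed))
  res <- purrr::map_dfr(traits_use, function(tr) {
    tt <- traits[traits$trait == tr, ]
    y <- tt$corrected[match(ds$samples$sample_id, tt$sample_id)]
    m <- vapply(seq_len(n_markers(ds)),
                function(j) fit_marker_core(y, X0, ds$dosage[, j]),
                numeric(10))
    rows <- tibble::tibble(
      marker_id = ds$markers$marker_id, trait = tr,
      n = as.integer(m["n", ]), n0 = as.integer(m["n0", ]),
      n1 = as.integer(m["n1", ]), n2 = as.integer(m["n2", ]),
      maf = m["maf", ], p = m["p", ], beta = m["beta", ],
      se = m["se", ], var_pct = m["var_pct", ],
      note = dplyr::case_match(m["note", ], 0 ~ NA_character_,
                               1 ~ "single_class",
                               2 ~ "collinear_with_breed"))
    rows$q <- NA_real_
    testable <- !is.na(rows$p)
    rows$q[testable] <- bh_fdr(rows$p[testable])
    rows
  })
  dplyr::left_join(
    res,
    ds$markers[, c("marker_id", "chromosome", "position_bp")],
    by = "marker_id") |>
    dplyr::relocate("chromosome", "position_bp", .after = "marker_id")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min over j >= i of min(1, p_(j) m/j)`,
#' returned in the input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' The ratio of the median observed association statistic to its null
#' median, on the 1-df chi-square scale: p-values are mapped through the
#' upper-tail chi-square quantile and the median of those statistics is
#' divided by `qchisq(0.5, df = 1)` (about 0.456). Lambda near 1 indicates
#' a calibrated scan; inflation above 1 signals residual structure or
#' widespread true signal. `literal = TRUE` instead returns the ratio of
#' the median p-value to 0.5, the direct reading of the
#' median-of-p-values phrasing some reports use.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @param literal Use the median-p ratio form (default `FALSE`).
#' @return Lambda (positive scalar).
#' @export
genomic_inflation <- function(p, literal = FALSE) {
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values")
  if (any(p <= 0)) stop("p-value of 0: chi-square quantile is infinite")
  if (any(p > 1)) stop("p-values outside (0, 1]")
  if (literal) return(stats::median(p) / 0.5)
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Per-trait scan summary
#'
#' @param scan Output of [assoc_scan()].
#' @return Tibble per trait: `lambda`, `n_tested`, significant marker
#'   counts at FDR 0.05 and 0.01.
#' @export
scan_summary <- function(scan) {
  scan |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      lambda = genomic_inflation(.data$p),
      n_tested = dplyr::n(),
      n_fdr_05 = sum(.data$q < 0.05),
      n_fdr_01 = sum(.data$q < 0.01),
      .groups = "drop")
}
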