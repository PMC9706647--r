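#' Sex-correct phenotypes within each breed
#'
#' For every breed x trait cell, fits ordinary least squares of the raw
#' trait value on sex (reference level female) and returns the corrected
#' value `Y' = intercept + residual`. The corrected value is on the
#' reference-sex scale: within a breed, male and female means of `Y'`
#' coincide, so downstream association is not confounded by sex.
#'
#' A breed observed in only one sex leaves that breed's values unchanged
#' (the sex effect is inestimable) with a warning. Missing raw values get
#' missing corrected values.
#'
#' @param traits Trait table (`sample_id`, `trait`, `value`).
#' @param samples Sample metadata (`sample_id`, `breed`, `sex`).
#' @param reference_sex Sex whose mean becomes the corrected scale
#'   (default `"female"`).
#' @return The trait table with an added `corrected` column.
#' @export
sex_correct <- function(traits, samples, reference_sex = "female") {
  df <- dplyr::left_join(traits,
                         dplyr::select(samples, "sample_id", "breed", "sex"),
                         by = "sample_id")
  if (anyNA(df$breed)) {
    stop("samples missing from metadata: ",
         paste(unique(df$sample_id[is.na(df$breed)]), collapse = ", "))
  }
  warned <- character()
  out <- df |>
    dplyr::group_by(.data$breed, .data$trait) |>
    dplyr::group_modify(function(g, key) {
      ok <- !is.na(g$value)
      sexes <- unique(g$sex[ok])
      g$corrected <- NA_real_
      if (length(sexes) < 2) {
        if (!(key$breed %in% warned)) warned <<- c(warned, key$breed)
        g$corrected[ok] <- g$value[ok]
        return(g)
      }
      sex_f <- stats::relevel(factor(g$sex[ok]), ref = reference_sex)
      fit <- stats::lm(g$value[ok] ~ sex_f)
      g$corrected[ok] <- unname(stats::coef(fit)[1] + stats::residuals(fit))
      g
    }) |>
    dplyr::ungroup()
  if (length(warned)) {
    warning("single-sex breed(s), sex effect inestimable, values kept: ",
            paste(warned, collapse = ", "))
  }
  dplyr::select(out, "sample_id", "trait", "value", "corrected")
}

#' Compare trait means between the two types, per trait and sex
#'
#' Two-sample two-tailed Student's t test (pooled variance by default) of
#' each trait between the two types, separately for males and females.
#' The significance threshold is the family alpha Bonferroni-divided by
#' the number of trait x sex comparisons (0.05 / (5 x 2) = 0.005 for the
#' five canonical traits).
#'
#' @param traits Trait table (`sample_id`, `trait`, `value`).
#' @param samples Sample metadata (`sample_id`, `type`, `sex`).
#' @param alpha_family Family-wise alpha (default 0.05).
#' @param welch Use Welch's unequal-variance t test instead of the pooled
#'   variance form (default `FALSE`).
#' @return Tibble with one row per trait x sex: group means and SDs, the
#'   t statistic, its p-value, the Bonferroni threshold used and a
#'   `significant` flag. Groups with fewer than 2 observations are
#'   skipped with a warning.
#' @export
compare_types <- function(traits, samples, alpha_family = 0.05,
                          welch = FALSE) {
  df <- dplyr::left_join(traits,
                         dplyr::select(samples, "sample_id", "type", "sex"),
                         by = "sample_id") |>
    dplyr::filter(!is.na(.data$value))
  types <- sort(unique(df$type))
  if (length(types) != 2) stop("exactly two types required, got ",
                               length(types))
  n_tests <- dplyr::n_distinct(df$trait) * dplyr::n_distinct(df$sex)
  threshold <- alpha_family / n_tests
  df |>
    dplyr::group_by(.data$trait, .data$sex) |>
    dplyr::group_modify(function(g, key) {
      x <- g$value[g$type == types[1]]
      y <- g$value[g$type == types[2]]
      if (length(x) < 2 || length(y) < 2) {
        warning("fewer than 2 observations for ", key$trait, " / ",
                key$sex, "; comparison skipped")
        return(tibble::tibble())
      }
      tt <- stats::t.test(x, y, var.equal = !welch)
      tibble::tibble(
        mean_1 = mean(x), sd_1 = stats::sd(x), n_1 = length(x),
        mean_2 = mean(y), sd_2 = stats::sd(y), n_2 = length(y),
        t = unname(tt$statistic), p = tt$p.value,
        threshold = threshold, significant = tt$p.value < threshold)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(type_1 = types[1], type_2 = types[2],
                  .after = "sex")
}
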