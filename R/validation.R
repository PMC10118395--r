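#' Truncate phenotypes for forward validation
#'
#' Removes all phenotype records of animals born after the cutoff year,
#' emulating an evaluation run some years in the past. Pedigree and
#' genotypes are never truncated.
#'
#' @param phenotypes Phenotype table with `animal_id`.
#' @param animals Tibble with `animal_id` and `birth_year` (e.g. the
#'   pedigree); every phenotyped animal must appear.
#' @param cutoff_year Records of animals born after this year are removed.
#' @return The truncated phenotype table (same columns, subset of rows).
#' @export
truncate_phenotypes <- function(phenotypes, animals, cutoff_year) {
  ph <- as_tibble(phenotypes)
  an <- as_tibble(animals)
  by <- an$birth_year[match(as.character(ph$animal_id), as.character(an$animal_id))]
  sb_assert(!anyNA(by), "birth year unknown for some phenotyped animals")
  ph[by <= cutoff_year, ]
}

#' Select a forward-validation cohort
#'
#' Validation animals are genotyped, have their own phenotype in the full
#' data, are born after the truncation cutoff (so their records are absent
#' from the truncated data), and belong to the requested stratum (cows or
#' steers; bulls are not used for validation).
#'
#' @param animals Tibble with `animal_id`, `birth_year`, `type`.
#' @param genotyped_ids Character vector of genotyped animal ids.
#' @param phenotypes_full Full (untruncated) phenotype table.
#' @param cutoff_year Truncation cutoff birth year.
#' @param stratum `"cows"`, `"steers"`, or both.
#' @return Tibble with `animal_id`, `stratum`; errors if empty.
#' @export
validation_cohort <- function(animals, genotyped_ids, phenotypes_full,
                              cutoff_year, stratum = c("cows", "steers")) {
  stratum <- match.arg(stratum, several.ok = TRUE)
  an <- as_tibble(animals)
  sb_assert(all(c("animal_id", "birth_year", "type") %in% names(an)),
            "animals needs animal_id, birth_year, type")
  type_for <- c(cows = "cow", steers = "steer")
  sel <- an$animal_id %in% as.character(genotyped_ids) &
    an$birth_year > cutoff_year &
    an$animal_id %in% as.character(phenotypes_full$animal_id) &
    an$type %in% type_for[stratum]
  out <- tibble(animal_id = as.character(an$animal_id[sel]),
                stratum = names(type_for)[match(an$type[sel], type_for)])
  sb_assert(nrow(out) > 0, "validation cohort is empty")
  out
}

#' Linear-regression (LR) validation test
#'
#' Regresses, per trait over the validation cohort, the full-data
#' predictions on the truncated-data predictions (both rebased to the same
#' base and in genetic-SD units). The intercept `b0` measures bias in
#' genetic-SD units, the slope `b1` measures inflation (`b1 < 1`) or
#' deflation (`b1 > 1`), and `r2` (squared Pearson correlation) relates to
#' prediction accuracy.
#'
#' @param gebv_full,gebv_truncated `gebv_tbl` tables from [gebv_rebase()]
#'   of the full and truncated evaluations, on a common base.
#' @param cohort Validation cohort tibble (or character ids).
#' @return Tibble of class `lr_tbl`: `trait`, `n`, `b0`, `b1`, `r2`.
#' @export
lr_test <- function(gebv_full, gebv_truncated, cohort) {
  ids <- if (is.data.frame(cohort)) as.character(cohort$animal_id) else as.character(cohort)
  both <- dplyr::inner_join(
    dplyr::select(dplyr::filter(gebv_full, .data$animal_id %in% ids),
                  "animal_id", "trait", full = "gebv_sd"),
    dplyr::select(dplyr::filter(gebv_truncated, .data$animal_id %in% ids),
                  "animal_id", "trait", trunc = "gebv_sd"),
    by = c("animal_id", "trait"))
  n_per <- min(table(both$trait))
  sb_assert(is.finite(n_per) && n_per >= 3, "fewer than 3 validation animals with both predictions")
  if (n_per < 10) rlang::warn("fewer than 10 validation animals; LR statistics are noisy")
  out <- both |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      b1 = stats::cov(.data$full, .data$trunc) / stats::var(.data$trunc),
      b0 = mean(.data$full) - .data$b1 * mean(.data$trunc),
      r2 = stats::cor(.data$full, .data$trunc)^2,
      .groups = "drop") |>
    dplyr::select("trait", "n", "b0", "b1", "r2")
  class(out) <- c("lr_tbl", class(out))
  out
}

#' Agreement of SNP-effect estimates between two evaluations
#'
#' Pearson correlation and regression slope (full on truncated) of the
#' marker-effect vectors of two runs over the same marker panel, per trait.
#'
#' @param g_full,g_truncated Tibbles with `marker_id`, `trait`, `g`.
#' @return Tibble with `trait`, `m`, `correlation`, `slope`.
#' @export
effect_agreement <- function(g_full, g_truncated) {
  both <- dplyr::inner_join(
    dplyr::select(as_tibble(g_full), "marker_id", "trait", full = "g"),
    dplyr::select(as_tibble(g_truncated), "marker_id", "trait", trunc = "g"),
    by = c("marker_id", "trait"))
  sb_assert(nrow(both) > 0, "no common markers between the two runs")
  chk <- both |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(v1 = stats::var(.data$full), v2 = stats::var(.data$trunc),
                     .groups = "drop")
  sb_assert(all(chk$v1 > 0 & chk$v2 > 0), "constant marker-effect vector")
  both |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(
      m = dplyr::n(),
      correlation = stats::cor(.data$full, .data$trunc),
      slope = stats::cov(.data$full, .data$trunc) / stats::var(.data$trunc),
      .groups = "drop")
}

#' Full-vs-truncated GEBV correlation by birth year
#'
#' Per-birth-year Pearson correlation between the full and truncated
#' evaluations for a cohort, the per-year view of prediction stability.
#' Years with data in both runs before the cutoff are expected at ~1;
#' post-cutoff years measure forward-prediction stability.
#'
#' @param gebv_full,gebv_truncated `gebv_tbl` tables.
#' @param animals Tibble with `animal_id`, `birth_year` defining the cohort.
#' @param min_n Years with fewer animals are flagged (`small = TRUE`).
#' @return Tibble: `birth_year`, `trait`, `n`, `correlation`, `small`.
#' @export
gebv_year_correlation <- function(gebv_full, gebv_truncated, animals, min_n = 3) {
  an <- dplyr::mutate(as_tibble(animals), animal_id = as.character(.data$animal_id))
  both <- dplyr::inner_join(
    dplyr::select(gebv_full, "animal_id", "trait", full = "gebv_sd"),
    dplyr::select(gebv_truncated, "animal_id", "trait", trunc = "gebv_sd"),
    by = c("animal_id", "trait")) |>
    dplyr::inner_join(dplyr::select(an, "animal_id", "birth_year"), by = "animal_id")
  out <- both |>
    dplyr::group_by(.data$birth_year, .data$trait) |>
    dplyr::summarise(
      n = dplyr::n(),
      correlation = if (dplyr::n() >= 2 && stats::var(.data$trunc) > 0 &&
                          stats::var(.data$full) > 0)
        stats::cor(.data$full, .data$trunc) else NA_real_,
      .groups = "drop") |>
    dplyr::mutate(small = .data$n < min_n) |>
    dplyr::arrange(.data$trait, .data$birth_year)
  out
}
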