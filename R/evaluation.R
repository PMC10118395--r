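#' Rebase GEBV to a common base cohort and scale to genetic SD units
#'
#' Subtracts, per trait, the mean GEBV of a base cohort (for carcass
#' evaluations typically the animals born in a reference year that have
#' carcass records) and divides by the genetic standard deviation of the
#' trait, so that evaluations and traits can be compared directly.
#'
#' @param gebv A GEBV table (`animal_id`, `trait`, `gebv`) from
#'   [gebv_table()], or an `ss_fit`.
#' @param base_ids Character vector of base-cohort animal ids (non-empty).
#' @param G0 Genetic covariance matrix with trait dimnames, or `NULL` to
#'   take it from the fit.
#' @return A tibble of class `gebv_tbl` with `animal_id`, `trait`,
#'   `gebv_raw`, `gebv_sd` (rebased, genetic-SD units).
#' @export
gebv_rebase <- function(gebv, base_ids, G0 = NULL) {
  if (inherits(gebv, "ss_fit")) {
    G0 <- G0 %||% gebv$vc$G0
    gebv <- gebv_table(gebv)
  }
  sb_assert(!is.null(G0), "G0 is needed to scale GEBV to genetic SD units")
  base_ids <- as.character(base_ids)
  sb_assert(length(base_ids) > 0, "base cohort is empty")
  G0 <- as.matrix(G0)
  traits <- unique(gebv$trait)
  gsd <- sqrt(diag(G0))
  if (!is.null(colnames(G0))) {
    sb_assert(all(traits %in% colnames(G0)), "traits missing from G0 dimnames")
    gsd <- gsd[match(traits, colnames(G0))]
  }
  gsd <- unname(gsd)
  sd_tbl <- tibble(trait = traits, .gsd = gsd)
  base <- gebv |>
    dplyr::filter(.data$animal_id %in% base_ids) |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(.base_mean = mean(.data$gebv), .groups = "drop")
  sb_assert(nrow(base) == length(traits), "base cohort has no animals with GEBV")
  out <- gebv |>
    dplyr::left_join(base, by = "trait") |>
    dplyr::left_join(sd_tbl, by = "trait") |>
    dplyr::mutate(gebv_raw = .data$gebv,
                  gebv_sd = (.data$gebv - .data$.base_mean) / .data$.gsd) |>
    dplyr::select("animal_id", "trait", "gebv_raw", "gebv_sd")
  class(out) <- c("gebv_tbl", class(out))
  out
}

#' Standardized SNP-effect scan table
#'
#' Divides estimated marker effects by the marker genetic standard
#' deviation of each trait, so effects are comparable across traits and a
#' Manhattan-style scan can be drawn.
#'
#' @param fit An `ss_fit` with marker effects, or a tibble with
#'   `marker_id`, `trait`, `g`.
#' @param map Marker map (`marker_id`, `chromosome`, `position`); taken
#'   from the fit when available.
#' @param snp_cov Marker covariance (`snp_cov`); taken from the fit when
#'   available.
#' @return Tibble of class `snp_scan`: `marker_id`, `chromosome`,
#'   `position`, `trait`, `effect_std`.
#' @export
snp_scan <- function(fit, map = NULL, snp_cov = NULL) {
  if (inherits(fit, "ss_fit")) {
    snp_cov <- snp_cov %||% fit$meta$snp_cov
    map <- map %||% fit$meta$map
    g <- fit$g_hat
    sb_assert(!is.null(g), "fit has no marker effects (conventional model?)")
  } else {
    g <- as_tibble(fit)
  }
  sb_assert(!is.null(snp_cov), "snp_cov is needed to standardize effects")
  sb_assert(!is.null(map), "marker map is needed for the scan table")
  sigma <- sqrt(diag(as.matrix(snp_cov$Sigma)))
  sb_assert(all(sigma > 0),
            "marker genetic SD is zero (k = 1): nothing to standardize")
  traits <- unique(g$trait)
  names_sigma <- colnames(as.matrix(snp_cov$Sigma))
  if (!is.null(names_sigma)) sigma <- sigma[match(traits, names_sigma)]
  sigma <- unname(sigma)
  sd_tbl <- tibble(trait = traits, .ssd = sigma)
  out <- g |>
    dplyr::left_join(sd_tbl, by = "trait") |>
    dplyr::left_join(as_tibble(map), by = "marker_id") |>
    dplyr::transmute(marker_id = .data$marker_id,
                     chromosome = .data$chromosome,
                     position = .data$position,
                     trait = .data$trait,
                     effect_std = .data$g / .data$.ssd)
  sb_assert(all(is.finite(out$effect_std)), "non-finite standardized effects")
  class(out) <- c("snp_scan", class(out))
  out
}

#' Genetic trend by birth year
#'
#' Mean rebased GEBV (genetic-SD units) of a cohort by year of birth, the
#' standard way of displaying realized genetic progress.
#'
#' @param gebv A `gebv_tbl` from [gebv_rebase()].
#' @param animals Tibble with `animal_id`, `birth_year` and optionally a
#'   `cohort` label; only these animals enter the trend.
#' @return Tibble of class `trend_tbl`: `birth_year`, `trait`, `cohort`,
#'   `mean_gebv_sd`, `n`.
#' @export
genetic_trend <- function(gebv, animals) {
  animals <- as_tibble(animals)
  sb_assert(all(c("animal_id", "birth_year") %in% names(animals)),
            "animals needs animal_id and birth_year")
  if (!"cohort" %in% names(animals)) animals$cohort <- "all"
  out <- gebv |>
    dplyr::inner_join(
      dplyr::mutate(animals, animal_id = as.character(.data$animal_id)),
      by = "animal_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$birth_year, .data$trait, .data$cohort) |>
    dplyr::summarise(mean_gebv_sd = mean(.data$gebv_sd), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::arrange(.data$cohort, .data$trait, .data$birth_year)
  class(out) <- c("trend_tbl", class(out))
  out
}
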