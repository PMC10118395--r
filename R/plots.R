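#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Manhattan-style plot of standardized SNP effects
#'
#' @param object A `snp_scan` table.
#' @param traits Optional subset of traits to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.snp_scan <- function(object, traits = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(traits)) df <- df[df$trait %in% traits, ]
  df <- df |>
    dplyr::arrange(.data$chromosome, .data$position) |>
    dplyr::mutate(.ord = match(.data$marker_id, unique(.data$marker_id)),
                  .chr_par = factor(.data$chromosome %% 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.ord, y = .data$effect_std,
                                   colour = .data$.chr_par)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(~trait, ncol = 1) +
    ggplot2::scale_colour_manual(values = c("grey35", "steelblue4")) +
    ggplot2::labs(x = "marker (ordered by chromosome, position)",
                  y = "SNP effect (marker genetic SD)") +
    ggplot2::theme_minimal()
}

#' Genetic trend plot
#'
#' @param object A `trend_tbl` (optionally with a `run` column).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_tbl <- function(object, ...) {
  df <- as_tibble(object)
  aes <- if ("run" %in% names(df)) {
    ggplot2::aes(x = .data$birth_year, y = .data$mean_gebv_sd,
                 colour = .data$cohort, linetype = .data$run)
  } else {
    ggplot2::aes(x = .data$birth_year, y = .data$mean_gebv_sd,
                 colour = .data$cohort)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "birth year", y = "mean GEBV (genetic SD, common base)") +
    ggplot2::theme_minimal()
}

#' Full-vs-truncated GEBV scatter for a validation cohort
#'
#' @param gebv_full,gebv_truncated `gebv_tbl` tables on a common base.
#' @param cohort Validation cohort (tibble or ids).
#' @return A ggplot with the identity line and per-trait LR fits.
#' @export
plot_lr_scatter <- function(gebv_full, gebv_truncated, cohort) {
  ids <- if (is.data.frame(cohort)) cohort$animal_id else cohort
  df <- dplyr::inner_join(
    dplyr::select(dplyr::filter(gebv_full, .data$animal_id %in% ids),
                  "animal_id", "trait", full = "gebv_sd"),
    dplyr::select(dplyr::filter(gebv_truncated, .data$animal_id %in% ids),
                  "animal_id", "trait", trunc = "gebv_sd"),
    by = c("animal_id", "trait"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trunc, y = .data$full)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue4", linewidth = 0.6) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "truncated evaluation (genetic SD)",
                  y = "full evaluation (genetic SD)") +
    ggplot2::theme_minimal()
}
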