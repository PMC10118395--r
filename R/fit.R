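#' Fit a multi-trait (genomic) evaluation
#'
#' One-call driver: sorts the pedigree, builds the relationship inverse
#' (optionally with phantom parent groups), prepares genotypes, assembles
#' the requested model and solves it.
#'
#' `model_kind` chooses the parameterization: `"conventional"` is the
#' pedigree-only multi-trait animal model; `"ssnpblup"` estimates SNP
#' effects jointly with breeding values (the marker-effect single-step
#' model); `"ssgblup"` is the algebraically equivalent breeding-value
#' (H-matrix) form, cheaper at this scale, from which marker effects are
#' backsolved exactly. Both single-step kinds return identical GEBV and
#' marker effects up to solver tolerance.
#'
#' @param phenotypes Phenotype table (see [build_design()]).
#' @param pedigree Pedigree table (sorted internally).
#' @param vc Variance components: list with `G0`, `R0` and RPG fraction `k`.
#' @param genotypes A `geno_set`, required for the single-step kinds.
#' @param model_kind One of `"ssgblup"`, `"ssnpblup"`, `"conventional"`.
#' @param groups Optional `phantom_groups` from [ped_phantom_groups()].
#' @param traits,class_effects,covariate Passed to [build_design()].
#' @param solver `"auto"` (direct up to 20,000 equations, else PCG),
#'   `"direct"` or `"pcg"`.
#' @param tol,max_iter PCG settings.
#' @param use_inbreeding Include inbreeding in the A-inverse coefficients.
#' @param a_inverse,a22 Optional precomputed relationship matrices (reused
#'   across the full/truncated runs of a study).
#' @return An `ss_fit`.
#' @export
fit_blup <- function(phenotypes, pedigree, vc, genotypes = NULL,
                     model_kind = c("ssgblup", "ssnpblup", "conventional"),
                     groups = NULL,
                     traits = CARCASS_TRAITS,
                     class_effects = c("herd_year", "year_season", "sex"),
                     covariate = "age",
                     solver = c("auto", "direct", "pcg"),
                     tol = 1e-10, max_iter = 5000,
                     use_inbreeding = TRUE,
                     a_inverse = NULL, a22 = NULL) {
  model_kind <- match.arg(model_kind)
  solver <- match.arg(solver)
  ped <- ped_sort(pedigree)
  Ainv <- a_inverse %||%
    ped_a_inverse(ped, groups = groups, use_inbreeding = use_inbreeding)
  design <- build_design(phenotypes, traits = traits,
                         class_effects = class_effects, covariate = covariate)
  k <- vc$k %||% 0.2
  if (model_kind == "conventional") {
    mme <- assemble_conventional(design, Ainv, vc)
  } else {
    sb_assert(!is.null(genotypes), "single-step models need genotypes")
    freq <- geno_allele_freq(genotypes)
    Z <- geno_center(geno_impute(genotypes, freq), freq)
    a22 <- a22 %||% ped_a22(ped, genotypes$animal_ids)
    scov <- snp_covariance(vc$G0, k, freq$p)
    Qg <- NULL
    if (!is.null(groups) && nrow(groups$groups) > 0) {
      Qg <- ped_group_fractions(ped, groups)[genotypes$animal_ids, , drop = FALSE]
    }
    mme <- switch(model_kind,
      ssnpblup = assemble_ssnpblup(design, Ainv, a22, Z, vc, scov, Qg = Qg),
      ssgblup = assemble_ssgblup(design, Ainv, a22, Z, vc, scov, Qg = Qg))
  }
  fit <- if (solver == "pcg" || (solver == "auto" && nrow(mme$C) > 20000)) {
    solve_pcg(mme, tol = tol, max_iter = max_iter)
  } else {
    solve_direct(mme)
  }
  fit$meta$model_kind <- model_kind
  fit$meta$map <- if (!is.null(genotypes)) genotypes$map
  fit
}

#' Extract the GEBV table from a fit
#'
#' @param fit An `ss_fit`.
#' @param drop_groups Drop phantom-group equations (default TRUE).
#' @return Tibble with `animal_id`, `trait`, `gebv`.
#' @export
gebv_table <- function(fit, drop_groups = TRUE) {
  u <- fit$u_hat
  if (drop_groups) u <- u[!grepl("^G[0-9]+$", u$animal_id), ]
  dplyr::rename(u, gebv = "u")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy solutions of a fitted evaluation
#'
#' @param x An `ss_fit`.
#' @param effects Which solution sets to stack: any of `"fixed"`, `"u"`,
#'   `"g"`, `"a"`.
#' @param ... Unused.
#' @return Tibble with `effect`, `level`, `trait`, `estimate`.
#' @export
tidy.ss_fit <- function(x, effects = c("fixed", "u", "g", "a"), ...) {
  out <- list()
  if ("fixed" %in% effects && !is.null(x$fixed)) {
    out$fixed <- dplyr::transmute(x$fixed,
      effect = paste0("fixed:", .data$effect), level = .data$level,
      trait = .data$trait, estimate = .data$estimate)
  }
  if ("u" %in% effects) {
    out$u <- dplyr::transmute(x$u_hat, effect = "breeding_value",
      level = .data$animal_id, trait = .data$trait, estimate = .data$u)
  }
  if ("g" %in% effects && !is.null(x$g_hat)) {
    out$g <- dplyr::transmute(x$g_hat, effect = "snp_effect",
      level = .data$marker_id, trait = .data$trait, estimate = .data$g)
  }
  if ("a" %in% effects && !is.null(x$a_hat)) {
    out$a <- dplyr::transmute(x$a_hat, effect = "residual_polygenic",
      level = .data$animal_id, trait = .data$trait, estimate = .data$a)
  }
  dplyr::bind_rows(out)
}

#' One-row summary of a fitted evaluation
#'
#' @param x An `ss_fit`.
#' @param ... Unused.
#' @export
glance.ss_fit <- function(x, ...) {
  tibble(
    kind = x$kind,
    n_traits = length(x$traits),
    n_animals = sum(!grepl("^G[0-9]+$", unique(x$u_hat$animal_id))),
    n_genotyped = length(x$meta$geno_ids %||% character(0)),
    n_markers = length(x$meta$marker_ids %||% character(0)),
    solver = x$convergence$method,
    iterations = x$convergence$iterations,
    converged = x$convergence$converged,
    relres = x$convergence$relres
  )
}
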