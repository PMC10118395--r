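#' Read a pedigree CSV
#'
#' Columns `animal_id, sire_id, dam_id, birth_year, sex, path, type`;
#' empty fields mark unknown parents; lines starting with `#` are comments.
#'
#' @param path File path.
#' @return Tibble (unsorted; pass through [ped_sort()] before use).
#' @export
read_pedigree <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    animal_id = readr::col_character(),
                    sire_id = readr::col_character(),
                    dam_id = readr::col_character(),
                    .default = readr::col_guess()))
}

#' Read a phenotype table (TSV)
#'
#' One slaughter record per animal: `animal_id`, the class-effect and
#' covariate columns, and one column per trait. `#` lines are comments.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    animal_id = readr::col_character(),
                    .default = readr::col_guess()))
}

#' Read genotypes (PLINK .raw-style or simple matrix TSV)
#'
#' Accepts the PLINK `.raw` dialect (whitespace-separated, header
#' `FID IID PAT MAT SEX PHENOTYPE` then one column per marker, values
#' 0/1/2/NA) or a simple TSV with `animal_id` plus one column per marker.
#'
#' @param path Genotype file.
#' @param map_path Optional marker map TSV (`marker_id`, `chromosome`,
#'   `position`) in column order of the genotype file.
#' @return A `geno_set`.
#' @export
read_genotypes <- function(path, map_path = NULL) {
  header <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  if (length(header) >= 6 && identical(header[1:6],
      c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))) {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab$IID)
    codes <- as.matrix(tab[, -(1:6), drop = FALSE])
    # PLINK appends the counted allele to the marker name (SNP_A)
    colnames(codes) <- sub("_[ACGT0-9]+$", "", colnames(codes))
  } else {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(
                             animal_id = readr::col_character(),
                             .default = readr::col_double()))
    ids <- tab$animal_id
    codes <- as.matrix(tab[, setdiff(names(tab), "animal_id"), drop = FALSE])
  }
  storage.mode(codes) <- "double"
  map <- NULL
  if (!is.null(map_path)) {
    map <- readr::read_tsv(map_path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(
                             marker_id = readr::col_character(),
                             .default = readr::col_guess()))
    sb_assert(nrow(map) == ncol(codes),
              paste0("marker map has ", nrow(map), " rows but genotype file has ",
                     ncol(codes), " marker columns"))
    sb_assert(all(map$marker_id == colnames(codes)) || is.null(colnames(codes)),
              "marker ids in map and genotype file disagree")
  }
  geno_set(codes, map = map, animal_ids = ids)
}

#' Read variance components from YAML
#'
#' Expected keys: `traits` (character), `G0` and `R0` (lists of rows), `k`.
#'
#' @param path YAML file.
#' @return List with `G0`, `R0` (dimnamed matrices) and `k`.
#' @export
read_varcomp <- function(path) {
  y <- yaml::read_yaml(path)
  traits <- y$traits
  as_mat <- function(rows) {
    M <- do.call(rbind, lapply(rows, as.numeric))
    dimnames(M) <- list(traits, traits)
    M
  }
  vc <- list(G0 = as_mat(y$G0), R0 = as_mat(y$R0), k = y$k %||% 0.2)
  check_vc(vc, length(traits))
  vc
}

#' Write a result table as TSV with a metadata header
#'
#' Metadata (units, run settings) goes into leading `# key: value` lines.
#'
#' @param tbl Data frame.
#' @param path Output path.
#' @param meta Named character vector of metadata.
#' @export
write_eval_tsv <- function(tbl, path, meta = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta)) {
    writeLines(paste0("# ", nm, ": ", meta[[nm]]), con)
  }
  utils::write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-checked input loading
#'
#' Reads all input files, verifies that every phenotyped and genotyped
#' animal appears in the pedigree and that the marker panel is consistent,
#' and logs a counts-by-birth-year summary.
#'
#' @param config Named list with paths `pedigree`, `phenotypes`,
#'   `genotypes`, optionally `marker_map` and `varcomp`.
#' @param quiet Suppress the summary log.
#' @return List with `pedigree` (sorted), `phenotypes`, `genotypes`, `vc`.
#' @export
read_inputs <- function(config, quiet = FALSE) {
  ped <- ped_sort(read_pedigree(config$pedigree))
  ph <- read_phenotypes(config$phenotypes)
  geno <- if (!is.null(config$genotypes)) {
    read_genotypes(config$genotypes, config$marker_map)
  }
  vc <- if (!is.null(config$varcomp)) read_varcomp(config$varcomp)
  orphan_ph <- setdiff(ph$animal_id, ped$animal_id)
  if (length(orphan_ph) > 0) {
    sb_abort(paste0("phenotyped animals missing from pedigree: ",
                    paste(head(orphan_ph, 5), collapse = ", ")))
  }
  if (!is.null(geno)) {
    orphan_g <- setdiff(geno$animal_ids, ped$animal_id)
    if (length(orphan_g) > 0) {
      sb_abort(paste0("genotyped animals missing from pedigree: ",
                      paste(head(orphan_g, 5), collapse = ", ")))
    }
  }
  if (!quiet) {
    cnt <- summarize_counts(ped, ph, if (!is.null(geno)) geno$animal_ids else character(0))
    inform(paste0("input counts by birth year:\n",
                  paste(utils::capture.output(print(as.data.frame(cnt))),
                        collapse = "\n")))
  }
  list(pedigree = ped, phenotypes = ph, genotypes = geno, vc = vc)
}

#' Counts of recorded and genotyped animals by birth year
#'
#' @param pedigree Pedigree with `birth_year`, `sex`, `type`.
#' @param phenotypes Phenotype table.
#' @param genotyped_ids Genotyped animal ids.
#' @return Tibble by `birth_year` with cows/steers recorded and genotyped
#'   males/females.
#' @export
summarize_counts <- function(pedigree, phenotypes, genotyped_ids) {
  ped <- as_tibble(pedigree)
  has_ph <- ped$animal_id %in% as.character(phenotypes$animal_id)
  is_g <- ped$animal_id %in% as.character(genotyped_ids)
  ped |>
    dplyr::mutate(has_ph = has_ph, is_g = is_g) |>
    dplyr::group_by(.data$birth_year) |>
    dplyr::summarise(
      cows_recorded = sum(.data$type == "cow" & .data$has_ph),
      steers_recorded = sum(.data$type == "steer" & .data$has_ph),
      genotyped_males = sum(.data$sex == "male" & .data$is_g),
      genotyped_females = sum(.data$sex == "female" & .data$is_g),
      .groups = "drop")
}

#' Write a simulated study as the package's input file dialects
#'
#' Writes `pedigree.csv`, `phenotypes.tsv`, `genotypes.tsv` (simple matrix
#' dialect), `marker_map.tsv`, `varcomp.yaml` and a `manifest.yaml` listing
#' the files, the seed and a configuration hash, so a simulated bundle can
#' be re-read with [read_inputs()].
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of file paths.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- study$population$pedigree
  paths <- list(
    pedigree = file.path(dir, "pedigree.csv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    genotypes = file.path(dir, "genotypes.tsv"),
    marker_map = file.path(dir, "marker_map.tsv"),
    varcomp = file.path(dir, "varcomp.yaml")
  )
  utils::write.csv(
    ped[, c("animal_id", "sire_id", "dam_id", "birth_year", "sex", "path", "type")],
    paths$pedigree, row.names = FALSE, quote = FALSE, na = "")
  write_eval_tsv(study$phenotypes, paths$phenotypes,
                 c(units = "trait columns in recorded trait units"))
  geno <- study$population$geno
  gt <- dplyr::bind_cols(tibble(animal_id = geno$animal_ids),
                         as_tibble(as.data.frame(geno$codes)))
  write_eval_tsv(gt, paths$genotypes, c(format = "simple matrix dialect, codes 0/1/2/NA"))
  write_eval_tsv(geno$map, paths$marker_map, character(0))
  traits <- colnames(as.matrix(study$vc$G0))
  yaml::write_yaml(list(
    traits = traits,
    G0 = apply(unname(as.matrix(study$vc$G0)), 1, as.list),
    R0 = apply(unname(as.matrix(study$vc$R0)), 1, as.list),
    k = study$vc$k
  ), paths$varcomp, precision = 15)
  yaml::write_yaml(list(
    files = lapply(paths, basename),
    seed = study$seed,
    config_hash = rlang::hash(study$config)
  ), file.path(dir, "manifest.yaml"))
  invisible(paths)
}

#' Run the four-evaluation validation study
#'
#' Orchestrates the full comparison design: single-step evaluations with
#' the full and truncated datasets and conventional BLUP evaluations with
#' both datasets, followed by common-base rebasing, SNP-effect scans and
#' agreement, genetic trends, per-year GEBV correlations and the LR test
#' per validation stratum.
#'
#' @param study A `sim_study` from [sim_carcass_study()], or a list with
#'   `phenotypes`, `pedigree`, `geno` (a `geno_set`), `vc`, `groups`,
#'   `cutoff_year`, `base_year`.
#' @param ssm_engine Parameterization used for the single-step runs:
#'   `"ssgblup"` (H-matrix form with exact marker-effect backsolve, the
#'   default) or `"ssnpblup"` (joint marker-effect system). Identical
#'   results up to solver tolerance.
#' @param solver,tol Passed to [fit_blup()].
#' @param run_ssm If `FALSE`, only the conventional BLUP pair is run:
#'   marker-effect outputs (scans, agreement) are absent and the LR test
#'   covers the conventional model only.
#' @param outdir Optional directory for TSV outputs.
#' @return An `ss_study_result` list: `fits`, `gebv`, `scan_full`,
#'   `scan_trunc`, `agreement`, `lr`, `trends`, `year_corr`, `base_ids`,
#'   `log`.
#' @export
run_pipeline <- function(study, ssm_engine = c("ssgblup", "ssnpblup"),
                         solver = "auto", tol = 1e-10, run_ssm = TRUE,
                         outdir = NULL) {
  ssm_engine <- match.arg(ssm_engine)
  if (inherits(study, "sim_study")) {
    ped_raw <- study$population$pedigree
    geno <- study$population$geno
  } else {
    ped_raw <- study$pedigree
    geno <- study$geno
  }
  ph_full <- study$phenotypes
  vc <- study$vc
  ped <- ped_sort(ped_raw)
  Ainv <- ped_a_inverse(ped, groups = study$groups)
  a22 <- ped_a22(ped, geno$animal_ids)
  ph_trunc <- truncate_phenotypes(ph_full, ped, study$cutoff_year)

  fit1 <- function(ph, kind) {
    fit_blup(ph, ped, vc, genotypes = if (kind != "conventional") geno,
             model_kind = kind, groups = study$groups, solver = solver,
             tol = tol, a_inverse = Ainv,
             a22 = if (kind != "conventional") a22)
  }
  fits <- list()
  if (run_ssm) {
    fits$ssm_full <- fit1(ph_full, ssm_engine)
    fits$ssm_trunc <- fit1(ph_trunc, ssm_engine)
  }
  fits$conv_full <- fit1(ph_full, "conventional")
  fits$conv_trunc <- fit1(ph_trunc, "conventional")

  base_ids <- ped$animal_id[ped$birth_year == study$base_year &
                              ped$animal_id %in% as.character(ph_full$animal_id)]
  sb_assert(length(base_ids) > 0, "base cohort (base_year, recorded) is empty")
  gebv <- purrr::map(fits, gebv_rebase, base_ids = base_ids, G0 = vc$G0)

  scan_full <- if (run_ssm) snp_scan(fits$ssm_full)
  scan_trunc <- if (run_ssm) snp_scan(fits$ssm_trunc)
  agreement <- if (run_ssm) {
    effect_agreement(fits$ssm_full$g_hat, fits$ssm_trunc$g_hat)
  }

  recorded <- ped$animal_id %in% as.character(ph_full$animal_id)
  cohorts <- dplyr::bind_rows(
    tibble(animal_id = ped$animal_id[ped$type == "steer" & recorded],
           birth_year = ped$birth_year[ped$type == "steer" & recorded],
           cohort = "steers_with_records"),
    tibble(animal_id = ped$animal_id[ped$type == "cow" & recorded],
           birth_year = ped$birth_year[ped$type == "cow" & recorded],
           cohort = "cows_with_records"),
    tibble(animal_id = geno$animal_ids,
           birth_year = ped$birth_year[match(geno$animal_ids, ped$animal_id)],
           cohort = "genotyped_all")
  )
  trend_src <- if (run_ssm) c(ssm_full = "ssm_full", ssm_trunc = "ssm_trunc")
               else c(conv_full = "conv_full", conv_trunc = "conv_trunc")
  trends <- purrr::map_dfr(trend_src, function(nm) {
    dplyr::mutate(genetic_trend(gebv[[nm]], cohorts), run = nm)
  })

  geno_cohort <- cohorts[cohorts$cohort == "genotyped_all", ]
  year_corr <- dplyr::bind_rows(
    if (run_ssm) dplyr::mutate(gebv_year_correlation(
      gebv$ssm_full, gebv$ssm_trunc, geno_cohort), model = "SSM"),
    dplyr::mutate(gebv_year_correlation(
      gebv$conv_full, gebv$conv_trunc, geno_cohort), model = "CONV")
  )

  lr <- purrr::map_dfr(c("cows", "steers"), function(st) {
    coh <- tryCatch(
      validation_cohort(ped, geno$animal_ids, ph_full, study$cutoff_year, st),
      error = function(e) NULL)
    if (is.null(coh)) return(NULL)
    dplyr::bind_rows(
      if (run_ssm) dplyr::mutate(lr_test(gebv$ssm_full, gebv$ssm_trunc, coh),
                                 model = "SSM", stratum = st),
      dplyr::mutate(lr_test(gebv$conv_full, gebv$conv_trunc, coh),
                    model = "CONV", stratum = st)
    )
  })

  log <- list(
    engine = ssm_engine,
    seed = study$seed %||% NA,
    config_hash = rlang::hash(study$config %||% study),
    glance = purrr::map_dfr(fits, glance, .id = "run")
  )

  out <- structure(list(
    fits = fits, gebv = gebv, base_ids = base_ids,
    scan_full = scan_full, scan_trunc = scan_trunc, agreement = agreement,
    lr = lr, trends = trends, year_corr = year_corr, log = log
  ), class = "ss_study_result")

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    meta <- c(units = "gebv_raw: trait units; gebv_sd: genetic SD, common base",
              config_hash = log$config_hash)
    for (nm in names(gebv)) {
      write_eval_tsv(gebv[[nm]], file.path(outdir, paste0("gebv_", nm, ".tsv")), meta)
    }
    if (run_ssm) {
      write_eval_tsv(scan_full, file.path(outdir, "snp_scan_full.tsv"),
                     c(units = "effect_std: marker genetic SD"))
      write_eval_tsv(scan_trunc, file.path(outdir, "snp_scan_trunc.tsv"),
                     c(units = "effect_std: marker genetic SD"))
      write_eval_tsv(agreement, file.path(outdir, "snp_agreement.tsv"),
                     c(units = "correlation, slope: unitless"))
    }
    write_eval_tsv(trends, file.path(outdir, "genetic_trends.tsv"),
                   c(units = "mean_gebv_sd: genetic SD, common base"))
    write_eval_tsv(lr, file.path(outdir, "lr_test.tsv"),
                   c(units = "b0: genetic SD; b1, r2: unitless"))
    write_eval_tsv(year_corr, file.path(outdir, "gebv_year_correlation.tsv"),
                   c(units = "correlation: unitless"))
  }
  out
}

#' @export
#' @method print ss_study_result
print.ss_study_result <- function(x, ...) {
  cat("<ss_study_result> four evaluations (", x$log$engine,
      " + conventional, full + truncated)\n", sep = "")
  if (!is.null(x$lr) && nrow(x$lr) > 0) {
    cat("LR test (full on truncated, genetic-SD units):\n")
    print(as.data.frame(x$lr), digits = 3)
  }
  invisible(x)
}
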