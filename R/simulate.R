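#' Default variance components for the four carcass traits
#'
#' Package defaults emulating the published ranges for Korean beef carcass
#' traits: heritabilities between 0.28 and 0.48, moderate positive genetic
#' correlations between all trait pairs except low negative correlations of
#' backfat with eye muscle area and marbling. These are plausible
#' round-number defaults, not estimates from any particular dataset.
#'
#' @param k Residual polygenic fraction (default 0.2).
#' @return List with `G0`, `R0` (4 x 4, dimnames CW/EMA/BF/MS), `k`,
#'   `h2`, and phenotypic variances `var_p`.
#' @export
carcass_varcomp <- function(k = 0.2) {
  traits <- CARCASS_TRAITS
  var_p <- c(CW = 900, EMA = 81, BF = 30, MS = 2.56)
  h2 <- c(CW = 0.40, EMA = 0.35, BF = 0.28, MS = 0.48)
  rg <- matrix(c(
    1.00, 0.50, 0.30, 0.30,
    0.50, 1.00, -0.15, 0.35,
    0.30, -0.15, 1.00, -0.10,
    0.30, 0.35, -0.10, 1.00), 4, 4, dimnames = list(traits, traits))
  re <- matrix(c(
    1.00, 0.35, 0.25, 0.15,
    0.35, 1.00, 0.10, 0.15,
    0.25, 0.10, 1.00, 0.05,
    0.15, 0.15, 0.05, 1.00), 4, 4, dimnames = list(traits, traits))
  sg <- sqrt(h2 * var_p)
  se <- sqrt((1 - h2) * var_p)
  G0 <- rg * tcrossprod(sg)
  R0 <- re * tcrossprod(se)
  list(G0 = G0, R0 = R0, k = k, h2 = h2, var_p = var_p)
}

#' Simulation configuration
#'
#' Collects the knobs of the breeding-population generator. Defaults give
#' a small population suitable for unit tests; [sim_carcass_study()] uses
#' a larger, field-realistic configuration.
#'
#' @param n_founders Named vector `c(male = , female = )`.
#' @param n_generations Breeding generations after the founders.
#' @param n_sires Sires used per generation (selected among the previous
#'   generation's males).
#' @param n_dams Dams used per generation.
#' @param offspring_per_dam Offspring per dam (litter of 1 repeated).
#' @param p_genotyped Probability of being genotyped, scalar or one value
#'   per generation (founders first).
#' @param m Number of SNP markers.
#' @param n_chrom Number of chromosomes (markers split evenly).
#' @param n_large_qtl Markers given an inflated effect on `qtl_trait`.
#' @param qtl_multiplier Effect multiplier for those markers.
#' @param qtl_trait Trait index carrying the large regions (1 = CW).
#' @param qtl_chroms Optional chromosomes for the planted regions.
#' @param vc Variance components list (`G0`, `R0`, `k`).
#' @param selection Sire selection rule: `"random"`; `"tbv"` (truncation
#'   on the equal-weight, genetic-SD-scaled index of true breeding values,
#'   an idealized upper bound); or `"ebv"` (truncation on the same index of
#'   EBV from a conventional BLUP of the records available at selection
#'   time, emulating a real breeding program whose selection information is
#'   contained in the evaluation data).
#' @param n_herds Number of herds for the herd-year effect.
#' @param sd_herd_year,sd_year_season Fixed-effect standard deviations as
#'   fractions of the phenotypic SD.
#' @param sex_effect Steer-minus-cow effect as a fraction of phenotypic SD.
#' @param trait_means Population means added to phenotypes.
#' @param age_mean,age_sd Age at slaughter (months).
#' @param age_slopes Per-trait regression of phenotype on age (units/month).
#' @param base_year Birth year of the founders.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = c(male = 30, female = 30),
                       n_generations = 2,
                       n_sires = 8,
                       n_dams = 25,
                       offspring_per_dam = 2,
                       p_genotyped = 0.4,
                       m = 120,
                       n_chrom = 5,
                       n_large_qtl = 0,
                       qtl_multiplier = 12,
                       qtl_trait = 1,
                       qtl_chroms = NULL,
                       vc = carcass_varcomp(),
                       selection = c("random", "tbv", "ebv"),
                       n_herds = 5,
                       sd_herd_year = 0.3,
                       sd_year_season = 0.1,
                       sex_effect = 0.5,
                       trait_means = c(CW = 430, EMA = 96, BF = 13, MS = 5.8),
                       age_mean = 30, age_sd = 3,
                       age_slopes = c(CW = 2, EMA = 0.5, BF = 0.2, MS = 0.05),
                       base_year = 2013) {
  selection <- match.arg(selection)
  if (length(p_genotyped) == 1) {
    p_genotyped <- rep(p_genotyped, n_generations + 1)
  }
  sb_assert(length(p_genotyped) == n_generations + 1,
            "p_genotyped needs one value per generation (founders first)")
  sb_assert(all(c(n_founders, n_sires, n_dams, offspring_per_dam, m, n_chrom) > 0),
            "all counts must be positive")
  k <- vc$k %||% 0.2
  sb_assert(k >= 0 && k <= 1, "k must be in [0, 1]")
  sb_assert(is_spd(vc$G0) && is_spd(vc$R0), "G0 and R0 must be positive definite")
  tr <- colnames(vc$G0) %||% CARCASS_TRAITS
  sb_assert(all(tr %in% names(trait_means)) && all(tr %in% names(age_slopes)),
            "trait_means and age_slopes must be named for every trait in vc$G0")
  structure(as.list(environment()), class = "sim_config")
}

# one slaughter record per cow/steer in `rows`; herd-year and year-season
# levels are cohort-specific (slaughter year differs by cohort), so
# per-call level draws are consistent across incremental calls
sim_pheno_records <- function(cf, ids, types, birth_years, tbv_mat, traits) {
  nt <- length(traits)
  n_rec <- length(ids)
  if (n_rec == 0) return(NULL)
  sd_p <- sqrt(diag(as.matrix(cf$vc$G0)) + diag(as.matrix(cf$vc$R0)))
  slaughter_year <- birth_years + 2L
  herd <- sample.int(cf$n_herds, n_rec, replace = TRUE)
  herd_year <- paste0("H", herd, "_", slaughter_year)
  season <- sample.int(2L, n_rec, replace = TRUE)
  year_season <- paste0(slaughter_year, "_S", season)
  age <- rnorm(n_rec, cf$age_mean, cf$age_sd)
  level_effects <- function(labels, sd_frac) {
    lev <- unique(labels)
    eff <- matrix(rnorm(length(lev) * nt), length(lev), nt) %*%
      diag(sd_frac * sd_p, nt)
    eff[match(labels, lev), , drop = FALSE]
  }
  e <- matrix(rnorm(n_rec * nt), n_rec, nt) %*% chol(as.matrix(cf$vc$R0))
  y <- matrix(rep(unname(cf$trait_means[traits]), each = n_rec), n_rec, nt) +
    level_effects(herd_year, cf$sd_herd_year) +
    level_effects(year_season, cf$sd_year_season) +
    outer(as.numeric(types == "steer"), cf$sex_effect * sd_p) +
    outer(age - cf$age_mean, unname(cf$age_slopes[traits])) +
    tbv_mat + e
  colnames(y) <- traits
  dplyr::bind_cols(
    tibble(animal_id = ids, herd_year = herd_year, year_season = year_season,
           sex = types, age = age),
    as_tibble(y)
  )
}

# one gamete from a parent: one crossover per chromosome per meiosis
make_gamete <- function(h1, h2, chrom_start, chrom_end) {
  gam <- h1
  for (cc in seq_along(chrom_start)) {
    a <- chrom_start[cc]
    b <- chrom_end[cc]
    len <- b - a + 1L
    start_hap <- sample.int(2L, 1L)
    xo <- if (len > 1L) sample.int(len - 1L, 1L) else 0L
    idx <- a:b
    from1 <- if (start_hap == 1L) c(rep(TRUE, xo), rep(FALSE, len - xo))
             else c(rep(FALSE, xo), rep(TRUE, len - xo))
    gam[idx] <- ifelse(from1, h1[idx], h2[idx])
  }
  gam
}

#' Simulate a breeding population by gene dropping
#'
#' Generates a multi-generation pedigree with overlapping fixed-effect
#' structure, founder genotypes drawn from uniform allele frequencies,
#' Mendelian transmission with one crossover per chromosome per meiosis,
#' true marker effects calibrated so that markers carry exactly
#' `(1 - k) G0` of genic variance in the founders (optionally with a few
#' large-effect regions), and residual polygenic effects following the
#' pedigree with covariance `k G0`.
#'
#' @param config A `sim_config`.
#' @param seed Optional seed (if `NULL` the current RNG stream is used).
#' @return A `sim_population`: list with `pedigree` (animal_id, sire_id,
#'   dam_id, birth_year, sex, path, type, generation, genotyped), `geno`
#'   (`geno_set` of the genotyped subset), `codes_all` (all animals),
#'   `map`, `freq0` (founder allele frequencies), `g_true`, `a_true`,
#'   `tbv`, `config`.
#' @export
simulate_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cf <- config
  traits <- colnames(cf$vc$G0) %||% CARCASS_TRAITS
  nt <- ncol(cf$vc$G0)
  m <- cf$m
  n_chrom <- cf$n_chrom
  chrom_of <- sort(rep_len(seq_len(n_chrom), m))
  chrom_start <- match(seq_len(n_chrom), chrom_of)
  chrom_end <- c(chrom_start[-1] - 1L, m)
  map <- tibble(marker_id = sprintf("M%04d", seq_len(m)),
                chromosome = chrom_of,
                position = unlist(lapply(seq_len(n_chrom), function(cc)
                  seq_len(sum(chrom_of == cc)))) * 50000L)

  n_found <- sum(cf$n_founders)
  n_per_gen <- cf$n_dams * cf$offspring_per_dam
  n_total <- n_found + cf$n_generations * n_per_gen

  # founder allele frequencies and haplotypes
  p_draw <- runif(m, 0.05, 0.95)
  H1 <- matrix(0L, n_total, m)
  H2 <- matrix(0L, n_total, m)
  H1[seq_len(n_found), ] <- matrix(rbinom(n_found * m, 1L, rep(p_draw, each = n_found)),
                                   n_found, m)
  H2[seq_len(n_found), ] <- matrix(rbinom(n_found * m, 1L, rep(p_draw, each = n_found)),
                                   n_found, m)
  freq0 <- colMeans(H1[seq_len(n_found), , drop = FALSE] +
                      H2[seq_len(n_found), , drop = FALSE]) / 2
  freq0 <- pmin(pmax(freq0, 0.5 / (2 * n_found)), 1 - 0.5 / (2 * n_found))

  # true marker effects: base draw, planted large regions, then an exact
  # linear recalibration so the founder genic covariance is (1 - k) G0
  k <- cf$vc$k
  w <- 2 * freq0 * (1 - freq0)
  G0 <- as.matrix(cf$vc$G0)
  target <- (1 - k) * G0
  g_true <- matrix(rnorm(m * nt), m, nt)
  qtl_idx <- integer(0)
  if (cf$n_large_qtl > 0) {
    qchroms <- cf$qtl_chroms %||%
      sample(seq_len(n_chrom), min(cf$n_large_qtl, n_chrom))
    qtl_idx <- vapply(qchroms[seq_len(cf$n_large_qtl)], function(cc) {
      sample(which(chrom_of == cc), 1L)
    }, integer(1))
    g_true[qtl_idx, cf$qtl_trait] <- cf$qtl_multiplier *
      sign(g_true[qtl_idx, cf$qtl_trait]) *
      pmax(abs(g_true[qtl_idx, cf$qtl_trait]), 1)
  }
  if (k < 1) {
    Cg <- crossprod(g_true, g_true * w)
    Mcal <- t(chol(target)) %*% solve(t(chol(Cg)))
    g_true <- g_true %*% t(Mcal)
  } else {
    g_true <- g_true * 0
  }
  colnames(g_true) <- traits
  rownames(g_true) <- map$marker_id

  # pedigree scaffolding
  ids <- sprintf("A%05d", seq_len(n_total))
  sire <- rep(NA_character_, n_total)
  dam <- rep(NA_character_, n_total)
  sex <- rep(NA_character_, n_total)
  gen <- integer(n_total)
  type <- rep(NA_character_, n_total)
  sex[seq_len(n_found)] <- rep(c("male", "female"), cf$n_founders)
  type[seq_len(n_found)] <- ifelse(sex[seq_len(n_found)] == "male", "steer", "cow")

  # residual polygenic effects along the pedigree
  a_true <- matrix(0, n_total, nt)
  kG0 <- k * G0
  LkG0 <- if (k > 0) t(chol(kG0)) else matrix(0, nt, nt)
  a_true[seq_len(n_found), ] <- matrix(rnorm(n_found * nt), n_found, nt) %*% t(LkG0)

  sire_i <- integer(n_total)  # integer parent indices, 0 = unknown
  dam_i <- integer(n_total)
  F <- numeric(n_total)       # inbreeding, grown generation by generation
  D <- numeric(n_total)
  D[seq_len(n_found)] <- 1

  gsd <- sqrt(diag(G0))
  tbv_rows <- function(rows) {
    Zr <- sweep(H1[rows, , drop = FALSE] + H2[rows, , drop = FALSE], 2, 2 * freq0)
    Zr %*% g_true + a_true[rows, , drop = FALSE]
  }

  at <- n_found
  ph_rows <- list()
  ph_done <- logical(n_total)
  # generate slaughter records for cohorts at least `lag` generations old
  phenotype_up_to <- function(max_gen) {
    todo <- which(gen[seq_len(at)] <= max_gen & !ph_done[seq_len(at)] &
                    type[seq_len(at)] %in% c("cow", "steer"))
    if (length(todo) > 0) {
      ph_rows[[length(ph_rows) + 1L]] <<- sim_pheno_records(
        cf, ids[todo], type[todo], cf$base_year + gen[todo],
        tbv_rows(todo), traits)
      ph_done[todo] <<- TRUE
    }
    invisible(NULL)
  }
  for (g in seq_len(cf$n_generations)) {
    prev <- if (g == 1) seq_len(n_found) else (at - n_per_gen + 1L):at
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    sb_assert(length(males) > 0 && length(females) > 0,
              "infeasible mating design: a generation lacks one sex")
    n_s <- min(cf$n_sires, length(males))
    phenotype_up_to(g - 2L)
    sires_g <- NULL
    if (length(males) > n_s && cf$selection == "tbv") {
      idx_val <- rowSums(sweep(tbv_rows(males), 2, gsd, "/"))
      sires_g <- males[order(-idx_val)][seq_len(n_s)]
    } else if (length(males) > n_s && cf$selection == "ebv") {
      ph_avail <- dplyr::bind_rows(ph_rows)
      if (!is.null(ph_avail) && nrow(ph_avail) >= 30) {
        sofar <- seq_len(at)
        ped_now <- tibble(animal_id = ids[sofar], sire_id = sire[sofar],
                          dam_id = dam[sofar],
                          birth_year = cf$base_year + gen[sofar],
                          sex = sex[sofar])
        fitc <- suppressMessages(fit_blup(
          ph_avail, ped_now, cf$vc, model_kind = "conventional",
          traits = traits, solver = "direct"))
        eb <- matrix(fitc$u_hat$u, nrow = nt)
        colnames(eb) <- unique(fitc$u_hat$animal_id)
        idx_val <- colSums(eb[, ids[males], drop = FALSE] / gsd)
        sires_g <- males[order(-idx_val)][seq_len(n_s)]
      }
    }
    if (is.null(sires_g)) {
      sires_g <- if (length(males) > n_s) sample(males, n_s) else males
    }
    type[sires_g] <- "bull"
    # a dam may raise more than one litter when females are scarce
    dams_g <- sample(females, cf$n_dams, replace = length(females) < cf$n_dams)

    dam_of <- rep(dams_g, each = cf$offspring_per_dam)
    n_off_g <- length(dam_of)
    sire_of <- sample(sires_g, n_off_g, replace = TRUE)
    rows <- at + seq_len(n_off_g)

    for (o in seq_len(n_off_g)) {
      r <- rows[o]
      s <- sire_of[o]
      d <- dam_of[o]
      H1[r, ] <- make_gamete(H1[s, ], H2[s, ], chrom_start, chrom_end)
      H2[r, ] <- make_gamete(H1[d, ], H2[d, ], chrom_start, chrom_end)
      sire_i[r] <- s
      dam_i[r] <- d
    }
    # inbreeding of the new cohort (Meuwissen-Luo trace on the grown pedigree)
    for (r in rows) {
      D[r] <- 0.5 - 0.25 * (F[sire_i[r]] + F[dam_i[r]])
      v <- numeric(r)
      v[r] <- 1
      aii <- 0
      for (j in rev(seq_len(r))) {
        if (v[j] == 0) next
        aii <- aii + v[j]^2 * D[j]
        if (sire_i[j] > 0L) v[sire_i[j]] <- v[sire_i[j]] + 0.5 * v[j]
        if (dam_i[j] > 0L) v[dam_i[j]] <- v[dam_i[j]] + 0.5 * v[j]
      }
      F[r] <- aii - 1
    }
    msv <- 0.5 - 0.25 * (F[sire_of] + F[dam_of])
    a_true[rows, ] <- 0.5 * (a_true[sire_of, , drop = FALSE] +
                               a_true[dam_of, , drop = FALSE]) +
      (matrix(rnorm(n_off_g * nt), n_off_g, nt) * sqrt(msv)) %*% t(LkG0)

    sire[rows] <- ids[sire_of]
    dam[rows] <- ids[dam_of]
    sex[rows] <- sample(c("male", "female"), n_off_g, replace = TRUE)
    type[rows] <- ifelse(sex[rows] == "male", "steer", "cow")
    gen[rows] <- g
    at <- at + n_off_g
  }

  phenotype_up_to(cf$n_generations)
  phenotypes <- dplyr::bind_rows(ph_rows)
  codes_all <- H1 + H2
  rownames(codes_all) <- ids
  colnames(codes_all) <- map$marker_id
  genotyped <- runif(n_total) < cf$p_genotyped[gen + 1L]
  path <- ifelse(sex == "male",
                 sample(c("SS", "SD"), n_total, replace = TRUE),
                 sample(c("DS", "DD"), n_total, replace = TRUE))
  pedigree <- tibble(
    animal_id = ids, sire_id = sire, dam_id = dam,
    birth_year = cf$base_year + gen,
    sex = sex, path = path, type = type,
    generation = gen, genotyped = genotyped, F = F
  )
  tbv <- tbv_rows(seq_len(n_total))
  rownames(tbv) <- ids
  geno <- geno_set(codes_all[genotyped, , drop = FALSE], map = map)
  structure(list(
    pedigree = pedigree, geno = geno, codes_all = codes_all, map = map,
    freq0 = freq0, g_true = g_true, a_true = a_true, tbv = tbv,
    phenotypes = phenotypes, qtl_idx = qtl_idx, config = cf, traits = traits
  ), class = "sim_population")
}

#' @export
#' @method print sim_population
print.sim_population <- function(x, ...) {
  cat("<sim_population> ", nrow(x$pedigree), " animals (",
      sum(x$pedigree$genotyped), " genotyped), ", nrow(x$map), " markers on ",
      max(x$map$chromosome), " chromosomes\n", sep = "")
  invisible(x)
}

#' Simulate one slaughter record per cow and steer
#'
#' Each cow and steer receives a single record of all traits:
#' herd-year and year-season effects (drawn per level), a sex (cow/steer)
#' effect, a linear age regression, the true breeding value, and a
#' residual drawn from `R0`. Bulls get no record.
#'
#' Records are already generated during [simulate_population()] (they may
#' drive EBV-based sire selection); with `fresh = FALSE` (default) the
#' stored table is returned. With `fresh = TRUE` a new, independent set of
#' records is drawn for the same population and true breeding values.
#'
#' @param pop A `sim_population`.
#' @param seed Optional seed (only used with `fresh = TRUE`).
#' @param fresh Redraw environmental effects and residuals.
#' @return Tibble with `animal_id`, `herd_year`, `year_season`, `sex`,
#'   `age`, and one column per trait.
#' @export
simulate_phenotypes <- function(pop, seed = NULL, fresh = FALSE) {
  if (!fresh && !is.null(pop$phenotypes)) return(pop$phenotypes)
  if (!is.null(seed)) set.seed(seed)
  cf <- pop$config
  traits <- pop$traits
  ped <- pop$pedigree
  rec <- ped$type %in% c("cow", "steer")
  sb_assert(sum(rec) > 0, "no cows or steers to phenotype")
  sb_assert(all(traits %in% names(cf$trait_means)) &&
              all(traits %in% names(cf$age_slopes)),
            "trait_means and age_slopes must be named for every trait")
  an <- ped[rec, ]
  sim_pheno_records(cf, an$animal_id, an$type, an$birth_year,
                    pop$tbv[match(an$animal_id, rownames(pop$tbv)), , drop = FALSE],
                    traits)
}

#' Field-realistic carcass evaluation scenario
#'
#' Bundles a complete study: a five-cohort population of about 2,000
#' animals (founders born 2013, last cohort 2017) with roughly 500
#' genotyped animals skewed towards recent birth years, 1,000 markers on
#' 29 chromosomes with three large-effect regions for carcass weight on
#' chromosomes 4, 6 and 14, EBV-based truncation selection of sires (so the
#' selection information is contained in the evaluation data), one
#' slaughter record per cow and steer, phantom parent groups for the
#' founders, a truncation cutoff at birth year 2016 and the 2015-born
#' recorded animals as the common base cohort.
#'
#' @param seed Seed for the whole bundle.
#' @param config Optional `sim_config` overriding the defaults.
#' @return A `sim_study`: list with `population`, `phenotypes`, `vc`,
#'   `groups`, `cutoff_year`, `base_year`, `config`, `seed`.
#' @export
sim_carcass_study <- function(seed = 1, config = NULL) {
  cf <- config %||% sim_config(
    n_founders = c(male = 130, female = 130),
    n_generations = 4,
    n_sires = 20,
    n_dams = 145,
    offspring_per_dam = 3,
    p_genotyped = c(0.02, 0.05, 0.12, 0.35, 0.60),
    m = 1000,
    n_chrom = 29,
    n_large_qtl = 3,
    qtl_multiplier = 15,
    qtl_trait = 1,
    qtl_chroms = c(4, 6, 14),
    selection = "ebv",
    n_herds = 15,
    base_year = 2013
  )
  set.seed(seed)
  pop <- simulate_population(cf)
  phenotypes <- pop$phenotypes
  ped_sorted <- ped_sort(pop$pedigree)
  groups <- ped_phantom_groups(ped_sorted,
                               year_bins = c(cf$base_year, cf$base_year + 1L))
  structure(list(
    population = pop,
    phenotypes = phenotypes,
    vc = cf$vc,
    groups = groups,
    cutoff_year = cf$base_year + cf$n_generations - 1L,
    base_year = cf$base_year + cf$n_generations - 2L,
    config = cf,
    seed = seed
  ), class = "sim_study")
}

#' @export
#' @method print sim_study
print.sim_study <- function(x, ...) {
  cat("<sim_study> seed ", x$seed, ": ", nrow(x$population$pedigree),
      " animals, ", nrow(x$phenotypes), " records, cutoff ", x$cutoff_year,
      ", base year ", x$base_year, "\n", sep = "")
  invisible(x)
}
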