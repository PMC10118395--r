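test_that("the generator is deterministic under a fixed seed", {
  cf <- sim_config(n_founders = c(male = 15, female = 15), n_generations = 1,
                   n_sires = 5, n_dams = 10, offspring_per_dam = 2,
                   p_genotyped = 0.5, m = 60, n_chrom = 3)
  p1 <- simulate_population(cf, seed = 42)
  p2 <- simulate_population(cf, seed = 42)
  expect_identical(p1$pedigree, p2$pedigree)
  expect_identical(p1$codes_all, p2$codes_all)
  expect_identical(p1$tbv, p2$tbv)
  expect_identical(p1$phenotypes, p2$phenotypes)
  st1 <- sim_carcass_study(seed = 9, config = cf)
  st2 <- sim_carcass_study(seed = 9, config = cf)
  expect_identical(st1$phenotypes, st2$phenotypes)
})

test_that("founder true breeding values have variance G0", {
  vc <- carcass_varcomp()
  cf <- sim_config(n_founders = c(male = 2500, female = 2500),
                   n_generations = 1, n_sires = 5, n_dams = 5,
                   offspring_per_dam = 1, p_genotyped = 0,
                   m = 200, n_chrom = 10, vc = vc)
  pop <- simulate_population(cf, seed = 43)
  founders <- pop$pedigree$generation == 0
  v_emp <- apply(pop$tbv[founders, ], 2, var)
  v_target <- diag(as.matrix(vc$G0))
  expect_true(all(abs(v_emp / v_target - 1) < 0.10))
})

test_that("phenotypes decompose as the record model states", {
  # no environmental terms and a near-zero residual: phenotype = mean + tbv
  traits <- stepblup:::CARCASS_TRAITS
  vc <- carcass_varcomp()
  vc$R0 <- diag(1e-8, 4, names = FALSE)
  dimnames(vc$R0) <- dimnames(vc$G0)
  cf <- sim_config(n_founders = c(male = 20, female = 20), n_generations = 1,
                   n_sires = 5, n_dams = 15, offspring_per_dam = 2,
                   p_genotyped = 0, m = 60, n_chrom = 3, vc = vc,
                   sd_herd_year = 0, sd_year_season = 0, sex_effect = 0,
                   age_slopes = c(CW = 0, EMA = 0, BF = 0, MS = 0))
  pop <- simulate_population(cf, seed = 44)
  ph <- pop$phenotypes
  tb <- pop$tbv[match(ph$animal_id, rownames(pop$tbv)), ]
  for (tr in traits) {
    expect_lt(max(abs(ph[[tr]] - cf$trait_means[tr] - tb[, tr])), 1e-3)
  }
})

test_that("simulated records recover the configured heritabilities", {
  vc <- carcass_varcomp()
  cf <- sim_config(n_founders = c(male = 2500, female = 2500),
                   n_generations = 0, n_sires = 5, n_dams = 5,
                   offspring_per_dam = 1, p_genotyped = 0, m = 200,
                   n_chrom = 10, vc = vc,
                   sd_herd_year = 0, sd_year_season = 0, sex_effect = 0,
                   age_slopes = c(CW = 0, EMA = 0, BF = 0, MS = 0))
  pop <- simulate_population(cf, seed = 45)
  ph <- pop$phenotypes
  for (tr in names(vc$h2)) {
    tb <- pop$tbv[match(ph$animal_id, rownames(pop$tbv)), tr]
    h2_emp <- var(tb) / var(ph[[tr]])
    expect_lt(abs(h2_emp - vc$h2[[tr]]), 0.05)
  }
})

test_that("the age regression is recovered from simulated records", {
  vc <- carcass_varcomp()
  cf <- sim_config(n_founders = c(male = 1500, female = 1500),
                   n_generations = 0, n_sires = 5, n_dams = 5,
                   offspring_per_dam = 1, p_genotyped = 0, m = 100,
                   n_chrom = 5, vc = vc, sd_herd_year = 0,
                   sd_year_season = 0, sex_effect = 0)
  pop <- simulate_population(cf, seed = 46)
  ph <- pop$phenotypes
  for (tr in c("CW", "MS")) {
    fit <- stats::lm(ph[[tr]] ~ ph$age)
    est <- coef(summary(fit))[2, ]
    expect_lt(abs(est["Estimate"] - cf$age_slopes[[tr]]), 2 * est["Std. Error"])
  }
})

test_that("gene dropping is Mendelian-consistent and detects shuffled parents", {
  sim <- small_sim(seed = 47, m = 300)
  allgeno <- geno_set(sim$pop$codes_all, map = sim$pop$map)
  rep_true <- verify_parentage(allgeno, ped_sort(sim$ped))
  expect_equal(sum(rep_true$conflict), 0L)
  # offspring TBV regress on mid-parent TBV with slope ~ 1 (no selection)
  ped <- sim$ped
  off <- which(!is.na(ped$sire_id) & !is.na(ped$dam_id))
  mid <- 0.5 * (sim$pop$tbv[match(ped$sire_id[off], ped$animal_id), ] +
                  sim$pop$tbv[match(ped$dam_id[off], ped$animal_id), ])
  sl <- coef(stats::lm(sim$pop$tbv[off, "CW"] ~ mid[, "CW"]))[2]
  expect_gt(sl, 0.7)
  expect_lt(sl, 1.3)
})

test_that("the field-realistic bundle has the documented structure", {
  cf_small <- sim_config(n_founders = c(male = 30, female = 30),
                         n_generations = 2, n_sires = 8, n_dams = 22,
                         offspring_per_dam = 2,
                         p_genotyped = c(0.1, 0.3, 0.6), m = 120, n_chrom = 5,
                         n_large_qtl = 2, qtl_multiplier = 15,
                         selection = "ebv", base_year = 2015)
  st <- sim_carcass_study(seed = 48, config = cf_small)
  ped <- st$population$pedigree
  expect_equal(sort(unique(ped$birth_year)), 2015:2017)
  # cutoff splits off the last cohort; base cohort is the year before
  expect_equal(st$cutoff_year, 2016)
  expect_equal(st$base_year, 2015)
  # genotyping skewed towards recent cohorts (expected by construction)
  frac <- tapply(ped$genotyped, ped$generation, mean)
  expect_gt(frac[3], frac[1])
  # planted markers are the top true effects for the target trait
  g1 <- abs(st$population$g_true[, 1])
  expect_setequal(order(-g1)[1:2], st$population$qtl_idx)
  # phantom groups cover every missing slot
  miss <- sum(is.na(ped$sire_id)) + sum(is.na(ped$dam_id))
  expect_equal(nrow(st$groups$assignments), miss)
  # bulls carry no slaughter record
  bulls <- ped$animal_id[ped$type == "bull"]
  expect_false(any(bulls %in% st$phenotypes$animal_id))
})
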