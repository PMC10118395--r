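# small hand-built phenotype table over an existing pedigree
manual_ph <- function(ped, traits = c("T1", "T2"), seed = 1, n_rec = nrow(ped)) {
  set.seed(seed)
  rec <- ped$animal_id[seq_len(n_rec)]
  n <- length(rec)
  tb <- tibble::tibble(
    animal_id = rec,
    herd_year = sample(paste0("H", 1:3, "_Y1"), n, replace = TRUE),
    year_season = sample(c("Y1_S1", "Y1_S2"), n, replace = TRUE),
    sex = sample(c("cow", "steer"), n, replace = TRUE),
    age = rnorm(n, 30, 3))
  for (tr in traits) tb[[tr]] <- rnorm(n, 10, 3)
  tb
}

vc_2trait <- function(k = 0.2) {
  tn <- c("T1", "T2")
  list(G0 = matrix(c(4, 1.2, 1.2, 9), 2, dimnames = list(tn, tn)),
       R0 = matrix(c(6, 0.8, 0.8, 12), 2, dimnames = list(tn, tn)),
       k = k)
}

test_that("the design reproduces record-to-level assignment", {
  set.seed(71)
  ped <- ped_sort(rand_ped(40, n_founders = 10))
  ph <- manual_ph(ped, n_rec = 30)
  des <- suppressMessages(build_design(ph, traits = c("T1", "T2")))
  X <- as.matrix(des$X)
  fl <- des$fixed_levels
  for (i in seq_len(nrow(ph))) {
    for (eff in c("herd_year", "year_season", "sex")) {
      lv <- as.character(ph[[eff]][i])
      col <- fl$col[fl$effect == eff & fl$level == lv]
      if (length(col) == 1) expect_equal(X[i, col], 1)
    }
  }
  # covariate centered
  agecol <- fl$col[fl$effect == "age"]
  expect_lt(abs(sum(X[, agecol])), 1e-8)
  # missing trait values rejected (all-or-none recording)
  ph_bad <- ph
  ph_bad$T1[3] <- NA
  expect_error(build_design(ph_bad, traits = c("T1", "T2")), "all-or-none")
})

test_that("a lone founder with one record shrinks by n/(n + lambda)", {
  ped <- ped_sort(tibble::tibble(animal_id = "a", sire_id = NA, dam_id = NA))
  vc <- list(G0 = matrix(4, dimnames = list("T1", "T1")),
             R0 = matrix(8, dimnames = list("T1", "T1")), k = 0.2)
  ph <- tibble::tibble(animal_id = "a", T1 = 3)
  fit <- fit_blup(ph, ped, vc, model_kind = "conventional",
                  traits = "T1", class_effects = character(0), covariate = NULL,
                  solver = "direct")
  lambda <- 8 / 4
  expect_equal(fit$u_hat$u, 3 / (1 + lambda), tolerance = 1e-12)
})

test_that("diagonal covariance matrices decouple the traits", {
  set.seed(72)
  ped <- ped_sort(rand_ped(30, n_founders = 8))
  ph <- manual_ph(ped, n_rec = 25)
  tn <- c("T1", "T2")
  vc_d <- list(G0 = matrix(c(4, 0, 0, 9), 2, dimnames = list(tn, tn)),
               R0 = matrix(c(6, 0, 0, 12), 2, dimnames = list(tn, tn)), k = 0.2)
  fit2 <- suppressMessages(fit_blup(ph, ped, vc_d, model_kind = "conventional",
                                    traits = tn, solver = "direct"))
  for (j in 1:2) {
    vc1 <- list(G0 = matrix(vc_d$G0[j, j], dimnames = list(tn[j], tn[j])),
                R0 = matrix(vc_d$R0[j, j], dimnames = list(tn[j], tn[j])), k = 0.2)
    fit1 <- suppressMessages(fit_blup(ph, ped, vc1, model_kind = "conventional",
                                      traits = tn[j], solver = "direct"))
    u2 <- fit2$u_hat$u[fit2$u_hat$trait == tn[j]]
    expect_equal(u2, fit1$u_hat$u, tolerance = 1e-9)
  }
})

test_that("conventional solutions match the dense GLS oracle", {
  set.seed(73)
  ped <- ped_sort(rand_ped(30, n_founders = 8, p_missing = 0))
  ph <- manual_ph(ped, n_rec = 24, seed = 4)
  vc <- vc_2trait()
  fit <- suppressMessages(fit_blup(ph, ped, vc, model_kind = "conventional",
                                   traits = c("T1", "T2"), solver = "direct"))
  orc <- oracle_gls(ph, ped, vc, traits = c("T1", "T2"))
  merged <- dplyr::inner_join(fit$u_hat, orc$u, by = c("animal_id", "trait"),
                              suffix = c("_fit", "_orc"))
  expect_equal(nrow(merged), nrow(ped) * 2)
  expect_lt(max(abs(merged$u_fit - merged$u_orc)), 1e-8)
})

test_that("k boundaries behave as the variance split dictates", {
  sim <- small_sim(seed = 14, m = 100)
  vc1 <- sim$vc
  vc1$k <- 1
  conv <- suppressMessages(fit_blup(sim$ph, sim$ped, vc1,
                                    model_kind = "conventional", solver = "direct"))
  for (kind in c("ssnpblup", "ssgblup")) {
    f <- suppressMessages(fit_blup(sim$ph, sim$ped, vc1, genotypes = sim$geno,
                                   model_kind = kind, solver = "direct"))
    expect_lt(max(abs(f$u_hat$u - conv$u_hat$u)), 1e-8)
  }
  vc0 <- sim$vc
  vc0$k <- 0
  expect_error(
    suppressMessages(fit_blup(sim$ph, sim$ped, vc0, genotypes = sim$geno,
                              model_kind = "ssnpblup", solver = "direct")),
    "k = 0")
})

test_that("uninformative markers leave both single-step forms in agreement", {
  # all-heterozygous codes: p = 0.5, Z = 0, D > 0; marker effects vanish and
  # the two parameterizations stay equivalent (they equal conventional BLUP
  # only at k = 1, since the RPG blend keeps weight k on A22)
  sim <- small_sim(seed = 15, m = 60)
  codes0 <- matrix(1, nrow(sim$geno$codes), ncol(sim$geno$codes),
                   dimnames = dimnames(sim$geno$codes))
  g0 <- geno_set(codes0, map = sim$geno$map)
  fs <- suppressMessages(fit_blup(sim$ph, sim$ped, sim$vc, genotypes = g0,
                                  model_kind = "ssnpblup", solver = "direct"))
  fg <- suppressMessages(fit_blup(sim$ph, sim$ped, sim$vc, genotypes = g0,
                                  model_kind = "ssgblup", solver = "direct"))
  expect_lt(max(abs(fs$u_hat$u - fg$u_hat$u)), 1e-8)
  expect_lt(max(abs(fs$g_hat$g)), 1e-10)
})

test_that("PCG solves the identity system in one iteration", {
  mme <- structure(list(
    C = Matrix::Diagonal(8),
    rhs = as.numeric(1:8),
    fixed_levels = tibble::tibble(effect = character(0), level = character(0),
                                  col = integer(0)),
    u_ids = paste0("a", 1:4),
    traits = c("T1", "T2"),
    vc = NULL, kind = "conventional", meta = list()
  ), class = "mme_system")
  fit <- solve_pcg(mme)
  expect_equal(fit$convergence$iterations, 1L)
  expect_true(fit$convergence$converged)
  expect_equal(fit$solution, as.numeric(1:8))
})

test_that("PCG agrees with the direct solver and flags non-convergence", {
  sim <- small_sim(seed = 16, m = 80)
  ped <- ped_sort(sim$ped)
  des <- suppressMessages(build_design(sim$ph))
  mme <- assemble_conventional(des, ped_a_inverse(ped), sim$vc)
  fd <- solve_direct(mme)
  fp <- solve_pcg(mme, tol = 1e-12)
  expect_lt(max(abs(fd$solution - fp$solution)), 1e-8)
  capped <- solve_pcg(mme, tol = 1e-12, max_iter = 3)
  expect_false(capped$convergence$converged)
  expect_equal(capped$convergence$iterations, 3L)
})

test_that("solutions are invariant to animal, record and marker ordering", {
  sim <- small_sim(seed = 17, m = 80)
  base <- suppressMessages(fit_blup(sim$ph, sim$ped, sim$vc, genotypes = sim$geno,
                                    model_kind = "ssgblup", solver = "direct"))
  set.seed(18)
  ped_p <- sim$ped[sample.int(nrow(sim$ped)), ]
  ph_p <- sim$ph[sample.int(nrow(sim$ph)), ]
  mperm <- sample.int(ncol(sim$geno$codes))
  geno_p <- geno_set(sim$geno$codes[sample.int(nrow(sim$geno$codes)), mperm],
                     map = sim$geno$map[mperm, ])
  perm <- suppressMessages(fit_blup(ph_p, ped_p, sim$vc, genotypes = geno_p,
                                    model_kind = "ssgblup", solver = "direct"))
  mu <- dplyr::inner_join(base$u_hat, perm$u_hat, by = c("animal_id", "trait"))
  expect_lt(max(abs(mu$u.x - mu$u.y)), 1e-8)
  mg <- dplyr::inner_join(base$g_hat, perm$g_hat, by = c("marker_id", "trait"))
  expect_equal(nrow(mg), nrow(base$g_hat))
  expect_lt(max(abs(mg$g.x - mg$g.y)), 1e-8)
})

test_that("GEBV of genotyped animals decompose into Zg + a", {
  sim <- small_sim(seed = 19, m = 120)
  fit <- suppressMessages(fit_blup(sim$ph, sim$ped, sim$vc, genotypes = sim$geno,
                                   model_kind = "ssnpblup", solver = "direct"))
  fr <- geno_allele_freq(sim$geno)
  Z <- geno_center(geno_impute(sim$geno, fr), fr)
  traits <- fit$traits
  gmat <- matrix(fit$g_hat$g, ncol = length(traits), byrow = TRUE)
  amat <- matrix(fit$a_hat$a, ncol = length(traits), byrow = TRUE)
  ug <- fit$u_hat[fit$u_hat$animal_id %in% sim$geno$animal_ids, ]
  umat <- matrix(ug$u[order(match(ug$animal_id, sim$geno$animal_ids))],
                 ncol = length(traits), byrow = TRUE)
  expect_lt(max(abs(umat - (Z %*% gmat + amat))), 10 * 1e-8)
})

test_that("adding a record never worsens the reliability proxy", {
  set.seed(74)
  ped <- ped_sort(rand_ped(15, n_founders = 5, p_missing = 0))
  vc <- vc_2trait()
  ph1 <- manual_ph(ped, n_rec = 10, seed = 6)
  ph2 <- dplyr::bind_rows(ph1, tibble::tibble(
    animal_id = ped$animal_id[11], herd_year = "H1_Y1", year_season = "Y1_S1",
    sex = "cow", age = 30, T1 = 11, T2 = 9))  # same records plus one
  Ainv <- ped_a_inverse(ped)
  m1 <- assemble_conventional(suppressMessages(build_design(ph1, traits = c("T1", "T2"))),
                              Ainv, vc)
  m2 <- assemble_conventional(suppressMessages(build_design(ph2, traits = c("T1", "T2"))),
                              Ainv, vc)
  pev <- dplyr::inner_join(reliability_pev(m1), reliability_pev(m2),
                           by = c("animal_id", "trait"))
  expect_true(all(pev$pev.y <= pev$pev.x + 1e-10))
})
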