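# Independent oracles, deliberately written as plain scalar loops / dense
# algebra so they share no code path with the package implementations.

# tabular additive relationship matrix, scalar double loop
oracle_tabular_a <- function(ped) {
  ids <- ped$animal_id
  s <- match(ped$sire_id, ids, nomatch = 0L)
  d <- match(ped$dam_id, ids, nomatch = 0L)
  n <- length(ids)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        aij <- 0
        if (s[i] > 0) aij <- aij + 0.5 * A[j, s[i]]
        if (d[i] > 0) aij <- aij + 0.5 * A[j, d[i]]
        A[i, j] <- A[j, i] <- aij
      }
    }
    A[i, i] <- 1 + if (s[i] > 0 && d[i] > 0) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(ids, ids)
  A
}

# random sorted pedigree; odd founders male, parents drawn from earlier rows
rand_ped <- function(n, n_founders = max(6L, n %/% 5L), p_missing = 0.1) {
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[1:2] <- c("male", "female")
  sire <- dam <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (i <= n_founders) next
    prev <- seq_len(i - 1L)
    ms <- prev[sex[prev] == "male"]
    fs <- prev[sex[prev] == "female"]
    if (length(ms) > 0 && runif(1) > p_missing) {
      sire[i] <- as.character(ms[sample.int(length(ms), 1L)])
    }
    if (length(fs) > 0 && runif(1) > p_missing) {
      dam[i] <- as.character(fs[sample.int(length(fs), 1L)])
    }
  }
  tibble::tibble(animal_id = as.character(seq_len(n)), sire_id = sire,
                 dam_id = dam, sex = sex,
                 birth_year = 2000L + (seq_len(n) - 1L) %/% max(1L, n %/% 5L),
                 path = sample(c("SS", "SD", "DS", "DD"), n, replace = TRUE))
}

# dense generalized-least-squares mixed-model oracle: BLUE of the fixed part
# and BLUP of breeding values from the variance matrices directly
oracle_gls <- function(phenotypes, pedigree, vc, traits,
                       class_effects = c("herd_year", "year_season", "sex"),
                       covariate = "age") {
  ped <- stepblup::ped_sort(pedigree)
  A <- oracle_tabular_a(ped)
  nt <- length(traits)
  G0 <- as.matrix(vc$G0)
  R0 <- as.matrix(vc$R0)
  n <- nrow(ped)
  n_rec <- nrow(phenotypes)
  # fixed design via base model.matrix (its own parameterization)
  fm <- stats::as.formula(paste(
    "~", paste(c(class_effects, sprintf("I(%s - mean(%s))", covariate, covariate)),
               collapse = " + ")))
  df <- as.data.frame(phenotypes)
  for (ce in class_effects) df[[ce]] <- factor(df[[ce]])
  Xf <- stats::model.matrix(fm, df)
  keep <- qr(Xf)$pivot[seq_len(qr(Xf)$rank)]
  Xf <- Xf[, keep, drop = FALSE]
  Zinc <- matrix(0, n_rec, n)
  Zinc[cbind(seq_len(n_rec), match(as.character(phenotypes$animal_id), ped$animal_id))] <- 1
  Gu <- kronecker(A, G0)
  Zbig <- kronecker(Zinc, diag(nt))
  Xbig <- kronecker(Xf, diag(nt))
  V <- Zbig %*% Gu %*% t(Zbig) + kronecker(diag(n_rec), R0)
  y <- as.vector(t(as.matrix(phenotypes[, traits])))
  Vi <- solve(V)
  XtVi <- t(Xbig) %*% Vi
  f <- solve(XtVi %*% Xbig, XtVi %*% y)
  u <- Gu %*% t(Zbig) %*% Vi %*% (y - Xbig %*% f)
  list(
    u = tibble::tibble(animal_id = rep(ped$animal_id, each = nt),
                       trait = rep(traits, n), u = as.vector(u)),
    fitted_fixed = as.vector(Xbig %*% f)
  )
}

# small simulated dataset for model tests
small_sim <- function(seed = 1, k = 0.2, m = 150, n_gen = 2, p_geno = 0.5) {
  vc <- stepblup::carcass_varcomp(k = k)
  cf <- stepblup::sim_config(
    n_founders = c(male = 25, female = 25), n_generations = n_gen,
    n_sires = 8, n_dams = 20, offspring_per_dam = 2,
    p_genotyped = p_geno, m = m, n_chrom = 5, vc = vc)
  pop <- stepblup::simulate_population(cf, seed = seed)
  list(pop = pop, ph = pop$phenotypes, vc = vc, ped = pop$pedigree,
       geno = pop$geno)
}

expect_silent_messages <- function(expr) {
  suppressMessages(expr)
}
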