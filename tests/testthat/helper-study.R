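# The forward-validation study used by several acceptance checks: ten
# field-realistic bundles (seeds fixed once) through the four-evaluation
# pipeline. Computed lazily and cached for the test session.
.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function(n_seeds = 10) {
  key <- paste0("s", n_seeds)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  runs <- lapply(seq_len(n_seeds), function(i) {
    st <- stepblup::sim_carcass_study(seed = 100 + i)
    out <- suppressWarnings(suppressMessages(stepblup::run_pipeline(st)))
    list(
      lr = out$lr,
      agreement = out$agreement,
      year_corr = out$year_corr,
      scan_full = out$scan_full,
      trends = out$trends,
      qtl = st$population$map[st$population$qtl_idx, ],
      map = st$population$map,
      cutoff = st$cutoff_year
    )
  })
  .study_cache[[key]] <- runs
  runs
}

# equivalence datasets: small populations spanning the RPG fractions
equiv_dataset <- function(seed, k) {
  vc <- stepblup::carcass_varcomp(k = k)
  cf <- stepblup::sim_config(
    n_founders = c(male = 30, female = 30), n_generations = 2,
    n_sires = 10, n_dams = 30, offspring_per_dam = 3,
    p_genotyped = 0.5, m = 300, n_chrom = 10, vc = vc)
  pop <- stepblup::simulate_population(cf, seed = seed)
  list(pop = pop, ph = pop$phenotypes, vc = vc)
}

# are the top scan markers inside a planted region (same chromosome, within
# `window` markers of a planted marker)?
in_planted_region <- function(marker_ids, map, qtl, window = 10) {
  pos <- match(marker_ids, map$marker_id)
  qpos <- match(qtl$marker_id, map$marker_id)
  vapply(pos, function(p) {
    any(map$chromosome[p] == map$chromosome[qpos] & abs(p - qpos) <= window)
  }, logical(1))
}
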