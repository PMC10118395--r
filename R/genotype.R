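#' Construct a genotype set
#'
#' Bundles a 0/1/2 dosage matrix with its marker map. Rows are animals,
#' columns are markers; `NA` marks a missing call.
#'
#' @param codes Numeric matrix of allele dosages in \{0, 1, 2, NA\} with
#'   animal ids as rownames (or supply `animal_ids`).
#' @param map Data frame with `marker_id`, `chromosome`, `position`
#'   (one row per column of `codes`). If omitted, markers are placed on one
#'   chromosome at consecutive positions.
#' @param animal_ids Optional character vector of animal ids.
#' @return An object of class `geno_set`.
#' @export
geno_set <- function(codes, map = NULL, animal_ids = NULL) {
  codes <- as.matrix(codes)
  animal_ids <- as.character(animal_ids %||% rownames(codes))
  sb_assert(length(animal_ids) == nrow(codes) && !anyNA(animal_ids),
            "genotype matrix needs one id per row")
  if (is.null(map)) {
    map <- tibble(marker_id = colnames(codes) %||% paste0("M", seq_len(ncol(codes))),
                  chromosome = 1L, position = seq_len(ncol(codes)))
  }
  map <- as_tibble(map)
  sb_assert(all(c("marker_id", "chromosome", "position") %in% names(map)),
            "marker map needs marker_id, chromosome, position")
  sb_assert(nrow(map) == ncol(codes), "map rows must match genotype columns")
  sb_assert(!anyDuplicated(map$marker_id), "marker ids must be unique")
  sb_assert(ncol(codes) > 0, "need at least one marker")
  ok <- codes %in% c(0, 1, 2) | is.na(codes)
  sb_assert(all(ok), "genotype codes must be 0, 1, 2 or NA")
  dimnames(codes) <- list(animal_ids, map$marker_id)
  structure(list(codes = codes, map = map, animal_ids = animal_ids),
            class = "geno_set")
}

#' @export
#' @method print geno_set
print.geno_set <- function(x, ...) {
  cat("<geno_set> ", nrow(x$codes), " animals x ", ncol(x$codes), " markers (",
      sum(is.na(x$codes)), " missing calls)\n", sep = "")
  invisible(x)
}

#' Observed allele frequencies
#'
#' Frequencies of the counted allele per marker, computed over non-missing
#' calls among the genotyped animals. Frequencies are clamped away from 0
#' and 1 (by half an allele count) so that no marker has zero variance.
#'
#' @param geno A `geno_set`.
#' @param clamp Clamp frequencies to `[0.5/(2n), 1 - 0.5/(2n)]` (default TRUE).
#' @return A tibble with `marker_id`, `p`, `n_called`, `monomorphic`.
#' @export
geno_allele_freq <- function(geno, clamp = TRUE) {
  codes <- geno$codes
  n_called <- colSums(!is.na(codes))
  if (any(n_called == 0)) {
    sb_abort(paste0("markers with no genotype calls: ",
                    paste(head(colnames(codes)[n_called == 0], 5), collapse = ", ")))
  }
  p <- colMeans(codes, na.rm = TRUE) / 2
  mono <- p <= 0 | p >= 1
  if (clamp) {
    lo <- 0.5 / (2 * n_called)
    p <- pmin(pmax(p, lo), 1 - lo)
  }
  tibble(marker_id = geno$map$marker_id, p = unname(p),
         n_called = unname(n_called), monomorphic = unname(mono))
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing call at marker j by the expected dosage `2 p_j`.
#' Fractional dosages are allowed downstream. (A haplotype-based imputer
#' would exploit linkage; mean dosage keeps column means exact and is
#' sufficient for the estimation machinery here.)
#'
#' @param geno A `geno_set`.
#' @param freq Allele frequency table from [geno_allele_freq()].
#' @return A `geno_set` without missing calls (codes may be fractional).
#' @export
geno_impute <- function(geno, freq = geno_allele_freq(geno)) {
  codes <- geno$codes
  if (anyNA(codes)) {
    miss <- which(is.na(codes), arr.ind = TRUE)
    codes[miss] <- 2 * freq$p[miss[, 2]]
  }
  out <- geno
  out$codes <- codes
  out
}

#' Center genotypes to the marker-effect design matrix Z
#'
#' @param geno A `geno_set` with no missing calls (see [geno_impute()]).
#' @param freq Allele frequency table.
#' @return Numeric matrix `Z = codes - 2p`, animals x markers.
#' @export
geno_center <- function(geno, freq = geno_allele_freq(geno)) {
  codes <- geno$codes
  sb_assert(!anyNA(codes), "impute missing genotypes before centering")
  sweep(codes, 2, 2 * freq$p, "-")
}

#' Marker-effect covariance from the genetic covariance
#'
#' Splits the additive genetic (co)variance between markers and the residual
#' polygenic effect: with RPG fraction k, markers carry `(1 - k)` of the
#' genetic variance spread over the markers,
#' `Sigma_SNP = (1 - k) G0 / D` with `D = sum_j 2 p_j (1 - p_j)`.
#'
#' @param G0 t x t additive genetic covariance matrix.
#' @param k Residual polygenic fraction in \[0, 1\].
#' @param p Vector of allele frequencies (or the tibble from
#'   [geno_allele_freq()]).
#' @return An object of class `snp_cov`: list with `Sigma` (t x t), `D`,
#'   and `k`.
#' @export
snp_covariance <- function(G0, k, p) {
  if (is.data.frame(p)) p <- p$p
  G0 <- as.matrix(G0)
  sb_assert(k >= 0 && k <= 1, "k must be in [0, 1]")
  sb_assert(isSymmetric(unname(G0), tol = 1e-8), "G0 must be symmetric")
  D <- sum(2 * p * (1 - p))
  sb_assert(D > 0, "all markers monomorphic: sum 2p(1-p) is zero")
  structure(list(Sigma = (1 - k) * G0 / D, D = D, k = k), class = "snp_cov")
}

#' @export
#' @method print snp_cov
print.snp_cov <- function(x, ...) {
  cat("<snp_cov> k = ", x$k, ", D = ", format(x$D), "\n", sep = "")
  print(x$Sigma, ...)
  invisible(x)
}

#' Genotype-based parentage verification
#'
#' For every genotyped animal whose recorded sire (or dam) is also
#' genotyped, counts markers where parent and offspring are opposing
#' homozygotes (codes 0 vs 2), impossible under Mendelian inheritance
#' without genotyping error. Duos whose opposing-homozygote rate exceeds
#' `conflict_threshold` are flagged as pedigree conflicts.
#'
#' @param geno A `geno_set` (raw codes; fractional imputed dosages are not
#'   counted as homozygous).
#' @param pedigree Sorted pedigree.
#' @param conflict_threshold Conflict rate above which a duo is flagged
#'   (default 0.01 of jointly called markers).
#' @param min_markers Duos with fewer jointly called markers are skipped
#'   with a warning (default 100).
#' @return A tibble with one row per checked duo: `animal_id`, `parent_id`,
#'   `side` (sire/dam), `n_checked`, `n_opposing`, `rate`, `conflict`, plus
#'   a `rates` attribute with the per-side conflict percentages.
#' @export
verify_parentage <- function(geno, pedigree, conflict_threshold = 0.01,
                             min_markers = 100) {
  codes <- geno$codes
  ids <- geno$animal_ids
  ped <- as_tibble(pedigree)
  duos <- dplyr::bind_rows(
    tibble(animal_id = ped$animal_id, parent_id = ped$sire_id, side = "sire"),
    tibble(animal_id = ped$animal_id, parent_id = ped$dam_id, side = "dam")
  )
  duos <- duos[!is.na(duos$parent_id) &
                 duos$animal_id %in% ids & duos$parent_id %in% ids, ]
  if (nrow(duos) == 0) {
    out <- tibble(animal_id = character(0), parent_id = character(0),
                  side = character(0), n_checked = integer(0),
                  n_opposing = integer(0), rate = numeric(0),
                  conflict = logical(0))
    attr(out, "rates") <- c(sire = NA_real_, dam = NA_real_)
    return(out)
  }
  oi <- match(duos$animal_id, ids)
  pi <- match(duos$parent_id, ids)
  res <- purrr::map2(oi, pi, function(o, p) {
    a <- codes[o, ]
    b <- codes[p, ]
    ok <- !is.na(a) & !is.na(b)
    opp <- sum((a[ok] == 0 & b[ok] == 2) | (a[ok] == 2 & b[ok] == 0))
    c(n = sum(ok), opp = opp)
  })
  duos$n_checked <- purrr::map_int(res, ~ as.integer(.x[["n"]]))
  duos$n_opposing <- purrr::map_int(res, ~ as.integer(.x[["opp"]]))
  skip <- duos$n_checked < min_markers
  if (any(skip)) {
    rlang::warn(paste0(sum(skip), " duos skipped: fewer than ", min_markers,
                       " jointly called markers"))
    duos <- duos[!skip, ]
  }
  duos$rate <- ifelse(duos$n_checked > 0, duos$n_opposing / duos$n_checked, NA_real_)
  duos$conflict <- duos$rate > conflict_threshold
  rates <- vapply(c("sire", "dam"), function(s) {
    sel <- duos$side == s
    if (!any(sel)) NA_real_ else 100 * mean(duos$conflict[sel])
  }, numeric(1))
  out <- as_tibble(duos)
  attr(out, "rates") <- rates
  out
}
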