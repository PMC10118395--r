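#' Build the fixed-effect and record design for the carcass model
#'
#' Codes the classification fixed effects (herd-year, year-season on
#' slaughter, sex) and the age-at-slaughter covariate into sparse incidence
#' structures, one record row per animal. Carcass traits are recorded
#' all-or-none at slaughter, so each record carries every trait.
#'
#' The first classification effect keeps all its levels (it absorbs the
#' intercept); later effects drop their first level, the usual full-rank
#' parameterization. The covariate is centered on its mean.
#'
#' @param phenotypes Data frame with `animal_id`, the class-effect columns,
#'   the covariate column, and one column per trait.
#' @param traits Character vector of trait columns (default the four
#'   carcass traits CW, EMA, BF, MS).
#' @param class_effects Character vector of classification effect columns.
#' @param covariate Name of the linear covariate column (age at slaughter),
#'   or `NULL` for none.
#' @return An object of class `mme_design`.
#' @export
build_design <- function(phenotypes,
                         traits = CARCASS_TRAITS,
                         class_effects = c("herd_year", "year_season", "sex"),
                         covariate = "age") {
  ph <- as_tibble(phenotypes)
  need <- c("animal_id", class_effects, covariate, traits)
  missing_cols <- setdiff(need, names(ph))
  sb_assert(length(missing_cols) == 0,
            paste0("phenotypes missing columns: ", paste(missing_cols, collapse = ", ")))
  n_rec <- nrow(ph)
  sb_assert(n_rec > 0, "no phenotype records")
  Y <- as.matrix(ph[, traits, drop = FALSE])
  storage.mode(Y) <- "double"
  sb_assert(!anyNA(Y),
            "carcass traits are recorded all-or-none: missing trait values found")
  for (ce in class_effects) {
    sb_assert(!anyNA(ph[[ce]]), paste0("missing labels in class effect ", ce))
  }

  cols <- list()
  trip_i <- list()
  trip_j <- list()
  trip_x <- list()
  col_at <- 0L
  for (e in seq_along(class_effects)) {
    ce <- class_effects[e]
    lev <- sort(unique(as.character(ph[[ce]])))
    keep <- if (e == 1L) lev else lev[-1L]
    if (length(keep) == 0) next
    j <- match(as.character(ph[[ce]]), keep)
    obs <- !is.na(j)
    trip_i[[length(trip_i) + 1L]] <- which(obs)
    trip_j[[length(trip_j) + 1L]] <- col_at + j[obs]
    trip_x[[length(trip_x) + 1L]] <- rep(1, sum(obs))
    cols[[length(cols) + 1L]] <- tibble(effect = ce, level = keep,
                                        col = col_at + seq_along(keep))
    col_at <- col_at + length(keep)
  }
  center <- NULL
  if (!is.null(covariate)) {
    sb_assert(!anyNA(ph[[covariate]]), paste0("missing covariate ", covariate))
    center <- mean(ph[[covariate]])
    trip_i[[length(trip_i) + 1L]] <- seq_len(n_rec)
    trip_j[[length(trip_j) + 1L]] <- rep(col_at + 1L, n_rec)
    trip_x[[length(trip_x) + 1L]] <- ph[[covariate]] - center
    cols[[length(cols) + 1L]] <- tibble(effect = covariate, level = "(slope)",
                                        col = col_at + 1L)
    col_at <- col_at + 1L
  }
  X <- if (col_at == 0L) {
    Matrix::Matrix(0, n_rec, 0, sparse = TRUE)
  } else {
    Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                         x = unlist(trip_x), dims = c(n_rec, col_at))
  }
  fixed_levels <- if (length(cols) > 0) dplyr::bind_rows(cols) else {
    tibble(effect = character(0), level = character(0), col = integer(0))
  }
  # crossed class effects alias each other (e.g. herd-year and year-season
  # share the slaughter-year span); constrain dependent columns to zero
  qrX <- if (col_at > 0L) qr(as.matrix(X)) else NULL
  if (col_at > 0L && qrX$rank < ncol(X)) {
    drop_cols <- sort(qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))])
    inform(paste0("constraining ", length(drop_cols),
                  " aliased fixed-effect level(s) to zero: ",
                  paste(fixed_levels$level[match(drop_cols, fixed_levels$col)],
                        collapse = ", ")))
    X <- X[, -drop_cols, drop = FALSE]
    fixed_levels <- fixed_levels[!fixed_levels$col %in% drop_cols, ]
    fixed_levels$col <- seq_len(nrow(fixed_levels))
  }
  structure(list(
    X = X,
    fixed_levels = fixed_levels,
    Y = Y,
    animal_id = as.character(ph$animal_id),
    traits = traits,
    covariate_center = center
  ), class = "mme_design")
}

#' @export
#' @method print mme_design
print.mme_design <- function(x, ...) {
  cat("<mme_design> ", nrow(x$Y), " records x ", length(x$traits),
      " traits, ", ncol(x$X), " fixed-effect columns\n", sep = "")
  invisible(x)
}

# ---- internal assembly pieces -------------------------------------------

# selector carrying genotyped-block corrections onto the equations.
# Without phantom groups this is the plain scatter S (u rows of genotyped
# animals). With groups, animal solutions are group-inclusive totals
# u* = u + Q gamma, so corrections on the deviations u transform to
# Sq = S - S_grp Q', placing the matching terms on the group equations.
geno_selector <- function(u_ids, gpos, Qg, geno_ids) {
  n_u <- length(u_ids)
  S <- Matrix::sparseMatrix(i = gpos, j = seq_along(gpos), x = rep(1, length(gpos)),
                            dims = c(n_u, length(gpos)))
  if (is.null(Qg)) return(S)
  sb_assert(identical(rownames(Qg), geno_ids),
            "Qg rows must match the genotyped animals in order")
  gidx <- match(colnames(Qg), u_ids)
  sb_assert(!anyNA(gidx), "group labels of Qg missing from a_inverse")
  Sg <- Matrix::sparseMatrix(i = gidx, j = seq_along(gidx), x = rep(1, length(gidx)),
                             dims = c(n_u, length(gidx)))
  S - Sg %*% as(t(Qg), "CsparseMatrix")
}

# shared data part: C_data = kron(W'W, R0inv), rhs = vec(t(W'Y R0inv))
mme_data_part <- function(design, u_ids, R0inv) {
  nt <- ncol(R0inv)
  pos <- match(design$animal_id, u_ids)
  sb_assert(!anyNA(pos), "phenotyped animals missing from the relationship matrix")
  n_rec <- nrow(design$Y)
  U <- Matrix::sparseMatrix(i = seq_len(n_rec), j = pos, x = rep(1, n_rec),
                            dims = c(n_rec, length(u_ids)))
  W <- cbind(design$X, U)
  WtW <- Matrix::crossprod(W)
  Cd <- kronecker(WtW, R0inv)
  M <- as.matrix(Matrix::crossprod(W, design$Y %*% R0inv))
  list(C = Cd, rhs = as.vector(t(M)), n_fixed = ncol(design$X))
}

mme_new <- function(C, rhs, design, u_ids, vc, kind, meta = list()) {
  structure(list(
    C = Matrix::forceSymmetric(C),
    rhs = rhs,
    fixed_levels = design$fixed_levels,
    u_ids = u_ids,
    traits = design$traits,
    vc = vc,
    kind = kind,
    meta = meta
  ), class = "mme_system")
}

#' @export
#' @method print mme_system
print.mme_system <- function(x, ...) {
  cat("<mme_system> ", x$kind, ": ", nrow(x$C), " equations (",
      length(x$traits), " traits x ", nrow(x$C) / length(x$traits),
      " levels)\n", sep = "")
  invisible(x)
}

check_vc <- function(vc, nt) {
  sb_assert(is.list(vc) && all(c("G0", "R0") %in% names(vc)),
            "variance components must be a list with G0 and R0")
  sb_assert(nrow(as.matrix(vc$G0)) == nt && nrow(as.matrix(vc$R0)) == nt,
            "G0/R0 dimension does not match the number of traits")
  sb_assert(is_spd(vc$G0), "G0 must be symmetric positive definite")
  sb_assert(is_spd(vc$R0), "R0 must be symmetric positive definite")
}

#' Assemble conventional multi-trait animal-model equations
#'
#' Standard multi-trait mixed-model equations: data part with per-record
#' residual precision `solve(R0)` plus the pedigree prior
#' `A-inverse (x) solve(G0)` on breeding values. Equations are grouped
#' level-major (the traits of one effect level are adjacent).
#'
#' @param design An `mme_design` from [build_design()].
#' @param a_inverse Sparse A-inverse over all animals (+ phantom groups)
#'   from [ped_a_inverse()].
#' @param vc List with `G0` (genetic) and `R0` (residual) t x t covariance
#'   matrices.
#' @return An `mme_system`.
#' @export
assemble_conventional <- function(design, a_inverse, vc) {
  nt <- length(design$traits)
  check_vc(vc, nt)
  R0inv <- solve(as.matrix(vc$R0))
  G0inv <- solve(as.matrix(vc$G0))
  u_ids <- rownames(a_inverse)
  dat <- mme_data_part(design, u_ids, R0inv)
  nf <- dat$n_fixed
  Pu <- kronecker(a_inverse, G0inv)
  prior <- Matrix::bdiag(Matrix::Matrix(0, nf * nt, nf * nt, sparse = TRUE), Pu)
  mme_new(dat$C + prior, dat$rhs, design, u_ids, vc, "conventional")
}

#' Assemble single-step SNP BLUP equations
#'
#' Joint equations for fixed effects, breeding values of all animals, and
#' SNP marker effects, with a residual polygenic effect carrying fraction
#' `k` of the genetic variance. The genotyped animals' breeding values are
#' their GEBV; marker effects are estimated directly. Prior precision
#' blocks (scaled by the trait covariance inverses):
#' `u,u`: A-inverse plus `(1/k - 1) A22-inverse` on the genotyped block;
#' `u_g,g`: `-A22-inverse Z / k`;
#' `g,g`: `Z' A22-inverse Z / k` plus the marker-variance identity.
#'
#' @inheritParams assemble_conventional
#' @param a22 Dense pedigree relationship matrix among genotyped animals
#'   from [ped_a22()] (its inverse is taken here).
#' @param Z Centered genotype matrix (genotyped animals x markers) from
#'   [geno_center()]; rownames identify the animals.
#' @param snp_cov Marker covariance from [snp_covariance()].
#' @param Qg Phantom-group gene fractions of the genotyped animals (rows of
#'   [ped_group_fractions()]); required when `a_inverse` carries group
#'   equations, so that the genotyped-block corrections act on breeding-value
#'   deviations rather than on the group-inclusive totals.
#' @return An `mme_system` with marker equations appended.
#' @export
assemble_ssnpblup <- function(design, a_inverse, a22, Z, vc, snp_cov,
                              Qg = NULL) {
  nt <- length(design$traits)
  check_vc(vc, nt)
  k <- snp_cov$k
  sb_assert(k > 0,
            "k = 0 leaves the residual polygenic precision undefined; use the ssGBLUP form")
  if (k == 1) {
    # markers carry no variance: model collapses to conventional BLUP
    out <- assemble_conventional(design, a_inverse, vc)
    out$kind <- "ssnpblup"
    out$meta <- list(k = 1, g_dropped = TRUE, geno_ids = rownames(Z),
                     marker_ids = colnames(Z))
    return(out)
  }
  R0inv <- solve(as.matrix(vc$R0))
  G0inv <- solve(as.matrix(vc$G0))
  u_ids <- rownames(a_inverse)
  geno_ids <- rownames(Z)
  sb_assert(!is.null(geno_ids), "Z needs animal ids as rownames")
  sb_assert(identical(rownames(a22), geno_ids), "a22 and Z must index the same animals")
  gpos <- match(geno_ids, u_ids)
  sb_assert(!anyNA(gpos), "genotyped animals missing from a_inverse")

  dat <- mme_data_part(design, u_ids, R0inv)
  nf <- dat$n_fixed
  n_u <- length(u_ids)
  m <- ncol(Z)
  A22inv <- solve(a22)
  Sq <- geno_selector(u_ids, gpos, Qg, geno_ids)
  Puu <- kronecker(a_inverse, G0inv) +
    kronecker(Sq %*% A22inv %*% Matrix::t(Sq), (1 / k - 1) * G0inv)
  Mug <- as(as(Sq %*% (A22inv %*% Z), "CsparseMatrix"), "generalMatrix")
  Pug <- kronecker(Mug, -G0inv / k)
  Pgg <- kronecker(crossprod(Z, A22inv %*% Z) / k, G0inv) +
    kronecker(Matrix::Diagonal(m), solve(snp_cov$Sigma))
  Zf <- Matrix::Matrix(0, nf * nt, nf * nt, sparse = TRUE)
  Zfu <- Matrix::Matrix(0, nf * nt, n_u * nt, sparse = TRUE)
  Zfg <- Matrix::Matrix(0, nf * nt, m * nt, sparse = TRUE)
  prior <- rbind(
    cbind(Zf, Zfu, Zfg),
    cbind(Matrix::t(Zfu), Puu, Pug),
    cbind(Matrix::t(Zfg), Matrix::t(Pug), Pgg)
  )
  Cd <- Matrix::bdiag(dat$C, Matrix::Matrix(0, m * nt, m * nt, sparse = TRUE))
  mme_new(Cd + prior, c(dat$rhs, numeric(m * nt)), design, u_ids, vc, "ssnpblup",
          meta = list(k = k, snp_cov = snp_cov, geno_ids = geno_ids,
                      marker_ids = colnames(Z), Z = Z, Qg = Qg))
}

#' Assemble single-step GBLUP equations (H-inverse form)
#'
#' The breeding-value parameterization equivalent to [assemble_ssnpblup()]:
#' `H-inverse = A-inverse + [[0, 0], [0, Gw-inverse - A22-inverse]]` on the
#' genotyped block, with the genomic relationship matrix `G = Z Z' / D` and
#' the polygenic-blended `Gw = (1 - k) G + k A22`. Marker effects can be
#' backsolved exactly from the GEBV of the genotyped animals.
#'
#' @inheritParams assemble_ssnpblup
#' @return An `mme_system`; its `meta$backsolve` matrix maps genotyped-animal
#'   GEBV (deviations, with any group contribution removed) to marker effects.
#' @export
assemble_ssgblup <- function(design, a_inverse, a22, Z, vc, snp_cov,
                             Qg = NULL) {
  nt <- length(design$traits)
  check_vc(vc, nt)
  k <- snp_cov$k
  R0inv <- solve(as.matrix(vc$R0))
  G0inv <- solve(as.matrix(vc$G0))
  u_ids <- rownames(a_inverse)
  geno_ids <- rownames(Z)
  sb_assert(identical(rownames(a22), geno_ids), "a22 and Z must index the same animals")
  gpos <- match(geno_ids, u_ids)
  sb_assert(!anyNA(gpos), "genotyped animals missing from a_inverse")

  dat <- mme_data_part(design, u_ids, R0inv)
  nf <- dat$n_fixed
  n_u <- length(u_ids)
  D <- snp_cov$D
  G <- Matrix::tcrossprod(Z) / D
  Gw <- (1 - k) * as.matrix(G) + k * a22
  Gwinv <- tryCatch(solve(Gw), error = function(e) {
    sb_abort(paste0("blended genomic relationship matrix Gw is singular; ",
                    "clamp allele frequencies or increase k (", conditionMessage(e), ")"))
  })
  A22inv <- solve(a22)
  Sq <- geno_selector(u_ids, gpos, Qg, geno_ids)
  Puu <- kronecker(a_inverse, G0inv) +
    kronecker(Sq %*% (Gwinv - A22inv) %*% Matrix::t(Sq), G0inv)
  prior <- Matrix::bdiag(Matrix::Matrix(0, nf * nt, nf * nt, sparse = TRUE), Puu)
  # exact marker-effect backsolve: g = ((1-k)/D) Z' Gw^-1 u_g (per trait)
  backsolve_mat <- if (k < 1) ((1 - k) / D) * crossprod(Z, Gwinv) else NULL
  mme_new(dat$C + prior, dat$rhs, design, u_ids, vc, "ssgblup",
          meta = list(k = k, snp_cov = snp_cov, geno_ids = geno_ids,
                      marker_ids = colnames(Z), Z = Z,
                      backsolve = backsolve_mat, Qg = Qg))
}

# ---- solvers -------------------------------------------------------------

# split a solution vector into an ss_fit result object
as_ss_fit <- function(mme, x, convergence) {
  nt <- length(mme$traits)
  nf <- max(c(0L, mme$fixed_levels$col))
  n_u <- length(mme$u_ids)
  fixed <- NULL
  if (nf > 0) {
    xf <- matrix(x[seq_len(nf * nt)], nrow = nt)
    fl <- mme$fixed_levels
    fixed <- tibble(
      effect = rep(fl$effect, each = nt),
      level = rep(fl$level, each = nt),
      trait = rep(mme$traits, nrow(fl)),
      estimate = as.vector(xf[, fl$col, drop = FALSE])
    )
  }
  xu <- matrix(x[nf * nt + seq_len(n_u * nt)], nrow = nt)
  u_tbl <- tibble(
    animal_id = rep(mme$u_ids, each = nt),
    trait = rep(mme$traits, n_u),
    u = as.vector(xu)
  )
  g_tbl <- NULL
  a_tbl <- NULL
  if (mme$kind == "ssnpblup" && is.null(mme$meta$g_dropped)) {
    m <- length(mme$meta$marker_ids)
    xg <- matrix(x[(nf + n_u) * nt + seq_len(m * nt)], nrow = nt)
    g_tbl <- tibble(
      marker_id = rep(mme$meta$marker_ids, each = nt),
      trait = rep(mme$traits, m),
      g = as.vector(xg)
    )
  }
  # genotyped animals' breeding-value deviations: with phantom groups the
  # animal solutions are group-inclusive totals u* = u + Q gamma
  geno_dev <- function() {
    Ug <- t(xu)[match(mme$meta$geno_ids, mme$u_ids), , drop = FALSE]
    if (!is.null(mme$meta$Qg)) {
      gam <- t(xu)[match(colnames(mme$meta$Qg), mme$u_ids), , drop = FALSE]
      Ug <- Ug - mme$meta$Qg %*% gam
    }
    Ug
  }
  if (mme$kind == "ssgblup" && !is.null(mme$meta$backsolve)) {
    gmat <- as.matrix(mme$meta$backsolve %*% geno_dev())
    g_tbl <- tibble(
      marker_id = rep(mme$meta$marker_ids, each = nt),
      trait = rep(mme$traits, length(mme$meta$marker_ids)),
      g = as.vector(t(gmat))
    )
  }
  if (!is.null(g_tbl) && !is.null(mme$meta$Z)) {
    geno_ids <- mme$meta$geno_ids
    gmat <- matrix(g_tbl$g, nrow = length(mme$meta$marker_ids), byrow = TRUE)
    amat <- geno_dev() - mme$meta$Z %*% gmat
    a_tbl <- tibble(
      animal_id = rep(geno_ids, each = nt),
      trait = rep(mme$traits, length(geno_ids)),
      a = as.vector(t(amat))
    )
  }
  structure(list(
    fixed = fixed,
    u_hat = u_tbl,
    g_hat = g_tbl,
    a_hat = a_tbl,
    traits = mme$traits,
    kind = mme$kind,
    vc = mme$vc,
    meta = mme$meta,
    convergence = convergence,
    solution = x
  ), class = "ss_fit")
}

#' Solve mixed-model equations by direct factorization
#'
#' Sparse Cholesky (falling back to LU) solution of the assembled system;
#' intended for desk-scale systems and as the oracle for the iterative
#' solver.
#'
#' @param mme An `mme_system`.
#' @param max_dim Guard against accidentally factorizing huge systems.
#' @return An `ss_fit` with solutions split by effect kind.
#' @export
solve_direct <- function(mme, max_dim = 20000) {
  N <- nrow(mme$C)
  sb_assert(N <= max_dim,
            paste0("system dimension ", N, " exceeds max_dim; use solve_pcg()"))
  x <- tryCatch(
    as.vector(Matrix::solve(mme$C, mme$rhs)),
    error = function(e) {
      as.vector(Matrix::solve(as(mme$C, "generalMatrix"), mme$rhs))
    }
  )
  relres <- sqrt(sum(as.vector(mme$C %*% x - mme$rhs)^2)) /
    max(sqrt(sum(mme$rhs^2)), .Machine$double.eps)
  as_ss_fit(mme, x, list(method = "direct", iterations = 1L,
                         converged = TRUE, relres = relres))
}

#' Solve mixed-model equations by preconditioned conjugate gradients
#'
#' Conjugate gradients with a block-Jacobi preconditioner built from the
#' t x t trait blocks on the diagonal (one block per effect level), the
#' natural preconditioner for the level-major equation ordering.
#' Convergence is declared when the relative residual norm
#' `||C x - rhs|| / ||rhs||` drops below `tol`.
#'
#' @param mme An `mme_system`.
#' @param tol Relative residual tolerance (default 1e-10).
#' @param max_iter Iteration cap; the result carries a non-converged flag
#'   if reached.
#' @return An `ss_fit`.
#' @export
solve_pcg <- function(mme, tol = 1e-10, max_iter = 5000) {
  C <- mme$C
  rhs <- mme$rhs
  N <- length(rhs)
  nt <- length(mme$traits)
  n_lev <- N %/% nt
  # block-Jacobi preconditioner: invert each t x t diagonal block
  Cg <- as(C, "generalMatrix")
  off <- rep((seq_len(n_lev) - 1L) * nt, each = nt * nt)
  ri <- off + rep(rep(seq_len(nt), times = nt), n_lev)
  ci <- off + rep(rep(seq_len(nt), each = nt), n_lev)
  vals <- Cg[cbind(ri, ci)]
  barr <- array(vals, dim = c(nt, nt, n_lev))
  blocks <- vector("list", n_lev)
  for (l in seq_len(n_lev)) {
    B <- barr[, , l]
    blocks[[l]] <- tryCatch(solve(B), error = function(e) {
      diag(1 / pmax(diag(B), .Machine$double.eps), nt)
    })
  }
  Minv <- Matrix::bdiag(blocks)
  rhs_norm <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  x <- numeric(N)
  r <- rhs
  z <- as.vector(Minv %*% r)
  p <- z
  rz <- sum(r * z)
  iter <- 0L
  relres <- sqrt(sum(r^2)) / rhs_norm
  while (relres >= tol && iter < max_iter) {
    iter <- iter + 1L
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    relres <- sqrt(sum(r^2)) / rhs_norm
    if (relres < tol) break
    z <- as.vector(Minv %*% r)
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  as_ss_fit(mme, x, list(method = "pcg", iterations = iter,
                         converged = relres < tol, relres = relres))
}

#' Prediction error variance of breeding values
#'
#' Diagonal of the inverse coefficient matrix at the breeding-value
#' equations, a model-based reliability proxy. Dense inversion; only for
#' small systems.
#'
#' @param mme An `mme_system` of dimension at most `max_dim`.
#' @param max_dim Dimension guard (default 3000).
#' @return Tibble with `animal_id`, `trait`, `pev`.
#' @export
reliability_pev <- function(mme, max_dim = 3000) {
  N <- nrow(mme$C)
  sb_assert(N <= max_dim, "system too large for dense PEV computation")
  Cinv <- solve(as.matrix(mme$C))
  nt <- length(mme$traits)
  nf <- max(c(0L, mme$fixed_levels$col))
  n_u <- length(mme$u_ids)
  dvals <- diag(Cinv)[nf * nt + seq_len(n_u * nt)]
  tibble(animal_id = rep(mme$u_ids, each = nt),
         trait = rep(mme$traits, n_u),
         pev = dvals)
}

#' @export
#' @method print ss_fit
print.ss_fit <- function(x, ...) {
  cat("<ss_fit> ", x$kind, ", ", length(unique(x$u_hat$animal_id)),
      " animals x ", length(x$traits), " traits",
      if (!is.null(x$g_hat)) paste0(", ", length(unique(x$g_hat$marker_id)), " markers"),
      "\n  solver: ", x$convergence$method, ", ", x$convergence$iterations,
      " iterations, relative residual ", format(x$convergence$relres, digits = 3),
      "\n", sep = "")
  invisible(x)
}
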