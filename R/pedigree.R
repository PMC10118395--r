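#' Sort and validate a pedigree
#'
#' Orders pedigree records so that every parent precedes its offspring
#' (topological order), validates identifiers, and rejects impossible
#' pedigrees (cycles, animals used as both sire and dam).
#'
#' @param pedigree A data frame with at least `animal_id`, `sire_id`,
#'   `dam_id`. Missing parents are `NA` (or `""`). Optional columns
#'   (`birth_year`, `sex`, `path`, `type`, ...) are carried through.
#' @return A tibble with the same columns, rows in topological order.
#' @examples
#' ped <- tibble::tibble(
#'   animal_id = c("c", "a", "b"),
#'   sire_id   = c("a", NA, NA),
#'   dam_id    = c("b", NA, NA)
#' )
#' ped_sort(ped)
#' @export
ped_sort <- function(pedigree) {
  ped <- as_tibble(pedigree)
  sb_assert(all(c("animal_id", "sire_id", "dam_id") %in% names(ped)),
            "pedigree needs columns animal_id, sire_id, dam_id")
  ids <- as.character(ped$animal_id)
  sb_assert(!anyNA(ids) && !any(ids == ""), "animal_id must be non-missing")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    sb_abort(paste0("duplicate animal_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  sire <- as.character(ped$sire_id)
  dam <- as.character(ped$dam_id)
  sire[!is.na(sire) & sire == ""] <- NA
  dam[!is.na(dam) & dam == ""] <- NA

  unknown <- setdiff(c(sire[!is.na(sire)], dam[!is.na(dam)]), ids)
  if (length(unknown) > 0) {
    sb_abort(paste0("parent ids not in pedigree: ",
                    paste(head(unknown, 5), collapse = ", ")))
  }
  both <- intersect(unique(sire[!is.na(sire)]), unique(dam[!is.na(dam)]))
  if (length(both) > 0) {
    sb_abort(paste0("animal used as both sire and dam: ", both[1]))
  }
  if ("sex" %in% names(ped)) {
    sex <- as.character(ped$sex)
    bad_sire <- intersect(unique(sire[!is.na(sire)]), ids[sex %in% "female"])
    bad_dam <- intersect(unique(dam[!is.na(dam)]), ids[sex %in% "male"])
    if (length(bad_sire) > 0) sb_abort(paste0("female animal used as sire: ", bad_sire[1]))
    if (length(bad_dam) > 0) sb_abort(paste0("male animal used as dam: ", bad_dam[1]))
  }

  n <- length(ids)
  si <- match(sire, ids, nomatch = 0L)
  di <- match(dam, ids, nomatch = 0L)

  # Kahn's algorithm, stable in input order
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (si[i] > 0L) children[[si[i]]] <- c(children[[si[i]]], i)
    if (di[i] > 0L) children[[di[i]]] <- c(children[[di[i]]], i)
  }
  order_out <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail) > 0) {
    i <- avail[1]
    avail <- avail[-1]
    order_out <- c(order_out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) avail <- c(avail, ch)
    }
  }
  if (length(order_out) < n) {
    on_cycle <- ids[which(indeg > 0L)[1]]
    sb_abort(paste0("pedigree cycle detected involving animal: ", on_cycle),
             class = "stepblup_cycle")
  }
  ped$sire_id <- sire
  ped$dam_id <- dam
  ped$animal_id <- ids
  ped[order_out, ]
}

# integer parent indices relative to the (sorted) pedigree; 0 = unknown
ped_index <- function(ped) {
  ids <- ped$animal_id
  list(
    sire = match(ped$sire_id, ids, nomatch = 0L),
    dam = match(ped$dam_id, ids, nomatch = 0L)
  )
}

# error unless every parent precedes its offspring
check_sorted <- function(ped) {
  idx <- ped_index(ped)
  n <- nrow(ped)
  ok <- all(idx$sire < seq_len(n)) && all(idx$dam < seq_len(n))
  sb_assert(ok, "pedigree is not sorted parents-first; call ped_sort() first")
  idx
}

#' Inbreeding coefficients by the Meuwissen-Luo recursion
#'
#' Computes per-animal inbreeding coefficients F from a sorted pedigree by
#' tracing each animal's ancestor contributions (the L-row of the
#' A = LDL' decursion) and accumulating squared path coefficients times the
#' Mendelian sampling variances.
#'
#' @param pedigree A sorted pedigree (see [ped_sort()]).
#' @return A tibble with `animal_id` and `F`.
#' @export
ped_inbreeding <- function(pedigree) {
  idx <- check_sorted(pedigree)
  n <- nrow(pedigree)
  si <- idx$sire
  di <- idx$dam
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    # Mendelian sampling variance given parents (unknown parent = founder-like)
    D[i] <- if (si[i] > 0L && di[i] > 0L) {
      0.5 - 0.25 * (F[si[i]] + F[di[i]])
    } else if (si[i] > 0L) {
      0.75 - 0.25 * F[si[i]]
    } else if (di[i] > 0L) {
      0.75 - 0.25 * F[di[i]]
    } else 1
    if (si[i] == 0L && di[i] == 0L) {
      F[i] <- 0
      next
    }
    # trace row i of L backwards: A[i,i] = sum_j L[i,j]^2 D[j]
    v <- numeric(i)
    v[i] <- 1
    aii <- 0
    for (j in rev(seq_len(i))) {
      if (v[j] == 0) next
      aii <- aii + v[j]^2 * D[j]
      if (si[j] > 0L) v[si[j]] <- v[si[j]] + 0.5 * v[j]
      if (di[j] > 0L) v[di[j]] <- v[di[j]] + 0.5 * v[j]
    }
    F[i] <- aii - 1
  }
  tibble(animal_id = pedigree$animal_id, F = F)
}

#' Assign phantom parent groups
#'
#' Maps every missing parent slot to an unknown-parent (phantom) group
#' defined by the animal's selection path and a birth-year bin, the usual
#' grouping for beef-cattle evaluations. Only (path, bin) combinations that
#' actually occur among missing slots become groups.
#'
#' @param pedigree Sorted pedigree with `path` and `birth_year` columns.
#' @param year_bins Increasing numeric breakpoints; bin k is the half-open
#'   interval `[year_bins[k], year_bins[k + 1])`. Years outside all bins are
#'   assigned to the nearest boundary bin with a warning.
#' @param paths Optional character vector of selection paths (defaults to
#'   those present in the pedigree).
#' @return An object of class `phantom_groups`: a list with `groups`
#'   (group_id, label, path, year bin) and `assignments` (animal_id, slot,
#'   group_id), one row per missing parent slot.
#' @export
ped_phantom_groups <- function(pedigree, year_bins, paths = NULL) {
  ped <- as_tibble(pedigree)
  sb_assert(all(c("path", "birth_year") %in% names(ped)),
            "phantom groups need `path` and `birth_year` columns")
  sb_assert(length(year_bins) >= 2 && !is.unsorted(year_bins, strictly = TRUE),
            "year_bins must be increasing breakpoints")
  paths <- paths %||% sort(unique(as.character(ped$path)))
  sb_assert(all(ped$path %in% paths), "pedigree contains paths not in `paths`")

  miss_sire <- is.na(ped$sire_id)
  miss_dam <- is.na(ped$dam_id)
  asn <- dplyr::bind_rows(
    tibble(animal_id = ped$animal_id[miss_sire], slot = "sire",
           path = as.character(ped$path[miss_sire]),
           birth_year = ped$birth_year[miss_sire]),
    tibble(animal_id = ped$animal_id[miss_dam], slot = "dam",
           path = as.character(ped$path[miss_dam]),
           birth_year = ped$birth_year[miss_dam])
  )
  n_bins <- length(year_bins) - 1L
  if (nrow(asn) == 0) {
    groups <- tibble(group_id = integer(0), label = character(0),
                     path = character(0), year_min = numeric(0),
                     year_max = numeric(0))
    out <- list(groups = groups, assignments = tibble(
      animal_id = character(0), slot = character(0), group_id = integer(0)))
    class(out) <- "phantom_groups"
    return(out)
  }
  bin <- findInterval(asn$birth_year, year_bins, rightmost.closed = FALSE)
  out_of_range <- bin < 1L | bin > n_bins
  if (any(out_of_range)) {
    rlang::warn(paste0(sum(out_of_range),
                       " birth years outside year_bins assigned to boundary bins"))
    bin <- pmin(pmax(bin, 1L), n_bins)
  }
  key <- paste(asn$path, bin, sep = "\r")
  combos <- sort(unique(key))
  gid <- match(key, combos)
  combo_path <- sub("\r.*$", "", combos)
  combo_bin <- as.integer(sub("^.*\r", "", combos))
  groups <- tibble(
    group_id = seq_along(combos),
    label = paste0("G", seq_along(combos)),
    path = combo_path,
    year_min = year_bins[combo_bin],
    year_max = year_bins[combo_bin + 1L]
  )
  out <- list(groups = groups,
              assignments = tibble(animal_id = asn$animal_id, slot = asn$slot,
                                   group_id = gid))
  class(out) <- "phantom_groups"
  out
}

#' @export
#' @method print phantom_groups
print.phantom_groups <- function(x, ...) {
  cat("<phantom_groups> ", nrow(x$groups), " groups covering ",
      nrow(x$assignments), " missing parent slots\n", sep = "")
  print(x$groups, ...)
  invisible(x)
}

#' Inverse of the numerator relationship matrix
#'
#' Builds the sparse inverse of the pedigree relationship matrix A by
#' Henderson's rules with inbreeding, extended with Westell/Quaas unknown-
#' parent-group contributions when `groups` is supplied.
#'
#' The Westell/Quaas grouped matrix is singular by construction (one null
#' direction per group), and group contrasts that the data cannot separate
#' (e.g. selection-path groups acting on the same founder cohort) would
#' otherwise drift freely in the solutions. Group diagonals therefore
#' receive a ridge of `group_ridge` times the mean animal diagonal,
#' equivalent to treating the group pseudo-effects as random with a vague
#' variance (`group_ridge = 0.01` corresponds to about 100 genetic
#' variances per group): unidentifiable contrasts are pinned at zero while
#' estimable group means are essentially unshrunk.
#'
#' @param pedigree Sorted pedigree.
#' @param groups Optional `phantom_groups` object from [ped_phantom_groups()].
#' @param use_inbreeding If `TRUE` (default) inbreeding enters the Mendelian
#'   sampling coefficients; set `FALSE` for the classical F = 0 rules.
#' @param inbreeding Optional precomputed result of [ped_inbreeding()].
#' @param group_ridge Ridge on group diagonals as a fraction of the mean
#'   animal diagonal.
#' @return A sparse symmetric matrix of dimension n_animals + n_groups, with
#'   dimnames giving animal ids then group labels.
#' @export
ped_a_inverse <- function(pedigree, groups = NULL, use_inbreeding = TRUE,
                          inbreeding = NULL, group_ridge = 0.01) {
  idx <- check_sorted(pedigree)
  n <- nrow(pedigree)
  si <- idx$sire
  di <- idx$dam
  F <- if (use_inbreeding) {
    (inbreeding %||% ped_inbreeding(pedigree))$F
  } else numeric(n)

  n_grp <- 0L
  if (!is.null(groups)) {
    sb_assert(inherits(groups, "phantom_groups"), "groups must be a phantom_groups object")
    n_grp <- nrow(groups$groups)
    # replace unknown parent slots by group equation indices (n + group_id)
    a <- groups$assignments
    srow <- match(a$animal_id[a$slot == "sire"], pedigree$animal_id)
    drow <- match(a$animal_id[a$slot == "dam"], pedigree$animal_id)
    sb_assert(!anyNA(c(srow, drow)), "group assignments refer to unknown animals")
    p1 <- si
    p2 <- di
    p1[srow] <- n + a$group_id[a$slot == "sire"]
    p2[drow] <- n + a$group_id[a$slot == "dam"]
  } else {
    p1 <- si
    p2 <- di
  }

  # Mendelian sampling precision b_i; group/unknown parents count as unknown
  Fs <- ifelse(si > 0L, F[pmax(si, 1L)], 0)
  Fd <- ifelse(di > 0L, F[pmax(di, 1L)], 0)
  n_known <- (si > 0L) + (di > 0L)
  b <- ifelse(n_known == 2L, 1 / (0.5 - 0.25 * (Fs + Fd)),
       ifelse(si > 0L, 1 / (0.75 - 0.25 * Fs),
       ifelse(di > 0L, 1 / (0.75 - 0.25 * Fd), 1)))

  i_all <- seq_len(n)
  has1 <- p1 > 0L
  has2 <- p2 > 0L
  both <- has1 & has2
  ti <- c(i_all, i_all[has1], i_all[has2], p1[has1], p2[has2], pmin(p1[both], p2[both]))
  tj <- c(i_all, p1[has1], p2[has2], p1[has1], p2[has2], pmax(p1[both], p2[both]))
  # when both slots hit the same equation (founders sharing one phantom
  # group) the two off-diagonal b/4 cells of the outer product fall on the
  # diagonal and must both count
  tx <- c(b, -b[has1] / 2, -b[has2] / 2, b[has1] / 4, b[has2] / 4,
          ifelse(p1[both] == p2[both], b[both] / 2, b[both] / 4))
  # store one triangle; duplicates are summed by sparseMatrix
  ii <- pmin(ti, tj)
  jj <- pmax(ti, tj)
  dim_tot <- n + n_grp
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = tx, dims = c(dim_tot, dim_tot),
                               symmetric = TRUE)
  labels <- c(pedigree$animal_id, if (n_grp > 0) groups$groups$label)
  dimnames(Ainv) <- list(labels, labels)
  if (n_grp > 0) {
    ridge <- group_ridge * mean(Matrix::diag(Ainv)[seq_len(n)])
    Matrix::diag(Ainv)[n + seq_len(n_grp)] <-
      Matrix::diag(Ainv)[n + seq_len(n_grp)] + ridge
  }
  Ainv
}

#' Phantom-group gene fractions per animal
#'
#' Computes the matrix Q whose row i gives the expected fraction of animal
#' i's genes tracing to each phantom parent group (a missing parent slot
#' contributes 1/2 to its group; known parents pass half their own
#' fractions on). Needed to carry genotyped-block corrections into the
#' group equations of the grouped (Quaas-Pollak) parameterization.
#'
#' @param pedigree Sorted pedigree.
#' @param groups A `phantom_groups` object.
#' @return Dense matrix (animals x groups) with animal ids and group
#'   labels as dimnames.
#' @export
ped_group_fractions <- function(pedigree, groups) {
  idx <- check_sorted(pedigree)
  n <- nrow(pedigree)
  ng <- nrow(groups$groups)
  asn <- groups$assignments
  g_of <- setNames(asn$group_id, paste(asn$animal_id, asn$slot))
  Q <- matrix(0, n, ng)
  for (i in seq_len(n)) {
    q <- numeric(ng)
    if (idx$sire[i] > 0L) {
      q <- q + Q[idx$sire[i], ] / 2
    } else {
      q[g_of[[paste(pedigree$animal_id[i], "sire")]]] <- 0.5
    }
    if (idx$dam[i] > 0L) {
      q <- q + Q[idx$dam[i], ] / 2
    } else {
      g <- g_of[[paste(pedigree$animal_id[i], "dam")]]
      q[g] <- q[g] + 0.5
    }
    Q[i, ] <- q
  }
  dimnames(Q) <- list(pedigree$animal_id, groups$groups$label)
  Q
}

#' Pedigree relationships among genotyped animals (A22)
#'
#' Computes the dense additive relationship matrix restricted to a set of
#' genotyped animals, using the tabular method on the sub-pedigree of those
#' animals and all their ancestors. Diagonals equal 1 + F.
#'
#' @param pedigree Sorted pedigree.
#' @param genotyped_ids Character vector of genotyped animal ids.
#' @return Dense symmetric matrix with `genotyped_ids` dimnames, in the
#'   order given.
#' @export
ped_a22 <- function(pedigree, genotyped_ids) {
  check_sorted(pedigree)
  genotyped_ids <- as.character(genotyped_ids)
  missing_ids <- setdiff(genotyped_ids, pedigree$animal_id)
  if (length(missing_ids) > 0) {
    sb_abort(paste0("genotyped ids not in pedigree: ",
                    paste(head(missing_ids, 5), collapse = ", ")))
  }
  idx <- ped_index(pedigree)
  n <- nrow(pedigree)
  need <- pedigree$animal_id %in% genotyped_ids
  for (i in rev(seq_len(n))) {
    if (need[i]) {
      if (idx$sire[i] > 0L) need[idx$sire[i]] <- TRUE
      if (idx$dam[i] > 0L) need[idx$dam[i]] <- TRUE
    }
  }
  sub <- pedigree[need, ]
  A <- tabular_a(sub)
  pos <- match(genotyped_ids, sub$animal_id)
  A22 <- A[pos, pos, drop = FALSE]
  dimnames(A22) <- list(genotyped_ids, genotyped_ids)
  A22
}

# dense additive relationship matrix by the tabular method (sorted pedigree)
tabular_a <- function(ped) {
  idx <- ped_index(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx$sire[i]
    d <- idx$dam[i]
    A[i, i] <- if (s > 0L && d > 0L) 1 + 0.5 * A[s, d] else 1
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s > 0L) v <- v + 0.5 * A[prev, s]
      if (d > 0L) v <- v + 0.5 * A[prev, d]
      A[prev, i] <- v
      A[i, prev] <- v
    }
  }
  dimnames(A) <- list(ped$animal_id, ped$animal_id)
  A
}
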