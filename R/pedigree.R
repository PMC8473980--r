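#' Construct a pedigree object
#'
#' A pedigree is a data frame of individual records with columns `id`,
#' `sire`, `dam`, `race` and `program`, ordered so that parents precede
#' their offspring.  Unknown parents are coded `NA`.  Race labels are
#' carried on founders (individuals with both parents unknown) and are
#' propagated to descendants through the group-fraction machinery (see
#' [group_fraction_matrix()]), not stored per descendant.
#'
#' @param id character vector of unique individual identifiers.
#' @param sire,dam character vectors of parent identifiers (`NA` =
#'   unknown).  Every named parent must itself appear in `id`.
#' @param race character vector of race/landrace labels (usually `NA` for
#'   non-founders).
#' @param program character vector (or scalar) labelling the breeding
#'   program each record belongs to.
#' @param sort logical; topologically sort the records (default `TRUE`).
#' @return A `pedigree` object: a data frame with attribute `sorted`.
#' @seealso [read_pedigree()], [topo_sort_validate()]
#' @export
pedigree <- function(id, sire = NA_character_, dam = NA_character_,
                     race = NA_character_, program = "P1", sort = TRUE) {
  id <- as.character(id)
  n <- length(id)
  ped <- data.frame(
    id = id,
    sire = rep_len(as.character(sire), n),
    dam = rep_len(as.character(dam), n),
    race = rep_len(as.character(race), n),
    program = rep_len(as.character(program), n),
    stringsAsFactors = FALSE
  )
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup))
    stop("duplicate pedigree id(s): ", paste(unique(dup), collapse = ", "))
  missing_par <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ped$id)
  if (length(missing_par)) {
    warning("parent(s) referenced but never defined; inserted as founders ",
            "with race 'UNKNOWN_RACE': ", paste(missing_par, collapse = ", "))
    ped <- rbind(data.frame(id = missing_par, sire = NA_character_,
                            dam = NA_character_, race = "UNKNOWN_RACE",
                            program = ped$program[1L],
                            stringsAsFactors = FALSE), ped)
  }
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "sorted") <- FALSE
  if (sort) ped <- topo_sort_validate(ped) else ped
}

#' Read a pedigree file
#'
#' Reads a CSV with header `id,sire,dam,race` (a `program` column, if
#' present, is ignored in favour of the `program` argument).  Unknown
#' parents may be coded `0`, empty, or `NA`.  All identifiers are
#' namespaced as `"<program>:<id>"` so pedigrees from different programs
#' can be merged without raw-id collisions.
#'
#' @param path path to the CSV file.
#' @param program program label used as the id namespace prefix.
#' @param races optional character vector restricting the admissible race
#'   vocabulary; an undeclared race label is an error.
#' @return A sorted [pedigree()] object.
#' @export
read_pedigree <- function(path, program, races = NULL) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(raw)))
    stop("pedigree file must have columns id,sire,dam (and optionally race)")
  if (!"race" %in% names(raw)) raw$race <- NA_character_
  norm_unknown <- function(x) {
    x <- trimws(x)
    x[x %in% c("", "0", "NA", "na", ".")] <- NA_character_
    x
  }
  raw$sire <- norm_unknown(raw$sire)
  raw$dam <- norm_unknown(raw$dam)
  raw$race <- norm_unknown(raw$race)
  if (!is.null(races)) {
    bad <- setdiff(stats::na.omit(unique(raw$race)), races)
    if (length(bad))
      stop("race label(s) not in declared vocabulary: ",
           paste(bad, collapse = ", "))
  }
  ns <- function(x) ifelse(is.na(x), NA_character_, paste0(program, ":", x))
  pedigree(id = ns(raw$id), sire = ns(raw$sire), dam = ns(raw$dam),
           race = raw$race, program = program)
}

#' Merge pedigrees from separate programs
#'
#' Concatenates program pedigrees into one joint pedigree.  Founders known
#' to be the same physical tree under different program codes are collapsed
#' to a single node through an alias table.
#'
#' @param ... `pedigree` objects (already namespaced, e.g. from
#'   [read_pedigree()]).
#' @param aliases optional two-column data frame; each row gives two ids
#'   (one per program) that refer to the same individual.  The first id is
#'   kept, occurrences of the second are rewritten.
#' @return A sorted joint [pedigree()].
#' @export
merge_pedigrees <- function(..., aliases = NULL) {
  peds <- list(...)
  all <- do.call(rbind, lapply(peds, as.data.frame))
  if (!is.null(aliases)) {
    for (k in seq_len(nrow(aliases))) {
      keep <- as.character(aliases[k, 1L])
      drop <- as.character(aliases[k, 2L])
      if (!keep %in% all$id || !drop %in% all$id)
        stop("alias id not present in merged pedigree: ",
             if (!keep %in% all$id) keep else drop)
      all <- all[all$id != drop, , drop = FALSE]
      all$sire[!is.na(all$sire) & all$sire == drop] <- keep
      all$dam[!is.na(all$dam) & all$dam == drop] <- keep
    }
  }
  if (anyDuplicated(all$id))
    stop("duplicate id(s) after merge: ",
         paste(unique(all$id[duplicated(all$id)]), collapse = ", "))
  pedigree(all$id, all$sire, all$dam, all$race, all$program)
}

#' Topologically sort and validate a pedigree
#'
#' Reorders records so that every parent precedes its offspring and checks
#' the parentage graph is acyclic.  Sorting is stable: an already sorted
#' pedigree is returned in identical order, so the operation is idempotent.
#'
#' @param p a [pedigree()] object.
#' @return The sorted pedigree (attribute `sorted` set to `TRUE`).
#' @export
topo_sort_validate <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  n <- nrow(p)
  idx <- match_parents(p)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (idx$sire == 0L | placed[pmax(idx$sire, 1L)]) &
      (idx$dam == 0L | placed[pmax(idx$dam, 1L)])
    ready <- which(ready)
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) {
    cyc <- find_cycle(p, idx, placed)
    stop("pedigree contains an ancestry cycle: ",
         paste(cyc, collapse = " -> "))
  }
  out <- p[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  attr(out, "sorted") <- TRUE
  out
}

# integer indices of sire/dam within the record table (0 = unknown)
match_parents <- function(p) {
  s <- match(p$sire, p$id)
  d <- match(p$dam, p$id)
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  list(sire = s, dam = d)
}

# walk parent pointers among unplaced nodes until a repeat is seen
find_cycle <- function(p, idx, placed) {
  start <- which(!placed)[1L]
  seen <- integer(0)
  cur <- start
  while (!cur %in% seen) {
    seen <- c(seen, cur)
    nxt <- c(idx$sire[cur], idx$dam[cur])
    nxt <- nxt[nxt != 0L & !placed[pmax(nxt, 1L)]]
    cur <- nxt[1L]
  }
  cyc <- seen[which(seen == cur):length(seen)]
  p$id[c(cyc, cur)]
}

#' Inbreeding coefficients by the Meuwissen--Luo algorithm
#'
#' Computes the inbreeding coefficient F for every individual, equal to
#' the coancestry of its parents.  Founders (and individuals with an
#' unknown parent) have F = 0.  The algorithm accumulates, for each
#' individual, the squared gene-flow contributions of its ancestors
#' weighted by their Mendelian-sampling variances, which yields the
#' diagonal of the numerator relationship matrix without forming it.
#'
#' @param p a sorted [pedigree()].
#' @return Named numeric vector of F, in pedigree order.
#' @export
inbreeding_meuwissen_luo <- function(p) {
  p <- ensure_sorted(p)
  n <- nrow(p)
  idx <- match_parents(p)
  s <- idx$sire; d <- idx$dam
  F <- numeric(n)
  D <- numeric(n)   # Mendelian sampling variance scale d_i
  Fpar <- function(j) if (j == 0L) -1 else F[j]
  L <- numeric(n)
  for (i in seq_len(n)) {
    D[i] <- 0.5 - 0.25 * (Fpar(s[i]) + Fpar(d[i]))
    if (s[i] == 0L || d[i] == 0L) { F[i] <- 0; next }
    # a_ii = sum_j L_j^2 D_j over ancestors j of i (including i)
    FI <- -1
    L[i] <- 1
    anc <- i
    while (length(anc)) {
      j <- max(anc)
      anc <- anc[anc != j]
      if (s[j] != 0L) { if (L[s[j]] == 0 && s[j] != j) anc <- c(anc, s[j]); L[s[j]] <- L[s[j]] + 0.5 * L[j] }
      if (d[j] != 0L) { if (L[d[j]] == 0 && d[j] != j) anc <- c(anc, d[j]); L[d[j]] <- L[d[j]] + 0.5 * L[j] }
      FI <- FI + L[j]^2 * D[j]
      L[j] <- 0
    }
    # ensure any residual L entries cleared (those added twice)
    F[i] <- FI
  }
  names(F) <- p$id
  F
}

ensure_sorted <- function(p) {
  stopifnot(inherits(p, "pedigree"))
  if (!isTRUE(attr(p, "sorted"))) p <- topo_sort_validate(p)
  p
}

#' Founder indicator
#'
#' @param p a [pedigree()].
#' @return Logical vector: both parents unknown.
#' @export
is_founder <- function(p) is.na(p$sire) & is.na(p$dam)

#' Numerator relationship matrix by the tabular method
#'
#' Builds the additive (numerator) relationship matrix A recursively:
#' `a_ij = (a_j,sire(i) + a_j,dam(i)) / 2` for j preceding i, with an
#' unknown parent contributing 0, and `a_ii = 1 + F_i` where `F_i` is half
#' the relationship between the parents.
#'
#' @param p a sorted [pedigree()].
#' @param subset optional character vector of ids; the full recursion is
#'   performed and rows/columns are then selected.
#' @return A [relmat()] with role `"A"`.
#' @export
build_A_tabular <- function(p, subset = NULL) {
  p <- ensure_sorted(p)
  n <- nrow(p)
  idx <- match_parents(p)
  s <- idx$sire; d <- idx$dam
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1L)
    if (i > 1L) {
      col <- numeric(i - 1L)
      if (s[i] != 0L) col <- col + A[prev, s[i]]
      if (d[i] != 0L) col <- col + A[prev, d[i]]
      col <- 0.5 * col
      A[prev, i] <- col
      A[i, prev] <- col
    }
    A[i, i] <- 1 + if (s[i] != 0L && d[i] != 0L) 0.5 * A[s[i], d[i]] else 0
  }
  dimnames(A) <- list(p$id, p$id)
  if (!is.null(subset)) {
    missing <- setdiff(subset, p$id)
    if (length(missing))
      stop("subset id(s) not in pedigree: ", paste(missing, collapse = ", "))
    A <- A[subset, subset, drop = FALSE]
    return(relmat(A, subset, role = "A"))
  }
  relmat(A, p$id, role = "A")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Direct construction of A-inverse by Henderson's rules with inbreeding:
#' each individual contributes `alpha = 1/d_i` to its own diagonal and
#' `-alpha/2`, `alpha/4` terms to parent cells, where the
#' Mendelian-sampling variance is `d_i = 0.5 - 0.25 (F_s + F_d)` and an
#' unknown parent enters with F = -1 (i.e. as an unrelated, non-inbred
#' population draw).
#'
#' @param p a sorted [pedigree()].
#' @return A [relmat()] with role `"Ainv"` holding a sparse symmetric
#'   matrix.
#' @export
build_A_inverse <- function(p) {
  p <- ensure_sorted(p)
  n <- nrow(p)
  idx <- match_parents(p)
  s <- idx$sire; d <- idx$dam
  F <- inbreeding_meuwissen_luo(p)
  Fpar <- function(j) ifelse(j == 0L, -1, F[pmax(j, 1L)])
  alpha <- 1 / (0.5 - 0.25 * (Fpar(s) + Fpar(d)))
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  # vectorized triplet assembly
  seqn <- seq_len(n)
  add(seqn, seqn, alpha)
  ks <- which(s != 0L); kd <- which(d != 0L); kb <- which(s != 0L & d != 0L)
  if (length(ks)) {
    add(s[ks], ks, -alpha[ks] / 2); add(ks, s[ks], -alpha[ks] / 2)
    add(s[ks], s[ks], alpha[ks] / 4)
  }
  if (length(kd)) {
    add(d[kd], kd, -alpha[kd] / 2); add(kd, d[kd], -alpha[kd] / 2)
    add(d[kd], d[kd], alpha[kd] / 4)
  }
  if (length(kb)) {
    add(s[kb], d[kb], alpha[kb] / 4); add(d[kb], s[kb], alpha[kb] / 4)
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(p$id, p$id))
  relmat(Matrix::forceSymmetric(Ainv), p$id, role = "Ainv")
}

#' Partition A by genotyping status
#'
#' Splits A into the blocks `A11` (nongenotyped), `A22` (genotyped) and
#' the rectangular blocks `A12`, `A21` connecting them, consistent with a
#' permutation of A.
#'
#' @param A a [relmat()] with role `"A"`.
#' @param genotyped character vector of genotyped ids (non-empty subset of
#'   `A$ids`).
#' @return List with components `A11`, `A12`, `A21`, `A22`.
#' @export
partition_A <- function(A, genotyped) {
  stopifnot(inherits(A, "relmat"))
  if (!length(genotyped))
    stop("empty genotyped list: H is undefined without genotyped individuals")
  missing <- setdiff(genotyped, A$ids)
  if (length(missing))
    stop("genotyped id(s) not in A: ", paste(missing, collapse = ", "))
  g <- A$ids %in% genotyped
  V <- as.matrix(A$values)
  ids_n <- A$ids[!g]; ids_g <- A$ids[g]
  list(
    A11 = relmat(V[!g, !g, drop = FALSE], ids_n, role = "A11"),
    A12 = relmat(V[!g, g, drop = FALSE], ids_n, role = "A12",
                 ids2 = ids_g, symmetric = FALSE),
    A21 = relmat(V[g, !g, drop = FALSE], ids_g, role = "A21",
                 ids2 = ids_n, symmetric = FALSE),
    A22 = relmat(V[g, g, drop = FALSE], ids_g, role = "A22")
  )
}

#' Expected founder-race fractions
#'
#' Westell-style genetic-group fractions: each founder's row is the
#' indicator of its race; every other row is the mean of its parents'
#' rows, an unknown parent contributing to the pseudo-group
#' `"UNKNOWN_RACE"`.  Rows sum to one, and the fractions equal the
#' expected proportion of an individual's genome descending from founders
#' of each race.
#'
#' @param p a sorted [pedigree()].
#' @return A `group_fractions` object: list with `ids`, `groups` and the
#'   fraction matrix `values`.
#' @export
group_fraction_matrix <- function(p) {
  p <- ensure_sorted(p)
  n <- nrow(p)
  idx <- match_parents(p)
  founder <- is_founder(p)
  race <- p$race
  if (any(founder & is.na(race))) {
    warning("founder(s) without race assigned to group UNKNOWN_RACE: ",
            paste(p$id[founder & is.na(race)], collapse = ", "))
    race[founder & is.na(race)] <- "UNKNOWN_RACE"
  }
  need_unknown <- any(!founder & (idx$sire == 0L | idx$dam == 0L))
  groups <- sort(unique(race[founder]))
  if (need_unknown && !"UNKNOWN_RACE" %in% groups)
    groups <- c(groups, "UNKNOWN_RACE")
  k <- length(groups)
  Q <- matrix(0, n, k, dimnames = list(p$id, groups))
  unk <- if ("UNKNOWN_RACE" %in% groups) {
    u <- numeric(k); u[match("UNKNOWN_RACE", groups)] <- 1; u
  } else NULL
  for (i in seq_len(n)) {
    if (founder[i]) {
      Q[i, match(race[i], groups)] <- 1
    } else {
      rs <- if (idx$sire[i] != 0L) Q[idx$sire[i], ] else unk
      rd <- if (idx$dam[i] != 0L) Q[idx$dam[i], ] else unk
      Q[i, ] <- 0.5 * (rs + rd)
    }
  }
  structure(list(ids = p$id, groups = groups, values = Q),
            class = "group_fractions")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,",
      sum(is_founder(x)), "founders,",
      length(unique(x$program)), "program(s)\n")
  NextMethod()
  invisible(x)
}
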