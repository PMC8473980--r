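#' Single-step relationship matrix H
#'
#' Combines the pedigree relationship matrix A with the blended genomic
#' matrix Gw over the genotyped subset.  Two algebraically equivalent
#' assemblies are provided: the `"direct"` form
#' `H11 = A11 + A12 A22^-1 (Gw - A22) A22^-1 A21`,
#' `H12 = A12 A22^-1 Gw`, `H22 = Gw`, and the `"expanded"` form that
#' writes `H11` as `A11 - A12 A22^-1 A21 + A12 A22^-1 Gw A22^-1 A21`.
#' The result is re-sorted to A's id order so it aligns with the
#' pedigree.
#'
#' @param A pedigree [relmat()] over all individuals.
#' @param Gw blended genomic [relmat()] over the genotyped individuals.
#' @param genotyped character vector of genotyped ids.
#' @param method `"direct"` or `"expanded"` assembly (identical results;
#'   both kept as a numerical cross-check).
#' @return A [relmat()] with role `"H"`, ids in A's order.
#' @export
build_H <- function(A, Gw, genotyped, method = c("direct", "expanded")) {
  method <- match.arg(method)
  stopifnot(inherits(A, "relmat"), inherits(Gw, "relmat"))
  if (!setequal(Gw$ids, genotyped))
    stop("Gw ids do not match the genotyped list")
  parts <- partition_A(A, genotyped)
  gids <- parts$A22$ids
  Gw <- rel_reorder(Gw, gids)
  A11 <- as.matrix(parts$A11$values)
  A12 <- as.matrix(parts$A12$values)
  A22 <- as.matrix(parts$A22$values)
  Gm <- as.matrix(Gw$values)
  A22inv <- tryCatch(solve(A22), error = function(e)
    stop("A22 is singular; consider a larger pedigree or check ids: ",
         conditionMessage(e)))
  P12 <- A12 %*% A22inv              # A12 A22^-1
  if (method == "direct") {
    H11 <- A11 + P12 %*% (Gm - A22) %*% t(P12)
  } else {
    H11 <- A11 - P12 %*% t(A12) + P12 %*% Gm %*% t(P12)
  }
  H12 <- P12 %*% Gm
  ids <- c(parts$A11$ids, gids)
  H <- rbind(cbind(H11, H12), cbind(t(H12), Gm))
  dimnames(H) <- list(ids, ids)
  H <- (H + t(H)) / 2
  rel_reorder(relmat(H, ids, role = "H", tol = 1e-8), A$ids)
}

#' Sparse single-step inverse H^-1
#'
#' `H^-1 = A^-1 + [0 0; 0 Gw^-1 - A22^-1]`: the sparse pedigree inverse
#' plus a dense correction on the genotyped block only.
#'
#' @param Ainv sparse pedigree inverse ([relmat()], role `"Ainv"`).
#' @param Gw blended genomic [relmat()] over the genotyped ids.
#' @param A22 pedigree block [relmat()] over the genotyped ids.
#' @param genotyped character vector of genotyped ids.
#' @return A [relmat()] with role `"Hinv"` (sparse with dense genotyped
#'   block), ids in Ainv's order.
#' @export
build_H_inverse <- function(Ainv, Gw, A22, genotyped) {
  stopifnot(inherits(Ainv, "relmat"))
  if (!setequal(Gw$ids, genotyped) || !setequal(A22$ids, genotyped))
    stop("Gw/A22 ids do not match the genotyped list")
  gids <- intersect(Ainv$ids, genotyped)
  if (length(gids) != length(genotyped))
    stop("genotyped id(s) missing from Ainv: ",
         paste(setdiff(genotyped, Ainv$ids), collapse = ", "))
  Gw <- rel_reorder(Gw, gids)
  A22 <- rel_reorder(A22, gids)
  Gwinv <- tryCatch(solve(as.matrix(Gw$values)), error = function(e)
    stop("Gw is numerically singular after blending: ",
         conditionMessage(e)))
  corr <- Gwinv - solve(as.matrix(A22$values))
  corr <- (corr + t(corr)) / 2
  gi <- match(gids, Ainv$ids)
  n <- length(Ainv$ids)
  Corr <- Matrix::sparseMatrix(
    i = rep(gi, each = length(gi)),
    j = rep(gi, times = length(gi)),
    x = as.numeric(t(corr)), dims = c(n, n),
    dimnames = list(Ainv$ids, Ainv$ids))
  Hinv <- Matrix::forceSymmetric(Ainv$values + Corr)
  relmat(Hinv, Ainv$ids, role = "Hinv")
}

#' Detect pedigree conflicts from genomic vs expected relationships
#'
#' Compares realized relationship coefficients in the raw (untuned) G
#' against pedigree expectations in A22 and flags pairs (and diagonal
#' self-comparisons) whose absolute deviation reaches `dev_threshold`.
#' Flagged parent-offspring pairs with near-zero realized relationship
#' indicate wrong parentage; unrelated pairs with realized coefficients
#' near 0.5 indicate unrecorded relationships or sample identity errors.
#'
#' @param G raw genomic [relmat()] (pre-tuning scale).
#' @param A22 matching pedigree block [relmat()] (same ids).
#' @param p the [pedigree()] (used to classify flagged pairs).
#' @param dev_threshold absolute deviation required to flag (default
#'   0.35, midway between half-sib and parent-offspring expectations).
#' @return A `conflict_report` data frame: id1, id2, expected, realized,
#'   deviation, relation_class; ordered by |deviation| decreasing.
#' @export
detect_pedigree_conflicts <- function(G, A22, p, dev_threshold = 0.35) {
  stopifnot(inherits(G, "relmat"), inherits(A22, "relmat"))
  A22 <- rel_reorder(A22, G$ids)
  Gm <- as.matrix(G$values); Am <- as.matrix(A22$values)
  dev <- Gm - Am
  flag <- which(abs(dev) >= dev_threshold & upper.tri(dev, diag = TRUE),
                arr.ind = TRUE)
  idx <- match_parents(p)
  pid <- p$id
  classify <- function(i, j) {
    if (i == j) return("self")
    pi <- match(G$ids[i], pid); pj <- match(G$ids[j], pid)
    if (is.na(pi) || is.na(pj)) return("unrelated")
    par_i <- c(idx$sire[pi], idx$dam[pi]); par_j <- c(idx$sire[pj], idx$dam[pj])
    if (pj %in% par_i || pi %in% par_j) return("parent-offspring")
    shared <- intersect(par_i[par_i != 0L], par_j[par_j != 0L])
    if (length(shared)) return("sib")
    "unrelated"
  }
  out <- data.frame(
    id1 = G$ids[flag[, 1L]],
    id2 = G$ids[flag[, 2L]],
    expected = Am[flag],
    realized = Gm[flag],
    deviation = dev[flag],
    stringsAsFactors = FALSE
  )
  out$relation_class <- if (nrow(out))
    mapply(classify, flag[, 1L], flag[, 2L]) else character(0)
  out <- out[order(-abs(out$deviation)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("conflict_report", "data.frame")
  attr(out, "dev_threshold") <- dev_threshold
  out
}

#' Drop conflicting parent links
#'
#' Applies the correction policy for confirmed pedigree conflicts: for
#' every flagged parent-offspring pair the parent link is severed (set to
#' unknown).  The relationship machinery is then expected to be re-run on
#' the corrected pedigree.
#'
#' @param p a [pedigree()].
#' @param conflicts a `conflict_report` from [detect_pedigree_conflicts()].
#' @return The corrected, re-sorted [pedigree()].
#' @export
correct_pedigree <- function(p, conflicts) {
  po <- conflicts[conflicts$relation_class == "parent-offspring", ,
                  drop = FALSE]
  for (k in seq_len(nrow(po))) {
    a <- po$id1[k]; b <- po$id2[k]
    for (pr in list(c(a, b), c(b, a))) {
      i <- match(pr[1L], p$id)
      if (!is.na(i)) {
        if (!is.na(p$sire[i]) && p$sire[i] == pr[2L]) p$sire[i] <- NA
        if (!is.na(p$dam[i]) && p$dam[i] == pr[2L]) p$dam[i] <- NA
      }
    }
  }
  topo_sort_validate(p)
}

#' Summarize founder relationships in H by race
#'
#' Within each race, statistics are taken over all unordered pairs of
#' distinct founders and tested against zero with a one-sided one-sample
#' t-test (H1: mean > 0).  Between races, all cross pairs are tested
#' two-sided.  Races contributing fewer than two pairs (or pairs with
#' zero variance) are reported but marked untestable.
#'
#' @param H a [relmat()] (typically role `"H"`).
#' @param p the [pedigree()]; founders are records with both parents
#'   unknown and a race label.
#' @return A `race_rel_summary`: list of data frames `within` and
#'   `between`.
#' @export
summarize_founder_relationships <- function(H, p) {
  stopifnot(inherits(H, "relmat"))
  fo <- p[is_founder(p) & !is.na(p$race) & p$id %in% H$ids, , drop = FALSE]
  races <- sort(unique(fo$race))
  M <- as.matrix(H$values)
  hidx <- match(fo$id, H$ids)
  pair_vals <- function(i1, i2, cross) {
    if (cross) as.numeric(M[i1, i2, drop = FALSE])
    else {
      if (length(i1) < 2) return(numeric(0))
      sub <- M[i1, i1, drop = FALSE]
      sub[upper.tri(sub)]
    }
  }
  trow <- function(v, alternative) {
    n <- length(v)
    if (n < 2 || stats::sd(v) == 0)
      return(list(t = NA_real_, pval = NA_real_, testable = FALSE))
    tt <- stats::t.test(v, mu = 0, alternative = alternative)
    list(t = unname(tt$statistic), pval = tt$p.value, testable = TRUE)
  }
  within <- do.call(rbind, lapply(races, function(r) {
    v <- pair_vals(hidx[fo$race == r], NULL, FALSE)
    tt <- trow(v, "greater")
    data.frame(race = r, n_founders = sum(fo$race == r), n_pairs = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else 0,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_,
               t = tt$t, pval = tt$pval, testable = tt$testable,
               stringsAsFactors = FALSE)
  }))
  cmb <- if (length(races) > 1) utils::combn(races, 2) else
    matrix(character(0), 2, 0)
  between <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    r1 <- cmb[1L, k]; r2 <- cmb[2L, k]
    v <- pair_vals(hidx[fo$race == r1], hidx[fo$race == r2], TRUE)
    tt <- trow(v, "two.sided")
    data.frame(race1 = r1, race2 = r2, n_pairs = length(v),
               mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v),
               t = tt$t, pval = tt$pval, testable = tt$testable,
               stringsAsFactors = FALSE)
  }))
  structure(list(within = within, between = between),
            class = "race_rel_summary")
}

#' @export
print.race_rel_summary <- function(x, ...) {
  cat("Within-race founder relationships in H:\n")
  print(x$within, digits = 3)
  if (!is.null(x$between) && nrow(x$between)) {
    cat("\nBetween-race founder relationships in H:\n")
    print(x$between, digits = 3)
  }
  invisible(x)
}

#' Write a conflict report or race summary as TSV
#'
#' @param x a `conflict_report` or one of the data frames of a
#'   `race_rel_summary`.
#' @param path output TSV path.
#' @export
write_report_tsv <- function(x, path) {
  if (inherits(x, "race_rel_summary")) {
    utils::write.table(x$within, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.table(as.data.frame(x), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
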