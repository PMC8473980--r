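#' Marker matrix container
#'
#' Individuals-by-markers genotype scores coded 0/1/2 (count of the
#' alternative allele) with `NA` for missing calls.  After [qc_filter()]
#' the matrix carries per-marker alternative-allele frequencies and no
#' missing entries.
#'
#' @param scores numeric matrix (individuals x markers), entries in
#'   \{0, 1, 2, NA\}.
#' @param ids individual ids (rows).
#' @param markers marker names (columns).
#' @param freq optional per-marker alternative-allele frequency.
#' @return A `marker_matrix` object.
#' @export
marker_matrix <- function(scores, ids = rownames(scores),
                          markers = colnames(scores), freq = NULL) {
  scores <- as.matrix(scores)
  if (is.null(ids) || is.null(markers))
    stop("marker matrix needs individual ids and marker names")
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(markers))
    stop("duplicate marker name(s): ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  bad <- !(scores %in% c(0, 1, 2) | is.na(scores))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(scores)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype score at individual '%s', marker '%s'",
                 ids[w[1L]], markers[w[2L]]))
  }
  dimnames(scores) <- list(ids, markers)
  structure(list(ids = ids, markers = markers, scores = scores,
                 freq = freq), class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("Marker matrix: %d individuals x %d markers, %.2f%% missing%s\n",
              length(x$ids), length(x$markers),
              100 * mean(is.na(x$scores)),
              if (is.null(x$freq)) "" else " (QC'd)"))
  invisible(x)
}

#' @export
dim.marker_matrix <- function(x) dim(x$scores)

#' Read a genotype file
#'
#' Accepts two dialects: a TSV with an `id` column followed by one column
#' per marker (values 0/1/2/NA), or the PLINK `.raw` dialect
#' (`FID IID PAT MAT SEX PHENOTYPE` then one allele-dosage column per
#' marker, whitespace separated).  The dialect is detected from the
#' header.
#'
#' @param path genotype file.
#' @return A [marker_matrix()] with missingness preserved.
#' @export
read_genotypes <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "[\t ]+")[[1L]]
  plink <- length(hdr) >= 6 &&
    all(toupper(hdr[1:6]) == c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
  if (plink) {
    tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                             na.strings = c("NA", "-9"))
    ids <- as.character(tab$IID)
    sc <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    tab <- utils::read.delim(path, check.names = FALSE,
                             na.strings = c("NA", ""))
    idcol <- which(tolower(names(tab)) == "id")[1L]
    if (is.na(idcol)) stop("genotype TSV must have an 'id' column")
    ids <- as.character(tab[[idcol]])
    sc <- as.matrix(tab[, -idcol, drop = FALSE])
  }
  storage.mode(sc) <- "double"
  bad <- !(sc %in% c(0, 1, 2) | is.na(sc))
  if (any(bad)) {
    w <- which(matrix(bad, nrow(sc)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-{0,1,2,NA} genotype token at row %d, column '%s'",
                 w[1L], colnames(sc)[w[2L]]))
  }
  marker_matrix(sc, ids = ids, markers = colnames(sc))
}

#' Genotype quality control
#'
#' Computes the alternative-allele frequency of each marker from
#' non-missing calls, removes markers whose minor allele frequency is
#' below `maf_threshold`, and mean-imputes remaining missing scores to
#' `2 p_j`.  An optional per-individual call-rate filter is available but
#' off by default.
#'
#' @param mm a [marker_matrix()].
#' @param maf_threshold minimum minor allele frequency (default 0.05).
#' @param min_call_rate optional minimum per-individual call rate; `NULL`
#'   (default) disables the filter.
#' @return A QC'd [marker_matrix()] with `freq` set and an attached
#'   `"qc_report"` attribute (data frame: marker, p, status, reason).
#' @export
qc_filter <- function(mm, maf_threshold = 0.05, min_call_rate = NULL) {
  stopifnot(inherits(mm, "marker_matrix"))
  sc <- mm$scores
  if (!is.null(min_call_rate)) {
    cr <- rowMeans(!is.na(sc))
    drop_id <- cr < min_call_rate
    if (any(drop_id)) {
      warning(sum(drop_id), " individual(s) removed by call-rate filter")
      sc <- sc[!drop_id, , drop = FALSE]
    }
  }
  p <- colMeans(sc, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= maf_threshold
  report <- data.frame(
    marker = colnames(sc),
    p = as.numeric(p),
    status = ifelse(keep, "kept", "removed"),
    reason = ifelse(keep, "", sprintf("MAF %.4f < %.4f", maf, maf_threshold)),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) stop("no informative markers after MAF filter")
  sc <- sc[, keep, drop = FALSE]
  p <- p[keep]
  # mean imputation to 2 p_j
  for (j in which(colSums(is.na(sc)) > 0L)) {
    sc[is.na(sc[, j]), j] <- 2 * p[j]
  }
  # imputed scores are fractional, so bypass the {0,1,2,NA} validation
  out <- structure(list(ids = rownames(sc), markers = colnames(sc),
                        scores = sc, freq = unname(p)),
                   class = "marker_matrix")
  attr(out, "qc_report") <- report
  out
}

#' Write the QC report
#'
#' @param mm a QC'd [marker_matrix()] (output of [qc_filter()]).
#' @param path output TSV.
#' @export
write_qc_report <- function(mm, path) {
  rep <- attr(mm, "qc_report")
  if (is.null(rep)) stop("no QC report attached; run qc_filter() first")
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum_j p_j (1 - p_j))` with `Z = M - 2P`, where `M` holds
#' 0/1/2 scores and `P` the alternative-allele frequencies.
#'
#' @param mm a QC'd [marker_matrix()] (no missing scores; frequencies
#'   recorded, or recomputed from the scores when absent).
#' @return A [relmat()] with role `"G"`.
#' @export
compute_G_vanraden1 <- function(mm) {
  stopifnot(inherits(mm, "marker_matrix"))
  if (anyNA(mm$scores))
    stop("marker matrix has missing scores; run qc_filter() first")
  p <- mm$freq
  if (is.null(p)) p <- colMeans(mm$scores) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("zero denominator: all markers are monomorphic")
  Z <- sweep(mm$scores, 2L, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  relmat(G, mm$ids, role = "G", tol = 1e-10)
}

#' Tune G to the scale of A22
#'
#' Solves for the intercept `a` and slope `b` that match the mean diagonal
#' and the overall mean of `G` to those of `A22`:
#' `a + b mean(diag G) = mean(diag A22)` and `a + b mean(G) = mean(A22)`,
#' where the overall means average all n^2 entries.  Returns
#' `Ga = a + b G` applied entrywise.
#'
#' @param G a [relmat()] (role `"G"`).
#' @param A22 a [relmat()] over the same ids in the same order.
#' @return List with `Ga` (a [relmat()], role `"Ga"`) and `coef`
#'   (named vector `a`, `b`).
#' @export
tune_G <- function(G, A22) {
  stopifnot(inherits(G, "relmat"), inherits(A22, "relmat"))
  if (!identical(G$ids, A22$ids))
    stop("G and A22 must be indexed by the same ids in the same order")
  mdG <- mean(rel_diag(G)); mG <- mean(G)
  mdA <- mean(rel_diag(A22)); mA <- mean(A22)
  if (abs(mdG - mG) < 1e-12)
    stop("degenerate G, cannot tune: mean(diag G) equals mean(G)")
  b <- (mdA - mA) / (mdG - mG)
  a <- mA - b * mG
  Ga <- relmat(a + b * as.matrix(G$values), G$ids, role = "Ga", tol = 1e-8)
  list(Ga = Ga, coef = c(a = a, b = b))
}

#' Blend the tuned G with A22
#'
#' `Gw = w Ga + (1 - w) A22`, the convex combination that guarantees an
#' invertible genomic block when `A22` is positive definite.
#'
#' @param Ga tuned genomic [relmat()].
#' @param A22 pedigree block [relmat()] (same ids/order).
#' @param w genomic weight in \[0, 1\] (default 0.95).
#' @return A [relmat()] with role `"Gw"`.
#' @export
blend_G <- function(Ga, A22, w = 0.95) {
  stopifnot(inherits(Ga, "relmat"), inherits(A22, "relmat"))
  if (w < 0 || w > 1) stop("blend weight w must be in [0, 1]")
  if (!identical(Ga$ids, A22$ids))
    stop("Ga and A22 must be indexed by the same ids in the same order")
  relmat(w * as.matrix(Ga$values) + (1 - w) * as.matrix(A22$values),
         Ga$ids, role = "Gw", tol = 1e-8)
}
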