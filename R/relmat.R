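#' Relationship matrix container
#'
#' Light wrapper pairing a (possibly sparse) relationship matrix with its
#' individual-id index and a role label (`"A"`, `"A22"`, `"G"`, `"Ga"`,
#' `"Gw"`, `"H"`, `"Ainv"`, `"Hinv"`, ...).  Square matrices are checked
#' for symmetry.
#'
#' @param values numeric matrix or `Matrix` sparse matrix.
#' @param ids character vector indexing the rows.
#' @param role role label.
#' @param ids2 column ids for rectangular blocks (defaults to `ids`).
#' @param symmetric check/enforce symmetry (default `TRUE`).
#' @param tol symmetry tolerance.
#' @return A `relmat` object (list with `ids`, `values`, `role`).
#' @export
relmat <- function(values, ids, role = "A", ids2 = ids,
                   symmetric = TRUE, tol = 1e-12) {
  if (nrow(values) != length(ids) || ncol(values) != length(ids2))
    stop("relmat dimension does not match id index")
  if (symmetric && length(values)) {
    asym <- max(abs(values - Matrix::t(values)))
    if (asym > tol)
      stop(sprintf("matrix is not symmetric (max asymmetry %.3g)", asym))
    values <- (values + Matrix::t(values)) / 2
  }
  dimnames(values) <- list(ids, ids2)
  structure(list(ids = ids, ids2 = ids2, values = values, role = role),
            class = "relmat")
}

#' @export
print.relmat <- function(x, ...) {
  cat(sprintf("Relationship matrix [%s]: %d x %d%s\n", x$role,
              nrow(x$values), ncol(x$values),
              if (is(x$values, "sparseMatrix")) " (sparse)" else ""))
  if (length(x$ids) <= 8) print(as.matrix(x$values)) else {
    cat("mean(diag) =", signif(mean(Matrix::diag(x$values)), 5),
        " mean =", signif(mean(x$values), 5), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.relmat <- function(x, ...) as.matrix(x$values)

#' @export
dim.relmat <- function(x) dim(x$values)

#' @export
mean.relmat <- function(x, ...) mean(as.numeric(as.matrix(x$values)))

rel_diag <- function(x) Matrix::diag(x$values)

# align a relmat to a given id order
rel_reorder <- function(x, ids) {
  stopifnot(setequal(ids, x$ids))
  i <- match(ids, x$ids)
  relmat(x$values[i, i, drop = FALSE], ids, role = x$role,
         symmetric = FALSE)
}

#' Write a relationship matrix to text
#'
#' Two dialects: `"dense"` writes a CSV with ids as header and row names;
#' `"triplet"` writes the nonzero lower triangle (including the diagonal)
#' as `rowid colid value` lines with 17 significant digits, the format
#' consumed by BLUPF90-family tools.
#'
#' @param x a [relmat()].
#' @param path output file.
#' @param format `"triplet"` or `"dense"`.
#' @export
write_relmat <- function(x, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  M <- as.matrix(x$values)
  if (format == "dense") {
    df <- as.data.frame(M)
    utils::write.csv(cbind(id = x$ids, df), path, row.names = FALSE,
                     quote = FALSE)
  } else {
    lt <- which(lower.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    lines <- sprintf("%s %s %.17g", x$ids[lt[, 1L]], x$ids2[lt[, 2L]],
                     M[lt])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a triplet-format relationship matrix
#'
#' @param path file of `rowid colid value` lines (lower triangle).
#' @param ids optional id order for the result; defaults to order of first
#'   appearance.
#' @param role role label for the result.
#' @return A [relmat()].
#' @export
read_relmat_triplet <- function(path, ids = NULL, role = "A") {
  tr <- utils::read.table(path, col.names = c("i", "j", "x"),
                          colClasses = c("character", "character", "numeric"))
  if (is.null(ids)) ids <- unique(c(tr$i, tr$j))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  M[cbind(match(tr$i, ids), match(tr$j, ids))] <- tr$x
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  relmat(M, ids, role = role)
}
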