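## Sparse mixed-model equations and AI-REML variance estimation.
##
## The model is y = Xb + sum_t Z_t u_t + e with u_additive ~
## N(0, Sigma_a (x) K) for the numerator-relationship term (K = A or H,
## region-major Kronecker layout), u_t ~ N(0, diag of per-group
## variances) for the iid terms (family, OP family, iblock, plot), and
## e ~ N(0, diag(sigma2_e by trial)).  All likelihood, gradient and
## average-information quantities are evaluated through one sparse
## Cholesky factorization of the MME coefficient matrix per parameter
## value.

# ---- variance component containers ----------------------------------

#' Variance components for an hblup design
#'
#' Assembles a variance-component list matching a design: `Sigma_a` is
#' the (region x region) additive covariance (a 1x1 matrix for a single
#' additive variance), `iid` holds one named vector of per-group
#' variances for each iid random term, and `residual` one variance per
#' trial.
#'
#' @param d an `hblup_design` from [build_design()].
#' @param sigma2_a additive variance (scalar) or full `Sigma_a` matrix.
#' @param family,opfamily,iblock,plot variances for the corresponding
#'   terms (recycled across groups); ignored if the term is absent.
#' @param residual residual variance(s), recycled across trials.
#' @return A `variance_components` list.
#' @export
variance_components <- function(d, sigma2_a, family = NULL, opfamily = NULL,
                                iblock = NULL, plot = NULL, residual) {
  stopifnot(inherits(d, "hblup_design"))
  r <- d$terms$additive$r
  Sigma <- if (is.matrix(sigma2_a)) sigma2_a else diag(sigma2_a, r)
  dimnames(Sigma) <- list(d$regions, d$regions)
  given <- list(family = family, opfamily = opfamily, iblock = iblock,
                plot = plot)
  iid <- list()
  for (nm in names(d$terms)) {
    t <- d$terms[[nm]]
    if (t$type != "iid") next
    v <- given[[nm]]
    if (is.null(v)) stop("no variance given for term '", nm, "'")
    iid[[nm]] <- stats::setNames(rep_len(v, length(t$group_names)),
                                 t$group_names)
  }
  structure(list(
    Sigma_a = Sigma,
    iid = iid,
    residual = stats::setNames(rep_len(residual, length(d$res_names)),
                               d$res_names)
  ), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Additive covariance Sigma_a:\n"); print(round(x$Sigma_a, 5))
  for (nm in names(x$iid)) {
    cat(nm, "variance(s): ")
    cat(paste(sprintf("%s=%.5g", names(x$iid[[nm]]), x$iid[[nm]]),
              collapse = ", "), "\n")
  }
  cat("residual variance(s): ")
  cat(paste(sprintf("%s=%.5g", names(x$residual), x$residual),
            collapse = ", "), "\n")
  invisible(x)
}

default_start <- function(d) {
  vy <- stats::var(d$y)
  r <- d$terms$additive$r
  Sigma <- 0.3 * vy * (0.5 * diag(r) + 0.5 * matrix(1, r, r))
  iidv <- list(family = 0.1 * vy, opfamily = 0.1 * vy,
               iblock = 0.1 * vy, plot = 0.1 * vy)
  variance_components(d, Sigma,
                      family = iidv$family, opfamily = iidv$opfamily,
                      iblock = iidv$iblock, plot = iidv$plot,
                      residual = 0.5 * vy)
}

# ---- parameter packing (log / log-Cholesky scale) --------------------

vech_idx <- function(r) {
  idx <- which(lower.tri(matrix(0, r, r), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # row-major lower
}

pack_par <- function(vc, d) {
  out <- numeric(0); lab <- character(0)
  r <- nrow(vc$Sigma_a)
  L <- t(tryCatch(chol(vc$Sigma_a), error = function(e)
    chol(vc$Sigma_a + diag(1e-10 * max(diag(vc$Sigma_a)), r))))
  iv <- vech_idx(r)
  v <- numeric(nrow(iv))
  for (k in seq_len(nrow(iv))) {
    a <- iv[k, 1L]; b <- iv[k, 2L]
    v[k] <- if (a == b) log(L[a, a]) else L[a, b]
  }
  out <- c(out, v)
  lab <- c(lab, paste0("Sa.", iv[, 1L], ".", iv[, 2L]))
  for (nm in names(vc$iid)) {
    out <- c(out, log(vc$iid[[nm]]))
    lab <- c(lab, paste0(nm, ".", names(vc$iid[[nm]])))
  }
  out <- c(out, log(vc$residual))
  lab <- c(lab, paste0("resid.", names(vc$residual)))
  stats::setNames(out, lab)
}

unpack_par <- function(par, vc) {
  r <- nrow(vc$Sigma_a)
  iv <- vech_idx(r)
  L <- matrix(0, r, r)
  k0 <- 0L
  for (k in seq_len(nrow(iv))) {
    a <- iv[k, 1L]; b <- iv[k, 2L]
    L[a, b] <- if (a == b) exp(par[k]) else par[k]
  }
  k0 <- nrow(iv)
  Sigma <- L %*% t(L)
  dimnames(Sigma) <- dimnames(vc$Sigma_a)
  vc$Sigma_a <- Sigma
  for (nm in names(vc$iid)) {
    q <- length(vc$iid[[nm]])
    vc$iid[[nm]][] <- exp(par[k0 + seq_len(q)])
    k0 <- k0 + q
  }
  q <- length(vc$residual)
  vc$residual[] <- exp(par[k0 + seq_len(q)])
  vc
}

# Jacobian d(natural params)/d(transformed params); natural order =
# [vech(Sigma_a); iid variances; residual variances]
par_jacobian <- function(par, vc) {
  r <- nrow(vc$Sigma_a)
  iv <- vech_idx(r)
  nS <- nrow(iv)
  L <- matrix(0, r, r)
  for (k in seq_len(nS)) {
    a <- iv[k, 1L]; b <- iv[k, 2L]
    L[a, b] <- if (a == b) exp(par[k]) else par[k]
  }
  JS <- matrix(0, nS, nS)
  for (k in seq_len(nS)) {          # chol param (a,b)
    a <- iv[k, 1L]; b <- iv[k, 2L]
    dL <- matrix(0, r, r)
    dL[a, b] <- if (a == b) L[a, b] else 1
    dS <- dL %*% t(L) + L %*% t(dL)
    JS[, k] <- dS[iv]               # vech rows
  }
  nv <- length(unlist(vc$iid)) + length(vc$residual)
  other <- exp(par[nS + seq_len(nv)])
  J <- matrix(0, nS + nv, nS + nv)
  J[seq_len(nS), seq_len(nS)] <- JS
  if (nv) J[nS + seq_len(nv), nS + seq_len(nv)] <- diag(other, nv)
  J
}

# ---- MME assembly and likelihood -------------------------------------

# one-off precomputation shared across REML iterations
mme_precompute <- function(d, nrm_inv) {
  add <- d$terms$additive
  if (!inherits(nrm_inv, "relmat"))
    stop("nrm_inv must be a relmat (role Ainv or Hinv)")
  if (!setequal(nrm_inv$ids, add$ids))
    stop("relationship inverse ids do not match the pedigree ids in the design")
  ord <- match(add$ids, nrm_inv$ids)
  Kinv <- as(Matrix::forceSymmetric(nrm_inv$values[ord, ord]), "CsparseMatrix")
  chK <- Matrix::Cholesky(Kinv, LDL = FALSE, perm = TRUE)
  logdetKinv <- chol_logdet(chK)
  Zs <- lapply(d$terms, function(t) as(t$Z, "CsparseMatrix"))
  Xs <- as(Matrix::Matrix(d$X, sparse = TRUE), "CsparseMatrix")
  M <- as(do.call(cbind, c(list(Xs), Zs)), "CsparseMatrix")
  p <- ncol(d$X)
  sizes <- vapply(d$terms, function(t) ncol(t$Z), 1L)
  offs <- p + c(0L, cumsum(sizes))[seq_along(sizes)]
  names(offs) <- names(d$terms)
  n_res <- tabulate(d$res_group, nbins = length(d$res_names))
  Kt <- as(as(Kinv, "generalMatrix"), "TsparseMatrix")
  list(M = M, tM = Matrix::t(M), p = p, offs = offs, sizes = sizes,
       Kinv = Kinv, Kt_i = Kt@i + 1L, Kt_j = Kt@j + 1L, Kt_x = Kt@x,
       logdetKinv = logdetKinv, n_res = n_res,
       n_mme = ncol(M))
}

chol_logdet <- function(ch) {
  # log-determinant of the factored (original) matrix
  as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
}

ginv_blocks <- function(d, pre, vc) {
  out <- list()
  logdetG <- 0
  for (nm in names(d$terms)) {
    t <- d$terms[[nm]]
    if (t$type == "nrm") {
      Sinv <- solve(vc$Sigma_a)
      out[[nm]] <- Matrix::kronecker(as(Sinv, "CsparseMatrix"), pre$Kinv)
      logdetG <- logdetG +
        t$nid * as.numeric(determinant(vc$Sigma_a, TRUE)$modulus) -
        t$r * pre$logdetKinv
    } else {
      v <- vc$iid[[nm]][t$group]
      out[[nm]] <- Matrix::Diagonal(x = 1 / v)
      logdetG <- logdetG + sum(log(v))
    }
  }
  list(blocks = out, logdetG = logdetG)
}

# assemble C, factorize, solve; returns the full fit state at vc
mme_solve <- function(d, pre, vc) {
  r_inv <- 1 / vc$residual[d$res_group]
  Mw <- Matrix::Diagonal(x = r_inv) %*% pre$M
  C <- Matrix::crossprod(pre$M, Mw)
  gb <- ginv_blocks(d, pre, vc)
  Gi <- Matrix::bdiag(c(list(Matrix::Matrix(0, pre$p, pre$p, sparse = TRUE)),
                        gb$blocks))
  C <- Matrix::forceSymmetric(C + Gi)
  # LL' factorization: fails (caught by callers) if C is not numerically
  # positive definite, which protects the AI line search from accepting
  # indefinite candidates
  ch <- Matrix::Cholesky(as(C, "CsparseMatrix"), LDL = FALSE, perm = TRUE)
  rhs <- as.numeric(Matrix::crossprod(pre$M, r_inv * d$y))
  sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
  yPy <- sum(d$y^2 * r_inv) - sum(rhs * sol)
  logdetR <- sum(pre$n_res * log(vc$residual))
  ll <- -0.5 * (chol_logdet(ch) + logdetR + gb$logdetG + yPy)
  b <- sol[seq_len(pre$p)]
  u <- lapply(names(d$terms), function(nm)
    sol[pre$offs[[nm]] + seq_len(pre$sizes[[nm]])])
  names(u) <- names(d$terms)
  fitted <- as.numeric(pre$M %*% sol)
  ehat <- d$y - fitted
  list(vc = vc, ch = ch, sol = sol, b = b, u = u, rhs = rhs,
       r_inv = r_inv, ehat = ehat, Py = r_inv * ehat, yPy = yPy,
       loglik = ll)
}

# chunked extraction of C-inverse statistics:
#  diag  - diagonal of C^-1 over the random-effect columns (additive
#          block only when final = TRUE, for PEV)
#  Tmat  - r x r matrix of tr(Kinv %*% C^{u_r u_s}) for the nrm term
#  s_rec - m_i' C^-1 m_i per record (only when >1 residual group)
#  diagX - fixed-effect block diagonal (final = TRUE, for SEs)
mme_inv_stats <- function(d, pre, state, chunk = 1024L, need_srec = TRUE,
                          final = FALSE) {
  nm_mme <- pre$n_mme
  qtot <- nm_mme - pre$p
  diagC <- numeric(qtot)          # indexed from first random column
  add <- d$terms$additive
  r <- add$r; nid <- add$nid
  Tmat <- matrix(0, r, r)
  a0 <- pre$offs[["additive"]]
  # additive block: chunk over ids, all regions at once; the trace
  # accumulates Kinv entries against C-inverse values on Kinv's pattern
  # solve with unit columns built directly as a dense Matrix object and
  # read results through the data slot (avoids S4 conversion copies)
  solve_cols <- function(cols) {
    nc <- length(cols)
    x <- numeric(nm_mme * nc)
    x[(seq_len(nc) - 1) * nm_mme + cols] <- 1
    E <- methods::new("dgeMatrix", Dim = c(nm_mme, nc), x = x)
    Matrix::solve(state$ch, E, system = "A")@x
  }
  idchunk <- max(64L, chunk %/% r)
  for (J in split(seq_len(nid), ceiling(seq_len(nid) / idchunk))) {
    cols <- as.vector(outer(J, (seq_len(r) - 1L) * nid, "+")) + a0
    bx <- solve_cols(cols)
    if (final)
      diagC[cols - pre$p] <- bx[(seq_along(cols) - 1) * nm_mme + cols]
    inJ <- pre$Kt_j %in% J
    ti <- pre$Kt_i[inJ]
    tjpos <- match(pre$Kt_j[inJ], J)
    tx <- pre$Kt_x[inJ]
    for (s in seq_len(r)) {
      bcols <- (s - 1L) * length(J)
      for (rr in seq_len(r)) {
        rows <- a0 + (rr - 1L) * nid
        Tmat[rr, s] <- Tmat[rr, s] +
          sum(tx * bx[(bcols + tjpos - 1) * nm_mme + rows + ti])
      }
    }
  }
  # other random terms: diagonal only
  for (nm in names(d$terms)) {
    if (nm == "additive") next
    off <- pre$offs[[nm]]; q <- pre$sizes[[nm]]
    for (J in split(seq_len(q), ceiling(seq_len(q) / chunk))) {
      cols <- off + J
      bx <- solve_cols(cols)
      diagC[cols - pre$p] <- bx[(seq_along(cols) - 1) * nm_mme + cols]
    }
  }
  s_rec <- NULL
  if (need_srec && length(d$res_names) > 1L) {
    s_rec <- numeric(d$n)
    for (J in split(seq_len(d$n), ceiling(seq_len(d$n) / chunk))) {
      R <- as.matrix(pre$tM[, J, drop = FALSE])
      B <- as.matrix(Matrix::solve(state$ch, R, system = "A"))
      s_rec[J] <- colSums(R * B)
    }
  }
  diagX <- NULL
  if (final) {
    bx <- solve_cols(seq_len(pre$p))
    diagX <- bx[(seq_len(pre$p) - 1) * nm_mme + seq_len(pre$p)]
  }
  list(diagC = diagC, Tmat = Tmat, s_rec = s_rec, diagX = diagX)
}

# tr(G_t^-1 C^{tt}) for every random term (uses stats)
trace_GinvC <- function(d, pre, vc, stats) {
  out <- numeric(0)
  for (nm in names(d$terms)) {
    t <- d$terms[[nm]]
    idx <- pre$offs[[nm]] - pre$p + seq_len(pre$sizes[[nm]])
    if (t$type == "nrm") {
      out[nm] <- sum(solve(vc$Sigma_a) * stats$Tmat)
    } else {
      out[nm] <- sum(stats$diagC[idx] / vc$iid[[nm]][t$group])
    }
  }
  out
}

# natural-scale gradient, AI matrix and EM update ingredients
reml_derivatives <- function(d, pre, vc, state, stats) {
  add <- d$terms$additive
  r <- add$r; nid <- add$nid
  Sinv <- solve(vc$Sigma_a)
  iv <- vech_idx(r)
  U <- matrix(state$u$additive, nid, r)      # region-major unstack
  KinvU <- as.matrix(pre$Kinv %*% U)
  W2 <- crossprod(U, KinvU)                  # U' Kinv U  (r x r)
  npar <- nrow(iv) + length(unlist(vc$iid)) + length(vc$residual)
  g <- numeric(npar)
  F <- matrix(0, d$n, npar)
  k <- 0L
  # --- Sigma_a vech parameters
  for (kk in seq_len(nrow(iv))) {
    a <- iv[kk, 1L]; b <- iv[kk, 2L]
    E <- matrix(0, r, r); E[a, b] <- E[b, a] <- 1
    M2 <- Sinv %*% E %*% Sinv
    trP <- nid * sum(Sinv * E) - sum(M2 * stats$Tmat)
    term2 <- sum(M2 * W2)
    g[k + kk] <- -0.5 * (trP - term2)
    U2 <- U %*% t(E %*% Sinv)
    F[, k + kk] <- as.numeric(add$Z %*% as.numeric(U2))
  }
  k <- k + nrow(iv)
  # --- iid term variances
  for (nm in names(vc$iid)) {
    t <- d$terms[[nm]]
    off0 <- pre$offs[[nm]] - pre$p
    for (gi in seq_along(vc$iid[[nm]])) {
      sel <- which(t$group == gi)
      s2 <- vc$iid[[nm]][gi]
      uS <- state$u[[nm]][sel]
      trC <- sum(stats$diagC[off0 + sel])
      trP <- length(sel) / s2 - trC / s2^2
      term2 <- sum(uS^2) / s2^2
      g[k + gi] <- -0.5 * (trP - term2)
      usel <- numeric(pre$sizes[[nm]]); usel[sel] <- uS
      F[, k + gi] <- as.numeric(t$Z %*% usel) / s2
    }
    k <- k + length(vc$iid[[nm]])
  }
  # --- residual variances per trial
  trG <- trace_GinvC(d, pre, vc, stats)
  for (gi in seq_along(vc$residual)) {
    sel <- d$res_group == gi
    s2 <- vc$residual[gi]
    nk <- sum(sel)
    if (length(vc$residual) == 1L) {
      qsum <- sum(pre$sizes) - sum(trG)
      ssum <- s2 * (pre$p + qsum)
    } else {
      ssum <- sum(stats$s_rec[sel])
    }
    trP <- nk / s2 - ssum / s2^2
    term2 <- sum(state$Py[sel]^2)
    g[k + gi] <- -0.5 * (trP - term2)
    F[sel, k + gi] <- state$Py[sel]
  }
  # average information: AI_kl = 0.5 f_k' P f_l
  RHS <- as.matrix(Matrix::crossprod(pre$M, state$r_inv * F))
  SOL <- as.matrix(Matrix::solve(state$ch, RHS, system = "A"))
  PF <- state$r_inv * (F - as.matrix(pre$M %*% SOL))
  AI <- 0.5 * crossprod(F, PF)
  AI <- (AI + t(AI)) / 2
  list(g = g, AI = AI, W2 = W2, trG = trG)
}

em_update <- function(d, pre, vc, state, stats, der, floor) {
  add <- d$terms$additive
  nid <- add$nid
  Tm <- stats$Tmat
  Sigma_new <- (der$W2 + Tm) / nid
  Sigma_new <- (Sigma_new + t(Sigma_new)) / 2
  dg <- pmax(diag(Sigma_new), floor)
  diag(Sigma_new) <- dg
  vc$Sigma_a <- Sigma_new
  for (nm in names(vc$iid)) {
    t <- d$terms[[nm]]
    off0 <- pre$offs[[nm]] - pre$p
    for (gi in seq_along(vc$iid[[nm]])) {
      sel <- which(t$group == gi)
      uS <- state$u[[nm]][sel]
      vc$iid[[nm]][gi] <- max((sum(uS^2) +
                                 sum(stats$diagC[off0 + sel])) / length(sel),
                              floor)
    }
  }
  for (gi in seq_along(vc$residual)) {
    sel <- d$res_group == gi
    nk <- sum(sel)
    if (length(vc$residual) == 1L) {
      s2 <- vc$residual[gi]
      qsum <- sum(pre$sizes) - sum(der$trG)
      ssum <- s2 * (pre$p + qsum)
      vc$residual[gi] <- max((sum(state$ehat^2) + ssum) / nk, floor)
    } else {
      vc$residual[gi] <- max((sum(state$ehat[sel]^2) +
                                sum(stats$s_rec[sel])) / nk, floor)
    }
  }
  vc
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Builds Henderson's mixed-model equations
#' `[X'R^-1X, X'R^-1W; W'R^-1X, W'R^-1W + G^-1]` for the design, solves
#' them by sparse Cholesky factorization, and returns the solutions
#' together with the factor (sufficient to extract exact prediction
#' error variances).
#'
#' @param d an `hblup_design`.
#' @param vc a [variance_components()] list (all variances strictly
#'   positive).
#' @param nrm_inv the relationship inverse ([relmat()] role `"Ainv"` or
#'   `"Hinv"`) over the design's pedigree ids.
#' @return List with `b` (fixed-effect solutions), `u` (random-effect
#'   solutions per term), `fitted`, `residuals`, `loglik` (REML
#'   log-likelihood at `vc`) and the Cholesky factor `ch`.
#' @export
solve_mme <- function(d, vc, nrm_inv) {
  if (any(unlist(vc$iid) <= 0) || any(vc$residual <= 0) ||
      any(diag(vc$Sigma_a) <= 0))
    stop("all variance components must be strictly positive")
  pre <- mme_precompute(d, nrm_inv)
  state <- mme_solve(d, pre, vc)
  names(state$b) <- colnames(d$X)
  for (nm in names(state$u)) names(state$u[[nm]]) <- d$terms[[nm]]$levels
  list(b = state$b, u = state$u,
       fitted = d$y - state$ehat, residuals = state$ehat,
       loglik = state$loglik, ch = state$ch, pre = pre, state = state)
}

#' REML estimation by average information with EM fallback
#'
#' Maximizes the restricted log-likelihood over the variance components
#' of the design.  Updates use the average-information (AI) algorithm on
#' transformed parameters (log variances; log-Cholesky for the
#' unstructured additive covariance); iterations fall back to an EM step
#' whenever the AI step is not uphill or leaves the parameter space.
#' Convergence requires both the log-likelihood change and the maximum
#' relative parameter change to fall below `tol`.
#'
#' @param d an `hblup_design` from [build_design()].
#' @param nrm_inv relationship inverse ([relmat()], role `"Ainv"` or
#'   `"Hinv"`).
#' @param start optional starting [variance_components()].
#' @param control list: `max_iter` (default 200), `tol_ll` (1e-6),
#'   `tol_par` (1e-6), `n_em` (number of initial EM steps, default 2),
#'   `verbose`.
#' @return An object of class `hblup_fit`; see [hblup()] for the
#'   components and available methods.
#' @export
reml_fit <- function(d, nrm_inv, start = NULL, control = list()) {
  ctl <- utils::modifyList(list(max_iter = 200L, tol_ll = 1e-6,
                                tol_par = 1e-6, n_em = 2L,
                                verbose = FALSE), control)
  pre <- mme_precompute(d, nrm_inv)
  vc <- if (is.null(start)) default_start(d) else start
  floor <- 1e-8 * stats::var(d$y)
  state <- mme_solve(d, pre, vc)
  ll <- state$loglik
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    stats <- mme_inv_stats(d, pre, state)
    der <- reml_derivatives(d, pre, vc, state, stats)
    par <- pack_par(vc, d)
    vc_new <- NULL
    step_type <- "EM"
    if (iter > ctl$n_em) {
      J <- par_jacobian(par, vc)
      g_t <- drop(t(J) %*% der$g)
      AI_t <- t(J) %*% der$AI %*% J
      # active set: freeze parameters pinned at the variance floor (or
      # the correlation restraint) whose gradient points outward, so the
      # Newton step is taken in the free subspace only
      free <- !pinned_par(vc, g_t, floor)
      step <- rep(0, length(par))
      sol_f <- tryCatch(
        solve(AI_t[free, free, drop = FALSE] +
                diag(1e-8, sum(free)), g_t[free]),
        error = function(e) NULL)
      if (!is.null(sol_f) && all(is.finite(sol_f))) {
        step[free] <- sol_f
        # cap the transformed-scale step to keep candidates well inside
        # the numerically stable region
        step <- step * min(1, 2 / max(abs(step)))
        sc <- 1
        for (h in 1:6) {
          cand <- unpack_par(par + sc * step, vc)
          cand <- floor_vc(cand, floor)
          st_cand <- tryCatch(mme_solve(d, pre, cand),
                              error = function(e) NULL)
          if (!is.null(st_cand) && is.finite(st_cand$loglik) &&
              st_cand$loglik >= ll - 1e-8) {
            vc_new <- cand; state_new <- st_cand
            step_type <- sprintf("AI/%g", sc)
            break
          }
          sc <- sc / 2
        }
      }
    }
    if (is.null(vc_new)) {   # EM step (guaranteed uphill)
      vc_new <- floor_vc(em_update(d, pre, vc, state, stats, der, floor),
                         floor)
      state_new <- mme_solve(d, pre, vc_new)
    }
    dll <- state_new$loglik - ll
    dpar <- max(abs(nat_par(vc_new) - nat_par(vc)) /
                  (abs(nat_par(vc)) + floor))
    if (ctl$verbose)
      message(sprintf("iter %3d  logLik %.6f  dll %.2e  dpar %.2e  [%s]",
                      iter, state_new$loglik, dll, dpar, step_type))
    vc <- vc_new; state <- state_new; ll <- state$loglik
    if (abs(dll) < ctl$tol_ll && dpar < ctl$tol_par) {
      converged <- TRUE
      break
    }
    if (iter >= ctl$max_iter) break
  }
  if (!converged)
    warning("REML did not converge in ", ctl$max_iter, " iterations")
  # final exact-PEV statistics
  stats <- mme_inv_stats(d, pre, state, need_srec = FALSE, final = TRUE)
  finish_fit(d, pre, vc, state, stats, converged, iter)
}

# transformed parameters held at a boundary with an outward gradient
pinned_par <- function(vc, g_t, floor, max_corr = 0.995) {
  r <- nrow(vc$Sigma_a)
  iv <- vech_idx(r)
  nS <- nrow(iv)
  pin <- logical(nS + length(unlist(vc$iid)) + length(vc$residual))
  corr <- stats::cov2cor(vc$Sigma_a)
  for (k in seq_len(nS)) {
    a <- iv[k, 1L]; b <- iv[k, 2L]
    if (a == b) {
      pin[k] <- vc$Sigma_a[a, a] <= floor * 1.01 && g_t[k] < 0
    } else {
      pin[k] <- abs(corr[a, b]) >= max_corr - 1e-4 &&
        sign(corr[a, b]) * g_t[k] > 0
    }
  }
  v <- c(unlist(vc$iid), vc$residual)
  pin[nS + seq_along(v)] <- v <= floor * 1.01 & g_t[nS + seq_along(v)] < 0
  pin
}

# natural-scale parameter vector for convergence checks
nat_par <- function(vc) {
  c(vc$Sigma_a[vech_idx(nrow(vc$Sigma_a))], unlist(vc$iid), vc$residual)
}

floor_vc <- function(vc, floor, max_corr = 0.995) {
  for (nm in names(vc$iid)) vc$iid[[nm]] <- pmax(vc$iid[[nm]], floor)
  vc$residual <- pmax(vc$residual, floor)
  dn <- dimnames(vc$Sigma_a)
  dg <- pmax(diag(vc$Sigma_a), floor)
  r <- length(dg)
  if (r > 1) {
    # restrain correlations away from the +/-1 boundary (where the
    # additive covariance is singular and the likelihood surface is a
    # flat ridge), as REML software routinely does
    C <- stats::cov2cor(vc$Sigma_a + diag(pmax(floor - diag(vc$Sigma_a), 0),
                                          r))
    C[C > max_corr] <- max_corr
    C[C < -max_corr] <- -max_corr
    diag(C) <- 1
    e <- eigen(C, symmetric = TRUE)
    if (min(e$values) < 1e-6) {
      C <- e$vectors %*% diag(pmax(e$values, 1e-6), r) %*% t(e$vectors)
      C <- stats::cov2cor(C)
    }
    vc$Sigma_a <- diag(sqrt(dg), r) %*% C %*% diag(sqrt(dg), r)
  } else {
    vc$Sigma_a <- matrix(dg, 1, 1)
  }
  dimnames(vc$Sigma_a) <- dn
  vc
}

finish_fit <- function(d, pre, vc, state, stats, converged, iter) {
  dimnames(vc$Sigma_a) <- list(d$regions, d$regions)
  names(vc$residual) <- d$res_names
  for (nm in names(vc$iid))
    names(vc$iid[[nm]]) <- d$terms[[nm]]$group_names
  add <- d$terms$additive
  r <- add$r; nid <- add$nid
  a0 <- pre$offs[["additive"]] - pre$p
  pev <- matrix(stats$diagC[a0 + seq_len(nid * r)], nid, r)
  ebv <- matrix(state$u$additive, nid, r)
  s2a <- diag(vc$Sigma_a)
  acc <- vapply(seq_len(r), function(s)
    compute_pev_accuracy(pev[, s], s2a[s], warn = FALSE), numeric(nid))
  acc <- matrix(acc, nid, r)
  ebv_df <- data.frame(
    id = rep(add$ids, r),
    region = rep(d$regions, each = nid),
    ebv = as.numeric(ebv),
    pev = as.numeric(pev),
    accuracy = as.numeric(acc),
    stringsAsFactors = FALSE
  )
  k <- length(pack_par(vc, d))
  beta <- stats::setNames(state$b, colnames(d$X))
  beta_se <- sqrt(pmax(stats$diagX, 0))
  u <- state$u
  for (nm in names(u)) names(u[[nm]]) <- d$terms[[nm]]$levels
  corr <- stats::cov2cor(vc$Sigma_a)
  structure(list(
    vc = vc, r_a = corr, beta = beta, beta_se = beta_se,
    assign = d$assign, u = u, ebv = ebv_df,
    loglik = state$loglik, n_vc = k, aic = model_aic(state$loglik, k),
    converged = converged, n_iter = iter,
    fitted = d$y - state$ehat, residuals = state$ehat,
    design = d[c("response", "n", "regions", "res_names",
                 "region_structure")],
    meta = d$meta
  ), class = "hblup_fit")
}

#' Breeding value accuracy from prediction error variance
#'
#' `r_i = sqrt(1 - PEV_i / sigma2_a)`, clipped to \[0, 1\] (with a warning
#' when any PEV exceeds the additive variance).
#'
#' @param pev numeric vector of prediction error variances.
#' @param sigma2_a additive genetic variance (must be positive).
#' @param warn warn when clipping occurs.
#' @return Numeric vector of accuracies.
#' @export
compute_pev_accuracy <- function(pev, sigma2_a, warn = TRUE) {
  if (sigma2_a <= 0) stop("sigma2_a must be positive")
  ratio <- pev / sigma2_a
  if (warn && any(ratio > 1 + 1e-8))
    warning("PEV exceeds sigma2_a for ", sum(ratio > 1), " individual(s);",
            " accuracy clipped to 0")
  sqrt(pmin(pmax(1 - ratio, 0), 1))
}

#' Akaike information criterion for a REML fit
#'
#' `AIC = -2 logLik + 2 k` with `k` the number of free variance
#' parameters.  Comparable only across fits with identical fixed
#' effects, since REML likelihoods condition on the fixed-effect design.
#'
#' @param loglik REML log-likelihood.
#' @param k number of free variance parameters.
#' @return AIC value.
#' @export
model_aic <- function(loglik, k) -2 * loglik + 2 * k
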