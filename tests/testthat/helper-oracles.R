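# Independent oracles used across the suite.  All are deliberately
# naive (recursive / dense / Monte-Carlo) implementations kept separate
# from the package's algorithms.

# recursive coancestry (kinship); f(i,i) = (1 + F_i)/2
kinship_oracle <- function(ped) {
  idx <- hblup:::match_parents(ped)
  n <- nrow(ped)
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste0(i, ",", j)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + f(idx$sire[i], idx$dam[i]))
    } else {
      # j is not an ancestor of i when j > i in topological order
      0.5 * (f(i, idx$sire[j]) + f(i, idx$dam[j]))
    }
    memo[[key]] <- v
    v
  }
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) K[i, j] <- K[j, i] <- f(i, j)
  dimnames(K) <- list(ped$id, ped$id)
  K
}

A_oracle <- function(ped) 2 * kinship_oracle(ped)

# random pedigree: founders then offspring with parents drawn from
# earlier individuals (possibly unknown)
random_pedigree <- function(n, n_founders = max(4L, n %/% 5L),
                            p_unknown = 0.1, races = c("R1", "R2")) {
  id <- sprintf("I%03d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    pool <- id[seq_len(i - 1L)]
    if (stats::runif(1) > p_unknown) sire[i] <- sample(pool, 1L)
    if (stats::runif(1) > p_unknown) dam[i] <- sample(pool, 1L)
    if (!is.na(sire[i]) && !is.na(dam[i]) && sire[i] == dam[i])
      dam[i] <- NA
  }
  race <- rep(NA_character_, n)
  race[seq_len(n_founders)] <- sample(races, n_founders, replace = TRUE)
  pedigree(id, sire, dam, race)
}

# dense-V GLS/BLUP oracle for the mixed model y = Xb + sum Z_t u_t + e
dense_blup_oracle <- function(y, X, Zs, Gs, Rmat) {
  V <- Rmat
  for (k in seq_along(Zs)) V <- V + Zs[[k]] %*% Gs[[k]] %*% t(Zs[[k]])
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  b <- solve(XVX, t(X) %*% Vi %*% y)
  resid <- y - X %*% b
  u <- lapply(seq_along(Zs), function(k)
    as.numeric(Gs[[k]] %*% t(Zs[[k]]) %*% Vi %*% resid))
  P <- Vi - Vi %*% X %*% solve(XVX) %*% t(X) %*% Vi
  ll <- -0.5 * (as.numeric(determinant(V, TRUE)$modulus) +
                  as.numeric(determinant(XVX, TRUE)$modulus) +
                  as.numeric(t(y) %*% P %*% y))
  list(b = as.numeric(b), u = u, loglik = ll)
}

# Monte-Carlo race-origin gene dropping: expected founder-race fractions
race_fraction_mc <- function(ped, n_drop = 2000L) {
  idx <- hblup:::match_parents(ped)
  founder <- is_founder(ped)
  races <- sort(unique(stats::na.omit(ped$race[founder])))
  groups <- c(races, "UNKNOWN_RACE")
  n <- nrow(ped)
  acc <- matrix(0, n, length(groups), dimnames = list(ped$id, groups))
  for (b in seq_len(n_drop)) {
    lab <- character(n)
    for (i in seq_len(n)) {
      if (founder[i]) {
        lab[i] <- if (is.na(ped$race[i])) "UNKNOWN_RACE" else ped$race[i]
      } else {
        pick <- if (stats::runif(1) < 0.5) idx$sire[i] else idx$dam[i]
        lab[i] <- if (pick == 0L) "UNKNOWN_RACE" else lab[pick]
      }
    }
    acc[cbind(seq_len(n), match(lab, groups))] <-
      acc[cbind(seq_len(n), match(lab, groups))] + 1
  }
  acc / n_drop
}

# small full-sib phenotype table generated straight from a design's
# matrices (model-matched data for engine checks)
simulate_from_design <- function(d, ped, Sigma_a, iid_vars, resid_var,
                                 mu = 10) {
  A <- as.matrix(build_A_tabular(ped)$values)
  G <- kronecker(Sigma_a, A)
  u <- drop(t(chol(G)) %*% stats::rnorm(nrow(G)))
  y <- mu + as.numeric(d$terms$additive$Z %*% u)
  for (nm in names(iid_vars)) {
    if (is.null(d$terms[[nm]])) next
    q <- ncol(d$terms[[nm]]$Z)
    y <- y + as.numeric(d$terms[[nm]]$Z %*%
                          stats::rnorm(q, 0, sqrt(iid_vars[[nm]])))
  }
  y + stats::rnorm(length(y), 0, sqrt(resid_var))
}

# compact full-sib trial layout for engine tests
toy_trial_pheno <- function(ped, prog_ids, trials, reps = 3, plot_size = 3,
                            iblocks = 3) {
  rows <- list()
  fams <- split(prog_ids, sub("_.*$", "", prog_ids))
  per_trial <- reps * plot_size
  for (fid in names(fams)) {
    kids <- fams[[fid]]
    used <- 0L
    for (t in seq_len(nrow(trials))) {
      take <- min(per_trial, length(kids) - used)
      if (take <= 0) break
      kk <- kids[used + seq_len(take)]; used <- used + take
      rp <- rep(seq_len(reps), each = plot_size)[seq_len(take)]
      rows[[length(rows) + 1L]] <- data.frame(
        tree_id = kk, program = "P", trial = trials$trial[t],
        region = trials$region[t], replicate = rp,
        iblock = ((seq_along(kk) + t) %% iblocks) + 1L,
        plot = paste0(fid, ".R", rp), entry_type = "full-sib",
        checklot_id = NA_character_, VOL = 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pedigree of full-sib families for engine tests: returns ped + progeny
# ids named by family ("F<k>_<j>")
fullsib_pedigree <- function(n_founders, n_fam, n_prog) {
  fnd <- sprintf("P%02d", seq_len(n_founders))
  pairs <- t(replicate(n_fam, sample(fnd, 2L)))
  prog <- unlist(lapply(seq_len(n_fam), function(k)
    sprintf("F%02d_%02d", k, seq_len(n_prog))))
  ped <- pedigree(
    id = c(fnd, prog),
    sire = c(rep(NA, n_founders), rep(pairs[, 1L], each = n_prog)),
    dam = c(rep(NA, n_founders), rep(pairs[, 2L], each = n_prog)),
    race = "R1")
  list(ped = ped, founders = fnd, progeny = prog)
}
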