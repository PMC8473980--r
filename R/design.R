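#' Build the mixed-model design for an individual-tree analysis
#'
#' Translates a phenotype table into the fixed and random design of the
#' individual-tree model: fixed overall mean, replicate-within-trial
#' contrasts, checklot effects and (optionally) founder-race fraction
#' covariates; random additive effects over every pedigree individual
#' (linked to the numerator relationship matrix supplied at fitting
#' time), full-sib family (SCA) effects keyed by the unordered parent
#' pair, open-pollinated family means (kept out of the additive
#' variance), and incomplete-block and row-plot effects nested in trial.
#'
#' Under `region_structure = "unstructured"` each individual carries one
#' additive effect per region with an unstructured region-by-region
#' additive covariance; every record links to its trial's region.
#'
#' @param ph phenotype data frame with columns `tree_id`, `trial`,
#'   `region`, `replicate`, `iblock`, `plot`, `entry_type`
#'   (`"full-sib"`, `"half-sib"` or `"checklot"`), `checklot_id` and the
#'   response column.
#' @param response name of the trait column.
#' @param ped the [pedigree()] providing the additive-effect id universe
#'   and the parent pairs defining full-sib families.
#' @param Q optional [group_fraction_matrix()] output; when supplied the
#'   race-fraction columns (reference race dropped) are appended to X.
#' @param region_structure `"none"` (single additive variance) or
#'   `"unstructured"` (region-specific variances and correlations).
#' @param family_term,op_term,iblock_term,plot_term logicals switching
#'   the corresponding random terms.
#' @param family_groups `"single"`, `"region"` or `"trial_group"`:
#'   grouping of the family (SCA) variance.
#' @param trial_groups optional named character vector mapping trial to a
#'   trial group (used when `family_groups = "trial_group"`).
#' @return An `hblup_design` object used by [reml_fit()] and
#'   [solve_mme()].
#' @export
build_design <- function(ph, response, ped, Q = NULL,
                         region_structure = c("none", "unstructured"),
                         family_term = TRUE, op_term = TRUE,
                         iblock_term = TRUE, plot_term = TRUE,
                         family_groups = NULL, trial_groups = NULL) {
  region_structure <- match.arg(region_structure)
  need <- c("tree_id", "trial", "region", "replicate", "iblock", "plot",
            "entry_type", response)
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table lacks column(s): ", paste(miss, collapse = ", "))
  ph <- ph[!is.na(ph[[response]]), , drop = FALSE]
  n <- nrow(ph)
  if (!n) stop("no non-missing records for response '", response, "'")
  ped <- ensure_sorted(ped)
  pidx <- match(ph$tree_id, ped$id)
  pedigreed <- ph$entry_type != "checklot"
  if (any(pedigreed & is.na(pidx)))
    stop("phenotyped tree(s) not in pedigree: ",
         paste(utils::head(unique(ph$tree_id[pedigreed & is.na(pidx)]), 5),
               collapse = ", "))
  y <- as.numeric(ph[[response]])

  ## ---- fixed effects -------------------------------------------------
  blocks <- list(intercept = matrix(1, n, 1,
                                    dimnames = list(NULL, "(Intercept)")))
  trialrep <- interaction(ph$trial, ph$replicate, drop = TRUE, sep = ":")
  if (nlevels(trialrep) > 1) {
    Xtr <- stats::model.matrix(~ 0 + trialrep)[, -1L, drop = FALSE]
    colnames(Xtr) <- paste0("trialrep.", levels(trialrep)[-1L])
    blocks$trialrep <- Xtr
  }
  if (any(!pedigreed)) {
    ck <- factor(ifelse(pedigreed, "none",
                        as.character(ph$checklot_id)))
    ck <- stats::relevel(ck, ref = "none")
    Xck <- stats::model.matrix(~ 0 + ck)[, -1L, drop = FALSE]
    colnames(Xck) <- sub("^ck", "checklot.", colnames(Xck))
    blocks$checklot <- Xck
  }
  if (!is.null(Q)) {
    qi <- match(ph$tree_id, Q$ids)
    Xq <- matrix(0, n, length(Q$groups),
                 dimnames = list(NULL, paste0("race.", Q$groups)))
    ok <- !is.na(qi) & pedigreed
    Xq[ok, ] <- Q$values[qi[ok], , drop = FALSE]
    ref <- which.max(colSums(Xq))
    blocks$race <- Xq[, -ref, drop = FALSE]
  }
  X <- do.call(cbind, blocks)
  assign <- rep(names(blocks), vapply(blocks, ncol, 1L))
  nz <- colSums(abs(X)) > 0
  X <- X[, nz, drop = FALSE]; assign <- assign[nz]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("fixed-effect design is rank deficient; confounded column(s): ",
         paste(dropped, collapse = ", "))
  }

  ## ---- random terms --------------------------------------------------
  regions <- if (region_structure == "unstructured")
    sort(unique(as.character(ph$region))) else "(all)"
  r <- length(regions)
  rec_region <- if (r > 1) match(as.character(ph$region), regions)
    else rep(1L, n)
  terms <- list()

  # additive: levels = region-major (region outer, pedigree id inner)
  nid <- nrow(ped)
  add_levels <- as.vector(outer(ped$id, regions,
                                function(i, g) paste(g, i, sep = "/")))
  fs <- pedigreed & ph$entry_type == "full-sib"
  arec <- which(fs)
  if (length(arec)) {
    Za <- Matrix::sparseMatrix(
      i = arec, j = (rec_region[arec] - 1L) * nid + pidx[arec],
      x = 1, dims = c(n, nid * r))
  } else Za <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                    dims = c(n, nid * r))
  terms$additive <- list(name = "additive", type = "nrm", Z = Za,
                         levels = add_levels, ids = ped$id,
                         regions = regions, r = r, nid = nid)

  # full-sib family (SCA): unordered parent pair
  if (family_term && any(fs)) {
    sire <- ped$sire[pidx]; dam <- ped$dam[pidx]
    both <- fs & !is.na(sire) & !is.na(dam)
    famkey <- rep(NA_character_, n)
    famkey[both] <- paste(pmin(sire[both], dam[both]),
                          pmax(sire[both], dam[both]), sep = "x")
    if (is.null(family_groups))
      family_groups <- if (r > 1) "region" else "single"
    fg <- switch(family_groups,
      single = rep("fam", n),
      region = as.character(ph$region),
      trial_group = {
        if (is.null(trial_groups))
          stop("family_groups='trial_group' needs a trial_groups map")
        unname(trial_groups[as.character(ph$trial)])
      },
      stop("unknown family_groups: ", family_groups))
    famlev <- ifelse(is.na(famkey), NA, paste(fg, famkey, sep = "/"))
    f <- factor(famlev)
    if (nlevels(f) > 0) {
      kr <- which(!is.na(famlev))
      Zf <- Matrix::sparseMatrix(i = kr, j = as.integer(f[kr]), x = 1,
                                 dims = c(n, nlevels(f)))
      lev_group <- sub("/.*$", "", levels(f))
      terms$family <- list(name = "family", type = "iid", Z = Zf,
                           levels = levels(f),
                           group = match(lev_group, unique(lev_group)),
                           group_names = unique(lev_group))
    }
  }

  # open-pollinated family means (half-sib records; outside sigma2_a)
  hs <- pedigreed & ph$entry_type == "half-sib"
  if (op_term && any(hs)) {
    par1 <- ifelse(is.na(ped$dam[pidx]), ped$sire[pidx], ped$dam[pidx])
    opkey <- ifelse(hs, paste0("OP:", par1), NA)
    f <- factor(opkey)
    kr <- which(!is.na(opkey))
    Zo <- Matrix::sparseMatrix(i = kr, j = as.integer(f[kr]), x = 1,
                               dims = c(n, nlevels(f)))
    terms$opfamily <- list(name = "opfamily", type = "iid", Z = Zo,
                           levels = levels(f),
                           group = rep(1L, nlevels(f)),
                           group_names = "opfamily")
  }

  trial_nested <- function(what, col) {
    key <- interaction(ph$trial, ph$replicate, col, drop = TRUE, sep = ":")
    Zb <- Matrix::sparseMatrix(i = seq_len(n), j = as.integer(key), x = 1,
                               dims = c(n, nlevels(key)))
    lev_trial <- sub(":.*$", "", levels(key))
    trials <- sort(unique(as.character(ph$trial)))
    list(name = what, type = "iid", Z = Zb, levels = levels(key),
         group = match(lev_trial, trials), group_names = trials)
  }
  if (iblock_term) terms$iblock <- trial_nested("iblock", ph$iblock)
  if (plot_term)
    terms$plot <- trial_nested("plot",
                               interaction(ph$iblock, ph$plot, sep = "."))

  trials <- sort(unique(as.character(ph$trial)))
  structure(list(
    y = y, X = X, assign = assign, terms = terms,
    res_group = match(as.character(ph$trial), trials),
    res_names = trials, n = n, response = response,
    regions = regions, region_structure = region_structure,
    meta = data.frame(tree_id = ph$tree_id, trial = as.character(ph$trial),
                      region = as.character(ph$region),
                      entry_type = as.character(ph$entry_type),
                      stringsAsFactors = FALSE)
  ), class = "hblup_design")
}

#' @export
print.hblup_design <- function(x, ...) {
  cat("Mixed-model design:", x$n, "records,", ncol(x$X), "fixed columns\n")
  cat("Random terms:",
      paste(vapply(x$terms, function(t)
        sprintf("%s[%d]", t$name, ncol(t$Z)), ""), collapse = ", "), "\n")
  cat("Residual groups (trials):", length(x$res_names), "\n")
  if (length(x$regions) > 1)
    cat("Regions (unstructured additive):",
        paste(x$regions, collapse = ", "), "\n")
  invisible(x)
}
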