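## Two-stage analysis flow: single-site adjustment, per-trial
## standardization, multi-region fits, and the scenario comparator
## (ABLUP with/without race groups, within-program and joint HBLUP).

#' Single-site adjustment of a trial
#'
#' Fits the individual-tree model to one trial (fixed mean, replicates
#' and checklots, plus race fractions when `Q` is given; random
#' additive, family, incomplete-block and row-plot effects with the
#' pedigree A-inverse) and returns trait values adjusted for the design
#' effects: `y_adj = y - replicate effect - iblock BLUP - plot BLUP`,
#' together with the trial's additive variance estimate.
#'
#' @param ph phenotype table (may span several trials).
#' @param trial trial id to adjust.
#' @param ped the [pedigree()].
#' @param Q optional [group_fraction_matrix()] output (race groups).
#' @param response trait column (default `"VOL"`).
#' @param control passed to [reml_fit()].
#' @return List with `data` (the trial's rows plus `<response>_adj`),
#'   `sigma2_a`, and the underlying `fit`.
#' @export
single_site_adjust <- function(ph, trial, ped, Q = NULL, response = "VOL",
                               control = list()) {
  rows <- ph$trial == trial
  if (!any(rows)) stop("no records for trial ", trial)
  phs <- ph[rows, , drop = FALSE]
  if (length(unique(phs$replicate)) < 2) {
    warning("trial ", trial,
            " has a single replicate; replicate effect dropped")
    phs$replicate <- 1L
  }
  d <- build_design(phs, response, ped, Q = Q, region_structure = "none")
  Ainv <- build_A_inverse(ped)
  fit <- reml_fit(d, Ainv, control = control)
  repcols <- which(d$assign == "trialrep")
  rep_eff <- if (length(repcols))
    as.numeric(d$X[, repcols, drop = FALSE] %*% fit$beta[repcols]) else 0
  blup_eff <- numeric(d$n)
  for (nm in intersect(c("iblock", "plot"), names(d$terms)))
    blup_eff <- blup_eff + as.numeric(d$terms[[nm]]$Z %*% fit$u[[nm]])
  keep <- !is.na(phs[[response]])
  adj <- rep(NA_real_, nrow(phs))
  adj[keep] <- phs[[response]][keep] - rep_eff - blup_eff
  phs[[paste0(response, "_adj")]] <- adj
  list(data = phs, sigma2_a = unname(diag(fit$vc$Sigma_a)[1L]), fit = fit)
}

#' Standardize adjusted values by trial
#'
#' Centers each trial's adjusted values to mean zero and scales them to
#' an additive standard deviation of one using the trial's
#' single-site additive variance estimate.  Trials whose additive
#' variance collapsed to the floor are excluded with a warning.
#'
#' @param adjusted data frame holding the adjusted values.
#' @param sigma2_a_by_trial named numeric vector of per-trial additive
#'   variances.
#' @param column name of the adjusted-value column.
#' @param min_sigma2 exclusion threshold for collapsed additive
#'   variances.
#' @return The table with a `<column>_std` column, floor-variance trials
#'   removed.
#' @export
standardize_by_trial <- function(adjusted, sigma2_a_by_trial,
                                 column = "VOL_adj", min_sigma2 = 1e-6) {
  bad <- names(sigma2_a_by_trial)[sigma2_a_by_trial < min_sigma2]
  if (length(bad)) {
    warning("trial(s) excluded (additive variance at floor): ",
            paste(bad, collapse = ", "))
    adjusted <- adjusted[!adjusted$trial %in% bad, , drop = FALSE]
  }
  out <- paste0(column, "_std")
  adjusted[[out]] <- NA_real_
  for (tr in unique(adjusted$trial)) {
    rows <- adjusted$trial == tr & !is.na(adjusted[[column]])
    v <- adjusted[[column]][rows]
    adjusted[[out]][rows] <- (v - mean(v)) /
      sqrt(sigma2_a_by_trial[[as.character(tr)]])
  }
  adjusted
}

#' Run the two-stage adjustment over all trials
#'
#' Convenience driver for the literal two-stage flow: single-site
#' adjustment of every trial followed by per-trial standardization.
#'
#' @inheritParams single_site_adjust
#' @return List with `data` (all rows, `<response>_adj` and
#'   `<response>_adj_std` columns) and `sigma2_a` (named per-trial
#'   vector).
#' @export
adjust_and_standardize <- function(ph, ped, Q = NULL, response = "VOL",
                                   control = list()) {
  trials <- unique(as.character(ph$trial))
  parts <- lapply(trials, function(tr)
    single_site_adjust(ph, tr, ped, Q = Q, response = response,
                       control = control))
  s2a <- stats::setNames(vapply(parts, `[[`, 0, "sigma2_a"), trials)
  all <- do.call(rbind, lapply(parts, `[[`, "data"))
  list(data = standardize_by_trial(all, s2a,
                                   column = paste0(response, "_adj")),
       sigma2_a = s2a)
}

#' Multi-region REML fit
#'
#' Fits the cross-site model with region-specific additive variances and
#' unstructured inter-region correlations; trial-specific
#' incomplete-block, plot and residual variances are retained.  Regions
#' absent from the data are simply not part of the covariance structure
#' and are reported `NA` downstream.
#'
#' @inheritParams hblup
#' @return An `hblup_fit`.
#' @export
fit_multiregion <- function(ph, ped, response = "VOL", genotypes = NULL,
                            races = FALSE, start = NULL, control = list()) {
  hblup(ph, ped, response = response, genotypes = genotypes,
        races = races, region_structure = "unstructured",
        start = start, control = control)
}

#' Heritability, dominance proportion and additive CV
#'
#' Regional mode: `h2 = sigma2_a(region) / (sigma2_a(region) +
#' sigma2_f(region) + mean_k(sigma2_bk + sigma2_pk + sigma2_ek))` over
#' the region's trials, and `d2 = 4 sigma2_f(region)` over the same
#' denominator.  Cross-site mode pools all trials and uses the
#' record-weighted mean family variance across groups.  `CVa = 100
#' sigma_a / mean(trait)` is reported when a trait mean is supplied
#' (it is meaningless on standardized data).
#'
#' @param fit an `hblup_fit`.
#' @param mode `"regional"` (default when the fit is multi-region) or
#'   `"xsite"`.
#' @param trait_mean optional trait mean for the CVa.
#' @return Data frame with one row per region (or one `xsite` row):
#'   h2, d2 and optionally CVa.
#' @export
heritability_dominance <- function(fit, mode = NULL, trait_mean = NULL) {
  stopifnot(inherits(fit, "hblup_fit"))
  vc <- fit$vc
  regions <- colnames(vc$Sigma_a)
  if (is.null(mode))
    mode <- if (length(regions) > 1) "regional" else "xsite"
  meta <- fit$meta
  trial_region <- unique(meta[, c("trial", "region")])
  env_of <- function(trials) {
    tr <- as.character(trials)
    env <- numeric(length(tr))
    for (nm in c("iblock", "plot")) {
      if (!is.null(vc$iid[[nm]])) {
        v <- vc$iid[[nm]][tr]
        env <- env + ifelse(is.na(v), 0, v)
      }
    }
    env + vc$residual[tr]
  }
  fam_var <- function(region) {
    if (is.null(vc$iid$family)) return(0)
    fv <- vc$iid$family
    if (region %in% names(fv)) return(unname(fv[region]))
    # pooled / single-group: record-weighted mean across groups
    grp <- names(fv)
    w <- vapply(grp, function(g) sum(meta$region == g), 0)
    if (all(w == 0)) w <- rep(1, length(fv))
    sum(fv * w) / sum(w)
  }
  if (mode == "regional") {
    rows <- lapply(regions, function(rg) {
      trials <- trial_region$trial[trial_region$region == rg]
      if (!length(trials)) return(NULL)
      s2a <- vc$Sigma_a[rg, rg]
      s2f <- fam_var(rg)
      denom <- s2a + s2f + mean(env_of(trials))
      if (denom <= 0) stop("zero denominator in heritability")
      data.frame(region = rg, sigma2_a = s2a, sigma2_f = s2f,
                 h2 = s2a / denom, d2 = 4 * s2f / denom,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  } else {
    s2a <- mean(diag(vc$Sigma_a))
    fv <- if (is.null(vc$iid$family)) 0 else {
      grp <- names(vc$iid$family)
      w <- vapply(grp, function(g)
        sum(meta$region == g) + sum(meta$trial == g), 0)
      if (all(w == 0)) w <- rep(1, length(grp))
      sum(vc$iid$family * w) / sum(w)
    }
    trials <- unique(as.character(meta$trial))
    denom <- s2a + fv + mean(env_of(trials))
    if (denom <= 0) stop("zero denominator in heritability")
    out <- data.frame(region = "xsite", sigma2_a = s2a, sigma2_f = fv,
                      h2 = s2a / denom, d2 = 4 * fv / denom,
                      stringsAsFactors = FALSE)
  }
  if (!is.null(trait_mean))
    out$CVa <- 100 * sqrt(out$sigma2_a) / trait_mean
  rownames(out) <- NULL
  out
}

# ancestral closure of a set of ids
pedigree_subset <- function(ped, ids) {
  keep <- ped$id %in% ids
  repeat {
    par <- unique(stats::na.omit(c(ped$sire[keep], ped$dam[keep])))
    new <- ped$id %in% par & !keep
    if (!any(new)) break
    keep <- keep | new
  }
  out <- ped[keep, , drop = FALSE]
  class(out) <- c("pedigree", "data.frame")
  attr(out, "sorted") <- attr(ped, "sorted")
  out
}

#' Classify individuals for accuracy reporting
#'
#' Deterministic classes used to compare breeding-value accuracy across
#' models, for a given target region: `parents_represented` (parents
#' with progeny records in the region), `parents_correlated` (parents
#' whose progeny were evaluated only in other regions),
#' `genotyped_related` / `genotyped_unrelated` (genotyped individuals
#' without progeny, with/without a pedigree link), and `progeny`
#' (phenotyped trees with records in the region).
#'
#' @param ped the [pedigree()].
#' @param ph the phenotype table defining which trees have records.
#' @param genotyped character vector of genotyped ids.
#' @param region target region.
#' @return Data frame with columns `id` and `class`.
#' @export
accuracy_classes <- function(ped, ph, genotyped, region) {
  ph <- ph[ph$entry_type != "checklot", , drop = FALSE]
  prog_ids <- unique(ph$tree_id)
  pidx <- match(prog_ids, ped$id)
  par_of <- rbind(
    data.frame(parent = ped$sire[pidx], tree = prog_ids,
               stringsAsFactors = FALSE),
    data.frame(parent = ped$dam[pidx], tree = prog_ids,
               stringsAsFactors = FALSE))
  par_of <- par_of[!is.na(par_of$parent), , drop = FALSE]
  tree_region <- split(ph$region, ph$tree_id)
  in_region <- vapply(par_of$tree, function(t)
    region %in% tree_region[[t]], TRUE)
  parents <- unique(par_of$parent)
  rep_par <- unique(par_of$parent[in_region])
  cor_par <- setdiff(parents, rep_par)
  gen_nonpar <- setdiff(intersect(genotyped, ped$id), parents)
  gidx <- match(gen_nonpar, ped$id)
  linked <- !is.na(ped$sire[gidx]) | !is.na(ped$dam[gidx])
  progeny <- unique(ph$tree_id[ph$region == region])
  blk <- function(ids, cls) {
    if (!length(ids)) return(NULL)
    data.frame(id = ids, class = cls, stringsAsFactors = FALSE)
  }
  out <- rbind(
    blk(rep_par, "parents_represented"),
    blk(cor_par, "parents_correlated"),
    blk(gen_nonpar[linked], "genotyped_related"),
    blk(gen_nonpar[!linked], "genotyped_unrelated"),
    blk(progeny, "progeny"))
  if (is.null(out))
    return(data.frame(id = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  out[!duplicated(out$id), , drop = FALSE]
}

# mean accuracy with SE of the mean per class, from a fit
class_accuracy <- function(fit, classes, region) {
  e <- fit$ebv[fit$ebv$region == region, , drop = FALSE]
  acc <- e$accuracy[match(classes$id, e$id)]
  ok <- !is.na(acc)
  agg <- split(acc[ok], classes$class[ok])
  do.call(rbind, lapply(names(agg), function(cl) {
    v <- agg[[cl]]
    data.frame(region = region, class = cl, n = length(v),
               mean_accuracy = mean(v),
               se = stats::sd(v) / sqrt(length(v)),
               stringsAsFactors = FALSE)
  }))
}

#' Compare ABLUP and HBLUP evaluation scenarios
#'
#' Runs the model set on identical phenotype rows: ABLUP with race
#' genetic groups (benchmark), ABLUP without groups, within-program
#' HBLUP, and (when requested) the joint HBLUP across programs.  Each
#' within-program comparison uses that program's data and ancestral
#' pedigree; the joint scenario pools everything through the joint H.
#'
#' @param ph phenotype table covering one or more programs (column
#'   `program`).
#' @param ped joint [pedigree()].
#' @param genotypes [marker_matrix()] of the genotyped subset (QC'd or
#'   raw); an empty/`NULL` value degrades HBLUP to ABLUP without
#'   groups.
#' @param response trait column.
#' @param scenarios subset of
#'   `c("ablup_race", "ablup_norace", "hblup", "hblup_joint")`.
#' @param control passed to [reml_fit()].
#' @return A `scenario_comparison`: list with `fits` (per program and
#'   joint), `summary` (per scenario/program/region: sigma2_a, h2, d2,
#'   AIC, logLik) and `accuracy` (per-class mean accuracies with SEs).
#' @export
scenario_compare <- function(ph, ped, genotypes = NULL, response = "VOL",
                             scenarios = c("ablup_race", "ablup_norace",
                                           "hblup", "hblup_joint"),
                             control = list()) {
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  programs <- sort(unique(as.character(ph$program)))
  gids_all <- if (is.null(genotypes)) character(0) else genotypes$ids
  fits <- list(); summaries <- list(); acc <- list()
  run_one <- function(ph_s, ped_s, gt, races, label, program) {
    fit <- hblup(ph_s, ped_s, response = response, genotypes = gt,
                 races = races, region_structure = "unstructured",
                 control = control)
    hd <- heritability_dominance(fit, mode = "regional")
    hd$scenario <- label; hd$program <- program
    hd$aic <- fit$aic; hd$loglik <- fit$loglik
    gids <- if (is.null(gt)) character(0) else gt$ids
    ac <- do.call(rbind, lapply(unique(hd$region), function(rg) {
      cls <- accuracy_classes(ped_s, ph_s, gids, rg)
      class_accuracy(fit, cls, rg)
    }))
    if (!is.null(ac)) { ac$scenario <- label; ac$program <- program }
    list(fit = fit, hd = hd, ac = ac)
  }
  subset_genotypes <- function(ids) {
    if (is.null(genotypes)) return(NULL)
    keep <- genotypes$ids %in% ids
    if (!any(keep)) return(NULL)
    mm <- genotypes
    mm$scores <- mm$scores[keep, , drop = FALSE]
    mm$ids <- mm$ids[keep]
    mm
  }
  for (p in programs) {
    ph_p <- ph[ph$program == p, , drop = FALSE]
    ped_p <- pedigree_subset(ped, unique(
      ph_p$tree_id[ph_p$entry_type != "checklot"]))
    # genotyped individuals of the program (incl. unpedigreed selections)
    pg <- union(ped_p$id, ped$id[ped$program == p])
    ped_p <- pedigree_subset(ped, union(ped_p$id, intersect(gids_all, pg)))
    gt_p <- subset_genotypes(ped_p$id)
    for (sc in intersect(scenarios,
                         c("ablup_race", "ablup_norace", "hblup"))) {
      res <- run_one(ph_p, ped_p,
                     gt = if (sc == "hblup") gt_p else NULL,
                     races = sc == "ablup_race",
                     label = sc, program = p)
      fits[[paste(p, sc, sep = ".")]] <- res$fit
      summaries[[paste(p, sc, sep = ".")]] <- res$hd
      acc[[paste(p, sc, sep = ".")]] <- res$ac
    }
  }
  if ("hblup_joint" %in% scenarios) {
    if (length(programs) < 2)
      warning("joint scenario requested with a single program")
    bridging <- length(programs) < 2 ||
      all(vapply(programs, function(p)
        any(gids_all %in% ped$id[ped$program == p]), TRUE))
    if (!bridging)
      warning("programs disconnected; joint EBVs not comparable ",
              "(no genotypes bridge the programs)")
    res <- run_one(ph, ped, gt = subset_genotypes(ped$id), races = FALSE,
                   label = "hblup_joint", program = "JOINT")
    fits$hblup_joint <- res$fit
    summaries$hblup_joint <- res$hd
    # joint accuracies evaluated per program's class definitions
    acc$hblup_joint <- do.call(rbind, lapply(programs, function(p) {
      ph_p <- ph[ph$program == p, , drop = FALSE]
      regs <- unique(as.character(ph$region))
      a <- do.call(rbind, lapply(regs, function(rg) {
        cls <- accuracy_classes(ped, ph_p, gids_all, rg)
        cls <- cls[cls$id %in% ped$id[ped$program == p] |
                     cls$id %in% ph_p$tree_id, , drop = FALSE]
        class_accuracy(res$fit, cls, rg)
      }))
      if (!is.null(a)) { a$scenario <- "hblup_joint"; a$program <- p }
      a
    }))
  }
  structure(list(
    fits = fits,
    summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
    accuracy = do.call(rbind, c(acc, list(make.row.names = FALSE)))
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison (", length(x$fits), " fits)\n", sep = "")
  cat("\nGenetic parameters by scenario:\n")
  print(x$summary[, c("scenario", "program", "region", "sigma2_a",
                      "h2", "d2", "aic")], digits = 4)
  cat("\nMean accuracy by class (head):\n")
  print(utils::head(x$accuracy, 12), digits = 3)
  invisible(x)
}

#' Write scenario comparison tables as TSV
#'
#' @param x a `scenario_comparison`.
#' @param dir output directory (created if needed).
#' @export
write_scenario_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$summary, file.path(dir, "genetic_parameters.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$accuracy, file.path(dir, "accuracy_by_class.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
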