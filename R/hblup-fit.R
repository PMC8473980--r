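#' Fit a pedigree or single-step genomic BLUP model
#'
#' Central fitting function.  Builds the relationship machinery for the
#' requested evaluation — pedigree A-inverse for ABLUP, or the
#' single-step H-inverse (pedigree plus tuned and blended genomic
#' relationships) for HBLUP — constructs the individual-tree design and
#' estimates variance components by AI-REML, returning breeding values
#' with exact prediction error variances and accuracies.
#'
#' The model fits a fixed overall mean, replicate-within-trial and
#' checklot effects (plus founder-race fraction covariates when
#' `races = TRUE`), random additive effects with the chosen numerator
#' relationship matrix (region-specific variances and unstructured
#' inter-region correlations under `region_structure = "unstructured"`),
#' full-sib family (SCA) effects, open-pollinated family means, and
#' incomplete-block and row-plot effects nested in trials, with one
#' residual variance per trial.
#'
#' @param ph phenotype data frame (see [build_design()] for the required
#'   columns).
#' @param ped a [pedigree()] covering all pedigreed phenotyped trees.
#' @param response trait column name (default `"VOL"`).
#' @param genotypes optional [marker_matrix()] for the genotyped subset
#'   (raw scores are QC-filtered automatically); when supplied the fit
#'   is single-step (HBLUP), otherwise pedigree-only (ABLUP).
#' @param races include founder-race genetic groups as fixed
#'   fraction covariates (default `FALSE`).
#' @param region_structure `"unstructured"` (default) or `"none"`.
#' @param blend_weight genomic weight for [blend_G()] (default 0.95).
#' @param maf_threshold MAF threshold if `genotypes` is raw.
#' @param start,control passed to [reml_fit()].
#' @return An object of class `hblup_fit` with components `vc`
#'   (variance components), `r_a` (inter-region additive correlations),
#'   `beta`/`beta_se` (fixed effects), `ebv` (data frame id, region,
#'   ebv, pev, accuracy), `loglik`, `aic`, `converged`, `n_iter`.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `logLik`, `plot`.
#' @examples
#' cfg <- sim_config(n_founders = c(EG1 = 20), generations = 2,
#'                   families_per_gen = 8, progeny_per_family = 6,
#'                   trials = data.frame(program = "EG1", region = "WA",
#'                                       n_trials = 1),
#'                   n_markers = 200)
#' sim <- simulate_breeding_data(cfg, seed = 1)
#' fit <- hblup(sim$phenotypes, sim$pedigree, region_structure = "none",
#'              control = list(max_iter = 20))
#' summary(fit)
#' @export
hblup <- function(ph, ped, response = "VOL", genotypes = NULL,
                  races = FALSE,
                  region_structure = c("unstructured", "none"),
                  blend_weight = 0.95, maf_threshold = 0.05,
                  start = NULL, control = list()) {
  region_structure <- match.arg(region_structure)
  ped <- ensure_sorted(ped)
  Ainv <- build_A_inverse(ped)
  if (!is.null(genotypes)) {
    stopifnot(inherits(genotypes, "marker_matrix"))
    if (length(genotypes$ids)) {
      if (is.null(genotypes$freq))
        genotypes <- qc_filter(genotypes, maf_threshold)
      gids <- intersect(ped$id, genotypes$ids)
      if (!length(gids))
        stop("no genotyped individual appears in the pedigree")
      mm <- genotypes
      keep <- match(gids, mm$ids)
      mm$scores <- mm$scores[keep, , drop = FALSE]
      mm$ids <- gids
      G <- compute_G_vanraden1(mm)
      A22 <- build_A_tabular(ped, subset = gids)
      A22$role <- "A22"
      Gw <- blend_G(tune_G(G, A22)$Ga, A22, w = blend_weight)
      nrm_inv <- build_H_inverse(Ainv, Gw, A22, gids)
    } else nrm_inv <- Ainv   # empty genotype set: H = A
  } else nrm_inv <- Ainv
  Q <- if (races) group_fraction_matrix(ped) else NULL
  d <- build_design(ph, response, ped, Q = Q,
                    region_structure = region_structure)
  fit <- reml_fit(d, nrm_inv, start = start, control = control)
  fit$nrm <- if (is.null(genotypes) || !length(genotypes$ids)) "A" else "H"
  fit$races <- races
  fit$call <- match.call()
  fit
}

#' Extract estimated breeding values
#'
#' @param object an `hblup_fit`.
#' @param ids optional id subset.
#' @param region optional region subset.
#' @return Data frame with id, region, ebv, pev, accuracy.
#' @export
ebv <- function(object, ids = NULL, region = NULL) {
  stopifnot(inherits(object, "hblup_fit"))
  out <- object$ebv
  if (!is.null(ids)) out <- out[out$id %in% ids, , drop = FALSE]
  if (!is.null(region)) out <- out[out$region %in% region, , drop = FALSE]
  out
}

#' @export
print.hblup_fit <- function(x, ...) {
  cat("Single-step genetic evaluation (", x$nrm, "BLUP",
      if (isTRUE(x$races)) " + race groups" else "", ")\n", sep = "")
  cat(sprintf("  %d records, response '%s'; logLik %.2f, AIC %.2f%s\n",
              x$design$n, x$design$response, x$loglik, x$aic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("  additive variance(s):",
      paste(sprintf("%s=%.4g", colnames(x$vc$Sigma_a),
                    diag(x$vc$Sigma_a)), collapse = ", "), "\n")
  if (nrow(x$r_a) > 1) {
    cat("  inter-region additive correlations:\n")
    print(round(x$r_a, 3))
  }
  invisible(x)
}

#' @export
summary.hblup_fit <- function(object, ...) {
  hd <- tryCatch(heritability_dominance(object), error = function(e) NULL)
  structure(list(fit = object, hd = hd), class = "summary.hblup_fit")
}

#' @export
print.summary.hblup_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  cat("\nVariance components:\n")
  print(f$vc)
  if (!is.null(x$hd)) {
    cat("\nHeritability and dominance proportion:\n")
    print(x$hd, digits = 3)
  }
  cat(sprintf("\nConverged: %s in %d iterations (%d variance parameters)\n",
              f$converged, f$n_iter, f$n_vc))
  invisible(x)
}

#' @export
coef.hblup_fit <- function(object, ...) object$beta

#' @export
fitted.hblup_fit <- function(object, ...) object$fitted

#' @export
residuals.hblup_fit <- function(object, ...) object$residuals

#' @export
logLik.hblup_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_vc, nobs = object$design$n,
            class = "logLik")
}

#' Predict breeding values for individuals
#'
#' Returns estimated breeding values (with PEV and accuracy) for the
#' requested individuals and regions; individuals without records or
#' relatives shrink to zero with accuracy near zero.
#'
#' @param object an `hblup_fit`.
#' @param newdata optional data frame with columns `id` and optionally
#'   `region`; default: all individuals, all regions.
#' @param ... unused.
#' @export
predict.hblup_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$ebv)
  reg <- if ("region" %in% names(newdata)) newdata$region else NULL
  key_fit <- paste(object$ebv$id, object$ebv$region, sep = "\r")
  if (is.null(reg)) {
    out <- object$ebv[object$ebv$id %in% newdata$id, , drop = FALSE]
  } else {
    key <- paste(newdata$id, reg, sep = "\r")
    out <- object$ebv[match(key, key_fit), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Serialize a fit: EBV table and variance-component report
#'
#' `write_fit_tsv()` writes one row per individual and region (id,
#' region, ebv, pev, accuracy); `write_fit_json()` writes the variance
#' components, correlations, likelihood and convergence information.
#'
#' @param fit an `hblup_fit`.
#' @param path output file.
#' @export
write_fit_tsv <- function(fit, path) {
  utils::write.table(fit$ebv, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_fit_tsv
#' @export
write_fit_json <- function(fit, path) {
  vc <- fit$vc
  jsonlite::write_json(list(
    Sigma_a = unclass(vc$Sigma_a), r_a = unclass(fit$r_a),
    iid = vc$iid, residual = as.list(vc$residual),
    loglik = fit$loglik, aic = fit$aic, n_vc = fit$n_vc,
    converged = fit$converged, n_iter = fit$n_iter),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @export
plot.hblup_fit <- function(x, which = c("accuracy", "residuals"), ...) {
  which <- match.arg(which)
  if (which == "residuals") {
    graphics::plot(x$fitted, x$residuals, xlab = "Fitted",
                   ylab = "Residual", pch = 20, col = "#00000044", ...)
    graphics::abline(h = 0, lty = 2)
  } else {
    acc <- split(x$ebv$accuracy, x$ebv$region)
    graphics::boxplot(acc, ylab = "EBV accuracy", xlab = "Region", ...)
  }
  invisible(x)
}
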