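test_that("design construction follows the model contract", {
  p <- pedigree(id = c("S", "D", "E", "X", "Y", "W", "Z"),
                sire = c(NA, NA, NA, "S", "D", "S", NA),
                dam = c(NA, NA, NA, "D", "S", "E", "E"),
                race = c("STRZ", "FURNX", "STRZ", NA, NA, NA, NA))
  ph <- data.frame(
    tree_id = c("X", "Y", "W", "Z", "CKT1"),
    program = "P", trial = "T1", region = "WA",
    replicate = c(1, 2, 1, 1, 2), iblock = 1, plot = 1:5,
    entry_type = c("full-sib", "full-sib", "full-sib", "half-sib",
                   "checklot"),
    checklot_id = c(NA, NA, NA, NA, "CK1"), VOL = rnorm(5))
  Q <- group_fraction_matrix(p)
  d <- build_design(ph, "VOL", p, Q = Q, region_structure = "none")
  # mean + 1 rep contrast + 1 checklot + (groups - 1) race columns
  expect_equal(sum(d$assign == "intercept"), 1L)
  expect_equal(sum(d$assign == "trialrep"), 1L)
  expect_equal(sum(d$assign == "checklot"), 1L)
  expect_equal(sum(d$assign == "race"), length(Q$groups) - 1L)
  # family key is the unordered parent pair: (S,D) and (D,S) collapse
  expect_equal(ncol(d$terms$family$Z), 2L)   # {S,D} and {S,E}
  # half-sib record feeds the OP family term, not the additive term
  expect_equal(ncol(d$terms$opfamily$Z), 1L)
  expect_equal(sum(d$terms$additive$Z[4, ]), 0)
  expect_equal(sum(d$terms$additive$Z[5, ]), 0)  # checklot: no pedigree
  # unknown phenotyped tree is an error
  ph_bad <- ph; ph_bad$tree_id[1] <- "GHOST"
  expect_error(build_design(ph_bad, "VOL", p), "not in pedigree")
})

test_that("MME solutions equal the dense GLS/BLUP oracle", {
  set.seed(61)
  fs <- fullsib_pedigree(n_founders = 10, n_fam = 12, n_prog = 18)
  trials <- data.frame(trial = c("T1", "T2"), region = c("WA", "WA"))
  ph <- toy_trial_pheno(fs$ped, fs$progeny, trials)
  ph$VOL <- rnorm(nrow(ph), 10)
  d <- build_design(ph, "VOL", fs$ped, region_structure = "none")
  vc <- variance_components(d, sigma2_a = 1.3, family = 0.4,
                            iblock = 0.25, plot = 0.3,
                            residual = c(2.5, 3.5))
  Ainv <- build_A_inverse(fs$ped)
  sol <- solve_mme(d, vc, Ainv)
  A <- as.matrix(build_A_tabular(fs$ped)$values)
  Zs <- c(list(as.matrix(d$terms$additive$Z)),
          lapply(c("family", "iblock", "plot"),
                 function(nm) as.matrix(d$terms[[nm]]$Z)))
  Gs <- list(1.3 * A,
             diag(0.4, ncol(Zs[[2]])), diag(0.25, ncol(Zs[[3]])),
             diag(0.3, ncol(Zs[[4]])))
  Rm <- diag(vc$residual[d$res_group])
  or <- dense_blup_oracle(ph$VOL, d$X, Zs, Gs, Rm)
  expect_lt(max(abs(sol$b - or$b)), 1e-8)
  expect_lt(max(abs(sol$u$additive - or$u[[1]])), 1e-8)
  expect_lt(max(abs(sol$u$plot - or$u[[4]])), 1e-8)
  expect_equal(sol$loglik, or$loglik, tolerance = 1e-8)
  # doubling all variances leaves solutions unchanged (ratio invariance)
  vc2 <- variance_components(d, sigma2_a = 2.6, family = 0.8,
                             iblock = 0.5, plot = 0.6,
                             residual = c(5, 7))
  sol2 <- solve_mme(d, vc2, Ainv)
  expect_lt(max(abs(sol2$b - sol$b)), 1e-8)
  expect_lt(max(abs(sol2$u$additive - sol$u$additive)), 1e-8)
})

test_that("fixed effects approach ordinary least squares as random terms vanish", {
  set.seed(62)
  fs <- fullsib_pedigree(n_founders = 8, n_fam = 6, n_prog = 5)
  trials <- data.frame(trial = "T1", region = "WA")
  ph <- toy_trial_pheno(fs$ped, fs$progeny, trials)
  ph$VOL <- rnorm(nrow(ph), 5)
  d <- build_design(ph, "VOL", fs$ped, region_structure = "none",
                    family_term = FALSE, iblock_term = FALSE,
                    plot_term = FALSE)
  vc <- variance_components(d, sigma2_a = 1e-9, residual = 1)
  sol <- solve_mme(d, vc, build_A_inverse(fs$ped))
  ols <- qr.solve(d$X, ph$VOL)
  expect_lt(max(abs(sol$b - ols)), 1e-5)
})

test_that("the REML gradient vanishes at the reported optimum", {
  set.seed(63)
  fs <- fullsib_pedigree(n_founders = 12, n_fam = 14, n_prog = 18)
  trials <- data.frame(trial = c("T1", "T2"), region = c("WA", "WA"))
  ph <- toy_trial_pheno(fs$ped, fs$progeny, trials)
  d0 <- build_design(ph, "VOL", fs$ped, region_structure = "none",
                     iblock_term = FALSE, plot_term = FALSE)
  ph$VOL <- simulate_from_design(d0, fs$ped, matrix(1), list(family = 0.3),
                                 3)
  d <- build_design(ph, "VOL", fs$ped, region_structure = "none",
                    iblock_term = FALSE, plot_term = FALSE)
  Ainv <- build_A_inverse(fs$ped)
  fit <- reml_fit(d, Ainv)
  expect_true(fit$converged)
  # central finite differences of the log-likelihood on the transformed
  # scale at the optimum
  vc <- fit$vc
  pre <- hblup:::mme_precompute(d, Ainv)
  par <- hblup:::pack_par(vc, d)
  h <- 1e-4
  for (k in seq_along(par)) {
    pp <- par; pp[k] <- pp[k] + h
    pm <- par; pm[k] <- pm[k] - h
    gnum <- (hblup:::mme_solve(d, pre, hblup:::unpack_par(pp, vc))$loglik -
               hblup:::mme_solve(d, pre, hblup:::unpack_par(pm, vc))$loglik) /
      (2 * h)
    expect_lt(abs(gnum), 1e-3)
  }
})

test_that("REML recovers simple variance components and floors null ones", {
  set.seed(64)
  fs <- fullsib_pedigree(n_founders = 12, n_fam = 24, n_prog = 8)
  trials <- data.frame(trial = "T1", region = "WA")
  ph <- toy_trial_pheno(fs$ped, fs$progeny, trials, reps = 4,
                        plot_size = 2)
  d0 <- build_design(ph, "VOL", fs$ped, region_structure = "none",
                     iblock_term = FALSE, plot_term = FALSE)
  Ainv <- build_A_inverse(fs$ped)
  est <- replicate(6, {
    ph$VOL <- simulate_from_design(d0, fs$ped, matrix(1),
                                   list(family = 0), 3)
    dd <- build_design(ph, "VOL", fs$ped, region_structure = "none",
                       iblock_term = FALSE, plot_term = FALSE)
    fit <- reml_fit(dd, Ainv)
    c(diag(fit$vc$Sigma_a), fit$vc$iid$family, fit$vc$residual)
  })
  mc_se <- apply(est, 1, sd) / sqrt(ncol(est))
  expect_lt(abs(mean(est[1, ]) - 1), 3 * mc_se[1] + 0.05)
  expect_lt(abs(mean(est[3, ]) - 3), 3 * mc_se[3] + 0.1)
  # a null family variance is a boundary parameter: REML puts it at the
  # floor in about half the replicates and near zero otherwise
  expect_gte(mean(est[2, ] < 1e-4), 1 / 3)
  expect_lt(mean(est[2, ]), 0.15)
})

test_that("accuracy follows the PEV formula and its limits", {
  expect_equal(compute_pev_accuracy(0, 1), 1)
  expect_equal(compute_pev_accuracy(1, 1), 0)
  expect_equal(compute_pev_accuracy(0.75, 1), 0.5)
  expect_error(compute_pev_accuracy(0.5, 0), "positive")
  expect_warning(a <- compute_pev_accuracy(1.2, 1), "clipped")
  expect_equal(a, 0)
  # monotone non-increasing in PEV
  pev <- seq(0, 1, by = 0.1)
  expect_true(all(diff(compute_pev_accuracy(pev, 1)) <= 0))
})

test_that("individuals without records or relatives shrink to zero", {
  set.seed(65)
  fs <- fullsib_pedigree(n_founders = 10, n_fam = 8, n_prog = 5)
  # add an unlinked individual
  extra <- data.frame(id = "LONER", sire = NA, dam = NA, race = "R1",
                      program = "P1", stringsAsFactors = FALSE)
  ped <- pedigree(c(fs$ped$id, "LONER"), c(fs$ped$sire, NA),
                  c(fs$ped$dam, NA), c(fs$ped$race, "R1"))
  trials <- data.frame(trial = "T1", region = "WA")
  ph <- toy_trial_pheno(ped, fs$progeny, trials)
  d0 <- build_design(ph, "VOL", ped, region_structure = "none",
                     iblock_term = FALSE, plot_term = FALSE)
  ph$VOL <- simulate_from_design(d0, ped, matrix(1), list(family = 0.2), 3)
  fit <- hblup(ph, ped, region_structure = "none")
  le <- ebv(fit, ids = "LONER")
  expect_equal(le$ebv, 0, tolerance = 1e-10)
  expect_equal(le$accuracy, 0, tolerance = 1e-6)
  expect_equal(le$pev, diag(fit$vc$Sigma_a)[1], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("AIC uses the variance-parameter count and is monotone in loglik", {
  expect_equal(model_aic(-100, 3), 206)
  expect_equal(model_aic(-50, 0), 100)
  expect_lt(model_aic(-99, 3), model_aic(-100, 3))
})
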