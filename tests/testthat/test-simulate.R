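test_that("Balding-Nichols race frequencies have the expected moments", {
  cfg <- sim_config(n_markers = 10000, races = c("RA", "RB"),
                    fst = c(0.12, 0.05))
  al <- simulate_founder_alleles(cfg, seed = 3)
  p <- al$ancestral
  for (r in c(RA = 0.12, RB = 0.05)) NULL
  # variance of race frequency around ancestral ~ p(1-p) Fst
  for (rr in list(c("RA", 0.12), c("RB", 0.05))) {
    dev2 <- (al$race_freq[, rr[1]] - p)^2
    ratio <- mean(dev2) / mean(p * (1 - p) * as.numeric(rr[2]))
    expect_equal(ratio, 1, tolerance = 0.1)
  }
  # Fst -> 0 degenerates to the ancestral frequencies
  cfg0 <- sim_config(n_markers = 50, races = "RA", fst = 0)
  al0 <- simulate_founder_alleles(cfg0, seed = 3)
  expect_equal(unname(al0$race_freq[, "RA"]), al0$ancestral)
  # landrace mixtures are weighted averages of source races
  cfgm <- sim_config(n_markers = 100, races = c("RA", "RB", "LMIX"),
                     fst = 0.1,
                     landrace_mixtures = list(LMIX = c(RA = 3, RB = 1)))
  alm <- simulate_founder_alleles(cfgm, seed = 4)
  expect_equal(alm$race_freq[, "LMIX"],
               0.75 * alm$race_freq[, "RA"] + 0.25 * alm$race_freq[, "RB"],
               tolerance = 1e-12)
})

test_that("founders of the same race share a genomic uplift", {
  cfg <- sim_config(n_markers = 2000, races = c("RA", "RB"), fst = 0.15)
  ped <- pedigree(id = sprintf("F%02d", 1:30),
                  race = rep(c("RA", "RB"), each = 15))
  al <- simulate_founder_alleles(cfg, seed = 5)
  mm <- gene_drop(ped, al$race_freq, seed = 5)
  G <- as.matrix(compute_G_vanraden1(qc_filter(mm, 0.05)))
  same <- outer(ped$race, ped$race, "==") & upper.tri(G)
  diff <- !outer(ped$race, ped$race, "==") & upper.tri(G)
  expect_gt(mean(G[same]), mean(G[diff]))
})

test_that("program pedigrees respect sharing and census configuration", {
  cfg <- sim_config(n_founders = c(EG1 = 20, EG2 = 15), shared_founders = 0,
                    generations = 2, families_per_gen = 10,
                    parents_per_gen = 10, op_families = 2, plot_size = 2,
                    reps = 2, n_markers = 20,
                    n_unpedigreed = c(EG1 = 0, EG2 = 0))
  sim <- simulate_breeding_programs(cfg, seed = 6)
  ped <- sim$pedigree
  A <- as.matrix(build_A_tabular(ped)$values)
  e1 <- ped$program == "EG1"; e2 <- ped$program == "EG2"
  expect_equal(max(A[e1, e2]), 0)   # fully disconnected
  cfg4 <- cfg; cfg4$shared_founders <- 4
  sim4 <- simulate_breeding_programs(cfg4, seed = 6)
  A4 <- as.matrix(build_A_tabular(sim4$pedigree)$values)
  ids4 <- sim4$pedigree$id
  prog_of <- function(id) sub(":.*$", "", id)
  # EG1 founders now have EG2 descendants: nonzero cross-program values
  g1 <- startsWith(ids4, "EG1:G"); g2 <- startsWith(ids4, "EG2:G")
  expect_gt(max(A4[g1, g2]), 0)
  expect_length(sim4$shared, 4L)
  # generation census matches configuration
  fam <- sim$families
  expect_equal(sum(fam$generation == 1), 2L * 2L)    # 2 OP per program
  expect_equal(sum(fam$generation == 2), 10L * 2L)
  expect_equal(sum(startsWith(ped$id, "EG1:G2_")),
               10L * cfg$progeny_per_family)
  # impossible family count errors out
  cfg_bad <- cfg; cfg_bad$families_per_gen <- 1000
  expect_error(simulate_breeding_programs(cfg_bad, seed = 6),
               "exceed possible")
})

test_that("gene dropping obeys Mendelian inheritance", {
  ped <- pedigree(id = c("S", "D", "X"), sire = c(NA, NA, "S"),
                  dam = c(NA, NA, "D"), race = "RA")
  mk <- function(m) {
    colnames(m) <- sprintf("m%03d", seq_len(ncol(m)))
    marker_matrix(m)
  }
  founder_scores <- mk(rbind(S = rep(c(0, 2, 1), each = 20),
                             D = rep(c(0, 0, 1), each = 20)))
  mm <- gene_drop(ped, founder_scores = founder_scores, seed = 7)
  sc <- mm$scores
  # parents 0 x 0 -> offspring 0; 2 x 0 -> offspring 1
  expect_true(all(sc["X", 1:20] == 0))
  expect_true(all(sc["X", 21:40] == 1))
  # het x het -> 0/1/2 in proportions 1/4, 1/2, 1/4 over many drops
  ped2 <- pedigree(id = c("S", "D", sprintf("K%04d", 1:8000)),
                   sire = c(NA, NA, rep("S", 8000)),
                   dam = c(NA, NA, rep("D", 8000)), race = "RA")
  fs2 <- mk(rbind(S = rep(1, 3), D = rep(1, 3)))
  mm2 <- gene_drop(ped2, founder_scores = fs2, seed = 8)
  tab <- table(factor(mm2$scores[-(1:2), 1], levels = 0:2)) / 8000
  expect_equal(as.numeric(tab), c(0.25, 0.5, 0.25), tolerance = 0.03)
})

test_that("pedigree-error injection corrupts, logs, and stays acyclic", {
  set.seed(9)
  fs <- fullsib_pedigree(n_founders = 30, n_fam = 100, n_prog = 10)
  out0 <- inject_pedigree_errors(fs$ped, rate = 0, seed = 10)
  expect_identical(out0$pedigree$sire, fs$ped$sire)
  expect_equal(nrow(out0$errors), 0L)
  out <- inject_pedigree_errors(fs$ped, rate = 0.05, seed = 10)
  n_swap <- nrow(out$errors)
  # ~5% of the 1000 non-founders, binomial spread
  expect_gt(n_swap, 25); expect_lt(n_swap, 80)
  expect_true(all(out$errors$true_sire != out$errors$false_sire))
  # every logged swap is present in the corrupted pedigree
  for (k in head(seq_len(n_swap), 10)) {
    i <- match(out$errors$id[k], out$pedigree$id)
    expect_equal(out$pedigree$sire[i], out$errors$false_sire[k])
  }
  expect_true(isTRUE(attr(out$pedigree, "sorted")))
})

test_that("the full generator is reproducible and internally consistent", {
  cfg <- sim_config(n_founders = c(EG1 = 15, EG2 = 12), generations = 2,
                    families_per_gen = 8, parents_per_gen = 10,
                    op_families = 2, plot_size = 2, reps = 2,
                    n_markers = 80, checklot_trees = 4,
                    n_unpedigreed = c(EG1 = 2, EG2 = 1),
                    genotyped_nonparents = 3)
  s1 <- simulate_breeding_data(cfg, seed = 11)
  s2 <- simulate_breeding_data(cfg, seed = 11)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$genotypes$scores, s2$genotypes$scores)
  expect_identical(s1$pedigree, s2$pedigree)
  s3 <- simulate_breeding_data(cfg, seed = 12)
  expect_false(identical(s1$phenotypes$VOL, s3$phenotypes$VOL))
  # every phenotyped pedigreed tree exists in the pedigree; each tree in
  # exactly one trial
  ph <- s1$phenotypes
  pedigreed <- ph$entry_type != "checklot"
  expect_true(all(ph$tree_id[pedigreed] %in% s1$pedigree$id))
  expect_true(all(tapply(ph$trial, ph$tree_id, function(x)
    length(unique(x))) == 1))
  # truth log covers every simulated individual
  expect_setequal(rownames(s1$truth$bv$VOL), s1$drop_pedigree$id)
  # noise-free limit: phenotype = trial mean + breeding value
  cfg0 <- cfg
  cfg0$traits <- list(VOL = list(sigma2_a = 1, r_a = 0.7, sigma2_f = 0,
                                 sigma2_b = 0, sigma2_p = 0, sigma2_e = 0))
  s0 <- simulate_breeding_data(cfg0, seed = 13)
  ph0 <- s0$phenotypes[s0$phenotypes$entry_type == "full-sib", ]
  B <- s0$truth$bv$VOL
  tm <- setNames(s0$truth$trials$mean, s0$truth$trials$trial)
  g <- B[cbind(match(ph0$tree_id, rownames(B)),
               match(ph0$region, cfg0$regions))]
  expect_equal(ph0$VOL, unname(tm[ph0$trial] + g), tolerance = 1e-10)
})

test_that("simulated breeding values match their configured moments", {
  cfg <- sim_config(n_founders = c(EG1 = 150), programs = "EG1",
                    generations = 1, op_families = 0, n_markers = 20,
                    n_unpedigreed = c(EG1 = 0), sigma2_race = 0,
                    trials = data.frame(program = "EG1", region = "WA",
                                        n_trials = 1),
                    traits = list(VOL = list(sigma2_a = 2, r_a = 0.6,
                                             sigma2_f = 0.1, sigma2_b = 0.1,
                                             sigma2_p = 0.1, sigma2_e = 1)))
  sim <- simulate_breeding_data(cfg, seed = 14)
  B <- sim$truth$bv$VOL
  fo <- sim$true_pedigree$id[is_founder(sim$true_pedigree)]
  v <- apply(B[fo, ], 2, var)
  # realized founder BV variance within MC spread of sigma2_a = 2
  expect_true(all(abs(v - 2) < 3 * 2 * sqrt(2 / (length(fo) - 1))))
  cr <- cor(B[fo, "WA"], B[fo, "GT"])
  expect_equal(cr, 0.6, tolerance = 3 * (1 - 0.6^2) / sqrt(length(fo)))
})

test_that("datasets round-trip through the file dialects", {
  cfg <- sim_config(n_founders = c(EG1 = 12, EG2 = 10), generations = 2,
                    families_per_gen = 5, parents_per_gen = 8,
                    op_families = 1, plot_size = 2, reps = 2,
                    n_markers = 40, checklot_trees = 4,
                    n_unpedigreed = c(EG1 = 1, EG2 = 1),
                    genotyped_nonparents = 2)
  sim <- simulate_breeding_data(cfg, seed = 15)
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  p1 <- read.csv(file.path(dir, "pedigree.csv"),
                 colClasses = "character")
  # ids are already namespaced; re-read without re-prefixing
  ped2 <- pedigree(p1$id, ifelse(p1$sire == "0", NA, p1$sire),
                   ifelse(p1$dam == "0", NA, p1$dam), p1$race, p1$program)
  expect_setequal(ped2$id, sim$pedigree$id)
  g2 <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_setequal(g2$ids, sim$genotypes$ids)
  expect_equal(unname(g2$scores[sim$genotypes$ids, ]),
               unname(sim$genotypes$scores))
  cfg2 <- sim_config_from_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg2$n_markers, cfg$n_markers)
  expect_equal(cfg2$families_per_gen, cfg$families_per_gen)
})
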