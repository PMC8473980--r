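make_geno_files <- function(dir) {
  tsv <- file.path(dir, "g.tsv")
  writeLines(c("id\tm1\tm2",
               "a\t0\t1",
               "b\t2\tNA",
               "c\t1\t2"), tsv)
  raw <- file.path(dir, "g.raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE m1_A m2_T",
               "f a 0 0 0 -9 0 1",
               "f b 0 0 0 -9 2 NA",
               "f c 0 0 0 -9 1 2"), raw)
  list(tsv = tsv, raw = raw)
}

test_that("genotype TSV and PLINK .raw dialects load identically", {
  files <- make_geno_files(withr::local_tempdir())
  g1 <- read_genotypes(files$tsv)
  g2 <- read_genotypes(files$raw)
  expect_equal(g1$ids, g2$ids)
  expect_equal(unname(g1$scores), unname(g2$scores))
  expect_equal(sum(is.na(g1$scores)), 1L)
  # invalid token and duplicate ids are hard errors
  bad <- file.path(withr::local_tempdir(), "bad.tsv")
  writeLines(c("id\tm1", "a\t3"), bad)
  expect_error(read_genotypes(bad), "row|token|score")
  expect_error(marker_matrix(matrix(0, 2, 1, dimnames = list(c("a", "a"), "m")),
                             ), "duplicate individual")
  expect_error(marker_matrix(matrix(0, 1, 2, dimnames = list("a", c("m", "m")))),
               "duplicate marker")
})

test_that("MAF filter and 2p imputation follow the QC contract", {
  sc <- cbind(m1 = c(rep(0, 9), 2),        # p = 0.1, kept
              m2 = rep(0, 10),             # p = 0 , removed
              m3 = c(rep(1, 9), NA))       # p = 0.5 with one missing call
  rownames(sc) <- sprintf("i%02d", 1:10)
  mm <- marker_matrix(sc)
  q <- qc_filter(mm, maf_threshold = 0.05)
  expect_setequal(q$markers, c("m1", "m3"))
  expect_equal(q$freq[q$markers == "m1"], 0.1)
  expect_equal(unname(q$scores["i10", "m3"]), 1.0)  # 2 * 0.5
  rep <- attr(q, "qc_report")
  expect_equal(rep$status[rep$marker == "m2"], "removed")
  mono <- matrix(0, 4, 1, dimnames = list(letters[1:4], "m"))
  expect_error(qc_filter(marker_matrix(mono)), "no informative")
})

test_that("a simulated panel retains about the expected marker fraction", {
  set.seed(7)
  n <- 60; m <- 2579
  p <- runif(m, 0.01, 0.5)   # some below the 5% threshold
  sc <- sapply(p, function(pp) rbinom(n, 2, pp))
  dimnames(sc) <- list(sprintf("i%02d", 1:n), sprintf("m%04d", 1:m))
  q <- qc_filter(marker_matrix(sc), 0.05)
  frac_true <- mean(p >= 0.05)   # realized frequencies wobble around p
  expect_equal(length(q$markers) / m, frac_true, tolerance = 0.05)
})

test_that("VanRaden G matches hand evaluation and a double-loop oracle", {
  # two ids, one marker, scores (0, 2): Z = (-1, 1), denominator 0.5
  mm <- marker_matrix(cbind(m1 = c(a = 0, b = 2)))
  mm$freq <- 0.5
  G <- compute_G_vanraden1(mm)
  expect_equal(as.matrix(G), matrix(c(2, -2, -2, 2), 2,
                                    dimnames = list(c("a", "b"), c("a", "b"))))
  # everyone heterozygous at p = 0.5 markers: Z = 0 so G = 0
  mh <- marker_matrix(matrix(1, 4, 6, dimnames = list(letters[1:4],
                                                      sprintf("m%d", 1:6))))
  mh$freq <- rep(0.5, 6)
  expect_true(all(as.matrix(compute_G_vanraden1(mh)) == 0))
  # random panel vs naive double loop
  set.seed(17)
  n <- 50; m <- 500
  sc <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.9), each = n)), n, m,
               dimnames = list(sprintf("i%02d", 1:n), sprintf("m%03d", 1:m)))
  q <- qc_filter(marker_matrix(sc), 0.05)
  G <- as.matrix(compute_G_vanraden1(q))
  p <- q$freq
  Gn <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    Gn[i, j] <- sum((q$scores[i, ] - 2 * p) * (q$scores[j, ] - 2 * p))
  Gn <- Gn / (2 * sum(p * (1 - p)))
  expect_lt(max(abs(G - Gn)), 1e-10)
  expect_lt(max(abs(G - t(G))), 1e-12)
  scNA <- sc; scNA[1, 1] <- NA
  expect_error(compute_G_vanraden1(marker_matrix(scNA)), "missing")
})

test_that("tuning solves the two-moment system and blending is convex", {
  # hand-solvable instance: means 1.0/0.2 vs 1.1/0.3 -> a = 0.1, b = 1.0
  ids <- c("x", "y")
  G <- relmat(matrix(c(1.0, 0.2, 0.2, 1.0), 2), ids, role = "G")
  A22 <- relmat(matrix(c(1.1, 0.3, 0.3, 1.1), 2), ids, role = "A22")
  tg <- tune_G(G, A22)
  expect_equal(unname(tg$coef), c(0.1, 1.0), tolerance = 1e-12)
  # already matched: identity solution
  t0 <- tune_G(A22, A22)
  expect_equal(unname(t0$coef), c(0, 1), tolerance = 1e-12)
  # defining moment conditions always hold on output
  set.seed(27)
  for (rep in 1:5) {
    n <- 15
    M <- crossprod(matrix(rnorm(n * n), n)) / n
    Gr <- relmat(M, sprintf("i%02d", 1:n), role = "G")
    B <- crossprod(matrix(rnorm(n * n), n)) / n + diag(0.5, n)
    A22r <- relmat(B, Gr$ids, role = "A22")
    Ga <- tune_G(Gr, A22r)$Ga
    expect_lt(abs(mean(diag(as.matrix(Ga))) - mean(diag(B))), 1e-10)
    expect_lt(abs(mean(as.matrix(Ga)) - mean(B)), 1e-10)
  }
  cG <- relmat(matrix(0.4, 2, 2), ids, role = "G")   # constant: degenerate
  expect_error(tune_G(cG, A22), "degenerate")
  # blending arithmetic and boundaries
  Ga <- relmat(matrix(c(1, 0.4, 0.4, 1), 2), ids, role = "Ga")
  A2 <- relmat(matrix(c(1, 0.2, 0.2, 1), 2), ids, role = "A22")
  Gw <- blend_G(Ga, A2, w = 0.95)
  expect_equal(as.matrix(Gw)[1, 2], 0.39, tolerance = 1e-12)
  expect_equal(as.matrix(blend_G(Ga, A2, w = 0)), as.matrix(A2),
               ignore_attr = TRUE)
  expect_equal(as.matrix(blend_G(A2, A2, w = 0.3)), as.matrix(A2),
               ignore_attr = TRUE)
  expect_error(blend_G(Ga, A2, w = 1.2), "\\[0, 1\\]")
  # mean diag of Gw lies between those of Ga and A22
  md <- sort(c(mean(diag(as.matrix(Ga))), mean(diag(as.matrix(A2)))))
  expect_gte(mean(diag(as.matrix(Gw))), md[1])
  expect_lte(mean(diag(as.matrix(Gw))), md[2])
})

test_that("gene-dropped G concentrates around pedigree expectations", {
  set.seed(37)
  fs <- fullsib_pedigree(n_founders = 12, n_fam = 8, n_prog = 4)
  cfg <- sim_config(n_markers = 5000, races = "R1", fst = 1e-9)
  al <- simulate_founder_alleles(cfg, seed = 5)
  mm <- gene_drop(fs$ped, al$race_freq, seed = 5)
  # evaluate G at the known base-population frequencies, where its
  # expectation is exactly the pedigree relationship
  mm$freq <- unname(al$race_freq[, "R1"])
  G <- as.matrix(compute_G_vanraden1(mm))
  A <- as.matrix(build_A_tabular(fs$ped))
  ii <- match(fs$ped$id, mm$ids)
  dev <- G[ii, ii] - A
  expect_lt(abs(mean(dev[upper.tri(dev)])), 0.02)
  # full-sib pairs realize ~0.5
  sib_pairs <- t(combn(match(sprintf("F01_%02d", 1:4), mm$ids), 2))
  expect_equal(mean(G[sib_pairs]), 0.5, tolerance = 0.1)
})
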