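test_that("pedigree files parse, namespace and normalize unknown parents", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,race",
               "P001,0,,STRZ",
               "P002,NA,0,FURNX",
               "X1,P001,P002,"), tmp)
  p <- read_pedigree(tmp, program = "EG1")
  expect_s3_class(p, "pedigree")
  expect_equal(nrow(p), 3L)
  expect_equal(sum(is_founder(p)), 2L)
  expect_setequal(p$id, c("EG1:P001", "EG1:P002", "EG1:X1"))
  expect_equal(p$sire[p$id == "EG1:X1"], "EG1:P001")
  # same raw ids under another program stay distinct
  p2 <- read_pedigree(tmp, program = "EG2")
  expect_length(intersect(p$id, p2$id), 0L)
})

test_that("parsing is invariant to record order and rejects duplicates", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,race",
               "X1,P001,P002,",
               "P001,0,0,STRZ",
               "P002,0,0,FURNX"), tmp)
  p <- read_pedigree(tmp, "EG1")   # offspring listed before sire
  expect_true(which(p$id == "EG1:P001") < which(p$id == "EG1:X1"))
  expect_error(pedigree(c("A", "A"), race = "R1"), "duplicate")
  # undefined parent auto-inserted as UNKNOWN_RACE founder, with warning
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,race", "X1,GHOST,0,"), tmp2)
  expect_warning(p3 <- read_pedigree(tmp2, "EG1"), "never defined")
  expect_true("EG1:GHOST" %in% p3$id)
  expect_equal(p3$race[p3$id == "EG1:GHOST"], "UNKNOWN_RACE")
})

test_that("topological sort is stable, idempotent and detects cycles", {
  n <- 10L
  chain <- pedigree(id = sprintf("C%02d", n:1),
                    sire = c(sprintf("C%02d", (n - 1):1), NA),
                    race = "R1", sort = TRUE)
  expect_equal(chain$id, sprintf("C%02d", 1:n))
  expect_equal(topo_sort_validate(chain)$id, chain$id)
  bad <- structure(data.frame(id = c("A", "B"), sire = c("B", "A"),
                              dam = NA_character_, race = NA_character_,
                              program = "P", stringsAsFactors = FALSE),
                   class = c("pedigree", "data.frame"))
  expect_error(topo_sort_validate(bad), "cycle")
})

test_that("inbreeding matches recursive-coancestry definitions", {
  fnd <- pedigree(id = c("A", "B", "C"), race = "R1")
  expect_equal(unname(inbreeding_meuwissen_luo(fnd)), rep(0, 3))
  # offspring of full sibs: F = 0.25
  p <- pedigree(id = c("A", "B", "X", "Y", "Z"),
                sire = c(NA, NA, "A", "A", "X"),
                dam = c(NA, NA, "B", "B", "Y"), race = "R1")
  expect_equal(unname(inbreeding_meuwissen_luo(p)["Z"]), 0.25)
  # offspring of parent-offspring mating: F = 0.25
  q <- pedigree(id = c("A", "B", "X", "Z"),
                sire = c(NA, NA, "A", "A"),
                dam = c(NA, NA, "B", "X"), race = "R1")
  expect_equal(unname(inbreeding_meuwissen_luo(q)["Z"]), 0.25)
  # random pedigrees vs oracle
  set.seed(11)
  for (rep in 1:5) {
    rp <- random_pedigree(60)
    K <- kinship_oracle(rp)
    expect_equal(unname(inbreeding_meuwissen_luo(rp)),
                 unname(2 * diag(K) - 1), tolerance = 1e-12)
  }
})

test_that("tabular A matches the brute-force oracle and its own inverse", {
  set.seed(21)
  fnd <- pedigree(id = sprintf("F%d", 1:4), race = "R1")
  expect_equal(as.matrix(build_A_tabular(fnd)), diag(4), ignore_attr = TRUE)
  trio <- pedigree(id = c("S", "D", "X"), sire = c(NA, NA, "S"),
                   dam = c(NA, NA, "D"), race = "R1")
  At <- as.matrix(build_A_tabular(trio))
  expect_equal(At["X", "S"], 0.5)
  expect_equal(At["X", "X"], 1.0)
  for (rep in 1:3) {
    rp <- random_pedigree(200)
    A <- as.matrix(build_A_tabular(rp))
    expect_lt(max(abs(A - A_oracle(rp))), 1e-10)
    Ainv <- as.matrix(build_A_inverse(rp)$values)
    expect_lt(max(abs(Ainv %*% A - diag(nrow(A)))), 1e-8)
    expect_equal(unname(diag(A) - 1),
                 unname(inbreeding_meuwissen_luo(rp)), tolerance = 1e-12)
  }
  # inbred pedigree (full-sib mating) exercises d_i with F > 0
  p <- pedigree(id = c("A", "B", "X", "Y", "Z", "W"),
                sire = c(NA, NA, "A", "A", "X", "Z"),
                dam = c(NA, NA, "B", "B", "Y", "X"), race = "R1")
  A <- as.matrix(build_A_tabular(p))
  Ainv <- as.matrix(build_A_inverse(p)$values)
  expect_lt(max(abs(Ainv %*% A - diag(6))), 1e-10)
})

test_that("A partitions into consistent genotyped blocks", {
  set.seed(31)
  rp <- random_pedigree(50)
  A <- build_A_tabular(rp)
  g <- sample(rp$id, 10)
  parts <- partition_A(A, g)
  expect_equal(dim(parts$A22), c(10L, 10L))
  expect_equal(as.matrix(parts$A21), t(as.matrix(parts$A12)),
               ignore_attr = TRUE)
  # reassembling the permuted blocks reproduces A
  ids <- c(parts$A11$ids, parts$A22$ids)
  R <- rbind(cbind(as.matrix(parts$A11), as.matrix(parts$A12)),
             cbind(as.matrix(parts$A21), as.matrix(parts$A22)))
  expect_equal(R, as.matrix(A)[ids, ids], ignore_attr = TRUE)
  # A22 equals a direct subset build
  expect_equal(as.matrix(parts$A22),
               as.matrix(build_A_tabular(rp, subset = parts$A22$ids)),
               ignore_attr = TRUE)
  expect_error(partition_A(A, character(0)), "empty")
  # all genotyped: A22 is A
  all_parts <- partition_A(A, rp$id)
  expect_equal(dim(all_parts$A11), c(0L, 0L))
  expect_equal(as.matrix(all_parts$A22), as.matrix(A), ignore_attr = TRUE)
})

test_that("race group fractions follow averaging rules and gene-drop expectations", {
  p <- pedigree(id = c("A", "B", "X"), sire = c(NA, NA, "A"),
                dam = c(NA, NA, "B"), race = c("STRZ", "FURNX", NA))
  Q <- group_fraction_matrix(p)
  expect_equal(Q$values["A", "STRZ"], 1)
  expect_equal(unname(Q$values["X", c("FURNX", "STRZ")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(Q$values)), rep(1, 3))
  # deeper pedigree vs Monte-Carlo gene dropping; order invariance
  set.seed(41)
  rp <- random_pedigree(40)
  Q1 <- group_fraction_matrix(rp)
  expect_equal(unname(rowSums(Q1$values)), rep(1, 40), tolerance = 1e-12)
  mc <- race_fraction_mc(rp, n_drop = 4000L)
  common <- intersect(colnames(mc), Q1$groups)
  expect_lt(max(abs(mc[, common] - Q1$values[rp$id, common])), 0.05)
  shuf <- rp[sample(nrow(rp)), ]
  class(shuf) <- c("pedigree", "data.frame")
  attr(shuf, "sorted") <- FALSE
  Q2 <- group_fraction_matrix(topo_sort_validate(shuf))
  expect_equal(Q2$values[rp$id, Q1$groups], Q1$values,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("merged program pedigrees collapse aliased founders", {
  p1 <- pedigree(c("EG1:F1", "EG1:X"), sire = c(NA, "EG1:F1"),
                 race = c("STRZ", NA), program = "EG1")
  p2 <- pedigree(c("EG2:F9", "EG2:Y"), sire = c(NA, "EG2:F9"),
                 race = c("STRZ", NA), program = "EG2")
  j <- merge_pedigrees(p1, p2,
                       aliases = data.frame(a = "EG1:F1", b = "EG2:F9"))
  expect_false("EG2:F9" %in% j$id)
  expect_equal(j$sire[j$id == "EG2:Y"], "EG1:F1")
  A <- as.matrix(build_A_tabular(j))
  expect_equal(A["EG1:X", "EG2:Y"], 0.25)
})

test_that("relationship matrices round-trip through triplet text", {
  set.seed(51)
  rp <- random_pedigree(20)
  A <- build_A_tabular(rp)
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_relmat(A, tmp, format = "triplet")
  A2 <- read_relmat_triplet(tmp, ids = A$ids)
  expect_equal(as.matrix(A2), as.matrix(A), tolerance = 1e-15,
               ignore_attr = TRUE)
})
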