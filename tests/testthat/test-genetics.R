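# Marker QC, LD pruning, relationship matrices, population PCA.

test_that("VCF writing and reading round-trip the dosage matrix", {
  set.seed(5)
  dos <- matrix(sample(c(0, 1, 2, NA), 60, replace = TRUE,
                       prob = c(0.4, 0.3, 0.25, 0.05)), nrow = 5)
  m <- toyMarkerMatrix(dos, chrom = rep(c(1L, 2L), each = 6),
                       pos = rep(c(100L, 200L, 300L, 400L, 500L, 600L), 2))
  path <- tempfile(fileext = ".vcf")
  writeVCF(m, path)
  m2 <- markerMatrixFromVCF(path)
  expect_equal(unname(dosage(m2)[hybrids(m), colnames(dosage(m))]),
               unname(dosage(m)))
  expect_equal(markerMap(m2)$pos, markerMap(m)$pos)
})

test_that("individual filtering honours the keep list and its order", {
  m <- toyMarkerMatrix(matrix(rep(c(0, 1, 2), 4), nrow = 4, byrow = TRUE))
  expect_identical(dosage(filterIndividuals(m, hybrids(m))), dosage(m))
  sub <- filterIndividuals(m, c("H03", "H01"))
  expect_identical(hybrids(sub), c("H03", "H01"))
  expect_error(filterIndividuals(m, c("H01", "nope")), "nope")
})

test_that("MAF filtering drops rare and monomorphic markers", {
  dos <- cbind(mono = c(0, 0, 0, 0), common = c(0, 1, 1, 2),
               rare = c(0, 0, 0, 1))
  m <- toyMarkerMatrix(dos)
  kept <- filterMAF(m, 0.2)
  expect_identical(colnames(dosage(kept)), "common")
  ## MAF of {0,1,1,2} is 0.5: kept at any threshold
  expect_true("common" %in% colnames(dosage(filterMAF(m, 0.5))))
  ## threshold 0 drops nothing
  expect_equal(ncol(dosage(filterMAF(m, 0))), 3L)
  expect_error(filterMAF(m, 0.7), "threshold")
})

test_that("LD pruning removes duplicates and keeps independent markers", {
  set.seed(6)
  base <- matrix(rbinom(40 * 3, 2, 0.4), nrow = 40)
  dos <- cbind(base[, 1], base[, 1], base[, 2], base[, 3])
  colnames(dos) <- sprintf("SNP_%05d", 1:4)
  m <- toyMarkerMatrix(dos)
  pruned <- ldPrune(m, window = 10, step = 2, r2 = 0.9)
  expect_equal(ncol(dosage(pruned)), 3L)
  expect_true(sum(colnames(dos)[1:2] %in% colnames(dosage(pruned))) == 1L)

  indep <- matrix(rbinom(200 * 20, 2, 0.5), nrow = 200)
  m2 <- toyMarkerMatrix(indep)
  expect_equal(ncol(dosage(ldPrune(m2, window = 10, step = 2, r2 = 0.9))),
               20L)
  m3 <- toyMarkerMatrix(indep, pos = rev(seq_len(20)))
  expect_error(ldPrune(m3), "ordering")
})

test_that("windowed pruning matches the exhaustive pairwise oracle", {
  set.seed(7)
  ## blocky structure: 300 markers in correlated blocks of 5
  n_ind <- 80
  blocks <- lapply(1:60, function(b) {
    anchor <- rbinom(n_ind, 2, runif(1, 0.2, 0.8))
    sapply(1:5, function(j) {
      flip <- rbinom(n_ind, 1, 0.03)
      pmin(2, pmax(0, ifelse(flip == 1, 2 - anchor, anchor)))
    })
  })
  dos <- do.call(cbind, blocks)
  colnames(dos) <- sprintf("SNP_%05d", seq_len(ncol(dos)))
  m <- toyMarkerMatrix(dos)
  ## window >= number of markers: identical semantics to the oracle
  pruned <- ldPrune(m, window = 400, step = 20, r2 = 0.9)
  expect_identical(colnames(dosage(pruned)), ldPruneOracle(dos, 0.9))
})

test_that("marker input order does not change the MAF survivor set", {
  st <- tinyStudy()
  m <- st@geno
  surv1 <- colnames(dosage(filterMAF(m, 0.1)))
  perm <- sample(ncol(dosage(m)))
  m2 <- methods::new("MarkerMatrix",
                     dosage = dosage(m)[, perm, drop = FALSE],
                     markers = markerMap(m)[perm, ])
  surv2 <- colnames(dosage(filterMAF(m2, 0.1)))
  expect_setequal(surv1, surv2)
})

test_that("the additive GRM matches hand computation and HWE expectation", {
  ## two individuals with contrasting homozygous genotypes at one
  ## marker with p = 0.5: Z = (-1, 1), A = ZZ' / (2 * 0.25)
  m <- toyMarkerMatrix(matrix(c(0, 2), ncol = 1))
  A <- relMatrix(grmAdditive(m))
  expect_equal(unname(A), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)

  ## large unrelated HWE panel: mean diagonal ~ 1
  set.seed(8)
  p <- runif(2000, 0.1, 0.9)
  dos <- sapply(p, function(pp) rbinom(200, 2, pp))
  hwe <- toyMarkerMatrix(dos)
  Ah <- relMatrix(grmAdditive(hwe))
  expect_lt(abs(mean(diag(Ah)) - 1), 0.05)
  ## Gram-matrix properties
  expect_equal(Ah, t(Ah), tolerance = 1e-12)
  for (i in c(1, 50)) for (j in c(100, 150))
    expect_gte(Ah[i, i] * Ah[j, j] - Ah[i, j]^2, -1e-8)
  ## monomorphic guard
  expect_error(grmAdditive(toyMarkerMatrix(cbind(c(0, 0), c(1, 2)))),
               "division guard")
})

test_that("the dominance GRM matches its coding table and brute force", {
  dos <- matrix(c(0, 1, 2,
                  2, 1, 0), nrow = 3)
  m <- toyMarkerMatrix(dos)
  D <- relMatrix(grmDominance(m))
  p <- colMeans(dos) / 2
  q <- 1 - p
  W <- sapply(1:2, function(j)
    c(`0` = -2 * p[j]^2, `1` = 2 * p[j] * q[j],
      `2` = -2 * q[j]^2)[as.character(dos[, j])])
  Dref <- W %*% t(W) / sum((2 * p * q)^2)
  expect_equal(unname(D), unname(Dref), tolerance = 1e-12)
  expect_equal(D, t(D), tolerance = 1e-12)

  ## all-homozygous marker set with p not in {0, 1}: finite D with
  ## entries built from -2p^2 / -2q^2
  dos2 <- matrix(c(0, 2, 2, 0, 0, 2), nrow = 3)
  D2 <- relMatrix(grmDominance(toyMarkerMatrix(dos2)))
  expect_true(all(is.finite(D2)))
})

test_that("the Vitezica coding is zero-mean under HWE proportions", {
  p <- 0.3; q <- 1 - p
  w <- c(-2 * p^2, 2 * p * q, -2 * q^2)
  expect_equal(sum(c(q^2, 2 * p * q, p^2) * w), 0, tolerance = 1e-12)
})

test_that("GRMs are reproducible and respect the pedigree structure", {
  st <- tinyStudy()
  g <- filterMAF(st@geno, 0.05)
  A1 <- relMatrix(grmAdditive(g))
  A2 <- relMatrix(grmAdditive(g))
  expect_identical(A1, A2)
  ped <- st@pedigree
  same <- outer(ped$Tester, ped$Tester, "==")
  diag(same) <- NA
  off <- A1[ped$Hybrid, ped$Hybrid]
  expect_gt(mean(off[same & upper.tri(off)], na.rm = TRUE),
            mean(off[!same & upper.tri(off)], na.rm = TRUE))
})

test_that("population PCA separates duplicated-genotype clusters", {
  set.seed(9)
  a <- rbinom(50, 2, 0.5); b <- rbinom(50, 2, 0.5)
  dos <- rbind(matrix(rep(a, 4), 4, byrow = TRUE),
               matrix(rep(b, 4), 4, byrow = TRUE))
  pca <- pcaPopulation(toyMarkerMatrix(dos), n_components = 3)
  pc1 <- pca$scores[, 1]
  expect_true(max(pc1[1:4]) < min(pc1[5:8]) ||
                min(pc1[1:4]) > max(pc1[5:8]))
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_lte(sum(pca$explained), 1 + 1e-12)

  ## eigen-decomposition oracle on a 10 x 50 toy
  dos2 <- matrix(rbinom(500, 2, 0.4), nrow = 10)
  pca2 <- pcaPopulation(toyMarkerMatrix(dos2), n_components = 3)
  ev <- eigen(stats::cov(dos2), symmetric = TRUE)
  scores_oracle <- sweep(dos2, 2, colMeans(dos2)) %*% ev$vectors[, 1:3]
  for (j in 1:3)
    expect_gt(abs(stats::cor(pca2$scores[, j], scores_oracle[, j])),
              1 - 1e-8)
})
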