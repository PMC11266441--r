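# Learner input constructions E, G, G+E, GEI and the Kronecker SVD.

toyGRM <- function(n = 4, seed = 12) {
  set.seed(seed)
  Z <- matrix(rnorm(n * 8), n)
  G <- tcrossprod(Z) / 8
  dimnames(G) <- list(paste0("H", seq_len(n)), paste0("H", seq_len(n)))
  methods::new("GenomicRelationship", kind = "additive",
               matrix = (G + t(G)) / 2)
}

toyBlues <- function(envs, hybs) {
  out <- expand.grid(Env = envs, Hybrid = hybs, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  out$y <- rnorm(nrow(out), 10, 1)
  out
}

test_that("the E input repeats environment features within environments", {
  set.seed(13)
  envs <- c("L01_2020", "L02_2020")
  em <- fakeEnvMatrix(envs)
  blues <- toyBlues(envs, c("H1", "H2", "H3"))
  inp <- buildE(blues, em)
  tab <- inputTable(inp)
  expect_equal(nrow(tab), 6L)
  ## 90 numeric features + the Location categorical
  expect_length(setdiff(names(tab), c("Env", "Hybrid", "y")), 91L)
  feats <- setdiff(names(tab), c("Env", "Hybrid", "y", "Location"))
  for (e in envs) {
    sub <- tab[tab$Env == e, feats]
    expect_true(all(vapply(sub, function(x) length(unique(x)) == 1L, TRUE)))
  }
  bad <- blues; bad$Env[1] <- "L99_2020"
  expect_error(buildE(bad, em), "L99_2020")
})

test_that("the G input scores satisfy the SVD identity at full rank", {
  G <- toyGRM(4)
  blues <- toyBlues("L01_2020", paste0("H", 1:4))
  inp <- buildG(blues, G, k = 4)
  tab <- inputTable(inp)
  sc <- as.matrix(tab[match(paste0("H", 1:4), tab$Hybrid),
                      grep("G_SVD_", names(tab))])
  ## scores = U S for the symmetric PSD G, so scores %*% scores' = G^2
  M <- relMatrix(G)
  expect_equal(unname(sc %*% t(sc)), unname(M %*% M), tolerance = 1e-6)
  expect_equal(inp@svdComponents, 4L)
})

test_that("identical hybrids get identical G scores", {
  M <- matrix(1, 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  G <- methods::new("GenomicRelationship", kind = "additive", matrix = M)
  blues <- toyBlues("L01_2020", c("H1", "H2"))
  tab <- inputTable(suppressWarnings(buildG(blues, G, k = 1)))
  expect_equal(tab$G_SVD_1[tab$Hybrid == "H1"],
               tab$G_SVD_1[tab$Hybrid == "H2"])
})

test_that("the G+E input matches a brute-force SVD of the wide table", {
  set.seed(14)
  envs <- c("L01_2020", "L02_2020", "L03_2021")
  em <- fakeEnvMatrix(envs)
  G <- toyGRM(4)
  blues <- toyBlues(envs, paste0("H", 1:4))
  inp <- buildGplusE(blues, em, G, k = 3)
  tab <- inputTable(inp)
  expect_equal(nrow(tab), nrow(blues))
  expect_length(grep("GE_SVD_", names(tab)), 3L)

  wide <- cbind(featureMatrix(em)[blues$Env, ],
                relMatrix(G)[blues$Hybrid, ])
  sv <- svd(wide)
  sgn <- apply(sv$v[, 1:3], 2, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  oracle <- sv$u[, 1:3] %*% diag(sv$d[1:3]) * rep(sgn, each = nrow(wide))
  got <- as.matrix(tab[, paste0("GE_SVD_", 1:3)])
  expect_equal(unname(got), unname(oracle), tolerance = 1e-8)

  ## duplicated (Env, Hybrid) records receive identical feature rows
  blues2 <- rbind(blues, blues[1, ])
  tab2 <- inputTable(buildGplusE(blues2, em, G, k = 3))
  first <- tab2[1, paste0("GE_SVD_", 1:3)]
  last <- tab2[nrow(tab2), paste0("GE_SVD_", 1:3)]
  expect_equal(unname(unlist(first)), unname(unlist(last)),
               tolerance = 1e-12)
})

test_that("a 1x1 environmental matrix reduces the GEI input to G", {
  G <- toyGRM(4)
  one <- matrix(1, 1, 1, dimnames = list("L01_2020", "Irrigated"))
  em <- methods::new("EnvironmentalMatrix", features = one,
                     manifest = data.frame(name = "Irrigated",
                                           category = "management",
                                           units = "flag", recipe = "as-is"))
  blues <- toyBlues("L01_2020", paste0("H", 1:4))
  gei <- inputTable(buildGEI(blues, em, G, k = 4))
  g <- inputTable(buildG(blues, G, k = 4))
  expect_equal(as.matrix(gei[, paste0("GEI_SVD_", 1:4)]),
               as.matrix(g[, paste0("G_SVD_", 1:4)]),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("factorized Kronecker SVD equals the materialized oracle", {
  set.seed(15)
  envs <- c("L01_2020", "L02_2020", "L03_2021")
  E <- matrix(rnorm(6), 3, dimnames = list(envs, c("f1", "f2")))
  G <- toyGRM(4)
  blues <- toyBlues(envs, paste0("H", 1:4))
  em <- methods::new("EnvironmentalMatrix", features = E,
                     manifest = data.frame(name = c("f1", "f2"),
                                           category = "soil",
                                           units = "u", recipe = "r"))
  fac <- inputTable(buildGEI(blues, em, G, k = 5))
  mat <- inputTable(buildGEI(blues, em, G, k = 5, materialize = TRUE))
  expect_equal(as.matrix(fac[, paste0("GEI_SVD_", 1:5)]),
               as.matrix(mat[, paste0("GEI_SVD_", 1:5)]),
               tolerance = 1e-8)

  ## conceptual dimensions follow n q x m q
  X <- kronecker(E, relMatrix(G))
  expect_equal(dim(X), c(3 * 4, 2 * 4))

  ## property: random toys with n q <= 200
  for (i in 1:5) {
    n <- sample(2:4, 1); m <- sample(2:5, 1); q <- sample(3:6, 1)
    E2 <- matrix(rnorm(n * m), n,
                 dimnames = list(sprintf("L%02d_2020", 1:n), paste0("f", 1:m)))
    G2 <- toyGRM(q, seed = 100 + i)
    em2 <- methods::new("EnvironmentalMatrix", features = E2,
                        manifest = data.frame(name = paste0("f", 1:m),
                                              category = "soil",
                                              units = "u", recipe = "r"))
    bl <- toyBlues(rownames(E2), rownames(relMatrix(G2)))
    kk <- min(4, n * m * 0 + min(n * q, m * q) - 1)
    f2 <- inputTable(buildGEI(bl, em2, G2, k = kk))
    m2 <- inputTable(buildGEI(bl, em2, G2, k = kk, materialize = TRUE))
    expect_equal(as.matrix(f2[, grep("GEI_SVD_", names(f2))]),
                 as.matrix(m2[, grep("GEI_SVD_", names(m2))]),
                 tolerance = 1e-8)
  }
})

test_that("GEI guards: k reduction warns, materialization has a memory cap", {
  set.seed(16)
  E <- matrix(rnorm(4), 2, dimnames = list(c("L01_2020", "L02_2020"),
                                           c("f1", "f2")))
  em <- methods::new("EnvironmentalMatrix", features = E,
                     manifest = data.frame(name = c("f1", "f2"),
                                           category = "soil",
                                           units = "u", recipe = "r"))
  G <- toyGRM(3)
  blues <- toyBlues(rownames(E), rownames(relMatrix(G)))
  expect_warning(buildGEI(blues, em, G, k = 50), "reduced")
  expect_error(buildGEI(blues, em, G, k = 2, materialize = TRUE,
                        size_cap = 10), "memory guard")
})

test_that("joins never drop or duplicate records", {
  set.seed(17)
  st <- mediumStudy()
  em <- mediumEnvMatrix()
  blues <- mediumBlues()
  g <- ldPrune(filterMAF(filterIndividuals(st@geno, unique(blues$Hybrid)),
                         0.01), window = 50, step = 10)
  A <- grmAdditive(g)
  for (inp in list(buildE(blues, em), buildG(blues, A, k = 10),
                   buildGplusE(blues, em, A, k = 10),
                   buildGEI(blues, em, A, k = 10))) {
    tab <- inputTable(inp)
    expect_equal(nrow(tab), nrow(blues))
    expect_identical(paste(tab$Env, tab$Hybrid),
                     paste(blues$Env, blues$Hybrid))
    expect_false(anyNA(tab$y))
  }
})
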