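# Stage 4: learner input tables E, G, G+E and GEI.
#
# The GEI construction conceptually forms X = E (x) G (Kronecker
# product, nq x mq) but never materializes it: with E = U_E S_E V_E'
# and G = U_G S_G V_G', the SVD of the product is
# (U_E (x) U_G)(S_E (x) S_G)(V_E (x) V_G)', so the top-k score columns
# are outer products of the factor singular vectors, evaluated only at
# the (Env, Hybrid) rows that actually occur.

#' Truncated SVD scores of a numeric matrix
#'
#' @param X numeric matrix (rows keyed by the caller).
#' @param k components to keep (reduced with a warning if it exceeds
#'   `min(dim(X))`).
#' @param center center columns first (default `FALSE`, matching the
#'   uncentered construction of the feature pipeline).
#' @param prefix column-name prefix for the scores.
#' @return list with `scores` (rows x k) and `explained` ratios.
#'   Component signs follow the convention that the largest-magnitude
#'   loading is positive.
#' @export
truncatedSVDScores <- function(X, k, center = FALSE, prefix = "SVD_") {
  X <- as.matrix(X)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    mu[!is.finite(mu)] <- 0
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  kmax <- min(dim(X))
  if (k > kmax) {
    warning(sprintf("k reduced from %d to %d (matrix rank bound)", k, kmax))
    k <- kmax
  }
  X0 <- if (center) sweep(X, 2, colMeans(X)) else X
  sv <- svd(X0, nu = k, nv = k)
  sgn <- svdSignConvention(sv$v)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k) * rep(sgn, each = nrow(X0))
  dimnames(scores) <- list(rownames(X), paste0(prefix, seq_len(k)))
  list(scores = scores, explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
}

#' Feature block -> data.frame with clean sequential row names
#' @noRd
featDF <- function(m) {
  rownames(m) <- NULL
  as.data.frame(m)
}

#' @noRd
newModelInput <- function(kind, grm_kind, table, k) {
  methods::new("ModelInput", kind = kind, grmKind = grm_kind,
               table = table, svdComponents = as.integer(k))
}

#' @noRd
baseTable <- function(blues) {
  assertColumns(blues, c("Env", "Hybrid", "y"), "BLUE table")
  data.frame(Env = blues$Env, Hybrid = blues$Hybrid, y = blues$y,
             Location = fieldLocation(blues$Env),
             stringsAsFactors = FALSE)
}

#' Environmental (E) model input
#'
#' Left join of the environmental matrix onto the BLUE table by `Env`.
#' No SVD is applied; because every feature is a property of the
#' environment alone, a model fitted on this input predicts the same
#' value for every hybrid within an environment.
#'
#' @param blues BLUE table (`Env`, `Hybrid`, `y`).
#' @param env_matrix an [EnvironmentalMatrix-class].
#' @return a [ModelInput-class] of kind `"E"`.
#' @export
buildE <- function(blues, env_matrix) {
  tab <- baseTable(blues)
  feats <- featureMatrix(env_matrix)
  bad <- setdiff(unique(tab$Env), rownames(feats))
  if (length(bad))
    stop("join error: environment(s) absent from environmental matrix: ",
         paste(bad, collapse = ", "))
  out <- cbind(tab, featDF(feats[tab$Env, , drop = FALSE]))
  newModelInput("E", "none", out, 0L)
}

#' Genetic (G) model input
#'
#' Truncated SVD of the genomic relationship matrix (first `k`
#' components), joined onto the BLUE table by `Hybrid`.
#'
#' @param blues BLUE table.
#' @param grm a [GenomicRelationship-class].
#' @param k SVD components (default 100).
#' @return a [ModelInput-class] of kind `"G"`.
#' @export
buildG <- function(blues, grm, k = 100) {
  tab <- baseTable(blues)
  M <- relMatrix(grm)
  bad <- setdiff(unique(tab$Hybrid), rownames(M))
  if (length(bad))
    stop("join error: hybrid(s) absent from relationship matrix: ",
         paste(bad, collapse = ", "))
  sv <- truncatedSVDScores(M, k, prefix = "G_SVD_")
  out <- cbind(tab, featDF(sv$scores[tab$Hybrid, , drop = FALSE]))
  newModelInput("G", grmTag(grm), out, ncol(sv$scores))
}

#' Genetic-and-environmental (G+E) model input
#'
#' Concatenates the environmental features (per `Env`) and the
#' relationship-matrix row (per `Hybrid`) of each BLUE record into one
#' wide table (width about 90 + q), reduces it with a truncated SVD to
#' `k` components, and joins the scores back by (`Env`, `Hybrid`).
#' There is no explicit interaction term; interactions are left to the
#' tree learner.
#'
#' @inheritParams buildG
#' @param env_matrix an [EnvironmentalMatrix-class].
#' @return a [ModelInput-class] of kind `"G+E"`.
#' @export
buildGplusE <- function(blues, env_matrix, grm, k = 100) {
  tab <- baseTable(blues)
  feats <- featureMatrix(env_matrix)
  M <- relMatrix(grm)
  badE <- setdiff(unique(tab$Env), rownames(feats))
  if (length(badE))
    stop("join error: environment(s) absent from environmental matrix: ",
         paste(badE, collapse = ", "))
  badH <- setdiff(unique(tab$Hybrid), rownames(M))
  if (length(badH))
    stop("join error: hybrid(s) absent from relationship matrix: ",
         paste(badH, collapse = ", "))
  wide <- cbind(feats[tab$Env, , drop = FALSE],
                M[tab$Hybrid, , drop = FALSE])
  sv <- truncatedSVDScores(wide, k, prefix = "GE_SVD_")
  out <- cbind(tab, featDF(sv$scores))
  newModelInput("G+E", grmTag(grm), out, ncol(sv$scores))
}

#' Genotype-by-environment interaction (GEI) model input
#'
#' Conceptually forms the Kronecker product X = E (x) G
#' (environments-x-features times hybrids-x-hybrids, so X is nq x mq)
#' and keeps the top-`k` SVD score columns, joined by
#' (`Env`, `Hybrid`). The factorization
#' SVD(E (x) G) = (U_E (x) U_G)(S_E (x) S_G)(V_E (x) V_G)' is used, so
#' X is never materialized; a materializing fallback (for oracle
#' checks) exists behind a size cap.
#'
#' @inheritParams buildGplusE
#' @param materialize if `TRUE`, build X explicitly and take its SVD
#'   (only allowed below `size_cap` elements).
#' @param size_cap maximum number of elements of X for which
#'   materialization is permitted.
#' @return a [ModelInput-class] of kind `"GEI"`.
#' @export
buildGEI <- function(blues, env_matrix, grm, k = 100,
                     materialize = FALSE, size_cap = 4e6) {
  tab <- baseTable(blues)
  E <- featureMatrix(env_matrix)
  if (anyNA(E)) {
    mu <- colMeans(E, na.rm = TRUE)
    idx <- which(is.na(E), arr.ind = TRUE)
    E[idx] <- mu[idx[, 2]]
  }
  G <- relMatrix(grm)
  badE <- setdiff(unique(tab$Env), rownames(E))
  if (length(badE))
    stop("join error: environment(s) absent from environmental matrix: ",
         paste(badE, collapse = ", "))
  badH <- setdiff(unique(tab$Hybrid), rownames(G))
  if (length(badH))
    stop("join error: hybrid(s) absent from relationship matrix: ",
         paste(badH, collapse = ", "))

  n <- nrow(E); m <- ncol(E); q <- nrow(G)
  if (materialize) {
    if (as.double(n) * q * m * q > size_cap)
      stop(sprintf("memory guard: materialized X would have %.3g elements",
                   as.double(n) * q * m * q))
    X <- kronecker(E, G)
    rn <- as.vector(t(outer(rownames(E), rownames(G), paste, sep = "\r")))
    rownames(X) <- rn
    sv <- truncatedSVDScores(X, k, prefix = "GEI_SVD_")
    key <- paste(tab$Env, tab$Hybrid, sep = "\r")
    scores <- sv$scores[key, , drop = FALSE]
  } else {
    scores <- kroneckerSVDScores(E, G, k, tab$Env, tab$Hybrid)
  }
  out <- cbind(tab, featDF(scores))
  newModelInput("GEI", grmTag(grm), out, ncol(scores))
}

#' Top-k SVD scores of E (x) G without materializing the product
#'
#' @param E environments x features matrix.
#' @param G hybrids x hybrids relationship matrix.
#' @param k components to keep.
#' @param env_keys,hybrid_keys row keys at which to evaluate the
#'   scores.
#' @return matrix length(env_keys) x k of score values.
#' @export
kroneckerSVDScores <- function(E, G, k, env_keys, hybrid_keys) {
  svE <- svd(E)
  svG <- svd(G)
  ## sign conventions applied to each factor so products inherit the
  ## largest-magnitude-loading-positive convention
  sE <- svdSignConvention(svE$v)
  sG <- svdSignConvention(svG$v)
  svE$u <- svE$u * rep(sE, each = nrow(svE$u))
  svG$u <- svG$u * rep(sG, each = nrow(svG$u))

  dprod <- outer(svE$d, svG$d)            # singular values s_a * t_b
  ord <- order(-as.vector(dprod))
  kmax <- sum(dprod > 0)
  if (k > kmax) {
    warning(sprintf("k reduced from %d to %d (rank of the Kronecker product)",
                    k, kmax))
    k <- kmax
  }
  sel <- ord[seq_len(k)]
  a <- (sel - 1L) %% length(svE$d) + 1L   # column-major index of outer()
  b <- (sel - 1L) %/% length(svE$d) + 1L

  ei <- match(env_keys, rownames(E))
  hi <- match(hybrid_keys, rownames(G))
  scores <- matrix(0, length(env_keys), k,
                   dimnames = list(NULL, paste0("GEI_SVD_", seq_len(k))))
  for (j in seq_len(k)) {
    scores[, j] <- svE$u[ei, a[j]] * svG$u[hi, b[j]] * dprod[a[j], b[j]]
  }
  scores
}

#' @noRd
grmTag <- function(grm) {
  switch(grmKind(grm), additive = "A", dominance = "D", "none")
}

#' Write a ModelInput to CSV with a JSON sidecar
#'
#' @param input a [ModelInput-class].
#' @param path CSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @param provenance optional named list of input-file hashes or other
#'   provenance to record.
#' @return invisibly, the CSV path.
#' @export
writeModelInput <- function(input, path, provenance = list()) {
  utils::write.csv(input@table, path, row.names = FALSE)
  meta <- list(kind = input@kind, grm_kind = input@grmKind,
               svd_components = input@svdComponents,
               n_records = nrow(input@table),
               provenance = provenance)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
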