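# Shared fixtures, built in code and cached per test run.

tinyConfig <- function(seed = 42, ...) {
  simConfig(n_parents = 6, n_markers = 200,
            n_environments_per_year = c(1, 2, 2), seed = seed, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tinyStudy <- function() cached("tinyStudy", simulateStudy(tinyConfig()))

## medium study: enough environments for the full 90-feature schema
## (>= 15 needed by the 15-component EC SVD)
mediumStudy <- function() cached("mediumStudy", simulateStudy(
  simConfig(n_parents = 8, n_markers = 300,
            n_environments_per_year = c(5, 6, 6), seed = 7)))

mediumEnvMatrix <- function() cached("mediumEM",
  buildEnvironmentalMatrix(mediumStudy()))

mediumBlues <- function() cached("mediumBlues", {
  pt <- plotTable(mediumStudy())
  ## plot means per (Env, Hybrid) stand in for BLUEs where only the
  ## join/CV structure matters (fast; BLUE numerics are tested in
  ## test-trial-models.R)
  agg <- stats::aggregate(Yield_Mg_ha ~ Env + Hybrid, data = pt, FUN = mean)
  data.frame(Env = agg$Env, Hybrid = agg$Hybrid, y = agg$Yield_Mg_ha,
             stringsAsFactors = FALSE)
})

## hand-made marker matrix
toyMarkerMatrix <- function(dos, chrom = NULL, pos = NULL) {
  n_mk <- ncol(dos)
  if (is.null(colnames(dos)))
    colnames(dos) <- sprintf("SNP_%05d", seq_len(n_mk))
  if (is.null(rownames(dos)))
    rownames(dos) <- sprintf("H%02d", seq_len(nrow(dos)))
  methods::new("MarkerMatrix", dosage = dos,
               markers = data.frame(id = colnames(dos),
                                    chrom = chrom %||% rep(1L, n_mk),
                                    pos = pos %||% seq_len(n_mk),
                                    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## independent brute-force LD pruning oracle: whole set treated as one
## window; repeatedly remove from the worst offending pair the marker
## with the higher mean r2 (ties: later position)
ldPruneOracle <- function(dos, r2_thr) {
  active <- rep(TRUE, ncol(dos))
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    R <- suppressWarnings(stats::cor(dos[, idx, drop = FALSE],
                                     use = "pairwise.complete.obs")^2)
    R[!is.finite(R)] <- 0
    diag(R) <- NA
    if (max(R, na.rm = TRUE) <= r2_thr) break
    ij <- which(R == max(R, na.rm = TRUE), arr.ind = TRUE)[1, ]
    mr <- vapply(ij, function(k) mean(R[k, -k], na.rm = TRUE), 0)
    victim <- if (mr[1] > mr[2]) ij[1] else if (mr[2] > mr[1]) ij[2]
              else max(ij)
    active[idx[victim]] <- FALSE
  }
  colnames(dos)[active]
}

## simple 90-feature environmental matrix built from raw blocks (used
## where the schema, not the recipe, is under test)
fakeEnvMatrix <- function(envs) {
  n <- length(envs)
  blk <- function(k, prefix) {
    m <- matrix(stats::rnorm(n * k), n,
                dimnames = list(envs, paste0(prefix, seq_len(k))))
    m
  }
  wf <- blk(63, "w"); colnames(wf) <- weatherFeatureNames()
  assembleEnvironmentalMatrix(
    weather_feats = wf,
    ec_scores = blk(15, "EC_SVD_"),
    lagged_feats = blk(6, "LagYield_"),
    soil = data.frame(Env = envs, Nitrate_ppm = stats::rnorm(n, 20),
                      Nitrogen_lb_ac = stats::rnorm(n, 80),
                      Calcium_pct = stats::rnorm(n, 1.5)),
    binned_coords = matrix(c(rep(39.6, n), rep(-97.2, n)), n,
                           dimnames = list(envs, c("Lat_bin", "Lon_bin"))),
    management = data.frame(Env = envs, Irrigated = rep(0L, n)))
}
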