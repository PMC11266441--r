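# S4 classes for the central data objects of the workflow.

#' MarkerMatrix: biallelic marker dosages for a hybrid panel
#'
#' Holds additive dosage codes (0, 1, 2 or `NA`) for a set of hybrids at a
#' set of ordered markers, plus the marker map (chromosome, position).
#' Rows are hybrids, columns are markers.
#'
#' @slot dosage numeric matrix, hybrids x markers, values in {0, 1, 2, NA};
#'   dimnames give hybrid and marker ids.
#' @slot markers `data.frame` with columns `id`, `chrom`, `pos` in the same
#'   column order as `dosage`.
#' @seealso [markerMatrixFromVCF()], [filterMAF()], [ldPrune()],
#'   [grmAdditive()], [grmDominance()]
#' @export
setClass("MarkerMatrix",
  representation(dosage = "matrix", markers = "data.frame"))

setValidity("MarkerMatrix", function(object) {
  d <- object@dosage
  m <- object@markers
  msg <- character()
  if (is.null(rownames(d)) || is.null(colnames(d)))
    msg <- c(msg, "dosage must have hybrid rownames and marker colnames")
  if (anyDuplicated(rownames(d))) msg <- c(msg, "duplicated hybrid ids")
  if (anyDuplicated(colnames(d))) msg <- c(msg, "duplicated marker ids")
  bad <- d[!is.na(d) & !(d %in% c(0, 1, 2))]
  if (length(bad)) msg <- c(msg, "dosage values must be in {0, 1, 2, NA}")
  if (!all(c("id", "chrom", "pos") %in% names(m)))
    msg <- c(msg, "markers needs columns id, chrom, pos")
  else if (nrow(m) != ncol(d) || !identical(as.character(m$id), colnames(d)))
    msg <- c(msg, "markers table must match dosage columns in order")
  if (length(msg)) msg else TRUE
})

#' GenomicRelationship: additive or dominance relationship matrix
#'
#' A symmetric hybrid x hybrid relationship matrix, either additive
#' (VanRaden) or dominance (Vitezica).
#'
#' @slot kind `"additive"` or `"dominance"`.
#' @slot matrix symmetric numeric matrix with hybrid dimnames.
#' @seealso [grmAdditive()], [grmDominance()]
#' @export
setClass("GenomicRelationship",
  representation(kind = "character", matrix = "matrix"))

setValidity("GenomicRelationship", function(object) {
  msg <- character()
  if (!object@kind %in% c("additive", "dominance"))
    msg <- c(msg, "kind must be 'additive' or 'dominance'")
  M <- object@matrix
  if (nrow(M) != ncol(M)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(M)) || !identical(rownames(M), colnames(M)))
    msg <- c(msg, "matrix needs matching hybrid dimnames")
  if (nrow(M) && max(abs(M - t(M))) > 1e-10)
    msg <- c(msg, "matrix must be symmetric to 1e-10")
  if (length(msg)) msg else TRUE
})

#' EnvironmentalMatrix: engineered per-environment features
#'
#' One row per environment, feature columns tagged with one of six
#' categories (weather, ec_svd, lagged_yield, soil, coordinates,
#' management). Under the default schema there are exactly 90 features.
#'
#' @slot features numeric matrix, environments x features, with Env
#'   rownames and feature colnames.
#' @slot manifest `data.frame` with one row per feature: `name`,
#'   `category`, `units`, `recipe`.
#' @seealso [assembleEnvironmentalMatrix()], [buildEnvironmentalMatrix()]
#' @export
setClass("EnvironmentalMatrix",
  representation(features = "matrix", manifest = "data.frame"))

setValidity("EnvironmentalMatrix", function(object) {
  f <- object@features
  man <- object@manifest
  msg <- character()
  if (is.null(rownames(f))) msg <- c(msg, "features must have Env rownames")
  if (anyDuplicated(rownames(f))) msg <- c(msg, "duplicated environments")
  if (anyDuplicated(colnames(f))) msg <- c(msg, "duplicated feature names")
  if (!all(c("name", "category", "units", "recipe") %in% names(man)))
    msg <- c(msg, "manifest needs columns name, category, units, recipe")
  else {
    if (!identical(as.character(man$name), colnames(f)))
      msg <- c(msg, "manifest rows must match feature columns in order")
    bad <- setdiff(unique(man$category),
                   c("weather", "ec_svd", "lagged_yield", "soil",
                     "coordinates", "management"))
    if (length(bad))
      msg <- c(msg, paste("unknown feature categories:",
                          paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' SingleTrialFit: per-environment mixed-model fit
#'
#' Result of the stage-1 single-trial model: hybrid BLUEs from the
#' fixed-hybrid fit, variance components, and the genetic variance and
#' mean pairwise prediction error variance from the companion
#' random-hybrid refit (used by the Cullis heritability).
#'
#' @slot env environment id.
#' @slot blues named numeric vector of hybrid BLUEs (Mg/ha).
#' @slot mu intercept of the fixed-hybrid fit.
#' @slot varComponents named numeric: `block`, `row`, `col`, `resid`.
#' @slot sigmaG genetic variance from the random-hybrid refit.
#' @slot pev mean pairwise prediction error variance V-bar(Delta).
#' @slot meanFitted mean of fitted values (denominator of the CV%).
#' @slot converged logical convergence flag.
#' @slot nIter number of optimizer evaluations.
#' @slot dropped hybrids dropped for having no non-missing plot.
#' @seealso [fitSingleTrial()], [coefficientOfVariation()],
#'   [cullisHeritability()]
#' @export
setClass("SingleTrialFit",
  representation(env = "character", blues = "numeric", mu = "numeric",
                 varComponents = "numeric", sigmaG = "numeric",
                 pev = "numeric", meanFitted = "numeric",
                 converged = "logical", nIter = "integer",
                 dropped = "character"))

setValidity("SingleTrialFit", function(object) {
  msg <- character()
  if (any(object@varComponents < 0)) msg <- c(msg, "variances must be >= 0")
  if (length(object@sigmaG) && object@sigmaG < 0)
    msg <- c(msg, "sigmaG must be >= 0")
  if (length(object@pev) && object@pev < -1e-8)
    msg <- c(msg, "V-bar(Delta) must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SyntheticStudy: a complete simulated multi-environment trial study
#'
#' Bundles every layer a real study would provide — genotypes, plot-level
#' phenotypes, weather, soil, crop-model covariates, coordinates,
#' management and historical yield — together with the realized
#' ground-truth effects, so that every downstream stage is testable.
#'
#' @slot config the validated simulation configuration (see [simConfig()]).
#' @slot geno a [MarkerMatrix-class] of hybrid dosages.
#' @slot pedigree `data.frame`: `Hybrid`, `Parent`, `Tester`.
#' @slot plotTable plot-level phenotypes: `Env`, `Hybrid`, `Replicate`,
#'   `Block`, `Row`, `Col`, `Yield_Mg_ha`.
#' @slot weather 30-minute weather records per environment.
#' @slot soil per-environment soil assays.
#' @slot ecs environments x 765 crop-model covariate matrix.
#' @slot coords per-environment latitude/longitude (`Env`, `Location`,
#'   `Latitude`, `Longitude`).
#' @slot management per-environment management table (`Env`, `Irrigated`).
#' @slot history location-year plot yields used for lagged features.
#' @slot truth list of realized effects (intercept, additive, dominance,
#'   env, gxe, block, row, col, residual, env_index).
#' @seealso [simulateStudy()]
#' @export
setClass("SyntheticStudy",
  representation(config = "list", geno = "MarkerMatrix",
                 pedigree = "data.frame", plotTable = "data.frame",
                 weather = "data.frame", soil = "data.frame",
                 ecs = "matrix", coords = "data.frame",
                 management = "data.frame", history = "data.frame",
                 truth = "list"))

setValidity("SyntheticStudy", function(object) {
  msg <- character()
  envs <- unique(object@plotTable$Env)
  for (nm in c("weather", "soil", "coords", "management")) {
    have <- unique(slot(object, nm)$Env)
    if (!all(envs %in% have))
      msg <- c(msg, sprintf("environments missing from %s: %s", nm,
                            paste(setdiff(envs, have), collapse = ", ")))
  }
  if (!all(envs %in% rownames(object@ecs)))
    msg <- c(msg, "environments missing from ecs")
  if (!all(unique(object@plotTable$Hybrid) %in% rownames(object@geno@dosage)))
    msg <- c(msg, "plot-table hybrids missing from genotypes")
  if (length(msg)) msg else TRUE
})

#' ModelInput: a learner-ready feature table
#'
#' One row per BLUE record with keys (`Env`, `Hybrid`), the response `y`,
#' the field-location categorical, and numeric feature columns. `kind`
#' records which construction produced it (E, G, G+E or GEI) and
#' `grmKind` which relationship matrix (if any) went in.
#'
#' @slot kind one of `"E"`, `"G"`, `"G+E"`, `"GEI"`.
#' @slot grmKind one of `"A"`, `"D"`, `"none"`.
#' @slot table the joined `data.frame`.
#' @slot svdComponents number of SVD components actually kept (0 for E).
#' @seealso [buildE()], [buildG()], [buildGplusE()], [buildGEI()]
#' @export
setClass("ModelInput",
  representation(kind = "character", grmKind = "character",
                 table = "data.frame", svdComponents = "integer"))

setValidity("ModelInput", function(object) {
  msg <- character()
  if (!object@kind %in% c("E", "G", "G+E", "GEI"))
    msg <- c(msg, "kind must be one of E, G, G+E, GEI")
  if (!object@grmKind %in% c("A", "D", "none"))
    msg <- c(msg, "grmKind must be one of A, D, none")
  need <- c("Env", "Hybrid", "y", "Location")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table needs columns Env, Hybrid, y, Location")
  else if (anyNA(object@table$Env) || anyNA(object@table$Hybrid))
    msg <- c(msg, "keys must not be missing")
  if (length(msg)) msg else TRUE
})

#' CVPlan: a cross-validation fold/repetition plan
#'
#' Assignment of BLUE records to training and validation sets under one
#' of the named schemes (CV2: untested combinations; CV1: untested
#' hybrids; CV0: untested year).
#'
#' @slot scheme `"CV2"`, `"CV1"` or `"CV0"`.
#' @slot folds number of folds (default 5).
#' @slot repetitions number of repetitions (default 10).
#' @slot assignments `data.frame` with columns `Rep`, `Fold`, `Set`
#'   (`"train"`/`"valid"`), `Env`, `Hybrid`.
#' @slot seed the seed the plan was built with.
#' @seealso [splitCV2()], [splitCV1()], [splitCV0()]
#' @export
setClass("CVPlan",
  representation(scheme = "character", folds = "integer",
                 repetitions = "integer", assignments = "data.frame",
                 seed = "integer"))

setValidity("CVPlan", function(object) {
  msg <- character()
  if (!object@scheme %in% c("CV2", "CV1", "CV0"))
    msg <- c(msg, "scheme must be CV2, CV1 or CV0")
  a <- object@assignments
  if (!all(c("Rep", "Fold", "Set", "Env", "Hybrid") %in% names(a)))
    msg <- c(msg, "assignments needs Rep, Fold, Set, Env, Hybrid")
  else if (!all(a$Set %in% c("train", "valid")))
    msg <- c(msg, "Set must be 'train' or 'valid'")
  if (length(msg)) msg else TRUE
})

#' GBMConfig: gradient-boosting hyperparameters
#'
#' Hyperparameters for the gradient-boosted regression trees, expressed
#' in the leaf-wise GBM vocabulary and mapped internally onto the
#' histogram tree builder.
#'
#' @slot numTrees number of boosting rounds.
#' @slot learningRate shrinkage per round.
#' @slot maxLeaves maximum leaves per tree (leaf-wise growth).
#' @slot minDataInLeaf minimum observations per leaf.
#' @slot featureFraction column subsample fraction per tree, in (0, 1].
#' @slot baggingFraction row subsample fraction per tree, in (0, 1].
#' @slot seed integer seed; fits are single-threaded and deterministic.
#' @slot categoricalFeatures names of categorical columns (one-hot
#'   encoded before fitting); default `"Location"`.
#' @seealso [gbmConfig()], [fitPredict()]
#' @export
setClass("GBMConfig",
  representation(numTrees = "integer", learningRate = "numeric",
                 maxLeaves = "integer", minDataInLeaf = "integer",
                 featureFraction = "numeric", baggingFraction = "numeric",
                 seed = "integer", categoricalFeatures = "character"))

setValidity("GBMConfig", function(object) {
  msg <- character()
  if (object@numTrees < 1L) msg <- c(msg, "numTrees must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@maxLeaves < 2L) msg <- c(msg, "maxLeaves must be >= 2")
  if (object@minDataInLeaf < 1L) msg <- c(msg, "minDataInLeaf must be >= 1")
  for (fr in c(object@featureFraction, object@baggingFraction))
    if (fr <= 0 || fr > 1) msg <- c(msg, "fractions must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' PredictionSet: observed and predicted yields for one validation set
#'
#' @slot records `data.frame` with `Env`, `Hybrid`, `y_observed`,
#'   `y_predicted`.
#' @slot modelKind the model token (e.g. `"G(A)+E"`).
#' @slot scheme the CV scheme the fold came from.
#' @slot rep repetition index.
#' @slot fold fold index.
#' @seealso [fitPredict()], [pearsonAccuracy()], [coincidenceIndex()]
#' @export
setClass("PredictionSet",
  representation(records = "data.frame", modelKind = "character",
                 scheme = "character", rep = "integer", fold = "integer"))

setValidity("PredictionSet", function(object) {
  r <- object@records
  msg <- character()
  if (!all(c("Env", "Hybrid", "y_observed", "y_predicted") %in% names(r)))
    msg <- c(msg, "records needs Env, Hybrid, y_observed, y_predicted")
  else if (any(!is.finite(r$y_predicted)))
    msg <- c(msg, "predictions must be finite")
  if (length(msg)) msg else TRUE
})
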