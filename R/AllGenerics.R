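# Generics and accessor/show methods.

#' Hybrid ids of an object
#' @param x a MarkerMatrix, GenomicRelationship or SyntheticStudy.
#' @return character vector of hybrid ids.
#' @export
setGeneric("hybrids", function(x) standardGeneric("hybrids"))

#' @rdname hybrids
#' @export
setMethod("hybrids", "MarkerMatrix", function(x) rownames(x@dosage))

#' @rdname hybrids
#' @export
setMethod("hybrids", "GenomicRelationship", function(x) rownames(x@matrix))

#' @rdname hybrids
#' @export
setMethod("hybrids", "SyntheticStudy", function(x) rownames(x@geno@dosage))

#' Dosage matrix (hybrids x markers)
#' @param x a MarkerMatrix.
#' @return numeric matrix of additive dosages.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "MarkerMatrix", function(x) x@dosage)

#' Marker map of a MarkerMatrix
#' @param x a MarkerMatrix.
#' @return `data.frame` with columns `id`, `chrom`, `pos`.
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname markerMap
#' @export
setMethod("markerMap", "MarkerMatrix", function(x) x@markers)

#' Relationship matrix and kind
#' @param x a GenomicRelationship.
#' @return `relMatrix`: the symmetric matrix; `grmKind`: its kind.
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))

#' @rdname relMatrix
#' @export
setMethod("relMatrix", "GenomicRelationship", function(x) x@matrix)

#' @rdname relMatrix
#' @export
setGeneric("grmKind", function(x) standardGeneric("grmKind"))

#' @rdname relMatrix
#' @export
setMethod("grmKind", "GenomicRelationship", function(x) x@kind)

#' Environment ids of an object
#' @param x an EnvironmentalMatrix or SyntheticStudy.
#' @return character vector of environment ids.
#' @export
setGeneric("envNames", function(x) standardGeneric("envNames"))

#' @rdname envNames
#' @export
setMethod("envNames", "EnvironmentalMatrix", function(x) rownames(x@features))

#' @rdname envNames
#' @export
setMethod("envNames", "SyntheticStudy",
          function(x) unique(x@plotTable$Env))

#' Feature matrix and manifest of an EnvironmentalMatrix
#' @param x an EnvironmentalMatrix.
#' @return `featureMatrix`: environments x features matrix;
#'   `manifest`: the feature schema table.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "EnvironmentalMatrix", function(x) x@features)

#' @rdname featureMatrix
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' @rdname featureMatrix
#' @export
setMethod("manifest", "EnvironmentalMatrix", function(x) x@manifest)

#' Hybrid BLUEs of a single-trial fit
#' @param x a SingleTrialFit.
#' @return named numeric vector of BLUEs (Mg/ha).
#' @export
setGeneric("blues", function(x) standardGeneric("blues"))

#' @rdname blues
#' @export
setMethod("blues", "SingleTrialFit", function(x) x@blues)

#' Variance components of a single-trial fit
#' @param x a SingleTrialFit.
#' @return named numeric vector (`block`, `row`, `col`, `resid`).
#' @export
setGeneric("varComponents", function(x) standardGeneric("varComponents"))

#' @rdname varComponents
#' @export
setMethod("varComponents", "SingleTrialFit", function(x) x@varComponents)

#' Plot table of a synthetic study
#' @param x a SyntheticStudy.
#' @return the plot-level phenotype `data.frame`.
#' @export
setGeneric("plotTable", function(x) standardGeneric("plotTable"))

#' @rdname plotTable
#' @export
setMethod("plotTable", "SyntheticStudy", function(x) x@plotTable)

#' Ground-truth effects of a synthetic study
#' @param x a SyntheticStudy.
#' @return list of realized effects.
#' @export
setGeneric("truth", function(x) standardGeneric("truth"))

#' @rdname truth
#' @export
setMethod("truth", "SyntheticStudy", function(x) x@truth)

#' Model-input table
#' @param x a ModelInput.
#' @return the learner-ready `data.frame`.
#' @export
setGeneric("inputTable", function(x) standardGeneric("inputTable"))

#' @rdname inputTable
#' @export
setMethod("inputTable", "ModelInput", function(x) x@table)

#' Fold assignments of a CV plan
#' @param x a CVPlan.
#' @return `data.frame` with columns `Rep`, `Fold`, `Set`, `Env`, `Hybrid`.
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))

#' @rdname assignments
#' @export
setMethod("assignments", "CVPlan", function(x) x@assignments)

#' Training / validation records of one CV cell
#' @param x a CVPlan.
#' @param rep repetition index.
#' @param fold fold index.
#' @return `data.frame` of (`Env`, `Hybrid`) keys.
#' @export
setGeneric("trainingSet",
           function(x, rep, fold) standardGeneric("trainingSet"))

#' @rdname trainingSet
#' @export
setMethod("trainingSet", "CVPlan", function(x, rep, fold) {
  a <- x@assignments
  a[a$Rep == rep & a$Fold == fold & a$Set == "train", c("Env", "Hybrid")]
})

#' @rdname trainingSet
#' @export
setGeneric("validationSet",
           function(x, rep, fold) standardGeneric("validationSet"))

#' @rdname trainingSet
#' @export
setMethod("validationSet", "CVPlan", function(x, rep, fold) {
  a <- x@assignments
  a[a$Rep == rep & a$Fold == fold & a$Set == "valid", c("Env", "Hybrid")]
})

#' Prediction records
#' @param x a PredictionSet.
#' @return `data.frame` with `Env`, `Hybrid`, `y_observed`, `y_predicted`.
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname predictions
#' @export
setMethod("predictions", "PredictionSet", function(x) x@records)

setMethod("show", "MarkerMatrix", function(object) {
  cat(sprintf("MarkerMatrix: %d hybrids x %d markers (%d chromosome%s)\n",
              nrow(object@dosage), ncol(object@dosage),
              length(unique(object@markers$chrom)),
              if (length(unique(object@markers$chrom)) == 1L) "" else "s"))
  nmiss <- sum(is.na(object@dosage))
  cat(sprintf("  missing dosages: %d (%.2f%%)\n", nmiss,
              100 * nmiss / length(object@dosage)))
})

setMethod("show", "GenomicRelationship", function(object) {
  cat(sprintf("GenomicRelationship (%s): %d x %d hybrids, mean diagonal %.3f\n",
              object@kind, nrow(object@matrix), ncol(object@matrix),
              mean(diag(object@matrix))))
})

setMethod("show", "EnvironmentalMatrix", function(object) {
  counts <- table(object@manifest$category)
  cat(sprintf("EnvironmentalMatrix: %d environments x %d features\n",
              nrow(object@features), ncol(object@features)))
  cat("  ", paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      "\n", sep = "")
})

setMethod("show", "SingleTrialFit", function(object) {
  cat(sprintf("SingleTrialFit [%s]: %d hybrids, converged: %s\n",
              object@env, length(object@blues), object@converged))
  vc <- object@varComponents
  cat(sprintf("  var(block)=%.4g var(row)=%.4g var(col)=%.4g var(resid)=%.4g\n",
              vc["block"], vc["row"], vc["col"], vc["resid"]))
  cat(sprintf("  sigma2_g=%.4g  V-bar(Delta)=%.4g\n",
              object@sigmaG, object@pev))
})

setMethod("show", "SyntheticStudy", function(object) {
  pt <- object@plotTable
  cat(sprintf("SyntheticStudy: %d plots, %d hybrids, %d environments, years %s\n",
              nrow(pt), length(unique(pt$Hybrid)),
              length(unique(pt$Env)),
              paste(sort(unique(envYear(pt$Env))), collapse = "-")))
  cat(sprintf("  genotypes: %d x %d; weather records: %d; ECs: %d\n",
              nrow(object@geno@dosage), ncol(object@geno@dosage),
              nrow(object@weather), ncol(object@ecs)))
})

setMethod("show", "ModelInput", function(object) {
  feats <- setdiff(names(object@table), c("Env", "Hybrid", "y", "Location"))
  cat(sprintf("ModelInput [%s%s]: %d records, %d numeric features + Location\n",
              object@kind,
              if (object@grmKind == "none") "" else paste0(", ", object@grmKind),
              nrow(object@table), length(feats)))
})

setMethod("show", "CVPlan", function(object) {
  cat(sprintf("CVPlan [%s]: %d folds x %d repetitions (seed %d)\n",
              object@scheme, object@folds, object@repetitions, object@seed))
  a <- object@assignments
  cell <- a[a$Rep == 1L & a$Fold == 1L, ]
  cat(sprintf("  rep 1 fold 1: %d training / %d validation records\n",
              sum(cell$Set == "train"), sum(cell$Set == "valid")))
})

setMethod("show", "GBMConfig", function(object) {
  cat(sprintf(paste0("GBMConfig: %d trees, lr %.3g, %d leaves, ",
                     "min leaf %d, feat frac %.2f, bag frac %.2f, seed %d\n"),
              object@numTrees, object@learningRate, object@maxLeaves,
              object@minDataInLeaf, object@featureFraction,
              object@baggingFraction, object@seed))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet [%s, %s rep %d fold %d]: %d records\n",
              object@modelKind, object@scheme, object@rep, object@fold,
              nrow(object@records)))
})
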