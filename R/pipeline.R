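# End-to-end orchestration: simulate -> BLUEs -> features -> genetics
# -> inputs -> fit -> evaluate, with per-stage outputs and provenance.

#' Model tokens understood by the pipeline
#' @noRd
knownModels <- c("E", "G(A)", "G(D)", "G(A)+E", "G(D)+E", "G(A)EI", "G(D)EI")

#' @noRd
parseModelToken <- function(token) {
  if (!token %in% knownModels)
    stop("unknown model token '", token, "'; known: ",
         paste(knownModels, collapse = ", "))
  list(token = token,
       uses_env = grepl("E", sub("\\((A|D)\\)", "", token)),
       grm = if (grepl("\\(A\\)", token)) "A"
             else if (grepl("\\(D\\)", token)) "D" else "none",
       kind = if (token == "E") "E"
              else if (grepl("EI$", token)) "GEI"
              else if (grepl("\\+E$", token)) "G+E" else "G")
}

#' Run the full prediction pipeline
#'
#' Orchestrates an end-to-end run from a configuration list (or YAML
#' file): simulate the study, fit single-trial models for BLUEs,
#' build the environmental matrix, run marker QC and relationship
#' matrices, assemble the requested model inputs, run every requested
#' CV scheme and write all stage outputs (with input-hash provenance)
#' into the run directory.
#'
#' Configuration fields: `simulate` (arguments to [simConfig()]),
#' `models` (tokens among E, G(A), G(D), G(A)+E, G(D)+E, G(A)EI,
#' G(D)EI), `schemes` (among CV2, CV1, CV0), `k` (SVD components),
#' `folds`, `repetitions`, `gbm` (arguments to [gbmConfig()]),
#' `seed` (mandatory).
#'
#' @param config a named list or a path to a YAML file.
#' @param out_dir run directory (created; stages overwrite their own
#'   outputs).
#' @return invisibly, a list with the in-memory stage objects
#'   (`study`, `blues`, `env_matrix`, `grms`, `inputs`, `plans`,
#'   `results`).
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config validation: seed is mandatory")
  models <- config$models %||% c("G(A)", "G(A)+E")
  schemes <- config$schemes %||% "CV2"
  if (!length(models) || !length(schemes))
    stop("config validation: need at least one model and one scheme")
  specs <- lapply(models, parseModelToken)   # validates before any compute
  bad_schemes <- setdiff(schemes, c("CV2", "CV1", "CV0"))
  if (length(bad_schemes))
    stop("config validation: unknown scheme(s): ",
         paste(bad_schemes, collapse = ", "))
  k <- config$k %||% 100
  folds <- config$folds %||% 5
  repetitions <- config$repetitions %||% 10

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "log.txt")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      logmsg("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logmsg("stage %s: done", name)
    out
  }

  ## 1. simulate
  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(simConfig, sim_args)
  study <- stage("simulate", simulateStudy(cfg))
  writeStudy(study, file.path(out_dir, "study"))

  ## 2. single-trial models -> BLUEs
  tm <- stage("blues", fitTrials(plotTable(study)))
  utils::write.csv(tm$blues, file.path(out_dir, "blues.csv"),
                   row.names = FALSE)
  utils::write.csv(tm$diagnostics,
                   file.path(out_dir, "trial_diagnostics.csv"),
                   row.names = FALSE)

  ## 3. envirotyping (EC components capped by the environment count)
  k_ec <- min(config$k_ec %||% 15,
              length(unique(plotTable(study)$Env)))
  em <- stage("envirotype", buildEnvironmentalMatrix(study, k_ec = k_ec))
  writeEnvironmentalMatrix(em, file.path(out_dir, "environmental_matrix.csv"))

  ## 4. genetics: QC + GRMs
  need_grms <- unique(unlist(lapply(specs, `[[`, "grm")))
  need_grms <- setdiff(need_grms, "none")
  grms <- stage("genetics", {
    geno <- filterIndividuals(study@geno, unique(tm$blues$Hybrid))
    geno <- filterMAF(geno, 0.01)
    geno <- ldPrune(geno)
    out <- list()
    if ("A" %in% need_grms) out$A <- grmAdditive(geno)
    if ("D" %in% need_grms) out$D <- grmDominance(geno)
    for (g in names(out))
      writeGRM(out[[g]], file.path(out_dir, sprintf("grm_%s.csv", g)))
    out
  })

  ## 5. model inputs
  prov <- list(seed = config$seed)
  inputs <- stage("inputs", {
    ins <- list()
    for (sp in specs) {
      ins[[sp$token]] <- switch(sp$kind,
        "E" = buildE(tm$blues, em),
        "G" = buildG(tm$blues, grms[[sp$grm]], k = k),
        "G+E" = buildGplusE(tm$blues, em, grms[[sp$grm]], k = k),
        "GEI" = buildGEI(tm$blues, em, grms[[sp$grm]], k = k))
      writeModelInput(ins[[sp$token]],
                      file.path(out_dir, sprintf("input_%s.csv",
                                                 gsub("[()+]", "", sp$token))),
                      provenance = prov)
    }
    ins
  })

  ## 6. CV plans + fits + metrics
  gbm_args <- config$gbm %||% list()
  gbm_args$seed <- gbm_args$seed %||% config$seed
  gcfg <- do.call(gbmConfig, gbm_args)
  tester_of <- testerMap(study)
  results <- list()
  for (sc in schemes) {
    splitter <- switch(sc, CV2 = splitCV2, CV1 = splitCV1, CV0 = splitCV0)
    plan <- stage(paste0("plan-", sc),
                  splitter(tm$blues, seed = config$seed,
                           folds = folds, repetitions = repetitions))
    writeCVPlan(plan, file.path(out_dir, sprintf("cvplan_%s.json", sc)))
    res <- stage(paste0("evaluate-", sc),
                 evaluateModels(inputs, plan, gcfg, tester_of = tester_of))
    utils::write.csv(res$metrics,
                     file.path(out_dir, sprintf("metrics_%s.csv", sc)),
                     row.names = FALSE)
    if (!is.null(res$comparisons))
      utils::write.csv(res$comparisons,
                       file.path(out_dir, sprintf("comparisons_%s.csv", sc)),
                       row.names = FALSE)
    for (nm in names(res$predictions)) {
      pr <- do.call(rbind, lapply(res$predictions[[nm]], function(p)
        cbind(predictions(p), rep = p@rep, fold = p@fold)))
      utils::write.csv(pr, file.path(out_dir,
        sprintf("predictions_%s_%s.csv", sc, gsub("[()+]", "", nm))),
        row.names = FALSE)
    }
    results[[sc]] <- res
  }

  ## provenance: content hashes of every stage output
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "provenance.json"))
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  jsonlite::write_json(list(seed = config$seed, models = models,
                            schemes = schemes, hashes = hashes),
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logmsg("run complete")
  invisible(list(study = study, blues = tm$blues, env_matrix = em,
                 grms = grms, inputs = inputs,
                 plans = NULL, results = results))
}

#' Write an EnvironmentalMatrix to CSV with a JSON manifest sidecar
#'
#' @param em an [EnvironmentalMatrix-class].
#' @param path CSV path; the manifest goes next to it as
#'   `<path>.manifest.json`.
#' @return invisibly, `path`.
#' @export
writeEnvironmentalMatrix <- function(em, path) {
  df <- data.frame(Env = rownames(em@features), em@features,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(em@manifest,
                       sub("\\.csv$", ".manifest.json", path),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write a GenomicRelationship to CSV (hybrid ids as header row/column)
#'
#' @param grm a [GenomicRelationship-class].
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
writeGRM <- function(grm, path) {
  df <- data.frame(Hybrid = rownames(grm@matrix), grm@matrix,
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
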