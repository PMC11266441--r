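# Orchestration of the synthetic study and its on-disk form.

#' Simulate a complete synthetic multi-environment study
#'
#' Runs [generatePopulation()], [generateTrials()] and
#' [generateEnvironmentLayers()] under sub-seeds derived from
#' `cfg$seed` and bundles the result into a [SyntheticStudy-class].
#' An identical configuration (including seed) reproduces the study
#' exactly.
#'
#' @param cfg a [simConfig()] object.
#' @return a [SyntheticStudy-class].
#' @examples
#' study <- simulateStudy(simConfig(n_parents = 4, n_markers = 60,
#'                                  n_environments_per_year = c(1, 2, 2),
#'                                  seed = 11))
#' study
#' @export
simulateStudy <- function(cfg) {
  pop <- generatePopulation(cfg)
  tr <- generateTrials(cfg, pop)
  lay <- generateEnvironmentLayers(cfg, plot_table = tr$plot_table)
  methods::new("SyntheticStudy",
               config = unclass(cfg), geno = pop$geno,
               pedigree = pop$pedigree, plotTable = tr$plot_table,
               weather = lay$weather, soil = lay$soil, ecs = lay$ecs,
               coords = lay$coords, management = lay$management,
               history = lay$history, truth = tr$truth)
}

#' Tester of each hybrid in a study
#'
#' @param study a [SyntheticStudy-class].
#' @return named character vector mapping hybrid id to tester id.
#' @export
testerMap <- function(study) {
  stats::setNames(study@pedigree$Tester, study@pedigree$Hybrid)
}

#' Write a synthetic study to disk in its interchange formats
#'
#' Genotypes go to VCF v4.2; the plot table, weather, soil, EC,
#' coordinate, management and history layers go to CSV with their
#' contract column names.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    plot_table = file.path(dir, "plot_table.csv"),
    weather = file.path(dir, "weather.csv"),
    soil = file.path(dir, "soil.csv"),
    ecs = file.path(dir, "ecs.csv"),
    coords = file.path(dir, "coords.csv"),
    management = file.path(dir, "management.csv"),
    history = file.path(dir, "history.csv"),
    pedigree = file.path(dir, "pedigree.csv"))
  writeVCF(study@geno, files["genotypes"])
  utils::write.csv(study@plotTable, files["plot_table"], row.names = FALSE)
  w <- study@weather
  w$Timestamp <- strftime(w$Timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(w, files["weather"], row.names = FALSE)
  utils::write.csv(study@soil, files["soil"], row.names = FALSE)
  ecs <- data.frame(Env = rownames(study@ecs), study@ecs,
                    check.names = FALSE, row.names = NULL)
  utils::write.csv(ecs, files["ecs"], row.names = FALSE)
  utils::write.csv(study@coords, files["coords"], row.names = FALSE)
  utils::write.csv(study@management, files["management"], row.names = FALSE)
  utils::write.csv(study@history, files["history"], row.names = FALSE)
  utils::write.csv(study@pedigree, files["pedigree"], row.names = FALSE)
  invisible(files)
}
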