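# Simulation configuration for the synthetic multi-environment study.

#' Configure a synthetic G2F-like study
#'
#' Builds and validates the configuration for [simulateStudy()]. The
#' defaults emulate the design of a three-year maize hybrid trial
#' network at desk scale: parent x tester hybrids with two testers in
#' the first year and four (one carried over) in the later years, a
#' small minority of hybrids from miscellaneous testers, a modified
#' RCBD with two replicates, and a trial network that grows across
#' years. Variance components are on the (Mg/ha)^2 scale.
#'
#' @param n_parents number of inbred parents crossed to each main tester.
#' @param testers_by_year named list mapping year to its main tester
#'   panel. Default: two testers in year one; four in later years with
#'   the first tester shared across all years.
#' @param n_markers total number of biallelic markers.
#' @param n_chromosomes chromosomes the markers are spread over.
#' @param n_environments_per_year environments (location-years) per
#'   year; recycled to the number of years. Locations are nested so a
#'   location present in year `y` tends to also run in year `y + 1`.
#' @param years vector of strictly increasing trial years (default
#'   three consecutive years).
#' @param reps replicates per environment (default 2).
#' @param field_cols field columns per environment layout.
#' @param rows_per_block field rows per incomplete block within a
#'   replicate.
#' @param coverage fraction of the year's hybrid cohort evaluated in
#'   each environment (incomplete overlap; every cohort hybrid is
#'   guaranteed at least one environment per year).
#' @param var_components named list of variance components in
#'   (Mg/ha)^2: `v_g_add`, `v_g_dom`, `v_env`, `v_gxe`, `v_block`,
#'   `v_row`, `v_col`, `v_resid`.
#' @param intercept overall mean yield (Mg/ha).
#' @param maf_range interval in (0, 0.5] from which marker minor-allele
#'   frequencies are drawn.
#' @param ld_dup_frac fraction of markers generated as near-duplicates
#'   of a neighbouring marker (exercises LD pruning).
#' @param other_tester_frac fraction of the later-year cohort coming
#'   from minor ("other") testers.
#' @param n_other_testers number of minor testers (present in the
#'   later years only).
#' @param env_index_cor correlation between the latent environmental
#'   index (which also drives weather and crop-model covariates) and
#'   the environment main effect.
#' @param gxe_index_cor correlation between the genotype-specific
#'   reaction-norm component (hybrid slope x environmental index) and
#'   the total G-by-E deviation.
#' @param n_regions number of regional centers the field locations are
#'   scattered around.
#' @param coord_jitter latitude/longitude jitter (degrees) around the
#'   regional center.
#' @param season month-day strings giving the planting-to-harvest
#'   window used for the 30-minute weather series.
#' @param missing_plot_frac fraction of plot yields set missing
#'   (default 0).
#' @param missing_weather_frac fraction of weather records dropped
#'   (default 0).
#' @param seed integer master seed; every stage derives its own stream
#'   from it, so an identical configuration reproduces the study
#'   byte for byte.
#' @return a validated configuration list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(n_parents = 4, n_markers = 50,
#'                  n_environments_per_year = c(1, 2, 2), seed = 7)
#' cfg$years
#' @export
simConfig <- function(n_parents = 125,
                      testers_by_year = NULL,
                      n_markers = 3000,
                      n_chromosomes = 10,
                      n_environments_per_year = c(7, 9, 10),
                      years = 2019:2021,
                      reps = 2,
                      field_cols = 20,
                      rows_per_block = 3,
                      coverage = 0.6,
                      var_components = list(),
                      intercept = 10.5,
                      maf_range = c(0.05, 0.5),
                      ld_dup_frac = 0.1,
                      other_tester_frac = 0.016,
                      n_other_testers = 2,
                      env_index_cor = 0.7,
                      gxe_index_cor = 0.7,
                      n_regions = 4,
                      coord_jitter = c(0.15, 0.45),
                      season = c("05-01", "09-30"),
                      missing_plot_frac = 0,
                      missing_weather_frac = 0,
                      seed = 1) {
  vc <- list(v_g_add = 0.35, v_g_dom = 0.05, v_env = 2.0, v_gxe = 0.25,
             v_block = 0.05, v_row = 0.03, v_col = 0.03, v_resid = 1.5)
  vc[names(var_components)] <- var_components
  unknown <- setdiff(names(var_components), names(vc))
  if (length(unknown))
    stop("unknown variance component(s): ", paste(unknown, collapse = ", "))
  if (any(unlist(vc) < 0)) stop("all variance components must be >= 0")

  years <- as.integer(years)
  if (length(years) < 1L || is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing")
  if (n_parents < 1) stop("invalid config: n_parents must be >= 1")
  if (n_markers < 1) stop("invalid config: n_markers must be >= 1")
  if (reps < 1) stop("invalid config: reps must be >= 1")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an interval within (0, 0.5]")
  if (coverage <= 0 || coverage > 1) stop("coverage must be in (0, 1]")

  if (is.null(testers_by_year)) {
    testers_by_year <- stats::setNames(vector("list", length(years)),
                                       as.character(years))
    for (i in seq_along(years)) {
      testers_by_year[[i]] <- if (i == 1L) c("T1", "T2")
                              else c("T1", "T3", "T4", "T5")
    }
  }
  if (is.null(names(testers_by_year)))
    names(testers_by_year) <- as.character(years)
  if (!setequal(names(testers_by_year), as.character(years)))
    stop("testers_by_year must be named by the configured years")
  if (any(vapply(testers_by_year, length, 1L) == 0L))
    stop("invalid config: empty tester list for at least one year")

  n_env <- rep_len(as.integer(n_environments_per_year), length(years))
  cfg <- list(n_parents = as.integer(n_parents),
              testers_by_year = testers_by_year[as.character(years)],
              n_markers = as.integer(n_markers),
              n_chromosomes = as.integer(n_chromosomes),
              n_environments_per_year = n_env,
              years = years,
              reps = as.integer(reps),
              field_cols = as.integer(field_cols),
              rows_per_block = as.integer(rows_per_block),
              coverage = coverage,
              var_components = vc,
              intercept = intercept,
              maf_range = maf_range,
              ld_dup_frac = ld_dup_frac,
              other_tester_frac = other_tester_frac,
              n_other_testers = as.integer(n_other_testers),
              env_index_cor = env_index_cor,
              gxe_index_cor = gxe_index_cor,
              n_regions = as.integer(n_regions),
              coord_jitter = rep_len(coord_jitter, 2L),
              season = season,
              missing_plot_frac = missing_plot_frac,
              missing_weather_frac = missing_weather_frac,
              seed = as.integer(seed))
  class(cfg) <- "SimConfig"
  cfg
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    "SimConfig: %d parents, %d markers, years %s, %s envs/year, seed %d\n",
    x$n_parents, x$n_markers, paste(range(x$years), collapse = "-"),
    paste(x$n_environments_per_year, collapse = "/"), x$seed))
  invisible(x)
}

#' Environment table implied by a configuration
#'
#' Locations are nested across years: year i uses locations
#' L01..L<n_env[i]>, so early locations persist (giving lagged-yield
#' history) while the network grows.
#' @noRd
envTable <- function(cfg) {
  out <- do.call(rbind, lapply(seq_along(cfg$years), function(i) {
    loc <- sprintf("L%02d", seq_len(cfg$n_environments_per_year[i]))
    data.frame(Env = paste0(loc, "_", cfg$years[i]), Location = loc,
               Year = cfg$years[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Latent per-environment index shared by the phenotype generator and
#' the environment layers (weather shift, EC signal), so that
#' environmental features carry recoverable signal about environment
#' effects.
#' @noRd
envIndex <- function(cfg) {
  et <- envTable(cfg)
  set.seed(deriveSeed(cfg$seed, "env-index"))
  z <- stats::rnorm(nrow(et))
  if (length(z) >= 2L && stats::sd(z) > 0) z <- as.vector(scale(z))
  stats::setNames(z, et$Env)
}
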