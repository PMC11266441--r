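# Synthetic hybrid population: inbred parents crossed to a tester panel.

#' Generate the hybrid population (genotypes + pedigree)
#'
#' Simulates fully inbred parent and tester genomes at biallelic
#' markers and crosses them: each hybrid's dosage at a marker is the
#' sum of one parent allele and one tester allele, so heterozygosity
#' (and hence dominance) is abundant, as in a parent x tester maize
#' program. Tester usage per year follows `cfg$testers_by_year`; a
#' small minority of hybrids come from minor testers present in the
#' later years. Marker allele frequencies are drawn within
#' `cfg$maf_range`; tester alleles are assigned frequency-matched so
#' the tiny tester panel does not distort the realized panel MAF. A
#' fraction `cfg$ld_dup_frac` of markers are near-duplicates of a
#' neighbouring marker to give the LD pruner something to remove.
#'
#' @param cfg a [simConfig()] object.
#' @return list with elements `geno` (a [MarkerMatrix-class] over all
#'   hybrids), `pedigree` (`data.frame`: `Hybrid`, `Parent`, `Tester`)
#'   and `hybrids_by_year` (list mapping year to the hybrid cohort
#'   evaluated that year).
#' @examples
#' pop <- generatePopulation(simConfig(n_parents = 3, n_markers = 20,
#'                                     seed = 1))
#' dim(dosage(pop$geno))
#' @export
generatePopulation <- function(cfg) {
  if (!inherits(cfg, "SimConfig")) stop("cfg must come from simConfig()")
  set.seed(deriveSeed(cfg$seed, "population"))

  years <- cfg$years
  main_testers <- unique(unlist(cfg$testers_by_year))
  later_years <- if (length(years) > 1L) years[-1L] else integer()
  minor_testers <- if (cfg$n_other_testers > 0L && length(later_years))
    sprintf("M%d", seq_len(cfg$n_other_testers)) else character()
  testers <- c(main_testers, minor_testers)

  parents <- sprintf("P%03d", seq_len(cfg$n_parents))

  ## main hybrids: every parent crossed to every main tester
  ped_main <- expand.grid(Parent = parents, Tester = main_testers,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ## minor hybrids: a small fraction of the later-year cohort size
  ped_minor <- NULL
  if (length(minor_testers)) {
    cohort_late <- cfg$n_parents *
      length(cfg$testers_by_year[[as.character(later_years[1])]])
    n_minor <- max(length(minor_testers),
                   round(cfg$other_tester_frac * cohort_late))
    mt <- rep_len(minor_testers, n_minor)
    mp <- sample(parents, n_minor, replace = n_minor > length(parents))
    ped_minor <- data.frame(Parent = mp, Tester = mt,
                            stringsAsFactors = FALSE)
    ped_minor <- unique(ped_minor)
  }
  ped <- rbind(ped_main, ped_minor)
  ped$Hybrid <- paste0(ped$Parent, "x", ped$Tester)
  ped <- ped[, c("Hybrid", "Parent", "Tester")]

  ## marker map: base markers plus near-duplicates within chromosomes
  n_dup <- round(cfg$n_markers * cfg$ld_dup_frac)
  n_base <- cfg$n_markers - n_dup
  if (n_base < 1L) stop("ld_dup_frac leaves no base markers")
  chrom_base <- sort(rep_len(seq_len(cfg$n_chromosomes), n_base))
  pos_base <- unlist(lapply(split(seq_len(n_base), chrom_base), function(i)
    sort(sample.int(1e8, length(i)))), use.names = FALSE)

  p <- stats::runif(n_base, cfg$maf_range[1], cfg$maf_range[2])

  ## inbred genomes: one allele per individual, doubled in the gamete
  par_allele <- matrix(stats::rbinom(length(parents) * n_base, 1L,
                                     rep(p, each = length(parents))),
                       nrow = length(parents),
                       dimnames = list(parents, NULL))
  ## frequency-matched alleles for the main testers (each carries many
  ## hybrids, so a plain Bernoulli draw over so few testers would let
  ## the realized panel MAF drift far from the configured range):
  ## round(p * n_main) of them carry the allele. Minor testers carry a
  ## negligible hybrid share and draw Bernoulli(p).
  tst_allele <- matrix(0L, nrow = length(testers), ncol = n_base,
                       dimnames = list(testers, NULL))
  n_main_t <- length(main_testers)
  carriers <- pmin(n_main_t, round(p * n_main_t))
  for (j in seq_len(n_base)) {
    if (carriers[j] > 0L)
      tst_allele[sample.int(n_main_t, carriers[j]), j] <- 1L
  }
  if (length(minor_testers)) {
    mi <- match(minor_testers, testers)
    tst_allele[mi, ] <- stats::rbinom(length(mi) * n_base, 1L,
                                      rep(p, each = length(mi)))
  }

  ## append near-duplicate markers: copy a base marker, flip ~2% alleles
  dup_of <- integer(0)
  if (n_dup > 0L) {
    dup_of <- sample.int(n_base, n_dup, replace = TRUE)
    flip_p <- 0.02
    par_dup <- par_allele[, dup_of, drop = FALSE]
    flip <- matrix(stats::rbinom(length(par_dup), 1L, flip_p) == 1L,
                   nrow = nrow(par_dup))
    par_dup[flip] <- 1L - par_dup[flip]
    tst_dup <- tst_allele[, dup_of, drop = FALSE]
    par_allele <- cbind(par_allele, par_dup)
    tst_allele <- cbind(tst_allele, tst_dup)
  }

  chrom <- c(chrom_base, chrom_base[dup_of])
  pos <- c(pos_base, pos_base[dup_of] + 1L + seq_len(n_dup) %% 7L)
  ord <- order(chrom, pos)
  marker_id <- sprintf("SNP_%05d", seq_len(cfg$n_markers))

  dos <- par_allele[ped$Parent, ord, drop = FALSE] +
         tst_allele[ped$Tester, ord, drop = FALSE]
  dimnames(dos) <- list(ped$Hybrid, marker_id)
  markers <- data.frame(id = marker_id, chrom = chrom[ord], pos = pos[ord],
                        stringsAsFactors = FALSE)

  geno <- methods::new("MarkerMatrix", dosage = dos, markers = markers)

  hby <- lapply(cfg$testers_by_year, function(tst)
    ped$Hybrid[ped$Tester %in% tst])
  if (length(minor_testers)) {
    minors <- ped$Hybrid[ped$Tester %in% minor_testers]
    for (y in as.character(later_years))
      hby[[y]] <- c(hby[[y]], minors)
  }
  names(hby) <- as.character(years)

  list(geno = geno, pedigree = ped, hybrids_by_year = hby)
}
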