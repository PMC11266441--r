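# Stage 3: marker QC and genomic relationship matrices.
#
# Pipeline order is fixed: individuals -> MAF filter -> LD prune ->
# relationship matrices, with allele frequencies always computed on
# the filtered hybrid set.

#' Read a MarkerMatrix from a VCF file
#'
#' Parses a biallelic-SNP VCF (GT field) and decodes genotypes to
#' additive dosages (count of ALT alleles; `NA` for missing calls).
#'
#' @param path VCF file (plain or gzipped).
#' @return a [MarkerMatrix-class] (hybrids x markers).
#' @export
markerMatrixFromVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt_count <- function(g) {
    lengths(regmatches(g, gregexpr("1", g)))
  }
  dos <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  ok <- !is.na(gt) & !grepl("\\.", gt)
  dos[ok] <- alt_count(gt[ok])
  fix <- vcfR::getFIX(v)
  markers <- data.frame(id = fix[, "ID"],
                        chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  ids <- markers$id
  ids[is.na(ids) | ids == "."] <- paste0(markers$chrom, "_",
                                         markers$pos)[is.na(ids) | ids == "."]
  markers$id <- ids
  dimnames(dos) <- list(ids, colnames(gt))
  methods::new("MarkerMatrix", dosage = t(dos), markers = markers)
}

#' Write a MarkerMatrix to a VCF v4.2 file
#'
#' Emits biallelic SNPs with a GT field (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param m a [MarkerMatrix-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeVCF <- function(m, path) {
  stopifnot(methods::is(m, "MarkerMatrix"))
  d <- t(m@dosage)                       # markers x hybrids
  gt <- matrix("./.", nrow(d), ncol(d))
  gt[!is.na(d) & d == 0] <- "0/0"
  gt[!is.na(d) & d == 1] <- "0/1"
  gt[!is.na(d) & d == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##source=enviroGP",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", colnames(d)),
                    collapse = "\t"))
  body <- paste(m@markers$chrom, m@markers$pos, m@markers$id, "A", "T",
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Keep only the listed hybrids
#'
#' @param m a [MarkerMatrix-class].
#' @param keep_ids hybrid ids to retain, in the requested order.
#' @return the filtered [MarkerMatrix-class].
#' @export
filterIndividuals <- function(m, keep_ids) {
  stopifnot(methods::is(m, "MarkerMatrix"))
  missing <- setdiff(keep_ids, rownames(m@dosage))
  if (length(missing))
    stop("missing sample(s) in genotype data: ",
         paste(missing, collapse = ", "))
  methods::new("MarkerMatrix", dosage = m@dosage[keep_ids, , drop = FALSE],
               markers = m@markers)
}

#' Per-marker minor allele frequency
#' @noRd
markerMAF <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Drop markers below a minor-allele-frequency threshold
#'
#' MAF is computed from the non-missing dosages of the current hybrid
#' set; markers with MAF strictly below the threshold are removed.
#'
#' @param m a [MarkerMatrix-class].
#' @param threshold MAF threshold in `[0, 0.5]` (default 0.01).
#' @return the filtered [MarkerMatrix-class].
#' @export
filterMAF <- function(m, threshold = 0.01) {
  stopifnot(methods::is(m, "MarkerMatrix"))
  if (threshold < 0 || threshold > 0.5)
    stop("threshold must be in [0, 0.5]")
  keep <- markerMAF(m@dosage) >= threshold
  keep[is.na(keep)] <- FALSE
  methods::new("MarkerMatrix",
               dosage = m@dosage[, keep, drop = FALSE],
               markers = m@markers[keep, , drop = FALSE])
}

#' Prune markers in high linkage disequilibrium
#'
#' Sliding-window pairwise pruning on the squared Pearson correlation
#' of dosages (indep-pairwise semantics): within each window of
#' `window` surviving markers, while any pair has r^2 strictly above
#' `r2`, remove one marker of the worst pair — the one with the higher
#' mean r^2 to the other markers in the window (ties broken by
#' position, the later marker going). The window then slides forward
#' by `step` markers. Markers must be ordered by chromosome and
#' position; windows never span chromosomes.
#'
#' @param m a [MarkerMatrix-class].
#' @param window window size in markers (default 100).
#' @param step step size in markers (default 20).
#' @param r2 squared-correlation threshold (default 0.9).
#' @return the pruned [MarkerMatrix-class].
#' @export
ldPrune <- function(m, window = 100, step = 20, r2 = 0.9) {
  stopifnot(methods::is(m, "MarkerMatrix"))
  mk <- m@markers
  ## chromosomes compared in order of first appearance (so "10" does not
  ## sort before "2" after a VCF round trip)
  o <- order(match(mk$chrom, unique(mk$chrom)), mk$pos)
  if (!identical(o, seq_len(nrow(mk))))
    stop("ordering error: markers must be sorted by chromosome and position")
  keep_all <- character()
  for (ch in unique(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    alive <- pruneChromosome(m@dosage[, idx, drop = FALSE], window, step, r2)
    keep_all <- c(keep_all, mk$id[idx][alive])
  }
  sel <- mk$id %in% keep_all
  methods::new("MarkerMatrix",
               dosage = m@dosage[, sel, drop = FALSE],
               markers = mk[sel, , drop = FALSE])
}

#' Greedy windowed pruning within one chromosome.
#' @noRd
pruneChromosome <- function(dos, window, step, r2) {
  n <- ncol(dos)
  alive <- rep(TRUE, n)
  start <- 1L
  repeat {
    live <- which(alive)
    if (length(live) < 2L || start > length(live)) break
    end <- min(start + window - 1L, length(live))
    win <- live[start:end]
    if (length(win) >= 2L) {
      removed <- pruneWindow(dos[, win, drop = FALSE], r2)
      alive[win[removed]] <- FALSE
    }
    if (end >= sum(alive)) break
    start <- start + step
  }
  alive
}

#' @noRd
pruneWindow <- function(dw, r2) {
  w <- ncol(dw)
  active <- rep(TRUE, w)
  R <- suppressWarnings(stats::cor(dw, use = "pairwise.complete.obs")^2)
  R[!is.finite(R)] <- 0
  diag(R) <- NA
  repeat {
    sub <- R[active, active, drop = FALSE]
    if (all(is.na(sub)) || max(sub, na.rm = TRUE) <= r2) break
    ij <- which(sub == max(sub, na.rm = TRUE), arr.ind = TRUE)[1, ]
    cand <- which(active)[ij]
    mean_r2 <- vapply(cand, function(k)
      mean(R[k, active & seq_len(w) != k], na.rm = TRUE), 0)
    drop <- if (mean_r2[1] > mean_r2[2]) cand[1]
            else if (mean_r2[2] > mean_r2[1]) cand[2]
            else max(cand)                       # tie: later position goes
    active[drop] <- FALSE
    if (sum(active) < 2L) break
  }
  which(!active)
}

#' Additive genomic relationship matrix (VanRaden)
#'
#' A = Z Z' / (2 sum p (1 - p)) with Z the dosage matrix centered at
#' 2p per marker (p = counted-allele frequency on the current hybrid
#' set). Missing dosages are mean-imputed per marker. Monomorphic
#' markers must be removed first (MAF filter); their presence raises
#' a division-guard error.
#'
#' @param m a [MarkerMatrix-class].
#' @return a [GenomicRelationship-class] of kind `"additive"`.
#' @export
grmAdditive <- function(m) {
  d <- imputedDosage(m)
  p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1))
    stop("division guard: monomorphic marker(s) present; apply filterMAF() first")
  Z <- sweep(d, 2, 2 * p)
  A <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  A <- (A + t(A)) / 2
  methods::new("GenomicRelationship", kind = "additive", matrix = A)
}

#' Dominance genomic relationship matrix (Vitezica)
#'
#' Per-marker dominance coding w = -2p^2, 2pq, -2q^2 for dosages
#' 0, 1, 2 (p the counted-allele frequency, q = 1 - p), which has
#' zero mean under Hardy-Weinberg proportions; D = W W' / sum((2pq)^2).
#' Missing dosages are mean-imputed before coding.
#'
#' @param m a [MarkerMatrix-class].
#' @return a [GenomicRelationship-class] of kind `"dominance"`.
#' @export
grmDominance <- function(m) {
  d <- imputedDosage(m)
  p <- colMeans(d) / 2
  if (any(p <= 0 | p >= 1))
    stop("division guard: monomorphic marker(s) present; apply filterMAF() first")
  q <- 1 - p
  W <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  for (j in seq_len(ncol(d))) {
    W[, j] <- ifelse(d[, j] < 0.5, -2 * p[j]^2,
                     ifelse(d[, j] < 1.5, 2 * p[j] * q[j], -2 * q[j]^2))
  }
  D <- tcrossprod(W) / sum((2 * p * q)^2)
  D <- (D + t(D)) / 2
  methods::new("GenomicRelationship", kind = "dominance", matrix = D)
}

#' @noRd
imputedDosage <- function(m) {
  stopifnot(methods::is(m, "MarkerMatrix"))
  d <- m@dosage
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  d
}

#' Principal components of population structure
#'
#' Centered PCA of the dosage matrix (or eigen-decomposition of a
#' relationship matrix), returning component scores — e.g. for
#' plotting hybrids coloured by tester — and explained-variance
#' ratios.
#'
#' @param x a [MarkerMatrix-class] or [GenomicRelationship-class].
#' @param n_components number of components to return.
#' @return list with `scores` (hybrids x components) and `explained`
#'   (non-increasing ratios summing to at most 1).
#' @export
pcaPopulation <- function(x, n_components = 10) {
  if (methods::is(x, "MarkerMatrix")) {
    d <- imputedDosage(x)
    k <- min(n_components, nrow(d) - 1L, ncol(d))
    pc <- stats::prcomp(d, center = TRUE, scale. = FALSE)
    scores <- pc$x[, seq_len(k), drop = FALSE]
    explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  } else if (methods::is(x, "GenomicRelationship")) {
    e <- eigen(x@matrix, symmetric = TRUE)
    k <- min(n_components, sum(e$values > 1e-10))
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(0, e$values[seq_len(k)])), k)
    rownames(scores) <- rownames(x@matrix)
    colnames(scores) <- paste0("PC", seq_len(k))
    explained <- (pmax(0, e$values) / sum(pmax(0, e$values)))[seq_len(k)]
  } else {
    stop("x must be a MarkerMatrix or GenomicRelationship")
  }
  list(scores = scores, explained = explained)
}
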