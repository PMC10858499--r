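#' Differential-test configuration
#'
#' @param trim_m Fraction of M-values (log fold changes vs the reference
#'   sample) trimmed from each tail in TMM (default 0.30, the classical
#'   value).
#' @param trim_a Fraction of A-values (average log abundances) trimmed from
#'   each tail (default 0.05).
#' @param prior_weight Pseudo-observations shrinking each region's
#'   method-of-moments dispersion toward the pooled common dispersion
#'   (default 20).
#' @param lfc_threshold Absolute log2 fold-change threshold for significance
#'   (default 1).
#' @param fdr_threshold BH FDR threshold for significance (default 0.05).
#' @return A list of class `diff_config`.
#' @export
diff_config <- function(trim_m = 0.30, trim_a = 0.05, prior_weight = 20,
                        lfc_threshold = 1, fdr_threshold = 0.05) {
  if (trim_m < 0 || trim_m >= 0.5 || trim_a < 0 || trim_a >= 0.5)
    stop("trims must lie in [0, 0.5)")
  if (lfc_threshold <= 0 || fdr_threshold <= 0)
    stop("thresholds must be positive")
  structure(list(trim_m = trim_m, trim_a = trim_a,
                 prior_weight = prior_weight,
                 lfc_threshold = lfc_threshold,
                 fdr_threshold = fdr_threshold),
            class = "diff_config")
}

#' Genome-wide 10 kb bin counts across samples
#'
#' Midpoint-assigned fragment counts per genomic bin per sample, used to
#' compute compositional normalisation factors. Bins with zero counts in all
#' samples are dropped.
#'
#' @param frags_list Named list of `fragment_set`s.
#' @param bin Bin width in bp (default 10000).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return List with `counts` (bins x samples integer matrix),
#'   `lib_sizes` (named vector) and `bins` (`GRanges` of retained bins).
#' @export
bin_genome_counts <- function(frags_list, bin = 10000L, chrom_sizes) {
  stopifnot(length(frags_list) >= 1)
  sizes <- as_chrom_sizes(chrom_sizes)
  nm <- names(frags_list) %||% vapply(frags_list, `[[`, "", "sample_id")
  cols <- lapply(frags_list, function(fs) {
    tr <- coverage_track(fs, bin, sizes)
    unlist(tr$counts, use.names = FALSE)
  })
  counts <- do.call(cbind, cols)
  colnames(counts) <- nm
  nbin <- ceiling(sizes / bin)
  start0 <- unlist(lapply(nbin, function(k) (seq_len(k) - 1) * bin),
                   use.names = FALSE)
  chr_all <- rep(names(sizes), nbin)
  bins_gr <- GenomicRanges::GRanges(
    chr_all, IRanges::IRanges(start0 + 1,
                              pmin(start0 + bin, sizes[chr_all])))
  keep <- rowSums(counts) > 0
  list(counts = counts[keep, , drop = FALSE],
       lib_sizes = setNames(vapply(frags_list, `[[`, 0L, "library_size"), nm),
       bins = bins_gr[keep])
}

#' Trimmed mean of M-values (TMM) normalisation factors
#'
#' The reference sample is the one whose upper-quartile count fraction is
#' closest to the mean upper quartile. For every other sample, M (log2 ratio
#' of count proportions vs the reference) and A (average log2 proportion) are
#' computed over bins positive in both; the `trim_m` tails of M and `trim_a`
#' tails of A are trimmed; the factor is 2 to the precision-weighted mean of
#' the surviving M values (weights: inverse asymptotic binomial variance).
#' Factors are rescaled so their geometric mean is 1.
#'
#' @param counts Bins x samples count matrix (e.g. from
#'   [bin_genome_counts()]).
#' @param lib_sizes Named vector of library sizes (default: column sums).
#' @param config A `diff_config`.
#' @return Named numeric vector of normalisation factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        config = diff_config()) {
  ns <- ncol(counts)
  if (ns < 2) stop("need at least 2 samples")
  uq <- vapply(seq_len(ns), function(j)
    quantile(counts[, j], 0.75, names = FALSE) / lib_sizes[j], 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ns), function(j) {
    if (j == ref) return(1)
    ok <- counts[, j] > 0 & counts[, ref] > 0
    if (!any(ok)) stop("no bins survive trimming between samples ",
                       j, " and ", ref)
    yk <- counts[ok, j]; yr <- counts[ok, ref]
    nk <- lib_sizes[j]; nr <- lib_sizes[ref]
    M <- log2((yk / nk) / (yr / nr))
    A <- 0.5 * log2((yk / nk) * (yr / nr))
    w <- 1 / ((nk - yk) / (nk * yk) + (nr - yr) / (nr * yr))
    # rank-based double trimming (robust to heavily tied M or A values)
    n <- length(M)
    rank_keep <- function(v, trim) {
      r <- rank(v, ties.method = "first")
      r > floor(n * trim) & r <= n - floor(n * trim)
    }
    keep <- rank_keep(M, config$trim_m) & rank_keep(A, config$trim_a)
    if (!any(keep)) stop("no bins survive trimming between samples ",
                         j, " and ", ref)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }, 0)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Count fragments at consensus regions across samples
#'
#' @param frags_list Named list of `fragment_set`s.
#' @param regions `GRanges` of consensus regions.
#' @return Integer matrix regions x samples, with a `lib_sizes` attribute.
#' @export
region_counts <- function(frags_list, regions) {
  nm <- names(frags_list) %||% vapply(frags_list, `[[`, "", "sample_id")
  m <- vapply(frags_list, function(fs) {
    al <- align_seqlevels(granges_only(regions), fs$ranges)
    GenomicRanges::countOverlaps(al$a, al$b, ignore.strand = TRUE)
  }, integer(length(regions)))
  m <- matrix(m, nrow = length(regions), dimnames = list(NULL, nm))
  attr(m, "lib_sizes") <- setNames(
    vapply(frags_list, `[[`, 0L, "library_size"), nm)
  m
}

# Vectorised NB log-likelihood (constants in y dropped) at rate q per region:
# mu_j = q * L_j, size = 1/phi per region. counts: regions x samples matrix.
nb_loglik <- function(counts, L, q, phi) {
  ll <- numeric(nrow(counts))
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]
    mu <- q * L[j]
    t1 <- ifelse(y > 0, y * log(pmax(mu, 1e-300)), 0)
    ll <- ll + t1 - (y + 1 / phi) * log1p(phi * mu)
  }
  ll
}

# Vectorised Newton MLE of the per-region rate q (counts ~ NB(q * L_j, 1/phi)).
nb_fit_rate <- function(counts, L, phi, iter = 30L) {
  q <- (rowSums(counts) + 0.1) / sum(L)
  theta <- log(q)
  for (it in seq_len(iter)) {
    grad <- numeric(nrow(counts)); hess <- numeric(nrow(counts))
    for (j in seq_len(ncol(counts))) {
      y <- counts[, j]
      mu <- exp(theta) * L[j]
      r <- phi * mu / (1 + phi * mu)
      grad <- grad + y - (y + 1 / phi) * r
      hess <- hess - (y + 1 / phi) * r / (1 + phi * mu)
    }
    step <- grad / pmin(hess, -1e-10)
    step <- pmax(pmin(step, 2), -2)
    theta <- theta - step
    if (max(abs(step)) < 1e-10) break
  }
  zero <- rowSums(counts) == 0
  q <- exp(theta)
  q[zero] <- 0
  q
}

#' Negative-binomial two-group differential test
#'
#' Per region: effective library sizes (library size x TMM factor) are used as
#' offsets; a method-of-moments dispersion is estimated from the residuals
#' around condition means and shrunk toward the pooled common dispersion with
#' `prior_weight` pseudo-observations; condition rates are fitted by NB
#' maximum likelihood and the null of equal rates is tested by a 1-df
#' likelihood-ratio chi-square; p-values are BH-adjusted across regions. The
#' log2 fold change contrasts the offset-normalised condition means with a
#' 0.5 pseudocount, second condition level vs first.
#'
#' @param counts Regions x samples integer matrix.
#' @param lib_sizes Named vector of library sizes (default: the matrix's
#'   `lib_sizes` attribute, else column sums).
#' @param factors Normalisation factors from [tmm_factors()] (default all 1).
#' @param condition Factor/character of length ncol(counts) with exactly two
#'   levels and >= 2 samples per level.
#' @param config A `diff_config`.
#' @return data.frame per region: `log2FC`, `dispersion`, `pvalue`, `fdr`,
#'   `significant`.
#' @export
nb_test <- function(counts, lib_sizes = NULL, factors = NULL, condition,
                    config = diff_config()) {
  counts <- as.matrix(counts)
  lib_sizes <- lib_sizes %||% attr(counts, "lib_sizes") %||% colSums(counts)
  factors <- factors %||% rep(1, ncol(counts))
  condition <- as.factor(condition)
  lv <- levels(droplevels(condition))
  if (length(lv) != 2) stop("condition must have exactly two levels")
  if (any(table(condition) < 2))
    stop("each condition needs >= 2 samples (dispersion unidentifiable)")
  L <- as.numeric(lib_sizes) * as.numeric(factors)
  gA <- which(condition == lv[1]); gB <- which(condition == lv[2])
  # moment dispersion around condition means (normalised rate scale)
  qA0 <- rowSums(counts[, gA, drop = FALSE]) / sum(L[gA])
  qB0 <- rowSums(counts[, gB, drop = FALSE]) / sum(L[gB])
  mu <- cbind(outer(qA0, L[gA]), outer(qB0, L[gB]))
  y <- counts[, c(gA, gB), drop = FALSE]
  # leverage correction (1 - p/n): fitted group means absorb p = 2 of the
  # n residual degrees of freedom, deflating raw squared residuals
  h <- 2 / ncol(counts)
  num <- rowSums((y - mu)^2) - (1 - h) * rowSums(mu)
  den <- (1 - h) * rowSums(mu^2)
  phi_raw <- pmax(num / pmax(den, 1e-300), 0)
  df_res <- ncol(counts) - 2
  phi_common <- max(mean(phi_raw), 1e-8)
  phi <- (df_res * phi_raw + config$prior_weight * phi_common) /
    (df_res + config$prior_weight)
  phi <- pmax(phi, 1e-8)
  # null and alternative fits
  q0 <- nb_fit_rate(counts, L, phi)
  qA <- nb_fit_rate(counts[, gA, drop = FALSE], L[gA], phi)
  qB <- nb_fit_rate(counts[, gB, drop = FALSE], L[gB], phi)
  ll0 <- nb_loglik(counts, L, q0, phi)
  llA <- nb_loglik(counts[, gA, drop = FALSE], L[gA], qA, phi) +
    nb_loglik(counts[, gB, drop = FALSE], L[gB], qB, phi)
  lrt <- pmax(2 * (llA - ll0), 0)
  p <- pchisq(lrt, df = 1, lower.tail = FALSE)
  fdr <- p.adjust(p, method = "BH")
  lfc <- log2(((rowSums(counts[, gB, drop = FALSE]) + 0.5) / sum(L[gB])) /
                ((rowSums(counts[, gA, drop = FALSE]) + 0.5) / sum(L[gA])))
  data.frame(log2FC = lfc, dispersion = phi, pvalue = p, fdr = fdr,
             significant = abs(lfc) > config$lfc_threshold &
               fdr < config$fdr_threshold)
}

#' Differential bivalency calls requiring both reChIP orientations
#'
#' A region is differentially bivalent only when it is significant with the
#' same fold-change sign in both the K4-K27 and K27-K4 differential results
#' (which must be row-aligned over the same region set). Promoters are called
#' by >= 1 bp overlap with such regions.
#'
#' @param res_k4k27,res_k27k4 data.frames from [nb_test()] over the same
#'   regions.
#' @param regions `GRanges` the rows refer to.
#' @param promoters Optional promoter classification data.frame from
#'   [classify_promoters()].
#' @param known_genes Optional character vector of previously known dependent
#'   genes, splitting promoter calls into known vs novel.
#' @return List with `region_calls` (logical), `n_regions`, `n_lost`,
#'   `n_gained`, and when promoters are given `promoter_genes`,
#'   `n_promoters`, `n_known`, `n_novel`.
#' @export
call_differential_bivalency <- function(res_k4k27, res_k27k4, regions,
                                        promoters = NULL,
                                        known_genes = NULL) {
  stopifnot(nrow(res_k4k27) == nrow(res_k27k4),
            nrow(res_k4k27) == length(regions))
  both <- res_k4k27$significant & res_k27k4$significant &
    sign(res_k4k27$log2FC) == sign(res_k27k4$log2FC)
  out <- list(region_calls = both,
              n_regions = sum(both),
              n_lost = sum(both & res_k4k27$log2FC < 0),
              n_gained = sum(both & res_k4k27$log2FC > 0))
  if (!is.null(promoters)) {
    prom_gr <- GenomicRanges::GRanges(
      promoters$chrom, IRanges::IRanges(promoters$start + 1, promoters$end))
    hit <- overlaps_any(prom_gr, regions[both]) & !is.na(promoters$class)
    genes <- promoters$gene[hit]
    out$promoter_genes <- genes
    out$n_promoters <- length(genes)
    if (!is.null(known_genes)) {
      out$n_known <- length(intersect(genes, known_genes))
      out$n_novel <- length(setdiff(genes, known_genes))
    }
  }
  out
}
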