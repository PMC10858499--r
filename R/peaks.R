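#' Peak-calling configuration
#'
#' Parameters of the Poisson island caller for diffuse histone marks: the
#' genome is tiled into `bin_size` windows, windows individually enriched over
#' the control-derived Poisson expectation are chained into islands allowing
#' up to `gaps_allowed` consecutive ineligible windows inside an island, and
#' islands are scored by the Poisson upper tail of their summed counts.
#'
#' @param bin_size Window size in bp (default 100).
#' @param gaps_allowed Maximum consecutive ineligible windows bridgeable
#'   inside an island (default 1).
#' @param fragment_size 5'-extension length applied when inputs are reads
#'   rather than full fragments (default 147).
#' @param island_fdr Benjamini-Hochberg FDR cutoff on islands (default 0.05).
#' @param window_p0 Poisson upper-tail threshold for window eligibility
#'   (default 0.2, the classical island-caller default).
#' @param post_log2fc Post-filter: retain peaks with log2 fold change strictly
#'   above this (default 2).
#' @param post_fdr Post-filter FDR threshold (default 0.05).
#' @param pseudocount Added to counts and expectations in the fold-change
#'   (default 0.5).
#' @return A list of class `peak_call_config`.
#' @export
peak_call_config <- function(bin_size = 100L, gaps_allowed = 1L,
                             fragment_size = 147L, island_fdr = 0.05,
                             window_p0 = 0.2, post_log2fc = 2,
                             post_fdr = 0.05, pseudocount = 0.5) {
  check_count(bin_size, "bin_size", min = 1)
  check_count(gaps_allowed, "gaps_allowed", min = 0)
  check_prob(island_fdr, "island_fdr")
  check_prob(window_p0, "window_p0")
  check_prob(post_fdr, "post_fdr")
  structure(list(bin_size = as.integer(bin_size),
                 gaps_allowed = as.integer(gaps_allowed),
                 fragment_size = as.integer(fragment_size),
                 island_fdr = island_fdr, window_p0 = window_p0,
                 post_log2fc = post_log2fc, post_fdr = post_fdr,
                 pseudocount = pseudocount),
            class = "peak_call_config")
}

# Chain eligible bins into islands bridging <= gaps_allowed consecutive
# ineligible bins; islands start and end on eligible bins.
# Returns a matrix with columns first, last (bin indices, 1-based).
chain_islands <- function(eligible, gaps_allowed) {
  idx <- which(eligible)
  if (!length(idx)) return(matrix(integer(0), ncol = 2))
  gap <- diff(idx)
  new_island <- c(TRUE, gap > gaps_allowed + 1L)
  grp <- cumsum(new_island)
  cbind(first = idx[!duplicated(grp)],
        last = idx[!duplicated(grp, fromLast = TRUE)])
}

#' Call enriched islands against a control sample
#'
#' Bins treatment and control fragments by midpoint, computes a per-bin
#' expected count from the control scaled to the treatment library size (with
#' a uniform-background floor so zero-control bins are never free), flags
#' bins whose Poisson upper tail falls below `window_p0`, chains flagged bins
#' into islands allowing short internal gaps, scores each island by the
#' Poisson upper tail of its summed treatment count against its summed
#' expectation, and keeps islands passing the BH FDR cutoff.
#'
#' @param treatment,control `fragment_set`s over the same chromosome universe.
#' @param config A `peak_call_config`.
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param extend_reads If TRUE, 5'-extend inputs to `fragment_size` before
#'   binning (use when inputs are reads, not full fragments).
#' @return A `GRanges` peak set with metadata columns `treat_count`,
#'   `ctrl_expect`, `log2FC`, `pvalue`, `fdr`, non-overlapping within the set.
#' @export
call_islands <- function(treatment, control, config = peak_call_config(),
                         chrom_sizes, extend_reads = FALSE) {
  stopifnot(is(treatment, "fragment_set"), is(control, "fragment_set"))
  sizes <- as_chrom_sizes(chrom_sizes)
  t_chr <- unique(as.character(seqnames(treatment$ranges)))
  c_chr <- unique(as.character(seqnames(control$ranges)))
  if (length(setdiff(c(t_chr, c_chr), names(sizes))))
    stop("mismatched chromosome universe between samples and chrom_sizes")
  if (treatment$library_size == 0L) stop("treatment sample is empty")
  ext <- if (extend_reads) config$fragment_size else NULL
  tt <- coverage_track(treatment, config$bin_size, sizes, extend_to = ext)
  Tn <- treatment$library_size
  Cn <- control$library_size
  genome_length <- sum(sizes)
  lambda_floor <- Tn * config$bin_size / genome_length
  if (Cn == 0L) {
    warning("empty control: falling back to uniform background expectation")
    ct <- NULL
  } else {
    ct <- coverage_track(control, config$bin_size, sizes, extend_to = ext)
  }
  res <- list()
  for (chr in names(sizes)) {
    k <- tt$counts[[chr]]
    lam <- if (is.null(ct)) rep(lambda_floor, length(k))
           else pmax(ct$counts[[chr]] * (Tn / Cn), lambda_floor)
    eligible <- k > 0 & ppois(k - 1, lam, lower.tail = FALSE) < config$window_p0
    isl <- chain_islands(eligible, config$gaps_allowed)
    if (!nrow(isl)) next
    K <- vapply(seq_len(nrow(isl)),
                function(i) sum(k[isl[i, 1]:isl[i, 2]]), 0)
    L <- vapply(seq_len(nrow(isl)),
                function(i) sum(lam[isl[i, 1]:isl[i, 2]]), 0)
    p <- ppois(K - 1, L, lower.tail = FALSE)
    res[[chr]] <- data.frame(
      chrom = chr,
      start0 = (isl[, 1] - 1L) * config$bin_size,
      end0 = pmin(isl[, 2] * config$bin_size, sizes[[chr]]),
      treat_count = K, ctrl_expect = L, pvalue = p)
  }
  if (!length(res)) return(empty_peakset())
  df <- do.call(rbind, res)
  df$fdr <- p.adjust(df$pvalue, method = "BH")
  df <- df[df$fdr < config$island_fdr, , drop = FALSE]
  if (!nrow(df)) return(empty_peakset())
  pc <- config$pseudocount
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start0 + 1, df$end0))
  mcols(gr)$treat_count <- df$treat_count
  mcols(gr)$ctrl_expect <- df$ctrl_expect
  mcols(gr)$log2FC <- log2((df$treat_count + pc) / (df$ctrl_expect + pc))
  mcols(gr)$pvalue <- df$pvalue
  mcols(gr)$fdr <- df$fdr
  BiocGenerics::sort(gr)
}

empty_peakset <- function() {
  gr <- GenomicRanges::GRanges()
  mcols(gr)$treat_count <- numeric(0)
  mcols(gr)$ctrl_expect <- numeric(0)
  mcols(gr)$log2FC <- numeric(0)
  mcols(gr)$pvalue <- numeric(0)
  mcols(gr)$fdr <- numeric(0)
  gr
}

#' Post-filter a peak set
#'
#' Retains peaks with `log2FC` strictly greater than `post_log2fc`, `fdr`
#' below `post_fdr`, and no overlap (>= 1 bp) with the blacklist.
#'
#' @param peaks A peak `GRanges` from [call_islands()].
#' @param config A `peak_call_config`.
#' @param blacklist Optional `GRanges` of regions to exclude.
#' @return The filtered peak `GRanges`.
#' @export
filter_peaks <- function(peaks, config = peak_call_config(),
                         blacklist = NULL) {
  keep <- mcols(peaks)$log2FC > config$post_log2fc &
    mcols(peaks)$fdr < config$post_fdr
  if (!is.null(blacklist) && length(blacklist))
    keep <- keep & !overlaps_any(peaks, blacklist)
  peaks[keep]
}

#' Write a peak set as BED6+3
#'
#' Columns: chrom, start, end, name, score (-10 log10 FDR, capped), strand
#' ".", then log2FC, p-value, FDR.
#'
#' @param peaks A peak `GRanges`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = BiocGenerics::start(peaks) - 1L,
    end = BiocGenerics::end(peaks),
    name = sprintf("peak_%d", seq_along(peaks)),
    score = round(pmin(-10 * log10(pmax(mcols(peaks)$fdr, 1e-100)), 1000)),
    strand = ".",
    log2FC = mcols(peaks)$log2FC,
    pvalue = mcols(peaks)$pvalue,
    fdr = mcols(peaks)$fdr)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
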