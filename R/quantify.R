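#' Log2 CPM/bp enrichment of regions in one sample
#'
#' Counts fragments overlapping (>= 1 bp) each region, normalises to counts
#' per million library fragments and per bp of region width, floors at
#' `floor` before taking log2 (so empty regions map to `log2(floor)`).
#'
#' @param frags A `fragment_set`.
#' @param regions `GRanges`.
#' @param floor Lower clamp applied before the log (default `2^-10`).
#' @return Numeric vector of log2 CPM/bp values along `regions`.
#' @export
log2_cpm_per_bp <- function(frags, regions, floor = 2^-10) {
  al <- align_seqlevels(granges_only(regions), frags$ranges)
  counts <- GenomicRanges::countOverlaps(al$a, al$b, ignore.strand = TRUE)
  cpm_bp <- (counts / max(frags$library_size, 1) * 1e6) /
    BiocGenerics::width(regions)
  log2(pmax(cpm_bp, floor))
}

#' Enrichment matrix of log2 CPM/bp values
#'
#' @param frags_list Named list of `fragment_set`s.
#' @param regions `GRanges`.
#' @param floor Log floor, see [log2_cpm_per_bp()].
#' @return Numeric matrix, regions x samples.
#' @export
enrichment_matrix <- function(frags_list, regions, floor = 2^-10) {
  stopifnot(length(frags_list) > 0)
  m <- vapply(frags_list, log2_cpm_per_bp, numeric(length(regions)),
              regions = regions, floor = floor)
  matrix(m, nrow = length(regions),
         dimnames = list(NULL, names(frags_list) %||%
                           vapply(frags_list, `[[`, "", "sample_id")))
}

#' Fraction of reads in peaks (FRiP)
#'
#' Counts each fragment at most once (a fragment overlapping several peaks
#' still contributes 1), divided by the library size, so the score is always
#' in [0, 1].
#'
#' @param frags A `fragment_set`.
#' @param peaks `GRanges` of peaks.
#' @return List with `sample_id`, `reads_in_peaks`, `library_size`, `frip`.
#' @export
frip <- function(frags, peaks) {
  in_peaks <- if (length(peaks) == 0L) 0L
              else sum(overlaps_any(frags$ranges, peaks))
  list(sample_id = frags$sample_id,
       reads_in_peaks = in_peaks,
       library_size = frags$library_size,
       frip = if (frags$library_size == 0L) 0 else
         in_peaks / frags$library_size)
}

#' Downsampling curve
#'
#' For each fraction, subsamples every sample without replacement (seeded)
#' and reruns a user-supplied pipeline closure on the subsampled list,
#' recording whatever named counts the closure returns.
#'
#' @param frags_list Named list of `fragment_set`s.
#' @param fractions Numeric vector of fractions in (0, 1]; reported sorted
#'   ascending.
#' @param seed Integer seed; per-fraction, per-sample seeds are derived
#'   deterministically from it.
#' @param pipeline_fn Function taking the subsampled named list and returning
#'   a named list/vector of numeric counts (e.g. `n_peaks`).
#' @return data.frame with `fraction`, `n_reads` (total fragments used) and
#'   one column per count returned by `pipeline_fn`.
#' @export
downsampling_curve <- function(frags_list, fractions, seed, pipeline_fn) {
  fractions <- sort(fractions)
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    sub <- lapply(seq_along(frags_list), function(j)
      subsample_fragments(frags_list[[j]], f,
                          seed = derive_seed(seed, sprintf("ds_%d_%d", i, j))))
    names(sub) <- names(frags_list)
    counts <- as.list(pipeline_fn(sub))
    c(list(fraction = f,
           n_reads = sum(vapply(sub, `[[`, 0L, "library_size"))),
      counts)
  })
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Profile matrix over region centres
#'
#' Regions are replaced by fixed windows of centre +/- `flank` (default 5 kb),
#' split into `nbin` equal bins (default 100). Per bin the mean CPM/bp over
#' fragments is computed, values above the 99th percentile of all bins are
#' masked (set to that percentile), and the matrix is scaled to [0, 1] by its
#' global maximum. Column means give the average profile with every region
#' weighted equally.
#'
#' @param frags A `fragment_set`.
#' @param regions `GRanges`.
#' @param flank Half-window in bp (default 5000).
#' @param nbin Number of bins (default 100).
#' @return List with `matrix` (regions x nbin, in [0, 1]), `profile` (column
#'   means) and `cap` (the masking value on the CPM/bp scale).
#' @export
profile_matrix <- function(frags, regions, flank = 5000L, nbin = 100L) {
  stopifnot(length(regions) > 0)
  center0 <- (BiocGenerics::start(regions) - 1L +
                BiocGenerics::end(regions)) %/% 2L
  win_start0 <- center0 - flank
  bin_w <- 2 * flank / nbin
  mid0 <- fragment_midpoints0(frags$ranges)
  frag_chr <- as.character(seqnames(frags$ranges))
  reg_chr <- as.character(seqnames(regions))
  mat <- matrix(0, nrow = length(regions), ncol = nbin)
  # assign fragment midpoints to (region, bin) cells
  win_gr <- GenomicRanges::GRanges(
    reg_chr, IRanges::IRanges(pmax(win_start0, 0) + 1, win_start0 + 2 * flank))
  mid_gr <- GenomicRanges::GRanges(frag_chr, IRanges::IRanges(mid0 + 1, mid0 + 1))
  al <- align_seqlevels(mid_gr, win_gr)
  ov <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
  if (length(ov)) {
    off <- mid0[queryHits(ov)] - win_start0[subjectHits(ov)]
    bin <- pmin(pmax(floor(off / bin_w), 0), nbin - 1) + 1
    lin <- (bin - 1) * length(regions) + subjectHits(ov)
    mat[] <- tabulate(lin, nbins = length(regions) * nbin)
  }
  # counts -> CPM/bp
  mat <- mat / max(frags$library_size, 1) * 1e6 / bin_w
  cap <- quantile(mat, 0.99, names = FALSE)
  mat[mat > cap] <- cap
  if (max(mat) > 0) mat <- mat / max(mat)
  list(matrix = mat, profile = colMeans(mat), cap = cap)
}
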