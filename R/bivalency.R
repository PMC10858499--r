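#' Consensus peaks across replicates
#'
#' With one replicate, returns its intervals unchanged; with several, returns
#' the merged overlap segments common to all replicates (iterated pairwise
#' intersection), i.e. bases enriched in every replicate.
#'
#' @param replicate_peaksets List of peak `GRanges` (length >= 1).
#' @return A merged `GRanges`.
#' @export
consensus_peaks <- function(replicate_peaksets) {
  if (!length(replicate_peaksets)) stop("need at least one replicate")
  if (length(replicate_peaksets) == 1L)
    return(granges_only(replicate_peaksets[[1]]))
  Reduce(interval_intersect, replicate_peaksets)
}

#' Reciprocally bivalent regions from the two reChIP orientations
#'
#' A region is called bivalent when a K4-K27 peak is supported by >= 1 bp
#' overlap with at least one K27-K4 peak. The representative interval is the
#' K4-K27 peak (the supporting K27-K4 peak indices are recorded in the
#' `supported_by` metadata column so the choice is auditable). Counts of both
#' input sets and of shared peaks are returned alongside.
#'
#' @param k4k27,k27k4 Peak `GRanges` for the two reChIP orientations.
#' @return List with `regions` (the shared K4-K27 peaks, with provenance) and
#'   `counts` (`n_k4k27`, `n_k27k4`, `n_shared`).
#' @export
reciprocal_bivalent <- function(k4k27, k27k4) {
  hit <- overlaps_any(k4k27, k27k4)
  regions <- k4k27[hit]
  if (length(regions)) {
    al <- align_seqlevels(regions, granges_only(k27k4))
    ov <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
    prov <- vapply(split(subjectHits(ov), factor(queryHits(ov),
                                                 seq_along(regions))),
                   function(i) paste(i, collapse = ","), "")
    mcols(regions)$supported_by <- unname(prov)
  }
  list(regions = regions,
       counts = list(n_k4k27 = length(k4k27), n_k27k4 = length(k27k4),
                     n_shared = sum(hit)))
}

biv_classes <- c("HC", "K4B", "K27B", "LC")

#' Classify bivalent peaks by overlap with total single-ChIP peaks
#'
#' Each reciprocally bivalent peak is stratified into exactly one confidence
#' class: HC (overlaps a peak in both total H3K4me3 and total H3K27me3), K4B
#' (only total H3K4me3), K27B (only total H3K27me3) or LC (neither). The
#' classes partition the set; the function asserts that the tallies sum to
#' the number of input peaks.
#'
#' @param bivalent `GRanges` of reciprocally bivalent peaks.
#' @param total_k4,total_k27 Peak `GRanges` from the total single ChIPs.
#' @return The input `GRanges` with metadata columns `overlaps_total_k4`,
#'   `overlaps_total_k27` and `class` (factor HC/K4B/K27B/LC), plus a
#'   `tallies` attribute (named integer vector).
#' @export
classify_peaks <- function(bivalent, total_k4, total_k27) {
  f4 <- overlaps_any(bivalent, total_k4)
  f27 <- overlaps_any(bivalent, total_k27)
  cls <- ifelse(f4 & f27, "HC",
                ifelse(f4, "K4B", ifelse(f27, "K27B", "LC")))
  mcols(bivalent)$overlaps_total_k4 <- f4
  mcols(bivalent)$overlaps_total_k27 <- f27
  mcols(bivalent)$class <- factor(cls, levels = biv_classes)
  tallies <- table(mcols(bivalent)$class)
  stopifnot(sum(tallies) == length(bivalent))  # classes partition the set
  attr(bivalent, "tallies") <- setNames(as.integer(tallies), names(tallies))
  bivalent
}

#' Compare in-silico overlap calling with reciprocal reChIP
#'
#' The in-silico putative bivalent set is the merged intersection of the total
#' H3K4me3 and total H3K27me3 peak sets. A member is validated when it
#' overlaps a reciprocally bivalent region; the remainder is the in-silico
#' false-positive rate, reported as a percentage to one decimal. Undefined
#' (NA) when the in-silico set is empty.
#'
#' @param total_k4,total_k27 Total single-ChIP peak `GRanges`.
#' @param bivalent `GRanges` of reciprocally bivalent regions.
#' @return List with `insilico` (the merged in-silico `GRanges`),
#'   `n_insilico`, `n_validated`, `n_unvalidated`, `fp_rate_percent`.
#' @export
in_silico_comparison <- function(total_k4, total_k27, bivalent) {
  insilico <- interval_merge(interval_intersect(total_k4, total_k27))
  n_in <- length(insilico)
  n_val <- sum(overlaps_any(insilico, bivalent))
  list(insilico = insilico,
       n_insilico = n_in,
       n_validated = n_val,
       n_unvalidated = n_in - n_val,
       fp_rate_percent = if (n_in == 0) NA_real_
                         else round(100 * (n_in - n_val) / n_in, 1))
}

#' Promoter windows around transcription start sites
#'
#' Builds symmetric windows of `TSS +/- half_width` (default 1.5 kb each
#' side). The TSS is the interval start for "+" and unstranded genes and the
#' last base for "-" strand genes; windows are clipped to chromosome bounds
#' when sizes are given.
#'
#' @param tss `GRanges` of gene intervals or 1-bp TSS records with a `gene`
#'   (or `name`) metadata column.
#' @param half_width Window half-width in bp (default 1500).
#' @param chrom_sizes Optional named vector for clipping.
#' @return `GRanges` of promoter windows with a `gene` column.
#' @export
promoter_windows <- function(tss, half_width = 1500L, chrom_sizes = NULL) {
  if (!length(tss)) return(GenomicRanges::GRanges())
  str <- as.character(BiocGenerics::strand(tss))
  tss0 <- ifelse(str == "-", BiocGenerics::end(tss) - 1L,
                 BiocGenerics::start(tss) - 1L)  # 0-based TSS position
  start0 <- pmax(tss0 - half_width, 0)
  end0 <- tss0 + half_width
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    end0 <- pmin(end0, sizes[as.character(seqnames(tss))])
  }
  gr <- GenomicRanges::GRanges(seqnames(tss),
                               IRanges::IRanges(start0 + 1, end0))
  mcols(gr)$gene <- mcols(tss)$gene %||% mcols(tss)$name %||%
    sprintf("gene_%d", seq_along(tss))
  gr
}

#' Hierarchical promoter classification
#'
#' Each promoter collects its overlapping classified bivalent peaks and is
#' assigned the highest-priority class present under HC > K4B > K27B > LC;
#' promoters overlapping no bivalent peak get class NA. Assignments are
#' independent of peak input order.
#'
#' @param promoters Promoter `GRanges` from [promoter_windows()].
#' @param classified Classified peak `GRanges` from [classify_peaks()].
#' @return data.frame with one row per gene: `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), `class`, `peak_ids` (comma-separated indices into
#'   `classified`).
#' @export
classify_promoters <- function(promoters, classified) {
  n <- length(promoters)
  cls <- rep(NA_character_, n)
  ids <- rep("", n)
  if (length(classified)) {
    al <- align_seqlevels(granges_only(promoters), granges_only(classified))
    ov <- GenomicRanges::findOverlaps(al$a, al$b, ignore.strand = TRUE)
    if (length(ov)) {
      pk_class <- as.character(mcols(classified)$class)[subjectHits(ov)]
      pk_rank <- match(pk_class, biv_classes)
      by_prom <- split(data.frame(id = subjectHits(ov), rank = pk_rank),
                       queryHits(ov))
      for (q in names(by_prom)) {
        qi <- as.integer(q)
        d <- by_prom[[q]]
        cls[qi] <- biv_classes[min(d$rank)]
        ids[qi] <- paste(sort(d$id), collapse = ",")
      }
    }
  }
  data.frame(gene = mcols(promoters)$gene,
             chrom = as.character(seqnames(promoters)),
             start = BiocGenerics::start(promoters) - 1L,
             end = BiocGenerics::end(promoters),
             class = factor(cls, levels = biv_classes),
             peak_ids = ids,
             stringsAsFactors = FALSE)
}

#' Compare two promoter classifications by gene
#'
#' Considers genes with an assigned (non-NA) class in each table and reports
#' shared and unique gene counts, plus the percentage of `b`'s bivalent genes
#' recovered in `a` (integer percent).
#'
#' @param a,b data.frames from [classify_promoters()].
#' @return List with `n_a`, `n_b`, `n_shared`, `unique_to_a`, `unique_to_b`,
#'   `pct_of_b_shared`.
#' @export
compare_promoter_sets <- function(a, b) {
  ga <- a$gene[!is.na(a$class)]
  gb <- b$gene[!is.na(b$class)]
  shared <- length(intersect(ga, gb))
  list(n_a = length(ga), n_b = length(gb), n_shared = shared,
       unique_to_a = length(setdiff(ga, gb)),
       unique_to_b = length(setdiff(gb, ga)),
       pct_of_b_shared = if (length(gb) == 0) NA_real_
                         else round(100 * shared / length(gb)))
}

#' Annotate peaks with overlap flags against named feature sets
#'
#' @param peaks `GRanges`, optionally carrying a `class` metadata column.
#' @param features Named list of `GRanges` (e.g. promoter, CpG island, cCRE).
#' @return List with `flags` (logical matrix peaks x features) and `tallies`
#'   (counts of flagged peaks per feature, split by class when available).
#' @export
annotate_features <- function(peaks, features = list()) {
  if (!length(features))
    return(list(flags = matrix(logical(0), nrow = length(peaks), ncol = 0),
                tallies = list()))
  stopifnot(!is.null(names(features)), all(nzchar(names(features))))
  flags <- vapply(features, function(f) overlaps_any(peaks, f),
                  logical(length(peaks)))
  flags <- matrix(flags, nrow = length(peaks),
                  dimnames = list(NULL, names(features)))
  cls <- mcols(peaks)$class
  tallies <- lapply(colnames(flags), function(nm) {
    if (is.null(cls)) sum(flags[, nm])
    else tapply(flags[, nm], cls, sum, default = 0L)
  })
  names(tallies) <- colnames(flags)
  list(flags = flags, tallies = tallies)
}
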