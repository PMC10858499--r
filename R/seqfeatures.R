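#' GC fraction and CpG dinucleotide frequency per sequence
#'
#' GC fraction sums C and G counts over the informative (non-N) length; CpG
#' frequency counts "CG" dinucleotides over `length - 1` positions. Input
#' case is ignored; values always lie in [0, 1].
#'
#' @param seqs A `Biostrings::DNAStringSet` or character vector over
#'   A/C/G/T/N.
#' @return data.frame with `gc_fraction` and `cpg_freq` per sequence.
#' @export
gc_metrics <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(toupper(seqs))
  stopifnot(is(seqs, "DNAStringSet"))
  lf <- Biostrings::letterFrequency(seqs, letters = c("C", "G", "N"))
  len <- Biostrings::width(seqs)
  informative <- len - lf[, "N"]
  gc <- ifelse(informative > 0, (lf[, "C"] + lf[, "G"]) / informative, 0)
  dn <- Biostrings::dinucleotideFrequency(seqs)
  cpg <- ifelse(len > 1, dn[, "CG"] / (len - 1), 0)
  data.frame(gc_fraction = as.numeric(gc), cpg_freq = as.numeric(cpg))
}

#' Extract interval sequences from a genome
#'
#' @param genome Named `DNAStringSet` (one entry per chromosome) or a FASTA
#'   path (plain or gzipped).
#' @param intervals `GRanges`.
#' @return A `DNAStringSet`, one sequence per interval, lengths equal to
#'   interval widths.
#' @export
interval_sequences <- function(genome, intervals) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(is(genome, "DNAStringSet"))
  chr <- as.character(seqnames(intervals))
  missing_chr <- setdiff(unique(chr), names(genome))
  if (length(missing_chr))
    stop("intervals on chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  Biostrings::DNAStringSet(lapply(seq_along(intervals), function(i)
    Biostrings::subseq(genome[[chr[i]]],
                       start = BiocGenerics::start(intervals)[i],
                       end = BiocGenerics::end(intervals)[i])))
}

#' Generate a synthetic genome sequence
#'
#' Draws i.i.d. bases at a background GC level, optionally raising GC inside
#' designated regions (emulating CpG-island-like promoter sequence; i.i.d.
#' letters with elevated G/C raise both GC fraction and CpG dinucleotide
#' frequency). This is a synthetic stand-in used to exercise the sequence
#' metrics, not a model of real genome composition.
#'
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param seed Integer seed.
#' @param gc_background Background GC fraction (default 0.42).
#' @param gc_regions Optional `GRanges` whose bases are drawn at `gc_high`.
#' @param gc_high GC fraction inside `gc_regions` (default 0.65).
#' @return Named `DNAStringSet`.
#' @export
synth_genome <- function(chrom_sizes, seed, gc_background = 0.42,
                         gc_regions = NULL, gc_high = 0.65) {
  sizes <- as_chrom_sizes(chrom_sizes)
  with_seed(seed, {
    seqs <- lapply(names(sizes), function(chr) {
      n <- sizes[[chr]]
      p_gc <- rep(gc_background, n)
      if (!is.null(gc_regions)) {
        sel <- gc_regions[as.character(seqnames(gc_regions)) == chr]
        for (i in seq_along(sel)) {
          lo <- BiocGenerics::start(sel)[i]
          hi <- min(BiocGenerics::end(sel)[i], n)
          p_gc[lo:hi] <- gc_high
        }
      }
      is_gc <- runif(n) < p_gc
      half <- runif(n) < 0.5
      base <- ifelse(is_gc, ifelse(half, "G", "C"),
                     ifelse(half, "A", "T"))
      paste(base, collapse = "")
    })
    out <- Biostrings::DNAStringSet(unlist(seqs))
    names(out) <- names(sizes)
    out
  })
}

#' Width- and GC-matched random control regions
#'
#' For each query interval, candidate regions of the same width are sampled
#' uniformly over the genome avoiding the query set (and an optional
#' blacklist); the candidate with GC fraction nearest the query's is selected
#' (without replacement within a width group). The control set therefore has
#' exactly the query's width multiset and a closely matched GC distribution.
#' Deterministic given the seed.
#'
#' @param query `GRanges`.
#' @param genome Named `DNAStringSet` or FASTA path.
#' @param seed Integer seed.
#' @param n_candidates Total candidates to draw (default `25 * length(query)`).
#' @param exclude Optional additional `GRanges` to avoid.
#' @return List with `regions` (matched `GRanges`), `query_gc`, `matched_gc`
#'   and `mean_abs_gc_diff`.
#' @export
matched_random_regions <- function(query, genome, seed,
                                   n_candidates = 25L * length(query),
                                   exclude = NULL) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(length(query) > 0)
  sizes <- setNames(as.numeric(Biostrings::width(genome)), names(genome))
  avoid <- granges_only(query)
  if (!is.null(exclude)) avoid <- c(avoid, granges_only(exclude))
  per_query <- max(ceiling(n_candidates / length(query)), 2L)
  q_gc <- gc_metrics(interval_sequences(genome, query))$gc_fraction
  with_seed(seed, {
    chroms <- character(0); starts0 <- numeric(0); widths <- integer(0)
    cand_of <- integer(0)
    for (i in seq_along(query)) {
      w <- BiocGenerics::width(query)[i]
      got <- 0L; tries <- 0L
      while (got < per_query && tries < 50L * per_query) {
        tries <- tries + 1L
        chr_i <- sample.int(length(sizes), 1, prob = sizes / sum(sizes))
        if (sizes[chr_i] <= w) next
        s0 <- floor(runif(1, 0, sizes[chr_i] - w))
        cand <- GenomicRanges::GRanges(names(sizes)[chr_i],
                                       IRanges::IRanges(s0 + 1, s0 + w))
        if (any(overlaps_any(cand, avoid))) next
        chroms <- c(chroms, names(sizes)[chr_i])
        starts0 <- c(starts0, s0); widths <- c(widths, w)
        cand_of <- c(cand_of, i)
        got <- got + 1L
      }
      if (got == 0L)
        stop("insufficient candidate regions; increase n_candidates")
    }
    cand_gr <- GenomicRanges::GRanges(chroms,
                                      IRanges::IRanges(starts0 + 1,
                                                       starts0 + widths))
    cand_gc <- gc_metrics(interval_sequences(genome, cand_gr))$gc_fraction
    pick <- integer(length(query))
    used <- rep(FALSE, length(cand_gr))
    for (i in seq_along(query)) {
      pool <- which(cand_of == i & !used)
      j <- pool[which.min(abs(cand_gc[pool] - q_gc[i]))]
      pick[i] <- j
      used[j] <- TRUE
    }
    matched <- cand_gr[pick]
    list(regions = matched, query_gc = q_gc, matched_gc = cand_gc[pick],
         mean_abs_gc_diff = mean(abs(cand_gc[pick] - q_gc)))
  })
}

#' Pairwise t-tests of sequence metrics between classes and controls
#'
#' Two-sided Welch t-tests between every pair of groups, with BH adjustment
#' across the pairs.
#'
#' @param metrics_by_group Named list of numeric vectors (e.g. GC fraction per
#'   class plus a "control" entry).
#' @return data.frame with `group1`, `group2`, `statistic`, `pvalue`, `fdr`.
#' @export
compare_classes <- function(metrics_by_group) {
  stopifnot(length(metrics_by_group) >= 2, !is.null(names(metrics_by_group)))
  nm <- names(metrics_by_group)
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- metrics_by_group[[pairs[1, k]]]
    b <- metrics_by_group[[pairs[2, k]]]
    tt <- t.test(a, b)
    data.frame(group1 = pairs[1, k], group2 = pairs[2, k],
               statistic = unname(tt$statistic),
               pvalue = tt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$pvalue, method = "BH")
  out
}
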