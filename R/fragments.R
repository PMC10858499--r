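#' Construct a fragment set
#'
#' A fragment set couples a `GRanges` of sequenced fragment intervals with its
#' library size (total number of fragments) and a sample identifier. The
#' library size always equals the number of fragments held.
#'
#' @param gr `GRanges` of fragment intervals.
#' @param sample_id Character scalar naming the sample.
#' @return An object of class `fragment_set`.
#' @export
fragment_set <- function(gr, sample_id = "sample") {
  stopifnot(is(gr, "GRanges"), is.character(sample_id),
            length(sample_id) == 1L)
  structure(list(ranges = GenomicRanges::granges(gr),  # strand kept for 5' extension
                 sample_id = sample_id,
                 library_size = length(gr)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> %s: %d fragments on %d chromosome(s)\n",
              x$sample_id, x$library_size,
              length(unique(as.character(seqnames(x$ranges))))))
  invisible(x)
}

#' @export
length.fragment_set <- function(x) x$library_size

#' Read a fragment BED file as a fragment set
#'
#' @param path BED3+ file of fragment intervals.
#' @param sample_id Sample identifier (default: file base name).
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path, sample_id = NULL) {
  sample_id <- sample_id %||% sub("\\.bed(\\.gz)?$", "", basename(path))
  fragment_set(read_bed(path), sample_id = sample_id)
}

#' Write a fragment set to BED3
#'
#' @param frags A `fragment_set`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments <- function(frags, path) {
  write_bed(frags$ranges, path)
}

# 0-based fragment midpoints (one bp per fragment), optionally after
# replacing each fragment by an `extend_to`-length interval from its 5' end.
fragment_midpoints0 <- function(gr, extend_to = NULL) {
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (!is.null(extend_to)) {
    str <- as.character(BiocGenerics::strand(gr))
    minus <- str == "-"
    new_start <- ifelse(minus, end0 - extend_to, start0)
    new_end <- new_start + extend_to
    start0 <- pmax(new_start, 0)
    end0 <- new_end
  }
  (start0 + end0) %/% 2L
}

#' Bin fragment counts into a coverage track
#'
#' Each fragment contributes its midpoint to exactly one bin, so the total
#' over all bins equals the library size exactly. With `extend_to` set, each
#' fragment is first replaced by an interval of that length anchored at its
#' 5' end (strand-aware when strand information is present, else leftmost).
#' Fragments whose midpoint falls beyond the chromosome end are clipped into
#' the final bin with a warning. A span-weighted mode is available but
#' midpoint counting is the default (it keeps count conservation exact for
#' the Poisson peak model).
#'
#' @param frags A `fragment_set`.
#' @param bin_width Bin width in bp.
#' @param chrom_sizes Named numeric vector (or 2-column data.frame) of
#'   chromosome lengths covering all fragments.
#' @param extend_to Optional extension length in bp (e.g. 200), or NULL to use
#'   fragments as-is.
#' @param mode "midpoint" (default) or "span" (each fragment spread across the
#'   bins it covers, fractionally).
#' @return A `coverage_track`: list with `bin_width`, `chrom_sizes` and
#'   `counts`, a named list of per-chromosome numeric vectors of length
#'   `ceiling(chrom_length / bin_width)`.
#' @export
coverage_track <- function(frags, bin_width, chrom_sizes, extend_to = NULL,
                           mode = c("midpoint", "span")) {
  mode <- match.arg(mode)
  sizes <- as_chrom_sizes(chrom_sizes)
  gr <- frags$ranges
  chroms <- as.character(seqnames(gr))
  missing_chr <- setdiff(unique(chroms), names(sizes))
  if (length(missing_chr))
    stop("fragments on chromosome(s) absent from chrom_sizes: ",
         paste(missing_chr, collapse = ", "))
  counts <- lapply(names(sizes), function(chr) {
    nbin <- ceiling(sizes[[chr]] / bin_width)
    sel <- chroms == chr
    if (!any(sel)) return(numeric(nbin))
    if (mode == "midpoint") {
      mid <- fragment_midpoints0(gr[sel], extend_to)
      bin <- mid %/% bin_width
      if (any(bin >= nbin)) {
        warning(sprintf("%d fragment(s) beyond end of %s clipped",
                        sum(bin >= nbin), chr))
        bin <- pmin(bin, nbin - 1L)
      }
      bin <- pmax(bin, 0L)
      as.numeric(tabulate(bin + 1L, nbins = nbin))
    } else {
      sub <- gr[sel]
      s0 <- pmax(BiocGenerics::start(sub) - 1L, 0L)
      e0 <- pmin(BiocGenerics::end(sub), sizes[[chr]])
      v <- numeric(nbin)
      first <- s0 %/% bin_width
      last <- (e0 - 1L) %/% bin_width
      for (i in seq_along(s0)) {
        bins <- first[i]:last[i]
        lo <- pmax(bins * bin_width, s0[i])
        hi <- pmin((bins + 1L) * bin_width, e0[i])
        v[bins + 1L] <- v[bins + 1L] + (hi - lo) / (e0[i] - s0[i])
      }
      v
    }
  })
  names(counts) <- names(sizes)
  structure(list(bin_width = bin_width, chrom_sizes = sizes,
                 counts = counts, library_size = frags$library_size),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %d bp bins over %d chromosome(s), total %g\n",
              x$bin_width, length(x$counts),
              sum(vapply(x$counts, sum, 0))))
  invisible(x)
}

#' Write a coverage track as bedGraph
#'
#' Values may be raw counts or CPM/bp-normalised counts (`normalize = TRUE`
#' divides by library size in millions and by bin width). Zero bins are
#' omitted; adjacent equal-valued bins are not run-length merged.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @param normalize Write CPM/bp values rather than raw counts.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path, normalize = TRUE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  scale <- if (normalize)
    1e6 / (max(track$library_size, 1) * track$bin_width) else 1
  for (chr in names(track$counts)) {
    v <- track$counts[[chr]]
    nz <- which(v != 0)
    if (!length(nz)) next
    start0 <- (nz - 1L) * track$bin_width
    end0 <- pmin(nz * track$bin_width, track$chrom_sizes[[chr]])
    writeLines(sprintf("%s\t%d\t%d\t%g", chr, start0, end0, v[nz] * scale),
               con)
  }
  invisible(path)
}

#' Subsample a fragment set without replacement
#'
#' @param frags A `fragment_set`.
#' @param fraction Fraction of fragments to keep, in [0, 1]. The subsample
#'   size is `round(fraction * n)`.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `fragment_set` with updated library size.
#' @export
subsample_fragments <- function(frags, fraction, seed) {
  check_prob(fraction, "fraction")
  n <- frags$library_size
  k <- round(fraction * n)
  idx <- with_seed(seed, sample.int(n, k))
  fragment_set(frags$ranges[sort(idx)], sample_id = frags$sample_id)
}
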