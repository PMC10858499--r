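#' Read a BED file into a GRanges
#'
#' Parses BED3 through BED6. Coordinates are taken as written: BED is 0-based
#' half-open, so a line `chr1 0 100` becomes a 100-bp interval covering bases
#' 0..99. Internally intervals are held as \link[GenomicRanges]{GRanges}
#' (1-based closed); all package I/O converts back and forth consistently.
#' Track/browser lines and `#` comments are skipped.
#'
#' @param path Path to a BED file.
#' @param dialect One of "auto", "BED3".."BED6". "auto" uses the number of
#'   columns present.
#' @return A `GRanges`. Name/score/strand columns are kept when present
#'   (`name` as metadata column `name`, score as `score`).
#' @export
read_bed <- function(path, dialect = c("auto", "BED3", "BED4", "BED5", "BED6")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_need <- switch(dialect, auto = min(lengths(fields)),
                      BED3 = 3L, BED4 = 4L, BED5 = 5L, BED6 = 6L)
  bad <- which(lengths(fields) < ncol_need)
  if (length(bad))
    stop(sprintf("line %d: expected >= %d columns", lineno[bad[1]], ncol_need))
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(start_chr))
  end <- suppressWarnings(as.numeric(end_chr))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop(sprintf("line %d: non-integer coordinates '%s' '%s'",
                 lineno[bad[1]], start_chr[bad[1]], end_chr[bad[1]]))
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop(sprintf("line %d: invalid interval [%s, %s) (need 0 <= start < end)",
                 lineno[bad[1]], start_chr[bad[1]], end_chr[bad[1]]))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  nmax <- min(lengths(fields))
  if (ncol_need >= 4L || (dialect == "auto" && nmax >= 4L))
    mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (ncol_need >= 5L || (dialect == "auto" && nmax >= 5L))
    mcols(gr)$score <- suppressWarnings(
      as.numeric(vapply(fields, `[[`, "", 5L)))
  if (ncol_need >= 6L || (dialect == "auto" && nmax >= 6L)) {
    str <- vapply(fields, `[[`, "", 6L)
    bad <- which(!str %in% c("+", "-", "."))
    if (length(bad))
      stop(sprintf("line %d: unknown strand '%s'", lineno[bad[1]], str[bad[1]]))
    BiocGenerics::strand(gr) <- str
  }
  gr
}

#' Write a GRanges to a BED file
#'
#' Output is sorted (chromosome lexical, then start) and written as 0-based
#' half-open coordinates. Columns written depend on available metadata:
#' BED3 always; name, score and strand appended when present.
#'
#' @param x A `GRanges`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(x, path) {
  ord <- order(as.character(seqnames(x)), BiocGenerics::start(x),
               BiocGenerics::end(x))
  x <- x[ord]
  df <- data.frame(chrom = as.character(seqnames(x)),
                   start = BiocGenerics::start(x) - 1L,
                   end = BiocGenerics::end(x),
                   stringsAsFactors = FALSE)
  mc <- mcols(x)
  has_strand <- any(as.character(BiocGenerics::strand(x)) != "*")
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score) || has_strand) {
    if (is.null(df$name)) df$name <- "."
    df$score <- if (is.null(mc$score)) 0 else mc$score
  }
  if (has_strand) {
    str <- as.character(BiocGenerics::strand(x))
    str[str == "*"] <- "."
    df$strand <- str
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Tab-separated file with chromosome name and length.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  as_chrom_sizes(df)
}

#' Intersect two interval sets
#'
#' Returns the merged union of all pairwise overlap segments between `a` and
#' `b`, i.e. the genomic bases covered by both sets. Commutative. Used with
#' any >= 1 bp overlap semantics throughout the pipeline.
#'
#' @param a,b `GRanges`.
#' @return A merged `GRanges` of overlap segments.
#' @export
interval_intersect <- function(a, b) {
  al <- align_seqlevels(granges_only(a), granges_only(b))
  GenomicRanges::intersect(al$a, al$b, ignore.strand = TRUE)
}

#' Flag query intervals overlapping any subject interval
#'
#' @param query,subject `GRanges`.
#' @param min_overlap_bp Minimum overlap in bp to count (default 1). With
#'   half-open coordinates, touching intervals do not overlap.
#' @return Logical vector along `query`.
#' @export
overlaps_any <- function(query, subject, min_overlap_bp = 1L) {
  if (length(subject) == 0L) return(rep(FALSE, length(query)))
  al <- align_seqlevels(query, subject)
  GenomicRanges::countOverlaps(al$a, al$b, minoverlap = min_overlap_bp,
                               ignore.strand = TRUE) > 0L
}

#' Merge an interval set
#'
#' Collapses overlapping (and, with `min_gap > 0`, nearby) intervals into
#' non-overlapping sorted intervals. Gaps of at most `min_gap` bp are bridged.
#'
#' @param x A `GRanges`.
#' @param min_gap Maximum gap width (bp) to bridge (default 0: only
#'   overlapping or book-ended intervals merge).
#' @return A merged `GRanges`.
#' @export
interval_merge <- function(x, min_gap = 0L) {
  GenomicRanges::reduce(granges_only(x), min.gapwidth = min_gap + 1L,
                        ignore.strand = TRUE)
}

# Strip metadata/strand so set algebra never segfaults on odd mcols.
granges_only <- function(x) {
  gr <- GenomicRanges::granges(x)
  BiocGenerics::strand(gr) <- "*"
  gr
}

# Put two GRanges on a shared seqlevel universe so overlap machinery never
# warns about disjoint chromosome sets.
align_seqlevels <- function(a, b) {
  lv <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- lv
  seqlevels(b) <- lv
  list(a = a, b = b)
}

#' Read a BED6 TSS table
#'
#' Single-bp transcription start sites with strand and gene name in the BED
#' name column. Duplicate gene names are de-duplicated keeping the first
#' occurrence.
#'
#' @param path BED6 file of 1-bp TSS intervals.
#' @return A `GRanges` of width-1 TSS positions with a `gene` metadata column.
#' @export
read_tss <- function(path) {
  gr <- read_bed(path, dialect = "BED6")
  if (length(gr) && any(BiocGenerics::width(gr) != 1L))
    stop("TSS table must contain single-bp intervals (end = start + 1)")
  if (length(gr)) {
    mcols(gr)$gene <- mcols(gr)$name
    gr <- gr[!duplicated(mcols(gr)$gene)]
  }
  gr
}
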