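# Brute-force oracles over small coordinate spaces, independent of the
# package's interval machinery: intervals are materialised as per-base
# logical masks.

gr <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
}

gr_df <- function(x) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
             start0 = BiocGenerics::start(x) - 1L,
             end0 = BiocGenerics::end(x))
}

# per-chromosome base mask of covered positions (0-based)
bf_mask <- function(x, max_coord) {
  df <- gr_df(x)
  masks <- list()
  for (chr in unique(df$chrom)) {
    m <- logical(max_coord)
    for (i in which(df$chrom == chr))
      m[(df$start0[i] + 1):df$end0[i]] <- TRUE
    masks[[chr]] <- m
  }
  masks
}

bf_intersect <- function(a, b, max_coord = 1000L) {
  ma <- bf_mask(a, max_coord); mb <- bf_mask(b, max_coord)
  out <- list()
  for (chr in intersect(names(ma), names(mb))) {
    m <- ma[[chr]] & mb[[chr]]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[chr]] <- data.frame(chrom = chr, start0 = starts[keep],
                               end0 = ends[keep])
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start0), ]
  gr(df$chrom, df$start0, df$end0)
}

bf_merge <- function(a, min_gap = 0L, max_coord = 1000L) {
  ma <- bf_mask(a, max_coord + min_gap + 2L)
  out <- list()
  for (chr in names(ma)) {
    m <- ma[[chr]]
    if (min_gap > 0) {  # bridge gaps of <= min_gap uncovered bases
      r <- rle(m)
      ends <- cumsum(r$lengths)
      for (k in seq_along(r$values))
        if (!r$values[k] && r$lengths[k] <= min_gap &&
            k > 1 && k < length(r$values))
          m[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
    }
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[chr]] <- data.frame(chrom = chr, start0 = starts[keep],
                               end0 = ends[keep])
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$start0), ]
  gr(df$chrom, df$start0, df$end0)
}

# quadratic any-overlap scan
bf_overlaps_any <- function(query, subject) {
  q <- gr_df(query); s <- gr_df(subject)
  vapply(seq_len(nrow(q)), function(i)
    any(s$chrom == q$chrom[i] & s$start0 < q$end0[i] & s$end0 > q$start0[i]),
    TRUE)
}

random_intervals <- function(n, seed, max_coord = 1000L, chroms = c("chrA", "chrB")) {
  set.seed(seed)
  chrom <- sample(chroms, n, replace = TRUE)
  start0 <- sample.int(max_coord - 50L, n, replace = TRUE) - 1L
  w <- sample.int(49L, n, replace = TRUE)
  gr(chrom, start0, start0 + w)
}

# Benjamini-Hochberg step-up by definition
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

same_regions <- function(a, b) {
  da <- gr_df(a); db <- gr_df(b)
  da <- da[order(da$chrom, da$start0), ]; db <- db[order(db$chrom, db$start0), ]
  rownames(da) <- NULL; rownames(db) <- NULL
  isTRUE(all.equal(da, db))
}

with_seed_perm <- function(seed, n) {
  set.seed(seed)
  sample.int(n)
}

# small simulator config shared by tests (kept at the defaults except genome
# scale and depth so the suite stays fast)
tiny_sim_config <- function(seed = 42, ...) {
  args <- list(...)
  defaults <- list(seed = seed, n_chrom = 1L, chrom_length = 2e6,
                   n_cells = 500L, depth = 1e5,
                   region_counts = c(K4_ONLY = 15L, K27_ONLY = 15L,
                                     BIVALENT = 20L, ALLELIC_HET = 10L,
                                     CELLULAR_HET = 10L))
  do.call(sim_config, utils::modifyList(defaults, args))
}
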