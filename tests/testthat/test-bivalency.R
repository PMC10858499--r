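test_that("consensus_peaks folds replicates by intersection", {
  a <- gr("chr1", c(0, 200), c(100, 300))
  expect_true(same_regions(consensus_peaks(list(a)), a))
  expect_true(same_regions(consensus_peaks(list(a, a)), a))
  b <- gr("chr1", 500, 600)
  expect_length(consensus_peaks(list(a, b)), 0L)
  expect_error(consensus_peaks(list()), "at least one")
  # three random replicates equal the fold-left brute-force intersection
  for (s in 1:15) {
    reps <- lapply(1:3, function(k) random_intervals(15, seed = s * 10 + k))
    expect_true(same_regions(
      consensus_peaks(reps),
      bf_intersect(bf_intersect(reps[[1]], reps[[2]]), reps[[3]])),
      info = paste("seed", s))
  }
})

test_that("reciprocal_bivalent requires support in both orientations", {
  a <- gr("chr1", c(0, 200, 400), c(100, 300, 500))
  res <- reciprocal_bivalent(a, a)
  expect_equal(res$counts, list(n_k4k27 = 3L, n_k27k4 = 3L, n_shared = 3L))
  expect_equal(reciprocal_bivalent(a, GenomicRanges::GRanges())$counts$n_shared,
               0L)
  # partial overlaps match a brute-force both-direction test
  for (s in 1:15) {
    x <- random_intervals(20, seed = s)
    y <- random_intervals(20, seed = s + 300)
    res <- reciprocal_bivalent(x, y)
    expect_true(same_regions(res$regions, x[bf_overlaps_any(x, y)]),
                info = paste("seed", s))
    expect_equal(res$counts$n_shared, sum(bf_overlaps_any(x, y)))
  }
  # representative interval comes from the first (K4-K27) set, with provenance
  x <- gr("chr1", 0, 100); y <- gr("chr1", c(50, 90), c(80, 200))
  res <- reciprocal_bivalent(x, y)
  expect_true(same_regions(res$regions, x))
  expect_equal(S4Vectors::mcols(res$regions)$supported_by, "1,2")
})

test_that("classify_peaks assigns one class per peak and tallies partition", {
  biv <- gr("chr1", c(0, 200, 400, 600), c(100, 300, 500, 700))
  tk4 <- gr("chr1", c(0, 200), c(50, 250))
  tk27 <- gr("chr1", c(0, 400), c(50, 450))
  out <- classify_peaks(biv, tk4, tk27)
  expect_equal(as.character(S4Vectors::mcols(out)$class),
               c("HC", "K4B", "K27B", "LC"))
  tal <- attr(out, "tallies")
  expect_equal(sum(tal), length(biv))
  expect_equal(unname(tal), c(1L, 1L, 1L, 1L))
  # class is determined by the overlap flags
  mc <- S4Vectors::mcols(out)
  expect_equal(as.character(mc$class) == "HC",
               mc$overlaps_total_k4 & mc$overlaps_total_k27)
  # random inputs: partition always holds
  for (s in 1:10) {
    b <- random_intervals(30, seed = s)
    out <- classify_peaks(b, random_intervals(10, seed = s + 40),
                          random_intervals(10, seed = s + 80))
    expect_equal(sum(attr(out, "tallies")), 30L)
    expect_false(any(is.na(S4Vectors::mcols(out)$class)))
  }
})

test_that("in_silico_comparison accounts validated and false-positive peaks", {
  # degenerate cases
  tk4 <- gr("chr1", 0, 100)
  expect_true(is.na(in_silico_comparison(tk4, gr("chr1", 500, 600),
                                         tk4)$fp_rate_percent))
  res <- in_silico_comparison(tk4, tk4, tk4)
  expect_equal(res$fp_rate_percent, 0)
  # arithmetic identities on constructed counts
  n_in <- 200; n_val <- 147
  s0 <- (seq_len(n_in) - 1) * 1000
  totals <- gr("chr1", s0, s0 + 500)
  bivalent <- gr("chr1", s0[seq_len(n_val)], s0[seq_len(n_val)] + 500)
  res <- in_silico_comparison(totals, totals, bivalent)
  expect_equal(res$n_insilico, n_in)
  expect_equal(res$n_validated, n_val)
  expect_equal(res$n_unvalidated, n_in - n_val)
  expect_equal(res$fp_rate_percent, round(100 * (n_in - n_val) / n_in, 1))
})

test_that("promoter windows are strand-aware and clipped", {
  tss <- gr("chr1", c(2000, 500), c(2001, 501))
  BiocGenerics::strand(tss) <- "+"
  S4Vectors::mcols(tss)$gene <- c("a", "b")
  w <- promoter_windows(tss, 1500, c(chr1 = 1e5))
  expect_equal(gr_df(w)$start0, c(500, 0))
  expect_equal(gr_df(w)$end0, c(3500, 2000))
  # minus-strand gene spanning (1000, 5000): TSS at 4999
  g <- gr("chr1", 1000, 5000)
  BiocGenerics::strand(g) <- "-"
  S4Vectors::mcols(g)$gene <- "m"
  wm <- promoter_windows(g, 1500)
  expect_equal(gr_df(wm)$start0, 4999 - 1500)
  expect_equal(gr_df(wm)$end0, 4999 + 1500)
})

test_that("promoter classification follows the HC > K4B > K27B > LC hierarchy", {
  prom <- gr("chr1", c(0, 1000, 2000), c(500, 1500, 2500))
  S4Vectors::mcols(prom)$gene <- c("g1", "g2", "g3")
  pks <- gr("chr1", c(10, 100, 1100, 2600), c(60, 150, 1200, 2700))
  tk4 <- gr("chr1", c(10, 100), c(60, 150))    # peaks 1,2 overlap total K4
  tk27 <- gr("chr1", 10, 60)                    # peak 1 overlaps total K27
  classified <- classify_peaks(pks, tk4, tk27)  # HC, K4B, LC, LC
  out <- classify_promoters(prom, classified)
  expect_equal(as.character(out$class), c("HC", "LC", NA))
  expect_equal(out$peak_ids, c("1,2", "3", ""))
  # order independence: permuting peaks never changes assignments
  for (s in 1:5) {
    perm <- with_seed_perm(s, length(classified))
    out_p <- classify_promoters(prom, classified[perm])
    expect_equal(as.character(out_p$class), as.character(out$class))
  }
  # brute-force max-priority oracle on random fixtures
  for (s in 1:10) {
    prom_r <- random_intervals(15, seed = s)
    S4Vectors::mcols(prom_r)$gene <- sprintf("g%d", seq_along(prom_r))
    pk_r <- random_intervals(25, seed = s + 99)
    cls_r <- classify_peaks(pk_r, random_intervals(8, seed = s + 7),
                            random_intervals(8, seed = s + 13))
    got <- classify_promoters(prom_r, cls_r)
    prio <- c(HC = 1, K4B = 2, K27B = 3, LC = 4)
    want <- vapply(seq_along(prom_r), function(i) {
      hit <- bf_overlaps_any(pk_r, prom_r[i])
      if (!any(hit)) return(NA_character_)
      cls <- as.character(S4Vectors::mcols(cls_r)$class)[hit]
      names(prio)[min(prio[cls])]
    }, "")
    expect_equal(as.character(got$class), want, info = paste("seed", s))
  }
})

test_that("promoter set comparison counts shared genes and percentages", {
  mk <- function(genes, cls = "HC") data.frame(
    gene = genes, chrom = "chr1", start = 0, end = 10,
    class = factor(cls, levels = c("HC", "K4B", "K27B", "LC")),
    peak_ids = "1", stringsAsFactors = FALSE)
  a <- mk(sprintf("g%d", 1:50))
  expect_equal(compare_promoter_sets(a, a)$pct_of_b_shared, 100)
  b <- mk(sprintf("h%d", 1:30))
  expect_equal(compare_promoter_sets(a, b)$n_shared, 0L)
  # unassigned promoters (class NA) are excluded
  a2 <- rbind(a, data.frame(gene = "gx", chrom = "chr1", start = 0, end = 10,
                            class = factor(NA, levels = levels(a$class)),
                            peak_ids = "", stringsAsFactors = FALSE))
  expect_equal(compare_promoter_sets(a2, a)$n_a, 50L)
  shared <- compare_promoter_sets(mk(sprintf("g%d", 1:77)),
                                  mk(sprintf("g%d", 50:149)))
  expect_equal(shared$n_shared, 28L)
  expect_equal(shared$pct_of_b_shared, 28)
})

test_that("annotate_features flags overlaps per named feature set", {
  pks <- gr("chr1", c(0, 1000), c(100, 1100))
  expect_equal(ncol(annotate_features(pks)$flags), 0L)
  feats <- list(cpg = gr("chr1", 0, 2000))
  expect_true(all(annotate_features(pks, feats)$flags[, "cpg"]))
  for (s in 1:10) {
    p <- random_intervals(20, seed = s)
    f <- list(x = random_intervals(10, seed = s + 1),
              y = random_intervals(5, seed = s + 2))
    got <- annotate_features(p, f)$flags
    expect_equal(unname(got[, "x"]), bf_overlaps_any(p, f$x))
    expect_equal(unname(got[, "y"]), bf_overlaps_any(p, f$y))
  }
})
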