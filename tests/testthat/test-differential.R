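test_that("genome binning conserves counts and matches brute force", {
  sizes <- c(chr1 = 55000, chr2 = 30000)
  set.seed(1)
  mk <- function(id) {
    n <- 500
    chrom <- sample(names(sizes), n, replace = TRUE)
    s0 <- floor(runif(n, 0, sizes[chrom] - 147))
    fragment_set(gr(chrom, s0, s0 + 147), id)
  }
  fl <- list(a = mk("a"), b = mk("b"))
  bc <- bin_genome_counts(fl, 10000, sizes)
  expect_equal(unname(colSums(bc$counts)), c(500, 500))
  # one fragment at position 5000 lands in bin 0
  f1 <- list(x = fragment_set(gr("chr1", 5000, 5147), "x"),
             y = fragment_set(gr("chr1", 5000, 5147), "y"))
  b1 <- bin_genome_counts(f1, 10000, sizes)
  expect_equal(nrow(b1$counts), 1L)
  expect_equal(gr_df(b1$bins)$start0, 0)
  expect_true(all(b1$counts == 1))
  # brute-force binning oracle
  mids <- (BiocGenerics::start(fl$a$ranges) - 1 +
             BiocGenerics::end(fl$a$ranges)) %/% 2
  chroms <- as.character(GenomicRanges::seqnames(fl$a$ranges))
  brute <- c(tabulate(mids[chroms == "chr1"] %/% 10000 + 1, 6),
             tabulate(mids[chroms == "chr2"] %/% 10000 + 1, 3))
  keep <- brute + c(tabulate((BiocGenerics::start(fl$b$ranges)[
    as.character(GenomicRanges::seqnames(fl$b$ranges)) == "chr1"] - 1 + 73)
    %/% 10000 + 1, 6), tabulate((BiocGenerics::start(fl$b$ranges)[
      as.character(GenomicRanges::seqnames(fl$b$ranges)) == "chr2"] - 1 + 73)
      %/% 10000 + 1, 3)) > 0
  expect_equal(unname(bc$counts[, "a"]), brute[keep])
})

test_that("TMM factors are 1 for identical and depth-scaled libraries", {
  set.seed(2)
  base <- rpois(5000, rgamma(5000, 2, 0.5))
  counts <- cbind(s1 = base, s2 = base)
  f <- tmm_factors(counts)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-9)
  # pure depth scaling with identical composition: factors stay 1
  counts2 <- cbind(s1 = base, s2 = 2L * base)
  f2 <- tmm_factors(counts2, lib_sizes = c(sum(base), 2 * sum(base)))
  expect_equal(unname(f2), c(1, 1), tolerance = 0.02)
  expect_equal(exp(mean(log(f2))), 1, tolerance = 1e-9)
})

test_that("TMM recovers the direction of a composition bias", {
  set.seed(3)
  base <- rpois(5000, rgamma(5000, 2, 0.2))
  spiked <- base
  idx <- sample.int(5000, 500)
  spiked[idx] <- spiked[idx] * 8L
  counts <- cbind(ref = base, spk = spiked)
  f <- tmm_factors(counts, lib_sizes = colSums(counts))
  # analytic sign: the spike inflates the library, so the spiked sample's
  # non-spiked bins look depleted and its factor falls below the reference's
  expect_lt(f["spk"], f["ref"])
  expect_error(tmm_factors(counts[, 1, drop = FALSE]), "at least 2")
  skip_if_not_installed("edgeR")
  fe <- edgeR::calcNormFactors(counts, lib.size = colSums(counts),
                               method = "TMM")
  expect_lt(fe[2], fe[1])  # independent implementation agrees on direction
  expect_equal(unname(f), unname(fe), tolerance = 0.1)
})

test_that("nb_test reports BH-adjusted p-values matching the step-up oracle", {
  set.seed(4)
  L <- rep(1e5, 4)
  y <- matrix(rnbinom(400, mu = 50, size = 10), 100, 4)
  y[1:5, 3:4] <- y[1:5, 3:4] * 20L
  res <- nb_test(y, lib_sizes = L, condition = c("A", "A", "B", "B"))
  expect_equal(res$fdr, bh_stepup(res$pvalue))
  expect_true(all(res$fdr >= res$pvalue - 1e-12))
})

test_that("an all-zero condition against a large one is significant with the right sign", {
  L <- rep(1e5, 4)
  y <- rbind(c(0, 0, 200, 220),
             c(150, 180, 0, 0),
             c(50, 55, 48, 52))
  res <- nb_test(y, lib_sizes = L, condition = c("A", "A", "B", "B"))
  expect_true(res$significant[1] && res$log2FC[1] > 0)
  expect_true(res$significant[2] && res$log2FC[2] < 0)
  expect_false(res$significant[3])
  expect_error(nb_test(y, lib_sizes = L, condition = c("A", "B", "B", "B")),
               ">= 2 samples")
})

test_that("type-I error is near nominal on null NB data", {
  typeI <- vapply(1:12, function(s) {
    set.seed(s)
    n <- 1500
    L <- c(1e6, 1.2e6, 0.9e6, 1.1e6)
    q <- exp(rnorm(n, log(1e-5), 1))
    y <- matrix(rnbinom(n * 4, mu = outer(q, L), size = 1 / 0.1), n, 4)
    res <- nb_test(y, lib_sizes = L, condition = c("A", "A", "B", "B"))
    mean(res$pvalue < 0.05)
  }, 0)
  expect_gte(mean(typeI), 0.03)
  expect_lte(mean(typeI), 0.07)
})

test_that("results are invariant to region and within-condition sample order", {
  set.seed(5)
  L <- c(1e5, 1.1e5, 0.9e5, 1.2e5)
  y <- matrix(rnbinom(200, mu = 40, size = 5), 50, 4)
  res <- nb_test(y, lib_sizes = L, condition = c("A", "A", "B", "B"))
  perm <- sample.int(50)
  res_p <- nb_test(y[perm, ], lib_sizes = L,
                   condition = c("A", "A", "B", "B"))
  expect_equal(res_p$pvalue, res$pvalue[perm])
  res_s <- nb_test(y[, c(2, 1, 4, 3)], lib_sizes = L[c(2, 1, 4, 3)],
                   condition = c("A", "A", "B", "B"))
  expect_equal(res_s$pvalue, res$pvalue, tolerance = 1e-8)
  expect_equal(res_s$log2FC, res$log2FC, tolerance = 1e-8)
})

test_that("detection power rises monotonically with effect size", {
  set.seed(6)
  n <- 400
  L <- rep(5e5, 4)
  power_at <- function(fold) {
    q <- rep(1e-4, n)
    muA <- outer(q, L[1:2])
    muB <- outer(q / fold, L[3:4])
    y <- cbind(matrix(rnbinom(n * 2, mu = muA, size = 1 / 0.05), n, 2),
               matrix(rnbinom(n * 2, mu = muB, size = 1 / 0.05), n, 2))
    res <- nb_test(y, lib_sizes = L, condition = c("A", "A", "B", "B"))
    mean(res$significant & res$log2FC < 0)
  }
  p <- vapply(c(2, 4, 8), power_at, 0)
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3], 0.9)
})

test_that("direction of calls agrees with edgeR on a spiked dataset", {
  skip_if_not_installed("edgeR")
  set.seed(7)
  n <- 300
  L <- rep(2e5, 4)
  q <- exp(rnorm(n, log(5e-4), 0.5))
  y <- matrix(rnbinom(n * 4, mu = outer(q, L), size = 1 / 0.05), n, 4)
  lost <- 1:30
  y[lost, 3:4] <- matrix(rnbinom(60, mu = outer(q[lost] / 6, L[3:4]),
                                 size = 1 / 0.05), 30, 2)
  res <- nb_test(y, lib_sizes = L, condition = c("A", "A", "B", "B"))
  dge <- edgeR::DGEList(counts = y, lib.size = L,
                        group = c("A", "A", "B", "B"))
  dge <- edgeR::estimateDisp(dge, model.matrix(~c(0, 0, 1, 1)))
  fit <- edgeR::glmQLFit(dge, model.matrix(~c(0, 0, 1, 1)))
  qlf <- edgeR::glmQLFTest(fit)
  tab <- edgeR::topTags(qlf, n = Inf, sort.by = "none")$table
  # fold-change direction agrees wherever either method is confident
  conf <- res$fdr < 0.05 | tab$FDR < 0.05
  expect_gt(mean(sign(res$log2FC[conf]) == sign(tab$logFC[conf])), 0.95)
  # and the spiked regions are recovered by both
  expect_gt(mean(res$significant[lost]), 0.8)
  expect_gt(mean(tab$FDR[lost] < 0.05), 0.8)
})

test_that("differential bivalency requires concordant calls in both orientations", {
  regions <- gr("chr1", c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500))
  mk <- function(sig, lfc) data.frame(log2FC = lfc, dispersion = 0.1,
                                      pvalue = 0.01, fdr = 0.01,
                                      significant = sig)
  a <- mk(c(TRUE, TRUE, FALSE, TRUE), c(-2, -2, -2, 2))
  b <- mk(c(TRUE, FALSE, TRUE, TRUE), c(-2, -2, -2, -2))
  calls <- call_differential_bivalency(a, b, regions)
  # region 1: both sig, same sign -> called; 2,3: one orientation only;
  # 4: both sig but opposite signs -> not called
  expect_equal(calls$region_calls, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(calls$n_lost, 1L)
  expect_equal(calls$n_gained, 0L)
  empty <- call_differential_bivalency(mk(TRUE, 1)[0, ], mk(TRUE, 1)[0, ],
                                       GenomicRanges::GRanges())
  expect_equal(empty$n_regions, 0L)
  # promoter roll-up with known/novel split
  prom <- data.frame(gene = c("g1", "g2"), chrom = "chr1",
                     start = c(0, 3000), end = c(100, 3100),
                     class = factor(c("HC", "HC"),
                                    levels = c("HC", "K4B", "K27B", "LC")),
                     peak_ids = "1", stringsAsFactors = FALSE)
  calls2 <- call_differential_bivalency(a, b, regions, promoters = prom,
                                        known_genes = "g1")
  expect_equal(calls2$promoter_genes, "g1")
  expect_equal(calls2$n_known, 1L)
  expect_equal(calls2$n_novel, 0L)
})
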