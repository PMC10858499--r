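test_that("config validation rejects physically meaningless parameters", {
  expect_error(sim_config(seed = 1, capture_specific = 0.002,
                          capture_nonspecific = 0.003), "exceed")
  expect_error(sim_config(seed = 1, mark_prob = 1.5), "probability")
  expect_error(sim_config(), "'seed' is required")
  expect_error(sim_config(seed = 1, region_width_range = c(50, 100)),
               "nucleosome_spacing")
})

test_that("build_truth satisfies counts, spacing and determinism", {
  cfg <- tiny_sim_config(seed = 1)
  tr1 <- build_truth(cfg)
  tr2 <- build_truth(cfg)
  expect_identical(gr_df(tr1), gr_df(tr2))
  expect_identical(S4Vectors::mcols(tr1)$state, S4Vectors::mcols(tr2)$state)
  counts <- table(S4Vectors::mcols(tr1)$state)
  expect_equal(counts[names(cfg$region_counts)][cfg$region_counts > 0],
               table(factor(rep(names(cfg$region_counts),
                                cfg$region_counts)))[
                 names(cfg$region_counts)][cfg$region_counts > 0])
  # non-overlapping, sorted, >= 2 * fragment_length apart, widths in range
  df <- gr_df(tr1)
  w <- df$end0 - df$start0
  expect_true(all(w >= cfg$region_width_range[1] &
                    w <= cfg$region_width_range[2]))
  expect_lte(sum(w), cfg$n_chrom * cfg$chrom_length)
  by_chr <- split(df, df$chrom)
  for (d in by_chr)
    if (nrow(d) > 1)
      expect_true(all(d$start0[-1] - d$end0[-nrow(d)] >=
                        2 * cfg$fragment_length))
})

test_that("empty region_counts give an empty truth map", {
  cfg <- tiny_sim_config(seed = 1)
  cfg$region_counts[] <- 0L
  expect_length(build_truth(cfg), 0L)
})

test_that("an overfull genome raises a capacity error", {
  cfg <- sim_config(seed = 1, n_chrom = 1, chrom_length = 60000,
                    region_counts = c(BIVALENT = 400L))
  expect_error(build_truth(cfg), "capacity")
})

test_that("simulate_sample is reproducible and validates its plan", {
  cfg <- tiny_sim_config(seed = 2)
  tr <- build_truth(cfg)
  a <- suppressWarnings(simulate_sample(tr, cfg, c("K4", "K27"), seed = 5))
  b <- suppressWarnings(simulate_sample(tr, cfg, c("K4", "K27"), seed = 5))
  expect_identical(gr_df(a$ranges), gr_df(b$ranges))
  expect_error(simulate_sample(tr, cfg, c("K4", "K27", "K4")), "plan")
  expect_error(simulate_sample(tr, cfg, "H3"), "plan")
})

test_that("reciprocal reChIP sees bivalent regions, not heterogeneity", {
  cfg <- tiny_sim_config(seed = 3)
  tr <- build_truth(cfg)
  st <- S4Vectors::mcols(tr)$state
  biv <- tr[st == "BIVALENT"]
  het <- tr[st %in% c("ALLELIC_HET", "CELLULAR_HET")]
  fs <- suppressWarnings(simulate_sample(tr, cfg, c("K4", "K27"), seed = 9))
  dens <- function(regions)
    sum(GenomicRanges::countOverlaps(regions, fs$ranges)) /
      sum(BiocGenerics::width(regions))
  # bivalency specificity: >= 10x density over heterogeneous regions
  expect_gte(dens(biv) / max(dens(het), 1e-12), 10)
})

test_that("heterogeneity-only truth yields orders of magnitude fewer reChIP survivors", {
  base <- tiny_sim_config(seed = 4)
  cfg_het <- tiny_sim_config(seed = 4, background_mark_prob = 0,
                             region_counts = c(ALLELIC_HET = 20L,
                                               CELLULAR_HET = 20L))
  cfg_biv <- tiny_sim_config(seed = 4, background_mark_prob = 0,
                             region_counts = c(BIVALENT = 40L))
  n_het <- suppressWarnings(simulate_sample(build_truth(cfg_het), cfg_het,
                                            c("K4", "K27"),
                                            seed = 11))$library_size
  n_biv <- suppressWarnings(simulate_sample(build_truth(cfg_biv), cfg_biv,
                                            c("K4", "K27"),
                                            seed = 11))$library_size
  expect_lt(n_het, n_biv / 20)
})

test_that("single ChIPs are blind to heterogeneity (comparable enrichment)", {
  cfg <- tiny_sim_config(seed = 5)
  tr <- build_truth(cfg)
  st <- S4Vectors::mcols(tr)$state
  for (plan in list("K4", "K27")) {
    fs <- suppressWarnings(simulate_sample(tr, cfg, plan, seed = 13))
    dens <- function(sel) {
      r <- tr[sel]
      sum(GenomicRanges::countOverlaps(r, fs$ranges)) /
        sum(BiocGenerics::width(r))
    }
    d_biv <- dens(st == "BIVALENT")
    d_het <- dens(st %in% c("ALLELIC_HET", "CELLULAR_HET"))
    expect_lt(d_biv / d_het, 2.3)
    expect_gt(d_biv / d_het, 1)
  }
})

test_that("capture probabilities are recoverable from pure-state regions", {
  cfg <- tiny_sim_config(seed = 6, depth = 5e6)  # emit all survivors
  tr <- build_truth(cfg)
  st <- S4Vectors::mcols(tr)$state
  fs <- suppressWarnings(simulate_sample(tr, cfg, "K4", seed = 17))
  units_per_bp <- 2 * cfg$n_cells / cfg$nucleosome_spacing
  frac <- function(sel) {
    r <- tr[sel]
    sum(GenomicRanges::countOverlaps(r, fs$ranges)) /
      (sum(BiocGenerics::width(r)) * units_per_bp)
  }
  # K27-only regions: capture is almost purely nonspecific -> b
  b_hat <- frac(st == "K27_ONLY")
  # K4-only regions: m*e + (1-m)*b
  e_hat <- (frac(st == "K4_ONLY") - (1 - cfg$mark_prob) * b_hat) /
    cfg$mark_prob
  expect_lt(abs(e_hat - cfg$capture_specific) / cfg$capture_specific, 0.2)
  expect_lt(abs(b_hat - cfg$capture_nonspecific) / cfg$capture_nonspecific,
            0.2)
})

test_that("empty fragment pools raise a stage-naming error", {
  cfg <- tiny_sim_config(seed = 7, background_mark_prob = 0,
                         capture_nonspecific = 0, carryover = 0,
                         region_counts = c(K4_ONLY = 5L))
  tr <- build_truth(cfg)
  # second round captures K27 but nothing carries K27 and carry-over is off
  expect_error(simulate_sample(tr, cfg, c("K4", "K27"), seed = 1),
               "second immunoprecipitation")
  expect_error(simulate_sample(tr, cfg, c("IGG", "IGG"), seed = 1),
               "first immunoprecipitation")
})

test_that("make_study writes the expected file set deterministically", {
  cfg <- sim_config(seed = 8, n_chrom = 1, chrom_length = 5e5, n_cells = 50,
                    depth = 2000,
                    region_counts = c(K4_ONLY = 3L, K27_ONLY = 3L,
                                      BIVALENT = 4L, ALLELIC_HET = 2L,
                                      CELLULAR_HET = 2L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- suppressWarnings(make_study(cfg, 2, d1, overwrite = TRUE))
  s2 <- suppressWarnings(make_study(cfg, 2, d2, overwrite = TRUE))
  beds <- list.files(d1, pattern = "\\.bed$")
  # 2 replicates x 4 plans + 1 shared IgG-IgG + truth.bed
  expect_length(setdiff(beds, "truth.bed"), 9L)
  expect_equal(nrow(s1$sample_sheet), 9L)
  expect_true(all(file.exists(s1$sample_sheet$path)))
  for (f in beds)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  # refusing to clobber
  expect_error(make_study(cfg, 1, d1), "overwrite")
  # truth round-trip
  tr <- read_truth(file.path(d1, "truth.bed"))
  expect_equal(sort(table(S4Vectors::mcols(tr)$state)),
               sort(table(S4Vectors::mcols(s1$truth)$state)))
})
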