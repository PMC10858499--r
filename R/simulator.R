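#' Simulator configuration
#'
#' Parameters of the generative model of sequential immunoprecipitation on a
#' mixed population of cells. Nucleosomes sit on a fixed spacing grid; inside
#' designated regions their H3K4me3/H3K27me3 marks follow the region's state
#' rule, outside they carry each mark at a low background rate. One or two
#' antibody capture rounds then thin the fragment pool.
#'
#' @param n_chrom Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in bp (default 5e6).
#' @param nucleosome_spacing Grid spacing between nucleosome centres, bp
#'   (default 200).
#' @param fragment_length Output fragment length, bp (default 147,
#'   mononucleosomal).
#' @param n_cells Number of cells in the population (default 2000); ploidy is
#'   fixed at 2, so each nucleosome position carries `2 * n_cells` units.
#' @param region_counts Named integer vector of region counts per state:
#'   K4_ONLY, K27_ONLY, BIVALENT, ALLELIC_HET, CELLULAR_HET.
#' @param region_width_range Length-2 numeric: min/max region width, bp.
#' @param het_fraction Proportion of cells in the K4 subpopulation for
#'   CELLULAR_HET regions (default 0.5).
#' @param mark_prob Per-nucleosome probability that a region's designated mark
#'   is present (default 0.8).
#' @param background_mark_prob Per-nucleosome mark probability outside
#'   designated regions, and for the non-designated mark inside them
#'   (default 0.001).
#' @param capture_specific Probability a fragment carrying the antibody's
#'   target mark is captured (default 0.3).
#' @param capture_nonspecific Capture probability otherwise; also the IgG
#'   capture probability (default 0.003). Must be below `capture_specific`.
#' @param elution_efficiency Probability a captured fragment survives elution
#'   into the second round (default 0.8).
#' @param carryover Probability a first-round fragment passes the second round
#'   regardless of its marks (default 0.002).
#' @param depth Target number of fragments per output sample (default 5e5).
#' @param seed Integer RNG seed (required).
#' @param mode One of "WT", "TAZ" (all H3K27me3 erased, emulating Ezh2
#'   inhibition) or "DKO" (a subset of bivalent regions loses both marks).
#' @param dko_dependent_fraction Proportion of BIVALENT regions that lose both
#'   marks in DKO mode (default 0.1).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 2L,
                       chrom_length = 5e6,
                       nucleosome_spacing = 200L,
                       fragment_length = 147L,
                       n_cells = 2000L,
                       region_counts = c(K4_ONLY = 60L, K27_ONLY = 60L,
                                         BIVALENT = 80L, ALLELIC_HET = 40L,
                                         CELLULAR_HET = 40L),
                       region_width_range = c(600L, 2000L),
                       het_fraction = 0.5,
                       mark_prob = 0.8,
                       background_mark_prob = 0.001,
                       capture_specific = 0.3,
                       capture_nonspecific = 0.003,
                       elution_efficiency = 0.8,
                       carryover = 0.002,
                       depth = 5e5,
                       seed,
                       mode = c("WT", "TAZ", "DKO"),
                       dko_dependent_fraction = 0.1) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("'seed' is required")
  check_count(seed, "seed")
  check_count(n_chrom, "n_chrom", min = 1)
  check_count(n_cells, "n_cells", min = 1)
  if (depth < 1) stop("'depth' must be >= 1")
  for (p in c("het_fraction", "mark_prob", "background_mark_prob",
              "capture_specific", "capture_nonspecific",
              "elution_efficiency", "carryover", "dko_dependent_fraction"))
    check_prob(get(p), p)
  if (capture_specific <= capture_nonspecific)
    stop("capture_specific must exceed capture_nonspecific, ",
         "otherwise the assay carries no signal")
  states <- c("K4_ONLY", "K27_ONLY", "BIVALENT", "ALLELIC_HET", "CELLULAR_HET")
  rc <- setNames(rep(0L, length(states)), states)
  if (length(region_counts)) {
    if (is.null(names(region_counts)) ||
        !all(names(region_counts) %in% states))
      stop("region_counts names must be among: ", paste(states, collapse = ", "))
    rc[names(region_counts)] <- as.integer(region_counts)
  }
  if (any(rc < 0)) stop("region_counts must be non-negative")
  if (length(region_width_range) != 2L ||
      region_width_range[1] > region_width_range[2])
    stop("region_width_range must be an increasing pair")
  if (region_width_range[1] < nucleosome_spacing)
    stop("region widths must be >= nucleosome_spacing")
  structure(list(
    n_chrom = as.integer(n_chrom), chrom_length = chrom_length,
    nucleosome_spacing = as.integer(nucleosome_spacing),
    fragment_length = as.integer(fragment_length),
    n_cells = as.integer(n_cells), ploidy = 2L,
    region_counts = rc, region_width_range = as.numeric(region_width_range),
    het_fraction = het_fraction, mark_prob = mark_prob,
    background_mark_prob = background_mark_prob,
    capture_specific = capture_specific,
    capture_nonspecific = capture_nonspecific,
    elution_efficiency = elution_efficiency, carryover = carryover,
    depth = depth, seed = as.integer(seed), mode = mode,
    dko_dependent_fraction = dko_dependent_fraction
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d x %g bp chromosomes, %d cells, mode %s, seed %d\n",
    x$n_chrom, x$chrom_length, x$n_cells, x$mode, x$seed))
  invisible(x)
}

#' Chromosome sizes implied by a simulator configuration
#' @param config A `sim_config`.
#' @return Named numeric vector `chr1..chrN`.
#' @export
sim_chrom_sizes <- function(config) {
  setNames(rep(config$chrom_length, config$n_chrom),
           paste0("chr", seq_len(config$n_chrom)))
}

#' Place ground-truth regions on the synthetic genome
#'
#' Draws the configured number of regions of each state, placed uniformly at
#' random without overlap and at least `2 * fragment_length` apart, widths
#' uniform within `region_width_range`. Deterministic given `config$seed`.
#' In DKO mode, a seeded `dko_dependent_fraction` subset of BIVALENT regions
#' is flagged as losing both marks.
#'
#' @param config A `sim_config`.
#' @return A `truth_map`: `GRanges` with metadata columns `state` and
#'   `dko_dependent`, sorted and non-overlapping; every base not listed is
#'   implicitly state NONE.
#' @export
build_truth <- function(config) {
  stopifnot(is(config, "sim_config"))
  sizes <- sim_chrom_sizes(config)
  states <- rep(names(config$region_counts), config$region_counts)
  gap <- 2L * config$fragment_length
  with_seed(config$seed, {
    states <- sample(states)  # interleave states across the genome
    chroms <- character(0); starts <- numeric(0); ends <- numeric(0)
    for (st in states) {
      w <- round(runif(1, config$region_width_range[1],
                       config$region_width_range[2]))
      placed <- FALSE
      for (try in seq_len(2000L)) {
        chr_i <- sample.int(config$n_chrom, 1,
                            prob = sizes / sum(sizes))
        chr <- names(sizes)[chr_i]
        s <- floor(runif(1, 0, sizes[[chr_i]] - w))
        same <- chroms == chr
        if (!any(same) ||
            all(s + w + gap <= starts[same] | s >= ends[same] + gap)) {
          chroms <- c(chroms, chr); starts <- c(starts, s)
          ends <- c(ends, s + w)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place all regions: genome too small for the ",
             "requested region_counts (capacity error)")
    }
    st_final <- states
    gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(starts + 1, ends))
    mcols(gr)$state <- st_final
    mcols(gr)$dko_dependent <- rep(FALSE, length(gr))
    if (config$mode == "DKO") {
      biv <- which(st_final == "BIVALENT")
      n_dep <- round(config$dko_dependent_fraction * length(biv))
      if (n_dep > 0)
        mcols(gr)$dko_dependent[sample(biv, n_dep)] <- TRUE
    }
    structure_truth(BiocGenerics::sort(gr), config)
  })
}

structure_truth <- function(gr, config) {
  attr(gr, "sim_chrom_sizes") <- sim_chrom_sizes(config)
  gr
}

#' Write a truth map as BED4 (name column = state)
#' @param truth A truth `GRanges` from [build_truth()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  gr <- granges_only(truth)
  mcols(gr)$name <- ifelse(mcols(truth)$dko_dependent,
                           paste0(mcols(truth)$state, ":dko_dependent"),
                           mcols(truth)$state)
  write_bed(gr, path)
}

#' Read a truth BED4 written by [write_truth()]
#' @param path Path to the truth BED file.
#' @return A truth `GRanges` with `state` and `dko_dependent` columns.
#' @export
read_truth <- function(path) {
  gr <- read_bed(path, dialect = "BED4")
  nm <- mcols(gr)$name
  mcols(gr)$state <- sub(":dko_dependent$", "", nm)
  mcols(gr)$dko_dependent <- grepl(":dko_dependent$", nm)
  mcols(gr)$name <- NULL
  gr
}

# Per-nucleosome-position state assignment and unit-class decomposition.
# Returns, for each position, one or two "classes" of (cell, allele) units
# with class-specific mark probabilities (p4, p27) and unit counts.
position_classes <- function(truth, config, chrom) {
  sp <- config$nucleosome_spacing
  len <- config$chrom_length
  centers <- seq.int(sp %/% 2L, len - 1L, by = sp)
  n_pos <- length(centers)
  state <- rep("NONE", n_pos)
  dko_dep <- rep(FALSE, n_pos)
  tr <- truth[as.character(seqnames(truth)) == chrom]
  if (length(tr)) {
    pos_gr <- GenomicRanges::GRanges(chrom,
                                     IRanges::IRanges(centers + 1, centers + 1))
    hits <- GenomicRanges::findOverlaps(pos_gr, tr)
    state[queryHits(hits)] <- mcols(tr)$state[subjectHits(hits)]
    dko_dep[queryHits(hits)] <- mcols(tr)$dko_dependent[subjectHits(hits)]
  }
  if (config$mode == "DKO") state[dko_dep] <- "NONE"
  eps <- config$background_mark_prob
  m <- config$mark_prob
  N <- 2L * config$n_cells
  n_k4cells <- 2L * round(config$het_fraction * config$n_cells)
  # class probabilities: two unit classes A and B per position
  p4A <- p27A <- p4B <- p27B <- numeric(n_pos)
  nA <- rep(N, n_pos); nB <- rep(0L, n_pos)
  idx <- state == "NONE"
  p4A[idx] <- eps; p27A[idx] <- eps
  idx <- state == "K4_ONLY"
  p4A[idx] <- m; p27A[idx] <- eps
  idx <- state == "K27_ONLY"
  p4A[idx] <- eps; p27A[idx] <- m
  idx <- state == "BIVALENT"
  p4A[idx] <- m; p27A[idx] <- m
  idx <- state == "ALLELIC_HET"   # allele 0: K4; allele 1: K27
  nA[idx] <- config$n_cells; nB[idx] <- config$n_cells
  p4A[idx] <- m; p27A[idx] <- eps
  p4B[idx] <- eps; p27B[idx] <- m
  idx <- state == "CELLULAR_HET"  # K4 subpopulation vs K27 subpopulation
  nA[idx] <- n_k4cells; nB[idx] <- N - n_k4cells
  p4A[idx] <- m; p27A[idx] <- eps
  p4B[idx] <- eps; p27B[idx] <- m
  if (config$mode == "TAZ") {  # global H3K27me3 depletion
    p27A[] <- 0; p27B[] <- 0
  }
  list(centers = centers, state = state,
       classes = list(list(n = nA, p4 = p4A, p27 = p27A),
                      list(n = nB, p4 = p4B, p27 = p27B)))
}

capture_prob <- function(antibody, has4, has27, e, b) {
  if (antibody == "IGG") return(b)
  target <- if (antibody == "K4") has4 else has27
  if (target) e else b
}

#' Simulate one (re)ChIP sample
#'
#' Applies the generative model: per cell, allele and nucleosome position,
#' marks are drawn per the region state rule; round 1 captures fragments with
#' probability `capture_specific` when the antibody's target mark is present
#' (IgG: always nonspecific); between rounds fragments survive elution with
#' probability `elution_efficiency`; round 2 captures by the same rule OR
#' retains the fragment with the mark-independent `carryover` probability.
#' Both histone-tail marks travel with the fragment, which is what makes the
#' two-round protocol specific for bona fide bivalency. The surviving pool is
#' subsampled without replacement to `depth` fragments; if fewer survive, all
#' survivors are emitted with a warning.
#'
#' Internally, identically distributed (cell, allele) units at a nucleosome
#' position are aggregated and each round is drawn as binomial thinning per
#' mark combination — distributionally identical to per-unit Bernoulli draws.
#'
#' @param truth A truth `GRanges` from [build_truth()].
#' @param config A `sim_config`.
#' @param plan Character vector of 1 (single ChIP) or 2 (reChIP) antibody
#'   targets from "K4", "K27", "IGG", in capture order.
#' @param seed Integer seed for this sample; defaults to a seed derived from
#'   `config$seed` and the plan.
#' @return A `fragment_set` of `fragment_length` intervals centred on
#'   nucleosome positions.
#' @export
simulate_sample <- function(truth, config, plan,
                            seed = derive_seed(config$seed,
                                               paste(plan, collapse = "-"))) {
  stopifnot(is(config, "sim_config"))
  plan <- toupper(plan)
  if (!length(plan) %in% 1:2 || !all(plan %in% c("K4", "K27", "IGG")))
    stop("plan must be 1 or 2 antibodies from K4, K27, IGG")
  e <- config$capture_specific; b <- config$capture_nonspecific
  eta <- config$elution_efficiency; cc <- config$carryover
  two_rounds <- length(plan) == 2L
  sizes <- sim_chrom_sizes(config)
  with_seed(seed, {
    frag_chrom <- character(0); frag_center <- numeric(0)
    n_marked <- n_cap1 <- n_eluted <- n_cap2 <- 0
    for (chr in names(sizes)) {
      pc <- position_classes(truth, config, chr)
      n_pos <- length(pc$centers)
      pos_counts <- numeric(n_pos)
      for (cl in pc$classes) {
        if (all(cl$n == 0L)) next
        # multinomial split of units into the 4 mark combinations,
        # drawn as sequential binomials (exact decomposition)
        p_bb <- cl$p4 * cl$p27
        p_40 <- cl$p4 * (1 - cl$p27)
        p_07 <- (1 - cl$p4) * cl$p27
        n_bb <- rbinom(n_pos, cl$n, p_bb)
        rem <- cl$n - n_bb
        q <- ifelse(p_bb < 1, p_40 / (1 - p_bb), 0)
        n_40 <- rbinom(n_pos, rem, pmin(q, 1))
        rem <- rem - n_40
        q <- ifelse(p_bb + p_40 < 1, p_07 / (1 - p_bb - p_40), 0)
        n_07 <- rbinom(n_pos, rem, pmin(q, 1))
        n_00 <- rem - n_07
        for (combo in list(list(n = n_bb, has4 = TRUE, has27 = TRUE),
                           list(n = n_40, has4 = TRUE, has27 = FALSE),
                           list(n = n_07, has4 = FALSE, has27 = TRUE),
                           list(n = n_00, has4 = FALSE, has27 = FALSE))) {
          if (combo$has4 || combo$has27) n_marked <- n_marked + sum(combo$n)
          p1 <- capture_prob(plan[1], combo$has4, combo$has27, e, b)
          cap1 <- rbinom(n_pos, combo$n, p1)
          n_cap1 <- n_cap1 + sum(cap1)
          if (!two_rounds) {
            pos_counts <- pos_counts + cap1
          } else {
            elu <- rbinom(n_pos, cap1, eta)
            n_eluted <- n_eluted + sum(elu)
            p2 <- capture_prob(plan[2], combo$has4, combo$has27, e, b)
            cap2 <- rbinom(n_pos, elu, 1 - (1 - p2) * (1 - cc))
            n_cap2 <- n_cap2 + sum(cap2)
            pos_counts <- pos_counts + cap2
          }
        }
      }
      nz <- which(pos_counts > 0)
      if (length(nz)) {
        frag_chrom <- c(frag_chrom, rep(chr, sum(pos_counts[nz])))
        frag_center <- c(frag_center, rep(pc$centers[nz], pos_counts[nz]))
      }
    }
    n_surv <- length(frag_center)
    if (n_surv == 0L) {
      stage <- if (n_cap1 == 0L) "first immunoprecipitation"
      else if (two_rounds && n_eluted == 0L) "elution"
      else "second immunoprecipitation"
      stop(sprintf("fragment pool emptied at stage: %s (plan %s)",
                   stage, paste(plan, collapse = "-")))
    }
    if (n_surv > config$depth) {
      keep <- sort(sample.int(n_surv, config$depth))
      frag_chrom <- frag_chrom[keep]; frag_center <- frag_center[keep]
    } else if (n_surv < config$depth) {
      warning(sprintf("only %d fragments survived (< depth %g); emitting all",
                      n_surv, config$depth))
    }
    half <- config$fragment_length %/% 2L
    start0 <- pmax(frag_center - half, 0)
    end0 <- pmin(start0 + config$fragment_length, sizes[frag_chrom])
    gr <- GenomicRanges::GRanges(frag_chrom,
                                 IRanges::IRanges(start0 + 1, end0))
    gr <- BiocGenerics::sort(gr)
    fragment_set(gr, sample_id = paste(c(plan, tolower(config$mode)),
                                       collapse = "-"))
  })
}

#' Generate a complete simulated study on disk
#'
#' Writes, per replicate, fragment BEDs for plans K4, K27, K4-K27 and K27-K4,
#' plus one shared IgG-IgG control, a truth BED, a plain-text YAML config echo
#' and a tab-separated sample sheet (sample_id, role, condition, replicate,
#' path, seed). Per-sample seeds are derived deterministically from
#' `config$seed` plus a stable hash of the sample id, so two runs with the
#' same config produce identical files.
#'
#' @param config A `sim_config`.
#' @param replicates Number of biological replicates (>= 1).
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing directory (default FALSE).
#' @param truth Optional pre-built truth map (so e.g. WT and DKO studies can
#'   share one genome); defaults to `build_truth(config)`.
#' @param condition Condition label recorded in the sample sheet (defaults to
#'   `config$mode`).
#' @return Invisibly, a list with `sample_sheet` (data.frame) and `truth`.
#' @export
make_study <- function(config, replicates, dir, overwrite = FALSE,
                       truth = NULL, condition = config$mode) {
  check_count(replicates, "replicates", min = 1)
  if (dir.exists(dir) && !overwrite &&
      length(list.files(dir)) > 0)
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(truth)) truth <- build_truth(config)
  plans <- list(k4_total = "K4", k27_total = "K27",
                k4k27 = c("K4", "K27"), k27k4 = c("K27", "K4"))
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    for (role in names(plans)) {
      sample_id <- sprintf("%s_%s_rep%d", condition, role, rep_i)
      seed <- derive_seed(config$seed, sample_id)
      fs <- simulate_sample(truth, config, plans[[role]], seed = seed)
      path <- file.path(dir, paste0(sample_id, ".bed"))
      write_fragments(fs, path)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, role = role, condition = condition,
        replicate = rep_i, path = path, seed = seed,
        stringsAsFactors = FALSE)
    }
  }
  sample_id <- sprintf("%s_igg_igg", condition)
  seed <- derive_seed(config$seed, sample_id)
  fs <- simulate_sample(truth, config, c("IGG", "IGG"), seed = seed)
  path <- file.path(dir, paste0(sample_id, ".bed"))
  write_fragments(fs, path)
  rows[[length(rows) + 1L]] <- data.frame(
    sample_id = sample_id, role = "igg_igg", condition = condition,
    replicate = 1L, path = path, seed = seed, stringsAsFactors = FALSE)
  sheet <- do.call(rbind, rows)
  write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_truth(truth, file.path(dir, "truth.bed"))
  cfg <- unclass(config)
  cfg$region_counts <- as.list(cfg$region_counts)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(list(sample_sheet = sheet, truth = truth))
}

#' Generate a paired wild-type / knockout study sharing one genome
#'
#' Builds a single truth map in DKO mode (so a seeded subset of bivalent
#' regions is flagged as knockout-dependent), then writes a WT study and a DKO
#' study against that shared truth into subdirectories `WT/` and `DKO/`, each
#' with `replicates` clones.
#'
#' @param config A `sim_config`; its `mode` is overridden per condition.
#' @param replicates Clones per condition (>= 2 needed for the differential
#'   test).
#' @param dir Output directory.
#' @param overwrite Allow existing directory.
#' @return Invisibly, list with combined `sample_sheet` and the shared `truth`.
#' @export
make_dko_study <- function(config, replicates, dir, overwrite = FALSE) {
  cfg_dko <- config; cfg_dko$mode <- "DKO"
  cfg_wt <- config; cfg_wt$mode <- "WT"
  truth <- build_truth(cfg_dko)
  if (dir.exists(dir) && !overwrite && length(list.files(dir)) > 0)
    stop("output directory exists and is non-empty; use overwrite = TRUE")
  wt <- make_study(cfg_wt, replicates, file.path(dir, "WT"),
                   overwrite = overwrite, truth = truth, condition = "WT")
  dko <- make_study(cfg_dko, replicates, file.path(dir, "DKO"),
                    overwrite = overwrite, truth = truth, condition = "DKO")
  sheet <- rbind(wt$sample_sheet, dko$sample_sheet)
  write.table(sheet, file.path(dir, "sample_sheet.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(list(sample_sheet = sheet, truth = truth))
}
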