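#' Pipeline configuration
#'
#' Bundles the simulator, peak-calling and differential configurations with a
#' master seed. Round-trips losslessly through a YAML file; unknown keys are
#' rejected.
#'
#' @param sim A `sim_config` (optional; only needed to simulate).
#' @param peaks A `peak_call_config`.
#' @param diff A `diff_config`.
#' @param seed Master integer seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, peaks = peak_call_config(),
                            diff = diff_config(), seed = 1L) {
  structure(list(sim = sim, peaks = peaks, diff = diff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  x <- lapply(unclass(config), function(v)
    if (is.list(v)) lapply(unclass(v), function(e)
      if (is.numeric(e) && !is.null(names(e))) as.list(e) else e)
    else v)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file written by [write_pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- c("sim", "peaks", "diff", "seed")
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  sim <- if (!is.null(x$sim)) {
    args <- x$sim
    args$ploidy <- NULL
    if (!is.null(args$region_counts))
      args$region_counts <- unlist(args$region_counts)
    do.call(sim_config, args)
  }
  peaks <- if (is.null(x$peaks)) peak_call_config()
           else do.call(peak_call_config, x$peaks)
  diffc <- if (is.null(x$diff)) diff_config() else do.call(diff_config, x$diff)
  pipeline_config(sim = sim, peaks = peaks, diff = diffc,
                  seed = x$seed %||% 1L)
}

#' Read a sample sheet
#'
#' Tab-separated with header; required columns `sample_id`, `role`, `path`;
#' optional `condition`, `replicate`, `seed`. Roles are from
#' `k4_total`, `k27_total`, `k4k27`, `k27k4`, `igg_igg`, `input`.
#'
#' @param path Sample sheet path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample_id", "role", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  ok <- c("k4_total", "k27_total", "k4k27", "k27k4", "igg_igg", "input")
  bad <- setdiff(unique(df$role), ok)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  if (is.null(df$condition)) df$condition <- "WT"
  if (is.null(df$replicate)) df$replicate <- 1L
  df
}

load_role <- function(sheet, role, condition = NULL) {
  sel <- sheet$role == role
  if (!is.null(condition)) sel <- sel & sheet$condition == condition
  rows <- sheet[sel, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i)
    read_fragments(rows$path[i], sample_id = rows$sample_id[i]))
}

# Peak-call each replicate of a role against the control, post-filter,
# and return the replicate-consensus interval set.
role_consensus <- function(frags_list, control, config, chrom_sizes,
                           blacklist = NULL) {
  peaksets <- lapply(frags_list, function(fs) {
    pk <- call_islands(fs, control, config, chrom_sizes)
    filter_peaks(pk, config, blacklist)
  })
  list(consensus = consensus_peaks(peaksets), replicates = peaksets)
}

#' Run the full bivalency pipeline from a sample sheet
#'
#' Executes peak calling per sample (IgG-IgG as control when present, else
#' input), replicate consensus per role, reciprocal bivalent calling,
#' confidence classification against the total single ChIPs, promoter
#' classification (when a TSS table is given), FRiP and in-silico comparison
#' QC, and — when the sheet holds two conditions with >= 2 replicates each —
#' TMM-normalised NB differential bivalency. A JSON summary holding every
#' count is written when `output_dir` is set.
#'
#' @param sample_sheet data.frame from [read_sample_sheet()], or a path.
#' @param chrom_sizes Named vector, 2-column data.frame, or a chrom.sizes
#'   path.
#' @param config A `pipeline_config`.
#' @param tss Optional TSS `GRanges` (see [read_tss()]) for promoter stages.
#' @param blacklist Optional `GRanges` excluded from peaks.
#' @param output_dir Optional directory for the JSON summary and result
#'   tables.
#' @return List with `peaks` (per role), `bivalent`, `classified`, `tallies`,
#'   `insilico`, `frip`, `promoters`, `differential` (when applicable) and
#'   `summary` (the flat count list written as JSON).
#' @export
run_all <- function(sample_sheet, chrom_sizes, config = pipeline_config(),
                    tss = NULL, blacklist = NULL, output_dir = NULL) {
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  if (is.character(chrom_sizes)) chrom_sizes <- read_chrom_sizes(chrom_sizes)
  sizes <- as_chrom_sizes(chrom_sizes)
  for (role in c("k4k27", "k27k4", "igg_igg"))
    if (!role %in% sample_sheet$role)
      stop("sample sheet is missing required role: ", role)
  conditions <- unique(sample_sheet$condition)
  main_cond <- conditions[1]
  ctrl <- load_role(sample_sheet, "igg_igg", main_cond)
  if (!length(ctrl)) ctrl <- load_role(sample_sheet, "igg_igg")
  control <- ctrl[[1]]
  pkcfg <- config$peaks
  stage <- function(nm, expr) tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", nm, conditionMessage(e)),
         call. = FALSE))

  frags <- list()
  cons <- list()
  for (role in c("k4_total", "k27_total", "k4k27", "k27k4")) {
    fl <- load_role(sample_sheet, role, main_cond)
    if (!length(fl)) next
    frags[[role]] <- fl
    cons[[role]] <- stage(paste0("peaks:", role),
                          role_consensus(fl, control, pkcfg, sizes, blacklist))
  }
  if (is.null(cons$k4k27) || is.null(cons$k27k4))
    stop("both reChIP orientations are required")

  biv <- stage("reciprocal_bivalent",
               reciprocal_bivalent(cons$k4k27$consensus,
                                   cons$k27k4$consensus))
  tk4 <- cons$k4_total$consensus %||% GenomicRanges::GRanges()
  tk27 <- cons$k27_total$consensus %||% GenomicRanges::GRanges()
  classified <- stage("classify_peaks",
                      classify_peaks(biv$regions, tk4, tk27))
  insilico <- stage("in_silico_comparison",
                    in_silico_comparison(tk4, tk27, biv$regions))
  frip_rows <- lapply(names(frags), function(role) {
    own_peaks <- cons[[role]]$consensus
    rows <- lapply(frags[[role]], frip, peaks = own_peaks)
    igg <- frip(control, own_peaks)
    igg$sample_id <- paste0("igg_igg@", role)
    c(rows, list(igg))
  })
  frip_df <- do.call(rbind, lapply(unlist(frip_rows, recursive = FALSE),
                                   as.data.frame))
  promoters <- NULL
  if (!is.null(tss) && length(tss)) {
    prom_win <- promoter_windows(tss, chrom_sizes = sizes)
    promoters <- stage("classify_promoters",
                       classify_promoters(prom_win, classified))
  }
  differential <- NULL
  if (length(conditions) == 2) {
    ok <- all(vapply(conditions, function(cd)
      sum(sample_sheet$role == "k4k27" & sample_sheet$condition == cd) >= 2 &&
      sum(sample_sheet$role == "k27k4" & sample_sheet$condition == cd) >= 2,
      TRUE))
    if (ok) differential <- stage("differential", {
      run_differential(sample_sheet, conditions, cons, control, config,
                       sizes, blacklist, promoters)
    })
  }
  tallies <- attr(classified, "tallies")
  summary <- c(
    list(n_k4k27 = biv$counts$n_k4k27, n_k27k4 = biv$counts$n_k27k4,
         n_shared = biv$counts$n_shared),
    as.list(setNames(as.integer(tallies), paste0("n_", names(tallies)))),
    list(n_insilico = insilico$n_insilico,
         n_validated = insilico$n_validated,
         n_unvalidated = insilico$n_unvalidated,
         fp_rate_percent = insilico$fp_rate_percent,
         frip = setNames(as.list(frip_df$frip), frip_df$sample_id)))
  if (!is.null(promoters))
    summary$n_bivalent_promoters <- sum(!is.na(promoters$class))
  if (!is.null(differential)) {
    summary$n_differential_regions <- differential$calls$n_regions
    summary$n_differential_lost <- differential$calls$n_lost
    summary$n_differential_gained <- differential$calls$n_gained
    if (!is.null(differential$calls$n_promoters))
      summary$n_differential_promoters <- differential$calls$n_promoters
  }
  stopifnot(sum(tallies) == biv$counts$n_shared)  # partition identity
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    biv_bed <- granges_only(classified)
    mcols(biv_bed)$name <- as.character(mcols(classified)$class)
    write_bed(biv_bed, file.path(output_dir, "bivalent_peaks.bed"))
    if (!is.null(promoters))
      write.table(promoters, file.path(output_dir, "promoters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(peaks = cons, bivalent = biv, classified = classified,
       tallies = tallies, insilico = insilico, frip = frip_df,
       promoters = promoters, differential = differential,
       summary = summary)
}

# Two-condition differential bivalency over consensus reChIP peaks.
run_differential <- function(sheet, conditions, cons, control, config,
                             sizes, blacklist, promoters) {
  out <- list()
  all_frags <- list()
  for (orient in c("k4k27", "k27k4")) {
    fl <- c(load_role(sheet, orient, conditions[1]),
            load_role(sheet, orient, conditions[2]))
    cond <- c(rep(conditions[1],
                  length(load_role_paths(sheet, orient, conditions[1]))),
              rep(conditions[2],
                  length(load_role_paths(sheet, orient, conditions[2]))))
    names(fl) <- vapply(fl, `[[`, "", "sample_id")
    # consensus regions: union of enriched regions across both conditions
    peaksets <- lapply(fl, function(fs)
      filter_peaks(call_islands(fs, control, config$peaks, sizes),
                   config$peaks, blacklist))
    regions <- interval_merge(do.call(c, unname(lapply(peaksets, granges_only))))
    bins <- bin_genome_counts(fl, 10000L, sizes)
    fac <- tmm_factors(bins$counts, bins$lib_sizes, config$diff)
    cm <- region_counts(fl, regions)
    res <- nb_test(cm, attr(cm, "lib_sizes"), fac,
                   factor(cond, levels = conditions), config$diff)
    out[[orient]] <- list(regions = regions, result = res, factors = fac)
  }
  # align the two orientations on the union of their region sets
  shared <- interval_merge(c(out$k4k27$regions, out$k27k4$regions))
  map_res <- function(o) {
    al <- align_seqlevels(shared, o$regions)
    idx <- GenomicRanges::findOverlaps(al$a, al$b,
                                       ignore.strand = TRUE,
                                       select = "first")
    r <- o$result[idx, , drop = FALSE]
    r$significant[is.na(idx)] <- FALSE
    r$log2FC[is.na(idx)] <- 0
    r
  }
  ra <- map_res(out$k4k27); rb <- map_res(out$k27k4)
  calls <- call_differential_bivalency(ra, rb, shared, promoters)
  list(k4k27 = out$k4k27, k27k4 = out$k27k4, regions = shared, calls = calls)
}

load_role_paths <- function(sheet, role, condition) {
  sheet$path[sheet$role == role & sheet$condition == condition]
}
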