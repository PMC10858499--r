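#' @importFrom methods is
#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<-
#' @importFrom stats ppois pchisq p.adjust rbinom runif rnorm t.test setNames
#' @importFrom utils read.table write.table head tail
NULL

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stable small integer hash of a string (independent of R internals), used to
# derive per-sample seeds from a master seed.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (k in utf8ToInt(x)) h <- (h * 31 + k) %% 1000003
  as.integer(h)
}

derive_seed <- function(master_seed, sample_id) {
  as.integer((as.numeric(master_seed) + stable_hash(sample_id)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# Normalise chrom sizes input (named numeric vector or 2-column data.frame).
as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    sizes <- setNames(as.numeric(chrom_sizes[[2]]),
                      as.character(chrom_sizes[[1]]))
  } else if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    sizes <- chrom_sizes
  } else {
    stop("chrom_sizes must be a named numeric vector or two-column data.frame")
  }
  if (any(sizes <= 0)) stop("chromosome sizes must be positive")
  sizes
}
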