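#' Minimum number of SNPs constituting a run of homozygosity
#'
#' The genome-wide false-positive calibration for consecutive-SNP ROH
#' detection: the smallest run length (in SNPs) such that the expected number
#' of runs arising by chance across the whole dataset stays below `alpha`,
#'
#'   l = ceiling( ln(alpha / (n_s * n_i)) / ln(1 - mean_het) ),
#'
#' where `n_s` is the number of genotyped SNPs per individual, `n_i` the
#' number of genotyped individuals and `mean_het` the average per-SNP
#' heterozygosity. The ceiling is taken because l is a minimum count; the
#' result is floored at 1.
#'
#' @param n_s number of genotyped SNPs per individual (>= 1).
#' @param n_i number of genotyped individuals (>= 1).
#' @param alpha tolerated fraction of false-positive runs, in (0, 1).
#' @param mean_het average per-SNP heterozygosity, in (0, 1).
#' @return An integer count >= 1.
#' @export
min_snp_count <- function(n_s, n_i, alpha = 0.05, mean_het) {
  if (!is.numeric(n_s) || n_s < 1 || !is.numeric(n_i) || n_i < 1) {
    stop("n_s and n_i must be >= 1")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.numeric(mean_het) || mean_het <= 0 || mean_het >= 1) {
    stop("mean_het must be in (0, 1)")
  }
  l <- log(alpha / (n_s * n_i)) / log(1 - mean_het)
  # guard against 21.000000001-type floating error before taking the ceiling
  max(1L, as.integer(ceiling(l - 1e-9)))
}

#' ROH detection configuration
#'
#' Parameters of the consecutive-SNP scan. The defaults are the settings of
#' a standard SNP-array ROH analysis: a 500 kb minimum run length (set well
#' above the reach of background linkage disequilibrium), at most one
#' heterozygous and one missing call tolerated inside a run (so that long
#' runs are not fragmented by isolated genotyping errors), a 1 Mb cap on the
#' gap between adjacent SNPs of a run, and the minimum SNP count calibrated
#' from the data by [min_snp_count()] at `alpha = 0.05`.
#'
#' @param alpha tolerated false-positive fraction for [min_snp_count()].
#' @param mean_het average per-SNP heterozygosity; `NULL` (default) computes
#'   it from the data with [mean_heterozygosity()].
#' @param min_length_bp minimum physical span of a run (end - start), bp.
#' @param max_het_in_run maximum heterozygous calls inside a run.
#' @param max_missing_in_run maximum missing calls inside a run.
#' @param min_snps minimum SNPs spanned by a run; `NULL` (default) computes
#'   it via [min_snp_count()].
#' @param max_gap_bp maximum distance between adjacent SNPs of a run, bp.
#' @return A list of class `roh_config`.
#' @export
roh_config <- function(alpha = 0.05, mean_het = NULL,
                       min_length_bp = 500000L,
                       max_het_in_run = 1L, max_missing_in_run = 1L,
                       min_snps = NULL, max_gap_bp = 1000000L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.null(mean_het) && (mean_het <= 0 || mean_het >= 1)) {
    stop("mean_het must be in (0, 1)")
  }
  if (min_length_bp <= 0) stop("min_length_bp must be positive")
  if (!is.null(min_snps) && min_snps < 1) stop("min_snps must be >= 1")
  if (max_het_in_run < 0 || max_missing_in_run < 0) stop("allowances must be >= 0")
  if (max_gap_bp <= 0) stop("max_gap_bp must be positive")
  structure(
    list(
      alpha = alpha, mean_het = mean_het,
      min_length_bp = as.integer(min_length_bp),
      max_het_in_run = as.integer(max_het_in_run),
      max_missing_in_run = as.integer(max_missing_in_run),
      min_snps = if (is.null(min_snps)) NULL else as.integer(min_snps),
      max_gap_bp = as.integer(max_gap_bp)
    ),
    class = "roh_config"
  )
}

#' Detect runs of homozygosity by the consecutive-SNP method
#'
#' Per individual and chromosome, markers are scanned in map order and
#' candidate runs grown while the cumulative heterozygous calls stay within
#' `max_het_in_run`, cumulative missing calls within `max_missing_in_run`,
#' and every inter-SNP gap within `max_gap_bp`. Runs are trimmed so they
#' start and end on homozygous SNPs, and emitted when they span at least
#' `min_snps` markers and at least `min_length_bp` of sequence
#' (end - start). The emitted set is exactly the set of *maximal* qualifying
#' windows: a qualifying run contained in a longer qualifying run is not
#' reported, but partially overlapping maximal runs of the same individual
#' can both appear.
#'
#' @param dataset a QC'd [genotype_dataset()].
#' @param config a [roh_config()]. Unset `mean_het` / `min_snps` are filled
#'   from the data (`n_s` = markers, `n_i` = samples of `dataset`).
#' @return A tibble of segments: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `length_bp` (= end - start), `n_snps` (markers spanned, inclusive),
#'   `n_het`, `n_missing`. The resolved `min_snps` and `mean_het` are
#'   attached as attributes `min_snps` and `mean_het`.
#' @export
detect_roh <- function(dataset, config = roh_config()) {
  stopifnot(inherits(config, "roh_config"))
  mk <- dataset$markers
  if (nrow(mk) > 1) {
    same <- mk$chrom[-1] == mk$chrom[-nrow(mk)]
    if (any(same & diff(mk$bp) <= 0)) stop("markers are not sorted by increasing bp")
  }
  mean_het <- config$mean_het
  min_snps <- config$min_snps
  if (is.null(min_snps)) {
    if (is.null(mean_het)) mean_het <- mean_heterozygosity(dataset)
    min_snps <- min_snp_count(n_markers(dataset), n_samples(dataset), config$alpha, mean_het)
  }

  out <- list()
  chroms <- unique(mk$chrom)
  for (chrom in chroms) {
    idx <- which(mk$chrom == chrom)
    pos <- mk$bp[idx]
    # gap rule: a run can never cross an inter-SNP gap above max_gap_bp,
    # so split the chromosome into gap-bounded blocks first
    breaks <- which(diff(pos) > config$max_gap_bp)
    block_start <- c(1L, breaks + 1L)
    block_end <- c(breaks, length(pos))
    for (i in seq_along(dataset$samples)) {
      g <- dataset$calls[i, idx]
      for (b in seq_along(block_start)) {
        rng <- block_start[b]:block_end[b]
        seg <- scan_block(
          g[rng], pos[rng],
          config$max_het_in_run, config$max_missing_in_run,
          min_snps, config$min_length_bp
        )
        if (!is.null(seg)) {
          seg$sample_id <- dataset$samples[i]
          seg$chrom <- chrom
          out[[length(out) + 1L]] <- seg
        }
      }
    }
  }
  res <- if (length(out)) {
    tibble::as_tibble(do.call(rbind, out))[, c(
      "sample_id", "chrom", "start_bp", "end_bp", "length_bp",
      "n_snps", "n_het", "n_missing"
    )]
  } else {
    tibble::tibble(
      sample_id = character(), chrom = character(),
      start_bp = integer(), end_bp = integer(), length_bp = integer(),
      n_snps = integer(), n_het = integer(), n_missing = integer()
    )
  }
  attr(res, "min_snps") <- min_snps
  attr(res, "mean_het") <- mean_het
  res
}

# Maximal qualifying windows within one gap-free block of one individual.
# For each homozygous start i the furthest extension e(i) compatible with the
# het/missing allowances is found in O(1) from cumulative counts (e is
# non-decreasing in i since a later start faces a subset of the constraints);
# the window end is then trimmed to the last homozygous SNP. Among qualifying
# windows sharing a trimmed end, the earliest start is the maximal one.
scan_block <- function(g, pos, max_het, max_miss, min_snps, min_len) {
  m <- length(g)
  if (m == 0) return(NULL)
  is_miss <- is.na(g)
  is_het <- !is_miss & g == 1L
  is_hom <- !is_miss & !is_het
  starts <- which(is_hom)
  if (!length(starts)) return(NULL)

  H <- c(0L, cumsum(is_het))
  M <- c(0L, cumsum(is_miss))
  # e_het(i): max j with H[j+1] - H[i] <= max_het (H is non-decreasing)
  e_het <- pmin(findInterval(H[starts] + max_het, H) - 1L, m)
  e_miss <- pmin(findInterval(M[starts] + max_miss, M) - 1L, m)
  e <- pmin(e_het, e_miss)

  last_hom <- cummax(ifelse(is_hom, seq_len(m), 0L))
  ends <- last_hom[e] # >= starts since start itself is homozygous

  n_snps <- ends - starts + 1L
  len <- pos[ends] - pos[starts]
  qual <- n_snps >= min_snps & len >= min_len
  if (!any(qual)) return(NULL)
  starts <- starts[qual]
  ends <- ends[qual]
  keep <- !duplicated(ends) # starts ascend, so first start per end is maximal
  starts <- starts[keep]
  ends <- ends[keep]

  data.frame(
    start_bp = pos[starts], end_bp = pos[ends],
    length_bp = pos[ends] - pos[starts],
    n_snps = ends - starts + 1L,
    n_het = H[ends + 1L] - H[starts],
    n_missing = M[ends + 1L] - M[starts]
  )
}

#' Physical length of ROH segments
#'
#' The length convention is `end_bp - start_bp` (no +1), i.e. the distance
#' between the first and last SNP of the run.
#'
#' @param segments a segment tibble from [detect_roh()] (or any data frame
#'   with `start_bp` and `end_bp` columns).
#' @return Integer vector of lengths in bp.
#' @export
roh_length <- function(segments) {
  if (any(segments$end_bp <= segments$start_bp)) {
    stop("invalid segment: end_bp must exceed start_bp")
  }
  segments$end_bp - segments$start_bp
}
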