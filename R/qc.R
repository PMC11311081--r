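#' Quality-control configuration
#'
#' The three genotype filters applied before ROH detection: a per-sample
#' call-rate floor, a per-SNP call-rate floor, and an exact Hardy-Weinberg
#' equilibrium test. Defaults are the standard SNP-array settings: 90%
#' call rate on both axes and an HWE rejection threshold of 1e-6.
#'
#' @param min_sample_callrate minimum fraction of non-missing calls per
#'   sample, in (0, 1].
#' @param min_snp_callrate minimum fraction of non-missing calls per marker,
#'   in (0, 1].
#' @param hwe_p_threshold markers with exact HWE p-value strictly below this
#'   are removed; in (0, 1].
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(min_sample_callrate = 0.90,
                      min_snp_callrate = 0.90,
                      hwe_p_threshold = 1e-6) {
  for (v in c(min_sample_callrate, min_snp_callrate, hwe_p_threshold)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      stop("qc_config thresholds must be single numbers in (0, 1]")
    }
  }
  structure(
    list(
      min_sample_callrate = min_sample_callrate,
      min_snp_callrate = min_snp_callrate,
      hwe_p_threshold = hwe_p_threshold
    ),
    class = "qc_config"
  )
}

#' Remove samples with low call rate
#'
#' @param dataset a [genotype_dataset()].
#' @param min_sample_callrate call-rate floor in (0, 1]; samples with a
#'   fraction of non-missing calls strictly below it are removed.
#' @return A list with elements `dataset` (filtered) and `removed`
#'   (character vector of removed sample ids).
#' @export
filter_samples_by_callrate <- function(dataset, min_sample_callrate = 0.90) {
  if (n_samples(dataset) == 0) stop("dataset has no samples")
  callrate <- rowSums(!is.na(dataset$calls)) / n_markers(dataset)
  keep <- callrate >= min_sample_callrate
  if (!any(keep)) stop("sample call-rate filter removed every sample: empty dataset")
  list(dataset = subset_samples(dataset, keep), removed = dataset$samples[!keep])
}

#' Remove markers with low call rate
#'
#' @param dataset a [genotype_dataset()].
#' @param min_snp_callrate call-rate floor in (0, 1]; markers with a fraction
#'   of non-missing calls strictly below it are removed.
#' @return A list with elements `dataset` and `removed` (marker ids).
#' @export
filter_snps_by_callrate <- function(dataset, min_snp_callrate = 0.90) {
  if (n_markers(dataset) == 0) stop("dataset has no markers")
  callrate <- colSums(!is.na(dataset$calls)) / n_samples(dataset)
  keep <- callrate >= min_snp_callrate
  list(dataset = subset_markers(dataset, keep), removed = dataset$markers$id[!keep])
}

#' Exact Hardy-Weinberg equilibrium test for one biallelic marker
#'
#' The two-sided exact test conditional on the observed allele counts: over
#' all heterozygote counts compatible with the allele counts, the conditional
#' probabilities of tables no more probable than the observed one are summed.
#' This is the standard SNP exact test; the asymptotic 1-df chi-square test
#' is its large-sample approximation.
#'
#' The conditional probability of `h` heterozygotes given `n` genotyped
#' individuals and `r` copies of the rarer allele is proportional to
#' `2^h / ((r-h)/2)! h! ((2n-r-h)/2)!`; `h` runs over the values with the
#' parity of `r` from `r mod 2` to `r`. Probabilities are normalized to sum
#' to one, so the returned p-value lies in (0, 1].
#'
#' @param n_AA,n_Ab,n_bb non-negative genotype counts (hom A, het, hom B);
#'   at least one must be positive.
#' @return The exact two-sided p-value.
#' @export
hwe_exact_pvalue <- function(n_AA, n_Ab, n_bb) {
  counts <- c(n_AA, n_Ab, n_bb)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop("all genotype counts are zero")
  n <- sum(counts)
  n_a <- 2 * n_AA + n_Ab
  rare <- min(n_a, 2L * n - n_a)
  hs <- seq.int(rare %% 2, rare, by = 2)
  # log of the unnormalized conditional probability of each het count
  logp <- hs * log(2) -
    lfactorial((rare - hs) / 2) - lfactorial(hs) - lfactorial((2 * n - rare - hs) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  p_obs <- p[match(n_Ab, hs)]
  # ties (tables exactly as probable as the observed) are included; the small
  # relative tolerance guards against floating-point inequality of equal terms
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

#' Remove markers deviating from Hardy-Weinberg equilibrium
#'
#' Genotype counts use only non-missing calls of the currently retained
#' samples. Monomorphic markers have p = 1 and are always retained.
#'
#' @param dataset a [genotype_dataset()].
#' @param hwe_p_threshold markers with exact p strictly below this are removed.
#' @return A list with elements `dataset`, `removed` (marker ids) and
#'   `p_values` (named by marker id; NA for markers with no calls, which are
#'   retained by this filter).
#' @export
filter_snps_by_hwe <- function(dataset, hwe_p_threshold = 1e-6) {
  calls <- dataset$calls
  n_AA <- colSums(calls == 0L, na.rm = TRUE)
  n_Ab <- colSums(calls == 1L, na.rm = TRUE)
  n_bb <- colSums(calls == 2L, na.rm = TRUE)
  tot <- n_AA + n_Ab + n_bb
  p <- rep(NA_real_, n_markers(dataset))
  idx <- which(tot > 0)
  p[idx] <- vapply(
    idx,
    function(j) hwe_exact_pvalue(n_AA[j], n_Ab[j], n_bb[j]),
    numeric(1)
  )
  names(p) <- dataset$markers$id
  drop <- !is.na(p) & p < hwe_p_threshold
  list(
    dataset = subset_markers(dataset, !drop),
    removed = dataset$markers$id[drop],
    p_values = p
  )
}

#' Run the full genotype QC
#'
#' Applies the three filters in a fixed order — sample call rate, then SNP
#' call rate, then the HWE exact test — each on the dataset as left by the
#' previous filter. The order matters: removing a low-call-rate sample can
#' rescue a marker's call rate.
#'
#' @param dataset a [genotype_dataset()].
#' @param config a [qc_config()].
#' @return A list with elements `dataset` (the analysis-ready dataset) and
#'   `report`, a tibble with one row of counts: samples and SNPs removed at
#'   each step and kept overall.
#' @export
run_qc <- function(dataset, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  n_samp0 <- n_samples(dataset)
  n_snp0 <- n_markers(dataset)

  s <- filter_samples_by_callrate(dataset, config$min_sample_callrate)
  g <- filter_snps_by_callrate(s$dataset, config$min_snp_callrate)
  h <- filter_snps_by_hwe(g$dataset, config$hwe_p_threshold)

  report <- tibble::tibble(
    n_samples_in = n_samp0,
    n_snps_in = n_snp0,
    n_samples_removed = length(s$removed),
    n_snps_removed_callrate = length(g$removed),
    n_snps_removed_hwe = length(h$removed),
    n_samples_kept = n_samples(h$dataset),
    n_snps_kept = n_markers(h$dataset)
  )
  stopifnot(
    report$n_samples_kept + report$n_samples_removed == n_samp0,
    report$n_snps_kept + report$n_snps_removed_callrate + report$n_snps_removed_hwe == n_snp0
  )
  list(dataset = h$dataset, report = report)
}
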