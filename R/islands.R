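#' Per-sample, per-marker ROH coverage indicator matrix
#'
#' Entry (i, j) is 1 when sample i has at least one detected segment on the
#' marker's chromosome whose closed interval `[start_bp, end_bp]` contains
#' the marker's position, else 0. Column means of this matrix are the island
#' support profile, and its columns are the regressors of the ROH-phenotype
#' scan.
#'
#' @param segments segment tibble from [detect_roh()].
#' @param dataset the [genotype_dataset()] the segments were detected on.
#' @return Integer 0/1 matrix, samples x markers, with dimnames.
#' @export
roh_state_matrix <- function(segments, dataset) {
  mk <- dataset$markers
  mat <- matrix(
    0L, nrow = length(dataset$samples), ncol = nrow(mk),
    dimnames = list(dataset$samples, mk$id)
  )
  if (nrow(segments) == 0) return(mat)
  missing_chrom <- setdiff(unique(segments$chrom), unique(mk$chrom))
  if (length(missing_chrom)) {
    stop("segments reference chromosome(s) absent from the map: ",
         paste(missing_chrom, collapse = ", "))
  }
  for (ch in unique(segments$chrom)) {
    idx <- which(mk$chrom == ch)
    pos <- mk$bp[idx]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    rows <- match(seg$sample_id, dataset$samples)
    if (anyNA(rows)) stop("segment sample id(s) not in dataset")
    for (k in seq_len(nrow(seg))) {
      j <- which(pos >= seg$start_bp[k] & pos <= seg$end_bp[k])
      if (length(j)) mat[rows[k], idx[j]] <- 1L
    }
  }
  mat
}

#' Population support profile over markers
#'
#' For every retained marker, the fraction of retained individuals whose
#' ROH covers the marker's position. The denominator is all retained
#' individuals, whether or not they carry any ROH.
#'
#' @inheritParams roh_state_matrix
#' @return A tibble: `chrom`, `id`, `bp`, `support` (in \[0, 1\]).
#' @export
support_profile <- function(segments, dataset) {
  state <- roh_state_matrix(segments, dataset)
  tibble::tibble(
    chrom = dataset$markers$chrom,
    id = dataset$markers$id,
    bp = dataset$markers$bp,
    support = if (nrow(state)) unname(colMeans(state)) else rep(0, ncol(state))
  )
}

#' Call ROH islands from a support profile
#'
#' Maximal runs of consecutive same-chromosome markers whose support meets
#' the threshold become islands; island boundaries are the positions of the
#' first and last qualifying marker. No minimum length or SNP-count filter
#' is applied, so a single qualifying marker forms a (zero-length-span)
#' island candidate; such singletons are reported with `n_snps = 1` and
#' `length_bp = 0`.
#'
#' @param profile a [support_profile()] tibble.
#' @param threshold minimum support fraction, in (0, 1]. The default 0.5
#'   calls regions shared by the majority of the population; 0.7 is the
#'   stricter variant.
#' @return A tibble of islands: `chrom`, `start_bp`, `end_bp`,
#'   `length_bp` (= end - start), `n_snps`, `peak_support`, `mean_support`,
#'   sorted by (chrom, start) and mutually disjoint.
#' @export
call_islands <- function(profile, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  out <- list()
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, , drop = FALSE]
    pr <- pr[order(pr$bp), , drop = FALSE]
    q <- pr$support >= threshold
    if (!any(q)) next
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch,
        start_bp = pr$bp[i[1]],
        end_bp = pr$bp[i[length(i)]],
        length_bp = pr$bp[i[length(i)]] - pr$bp[i[1]],
        n_snps = length(i),
        peak_support = max(pr$support[i]),
        mean_support = mean(pr$support[i])
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(
      chrom = character(), start_bp = integer(), end_bp = integer(),
      length_bp = integer(), n_snps = integer(),
      peak_support = numeric(), mean_support = numeric()
    ))
  }
  res <- do.call(rbind, out)
  res[order(chrom_rank(res$chrom), res$start_bp), , drop = FALSE]
}

#' Tabulate called islands with totals
#'
#' One row per island (chromosome, start, end, length = end - start, SNP
#' count) plus a totals summary: the number of islands, the summed SNP count
#' and the summed length.
#'
#' @param islands island tibble from [call_islands()], or any data frame
#'   with columns `chrom`, `start_bp`, `end_bp`, `n_snps`.
#' @return A list with `table` (tibble: `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_snps`) and `totals` (tibble with one row: `n_islands`,
#'   `total_snps`, `total_length_bp`).
#' @export
island_report <- function(islands) {
  tab <- tibble::tibble(
    chrom = as.character(islands$chrom),
    start_bp = islands$start_bp,
    end_bp = islands$end_bp,
    length_bp = islands$end_bp - islands$start_bp,
    n_snps = islands$n_snps
  )
  list(
    table = tab,
    totals = tibble::tibble(
      n_islands = nrow(tab),
      total_snps = sum(tab$n_snps),
      total_length_bp = sum(tab$length_bp)
    )
  )
}

#' Plot a per-chromosome support profile
#'
#' A per-SNP support plot for one chromosome with the island threshold drawn
#' as a horizontal line; requires ggplot2.
#'
#' @param profile a [support_profile()] tibble.
#' @param chrom chromosome label to plot.
#' @param threshold support threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_support_profile <- function(profile, chrom, threshold = 0.5) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_support_profile requires the ggplot2 package")
  }
  pr <- profile[profile$chrom == chrom, , drop = FALSE]
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$bp / 1e6, y = .data$support)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = sprintf("position on chromosome %s (Mb)", chrom),
      y = "fraction of individuals in ROH"
    ) +
    ggplot2::ylim(0, 1)
}
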