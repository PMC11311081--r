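#' Summarize ROH (or island) lengths by Mb class
#'
#' Bins lengths into half-open Mb classes `[b1, b2), [b2, b3), ...` defined
#' by `class_bounds_mb` and reports, per class and for the full input
#' (totals row): count, percent, mean, sample standard deviation (n - 1
#' denominator), minimum and maximum, all in Mb. Lengths falling outside
#' every class still count in the totals row, so the class percentages plus
#' the unclassified remainder sum to 100.
#'
#' @param lengths_bp positive lengths in bp.
#' @param class_bounds_mb strictly increasing class boundaries in Mb;
#'   consecutive pairs define the classes. Default `c(0.5, 1, 2, 4, 8, 16)`.
#' @param total_n denominator for the percent column; defaults to
#'   `length(lengths_bp)`. Supply a larger value when summarizing a subset
#'   of a known larger collection.
#' @return A tibble with one row per class plus a `Total` row: `class_label`,
#'   `lower_mb`, `upper_mb` (NA on the totals row), `n`, `percent`,
#'   `mean_mb`, `sd_mb`, `min_mb`, `max_mb`. Classes with n = 0 and the
#'   SD of single-member classes are reported as NA.
#' @export
summarize_length_classes <- function(lengths_bp,
                                     class_bounds_mb = c(0.5, 1, 2, 4, 8, 16),
                                     total_n = length(lengths_bp)) {
  if (length(lengths_bp) && any(lengths_bp <= 0)) stop("lengths must be positive")
  if (length(class_bounds_mb) < 2 || any(diff(class_bounds_mb) <= 0)) {
    stop("class_bounds_mb must be strictly increasing with at least two values")
  }
  if (total_n < length(lengths_bp)) stop("total_n cannot be below the number of lengths")
  mb <- lengths_bp / 1e6

  stats_row <- function(x) {
    if (length(x) == 0) {
      c(mean = NA_real_, sd = NA_real_, min = NA_real_, max = NA_real_)
    } else {
      c(
        mean = mean(x),
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        min = min(x), max = max(x)
      )
    }
  }

  lower <- class_bounds_mb[-length(class_bounds_mb)]
  upper <- class_bounds_mb[-1]
  rows <- lapply(seq_along(lower), function(k) {
    x <- mb[mb >= lower[k] & mb < upper[k]]
    s <- stats_row(x)
    tibble::tibble(
      class_label = paste0(format(lower[k]), "-", format(upper[k])),
      lower_mb = lower[k], upper_mb = upper[k],
      n = length(x),
      percent = if (total_n > 0) 100 * length(x) / total_n else NA_real_,
      mean_mb = s[["mean"]], sd_mb = s[["sd"]],
      min_mb = s[["min"]], max_mb = s[["max"]]
    )
  })
  s <- stats_row(mb)
  totals <- tibble::tibble(
    class_label = "Total",
    lower_mb = NA_real_, upper_mb = NA_real_,
    n = length(mb),
    percent = if (total_n > 0) 100 * length(mb) / total_n else NA_real_,
    mean_mb = s[["mean"]], sd_mb = s[["sd"]],
    min_mb = s[["min"]], max_mb = s[["max"]]
  )
  do.call(rbind, c(rows, list(totals)))
}

#' Per-chromosome ROH counts and mean coverage
#'
#' For each chromosome of the map: the total number of detected segments
#' (across individuals) and the percentage of the chromosome covered by ROH,
#' computed per individual as union-of-segments bp divided by the chromosome
#' extent and then averaged over *all* retained individuals (individuals
#' without ROH contribute zeros).
#'
#' @param segments segment tibble from [detect_roh()].
#' @param dataset the [genotype_dataset()] the segments were detected on
#'   (supplies both the marker map and the retained-sample list).
#' @param extents optional named numeric vector (chromosome -> extent in bp)
#'   overriding the default extent, the position of the last mapped SNP.
#' @return A tibble: `chrom`, `extent_bp`, `n_roh`, `pct_covered`.
#' @export
chromosome_coverage <- function(segments, dataset, extents = NULL) {
  mk <- dataset$markers
  chroms <- unique(mk$chrom)
  missing_chrom <- setdiff(unique(segments$chrom), chroms)
  if (length(missing_chrom)) {
    stop("segments reference chromosome(s) absent from the map: ",
         paste(missing_chrom, collapse = ", "))
  }
  default_ext <- vapply(chroms, function(ch) max(mk$bp[mk$chrom == ch]), numeric(1))
  names(default_ext) <- chroms
  if (!is.null(extents)) default_ext[names(extents)] <- extents

  n_ind <- length(dataset$samples)
  rows <- lapply(chroms, function(ch) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    per_ind <- numeric(n_ind)
    if (nrow(seg)) {
      by_sample <- split(seg, seg$sample_id)
      for (sid in names(by_sample)) {
        i <- match(sid, dataset$samples)
        if (is.na(i)) stop("segment sample ", sid, " not in dataset")
        per_ind[i] <- union_length(by_sample[[sid]]$start_bp, by_sample[[sid]]$end_bp)
      }
    }
    tibble::tibble(
      chrom = ch,
      extent_bp = default_ext[[ch]],
      n_roh = nrow(seg),
      pct_covered = 100 * mean(per_ind / default_ext[[ch]])
    )
  })
  do.call(rbind, rows)
}

# Total bp covered by the union of [start, end] intervals, with the
# end - start length convention.
union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]
  end <- end[o]
  total <- 0
  cur_s <- start[1]
  cur_e <- end[1]
  for (k in seq_along(start)[-1]) {
    if (start[k] <= cur_e) {
      cur_e <- max(cur_e, end[k])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[k]
      cur_e <- end[k]
    }
  }
  total + (cur_e - cur_s)
}
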