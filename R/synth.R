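#' Synthetic-population configuration
#'
#' Describes a diploid SNP-array cohort with Hardy-Weinberg background
#' genotypes, optional planted autozygous segments at controlled carrier
#' fractions, genotyping error, missingness, and an optional additive
#' phenotype. The defaults emulate a 189-animal beef-cattle cohort on a
#' scaled-down high-density panel: three 50 Mb chromosomes of 2,000 markers
#' each (one marker per 25 kb, the density of a ~150K array on a ~2.7 Gb
#' genome), allele frequencies uniform on \[0.05, 0.5\], 0.5% missing calls
#' and a 0.2% heterozygous-error rate.
#'
#' @param n_individuals cohort size; default 189.
#' @param chromosomes list of `list(label =, n_markers =, extent_bp =)`
#'   entries.
#' @param maf_range minor-allele-frequency range, drawn uniformly per marker.
#' @param missing_rate probability a call is set missing.
#' @param het_error_rate probability a call is rendered heterozygous
#'   (applied everywhere, after segment planting).
#' @param planted_segments data frame (or NULL) with columns `chrom`,
#'   `start_bp`, `end_bp`, `carrier_fraction`; each segment makes a random
#'   `ceiling(carrier_fraction * n)`-subset of individuals homozygous for
#'   the per-marker major allele across all covered markers. Planted
#'   segments on one chromosome must not overlap.
#' @param phenotype NULL or `list(mu =, sigma =, effects =)` where `effects`
#'   is a data frame with columns `segment` (row index into
#'   `planted_segments`) and `beta`; phenotype = mu + sum(beta * carrier) +
#'   Normal(0, sigma^2).
#' @param seed integer seed governing every stochastic draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 189L,
                       chromosomes = list(
                         list(label = "1", n_markers = 2000L, extent_bp = 50000000L),
                         list(label = "2", n_markers = 2000L, extent_bp = 50000000L),
                         list(label = "3", n_markers = 2000L, extent_bp = 50000000L)
                       ),
                       maf_range = c(0.05, 0.5),
                       missing_rate = 0.005,
                       het_error_rate = 0.002,
                       planted_segments = NULL,
                       phenotype = NULL,
                       seed = 1L) {
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  for (ch in chromosomes) {
    stopifnot(all(c("label", "n_markers", "extent_bp") %in% names(ch)))
    if (ch$extent_bp < ch$n_markers) stop("chromosome extent smaller than marker count")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] and non-decreasing")
  }
  for (v in c(missing_rate, het_error_rate)) {
    if (v < 0 || v > 1) stop("rates must be in [0, 1]")
  }
  labels <- vapply(chromosomes, `[[`, character(1), "label")
  if (!is.null(planted_segments)) {
    planted_segments <- tibble::as_tibble(planted_segments)
    stopifnot(all(c("chrom", "start_bp", "end_bp", "carrier_fraction") %in%
                    names(planted_segments)))
    planted_segments$chrom <- as.character(planted_segments$chrom)
    if (any(planted_segments$carrier_fraction <= 0 |
              planted_segments$carrier_fraction > 1)) {
      stop("carrier_fraction must be in (0, 1]")
    }
    for (k in seq_len(nrow(planted_segments))) {
      ps <- planted_segments[k, ]
      ci <- match(ps$chrom, labels)
      if (is.na(ci)) stop("planted segment on unknown chromosome ", ps$chrom)
      if (ps$start_bp < 1 || ps$end_bp > chromosomes[[ci]]$extent_bp ||
          ps$end_bp <= ps$start_bp) {
        stop("planted segment interval outside chromosome extent")
      }
    }
    for (ch in unique(planted_segments$chrom)) {
      seg <- planted_segments[planted_segments$chrom == ch, , drop = FALSE]
      seg <- seg[order(seg$start_bp), , drop = FALSE]
      if (nrow(seg) > 1 && any(seg$start_bp[-1] <= seg$end_bp[-nrow(seg)])) {
        stop("planted segments overlap on chromosome ", ch)
      }
    }
  }
  if (!is.null(phenotype)) {
    stopifnot(all(c("mu", "sigma") %in% names(phenotype)), phenotype$sigma > 0)
    if (!is.null(phenotype$effects)) {
      eff <- tibble::as_tibble(phenotype$effects)
      stopifnot(all(c("segment", "beta") %in% names(eff)))
      if (is.null(planted_segments) || any(eff$segment > nrow(planted_segments)) ||
          any(eff$segment < 1)) {
        stop("phenotype effects reference planted segments that do not exist")
      }
      phenotype$effects <- eff
    }
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals), chromosomes = chromosomes,
      maf_range = maf_range, missing_rate = missing_rate,
      het_error_rate = het_error_rate, planted_segments = planted_segments,
      phenotype = phenotype, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a genotyped population
#'
#' Marker positions are distinct uniform draws over each chromosome extent,
#' sorted. Per marker a minor-allele frequency is drawn from `maf_range` and
#' background genotypes are sampled from Hardy-Weinberg proportions,
#' independently across markers (no linkage disequilibrium). Each planted
#' segment then overwrites the calls of its carrier subset with the
#' per-marker major-allele homozygote across every covered marker, after
#' which the heterozygous-error and missingness processes are applied to all
#' calls. The returned dataset is in canonical allele orientation, so a
#' PED/MAP round trip reproduces it exactly. The same seed always yields
#' identical output.
#'
#' @param config a [sim_config()].
#' @return A list: `dataset` (a [genotype_dataset()]), `truth` (a list with
#'   `segments`, the planted-segment tibble, and `carriers`, a list of
#'   carrier-id character vectors parallel to its rows), `phenotype`
#'   (tibble `sample_id`, `value`, or NULL), and `maf` (the simulated
#'   per-marker minor-allele frequency, named by marker id).
#' @export
simulate_population <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  samples <- sprintf("ind_%04d", seq_len(n))

  marker_list <- list()
  for (ch in config$chromosomes) {
    pos <- sort(sample.int(ch$extent_bp, ch$n_markers))
    marker_list[[length(marker_list) + 1L]] <- tibble::tibble(
      chrom = ch$label,
      id = sprintf("snp_%s_%05d", ch$label, seq_len(ch$n_markers)),
      cM = 0, bp = pos
    )
  }
  markers <- do.call(rbind, marker_list)
  m <- nrow(markers)

  q <- stats::runif(m, config$maf_range[1], config$maf_range[2]) # freq of allele b
  calls <- matrix(
    stats::rbinom(n * m, 2L, rep(q, each = n)),
    nrow = n, ncol = m
  )

  truth_seg <- config$planted_segments
  carriers <- list()
  if (!is.null(truth_seg) && nrow(truth_seg)) {
    for (k in seq_len(nrow(truth_seg))) {
      ps <- truth_seg[k, ]
      idx <- which(markers$chrom == ps$chrom &
                     markers$bp >= ps$start_bp & markers$bp <= ps$end_bp)
      who <- sort(sample.int(n, ceiling(ps$carrier_fraction * n)))
      carriers[[k]] <- samples[who]
      if (length(idx)) {
        maj <- ifelse(q[idx] < 0.5, 0L, 2L) # per-marker major-allele homozygote
        calls[who, idx] <- rep(maj, each = length(who))
      }
    }
  } else {
    truth_seg <- tibble::tibble(
      chrom = character(), start_bp = integer(), end_bp = integer(),
      carrier_fraction = numeric()
    )
  }

  if (config$het_error_rate > 0) {
    flip <- which(stats::runif(n * m) < config$het_error_rate)
    calls[flip] <- 1L
  }
  if (config$missing_rate > 0) {
    calls[stats::runif(n * m) < config$missing_rate] <- NA_integer_
  }

  dataset <- canonicalize_alleles(genotype_dataset(samples, markers, calls))

  pheno <- NULL
  if (!is.null(config$phenotype)) {
    pm <- config$phenotype
    value <- rep(pm$mu, n) + stats::rnorm(n, 0, pm$sigma)
    if (!is.null(pm$effects)) {
      for (r in seq_len(nrow(pm$effects))) {
        k <- pm$effects$segment[r]
        value <- value + pm$effects$beta[r] * (samples %in% carriers[[k]])
      }
    }
    pheno <- tibble::tibble(sample_id = samples, value = value)
  }

  names(q) <- markers$id
  list(
    dataset = dataset,
    truth = list(segments = truth_seg, carriers = carriers),
    phenotype = pheno,
    maf = q[dataset$markers$id]
  )
}

#' Serialize simulation truth
#'
#' Writes the planted segments as BED-style intervals (0-based half-open)
#' with the carrier fraction and comma-joined carrier ids as extra columns.
#' [read_truth()] inverts the format exactly.
#'
#' @param truth the `truth` element returned by [simulate_population()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  seg <- truth$segments
  lines <- character(nrow(seg))
  for (k in seq_len(nrow(seg))) {
    lines[k] <- paste(
      seg$chrom[k], seg$start_bp[k] - 1L, seg$end_bp[k],
      format(seg$carrier_fraction[k]),
      paste(truth$carriers[[k]], collapse = ","),
      sep = "\t"
    )
  }
  tryCatch(
    writeLines(lines, path),
    error = function(e) stop("cannot write truth file ", path, ": ", conditionMessage(e))
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(list(
      segments = tibble::tibble(
        chrom = character(), start_bp = integer(), end_bp = integer(),
        carrier_fraction = numeric()
      ),
      carriers = list()
    ))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 5)) stop("malformed truth file: expected 5 tab-separated columns")
  mat <- do.call(rbind, f)
  list(
    segments = tibble::tibble(
      chrom = mat[, 1],
      start_bp = as.integer(mat[, 2]) + 1L,
      end_bp = as.integer(mat[, 3]),
      carrier_fraction = as.numeric(mat[, 4])
    ),
    carriers = lapply(mat[, 5], function(s) if (nzchar(s)) strsplit(s, ",")[[1]] else character(0))
  )
}
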