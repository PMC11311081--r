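#' Association-scan configuration
#'
#' @param bonferroni_p family-wise significance threshold applied to each
#'   per-marker p-value; default `1.5e-6`. Override with `0.05 / n_tests`
#'   for an exact Bonferroni rule on a given panel.
#' @param min_per_state markers with fewer than this many phenotyped samples
#'   in either regressor state are skipped (degenerate-fit guard).
#' @return A list of class `assoc_config`.
#' @export
assoc_config <- function(bonferroni_p = 1.5e-6, min_per_state = 5L) {
  if (bonferroni_p <= 0 || bonferroni_p >= 1) stop("bonferroni_p must be in (0, 1)")
  if (min_per_state < 1) stop("min_per_state must be >= 1")
  structure(
    list(bonferroni_p = bonferroni_p, min_per_state = as.integer(min_per_state)),
    class = "assoc_config"
  )
}

#' Per-locus linear association of a phenotype with ROH state
#'
#' Ordinary least squares of the phenotype on the per-marker regressor
#' (by default the 0/1 ROH-coverage indicator from [roh_state_matrix()]):
#' `phenotype = b0 + b1 * state`, with a two-sided t-test on `b1` at
#' `n_used - 2` degrees of freedom. For a binary regressor `b1` equals the
#' difference of phenotype group means. Markers where either state has fewer
#' than `min_per_state` phenotyped samples are skipped; fits with zero
#' residual variance are flagged (`p_value = NA`, `note = "degenerate"`)
#' rather than reported as infinitely significant.
#'
#' @param state_matrix samples x markers numeric matrix of regressors, with
#'   sample rownames (0/1 ROH indicators, or genotype dosages for the
#'   genotype-regressor variant).
#' @param phenotype either a named numeric vector (names = sample ids) or a
#'   data frame with columns `sample_id` and `value`. Samples with missing
#'   phenotype are dropped from every fit.
#' @param config an [assoc_config()].
#' @param markers optional marker map tibble (columns `chrom`, `id`, `bp`)
#'   used to attach coordinates; defaults to the state-matrix column names
#'   only.
#' @return A tibble with one row per tested marker: `marker_id`, `chrom`,
#'   `bp`, `n_used`, `n_state1`, `beta`, `se`, `t_stat`, `p_value`,
#'   `significant`, `note`. Skipped markers are returned in the
#'   `"skipped"` attribute with their reason.
#' @export
assoc_scan <- function(state_matrix, phenotype, config = assoc_config(),
                       markers = NULL) {
  stopifnot(inherits(config, "assoc_config"))
  if (is.data.frame(phenotype)) {
    y_all <- stats::setNames(phenotype$value, phenotype$sample_id)
  } else {
    y_all <- phenotype
  }
  if (is.null(names(y_all)) || is.null(rownames(state_matrix))) {
    stop("phenotype and state_matrix must carry sample ids")
  }
  y <- y_all[rownames(state_matrix)]
  obs <- !is.na(y)
  if (sum(obs) < 3) stop("need phenotype values for at least 3 samples")
  y <- as.numeric(y[obs])
  X <- state_matrix[obs, , drop = FALSE]
  n <- length(y)

  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("m", seq_len(ncol(X)))
  meta <- if (!is.null(markers)) {
    i <- match(ids, markers$id)
    list(chrom = markers$chrom[i], bp = markers$bp[i])
  } else {
    list(chrom = rep(NA_character_, ncol(X)), bp = rep(NA_integer_, ncol(X)))
  }

  skipped_reason <- rep(NA_character_, ncol(X))
  if (stats::sd(y) == 0) {
    warning("phenotype is constant among phenotyped samples; all markers skipped")
    skipped_reason[] <- "constant phenotype"
  } else {
    binary <- all(X %in% c(0, 1))
    if (binary) {
      n1 <- colSums(X)
      low <- pmin(n1, n - n1) < config$min_per_state
      skipped_reason[low] <- sprintf(
        "fewer than %d samples in one ROH state", config$min_per_state
      )
    } else {
      novar <- apply(X, 2, function(x) stats::var(x) == 0)
      skipped_reason[novar] <- "regressor has no variance"
    }
  }
  test <- is.na(skipped_reason)

  empty <- tibble::tibble(
    marker_id = character(), chrom = character(), bp = integer(),
    n_used = integer(), n_state1 = integer(),
    beta = numeric(), se = numeric(), t_stat = numeric(),
    p_value = numeric(), significant = logical(), note = character()
  )
  skipped <- tibble::tibble(
    marker_id = ids[!test],
    reason = skipped_reason[!test]
  )
  if (!any(test)) {
    attr(empty, "skipped") <- skipped
    return(empty)
  }

  Xt <- X[, test, drop = FALSE]
  xbar <- unname(colMeans(Xt))
  sxx <- unname(colSums(Xt^2)) - n * xbar^2
  sxy <- as.numeric(crossprod(Xt, y)) - n * xbar * mean(y)
  syy <- sum(y^2) - n * mean(y)^2
  beta <- sxy / sxx
  sse <- pmax(0, syy - beta * sxy) # clamp tiny negative rounding error
  s2 <- sse / (n - 2)
  se <- sqrt(s2 / sxx)
  t_stat <- ifelse(se > 0, beta / se, NA_real_)
  p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  note <- ifelse(se > 0, NA_character_, "degenerate")

  res <- tibble::tibble(
    marker_id = ids[test],
    chrom = meta$chrom[test],
    bp = meta$bp[test],
    n_used = n,
    n_state1 = as.integer(round(colSums(Xt != 0))),
    beta = beta,
    se = se,
    t_stat = t_stat,
    p_value = p,
    significant = !is.na(p) & p < config$bonferroni_p,
    note = note
  )
  attr(res, "skipped") <- skipped
  res
}
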