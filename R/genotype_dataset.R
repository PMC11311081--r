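#' Construct a genotype dataset
#'
#' The container consumed by every pipeline stage: an ordered sample list, an
#' ordered marker map, and a samples-by-markers matrix of genotype codes.
#' Codes are `0` (homozygous for the A allele), `1` (heterozygous), `2`
#' (homozygous for the B allele) and `NA` (missing call). Which physical
#' allele is "A" at a marker is arbitrary and fixed at load time; all
#' downstream ROH logic depends only on the hom/het/missing distinction.
#'
#' Markers are sorted by chromosome and strictly increasing physical position
#' (1-based bp); the genotype columns are permuted accordingly. Duplicate
#' positions on one chromosome are rejected. Chromosome order is
#' natural-numeric when every label is an integer string, lexicographic
#' otherwise.
#'
#' @param samples character vector of unique sample ids.
#' @param markers data frame with columns `chrom` (character), `id`
#'   (character, unique), `cM` (numeric genetic position, may be 0) and `bp`
#'   (integer physical position, >= 1).
#' @param calls integer matrix, `length(samples)` rows by `nrow(markers)`
#'   columns, values in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_dataset`: a list with elements
#'   `samples`, `markers` (tibble) and `calls` (integer matrix with sample
#'   rownames and marker-id colnames).
#' @export
genotype_dataset <- function(samples, markers, calls) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids: ", paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  markers <- tibble::as_tibble(markers)
  required <- c("chrom", "id", "cM", "bp")
  if (!all(required %in% names(markers))) {
    stop("markers must have columns: ", paste(required, collapse = ", "))
  }
  markers$chrom <- as.character(markers$chrom)
  markers$id <- as.character(markers$id)
  markers$cM <- as.numeric(markers$cM)
  markers$bp <- as.integer(markers$bp)
  if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  if (nrow(markers) > 0 && any(markers$bp < 1L)) stop("marker bp positions must be >= 1")

  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(samples) || ncol(calls) != nrow(markers)) {
    stop(sprintf(
      "calls matrix is %d x %d but expected %d samples x %d markers",
      nrow(calls), ncol(calls), length(samples), nrow(markers)
    ))
  }
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2)) stop("genotype codes must be 0, 1, 2 or NA")

  ord <- order(chrom_rank(markers$chrom), markers$bp)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  dup <- duplicated(markers[, c("chrom", "bp")])
  if (any(dup)) {
    stop(
      "duplicate physical position on chromosome ",
      markers$chrom[dup][1], " at bp ", markers$bp[dup][1]
    )
  }
  rownames(calls) <- samples
  colnames(calls) <- markers$id

  structure(
    list(samples = samples, markers = markers, calls = calls),
    class = "genotype_dataset"
  )
}

# Natural-numeric chromosome rank when all labels are integers, else alphabetical.
chrom_rank <- function(chrom) {
  u <- unique(chrom)
  if (length(u) && all(grepl("^[0-9]+$", u))) {
    match(chrom, u[order(as.integer(u))])
  } else {
    match(chrom, sort(u))
  }
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "<genotype_dataset> %d samples x %d markers on %d chromosome(s)\n",
    length(x$samples), nrow(x$markers), length(unique(x$markers$chrom))
  ))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call fraction: %.4f\n", if (is.nan(miss)) 0 else miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) c(length(x$samples), nrow(x$markers))

n_samples <- function(dataset) length(dataset$samples)
n_markers <- function(dataset) nrow(dataset$markers)

#' Flip markers into the canonical allele orientation
#'
#' The A/B orientation of a marker is arbitrary. The canonical orientation —
#' the one a PED file written by [write_ped_map()] re-reads to an identical
#' code matrix — is the one in which the first non-missing call at each
#' marker is code 0 or 1 (so the first allele encountered in the file is the
#' A allele). Markers whose first non-missing call is code 2 are flipped
#' (0 and 2 swapped); heterozygous and missing calls are unchanged, so all
#' ROH-related structure is preserved.
#'
#' @param dataset a [genotype_dataset()].
#' @return The dataset with every marker in canonical orientation.
#' @export
canonicalize_alleles <- function(dataset) {
  calls <- dataset$calls
  if (nrow(calls) == 0 || ncol(calls) == 0) return(dataset)
  first_code <- apply(calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g)) g[1] else NA_integer_
  })
  flip <- which(!is.na(first_code) & first_code == 2L)
  for (j in flip) calls[, j] <- 2L - calls[, j]
  dataset$calls <- calls
  dataset
}

# Subset helpers used by the QC filters; preserve order.
subset_samples <- function(dataset, keep) {
  genotype_dataset(
    dataset$samples[keep],
    dataset$markers,
    dataset$calls[keep, , drop = FALSE]
  )
}

subset_markers <- function(dataset, keep) {
  genotype_dataset(
    dataset$samples,
    dataset$markers[keep, , drop = FALSE],
    dataset$calls[, keep, drop = FALSE]
  )
}

#' Mean per-SNP heterozygosity
#'
#' The average, over markers, of the fraction of heterozygous calls among
#' non-missing calls — the quantity that calibrates the minimum SNP count of
#' a run (see [min_snp_count()]). Markers with no non-missing calls are
#' excluded.
#'
#' @param dataset a [genotype_dataset()].
#' @return A single value in \[0, 1\].
#' @export
mean_heterozygosity <- function(dataset) {
  calls <- dataset$calls
  if (ncol(calls) == 0) stop("dataset has no markers")
  het <- colSums(calls == 1L, na.rm = TRUE)
  nn <- colSums(!is.na(calls))
  ok <- nn > 0
  if (!any(ok)) stop("all markers are entirely missing")
  mean(het[ok] / nn[ok])
}
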