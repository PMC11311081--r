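# Build a genotype_dataset from a call matrix and positions on one or more
# chromosomes; defaults give one chromosome with 25 kb marker spacing.
make_dataset <- function(calls, bp = NULL, chrom = "1",
                         samples = sprintf("s%02d", seq_len(nrow(calls)))) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(bp)) bp <- seq_len(m) * 25000L
  chrom <- rep_len(chrom, m)
  genotype_dataset(
    samples,
    tibble::tibble(
      chrom = chrom,
      id = sprintf("m%04d", seq_len(m)),
      cM = 0, bp = as.integer(bp)
    ),
    calls
  )
}

# One-individual dataset wrapper around detect_roh for oracle comparisons.
detect_one <- function(g, pos, ...) {
  ds <- make_dataset(matrix(g, nrow = 1), bp = pos, samples = "s1")
  detect_roh(ds, roh_config(...))
}

# The printed worked-example island table used by the descriptive-statistics
# golden tests (chromosome, start, end, SNP count of nine cattle ROH islands).
island_table_fixture <- function() {
  tibble::tibble(
    chrom = c("7", "8", "8", "11", "13", "14", "14", "20", "28"),
    start_bp = c(52757805L, 55718826L, 93132174L, 52843813L, 64228423L,
                 24326513L, 36817690L, 30865802L, 2116842L),
    end_bp = c(53310739L, 56283438L, 93792855L, 53351806L, 66040326L,
               25098364L, 37791273L, 31752546L, 2869287L),
    n_snps = c(16L, 23L, 20L, 18L, 47L, 57L, 23L, 29L, 22L)
  )
}
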