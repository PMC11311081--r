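#' Load a gene track from a BED file
#'
#' Reads a BED3+ file via rtracklayer and returns a gene-interval table in
#' 1-based closed coordinates (BED's 0-based half-open convention is
#' converted on import). Features without a name field get generated names.
#' The track is sorted by (chromosome, start).
#'
#' @param bed_path path to a BED file.
#' @return A tibble: `chrom`, `start_bp`, `end_bp`, `name`.
#' @export
load_gene_track <- function(bed_path) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  content <- which(nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines))
  for (k in content) {
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (length(f) < 3 || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      stop(sprintf("malformed BED line %d: %s", k, lines[k]))
    }
  }
  if (!length(content)) {
    return(tibble::tibble(
      chrom = character(), start_bp = integer(),
      end_bp = integer(), name = character()
    ))
  }
  gr <- rtracklayer::import(bed_path, format = "BED")
  name <- if (!is.null(gr$name)) as.character(gr$name) else rep(NA_character_, length(gr))
  name[is.na(name) | !nzchar(name)] <-
    paste0("feature_", seq_len(length(gr)))[is.na(name) | !nzchar(name)]
  track <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr),
    end_bp = GenomicRanges::end(gr),
    name = name
  )
  track[order(chrom_rank(track$chrom), track$start_bp), , drop = FALSE]
}

#' Genes intersecting ROH islands
#'
#' Intersects islands with a gene track. In `overlap` mode (the default) a
#' gene is listed for an island when the two closed intervals share at least
#' one bp; in `contained` mode the gene must lie fully inside the island.
#' `flank_bp` symmetrically pads the islands before intersection, capturing
#' genes in close proximity; the default is no padding.
#'
#' @param islands island tibble from [call_islands()] (columns `chrom`,
#'   `start_bp`, `end_bp`).
#' @param track gene track from [load_gene_track()].
#' @param mode `"overlap"` or `"contained"`.
#' @param flank_bp non-negative padding added to each island side.
#' @return The islands tibble with two added columns: `n_genes` and `genes`
#'   (list column of gene-name character vectors, sorted).
#' @export
genes_in_islands <- function(islands, track, mode = c("overlap", "contained"),
                             flank_bp = 0) {
  mode <- match.arg(mode)
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  islands <- tibble::as_tibble(islands)
  if (nrow(islands) == 0 || nrow(track) == 0) {
    islands$n_genes <- integer(nrow(islands))
    islands$genes <- rep(list(character(0)), nrow(islands))
    return(islands)
  }
  isl_gr <- GenomicRanges::GRanges(
    seqnames = islands$chrom,
    ranges = IRanges::IRanges(
      start = pmax(1L, islands$start_bp - as.integer(flank_bp)),
      end = islands$end_bp + as.integer(flank_bp)
    )
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = track$chrom,
    ranges = IRanges::IRanges(start = track$start_bp, end = track$end_bp)
  )
  hits <- GenomicRanges::findOverlaps(
    gene_gr, isl_gr,
    type = if (mode == "contained") "within" else "any"
  )
  genes <- lapply(seq_len(nrow(islands)), function(k) {
    sort(unique(track$name[S4Vectors::queryHits(hits)[S4Vectors::subjectHits(hits) == k]]))
  })
  islands$n_genes <- lengths(genes)
  islands$genes <- genes
  islands
}
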