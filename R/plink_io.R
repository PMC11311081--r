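#' Read PLINK text PED/MAP files
#'
#' Parses the whitespace-delimited PLINK text dialect: MAP with four columns
#' (chromosome, marker id, genetic position in cM, physical position in bp)
#' and PED with six mandatory leading fields (family, individual, father,
#' mother, sex, phenotype) followed by two allele fields per marker.
#'
#' Allele pairs are recoded per marker by observed allele order: the first
#' non-missing allele encountered (scanning samples in file order, first
#' allele of a pair before the second) becomes the A allele (code 0 when
#' homozygous); the other observed allele becomes B (code 2). `0 0` is the
#' missing call. More than two distinct non-missing alleles at a marker is an
#' error. After recoding, markers are sorted by (chromosome, bp) and the
#' genotype columns permuted to match; duplicate bp on one chromosome is an
#' error.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @return A [genotype_dataset()]. Sample ids are the PED individual ids
#'   (column 2).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_fields) != 4L)
  if (length(bad)) {
    stop(sprintf("MAP line %d has %d fields, expected 4", bad[1], lengths(map_fields)[bad[1]]))
  }
  mf <- do.call(rbind, map_fields)
  markers <- tibble::tibble(
    chrom = mf[, 1], id = mf[, 2],
    cM = as.numeric(mf[, 3]), bp = as.integer(mf[, 4])
  )
  m <- nrow(markers)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  samples <- character(n)
  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  # per-marker first-seen (A) and second-seen (B) allele labels
  a1 <- rep(NA_character_, m)
  a2 <- rep(NA_character_, m)

  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m) {
      stop(sprintf(
        "PED line %d has %d fields, expected %d (6 + 2 x %d markers)",
        i, length(f), 6L + 2L * m, m
      ))
    }
    samples[i] <- f[2]
    al1 <- f[seq(7L, by = 2L, length.out = m)]
    al2 <- f[seq(8L, by = 2L, length.out = m)]
    miss <- al1 == "0" | al2 == "0"
    for (j in which(!miss)) {
      for (al in c(al1[j], al2[j])) {
        if (is.na(a1[j])) {
          a1[j] <- al
        } else if (al != a1[j] && is.na(a2[j])) {
          a2[j] <- al
        } else if (al != a1[j] && al != a2[j]) {
          stop(sprintf(
            "marker %s has more than 2 distinct alleles (%s, %s, %s)",
            markers$id[j], a1[j], a2[j], al
          ))
        }
      }
      calls[i, j] <- (al1[j] != a1[j]) + (al2[j] != a1[j])
    }
  }

  genotype_dataset(samples, markers, calls)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' The inverse of [read_ped_map()]: code 0 is written as `A A`, 1 as `A B`,
#' 2 as `B B` and missing as `0 0`. Family id equals the sample id, parents
#' are `0`, sex and phenotype are `0` and `-9`. For a dataset in canonical
#' allele orientation (see [canonicalize_alleles()]) re-reading the written
#' files reproduces the code matrix, sample order and marker map exactly.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  mk <- dataset$markers
  map_lines <- sprintf("%s\t%s\t%s\t%d", mk$chrom, mk$id, format(mk$cM, trim = TRUE, scientific = FALSE), mk$bp)
  ok <- tryCatch(
    {
      writeLines(map_lines, map_path)
      TRUE
    },
    error = function(e) stop("cannot write MAP file ", map_path, ": ", conditionMessage(e))
  )

  geno_str <- c(`0` = "A A", `1` = "A B", `2` = "B B")
  con <- tryCatch(
    file(ped_path, open = "wt"),
    error = function(e) stop("cannot write PED file ", ped_path, ": ", conditionMessage(e))
  )
  on.exit(close(con))
  for (i in seq_along(dataset$samples)) {
    g <- dataset$calls[i, ]
    fields <- ifelse(is.na(g), "0 0", geno_str[as.character(g)])
    line <- paste(
      c(dataset$samples[i], dataset$samples[i], "0", "0", "0", "-9", fields),
      collapse = " "
    )
    writeLines(line, con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

# Write a TSV with a single '#'-prefixed provenance header line followed by a
# column header; used for every pipeline output table.
write_table_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(
    as.data.frame(df), con,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
}

read_table_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, comment.char = "#", sep = "\t", stringsAsFactors = FALSE))
}
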