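#' Pipeline configuration
#'
#' Aggregates the stage configurations and I/O paths for [run_pipeline()].
#' All thresholds default to the standard analysis settings: 0.90 call rate
#' on both axes, HWE p < 1e-6, alpha = 0.05, 500 kb minimum run length, one
#' heterozygote and one missing call allowed per run, island support
#' thresholds 0.5 and 0.7, Bonferroni p < 1.5e-6.
#'
#' @param ped,map input PLINK text genotype paths.
#' @param out_dir output directory (created if absent).
#' @param qc a [qc_config()].
#' @param roh a [roh_config()].
#' @param island_thresholds island support thresholds, each in (0, 1].
#' @param class_bounds_mb ROH length-class boundaries in Mb.
#' @param genes_bed optional BED gene track; enables the annotation stage.
#' @param annotation_mode `"overlap"` or `"contained"`.
#' @param flank_bp island padding for annotation.
#' @param phenotype optional TSV path with columns `sample_id` and `value`;
#'   enables the association stage.
#' @param assoc an [assoc_config()].
#' @param seed integer recorded in output headers (the pipeline itself is
#'   deterministic given its inputs).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ped, map, out_dir,
                            qc = qc_config(), roh = roh_config(),
                            island_thresholds = c(0.5, 0.7),
                            class_bounds_mb = c(0.5, 1, 2, 4, 8, 16),
                            genes_bed = NULL,
                            annotation_mode = "overlap", flank_bp = 0,
                            phenotype = NULL, assoc = assoc_config(),
                            seed = 1L) {
  stopifnot(inherits(qc, "qc_config"), inherits(roh, "roh_config"),
            inherits(assoc, "assoc_config"))
  if (any(island_thresholds <= 0 | island_thresholds > 1)) {
    stop("island thresholds must be in (0, 1]")
  }
  structure(
    list(
      ped = ped, map = map, out_dir = out_dir, qc = qc, roh = roh,
      island_thresholds = island_thresholds, class_bounds_mb = class_bounds_mb,
      genes_bed = genes_bed, annotation_mode = annotation_mode,
      flank_bp = flank_bp, phenotype = phenotype, assoc = assoc,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `qc`,
#' `roh` and `assoc` keys are mappings passed to the respective config
#' constructors. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c(
    "ped", "map", "out_dir", "qc", "roh", "island_thresholds",
    "class_bounds_mb", "genes_bed", "annotation_mode", "flank_bp",
    "phenotype", "assoc", "seed"
  )
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- y
  if (!is.null(y$qc)) args$qc <- do.call(qc_config, y$qc)
  if (!is.null(y$roh)) args$roh <- do.call(roh_config, y$roh)
  if (!is.null(y$assoc)) args$assoc <- do.call(assoc_config, y$assoc)
  if (!is.null(y$island_thresholds)) args$island_thresholds <- unlist(y$island_thresholds)
  if (!is.null(y$class_bounds_mb)) args$class_bounds_mb <- unlist(y$class_bounds_mb)
  do.call(pipeline_config, args)
}

#' Run the end-to-end ROH-island pipeline
#'
#' Executes qc -> detect -> summarize -> islands (-> annotate, with a gene
#' track) (-> assoc, with a phenotype table) and writes one TSV per stage
#' into `out_dir`. Every table carries a header comment with the package
#' version, a configuration hash and the seed, so reruns are verifiably
#' identical. Stage errors abort with a message naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`qc`,
#'   `segments`, `length_classes`, `coverage`, `profile`, `islands` — a list
#'   keyed by threshold —, `annotated`, `assoc`) and `files`, the written
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  # hash covers the analysis parameters only, so runs of the same settings on
  # the same inputs are verifiably identical regardless of where they write
  params <- unclass(config)
  params[c("ped", "map", "out_dir", "genes_bed", "phenotype")] <- NULL
  stamp <- sprintf(
    "rohscan %s config_hash=%s seed=%d",
    as.character(utils::packageVersion("rohscan")),
    rlang::hash(params), config$seed
  )
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_table_tsv(df, path, comment = stamp)
    files[[name]] <<- path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  dataset <- stage("load", read_ped_map(config$ped, config$map))
  message(sprintf("load: %d samples x %d markers", n_samples(dataset), n_markers(dataset)))

  qc_res <- stage("qc", run_qc(dataset, config$qc))
  dataset <- qc_res$dataset
  emit(qc_res$report, "qc_report.tsv")
  stage("qc", write_ped_map(
    dataset,
    file.path(config$out_dir, "filtered.ped"),
    file.path(config$out_dir, "filtered.map")
  ))
  files[["filtered.ped"]] <- file.path(config$out_dir, "filtered.ped")
  files[["filtered.map"]] <- file.path(config$out_dir, "filtered.map")
  message(sprintf(
    "qc: kept %d samples, %d markers", n_samples(dataset), n_markers(dataset)
  ))

  segments <- stage("detect", detect_roh(dataset, config$roh))
  emit(segments, "roh_segments.tsv")
  message(sprintf(
    "detect: %d segments (min_snps = %d)", nrow(segments), attr(segments, "min_snps")
  ))

  length_classes <- stage(
    "summarize",
    summarize_length_classes(segments$length_bp, config$class_bounds_mb)
  )
  emit(length_classes, "length_classes.tsv")
  coverage <- stage("summarize", chromosome_coverage(segments, dataset))
  emit(coverage, "chromosome_coverage.tsv")

  profile <- stage("islands", support_profile(segments, dataset))
  emit(profile, "support_profile.tsv")
  islands <- list()
  for (thr in config$island_thresholds) {
    isl <- stage("islands", call_islands(profile, thr))
    islands[[as.character(thr)]] <- isl
    emit(isl, sprintf("islands_%s.tsv", format(thr)))
    message(sprintf("islands: %d island(s) at support >= %s", nrow(isl), format(thr)))
  }

  annotated <- NULL
  if (!is.null(config$genes_bed)) {
    annotated <- stage("annotate", {
      track <- load_gene_track(config$genes_bed)
      ann <- genes_in_islands(
        islands[[1]], track,
        mode = config$annotation_mode, flank_bp = config$flank_bp
      )
      ann$genes <- vapply(ann$genes, paste, character(1), collapse = ",")
      ann
    })
    emit(annotated, "island_genes.tsv")
  }

  assoc_res <- NULL
  if (!is.null(config$phenotype)) {
    assoc_res <- stage("assoc", {
      pheno <- read_table_tsv(config$phenotype)
      state <- roh_state_matrix(segments, dataset)
      assoc_scan(state, pheno, config$assoc, markers = dataset$markers)
    })
    emit(assoc_res, "assoc.tsv")
    message(sprintf(
      "assoc: %d markers tested, %d significant at p < %g",
      nrow(assoc_res), sum(assoc_res$significant), config$assoc$bonferroni_p
    ))
  }

  invisible(list(
    qc = qc_res, segments = segments, length_classes = length_classes,
    coverage = coverage, profile = profile, islands = islands,
    annotated = annotated, assoc = assoc_res, files = files
  ))
}
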