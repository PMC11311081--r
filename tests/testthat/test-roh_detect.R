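test_that("minimum SNP count matches direct evaluation and handles domains", {
  expect_identical(min_snp_count(1, 1, 0.5, 0.5), 1L)
  expect_identical(min_snp_count(1000, 100, 0.05, 0.5), 21L)
  expect_identical(min_snp_count(106828, 189, 0.05, 0.37), 43L)
  expect_error(min_snp_count(100, 10, 0.05, 1.2), "mean_het")
  expect_error(min_snp_count(100, 10, 0.05, 0), "mean_het")
  expect_error(min_snp_count(100, 10, 1.5, 0.4), "alpha")
  expect_error(min_snp_count(0, 10, 0.05, 0.4), ">= 1")
})

test_that("minimum SNP count is monotone in each argument", {
  grid_ns <- c(10, 1000, 106828)
  grid_ni <- c(1, 50, 189)
  grid_a <- c(0.01, 0.05, 0.2)
  grid_h <- c(0.1, 0.37, 0.6)
  for (ni in grid_ni) for (a in grid_a) for (h in grid_h) {
    l <- vapply(grid_ns, min_snp_count, integer(1), n_i = ni, alpha = a, mean_het = h)
    expect_true(all(diff(l) >= 0)) # non-decreasing in n_s
  }
  for (ns in grid_ns) for (a in grid_a) for (h in grid_h) {
    l <- vapply(grid_ni, function(ni) min_snp_count(ns, ni, a, h), integer(1))
    expect_true(all(diff(l) >= 0)) # non-decreasing in n_i
  }
  for (ns in grid_ns) for (ni in grid_ni) for (h in grid_h) {
    l <- vapply(grid_a, function(a) min_snp_count(ns, ni, a, h), integer(1))
    expect_true(all(diff(l) <= 0)) # non-increasing in alpha
  }
  for (ns in grid_ns) for (ni in grid_ni) for (a in grid_a) {
    l <- vapply(grid_h, function(h) min_snp_count(ns, ni, a, h), integer(1))
    expect_true(all(diff(l) <= 0)) # non-increasing in mean_het
  }
})

test_that("an all-heterozygous individual yields no runs", {
  segs <- detect_one(rep(1L, 50), seq_len(50) * 25000L, min_snps = 5)
  expect_identical(nrow(segs), 0L)
})

test_that("a clean homozygous stretch is emitted as a single run", {
  pos <- seq_len(25) * 25000L # span 600 kb
  segs <- detect_one(rep(0L, 25), pos, min_snps = 20, min_length_bp = 500000L)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$start_bp, pos[1])
  expect_identical(segs$end_bp, pos[25])
  expect_identical(segs$n_snps, 25L)
  expect_identical(segs$n_het, 0L)
  oracle <- brute_force_roh(rep(0L, 25), pos, 1, 1, 20, 500000L, 1e6)
  expect_equal(segs[, c("start_bp", "end_bp", "n_snps")],
               oracle[, c("start_bp", "end_bp", "n_snps")],
               ignore_attr = TRUE)
})

test_that("the heterozygote allowance decides whether a run survives an interior het", {
  g <- rep(0L, 25)
  g[13] <- 1L
  pos <- seq_len(25) * 25000L
  with_allow <- detect_one(g, pos, min_snps = 20, min_length_bp = 500000L,
                           max_het_in_run = 1)
  expect_identical(nrow(with_allow), 1L)
  expect_identical(with_allow$n_het, 1L)
  expect_identical(with_allow$n_snps, 25L)
  without <- detect_one(g, pos, min_snps = 20, min_length_bp = 500000L,
                        max_het_in_run = 0)
  expect_identical(nrow(without), 0L) # each half has only 12 SNPs
})

test_that("detection equals the brute-force maximal-window oracle on random chromosomes", {
  set.seed(101)
  for (rep in 1:60) {
    m <- sample(20:200, 1)
    rc <- random_chromosome(m)
    max_het <- sample(0:2, 1)
    max_miss <- sample(0:2, 1)
    min_snps <- sample(3:8, 1)
    min_len <- sample(c(1L, 5000L, 20000L), 1)
    max_gap <- sample(c(500L, 5000L, 1e6L), 1)
    segs <- detect_one(
      rc$g, rc$pos,
      max_het_in_run = max_het, max_missing_in_run = max_miss,
      min_snps = min_snps, min_length_bp = min_len, max_gap_bp = max_gap
    )
    oracle <- brute_force_roh(rc$g, rc$pos, max_het, max_miss, min_snps, min_len, max_gap)
    expect_equal(
      as.data.frame(segs[, c("start_bp", "end_bp", "n_snps", "n_het", "n_missing")]),
      oracle,
      ignore_attr = TRUE
    )
  }
})

test_that("emitted segments satisfy every segment invariant", {
  set.seed(55)
  cfg <- roh_config(min_snps = 5, min_length_bp = 10000L,
                    max_het_in_run = 1, max_missing_in_run = 1)
  for (rep in 1:10) {
    calls <- matrix(
      sample(c(0L, 0L, 0L, 1L, 2L, 2L, NA), 5 * 150, replace = TRUE),
      nrow = 5
    )
    ds <- make_dataset(calls, bp = sort(sample.int(2e6, 150)))
    segs <- detect_roh(ds, cfg)
    if (nrow(segs)) {
      expect_true(all(segs$end_bp > segs$start_bp))
      expect_true(all(segs$length_bp == segs$end_bp - segs$start_bp))
      expect_true(all(segs$n_het <= 1))
      expect_true(all(segs$n_missing <= 1))
      expect_true(all(segs$n_snps >= 5))
      expect_true(all(segs$length_bp >= 10000))
    }
  }
})

test_that("tightening thresholds never adds runs; relaxing the het allowance never shrinks coverage", {
  set.seed(77)
  calls <- matrix(
    sample(c(0L, 0L, 0L, 0L, 1L, 2L, 2L, NA), 4 * 300, replace = TRUE),
    nrow = 4
  )
  ds <- make_dataset(calls, bp = sort(sample.int(4e6, 300)))
  key <- function(s) paste(s$sample_id, s$start_bp, s$end_bp)
  covered <- function(s) sum(vapply(split(s, s$sample_id), function(x) {
    rohscan:::union_length(x$start_bp, x$end_bp)
  }, numeric(1)))

  base <- detect_roh(ds, roh_config(min_snps = 4, min_length_bp = 10000L))
  for (ms in c(6, 10)) {
    stricter <- detect_roh(ds, roh_config(min_snps = ms, min_length_bp = 10000L))
    expect_true(all(key(stricter) %in% key(base)))
  }
  for (ml in c(50000L, 200000L)) {
    stricter <- detect_roh(ds, roh_config(min_snps = 4, min_length_bp = ml))
    expect_true(all(key(stricter) %in% key(base)))
  }
  cov <- vapply(0:3, function(mh) {
    covered(detect_roh(ds, roh_config(min_snps = 4, min_length_bp = 10000L,
                                      max_het_in_run = mh)))
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("roh_length uses the end-minus-start convention", {
  segs <- tibble::tibble(start_bp = c(100L, 500L), end_bp = c(400L, 2500L))
  expect_identical(roh_length(segs), c(300L, 2000L))
  expect_error(roh_length(tibble::tibble(start_bp = 5L, end_bp = 5L)), "invalid")
})

test_that("zero-error planted segments are recovered at SNP resolution", {
  planted <- data.frame(
    chrom = "1", start_bp = 10000000L, end_bp = 12000000L, carrier_fraction = 0.4
  )
  sim <- simulate_population(sim_config(
    n_individuals = 30,
    chromosomes = list(list(label = "1", n_markers = 1200L, extent_bp = 30000000L)),
    missing_rate = 0, het_error_rate = 0,
    planted_segments = planted, seed = 21
  ))
  segs <- detect_roh(sim$dataset, roh_config())
  mk <- sim$dataset$markers
  in_seg <- mk$bp >= planted$start_bp & mk$bp <= planted$end_bp
  first_bp <- min(mk$bp[in_seg])
  last_bp <- max(mk$bp[in_seg])
  carriers <- sim$truth$carriers[[1]]
  for (cid in carriers) {
    own <- segs[segs$sample_id == cid, ]
    covering <- own[own$start_bp <= first_bp & own$end_bp >= last_bp, ]
    # at least one run spans every planted marker (two maximal runs can both
    # cover it when the het allowance is spent on opposite flanks)
    expect_gte(nrow(covering), 1L)
  }
  # a hand-built het-flanked run gives exact boundary agreement
  g <- c(1L, rep(0L, 30), 1L)
  pos <- c(1000L, seq(100000L, by = 25000L, length.out = 30), 999000L)
  exact <- detect_one(g, pos, min_snps = 20, min_length_bp = 500000L,
                      max_het_in_run = 0)
  expect_identical(exact$start_bp, 100000L)
  expect_identical(exact$end_bp, 100000L + 29L * 25000L)
})
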