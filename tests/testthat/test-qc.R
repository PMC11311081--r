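test_that("sample call-rate filter removes samples strictly below threshold", {
  calls <- matrix(0L, nrow = 3, ncol = 100)
  calls[2, 1:11] <- NA # call rate 0.89
  calls[3, 1] <- NA # call rate 0.99
  ds <- make_dataset(calls)
  res <- filter_samples_by_callrate(ds, 0.90)
  expect_identical(res$removed, "s02")
  expect_identical(res$dataset$samples, c("s01", "s03"))
  expect_identical(n_markers(res$dataset), 100L)

  # threshold 1.0: any missing call removes the sample
  res1 <- filter_samples_by_callrate(ds, 1.0)
  expect_setequal(res1$removed, c("s02", "s03"))
  expect_error(qc_config(min_sample_callrate = 0), "\\(0, 1\\]")
  expect_error(
    filter_samples_by_callrate(make_dataset(matrix(NA_integer_, 2, 4)), 0.5),
    "empty dataset"
  )
})

test_that("SNP call-rate filter matches a brute-force recount on a planted pattern", {
  set.seed(42)
  calls <- matrix(sample(0:2, 100, replace = TRUE), nrow = 10)
  miss <- matrix(runif(100) < 0.15, nrow = 10)
  calls[miss] <- NA
  calls[, 4] <- 0L # fully observed marker: kept at any threshold
  ds <- make_dataset(calls)
  for (thr in c(0.5, 0.8, 0.9, 1.0)) {
    res <- filter_snps_by_callrate(ds, thr)
    oracle <- ds$markers$id[colSums(!is.na(calls)) / 10 < thr]
    expect_identical(res$removed, oracle)
    expect_false("m0004" %in% res$removed)
  }
  # 2 of 10 missing -> call rate 0.8 < 0.9 -> removed
  calls2 <- matrix(1L, nrow = 10, ncol = 2)
  calls2[1:2, 1] <- NA
  res <- filter_snps_by_callrate(make_dataset(calls2), 0.9)
  expect_identical(res$removed, "m0001")
})

test_that("exact HWE p-values match the enumeration oracle and known values", {
  # monomorphic: single possible table
  expect_identical(hwe_exact_pvalue(50, 0, 0), 1)
  expect_identical(hwe_exact_pvalue(0, 0, 7), 1)
  # frozen value computed once in exact rational arithmetic: 26029/46189
  expect_equal(hwe_exact_pvalue(3, 4, 3), 26029 / 46189, tolerance = 1e-12)
  # independent lfactorial enumeration across a deterministic sweep
  set.seed(1)
  for (rep in 1:200) {
    cnt <- as.vector(stats::rmultinom(1, sample(1:60, 1), prob = runif(3)))
    expect_equal(
      hwe_exact_pvalue(cnt[1], cnt[2], cnt[3]),
      hwe_oracle(cnt[1], cnt[2], cnt[3]),
      tolerance = 1e-9
    )
  }
  expect_error(hwe_exact_pvalue(0, 0, 0), "zero")
  expect_error(hwe_exact_pvalue(-1, 2, 3), "non-negative")
})

test_that("exact HWE test is symmetric and approaches the chi-square asymptote", {
  for (cnt in list(c(3, 4, 3), c(10, 2, 30), c(7, 0, 1))) {
    expect_equal(
      hwe_exact_pvalue(cnt[1], cnt[2], cnt[3]),
      hwe_exact_pvalue(cnt[3], cnt[2], cnt[1])
    )
  }
  # the exact test's discreteness vanishes asymptotically: agreement with the
  # 1-df chi-square tightens as the same genotype proportions are scaled up
  gap <- vapply(c(1, 5, 20), function(mult) {
    cnt <- c(300, 500, 200) * mult
    abs(hwe_exact_pvalue(cnt[1], cnt[2], cnt[3]) - hwe_chisq_p(cnt[1], cnt[2], cnt[3]))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[3], 0.02)
})

test_that("HWE filter removes het-deficient markers and retains balanced ones", {
  # marker 1: perfect HWE proportions; marker 2: total het deficit; marker 3: monomorphic
  calls <- cbind(
    rep(c(0L, 1L, 2L), times = c(25, 50, 25)),
    rep(c(0L, 2L), times = c(50, 50)),
    rep(0L, 100)
  )
  ds <- make_dataset(calls)
  res <- filter_snps_by_hwe(ds, 1e-6)
  expect_identical(res$removed, "m0002")
  expect_identical(res$dataset$markers$id, c("m0001", "m0003"))
  expect_equal(unname(res$p_values[["m0003"]]), 1)
  expect_lt(res$p_values[["m0002"]], 1e-6)
})

test_that("run_qc applies sample -> SNP -> HWE in order and reports counts", {
  set.seed(7)
  n <- 40
  good <- matrix(rbinom(n * 15, 2, 0.4), nrow = n)
  bad_snp <- matrix(rbinom(n, 2, 0.4), ncol = 1)
  bad_snp[1:8, 1] <- NA # call rate 0.8
  hwe_bad <- matrix(rep(c(0L, 2L), each = n / 2), ncol = 1)
  calls <- cbind(good, bad_snp, hwe_bad)
  calls[n, ] <- NA # bad sample: call rate 0
  ds <- make_dataset(calls)
  res <- run_qc(ds, qc_config(0.9, 0.9, 1e-6))
  expect_equal(res$report$n_samples_removed, 1)
  expect_equal(res$report$n_snps_removed_callrate, 1)
  expect_equal(res$report$n_snps_removed_hwe, 1)
  expect_equal(res$report$n_samples_kept + res$report$n_samples_removed, n)
  expect_equal(
    res$report$n_snps_kept + res$report$n_snps_removed_callrate +
      res$report$n_snps_removed_hwe,
    17
  )

  # idempotence: a second pass removes nothing
  res2 <- run_qc(res$dataset, qc_config(0.9, 0.9, 1e-6))
  expect_equal(res2$report$n_samples_removed, 0)
  expect_equal(res2$report$n_snps_removed_callrate, 0)
  expect_equal(res2$report$n_snps_removed_hwe, 0)
  expect_identical(res2$dataset$calls, res$dataset$calls)
})

test_that("removing a low-call-rate sample first can rescue a SNP's call rate", {
  # sample 10 is missing everywhere; marker 1 is missing only in sample 10
  calls <- matrix(1L, nrow = 10, ncol = 10)
  calls[10, ] <- NA
  ds <- make_dataset(calls)
  # SNP filter alone (wrong order) would drop every marker at threshold 0.95
  expect_length(filter_snps_by_callrate(ds, 0.95)$removed, 10)
  # declared order keeps all markers
  res <- run_qc(ds, qc_config(0.9, 0.95, 1e-6))
  expect_identical(res$report$n_snps_removed_callrate, 0L)
  expect_identical(res$report$n_samples_removed, 1L)
})

test_that("clean data passes QC untouched", {
  calls <- matrix(rep(c(0L, 1L, 2L, 1L), times = 25), nrow = 10)
  ds <- make_dataset(calls)
  res <- run_qc(ds)
  expect_equal(res$report$n_samples_removed, 0)
  expect_equal(res$report$n_snps_removed_callrate, 0)
  expect_equal(res$report$n_snps_removed_hwe, 0)
  expect_identical(res$dataset$calls, ds$calls)
})
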