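# Independent oracles, deliberately coded by different routes than the
# package implementation.

# Exact HWE test by direct enumeration of the fully normalized conditional
# distribution over heterozygote counts (multinomial / allele-permanence
# formula evaluated with lfactorial, no recurrences, no rescaling tricks).
hwe_oracle <- function(n_AA, n_Ab, n_bb) {
  n <- n_AA + n_Ab + n_bb
  nA <- 2 * n_AA + n_Ab
  hmax <- min(nA, 2 * n - nA)
  hs <- seq.int(nA %% 2, hmax, by = 2)
  logp <- lfactorial(n) -
    lfactorial((nA - hs) / 2) - lfactorial(hs) - lfactorial((2 * n - nA - hs) / 2) +
    hs * log(2) +
    lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  p <- exp(logp)
  stopifnot(abs(sum(p) - 1) < 1e-9)
  p_obs <- p[match(n_Ab, hs)]
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# Asymptotic 1-df chi-square HWE p-value.
hwe_chisq_p <- function(n_AA, n_Ab, n_bb) {
  n <- n_AA + n_Ab + n_bb
  p <- (2 * n_AA + n_Ab) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_AA, n_Ab, n_bb)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

# Brute-force ROH scanner for one individual on one chromosome: enumerates
# every homozygous-ended window, keeps those satisfying all constraints, and
# drops windows contained in another qualifying window.
brute_force_roh <- function(g, pos, max_het = 1, max_miss = 1,
                            min_snps = 2, min_len = 1, max_gap = Inf) {
  m <- length(g)
  is_miss <- is.na(g)
  is_het <- !is_miss & g == 1L
  is_hom <- !is_miss & !is_het
  H <- cumsum(is_het)
  M <- cumsum(is_miss)
  G <- c(0, cumsum(if (m > 1) diff(pos) > max_gap else logical(0)))
  win_i <- integer(0)
  win_j <- integer(0)
  for (i in which(is_hom)) {
    j <- seq(i, m)
    ok <- is_hom[j] &
      (j - i + 1) >= min_snps &
      (pos[j] - pos[i]) >= min_len &
      (H[j] - H[i]) <= max_het &
      (M[j] - M[i]) <= max_miss &
      G[j] == G[i]
    win_i <- c(win_i, rep(i, sum(ok)))
    win_j <- c(win_j, j[ok])
  }
  if (!length(win_i)) {
    return(data.frame(
      start_bp = integer(0), end_bp = integer(0),
      n_snps = integer(0), n_het = integer(0), n_missing = integer(0)
    ))
  }
  dominated <- vapply(seq_along(win_i), function(k) {
    any(win_i <= win_i[k] & win_j >= win_j[k] & (win_i < win_i[k] | win_j > win_j[k]))
  }, logical(1))
  i <- win_i[!dominated]
  j <- win_j[!dominated]
  o <- order(i)
  i <- i[o]
  j <- j[o]
  data.frame(
    start_bp = pos[i], end_bp = pos[j],
    n_snps = j - i + 1L,
    n_het = H[j] - H[i],
    n_missing = M[j] - M[i]
  )
}

# Random single-sample chromosome for oracle-equivalence checks.
random_chromosome <- function(m, span = 2000L,
                              probs = c(hom0 = 0.5, het = 0.15, hom2 = 0.25, miss = 0.1)) {
  pos <- sort(sample.int(span * 10L, m))
  g <- sample(c(0L, 1L, 2L, NA_integer_), m, replace = TRUE, prob = probs)
  list(g = g, pos = pos)
}
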