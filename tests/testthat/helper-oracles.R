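# Independent oracles used across the suite: literal transcriptions of the
# definitions, deliberately naive and separate from the package internals.

# Pincus ApEn by direct template counting (double loop over template
# positions); natural log, Chebyshev distance, self-matches included.
apen_naive <- function(x, m, r_abs) {
  n <- length(x)
  phi <- function(mm) {
    nm <- n - mm + 1
    tmpl <- sapply(seq_len(mm), function(k) x[k:(nm + k - 1)])
    s <- 0
    for (i in seq_len(nm)) {
      cnt <- 0
      for (j in seq_len(nm)) {
        if (max(abs(tmpl[i, ] - tmpl[j, ])) <= r_abs) cnt <- cnt + 1
      }
      s <- s + log(cnt / nm)
    }
    s / nm
  }
  phi(m) - phi(m + 1)
}

# Exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# choose(n1+n2, n1) rank assignments (tie-free samples only).
wilcoxon_enum_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  ws <- colSums(matrix(seq_len(n)[combos], nrow = n1))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Analytic autocovariance of standard fGn.
fgn_acov <- function(k, hurst) {
  h2 <- 2 * hurst
  0.5 * (abs(k + 1)^h2 - 2 * abs(k)^h2 + abs(k - 1)^h2)
}

# Small persistent-walk cohort shared by several tests.
make_persistent <- function(seed, n_frames = 4100, tau = 540, bias = 0) {
  gen_persistent(walker_config("persistent", persistence_time = tau,
                               bias_strength = bias, n_frames = n_frames,
                               seed = seed))
}
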