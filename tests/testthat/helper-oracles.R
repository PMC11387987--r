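# Independent oracles and small fixture builders used across the suite.

# Naive O(N^2) one-sided DFT magnitudes of a (windowed, zero-padded) frame.
naive_dft_magnitudes <- function(x, nfft) {
  x <- c(x, rep(0, nfft - length(x)))
  n <- seq_len(nfft) - 1
  vapply(0:(nfft / 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * n / nfft)))
  }, numeric(1))
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments;
# two-sided by doubling the smaller tail of the U distribution (the same
# convention as the exact rank-sum distribution).
permutation_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - na * (na + 1) / 2
  }
  obs <- u_of(seq_len(na))
  all_u <- apply(utils::combn(length(pooled), na), 2,
                 function(idx) u_of(idx))
  p_low <- mean(all_u <= obs)
  p_high <- mean(all_u >= obs)
  min(1, 2 * min(p_low, p_high))
}

# Two well-separated Gaussian clusters in 2 features; linearly separable.
separable_table <- function(n_per_class = 10, gap = 10, seed = 99) {
  m <- with_test_seed(seed, {
    rbind(matrix(rnorm(2 * n_per_class), ncol = 2),
          matrix(rnorm(2 * n_per_class, mean = gap), ncol = 2))
  })
  colnames(m) <- c("f1", "f2")
  feature_table(m, sprintf("s%02d", seq_len(2 * n_per_class)),
                rep(c("improved", "unimproved"), each = n_per_class))
}

# Run code under a seed without touching the suite's RNG stream.
with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  force(code)
}

# A normalized series wrapper for plain numeric vectors in [0, 1].
norm_series <- function(values, id = "s", label = NA_character_) {
  mfc_series(values, id, label, normalized = TRUE)
}

sum_hamming <- function(m) sum(as.numeric(signal::hamming(m)))
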