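# Independent brute-force oracles, deliberately written in plain R with no
# shared code with the package internals.

# Richman–Moorman sample entropy by direct pairwise enumeration.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  B <- 0; A <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# Pincus approximate entropy with self-matches.
brute_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1
    logc <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      logc[i] <- log(cnt / nt)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

# Energy of a pure tone window via the analytic variance of a sinusoid.
tone_energy <- function(amplitude, n) amplitude^2 / 2 * n / 2
# (periodogram power summed over the two conjugate bins is n * A^2 / 4 each;
# the positive-frequency bin alone carries n * A^2 / 4)

# Dense direction grid maximising the negentropy contrast in 2-D.
grid_max_contrast <- function(Z, nl, n_grid = 720) {
  th <- seq(0, pi, length.out = n_grid)
  vals <- vapply(th, function(a) {
    w <- c(cos(a), sin(a))
    wz <- drop(crossprod(w, Z))
    abs(mean(nl$G(wz)) - nl$EG_gauss)
  }, numeric(1))
  list(theta = th[which.max(vals)], value = max(vals),
       w = c(cos(th[which.max(vals)]), sin(th[which.max(vals)])))
}

# Greedy best-match absolute Pearson correlations between recovered and true
# source rows.
match_abs_cor <- function(S_est, S_true) {
  R <- abs(stats::cor(t(S_est), t(S_true)))
  k <- nrow(R)
  out <- numeric(k)
  for (i in seq_len(k)) {
    idx <- which(R == max(R), arr.ind = TRUE)[1, ]
    out[i] <- R[idx[1], idx[2]]
    R[idx[1], ] <- -1
    R[, idx[2]] <- -1
  }
  sort(out)
}

# Small deterministic multichannel recording for I/O tests.
tiny_recording <- function(n_ch = 2, n_samp = 10, fs = 4, seed = 99) {
  set.seed(seed)
  recording(matrix(round(rnorm(n_ch * n_samp), 6), nrow = n_ch), fs = fs,
            channel_names = paste0("E", seq_len(n_ch)))
}
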