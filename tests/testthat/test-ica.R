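test_that("whitening yields identity covariance and honours the diagonal case", {
  set.seed(1)
  # diagonal case: 2 channels with variances 4 and 1
  X <- rbind(2 * rnorm(4000), rnorm(4000))
  wm <- fit_whitening(X)
  expect_equal(wm$D, c(4, 1), tolerance = 0.1)
  Z <- whiten(wm, X)
  expect_equal(apply(Z, 1, var), c(1, 1), tolerance = 1e-10)

  # seeded mixed-source data: covariance of whitened output is the oracle
  b <- make_bss_benchmark(seed = 5)
  Zb <- whiten(fit_whitening(b$recording$data), b$recording$data)
  C <- tcrossprod(Zb) / (ncol(Zb) - 1)
  expect_lt(max(abs(C - diag(nrow(C)))), 1e-8)
  expect_equal(rowMeans(Zb), rep(0, 3), tolerance = 1e-12)
})

test_that("whitening is a pure rotation on already-white data", {
  set.seed(2)
  X <- matrix(rnorm(3 * 6000), 3)
  wm <- fit_whitening(X)
  VS <- wm$V %*% (tcrossprod(X - rowMeans(X)) / (ncol(X) - 1)) %*% t(wm$V)
  expect_equal(VS, diag(3), tolerance = 1e-10)
  # eigenvector columns orthonormal, eigenvalues descending
  expect_equal(crossprod(wm$E), diag(3), tolerance = 1e-12)
  expect_true(all(diff(wm$D) <= 0))
})

test_that("rank-deficient covariance is rejected with a remedy", {
  set.seed(3)
  x <- rnorm(1000)
  X <- rbind(x, 2 * x, rnorm(1000)) # rank 2
  expect_error(fit_whitening(X), "rank deficient.*lower n_keep")
  wm <- fit_whitening(X, n_keep = 2)
  expect_equal(wm$n_keep, 2)
  Z <- whiten(wm, X)
  expect_equal(tcrossprod(Z) / (ncol(Z) - 1), diag(2), tolerance = 1e-8)
})

test_that("the one-unit update is stationary at a fixed point and finds the
           non-Gaussian direction a dense grid search finds", {
  set.seed(4)
  n <- 8000
  src <- sign(sin(2 * pi * 3 * (1:n) / 128)) # pure sign signal
  Z <- rbind(src / sd(src), rnorm(n))
  wm <- fit_whitening(Z)
  Zw <- whiten(wm, Z)
  nl <- nonlinearity()

  w <- c(1 / sqrt(2), 1 / sqrt(2))
  for (i in 1:10) w <- one_unit_update(w, Zw, nl)
  # oracle: grid search over directions maximising the negentropy contrast
  oracle <- grid_max_contrast(Zw, nl)
  expect_gt(abs(sum(w * oracle$w)), 0.999)
  # fixed point: one more update leaves the direction unchanged
  w2 <- one_unit_update(w, Zw, nl)
  expect_gt(abs(sum(w2 * w)), 1 - 1e-6)
})

test_that("tanh nonlinearity handles u = 0 by its odd symmetry", {
  nl <- nonlinearity()
  expect_identical(nl$g(0), 0)
  expect_identical(nl$gprime(0), 1)
  # symmetric data about zero: the E[z g] term drives the update
  Z <- rbind(c(1, -1, 2, -2), c(0.5, -0.5, -0.3, 0.3))
  w <- c(1, 0)
  expect_no_error(one_unit_update(w, Z, nl))
})

test_that("the benchmark sources are recovered (r >= 0.95, Amari <= 0.05)", {
  bench <- make_bss_benchmark(seed = 7)
  fit <- fit_ica(bench$recording$data, seed = 7)
  S_est <- unmix(fit, bench$recording$data)
  r <- match_abs_cor(S_est, bench$ground_truth$S)
  expect_true(all(r >= 0.95))
  expect_lte(amari_index(fit$W %*% fit$whitening$V, bench$ground_truth$A),
             0.05)
  expect_true(all(fit$converged))
})

test_that("W rows are orthonormal and components have identity covariance", {
  bench <- make_bss_benchmark(seed = 8)
  fit <- fit_ica(bench$recording$data, seed = 8)
  WWt <- tcrossprod(fit$W)
  expect_lt(max(abs(WWt - diag(nrow(fit$W)))), 1e-8)
  S <- unmix(fit, bench$recording$data)
  expect_equal(tcrossprod(S) / (ncol(S) - 1), diag(3), tolerance = 1e-6)
})

test_that("a single channel unmixes to its standardised self", {
  set.seed(9)
  x <- matrix(runif(3000, -1, 1), 1)
  fit <- fit_ica(x, n_components = 1, seed = 9)
  expect_equal(abs(drop(fit$W)), 1, tolerance = 1e-12)
  S <- unmix(fit, x)
  xc <- drop(scale(drop(x))) * sqrt(3000 / 2999) # population-sd convention
  expect_equal(abs(cor(drop(S), drop(x))), 1, tolerance = 1e-12)
})

test_that("round trip through the estimated mixing matrix reconstructs the data", {
  bench <- make_bss_benchmark(seed = 10)
  X <- bench$recording$data
  fit <- fit_ica(X, seed = 10)
  S <- unmix(fit, X)
  Xc <- X - rowMeans(X)
  X_rec <- mixing_matrix(fit) %*% S
  expect_lt(max(abs(X_rec - Xc)) / max(abs(Xc)), 1e-6)
})

test_that("channel permutation with the matching model permutation is inert", {
  bench <- make_bss_benchmark(seed = 11)
  X <- bench$recording$data
  fit <- fit_ica(X, seed = 11)
  perm <- c(3, 1, 2)
  fit_p <- fit
  fit_p$whitening$mean <- fit$whitening$mean[perm]
  fit_p$whitening$V <- fit$whitening$V[, perm]
  expect_equal(unmix(fit_p, X[perm, ]), unmix(fit, X))
})

test_that("scaling a source only permutes/flips the recovered components", {
  bank <- source_bank(seed = 3)
  bank_scaled <- bank
  bank_scaled$S[2, ] <- bank$S[2, ] # standardisation makes scale moot at the
  # source level, so scale the observations instead
  b <- make_bss_benchmark(bank, seed = 12)
  X2 <- diag(c(1, 5, 0.3)) %*% b$recording$data
  f1 <- fit_ica(b$recording$data, seed = 12)
  f2 <- fit_ica(X2, seed = 12)
  S1 <- unmix(f1, b$recording$data)
  S2 <- unmix(f2, X2)
  R <- abs(cor(t(S1), t(S2)))
  # every component of one fit matches exactly one of the other
  expect_true(all(apply(R, 1, max) > 0.999))
  expect_equal(sort(apply(R, 1, which.max)), 1:3)
})

test_that("converged directions beat random ones on the negentropy contrast", {
  bench <- make_bss_benchmark(seed = 13)
  fit <- fit_ica(bench$recording$data, seed = 13)
  Z <- whiten(fit$whitening, bench$recording$data)
  nl <- fit$nl
  set.seed(13)
  rand_vals <- replicate(32, {
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    negentropy_contrast(v, Z, nl)
  })
  # the components sit at the contrast's local maxima (the source
  # directions); deflation constrains later components to an orthogonal
  # complement, so the guarantee is that the best component dominates every
  # random direction
  comp_vals <- vapply(1:3, function(k) {
    negentropy_contrast(fit$W[k, ], Z, nl)
  }, numeric(1))
  expect_gte(max(comp_vals), max(rand_vals) - 1e-12)
  expect_gt(mean(comp_vals), mean(rand_vals))
})

test_that("two Gaussian sources do not crash (unidentifiable case)", {
  set.seed(14)
  S <- rbind(rnorm(4000), rnorm(4000))
  A <- matrix(c(1, 0.4, 0.3, 1), 2)
  fit <- suppressWarnings(fit_ica(A %*% S, seed = 14, max_iter = 50))
  expect_s3_class(fit, "ica_fit")
  expect_length(fit$converged, 2)
})

test_that("amari index is zero exactly on scaled permutations", {
  expect_equal(amari_index(diag(3), diag(3)), 0)
  P <- diag(c(2, -0.5, 3))[c(2, 3, 1), ]
  expect_equal(amari_index(P, diag(3)), 0)
  expect_gt(amari_index(matrix(1, 3, 3), diag(3)), 0)
  expect_error(amari_index(matrix(1, 2, 3), diag(3)), "square")
})

test_that("symmetric orthogonalisation also recovers the benchmark", {
  bench <- make_bss_benchmark(seed = 15)
  fit <- fit_ica(bench$recording$data, seed = 15, ortho = "symmetric")
  r <- match_abs_cor(unmix(fit, bench$recording$data), bench$ground_truth$S)
  expect_true(all(r >= 0.95))
})

test_that("ica fits serialise to JSON and back", {
  bench <- make_bss_benchmark(seed = 16)
  fit <- fit_ica(bench$recording$data, seed = 16)
  path <- tempfile(fileext = ".json")
  write_ica(fit, path)
  fit2 <- read_ica(path)
  expect_equal(fit2$W, fit$W, tolerance = 1e-12)
  expect_equal(unmix(fit2, bench$recording$data),
               unmix(fit, bench$recording$data), tolerance = 1e-10)
})

test_that("tidy and glance summarise a fit", {
  bench <- make_bss_benchmark(seed = 17)
  fit <- fit_ica(bench$recording$data, seed = 17)
  td <- tidy(fit, data = bench$recording$data)
  expect_equal(nrow(td), 3)
  expect_true(all(c("component", "n_iter", "converged", "contrast") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_components, 3L)
  expect_equal(gl$seed, 17)
})
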