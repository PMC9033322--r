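fs <- 128
tone <- function(f, seconds = 5, amp = 1, fs. = fs) {
  amp * sin(2 * pi * f * seq(0, seconds - 1 / fs., by = 1 / fs.))
}

test_that("a pure 10 Hz sine concentrates its energy in alpha", {
  be <- band_energy(tone(10), fs)
  expect_gte(be$rel_energy[be$band == "alpha"], 0.99)
})

test_that("band energies partition total power for a covering scheme", {
  covering <- band_scheme(tibble::tibble(
    band = c("low", "mid", "high"),
    f_lo = c(1e-9, 16, 32),
    f_hi = c(16, 32, fs / 2)
  ))
  set.seed(21)
  x <- rnorm(640)
  be <- band_energy(x, fs, covering)
  expect_lt(abs(sum(be$energy) - attr(be, "total")) / attr(be, "total"), 1e-9)
  expect_lt(abs(sum(be$rel_energy) - 1), 1e-9)
})

test_that("equal-amplitude 8 Hz and 20 Hz tones give equal band energies", {
  x <- tone(8) + tone(20)
  be <- band_energy(x, fs)
  e_alpha <- be$energy[be$band == "alpha"]
  e_beta3 <- be$energy[be$band == "beta3"]
  expect_lt(abs(e_alpha - e_beta3) / e_alpha, 0.02)
  # closed-form oracle: each unit tone carries n * A^2 / 4 in its positive bin
  expect_equal(e_alpha, tone_energy(1, 640), tolerance = 0.02)
})

test_that("band energies are non-negative and a constant window is degenerate", {
  set.seed(22)
  be <- band_energy(rnorm(256), fs)
  expect_true(all(be$energy >= 0))
  bd <- band_energy(rep(3, 256), fs)
  expect_true(attr(bd, "degenerate"))
  expect_true(all(is.na(bd$rel_energy)))
})

test_that("averaging band features matches a direct mean and skips degenerate windows", {
  set.seed(23)
  tabs <- lapply(1:8, function(i) band_energy(rnorm(640), fs))
  avg <- average_band_features(tabs)
  direct <- rowMeans(vapply(tabs, `[[`, numeric(7), "energy"))
  expect_equal(avg$energy, direct)
  expect_equal(attr(avg, "n_windows"), 8)

  one <- band_energy(rnorm(640), fs)
  same <- average_band_features(list(one, one))
  expect_equal(same$energy, one$energy)

  two <- list(band_energy(rep(0, 640), fs), one)
  avg2 <- average_band_features(two)
  expect_equal(attr(avg2, "n_excluded"), 1)
  expect_equal(avg2$energy, one$energy)
  expect_error(average_band_features(list(band_energy(rep(1, 64), fs))),
               "dropped")
})

test_that("sample entropy matches the brute-force oracle on short fixtures", {
  set.seed(24)
  fixtures <- list(
    rnorm(60), rnorm(120), rnorm(200),
    sin(1:150 / 4), cumsum(rnorm(100)), runif(80)
  )
  for (x in fixtures) {
    for (m in c(1, 2)) {
      r <- 0.2 * sd(x)
      expect_identical(sample_entropy(x, m, r), brute_sampen(x, m, r))
    }
  }
})

test_that("approximate entropy matches the brute-force oracle", {
  set.seed(25)
  for (x in list(rnorm(80), sin(1:90 / 3), runif(70))) {
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, 2, r), brute_apen(x, 2, r),
                 tolerance = 1e-12)
  }
})

test_that("entropy of a constant signal is zero and of noise exceeds a sine", {
  expect_identical(sample_entropy(rep(2, 50)), 0)
  expect_identical(approximate_entropy(rep(-1, 50)), 0)
  set.seed(26)
  noise <- rnorm(1000)
  pure <- sin(2 * pi * (1:1000) / 50)
  expect_gt(sample_entropy(noise, 2, 0.2 * sd(noise)),
            sample_entropy(pure, 2, 0.2 * sd(pure)))
  expect_gt(approximate_entropy(noise, 2, 0.2 * sd(noise)),
            approximate_entropy(pure, 2, 0.2 * sd(pure)))
})

test_that("entropies are invariant to offset and jointly scale with (x, r)", {
  set.seed(27)
  x <- rnorm(300)
  r <- 0.2 * sd(x)
  expect_identical(sample_entropy(x + 7, 2, r), sample_entropy(x, 2, r))
  expect_identical(sample_entropy(3 * x, 2, 3 * r), sample_entropy(x, 2, r))
  expect_equal(approximate_entropy(x - 2, 2, r), approximate_entropy(x, 2, r))
})

test_that("undefined sample entropy is flagged, not infinite", {
  # strictly monotone series with tiny r: no m-matches at all
  x <- (1:30)^1.5
  se <- sample_entropy(x, 2, 1e-6)
  expect_true(is.na(se))
  expect_match(attr(se, "reason"), "B = 0")
  # approximate entropy stays finite on the same input
  expect_true(is.finite(approximate_entropy(x, 2, 1e-6)))
})

test_that("composite multiscale entropy at scale 1 is bit-identical to SampEn", {
  set.seed(28)
  x <- rnorm(400)
  cm <- composite_multiscale_entropy(x, entropy_params(scales = 1:5))
  expect_identical(cm$entropy[cm$scale == 1],
                   as.numeric(sample_entropy(x, 2, 0.2 * sd(x))))
})

test_that("composite multiscale entropy matches a per-offset oracle", {
  set.seed(29)
  x <- rnorm(240)
  r <- 0.2 * sd(x)
  cm <- composite_multiscale_entropy(x, entropy_params(scales = c(2, 3)))
  for (tau in c(2, 3)) {
    vals <- sapply(0:(tau - 1), function(off) {
      y <- x[(1 + off):length(x)]
      nb <- length(y) %/% tau
      cg <- colMeans(matrix(y[1:(nb * tau)], nrow = tau))
      brute_sampen(cg, 2, r)
    })
    expect_equal(cm$entropy[cm$scale == tau], mean(vals), tolerance = 1e-12)
  }
})

test_that("white-noise multiscale entropy decreases with scale", {
  set.seed(30)
  x <- rnorm(2000)
  cm <- composite_multiscale_entropy(x, entropy_params(scales = c(1, 2, 5, 10)))
  expect_true(all(diff(cm$entropy) < 0))
})

test_that("the feature table has one row per trial-channel and sane columns", {
  set.seed(31)
  trials <- replicate(3, recording(matrix(rnorm(2 * 10 * fs), 2), fs = fs),
                      simplify = FALSE)
  ft <- extract_features(trials, entropy = entropy_params(scales = 1:3),
                         labels = c("a", "b", "a"))
  expect_equal(nrow(ft), 6)
  expect_true(all(c("alpha_rel", "beta3_energy", "sampen", "apen",
                    "cmse_s1", "cmse_s3", "label") %in% names(ft)))
  expect_equal(ft$n_windows, rep(2, 6))
  wide <- features_wide(ft)
  expect_equal(nrow(wide), 3)
  expect_true("ch1_sampen" %in% names(wide))
})

test_that("feature tables round-trip through CSV", {
  set.seed(32)
  trials <- list(recording(matrix(rnorm(2 * 10 * fs), 2), fs = fs))
  ft <- extract_features(trials, entropy = NULL)
  p <- tempfile(fileext = ".csv")
  write_features(ft, p)
  ft2 <- read_features(p)
  expect_equal(as.data.frame(ft2), as.data.frame(ft), tolerance = 1e-12)
})
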