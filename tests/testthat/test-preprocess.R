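test_that("Savitzky-Golay reproduces polynomials and matches the refit oracle", {
  x <- seq_len(60)
  expect_near(savitzky_golay(rep(2.5, 60), 13, 5), rep(2.5, 60), 1e-12)
  p5 <- 1 + 0.1 * x - 3e-3 * x^2 + 5e-5 * x^3 - 2e-7 * x^4 + 1e-9 * x^5
  expect_near(savitzky_golay(p5, 13, 5), p5, 1e-9)
  set.seed(7)
  y <- rnorm(50)
  expect_near(savitzky_golay(y, 7, 3), sg_oracle(y, 7, 3), 1e-10)
  expect_error(savitzky_golay(y, 8, 3), "odd")
  expect_error(savitzky_golay(y, 7, 7), "order")
})

test_that("Savitzky-Golay is linear", {
  set.seed(8)
  a <- rnorm(80); b <- rnorm(80)
  lhs <- savitzky_golay(2.5 * a - 1.3 * b, 13, 5)
  rhs <- 2.5 * savitzky_golay(a, 13, 5) - 1.3 * savitzky_golay(b, 13, 5)
  expect_near(lhs, rhs, 1e-9)
})

test_that("rubberband baseline equals the lower convex hull", {
  x <- seq(1000, 1200, by = 2)
  v <- abs(x - 1100) / 50 # convex: every point on the hull
  rb <- rubberband_baseline(x, v)
  expect_near(rb$corrected, 0, 1e-12)
  g <- 2 * exp(-((x - 1100) / 20)^2) # equal endpoints, single band
  rb <- rubberband_baseline(x, g)
  expect_near(max(rb$corrected), max(g) - g[1], 1e-9)
  set.seed(9)
  y <- rnorm(200) + 0.01 * seq_len(200)
  xr <- sort(runif(200, 1000, 2000)) # non-uniform axis on purpose
  rb <- rubberband_baseline(xr, y)
  expect_near(rb$baseline, rubberband_oracle(xr, y), 1e-9)
  expect_error(rubberband_baseline(x[1:2], v[1:2]), "3 points")
})

test_that("rubberband corrected spectra are non-negative and pinned at ends", {
  set.seed(10)
  x <- seq(500, 3200, length.out = 300)
  for (i in 1:10) {
    y <- rnorm(300) + cumsum(rnorm(300, 0, 0.2))
    rb <- rubberband_baseline(x, y)
    expect_true(all(rb$corrected >= 0))
    expect_near(rb$corrected[c(1, 300)], 0, 1e-9)
  }
})

test_that("cosmic-ray removal replaces spikes and nothing else", {
  set.seed(11)
  x <- seq(500, 3200, by = 1)
  clean <- 5e-3 * exp(-((x - 1440) / 10)^2) + rnorm(length(x), 0, 1e-4)
  spiked <- clean
  spiked[800] <- spiked[800] + 50 * 1e-4
  ds <- spectral_dataset(x, rbind(clean, spiked), "RAMAN")
  out <- remove_cosmic_rays(ds)
  expect_equal(attr(out, "n_spikes"), 1L)
  expect_near(out$intensities[1, ], clean, 1e-12) # spike-free row untouched
  expect_near(out$intensities[2, -800], spiked[-800], 1e-12)
  expect_lt(abs(out$intensities[2, 800] - clean[800]), 5e-4)
  expect_error(remove_cosmic_rays(spectral_dataset(x, clean, "FTIR")),
               "modality")
})

test_that("despiking removes >= 95% of seeded spikes, no band damage", {
  set.seed(12)
  x <- seq(500, 3200, by = 1)
  n <- 20
  bands <- 4e-3 * exp(-((x - 1003) / 6)^2) + 6e-3 * exp(-((x - 2900) / 14)^2)
  X <- t(replicate(n, bands + rnorm(length(x), 0, 1e-4)))
  pos <- matrix(sample(50:2600, 2 * n), n)
  for (i in seq_len(n)) X[i, pos[i, ]] <- X[i, pos[i, ]] + 40 * 1e-4
  ds <- spectral_dataset(x, X, "RAMAN")
  out <- remove_cosmic_rays(ds)
  fixed <- 0
  for (i in seq_len(n))
    fixed <- fixed + sum(abs(out$intensities[i, pos[i, ]] - X[i, pos[i, ]]) > 1e-6)
  expect_gte(fixed / (2 * n), 0.95)
  # the genuine bands (width >= 5 points) are never replaced
  core <- which(abs(x - 1003) < 10 | abs(x - 2900) < 20)
  for (i in seq_len(n)) {
    untouched <- setdiff(core, pos[i, ])
    expect_near(out$intensities[i, untouched], X[i, untouched], 1e-12)
  }
})

test_that("area normalization yields unit trapezoid integral", {
  x <- seq(0, 1, length.out = 3) + 1000
  expect_near(trapz_oracle(x - 1000, area_normalize(x, rep(2, 3))), 1, 1e-12)
  set.seed(13)
  x <- sort(runif(150, 900, 3800))
  y <- abs(rnorm(150)) + 0.1
  yn <- area_normalize(x, y)
  expect_near(trapz_oracle(x, yn), 1, 1e-10)
  expect_near(area_normalize(x, yn), yn, 1e-12)      # idempotent
  expect_near(area_normalize(x, 37.5 * y), yn, 1e-12) # scale invariant
  expect_error(area_normalize(x, rep(0, 150)), "area")
})

test_that("low-SNR rejection uses a robust band/noise statistic", {
  set.seed(14)
  x <- seq(900, 3800, by = 4)
  band <- 6e-3 * exp(-((x - 1650) / 30)^2)
  noise_only <- t(replicate(3, rnorm(726, 0, 1e-4)))
  clean <- rbind(band, band * 2)
  cfg <- preprocess_config("FTIR", snr_min = 3)
  r <- reject_low_snr(spectral_dataset(x, rbind(clean, noise_only), "FTIR"), cfg)
  expect_equal(r$mask, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # noiseless spectra survive any finite threshold (noise floor applied)
  r2 <- reject_low_snr(spectral_dataset(x, clean, "FTIR"),
                       preprocess_config("FTIR", snr_min = 1e6))
  expect_false(any(r2$mask))
  # 100 spectra, 10 with signal attenuated x0.01 (same detector noise):
  # exactly those rejected
  X <- t(replicate(100, band + rnorm(726, 0, 1e-4)))
  weak <- sample(100, 10)
  X[weak, ] <- t(replicate(10, 0.01 * band + rnorm(726, 0, 1e-4)))
  r3 <- reject_low_snr(spectral_dataset(x, X, "FTIR"), cfg)
  expect_equal(sort(which(r3$mask)), sort(weak))
  expect_error(reject_low_snr(spectral_dataset(seq(900, 1100, 4),
                                               matrix(1, 2, 51), "FTIR"), cfg),
               "config error")
})

test_that("the preprocessing chain is stable on its own output", {
  ds <- sample_dataset(tissue_model("FTIR"), n_per_class = 20, seed = 5)
  p1 <- preprocess(ds)
  expect_equal(attr(p1, "log")$n_rejected, 0L)
  # every preprocessed spectrum has unit area
  areas <- apply(p1$intensities, 1, function(y) trapz_oracle(p1$wavenumbers, y))
  expect_near(areas, 1, 1e-10)
  # a second pass changes spectra only marginally: normalization is exactly
  # idempotent, the re-fitted baseline is tiny, and the only real change is
  # the extra smoothing pass narrowing bands by a few percent
  p2 <- preprocess(p1, preprocess_config("FTIR", snr_min = 0))
  rel <- rowSums(abs(p2$intensities - p1$intensities)) / rowSums(abs(p1$intensities))
  expect_lt(max(rel), 0.06)
  renorm <- t(apply(p1$intensities, 1, function(y) area_normalize(p1$wavenumbers, y)))
  expect_near(renorm, p1$intensities, 1e-12)
})
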