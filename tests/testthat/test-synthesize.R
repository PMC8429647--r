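test_that("basis components are unit-area, non-negative, correctly placed", {
  for (mod in c("FTIR", "RAMAN")) {
    x <- default_axis(mod)
    B <- eval_basis(make_basis(mod), x)
    areas <- apply(B, 1, function(y) trapz_oracle(x, y))
    expect_near(areas, 1, 1e-9)
    expect_true(all(B >= 0))
  }
  # FT-IR lipid ester: carbonyl-region global maximum at 1746 +/- spacing
  x <- default_axis("FTIR")
  B <- eval_basis(make_basis("FTIR"), x)
  co <- x >= 1650 & x <= 1850
  expect_lte(abs(x[co][which.max(B["lipid_ester", co])] - 1746), 4)
  # carbohydrate peaks near 1047; Raman nucleic acid has the DNA modes
  expect_lte(abs(x[which.max(B["carbohydrate", ])] - 1047), 4)
  xr <- default_axis("RAMAN")
  Br <- eval_basis(make_basis("RAMAN"), xr)
  na <- Br["nucleic_acid", ]
  expect_gt(na[xr == 744], 10 * median(na))
  expect_gt(na[xr == 792], 10 * median(na))
})

test_that("sampling is deterministic under a seed and leaves the RNG alone", {
  m <- tissue_model("FTIR")
  set.seed(99); before <- rnorm(1)
  a <- sample_dataset(m, 15, seed = 4)
  b <- sample_dataset(m, 15, seed = 4)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$meta, b$meta)
  set.seed(99)
  expect_identical(rnorm(1), before) # global RNG state restored
  expect_false(identical(a$intensities,
                         sample_dataset(m, 15, seed = 5)$intensities))
})

test_that("margin ester integrals are right-skewed, tumor near-symmetric", {
  ds <- preprocess(sample_dataset(tissue_model("FTIR"), 400, seed = 41))
  lab <- tissue_labels(ds)
  cfg <- lipid_filter_config("FTIR")
  v <- vapply(seq_len(n_spectra(ds)), function(i)
    band_integral(ds$wavenumbers, ds$intensities[i, ], cfg$band), numeric(1))
  expect_gt(distribution_stats(v[lab == "margin"])$skewness, 0)
  expect_lt(abs(distribution_stats(v[lab == "tumor"])$skewness), 0.5)
})

test_that("filtered-out spectra have genuinely higher lipid content", {
  ds <- preprocess(sample_dataset(tissue_model("FTIR"), 400, seed = 42))
  fl <- filter_lipid_rich(ds, lipid_filter_config("FTIR"))
  truth <- ds$meta$lipid_weight
  w <- wilcox.test(truth[fl$removed_mask], truth[!fl$removed_mask],
                   alternative = "greater")
  expect_lt(w$p.value, 0.01)
})

test_that("margin PC1 spread grows with the lipid-rich fraction", {
  sds <- vapply(c(0.1, 0.2, 0.3, 0.4), function(p) {
    ds <- preprocess(sample_dataset(tissue_model("FTIR", p_rich = p),
                                    150, seed = 43))
    g <- summarize_groups(fit_pca(ds, 2))
    g$per_class$sd[g$per_class$class == "margin"]
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("the null model is class-exchangeable (AUC near 1/2)", {
  ds <- preprocess(sample_dataset(tissue_model("FTIR", null = TRUE),
                                  400, seed = 44))
  fit <- specmargin(ds, preprocess = FALSE, k = 2)
  # sign convention guarantees AUC >= ~0.5; exchangeability bounds it above
  expect_lt(fit$roc$auc, 0.55)
})

test_that("map-shaped sampling lays rich domains out as labeled pixels", {
  ds <- sample_dataset(tissue_model("FTIR"), 128, seed = 45,
                       map_shape = c(8, 8))
  expect_true(all(c("px_row", "px_col", "map_id") %in% names(ds$meta)))
  expect_true(all(ds$meta$px_row %in% 1:8))
  mar <- ds$meta[ds$meta$tissue == "margin", ]
  expect_near(mean(mar$rich_domain), 0.62, 0.15) # field thresholded at p_rich
  expect_error(sample_dataset(tissue_model("FTIR"), 10, map_shape = c(0, 4)),
               "config error")
})

test_that("single-target calibration reaches the requested statistic", {
  m <- tissue_model("FTIR")
  # a margin mean a bit away from the shipped default
  target <- c(margin_mean = 0.012)
  cal <- calibrate_model(m, target, tol = 0.1, n = 250, seed = 6, max_iter = 6)
  expect_lt(abs(attr(cal, "calibration")[["margin_mean"]] - 0.012) / 0.012, 0.1)
  # already-met targets leave the model untouched
  got <- attr(cal, "calibration")
  cal2 <- calibrate_model(cal, c(margin_mean = unname(got["margin_mean"])),
                          tol = 0.1, n = 250, seed = 6, max_iter = 6)
  expect_equal(cal2$margin, cal$margin)
  expect_error(calibrate_model(m, c(bogus = 1)), "targets")
})
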