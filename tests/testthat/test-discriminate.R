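test_that("PCA matches a brute-force eigendecomposition of the covariance", {
  set.seed(30)
  X <- matrix(rnorm(120), 10, 12)
  ds <- spectral_dataset(seq(1000, 1044, 4), X, "FTIR")
  p <- fit_pca(ds, 5)
  ev <- eigen(cov(X), symmetric = TRUE)
  Xc <- sweep(X, 2, colMeans(X))
  for (j in 1:5) {
    expect_near(abs(p$loadings[j, ]), abs(ev$vectors[, j]), 1e-8)
    expect_near(abs(p$scores[, j]), abs(Xc %*% ev$vectors[, j]), 1e-8)
  }
  expect_near(p$explained_var[1:5], (ev$values / sum(ev$values))[1:5], 1e-10)
  # structural invariants
  expect_near(tcrossprod(p$loadings), diag(5), 1e-8)
  expect_near(colMeans(p$scores), 0, 1e-8)
  expect_true(all(diff(p$explained_var) <= 1e-12))
})

test_that("PCA degeneracy, single-mode geometry and sign convention", {
  x <- seq(1000, 1199, length.out = 50)
  same <- spectral_dataset(x, matrix(1, 5, 50), "FTIR")
  expect_error(fit_pca(same, 2), "degeneracy")
  # one known variation direction: PC1 collinear, explains > 99%
  set.seed(31)
  dir <- dnorm(x, 1050, 12) - dnorm(x, 1150, 12)
  X <- outer(rnorm(30), dir) + rnorm(30 * 50, 0, 1e-6)
  p <- fit_pca(spectral_dataset(x, X, "FTIR"), 2)
  cosang <- sum(p$loadings[1, ] * dir) / sqrt(sum(dir^2))
  expect_gt(abs(cosang), 0.999)
  expect_gt(p$explained_var[1], 0.99)
  # margin-positive orientation
  ds <- toy_dataset(8, seed = 32)
  p <- fit_pca(ds, 2)
  lab <- tissue_labels(ds)
  expect_gte(mean(p$scores[lab == "margin", 1]),
             mean(p$scores[lab == "tumor", 1]))
})

test_that("k = min(n-1, p) reconstruction reproduces the data", {
  set.seed(33)
  X <- matrix(rnorm(15 * 40), 15, 40)
  ds <- spectral_dataset(seq_len(40) + 900, X, "FTIR")
  p <- fit_pca(ds, 14)
  recon <- sweep(p$scores %*% p$loadings, 2, p$mean_spectrum, `+`)
  expect_lt(norm(X - recon, "F") / norm(sweep(X, 2, colMeans(X)), "F"), 1e-6)
})

test_that("group summaries report per-class PC1 spread", {
  fake <- structure(list(scores = cbind(c(-1, -1, 1, 1)),
                         loadings = matrix(1, 1, 1), explained_var = 1,
                         labels = c("tumor", "tumor", "margin", "margin"),
                         k = 1L), class = "spectral_pca")
  g <- summarize_groups(fake)
  expect_equal(g$per_class$mean, c(-1, 1))
  expect_false(g$sd_ratio_defined)
  fake$scores <- cbind(c(0, 2, 0, 10))
  g <- summarize_groups(fake)
  expect_equal(g$per_class$sd, c(sqrt(2), 5 * sqrt(2)))
  expect_equal(g$sd_ratio, 5)
  fake$labels <- c("tumor", "margin", "margin", "margin")
  expect_error(summarize_groups(fake), "size error")
})

test_that("AUC equals the exhaustive pair-count statistic", {
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.35, 0.9)
  lab <- c("tumor", "tumor", "tumor", "margin", "margin", "margin")
  r <- roc_auc(sc, lab)
  expect_equal(r$auc, auc_oracle(sc, lab)) # includes a tie
  expect_equal(roc_auc(c(1, 2, 3, 4), c("tumor", "tumor", "margin", "margin"))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 1, 2), c("tumor", "tumor", "margin", "margin"))$auc, 0.5)
  set.seed(34)
  sc <- rnorm(40); lab2 <- sample(c("tumor", "margin"), 40, TRUE)
  expect_equal(roc_auc(sc, lab2)$auc, auc_oracle(sc, lab2))
  expect_error(roc_auc(sc, rep("margin", 40)), "label error")
  # curve is a valid monotone sweep
  r <- roc_auc(sc, lab2)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(35)
  sc <- rnorm(60); lab <- sample(c("tumor", "margin"), 60, TRUE)
  a <- roc_auc(sc, lab)$auc
  expect_equal(roc_auc(exp(2 * sc) + 5, lab)$auc, a)
  flip <- ifelse(lab == "tumor", "margin", "tumor")
  expect_equal(roc_auc(sc, flip)$auc, 1 - a)
})

test_that("our AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(36)
  sc <- rnorm(100); lab <- sample(c("tumor", "margin"), 100, TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                        levels = c("tumor", "margin"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, lab)$auc, ref)
})

test_that("loading features are extracted, signed and annotated", {
  x <- seq(900, 3800, by = 4)
  g <- function(c0, w) exp(-((x - c0) / w)^2)
  mk_pca <- function(v) structure(list(loadings = matrix(v / sqrt(sum(v^2)), 1),
                                       scores = matrix(0, 2, 1),
                                       explained_var = 1, wavenumbers = x,
                                       labels = NULL, k = 1L),
                                  class = "spectral_pca")
  f <- extract_loading_features(mk_pca(g(1746, 15)), modality = "FTIR")
  expect_equal(nrow(f), 1L)
  expect_lte(abs(f$wavenumber - 1746), 4)
  expect_equal(f$sign, "positive")
  expect_equal(f$label, "ester C=O (lipid)")
  f <- extract_loading_features(mk_pca(g(1300, 20) - g(2800, 20)), modality = "FTIR")
  expect_setequal(f$sign, c("positive", "negative"))
  expect_near(diff(f$magnitude), 0, 1e-9)
  expect_equal(nrow(extract_loading_features(mk_pca(rep(1, 726) + 1e-9 * x),
                                             min_prominence = 0.5)), 0L)
})
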