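# Independent brute-force oracles used to validate the numeric operators.

# per-point local least-squares polynomial refit (Savitzky-Golay oracle),
# terminal-window evaluation at the edges
sg_oracle <- function(y, n, p) {
  N <- length(y); h <- (n - 1) / 2
  out <- numeric(N)
  for (i in seq_len(N)) {
    c0 <- min(max(i, h + 1), N - h)
    idx <- (c0 - h):(c0 + h)
    fit <- lm.fit(outer(idx - c0, 0:p, "^"), y[idx])
    out[i] <- sum(fit$coefficients * (i - c0)^(0:p))
  }
  out
}

# O(n^2) lower-hull baseline: for every axis point, the highest chord
# between two data points that lies weakly below all data points
rubberband_oracle <- function(x, y) {
  n <- length(x)
  base <- rep(-Inf, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sl <- (y[j] - y[i]) / (x[j] - x[i])
    line <- y[i] + sl * (x - x[i])
    if (all(line <= y + 1e-9)) base <- pmax(base, line)
  }
  pmin(base, y)
}

# exhaustive pair-counting AUC (margin positive)
auc_oracle <- function(scores, labels) {
  sp <- scores[labels == "margin"]; sn <- scores[labels == "tumor"]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# trapezoid sum written independently of pracma
trapz_oracle <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# tiny labeled dataset of two Gaussian-band spectra classes on a short axis
toy_dataset <- function(n_per_class = 6, npts = 120, seed = 42,
                        modality = "FTIR", sep = 1) {
  set.seed(seed)
  x <- seq(1000, 1000 + 4 * (npts - 1), by = 4)
  mk <- function(a1, a2) a1 * dnorm(x, 1100, 25) + a2 * dnorm(x, 1300, 30) +
    rnorm(npts, 0, 1e-4)
  X <- rbind(
    t(replicate(n_per_class, mk(1, 1 + sep * 0.5 + rnorm(1, 0, 0.05)))),
    t(replicate(n_per_class, mk(1, 1 - sep * 0.5 + rnorm(1, 0, 0.05)))))
  spectral_dataset(x, X, modality,
                   data.frame(tissue = rep(c("margin", "tumor"),
                                           each = n_per_class)))
}

expect_near <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max|diff| = %.3g (tol %.3g)",
                              max(abs(object - expected)), tol))
}
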