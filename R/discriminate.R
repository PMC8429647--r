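#' Principal component analysis of a pooled spectral dataset
#'
#' Mean-centered (unscaled) PCA of the spectrum matrix via
#' [stats::prcomp()]. Eigenvector sign ambiguity is resolved
#' deterministically: when tissue labels are present, PC1 is oriented so
#' that the mean margin score is at least the mean tumor score; every other
#' component (and PC1 in unlabeled data) is oriented so its
#' largest-magnitude loading element is positive.
#'
#' @param ds a preprocessed [spectral_dataset()] with `n_spectra > k`.
#' @param k number of components to retain (default 10).
#' @return an object of class `spectral_pca`: `scores` (n x k), `loadings`
#'   (k x p, unit-norm orthonormal rows), `explained_var` (fractions of
#'   total variance, non-increasing), `mean_spectrum`, `wavenumbers`,
#'   `labels` (or `NULL`), `k`.
#' @export
fit_pca <- function(ds, k = 10L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- n_spectra(ds)
  if (!(n > k && k >= 1L)) stop("need n_spectra > k >= 1")
  X <- ds$intensities
  tot_var <- sum(apply(X, 2L, stats::var))
  if (!is.finite(tot_var) || tot_var <= 1e-30)
    stop("degeneracy error: dataset has zero total variance")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pr$rotation))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- t(pr$rotation[, seq_len(k), drop = FALSE])
  labels <- tissue_labels(ds)
  for (j in seq_len(k)) {
    flip <- FALSE
    if (j == 1L && !is.null(labels) && all(c("tumor", "margin") %in% labels)) {
      flip <- mean(scores[labels == "margin", 1L]) < mean(scores[labels == "tumor", 1L])
    } else {
      flip <- loadings[j, which.max(abs(loadings[j, ]))] < 0
    }
    if (flip) { scores[, j] <- -scores[, j]; loadings[j, ] <- -loadings[j, ] }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_var = pr$sdev^2 / sum(pr$sdev^2),
                 mean_spectrum = pr$center,
                 wavenumbers = ds$wavenumbers,
                 labels = labels, k = k),
            class = "spectral_pca")
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat(sprintf("<spectral_pca> %d spectra, k=%d; explained variance: %s\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.1f%%", 100 * x$explained_var[seq_len(min(3, x$k))]),
                    collapse = ", ")))
  invisible(x)
}

#' Per-class PC1 score summary
#'
#' Mean and sample standard deviation (n - 1) of the PC1 score for the
#' tumor and margin classes, and the ratio SD(margin) / SD(tumor) — a
#' direct readout of margin heterogeneity relative to the tumor.
#'
#' @param pca a [fit_pca()] result.
#' @param labels class labels; defaults to the labels stored in `pca`.
#' @return an object of class `group_summary` with a per-class data frame
#'   and `sd_ratio` (`NA` with an `undefined` flag when SD(tumor) is 0).
#' @export
summarize_groups <- function(pca, labels = pca$labels) {
  stopifnot(inherits(pca, "spectral_pca"))
  labels <- as.character(labels)
  if (!all(c("tumor", "margin") %in% labels))
    stop("both classes (tumor, margin) must be present")
  s <- pca$scores[, 1L]
  per <- do.call(rbind, lapply(c("tumor", "margin"), function(cl) {
    v <- s[labels == cl]
    if (length(v) < 2L) stop("size error: class ", cl, " has fewer than 2 spectra")
    data.frame(class = cl, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  sd_t <- per$sd[per$class == "tumor"]
  sd_m <- per$sd[per$class == "margin"]
  structure(list(per_class = per,
                 sd_ratio = if (sd_t > 0) sd_m / sd_t else NA_real_,
                 sd_ratio_defined = sd_t > 0),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  print(x$per_class, row.names = FALSE)
  cat(sprintf("SD(margin)/SD(tumor) = %s\n",
              if (x$sd_ratio_defined) sprintf("%.2f", x$sd_ratio) else "undefined"))
  invisible(x)
}

#' ROC curve and AUC of a score-threshold classifier
#'
#' Sweeps a decision threshold over the scores (margin = positive class,
#' predicted positive when `score > threshold`) and computes the AUC as the
#' Mann-Whitney pair statistic `P(score_margin > score_tumor) + 0.5 *
#' P(tie)`, i.e. via midranks — no numeric integration of the curve. The
#' orientation is fixed by the PC1 sign convention; `max(AUC, 1 - AUC)` is
#' deliberately not taken.
#'
#' @param scores numeric vector (e.g. PC1 scores).
#' @param labels class labels containing both `"tumor"` and `"margin"`.
#' @return an object of class `roc_result`: `thresholds`, `tpr`, `fpr`
#'   (monotone along the sweep), `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- labels == "margin"; neg <- labels == "tumor"
  if (!any(pos) || !any(neg))
    stop("label error: both classes (tumor, margin) are required")
  n_pos <- sum(pos); n_neg <- sum(neg)
  r <- rank(scores[pos | neg]) # midranks handle ties as half-wins
  auc <- (sum(r[pos[pos | neg]]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[pos] > t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores[neg] > t), numeric(1))
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc> AUC = %.4f (margin positive, %d thresholds)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' Built-in vibrational band assignment table
#'
#' Reference positions of the lipid, protein (Amide I/II/III and side
#' chain), carbohydrate and nucleic-acid bands used to annotate loading
#' features, per modality.
#'
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @return data frame with `wavenumber`, `assignment`, `label`.
#' @export
band_assignments <- function(modality = c("FTIR", "RAMAN")) {
  modality <- match.arg(modality)
  if (modality == "FTIR") {
    data.frame(
      wavenumber = c(1047, 1085, 1165, 1240, 1304, 1339, 1455, 1466, 1547,
                     1631, 1656, 1669, 1746, 2854, 2874, 2924, 2960),
      assignment = c("carbohydrate", "nucleic_acid", "lipid", "protein",
                     "protein", "protein", "protein", "lipid", "protein",
                     "protein", "protein", "protein", "lipid", "lipid",
                     "lipid", "lipid", "protein"),
      label = c("C-O stretch (carbohydrates)", "PO2- stretch (nucleic acids)",
                "ester C-O (lipid)", "Amide III", "Amide III", "CH deformation (protein)",
                "CH2/CH3 deformation (protein)", "CH2 scissoring (lipid)", "Amide II",
                "Amide I (beta-sheet)", "Amide I (random coil)", "Amide I (beta-turn/sheet)",
                "ester C=O (lipid)", "CH2 symmetric stretch (lipid)",
                "CH3 symmetric stretch (lipid)", "CH2 asymmetric stretch (lipid)",
                "CH3 asymmetric stretch (protein)"))
  } else {
    data.frame(
      wavenumber = c(621, 643, 744, 792, 855, 939, 973, 1003, 1032, 1047,
                     1066, 1082, 1129, 1130, 1209, 1241, 1302, 1339, 1366,
                     1438, 1578, 1621, 1655, 1676, 1748, 2853, 2889, 2949, 2978),
      assignment = c("protein", "protein", "nucleic_acid", "nucleic_acid",
                     "protein", "protein", "lipid", "protein", "protein",
                     "carbohydrate", "mixed", "lipid", "protein", "mixed",
                     "protein", "protein", "lipid", "protein", "lipid",
                     "lipid", "nucleic_acid", "mixed", "lipid", "protein",
                     "lipid", "lipid", "lipid", "protein", "protein"),
      label = c("phenylalanine ring", "tyrosine ring", "thymine/DNA", "DNA backbone",
                "tyrosine/proline", "C-C skeletal (protein)", "=CH bend (lipid)",
                "phenylalanine ring breathing", "phenylalanine", "C-O stretch (carbohydrates)",
                "proteins and lipids", "C-C gauche (lipid chain)", "C-N stretch (protein)",
                "proteins and lipids", "tyrosine/phenylalanine", "Amide III",
                "CH2 twist (lipid)", "CH deformation (protein)", "CH3 bend (lipid)",
                "CH2 scissoring (lipid)", "guanine/adenine", "C=C stretch",
                "C=C stretch (unsaturated lipid)", "Amide I", "ester C=O (lipid)",
                "CH2 symmetric stretch (lipid)", "CH2 asymmetric stretch (lipid)",
                "CH3 stretch (protein)", "CH3 asymmetric stretch (protein)"))
  }
}

peak_prominence <- function(v, peaks) {
  # topographic prominence of local maxima of v
  vapply(peaks, function(i) {
    left <- v[seq_len(i)]; right <- v[seq(i, length(v))]
    higher_l <- which(left > v[i]); higher_r <- which(right > v[i])
    base_l <- if (length(higher_l)) min(left[seq(max(higher_l), i)]) else min(left)
    base_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
    v[i] - max(base_l, base_r)
  }, numeric(1))
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Extract annotated features from a PCA loading vector
#'
#' Finds the local extrema of a loading vector with topographic prominence
#' at least `min_prominence`, splits them by sign, and annotates each with
#' the nearest entry of the built-in band table (within +/- 8 1/cm, else
#' `"unassigned"`).
#'
#' @param pca a [fit_pca()] result.
#' @param component which component's loading to analyze (default 1).
#' @param min_prominence minimum prominence, on the unit-norm loading
#'   scale; the default keeps features at least 15% as prominent as the
#'   largest one.
#' @param modality modality for the assignment table.
#' @return data frame (possibly empty) with `wavenumber`, `sign`,
#'   `magnitude`, `prominence`, `assignment`, `label`, ordered by
#'   decreasing prominence.
#' @export
extract_loading_features <- function(pca, component = 1L, min_prominence = NULL,
                                     modality = c("FTIR", "RAMAN")) {
  stopifnot(inherits(pca, "spectral_pca"))
  modality <- match.arg(modality)
  if (component > pca$k) stop("component exceeds the number of fitted components")
  v <- pca$loadings[component, ]
  x <- pca$wavenumbers
  tab <- band_assignments(modality)
  one_sign <- function(w, sgn) {
    pk <- local_maxima(w)
    if (!length(pk)) return(NULL)
    prom <- peak_prominence(w, pk)
    data.frame(wavenumber = x[pk], sign = sgn, magnitude = abs(v[pk]),
               prominence = prom)
  }
  feats <- rbind(one_sign(v, "positive"), one_sign(-v, "negative"))
  if (is.null(feats) || !nrow(feats))
    return(data.frame(wavenumber = numeric(0), sign = character(0),
                      magnitude = numeric(0), prominence = numeric(0),
                      assignment = character(0), label = character(0)))
  if (is.null(min_prominence)) min_prominence <- 0.15 * max(feats$prominence)
  feats <- feats[feats$prominence >= min_prominence, , drop = FALSE]
  idx <- vapply(feats$wavenumber, function(w) {
    j <- which.min(abs(tab$wavenumber - w))
    if (abs(tab$wavenumber[j] - w) <= 8) j else NA_integer_
  }, integer(1))
  feats$assignment <- ifelse(is.na(idx), "unassigned", tab$assignment[idx])
  feats$label <- ifelse(is.na(idx), "unassigned", tab$label[idx])
  feats[order(-feats$prominence), ]
}
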