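#' Fit the PC1-score tumor-margin discrimination model
#'
#' The package's central fitting function. Given a labeled spectral
#' dataset it (optionally) runs the preprocessing chain, (optionally)
#' removes lipid-rich spectra by the ester-band rule, performs pooled
#' mean-centered PCA, and evaluates the PC1-score classifier: per-class
#' score summaries, the ROC curve with its Mann-Whitney AUC, annotated PC1
#' loading features, and the per-class ester-band integral distributions.
#'
#' @param ds a labeled [spectral_dataset()] (metadata column `tissue` with
#'   values `"tumor"`/`"margin"`).
#' @param preprocess `TRUE` (modality defaults), `FALSE` (data already
#'   preprocessed), or a [preprocess_config()].
#' @param lipid_filter `FALSE` (fit on the full dataset), `TRUE` (modality
#'   default [lipid_filter_config()]), or a config object.
#' @param k number of PCA components retained (default 10).
#' @return an object of class `specmargin` with components `pca`,
#'   `groups` (per-class PC1 summary), `roc`, `features` (PC1 loading
#'   features), `band_stats` (per-class ester-integral
#'   [distribution_stats()]), `filter` (retained fraction, per-class
#'   counts; `NULL` when unfiltered), `threshold` (Youden-optimal PC1
#'   cutoff used by [predict.specmargin()]), and bookkeeping fields.
#' @examples
#' \donttest{
#' ds <- sample_dataset(tissue_model("FTIR"), n_per_class = 120, seed = 1)
#' fit <- specmargin(ds)
#' fit
#' coef(fit)[1:5]
#' }
#' @export
specmargin <- function(ds, preprocess = TRUE, lipid_filter = FALSE, k = 10L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  cl <- match.call()
  if (is.null(tissue_labels(ds)))
    stop("dataset must carry tissue labels (meta column 'tissue')")
  prep_log <- NULL
  if (!isFALSE(preprocess)) {
    cfg <- if (isTRUE(preprocess)) preprocess_config(ds$modality) else preprocess
    ds <- preprocess(ds, cfg)
    prep_log <- attr(ds, "log")
  }
  fcfg <- lipid_filter_config(ds$modality)
  filt <- NULL
  ints_full <- band_integrals(ds, fcfg$band, fcfg$local_baseline)
  lab_full <- tissue_labels(ds)
  if (!isFALSE(lipid_filter)) {
    if (!isTRUE(lipid_filter)) fcfg <- lipid_filter
    fl <- filter_lipid_rich(ds, fcfg)
    filt <- fl[c("retained_fraction", "per_class", "threshold")]
    filt$removed_mask <- fl$removed_mask
    ds <- fl$dataset
  }
  pca <- fit_pca(ds, min(k, n_spectra(ds) - 1L))
  groups <- summarize_groups(pca)
  roc <- roc_auc(pca$scores[, 1L], pca$labels)
  feats <- extract_loading_features(pca, 1L, modality = ds$modality)
  ints <- band_integrals(ds, fcfg$band, fcfg$local_baseline)
  lab <- tissue_labels(ds)
  band_stats <- lapply(split(ints, lab), distribution_stats)
  # Youden-optimal PC1 cutoff for predict()
  j <- which.max(roc$tpr - roc$fpr)
  structure(list(call = cl, modality = ds$modality, pca = pca, data = ds,
                 groups = groups, roc = roc, features = feats,
                 band_stats = band_stats, band = fcfg$band,
                 filter = filt, threshold = roc$thresholds[j],
                 n = n_spectra(ds), labels = lab,
                 integrals = ints, integrals_prefilter = ints_full,
                 labels_prefilter = lab_full,
                 preprocess_log = prep_log),
            class = "specmargin")
}

#' @export
print.specmargin <- function(x, ...) {
  cat("PC1-score tumor-margin discrimination (", x$modality, ")\n", sep = "")
  tab <- table(x$labels)
  cat(sprintf("  %d spectra (%s)%s\n", x$n,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              if (!is.null(x$filter))
                sprintf("; lipid filter retained %.1f%%",
                        100 * x$filter$retained_fraction) else " (unfiltered)"))
  cat(sprintf("  PC1 explains %.1f%% of variance; AUC = %.3f\n",
              100 * x$pca$explained_var[1], x$roc$auc))
  g <- x$groups
  cat(sprintf("  PC1 score: tumor %.4g +/- %.4g, margin %.4g +/- %.4g (SD ratio %s)\n",
              g$per_class$mean[1], g$per_class$sd[1],
              g$per_class$mean[2], g$per_class$sd[2],
              if (g$sd_ratio_defined) sprintf("%.2f", g$sd_ratio) else "undefined"))
  invisible(x)
}

#' @export
summary.specmargin <- function(object, ...) {
  structure(object, class = c("summary.specmargin", "specmargin"))
}

#' @export
print.summary.specmargin <- function(x, ...) {
  print.specmargin(x)
  cat("\nPC1 loading features:\n")
  print(x$features, row.names = FALSE, digits = 4)
  cat("\nEster-band (", x$band$center, " 1/cm) integral by class:\n", sep = "")
  for (nm in names(x$band_stats)) {
    cat("  ", nm, ": ", sep = ""); print(x$band_stats[[nm]])
  }
  invisible(x)
}

#' PC1 loading coefficients of a fitted model
#' @param object a [specmargin()] fit.
#' @param component which component (default 1).
#' @param ... unused.
#' @return named numeric vector (names = wavenumbers).
#' @export
coef.specmargin <- function(object, component = 1L, ...) {
  v <- object$pca$loadings[component, ]
  names(v) <- format(object$pca$wavenumbers, trim = TRUE)
  v
}

#' Classify new spectra with a fitted model
#'
#' Projects preprocessed spectra onto the fitted PC1 axis and classifies
#' with the stored Youden-optimal score cutoff (margin when
#' `score > threshold`).
#'
#' @param object a [specmargin()] fit.
#' @param newdata a preprocessed [spectral_dataset()] on the same axis.
#' @param ... unused.
#' @return data frame with `score` and predicted `class`.
#' @export
predict.specmargin <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectral_dataset"))
  if (length(newdata$wavenumbers) != length(object$pca$wavenumbers) ||
      max(abs(newdata$wavenumbers - object$pca$wavenumbers)) > 1e-9)
    stop("newdata is not on the fitted wavenumber axis")
  Xc <- sweep(newdata$intensities, 2L, object$pca$mean_spectrum)
  s <- drop(Xc %*% object$pca$loadings[1L, ])
  data.frame(score = s,
             class = ifelse(s > object$threshold, "margin", "tumor"))
}

#' Reconstruction residuals of the retained-component PCA
#' @param object a [specmargin()] fit.
#' @param ... unused.
#' @return matrix of residuals: the fitted (preprocessed, filtered) data
#'   minus its mean-plus-k-component reconstruction.
#' @export
residuals.specmargin <- function(object, ...) {
  p <- object$pca
  recon <- sweep(p$scores %*% p$loadings, 2L, p$mean_spectrum, `+`)
  object$data$intensities - recon
}

#' Diagnostic plots for a fitted discrimination model
#'
#' @param x a [specmargin()] fit.
#' @param type `"loading"` (PC1 loading with annotated features), `"roc"`,
#'   `"scores"` (per-class mean +/- SD bars), or `"histogram"` (per-class
#'   ester-integral histograms).
#' @param ... passed to the underlying base-graphics call.
#' @return invisibly, `x`.
#' @export
plot.specmargin <- function(x, type = c("loading", "roc", "scores", "histogram"),
                            ...) {
  type <- match.arg(type)
  if (type == "loading") {
    graphics::plot(x$pca$wavenumbers, x$pca$loadings[1L, ], type = "l",
                   xlab = "wavenumber (1/cm)", ylab = "PC1 loading", ...)
    graphics::abline(h = 0, lty = 3)
    f <- x$features
    if (nrow(f)) {
      up <- f$sign == "positive"
      graphics::points(f$wavenumber[up], f$magnitude[up], col = 2, pch = 16)
      graphics::points(f$wavenumber[!up], -f$magnitude[!up], col = 4, pch = 16)
    }
  } else if (type == "roc") {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                   xlab = "false positive rate", ylab = "true positive rate",
                   main = sprintf("AUC = %.3f", x$roc$auc), ...)
    graphics::abline(0, 1, lty = 3)
  } else if (type == "scores") {
    g <- x$groups$per_class
    bp <- graphics::barplot(g$mean, names.arg = g$class, ylab = "mean PC1 score",
                            ylim = range(c(g$mean - g$sd, g$mean + g$sd)) * 1.2, ...)
    graphics::arrows(bp, g$mean - g$sd, bp, g$mean + g$sd,
                     angle = 90, code = 3, length = 0.08)
  } else {
    old <- graphics::par(mfrow = c(1, length(x$band_stats)))
    on.exit(graphics::par(old))
    for (nm in names(x$band_stats)) {
      h <- x$band_stats[[nm]]$histogram
      graphics::plot(utils::head(h$breaks, -1), h$counts, type = "h",
                     xlab = sprintf("%g 1/cm band integral", x$band$center),
                     ylab = "count", main = nm, ...)
    }
  }
  invisible(x)
}
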