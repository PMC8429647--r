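#' Locally baselined band integral
#'
#' Trapezoidal integral of a spectrum over a closed band window, minus (when
#' `local_baseline = TRUE`) the trapezoid under the straight line joining
#' the window's endpoint intensities. The local baseline isolates the band
#' from broad underlying features (e.g. the Amide I wing under the ester
#' carbonyl); the result can be negative for noise-only windows.
#'
#' @param x wavenumber axis (ascending).
#' @param y intensity vector (normally a preprocessed, area-normalized
#'   spectrum).
#' @param band a [band_definition()]; the window must lie within the axis.
#' @param local_baseline subtract the endpoint chord (default `TRUE`).
#' @return the integral in intensity times 1/cm units.
#' @examples
#' x <- seq(1700, 1800, by = 2)
#' tri <- pmax(0, 1 - abs(x - 1746) / 20)  # height 1, base 40
#' band <- band_definition("ester C=O", 1746, 1710, 1790, "lipid")
#' band_integral(x, tri, band)             # ~ 1 * 40 / 2 = 20
#' @export
band_integral <- function(x, y, band, local_baseline = TRUE) {
  stopifnot(inherits(band, "band_definition"))
  lo <- band$window[1]; hi <- band$window[2]
  if (lo < min(x) || hi > max(x))
    stop("range error: band window [", lo, ", ", hi, "] outside the axis")
  k <- which(x >= lo & x <= hi)
  if (length(k) < 2L) stop("range error: fewer than 2 axis points in the band window")
  xi <- x[k]; yi <- y[k]
  a <- pracma::trapz(xi, yi)
  if (local_baseline)
    a <- a - (yi[1L] + yi[length(yi)]) / 2 * (xi[length(xi)] - xi[1L])
  a
}

band_integrals <- function(ds, band, local_baseline = TRUE) {
  apply(ds$intensities, 1L, function(y)
    band_integral(ds$wavenumbers, y, band, local_baseline))
}

#' Summary statistics of a band-integral distribution
#'
#' @param values numeric vector of per-spectrum band integrals, `n >= 2`.
#' @param bins number of equal-width histogram bins over `[min, max]`
#'   (default 50).
#' @return an object of class `band_integral_stats`: `n`, `mean`, `median`,
#'   `min`, `max`, `mode_center` (center of the most populated bin),
#'   `skewness` (adjusted Fisher-Pearson sample skewness, via
#'   [e1071::skewness()] type 2), and `histogram` (`breaks`, `counts`).
#' @export
distribution_stats <- function(values, bins = 50L) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("size error: need at least 2 values")
  breaks <- seq(min(values), max(values), length.out = bins + 1L)
  if (breaks[1L] == breaks[length(breaks)])
    breaks <- breaks[1L] + seq(-0.5, 0.5, length.out = bins + 1L)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  structure(list(n = length(values),
                 mean = mean(values), median = stats::median(values),
                 min = min(values), max = max(values),
                 mode_center = h$mids[which.max(h$counts)],
                 skewness = e1071::skewness(values, type = 2),
                 histogram = list(breaks = h$breaks, counts = h$counts)),
            class = "band_integral_stats")
}

#' @export
print.band_integral_stats <- function(x, ...) {
  cat(sprintf("<band integral stats> n=%d mean=%.4g median=%.4g max=%.4g mode~%.4g skew=%.3g\n",
              x$n, x$mean, x$median, x$max, x$mode_center, x$skewness))
  invisible(x)
}

#' Lipid filter configuration
#'
#' The filter scores every spectrum by the locally baselined integral of the
#' ester carbonyl band (center 1746 1/cm, window 1710-1790) and removes
#' spectra whose integral exceeds the threshold. The FT-IR default
#' threshold, 0.014 in post-area-normalization units, is the cutoff at
#' which the lipid-rich shoulder of the margin histogram is removed; the
#' Raman default (0.006) comes from the calibration of the synthetic
#' generator, which places it between the two modes of the margin
#' distribution.
#'
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param band a [band_definition()]; default ester C=O at 1746 (FT-IR) /
#'   1748 (Raman), window 1710-1790.
#' @param threshold removal threshold (> 0) on the band integral.
#' @param local_baseline use a local linear baseline inside the window.
#' @return an object of class `lipid_filter_config`.
#' @export
lipid_filter_config <- function(modality = c("FTIR", "RAMAN"),
                                band = NULL, threshold = NULL,
                                local_baseline = TRUE) {
  modality <- match.arg(modality)
  if (is.null(band))
    band <- band_definition("ester C=O", if (modality == "FTIR") 1746 else 1748,
                            1710, 1790, "lipid")
  if (is.null(threshold)) threshold <- if (modality == "FTIR") 0.014 else 0.006
  if (threshold < 0)
    stop("config error: threshold must be non-negative")
  structure(list(modality = modality, band = band, threshold = threshold,
                 local_baseline = local_baseline),
            class = "lipid_filter_config")
}

#' Remove lipid-rich spectra from a dataset
#'
#' Spectra whose ester-band integral exceeds the configured threshold are
#' removed; the analysis of the reduced dataset is then driven by
#' protein/carbohydrate/nucleic-acid differences rather than lipid-domain
#' heterogeneity.
#'
#' @param ds a preprocessed [spectral_dataset()].
#' @param cfg a [lipid_filter_config()].
#' @return list with `dataset` (the reduced dataset), `retained_fraction`
#'   (retained / total, over the whole dataset), `removed_mask` (logical,
#'   `TRUE` where removed), `integrals` (per-spectrum values),
#'   `per_class` (data frame of total/retained/removed counts by class) and
#'   `threshold`. A class losing all its spectra raises a warning, not an
#'   error.
#' @export
filter_lipid_rich <- function(ds, cfg = lipid_filter_config(ds$modality)) {
  stopifnot(inherits(ds, "spectral_dataset"), inherits(cfg, "lipid_filter_config"))
  v <- band_integrals(ds, cfg$band, cfg$local_baseline)
  removed <- v > cfg$threshold
  lab <- tissue_labels(ds)
  per_class <- NULL
  if (!is.null(lab)) {
    per_class <- as.data.frame(t(vapply(unique(lab), function(cl) {
      c(total = sum(lab == cl), retained = sum(lab == cl & !removed),
        removed = sum(lab == cl & removed))
    }, numeric(3))))
    per_class$class <- rownames(per_class)
    empty <- per_class$class[per_class$retained == 0]
    if (length(empty))
      warning("lipid filter removed every spectrum of class: ",
              paste(empty, collapse = ", "))
  } else if (!any(!removed)) {
    warning("lipid filter removed every spectrum")
  }
  list(dataset = ds[!removed],
       retained_fraction = mean(!removed),
       removed_mask = removed,
       integrals = v,
       per_class = per_class,
       threshold = cfg$threshold)
}
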