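#' Labeled collection of vibrational spectra on a shared wavenumber axis
#'
#' `spectral_dataset()` is the central container of the package: a set of
#' spectra (one per row of `intensities`) sharing a single strictly monotone
#' wavenumber axis and one modality (`"FTIR"` or `"RAMAN"`), together with
#' per-spectrum metadata (tissue label, patient, map, pixel coordinates).
#' Axes supplied in descending order are reversed (with the intensity
#' columns) so that the internal convention is always ascending wavenumber.
#'
#' @param wavenumbers numeric vector of wavenumbers in 1/cm, strictly
#'   monotone, all positive, length >= 2.
#' @param intensities numeric matrix, one spectrum per row, `length(wavenumbers)`
#'   columns. A single spectrum may be given as a vector.
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param meta optional `data.frame` with one row per spectrum. The column
#'   `tissue` (values `"tumor"`/`"margin"`) is used as the class label
#'   throughout the package; `patient_id`, `map_id`, `px_row`, `px_col` are
#'   conventional.
#' @return An object of class `spectral_dataset`: a list with elements
#'   `wavenumbers`, `intensities`, `modality`, `meta`, `resolution` (median
#'   axis spacing).
#' @examples
#' wn <- seq(900, 3800, by = 4)
#' ds <- spectral_dataset(wn, matrix(rnorm(3 * length(wn)), 3), "FTIR")
#' ds
#' @export
spectral_dataset <- function(wavenumbers, intensities, modality = c("FTIR", "RAMAN"),
                             meta = NULL) {
  modality <- match.arg(modality)
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2L)
    stop("wavenumber axis must have at least 2 points")
  if (any(!is.finite(wavenumbers)) || any(wavenumbers <= 0))
    stop("wavenumbers must be finite and positive")
  d <- diff(wavenumbers)
  if (all(d < 0)) { # descending input: flip to the ascending convention
    wavenumbers <- rev(wavenumbers)
    if (!is.null(dim(intensities))) intensities <- intensities[, rev(seq_along(wavenumbers)), drop = FALSE]
    else intensities <- rev(intensities)
    d <- diff(wavenumbers)
  }
  if (any(d <= 0))
    stop("wavenumber axis must be strictly monotone")
  if (is.null(dim(intensities)))
    intensities <- matrix(intensities, nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(wavenumbers))
    stop("intensities must have one column per wavenumber (got ",
         ncol(intensities), ", expected ", length(wavenumbers), ")")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  n <- nrow(intensities)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta)
  if (nrow(meta) != n)
    stop("meta must have one row per spectrum")
  structure(list(wavenumbers = wavenumbers,
                 intensities = intensities,
                 modality = modality,
                 meta = meta,
                 resolution = stats::median(d)),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d %s spectra, %d points (%.6g-%.6g 1/cm, ~%.3g 1/cm spacing)\n",
              n_spectra(x), x$modality, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers), x$resolution))
  lab <- tissue_labels(x)
  if (!is.null(lab)) {
    tab <- table(lab)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (ncol(x$meta)) cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a dataset
#' @param ds a `spectral_dataset`.
#' @return integer count.
#' @export
n_spectra <- function(ds) nrow(ds$intensities)

#' Tissue class labels of a dataset
#' @param ds a `spectral_dataset`.
#' @return character vector (`"tumor"`/`"margin"`), or `NULL` when the
#'   dataset carries no `tissue` metadata column.
#' @export
tissue_labels <- function(ds) {
  if (!"tissue" %in% names(ds$meta)) return(NULL)
  as.character(ds$meta$tissue)
}

#' Subset a spectral dataset by spectrum index
#' @param x a `spectral_dataset`.
#' @param i integer or logical index over spectra (rows).
#' @param ... unused.
#' @return a `spectral_dataset` with the selected spectra.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  spectral_dataset(x$wavenumbers, x$intensities[i, , drop = FALSE], x$modality,
                   x$meta[i, , drop = FALSE])
}

#' Concatenate spectral datasets
#'
#' All arguments must share an identical axis and modality; metadata columns
#' are merged by name (missing columns filled with `NA`).
#' @param ... `spectral_dataset` objects.
#' @return the combined `spectral_dataset`; per-class spectrum counts are
#'   the sums of the inputs' counts.
#' @export
c.spectral_dataset <- function(...) {
  parts <- list(...)
  ref <- parts[[1L]]
  for (p in parts[-1L]) {
    if (!identical(p$modality, ref$modality)) stop("cannot combine different modalities")
    if (length(p$wavenumbers) != length(ref$wavenumbers) ||
        max(abs(p$wavenumbers - ref$wavenumbers)) > 1e-9)
      stop("cannot combine datasets on different axes")
  }
  cols <- unique(unlist(lapply(parts, function(p) names(p$meta))))
  metas <- lapply(parts, function(p) {
    m <- p$meta
    for (cc in setdiff(cols, names(m))) m[[cc]] <- NA
    m[, cols, drop = FALSE]
  })
  spectral_dataset(ref$wavenumbers, do.call(rbind, lapply(parts, `[[`, "intensities")),
                   ref$modality, do.call(rbind, metas))
}

#' Crop a dataset to a closed wavenumber interval
#'
#' Retains exactly the axis points `p` with `lo <= p <= hi`.
#'
#' @param ds a `spectral_dataset`.
#' @param lo,hi interval bounds in 1/cm, `lo < hi`.
#' @return the cropped `spectral_dataset`.
#' @export
crop <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!(lo < hi)) stop("crop requires lo < hi")
  keep <- ds$wavenumbers >= lo & ds$wavenumbers <= hi
  if (sum(keep) < 2L) stop("crop range [", lo, ", ", hi, "] does not overlap the axis")
  spectral_dataset(ds$wavenumbers[keep], ds$intensities[, keep, drop = FALSE],
                   ds$modality, ds$meta)
}

#' Define a spectral band for integration or assignment
#'
#' @param name band name, e.g. `"ester C=O"`.
#' @param center band center in 1/cm.
#' @param lo,hi closed integration window in 1/cm with `lo < center < hi`.
#' @param assignment one of `"lipid"`, `"protein"`, `"carbohydrate"`,
#'   `"nucleic_acid"`, `"mixed"`.
#' @return an object of class `band_definition`.
#' @examples
#' band_definition("ester C=O", 1746, 1710, 1790, "lipid")
#' @export
band_definition <- function(name, center, lo, hi,
                            assignment = c("lipid", "protein", "carbohydrate",
                                           "nucleic_acid", "mixed")) {
  assignment <- match.arg(assignment)
  if (!(lo < center && center < hi))
    stop("band window must satisfy lo < center < hi")
  structure(list(name = name, center = center, window = c(lo, hi),
                 assignment = assignment),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: center %g 1/cm, window [%g, %g], %s\n",
              x$name, x$center, x$window[1], x$window[2], x$assignment))
  invisible(x)
}
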