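#' Preprocessing configuration
#'
#' Bundles the parameters of the spectral preprocessing chain. The defaults
#' follow common chemometric practice for tissue maps: Savitzky-Golay
#' smoothing with 13 points / 5th order for FT-IR and 7 points / 3rd order
#' for Raman, rubberband baseline correction, and area normalization.
#' Cosmic-ray despiking is enabled for Raman only.
#'
#' @param modality `"FTIR"` or `"RAMAN"`; sets all modality defaults.
#' @param sg_window odd Savitzky-Golay window length in points.
#' @param sg_order polynomial order, `< sg_window`.
#' @param snr_min spectra with estimated SNR below this are rejected
#'   (default 3). The SNR statistic is the peak-to-baseline amplitude of the
#'   strongest band of the smoothed spectrum divided by a robust noise
#'   estimate from a signal-free window.
#' @param noise_window signal-free window (1/cm) used for the noise
#'   estimate; defaults 1800-2600 (FT-IR) and 1800-2500 (Raman).
#' @param despike logical; remove cosmic-ray spikes (Raman only).
#' @param despike_z modified z-score threshold on first differences
#'   (default 8).
#' @param normalize `"area"` or `"none"`.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(modality = c("FTIR", "RAMAN"),
                              sg_window = NULL, sg_order = NULL,
                              snr_min = 3,
                              noise_window = NULL,
                              despike = NULL, despike_z = 8,
                              normalize = c("area", "none")) {
  modality <- match.arg(modality)
  normalize <- match.arg(normalize)
  if (is.null(sg_window)) sg_window <- if (modality == "FTIR") 13L else 7L
  if (is.null(sg_order))  sg_order  <- if (modality == "FTIR") 5L else 3L
  if (is.null(noise_window))
    noise_window <- if (modality == "FTIR") c(1800, 2600) else c(1800, 2500)
  if (is.null(despike)) despike <- modality == "RAMAN"
  if (sg_window %% 2 == 0) stop("config error: sg_window must be odd")
  if (sg_order >= sg_window) stop("config error: sg_order must be < sg_window")
  if (snr_min < 0) stop("config error: snr_min must be >= 0")
  structure(list(modality = modality, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order), snr_min = snr_min,
                 noise_window = noise_window, despike = despike,
                 despike_z = despike_z, normalize = normalize),
            class = "preprocess_config")
}

robust_noise <- function(y) {
  # robust white-noise SD from first differences; immune to smooth trends
  # and to a few spikes. Floor keeps noiseless spectra at a huge SNR.
  max(stats::mad(diff(y)) / sqrt(2), 1e-12)
}

#' Reject low signal-to-noise spectra
#'
#' The SNR of each spectrum is the peak-to-baseline amplitude of its
#' strongest band, computed on a Savitzky-Golay smoothed copy (so that
#' single noise excursions do not count as a band), divided by a robust
#' noise estimate (scaled MAD of first differences) taken inside a
#' signal-free window. Spectra with `SNR < snr_min` are removed.
#'
#' @param ds a [spectral_dataset()] with at least 2 spectra.
#' @param cfg a [preprocess_config()].
#' @return list with `dataset` (retained spectra), `mask` (logical, `TRUE`
#'   where rejected) and `snr` (the per-spectrum statistic).
#' @export
reject_low_snr <- function(ds, cfg = preprocess_config(ds$modality)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (n_spectra(ds) < 2L) stop("reject_low_snr needs >= 2 spectra")
  win <- ds$wavenumbers >= cfg$noise_window[1] & ds$wavenumbers <= cfg$noise_window[2]
  if (sum(win) < 8L)
    stop("config error: signal-free window [", cfg$noise_window[1], ", ",
         cfg$noise_window[2], "] outside the axis")
  snr <- unname(apply(ds$intensities, 1L, function(y) {
    ys <- savitzky_golay(y, cfg$sg_window, cfg$sg_order)
    amp <- max(ys) - stats::median(ys[win])
    amp / robust_noise(y[win])
  }))
  mask <- snr < cfg$snr_min
  list(dataset = ds[!mask], mask = mask, snr = snr)
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: every interior point is
#' replaced by the value, at the window center, of the degree-`order`
#' polynomial fitted over the surrounding `window` points. The first and
#' last half-windows are handled by evaluating the terminal window's fit at
#' the edge positions, so the axis is not shrunk. Backed by
#' [signal::sgolayfilt()].
#'
#' @param y numeric vector (a spectrum's intensities) or a matrix with one
#'   spectrum per row.
#' @param window odd window length in points, `<= length(y)`.
#' @param order polynomial order, `< window`.
#' @return smoothed vector or matrix of the same shape.
#' @export
savitzky_golay <- function(y, window, order) {
  if (window %% 2 == 0) stop("config error: window must be odd")
  if (order >= window) stop("config error: order must be < window")
  if (is.matrix(y)) {
    if (ncol(y) < window) stop("spectrum shorter than the smoothing window")
    return(t(apply(y, 1L, signal::sgolayfilt, p = order, n = window)))
  }
  if (length(y) < window) stop("spectrum shorter than the smoothing window")
  signal::sgolayfilt(y, p = order, n = window)
}

lower_hull_idx <- function(x, y) {
  # Andrew monotone-chain lower hull of (x, y), x strictly ascending
  n <- length(x)
  idx <- integer(0)
  for (i in seq_len(n)) {
    while (length(idx) >= 2L) {
      a <- idx[length(idx) - 1L]; b <- idx[length(idx)]
      # pop b unless (a, b, i) makes a strict counter-clockwise turn
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        idx <- idx[-length(idx)]
      else break
    }
    idx <- c(idx, i)
  }
  idx
}

#' Rubberband (lower convex hull) baseline correction
#'
#' The baseline is the lower convex hull of the points
#' (wavenumber, intensity), evaluated by linear interpolation between hull
#' vertices; the corrected spectrum is the input minus this baseline. The
#' hull is computed in the physical wavenumber coordinate, so the result is
#' invariant to non-uniform axis spacing. The corrected spectrum is
#' non-negative and exactly zero at every hull vertex, including both
#' endpoints.
#'
#' @param x wavenumber axis (ascending).
#' @param y intensity vector, `length(y) == length(x) >= 3`.
#' @return list with `baseline` and `corrected` vectors.
#' @export
rubberband_baseline <- function(x, y) {
  if (length(y) < 3L) stop("rubberband baseline needs at least 3 points")
  stopifnot(length(x) == length(y))
  h <- lower_hull_idx(x, y)
  baseline <- stats::approx(x[h], y[h], xout = x)$y
  corrected <- pmax(y - baseline, 0) # clamp float dust; y >= hull by construction
  list(baseline = baseline, corrected = corrected)
}

despike_one <- function(y, z_thresh = 8, max_width = 2L) {
  d <- diff(y)
  md <- stats::mad(d)
  if (md <= 0) return(list(y = y, n = 0L))
  z <- (d - stats::median(d)) / md
  # a spike at j produces |z| spikes at the jumps entering and leaving it;
  # candidate points are those adjacent to any excessive jump
  big <- abs(z) > z_thresh
  cand <- which(big | c(FALSE, big[-length(big)]))  # j and j+1 for jump j
  cand <- sort(unique(c(cand, cand + 1L)))
  cand <- cand[cand >= 1L & cand <= length(y)]
  if (!length(cand)) return(list(y = y, n = 0L))
  runs <- split(cand, cumsum(c(1L, diff(cand) > 1L)))
  out <- y; n_fix <- 0L
  noise <- md / sqrt(2) # robust point-noise SD implied by the diff series
  for (r in runs) {
    if (length(r) > max_width + 2L) next # wide feature: a genuine band, leave it
    lo <- max(min(r) - 1L, 1L); hi <- min(max(r) + 1L, length(y))
    ref <- stats::approx(c(lo, hi), y[c(lo, hi)], xout = r)$y
    # replace only points that protrude beyond BOTH flanking points: a band
    # edge is monotone (the point lies between its flanks) and stays intact
    marg <- z_thresh * noise / 2
    bad <- y[r] > pmax(y[lo], y[hi]) + marg | y[r] < pmin(y[lo], y[hi]) - marg
    if (any(bad)) {
      out[r[bad]] <- ref[bad]
      n_fix <- n_fix + sum(bad)
    }
  }
  list(y = out, n = n_fix)
}

#' Remove cosmic-ray spikes from Raman spectra
#'
#' Detects one- and two-channel spikes with a modified z-score of the
#' point-to-point difference series (threshold `z_thresh`, default 8) and
#' replaces only the offending points by linear interpolation of the
#' flanking intact points. Genuine bands (wide features) are left
#' untouched. Raman modality only.
#'
#' @param ds a `RAMAN` [spectral_dataset()].
#' @param z_thresh modified z-score threshold.
#' @return the despiked dataset; attribute `n_spikes` carries the total
#'   number of replaced points.
#' @export
remove_cosmic_rays <- function(ds, z_thresh = 8) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (ds$modality != "RAMAN")
    stop("modality error: cosmic-ray removal applies to RAMAN data only")
  total <- 0L
  X <- ds$intensities
  for (i in seq_len(nrow(X))) {
    r <- despike_one(X[i, ], z_thresh)
    X[i, ] <- r$y
    total <- total + r$n
  }
  out <- spectral_dataset(ds$wavenumbers, X, ds$modality, ds$meta)
  attr(out, "n_spikes") <- total
  out
}

#' Area-under-the-curve normalization
#'
#' Scales a spectrum so its trapezoidal integral over the wavenumber axis
#' equals 1 (in intensity times 1/cm units), removing gross intensity
#' differences between pixels (section thickness, laser power).
#'
#' @param x wavenumber axis.
#' @param y intensity vector.
#' @return the scaled vector, with `pracma::trapz(x, y) == 1` to 1e-10.
#' @export
area_normalize <- function(x, y) {
  a <- pracma::trapz(x, y)
  if (!is.finite(a) || pracma::trapz(x, abs(y)) <= 1e-12 || a <= 1e-12)
    stop("normalization error: spectrum area is zero or near zero")
  y / a
}

#' Run the full preprocessing chain on a dataset
#'
#' Fixed stage order: low-SNR rejection, cosmic-ray removal (Raman),
#' Savitzky-Golay smoothing, rubberband baseline correction, area
#' normalization. Stage bookkeeping (number rejected, spikes removed) is
#' attached as the `"log"` attribute and reported by the pipeline runners.
#'
#' @param ds a [spectral_dataset()].
#' @param cfg a [preprocess_config()]; defaults to the dataset's modality
#'   defaults.
#' @return the preprocessed `spectral_dataset`.
#' @export
preprocess <- function(ds, cfg = preprocess_config(ds$modality)) {
  stopifnot(inherits(ds, "spectral_dataset"))
  log <- list(n_input = n_spectra(ds), n_rejected = 0L, n_spikes = 0L)
  if (cfg$snr_min > 0 && n_spectra(ds) >= 2L) {
    r <- reject_low_snr(ds, cfg)
    log$n_rejected <- sum(r$mask)
    ds <- r$dataset
  }
  if (n_spectra(ds) == 0L) stop("preprocess: all spectra rejected")
  if (ds$modality == "RAMAN" && isTRUE(cfg$despike)) {
    ds <- remove_cosmic_rays(ds, cfg$despike_z)
    log$n_spikes <- attr(ds, "n_spikes")
  }
  X <- savitzky_golay(ds$intensities, cfg$sg_window, cfg$sg_order)
  x <- ds$wavenumbers
  for (i in seq_len(nrow(X))) {
    yc <- rubberband_baseline(x, X[i, ])$corrected
    X[i, ] <- if (cfg$normalize == "area") area_normalize(x, yc) else yc
  }
  out <- spectral_dataset(x, X, ds$modality, ds$meta)
  attr(out, "log") <- log
  out
}
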