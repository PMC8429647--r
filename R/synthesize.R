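#' Default wavenumber axis per modality
#'
#' FT-IR: 900-3800 1/cm at 4 1/cm spacing (726 points). Raman: 500-3200
#' 1/cm at 1 1/cm spacing (2701 points).
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @return numeric ascending axis.
#' @export
default_axis <- function(modality = c("FTIR", "RAMAN")) {
  modality <- match.arg(modality)
  if (modality == "FTIR") seq(900, 3800, by = 4) else seq(500, 3200, by = 1)
}

pseudo_voigt <- function(x, center, fwhm, eta = 0.3) {
  # unit-area pseudo-Voigt: eta Lorentzian + (1 - eta) Gaussian
  g <- exp(-4 * log(2) * ((x - center) / fwhm)^2) * (2 / fwhm) * sqrt(log(2) / pi)
  l <- (2 / (pi * fwhm)) / (1 + 4 * ((x - center) / fwhm)^2)
  eta * l + (1 - eta) * g
}

#' Component basis spectra for the tissue generator
#'
#' Builds the per-modality set of unit-area component spectra: an
#' ester-rich lipid (triacylglycerol-like, carbonyl at 1746/1748 1/cm), a
#' CH-rich ester-poor lipid (membrane/sterol-like CH stretches), random-coil
#' and beta-sheet protein (Amide I/II/III), carbohydrate (C-O region near
#' 1047) and nucleic acid (Raman: DNA modes at 744 and 792). Band positions
#' follow the package's built-in assignment table so that loading-feature
#' extraction can recover them.
#'
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @return named list of components, each a list with `name`, `bands`
#'   (data frame `center`, `fwhm`, `amp`) and `eta` (pseudo-Voigt mixing).
#' @seealso [eval_basis()], [tissue_model()]
#' @export
make_basis <- function(modality = c("FTIR", "RAMAN")) {
  modality <- match.arg(modality)
  comp <- function(name, centers, fwhms, amps, eta = 0.3)
    list(name = name,
         bands = data.frame(center = centers, fwhm = fwhms, amp = amps),
         eta = eta)
  if (modality == "FTIR") {
    list(
      lipid_ester = comp("lipid_ester",
        c(1746, 1165), c(24, 30), c(1.00, 0.30)),
      lipid_ch = comp("lipid_ch",
        c(1466, 2854, 2924, 2956, 3012), c(22, 18, 24, 18, 14),
        c(0.22, 0.70, 1.00, 0.25, 0.06)),
      protein_coil = comp("protein_coil",
        c(1656, 1547, 1455, 1404, 1339, 1304, 1240, 2933, 2960, 2874, 3290),
        c(44, 40, 28, 24, 22, 28, 34, 36, 22, 22, 130),
        c(1.00, 0.62, 0.20, 0.12, 0.08, 0.14, 0.16, 0.22, 0.12, 0.08, 0.30)),
      protein_sheet = comp("protein_sheet",
        c(1631, 1685, 1530, 1239, 1455, 2933, 3290),
        c(30, 24, 38, 30, 28, 36, 130),
        c(1.00, 0.28, 0.55, 0.18, 0.18, 0.20, 0.28)),
      carbohydrate = comp("carbohydrate",
        c(1047, 1080, 1155, 2920), c(36, 32, 28, 50), c(1.00, 0.20, 0.22, 0.08)),
      nucleic_acid = comp("nucleic_acid",
        c(1085, 1236, 965), c(36, 28, 24), c(0.60, 0.45, 0.25)))
  } else {
    list(
      lipid_ester = comp("lipid_ester", 1748, 12, 1.00),
      lipid_ch = comp("lipid_ch",
        c(973, 1082, 1302, 1366, 1438, 1655, 2853, 2889),
        c(12, 16, 16, 14, 18, 16, 20, 24),
        c(0.12, 0.30, 0.75, 0.10, 1.00, 0.45, 1.60, 1.10)),
      protein_coil = comp("protein_coil",
        c(621, 643, 855, 939, 1003, 1032, 1129, 1209, 1241, 1339, 1450, 1660,
          2949, 2978),
        c(10, 10, 14, 16, 7, 10, 12, 12, 22, 18, 20, 22, 28, 20),
        c(0.06, 0.06, 0.18, 0.18, 0.40, 0.15, 0.12, 0.10, 0.28, 0.18, 0.35,
          0.50, 1.00, 0.30)),
      protein_sheet = comp("protein_sheet",
        c(940, 1003, 1235, 1450, 1671, 2949),
        c(16, 7, 20, 20, 20, 28),
        c(0.20, 0.38, 0.28, 0.33, 0.55, 0.95)),
      carbohydrate = comp("carbohydrate",
        c(1047, 1126, 940, 1340), c(16, 14, 16, 18), c(0.50, 0.35, 0.25, 0.20)),
      nucleic_acid = comp("nucleic_acid",
        c(744, 792, 1094, 1578), c(10, 12, 14, 14), c(0.45, 0.55, 0.30, 0.35)))
  }
}

#' Evaluate basis components on an axis
#'
#' @param basis a [make_basis()] result (or subset).
#' @param x wavenumber axis.
#' @return matrix with one unit-area (trapezoid = 1) row per component.
#' @export
eval_basis <- function(basis, x) {
  B <- t(vapply(basis, function(cm) {
    y <- numeric(length(x))
    for (i in seq_len(nrow(cm$bands)))
      y <- y + cm$bands$amp[i] * pseudo_voigt(x, cm$bands$center[i],
                                              cm$bands$fwhm[i], cm$eta)
    y / pracma::trapz(x, y)
  }, numeric(length(x))))
  rownames(B) <- names(basis)
  B
}

#' Generative model of tumor and margin tissue spectra
#'
#' Parametrizes the synthetic study: component basis spectra, per-class
#' mixing distributions, baseline drift, noise, and (Raman) cosmic-ray
#' rate. Lipid content is parametrized directly in post-normalization
#' band-integral units (the scale on which the analysis operates): per
#' spectrum the model draws a target ester-band integral and CH-stretch
#' integral and inverts the closure (area-normalization) algebra to obtain
#' component weights.
#'
#' The defaults are the calibrated study conditions: a homogeneous
#' low-lipid tumor class (near-symmetric ester-integral distribution kept
#' below the 0.014 filter cutoff, with membrane-lipid CH variability) and a
#' heterogeneous margin class, a two-component mixture of a lipid-poor
#' matrix and lipid-rich (adipocyte-domain) spectra whose ester integral
#' reaches ~0.11.
#'
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @param p_rich probability that a margin spectrum falls in the lipid-rich
#'   mixture component.
#' @param contrast_scale scales the tumor-margin difference in
#'   protein/carbohydrate/nucleic-acid weights (0 = no compositional
#'   contrast).
#' @param null if `TRUE`, the margin class is drawn from the tumor
#'   distributions with `p_rich = 0` and zero contrast: the classes are
#'   exchangeable (for null-calibration checks).
#' @return an object of class `tissue_model` (a parameter list).
#' @export
tissue_model <- function(modality = c("FTIR", "RAMAN"), p_rich = NULL,
                         contrast_scale = 1, null = FALSE) {
  modality <- match.arg(modality)
  basis <- make_basis(modality)
  if (modality == "FTIR") {
    m <- list(
      modality = modality, basis = basis,
      ester_band = band_definition("ester C=O", 1746, 1710, 1790, "lipid"),
      ch_band = band_definition("CH stretch", 2920, 2800, 3000, "lipid"),
      tumor = list(ester_mean = 0.005, ester_sd = 0.0012,
                   ch_meanlog = log(0.050), ch_sdlog = 0.15),
      margin = list(p_rich = if (is.null(p_rich)) 0.62 else p_rich,
                    poor_meanlog = log(0.004), poor_sdlog = 0.55,
                    rich_shift = 0.0145, rich_meanlog = log(0.0046),
                    rich_sdlog = 1.00,
                    ch_ratio_meanlog = log(2.60), ch_ratio_sdlog = 0.25,
                    ch_base_meanlog = log(0.002), ch_base_sdlog = 0.40),
      weights = list(
        tumor  = c(protein_coil = 0.5143, protein_sheet = 0.1310,
                   carbohydrate = 0.2251, nucleic_acid = 0.1429),
        margin = c(protein_coil = 0.4857, protein_sheet = 0.1690,
                   carbohydrate = 0.1909, nucleic_acid = 0.1159)),
      jitter_sdlog = 0.012, contrast_scale = contrast_scale,
      amp_sdlog = 0.15, noise_sd = 8e-5, baseline_scale = 1e-4,
      spike_rate = 0, spike_amp = c(25, 100),
      gain = 0.80)
  } else {
    m <- list(
      modality = modality, basis = basis,
      ester_band = band_definition("ester C=O", 1748, 1710, 1790, "lipid"),
      ch_band = band_definition("CH stretch", 2890, 2800, 3000, "lipid"),
      tumor = list(ester_mean = 0.001, ester_sd = 0.0007,
                   ch_meanlog = log(0.010), ch_sdlog = 0.60),
      margin = list(p_rich = if (is.null(p_rich)) 0.50 else p_rich,
                    poor_meanlog = log(0.003), poor_sdlog = 0.40,
                    rich_shift = 0, rich_meanlog = log(0.008),
                    rich_sdlog = 0.45,
                    ch_ratio_meanlog = log(4.0), ch_ratio_sdlog = 0.30,
                    ch_base_meanlog = log(0.002), ch_base_sdlog = 0.40),
      weights = list(
        tumor  = c(protein_coil = 0.52, protein_sheet = 0.13,
                   carbohydrate = 0.16, nucleic_acid = 0.19),
        margin = c(protein_coil = 0.48, protein_sheet = 0.18,
                   carbohydrate = 0.20, nucleic_acid = 0.14)),
      jitter_sdlog = 0.015, contrast_scale = contrast_scale,
      amp_sdlog = 0.15, noise_sd = 2.5e-5, baseline_scale = 1.2e-4,
      spike_rate = 0.3, spike_amp = c(25, 100),
      gain = 0.83)
  }
  m$null <- null
  if (null) {
    m$margin$p_rich <- 0
    m$contrast_scale <- 0
  }
  structure(m, class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %s; p_rich=%.2f, contrast=%.2f%s\n",
              x$modality, x$margin$p_rich, x$contrast_scale,
              if (isTRUE(x$null)) " (null)" else ""))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

gaussian_field <- function(rows, cols, corr_len = 6) {
  # smoothed white noise; separable Gaussian kernel, reflected edges
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * corr_len + 1))
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(corr_len)]), v, rev(v[n - seq_len(corr_len) + 1L]))
    stats::filter(vp, k, sides = 2)[(corr_len + 1):(corr_len + n)]
  }
  z <- apply(z, 2L, smooth_vec)
  z <- t(apply(z, 1L, smooth_vec))
  (z - mean(z)) / stats::sd(z)
}

window_shares <- function(model, x) {
  # per-component locally-baselined integral over the ester and CH windows,
  # for unit component weight (used to invert the closure algebra)
  B <- eval_basis(model$basis, x)
  s_e <- apply(B, 1L, function(y) band_integral(x, y, model$ester_band, TRUE))
  s_c <- apply(B, 1L, function(y) band_integral(x, y, model$ch_band, TRUE))
  list(B = B, s_e = s_e, s_c = s_c)
}

draw_lipid_targets <- function(model, class, n) {
  g <- model$gain
  if (class == "tumor" || isTRUE(model$null)) {
    eps <- pmax(stats::rnorm(n, model$tumor$ester_mean, model$tumor$ester_sd), 0)
    chi <- stats::rlnorm(n, model$tumor$ch_meanlog, model$tumor$ch_sdlog)
    rich <- rep(FALSE, n)
  } else {
    mg <- model$margin
    rich <- stats::runif(n) < mg$p_rich
    eps <- numeric(n)
    eps[!rich] <- stats::rlnorm(sum(!rich), mg$poor_meanlog, mg$poor_sdlog)
    eps[rich] <- mg$rich_shift + stats::rlnorm(sum(rich), mg$rich_meanlog,
                                               mg$rich_sdlog)
    ratio <- stats::rlnorm(n, mg$ch_ratio_meanlog, mg$ch_ratio_sdlog)
    chi <- ratio * eps + stats::rlnorm(n, mg$ch_base_meanlog, mg$ch_base_sdlog)
  }
  list(eps = eps / g, chi = chi / g, rich = rich)
}

sample_class <- function(model, class, n, shares, x, patient_pool, map_shape) {
  lip <- draw_lipid_targets(model, class, n)
  # biochemical component weights (coil, sheet, carb, nucleic) with contrast
  w_avg <- (model$weights$tumor + model$weights$margin) / 2
  w_base <- w_avg + model$contrast_scale *
    (model$weights[[if (isTRUE(model$null)) "tumor" else class]] - w_avg)
  comp_names <- names(w_base)
  Wj <- matrix(stats::rlnorm(n * length(w_base), 0, model$jitter_sdlog),
               n, length(w_base))
  W_other <- sweep(Wj, 2L, w_base, `*`)
  colnames(W_other) <- comp_names
  # closure inversion: solve 2x2 per spectrum for the two lipid weights
  s_e <- shares$s_e; s_c <- shares$s_c
  K_e <- drop(W_other %*% s_e[comp_names])
  W0 <- rowSums(W_other)
  eps <- lip$eps; chi <- lip$chi
  # eps is the total ester-window integral target; chi is the *lipid*
  # contribution to the CH window (protein CH rides on top of it)
  a11 <- s_e["lipid_ester"] - eps; a12 <- s_e["lipid_ch"] - eps
  a21 <- s_c["lipid_ester"] - chi; a22 <- s_c["lipid_ch"] - chi
  b1 <- eps * W0 - K_e; b2 <- chi * W0
  det <- a11 * a22 - a12 * a21
  we <- pmax((b1 * a22 - b2 * a12) / det, 0)
  wc <- pmax((a11 * b2 - a21 * b1) / det, 0)
  W <- cbind(lipid_ester = we, lipid_ch = wc, W_other)
  X <- W %*% shares$B[colnames(W), , drop = FALSE]
  # baseline drift: random low-order polynomial in the scaled axis
  t01 <- (x - min(x)) / diff(range(x))
  bs <- model$baseline_scale
  cf <- matrix(stats::runif(n * 3, -1, 1), n, 3)
  X <- X + bs * (cf[, 1] + 1.5) + bs * cf[, 2] %o% t01 + bs * cf[, 3] %o% t01^2
  amp <- stats::rlnorm(n, 0, model$amp_sdlog)
  X <- X * amp
  X <- X + matrix(stats::rnorm(n * length(x), 0, model$noise_sd), n)
  # cosmic rays (Raman)
  spikes <- NULL
  if (model$modality == "RAMAN" && model$spike_rate > 0) {
    n_sp <- stats::rpois(n, model$spike_rate)
    for (i in which(n_sp > 0)) {
      pos <- sample.int(length(x) - 1L, n_sp[i])
      hgt <- stats::runif(n_sp[i], model$spike_amp[1], model$spike_amp[2]) *
        model$noise_sd
      wid <- sample(c(1L, 2L), n_sp[i], replace = TRUE, prob = c(0.7, 0.3))
      for (j in seq_along(pos)) {
        cols <- pos[j]:min(pos[j] + wid[j] - 1L, length(x))
        X[i, cols] <- X[i, cols] + hgt[j]
      }
      spikes <- rbind(spikes, data.frame(spectrum = i, index = pos, height = hgt))
    }
  }
  # map geometry / patient assignment
  meta <- data.frame(tissue = rep(class, n),
                     lipid_weight = we + wc,
                     ester_target = eps * model$gain,
                     rich_domain = lip$rich)
  if (!is.null(map_shape)) {
    per_map <- prod(map_shape)
    n_maps <- ceiling(n / per_map)
    idx <- seq_len(n) - 1L
    meta$map_id <- paste0(class, "_map", idx %/% per_map + 1L)
    meta$px_row <- (idx %% per_map) %/% map_shape[2] + 1L
    meta$px_col <- (idx %% per_map) %% map_shape[2] + 1L
    meta$patient_id <- patient_pool[(idx %/% per_map) %% length(patient_pool) + 1L]
  } else {
    meta$map_id <- paste0(class, "_map", (seq_len(n) - 1L) %% 4L + 1L)
    meta$patient_id <- patient_pool[(seq_len(n) - 1L) %% length(patient_pool) + 1L]
  }
  list(X = X, meta = meta, spikes = spikes)
}

#' Sample a labeled synthetic dataset from a tissue model
#'
#' Deterministic under `seed` (the global RNG state is restored on exit).
#' The per-spectrum ground truth (total lipid weight, target ester
#' integral, rich-domain flag) is stored in the metadata for test oracles.
#' When `map_shape` is given, margin lipid-rich domains are laid out as
#' blobs: a smoothed Gaussian random field per map is thresholded at the
#' `1 - p_rich` quantile and pixels above it are drawn from the rich
#' component.
#'
#' @param model a [tissue_model()].
#' @param n_per_class number of spectra per class (>= 10 recommended for
#'   distributional targets).
#' @param seed integer seed.
#' @param map_shape optional `c(rows, cols)` map geometry.
#' @return a labeled raw (unpreprocessed) [spectral_dataset()]; Raman data
#'   include injected cosmic-ray spikes (ground truth in the `"spikes"`
#'   attribute).
#' @export
sample_dataset <- function(model, n_per_class = 1000L, seed = 1L,
                           map_shape = NULL) {
  stopifnot(inherits(model, "tissue_model"))
  if (n_per_class < 2L) stop("config error: n_per_class must be >= 2")
  if (!is.null(map_shape) &&
      (length(map_shape) != 2L || any(map_shape < 1L)))
    stop("config error: map_shape must be c(rows, cols)")
  x <- default_axis(model$modality)
  shares <- window_shares(model, x)
  patients <- sprintf("P%02d", 1:10)
  with_seed(seed, {
    tum <- sample_class(model, "tumor", n_per_class, shares, x, patients, map_shape)
    mar <- if (!is.null(map_shape) && !isTRUE(model$null)) {
      sample_margin_maps(model, n_per_class, shares, x, patients, map_shape)
    } else {
      sample_class(model, "margin", n_per_class, shares, x, patients, map_shape)
    }
    sp <- rbind(tum$spikes,
                if (!is.null(mar$spikes))
                  transform(mar$spikes, spectrum = spectrum + n_per_class))
    ds <- spectral_dataset(x, rbind(tum$X, mar$X), model$modality,
                           rbind(tum$meta, mar$meta))
    attr(ds, "spikes") <- sp
    ds
  })
}

sample_margin_maps <- function(model, n, shares, x, patient_pool, map_shape) {
  # spatially structured rich domains: thresholded Gaussian random field
  per_map <- prod(map_shape)
  n_maps <- ceiling(n / per_map)
  rich <- logical(0)
  for (m in seq_len(n_maps)) {
    f <- gaussian_field(map_shape[1], map_shape[2])
    thr <- stats::quantile(f, 1 - model$margin$p_rich)
    rich <- c(rich, as.vector(t(f >= thr)))
  }
  rich <- rich[seq_len(n)]
  # draw the two sub-populations with the class machinery, then interleave
  model_poor <- model; model_poor$margin$p_rich <- 0
  model_rich <- model; model_rich$margin$p_rich <- 1
  out_p <- sample_class(model_poor, "margin", max(sum(!rich), 1L), shares, x,
                        patient_pool, NULL)
  out_r <- sample_class(model_rich, "margin", max(sum(rich), 1L), shares, x,
                        patient_pool, NULL)
  X <- matrix(0, n, length(x))
  X[!rich, ] <- out_p$X[seq_len(sum(!rich)), , drop = FALSE]
  X[rich, ] <- out_r$X[seq_len(sum(rich)), , drop = FALSE]
  meta <- out_p$meta[rep(1L, n), ]
  meta[!rich, ] <- out_p$meta[seq_len(sum(!rich)), ]
  meta[rich, ] <- out_r$meta[seq_len(sum(rich)), ]
  idx <- seq_len(n) - 1L
  meta$map_id <- paste0("margin_map", idx %/% per_map + 1L)
  meta$px_row <- (idx %% per_map) %/% map_shape[2] + 1L
  meta$px_col <- (idx %% per_map) %% map_shape[2] + 1L
  meta$patient_id <- patient_pool[(idx %/% per_map) %% length(patient_pool) + 1L]
  rownames(meta) <- NULL
  list(X = X, meta = meta, spikes = NULL)
}

#' Calibrate scalar model parameters toward target statistics
#'
#' Deterministic coordinate search: the model is simulated (`n` spectra per
#' class, fixed seed), run through the preprocessing and filtering
#' pipeline, and scalar mixing parameters are nudged multiplicatively until
#' every requested statistic is within `tol` (relative). Supported target
#' names: `margin_mean`, `margin_median`, `margin_max`, `tumor_max`
#' (ester-integral distribution statistics), `retained_fraction` (at the
#' default threshold), `sd_ratio` (PC1 SD ratio).
#'
#' @param model a [tissue_model()].
#' @param targets named numeric vector of target values.
#' @param tol relative tolerance (default 0.15).
#' @param n spectra per class per evaluation (default 2000).
#' @param seed fixed evaluation seed.
#' @param max_iter iteration budget.
#' @return the calibrated `tissue_model`; attribute `"calibration"` holds
#'   the achieved statistics. If the budget is exhausted the search stops
#'   with a calibration error whose message reports the best round found.
#' @export
calibrate_model <- function(model, targets, tol = 0.15, n = 2000L, seed = 7L,
                            max_iter = 12L) {
  stopifnot(inherits(model, "tissue_model"))
  allowed <- c("margin_mean", "margin_median", "margin_max", "tumor_max",
               "retained_fraction", "sd_ratio")
  if (is.null(names(targets)) || !all(names(targets) %in% allowed))
    stop("targets must be named with a subset of: ", paste(allowed, collapse = ", "))
  measure <- function(m) {
    ds <- preprocess(sample_dataset(m, n, seed))
    lab <- tissue_labels(ds)
    fcfg <- lipid_filter_config(m$modality)
    v <- band_integrals(ds, fcfg$band, fcfg$local_baseline)
    fl <- suppressWarnings(filter_lipid_rich(ds, fcfg))
    stats_out <- c(margin_mean = mean(v[lab == "margin"]),
                   margin_median = stats::median(v[lab == "margin"]),
                   margin_max = max(v[lab == "margin"]),
                   tumor_max = max(v[lab == "tumor"]),
                   retained_fraction = fl$retained_fraction,
                   sd_ratio = NA_real_)
    if (!is.null(names(targets)) && "sd_ratio" %in% names(targets)) {
      p <- fit_pca(ds, 2L)
      stats_out["sd_ratio"] <- summarize_groups(p)$sd_ratio
    }
    stats_out
  }
  best <- NULL; best_err <- Inf
  for (it in seq_len(max_iter)) {
    got <- measure(model)[names(targets)]
    rel <- abs(got - targets) / abs(targets)
    if (all(rel <= tol)) {
      attr(model, "calibration") <- got
      return(model)
    }
    if (max(rel) < best_err) { best <- got; best_err <- max(rel) }
    damp <- 0.7
    for (nm in names(targets)) {
      f <- (targets[[nm]] / got[[nm]])^damp
      if (!is.finite(f) || f <= 0) next
      if (nm == "margin_mean") {
        model$margin$rich_meanlog <- model$margin$rich_meanlog + log(f)
        model$margin$rich_shift <- model$margin$rich_shift * f
      } else if (nm == "margin_median") {
        model$margin$poor_meanlog <- model$margin$poor_meanlog + log(f)
      } else if (nm == "margin_max") {
        model$margin$rich_sdlog <- model$margin$rich_sdlog * f^(1 / 3)
      } else if (nm == "tumor_max") {
        model$tumor$ester_mean <- model$tumor$ester_mean * f
      } else if (nm == "retained_fraction") {
        rem <- (1 - targets[[nm]]) / max(1 - got[[nm]], 1e-6)
        model$margin$p_rich <- min(max(model$margin$p_rich * rem^damp, 0), 1)
      } else if (nm == "sd_ratio") {
        model$tumor$ch_sdlog <- model$tumor$ch_sdlog / f
      }
    }
  }
  stop("calibration error: budget exhausted; best round: ",
       paste(sprintf("%s=%.4g (target %.4g)", names(targets), best,
                     targets), collapse = ", "))
}
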