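test_that("dataset construction enforces the axis and shape invariants", {
  wn <- seq(900, 3800, by = 4)
  expect_length(wn, 726) # (3800 - 900) / 4 + 1
  ds <- spectral_dataset(wn, matrix(1, 3, length(wn)), "FTIR")
  expect_equal(n_spectra(ds), 3L)
  expect_error(spectral_dataset(c(1, 1, 2), matrix(0, 1, 3), "FTIR"),
               "monotone")
  expect_error(spectral_dataset(c(-1, 2), matrix(0, 1, 2), "FTIR"), "positive")
  expect_error(spectral_dataset(wn, matrix(0, 2, 10), "FTIR"), "column")
  expect_error(spectral_dataset(wn, matrix(NA_real_, 1, 726), "FTIR"), "finite")
})

test_that("descending axes are reversed consistently with intensities", {
  wn <- seq(2000, 1000, by = -10)
  y <- seq_along(wn) # distinct values so we can track the flip
  ds <- spectral_dataset(wn, y, "FTIR")
  expect_equal(ds$wavenumbers, rev(wn))
  expect_equal(ds$intensities[1, ], rev(y))
  expect_equal(ds$intensities[1, ds$wavenumbers == 2000], 1)
})

test_that("matrix write/read round trip preserves values and metadata", {
  set.seed(3)
  wn <- seq(900, 1100, by = 4)
  meta <- data.frame(patient_id = c("P01", "P01", "P02"),
                     tissue = c("tumor", "margin", "margin"),
                     map_id = "m1", px_row = 1:3, px_col = 3:1)
  ds <- spectral_dataset(wn, matrix(rnorm(3 * length(wn)), 3), "FTIR", meta)
  for (ext in c("csv", "tsv")) {
    path <- file.path(tempdir(), paste0("rt.", ext))
    write_spectra(ds, path)
    back <- read_spectra(path, "FTIR")
    expect_near(back$intensities, ds$intensities, 1e-12)
    expect_near(back$wavenumbers, ds$wavenumbers, 1e-12)
    expect_equal(back$meta$tissue, meta$tissue)
    expect_equal(back$meta$px_row, meta$px_row)
  }
})

test_that("malformed spectrum matrices are rejected", {
  p <- file.path(tempdir(), "bad.csv")
  writeLines(c("1000,996,1004", "1,2,3"), p) # non-monotone header
  expect_error(read_spectra(p, "FTIR"), "monotone")
  writeLines(c("tissue,1000,1004", "tumor,1,2", "tumor,1"), p) # ragged
  expect_error(suppressWarnings(read_spectra(p, "FTIR")))
})

test_that("JCAMP-DX AFFN X++(Y..Y) blocks are parsed with factors", {
  p <- file.path(tempdir(), "one.jdx")
  writeLines(c("##TITLE=synthetic test spectrum", "##JCAMP-DX=4.24",
               "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
               "##XFACTOR=1", "##YFACTOR=0.5",
               "##FIRSTX=1000", "##LASTX=1016", "##NPOINTS=5",
               "##XYDATA=(X++(Y..Y))",
               "1000 2 4 6", "1012 8 10",
               "##END="), p)
  ds <- read_jcampdx(p, "FTIR")
  expect_equal(ds$wavenumbers, seq(1000, 1016, by = 4))
  expect_equal(ds$intensities[1, ], c(1, 2, 3, 4, 5)) # YFACTOR applied
})

test_that("crop keeps exactly the closed-interval points and composes", {
  wn <- seq(900, 3800, by = 4)
  ds <- spectral_dataset(wn, matrix(rnorm(2 * 726), 2), "FTIR")
  cr <- crop(ds, 1000, 1100)
  expect_equal(length(cr$wavenumbers), 26L)
  expect_true(all(cr$wavenumbers >= 1000 & cr$wavenumbers <= 1100))
  expect_equal(crop(ds, 900, 3800)$intensities, ds$intensities)
  # composition property over random window pairs
  set.seed(1)
  for (i in 1:5) {
    w <- sort(runif(4, 950, 3700))
    a <- crop(crop(ds, w[1], w[4]), w[2], w[3])
    b <- crop(ds, max(w[1], w[2]), min(w[4], w[3]))
    expect_equal(a$wavenumbers, b$wavenumbers)
    expect_equal(a$intensities, b$intensities)
  }
  expect_error(crop(ds, 4000, 4100), "overlap")
  expect_error(crop(ds, 1100, 1000), "lo < hi")
})

test_that("dataset concatenation preserves per-class counts", {
  a <- toy_dataset(3, seed = 1)
  b <- toy_dataset(5, seed = 2)
  both <- c(a, b)
  expect_equal(unname(table(tissue_labels(both))["margin"]), 8L)
  expect_equal(unname(table(tissue_labels(both))["tumor"]), 8L)
  expect_error(c(a, crop(b, 1000, 1200)), "axes")
})

test_that("band definitions validate their window", {
  b <- band_definition("ester C=O", 1746, 1710, 1790, "lipid")
  expect_s3_class(b, "band_definition")
  expect_error(band_definition("x", 1800, 1710, 1790, "lipid"), "lo < center < hi")
})
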