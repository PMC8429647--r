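META_COLUMNS <- c("patient_id", "tissue", "map_id", "px_row", "px_col")

#' Read a spectrum matrix from CSV/TSV
#'
#' The expected layout is one spectrum per row with a header naming the
#' wavenumber of every intensity column; any leading non-numeric header
#' names (conventionally `patient_id`, `tissue`, `map_id`, `px_row`,
#' `px_col`) are parsed as metadata. A descending wavenumber header is
#' accepted and reversed to the internal ascending convention.
#'
#' @param path file path; tab-separated when the extension is `.tsv`,
#'   comma-separated otherwise.
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @return a [spectral_dataset()] preserving the file's row order.
#' @seealso [write_spectra()], [read_jcampdx()]
#' @export
read_spectra <- function(path, modality = c("FTIR", "RAMAN")) {
  modality <- match.arg(modality)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  wn <- suppressWarnings(as.numeric(names(df)))
  is_num <- !is.na(wn)
  if (sum(is_num) < 2L)
    stop("format error: header contains fewer than 2 numeric wavenumber columns")
  # metadata columns must precede the spectral block
  first_num <- which(is_num)[1L]
  if (any(!is_num[seq(first_num, length(is_num))]))
    stop("format error: non-numeric header column inside the spectral block")
  axis <- wn[is_num]
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0)))
    stop("format error: wavenumber header is not monotone")
  if (nrow(df) == 0L) stop("input error: empty input dataset (no spectra rows)")
  X <- as.matrix(df[, is_num, drop = FALSE])
  if (!is.numeric(X)) stop("format error: non-numeric intensity values (ragged rows?)")
  meta <- df[, !is_num, drop = FALSE]
  spectral_dataset(axis, X, modality, meta)
}

#' Write a spectrum matrix to CSV/TSV
#'
#' Inverse of [read_spectra()]: metadata columns first, then one column per
#' wavenumber. Values are written in full precision so that a
#' write/read round trip preserves intensities to better than 1e-12.
#'
#' @param ds a [spectral_dataset()].
#' @param path output path (`.tsv` for tab separation).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  X <- as.data.frame(ds$intensities)
  names(X) <- format(ds$wavenumbers, digits = 15, trim = TRUE, scientific = FALSE)
  out <- if (ncol(ds$meta)) cbind(ds$meta, X) else X
  utils::write.table(format(out, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Minimal reader for single-spectrum JCAMP-DX files with an
#' `##XYDATA=(X++(Y..Y))` block in AFFN (plain decimal) form. `##XFACTOR`,
#' `##YFACTOR`, `##FIRSTX`, `##LASTX` and `##NPOINTS` are honored; tabular
#' `(XY..XY)` pairs are also accepted. Compressed (SQZ/DIF/DUP) encodings
#' and multi-spectrum files are not supported.
#'
#' @param path file path.
#' @param modality `"FTIR"` or `"RAMAN"`.
#' @return a one-spectrum [spectral_dataset()].
#' @export
read_jcampdx <- function(path, modality = c("FTIR", "RAMAN")) {
  modality <- match.arg(modality)
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name, default = NA_real_) {
    hit <- grep(paste0("^##", name, "\\s*="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(default)
    suppressWarnings(as.numeric(sub("^##[^=]*=\\s*", "", hit[1L])))
  }
  xf <- ldr("XFACTOR", 1); yf <- ldr("YFACTOR", 1)
  firstx <- ldr("FIRSTX"); lastx <- ldr("LASTX"); npts <- ldr("NPOINTS")
  start <- grep("^##XYDATA\\s*=|^##XYPOINTS\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) stop("format error: no ##XYDATA block found")
  start <- start[1L]
  rest <- lines[seq(start + 1L, length(lines))]
  stop_at <- grep("^##", rest)
  end <- if (length(stop_at)) start + stop_at[1L] else length(lines) + 1L
  body <- if (end > start + 1L) lines[seq(start + 1L, end - 1L)] else character(0)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("format error: empty XYDATA block")
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1]]))
    v[!is.na(v)]
  })
  pairs <- grepl("XYPOINTS|\\(XY", lines[start], ignore.case = TRUE)
  if (pairs) {
    v <- unlist(rows)
    x <- v[seq(1, length(v), by = 2)] * xf
    y <- v[seq(2, length(v), by = 2)] * yf
  } else {
    # X++(Y..Y): first value of each line is the x of the first y on the line
    if (is.finite(firstx) && is.finite(lastx) && is.finite(npts) && npts >= 2) {
      dx <- (lastx - firstx) / (npts - 1)
    } else {
      x0 <- vapply(rows, `[`, numeric(1), 1L) * xf
      ny <- vapply(rows, length, integer(1)) - 1L
      dx <- diff(x0)[1L] / ny[1L]
      firstx <- x0[1L]
    }
    y <- unlist(lapply(rows, function(r) r[-1L])) * yf
    x <- firstx + (seq_along(y) - 1L) * dx  # FIRSTX/LASTX are in real units
    if (is.finite(npts) && length(y) != npts)
      warning("NPOINTS (", npts, ") does not match data length (", length(y), ")")
  }
  spectral_dataset(x, y, modality)
}
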