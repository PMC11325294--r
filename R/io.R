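# Delimited-text formats for traces and spectra (inspectable, diff-able,
# full float precision), a minimal JCAMP-DX reader for FTIR import, and
# directory-based spectral libraries with a JSON manifest.

#' Write / read a time trace as delimited text
#'
#' Two tab-separated columns `time_fs`, `amplitude`, preceded by a single
#' `#`-prefixed header line carrying the trace metadata as JSON. Floats are
#' written with 17 significant digits, so write/read round trips are
#' bit-exact. Complex metadata entries are serialised as `{re, im}` pairs.
#'
#' @param trace A [time_trace()].
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [time_trace()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "time_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta_json(trace$meta)), con)
  writeLines("time_fs\tamplitude", con)
  writeLines(sprintf("%.17g\t%.17g", trace$t, trace$values), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  parsed <- read_delim_body(path)
  cols <- parsed$cols
  if (!all(c("time_fs", "amplitude") %in% names(cols))) {
    stop(sprintf("trace file %s lacks required columns time_fs, amplitude",
                 path))
  }
  if (anyNA(cols$time_fs) || anyNA(cols$amplitude)) {
    stop(sprintf("trace file %s contains non-numeric or NaN values", path))
  }
  time_trace(cols$time_fs, cols$amplitude, meta = parsed$meta)
}

#' Write / read a spectrum as delimited text
#'
#' Complex spectra use columns `wavenumber_cm1`, `real`, `imag`; real
#' (magnitude) spectra use `wavenumber_cm1`, `magnitude`. One `#`-prefixed
#' JSON header line carries the metadata (ROI, filter, offset, ...).
#'
#' @param spec A [complex_spectrum()].
#' @param path File path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` a
#'   [complex_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "complex_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta_json(spec$meta)), con)
  if (is.complex(spec$values)) {
    writeLines("wavenumber_cm1\treal\timag", con)
    writeLines(sprintf("%.17g\t%.17g\t%.17g",
                       spec$nu, Re(spec$values), Im(spec$values)), con)
  } else {
    writeLines("wavenumber_cm1\tmagnitude", con)
    writeLines(sprintf("%.17g\t%.17g", spec$nu, spec$values), con)
  }
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  parsed <- read_delim_body(path)
  cols <- parsed$cols
  if (!"wavenumber_cm1" %in% names(cols)) {
    stop(sprintf("spectrum file %s lacks column wavenumber_cm1", path))
  }
  if (all(c("real", "imag") %in% names(cols))) {
    vals <- complex(real = cols$real, imaginary = cols$imag)
  } else if ("magnitude" %in% names(cols)) {
    vals <- cols$magnitude
  } else {
    stop(sprintf("spectrum file %s lacks real/imag or magnitude columns",
                 path))
  }
  complex_spectrum(cols$wavenumber_cm1, vals, meta = parsed$meta)
}

#' Read a JCAMP-DX infrared spectrum
#'
#' Minimal JCAMP-DX reader for importing FTIR absorbance spectra so they can
#' be filtered with the same pipeline as FRS data. Supports AFFN-encoded
#' `##XYDATA=(X++(Y..Y))` tables and `##XYPOINTS=(XY..XY)` pair lists with
#' `##XUNITS=1/CM`; `XFACTOR`/`YFACTOR` are applied. Descending abscissae
#' are returned ascending with the values reversed. Compressed encodings
#' (SQZ/DIF/DUP) and other abscissa units are rejected with an error naming
#' the offending record.
#'
#' @param path File path.
#' @return A [complex_spectrum()] with real values; `meta` carries `title`
#'   and `yunits` when present.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "\\s*="), lines, ignore.case = TRUE,
                value = TRUE)
    if (length(hit) == 0L) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  xunits <- get_field("XUNITS")
  if (!is.null(xunits) && !grepl("1\\s*/\\s*CM|CM-1|CM\\^-1", toupper(xunits))) {
    stop(sprintf("unsupported JCAMP XUNITS record: %s", xunits))
  }
  xf <- as.numeric(get_field("XFACTOR") %||% "1")
  yf <- as.numeric(get_field("YFACTOR") %||% "1")
  istart <- grep("^##(XYDATA|XYPOINTS|PEAK TABLE)\\s*=", lines,
                 ignore.case = TRUE)
  if (length(istart) == 0L) {
    stop("unsupported JCAMP file: no XYDATA or XYPOINTS record found")
  }
  istart <- istart[1L]
  form <- toupper(trimws(sub("^##[^=]*=", "", lines[istart])))
  iend <- grep("^##", lines)
  iend <- iend[iend > istart]
  iend <- if (length(iend)) iend[1L] - 1L else length(lines)
  body <- lines[(istart + 1L):iend]
  body <- body[nzchar(trimws(body))]
  if (any(grepl("[A-DF-Za-df-z%@]", gsub("[eE][+-]?[0-9]+", "", body)))) {
    stop(sprintf("unsupported JCAMP data encoding in record %s (AFFN only)",
                 lines[istart]))
  }
  toks <- lapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "[,;[:space:]]+")[[1L]])
  })
  if (grepl("X\\+\\+", form)) {
    # (X++(Y..Y)): first token per line is X of the first Y
    npoints <- as.numeric(get_field("NPOINTS"))
    firstx <- as.numeric(get_field("FIRSTX")) * xf
    lastx <- as.numeric(get_field("LASTX")) * xf
    y <- unlist(lapply(toks, function(v) v[-1L])) * yf
    if (!is.na(npoints) && length(y) != npoints) {
      stop(sprintf("JCAMP NPOINTS=%d but %d ordinates parsed",
                   as.integer(npoints), length(y)))
    }
    x <- seq(firstx, lastx, length.out = length(y))
  } else {
    # (XY..XY): alternating pairs
    v <- unlist(toks)
    if (length(v) %% 2L != 0L) stop("JCAMP XYPOINTS table has odd length")
    x <- v[seq(1L, length(v), by = 2L)] * xf
    y <- v[seq(2L, length(v), by = 2L)] * yf
  }
  if (x[1L] > x[length(x)]) {
    x <- rev(x); y <- rev(y)
  }
  complex_spectrum(x, y, meta = list(title = get_field("TITLE"),
                                     yunits = get_field("YUNITS")))
}

#' Read / write a spectral library directory
#'
#' A library is a directory of spectrum files plus a `manifest.json` mapping
#' entry names to file names. All entries must share one wavenumber grid.
#'
#' @param lib A [spectral_library()].
#' @param dir Directory path.
#' @return `write_spectral_library` returns `dir` invisibly;
#'   `read_spectral_library` a [spectral_library()].
#' @export
write_spectral_library <- function(lib, dir) {
  stopifnot(inherits(lib, "spectral_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (nm in names(lib$entries)) {
    fn <- paste0(gsub("[^A-Za-z0-9._-]", "_", nm), ".tsv")
    write_spectrum(complex_spectrum(lib$grid, lib$entries[[nm]],
                                    meta = list(name = nm)),
                   file.path(dir, fn))
    files[[nm]] <- fn
  }
  jsonlite::write_json(list(entries = files), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_spectral_library
#' @export
read_spectral_library <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json in %s", dir))
  manifest <- jsonlite::fromJSON(mf)
  entries <- lapply(manifest$entries, function(fn) {
    read_spectrum(file.path(dir, fn))
  })
  spectral_library(entries)
}

# shared body parser: leading '#' lines (first parseable one is JSON meta),
# then a tab/whitespace-delimited header row and numeric columns
read_delim_body <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop(sprintf("file %s is too short to parse", path))
  is_comment <- grepl("^#", lines)
  hdr_idx <- which(!is_comment)[1L]
  meta <- list()
  for (l in lines[is_comment & seq_along(lines) < hdr_idx]) {
    m <- tryCatch(jsonlite::fromJSON(sub("^#\\s*", "", l),
                                     simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.list(m)) { meta <- m; break }
  }
  header <- strsplit(trimws(lines[hdr_idx]), "[\t,;[:space:]]+")[[1L]]
  body <- lines[(hdr_idx + 1L):length(lines)]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  rows <- strsplit(trimws(body), "[\t,;[:space:]]+")
  ncol <- length(header)
  if (any(lengths(rows) != ncol)) {
    stop(sprintf("file %s: rows do not match the %d-column header", path, ncol))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = ncol, byrow = TRUE)
  cols <- stats::setNames(lapply(seq_len(ncol), function(j) mat[, j]), header)
  list(meta = meta, cols = cols)
}

# JSON-serialise metadata, flattening complex scalars to {re, im}
meta_json <- function(meta) {
  flatten <- function(x) {
    if (is.complex(x)) {
      list(re = Re(x), im = Im(x))
    } else if (is.list(x)) {
      lapply(x, flatten)
    } else x
  }
  as.character(jsonlite::toJSON(flatten(meta), auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
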