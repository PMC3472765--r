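#' Construct an MS2 spectrum
#'
#' @param spectrum_id Identifier string.
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge (1..4).
#' @param retention_time Retention time in seconds.
#' @param peaks data.frame with columns `mz`, `intensity`; stored sorted
#'   ascending by m/z.
#' @return Object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(spectrum_id, precursor_mz, precursor_charge,
                         retention_time, peaks) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) && any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  precursor_charge <- as.integer(precursor_charge)
  if (!precursor_charge %in% 1:4) stop("precursor charge must be in 1..4")
  peaks <- peaks[order(peaks$mz), c("mz", "intensity"), drop = FALSE]
  rownames(peaks) <- NULL
  structure(
    list(spectrum_id = as.character(spectrum_id),
         precursor_mz = as.numeric(precursor_mz),
         precursor_charge = precursor_charge,
         retention_time = as.numeric(retention_time),
         peaks = peaks),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum %s: m/z %.4f (%d+), rt %.1f s, %d peaks>\n",
              x$spectrum_id, x$precursor_mz, x$precursor_charge,
              x$retention_time, nrow(x$peaks)))
  invisible(x)
}

#' Construct an MS1 trace
#'
#' A tidy table of MS1 observations: one row per (scan retention time, m/z,
#' intensity).  Scans must be sorted by strictly increasing retention time;
#' the extracted-ion-chromatography code treats each distinct retention
#' time as one scan.
#'
#' @param points data.frame with columns `rt_seconds`, `mz`, `intensity`.
#' @return Object of class `ms1_trace` (a data.frame).
#' @export
ms1_trace <- function(points = data.frame(rt_seconds = numeric(),
                                          mz = numeric(),
                                          intensity = numeric())) {
  stopifnot(is.data.frame(points),
            all(c("rt_seconds", "mz", "intensity") %in% names(points)))
  if (nrow(points)) {
    if (is.unsorted(points$rt_seconds)) {
      bad <- which(diff(points$rt_seconds) < 0)[1] + 1L
      stop("MS1 scans out of retention-time order at row ", bad)
    }
    if (any(points$intensity < 0)) stop("MS1 intensities must be >= 0")
  }
  points <- points[, c("rt_seconds", "mz", "intensity"), drop = FALSE]
  rownames(points) <- NULL
  class(points) <- c("ms1_trace", "data.frame")
  points
}

.parse_mgf_charge <- function(value, line) {
  m <- regmatches(value, regexec("^([0-9]+)\\+?$", trimws(value)))[[1]]
  if (length(m) < 2) stop("malformed CHARGE at line ", line, ": ", value)
  as.integer(m[2])
}

#' Read MS2 spectra from a Mascot generic format (MGF) file
#'
#' One spectrum per `BEGIN IONS` block.  `PEPMASS` (first token) maps to
#' the precursor m/z, `CHARGE` to the precursor charge and `RTINSECONDS`
#' to the retention time.  A block without `CHARGE` defaults to 2+ with a
#' warning.  Malformed blocks are rejected with the offending line number.
#'
#' @param path Path to an MGF file.
#' @return List of [ms2_spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n_spec <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (line != "BEGIN IONS") stop("expected BEGIN IONS at line ", i, ", got: ", line)
    begin_line <- i
    i <- i + 1L
    keys <- list()
    mzs <- numeric()
    ints <- numeric()
    closed <- FALSE
    while (i <= length(lines)) {
      line <- trimws(lines[i])
      if (line == "END IONS") { closed <- TRUE; i <- i + 1L; break }
      if (line == "") { i <- i + 1L; next }
      if (grepl("=", line, fixed = TRUE)) {
        kv <- regmatches(line, regexpr("=", line, fixed = TRUE), invert = TRUE)[[1]]
        keys[[toupper(kv[1])]] <- kv[2]
      } else {
        tokens <- strsplit(line, "[ \t]+")[[1]]
        vals <- suppressWarnings(as.numeric(tokens[1:2]))
        if (length(tokens) < 2 || anyNA(vals)) {
          stop("malformed peak line at line ", i, ": ", line)
        }
        mzs <- c(mzs, vals[1])
        ints <- c(ints, vals[2])
        i <- i + 1L
        next
      }
      i <- i + 1L
    }
    if (!closed) stop("BEGIN IONS at line ", begin_line, " has no END IONS")
    if (is.null(keys$PEPMASS)) stop("block at line ", begin_line, " lacks PEPMASS")
    pepmass <- suppressWarnings(as.numeric(strsplit(trimws(keys$PEPMASS), "[ \t]+")[[1]][1]))
    if (is.na(pepmass)) stop("malformed PEPMASS in block at line ", begin_line)
    if (is.null(keys$CHARGE)) {
      warning("block at line ", begin_line, " lacks CHARGE; defaulting to 2+")
      charge <- 2L
    } else {
      charge <- .parse_mgf_charge(keys$CHARGE, begin_line)
    }
    n_spec <- n_spec + 1L
    id <- if (!is.null(keys$TITLE)) keys$TITLE else sprintf("spectrum_%d", n_spec)
    rt <- if (!is.null(keys$RTINSECONDS)) as.numeric(keys$RTINSECONDS) else NA_real_
    spectra[[n_spec]] <- ms2_spectrum(
      spectrum_id = id, precursor_mz = pepmass, precursor_charge = charge,
      retention_time = rt,
      peaks = data.frame(mz = mzs, intensity = ints)
    )
  }
  spectra
}

#' Write MS2 spectra to an MGF file
#'
#' Numeric fields are written at 6 decimal places, so a
#' `write_mgf()`/[read_mgf()] round trip preserves peak lists to 1e-6.
#'
#' @param spectra List of [ms2_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(sprintf("TITLE=%s", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (!is.na(s$retention_time)) {
      writeLines(sprintf("RTINSECONDS=%.6f", s$retention_time), con)
    }
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.6f %.6f", s$peaks$mz, s$peaks$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read an MS1 trace from CSV
#'
#' Expects columns `rt_seconds`, `mz`, `intensity` (comma separated,
#' header row, '.' decimal).  Retention times must be non-decreasing in
#' file order; a violation is rejected naming the offending row.
#'
#' @param path Path to a CSV file.
#' @return An [ms1_trace()].
#' @export
read_ms1_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rt_seconds", "mz", "intensity")
  if (!all(need %in% names(df))) {
    stop("MS1 CSV must have columns ", paste(need, collapse = ", "))
  }
  ms1_trace(df)
}

#' Write an MS1 trace to CSV
#'
#' @param trace An [ms1_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ms1_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("rt_seconds,mz,intensity", con)
  if (nrow(trace)) {
    writeLines(sprintf("%.6f,%.6f,%.6f",
                       trace$rt_seconds, trace$mz, trace$intensity), con)
  }
  invisible(path)
}
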