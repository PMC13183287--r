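# Functional connectivity: amplitude-envelope correlation for band-limited
# EEG-like signals, Pearson correlation for band-passed BOLD.

fc_matrix <- function(values, band, n_samples) {
  diag(values) <- 0
  structure(values, band = band, n_samples = n_samples,
            class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  off <- x[upper.tri(x)]
  cat(sprintf("fc_matrix (%s): %d regions, mean off-diagonal %.3f\n",
              attr(x, "band"), nrow(x), mean(off)))
  invisible(x)
}

#' Mean off-diagonal functional connectivity
#'
#' @param fc An `fc_matrix` (or plain square matrix).
#' @return Mean of the upper-triangular entries.
#' @export
mean_fc <- function(fc) {
  mean(fc[upper.tri(fc)])
}

#' Amplitude-envelope correlation FC for one EEG band
#'
#' Band-passes every region (3rd-order zero-phase Bessel), extracts the
#' high-passed Hilbert envelope, and correlates all pairs (Pearson). The
#' diagonal is set to 0 by convention. Regions with a constant envelope get
#' zero rows/columns with a warning.
#'
#' @param signals T x N matrix of EEG-like signals.
#' @param fs Sampling rate, Hz.
#' @param band Either a band name from [band_definitions()] or a numeric
#'   `c(lo, hi)`.
#' @return An `fc_matrix`.
#' @export
eeg_band_fc <- function(signals, fs, band = "alpha") {
  signals <- as.matrix(signals)
  if (nrow(signals) / fs < 10)
    warning("less than 10 s of signal; envelope FC is unreliable")
  if (is.character(band)) {
    bd <- band_definitions()
    row <- bd[bd$name == band, ]
    if (!nrow(row)) stop("unknown band name: ", band)
    lohi <- c(row$lo, row$hi); band_name <- band
  } else {
    lohi <- band; band_name <- paste0(band[1], "-", band[2], "Hz")
  }
  env <- apply(signals, 2, function(x)
    signal_envelope(bandpass_filter(x, fs, lohi[1], lohi[2]), fs))
  pearson_fc(env, band_name)
}

#' BOLD functional connectivity
#'
#' Band-passes each region between `lo` and `hi` Hz (3rd-order zero-phase
#' Bessel) and correlates all pairs.
#'
#' @param bold T x N matrix of BOLD signals, or a `bold_sim`.
#' @param fs Sampling rate, Hz (taken from a `bold_sim` automatically).
#' @param lo,hi Band edges, Hz (defaults 0.01 and 0.08).
#' @param min_duration Minimal duration in seconds for a meaningful slow
#'   band-pass (default 200).
#' @return An `fc_matrix` with band `"bold"`.
#' @export
bold_fc <- function(bold, fs = NULL, lo = 0.01, hi = 0.08,
                    min_duration = 200) {
  if (inherits(bold, "bold_sim")) {
    fs <- bold$fs
    bold <- bold$bold
  }
  if (is.null(fs)) stop("fs required")
  bold <- as.matrix(bold)
  if (nrow(bold) / fs < min_duration)
    stop("BOLD record shorter than ", min_duration, " s")
  flt <- apply(bold, 2, function(x) bandpass_filter(x, fs, lo, hi))
  pearson_fc(flt, "bold")
}

# pairwise Pearson with constant-column guard
pearson_fc <- function(m, band_name) {
  N <- ncol(m)
  sds <- apply(m, 2, sd)
  bad <- sds < 1e-12
  vals <- matrix(0, N, N)
  ok <- which(!bad)
  if (length(ok) >= 2) vals[ok, ok] <- cor(m[, ok, drop = FALSE])
  if (any(bad)) warning("constant signal in region(s) ",
                        paste(which(bad), collapse = ", "),
                        "; their FC set to 0")
  fc_matrix(vals, band_name, nrow(m))
}

#' Read / write an FC matrix as CSV
#'
#' CSV with a header of region labels; the band is stored in a JSON sidecar
#' `<path>.json`.
#'
#' @param path CSV path.
#' @return `read_fc` returns an `fc_matrix`.
#' @export
read_fc <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  band <- "unknown"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    band <- jsonlite::read_json(sidecar)$band %||% "unknown"
  fc_matrix(m, band, NA_integer_)
}

#' @rdname read_fc
#' @param fc An `fc_matrix` to write.
#' @export
write_fc <- function(fc, path) {
  utils::write.csv(as.data.frame(unclass(fc)), path, row.names = FALSE)
  jsonlite::write_json(list(band = attr(fc, "band"),
                            n_samples = attr(fc, "n_samples")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
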