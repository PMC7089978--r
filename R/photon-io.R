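# Photon-stream data model and I/O.
#
# Interchange format: a columnar text dialect,
#   header lines  "# key=value"   (sync_rate_hz and duration_s recognised,
#                                  other keys land in metadata)
#   records       "macrotime<TAB>microtime_ps<TAB>channel", one per line.
# Macrotimes are integer sync counts; keeping them as counts (not seconds)
# preserves exactness over a 60 s acquisition.

#' Construct a TTTRTrace
#'
#' @param macrotimes numeric, non-decreasing integer sync counts.
#' @param microtimes numeric, picoseconds within the sync period.
#' @param channels integer detector ids (recycled if length 1).
#' @param syncRate numeric, Hz.
#' @param duration numeric, acquisition length (s). Defaults to the span of
#'   the records.
#' @param metadata named list of condition labels.
#' @param labels optional integer per-photon ground-truth states.
#' @return a [TTTRTrace-class]
#' @examples
#' tr <- TTTRTrace(c(0, 40, 80), c(500, 1200, 300), syncRate = 4e7)
#' nPhotons(tr)
#' @export
TTTRTrace <- function(macrotimes, microtimes,
                      channels = rep.int(0L, length(macrotimes)),
                      syncRate = 4e7, duration = NULL, metadata = list(),
                      labels = integer(0)) {
  if (length(channels) == 1L)
    channels <- rep.int(as.integer(channels), length(macrotimes))
  if (is.null(duration)) {
    duration <- if (length(macrotimes))
      macrotimes[length(macrotimes)] / syncRate else 0
  }
  new("TTTRTrace", macrotimes = as.numeric(macrotimes),
      microtimes = as.numeric(microtimes), channels = as.integer(channels),
      syncRate = as.numeric(syncRate), duration = as.numeric(duration),
      metadata = metadata, labels = as.integer(labels))
}

#' Read a photon stream from the columnar text format
#'
#' Parses the tab-separated photon dialect (see package vignette): `#`
#' header lines with `key=value` pairs, then one
#' `macrotime<TAB>microtime_ps<TAB>channel` record per line. Malformed
#' records and non-monotonic macrotimes raise errors naming the first
#' offending line.
#'
#' @param path file path.
#' @param formatHint only `"text"` is supported; other values error.
#' @return a validated [TTTRTrace-class]
#' @seealso [writePhotonFile()]
#' @export
readPhotonFile <- function(path, formatHint = "text") {
  if (!identical(formatHint, "text"))
    stop("unsupported photon format '", formatHint,
         "': only the columnar text dialect is supported")
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_head <- grepl("^\\s*#", lines)
  # header block must be leading; later '#' lines are treated as malformed
  n_head <- match(FALSE, is_head, nomatch = length(lines) + 1L) - 1L
  header <- lines[seq_len(n_head)]
  body <- lines[seq.int(n_head + 1L, length.out = length(lines) - n_head)]
  body_line_no <- seq.int(n_head + 1L, length.out = length(body))
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_line_no <- body_line_no[keep]

  meta <- list()
  for (h in header) {
    kv <- regmatches(h, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", h))[[1]]
    if (length(kv) == 3) {
      val <- trimws(kv[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[kv[2]]] <- if (!is.na(num)) num else val
    }
  }
  sync_rate <- if (!is.null(meta$sync_rate_hz)) meta$sync_rate_hz else 4e7
  duration <- meta$duration_s
  meta$sync_rate_hz <- NULL; meta$duration_s <- NULL

  if (!length(body)) {
    return(TTTRTrace(numeric(0), numeric(0), integer(0),
                     syncRate = sync_rate,
                     duration = if (is.null(duration)) 0 else duration,
                     metadata = meta))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1]
    stop(sprintf("parse error at line %d of %s: expected 3 tab-separated fields, got %d",
                 body_line_no[bad], path, nf[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 body_line_no[bad], path))
  }
  if (any(diff(m[, 1]) < 0)) {
    bad <- which(diff(m[, 1]) < 0)[1] + 1L
    stop(sprintf("validation error at line %d of %s: macrotimes not non-decreasing",
                 body_line_no[bad], path))
  }
  TTTRTrace(m[, 1], m[, 2], as.integer(m[, 3]), syncRate = sync_rate,
            duration = duration, metadata = meta)
}

#' Write a photon stream in the columnar text format
#'
#' @param trace a [TTTRTrace-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writePhotonFile <- function(trace, path) {
  stopifnot(is(trace, "TTTRTrace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sync_rate_hz=%.10g", trace@syncRate), con)
  writeLines(sprintf("# duration_s=%.10g", trace@duration), con)
  for (k in names(trace@metadata)) {
    v <- trace@metadata[[k]]
    if (length(v) == 1 && (is.numeric(v) || is.character(v)))
      writeLines(sprintf("# %s=%s", k,
                         if (is.numeric(v)) sprintf("%.10g", v) else v), con)
  }
  if (nPhotons(trace))
    writeLines(sprintf("%.0f\t%.0f\t%d", trace@macrotimes, trace@microtimes,
                       trace@channels), con)
  invisible(path)
}

#' Bin a photon stream into an intensity time trace
#'
#' Photon `k` falls into bin `floor(t_k / binWidth)` (half-open bins, right
#' boundary exclusive). Total counts are conserved.
#'
#' @param trace a [TTTRTrace-class]
#' @param binWidth bin width in seconds (> 0).
#' @return an [IntensityTrace-class] spanning the acquisition duration
#' @examples
#' tr <- TTTRTrace(c(0, 10, 20, 4e6), rep(100, 4))
#' counts(binIntensity(tr, 0.05))
#' @export
binIntensity <- function(trace, binWidth) {
  stopifnot(is(trace, "TTTRTrace"))
  if (!is.numeric(binWidth) || length(binWidth) != 1 || !is.finite(binWidth) ||
      binWidth <= 0)
    stop("binWidth must be a single positive number")
  n_bins <- max(1L, as.integer(ceiling(trace@duration / binWidth - 1e-9)))
  if (!nPhotons(trace))
    return(new("IntensityTrace", binWidth = binWidth,
               counts = numeric(n_bins), originTime = 0))
  idx <- floor(arrivalTimes(trace) / binWidth)
  n_bins <- max(n_bins, as.integer(max(idx)) + 1L)
  cnt <- tabulate(as.integer(idx) + 1L, nbins = n_bins)
  new("IntensityTrace", binWidth = binWidth, counts = as.numeric(cnt),
      originTime = 0)
}

#' Build a TCSPC histogram of photon microtimes
#'
#' Channel index is `floor(microtime / channelWidth)`; the grid spans one
#' sync period. Default channel width 16 ps, finer than either instrument
#' response (38 ps green / 110 ps red detection path).
#'
#' @param trace a [TTTRTrace-class]
#' @param channelWidth channel width in picoseconds.
#' @return a [TCSPCHistogram-class]
#' @export
buildTCSPCHistogram <- function(trace, channelWidth = 16) {
  stopifnot(is(trace, "TTTRTrace"))
  if (!is.numeric(channelWidth) || length(channelWidth) != 1 ||
      !is.finite(channelWidth) || channelWidth <= 0)
    stop("channelWidth must be a single positive number")
  period <- 1e12 / trace@syncRate
  n_ch <- as.integer(ceiling(period / channelWidth - 1e-9))
  cnt <- if (nPhotons(trace))
    tabulate(as.integer(trace@microtimes %/% channelWidth) + 1L, nbins = n_ch)
  else numeric(n_ch)
  new("TCSPCHistogram", channelWidth = channelWidth, counts = as.numeric(cnt),
      syncPeriod = period)
}

#' Read / write histograms as two-column CSV
#'
#' Histograms and measured IRFs are exchanged as CSV with columns
#' `channel_start_ps, counts`.
#'
#' @param hist a [TCSPCHistogram-class]
#' @param path file path
#' @return `readHistogramCsv`: a [TCSPCHistogram-class];
#'   `writeHistogramCsv`: `path` invisibly.
#' @export
writeHistogramCsv <- function(hist, path) {
  stopifnot(is(hist, "TCSPCHistogram"))
  df <- data.frame(
    channel_start_ps = (seq_along(hist@counts) - 1) * hist@channelWidth,
    counts = hist@counts)
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHistogramCsv
#' @param syncPeriod picoseconds; default inferred from the channel span.
#' @export
readHistogramCsv <- function(path, syncPeriod = NULL) {
  df <- read.table(path, sep = ",", header = TRUE)
  if (ncol(df) < 2) stop("expected columns channel_start_ps, counts")
  w <- if (nrow(df) > 1) df[[1]][2] - df[[1]][1] else df[[1]][1] + 1
  if (is.null(syncPeriod)) syncPeriod <- nrow(df) * w
  new("TCSPCHistogram", channelWidth = w, counts = as.numeric(df[[2]]),
      syncPeriod = syncPeriod)
}

#' Serialize a correlation curve as CSV
#'
#' Columns `lag_s, g, weight`.
#' @param curve a [CorrelationCurve-class]
#' @param path file path
#' @export
writeCorrelationCsv <- function(curve, path) {
  stopifnot(is(curve, "CorrelationCurve"))
  df <- data.frame(lag_s = curve@lags, g = curve@g, weight = curve@weights)
  attr_line <- sprintf("# total_photons=%.10g mean_rate=%.10g bin_width=%.10g",
                       curve@totalPhotons, curve@meanRate, curve@binWidth)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCorrelationCsv
#' @export
readCorrelationCsv <- function(path) {
  lines <- readLines(path)
  meta <- c(total_photons = 0, mean_rate = 0, bin_width = NA_real_)
  if (grepl("^#", lines[1])) {
    for (nm in names(meta)) {
      m <- regmatches(lines[1], regexec(paste0(nm, "=([0-9.eE+-]+)"), lines[1]))[[1]]
      if (length(m) == 2) meta[nm] <- as.numeric(m[2])
    }
    lines <- lines[-1]
  }
  df <- read.table(text = lines, sep = ",", header = TRUE)
  new("CorrelationCurve", lags = df$lag_s, g = df$g,
      weights = as.numeric(df$weight), totalPhotons = meta[["total_photons"]],
      meanRate = meta[["mean_rate"]], binWidth = meta[["bin_width"]])
}
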