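#' Build a probe track from positions and replicate intensities
#'
#' @param chrom chromosome per probe.
#' @param start 0-based probe start per probe (strictly increasing within
#'   a chromosome).
#' @param intensities numeric matrix, probes x replicates; all values
#'   must be positive.
#' @param genome optional named vector of chromosome lengths.
#' @return a `probe_track` object.
#' @export
probe_track <- function(chrom, start, intensities, genome = NULL) {
  intensities <- as.matrix(intensities)
  if (length(chrom) != length(start) || nrow(intensities) != length(start))
    stop("chrom, start and intensity rows must align")
  if (ncol(intensities) < 1L) stop("at least one replicate is required")
  if (any(intensities <= 0)) stop("intensities must be positive")
  for (ch in unique(chrom)) {
    p <- start[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("probe positions must be strictly increasing on ", ch)
  }
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 intensities = intensities, genome = genome),
            class = "probe_track")
}

#' Quantile-normalize intensity columns to a common distribution
#'
#' Every sample (column) is mapped onto the mean of the column-wise
#' sorted values; ties receive the average of the values they span, so
#' rank order within each column is preserved and all columns end up
#' with identical sorted values.
#'
#' @param x numeric matrix (probes x samples) or a list of equal-length
#'   numeric vectors.
#' @return matrix of the same shape (or list, matching the input).
#' @examples
#' quantile_normalize(cbind(a = c(1, 2), b = c(3, 4)))
#' @export
quantile_normalize <- function(x) {
  was_list <- is.list(x) && !is.data.frame(x)
  if (was_list) {
    if (length(unique(lengths(x))) != 1L)
      stop("ragged input: all samples must have the same probe count")
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (anyNA(x)) stop("missing values are not supported")
  n <- nrow(x)
  if (n == 0L) return(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")
    out[, j] <- if (n == 1L) ref else stats::approx(seq_len(n), ref, xout = r)$y
  }
  out
}

#' Per-probe log2 IP/input ratio from replicate-averaged intensities
#'
#' Replicates are averaged on the linear intensity scale before the log2
#' ratio is taken.
#'
#' @param ip,input `probe_track` objects on identical probe grids.
#' @return an (unsmoothed) `binding_profile`; `smoothed` equals the raw
#'   ratio until [smooth_profile()] is applied.
#' @export
ratio_profile <- function(ip, input) {
  stopifnot(inherits(ip, "probe_track"), inherits(input, "probe_track"))
  if (!identical(ip$chrom, input$chrom) || !identical(ip$start, input$start))
    stop("IP and input probe grids differ")
  m_ip <- rowMeans(ip$intensities)
  m_in <- rowMeans(input$intensities)
  if (any(m_ip <= 0) || any(m_in <= 0))
    stop("non-positive mean intensity")
  ratio <- log2(m_ip / m_in)
  structure(
    data.frame(chrom = ip$chrom, start = ip$start, ratio = ratio,
               smoothed = ratio, positive = ratio > 0,
               stringsAsFactors = FALSE),
    genome = ip$genome,
    class = c("binding_profile", "data.frame"))
}

# Windowed statistics on a sorted position grid.  Window is
# [pos - half, pos + half], inclusive at both edges, and never crosses
# chromosome boundaries (callers split by chromosome).
window_mean <- function(pos, values, half) {
  hi <- findInterval(pos + half, pos)
  lo <- findInterval(pos - half - 1e-9, pos) + 1L
  cs <- c(0, cumsum(values))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

window_fraction <- function(pos, flag, half) {
  window_mean(pos, as.numeric(flag), half)
}

#' Smooth a binding profile with a centred base-pair window
#'
#' Each probe's smoothed value is the mean of raw ratios of all probes
#' whose start lies within `window_bp / 2` of its own start (inclusive at
#' both edges); windows never cross chromosome boundaries.
#'
#' @param profile a `binding_profile`.
#' @param window_bp window width in bp (default 500).
#' @return the profile with updated `smoothed` and `positive` columns.
#' @export
smooth_profile <- function(profile, window_bp = 500) {
  stopifnot(inherits(profile, "binding_profile"))
  if (window_bp <= 0) stop("window_bp must be positive")
  half <- window_bp / 2
  sm <- profile$ratio
  for (ch in unique(profile$chrom)) {
    i <- which(profile$chrom == ch)
    sm[i] <- window_mean(profile$start[i], profile$ratio[i], half)
  }
  profile$smoothed <- sm
  profile$positive <- sm > 0
  profile
}
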