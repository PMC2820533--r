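#' Read a bedGraph file into an interval track
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based
#' half-open.  Overlapping intervals within a chromosome are rejected;
#' malformed lines are reported with their line number.  Track and
#' comment lines are skipped.
#'
#' @param path file path.
#' @return data frame `chrom`, `start`, `end`, `value`, sorted by
#'   chromosome (order of first appearance) then start.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), value = numeric(),
                    stringsAsFactors = FALSE)
  if (!any(keep)) return(out)
  ln <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed bedGraph line ", ln[which(nf != 4L)[1]],
         ": expected 4 tab-separated fields")
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 4]))
  bad <- which(is.na(start) | is.na(end) | is.na(value) | end <= start)
  if (length(bad))
    stop("malformed bedGraph line ", ln[bad[1]],
         ": non-numeric fields or end <= start")
  out <- data.frame(chrom = m[, 1], start = start, end = end, value = value,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, unique(out$chrom)), out$start), ]
  rownames(out) <- NULL
  check_intervals(out, what = "bedGraph interval")
  out
}

#' Write an interval track as bedGraph
#'
#' @param track data frame with `chrom`, `start`, `end`, `value` (a
#'   `binding_profile` is converted using its probe spacing; the
#'   smoothed value is written).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  if (inherits(track, "binding_profile")) {
    sp <- probe_spacing_of(track)
    track <- data.frame(chrom = track$chrom, start = track$start,
                        end = track$start + sp, value = track$smoothed)
  }
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, as.integer(track$start),
                   as.integer(track$end),
                   formatC(track$value, format = "g", digits = 10))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a bedGraph track into a binding profile
#'
#' Interval starts become probe starts and values become the smoothed
#' log2 ratio (positivity = value > 0), matching the exported smoothed
#' profile format.
#'
#' @param track data frame from [read_bedgraph()].
#' @param genome optional named chromosome lengths.
#' @return a `binding_profile`.
#' @export
track_to_profile <- function(track, genome = NULL) {
  structure(
    data.frame(chrom = track$chrom, start = track$start,
               ratio = track$value, smoothed = track$value,
               positive = track$value > 0, stringsAsFactors = FALSE),
    genome = genome,
    class = c("binding_profile", "data.frame"))
}

#' Read a BED file (BED3/BED6/BED12)
#'
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`; coordinates stay 0-based half-open.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  if (!any(keep))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  ln <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", ln[which(nf < 3L)[1]],
         ": fewer than 3 fields")
  ncol_use <- min(nf)
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_use)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad))
    stop("malformed BED line ", ln[bad[1]], ": start >= end")
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (ncol_use >= 4L) out$name <- m[, 4]
  if (ncol_use >= 5L) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol_use >= 6L) out$strand <- m[, 6]
  out <- out[order(match(out$chrom, unique(out$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Write intervals as BED
#'
#' Domain sets are written as BED5 with score = mean window density x
#' 1000; gene tables as BED6 with strand.  Output is sorted.
#'
#' @param x a `domain_set`, `gene_table`, or plain interval data frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- x[order(match(x$chrom, unique(x$chrom)), x$start), , drop = FALSE]
  if (inherits(x, "domain_set")) {
    nm <- sprintf("NAR_%04d", seq_len(nrow(x)))
    score <- if (nrow(x)) as.integer(round(1000 * x$mean_density)) else integer()
    lines <- sprintf("%s\t%d\t%d\t%s\t%d", x$chrom, as.integer(x$start),
                     as.integer(x$end), nm, score)
  } else if (inherits(x, "gene_table")) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), x$gene_id, x$strand)
  } else {
    nm <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
    lines <- sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), nm)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a voxel stack as plain text
#'
#' Portable text exchange format for simulated image stacks: a header
#' line `#dims nx ny nz`, then one z-slice per line of space-separated
#' intensities in column-major order.  (Binary TIFF is deliberately not
#' used so fixtures remain plain text.)
#'
#' @param x 3D numeric array.
#' @param path file path.
#' @return `write_stack`: the path, invisibly; `read_stack`: the array.
#' @export
write_stack <- function(x, path) {
  stopifnot(length(dim(x)) == 3L)
  d <- dim(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#dims %d %d %d", d[1], d[2], d[3]), con)
  for (z in seq_len(d[3]))
    writeLines(paste(formatC(x[, , z], format = "g", digits = 8),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  lines <- readLines(path)
  if (!grepl("^#dims ", lines[1])) stop("missing #dims header")
  d <- as.integer(strsplit(sub("^#dims ", "", lines[1]), " ")[[1]])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), " +")))
  if (length(vals) != prod(d)) stop("stack payload does not match dims")
  array(vals, dim = d)
}
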