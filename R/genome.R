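#' Describe a genome and its tiling-probe layout
#'
#' A `genome_spec` fixes the chromosome complement, the regular probe
#' spacing of the emulated tiling array, and a seed.  Probe spacing
#' defaults to 35 bp (25-mer probes plus a 10 bp gap, typical of dense
#' genome tiling designs).
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param probe_spacing distance between consecutive probe starts, bp.
#' @param seed integer seed recorded with the spec.
#' @return an object of class `genome_spec`.
#' @examples
#' genome_spec(c(chr2L = 1e6, chrX = 5e5))
#' @export
genome_spec <- function(chromosomes, probe_spacing = 35L, seed = 1L) {
  if (length(chromosomes) == 0L) stop("at least one chromosome is required")
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chromosomes)))
    stop("duplicated chromosome names")
  if (any(!is.finite(chromosomes)) || any(chromosomes <= 0))
    stop("chromosome lengths must be positive")
  if (!is.finite(probe_spacing) || probe_spacing <= 0)
    stop("probe_spacing must be positive")
  structure(
    list(chromosomes = chromosomes, probe_spacing = as.integer(probe_spacing),
         seed = as.integer(seed)),
    class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", length(x$chromosomes), " chromosome(s), ",
      format(sum(x$chromosomes), big.mark = ","), " bp total, probe spacing ",
      x$probe_spacing, " bp\n", sep = "")
  invisible(x)
}

#' Generate the probe layout for a genome
#'
#' Probes start at 0 and are placed every `probe_spacing` bp; each
#' chromosome carries `floor(length / spacing)` probes.  The layout is
#' fully determined by the spec.
#'
#' @param spec a [genome_spec()].
#' @return a `probe_layout` data frame with columns `chrom` and `start`
#'   (0-based), carrying `spacing` and `genome` attributes.
#' @examples
#' nrow(generate_probe_layout(genome_spec(c(chr1 = 350), probe_spacing = 35)))
#' @export
generate_probe_layout <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  sp <- spec$probe_spacing
  parts <- lapply(names(spec$chromosomes), function(ch) {
    n <- floor(spec$chromosomes[[ch]] / sp)
    if (n == 0L) return(NULL)
    data.frame(chrom = rep(ch, n), start = (seq_len(n) - 1L) * sp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer())
  structure(out, spacing = sp, genome = spec$chromosomes,
            class = c("probe_layout", "data.frame"))
}

# Shared accessors -----------------------------------------------------------

probe_spacing_of <- function(x) {
  sp <- attr(x, "spacing")
  if (!is.null(sp)) return(sp)
  d <- unlist(lapply(split(x$start, x$chrom), function(p) diff(sort(p))))
  if (length(d) == 0L) stop("cannot infer probe spacing from a single probe")
  as.integer(stats::median(d))
}

genome_of <- function(x) attr(x, "genome")

check_same_genome <- function(a, b) {
  ga <- genome_of(a); gb <- genome_of(b)
  if (!is.null(ga) && !is.null(gb) &&
      !identical(sort(names(ga)), sort(names(gb))))
    stop("chromosome sets differ between the two objects")
  invisible(TRUE)
}

# Validate a data.frame of intervals (chrom, start, end; 0-based half-open)
check_intervals <- function(x, genome = NULL, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(TRUE))
  if (any(x$end <= x$start))
    stop(what, "s must satisfy end > start")
  if (!is.null(genome)) {
    bad <- !(x$chrom %in% names(genome)) | x$start < 0 |
      x$end > genome[x$chrom]
    if (any(bad))
      stop(what, " outside genome bounds: row ", which(bad)[1])
  }
  for (ch in unique(x$chrom)) {
    xi <- x[x$chrom == ch, , drop = FALSE]
    xi <- xi[order(xi$start), , drop = FALSE]
    if (nrow(xi) > 1L && any(xi$start[-1] < xi$end[-nrow(xi)]))
      stop("overlapping ", what, "s on ", ch)
  }
  invisible(TRUE)
}
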