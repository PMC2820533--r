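#' Simulate a probe-level binding profile with planted domains
#'
#' Each probe receives a Bernoulli "positive" label: probability `p_in`
#' inside a planted domain, `p_out` elsewhere.  A continuous log2 ratio
#' is attached by drawing a half-normal magnitude (scale 0.5) and signing
#' it by the label, so only the sign carries the planted structure —
#' exactly what the downstream density-based domain caller consumes.
#' The returned profile has `smoothed` equal to the raw ratio (the
#' synthetic ratios already encode final positivity; smoothing real
#' tracks is done by [smooth_profile()]).
#'
#' @param layout a [generate_probe_layout()] result.
#' @param domains planted domains: data frame with columns `chrom`,
#'   `start`, `end` (0-based half-open) and optionally per-domain `p_in`.
#'   `NULL` means no domains.
#' @param p_in,p_out probability that a probe inside / outside a domain
#'   is positive; must satisfy `0 <= p_out < p_in <= 1` (when domains are
#'   present).
#' @param scale half-normal scale of the ratio magnitudes.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return a `binding_profile` data frame with columns `chrom`, `start`,
#'   `ratio`, `smoothed`, `positive` and a logical `in_domain` column
#'   recording the planted truth.
#' @examples
#' lay <- generate_probe_layout(genome_spec(c(chr1 = 1e5)))
#' dom <- data.frame(chrom = "chr1", start = 2e4, end = 5e4)
#' prof <- generate_binding_profile(lay, dom, p_in = 1, p_out = 0, seed = 1)
#' mean(prof$positive[prof$in_domain])
#' @export
generate_binding_profile <- function(layout, domains = NULL, p_in = 0.9,
                                     p_out = 0.3, scale = 0.5, seed = NULL) {
  stopifnot(inherits(layout, "probe_layout"))
  genome <- genome_of(layout)
  if (!is.null(domains) && nrow(domains) > 0) {
    check_intervals(domains, genome, what = "planted domain")
    pin <- if ("p_in" %in% names(domains)) domains$p_in else rep(p_in, nrow(domains))
    if (any(pin > 1) || any(p_out < 0) || any(p_out >= pin))
      stop("need 0 <= p_out < p_in <= 1")
  } else {
    domains <- NULL
    if (p_out < 0 || p_out > 1) stop("p_out must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(layout)
  p <- rep(p_out, n)
  in_domain <- rep(FALSE, n)
  if (!is.null(domains)) {
    for (i in seq_len(nrow(domains))) {
      sel <- layout$chrom == domains$chrom[i] &
        layout$start >= domains$start[i] & layout$start < domains$end[i]
      p[sel] <- pin[i]
      in_domain[sel] <- TRUE
    }
  }
  lab <- rbinom(n, 1L, p) == 1L
  mag <- abs(rnorm(n, 0, scale))
  mag[mag == 0] <- scale * 1e-6   # keep strict sign information
  ratio <- ifelse(lab, mag, -mag)
  structure(
    data.frame(chrom = layout$chrom, start = layout$start, ratio = ratio,
               smoothed = ratio, positive = ratio > 0, in_domain = in_domain,
               stringsAsFactors = FALSE),
    spacing = probe_spacing_of(layout), genome = genome,
    class = c("binding_profile", "data.frame"))
}

#' @export
print.binding_profile <- function(x, ...) {
  cat("<binding_profile> ", nrow(x), " probes on ",
      length(unique(x$chrom)), " chromosome(s); ",
      round(100 * mean(x$positive), 1), "% positive\n", sep = "")
  invisible(x)
}

#' Simulate a gene table conditioned on planted domains
#'
#' Genes are placed without overlap by slotting each chromosome into
#' equal-sized bins and drawing one gene per bin.  Expression calls are
#' Bernoulli conditional on domain membership (defaults 0.63 inside vs
#' 0.40 outside, the contrast the enrichment stage is designed to
#' detect); differential-expression labels are drawn with a higher
#' down-regulation probability inside domains.
#'
#' @param layout probe layout (supplies the genome) or a `genome_spec`.
#' @param domains planted domain data frame (may be `NULL` or empty).
#' @param n_genes number of genes to place.
#' @param gene_length fixed gene length, bp.
#' @param p_expr_in,p_expr_out P(expressed) inside / outside domains.
#' @param p_down_in,p_down_out P(down-regulated) inside / outside.
#' @param p_up P(up-regulated), independent of membership.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return a `gene_table` data frame: `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `expressed`, `de_status` (down/up/unchanged) and the
#'   planted membership `in_domain`.
#' @export
generate_gene_table <- function(layout, domains = NULL, n_genes = 200,
                                gene_length = 2000,
                                p_expr_in = 0.63, p_expr_out = 0.40,
                                p_down_in = 0.25, p_down_out = 0.10,
                                p_up = 0.08, seed = NULL) {
  genome <- if (inherits(layout, "genome_spec")) layout$chromosomes
            else genome_of(layout)
  probs <- c(p_expr_in, p_expr_out, p_down_in, p_down_out, p_up)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0, 1]")
  if (!is.null(domains) && nrow(domains) > 0)
    check_intervals(domains, genome, what = "planted domain")
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      expressed = logical(),
                      de_status = character(), in_domain = logical(),
                      stringsAsFactors = FALSE)
  if (n_genes == 0)
    return(structure(empty, genome = genome,
                     class = c("gene_table", "data.frame")))
  if (!is.null(seed)) set.seed(seed)
  # apportion genes to chromosomes by length
  total <- sum(genome)
  alloc <- round(n_genes * genome / total)  # keeps chromosome names
  alloc[alloc < 0] <- 0
  # fix rounding drift
  while (sum(alloc) != n_genes) {
    i <- which.max(genome / pmax(alloc, 1L))
    alloc[i] <- alloc[i] + sign(n_genes - sum(alloc))
  }
  rows <- list()
  for (ch in names(genome)) {
    k <- alloc[[ch]]
    if (k == 0L) next
    slot <- genome[[ch]] / k
    if (slot < gene_length)
      stop("gene density exceeds genome capacity on ", ch)
    jitter <- floor(runif(k) * (slot - gene_length))
    start <- floor((seq_len(k) - 1L) * slot) + jitter
    rows[[ch]] <- data.frame(
      chrom = rep(ch, k), start = start, end = start + gene_length,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  genes <- genes[order(match(genes$chrom, names(genome)), genes$start), ]
  genes$gene_id <- sprintf("gene%05d", seq_len(nrow(genes)))
  genes$in_domain <- interval_overlap_fraction(genes, domains) > 0.5
  p_expr <- ifelse(genes$in_domain, p_expr_in, p_expr_out)
  genes$expressed <- rbinom(nrow(genes), 1L, p_expr) == 1L
  p_down <- ifelse(genes$in_domain, p_down_in, p_down_out)
  u <- runif(nrow(genes))
  genes$de_status <- ifelse(u < p_down, "down",
                     ifelse(u < p_down + p_up, "up", "unchanged"))
  genes <- genes[, c("gene_id", "chrom", "start", "end", "strand",
                     "expressed", "de_status", "in_domain")]
  rownames(genes) <- NULL
  structure(genes, genome = genome, class = c("gene_table", "data.frame"))
}

# Fraction of each interval in `x` covered by the (non-overlapping)
# intervals in `y`; both 0-based half-open data frames.
interval_overlap_fraction <- function(x, y) {
  if (nrow(x) == 0L) return(numeric(0))
  if (is.null(y) || nrow(y) == 0L) return(rep(0, nrow(x)))
  frac <- numeric(nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    yi <- y[y$chrom == ch, , drop = FALSE]
    if (nrow(yi) == 0L) next
    xr <- IRanges::IRanges(start = x$start[xi] + 1L, end = x$end[xi])
    yr <- IRanges::reduce(IRanges::IRanges(start = yi$start + 1L, end = yi$end))
    ov <- IRanges::findOverlaps(xr, yr)
    if (length(ov) == 0L) next
    w <- IRanges::width(IRanges::pintersect(
      xr[S4Vectors::queryHits(ov)], yr[S4Vectors::subjectHits(ov)]))
    cov <- tapply(w, S4Vectors::queryHits(ov), sum)
    frac[xi[as.integer(names(cov))]] <- cov / IRanges::width(xr)[as.integer(names(cov))]
  }
  frac
}
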