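#' Partition genes into inside / outside a domain set
#'
#' Default rule: a gene is "inside" iff more than 50% of its length is
#' covered by domain base pairs.  Alternatives: `"any"` (any overlap) and
#' `"tss"` (transcription start site falls in a domain).
#'
#' @param genes a `gene_table` (or data frame with `chrom`, `start`,
#'   `end`, and `strand` for the `"tss"` rule).
#' @param nars a `domain_set`.
#' @param rule membership rule, one of `"half"`, `"any"`, `"tss"`.
#' @return the gene table with a logical `in_domain` column replaced by
#'   the computed membership.
#' @export
partition_genes <- function(genes, nars, rule = c("half", "any", "tss")) {
  rule <- match.arg(rule)
  check_same_genome(genes, nars)
  if (nrow(genes) == 0L) {
    genes$in_domain <- logical(0)
    return(genes)
  }
  if (rule == "tss") {
    if (!"strand" %in% names(genes) || anyNA(genes$strand))
      stop("tss rule requires strands")
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
    pt <- data.frame(chrom = genes$chrom, start = tss, end = tss + 1L)
    genes$in_domain <- interval_overlap_fraction(pt, nars) > 0
  } else {
    frac <- interval_overlap_fraction(genes, nars)
    genes$in_domain <- if (rule == "half") frac > 0.5 else frac > 0
  }
  genes
}

new_enrichment_result <- function(feature, test, statistic, inside, outside,
                                  estimate, p) {
  structure(
    data.frame(feature = feature, test = test, statistic = statistic,
               inside = inside, outside = outside, estimate = estimate,
               p_value = p, q_value = NA_real_, stringsAsFactors = FALSE),
    class = c("enrichment_result", "data.frame"))
}

#' Fisher's exact test of a binary gene label against domain membership
#'
#' @param membership logical vector, TRUE = inside.
#' @param label logical vector of the same length (e.g. expressed).
#' @param feature label used in the output row.
#' @return one-row `enrichment_result` with the inside/outside label
#'   fractions, odds ratio and two-sided exact p-value.
#' @export
categorical_enrichment <- function(membership, label, feature = "feature") {
  stopifnot(is.logical(membership), is.logical(label),
            length(membership) == length(label))
  if (length(membership) == 0L) stop("empty partition")
  if (!any(membership) || all(membership))
    stop("degenerate partition: need genes both inside and outside")
  if (!any(label) || all(label))
    stop("degenerate label margin: label is constant")
  tab <- table(factor(membership, levels = c(TRUE, FALSE)),
               factor(label, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  new_enrichment_result(
    feature, "fisher", unname(ft$estimate),
    inside = mean(label[membership]), outside = mean(label[!membership]),
    estimate = unname(ft$estimate), p = ft$p.value)
}

#' Compare probe-level signal inside versus outside domains
#'
#' Positions are assigned by point-in-interval membership; inside and
#' outside values are compared with Welch's t-test (default) or the
#' Wilcoxon rank-sum test.
#'
#' @param track data frame with `chrom`, `pos`, `value` (probe-level or
#'   window-level signal).
#' @param nars a `domain_set`.
#' @param feature label used in the output row.
#' @param test `"t"` (Welch) or `"wilcox"`.
#' @return one-row `enrichment_result` (means inside/outside, statistic,
#'   two-sided p).
#' @export
signal_enrichment <- function(track, nars, feature = "signal",
                              test = c("t", "wilcox")) {
  test <- match.arg(test)
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)))
  pt <- data.frame(chrom = track$chrom, start = track$pos,
                   end = track$pos + 1L)
  inside <- interval_overlap_fraction(pt, nars) > 0
  xi <- track$value[inside]; xo <- track$value[!inside]
  if (length(xi) < 2L || length(xo) < 2L)
    stop("need at least 2 probes on each side")
  if (test == "t") {
    if (stats::var(xi) == 0 && stats::var(xo) == 0)
      stop("constant signal on both sides: t statistic undefined")
    tt <- t.test(xi, xo)
    new_enrichment_result(feature, "welch_t", unname(tt$statistic),
                          inside = mean(xi), outside = mean(xo),
                          estimate = mean(xi) - mean(xo), p = tt$p.value)
  } else {
    wt <- suppressWarnings(wilcox.test(xi, xo))
    new_enrichment_result(feature, "wilcoxon", unname(wt$statistic),
                          inside = median(xi), outside = median(xo),
                          estimate = median(xi) - median(xo), p = wt$p.value)
  }
}

#' Gene counts in tiled windows along the genome
#'
#' Windows of `window_bp` start every `offset_bp` and are kept only when
#' fully inside the chromosome; a gene counts towards every window its
#' interval overlaps.
#'
#' @param genes a `gene_table`.
#' @param genome named chromosome lengths (taken from `genes` when
#'   absent).
#' @param window_bp window width (default 20000).
#' @param offset_bp window step (default 1000); must be smaller than the
#'   window.
#' @return data frame `chrom`, `start`, `end`, `pos` (window centre),
#'   `value` (gene count), directly usable by [signal_enrichment()].
#' @export
gene_density_track <- function(genes, genome = NULL, window_bp = 20000,
                               offset_bp = 1000) {
  if (is.null(genome)) genome <- genome_of(genes)
  if (is.null(genome)) stop("genome lengths required")
  if (offset_bp >= window_bp) stop("window must exceed offset")
  out <- list()
  for (ch in names(genome)) {
    if (genome[[ch]] < window_bp) next
    starts <- seq(0, genome[[ch]] - window_bp, by = offset_bp)
    gi <- genes[genes$chrom == ch, , drop = FALSE]
    counts <- integer(length(starts))
    if (nrow(gi) > 0L) {
      wr <- IRanges::IRanges(starts + 1L, starts + window_bp)
      gr <- IRanges::IRanges(gi$start + 1L, gi$end)
      counts <- IRanges::countOverlaps(wr, gr)
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts,
                            end = starts + window_bp,
                            pos = starts + window_bp / 2, value = counts,
                            stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out)
        else data.frame(chrom = character(), start = numeric(),
                        end = numeric(), pos = numeric(), value = integer())
  rownames(df) <- NULL
  structure(df, genome = genome, class = c("data.frame"))
}

#' Fixed-width windows centred on transcription start sites
#'
#' TSS is the interval start for `+` genes and `end - 1` for `-` genes;
#' windows are `[TSS - width/2, TSS + width/2)` clipped at chromosome
#' bounds.
#'
#' @param genes gene table with strands.
#' @param width_bp window width (default 1000).
#' @param genome optional named lengths used for right-clipping.
#' @return interval data frame `chrom`, `start`, `end`, `gene_id`.
#' @export
tss_window_track <- function(genes, width_bp = 1000, genome = NULL) {
  if (nrow(genes) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), gene_id = character()))
  if (!"strand" %in% names(genes) || anyNA(genes$strand) ||
      !all(genes$strand %in% c("+", "-")))
    stop("strand information required for TSS windows")
  if (is.null(genome)) genome <- genome_of(genes)
  half <- width_bp / 2
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  start <- pmax(0, tss - half)
  end <- tss + half
  if (!is.null(genome)) end <- pmin(end, unname(genome[genes$chrom]))
  data.frame(chrom = genes$chrom, start = start, end = end,
             gene_id = if ("gene_id" %in% names(genes)) genes$gene_id
                       else as.character(seq_len(nrow(genes))),
             stringsAsFactors = FALSE)
}

#' Co-occurrence of two probe-level markers
#'
#' Probes are classified significant/not per marker by the supplied
#' cut-offs (value >= cutoff); reports the fraction significant for
#' both, the product-of-marginals expectation, and a Fisher test of the
#' 2x2 cross-classification (odds ratio < 1 indicates mutual
#' exclusivity).
#'
#' @param a,b numeric vectors of marker signal on the same probe grid.
#' @param cutoff_a,cutoff_b significance cut-offs.
#' @return list with the marginal fractions, `frac_both`,
#'   `expected_both`, `odds_ratio`, `p_value`.
#' @export
marker_cooccurrence <- function(a, b, cutoff_a, cutoff_b) {
  if (length(a) != length(b))
    stop("probe grids differ: marker vectors have different lengths")
  ma <- a >= cutoff_a
  mb <- b >= cutoff_b
  tab <- table(factor(ma, levels = c(TRUE, FALSE)),
               factor(mb, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  list(frac_a = mean(ma), frac_b = mean(mb), frac_both = mean(ma & mb),
       expected_both = mean(ma) * mean(mb),
       odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Benjamini-Hochberg step-up adjusted q-values
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the original order, capped at 1.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  q_sorted <- pmin(1, rev(cummin(rev(adj))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

#' Apply BH correction across an enrichment table
#'
#' @param results an `enrichment_result` table (rows from several tests
#'   bound together).
#' @param floor_text when TRUE, the printed table floors p below
#'   2.2e-16 to "<2.2e-16" (machine values are kept in the columns).
#' @return the table with `q_value` filled in.
#' @export
adjust_enrichment <- function(results, floor_text = FALSE) {
  results$q_value <- bh_fdr(results$p_value)
  if (floor_text)
    attr(results, "display_p") <- ifelse(results$p_value < 2.2e-16,
                                         "<2.2e-16",
                                         format(results$p_value, digits = 3))
  results
}
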