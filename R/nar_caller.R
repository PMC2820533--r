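#' Density of positively bound probes in a sliding window
#'
#' For every probe, the fraction of probes with positive smoothed signal
#' among all probes whose start lies within a `window_bp` window centred
#' on the probe start (inclusive edges, truncated at chromosome ends).
#'
#' @param profile a `binding_profile` with smoothed values.
#' @param window_bp window width in bp (default 10000).
#' @return a `density_track` data frame with columns `chrom`, `start`,
#'   `density`, `smoothed`.
#' @export
positive_probe_density <- function(profile, window_bp = 10000) {
  stopifnot(inherits(profile, "binding_profile"))
  if (window_bp <= 0) stop("window_bp must be positive")
  half <- window_bp / 2
  dens <- numeric(nrow(profile))
  for (ch in unique(profile$chrom)) {
    i <- which(profile$chrom == ch)
    dens[i] <- window_fraction(profile$start[i], profile$positive[i], half)
  }
  structure(
    data.frame(chrom = profile$chrom, start = profile$start,
               density = dens, smoothed = profile$smoothed,
               stringsAsFactors = FALSE),
    window_bp = window_bp,
    spacing = attr(profile, "spacing"), genome = genome_of(profile),
    class = c("density_track", "data.frame"))
}

new_domain_set <- function(df, theta, window_bp, genome) {
  structure(df, theta = theta, window_bp = window_bp, genome = genome,
            class = c("domain_set", "data.frame"))
}

#' @export
print.domain_set <- function(x, ...) {
  cat("<domain_set> ", nrow(x), " domain(s), ",
      format(sum(x$end - x$start), big.mark = ","), " bp total",
      if (!is.null(attr(x, "theta")))
        paste0(" (theta = ", attr(x, "theta"), ")"), "\n", sep = "")
  invisible(x)
}

empty_domain_df <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             n_probes = integer(), mean_ratio = numeric(),
             mean_density = numeric(), stringsAsFactors = FALSE)
}

# Convert runs of qualifying probes into domain intervals.  The domain
# spans [first qualifying probe start, last qualifying probe start +
# probe spacing).
runs_to_domains <- function(track, qualifying, spacing) {
  out <- list()
  for (ch in unique(track$chrom)) {
    i <- which(track$chrom == ch)
    q <- qualifying[i]
    if (!any(q)) next
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = track$start[i][starts[keep]],
      end = track$start[i][ends[keep]] + spacing,
      n_probes = r$lengths[keep],
      mean_ratio = vapply(keep, function(k)
        mean(track$smoothed[i][starts[k]:ends[k]]), numeric(1)),
      mean_density = vapply(keep, function(k)
        mean(track$density[i][starts[k]:ends[k]]), numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty_domain_df())
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Call high-density binding domains from a density track
#'
#' Maximal runs of consecutive probes whose window density strictly
#' exceeds `theta` become one domain each; a single non-qualifying probe
#' splits a domain unless `max_gap_probes` allows short gaps to be
#' bridged.
#'
#' @param density a [positive_probe_density()] track (or a
#'   `binding_profile`, in which case the density is computed first with
#'   `window_bp`).
#' @param theta density threshold in (0, 1); strictly "more than"
#'   (default 0.70).
#' @param window_bp used only when `density` is a profile.
#' @param max_gap_probes runs of up to this many non-qualifying probes
#'   between qualifying ones are absorbed (default 0).
#' @param extent `"probes"` (default): the domain spans the run of
#'   qualifying probes; `"windows"`: the union of the qualifying probes'
#'   centred windows, i.e. the probe-run extent widened by half a window
#'   on each side (clipped at chromosome bounds when known).
#' @param spacing probe spacing in bp; inferred when absent.
#' @return a `domain_set` data frame.
#' @export
call_domains <- function(density, theta = 0.70, window_bp = 10000,
                         max_gap_probes = 0L,
                         extent = c("probes", "windows"), spacing = NULL) {
  extent <- match.arg(extent)
  if (inherits(density, "binding_profile"))
    density <- positive_probe_density(density, window_bp)
  stopifnot(inherits(density, "density_track"))
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (is.null(spacing)) spacing <- probe_spacing_of(density)
  qual <- density$density > theta
  if (max_gap_probes > 0L && any(qual)) {
    for (ch in unique(density$chrom)) {
      i <- which(density$chrom == ch)
      q <- qual[i]
      r <- rle(q)
      inner <- which(!r$values & r$lengths <= max_gap_probes)
      inner <- inner[inner > 1 & inner < length(r$values)]
      r$values[inner] <- TRUE
      qual[i] <- inverse.rle(r)
    }
  }
  df <- runs_to_domains(density, qual, spacing)
  if (extent == "windows" && nrow(df)) {
    half <- attr(density, "window_bp") / 2
    genome <- genome_of(density)
    df$start <- pmax(0, df$start - half)
    df$end <- df$end - spacing + half
    if (!is.null(genome)) df$end <- pmin(df$end, unname(genome[df$chrom]))
    # widening may make neighbours touch; merge them
    for (ch in unique(df$chrom)) {
      repeat {
        i <- which(df$chrom == ch)
        if (length(i) < 2L) break
        j <- which(df$start[i][-1] <= df$end[i][-length(i)])
        if (length(j) == 0L) break
        k <- i[j[1]]
        df$end[k] <- max(df$end[k], df$end[k + 1L])
        df$n_probes[k] <- df$n_probes[k] + df$n_probes[k + 1L]
        df <- df[-(k + 1L), , drop = FALSE]
      }
    }
    rownames(df) <- NULL
  }
  new_domain_set(df, theta = theta, window_bp = attr(density, "window_bp"),
                 genome = genome_of(density))
}

#' Permute positive/negative probe labels across the genome
#'
#' Positions stay fixed; the per-probe (ratio, smoothed, positive)
#' triples are randomly permuted across all probes, preserving the
#' multiset of labels.  Used to show the domain caller is silent on
#' randomized binding.
#'
#' @param profile a `binding_profile`.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @return a `binding_profile` with permuted values.
#' @export
shuffle_binding <- function(profile, seed = NULL) {
  stopifnot(inherits(profile, "binding_profile"))
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(nrow(profile))
  for (col in intersect(c("ratio", "smoothed", "positive", "in_domain"),
                        names(profile)))
    profile[[col]] <- profile[[col]][perm]
  profile
}

#' Two-stage domain calling: strict seeds extended at a laxer threshold
#'
#' Stage 1 marks probes whose density exceeds `seed_theta`; stage 2
#' extends each seed outward probe-by-probe while the density still
#' exceeds `extend_theta`.  Implemented as: maximal runs above
#' `extend_theta` that contain at least one seed probe (equivalent, and
#' merges overlapping extensions by construction).
#'
#' @param density density track or binding profile (see [call_domains()]).
#' @param seed_theta,extend_theta thresholds in (0, 1) with
#'   `extend_theta <= seed_theta`.
#' @inheritParams call_domains
#' @return a `domain_set`.
#' @export
call_domains_two_stage <- function(density, seed_theta = 0.8,
                                   extend_theta = 0.6, window_bp = 10000,
                                   spacing = NULL) {
  if (inherits(density, "binding_profile"))
    density <- positive_probe_density(density, window_bp)
  stopifnot(inherits(density, "density_track"))
  if (seed_theta <= 0 || seed_theta >= 1 || extend_theta <= 0 ||
      extend_theta >= 1)
    stop("thresholds must be in (0, 1)")
  if (extend_theta > seed_theta) stop("extend_theta must be <= seed_theta")
  if (is.null(spacing)) spacing <- probe_spacing_of(density)
  qual <- logical(nrow(density))
  for (ch in unique(density$chrom)) {
    i <- which(density$chrom == ch)
    ext <- density$density[i] > extend_theta
    seed_p <- density$density[i] > seed_theta
    r <- rle(ext)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & vapply(seq_along(r$values), function(k)
      r$values[k] && any(seed_p[starts[k]:ends[k]]), logical(1))
    q <- logical(length(i))
    for (k in which(keep)) q[starts[k]:ends[k]] <- TRUE
    qual[i] <- q
  }
  df <- runs_to_domains(density, qual, spacing)
  new_domain_set(df, theta = extend_theta,
                 window_bp = attr(density, "window_bp"),
                 genome = genome_of(density))
}

#' Base-pair overlap between two domain sets
#'
#' @param a,b `domain_set` objects (or plain interval data frames) on the
#'   same genome.
#' @return list with `shared_bp`, `bp_a`, `bp_b`, `frac_a_in_b`,
#'   `frac_b_in_a` and the base-pair `jaccard` index.
#' @export
domain_overlap <- function(a, b) {
  check_same_genome(a, b)
  bp <- function(x) if (nrow(x)) sum(x$end - x$start) else 0
  shared <- 0
  for (ch in union(unique(a$chrom), unique(b$chrom))) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    if (nrow(ai) == 0L || nrow(bi) == 0L) next
    ar <- IRanges::reduce(IRanges::IRanges(ai$start + 1L, ai$end))
    br <- IRanges::reduce(IRanges::IRanges(bi$start + 1L, bi$end))
    shared <- shared + sum(IRanges::width(IRanges::intersect(ar, br)))
  }
  bpa <- bp(a); bpb <- bp(b)
  uni <- bpa + bpb - shared
  list(shared_bp = shared, bp_a = bpa, bp_b = bpb,
       frac_a_in_b = if (bpa > 0) shared / bpa else 0,
       frac_b_in_a = if (bpb > 0) shared / bpb else 0,
       jaccard = if (uni > 0) shared / uni else 0)
}

#' Probe-level agreement between two domain sets
#'
#' Fraction of probes inside `b`'s domains that are also inside `a`'s —
#' the "recovered at least this share of the other method's probes"
#' statistic used to compare domain callers.
#'
#' @param a,b `domain_set` objects.
#' @param layout probe layout providing probe positions.
#' @return fraction in `[0, 1]` (NA when `b` covers no probes).
#' @export
probe_agreement <- function(a, b, layout) {
  in_set <- function(set) {
    hit <- logical(nrow(layout))
    for (i in seq_len(nrow(set))) {
      hit <- hit | (layout$chrom == set$chrom[i] &
                    layout$start >= set$start[i] & layout$start < set$end[i])
    }
    hit
  }
  ia <- in_set(a); ib <- in_set(b)
  if (!any(ib)) return(NA_real_)
  sum(ia & ib) / sum(ib)
}

#' Occupancy and length statistics of a domain set
#'
#' @param domains a `domain_set`.
#' @param genome named numeric vector of chromosome lengths.
#' @param groups named list mapping group name to chromosome names;
#'   default one group covering the whole genome.
#' @return data frame with per-group occupancy percentage, domain count
#'   and length quartiles (NA when the group has no domains).
#' @export
occupancy_stats <- function(domains, genome, groups = NULL) {
  check_intervals(domains, genome, what = "domain")
  if (is.null(groups)) groups <- list(genome = names(genome))
  rows <- lapply(names(groups), function(g) {
    chs <- groups[[g]]
    if (!all(chs %in% names(genome))) stop("unknown chromosome in group ", g)
    d <- domains[domains$chrom %in% chs, , drop = FALSE]
    len <- d$end - d$start
    data.frame(group = g,
               chrom_bp = sum(genome[chs]),
               domain_bp = sum(len),
               occupancy_pct = 100 * sum(len) / sum(genome[chs]),
               n_domains = nrow(d),
               median_length = if (nrow(d)) median(len) else NA_real_,
               q1_length = if (nrow(d)) unname(quantile(len, 0.25)) else NA_real_,
               q3_length = if (nrow(d)) unname(quantile(len, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
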