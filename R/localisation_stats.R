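#' Construct a per-nucleus distance sample
#'
#' The unit of all localisation statistics: one normalized mean boundary
#' distance per nucleus for a single locus and condition.
#'
#' @param values numeric vector of per-nucleus normalized mean distances.
#' @param locus locus identifier.
#' @param condition condition label (e.g. `"mock"`, `"depleted"`).
#' @return a `distance_sample`.
#' @export
distance_sample <- function(values, locus = "locus", condition = "na") {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a distance sample needs at least one nucleus")
  if (any(!is.finite(values)) || any(values < 0))
    stop("normalized distances must be finite and non-negative")
  structure(list(locus = locus, condition = condition, values = values,
                 n = length(values)),
            class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat("<distance_sample> ", x$locus, " (", x$condition, "): n = ", x$n,
      ", median = ", round(median(x$values), 3), "\n", sep = "")
  invisible(x)
}

#' Simulate a reference distance distribution through the voxel pipeline
#'
#' For each simulated nucleus a voxelized sphere with a boundary-centred
#' (`"peripheral"`) or halfway-positioned (`"interior"`) FISH signal is
#' generated, and the full measurement chain (segmentation, distance
#' map, FISH thresholding) is run — no analytic shortcut, so
#' voxelization biases match those of measured stacks.  Nucleus-to-
#' nucleus variation comes from intensity noise, a random signal
#' direction and Gaussian jitter of the signal centre.
#'
#' @param mode `"peripheral"` or `"interior"`.
#' @param n number of nuclei.
#' @param radius nuclear radius in voxels.
#' @param signal_extent signal radius as a fraction of the nuclear
#'   radius (default 0.30).
#' @param noise_sd intensity noise SD.
#' @param center_jitter_sd SD of the per-nucleus jitter applied to the
#'   normalized signal-centre position (truncated to `[0, 1]`).
#' @param pooling `"nuclei"` returns per-nucleus mean distances (the
#'   default summary); `"voxels"` pools every signal-voxel distance from
#'   all nuclei.
#' @param refine run the lamin consistency check per nucleus.
#' @param seed integer seed; `NULL` uses the ambient RNG stream.
#' @param locus label for the resulting sample.
#' @return a `distance_sample`.
#' @export
simulate_reference <- function(mode = c("peripheral", "interior"), n = 60,
                               radius = 25, signal_extent = 0.30,
                               noise_sd = 10, center_jitter_sd = 0.05,
                               pooling = c("nuclei", "voxels"),
                               refine = FALSE, seed = NULL,
                               locus = NULL) {
  mode <- match.arg(mode)
  pooling <- match.arg(pooling)
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(locus)) locus <- paste0("sim_", mode)
  base_center <- if (mode == "peripheral") 0 else 0.5
  out <- numeric(0)
  for (i in seq_len(n)) {
    center <- min(1, max(0, base_center + rnorm(1, 0, center_jitter_sd)))
    spec <- nucleus_spec(radius = radius, signal_mode = "custom",
                         signal_center = center,
                         signal_extent = signal_extent,
                         noise_sd = noise_sd, direction = NA, seed = NULL)
    stk <- generate_nucleus_stack(spec)
    fm <- measure_nucleus(stk, refine = refine, nucleus_id = i,
                          locus = locus)
    out <- c(out, if (pooling == "nuclei") fm$normalized
                  else fm$distances_vox / fm$radius_vox)
  }
  distance_sample(out, locus = locus, condition = mode)
}

wilcox_p <- function(a, b) {
  suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))$p.value
}

#' Classify loci as peripheral / non-peripheral against two controls
#'
#' Each target is compared with the peripheral control and the interior
#' control by two-sided Wilcoxon rank-sum tests; p-values from the whole
#' batch are BH-adjusted together.  A non-significant comparison with
#' the peripheral control indicates peripheral localisation; a
#' non-significant comparison with the interior control indicates
#' non-peripheral localisation.  Both non-significant is reported as
#' `"intermediate"`, both significant as `"ambiguous"` (package
#' conventions for the two undecided cells).
#'
#' @param targets a `distance_sample` or list of them (the batch).
#' @param peripheral_ctrl,interior_ctrl control `distance_sample`s.
#' @param alpha significance level applied to the adjusted q-values.
#' @return a `localisation_call` data frame: one row per target with
#'   both p- and q-values, the call, and a low-power flag for samples
#'   with fewer than 5 nuclei.
#' @export
classify_locus <- function(targets, peripheral_ctrl, interior_ctrl,
                           alpha = 0.05) {
  if (inherits(targets, "distance_sample")) targets <- list(targets)
  stopifnot(length(targets) >= 1L,
            inherits(peripheral_ctrl, "distance_sample"),
            inherits(interior_ctrl, "distance_sample"))
  p_per <- vapply(targets, function(t)
    wilcox_p(t$values, peripheral_ctrl$values), numeric(1))
  p_int <- vapply(targets, function(t)
    wilcox_p(t$values, interior_ctrl$values), numeric(1))
  q <- bh_fdr(c(p_per, p_int))
  k <- length(targets)
  q_per <- q[seq_len(k)]
  q_int <- q[k + seq_len(k)]
  call <- ifelse(q_per >= alpha & q_int < alpha, "peripheral",
          ifelse(q_int >= alpha & q_per < alpha, "non-peripheral",
          ifelse(q_per >= alpha & q_int >= alpha, "intermediate",
                 "ambiguous")))
  low_power <- vapply(targets, function(t) t$n < 5, logical(1))
  if (any(low_power))
    warning("fewer than 5 nuclei for some targets: low-power calls")
  structure(
    data.frame(locus = vapply(targets, `[[`, character(1), "locus"),
               n = vapply(targets, `[[`, numeric(1), "n"),
               median = vapply(targets, function(t) median(t$values),
                               numeric(1)),
               p_vs_peripheral = p_per, p_vs_interior = p_int,
               q_vs_peripheral = q_per, q_vs_interior = q_int,
               call = call, low_power = low_power,
               stringsAsFactors = FALSE),
    alpha = alpha,
    class = c("localisation_call", "data.frame"))
}

#' Test for depletion-induced relocalisation away from the periphery
#'
#' Two-sided Wilcoxon rank-sum between the mock and depleted samples;
#' the locus is called relocalised when the test is significant and the
#' depleted median lies farther from the boundary.  Also reports, per
#' condition, the proportion of nuclei whose normalized distance falls
#' within the peripheral `threshold` (default 30% of the radius).
#'
#' @param mock,depleted `distance_sample`s for the two conditions.
#' @param alpha significance level.
#' @param threshold peripheral distance threshold on the normalized
#'   scale.
#' @return list with the p-value, per-condition medians and peripheral
#'   proportions, and the `relocalised` flag.
#' @export
depletion_shift <- function(mock, depleted, alpha = 0.05, threshold = 0.30) {
  stopifnot(inherits(mock, "distance_sample"),
            inherits(depleted, "distance_sample"))
  p <- wilcox_p(mock$values, depleted$values)
  med_m <- median(mock$values)
  med_d <- median(depleted$values)
  list(locus = mock$locus, p_value = p,
       median_mock = med_m, median_depleted = med_d,
       prop_peripheral_mock = mean(mock$values <= threshold),
       prop_peripheral_depleted = mean(depleted$values <= threshold),
       relocalised = (p < alpha) && (med_d > med_m))
}

#' Pool distance samples into one aggregate distribution
#'
#' @param samples list of `distance_sample`s measured on the same
#'   normalized scale.
#' @param locus label for the pooled sample.
#' @return a pooled `distance_sample` with `n` equal to the summed
#'   nucleus counts, or `NULL` for an empty group.
#' @export
aggregate_distributions <- function(samples, locus = "aggregate") {
  if (length(samples) == 0L) return(NULL)
  stopifnot(all(vapply(samples, inherits, logical(1), "distance_sample")))
  vals <- unlist(lapply(samples, `[[`, "values"))
  conds <- unique(vapply(samples, `[[`, character(1), "condition"))
  distance_sample(vals, locus = locus,
                  condition = paste(conds, collapse = "+"))
}
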