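# Density track, domain calling (single and two-stage), shuffling,
# overlap and occupancy statistics.

test_that("positive probe density counts within the centred window", {
  all_pos <- manual_profile(seq(0, 35 * 20, 35), rep(1, 21))
  expect_equal(positive_probe_density(all_pos, 10000)$density, rep(1, 21))

  none <- manual_profile(seq(0, 35 * 20, 35), rep(-1, 21))
  expect_equal(positive_probe_density(none, 10000)$density, rep(0, 21))

  alt <- manual_profile(seq(0, 35 * 10, 35), rep(c(1, -1), length.out = 11))
  d <- positive_probe_density(alt, 10000)   # window covers all 11 probes
  expect_equal(d$density, rep(6 / 11, 11))

  empty <- manual_profile(numeric(0), numeric(0))
  expect_equal(nrow(positive_probe_density(empty, 10000)), 0L)
})

test_that("call_domains groups qualifying runs with strict threshold", {
  lay <- toy_layout(len = 35 * 50)
  all_pos <- manual_profile(seq(0, 35 * 49, 35), rep(1, 50))
  ds <- call_domains(all_pos, theta = 0.7, window_bp = 10000)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$start, 0)
  expect_equal(ds$end, 35 * 49 + 35)
  expect_equal(ds$n_probes, 50L)

  # density exactly at theta is not "more than": no domains
  dens <- structure(
    data.frame(chrom = "chr1", start = seq(0, 35 * 9, 35),
               density = rep(0.70, 10), smoothed = rep(1, 10)),
    window_bp = 10000, spacing = 35,
    class = c("density_track", "data.frame"))
  expect_equal(nrow(call_domains(dens, theta = 0.70)), 0L)

  # hand-enumerated toy: 30 probes, qualifying run at probes 11..22 (1-based)
  q <- rep(0.2, 30); q[11:22] <- 0.9
  dens2 <- structure(
    data.frame(chrom = "chr1", start = seq(0, 35 * 29, 35), density = q,
               smoothed = rep(1, 30)),
    window_bp = 10000, spacing = 35,
    class = c("density_track", "data.frame"))
  ds2 <- call_domains(dens2, theta = 0.7)
  expect_equal(nrow(ds2), 1L)
  expect_equal(ds2$start, 35 * 10)
  expect_equal(ds2$end, 35 * 21 + 35)
  expect_equal(ds2$n_probes, 12L)

  expect_error(call_domains(dens2, theta = 1.2), "theta")
})

test_that("gap bridging and window extent behave as documented", {
  q <- rep(0.9, 20); q[10] <- 0.1
  dens <- structure(
    data.frame(chrom = "chr1", start = seq(0, 35 * 19, 35), density = q,
               smoothed = rep(1, 20)),
    window_bp = 10000, spacing = 35, genome = c(chr1 = 1e5),
    class = c("density_track", "data.frame"))
  expect_equal(nrow(call_domains(dens, 0.7)), 2L)              # gap splits
  expect_equal(nrow(call_domains(dens, 0.7, max_gap_probes = 1L)), 1L)

  w <- call_domains(dens, 0.7, extent = "windows")
  p <- call_domains(dens, 0.7, extent = "probes")
  expect_equal(nrow(w), 1L)   # widened flanks merge across the gap
  expect_equal(w$start, 0)    # clipped at the chromosome start
  expect_equal(w$end, p$end[2] - 35 + 5000)
})

test_that("shuffling preserves the label multiset and is reproducible", {
  lay <- toy_layout(len = 1e5)
  prof <- generate_binding_profile(lay, NULL, p_out = 0.4, seed = 1)
  sh1 <- shuffle_binding(prof, seed = 9)
  sh2 <- shuffle_binding(prof, seed = 9)
  expect_identical(sh1, sh2)
  expect_equal(sum(sh1$positive), sum(prof$positive))
  expect_identical(sh1$start, prof$start)
  expect_identical(sort(sh1$ratio), sort(prof$ratio))
})

test_that("two-stage calling degenerates to single-stage and handles no seeds", {
  gs <- planted_genome()
  lay <- generate_probe_layout(gs)
  prof <- generate_binding_profile(lay, planted_domains(), p_in = 0.9,
                                   p_out = 0.3, seed = 5)
  dens <- positive_probe_density(prof, 10000)
  one <- call_domains(dens, theta = 0.70)
  two <- call_domains_two_stage(dens, seed_theta = 0.70, extend_theta = 0.70)
  expect_equal(as.data.frame(two), as.data.frame(one))

  # background-only profile: no seeds, empty set
  bg <- generate_binding_profile(toy_layout(len = 5e5), NULL, p_out = 0.3,
                                 seed = 6)
  expect_equal(nrow(call_domains_two_stage(bg, 0.8, 0.6)), 0L)

  expect_error(call_domains_two_stage(dens, 0.6, 0.8), "<=")
  expect_error(call_domains_two_stage(dens, 1.2, 0.6), "0, 1")
})

test_that("domain overlap fractions and Jaccard follow interval arithmetic", {
  a <- make_domain_set("c", 0, 100)
  b <- make_domain_set("c", 50, 150)
  ov <- domain_overlap(a, b)
  expect_equal(ov$shared_bp, 50)
  expect_equal(ov$jaccard, 1 / 3)
  expect_equal(ov$frac_a_in_b, 0.5)

  same <- domain_overlap(a, a)
  expect_equal(same$jaccard, 1)
  expect_equal(same$frac_a_in_b, 1)

  disj <- domain_overlap(a, make_domain_set("c", 200, 300))
  expect_equal(disj$shared_bp, 0)
  expect_equal(disj$jaccard, 0)

  ga <- make_domain_set("c", 0, 100, genome = c(c = 1e3))
  gb <- make_domain_set("d", 0, 100, genome = c(d = 1e3))
  expect_error(domain_overlap(ga, gb), "differ")
})

test_that("occupancy statistics summarize per group", {
  gen <- c(chr1 = 1e6)
  one <- make_domain_set("chr1", 0, 250000)
  st <- occupancy_stats(one, gen)
  expect_equal(st$occupancy_pct, 25)

  emp <- make_domain_set(character(0), numeric(0), numeric(0))
  st0 <- occupancy_stats(emp, gen)
  expect_equal(st0$occupancy_pct, 0)
  expect_true(is.na(st0$median_length))

  two <- make_domain_set(c("chr1", "chr1"), c(0, 50000), c(10000, 80000))
  expect_equal(occupancy_stats(two, gen)$median_length, 20000)

  out <- make_domain_set("chr1", 9e5, 1.2e6)
  expect_error(occupancy_stats(out, gen), "bounds")

  # grouping splits chromosomes
  gen2 <- c(chrX = 1e6, chr2 = 2e6)
  d2 <- make_domain_set(c("chrX", "chr2"), c(0, 0), c(5e5, 2e5))
  g <- occupancy_stats(d2, gen2, groups = list(X = "chrX", A = "chr2"))
  expect_equal(g$occupancy_pct[g$group == "X"], 50)
  expect_equal(g$occupancy_pct[g$group == "A"], 10)
})

test_that("raising theta never increases total domain bp", {
  gs <- planted_genome()
  prof <- generate_binding_profile(generate_probe_layout(gs),
                                   planted_domains(), seed = 8)
  dens <- positive_probe_density(prof, 10000)
  bp <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9), function(th) {
    d <- call_domains(dens, th)
    if (nrow(d)) sum(d$end - d$start) else 0
  }, numeric(1))
  expect_true(all(diff(bp) <= 0))
})

test_that("no domains are called on shuffled labels up to fraction 0.5", {
  lay <- generate_probe_layout(genome_spec(c(chrN = 1e6)))
  prof <- generate_binding_profile(lay, NULL, p_out = 0.5, seed = 40)
  total <- 0
  for (s in 1:20) {
    sh <- shuffle_binding(prof, seed = s)
    total <- total + nrow(call_domains(sh, theta = 0.70, window_bp = 10000))
  }
  expect_equal(total, 0)
})
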