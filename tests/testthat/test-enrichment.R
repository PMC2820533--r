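# Gene partitioning, Fisher/t/Wilcoxon enrichment, TSS windows,
# marker co-occurrence, BH-FDR.

test_that("gene partition applies the >50% length-overlap rule", {
  nars <- make_domain_set("c", 1000, 2000)
  genes <- structure(
    data.frame(gene_id = c("in", "zero", "forty", "sixty"),
               chrom = "c",
               start = c(1100, 5000, 400, 600),
               end = c(1900, 6000, 1400, 1600),
               strand = "+", stringsAsFactors = FALSE),
    class = c("gene_table", "data.frame"))
  part <- partition_genes(genes, nars)
  # fully inside -> in; no overlap -> out; 40% covered -> out; 60% -> in
  expect_equal(part$in_domain, c(TRUE, FALSE, FALSE, TRUE))

  any_rule <- partition_genes(genes, nars, rule = "any")
  expect_equal(any_rule$in_domain, c(TRUE, FALSE, TRUE, TRUE))

  tss_rule <- partition_genes(genes, nars, rule = "tss")
  expect_equal(tss_rule$in_domain, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("Fisher enrichment matches a brute-force hypergeometric oracle", {
  # table [[63,37],[40,60]]: enumerate all tables with fixed margins
  brute_fisher <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    p_tab <- function(a) {
      # a = count in cell [1,1]
      exp(lchoose(rs[1], a) + lchoose(rs[2], cs[1] - a) - lchoose(n, cs[1]))
    }
    support <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- vapply(support, p_tab, numeric(1))
    p_obs <- p_tab(tab[1, 1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  tab <- matrix(c(63, 40, 37, 60), nrow = 2)
  membership <- rep(c(TRUE, FALSE), times = c(100, 100))
  label <- c(rep(c(TRUE, FALSE), c(63, 37)), rep(c(TRUE, FALSE), c(40, 60)))
  res <- categorical_enrichment(membership, label, "expressed")
  expect_equal(res$p_value, brute_fisher(tab), tolerance = 1e-10)
  expect_equal(res$inside, 0.63)
  expect_equal(res$outside, 0.40)
  expect_gt(res$estimate, 1)

  # symmetric table: odds ratio 1, p = 1
  sym <- categorical_enrichment(rep(c(TRUE, FALSE), each = 100),
                                rep(c(TRUE, FALSE), times = 100))
  expect_equal(sym$p_value, 1)
  expect_equal(sym$estimate, 1, tolerance = 1e-6)

  expect_error(categorical_enrichment(rep(TRUE, 10), rep(c(TRUE, FALSE), 5)),
               "degenerate")
  expect_error(categorical_enrichment(rep(c(TRUE, FALSE), 5), rep(TRUE, 10)),
               "degenerate")
})

test_that("signal enrichment detects shifts and is antisymmetric", {
  nars <- make_domain_set("c", 0, 5000)
  set.seed(3)
  pos <- seq(0, 10000 - 10, by = 10)
  inside <- pos < 5000

  # null: identical distributions -> small |t|
  tr0 <- data.frame(chrom = "c", pos = pos, value = rnorm(length(pos)))
  r0 <- signal_enrichment(tr0, nars)
  expect_lt(abs(r0$statistic), 4)

  # +1 SD shift inside, 500/side -> overwhelming significance
  v <- rnorm(length(pos)) + ifelse(inside, 1, 0)
  r1 <- signal_enrichment(data.frame(chrom = "c", pos = pos, value = v), nars)
  expect_lt(r1$p_value, 1e-6)
  expect_gt(r1$estimate, 0)

  # swapping inside/outside negates t
  swapped <- make_domain_set("c", 5000, 10000)
  r2 <- signal_enrichment(data.frame(chrom = "c", pos = pos, value = v),
                          swapped)
  expect_equal(r2$statistic, -r1$statistic, tolerance = 1e-9)

  cst <- data.frame(chrom = "c", pos = pos, value = rep(1, length(pos)))
  expect_error(signal_enrichment(cst, nars), "constant")
  expect_error(signal_enrichment(tr0[1:2, ], nars), "at least 2")

  # wilcoxon route
  rw <- signal_enrichment(data.frame(chrom = "c", pos = pos, value = v),
                          nars, test = "wilcox")
  expect_lt(rw$p_value, 1e-6)
})

test_that("gene density windows tile at the offset and count overlaps", {
  gen <- c(c = 1e5)
  genes <- structure(
    data.frame(gene_id = sprintf("g%d", 1:10), chrom = "c",
               start = seq(0, 9e4, by = 1e4),
               end = seq(0, 9e4, by = 1e4) + 500, strand = "+",
               stringsAsFactors = FALSE),
    genome = gen, class = c("gene_table", "data.frame"))
  tr <- gene_density_track(genes, gen, window_bp = 20000, offset_bp = 1000)
  # genes every 10 kb in a 20 kb window: 2 or 3 genes per window
  expect_true(all(tr$value %in% c(2L, 3L)))
  expect_equal(nrow(tr), length(seq(0, 1e5 - 2e4, by = 1000)))

  # doubling the offset halves the window count (+/- 1)
  tr2 <- gene_density_track(genes, gen, window_bp = 20000, offset_bp = 2000)
  expect_lte(abs(nrow(tr) - 2 * nrow(tr2)), 2)

  none <- gene_density_track(genes[0, ], gen)
  expect_true(all(none$value == 0))

  expect_error(gene_density_track(genes, gen, window_bp = 500,
                                  offset_bp = 1000), "exceed")
})

test_that("TSS windows follow strand and clip at chromosome bounds", {
  genes <- structure(
    data.frame(gene_id = c("gp", "gm"), chrom = "c",
               start = c(100, 100), end = c(900, 900),
               strand = c("+", "-"), stringsAsFactors = FALSE),
    genome = c(c = 1e4), class = c("gene_table", "data.frame"))
  tw <- tss_window_track(genes, 1000)
  # + strand: TSS = 100, window [-400, 600) clipped to [0, 600)
  expect_equal(tw$start[1], 0)
  expect_equal(tw$end[1], 600)
  # - strand: TSS = end - 1 = 899, centred window
  expect_equal(tw$start[2], 899 - 500)
  expect_equal(tw$end[2], 899 + 500)

  expect_equal(nrow(tss_window_track(genes[0, ])), 0L)

  genes$strand <- NA_character_
  expect_error(tss_window_track(genes), "strand")
})

test_that("marker co-occurrence reports marginals, joint and exclusivity", {
  set.seed(4)
  n <- 20000
  a <- runif(n); b <- runif(n)
  co <- marker_cooccurrence(a, b, cutoff_a = 0.7, cutoff_b = 0.7)
  # independent masks at 30%/30%: joint ~ 9%
  expect_lt(abs(co$frac_both - 0.09), 0.01)
  expect_equal(co$expected_both, co$frac_a * co$frac_b)

  same <- marker_cooccurrence(a, a, 0.7, 0.7)
  expect_equal(same$frac_both, same$frac_a)

  # disjoint masks: zero joint, odds ratio < 1
  x <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(0, 100), rep(1, 100))
  disj <- marker_cooccurrence(x, y, 0.5, 0.5)
  expect_equal(disj$frac_both, 0)
  expect_lt(disj$odds_ratio, 1)

  expect_error(marker_cooccurrence(a, b[1:10], 0.5, 0.5), "grids differ")
})

test_that("bh_fdr reproduces the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.5, NA)), "0, 1")

  # oracle: p.adjust on random vectors, order preserved
  set.seed(5)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  }
  # q >= p always
  p <- runif(100)
  expect_true(all(bh_fdr(p) >= p))
})

test_that("adjust_enrichment fills q-values and keeps machine precision", {
  tab <- rbind(
    new_enr <- categorical_enrichment(rep(c(TRUE, FALSE), each = 50),
                                      rep(c(TRUE, FALSE, TRUE, FALSE),
                                          c(40, 10, 10, 40)), "m1"))
  out <- adjust_enrichment(tab, floor_text = TRUE)
  expect_equal(out$q_value, out$p_value)  # single test
  expect_true(is.numeric(out$p_value))
})

test_that("the expressed-fraction contrast is recovered with full power", {
  # >= 500 genes on each side: domains cover half of a 2 Mb chromosome
  gs <- genome_spec(c(chrE = 2e6))
  lay <- generate_probe_layout(gs)
  dom <- data.frame(chrom = "chrE", start = seq(0, 1.8e6, by = 4e5),
                    end = seq(0, 1.8e6, by = 4e5) + 2e5)
  set.seed(55)
  est_ok <- 0; rejections <- 0
  n_seeds <- 100
  for (i in seq_len(n_seeds)) {
    g <- generate_gene_table(lay, dom, n_genes = 1600, gene_length = 1000)
    r <- categorical_enrichment(g$in_domain, g$expressed)
    if (abs(r$inside - 0.63) <= 0.05) est_ok <- est_ok + 1
    if (r$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gte(est_ok / n_seeds, 0.99)
  expect_gte(rejections / n_seeds, 0.99)
})

test_that("Fisher p-values are super-uniform under the null", {
  gs <- genome_spec(c(chrE = 2e6))
  lay <- generate_probe_layout(gs)
  dom <- data.frame(chrom = "chrE", start = seq(0, 1.8e6, by = 4e5),
                    end = seq(0, 1.8e6, by = 4e5) + 2e5)
  set.seed(56)
  rejections <- 0
  for (i in 1:500) {
    g <- generate_gene_table(lay, dom, n_genes = 300, gene_length = 1000,
                             p_expr_in = 0.5, p_expr_out = 0.5)
    if (categorical_enrichment(g$in_domain, g$expressed)$p_value < 0.05)
      rejections <- rejections + 1
  }
  expect_lte(rejections / 500, 0.06)
})
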