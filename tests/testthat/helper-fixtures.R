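# Shared fixture builders; everything is generated in code at test time.

toy_layout <- function(len = 1e5, spacing = 35, chroms = c(chr1 = 1)) {
  generate_probe_layout(genome_spec(setNames(rep(len, length(chroms)),
                                             names(chroms)),
                                    probe_spacing = spacing))
}

# Planted-domain genome used by the caller-recovery and enrichment suites:
# one 4 Mb chromosome with domains spanning the 20-100 kb length scale.
planted_genome <- function() genome_spec(c(chrA = 4e6), probe_spacing = 35)

planted_domains <- function(seed = 1) {
  set.seed(seed)
  lens <- c(20e3, 40e3, 60e3, 60e3, 80e3, 100e3)
  gaps <- 60e3 + floor(runif(length(lens) + 1) * 400e3)
  gaps <- floor(gaps * (4e6 - sum(lens) - 1e5) / sum(gaps))
  starts <- cumsum(gaps)[seq_along(lens)] +
    cumsum(c(0, lens[-length(lens)]))
  data.frame(chrom = "chrA", start = starts, end = starts + lens)
}

# Minimal profile built directly from explicit values (bypasses generators)
manual_profile <- function(start, ratio, chrom = "chr1", spacing = 35,
                           genome = NULL) {
  structure(
    data.frame(chrom = rep(chrom, length.out = length(start)),
               start = start, ratio = ratio,
               smoothed = ratio, positive = ratio > 0,
               stringsAsFactors = FALSE),
    spacing = spacing, genome = genome,
    class = c("binding_profile", "data.frame"))
}

make_domain_set <- function(chrom, start, end, genome = NULL) {
  structure(
    data.frame(chrom = rep(chrom, length.out = length(start)),
               start = start, end = end,
               n_probes = rep(NA_integer_, length(start)),
               mean_ratio = rep(NA_real_, length(start)),
               mean_density = rep(1, length(start)),
               stringsAsFactors = FALSE),
    genome = genome, class = c("domain_set", "data.frame"))
}
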