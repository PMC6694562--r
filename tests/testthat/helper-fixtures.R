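# Shared fixtures: everything is generated in code at test time.

# binomial read-sampling oracle: allele fractions observed at `depth` for
# SNVs whose true allele fraction is `vaf`
draw_mafs <- function(n, vaf, depth) {
  d <- pmax(rpois(n, depth), 1)
  rbinom(n, d, vaf) / d
}

# segments whose observed ratio/BAF are the exact expectations at `purity`
# (noiseless forward simulation through the closed-form model)
noiseless_segments <- function(purity, states,
                               chroms = as.character(seq_along(states))) {
  ctx <- sample_context(purity)
  do.call(rbind, lapply(seq_along(states), function(i) {
    st <- copy_state(states[[i]][1], states[[i]][2])
    data.frame(chrom = chroms[i], start = 1, end = 1e8,
               copy_ratio = expected_copy_ratio(ctx, st),
               baf = expected_baf(ctx, st)$baf)
  }))
}

# uniform-per-bp SNV background, all C>T/C>G, for kataegis tests
# (counts scale with chromosome length, as in real genomes)
uniform_snv_background <- function(rate_per_mb = 0.8,
                                   chroms = names(default_chrom_sizes())) {
  sizes <- default_chrom_sizes()
  do.call(rbind, lapply(chroms, function(ch) {
    n <- rpois(1, rate_per_mb * sizes[[ch]] / 1e6)
    if (n == 0) return(NULL)
    pos <- sort(sample.int(sizes[[ch]], n))
    alt <- sample(c("T", "G"), n, replace = TRUE)
    data.frame(chrom = ch, pos = pos, ref = "C", alt = alt,
               depth = 60L, alt_count = 21L, maf = 0.35)
  }))
}

# two-sided Fisher p for a 2x2 table by brute-force hypergeometric
# enumeration (independent of stats::fisher.test)
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  ks <- max(0, k - n):min(k, m)
  probs <- dhyper(ks, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
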