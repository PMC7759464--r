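#!/usr/bin/env Rscript
# Build the synthetic study inputs: a phased two-population cohort over
# two 2-Mb chromosomes with five planted divergent sweeps, an
# accessibility mask (~38% masked), a popfile, an outgroup panel for
# polarization and per-sample depths. Everything downstream reads these
# files exactly as it would read empirical data.

library(diverscan)

out <- "results/fixtures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- fixture_spec(n_chroms = 2L, chrom_bp = 2e6, model = desk_model(),
                     planted = default_planted(2e6),
                     n_samples = c(20L, 20L), masked_fraction = 0.38,
                     outgroup_n = 5L, depth_fail_frac = 0.05, seed = 20260920L)
co <- make_cohort(spec, out)

cat("wrote cohort to", out, "\n")
cat("planted loci:\n")
print(co$truth$planted)
for (ch in names(co$truth$haps)) {
  h <- co$truth$haps[[ch]]
  m <- co$truth$masks[[ch]]
  cat(sprintf("%s: %d SNPs, %.1f%% masked\n", ch, ncol(h$alleles),
              100 * (1 - accessible_bp(m, 0, m$length) / m$length)))
}
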