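mk <- function(m, pops = c("A", "B"), polarized = TRUE) {
  m <- as.matrix(m)
  ns <- nrow(m) / 2L
  pv <- if (length(unique(pops)) == 1L) rep(pops[1], ns)
  else rep(pops, each = ceiling(ns / 2))[seq_len(ns)]
  hapmat(m, seq_len(ncol(m)) * 2L, "chr1", paste0("s", seq_len(ns)),
         pv, polarized = rep(polarized, ncol(m)))
}

test_that("nucleotide diversity matches hand-computed cases", {
  h <- mk(rbind(c(0, 0), c(0, 1)), pops = c("A", "A"))
  expect_equal(nucleotide_diversity(h, NULL, 2), 0.5)
  h0 <- mk(rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0)), pops = c("A", "A"))
  expect_equal(nucleotide_diversity(h0, NULL, 10), 0)
  # n = 4, one site at derived count 2: brute force 2*2*2/(4*3)
  h2 <- mk(cbind(c(1, 1, 0, 0)), pops = c("A", "A"))
  expect_equal(nucleotide_diversity(h2, NULL, 1), 2 * 2 * 2 / (4 * 3))
  expect_warning(nucleotide_diversity(h2, NULL, 0), "accessible")
  # per-window total variant
  expect_equal(nucleotide_diversity(h2, NULL, 10, per_site = FALSE),
               10 * nucleotide_diversity(h2, NULL, 10))
})

test_that("Tajima's D: numerator identity and oracle agreement", {
  # all singletons at n = 10 gives negative D
  m <- matrix(0L, nrow = 10, ncol = 5)
  for (j in 1:5) m[j, j] <- 1L
  h <- mk(m, pops = c("A", "A"))
  expect_lt(tajimas_d(h), 0)
  expect_equal(tajimas_d(h), bf_tajd(m), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    hh <- random_hapmat(8L, 20L)
    expect_equal(tajimas_d(hh), bf_tajd(hh$alleles), tolerance = 1e-9)
  }
  expect_true(is.nan(tajimas_d(mk(matrix(0L, 4, 2), pops = c("A", "A")))))
})

test_that("Fay and Wu's H matches direct evaluation and sign checks", {
  # n = 2: theta_pi == theta_H identically
  h2 <- mk(rbind(c(0, 1, 0), c(1, 0, 1)), pops = c("A", "A"))
  expect_equal(fay_wu_h(h2), 0)
  # n = 4, single site with derived count 3: 0.5 - 1.5 = -1
  h4 <- mk(cbind(c(1, 1, 1, 0)), pops = c("A", "A"))
  expect_equal(fay_wu_h(h4), -1)
  # all-singleton data: H > 0
  m <- matrix(0L, nrow = 8, ncol = 4)
  for (j in 1:4) m[j, j] <- 1L
  expect_gt(fay_wu_h(mk(m, pops = c("A", "A"))), 0)
  # polarization-dependence: allele flip changes H on an asymmetric case
  flip <- mk(cbind(1L - c(1, 1, 1, 0)), pops = c("A", "A"))
  expect_false(isTRUE(all.equal(fay_wu_h(h4), fay_wu_h(flip))))
  # unpolarized sites are skipped
  hu <- mk(cbind(c(1, 1, 1, 0)), pops = c("A", "A"), polarized = FALSE)
  expect_true(is.nan(fay_wu_h(hu)))
})

test_that("Garud statistics match direct evaluation", {
  # two classes at 0.5/0.5
  h <- mk(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1)), pops = c("A", "A"))
  g <- garud_h(h)
  expect_equal(unname(g), c(0.5, 1.0, 0.5))
  # monomorphic interval
  g0 <- garud_h(mk(matrix(0L, 4, 3), pops = c("A", "A")))
  expect_equal(unname(g0), c(1, 1, 0))
  # frequencies (0.6, 0.3, 0.1)
  m <- rbind(matrix(rep(c(0, 0), 6), ncol = 2, byrow = TRUE),
             matrix(rep(c(1, 0), 3), ncol = 2, byrow = TRUE),
             c(1, 1))
  g3 <- garud_h(mk(m, pops = c("A", "A")))
  expect_equal(g3[["h1"]], 0.46)
  expect_equal(g3[["h12"]], 0.82)
  expect_equal(g3[["h2h1"]], (0.46 - 0.36) / 0.46)
})

test_that("1-HAF summary matches hand enumeration and is linear", {
  # n = 3 is not even; use 4 haplotypes, one site with 2 carriers:
  # scores (2, 2, 0, 0), mean 1
  h <- mk(cbind(c(1, 1, 0, 0)), pops = c("A", "A"))
  expect_equal(haf_score(h), 1)
  # doubling every column doubles the summary
  m <- rbind(c(1, 0, 1), c(0, 1, 1), c(1, 1, 0), c(0, 0, 0))
  expect_equal(haf_score(mk(cbind(m, m), pops = c("A", "A"))),
               2 * haf_score(mk(m, pops = c("A", "A"))))
  # no derived alleles anywhere (monomorphic polarized column)
  expect_equal(haf_score(mk(matrix(0L, 4, 2), pops = c("A", "A"))), 0)
})

test_that("Hudson FST follows the ratio-of-averages formula", {
  # fixed difference
  h <- mk(cbind(c(1, 1, 0, 0)))
  r <- hudson_fst(h)
  expect_equal(r$fst, 1)
  expect_equal(r$num, 1)
  expect_equal(r$den, 1)
  # p1 = p2 = 0.5 at n1 = n2 = 10
  m <- rbind(matrix(rep(c(1, 0), 5), ncol = 1),
             matrix(rep(c(1, 0), 5), ncol = 1))
  h2 <- mk(m)
  r2 <- hudson_fst(h2)
  expect_equal(r2$num, -0.05556, tolerance = 1e-3)
  expect_equal(r2$den, 0.5)
  expect_equal(r2$fst, -0.1111, tolerance = 1e-3)
  # panmictic split: near-zero in expectation over random splits
  set.seed(9)
  m <- matrix(rbinom(40 * 30, 1, 0.3), nrow = 40)
  vals <- sapply(1:100, function(i) {
    rows <- sample.int(40)
    hp <- hapmat(m[rows, ], seq_len(30) * 3L, "c",
                 paste0("x", 1:20), rep(c("A", "B"), each = 10))
    hudson_fst(hp)$fst
  })
  expect_lt(abs(mean(vals)), 0.01)
})

test_that("DXY and Gmin match pair enumeration", {
  # fixed difference at the only accessible site
  expect_equal(dxy(mk(cbind(c(1, 1, 0, 0))), accessible_bp = 1), 1)
  # n_a = n_b = 2, one of four cross pairs differs at one site, 10 bp
  h <- mk(rbind(c(0, 0), c(0, 1), c(0, 0), c(0, 1)))
  # cross pairs differ in 2 of 4 pairs at 1 site -> recompute directly
  sp <- ab_split(h)
  expect_equal(dxy(h, accessible_bp = 10), bf_dxy(sp$A, sp$B, 10))
  # distances {0, 2, 2, 4} -> min/mean = 0
  hg <- mk(rbind(c(0, 0), c(1, 1), c(0, 0), c(1, 1)))
  expect_equal(gmin(hg), 0)
  expect_equal(gmin(mk(rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0)))), 1)
})

test_that("SS-H12 sign separates shared from private modal haplotypes", {
  # same haplotype at high frequency in both populations: positive
  m <- rbind(c(1, 1), c(1, 1), c(0, 1), c(1, 1), c(1, 1), c(0, 0),
             c(1, 1), c(1, 1))
  expect_gt(ss_h12(mk(m)), 0)
  # different haplotypes fixed in each population: negative, magnitude 1
  m2 <- rbind(c(0, 0), c(0, 0), c(0, 0), c(0, 0),
              c(1, 1), c(1, 1), c(1, 1), c(1, 1))
  expect_equal(ss_h12(mk(m2)), -1)
  # identical completed sweep fixed in both: positive magnitude 1
  m3 <- rbind(c(1, 0), c(1, 0), c(1, 0), c(1, 0),
              c(1, 0), c(1, 0), c(1, 0), c(1, 0))
  expect_equal(ss_h12(mk(m3)), 1)
})

test_that("Watterson's theta matches the closed form", {
  h <- mk(matrix(c(0, 1), nrow = 2, ncol = 7), pops = c("A", "A"))
  expect_equal(watterson_theta(h, NULL, 1000), 0.007)
  expect_equal(watterson_theta(mk(matrix(0L, 4, 2),
                                  pops = c("A", "A")), NULL, 50), 0)
})

test_that("statistics agree with brute-force oracles on random matrices", {
  set.seed(1234)
  for (i in 1:60) {
    h <- random_hapmat(sample(c(8L, 12L, 16L), 1), sample(6:30, 1))
    sp <- ab_split(h)
    acc <- 100
    expect_equal(nucleotide_diversity(h, NULL, acc),
                 bf_pi(h$alleles, acc), tolerance = 1e-9)
    expect_equal(watterson_theta(h, NULL, acc),
                 bf_theta_w(h$alleles, acc), tolerance = 1e-9)
    expect_equal(tajimas_d(h), bf_tajd(h$alleles), tolerance = 1e-9)
    expect_equal(fay_wu_h(h), bf_faywu(h$alleles), tolerance = 1e-9)
    expect_equal(unname(garud_h(h)), unname(bf_garud(h$alleles)),
                 tolerance = 1e-9)
    expect_equal(haf_score(h), bf_haf(h$alleles), tolerance = 1e-9)
    expect_equal(hudson_fst(h)$fst, bf_fst(sp$A, sp$B), tolerance = 1e-9)
    expect_equal(dxy(h, accessible_bp = acc), bf_dxy(sp$A, sp$B, acc),
                 tolerance = 1e-9)
    expect_equal(gmin(h), bf_gmin(sp$A, sp$B), tolerance = 1e-9)
  }
})

test_that("haplotype statistics are invariant to row and site order", {
  set.seed(77)
  h <- random_hapmat(8L, 14L)
  g1 <- garud_h(h)
  s1 <- ss_h12(h)
  # permute sites
  perm <- sample.int(ncol(h$alleles))
  h2 <- hapmat(h$alleles[, perm][, order(perm)], h$positions, h$chrom,
               h$sample_ids, h$pop_of_sample, h$polarized)
  expect_equal(garud_h(h2), g1)
  # permute haplotypes within populations
  rows <- c(sample(1:4), sample(5:8))
  h3 <- hapmat(h$alleles[rows, ], h$positions, h$chrom, h$sample_ids,
               h$pop_of_sample, h$polarized)
  expect_equal(garud_h(h3), g1)
  expect_equal(ss_h12(h3), s1)
  g <- garud_h(h)
  expect_gte(g[["h12"]], g[["h1"]])
  expect_gte(g[["h1"]], g[["h1"]] * g[["h2h1"]])  # h1 >= h2
  # pi and dxy invariant to ancestral/derived relabelling
  hf <- hapmat(1L - h$alleles, h$positions, h$chrom, h$sample_ids,
               h$pop_of_sample, h$polarized)
  expect_equal(nucleotide_diversity(hf, NULL, 10),
               nucleotide_diversity(h, NULL, 10))
  expect_equal(dxy(hf, accessible_bp = 10), dxy(h, accessible_bp = 10))
})
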