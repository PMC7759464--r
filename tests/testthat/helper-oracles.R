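# Brute-force oracle implementations: direct pair enumeration and
# textbook formulas, kept deliberately independent of the package's
# vectorized code paths.

# random haplotype matrix fixture (no missing data unless asked)
random_hapmat <- function(n_hap = 8L, n_sites = 12L, miss_frac = 0,
                          pops = c("A", "B"), polarized = TRUE,
                          chrom = "chrT") {
  stopifnot(n_hap %% 4L == 0L)
  repeat {
    m <- matrix(rbinom(n_hap * n_sites, 1L, runif(1, 0.15, 0.6)),
                nrow = n_hap)
    seg <- colSums(m) > 0L & colSums(m) < n_hap
    if (sum(seg) >= 2L) { m <- m[, seg, drop = FALSE]; break }
  }
  if (miss_frac > 0)
    m[runif(length(m)) < miss_frac] <- NA_integer_
  ns <- n_hap / 2L
  hapmat(m, sort(sample.int(10 * ncol(m), ncol(m))), chrom,
         paste0("s", seq_len(ns)),
         rep(pops, each = ns / 2L),
         polarized = rep(polarized, ncol(m)))
}

# pairwise difference count between two haplotype vectors (complete data)
pair_diff <- function(x, y) sum(x != y)

bf_pi <- function(alle, acc) {
  n <- nrow(alle)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    tot <- tot + pair_diff(alle[i, ], alle[j, ])
  tot / choose(n, 2) / acc
}

bf_theta_w <- function(alle, acc) {
  n <- nrow(alle)
  S <- sum(colSums(alle) > 0 & colSums(alle) < n)
  S / sum(1 / seq_len(n - 1L)) / acc
}

bf_tajd <- function(alle) {
  n <- nrow(alle)
  S <- sum(colSums(alle) > 0 & colSums(alle) < n)
  if (S == 0L || n < 3L) return(NaN)
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pit <- bf_pi(alle, 1)
  (pit - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

bf_faywu <- function(alle) {
  n <- nrow(alle)
  d <- colSums(alle)
  d <- d[d > 0 & d < n]
  if (!length(d)) return(NaN)
  th_pi <- sum(2 * d * (n - d)) / (n * (n - 1))
  th_h <- sum(2 * d^2) / (n * (n - 1))
  th_pi - th_h
}

bf_garud <- function(alle) {
  p <- sort(table(apply(alle, 1, paste, collapse = "")),
            decreasing = TRUE) / nrow(alle)
  p <- as.numeric(p)
  h1 <- sum(p^2)
  p2 <- if (length(p) > 1) p[2] else 0
  h12 <- (p[1] + p2)^2 + if (length(p) > 2) sum(p[-(1:2)]^2) else 0
  c(h1 = h1, h12 = h12, h2h1 = (h1 - p[1]^2) / h1)
}

bf_haf <- function(alle) {
  d <- colSums(alle)
  mean(sapply(seq_len(nrow(alle)), function(i) sum(d[alle[i, ] == 1])))
}

bf_fst <- function(A, B) {
  num <- den <- 0
  for (s in seq_len(ncol(A))) {
    n1 <- nrow(A); n2 <- nrow(B)
    p1 <- mean(A[, s]); p2 <- mean(B[, s])
    dn <- p1 * (1 - p2) + p2 * (1 - p1)
    if (dn == 0) next
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) -
      p2 * (1 - p2) / (n2 - 1)
    den <- den + dn
  }
  if (den == 0) NaN else num / den
}

bf_dxy <- function(A, B, acc) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + pair_diff(A[i, ], B[j, ])
  tot / (nrow(A) * nrow(B)) / acc
}

bf_gmin <- function(A, B) {
  d <- c()
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    d <- c(d, pair_diff(A[i, ], B[j, ]))
  if (mean(d) == 0) NaN else min(d) / mean(d)
}

# split the allele matrix of a two-population hapmat fixture
ab_split <- function(hap) {
  pops <- rep(hap$pop_of_sample, each = 2L)
  list(A = hap$alleles[pops == "A", , drop = FALSE],
       B = hap$alleles[pops == "B", , drop = FALSE])
}

# write a small VCF text fixture
write_vcf_text <- function(path, samples, records) {
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=chr1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), path)
  path
}

# tiny demographic model for fast mechanical tests
tiny_model <- function() {
  demographic_model(ancestral_size = 60, source_size = 60,
                    colonization_time = 60, founder_size = 25,
                    split_time = 30, daughter_sizes = c(80, 80),
                    migration_rate = 2e-3, mutation_rate = 1e-6,
                    recombination_rate = 3e-6)
}

tiny_profile <- function(n_train = 3L, n_test = 2L) {
  sim_profile(locus_bp = 21000, subwindows = 21L,
              u_range = c(0.02, 0.05), r_mean = 0.05, r_max = 0.15,
              s_range = c(0.08, 0.1), n_train = n_train, n_test = n_test,
              burnin_factor = 3)
}
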