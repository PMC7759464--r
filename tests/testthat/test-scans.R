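scan_fixture <- function(seed = 1, L = 6e4, n = 24L, nsnp = 300L) {
  set.seed(seed)
  m <- matrix(rbinom(n * nsnp, 1, runif(nsnp, 0.05, 0.6)), nrow = n,
              byrow = TRUE)
  keep <- colSums(m) > 0 & colSums(m) < n
  m <- m[, keep, drop = FALSE]
  pos <- sort(sample.int(L, ncol(m)))
  hapmat(m, pos - 1L, "chr1", paste0("s", seq_len(n / 2)),
         rep(c("A", "B"), each = n / 4),
         polarized = rep(TRUE, ncol(m)))
}

test_that("FST windows honour the valid-site threshold and tiling", {
  h <- scan_fixture()
  # mask that blanks most of window [10000, 20000)
  mask <- sitemask("chr1", 6e4, cbind(10500, 19800))
  tr <- window_fst_scan(h, mask, window_bp = 10000L, min_valid = 2000L)
  expect_false(10000 %in% tr$start)  # 700 valid bp < 2000
  expect_true(all(tr$n_valid_sites >= 2000))
  expect_true(all(diff(tr$start) > 0))
  expect_equal(tr$end - tr$start, rep(10000, nrow(tr)))
  # a window of only fixed differences yields exactly 1
  mfix <- matrix(rep(c(rep(1L, 6), rep(0L, 6)), 2), ncol = 2)
  hfix <- hapmat(mfix, c(100L, 5000L), "chr1", paste0("x", 1:6),
                 rep(c("A", "B"), each = 3))
  trf <- window_fst_scan(hfix, sitemask("chr1", 1e4),
                         window_bp = 10000L, min_valid = 2000L)
  expect_equal(trf$fst, 1)
  # locality: scanning two halves equals scanning the genome
  full <- window_fst_scan(h, sitemask("chr1", 6e4))
  h1 <- hap_subset_interval(h, 0, 3e4)
  h2 <- hap_subset_interval(h, 3e4, 6e4)
  left <- window_fst_scan(h1, sitemask("chr1", 3e4))
  right <- window_fst_scan(h2, sitemask("chr1", 6e4))
  right <- right[right$start >= 3e4, ]
  expect_equal(c(left$fst, right$fst), full$fst)
})

test_that("loess smoothing reproduces polynomials and stats::loess", {
  tr <- data.frame(chrom = "c", start = seq(0, 99) * 1000,
                   end = seq(1, 100) * 1000)
  tr$fst <- 0.3
  out <- loess_smooth(tr, span = 0.3)
  expect_equal(out$smoothed, rep(0.3, 100))
  # linear trend recovered away from edges
  tr$fst <- seq(0.01, 1, length.out = 100)
  out <- loess_smooth(tr, span = 0.2, degree = 1)
  expect_equal(out$smoothed[11:90], tr$fst[11:90], tolerance = 1e-6)
  # random track matches stats::loess at matched span
  set.seed(33)
  tr$fst <- cumsum(rnorm(100, sd = 0.05))
  mine <- loess_smooth(tr, span = 0.35, degree = 1)$smoothed
  x <- (tr$start + tr$end) / 2
  ref <- stats::predict(stats::loess(fst ~ x, tr, span = 0.35, degree = 1,
                                     family = "gaussian",
                                     surface = "direct"))
  expect_equal(mine, unname(ref), tolerance = 1e-4)
  # too few windows: raw values with a warning
  short <- tr[1:5, ]
  expect_warning(s5 <- loess_smooth(short, span = 0.01), "few")
  expect_equal(s5$smoothed, short$fst)
})

test_that("tracks serialize undefined values as NA", {
  tr <- data.frame(chrom = "c", start = 0, end = 1e4,
                   n_valid_sites = 5000, fst = NaN)
  f <- tempfile()
  write_track(tr, f)
  expect_match(readLines(f)[2], "NA$")
})

test_that("the 2D SFS conserves counts, transposes and excludes", {
  h <- scan_fixture(seed = 5, n = 24L)
  sfs <- build_2dsfs(h, n_down_a = 8L, n_down_b = 8L, seed = 3)
  expect_equal(sum(sfs$counts), ncol(h$alleles))
  # population swap transposes exactly (same per-site keyed draws)
  pair <- hap_pair(h)
  swapped <- population_pair(pair$pop_b, pair$pop_a, pair$n_b, pair$n_a)
  sfs2 <- build_2dsfs(h, swapped, 8L, 8L, seed = 3)
  expect_equal(sfs2$counts, t(sfs$counts))
  # a site fixed derived in both populations lands in the corner
  hf <- hapmat(matrix(1L, 8, 1), c(5L), "chr1", paste0("s", 1:4),
               rep(c("A", "B"), each = 2), polarized = TRUE)
  sf <- build_2dsfs(hf, n_down_a = 4L, n_down_b = 4L, seed = 1)
  expect_equal(sf$counts[5, 5], 1L)
  expect_equal(sum(sf$counts), 1L)
  # sites with insufficient valid alleles are excluded
  hm <- h
  hm$alleles[1:20, 3] <- NA_integer_
  sm <- build_2dsfs(hm, n_down_a = 8L, n_down_b = 8L, seed = 3)
  expect_equal(sum(sm$counts), ncol(h$alleles) - 1L)
  # unpolarized sites never contribute
  hu <- h
  hu$polarized[] <- FALSE
  expect_equal(sum(build_2dsfs(hu, n_down_a = 8L, n_down_b = 8L,
                               seed = 3)$counts), 0L)
  expect_error(build_2dsfs(h, n_down_a = 1L), ">= 2")
})

test_that("2D SFS marginals equal independently drawn 1D spectra", {
  h <- scan_fixture(seed = 9, n = 24L)
  pair <- hap_pair(h)
  sfs <- build_2dsfs(h, pair, 8L, 8L, seed = 11)
  # independent 1D reimplementation with the same per-site keying
  keyhash <- function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))
  pops <- rep(h$pop_of_sample, each = 2L)
  sfs1d <- function(pop_label, rows, n_down) {
    out <- rep(0L, n_down + 1L)
    other <- setdiff(unique(pops), pop_label)
    orows <- pops == other
    for (j in seq_len(ncol(h$alleles))) {
      x <- h$alleles[rows, j]; xo <- h$alleles[orows, j]
      if (sum(!is.na(x)) < n_down || sum(!is.na(xo)) < n_down) next
      d <- sum(x == 1L, na.rm = TRUE); a <- sum(x == 0L, na.rm = TRUE)
      set.seed(diverscan:::derive_seed(11 + keyhash(h$chrom),
                                       h$positions[j] * 4L +
                                         keyhash(pop_label)))
      k <- rhyper(1L, d, a, n_down)
      out[k + 1L] <- out[k + 1L] + 1L
    }
    out
  }
  expect_equal(rowSums(sfs$counts), sfs1d(pair$pop_a, pops == pair$pop_a, 8L))
  expect_equal(colSums(sfs$counts), sfs1d(pair$pop_b, pops == pair$pop_b, 8L))
})

test_that("call-set intersection matches brute-force set logic", {
  mkcalls <- function(centers, div) {
    data.frame(chrom = "chr1", center_start = centers,
               center_end = centers + 5000,
               call = ifelse(div, "divergent", "neutral"),
               supported = div)
  }
  a <- mkcalls(seq(0, 95000, 5000), rep(c(TRUE, FALSE), 10))
  expect_equal(intersect_calls(list(a),
                               mode = "shared_divergent")$n_common, 10L)
  b <- mkcalls(seq(0, 45000, 5000), c(rep(FALSE, 5), rep(TRUE, 5)))
  both <- intersect_calls(list(a, b), mode = "shared_divergent")
  manual <- intersect(a$center_start[a$supported],
                      b$center_start[b$supported])
  expect_equal(sort(both$windows$center_start), sort(manual))
  disj <- mkcalls(seq(0, 45000, 5000), c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(intersect_calls(list(b, disj),
                               mode = "shared_divergent")$n_common, 0L)
  uni <- intersect_calls(list(a, b), mode = "all_pairs_common_windows")
  expect_equal(uni$n_common, 10L)
  bad <- b; bad$center_end <- bad$center_start + 4000
  expect_error(intersect_calls(list(a, bad)), "grids")
})

test_that("drift-null comparison runs and rejects zero replicates", {
  m <- tiny_model()
  expect_error(drift_null_compare(NULL, m, chrom_lengths = c(3e4),
                                  n_replicates = 0), "replicate")
  g <- simulate_genome(m, c(chr1 = 4e4), 1, seed = 3,
                       sample_sizes = c(12L, 12L), burnin_factor = 3)
  emp <- window_fst_scan(g[[1]]$chr1, sitemask("chr1", 4e4))
  dn <- drift_null_compare(emp, m, chrom_lengths = c(4e4),
                           n_replicates = 3, seed = 5,
                           sample_sizes = c(12L, 12L))
  expect_length(dn$sim_fst, 3L)
  expect_true(is.finite(dn$ks_median))
  expect_false(dn$swapped)
})
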