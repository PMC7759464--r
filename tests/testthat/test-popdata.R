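test_that("phased VCF reading transcribes biallelic phased genotypes", {
  vcf <- write_vcf_text(tempfile(fileext = ".vcf"), c("s1", "s2"), c(
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t205\t.\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0"))
  pops <- c(s1 = "A", s2 = "B")
  h <- read_phased_vcf(vcf, pops)
  expect_equal(dim(h$alleles), c(4L, 3L))
  expect_equal(sum(is.na(h$alleles)), 0L)
  expect_equal(h$positions, c(100L, 204L, 299L))  # 0-based internally
  expect_equal(unname(h$alleles[, 1]), c(0L, 1L, 1L, 1L))
  expect_equal(h$pop_of_sample, c("A", "B"))
})

test_that("multi-allelic sites and half/unphased calls are handled", {
  vcf <- write_vcf_text(tempfile(fileext = ".vcf"), c("s1", "s2"), c(
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0",
    "chr1\t20\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t0|2",
    "chr1\t30\t.\tA\tG\t.\tPASS\t.\tGT\t./.\t0|1",
    "chr1\t40\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0|1",
    "chr1\t50\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "chr1\t60\t.\tA\tG\t.\tPASS\t.\tGT\t.|1\t0|0"))
  h <- read_phased_vcf(vcf, c(s1 = "A", s2 = "B"))
  expect_equal(ncol(h$alleles), 5L)       # tri-allelic site dropped
  expect_equal(sum(is.na(h$alleles[1:2, h$positions == 29L])), 2L)
  expect_equal(sum(is.na(h$alleles[1:2, h$positions == 39L])), 2L)
  expect_equal(sum(is.na(h$alleles[1:2, h$positions == 59L])), 2L)
})

test_that("VCF reading errors name missing samples and missing GT", {
  vcf <- write_vcf_text(tempfile(fileext = ".vcf"), c("s1", "sX"),
    "chr1\t10\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t0|0")
  expect_error(read_phased_vcf(vcf, c(s1 = "A")), "sX")
})

test_that("write/read round-trip preserves genotypes, phase, positions", {
  set.seed(42)
  h <- random_hapmat(8L, 15L)
  # missingness is a diploid-genotype property in a VCF
  al <- h$alleles
  for (j in seq_len(nrow(al) / 2L)) {
    gm <- runif(ncol(al)) < 0.1
    al[2L * j - 1L, gm] <- NA_integer_
    al[2L * j, gm] <- NA_integer_
  }
  h <- hapmat(al, h$positions, h$chrom, h$sample_ids, h$pop_of_sample,
              h$polarized)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(h, path)
  pops <- setNames(h$pop_of_sample, h$sample_ids)
  h2 <- read_phased_vcf(path, pops)
  expect_equal(unname(h2$alleles), unname(h$alleles))
  expect_equal(h2$positions, h$positions)
  expect_equal(h2$sample_ids, h$sample_ids)
})

test_that("masking removes sites and counts accessible bp", {
  set.seed(7)
  h <- random_hapmat(4L, 10L)
  empty <- sitemask(h$chrom, 1e5)
  expect_equal(apply_mask(h, empty)$positions, h$positions)
  full <- sitemask(h$chrom, 1e5, cbind(0, 1e5))
  expect_equal(ncol(apply_mask(h, full)$alleles), 0L)
  expect_equal(accessible_bp(full, 0, 1e5), 0)
  # 10-kb interval with 3.8 kb masked -> 6,200 accessible
  m <- sitemask("chr1", 5e4, cbind(c(1000, 9000), c(3800, 10800)))
  expect_equal(accessible_bp(m, 0, 10000), 6200)
})

test_that("accessibility queries match brute-force membership counts", {
  set.seed(11)
  for (rep in 1:20) {
    L <- sample(2000:9000, 1)
    n_iv <- sample(1:8, 1)
    s <- sort(sample.int(L - 60L, n_iv))
    iv <- cbind(s, pmin(s + sample(10:400, n_iv, replace = TRUE), L))
    m <- sitemask("c", L, iv)
    masked <- rep(FALSE, L)
    for (k in seq_len(n_iv)) masked[(iv[k, 1] + 1L):iv[k, 2]] <- TRUE
    a <- sort(sample.int(L, 2)) - 1L
    expect_equal(accessible_bp(m, a[1], a[2]),
                 sum(!masked[(a[1] + 1L):a[2]]))
  }
})

test_that("FASTA masks honour both hard- and soft-mask dialects", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chrZ desc", "ACGTNNacgTA"), fa)
  mN <- read_mask_fasta(fa, "chrZ", dialect = "N")
  expect_equal(mN$masked, cbind(4, 6))
  mL <- read_mask_fasta(fa, "chrZ", dialect = "lowercase")
  expect_equal(mL$masked, cbind(4, 9))
  expect_equal(mL$length, 11)
})

test_that("polarization follows the outgroup validity/monomorphism rule", {
  # 4 ingroup haplotypes segregating at 3 sites; 5 outgroup diploids
  ing <- hapmat(matrix(c(0, 1, 1, 0,
                         1, 1, 0, 0,
                         0, 0, 1, 1), nrow = 4),
                c(10L, 20L, 30L), "chr1", c("i1", "i2"), c("A", "B"))
  og_al <- matrix(0L, nrow = 10, ncol = 3)
  og_al[, 2] <- 1L                  # site 2: outgroup fixed for ALT
  og_al[1:4, 3] <- NA_integer_      # site 3: only 3/5 valid
  og <- hapmat(og_al, c(10L, 20L, 30L), "chr1", paste0("o", 1:5),
               rep("OG", 5))
  ph <- polarize(ing, og)
  expect_equal(ph$polarized, c(TRUE, TRUE, FALSE))
  # site 1: REF ancestral, codes unchanged
  expect_equal(ph$alleles[, 1], ing$alleles[, 1])
  # site 2: ALT ancestral, codes flipped
  expect_equal(ph$alleles[, 2], 1L - ing$alleles[, 2])
  # heterozygous outgroup individual defeats monomorphism
  og_al2 <- matrix(0L, nrow = 10, ncol = 3)
  og_al2[1, 1] <- 1L
  og2 <- hapmat(og_al2, c(10L, 20L, 30L), "chr1", paste0("o", 1:5),
                rep("OG", 5))
  expect_false(polarize(ing, og2)$polarized[1])
  # genotype multiset at each site is never altered
  for (s in 1:3)
    expect_equal(sort(table(ph$alleles[, s])),
                 sort(table(ing$alleles[, s])))
})

test_that("coverage filtering applies the 5x-in-80% rule", {
  set.seed(3)
  h <- random_hapmat(20L, 6L, pops = c("A", "A"))  # one population
  ns <- 10L
  deep <- matrix(30L, nrow = 6L, ncol = ns)
  expect_equal(coverage_filter(h, deep)$positions, h$positions)
  d <- deep
  d[2, 1:3] <- 2L   # site 2: 7/10 pass -> dropped
  d[4, 1:2] <- 1L   # site 4: exactly 8/10 pass -> kept, 2 set missing
  hf <- coverage_filter(h, d)
  expect_equal(ncol(hf$alleles), 5L)
  expect_false(h$positions[2] %in% hf$positions)
  col4 <- which(hf$positions == h$positions[4])
  expect_equal(sum(is.na(hf$alleles[, col4])), 4L)  # 2 samples x 2 haps
  expect_error(coverage_filter(h, deep[1:3, ]), "aligned")
})

test_that("popfiles accept comments and model configs round-trip", {
  pf <- tempfile()
  writeLines(c("# a comment", "s1\tA", "s2 B"), pf)
  expect_equal(read_popfile(pf), c(s1 = "A", s2 = "B"))
  mj <- tempfile(fileext = ".json")
  write_model_config(desk_model(), mj)
  m2 <- read_model_config(mj)
  expect_equal(unclass(m2), unclass(desk_model()))
  my <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(desk_model()), my)
  expect_equal(unclass(read_model_config(my)), unclass(desk_model()))
})
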