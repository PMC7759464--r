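test_that("parameter draws respect their stated supports and onsets", {
  m <- desk_model()
  pr <- desk_profile()
  set.seed(101)
  draws <- replicate(2000, {
    p <- draw_sim_params("divergent", "standing", m, pr)
    c(p$theta_locus, p$rho_locus, p$sel_pos_rel, p$s, p$f0)
  })
  expect_true(all(draws[1, ] >= pr$u_range[1] & draws[1, ] <= pr$u_range[2]))
  expect_true(all(draws[2, ] > 0 & draws[2, ] <= pr$r_max))
  expect_true(all(draws[3, ] >= 0.4 & draws[3, ] <= 0.6))
  expect_true(all(draws[4, ] >= pr$s_range[1] & draws[4, ] <= pr$s_range[2]))
  expect_true(all(draws[5, ] >= 1e-5 & draws[5, ] <= 1e-2))
  set.seed(1)
  expect_equal(draw_sim_params("shared", "de_novo", m, pr)$onset,
               m$colonization_time)
  set.seed(1)
  expect_equal(draw_sim_params("divergent", "de_novo", m, pr)$onset,
               m$split_time)
  set.seed(1)
  expect_equal(draw_sim_params("shared", "de_novo", m, pr)$f0,
               1 / (2 * m$founder_size))
  set.seed(1)
  expect_true(is.na(draw_sim_params("neutral", "de_novo", m, pr)$onset))
})

test_that("trajectories are WF-consistent and honour conditioning", {
  # f0 = 1: constant path
  set.seed(2)
  expect_equal(simulate_trajectory(0.1, 1, 100, onset = 20, f_end = 0),
               rep(1, 21))
  # s = 0, unconditioned: martingale (mean final freq ~ f0)
  set.seed(3)
  finals <- replicate(2000,
    simulate_trajectory(0, 0.3, 50, onset = 10, f_end = 0)[11])
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.3), 3 * se)
  # strong selection, conditioned: near-fixation typical
  set.seed(4)
  ends <- replicate(30,
    simulate_trajectory(0.1, 0.01, 1000, onset = 2000, f_end = 0.99)[2001])
  expect_true(all(ends >= 0.99))
  # unreachable conditioning errors with advice
  set.seed(5)
  expect_error(simulate_trajectory(0, 0.01, 50, onset = 3, f_end = 0.99,
                                   max_tries = 5), "f_end")
})

test_that("simulated instances carry consistent labels and sweeps", {
  m <- tiny_model()
  pr <- tiny_profile()
  set.seed(11)
  pn <- draw_sim_params("neutral", "de_novo", m, pr)
  i0 <- simulate_instance(pn, m, 8L, 8L, seed = 21)
  expect_s3_class(i0$hap, "hapmat")
  expect_equal(i0$label, "neutral")
  expect_equal(n_haplotypes(i0$hap), 16L)
  expect_true(all(i0$hap$polarized))
  set.seed(12)
  pd <- draw_sim_params("divergent", "de_novo", m, pr)
  i1 <- simulate_instance(pd, m, 8L, 8L, seed = 22, f_end = 0.3)
  expect_true(i1$swept_pop %in% c("A", "B"))
  expect_gte(i1$sel_freq[[i1$swept_pop]], 0.3)
  # determinism: same params and seed give identical output
  i1b <- simulate_instance(pd, m, 8L, 8L, seed = 22, f_end = 0.3)
  expect_identical(i1$hap$alleles, i1b$hap$alleles)
  expect_identical(i1$hap$positions, i1b$hap$positions)
})

test_that("neutral simulations are calibrated (theta and Tajima's D)", {
  m <- tiny_model()
  u <- 0.04
  L <- 2e4
  th <- 4 * m$source_size * u
  vals <- t(sapply(1:60, function(i) {
    res <- diverscan:::run_forward(m, L, u, 0.05, 20L, 0L, seed = 9000 + i,
                                   single_pop = TRUE, burnin_factor = 8)
    h <- diverscan:::engine_to_hapmat(res, "c")
    c(watterson_theta(h, NULL, L) * L, tajimas_d(h))
  }))
  se <- sd(vals[, 1]) / sqrt(nrow(vals))
  expect_lt(abs(mean(vals[, 1]) - th), 3 * se)
  expect_lt(abs(mean(vals[, 2], na.rm = TRUE)), 0.25)
})

test_that("mask mirroring is uniform, deterministic and identity-safe", {
  m <- tiny_model()
  pr <- tiny_profile()
  set.seed(31)
  p <- draw_sim_params("neutral", "de_novo", m, pr)
  inst <- simulate_instance(p, m, 8L, 8L, seed = 41)
  open_mask <- sitemask("big", 1e6)
  id <- mirror_mask(inst, open_mask, seed = 1)
  expect_equal(ncol(id$hap$alleles), ncol(inst$hap$alleles))
  # fixed seed: identical slice twice
  mm <- sitemask("big", 1e6,
                 cbind(seq(0, 9.9e5, 1e4), seq(0, 9.9e5, 1e4) + 4000))
  a <- mirror_mask(inst, mm, seed = 7)
  b <- mirror_mask(inst, mm, seed = 7)
  expect_identical(a$mask_offset, b$mask_offset)
  expect_identical(a$hap$positions, b$hap$positions)
  # ~40% masked mask loses ~40% of accessible bp on average
  fr <- sapply(1:50, function(i)
    1 - accessible_bp(mirror_mask(inst, mm, seed = i)$mask, 0,
                      p$locus_bp) / p$locus_bp)
  expect_lt(abs(mean(fr) - 0.4), 0.05)
  expect_error(mirror_mask(inst, sitemask("s", 1000), 1), "shorter")
})

test_that("training sets are balanced, mixed-origin and reproducible", {
  m <- tiny_model()
  pr <- tiny_profile(n_train = 4L, n_test = 2L)
  ts <- make_training_set(m, pr, pair_sizes = c(8L, 8L), seed = 5L,
                          f_end = 0.2)
  expect_length(ts$train, 12L)
  expect_length(ts$test, 6L)
  labs <- sapply(ts$train, `[[`, "label")
  expect_equal(unname(table(labs)[c("neutral", "shared", "divergent")]),
               rep(4L, 3), ignore_attr = TRUE)
  origins <- sapply(ts$train, function(i) i$params$origin)
  expect_equal(sum(origins == "de_novo", na.rm = TRUE), 4L)
  expect_equal(sum(origins == "standing", na.rm = TRUE), 4L)
  # byte-identical serialization under the same master seed
  ts2 <- make_training_set(m, pr, pair_sizes = c(8L, 8L), seed = 5L,
                           f_end = 0.2)
  d1 <- tempfile(); d2 <- tempfile()
  save_training_set(ts, d1)
  save_training_set(ts2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
})

test_that("genome simulation yields the requested shapes and FST order", {
  m <- tiny_model()
  reps <- simulate_genome(m, c(chrA = 5e4, chrB = 3e4), n_replicates = 3,
                          seed = 17, sample_sizes = c(12L, 12L),
                          burnin_factor = 3)
  expect_length(reps, 3L)
  expect_length(reps[[1]], 2L)
  expect_equal(reps[[1]]$chrA$chrom, "chrA")
  expect_true(all(reps[[2]]$chrB$positions < 3e4))
  # drift monotonicity: no migration + halved founder/daughter sizes
  # raises windowed FST
  strong_drift <- m
  strong_drift$migration_rate <- 0
  strong_drift$founder_size <- m$founder_size / 2
  strong_drift$daughter_sizes <- m$daughter_sizes / 4
  fst_of <- function(mod, seeds) {
    unlist(lapply(seeds, function(s) {
      g <- simulate_genome(mod, c(chr = 5e4), 1, seed = s,
                           sample_sizes = c(12L, 12L),
                           burnin_factor = 3)[[1]]$chr
      sapply(seq(0, 4e4, 1e4), function(w)
        hudson_fst(g, c(w, w + 1e4))$fst)
    }))
  }
  f_base <- fst_of(m, 1:8)
  f_drift <- fst_of(strong_drift, 1:8)
  expect_gt(median(f_drift, na.rm = TRUE), median(f_base, na.rm = TRUE))
  # high symmetric migration flattens differentiation
  panmix <- m
  panmix$migration_rate <- 0.05   # 4Nm >> 1
  f_mig <- fst_of(panmix, 1:6)
  expect_lt(median(f_mig, na.rm = TRUE), 0.05)
})

test_that("the Ne swap exchanges sizes only and is an involution", {
  a <- desk_model()
  b <- tiny_model()
  sw <- ne_swap_experiment(a, b)
  expect_equal(sw$model_a$source_size, b$source_size)
  expect_equal(sw$model_a$daughter_sizes, b$daughter_sizes)
  expect_equal(sw$model_a$colonization_time, a$colonization_time)
  expect_equal(sw$model_a$mutation_rate, a$mutation_rate)
  back <- ne_swap_experiment(sw$model_a, sw$model_b)
  expect_equal(unclass(back$model_a), unclass(a))
  expect_equal(unclass(back$model_b), unclass(b))
  same <- ne_swap_experiment(a, a)
  expect_equal(unclass(same$model_a), unclass(a))
})
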