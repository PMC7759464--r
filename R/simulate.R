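# Training-data simulation: parameter draws, the forward-engine wrapper,
# mask mirroring and training-set assembly.

# deterministic 31-bit sub-seed derivation (splitmix-style)
derive_seed <- function(master, i) {
  x <- (as.double(master) * 2654435761 + as.double(i) * 40503 + 12345) %%
    2147483647
  as.integer(x) + 1L
}

#' Draw one set of simulation parameters
#'
#' Draws the per-locus mutation rate (uniform), the per-locus
#' recombination rate (truncated exponential, redrawn beyond its
#' maximum), the relative selected-site position, the selection
#' coefficient and the initial selected-allele frequency from the
#' profile's distributions. The onset of selection directly follows lake
#' colonization (shared sweeps) or the sympatric split (divergent
#' sweeps). Uses R's RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param category `"neutral"`, `"shared"` or `"divergent"`.
#' @param origin `"de_novo"` or `"standing"` (ignored for neutral).
#' @param model a [demographic_model()].
#' @param profile a [sim_profile()].
#' @return object of class `sim_params`.
#' @export
draw_sim_params <- function(category = c("neutral", "shared", "divergent"),
                            origin = c("de_novo", "standing"), model,
                            profile = desk_profile()) {
  category <- match.arg(category)
  origin <- match.arg(origin)
  u <- stats::runif(1, profile$u_range[1], profile$u_range[2])
  repeat {
    rho <- stats::rexp(1, rate = 1 / profile$r_mean)
    if (rho <= profile$r_max && rho > 0) break
  }
  sel_pos <- stats::runif(1, profile$sel_pos_range[1],
                          profile$sel_pos_range[2])
  s <- stats::runif(1, profile$s_range[1], profile$s_range[2])
  onset <- switch(category, neutral = NA_real_,
                  shared = model$colonization_time,
                  divergent = model$split_time)
  sweep_n2 <- switch(category, neutral = NA_real_,
                     shared = 2 * model$founder_size,
                     divergent = 2 * model$daughter_sizes[1])
  f0 <- if (category == "neutral") NA_real_
  else if (origin == "de_novo") 1 / sweep_n2
  else exp(stats::runif(1, log(profile$f0_range[1]),
                        log(profile$f0_range[2])))
  structure(list(locus_bp = profile$locus_bp, theta_locus = u,
                 rho_locus = rho, sel_pos_rel = sel_pos,
                 s = if (category == "neutral") 0 else s, f0 = f0,
                 category = category,
                 origin = if (category == "neutral") NA_character_
                          else origin,
                 onset = onset, seed = NA_integer_),
            class = "sim_params")
}

#' Wright-Fisher selected-allele frequency trajectory
#'
#' Forward binomial sampling with genic selection (per-copy coefficient
#' `s`): `p' ~ Binom(2N, p (1 + s) / (1 + p s)) / 2N`, starting `onset`
#' generations ago at frequency `f0`, optionally conditioned (by
#' rejection) on a final frequency of at least `f_end`.
#'
#' @param s per-copy selection coefficient (>= 0).
#' @param f0 initial frequency, in (0, 1].
#' @param N_path diploid population size per generation (recycled to
#'   `onset` generations).
#' @param onset trajectory length in generations.
#' @param f_end conditioning threshold at sampling time; `NULL` or 0
#'   disables conditioning.
#' @param max_tries rejection budget before erroring.
#' @return numeric vector of length `onset + 1` (frequency at each
#'   generation from onset to sampling).
#' @export
simulate_trajectory <- function(s, f0, N_path, onset = length(N_path),
                                f_end = 0.5, max_tries = 1000L) {
  stopifnot(f0 > 0, f0 <= 1, s >= 0, onset >= 1)
  N <- rep_len(N_path, onset)
  for (t in seq_len(max_tries)) {
    p <- numeric(onset + 1L)
    p[1] <- f0
    for (g in seq_len(onset)) {
      n2 <- round(2 * N[g])
      pe <- p[g] * (1 + s) / (1 + p[g] * s)
      p[g + 1L] <- stats::rbinom(1L, n2, pe) / n2
    }
    if (is.null(f_end) || f_end <= 0 || p[onset + 1L] >= f_end) return(p)
  }
  stop("trajectory failed to reach f_end within max_tries; ",
       "increase s or f0")
}

# low-level engine wrapper; sizes in the model are diploid, the engine
# works in haplotypes
run_forward <- function(model, locus_bp, u_locus, r_locus, n_a, n_b, seed,
                        sel = NULL, f_end = 0.5, max_tries = 500L,
                        burnin_factor = 4, single_pop = FALSE) {
  n2_src <- round(2 * model$source_size)
  burnin <- round(burnin_factor * n2_src)
  if (single_pop) {
    res <- sim_forward_cpp(locus_bp, u_locus, r_locus, n2_src, 0L, 0L, 0L,
                           0L, 0L, 0, burnin, numeric(0), numeric(0),
                           integer(0), integer(0), integer(0), 0, 1L,
                           n_a, 0L, as.double(seed))
  } else {
    if (is.null(sel)) sel <- data.frame(pos_rel = numeric(0),
                                        s = numeric(0), copies = integer(0),
                                        onset = integer(0),
                                        daughter = integer(0))
    res <- sim_forward_cpp(locus_bp, u_locus, r_locus, n2_src,
                           round(2 * model$founder_size),
                           round(2 * model$daughter_sizes[1]),
                           round(2 * model$daughter_sizes[2]),
                           round(model$colonization_time),
                           round(model$split_time), model$migration_rate,
                           burnin, sel$pos_rel, sel$s,
                           as.integer(sel$copies),
                           as.integer(sel$onset),
                           as.integer(sel$daughter), f_end,
                           as.integer(max_tries), n_a, n_b,
                           as.double(seed))
  }
  res
}

engine_to_hapmat <- function(res, chrom, pop_labels = c("A", "B")) {
  n_a <- res$n_a; n_b <- res$n_b
  ns <- (n_a + n_b) / 2L
  if (n_a %% 2L || n_b %% 2L)
    stop("haplotype sample sizes must be even (diploid samples)")
  ids <- c(if (n_a > 0) paste0(pop_labels[1], "_", seq_len(n_a / 2L)),
           if (n_b > 0) paste0(pop_labels[2], "_", seq_len(n_b / 2L)))
  pops <- c(rep(pop_labels[1], n_a / 2L), rep(pop_labels[2], n_b / 2L))
  hapmat(res$genotypes, as.integer(res$positions), chrom, ids, pops,
         polarized = rep(TRUE, length(res$positions)))
}

#' Simulate one labelled two-population locus
#'
#' Runs the forward Wright-Fisher engine under the colonization-split
#' model: neutral loci carry no selected site; shared sweeps start in the
#' colony at colonization and remain beneficial in both daughters;
#' divergent sweeps start at the split in one daughter (fair coin, not
#' revealed to the classifier) and are strictly neutral in the other.
#' Output is polarized by construction (the ancestral state is the
#' mutation-free state).
#'
#' @param params a `sim_params` from [draw_sim_params()].
#' @param model a [demographic_model()].
#' @param n_a,n_b haplotypes sampled per daughter population.
#' @param seed integer seed (engine RNG; also seeds the daughter coin).
#' @param f_end,max_tries sweep conditioning (see
#'   [simulate_trajectory()]).
#' @param burnin_factor source-population burn-in, in units of source
#'   haplotype count.
#' @return object of class `sim_instance`: fields `params`, `hap`,
#'   `label`, `swept_pop`, `tries`.
#' @export
simulate_instance <- function(params, model, n_a = 40L, n_b = 40L, seed,
                              f_end = 0.5, max_tries = 500L,
                              burnin_factor = 4) {
  sel <- NULL
  swept <- NA_character_
  if (params$category != "neutral") {
    if (params$category == "shared") {
      daughter <- 0L
      onset <- 0L
      n2 <- 2 * model$founder_size
      swept <- "both"
    } else {
      coin <- derive_seed(seed, 777L) %% 2L
      daughter <- 1L + coin
      onset <- 1L
      n2 <- 2 * model$daughter_sizes[daughter]
      swept <- c("A", "B")[daughter]
    }
    sel <- data.frame(pos_rel = params$sel_pos_rel, s = params$s,
                      copies = max(1L, round(params$f0 * n2)),
                      onset = onset, daughter = daughter)
  }
  res <- run_forward(model, params$locus_bp, params$theta_locus,
                     params$rho_locus, n_a, n_b, seed, sel, f_end,
                     max_tries, burnin_factor)
  params$seed <- as.integer(seed)
  structure(list(params = params,
                 hap = engine_to_hapmat(res, "simlocus"),
                 label = params$category, swept_pop = swept,
                 sel_bp = if (length(res$sel_bp)) res$sel_bp else NA_real_,
                 sel_freq = c(A = if (length(res$sel_freq_a))
                   res$sel_freq_a[1] else NA_real_,
                   B = if (length(res$sel_freq_b))
                     res$sel_freq_b[1] else NA_real_),
                 tries = res$tries, mask = NULL),
            class = "sim_instance")
}

#' Mirror an empirical missing-data pattern onto a simulated locus
#'
#' Draws a uniformly random locus-length slice from an empirical
#' accessibility mask, removes the simulated sites falling in its masked
#' intervals, and attaches the relocated slice to the instance so that
#' feature construction sees the same per-subwindow accessible-bp
#' pattern as the empirical data.
#'
#' @param inst a [simulate_instance()] result.
#' @param empirical_mask a [sitemask()] with length >= the locus.
#' @param seed integer seed for the slice draw.
#' @return the instance with `hap` filtered, `mask` set to the slice and
#'   `mask_offset` recording the drawn position.
#' @export
mirror_mask <- function(inst, empirical_mask, seed) {
  L <- inst$params$locus_bp
  if (empirical_mask$length < L)
    stop("mask is shorter than the simulated locus")
  set.seed(derive_seed(seed, 99L))
  start <- floor(stats::runif(1, 0, empirical_mask$length - L + 1))
  slice <- mask_slice(empirical_mask, start, L)
  slice$chrom <- inst$hap$chrom
  inst$hap <- apply_mask(inst$hap, slice)
  inst$mask <- slice
  inst$mask_offset <- start
  inst
}

#' Simulate a labelled training and test collection
#'
#' Balanced per-class instance counts with deterministic per-instance
#' seeds derived from one master seed; sweep origins alternate
#' de novo / standing within each selected class according to
#' `origin_mix`.
#'
#' @param model a [demographic_model()].
#' @param profile a [sim_profile()]; its `n_train`/`n_test` are used
#'   unless overridden.
#' @param pair_sizes haplotypes sampled per population.
#' @param n_train,n_test instances per class.
#' @param mask optional [sitemask()] for mask mirroring.
#' @param seed master seed.
#' @param origin_mix fraction of selected instances from de novo
#'   mutations (default 0.5, alternating deterministically).
#' @param classes class labels to simulate.
#' @return list with `train`, `test` (lists of `sim_instance`) and
#'   `config`.
#' @export
make_training_set <- function(model, profile = desk_profile(),
                              pair_sizes = c(40L, 40L),
                              n_train = profile$n_train,
                              n_test = profile$n_test, mask = NULL,
                              seed = 1L, origin_mix = 0.5,
                              classes = c("neutral", "shared",
                                          "divergent"),
                              f_end = profile$f_end, max_tries = 500L) {
  gen <- function(n, which_half) {
    out <- vector("list", n * length(classes))
    k <- 0L
    for (cl in classes) {
      n_denovo <- round(n * origin_mix)
      for (i in seq_len(n)) {
        k <- k + 1L
        si <- derive_seed(seed, k * 7L + which_half * 1000003L)
        set.seed(si)
        origin <- if (i <= n_denovo) "de_novo" else "standing"
        params <- draw_sim_params(cl, origin, model, profile)
        inst <- simulate_instance(params, model, pair_sizes[1],
                                  pair_sizes[2], seed = si,
                                  f_end = f_end, max_tries = max_tries,
                                  burnin_factor = profile$burnin_factor)
        if (!is.null(mask)) inst <- mirror_mask(inst, mask, si)
        out[[k]] <- inst
      }
    }
    out
  }
  list(train = gen(n_train, 0L), test = gen(n_test, 1L),
       config = list(model = model, profile = profile,
                     pair_sizes = pair_sizes, n_train = n_train,
                     n_test = n_test, seed = seed,
                     origin_mix = origin_mix, classes = classes,
                     masked = !is.null(mask)))
}

#' Serialize a training set to a directory
#'
#' One text file per instance (JSON parameter header, positions line,
#' one 0/1 haplotype string per row) plus a JSON manifest; byte-identical
#' for identical master seeds.
#'
#' @param ts a [make_training_set()] result.
#' @param dir output directory (created).
#' @export
save_training_set <- function(ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump1 <- function(inst, path) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- jsonlite::toJSON(c(unclass(inst$params),
                              list(label = inst$label,
                                   swept_pop = inst$swept_pop)),
                            auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(c(as.character(hdr),
                 paste(inst$hap$positions, collapse = " "),
                 apply(inst$hap$alleles, 1L, paste, collapse = "")),
               con, sep = "\n")
  }
  for (part in c("train", "test")) {
    for (i in seq_along(ts[[part]]))
      dump1(ts[[part]][[i]], file.path(dir, sprintf("%s_%05d.txt", part, i)))
  }
  cfg <- ts$config
  cfg$model <- unclass(cfg$model)
  cfg$profile <- unclass(cfg$profile)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Simulate neutral whole genomes under the two-population model
#'
#' Runs the forward engine in neutral mode for each chromosome and
#' replicate; used for the drift-null windowed-FST comparison.
#'
#' @param model a [demographic_model()].
#' @param chrom_lengths named or unnamed vector of chromosome lengths.
#' @param n_replicates replicate genomes.
#' @param seed master seed.
#' @param sample_sizes haplotypes per population.
#' @param burnin_factor burn-in multiple of source haplotype count.
#' @return list of replicates, each a list of [hapmat()] per chromosome.
#' @export
simulate_genome <- function(model, chrom_lengths, n_replicates = 1L,
                            seed = 1L, sample_sizes = c(40L, 40L),
                            burnin_factor = 4) {
  if (n_replicates < 1L) stop("need at least one replicate")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  lapply(seq_len(n_replicates), function(rep) {
    out <- lapply(seq_along(chrom_lengths), function(ci) {
      L <- chrom_lengths[ci]
      res <- run_forward(model, L, model$mutation_rate * L,
                         model$recombination_rate * L, sample_sizes[1],
                         sample_sizes[2],
                         seed = derive_seed(seed, rep * 131L + ci),
                         burnin_factor = burnin_factor)
      engine_to_hapmat(res, names(chrom_lengths)[ci])
    })
    names(out) <- names(chrom_lengths)
    out
  })
}
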