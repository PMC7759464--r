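#' Colonization-split demographic model
#'
#' Describes the history assumed by the training simulations and the
#' drift-null genome simulations: an ancestral/source population, a
#' founder event (lake colonization) at `colonization_time`, a sympatric
#' split of the colony into two daughter populations at `split_time`, and
#' symmetric migration between the daughters until the present. The colony
#' stays at `founder_size` between colonization and split (sustained
#' founder bottleneck).
#'
#' All sizes are diploid effective sizes; all times are in generations
#' before sampling; `mutation_rate` and `recombination_rate` are per site
#' per generation.
#'
#' @param ancestral_size,source_size diploid Ne of the deep ancestral and
#'   the source-lake population (the engine holds the pre-colonization
#'   population at `source_size`).
#' @param colonization_time founder event, generations ago.
#' @param founder_size diploid Ne of the colony.
#' @param split_time sympatric split, generations ago
#'   (`<= colonization_time`).
#' @param daughter_sizes numeric length-2, diploid Ne of the daughters.
#' @param migration_rate per-generation fraction of each daughter drawn
#'   from the other after the split.
#' @param mutation_rate,recombination_rate per site per generation.
#' @param generation_time years per generation (bookkeeping only).
#' @return object of class `demographic_model`.
#' @export
demographic_model <- function(ancestral_size, source_size,
                              colonization_time, founder_size, split_time,
                              daughter_sizes, migration_rate,
                              mutation_rate, recombination_rate,
                              generation_time = 1.5) {
  m <- list(ancestral_size = ancestral_size, source_size = source_size,
            colonization_time = colonization_time,
            founder_size = founder_size, split_time = split_time,
            daughter_sizes = as.numeric(daughter_sizes),
            migration_rate = migration_rate,
            mutation_rate = mutation_rate,
            recombination_rate = recombination_rate,
            generation_time = generation_time)
  rates <- c(m$migration_rate, m$mutation_rate, m$recombination_rate)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (m$split_time > m$colonization_time)
    stop("split_time must be <= colonization_time")
  sizes <- c(m$ancestral_size, m$source_size, m$founder_size,
             m$daughter_sizes)
  if (any(sizes < 2)) stop("population sizes must be >= 2 diploids")
  if (length(m$daughter_sizes) != 2L)
    stop("daughter_sizes must have length 2")
  structure(m, class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf(paste0(
    "demographic model: source Ne=%g -> founder Ne=%g at %g gens ago,\n",
    "  split %g gens ago into Ne=(%g, %g), migration %g/gen,\n",
    "  mu=%g, r=%g per site per gen, generation time %g y\n"),
    x$source_size, x$founder_size, x$colonization_time, x$split_time,
    x$daughter_sizes[1], x$daughter_sizes[2], x$migration_rate,
    x$mutation_rate, x$recombination_rate, x$generation_time))
  invisible(x)
}

#' Desk-scale demographic model
#'
#' A reduced-scale colonization-split history sized so that the full
#' pipeline (training-set simulation, classifier training, genome scans)
#' runs in minutes on one CPU while keeping the population-genetic regime
#' of the emulated system: a founder bottleneck at colonization followed
#' by a brief colony phase (a founder event, then expansion), daughters
#' a tenth of a coalescent unit old with mild migration (4Nm near 2,
#' window FST around 0.1-0.2), and timescales on which the desk
#' strong-sweep range completes shortly before sampling so that both
#' shared and divergent signatures are still visible. Per-site rates are
#' set so a desk chromosome carries realistic SNP density at these
#' population sizes.
#'
#' @export
desk_model <- function() {
  demographic_model(
    ancestral_size = 150, source_size = 150,
    colonization_time = 125, founder_size = 75,
    split_time = 100, daughter_sizes = c(500, 500),
    migration_rate = 5e-4,
    mutation_rate = 1.6e-6, recombination_rate = 2.1e-6,
    generation_time = 1.5)
}

#' Simulation profile: locus geometry and parameter distributions
#'
#' Bundles the training-locus size, the subwindow count and the
#' distributions that per-instance parameters are drawn from. The
#' full-scale profile uses the published distributions for a 1.05-Mb
#' locus; the desk profile shrinks the locus tenfold (105 kb, 21 x 5-kb
#' subwindows) and rescales the per-locus mutation/recombination draws to
#' keep realistic per-site diversity at desk population sizes, restricting
#' the selection coefficient to the strong-sweep range so sweeps complete
#' within the compressed desk timescale.
#'
#' @param locus_bp training-locus length.
#' @param subwindows subwindows per locus (feature-matrix columns).
#' @param u_range uniform range of the per-locus per-generation mutation
#'   rate.
#' @param r_mean,r_max mean and truncation point of the exponential
#'   per-locus per-generation recombination rate (redraw beyond `r_max`).
#' @param s_range uniform range of the selection coefficient.
#' @param f0_range loguniform range of the initial selected-allele
#'   frequency for standing-variation sweeps.
#' @param f_end frequency the selected allele must reach in its sweeping
#'   population(s) by sampling time (rejection conditioning).
#' @param sel_pos_range uniform range of the relative selected-site
#'   position.
#' @param n_train,n_test instances per class.
#' @param burnin_factor burn-in length as a multiple of the source
#'   haplotype count.
#' @export
sim_profile <- function(locus_bp, subwindows, u_range, r_mean, r_max,
                        s_range, f0_range = c(1e-5, 1e-2),
                        f_end = 0.9, sel_pos_range = c(0.4, 0.6),
                        n_train = 4000L, n_test = 2000L,
                        burnin_factor = 4) {
  structure(list(locus_bp = locus_bp, subwindows = as.integer(subwindows),
                 u_range = u_range, r_mean = r_mean, r_max = r_max,
                 s_range = s_range, f0_range = f0_range, f_end = f_end,
                 sel_pos_range = sel_pos_range,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 burnin_factor = burnin_factor),
            class = "sim_profile")
}

#' @rdname sim_profile
#' @export
paper_profile <- function() {
  sim_profile(locus_bp = 1.05e6, subwindows = 21L,
              u_range = c(0.000668, 0.00668),
              r_mean = 0.018375, r_max = 0.055125,
              s_range = c(0.01, 0.1),
              n_train = 4000L, n_test = 2000L)
}

#' @rdname sim_profile
#' @export
desk_profile <- function() {
  sim_profile(locus_bp = 105000, subwindows = 21L,
              u_range = c(0.06, 0.3),
              r_mean = 0.22, r_max = 0.66,
              s_range = c(0.2, 0.4),
              n_train = 400L, n_test = 200L)
}

#' Exchange the size fields of two demographic models
#'
#' Swaps past and present effective population sizes (ancestral, source,
#' founder and daughter sizes) between two structurally compatible models,
#' leaving times and rates untouched. Applying the swap twice restores the
#' originals.
#'
#' @param model_a,model_b [demographic_model()] objects.
#' @return list with elements `model_a` and `model_b`, sizes exchanged.
#' @export
ne_swap_experiment <- function(model_a, model_b) {
  size_fields <- c("ancestral_size", "source_size", "founder_size",
                   "daughter_sizes")
  if (length(model_a$daughter_sizes) != length(model_b$daughter_sizes))
    stop("models have incompatible epoch structure")
  a <- model_a; b <- model_b
  for (f in size_fields) {
    a[[f]] <- model_b[[f]]
    b[[f]] <- model_a[[f]]
  }
  list(model_a = a, model_b = b)
}
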