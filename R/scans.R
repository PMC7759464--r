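# Genome-wide empirical analyses: windowed Hudson-FST tracks, loess
# smoothing, the unfolded 2D SFS, the classifier scan and the drift-null
# comparison.

#' Windowed Hudson-FST genome scan
#'
#' Ratio-of-averages Hudson FST in non-overlapping windows (default
#' 10 kb). Valid sites are the accessible (unmasked) bp of a window;
#' windows under `min_valid` valid sites are absent from the track (not
#' NaN rows). When a depth matrix is supplied the coverage rule
#' (>= `min_depth` in >= `min_frac` of individuals, per population) is
#' applied first via [coverage_filter()].
#'
#' @param hap a [hapmat()].
#' @param mask a [sitemask()] for the chromosome (also provides its
#'   length).
#' @param pair a [population_pair()].
#' @param depth optional sites x samples depth matrix.
#' @param window_bp window width (default 10000).
#' @param min_valid minimum accessible bp per reported window (default
#'   2000).
#' @return data.frame (class `fst_track`): chrom, start, end,
#'   n_valid_sites, fst.
#' @export
window_fst_scan <- function(hap, mask, pair = hap_pair(hap), depth = NULL,
                            window_bp = 10000L, min_valid = 2000L) {
  if (!is.null(depth)) hap <- coverage_filter(hap, depth)
  hap <- apply_mask(hap, mask)
  starts <- seq(0, mask$length - 1, by = window_bp)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_bp, mask$length)
    nv <- accessible_bp(mask, s, e)
    if (nv < min_valid) return(NULL)
    fst <- hudson_fst(hap, c(s, e), pair)$fst
    data.frame(chrom = hap$chrom, start = s, end = e,
               n_valid_sites = nv, fst = fst)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_valid_sites = numeric(0),
                      fst = numeric(0))
  class(out) <- c("fst_track", "data.frame")
  out
}

#' Loess smoothing of a windowed track
#'
#' Locally weighted linear regression with tricube weights over the
#' `ceiling(span * n)` nearest windows, evaluated at each window
#' midpoint (gaussian/least-squares family). Presentation-layer only:
#' smoothed values never feed statistics.
#'
#' @param track an `fst_track` (or any data.frame with start/end and a
#'   value column).
#' @param span fraction of windows in each local neighbourhood (default
#'   0.01).
#' @param degree local polynomial degree (1 = linear).
#' @param value column to smooth (default "fst").
#' @return the track with a `smoothed` column.
#' @export
loess_smooth <- function(track, span = 0.01, degree = 1L,
                         value = "fst") {
  n <- nrow(track)
  x <- (track$start + track$end) / 2
  y <- track[[value]]
  q <- max(degree + 2L, ceiling(span * n))
  if (n < max(10L, q)) {
    warning("too few windows for loess smoothing; returning raw values")
    track$smoothed <- y
    return(track)
  }
  sm <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(q)]
    dq <- max(d[idx])
    w <- if (dq <= 0) rep(1, q) else (1 - pmin(d[idx] / dq, 1)^3)^3
    xi <- x[idx] - x[i]
    X <- stats::poly(xi, degree = degree, raw = TRUE, simple = TRUE)
    X <- cbind(1, X)
    fit <- stats::lm.wfit(X, y[idx], w)
    sm[i] <- fit$coefficients[1]
  }
  track$smoothed <- sm
  track
}

#' Unfolded two-dimensional site-frequency spectrum
#'
#' For every polarized biallelic site, draws `n_down` alleles per
#' population without replacement from the non-missing alleles
#' (hypergeometric downsampling) and increments the corresponding
#' derived-count cell. Sites with fewer available alleles than the
#' downsampling size in either population are excluded. The per-site
#' draw is keyed by (chromosome, position, population label, seed), so
#' swapping the populations transposes the spectrum exactly.
#'
#' @param hap a polarized [hapmat()].
#' @param pair a [population_pair()].
#' @param n_down_a,n_down_b downsampled allele counts (>= 2).
#' @param seed master seed for the per-site substreams.
#' @return object of class `sfs2d`: `counts` matrix
#'   (`n_down_a + 1` x `n_down_b + 1`), sizes and labels.
#' @export
build_2dsfs <- function(hap, pair = hap_pair(hap), n_down_a = 40L,
                        n_down_b = 40L, seed = 1L) {
  if (n_down_a < 2L || n_down_b < 2L)
    stop("downsampling sizes must be >= 2")
  sp <- split_pair(hap, pair)
  ca <- site_counts(sp$a); cb <- site_counts(sp$b)
  counts <- matrix(0L, n_down_a + 1L, n_down_b + 1L)
  keyhash <- function(s) sum(utf8ToInt(s) * seq_along(utf8ToInt(s)))
  ha <- keyhash(pair$pop_a); hb <- keyhash(pair$pop_b)
  hc <- keyhash(hap$chrom)
  for (j in which(hap$polarized)) {
    if (ca$n[j] < n_down_a || cb$n[j] < n_down_b) next
    set.seed(derive_seed(seed + hc, hap$positions[j] * 4L + ha))
    ka <- stats::rhyper(1L, ca$d[j], ca$n[j] - ca$d[j], n_down_a)
    set.seed(derive_seed(seed + hc, hap$positions[j] * 4L + hb))
    kb <- stats::rhyper(1L, cb$d[j], cb$n[j] - cb$d[j], n_down_b)
    counts[ka + 1L, kb + 1L] <- counts[ka + 1L, kb + 1L] + 1L
  }
  structure(list(counts = counts, n_down_a = n_down_a,
                 n_down_b = n_down_b, pop_a = pair$pop_a,
                 pop_b = pair$pop_b),
            class = "sfs2d")
}

#' Write a windowed track as TSV (NaN serialized as NA)
#' @param track a track data.frame (e.g. an `fst_track`).
#' @param path output path.
#' @export
write_track <- function(track, path) {
  for (j in seq_along(track))
    if (is.numeric(track[[j]])) track[[j]][is.nan(track[[j]])] <- NA
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# per-chromosome subwindow statistic grid: statistics x subwindows over
# the whole chromosome, plus unmasked fractions
subwindow_grid <- function(hap, mask, pair, subwindow_bp) {
  hap <- apply_mask(hap, mask)
  n_sub <- floor(mask$length / subwindow_bp)
  stats <- matrix(NA_real_, length(stat_set_names()), n_sub,
                  dimnames = list(stat_set_names(), NULL))
  unmasked <- numeric(n_sub)
  for (k in seq_len(n_sub)) {
    s <- (k - 1L) * subwindow_bp
    e <- s + subwindow_bp
    acc <- accessible_bp(mask, s, e)
    unmasked[k] <- acc / subwindow_bp
    stats[, k] <- if (acc > 0)
      suppressWarnings(compute_stat_set(hap, c(s, e), pair, acc))
    else rep(NaN, nrow(stats))
  }
  list(stats = stats, unmasked = unmasked, subwindow_bp = subwindow_bp,
       chrom = hap$chrom)
}

#' Classifier scan along chromosomes
#'
#' Slides a frame of `subwindows` subwindows one subwindow at a time
#' along each chromosome, classifying the frame's central subwindow.
#' Frames whose central subwindow has fewer than `min_unmasked`
#' accessible sites are skipped. Returns the per-window calls and a
#' summary with genome-wide and per-chromosome fractions of classified
#' windows whose divergent posterior reaches the support threshold.
#'
#' @param haps a [hapmat()] or list of them (one per chromosome).
#' @param masks a [sitemask()] or list matching `haps`.
#' @param pair a [population_pair()].
#' @param classifier a trained `sweep_classifier`.
#' @param subwindow_bp subwindow width (training locus / subwindows).
#' @param subwindows frame width in subwindows (must match training).
#' @param support_threshold posterior needed to assert a category.
#' @param min_unmasked minimum accessible fraction of the central
#'   subwindow (default 0.2).
#' @return list with `calls` (data.frame) and `summary`.
#' @export
selection_scan <- function(haps, masks, pair, classifier,
                           subwindow_bp = 5000L, subwindows = 21L,
                           support_threshold = 0.99,
                           min_unmasked = 0.2) {
  if (inherits(haps, "hapmat")) haps <- list(haps)
  if (inherits(masks, "sitemask")) masks <- list(masks)
  stopifnot(length(haps) == length(masks))
  feats <- list()
  for (ci in seq_along(haps)) {
    grid <- subwindow_grid(haps[[ci]], masks[[ci]], pair, subwindow_bp)
    n_sub <- ncol(grid$stats)
    if (n_sub < subwindows) next
    center_off <- (subwindows + 1L) %/% 2L
    for (t in seq_len(n_sub - subwindows + 1L)) {
      kc <- t + center_off - 1L
      if (grid$unmasked[kc] < min_unmasked) next
      raw <- grid$stats[, t:(t + subwindows - 1L), drop = FALSE]
      fm <- normalize_features(raw)
      fm$meta <- list(chrom = grid$chrom,
                      start = (t - 1L) * subwindow_bp,
                      end = (t - 1L + subwindows) * subwindow_bp,
                      subwindow_bp = subwindow_bp,
                      center_start = (kc - 1L) * subwindow_bp,
                      center_end = kc * subwindow_bp,
                      unmasked_frac = grid$unmasked[t:(t + subwindows - 1L)])
      feats[[length(feats) + 1L]] <- fm
    }
  }
  if (!length(feats))
    return(list(calls = NULL,
                summary = list(n_windows = 0L, divergent_fraction = NaN)))
  calls <- predict_windows(classifier, feats, support_threshold)
  div <- calls$call == "divergent" & calls$supported
  per_chrom <- tapply(div, calls$chrom, mean)
  list(calls = calls,
       summary = list(n_windows = nrow(calls),
                      divergent_supported = sum(div),
                      divergent_fraction = mean(div),
                      per_chrom_fraction = per_chrom,
                      support_threshold = support_threshold))
}

#' Intersect classified-window sets across comparisons
#'
#' `all_pairs_common_windows` returns the classified-window universe
#' present in every comparison (denominator harmonization for
#' percent-of-genome summaries); `shared_divergent` returns the windows
#' divergent-supported in every comparison.
#'
#' @param call_sets list of `calls` data.frames from [selection_scan()].
#' @param mode intersection mode.
#' @return list with `windows` (data.frame of chrom/center coordinates)
#'   and `retained` (per-comparison counts).
#' @export
intersect_calls <- function(call_sets,
                            mode = c("all_pairs_common_windows",
                                     "shared_divergent")) {
  mode <- match.arg(mode)
  widths <- vapply(call_sets, function(cs)
    cs$center_end[1] - cs$center_start[1], numeric(1))
  if (length(unique(widths)) != 1L)
    stop("window grids differ between comparisons")
  keyof <- function(cs) paste(cs$chrom, cs$center_start, sep = ":")
  keys <- lapply(call_sets, function(cs) {
    if (mode == "shared_divergent")
      keyof(cs)[cs$call == "divergent" & cs$supported]
    else keyof(cs)
  })
  common <- Reduce(intersect, keys)
  ref <- call_sets[[1]]
  sel <- match(common, keyof(ref))
  list(windows = ref[sel, c("chrom", "center_start", "center_end")],
       retained = vapply(keys, length, integer(1)),
       n_common = length(common))
}

#' Drift-null genome simulations versus an empirical FST track
#'
#' Simulates neutral genomes under the model (optionally with past and
#' present effective sizes exchanged with a second model via
#' [ne_swap_experiment()]), computes windowed Hudson FST identically to
#' the empirical pipeline, and reports the simulated versus empirical
#' FST distributions.
#'
#' @param empirical_track an `fst_track`.
#' @param model the [demographic_model()] of the focal pair.
#' @param swap_with optional second model; when supplied, the focal
#'   model's sizes are replaced with `swap_with`'s before simulating.
#' @param chrom_lengths chromosome lengths to simulate.
#' @param n_replicates replicate genomes (>= 1).
#' @param seed master seed.
#' @param sample_sizes haplotypes per population.
#' @param window_bp,min_valid window grid (match the empirical scan).
#' @return list with per-replicate windowed FST, pooled simulated
#'   quantiles, empirical quantiles, medians and the median
#'   Kolmogorov-Smirnov statistic.
#' @export
drift_null_compare <- function(empirical_track, model, swap_with = NULL,
                               chrom_lengths, n_replicates, seed = 1L,
                               sample_sizes = c(40L, 40L),
                               window_bp = 10000L, min_valid = 2000L) {
  if (n_replicates < 1L) stop("need at least one replicate")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (!is.null(swap_with))
    model <- ne_swap_experiment(model, swap_with)$model_a
  reps <- simulate_genome(model, chrom_lengths, n_replicates, seed,
                          sample_sizes)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  sim_fst <- lapply(reps, function(chroms) {
    unlist(lapply(chroms, function(h) {
      mask <- sitemask(h$chrom, chrom_lengths[[h$chrom]])
      window_fst_scan(h, mask, hap_pair(h), window_bp = window_bp,
                      min_valid = min_valid)$fst
    }), use.names = FALSE)
  })
  pooled <- unlist(sim_fst, use.names = FALSE)
  ks <- if (!is.null(empirical_track) && nrow(empirical_track) > 1) {
    stats::median(vapply(sim_fst, function(v)
      suppressWarnings(stats::ks.test(v, empirical_track$fst)$statistic),
      numeric(1)))
  } else NA_real_
  list(sim_fst = sim_fst,
       sim_quantiles = stats::quantile(pooled, qs, na.rm = TRUE),
       sim_median = stats::median(pooled, na.rm = TRUE),
       emp_quantiles = if (!is.null(empirical_track))
         stats::quantile(empirical_track$fst, qs, na.rm = TRUE)
       else NULL,
       emp_median = if (!is.null(empirical_track))
         stats::median(empirical_track$fst, na.rm = TRUE) else NA_real_,
       ks_median = ks, swapped = !is.null(swap_with))
}
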