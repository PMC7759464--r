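# Feature matrices: statistics x subwindow summaries of a locus,
# sum-normalized per statistic.

#' Build the statistics-by-subwindow feature matrix for one locus
#'
#' Divides `locus_interval` into `subwindows` equal subwindows, computes
#' the full summary-statistic set (see [stat_set_names()]) in each, and
#' normalizes each statistic by its sum across subwindows. Subwindows
#' with no accessible bp or no retained sites yield `NaN` statistics,
#' which the normalization step imputes (and counts).
#'
#' @param hap a [hapmat()] (two populations).
#' @param mask optional [sitemask()]; drives per-subwindow accessible-bp
#'   denominators. `NULL` means fully accessible.
#' @param locus_interval `c(start, end)` 0-based half-open; its width
#'   must divide evenly into `subwindows`.
#' @param pair a [population_pair()].
#' @param subwindows number of subwindows (default 21).
#' @return object of class `feature_matrix` with elements `raw`,
#'   `values` (normalized), `meta`, `n_imputed`.
#' @export
build_features <- function(hap, mask = NULL, locus_interval,
                           pair = hap_pair(hap), subwindows = 21L) {
  width <- (locus_interval[2] - locus_interval[1]) / subwindows
  if (abs(width - round(width)) > 1e-9)
    stop("locus length must divide evenly into subwindows")
  width <- round(width)
  starts <- locus_interval[1] + width * (seq_len(subwindows) - 1L)
  raw <- matrix(NA_real_, nrow = length(stat_set_names()),
                ncol = subwindows, dimnames = list(stat_set_names(), NULL))
  unmasked <- numeric(subwindows)
  for (k in seq_len(subwindows)) {
    iv <- c(starts[k], starts[k] + width)
    acc <- if (is.null(mask)) width else accessible_bp(mask, iv[1], iv[2])
    unmasked[k] <- acc / width
    raw[, k] <- if (acc > 0)
      suppressWarnings(compute_stat_set(hap, iv, pair, acc))
    else rep(NaN, nrow(raw))
  }
  center <- (subwindows + 1L) %/% 2L
  fm <- structure(list(raw = raw, values = NULL,
                       meta = list(chrom = hap$chrom,
                                   start = locus_interval[1],
                                   end = locus_interval[2],
                                   subwindow_bp = width,
                                   center_start = starts[center],
                                   center_end = starts[center] + width,
                                   unmasked_frac = unmasked),
                       n_imputed = NA_integer_),
                  class = "feature_matrix")
  normalize_features(fm)
}

#' Sum-normalize a feature matrix
#'
#' Each statistic (row) is divided by its sum across subwindows. Rows of
#' signed statistics that contain negative entries are first shifted by
#' their minimum (`shift_negative`, the behaviour of the diploS/HIC
#' family of feature vectors) so that the result is a proper spatial
#' profile in `[0, 1]`; without the shift, near-zero signed row sums
#' produce unbounded values. `NaN` cells are imputed to the row mean of
#' the defined cells (counted in `n_imputed`); rows that are entirely
#' undefined, or whose absolute sum falls below `eps` after any shift
#' (e.g. constant rows), fall back to the uniform row `1/K`.
#' Normalization is idempotent for non-negative rows.
#'
#' @param fm a `feature_matrix` (or a bare statistics x subwindow
#'   matrix).
#' @param eps row-sum guard (default 1e-8).
#' @param shift_negative shift rows containing negatives by their
#'   minimum before dividing (default `TRUE`).
#' @return the feature matrix with `values` filled in.
#' @export
normalize_features <- function(fm, eps = 1e-8, shift_negative = TRUE) {
  raw <- if (inherits(fm, "feature_matrix")) fm$raw else fm
  K <- ncol(raw)
  vals <- raw
  n_imp <- 0L
  for (i in seq_len(nrow(raw))) {
    x <- raw[i, ]
    bad <- !is.finite(x)
    if (any(bad)) {
      n_imp <- n_imp + sum(bad)
      if (all(bad)) {
        vals[i, ] <- 1 / K
        next
      }
      x[bad] <- mean(x[!bad])
    }
    if (shift_negative && any(x < 0)) x <- x - min(x)
    s <- sum(x)
    vals[i, ] <- if (abs(s) < eps) rep(1 / K, K) else x / s
  }
  if (inherits(fm, "feature_matrix")) {
    fm$values <- vals
    fm$n_imputed <- n_imp
    fm
  } else {
    structure(list(raw = raw, values = vals, meta = NULL,
                   n_imputed = n_imp), class = "feature_matrix")
  }
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d statistics x %d subwindows (%d imputed)\n",
              nrow(x$raw), ncol(x$raw), x$n_imputed))
  if (!is.null(x$meta))
    cat(sprintf("  %s:%d-%d (central %d-%d)\n", x$meta$chrom, x$meta$start,
                x$meta$end, x$meta$center_start, x$meta$center_end))
  invisible(x)
}

#' Feature arrays from simulated instances
#'
#' Computes the normalized feature matrix of every instance (over its
#' full locus, with its mirrored mask if present) and stacks them into
#' the array consumed by the classifier.
#'
#' @param instances list of `sim_instance`.
#' @param subwindows subwindows per locus.
#' @param drop_nan_frac instances whose feature matrix needed more than
#'   this fraction of imputed cells are dropped (default 0.5).
#' @return list with `x` (n x statistics x subwindows array), `y`
#'   (factor of labels), `dropped` (count).
#' @export
featurize_instances <- function(instances, subwindows = 21L,
                                drop_nan_frac = 0.5) {
  ns <- length(stat_set_names())
  keep <- logical(length(instances))
  mats <- vector("list", length(instances))
  labs <- character(length(instances))
  for (i in seq_along(instances)) {
    inst <- instances[[i]]
    fm <- build_features(inst$hap, inst$mask,
                         c(0, inst$params$locus_bp),
                         subwindows = subwindows)
    frac <- fm$n_imputed / length(fm$raw)
    keep[i] <- frac <= drop_nan_frac
    mats[[i]] <- fm$values
    labs[i] <- inst$label
  }
  mats <- mats[keep]
  labs <- labs[keep]
  x <- array(0, dim = c(length(mats), ns, subwindows))
  for (i in seq_along(mats)) x[i, , ] <- mats[[i]]
  list(x = x, y = factor(labs, levels = c("neutral", "shared",
                                          "divergent")),
       dropped = sum(!keep))
}
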