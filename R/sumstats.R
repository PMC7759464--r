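#' @useDynLib diverscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal helpers -------------------------------------------------

# Subset an allele matrix to an interval of site positions.
sites_in <- function(hap, interval) {
  if (is.null(interval)) rep(TRUE, length(hap$positions))
  else hap$positions >= interval[1] & hap$positions < interval[2]
}

# Per-site observed haplotype count and derived(/alt)-allele count.
site_counts <- function(alle) {
  list(n = colSums(!is.na(alle)),
       d = colSums(alle == 1L, na.rm = TRUE))
}

# Haplotype-identity preparation: drop sites with more than `max_missing`
# missing alleles in the panel, then impute remaining missing alleles to
# the panel major allele, so haplotype strings are comparable. Frequency
# statistics never see imputed alleles; only string identity does.
prep_identity <- function(alle, max_missing = 0.2) {
  if (ncol(alle) == 0L) return(alle)
  frac_na <- colMeans(is.na(alle))
  alle <- alle[, frac_na <= max_missing, drop = FALSE]
  if (anyNA(alle)) {
    for (j in which(colSums(is.na(alle)) > 0L)) {
      col <- alle[, j]
      maj <- if (mean(col, na.rm = TRUE) > 0.5) 1L else 0L
      col[is.na(col)] <- maj
      alle[, j] <- col
    }
  }
  alle
}

# Haplotype-class frequencies, sorted descending with lexicographic
# tie-break on the haplotype string (determinism).
hap_strings <- function(alle) {
  do.call(paste0, as.data.frame(alle))
}

hap_class_freqs <- function(alle) {
  if (nrow(alle) == 0L) return(numeric(0))
  if (ncol(alle) == 0L) return(1)
  str <- hap_strings(alle)
  tb <- table(str)
  tb <- tb[order(-as.integer(tb), names(tb))]
  as.numeric(tb) / nrow(alle)
}

# Pairwise difference counts between two 0/1 matrices (rows = haplotypes).
cross_distances <- function(A, B) {
  if (ncol(A) == 0L) return(matrix(0, nrow(A), nrow(B)))
  A %*% t(1 - B) + (1 - A) %*% t(B)
}

split_pair <- function(hap, pair) {
  pops <- hap_pops(hap)
  list(a = hap$alleles[pops == pair$pop_a, , drop = FALSE],
       b = hap$alleles[pops == pair$pop_b, , drop = FALSE])
}

# ---- within-population statistics ------------------------------------

#' Per-site nucleotide diversity (pi)
#'
#' Mean pairwise difference over all haplotype pairs, divided by the
#' number of accessible bp. Sites with fewer than two non-missing
#' haplotypes contribute nothing.
#'
#' @param hap a [hapmat()].
#' @param interval optional `c(start, end)` 0-based half-open restriction.
#' @param accessible_bp accessible (unmasked) bp of the interval.
#' @param per_site divide by `accessible_bp` (default); `FALSE` returns
#'   the per-window total.
#' @return pi per site; `NaN` (with a warning) when `accessible_bp` is 0.
#' @export
nucleotide_diversity <- function(hap, interval = NULL, accessible_bp,
                                 per_site = TRUE) {
  if (per_site && accessible_bp <= 0) {
    warning("accessible_bp is 0; pi undefined")
    return(NaN)
  }
  sc <- site_counts(hap$alleles[, sites_in(hap, interval), drop = FALSE])
  ok <- sc$n >= 2L
  tot <- sum(2 * sc$d[ok] * (sc$n[ok] - sc$d[ok]) /
               (sc$n[ok] * (sc$n[ok] - 1)))
  if (per_site) tot / accessible_bp else tot
}

# Total (not per-bp) mean pairwise difference over an allele matrix.
pi_total <- function(alle) {
  sc <- site_counts(alle)
  ok <- sc$n >= 2L
  sum(2 * sc$d[ok] * (sc$n[ok] - sc$d[ok]) / (sc$n[ok] * (sc$n[ok] - 1)))
}

#' Watterson's theta per site
#'
#' `S / (a1 * accessible_bp)` with `a1 = sum(1/i, i < n)` taken at the
#' panel haplotype count.
#'
#' @inheritParams nucleotide_diversity
#' @export
watterson_theta <- function(hap, interval = NULL, accessible_bp) {
  if (accessible_bp <= 0) return(NaN)
  alle <- hap$alleles[, sites_in(hap, interval), drop = FALSE]
  sc <- site_counts(alle)
  S <- sum(sc$d > 0L & sc$d < sc$n)
  n <- nrow(alle)
  if (n < 2L) return(NaN)
  a1 <- sum(1 / seq_len(n - 1L))
  S / (a1 * accessible_bp)
}

#' Tajima's D
#'
#' Standard normalization: `D = (pi_total - S/a1) / sqrt(e1 S + e2 S(S-1))`
#' with the usual constants derived from the haplotype count.
#'
#' @inheritParams nucleotide_diversity
#' @return `NaN` when there are no segregating sites or fewer than three
#'   haplotypes.
#' @export
tajimas_d <- function(hap, interval = NULL) {
  alle <- hap$alleles[, sites_in(hap, interval), drop = FALSE]
  n <- nrow(alle)
  if (n < 3L) return(NaN)
  sc <- site_counts(alle)
  seg <- sc$d > 0L & sc$d < sc$n
  S <- sum(seg)
  if (S == 0L) return(NaN)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total(alle) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fay and Wu's H (unnormalized)
#'
#' `H = theta_pi - theta_H` over polarized segregating sites, with
#' `theta_H = sum(2 d^2) / (n (n - 1))` where `d` is the derived-allele
#' count. Requires polarized sites; unpolarized sites are skipped.
#'
#' @inheritParams nucleotide_diversity
#' @param normalized if `TRUE`, divide by the standard variance term
#'   (Zeng et al. normalization); default is the original unnormalized
#'   statistic.
#' @export
fay_wu_h <- function(hap, interval = NULL, normalized = FALSE) {
  keep <- sites_in(hap, interval) & hap$polarized
  alle <- hap$alleles[, keep, drop = FALSE]
  sc <- site_counts(alle)
  seg <- sc$d > 0L & sc$d < sc$n
  if (!any(seg)) return(NaN)
  d <- sc$d[seg]; nn <- sc$n[seg]
  th_pi <- sum(2 * d * (nn - d) / (nn * (nn - 1)))
  th_h <- sum(2 * d^2 / (nn * (nn - 1)))
  H <- th_pi - th_h
  if (!normalized) return(H)
  # variance per Zeng et al. 2006 using theta_W estimates at panel size
  n <- nrow(alle)
  S <- sum(seg)
  a1 <- sum(1 / seq_len(n - 1L))
  bn1 <- sum(1 / seq_len(n)^2)
  th <- S / a1
  th2 <- S * (S - 1) / (a1^2 + sum(1 / seq_len(n - 1L)^2))
  v <- (n - 2) / (6 * (n - 1)) * th +
    (18 * n^2 * (3 * n + 2) * bn1 - (88 * n^3 + 9 * n^2 - 13 * n + 6)) /
      (9 * n * (n - 1)^2) * th2
  H / sqrt(max(v, .Machine$double.eps))
}

#' Garud's haplotype homozygosity statistics
#'
#' `H1 = sum(p_i^2)`, `H12 = (p1 + p2)^2 + sum(p_i^2, i >= 3)` and
#' `H2/H1 = (H1 - p1^2)/H1`, with `p_i` the descending haplotype-class
#' frequencies over the interval (exact string identity; frequency ties
#' broken lexicographically). An interval with no segregating sites
#' returns `(1, 1, 0)`.
#'
#' @inheritParams nucleotide_diversity
#' @return named numeric: `h1`, `h12`, `h2h1`.
#' @export
garud_h <- function(hap, interval = NULL) {
  alle <- prep_identity(hap$alleles[, sites_in(hap, interval),
                                    drop = FALSE])
  p <- hap_class_freqs(alle)
  if (length(p) == 0L) return(c(h1 = NaN, h12 = NaN, h2h1 = NaN))
  h1 <- sum(p^2)
  p1 <- p[1]
  p2 <- if (length(p) >= 2L) p[2] else 0
  h12 <- (p1 + p2)^2 + if (length(p) >= 3L) sum(p[-(1:2)]^2) else 0
  c(h1 = h1, h12 = h12, h2h1 = (h1 - p1^2) / h1)
}

#' 1-HAF score summary
#'
#' Each haplotype's HAF-1 score is the sum, over the polarized sites at
#' which it carries the derived allele, of that site's derived-allele
#' count. The window summary is the mean score over haplotypes (making it
#' comparable across sample sizes; note that some applications sum
#' instead).
#'
#' @inheritParams nucleotide_diversity
#' @export
haf_score <- function(hap, interval = NULL) {
  keep <- sites_in(hap, interval) & hap$polarized
  if (!any(keep)) return(NaN)
  alle <- hap$alleles[, keep, drop = FALSE]
  keep2 <- colMeans(is.na(alle)) <= 0.2
  alle <- alle[, keep2, drop = FALSE]
  if (ncol(alle) == 0L) return(NaN)
  d <- site_counts(alle)$d
  carry <- prep_identity(alle, max_missing = 1)  # impute for carriage only
  mean(carry %*% d)
}

# ---- between-population statistics -----------------------------------

#' Hudson's FST as a ratio of averages
#'
#' Per site, with sample allele frequencies `p1`, `p2` and haplotype
#' counts `n1`, `n2`:
#' `num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `den = p1(1-p2) + p2(1-p1)`. The window value is `sum(num)/sum(den)`;
#' sites monomorphic across both samples contribute nothing, and the
#' window value may be negative.
#'
#' @inheritParams nucleotide_diversity
#' @param pair a [population_pair()].
#' @return list with `fst` and the per-site `num` and `den` vectors.
#' @export
hudson_fst <- function(hap, interval = NULL, pair = hap_pair(hap)) {
  sp <- split_pair(hap_subset_sites(hap, sites_in(hap, interval)), pair)
  ca <- site_counts(sp$a); cb <- site_counts(sp$b)
  ok <- ca$n >= 2L & cb$n >= 2L
  p1 <- ca$d[ok] / ca$n[ok]; p2 <- cb$d[ok] / cb$n[ok]
  n1 <- ca$n[ok]; n2 <- cb$n[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- den > 0
  fst <- if (sum(den[use]) == 0) NaN else sum(num[use]) / sum(den[use])
  list(fst = fst, num = num[use], den = den[use])
}

#' Between-population divergence DXY
#'
#' Mean per-site difference over all between-population haplotype pairs,
#' divided by the accessible bp.
#'
#' @inheritParams hudson_fst
#' @param accessible_bp accessible bp of the interval.
#' @export
dxy <- function(hap, interval = NULL, pair = hap_pair(hap),
                accessible_bp) {
  if (accessible_bp <= 0) return(NaN)
  sp <- split_pair(hap_subset_sites(hap, sites_in(hap, interval)), pair)
  ca <- site_counts(sp$a); cb <- site_counts(sp$b)
  ok <- ca$n >= 1L & cb$n >= 1L
  sum((ca$d[ok] * (cb$n[ok] - cb$d[ok]) +
         cb$d[ok] * (ca$n[ok] - ca$d[ok])) /
        (ca$n[ok] * cb$n[ok])) / accessible_bp
}

#' Gmin: minimum over mean between-population distance
#'
#' The minimum pairwise difference count across all between-population
#' haplotype pairs divided by the mean; values near 0 flag recently
#' shared haplotypes across the pair.
#'
#' @inheritParams hudson_fst
#' @export
gmin <- function(hap, interval = NULL, pair = hap_pair(hap)) {
  sub <- hap_subset_sites(hap, sites_in(hap, interval))
  pops <- hap_pops(sub)
  alle <- prep_identity(sub$alleles)
  A <- alle[pops == pair$pop_a, , drop = FALSE]
  B <- alle[pops == pair$pop_b, , drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L) return(NaN)
  d <- cross_distances(A, B)
  if (mean(d) == 0) return(NaN)
  min(d) / mean(d)
}

#' SS-H12: signed pooled haplotype homozygosity
#'
#' Pooled-sample H12 with a sign encoding whether the modal pooled
#' haplotype class is shared between the two populations: +1 when the
#' modal class occurs in both populations at no less than half its pooled
#' frequency (shared sweep), -1 otherwise (population-private modal
#' class, divergent sweep). Large magnitude indicates a sweep; values
#' near 0 indicate neutrality.
#'
#' @inheritParams hudson_fst
#' @export
ss_h12 <- function(hap, interval = NULL, pair = hap_pair(hap)) {
  sub <- hap_subset_sites(hap, sites_in(hap, interval))
  if (ncol(sub$alleles) == 0L || nrow(sub$alleles) == 0L) return(NaN)
  pops <- hap_pops(sub)
  alle <- prep_identity(sub$alleles)
  if (ncol(alle) == 0L) return(NaN)
  str <- hap_strings(alle)
  tb <- table(str)
  tb <- tb[order(-as.integer(tb), names(tb))]
  p <- as.numeric(tb) / length(str)
  h12 <- (p[1] + if (length(p) >= 2L) p[2] else 0)^2 +
    if (length(p) >= 3L) sum(p[-(1:2)]^2) else 0
  modal <- names(tb)[1]
  qa <- mean(str[pops == pair$pop_a] == modal)
  qb <- mean(str[pops == pair$pop_b] == modal)
  sign <- if (min(qa, qb) >= p[1] / 2) 1 else -1
  sign * h12
}

# ---- the full statistic set ------------------------------------------

#' Row order of the feature matrix
#' @export
stat_set_names <- function() {
  c("pi_a", "pi_b", "tajd_a", "tajd_b", "faywu_h_a", "faywu_h_b",
    "h1_a", "h1_b", "h12_a", "h12_b", "h2h1_a", "h2h1_b",
    "haf1_a", "haf1_b", "fst", "dxy", "gmin", "ssh12")
}

# matrix-level building blocks used by the windowed driver (avoid
# repeated container construction in hot loops)

pi_mat <- function(alle, acc) {
  if (acc <= 0) return(NaN)
  sc <- site_counts(alle)
  ok <- sc$n >= 2L
  sum(2 * sc$d[ok] * (sc$n[ok] - sc$d[ok]) /
        (sc$n[ok] * (sc$n[ok] - 1))) / acc
}

tajd_mat <- function(alle) {
  n <- nrow(alle)
  if (n < 3L) return(NaN)
  sc <- site_counts(alle)
  S <- sum(sc$d > 0L & sc$d < sc$n)
  if (S == 0L) return(NaN)
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total(alle) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

fwh_mat <- function(alle, pol) {
  alle <- alle[, pol, drop = FALSE]
  sc <- site_counts(alle)
  seg <- sc$d > 0L & sc$d < sc$n
  if (!any(seg)) return(NaN)
  d <- sc$d[seg]; nn <- sc$n[seg]
  sum(2 * d * (nn - d) / (nn * (nn - 1))) -
    sum(2 * d^2 / (nn * (nn - 1)))
}

garud_mat <- function(alle) {
  p <- hap_class_freqs(prep_identity(alle))
  if (length(p) == 0L) return(c(h1 = NaN, h12 = NaN, h2h1 = NaN))
  h1 <- sum(p^2)
  p1 <- p[1]
  p2 <- if (length(p) >= 2L) p[2] else 0
  h12 <- (p1 + p2)^2 + if (length(p) >= 3L) sum(p[-(1:2)]^2) else 0
  c(h1 = h1, h12 = h12, h2h1 = (h1 - p1^2) / h1)
}

haf_mat <- function(alle, pol) {
  alle <- alle[, pol, drop = FALSE]
  if (ncol(alle) == 0L) return(NaN)
  keep2 <- colMeans(is.na(alle)) <= 0.2
  alle <- alle[, keep2, drop = FALSE]
  if (ncol(alle) == 0L) return(NaN)
  d <- site_counts(alle)$d
  carry <- prep_identity(alle, max_missing = 1)
  mean(carry %*% d)
}

fst_mat <- function(A, B) {
  ca <- site_counts(A); cb <- site_counts(B)
  ok <- ca$n >= 2L & cb$n >= 2L
  p1 <- ca$d[ok] / ca$n[ok]; p2 <- cb$d[ok] / cb$n[ok]
  n1 <- ca$n[ok]; n2 <- cb$n[ok]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  use <- den > 0
  if (sum(den[use]) == 0) NaN else sum(num[use]) / sum(den[use])
}

dxy_mat <- function(A, B, acc) {
  if (acc <= 0) return(NaN)
  ca <- site_counts(A); cb <- site_counts(B)
  ok <- ca$n >= 1L & cb$n >= 1L
  sum((ca$d[ok] * (cb$n[ok] - cb$d[ok]) +
         cb$d[ok] * (ca$n[ok] - ca$d[ok])) /
        (ca$n[ok] * cb$n[ok])) / acc
}

gmin_mat <- function(A, B) {
  keep <- colMeans(is.na(rbind(A, B))) <= 0.2
  Ai <- prep_identity(rbind(A, B))
  A2 <- Ai[seq_len(nrow(A)), , drop = FALSE]
  B2 <- Ai[nrow(A) + seq_len(nrow(B)), , drop = FALSE]
  if (nrow(A2) == 0L || nrow(B2) == 0L) return(NaN)
  d <- cross_distances(A2, B2)
  if (mean(d) == 0) return(NaN)
  min(d) / mean(d)
}

ssh12_mat <- function(A, B) {
  alle <- rbind(A, B)
  if (ncol(alle) == 0L || nrow(alle) == 0L) return(NaN)
  alle <- prep_identity(alle)
  if (ncol(alle) == 0L) return(NaN)
  str <- hap_strings(alle)
  tb <- table(str)
  tb <- tb[order(-as.integer(tb), names(tb))]
  p <- as.numeric(tb) / length(str)
  h12 <- (p[1] + if (length(p) >= 2L) p[2] else 0)^2 +
    if (length(p) >= 3L) sum(p[-(1:2)]^2) else 0
  modal <- names(tb)[1]
  qa <- mean(str[seq_len(nrow(A))] == modal)
  qb <- mean(str[nrow(A) + seq_len(nrow(B))] == modal)
  (if (min(qa, qb) >= p[1] / 2) 1 else -1) * h12
}

#' Compute the full summary-statistic set on an interval
#'
#' Seven within-population statistics for each population plus four
#' between-population statistics; undefined values are carried as `NaN`,
#' never silently zero.
#'
#' @inheritParams hudson_fst
#' @param accessible_bp accessible bp of the interval.
#' @return named numeric vector in [stat_set_names()] order.
#' @export
compute_stat_set <- function(hap, interval = NULL, pair = hap_pair(hap),
                             accessible_bp) {
  keep <- sites_in(hap, interval)
  alle <- hap$alleles[, keep, drop = FALSE]
  pol <- hap$polarized[keep]
  pops <- hap_pops(hap)
  A <- alle[pops == pair$pop_a, , drop = FALSE]
  B <- alle[pops == pair$pop_b, , drop = FALSE]
  ga <- garud_mat(A); gb <- garud_mat(B)
  out <- c(
    pi_a = pi_mat(A, accessible_bp), pi_b = pi_mat(B, accessible_bp),
    tajd_a = tajd_mat(A), tajd_b = tajd_mat(B),
    faywu_h_a = fwh_mat(A, pol), faywu_h_b = fwh_mat(B, pol),
    h1_a = ga[["h1"]], h1_b = gb[["h1"]],
    h12_a = ga[["h12"]], h12_b = gb[["h12"]],
    h2h1_a = ga[["h2h1"]], h2h1_b = gb[["h2h1"]],
    haf1_a = haf_mat(A, pol), haf1_b = haf_mat(B, pol),
    fst = fst_mat(A, B), dxy = dxy_mat(A, B, accessible_bp),
    gmin = gmin_mat(A, B), ssh12 = ssh12_mat(A, B))
  out[stat_set_names()]
}
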