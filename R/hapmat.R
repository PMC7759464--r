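#' Phased haplotype matrix
#'
#' The central container of the pipeline: a matrix of phased alleles with
#' rows = haplotypes and columns = biallelic polymorphic sites. Alleles are
#' coded 0 (reference, or ancestral once polarized), 1 (alternate/derived)
#' and `NA` (missing). Two consecutive rows belong to one diploid sample.
#' All coordinates are 0-based internally; 1-based coordinates appear only
#' at the VCF boundary.
#'
#' @param alleles integer matrix of 0/1/NA, haplotypes x sites.
#' @param positions integer vector of 0-based site coordinates, strictly
#'   increasing.
#' @param chrom chromosome identifier (scalar character).
#' @param sample_ids one id per diploid sample (`nrow(alleles)/2` of them).
#' @param pop_of_sample population label per sample, parallel to
#'   `sample_ids`.
#' @param polarized logical per site; `TRUE` means codes 0/1 are
#'   ancestral/derived rather than ref/alt.
#' @return an object of class `hapmat`.
#' @export
hapmat <- function(alleles, positions, chrom, sample_ids, pop_of_sample,
                   polarized = rep(FALSE, length(positions))) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  positions <- as.integer(positions)
  stopifnot(ncol(alleles) == length(positions),
            length(polarized) == length(positions))
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotype count must be even (two rows per diploid sample)")
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("need exactly two haplotype rows per sample id")
  if (length(sample_ids) != length(pop_of_sample))
    stop("pop_of_sample must be parallel to sample_ids")
  if (length(positions) > 1L && any(diff(positions) <= 0L))
    stop("positions must be strictly increasing")
  bad <- alleles[!is.na(alleles)]
  if (length(bad) && !all(bad %in% c(0L, 1L)))
    stop("alleles must be 0, 1 or NA")
  structure(list(alleles = alleles,
                 positions = positions,
                 chrom = as.character(chrom)[1],
                 sample_ids = as.character(sample_ids),
                 pop_of_sample = as.character(pop_of_sample),
                 polarized = as.logical(polarized)),
            class = "hapmat")
}

#' @export
print.hapmat <- function(x, ...) {
  cat(sprintf("hapmat: %d haplotypes (%d samples) x %d sites on %s\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles),
              x$chrom))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(table(x$pop_of_sample)),
                            table(x$pop_of_sample)), collapse = ", ")))
  cat(sprintf("  polarized sites: %d / %d\n",
              sum(x$polarized), length(x$polarized)))
  invisible(x)
}

#' Population label of every haplotype row
#' @param hap a [hapmat()].
#' @return character vector of length `nrow(hap$alleles)`.
#' @export
hap_pops <- function(hap) rep(hap$pop_of_sample, each = 2L)

#' Number of haplotypes
#' @param hap a [hapmat()].
#' @export
n_haplotypes <- function(hap) nrow(hap$alleles)

#' Subset a haplotype matrix by site index
#' @param hap a [hapmat()].
#' @param idx integer or logical index over sites (columns).
#' @export
hap_subset_sites <- function(hap, idx) {
  hapmat(hap$alleles[, idx, drop = FALSE], hap$positions[idx], hap$chrom,
         hap$sample_ids, hap$pop_of_sample, hap$polarized[idx])
}

#' Restrict to sites within a 0-based half-open interval
#' @param hap a [hapmat()].
#' @param start,end interval bounds, 0-based half-open.
#' @export
hap_subset_interval <- function(hap, start, end) {
  hap_subset_sites(hap, hap$positions >= start & hap$positions < end)
}

#' Restrict to the haplotypes of given populations
#' @param hap a [hapmat()].
#' @param pops character vector of population labels to keep.
#' @export
hap_subset_pops <- function(hap, pops) {
  keep <- hap$pop_of_sample %in% pops
  rows <- rep(keep, each = 2L)
  hapmat(hap$alleles[rows, , drop = FALSE], hap$positions, hap$chrom,
         hap$sample_ids[keep], hap$pop_of_sample[keep], hap$polarized)
}

#' A pair of focal populations
#'
#' @param pop_a,pop_b distinct population labels.
#' @param n_a,n_b haplotype sample sizes (>= 2 each).
#' @export
population_pair <- function(pop_a, pop_b, n_a = NA_integer_,
                            n_b = NA_integer_) {
  if (identical(pop_a, pop_b)) stop("population labels must be distinct")
  if (!is.na(n_a) && n_a < 2L || !is.na(n_b) && n_b < 2L)
    stop("need at least 2 haplotypes per population")
  structure(list(pop_a = pop_a, pop_b = pop_b,
                 n_a = as.integer(n_a), n_b = as.integer(n_b)),
            class = "population_pair")
}

#' Derive a population pair from a haplotype matrix
#' @param hap a [hapmat()] carrying exactly two population labels.
#' @export
hap_pair <- function(hap) {
  tb <- table(hap$pop_of_sample)
  if (length(tb) != 2L)
    stop("haplotype matrix must carry exactly two populations")
  population_pair(names(tb)[1], names(tb)[2], 2L * tb[[1]], 2L * tb[[2]])
}
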