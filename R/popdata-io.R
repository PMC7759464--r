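#' Read a two-column population file
#'
#' Whitespace- or tab-separated `sample  population` table; lines starting
#' with `#` are comments.
#'
#' @param path popfile path.
#' @return named character vector: population label per sample id.
#' @export
read_popfile <- function(path) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          colClasses = "character")
  if (ncol(tb) < 2L) stop("popfile must have two columns: sample, population")
  stats::setNames(tb[[2]], tb[[1]])
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Keeps biallelic SNPs only. Unphased or half-called genotypes become
#' missing on both haplotypes of the sample. VCF 1-based positions are
#' converted to the package's 0-based convention.
#'
#' @param path VCF (optionally bgzipped) with GT fields for all samples.
#' @param popfile path to a popfile, or a named vector as returned by
#'   [read_popfile()].
#' @param region optional `chrom:start-end` restriction (1-based,
#'   inclusive, as in the VCF).
#' @return a [hapmat()].
#' @export
read_phased_vcf <- function(path, popfile, region = NULL) {
  pops <- if (is.character(popfile) && length(popfile) == 1L &&
              file.exists(popfile)) read_popfile(popfile) else popfile
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(v@gt) == 0L || !"FORMAT" %in% colnames(v@gt))
    stop("VCF has no genotype (GT) section")
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("VCF records lack a GT field")
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, names(pops))
  if (length(unknown))
    stop("sample(s) absent from popfile: ", paste(unknown, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
    keep <- keep & chrom == m[2]
    if (nzchar(m[3]))
      keep <- keep & pos >= as.integer(m[4]) & pos <= as.integer(m[5])
  } else if (length(unique(chrom[keep])) > 1L) {
    stop("VCF spans several chromosomes; pass `region`")
  }
  gt <- gt[keep, , drop = FALSE]
  pos <- pos[keep]; chrom <- chrom[keep]
  ns <- length(samples)
  alle <- matrix(NA_integer_, nrow = 2L * ns, ncol = nrow(gt))
  for (j in seq_len(ns)) {
    g <- gt[, j]
    ok <- !is.na(g) & grepl("^[01]\\|[01]$", g)
    a1 <- a2 <- rep(NA_integer_, length(g))
    a1[ok] <- as.integer(substr(g[ok], 1L, 1L))
    a2[ok] <- as.integer(substr(g[ok], 3L, 3L))
    alle[2L * j - 1L, ] <- a1
    alle[2L * j, ] <- a2
  }
  o <- order(pos)
  hapmat(alle[, o, drop = FALSE], pos[o] - 1L,
         if (length(chrom)) chrom[1] else "NA",
         samples, unname(pops[samples]))
}

#' Write a haplotype matrix as a minimal phased VCF
#'
#' Site alleles are written as A (code 0) / T (code 1) unless `ref`/`alt`
#' are supplied; this is sufficient for round-tripping genotypes, phase and
#' positions.
#'
#' @param hap a [hapmat()].
#' @param path output VCF path.
#' @param ref,alt optional per-site allele characters.
#' @export
write_phased_vcf <- function(hap, path, ref = NULL, alt = NULL) {
  ns <- length(hap$sample_ids)
  S <- ncol(hap$alleles)
  if (is.null(ref)) ref <- rep("A", S)
  if (is.null(alt)) alt <- rep("T", S)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", hap$chrom),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", hap$sample_ids),
                     collapse = "\t")), con)
  if (S > 0L) {
    gt <- matrix("", nrow = S, ncol = ns)
    for (j in seq_len(ns)) {
      a1 <- hap$alleles[2L * j - 1L, ]
      a2 <- hap$alleles[2L * j, ]
      g <- paste0(a1, "|", a2)
      g[is.na(a1) | is.na(a2)] <- ".|."
      gt[, j] <- g
    }
    lines <- paste(hap$chrom, hap$positions + 1L, ".", ref, alt, ".",
                   "PASS", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Polarize a haplotype matrix against an outgroup
#'
#' A site receives an ancestral-allele assignment when at least
#' `min_valid` of the `k` outgroup diploids have a fully called genotype,
#' the outgroup is monomorphic at the site, and the outgroup allele is one
#' of the two alleles present in the ingroup encoding (code 0 or 1).
#' Passing sites are recoded so that 0 = ancestral and flagged
#' `polarized = TRUE`; failing sites are left unchanged with
#' `polarized = FALSE` and are skipped by unfolded statistics.
#'
#' @param hap ingroup [hapmat()].
#' @param outgroup outgroup [hapmat()] over the same sites (same
#'   chromosome and positions).
#' @param k expected number of outgroup diploids (default 5).
#' @param min_valid minimum fully-called outgroup diploids (default
#'   `k - 1`).
#' @return `hap` with recoded alleles and updated `polarized` flags.
#' @export
polarize <- function(hap, outgroup, k = length(outgroup$sample_ids),
                     min_valid = k - 1L) {
  if (!identical(hap$positions, outgroup$positions) ||
      !identical(hap$chrom, outgroup$chrom))
    stop("ingroup and outgroup must cover the same sites")
  og <- outgroup$alleles
  ns <- length(outgroup$sample_ids)
  alle <- hap$alleles
  pol <- rep(FALSE, ncol(alle))
  for (s in seq_len(ncol(alle))) {
    g <- matrix(og[, s], nrow = 2L)   # 2 x ns
    valid <- colSums(is.na(g)) == 0L
    if (sum(valid) < min_valid) next
    obs <- unique(as.vector(g[, valid, drop = FALSE]))
    if (length(obs) != 1L) next       # outgroup not monomorphic
    anc <- obs[1]
    ing <- alle[, s]
    if (!anc %in% c(0L, 1L)) next     # outgroup allele absent from ingroup
    if (anc == 1L) alle[, s] <- 1L - ing
    pol[s] <- TRUE
  }
  hapmat(alle, hap$positions, hap$chrom, hap$sample_ids,
         hap$pop_of_sample, pol)
}

#' Read a per-sample, per-site depth matrix
#'
#' TSV with a header of sample ids and one row per site (aligned with the
#' haplotype matrix it accompanies).
#'
#' @param path TSV file.
#' @return integer matrix sites x samples.
#' @export
read_depth_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  storage.mode(m) <- "integer"
  if (any(m < 0, na.rm = TRUE)) stop("depths must be non-negative")
  m
}

#' Site and genotype filtering on sequencing depth
#'
#' Sites where fewer than `min_frac` of the diploid samples reach
#' `min_depth` coverage are removed entirely; at retained sites, genotypes
#' below `min_depth` are set to missing on both haplotypes.
#'
#' @param hap a [hapmat()].
#' @param depth sites x samples integer matrix (see
#'   [read_depth_matrix()]); columns ordered as `hap$sample_ids`.
#' @param min_depth minimum per-genotype depth (default 5).
#' @param min_frac minimum fraction of samples at `min_depth` (default
#'   0.8).
#' @param per_population apply the `min_frac` rule within every
#'   population separately (default) rather than panel-wide.
#' @return filtered [hapmat()].
#' @export
coverage_filter <- function(hap, depth, min_depth = 5L, min_frac = 0.8,
                            per_population = TRUE) {
  ns <- length(hap$sample_ids)
  if (nrow(depth) != ncol(hap$alleles) || ncol(depth) != ns)
    stop("depth matrix must be sites x samples, aligned with `hap`")
  ok <- depth >= min_depth        # sites x samples
  if (per_population) {
    keep <- rep(TRUE, nrow(depth))
    for (p in unique(hap$pop_of_sample)) {
      cols <- hap$pop_of_sample == p
      keep <- keep &
        rowMeans(ok[, cols, drop = FALSE]) >= min_frac - 1e-12
    }
  } else {
    keep <- rowMeans(ok) >= min_frac - 1e-12
  }
  alle <- hap$alleles
  for (j in seq_len(ns)) {
    miss <- !ok[, j]
    alle[2L * j - 1L, miss] <- NA_integer_
    alle[2L * j, miss] <- NA_integer_
  }
  hap2 <- hapmat(alle, hap$positions, hap$chrom, hap$sample_ids,
                 hap$pop_of_sample, hap$polarized)
  hap_subset_sites(hap2, keep)
}

#' Read a demographic-model configuration (JSON or YAML)
#'
#' @param path file ending in `.json`, `.yml` or `.yaml` holding the
#'   fields of [demographic_model()].
#' @export
read_model_config <- function(path) {
  lst <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(demographic_model, lst)
}

#' Write a demographic-model configuration as JSON
#' @param model a [demographic_model()].
#' @param path output path.
#' @export
write_model_config <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
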