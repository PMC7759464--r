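# Synthetic end-to-end fixtures: a phased two-population cohort VCF with
# planted sweeps, an accessibility mask, a popfile, a synthetic outgroup
# for polarization and a depth matrix - everything the empirical pipeline
# consumes, with known ground truth.

#' Specification of a synthetic cohort fixture
#'
#' @param n_chroms,chrom_bp chromosome count and length.
#' @param model a [demographic_model()] (defaults to the desk model).
#' @param planted data.frame with columns chrom (index), position (bp),
#'   category ("shared"/"divergent"), s, origin; `NULL` for a fully
#'   neutral genome. Planted positions must be at least `min_spacing_bp`
#'   apart.
#' @param n_samples diploids per population.
#' @param masked_fraction target fraction of masked sites (0 to 0.9).
#' @param outgroup_n outgroup diploids (polarization panel).
#' @param outgroup_miss_frac per-genotype missing probability in the
#'   outgroup.
#' @param outgroup_poly_frac fraction of sites where the outgroup is
#'   polymorphic (defeating the polarization rule).
#' @param refalt_swap_frac fraction of sites written with the derived
#'   allele as VCF REF (exercising ancestral-allele recoding).
#' @param depth_mean,depth_disp negative-binomial depth model (mean,
#'   dispersion).
#' @param depth_fail_frac fraction of sites engineered to fail the
#'   coverage rule.
#' @param min_spacing_bp minimum distance between planted loci.
#' @param seed master seed.
#' @export
fixture_spec <- function(n_chroms = 2L, chrom_bp = 2e6,
                         model = desk_model(), planted = NULL,
                         n_samples = c(20L, 20L),
                         masked_fraction = 0.38, outgroup_n = 5L,
                         outgroup_miss_frac = 0.05,
                         outgroup_poly_frac = 0.03,
                         refalt_swap_frac = 0.3, depth_mean = 20,
                         depth_disp = 5, depth_fail_frac = 0,
                         min_spacing_bp = 105000, seed = 1L) {
  if (masked_fraction < 0 || masked_fraction > 0.9)
    stop("masked_fraction must be in [0, 0.9]")
  if (!is.null(planted) && nrow(planted)) {
    if (any(planted$position < 0 | planted$position >= chrom_bp) ||
        any(planted$chrom < 1L | planted$chrom > n_chroms))
      stop("planted loci must lie within the chromosomes")
    for (ch in unique(planted$chrom)) {
      p <- sort(planted$position[planted$chrom == ch])
      if (length(p) > 1L && any(diff(p) < min_spacing_bp))
        stop("planted loci closer than one locus length: infeasible")
    }
  }
  structure(list(n_chroms = as.integer(n_chroms), chrom_bp = chrom_bp,
                 model = model, planted = planted,
                 n_samples = as.integer(n_samples),
                 masked_fraction = masked_fraction,
                 outgroup_n = as.integer(outgroup_n),
                 outgroup_miss_frac = outgroup_miss_frac,
                 outgroup_poly_frac = outgroup_poly_frac,
                 refalt_swap_frac = refalt_swap_frac,
                 depth_mean = depth_mean, depth_disp = depth_disp,
                 depth_fail_frac = depth_fail_frac,
                 min_spacing_bp = min_spacing_bp,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Default planted-sweep layout: five strong divergent sweeps
#' @param spec_chrom_bp chromosome length the layout is spread over.
#' @export
default_planted <- function(spec_chrom_bp = 2e6) {
  data.frame(chrom = c(1L, 1L, 1L, 2L, 2L),
             position = round(spec_chrom_bp * c(0.2, 0.5, 0.8, 0.35, 0.7)),
             category = "divergent", s = 0.3, origin = "de_novo")
}

# random mask intervals (exponential lengths) until the target fraction
random_mask <- function(chrom, chrom_bp, frac, seed, mean_len = 500) {
  if (frac <= 0) return(sitemask(chrom, chrom_bp))
  set.seed(seed)
  covered <- 0
  iv <- matrix(numeric(0), ncol = 2L)
  target <- frac * chrom_bp
  while (covered < target) {
    len <- max(50, round(stats::rexp(1, 1 / mean_len)))
    s <- floor(stats::runif(1, 0, chrom_bp - len))
    iv <- rbind(iv, c(s, s + len))
    m <- sitemask(chrom, chrom_bp, iv)
    covered <- masked_bp(m)
  }
  sitemask(chrom, chrom_bp, iv)
}

#' Generate a complete synthetic cohort
#'
#' Simulates each chromosome with the forward engine (planting the
#' specified sweeps), synthesizes an outgroup panel that is ancestral
#' and monomorphic at most sites (with configurable missingness and
#' polymorphism so the polarization rule is exercised), draws a random
#' accessibility mask to the target masked fraction, and writes the
#' standard file set: phased cohort VCF, outgroup VCF, mask BED, popfile
#' TSV, truth BED of planted loci, depth TSV and a JSON manifest. The
#' matching in-memory ground truth is returned alongside the paths.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory.
#' @return list with `files` (paths) and `truth` (haps, masks, outgroup
#'   haps, planted table, per-chromosome polarizable flags).
#' @export
make_cohort <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  model <- spec$model
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  haps <- list(); masks <- list(); oghaps <- list()
  depth_files <- character(0)
  vcf_in <- file.path(dir, "cohort.vcf")
  vcf_og <- file.path(dir, "outgroup.vcf")
  unlink(c(vcf_in, vcf_og))
  truth_rows <- list()
  n_a <- 2L * spec$n_samples[1]; n_b <- 2L * spec$n_samples[2]
  for (ci in seq_len(spec$n_chroms)) {
    ch <- chroms[ci]
    sel <- NULL
    pl <- spec$planted
    if (!is.null(pl) && any(pl$chrom == ci)) {
      pl <- pl[pl$chrom == ci, , drop = FALSE]
      set.seed(derive_seed(spec$seed, 5000L + ci))
      daughters <- ifelse(pl$category == "shared", 0L,
                          1L + (stats::runif(nrow(pl)) < 0.5))
      n2 <- ifelse(pl$category == "shared", 2 * model$founder_size,
                   2 * model$daughter_sizes[1])
      f0 <- ifelse(pl$origin == "de_novo", 1 / n2, 1e-2)
      sel <- data.frame(pos_rel = pl$position / spec$chrom_bp,
                        s = pl$s,
                        copies = pmax(1L, round(f0 * n2)),
                        onset = ifelse(pl$category == "shared", 0L, 1L),
                        daughter = daughters)
      for (i in seq_len(nrow(pl)))
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(chrom = ch, position = pl$position[i],
                     category = pl$category[i], s = pl$s[i],
                     swept_pop = c("both", "A", "B")[daughters[i] + 1L])
    }
    res <- run_forward(model, spec$chrom_bp,
                       model$mutation_rate * spec$chrom_bp,
                       model$recombination_rate * spec$chrom_bp,
                       n_a, n_b, seed = derive_seed(spec$seed, 100L + ci),
                       sel = sel, f_end = 0.5, max_tries = 500L)
    hap <- engine_to_hapmat(res, ch)
    haps[[ch]] <- hap
    masks[[ch]] <- random_mask(ch, spec$chrom_bp, spec$masked_fraction,
                               derive_seed(spec$seed, 200L + ci))
    # ---- synthetic outgroup: ancestral & monomorphic at most sites ----
    S <- ncol(hap$alleles)
    set.seed(derive_seed(spec$seed, 300L + ci))
    og <- matrix(0L, nrow = 2L * spec$outgroup_n, ncol = S)
    # missingness acts per diploid genotype: both haplotypes together
    for (j in seq_len(spec$outgroup_n)) {
      gm <- stats::runif(S) < spec$outgroup_miss_frac
      og[2L * j - 1L, gm] <- NA_integer_
      og[2L * j, gm] <- NA_integer_
    }
    polysite <- stats::runif(S) < spec$outgroup_poly_frac
    for (s in which(polysite)) {
      j <- sample.int(spec$outgroup_n, 1L)
      og[2L * j - 1L, s] <- 1L  # heterozygous individual: not monomorphic
    }
    oghap <- hapmat(og, hap$positions, ch,
                    paste0("OG_", seq_len(spec$outgroup_n)),
                    rep("outgroup", spec$outgroup_n))
    oghaps[[ch]] <- oghap
    # ---- VCF coding: swap REF/ALT at a fraction of sites --------------
    set.seed(derive_seed(spec$seed, 400L + ci))
    swap <- stats::runif(S) < spec$refalt_swap_frac
    ing_vcf <- hap
    ing_vcf$alleles[, swap] <- 1L - ing_vcf$alleles[, swap]
    og_vcf <- oghap
    og_vcf$alleles[, swap] <- 1L - og_vcf$alleles[, swap]
    append_vcf(ing_vcf, vcf_in, first = ci == 1L)
    append_vcf(og_vcf, vcf_og, first = ci == 1L)
    # ---- depths -------------------------------------------------------
    dfile <- file.path(dir, sprintf("depth_%s.tsv", ch))
    make_depths(spec, S, c(hap$sample_ids),
                derive_seed(spec$seed, 600L + ci), dfile)
    depth_files <- c(depth_files, dfile)
    write_mask_bed(masks[[ch]], file.path(dir, sprintf("mask_%s.bed", ch)))
  }
  popfile <- file.path(dir, "popfile.tsv")
  utils::write.table(
    data.frame(sample = haps[[1]]$sample_ids,
               pop = haps[[1]]$pop_of_sample),
    popfile, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
  else data.frame(chrom = character(0), position = numeric(0),
                  category = character(0), s = numeric(0),
                  swept_pop = character(0))
  truth_bed <- file.path(dir, "truth.bed")
  utils::write.table(
    if (nrow(truth))
      data.frame(truth$chrom,
                 format(pmax(0, truth$position - spec$min_spacing_bp / 2),
                        scientific = FALSE, trim = TRUE),
                 format(truth$position + spec$min_spacing_bp / 2,
                        scientific = FALSE, trim = TRUE),
                 truth$category)
    else data.frame(character(0), character(0), character(0),
                    character(0)),
    truth_bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  sp <- unclass(spec)
  sp$model <- unclass(sp$model)
  sp$planted <- NULL
  jsonlite::write_json(list(spec = sp, chroms = chroms,
                            planted = truth),
                       manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(files = list(vcf = vcf_in, outgroup_vcf = vcf_og,
                    popfile = popfile,
                    masks = file.path(dir, sprintf("mask_%s.bed", chroms)),
                    depths = depth_files, truth_bed = truth_bed,
                    manifest = manifest),
       truth = list(haps = haps, masks = masks, outgroup = oghaps,
                    planted = truth))
}

# append one chromosome's records to a growing multi-chromosome VCF
append_vcf <- function(hap, path, first) {
  tmp <- tempfile(fileext = ".vcf")
  write_phased_vcf(hap, tmp)
  lines <- readLines(tmp)
  unlink(tmp)
  if (first) {
    writeLines(lines, path)
  } else {
    body <- lines[!startsWith(lines, "#")]
    con <- file(path, "a")
    writeLines(body, con)
    close(con)
  }
  invisible(path)
}

#' Synthetic per-sample sequencing depths
#'
#' Negative-binomial depths with a configurable fraction of sites
#' engineered to fail the coverage rule (more than 20 percent of samples
#' below 5x). When the requested mean depth makes the all-pass state
#' impossible, that is flagged in the returned report.
#'
#' @param spec a [fixture_spec()].
#' @param n_sites number of sites.
#' @param sample_ids diploid sample ids (column names).
#' @param seed RNG seed.
#' @param path optional TSV output path.
#' @return invisible list: the depth matrix and a small report.
#' @export
make_depths <- function(spec, n_sites, sample_ids, seed, path = NULL) {
  set.seed(seed)
  ns <- length(sample_ids)
  depth <- matrix(stats::rnbinom(n_sites * ns, mu = spec$depth_mean,
                                 size = spec$depth_disp),
                  nrow = n_sites, ncol = ns,
                  dimnames = list(NULL, sample_ids))
  n_fail <- round(spec$depth_fail_frac * n_sites)
  if (n_fail > 0) {
    fail_sites <- sample.int(n_sites, n_fail)
    n_low <- ceiling(0.2 * ns) + 1L  # > 20% of samples below threshold
    for (s in fail_sites) {
      low <- sample.int(ns, min(n_low, ns))
      depth[s, low] <- sample(0:4, length(low), replace = TRUE)
    }
  }
  report <- list(mean_depth = mean(depth),
                 all_pass_impossible = spec$depth_mean <= 5)
  if (report$all_pass_impossible)
    warning("mean depth <= 5: the coverage rule cannot pass everywhere")
  if (!is.null(path))
    utils::write.table(depth, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(depth = depth, report = report))
}
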