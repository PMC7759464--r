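#' Accessibility mask for one chromosome
#'
#' Stores the *masked* (inaccessible) intervals of a chromosome as 0-based
#' half-open intervals, normalized (sorted, merged) on construction.
#' Everything not masked is accessible; accessibility drives valid-site
#' counts, window filters and mask mirroring onto simulated loci.
#'
#' @param chrom chromosome identifier.
#' @param length chromosome length in bp.
#' @param masked two-column matrix or data.frame of (start, end) masked
#'   intervals, 0-based half-open; may be empty.
#' @return an object of class `sitemask`.
#' @export
sitemask <- function(chrom, length, masked = NULL) {
  length <- as.numeric(length)
  if (is.null(masked) || NROW(masked) == 0L) {
    iv <- matrix(numeric(0), ncol = 2L)
  } else {
    iv <- as.matrix(masked[, 1:2, drop = FALSE])
    if (any(iv[, 1] < 0) || any(iv[, 2] > length) || any(iv[, 2] <= iv[, 1]))
      stop("masked intervals must be non-empty and within [0, length)")
    ir <- IRanges::reduce(IRanges::IRanges(start = iv[, 1] + 1L,
                                           end = iv[, 2]))
    iv <- cbind(IRanges::start(ir) - 1L, IRanges::end(ir))
  }
  structure(list(chrom = as.character(chrom)[1], length = length,
                 masked = unname(iv)),
            class = "sitemask")
}

#' @export
print.sitemask <- function(x, ...) {
  cat(sprintf("sitemask: %s (%.0f bp), %d masked intervals (%.1f%% masked)\n",
              x$chrom, x$length, nrow(x$masked),
              100 * masked_bp(x) / x$length))
  invisible(x)
}

masked_bp <- function(mask) {
  if (nrow(mask$masked) == 0L) 0 else sum(mask$masked[, 2] - mask$masked[, 1])
}

#' Accessible (unmasked) bp within a 0-based half-open interval
#'
#' @param mask a [sitemask()].
#' @param start,end query interval, 0-based half-open; clipped to the
#'   chromosome.
#' @return number of unmasked bp in `[start, end)`.
#' @export
accessible_bp <- function(mask, start, end) {
  start <- max(0, start); end <- min(mask$length, end)
  if (end <= start) return(0)
  width <- end - start
  if (nrow(mask$masked) == 0L) return(width)
  ov_start <- pmax(mask$masked[, 1], start)
  ov_end <- pmin(mask$masked[, 2], end)
  width - sum(pmax(0, ov_end - ov_start))
}

#' Is each position masked?
#' @param mask a [sitemask()].
#' @param positions 0-based positions.
#' @return logical vector, `TRUE` where masked.
#' @export
is_masked <- function(mask, positions) {
  if (nrow(mask$masked) == 0L) return(rep(FALSE, length(positions)))
  q <- IRanges::IRanges(start = positions + 1L, width = 1L)
  m <- IRanges::IRanges(start = mask$masked[, 1] + 1L,
                        end = mask$masked[, 2])
  IRanges::overlapsAny(q, m)
}

#' Remove masked sites from a haplotype matrix
#'
#' Columns whose position falls in a masked interval are dropped. Use
#' [accessible_bp()] on the same mask for denominator (valid-site) counts.
#'
#' @param hap a [hapmat()].
#' @param mask a [sitemask()] for the same chromosome.
#' @return filtered [hapmat()].
#' @export
apply_mask <- function(hap, mask) {
  if (!identical(hap$chrom, mask$chrom))
    warning("applying mask for ", mask$chrom, " to haplotypes on ",
            hap$chrom)
  hap_subset_sites(hap, !is_masked(mask, hap$positions))
}

#' Extract a relocated slice of a mask
#'
#' Returns the mask restricted to `[start, start + width)`, shifted to
#' coordinates `[0, width)`. Used to mirror empirical missing-data
#' patterns onto simulated loci.
#'
#' @param mask a [sitemask()].
#' @param start 0-based slice start.
#' @param width slice width in bp.
#' @export
mask_slice <- function(mask, start, width) {
  end <- start + width
  if (end > mask$length) stop("slice extends beyond the mask")
  if (nrow(mask$masked) == 0L) return(sitemask(mask$chrom, width))
  s <- pmax(mask$masked[, 1], start) - start
  e <- pmin(mask$masked[, 2], end) - start
  keep <- e > s & s < width
  sitemask(mask$chrom, width, cbind(s[keep], pmin(e[keep], width)))
}

#' Read a mask from BED (masked intervals, 0-based half-open)
#'
#' @param path BED file whose rows are masked intervals of one chromosome.
#' @param chrom chromosome to extract.
#' @param length chromosome length in bp (BED does not carry it).
#' @export
read_mask_bed <- function(path, chrom, length) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "#",
                           col.names = c("chrom", "start", "end")[1:3],
                           colClasses = c("character", "numeric", "numeric"))
  bed <- bed[bed$chrom == chrom, , drop = FALSE]
  sitemask(chrom, length, bed[, c("start", "end")])
}

#' Read a mask from a hard- or soft-masked FASTA
#'
#' @param path FASTA file; each record is a chromosome.
#' @param chrom record name to extract.
#' @param dialect `"N"` treats N/n as masked (hard mask); `"lowercase"`
#'   treats lowercase bases and N as masked (soft mask).
#' @export
read_mask_fasta <- function(path, chrom, dialect = c("N", "lowercase")) {
  dialect <- match.arg(dialect)
  seqs <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (!chrom %in% nm) stop("record ", chrom, " not found in ", path)
  s <- strsplit(as.character(seqs[[match(chrom, nm)]]), "")[[1]]
  bad <- if (dialect == "N") s %in% c("N", "n")
         else s %in% c("N", "n", letters)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  iv <- cbind(starts[r$values], ends[r$values])
  sitemask(chrom, length(s), iv)
}

#' Write masked intervals as BED
#' @param mask a [sitemask()].
#' @param path output file.
#' @export
write_mask_bed <- function(mask, path) {
  df <- data.frame(chrom = mask$chrom,
                   start = format(mask$masked[, 1], scientific = FALSE,
                                  trim = TRUE),
                   end = format(mask$masked[, 2], scientific = FALSE,
                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
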