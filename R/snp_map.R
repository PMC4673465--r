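#' Build a SNP map
#'
#' A SNP map is the ordered marker metadata shared by every matrix in a
#' popdiffr analysis: one row per biallelic marker with its chromosome,
#' 1-based physical position (NCBI Build 37 convention throughout) and the
#' two alleles. `allele0` is the allele counted as 0 in haplotype matrices
#' and `allele1` the allele whose copies are counted in genotype matrices.
#'
#' @param snp_id character vector of unique marker identifiers.
#' @param chrom character (or coercible) chromosome labels.
#' @param pos integer 1-based base-pair positions, strictly increasing
#'   within each chromosome.
#' @param allele0,allele1 single-character alleles; must differ per marker.
#'
#' @return A tibble of class `snp_map` with columns `snp_id`, `chrom`,
#'   `pos`, `allele0`, `allele1`.
#' @examples
#' snp_map(c("rs1", "rs2"), "6", c(100L, 200L), c("A", "C"), c("G", "T"))
#' @export
snp_map <- function(snp_id, chrom, pos, allele0, allele1) {
  out <- tibble::tibble(
    snp_id  = as.character(snp_id),
    chrom   = as.character(chrom),
    pos     = as.integer(pos),
    allele0 = as.character(allele0),
    allele1 = as.character(allele1)
  )
  validate_snp_map(out)
}

validate_snp_map <- function(map) {
  if (anyDuplicated(map$snp_id)) {
    stop("snp_map: duplicated snp_id: ",
         map$snp_id[duplicated(map$snp_id)][1], call. = FALSE)
  }
  if (any(map$allele0 == map$allele1)) {
    stop("snp_map: allele0 must differ from allele1", call. = FALSE)
  }
  if (any(is.na(map$pos)) || any(map$pos < 1L)) {
    stop("snp_map: positions must be positive integers", call. = FALSE)
  }
  bad <- unlist(lapply(split(map$pos, map$chrom), function(p) any(diff(p) <= 0)))
  if (any(bad)) {
    stop("snp_map: positions must be strictly increasing within chromosome ",
         names(bad)[bad][1], call. = FALSE)
  }
  class(map) <- unique(c("snp_map", class(tibble::tibble())))
  map
}

is_snp_map <- function(x) inherits(x, "snp_map")

#' Select markers inside a genomic window
#'
#' Convenience selector used e.g. to restrict F_ST averaging to the
#' 25-35 Mb MHC interval on chromosome 6.
#'
#' @param map a [snp_map()].
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds in base pairs.
#' @return Character vector of `snp_id`s falling inside the window.
#' @export
markers_in_window <- function(map, chrom, start, end) {
  stopifnot(is_snp_map(map), start <= end)
  map$snp_id[map$chrom == as.character(chrom) & map$pos >= start & map$pos <= end]
}

#' Define a gene region
#'
#' Coordinates are 1-based and inclusive on both ends.
#'
#' @param name region name (e.g. `"HLA-B"`).
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return A one-row tibble of class `gene_region`.
#' @export
gene_region <- function(name, chrom, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start > end) {
    stop("gene_region: require start <= end", call. = FALSE)
  }
  out <- tibble::tibble(name = as.character(name), chrom = as.character(chrom),
                        start = start, end = end)
  class(out) <- unique(c("gene_region", class(tibble::tibble())))
  out
}

#' Extend a gene region by a flanking buffer
#'
#' Appends `buffer` base pairs up- and downstream; the start is clamped at
#' position 1. Used to add the 100 kb flanks around each HLA gene before
#' haplotype extraction.
#'
#' @param region a [gene_region()] (one or more rows).
#' @param buffer non-negative flank size in base pairs.
#' @return The extended `gene_region`.
#' @examples
#' extend_region(gene_region("HLA-A", "6", 1000000, 1003621), 100000)
#' @export
extend_region <- function(region, buffer) {
  stopifnot(inherits(region, "gene_region"), buffer >= 0)
  region$start <- pmax(1L, as.integer(region$start - buffer))
  region$end <- as.integer(region$end + buffer)
  region
}

#' Packaged HLA region definitions
#'
#' The six classical HLA gene regions on chromosome 6 (NCBI Build 37) used
#' by the haplotype analyses: Class I *HLA-A*, *-B*, *-C* and Class II
#' *HLA-DR* (DRA1+DRB1 merged), *-DQ* (DQA1+DQB1), *-DP* (DPA1+DPB1).
#' The shipped coordinates already include the 100 kb up/downstream flanks,
#' so they are used directly without a further [extend_region()] call.
#'
#' @return A `gene_region` tibble with six rows.
#' @export
hla_regions <- function() {
  out <- tibble::tibble(
    name  = c("HLA-A", "HLA-B", "HLA-C", "HLA-DR", "HLA-DQ", "HLA-DP"),
    chrom = "6",
    start = c(29810247L, 31221649L, 31136526L, 32307619L, 32505183L, 32932346L),
    end   = c(30013868L, 31424989L, 31339913L, 32657613L, 32734466L, 33153681L)
  )
  class(out) <- unique(c("gene_region", class(tibble::tibble())))
  out
}
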