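#' Catalog the distinct haplotypes of a gene region
#'
#' Restricts a phased panel to the markers with `start <= pos <= end`
#' (1-based, inclusive on both ends) on the region's chromosome and
#' enumerates the distinct haplotype strings with per-population counts
#' and frequencies. Frequencies use 2 x (population sample count) as the
#' denominator. Distinct haplotypes are ordered by first appearance in row
#' order, which makes the catalog deterministic for a given panel.
#'
#' @param panel a [haplotype_panel()] (phased, complete; genotype input is
#'   rejected by construction).
#' @param region a one-row [gene_region()].
#' @return An object of class `haplotype_catalog`: the region, the marker
#'   subset (`snp_map`), the distinct `haplotypes` (binary strings), and
#'   populations x haplotypes `freq` and `counts` matrices.
#' @export
extract_region_haplotypes <- function(panel, region) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(region, "gene_region"))
  if (nrow(region) != 1L) stop("extract_region_haplotypes: one region at a time",
                               call. = FALSE)
  sel <- panel$map$chrom == region$chrom &
    panel$map$pos >= region$start & panel$map$pos <= region$end
  if (!any(sel)) {
    stop("no markers fall inside region '", region$name, "'", call. = FALSE)
  }
  sub <- panel$hap[, sel, drop = FALSE]
  strings <- apply(sub, 1L, paste0, collapse = "")
  haps <- unique(strings)  # first-appearance order
  pops <- sort(unique(panel$population))
  rowpop <- hap_row_population(panel)
  counts <- matrix(0L, nrow = length(pops), ncol = length(haps),
                   dimnames = list(pops, haps))
  tab <- table(factor(rowpop, levels = pops), factor(strings, levels = haps))
  counts[] <- as.integer(tab)
  freq <- counts / rowSums(counts)
  structure(list(
    region = region,
    map = validate_snp_map(panel$map[sel, , drop = FALSE]),
    haplotypes = haps, counts = counts, freq = freq
  ), class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("<haplotype_catalog> region '", x$region$name, "': ",
      length(x$haplotypes), " distinct haplotypes over ", nrow(x$map),
      " SNPs in ", nrow(x$freq), " populations\n", sep = "")
  invisible(x)
}

#' Identify major haplotypes
#'
#' A major haplotype is a distinct haplotype whose frequency reaches
#' `threshold` in at least one population (inclusive: exactly the
#' threshold qualifies). Members are labelled `H1, H2, ...` in descending
#' order of their maximum per-population frequency, ties broken by the
#' haplotype string. Typical thresholds are 0.10 for compact regions and
#' 0.06 where haplotype diversity is high (e.g. HLA-DQ/-DP).
#'
#' @param catalog a `haplotype_catalog`.
#' @param threshold frequency threshold in `(0, 1]`.
#' @return An object of class `major_haplotypes`: tibble-like fields
#'   `label`, `haplotype`, `max_freq`, plus the catalog and threshold.
#' @export
major_haplotypes <- function(catalog, threshold = 0.10) {
  stopifnot(inherits(catalog, "haplotype_catalog"),
            threshold > 0, threshold <= 1)
  max_freq <- apply(catalog$freq, 2L, max)
  member <- which(max_freq >= threshold)
  ord <- member[order(-max_freq[member], catalog$haplotypes[member])]
  structure(list(
    label = if (length(ord)) paste0("H", seq_along(ord)) else character(0),
    haplotype = catalog$haplotypes[ord],
    max_freq = unname(max_freq[ord]),
    threshold = threshold, catalog = catalog
  ), class = "major_haplotypes")
}

#' @export
print.major_haplotypes <- function(x, ...) {
  cat("<major_haplotypes> ", length(x$label), " haplotypes at threshold ",
      x$threshold, " in region '", x$catalog$region$name, "'\n", sep = "")
  invisible(x)
}

#' Percent dissimilarity between two haplotypes
#'
#' The percentage of SNP sites at which the two haplotypes carry different
#' alleles: `100 * hamming / n`. For example, two 39-SNP haplotypes
#' differing at 12 sites are 30.77% dissimilar.
#'
#' @param h1,h2 binary haplotype strings of equal length `n >= 1`.
#' @return Percent dissimilarity in `[0, 100]`.
#' @examples
#' dissimilarity(strrep("0", 39), paste0(strrep("1", 12), strrep("0", 27)))
#' @export
dissimilarity <- function(h1, h2) {
  if (nchar(h1) != nchar(h2) || nchar(h1) < 1L) {
    stop("dissimilarity: haplotype strings must have equal length >= 1",
         call. = FALSE)
  }
  a <- strsplit(h1, "", fixed = TRUE)[[1]]
  b <- strsplit(h2, "", fixed = TRUE)[[1]]
  100 * sum(a != b) / length(a)
}

#' Pairwise and minimum dissimilarity among major haplotypes
#'
#' For each major haplotype, the least dissimilarity against all other
#' members: the distance to its nearest major neighbour. With a single
#' member the minimum is undefined and reported as `NA` (rendered "-" in
#' text output).
#'
#' @param major a `major_haplotypes` set.
#' @return A tibble `label`, `haplotype`, `min_dissimilarity` (percent,
#'   `NA` when undefined). The full pairwise percent matrix is attached as
#'   attribute `"matrix"`.
#' @export
min_dissimilarity_table <- function(major) {
  stopifnot(inherits(major, "major_haplotypes"))
  h <- major$haplotype
  n <- length(h)
  d <- matrix(0, n, n, dimnames = list(major$label, major$label))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      d[i, j] <- d[j, i] <- dissimilarity(h[i], h[j])
    }
  }
  mins <- if (n >= 2L) {
    vapply(seq_len(n), function(i) min(d[i, -i]), numeric(1))
  } else rep(NA_real_, n)
  out <- tibble::tibble(label = major$label, haplotype = h,
                        min_dissimilarity = mins)
  attr(out, "matrix") <- d
  out
}

#' Classify major-haplotype sharing across ancestry groups
#'
#' A haplotype is "present" in an ancestry group iff its frequency is
#' non-zero in at least one of the group's populations. The result is the
#' Venn partition of major haplotypes over groups.
#'
#' @param major a `major_haplotypes` set.
#' @param groups named character vector mapping every catalog population
#'   to its ancestry group.
#' @return A tibble `label`, `haplotype`, `groups` (list-column of group
#'   names present) and `pattern` (`+`-joined sorted group names). Venn
#'   cell counts are attached as attribute `"venn"` (named integer
#'   vector over observed patterns).
#' @export
sharing_classification <- function(major, groups) {
  stopifnot(inherits(major, "major_haplotypes"))
  freq <- major$catalog$freq
  pops <- rownames(freq)
  un <- setdiff(pops, names(groups))
  if (length(un)) {
    stop("sharing_classification: population without ancestry group: ",
         un[1], call. = FALSE)
  }
  glev <- sort(unique(unname(groups[pops])))
  present <- lapply(major$haplotype, function(h) {
    p <- freq[, h]
    glev[vapply(glev, function(g) any(p[pops[groups[pops] == g]] > 0), logical(1))]
  })
  pattern <- vapply(present, paste, character(1), collapse = "+")
  out <- tibble::tibble(label = major$label, haplotype = major$haplotype,
                        groups = present, pattern = pattern)
  attr(out, "venn") <- table(pattern)
  out
}
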