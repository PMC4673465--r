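#' Filter markers by genotype call rate
#'
#' Retains markers whose fraction of non-missing genotypes exceeds
#' `min_rate`. The comparison is strict by default, reading a "call rate
#' greater than 95%" threshold literally, so a marker at exactly 95% is
#' dropped; set `strict = FALSE` for `>=`.
#'
#' @param g a [genotype_matrix()].
#' @param min_rate required call-rate fraction in `[0, 1]`.
#' @param strict logical; strict (`>`) or inclusive (`>=`) comparison.
#' @return The filtered `genotype_matrix` (SNP map subset accordingly).
#' @export
call_rate_filter <- function(g, min_rate = 0.95, strict = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"), min_rate >= 0, min_rate <= 1)
  rate <- colMeans(!is.na(g$geno))
  keep <- if (strict) rate > min_rate else rate >= min_rate
  if (!any(keep)) stop("call_rate_filter: no markers retained", call. = FALSE)
  subset_markers(g, g$map$snp_id[keep])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the summed probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' A monomorphic marker has a single attainable outcome and p = 1.
#'
#' @param n_aa,n_ab,n_bb genotype counts (AA homozygote, heterozygote,
#'   BB homozygote); non-negative, summing to at least 1.
#' @return The exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  counts <- c(n_aa, n_ab, n_bb)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("hwe_exact_test: counts must be non-negative", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("hwe_exact_test: all-zero genotype counts", call. = FALSE)
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  # attainable heterozygote counts share the parity of min(n_a, n_b)
  h_max <- min(n_a, n_b)
  h <- seq(h_max %% 2L, h_max, by = 2L)
  # log conditional probability up to the shared normalizing constant
  logp <- h * log(2) - lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_b - h) / 2 + 1)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, h)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Filter markers by Hardy-Weinberg equilibrium
#'
#' Applies [hwe_exact_test()] per marker and keeps markers whose p-value
#' exceeds `alpha`. By default the test is run within each population
#' separately and a marker must pass in every population (differentiated
#' populations pooled together fail HWE by construction, which would
#' discard exactly the informative markers); `per_population = FALSE`
#' pools all samples.
#'
#' @param g a [genotype_matrix()].
#' @param alpha significance level in `(0, 1)`; markers with `p > alpha`
#'   in every tested stratum are retained.
#' @param per_population test within populations (default) or pooled.
#' @return The filtered `genotype_matrix`.
#' @export
hwe_filter <- function(g, alpha = 0.05, per_population = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"), alpha > 0, alpha < 1)
  strata <- if (per_population) split(seq_along(g$sample_id), g$population)
            else list(all = seq_along(g$sample_id))
  keep <- rep(TRUE, n_markers(g))
  for (idx in strata) {
    sub <- g$geno[idx, , drop = FALSE]
    for (j in which(keep)) {
      gj <- sub[, j]
      gj <- gj[!is.na(gj)]
      if (!length(gj)) next
      p <- hwe_exact_test(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L))
      if (p <= alpha) keep[j] <- FALSE
    }
  }
  if (!any(keep)) stop("hwe_filter: no markers retained", call. = FALSE)
  subset_markers(g, g$map$snp_id[keep])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_strand_ambiguous <- function(a0, a1) {
  (a0 == "A" & a1 == "T") | (a0 == "T" & a1 == "A") |
    (a0 == "C" & a1 == "G") | (a0 == "G" & a1 == "C")
}

#' Intersect marker sets across datasets
#'
#' Restricts two or more genotype matrices / haplotype panels to the
#' markers present in all of them, keyed by `(chrom, pos)` with an
#' unambiguous allele match. Alleles may be swapped (coding is flipped to
#' match the first input) or strand-complemented; A/T and C/G SNPs are
#' dropped because their strand cannot be resolved across genotyping
#' arrays.
#'
#' @param ... two or more `genotype_matrix` / `haplotype_panel` objects,
#'   or a single list of them.
#' @param drop_ambiguous drop A/T and C/G SNPs (default `TRUE`).
#' @return A list of the input objects restricted to (and aligned on) the
#'   common markers, all sharing the first input's SNP map.
#' @export
intersect_markers <- function(..., drop_ambiguous = TRUE) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) &&
      !inherits(xs[[1]], c("genotype_matrix", "haplotype_panel"))) {
    xs <- xs[[1]]
  }
  if (length(xs) < 2L) stop("intersect_markers: need at least 2 inputs", call. = FALSE)

  ref <- xs[[1]]$map
  key <- function(map) paste(map$chrom, map$pos, sep = ":")
  common <- Reduce(intersect, lapply(xs, function(x) key(x$map)))
  keep_ref <- key(ref) %in% common
  if (drop_ambiguous) {
    keep_ref <- keep_ref & !is_strand_ambiguous(ref$allele0, ref$allele1)
  }
  # require a resolvable allele match in every dataset
  ref_keys <- key(ref)[keep_ref]
  match_mode <- function(map, i_ref, i_x) {
    a0 <- ref$allele0[i_ref]; a1 <- ref$allele1[i_ref]
    b0 <- map$allele0[i_x];   b1 <- map$allele1[i_x]
    dplyr::case_when(
      b0 == a0 & b1 == a1 ~ "same",
      b0 == a1 & b1 == a0 ~ "swap",
      COMPLEMENT[b0] == a0 & COMPLEMENT[b1] == a1 ~ "same",
      COMPLEMENT[b0] == a1 & COMPLEMENT[b1] == a0 ~ "swap",
      TRUE ~ "mismatch"
    )
  }
  i_ref <- which(keep_ref)
  modes <- lapply(xs, function(x) {
    i_x <- match(ref_keys, key(x$map))
    match_mode(x$map, i_ref, i_x)
  })
  resolvable <- Reduce(`&`, lapply(modes, function(m) m != "mismatch"))
  i_ref <- i_ref[resolvable]
  if (!length(i_ref)) stop("intersect_markers: empty marker intersection", call. = FALSE)
  ids_ref <- ref$snp_id[i_ref]

  out <- vector("list", length(xs))
  for (k in seq_along(xs)) {
    x <- xs[[k]]
    i_x <- match(key(ref)[i_ref], key(x$map))
    swap <- modes[[k]][resolvable] == "swap"
    if (inherits(x, "haplotype_panel")) {
      m <- x$hap[, i_x, drop = FALSE]
      if (any(swap)) m[, swap] <- 1L - m[, swap]
      out[[k]] <- haplotype_panel(m, ref[i_ref, , drop = FALSE],
                                  x$sample_id, x$population)
    } else {
      m <- x$geno[, i_x, drop = FALSE]
      if (any(swap)) m[, swap] <- 2L - m[, swap]
      out[[k]] <- genotype_matrix(m, ref[i_ref, , drop = FALSE],
                                  x$sample_id, x$population)
    }
  }
  names(out) <- names(xs)
  out
}
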