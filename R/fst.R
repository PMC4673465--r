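#' SNP-level two-population F_ST
#'
#' The frequency-based two-population fixation index
#' \deqn{F_{ST} = \frac{(p_1 - p_2)^2}{4 \bar p (1 - \bar p)}, \qquad
#'       \bar p = (p_1 + p_2)/2,}
#' which is identical to the heterozygosity form
#' `(H_T - H_S) / H_T` with `H_T = 2 p_bar q_bar` and
#' `H_S = (2 p_1 q_1 + 2 p_2 q_2) / 2`. Markers monomorphic in the pooled
#' pair (`p_bar` of 0 or 1) return 0.
#'
#' An optional sample-size-corrected alternative ([snp_fst_hudson()]) is
#' available through `mean_fst_matrix(estimator = "hudson")`.
#'
#' @param p1,p2 allele frequencies in `[0, 1]`; vectorized.
#' @return F_ST values in `[0, 1]`.
#' @examples
#' snp_fst(0.2, 0.4)  # 0.047619...
#' @export
snp_fst <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE)) {
    stop("snp_fst: frequencies must lie in [0, 1]", call. = FALSE)
  }
  pbar <- (p1 + p2) / 2
  denom <- 4 * pbar * (1 - pbar)
  out <- ifelse(denom == 0, 0, (p1 - p2)^2 / denom)
  out[is.na(p1) | is.na(p2)] <- NA_real_
  out
}

#' Hudson-style sample-size-corrected two-population F_ST
#'
#' `((p1 - p2)^2 - p1 q1 / (n1 - 1) - p2 q2 / (n2 - 1)) / (p1 q2 + p2 q1)`
#' with `n1`, `n2` the numbers of sampled alleles. Unbiased under the
#' island model; can go slightly negative at weak differentiation, which
#' is reported as-is.
#'
#' @param p1,p2 sample allele frequencies.
#' @param n1,n2 numbers of alleles sampled (2 x diploid sample size).
#' @return Estimates (not clamped to `[0, 1]`); `NaN` when the pooled pair
#'   is monomorphic.
#' @export
snp_fst_hudson <- function(p1, p2, n1, n2) {
  stopifnot(all(n1 > 1), all(n2 > 1))
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num / den
}

new_fst_matrix <- function(fst, n_markers_used, populations) {
  dimnames(fst) <- list(populations, populations)
  structure(list(fst = fst, n_markers = n_markers_used,
                 populations = populations),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, digits = 4, ...) {
  cat("<fst_matrix> ", length(x$populations), " populations\n", sep = "")
  print(round(x$fst, digits))
  invisible(x)
}

#' Pairwise mean SNP-level F_ST distance matrix
#'
#' For every pair of populations, averages [snp_fst()] (or the Hudson
#' estimator) over a marker subset, using observed per-population allele
#' frequencies with missing genotypes excluded from the denominators.
#' Markers with zero called alleles in either member of a pair are skipped
#' for that pair. Monomorphic-in-pair markers contribute 0 by default
#' (`drop_monomorphic = TRUE` excludes them from the average instead).
#'
#' @param x a `genotype_matrix` or `haplotype_panel` carrying population
#'   labels for at least two populations.
#' @param markers optional character vector of `snp_id`s to average over
#'   (e.g. from [markers_in_window()]); default uses every marker.
#' @param estimator `"nei"` (default, the frequency form) or `"hudson"`.
#' @param drop_monomorphic exclude pair-monomorphic markers from averages.
#' @return An `fst_matrix`: symmetric K x K with zero diagonal, plus the
#'   per-cell count of markers used.
#' @export
mean_fst_matrix <- function(x, markers = NULL,
                            estimator = c("nei", "hudson"),
                            drop_monomorphic = FALSE) {
  estimator <- match.arg(estimator)
  af <- pop_allele_freqs(x)
  pops <- rownames(af$freq)
  if (length(pops) < 2L) stop("mean_fst_matrix: need >= 2 populations", call. = FALSE)
  if (!is.null(markers)) {
    sel <- x$map$snp_id %in% markers
    if (!any(sel)) stop("mean_fst_matrix: empty marker subset", call. = FALSE)
    af$freq <- af$freq[, sel, drop = FALSE]
    af$n_alleles <- af$n_alleles[, sel, drop = FALSE]
  }
  k <- length(pops)
  fst <- matrix(0, k, k)
  used <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      p1 <- af$freq[i, ]; p2 <- af$freq[j, ]
      ok <- af$n_alleles[i, ] > 0 & af$n_alleles[j, ] > 0
      if (estimator == "hudson") {
        ok <- ok & af$n_alleles[i, ] > 1 & af$n_alleles[j, ] > 1
        v <- snp_fst_hudson(p1[ok], p2[ok], af$n_alleles[i, ok], af$n_alleles[j, ok])
        v[!is.finite(v)] <- 0
      } else {
        v <- snp_fst(p1[ok], p2[ok])
      }
      if (drop_monomorphic) {
        pbar <- (p1[ok] + p2[ok]) / 2
        poly <- pbar > 0 & pbar < 1
        v <- v[poly]
      }
      if (!length(v)) stop("mean_fst_matrix: no usable markers for pair ",
                           pops[i], "-", pops[j], call. = FALSE)
      fst[i, j] <- fst[j, i] <- mean(v)
      used[i, j] <- used[j, i] <- length(v)
    }
  }
  new_fst_matrix(fst, used, pops)
}

#' Multi-allelic haplotype-level F_ST (G_ST)
#'
#' The heterozygosity-based multi-allelic fixation index between two
#' populations, computed from observed haplotype frequency vectors:
#' `H_S` is the mean within-population expected heterozygosity
#' `1 - sum(p_h^2)` and `H_T = 1 - sum(p_bar_h^2)` uses the mean frequency
#' vector; the statistic is `(H_T - H_S) / H_T`, or 0 when `H_T = 0`.
#' With exactly two "haplotypes" (the alleles of one biallelic SNP) this
#' reduces to [snp_fst()].
#'
#' @param freqs1,freqs2 frequency vectors over the same haplotype catalog,
#'   each summing to 1 (tolerance 1e-9).
#' @return G_ST in `[0, 1]`.
#' @examples
#' haplotype_gst(c(0.5, 0.5), c(0.9, 0.1))  # 0.190476...
#' @export
haplotype_gst <- function(freqs1, freqs2) {
  if (length(freqs1) != length(freqs2)) {
    stop("haplotype_gst: frequency vectors must share the same catalog",
         call. = FALSE)
  }
  if (abs(sum(freqs1) - 1) > 1e-9 || abs(sum(freqs2) - 1) > 1e-9) {
    stop("haplotype_gst: frequencies must each sum to 1", call. = FALSE)
  }
  hs <- mean(c(1 - sum(freqs1^2), 1 - sum(freqs2^2)))
  pbar <- (freqs1 + freqs2) / 2
  ht <- 1 - sum(pbar^2)
  if (ht == 0) return(0)
  (ht - hs) / ht
}

#' Pairwise haplotype-level F_ST matrix for a gene region
#'
#' Applies [haplotype_gst()] to every pair of populations in a
#' [extract_region_haplotypes()] catalog.
#'
#' @param catalog a `haplotype_catalog`.
#' @return An `fst_matrix` over the catalog's populations; a warning is
#'   issued (and an all-zero matrix returned) when the region carries a
#'   single distinct haplotype everywhere.
#' @export
haplotype_fst_matrix <- function(catalog) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  freq <- catalog$freq
  pops <- rownames(freq)
  k <- length(pops)
  if (k < 2L) stop("haplotype_fst_matrix: need >= 2 populations", call. = FALSE)
  if (ncol(freq) == 1L) {
    warning("haplotype_fst_matrix: single distinct haplotype in region '",
            catalog$region$name, "'; F_ST is identically zero")
  }
  fst <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      fst[i, j] <- fst[j, i] <- haplotype_gst(freq[i, ], freq[j, ])
    }
  }
  new_fst_matrix(fst, matrix(ncol(freq), k, k), pops)
}

#' Pool per-SNP F_ST values over all population pairs
#'
#' One record per (population pair, marker): the raw material of the
#' top-quantile enrichment test.
#'
#' @inheritParams mean_fst_matrix
#' @return A tibble with columns `pop_i`, `pop_j` (`pop_i < pop_j`),
#'   `snp_id`, `fst`.
#' @export
pooled_fst_records <- function(x, markers = NULL) {
  af <- pop_allele_freqs(x)
  if (!is.null(markers)) {
    sel <- x$map$snp_id %in% markers
    af$freq <- af$freq[, sel, drop = FALSE]
    af$n_alleles <- af$n_alleles[, sel, drop = FALSE]
  }
  pops <- rownames(af$freq)
  pairs <- utils::combn(pops, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c_idx) {
    i <- pairs[1L, c_idx]; j <- pairs[2L, c_idx]
    ok <- af$n_alleles[i, ] > 0 & af$n_alleles[j, ] > 0
    tibble::tibble(
      pop_i = i, pop_j = j,
      snp_id = colnames(af$freq)[ok],
      fst = snp_fst(af$freq[i, ok], af$freq[j, ok])
    )
  })
}

#' Top-quantile F_ST enrichment test for one population
#'
#' Pools the per-pair, per-SNP F_ST records, takes the top `quantile`
#' fraction (`n_top = ceiling(quantile * N)` records, ties broken
#' deterministically by pair then marker id), counts how many involve the
#' focal population, and tests that count against the null that each of
#' the `choose(K, 2)` pairs is equally likely to appear in the tail: a
#' record involves the focal population with probability
#' `(K - 1) / choose(K, 2) = 2 / K`. The p-value is the one-sided exact
#' binomial upper tail `P(X >= count)`.
#'
#' @param records tibble from [pooled_fst_records()].
#' @param focal focal population name.
#' @param quantile tail fraction in (0, 1); default 0.01.
#' @return A one-row tibble: `focal`, `n_top`, `count_in_top`,
#'   `null_prob`, `p_value`.
#' @export
top_fst_enrichment <- function(records, focal, quantile = 0.01) {
  stopifnot(quantile > 0, quantile < 1)
  pops <- sort(unique(c(records$pop_i, records$pop_j)))
  if (!focal %in% pops) {
    stop("top_fst_enrichment: focal population '", focal,
         "' not among record populations", call. = FALSE)
  }
  k <- length(pops)
  ord <- order(-records$fst, records$pop_i, records$pop_j, records$snp_id)
  n_top <- as.integer(ceiling(quantile * nrow(records)))
  top <- records[ord[seq_len(n_top)], ]
  count <- sum(top$pop_i == focal | top$pop_j == focal)
  null_prob <- (k - 1) / choose(k, 2)
  p <- stats::pbinom(count - 1L, n_top, null_prob, lower.tail = FALSE)
  tibble::tibble(focal = focal, n_top = n_top, count_in_top = count,
                 null_prob = null_prob, p_value = p)
}
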