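#' Standardize a genotype matrix for PCA
#'
#' Per marker: center by the mean observed genotype, scale by
#' `sqrt(p_hat (1 - p_hat))` where `p_hat = (1 + sum g) / (2 + 2 n_called)`
#' is a shrunk allele-frequency estimate (the posterior mean under a
#' uniform prior, which keeps the denominator away from zero for rare
#' alleles); missing entries are set to 0 after centering, and
#' zero-variance markers are dropped. Columns of the returned matrix are
#' finally re-centered so that sample scores are exactly mean-zero even in
#' the presence of missingness.
#'
#' @param g a [genotype_matrix()] with at least 2 samples.
#' @param shrink use the shrunk frequency (default); `FALSE` uses the
#'   plain observed frequency `p_hat = sum g / (2 n_called)`.
#' @return A numeric samples x retained-markers matrix; retained marker
#'   ids in `attr(, "snp_id")`.
#' @export
standardize_genotypes <- function(g, shrink = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"), n_samples(g) >= 2L)
  geno <- g$geno
  called <- !is.na(geno)
  n_called <- colSums(called)
  gsum <- colSums(geno, na.rm = TRUE)
  mu <- gsum / n_called
  keep <- n_called > 0 & apply(geno, 2L, function(v) stats::var(v, na.rm = TRUE) > 0)
  keep[is.na(keep)] <- FALSE
  p_hat <- if (shrink) (1 + gsum) / (2 + 2 * n_called) else gsum / (2 * n_called)
  sd_col <- sqrt(p_hat * (1 - p_hat))
  keep <- keep & sd_col > 0
  x <- sweep(geno[, keep, drop = FALSE], 2L, mu[keep], `-`)
  x <- sweep(x, 2L, sd_col[keep], `/`)
  x[!called[, keep, drop = FALSE]] <- 0
  x <- sweep(x, 2L, colMeans(x), `-`)
  rownames(x) <- g$sample_id
  attr(x, "snp_id") <- g$map$snp_id[keep]
  x
}

new_pca_result <- function(coordinates, eigenvalues, kind, population,
                           markers = NULL, negative_eigenvalues = numeric(0)) {
  structure(list(coordinates = coordinates, eigenvalues = eigenvalues,
                 kind = kind, population = population, markers = markers,
                 negative_eigenvalues = negative_eigenvalues),
            class = "pop_pca")
}

#' @export
print.pop_pca <- function(x, ...) {
  cat("<pop_pca> ", x$kind, "-level, ", nrow(x$coordinates), " entities x ",
      ncol(x$coordinates), " components; top eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 3), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Subject-level PCA of standardized genotypes
#'
#' Principal axes of the [standardize_genotypes()] matrix via singular
#' value decomposition (equivalent to eigen-decomposition of the sample
#' covariance). Eigenvector signs are fixed by making the
#' largest-magnitude marker loading positive, removing the arbitrary sign
#' flip of eigenvectors.
#'
#' @param g a [genotype_matrix()].
#' @param n_components number of components, `< n_samples`.
#' @param shrink passed to [standardize_genotypes()].
#' @return A `pop_pca` with sample coordinates (scores), eigenvalues of
#'   the sample covariance (non-increasing), and population labels.
#' @export
subject_pca <- function(g, n_components = 10L, shrink = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- n_samples(g)
  if (n < 2L) stop("subject_pca: need at least 2 samples", call. = FALSE)
  if (n_components >= n) stop("subject_pca: n_components must be < samples",
                              call. = FALSE)
  x <- standardize_genotypes(g, shrink = shrink)
  sv <- svd(x, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components) %*% diag(flip, n_components)
  dimnames(scores) <- list(g$sample_id, paste0("PC", seq_len(n_components)))
  eig <- sv$d^2 / (n - 1)
  new_pca_result(scores, eig, kind = "sample", population = g$population,
                 markers = attr(x, "snp_id"))
}

#' Principal coordinates of an F_ST distance matrix
#'
#' Classical multidimensional scaling of a K x K distance matrix:
#' double-center the elementwise-squared distances,
#' `B = -1/2 C D^(2) C`, and take coordinates from the positive
#' eigenpairs. F_ST matrices are generally non-Euclidean, so negative
#' eigenvalues can occur; their axes are discarded and the negative
#' eigenvalues reported as a diagnostic.
#'
#' @param d an `fst_matrix` or a symmetric zero-diagonal numeric matrix.
#' @param n_components components requested (capped at the number of
#'   positive eigenvalues, itself at most K - 1).
#' @return A `pop_pca` with population coordinates, the positive
#'   eigenvalues used, and `negative_eigenvalues` as diagnostic.
#' @export
population_pcoa <- function(d, n_components = 2L) {
  m <- if (inherits(d, "fst_matrix")) d$fst else as.matrix(d)
  k <- nrow(m)
  if (!isSymmetric(unname(m), tol = 1e-8) || any(abs(diag(m)) > 1e-12)) {
    stop("population_pcoa: need a symmetric zero-diagonal distance matrix",
         call. = FALSE)
  }
  if (k < 3L && n_components >= k) {
    stop("population_pcoa: n_components must be < K for K < 3", call. = FALSE)
  }
  pops <- rownames(m)
  if (is.null(pops)) pops <- paste0("pop", seq_len(k))
  mds <- suppressWarnings(
    stats::cmdscale(m, k = min(n_components, k - 1L), eig = TRUE)
  )
  eig <- mds$eig
  pos <- eig[eig > 1e-12]
  coords <- mds$points
  if (ncol(coords) > length(pos)) coords <- coords[, seq_along(pos), drop = FALSE]
  if (ncol(coords) == 0L) {
    # fully degenerate distance matrix: all populations coincide at the origin
    coords <- matrix(0, k, 1L, dimnames = list(pops, "PCo1"))
    return(new_pca_result(coords, numeric(0), kind = "population",
                          population = pops,
                          negative_eigenvalues = eig[eig < -1e-12]))
  }
  if (ncol(coords) > 0) {
    flip <- vapply(seq_len(ncol(coords)), function(j) {
      v <- coords[, j]
      s <- sign(v[which.max(abs(v))])
      if (s == 0) 1 else s
    }, numeric(1))
    coords <- sweep(coords, 2L, flip, `*`)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  }
  rownames(coords) <- pops
  new_pca_result(coords, pos[seq_len(min(length(pos), ncol(coords)))],
                 kind = "population", population = pops,
                 negative_eigenvalues = eig[eig < -1e-12])
}

#' Average subject coordinates within populations
#'
#' Collapses a sample-level PCA to one coordinate per population by
#' component-wise arithmetic means, giving the population-level summary of
#' a subject-level analysis.
#'
#' @param pca a sample-level `pop_pca`.
#' @param labels optional population labels (defaults to those stored in
#'   the result).
#' @return A population-level `pop_pca` (eigenvalues carried over).
#' @export
average_population_coords <- function(pca, labels = NULL) {
  stopifnot(inherits(pca, "pop_pca"))
  if (pca$kind != "sample") stop("average_population_coords: sample-level input required",
                                 call. = FALSE)
  labels <- labels %||% pca$population
  if (length(labels) != nrow(pca$coordinates)) {
    stop("average_population_coords: one label per sample required", call. = FALSE)
  }
  means <- rowsum(pca$coordinates, labels, reorder = TRUE) /
    as.vector(table(factor(labels, levels = sort(unique(labels)))))
  new_pca_result(means, pca$eigenvalues, kind = "population",
                 population = rownames(means), markers = pca$markers)
}
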