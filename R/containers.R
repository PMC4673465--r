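#' Construct a genotype matrix
#'
#' Unphased genotypes for `n` samples at `m` markers, coded 0/1/2 as the
#' number of `allele1` copies, `NA` for missing. This is the unit of QC
#' filtering, SNP-level F_ST and subject-level PCA.
#'
#' @param geno integer matrix, samples in rows, markers in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param map a [snp_map()] with one row per column of `geno`.
#' @param sample_id character sample identifiers (row order).
#' @param population character population label per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map, sample_id, population) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) != nrow(map)) {
    stop("genotype_matrix: column count must equal snp_map length", call. = FALSE)
  }
  if (nrow(geno) != length(sample_id) || length(sample_id) != length(population)) {
    stop("genotype_matrix: sample_id/population length mismatch", call. = FALSE)
  }
  ok <- geno %in% c(0L, 1L, 2L) | is.na(geno)
  if (!all(ok)) stop("genotype_matrix: entries must be 0, 1, 2 or NA", call. = FALSE)
  rownames(geno) <- as.character(sample_id)
  colnames(geno) <- map$snp_id
  structure(
    list(geno = geno, map = validate_snp_map(map),
         sample_id = as.character(sample_id),
         population = as.character(population)),
    class = "genotype_matrix"
  )
}

#' Construct a phased haplotype panel
#'
#' Binary haplotypes for `n` samples at `m` markers. Rows `2i - 1` and `2i`
#' are the two chromosome copies of sample `i`; entries are 0 (`allele0`)
#' or 1 (`allele1`) with no missing values. Panels are the unit of all
#' haplotype analyses and of imputation reference/target data.
#'
#' @param hap integer 0/1 matrix with `2 * length(sample_id)` rows.
#' @param map a [snp_map()].
#' @param sample_id,population per-sample identifiers and labels.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(hap, map, sample_id, population) {
  hap <- as.matrix(hap)
  storage.mode(hap) <- "integer"
  if (ncol(hap) != nrow(map)) {
    stop("haplotype_panel: column count must equal snp_map length", call. = FALSE)
  }
  if (nrow(hap) != 2L * length(sample_id)) {
    stop("haplotype_panel: need exactly two haplotype rows per sample", call. = FALSE)
  }
  if (length(sample_id) != length(population)) {
    stop("haplotype_panel: sample_id/population length mismatch", call. = FALSE)
  }
  if (anyNA(hap) || !all(hap == 0L | hap == 1L)) {
    stop("haplotype_panel: entries must be 0 or 1 with no missing values", call. = FALSE)
  }
  if (length(sample_id)) {
    rownames(hap) <- paste0(rep(as.character(sample_id), each = 2L),
                            c("_h1", "_h2"))
  }
  colnames(hap) <- map$snp_id
  structure(
    list(hap = hap, map = validate_snp_map(map),
         sample_id = as.character(sample_id),
         population = as.character(population)),
    class = "haplotype_panel"
  )
}

#' Collapse a haplotype panel to genotypes
#'
#' Adds the two haplotype rows of each sample, giving the 0/1/2 count of
#' `allele1` copies.
#'
#' @param panel a [haplotype_panel()].
#' @return A [genotype_matrix()].
#' @export
as_genotype_matrix <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- length(panel$sample_id)
  g <- panel$hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    panel$hap[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  genotype_matrix(g, panel$map, panel$sample_id, panel$population)
}

n_samples <- function(x) length(x$sample_id)
n_markers <- function(x) nrow(x$map)

# population labels repeated per haplotype row
hap_row_population <- function(panel) rep(panel$population, each = 2L)

#' Subset samples of a panel or genotype matrix
#'
#' @param x a `haplotype_panel` or `genotype_matrix`.
#' @param idx integer or logical index over samples.
#' @return Object of the same class with the selected samples.
#' @export
subset_samples <- function(x, idx) {
  idx <- seq_along(x$sample_id)[idx]
  if (inherits(x, "haplotype_panel")) {
    rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    haplotype_panel(x$hap[rows, , drop = FALSE], x$map,
                    x$sample_id[idx], x$population[idx])
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$geno[idx, , drop = FALSE], x$map,
                    x$sample_id[idx], x$population[idx])
  } else {
    stop("subset_samples: unsupported class", call. = FALSE)
  }
}

#' Subset markers by snp_id
#'
#' @param x a `haplotype_panel` or `genotype_matrix`.
#' @param snp_ids markers to keep, in map order.
#' @return Object of the same class restricted to those markers.
#' @export
subset_markers <- function(x, snp_ids) {
  keep <- x$map$snp_id %in% snp_ids
  if (!any(keep)) stop("subset_markers: no markers retained", call. = FALSE)
  map <- validate_snp_map(x$map[keep, , drop = FALSE])
  if (inherits(x, "haplotype_panel")) {
    haplotype_panel(x$hap[, keep, drop = FALSE], map, x$sample_id, x$population)
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$geno[, keep, drop = FALSE], map, x$sample_id, x$population)
  } else {
    stop("subset_markers: unsupported class", call. = FALSE)
  }
}

#' Combine haplotype panels sample-wise
#'
#' Panels must share an identical SNP map; used e.g. to build combined
#' imputation reference panels from several population panels.
#'
#' @param ... `haplotype_panel` objects.
#' @return A single `haplotype_panel`.
#' @export
bind_panels <- function(...) {
  panels <- list(...)
  if (length(panels) == 1L && is.list(panels[[1]]) &&
      !inherits(panels[[1]], "haplotype_panel")) {
    panels <- panels[[1]]
  }
  stopifnot(length(panels) >= 1L)
  map <- panels[[1]]$map
  for (p in panels) {
    if (!identical(p$map$snp_id, map$snp_id) || !identical(p$map$pos, map$pos)) {
      stop("bind_panels: panels must share an identical snp_map", call. = FALSE)
    }
  }
  haplotype_panel(
    do.call(rbind, lapply(panels, `[[`, "hap")), map,
    unlist(lapply(panels, `[[`, "sample_id")),
    unlist(lapply(panels, `[[`, "population"))
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", n_samples(x), " samples x ", n_markers(x),
      " markers; populations: ",
      paste(names(table(x$population)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("<haplotype_panel> ", n_samples(x), " samples (",
      2L * n_samples(x), " haplotypes) x ", n_markers(x),
      " markers; populations: ",
      paste(names(table(x$population)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# per-population allele-1 frequencies, missing genotypes excluded from the
# denominator; returns list(freq = K x m, n_called = K x m allele counts)
pop_allele_freqs <- function(x) {
  if (inherits(x, "haplotype_panel")) {
    g <- x$hap
    pops <- hap_row_population(x)
    ploidy <- 1L
  } else if (inherits(x, "genotype_matrix")) {
    g <- x$geno
    pops <- x$population
    ploidy <- 2L
  } else stop("pop_allele_freqs: unsupported class", call. = FALSE)
  pop_levels <- sort(unique(pops))
  called <- !is.na(g)
  gz <- g
  gz[!called] <- 0L
  counts <- rowsum(gz, pops, reorder = TRUE)
  denom <- ploidy * rowsum(called + 0L, pops, reorder = TRUE)
  freq <- counts / denom
  freq[denom == 0] <- NA_real_
  list(freq = freq[pop_levels, , drop = FALSE],
       n_alleles = denom[pop_levels, , drop = FALSE])
}
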