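#' Read a phased haplotype panel
#'
#' Reads either a phased VCF (genotypes must use the `|` separator) or the
#' package's tabular haplotype format (see [write_haplotype_panel()]),
#' together with a two-column tab-separated labels file mapping
#' `sample_id` to `population`. Markers are ordered by position.
#'
#' @param path phased VCF (`.vcf`) or tabular haplotype file.
#' @param labels_path tab-separated file with header `sample_id`,
#'   `population`; every panel sample must appear.
#' @return A [haplotype_panel()].
#' @export
read_haplotype_panel <- function(path, labels_path) {
  labels <- read_population_labels(labels_path)
  first <- readLines(path, n = 1L)
  if (startsWith(first, "##fileformat=VCF")) {
    panel <- read_panel_vcf(path)
  } else {
    panel <- read_panel_tabular(path)
  }
  miss <- setdiff(panel$sample_id, labels$sample_id)
  if (length(miss)) {
    stop("sample missing from labels file: ", miss[1], call. = FALSE)
  }
  pop <- labels$population[match(panel$sample_id, labels$sample_id)]
  haplotype_panel(panel$hap, panel$map, panel$sample_id, pop)
}

read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  unphased <- array(grepl("/", gt, fixed = TRUE), dim = dim(gt))
  if (any(unphased)) {
    i <- which(unphased, arr.ind = TRUE)[1L, , drop = TRUE]
    stop("unphased genotype at ", fix[i[1L], "CHROM"], ":", fix[i[1L], "POS"],
         " sample ", colnames(gt)[i[2L]],
         " (phased '|' separators required)", call. = FALSE)
  }
  bad <- array(is.na(gt) | !grepl("^[01]\\|[01]$", gt), dim = dim(gt))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, , drop = TRUE]
    stop("non-biallelic or missing genotype at ", fix[i[1L], "CHROM"], ":",
         fix[i[1L], "POS"], call. = FALSE)
  }
  ids <- fix[, "ID"]
  if (any(is.na(ids)) || anyDuplicated(ids)) {
    ids <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
  }
  map <- tibble::tibble(
    snp_id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    allele0 = fix[, "REF"], allele1 = fix[, "ALT"]
  )
  ord <- order(map$chrom, map$pos)
  map <- validate_snp_map(map[ord, ])
  gt <- gt[ord, , drop = FALSE]
  n <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n, ncol = nrow(map))
  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"
  hap[seq(1L, 2L * n, 2L), ] <- t(a1) + 0L
  hap[seq(2L, 2L * n, 2L), ] <- t(a2) + 0L
  list(hap = hap, map = map, sample_id = colnames(gt))
}

# tabular format: header columns snp_id chrom pos allele0 allele1 then one
# column per haplotype named <sample>_h1 / <sample>_h2
read_panel_tabular <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- c("snp_id", "chrom", "pos", "allele0", "allele1")
  if (!all(meta %in% names(tab))) {
    stop("tabular haplotype file must have columns ",
         paste(meta, collapse = ", "), call. = FALSE)
  }
  hap_cols <- setdiff(names(tab), meta)
  samples <- unique(sub("_h[12]$", "", hap_cols))
  expected <- paste0(rep(samples, each = 2L), c("_h1", "_h2"))
  if (!identical(sort(hap_cols), sort(expected))) {
    stop("haplotype columns must come in <sample>_h1/<sample>_h2 pairs",
         call. = FALSE)
  }
  map <- validate_snp_map(tibble::as_tibble(tab[meta]))
  hap <- t(as.matrix(tab[expected]))
  list(hap = hap, map = map, sample_id = samples)
}

#' Write a haplotype panel
#'
#' Writes either a plain-text phased VCF 4.2 (`format = "vcf"`) or the
#' package's tab-separated haplotype table (`format = "tsv"`), plus the
#' accompanying sample-to-population labels file. Both round-trip through
#' [read_haplotype_panel()].
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @param labels_path output labels file (tab-separated, with header).
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_haplotype_panel <- function(panel, path, labels_path,
                                  format = c("vcf", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(panel, "haplotype_panel"))
  n <- n_samples(panel)
  if (format == "vcf") {
    h1 <- panel$hap[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- panel$hap[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(t(h1), "|", t(h2)), nrow = n_markers(panel))
    body <- paste(panel$map$chrom, panel$map$pos, panel$map$snp_id,
                  panel$map$allele0, panel$map$allele1, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=popdiffr",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", panel$sample_id), collapse = "\t")
    )
    writeLines(c(header, body), path)
  } else {
    tab <- tibble::as_tibble(panel$map)
    hap <- t(panel$hap)
    colnames(hap) <- rownames(panel$hap)
    readr::write_tsv(dplyr::bind_cols(tab, tibble::as_tibble(hap)), path,
                     progress = FALSE)
  }
  readr::write_tsv(
    tibble::tibble(sample_id = panel$sample_id, population = panel$population),
    labels_path, progress = FALSE
  )
  invisible(path)
}

#' Read a sample-to-population labels file
#'
#' @param path tab-separated file with header columns `sample_id` and
#'   `population`.
#' @return A tibble with those two columns.
#' @export
read_population_labels <- function(path) {
  labels <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample_id", "population") %in% names(labels))) {
    stop("labels file must have columns sample_id, population", call. = FALSE)
  }
  labels$sample_id <- as.character(labels$sample_id)
  labels$population <- as.character(labels$population)
  if (anyDuplicated(labels$sample_id)) {
    stop("labels file: duplicated sample_id", call. = FALSE)
  }
  labels
}

#' Read gene regions from a 1-based region file
#'
#' Tab-separated with header `name`, `chrom`, `start`, `end`; coordinates
#' 1-based inclusive on both ends.
#'
#' @param path region file.
#' @return A `gene_region` tibble.
#' @export
read_gene_regions <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("name", "chrom", "start", "end") %in% names(tab))) {
    stop("region file must have columns name, chrom, start, end", call. = FALSE)
  }
  if (any(tab$start > tab$end)) stop("region file: start > end", call. = FALSE)
  out <- tibble::tibble(name = as.character(tab$name),
                        chrom = as.character(tab$chrom),
                        start = as.integer(tab$start), end = as.integer(tab$end))
  class(out) <- unique(c("gene_region", class(tibble::tibble())))
  out
}
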