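test_that("region extension clamps at position 1 and is identity at buffer 0", {
  r <- gene_region("G", "6", 1000000L, 1003621L)
  e <- extend_region(r, 100000L)
  expect_identical(c(e$start, e$end), c(900000L, 1103621L))
  expect_identical(extend_region(r, 0L), r)
  expect_identical(extend_region(gene_region("G", "6", 50000L, 60000L), 100000L)$start, 1L)
  expect_error(gene_region("G", "6", 10L, 5L), "start <= end")
})

test_that("packaged HLA regions are well-formed and cover the MHC window", {
  regs <- hla_regions()
  expect_identical(nrow(regs), 6L)
  expect_true(all(regs$start < regs$end))
  expect_true(all(regs$chrom == "6"))
  expect_true(all(regs$start > 25e6 & regs$end < 35e6))
})

test_that("region haplotype extraction counts, frequencies and ordering are correct", {
  # 2 samples (4 rows) in one population: "01" x3, "11" x1
  hap <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 1L), c(0L, 1L))
  panel <- tiny_panel(hap, c("popA", "popA"))
  cat_ <- extract_region_haplotypes(panel, gene_region("r", "6", 1L, 1000L))
  expect_identical(cat_$haplotypes, c("01", "11"))
  expect_equal(unname(cat_$freq["popA", ]), c(0.75, 0.25))
  expect_equal(sum(cat_$freq["popA", ]), 1)

  # row permutation leaves the frequency table unchanged
  perm_panel <- subset_samples(panel, c(2L, 1L))
  cat_p <- extract_region_haplotypes(perm_panel, gene_region("r", "6", 1L, 1000L))
  expect_equal(cat_p$freq[, sort(colnames(cat_p$freq))],
               cat_$freq[, sort(colnames(cat_$freq))])

  # populations absent from the panel are absent from the table
  expect_identical(rownames(cat_$freq), "popA")
  expect_error(extract_region_haplotypes(panel, gene_region("r", "6", 5000L, 6000L)),
               "no markers")
})

test_that("catalogs rebuilt from written panel files are identical", {
  withr::local_seed(29)
  cfg <- synth_config(n_pops = 2, n_samples_per_pop = 25, n_snps = 20,
                      n_founders = 4, seed = 29)
  panel <- founder_mosaic_panel(cfg)$panel
  vcf <- withr::local_tempfile(fileext = ".vcf")
  lab <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_panel(panel, vcf, lab)
  back <- read_haplotype_panel(vcf, lab)
  region <- gene_region("r", "6", min(panel$map$pos), max(panel$map$pos))
  c1 <- extract_region_haplotypes(panel, region)
  c2 <- extract_region_haplotypes(back, region)
  expect_identical(c1$haplotypes, c2$haplotypes)
  expect_equal(c1$freq, c2$freq)
})

test_that("major-haplotype selection is inclusive at the threshold and ordered", {
  # popA freqs: h0 = 0.55, h1 = 0.10, h2 = 0.099 (over 1000 rows == 500 samples)
  counts <- c(551L, 100L, 99L, 250L)
  strings <- rep(c("000", "001", "010", "011"), counts)
  m <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  panel <- tiny_panel(m, rep("popA", 500L))
  cat_ <- extract_region_haplotypes(panel, gene_region("r", "6", 1L, 1000L))

  mh <- major_haplotypes(cat_, 0.10)
  expect_identical(mh$haplotype, c("000", "011", "001"))  # 0.099 excluded
  expect_identical(mh$label, c("H1", "H2", "H3"))
  expect_true(all(mh$max_freq >= 0.10))

  # threshold 1.0 keeps only haplotypes fixed in some population
  expect_length(major_haplotypes(cat_, 1)$label, 0L)
})

test_that("dissimilarity reproduces the worked percentages and is a metric", {
  h39 <- function(k) paste0(strrep("1", k), strrep("0", 39 - k))
  expect_equal(round(dissimilarity(h39(0), h39(12)), 2), 30.77)
  expect_equal(round(dissimilarity(h39(0), h39(11)), 2), 28.21)
  expect_equal(round(dissimilarity(h39(0), h39(1)), 2), 2.56)
  expect_equal(dissimilarity("0101", "0101"), 0)
  expect_error(dissimilarity("01", "011"), "equal length")

  # metric properties on random binary strings
  withr::local_seed(37)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- vapply(1:3, function(...) paste0(sample(0:1, n, TRUE), collapse = ""),
                character(1))
    d12 <- dissimilarity(s[1], s[2])
    d13 <- dissimilarity(s[1], s[3])
    d23 <- dissimilarity(s[2], s[3])
    expect_equal(d12, dissimilarity(s[2], s[1]))
    expect_gte(d13 + d23, d12 - 1e-12)
    expect_equal(dissimilarity(s[1], s[1]), 0)
  }
})

test_that("minimum dissimilarity table matches brute force over all pairs", {
  counts <- c(400L, 300L, 300L)
  strings <- rep(c("000000", "000001", "111111"), counts)
  m <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  panel <- tiny_panel(m, rep("popA", 500L))
  cat_ <- extract_region_haplotypes(panel, gene_region("r", "6", 1L, 1000L))
  mh <- major_haplotypes(cat_, 0.10)
  tab <- min_dissimilarity_table(mh)

  # brute force over all pairs
  brute <- vapply(seq_along(mh$haplotype), function(i) {
    min(vapply(seq_along(mh$haplotype)[-i], function(j) {
      dissimilarity(mh$haplotype[i], mh$haplotype[j])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(tab$min_dissimilarity, brute)
  expect_equal(sort(round(tab$min_dissimilarity, 2)),
               sort(c(16.67, 16.67, 83.33)))
  # entries are integer multiples of 100/n and positive (catalog is distinct)
  expect_true(all(tab$min_dissimilarity > 0))
  sites <- tab$min_dissimilarity * 6 / 100
  expect_equal(sites, round(sites), tolerance = 1e-9)

  # single member: undefined minimum reported as NA
  single <- major_haplotypes(cat_, 0.35)
  expect_identical(min_dissimilarity_table(single)$min_dissimilarity, NA_real_)
})

test_that("ancestry-group sharing partitions major haplotypes as a Venn diagram", {
  # popA/popB in group G1, popC in group G2; one haplotype private to popC
  hap <- rbind(
    matrix(rep(c(0L, 0L), 4L), ncol = 2L, byrow = TRUE),  # popA,popB: "00"
    matrix(rep(c(1L, 1L), 2L), ncol = 2L, byrow = TRUE)   # popC: "11"
  )
  panel <- tiny_panel(hap, c("popA", "popB", "popC"))
  cat_ <- extract_region_haplotypes(panel, gene_region("r", "6", 1L, 1000L))
  mh <- major_haplotypes(cat_, 0.10)
  groups <- c(popA = "G1", popB = "G1", popC = "G2")
  sh <- sharing_classification(mh, groups)

  expect_identical(sh$pattern[sh$haplotype == "00"], "G1")
  expect_identical(sh$pattern[sh$haplotype == "11"], "G2")
  expect_identical(sum(attr(sh, "venn")), length(mh$label))
  expect_error(sharing_classification(mh, c(popA = "G1", popB = "G1")),
               "without ancestry group")
})
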