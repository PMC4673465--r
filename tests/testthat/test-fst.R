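test_that("snp_fst matches the heterozygosity-decomposition oracle", {
  expect_equal(snp_fst(0.3, 0.3), 0)
  expect_equal(snp_fst(0, 1), 1)
  expect_equal(snp_fst(0.2, 0.4), fst_het_oracle(0.2, 0.4))
  expect_equal(snp_fst(0.2, 0.4), 1 / 21)  # 0.047619...
  expect_equal(snp_fst(0, 0), 0)           # monomorphic pair flagged as 0
  withr::with_seed(7, {
    p1 <- runif(200); p2 <- runif(200)
    expect_equal(snp_fst(p1, p2),
                 mapply(fst_het_oracle, p1, p2), tolerance = 1e-12)
    # symmetry and bounds
    expect_equal(snp_fst(p1, p2), snp_fst(p2, p1))
    expect_true(all(snp_fst(p1, p2) >= 0 & snp_fst(p1, p2) <= 1))
  })
  expect_error(snp_fst(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("haplotype G_ST follows the stated heterozygosity formula", {
  expect_equal(haplotype_gst(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(haplotype_gst(c(1, 0), c(0, 1)), 1)
  # hand evaluation: H_S = (0.5 + 0.18)/2 = 0.34, H_T = 1 - 0.58 = 0.42
  expect_equal(haplotype_gst(c(0.5, 0.5), c(0.9, 0.1)), 0.08 / 0.42)
  expect_error(haplotype_gst(c(0.5, 0.5), c(1, 0, 0)), "catalog")
  expect_error(haplotype_gst(c(0.5, 0.4), c(0.5, 0.5)), "sum to 1")
})

test_that("G_ST on a biallelic two-haplotype catalog reduces to snp_fst", {
  withr::with_seed(19, {
    for (i in 1:25) {
      p1 <- runif(1); p2 <- runif(1)
      expect_lt(abs(haplotype_gst(c(p1, 1 - p1), c(p2, 1 - p2)) -
                      snp_fst(p1, p2)), 1e-12)
    }
  })
})

test_that("mean F_ST matrix is symmetric, zero-diagonal and order/label invariant", {
  withr::local_seed(101)
  hap <- matrix(rbinom(40 * 12, 1, 0.4), nrow = 40L)
  panel <- tiny_panel(hap, rep(c("a", "b"), each = 10L))
  fm <- mean_fst_matrix(panel)
  expect_equal(fm$fst, t(fm$fst))
  expect_equal(diag(fm$fst), c(a = 0, b = 0))
  expect_true(all(fm$fst >= 0 & fm$fst <= 1))

  # sample order invariance
  perm <- sample(20L)
  fm2 <- mean_fst_matrix(subset_samples(panel, perm))
  expect_equal(fm2$fst, fm$fst)

  # allele-label invariance: flipping 0<->1 everywhere leaves F_ST unchanged
  flipped <- haplotype_panel(1L - panel$hap, panel$map, panel$sample_id,
                             panel$population)
  expect_equal(mean_fst_matrix(flipped)$fst, fm$fst)

  # identical populations have distance zero
  dup <- tiny_panel(rbind(hap[1:20, ], hap[1:20, ]),
                    rep(c("a", "b"), each = 10L))
  expect_equal(mean_fst_matrix(dup)$fst[1, 2], 0)

  # a fixed-difference marker alone gives cell 1
  fix_hap <- matrix(rep(c(0L, 1L), each = 4L), ncol = 1L)
  fixed <- tiny_panel(fix_hap, rep(c("a", "b"), each = 2L))
  expect_equal(mean_fst_matrix(fixed)$fst[1, 2], 1)
})

test_that("haplotype F_ST matrix equals brute-force recomputation from raw counts", {
  cfg <- synth_config(n_pops = 3, n_samples_per_pop = 40, n_snps = 30,
                      n_founders = 5, founder_weight_concentration = 0.4,
                      seed = 17)
  ds <- founder_mosaic_panel(cfg)
  region <- gene_region("mid", "6", ds$panel$map$pos[5], ds$panel$map$pos[25])
  cat_ <- extract_region_haplotypes(ds$panel, region)
  fm <- haplotype_fst_matrix(cat_)

  # independent recount from the raw haplotype rows
  sel <- ds$panel$map$pos >= region$start & ds$panel$map$pos <= region$end
  strings <- apply(ds$panel$hap[, sel, drop = FALSE], 1L, paste0, collapse = "")
  pops <- rep(ds$panel$population, each = 2L)
  for (i in 1:2) for (j in (i + 1):3) {
    pi <- paste0("pop", i); pj <- paste0("pop", j)
    lev <- unique(strings)
    f1 <- as.vector(table(factor(strings[pops == pi], levels = lev)))
    f2 <- as.vector(table(factor(strings[pops == pj], levels = lev)))
    f1 <- f1 / sum(f1); f2 <- f2 / sum(f2)
    hs <- mean(c(1 - sum(f1^2), 1 - sum(f2^2)))
    ht <- 1 - sum(((f1 + f2) / 2)^2)
    expect_equal(fm$fst[pi, pj], (ht - hs) / ht, tolerance = 1e-12)
  }

  # one shared haplotype everywhere: zero matrix with a warning
  mono <- tiny_panel(matrix(0L, nrow = 8L, ncol = 3L),
                     rep(c("a", "b"), each = 2L))
  cat_mono <- extract_region_haplotypes(mono, gene_region("m", "6", 1, 1e6))
  expect_warning(fm0 <- haplotype_fst_matrix(cat_mono), "single distinct")
  expect_true(all(fm0$fst == 0))

  # a private haplotype fixed in one population scores 1 against the rest
  priv <- tiny_panel(rbind(matrix(0L, 4L, 3L), matrix(1L, 4L, 3L)),
                     rep(c("a", "b"), each = 2L))
  cat_priv <- extract_region_haplotypes(priv, gene_region("p", "6", 1, 1e6))
  expect_equal(haplotype_fst_matrix(cat_priv)$fst[1, 2], 1)
})

test_that("top-quantile enrichment matches exact binomial enumeration", {
  # K = 7 gives the 2/7 null probability identity
  pops <- paste0("P", 1:7)
  withr::with_seed(23, {
    pairs <- utils::combn(pops, 2L)
    recs <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
      tibble::tibble(pop_i = pairs[1, k], pop_j = pairs[2, k],
                     snp_id = paste0("s", 1:40),
                     fst = runif(40))
    })
  })
  res <- top_fst_enrichment(recs, focal = "P3", quantile = 0.01)
  expect_equal(res$null_prob, 2 / 7)
  expect_equal(res$n_top, ceiling(0.01 * nrow(recs)))
  expect_equal(res$p_value,
               binom_tail_oracle(res$count_in_top, res$n_top, 2 / 7),
               tolerance = 1e-12)

  # exhaustive check for all counts at n_top <= 20
  for (x in 0:20) {
    expect_equal(stats::pbinom(x - 1, 20, 2 / 7, lower.tail = FALSE),
                 binom_tail_oracle(x, 20, 2 / 7), tolerance = 1e-12)
  }

  # count 0 has p-value 1; a saturated tail of 3 gives (2/7)^3
  expect_equal(binom_tail_oracle(0, 5, 2 / 7), 1)
  expect_equal(binom_tail_oracle(3, 3, 2 / 7), (2 / 7)^3)
  expect_error(top_fst_enrichment(recs, "nowhere"), "not among")
})

test_that("pooled records cover all pairs and feed the enrichment test deterministically", {
  withr::local_seed(103)
  hap <- matrix(rbinom(120, 1, 0.5), nrow = 12L)
  panel <- tiny_panel(hap, rep(c("a", "b", "c"), each = 2L))
  recs <- pooled_fst_records(panel)
  expect_identical(nrow(recs), 3L * 10L)
  expect_true(all(recs$pop_i < recs$pop_j))
  # deterministic tie handling: same input, same result
  r1 <- top_fst_enrichment(recs, "a", 0.1)
  r2 <- top_fst_enrichment(recs, "a", 0.1)
  expect_identical(r1, r2)
})
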