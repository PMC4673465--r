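test_that("mask plans are uniform, seed-stable and sized exactly", {
  map <- snp_map(paste0("s", 1:50), "6", (1:50) * 100L, "A", "G")
  m1 <- make_mask(map, 10L, seed = 1)
  m2 <- make_mask(map, 10L, seed = 1)
  expect_identical(m1$masked, m2$masked)
  expect_length(m1$masked, 10L)
  expect_length(m1$typed, 40L)
  expect_length(intersect(m1$masked, m1$typed), 0L)
  expect_error(make_mask(map, 50L, seed = 1), "< total")
  # boundary: all but one marker masked
  mb <- make_mask(map, 49L, seed = 2)
  expect_length(mb$typed, 1L)
})

test_that("copying-model limits behave as forced posteriors", {
  map <- snp_map(paste0("s", 1:6), "6", (1:6) * 100L, "A", "G")
  ref_hap <- rbind(c(0L, 1L, 0L, 1L, 0L, 1L),
                   c(1L, 1L, 1L, 0L, 0L, 0L))
  reference <- haplotype_panel(ref_hap, map, "r1", "ref")
  mask <- make_mask(map, 2L, seed = 3)
  at_masked <- map$snp_id %in% mask$masked

  # target identical to reference row 1, tiny epsilon/rho: dosages follow row 1
  params <- copying_params(epsilon = 1e-9, rho = 1e-9)
  d <- li_stephens_dosage(ref_hap[1, ], reference, params, mask)
  expect_equal(unname(d), unname(ref_hap[1, at_masked]), tolerance = 1e-6)

  # a panel holding one distinct haplotype forces the posterior:
  # dosage = eps + (1 - 2 eps) * allele, independent of the typed data
  one_row <- haplotype_panel(rbind(ref_hap[1, ], ref_hap[1, ]), map, "r1", "ref")
  params2 <- copying_params(epsilon = 0.1, rho = 0.2)
  d2 <- li_stephens_dosage(c(1L, 0L, 1L, 0L, 1L, 0L), one_row, params2, mask)
  expect_equal(unname(d2), unname(0.1 + 0.8 * ref_hap[1, at_masked]),
               tolerance = 1e-10)

  # epsilon -> 0.5 is uninformative: every genotype dosage is exactly 1
  half <- copying_params(epsilon = 0.4999999999, rho = 0.1)
  tg <- haplotype_panel(ref_hap, map, "t1", "tp")
  dos_half <- impute_targets(tg, reference, half, mask)
  expect_equal(unname(as.vector(dos_half)), rep(1, 2), tolerance = 1e-6)
})

test_that("forward-backward dosages equal exhaustive path enumeration", {
  withr::local_seed(67)
  for (rep_i in 1:40) {
    m <- sample(2:4, 1)
    n_ref <- sample(1:3, 1)
    map <- snp_map(paste0("s", 1:m), "6", (1:m) * 100L, "A", "G")
    ref_hap <- matrix(sample(0:1, 2 * n_ref * m, TRUE), nrow = 2 * n_ref)
    reference <- haplotype_panel(ref_hap, map,
                                 paste0("r", 1:n_ref),
                                 rep("ref", n_ref))
    n_masked <- sample(1:(m - 1), 1)
    mask <- make_mask(map, n_masked, seed = rep_i)
    masked <- map$snp_id %in% mask$masked
    target <- sample(0:1, m, TRUE)
    eps <- runif(1, 0.01, 0.4)
    rho <- runif(1, 0, 0.8)
    params <- copying_params(epsilon = eps, rho = rho)

    got <- li_stephens_dosage(target, reference, params, mask)
    want <- ls_path_oracle(target, reference$hap, eps, rho, masked)
    expect_equal(unname(got), want, tolerance = 1e-10)
  }
})

test_that("genotype dosages are haplotype sums with bounds and guards", {
  withr::local_seed(71)
  map <- snp_map(paste0("s", 1:8), "6", (1:8) * 50L, "A", "G")
  ref_hap <- matrix(sample(0:1, 6 * 8, TRUE), nrow = 6L)
  reference <- haplotype_panel(ref_hap, map, paste0("r", 1:3), rep("ref", 3))
  tg_hap <- matrix(sample(0:1, 4 * 8, TRUE), nrow = 4L)
  target <- haplotype_panel(tg_hap, map, c("t1", "t2"), rep("tp", 2))
  mask <- make_mask(map, 3L, seed = 5)
  eps <- 0.05
  params <- copying_params(epsilon = eps, rho = 0.1)

  dos <- impute_targets(target, reference, params, mask)
  expect_identical(dim(dos), c(2L, 3L))
  expect_true(all(dos >= 2 * eps - 1e-12 & dos <= 2 - 2 * eps + 1e-12))
  # dosage equals sum of the two per-haplotype dosages
  d1 <- li_stephens_dosage(tg_hap[1, ], reference, params, mask)
  d2 <- li_stephens_dosage(tg_hap[2, ], reference, params, mask)
  expect_equal(unname(dos[1, ]), unname(d1 + d2), tolerance = 1e-12)

  # overfitting guard: shared sample ids are rejected
  leaky <- haplotype_panel(tg_hap, map, c("r1", "t2"), rep("tp", 2))
  expect_error(impute_targets(leaky, reference, params, mask),
               "overfitting guard")
})

test_that("discordance is 0 for perfect dosages, sign-blind, and order-invariant", {
  withr::local_seed(73)
  g <- matrix(sample(0:2, 15 * 8, TRUE), nrow = 15L)
  gm <- tiny_geno(g, rep("tp", 15L))
  ids <- gm$map$snp_id[1:5]
  dosages <- matrix(as.numeric(g[, 1:5]), nrow = 15L,
                    dimnames = list(gm$sample_id, ids))

  ev <- evaluate_discordance(gm, dosages)
  expect_equal(ev$discordance, 0, tolerance = 1e-12)
  expect_equal(ev$n_eval, 5L)

  # perfect anticorrelation also gives r^2 = 1 (r^2 is sign-blind)
  ev_anti <- evaluate_discordance(gm, 2 - dosages)
  expect_equal(ev_anti$discordance, 0, tolerance = 1e-12)

  # sample order invariance
  perm <- sample(15L)
  ev_perm <- evaluate_discordance(subset_samples(gm, perm), dosages)
  expect_equal(ev_perm$discordance, ev$discordance, tolerance = 1e-12)

  # pooled mode returns a single r^2
  ev_pool <- evaluate_discordance(gm, dosages, pooled = TRUE)
  expect_equal(ev_pool$mean_r2, 1, tolerance = 1e-12)
})

test_that("random dosages give discordance near 1 with mean r2 about 1/(n-1)", {
  withr::local_seed(79)
  n <- 19L
  m <- 400L
  g <- matrix(sample(0:2, n * m, TRUE), nrow = n)
  gm <- tiny_geno(g, rep("tp", n), pos = seq_len(m) * 10L)
  dosages <- matrix(runif(n * m, 0, 2), nrow = n,
                    dimnames = list(gm$sample_id, gm$map$snp_id))
  ev <- evaluate_discordance(gm, dosages)
  # independent pairs: E[r^2] = 1/(n-1) = 0.0556; MC tolerance ~4 se
  expect_equal(ev$mean_r2, 1 / (n - 1), tolerance = 0.35)
  expect_gt(ev$discordance, 0.9)
})

test_that("panel comparison crosses targets and panels; duplicate panels match", {
  cfg <- synth_config(n_pops = 2, n_samples_per_pop = 30, n_snps = 40,
                      n_founders = 5, founder_weight_concentration = 0.4,
                      seed = 83)
  panel <- founder_mosaic_panel(cfg)$panel
  sp <- split_reference_target(panel, 5L, seed = 7)
  mask <- make_mask(panel$map, 8L, seed = 7)
  params <- copying_params()
  refs <- split(seq_along(sp$reference$sample_id), sp$reference$population)
  panels <- list(p1 = subset_samples(sp$reference, refs$pop1),
                 dup = subset_samples(sp$reference, refs$pop1))
  cmp <- panel_comparison(sp$target, panels, params, mask)
  expect_identical(nrow(cmp), 4L)  # 2 target pops x 2 panels
  wide <- tidyr::pivot_wider(cmp[, c("target_pop", "panel", "discordance")],
                             names_from = "panel", values_from = "discordance")
  expect_equal(wide$p1, wide$dup, tolerance = 1e-12)
  expect_true(all(cmp$discordance >= 0 & cmp$discordance <= 1))
})
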