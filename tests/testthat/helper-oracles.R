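# Independent oracles and tiny fixture builders used across the suite.

# Exact HWE p-value by building the conditional heterozygote-count
# distribution with a successive-ratio recurrence (independent of the
# log-gamma closed form in the implementation).
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n_a <- 2L * n_aa + n_ab
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)
  h_max <- min(n_a, n_b)
  h <- seq(h_max %% 2L, h_max, by = 2L)
  p <- numeric(length(h))
  p[1] <- 1
  if (length(h) > 1) {
    for (k in seq_len(length(h) - 1L)) {
      hk <- h[k]
      # P(h+2)/P(h) = 4 * ((nA-h)/2) * ((nB-h)/2) / ((h+2)(h+1))
      p[k + 1] <- p[k] * 4 * ((n_a - hk) / 2) * ((n_b - hk) / 2) /
        ((hk + 2) * (hk + 1))
    }
  }
  p <- p / sum(p)
  obs <- p[match(n_ab, h)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# F_ST via the heterozygosity decomposition, written as H_T / H_S rather
# than the closed-form ratio used by snp_fst().
fst_het_oracle <- function(p1, p2) {
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  if (ht == 0) return(0)
  (ht - hs) / ht
}

# Li-Stephens posterior dosages by exhaustive enumeration of all state
# paths (reference-row sequences); feasible for <= 4 markers x <= 3 rows.
ls_path_oracle <- function(target_hap, ref_hap, eps, rho, masked) {
  n <- nrow(ref_hap); m <- ncol(ref_hap)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  w <- rep(1 / n, nrow(paths))
  if (m >= 2) {
    for (j in 2:m) {
      stay <- paths[, j] == paths[, j - 1L]
      w <- w * ((1 - rho) * stay + rho / n)
    }
  }
  for (j in which(!masked)) {
    match_j <- ref_hap[paths[, j], j] == target_hap[j]
    w <- w * ifelse(match_j, 1 - eps, eps)
  }
  vapply(which(masked), function(j) {
    sum(w * (eps + (1 - 2 * eps) * ref_hap[paths[, j], j])) / sum(w)
  }, numeric(1))
}

# exact upper-tail binomial P(X >= x) via explicit term enumeration
binom_tail_oracle <- function(x, size, prob) {
  if (x <= 0) return(1)
  ks <- x:size
  sum(choose(size, ks) * prob^ks * (1 - prob)^(size - ks))
}

# Monte-Carlo oracle for the mean two-population Nei F_ST under the
# Balding-Nichols model with binomial allele sampling (n_alleles per pop).
bn_fst_mc_oracle <- function(f, n_alleles, n_draws, seed) {
  withr::with_seed(seed, {
    p <- runif(n_draws, 0.05, 0.95)
    if (f == 0) {
      p1 <- p; p2 <- p
    } else {
      a <- p * (1 - f) / f
      b <- (1 - p) * (1 - f) / f
      p1 <- rbeta(n_draws, a, b)
      p2 <- rbeta(n_draws, a, b)
    }
    x1 <- rbinom(n_draws, n_alleles, p1) / n_alleles
    x2 <- rbinom(n_draws, n_alleles, p2) / n_alleles
    pb <- (x1 + x2) / 2
    mean(ifelse(pb * (1 - pb) == 0, 0, (x1 - x2)^2 / (4 * pb * (1 - pb))))
  })
}

# small deterministic panel: 2 populations x n samples, explicit matrix
tiny_panel <- function(hap, pops_per_sample, pos = NULL) {
  n <- length(pops_per_sample)
  stopifnot(nrow(hap) == 2L * n)
  m <- ncol(hap)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  map <- snp_map(paste0("s", seq_len(m)), "6", pos, "A", "G")
  haplotype_panel(hap, map, paste0("ind", seq_len(n)), pops_per_sample)
}

tiny_geno <- function(geno, pops_per_sample, pos = NULL) {
  m <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  map <- snp_map(paste0("s", seq_len(m)), "6", pos, "A", "G")
  genotype_matrix(geno, map, paste0("ind", seq_len(nrow(geno))),
                  pops_per_sample)
}
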