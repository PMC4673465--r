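#' Configuration for the synthetic multi-population generator
#'
#' Bundles every knob of the generator. Defaults emulate the study design
#' the package targets: a handful of populations of 200 diploid samples
#' genotyped at ~1,600 biallelic SNPs in a 10 Mb window, with weak
#' Balding-Nichols allele-frequency differentiation (F of the order of
#' 0.01, the magnitude seen between closely related cohorts) and a shared
#' set of founder haplotypes whose population usage frequencies differ, so
#' that both SNP-level and haplotype-level differentiation statistics have
#' signal.
#'
#' @param n_pops number of populations K.
#' @param n_samples_per_pop diploid samples per population.
#' @param n_snps number of biallelic markers.
#' @param region_length simulated window length in base pairs (markers are
#'   placed uniformly; positions only matter for region extraction).
#' @param fst_target Balding-Nichols differentiation parameter F in
#'   `[0, 1)`; 0 is the exchangeable-population limit.
#' @param n_founders number of founder haplotypes (>= 2).
#' @param switch_rate per-marker probability that a sampled haplotype
#'   switches to a freshly drawn founder (mosaic structure / LD decay).
#' @param mutation_rate per-site allele flip probability after copying.
#' @param founder_weight_concentration symmetric Dirichlet concentration
#'   for per-population founder usage weights; small values give skewed,
#'   population-specific usage, large values make populations similar.
#' @param seed integer master seed; all draws derive from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_pops = 2L, n_samples_per_pop = 200L,
                         n_snps = 1607L, region_length = 1e7,
                         fst_target = 0.01, n_founders = 12L,
                         switch_rate = 0.02, mutation_rate = 0.002,
                         founder_weight_concentration = 1,
                         seed = 1L) {
  stopifnot(n_pops >= 1, n_samples_per_pop >= 1, n_snps >= 1,
            fst_target >= 0, fst_target < 1, n_founders >= 2,
            switch_rate >= 0, switch_rate < 1,
            mutation_rate >= 0, mutation_rate <= 0.5,
            founder_weight_concentration > 0)
  structure(list(
    n_pops = as.integer(n_pops),
    n_samples_per_pop = as.integer(n_samples_per_pop),
    n_snps = as.integer(n_snps), region_length = region_length,
    fst_target = fst_target, n_founders = as.integer(n_founders),
    switch_rate = switch_rate, mutation_rate = mutation_rate,
    founder_weight_concentration = founder_weight_concentration,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# deterministic sub-stream seeds, kept below 2^31
sub_seed <- function(seed, offset) (as.integer(seed) %% 1000003L) * 2011L + offset

synth_map <- function(config, chrom = "6", start = 25e6) {
  pos <- start + sort(sample.int(as.integer(config$region_length),
                                 config$n_snps, replace = FALSE))
  snp_map(sprintf("snp%05d", seq_len(config$n_snps)), chrom, pos, "A", "G")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws one ancestral frequency per marker from Uniform(0.05, 0.95) (the
#' clipping keeps markers polymorphic so downstream F_ST estimators are
#' well-conditioned), then an independent frequency per population from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, whose mean is the ancestral
#' `p` and whose normalized variance is the target differentiation F. At
#' `F = 0` the populations share the ancestral frequency exactly.
#'
#' @param config a [synth_config()].
#' @return A `n_pops x n_snps` matrix of allele-1 frequencies with an
#'   `ancestral` attribute holding the ancestral frequency vector;
#'   rownames are `pop1..popK`.
#' @export
balding_nichols_freqs <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(sub_seed(config$seed, 1L), {
    p_anc <- stats::runif(config$n_snps, 0.05, 0.95)
    f <- config$fst_target
    if (f == 0) {
      freq <- matrix(rep(p_anc, each = config$n_pops), nrow = config$n_pops)
    } else {
      a <- p_anc * (1 - f) / f
      b <- (1 - p_anc) * (1 - f) / f
      freq <- matrix(stats::rbeta(config$n_pops * config$n_snps,
                                  rep(a, each = config$n_pops),
                                  rep(b, each = config$n_pops)),
                     nrow = config$n_pops)
    }
    rownames(freq) <- paste0("pop", seq_len(config$n_pops))
    attr(freq, "ancestral") <- p_anc
    freq
  })
}

#' Sample a linkage-equilibrium haplotype panel from given frequencies
#'
#' Draws each haplotype allele independently as Bernoulli(population
#' frequency). No linkage structure is induced; this is the appropriate
#' input for testing SNP-level statistics (F_ST recovery, PCA) where only
#' marginal frequencies matter.
#'
#' @param freqs populations x markers frequency matrix (rownames used as
#'   population labels), e.g. from [balding_nichols_freqs()].
#' @param n_samples_per_pop diploid samples drawn per population.
#' @param seed integer seed.
#' @param map optional [snp_map()]; autogenerated if `NULL`.
#' @return A [haplotype_panel()].
#' @export
sample_haplotype_panel <- function(freqs, n_samples_per_pop, seed, map = NULL) {
  k <- nrow(freqs); m <- ncol(freqs)
  if (is.null(map)) {
    map <- snp_map(sprintf("snp%05d", seq_len(m)), "6",
                   25e6 + seq_len(m) * 1000L, "A", "G")
  }
  withr::with_seed(sub_seed(seed, 2L), {
    hap <- matrix(0L, nrow = 2L * k * n_samples_per_pop, ncol = m)
    for (i in seq_len(k)) {
      rows <- (i - 1L) * 2L * n_samples_per_pop + seq_len(2L * n_samples_per_pop)
      hap[rows, ] <- matrix(
        stats::rbinom(length(rows) * m, 1L, rep(freqs[i, ], each = length(rows))),
        nrow = length(rows)
      )
    }
    pops <- rep(rownames(freqs), each = n_samples_per_pop)
    ids <- paste0(pops, "_s", rep(seq_len(n_samples_per_pop), k))
    haplotype_panel(hap, map, ids, pops)
  })
}

#' Generate a founder-mosaic multi-population panel
#'
#' Produces phased haplotypes with both allele-frequency differentiation
#' and shared haplotype structure. A pool of founder haplotypes is drawn
#' from a single ancestral frequency profile; each population receives
#' Dirichlet founder-usage weights; each sampled haplotype is then a
#' left-to-right mosaic of founders (switching to a freshly drawn founder
#' with probability `switch_rate` per marker interval) with per-site
#' mutation at rate `mutation_rate`. Populations therefore share the same
#' founder (major) haplotypes but at different frequencies - the structure
#' in which major-haplotype and haplotype-F_ST analyses have signal. SNP
#' marginal differentiation emerges from the weight differences rather
#' than from `fst_target`, which this generator does not use.
#'
#' @param config a [synth_config()].
#' @return A list of class `synth_dataset` with elements `panel` (a
#'   [haplotype_panel()]), `true_pop_freqs` (populations x markers
#'   expected allele-1 frequencies implied by weights, founders and
#'   mutation), `founders` (founders x markers binary matrix),
#'   `founder_weights` (populations x founders) and `config`.
#' @export
founder_mosaic_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  m <- config$n_snps
  k <- config$n_pops
  nf <- config$n_founders
  withr::with_seed(sub_seed(config$seed, 3L), {
    map <- synth_map(config)
    p_anc <- stats::runif(m, 0.05, 0.95)
    founders <- matrix(stats::rbinom(nf * m, 1L, rep(p_anc, each = nf)),
                       nrow = nf)
    # per-population founder usage: symmetric Dirichlet via gamma draws
    w <- matrix(stats::rgamma(k * nf, shape = config$founder_weight_concentration),
                nrow = k)
    w <- w / rowSums(w)
    rownames(w) <- paste0("pop", seq_len(k))

    n <- config$n_samples_per_pop
    hap <- matrix(0L, nrow = 2L * k * n, ncol = m)
    row <- 0L
    for (i in seq_len(k)) {
      for (s in seq_len(2L * n)) {
        row <- row + 1L
        # mosaic: segment boundaries where a switch fires, founder per segment
        switches <- c(TRUE, stats::runif(m - 1L) < config$switch_rate)
        seg <- cumsum(switches)
        fid <- sample.int(nf, max(seg), replace = TRUE, prob = w[i, ])
        h <- founders[cbind(fid[seg], seq_len(m))]
        if (config$mutation_rate > 0) {
          flip <- stats::runif(m) < config$mutation_rate
          h[flip] <- 1L - h[flip]
        }
        hap[row, ] <- h
      }
    }
    pops <- rep(rownames(w), each = n)
    ids <- paste0(pops, "_s", rep(seq_len(n), k))
    mu <- config$mutation_rate
    p_copy <- w %*% founders          # frequency before mutation
    true_freqs <- p_copy * (1 - mu) + (1 - p_copy) * mu
    colnames(true_freqs) <- map$snp_id
    structure(list(
      panel = haplotype_panel(hap, map, ids, pops),
      true_pop_freqs = true_freqs, founders = founders,
      founder_weights = w, config = config
    ), class = "synth_dataset")
  })
}

#' Split a panel into reference and target sets
#'
#' Draws `n_target_per_pop` samples per population into a target panel and
#' leaves the rest as reference, with disjoint sample sets (the guard
#' against overfitting in imputation evaluation).
#'
#' @param panel a [haplotype_panel()].
#' @param n_target_per_pop samples per population to hold out.
#' @param seed integer seed.
#' @return A list with elements `reference` and `target`, both
#'   [haplotype_panel()]s.
#' @export
split_reference_target <- function(panel, n_target_per_pop, seed) {
  stopifnot(inherits(panel, "haplotype_panel"), n_target_per_pop >= 0)
  pops <- split(seq_along(panel$sample_id), panel$population)
  small <- names(pops)[vapply(pops, length, 1L) <= n_target_per_pop]
  if (n_target_per_pop > 0 && length(small)) {
    stop("split_reference_target: population too small: ", small[1], call. = FALSE)
  }
  if (n_target_per_pop == 0L) {
    empty <- haplotype_panel(panel$hap[0L, , drop = FALSE], panel$map,
                             character(0), character(0))
    return(list(reference = panel, target = empty))
  }
  withr::with_seed(sub_seed(seed, 4L), {
    target_idx <- sort(unlist(lapply(pops, function(idx) {
      sample(idx, n_target_per_pop)
    }), use.names = FALSE))
  })
  list(reference = subset_samples(panel, setdiff(seq_along(panel$sample_id), target_idx)),
       target = subset_samples(panel, target_idx))
}
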