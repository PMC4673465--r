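#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an F_ST matrix into long pair records
#'
#' @param x an `fst_matrix`.
#' @param ... unused.
#' @return A tibble `pop_i`, `pop_j` (`pop_i < pop_j`), `fst`,
#'   `n_markers`.
#' @export
tidy.fst_matrix <- function(x, ...) {
  pops <- x$populations
  pairs <- utils::combn(seq_along(pops), 2L)
  nm <- x$n_markers
  tibble::tibble(
    pop_i = pops[pairs[1L, ]], pop_j = pops[pairs[2L, ]],
    fst = x$fst[t(pairs)],
    n_markers = if (is.matrix(nm)) as.integer(nm[t(pairs)])
                else rep(as.integer(nm), ncol(pairs))
  )
}

#' @export
glance.fst_matrix <- function(x, ...) {
  v <- x$fst[upper.tri(x$fst)]
  tibble::tibble(n_populations = length(x$populations),
                 mean_fst = mean(v), min_fst = min(v), max_fst = max(v))
}

#' Tidy PCA / PCoA coordinates
#'
#' @param x a `pop_pca`.
#' @param ... unused.
#' @return A tibble with `entity`, `population` and one column per
#'   component.
#' @export
tidy.pop_pca <- function(x, ...) {
  coords <- tibble::as_tibble(x$coordinates, .name_repair = "minimal")
  entity <- rownames(x$coordinates)
  if (is.null(entity)) entity <- as.character(seq_len(nrow(x$coordinates)))
  pop <- if (x$kind == "sample") x$population else entity
  dplyr::bind_cols(tibble::tibble(entity = entity, population = pop), coords)
}

#' @export
glance.pop_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(
    kind = x$kind, n_entities = nrow(x$coordinates),
    n_components = ncol(x$coordinates),
    prop_var_pc1 = if (tot > 0) x$eigenvalues[1] / tot else NA_real_,
    negative_eigenvalue_mass = sum(abs(x$negative_eigenvalues))
  )
}

#' Tidy a haplotype catalog into long frequency records
#'
#' @param x a `haplotype_catalog`.
#' @param ... unused.
#' @return A tibble `region`, `population`, `haplotype`, `count`, `freq`.
#' @export
tidy.haplotype_catalog <- function(x, ...) {
  tibble::tibble(
    region = x$region$name,
    population = rep(rownames(x$freq), times = ncol(x$freq)),
    haplotype = rep(colnames(x$freq), each = nrow(x$freq)),
    count = as.integer(x$counts), freq = as.vector(x$freq)
  )
}

#' @export
glance.haplotype_catalog <- function(x, ...) {
  tibble::tibble(region = x$region$name, n_snps = nrow(x$map),
                 n_distinct_haplotypes = length(x$haplotypes),
                 n_populations = nrow(x$freq))
}

#' Tidy a major-haplotype set
#'
#' @param x a `major_haplotypes` object.
#' @param ... unused.
#' @return A tibble `label`, `haplotype`, `max_freq` plus one frequency
#'   column per population.
#' @export
tidy.major_haplotypes <- function(x, ...) {
  base <- tibble::tibble(label = x$label, haplotype = x$haplotype,
                         max_freq = x$max_freq)
  if (!length(x$label)) return(base)
  freqs <- t(x$catalog$freq[, x$haplotype, drop = FALSE])
  dplyr::bind_cols(base, tibble::as_tibble(freqs, .name_repair = "minimal"))
}

#' @export
tidy.imputation_eval <- function(x, ...) {
  dplyr::mutate(x$per_marker, target_pop = x$target_pop, panel = x$panel)
}

#' @export
glance.imputation_eval <- function(x, ...) {
  tibble::tibble(target_pop = x$target_pop, panel = x$panel,
                 n_eval = x$n_eval, n_skipped = x$n_skipped,
                 mean_r2 = x$mean_r2, discordance = x$discordance)
}
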