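# Haploid diversity summaries: haplotype/nucleotide diversity, singleton
# accounting, SNP-density chi-square, haplotype-frequency PCA, KS comparison.

#' Haplotype (gene) diversity
#'
#' Nei's unbiased gene diversity on haploid data,
#' `H = n/(n-1) * (1 - sum p_k^2)` over haplotype frequencies `p_k`.
#'
#' @param h Either a character vector of haplotype identifiers (one per
#'   chromosome) or a [haplotype_matrix] (complete-case haplotypes over
#'   `sites`).
#' @param sites,samples Selection used when `h` is a matrix.
#' @return `H` in `[0, 1]`.
#' @examples
#' haplotype_diversity(c("a", "a", "b", "c"))  # 4/3 * (1 - 0.375) = 0.8333
#' @export
haplotype_diversity <- function(h, sites = NULL, samples = NULL) {
  h <- as_hap_vector(h, sites, samples)
  n <- length(h)
  if (n < 2L) stop_("need at least 2 haplotypes")
  p <- as.numeric(table(h)) / n
  n / (n - 1) * (1 - sum(p^2))
}

as_hap_vector <- function(h, sites = NULL, samples = NULL) {
  if (inherits(h, "haplotype_matrix"))
    hap_keys(h, sites %||% seq_len(n_sites(h)), samples %||% h$samples)
  else as.character(h)
}

#' Nucleotide diversity (mean pairwise differences)
#'
#' Average number of allele differences over all chromosome pairs, with
#' complete-case comparison per site pair (a site enters a pair's count only
#' when called in both chromosomes). Optionally also scaled per site.
#'
#' @param x A [haplotype_matrix].
#' @param sites,samples Selection (defaults: everything).
#' @param L Sequence length in bp for the per-site value; defaults to the
#'   number of selected sites (appropriate for SNP-only input; pass the
#'   block's called length to express diversity per sequenced base).
#' @return A list with `pi` (per block, mean pairwise differences),
#'   `pi_per_site` (`pi / L`) and `n` chromosomes used.
#' @export
nucleotide_diversity <- function(x, sites = seq_len(n_sites(x)),
                                 samples = x$samples, L = NULL) {
  g <- x$geno[samples, sites, drop = FALSE]
  n <- nrow(g)
  if (n < 2L) stop_("need at least 2 haplotypes")
  tot <- 0
  for (i in seq_len(n - 1L)) {
    a <- g[i, ]
    rest <- g[(i + 1L):n, , drop = FALSE]
    cmp <- sweep(rest, 2L, a, `!=`)
    cmp[is.na(cmp)] <- FALSE  # pairwise-complete: uncalled sites drop out
    tot <- tot + sum(cmp)
  }
  pi <- tot / choose(n, 2L)
  L <- L %||% length(sites)
  list(pi = pi, pi_per_site = if (L > 0) pi / L else NA_real_, n = n)
}

#' Singleton and novelty accounting over the full data set
#'
#' A singleton is a derived allele carried by exactly one chromosome in the
#' entire data set. Requires ancestral states; if any are unknown the count
#' falls back to minor-allele-count-one with a warning. Each singleton site
#' is attributed to the population of its single carrier. An optional known-
#' variant list partitions SNPs into known and novel.
#'
#' @param x A [haplotype_matrix].
#' @param known_variants Optional `data.frame` with columns `chrom`, `pos`
#'   listing previously reported variants.
#' @return A list: `n_sites`, `n_singletons`, `pct_singletons` (1 decimal),
#'   `by_population` (named counts), and when `known_variants` is given,
#'   `n_novel` / `pct_novel`.
#' @export
singleton_summary <- function(x, known_variants = NULL) {
  anc <- ancestral_index(x)
  use_derived <- !anyNA(anc)
  if (!use_derived && n_sites(x))
    warning("ancestral state unknown at some sites; using minor-allele count",
            call. = FALSE)
  is_singleton <- logical(n_sites(x))
  carrier <- rep(NA_character_, n_sites(x))
  for (j in seq_len(n_sites(x))) {
    g <- x$geno[, j]
    g <- g[!is.na(g)]
    if (length(unique(g)) < 2L) next
    if (use_derived) {
      nonanc <- which(x$geno[, j] != anc[j])
      if (length(nonanc) == 1L) {
        is_singleton[j] <- TRUE
        carrier[j] <- x$samples[nonanc]
      }
    } else {
      tab <- table(g)
      if (min(tab) == 1L && length(tab) == 2L) {
        rare <- as.integer(names(tab)[which.min(tab)])
        idx <- which(x$geno[, j] == rare)
        is_singleton[j] <- TRUE
        carrier[j] <- x$samples[idx[1L]]
      }
    }
  }
  by_pop <- table(factor(x$populations[carrier[is_singleton]],
                         levels = sort(unique(unname(x$populations)))))
  out <- list(n_sites = n_sites(x),
              n_singletons = sum(is_singleton),
              pct_singletons = round(100 * sum(is_singleton) /
                                       max(1L, n_sites(x)), 1L),
              by_population = c(by_pop),
              singleton_sites = which(is_singleton))
  if (!is.null(known_variants)) {
    key <- paste(known_variants$chrom, known_variants$pos)
    novel <- !(paste(x$sites$chrom, x$sites$pos) %in% key)
    out$n_novel <- sum(novel)
    out$pct_novel <- round(100 * sum(novel) / max(1L, n_sites(x)), 1L)
  }
  out
}

#' SNP-density heterogeneity test with Yates' correction
#'
#' Tests whether SNP counts across blocks are proportional to block lengths,
#' with the continuity correction applied to every cell (the convention here
#' even for more than two categories): `sum((|O - E| - 0.5)^2 / E)` on
#' `k - 1` degrees of freedom.
#'
#' @param counts Observed SNP counts per block.
#' @param lengths Block lengths in bp (same order).
#' @return List with `chi2`, `df`, `p_value`.
#' @export
snp_density_test <- function(counts, lengths) {
  if (length(counts) < 2L || length(counts) != length(lengths))
    stop_("need matching counts and lengths for >= 2 blocks")
  if (any(lengths <= 0)) stop_("lengths must be positive")
  total <- sum(counts)
  if (total == 0) stop_("zero total count")
  expected <- total * lengths / sum(lengths)
  chi2 <- sum((abs(counts - expected) - 0.5)^2 / expected)
  df <- length(counts) - 1L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Per-population haplotype frequency table
#'
#' @param x A [haplotype_matrix].
#' @param sites Site indices defining the haplotypes.
#' @return Numeric matrix, populations in rows, distinct haplotypes in
#'   columns, entries relative frequencies (rows sum to 1).
#' @export
haplotype_frequencies <- function(x, sites = seq_len(n_sites(x))) {
  keys <- hap_keys(x, sites)
  pops <- x$populations[names(keys)]
  tab <- table(factor(pops), factor(keys))
  freq <- sweep(unclass(tab), 1L, rowSums(tab), `/`)
  freq[is.nan(freq)] <- 0
  freq
}

#' PCA on haplotype frequencies by population
#'
#' Centred (unscaled) principal components of the population-by-haplotype
#' frequency matrix, the standard first look at population structure from
#' haplotype data.
#'
#' @param freq Matrix from [haplotype_frequencies()]: populations in rows.
#' @return List: `scores` (populations x PCs), `var_explained_pct`
#'   (per component, summing to 100 over all non-degenerate components).
#' @export
haplotype_freq_pca <- function(freq) {
  if (nrow(freq) < 3L) stop_("need at least 3 populations")
  pc <- stats::prcomp(freq, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  pct <- if (sum(v) > 0) 100 * v / sum(v) else rep(0, length(v))
  list(scores = pc$x, var_explained_pct = pct)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] (asymptotic p-value), used to
#' compare per-population diversity distributions between blocks.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `statistic` (sup ECDF difference) and `p_value`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop_("empty sample")
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Per-group diversity and neutrality summary
#'
#' The full per-block summary: for each sample group it reports n
#' chromosomes, segregating sites S, singletons, distinct haplotypes K,
#' haplotype diversity H, nucleotide diversity (per block and per site),
#' Tajima's D, Fu's Fs and Fu & Li's D, optionally with
#' coalescent-simulation p-values.
#'
#' @param x A [haplotype_matrix].
#' @param sites Site indices of the block (default all).
#' @param groups Named list of population-label vectors; default: one group
#'   per population plus `"Total"` with everything.
#' @param L Block length in bp for per-site diversity (default: SNP count).
#' @param n_sim Replicates for significance by fixed-S coalescent simulation
#'   (0 = skip, p-values `NA`).
#' @param seed Seed for the significance simulations.
#' @return A `data.frame`, one row per group.
#' @export
diversity_stats <- function(x, sites = seq_len(n_sites(x)), groups = NULL,
                            L = NULL, n_sim = 0L, seed = NULL) {
  if (is.null(groups)) {
    labs <- sort(unique(unname(x$populations)))
    groups <- c(stats::setNames(as.list(labs), labs), list(Total = labs))
  }
  rows <- lapply(names(groups), function(gname) {
    samples <- x$samples[x$populations %in% groups[[gname]]]
    sub <- x[samples, sites]
    n <- n_samples(sub)
    S <- sum(vapply(seq_len(n_sites(sub)), function(j)
      n_observed_alleles(sub, j) > 1L, logical(1L)))
    eta_s <- group_singletons(sub)
    K <- count_haplotypes(sub)
    H <- if (n >= 2L) haplotype_diversity(sub) else NA_real_
    nd <- if (n >= 2L) nucleotide_diversity(sub, L = L) else
      list(pi = NA_real_, pi_per_site = NA_real_)
    D <- if (n >= 4L && S >= 1L) tajimas_d_stat(n, S, nd$pi) else NA_real_
    Fs <- if (n >= 2L && nd$pi > 0 && K >= 2L)
      fu_fs_stat(n, K, nd$pi) else NA_real_
    DFL <- if (n >= 4L && S >= 1L && !is.na(eta_s))
      fu_li_d_stat(n, S, eta_s) else NA_real_
    p <- c(tajima_d = NA_real_, fu_fs = NA_real_, fu_li_d = NA_real_)
    if (n_sim > 0L && S >= 1L && n >= 4L) {
      null <- neutrality_null(n, S, n_sim, seed = seed)
      if (!is.na(D))
        p["tajima_d"] <- two_tailed_p(null$tajima_d, D)
      if (!is.na(Fs))
        p["fu_fs"] <- mean(null$fu_fs <= Fs, na.rm = TRUE)
      if (!is.na(DFL))
        p["fu_li_d"] <- two_tailed_p(null$fu_li_d, DFL)
    }
    data.frame(group = gname, n = n, S = S, singletons = eta_s,
               K = K, H = H, pi = nd$pi, pi_per_site = nd$pi_per_site,
               tajima_d = D, p_tajima_d = p[["tajima_d"]],
               fu_fs = Fs, p_fu_fs = p[["fu_fs"]],
               fu_li_d = DFL, p_fu_li_d = p[["fu_li_d"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Derived singletons within a group; NA when ancestral states are unknown
# and the group-level count would be ambiguous (minor-allele fallback).
group_singletons <- function(x) {
  anc <- ancestral_index(x)
  cnt <- 0L
  for (j in seq_len(n_sites(x))) {
    g <- x$geno[, j]
    g <- g[!is.na(g)]
    if (length(unique(g)) < 2L) next
    if (!is.na(anc[j])) {
      if (sum(g != anc[j]) == 1L) cnt <- cnt + 1L
    } else {
      tab <- table(g)
      if (length(tab) == 2L && min(tab) == 1L) cnt <- cnt + 1L
    }
  }
  cnt
}

two_tailed_p <- function(null, obs) {
  null <- null[is.finite(null)]
  if (!length(null)) return(NA_real_)
  min(1, 2 * min(mean(null <= obs), mean(null >= obs)))
}
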