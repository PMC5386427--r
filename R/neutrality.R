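# Neutrality statistics on haploid data: Tajima's D, Fu's Fs (Ewens
# sampling formula via Stirling numbers), Fu & Li's D (outgroup-rooted),
# and their significance under a fixed-S coalescent null.

#' Tajima's D from summary quantities
#'
#' The classical frequency-spectrum test statistic
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the 1989 constants
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i up to n-1), `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`.
#'
#' @param n Number of chromosomes (>= 4).
#' @param S Number of segregating sites (>= 1; `NA` returned for `S = 0`,
#'   where D is undefined).
#' @param pi Mean pairwise differences.
#' @return Numeric `D`.
#' @export
tajimas_d_stat <- function(n, S, pi) {
  if (n < 4L) stop_("Tajima's D needs n >= 4")
  if (S < 1L) return(NA_real_)
  a1 <- harmonic(n - 1L)
  a2 <- harmonic2(n - 1L)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Fu's Fs from summary quantities
#'
#' `Fs = ln(S'/(1-S'))` with `S' = P(K >= k_obs | theta)` under the Ewens
#' sampling formula, `P(K = k) = |s(n,k)| theta^k / theta^{(n)}` with
#' unsigned Stirling numbers of the first kind and the rising factorial
#' `theta^{(n)}`. Stirling numbers are evaluated by the standard recurrence
#' in log space, so arbitrarily large n poses no overflow problem.
#'
#' @param n Number of chromosomes.
#' @param k_obs Observed number of distinct haplotypes.
#' @param theta Estimate of theta; the statistic plugs in the mean pairwise
#'   differences (must be > 0).
#' @return Numeric `Fs` (strongly negative = excess of haplotypes, as after
#'   an expansion).
#' @export
fu_fs_stat <- function(n, k_obs, theta) {
  if (theta <= 0) return(NA_real_)
  if (k_obs < 1L || k_obs > n) stop_("k_obs must be in 1..n")
  lst <- log_stirling_row(n)
  lrf <- sum(log(theta + 0:(n - 1L)))
  logp <- lst + seq_len(n) * log(theta) - lrf
  logSp <- logsumexp(logp[k_obs:n])
  if (logSp >= 0) return(-Inf)          # S' = 1 (k_obs = 1): no signal
  log1mSp <- log(-expm1(logSp))
  logSp - log1mSp
}

# log |s(n, k)| for k = 1..n, cached per n. Recurrence:
# |s(n,k)| = |s(n-1,k-1)| + (n-1)|s(n-1,k)|.
.phax_cache <- new.env(parent = emptyenv())
log_stirling_row <- function(n) {
  key <- paste0("stirling", n)
  v <- .phax_cache[[key]]
  if (!is.null(v)) return(v)
  row <- 0  # n = 1: |s(1,1)| = 1
  if (n > 1L) for (m in 2:n) {
    prev <- c(row, -Inf)          # k = 1..m with |s(m-1, m)| = 0
    shifted <- c(-Inf, row)       # |s(m-1, k-1)|
    row <- vapply(seq_len(m), function(k)
      logsumexp(c(shifted[k], log(m - 1) + prev[k])), numeric(1L))
  }
  .phax_cache[[key]] <- row
  row
}

#' Fu & Li's D from summary quantities (outgroup-rooted)
#'
#' `D = (eta - a_n * eta_s) / sqrt(u_D * eta + v_D * eta^2)` where `eta` is
#' the total number of mutations, `eta_s` the number of derived singletons
#' (requires the outgroup-polarized definition), `a_n = sum_{i<n} 1/i`, and
#' `u_D`, `v_D` the original variance constants
#' (`c_n = 2(n a_n - 2(n-1))/((n-1)(n-2))`,
#' `v_D = 1 + a_n^2/(b_n + a_n^2) (c_n - (n+1)/(n-1))`,
#' `u_D = a_n - 1 - v_D`, `b_n = sum_{i<n} 1/i^2`).
#'
#' @param n Number of chromosomes (>= 4).
#' @param eta Total mutations (segregating sites under infinite sites).
#' @param eta_s Derived singletons.
#' @return Numeric `D` (`NA` when `eta = 0`, where it is undefined).
#' @export
fu_li_d_stat <- function(n, eta, eta_s) {
  if (n < 4L) stop_("Fu & Li's D needs n >= 4")
  if (eta < 1L) return(NA_real_)
  a_n <- harmonic(n - 1L)
  b_n <- harmonic2(n - 1L)
  c_n <- 2 * (n * a_n - 2 * (n - 1)) / ((n - 1) * (n - 2))
  v_D <- 1 + a_n^2 / (b_n + a_n^2) * (c_n - (n + 1) / (n - 1))
  u_D <- a_n - 1 - v_D
  (eta - a_n * eta_s) / sqrt(u_D * eta + v_D * eta^2)
}

#' Tajima's D of a haplotype matrix
#'
#' @param x A [haplotype_matrix].
#' @param sites,samples Selection (defaults: everything).
#' @param n_sim Fixed-S coalescent replicates for a two-tailed p-value
#'   (0 = none).
#' @param seed Seed for the null simulation.
#' @return List with `statistic`, `S`, `pi`, `n`, `p_value`.
#' @export
tajimas_d <- function(x, sites = seq_len(n_sites(x)), samples = x$samples,
                      n_sim = 0L, seed = NULL) {
  sub <- x[samples, sites]
  n <- n_samples(sub)
  S <- sum(vapply(seq_len(n_sites(sub)), function(j)
    n_observed_alleles(sub, j) > 1L, logical(1L)))
  pi <- if (n >= 2L) nucleotide_diversity(sub)$pi else NA_real_
  D <- if (n >= 4L) tajimas_d_stat(n, S, pi) else NA_real_
  p <- NA_real_
  if (n_sim > 0L && !is.na(D))
    p <- two_tailed_p(neutrality_null(n, S, n_sim, seed)$tajima_d, D)
  list(statistic = D, S = S, pi = pi, n = n, p_value = p)
}

#' Fu's Fs of a haplotype matrix
#'
#' @inheritParams tajimas_d
#' @return List with `statistic`, `k`, `pi`, `n`, `p_value` (one-tailed,
#'   `P(Fs_sim <= Fs_obs)`, the usual convention for this statistic).
#' @export
fu_fs <- function(x, sites = seq_len(n_sites(x)), samples = x$samples,
                  n_sim = 0L, seed = NULL) {
  sub <- x[samples, sites]
  n <- n_samples(sub)
  if (n < 2L) stop_("need at least 2 haplotypes")
  k <- count_haplotypes(sub)
  pi <- nucleotide_diversity(sub)$pi
  Fs <- fu_fs_stat(n, k, pi)
  p <- NA_real_
  if (n_sim > 0L && !is.na(Fs) && is.finite(Fs)) {
    S <- sum(vapply(seq_len(n_sites(sub)), function(j)
      n_observed_alleles(sub, j) > 1L, logical(1L)))
    null <- neutrality_null(n, S, n_sim, seed)$fu_fs
    p <- mean(null <= Fs, na.rm = TRUE)
  }
  list(statistic = Fs, k = k, pi = pi, n = n, p_value = p)
}

#' Fu & Li's D of a haplotype matrix
#'
#' Uses the outgroup-rooted singleton definition, so ancestral states must
#' be known at the selected sites.
#'
#' @inheritParams tajimas_d
#' @return List with `statistic`, `eta`, `eta_s`, `n`, `p_value`.
#' @export
fu_li_d <- function(x, sites = seq_len(n_sites(x)), samples = x$samples,
                    n_sim = 0L, seed = NULL) {
  sub <- x[samples, sites]
  if (anyNA(ancestral_index(sub)))
    stop_("Fu & Li's D needs known ancestral states at all selected sites")
  n <- n_samples(sub)
  seg <- vapply(seq_len(n_sites(sub)), function(j)
    n_observed_alleles(sub, j) > 1L, logical(1L))
  eta <- sum(seg)
  eta_s <- group_singletons(sub)
  D <- if (n >= 4L) fu_li_d_stat(n, eta, eta_s) else NA_real_
  p <- NA_real_
  if (n_sim > 0L && !is.na(D))
    p <- two_tailed_p(neutrality_null(n, eta, n_sim, seed)$fu_li_d, D)
  list(statistic = D, eta = eta, eta_s = eta_s, n = n, p_value = p)
}

#' Fixed-S coalescent null distribution of the neutrality statistics
#'
#' Simulates constant-size Kingman genealogies and drops exactly `S`
#' mutations multinomially along branches in proportion to branch length
#' (Hudson's fixed-S conditioning), returning the joint null sample of
#' Tajima's D, Fu's Fs and Fu & Li's D. The effective size cancels under
#' fixed-S, so the null depends only on `n` and `S`.
#'
#' @param n Chromosomes sampled.
#' @param S Segregating sites conditioned on.
#' @param n_sim Replicates.
#' @param seed Optional seed.
#' @return List of numeric vectors `tajima_d`, `fu_fs`, `fu_li_d`.
#' @export
neutrality_null <- function(n, S, n_sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- demographic_model("constant", N0 = 1000, L = 1L)
  td <- fs <- fl <- numeric(n_sim)
  for (r in seq_len(n_sim)) {
    tree <- simulate_genealogy(model, n)
    len <- tree$edge.length
    muts <- as.vector(stats::rmultinom(1L, S, len / sum(len)))
    ntips <- length(tree$tip.label)
    dcounts <- edge_tip_counts(tree)
    # site frequency spectrum quantities
    d <- rep(dcounts, muts)
    pi <- sum(d * (n - d)) / choose(n, 2L)
    eta_s <- sum(d == 1L)
    # distinct haplotypes: tips partitioned by their set of mutated edges
    mut_edges <- which(muts > 0L)
    profiles <- hap_profiles(tree, mut_edges, ntips)
    k <- length(unique(profiles))
    td[r] <- tajimas_d_stat(n, S, pi)
    fs[r] <- if (pi > 0) fu_fs_stat(n, k, pi) else NA_real_
    fl[r] <- fu_li_d_stat(n, S, eta_s)
  }
  list(tajima_d = td, fu_fs = fs, fu_li_d = fl)
}

# Number of tips below each edge of a phylo tree.
edge_tip_counts <- function(tree) {
  ntips <- length(tree$tip.label)
  nn <- max(tree$edge)
  cnt <- integer(nn)
  cnt[seq_len(ntips)] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge)))
    cnt[ord$edge[e, 1L]] <- cnt[ord$edge[e, 1L]] + cnt[ord$edge[e, 2L]]
  cnt[tree$edge[, 2L]]
}

# For each tip, a key identifying which of the given edges lie on its path
# to the root (= its haplotype under one mutation cluster per edge).
hap_profiles <- function(tree, mut_edges, ntips) {
  if (!length(mut_edges)) return(rep("", ntips))
  below <- lapply(mut_edges, function(e)
    tips_below(tree, tree$edge[e, 2L], ntips))
  prof <- matrix(FALSE, ntips, length(mut_edges))
  for (m in seq_along(below)) prof[below[[m]], m] <- TRUE
  apply(prof, 1L, paste, collapse = "")
}

tips_below <- function(tree, node, ntips) {
  if (node <= ntips) return(node)
  out <- integer(0)
  stack <- node
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  while (length(stack)) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    ch <- children[[as.character(nd)]]
    tipch <- ch[ch <= ntips]
    out <- c(out, tipch)
    stack <- c(stack, ch[ch > ntips])
  }
  out
}
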