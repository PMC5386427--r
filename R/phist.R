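# AMOVA-based phi-st between populations of haploid chromosomes, with
# permutation significance (the molecular analogue of Fst on haplotype
# distance matrices).

#' Pairwise difference matrix between chromosomes
#'
#' Hamming distances (number of differing sites, pairwise-complete) between
#' all selected chromosomes; AMOVA treats these counts as squared molecular
#' distances.
#'
#' @param x A [haplotype_matrix].
#' @param sites,samples Selection (defaults: everything).
#' @return Symmetric numeric matrix with sample names as dimnames.
#' @export
pairwise_differences <- function(x, sites = seq_len(n_sites(x)),
                                 samples = x$samples) {
  g <- x$geno[samples, sites, drop = FALSE]
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) {
    a <- g[i, ]
    rest <- g[(i + 1L):n, , drop = FALSE]
    cmp <- sweep(rest, 2L, a, `!=`)
    cmp[is.na(cmp)] <- FALSE
    dd <- rowSums(cmp)
    d[i, (i + 1L):n] <- dd
    d[(i + 1L):n, i] <- dd
  }
  d
}

# Two-level AMOVA on squared distances: returns phi_st.
amova_phi <- function(d2, groups) {
  groups <- as.factor(groups)
  N <- length(groups)
  P <- nlevels(groups)
  ssd_total <- sum(d2[lower.tri(d2)]) / N
  ssd_within <- 0
  n_g <- integer(P)
  for (l in seq_len(P)) {
    idx <- which(groups == levels(groups)[l])
    n_g[l] <- length(idx)
    sub <- d2[idx, idx, drop = FALSE]
    ssd_within <- ssd_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  ssd_among <- ssd_total - ssd_within
  sigma_w <- ssd_within / (N - P)
  n_c <- (N - sum(n_g^2) / N) / (P - 1)
  sigma_a <- (ssd_among / (P - 1) - sigma_w) / n_c
  denom <- sigma_a + sigma_w
  if (denom == 0) return(0)
  sigma_a / denom
}

#' Pairwise phi-st with permutation significance
#'
#' For every population pair, computes phi-st from the AMOVA variance
#' components of the squared pairwise-difference matrix (among-population
#' variance over total), with a significance level from random permutations
#' of population labels. Slightly negative estimates are reported as
#' computed.
#'
#' @param x A [haplotype_matrix] with at least two populations of >= 2
#'   samples each.
#' @param sites Site selection (default all).
#' @param populations Labels to include (default all).
#' @param n_permutations Label permutations per pair (0 = no p-values).
#' @param seed Seed for the permutations.
#' @return List of class `phi_st_matrix`: `phi` (symmetric matrix, zero
#'   diagonal), `p` (permutation p-values, `P(phi_perm >= phi_obs)`),
#'   `n_permutations`, `seed`.
#' @export
phi_st <- function(x, sites = seq_len(n_sites(x)), populations = NULL,
                   n_permutations = 0L, seed = NULL) {
  populations <- populations %||% sort(unique(unname(x$populations)))
  if (length(populations) < 2L) stop_("need at least 2 populations")
  sizes <- vapply(populations, function(p)
    sum(x$populations == p), integer(1L))
  if (any(sizes < 2L))
    stop_("population(s) with fewer than 2 samples: %s",
          paste(populations[sizes < 2L], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  keep <- x$samples[x$populations %in% populations]
  d2 <- pairwise_differences(x, sites, keep)
  labs <- x$populations[keep]
  P <- length(populations)
  phi <- matrix(0, P, P, dimnames = list(populations, populations))
  pmat <- matrix(NA_real_, P, P, dimnames = list(populations, populations))
  for (a in seq_len(P - 1L)) for (b in (a + 1L):P) {
    idx <- which(labs %in% populations[c(a, b)])
    sub <- d2[idx, idx, drop = FALSE]
    g <- labs[idx]
    obs <- amova_phi(sub, g)
    phi[a, b] <- phi[b, a] <- obs
    if (n_permutations > 0L) {
      perm <- vapply(seq_len(n_permutations), function(r)
        amova_phi(sub, sample(g)), numeric(1L))
      pv <- mean(perm >= obs)
      pmat[a, b] <- pmat[b, a] <- pv
    }
  }
  structure(list(phi = phi, p = pmat, n_permutations = n_permutations,
                 seed = seed),
            class = "phi_st_matrix")
}

#' @export
print.phi_st_matrix <- function(x, ...) {
  cat("pairwise phi_st:\n")
  print(round(x$phi, 4))
  if (x$n_permutations > 0L) {
    cat(sprintf("p-values (%d permutations):\n", x$n_permutations))
    print(round(x$p, 4))
  }
  invisible(x)
}

#' Average phi-st per population
#'
#' Mean of a population's pairwise phi-st values against all others, the
#' usual single-number summary per group.
#'
#' @param ps A `phi_st_matrix` from [phi_st()].
#' @return Named numeric vector.
#' @export
mean_phi_st <- function(ps) {
  phi <- ps$phi
  diag(phi) <- NA
  rowMeans(phi, na.rm = TRUE)
}
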