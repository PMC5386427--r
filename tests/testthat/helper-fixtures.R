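# Fixture builders shared across tests. Everything is generated in code;
# no binary fixtures.

# haplotype_matrix from one string per chromosome ("0110", "ACGT", ...).
# Ancestral defaults to unknown; pass a string to set it per site.
hm_from_strings <- function(strings, populations = NULL, ancestral = NULL,
                            chrom = "chr1", pos = NULL) {
  n_sites <- if (length(strings)) nchar(strings[1L]) else 0L
  chars <- do.call(rbind, strsplit(strings, ""))
  anc_chars <- if (is.null(ancestral)) rep(NA_character_, n_sites)
               else strsplit(ancestral, "")[[1L]]
  alleles <- lapply(seq_len(n_sites), function(j)
    sort(unique(c(chars[, j], anc_chars[j][!is.na(anc_chars[j])]))))
  geno <- vapply(seq_len(n_sites), function(j)
    match(chars[, j], alleles[[j]]), integer(length(strings)))
  if (length(strings) == 1L) geno <- matrix(geno, nrow = 1L)
  sites <- data.frame(chrom = rep(chrom, n_sites),
                      pos = pos %||% seq_len(n_sites),
                      ancestral = anc_chars, stringsAsFactors = FALSE)
  sites$alleles <- alleles
  haplotype_matrix(geno, sites, populations = populations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small constant-size simulated data set with everything polarized.
sim_fixture <- function(seed, n = 12L, N0 = 20000, L = 10000L,
                        mu = 6.59e-10, gen_time = 30.8) {
  m <- demographic_model("constant", N0 = N0, mu = mu,
                         gen_time = gen_time, L = L)
  tree <- simulate_genealogy(m, n, seed = seed)
  drop_mutations(tree, m, seed = seed + 1L)
}

# A star genealogy of known age (generations): n tips radiating from the
# root, the idealized shape of a sudden expansion.
star_tree <- function(n, depth_gen) {
  tree <- structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                         edge.length = rep(depth_gen, n),
                         tip.label = paste0("hap", seq_len(n)),
                         Nnode = 1L), class = "phylo")
  attr(tree, "tip_populations") <- stats::setNames(rep("star", n),
                                                   tree$tip.label)
  attr(tree, "tmrca_gen") <- depth_gen
  tree
}

# Brute-force gamete enumerator: distinct observed two-site combinations
# among complete cases of the given samples (the independent oracle for
# d_prime / gamete_count equivalence checks).
brute_gametes <- function(x, i, j, samples = x$samples) {
  g <- x$geno[samples, c(i, j), drop = FALSE]
  g <- g[!is.na(g[, 1L]) & !is.na(g[, 2L]), , drop = FALSE]
  nrow(unique(g))
}

# Donor pair for a detectable recombinant: A derived where B is ancestral
# at some left-of-breakpoint site i, and the reverse at a right site j.
# The chimera then pairs both derived alleles, which cannot pre-exist on a
# recombination-free genealogy, forcing 4 gametes at (i, j).
find_crossing_donors <- function(x, bp) {
  M <- x$geno == 2L
  n <- nrow(M)
  right <- (bp + 1L):ncol(M)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    li <- which(M[a, 1:bp] & !M[b, 1:bp])
    ri <- which(!M[a, right] & M[b, right]) + bp
    if (length(li) && length(ri))
      return(list(a = x$samples[a], b = x$samples[b],
                  i = max(li), j = min(ri)))
  }
  NULL
}

# Random biallelic two-population matrix for property tests.
random_biallelic <- function(n_samples, n_sites, p_missing = 0) {
  geno <- matrix(sample(1:2, n_samples * n_sites, replace = TRUE),
                 n_samples, n_sites)
  if (p_missing > 0)
    geno[stats::runif(length(geno)) < p_missing] <- NA_integer_
  sites <- data.frame(chrom = rep("chr1", n_sites), pos = seq_len(n_sites),
                      ancestral = rep("0", n_sites))
  sites$alleles <- rep(list(c("0", "1")), n_sites)
  haplotype_matrix(geno, sites,
                   populations = rep(c("A", "B"), length.out = n_samples))
}
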