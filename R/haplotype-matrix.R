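# The haplotype_matrix container: haploid samples x SNP sites.

#' Construct a haplotype matrix
#'
#' The central container of the package: an `n_samples x n_sites` matrix of
#' allele indices over phased haploid chromosomes (e.g. male X chromosomes),
#' together with site metadata (chromosome, 1-based position, allele symbols,
#' ancestral state) and per-sample population labels.
#'
#' @param geno Integer matrix, samples in rows, sites in columns. Entries are
#'   1-based indices into the corresponding site's allele vector; `NA` marks a
#'   missing call. Row names, if present, are used as sample identifiers.
#' @param sites A `data.frame` with one row per site and columns `chrom`,
#'   `pos` (1-based physical coordinate), optional `id`, optional `ancestral`
#'   (allele symbol or `NA` for unknown), and a list column `alleles` of
#'   character vectors (ordered allele symbols).
#' @param populations Character vector of population labels, one per sample
#'   (recycled if length 1), or `NULL` for a single unnamed population.
#' @param samples Optional character vector of sample names, overriding
#'   `rownames(geno)`.
#'
#' @return An object of class `haplotype_matrix`: a list with elements
#'   `geno`, `sites`, `samples`, `populations`. Sites are stored sorted by
#'   `(chrom, pos)`.
#'
#' @details Positions must be strictly increasing within a chromosome.
#'   The ancestral symbol, where given, must be one of the site's alleles;
#'   use `NA` (printed as "unknown") otherwise.
#'
#' @examples
#' sites <- data.frame(chrom = "chrX", pos = c(100L, 200L))
#' sites$alleles <- list(c("A", "G"), c("C", "T"))
#' sites$ancestral <- c("A", "C")
#' hm <- haplotype_matrix(rbind(s1 = c(1L, 1L), s2 = c(2L, 2L)), sites,
#'                        populations = c("CEU", "YRI"))
#' hm
#' @export
haplotype_matrix <- function(geno, sites, populations = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(samples)) samples <- rownames(geno)
  if (is.null(samples)) samples <- paste0("hap", seq_len(nrow(geno)))
  if (anyDuplicated(samples)) stop_("duplicate sample names")
  if (length(samples) != nrow(geno))
    stop_("length(samples) != nrow(geno)")
  sites <- as.data.frame(sites)
  if (!all(c("chrom", "pos", "alleles") %in% names(sites)))
    stop_("sites needs columns chrom, pos, alleles")
  if (is.null(sites$id)) sites$id <- rep(NA_character_, nrow(sites))
  if (is.null(sites$ancestral))
    sites$ancestral <- rep(NA_character_, nrow(sites))
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (nrow(sites) != ncol(geno)) stop_("nrow(sites) != ncol(geno)")
  if (nrow(sites) && any(sites$pos < 1L)) stop_("site positions must be >= 1")
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[, ord, drop = FALSE]
  rownames(sites) <- NULL
  if (nrow(sites) > 1L) {
    same <- sites$chrom[-1L] == sites$chrom[-nrow(sites)]
    if (any(same & diff(sites$pos) <= 0L))
      stop_("site positions must be strictly increasing within a chromosome")
  }
  for (j in seq_len(nrow(sites))) {
    al <- sites$alleles[[j]]
    if (!length(al)) stop_("site %d has an empty allele list", j)
    g <- geno[, j]
    bad <- !is.na(g) & (g < 1L | g > length(al))
    if (any(bad))
      stop_("allele index out of range at site %d (sample %s)",
            j, samples[which(bad)[1L]])
    anc <- sites$ancestral[[j]]
    if (!is.na(anc) && !anc %in% al)
      stop_("ancestral allele '%s' not among alleles of site %d", anc, j)
  }
  if (is.null(populations)) populations <- "pop1"
  populations <- rep_len(as.character(populations), length(samples))
  names(populations) <- samples
  dimnames(geno) <- list(samples, NULL)
  structure(list(geno = geno, sites = sites, samples = samples,
                 populations = populations),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haploid samples x %d sites\n",
              n_samples(x), n_sites(x)))
  pops <- table(x$populations)
  cat("populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$geno))
  if (nmiss) cat(sprintf("missing calls: %d\n", nmiss))
  nanc <- sum(!is.na(x$sites$ancestral))
  cat(sprintf("ancestral state known at %d/%d sites\n", nanc, n_sites(x)))
  invisible(x)
}

#' @rdname haplotype_matrix
#' @param x A `haplotype_matrix`.
#' @export
n_samples <- function(x) nrow(x$geno)

#' @rdname haplotype_matrix
#' @export
n_sites <- function(x) ncol(x$geno)

#' Subset a haplotype matrix
#'
#' @param x A `haplotype_matrix`.
#' @param i Sample selector (names, indices or logical).
#' @param j Site selector (indices or logical).
#' @param ... Ignored.
#' @return A `haplotype_matrix` over the selected samples and sites.
#' @export
`[.haplotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_sites(x))
  if (is.character(i)) i <- match(i, x$samples)
  i <- seq_len(n_samples(x))[i]
  haplotype_matrix(x$geno[i, j, drop = FALSE],
                   x$sites[j, , drop = FALSE],
                   populations = x$populations[i],
                   samples = x$samples[i])
}

#' Ancestral allele indices
#'
#' Index of the ancestral allele within each site's allele vector, `NA` where
#' the ancestral state is unknown.
#'
#' @param x A `haplotype_matrix`.
#' @return Integer vector of length `n_sites(x)`.
#' @export
ancestral_index <- function(x) {
  vapply(seq_len(n_sites(x)), function(j) {
    anc <- x$sites$ancestral[[j]]
    if (is.na(anc)) NA_integer_ else match(anc, x$sites$alleles[[j]])
  }, integer(1L))
}

#' Haplotype key strings
#'
#' Collapses each sample's alleles over a set of sites into a single string
#' key (allele indices separated by "/"; missing as "."), used for counting
#' distinct haplotypes.
#'
#' @param x A `haplotype_matrix`.
#' @param sites Site indices (default all).
#' @param samples Sample selector (default all).
#' @param complete_only Drop samples with any missing call over `sites`.
#' @return Named character vector (names = sample ids).
#' @export
hap_keys <- function(x, sites = seq_len(n_sites(x)),
                     samples = x$samples, complete_only = TRUE) {
  g <- x$geno[samples, sites, drop = FALSE]
  if (complete_only) {
    keep <- rowSums(is.na(g)) == 0L
    g <- g[keep, , drop = FALSE]
  }
  keys <- apply(g, 1L, function(r) paste(ifelse(is.na(r), ".", r),
                                         collapse = "/"))
  if (!nrow(g)) keys <- character(0)
  keys
}

#' Count distinct haplotypes over a set of sites
#'
#' @inheritParams hap_keys
#' @return Number of distinct complete-case haplotypes.
#' @export
count_haplotypes <- function(x, sites = seq_len(n_sites(x)),
                             samples = x$samples) {
  length(unique(hap_keys(x, sites, samples)))
}

#' Haplotypes as allele-symbol strings
#'
#' One string per sample, concatenating allele symbols over the selected
#' sites ("?" for missing). The symbol representation feeds the network and
#' alignment-export code.
#'
#' @inheritParams hap_keys
#' @return Named character vector of sequences.
#' @export
hap_strings <- function(x, sites = seq_len(n_sites(x)), samples = x$samples) {
  g <- x$geno[samples, sites, drop = FALSE]
  al <- x$sites$alleles[sites]
  out <- vapply(seq_len(nrow(g)), function(i) {
    sym <- vapply(seq_along(sites), function(k) {
      a <- g[i, k]
      if (is.na(a)) "?" else al[[k]][a]
    }, character(1L))
    paste(sym, collapse = "")
  }, character(1L))
  names(out) <- rownames(g)
  out
}

#' Ancestral haplotype string over selected sites
#' @inheritParams hap_keys
#' @return Single string, with "?" where the ancestral state is unknown.
#' @export
ancestral_string <- function(x, sites = seq_len(n_sites(x))) {
  anc <- x$sites$ancestral[sites]
  paste(ifelse(is.na(anc), "?", anc), collapse = "")
}
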