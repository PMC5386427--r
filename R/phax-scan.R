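# PHAX detection: pairwise LD (|D'|), pooled gamete counts with ancestral
# inclusion, greedy block scan, genomic candidate filters and ranking.

#' Lewontin's |D'| between two sites within one population
#'
#' Computed on complete-case haploid chromosomes of a single population.
#' For a biallelic, polymorphic pair, `D = p_AB - p_A p_B` is normalized by
#' its maximum attainable magnitude given the allele frequencies:
#' `D_max = min(p_A p_b, p_a p_B)` when `D > 0`, `min(p_A p_B, p_a p_b)`
#' when `D < 0`.
#'
#' @param x A [haplotype_matrix].
#' @param i,j Distinct site indices.
#' @param population Population label.
#' @return `|D'|` in `[0, 1]`, or `NA` ("undefined") if either site is
#'   monomorphic in the population, has more than two alleles there, or
#'   fewer than two complete haplotypes remain.
#' @examples
#' # complete LD: only two of the four gametes observed
#' sites <- data.frame(chrom = "chrX", pos = c(1L, 2L))
#' sites$alleles <- list(c("A", "a"), c("B", "b"))
#' g <- rbind(matrix(1L, 5, 2), matrix(2L, 5, 2))
#' d_prime(haplotype_matrix(g, sites), 1, 2, "pop1")  # 1
#' @export
d_prime <- function(x, i, j, population) {
  if (i == j) stop_("i and j must differ")
  keep <- x$populations == population
  if (!any(keep)) stop_("unknown population: %s", population)
  g <- x$geno[keep, c(i, j), drop = FALSE]
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (nrow(g) < 2L) return(NA_real_)
  ai <- sort(unique(g[, 1L])); aj <- sort(unique(g[, 2L]))
  if (length(ai) != 2L || length(aj) != 2L) return(NA_real_)
  pA <- mean(g[, 1L] == ai[1L]); pB <- mean(g[, 2L] == aj[1L])
  pAB <- mean(g[, 1L] == ai[1L] & g[, 2L] == aj[1L])
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(0)
  val <- min(1, abs(D) / dmax)
  # snap float noise at the boundaries: |D'| = 1 is a discrete statement
  # (a missing gamete class), not a continuous one
  if (val > 1 - 1e-9) val <- 1
  if (val < 1e-12) val <- 0
  val
}

#' Pooled two-site gamete count with ancestral inclusion
#'
#' Number of distinct two-site allele combinations among complete-case
#' chromosomes pooled over all populations, optionally counting the
#' ancestral combination as an extra gamete when both sites have a known
#' ancestral state and the combination was not itself sampled. Under the
#' four-gamete logic, a biallelic pair reaching 4 implies recombination or
#' recurrent mutation in its history.
#'
#' @inheritParams d_prime
#' @param include_ancestral Count the (ancestral_i, ancestral_j) pair,
#'   observed or not (default `TRUE`).
#' @return Integer gamete count.
#' @export
gamete_count <- function(x, i, j, include_ancestral = TRUE) {
  if (i == j) stop_("i and j must differ")
  g <- x$geno[, c(i, j), drop = FALSE]
  g <- g[stats::complete.cases(g), , drop = FALSE]
  combos <- unique(paste(g[, 1L], g[, 2L]))
  if (include_ancestral) {
    anc <- ancestral_index(x)[c(i, j)]
    if (!anyNA(anc)) combos <- union(combos, paste(anc[1L], anc[2L]))
  }
  length(combos)
}

# A site pair is scan-compatible when (a) |D'| is 1 (or undefined, a vacuous
# pass) in every scan population and (b) the pooled gamete count, ancestral
# haplotype included, stays below the "all combinations" ceiling: <= 3 for a
# biallelic pair, <= (k_i * k_j - 1) in general.
pair_compatible <- function(x, i, j, scan_pops, dprime_tol = 1e-9) {
  for (p in scan_pops) {
    dp <- d_prime_pooled(x, i, j, p)
    if (!is.na(dp) && dp < 1 - dprime_tol) return(FALSE)
  }
  ki <- n_observed_alleles(x, i)
  kj <- n_observed_alleles(x, j)
  gamete_count(x, i, j, include_ancestral = TRUE) <= max(3L, ki * kj - 1L)
}

n_observed_alleles <- function(x, j) {
  g <- x$geno[, j]
  length(unique(g[!is.na(g)]))
}

# |D'| over a scan population that may pool several labels (e.g. JPT+CHB).
d_prime_pooled <- function(x, i, j, pop_labels) {
  keep <- x$populations %in% pop_labels
  if (!any(keep)) return(NA_real_)
  y <- x
  y$populations[keep] <- ".scanpool."
  d_prime(y, i, j, ".scanpool.")
}

#' Scan for PHAX blocks
#'
#' Identifies non-overlapping runs of at least `min_sites` adjacent SNPs in
#' which every within-run site pair shows (a) `|D'| = 1` (or undefined) in
#' each scan population and (b) at most three of the four possible two-site
#' haplotypes in the pooled sample, counting the ancestral haplotype whether
#' or not it was itself sampled. Runs are grown by greedy left-to-right
#' maximal extension, independently per chromosome, so the output is
#' deterministic and blocks never overlap.
#'
#' @param x A [haplotype_matrix] with every sample assigned a population.
#' @param scan_populations Named list defining the scan partition: each
#'   element is a character vector of population labels pooled into one scan
#'   population (e.g. `list(CEU = "CEU", YRI = "YRI", ASN = c("JPT","CHB"))`).
#'   Default: every population label is its own scan population. Every
#'   sample must fall in exactly one scan population.
#' @param min_sites Minimum number of SNPs per block (default 3).
#' @param pair_mode `"all"` (default) requires every within-run pair to pass;
#'   `"adjacent"` tests only consecutive pairs.
#' @return A `data.frame` of class `phax_blocks`: one row per block with
#'   `chrom`, `start`, `end` (1-based inclusive SNP coordinates), `span_bp`
#'   (`end - start + 1`), `n_sites`, a list column `site_idx`, and one
#'   `haps_<pop>` column per population label with the distinct-haplotype
#'   count over the block's sites.
#' @export
scan_blocks <- function(x, scan_populations = NULL, min_sites = 3L,
                        pair_mode = c("all", "adjacent")) {
  pair_mode <- match.arg(pair_mode)
  if (is.null(scan_populations)) {
    labs <- unique(unname(x$populations))
    scan_populations <- stats::setNames(as.list(labs), labs)
  }
  if (!length(scan_populations)) stop_("empty scan population partition")
  cover <- unlist(scan_populations)
  if (anyDuplicated(cover))
    stop_("population label assigned to more than one scan population")
  uncovered <- setdiff(unique(x$populations), cover)
  if (length(uncovered))
    stop_("samples of population(s) %s not assigned to any scan population",
          paste(uncovered, collapse = ", "))
  blocks <- list()
  for (chr in unique(x$sites$chrom)) {
    idx <- which(x$sites$chrom == chr)
    n <- length(idx)
    if (n < min_sites) next
    cache <- new.env(parent = emptyenv())
    ok <- function(a, b) {
      key <- paste0(a, ",", b)
      v <- cache[[key]]
      if (is.null(v)) {
        v <- pair_compatible(x, idx[a], idx[b], scan_populations)
        cache[[key]] <- v
      }
      v
    }
    s <- 1L
    while (s <= n - min_sites + 1L) {
      e <- s
      repeat {
        if (e + 1L > n) break
        back <- if (pair_mode == "all") s:e else e
        if (!all(vapply(back, ok, logical(1L), b = e + 1L))) break
        e <- e + 1L
      }
      if (e - s + 1L >= min_sites) {
        blocks[[length(blocks) + 1L]] <- idx[s:e]
        s <- e + 1L
      } else s <- s + 1L
    }
  }
  block_table(x, blocks)
}

block_table <- function(x, site_idx_list) {
  pops <- sort(unique(unname(x$populations)))
  rows <- lapply(site_idx_list, function(si) {
    pos <- x$sites$pos[si]
    row <- data.frame(chrom = x$sites$chrom[si[1L]],
                      start = min(pos), end = max(pos),
                      span_bp = max(pos) - min(pos) + 1L,
                      n_sites = length(si), stringsAsFactors = FALSE)
    for (p in pops)
      row[[paste0("haps_", p)]] <-
        count_haplotypes(x, si, x$samples[x$populations == p])
    row
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               span_bp = integer(0), n_sites = integer(0))
  out$site_idx <- I(site_idx_list)
  class(out) <- c("phax_blocks", "data.frame")
  out
}

#' Apply genomic candidate filters to PHAX blocks
#'
#' Flags each block for the four candidate criteria used to pick blocks
#' worth resequencing: (i) free of genes, (ii) separated from the nearest
#' gene on each side by at least one recombination hotspot lying strictly in
#' the gap (vacuously satisfied on a side with no gene on the chromosome),
#' (iii) free of segmental duplications, and (iv) fully contained in a
#' region with an outgroup ortholog.
#'
#' @param blocks A `phax_blocks` table from [scan_blocks()].
#' @param genes,hotspots,segdups,ortholog_regions `GRanges` from
#'   [read_intervals()] (same assembly as the block coordinates). Any of
#'   them may be `NULL`, in which case the corresponding flag is `TRUE`.
#' @param keep_all Return all blocks with flags (`TRUE`) or only those
#'   passing every filter (default).
#' @return The block table with logical columns `gene_free`,
#'   `hotspot_separated`, `segdup_free`, `has_ortholog`, `pass`.
#' @export
filter_candidates <- function(blocks, genes = NULL, hotspots = NULL,
                              segdups = NULL, ortholog_regions = NULL,
                              keep_all = FALSE) {
  if (!nrow(blocks)) {
    for (f in c("gene_free", "hotspot_separated", "segdup_free",
                "has_ortholog", "pass")) blocks[[f]] <- logical(0)
    return(blocks)
  }
  bgr <- GenomicRanges::GRanges(blocks$chrom,
                                IRanges::IRanges(blocks$start, blocks$end))
  overlaps_any <- function(gr) {
    if (is.null(gr)) return(rep(FALSE, nrow(blocks)))
    GenomicRanges::countOverlaps(bgr, gr) > 0L
  }
  blocks$gene_free <- !overlaps_any(genes)
  blocks$segdup_free <- !overlaps_any(segdups)
  blocks$has_ortholog <- if (is.null(ortholog_regions))
    rep(TRUE, nrow(blocks))
  else GenomicRanges::countOverlaps(bgr, ortholog_regions,
                                    type = "within") > 0L
  blocks$hotspot_separated <- vapply(seq_len(nrow(blocks)), function(b)
    hotspot_separated(blocks$chrom[b], blocks$start[b], blocks$end[b],
                      genes, hotspots), logical(1L))
  blocks$pass <- blocks$gene_free & blocks$hotspot_separated &
    blocks$segdup_free & blocks$has_ortholog
  if (keep_all) blocks else blocks[blocks$pass, , drop = FALSE]
}

# On each side with a gene, at least one hotspot interval must lie strictly
# inside the gap between the block and the nearest gene on that side.
hotspot_separated <- function(chrom, bstart, bend, genes, hotspots) {
  if (is.null(genes)) return(TRUE)
  on_chr <- function(gr) {
    if (is.null(gr)) return(gr)
    gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  }
  g <- on_chr(genes); h <- on_chr(hotspots)
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  check_side <- function(gap_lo, gap_hi) {
    # gap is the open interval between nearest gene and block
    if (is.null(h) || !length(h)) return(FALSE)
    any(GenomicRanges::start(h) > gap_lo & GenomicRanges::end(h) < gap_hi)
  }
  left_genes <- ge < bstart
  ok_left <- if (!any(left_genes)) TRUE else
    check_side(max(ge[left_genes]), bstart)
  right_genes <- gs > bend
  ok_right <- if (!any(right_genes)) TRUE else
    check_side(bend, min(gs[right_genes]))
  ok_left && ok_right
}

#' Rank PHAX blocks by focal-population haplotype count
#'
#' Orders candidate blocks by the number of distinct haplotypes their SNPs
#' define among samples of a focal population (descending), the criterion
#' used to prioritize blocks for European-focused resequencing. Ties break
#' by more SNPs, then by leftmost coordinate, making the ranking
#' deterministic.
#'
#' @param blocks A `phax_blocks` table.
#' @param x The [haplotype_matrix] the blocks were scanned from.
#' @param focal_population Population label used for ranking.
#' @return `blocks` reordered, with a `haps_focal` column prepended.
#' @export
rank_blocks <- function(blocks, x, focal_population) {
  if (!focal_population %in% x$populations)
    stop_("unknown focal population: %s", focal_population)
  focal_samples <- x$samples[x$populations == focal_population]
  blocks$haps_focal <- vapply(blocks$site_idx, function(si)
    count_haplotypes(x, si, focal_samples), integer(1L))
  ord <- order(-blocks$haps_focal, -blocks$n_sites, blocks$chrom,
               blocks$start)
  blocks[ord, , drop = FALSE]
}
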