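test_that("d_prime matches hand-computed values and undefined cases", {
  # two gametes only: complete LD
  x <- hm_from_strings(c(rep("AB", 5), rep("ab", 5)))
  expect_equal(d_prime(x, 1, 2, "pop1"), 1)
  # counts AB=4, Ab=1, aB=1, ab=4: D = 0.4 - 0.25 = 0.15, Dmax = 0.25
  y <- hm_from_strings(c(rep("AB", 4), "Ab", "aB", rep("ab", 4)))
  expect_equal(d_prime(y, 1, 2, "pop1"), 0.6)
  # monomorphic second site -> undefined
  z <- hm_from_strings(c("AB", "aB", "AB"))
  expect_true(is.na(d_prime(z, 1, 2, "pop1")))
  expect_error(d_prime(y, 2, 2, "pop1"), "differ")
})

test_that("gamete counting honours ancestral-haplotype inclusion", {
  x4 <- hm_from_strings(c("00", "01", "10", "11"))
  expect_equal(gamete_count(x4, 1, 2), 4L)
  # three observed + unobserved ancestral 00 counts as a fourth
  x3 <- hm_from_strings(c("01", "10", "11"), ancestral = "00")
  expect_equal(gamete_count(x3, 1, 2, include_ancestral = TRUE), 4L)
  expect_equal(gamete_count(x3, 1, 2, include_ancestral = FALSE), 3L)
  # ancestral combination already observed adds nothing
  x3b <- hm_from_strings(c("00", "01", "11"), ancestral = "00")
  expect_equal(gamete_count(x3b, 1, 2, include_ancestral = TRUE), 3L)
})

test_that("|D'| = 1 iff at most 3 gametes, against the brute-force enumerator", {
  set.seed(11)
  checked <- 0L
  while (checked < 400L) {
    x <- random_biallelic(16L, 2L)
    samples <- x$samples[x$populations == "A"]
    dp <- d_prime(x, 1, 2, "A")
    if (is.na(dp)) next  # monomorphic in A: equivalence claim doesn't apply
    g <- brute_gametes(x, 1, 2, samples)
    expect_equal(dp == 1, g <= 3L,
                 info = sprintf("D'=%g gametes=%d", dp, g))
    checked <- checked + 1L
  }
})

test_that("runs below the minimum SNP count are not reported", {
  x <- hm_from_strings(c(rep("00", 5), rep("11", 5)), ancestral = "00")
  expect_equal(nrow(scan_blocks(x)), 0L)  # 2 perfectly linked sites only
})

test_that("recombination-free data yield one full block; a recombinant splits it", {
  sim <- sim_fixture(21, n = 10L)
  x <- sim$matrix
  skip_if(n_sites(x) < 6L)  # guaranteed by the chosen theta in practice
  blocks <- scan_blocks(x)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$n_sites, n_sites(x))
  # oracle: every within-block pair has <= 3 gametes
  pairs <- utils::combn(blocks$site_idx[[1]], 2L)
  for (p in seq_len(ncol(pairs)))
    expect_lte(brute_gametes(x, pairs[1L, p], pairs[2L, p]), 3L)

  # find donors where A is derived/B ancestral at a left site and the
  # reverse at a right site: the chimera then carries both derived alleles,
  # a combination that cannot pre-exist on a recombination-free genealogy,
  # so the spanning pair is forced to 4 gametes
  bp <- floor(n_sites(x) / 2)
  donors <- NULL
  for (a in x$samples) {
    for (b in x$samples) {
      ga <- x$geno[a, ]; gb <- x$geno[b, ]
      li <- which(ga[1:bp] == 2L & gb[1:bp] == 1L)
      ri <- which(ga[-(1:bp)] == 1L & gb[-(1:bp)] == 2L) + bp
      if (length(li) && length(ri)) {
        donors <- c(a, b)
        break
      }
    }
    if (!is.null(donors)) break
  }
  skip_if(is.null(donors))
  xr <- inject_recombinants(x, donors[1L], donors[2L], bp, n_copies = 2L)
  br <- scan_blocks(xr)
  expect_equal(gamete_count(xr, max(li), min(ri)), 4L)
  if (nrow(br)) for (k in seq_len(nrow(br)))
    expect_false(max(li) %in% br$site_idx[[k]] &&
                 min(ri) %in% br$site_idx[[k]])
})

test_that("scan output is deterministic and invariant to sample order", {
  sim <- sim_fixture(31, n = 10L)
  x <- sim$matrix
  b1 <- scan_blocks(x)
  perm <- sample(seq_len(n_samples(x)))
  xp <- x[perm, ]
  b2 <- scan_blocks(xp)
  expect_equal(b1$start, b2$start)
  expect_equal(b1$end, b2$end)
  expect_equal(b1$n_sites, b2$n_sites)
})

test_that("adding recombinants never enlarges a block", {
  set.seed(5)
  sim <- sim_fixture(41, n = 10L)
  x <- sim$matrix
  skip_if(n_sites(x) < 4L)
  sizes0 <- scan_blocks(x)$n_sites
  xr <- x
  for (k in 1:3) {
    d <- sample(x$samples, 2L)
    xr <- inject_recombinants(xr, d[1L], d[2L],
                              sample(n_sites(x) - 1L, 1L), n_copies = 1L)
    sizes <- scan_blocks(xr)$n_sites
    expect_lte(sum(sizes), sum(sizes0))
    sizes0 <- sizes
  }
})

test_that("candidate filters implement the four genomic criteria", {
  mk_gr <- function(s, e) GenomicRanges::GRanges("chrX",
                                                 IRanges::IRanges(s, e))
  blocks <- data.frame(chrom = "chrX", start = 30000L, end = 35000L,
                       span_bp = 5001L, n_sites = 4L)
  blocks$site_idx <- I(list(1:4))
  class(blocks) <- c("phax_blocks", "data.frame")
  # gene at 10-20 kb, hotspot at 25-26 kb: separated on the left,
  # vacuously on the right
  f <- filter_candidates(blocks, genes = mk_gr(10000, 20000),
                         hotspots = mk_gr(25000, 26000),
                         keep_all = TRUE)
  expect_true(f$gene_free)
  expect_true(f$hotspot_separated)
  expect_true(f$pass)
  # no hotspot in the gap -> fails criterion (ii)
  f2 <- filter_candidates(blocks, genes = mk_gr(10000, 20000),
                          hotspots = mk_gr(50000, 51000), keep_all = TRUE)
  expect_false(f2$hotspot_separated)
  # overlapping gene -> excluded
  f3 <- filter_candidates(blocks, genes = mk_gr(34000, 40000))
  expect_equal(nrow(f3), 0L)
  # inside a segmental duplication -> excluded
  f4 <- filter_candidates(blocks, segdups = mk_gr(20000, 40000),
                          keep_all = TRUE)
  expect_false(f4$segdup_free)
  # ortholog containment is required, overlap is not enough
  f5 <- filter_candidates(blocks, ortholog_regions = mk_gr(32000, 40000),
                          keep_all = TRUE)
  expect_false(f5$has_ortholog)
  f6 <- filter_candidates(blocks, ortholog_regions = mk_gr(29000, 36000),
                          keep_all = TRUE)
  expect_true(f6$has_ortholog)
})

test_that("blocks rank by focal haplotype count with stated tie-breaks", {
  # population F: block over sites 1-3 has 3 distinct haplotypes,
  # block over sites 4-6 has 2
  strings <- c("001000", "010000", "100000", "000011")
  x <- hm_from_strings(strings, populations = c("F", "F", "F", "G"))
  blocks <- data.frame(chrom = rep("chr1", 2), start = c(1L, 4L),
                       end = c(3L, 6L), span_bp = c(3L, 3L),
                       n_sites = c(3L, 3L))
  blocks$site_idx <- I(list(1:3, 4:6))
  class(blocks) <- c("phax_blocks", "data.frame")
  r <- rank_blocks(blocks, x, "F")
  expect_equal(r$start, c(1L, 4L))
  expect_equal(r$haps_focal, c(3L, 1L))
  expect_error(rank_blocks(blocks, x, "NOPE"), "NOPE")
  # equal counts: more sites first, then leftmost
  blocks2 <- blocks
  blocks2$site_idx <- I(list(1:2, 4:6))
  blocks2$n_sites <- c(2L, 3L)
  blocks2$end <- c(2L, 6L)
  x2 <- hm_from_strings(c("110110", "001001"), populations = "F")
  r2 <- rank_blocks(blocks2, x2, "F")
  expect_equal(r2$n_sites, c(3L, 2L))
  expect_equal(rank_blocks(blocks2[1L, ], x2, "F")$start, 1L)
})
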