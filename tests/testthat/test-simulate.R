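test_that("pairwise coalescence time matches the Kingman expectation", {
  set.seed(1)
  N <- 2000
  m <- demographic_model("constant", N0 = N, L = 100L)
  t2 <- replicate(3000, attr(simulate_genealogy(m, 2L), "tmrca_gen"))
  # T2 ~ Exp(1/N): mean N, sd N
  se <- N / sqrt(length(t2))
  expect_lt(abs(mean(t2) - N), 3 * se)
})

test_that("total branch length matches 2N * sum(1/i) for n = 10", {
  set.seed(2)
  N <- 1500
  m <- demographic_model("constant", N0 = N, L = 100L)
  tot <- replicate(2000, sum(simulate_genealogy(m, 10L)$edge.length))
  expected <- 2 * N * sum(1 / 1:9)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("simulation is deterministic given the seed", {
  m <- demographic_model("constant", N0 = 5000, L = 1000L)
  t1 <- simulate_genealogy(m, 8L, seed = 99)
  t2 <- simulate_genealogy(m, 8L, seed = 99)
  expect_identical(t1$edge, t2$edge)
  expect_identical(t1$edge.length, t2$edge.length)
  s1 <- drop_mutations(t1, m, seed = 100)
  s2 <- drop_mutations(t2, m, seed = 100)
  expect_identical(s1$matrix$geno, s2$matrix$geno)
  expect_identical(s1$matrix$sites$pos, s2$matrix$sites$pos)
})

test_that("segregating sites match theta * a_n and the SFS matches theta/i", {
  set.seed(3)
  N <- 5000; L <- 10000L; n <- 10L
  m <- demographic_model("constant", N0 = N, L = L)
  theta <- 2 * N * m$mu * m$gen_time * L
  n_rep <- 2000L
  S <- xi1 <- xi2 <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- drop_mutations(simulate_genealogy(m, n), m)
    x <- sim$matrix
    S[r] <- n_sites(x)
    dc <- colSums(x$geno == 2L)
    xi1[r] <- sum(dc == 1L)
    xi2[r] <- sum(dc == 2L)
  }
  a_n <- sum(1 / 1:(n - 1))
  expect_lt(abs(mean(S) - theta * a_n), 3 * sd(S) / sqrt(n_rep))
  expect_lt(abs(mean(xi1) - theta), 3 * sd(xi1) / sqrt(n_rep))
  expect_lt(abs(mean(xi2) - theta / 2), 3 * sd(xi2) / sqrt(n_rep))
})

test_that("every site's derived carriers form a clade of the true tree", {
  sim <- sim_fixture(6, n = 10L)
  tree <- sim$tree
  x <- sim$matrix
  for (s in seq_len(n_sites(x))) {
    carriers <- which(x$geno[, s] == 2L)
    node <- sim$tree$edge[sim$mutations$edge[s], 2L]
    tips <- if (node <= 10L) node else
      unlist(phangorn::Descendants(tree, node, "tips"))
    expect_setequal(carriers, tips)
  }
})

test_that("recombinant injection behaves at the edges", {
  x <- hm_from_strings(c("0011", "1100", "0011"), ancestral = "0000")
  same <- inject_recombinants(x, "hap1", "hap3", 2L, n_copies = 1L)
  # identical donors: chimera equals both, no new gamete anywhere
  for (i in 1:3) for (j in (i + 1):4) if (i < j)
    expect_equal(gamete_count(same, i, j), gamete_count(x, i, j))
  expect_identical(inject_recombinants(x, "hap1", "hap2", 2L, 0L), x)
  expect_error(inject_recombinants(x, "hap1", "hap2", 4L), "breakpoint")
  expect_error(inject_recombinants(x, "hap1", "nope", 2L), "donor")
  mix <- inject_recombinants(x, "hap1", "hap2", 2L, n_copies = 2L,
                             population = "REC")
  expect_equal(n_samples(mix), 5L)
  expect_equal(unname(mix$geno[4L, ]), c(1L, 1L, 1L, 1L))  # 00 then 00
  expect_equal(sum(mix$populations == "REC"), 2L)
})

test_that("expansion model uses the reduced ancestral size", {
  set.seed(8)
  # strong expansion: most coalescence should pile up just beyond onset
  m <- demographic_model("expansion", N0 = 1e6, t_onset = 3080,
                         factor = 1e4, L = 100L)
  onset_gen <- 3080 / 30.8
  t2 <- replicate(500, attr(simulate_genealogy(m, 2L), "tmrca_gen"))
  # almost no coalescence before onset (rate 1/N0 is negligible), and the
  # ancestral size N0/f = 100 coalesces fast after it
  expect_gt(mean(t2 > onset_gen), 0.95)
  expect_lt(mean(t2), onset_gen + 10 * 100)
  expect_error(demographic_model("expansion", N0 = 100, t_onset = 10,
                                 factor = 0.5), "exceed 1")
})

test_that("the study fixture shows the expected continental signatures", {
  fx <- make_study_fixture(seed = 321, n_per_deme = 12L,
                           lengths = c(8000L, 36857L))
  expect_named(fx, c("block8000", "block36857"))
  x <- fx$block36857$matrix
  expect_equal(n_samples(x), 12L * 12L)
  # round-trips through the VCF writer/reader
  vcf <- tempfile(fileext = ".vcf")
  pops <- tempfile(fileext = ".tsv")
  write_haplotypes(x, vcf, populations_file = pops)
  y <- read_haplotypes(vcf, populations_file = pops)
  expect_identical(unname(y$geno), unname(x$geno))
  expect_identical(y$populations, x$populations)
  # star-like European genealogies: D more negative than the constant-size
  # African deme, and Africa-Europe phi_st exceeds within-Europe phi_st
  d_eur <- tajimas_d(x, samples = x$samples[x$populations == "CEU"])$statistic
  d_afr <- tajimas_d(x, samples = x$samples[x$populations == "YRI"])$statistic
  expect_lt(d_eur, d_afr + 1e-9)
  ps <- phi_st(x, populations = c("YRI", "CEU", "DEN"))
  expect_gt(ps$phi["YRI", "CEU"], ps$phi["CEU", "DEN"])
})
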