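# Independent re-implementations of the published constants serve as
# oracles; they are deliberately written from the formulas, not by calling
# the package.

oracle_tajima <- function(n, S, pi) {
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

oracle_fu_li <- function(n, eta, eta_s) {
  an <- sum(1 / 1:(n - 1)); bn <- sum(1 / (1:(n - 1))^2)
  cn <- 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  (eta - an * eta_s) / sqrt(uD * eta + vD * eta^2)
}

test_that("Tajima's D matches the independent constant evaluation", {
  x <- hm_from_strings(c("0000", "0001", "0011", "0111"), ancestral = "0000")
  td <- tajimas_d(x)
  expect_equal(td$S, 3L)       # first column is monomorphic
  expect_equal(td$pi, 10 / 6)
  expect_equal(td$statistic, oracle_tajima(4, 3, 10 / 6))
  # no polymorphism: undefined
  x0 <- hm_from_strings(rep("0000", 4))
  expect_true(is.na(tajimas_d(x0)$statistic))
})

test_that("Fu's Fs matches exhaustive Ewens-formula summation at n = 5", {
  # unsigned Stirling numbers |s(5,k)|, k = 1..5 (known closed values)
  s5 <- c(24, 50, 35, 10, 1)
  x <- hm_from_strings(c("100", "010", "001", "000", "000"),
                       ancestral = "000")
  fs <- fu_fs(x)
  theta <- fs$pi
  expect_equal(fs$k, 4L)
  probs <- s5 * theta^(1:5) / prod(theta + 0:4)
  expect_equal(sum(probs), 1, tolerance = 1e-12)  # Ewens sanity
  Sp <- sum(probs[4:5])
  expect_equal(fs$statistic, log(Sp / (1 - Sp)), tolerance = 1e-10)
  # pi = 0: undefined
  expect_true(is.na(fu_fs_stat(5, 1, 0)))
})

test_that("Fu & Li's D matches the oracle and has the forced sign", {
  x <- hm_from_strings(c("000011", "000011", "110000", "110011",
                         "000000", "000111"), ancestral = "000000")
  fl <- fu_li_d(x)
  expect_equal(fl$statistic, oracle_fu_li(6, fl$eta, fl$eta_s))
  # eta_s = 0 with eta > 0 forces a positive value
  y <- hm_from_strings(c("11", "11", "00", "00"), ancestral = "00")
  expect_gt(fu_li_d(y)$statistic, 0)
  expect_true(is.na(fu_li_d_stat(6, 0, 0)))
  # unknown ancestral states are refused
  z <- hm_from_strings(c("10", "01", "00", "11"))
  expect_error(fu_li_d(z), "ancestral")
})

test_that("log-space Stirling numbers survive large n without overflow", {
  # spot-check against exact small values and a large-n sanity bound
  expect_equal(exp(phaxkit:::log_stirling_row(5)), c(24, 50, 35, 10, 1),
               tolerance = 1e-10)
  big <- phaxkit:::log_stirling_row(240)
  expect_true(all(is.finite(big)))
  # sum_k |s(n,k)| = n!, i.e. logsumexp equals lfactorial(n)
  expect_equal(phaxkit:::logsumexp(big), lfactorial(240), tolerance = 1e-8)
})

test_that("neutrality statistics are calibrated under constant size", {
  set.seed(99)
  m <- demographic_model("constant", N0 = 10000, L = 12300L)  # theta ~ 5
  n_rep <- 400L
  d <- fl <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- drop_mutations(simulate_genealogy(m, 20L), m)
    x <- sim$matrix
    d[r] <- if (n_sites(x) >= 1L) tajimas_d(x)$statistic else NA
    fl[r] <- if (n_sites(x) >= 1L) fu_li_d(x)$statistic else NA
  }
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.5)
  expect_lt(abs(mean(fl, na.rm = TRUE)), 0.5)
})

test_that("expansion drives Tajima's D, Fu's Fs and Fu & Li's D negative", {
  set.seed(77)
  m <- demographic_model("expansion", N0 = 50000, t_onset = 15000,
                         factor = 100, L = 20000L)
  n_rep <- 150L
  d <- fs <- fl <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- drop_mutations(simulate_genealogy(m, 20L), m)
    x <- sim$matrix
    if (n_sites(x) < 2L) { d[r] <- fs[r] <- fl[r] <- NA; next }
    d[r] <- tajimas_d(x)$statistic
    f <- fu_fs(x)$statistic
    fs[r] <- if (is.finite(f)) f else NA
    fl[r] <- fu_li_d(x)$statistic
  }
  expect_lt(mean(d, na.rm = TRUE), 0)
  expect_lt(mean(fs, na.rm = TRUE), 0)
  expect_lt(mean(fl, na.rm = TRUE), 0)
})

test_that("fixed-S significance rejects at close to the nominal level", {
  set.seed(123)
  m <- demographic_model("constant", N0 = 10000, L = 12300L)
  n_rep <- 150L
  null_cache <- new.env()
  rej <- logical(0)
  for (r in seq_len(n_rep)) {
    sim <- drop_mutations(simulate_genealogy(m, 12L), m)
    x <- sim$matrix
    S <- n_sites(x)
    if (S < 1L) next
    key <- as.character(S)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- neutrality_null(12L, S, 200L)$tajima_d
    D <- tajimas_d(x)$statistic
    p <- min(1, 2 * min(mean(null_cache[[key]] <= D),
                        mean(null_cache[[key]] >= D)))
    rej <- c(rej, p < 0.05)
  }
  # conservative test: rejection rate should not exceed 5% by more than
  # 3 binomial standard errors
  expect_lt(mean(rej), 0.05 + 3 * sqrt(0.05 * 0.95 / length(rej)))
})
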