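test_that("a single haplotype gives a single node and no edges", {
  net <- build_mj_network("0101")
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(net$cost, 0L)
  expect_error(build_mj_network(character(0)), "zero")
})

test_that("the {000, 011, 101} triplet gets its optimal Steiner median", {
  net <- build_mj_network(c("000", "011", "101"))
  expect_true("001" %in% net$nodes$id)
  expect_equal(net$cost, 3L)
  expect_equal(count_reticulations(net), 0L)
  expect_false(net$nodes$sampled[net$nodes$id == "001"])
  # exhaustive Steiner search over all 8 binary vectors: adding any set of
  # extra nodes cannot beat a total MST cost of 3
  all_vec <- do.call(paste0, expand.grid(0:1, 0:1, 0:1))
  base <- c("000", "011", "101")
  mst_cost <- function(nodes) {
    d <- as.matrix(stats::dist(do.call(rbind, lapply(strsplit(nodes, ""),
                                                     as.integer)),
                               method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                             mode = "undirected")
    sum(igraph::E(igraph::mst(g))$weight)
  }
  extras <- setdiff(all_vec, base)
  best <- min(vapply(0:length(extras), function(k) {
    if (k == 0) return(mst_cost(base))
    min(apply(utils::combn(extras, k), 2L,
              function(e) mst_cost(c(base, e))))
  }, numeric(1L)))
  expect_equal(best, 3)
  expect_equal(net$cost, best)
})

test_that("infinite-sites tree data give a tree-shaped network of true cost", {
  for (seed in c(2, 14, 29)) {
    sim <- sim_fixture(seed, n = 12L)
    x <- sim$matrix
    haps <- hap_strings(x)
    net <- build_mj_network(haps, ancestral = ancestral_string(x))
    expect_equal(count_reticulations(net), 0L)
    expect_equal(net$cost, nrow(sim$mutations))
  }
})

test_that("cycle rank counts reticulations", {
  # any tree has rank 0 (covered above); a sampled square cycle has rank 1
  net <- build_mj_network(c("00", "01", "11", "10"))
  expect_equal(count_reticulations(net), 1L)
  expect_equal(nrow(net$edges) - nrow(net$nodes) + 1L, 1L)
  # two independent squares over disjoint coordinates
  sq2 <- c("0000", "0100", "1100", "1000", "0011", "0010", "0001")
  net2 <- build_mj_network(sq2)
  expect_equal(count_reticulations(net2),
               nrow(net2$edges) - nrow(net2$nodes) + 1L)
})

test_that("a recombinant haplotype introduces a reticulation", {
  sim <- sim_fixture(14, n = 12L)
  x <- sim$matrix
  bp <- floor(n_sites(x) / 2)
  donors <- NULL
  for (a in x$samples) {
    for (b in x$samples) {
      ga <- x$geno[a, ]; gb <- x$geno[b, ]
      if (any(ga[1:bp] == 2L & gb[1:bp] == 1L) &&
          any(ga[-(1:bp)] == 1L & gb[-(1:bp)] == 2L)) {
        donors <- c(a, b); break
      }
    }
    if (!is.null(donors)) break
  }
  expect_false(is.null(donors))
  xr <- inject_recombinants(x, donors[1L], donors[2L], bp)
  net <- build_mj_network(hap_strings(xr), ancestral = ancestral_string(xr))
  expect_gte(count_reticulations(net), 1L)
})

test_that("network construction is deterministic and order-invariant", {
  sim <- sim_fixture(8, n = 10L)
  haps <- hap_strings(sim$matrix)
  n1 <- build_mj_network(haps)
  n2 <- build_mj_network(rev(haps))
  expect_identical(n1$nodes, n2$nodes)
  expect_identical(n1$edges$from, n2$edges$from)
  expect_identical(n1$cost, n2$cost)
})

test_that("node bookkeeping: frequencies, population counts, ancestral flag", {
  haps <- c("00", "00", "01", "11")
  net <- build_mj_network(haps, populations = c("A", "A", "B", "B"),
                          ancestral = "10")
  expect_equal(sum(net$nodes$freq), 4L)
  expect_equal(net$nodes$freq[net$nodes$id == "00"], 2L)
  expect_true(net$nodes$ancestral[net$nodes$id == "10"])
  expect_equal(net$nodes$freq[net$nodes$id == "10"], 0L)
  expect_equal(unname(net$pop_counts["00", "A"]), 2L)
  expect_equal(unname(net$pop_counts["01", "B"]), 1L)
  # every edge changes at least one site
  expect_true(all(net$edges$length >= 1L))
  # igraph export carries the attributes
  g <- as_igraph(net)
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes$id))
  expect_equal(igraph::vertex_attr(g, "n_A")[igraph::V(g)$name == "00"], 2L)
})
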