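# Rho-statistic dating of haplotype clusters on a network.

#' Years-per-mutation scaling constant
#'
#' Converts a per-site per-year mutation rate and a locus length into the
#' scaled rate used by rho dating: `1 / (mu * L)` years per mutation,
#' truncated to whole years (the convention these scaled rates are quoted
#' in).
#'
#' @param mu Mutation rate per site per year (> 0).
#' @param L Number of called nucleotides in the locus (> 0).
#' @return Years per mutation (whole years).
#' @examples
#' years_per_mutation(6.59e-10, 36857)  # 41171
#' @export
years_per_mutation <- function(mu, L) {
  if (mu <= 0 || L <= 0) stop_("mu and L must be positive")
  trunc(1 / (mu * L))
}

#' Date a haplotype cluster with the rho statistic
#'
#' `rho` is the mean mutational distance from the root haplotype to each
#' sampled chromosome of the cluster (each chromosome counts individually,
#' so haplotype frequency weights the distances). Its standard error
#' follows Saillard: on the rooted cluster tree,
#' `sigma_rho^2 = sum_mutations (n_b / n)^2`, where `n_b` is the number of
#' cluster chromosomes descending through that mutation. TMRCA is
#' `rho * years_per_mutation`, SD is `sigma_rho * years_per_mutation`.
#'
#' @param net A `haplo_network` from [build_mj_network()].
#' @param members Character vector of node ids (haplotype strings), one
#'   entry per chromosome in the cluster.
#' @param root Node id of the cluster root (e.g. the ancestral node).
#' @param years_per_mutation Scaling from [years_per_mutation()].
#' @return List of class `rho_estimate`: `rho`, `sigma_rho`, `n`,
#'   `years_per_mutation`, `tmrca_years`, `sd_years`.
#' @section Errors: a member disconnected from the root is an error; so is
#'   a member with more than one shortest path to the root (a reticulation
#'   inside the cluster) — refine the cluster so its rooted tree is
#'   unambiguous.
#' @export
rho_tmrca <- function(net, members, root, years_per_mutation) {
  all_ids <- net$nodes$id
  if (!root %in% all_ids) stop_("root '%s' is not a network node", root)
  bad <- setdiff(unique(members), all_ids)
  if (length(bad))
    stop_("cluster member(s) not in network: %s", paste(bad, collapse = ", "))
  n <- length(members)
  if (!n) stop_("empty cluster")
  g <- as_igraph(net)
  uniq <- unique(members)
  dist <- igraph::distances(g, v = root, to = uniq, weights = igraph::E(g)$weight)
  if (any(is.infinite(dist)))
    stop_("cluster member(s) disconnected from root: %s",
          paste(uniq[is.infinite(dist)], collapse = ", "))
  # unique shortest paths -> rooted cluster tree; count chromosomes per edge
  mult <- table(factor(members, levels = uniq))
  edge_n <- numeric(igraph::ecount(g))
  total <- 0
  for (u in uniq) {
    if (u == root) next
    paths <- igraph::all_shortest_paths(g, from = root, to = u,
                                        weights = igraph::E(g)$weight)$res
    if (length(paths) > 1L)
      stop_("ambiguous shortest path from root to '%s' (reticulation inside the cluster); refine the cluster",
            u)
    vp <- paths[[1L]]
    eids <- igraph::get_edge_ids(g, rep(as.integer(vp),
                                        c(1L, rep(2L, length(vp) - 2L), 1L)))
    edge_n[eids] <- edge_n[eids] + mult[[u]]
  }
  w <- igraph::E(g)$weight
  rho <- sum(dist[1L, uniq] * as.numeric(mult)) / n
  sigma2 <- sum(w * (edge_n / n)^2)
  sigma <- sqrt(sigma2)
  structure(list(rho = rho, sigma_rho = sigma, n = n,
                 years_per_mutation = years_per_mutation,
                 tmrca_years = rho * years_per_mutation,
                 sd_years = sigma * years_per_mutation),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf(
    "rho = %.4f (sigma %.4f, n = %d) x %g y/mut -> TMRCA %.0f +/- %.0f years\n",
    x$rho, x$sigma_rho, x$n, x$years_per_mutation,
    x$tmrca_years, x$sd_years))
  invisible(x)
}
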