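# Bandelt median-joining haplotype networks.

#' Build a median-joining haplotype network
#'
#' The Bandelt median-joining construction: starting from the distinct
#' observed haplotypes, iterate (a) build the minimum-spanning network
#' (union of all minimum spanning trees, with relaxation parameter
#' `epsilon`) under Hamming distance, (b) for every path `u - v - w` in it,
#' compute the coordinate-wise majority (median/Steiner) vector of the
#' triplet and add the cheapest new median vectors (connection cost within
#' `epsilon` of the minimum), (c) repeat to a fixed point, then (d) prune
#' median vectors that end up superfluous (unsampled nodes of degree <= 2).
#' Nodes are processed in sorted haplotype order so the result is
#' deterministic.
#'
#' @param haplotypes Character vector of equal-length haplotype strings, one
#'   per chromosome (repeats encode frequency).
#' @param populations Optional population label per chromosome, stored as
#'   per-node counts.
#' @param ancestral Optional ancestral haplotype string; it is added as a
#'   node (frequency 0 if unsampled) and marked, providing the conventional
#'   root for dating. Median ties at multi-state positions resolve toward
#'   the ancestral state, then lexicographically.
#' @param epsilon Non-negative relaxation parameter (default 0, the usual
#'   setting).
#' @return An object of class `haplo_network`: list with `nodes`
#'   (data.frame: `id` = haplotype string, `freq`, `sampled`, `ancestral`),
#'   `edges` (data.frame: `from`, `to`, `length`, list column `sites` of
#'   0-based offsets of the changing positions), `pop_counts` (node x
#'   population matrix), `cost` (sum of edge lengths).
#' @examples
#' net <- build_mj_network(c("000", "011", "101"))
#' net$nodes$id          # includes the inferred median "001"
#' net$cost              # 3
#' @export
build_mj_network <- function(haplotypes, populations = NULL,
                             ancestral = NULL, epsilon = 0) {
  if (!length(haplotypes)) stop_("zero haplotypes")
  nc <- unique(nchar(haplotypes))
  if (length(nc) > 1L) stop_("haplotypes must have equal length")
  freq <- table(haplotypes)
  types <- sort(names(freq))
  anc_chars <- NULL
  if (!is.null(ancestral)) {
    if (nchar(ancestral) != nc) stop_("ancestral length mismatch")
    anc_chars <- strsplit(ancestral, "")[[1L]]
    if (!ancestral %in% types) types <- sort(c(types, ancestral))
  }
  seqs <- do.call(rbind, strsplit(types, ""))
  rownames(seqs) <- types
  sampled <- types %in% names(freq)

  # iterate: MSN -> add median vectors -> repeat
  for (iter in seq_len(200L)) {
    if (nrow(seqs) == 1L) break
    D <- hamming_matrix(seqs)
    adj <- msn_adjacency(D, epsilon)
    cand <- list(); cand_cost <- numeric(0)
    for (v in seq_len(nrow(seqs))) {
      nb <- which(adj[v, ])
      if (length(nb) < 2L) next
      pairs <- utils::combn(nb, 2L)
      for (p in seq_len(ncol(pairs))) {
        u <- pairs[1L, p]; w <- pairs[2L, p]
        m <- median_vector(seqs[u, ], seqs[v, ], seqs[w, ], anc_chars)
        key <- paste(m, collapse = "")
        if (key %in% rownames(seqs)) next
        cost <- sum(m != seqs[u, ]) + sum(m != seqs[v, ]) +
          sum(m != seqs[w, ])
        if (is.null(cand[[key]]) || cost < cand_cost[[key]]) {
          cand[[key]] <- m
          cand_cost[[key]] <- cost
        }
      }
    }
    if (!length(cand)) break
    lambda <- min(unlist(cand_cost))
    keep <- names(cand)[unlist(cand_cost) <= lambda + epsilon]
    keep <- sort(keep)
    seqs <- rbind(seqs, do.call(rbind, cand[keep]))
    rownames(seqs) <- c(rownames(seqs)[seq_len(nrow(seqs) - length(keep))],
                        keep)
    sampled <- c(sampled, rep(FALSE, length(keep)))
    ord <- order(rownames(seqs))
    seqs <- seqs[ord, , drop = FALSE]
    sampled <- sampled[ord]
  }

  # prune superfluous medians: unsampled, non-ancestral nodes of degree <= 2
  anc_key <- if (is.null(ancestral)) NA_character_ else ancestral
  repeat {
    if (nrow(seqs) == 1L) { adj <- matrix(FALSE, 1L, 1L); break }
    D <- hamming_matrix(seqs)
    adj <- msn_adjacency(D, epsilon)
    deg <- rowSums(adj)
    drop <- which(!sampled & rownames(seqs) != anc_key & deg <= 2L)
    if (!length(drop)) break
    drop <- drop[1L]
    seqs <- seqs[-drop, , drop = FALSE]
    sampled <- sampled[-drop]
  }

  types <- rownames(seqs)
  nfreq <- as.integer(freq[types])
  nfreq[is.na(nfreq)] <- 0L
  nodes <- data.frame(id = types, freq = nfreq, sampled = nfreq > 0L,
                      ancestral = types == (anc_key %|NA|% ""),
                      stringsAsFactors = FALSE)
  pops <- sort(unique(populations %||% character(0)))
  pop_counts <- matrix(0L, nrow(nodes), length(pops),
                       dimnames = list(types, pops))
  if (length(pops)) {
    tab <- table(factor(haplotypes, levels = types), factor(populations))
    pop_counts[rownames(tab), colnames(tab)] <- unclass(tab)
  }
  ed <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(from = types[ed[, 1L]], to = types[ed[, 2L]],
                      stringsAsFactors = FALSE)
  edges$length <- vapply(seq_len(nrow(edges)), function(e)
    sum(seqs[ed[e, 1L], ] != seqs[ed[e, 2L], ]), integer(1L))
  edges$sites <- I(lapply(seq_len(nrow(edges)), function(e)
    which(seqs[ed[e, 1L], ] != seqs[ed[e, 2L], ])))
  if (!nrow(edges))
    edges <- data.frame(from = character(0), to = character(0),
                        length = integer(0), sites = I(list()))
  structure(list(nodes = nodes, edges = edges, pop_counts = pop_counts,
                 cost = sum(edges$length), epsilon = epsilon),
            class = "haplo_network")
}

hamming_matrix <- function(seqs) {
  n <- nrow(seqs)
  D <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    di <- colSums(t(seqs[(i + 1L):n, , drop = FALSE]) != seqs[i, ])
    D[i, (i + 1L):n] <- di
    D[(i + 1L):n, i] <- di
  }
  D
}

# Minimum-spanning network: process distance levels in increasing order;
# a link at level d joins nodes whose components (as of the previous
# feasible level) are at distance <= current + epsilon apart. With
# epsilon = 0 this is the union of all minimum spanning trees.
msn_adjacency <- function(D, epsilon = 0) {
  n <- nrow(D)
  adj <- matrix(FALSE, n, n)
  comp <- seq_len(n)
  levels_ <- sort(unique(D[upper.tri(D)]))
  for (d in levels_) {
    if (length(unique(comp)) == 1L && d > max_linked(D, adj) + epsilon) break
    pre <- comp  # component structure before this level
    link <- which(D == d & upper.tri(D), arr.ind = TRUE)
    use <- link[pre[link[, 1L]] != pre[link[, 2L]], , drop = FALSE]
    if (!nrow(use)) next
    for (e in seq_len(nrow(use))) {
      adj[use[e, 1L], use[e, 2L]] <- TRUE
      adj[use[e, 2L], use[e, 1L]] <- TRUE
    }
    for (e in seq_len(nrow(use))) {
      ca <- comp[use[e, 1L]]; cb <- comp[use[e, 2L]]
      if (ca != cb) comp[comp == cb] <- ca
    }
  }
  adj
}

max_linked <- function(D, adj) {
  v <- D[adj]
  if (length(v)) max(v) else 0L
}

# Coordinate-wise majority of three aligned sequences; a three-way tie
# resolves to the ancestral character when it is among the three, else to
# the lexicographically smallest.
median_vector <- function(a, b, c_, anc_chars = NULL) {
  vapply(seq_along(a), function(k) {
    ch <- c(a[k], b[k], c_[k])
    tab <- sort(table(ch), decreasing = TRUE)
    if (tab[1L] > 1L) return(names(tab)[1L])
    if (!is.null(anc_chars) && anc_chars[k] %in% ch) return(anc_chars[k])
    min(ch)
  }, character(1L))
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf(
    "median-joining network: %d nodes (%d sampled, %d median), %d edges, cost %d, %d reticulation(s)\n",
    nrow(x$nodes), sum(x$nodes$sampled), sum(!x$nodes$sampled),
    nrow(x$edges), x$cost, count_reticulations(x)))
  invisible(x)
}

#' Number of reticulations in a network
#'
#' The cycle-space rank `edges - nodes + components`; a tree has 0, and each
#' independent cycle (signal of recombination or recurrent mutation)
#' adds 1.
#'
#' @param net A `haplo_network`.
#' @return Integer count.
#' @export
count_reticulations <- function(net) {
  g <- as_igraph(net)
  igraph::ecount(g) - igraph::vcount(g) +
    igraph::count_components(g)
}

#' Convert a haplotype network to an igraph object
#'
#' Edge attribute `weight` is the mutational length; node attributes carry
#' frequency, sampled/median status and per-population counts, so
#' [igraph::write_graph()] exports a complete GraphML.
#'
#' @param net A `haplo_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to", "length")],
    directed = FALSE, vertices = net$nodes)
  igraph::E(g)$weight <- igraph::E(g)$length
  if (ncol(net$pop_counts))
    for (p in colnames(net$pop_counts))
      g <- igraph::set_vertex_attr(
        g, paste0("n_", p),
        value = net$pop_counts[igraph::V(g)$name, p])
  g
}
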