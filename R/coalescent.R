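# Kingman coalescent simulator with infinite-sites mutation: the ground
# truth engine behind every testable claim in the package.

#' Specify a demographic model
#'
#' Haploid coalescent models in three flavours:
#' * `"constant"` — size `N0` forever;
#' * `"expansion"` — size `N0` back to `t_onset` years ago, ancestral size
#'   `N0 / factor` before that (piecewise-constant, i.e. an instantaneous
#'   expansion at `t_onset`);
#' * `"split"` — `deme_sizes` demes with no migration, merging into a single
#'   ancestral deme of size `N_ancestral` at `split_time` years ago.
#'
#' Sizes are haploid effective sizes: with `k` lineages in a deme of size
#' `N`, the coalescence rate is `k(k-1)/(2N)` per generation. For
#' X-chromosomal applications pass the X-specific effective size (about 3/4
#' of the autosomal one); the package does not rescale for you.
#'
#' @param kind `"constant"`, `"expansion"` or `"split"`.
#' @param N0 Current haploid effective size (constant/expansion), or the
#'   default deme size for splits.
#' @param t_onset Expansion onset, in years ago.
#' @param factor Expansion factor `f > 1`; ancestral size is `N0 / f`.
#' @param deme_sizes Named vector of per-deme sizes for `"split"`.
#' @param split_time Merge time in years ago for `"split"`.
#' @param N_ancestral Ancestral deme size after the merge (default `N0`).
#' @param mu Mutation rate per site per year (default `6.59e-10`).
#' @param gen_time Generation time in years (default 30.8).
#' @param L Segment length in bp.
#' @return A `demographic_model` object.
#' @export
demographic_model <- function(kind = c("constant", "expansion", "split"),
                              N0 = 10000, t_onset = NULL, factor = NULL,
                              deme_sizes = NULL, split_time = NULL,
                              N_ancestral = NULL,
                              mu = 6.59e-10, gen_time = 30.8, L = 5000L) {
  kind <- match.arg(kind)
  if (N0 <= 0 || mu <= 0 || gen_time <= 0 || L <= 0)
    stop_("all model parameters must be positive")
  m <- list(kind = kind, N0 = N0, mu = mu, gen_time = gen_time,
            L = as.integer(L))
  if (kind == "expansion") {
    if (is.null(t_onset) || is.null(factor))
      stop_("expansion model needs t_onset and factor")
    if (factor <= 1) stop_("expansion factor must exceed 1")
    m$t_onset <- t_onset
    m$factor <- factor
  }
  if (kind == "split") {
    if (is.null(deme_sizes) || is.null(split_time))
      stop_("split model needs deme_sizes and split_time")
    if (is.null(names(deme_sizes)))
      names(deme_sizes) <- paste0("deme", seq_along(deme_sizes))
    if (any(deme_sizes <= 0) || split_time <= 0)
      stop_("all model parameters must be positive")
    m$deme_sizes <- deme_sizes
    m$split_time <- split_time
    m$N_ancestral <- N_ancestral %||% N0
  }
  structure(m, class = "demographic_model")
}

#' Simulate a coalescent genealogy
#'
#' Backwards-in-time Kingman coalescent under a [demographic_model()]: with
#' `k` lineages in a deme of current size `N`, the waiting time to the next
#' coalescence is exponential with rate `k(k-1)/(2N)` per generation,
#' time-rescaled across the piecewise-constant epochs; split-model demes
#' evolve independently until their merge time. Fully reproducible from
#' `seed`.
#'
#' @param model A [demographic_model()].
#' @param sample_sizes Number of sampled chromosomes; for split models a
#'   vector (recycled over demes, named to target specific demes). Must sum
#'   to >= 2.
#' @param seed Optional integer seed.
#' @return An [ape::phylo] tree with branch lengths in generations and
#'   attributes `tip_populations` (deme of each tip, in tip order) and
#'   `tmrca_gen` (root age in generations).
#' @export
simulate_genealogy <- function(model, sample_sizes, seed = NULL) {
  if (!inherits(model, "demographic_model")) stop_("invalid model")
  if (!is.null(seed)) set.seed(seed)
  if (model$kind == "split") {
    demes <- names(model$deme_sizes)
    sizes <- model$deme_sizes
    ss <- rep_len(sample_sizes, length(demes))
    if (!is.null(names(sample_sizes))) {
      ss <- sample_sizes[demes]
      if (anyNA(ss)) stop_("sample_sizes names must cover every deme")
    }
    merge_gen <- model$split_time / model$gen_time
    epochs <- function(deme) list(t = 0, N = sizes[[deme]])
  } else {
    demes <- "deme1"
    ss <- sum(sample_sizes)
    merge_gen <- Inf
    epochs <- NULL
  }
  if (sum(ss) < 2L) stop_("need at least 2 sampled chromosomes")

  n <- sum(ss)
  tip_pop <- rep(demes, times = ss)
  lineage <- seq_len(n)                # current node ids
  deme_of <- rep(demes, times = ss)
  node_time <- numeric(2L * n - 1L)    # generations ago
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)

  # size of a deme at time t (generations ago)
  size_at <- function(deme, t, merged) {
    if (model$kind == "constant") return(model$N0)
    if (model$kind == "expansion")
      return(if (t < model$t_onset / model$gen_time) model$N0
             else model$N0 / model$factor)
    if (merged) model$N_ancestral else model$deme_sizes[[deme]]
  }
  # next epoch boundary strictly after t, or Inf
  next_change <- function(t, merged) {
    bounds <- numeric(0)
    if (model$kind == "expansion")
      bounds <- model$t_onset / model$gen_time
    if (model$kind == "split" && !merged) bounds <- merge_gen
    bounds <- bounds[bounds > t]
    if (length(bounds)) min(bounds) else Inf
  }

  t <- 0
  merged <- model$kind != "split"
  repeat {
    k_by_deme <- table(factor(deme_of, levels = unique(deme_of)))
    active <- names(k_by_deme)[k_by_deme >= 2L]
    rates <- vapply(active, function(d) {
      k <- as.integer(k_by_deme[[d]])
      k * (k - 1) / (2 * size_at(d, t, merged))
    }, numeric(1L))
    total_rate <- sum(rates)
    boundary <- next_change(t, merged)
    wait <- if (total_rate > 0) stats::rexp(1L, total_rate) else Inf
    if (t + wait >= boundary) {
      t <- boundary
      if (model$kind == "split" && !merged && t >= merge_gen) {
        deme_of[] <- ".ancestral."
        merged <- TRUE
      }
      if (is.infinite(boundary) && total_rate == 0)
        stop_("no coalescence possible: disjoint demes never merge")
      next
    }
    t <- t + wait
    d <- if (length(active) == 1L) active else
      sample(active, 1L, prob = rates)
    in_d <- which(deme_of == d)
    pair <- if (length(in_d) == 2L) in_d else sample(in_d, 2L)
    parent <- next_node
    next_node <- next_node + 1L
    node_time[parent] <- t
    edges <- rbind(edges, c(parent, lineage[pair[1L]]),
                   c(parent, lineage[pair[2L]]))
    edge_len <- c(edge_len, t - node_time[lineage[pair[1L]]],
                  t - node_time[lineage[pair[2L]]])
    lineage <- c(lineage[-pair], parent)
    deme_of <- c(deme_of[-pair], d)
    if (length(lineage) == 1L) break
  }

  tree <- finish_phylo(edges, edge_len, n, tip_pop, t)
  tree
}

# Renumber internal nodes so the root is n+1 (the ape convention; internal
# nodes were created in coalescence order, so the root is the last id).
finish_phylo <- function(edges, edge_len, n, tip_pop, tmrca) {
  remap <- function(v) ifelse(v > n, 3L * n - v, v)
  edges <- cbind(remap(edges[, 1L]), remap(edges[, 2L]))
  tree <- structure(list(edge = edges, edge.length = edge_len,
                         tip.label = paste0("hap", seq_len(n)),
                         Nnode = n - 1L), class = "phylo")
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "tip_populations") <- stats::setNames(tip_pop, tree$tip.label)
  attr(tree, "tmrca_gen") <- tmrca
  tree
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Each branch receives a Poisson number of mutations with mean
#' `branch_length_generations * mu * gen_time * L`; every mutation creates a
#' fresh segregating site (infinite sites) at a distinct position uniform in
#' `1..L`, with derived allele `"1"` carried by all tips below the branch.
#' The ancestral allele is `"0"` at every site, so polarization is exact by
#' construction.
#'
#' @param tree A genealogy from [simulate_genealogy()].
#' @param model The [demographic_model()] supplying `mu`, `gen_time`, `L`
#'   (or pass them individually).
#' @param mu,gen_time,L Overrides for the model's values.
#' @param seed Optional integer seed.
#' @param chrom Chromosome name for the simulated sites.
#' @return A `sim_result` list: `matrix` (a [haplotype_matrix] whose
#'   populations are the tip demes), `tree`, `mutations` (data.frame
#'   `site`, `pos`, `edge`), `seed`.
#' @export
drop_mutations <- function(tree, model = NULL, mu = NULL, gen_time = NULL,
                           L = NULL, seed = NULL, chrom = "chrSim") {
  mu <- mu %||% model$mu
  gen_time <- gen_time %||% model$gen_time
  L <- L %||% model$L
  if (is.null(mu) || is.null(gen_time) || is.null(L))
    stop_("mu, gen_time and L must come from the model or be given")
  if (!is.null(seed)) set.seed(seed)
  rate <- mu * gen_time * L
  muts_per_edge <- stats::rpois(nrow(tree$edge), tree$edge.length * rate)
  S <- sum(muts_per_edge)
  if (S > L)
    stop_("more mutations (%d) than sites (%d): increase L", S, L)
  pos <- sort(sample.int(L, S))
  ntips <- length(tree$tip.label)
  geno <- matrix(1L, ntips, S)  # index 1 = ancestral allele "0"
  edge_of_site <- rep(seq_len(nrow(tree$edge)), muts_per_edge)
  # assign positions to mutations in edge order; shuffle so position carries
  # no information about the branch
  site_order <- sample.int(S)
  edge_of_site <- edge_of_site[site_order]
  for (s in seq_len(S)) {
    tips <- tips_below(tree, tree$edge[edge_of_site[s], 2L], ntips)
    geno[tips, s] <- 2L
  }
  sites <- data.frame(chrom = rep(chrom, S), pos = pos,
                      ancestral = rep("0", S), stringsAsFactors = FALSE)
  sites$alleles <- rep(list(c("0", "1")), S)
  if (!S) {
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        ancestral = character(0))
    sites$alleles <- list()
  }
  tip_pop <- attr(tree, "tip_populations")
  hm <- haplotype_matrix(geno, sites,
                         populations = unname(tip_pop[tree$tip.label]),
                         samples = tree$tip.label)
  structure(list(matrix = hm, tree = tree,
                 mutations = data.frame(site = seq_len(S), pos = pos,
                                        edge = edge_of_site),
                 seed = seed),
            class = "sim_result")
}

#' Append recombinant chimeric haplotypes
#'
#' Builds `n_copies` of the chimera taking donor A's alleles at sites
#' `1..breakpoint_site` and donor B's from `breakpoint_site + 1` on, and
#' appends them as new samples. Used to plant known four-gamete violations.
#'
#' @param x A [haplotype_matrix].
#' @param donor_a,donor_b Sample names of the two donors.
#' @param breakpoint_site Site index `b` with `1 <= b < n_sites(x)`.
#' @param n_copies Number of chimeric copies to append (0 = no-op).
#' @param population Population label for the new samples.
#' @return The augmented [haplotype_matrix].
#' @export
inject_recombinants <- function(x, donor_a, donor_b, breakpoint_site,
                                n_copies = 1L, population = "REC") {
  if (!all(c(donor_a, donor_b) %in% x$samples)) stop_("unknown donor sample")
  if (breakpoint_site < 1L || breakpoint_site >= n_sites(x))
    stop_("breakpoint_site must be in 1..(n_sites - 1)")
  if (n_copies == 0L) return(x)
  chim <- x$geno[donor_a, ]
  chim[(breakpoint_site + 1L):n_sites(x)] <-
    x$geno[donor_b, (breakpoint_site + 1L):n_sites(x)]
  add <- matrix(rep(chim, each = n_copies), nrow = n_copies)
  newnames <- paste0("rec", seq_len(n_copies) + sum(grepl("^rec", x$samples)))
  haplotype_matrix(rbind(x$geno, add), x$sites,
                   populations = c(unname(x$populations),
                                   rep(population, n_copies)),
                   samples = c(x$samples, newnames))
}

#' Simulate the full multi-population study fixture
#'
#' Emulates the design this package targets: 12 demes of haploid male X
#' chromosomes — one deeply diverged constant-size African-like deme, one
#' Middle-Eastern-like and ten European-like demes that share a bottleneck
#' and a post-glacial expansion — typed at three loci whose lengths match
#' the called lengths of the three resequenced blocks (4983, 36 857 and
#' 5763 bp). The non-African demes split from each other at the expansion
#' onset (default 20 kya) through an ancestral bottleneck deme, which joins
#' the African deme deeper in time (default 70 kya); this produces the
#' expected signatures (star-like European genealogies with negative
#' Tajima's D / Fu's Fs, strong Africa-vs-Europe differentiation, weak
#' structure within Europe).
#'
#' @param seed Integer seed (required: the fixture is meant to be
#'   reproducible).
#' @param n_per_deme Chromosomes per deme (default 20, the study design;
#'   lower it for fast tests).
#' @param lengths Block lengths in bp.
#' @param N_afr,N_eur,N_bottleneck Haploid effective sizes.
#' @param t_expansion,t_africa Split/expansion times in years ago.
#' @param gen_time,mu As in [demographic_model()].
#' @return A list of three `sim_result`s (one per block), named by length.
#' @export
make_study_fixture <- function(seed, n_per_deme = 20L,
                               lengths = c(4983L, 36857L, 5763L),
                               N_afr = 12000, N_eur = 10000,
                               N_bottleneck = 500,
                               t_expansion = 20000, t_africa = 70000,
                               gen_time = 30.8, mu = 6.59e-10) {
  set.seed(seed)
  demes <- c("YRI", "PAL", "CEU", "DEN", "ENG", "NLD", "HUN", "IRE",
             "NOR", "ORK", "SPA", "TUR")
  out <- lapply(lengths, function(L) {
    tree <- simulate_study_tree(demes, n_per_deme, N_afr, N_eur,
                                N_bottleneck, t_expansion / gen_time,
                                t_africa / gen_time)
    model <- demographic_model("constant", N0 = N_eur, mu = mu,
                               gen_time = gen_time, L = L)
    drop_mutations(tree, model, chrom = paste0("block", L))
  })
  names(out) <- paste0("block", lengths)
  out
}

# Structured coalescent for the fixture: non-African demes merge into a
# bottleneck deme at t_eur, which merges into the African deme at t_afr.
simulate_study_tree <- function(demes, n_per_deme, N_afr, N_eur,
                                N_bottleneck, t_eur, t_afr) {
  n <- n_per_deme * length(demes)
  deme_of <- rep(demes, each = n_per_deme)
  tip_pop <- deme_of
  lineage <- seq_len(n)
  node_time <- numeric(2L * n - 1L)
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  edge_len <- numeric(0)
  deme_size <- function(d, t) {
    if (d == "YRI") N_afr
    else if (d == ".ooa.") N_bottleneck
    else N_eur
  }
  t <- 0
  phase <- 0L  # 0: all split; 1: non-African merged; 2: everything merged
  repeat {
    kt <- table(deme_of)
    active <- names(kt)[kt >= 2L]
    rates <- vapply(active, function(d) {
      k <- as.integer(kt[[d]])
      k * (k - 1) / (2 * deme_size(d, t))
    }, numeric(1L))
    total <- sum(rates)
    boundary <- if (phase == 0L) t_eur else if (phase == 1L) t_afr else Inf
    wait <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t + wait >= boundary) {
      t <- boundary
      if (phase == 0L) {
        deme_of[deme_of != "YRI"] <- ".ooa."
        phase <- 1L
      } else {
        deme_of[] <- "YRI"
        phase <- 2L
      }
      next
    }
    t <- t + wait
    d <- if (length(active) == 1L) active else sample(active, 1L, prob = rates)
    in_d <- which(deme_of == d)
    pair <- if (length(in_d) == 2L) in_d else sample(in_d, 2L)
    parent <- next_node; next_node <- next_node + 1L
    node_time[parent] <- t
    edges <- rbind(edges, c(parent, lineage[pair[1L]]),
                   c(parent, lineage[pair[2L]]))
    edge_len <- c(edge_len, t - node_time[lineage[pair[1L]]],
                  t - node_time[lineage[pair[2L]]])
    lineage <- c(lineage[-pair], parent)
    deme_of <- c(deme_of[-pair], d)
    if (length(lineage) == 1L) break
  }
  finish_phylo(edges, edge_len, n, tip_pop, t)
}
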