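# End-to-end orchestration: scan -> per-block stats -> networks -> dating,
# with a serialized run manifest.

#' Run the full block-detection and analysis pipeline
#'
#' Orchestrates the package's stages on one input data set: read haplotypes,
#' scan for non-recombining blocks, per-block diversity/differentiation
#' statistics, median-joining network (GraphML) and ancestral-node rho
#' dating. All outputs are plain text (TSV/GraphML/JSON) and a rerun with
#' the same configuration and seed is byte-identical. Each stage adds no
#' computation beyond the exported function it calls.
#'
#' @param config A named list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{input}{path to a VCF or haplotype table (or a
#'       [haplotype_matrix] passed directly).}
#'     \item{populations_file}{optional sample-population TSV.}
#'     \item{ancestral_file}{optional outgroup-allele TSV for
#'       [assign_ancestral()].}
#'     \item{scan_populations}{named list passed to [scan_blocks()]
#'       (optional).}
#'     \item{focal_population}{label for [rank_blocks()] (optional).}
#'     \item{genes, hotspots, segdups, orthologs}{optional BED paths for
#'       [filter_candidates()].}
#'     \item{min_sites}{minimum SNPs per block (default 3).}
#'     \item{mu, gen_time}{rate constants (defaults 6.59e-10, 30.8).}
#'     \item{length_convention}{`"span"` (default) or `"n_sites"`: the L
#'       used for years-per-mutation scaling.}
#'     \item{n_permutations}{phi-st permutations (default 0).}
#'     \item{n_sim}{neutrality-test null replicates (default 0).}
#'     \item{seed}{integer seed (default 1).}
#'     \item{out_dir}{output directory (created).}
#'   }
#' @return Invisibly, a list with the blocks table, per-block stats,
#'   networks, rho estimates and the manifest; files `blocks.tsv`,
#'   `stats.tsv`, `net_block<i>.graphml`, `tmrca.tsv`, `manifest.json`
#'   are written under `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(min_sites = 3L, mu = 6.59e-10, gen_time = 30.8,
         length_convention = "span", n_permutations = 0L, n_sim = 0L,
         seed = 1L),
    config)
  problems <- character(0)
  if (is.null(cfg$input)) problems <- c(problems, "missing 'input'")
  if (is.null(cfg$out_dir)) problems <- c(problems, "missing 'out_dir'")
  for (f in c("input", "populations_file", "ancestral_file", "genes",
              "hotspots", "segdups", "orthologs"))
    if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
        !file.exists(cfg[[f]]))
      problems <- c(problems, sprintf("file for '%s' not found: %s", f,
                                      cfg[[f]]))
  if (!cfg$length_convention %in% c("span", "n_sites"))
    problems <- c(problems, "length_convention must be 'span' or 'n_sites'")
  if (length(problems))
    stop_("pre-flight failure:\n  - %s", paste(problems, collapse = "\n  - "))

  set.seed(cfg$seed)
  x <- if (inherits(cfg$input, "haplotype_matrix")) cfg$input
       else read_haplotypes(cfg$input,
                            populations_file = cfg$populations_file)
  if (!is.null(cfg$ancestral_file)) x <- assign_ancestral(x, cfg$ancestral_file)
  if (!is.null(cfg$focal_population) &&
      !cfg$focal_population %in% x$populations)
    stop_("pre-flight failure:\n  - unknown focal_population '%s'",
          cfg$focal_population)
  if (!is.null(cfg$scan_populations)) {
    unknown <- setdiff(unlist(cfg$scan_populations), unique(x$populations))
    if (length(unknown))
      stop_("pre-flight failure:\n  - unknown scan population label(s): %s",
            paste(unknown, collapse = ", "))
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[phaxkit] ", fmt), ...))
  log_stage("read: %d samples x %d sites, %d population(s)",
            n_samples(x), n_sites(x), length(unique(x$populations)))

  blocks <- scan_blocks(x, cfg$scan_populations, min_sites = cfg$min_sites)
  intervals <- lapply(cfg[c("genes", "hotspots", "segdups", "orthologs")],
                      function(p) if (is.null(p)) NULL else read_intervals(p))
  if (!all(vapply(intervals, is.null, logical(1L))))
    blocks <- filter_candidates(blocks, intervals$genes, intervals$hotspots,
                                intervals$segdups, intervals$orthologs,
                                keep_all = FALSE)
  if (!is.null(cfg$focal_population))
    blocks <- rank_blocks(blocks, x, cfg$focal_population)
  log_stage("scan: %d block(s) of >= %d SNPs", nrow(blocks), cfg$min_sites)
  write_tsv(drop_list_cols(blocks), file.path(cfg$out_dir, "blocks.tsv"))

  stats_rows <- list(); networks <- list(); rho_rows <- list()
  for (b in seq_len(nrow(blocks))) {
    si <- blocks$site_idx[[b]]
    st <- diversity_stats(x, sites = si,
                          L = block_length(blocks[b, ], cfg),
                          n_sim = cfg$n_sim, seed = cfg$seed + b)
    st <- cbind(block = b, st)
    ps <- tryCatch(phi_st(x, sites = si,
                          n_permutations = cfg$n_permutations,
                          seed = cfg$seed + b),
                   error = function(e) NULL)
    st$mean_phi_st <- if (is.null(ps)) NA_real_ else
      c(mean_phi_st(ps), Total = mean(ps$phi[upper.tri(ps$phi)]))[st$group]
    stats_rows[[b]] <- st
    haps <- hap_strings(x, si)
    anc <- ancestral_string(x, si)
    net <- build_mj_network(haps, populations = x$populations[names(haps)],
                            ancestral = if (grepl("\\?", anc)) NULL else anc)
    networks[[b]] <- net
    igraph::write_graph(as_igraph(net),
                        file.path(cfg$out_dir,
                                  sprintf("net_block%d.graphml", b)),
                        format = "graphml")
    ypm <- years_per_mutation(cfg$mu, block_length(blocks[b, ], cfg))
    rho_rows[[b]] <- if (!grepl("\\?", anc)) {
      est <- tryCatch(rho_tmrca(net, members = haps, root = anc,
                                years_per_mutation = ypm),
                      error = function(e) NULL)
      if (is.null(est))
        data.frame(block = b, cluster = "ancestral_node", n = length(haps),
                   rho = NA_real_, sigma_rho = NA_real_,
                   years_per_mutation = ypm, tmrca_years = NA_real_,
                   sd_years = NA_real_)
      else
        data.frame(block = b, cluster = "ancestral_node", n = est$n,
                   rho = est$rho, sigma_rho = est$sigma_rho,
                   years_per_mutation = ypm,
                   tmrca_years = est$tmrca_years, sd_years = est$sd_years)
    } else NULL
    log_stage("block %d: %d SNPs, %d haplotypes, %d reticulation(s)",
              b, length(si), sum(net$nodes$sampled),
              count_reticulations(net))
  }
  stats <- if (length(stats_rows)) do.call(rbind, stats_rows) else NULL
  rho <- if (length(rho_rows)) do.call(rbind, rho_rows) else NULL
  if (!is.null(stats)) write_tsv(stats, file.path(cfg$out_dir, "stats.tsv"))
  if (!is.null(rho)) write_tsv(rho, file.path(cfg$out_dir, "tmrca.tsv"))

  manifest <- list(package = "phaxkit",
                   version = as.character(utils::packageVersion("phaxkit")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "input")],
                   n_samples = n_samples(x), n_sites = n_sites(x),
                   n_blocks = nrow(blocks))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(blocks = blocks, stats = stats, networks = networks,
                 tmrca = rho, manifest = manifest))
}

block_length <- function(block_row, cfg) {
  if (cfg$length_convention == "span") block_row$span_bp else block_row$n_sites
}

drop_list_cols <- function(df) {
  df[, !vapply(df, is.list, logical(1L)), drop = FALSE]
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
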