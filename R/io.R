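# Readers/writers: haploid VCF, plain haplotype tables, BED intervals,
# alignment export for external phylogenetic software.

#' Read phased haploid haplotypes
#'
#' Reads a [haplotype_matrix] from a VCF with haploid genotypes (the usual
#' representation for male X/Y calls) or from a plain tab-separated haplotype
#' table. Homozygous diploid genotypes (`0/0`, `1|1`, ...) are collapsed to
#' the haploid allele with a warning; a heterozygous genotype is a hard
#' error, because phased haploid input is the contract.
#'
#' @param path Path to the input file.
#' @param format `"vcf"`, `"table"`, or `"auto"` (by file extension).
#' @param populations_file Optional TSV (columns `sample`, `population`)
#'   attaching population labels. The table format carries its own
#'   `population` column.
#' @return A [haplotype_matrix]. For VCF input the `AA=` INFO tag, when
#'   present, populates the ancestral state.
#'
#' @details The table format is: header row `sample<TAB>population<TAB>` then
#'   one column per site named `chrom:pos`; cells hold allele symbols, `.`
#'   for missing. Site allele vectors are the sorted distinct observed
#'   symbols. VCF input preserves REF/ALT allele order and retains
#'   multiallelic sites.
#' @seealso [write_haplotypes()]
#' @export
read_haplotypes <- function(path, format = c("auto", "vcf", "table"),
                            populations_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "table"
  }
  x <- if (format == "vcf") read_haplotypes_vcf(path)
       else read_haplotypes_table(path)
  if (!is.null(populations_file)) {
    pops <- utils::read.table(populations_file, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (!all(c("sample", "population") %in% names(pops)))
      stop_("populations file needs columns sample, population")
    idx <- match(x$samples, pops$sample)
    if (anyNA(idx))
      stop_("no population label for sample(s): %s",
            paste(x$samples[is.na(idx)], collapse = ", "))
    x$populations[] <- pops$population[idx]
  }
  x
}

read_haplotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  n_var <- nrow(fix)
  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (n_var && anyNA(pos)) stop_("malformed POS field in %s", path)
  alleles <- lapply(seq_len(n_var), function(i) {
    alt <- fix[i, "ALT"]
    if (is.na(alt) || alt == ".") unname(fix[i, "REF"])
    else unname(c(fix[i, "REF"], strsplit(alt, ",", fixed = TRUE)[[1L]]))
  })
  info <- if (n_var) fix[, "INFO"] else character(0)
  anc <- vapply(info, function(s) {
    if (is.na(s)) return(NA_character_)
    m <- regmatches(s, regexec("(?:^|;)AA=([^;]+)", s))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }, character(1L), USE.NAMES = FALSE)
  anc[!is.na(anc) & !mapply(function(a, al) a %in% al, anc, alleles)] <-
    NA_character_
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  geno <- matrix(NA_integer_, length(samples), n_var,
                 dimnames = list(samples, NULL))
  warned_diploid <- FALSE
  if (n_var) {
    for (i in seq_len(n_var)) {
      calls <- sub(":.*", "", gt[i, -1L])
      for (s in seq_along(calls)) {
        cl <- calls[s]
        if (is.na(cl) || cl == "." || cl == "./." || cl == ".|.") next
        parts <- strsplit(cl, "[/|]")[[1L]]
        parts <- parts[parts != ""]
        if (length(parts) == 2L) {
          if (parts[1L] != parts[2L])
            stop_("heterozygous genotype %s for sample %s at %s:%s; haploid calls required",
                  cl, samples[s], fix[i, "CHROM"], fix[i, "POS"])
          if (!warned_diploid) {
            warning("collapsing homozygous diploid genotypes to haploid calls",
                    call. = FALSE)
            warned_diploid <- TRUE
          }
          parts <- parts[1L]
        }
        if (parts[1L] != ".") geno[s, i] <- as.integer(parts[1L]) + 1L
      }
    }
  }
  sites <- data.frame(chrom = as.character(fix[, "CHROM"]),
                      pos = pos,
                      id = ifelse(fix[, "ID"] == ".", NA_character_,
                                  as.character(fix[, "ID"])),
                      ancestral = anc, stringsAsFactors = FALSE)
  if (!n_var) sites <- data.frame(chrom = character(0), pos = integer(0),
                                  id = character(0), ancestral = character(0))
  sites$alleles <- alleles
  haplotype_matrix(geno, sites)
}

read_haplotypes_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("sample", "population") %in% names(tab)))
    stop_("haplotype table needs leading columns sample, population")
  site_cols <- setdiff(names(tab), c("sample", "population"))
  parts <- strsplit(site_cols, ":", fixed = TRUE)
  if (length(site_cols) && any(lengths(parts) != 2L))
    stop_("site columns must be named chrom:pos")
  pos <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  if (length(site_cols) && anyNA(pos))
    stop_("malformed position in site column name")
  alleles <- lapply(site_cols, function(cn) {
    obs <- setdiff(unique(tab[[cn]]), ".")
    if (!length(obs)) "N" else sort(obs)
  })
  geno <- matrix(NA_integer_, nrow(tab), length(site_cols))
  for (j in seq_along(site_cols)) {
    v <- tab[[site_cols[j]]]
    geno[, j] <- ifelse(v == ".", NA_integer_, match(v, alleles[[j]]))
  }
  sites <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                      pos = pos, stringsAsFactors = FALSE)
  if (!length(site_cols)) sites <- data.frame(chrom = character(0),
                                              pos = integer(0))
  sites$alleles <- alleles
  haplotype_matrix(geno, sites, populations = tab$population,
                   samples = tab$sample)
}

#' Write haplotypes to VCF or haplotype table
#'
#' The VCF writer emits haploid genotypes, REF/ALT in the stored allele
#' order, and the ancestral state as `AA=` INFO; reading the file back with
#' [read_haplotypes()] reproduces the matrix exactly. Population labels go
#' to a sidecar TSV when `populations_file` is given (VCF carries none).
#'
#' @param x A [haplotype_matrix].
#' @param path Output file.
#' @param format `"vcf"` or `"table"`.
#' @param populations_file Optional path for a `sample<TAB>population` TSV.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(x, path, format = c("vcf", "table"),
                             populations_file = NULL) {
  format <- match.arg(format)
  if (format == "vcf") {
    hdr <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", x$samples), collapse = "\t"))
    rows <- vapply(seq_len(n_sites(x)), function(j) {
      al <- x$sites$alleles[[j]]
      anc <- x$sites$ancestral[[j]]
      g <- x$geno[, j]
      paste(c(x$sites$chrom[j], x$sites$pos[j],
              x$sites$id[j] %|NA|% ".",
              al[1L], if (length(al) > 1L) paste(al[-1L], collapse = ",") else ".",
              ".", "PASS",
              if (is.na(anc)) "." else paste0("AA=", anc),
              "GT", ifelse(is.na(g), ".", g - 1L)), collapse = "\t")
    }, character(1L))
    writeLines(c(hdr, rows), path)
  } else {
    cols <- hap_table_columns(x)
    utils::write.table(cols, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(populations_file))
    utils::write.table(data.frame(sample = x$samples,
                                  population = unname(x$populations)),
                       populations_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

`%|NA|%` <- function(a, b) if (is.na(a)) b else a

hap_table_columns <- function(x) {
  out <- data.frame(sample = x$samples,
                    population = unname(x$populations),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(n_sites(x))) {
    al <- x$sites$alleles[[j]]
    g <- x$geno[, j]
    out[[paste0(x$sites$chrom[j], ":", x$sites$pos[j])]] <-
      ifelse(is.na(g), ".", al[g])
  }
  out
}

#' Assign ancestral states from outgroup alleles
#'
#' Polarizes each site against an outgroup (e.g. the chimpanzee reference
#' base at the orthologous position). A site whose outgroup allele is not
#' among its observed alleles keeps an unknown ancestral state and is
#' counted in the returned attribute.
#'
#' @param x A [haplotype_matrix].
#' @param outgroup A `data.frame` with columns `chrom`, `pos`, `allele`, or a
#'   path to such a TSV (with header).
#' @return `x` with `sites$ancestral` filled in; attribute `n_unknown` gives
#'   the number of sites left unknown. Idempotent for a fixed outgroup.
#' @export
assign_ancestral <- function(x, outgroup) {
  if (is.character(outgroup) && length(outgroup) == 1L)
    outgroup <- utils::read.table(outgroup, header = TRUE, sep = "\t",
                                  colClasses = "character")
  outgroup <- as.data.frame(outgroup)
  if (!all(c("chrom", "pos", "allele") %in% names(outgroup)))
    stop_("outgroup needs columns chrom, pos, allele")
  key <- paste(outgroup$chrom, outgroup$pos)
  skey <- paste(x$sites$chrom, x$sites$pos)
  idx <- match(skey, key)
  anc <- rep(NA_character_, n_sites(x))
  for (j in seq_len(n_sites(x))) {
    if (is.na(idx[j])) next
    a <- as.character(outgroup$allele[idx[j]])
    if (a %in% x$sites$alleles[[j]]) anc[j] <- a
  }
  x$sites$ancestral <- anc
  attr(x, "n_unknown") <- sum(is.na(anc))
  x
}

#' Read a BED file of genomic intervals
#'
#' BED3+ reader returning a `GRanges`. BED is 0-based half-open; the returned
#' ranges use the 1-based closed convention of `GenomicRanges`, so interval
#' arithmetic downstream is delegated entirely to that infrastructure.
#'
#' @param path BED3 or BED4 file (optional 4th column becomes `label`).
#' @return A sorted `GRanges` with a `label` metadata column.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(GenomicRanges::GRanges(label = character(0)))
  fields <- strsplit(lines, "\t")
  if (any(lengths(fields) < 3L))
    stop_("BED line %d has fewer than 3 fields", which(lengths(fields) < 3L)[1L])
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start0) || anyNA(end0))
    stop_("malformed coordinate at BED line %d",
          which(is.na(start0) | is.na(end0))[1L])
  bad <- start0 >= end0
  if (any(bad))
    stop_("start >= end at BED line %d", which(bad)[1L])
  label <- vapply(fields, function(f)
    if (length(f) >= 4L) f[4L] else NA_character_, character(1L))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1L,
                                                end = end0),
                               label = label)
  GenomicRanges::sort(gr)
}

#' Export haplotypes as a sequence alignment
#'
#' Writes one sequence per haploid sample over the selected SNP sites, in
#' FASTA or NEXUS, for downstream phylogenetic/coalescent software. Only the
#' variant columns are written; invariant flanking sequence is not
#' fabricated. A JSON sidecar can record the substitution-rate constants a
#' strict-clock analysis of these loci uses.
#'
#' @param x A [haplotype_matrix].
#' @param path Output file.
#' @param samples Non-empty sample subset (default all).
#' @param sites Site indices (default all).
#' @param format `"fasta"` or `"nexus"`.
#' @param config_path Optional path for the JSON sidecar.
#' @param mu Mutation rate per site per year recorded in the sidecar
#'   (default `6.59e-10`, a male-X pedigree-calibrated rate).
#' @param generation_time Generation time in years for the sidecar
#'   (default 30.8).
#' @return `path`, invisibly.
#' @export
export_alignment <- function(x, path, samples = x$samples,
                             sites = seq_len(n_sites(x)),
                             format = c("fasta", "nexus"),
                             config_path = NULL,
                             mu = 6.59e-10, generation_time = 30.8) {
  format <- match.arg(format)
  if (!length(samples)) stop_("empty sample subset")
  seqs <- hap_strings(x, sites, samples)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  } else {
    symbols <- sort(unique(unlist(x$sites$alleles[sites])))
    dtype <- if (all(symbols %in% c("A", "C", "G", "T"))) "DNA" else "STANDARD"
    fmt <- sprintf("FORMAT DATATYPE=%s MISSING=? GAP=-%s;", dtype,
                   if (dtype == "STANDARD")
                     sprintf(" SYMBOLS=\"%s\"", paste(symbols, collapse = ""))
                   else "")
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("DIMENSIONS NTAX=%d NCHAR=%d;",
                         length(seqs), length(sites)),
                 fmt, "MATRIX",
                 paste(names(seqs), unname(seqs)),
                 ";", "END;"), path)
  }
  if (!is.null(config_path))
    jsonlite::write_json(list(mutation_rate_per_site_per_year = mu,
                              generation_time_years = generation_time,
                              n_sequences = length(seqs),
                              n_sites = length(sites)),
                         config_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
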