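# End-to-end orchestration: configuration, the three pipeline stages
# (simulate / quantify / differential), matrix I/O and provenance.

#' Pipeline configuration
#'
#' Collects every tunable parameter with its default, so each run can
#' echo the full configuration into its provenance record.
#'
#' @param ref An [amplicon_reference()].
#' @param min_mapq Mapping-quality floor for SAM/BAM input (default 30).
#' @param policy Ambiguous-base policy for [call_patterns()].
#' @param rpkm_threshold Mean-RPKM filter threshold (default 10).
#' @param groups Optional two genotype labels (numerator first).
#' @param seed Integer seed for anything stochastic.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ref = default_amplicon_reference(),
                            min_mapq = 30L,
                            policy = c("strict", "lenient"),
                            rpkm_threshold = 10,
                            groups = NULL,
                            seed = 1L) {
  structure(list(ref = ref, min_mapq = as.integer(min_mapq),
                 policy = match.arg(policy),
                 rpkm_threshold = rpkm_threshold, groups = groups,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_provenance <- function(out_dir, config, extra = list(),
                              inputs = character(0)) {
  prov <- list(
    package = "ampedit",
    version = as.character(utils::packageVersion("ampedit")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = list(min_mapq = config$min_mapq, policy = config$policy,
                  rpkm_threshold = config$rpkm_threshold,
                  groups = config$groups, seed = config$seed,
                  full_contig_length = nchar(config$ref$full_contig),
                  truncated_contig_length = nchar(config$ref$truncated_contig),
                  site_labels = config$ref$site_map$label,
                  site_positions = config$ref$site_map$position))
  if (length(inputs))
    prov$input_md5 <- as.list(tools::md5sum(inputs))
  prov <- c(prov, extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(prov)
}

.ensure_outdir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE): ",
         out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(out_dir)
}

#' Run the simulation stage
#'
#' Wraps [simulate_design()]: writes per-library FASTQ files, the truth
#' TSV, the design manifest and a provenance record.
#'
#' @param config A [pipeline_config()].
#' @param design A [sim_design()]; its seed defaults to the config seed.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the library manifest data frame.
#' @export
run_simulate <- function(config = pipeline_config(),
                         design = NULL, out_dir, force = FALSE) {
  .ensure_outdir(out_dir, force)
  if (is.null(design)) design <- sim_design(seed = config$seed)
  manifest <- simulate_design(config$ref, design, out_dir)
  .write_provenance(out_dir, config,
                    extra = list(stage = "simulate",
                                 design = list(
                                   replicates_per_genotype =
                                     design$replicates_per_genotype,
                                   reads_per_library = design$reads_per_library,
                                   per_base_error_rate =
                                     design$per_base_error_rate,
                                   master_seed = design$seed)))
  invisible(manifest)
}

#' Run the quantification stage
#'
#' Processes a set of libraries (all FASTQ/FASTA, or all SAM/BAM -- mixed
#' input types are rejected) into per-library stats, pattern counts, the
#' RPKM pattern matrix and a splice-isoform summary, all written as TSV.
#'
#' @param config A [pipeline_config()].
#' @param inputs Character vector of input files, named by library ID
#'   (basenames used otherwise).
#' @param genotypes Genotype label per input library.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, a list: `matrix` (the [build_pattern_matrix()]
#'   result), `stats`, `splice`, `rejected`.
#' @export
run_quantify <- function(config = pipeline_config(), inputs, genotypes,
                         out_dir, force = FALSE) {
  if (length(inputs) < 1L) stop("need at least one input library")
  stopifnot(length(genotypes) == length(inputs))
  is_aln <- grepl("\\.(sam|bam)$", inputs, ignore.case = TRUE)
  if (any(is_aln) && !all(is_aln))
    stop("mixed input types: supply either all SAM/BAM or all FASTQ/FASTA")
  miss <- inputs[!file.exists(inputs)]
  if (length(miss)) stop("missing input file(s): ", paste(miss, collapse = ", "))
  if (is.null(names(inputs)))
    names(inputs) <- sub("\\.[^.]+$", "", basename(inputs))
  .ensure_outdir(out_dir, force)

  counts <- list(); stats <- list(); rejected <- list()
  for (i in seq_along(inputs)) {
    lib <- names(inputs)[i]
    res <- if (is_aln[i])
      read_alignments(inputs[i], config$ref, min_mapq = config$min_mapq,
                      library_id = lib)
    else
      classify_raw_reads(inputs[i], config$ref, library_id = lib)
    if (res$stats$total_reads == 0L)
      warning("empty input library: ", lib)
    calls <- call_patterns(res$observations, config$ref$site_map,
                           policy = config$policy)
    tab <- count_patterns(calls)
    counts[[lib]] <- tab$counts
    rejected[[lib]] <- tab$rejected
    st <- res$stats
    st$genotype <- genotypes[i]
    stats[[lib]] <- st
  }
  stats <- do.call(rbind, stats)
  nonempty <- stats$mapped_reads > 0
  pm <- build_pattern_matrix(counts[nonempty],
                             data.frame(library_id = stats$library_id,
                                        genotype = stats$genotype,
                                        total_mapped = stats$mapped_reads,
                                        stringsAsFactors = FALSE)[nonempty, ],
                             config$ref)
  spl <- splice_summary(stats)

  write.table(stats, file.path(out_dir, "library_stats.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(spl, file.path(out_dir, "splice_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_pattern_matrix(pm, out_dir)
  rej <- data.frame(library_id = rep(names(rejected),
                                     lengths(rejected)),
                    reason = unlist(lapply(rejected, names), use.names = FALSE),
                    n = unlist(rejected, use.names = FALSE),
                    stringsAsFactors = FALSE)
  write.table(rej, file.path(out_dir, "rejected_reads.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .write_provenance(out_dir, config, extra = list(stage = "quantify"),
                    inputs = unname(inputs))
  invisible(list(matrix = pm, stats = stats, splice = spl, rejected = rej))
}

#' Run the differential stage
#'
#' Filters the pattern matrix by mean RPKM, runs
#' [differential_analysis()], and writes pattern-level and site-level
#' report TSVs (columns named as in the study-style tables), the overall
#' editing level, a machine-readable JSON bundle and a provenance
#' record.  A console summary prints the editing levels and the top
#' patterns by absolute log fold change.
#'
#' @param config A [pipeline_config()].
#' @param matrix_in A `pattern_matrix` or a directory written by
#'   [run_quantify()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty output directory.
#' @return Invisibly, the `editing_diff` object.
#' @export
run_differential <- function(config = pipeline_config(), matrix_in, out_dir,
                             force = FALSE) {
  pm <- if (inherits(matrix_in, "pattern_matrix")) matrix_in
        else read_pattern_matrix(matrix_in)
  if (length(unique(pm$libraries$genotype)) < 2L)
    stop("matrix has a single genotype; differential analysis needs two")
  fpm <- filter_by_mean_rpkm(pm, threshold = config$rpkm_threshold,
                             groups = config$groups)
  if (nrow(fpm$rpkm) == 0L)
    stop("no patterns survive the mean-RPKM filter (threshold ",
         config$rpkm_threshold, ")")
  .ensure_outdir(out_dir, force)
  fit <- differential_analysis(fpm, groups = config$groups)
  g <- fit$groups

  pt <- fit$patterns
  pat_tab <- data.frame(Pattern = pt$pattern, check.names = FALSE,
                        stringsAsFactors = FALSE)
  pat_tab[[paste("Mean RPKM", g[1L])]] <- pt$mean1
  pat_tab[[paste("Mean RPKM", g[2L])]] <- pt$mean2
  pat_tab[["Fold change"]] <- pt$fold_change
  pat_tab[["P-value"]] <- pt$p_value
  pat_tab[["SIG"]] <- pt$sig
  pat_tab[["pBH"]] <- pt$p_bh
  pat_tab[[paste0(g[1L], " %")]] <- pt$pct1
  pat_tab[[paste0(g[2L], " %")]] <- pt$pct2
  write.table(pat_tab, file.path(out_dir, "pattern_differential.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  st <- fit$sites
  site_tab <- data.frame(`Edited Site` = st$site, check.names = FALSE,
                         stringsAsFactors = FALSE)
  site_tab[[paste("Mean RPKM", g[1L])]] <- st$mean1
  site_tab[[paste("Mean RPKM", g[2L])]] <- st$mean2
  site_tab[["Fold change"]] <- st$fold_change
  site_tab[["P-value"]] <- st$p_value
  site_tab[["SIG"]] <- st$sig
  site_tab[["pBH"]] <- st$p_bh
  site_tab[[paste0(g[1L], " %")]] <- st$pct1
  site_tab[[paste0(g[2L], " %")]] <- st$pct2
  write.table(site_tab, file.path(out_dir, "site_contribution.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  write.table(fit$editing_level, file.path(out_dir, "editing_level.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(groups = g, patterns = pt, sites = st,
         editing_level = fit$editing_level),
    file.path(out_dir, "differential.json"), auto_unbox = TRUE, digits = NA)
  .write_provenance(out_dir, config, extra = list(
    stage = "differential", n_patterns_tested = nrow(pt)))

  el <- fit$editing_level
  message(sprintf("overall editing level: %s %.1f%%, %s %.1f%%",
                  el$genotype[1L], el$pct_edited[1L],
                  el$genotype[2L], el$pct_edited[2L]))
  message("top patterns by |log fold change|: ",
          paste(.top_by_lfc(pt)$pattern, collapse = ", "))
  invisible(fit)
}

#' Pattern-matrix I/O
#'
#' Writes/reads a `pattern_matrix` as TSV: `pattern_counts.tsv` and
#' `pattern_rpkm.tsv` (patterns x libraries) with a sidecar
#' `matrix_metadata.tsv` (genotype and total mapped reads per library,
#' contig length, site map).
#'
#' @param pm A `pattern_matrix`.
#' @param dir Directory holding the three files.
#' @return `write_pattern_matrix()` the input invisibly;
#'   `read_pattern_matrix()` the reconstructed `pattern_matrix`.
#' @export
write_pattern_matrix <- function(pm, dir) {
  stopifnot(inherits(pm, "pattern_matrix"))
  w <- function(m, f) {
    df <- data.frame(pattern = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(pm$counts, "pattern_counts.tsv")
  w(pm$rpkm, "pattern_rpkm.tsv")
  meta <- pm$libraries
  meta$contig_length <- pm$contig_length
  write.table(meta, file.path(dir, "matrix_metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sm <- pm$site_map
  write.table(sm, file.path(dir, "matrix_site_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(pm)
}

#' @rdname write_pattern_matrix
#' @export
read_pattern_matrix <- function(dir) {
  rd <- function(f) {
    df <- read.delim(file.path(dir, f), check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  }
  cm <- rd("pattern_counts.tsv")
  rk <- rd("pattern_rpkm.tsv")
  meta <- read.delim(file.path(dir, "matrix_metadata.tsv"),
                     stringsAsFactors = FALSE)
  smf <- file.path(dir, "matrix_site_map.tsv")
  sm <- if (file.exists(smf)) {
    s <- read.delim(smf, colClasses = c(label = "character"))
    editing_site_map(s$label, s$position)
  } else default_site_map()
  structure(list(counts = cm, rpkm = rk,
                 libraries = meta[, c("library_id", "genotype",
                                      "total_mapped")],
                 contig_length = meta$contig_length[1L], site_map = sm),
            class = "pattern_matrix")
}
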