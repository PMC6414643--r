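# RPKM quantification and splice-isoform summaries.

#' RPKM normalization
#'
#' `RPKM = reads / sequence_length * (1e9 / total_mapped)` -- the exact
#' definition used throughout the pipeline, with no pseudocounts.  The
#' sequence length is the length of the contig the isoform maps to (the
#' full-length contig for every editing pattern), and `total_mapped` is
#' the library's mapped reads over both splice contigs.
#'
#' @param reads Read count(s).
#' @param sequence_length Contig length in nt.
#' @param total_mapped Total mapped reads of the library.
#' @return RPKM value(s).
#' @examples
#' rpkm(100, 209, 1e6)    # 478.4689
#' rpkm(209, 209, 1e9)    # 1
#' @export
rpkm <- function(reads, sequence_length, total_mapped) {
  if (any(sequence_length <= 0)) stop("`sequence_length` must be positive")
  if (any(total_mapped == 0)) stop("empty library: total_mapped is 0")
  if (any(total_mapped < 0)) stop("`total_mapped` must be positive")
  reads / sequence_length * (1e9 / total_mapped)
}

#' Build a libraries-by-patterns count/RPKM matrix
#'
#' Assembles per-library pattern counts into a single matrix (patterns
#' in rows, libraries in columns, mirroring the 12-experiments-by-112-
#' patterns layout of the emulated study) and computes the matching RPKM
#' matrix.  Patterns absent from a library get count 0.
#'
#' @param counts Named list, one element per library: a named numeric
#'   vector of pattern counts (as in [count_patterns()]`$counts`).
#' @param libraries Data frame with columns `library_id`, `genotype` and
#'   `total_mapped`, one row per element of `counts`.
#' @param ref An [amplicon_reference()]; supplies the contig length.
#' @return A `pattern_matrix` object: list with `counts` and `rpkm`
#'   matrices, the `libraries` data frame, `contig_length` and the site
#'   map.
#' @export
build_pattern_matrix <- function(counts, libraries, ref) {
  stopifnot(is.list(counts), inherits(ref, "amplicon_reference"))
  if (is.null(names(counts)))
    names(counts) <- libraries$library_id
  if (!all(c("library_id", "genotype", "total_mapped") %in% names(libraries)))
    stop("`libraries` needs columns library_id, genotype, total_mapped")
  if (anyDuplicated(libraries$library_id))
    stop("duplicate library IDs: ",
         paste(unique(libraries$library_id[duplicated(libraries$library_id)]),
               collapse = ", "))
  if (!setequal(names(counts), libraries$library_id))
    stop("`counts` names and `libraries$library_id` must match")
  counts <- counts[libraries$library_id]

  pats <- unique(unlist(lapply(counts, names)))
  if (is.null(pats) || !length(pats)) stop("no patterns observed")
  # order patterns canonically by site-subset bitmask (NoEdit first)
  masks <- vapply(pats, .pattern_mask, 0, site_map = ref$site_map)
  pats <- pats[order(masks)]
  cm <- matrix(0, nrow = length(pats), ncol = length(counts),
               dimnames = list(pats, libraries$library_id))
  for (j in seq_along(counts)) {
    v <- counts[[j]]
    if (length(v)) cm[names(v), j] <- v
  }
  len <- nchar(ref$full_contig)
  rk <- sweep(cm / len, 2L, 1e9 / libraries$total_mapped, `*`)
  structure(list(counts = cm, rpkm = rk, libraries = libraries,
                 contig_length = len, site_map = ref$site_map),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat(sprintf("Pattern matrix: %d patterns x %d libraries (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(table(x$libraries$genotype)),
                            as.integer(table(x$libraries$genotype))),
                    collapse = ", ")))
  tot <- rowMeans(x$rpkm)
  top <- head(sort(tot, decreasing = TRUE), 5L)
  cat("  top patterns by mean RPKM: ",
      paste(sprintf("%s %.0f", names(top), top), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Filter patterns by group-mean RPKM
#'
#' Keeps a pattern when its mean RPKM is at or above `threshold` in at
#' least one genotype group ("in either" = OR, inclusive `>=`).  The
#' non-edited pattern is retained or dropped like any other.
#'
#' @param pm A [build_pattern_matrix()] result.
#' @param threshold Mean-RPKM threshold (study default: 10).
#' @param groups Genotype labels to evaluate; defaults to all genotypes
#'   present.  Unknown labels are an error.
#' @return The filtered `pattern_matrix`.
#' @export
filter_by_mean_rpkm <- function(pm, threshold = 10, groups = NULL) {
  stopifnot(inherits(pm, "pattern_matrix"))
  geno <- pm$libraries$genotype
  if (is.null(groups)) groups <- unique(geno)
  missing <- setdiff(groups, geno)
  if (length(missing))
    stop("unknown genotype label(s): ", paste(missing, collapse = ", "))
  keep <- rep(FALSE, nrow(pm$rpkm))
  for (g in groups)
    keep <- keep | rowMeans(pm$rpkm[, geno == g, drop = FALSE]) >= threshold
  pm$counts <- pm$counts[keep, , drop = FALSE]
  pm$rpkm <- pm$rpkm[keep, , drop = FALSE]
  pm
}

# group-mean RPKM vector for one genotype
.group_mean <- function(pm, group) {
  rowMeans(pm$rpkm[, pm$libraries$genotype == group, drop = FALSE])
}

#' Splice-isoform summary per genotype
#'
#' Averages mapped/full-length/truncated read counts over the libraries
#' of each genotype and reports the percentage of reads representing the
#' functional (full-length) and truncated receptor isoforms, at 1
#' decimal.
#'
#' @param stats Per-library stats data frame (rows as produced by
#'   [classify_raw_reads()]/[read_alignments()], possibly `rbind`-ed),
#'   plus a `genotype` column.
#' @return Data frame with one row per genotype: average mapped, full
#'   and truncated reads, `pct_full` and `pct_truncated` (percent of
#'   average mapped reads, rounded to 1 decimal; full precision in
#'   `frac_full`).
#' @export
splice_summary <- function(stats) {
  stopifnot(all(c("genotype", "mapped_reads", "full_reads",
                  "truncated_reads") %in% names(stats)))
  res <- lapply(split(stats, stats$genotype), function(s) {
    m <- mean(s$mapped_reads); f <- mean(s$full_reads)
    t <- mean(s$truncated_reads)
    data.frame(genotype = s$genotype[1L], n_libraries = nrow(s),
               avg_mapped_reads = m, avg_full_reads = f,
               avg_truncated_reads = t,
               frac_full = if (m > 0) f / m else NA_real_,
               pct_full = if (m > 0) round(100 * f / m, 1) else NA_real_,
               pct_truncated = if (m > 0) round(100 * t / m, 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
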