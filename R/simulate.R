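# Synthetic amplicon-read generator.
#
# Emulates the study design the pipeline was built for: amplicon deep
# sequencing of the 5-Ht2cr exon IV-VI RT-PCR product in choroid plexus,
# twelve cDNA libraries (six biological replicates for each of two
# genotypes), every read covering the whole amplicon.  Each read draws a
# splice isoform (Bernoulli), full-length reads draw an editing pattern,
# edited sites are written as 'G' on the sense strand, and i.i.d. uniform
# per-base substitution errors are applied on top (also at editing sites,
# which creates realistic false A<->G flips at rate error_rate/3 per site).

#' Genotype simulation profile
#'
#' The generative model of one genotype: the probability that a read
#' derives from the full-length splice isoform, and the distribution of
#' editing patterns over full-length reads (must include `"NoEdit"`).
#'
#' @param name Genotype name, e.g. `"WT"`.
#' @param splice_full_fraction Probability in `[0, 1]` that a read is
#'   full-length (exon Vb retained).
#' @param pattern_probs Named numeric vector of pattern probabilities
#'   over full-length reads, summing to 1; names are canonical pattern
#'   labels and must include `"NoEdit"`.
#' @param site_map Site map used to validate the pattern labels.
#' @return A `genotype_profile` object.
#' @examples
#' genotype_profile("WT", 0.45, c(NoEdit = 0.3, D = 0.5, CD = 0.2))
#' @export
genotype_profile <- function(name, splice_full_fraction, pattern_probs,
                             site_map = default_site_map()) {
  stopifnot(is.numeric(splice_full_fraction),
            splice_full_fraction >= 0, splice_full_fraction <= 1)
  if (is.null(names(pattern_probs)) || any(names(pattern_probs) == ""))
    stop("`pattern_probs` must be a fully named vector")
  if (anyDuplicated(names(pattern_probs)))
    stop("duplicated pattern labels in `pattern_probs`")
  if (!.NOEDIT %in% names(pattern_probs))
    stop("`pattern_probs` must include \"", .NOEDIT, "\"")
  # canonicalize + validate every label against the 2^n universe
  canon <- vapply(names(pattern_probs), function(l)
    make_pattern_label(parse_pattern_label(l, site_map), site_map), "")
  if (any(canon != names(pattern_probs)))
    stop("non-canonical pattern label(s): ",
         paste(names(pattern_probs)[canon != names(pattern_probs)],
               collapse = ", "))
  if (any(pattern_probs < 0))
    stop("negative pattern probabilities")
  if (abs(sum(pattern_probs) - 1) > 1e-9)
    stop("pattern probabilities must sum to 1 (got ",
         format(sum(pattern_probs)), ")")
  structure(list(name = name,
                 splice_full_fraction = splice_full_fraction,
                 pattern_probs = pattern_probs),
            class = "genotype_profile")
}

#' @export
print.genotype_profile <- function(x, ...) {
  cat(sprintf("Genotype profile '%s': %.1f%% full-length, %d patterns\n",
              x$name, 100 * x$splice_full_fraction, length(x$pattern_probs)))
  top <- sort(x$pattern_probs, decreasing = TRUE)
  top <- head(top[names(top) != .NOEDIT], 5L)
  cat(sprintf("  NoEdit %.3f; top edited: %s\n",
              x$pattern_probs[[.NOEDIT]],
              paste(sprintf("%s %.3f", names(top), top), collapse = ", ")))
  invisible(x)
}

#' Genotype profile from per-site marginal editing probabilities
#'
#' Alternative parameterization: sites edited independently with the
#' given marginal probabilities.  The full `2^n` pattern distribution is
#' enumerated (products of per-site probabilities); patterns with zero
#' probability are dropped except `"NoEdit"`.
#'
#' @inheritParams genotype_profile
#' @param marginals Named numeric vector of per-site editing
#'   probabilities; names must be exactly the site labels.
#' @return A [genotype_profile()].
#' @export
profile_from_site_marginals <- function(name, splice_full_fraction, marginals,
                                        site_map = default_site_map()) {
  if (!setequal(names(marginals), site_map$label))
    stop("`marginals` must be named with exactly the site labels")
  p <- marginals[site_map$label]
  stopifnot(all(p >= 0), all(p <= 1))
  labs <- pattern_universe(site_map)
  n <- nrow(site_map)
  masks <- 0:(2^n - 1L)
  prob <- rep(1, length(masks))
  for (b in seq_len(n)) {
    on <- bitwAnd(masks, bitwShiftL(1L, b - 1L)) > 0L
    prob <- prob * ifelse(on, p[b], 1 - p[b])
  }
  keep <- prob > 0 | labs == .NOEDIT
  genotype_profile(name, splice_full_fraction,
                   setNames(prob[keep], labs[keep]), site_map)
}

#' Built-in WT/LoxP genotype profile pair
#'
#' A reference profile pair emulating Snord115-perturbation data in mouse
#' choroid plexus: a D-site-dominant editing-pattern distribution (the
#' single-D isoform is ~61% of edited transcripts in WT), overall editing
#' levels of 69% (WT) and 64% (LoxP), splice full-length fractions of
#' 45.2% / 45.3%, and WT/LoxP pattern probability ratios equal to the
#' fold changes the pipeline is expected to recover (e.g. BCD 4.9,
#' AECD 2.8, ABCD 2.5, ABD 1.75, AC 1.6).  Intended for end-to-end
#' parameter-recovery tests.
#'
#' @return A list with elements `WT` and `LoxP`, both [genotype_profile()]
#'   objects defined on the same pattern set.
#' @examples
#' pp <- snord115_profile_pair()
#' pp$WT$pattern_probs[["BCD"]] / pp$LoxP$pattern_probs[["BCD"]]  # 4.9
#' @export
snord115_profile_pair <- function() {
  # WT pattern weights (arbitrary RPKM-like units) and WT/LoxP ratios for
  # the differentially edited patterns
  wt <- c(CD = 126959, AD = 44104.5, ABD = 32223, ED = 23259, ACD = 19010,
          ABCD = 12761, E = 11309, AC = 5546, AECD = 3544, BCD = 2631,
          CDH = 262, "2AD" = 64.5, ADG = 61.5, ABDG = 44, "1ABD" = 35.5,
          ABCDG = 24.6, ABCDF = 21, "2ABCD" = 19.5, "1ABCD" = 19,
          ABCDH = 12, "1AC" = 11)
  fc <- c(CD = 1.2, AD = 1.3, ABD = 1.75, ED = 1.2, ACD = 1.3,
          ABCD = 2.5, E = 0.64, AC = 1.6, AECD = 2.8, BCD = 4.9,
          CDH = 3.3, "2AD" = 1.46, ADG = 1.34, ABDG = 1.8, "1ABD" = 1.6,
          ABCDG = 3.2, ABCDF = 3.2, "2ABCD" = 2.9, "1ABCD" = 5,
          ABCDH = 3.6, "1AC" = 2.33)
  # minor background patterns, unchanged between genotypes
  filler <- c("2D" = 12000, DG = 6000, "1D" = 3000, DH = 2223,
              B = 30000, C = 25000, A = 20000, BC = 14341)
  wt_edited_total <- 1011500          # total edited weight, WT
  level_wt <- 0.69                    # overall editing level, WT
  level_loxp <- 0.64                  # overall editing level, LoxP
  d_wt <- wt_edited_total - sum(wt) - sum(filler)   # single-D isoform, ~61%
  noedit_wt <- wt_edited_total * (1 - level_wt) / level_wt
  total <- wt_edited_total + noedit_wt
  w_wt <- c(wt, filler, D = d_wt, NoEdit = noedit_wt)

  loxp_edited_total <- level_loxp * total
  lx <- wt / fc
  d_loxp <- loxp_edited_total - sum(lx) - sum(filler)
  noedit_loxp <- total - loxp_edited_total
  w_lx <- c(lx, filler, D = d_loxp, NoEdit = noedit_loxp)
  # equal totals by construction => probability ratios == weight ratios
  stopifnot(abs(sum(w_wt) - sum(w_lx)) < 1e-6)

  list(WT = genotype_profile("WT", 0.452, w_wt / sum(w_wt)),
       LoxP = genotype_profile("LoxP", 0.453, w_lx / sum(w_lx)))
}

#' Simulation design
#'
#' @param genotypes List of [genotype_profile()] objects (default: the
#'   built-in [snord115_profile_pair()]).
#' @param replicates_per_genotype Libraries per genotype (default 6, the
#'   emulated study layout: 6 + 6 = 12 libraries).
#' @param reads_per_library Reads per library.
#' @param per_base_error_rate i.i.d. per-base substitution error
#'   probability (default 0.005, an Ion-PGM-like substitution rate).
#' @param seed Master seed; per-library seeds are derived from it (see
#'   [simulate_design()]).
#' @return A `sim_design` list.
#' @export
sim_design <- function(genotypes = snord115_profile_pair(),
                       replicates_per_genotype = 6L,
                       reads_per_library = 10000L,
                       per_base_error_rate = 0.005,
                       seed = 1L) {
  stopifnot(length(genotypes) >= 1L,
            all(vapply(genotypes, inherits, TRUE, "genotype_profile")))
  replicates_per_genotype <- as.integer(replicates_per_genotype)
  if (is.na(replicates_per_genotype) || replicates_per_genotype < 1L)
    stop("`replicates_per_genotype` must be a positive integer")
  if (reads_per_library < 1L)
    stop("`reads_per_library` must be positive")
  stopifnot(per_base_error_rate >= 0, per_base_error_rate < 1)
  structure(list(genotypes = genotypes,
                 replicates_per_genotype = replicates_per_genotype,
                 reads_per_library = as.integer(reads_per_library),
                 per_base_error_rate = per_base_error_rate,
                 seed = as.integer(seed)),
            class = "sim_design")
}

# Deterministic per-library seed derived from the master seed: a simple
# 31-bit multiplicative hash, documented so runs are reproducible.
.library_seed <- function(master_seed, library_index) {
  as.integer((as.numeric(master_seed) * 48271 + library_index * 16807) %%
               2147483647)
}

.BASES_RAW <- charToRaw("ACGT")

# Apply i.i.d. substitution errors in place on a raw base matrix
# (positions x reads); returns list(mat, read, pos) with injected
# error coordinates.
.inject_errors <- function(mat, error_rate) {
  if (error_rate <= 0 || length(mat) == 0L)
    return(list(mat = mat, read = integer(0), pos = integer(0)))
  n_cells <- length(mat)
  n_err <- rbinom(1L, n_cells, error_rate)
  if (n_err == 0L)
    return(list(mat = mat, read = integer(0), pos = integer(0)))
  idx <- sample.int(n_cells, n_err)
  cur <- match(mat[idx], .BASES_RAW)
  new <- ((cur - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L) + 1L
  mat[idx] <- .BASES_RAW[new]
  nr <- nrow(mat)
  list(mat = mat,
       read = ((idx - 1L) %/% nr) + 1L,
       pos = ((idx - 1L) %% nr) + 1L)
}

# Column-wise raw matrix -> character vector of sequences
.mat_to_strings <- function(mat) {
  if (length(mat) == 0L) return(character(0))
  s <- rawToChar(as.raw(mat))
  nr <- nrow(mat)
  substring(s, seq(1L, nchar(s), by = nr), seq(nr, nchar(s), by = nr))
}

#' Simulate one amplicon library
#'
#' Draws `n_reads` independent full-amplicon reads: splice isoform ~
#' Bernoulli(`splice_full_fraction`); for full-length reads an editing
#' pattern ~ `pattern_probs`, with every edited site written as 'G' on
#' the sense strand; i.i.d. per-base substitution errors at `error_rate`
#' (uniform over the three alternative bases, editing sites included).
#' Deterministic given `seed`.
#'
#' @param ref An [amplicon_reference()].
#' @param profile A [genotype_profile()].
#' @param n_reads Number of reads.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param library_id Library identifier used in read names and truth rows.
#' @return A list: `reads` (named character vector of read sequences) and
#'   `truth`, a data frame with one row per read (`read_id`, `library_id`,
#'   `isoform` of `"full"`/`"truncated"`, `pattern` (`NA` for truncated
#'   reads, which lack exon Vb), `n_errors`, `error_positions`
#'   (comma-separated 1-based read positions)).
#' @examples
#' ref <- default_amplicon_reference()
#' p <- genotype_profile("toy", 1, c(NoEdit = 0.5, D = 0.5))
#' sim <- simulate_library(ref, p, 5, error_rate = 0, seed = 1)
#' sim$truth$pattern
#' @export
simulate_library <- function(ref, profile, n_reads, error_rate = 0,
                             seed = NULL, library_id = "lib1") {
  stopifnot(inherits(ref, "amplicon_reference"),
            inherits(profile, "genotype_profile"), n_reads > 0)
  if (!is.null(seed)) set.seed(seed)
  n_reads <- as.integer(n_reads)
  labs <- names(profile$pattern_probs)
  # validate against the pattern universe (unknown labels rejected in
  # genotype_profile(), but the profile may carry a foreign site map)
  for (l in labs) parse_pattern_label(l, ref$site_map)

  is_full <- runif(n_reads) < profile$splice_full_fraction
  n_full <- sum(is_full)
  n_tr <- n_reads - n_full
  pat <- character(n_reads)
  pat[!is_full] <- NA_character_

  full_tmpl <- charToRaw(ref$full_contig)
  tr_tmpl <- charToRaw(ref$truncated_contig)
  site1 <- .site_pos1(ref)

  reads <- character(n_reads)
  n_err <- integer(n_reads)
  err_pos <- character(n_reads)

  if (n_full > 0L) {
    draw <- sample(labs, n_full, replace = TRUE, prob = profile$pattern_probs)
    pat[is_full] <- draw
    m <- matrix(rep(full_tmpl, n_full), nrow = length(full_tmpl))
    g <- charToRaw("G")
    for (l in unique(draw)) {
      sites <- parse_pattern_label(l, ref$site_map)
      if (!length(sites)) next
      cols <- which(draw == l)
      m[site1[match(sites, ref$site_map$label)], cols] <- g
    }
    e <- .inject_errors(m, error_rate)
    reads[is_full] <- .mat_to_strings(e$mat)
    idx_full <- which(is_full)
    if (length(e$read)) {
      tab <- tapply(e$pos, e$read, function(p) paste(sort(p), collapse = ","))
      cnt <- tabulate(e$read, nbins = n_full)
      n_err[idx_full] <- cnt
      err_pos[idx_full[as.integer(names(tab))]] <- as.character(tab)
    }
  }
  if (n_tr > 0L) {
    m <- matrix(rep(tr_tmpl, n_tr), nrow = length(tr_tmpl))
    e <- .inject_errors(m, error_rate)
    reads[!is_full] <- .mat_to_strings(e$mat)
    idx_tr <- which(!is_full)
    if (length(e$read)) {
      tab <- tapply(e$pos, e$read, function(p) paste(sort(p), collapse = ","))
      cnt <- tabulate(e$read, nbins = n_tr)
      n_err[idx_tr] <- cnt
      err_pos[idx_tr[as.integer(names(tab))]] <- as.character(tab)
    }
  }
  ids <- sprintf("%s_r%06d", library_id, seq_len(n_reads))
  names(reads) <- ids
  truth <- data.frame(read_id = ids, library_id = library_id,
                      isoform = ifelse(is_full, "full", "truncated"),
                      pattern = pat, n_errors = n_err,
                      error_positions = err_pos,
                      stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate a full multi-library design to disk
#'
#' Writes one FASTQ per library (Phred+33, constant quality), a combined
#' truth TSV with per-read ground truth, and a flat key=value manifest
#' recording every design parameter.  Library seeds are derived
#' deterministically from the master seed, so two runs of the same design
#' are byte-identical.
#'
#' @param ref An [amplicon_reference()].
#' @param design A [sim_design()].
#' @param out_dir Output directory (created if missing).
#' @param quality_char Constant Phred+33 quality character.
#' @return Invisibly, a data frame describing the libraries
#'   (`library_id`, `genotype`, `fastq`, `seed`, `n_reads`).
#' @export
simulate_design <- function(ref, design, out_dir, quality_char = "I") {
  stopifnot(inherits(design, "sim_design"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  libs <- list(); truths <- list(); k <- 0L
  for (g in seq_along(design$genotypes)) {
    prof <- design$genotypes[[g]]
    for (r in seq_len(design$replicates_per_genotype)) {
      k <- k + 1L
      lib_id <- sprintf("%s_rep%d", prof$name, r)
      lib_seed <- .library_seed(design$seed, k)
      sim <- simulate_library(ref, prof, design$reads_per_library,
                              error_rate = design$per_base_error_rate,
                              seed = lib_seed, library_id = lib_id)
      fq <- file.path(out_dir, paste0(lib_id, ".fastq"))
      .write_fastq(sim$reads, fq, quality_char)
      tr <- sim$truth
      tr$genotype <- prof$name
      truths[[k]] <- tr
      libs[[k]] <- data.frame(library_id = lib_id, genotype = prof$name,
                              fastq = fq, seed = lib_seed,
                              n_reads = design$reads_per_library,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, libs)
  truth <- do.call(rbind, truths)
  write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # on-disk manifest uses paths relative to out_dir so identical designs
  # produce byte-identical files wherever they are written
  rel <- manifest
  rel$fastq <- basename(rel$fastq)
  write.table(rel, file.path(out_dir, "libraries.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  keyval <- c(master_seed = design$seed,
              replicates_per_genotype = design$replicates_per_genotype,
              reads_per_library = design$reads_per_library,
              per_base_error_rate = design$per_base_error_rate,
              genotypes = paste(vapply(design$genotypes, `[[`, "", "name"),
                                collapse = ","),
              full_contig_length = nchar(ref$full_contig),
              truncated_contig_length = nchar(ref$truncated_contig),
              n_libraries = k)
  writeLines(paste0(names(keyval), "=", keyval),
             file.path(out_dir, "manifest.txt"))
  invisible(manifest)
}

.write_fastq <- function(reads, path, quality_char = "I") {
  quals <- strrep(quality_char, nchar(reads))
  con <- file(path, "wb")  # binary: fixed LF line endings => reproducible
  on.exit(close(con))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n", quals),
             con, sep = "\n")
  invisible(path)
}

#' Count-level library simulation
#'
#' Draws per-library pattern/isoform counts directly from the profile's
#' multinomial read distribution, i.e. the exact marginal law of
#' [simulate_library()] at `error_rate = 0` without materializing read
#' sequences.  Useful for statistical calibration experiments at
#' realistic depths.
#'
#' @param profile A [genotype_profile()].
#' @param n_reads Reads per library (the multinomial size).
#' @param n_libraries Number of independent libraries to draw.
#' @param seed Optional integer seed.
#' @return A list: `counts` (patterns x libraries integer matrix of
#'   full-length pattern counts), `truncated` (per-library truncated-read
#'   counts) and `total_mapped` (per-library totals, all equal
#'   `n_reads`).
#' @export
simulate_pattern_counts <- function(profile, n_reads, n_libraries = 1L,
                                    seed = NULL) {
  stopifnot(inherits(profile, "genotype_profile"), n_reads > 0,
            n_libraries >= 1L)
  if (!is.null(seed)) set.seed(seed)
  f <- profile$splice_full_fraction
  probs <- c(truncated = 1 - f, f * profile$pattern_probs)
  x <- rmultinom(n_libraries, size = n_reads, prob = probs)
  list(counts = x[-1L, , drop = FALSE],
       truncated = x[1L, ],
       total_mapped = rep(as.integer(n_reads), n_libraries))
}
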