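# Read ingestion: splice-isoform assignment and per-site base calls.
#
# Two routes produce the same per-read observations: read_alignments()
# consumes SAM/BAM produced by an external aligner (per-read CIGAR walked
# to reference-coordinate base calls, mapping-quality filtered), and
# classify_raw_reads() is a built-in two-contig classifier for raw
# FASTQ/FASTA so the pipeline runs without external tools (global edit
# distance against both contigs in both orientations; smaller distance
# wins, ties are unassigned).

.COMP <- {
  x <- raw(256)
  x[as.integer(charToRaw("ACGTN"))] <- charToRaw("TGCAN")
  x
}

.revcomp_raw <- function(r) rev(.COMP[as.integer(r)])

.revcomp_chr <- function(s) rawToChar(.revcomp_raw(charToRaw(s)))

.empty_obs <- function() {
  data.frame(read_id = character(0), library_id = character(0),
             contig = character(0), mapq = integer(0),
             edit_dist = integer(0), site_bases = character(0),
             covered_all_sites = logical(0),
             has_indel_in_window = logical(0), stringsAsFactors = FALSE)
}

.stats_row <- function(library_id, total = 0L, full = 0L, truncated = 0L,
                       unassigned = 0L, unmapped = 0L, low_mapq = 0L,
                       malformed = 0L) {
  data.frame(library_id = library_id, total_reads = total,
             mapped_reads = full + truncated, full_reads = full,
             truncated_reads = truncated, unassigned = unassigned,
             discarded_unmapped = unmapped, discarded_by_mapq = low_mapq,
             discarded_malformed = malformed, stringsAsFactors = FALSE)
}

#' Classify raw amplicon reads against the two splice contigs
#'
#' Assigns each read to the full-length or truncated contig by global
#' edit distance (both orientations tried, the better one kept); ties
#' between contigs give `"unassigned"`.  For full-contig reads the bases
#' at the eleven editing-site positions are extracted from the
#' alignment.  Reads whose length matches a contig take a fast
#' mismatch-counting path; anything else falls back to full dynamic
#' programming (`utils::adist`).
#'
#' @param x A FASTQ/FASTA path, a character vector of read sequences, or
#'   a [Biostrings::DNAStringSet].
#' @param ref An [amplicon_reference()].
#' @param library_id Library identifier attached to the observations.
#' @return A list with `observations` (one row per read: `read_id`,
#'   `contig`, `edit_dist`, `site_bases`, `covered_all_sites`,
#'   `has_indel_in_window`) and `stats` (a one-row library tally; every
#'   input read lands in exactly one of full/truncated/unassigned).
#' @examples
#' ref <- default_amplicon_reference()
#' classify_raw_reads(c(r1 = ref$full_contig), ref)$observations$contig
#' @export
classify_raw_reads <- function(x, ref, library_id = "lib1") {
  stopifnot(inherits(ref, "amplicon_reference"))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    fmt <- if (grepl("\\.(fa|fasta)$", x, ignore.case = TRUE)) "fasta"
           else "fastq"
    x <- Biostrings::readDNAStringSet(x, format = fmt)
  }
  if (inherits(x, "DNAStringSet")) {
    ids <- names(x)
    chars <- unname(as.character(x))
  } else {
    ids <- names(x)
    chars <- toupper(unname(as.character(x)))
  }
  n <- length(chars)
  if (n == 0L)
    return(list(observations = .empty_obs(),
                stats = .stats_row(library_id)))
  if (is.null(ids)) ids <- sprintf("read%06d", seq_len(n))

  full <- ref$full_contig; trc <- ref$truncated_contig
  Lf <- nchar(full); Lt <- nchar(trc)
  gap <- abs(Lf - Lt)      # lower bound on cross-contig edit distance
  f_raw <- charToRaw(full); f_rc <- .revcomp_raw(f_raw)
  t_raw <- charToRaw(trc); t_rc <- .revcomp_raw(t_raw)
  site1 <- .site_pos1(ref)
  win <- .site_window1(ref)

  contig <- rep("unassigned", n)
  dist <- rep(NA_integer_, n)
  sbases <- rep(NA_character_, n)
  covered <- rep(FALSE, n)
  indel <- rep(FALSE, n)
  slow <- rep(FALSE, n)
  w <- nchar(chars)

  # fast path: length-matched reads, mismatch counting in both orientations
  for (tgt in list(list(len = Lf, fwd = f_raw, rev = f_rc, lab = "full"),
                   list(len = Lt, fwd = t_raw, rev = t_rc, lab = "truncated"))) {
    idx <- which(w == tgt$len)
    if (!length(idx)) next
    M <- matrix(charToRaw(paste(chars[idx], collapse = "")), nrow = tgt$len)
    d_fwd <- colSums(M != tgt$fwd)
    d_rev <- colSums(M != tgt$rev)
    d_ub <- pmin(d_fwd, d_rev)
    ok <- d_ub < gap
    slow[idx[!ok]] <- TRUE
    hit <- idx[ok]
    contig[hit] <- tgt$lab
    dist[hit] <- as.integer(d_ub[ok])
    if (tgt$lab == "full" && any(ok)) {
      fwd_ok <- ok & d_fwd <= d_rev
      rev_ok <- ok & d_fwd > d_rev
      if (any(fwd_ok)) {
        sb <- .mat_to_strings(M[site1, fwd_ok, drop = FALSE])
        sbases[idx[fwd_ok]] <- sb
      }
      if (any(rev_ok)) {
        rows <- .COMP[as.integer(M[Lf - site1 + 1L, rev_ok, drop = FALSE])]
        sb <- .mat_to_strings(matrix(rows, nrow = length(site1)))
        sbases[idx[rev_ok]] <- sb
      }
      covered[hit] <- TRUE
    }
  }
  slow[w != Lf & w != Lt] <- TRUE

  # slow path: full DP edit distance against both contigs, both orientations
  for (i in which(slow)) {
    r <- chars[i]
    rc <- .revcomp_chr(r)
    d4 <- c(adist(r, full), adist(rc, full), adist(r, trc), adist(rc, trc))
    d_full <- min(d4[1:2]); d_tr <- min(d4[3:4])
    if (d_full == d_tr) next               # tie -> unassigned
    if (d_full < d_tr) {
      contig[i] <- "full"; dist[i] <- as.integer(d_full)
      r_or <- if (d4[1] <= d4[2]) r else rc
      al <- .align_to_ref(full, r_or, site1, win)
      sbases[i] <- al$site_bases
      covered[i] <- al$covered
      indel[i] <- al$indel
    } else {
      contig[i] <- "truncated"; dist[i] <- as.integer(d_tr)
    }
  }

  obs <- data.frame(read_id = ids, library_id = library_id, contig = contig,
                    mapq = NA_integer_, edit_dist = dist,
                    site_bases = sbases, covered_all_sites = covered,
                    has_indel_in_window = indel, stringsAsFactors = FALSE)
  stats <- .stats_row(library_id, total = n, full = sum(contig == "full"),
                      truncated = sum(contig == "truncated"),
                      unassigned = sum(contig == "unassigned"))
  list(observations = obs, stats = stats)
}

# Global alignment of one read to the full contig (adist traceback);
# returns the site-base string, full-coverage flag, and whether an indel
# touches the site window.  Deleted sites yield 'N' and are not covered.
.align_to_ref <- function(refseq, read, site1, win) {
  d <- adist(refseq, read, counts = TRUE)
  trafo <- strsplit(attr(d, "trafos")[1, 1], "")[[1]]
  ref_chars_n <- nchar(refseq)
  read_chars <- strsplit(read, "")[[1]]
  bases <- rep(NA_character_, length(site1))
  got <- logical(length(site1))
  indel <- FALSE
  rp <- 0L; qp <- 0L
  for (op in trafo) {
    if (op == "M" || op == "S") {
      rp <- rp + 1L; qp <- qp + 1L
      k <- match(rp, site1)
      if (!is.na(k)) { bases[k] <- read_chars[qp]; got[k] <- TRUE }
    } else if (op == "I") {
      qp <- qp + 1L
      if (rp >= win[1] - 1L && rp < win[2]) indel <- TRUE
    } else if (op == "D") {
      rp <- rp + 1L
      if (rp >= win[1] && rp <= win[2]) indel <- TRUE
      k <- match(rp, site1)
      if (!is.na(k)) bases[k] <- "N"
    }
  }
  list(site_bases = paste(ifelse(is.na(bases), "N", bases), collapse = ""),
       covered = all(got), indel = indel)
}

#' Read per-read observations from SAM/BAM alignments
#'
#' Consumes alignments of amplicon reads against the two splice contigs.
#' Secondary and supplementary alignments are ignored; unmapped reads and
#' reads below `min_mapq` are tallied and excluded.  For reads on the
#' full-length contig the CIGAR is walked to produce reference-coordinate
#' base calls at every editing site; reads with an indel inside the site
#' window are flagged (`has_indel_in_window`) and reads not covering all
#' sites are flagged (`covered_all_sites = FALSE`) -- both remain counted
#' as mapped (the RPKM denominator is alignment-level) but are rejected
#' later by the pattern caller.
#'
#' @param path A SAM (`.sam`) or BAM file; SAM is converted on the fly
#'   via [Rsamtools::asBam()].
#' @param ref An [amplicon_reference()]; alignment target names must
#'   match the reference's two contig names.
#' @param min_mapq Minimum mapping quality; the conventional
#'   high-confidence default is 30.
#' @param library_id Library identifier attached to the observations.
#' @return A list with `observations` and `stats` as in
#'   [classify_raw_reads()] (here `mapq` is populated and `edit_dist` is
#'   `NA`).
#' @export
read_alignments <- function(path, ref, min_mapq = 30L, library_id = NULL) {
  stopifnot(inherits(ref, "amplicon_reference"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(library_id))
    library_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE))
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]

  seen <- levels(droplevels(b$rname[!is.na(b$rname)]))
  known <- c(ref$full_name, ref$truncated_name)
  if (length(setdiff(seen, known)))
    stop("alignment contig names do not match the reference (observed: ",
         paste(seen, collapse = ", "), "; expected: ",
         paste(known, collapse = ", "), ")")

  keep <- bitwAnd(b$flag, 256L) == 0L & bitwAnd(b$flag, 2048L) == 0L
  n_total <- sum(keep)
  unmapped <- keep & bitwAnd(b$flag, 4L) != 0L
  n_unmapped <- sum(unmapped)
  cand <- keep & !unmapped
  low <- cand & !is.na(b$mapq) & b$mapq < min_mapq
  n_low <- sum(low)
  use <- which(cand & !low)

  site1 <- .site_pos1(ref)
  win <- .site_window1(ref)
  n_use <- length(use)
  contig <- character(n_use); mapq <- integer(n_use)
  sbases <- rep(NA_character_, n_use)
  covered <- rep(FALSE, n_use); indel <- rep(FALSE, n_use)
  ok <- rep(TRUE, n_use)
  seqs <- as.character(b$seq[use])
  for (j in seq_len(n_use)) {
    i <- use[j]
    rn <- as.character(b$rname[i])
    mapq[j] <- b$mapq[i]
    if (rn == ref$truncated_name) { contig[j] <- "truncated"; next }
    contig[j] <- "full"
    res <- tryCatch(
      .sites_from_cigar(b$pos[i], b$cigar[i], seqs[j], site1, win),
      error = function(e) NULL)
    if (is.null(res)) { ok[j] <- FALSE; next }   # malformed CIGAR
    sbases[j] <- res$site_bases
    covered[j] <- res$covered
    indel[j] <- res$indel
  }
  n_malformed <- sum(!ok)
  obs <- data.frame(read_id = b$qname[use][ok], library_id = library_id,
                    contig = contig[ok], mapq = mapq[ok],
                    edit_dist = NA_integer_, site_bases = sbases[ok],
                    covered_all_sites = covered[ok],
                    has_indel_in_window = indel[ok],
                    stringsAsFactors = FALSE)
  stats <- .stats_row(library_id, total = n_total,
                      full = sum(obs$contig == "full"),
                      truncated = sum(obs$contig == "truncated"),
                      unmapped = n_unmapped, low_mapq = n_low,
                      malformed = n_malformed)
  list(observations = obs, stats = stats)
}

# Walk a CIGAR string, returning the read base at each 1-based reference
# site position.  M/=/X consume both sequences, I/S read only, D/N
# reference only, H/P neither.  Errors on malformed CIGARs.
.sites_from_cigar <- function(pos, cigar, seq, site1, win) {
  if (is.na(cigar) || cigar == "*") stop("missing CIGAR")
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  ops <- sub("^\\d+", "", toks)
  if (sum(lens[ops %in% c("M", "I", "S", "=", "X")]) != nchar(seq))
    stop("CIGAR does not match sequence length: ", cigar)
  bases <- rep(NA_character_, length(site1))
  indel <- FALSE
  rp <- pos; qp <- 1L
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X")) {
      hit <- which(site1 >= rp & site1 <= rp + len - 1L)
      if (length(hit))
        bases[hit] <- substring(seq, qp + site1[hit] - rp, qp + site1[hit] - rp)
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("I", "S")) {
      if (op == "I" && rp - 1L >= win[1] - 1L && rp - 1L < win[2]) indel <- TRUE
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      if (op == "D" && rp <= win[2] && rp + len - 1L >= win[1]) indel <- TRUE
      rp <- rp + len
    }
  }
  covered <- !anyNA(bases)
  list(site_bases = paste(ifelse(is.na(bases), "N", bases), collapse = ""),
       covered = covered, indel = indel)
}
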