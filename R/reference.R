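# Default synthetic amplicon reference.
#
# The real murine exon Vb sequence and exact site offsets are not bundled;
# the default is a fixed synthetic 209/114 nt contig pair with the eleven
# editing sites placed inside a 30 nt window of the exon Vb block, in the
# canonical 5'->3' order 1,2,3,A,B,E,C,D,F,G,H.  Real coordinates can be
# supplied through amplicon_reference() / read_reference().
.AMPEDIT_FULL <- paste0(
  "GACCGATGGTCCAGCAGCGTCGCTTCGTCACACATTATCCCCGGCGTGCTAGTCAAT",
  "ATTTCTGCTTCAATGTTAGATAAGATAAGATATCAGGTTCAAAGCAGCAAATTGACAGAGAGATTAAATACACCTATTAGTGTTCACATCATTAG",
  "AACTCGCACTATATGCCCGAGACTTGTCAGGCCGTCTCACCTCCATGAGCCGGTTAA")
.AMPEDIT_SITE_LABELS <- c("1", "2", "3", "A", "B", "E", "C", "D", "F", "G", "H")
.AMPEDIT_SITE_POS <- c(97L, 99L, 102L, 106L, 107L, 111L, 113L, 115L, 119L, 122L, 126L)
.AMPEDIT_DONOR <- 57L
.AMPEDIT_FULL_NAME <- "5-Ht2cr"
.AMPEDIT_TR_NAME <- "5-Ht2cr-tr"

#' Editing-site map
#'
#' An ordered map of A-to-I editing sites on the full-length contig.  The
#' canonical site order is genomic 5'->3'; pattern labels concatenate site
#' labels in this order (so the set \{D,A,E,C\} is labelled `"AECD"`).
#'
#' @param labels Character vector of unique single-character site labels.
#' @param positions Integer vector of 0-based offsets on the full-length
#'   contig, strictly increasing, same length as `labels`.
#' @return A `site_map` data frame with columns `label` and `position`.
#' @examples
#' default_site_map()
#' @export
editing_site_map <- function(labels, positions) {
  labels <- as.character(labels)
  positions <- as.integer(positions)
  if (length(labels) != length(positions))
    stop("`labels` and `positions` must have the same length")
  if (anyDuplicated(labels))
    stop("site labels must be unique: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (any(nchar(labels) != 1L))
    stop("site labels must be single characters")
  if (any(diff(positions) <= 0L))
    stop("site positions must be strictly increasing (non-monotonic site map)")
  sm <- data.frame(label = labels, position = positions,
                   stringsAsFactors = FALSE)
  class(sm) <- c("site_map", "data.frame")
  sm
}

#' @rdname editing_site_map
#' @export
default_site_map <- function() {
  editing_site_map(.AMPEDIT_SITE_LABELS, .AMPEDIT_SITE_POS)
}

#' Amplicon reference: two splice contigs plus the editing-site map
#'
#' Describes the RT-PCR amplicon used for deep sequencing: the full-length
#' splice variant containing exon Vb (and with it the editing sites) and
#' the truncated variant that lacks it.  Site positions refer to the
#' full-length contig and are 0-based internally.
#'
#' @param full_contig Full-length contig sequence (character, default 209 nt).
#' @param truncated_contig Truncated contig sequence (default 114 nt).
#' @param site_map A [editing_site_map()].
#' @param splice_donor_offset 0-based position on `full_contig` of the
#'   alternative 5' donor, i.e. the start of the block absent from the
#'   truncated contig.
#' @param full_name,truncated_name Contig identifiers used in FASTA and
#'   SAM/BAM files.
#' @return An `amplicon_reference` object.
#' @examples
#' ref <- default_amplicon_reference()
#' validate_reference(ref)
#' @export
amplicon_reference <- function(full_contig, truncated_contig, site_map,
                               splice_donor_offset,
                               full_name = .AMPEDIT_FULL_NAME,
                               truncated_name = .AMPEDIT_TR_NAME) {
  ref <- structure(list(
    full_contig = toupper(as.character(full_contig)),
    truncated_contig = toupper(as.character(truncated_contig)),
    site_map = site_map,
    splice_donor_offset = as.integer(splice_donor_offset),
    full_name = full_name,
    truncated_name = truncated_name
  ), class = "amplicon_reference")
  viol <- validate_reference(ref)
  if (length(viol))
    warning("reference has validation issues:\n  ",
            paste(viol, collapse = "\n  "))
  ref
}

#' @rdname amplicon_reference
#' @export
default_amplicon_reference <- function() {
  tr <- paste0(substr(.AMPEDIT_FULL, 1L, .AMPEDIT_DONOR),
               substr(.AMPEDIT_FULL, 153L, 209L))
  amplicon_reference(.AMPEDIT_FULL, tr, default_site_map(), .AMPEDIT_DONOR)
}

#' Validate an amplicon reference
#'
#' Checks every site-map invariant: unique labels, strictly increasing
#' positions, a site window of at most 30 nt, reference base 'A' at every
#' site, and all sites downstream of the prefix shared with the truncated
#' contig (sites live in exon Vb, which the truncated form lacks).
#'
#' @param ref An [amplicon_reference()].
#' @param max_window Maximum allowed span of the site window in nt.
#' @return Character vector of violations; empty when the reference is valid.
#' @export
validate_reference <- function(ref, max_window = 30L) {
  v <- character(0)
  sm <- ref$site_map
  if (anyDuplicated(sm$label))
    v <- c(v, "duplicate site labels")
  if (any(diff(sm$position) <= 0L))
    v <- c(v, "non-monotonic site map")
  span <- max(sm$position) - min(sm$position) + 1L
  if (span > max_window)
    v <- c(v, sprintf("site window spans %d nt (> %d)", span, max_window))
  if (any(sm$position < 0L) || any(sm$position >= nchar(ref$full_contig)))
    v <- c(v, "site position outside full contig")
  bases <- substring(ref$full_contig, sm$position + 1L, sm$position + 1L)
  bad <- sm$label[bases != "A"]
  if (length(bad))
    v <- c(v, sprintf("reference base at site %s is not 'A'", bad))
  if (any(sm$position < ref$splice_donor_offset))
    v <- c(v, "site upstream of the alternative splice donor (outside exon Vb)")
  exon_vb_len <- nchar(ref$full_contig) - nchar(ref$truncated_contig)
  if (any(sm$position >= ref$splice_donor_offset + exon_vb_len))
    v <- c(v, "site downstream of exon Vb (present in truncated contig)")
  v
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat("Amplicon reference\n")
  cat(sprintf("  %s: %d nt (full-length, exon Vb retained)\n",
              x$full_name, nchar(x$full_contig)))
  cat(sprintf("  %s: %d nt (truncated, exon Vb skipped)\n",
              x$truncated_name, nchar(x$truncated_contig)))
  cat(sprintf("  alternative 5' donor at offset %d (0-based)\n",
              x$splice_donor_offset))
  cat(sprintf("  %d editing sites [%s] in window %d-%d\n",
              nrow(x$site_map), paste(x$site_map$label, collapse = ""),
              min(x$site_map$position), max(x$site_map$position)))
  invisible(x)
}

#' Read and write an amplicon reference
#'
#' The on-disk form is a two-record FASTA (full-length first) plus a
#' 3-column TSV site map (`label`, `position`, `ref_base`) with 0-based
#' positions.
#'
#' @param fasta_path Path to the contig FASTA.
#' @param site_map_path Path to the site-map TSV.
#' @param splice_donor_offset 0-based donor offset; defaults to the length
#'   of the longest common prefix of the two contigs.
#' @return [read_reference()] returns an [amplicon_reference()];
#'   [write_reference()] returns the input invisibly.
#' @export
read_reference <- function(fasta_path, site_map_path,
                           splice_donor_offset = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 2L)
    stop("reference FASTA must contain exactly two records, found ",
         length(seqs))
  o <- order(Biostrings::width(seqs), decreasing = TRUE)
  seqs <- seqs[o]
  sm <- read.delim(site_map_path, stringsAsFactors = FALSE,
                   comment.char = "#",
                   colClasses = c(label = "character"))
  if (!all(c("label", "position") %in% names(sm)))
    stop("site map TSV needs columns `label` and `position`")
  if (is.null(splice_donor_offset)) {
    hdr <- grep("^#\\s*splice_donor_offset=",
                readLines(site_map_path, n = 5L), value = TRUE)
    if (length(hdr))
      splice_donor_offset <- as.integer(sub(".*=", "", hdr[1L]))
  }
  if (is.null(splice_donor_offset)) {
    a <- strsplit(as.character(seqs[[1]]), "")[[1]]
    b <- strsplit(as.character(seqs[[2]]), "")[[1]]
    n <- min(length(a), length(b))
    same <- a[seq_len(n)] == b[seq_len(n)]
    splice_donor_offset <- if (all(same)) n else which(!same)[1L] - 1L
  }
  amplicon_reference(as.character(seqs[[1]]), as.character(seqs[[2]]),
                     editing_site_map(sm$label, sm$position),
                     splice_donor_offset,
                     full_name = names(seqs)[1L],
                     truncated_name = names(seqs)[2L])
}

#' @rdname read_reference
#' @param ref An [amplicon_reference()].
#' @export
write_reference <- function(ref, fasta_path, site_map_path) {
  seqs <- Biostrings::DNAStringSet(c(ref$full_contig, ref$truncated_contig))
  names(seqs) <- c(ref$full_name, ref$truncated_name)
  Biostrings::writeXStringSet(seqs, fasta_path)
  sm <- ref$site_map
  sm$ref_base <- substring(ref$full_contig, sm$position + 1L, sm$position + 1L)
  writeLines(sprintf("# splice_donor_offset=%d", ref$splice_donor_offset),
             site_map_path)
  suppressWarnings(
    write.table(sm, site_map_path, sep = "\t", quote = FALSE,
                row.names = FALSE, append = TRUE))
  invisible(ref)
}

# 1-based site positions, internal convenience
.site_pos1 <- function(ref) ref$site_map$position + 1L

# [start, end] (1-based, inclusive) of the editing-site window
.site_window1 <- function(ref) {
  c(min(ref$site_map$position) + 1L, max(ref$site_map$position) + 1L)
}
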