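# Per-read editing-pattern calling.
#
# The unit of counting is the complete joint pattern of one read: a site
# base 'G' means edited (inosine is read as guanosine), 'A' unedited.
# Editing is only ever observed as A->G on the mRNA sense strand; reads
# arriving in reverse orientation are reverse-complemented upstream, and
# truncated-contig reads (no exon Vb) are structurally excluded.

#' Call editing patterns from read observations
#'
#' Converts full-contig read observations into per-read pattern labels.
#' Only observations with `contig == "full"` are considered; reads not
#' covering all sites are rejected as `partial_coverage`, reads with an
#' indel in the site window as `indel`.  Under the default `"strict"`
#' policy a read with any site base outside \{A, G\} is rejected
#' (`non_AG_base`), because a single miscalled site corrupts the joint
#' pattern; under `"lenient"` such sites count as unedited and the read
#' is kept.
#'
#' @param obs Observation data frame from [classify_raw_reads()] or
#'   [read_alignments()] (the `observations` element).
#' @param site_map The [editing_site_map()] the observations were made
#'   against.
#' @param policy `"strict"` (default) or `"lenient"` ambiguous-base
#'   handling.
#' @return A data frame with one row per full-contig read: `read_id`,
#'   `pattern` (canonical label or `NA` when rejected), `n_edited`, and
#'   `rejected_reason` in `none`/`non_AG_base`/`partial_coverage`/`indel`.
#' @export
call_patterns <- function(obs, site_map = default_site_map(),
                          policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  obs <- obs[obs$contig == "full", , drop = FALSE]
  n <- nrow(obs)
  ns <- nrow(site_map)
  out <- data.frame(read_id = obs$read_id,
                    pattern = rep(NA_character_, n),
                    n_edited = rep(NA_integer_, n),
                    rejected_reason = rep("none", n),
                    stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  out$rejected_reason[obs$has_indel_in_window] <- "indel"
  out$rejected_reason[!obs$covered_all_sites &
                        out$rejected_reason == "none"] <- "partial_coverage"
  cand <- which(out$rejected_reason == "none")
  if (!length(cand)) return(out)

  sb <- obs$site_bases[cand]
  stopifnot(all(nchar(sb) == ns))
  # ns x k base matrix
  M <- matrix(charToRaw(paste(sb, collapse = "")), nrow = ns)
  is_g <- M == charToRaw("G")
  is_a <- M == charToRaw("A")
  bad <- colSums(!(is_g | is_a)) > 0L
  if (policy == "strict") {
    out$rejected_reason[cand[bad]] <- "non_AG_base"
    cand <- cand[!bad]
    is_g <- is_g[, !bad, drop = FALSE]
  }
  if (!length(cand)) return(out)
  labs <- pattern_universe(site_map)          # indexed by bitmask + 1
  mask <- as.integer(2^(seq_len(ns) - 1L) %*% is_g)
  out$pattern[cand] <- labs[mask + 1L]
  out$n_edited[cand] <- as.integer(colSums(is_g))
  out
}

#' Tabulate pattern calls
#'
#' Counts accepted calls per pattern (including `"NoEdit"`); rejected
#' reads are tallied separately by reason.  The counts sum to the number
#' of accepted calls.
#'
#' @param calls Data frame from [call_patterns()].
#' @return A list: `counts` (named integer vector, pattern -> count),
#'   `rejected` (named integer vector by rejection reason) and
#'   `n_accepted`.
#' @export
count_patterns <- function(calls) {
  acc <- calls[calls$rejected_reason == "none", , drop = FALSE]
  counts <- integer(0)
  if (nrow(acc)) {
    tab <- table(acc$pattern)
    counts <- setNames(as.integer(tab), names(tab))
  }
  rej <- calls$rejected_reason[calls$rejected_reason != "none"]
  rejected <- integer(0)
  if (length(rej)) {
    tab <- table(rej)
    rejected <- setNames(as.integer(tab), names(tab))
  }
  list(counts = counts, rejected = rejected, n_accepted = nrow(acc))
}
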