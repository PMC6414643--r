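# Canonical editing-pattern labels.
#
# A pattern is the joint edited/unedited state of all mapped sites on one
# read.  Its label concatenates the labels of the edited sites in the
# site map's canonical 5'->3' order; the empty set is "NoEdit".  With 11
# sites there are 2^11 = 2048 possible labels.

.NOEDIT <- "NoEdit"

#' Canonical editing-pattern labels
#'
#' `make_pattern_label()` turns a set of edited-site labels into the
#' canonical pattern string; `parse_pattern_label()` is its exact inverse;
#' `pattern_universe()` enumerates all `2^n` labels.
#'
#' @param edited_sites Character vector (a set) of site labels; may be
#'   empty.
#' @param site_map A [editing_site_map()]; defines membership and the
#'   canonical order.
#' @return `make_pattern_label()`: a single string (`"NoEdit"` for the
#'   empty set).  `parse_pattern_label()`: a character vector of site
#'   labels in canonical order.  `pattern_universe()`: all labels, ordered
#'   by the site-subset bitmask (so `"NoEdit"` is first).
#' @examples
#' make_pattern_label(c("D", "A", "E", "C"))   # "AECD"
#' parse_pattern_label("1ABD")
#' length(pattern_universe())                  # 2048
#' @export
make_pattern_label <- function(edited_sites, site_map = default_site_map()) {
  edited_sites <- unique(as.character(edited_sites))
  if (length(edited_sites) == 0L) return(.NOEDIT)
  unknown <- setdiff(edited_sites, site_map$label)
  if (length(unknown))
    stop("unknown editing site label(s): ", paste(unknown, collapse = ", "))
  idx <- sort(match(edited_sites, site_map$label))
  paste(site_map$label[idx], collapse = "")
}

#' @rdname make_pattern_label
#' @param label A pattern label string.
#' @export
parse_pattern_label <- function(label, site_map = default_site_map()) {
  stopifnot(length(label) == 1L)
  if (identical(label, .NOEDIT)) return(character(0))
  sites <- strsplit(label, "")[[1]]
  unknown <- setdiff(sites, site_map$label)
  if (length(unknown))
    stop("unknown editing site label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(sites))
    stop("duplicated site label in pattern: ", label)
  sites[order(match(sites, site_map$label))]
}

#' @rdname make_pattern_label
#' @export
pattern_universe <- function(site_map = default_site_map()) {
  n <- nrow(site_map)
  masks <- 0:(2^n - 1L)
  bits <- vapply(seq_len(n) - 1L,
                 function(b) bitwAnd(masks, bitwShiftL(1L, b)) > 0L,
                 logical(length(masks)))
  labs <- apply(bits, 1L, function(m) paste(site_map$label[m], collapse = ""))
  labs[1L] <- .NOEDIT
  labs
}

# Bitmask of a site subset (bit i set <=> site i of the map edited);
# inverse of the pattern_universe() ordering.
.pattern_mask <- function(label, site_map = default_site_map()) {
  sites <- parse_pattern_label(label, site_map)
  sum(bitwShiftL(1L, match(sites, site_map$label) - 1L))
}
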