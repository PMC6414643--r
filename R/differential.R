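# Genotype differential statistics: per-pattern and per-site Student's
# t-tests on RPKM values, Benjamini-Hochberg FDR, fold changes and
# isoform percentages, and the overall editing level.

#' Fold changes with a safe zero convention
#'
#' Elementwise `mean1 / mean2`; a zero denominator yields `NA` (never
#' infinity).
#'
#' @param mean1,mean2 Numeric vectors of group means (group 1 is the
#'   numerator).
#' @return Numeric vector of fold changes.
#' @export
fold_changes <- function(mean1, mean2) {
  fc <- mean1 / mean2
  fc[mean2 == 0] <- NA_real_
  fc
}

# Graphpad-style significance stars from raw p-values
.sig_label <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

# Two-sided Student's (equal variance) t-test per matrix row, with the
# degenerate-case convention: both groups constant -> p = 1 if the means
# agree, p = 0 (with a warning) otherwise.
.row_ttests <- function(m, g1, g2, var_equal = TRUE) {
  vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, g1]; y <- m[i, g2]
    if (max(x) == min(x) && max(y) == min(y)) {
      if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
      warning("zero variance in both groups with unequal means (row ", i,
              "); p set to 0")
      return(0)
    }
    t.test(x, y, var.equal = var_equal)$p.value
  }, 0)
}

#' Per-pattern differential expression between two genotypes
#'
#' For every pattern in the (typically mean-RPKM-filtered) matrix:
#' group-mean RPKM, fold change (group 1 / group 2), a two-sided
#' Student's equal-variance t-test on the per-library RPKM values, and
#' Benjamini-Hochberg adjusted p-values computed jointly across all
#' tested patterns.  Percentages are each pattern's share of the
#' group-mean RPKM summed over edited patterns (the non-edited pattern
#' is excluded from the denominator).
#'
#' @param pm A [build_pattern_matrix()] result, usually after
#'   [filter_by_mean_rpkm()].
#' @param groups Character vector of two genotype labels; the first is
#'   the fold-change numerator.  Defaults to the genotypes in library
#'   order.
#' @param var_equal Use the classical equal-variance statistic (default);
#'   `FALSE` gives Welch.
#' @return Data frame with one row per pattern: `pattern`, `mean1`,
#'   `mean2`, `fold_change`, `p_value`, `sig`, `p_bh`, `pct1`, `pct2`;
#'   the compared groups are recorded in `attr(, "groups")`.
#' @export
differential_patterns <- function(pm, groups = NULL, var_equal = TRUE) {
  stopifnot(inherits(pm, "pattern_matrix"))
  groups <- .check_groups(pm, groups)
  geno <- pm$libraries$genotype
  g1 <- geno == groups[1L]; g2 <- geno == groups[2L]
  if (sum(g1) < 2L || sum(g2) < 2L)
    stop("need at least 2 libraries per group")
  m <- pm$rpkm
  mean1 <- rowMeans(m[, g1, drop = FALSE])
  mean2 <- rowMeans(m[, g2, drop = FALSE])
  p <- .row_ttests(m, g1, g2, var_equal)
  pct <- percent_of_edited(pm, groups)
  out <- data.frame(pattern = rownames(m), mean1 = mean1, mean2 = mean2,
                    fold_change = fold_changes(mean1, mean2),
                    p_value = p, sig = as.character(.sig_label(p)),
                    p_bh = p.adjust(p, method = "BH"),
                    pct1 = pct[, 1L], pct2 = pct[, 2L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  out
}

#' Pattern percentages of total edited expression
#'
#' `percent(pattern, group)` = group-mean RPKM of the pattern divided by
#' the sum of group-mean RPKM over all *edited* patterns (excluding
#' `"NoEdit"`), times 100.  `"NoEdit"` rows get `NA`.
#'
#' @inheritParams differential_patterns
#' @return Numeric matrix, patterns x 2 groups.
#' @export
percent_of_edited <- function(pm, groups = NULL) {
  stopifnot(inherits(pm, "pattern_matrix"))
  groups <- .check_groups(pm, groups)
  edited <- rownames(pm$rpkm) != .NOEDIT
  if (!any(edited)) stop("no edited patterns in the matrix")
  out <- vapply(groups, function(g) {
    gm <- .group_mean(pm, g)
    pct <- 100 * gm / sum(gm[edited])
    pct[!edited] <- NA_real_
    pct
  }, numeric(nrow(pm$rpkm)))
  rownames(out) <- rownames(pm$rpkm)
  out
}

#' Single-site contribution to editing
#'
#' Collapses the pattern matrix to the eleven sites: for each site the
#' per-library value is the RPKM sum over all patterns containing the
#' site (sites co-occur, so site percentages may sum to more than 100).
#' Group means, fold changes and Student's t-tests as in
#' [differential_patterns()]; BH correction is applied across the sites
#' only.  Percentages use the same edited-patterns denominator.
#'
#' @inheritParams differential_patterns
#' @return Data frame with one row per site: `site`, `mean1`, `mean2`,
#'   `fold_change`, `p_value`, `sig`, `p_bh`, `pct1`, `pct2`.
#' @export
site_contribution <- function(pm, groups = NULL, var_equal = TRUE) {
  stopifnot(inherits(pm, "pattern_matrix"))
  groups <- .check_groups(pm, groups)
  geno <- pm$libraries$genotype
  g1 <- geno == groups[1L]; g2 <- geno == groups[2L]
  sites <- pm$site_map$label
  member <- vapply(rownames(pm$rpkm), function(p) {
    s <- if (identical(p, .NOEDIT)) character(0) else
      parse_pattern_label(p, pm$site_map)
    sites %in% s
  }, logical(length(sites)))          # sites x patterns
  collapsed <- member %*% pm$rpkm     # sites x libraries
  rownames(collapsed) <- sites
  mean1 <- rowMeans(collapsed[, g1, drop = FALSE])
  mean2 <- rowMeans(collapsed[, g2, drop = FALSE])
  p <- .row_ttests(collapsed, g1, g2, var_equal)
  edited <- rownames(pm$rpkm) != .NOEDIT
  den1 <- sum(.group_mean(pm, groups[1L])[edited])
  den2 <- sum(.group_mean(pm, groups[2L])[edited])
  out <- data.frame(site = sites, mean1 = mean1, mean2 = mean2,
                    fold_change = fold_changes(mean1, mean2),
                    p_value = p, sig = as.character(.sig_label(p)),
                    p_bh = p.adjust(p, method = "BH"),
                    pct1 = 100 * mean1 / den1, pct2 = 100 * mean2 / den2,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  out
}

#' Overall editing level per genotype
#'
#' Percent edited = sum of group-mean RPKM over edited patterns divided
#' by the sum over all patterns (including the non-edited isoform),
#' times 100.
#'
#' @inheritParams differential_patterns
#' @return Data frame: `genotype`, `pct_edited`; plus the
#'   group-1-minus-group-2 difference in `attr(, "difference")`.
#' @export
overall_editing_level <- function(pm, groups = NULL) {
  stopifnot(inherits(pm, "pattern_matrix"))
  groups <- .check_groups(pm, groups)
  edited <- rownames(pm$rpkm) != .NOEDIT
  pct <- vapply(groups, function(g) {
    gm <- .group_mean(pm, g)
    100 * sum(gm[edited]) / sum(gm)
  }, 0)
  out <- data.frame(genotype = groups, pct_edited = pct, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "difference") <- unname(pct[1L] - pct[2L])
  out
}

# top-n rows by |log fold change|, restricted to FDR-significant
# patterns when any exist (raw |log FC| alone surfaces one-read noise)
.top_by_lfc <- function(pt, n = 5L) {
  ok <- is.finite(pt$fold_change) & pt$fold_change > 0
  if (any(pt$p_bh < 0.05 & ok, na.rm = TRUE)) ok <- ok & pt$p_bh < 0.05
  cand <- pt[ok, , drop = FALSE]
  cand[head(order(-abs(log(cand$fold_change))), n), , drop = FALSE]
}

.check_groups <- function(pm, groups) {
  geno <- unique(pm$libraries$genotype)
  if (is.null(groups)) groups <- geno
  if (length(groups) != 2L)
    stop("exactly two genotype groups required (got ",
         length(groups), ")")
  missing <- setdiff(groups, geno)
  if (length(missing))
    stop("unknown genotype label(s): ", paste(missing, collapse = ", "))
  as.character(groups)
}

#' Full differential analysis
#'
#' Bundles [differential_patterns()], [site_contribution()] and
#' [overall_editing_level()] into one classed result with print,
#' summary and plot methods.
#'
#' @inheritParams differential_patterns
#' @return An `editing_diff` object (list with `patterns`, `sites`,
#'   `editing_level`, `groups`).
#' @examples
#' pp <- snord115_profile_pair()
#' sim <- simulate_pattern_counts(pp$WT, 2e5, 6, seed = 1)
#' sim2 <- simulate_pattern_counts(pp$LoxP, 2e5, 6, seed = 2)
#' libs <- data.frame(
#'   library_id = sprintf("L%d", 1:12),
#'   genotype = rep(c("WT", "LoxP"), each = 6),
#'   total_mapped = c(sim$total_mapped, sim2$total_mapped))
#' cnt <- c(apply(sim$counts, 2, identity, simplify = FALSE),
#'          apply(sim2$counts, 2, identity, simplify = FALSE))
#' pm <- build_pattern_matrix(setNames(cnt, libs$library_id), libs,
#'                            default_amplicon_reference())
#' fit <- differential_analysis(filter_by_mean_rpkm(pm, 10),
#'                              groups = c("WT", "LoxP"))
#' fit
#' @export
differential_analysis <- function(pm, groups = NULL, var_equal = TRUE) {
  groups <- .check_groups(pm, groups)
  structure(list(patterns = differential_patterns(pm, groups, var_equal),
                 sites = site_contribution(pm, groups, var_equal),
                 editing_level = overall_editing_level(pm, groups),
                 groups = groups),
            class = "editing_diff")
}

#' @export
print.editing_diff <- function(x, n = 5L, ...) {
  g <- x$groups
  el <- x$editing_level
  cat(sprintf("Differential editing analysis: %s vs %s\n", g[1L], g[2L]))
  cat(sprintf("  overall editing level: %s %.1f%%, %s %.1f%% (diff %.1f)\n",
              el$genotype[1L], el$pct_edited[1L],
              el$genotype[2L], el$pct_edited[2L],
              attr(el, "difference")))
  pt <- x$patterns
  cat(sprintf("  %d patterns tested, %d with pBH < 0.05\n",
              nrow(pt), sum(pt$p_bh < 0.05, na.rm = TRUE)))
  cat("  top patterns by |log fold change|",
      if (any(pt$p_bh < 0.05, na.rm = TRUE)) " (pBH < 0.05)", ":\n",
      sep = "")
  top <- .top_by_lfc(pt, n)[, c("pattern", "mean1", "mean2", "fold_change",
                                "p_value", "p_bh", "sig")]
  print(format(top, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
summary.editing_diff <- function(object, alpha = 0.05, ...) {
  pt <- object$patterns; st <- object$sites
  cat(sprintf("Patterns tested: %d; raw p < %.2f: %d; pBH < %.2f: %d\n",
              nrow(pt), alpha, sum(pt$p_value < alpha),
              alpha, sum(pt$p_bh < alpha)))
  cat(sprintf("Sites with pBH < %.2f: %s\n", alpha,
              paste(st$site[st$p_bh < alpha], collapse = ", ")))
  print(object, ...)
  invisible(object)
}

#' @export
#' @importFrom graphics abline text plot
plot.editing_diff <- function(x, ...) {
  pt <- x$patterns
  ok <- is.finite(pt$fold_change) & pt$fold_change > 0
  lfc <- log2(pt$fold_change[ok])
  lp <- -log10(pt$p_value[ok])
  plot(lfc, lp, pch = 19,
       col = ifelse(pt$p_bh[ok] < 0.05, "firebrick", "grey50"),
       xlab = sprintf("log2 fold change (%s / %s)", x$groups[1L],
                      x$groups[2L]),
       ylab = "-log10 p (Student's t)", ...)
  abline(h = -log10(0.05), lty = 2, col = "grey70")
  lab <- pt$p_bh[ok] < 0.05
  if (any(lab))
    text(lfc[lab], lp[lab], pt$pattern[ok][lab], pos = 3, cex = 0.7)
  invisible(x)
}
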