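# small deterministic matrix fixture: two genotypes x 3 libraries
mk_pm <- function(rpkm_rows, genotypes = rep(c("WT", "LoxP"), each = 3)) {
  n <- length(genotypes)
  libs <- data.frame(library_id = sprintf("L%d", seq_len(n)),
                     genotype = genotypes, total_mapped = rep(1e6, n))
  counts <- lapply(seq_len(n), function(j)
    vapply(rpkm_rows, function(v) v[j] * 209 / 1000, 0))
  names(counts) <- libs$library_id
  build_pattern_matrix(counts, libs, .ref)
}

test_that("fold changes follow the group-mean ratio with NA on zero", {
  expect_equal(fold_changes(c(2631, 10), c(535, 0)), c(2631 / 535, NA))
  expect_equal(round(fold_changes(2631, 535), 1), 4.9)
})

test_that("pattern t-tests, stars and BH behave as specified", {
  pm <- mk_pm(list(
    D = c(100, 110, 90, 50, 55, 45),
    CD = c(20, 22, 18, 20.5, 21, 19),
    NoEdit = c(40, 41, 39, 60, 62, 58)))
  res <- differential_patterns(pm, groups = c("WT", "LoxP"))
  expect_identical(attr(res, "groups"), c("WT", "LoxP"))
  d <- res[res$pattern == "D", ]
  expect_equal(d$fold_change, 100 / 50)
  # equal-variance Student's t, two-sided, against stats::t.test directly
  tt <- t.test(c(100, 110, 90), c(50, 55, 45), var.equal = TRUE)
  expect_equal(d$p_value, tt$p.value)
  expect_true(all(res$p_bh >= res$p_value))
  expect_equal(res$p_bh, bh_stepup_oracle(res$p_value))

  # identical groups: fold change 1, p-value 1 by the degenerate rule
  same <- mk_pm(list(D = rep(10, 6), NoEdit = rep(5, 6)))
  r2 <- differential_patterns(same, c("WT", "LoxP"))
  expect_true(all(r2$fold_change == 1))
  expect_true(all(r2$p_value == 1))
  expect_identical(unique(r2$sig), "ns")

  # significance stars at the conventional cuts
  expect_identical(as.character(ampedit:::.sig_label(
    c(2e-1, 4e-2, 9e-3, 9e-4, 9e-5))),
    c("ns", "*", "**", "***", "****"))
})

test_that("BH step-up agrees with the hand-applied definition", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(bh_stepup_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("percentages cover edited patterns only and sum to 100", {
  pm <- mk_pm(list(D = rep(c(60, 30), each = 3),
                   CD = rep(c(40, 10), each = 3),
                   NoEdit = rep(c(100, 200), each = 3)))
  pct <- percent_of_edited(pm, c("WT", "LoxP"))
  expect_equal(pct["D", "WT"], 60)
  expect_equal(pct["CD", "LoxP"], 25)
  expect_true(all(is.na(pct["NoEdit", ])))
  expect_equal(colSums(pct, na.rm = TRUE), c(WT = 100, LoxP = 100))

  single <- mk_pm(list(D = rep(10, 6), NoEdit = rep(90, 6)))
  expect_equal(unname(percent_of_edited(single)["D", ]), c(100, 100))

  only_ne <- mk_pm(list(NoEdit = rep(1, 6)))
  expect_error(percent_of_edited(only_ne), "no edited patterns")
})

test_that("site collapsing sums patterns containing each site", {
  pm <- mk_pm(list(ABD = rep(c(30, 10), each = 3),
                   NoEdit = rep(5, 6)))
  # constant-but-unequal groups trip the degenerate t-test convention
  expect_warning(dp <- differential_patterns(pm, c("WT", "LoxP")),
                 "zero variance")
  expect_identical(dp$p_value[dp$pattern == "ABD"], 0)
  st <- suppressWarnings(site_contribution(pm, c("WT", "LoxP")))
  expect_true(all(st$p_value[st$site %in% c("A", "B", "D")] == 0))
  abd <- st$mean1[st$site %in% c("A", "B", "D")]
  expect_true(all(abd == 30))
  expect_equal(st$mean1[st$site == "C"], 0)
  expect_true(is.na(st$fold_change[st$site == "C"]))  # 0/0 -> NA

  # two overlapping patterns: site percentages can exceed 100 jointly
  pm2 <- mk_pm(list(D = rep(60, 6), CD = rep(40, 6), NoEdit = rep(1, 6)))
  st2 <- site_contribution(pm2)
  expect_equal(st2$pct1[st2$site == "D"], 100)   # D in both patterns
  expect_equal(st2$pct1[st2$site == "C"], 40)
  expect_gt(sum(st2$pct1), 100)
  # BH is computed across the 11 sites only
  expect_equal(st2$p_bh, bh_stepup_oracle(st2$p_value))
})

test_that("overall editing level uses the all-patterns denominator", {
  all_ne <- mk_pm(list(NoEdit = rep(10, 6)))
  expect_equal(overall_editing_level(all_ne)$pct_edited, c(0, 0))
  none_ne <- mk_pm(list(D = rep(10, 6), CD = rep(1, 6)))
  expect_equal(overall_editing_level(none_ne)$pct_edited, c(100, 100))

  # independent-site profile with only D at 0.6: editing level ~60%
  marg <- setNames(rep(0, 11), default_site_map()$label)
  marg["D"] <- 0.6
  prof <- profile_from_site_marginals("M", 1, marg)
  pm <- pm_from_count_sim(prof, {
    p2 <- prof; p2$name <- "M2"; p2
  }, n_reads = 2e4, seed = 81)
  lvl <- overall_editing_level(pm, c("M", "M2"))
  se3 <- 3 * 100 * sqrt(0.6 * 0.4 / (2e4 * 6))
  expect_true(all(abs(lvl$pct_edited - 60) < se3))
  expect_equal(attr(lvl, "difference"),
               lvl$pct_edited[1] - lvl$pct_edited[2])
})

test_that("differential_analysis bundles results with working methods", {
  pp <- snord115_profile_pair()
  pm <- filter_by_mean_rpkm(
    pm_from_count_sim(pp$WT, pp$LoxP, n_reads = 5e4, seed = 91), 10)
  fit <- differential_analysis(pm, groups = c("WT", "LoxP"))
  expect_s3_class(fit, "editing_diff")
  expect_identical(nrow(fit$sites), 11L)
  expect_setequal(fit$sites$site, default_site_map()$label)
  expect_output(print(fit), "overall editing level")
  expect_output(summary(fit), "Patterns tested")
  pf <- tempfile(fileext = ".png")
  png(pf); plot(fit); dev.off()
  expect_true(file.exists(pf))
  # group order convention: first group is the numerator
  rev_fit <- differential_analysis(pm, groups = c("LoxP", "WT"))
  d1 <- fit$patterns$fold_change[fit$patterns$pattern == "D"]
  d2 <- rev_fit$patterns$fold_change[rev_fit$patterns$pattern == "D"]
  expect_equal(d1 * d2, 1)
  expect_error(differential_analysis(pm, groups = c("WT")), "two")
})
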