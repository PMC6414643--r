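test_that("noise-free simulation writes exactly the expected sequences", {
  ref <- .ref
  p_ne <- genotype_profile("g", 1, c(NoEdit = 1))
  sim <- simulate_library(ref, p_ne, 50, error_rate = 0, seed = 3)
  expect_true(all(sim$reads == ref$full_contig))
  expect_true(all(sim$truth$pattern == "NoEdit"))

  # single-D profile: 'G' at site D, 'A' at the other ten sites
  p_d <- genotype_profile("g", 1, c(NoEdit = 0, D = 1))
  sim <- simulate_library(ref, p_d, 50, error_rate = 0, seed = 3)
  pos <- ref$site_map$position + 1L
  d <- ref$site_map$label == "D"
  for (r in sim$reads) {
    expect_identical(substr(r, pos[d], pos[d]), "G")
    expect_true(all(substring(r, pos[!d], pos[!d]) == "A"))
  }
  # truncated reads carry no pattern
  p_tr <- genotype_profile("g", 0, c(NoEdit = 1))
  sim <- simulate_library(ref, p_tr, 20, error_rate = 0, seed = 3)
  expect_true(all(sim$reads == ref$truncated_contig))
  expect_true(all(is.na(sim$truth$pattern)))
})

test_that("splice fraction is recovered within 3 binomial SDs", {
  p <- genotype_profile("g", 0.452, c(NoEdit = 1))
  n <- 1e5
  sim <- simulate_library(.ref, p, n, error_rate = 0, seed = 11)
  frac <- mean(sim$truth$isoform == "full")
  tol <- 3 * sqrt(0.452 * (1 - 0.452) / n)
  expect_lt(abs(frac - 0.452), tol)
})

test_that("pattern frequencies match the profile (chi-square GOF)", {
  pp <- snord115_profile_pair()
  prof <- pp$WT
  sim <- simulate_library(.ref, prof, 1e5, error_rate = 0, seed = 5)
  obs <- table(factor(sim$truth$pattern[sim$truth$isoform == "full"],
                      levels = names(prof$pattern_probs)))
  expect_gt(pooled_gof_p(obs, prof$pattern_probs), 0.01)
})

test_that("the error model injects uniform substitutions at the stated rate", {
  p <- genotype_profile("g", 1, c(NoEdit = 1))
  e <- 0.01
  sim <- simulate_library(.ref, p, 5000, error_rate = e, seed = 13)
  L <- nchar(.ref$full_contig)
  n_err <- sum(sim$truth$n_errors)
  expect_lt(abs(n_err / (5000 * L) - e), 3 * sqrt(e * (1 - e) / (5000 * L)))
  # false-edit rate at a site is about e/3 (A -> G specifically)
  pos_d <- .ref$site_map$position[.ref$site_map$label == "D"] + 1L
  g_at_d <- mean(substring(sim$reads, pos_d, pos_d) == "G")
  expect_lt(abs(g_at_d - e / 3), 4 * sqrt((e / 3) / 5000))
})

test_that("simulate_design writes a reproducible 12-library dataset", {
  des <- sim_design(reads_per_library = 200, per_base_error_rate = 0.005,
                    seed = 9)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- simulate_design(.ref, des, d1)
  expect_identical(nrow(m1), 12L)
  expect_length(list.files(d1, pattern = "\\.fastq$"), 12L)
  truth <- read.delim(file.path(d1, "truth.tsv"))
  expect_identical(nrow(truth), 12L * 200L)
  expect_true(all(is.na(truth$pattern[truth$isoform == "truncated"])))

  # same seed => byte-identical outputs
  simulate_design(.ref, des, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }

  # one replicate per genotype => 2 libraries
  des1 <- sim_design(replicates_per_genotype = 1, reads_per_library = 50,
                     seed = 9)
  d3 <- tempfile()
  expect_identical(nrow(simulate_design(.ref, des1, d3)), 2L)
  expect_error(sim_design(replicates_per_genotype = 0), "positive")
})

test_that("built-in WT/LoxP profile pair encodes the expected effect sizes", {
  pp <- snord115_profile_pair()
  for (g in pp) expect_equal(sum(g$pattern_probs), 1, tolerance = 1e-12)
  ratio <- function(pat) pp$WT$pattern_probs[[pat]] / pp$LoxP$pattern_probs[[pat]]
  expect_equal(ratio("BCD"), 4.9, tolerance = 1e-9)
  expect_equal(ratio("AECD"), 2.8, tolerance = 1e-9)
  expect_equal(ratio("ABCD"), 2.5, tolerance = 1e-9)
  expect_equal(ratio("ABD"), 1.75, tolerance = 1e-9)
  expect_equal(ratio("AC"), 1.6, tolerance = 1e-9)
  # D-site single edit dominates the edited patterns in both genotypes
  for (g in pp) {
    ed <- g$pattern_probs[names(g$pattern_probs) != "NoEdit"]
    expect_identical(names(which.max(ed)), "D")
  }
  # overall editing levels built into the pair
  lvl <- function(g) {
    ed <- g$pattern_probs[names(g$pattern_probs) != "NoEdit"]
    100 * sum(ed) / sum(g$pattern_probs)
  }
  expect_equal(lvl(pp$WT), 69, tolerance = 1e-6)
  expect_equal(lvl(pp$LoxP), 64, tolerance = 1e-6)
})

test_that("count-level generator matches the read-level marginal law", {
  pp <- snord115_profile_pair()
  prof <- pp$WT
  n <- 5e4
  cnt <- simulate_pattern_counts(prof, n, 1, seed = 21)
  expect_identical(sum(cnt$counts) + sum(cnt$truncated), as.integer(n))
  # read-level counts at error 0 follow the same multinomial; compare
  # both against the profile by chi-square on pooled cells
  sim <- simulate_library(.ref, prof, n, error_rate = 0, seed = 22)
  rl <- table(factor(sim$truth$pattern[sim$truth$isoform == "full"],
                     levels = rownames(cnt$counts)))
  pr <- prof$pattern_probs[rownames(cnt$counts)]
  expect_gt(pooled_gof_p(as.integer(cnt$counts), pr), 0.005)
  expect_gt(pooled_gof_p(as.integer(rl), pr), 0.005)
})

test_that("profiles from independent site marginals compose correctly", {
  marg <- setNames(rep(0, 11), default_site_map()$label)
  marg["D"] <- 0.6
  p <- profile_from_site_marginals("g", 1, marg)
  expect_equal(unname(p$pattern_probs[["D"]]), 0.6)
  expect_equal(unname(p$pattern_probs[["NoEdit"]]), 0.4)
  marg["C"] <- 0.5
  p <- profile_from_site_marginals("g", 1, marg)
  expect_equal(unname(p$pattern_probs[["CD"]]), 0.3)
  expect_equal(sum(p$pattern_probs), 1)
})

test_that("invalid profiles are rejected", {
  expect_error(genotype_profile("g", 0.5, c(NoEdit = 0.5, D = 0.4)), "sum")
  expect_error(genotype_profile("g", 0.5, c(D = 1)), "NoEdit")
  expect_error(genotype_profile("g", 0.5, c(NoEdit = 0.5, DA = 0.5)),
               "non-canonical")
  expect_error(genotype_profile("g", 0.5, c(NoEdit = 0.5, AZ = 0.5)))
})
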