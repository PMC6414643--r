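# Shared fixtures and independent oracles for the test suite.

.ref <- default_amplicon_reference()

# --- independent oracle: naive per-read re-scan -------------------------
# Compares the read's site-window substring against the reference window
# with all 2^11 edited variants enumerated.  Returns the matched pattern
# label, or NA when no variant matches (non-A/G site base, off-window
# mismatch, or length change from an indel).  Completely independent of
# the caller's CIGAR/bitmask machinery.
naive_window_variants <- function(ref = .ref) {
  sm <- ref$site_map
  win <- c(min(sm$position) + 1L, max(sm$position) + 1L)
  refwin <- strsplit(substr(ref$full_contig, win[1], win[2]), "")[[1]]
  labs <- pattern_universe(sm)
  v <- vapply(labs, function(l) {
    w <- refwin
    if (l != "NoEdit") {
      s <- parse_pattern_label(l, sm)
      w[sm$position[match(s, sm$label)] + 1L - win[1] + 1L] <- "G"
    }
    paste(w, collapse = "")
  }, "")
  list(variants = v, labels = labs, win = win)
}

naive_pattern_scan <- function(reads, ref = .ref,
                               vv = naive_window_variants(ref)) {
  Lf <- nchar(ref$full_contig)
  vapply(reads, function(r) {
    if (nchar(r) != Lf) return(NA_character_)
    hit <- match(substr(r, vv$win[1], vv$win[2]), vv$variants)
    if (is.na(hit)) NA_character_ else vv$labels[hit]
  }, "", USE.NAMES = FALSE)
}

# chi-square GOF with standard pooling of cells whose expected count is
# below 5 (the asymptotic test is unreliable there)
pooled_gof_p <- function(obs, probs) {
  obs <- as.numeric(obs)
  n <- sum(obs)
  exp_ <- n * probs / sum(probs)
  small <- exp_ < 5
  if (sum(small) > 1L) {
    obs <- c(obs[!small], sum(obs[small]))
    probs <- c(probs[!small], sum(probs[small]))
  }
  suppressWarnings(chisq.test(obs, p = probs / sum(probs)))$p.value
}

# --- independent oracle: Benjamini-Hochberg step-up ---------------------
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# --- minimal SAM writer for fixtures ------------------------------------
write_sam <- function(path, ref, qname, flag, rname, pos, mapq, cigar, seq) {
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d",
                   c(ref$full_name, ref$truncated_name),
                   c(nchar(ref$full_contig), nchar(ref$truncated_contig))))
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                 qname, flag, rname, pos, mapq, cigar, seq)
  writeLines(c(hdr, rec), path)
  path
}

# SAM with one exact-alignment record per simulated read (substitution
# errors only, so CIGARs are all <len>M at pos 1)
sam_from_sim <- function(sim, ref, path, truth = sim$truth) {
  rn <- ifelse(truth$isoform == "full", ref$full_name, ref$truncated_name)
  write_sam(path, ref, qname = truth$read_id, flag = 0L, rname = rn,
            pos = 1L, mapq = 60L,
            cigar = paste0(nchar(sim$reads), "M"), seq = unname(sim$reads))
}

# --- pattern matrix from the count-level generator ----------------------
counts_to_list <- function(cm) apply(cm, 2L, identity, simplify = FALSE)

pm_from_count_sim <- function(profile1, profile2, n_reads, n_per_group = 6L,
                              seed = 1L, ref = .ref) {
  a <- simulate_pattern_counts(profile1, n_reads, n_per_group, seed = seed)
  b <- simulate_pattern_counts(profile2, n_reads, n_per_group,
                               seed = seed + 1L)
  libs <- data.frame(
    library_id = sprintf("%s_rep%d",
                         rep(c(profile1$name, profile2$name),
                             each = n_per_group),
                         rep(seq_len(n_per_group), 2L)),
    genotype = rep(c(profile1$name, profile2$name), each = n_per_group),
    total_mapped = c(a$total_mapped, b$total_mapped),
    stringsAsFactors = FALSE)
  cnt <- c(counts_to_list(a$counts), counts_to_list(b$counts))
  names(cnt) <- libs$library_id
  build_pattern_matrix(cnt, libs, ref)
}

# run reads through classification + calling + counting
counts_from_reads <- function(reads, ref = .ref, library_id = "lib1",
                              policy = "strict") {
  cl <- classify_raw_reads(reads, ref, library_id = library_id)
  calls <- call_patterns(cl$observations, ref$site_map, policy = policy)
  list(counts = count_patterns(calls), stats = cl$stats, calls = calls,
       observations = cl$observations)
}

# set the base at a given site of a full-length read string
set_site_base <- function(read, site, base, ref = .ref) {
  p <- ref$site_map$position[ref$site_map$label == site] + 1L
  substr(read, p, p) <- base
  read
}
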