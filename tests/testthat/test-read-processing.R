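test_that("SAM/BAM ingestion walks CIGARs to per-site base calls", {
  ref <- .ref
  Lf <- nchar(ref$full_contig)
  full <- ref$full_contig
  tr <- ref$truncated_contig
  edited <- set_site_base(set_site_base(full, "A", "G"), "D", "G")
  sam <- tempfile(fileext = ".sam")
  write_sam(sam, ref,
            qname = c("perfect", "edited_AD", "trunc", "lowq", "unmapped",
                      "clipped", "del_in_window", "ins_in_window"),
            flag = c(0L, 0L, 0L, 0L, 4L, 0L, 0L, 0L),
            rname = c(ref$full_name, ref$full_name, ref$truncated_name,
                      ref$full_name, ref$full_name, ref$full_name,
                      ref$full_name, ref$full_name),
            pos = c(1L, 1L, 1L, 1L, 1L, 11L, 1L, 1L),
            mapq = c(60L, 60L, 60L, 5L, 0L, 60L, 60L, 60L),
            cigar = c("209M", "209M", "114M", "209M", "*",
                      paste0("10S", Lf - 10L, "M"),
                      "111M1D97M",                 # deletes base 112 (site E)
                      "100M2I109M"),               # insertion inside window
            seq = c(full, edited, tr, full, full,
                    paste0(strrep("T", 10L), substr(full, 11L, Lf)),
                    paste0(substr(full, 1L, 111L), substr(full, 113L, Lf)),
                    paste0(substr(full, 1L, 100L), "TT",
                           substr(full, 101L, Lf))))
  res <- read_alignments(sam, ref, min_mapq = 30)
  obs <- res$observations
  st <- res$stats

  expect_identical(st$total_reads, 8L)
  expect_identical(st$discarded_unmapped, 1L)
  expect_identical(st$discarded_by_mapq, 1L)
  expect_identical(st$mapped_reads, st$full_reads + st$truncated_reads)
  expect_identical(st$full_reads, 5L)
  expect_identical(st$truncated_reads, 1L)

  perfect <- obs[obs$read_id == "perfect", ]
  expect_identical(perfect$contig, "full")
  expect_identical(perfect$site_bases, strrep("A", 11L))
  expect_true(perfect$covered_all_sites)
  expect_false(perfect$has_indel_in_window)

  ad <- obs[obs$read_id == "edited_AD", ]
  g_at <- strsplit(ad$site_bases, "")[[1]] == "G"
  expect_identical(.ref$site_map$label[g_at], c("A", "D"))

  expect_identical(obs[obs$read_id == "trunc", "contig"], "truncated")
  expect_true(is.na(obs[obs$read_id == "trunc", "site_bases"]))
  expect_false("lowq" %in% obs$read_id)
  expect_false("unmapped" %in% obs$read_id)

  # soft-clipped alignment starting mid-contig: all sites still covered
  clipped <- obs[obs$read_id == "clipped", ]
  expect_identical(clipped$site_bases, strrep("A", 11L))
  expect_true(clipped$covered_all_sites)

  del <- obs[obs$read_id == "del_in_window", ]
  expect_true(del$has_indel_in_window)
  expect_false(del$covered_all_sites)   # site E base deleted

  ins <- obs[obs$read_id == "ins_in_window", ]
  expect_true(ins$has_indel_in_window)
  expect_true(ins$covered_all_sites)
  expect_identical(ins$site_bases, strrep("A", 11L))
})

test_that("foreign contig names and malformed CIGARs are handled", {
  ref <- .ref
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000")
  rec <- sprintf("r1\t0\tchr1\t1\t60\t10M\t*\t0\t0\t%s\t*",
                 substr(ref$full_contig, 1, 10))
  writeLines(c(hdr, rec), sam)
  expect_error(read_alignments(sam, ref), "chr1")

  # a mapped record with CIGAR "*" is demoted to unmapped by the SAM->BAM
  # conversion and tallied as such
  sam2 <- tempfile(fileext = ".sam")
  write_sam(sam2, ref, qname = c("ok", "badcigar"), flag = c(0L, 0L),
            rname = rep(ref$full_name, 2L), pos = c(1L, 1L),
            mapq = c(60L, 60L), cigar = c("209M", "*"),
            seq = rep(ref$full_contig, 2L))
  res <- suppressWarnings(read_alignments(sam2, ref))
  expect_identical(res$stats$discarded_unmapped, 1L)
  expect_identical(res$observations$read_id, "ok")

  # the CIGAR walker itself refuses malformed strings (defensive path:
  # htslib sanitizes BAM input, so these never arrive from files)
  s1 <- ampedit:::.site_pos1(ref)
  w1 <- ampedit:::.site_window1(ref)
  expect_error(ampedit:::.sites_from_cigar(1L, "10Z", ref$full_contig, s1, w1),
               "malformed")
  expect_error(ampedit:::.sites_from_cigar(1L, "100M", ref$full_contig, s1, w1),
               "length")
  expect_error(ampedit:::.sites_from_cigar(1L, "*", ref$full_contig, s1, w1),
               "CIGAR")
})

test_that("raw-read classifier assigns by edit distance in both orientations", {
  ref <- .ref
  cl <- classify_raw_reads(c(f = ref$full_contig, t = ref$truncated_contig),
                           ref)
  expect_identical(cl$observations$contig, c("full", "truncated"))
  expect_identical(cl$observations$edit_dist, c(0L, 0L))

  # reverse-complement handling, via Biostrings as an independent route
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(c(ref$truncated_contig, ref$full_contig))))
  cl <- classify_raw_reads(c(a = rc[1L], b = rc[2L]), ref)
  expect_identical(cl$observations$contig, c("truncated", "full"))
  # site bases of a reverse-orientation edited read are complemented back
  edited <- set_site_base(ref$full_contig, "C", "G")
  rc_e <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(edited)))
  cl <- classify_raw_reads(c(x = rc_e), ref)
  g_at <- strsplit(cl$observations$site_bases, "")[[1]] == "G"
  expect_identical(ref$site_map$label[g_at], "C")

  # empty input
  cl <- classify_raw_reads(character(0), ref)
  expect_identical(nrow(cl$observations), 0L)
  expect_identical(cl$stats$total_reads, 0L)
})

test_that("indel-bearing reads go through the alignment fallback", {
  ref <- .ref
  full <- ref$full_contig
  win <- c(min(ref$site_map$position), max(ref$site_map$position)) + 1L
  del_in <- paste0(substr(full, 1L, win[1] + 1L), substr(full, win[1] + 3L,
                                                         nchar(full)))
  ins_out <- paste0(substr(full, 1L, 10L), "A", substr(full, 11L, nchar(full)))
  cl <- classify_raw_reads(c(d = del_in, i = ins_out), ref)
  obs <- cl$observations
  expect_identical(obs$contig, c("full", "full"))
  expect_true(obs$has_indel_in_window[1L])
  expect_false(obs$has_indel_in_window[2L])
  expect_true(obs$covered_all_sites[2L])
  expect_identical(obs$site_bases[2L], strrep("A", 11L))
})

test_that("classifier and external-alignment route agree on simulated reads", {
  ref <- .ref
  pp <- snord115_profile_pair()
  sim <- simulate_library(ref, pp$WT, 2000, error_rate = 0.01, seed = 31)
  cl <- classify_raw_reads(sim$reads, ref)

  # no misassignments at 1% error (contigs differ by a 95 nt block)
  merged <- merge(cl$observations, sim$truth, by = "read_id")
  expect_identical(nrow(merged), 2000L)
  expect_true(all(merged$contig ==
                    ifelse(merged$isoform == "full", "full", "truncated")))

  # SAM route over the same reads (exact alignments, substitutions only)
  sam <- tempfile(fileext = ".sam")
  sam_from_sim(sim, ref, sam)
  al <- read_alignments(sam, ref, min_mapq = 30)
  both <- merge(cl$observations, al$observations, by = "read_id",
                suffixes = c(".cl", ".al"))
  expect_identical(nrow(both), 2000L)
  expect_gte(mean(both$contig.cl == both$contig.al), 0.999)
  same_bases <- both$site_bases.cl == both$site_bases.al
  expect_true(all(same_bases | (is.na(both$site_bases.cl) &
                                  is.na(both$site_bases.al))))

  # conservation: every read lands in exactly one tally
  st <- cl$stats
  expect_identical(st$total_reads,
                   st$full_reads + st$truncated_reads + st$unassigned)
})
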