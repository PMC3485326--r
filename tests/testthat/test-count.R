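test_that("the M13f check is a fixed-offset test with a mismatch budget", {
  good <- paste0("AAAAAA", m13f_sequence(), "ACGTACGT")
  expect_identical(locate_m13f(good), 6L)
  # random non-FREQ-Seq content is rejected
  set.seed(2)
  foreign <- random_dna(50, 40)
  d <- mapply(function(s) {
    sum(charToRaw(substr(s, 7, 23)) != charToRaw(m13f_sequence()))
  }, foreign)
  expect_true(all(is.na(locate_m13f(foreign[d > 1]))))
  # one substitution passes at the default budget, fails at zero
  mut <- good
  substr(mut, 8, 8) <- "A" # inside the 17-mer (position 2: T -> A)
  expect_identical(locate_m13f(mut, max_mismatches = 1), 6L)
  expect_true(is.na(locate_m13f(mut, max_mismatches = 0)))
  # short reads can never carry the adapter
  expect_true(is.na(locate_m13f("ACGTACGTACGT")))
})

test_that("barcode demultiplexing is exact-match only", {
  map <- c(ACGTAC = "S1", TTGGCC = "S2")
  expect_identical(assign_barcode(paste0("ACGTAC", m13f_sequence()), map),
                   "S1")
  # one error off a library barcode: detected, not corrected
  expect_true(is.na(assign_barcode(paste0("ACGTAG", m13f_sequence()), map)))
  expect_error(assign_barcode("ACGTAC", c(AAAAAA = "S1", AAAAAA = "S2")),
               "duplicate")
})

test_that("allele assignment separates SNPs, deletions and junctions", {
  snp <- snp_locus()
  rd <- build_read("ACGTAC", snp$alleles$EVO, 50)
  res <- align_allele(rd, snp)
  expect_identical(res$status, "ASSIGNED")
  expect_identical(res$allele, "EVO")
  expect_identical(res$distance, 0L)
  expect_identical(res$margin, 1L)

  # an 11-bp deletion allele: exact WT read matches WT at distance 0
  del <- del_locus()
  rd_wt <- build_read("ACGTAC", del$alleles$WT, 50)
  rd_evo <- build_read("ACGTAC", del$alleles$EVO, 50)
  res <- align_allele(c(rd_wt, rd_evo), del)
  expect_identical(res$status, c("ASSIGNED", "ASSIGNED"))
  expect_identical(res$allele, c("WT", "EVO"))
  expect_identical(res$distance, c(0L, 0L))

  # junction alleles carry distinct anchors; reads only match their own
  jc <- junction_locus()
  rd_j <- build_read("ACGTAC", jc$alleles$EVO, 50)
  res <- align_allele(rd_j, jc)
  expect_identical(res$allele, "EVO")
  expect_identical(res$distance, 0L)
  expect_gte(res$margin, 2L) # runner-up beyond the band cap

  # a read equidistant from both alleles is ambiguous: mutate the SNP base
  # to a third base
  amb <- rd
  substr(amb, 48, 48) <- "T" # SNP position: WT C, EVO G
  res <- align_allele(amb, snp)
  expect_identical(res$status, "AMBIGUOUS_ALLELE")

  # garbage template: no allele within the edit budget
  res <- align_allele(paste0("ACGTAC", m13f_sequence(), strrep("T", 27)),
                      snp)
  expect_identical(res$status, "NO_ALLELE")
})

test_that("banded distances agree with full dynamic programming", {
  set.seed(31)
  refs <- random_dna(5, 12)
  for (ref in refs) {
    qs <- c(random_dna(150, 12), random_dna(25, 10), random_dna(25, 14))
    # generous band: exact equality with the unbanded oracle
    expect_identical(edit_distance(qs, ref),
                     as.integer(adist(qs, ref)))
    # narrow band: exact up to the cap, clamped beyond it
    for (band in 1:4) {
      got <- freqseq:::.edit_distance_banded(qs, ref, band, FALSE)
      expect_identical(got, pmin(as.integer(adist(qs, ref)), band + 1L))
    }
  }
})

test_that("error-free pools are recovered read-for-read from the manifest", {
  loc <- snp_locus()
  spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0.7, EVO = 0.3),
                      n_reads = 2000, error_rate = 0, seed = 8)
  out <- count_simulated(spec, audit = TRUE)
  man <- table(out$sim$manifest$allele)
  cnt <- setNames(out$counts$counts$count, out$counts$counts$allele)
  expect_identical(as.integer(cnt[names(man)]), as.integer(man))
  expect_identical(sum(out$counts$discards$count), 0L)
  expect_identical(out$counts$total_reads, 2000L)
  # audit stream agrees with the truth for every read
  aud <- merge(out$counts$audit, out$sim$manifest, by = "read_id")
  expect_true(all(aud$allele.x == aud$allele.y))
})

test_that("counts are conserved, order-invariant and linear in the input", {
  loc <- snp_locus()
  spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0.5, EVO = 0.5),
                      n_reads = 1500, error_rate = 0.01, seed = 13)
  sim <- simulate_sample(spec)
  cfg <- run_config(data.frame(sample_id = "S1", barcode = "ACGTAC",
                               locus = "pntAB"), list(loc))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(sim, f1)
  r1 <- process_fastq(f1, cfg)
  expect_identical(sum(r1$counts$count) + sum(r1$discards$count),
                   r1$total_reads)

  # permutation invariance
  shuffled <- sim$reads[rev(seq_len(nrow(sim$reads))), ]
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(shuffled, f2)
  r2 <- process_fastq(f2, cfg)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$discards, r2$discards)

  # processing the same file twice doubles every tally
  r3 <- process_fastq(c(f1, f1), cfg)
  expect_identical(r3$counts$count, 2L * r1$counts$count)
  expect_identical(r3$discards$count, 2L * r1$discards$count)
})

test_that("foreign reads are discarded as NO_M13F without disturbing counts", {
  loc <- snp_locus()
  traj <- data.frame(locus = "pntAB", timepoint = c(0, 0),
                     allele = c("WT", "EVO"), freq = c(0.4, 0.6))
  cfg <- run_config(data.frame(sample_id = "pntAB_t0", barcode = "ACGTAC",
                               locus = "pntAB"), list(loc))
  with_f <- simulate_timecourse(list(loc), traj, "ACGTAC", n_reads = 1000,
                                error_rate = 0, foreign_fraction = 0.3,
                                seed = 17)
  no_f <- simulate_timecourse(list(loc), traj, "ACGTAC", n_reads = 1000,
                              error_rate = 0, foreign_fraction = 0,
                              seed = 17)
  fa <- withr::local_tempfile(fileext = ".fastq")
  fb <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(with_f, fa)
  write_fastq(no_f, fb)
  ra <- process_fastq(fa, cfg)
  rb <- process_fastq(fb, cfg)
  expect_identical(ra$counts, rb$counts)
  no_m13f <- ra$discards$count[ra$discards$status == "NO_M13F" &
                                 is.na(ra$discards$sample_id)]
  expect_identical(no_m13f, sum(with_f$layout$n_foreign))
})

test_that("rising error rates never inflate the true-allele count", {
  loc <- snp_locus()
  base <- vapply(1:5, function(s) {
    spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0, EVO = 1),
                        n_reads = 800, error_rate = 0, seed = s)
    out <- count_simulated(spec)
    out$counts$counts$count[out$counts$counts$allele == "EVO"]
  }, integer(1))
  noisy <- vapply(1:5, function(s) {
    spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0, EVO = 1),
                        n_reads = 800, error_rate = 0.05, seed = s)
    out <- count_simulated(spec)
    out$counts$counts$count[out$counts$counts$allele == "EVO"]
  }, integer(1))
  expect_true(all(base == 800L))
  expect_true(all(noisy <= base))
})

test_that("empty and malformed input are handled explicitly", {
  loc <- snp_locus()
  cfg <- run_config(data.frame(sample_id = "S1", barcode = "ACGTAC",
                               locus = "pntAB"), list(loc))
  empty <- withr::local_tempfile(fileext = ".fastq")
  file.create(empty)
  expect_warning(res <- process_fastq(empty, cfg), "empty")
  expect_identical(res$total_reads, 0L)
  expect_true(all(res$counts$count == 0L))

  bad <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "IIII"), bad) # truncated record
  expect_error(process_fastq(bad, cfg), "malformed|read")
})
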