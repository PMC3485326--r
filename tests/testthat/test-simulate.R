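test_that("build_read concatenates the layout and enforces window visibility", {
  a <- allele("EVO", anchor = "GG", window = "T")
  expect_identical(build_read("AAAAAA", a, 26), "AAAAAAGTAAAACGACGGCCAGTGGT")
  # 22-nt anchor: the window starts at 0-based offset 45
  b <- allele("WT", anchor = strrep("A", 22), window = "CGCG")
  rd <- build_read("TTTTTT", b, 50)
  expect_identical(substr(rd, 46, 49), "CGCG")
  expect_error(build_read("AAAAAA", a, 25), "too short")
  expect_error(build_read("AAAAA", a, 30), "length 6")
})

test_that("error-free pure samples reproduce the construct exactly", {
  loc <- snp_locus()
  spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0, EVO = 1),
                      n_reads = 100, error_rate = 0, seed = 4)
  sim <- simulate_sample(spec)
  expect_identical(nrow(sim$reads), 100L)
  ref <- build_read("ACGTAC", loc$alleles$EVO, 50)
  expect_true(all(sim$reads$seq == ref))
  expect_true(all(sim$manifest$allele == "EVO"))
  expect_true(all(sim$manifest$n_errors == 0))
  expect_identical(unname(sim$counts), c(0L, 100L))
  # constant Phred 30 in Sanger +33 encoding
  expect_true(all(sim$reads$qual == strrep("?", nchar(sim$reads$seq))))
})

test_that("simulation is byte-identical given the seed", {
  loc <- snp_locus()
  spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0.6, EVO = 0.4),
                      n_reads = 500, error_rate = 0.01, seed = 99)
  a <- simulate_sample(spec)
  b <- simulate_sample(spec)
  expect_identical(a$reads, b$reads)
  expect_identical(a$manifest, b$manifest)
  fa <- withr::local_tempfile(fileext = ".fastq")
  fb <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(a, fa)
  write_fastq(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("allele draws and the error process match their sampling models", {
  loc <- snp_locus()
  # mean minor-allele fraction across seeds is binomial around the truth
  p <- 0.3
  seeds <- 1:30
  n <- 2000
  fracs <- vapply(seeds, function(s) {
    spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 1 - p, EVO = p),
                        n_reads = n, error_rate = 0, seed = s)
    sim <- simulate_sample(spec)
    unname(sim$counts["EVO"] / n)
  }, numeric(1))
  tol <- 3 * sqrt(p * (1 - p) / (length(seeds) * n))
  expect_lt(abs(mean(fracs) - p), tol)

  # total mutated bases within 5 SD of error_rate * total bases
  e <- 0.001
  spec <- sample_spec("S1", "ACGTAC", loc, c(WT = 0.5, EVO = 0.5),
                      n_reads = 20000, error_rate = e, seed = 12)
  sim <- simulate_sample(spec)
  total_bases <- sum(nchar(sim$reads$seq))
  mu <- e * total_bases
  expect_lt(abs(sum(sim$manifest$n_errors) - mu),
            5 * sqrt(total_bases * e * (1 - e)))
  # manifest positions actually differ from the clean construct
  i <- which(sim$manifest$n_errors > 0)[1]
  clean <- build_read("ACGTAC", loc$alleles[[sim$manifest$allele[i]]], 50)
  pos <- as.integer(strsplit(sim$manifest$error_positions[i], ";")[[1]])
  for (pp in pos) {
    expect_false(substr(sim$reads$seq[i], pp, pp) == substr(clean, pp, pp))
  }
})

test_that("degenerate two-timepoint pools partition perfectly by barcode", {
  loc <- snp_locus()
  traj <- data.frame(locus = "pntAB", timepoint = rep(c(0, 1), each = 2),
                     allele = rep(c("WT", "EVO"), 2),
                     freq = c(1, 0, 0, 1))
  pool <- simulate_timecourse(list(loc), traj, c("AAAAAA", "CCCCCC"),
                              n_reads = 200, error_rate = 0, seed = 5)
  expect_identical(nrow(pool$reads), 400L)
  expect_identical(length(unique(pool$reads$seq)), 2L)
  bc <- substr(pool$reads$seq, 1, 6)
  win <- substr(pool$reads$seq, 46, 50)
  expect_true(all(win[bc == "AAAAAA"] ==
                    substr(loc$alleles$WT$window, 1, 5)))
  expect_true(all(win[bc == "CCCCCC"] ==
                    substr(loc$alleles$EVO$window, 1, 5)))
})

test_that("foreign reads are injected at the stated rate and lack M13f", {
  loc <- snp_locus()
  traj <- data.frame(locus = "pntAB", timepoint = c(0, 0),
                     allele = c("WT", "EVO"), freq = c(0.5, 0.5))
  pool <- simulate_timecourse(list(loc), traj, "ACGTAC", n_reads = 1000,
                              error_rate = 0, foreign_fraction = 0.5,
                              seed = 21)
  nf <- sum(pool$manifest$allele == "FOREIGN")
  expect_identical(nf, pool$layout$n_foreign[1])
  expect_lt(abs(nf - 500), 5 * sqrt(1000 * 0.5 * 0.5))
  foreign_seq <- pool$reads$seq[match(
    pool$manifest$read_id[pool$manifest$allele == "FOREIGN"],
    pool$reads$id)]
  expect_true(all(is.na(locate_m13f(foreign_seq))))
  # conservation including foreign content
  expect_identical(nrow(pool$reads), 1000L + nf)
  # sample-level allele draws are unchanged vs a no-foreign run
  clean <- simulate_timecourse(list(loc), traj, "ACGTAC", n_reads = 1000,
                               error_rate = 0, foreign_fraction = 0,
                               seed = 21)
  expect_identical(pool$samples[[1]]$counts, clean$samples[[1]]$counts)
})

test_that("multi-locus pools keep exact per-sample bookkeeping", {
  loci <- list(snp_locus(), del_locus())
  tps <- 0:4
  traj <- do.call(rbind, lapply(loci, function(l) {
    do.call(rbind, lapply(tps, function(tp) {
      f <- tp / max(tps)
      data.frame(locus = l$name, timepoint = tp,
                 allele = c("WT", "EVO"), freq = c(1 - f, f))
    }))
  }))
  lib <- design_barcodes(10, seed = 2)
  pool <- simulate_timecourse(loci, traj, lib, n_reads = 100,
                              error_rate = 0, seed = 3)
  expect_identical(nrow(pool$layout), 10L)
  expect_identical(nrow(pool$reads), 1000L)
  expect_identical(nrow(pool$manifest), 1000L)
  tab <- table(pool$manifest$sample_id)
  expect_true(all(tab == 100))
  # per-sample counts in the manifest agree with the recorded draws
  for (s in pool$layout$sample_id) {
    m <- table(pool$manifest$allele[pool$manifest$sample_id == s])
    cs <- pool$samples[[s]]$counts
    expect_identical(as.integer(m[names(cs)][cs > 0]),
                     as.integer(cs[cs > 0]))
  }
  expect_error(
    simulate_timecourse(loci, traj, rep("AAAAAA", 10), n_reads = 10,
                        seed = 1),
    "duplicate")
})

test_that("sample specs validate frequencies and read length", {
  loc <- snp_locus()
  expect_error(sample_spec("S", "ACGTAC", loc, c(WT = 0.5, EVO = 0.6), 10),
               "sum to 1")
  expect_error(sample_spec("S", "ACGTAC", loc, c(WT = 1, XX = 0), 10),
               "named after")
  expect_error(sample_spec("S", "ACGTAC", loc, c(WT = 0.5, EVO = 0.5), 10,
                           read_length = 30),
               "read_length")
})
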