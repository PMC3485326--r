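# Shared fixture builders.  All fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# two-allele SNP locus; anchor 22 nt so the consumed prefix is 45 bases
snp_locus <- function(window_wt = "ACCTTGGA", window_evo = "ACGTTGGA",
                      name = "pntAB") {
  locus(name,
        allele("WT",  anchor = "ACGGATTACCAGGTACCAGGTA", window = window_wt),
        allele("EVO", anchor = "ACGGATTACCAGGTACCAGGTA", window = window_evo))
}

# deletion locus: EVO window lacks 11 bp present in WT
del_locus <- function(name = "fghA") {
  locus(name,
        allele("WT",  anchor = "GTCCATGGACTT",
               window = "ACGTACGTACGTTTGCAGGA", kind = "INDEL"),
        allele("EVO", anchor = "GTCCATGGACTT",
               window = "ATTGCAGGA", kind = "INDEL"))
}

# novel-junction locus: allele-specific anchors
junction_locus <- function(name = "icuAB") {
  locus(name,
        allele("WT",  anchor = "ACCGGTTACA", window = "GGATCCAAGG",
               kind = "JUNCTION"),
        allele("EVO", anchor = "TTGACCGGCA", window = "CATTGGAACC",
               kind = "JUNCTION"))
}

# Net frequency-shift contributed by read misassignment, measured from the
# audit-vs-manifest join: (estimated fraction among assigned reads) minus
# (true source fraction among the same assigned reads).
net_misassignment <- function(counts_obj, sim, allele_name) {
  aud <- merge(counts_obj$audit, sim$manifest, by = "read_id")
  asg <- aud[aud$status == "ASSIGNED", , drop = FALSE]
  mean(asg$allele.x == allele_name) - mean(asg$allele.y == allele_name)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

# simulate one sample, write it to a temp FASTQ, and count it
count_simulated <- function(spec, cfg = NULL, audit = FALSE) {
  sim <- simulate_sample(spec)
  fq <- withr::local_tempfile(fileext = ".fastq",
                              .local_envir = parent.frame())
  write_fastq(sim, fq)
  if (is.null(cfg)) {
    cfg <- run_config(
      data.frame(sample_id = spec$sample_id, barcode = spec$barcode,
                 locus = spec$locus$name),
      list(spec$locus))
  }
  list(sim = sim, counts = process_fastq(fq, cfg, audit = audit), fastq = fq)
}
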