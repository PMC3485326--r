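# Read simulation with the FREQ-Seq layout.
#
# A simulated read is barcode (6 nt) + M13f (17 nt) + allele anchor +
# diagnostic window, truncated to the read length, with iid per-base
# substitution errors (uniform over the three alternative bases) and a
# constant Phred 30 quality string.  Every read carries a truth-manifest row
# (source allele, mutated positions), so downstream counting can be checked
# against ground truth exactly.

#' Define an allele of a locus
#'
#' An allele is described by its sequencing-end anchor (the locus-specific
#' forward primer; allele-specific for novel-junction loci) and the
#' diagnostic window immediately downstream that distinguishes it from the
#' other alleles.
#'
#' @param name Allele name (e.g. `"WT"`, `"EVO"`).
#' @param anchor Anchor sequence, non-empty DNA string.
#' @param window Diagnostic window, non-empty DNA string.
#' @param kind One of `"SNP"`, `"INDEL"`, `"JUNCTION"`.
#' @return An object of class `freq_allele`.
#' @export
allele <- function(name, anchor, window, kind = c("SNP", "INDEL", "JUNCTION")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  anchor <- .check_dna(anchor, "anchor")
  window <- .check_dna(window, "window")
  if (!nzchar(anchor)) stop("anchor must be non-empty", call. = FALSE)
  if (!nzchar(window)) stop("window must be non-empty", call. = FALSE)
  structure(list(name = name, anchor = anchor, window = window, kind = kind),
            class = "freq_allele")
}

#' Define a locus as a set of alternative alleles
#'
#' @param name Locus name.
#' @param ... Two or more [allele()] objects with distinct names; every pair
#'   must differ in anchor or window (otherwise reads could never be
#'   assigned).
#' @return An object of class `freq_locus`.
#' @examples
#' loc <- locus("pntAB",
#'   allele("WT",  anchor = "ACGGATTACCAGGT", window = "ACCTTGGA"),
#'   allele("EVO", anchor = "ACGGATTACCAGGT", window = "ACCTAGGA"))
#' @export
locus <- function(name, ...) {
  alleles <- list(...)
  if (length(alleles) == 1L && is.list(alleles[[1]]) &&
      !inherits(alleles[[1]], "freq_allele")) {
    alleles <- alleles[[1]]
  }
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(alleles) < 2L) stop("a locus needs >= 2 alleles", call. = FALSE)
  if (!all(vapply(alleles, inherits, TRUE, "freq_allele"))) {
    stop("alleles must be freq_allele objects", call. = FALSE)
  }
  nm <- vapply(alleles, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("allele names must be unique", call. = FALSE)
  names(alleles) <- nm
  refs <- vapply(alleles, function(a) paste0(a$anchor, a$window), "")
  if (anyDuplicated(refs)) {
    stop("every allele pair must differ in anchor or window", call. = FALSE)
  }
  kinds <- vapply(alleles, `[[`, "", "kind")
  if (all(kinds == "SNP")) {
    wl <- unique(nchar(vapply(alleles, `[[`, "", "window")))
    if (length(wl) != 1L) {
      stop("SNP alleles of one locus must have equal-length windows",
           call. = FALSE)
    }
  }
  structure(list(name = name, alleles = alleles), class = "freq_locus")
}

#' @export
print.freq_locus <- function(x, ...) {
  cat("Locus", x$name, "with", length(x$alleles), "alleles:\n")
  for (a in x$alleles) {
    cat(sprintf("  %-8s [%s] anchor %d nt, window %d nt\n", a$name, a$kind,
                nchar(a$anchor), nchar(a$window)))
  }
  invisible(x)
}

# reference sequence a read of this allele should carry from offset 23
.allele_ref <- function(a) paste0(a$anchor, a$window)

#' Construct the error-free read sequence for one allele
#'
#' Concatenates barcode, M13f, anchor and window and truncates to
#' `read_length`.  The variable window begins at 0-based offset
#' `23 + nchar(anchor)`; with a 22-nt anchor the consumed prefix is 45 bases.
#'
#' @param bc 6-nt barcode.
#' @param allele A [allele()] object.
#' @param read_length Read length; must reach at least one window base.
#' @return A DNA string of exactly `read_length` characters (or shorter only
#'   if the full construct is shorter).
#' @examples
#' build_read("AAAAAA", allele("EVO", "GG", "T", "SNP"), 26)
#' @export
build_read <- function(bc, allele, read_length) {
  bc <- .check_dna(bc, "barcode", len = .BARCODE_LEN)
  stopifnot(inherits(allele, "freq_allele"))
  minimum <- .TEMPLATE_OFFSET + nchar(allele$anchor) + 1L
  if (read_length < minimum) {
    stop("read_length ", read_length, " too short: layout needs >= ", minimum,
         " to reach the diagnostic window", call. = FALSE)
  }
  full <- paste0(bc, m13f_sequence(), allele$anchor, allele$window)
  substr(full, 1L, read_length)
}

#' Specify one simulated sample
#'
#' @param sample_id Sample identifier.
#' @param barcode 6-nt barcode assigned to the sample.
#' @param locus A [locus()] object.
#' @param true_freqs Named numeric vector of allele frequencies (names must
#'   match the locus's alleles; must sum to 1).
#' @param n_reads Number of reads to emit.
#' @param read_length Read length (default 50, the binding constraint for
#'   window placement in this protocol).
#' @param error_rate Per-base substitution probability in `[0, 0.1]`.
#' @param seed Integer seed.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(sample_id, barcode, locus, true_freqs, n_reads,
                        read_length = 50L, error_rate = 0, seed = 1L) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L,
            inherits(locus, "freq_locus"),
            n_reads >= 1, error_rate >= 0, error_rate <= 0.1)
  barcode <- .check_dna(barcode, "barcode", len = .BARCODE_LEN)
  if (is.null(names(true_freqs)) ||
      !setequal(names(true_freqs), names(locus$alleles))) {
    stop("true_freqs must be named after the locus's alleles", call. = FALSE)
  }
  true_freqs <- true_freqs[names(locus$alleles)]
  if (abs(sum(true_freqs) - 1) > 1e-9) {
    stop("true_freqs must sum to 1", call. = FALSE)
  }
  need <- .TEMPLATE_OFFSET +
    max(vapply(locus$alleles, function(a) nchar(a$anchor), 0L)) + 1L
  if (read_length < need) {
    stop("read_length must be >= ", need,
         " to expose the diagnostic window of every allele", call. = FALSE)
  }
  structure(list(sample_id = sample_id, barcode = barcode, locus = locus,
                 true_freqs = true_freqs, n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sample_spec")
}

# Apply iid per-base substitution errors to a character vector of reads.
# Returns list(seqs, positions) where positions is a list of mutated
# 1-based positions per read (integer(0) where untouched).
.mutate_reads <- function(seqs, error_rate) {
  n <- length(seqs)
  positions <- rep(list(integer(0)), n)
  if (error_rate > 0 && n > 0) {
    L <- nchar(seqs) # may vary
    Lmax <- max(L)
    hits <- which(runif(n * Lmax) < error_rate)
    if (length(hits)) {
      read_i <- (hits - 1L) %/% Lmax + 1L
      pos <- (hits - 1L) %% Lmax + 1L
      keep <- pos <= L[read_i]
      read_i <- read_i[keep]
      pos <- pos[keep]
      if (length(read_i)) {
        # uniform choice among the 3 alternative bases, per hit
        alt_idx <- sample.int(3L, length(read_i), replace = TRUE)
        for (k in seq_along(read_i)) {
          i <- read_i[k]
          p <- pos[k]
          old <- substr(seqs[i], p, p)
          new <- setdiff(.DNA_BASES, old)[alt_idx[k]]
          substr(seqs[i], p, p) <- new
          positions[[i]] <- c(positions[[i]], p)
        }
      }
    }
  }
  list(seqs = seqs, positions = positions)
}

#' Simulate reads for one sample
#'
#' Draws each read's source allele from the sample's allele frequencies
#' (seeded; iid draws, i.e. a multinomial overall), applies the substitution
#' error model, and records every draw and mutation in a truth manifest.
#' Quality strings are constant Phred 30 (Sanger +33).  Byte-identical
#' output for identical spec + seed.
#'
#' @param spec A [sample_spec()].
#' @return An object of class `freq_sim`: list with `reads` (data frame:
#'   id, seq, qual), `manifest` (data frame: read_id, sample_id, allele,
#'   n_errors, error_positions), `counts` (named integer per allele) and
#'   `spec`.
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "sample_spec"))
  .with_seed(spec$seed, .simulate_sample_impl(spec))
}

.simulate_sample_impl <- function(spec, id_prefix = spec$sample_id) {
  alle <- spec$locus$alleles
  nm <- names(alle)
  src <- nm[sample.int(length(nm), spec$n_reads, replace = TRUE,
                       prob = spec$true_freqs)]
  base_read <- vapply(alle, function(a) {
    build_read(spec$barcode, a, spec$read_length)
  }, "")
  seqs <- base_read[src]
  mut <- .mutate_reads(unname(seqs), spec$error_rate)
  ids <- sprintf("%s:%07d", id_prefix, seq_len(spec$n_reads))
  qual <- strrep(rawToChar(as.raw(30L + 33L)), nchar(mut$seqs))
  n_err <- lengths(mut$positions)
  manifest <- data.frame(
    read_id = ids,
    sample_id = spec$sample_id,
    allele = src,
    n_errors = n_err,
    error_positions = vapply(mut$positions, paste, "", collapse = ";"),
    stringsAsFactors = FALSE
  )
  counts <- setNames(tabulate(match(src, nm), nbins = length(nm)), nm)
  structure(list(
    reads = data.frame(id = ids, seq = mut$seqs, qual = qual,
                       stringsAsFactors = FALSE),
    manifest = manifest,
    counts = counts,
    spec = spec
  ), class = "freq_sim")
}

#' @export
print.freq_sim <- function(x, ...) {
  cat("Simulated sample", x$spec$sample_id, "-", nrow(x$reads), "reads\n")
  cat("  allele draws:", paste(names(x$counts), x$counts, sep = "=",
                               collapse = ", "), "\n")
  cat("  mutated reads:", sum(x$manifest$n_errors > 0), "\n")
  invisible(x)
}

# random read with no M13f at the layout offset (foreign lane content)
.foreign_reads <- function(n, read_length) {
  if (n == 0) return(character(0))
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(.DNA_BASES, read_length, replace = TRUE), collapse = "")
  }, "")
  # guarantee the M13f check cannot fire (within 1 mismatch)
  bad <- .hamming_to_ref(substr(seqs, .M13F_OFFSET + 1L,
                                .M13F_OFFSET + 17L), m13f_sequence())
  bad <- which(bad >= 0 & bad <= 1)
  while (length(bad)) {
    for (i in bad) {
      seqs[i] <- paste(sample(.DNA_BASES, read_length, replace = TRUE),
                       collapse = "")
    }
    d <- .hamming_to_ref(substr(seqs[bad], .M13F_OFFSET + 1L,
                                .M13F_OFFSET + 17L), m13f_sequence())
    bad <- bad[d >= 0 & d <= 1]
  }
  seqs
}

#' Simulate a multiplexed pool across loci and timepoints
#'
#' Builds one sample per (locus, timepoint) cell of the trajectory table,
#' assigns each a barcode from the library, simulates all samples, optionally
#' injects foreign reads (non-FREQ-Seq lane content lacking the M13f
#' adapter), and interleaves everything in a seeded shuffle emulating a
#' pooled flow-cell lane.
#'
#' @param loci List of [locus()] objects.
#' @param trajectories Data frame with columns `locus`, `timepoint`,
#'   `allele`, `freq`; per (locus, timepoint) the frequencies must sum to 1.
#' @param barcodes A `barcode_library` or character vector with at least as
#'   many barcodes as (locus, timepoint) samples; assigned in order.
#' @param n_reads Reads per sample.
#' @param read_length,error_rate As in [sample_spec()].
#' @param foreign_fraction Expected fraction (of `n_reads`) of foreign reads
#'   added per sample.
#' @param seed Integer seed.
#' @return An object of class `freq_pool`: list with `reads` (pooled,
#'   shuffled data frame id/seq/qual), `manifest` (truth rows; foreign reads
#'   have allele `"FOREIGN"`), `layout` (data frame sample_id, barcode,
#'   locus, timepoint, n_reads, n_foreign) and `samples` (list of
#'   `freq_sim`).
#' @export
simulate_timecourse <- function(loci, trajectories, barcodes, n_reads,
                                read_length = 50L, error_rate = 0,
                                foreign_fraction = 0, seed = 1L) {
  if (inherits(loci, "freq_locus")) loci <- list(loci)
  names(loci) <- vapply(loci, `[[`, "", "name")
  stopifnot(is.data.frame(trajectories),
            all(c("locus", "timepoint", "allele", "freq") %in%
                  names(trajectories)),
            foreign_fraction >= 0, foreign_fraction < 1)
  codes <- if (inherits(barcodes, "barcode_library")) barcodes$barcodes
           else barcodes
  cells <- unique(trajectories[c("locus", "timepoint")])
  cells <- cells[order(match(cells$locus, names(loci)), cells$timepoint), ]
  if (length(codes) < nrow(cells)) {
    stop("need ", nrow(cells), " barcodes, got ", length(codes),
         call. = FALSE)
  }
  codes <- codes[seq_len(nrow(cells))]
  if (anyDuplicated(codes)) {
    stop("duplicate barcode assignment within one pool", call. = FALSE)
  }

  .with_seed(seed, {
    sims <- vector("list", nrow(cells))
    layout <- cells
    layout$sample_id <- sprintf("%s_t%s", cells$locus, cells$timepoint)
    layout$barcode <- codes
    layout$n_reads <- as.integer(n_reads)
    layout$n_foreign <- 0L
    foreign <- list()
    for (i in seq_len(nrow(cells))) {
      loc <- loci[[cells$locus[i]]]
      if (is.null(loc)) {
        stop("trajectories reference unknown locus ", cells$locus[i],
             call. = FALSE)
      }
      rows <- trajectories$locus == cells$locus[i] &
        trajectories$timepoint == cells$timepoint[i]
      fr <- setNames(trajectories$freq[rows], trajectories$allele[rows])
      spec <- sample_spec(layout$sample_id[i], codes[i], loc, fr, n_reads,
                          read_length, error_rate, seed = 0L)
      # draws come from the pool-level RNG stream, not per-sample reseeding
      sims[[i]] <- .simulate_sample_impl(spec)
    }
    # foreign lane content in a second pass, so the per-sample allele draws
    # are identical to a foreign_fraction = 0 run at the same seed
    if (foreign_fraction > 0) {
      for (i in seq_len(nrow(cells))) {
        nf <- rbinom(1L, as.integer(n_reads), foreign_fraction)
        layout$n_foreign[i] <- nf
        if (nf > 0) {
          fs <- .foreign_reads(nf, read_length)
          fid <- sprintf("%s:F%06d", layout$sample_id[i], seq_len(nf))
          foreign[[length(foreign) + 1L]] <- list(
            reads = data.frame(id = fid, seq = fs,
                               qual = strrep("?", nchar(fs)),
                               stringsAsFactors = FALSE),
            manifest = data.frame(read_id = fid,
                                  sample_id = layout$sample_id[i],
                                  allele = "FOREIGN", n_errors = 0L,
                                  error_positions = "",
                                  stringsAsFactors = FALSE))
        }
      }
    }
    reads <- do.call(rbind, c(lapply(sims, `[[`, "reads"),
                              lapply(foreign, `[[`, "reads")))
    manifest <- do.call(rbind, c(lapply(sims, `[[`, "manifest"),
                                 lapply(foreign, `[[`, "manifest")))
    ord <- sample.int(nrow(reads))
    structure(list(
      reads = reads[ord, , drop = FALSE],
      manifest = manifest,
      layout = layout[c("sample_id", "barcode", "locus", "timepoint",
                        "n_reads", "n_foreign")],
      samples = setNames(sims, layout$sample_id)
    ), class = "freq_pool")
  })
}

#' @export
print.freq_pool <- function(x, ...) {
  cat("Simulated pool:", nrow(x$layout), "samples,", nrow(x$reads),
      "reads (incl.", sum(x$layout$n_foreign), "foreign)\n")
  invisible(x)
}
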