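# Demultiplexing and allele assignment.
#
# Pipeline per read: check the M13f adapter at its fixed offset (reads
# lacking it are foreign lane content), demultiplex by exact barcode match
# (a distance-2 code detects single errors but cannot correct them), then
# assign the template segment to the allele with the smallest banded global
# edit distance, requiring a margin over the runner-up.  Every failure mode
# is a status, never an exception; counts are conserved by construction.

.STATUSES <- c("ASSIGNED", "NO_M13F", "BAD_BARCODE", "AMBIGUOUS_ALLELE",
               "NO_ALLELE")

#' Banded global edit distance
#'
#' Unit-cost global (Levenshtein) distance of each string in `a` against a
#' single reference, computed by banded dynamic programming.  Distances not
#' exceeding `band` are exact; larger distances are reported as the cap
#' `band + 1`.  With the default band (the longer input length) the result
#' equals the full unbanded distance.
#'
#' @param a Character vector of query strings.
#' @param ref Single reference string.
#' @param band Band half-width; `NULL` for exact (full-band) computation.
#' @return Integer vector of distances.
#' @examples
#' edit_distance(c("ACGT", "AGGT", "ACG"), "ACGT") # 0 1 1
#' @export
edit_distance <- function(a, ref, band = NULL) {
  stopifnot(is.character(a), is.character(ref), length(ref) == 1L)
  if (is.null(band)) band <- max(nchar(a), nchar(ref), 1L)
  .edit_distance_banded(a, ref, as.integer(band), FALSE)
}

#' Locate the M13f adapter in a read
#'
#' The construct places the 17-nt M13f adapter at 0-based offset 6, directly
#' after the barcode; this is a fixed-offset check, not a scan.  Returns 6
#' where the 17-mer at that offset matches `m13f_sequence()` with at most
#' `max_mismatches` mismatches, `NA` otherwise (including reads shorter than
#' 23 bases).  Vectorised.
#'
#' @param seq Character vector of read sequences.
#' @param max_mismatches Allowed mismatches inside the 17-mer (default 1).
#' @return Integer vector: 6 or `NA`.
#' @export
locate_m13f <- function(seq, max_mismatches = 1L) {
  stopifnot(max_mismatches >= 0)
  out <- rep(NA_integer_, length(seq))
  long_enough <- !is.na(seq) & nchar(seq) >= .TEMPLATE_OFFSET
  if (any(long_enough)) {
    d <- .hamming_to_ref(substr(seq[long_enough], .M13F_OFFSET + 1L,
                                .TEMPLATE_OFFSET), m13f_sequence())
    out[long_enough][d >= 0 & d <= max_mismatches] <- .M13F_OFFSET
  }
  out
}

#' Demultiplex a read by its barcode
#'
#' Exact match of the first 6 bases against the sample map; no error
#' correction is attempted because a minimum-distance-2 code can only detect
#' single errors.  Vectorised.
#'
#' @param seq Character vector of read sequences (M13f already located).
#' @param sample_map Named character vector (`barcode -> sample_id`) or a
#'   data frame with columns `barcode` and `sample_id`.
#' @return Character vector of sample ids, `NA` where the barcode maps to no
#'   sample.
#' @export
assign_barcode <- function(seq, sample_map) {
  if (is.data.frame(sample_map)) {
    sample_map <- setNames(as.character(sample_map$sample_id),
                           sample_map$barcode)
  }
  if (anyDuplicated(names(sample_map))) {
    stop("duplicate barcodes in sample map", call. = FALSE)
  }
  bc <- substr(seq, 1L, .BARCODE_LEN)
  unname(sample_map[bc])
}

# Vectorised allele assignment of template segments (read sequence from
# 0-based offset 23 on) against a locus.  Returns a data frame with columns
# allele, distance, margin, status for each input read.
.align_to_locus <- function(seqs, loc, max_edits = NULL, min_margin = 1L) {
  alle <- loc$alleles
  refs <- vapply(alle, .allele_ref, "")
  rlens <- nchar(refs)
  n <- length(seqs)
  seg_avail <- pmax(nchar(seqs) - .TEMPLATE_OFFSET, 0L)

  # band: large enough that distances up to the decision threshold plus the
  # required margin are exact; beyond that the cap band+1 keeps ordering.
  lendiff <- max(rlens) - min(rlens)
  me_cap <- if (is.null(max_edits)) ceiling(max(pmin(max(seg_avail), rlens)) / 10)
            else max_edits
  band <- as.integer(lendiff + me_cap + max(1L, min_margin))

  dists <- matrix(NA_integer_, n, length(alle),
                  dimnames = list(NULL, names(alle)))
  medits <- matrix(NA_real_, n, length(alle))
  for (k in seq_along(alle)) {
    seg <- substr(seqs, .TEMPLATE_OFFSET + 1L, .TEMPLATE_OFFSET + rlens[k])
    dists[, k] <- .edit_distance_banded(seg, refs[k], band, TRUE)
    m <- pmin(seg_avail, rlens[k]) # compared length after truncation
    medits[, k] <- if (is.null(max_edits)) ceiling(m / 10) else max_edits
  }

  best_k <- max.col(-dists, ties.method = "first")
  best <- dists[cbind(seq_len(n), best_k)]
  tmp <- dists
  tmp[cbind(seq_len(n), best_k)] <- .Machine$integer.max
  second_k <- max.col(-tmp, ties.method = "first")
  second <- tmp[cbind(seq_len(n), second_k)]
  margin <- second - best
  thresh <- medits[cbind(seq_len(n), best_k)]

  status <- rep("ASSIGNED", n)
  status[best > thresh] <- "NO_ALLELE"
  status[best <= thresh & margin < min_margin] <- "AMBIGUOUS_ALLELE"
  out <- data.frame(
    allele = ifelse(status == "ASSIGNED", names(alle)[best_k], NA_character_),
    distance = as.integer(best),
    margin = as.integer(margin),
    status = status,
    stringsAsFactors = FALSE
  )
  out
}

#' Assign reads to an allele of a locus
#'
#' For each allele the global edit distance (unit costs) between the read
#' segment starting at 0-based offset 23 and the allele's anchor-plus-window
#' reference is computed by banded dynamic programming, both strings
#' truncated to the shorter length.  The read is assigned to the
#' minimal-distance allele if that distance is at most `max_edits` and the
#' runner-up is at least `min_margin` further away; an equal best gives
#' `AMBIGUOUS_ALLELE`, a best beyond `max_edits` gives `NO_ALLELE`.
#'
#' @param seq Character vector of full read sequences.
#' @param locus A [locus()] object.
#' @param max_edits Maximum acceptable distance; `NULL` (default) uses
#'   `ceiling(compared_length / 10)` per read/allele pair.
#' @param min_margin Required gap to the second-best allele (default 1).
#' @return Data frame with columns `allele`, `distance`, `margin`, `status`.
#' @export
align_allele <- function(seq, locus, max_edits = NULL, min_margin = 1L) {
  stopifnot(inherits(locus, "freq_locus"))
  .align_to_locus(seq, locus, max_edits, min_margin)
}

#' Count reads per sample, locus and allele
#'
#' Single pass over one or more FASTQ files: M13f check, barcode
#' demultiplexing, allele assignment, and aggregation into a count table
#' with categorised discards.  Deterministic; shuffling the input order
#' leaves the table unchanged.
#'
#' @param fastq Character vector of FASTQ paths (optionally gzipped).
#' @param config A [run_config()] object (sample map, loci, thresholds).
#' @param audit If `TRUE`, the per-read assignment stream is returned as
#'   `$audit`.
#' @return An object of class `freq_counts`: list with
#'   `counts` (data frame sample_id, locus, allele, count — full grid,
#'   zeros included), `discards` (data frame sample_id, status, count;
#'   `NO_M13F`/`BAD_BARCODE` rows carry `NA` sample_id since the read cannot
#'   be attributed), `stats` (per-sample summary incl. mean edit distance and
#'   mean quality), `total_reads`, `params`, and optionally `audit`.
#' @export
process_fastq <- function(fastq, config, audit = FALSE) {
  stopifnot(inherits(config, "freq_run_config"))
  reads <- do.call(rbind, lapply(fastq, read_fastq))
  if (is.null(reads) || nrow(reads) == 0L) {
    warning("empty FASTQ input", call. = FALSE)
    reads <- data.frame(id = character(), seq = character(),
                        qual = character())
  }
  p <- config$params
  n <- nrow(reads)
  status <- rep(NA_character_, n)
  sample_id <- rep(NA_character_, n)
  allele_nm <- rep(NA_character_, n)
  distance <- rep(NA_integer_, n)
  margin <- rep(NA_integer_, n)

  off <- locate_m13f(reads$seq, p$max_mismatches)
  status[is.na(off)] <- "NO_M13F"

  smap <- setNames(config$samples$sample_id, config$samples$barcode)
  idx <- which(is.na(status))
  if (length(idx)) {
    sid <- assign_barcode(reads$seq[idx], smap)
    sample_id[idx] <- sid
    status[idx[is.na(sid)]] <- "BAD_BARCODE"
  }

  sample_locus <- setNames(config$samples$locus, config$samples$sample_id)
  for (loc_name in unique(sample_locus)) {
    loc <- config$loci[[loc_name]]
    idx <- which(is.na(status) & sample_locus[sample_id] == loc_name)
    if (!length(idx)) next
    res <- .align_to_locus(reads$seq[idx], loc, p$max_edits, p$min_margin)
    status[idx] <- res$status
    allele_nm[idx] <- res$allele
    distance[idx] <- res$distance
    margin[idx] <- res$margin
  }

  # full (sample, locus, allele) grid so absent alleles count as zero
  grid <- do.call(rbind, lapply(seq_len(nrow(config$samples)), function(i) {
    loc <- config$loci[[config$samples$locus[i]]]
    data.frame(sample_id = config$samples$sample_id[i],
               locus = loc$name, allele = names(loc$alleles),
               stringsAsFactors = FALSE)
  }))
  asg <- status == "ASSIGNED"
  key <- paste(sample_id[asg], allele_nm[asg], sep = "\r")
  gkey <- paste(grid$sample_id, grid$allele, sep = "\r")
  grid$count <- as.integer(tabulate(match(key, gkey), nbins = nrow(grid)))

  disc <- .tally_discards(status, sample_id, config)
  stats <- .per_sample_stats(status, sample_id, distance, reads$qual, config)

  out <- structure(list(
    counts = grid,
    discards = disc,
    stats = stats,
    total_reads = n,
    params = p
  ), class = "freq_counts")
  stopifnot(sum(out$counts$count) + sum(out$discards$count) == n)
  if (audit) {
    out$audit <- data.frame(read_id = reads$id, status = status,
                            sample_id = sample_id, allele = allele_nm,
                            edit_distance = distance, margin = margin,
                            stringsAsFactors = FALSE)
  }
  out
}

.tally_discards <- function(status, sample_id, config) {
  pool <- data.frame(
    sample_id = NA_character_,
    status = c("NO_M13F", "BAD_BARCODE"),
    count = c(sum(status == "NO_M13F"), sum(status == "BAD_BARCODE")),
    stringsAsFactors = FALSE
  )
  per <- expand.grid(sample_id = config$samples$sample_id,
                     status = c("AMBIGUOUS_ALLELE", "NO_ALLELE"),
                     stringsAsFactors = FALSE)
  key <- paste(sample_id, status, sep = "\r")
  pkey <- paste(per$sample_id, per$status, sep = "\r")
  per$count <- as.integer(tabulate(match(key, pkey), nbins = nrow(per)))
  rbind(pool, per)
}

.per_sample_stats <- function(status, sample_id, distance, qual, config) {
  mean_qual <- function(q) {
    if (!length(q)) return(NA_real_)
    mean(utf8ToInt(paste(q, collapse = ""))) - 33
  }
  do.call(rbind, lapply(config$samples$sample_id, function(s) {
    i <- !is.na(sample_id) & sample_id == s
    a <- i & status == "ASSIGNED"
    data.frame(
      sample_id = s,
      n_reads = sum(i),
      n_assigned = sum(a),
      n_ambiguous = sum(i & status == "AMBIGUOUS_ALLELE"),
      n_no_allele = sum(i & status == "NO_ALLELE"),
      mean_edit_distance = if (any(a)) mean(distance[a]) else NA_real_,
      mean_quality_assigned = mean_qual(qual[a]),
      mean_quality_discarded = mean_qual(qual[i & !a]),
      stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.freq_counts <- function(x, ...) {
  cat("Read counts:", x$total_reads, "reads processed\n")
  cat("  assigned:", sum(x$counts$count), " discarded:",
      sum(x$discards$count), "\n")
  by_status <- aggregate(count ~ status, x$discards, sum)
  for (i in seq_len(nrow(by_status))) {
    cat(sprintf("    %-17s %d\n", by_status$status[i], by_status$count[i]))
  }
  cat("  counts:\n")
  print(utils::head(x$counts, 12), row.names = FALSE)
  if (nrow(x$counts) > 12) cat("  ...", nrow(x$counts), "rows\n")
  invisible(x)
}

#' Write a count table and its per-sample statistics as CSV
#'
#' @param x A `freq_counts` object.
#' @param counts_csv,stats_csv,audit_tsv Output paths (`NULL` skips; the
#'   audit stream requires `process_fastq(..., audit = TRUE)`).
#' @return Invisibly, `x`.
#' @export
write_counts <- function(x, counts_csv = NULL, stats_csv = NULL,
                         audit_tsv = NULL) {
  stopifnot(inherits(x, "freq_counts"))
  if (!is.null(counts_csv)) write.csv(x$counts, counts_csv, row.names = FALSE)
  if (!is.null(stats_csv)) {
    disc <- x$discards
    pool <- disc[is.na(disc$sample_id), ]
    stats <- x$stats
    stats$n_no_m13f_pool <- sum(pool$count[pool$status == "NO_M13F"])
    stats$n_bad_barcode_pool <- sum(pool$count[pool$status == "BAD_BARCODE"])
    write.csv(stats, stats_csv, row.names = FALSE)
  }
  if (!is.null(audit_tsv)) {
    if (is.null(x$audit)) {
      stop("no audit stream: run process_fastq(..., audit = TRUE)",
           call. = FALSE)
    }
    write.table(x$audit, audit_tsv, sep = "\t", row.names = FALSE,
                quote = FALSE)
  }
  invisible(x)
}
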