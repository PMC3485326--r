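# Barcode library design and validation.
#
# Sample barcodes are the first 6 bases of every read.  A minimum pairwise
# Hamming distance of 2 makes any single sequencing error detectable (the
# mutated barcode matches no library member), though not correctable.  The
# first four positions are additionally kept compositionally balanced,
# because strong base bias in the first sequencing cycles degrades Illumina
# cluster identification.

#' Hamming distance between equal-length DNA strings
#'
#' Number of positions at which two strings differ.  Vectorised over pairs
#' with the usual recycling rules.
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of distances.
#' @examples
#' hamming_distance("ACGTAC", "ACGTAG") # 1
#' @export
hamming_distance <- function(a, b) {
  if (!is.character(a) || !is.character(b)) {
    stop("a and b must be character vectors", call. = FALSE)
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("Hamming distance is undefined for strings of unequal length",
         call. = FALSE)
  }
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

# Integer encoding (1..4 per base) of equal-length barcodes as a matrix;
# rows are barcodes.
.bc_matrix <- function(codes) {
  t(vapply(strsplit(codes, ""), function(ch) match(ch, .DNA_BASES),
           integer(nchar(codes[1]))))
}

# All pairwise Hamming distances of a barcode set, brute force.
.pairwise_hamming <- function(codes) {
  if (length(codes) < 2) {
    return(data.frame(i = integer(), j = integer(), distance = integer()))
  }
  m <- .bc_matrix(codes)
  pairs <- combn(length(codes), 2)
  d <- vapply(seq_len(ncol(pairs)), function(k) {
    sum(m[pairs[1, k], ] != m[pairs[2, k], ])
  }, integer(1))
  data.frame(i = pairs[1, ], j = pairs[2, ], distance = d)
}

# Per-position base composition (positions x A,C,G,T fractions).
.composition <- function(codes) {
  m <- .bc_matrix(codes)
  k <- ncol(m)
  comp <- t(vapply(seq_len(k), function(p) {
    tabulate(m[, p], nbins = 4L) / nrow(m)
  }, numeric(4)))
  dimnames(comp) <- list(position = seq_len(k), base = .DNA_BASES)
  comp
}

.balance_tol <- function(n) max(0.15, 2 * sqrt(3 / 16 / n))

.balanced <- function(codes, first_k) {
  if (first_k < 1) return(TRUE)
  comp <- .composition(codes)
  first_k <- min(first_k, nrow(comp))
  tol <- .balance_tol(length(codes))
  all(abs(comp[seq_len(first_k), , drop = FALSE] - 0.25) <= tol)
}

#' Design an error-detecting barcode library
#'
#' Draws `n` distinct barcodes of the given length whose minimum pairwise
#' Hamming distance is at least `min_dist` and whose first `balance_first_k`
#' positions are compositionally balanced (every base frequency within
#' `max(0.15, 2*sqrt(3/16/n))` of 1/4).  The search is a seeded random
#' shuffle of the full sequence space with greedy accept/reject under the
#' distance constraint, restarted until the balance constraint is also met;
#' an infeasible request fails explicitly rather than returning a smaller
#' set.
#'
#' @param n Number of barcodes required.
#' @param length Barcode length in nt (default 6, the protocol's barcode).
#' @param min_dist Minimum pairwise Hamming distance (default 2: single
#'   sequencing errors are detectable but not correctable).
#' @param balance_first_k Number of leading positions subject to the
#'   composition-balance constraint (default 4, the cycles that matter for
#'   cluster identification).
#' @param seed Integer seed; the design is reproducible given the seed.
#' @param max_tries Bound on candidate evaluations per restart.
#' @param max_restarts Bound on restarts before declaring infeasibility.
#' @return An object of class `barcode_library`: list with elements
#'   `barcodes` (character), `length`, `min_pairwise_distance` (recomputed by
#'   brute force), `composition` (position x base fractions), `seed`.
#' @examples
#' lib <- design_barcodes(48, seed = 1)
#' lib$min_pairwise_distance # >= 2
#' @export
design_barcodes <- function(n, length = 6L, min_dist = 2L,
                            balance_first_k = 4L, seed = 1L,
                            max_tries = 1e5, max_restarts = 100L) {
  len <- as.integer(length)
  rm(length) # unshadow base::length
  stopifnot(n >= 1, len >= 1, min_dist >= 1, balance_first_k >= 0)
  if (4^len < n) {
    stop("infeasible: 4^", len, " < ", n, " sequences requested",
         call. = FALSE)
  }
  if (len > 10) stop("barcode length > 10 not supported", call. = FALSE)

  # full space as an integer matrix, one row per sequence
  space <- as.matrix(expand.grid(rep(list(1:4), len)))[, len:1, drop = FALSE]
  dimnames(space) <- NULL

  .with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      ord <- sample.int(nrow(space))
      acc <- integer(0)
      tries <- 0
      for (cand in ord) {
        tries <- tries + 1
        if (tries > max_tries) break
        if (length(acc) == 0L ||
            min(rowSums(space[acc, , drop = FALSE] !=
                          matrix(space[cand, ], nrow = length(acc),
                                 ncol = len, byrow = TRUE))) >= min_dist) {
          acc <- c(acc, cand)
          if (length(acc) == n) break
        }
      }
      if (length(acc) < n) next
      codes <- apply(space[acc, , drop = FALSE], 1,
                     function(r) paste(.DNA_BASES[r], collapse = ""))
      if (.balanced(codes, balance_first_k)) {
        pw <- .pairwise_hamming(codes)
        out <- structure(list(
          barcodes = codes,
          length = len,
          min_pairwise_distance = if (nrow(pw)) min(pw$distance) else NA_integer_,
          composition = .composition(codes),
          seed = seed,
          balance_first_k = as.integer(balance_first_k),
          restarts = restart
        ), class = "barcode_library")
        return(out)
      }
    }
  })
  stop("infeasible: could not assemble ", n, " barcodes of length ", len,
       " with min Hamming distance ", min_dist,
       " and the balance constraint within ", max_restarts, " restarts",
       call. = FALSE)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("Barcode library:", length(x$barcodes), "barcodes of length",
      x$length, "nt\n")
  cat("  min pairwise Hamming distance:", x$min_pairwise_distance, "\n")
  cat("  composition (first", min(4L, x$length), "positions):\n")
  print(round(x$composition[seq_len(min(4L, x$length)), , drop = FALSE], 3))
  invisible(x)
}

#' Validate a barcode library
#'
#' Recomputes all pairwise Hamming distances by brute force, reports every
#' pair below `min_dist` (and duplicate barcodes), the per-position base
#' composition, and a per-position chi-square statistic against uniform base
#' usage for the first four positions.  Report-style: never errors.
#'
#' @param lib A `barcode_library` or a character vector of equal-length
#'   barcodes.
#' @param min_dist Minimum acceptable pairwise Hamming distance.
#' @return An object of class `barcode_validation`: list with `pass`,
#'   `min_distance`, `violations` (data frame of offending pairs),
#'   `composition`, and `chisq` (data frame: position, statistic, df,
#'   p.value).
#' @examples
#' v <- validate_barcodes(c("AAAAAA", "AAAAAT"), min_dist = 2)
#' v$pass # FALSE: distance 1 pair
#' @export
validate_barcodes <- function(lib, min_dist = 2L) {
  codes <- if (inherits(lib, "barcode_library")) lib$barcodes else lib
  codes <- .check_dna(codes, "barcodes")
  if (length(unique(nchar(codes))) != 1L) {
    stop("barcodes must all have the same length", call. = FALSE)
  }
  pw <- .pairwise_hamming(codes)
  viol <- pw[pw$distance < min_dist, , drop = FALSE]
  viol <- data.frame(barcode1 = codes[viol$i], barcode2 = codes[viol$j],
                     distance = viol$distance)
  comp <- .composition(codes)
  kmax <- min(4L, nchar(codes[1]))
  n <- length(codes)
  chisq <- do.call(rbind, lapply(seq_len(kmax), function(p) {
    obs <- comp[p, ] * n
    stat <- sum((obs - n / 4)^2 / (n / 4))
    data.frame(position = p, statistic = stat, df = 3,
               p.value = pchisq(stat, df = 3, lower.tail = FALSE))
  }))
  structure(list(
    pass = nrow(viol) == 0L && !anyDuplicated(codes),
    min_distance = if (nrow(pw)) min(pw$distance) else NA_integer_,
    violations = viol,
    composition = comp,
    chisq = chisq,
    min_dist_required = as.integer(min_dist)
  ), class = "barcode_validation")
}

#' @export
print.barcode_validation <- function(x, ...) {
  cat("Barcode validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  min pairwise distance:", x$min_distance,
      "(required >=", paste0(x$min_dist_required, ")"), "\n")
  if (nrow(x$violations)) {
    cat("  offending pairs:\n")
    print(x$violations)
  }
  cat("  chi-square vs uniform base usage (positions 1-",
      max(x$chisq$position), "):\n", sep = "")
  print(x$chisq, row.names = FALSE)
  invisible(x)
}

#' Assemble a bridging primer for a barcode
#'
#' The 81-nt bridging primer is the fixed 58-nt Illumina "A"-side prefix,
#' the 6-nt barcode, then the 17-nt M13f tail; the barcode occupies
#' positions 59-64 (1-based).  Vectorised over barcodes.
#'
#' @param bc Character vector of 6-nt barcodes.
#' @return Named character vector of 81-nt primer sequences (names = barcodes).
#' @examples
#' nchar(bridging_primer("ACGTAC")) # 81
#' @export
bridging_primer <- function(bc) {
  bc <- .check_dna(bc, "barcode", len = .BARCODE_LEN)
  setNames(paste0(bridging_prefix(), bc, m13f_sequence()), bc)
}

#' Write bridging primers as FASTA and the library manifest as CSV
#'
#' @param lib A `barcode_library`.
#' @param fasta,csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the manifest data frame.
#' @export
write_barcode_library <- function(lib, fasta = NULL, csv = NULL) {
  stopifnot(inherits(lib, "barcode_library"))
  primers <- bridging_primer(lib$barcodes)
  if (!is.null(fasta)) {
    set <- Biostrings::DNAStringSet(primers)
    names(set) <- lib$barcodes
    Biostrings::writeXStringSet(set, fasta)
  }
  comp <- lib$composition
  manifest <- data.frame(
    index = seq_along(lib$barcodes),
    barcode = lib$barcodes,
    min_pairwise_distance = lib$min_pairwise_distance
  )
  for (b in colnames(comp)) {
    for (p in seq_len(nrow(comp))) {
      manifest[[paste0("comp_pos", p, "_", b)]] <- comp[p, b]
    }
  }
  if (!is.null(csv)) write.csv(manifest, csv, row.names = FALSE)
  invisible(manifest)
}
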