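# FASTQ input/output, delegated to Biostrings.

#' Write simulated reads to FASTQ
#'
#' @param x A `freq_sim`, `freq_pool`, or data frame with columns
#'   `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix writes gzip-compressed FASTQ.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(x, path) {
  reads <- if (is.data.frame(x)) x else x$reads
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  set <- Biostrings::DNAStringSet(reads$seq)
  names(set) <- reads$id
  x <- Biostrings::QualityScaledDNAStringSet(
    set, Biostrings::PhredQuality(reads$qual))
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ path (optionally gzip-compressed).
#' @return Data frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) {
        stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }),
    # readFastq keeps the record ids in mcols; the quality-scaled
    # constructor drops them with a warning that is noise here
    warning = function(w) {
      if (grepl("metadata columns .* dropped", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}
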